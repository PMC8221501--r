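{"class_of_sample":[{"sample_id":"S001","class":1},{"sample_id":"S002","class":1},{"sample_id":"S003","class":1},{"sample_id":"S004","class":1},{"sample_id":"S005","class":1},{"sample_id":"S006","class":1},{"sample_id":"S007","class":1},{"sample_id":"S008","class":1},{"sample_id":"S009","class":1},{"sample_id":"S010","class":1},{"sample_id":"S011","class":1},{"sample_id":"S012","class":1},{"sample_id":"S013","class":2},{"sample_id":"S014","class":2},{"sample_id":"S015","class":2},{"sample_id":"S016","class":2},{"sample_id":"S017","class":2},{"sample_id":"S018","class":2},{"sample_id":"S019","class":2},{"sample_id":"S020","class":2},{"sample_id":"S021","class":2},{"sample_id":"S022","class":2},{"sample_id":"S023","class":2},{"sample_id":"S024","class":2}],"hub_genes":"G001","triads":[{"gene_i":"G008","gene_j":"G009","gene_k":"G010","code":"030"}],"informative_genes":["G001","G002","G004","G005","G009","G012"]}
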