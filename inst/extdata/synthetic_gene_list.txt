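# synthetic example gene list (all genes of the bundled cohort)
G001 NR
G002 coregulator
G003 coregulator
G004 coregulator
G005 coregulator
G006 coregulator
G007 coregulator
G008 coregulator
G009 coregulator
G010 coregulator
G011 coregulator
G012 coregulator
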