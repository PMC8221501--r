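test_that("NPU codes count negative, positive and absent pairs", {
  expect_equal(npu_code(c("positive", "positive", "absent")), "021")
  expect_equal(npu_code(c("absent", "absent", "absent")), "003")
  expect_equal(npu_code(c("positive", "positive", "positive")), "030")
  expect_equal(npu_code(c("negative", "positive", "absent")), "111")
  # order-invariant
  expect_equal(npu_code(c("absent", "positive", "positive")), "021")
})

test_that("topology and coherence follow the edge count and sign product", {
  cl <- classify_triad(c("positive", "positive", "positive"))
  expect_equal(cl[c("code", "topology", "coherence")],
               list(code = "030", topology = "complete", coherence = "coherent"))
  cl <- classify_triad(c("negative", "positive", "positive"))
  expect_equal(cl$code, "120")
  expect_equal(cl$coherence, "incoherent")
  cl <- classify_triad(c("positive", "positive", "absent"))
  expect_equal(cl$topology, "linear")
  expect_equal(cl$coherence, "n/a")
  expect_equal(classify_triad(c("absent", "absent", "absent"))$topology, "empty")
  expect_equal(classify_triad(c("negative", "absent", "absent"))$topology, "one_edge")

  # all 8 complete sign assignments: coherent iff the sign product is +1
  signs <- c(-1, 1)
  for (a in signs) for (b in signs) for (c_ in signs) {
    states <- ifelse(c(a, b, c_) > 0, "positive", "negative")
    got <- classify_triad(states)$coherence
    expect_equal(got, if (a * b * c_ > 0) "coherent" else "incoherent")
  }
})

test_that("the exhaustive configuration census reproduces the signed-triad combinatorics", {
  en <- enumerate_npu_configurations()
  expect_equal(en$total, 27L)
  expect_equal(en$n_codes, 10L)
  expect_equal(en$codes$n_configurations[en$codes$code == "111"], 6L)
  expect_equal(en$n_linear_configurations, 12L)
  expect_equal(en$n_complete_configurations, 8L)
  expect_equal(sum(en$codes$n_configurations), 27L)
  expect_setequal(en$configurations$code[en$configurations$topology == "linear"],
                  c("021", "201", "111"))
  expect_setequal(en$configurations$code[en$configurations$topology == "complete"],
                  c("120", "210", "030", "300"))
})

test_that("hub local networks contain exactly the radius-2 induced subgraph", {
  path <- signed_network(c("H", "A", "B", "C"), tibble::tibble(
    gene_i = c("H", "A", "B"), gene_j = c("A", "B", "C"), weight = c(1, 1, 1) * 0.5))
  loc <- hub_local_network(path, "H")
  expect_setequal(loc$nodes, c("H", "A", "B"))
  expect_equal(nrow(loc$edges), 2L)   # the B-C edge leaves the induced set

  lonely <- signed_network(c("H", "X", "Y"), tibble::tibble(
    gene_i = "X", gene_j = "Y", weight = 0.5))
  loc2 <- hub_local_network(lonely, "H")
  expect_equal(loc2$nodes, "H")
  expect_equal(nrow(loc2$edges), 0L)

  tri <- signed_network(c("H", "A", "B"), tibble::tibble(
    gene_i = c("H", "H", "A"), gene_j = c("A", "B", "B"), weight = c(0.5, 0.5, -0.2)))
  expect_setequal(hub_local_network(tri, "H")$nodes, c("H", "A", "B"))
  expect_error(hub_local_network(tri, "ZZ"), "data error")
})

test_that("hub-centred censuses classify the canonical small cases", {
  v_shape <- signed_network(c("H", "A", "B"), tibble::tibble(
    gene_i = c("H", "H"), gene_j = c("A", "B"), weight = c(0.5, 0.6)))
  cen <- census_hub_motifs(hub_local_network(v_shape, "H"))
  expect_equal(cen$counts$n[cen$counts$code == "021"], 1L)
  expect_equal(sum(cen$counts$n), 1L)
  expect_equal(cen$triads$centre, "H")

  tri <- signed_network(c("H", "A", "B"), tibble::tibble(
    gene_i = c("H", "H", "A"), gene_j = c("A", "B", "B"), weight = c(0.5, 0.5, 0.2)))
  cen2 <- census_hub_motifs(hub_local_network(tri, "H"))
  expect_equal(cen2$counts$n[cen2$counts$code == "030"], 1L)

  # a linear chain through the hub records the hub as centre only when it is
  chain <- signed_network(c("A", "H", "B"), tibble::tibble(
    gene_i = c("A", "H"), gene_j = c("H", "B"), weight = c(0.5, -0.5)))
  cen3 <- census_hub_motifs(hub_local_network(chain, "H"))
  expect_equal(cen3$triads$code, "111")
  expect_equal(cen3$triads$centre, "H")
})

test_that("census counts equal the exhaustive triple enumeration on random graphs", {
  for (seed in 1:6) {
    net <- random_signed_network(sample(8:15, 1), p_edge = 0.3, seed = seed)
    hub <- net$nodes[1]
    loc <- hub_local_network(net, hub)
    cen <- census_hub_motifs(loc)
    oracle <- oracle_triad_census(loc$nodes, loc$edges, hub = hub)
    expect_equal(stats::setNames(cen$counts$n, cen$counts$code), oracle)
    # conservation: counts sum to the number of edge-bearing hub triples
    expect_equal(sum(cen$counts$n), nrow(cen$triads))
    # permutation invariance of node labelling
    relabel <- stats::setNames(sample(LETTERS, length(loc$nodes)), loc$nodes)
    loc2 <- loc
    loc2$hub <- unname(relabel[loc$hub])
    loc2$nodes <- unname(relabel[loc$nodes])
    loc2$edges$gene_i <- unname(relabel[loc$edges$gene_i])
    loc2$edges$gene_j <- unname(relabel[loc$edges$gene_j])
    cen2 <- census_hub_motifs(loc2)
    expect_equal(cen2$counts$n, cen$counts$n)
  }
})

test_that("the all-triples sensitivity mode counts non-hub triples too", {
  net <- random_signed_network(10, p_edge = 0.4, seed = 3)
  loc <- hub_local_network(net, net$nodes[1])
  cen_all <- census_hub_motifs(loc, hub_all_triples = TRUE)
  oracle_all <- oracle_triad_census(loc$nodes, loc$edges, hub = NULL)
  expect_equal(stats::setNames(cen_all$counts$n, cen_all$counts$code), oracle_all)
  expect_gte(sum(cen_all$counts$n), sum(census_hub_motifs(loc)$counts$n))
})

test_that("conservation requires enough networks spanning both cohorts", {
  mk_census <- function(code, topology, genes = c("A", "H", "Z")) {
    srt <- sort(genes)
    structure(list(hub = "H",
                   counts = tibble::tibble(code = MOTIF_CODES,
                                           n = as.integer(MOTIF_CODES == code)),
                   triads = tibble::tibble(gene_a = srt[1], gene_b = srt[2],
                                           gene_c = srt[3], code = code,
                                           topology = topology,
                                           coherence = "n/a", centre = "H")),
              class = "motif_census")
  }
  entry <- function(net, cohort, census) list(network = net, cohort = cohort,
                                              census = census)
  nets <- sprintf("net%d", 1:8)
  cohorts <- rep(c("tcga", "metabric"), each = 4)

  # present in 6 of 8 networks across the two cohorts: reported
  censuses <- purrr::map2(nets, cohorts, function(nm, co) {
    entry(nm, co, if (nm %in% c("net4", "net8")) mk_census("021", "linear", c("X", "H", "Y"))
          else mk_census("021", "linear"))
  })
  rep1 <- cross_network_conservation(censuses, min_networks = 6, min_cohorts = 2)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$n_networks, 6L)
  expect_equal(rep1$net1, "Present(linear, 021)")
  expect_equal(rep1$net4, "Absent")

  # present in 5 networks of a single cohort: not reported
  censuses2 <- purrr::map2(nets, cohorts, function(nm, co) {
    entry(nm, co, if (co == "tcga" || nm == "net5") mk_census("021", "linear")
          else mk_census("021", "linear", c("P", "Q", "R")))
  })
  rep2 <- cross_network_conservation(censuses2, min_networks = 6, min_cohorts = 2)
  expect_false(any(rep2$gene_a == "A" & rep2$gene_b == "H" & rep2$gene_c == "Z"))

  # the same triple with different codes is reported once, per-network codes kept
  censuses3 <- purrr::map2(nets, cohorts, function(nm, co) {
    entry(nm, co, if (nm %in% c("net1", "net2")) mk_census("030", "complete")
          else mk_census("021", "linear"))
  })
  rep3 <- cross_network_conservation(censuses3, min_networks = 6, min_cohorts = 2)
  expect_equal(nrow(rep3), 1L)
  expect_equal(rep3$net1, "Present(complete, 030)")
  expect_equal(rep3$net3, "Present(linear, 021)")

  expect_error(cross_network_conservation(censuses, min_networks = 9),
               "configuration error")
})

test_that("a planted triad surviving thresholding appears with its planted code", {
  st <- plant_precision(40, hub_count = 0,
                        triads = list(list(genes = c(5, 6, 7), code = "030"),
                                      list(genes = c(20, 21, 22), code = "120")),
                        base_weight = 0.45, seed = 6)
  cfg <- sim_config(n_genes = 40, n_per_subtype = c(Basal = 75, LuminalA = 75),
                    n_classes = 2, class_mean_shift = 0, seed = 6)
  sim <- simulate_cohort(cfg, st)
  pc <- partial_correlations(sim$expression)
  net <- threshold_edges(rank_edges(pc), fraction = 0.01, nodes = rownames(pc$values))
  keys <- paste(net$edges$gene_i, net$edges$gene_j)
  for (i in seq_len(nrow(st$triads))) {
    tr <- sort(unlist(st$triads[i, c("gene_i", "gene_j", "gene_k")]))
    pairs <- paste(c(tr[1], tr[1], tr[2]), c(tr[2], tr[3], tr[3]))
    if (!all(pairs %in% keys)) next    # an edge fell below the cut
    loc <- hub_local_network(net, tr[1])
    cen <- census_hub_motifs(loc)
    hit <- cen$triads$gene_a == tr[1] & cen$triads$gene_b == tr[2] &
      cen$triads$gene_c == tr[3]
    expect_true(any(hit))
    expect_equal(cen$triads$code[hit], st$triads$code[i])
  }
})

test_that("census tables write in the hub-by-network layout", {
  net <- random_signed_network(10, p_edge = 0.4, seed = 2)
  cen <- census_hub_motifs(hub_local_network(net, net$nodes[1]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_census_table(list(list(network = "netA", cohort = "c1", census = cen)), path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(tab), c("hub", "network", MOTIF_CODES))
})
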