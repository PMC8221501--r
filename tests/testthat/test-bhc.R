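make_discrete <- function(codes) {
  structure(list(codes = codes, bin_edges = NULL, constant_genes = character(0)),
            class = "nr_discrete")
}

# hand-built dendrogram: merges = list(c(left, right, log_odds), ...) in
# creation order; node ids continue after the n leaves
make_tree <- function(labels, merges) {
  n <- length(labels)
  m <- n + length(merges)
  left <- right <- rep(NA_integer_, m)
  size <- rep(1L, m)
  log_odds <- log_ml <- log_d <- log_p <- rep(NA_real_, m)
  members <- as.list(seq_len(n))
  for (k in seq_along(merges)) {
    id <- n + k
    left[id] <- merges[[k]][1]
    right[id] <- merges[[k]][2]
    log_odds[id] <- merges[[k]][3]
    members[[id]] <- c(members[[left[id]]], members[[right[id]]])
    size[id] <- length(members[[id]])
  }
  nrstrata:::new_bhc_tree(labels, left, right, size, log_odds, log_ml, log_d,
                          log_p, members, root = m, n = n)
}

test_that("an identical pair of samples merges before a dissimilar one", {
  codes <- cbind(a = c(0L, 2L, 1L, 0L), b = c(0L, 2L, 1L, 0L), c = c(2L, 0L, 0L, 2L))
  rownames(codes) <- paste0("g", 1:4)
  tree <- bhc(make_discrete(codes))
  first_merge <- tree$nodes[tree$nodes$id == 4, ]
  expect_equal(sort(c(first_merge$left, first_merge$right)), c(1L, 2L))
})

test_that("a single sample yields a lone leaf with no merges", {
  codes <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(paste0("g", 1:3), "only"))
  tree <- bhc(make_discrete(codes))
  expect_equal(tree$n_leaves, 1L)
  expect_equal(tree$root, 1L)
  expect_true(all(is.na(tree$nodes$log_odds)))
  expect_equal(cut_clusters(tree)$cluster, 1L)
})

test_that("greedy-tree root evidence matches an independent slow recursion", {
  for (case in list(list(n = 5, alpha = 1, beta = c(1, 1, 1), seed = 1),
                    list(n = 8, alpha = 1, beta = c(1, 1, 1), seed = 2),
                    list(n = 7, alpha = 0.5, beta = c(0.5, 1, 2), seed = 3))) {
    set.seed(case$seed)
    codes <- matrix(sample(0:2, 6 * case$n, replace = TRUE), nrow = 6,
                    dimnames = list(paste0("g", 1:6), paste0("s", seq_len(case$n))))
    tree <- bhc(make_discrete(codes), alpha = case$alpha, pseudocounts = case$beta)
    expect_equal(tree$nodes$log_p[tree$root],
                 oracle_bhc_evidence(tree, codes, case$alpha, case$beta),
                 tolerance = 1e-8)
  }
})

test_that("cluster cutting keeps maximal all-positive subtrees", {
  # all merges preferred: one cluster of everything
  t1 <- make_tree(paste0("s", 1:3), list(c(1, 2, 5), c(4, 3, 2)))
  expect_equal(unique(cut_clusters(t1)$cluster), 1L)
  # no merge preferred: all singletons
  t2 <- make_tree(paste0("s", 1:3), list(c(1, 2, -5), c(4, 3, -2)))
  expect_equal(sort(cut_clusters(t2)$cluster), 1:3)
  # negative only at the root: the root's two children
  t3 <- make_tree(paste0("s", 1:4), list(c(1, 2, 3), c(3, 4, 2), c(5, 6, -1)))
  cl <- cut_clusters(t3)
  expect_equal(cl$cluster[match(paste0("s", 1:4), cl$sample_id)], c(1L, 1L, 2L, 2L))
})

test_that("class consolidation splits the top fusions down to whole clusters", {
  # balanced 4-leaf tree, everything below the root preferred
  t <- make_tree(paste0("s", 1:4), list(c(1, 2, 4), c(3, 4, 5), c(5, 6, -2)))
  classes <- consolidate_classes(t, max_classes = 2)
  expect_equal(classes$class[match(paste0("s", 1:4), classes$sample_id)],
               c(1L, 1L, 2L, 2L))
  # clusters already fewer than the cap: classes coincide with clusters
  cl <- cut_clusters(t)
  cls <- consolidate_classes(t, max_classes = 5)
  expect_equal(cls$class, cl$cluster)
  # the cap is binding when clusters are many
  t5 <- make_tree(paste0("s", 1:4),
                  list(c(1, 2, -1), c(3, 4, -1), c(5, 6, -3)))
  expect_equal(max(consolidate_classes(t5, max_classes = 2)$class), 2L)
  expect_equal(max(consolidate_classes(t5, max_classes = 4)$class), 4L)
  expect_error(consolidate_classes(t5, max_classes = 1), "configuration error")
})

test_that("class labels follow the dominance thresholds", {
  mk <- function(n_a, n_b, st_a, st_b) {
    list(classes = tibble::tibble(sample_id = paste0("s", seq_len(n_a + n_b)), class = 1L),
         ann = tibble::tibble(sample_id = paste0("s", seq_len(n_a + n_b)),
                              subtype = c(rep(st_a, n_a), rep(st_b, n_b))))
  }
  x <- mk(97, 1, "Basal", "LuminalA")
  expect_equal(tidy(label_classes(x$classes, x$ann))$label, "dominant(Basal)")
  x <- mk(50, 13, "Basal", "LuminalB")
  expect_equal(tidy(label_classes(x$classes, x$ann))$label,
               "insubstantial_dominant(Basal)")
  x <- mk(20, 22, "Basal", "Her2")
  expect_equal(tidy(label_classes(x$classes, x$ann))$label, "ambiguous")
})

test_that("labelling is symmetric under subtype relabelling", {
  classes <- tibble::tibble(sample_id = paste0("s", 1:40),
                            class = rep(1:2, each = 20))
  ann <- tibble::tibble(sample_id = paste0("s", 1:40),
                        subtype = rep(c("Basal", "LuminalA"), each = 20))
  swapped <- dplyr::mutate(ann, subtype = ifelse(.data$subtype == "Basal",
                                                 "LuminalA", "Basal"))
  l1 <- tidy(label_classes(classes, ann))
  l2 <- tidy(label_classes(classes, swapped))
  expect_equal(l1$label, c("dominant(Basal)", "dominant(LuminalA)"))
  expect_equal(l2$label, c("dominant(LuminalA)", "dominant(Basal)"))
})

test_that("clustering output is invariant to sample order", {
  sim <- standard_cohort(seed = 21, n_genes = 20, n_per = 15)
  disc <- discretize_tertiles(median_center(sim$expression))
  part1 <- cut_clusters(bhc(disc))
  perm <- sample(ncol(disc$codes))
  disc2 <- disc
  disc2$codes <- disc$codes[, perm]
  part2 <- cut_clusters(bhc(disc2))
  m <- merge(part1, part2, by = "sample_id")
  expect_equal(mclust::adjustedRandIndex(m$cluster.x, m$cluster.y), 1)
})

test_that("class and cluster assignments partition the samples", {
  sim <- standard_cohort(seed = 5, n_genes = 20, n_per = 15)
  disc <- discretize_tertiles(median_center(sim$expression))
  tree <- bhc(disc)
  for (part in list(cut_clusters(tree), consolidate_classes(tree, max_classes = 4))) {
    expect_setequal(part$sample_id, colnames(disc$codes))
    expect_false(anyDuplicated(part$sample_id) > 0)
  }
})

test_that("a strongly shifted two-class cohort is recovered", {
  sim <- standard_cohort(seed = 31)
  disc <- discretize_tertiles(median_center(sim$expression))
  classes <- consolidate_classes(bhc(disc), max_classes = 2)
  expect_gte(recovery_ari(classes, sim$truth$class_of_sample), 0.9)
})

test_that("the dendrogram exports as Newick with log-odds labels", {
  t <- make_tree(c("A", "B", "C"), list(c(1, 2, 2.5), c(4, 3, -1)))
  s <- export_newick(t)
  expect_match(s, "^\\(\\(A,B\\)2\\.5,C\\)-1;$")
})
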