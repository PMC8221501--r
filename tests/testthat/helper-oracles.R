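# Independent slow oracles used to cross-check the fast implementations.

# Partial correlations by residual regression: regress genes i and j on all
# remaining genes and correlate the residuals. Complete data only.
oracle_pcor_residuals <- function(x) {
  # x: samples x genes
  p <- ncol(x)
  out <- diag(p)
  dimnames(out) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- stats::residuals(stats::lm(x[, i] ~ others))
      rj <- stats::residuals(stats::lm(x[, j] ~ others))
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# Dirichlet-multinomial log marginal likelihood of a block of codes,
# written plainly (per-gene loops, direct counts).
oracle_dm_logml <- function(codes_block, beta) {
  total <- 0
  for (g in seq_len(nrow(codes_block))) {
    cs <- codes_block[g, ]
    cs <- cs[!is.na(cs)]
    counts <- c(sum(cs == 0), sum(cs == 1), sum(cs == 2))
    total <- total + lgamma(sum(beta)) - lgamma(length(cs) + sum(beta)) +
      sum(lgamma(counts + beta) - lgamma(beta))
  }
  total
}

# Tree evidence by the Dirichlet-process recursion, evaluated in raw
# (non-log) space from scratch at every node. Only safe at tiny n.
oracle_bhc_evidence <- function(tree, codes, alpha, beta) {
  rec <- function(id) {
    if (id <= tree$n_leaves) {
      return(list(d = alpha, p = exp(oracle_dm_logml(codes[, id, drop = FALSE], beta))))
    }
    l <- rec(tree$nodes$left[id])
    r <- rec(tree$nodes$right[id])
    members <- tree$members[[id]]
    n_k <- length(members)
    d_k <- alpha * gamma(n_k) + l$d * r$d
    pi_k <- alpha * gamma(n_k) / d_k
    ml <- exp(oracle_dm_logml(codes[, members, drop = FALSE], beta))
    list(d = d_k, p = pi_k * ml + (1 - pi_k) * l$p * r$p)
  }
  log(rec(tree$root)$p)
}

# Exhaustive signed triad census: every unordered triple (optionally
# restricted to those containing `hub`) with at least two present edges.
oracle_triad_census <- function(nodes, edges, hub = NULL) {
  state <- function(a, b) {
    hit <- (edges$gene_i == a & edges$gene_j == b) |
      (edges$gene_i == b & edges$gene_j == a)
    if (any(hit)) edges$sign[hit][1] else "absent"
  }
  counts <- stats::setNames(integer(length(MOTIF_CODES)), MOTIF_CODES)
  if (length(nodes) < 3) return(counts)
  for (tr in utils::combn(nodes, 3, simplify = FALSE)) {
    if (!is.null(hub) && !hub %in% tr) next
    signs <- c(state(tr[1], tr[2]), state(tr[1], tr[3]), state(tr[2], tr[3]))
    if (sum(signs != "absent") < 2) next
    code <- paste0(sum(signs == "negative"), sum(signs == "positive"),
                   sum(signs == "absent"))
    counts[code] <- counts[code] + 1L
  }
  counts
}

# Random signed network on n nodes with edge probability p_edge.
random_signed_network <- function(n_nodes, p_edge = 0.25, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  w <- stats::runif(sum(keep), 0.1, 1) * sample(c(-1, 1), sum(keep), replace = TRUE)
  edges <- tibble::tibble(gene_i = pairs[keep, 1], gene_j = pairs[keep, 2], weight = w)
  signed_network(nodes, edges)
}

# Small simulated two-class cohort under the standard study conditions.
standard_cohort <- function(seed, shift = 3, n_genes = 50, n_per = 60,
                            frac_informative = 0.4) {
  st <- plant_precision(n_genes, hub_count = 1,
                        hub_degree = min(10, n_genes - 4),
                        triads = list(list(genes = n_genes - c(2, 1, 0),
                                           code = "030")),
                        base_weight = 0.25, seed = seed)
  cfg <- sim_config(n_genes = n_genes,
                    n_per_subtype = c(Basal = n_per, LuminalA = n_per),
                    n_classes = 2, class_mean_shift = shift,
                    fraction_informative = frac_informative, seed = seed)
  simulate_cohort(cfg, st)
}

# ARI between a recovered class assignment tibble and the planted truth.
recovery_ari <- function(classes, truth) {
  m <- merge(classes, truth, by = "sample_id")
  mclust::adjustedRandIndex(m[[2]], m[[3]])
}
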