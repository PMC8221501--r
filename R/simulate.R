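#' Partial correlations implied by a precision matrix
#'
#' Closed-form scaling of a precision (inverse-covariance) matrix to the
#' partial-correlation matrix: `r_ij = -p_ij / sqrt(p_ii * p_jj)` with a
#' unit diagonal. Used as the ground-truth oracle for network recovery
#' tests.
#'
#' @param precision symmetric positive-definite matrix.
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_cor_from_precision <- function(precision) {
  stopifnot(is.matrix(precision), isSymmetric(unname(precision)))
  d <- sqrt(diag(precision))
  r <- -precision / tcrossprod(d)
  diag(r) <- 1
  r
}

triad_signs_from_code <- function(code) {
  digits <- as.integer(strsplit(code, "")[[1]])
  if (length(digits) != 3 || sum(digits) != 3) {
    stop("configuration error: NPU code must be three digits summing to 3: ", code,
         call. = FALSE)
  }
  # edges in fixed order (i-j, i-k, j-k): negatives first, then positives,
  # then absent -- one canonical representative per code
  rep(c(-1L, 1L, 0L), times = digits)
}

#' Plant a sparse precision matrix with hubs and signed triads
#'
#' Builds the ground-truth Gaussian graphical model for the synthetic
#' cohorts: identity diagonal, a star of `hub_degree` edges around each of
#' the first `hub_count` genes, plus the edges of the requested signed
#' triads. The sign convention follows partial correlations: a requested
#' positive association is encoded as a negative off-diagonal precision
#' entry (and vice versa), so [partial_cor_from_precision()] of the result
#' reproduces the requested sign pattern exactly. Positive definiteness is
#' enforced by diagonal loading until the smallest eigenvalue reaches 0.1.
#'
#' @param n_genes number of genes.
#' @param hub_count number of hub genes (placed at indices `1:hub_count`).
#' @param hub_degree star degree of each hub.
#' @param triads list of `list(genes = c(i, j, k), code = "030")` entries;
#'   the NPU code's negative/positive/absent digits are laid onto the edges
#'   (i-j, i-k, j-k) in that order.
#' @param base_weight magnitude of each planted off-diagonal entry.
#' @param hub_sign sign of the hubs' partial correlations (+1 or -1).
#' @param seed integer seed controlling the random choice of hub partners.
#' @return A list of class `planted_structure` with elements `precision`
#'   (dimnames `G001`, ...), `hub_genes`, `triads` (tibble of planted gene
#'   triples and codes), and `gene_ids`.
#' @export
plant_precision <- function(n_genes, hub_count = 1, hub_degree = 10,
                            triads = list(), base_weight = 0.25,
                            hub_sign = 1, seed = 1) {
  stopifnot(n_genes >= 3, hub_count >= 0, hub_degree >= 0)
  if (hub_count * hub_degree + 3L * length(triads) > n_genes * (n_genes - 1) / 2) {
    stop("configuration error: requested edges exceed available gene pairs", call. = FALSE)
  }
  genes <- sprintf("G%03d", seq_len(n_genes))
  omega <- diag(n_genes)
  dimnames(omega) <- list(genes, genes)
  requested <- new.env(parent = emptyenv())

  set_edge <- function(i, j, pcor_sign) {
    if (i == j) stop("configuration error: self-edge requested", call. = FALSE)
    key <- paste(sort(c(i, j)), collapse = "-")
    prev <- requested[[key]]
    if (!is.null(prev) && prev != pcor_sign) {
      stop("configuration error: conflicting signs requested for edge ", key, call. = FALSE)
    }
    requested[[key]] <- pcor_sign
    omega[i, j] <<- omega[j, i] <<- -pcor_sign * base_weight
  }

  set.seed(seed)
  hub_idx <- seq_len(hub_count)
  for (h in hub_idx) {
    pool <- setdiff(seq_len(n_genes), hub_idx)
    partners <- sample(pool, hub_degree)
    for (p in partners) set_edge(h, p, hub_sign)
  }

  triad_rows <- purrr::map(triads, function(tr) {
    idx <- tr$genes
    stopifnot(length(idx) == 3, !anyDuplicated(idx))
    signs <- triad_signs_from_code(tr$code)
    pairs <- rbind(idx[c(1, 2)], idx[c(1, 3)], idx[c(2, 3)])
    for (e in 1:3) if (signs[e] != 0) set_edge(pairs[e, 1], pairs[e, 2], signs[e])
    tibble::tibble(gene_i = genes[idx[1]], gene_j = genes[idx[2]],
                   gene_k = genes[idx[3]], code = tr$code)
  })

  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0.1) diag(omega) <- diag(omega) + (0.1 - min(ev))

  structure(list(
    precision = omega,
    hub_genes = genes[hub_idx],
    triads = dplyr::bind_rows(triad_rows),
    gene_ids = genes
  ), class = "planted_structure")
}

#' Simulation configuration for synthetic cohorts
#'
#' @param n_genes number of genes.
#' @param n_per_subtype named integer vector, samples per subtype (exactly
#'   two subtypes).
#' @param n_classes number of latent patient classes (>= 2). Classes 1 and
#'   2 are pure one-subtype classes; classes 3 and above are 50/50 mixed,
#'   emulating ambiguous classes.
#' @param class_mean_shift mean shift of informative genes between classes,
#'   in units of each gene's residual standard deviation.
#' @param fraction_informative fraction of genes carrying the class shift.
#' @param seed integer seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 50,
                       n_per_subtype = c(Basal = 60, LuminalA = 60),
                       n_classes = 2,
                       class_mean_shift = 3,
                       fraction_informative = 0.4,
                       seed = 1) {
  stopifnot(n_genes >= 3, length(n_per_subtype) == 2, all(n_per_subtype >= 1),
            !is.null(names(n_per_subtype)), n_classes >= 2,
            fraction_informative > 0, fraction_informative <= 1)
  structure(list(n_genes = n_genes, n_per_subtype = n_per_subtype,
                 n_classes = n_classes, class_mean_shift = class_mean_shift,
                 fraction_informative = fraction_informative, seed = seed),
            class = "sim_config")
}

#' Simulate an expression cohort with planted structure
#'
#' Each sample belongs to a latent class; its expression is the class mean
#' profile plus a multivariate-Gaussian residual whose covariance is the
#' inverse of the planted precision matrix. Class 1 is all one subtype and
#' class 2 all the other (the subtype-dominant classes); any further class
#' mixes both subtypes 50/50 (the ambiguous classes). Informative genes are
#' shifted by `class_mean_shift` residual standard deviations with a
#' class-specific sign pattern. Fully deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @param structure a [plant_precision()] result with `n_genes` genes.
#' @return A list with `expression` ([nr_expr]), `annotation` (tibble of
#'   `sample_id`, `subtype`) and `truth` (the `planted_structure` extended
#'   with `class_of_sample`, `class_means` and `informative_genes`).
#' @export
simulate_cohort <- function(cfg, structure) {
  stopifnot(inherits(cfg, "sim_config"), inherits(structure, "planted_structure"))
  p <- cfg$n_genes
  if (nrow(structure$precision) != p) {
    stop("configuration error: structure dimension does not match config", call. = FALSE)
  }
  ev <- eigen(structure$precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("configuration error: precision not positive definite", call. = FALSE)

  set.seed(cfg$seed)
  sigma <- solve(structure$precision)
  sd_g <- sqrt(diag(sigma))
  genes <- structure$gene_ids
  subtypes <- names(cfg$n_per_subtype)

  # sample -> (subtype, class)
  per_class <- list()
  for (st_i in 1:2) {
    n_st <- cfg$n_per_subtype[[st_i]]
    n_mixed_classes <- max(cfg$n_classes - 2L, 0L)
    # reserve roughly a third of each subtype for the mixed classes
    n_to_mixed <- if (n_mixed_classes > 0) floor(n_st / 3) else 0L
    pure_class <- st_i
    classes <- rep(pure_class, n_st)
    if (n_to_mixed > 0) {
      classes[seq_len(n_to_mixed)] <- rep(2L + seq_len(n_mixed_classes),
                                          length.out = n_to_mixed)
    }
    per_class[[st_i]] <- tibble::tibble(subtype = subtypes[st_i], class = classes)
  }
  assign <- dplyr::bind_rows(per_class)
  n <- nrow(assign)
  assign$sample_id <- sprintf("S%03d", seq_len(n))

  n_inf <- max(1L, ceiling(cfg$fraction_informative * p))
  informative <- sort(sample(seq_len(p), n_inf))

  class_means <- matrix(0, nrow = cfg$n_classes, ncol = p,
                        dimnames = list(NULL, genes))
  half <- seq_len(ceiling(n_inf / 2))
  for (c_i in seq_len(cfg$n_classes)[-1]) {
    pattern <- rep(1, n_inf)
    if (c_i >= 3) pattern[-half] <- -1            # mixed classes get their own direction
    if (c_i >= 4) pattern <- pattern * sample(c(-1, 1), n_inf, replace = TRUE)
    class_means[c_i, informative] <- cfg$class_mean_shift * sd_g[informative] * pattern
  }

  cr <- chol(sigma)
  z <- matrix(stats::rnorm(n * p), nrow = n) %*% cr
  x <- class_means[assign$class, , drop = FALSE] + z
  vals <- t(x)                                    # genes x samples
  dimnames(vals) <- list(genes, assign$sample_id)

  truth <- structure
  truth$class_of_sample <- tibble::tibble(sample_id = assign$sample_id,
                                          class = assign$class)
  truth$class_means <- class_means
  truth$informative_genes <- genes[informative]

  list(expression = nr_expr(vals),
       annotation = tibble::tibble(sample_id = assign$sample_id,
                                   subtype = assign$subtype),
       truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the same TSV dialects the readers consume (expression table with a
#' `Hugo_Symbol` column; two-column clinical table) plus a JSON sidecar
#' holding the ground truth (class assignment, hub genes, planted triads).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Named vector of the three paths written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "data_expression.txt"),
             clinical = file.path(dir, "data_clinical_supp_patient.txt"),
             truth = file.path(dir, "ground_truth.json"))
  write_expression(sim$expression, paths[["expression"]])
  readr::write_tsv(
    tibble::tibble(PATIENT_ID = sim$annotation$sample_id,
                   CLAUDIN_SUBTYPE = sim$annotation$subtype),
    paths[["clinical"]], progress = FALSE
  )
  jsonlite::write_json(list(
    class_of_sample = sim$truth$class_of_sample,
    hub_genes = sim$truth$hub_genes,
    triads = sim$truth$triads,
    informative_genes = sim$truth$informative_genes
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
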