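#' Shrinkage partial correlations within one patient class
#'
#' Estimates the gene-gene partial-correlation matrix from a (typically
#' small) class of samples. The sample correlation matrix is shrunk toward
#' the identity with the analytic, data-driven intensity
#' `lambda* = sum Var(r_ij) / sum r_ij^2` (clipped to `[0, 1]`), which keeps
#' the estimate well conditioned when genes outnumber samples. The shrunk
#' correlation matrix is inverted and rescaled,
#' `r_ij = -w_ij / sqrt(w_ii * w_jj)`, to give partial correlations.
#'
#' Missing values are handled pairwise-complete: each pair's correlation
#' uses the samples where both genes are observed, and pairs with fewer
#' than `min_overlap` shared observations get correlation 0. Zero-variance
#' genes must be removed first (see `drop_constant_genes`).
#'
#' @param x an [nr_expr] restricted to the class samples, or a samples x
#'   genes numeric matrix.
#' @param lambda optional fixed shrinkage intensity; `NULL` (default) uses
#'   the analytic estimate.
#' @param min_overlap minimum pairwise-complete sample count.
#' @param drop_constant_genes drop zero-variance genes (with a message)
#'   instead of erroring.
#' @return A `pcor_matrix`: `values` (symmetric, unit diagonal),
#'   `shrinkage_intensity`, `n_samples`, `dropped_genes`.
#' @export
partial_correlations <- function(x, lambda = NULL, min_overlap = 10,
                                 drop_constant_genes = TRUE) {
  xm <- if (inherits(x, "nr_expr")) t(x$values) else as.matrix(x)  # samples x genes
  n <- nrow(xm)
  if (n < 3) stop("data error: need at least 3 samples", call. = FALSE)

  sds <- apply(xm, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(xm)[is.na(sds) | sds == 0]
  if (length(dropped)) {
    if (!drop_constant_genes) stop("data error: zero-variance gene(s): ",
                                   paste(dropped, collapse = ", "), call. = FALSE)
    message("dropping ", length(dropped), " zero-variance gene(s)")
    xm <- xm[, !(colnames(xm) %in% dropped), drop = FALSE]
  }
  p <- ncol(xm)

  xs <- scale(xm)                      # per-gene standardisation (NA-safe via sd above)
  complete <- !is.na(xs)
  n_pair <- crossprod(complete)        # pairwise-complete counts
  xs0 <- xs; xs0[!complete] <- 0
  w_sum <- crossprod(xs0)              # sum_k x_ki x_kj over shared samples
  w_bar <- w_sum / pmax(n_pair, 1)
  r <- (n_pair / pmax(n_pair - 1, 1)) * w_bar
  r[n_pair < min_overlap] <- 0
  r[n_pair < 2] <- 0
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)

  if (is.null(lambda)) {
    # Var-hat(r_ij) = n/(n-1)^3 * sum_k (w_kij - w_bar_ij)^2, pairwise-complete
    w_sq <- crossprod(xs0^2)
    ss <- w_sq - n_pair * w_bar^2
    var_r <- (n_pair / pmax(n_pair - 1, 1)^3) * ss
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
  }

  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- 1
  omega <- tryCatch(chol2inv(chol(r_shrunk)), error = function(e) {
    stop("inference error: shrunk correlation matrix is numerically singular; ",
         "set a positive lambda floor", call. = FALSE)
  })
  pc <- -omega / tcrossprod(sqrt(diag(omega)))
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- list(colnames(xm), colnames(xm))

  structure(list(values = pc, shrinkage_intensity = lambda,
                 n_samples = n, dropped_genes = dropped),
            class = "pcor_matrix")
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("<pcor_matrix> %d genes, n = %d, lambda = %.4f\n",
              nrow(x$values), x$n_samples, x$shrinkage_intensity))
  invisible(x)
}

#' Rank all gene pairs by partial-correlation magnitude
#'
#' @param p a `pcor_matrix` (or plain symmetric matrix with gene dimnames).
#' @return Tibble (`gene_i`, `gene_j`, `pcor`) over all unordered pairs,
#'   sorted by `abs(pcor)` descending; equal magnitudes are ordered by the
#'   lexicographically smaller pair.
#' @export
rank_edges <- function(p) {
  v <- if (inherits(p, "pcor_matrix")) p$values else p
  genes <- rownames(v)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  gi <- genes[idx[, 1]]; gj <- genes[idx[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  out <- tibble::tibble(gene_i = gi, gene_j = gj, pcor = v[idx])
  dplyr::arrange(out, dplyr::desc(abs(.data$pcor)), .data$gene_i, .data$gene_j)
}

#' Threshold a ranked edge list into a signed network
#'
#' The default ("rank") mode keeps the strongest
#' `ceiling(fraction * n_pairs)` edges — marginalised thresholding of the
#' candidate-pair list. The alternative "magnitude" mode keeps edges with
#' `abs(pcor) > fraction`; the threshold description in the source method
#' is ambiguous between the two readings, and the rank cut is the default.
#'
#' @param ranked tibble from [rank_edges()].
#' @param fraction retained fraction of pairs (rank mode) or the magnitude
#'   cut (magnitude mode); in `(0, 1]`.
#' @param nodes full gene set (isolated genes are kept in the node set and
#'   reported); defaults to the genes appearing in `ranked`.
#' @param mode `"rank"` or `"magnitude"`.
#' @param source_class identifier carried on the network.
#' @return A `signed_network`: `nodes`, `edges` tibble (`gene_i`, `gene_j`,
#'   `weight`, `sign`), `isolated`, `source_class`.
#' @export
threshold_edges <- function(ranked, fraction = 0.01, nodes = NULL,
                            mode = c("rank", "magnitude"), source_class = NA_character_) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("configuration error: fraction must be in (0, 1]", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(ranked$gene_i, ranked$gene_j)))
  edges <- if (mode == "rank") {
    utils::head(ranked, ceiling(fraction * nrow(ranked)))
  } else {
    dplyr::filter(ranked, abs(.data$pcor) > fraction)
  }
  edges <- edges |>
    dplyr::filter(.data$pcor != 0) |>
    dplyr::transmute(gene_i = .data$gene_i, gene_j = .data$gene_j,
                     weight = .data$pcor,
                     sign = ifelse(.data$pcor > 0, "positive", "negative"))
  signed_network(nodes, edges, source_class)
}

#' Construct a signed undirected network
#'
#' @param nodes character vector of gene ids.
#' @param edges tibble with `gene_i`, `gene_j`, `weight` (non-zero) and
#'   optionally `sign` (recomputed from `weight` if absent).
#' @param source_class identifier of the patient class the network was
#'   inferred from.
#' @return A `signed_network` object.
#' @export
signed_network <- function(nodes, edges, source_class = NA_character_) {
  stopifnot(all(c("gene_i", "gene_j", "weight") %in% names(edges)))
  if (any(edges$gene_i == edges$gene_j)) stop("self-edges are not allowed", call. = FALSE)
  if (any(edges$weight == 0)) stop("zero-weight edges are not allowed", call. = FALSE)
  swap <- edges$gene_i > edges$gene_j
  tmp <- edges$gene_i[swap]
  edges$gene_i[swap] <- edges$gene_j[swap]
  edges$gene_j[swap] <- tmp
  if (anyDuplicated(paste(edges$gene_i, edges$gene_j))) {
    stop("duplicate edges", call. = FALSE)
  }
  edges$sign <- ifelse(edges$weight > 0, "positive", "negative")
  nodes <- as.character(nodes)
  connected <- unique(c(edges$gene_i, edges$gene_j))
  missing <- setdiff(connected, nodes)
  if (length(missing)) nodes <- c(nodes, missing)
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 isolated = setdiff(nodes, connected),
                 source_class = source_class),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d edges (%d positive, %d negative), %d isolated\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative"), length(x$isolated)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_i", "gene_j", "weight", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  g
}

#' Write a signed network as a 3-column edge list TSV
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  out <- dplyr::transmute(net$edges, gene_i = .data$gene_i, gene_j = .data$gene_j,
                          partial_correlation = signif(.data$weight, 6))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a signed network as GraphML
#'
#' Edge attributes `weight` and `sign` are carried through.
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
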