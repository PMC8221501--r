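#' Discretise each gene into three expression levels
#'
#' Per-gene quantile thresholds (tertiles by default) split expression into
#' a lower bound (code 0), a middle signal band (code 1) and an upper bound
#' (code 2). Values strictly below the lower cut are 0, strictly above the
#' upper cut are 2, and everything else — including ties with either cut —
#' falls in the middle band. Constant genes are coded all-middle and
#' flagged rather than dropped.
#'
#' @param x an [nr_expr].
#' @param lower_q,upper_q quantile positions of the two cuts.
#' @return An `nr_discrete` object: integer `codes` matrix (genes x
#'   samples, values 0/1/2, `NA` preserved), `bin_edges` tibble (gene,
#'   lower, upper), and `constant_genes` (character vector flag).
#' @export
discretize_tertiles <- function(x, lower_q = 1 / 3, upper_q = 2 / 3) {
  stopifnot(inherits(x, "nr_expr"), lower_q <= upper_q,
            lower_q > 0, upper_q < 1)
  v <- x$values
  lower <- apply(v, 1, stats::quantile, probs = lower_q, na.rm = TRUE, names = FALSE)
  upper <- apply(v, 1, stats::quantile, probs = upper_q, na.rm = TRUE, names = FALSE)
  codes <- matrix(1L, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  codes[v < lower] <- 0L
  codes[v > upper] <- 2L
  codes[is.na(v)] <- NA_integer_
  n_distinct <- apply(v, 1, function(r) length(unique(r[!is.na(r)])))
  constant <- rownames(v)[n_distinct <= 1]
  structure(list(
    codes = codes,
    bin_edges = tibble::tibble(gene = rownames(v), lower = lower, upper = upper),
    constant_genes = constant
  ), class = "nr_discrete")
}

#' @export
print.nr_discrete <- function(x, ...) {
  cat(sprintf("<nr_discrete> %d genes x %d samples (%d constant gene(s) flagged)\n",
              nrow(x$codes), ncol(x$codes), length(x$constant_genes)))
  invisible(x)
}
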