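#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an expression matrix into a long tibble
#'
#' @param x an [nr_expr].
#' @param ... unused.
#' @return Tibble with `gene`, `sample_id`, `value`.
#' @export
#' @exportS3Method generics::tidy
tidy.nr_expr <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
}

#' @rdname tidy.nr_expr
#' @export
#' @exportS3Method generics::glance
glance.nr_expr <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$values), n_samples = ncol(x$values),
                 centred = x$centred, n_missing = sum(is.na(x$values)))
}

#' Tidy a BHC tree into its merge table
#'
#' @param x a [bhc()] tree.
#' @param ... unused.
#' @return Tibble of internal nodes with children, sizes and log odds.
#' @export
#' @exportS3Method generics::tidy
tidy.bhc_tree <- function(x, ...) {
  dplyr::filter(x$nodes, !is.na(.data$log_odds))
}

#' @rdname tidy.bhc_tree
#' @export
#' @exportS3Method generics::glance
glance.bhc_tree <- function(x, ...) {
  merges <- x$nodes$log_odds[!is.na(x$nodes$log_odds)]
  tibble::tibble(n_samples = x$n_leaves,
                 n_merges = length(merges),
                 n_preferred_merges = sum(merges > 0),
                 root_log_odds = x$nodes$log_odds[x$root],
                 root_log_evidence = x$nodes$log_p[x$root])
}

#' Tidy class labels into the per-class summary
#'
#' @param x a [label_classes()] result.
#' @param ... unused.
#' @return The per-class summary tibble (`class`, `n`, `top_subtype`,
#'   `top_fraction`, `label`).
#' @export
#' @exportS3Method generics::tidy
tidy.class_labels <- function(x, ...) x$summary

#' @rdname tidy.class_labels
#' @export
#' @exportS3Method generics::glance
glance.class_labels <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$summary),
                 n_samples = nrow(x$assignment),
                 n_dominant = sum(startsWith(x$summary$label, "dominant")),
                 n_insubstantial = sum(startsWith(x$summary$label, "insubstantial")),
                 n_ambiguous = sum(x$summary$label == "ambiguous"))
}

#' Tidy a partial-correlation matrix into the ranked edge list
#'
#' @param x a [partial_correlations()] result.
#' @param ... unused.
#' @return The [rank_edges()] tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.pcor_matrix <- function(x, ...) rank_edges(x)

#' @rdname tidy.pcor_matrix
#' @export
#' @exportS3Method generics::glance
glance.pcor_matrix <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$values), n_samples = x$n_samples,
                 shrinkage_intensity = x$shrinkage_intensity,
                 n_dropped_genes = length(x$dropped_genes))
}

#' Tidy a signed network into its edge tibble
#'
#' @param x a [signed_network()].
#' @param ... unused.
#' @return The edge tibble (`gene_i`, `gene_j`, `weight`, `sign`).
#' @export
#' @exportS3Method generics::tidy
tidy.signed_network <- function(x, ...) x$edges

#' @rdname tidy.signed_network
#' @export
#' @exportS3Method generics::glance
glance.signed_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_positive = sum(x$edges$sign == "positive"),
                 n_negative = sum(x$edges$sign == "negative"),
                 n_isolated = length(x$isolated))
}

#' Tidy a degree summary into the ranked total-degree table
#'
#' @param x a [total_degree()] result.
#' @param ... unused.
#' @return Tibble (`gene`, `total_degree`, `rank`).
#' @export
#' @exportS3Method generics::tidy
tidy.degree_summary <- function(x, ...) x$total

#' Tidy a motif census into its triad records
#'
#' @param x a [census_hub_motifs()] result.
#' @param ... unused.
#' @return Tibble of triad records.
#' @export
#' @exportS3Method generics::tidy
tidy.motif_census <- function(x, ...) x$triads

#' @rdname tidy.motif_census
#' @export
#' @exportS3Method generics::glance
glance.motif_census <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "code", values_from = "n") |>
    dplyr::mutate(hub = x$hub, total = sum(x$counts$n), .before = 1)
}
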