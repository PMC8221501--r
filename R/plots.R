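#' Total-degree distribution plot
#'
#' Histogram of per-gene total degree across the analysed networks, the
#' standard view for spotting hub genes in the upper tail.
#'
#' @param object a [total_degree()] result.
#' @param label_top annotate this many top-ranked genes.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.degree_summary <- function(object, label_top = 2, ...) {
  top <- utils::head(object$total, label_top)
  ggplot2::ggplot(object$total, ggplot2::aes(x = .data$total_degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40", colour = "white") +
    ggplot2::geom_text(data = top, y = 0.5, vjust = 0, angle = 90,
                       ggplot2::aes(label = .data$gene), size = 3) +
    ggplot2::labs(x = "total degree across networks", y = "number of genes") +
    ggplot2::theme_minimal()
}

#' Signed-network plot
#'
#' Draws the network with a deterministic Fruchterman–Reingold layout;
#' positive edges red, negative edges black, the field's convention for
#' signed co-expression networks.
#'
#' @param object a [signed_network()].
#' @param drop_isolated hide degree-zero nodes.
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.signed_network <- function(object, drop_isolated = TRUE, seed = 1, ...) {
  net <- object
  nodes <- if (drop_isolated) setdiff(net$nodes, net$isolated) else net$nodes
  if (length(nodes) == 0) stop("nothing to plot: empty network", call. = FALSE)
  g <- as_igraph(net)
  g <- igraph::induced_subgraph(g, nodes)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  node_df <- tibble::tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edge_df <- dplyr::left_join(net$edges, node_df, by = c(gene_i = "gene")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(node_df, by = c(gene_j = "gene")) |>
    dplyr::filter(!is.na(.data$x0), !is.na(.data$x))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edge_df,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       colour = .data$sign)) +
    ggplot2::scale_colour_manual(values = c(positive = "red3", negative = "black")) +
    ggplot2::geom_point(data = node_df, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = node_df, ggplot2::aes(.data$x, .data$y, label = .data$gene),
                       vjust = -0.8, size = 2.8) +
    ggplot2::theme_void()
}

#' Class-composition plot
#'
#' Stacked per-class subtype counts, mirroring the composition tables that
#' accompany stratification dendrograms.
#'
#' @param object a [label_classes()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.class_labels <- function(object, ...) {
  comp <- dplyr::left_join(object$composition,
                           dplyr::select(object$summary, "class", "label"),
                           by = "class")
  ggplot2::ggplot(comp, ggplot2::aes(x = factor(.data$class), y = .data$n,
                                     fill = .data$subtype)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = object$summary, inherit.aes = FALSE, vjust = -0.3,
                       ggplot2::aes(x = factor(.data$class), y = .data$n,
                                    label = .data$label), size = 2.6) +
    ggplot2::labs(x = "class", y = "patients") +
    ggplot2::theme_minimal()
}

#' Motif-census plot
#'
#' Bar chart of NPU code counts for one hub-associated local network.
#'
#' @param object a [census_hub_motifs()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.motif_census <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = factor(.data$code, levels = MOTIF_CODES),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "NPU code", y = "motif count",
                  title = paste("hub", object$hub)) +
    ggplot2::theme_minimal()
}
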