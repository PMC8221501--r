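#' Node degrees of a signed network
#'
#' Degree is the number of connections a node makes, counting positive and
#' negative edges alike; genes in the node set without edges get 0.
#'
#' @param net a [signed_network()].
#' @return Tibble (`gene`, `degree`), in node-set order.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  counts <- table(factor(c(net$edges$gene_i, net$edges$gene_j), levels = net$nodes))
  tibble::tibble(gene = net$nodes, degree = as.integer(counts))
}

#' Total degree across a set of networks
#'
#' Sums each gene's degree over all supplied networks (e.g. the
#' Basal-specific networks from every pairwise comparison) and ranks genes
#' by the total, ties broken alphabetically.
#'
#' @param networks named list of [signed_network()] objects; names are used
#'   as network ids (defaults to `net1`, `net2`, ...).
#' @param genes optional full gene universe; genes absent from every
#'   network are kept with total 0.
#' @return A `degree_summary`: `per_network` tibble (`network`, `gene`,
#'   `degree`), `total` tibble (`gene`, `total_degree`, `rank`) sorted by
#'   rank, and `histogram` tibble of total-degree counts.
#' @export
total_degree <- function(networks, genes = NULL) {
  stopifnot(length(networks) >= 1)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- sprintf("net%d", seq_along(networks))
  }
  per_network <- purrr::imap_dfr(networks, function(net, id) {
    dplyr::mutate(node_degrees(net), network = id, .before = 1)
  })
  universe <- sort(unique(c(genes, per_network$gene)))
  total <- per_network |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(total_degree = sum(.data$degree), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(gene = universe), by = "gene") |>
    dplyr::mutate(total_degree = dplyr::coalesce(.data$total_degree, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$total_degree), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  histogram <- dplyr::count(total, .data$total_degree, name = "n_genes")
  structure(list(per_network = per_network, total = total, histogram = histogram),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("<degree_summary> %d networks, %d genes; top: %s (%d)\n",
              length(unique(x$per_network$network)), nrow(x$total),
              x$total$gene[1], x$total$total_degree[1]))
  invisible(x)
}

#' Identify hub genes by total degree
#'
#' Returns the top `k` genes of the total-degree ranking. A tie crossing
#' the k-th position expands the returned list (attribute `tied = TRUE`)
#' rather than truncating arbitrarily.
#'
#' @param summary a [total_degree()] result.
#' @param k number of hubs.
#' @return Character vector of hub genes, possibly longer than `k` under
#'   ties; attribute `tied` flags the expansion.
#' @export
identify_hubs <- function(summary, k = 2) {
  stopifnot(inherits(summary, "degree_summary"))
  if (!is.numeric(k) || k < 1) stop("configuration error: k must be >= 1", call. = FALSE)
  total <- summary$total
  if (k > nrow(total)) stop("configuration error: k exceeds gene count", call. = FALSE)
  cutoff <- total$total_degree[k]
  hubs <- total$gene[total$total_degree >= cutoff]
  structure(hubs, tied = length(hubs) > k)
}

#' Write the degree summary as a wide TSV
#'
#' One row per gene, one column per network, and a final total column.
#'
#' @param summary a [total_degree()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_degree_summary <- function(summary, path) {
  wide <- summary$per_network |>
    tidyr::pivot_wider(names_from = "network", values_from = "degree",
                       values_fill = 0L) |>
    dplyr::right_join(summary$total, by = "gene") |>
    dplyr::arrange(.data$rank) |>
    dplyr::select(-"rank") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ dplyr::coalesce(.x, 0L)))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
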