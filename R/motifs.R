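#' The seven edge-bearing NPU motif codes
#'
#' Census tables cover the three linear (two-edge) codes and the four
#' complete (three-edge) codes; the no-edge and single-edge codes are
#' classifiable via [npu_code()] but excluded from census tables.
#' @export
MOTIF_CODES <- c("021", "201", "111", "120", "210", "030", "300")

EDGE_STATES <- c("negative", "positive", "absent")

#' NPU code of a signed 3-node motif
#'
#' The code concatenates the counts of Negative, Positive and Un-associated
#' (absent) pairs among the three node pairs, e.g. two positive edges and
#' one absent pair give `"021"`. Order of the supplied pair states is
#' immaterial.
#'
#' @param signs character vector of length 3 with values `"negative"`,
#'   `"positive"`, `"absent"`.
#' @return A 3-character string; the three digits sum to 3.
#' @export
npu_code <- function(signs) {
  stopifnot(length(signs) == 3, all(signs %in% EDGE_STATES))
  paste0(sum(signs == "negative"), sum(signs == "positive"), sum(signs == "absent"))
}

#' Topology and coherence of a signed triad
#'
#' Two present edges make a linear motif, three a complete motif. A
#' complete motif is coherent when its edge-sign product is positive (an
#' even number of negative edges) — the structural-balance convention —
#' and incoherent otherwise. Coherence is undefined (`"n/a"`) for
#' non-complete triads.
#'
#' @param signs character vector of length 3 of pair states (see
#'   [npu_code()]).
#' @return List with `code`, `topology` (`empty`, `one_edge`, `linear`,
#'   `complete`) and `coherence` (`coherent`, `incoherent`, `n/a`).
#' @export
classify_triad <- function(signs) {
  code <- npu_code(signs)
  n_edges <- sum(signs != "absent")
  topology <- c("empty", "one_edge", "linear", "complete")[n_edges + 1L]
  coherence <- if (n_edges == 3L) {
    if (sum(signs == "negative") %% 2L == 0L) "coherent" else "incoherent"
  } else "n/a"
  list(code = code, topology = topology, coherence = coherence)
}

#' Enumerate all signed 3-node configurations
#'
#' Exhaustively generates the `3^3 = 27` ordered assignments of
#' negative / positive / absent over the three node pairs and summarises
#' them: the distinct NPU codes, configurations per code, the linear
#' (two-edge) configurations distinguished by the hub position, and the
#' complete (three-edge) sign configurations.
#'
#' @return List with `total` (27), `configurations` tibble (one row per
#'   ordered assignment with its code and topology), `codes` tibble
#'   (`code`, `n_configurations`), `n_codes`, `n_linear_configurations`,
#'   `n_complete_configurations`.
#' @export
enumerate_npu_configurations <- function() {
  grid <- expand.grid(ab = EDGE_STATES, ac = EDGE_STATES, bc = EDGE_STATES,
                      stringsAsFactors = FALSE)
  configurations <- purrr::pmap_dfr(grid, function(ab, ac, bc) {
    cl <- classify_triad(c(ab, ac, bc))
    tibble::tibble(ab = ab, ac = ac, bc = bc, code = cl$code,
                   topology = cl$topology, coherence = cl$coherence)
  })
  codes <- dplyr::count(configurations, .data$code, name = "n_configurations")
  list(
    total = nrow(configurations),
    configurations = configurations,
    codes = codes,
    n_codes = nrow(codes),
    n_linear_configurations = sum(configurations$topology == "linear"),
    n_complete_configurations = sum(configurations$topology == "complete")
  )
}

#' Hub-associated local network
#'
#' The induced subgraph on all nodes within two edges of the hub: the hub,
#' its neighbours, and their neighbours, with every parent-network edge
#' among them.
#'
#' @param net a [signed_network()].
#' @param hub gene id; must be a node of `net`.
#' @return A `local_network`: `hub`, `nodes`, `edges` (tibble subset of the
#'   parent edges), `source_class`.
#' @export
hub_local_network <- function(net, hub) {
  stopifnot(inherits(net, "signed_network"))
  if (!hub %in% net$nodes) stop("data error: hub '", hub, "' not in network", call. = FALSE)
  g <- as_igraph(net)
  nodes <- names(igraph::ego(g, order = 2, nodes = hub)[[1]])
  edges <- dplyr::filter(net$edges, .data$gene_i %in% nodes & .data$gene_j %in% nodes)
  structure(list(hub = hub, nodes = nodes, edges = edges,
                 source_class = net$source_class),
            class = "local_network")
}

#' @export
print.local_network <- function(x, ...) {
  cat(sprintf("<local_network> hub %s: %d nodes, %d edges\n",
              x$hub, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_sign_lookup <- function(edges) {
  key <- paste(pmin(edges$gene_i, edges$gene_j), pmax(edges$gene_i, edges$gene_j),
               sep = "\r")
  stats::setNames(edges$sign, key)
}

pair_state <- function(lookup, a, b) {
  s <- unname(lookup[paste(min(a, b), max(a, b), sep = "\r")])
  if (is.na(s)) "absent" else s
}

#' NPU census of a hub-associated local network
#'
#' Enumerates every unordered triple of distinct nodes that contains the
#' hub and carries at least two present edges (a linear or complete
#' motif), classifies each by NPU code, and tabulates counts over the
#' seven edge-bearing codes ([MOTIF_CODES]). For linear motifs the centre
#' gene (the node adjacent to both others) is recorded.
#'
#' @param local a [hub_local_network()]; or a [signed_network()] with
#'   `hub_all_triples = TRUE`.
#' @param hub_all_triples also count triples that do not contain the hub
#'   (sensitivity mode; the default mirrors hub-centred census tables).
#' @return A `motif_census`: `hub`, `counts` tibble (`code`, `n` over all
#'   seven codes), `triads` tibble (`gene_a` < `gene_b` < `gene_c`, `code`,
#'   `topology`, `coherence`, `centre`).
#' @export
census_hub_motifs <- function(local, hub_all_triples = FALSE) {
  stopifnot(inherits(local, "local_network"))
  lookup <- edge_sign_lookup(local$edges)
  others <- setdiff(local$nodes, local$hub)

  triples <- if (hub_all_triples) {
    if (length(local$nodes) < 3) list() else
      utils::combn(sort(local$nodes), 3, simplify = FALSE)
  } else {
    if (length(others) < 2) list() else
      purrr::map(utils::combn(sort(others), 2, simplify = FALSE),
                 function(p) c(local$hub, p))
  }

  rows <- purrr::map_dfr(triples, function(tr) {
    signs <- c(pair_state(lookup, tr[1], tr[2]),
               pair_state(lookup, tr[1], tr[3]),
               pair_state(lookup, tr[2], tr[3]))
    if (sum(signs != "absent") < 2) return(NULL)
    cl <- classify_triad(signs)
    centre <- NA_character_
    if (cl$topology == "linear") {
      # the centre node is on both present edges
      pairs <- rbind(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)])
      present_nodes <- as.vector(pairs[signs != "absent", ])
      centre <- names(which(table(present_nodes) == 2))
    }
    srt <- sort(tr)
    tibble::tibble(gene_a = srt[1], gene_b = srt[2], gene_c = srt[3],
                   code = cl$code, topology = cl$topology,
                   coherence = cl$coherence, centre = centre)
  })
  counts <- tibble::tibble(code = MOTIF_CODES,
                           n = vapply(MOTIF_CODES, function(cd) sum(rows$code == cd),
                                      integer(1), USE.NAMES = FALSE))
  structure(list(hub = local$hub, counts = counts, triads = rows,
                 source_class = local$source_class),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census> hub %s: %d motifs (%s)\n", x$hub, sum(x$counts$n),
              paste(sprintf("%s:%d", x$counts$code, x$counts$n), collapse = " ")))
  invisible(x)
}

#' Gene triples conserved across networks
#'
#' A triple is reported when it occurs as an edge-bearing hub motif in at
#' least `min_networks` of the analysed networks spanning at least
#' `min_cohorts` distinct cohorts. Output follows the one-row-per-triple,
#' one-column-per-network layout with `Present(<topology>, <code>)` or
#' `Absent` cells, so the same triple may legitimately appear with
#' different codes in different networks.
#'
#' @param censuses list of entries `list(network =, cohort =, census =)`
#'   where `census` is a [census_hub_motifs()] result (several censuses may
#'   share a network id, e.g. one per hub).
#' @param min_networks minimum number of networks containing the triple.
#' @param min_cohorts minimum number of distinct cohort tags spanned.
#' @return Tibble: `gene_a`, `gene_b`, `gene_c`, `n_networks`, `n_cohorts`,
#'   then one `Present(...)`/`Absent` column per network id.
#' @export
cross_network_conservation <- function(censuses, min_networks = 6, min_cohorts = 2) {
  stopifnot(length(censuses) >= 1)
  network_ids <- unique(vapply(censuses, `[[`, character(1), "network"))
  if (length(network_ids) < 2) stop("need at least 2 networks", call. = FALSE)
  if (min_networks > length(network_ids)) {
    stop("configuration error: min_networks exceeds the number of networks", call. = FALSE)
  }
  cohort_of <- vapply(censuses, `[[`, character(1), "cohort")
  names(cohort_of) <- vapply(censuses, `[[`, character(1), "network")
  cohort_of <- cohort_of[!duplicated(names(cohort_of))]

  occurrences <- purrr::map_dfr(censuses, function(entry) {
    tr <- entry$census$triads
    if (is.null(tr) || nrow(tr) == 0) return(NULL)
    dplyr::mutate(tr, network = entry$network, cohort = entry$cohort)
  })
  if (nrow(occurrences) == 0) return(tibble::tibble())
  occurrences <- dplyr::distinct(occurrences, .data$gene_a, .data$gene_b,
                                 .data$gene_c, .data$network,
                                 .keep_all = TRUE)

  conserved <- occurrences |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$gene_c) |>
    dplyr::summarise(n_networks = dplyr::n_distinct(.data$network),
                     n_cohorts = dplyr::n_distinct(.data$cohort),
                     .groups = "drop") |>
    dplyr::filter(.data$n_networks >= min_networks, .data$n_cohorts >= min_cohorts)
  if (nrow(conserved) == 0) return(conserved)

  cells <- occurrences |>
    dplyr::semi_join(conserved, by = c("gene_a", "gene_b", "gene_c")) |>
    dplyr::mutate(cell = sprintf("Present(%s, %s)", .data$topology, .data$code)) |>
    dplyr::select("gene_a", "gene_b", "gene_c", "network", "cell") |>
    tidyr::pivot_wider(names_from = "network", values_from = "cell")
  out <- dplyr::left_join(conserved, cells, by = c("gene_a", "gene_b", "gene_c"))
  for (id in network_ids) {
    if (!id %in% names(out)) out[[id]] <- "Absent"
    out[[id]][is.na(out[[id]])] <- "Absent"
  }
  dplyr::select(out, "gene_a", "gene_b", "gene_c", "n_networks", "n_cohorts",
                dplyr::all_of(network_ids))
}

#' Write a hub-by-network census table (seven NPU columns)
#'
#' @param censuses list of `list(network =, cohort =, census =)` entries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(censuses, path) {
  tab <- purrr::map_dfr(censuses, function(entry) {
    wide <- tidyr::pivot_wider(entry$census$counts, names_from = "code",
                               values_from = "n")
    dplyr::bind_cols(tibble::tibble(hub = entry$census$hub, network = entry$network),
                     wide)
  })
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
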