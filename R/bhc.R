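#' Bayesian hierarchical clustering of samples
#'
#' Greedy agglomerative clustering under a Dirichlet-process mixture of
#' per-gene multinomials (genes independent given the cluster). Starting
#' from singleton leaves, each step merges the pair of subtrees with the
#' highest posterior probability that their samples form a single cluster,
#' computed from Dirichlet-multinomial marginal likelihoods and the
#' Heller–Ghahramani tree-prior recursion. Every internal node stores the
#' log posterior odds of "merged" versus "kept as the two subtrees'
#' partitions"; positive log odds mark preferred merges.
#'
#' Merge ties are broken by the lexicographically smallest pair of subtree
#' ids (leaves are numbered in input order, internal nodes in creation
#' order), which makes the tree deterministic.
#'
#' @param d an `nr_discrete` from [discretize_tertiles()]; `NA` codes are
#'   simply absent from that gene's counts.
#' @param alpha Dirichlet-process concentration (> 0).
#' @param pseudocounts length-3 positive Dirichlet pseudocounts for the
#'   low/middle/high bins.
#' @return A `bhc_tree`: `labels` (sample ids, input order), `nodes` tibble
#'   (one row per node: `id`, `left`, `right`, `size`, `log_odds`,
#'   `log_ml`, `log_d`, `log_p`), `root` id and `members` list.
#' @export
bhc <- function(d, alpha = 1, pseudocounts = c(1, 1, 1)) {
  stopifnot(inherits(d, "nr_discrete"), alpha > 0,
            length(pseudocounts) == 3, all(pseudocounts > 0))
  codes <- d$codes
  g <- nrow(codes)
  n <- ncol(codes)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  labels <- colnames(codes)

  beta <- as.numeric(pseudocounts)
  beta_vec <- rep(beta, each = g)             # layout: [bin0 x g | bin1 x g | bin2 x g]
  bsum <- sum(beta)
  const_per_gene <- lgamma(bsum) - sum(lgamma(beta))

  # counts: k x 3g matrix of per-cluster bin counts
  leaf_counts <- function(j) {
    cj <- codes[, j]
    out <- numeric(3 * g)
    for (b in 0:2) out[b * g + which(cj == b)] <- 1
    out
  }
  counts <- t(vapply(seq_len(n), leaf_counts, numeric(3 * g)))

  log_ml_rows <- function(cm) {
    # cm: k x 3g counts; returns per-row log marginal likelihood
    cm <- rbind(cm)
    ng <- cm[, 1:g, drop = FALSE] + cm[, g + 1:g, drop = FALSE] +
      cm[, 2 * g + 1:g, drop = FALSE]
    g * const_per_gene +
      rowSums(lgamma(sweep(cm, 2, beta_vec, "+"))) -
      rowSums(lgamma(ng + bsum))
  }
  lse2 <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

  max_nodes <- 2L * n - 1L
  node_left <- node_right <- rep(NA_integer_, max_nodes)
  node_size <- rep(1L, max_nodes)
  node_log_odds <- rep(NA_real_, max_nodes)
  node_log_ml <- node_log_d <- node_log_p <- rep(NA_real_, max_nodes)
  members <- vector("list", max_nodes)

  leaf_ml <- log_ml_rows(counts)
  for (j in seq_len(n)) {
    members[[j]] <- j
    node_log_ml[j] <- leaf_ml[j]
    node_log_d[j] <- log(alpha)
    node_log_p[j] <- leaf_ml[j]
  }

  if (n == 1L) {
    return(new_bhc_tree(labels, node_left, node_right, node_size, node_log_odds,
                        node_log_ml, node_log_d, node_log_p, members, root = 1L, n = n))
  }

  # active clusters: vectors indexed in parallel
  act_id <- seq_len(n)
  act_counts <- counts

  pair_stats <- function(i_rows, j_row) {
    # merge stats of each active row in i_rows with the single row j_row
    cm <- sweep(act_counts[i_rows, , drop = FALSE], 2, act_counts[j_row, ], "+")
    ml_m <- log_ml_rows(cm)
    ids_i <- act_id[i_rows]; id_j <- act_id[j_row]
    n_m <- node_size[ids_i] + node_size[id_j]
    log_ag <- log(alpha) + lgamma(n_m)
    log_dd <- node_log_d[ids_i] + node_log_d[id_j]
    log_d_m <- lse2(log_ag, log_dd)
    log_num1 <- (log_ag - log_d_m) + ml_m
    log_num2 <- (log_dd - log_d_m) + node_log_p[ids_i] + node_log_p[id_j]
    log_p_m <- lse2(log_num1, log_num2)
    list(score = log_num1 - log_p_m, log_odds = log_num1 - log_num2,
         log_ml = ml_m, log_d = log_d_m, log_p = log_p_m)
  }

  k <- n
  score <- matrix(-Inf, k, k)                 # upper triangle: score[i, j], i < j
  for (j in 2:k) score[1:(j - 1), j] <- pair_stats(1:(j - 1), j)$score

  next_id <- n
  while (k > 1L) {
    best <- which(score == max(score), arr.ind = TRUE)
    if (nrow(best) > 1L) {                    # ties: smallest (id_i, id_j) pair
      ids <- cbind(act_id[best[, 1]], act_id[best[, 2]])
      ids <- t(apply(ids, 1, sort))
      best <- best[order(ids[, 1], ids[, 2])[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    st <- pair_stats(i, j)
    next_id <- next_id + 1L
    id_i <- act_id[i]; id_j <- act_id[j]
    node_left[next_id] <- min(id_i, id_j)
    node_right[next_id] <- max(id_i, id_j)
    node_size[next_id] <- node_size[id_i] + node_size[id_j]
    node_log_odds[next_id] <- st$log_odds
    node_log_ml[next_id] <- st$log_ml
    node_log_d[next_id] <- st$log_d
    node_log_p[next_id] <- st$log_p
    members[[next_id]] <- c(members[[id_i]], members[[id_j]])

    act_counts[i, ] <- act_counts[i, ] + act_counts[j, ]
    act_id[i] <- next_id
    keep <- setdiff(seq_len(k), j)
    act_counts <- act_counts[keep, , drop = FALSE]
    act_id <- act_id[keep]
    score <- score[keep, keep, drop = FALSE]
    k <- k - 1L
    i <- match(next_id, act_id)
    if (k > 1L) {
      others <- setdiff(seq_len(k), i)
      s <- pair_stats(others, i)$score
      for (idx in seq_along(others)) {
        o <- others[idx]
        if (o < i) score[o, i] <- s[idx] else score[i, o] <- s[idx]
      }
    }
  }

  new_bhc_tree(labels, node_left, node_right, node_size, node_log_odds,
               node_log_ml, node_log_d, node_log_p, members,
               root = next_id, n = n)
}

new_bhc_tree <- function(labels, left, right, size, log_odds, log_ml, log_d,
                         log_p, members, root, n) {
  m <- if (root > n) root else n
  structure(list(
    labels = labels,
    nodes = tibble::tibble(id = seq_len(m), left = left[1:m], right = right[1:m],
                           size = size[1:m], log_odds = log_odds[1:m],
                           log_ml = log_ml[1:m], log_d = log_d[1:m],
                           log_p = log_p[1:m]),
    members = members[1:m],
    root = root,
    n_leaves = n
  ), class = "bhc_tree")
}

#' @export
print.bhc_tree <- function(x, ...) {
  cat(sprintf("<bhc_tree> %d samples, %d merges, root log-odds %s\n",
              x$n_leaves, sum(!is.na(x$nodes$log_odds)),
              format(x$nodes$log_odds[x$root], digits = 4)))
  invisible(x)
}

is_leaf <- function(tree, id) id <= tree$n_leaves

#' Leaf order of the dendrogram (left to right)
#' @param tree a [bhc()] tree.
#' @return Character vector of sample ids in display order.
#' @export
leaf_order <- function(tree) {
  out <- integer(0)
  walk <- function(id) {
    if (is_leaf(tree, id)) out[[length(out) + 1L]] <<- id
    else { walk(tree$nodes$left[id]); walk(tree$nodes$right[id]) }
  }
  walk(tree$root)
  tree$labels[unlist(out)]
}

# per-node flag: all internal nodes in the subtree have log_odds > 0
all_positive_flags <- function(tree) {
  flag <- rep(TRUE, nrow(tree$nodes))
  internal <- which(!is.na(tree$nodes$log_odds))
  for (id in internal) {                      # children precede parents by id
    flag[id] <- tree$nodes$log_odds[id] > 0 &&
      flag[tree$nodes$left[id]] && flag[tree$nodes$right[id]]
  }
  flag
}

cluster_root_ids <- function(tree) {
  flag <- all_positive_flags(tree)
  parent <- rep(NA_integer_, nrow(tree$nodes))
  internal <- which(!is.na(tree$nodes$log_odds))
  parent[tree$nodes$left[internal]] <- internal
  parent[tree$nodes$right[internal]] <- internal
  which(flag & (is.na(parent) | !flag[pmax(parent, 1L)]))
}

order_groups_left_to_right <- function(tree, group_ids) {
  disp <- match(tree$labels, leaf_order(tree))
  first <- vapply(group_ids, function(id) min(disp[tree$members[[id]]]), numeric(1))
  group_ids[order(first)]
}

#' Cut a BHC tree into its preferred-merge clusters
#'
#' Clusters are the maximal subtrees whose internal merges all carry
#' positive log odds; merges with non-positive log odds sit further up the
#' hierarchy and are not applied.
#'
#' @param tree a [bhc()] tree.
#' @return Tibble with `sample_id` and `cluster` (integer, numbered left to
#'   right in dendrogram order).
#' @export
cut_clusters <- function(tree) {
  roots <- order_groups_left_to_right(tree, cluster_root_ids(tree))
  purrr::imap_dfr(roots, function(id, k) {
    tibble::tibble(sample_id = tree$labels[tree$members[[id]]], cluster = k)
  })
}

#' Consolidate clusters into classes via the top fusions
#'
#' Starting from the whole tree, the highest fusions (the merges performed
#' last) are undone one at a time — never splitting inside a preferred-merge
#' cluster — until every group is a whole cluster or a union of clusters,
#' capped at `max_classes` groups. This reproduces class formation from the
#' final or penultimate dendrogram fusions while keeping classes aligned
#' with the clusters.
#'
#' @param tree a [bhc()] tree.
#' @param max_classes maximum number of classes (>= 2).
#' @return Tibble with `sample_id` and `class` (numbered left to right).
#' @export
consolidate_classes <- function(tree, max_classes = 7) {
  if (max_classes < 2) stop("configuration error: max_classes must be >= 2", call. = FALSE)
  flag <- all_positive_flags(tree)
  frontier <- tree$root
  repeat {
    splittable <- frontier[!is_leaf(tree, frontier) & !flag[frontier]]
    if (length(splittable) == 0L || length(frontier) >= max_classes) break
    pick <- splittable[which.max(splittable)]   # latest merge = highest fusion
    frontier <- c(setdiff(frontier, pick),
                  tree$nodes$left[pick], tree$nodes$right[pick])
  }
  frontier <- order_groups_left_to_right(tree, frontier)
  purrr::imap_dfr(frontier, function(id, k) {
    tibble::tibble(sample_id = tree$labels[tree$members[[id]]], class = k)
  })
}

#' Label classes by subtype composition
#'
#' For each class, let `f` be the largest subtype fraction: the class is
#' `dominant` when `f >= dominance_frac`, `insubstantial_dominant` when
#' `insubstantial_frac <= f < dominance_frac`, and `ambiguous` otherwise.
#' The numeric thresholds are configuration, chosen to reproduce the
#' labelling conventions of published pairwise cohorts (a 97:1 class is
#' dominant; a 50:13 class is an insubstantial dominant class; a near-even
#' mixture is ambiguous).
#'
#' @param classes tibble (`sample_id`, `class`) from [consolidate_classes()]
#'   or [cut_clusters()] (a `cluster` column is accepted as `class`).
#' @param annotation tibble (`sample_id`, `subtype`).
#' @param dominance_frac,insubstantial_frac thresholds in (0, 1].
#' @return A `class_labels` object: `assignment` tibble, `composition`
#'   (class x subtype counts, long) and `summary` (one row per class with
#'   `n`, `top_subtype`, `top_fraction`, `label`).
#' @export
label_classes <- function(classes, annotation, dominance_frac = 0.85,
                          insubstantial_frac = 0.60) {
  stopifnot(dominance_frac > insubstantial_frac, dominance_frac <= 1,
            insubstantial_frac > 0)
  if (!"class" %in% names(classes) && "cluster" %in% names(classes)) {
    classes <- dplyr::rename(classes, class = "cluster")
  }
  joined <- dplyr::inner_join(classes, annotation, by = "sample_id")
  if (nrow(joined) < nrow(classes)) {
    stop("data error: unannotated sample(s) in class assignment", call. = FALSE)
  }
  composition <- dplyr::count(joined, .data$class, .data$subtype, name = "n")
  summary <- composition |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      top_subtype = .data$subtype[which.max(.data$n)],
      top_fraction = max(.data$n) / sum(.data$n),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::relocate("n", .after = "class") |>
    dplyr::mutate(label = dplyr::case_when(
      .data$top_fraction >= dominance_frac ~ paste0("dominant(", .data$top_subtype, ")"),
      .data$top_fraction >= insubstantial_frac ~
        paste0("insubstantial_dominant(", .data$top_subtype, ")"),
      TRUE ~ "ambiguous"
    ))
  structure(list(assignment = classes, composition = composition, summary = summary),
            class = "class_labels")
}

#' @export
print.class_labels <- function(x, ...) {
  cat("<class_labels>\n")
  print(x$summary)
  invisible(x)
}

#' Classes dominated by a given subtype
#'
#' @param labels a [label_classes()] result.
#' @param subtype subtype of interest (e.g. `"Basal"`).
#' @param include_insubstantial also return insubstantial dominant classes.
#' @return Integer vector of class indices.
#' @export
dominant_classes <- function(labels, subtype, include_insubstantial = TRUE) {
  stopifnot(inherits(labels, "class_labels"))
  want <- paste0("dominant(", subtype, ")")
  if (include_insubstantial) want <- c(want, paste0("insubstantial_dominant(", subtype, ")"))
  labels$summary$class[labels$summary$label %in% want]
}

#' Export a BHC dendrogram as a Newick string
#'
#' Internal nodes carry their merge log odds (rounded to 4 significant
#' digits) as node labels.
#'
#' @param tree a [bhc()] tree.
#' @param path optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  build <- function(id) {
    if (is_leaf(tree, id)) return(tree$labels[id])
    sprintf("(%s,%s)%s", build(tree$nodes$left[id]), build(tree$nodes$right[id]),
            format(tree$nodes$log_odds[id], digits = 4, trim = TRUE))
  }
  s <- paste0(build(tree$root), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}
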