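#' Pipeline configuration
#'
#' Bundles every stage's knobs — including each knob whose published
#' description is ambiguous (threshold interpretation, hub count, dominance
#' fractions, conservation thresholds) — so sensitivity analyses are
#' one-argument changes. Each cohort entry either points at expression and
#' clinical files or embeds a synthetic-cohort specification.
#'
#' @param cohorts named list; each element is either
#'   `list(expression = path, clinical = path, ...)` (optional
#'   `gene_col`, `sample_col`, `subtype_col`) or
#'   `list(simulation = sim_config, structure = planted_structure)`.
#' @param gene_list optional path to a gene-list file; the analysis is
#'   restricted to those genes.
#' @param subtype_pairs list of length-2 character vectors, each a pairwise
#'   comparison; the first element is the target subtype whose dominant
#'   classes get networks.
#' @param target_subtype subtype whose dominant classes are analysed.
#' @param lower_q,upper_q discretisation quantiles.
#' @param alpha,pseudocounts clustering hyperparameters (see [bhc()]).
#' @param max_classes class-consolidation cap.
#' @param dominance_frac,insubstantial_frac class labelling thresholds.
#' @param edge_fraction retained edge fraction (or magnitude cut).
#' @param threshold_mode `"rank"` or `"magnitude"`.
#' @param include_insubstantial analyse insubstantial dominant classes too.
#' @param hub_k number of hubs.
#' @param min_networks,min_cohorts conservation thresholds.
#' @param min_per_arm minimum samples per cohort arm.
#' @param outdir optional output directory for artifacts.
#' @param seed integer seed recorded in, and governing, the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts,
                            gene_list = NULL,
                            subtype_pairs = list(c("Basal", "LuminalA")),
                            target_subtype = "Basal",
                            lower_q = 1 / 3, upper_q = 2 / 3,
                            alpha = 1, pseudocounts = c(1, 1, 1),
                            max_classes = 7,
                            dominance_frac = 0.85, insubstantial_frac = 0.60,
                            edge_fraction = 0.01,
                            threshold_mode = c("rank", "magnitude"),
                            include_insubstantial = TRUE,
                            hub_k = 2,
                            min_networks = 6, min_cohorts = 2,
                            min_per_arm = 10,
                            outdir = NULL,
                            seed = 1) {
  structure(list(
    cohorts = cohorts, gene_list = gene_list, subtype_pairs = subtype_pairs,
    target_subtype = target_subtype, lower_q = lower_q, upper_q = upper_q,
    alpha = alpha, pseudocounts = pseudocounts, max_classes = max_classes,
    dominance_frac = dominance_frac, insubstantial_frac = insubstantial_frac,
    edge_fraction = edge_fraction, threshold_mode = match.arg(threshold_mode),
    include_insubstantial = include_insubstantial, hub_k = hub_k,
    min_networks = min_networks, min_cohorts = min_cohorts,
    min_per_arm = min_per_arm, outdir = outdir, seed = seed
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' All range and consistency checks are evaluated and the problems are
#' returned together rather than failing at the first one.
#'
#' @param config a [pipeline_config()].
#' @return Character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x > 0 && x <= 1
  if (length(config$cohorts) < 1 || is.null(names(config$cohorts))) {
    add("cohorts: need a named list of at least one cohort")
  }
  if (!frac_ok(config$edge_fraction)) add("edge_fraction: must be in (0, 1]")
  if (!frac_ok(config$dominance_frac)) add("dominance_frac: must be in (0, 1]")
  if (!frac_ok(config$insubstantial_frac)) add("insubstantial_frac: must be in (0, 1]")
  if (frac_ok(config$dominance_frac) && frac_ok(config$insubstantial_frac) &&
      config$dominance_frac <= config$insubstantial_frac) {
    add("dominance_frac: must exceed insubstantial_frac")
  }
  if (!is.numeric(config$lower_q) || !is.numeric(config$upper_q) ||
      config$lower_q <= 0 || config$upper_q >= 1 ||
      config$lower_q > config$upper_q) {
    add("lower_q/upper_q: need 0 < lower_q <= upper_q < 1")
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0) add("alpha: must be > 0")
  if (length(config$pseudocounts) != 3 || any(config$pseudocounts <= 0)) {
    add("pseudocounts: need 3 positive values")
  }
  if (!is.numeric(config$max_classes) || config$max_classes < 2) {
    add("max_classes: must be >= 2")
  }
  if (!is.numeric(config$hub_k) || config$hub_k < 1) add("hub_k: must be >= 1")
  if (!is.numeric(config$min_networks) || config$min_networks < 1) {
    add("min_networks: must be >= 1")
  }
  for (pair in config$subtype_pairs) {
    if (length(pair) != 2 || pair[1] == pair[2]) {
      add("subtype_pairs: each pair needs two distinct subtypes")
    }
  }
  errs
}

load_cohort <- function(spec, config) {
  if (!is.null(spec$simulation)) {
    sim <- simulate_cohort(spec$simulation, spec$structure)
    return(list(expression = sim$expression, annotation = sim$annotation,
                truth = sim$truth))
  }
  expr <- read_expression(spec$expression, gene_col = spec$gene_col %||% "Hugo_Symbol")
  ann <- read_subtype_labels(spec$clinical,
                             sample_col = spec$sample_col %||% "PATIENT_ID",
                             subtype_col = spec$subtype_col %||% "CLAUDIN_SUBTYPE")
  list(expression = expr, annotation = ann, truth = NULL)
}

#' Run the full stratification-to-motifs pipeline
#'
#' Executes, per cohort and subtype pair: preprocessing (gene-list
#' restriction, median-centring), discretisation, Bayesian hierarchical
#' clustering, class consolidation and labelling; then, per
#' target-subtype-dominant class, shrinkage partial-correlation network
#' inference and thresholding; finally degree aggregation, hub
#' identification, the hub-centred NPU motif census of every network, and
#' the cross-network conservation report. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list: `config_hash`, `seed`, `classes` (per
#'   cohort/pair labelling summaries), `networks` (edge/node counts),
#'   `degree_summary`, `hubs`, `censuses`, `conserved`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errs <- validate_config(config)
  if (length(errs)) {
    stop("configuration error:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  set.seed(config$seed)
  gene_list <- if (!is.null(config$gene_list)) read_gene_list(config$gene_list)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  networks <- list()
  censuses_meta <- list()
  class_reports <- list()

  for (cohort_name in names(config$cohorts)) {
    cohort <- withCallingHandlers(
      load_cohort(config$cohorts[[cohort_name]], config),
      message = function(m) invokeRestart("muffleMessage")
    )
    expr <- cohort$expression
    if (!is.null(gene_list)) {
      expr <- suppressMessages(restrict_genes(expr, gene_list))
    }
    expr <- median_center(expr)

    for (pair in config$subtype_pairs) {
      pair_id <- paste0(pair[1], "_vs_", pair[2])
      co <- tryCatch(
        build_pairwise_cohort(expr, cohort$annotation, pair[1], pair[2],
                              min_per_arm = config$min_per_arm),
        error = function(e) {
          stop("stage build_pairwise_cohort [", cohort_name, " ", pair_id, "]: ",
               conditionMessage(e), call. = FALSE)
        }
      )
      disc <- discretize_tertiles(co$expression, config$lower_q, config$upper_q)
      tree <- bhc(disc, alpha = config$alpha, pseudocounts = config$pseudocounts)
      classes <- consolidate_classes(tree, max_classes = config$max_classes)
      labels <- label_classes(classes, co$annotation,
                              dominance_frac = config$dominance_frac,
                              insubstantial_frac = config$insubstantial_frac)
      class_reports[[paste(cohort_name, pair_id, sep = ".")]] <-
        list(cohort = cohort_name, pair = pair_id,
             n_samples = ncol(co$expression$values),
             summary = labels$summary, composition = labels$composition)
      if (!is.null(outdir)) {
        readr::write_tsv(classes,
                         file.path(outdir, paste0(cohort_name, "_", pair_id, "_classes.tsv")),
                         progress = FALSE)
        export_newick(tree,
                      file.path(outdir, paste0(cohort_name, "_", pair_id, "_dendrogram.nwk")))
      }

      for (cls in dominant_classes(labels, config$target_subtype,
                                   include_insubstantial = config$include_insubstantial)) {
        net_id <- paste(cohort_name, pair_id, paste0("class", cls), sep = ".")
        cls_samples <- classes$sample_id[classes$class == cls]
        if (length(cls_samples) < 3) next
        pc <- suppressMessages(
          partial_correlations(select_samples(co$expression, cls_samples))
        )
        net <- threshold_edges(rank_edges(pc), fraction = config$edge_fraction,
                               nodes = rownames(pc$values),
                               mode = config$threshold_mode,
                               source_class = net_id)
        networks[[net_id]] <- net
        censuses_meta[[net_id]] <- list(network = net_id, cohort = cohort_name)
        if (!is.null(outdir)) {
          write_edge_list(net, file.path(outdir, paste0(net_id, "_edges.tsv")))
        }
      }
    }
  }

  if (length(networks) == 0) stop("no target-subtype-dominant class produced a network",
                                  call. = FALSE)
  degrees <- total_degree(networks)
  hubs <- identify_hubs(degrees, k = config$hub_k)

  censuses <- list()
  for (net_id in names(networks)) {
    for (hub in hubs) {
      if (!hub %in% networks[[net_id]]$nodes) next
      local <- hub_local_network(networks[[net_id]], hub)
      censuses[[paste(net_id, hub, sep = "#")]] <- list(
        network = net_id,
        cohort = censuses_meta[[net_id]]$cohort,
        census = census_hub_motifs(local)
      )
    }
  }
  conserved <- if (length(networks) >= 2 &&
                   config$min_networks <= length(networks)) {
    cross_network_conservation(censuses, min_networks = config$min_networks,
                               min_cohorts = config$min_cohorts)
  } else {
    tibble::tibble()
  }

  report <- structure(list(
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    seed = config$seed,
    classes = class_reports,
    networks = purrr::imap(networks, function(net, id) {
      list(id = id, n_nodes = length(net$nodes), n_edges = nrow(net$edges),
           n_positive = sum(net$edges$sign == "positive"),
           n_negative = sum(net$edges$sign == "negative"))
    }),
    degree_summary = degrees,
    hubs = as.character(hubs),
    censuses = censuses,
    conserved = conserved
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    write_degree_summary(degrees, file.path(outdir, "degree_summary.tsv"))
    if (length(censuses)) write_census_table(censuses, file.path(outdir, "motif_census.tsv"))
    if (nrow(conserved)) readr::write_tsv(conserved, file.path(outdir, "conserved_motifs.tsv"),
                                          progress = FALSE)
    jsonlite::write_json(report_to_json(report), file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  list(
    schema_version = "1.0",
    config_hash = report$config_hash,
    seed = report$seed,
    classes = purrr::map(report$classes, function(cr) {
      list(cohort = cr$cohort, pair = cr$pair, n_samples = cr$n_samples,
           summary = cr$summary)
    }),
    networks = report$networks,
    hubs = report$hubs,
    census = purrr::map(report$censuses, function(entry) {
      list(network = entry$network, hub = entry$census$hub,
           counts = entry$census$counts)
    }),
    conserved = report$conserved
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d network(s), hubs: %s, %d conserved triple(s)\n",
              length(x$networks), paste(x$hubs, collapse = ", "),
              if (is.null(nrow(x$conserved))) 0L else nrow(x$conserved)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
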