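#' Expression matrix container
#'
#' A light wrapper around a genes x samples numeric matrix carrying a flag
#' recording whether rows have been median-centred. All pipeline stages
#' consume this object; [tidy()] turns it into a long tibble.
#'
#' @param values numeric matrix with gene symbols as rownames and sample
#'   identifiers as colnames.
#' @param centred logical; `TRUE` once [median_center()] has been applied.
#' @return An object of class `nr_expr`.
#' @export
nr_expr <- function(values, centred = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers", call. = FALSE)
  structure(list(values = values, centred = isTRUE(centred)), class = "nr_expr")
}

#' @export
print.nr_expr <- function(x, ...) {
  cat(sprintf(
    "<nr_expr> %d genes x %d samples%s\n",
    nrow(x$values), ncol(x$values),
    if (x$centred) ", median-centred" else ""
  ))
  invisible(x)
}

#' @export
dim.nr_expr <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a cBioPortal-dialect expression table
#'
#' Parses a tab-separated table with a gene-symbol column (`Hugo_Symbol` by
#' default) followed by one numeric column per sample. An `Entrez_Gene_Id`
#' column, if present, is ignored. Rows with an empty gene symbol are
#' dropped; duplicated symbols keep the highest-variance row (with a
#' warning), on the grounds that the most variable probe is the most
#' informative one.
#'
#' @param path path to the TSV file.
#' @param gene_col name of the gene-symbol column.
#' @return An [nr_expr] with `centred = FALSE`.
#' @export
read_expression <- function(path, gene_col = "Hugo_Symbol") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA", "NaN", "null"))
  if (!gene_col %in% names(raw)) {
    stop("malformed header: expected gene column '", gene_col, "', found: ",
         paste(utils::head(names(raw), 5), collapse = ", "), call. = FALSE)
  }
  drop_cols <- intersect(c(gene_col, "Entrez_Gene_Id"), names(raw))
  sample_cols <- setdiff(names(raw), drop_cols)
  if (length(sample_cols) == 0L) stop("malformed header: no sample columns", call. = FALSE)

  symbols <- trimws(raw[[gene_col]])
  keep <- !is.na(symbols) & symbols != ""
  raw <- raw[keep, , drop = FALSE]
  symbols <- symbols[keep]

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_cols),
                 dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    cell <- raw[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], sample_cols[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  rownames(vals) <- symbols

  if (anyDuplicated(symbols)) {
    v <- apply(vals, 1, stats::var, na.rm = TRUE)
    v[is.na(v)] <- -Inf
    ord <- order(-v)                       # highest variance wins within a symbol
    keep_idx <- ord[!duplicated(symbols[ord])]
    keep_idx <- sort(keep_idx)             # retain original row order
    dups <- unique(symbols[duplicated(symbols)])
    warning(sprintf("%d duplicated gene symbol(s) (%s); kept highest-variance row each",
                    length(dups), paste(utils::head(dups, 5), collapse = ", ")),
            call. = FALSE)
    vals <- vals[keep_idx, , drop = FALSE]
  }
  nr_expr(vals, centred = FALSE)
}

#' Write an expression matrix as a cBioPortal-dialect TSV
#'
#' Inverse of [read_expression()]: the round trip preserves values and
#' identifier order.
#'
#' @param x an [nr_expr].
#' @param path output path.
#' @param gene_col header for the gene-symbol column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, gene_col = "Hugo_Symbol") {
  stopifnot(inherits(x, "nr_expr"))
  df <- tibble::as_tibble(x$values)
  df <- dplyr::bind_cols(tibble::tibble(!!gene_col := gene_ids(x)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

normalise_subtype <- function(s) {
  key <- gsub("[^a-z0-9]", "", tolower(s))
  dplyr::case_when(
    key %in% c("luminala", "luma") ~ "LuminalA",
    key %in% c("luminalb", "lumb") ~ "LuminalB",
    key %in% c("her2", "her2enriched") ~ "Her2",
    key %in% c("basal", "basallike") ~ "Basal",
    TRUE ~ "Other"                      # incl. claudin-low, normal-like, NC
  )
}

#' Read PAM50 subtype annotations from a clinical table
#'
#' Reads a tab-separated clinical table and returns one row per sample with
#' its PAM50 subtype. Claudin-low, normal-like and any unrecognised label
#' map to `Other` and are excluded from pairwise cohorts downstream.
#'
#' @param path path to the clinical TSV.
#' @param sample_col,subtype_col column names holding the sample identifier
#'   and the PAM50 label.
#' @return A tibble with columns `sample_id`, `subtype`.
#' @export
read_subtype_labels <- function(path, sample_col = "PATIENT_ID",
                                subtype_col = "CLAUDIN_SUBTYPE") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, comment = "#")
  missing <- setdiff(c(sample_col, subtype_col), names(raw))
  if (length(missing)) {
    stop("configuration error: clinical table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = trimws(raw[[sample_col]]),
    subtype = normalise_subtype(raw[[subtype_col]])
  )
  if (anyDuplicated(out$sample_id)) stop("duplicate sample identifiers in clinical table", call. = FALSE)
  out
}

#' Read a gene list (one symbol per line, `#` comments)
#'
#' An optional second whitespace-separated token per line is read as the
#' gene's role (e.g. `NR` or `coregulator`).
#'
#' @param path path to the list file.
#' @return A tibble with columns `symbol` and `role` (`NA` when absent).
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "[\t ]+")
  out <- tibble::tibble(
    symbol = vapply(parts, `[[`, character(1), 1L),
    role = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, character(1))
  )
  if (anyDuplicated(out$symbol)) stop("duplicate symbols in gene list", call. = FALSE)
  out
}

#' Restrict an expression matrix to a gene list
#'
#' Keeps the rows whose symbol is on the list, in list order, and reports
#' how many listed genes the matrix lacks (available through the
#' `absent_genes` attribute and a message).
#'
#' @param x an [nr_expr].
#' @param genes character vector of symbols, or a tibble with a `symbol`
#'   column as returned by [read_gene_list()].
#' @return The row-subset [nr_expr]; attribute `absent_genes` lists the
#'   symbols not found.
#' @export
restrict_genes <- function(x, genes) {
  stopifnot(inherits(x, "nr_expr"))
  if (is.data.frame(genes)) genes <- genes$symbol
  present <- genes[genes %in% gene_ids(x)]
  absent <- setdiff(genes, present)
  if (length(present) == 0L) stop("data error: no listed gene present in the matrix", call. = FALSE)
  message(sprintf("%d of %d listed genes present; %d absent",
                  length(present), length(genes), length(absent)))
  out <- nr_expr(x$values[present, , drop = FALSE], centred = x$centred)
  attr(out, "absent_genes") <- absent
  out
}

#' Median-centre each gene
#'
#' Subtracts each gene's own median (missing values ignored), flags the
#' matrix as centred, and is idempotent.
#'
#' @param x an [nr_expr].
#' @return The centred [nr_expr].
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "nr_expr"))
  med <- apply(x$values, 1, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("data error: gene(s) with all values missing: ",
         paste(gene_ids(x)[is.na(med)], collapse = ", "), call. = FALSE)
  }
  nr_expr(x$values - med, centred = TRUE)
}

#' Subset an expression matrix to a set of samples
#'
#' @param x an [nr_expr].
#' @param samples character vector of sample identifiers (order preserved).
#' @return The column-subset [nr_expr].
#' @export
select_samples <- function(x, samples) {
  stopifnot(inherits(x, "nr_expr"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) stop("unknown sample(s): ", paste(utils::head(missing, 5), collapse = ", "),
                            call. = FALSE)
  nr_expr(x$values[, samples, drop = FALSE], centred = x$centred)
}

#' Build a pairwise subtype cohort
#'
#' Restricts the matrix to the samples annotated with one of two subtypes
#' (e.g. Basal vs Luminal A). Samples present in the matrix but lacking an
#' annotation are dropped and counted.
#'
#' @param x an [nr_expr].
#' @param annotation tibble with `sample_id`, `subtype` columns.
#' @param a,b the two subtypes to retain (`a != b`).
#' @param min_per_arm minimum sample count required in each arm.
#' @return A list with `expression` (column-subset [nr_expr]), `annotation`
#'   (matching tibble), and `n_unannotated` (dropped sample count).
#' @export
build_pairwise_cohort <- function(x, annotation, a, b, min_per_arm = 10) {
  stopifnot(inherits(x, "nr_expr"))
  if (identical(a, b)) stop("configuration error: a and b must differ", call. = FALSE)
  ann <- dplyr::filter(annotation, .data$sample_id %in% sample_ids(x))
  n_unannotated <- ncol(x$values) - nrow(ann)
  ann <- dplyr::filter(ann, .data$subtype %in% c(a, b))
  counts <- table(factor(ann$subtype, levels = c(a, b)))
  if (any(counts == 0)) {
    stop("data error: subtype(s) absent from annotated samples: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  if (any(counts < min_per_arm)) {
    stop(sprintf("data error: fewer than %d samples in arm(s): %s", min_per_arm,
                 paste(names(counts)[counts < min_per_arm], collapse = ", ")), call. = FALSE)
  }
  keep <- sample_ids(x)[sample_ids(x) %in% ann$sample_id]
  ann <- ann[match(keep, ann$sample_id), ]
  list(expression = select_samples(x, keep),
       annotation = ann,
       n_unannotated = n_unannotated)
}
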