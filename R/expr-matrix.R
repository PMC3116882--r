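#' Expression matrix container
#'
#' `expression_matrix()` builds the package's core container: a numeric matrix
#' of log2 intensities with probes as rows and samples as columns, optionally
#' carrying a same-shaped matrix of detection-call p-values (per-probe,
#' per-sample evidence that the transcript is expressed above background).
#'
#' Probe and sample identifiers must be unique; values must be finite;
#' detection p-values, when present, must lie in \[0, 1\] and share both
#' dimnames with the intensity matrix.
#'
#' @param values Numeric matrix, probes as rows, with rownames (probe ids)
#'   and colnames (sample ids).
#' @param detection_p Optional numeric matrix of detection-call p-values with
#'   the same dimensions and dimnames as `values`.
#' @return An `expr_mat` object (a classed numeric matrix).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("a", "b")))
#' x <- expression_matrix(m)
#' dim(x)
#' @export
expression_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (probes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (probe ids) and colnames (sample ids).")
  }
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p) > 0) {
    abort(paste0("Duplicated probe id(s): ", paste(head(dup_p, 5), collapse = ", ")))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicated sample id(s): ", paste(head(dup_s, 5), collapse = ", ")))
  }
  if (any(!is.finite(values))) {
    abort("Expression values must all be finite.")
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values))) {
      abort("`detection_p` must be a matrix with the same shape as `values`.")
    }
    if (any(is.na(detection_p)) || any(detection_p < 0) || any(detection_p > 1)) {
      abort("`detection_p` entries must lie in [0, 1].")
    }
    dimnames(detection_p) <- dimnames(values)
  }
  structure(values, detection_p = detection_p, class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d probes x %d samples%s\n", nrow(x), ncol(x),
    if (is.null(attr(x, "detection_p"))) "" else " (with detection p-values)"
  ))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' Extract the intensity matrix / detection p-values
#'
#' @param x An `expr_mat`.
#' @return `exprs()` returns the bare numeric matrix; `detection_p()` returns
#'   the detection p-value matrix or `NULL`.
#' @export
exprs <- function(x) {
  m <- unclass(x)
  attr(m, "detection_p") <- NULL
  m
}

#' @rdname exprs
#' @export
detection_p <- function(x) attr(x, "detection_p")

#' @export
`[.expr_mat` <- function(x, i, j, ..., drop = FALSE) {
  m <- exprs(x)[i, j, ..., drop = FALSE]
  d <- attr(x, "detection_p")
  if (!is.null(d)) d <- d[i, j, ..., drop = FALSE]
  expression_matrix(m, d)
}

#' Probe and sample identifiers
#'
#' @param x An `expr_mat`.
#' @return Character vector of ids.
#' @export
probe_ids <- function(x) rownames(x)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x)

#' Read an expression matrix from disk
#'
#' Two dialects are supported. `"tsv"` is the native interchange format: a
#' tab-separated table whose first column holds probe ids and whose header row
#' holds sample ids. `"geo_series_matrix"` reads the expression table embedded
#' in a GEO Series-Matrix file (the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`), using the GEO
#' sample accessions as sample ids.
#'
#' @param path Path to the file.
#' @param format One of `"tsv"` or `"geo_series_matrix"`.
#' @param detection_path Optional path to a same-shaped TSV of detection-call
#'   p-values (identical probe/sample ids).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "geo_series_matrix"),
                            detection_path = NULL) {
  format <- match.arg(format)
  values <- switch(format,
    tsv = .read_expr_tsv(path),
    geo_series_matrix = .read_series_matrix(path)
  )
  det <- NULL
  if (!is.null(detection_path)) {
    det <- .read_expr_tsv(detection_path)
    if (!identical(dimnames(det), dimnames(values))) {
      abort("Detection matrix ids do not match the expression matrix.")
    }
  }
  expression_matrix(values, det)
}

.read_expr_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (ncol(tab) < 2) abort(paste0("Malformed expression table (need id column + >=1 sample): ", path))
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated probe id(s) in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  body <- tab[, -1, drop = FALSE]
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric expression column(s): ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

.read_series_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    abort("No series-matrix table block found.")
  }
  block <- lines[(beg + 1):(end - 1)]
  tab <- utils::read.delim(text = block, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- gsub('^"|"$', "", as.character(tab[[1]]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- gsub('^"|"$', "", colnames(tab)[-1])
  m
}

#' Write an expression matrix as TSV
#'
#' Doubles are serialized with shortest round-trip representation, so a
#' write/read cycle reproduces the values exactly.
#'
#' @param x An `expr_mat` (or bare matrix with dimnames).
#' @param path Output path for the intensity matrix.
#' @param detection_path Optional output path for the detection p-values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, detection_path = NULL) {
  .write_matrix_tsv(exprs(x), path)
  if (!is.null(detection_path)) {
    d <- detection_p(x)
    if (is.null(d)) abort("No detection p-values to write.")
    .write_matrix_tsv(d, detection_path)
  }
  invisible(path)
}

.write_matrix_tsv <- function(m, path) {
  tab <- tibble::as_tibble(m, rownames = "probe_id")
  readr::write_tsv(tab, path, progress = FALSE)
}

#' Read a sample annotation table
#'
#' Accepts CSV or TSV (sniffed from the header line). Requires columns
#' `sample_id` and `case_status`; `case_status` must be codable as 0/1
#' (1 = atherosclerosis case). Optional columns `frs` (Framingham 10-year
#' risk, percent) and `age` (years) are used by downstream covariate-adjusted
#' models; further columns are carried along untouched.
#'
#' @param path Path to the annotation file.
#' @return A tibble with one row per sample.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort(paste0("Empty annotation file: ", path))
  delim <- if (grepl("\t", first)) "\t" else ","
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(ann) == 0) abort(paste0("Annotation file has no rows: ", path))
  validate_annotation(ann)
}

#' Validate a sample annotation tibble
#'
#' @param ann A data frame with at least `sample_id` and `case_status`.
#' @return The validated tibble (with `case_status` coerced to integer 0/1).
#' @export
validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  miss <- setdiff(c("sample_id", "case_status"), names(ann))
  if (length(miss) > 0) {
    abort(paste0("Annotation is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ann$sample_id <- as.character(ann$sample_id)
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated sample id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  cs <- ann$case_status
  if (is.logical(cs)) cs <- as.integer(cs)
  cs <- suppressWarnings(as.numeric(cs))
  if (any(is.na(cs)) || !all(cs %in% c(0, 1))) {
    abort("`case_status` must be coded 0/1 (1 = case).")
  }
  ann$case_status <- as.integer(cs)
  if ("frs" %in% names(ann)) {
    if (any(ann$frs < 0, na.rm = TRUE)) abort("`frs` must be >= 0.")
  }
  ann
}

#' Align an expression matrix with a sample annotation table
#'
#' Restricts both inputs to the intersection of their sample ids, in matrix
#' order, warning about any samples dropped from either side.
#'
#' @param x An `expr_mat`.
#' @param ann A sample annotation tibble (see [read_annotation()]).
#' @return A list with elements `expr` and `annotation`, sample-aligned.
#' @export
align_samples <- function(x, ann) {
  ann <- validate_annotation(ann)
  common <- intersect(sample_ids(x), ann$sample_id)
  if (length(common) == 0) abort("Expression matrix and annotation share no sample ids.")
  dropped <- setdiff(union(sample_ids(x), ann$sample_id), common)
  if (length(dropped) > 0) {
    warn(paste0("Dropping ", length(dropped), " unmatched sample(s): ",
                paste(head(dropped, 5), collapse = ", ")))
  }
  keep <- sample_ids(x)[sample_ids(x) %in% common]
  list(
    expr = x[, keep],
    annotation = ann[match(keep, ann$sample_id), , drop = FALSE]
  )
}
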