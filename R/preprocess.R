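#' Log2-transform intensities
#'
#' @param x An `expr_mat` of raw intensities.
#' @param offset Non-negative constant added before taking logs (default 0).
#' @return An `expr_mat` of `log2(value + offset)`.
#' @export
log2_transform <- function(x, offset = 0) {
  if (offset < 0) abort("`offset` must be >= 0.")
  m <- exprs(x)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-positive value at probe '%s', sample '%s' (offset %g); cannot log-transform.",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], offset
    ))
  }
  expression_matrix(log2(m + offset), detection_p(x))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the identical distribution: the
#' across-sample mean of order statistics. Ties within a column receive the
#' mean of the quantile values they span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x An `expr_mat` with at least 2 samples and no missing values.
#' @return A quantile-normalized `expr_mat`.
#' @export
quantile_normalize <- function(x) {
  m <- exprs(x)
  if (ncol(m) < 2) abort("Quantile normalization needs >= 2 samples.")
  if (any(is.na(m))) abort("Quantile normalization requires complete data.")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  expression_matrix(out, detection_p(x))
}

#' Filter probes by variability and detection
#'
#' Reproduces the analysis-ready probe-set step: a probe is retained iff its
#' coefficient of variation (sd/mean) across all samples is at least
#' `cv_exclude_below` *and* it is detected (detection p below
#' `detection_alpha`) in at least `min_detected_samples` samples. Probes with
#' a non-positive mean have an undefined CV and are removed with reason
#' "degenerate". The CV is computed on the matrix exactly as supplied; callers
#' choose whether that is the pre- or post-log scale.
#'
#' If the matrix carries no detection p-values the detection filter is skipped
#' with a warning.
#'
#' @param x An `expr_mat`.
#' @param config An [analysis_config()] supplying the filter constants.
#' @return A list: `expr` (the retained probes) and `report`, a
#'   `filter_report` accounting for every input probe. `tidy()` on the report
#'   gives the per-probe table; `glance()` the counts.
#' @export
filter_probes <- function(x, config = analysis_config()) {
  validate_config(config)
  m <- exprs(x)
  d <- detection_p(x)
  mu <- rowMeans(m)
  sdev <- apply(m, 1, sd)
  degenerate <- mu <= 0
  cv <- ifelse(degenerate, NA_real_, sdev / mu)
  fail_cv <- degenerate | (!degenerate & cv < config$cv_exclude_below)
  if (any(degenerate)) {
    warn(sprintf("%d probe(s) with non-positive mean removed as degenerate.",
                 sum(degenerate)))
  }
  if (is.null(d)) {
    warn("No detection p-values present; detection filter skipped.")
    n_detected <- rep(NA_integer_, nrow(m))
    fail_det <- rep(FALSE, nrow(m))
  } else {
    n_detected <- as.integer(rowSums(d < config$detection_alpha))
    fail_det <- n_detected < config$min_detected_samples
  }
  retained <- !fail_cv & !fail_det
  probe_tab <- tibble::tibble(
    probe_id = rownames(m),
    cv = cv,
    n_detected = n_detected,
    removed_cv = fail_cv & !degenerate,
    removed_detection = fail_det,
    degenerate = degenerate,
    retained = retained
  )
  report <- structure(
    list(
      n_input_probes = nrow(m),
      n_removed_cv = sum(fail_cv),
      n_removed_detection = sum(fail_det),
      n_retained = sum(retained),
      probes = probe_tab
    ),
    class = "filter_report"
  )
  list(expr = x[retained, ], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d probes in; %d failed CV, %d failed detection; %d retained\n",
    x$n_input_probes, x$n_removed_cv, x$n_removed_detection, x$n_retained
  ))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$probes

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(
    n_input_probes = x$n_input_probes,
    n_removed_cv = x$n_removed_cv,
    n_removed_detection = x$n_removed_detection,
    n_retained = x$n_retained
  )
}
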