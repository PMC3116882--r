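#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults reproduce the
#' study design the package emulates: probes are excluded when their
#' coefficient of variation falls below 0.03 or when they are called detected
#' (detection p < 0.01) in fewer than 61 samples; the subtype procedure uses
#' the top 50 genes by absolute t statistic, 10 stratified folds, 1,000
#' repeats, and a strict majority vote.
#'
#' @param cv_exclude_below Probes with coefficient of variation below this are
#'   excluded (default 0.03).
#' @param detection_alpha Detection-call threshold: a probe counts as detected
#'   in a sample when its detection p-value is below this (default 0.01).
#' @param min_detected_samples Minimum number of samples a probe must be
#'   detected in to be retained (default 61, i.e. "detected in more than 60
#'   samples" for a 119-sample cohort).
#' @param k_genes Number of top-ranked genes per training set (default 50).
#' @param k_genes_sweep Range of k values for [sweep_k()] (default 1:100).
#' @param n_folds Number of stratified cross-validation folds (default 10).
#' @param n_repeats Number of repeats of the whole fold/train/vote cycle
#'   (default 1000).
#' @param vote_threshold Votes strictly above this make a sample
#'   atherosclerosis-profile positive; `NULL` means `n_repeats / 2`
#'   (strict majority).
#' @param kernel,cost,gamma Support-vector-machine hyperparameters; `gamma =
#'   NULL` means `1 / k_genes`.
#' @param n_permutations Label permutations for the SAM false-discovery
#'   estimate (default 1000).
#' @param rng_seed Integer seed from which all per-repeat seeds are derived.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(cv_exclude_below = 0.03,
                            detection_alpha = 0.01,
                            min_detected_samples = 61L,
                            k_genes = 50L,
                            k_genes_sweep = 1:100,
                            n_folds = 10L,
                            n_repeats = 1000L,
                            vote_threshold = NULL,
                            kernel = c("radial", "linear"),
                            cost = 1,
                            gamma = NULL,
                            n_permutations = 1000L,
                            rng_seed = 1L) {
  kernel <- match.arg(kernel)
  cfg <- list(
    cv_exclude_below = cv_exclude_below,
    detection_alpha = detection_alpha,
    min_detected_samples = as.integer(min_detected_samples),
    k_genes = as.integer(k_genes),
    k_genes_sweep = as.integer(k_genes_sweep),
    n_folds = as.integer(n_folds),
    n_repeats = as.integer(n_repeats),
    vote_threshold = vote_threshold,
    kernel = kernel,
    cost = cost,
    gamma = gamma,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (cfg$n_folds < 2) abort("`n_folds` must be >= 2.")
  if (cfg$n_repeats < 1) abort("`n_repeats` must be >= 1.")
  if (cfg$cv_exclude_below < 0) abort("`cv_exclude_below` must be >= 0.")
  if (cfg$detection_alpha <= 0 || cfg$detection_alpha >= 1) {
    abort("`detection_alpha` must lie in (0, 1).")
  }
  if (cfg$min_detected_samples < 0) abort("`min_detected_samples` must be >= 0.")
  if (!(cfg$k_genes %in% cfg$k_genes_sweep)) {
    abort("`k_genes` must lie within `k_genes_sweep`.")
  }
  if (!is.null(cfg$vote_threshold) &&
      (cfg$vote_threshold < 0 || cfg$vote_threshold > cfg$n_repeats)) {
    abort("`vote_threshold` must lie in [0, n_repeats].")
  }
  if (cfg$n_permutations < 1) abort("`n_permutations` must be >= 1.")
  cfg
}

#' Read an analysis configuration from YAML
#'
#' The YAML file mirrors [analysis_config()] field for field; absent fields
#' keep their defaults, unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  flat <- x
  flat$k_genes_sweep <- paste0(min(x$k_genes_sweep), "-", max(x$k_genes_sweep))
  flat$vote_threshold <- x$vote_threshold %||% "n_repeats/2 (strict majority)"
  flat$gamma <- x$gamma %||% "1/k_genes"
  for (nm in names(flat)) cat(sprintf("  %-22s %s\n", nm, flat[[nm]]))
  invisible(x)
}
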