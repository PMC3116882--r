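# Small in-code fixtures used across the suite.

# A tiny expression matrix with named probes/samples.
toy_expr <- function(values, n_probes = NULL, n_samples = NULL,
                     detection = NULL) {
  if (is.matrix(values)) {
    m <- values
  } else {
    m <- matrix(values, n_probes, n_samples)
  }
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, detection)
}

# Gaussian matrix with an optional planted two-group shift on some probes.
random_expr <- function(n_probes, n_samples, seed = 1, shift = 0,
                        shift_probes = integer(0), labels = NULL,
                        noise_sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples, sd = noise_sd), n_probes, n_samples)
  if (length(shift_probes) > 0 && !is.null(labels)) {
    m[shift_probes, labels == 1] <- m[shift_probes, labels == 1] + shift
  }
  rownames(m) <- sprintf("p%03d", seq_len(n_probes))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  expression_matrix(m)
}

# Balanced binary labels.
toy_labels <- function(n1, n0) c(rep(1L, n1), rep(0L, n0))

# A small, fast cohort for pipeline-level tests.
small_cohort_spec <- function(seed = 1, ...) {
  cohort_spec(n_cases = 20L, n_controls = 30L, n_probes = 300L, seed = seed, ...)
}
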