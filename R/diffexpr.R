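#' Per-probe two-sample t tests
#'
#' Computes, for every probe, the two-sample t statistic comparing cases
#' (label 1) with controls (label 0), a two-sided p-value, and the log2 fold
#' change (case mean minus control mean). The default is the
#' unequal-variance (Welch) test with Welch-Satterthwaite degrees of freedom;
#' `var_equal = TRUE` gives the pooled-variance test. Probes at which both
#' groups have essentially zero variance are computed with a variance floor
#' of 1e-12 and flagged.
#'
#' @param x An `expr_mat` (log2 scale).
#' @param labels Binary vector (1 = case), one entry per sample.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return A tibble of class `de_result` with columns `probe_id`, `t`, `df`,
#'   `p_value`, `log2_fc`, `mean_case`, `mean_control`, `low_variance`.
#' @export
welch_t <- function(x, labels, var_equal = FALSE) {
  m <- exprs(x)
  labels <- .check_labels(labels, ncol(m))
  g1 <- which(labels == 1)
  g0 <- which(labels == 0)
  if (length(g1) < 2 || length(g0) < 2) {
    abort("Each group needs at least 2 samples.")
  }
  st <- .row_t(m, g1, g0, var_equal = var_equal)
  tibble::new_tibble(
    tibble::tibble(
      probe_id = rownames(m),
      t = unname(st$t), df = unname(st$df), p_value = unname(st$p),
      log2_fc = unname(st$fc),
      mean_case = unname(st$m1), mean_control = unname(st$m0),
      low_variance = unname(st$low_var)
    ),
    class = "de_result"
  )
}

# Vectorized row-wise two-sample t. Returns list of vectors.
.row_t <- function(m, g1, g0, var_equal = FALSE, var_floor = 1e-12) {
  n1 <- length(g1); n0 <- length(g0)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m0 <- rowMeans(m[, g0, drop = FALSE])
  v1 <- rowSums((m[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((m[, g0, drop = FALSE] - m0)^2) / (n0 - 1)
  low_var <- (v1 + v0) < var_floor
  v1f <- pmax(v1, ifelse(low_var, var_floor, 0))
  v0f <- pmax(v0, ifelse(low_var, var_floor, 0))
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1f + (n0 - 1) * v0f) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(m1))
  } else {
    se <- sqrt(v1f / n1 + v0f / n0)
    df <- (v1f / n1 + v0f / n0)^2 /
      ((v1f / n1)^2 / (n1 - 1) + (v0f / n0)^2 / (n0 - 1))
  }
  tt <- (m1 - m0) / se
  p <- 2 * pt(-abs(tt), df)
  list(t = tt, df = df, p = p, fc = m1 - m0, m1 = m1, m0 = m0, low_var = low_var)
}

.check_labels <- function(labels, n) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  if (length(labels) != n) abort("`labels` length must equal the sample count.")
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    abort("`labels` must be coded 0/1.")
  }
  as.integer(labels)
}

#' Two-sample t test from summary statistics
#'
#' Recomputes a two-group comparison from printed summary statistics
#' (mean, SD, n per group), as needed to reproduce cohort-characteristics
#' tables. Welch by default.
#'
#' @param mean1,sd1,n1 Group 1 summary.
#' @param mean2,sd2,n2 Group 2 summary.
#' @param var_equal Use pooled variance.
#' @return A tibble with columns `t`, `df`, `p_value`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be >= 0.")
  if (sd1 == 0 && sd2 == 0) abort("Both SDs are zero; t is undefined.")
  v1 <- sd1^2; v2 <- sd2^2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  tibble::tibble(t = tt, df = df, p_value = 2 * pt(-abs(tt), df))
}

#' Storey q-values and the proportion of null features
#'
#' Estimates pi0 (the proportion of truly null features) by evaluating
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a lambda grid and
#' smoothing with a natural cubic spline (3 df), taking the smoothed value at
#' the largest lambda; short vectors fall back to the fixed-lambda estimate at
#' `lambda = 0.5`. q-values are the step-up quantities
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j`, clipped to \[0, 1\].
#' With `pi0` forced to 1 this reduces exactly to Benjamini-Hochberg.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param lambda Grid of lambda values in \[0, 1) (default `seq(0, 0.90, 0.05)`).
#' @param pi0_method `"spline"` (default; needs `length(p) >= 10`) or
#'   `"fixed_lambda"`.
#' @param fixed_lambda Lambda used by the fixed-lambda fallback (default 0.5).
#' @param pi0 Optionally force pi0 (e.g. `pi0 = 1` for plain BH).
#' @return A list with `q_values` (same order as `p`) and `pi0_estimate`
#'   (class `pi0_estimate`; see [estimate_de_fraction()]).
#' @export
storey_qvalue <- function(p, lambda = seq(0, 0.90, by = 0.05),
                          pi0_method = c("spline", "fixed_lambda"),
                          fixed_lambda = 0.5, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m == 0) abort("Empty p-value vector.")
  if (is.null(pi0)) {
    if (pi0_method == "spline" && m < 10) pi0_method <- "fixed_lambda"
    raw <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    if (pi0_method == "spline") {
      fit <- smooth.spline(lambda, raw, df = 3)
      pi0_hat <- predict(fit, x = max(lambda))$y
    } else {
      pi0_hat <- mean(p > fixed_lambda) / (1 - fixed_lambda)
    }
    pi0_hat <- min(max(pi0_hat, 1e-8), 1)
    est <- structure(
      list(pi0 = pi0_hat, lambda = lambda, pi0_lambda = raw,
           method = pi0_method),
      class = "pi0_estimate"
    )
  } else {
    if (pi0 <= 0 || pi0 > 1) abort("`pi0` must lie in (0, 1].")
    pi0_hat <- pi0
    est <- structure(
      list(pi0 = pi0_hat, lambda = numeric(0), pi0_lambda = numeric(0),
           method = "forced"),
      class = "pi0_estimate"
    )
  }
  o <- order(p)
  qo <- pi0_hat * m * p[o] / seq_len(m)
  qo <- rev(cummin(rev(qo)))
  q <- numeric(m)
  q[o] <- pmin(qo, 1)
  list(q_values = q, pi0_estimate = est)
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("<pi0_estimate> pi0 = %.4f (method: %s)\n", x$pi0, x$method))
  invisible(x)
}

#' @export
tidy.pi0_estimate <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, pi0_lambda = x$pi0_lambda)
}

#' Estimated fraction of differentially expressed features
#'
#' @param pi0_estimate A `pi0_estimate` from [storey_qvalue()].
#' @return `1 - pi0`: the estimated proportion of features that are truly
#'   differentially expressed.
#' @export
estimate_de_fraction <- function(pi0_estimate) {
  stopifnot(inherits(pi0_estimate, "pi0_estimate"))
  1 - pi0_estimate$pi0
}

#' SAM-style permutation false discovery rates
#'
#' Computes the moderated d statistic `d_i = (case mean - control mean) /
#' (pooled standard error + s0)`, choosing the fudge factor s0 from candidate
#' percentiles \{0, 5, ..., 100\} of the standard-error distribution so as to
#' minimize the coefficient of variation of the spread of d across
#' standard-error bins. Label permutations (full enumeration when at most
#' `n_permutations` distinct case assignments exist) yield the median number
#' of false calls and an FDR estimate at each |d| cutoff, scaled by a
#' permutation-based pi0.
#'
#' @param x An `expr_mat`.
#' @param labels Binary vector (1 = case).
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @param n_cutoffs Size of the |d| cutoff grid for the FDR table.
#' @return A `sam_result`: list with per-probe `d`, `se`, the chosen `s0` and
#'   its percentile, `pi0`, and `table`, a tibble of
#'   (`cutoff`, `called`, `median_false`, `fdr`). `glance()` summarizes.
#' @export
sam_permutation <- function(x, labels, n_permutations = 1000L, seed = 1L,
                            n_cutoffs = 100L) {
  m <- exprs(x)
  labels <- .check_labels(labels, ncol(m))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both groups must be non-empty.")
  if (n_permutations < 100) abort("`n_permutations` must be >= 100.")
  g1 <- which(labels == 1); g0 <- which(labels == 0)

  sam_stat <- function(idx1) {
    idx0 <- setdiff(seq_len(ncol(m)), idx1)
    mm1 <- rowMeans(m[, idx1, drop = FALSE])
    mm0 <- rowMeans(m[, idx0, drop = FALSE])
    v1 <- rowSums((m[, idx1, drop = FALSE] - mm1)^2)
    v0 <- rowSums((m[, idx0, drop = FALSE] - mm0)^2)
    sp <- sqrt((1 / length(idx1) + 1 / length(idx0)) *
                 (v1 + v0) / (length(idx1) + length(idx0) - 2))
    list(r = mm1 - mm0, s = sp)
  }

  obs <- sam_stat(g1)
  s0 <- .sam_s0(obs$r, obs$s)

  d_obs <- obs$r / (obs$s + s0$s0)

  # permutation null
  n_all <- ncol(m)
  n_distinct <- choose(n_all, n1)
  withr_seed <- seed
  set.seed(withr_seed)
  if (!is.na(n_distinct) && n_distinct <= n_permutations) {
    perms <- utils::combn(n_all, n1, simplify = FALSE)
  } else {
    perms <- replicate(n_permutations, sample(n_all, n1), simplify = FALSE)
  }
  d_perm <- vapply(perms, function(idx1) {
    st <- sam_stat(idx1)
    st$r / (st$s + s0$s0)
  }, numeric(nrow(m)))

  # pi0: fraction of observed d inside the central half of the permutation d's
  q25 <- quantile(d_perm, 0.25)
  q75 <- quantile(d_perm, 0.75)
  pi0 <- min(1, sum(d_obs >= q25 & d_obs <= q75) / (0.5 * length(d_obs)))

  cutoffs <- unique(quantile(abs(d_obs), probs = seq(0, 1, length.out = n_cutoffs)))
  called <- vapply(cutoffs, function(cc) sum(abs(d_obs) >= cc), integer(1))
  med_false <- vapply(cutoffs, function(cc) {
    median(colSums(abs(d_perm) >= cc))
  }, numeric(1))
  fdr <- ifelse(called > 0, pmin(1, pi0 * med_false / called), NA_real_)

  structure(
    list(
      probe_id = rownames(m),
      d = unname(d_obs), se = unname(obs$s), s0 = s0$s0,
      s0_percentile = s0$percentile,
      pi0 = pi0, n_permutations = length(perms), seed = seed,
      table = tibble::tibble(cutoff = as.numeric(cutoffs), called = called,
                             median_false = med_false, fdr = fdr)
    ),
    class = "sam_result"
  )
}

# SAM fudge-factor selection: candidates are percentiles of the
# per-probe standard error; pick the one minimizing the coefficient of
# variation of the MAD of d across s-quantile bins.
.sam_s0 <- function(r, s, candidates = seq(0, 1, by = 0.05), n_bins = 100L) {
  n_bins <- min(n_bins, max(2L, floor(length(s) / 5)))
  brk <- unique(quantile(s, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(s, breaks = brk, include.lowest = TRUE)
  cand_s0 <- quantile(s, probs = candidates)
  cvs <- vapply(cand_s0, function(a) {
    d_a <- r / (s + a)
    v <- tapply(d_a, bin, function(z) mad(z))
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cvs)
  list(s0 = unname(cand_s0[best]), percentile = candidates[best] * 100)
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "<sam_result> %d probes; s0 = %.4g (%.0fth percentile); pi0 = %.3f; %d permutations\n",
    length(x$d), x$s0, x$s0_percentile, x$pi0, x$n_permutations
  ))
  invisible(x)
}

#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(
    n_probes = length(x$d), s0 = x$s0, s0_percentile = x$s0_percentile,
    pi0 = x$pi0, n_permutations = x$n_permutations
  )
}

#' Number of features called at an FDR threshold by SAM
#'
#' Walks the |d|-cutoff table and reports the largest called set whose
#' estimated FDR is below `fdr`.
#'
#' @param x A `sam_result`.
#' @param fdr FDR threshold.
#' @return Named list: `called` (count) and `cutoff` (the |d| cutoff used).
#' @export
sam_called_at_fdr <- function(x, fdr) {
  stopifnot(inherits(x, "sam_result"))
  ok <- which(!is.na(x$table$fdr) & x$table$fdr < fdr)
  if (length(ok) == 0) return(list(called = 0L, cutoff = NA_real_))
  best <- ok[which.max(x$table$called[ok])]
  list(called = x$table$called[best], cutoff = x$table$cutoff[best])
}

#' Binned p-value histogram with uniform reference
#'
#' @param p Vector of p-values.
#' @param n_bins Number of equal-width bins (>= 2).
#' @return A tibble of class `pvalue_histogram` with columns `bin_low`,
#'   `bin_high`, `count`, and `expected` (the uniform reference `m / n_bins`).
#' @export
pvalue_histogram <- function(p, n_bins = 20L) {
  if (length(p) == 0) abort("Empty p-value vector.")
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  if (any(p < 0 | p > 1)) abort("All p-values must lie in [0, 1].")
  brk <- seq(0, 1, length.out = n_bins + 1)
  cnt <- as.integer(table(cut(p, breaks = brk, include.lowest = TRUE)))
  tibble::new_tibble(
    tibble::tibble(
      bin_low = brk[-length(brk)], bin_high = brk[-1],
      count = cnt, expected = length(p) / n_bins
    ),
    class = "pvalue_histogram"
  )
}
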