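#' Synthetic cohort specification
#'
#' Describes the study conditions the generator emulates: a 119-woman
#' case-control cohort (48 cases with subclinical atherosclerosis, 71
#' controls), ~2,057 analysis-ready probes, a latent binary molecular subtype
#' linked to case status at sensitivity 0.60 / specificity 0.76, 20% of
#' probes differentially expressed between the subtype strata, four
#' block-correlated probe groups emulating the major co-expression clusters,
#' per-probe/per-sample detection p-values, and Framingham-risk / age
#' covariates drawn from the published group summaries.
#'
#' @param n_cases,n_controls Group sizes (48 / 71).
#' @param n_probes Number of probes (2057).
#' @param frac_de Fraction of probes differentially expressed between the
#'   subtype strata (0.20).
#' @param effect_size_sd SD (log2 units) of the planted subtype effects
#'   (0.5); effects are truncated away from 0 at `min_effect`.
#' @param min_effect Minimum absolute planted effect (0.1 log2 units).
#' @param sensitivity `P(subtype = 1 | case)` (0.60).
#' @param specificity `P(subtype = 0 | control)` (0.76).
#' @param n_blocks Number of correlated probe blocks (4).
#' @param block_cor Within-block correlation of probe noise (0.6). One block
#'   shares its factor with inverse sign to emulate the anticorrelated
#'   cluster pair seen in blood co-expression structure.
#' @param noise_sd Per-measurement noise SD, log2 units (0.7).
#' @param baseline_range Range of per-probe baseline means, log2 units.
#' @param detect_fail_rate Target fraction of probe/sample pairs failing the
#'   detection call at p >= 0.01 (0.05).
#' @param frs_case,frs_control,age_case,age_control `c(mean, sd)` of the
#'   covariate models per group (FRS truncated at 0).
#' @param seed Integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 48L, n_controls = 71L, n_probes = 2057L,
                        frac_de = 0.20, effect_size_sd = 0.5,
                        min_effect = 0.1,
                        sensitivity = 0.60, specificity = 0.76,
                        n_blocks = 4L, block_cor = 0.6, noise_sd = 0.7,
                        baseline_range = c(6, 12),
                        detect_fail_rate = 0.05,
                        frs_case = c(5.8, 4.5), frs_control = c(2.6, 2.9),
                        age_case = c(69.4, 6.8), age_control = c(64.3, 7.3),
                        seed = 1L) {
  spec <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_probes = as.integer(n_probes), frac_de = frac_de,
    effect_size_sd = effect_size_sd, min_effect = min_effect,
    sensitivity = sensitivity, specificity = specificity,
    n_blocks = as.integer(n_blocks), block_cor = block_cor,
    noise_sd = noise_sd, baseline_range = baseline_range,
    detect_fail_rate = detect_fail_rate,
    frs_case = frs_case, frs_control = frs_control,
    age_case = age_case, age_control = age_control,
    seed = as.integer(seed)
  )
  if (spec$frac_de < 0 || spec$frac_de > 1) abort("`frac_de` must lie in [0, 1].")
  if (spec$sensitivity <= 0 || spec$sensitivity >= 1 ||
      spec$specificity <= 0 || spec$specificity >= 1) {
    abort("`sensitivity` and `specificity` must lie in (0, 1).")
  }
  if (spec$n_blocks > spec$n_probes) abort("More blocks than probes.")
  if (spec$block_cor < 0 || spec$block_cor >= 1) abort("`block_cor` must lie in [0, 1).")
  structure(spec, class = "cohort_spec")
}

#' Expected crude odds ratio implied by a cohort spec
#'
#' Closed form for the subtype-vs-phenotype odds ratio implied by the
#' (sensitivity, specificity) linkage:
#' `(sens / (1 - sens)) / ((1 - spec) / spec)`. For the defaults
#' (0.60, 0.76) this is 4.75.
#'
#' @param spec A [cohort_spec()].
#' @return The implied odds ratio.
#' @export
expected_crude_or <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  (spec$sensitivity / (1 - spec$sensitivity)) /
    ((1 - spec$specificity) / spec$specificity)
}

# |N(0, sd)| >= min via rejection sampling.
.rtrunc_effect <- function(n, sd, min_abs) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rnorm(2 * n, 0, sd)
    out <- c(out, cand[abs(cand) >= min_abs])
  }
  out[seq_len(n)]
}

.rtrunc_pos <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rnorm(2 * n, mean, sd)
    out <- c(out, cand[cand >= 0])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with a planted molecular subtype
#'
#' Draws the full study design described by a [cohort_spec()]. The latent
#' subtype is assigned with *exact* counts (`round(sensitivity * n_cases)`
#' subtype-positive cases, `round((1 - specificity) * n_controls)`
#' subtype-positive controls; which samples is random), so the ground-truth
#' confusion structure is conserved exactly. Planted effects shift the
#' differentially expressed probes between the subtype strata; block
#' correlation is induced by per-sample latent factors with loadings confined
#' to disjoint probe blocks (one block pair anticorrelated); detection
#' p-values are drawn from a two-component model so that about
#' `detect_fail_rate` of probe/sample pairs fail detection at p >= 0.01.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `expr` (an `expr_mat` with
#'   detection p-values, log2 scale), `annotation` (tibble `sample_id`,
#'   `case_status`, `frs`, `age`), and `truth` (list with `samples` tibble
#'   `sample_id`, `subtype` and `probes` tibble `probe_id`, `de`, `effect`,
#'   `block`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  case <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  n_z_case <- round(spec$sensitivity * spec$n_cases)
  n_z_ctrl <- round((1 - spec$specificity) * spec$n_controls)
  if (n_z_case < 1 || n_z_ctrl < 0 || n_z_case > spec$n_cases ||
      n_z_ctrl > spec$n_controls) {
    abort("Infeasible sensitivity/specificity for these group sizes.")
  }
  z <- integer(n)
  z[sample(which(case == 1), n_z_case)] <- 1L
  z[sample(which(case == 0), n_z_ctrl)] <- 1L

  g <- spec$n_probes
  probe_id <- sprintf("P%05d", seq_len(g))
  sample_id <- sprintf("S%03d", seq_len(n))
  de <- rep(FALSE, g)
  de[sample(g, round(spec$frac_de * g))] <- TRUE
  effect <- numeric(g)
  effect[de] <- .rtrunc_effect(sum(de), spec$effect_size_sd, spec$min_effect)
  block <- as.integer(cut(seq_len(g), breaks = spec$n_blocks, labels = FALSE))

  mu <- runif(g, spec$baseline_range[1], spec$baseline_range[2])
  rho <- spec$block_cor
  # factor loadings: block b loads on factor b; when >= 3 blocks, block 3
  # additionally shares factor 1 with inverse sign (anticorrelated pair)
  fac <- matrix(rnorm(spec$n_blocks * n), spec$n_blocks, n)
  shared <- matrix(0, g, n)
  if (rho > 0) {
    for (b in seq_len(spec$n_blocks)) {
      idx <- which(block == b)
      if (spec$n_blocks >= 3 && b == 3) {
        shared[idx, ] <- matrix(
          -sqrt(0.5) * fac[1, ] + sqrt(0.5) * fac[3, ],
          length(idx), n, byrow = TRUE
        )
      } else {
        shared[idx, ] <- matrix(fac[b, ], length(idx), n, byrow = TRUE)
      }
    }
  }
  eps <- matrix(rnorm(g * n), g, n)
  values <- mu + outer(effect, as.numeric(z)) +
    spec$noise_sd * (sqrt(rho) * shared + sqrt(1 - rho) * eps)
  dimnames(values) <- list(probe_id, sample_id)

  # detection p-values: two-component model
  u <- spec$detect_fail_rate / 0.99  # so that ~detect_fail_rate have p >= 0.01
  unexpressed <- matrix(runif(g * n) < u, g, n)
  det <- matrix(runif(g * n, 0, 0.001), g, n)
  det[unexpressed] <- runif(sum(unexpressed))
  dimnames(det) <- dimnames(values)

  frs <- numeric(n); age <- numeric(n)
  frs[case == 1] <- .rtrunc_pos(spec$n_cases, spec$frs_case[1], spec$frs_case[2])
  frs[case == 0] <- .rtrunc_pos(spec$n_controls, spec$frs_control[1], spec$frs_control[2])
  age[case == 1] <- rnorm(spec$n_cases, spec$age_case[1], spec$age_case[2])
  age[case == 0] <- rnorm(spec$n_controls, spec$age_control[1], spec$age_control[2])

  structure(
    list(
      expr = expression_matrix(values, det),
      annotation = tibble::tibble(
        sample_id = sample_id, case_status = case, frs = frs, age = age
      ),
      truth = list(
        samples = tibble::tibble(sample_id = sample_id, subtype = z),
        probes = tibble::tibble(probe_id = probe_id, de = de,
                                effect = effect, block = block)
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d probes x %d samples (%d cases / %d controls); %d DE probes; %d subtype-positive\n",
    nrow(x$expr), ncol(x$expr), sum(x$annotation$case_status),
    sum(1 - x$annotation$case_status), sum(x$truth$probes$de),
    sum(x$truth$samples$subtype)
  ))
  invisible(x)
}

#' Generate a null cohort with no planted structure
#'
#' Labels are exchangeable with expression: no subtype-probe and no
#' subtype-phenotype dependence. Probe noise is i.i.d. (no planted effects
#' and no block factors), so p-value calibration checks carry binomial
#' precision.
#'
#' @param spec A [cohort_spec()]; `frac_de` and `block_cor` are forced to 0.
#' @return A `synthetic_cohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  null_spec <- spec
  null_spec$frac_de <- 0
  null_spec$block_cor <- 0
  generate_cohort(null_spec)
}

#' Generate a paired baseline/post-stimulus dataset
#'
#' Emulates an acute-stimulus (endotoxin-challenge-like) design paired with
#' the chronic cohort: the same probes as [generate_cohort()] under `spec`,
#' measured in `n_subjects` paired baseline/post samples. For a
#' `shared_effect_fraction` of the cohort's differentially expressed probes,
#' the post-stimulus shift is drawn correlated at `cross_corr` with the
#' cohort's planted subtype effect; remaining probes do not respond. Acute
#' stimulus responses are larger than the chronic subtype contrasts, hence
#' the larger default shift scale.
#'
#' @param spec A [cohort_spec()] (its seed drives this draw too).
#' @param shared_effect_fraction Fraction of cohort DE probes that also
#'   respond to the stimulus (default 1).
#' @param cross_corr Planted correlation between cohort effects and stimulus
#'   shifts on the shared set, in \[-1, 1\] (default 0.6).
#' @param n_subjects Number of paired subjects (default 8).
#' @param stimulus_sd SD of the stimulus shifts, log2 units (default 1.0).
#' @param paired_noise_sd Within-subject measurement noise SD (default 0.4).
#' @return A list of class `paired_stimulus`: `baseline` and `post`
#'   `expr_mat`s and `truth`, a tibble (`probe_id`, `cohort_effect`,
#'   `shift`, `shared`).
#' @export
generate_paired_stimulus <- function(spec = cohort_spec(),
                                     shared_effect_fraction = 1,
                                     cross_corr = 0.6,
                                     n_subjects = 8L,
                                     stimulus_sd = 1.0,
                                     paired_noise_sd = 0.4) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (cross_corr < -1 || cross_corr > 1) abort("`cross_corr` must lie in [-1, 1].")
  if (shared_effect_fraction < 0 || shared_effect_fraction > 1) {
    abort("`shared_effect_fraction` must lie in [0, 1].")
  }
  cohort <- generate_cohort(spec)
  probes <- cohort$truth$probes
  g <- nrow(probes)
  set.seed(.mix_seed(spec$seed, 104729L))
  de_idx <- which(probes$de)
  shared <- rep(FALSE, g)
  shared[sample(de_idx, round(shared_effect_fraction * length(de_idx)))] <- TRUE
  shift <- numeric(g)
  if (any(shared)) {
    e_std <- probes$effect[shared] / max(sd(probes$effect[de_idx]), 1e-12)
    shift[shared] <- stimulus_sd *
      (cross_corr * e_std + sqrt(1 - cross_corr^2) * rnorm(sum(shared)))
  }
  mu <- runif(g, spec$baseline_range[1], spec$baseline_range[2])
  subj <- sprintf("B%02d", seq_len(n_subjects))
  base_m <- mu + paired_noise_sd * matrix(rnorm(g * n_subjects), g, n_subjects)
  post_m <- mu + shift + paired_noise_sd * matrix(rnorm(g * n_subjects), g, n_subjects)
  dimnames(base_m) <- dimnames(post_m) <- list(probes$probe_id, subj)
  structure(
    list(
      baseline = expression_matrix(base_m),
      post = expression_matrix(post_m),
      truth = tibble::tibble(
        probe_id = probes$probe_id,
        cohort_effect = probes$effect,
        shift = shift,
        shared = shared
      )
    ),
    class = "paired_stimulus"
  )
}
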