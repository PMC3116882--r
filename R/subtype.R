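#' Stratified fold assignment
#'
#' Randomly divides samples into `n_folds` groups of approximately equal size
#' such that every fold carries approximately the same number of cases
#' (per-fold sizes and per-fold case counts each differ by at most 1).
#' Deterministic given `seed`.
#'
#' @param labels Binary vector (1 = case).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
stratified_partition <- function(labels, n_folds, seed) {
  labels <- .check_labels(labels, length(labels))
  n <- length(labels)
  n1 <- sum(labels == 1); n0 <- n - n1
  if (min(n1, n0) < n_folds) {
    abort("Each class must have at least `n_folds` members.")
  }
  set.seed(seed)
  # Per-fold case counts and total sizes, with the "extra" samples aligned on
  # the same folds so that control counts also differ by at most 1.
  c1 <- rep(n1 %/% n_folds, n_folds)
  e1 <- n1 %% n_folds
  if (e1 > 0) c1[seq_len(e1)] <- c1[seq_len(e1)] + 1L
  sz <- rep(n %/% n_folds, n_folds)
  e <- n %% n_folds
  if (e > 0) sz[seq_len(e)] <- sz[seq_len(e)] + 1L
  c0 <- sz - c1
  stopifnot(all(c0 >= 0), sum(c0) == n0)
  fold_order <- sample(n_folds)
  c1 <- c1[order(fold_order)]; c0 <- c0[order(fold_order)]
  folds <- integer(n)
  folds[sample(which(labels == 1))] <- rep(seq_len(n_folds), times = c1)
  folds[sample(which(labels == 0))] <- rep(seq_len(n_folds), times = c0)
  folds
}

#' Rank probes by absolute t statistic within a training set
#'
#' Orders probes by decreasing |t| (two-sample t comparing cases and controls
#' in the training samples), breaking ties by probe id so the ranking is
#' deterministic.
#'
#' @param x An `expr_mat` restricted to the training samples.
#' @param labels Binary training labels (both classes must be present).
#' @param var_equal Use the pooled-variance t statistic.
#' @return Character vector of probe ids, best first.
#' @export
rank_genes_by_t <- function(x, labels, var_equal = FALSE) {
  labels <- .check_labels(labels, ncol(x))
  if (length(unique(labels)) < 2) abort("Training set must contain both classes.")
  m <- exprs(x)
  st <- .row_t(m, which(labels == 1), which(labels == 0), var_equal = var_equal)
  ids <- rownames(m)
  ids[order(-abs(st$t), ids)]
}

#' Train a classifier on top-ranked genes and classify test samples
#'
#' Selects the `k_genes` probes with the largest |t| in the training set,
#' standardizes each selected probe by its training mean and SD, fits a
#' support-vector machine ([e1071::svm()]; radial kernel, cost 1, gamma
#' `1/k_genes` by default), and predicts the test samples. Nothing is learned
#' from the test columns: gene ranking and standardization parameters come
#' from the training data only.
#'
#' @param train_x,train_labels Training `expr_mat` and binary labels.
#' @param test_x Test `expr_mat` (same probes).
#' @param k_genes Number of top-ranked probes to use.
#' @param kernel,cost,gamma SVM hyperparameters (`gamma = NULL` means
#'   `1/k_genes`).
#' @return Integer vector of 0/1 predictions, one per test sample, with
#'   attributes `probes_used`, `center`, `scale` (the training-derived
#'   parameters, exposed for leakage checks).
#' @export
fit_and_classify <- function(train_x, train_labels, test_x, k_genes,
                             kernel = "radial", cost = 1, gamma = NULL) {
  train_labels <- .check_labels(train_labels, ncol(train_x))
  if (k_genes > nrow(train_x)) {
    abort("`k_genes` exceeds the number of available probes.")
  }
  top <- head(rank_genes_by_t(train_x, train_labels), k_genes)
  .svm_on_top(exprs(train_x)[top, , drop = FALSE], train_labels,
              exprs(test_x)[top, , drop = FALSE],
              kernel = kernel, cost = cost, gamma = gamma)
}

# Standardize by training mean/SD and fit/predict the SVM. Both inputs are
# bare matrices already restricted to the selected probes.
.svm_on_top <- function(m_tr, train_labels, m_te, kernel, cost, gamma) {
  k_genes <- nrow(m_tr)
  tr <- t(m_tr)
  te <- t(m_te)
  n <- nrow(tr)
  ctr <- colMeans(tr)
  scl <- pmax(sqrt(pmax(colSums(tr^2) - n * ctr^2, 0) / (n - 1)), 1e-8)
  tr <- sweep(sweep(tr, 2, ctr), 2, scl, "/")
  te <- sweep(sweep(te, 2, ctr), 2, scl, "/")
  fit <- e1071::svm(
    x = tr, y = factor(train_labels, levels = c(0, 1)),
    kernel = kernel, cost = cost,
    gamma = if (is.null(gamma)) 1 / k_genes else gamma,
    scale = FALSE
  )
  pred <- as.integer(as.character(predict(fit, te)))
  structure(pred, probes_used = rownames(m_tr), center = ctr, scale = scl)
}

# Welch |t| ranking from precomputed m and m^2 via BLAS group sums; returns
# the row indices of the strongest k probes (ties by probe id).
.fast_top_k <- function(m, msq, idx1, idx0, k, ids) {
  n_all <- ncol(m)
  ind1 <- numeric(n_all); ind1[idx1] <- 1
  ind0 <- numeric(n_all); ind0[idx0] <- 1
  n1 <- length(idx1); n0 <- length(idx0)
  rs1 <- drop(m %*% ind1); rs0 <- drop(m %*% ind0)
  rq1 <- drop(msq %*% ind1); rq0 <- drop(msq %*% ind0)
  v1 <- pmax(rq1 - rs1^2 / n1, 0) / (n1 - 1)
  v0 <- pmax(rq0 - rs0^2 / n0, 0) / (n0 - 1)
  se <- sqrt(pmax(v1 / n1 + v0 / n0, 1e-24))
  tt <- (rs1 / n1 - rs0 / n0) / se
  head(order(-abs(tt), ids), k)
}

# Stable per-repeat seed derivation (Lehmer-style mix, stays below 2^31).
.mix_seed <- function(seed, r) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + r * 16807) %% 2147483647)
}

#' Multiple random validation: repeated cross-validated classifier voting
#'
#' The subtype-discovery engine. For each repeat, samples are freshly divided
#' into `n_folds` stratified folds; for each fold a classifier is trained on
#' the remaining folds (gene ranking and standardization recomputed within
#' every training set) and the held-out samples are classified as
#' atherosclerosis-like or not. Each sample therefore receives exactly one
#' vote per repeat. Per-repeat seeds are derived deterministically from
#' `config$rng_seed`.
#'
#' @param x An `expr_mat` (filtered, log2 scale).
#' @param labels Binary vector (1 = case), aligned with `x`.
#' @param config An [analysis_config()]; uses `n_repeats`, `n_folds`,
#'   `k_genes`, `kernel`, `cost`, `gamma`, `rng_seed`.
#' @return A `vote_matrix`: samples x repeats binary matrix with attributes
#'   `labels` and `config`.
#' @export
multiple_random_validation <- function(x, labels, config = analysis_config()) {
  validate_config(config)
  labels <- .check_labels(labels, ncol(x))
  n <- ncol(x)
  m <- exprs(x)
  msq <- m^2
  ids <- rownames(m)
  if (config$k_genes > nrow(m)) abort("`k_genes` exceeds the number of available probes.")
  votes <- matrix(NA_integer_, n, config$n_repeats,
                  dimnames = list(sample_ids(x), NULL))
  for (r in seq_len(config$n_repeats)) {
    seed_r <- .mix_seed(config$rng_seed, r)
    folds <- withCallingHandlers(
      stratified_partition(labels, config$n_folds, seed_r),
      error = function(e) abort(sprintf("Repeat %d: %s", r, conditionMessage(e)))
    )
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      idx1 <- train_idx[labels[train_idx] == 1]
      idx0 <- train_idx[labels[train_idx] == 0]
      pred <- tryCatch({
        if (length(idx1) < 2 || length(idx0) < 2) {
          abort("training set lacks two samples of each class")
        }
        top <- .fast_top_k(m, msq, idx1, idx0, config$k_genes, ids)
        .svm_on_top(m[top, train_idx, drop = FALSE], labels[train_idx],
                    m[top, test_idx, drop = FALSE],
                    kernel = config$kernel, cost = config$cost,
                    gamma = config$gamma)
        },
        error = function(e) {
          abort(sprintf("Repeat %d, fold %d: %s", r, f, conditionMessage(e)))
        }
      )
      votes[test_idx, r] <- as.integer(pred)
    }
  }
  stopifnot(!anyNA(votes))
  structure(votes, labels = labels, config = config,
            class = c("vote_matrix", "matrix", "array"))
}

#' @export
print.vote_matrix <- function(x, ...) {
  cat(sprintf("<vote_matrix> %d samples x %d repeats\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Majority-vote subtype assignment
#'
#' Aggregates a vote matrix into the final molecular-profile call: a sample
#' is assigned the atherosclerosis-associated (AWA) profile iff its vote
#' count strictly exceeds `vote_threshold` (default `n_repeats / 2`, i.e.
#' a strict majority; a count exactly at the threshold is not AWA).
#'
#' @param votes A `vote_matrix` from [multiple_random_validation()].
#' @param vote_threshold Numeric threshold; default `ncol(votes) / 2`.
#' @return A tibble of class `subtype_assignment` with columns `sample_id`,
#'   `vote_count`, `vote_fraction`, `awa` (integer 0/1).
#' @export
assign_subtypes <- function(votes, vote_threshold = NULL) {
  n_repeats <- ncol(votes)
  thr <- vote_threshold %||%
    (attr(votes, "config")$vote_threshold %||% (n_repeats / 2))
  counts <- as.integer(rowSums(unclass(votes)))
  tibble::new_tibble(
    tibble::tibble(
      sample_id = rownames(votes) %||% as.character(seq_len(nrow(votes))),
      vote_count = counts,
      vote_fraction = counts / n_repeats,
      awa = as.integer(counts > thr)
    ),
    class = "subtype_assignment",
    n_repeats = n_repeats, vote_threshold = thr
  )
}

#' Sweep the signature size k and summarize association strength
#'
#' Runs [multiple_random_validation()] for each candidate number of genes and
#' reports the odds ratio (Haldane-corrected if needed) between the resulting
#' majority-vote assignment and the case labels. The k maximizing the odds
#' ratio is reported as `best_k`.
#'
#' @param x,labels As in [multiple_random_validation()].
#' @param config An [analysis_config()].
#' @param k_values Candidate k values (default `config$k_genes_sweep`).
#' @param n_repeats Repeats per k (default `config$n_repeats`; a reduced
#'   count is commonly used for sweeps).
#' @return A tibble of class `k_sweep` with columns `k`, `n_awa`,
#'   `odds_ratio`, and attribute `best_k`.
#' @export
sweep_k <- function(x, labels, config = analysis_config(),
                    k_values = config$k_genes_sweep,
                    n_repeats = config$n_repeats) {
  validate_config(config)
  rows <- purrr::map(k_values, function(k) {
    cfg_k <- config
    cfg_k$k_genes <- as.integer(k)
    cfg_k$k_genes_sweep <- as.integer(k)
    cfg_k$n_repeats <- as.integer(n_repeats)
    cfg_k$vote_threshold <- NULL
    votes <- multiple_random_validation(x, labels, cfg_k)
    asg <- assign_subtypes(votes)
    tab <- crosstab(asg, labels)
    or <- odds_ratio(tab, correction = if (any(unlist(tab[c("tp", "fp", "fn", "tn")]) == 0)) "haldane" else "none")
    tibble::tibble(k = as.integer(k), n_awa = sum(asg$awa),
                   odds_ratio = or$odds_ratio)
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "k_sweep",
                     best_k = out$k[which.max(out$odds_ratio)])
}

#' @rdname sweep_k
#' @param sweep A `k_sweep`.
#' @export
best_k <- function(sweep) attr(sweep, "best_k")
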