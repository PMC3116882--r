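test_that("stratified partition balances fold sizes and case counts", {
  labels <- toy_labels(48, 71)
  folds <- stratified_partition(labels, 10, seed = 3)
  sizes <- tabulate(folds, 10)
  cases <- vapply(1:10, function(f) sum(labels[folds == f]), integer(1))
  expect_true(all(sizes %in% c(11L, 12L)))
  expect_true(all(cases %in% c(4L, 5L)))
  expect_identical(sum(sizes), 119L)
  expect_identical(sum(cases), 48L)
  # controls also differ by at most 1 across folds
  expect_lte(diff(range(sizes - cases)), 1)

  # 5/5 samples in 5 folds: exactly one of each class per fold
  lab2 <- toy_labels(5, 5)
  f2 <- stratified_partition(lab2, 5, seed = 1)
  expect_true(all(vapply(1:5, function(f) sum(lab2[f2 == f]), integer(1)) == 1L))
  expect_true(all(tabulate(f2, 5) == 2L))

  # determinism and error on infeasible class size
  expect_identical(stratified_partition(labels, 10, seed = 9),
                   stratified_partition(labels, 10, seed = 9))
  expect_false(identical(stratified_partition(labels, 10, seed = 9),
                         stratified_partition(labels, 10, seed = 10)))
  expect_error(stratified_partition(toy_labels(3, 50), 10), "at least")
})

test_that("gene ranking finds planted signal and breaks ties by probe id", {
  labels <- toy_labels(10, 10)
  hits <- 0
  for (s in 1:20) {
    x <- random_expr(100, 20, seed = s, shift = 3, shift_probes = 50,
                     labels = labels)
    if (rank_genes_by_t(x, labels)[1] == "p050") hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 0.95 of seeds at 3-SD planted shift

  # exact tie: duplicate probe rows -> lexicographic order
  m <- rbind(a = c(1, 2, 3, 5, 6, 7), b = c(1, 2, 3, 5, 6, 7),
             z = c(4, 4, 4, 4, 4, 4.0001))
  colnames(m) <- sprintf("s%d", 1:6)
  r <- rank_genes_by_t(expression_matrix(m), toy_labels(3, 3))
  expect_identical(r[1:2], c("a", "b"))
  expect_error(rank_genes_by_t(expression_matrix(m), rep(1L, 6)), "both classes")
})

test_that("classifier separates planted structure and never touches the test set", {
  labels <- toy_labels(20, 20)
  x <- random_expr(50, 40, seed = 4, shift = 10, shift_probes = 1:50,
                   labels = labels)  # two point clouds at ~10 SD
  test_x <- x[, c(1, 2, 39, 40)]
  train_x <- x[, 3:38]
  pred <- fit_and_classify(train_x, labels[3:38], test_x, k_genes = 50)
  expect_identical(as.integer(pred), c(1L, 1L, 0L, 0L))

  # leakage check: perturbing the test matrix leaves all training-derived
  # parameters (gene ranks, centering, scaling) untouched
  test_perturbed <- expression_matrix(exprs(test_x) + 100)
  pred2 <- fit_and_classify(train_x, labels[3:38], test_perturbed, k_genes = 50)
  expect_identical(attr(pred, "probes_used"), attr(pred2, "probes_used"))
  expect_identical(attr(pred, "center"), attr(pred2, "center"))
  expect_identical(attr(pred, "scale"), attr(pred2, "scale"))

  expect_error(fit_and_classify(train_x, labels[3:38], test_x, k_genes = 999),
               "exceeds")
})

test_that("null-data classification accuracy hovers at chance", {
  accs <- vapply(1:30, function(s) {
    labels <- toy_labels(20, 20)
    x <- random_expr(60, 40, seed = 100 + s)
    folds <- stratified_partition(labels, 4, seed = s)
    pred <- unlist(lapply(1:4, function(f) {
      fit_and_classify(x[, folds != f], labels[folds != f], x[, folds == f],
                       k_genes = 10)
    }))
    truth <- unlist(lapply(1:4, function(f) labels[folds == f]))
    mean(pred == truth)
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("vote matrix conserves one vote per sample per repeat", {
  co <- generate_cohort(small_cohort_spec(seed = 2))
  cfg <- analysis_config(n_repeats = 3, n_folds = 5, k_genes = 10,
                         rng_seed = 7)
  v <- multiple_random_validation(co$expr, co$annotation$case_status, cfg)
  expect_identical(dim(v), c(50L, 3L))
  expect_true(all(unclass(v) %in% 0:1))
  expect_false(anyNA(v))
  # determinism under the same rng_seed
  v2 <- multiple_random_validation(co$expr, co$annotation$case_status, cfg)
  expect_identical(unclass(v), unclass(v2))
})

test_that("majority vote uses a strict threshold", {
  votes <- structure(
    matrix(c(rep(1L, 600), rep(0L, 400),
             rep(1L, 500), rep(0L, 500),
             rep(0L, 1000)),
           nrow = 3, ncol = 1000, byrow = TRUE,
           dimnames = list(c("s600", "s500", "s0"), NULL)),
    class = c("vote_matrix", "matrix", "array")
  )
  asg <- assign_subtypes(votes)
  expect_identical(asg$awa, c(1L, 0L, 0L))  # 600 > 500; 500 is not strict
  expect_equal(asg$vote_fraction, c(0.6, 0.5, 0))
  expect_identical(asg$vote_count, c(600L, 500L, 0L))
})

test_that("repeated validation recovers a planted subtype's vote structure", {
  co <- generate_cohort(cohort_spec(seed = 42))
  cfg <- analysis_config(n_repeats = 100, rng_seed = 42)
  v <- multiple_random_validation(co$expr, co$annotation$case_status, cfg)
  asg <- assign_subtypes(v)
  z <- co$truth$samples$subtype
  expect_gte(median(asg$vote_fraction[z == 1]), 0.7)
  expect_lte(median(asg$vote_fraction[z == 0]), 0.3)
})

test_that("k sweep prefers signature sizes that cover the planted signal", {
  co <- generate_cohort(small_cohort_spec(seed = 8, frac_de = 0.25))
  cfg <- analysis_config(n_folds = 5, rng_seed = 11,
                         k_genes_sweep = c(5L, 50L), k_genes = 5L)
  sw <- sweep_k(co$expr, co$annotation$case_status, cfg,
                k_values = c(5L, 50L), n_repeats = 20L)
  expect_identical(nrow(sw), 2L)
  expect_gte(sw$odds_ratio[sw$k == 50], sw$odds_ratio[sw$k == 5])
  expect_true(best_k(sw) %in% c(5L, 50L))
  # n_repeats = 1 smoke run completes
  sw1 <- sweep_k(co$expr, co$annotation$case_status, cfg,
                 k_values = c(5L, 10L), n_repeats = 1L)
  expect_identical(nrow(sw1), 2L)
})
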