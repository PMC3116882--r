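test_that("per-probe Welch t matches stats::t.test probe by probe", {
  labels <- toy_labels(4, 5)
  x <- random_expr(20, 9, seed = 11, shift = 1.5, shift_probes = 1:5,
                   labels = labels)
  de <- welch_t(x, labels)
  for (i in c(1, 3, 10, 20)) {
    ref <- t.test(exprs(x)[i, labels == 1], exprs(x)[i, labels == 0])
    expect_equal(de$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$p_value[i], ref$p.value, tolerance = 1e-12)
  }
  pooled <- welch_t(x, labels, var_equal = TRUE)
  ref <- t.test(exprs(x)[2, labels == 1], exprs(x)[2, labels == 0],
                var.equal = TRUE)
  expect_equal(pooled$t[2], unname(ref$statistic), tolerance = 1e-12)
})

test_that("Welch t handles degenerate probes and trivial contrasts", {
  m <- rbind(
    c(1, 2, 3, 1, 2, 3),    # identical groups -> t = 0, fc = 0
    c(rep(2, 6)),           # zero variance everywhere -> flagged
    c(2.0, 2.2, 1.8, 1.0, 1.2, 0.8)
  )
  rownames(m) <- c("same", "flat", "shift")
  colnames(m) <- sprintf("s%d", 1:6)
  labels <- toy_labels(3, 3)
  de <- welch_t(expression_matrix(m), labels)
  expect_equal(de$t[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_equal(de$log2_fc[1], 0)
  expect_true(de$low_variance[2])
  # textbook formula oracle for the shifted probe
  se <- sqrt(0.04 / 3 + 0.04 / 3)
  expect_equal(de$t[3], 1 / se, tolerance = 1e-10)
  expect_equal(de$log2_fc[3], 1)
})

test_that("Welch t is invariant to adding a probe-wise constant", {
  labels <- toy_labels(5, 5)
  x <- random_expr(10, 10, seed = 2)
  de1 <- welch_t(x, labels)
  shifted <- expression_matrix(exprs(x) + 7)
  de2 <- welch_t(shifted, labels)
  expect_equal(de2$t, de1$t, tolerance = 1e-9)
  expect_equal(de2$log2_fc, de1$log2_fc, tolerance = 1e-9)
})

test_that("summary-statistic t test reproduces cohort-table comparisons", {
  # Framingham risk score row: strongly significant
  frs <- t_from_summary(5.8, 4.5, 48, 2.6, 2.9, 71)
  expect_lt(frs$p_value, 0.001)
  # body-mass-index row: null-ish, near the printed two-sided p
  bmi <- t_from_summary(28.2, 6.0, 48, 27.2, 5.8, 71)
  expect_equal(bmi$p_value, 0.37, tolerance = 0.02)
  # equal means
  eq <- t_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5), "zero")
  # agrees with the full-data Welch test on reconstructed data
  g1 <- c(2.0, 2.2, 1.8); g2 <- c(1.0, 1.2, 0.8)
  ref <- t.test(g1, g2)
  got <- t_from_summary(mean(g1), sd(g1), 3, mean(g2), sd(g2), 3)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(3:20, 1)
    p <- runif(m)^sample(c(1, 2), 1)  # mix of null-ish and signal-ish
    q <- storey_qvalue(p, pi0 = 1)$q_values
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # hand-computed BH for the canonical 5-value example
  p5 <- c(0.001, 0.01, 0.2, 0.5, 0.9)
  q5 <- storey_qvalue(p5, pi0 = 1)$q_values
  expect_equal(q5, c(0.005, 0.025, 1 / 3, 0.625, 0.9), tolerance = 1e-12)
})

test_that("pi0 estimation is calibrated under the uniform null", {
  set.seed(7)
  p <- runif(10000)
  res <- storey_qvalue(p)
  expect_gte(res$pi0_estimate$pi0, 0.95)
  expect_lte(res$pi0_estimate$pi0, 1.05)  # clipped at 1
  expect_lte(estimate_de_fraction(res$pi0_estimate), 0.05)
  # all-ones p-vector
  q1 <- storey_qvalue(rep(1, 20))
  expect_true(all(q1$q_values == 1))
})

test_that("estimated DE fraction is one minus pi0", {
  est <- structure(list(pi0 = 0.8, lambda = numeric(0),
                        pi0_lambda = numeric(0), method = "forced"),
                   class = "pi0_estimate")
  expect_equal(estimate_de_fraction(est), 0.20)
  est$pi0 <- 1
  expect_equal(estimate_de_fraction(est), 0)
  est$pi0 <- 0.804
  expect_equal(estimate_de_fraction(est), 0.196)
})

test_that("q-values reject invalid inputs", {
  expect_error(storey_qvalue(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalue(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("SAM d reduces to the pooled t up to a constant when s0 = 0", {
  labels <- toy_labels(6, 6)
  x <- random_expr(150, 12, seed = 3, shift = 1, shift_probes = 1:20,
                   labels = labels)
  sam <- sam_permutation(x, labels, n_permutations = 100, seed = 1)
  pooled <- welch_t(x, labels, var_equal = TRUE)
  d0 <- sam$d * (sam$se + sam$s0) / sam$se  # undo the fudge factor
  expect_equal(d0, pooled$t, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("SAM estimates high FDR on null data and recovers planted signal", {
  labels <- toy_labels(25, 25)
  # pure null: at a cutoff calling ~5% of probes, FDR should be high
  null_x <- random_expr(400, 50, seed = 9)
  sam_null <- sam_permutation(null_x, labels, n_permutations = 100, seed = 5)
  tab <- sam_null$table
  near5 <- tab[which.min(abs(tab$called - 0.05 * 400)), ]
  expect_gte(near5$fdr, 0.8)
  # monotone-ish: larger cutoffs never raise called counts
  expect_true(all(diff(tab$called) <= 0))

  # planted 10% of probes with 2-SD shifts
  planted <- seq_len(40)
  x <- random_expr(400, 50, seed = 10, shift = 2, shift_probes = planted,
                   labels = labels)
  sam <- sam_permutation(x, labels, n_permutations = 100, seed = 6)
  at <- sam_called_at_fdr(sam, 0.2)
  called_ids <- sam$probe_id[abs(sam$d) >= at$cutoff]
  truth <- sprintf("p%03d", planted)
  recovered <- mean(truth %in% called_ids)
  false_frac <- mean(!(called_ids %in% truth))
  expect_gte(recovered, 0.7)
  expect_lte(false_frac, 0.3)
})

test_that("p-value histogram counts conserve mass with a uniform reference", {
  set.seed(21)
  p <- runif(2000)
  h <- pvalue_histogram(p, n_bins = 20)
  expect_identical(sum(h$count), 2000L)
  expect_equal(h$expected[1], 100)
  expect_true(all(abs(h$count - 100) <= 3 * sqrt(2000 / 20)))
  h2 <- pvalue_histogram(rep(0.001, 50), n_bins = 20)
  expect_identical(h2$count[1], 50L)
  expect_error(pvalue_histogram(numeric(0)), "[Ee]mpty")
})
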