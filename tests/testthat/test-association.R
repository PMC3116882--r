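test_that("odds ratio, CI, and sensitivity/specificity match the confusion counts", {
  tab <- contingency_2x2(tp = 29, fp = 17, fn = 19, tn = 54)
  or <- odds_ratio(tab)
  expect_equal(round(or$odds_ratio, 2), 4.85)
  expect_true(or$ci_low <= or$odds_ratio && or$odds_ratio <= or$ci_high)
  ss <- sens_spec(tab)
  expect_equal(round(100 * ss$sensitivity), 60)
  expect_equal(round(100 * ss$specificity), 76)

  sub <- contingency_2x2(tp = 24, fp = 16, fn = 15, tn = 53)
  expect_equal(round(odds_ratio(sub)$odds_ratio, 1), 5.3)

  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$odds_ratio, 1)
  expect_equal(sens_spec(contingency_2x2(10, 0, 0, 10)),
               tibble::tibble(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(contingency_2x2(0, 10, 10, 0)),
               tibble::tibble(sensitivity = 0, specificity = 0))
})

test_that("odds ratio symmetry and scaling invariants hold", {
  tab <- contingency_2x2(8, 3, 5, 12)
  flipped <- contingency_2x2(5, 12, 8, 3)  # swap rows -> reciprocal OR
  expect_equal(odds_ratio(tab)$odds_ratio,
               1 / odds_ratio(flipped)$odds_ratio)
  # scaling all cells tightens the Wald CI around the same point estimate
  big <- contingency_2x2(80, 30, 50, 120)
  or1 <- odds_ratio(tab); or2 <- odds_ratio(big)
  expect_equal(or1$odds_ratio, or2$odds_ratio)
  expect_lt(log(or2$ci_high) - log(or2$ci_low),
            log(or1$ci_high) - log(or1$ci_low))
  # zero cell requires the Haldane correction
  z <- contingency_2x2(5, 0, 3, 7)
  expect_error(odds_ratio(z), "haldane")
  expect_true(is.finite(odds_ratio(z, correction = "haldane")$odds_ratio))
})

test_that("crosstab partitions samples and matches direct counting", {
  awa <- c(1, 1, 0, 0, 1, 0)
  lab <- c(1, 0, 1, 0, 1, 0)
  tab <- crosstab(awa, lab)
  expect_identical(c(tab$tp, tab$fp, tab$fn, tab$tn), c(2L, 1L, 1L, 2L))
  expect_identical(tab$tp + tab$fp + tab$fn + tab$tn, 6L)
  all0 <- crosstab(rep(0, 6), lab)
  expect_identical(c(all0$tp, all0$fp), c(0L, 0L))
  perfect <- crosstab(lab, lab)
  expect_identical(c(perfect$fp, perfect$fn), c(0L, 0L))
  expect_error(crosstab(c(1, 0), c(1, 0, 1)), "length")
})

test_that("chi-square matches the closed-form statistic and handles corrections", {
  # hand oracle: Pearson X2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  tab <- contingency_2x2(24, 24, 19, 52)
  a <- 24; b <- 24; cc <- 19; d <- 52; n <- a + b + cc + d
  x2_hand <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  got <- chi_square(tab)
  expect_equal(got$statistic, x2_hand, tolerance = 1e-12)
  expect_lt(got$p_value, 0.05)  # smoking-rate contrast is significant

  # small male-cohort branch table with Yates correction
  branch16 <- chi_square(contingency_2x2(8, 2, 0, 6), yates = TRUE)
  expect_equal(branch16$p_value, 0.0098, tolerance = 1e-2)

  flat <- chi_square(contingency_2x2(10, 10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  fish <- chi_square(contingency_2x2(8, 2, 0, 6), fisher_fallback = TRUE)
  expect_identical(fish$method, "fisher")
  expect_equal(fish$p_value, fisher.test(matrix(c(8, 0, 2, 6), 2))$p.value)
})

test_that("adjusted logistic regression reproduces the crude OR when the covariate is constant", {
  set.seed(5)
  awa <- rbinom(80, 1, 0.4)
  lab <- rbinom(80, 1, plogis(-1 + 1.2 * awa))
  tab <- crosstab(awa, lab)
  crude <- odds_ratio(tab)$odds_ratio
  adj <- adjusted_logistic(awa, lab, data.frame(const = rep(0, 80)))
  expect_equal(adj$result$odds_ratio, crude, tolerance = 1e-6)
  expect_true("awa" %in% tidy(adj)$term)
})

test_that("adjusted logistic recovers a planted conditional OR under confounding", {
  set.seed(77)
  n <- 4000
  conf <- rbinom(n, 1, 0.5)
  awa <- rbinom(n, 1, plogis(-1.5 + 2.5 * conf))
  beta_awa <- log(2.5)
  lab <- rbinom(n, 1, plogis(-1.5 + beta_awa * awa + 1.5 * conf))
  crude <- odds_ratio(crosstab(awa, lab))$odds_ratio
  expect_gte(crude / 2.5, 1.5)  # confounder inflates the crude OR
  adj <- adjusted_logistic(awa, lab, data.frame(conf = conf))
  expect_equal(adj$result$odds_ratio, 2.5, tolerance = 0.2 * 2.5)
})

test_that("perfect separation is detected and rejected", {
  awa <- c(rep(1, 10), rep(0, 10))
  lab <- awa
  x <- seq_len(20)
  expect_error(adjusted_logistic(awa, lab, data.frame(x = x)), "separation")
})

test_that("subgroup association equals direct computation on the subset", {
  set.seed(9)
  awa <- rbinom(119, 1, 0.4)
  lab <- c(rep(1, 48), rep(0, 71))
  mask <- rep(TRUE, 119); mask[sample(119, 11)] <- FALSE
  sub <- subgroup_association(awa, lab, mask)
  direct <- associate(awa[mask], lab[mask])
  expect_equal(sub, direct)
  full <- subgroup_association(awa, lab, rep(TRUE, 119))
  expect_equal(full, associate(awa, lab))
  expect_error(subgroup_association(awa, lab, lab == 0), "both cases")
})

test_that("counts reconstructed from printed percentages round correctly", {
  expect_identical(counts_from_percent(50.0, 48), 24L)
  expect_identical(counts_from_percent(26.7, 71), 19L)
  expect_identical(counts_from_percent(62, 39), 24L)
  expect_identical(counts_from_percent(77, 69), 53L)
  expect_error(counts_from_percent(120, 10), "percent")
})
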