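#' 2x2 subtype-by-phenotype contingency table
#'
#' Cell convention: `tp` = AWA profile and case, `fp` = AWA and control,
#' `fn` = not-AWA and case, `tn` = not-AWA and control.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `contingency_2x2` (named list of the four cells).
#' @export
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("Empty table.")
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2>\n")
  print(as_matrix_2x2(x))
  invisible(x)
}

#' @rdname contingency_2x2
#' @param x A `contingency_2x2`.
#' @return `as_matrix_2x2()` returns the table as a 2x2 matrix
#'   (rows: AWA/notAWA, columns: case/control).
#' @export
as_matrix_2x2 <- function(x) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(profile = c("AWA", "notAWA"),
                         phenotype = c("case", "control")))
}

#' Cross-tabulate a subtype assignment against phenotype labels
#'
#' @param assignment A `subtype_assignment` tibble (from [assign_subtypes()])
#'   or a binary 0/1 vector of profile calls.
#' @param labels Binary phenotype vector (1 = case), same length/order.
#' @return A [contingency_2x2()].
#' @export
crosstab <- function(assignment, labels) {
  awa <- if (is.data.frame(assignment)) assignment$awa else assignment
  awa <- .check_labels(awa, length(awa))
  labels <- .check_labels(labels, length(labels))
  if (length(awa) != length(labels)) abort("Assignment and labels differ in length.")
  contingency_2x2(
    tp = sum(awa == 1 & labels == 1),
    fp = sum(awa == 1 & labels == 0),
    fn = sum(awa == 0 & labels == 1),
    tn = sum(awa == 0 & labels == 0)
  )
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = (tp * tn) / (fp * fn)` with the Wald interval
#' `exp(log OR +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`. With
#' `correction = "haldane"`, 0.5 is added to every cell when any cell is 0.
#'
#' @param table A [contingency_2x2()].
#' @param correction `"none"` (error on zero cells) or `"haldane"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `assoc_result` with columns `method`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value` (NA here; see
#'   [chi_square()]).
#' @export
odds_ratio <- function(table, correction = c("none", "haldane"),
                       conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  correction <- match.arg(correction)
  cells <- c(table$tp, table$fp, table$fn, table$tn)
  if (any(cells == 0)) {
    if (correction == "none") {
      abort("Zero cell in the 2x2 table; use correction = \"haldane\".")
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  tibble::new_tibble(
    tibble::tibble(
      method = paste0("wald", if (correction == "haldane" && any(c(table$tp, table$fp, table$fn, table$tn) == 0)) "_haldane" else ""),
      odds_ratio = or,
      ci_low = exp(log(or) - z * se),
      ci_high = exp(log(or) + z * se),
      p_value = NA_real_
    ),
    class = "assoc_result"
  )
}

#' Sensitivity and specificity of a subtype call
#'
#' Treats the AWA profile as a test for case status: sensitivity
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)`.
#'
#' @param table A [contingency_2x2()].
#' @return A tibble with columns `sensitivity` and `specificity`.
#' @export
sens_spec <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if ((table$tp + table$fn) == 0 || (table$tn + table$fp) == 0) {
    abort("Empty phenotype margin; sensitivity/specificity undefined.")
  }
  tibble::tibble(
    sensitivity = table$tp / (table$tp + table$fn),
    specificity = table$tn / (table$tn + table$fp)
  )
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square (optional Yates continuity correction) via
#' [stats::chisq.test()]; with `fisher_fallback = TRUE` the Fisher exact test
#' is used instead whenever any expected cell count is below 5.
#'
#' @param table A [contingency_2x2()].
#' @param yates Apply the continuity correction.
#' @param fisher_fallback Switch to Fisher's exact test for sparse tables.
#' @return An `assoc_result` tibble (`method`, `statistic`, `p_value`).
#' @export
chi_square <- function(table, yates = FALSE, fisher_fallback = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- as_matrix_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (fisher_fallback && any(expected < 5)) {
    ft <- fisher.test(m)
    return(tibble::new_tibble(
      tibble::tibble(method = "fisher", statistic = NA_real_,
                     p_value = ft$p.value),
      class = "assoc_result"
    ))
  }
  ct <- suppressWarnings(chisq.test(m, correct = yates))
  tibble::new_tibble(
    tibble::tibble(
      method = if (yates) "chi2_yates" else "chi2",
      statistic = unname(ct$statistic),
      p_value = ct$p.value
    ),
    class = "assoc_result"
  )
}

#' Full crude association summary
#'
#' Convenience wrapper combining [crosstab()], [odds_ratio()], [sens_spec()]
#' and [chi_square()] for a subtype assignment versus phenotype labels.
#'
#' @param assignment,labels As in [crosstab()].
#' @param correction Passed to [odds_ratio()].
#' @param yates Passed to [chi_square()].
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`, `p_value`.
#' @export
associate <- function(assignment, labels, correction = "haldane",
                      yates = FALSE) {
  tab <- crosstab(assignment, labels)
  or <- odds_ratio(tab, correction = correction)
  ss <- sens_spec(tab)
  ch <- chi_square(tab, yates = yates)
  tibble::tibble(
    tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
    odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    p_value = ch$p_value
  )
}

#' Covariate-adjusted logistic regression for the subtype association
#'
#' Fits `case_status ~ awa + covariates` by maximum-likelihood logistic
#' regression and reports the adjusted odds ratio for the molecular profile
#' (exp of its coefficient) with a Wald confidence interval. Errors when the
#' fit shows signs of complete separation.
#'
#' @param assignment A `subtype_assignment` or binary vector.
#' @param labels Binary phenotype vector (1 = case).
#' @param covariates Data frame of covariates (e.g. a single `frs` column),
#'   same row order as `labels`; must be complete.
#' @param conf_level Confidence level (default 0.95).
#' @return An `adjusted_logistic` object; `tidy()` gives all coefficients,
#'   and `$result` holds the one-row AWA summary
#'   (`odds_ratio`, `ci_low`, `ci_high`, `p_value`).
#' @export
adjusted_logistic <- function(assignment, labels, covariates,
                              conf_level = 0.95) {
  awa <- if (is.data.frame(assignment)) assignment$awa else assignment
  awa <- .check_labels(awa, length(awa))
  labels <- .check_labels(labels, length(labels))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(labels)) {
    abort("`covariates` must have one row per sample.")
  }
  if (anyNA(covariates)) {
    abort("Missing covariate values; adjusted regression refuses incomplete data.")
  }
  dat <- cbind(data.frame(.case = labels, awa = awa), covariates)
  fit <- suppressWarnings(glm(.case ~ ., data = dat, family = binomial()))
  if (!fit$converged || abs(coef(fit)["awa"]) > 15) {
    abort(paste0(
      "Logistic fit shows separation or failed to converge; ",
      "consider a penalized (e.g. Firth) fit."
    ))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  b <- coef(fit)["awa"]
  se <- sqrt(diag(vcov(fit)))["awa"]
  res <- tibble::tibble(
    method = "logistic",
    odds_ratio = exp(unname(b)),
    ci_low = exp(unname(b - z * se)),
    ci_high = exp(unname(b + z * se)),
    p_value = 2 * stats::pnorm(-abs(unname(b / se)))
  )
  structure(list(fit = fit, result = res, conf_level = conf_level),
            class = "adjusted_logistic")
}

#' @export
print.adjusted_logistic <- function(x, ...) {
  cat("<adjusted_logistic>\n")
  print(x$result)
  invisible(x)
}

#' @export
tidy.adjusted_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4],
    odds_ratio = exp(sm[, 1])
  )
}

#' @export
glance.adjusted_logistic <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    aic = x$fit$aic, n = length(x$fit$y)
  )
}

#' Association within a sample subgroup
#'
#' Recomputes the crude association on the samples selected by `mask`
#' (e.g. the low-Framingham-risk stratum).
#'
#' @param assignment,labels As in [crosstab()].
#' @param mask Logical (or 0/1) vector selecting the subgroup.
#' @param ... Passed to [associate()].
#' @return The [associate()] summary for the subgroup.
#' @export
subgroup_association <- function(assignment, labels, mask, ...) {
  awa <- if (is.data.frame(assignment)) assignment$awa else assignment
  mask <- as.logical(mask)
  if (length(mask) != length(labels)) abort("`mask` length mismatch.")
  sub_labels <- labels[mask]
  if (length(unique(sub_labels)) < 2) {
    abort("Subgroup must contain both cases and controls.")
  }
  associate(awa[mask], sub_labels, ...)
}

#' Reconstruct counts from printed percentages
#'
#' Cohort tables often print only a percentage and a group size; this helper
#' rebuilds the integer count as `round(percent / 100 * n)`. The
#' reconstruction is explicit rather than silent so analyses derived from
#' published percentages are auditable.
#'
#' @param percent Percentage (0-100).
#' @param n Group size.
#' @return Integer count.
#' @export
counts_from_percent <- function(percent, n) {
  if (any(percent < 0 | percent > 100)) abort("`percent` must lie in [0, 100].")
  as.integer(round(percent / 100 * n))
}
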