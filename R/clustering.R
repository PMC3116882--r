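#' Center each probe on its mean across samples
#'
#' @param x An `expr_mat`.
#' @return An `expr_mat` whose rows each have mean 0.
#' @export
center_genes <- function(x) {
  m <- exprs(x)
  expression_matrix(m - rowMeans(m), detection_p(x))
}

#' Pearson-correlation distance matrix
#'
#' `d(i, j) = 1 - r(i, j)` with r the (centered) Pearson correlation, on
#' either the probe or the sample axis. Items with zero variance have no
#' defined correlation and are dropped with a warning.
#'
#' @param x An `expr_mat`.
#' @param axis `"probes"` (rows) or `"samples"` (columns).
#' @param uncentered Use the uncentered correlation
#'   (`sum(xy) / sqrt(sum(x^2) sum(y^2))`) instead of Pearson.
#' @return A [stats::dist] object.
#' @export
pearson_distance <- function(x, axis = c("probes", "samples"),
                             uncentered = FALSE) {
  axis <- match.arg(axis)
  m <- exprs(x)
  v <- if (axis == "probes") t(m) else m  # items become columns
  if (ncol(v) < 2) abort("Need at least 2 items to compute distances.")
  if (uncentered) {
    norms <- sqrt(colSums(v^2))
    zero <- norms == 0
  } else {
    zero <- apply(v, 2, sd) == 0
  }
  if (any(zero)) {
    warn(sprintf("Dropping %d zero-variance item(s) from the distance matrix.",
                 sum(zero)))
    v <- v[, !zero, drop = FALSE]
    if (ncol(v) < 2) abort("Fewer than 2 items left after dropping degenerate ones.")
  }
  r <- if (uncentered) {
    crossprod(v) / tcrossprod(sqrt(colSums(v^2)))
  } else {
    cor(v)
  }
  d <- 1 - r
  diag(d) <- 0
  stats::as.dist(d)
}

#' Average-linkage hierarchical clustering
#'
#' Unweighted pair-group average (UPGMA-style) agglomeration via
#' [stats::hclust()] with `method = "average"`; merge heights are
#' non-decreasing since average linkage is monotone.
#'
#' @param d A [stats::dist] object (e.g. from [pearson_distance()]).
#' @return An `hclust` tree.
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) abort("`d` must be a dist object.")
  hclust(d, method = "average")
}

#' Cut a dendrogram into branches
#'
#' @param tree An `hclust` tree.
#' @param n_branches Number of branches (1..n_leaves).
#' @return A tibble with columns `item` (leaf label, in the tree's input
#'   order) and `branch` (integer label).
#' @export
cut_tree <- function(tree, n_branches) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (n_branches < 1 || n_branches > n) {
    abort("`n_branches` must lie in [1, number of leaves].")
  }
  labs <- cutree(tree, k = n_branches)
  tibble::tibble(
    item = names(labs) %||% as.character(seq_along(labs)),
    branch = as.integer(labs)
  )
}

#' Per-branch phenotype enrichment
#'
#' Reports the phenotype prevalence within every dendrogram branch plus an
#' overall chi-square test of branch-by-phenotype independence (Fisher exact
#' for 2x2 tables with sparse expected counts when `fisher_fallback`).
#'
#' @param branch_labels Integer/character branch label per sample (empty
#'   branches are excluded).
#' @param phenotype Binary vector (1 = case), aligned with `branch_labels`.
#' @param yates Continuity correction for the 2-branch case.
#' @param fisher_fallback Use Fisher's exact test for sparse 2x2 tables.
#' @return A list: `rates` (tibble `branch`, `n`, `n_case`, `rate`) and
#'   `test` (an `assoc_result` tibble).
#' @export
branch_enrichment <- function(branch_labels, phenotype, yates = FALSE,
                              fisher_fallback = FALSE) {
  if (is.data.frame(branch_labels)) branch_labels <- branch_labels$branch
  phenotype <- .check_labels(phenotype, length(phenotype))
  if (length(branch_labels) != length(phenotype)) {
    abort("`branch_labels` and `phenotype` differ in length.")
  }
  rates <- tibble::tibble(branch = branch_labels, case = phenotype) |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(n = dplyr::n(), n_case = sum(.data$case),
                     rate = mean(.data$case), .groups = "drop")
  tab <- table(branch_labels, phenotype)
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    t2 <- contingency_2x2(tp = tab[1, "1"], fp = tab[1, "0"],
                          fn = tab[2, "1"], tn = tab[2, "0"])
    test <- chi_square(t2, yates = yates, fisher_fallback = fisher_fallback)
  } else {
    ct <- suppressWarnings(chisq.test(tab))
    test <- tibble::new_tibble(
      tibble::tibble(method = "chi2", statistic = unname(ct$statistic),
                     p_value = ct$p.value),
      class = "assoc_result"
    )
  }
  list(rates = rates, test = test)
}
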