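#' Map probes across platforms by gene symbol
#'
#' Joins two probe-to-symbol annotation tables on gene symbol, keeping only
#' symbols present on both platforms. Genes measured by several probes on a
#' platform are collapsed to a single probe: by default the probe with the
#' highest mean expression (when the matching expression matrix is supplied),
#' otherwise the first probe in table order.
#'
#' @param annot_a,annot_b Data frames with columns `probe_id`, `gene_symbol`.
#' @param collapse `"max_mean_expression"` or `"first"`.
#' @param expr_a,expr_b Optional `expr_mat`s used by the
#'   `max_mean_expression` rule.
#' @return A tibble of class `probe_map` with columns `gene_symbol`,
#'   `probe_a`, `probe_b`; attribute `n_genes`.
#' @export
map_by_symbol <- function(annot_a, annot_b,
                          collapse = c("max_mean_expression", "first"),
                          expr_a = NULL, expr_b = NULL) {
  collapse <- match.arg(collapse)
  a <- .collapse_annot(annot_a, collapse, expr_a, "A")
  b <- .collapse_annot(annot_b, collapse, expr_b, "B")
  map <- dplyr::inner_join(
    dplyr::rename(a, probe_a = "probe_id"),
    dplyr::rename(b, probe_b = "probe_id"),
    by = "gene_symbol"
  )
  if (nrow(map) == 0) abort("No gene symbols shared between the two platforms.")
  tibble::new_tibble(map[, c("gene_symbol", "probe_a", "probe_b")],
                     class = "probe_map", n_genes = nrow(map))
}

.collapse_annot <- function(annot, collapse, expr, tag) {
  annot <- tibble::as_tibble(annot)
  if (!all(c("probe_id", "gene_symbol") %in% names(annot)) || nrow(annot) == 0) {
    abort(sprintf("Annotation %s needs non-empty columns probe_id, gene_symbol.", tag))
  }
  annot <- dplyr::filter(annot, !is.na(.data$gene_symbol), .data$gene_symbol != "")
  if (collapse == "max_mean_expression" && !is.null(expr)) {
    mu <- rowMeans(exprs(expr))
    annot$.mean <- mu[match(annot$probe_id, names(mu))]
    annot <- annot |>
      dplyr::arrange(dplyr::desc(.data$.mean)) |>
      dplyr::distinct(.data$gene_symbol, .keep_all = TRUE) |>
      dplyr::select(-".mean")
  } else {
    annot <- dplyr::distinct(annot, .data$gene_symbol, .keep_all = TRUE)
  }
  annot[, c("probe_id", "gene_symbol")]
}

#' Paired fold changes between baseline and post-stimulus matrices
#'
#' For each probe, the mean within-subject log2 difference (post minus
#' baseline) and a paired t-test p-value. Subjects are paired by sample id;
#' both matrices must contain exactly the same subjects.
#'
#' @param baseline,post `expr_mat`s with identical probes and subject ids.
#' @return A tibble with columns `probe_id`, `log2_fc`, `p_value`.
#' @export
paired_fold_changes <- function(baseline, post) {
  if (!setequal(sample_ids(baseline), sample_ids(post))) {
    abort("Baseline and post matrices must contain the same subjects.")
  }
  if (!identical(probe_ids(baseline), probe_ids(post))) {
    abort("Baseline and post matrices must share the same probes.")
  }
  diff <- exprs(post)[, sample_ids(baseline), drop = FALSE] - exprs(baseline)
  n <- ncol(diff)
  if (n < 2) abort("Paired test needs at least 2 subjects.")
  mu <- rowMeans(diff)
  se <- sqrt(pmax(rowSums((diff - mu)^2) / (n - 1), 1e-24) / n)
  tt <- mu / se
  tibble::tibble(
    probe_id = rownames(diff),
    log2_fc = mu,
    p_value = 2 * pt(-abs(tt), df = n - 1)
  )
}

#' Cross-study fold-change concordance
#'
#' Restricts mapped genes to those significant (p < `alpha`) in *both*
#' studies (or all mapped genes when `restrict = FALSE`), then reports the
#' overlap count, the Pearson correlation of the two log2 fold-change vectors
#' over that set, and a hypergeometric tail p-value for the size of the
#' dual-significant overlap relative to chance.
#'
#' @param de_a A `de_result` (or any data frame with `probe_id`, `log2_fc`,
#'   `p_value`) for study A.
#' @param fc_b A data frame with `probe_id`, `log2_fc`, `p_value` for study B
#'   (e.g. from [paired_fold_changes()]).
#' @param map A `probe_map` from [map_by_symbol()].
#' @param alpha Per-study significance threshold (default 0.05).
#' @param restrict Correlate over the dual-significant set (default) or over
#'   all mapped genes.
#' @return A `concordance_result`: list with `per_gene` tibble, `n_mapped`,
#'   `n_overlap`, `r` (NA when the overlap has < 3 genes), `overlap_p`
#'   (hypergeometric), `alpha`, `restricted`.
#' @export
concordance <- function(de_a, fc_b, map, alpha = 0.05, restrict = TRUE) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  a <- tibble::as_tibble(de_a)[, c("probe_id", "log2_fc", "p_value")]
  b <- tibble::as_tibble(fc_b)[, c("probe_id", "log2_fc", "p_value")]
  per_gene <- map |>
    dplyr::inner_join(dplyr::rename(a, probe_a = "probe_id", fc_a = "log2_fc",
                                    p_a = "p_value"), by = "probe_a") |>
    dplyr::inner_join(dplyr::rename(b, probe_b = "probe_id", fc_b = "log2_fc",
                                    p_b = "p_value"), by = "probe_b") |>
    dplyr::mutate(significant_both = .data$p_a < alpha & .data$p_b < alpha)
  n_mapped <- nrow(per_gene)
  if (n_mapped == 0) abort("No mapped genes with statistics in both studies.")
  n_overlap <- sum(per_gene$significant_both)
  use <- if (restrict) dplyr::filter(per_gene, .data$significant_both) else per_gene
  r <- if (nrow(use) >= 3) cor(use$fc_a, use$fc_b) else NA_real_
  n_sig_a <- sum(per_gene$p_a < alpha)
  n_sig_b <- sum(per_gene$p_b < alpha)
  overlap_p <- phyper(n_overlap - 1, n_sig_a, n_mapped - n_sig_a, n_sig_b,
                      lower.tail = FALSE)
  structure(
    list(per_gene = per_gene, n_mapped = n_mapped, n_overlap = n_overlap,
         r = r, overlap_p = overlap_p, alpha = alpha, restricted = restrict),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %d mapped genes; %d significant in both at alpha = %g\n  Pearson r = %s (%s set); overlap p = %.3g\n",
    x$n_mapped, x$n_overlap, x$alpha,
    ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r)),
    if (x$restricted) "dual-significant" else "all-mapped",
    x$overlap_p
  ))
  invisible(x)
}

#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(
    n_mapped = x$n_mapped, n_overlap = x$n_overlap, r = x$r,
    overlap_p = x$overlap_p, alpha = x$alpha, restricted = x$restricted
  )
}

#' @export
tidy.concordance_result <- function(x, ...) x$per_gene
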