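#' Log2 fold change between two floored group TPM values
#'
#' Group-level TPM values are floored (zeros replaced by 0.01) before the
#' ratio is taken, so both arguments must be strictly positive.
#'
#' @param tpm_a,tpm_b Positive group TPM values (numerator and denominator).
#' @return `log2(tpm_a / tpm_b)`, vectorized.
#' @examples
#' log2_fold_change(0.151394564, 0.01)
#' @export
log2_fold_change <- function(tpm_a, tpm_b) {
  if (any(!is.finite(tpm_a)) || any(!is.finite(tpm_b)) ||
      any(tpm_a <= 0) || any(tpm_b <= 0))
    stop_arg("TPM values must be positive and finite; floor zeros upstream (group_tpm)")
  log2(tpm_a / tpm_b)
}

#' Classify differential direction from fold change and p-value
#'
#' A miRNA is called `"up"` when its log2 fold change is at least
#' `log2(fc_threshold)` and its p-value is below `p_threshold`, `"down"` for
#' the mirrored condition, and `"ns"` otherwise. The fold-change threshold is
#' inclusive and the p-value threshold strict, matching the selection rule
#' "fold change >= 2 and P < 0.05".
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param fc_threshold Fold-change threshold on the natural (ratio) scale.
#' @param p_threshold Significance threshold.
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
classify_de <- function(log2fc, p, fc_threshold = 2, p_threshold = 0.05) {
  check_scalar_number(fc_threshold, "fc_threshold", lower = 1)
  check_scalar_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  if (any(!is.finite(log2fc))) stop_arg("log2fc must be finite")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_arg("p must lie in [0, 1]")
  lfc_cut <- log2(fc_threshold)
  out <- rep("ns", length(log2fc))
  out[log2fc >= lfc_cut & p < p_threshold] <- "up"
  out[log2fc <= -lfc_cut & p < p_threshold] <- "down"
  out
}

#' Differential expression table between two groups of pooled libraries
#'
#' Pools raw counts and clean-tag totals within each group (the exact test is
#' defined for a pair of libraries; replicates enter by pooling), runs the
#' exact count-based test per miRNA, computes floored group TPM values and
#' their log2 fold change, adjusts p-values by Benjamini-Hochberg, and
#' classifies each miRNA as up / down / ns.
#'
#' @param m A miRNA count matrix object from [count_matrix()] or
#'   [simulate_counts()].
#' @param design Sample-to-group assignment: a `data.frame(sample_id, group)`
#'   or a named character vector.
#' @param group_a,group_b The two group labels to compare (fold changes are
#'   `group_a` over `group_b`).
#' @param fc_threshold,p_threshold Selection thresholds; see [classify_de()].
#' @param tail Tail construction for the exact test; see [ac_pvalue()].
#' @param floor Zero-replacement floor for group TPM values.
#' @return A `data.frame` with one row per miRNA, columns `mirna_id`,
#'   `tpm_a`, `tpm_b`, `log2fc`, `p`, `q`, `direction`, sorted by `p`, then
#'   decreasing `|log2fc|`, then `mirna_id`.
#' @examples
#' ref <- make_reference(20, 0, seed = 1)
#' design <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
#' truth <- simulation_truth(spiked = data.frame(
#'   mirna_id = ref$mirna$mirna_id[1], group = "A", fold = 8))
#' sim <- simulate_counts(ref, design, truth, baseline_mean = 200, seed = 7)
#' head(de_table(sim$matrix, design, "A", "B"))
#' @export
de_table <- function(m, design, group_a, group_b,
                     fc_threshold = 2, p_threshold = 0.05,
                     tail = "two-sided", floor = 0.01) {
  design <- as_design(design)
  samples_a <- names(design)[design == group_a]
  samples_b <- names(design)[design == group_b]
  if (length(samples_a) == 0L || length(samples_b) == 0L)
    stop_arg("both groups must have at least one sample")
  if (length(intersect(samples_a, samples_b)) > 0L)
    stop_arg("groups '%s' and '%s' share samples", group_a, group_b)
  missing <- setdiff(c(samples_a, samples_b), colnames(m$counts))
  if (length(missing) > 0L)
    stop_arg("design samples absent from count matrix: %s",
             paste(missing, collapse = ", "))

  x <- rowSums(m$counts[, samples_a, drop = FALSE])
  y <- rowSums(m$counts[, samples_b, drop = FALSE])
  N1 <- sum(m$clean_totals[samples_a])
  N2 <- sum(m$clean_totals[samples_b])
  if (N1 <= 0 || N2 <= 0) stop_arg("pooled clean totals must be positive")

  tpm_a <- floor_tpm(x / N1 * 1e6, floor)
  tpm_b <- floor_tpm(y / N2 * 1e6, floor)
  log2fc <- log2_fold_change(tpm_a, tpm_b)
  p <- vapply(seq_along(x), function(i)
    ac_pvalue(x[[i]], y[[i]], N1, N2, tail = tail)$p_two_sided, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  direction <- classify_de(log2fc, p, fc_threshold, p_threshold)

  out <- data.frame(
    mirna_id = rownames(m$counts),
    tpm_a = unname(tpm_a), tpm_b = unname(tpm_b),
    log2fc = unname(log2fc), p = unname(p), q = unname(q),
    direction = direction,
    stringsAsFactors = FALSE
  )
  ord <- order(out$p, -abs(out$log2fc), out$mirna_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- c(group_a = group_a, group_b = group_b)
  out
}
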