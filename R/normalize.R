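## Replace exact zeros by the floor; positive values below the floor are
## reported as-is (only absent miRNAs are floored).
floor_tpm <- function(tpm, floor = 0.01) {
  tpm[tpm == 0] <- floor
  tpm
}

#' TPM normalization of a miRNA count matrix
#'
#' Transcripts per million: `tpm[i, j] = counts[i, j] / clean_totals[j] * 1e6`,
#' where the denominator is the sample's total clean-tag count (all annotation
#' classes surviving QC and length selection, not only miRNA-assigned tags).
#' No flooring is applied at the per-sample level.
#'
#' @param m A miRNA count matrix object (see [count_matrix()]).
#' @return Numeric matrix of TPM values with the same dimnames as the counts.
#' @export
tpm_normalize <- function(m) {
  totals <- m$clean_totals[colnames(m$counts)]
  bad <- names(totals)[is.na(totals) | totals <= 0]
  if (length(bad) > 0L)
    stop_arg("zero or missing clean-tag total for sample(s): %s",
             paste(bad, collapse = ", "))
  sweep(m$counts, 2, totals, "/") * 1e6
}

#' Group-level TPM with zero floor
#'
#' The group TPM of a miRNA is computed from pooled counts — the sum of its
#' counts over the group's samples divided by the sum of the group's
#' clean-tag totals, times 1e6 — not as a mean of per-sample TPM values.
#' Exact zeros (miRNA absent from every library of the group) are replaced by
#' `floor`; positive values below the floor are kept as-is.
#'
#' @inheritParams de_table
#' @param group The group label to pool.
#' @param floor Zero-replacement value.
#' @return Named numeric vector of group TPM values, one per miRNA.
#' @export
group_tpm <- function(m, design, group, floor = 0.01) {
  design <- as_design(design)
  samples <- names(design)[design == group]
  if (length(samples) == 0L) stop_arg("unknown or empty group '%s'", group)
  missing <- setdiff(samples, colnames(m$counts))
  if (length(missing) > 0L)
    stop_arg("samples absent from count matrix: %s", paste(missing, collapse = ", "))
  pooled <- rowSums(m$counts[, samples, drop = FALSE])
  total <- sum(m$clean_totals[samples])
  if (total <= 0) stop_arg("pooled clean total for group '%s' is not positive", group)
  floor_tpm(pooled / total * 1e6, floor)
}

#' Per-miRNA z-score matrix for heat-map display
#'
#' Row-standardizes `log2(tpm + pseudo)` so that each miRNA has mean 0 and
#' (population) standard deviation 1 across samples; rows with zero variance
#' map to all zeros.
#'
#' @param tpm Numeric TPM matrix (miRNAs in rows, samples in columns).
#' @param pseudo Pseudo-count added before the log transform.
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_matrix <- function(tpm, pseudo = 0.01) {
  if (ncol(tpm) < 2L) stop_arg("z-scores need at least 2 samples")
  lx <- log2(tpm + pseudo)
  mu <- rowMeans(lx)
  centered <- lx - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  z <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  z
}
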