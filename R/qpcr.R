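#' Delta-delta-Ct relative quantification
#'
#' Classic comparative-Ct analysis of qPCR data: per sample,
#' `dCt = target_ct - ref_ct` (normalization to the reference small RNA,
#' e.g. 5sRNA); `ddCt = dCt - mean(dCt of the calibrator group)`; relative
#' expression `fold = 2^(-ddCt)` and `log2_fold = -ddCt`, assuming
#' amplification efficiency 2.
#'
#' @param ct A `data.frame` with columns `sample_id`, `group`, `target_ct`,
#'   `ref_ct` (see [simulate_qpcr()] / [read_ct_table()]).
#' @param calibrator Group label used as the baseline.
#' @return The input with added columns `dct`, `ddct`, `fold`, `log2_fold`;
#'   the calibrator group's mean `log2_fold` is 0 by construction.
#' @export
delta_delta_ct <- function(ct, calibrator) {
  need <- c("sample_id", "group", "target_ct", "ref_ct")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols) > 0L)
    stop_arg("Ct table missing column(s): %s", paste(missing_cols, collapse = ", "))
  bad <- !is.finite(ct$target_ct) | !is.finite(ct$ref_ct) |
    ct$target_ct <= 0 | ct$ref_ct <= 0
  if (any(bad))
    stop_arg("non-finite or non-positive Ct for sample(s): %s",
             paste(ct$sample_id[bad], collapse = ", "))
  if (!calibrator %in% ct$group)
    stop_arg("calibrator group '%s' has no samples", calibrator)
  ct$dct <- ct$target_ct - ct$ref_ct
  baseline <- mean(ct$dct[ct$group == calibrator])
  ct$ddct <- ct$dct - baseline
  ct$fold <- 2^(-ct$ddct)
  ct$log2_fold <- -ct$ddct
  attr(ct, "calibrator") <- calibrator
  ct
}

#' One-way ANOVA on per-sample log2 fold changes
#'
#' Ordinary one-way ANOVA across groups. The fully degenerate case — zero
#' between-group and zero within-group variance — is reported as `F = 0`,
#' `p = 1` by convention. Zero within-group variance with distinct group
#' means yields `F = Inf`, `p = 0`.
#'
#' @param values Numeric vector of per-sample log2 fold changes (or any
#'   response).
#' @param groups Group labels, one per value; at least 2 groups, each with at
#'   least 2 samples.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @export
group_anova <- function(values, groups) {
  if (length(values) != length(groups))
    stop_arg("values and groups must have the same length")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop_arg("need at least 2 groups")
  if (any(sizes < 2L))
    stop_arg("every group needs >= 2 samples (offending: %s)",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
  df_b <- length(sizes) - 1L
  df_w <- length(values) - length(sizes)
  ## degenerate-variance guard: oneway.test returns NaN when a sum of
  ## squares is exactly zero
  means <- tapply(values, groups, mean)
  ss_between <- sum(sizes * (means - mean(values))^2)
  ss_within <- sum((values - means[groups])^2)
  eps <- .Machine$double.eps * max(1, sum(values^2))
  if (ss_between <= eps && ss_within <= eps) {
    Fstat <- 0; p <- 1
  } else if (ss_within <= eps) {
    Fstat <- Inf; p <- 0
  } else {
    fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    Fstat <- unname(fit$statistic)
    p <- fit$p.value
  }
  list(F = Fstat, p = p, df_between = df_b, df_within = df_w)
}

#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with header columns `sample_id`, `group`, `target_ct`,
#'   `ref_ct`.
#' @return The Ct `data.frame`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target_ct", "ref_ct")
  if (!all(need %in% names(df)))
    stop_arg("Ct table '%s' must contain columns %s", path,
             paste(need, collapse = ", "))
  df
}
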