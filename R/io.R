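#' Write and read miRNA count matrices as TSV
#'
#' The layout is one header row, first column `mirna_id`, one column per
#' sample; per-sample clean-tag totals travel in a companion file (same path
#' with suffix `.totals.tsv`) with columns `sample_id`, `clean_total`.
#'
#' @param m A `mirna_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(mirna_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  totals <- data.frame(sample_id = names(m$clean_totals),
                       clean_total = unname(m$clean_totals))
  utils::write.table(totals, totals_path(path), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

totals_path <- function(path) sub("(\\.tsv)?$", ".totals.tsv", path)

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "mirna_id")
    stop_arg("count matrix '%s' must start with a 'mirna_id' column", path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$mirna_id
  totals <- utils::read.delim(totals_path(path), stringsAsFactors = FALSE)
  mirna_counts(counts, stats::setNames(totals$clean_total, totals$sample_id))
}

#' Write a generic matrix with a mirna_id first column
#' @param x Numeric matrix with rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(mirna_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return Named character vector `sample_id -> group`.
#' @export
read_design <- function(path) {
  as_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write target predictions as per-source TSV files
#'
#' @param preds A `target_predictions` object.
#' @param out_dir Output directory; one `<source>.tsv` per source with
#'   columns `mirna_id`, `gene`.
#' @return Named vector of written paths.
#' @export
write_target_lists <- function(preds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stats::setNames(character(length(preds$sources)), preds$sources)
  for (src in preds$sources) {
    p <- preds$predictions[[src]]
    df <- data.frame(
      mirna_id = rep(names(p), lengths(p)),
      gene = unlist(p, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    paths[[src]] <- file.path(out_dir, paste0(src, ".tsv"))
    utils::write.table(df, paths[[src]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}
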