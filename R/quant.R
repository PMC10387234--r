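#' Read a small-RNA FASTQ file
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()] for 4-line
#' FASTQ with Phred+33 qualities.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A [Biostrings::QualityScaledDNAStringSet-class] object.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_arg("FASTQ file not found: %s", path)
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Quality-filter raw small-RNA reads
#'
#' Applies the two read-level quality rules: a read is discarded when its
#' fraction of N bases exceeds `max_n_frac` (strictly greater than — a read at
#' exactly the threshold is kept), or when the fraction of bases with Phred
#' quality below `min_phred` exceeds `max_lowqual_frac`. The poly-N rule is
#' attributed first, so a read failing both counts as a poly-N removal.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet-class] or a FASTQ
#'   file path.
#' @param max_n_frac Maximum tolerated N fraction (default 0.10).
#' @param min_phred Phred score below which a base counts as low-quality
#'   (default 5).
#' @param max_lowqual_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.10).
#' @return A list with `reads` (the surviving reads) and `report`, a one-row
#'   `data.frame` with `n_input`, `n_polyN_removed`, `n_lowqual_removed`,
#'   `n_kept` (removals and survivors sum to the input).
#' @export
filter_reads <- function(reads, max_n_frac = 0.10, min_phred = 5L,
                         max_lowqual_frac = 0.10) {
  if (is.character(reads)) reads <- read_fastq(reads)
  check_scalar_number(max_n_frac, "max_n_frac", lower = 0, upper = 1)
  check_scalar_number(max_lowqual_frac, "max_lowqual_frac", lower = 0, upper = 1)
  check_scalar_number(min_phred, "min_phred", lower = 0, integer = TRUE)

  n <- length(reads)
  if (n == 0L) {
    report <- data.frame(n_input = 0L, n_polyN_removed = 0L,
                         n_lowqual_removed = 0L, n_kept = 0L)
    return(list(reads = reads, report = report))
  }
  widths <- Biostrings::width(reads)
  n_frac <- as.vector(Biostrings::letterFrequency(reads, "N")) / widths
  qs <- as(Biostrings::quality(reads), "IntegerList")
  lowqual_frac <- sum(qs < min_phred) / widths

  polyN_fail <- n_frac > max_n_frac
  lowqual_fail <- !polyN_fail & lowqual_frac > max_lowqual_frac
  keep <- !polyN_fail & !lowqual_fail

  report <- data.frame(
    n_input = n,
    n_polyN_removed = sum(polyN_fail),
    n_lowqual_removed = sum(lowqual_fail),
    n_kept = sum(keep)
  )
  list(reads = reads[keep], report = report)
}

#' Trim the 3' sequencing adapter from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring at least `min_overlap` matching bases. Reads with no
#' qualifying match are returned as `NA` (no-adapter sentinel) rather than
#' raising an error, so callers can count and drop them.
#'
#' @param seqs Character vector of read sequences (DNA alphabet).
#' @param adapter3 The 3' adapter sequence.
#' @param min_overlap Minimum exact overlap with the adapter prefix.
#' @return Character vector of trimmed inserts, `NA` where no adapter match
#'   of sufficient length exists.
#' @export
trim_adapter <- function(seqs, adapter3, min_overlap = 6L) {
  if (!is.character(adapter3) || length(adapter3) != 1L || nchar(adapter3) == 0L)
    stop_arg("adapter3 must be a single non-empty string")
  check_scalar_number(min_overlap, "min_overlap", lower = 1, integer = TRUE)
  if (any(nchar(seqs) == 0L)) stop_arg("empty read sequence")

  out <- rep(NA_character_, length(seqs))
  widths <- nchar(seqs)
  pending <- seq_along(seqs)
  kmax <- min(max(widths), nchar(adapter3))
  if (kmax < min_overlap) return(out)
  ## longest-match-first: at each k, resolve pending reads whose suffix of
  ## length k equals the adapter prefix of length k
  for (k in seq(from = kmax, to = min_overlap)) {
    if (length(pending) == 0L) break
    idx <- pending[widths[pending] >= k]
    if (length(idx) == 0L) next
    ap <- substr(adapter3, 1L, k)
    hit <- substr(seqs[idx], widths[idx] - k + 1L, widths[idx]) == ap
    matched <- idx[hit]
    out[matched] <- substr(seqs[matched], 1L, widths[matched] - k)
    pending <- setdiff(pending, matched)
  }
  out
}

#' Select tags in the small-RNA length window
#'
#' Keeps sequences whose length lies in the inclusive window
#' `[min_len, max_len]`, mirroring the 18-30 nt size selection of small-RNA
#' library preparation.
#'
#' @param seqs Character vector of trimmed sequences.
#' @param min_len,max_len Inclusive length bounds.
#' @return The surviving subset of `seqs`.
#' @export
select_length <- function(seqs, min_len = 18L, max_len = 30L) {
  check_scalar_number(min_len, "min_len", lower = 1, integer = TRUE)
  check_scalar_number(max_len, "max_len", lower = min_len, integer = TRUE)
  w <- nchar(seqs)
  seqs[w >= min_len & w <= max_len]
}

#' Collapse identical reads into unique tags
#'
#' @param seqs Character vector of cleaned, trimmed, length-selected reads.
#' @return A `data.frame` with columns `seq` and `count`, one row per
#'   distinct sequence, sorted by sequence; counts sum to `length(seqs)`.
#' @export
collapse_tags <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(seq = character(0), count = integer(0)))
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$seq), , drop = FALSE]
}

## Normalize RNA/DNA alphabet for comparison: uppercase, U -> T.
normalize_alphabet <- function(seqs) {
  chartr("u", "T", chartr("U", "T", toupper(seqs)))
}

#' Annotate unique tags against a small-RNA reference
#'
#' Tags are matched by exact full-length sequence identity, with contaminant
#' classes (rRNA, scRNA, snoRNA, snRNA, tRNA) taking precedence over mature
#' miRNAs: a tag equal to a contaminant sequence is labelled with that class
#' and excluded from miRNA counting even if it would also match a miRNA.
#' Remaining tags matching a mature miRNA get class `"miRNA"` and its id;
#' everything else is `"unannotated"`. Comparison is alphabet-normalized
#' (U and T are equivalent), so an RNA-alphabet reference annotates
#' DNA-alphabet reads.
#'
#' @param tags A `data.frame(seq, count)` from [collapse_tags()].
#' @param reference A [make_reference()] object (or any list with `mirna` and
#'   `contaminants` data.frames of the same shape).
#' @return `tags` with added columns `class` and `id` (`NA` for
#'   unannotated tags).
#' @export
annotate_tags <- function(tags, reference) {
  ref_mirna <- normalize_alphabet(reference$mirna$mature_seq)
  if (anyDuplicated(ref_mirna) || anyDuplicated(reference$mirna$mirna_id))
    stop_arg("reference integrity error: duplicated mature sequences or ids")
  tag_seq <- normalize_alphabet(tags$seq)

  class <- rep("unannotated", nrow(tags))
  id <- rep(NA_character_, nrow(tags))

  if (nrow(reference$contaminants) > 0L) {
    contam_seq <- normalize_alphabet(reference$contaminants$seq)
    hit <- match(tag_seq, contam_seq)
    found <- !is.na(hit)
    class[found] <- reference$contaminants$class[hit[found]]
  }
  open <- class == "unannotated"
  hit <- match(tag_seq[open], ref_mirna)
  found <- !is.na(hit)
  class[open][found] <- "miRNA"
  id[open][found] <- reference$mirna$mirna_id[hit[found]]

  tags$class <- class
  tags$id <- id
  tags
}

#' Assemble a miRNA count matrix from per-sample annotated tags
#'
#' @param annotations Named list (one element per sample) of annotated tag
#'   `data.frame`s from [annotate_tags()].
#' @param reference The reference used for annotation; fixes the miRNA id
#'   universe and row order.
#' @return An object of class `mirna_counts`: a list with `counts` (integer
#'   matrix, miRNAs x samples), and `clean_totals` (named vector; the total
#'   clean-tag count per sample over all annotation classes — the TPM
#'   denominator).
#' @export
count_matrix <- function(annotations, reference) {
  if (is.null(names(annotations)) || anyDuplicated(names(annotations)))
    stop_arg("annotations must be a named list with unique sample ids")
  mirna_ids <- reference$mirna$mirna_id
  samples <- names(annotations)
  counts <- matrix(0L, nrow = length(mirna_ids), ncol = length(samples),
                   dimnames = list(mirna_ids, samples))
  clean_totals <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    ann <- annotations[[s]]
    clean_totals[[s]] <- sum(ann$count)
    mir <- ann[ann$class == "miRNA", , drop = FALSE]
    if (nrow(mir) > 0L) {
      agg <- tapply(mir$count, mir$id, sum)
      counts[names(agg), s] <- as.integer(agg)
    }
  }
  mirna_counts(counts, clean_totals)
}

#' Construct a miRNA count matrix object
#'
#' @param counts Integer matrix, miRNAs in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids).
#' @param clean_totals Named numeric vector of per-sample total clean-tag
#'   counts; must cover every sample and be at least the per-sample miRNA
#'   count sum.
#' @return A list of class `mirna_counts`.
#' @export
mirna_counts <- function(counts, clean_totals) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_arg("counts must have miRNA rownames and sample colnames")
  if (any(counts < 0)) stop_arg("counts must be non-negative")
  missing <- setdiff(colnames(counts), names(clean_totals))
  if (length(missing) > 0L)
    stop_arg("clean_totals missing sample(s): %s", paste(missing, collapse = ", "))
  clean_totals <- clean_totals[colnames(counts)]
  short <- colSums(counts) > clean_totals
  if (any(short))
    stop_arg("clean_totals below miRNA count sum for sample(s): %s",
             paste(colnames(counts)[short], collapse = ", "))
  structure(list(counts = counts, clean_totals = clean_totals),
            class = "mirna_counts")
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf("miRNA count matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("clean-tag totals:",
      paste(sprintf("%s=%s", names(x$clean_totals),
                    format(x$clean_totals, big.mark = ",")), collapse = " "),
      "\n")
  invisible(x)
}

#' Quantify mature miRNAs from per-sample FASTQ files
#'
#' End-to-end per-sample quantification: quality filter, 3' adapter trim
#' (reads without an adapter match are dropped), length selection, tag
#' collapsing, and reference annotation, assembled into a count matrix. The
#' per-sample clean-tag total — the TPM denominator — counts every tag
#' surviving QC and length selection regardless of annotation class.
#'
#' @param fastq_files Named character vector of FASTQ paths; names are
#'   sample ids.
#' @param reference A [make_reference()] object.
#' @param adapter3 3' adapter sequence used in library construction.
#' @param max_n_frac,min_phred,max_lowqual_frac QC thresholds, see
#'   [filter_reads()].
#' @param min_len,max_len Length window, see [select_length()].
#' @param min_overlap Adapter-match overlap, see [trim_adapter()].
#' @return A list with `matrix` (a `mirna_counts` object) and `qc` (a
#'   `data.frame`, one row per sample, with stage-by-stage read counts:
#'   `n_input`, `n_polyN_removed`, `n_lowqual_removed`, `n_no_adapter`,
#'   `n_length_removed`, `n_clean`, `n_contaminant`, `n_mirna`,
#'   `n_unannotated`).
#' @export
quantify_fastq <- function(fastq_files, reference, adapter3,
                           max_n_frac = 0.10, min_phred = 5L,
                           max_lowqual_frac = 0.10,
                           min_len = 18L, max_len = 30L, min_overlap = 6L) {
  if (is.null(names(fastq_files)) || anyDuplicated(names(fastq_files)))
    stop_arg("fastq_files must be named by unique sample ids")
  annotations <- list()
  qc_rows <- list()
  for (s in names(fastq_files)) {
    flt <- filter_reads(read_fastq(fastq_files[[s]]),
                        max_n_frac = max_n_frac, min_phred = min_phred,
                        max_lowqual_frac = max_lowqual_frac)
    seqs <- as.character(flt$reads)
    trimmed <- if (length(seqs)) trim_adapter(seqs, adapter3, min_overlap) else character(0)
    n_no_adapter <- sum(is.na(trimmed))
    trimmed <- trimmed[!is.na(trimmed)]
    selected <- select_length(trimmed, min_len, max_len)
    tags <- annotate_tags(collapse_tags(selected), reference)
    annotations[[s]] <- tags
    qc_rows[[s]] <- data.frame(
      sample_id = s,
      n_input = flt$report$n_input,
      n_polyN_removed = flt$report$n_polyN_removed,
      n_lowqual_removed = flt$report$n_lowqual_removed,
      n_no_adapter = n_no_adapter,
      n_length_removed = length(trimmed) - length(selected),
      n_clean = length(selected),
      n_contaminant = sum(tags$count[!tags$class %in% c("miRNA", "unannotated")]),
      n_mirna = sum(tags$count[tags$class == "miRNA"]),
      n_unannotated = sum(tags$count[tags$class == "unannotated"])
    )
  }
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  list(matrix = count_matrix(annotations, reference), qc = qc)
}
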