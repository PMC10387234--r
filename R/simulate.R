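#' Default 3' adapter of the read simulator
#'
#' The classic small-RNA ligation adapter extended with downstream primer
#' bases (41 nt) so that even the shortest 18-nt inserts can be padded to the
#' default 50-nt read length.
#'
#' @return The adapter sequence as a string.
#' @export
default_adapter3 <- function() "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCACATCACGAT"

## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  check_scalar_number(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n, lengths) {
  vapply(lengths, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic small-RNA reference
#'
#' Builds a miniature stand-in for a mature-miRNA catalogue plus a set of
#' contaminant small RNAs (rRNA, scRNA, snoRNA, snRNA, tRNA classes), as used
#' for annotation of clean sequencing tags. Mature sequences are 18-25 nt,
#' contaminants 20-28 nt, all over the DNA alphabet. The generator enforces
#' substring-freedom — no sequence is a substring of any other, across both
#' miRNAs and contaminants — so exact-match annotation is unambiguous and
#' class precedence is decided by the reference, never by luck.
#'
#' @param n_mirnas Number of mature miRNAs (>= 0).
#' @param n_contaminants Number of contaminant sequences (>= 0).
#' @param seed Integer RNG seed; output is byte-reproducible per seed.
#' @return A list of class `mirna_reference`: `mirna` (data.frame `mirna_id`,
#'   `mature_seq`) and `contaminants` (data.frame `class`, `seq`).
#' @export
make_reference <- function(n_mirnas, n_contaminants = 0L, seed = 1L) {
  check_scalar_number(n_mirnas, "n_mirnas", lower = 0, integer = TRUE)
  check_scalar_number(n_contaminants, "n_contaminants", lower = 0, integer = TRUE)
  with_seed(seed, {
    accepted <- character(0)
    draw_free <- function(n, len_range) {
      out <- character(n)
      i <- 1L
      while (i <= n) {
        cand <- random_dna(1L, sample(seq(len_range[1], len_range[2]), 1L))
        clash <- any(vapply(accepted, function(s)
          grepl(cand, s, fixed = TRUE) || grepl(s, cand, fixed = TRUE),
          logical(1)))
        if (!clash) {
          accepted <<- c(accepted, cand)
          out[i] <- cand
          i <- i + 1L
        }
      }
      out
    }
    mirna_seqs <- draw_free(n_mirnas, c(18L, 25L))
    contam_seqs <- draw_free(n_contaminants, c(20L, 28L))
    classes <- c("rRNA", "scRNA", "snoRNA", "snRNA", "tRNA")
    structure(list(
      mirna = data.frame(
        mirna_id = sprintf("sim-miR-%03d", seq_len(n_mirnas)),
        mature_seq = mirna_seqs,
        stringsAsFactors = FALSE
      ),
      contaminants = data.frame(
        class = if (n_contaminants > 0L)
          classes[(seq_len(n_contaminants) - 1L) %% length(classes) + 1L]
        else character(0),
        seq = contam_seqs,
        stringsAsFactors = FALSE
      )
    ), class = "mirna_reference")
  })
}

#' Write a reference to FASTA
#'
#' @param reference A [make_reference()] object.
#' @param path Output FASTA path; contaminants are written with
#'   `class|` prefixed ids.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  ids <- c(reference$mirna$mirna_id,
           if (nrow(reference$contaminants) > 0L)
             sprintf("%s|contam-%03d", reference$contaminants$class,
                     seq_len(nrow(reference$contaminants))))
  seqs <- Biostrings::DNAStringSet(c(reference$mirna$mature_seq,
                                     reference$contaminants$seq))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Bundle the ground truth of a simulation
#'
#' @param spiked `data.frame(mirna_id, group, fold)`: miRNAs whose expected
#'   expression is multiplied by `fold` (> 0) in samples of `group`.
#' @param library_sizes Optional named vector of per-sample clean-tag library
#'   sizes; unspecified samples default to 1e6 in [simulate_counts()].
#' @param seed Optional integer recorded with the truth.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(spiked = NULL, library_sizes = NULL, seed = NULL) {
  if (is.null(spiked))
    spiked <- data.frame(mirna_id = character(0), group = character(0),
                         fold = numeric(0))
  if (!all(c("mirna_id", "group", "fold") %in% names(spiked)))
    stop_arg("spiked needs columns mirna_id, group, fold")
  if (any(spiked$fold <= 0)) stop_arg("true fold changes must be positive")
  structure(list(spiked = spiked, library_sizes = library_sizes, seed = seed),
            class = "simulation_truth")
}

#' Simulate a miRNA count matrix with known spiked effects
#'
#' Per-miRNA baseline expression rates are drawn log-normally around
#' `baseline_mean` (expected count at a library size of 1e6 clean tags), then
#' counts are drawn negative-binomially with the given dispersion — Poisson
#' when `dispersion = 0`, matching the sampling model underlying the exact
#' test — with the mean scaled by each sample's library size and by the true
#' fold change for spiked miRNAs in their elevated group.
#'
#' @param reference A [make_reference()] object.
#' @param design Sample-to-group map (named vector or data.frame).
#' @param truth A [simulation_truth()] object; every spiked id must exist in
#'   the reference.
#' @param baseline_mean Mean expected count per miRNA at library size 1e6.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); 0
#'   gives Poisson counts.
#' @param baseline_sdlog Log-normal sd of per-miRNA baselines; 0 makes all
#'   baselines equal to `baseline_mean`.
#' @param seed Integer seed (defaults to `truth$seed`, else 1).
#' @return A list with `matrix` (a `mirna_counts` object whose clean-tag
#'   totals are the nominal library sizes) and `truth` (the input truth with
#'   `baselines` attached).
#' @export
simulate_counts <- function(reference, design, truth = simulation_truth(),
                            baseline_mean = 100, dispersion = 0,
                            baseline_sdlog = 1,
                            seed = if (!is.null(truth$seed)) truth$seed else 1L) {
  design <- as_design(design)
  check_scalar_number(baseline_mean, "baseline_mean", lower = 0)
  check_scalar_number(dispersion, "dispersion", lower = 0)
  check_scalar_number(baseline_sdlog, "baseline_sdlog", lower = 0)
  ids <- reference$mirna$mirna_id
  unknown <- setdiff(truth$spiked$mirna_id, ids)
  if (length(unknown) > 0L)
    stop_arg("spiked miRNAs absent from reference: %s",
             paste(unknown, collapse = ", "))
  unknown_grp <- setdiff(truth$spiked$group, design)
  if (length(unknown_grp) > 0L)
    stop_arg("spiked groups absent from design: %s",
             paste(unknown_grp, collapse = ", "))

  samples <- names(design)
  lib <- stats::setNames(rep(1e6, length(samples)), samples)
  if (!is.null(truth$library_sizes)) {
    if (any(truth$library_sizes <= 0)) stop_arg("library sizes must be positive")
    lib[names(truth$library_sizes)] <- truth$library_sizes
  }

  with_seed(seed, {
    baselines <- if (baseline_sdlog > 0)
      stats::rlnorm(length(ids),
                    meanlog = log(baseline_mean) - baseline_sdlog^2 / 2,
                    sdlog = baseline_sdlog)
    else rep(baseline_mean, length(ids))
    names(baselines) <- ids

    fold <- matrix(1, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
    for (k in seq_len(nrow(truth$spiked))) {
      sp <- truth$spiked[k, ]
      fold[sp$mirna_id, design == sp$group] <- sp$fold
    }
    mu <- baselines * fold %*% diag(lib / 1e6, nrow = length(samples))
    dimnames(mu) <- list(ids, samples)
    draw <- if (dispersion == 0)
      function(m) stats::rpois(length(m), m)
    else
      function(m) stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
    counts <- matrix(as.integer(draw(mu)), nrow = length(ids),
                     dimnames = list(ids, samples))
    clean_totals <- pmax(lib, colSums(counts))
    truth$library_sizes <- lib
    truth$baselines <- baselines
    list(matrix = mirna_counts(counts, clean_totals), truth = truth)
  })
}

#' Simulate adapter-ligated small-RNA FASTQ files
#'
#' Each counted miRNA molecule becomes one read: the mature sequence followed
#' by the 3' adapter, truncated to `read_length` (the adapter must be long
#' enough to pad the shortest insert). Junk reads are injected per sample at
#' the requested fractions of the miRNA read count, one class per QC rule so
#' filter attribution is testable: poly-N reads (all-N body, high quality;
#' removed by the N-fraction rule), low-quality reads (random insert, Phred 2
#' throughout; removed by the quality rule) and contaminant reads (a
#' contaminant sequence plus adapter, high quality; these survive QC and are
#' set aside at annotation). Read order within a sample is shuffled.
#'
#' @param sim Output of [simulate_counts()] (or any list with `matrix` being
#'   a `mirna_counts`).
#' @param reference The [make_reference()] object the counts refer to.
#' @param out_dir Directory for the per-sample FASTQ files.
#' @param adapter3 3' adapter sequence.
#' @param frac_polyN,frac_lowqual,frac_contaminant Injection fractions in
#'   \[0, 1\], relative to the sample's miRNA read count.
#' @param read_length Fixed read length in nt.
#' @param seed Integer seed.
#' @return Named character vector of FASTQ paths (one per sample).
#' @export
simulate_reads <- function(sim, reference, out_dir = tempfile("reads_"),
                           adapter3 = default_adapter3(),
                           frac_polyN = 0, frac_lowqual = 0,
                           frac_contaminant = 0,
                           read_length = 50L, seed = 1L) {
  check_scalar_number(frac_polyN, "frac_polyN", lower = 0, upper = 1)
  check_scalar_number(frac_lowqual, "frac_lowqual", lower = 0, upper = 1)
  check_scalar_number(frac_contaminant, "frac_contaminant", lower = 0, upper = 1)
  check_scalar_number(read_length, "read_length", lower = 1, integer = TRUE)
  m <- sim$matrix
  seqs <- reference$mirna$mature_seq
  names(seqs) <- reference$mirna$mirna_id
  max_pad <- read_length - min(nchar(seqs))
  if (max_pad > nchar(adapter3))
    stop_arg("adapter3 (%d nt) too short to pad the shortest insert to %d nt",
             nchar(adapter3), read_length)
  if (frac_contaminant > 0 && nrow(reference$contaminants) == 0L)
    stop_arg("frac_contaminant > 0 but the reference has no contaminants")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  as_read <- function(insert) {
    full <- paste0(insert, adapter3)
    substr(full, 1L, read_length)
  }
  hi_q <- strrep("I", read_length)   # Phred 40
  lo_q <- strrep("#", read_length)   # Phred 2 (< 5) at every base

  paths <- stats::setNames(character(ncol(m$counts)), colnames(m$counts))
  with_seed(seed, {
    for (s in colnames(m$counts)) {
      cnt <- m$counts[, s]
      mir_reads <- as_read(rep(seqs[names(cnt)], times = cnt))
      n_mir <- length(mir_reads)
      n_polyN <- round(frac_polyN * n_mir)
      n_lowq <- round(frac_lowqual * n_mir)
      n_contam <- round(frac_contaminant * n_mir)

      contam_reads <- if (n_contam > 0L)
        as_read(sample(reference$contaminants$seq, n_contam, replace = TRUE))
      else character(0)
      lowq_reads <- if (n_lowq > 0L) as_read(random_dna(n_lowq, rep(22L, n_lowq)))
        else character(0)
      polyN_reads <- rep(strrep("N", read_length), n_polyN)

      reads <- c(mir_reads, contam_reads, lowq_reads, polyN_reads)
      quals <- c(rep(hi_q, n_mir + n_contam), rep(lo_q, n_lowq),
                 rep(hi_q, n_polyN))
      if (length(reads) > 0L) {
        ord <- sample.int(length(reads))
        reads <- reads[ord]; quals <- quals[ord]
      }
      x <- Biostrings::DNAStringSet(reads)
      names(x) <- sprintf("%s_read_%06d", s, seq_along(reads))
      path <- file.path(out_dir, paste0(s, ".fastq"))
      file.create(path)   # ensure an (empty) FASTQ exists for 0-read samples
      if (length(x) > 0L)
        Biostrings::writeXStringSet(x, path, format = "fastq",
                                    qualities = Biostrings::BStringSet(quals))
      paths[[s]] <- path
    }
  })
  paths
}

#' Simulate a qPCR Ct table with known group effects
#'
#' Produces per-sample threshold-cycle values for a target miRNA and a
#' reference small RNA (e.g. 5sRNA) such that, in expectation, delta-delta-Ct
#' analysis against the calibrator group recovers exactly the injected log2
#' fold changes (assuming amplification efficiency 2).
#'
#' @param groups Named character vector `sample_id -> group`.
#' @param true_log2fc Named numeric vector `group -> log2 fold change`
#'   relative to the calibrator group (whose own entry should be 0); must
#'   cover every group in `groups`.
#' @param ct_ref_mean Mean reference-gene Ct.
#' @param ct_target_base Target Ct at log2 fold change 0.
#' @param noise_sd Gaussian noise sd (cycles) added independently to target
#'   and reference Ct; 0 gives exact recovery.
#' @param seed Integer seed.
#' @return `data.frame(sample_id, group, target_ct, ref_ct)`.
#' @export
simulate_qpcr <- function(groups, true_log2fc, ct_ref_mean = 20,
                          ct_target_base = 26, noise_sd = 0, seed = 1L) {
  if (length(groups) == 0L) stop_arg("groups must be non-empty")
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  missing <- setdiff(unique(groups), names(true_log2fc))
  if (length(missing) > 0L)
    stop_arg("true_log2fc missing group(s): %s", paste(missing, collapse = ", "))
  with_seed(seed, {
    n <- length(groups)
    ## one extra target cycle halves expression: lower Ct = higher level
    target_ct <- ct_target_base - true_log2fc[groups] + stats::rnorm(n, 0, noise_sd)
    ref_ct <- ct_ref_mean + stats::rnorm(n, 0, noise_sd)
    data.frame(sample_id = names(groups), group = unname(groups),
               target_ct = unname(target_ct), ref_ct = unname(ref_ct),
               stringsAsFactors = FALSE)
  })
}

#' Simulate multi-source miRNA target-prediction lists
#'
#' Emulates the output of several target-prediction tools: for each miRNA a
#' core set of genes (fraction `overlap` of `genes_per_mirna`) is shared by
#' every source, while the remaining genes of each source are drawn disjoint
#' across sources, so the all-source consensus equals the core exactly.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param gene_universe Character vector of candidate gene symbols; must be
#'   large enough for the disjoint peripheries.
#' @param n_sources Number of prediction sources (>= 1).
#' @param overlap Fraction in \[0, 1\] of each miRNA's genes shared by all
#'   sources.
#' @param genes_per_mirna Genes predicted per miRNA per source.
#' @param source_names Optional source labels (defaults to generic
#'   predictor-style names).
#' @param seed Integer seed.
#' @return A list of class `target_predictions`: `sources`, `predictions`
#'   (list source -> list miRNA -> gene character vector) and `core` (the
#'   per-miRNA shared set, for truth bookkeeping).
#' @export
simulate_target_lists <- function(mirnas, gene_universe, n_sources = 4L,
                                  overlap = 0.5, genes_per_mirna = 100L,
                                  source_names = NULL, seed = 1L) {
  check_scalar_number(n_sources, "n_sources", lower = 1, integer = TRUE)
  check_scalar_number(overlap, "overlap", lower = 0, upper = 1)
  check_scalar_number(genes_per_mirna, "genes_per_mirna", lower = 1,
                      integer = TRUE)
  n_core <- round(overlap * genes_per_mirna)
  need <- n_core + n_sources * (genes_per_mirna - n_core)
  if (length(gene_universe) < need)
    stop_arg("gene_universe too small: need >= %d genes, have %d",
             need, length(gene_universe))
  if (is.null(source_names))
    source_names <- paste0("source", seq_len(n_sources))
  if (length(source_names) != n_sources)
    stop_arg("source_names must have length n_sources")

  with_seed(seed, {
    core <- list()
    predictions <- stats::setNames(
      lapply(source_names, function(.)
        stats::setNames(vector("list", length(mirnas)), mirnas)),
      source_names)
    for (m in mirnas) {
      pool <- sample(gene_universe, need)
      core[[m]] <- sort(pool[seq_len(n_core)])
      periph <- pool[-seq_len(n_core)]
      for (i in seq_len(n_sources)) {
        extra <- if (genes_per_mirna > n_core)
          periph[seq.int((i - 1L) * (genes_per_mirna - n_core) + 1L,
                         i * (genes_per_mirna - n_core))]
        else character(0)
        predictions[[source_names[i]]][[m]] <- sort(c(core[[m]], extra))
      }
    }
    structure(list(sources = source_names, predictions = predictions,
                   core = core),
              class = "target_predictions")
  })
}

#' Simulate a term-to-gene annotation map
#'
#' Random GO/pathway-style annotation: each term draws its gene set from the
#' universe, with sizes uniform in `term_size_range`.
#'
#' @param gene_universe Character vector of gene symbols (the background).
#' @param n_terms Number of terms.
#' @param term_size_range Inclusive range of term sizes.
#' @param category Category label attached to every term.
#' @param seed Integer seed.
#' @return `data.frame(term_id, term_name, category, gene)` in the one-row-
#'   per-gene annotation layout accepted by [annotation_map()].
#' @export
simulate_annotations <- function(gene_universe, n_terms = 20L,
                                 term_size_range = c(10L, 50L),
                                 category = "GO", seed = 1L) {
  check_scalar_number(n_terms, "n_terms", lower = 1, integer = TRUE)
  if (term_size_range[2] > length(gene_universe))
    stop_arg("term sizes exceed the gene universe")
  with_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(i) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      data.frame(term_id = sprintf("%s:%04d", category, i),
                 term_name = sprintf("synthetic term %d", i),
                 category = category,
                 gene = sort(sample(gene_universe, size)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
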