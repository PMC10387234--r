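#' Bundled serum RA differential-miRNA reference tables
#'
#' Group-level TPM pairs, directions and log2 fold changes of the
#' differential serum miRNAs reported in a published small-RNA profiling
#' study of seronegative rheumatoid arthritis (N-RA), seropositive RA (P-RA)
#' and healthy controls (HC). The three comparisons are N-RA vs HC, N-RA vs
#' P-RA and P-RA vs HC; zero-count group TPM cells carry the 0.01 floor.
#' These tables are the input of the replay mode ([replay_tables()]), which
#' re-derives the fold-change statistics from the printed TPM columns.
#'
#' @param comparison One of `"nra_vs_hc"`, `"nra_vs_pra"`, `"pra_vs_hc"`, or
#'   `"all"` for a named list of the three.
#' @return A `data.frame` with columns `mirna_id`, `tpm_a`, `tpm_b`,
#'   `direction`, `log2fc` (groups a/b in the comparison's order), or a
#'   named list of such data frames.
#' @export
serum_ra_tables <- function(comparison = c("all", "nra_vs_hc", "nra_vs_pra",
                                           "pra_vs_hc")) {
  comparison <- match.arg(comparison)
  load1 <- function(cmp) {
    path <- system.file("extdata", paste0("serum_ra_", cmp, ".tsv"),
                        package = "serumiR", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (comparison == "all") {
    cmps <- c("nra_vs_hc", "nra_vs_pra", "pra_vs_hc")
    stats::setNames(lapply(cmps, load1), cmps)
  } else load1(comparison)
}

#' Re-derive fold-change statistics from published group-TPM columns
#'
#' Recomputes the log2 fold change from the two group TPM columns of a
#' differential-miRNA table and classifies each row's direction by the sign
#' and magnitude of the recomputed fold change (the table rows are already
#' the significant miRNAs, so only the fold-change threshold applies). When
#' the table carries a printed `log2fc` column, the per-row absolute
#' deviation `|recomputed - printed|` is reported alongside.
#'
#' @param table `data.frame` with columns `mirna_id`, `tpm_a`, `tpm_b` and
#'   optionally `log2fc` (printed values); TPM values must be positive —
#'   published tables are pre-floored.
#' @param fc_threshold Fold-change threshold for the direction call.
#' @return The input columns plus `log2fc_recomputed`, `direction_recomputed`
#'   and (when printed values are present) `abs_dev`.
#' @export
replay_tables <- function(table, fc_threshold = 2) {
  need <- c("mirna_id", "tpm_a", "tpm_b")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L)
    stop_arg("replay table missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  if (any(table$tpm_a <= 0 | table$tpm_b <= 0))
    stop_arg("non-positive TPM in replay table; published tables are pre-floored")
  out <- table
  out$log2fc_recomputed <- log2_fold_change(table$tpm_a, table$tpm_b)
  out$direction_recomputed <- classify_de(out$log2fc_recomputed,
                                          p = rep(0, nrow(out)),
                                          fc_threshold = fc_threshold)
  if ("log2fc" %in% names(table))
    out$abs_dev <- abs(out$log2fc_recomputed - table$log2fc)
  out
}

#' Default pipeline configuration
#'
#' Study-scale defaults: three groups (12 N-RA, 9 HC, 9 P-RA libraries),
#' 200 known miRNAs plus 10 contaminant small RNAs, a handful of miRNAs
#' spiked at >= 2-fold between groups, nominal library sizes of 1e6 clean
#' tags for count simulation, and the selection thresholds of the analysis
#' (length window 18-30 nt, N-fraction and low-quality fraction 0.10, Phred
#' cutoff 5, TPM zero floor 0.01, fold change 2, alpha 0.05, all-source
#' target consensus). Every threshold appears here exactly once.
#'
#' @param seed Integer master seed; each stage derives its own stream.
#' @param out_dir Output directory of the run.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "quant", "diffexpr", "targets", "enrichment", "qpcr")`.
#' @param ... Overrides for any default listed below (unknown names error).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("serumir_run_"),
                            stages = c("simulate", "quant", "diffexpr",
                                       "targets", "enrichment", "qpcr"),
                            ...) {
  config <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    ## study design
    n_nra = 12L, n_hc = 9L, n_pra = 9L,
    ## synthetic inputs
    n_mirnas = 200L, n_contaminants = 10L,
    baseline_mean = 100, dispersion = 0, baseline_sdlog = 1,
    library_size = 1e6,
    n_spiked_per_comparison = 2L, spike_fold = 8,
    frac_polyN = 0.02, frac_lowqual = 0.02, frac_contaminant = 0.05,
    read_length = 50L, adapter3 = default_adapter3(),
    n_genes = 2000L, genes_per_mirna = 100L, target_overlap = 0.5,
    n_terms = 30L,
    qpcr_noise_sd = 0.2, qpcr_log2fc = c(`N-RA` = 1, HC = 0, `P-RA` = 0),
    ## analysis thresholds
    max_n_frac = 0.10, min_phred = 5L, max_lowqual_frac = 0.10,
    min_len = 18L, max_len = 30L, min_overlap = 6L,
    tpm_floor = 0.01, fc_threshold = 2, alpha = 0.05,
    tail = "two-sided", min_sources = NULL, min_term_size = 5L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown) > 0L)
    stop_arg("unknown config field(s): %s", paste(unknown, collapse = ", "))
  config[names(dots)] <- dots
  bad <- setdiff(config$stages,
                 c("simulate", "quant", "diffexpr", "targets", "enrichment",
                   "qpcr"))
  if (length(bad) > 0L) stop_arg("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(config, class = "run_config")
}

pipeline_design <- function(config) {
  groups <- c(rep("N-RA", config$n_nra), rep("HC", config$n_hc),
              rep("P-RA", config$n_pra))
  stats::setNames(groups, sprintf("%s_%02d", gsub("-", "", groups),
                                  unlist(lapply(table(groups)[unique(groups)],
                                                seq_len))))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> quantify -> differential expression -> target
#' consensus -> enrichment -> qPCR on synthetic data, writing every stage's
#' outputs as TSV under `config$out_dir` together with a JSON manifest
#' (stage status, parameters, seed, and md5 hash of every output file).
#' Identical configuration and seed produce identical manifest hashes. A
#' stage failure aborts the run naming the stage; outputs of completed
#' stages are retained.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `out_dir`, `manifest` (the parsed
#'   manifest) and in-memory stage results (`reference`, `sim`, `quant`,
#'   `de`, `consensus`, `enrichment`, `qpcr`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "run_config")) stop_arg("config must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = config$out_dir)
  status <- stats::setNames(
    rep("skipped", 6),
    c("simulate", "quant", "diffexpr", "targets", "enrichment", "qpcr"))
  outputs <- character(0)
  design <- pipeline_design(config)
  comparisons <- list(c("N-RA", "HC"), c("N-RA", "P-RA"), c("P-RA", "HC"))

  run_stage <- function(name, code) {
    if (!name %in% config$stages) return(invisible(NULL))
    message(sprintf("[%s] running", name))
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    status[[name]] <<- "ok"
  }
  emit <- function(path) outputs <<- c(outputs, path)

  run_stage("simulate", {
    res$reference <- make_reference(config$n_mirnas, config$n_contaminants,
                                    seed = config$seed)
    ## spike the first miRNAs, one comparison at a time, alternating the
    ## elevated group so both directions occur
    ids <- res$reference$mirna$mirna_id
    spiked <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
      k <- config$n_spiked_per_comparison
      idx <- (i - 1L) * k + seq_len(k)
      data.frame(mirna_id = ids[idx],
                 group = rep(comparisons[[i]], length.out = k),
                 fold = config$spike_fold, stringsAsFactors = FALSE)
    }))
    truth <- simulation_truth(
      spiked = spiked,
      library_sizes = stats::setNames(rep(config$library_size, length(design)),
                                      names(design)),
      seed = config$seed)
    res$sim <- simulate_counts(res$reference, design, truth,
                               baseline_mean = config$baseline_mean,
                               dispersion = config$dispersion,
                               baseline_sdlog = config$baseline_sdlog)
    res$fastq <- simulate_reads(res$sim, res$reference,
                                out_dir = file.path(config$out_dir, "fastq"),
                                adapter3 = config$adapter3,
                                frac_polyN = config$frac_polyN,
                                frac_lowqual = config$frac_lowqual,
                                frac_contaminant = config$frac_contaminant,
                                read_length = config$read_length,
                                seed = config$seed + 1L)
    emit(write_reference_fasta(res$reference,
                               file.path(config$out_dir, "reference.fasta")))
    emit(write_count_matrix(res$sim$matrix,
                            file.path(config$out_dir, "simulated_counts.tsv")))
    utils::write.table(res$sim$truth$spiked,
                       file.path(config$out_dir, "truth_spiked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "truth_spiked.tsv"))
    utils::write.table(data.frame(sample_id = names(design), group = design),
                       file.path(config$out_dir, "design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "design.tsv"))
  })

  run_stage("quant", {
    res$quant <- quantify_fastq(res$fastq, res$reference, config$adapter3,
                                max_n_frac = config$max_n_frac,
                                min_phred = config$min_phred,
                                max_lowqual_frac = config$max_lowqual_frac,
                                min_len = config$min_len,
                                max_len = config$max_len,
                                min_overlap = config$min_overlap)
    emit(write_count_matrix(res$quant$matrix,
                            file.path(config$out_dir, "counts.tsv")))
    emit(write_matrix_tsv(tpm_normalize(res$quant$matrix),
                          file.path(config$out_dir, "tpm.tsv")))
    emit(write_matrix_tsv(zscore_matrix(tpm_normalize(res$quant$matrix),
                                        pseudo = config$tpm_floor),
                          file.path(config$out_dir, "zscore.tsv")))
    utils::write.table(res$quant$qc, file.path(config$out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "qc_report.tsv"))
  })

  run_stage("diffexpr", {
    m <- if (!is.null(res$quant)) res$quant$matrix else res$sim$matrix
    res$de <- lapply(comparisons, function(cmp) {
      de_table(m, design, cmp[1], cmp[2],
               fc_threshold = config$fc_threshold,
               p_threshold = config$alpha,
               tail = config$tail, floor = config$tpm_floor)
    })
    names(res$de) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
    for (nm in names(res$de)) {
      path <- file.path(config$out_dir, paste0("de_", gsub("-", "", nm), ".tsv"))
      utils::write.table(res$de[[nm]], path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(path)
    }
  })

  run_stage("targets", {
    sig <- unique(unlist(lapply(res$de, function(d)
      d$mirna_id[d$direction != "ns"])))
    if (length(sig) == 0L) sig <- res$de[[1]]$mirna_id[1]
    res$preds <- simulate_target_lists(
      sig, gene_universe = sprintf("GENE%04d", seq_len(config$n_genes)),
      n_sources = 4L, overlap = config$target_overlap,
      genes_per_mirna = config$genes_per_mirna, seed = config$seed + 2L)
    min_src <- if (is.null(config$min_sources)) length(res$preds$sources)
      else config$min_sources
    res$consensus <- consensus_targets(res$preds, min_sources = min_src)
    cons_df <- data.frame(
      mirna_id = rep(names(res$consensus), lengths(res$consensus)),
      gene = unlist(res$consensus, use.names = FALSE))
    utils::write.table(cons_df, file.path(config$out_dir, "consensus_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "consensus_targets.tsv"))
    utils::write.table(venn_counts(res$preds),
                       file.path(config$out_dir, "venn_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "venn_regions.tsv"))
    de_sig <- do.call(rbind, lapply(res$de, function(d)
      d[d$direction != "ns", c("mirna_id", "direction")]))
    de_sig <- de_sig[!duplicated(de_sig$mirna_id), , drop = FALSE]
    res$network <- build_network(de_sig, res$consensus)
    write_network(res$network,
                  tsv_path = file.path(config$out_dir, "network_edges.tsv"),
                  sif_path = file.path(config$out_dir, "network.sif"))
    emit(file.path(config$out_dir, "network_edges.tsv"))
    emit(file.path(config$out_dir, "network.sif"))
  })

  run_stage("enrichment", {
    universe <- sprintf("GENE%04d", seq_len(config$n_genes))
    annot <- annotation_map(
      simulate_annotations(universe, n_terms = config$n_terms,
                           seed = config$seed + 3L),
      background = universe)
    query <- unique(unlist(res$consensus, use.names = FALSE))
    res$enrichment <- enrich(query, annot,
                             min_term_size = config$min_term_size)
    utils::write.table(res$enrichment,
                       file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "enrichment.tsv"))
  })

  run_stage("qpcr", {
    ct <- simulate_qpcr(design, true_log2fc = config$qpcr_log2fc,
                        noise_sd = config$qpcr_noise_sd,
                        seed = config$seed + 4L)
    folds <- delta_delta_ct(ct, calibrator = "HC")
    res$qpcr <- list(
      folds = folds,
      anova = group_anova(folds$log2_fold, folds$group))
    utils::write.table(folds, file.path(config$out_dir, "qpcr_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "qpcr_folds.tsv"))
    summ <- do.call(rbind, lapply(split(folds$log2_fold, folds$group),
                                  function(v) data.frame(
                                    mean_log2_fold = mean(v),
                                    sem = stats::sd(v) / sqrt(length(v)),
                                    n = length(v))))
    summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
    summ$anova_F <- res$qpcr$anova$F
    summ$anova_p <- res$qpcr$anova$p
    utils::write.table(summ, file.path(config$out_dir, "qpcr_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(config$out_dir, "qpcr_summary.tsv"))
  })

  manifest <- list(
    seed = config$seed,
    stages = as.list(status),
    parameters = config[setdiff(names(config), c("stages", "out_dir"))],
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
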