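test_that("make_reference handles the empty case and is seed-deterministic", {
  empty <- make_reference(0, 0, seed = 1)
  expect_equal(nrow(empty$mirna), 0L)
  expect_equal(nrow(empty$contaminants), 0L)

  a <- make_reference(5, 2, seed = 42)
  b <- make_reference(5, 2, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, make_reference(5, 2, seed = 43)))

  expect_error(make_reference(-1), "n_mirnas")
})

test_that("reference sequences are unique, length-bounded and substring-free", {
  ref <- make_reference(50, 10, seed = 7)
  expect_equal(length(unique(ref$mirna$mirna_id)), 50L)
  lens <- nchar(ref$mirna$mature_seq)
  expect_true(all(lens >= 18 & lens <= 25))
  expect_true(all(grepl("^[ACGT]+$", ref$mirna$mature_seq)))
  ## all-pairs substring scan over miRNAs and contaminants together
  seqs <- c(ref$mirna$mature_seq, ref$contaminants$seq)
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i != j) expect_false(grepl(seqs[i], seqs[j], fixed = TRUE))
  }
})

test_that("simulated counts recover spiked fold changes in expectation", {
  ref <- make_reference(5, 0, seed = 3)
  design <- setNames(rep(c("A", "B"), each = 2), paste0("s", 1:4))
  truth <- simulation_truth(
    spiked = data.frame(mirna_id = "sim-miR-001", group = "A", fold = 8),
    library_sizes = setNames(rep(1e6, 4), names(design)))
  ## Poisson at a large mean and equal baselines: law of large numbers puts
  ## the empirical group-mean ratio within 10% of the true fold
  sim <- simulate_counts(ref, design, truth, baseline_mean = 2.5e5,
                         dispersion = 0, baseline_sdlog = 0, seed = 11)
  cnt <- sim$matrix$counts["sim-miR-001", ]
  ratio <- mean(cnt[design == "A"]) / mean(cnt[design == "B"])
  expect_lt(abs(ratio / 8 - 1), 0.10)

  ## no spikes: per-miRNA log-ratios centre on zero
  null <- simulate_counts(ref, design, simulation_truth(),
                          baseline_mean = 1e4, dispersion = 0,
                          baseline_sdlog = 0, seed = 12)
  lr <- log2(rowMeans(null$matrix$counts[, design == "A"]) /
             rowMeans(null$matrix$counts[, design == "B"]))
  expect_lt(max(abs(lr)), 0.1)

  ## seeded determinism
  again <- simulate_counts(ref, design, truth, baseline_mean = 2.5e5,
                           dispersion = 0, baseline_sdlog = 0, seed = 11)
  expect_identical(sim$matrix, again$matrix)
  expect_error(simulate_counts(ref, design, truth, dispersion = -1),
               "dispersion")
})

test_that("simulated FASTQ is byte-reproducible and junk is attributable", {
  ref <- tiny_reference()
  design <- c(s1 = "A", s2 = "B")
  counts <- matrix(c(5L, 3L, 2L, 4L, 0L, 6L), nrow = 3,
                   dimnames = list(ref$mirna$mirna_id, names(design)))
  sim <- list(matrix = mirna_counts(counts, c(s1 = 1e4, s2 = 1e4)))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_reads(sim, ref, out_dir = d1, frac_polyN = 0.2,
                       frac_lowqual = 0.2, frac_contaminant = 0.2, seed = 5)
  p2 <- simulate_reads(sim, ref, out_dir = d2, frac_polyN = 0.2,
                       frac_lowqual = 0.2, frac_contaminant = 0.2, seed = 5)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  ## saturated poly-N injection is fully removed by the N-rule
  flt <- filter_reads(p1[["s1"]])
  expect_equal(flt$report$n_polyN_removed, round(0.2 * 10))
  expect_equal(flt$report$n_lowqual_removed, round(0.2 * 10))

  ## adapter too short for the padding is an argument error
  expect_error(simulate_reads(sim, ref, out_dir = withr::local_tempdir(),
                              adapter3 = "TGGAAT", seed = 1),
               "adapter")
})

test_that("simulated qPCR tables reproduce injected effects", {
  groups <- setNames(rep(c("HC", "N-RA"), each = 3), paste0("s", 1:6))
  lfc <- c(HC = 0, `N-RA` = 0)

  ## zero effect, zero noise: every fold change is exactly 1
  ct <- simulate_qpcr(groups, lfc, noise_sd = 0, seed = 1)
  folds <- delta_delta_ct(ct, calibrator = "HC")
  expect_equal(folds$fold, rep(1, 6))

  ## +1 log2 in one group: that group's fold is exactly 2
  ct2 <- simulate_qpcr(groups, c(HC = 0, `N-RA` = 1), noise_sd = 0, seed = 1)
  f2 <- delta_delta_ct(ct2, calibrator = "HC")
  expect_equal(unname(f2$fold[f2$group == "N-RA"]), rep(2, 3))

  ## Monte-Carlo recovery at noise_sd = 0.2, n = 10/group: group mean within
  ## 3 SEM of the injected value
  g10 <- setNames(rep(c("HC", "N-RA"), each = 10), paste0("t", 1:20))
  ct3 <- simulate_qpcr(g10, c(HC = 0, `N-RA` = 1), noise_sd = 0.2, seed = 9)
  f3 <- delta_delta_ct(ct3, calibrator = "HC")
  vals <- f3$log2_fold[f3$group == "N-RA"]
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * sem)

  expect_error(simulate_qpcr(character(0), lfc), "non-empty")
})

test_that("simulated target lists honour the overlap contract", {
  genes <- sprintf("G%04d", 1:600)
  mirnas <- c("m1", "m2")

  full <- simulate_target_lists(mirnas, genes, n_sources = 4, overlap = 1,
                                genes_per_mirna = 20, seed = 2)
  cons <- consensus_targets(full)
  for (m in mirnas)
    expect_identical(cons[[m]], full$predictions[[1]][[m]])

  none <- simulate_target_lists(mirnas, genes, n_sources = 4, overlap = 0,
                                genes_per_mirna = 20, seed = 2)
  expect_true(all(lengths(consensus_targets(none)) == 0))

  half <- simulate_target_lists(mirnas, genes, n_sources = 4, overlap = 0.5,
                                genes_per_mirna = 100, seed = 2)
  cons_half <- consensus_targets(half)
  expect_true(all(lengths(cons_half) == 50))
  expect_identical(cons_half, half$core[mirnas])

  expect_error(simulate_target_lists(mirnas, genes, n_sources = 0), "n_sources")
  expect_error(simulate_target_lists(mirnas, genes[1:50]), "universe")
})
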