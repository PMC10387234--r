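test_that("quality filter applies both discard rules with strict thresholds", {
  base <- strrep("A", 50)
  seq_10pct_N <- paste0(strrep("N", 5), strrep("A", 45))   # exactly 10%
  seq_12pct_N <- paste0(strrep("N", 6), strrep("A", 44))   # 12% > 10%
  hi <- strrep("I", 50)
  ## 6 of 50 bases below Phred 5 (12%) vs exactly 5 (10%)
  q_12pct_low <- paste0(strrep("#", 6), strrep("I", 44))
  q_10pct_low <- paste0(strrep("#", 5), strrep("I", 45))

  reads <- make_reads(c(base, seq_10pct_N, seq_12pct_N, base, base),
                      c(hi, hi, hi, q_12pct_low, q_10pct_low))
  flt <- filter_reads(reads)
  expect_equal(flt$report$n_input, 5L)
  expect_equal(flt$report$n_polyN_removed, 1L)
  expect_equal(flt$report$n_lowqual_removed, 1L)
  expect_equal(flt$report$n_kept, 3L)
  ## conservation at the stage boundary
  expect_equal(with(flt$report, n_polyN_removed + n_lowqual_removed + n_kept),
               flt$report$n_input)
  expect_equal(length(flt$reads), 3L)
})

test_that("constructed violator batches are counted exactly", {
  good <- strrep("ACGTT", 10)
  bad <- paste0(strrep("N", 10), strrep("A", 40))
  hi <- strrep("I", 50)
  reads <- make_reads(c(rep(good, 900), rep(bad, 100)), rep(hi, 1000))
  flt <- filter_reads(reads)
  expect_equal(flt$report$n_polyN_removed, 100L)
  expect_equal(flt$report$n_kept, 900L)
})

test_that("adapter trimming removes the longest matching suffix", {
  adapter <- default_adapter3()
  insert <- "ACGTACGTACGTACGTAC"
  full <- substr(paste0(insert, adapter), 1, 50)
  expect_identical(trim_adapter(full, adapter), insert)
  ## exact ligation inverse with the whole adapter present
  expect_identical(trim_adapter(paste0("ACGT", adapter), adapter), "ACGT")
  ## no qualifying overlap -> sentinel
  expect_identical(trim_adapter("ACGTACGTACGTACGT", adapter), NA_character_)
  expect_error(trim_adapter("", adapter), "empty")
})

test_that("length selection uses the inclusive 18-30 window", {
  seqs <- vapply(c(17, 18, 19, 25, 30, 31, 40, 10, 22, 29),
                 function(l) strrep("A", l), character(1))
  kept <- select_length(seqs)
  expect_equal(sort(nchar(kept)), c(18, 19, 22, 25, 29, 30))
})

test_that("tag collapsing conserves read counts", {
  expect_equal(nrow(collapse_tags(character(0))), 0L)
  seqs <- c(rep(strrep("A", 20), 2), strrep("C", 20))
  tags <- collapse_tags(seqs)
  expect_equal(nrow(tags), 2L)
  expect_equal(sum(tags$count), 3L)
  ## conservation on an arbitrary batch
  batch <- sample(c(strrep("A", 18), strrep("G", 22), strrep("T", 30)),
                  57, replace = TRUE)
  expect_equal(sum(collapse_tags(batch)$count), 57L)
})

test_that("annotation applies contaminant precedence and exact matching", {
  ref <- tiny_reference()
  tags <- collapse_tags(c(ref$mirna$mature_seq[1],
                          ref$contaminants$seq[1],
                          strrep("T", 20)))
  ann <- annotate_tags(tags, ref)
  expect_equal(ann$class[ann$seq == ref$mirna$mature_seq[1]], "miRNA")
  expect_equal(ann$id[ann$seq == ref$mirna$mature_seq[1]], "miR-a")
  expect_equal(ann$class[ann$seq == ref$contaminants$seq[1]], "tRNA")
  expect_equal(ann$class[ann$seq == strrep("T", 20)], "unannotated")

  ## a contaminant that would also be a miRNA is labelled contaminant
  ref2 <- ref
  ref2$contaminants <- rbind(ref2$contaminants,
                             data.frame(class = "rRNA",
                                        seq = ref$mirna$mature_seq[2]))
  ann2 <- annotate_tags(collapse_tags(ref$mirna$mature_seq[2]), ref2)
  expect_equal(ann2$class, "rRNA")
  expect_true(is.na(ann2$id))

  ## RNA-alphabet reference still annotates DNA reads
  ref3 <- ref
  ref3$mirna$mature_seq <- chartr("T", "U", ref3$mirna$mature_seq)
  ann3 <- annotate_tags(collapse_tags(ref$mirna$mature_seq[1]), ref3)
  expect_equal(ann3$class, "miRNA")

  ## annotation is order-independent
  shuffled <- collapse_tags(rev(c(ref$mirna$mature_seq, strrep("T", 20))))
  a <- annotate_tags(shuffled, ref)
  b <- annotate_tags(collapse_tags(c(ref$mirna$mature_seq, strrep("T", 20))),
                     ref)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$seq), ], b[order(b$seq), ], ignore_attr = TRUE)
})

test_that("TPM normalization follows the count / clean-total * 1e6 formula", {
  counts <- matrix(c(10L, 0L, 5L, 7L), nrow = 2,
                   dimnames = list(c("m1", "m2"), c("s1", "s2")))
  m <- mirna_counts(counts, c(s1 = 1e6, s2 = 2e6))
  tpm <- tpm_normalize(m)
  expect_equal(tpm["m1", "s1"], 10)
  expect_equal(tpm["m2", "s1"], 0)
  expect_equal(tpm["m1", "s2"], 2.5)

  ## conservation identity on a random matrix
  set.seed(42)
  rc <- matrix(rpois(120, 50), nrow = 20,
               dimnames = list(sprintf("m%02d", 1:20), sprintf("s%d", 1:6)))
  totals <- setNames(colSums(rc) + rpois(6, 1000), colnames(rc))
  mr <- mirna_counts(rc, totals)
  tpm_r <- tpm_normalize(mr)
  expect_equal(colSums(tpm_r), 1e6 * colSums(rc) / totals)
  ## integer round-trip: multiplying back recovers counts exactly
  back <- sweep(tpm_r, 2, totals / 1e6, "*")
  expect_true(all(round(back) == rc))

  expect_error(tpm_normalize(mirna_counts(counts, c(s1 = 0, s2 = 1e6))),
               "s1")
})

test_that("group TPM pools counts and floors only exact zeros", {
  counts <- matrix(c(0L, 3L, 0L, 5L, 2L, 0L), nrow = 2,
                   dimnames = list(c("m1", "m2"), c("a1", "a2", "b1")))
  m <- mirna_counts(counts, c(a1 = 1e6, a2 = 1e6, b1 = 1e6))
  design <- c(a1 = "A", a2 = "A", b1 = "B")
  gA <- group_tpm(m, design, "A")
  ## pooled: m1 has 0 reads in A -> floored; m2 has 8 reads / 2e6 * 1e6 = 4
  expect_equal(unname(gA["m1"]), 0.01)
  expect_equal(unname(gA["m2"]), 4)
  ## a positive value below the floor is reported as-is
  tiny <- mirna_counts(matrix(c(1L, 0L), nrow = 2,
                              dimnames = list(c("m1", "m2"), "s1")),
                       c(s1 = 1e9))
  g <- group_tpm(tiny, c(s1 = "A"), "A")
  expect_equal(unname(g["m1"]), 0.001)
  expect_equal(unname(g["m2"]), 0.01)
  expect_error(group_tpm(m, design, "nope"), "group")
})

test_that("z-score rows standardize to mean 0, population SD 1", {
  tpm <- matrix(c(1, 1, 1,
                  2, 8, 32,
                  5, 40, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("flat", "rise", "bump"), c("s1", "s2", "s3")))
  z <- zscore_matrix(tpm)
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  expect_equal(mean(z["rise", ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z["rise", ]^2)), 1, tolerance = 1e-9)
  ## closed form for two samples: (-1, +1) orientation by value order
  z2 <- zscore_matrix(matrix(c(2, 8), nrow = 1,
                             dimnames = list("m", c("s1", "s2"))))
  expect_equal(unname(z2["m", ]), c(-1, 1))
})

test_that("zero-noise reads round-trip through quantification exactly", {
  ref <- make_reference(10, 3, seed = 21)
  design <- c(s1 = "A", s2 = "B")
  truth <- simulation_truth(
    library_sizes = c(s1 = 1e6, s2 = 1e6))
  sim <- simulate_counts(ref, design, truth, baseline_mean = 30,
                         dispersion = 0, seed = 22)
  paths <- simulate_reads(sim, ref, out_dir = withr::local_tempdir(),
                          frac_polyN = 0, frac_lowqual = 0, seed = 23)
  quant <- quantify_fastq(paths, ref, default_adapter3())
  expect_identical(quant$matrix$counts, sim$matrix$counts)
  ## with no junk, every clean tag is a miRNA tag
  expect_equal(unname(quant$matrix$clean_totals),
               unname(colSums(sim$matrix$counts)))
  ## all miRNA-derived reads trimmed to their mature sequence
  expect_equal(sum(quant$qc$n_no_adapter), 0L)
  expect_equal(sum(quant$qc$n_length_removed), 0L)
})
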