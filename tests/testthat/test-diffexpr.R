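test_that("log-space pmf matches direct factorial evaluation", {
  ## closed-form reductions
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5, tolerance = 1e-12)
  expect_equal(ac_probability(0, 1, 1e6, 1e6), 0.25, tolerance = 1e-12)
  expect_equal(ac_probability(7, 3, 1e6, 2e6),
               ac_pmf_direct(7, 3, 1e6, 2e6), tolerance = 1e-12)

  ## oracle equivalence across the small-count grid and library ratios
  for (ratio in c(0.5, 1, 2)) {
    for (x in c(0:5, 10, 20, 30)) {
      y <- 0:30
      got <- vapply(y, function(yy)
        ac_probability(x, yy, 1e6, ratio * 1e6), numeric(1))
      want <- vapply(y, function(yy)
        ac_pmf_direct(x, yy, 1e6, ratio * 1e6), numeric(1))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the pmf normalizes to 1 over y", {
  for (x in c(0L, 1L, 5L, 17L, 50L)) {
    for (ratio in c(0.5, 1, 2)) {
      total <- sum(vapply(0:2000, function(y)
        ac_probability(x, y, 1e6, ratio * 1e6), numeric(1)))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("tail p-values satisfy the exact-test identities", {
  ## symmetric mode: equal counts and equal library sizes give p = 1
  expect_equal(ac_pvalue(12, 12, 1e6, 1e6)$p_two_sided, 1)

  ## C + D = 1 + p(y|x) at the observed count
  for (x in c(0, 3, 20)) for (y in c(0, 5, 40)) {
    r <- ac_pvalue(x, y, 1e6, 3e6)
    expect_equal(r$C + r$D, 1 + exp(r$log_p_xy), tolerance = 1e-9)
  }

  ## label-swap symmetry over a small grid
  for (x in 0:6) for (y in 0:6) {
    expect_equal(ac_pvalue(x, y, 1e6, 2e6)$p_two_sided,
                 ac_pvalue(y, x, 2e6, 1e6)$p_two_sided, tolerance = 1e-12)
  }

  ## brute-force upper-tail oracle at x = 0, y = 20, N1 = N2:
  ## p(y|0) = (1/2)^(y+1), so D = sum_{y'>=20} 2^-(y'+1) = 2^-20
  r <- ac_pvalue(0, 20, 1e6, 1e6)
  brute <- sum(0.5^((20:2000) + 1))
  expect_equal(r$D, brute, tolerance = 1e-10)
  expect_equal(r$p_two_sided, 2 * brute, tolerance = 1e-10)

  ## independent distributional route: the pmf in y is negative binomial
  ## with size x + 1 and prob N1 / (N1 + N2)
  for (x in c(2, 9)) for (y in c(0, 4, 15)) {
    r2 <- ac_pvalue(x, y, 1e6, 2e6)
    expect_equal(r2$C, pnbinom(y, size = x + 1, prob = 1 / 3),
                 tolerance = 1e-12)
    expect_equal(r2$D, pnbinom(y - 1, size = x + 1, prob = 1 / 3,
                               lower.tail = FALSE), tolerance = 1e-12)
  }

  ## the upper tail is non-increasing in the observed count
  D <- vapply(0:30, function(y) ac_pvalue(5, y, 1e6, 1e6)$D, numeric(1))
  expect_true(all(diff(D) <= 1e-15))
})

test_that("log2 fold change reproduces published floored-TPM examples", {
  expect_equal(log2_fold_change(0.151394564, 0.01), 3.920241501,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(0.01, 0.539587039), -5.753783791,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(3.7, 3.7), 0)
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("direction classification uses FC >= 2 (inclusive) and p < 0.05 (strict)", {
  expect_equal(classify_de(3.69922099, 0.01), "up")
  expect_equal(classify_de(1.74861923, 0.01), "up")
  expect_equal(classify_de(0.99, 0.001), "ns")
  expect_equal(classify_de(1, 0.049), "up")       # FC threshold inclusive
  expect_equal(classify_de(-1, 0.049), "down")
  expect_equal(classify_de(2, 0.05), "ns")        # p threshold strict
  expect_equal(classify_de(c(2, -2, 0.5), c(0.01, 0.01, 0.01)),
               c("up", "down", "ns"))
})

test_that("de_table pools groups, adjusts p and is antisymmetric", {
  ref <- make_reference(30, 0, seed = 31)
  design <- setNames(rep(c("A", "B"), times = c(3, 2)), paste0("s", 1:5))
  truth <- simulation_truth(
    spiked = data.frame(mirna_id = c("sim-miR-001", "sim-miR-002"),
                        group = c("A", "B"), fold = 8),
    library_sizes = setNames(rep(2e5, 5), names(design)))
  sim <- simulate_counts(ref, design, truth, baseline_mean = 200, seed = 32)
  de_ab <- de_table(sim$matrix, design, "A", "B")
  de_ba <- de_table(sim$matrix, design, "B", "A")

  expect_setequal(de_ab$mirna_id, ref$mirna$mirna_id)
  ## BH: q monotone in p and q >= p
  expect_true(all(de_ab$q >= de_ab$p - 1e-15))
  expect_true(all(diff(de_ab$q[order(de_ab$p)]) >= -1e-15))
  ## sorted by p then |log2fc| descending
  expect_true(!is.unsorted(de_ab$p))
  ## antisymmetry under group swap
  m <- match(de_ab$mirna_id, de_ba$mirna_id)
  expect_equal(de_ab$log2fc, -de_ba$log2fc[m], tolerance = 1e-12)
  expect_equal(de_ab$p, de_ba$p[m], tolerance = 1e-12)
  ## spiked miRNAs called in the right direction
  expect_equal(de_ab$direction[de_ab$mirna_id == "sim-miR-001"], "up")
  expect_equal(de_ab$direction[de_ab$mirna_id == "sim-miR-002"], "down")
  ## significance invariant holds on every record
  sig <- de_ab[de_ab$direction != "ns", ]
  expect_true(all(abs(sig$log2fc) >= 1 & sig$p < 0.05))

  expect_error(de_table(sim$matrix, design, "A", "A"), "share")
})
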