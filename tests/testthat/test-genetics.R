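test_that("dosage orientation reflects only when counted != increasing", {
  sp_same <- variant_spec("rsX", "T", "T")
  sp_flip <- variant_spec("rsY", "T", "C", ref = "C", alt = "T")
  expect_equal(orient_dosage(0.5, sp_same), 0.5)
  expect_equal(orient_dosage(0.5, sp_flip), 1.5)
  ## involution: orienting a reflected dosage with the reverse spec
  sp_back <- variant_spec("rsY", "C", "T", ref = "C", alt = "T")
  expect_equal(orient_dosage(orient_dosage(0.5, sp_flip), sp_back), 0.5)
  ## variance is preserved under reflection
  d <- runif(50, 0, 2)
  expect_equal(var(orient_dosage(d, sp_flip)), var(d))
  expect_error(orient_dosage(2.4, sp_same), "\\[0, 2\\]")
})

test_that("the genetic risk score is an order-invariant additive sum", {
  expect_equal(compute_grs(2, 2), 4)
  expect_equal(compute_grs(0, 0), 0)
  expect_equal(compute_grs(1.2, 0.4), 1.6)
  a <- runif(20, 0, 2)
  b <- runif(20, 0, 2)
  expect_equal(compute_grs(a, b), compute_grs(b, a))
  ## missing dosage propagates, never imputed
  expect_true(is.na(compute_grs(c(1, NA), c(0.5, 0.5))[2]))
})

test_that("mean GRS converges to twice the summed allele frequencies", {
  n <- 2e5
  g <- compute_grs(simulate_genotypes(n, 0.63, 1, seed = 31),
                   simulate_genotypes(n, 0.26, 1, seed = 32))
  expect_equal(mean(g), 2 * (0.63 + 0.26), tolerance = 0.01)
})

test_that("HWE chi-square agrees with the exact-test oracle", {
  ## exact HW proportions: statistic 0, p = 1
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  ## complete heterozygote deficit: both tests far below the QC threshold
  r2 <- hwe_test(c(50, 0, 50))
  expect_equal(r2$statistic, 100)  # chi-square statistic = n
  expect_lt(r2$p, 1e-7)
  expect_lt(oracle_hwe_exact(c(50, 0, 50)), 1e-7)
  ## the two tests classify a spread of cases identically at 1e-7
  cases <- list(c(30, 40, 30), c(10, 60, 30), c(70, 25, 5),
                c(40, 5, 55), c(5, 90, 5), c(81, 18, 1))
  for (cc in cases) {
    chi <- hwe_test(cc)$p
    exact <- oracle_hwe_exact(cc)
    expect_identical(chi < 1e-7, exact < 1e-7)
    ## and p values agree to order of magnitude on non-extreme cases
    if (chi > 1e-5) expect_lt(abs(log10(chi) - log10(exact)), 1)
  }
  expect_warning(r3 <- hwe_test(c(0, 0, 100)), "monomorphic")
  expect_equal(r3$p, 1)
})

test_that("variant QC applies the thresholds inclusively", {
  n <- 4000
  case <- rep(c(0L, 1L), n / 2)
  d1 <- simulate_genotypes(n, 0.3, 1, seed = 41)
  ## exactly at the call-rate threshold: 5% missing passes
  d_thr <- d1
  d_thr[seq_len(n * 0.05)] <- NA
  specs <- list(v1 = variant_spec("v1", "T", "T"))
  expect_warning(
    rep1 <- qc_variants(list(v1 = d_thr), case, specs,
                        imputation_r2 = c(v1 = 0.3)),
    "skipped")
  expect_true(rep1$pass)
  ## just below: fails with reason call_rate
  d_low <- d1
  d_low[seq_len(ceiling(n * 0.06))] <- NA
  rep2 <- qc_variants(list(v1 = d_low), case, specs,
                      imputation_r2 = c(v1 = 1))
  expect_false(rep2$pass)
  expect_match(rep2$reasons, "call_rate")
  ## poor imputation fails with reason imputation_r2
  expect_warning(
    rep3 <- qc_variants(list(v1 = d1), case, specs,
                        imputation_r2 = c(v1 = 0.29)),
    "skipped")
  expect_false(rep3$pass)
  expect_match(rep3$reasons, "imputation_r2")
  ## HWE violation caught in controls (hard calls)
  case_sorted <- c(rep(0L, n / 2), rep(1L, n / 2))
  d_hwe <- ifelse(case_sorted == 0, rep(c(0, 2), n / 4), d1)
  rep4 <- qc_variants(list(v1 = d_hwe), case_sorted, specs,
                      imputation_r2 = c(v1 = 1))
  expect_false(rep4$pass)
  expect_match(rep4$reasons, "hwe")
  ## no controls: HWE not assessable, pass on remaining criteria
  expect_warning(
    rep5 <- qc_variants(list(v1 = d1), rep(1L, n), specs,
                        imputation_r2 = c(v1 = 1)),
    "no controls")
  expect_true(rep5$pass)
  expect_true(is.na(rep5$hwe_p))
})
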