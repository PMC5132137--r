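test_that("simulated dosages reproduce hard calls at r2 = 1", {
  d <- simulate_genotypes(1e5, freq = 0.26, r2 = 1, seed = 11)
  expect_true(all(d == round(d)))
  expect_equal(mean(d), 0.52, tolerance = 0.02)
})

test_that("imputation noise hits the target dosage-genotype correlation", {
  d <- simulate_genotypes(1e5, freq = 0.5, r2 = 0.5, seed = 12)
  g <- attr(d, "hard")
  expect_equal(cor(d, g)^2, 0.5, tolerance = 0.05)
  expect_true(all(d >= 0 & d <= 2))
  ## realistic high-quality imputation too
  d2 <- simulate_genotypes(1e5, freq = 0.26, r2 = 0.9, seed = 13)
  expect_equal(cor(d2, attr(d2, "hard"))^2, 0.9, tolerance = 0.05)
})

test_that("genotype simulation is deterministic under a fixed seed", {
  a <- simulate_genotypes(5, 0.26, 0.3, seed = 7)
  b <- simulate_genotypes(5, 0.26, 0.3, seed = 7)
  expect_identical(a, b)
})

test_that("genotype simulation rejects invalid arguments", {
  expect_error(simulate_genotypes(0, 0.5), "positive")
  expect_error(simulate_genotypes(10, 1.2), "freq")
  expect_error(simulate_genotypes(10, 0.5, r2 = 0), "r2")
})

test_that("fixed seed gives a byte-identical cohort and per-study streams", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ## adding a study never changes earlier studies' data
  cfg8 <- tiny_config(n_studies = 7L,
                      study_sizes = c(cfg$study_sizes, 300L))
  c8 <- simulate_cohort(cfg8)
  first6 <- c8[c8$study %in% unique(a$study), ]
  rownames(first6) <- NULL
  attr(first6, "config") <- attr(a, "config")
  expect_identical(first6, a)
})

test_that("realized case fraction tracks the configured fraction", {
  cfg <- tiny_config(n_studies = 4L, total_n = 20000L, case_fraction = 0.4)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$case) - 0.4), 0.01)
})

test_that("unattainable case fractions are reported, not clipped", {
  ## a fraction no admissible intercept can reach given the effects
  cfg <- tiny_config(case_fraction = 1e-14)
  expect_error(simulate_cohort(cfg), "unattainable")
})

test_that("cohort invariants hold: dosage range, ages, case-only fields", {
  co <- simulate_cohort(tiny_config())
  expect_true(all(co$dos_rs4410790 >= 0 & co$dos_rs4410790 <= 2))
  expect_true(all(co$dos_rs2472297 >= 0 & co$dos_rs2472297 <= 2))
  cases <- co$case == 1
  expect_true(all(is.na(co$tnm[!cases]) & is.na(co$seer[!cases])))
  expect_true(all(is.na(co$gleason[!cases])))
  ok <- !is.na(co$age_exit)
  expect_true(all(co$age_exit[ok] > co$age_diagnosis[ok]))
  ## odd studies code TNM, even studies SEER
  odd <- co$study %in% c("STUDY01", "STUDY03", "STUDY05")
  expect_true(all(is.na(co$seer[odd])))
  expect_true(all(is.na(co$tnm[!odd])))
})

test_that("first-stage slope converges to gamma under the null confounding path", {
  cfg <- sim_config(n_studies = 1L, study_sizes = 1e5L, case_fraction = 0.5,
                    gamma_coffee = 0.10, n_coffee_studies = 1L, seed = 21)
  co <- add_instruments(simulate_cohort(cfg))
  co$cups <- co$coffee_cups + co$tea_cups
  slope <- coef(fit_linear_robust(cups ~ grs, co))["grs"]
  expect_lt(abs(slope - 0.10), 0.005)
})

test_that("null generative model yields null case-status estimates", {
  cfg <- tiny_config(n_studies = 4L, total_n = 30000L,
                     theta_reduced = 0, confounder_logor = 0)
  co <- add_instruments(simulate_cohort(cfg))
  f <- fit_logistic(case ~ grs + study, co, cluster = "study")
  i <- match("grs", f$table$term)
  expect_lt(abs(f$table$estimate[i]), 3.5 * f$table$se[i])
  expect_equal(f$table$or[i], 1.0, tolerance = 0.06)
})

test_that("cohort write/read round trip is exact, including missing values", {
  co <- simulate_cohort(tiny_config(n_studies = 2L, total_n = 120L))
  gp <- tempfile(fileext = ".vcf")
  pp <- tempfile(fileext = ".tsv")
  write_cohort(co, gp, pp)
  lines <- readLines(gp)
  expect_identical(sum(!startsWith(lines, "#")), 2L)  # two variant records
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_identical(length(header) - 9L, nrow(co))     # one column per sample
  back <- read_cohort(gp, pp)
  expect_identical(back$dos_rs4410790, co$dos_rs4410790)
  expect_identical(back$dos_rs2472297, co$dos_rs2472297)
  expect_identical(back$gleason, co$gleason)          # NA round trip
  expect_identical(back$coffee_cups, co$coffee_cups)
  expect_identical(back$tnm, co$tnm)
})
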