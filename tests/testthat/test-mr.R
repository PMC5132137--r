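test_that("categorical-to-per-cup scaling reproduces the published arithmetic", {
  expect_equal(round(scale_categorical_or(0.96, 3.5, 0.06), 3), 0.999)
  expect_equal(scale_categorical_or(1.0, 3.5, 0.06), 1.0)
  expect_equal(scale_categorical_or(0.96, 0.06, 0.06), 0.96)
  expect_error(scale_categorical_or(-1, 1, 1), "positive")
  ## transitivity: extreme -> per-cup -> per-0.06-cup equals direct
  direct <- scale_categorical_or(0.96, 3.5, 0.06)
  per_cup <- scale_categorical_or(0.96, 3.5, 1)
  expect_equal(scale_categorical_or(per_cup, 1, 0.06), direct,
               tolerance = 1e-12)
  ## across plausible contrasts the per-0.06-cup OR never strays further
  ## than half a rounding unit from 0.999
  sens <- scaling_sensitivity(0.96, seq(2.5, 6, 0.5), 0.06)
  expect_true(all(abs(sens$or_per_unit - 0.999) < 6e-4))
  expect_equal(sens$rounded[sens$contrast == 3.5], 0.999)
})

test_that("Wald ratio evaluates the ratio and delta-method SE", {
  w <- wald_ratio(log(1.03), 0.012, 0.10, 0.02)
  expect_equal(w$estimate, log(1.03) / 0.10)
  expect_equal(w$or, 1.344, tolerance = 1e-3)
  expect_equal(w$se,
               sqrt(0.012^2 / 0.01 + log(1.03)^2 * 0.02^2 / 1e-4),
               tolerance = 1e-12)
  ## null reduced form transmits a null causal estimate with finite SE
  w0 <- wald_ratio(0, 0.01, 0.10, 0.02)
  expect_equal(w0$estimate, 0)
  expect_true(is.finite(w0$se) && w0$se > 0)
  ## zero first-stage SE reduces to se_r / gamma
  w1 <- wald_ratio(0.03, 0.012, 0.10, 0)
  expect_equal(w1$se, 0.012 / 0.10)
  expect_error(wald_ratio(0.03, 0.01, 0), "nonzero")
  expect_warning(wald_ratio(0.03, 0.01, 0.05, 0.04), "weak instrument")
})

test_that("Wald ratio agrees with two-stage least squares on simulated data", {
  set.seed(91)
  n <- 1e5
  g <- as.numeric(simulate_genotypes(n, 0.63, 1)) +
    as.numeric(simulate_genotypes(n, 0.26, 1))
  u <- rbinom(n, 1, 0.5)
  cups <- 1.5 + 0.10 * g + 0.5 * u + rgamma(n, 2, scale = 0.75)
  ## outcome caused by cups (log OR 0.2 per cup) and confounded by u
  y <- rbinom(n, 1, plogis(-2 + 0.2 * cups + 0.3 * u))
  d <- data.frame(g = g, cups = cups, y = y)
  ## Wald ratio from reduced form and first stage
  rf <- fit_logistic(y ~ g, d)
  fs <- fit_linear_robust(cups ~ g, d)
  w <- wald_ratio(rf$table$estimate[2], rf$table$se[2],
                  fs$table$estimate[2], fs$table$se[2])
  ## 2SLS: regress outcome on fitted cups (linear probability analogue is
  ## biased for logistic scale, so use the ratio of logistic coefficients
  ## via the control-function route as the independent check)
  cups_hat <- fitted(lm(cups ~ g))
  tsls <- coef(glm(y ~ cups_hat, binomial))["cups_hat"]
  expect_equal(w$estimate, unname(tsls), tolerance = 0.02 * abs(tsls))
  expect_false(w$weak_instrument)
})

test_that("minimal detectable OR follows the Wald power formula", {
  vg <- grs_variance(c(0.63, 0.26))
  expect_equal(vg, 2 * 0.63 * 0.37 + 2 * 0.26 * 0.74)
  det <- detectable_or(22721, 23034, var_g = vg)
  ## hand evaluation of the formula
  se <- 1 / sqrt(45755 * (22721 / 45755) * (23034 / 45755) * vg)
  beta <- (qnorm(0.975) + qnorm(0.8)) * se
  expect_equal(det$or_per_allele, exp(-beta), tolerance = 1e-12)
  expect_equal(det$or_per_allele, 0.97, tolerance = 0.005)
  ## asymptotics: more samples -> detectable OR increases toward 1
  det2 <- detectable_or(45442, 46068, var_g = vg)
  expect_gt(det2$or_per_allele, det$or_per_allele)
  ## halving N scales the detectable log OR by sqrt(2)
  half <- detectable_or(22721 / 2, 23034 / 2, var_g = vg)
  expect_equal(half$beta / det$beta, sqrt(2), tolerance = 1e-9)
  expect_error(detectable_or(0, 10, vg), "degenerate")
})
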