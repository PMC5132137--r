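test_that("Cox estimate matches the exhaustive partial-likelihood oracle", {
  ## 4 subjects, known event order, no ties
  d <- data.frame(x = c(1, 0, 1, 0), en = c(0, 0, 0, 0),
                  ex = c(2, 3, 5, 7), ev = c(1, 1, 1, 0))
  f <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
  expect_equal(unname(coef(f)), oracle_cox_fit(d$x, d$en, d$ex, d$ev),
               tolerance = 1e-4)
  ## 5 subjects with left truncation and a tie (Efron)
  d2 <- data.frame(x = c(0.5, -1, 2, 0, 1), en = c(0, 1, 0.5, 2, 0),
                   ex = c(3, 3, 4, 6, 5), ev = c(1, 1, 1, 0, 1))
  f2 <- fit_cox(~ x, d2, entry = "en", exit = "ex", event = "ev")
  expect_equal(unname(coef(f2)), oracle_cox_fit(d2$x, d2$en, d2$ex, d2$ev),
               tolerance = 1e-4)
})

test_that("Cox fit equals survival::coxph with and without truncation", {
  skip_if_not_installed("survival")
  set.seed(71)
  n <- 600
  x <- rnorm(n)
  z <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.15 * exp(0.4 * x - 0.3 * z))
  ## right-censored, entry 0
  ex <- pmin(t, 8)
  ev <- as.integer(t <= 8)
  d <- data.frame(x = x, z = z, en = 0, ex = ex, ev = ev)
  f <- fit_cox(~ x + z, d, entry = "en", exit = "ex", event = "ev")
  s <- survival::coxph(survival::Surv(ex, ev) ~ x + z, d, ties = "efron")
  expect_equal(unname(coef(f)), unname(coef(s)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(f$vcov_model))),
               unname(sqrt(diag(vcov(s)))), tolerance = 1e-7)
  ## left-truncated on an age-like timescale with heavy ties
  en2 <- runif(n, 50, 70)
  t2 <- round(rexp(n, 0.2 * exp(0.3 * x)), 0) + 0.5
  d2 <- data.frame(x = x, en = en2, ex = en2 + pmin(t2, 6),
                   ev = as.integer(t2 <= 6))
  f2 <- fit_cox(~ x, d2, entry = "en", exit = "ex", event = "ev")
  s2 <- survival::coxph(survival::Surv(en, ex, ev) ~ x, d2, ties = "efron")
  expect_equal(unname(coef(f2)), unname(coef(s2)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(f2$vcov_model))),
               unname(sqrt(diag(vcov(s2)))), tolerance = 1e-7)
})

test_that("partial likelihood is invariant to scaling the timescale", {
  set.seed(72)
  n <- 300
  x <- rnorm(n)
  en <- runif(n, 0, 1)
  t <- rexp(n, 0.3 * exp(0.5 * x))
  d <- data.frame(x = x, en = en, ex = en + pmin(t, 4),
                  ev = as.integer(t <= 4))
  f1 <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
  d2 <- transform(d, en = en * 365.25, ex = ex * 365.25)
  f2 <- fit_cox(~ x, d2, entry = "en", exit = "ex", event = "ev")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("null covariate yields HR near 1 at large n", {
  set.seed(73)
  n <- 20000
  x <- rnorm(n)
  t <- rexp(n, 0.2)
  d <- data.frame(x = x, en = 0, ex = pmin(t, 6), ev = as.integer(t <= 6))
  f <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
  expect_equal(unname(exp(coef(f))), 1, tolerance = 0.04)
})

test_that("degenerate survival inputs are handled explicitly", {
  d <- data.frame(x = rnorm(10), en = 0, ex = 1:10, ev = 0)
  expect_error(fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev"),
               "no events")
  d2 <- data.frame(x = rnorm(10), en = c(0, rep(1, 9)),
                   ex = c(1, rep(1, 9) + 0), ev = c(1, rep(0, 9)))
  d2$ex[2:10] <- 2
  d2$en[1] <- 1  # exit == entry for the event record
  expect_warning(
    fit_cox(~ x, d2, entry = "en", exit = "ex", event = "ev"),
    "shifted")
})

test_that("log HR recovery is unbiased at consortium scale", {
  ## narrower version of the full recovery experiment: median over a few
  ## replicates sits near the generative value
  r <- recovery_study("pca_mortality", n_rep = 12, seed = 300)
  ## 12-replicate smoke check: within ~2 Monte-Carlo SDs of the median
  expect_lt(abs(r$median_estimate - log(1.03)), 0.02)
  expect_lt(abs(r$mean_events - 1754), 0.08 * 1754)
})

test_that("PH test is well behaved under proportional hazards", {
  set.seed(74)
  pv <- replicate(60, {
    n <- 400
    x <- rnorm(n)
    t <- rexp(n, 0.3 * exp(0.3 * x))
    d <- data.frame(x = x, en = 0, ex = pmin(t, 5),
                    ev = as.integer(t <= 5))
    f <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
    ph_test(f)$p[1]
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.07)
})

test_that("PH test detects a reversing hazard ratio", {
  set.seed(75)
  hits <- replicate(15, {
    n <- 3000
    x <- rnorm(n)
    ## effect +0.6 before t = 2, -0.6 after: non-proportional
    u <- runif(n)
    t1 <- -log(u) / (0.25 * exp(0.6 * x))
    t <- ifelse(t1 <= 2, t1,
                2 + (t1 - 2) * exp(0.6 * x) / exp(-0.6 * x))
    d <- data.frame(x = x, en = 0, ex = pmin(t, 8),
                    ev = as.integer(t <= 8))
    f <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
    ph_test(f)$p[1] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("PH test returns a value on minimal input", {
  d <- data.frame(x = c(1, 0, 1, 0), en = 0, ex = c(1, 2, 3, 4),
                  ev = c(1, 1, 0, 0))
  f <- fit_cox(~ x, d, entry = "en", exit = "ex", event = "ev")
  out <- ph_test(f)
  expect_true(is.finite(out$p[1]))
})
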