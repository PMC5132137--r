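test_that("saturated 2x2 logistic reproduces the closed-form odds ratio", {
  ## cases: 20 exposed / 10 unexposed; controls: 10 exposed / 20 unexposed
  d <- data.frame(
    y = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
    x = rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  )
  f <- fit_logistic(y ~ x, d)
  expect_equal(unname(exp(coef(f)["x"])), 4.0, tolerance = 1e-6)
  ## CI bounds on the OR scale are exp of the log-scale bounds exactly
  i <- match("x", f$table$term)
  expect_identical(f$table$or_low[i],
                   exp(f$table$estimate[i] - 1.96 * f$table$se[i]))
})

test_that("logistic MLE matches the likelihood-grid oracle to 4 decimals", {
  set.seed(51)
  ## 6-observation dataset, two parameters
  d6 <- data.frame(y = c(1, 0, 1, 1, 0, 0), x = c(2, 1, 1.5, 0.5, -1, 0.2))
  f6 <- fit_logistic(y ~ x, d6)
  X6 <- cbind(1, d6$x)
  expect_equal(unname(coef(f6)), oracle_logistic_grid(X6, d6$y),
               tolerance = 1e-4)
  ## three-parameter problem
  n <- 40
  d <- data.frame(x = rnorm(n), z = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$x - 0.5 * d$z))
  f <- fit_logistic(y ~ x + z, d)
  X <- cbind(1, d$x, d$z)
  expect_equal(unname(coef(f)), oracle_logistic_grid(X, d$y),
               tolerance = 1e-4)
})

test_that("null covariates give odds ratios near 1 at large n", {
  set.seed(52)
  n <- 20000
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, 0.3)
  f <- fit_logistic(y ~ x, d)
  expect_equal(f$table$or[match("x", f$table$term)], 1.0, tolerance = 0.05)
})

test_that("degenerate inputs raise informative errors", {
  d <- data.frame(y = rep(1, 20), x = rnorm(20))
  expect_error(fit_logistic(y ~ x, d), "constant")
  ## complete separation names the offending term
  ds <- data.frame(y = rep(c(0, 1), each = 10),
                   x = c(rnorm(10, -3), rnorm(10, 3)))
  expect_error(fit_logistic(y ~ x, ds), "separation.*'x'")
})

test_that("aliased columns are dropped leaving estimates unchanged", {
  set.seed(53)
  n <- 500
  d <- data.frame(x = rnorm(n), s = factor(rep(c("a", "b"), n / 2)))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x))
  d$s_copy <- as.numeric(d$s == "b")  # aliased with the factor dummy
  f0 <- fit_logistic(y ~ x + s, d)
  f1 <- fit_logistic(y ~ x + s + s_copy, d)
  expect_identical(f1$dropped, "s_copy")
  expect_equal(coef(f1), coef(f0))
})

test_that("clustered sandwich reduces to HC0 times G/(G-1) with singleton clusters", {
  set.seed(54)
  n <- 300
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.4 * d$x))
  f <- fit_logistic(y ~ x, d)
  V_cl <- cluster_robust_cov(f, seq_len(n))
  ## HC0 by hand from the stored scores
  U <- f$score_rows
  hc0 <- f$bread %*% crossprod(U) %*% f$bread
  expect_equal(unname(V_cl), unname(hc0 * n / (n - 1)), tolerance = 1e-10)
})

test_that("duplicating the data into two identical clusters keeps the estimate", {
  set.seed(55)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.3 * d$x))
  d2 <- rbind(d, d)
  d2$cl <- rep(c("a", "b"), each = n)
  f1 <- fit_logistic(y ~ x, d)
  f2 <- fit_logistic(y ~ x, d2, cluster = "cl")
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
})

test_that("robust SE tracks model SE under correct specification", {
  set.seed(56)
  n <- 20000
  d <- data.frame(x = rnorm(n), cl = sample(20, n, TRUE))
  d$y <- rbinom(n, 1, plogis(-0.2 + 0.3 * d$x))
  f <- fit_logistic(y ~ x, d, cluster = "cl")
  i <- match("x", names(coef(f)))
  expect_equal(unname(sqrt(diag(f$vcov_robust))[i] /
                        sqrt(diag(f$vcov_model))[i]),
               1, tolerance = 0.1)
  expect_error(cluster_robust_cov(f, rep(1, n)), "one cluster")
})

test_that("logistic fit agrees with glm on an adjusted model", {
  set.seed(57)
  n <- 3000
  d <- data.frame(x = rnorm(n), z = rnorm(n),
                  s = factor(sample(letters[1:4], n, TRUE)))
  d$y <- rbinom(n, 1, plogis(-0.4 + 0.2 * d$x + 0.1 * d$z))
  f <- fit_logistic(y ~ x + z + s, d)
  g <- stats::glm(y ~ x + z + s, binomial, d)
  expect_equal(coef(f), coef(g), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(f$vcov_model))),
               unname(summary(g)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
})

test_that("noiseless linear outcome is recovered with zero robust SE", {
  d <- data.frame(grs = runif(50, 0, 4))
  d$cups <- 1.5 + 0.10 * d$grs
  f <- fit_linear_robust(cups ~ grs, d)
  i <- match("grs", f$table$term)
  expect_equal(f$table$estimate[i], 0.10, tolerance = 1e-12)
  expect_lt(f$table$se[i], 1e-10)
  expect_error(fit_linear_robust(cups ~ grs, d[1:2, ]), "observations")
})

test_that("permuting the outcome against the GRS gives calibrated nulls", {
  set.seed(58)
  n <- 400
  g <- runif(n, 0, 4)
  cups <- 1.5 + 0.10 * g + rgamma(n, 2, scale = 0.75)
  pvals <- replicate(200, {
    d <- data.frame(g = g, cups = sample(cups))
    f <- fit_linear_robust(cups ~ g, d)
    f$table$p[match("g", f$table$term)]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("HC1 linear SEs match the sandwich computed by hand", {
  set.seed(59)
  n <- 150
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n) * (1 + abs(d$x))  # heteroscedastic
  f <- fit_linear_robust(y ~ x, d)
  X <- cbind(1, d$x)
  e <- d$y - X %*% solve(crossprod(X), crossprod(X, d$y))
  bread <- solve(crossprod(X))
  V <- bread %*% crossprod(X * drop(e)) %*% bread * n / (n - 2)
  expect_equal(unname(f$se), unname(sqrt(diag(V))), tolerance = 1e-10)
})

test_that("interaction test is calibrated under equal stratum effects", {
  set.seed(60)
  pvals <- replicate(60, {
    n <- 1200
    d <- data.frame(g = runif(n, 0, 4),
                    smoking = sample(c("ever", "never"), n, TRUE))
    d$y <- rbinom(n, 1, plogis(-0.5 + 0.1 * d$g))
    subgroup_interaction(y ~ g, d, "smoking", "g")$interaction_p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.07)
})

test_that("a real effect difference between strata is detected", {
  set.seed(61)
  hits <- replicate(20, {
    n <- 8000
    d <- data.frame(g = runif(n, 0, 4),
                    smoking = rep(c("ever", "never"), each = n / 2))
    b <- ifelse(d$smoking == "ever", log(1.5), 0)
    d$y <- rbinom(n, 1, plogis(-0.5 + b * d$g))
    subgroup_interaction(y ~ g, d, "smoking", "g")$interaction_p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("a single-class stratum is skipped with a warning", {
  d <- data.frame(g = runif(60, 0, 4),
                  smoking = rep(c("ever", "never"), each = 30))
  d$y <- ifelse(d$smoking == "never", 1L, rbinom(60, 1, 0.5))
  expect_warning(
    out <- subgroup_interaction(y ~ g, d, "smoking", "g"),
    "skipped|constant")
  expect_null(out$fits$never)
  expect_false(is.null(out$fits$ever))
})
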