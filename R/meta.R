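#' Per-study estimates container
#'
#' Convenience constructor validating a set of study estimates for
#' meta-analysis.
#'
#' @param estimate Numeric effect estimates (log OR, log HR or cups/day).
#' @param se Standard errors (> 0).
#' @param study Study labels.
#' @param n Optional per-study sample sizes.
#' @return A data.frame of class `study_estimates`.
#' @export
study_estimates <- function(estimate, se, study = NULL, n = NULL) {
  k <- length(estimate)
  stopifnot(length(se) == k)
  if (any(!is.finite(se)) || any(se <= 0)) stop("all SEs must be positive")
  if (is.null(study)) study <- paste0("study", seq_len(k))
  d <- data.frame(study = study, estimate = estimate, se = se,
                  stringsAsFactors = FALSE)
  if (!is.null(n)) d$n <- n
  class(d) <- c("study_estimates", "data.frame")
  d
}

meta_result <- function(model, est, se, Q, tau2, i2, k, weights, studies) {
  structure(
    list(model = model, estimate = est, se = se,
         ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
         Q = Q, tau2 = tau2, i2 = i2, k = k,
         weights = weights, studies = studies),
    class = "meta_result"
  )
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools study estimates with weights `1/se^2`; the pooled standard error
#' is `(sum of weights)^(-1/2)`. Heterogeneity (Cochran's Q, I-squared)
#' is reported alongside.
#'
#' @param estimates A [study_estimates()] data.frame (or anything with
#'   `estimate` and `se` columns).
#' @return A `meta_result` with the pooled estimate, SE, 95% CI, `Q`,
#'   `tau2` (always 0 for the fixed-effect model), `i2` (%), and weights.
#' @export
fixed_effect <- function(estimates) {
  b <- estimates$estimate
  se <- estimates$se
  k <- length(b)
  if (k < 1L) stop("need at least one study")
  if (any(se <= 0)) stop("all SEs must be positive")
  w <- 1 / se^2
  est <- sum(w * b) / sum(w)
  het <- het_stats(b, se)
  meta_result("fixed", est, sqrt(1 / sum(w)), het$Q, 0, het$i2, k,
              w / sum(w), estimates$study)
}

het_stats <- function(b, se) {
  k <- length(b)
  if (k < 2L) return(list(Q = NA_real_, i2 = NA_real_))
  w <- 1 / se^2
  bfe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bfe)^2)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(Q = Q, i2 = i2)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' inverse-variance weights `w = 1/se^2`; the pooled estimate and SE are
#' recomputed with weights `1/(se^2 + tau2)`. With homogeneous studies
#' (`tau2 = 0`) the result equals the fixed-effect pool.
#'
#' @inheritParams fixed_effect
#' @return A `meta_result` with `Q`, `tau2`, `i2` and the random-effects
#'   pooled estimate.
#' @export
random_effects_dl <- function(estimates) {
  b <- estimates$estimate
  se <- estimates$se
  k <- length(b)
  if (k < 2L) stop("need at least two studies; use fixed_effect() for k = 1")
  if (any(se <= 0)) stop("all SEs must be positive")
  w <- 1 / se^2
  het <- het_stats(b, se)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - (k - 1)) / denom)
  wr <- 1 / (se^2 + tau2)
  est <- sum(wr * b) / sum(wr)
  meta_result("random", est, sqrt(1 / sum(wr)), het$Q, tau2, het$i2, k,
              wr / sum(wr), estimates$study)
}

#' Between-study heterogeneity statistics
#'
#' Cochran's `Q` and `I2 = max(0, (Q - (k-1))/Q) * 100` (floored at 0).
#' Undefined (reported as `NA`) for fewer than two studies.
#'
#' @inheritParams fixed_effect
#' @return List with `Q` and `i2`.
#' @export
heterogeneity <- function(estimates) {
  het_stats(estimates$estimate, estimates$se)
}

#' @method print meta_result
#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d studies\n",
              if (x$model == "fixed") "Fixed" else "Random", x$k))
  cat(sprintf("  pooled estimate %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$estimate, x$se, x$ci_low, x$ci_high))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q = %.3f on %d df, tau^2 = %.4f, I^2 = %.1f%%\n",
                x$Q, x$k - 1, x$tau2, x$i2))
  }
  invisible(x)
}

#' Forest plot of a meta-analysis
#'
#' Base-graphics forest plot: per-study estimates with 95% CIs sized by
#' weight, plus the pooled diamond.
#'
#' @param x A `meta_result`; the per-study inputs must be supplied.
#' @param estimates The [study_estimates()] that were pooled.
#' @param exponentiate Plot on the ratio (exp) scale.
#' @param xlab Axis label.
#' @param ... Ignored.
#' @return Invisibly, the plotted coordinates.
#' @method plot meta_result
#' @export
plot.meta_result <- function(x, estimates, exponentiate = FALSE,
                             xlab = if (exponentiate) "ratio" else "estimate",
                             ...) {
  b <- estimates$estimate
  lo <- b - 1.96 * estimates$se
  hi <- b + 1.96 * estimates$se
  tr <- if (exponentiate) exp else identity
  k <- length(b)
  ys <- rev(seq_len(k))
  graphics::plot(tr(c(lo, hi, x$ci_low, x$ci_high)),
                 rep(c(ys, 0, 0), 2)[seq_len(2 * k + 2)],
                 type = "n", yaxt = "n", ylab = "", xlab = xlab,
                 ylim = c(-1, k + 1), log = if (exponentiate) "x" else "")
  graphics::segments(tr(lo), ys, tr(hi), ys)
  graphics::points(tr(b), ys, pch = 15,
                   cex = 0.6 + 1.6 * x$weights / max(x$weights))
  graphics::axis(2, at = ys, labels = estimates$study, las = 1,
                 cex.axis = 0.7)
  graphics::segments(tr(x$ci_low), 0, tr(x$ci_high), 0, lwd = 2)
  graphics::points(tr(x$estimate), 0, pch = 18, cex = 1.6)
  graphics::abline(v = tr(0), lty = 3)
  invisible(list(y = ys))
}
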