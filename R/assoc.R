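## Association models: logistic regression by IRLS and OLS with
## heteroscedasticity/cluster-robust sandwich variance, written directly on
## the score equations so that the clustered sandwich reuses the same
## building blocks for every model class (including the Cox fits).

## Build X, y and cluster ids from a formula, dropping incomplete rows and
## aliased columns (by pivoted QR).
build_design <- function(formula, data, cluster = NULL, need_response = TRUE) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- if (need_response) stats::model.response(mf) else NULL
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  cl <- NULL
  if (!is.null(cluster)) {
    cl <- if (is.character(cluster) && length(cluster) == 1L) {
      data[[cluster]]
    } else {
      cluster
    }
    if (length(cl) != nrow(data)) stop("cluster must align with data rows")
  }
  keep_row <- stats::complete.cases(X) &
    (if (need_response) !is.na(y) else TRUE) &
    (if (is.null(cl)) TRUE else !is.na(cl))
  X <- X[keep_row, , drop = FALSE]
  if (need_response) y <- y[keep_row]
  if (!is.null(cl)) cl <- cl[keep_row]

  dropped <- character(0)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_col <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep_col]
    X <- X[, keep_col, drop = FALSE]
  }
  list(X = X, y = y, cluster = cl, dropped = dropped, rows = which(keep_row))
}

mrfit_table <- function(beta, se, scale) {
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), z = unname(z), p = unname(p),
                    stringsAsFactors = FALSE)
  if (scale %in% c("logit", "log-hazard")) {
    lab <- if (scale == "logit") "or" else "hr"
    tab[[lab]] <- exp(tab$estimate)
    tab[[paste0(lab, "_low")]] <- exp(tab$estimate - 1.96 * tab$se)
    tab[[paste0(lab, "_high")]] <- exp(tab$estimate + 1.96 * tab$se)
  } else {
    tab$ci_low <- tab$estimate - 1.96 * tab$se
    tab$ci_high <- tab$estimate + 1.96 * tab$se
  }
  rownames(tab) <- NULL
  tab
}

new_mrfit <- function(subclass, coefficients, bread, meat_rows, scale,
                      n, cluster = NULL, dropped = character(0), ...) {
  vcov_model <- bread
  fit <- list(coefficients = coefficients, bread = bread,
              vcov_model = vcov_model, vcov_robust = NULL,
              score_rows = meat_rows, scale = scale, n = n,
              cluster = cluster, dropped = dropped, ...)
  class(fit) <- c(subclass, "mrfit")
  if (!is.null(cluster)) {
    fit$vcov_robust <- cluster_robust_cov(fit, cluster)
  }
  se <- sqrt(diag(if (is.null(fit$vcov_robust)) fit$vcov_model
                  else fit$vcov_robust))
  fit$se <- se
  fit$table <- mrfit_table(coefficients, se, scale)
  fit
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression written on the score equations,
#' with Wald inference. Convergence is declared when the largest absolute
#' score component falls below `tol_score` or the relative change in
#' log-likelihood falls below `tol_ll` (at most `maxit` iterations).
#' Aliased design columns are dropped automatically; a diverging
#' coefficient raises a complete-separation error naming the term. When
#' `cluster` is supplied the reported standard errors are cluster-robust
#' (see [cluster_robust_cov()]); otherwise they are model-based.
#'
#' @param formula Model formula, e.g. `case ~ grs + PC1 + ... + study`.
#' @param data Data frame.
#' @param cluster Optional cluster labels (column name or vector), e.g.
#'   study, for sandwich standard errors.
#' @param tol_score,tol_ll,maxit Convergence controls.
#' @return An object of class `c("mr_logit", "mrfit")` with
#'   `coefficients`, model-based and robust covariance, a Wald `table`
#'   with odds ratios and 95% CIs, `n`, `converged` and `iterations`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
#' fit_logistic(y ~ x, d)
#' @export
fit_logistic <- function(formula, data, cluster = NULL,
                         tol_score = 1e-8, tol_ll = 1e-10, maxit = 50L) {
  des <- build_design(formula, data, cluster)
  X <- des$X
  y <- as.numeric(des$y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("outcome is constant; cannot fit")

  beta <- numeric(ncol(X))
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    score <- drop(crossprod(X, y - pr))
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(X * w, X)
    ll_new <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                         stats::plogis(-eta, log.p = TRUE)))
    if (max(abs(score)) < tol_score ||
        (it > 1L && abs(ll_new - ll) < tol_ll * (abs(ll_new) + tol_ll))) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("information matrix is singular; check for aliased covariates")
    })
    ## step-halving keeps the likelihood ascending
    half <- 0L
    repeat {
      cand <- beta + step
      eta_c <- drop(X %*% cand)
      ll_c <- sum(ifelse(y == 1, stats::plogis(eta_c, log.p = TRUE),
                         stats::plogis(-eta_c, log.p = TRUE)))
      if (ll_c >= ll_new - 1e-12 || half >= 20L) break
      step <- step / 2
      half <- half + 1L
    }
    beta <- beta + step
    ll <- ll_new
    ## a diverging coefficient with a near-perfect likelihood marks
    ## (quasi-)complete separation
    if (any(abs(beta) > 15) && ll_new > -1e-5 * length(y)) {
      bad <- colnames(X)[which.max(abs(beta))]
      stop("complete (or quasi-complete) separation detected: coefficient ",
           "for term '", bad, "' is diverging")
    }
    if (any(abs(beta) > 30)) {
      bad <- colnames(X)[which.max(abs(beta))]
      stop("complete (or quasi-complete) separation detected: coefficient ",
           "for term '", bad, "' is diverging")
    }
  }
  eta <- drop(X %*% beta)
  pr <- stats::plogis(eta)
  w <- pmax(pr * (1 - pr), 1e-12)
  info <- crossprod(X * w, X)
  bread <- solve(info)
  names(beta) <- colnames(X)
  new_mrfit("mr_logit", beta, bread, meat_rows = X * (y - pr),
            scale = "logit", n = nrow(X), cluster = des$cluster,
            dropped = des$dropped, converged = converged, iterations = iter,
            loglik = ll, fitted = pr, y = y, X = X,
            call = match.call())
}

#' Cluster-robust sandwich covariance
#'
#' Computes the sandwich `A^{-1} B A^{-1}` where `A` is the observed
#' information (or `X'X` for least squares) and `B` is the sum over
#' clusters of outer products of within-cluster score sums, scaled by the
#' small-sample factor `G/(G-1)` for `G` clusters. With one individual per
#' cluster this reduces to the HC0-type heteroscedasticity-robust sandwich
#' times `G/(G-1)`.
#'
#' @param fit An `mrfit` object (logistic, linear or Cox).
#' @param cluster Cluster labels aligned with the rows used in the fit.
#' @return Covariance matrix on the coefficient scale.
#' @export
cluster_robust_cov <- function(fit, cluster) {
  stopifnot(inherits(fit, "mrfit"))
  U <- fit$score_rows
  if (length(cluster) != nrow(U)) {
    stop("cluster labels must align with the ", nrow(U), " rows used in the fit")
  }
  G <- length(unique(cluster))
  if (G < 2L) {
    stop("only one cluster: use the unclustered robust (HC) variance instead")
  }
  Usum <- rowsum(U, cluster)
  meat <- crossprod(as.matrix(Usum)) * G / (G - 1)
  V <- fit$bread %*% meat %*% fit$bread
  dimnames(V) <- dimnames(fit$bread)
  (V + t(V)) / 2
}

#' Linear regression with robust standard errors
#'
#' Ordinary least squares with heteroscedasticity-robust (HC1) standard
#' errors, or cluster-robust errors when `cluster` is given. Used for the
#' first-stage regressions of cups/day on the genetic risk score, whose
#' residuals are right-skewed.
#'
#' @inheritParams fit_logistic
#' @return An object of class `c("mr_linear", "mrfit")`.
#' @export
fit_linear_robust <- function(formula, data, cluster = NULL) {
  des <- build_design(formula, data, cluster)
  X <- des$X
  y <- as.numeric(des$y)
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop("need more observations (", n, ") than parameters (", k, ")")
  XtX <- crossprod(X)
  bread <- solve(XtX)
  beta <- drop(bread %*% crossprod(X, y))
  names(beta) <- colnames(X)
  e <- y - drop(X %*% beta)
  fit <- new_mrfit("mr_linear", beta, bread, meat_rows = X * e,
                   scale = "identity", n = n, cluster = des$cluster,
                   dropped = des$dropped, converged = TRUE, iterations = 1L,
                   residuals = e, y = y, X = X, call = match.call())
  fit$vcov_model <- bread * sum(e^2) / (n - k)
  if (is.null(des$cluster)) {
    ## HC1: HC0 scaled by n/(n-k)
    meat <- crossprod(X * e)
    V <- bread %*% meat %*% bread * n / (n - k)
    fit$vcov_robust <- (V + t(V)) / 2
    fit$se <- sqrt(diag(fit$vcov_robust))
    fit$table <- mrfit_table(fit$coefficients, fit$se, "identity")
  }
  fit
}

#' Stratified fits with an interaction test
#'
#' Fits the model separately within each level of a binary stratum (e.g.
#' ever vs never smoking) and a pooled model augmented with an
#' exposure-by-stratum product term, reporting the product-term Wald p
#' value. A stratum whose outcome has a single class is skipped with a
#' warning.
#'
#' @param formula Base model formula including the exposure term.
#' @param data Data frame.
#' @param stratum Name of the stratum column (a factor or character with
#'   two levels; missing values are dropped).
#' @param exposure Name of the exposure term whose effect may differ
#'   between strata.
#' @param cluster Optional cluster labels column name.
#' @param fitter Fitting function (default [fit_logistic()]).
#' @return List with `fits` (per-stratum `mrfit`s), `pooled` (the
#'   interaction model) and `interaction_p`.
#' @export
subgroup_interaction <- function(formula, data, stratum, exposure,
                                 cluster = NULL, fitter = fit_logistic) {
  s <- data[[stratum]]
  keep <- !is.na(s)
  data <- data[keep, , drop = FALSE]
  s <- factor(data[[stratum]])
  levs <- levels(s)
  if (length(levs) < 2L) {
    warning("stratum '", stratum, "' has a single non-missing level: '",
            levs, "'; returning that stratum only")
  }
  fits <- list()
  for (lv in levs) {
    sub <- data[s == lv, , drop = FALSE]
    fits[[lv]] <- tryCatch(
      fitter(formula, sub, cluster = cluster),
      error = function(e) {
        warning("stratum '", lv, "' skipped: ", conditionMessage(e))
        NULL
      }
    )
  }
  pooled <- NULL
  interaction_p <- NA_real_
  if (length(levs) >= 2L) {
    f2 <- stats::update(
      stats::as.formula(formula),
      stats::as.formula(paste(". ~ . +", stratum, "+", exposure, ":", stratum))
    )
    pooled <- tryCatch(fitter(f2, data, cluster = cluster),
                       error = function(e) {
                         warning("pooled interaction model failed: ",
                                 conditionMessage(e))
                         NULL
                       })
    if (!is.null(pooled)) {
      tt <- pooled$table
      hit <- grepl(":", tt$term) & grepl(exposure, tt$term, fixed = TRUE)
      if (any(hit)) interaction_p <- tt$p[which(hit)[1L]]
    }
  }
  list(fits = fits, pooled = pooled, interaction_p = interaction_p)
}
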