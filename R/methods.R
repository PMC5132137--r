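#' @method print mrfit
#' @export
print.mrfit <- function(x, ...) {
  kind <- switch(class(x)[1],
                 mr_logit = "Logistic regression (IRLS)",
                 mr_linear = "Linear regression (OLS, robust SE)",
                 mr_cox = "Cox proportional hazards (delayed entry, Efron ties)",
                 "Model fit")
  cat(kind, "\n")
  cat(sprintf("  n = %d%s%s\n", x$n,
              if (!is.null(x$n_events)) sprintf(", events = %d", x$n_events)
              else "",
              if (!is.null(x$cluster))
                sprintf(", clusters = %d", length(unique(x$cluster)))
              else ""))
  if (length(x$dropped)) {
    cat("  dropped aliased terms:", paste(x$dropped, collapse = ", "), "\n")
  }
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method summary mrfit
#' @export
summary.mrfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mrfit")
}

#' @method print summary.mrfit
#' @export
print.summary.mrfit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$converged)) {
    cat(sprintf("converged: %s in %d iterations\n",
                f$converged, f$iterations))
  }
  if (!is.null(f$person_years)) {
    cat(sprintf("person-years: %.1f (%.1f thousands)\n",
                f$person_years, f$person_years / 1000))
  }
  se_kind <- if (!is.null(f$cluster)) "cluster-robust (sandwich)"
  else if (inherits(f, "mr_linear")) "heteroscedasticity-robust (HC1)"
  else "model-based"
  cat("standard errors:", se_kind, "\n")
  invisible(x)
}

#' @method coef mrfit
#' @export
coef.mrfit <- function(object, ...) object$coefficients

#' @method vcov mrfit
#' @export
vcov.mrfit <- function(object, robust = !is.null(object$vcov_robust), ...) {
  if (robust && !is.null(object$vcov_robust)) object$vcov_robust
  else object$vcov_model
}

#' @method confint mrfit
#' @export
confint.mrfit <- function(object, parm, level = 0.95, exponentiate = FALSE,
                          ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- object$coefficients
  se <- object$se
  ci <- cbind(b - z * se, b + z * se)
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  if (exponentiate) exp(ci) else ci
}

#' @method predict mr_logit
#' @export
predict.mr_logit <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(
      stats::delete.response(stats::terms(object$call$formula)), newdata)
    drop(X[, names(object$coefficients), drop = FALSE] %*%
           object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @method residuals mr_logit
#' @export
residuals.mr_logit <- function(object, ...) object$y - object$fitted

#' @method residuals mr_linear
#' @export
residuals.mr_linear <- function(object, ...) object$residuals

#' @method residuals mr_cox
#' @export
residuals.mr_cox <- function(object,
                             type = c("score", "schoenfeld"), ...) {
  type <- match.arg(type)
  if (type == "score") object$score_rows else object$schoenfeld
}
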