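## Cox proportional-hazards regression on the age timescale with delayed
## entry (left truncation). The partial likelihood is maximized by Newton
## iterations written directly on the risk-set sums; risk sets at an event
## age t are {entry < t <= exit}, evaluated through two prefix-sum sweeps
## (one over exit ages, one over entry ages) so each iteration is O(n d^2)
## without forming any risk set explicitly. Tied event ages are handled
## with the Efron correction.

col_cumsum <- function(B) {
  for (j in seq_len(ncol(B))) B[, j] <- cumsum(B[, j])
  B
}

## Prefix-sum sweeper: returns a closure evaluating, for any n x p matrix
## M, the running sums of M in the order `ord` at the row counts `pos`
## (0 allowed): out[k, ] = sum of the first pos[k] rows of M[ord, ].
make_sweeper <- function(ord, pos) {
  np <- length(pos)
  mx <- max(pos)
  nz <- which(pos > 0L)
  if (mx == 0L) {
    return(function(M) matrix(0, np, ncol(M)))
  }
  ord_keep <- ord[seq_len(mx)]
  pos_nz <- pos[nz]
  function(M) {
    cs <- col_cumsum(M[ord_keep, , drop = FALSE])
    out <- matrix(0, np, ncol(M))
    out[nz, ] <- cs[pos_nz, , drop = FALSE]
    out
  }
}

cox_engine <- function(X, entry, exit, event, maxit = 30L, tol_score = 1e-8) {
  n <- nrow(X)
  d <- ncol(X)
  ## center covariates for numerical stability (beta is unaffected)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)

  ord_exit <- order(exit)
  ord_entry <- order(entry)
  exitS <- exit[ord_exit]
  entryS <- entry[ord_entry]

  death <- which(event == 1L)
  if (length(death) == 0L) stop("no events in the data; cannot fit")
  ut <- sort(unique(exit[death]))
  m <- length(ut)
  grp <- match(exit[death], ut)
  dcnt <- tabulate(grp, m)
  tied <- which(dcnt > 1L)
  untied <- which(dcnt == 1L)

  cnt_exit <- findInterval(ut, exitS, left.open = TRUE)   # exit  < t
  cnt_entry <- findInterval(ut, entryS, left.open = TRUE) # entry < t
  sweep_exit <- make_sweeper(ord_exit, cnt_exit)
  sweep_entry <- make_sweeper(ord_entry, cnt_entry)

  sumXd <- colSums(Xc[death, , drop = FALSE])
  ## per-subject risk-window boundaries on the event-time grid, used both
  ## for the folded information sums and for the score residuals
  a_idx <- findInterval(exit, ut)   # events with t <= exit
  b_idx <- findInterval(entry, ut)  # events with t <= entry

  beta <- numeric(d)
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  final <- NULL

  eval_at <- function(beta, loglik_only = FALSE) {
    w <- exp(drop(Xc %*% beta))
    S0 <- drop(sweep_entry(cbind(w)) - sweep_exit(cbind(w)))
    s0D <- drop(rowsum(w[death], grp))
    if (loglik_only) {
      loglik <- sum(log(w[death]))
      if (length(untied)) loglik <- loglik - sum(log(S0[untied]))
      for (k in tied) {
        dk <- dcnt[k]
        loglik <- loglik -
          sum(log(S0[k] - (seq_len(dk) - 1) / dk * s0D[k]))
      }
      return(list(loglik = loglik))
    }
    wX <- Xc * w
    S1 <- sweep_entry(wX) - sweep_exit(wX)

    ## Fold the risk-set second-moment sums over events into per-subject
    ## weights: sum_k S2_k/S0_k = sum_i w_i A_i x_i x_i' with A_i the
    ## integral of the per-event weights over subject i's risk window.
    ## For Efron-tied times the per-event weight is sum_j 1/(S0 - f_j s0D)
    ## and the death-set members get an explicit correction.
    ev_wt <- 1 / S0
    c2 <- numeric(m)  # sum_j f_j / (S0 - f_j s0D); 0 at untied times
    loglik <- sum(log(w[death]))
    if (length(untied)) loglik <- loglik - sum(log(S0[untied]))
    for (k in tied) {
      dk <- dcnt[k]
      f <- (seq_len(dk) - 1) / dk
      den <- S0[k] - f * s0D[k]
      ev_wt[k] <- sum(1 / den)
      c2[k] <- sum(f / den)
      loglik <- loglik - sum(log(den))
    }
    Hstar <- c(0, cumsum(ev_wt))
    A <- Hstar[a_idx + 1L] - Hstar[b_idx + 1L]
    wA <- w * A
    score_risk <- colSums(Xc * wA)
    term1 <- crossprod(Xc * wA, Xc)

    outer_sum <- matrix(0, d, d)
    if (length(untied)) {
      r1 <- S1[untied, , drop = FALSE] / S0[untied]
      outer_sum <- outer_sum + crossprod(r1)
    }
    for (k in tied) {
      dk <- dcnt[k]
      f <- (seq_len(dk) - 1) / dk
      den <- S0[k] - f * s0D[k]
      rows <- death[grp == k]
      wXD <- wX[rows, , drop = FALSE]
      s1Dk <- colSums(wXD)
      score_risk <- score_risk - c2[k] * s1Dk
      term1 <- term1 - c2[k] * crossprod(Xc[rows, , drop = FALSE] * w[rows],
                                         Xc[rows, , drop = FALSE])
      for (j in seq_len(dk)) {
        mkj <- (S1[k, ] - f[j] * s1Dk) / den[j]
        outer_sum <- outer_sum + tcrossprod(mkj)
      }
    }
    info <- term1 - outer_sum
    info <- (info + t(info)) / 2
    list(loglik = loglik, score = sumXd - score_risk, info = info,
         S0 = S0, S1 = S1, w = w)
  }

  for (it in seq_len(maxit)) {
    iter <- it
    ev <- eval_at(beta)
    if (!is.finite(ev$loglik)) stop("partial likelihood overflow; ",
                                    "check covariate scaling")
    if (max(abs(ev$score)) < tol_score) {
      converged <- TRUE
      final <- ev
      break
    }
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) {
      bad <- colnames(X)[which.min(diag(ev$info))]
      stop("covariate '", bad, "' does not vary within risk sets; ",
           "information matrix is singular")
    })
    half <- 0L
    repeat {
      cand <- beta + step
      ll_c <- eval_at(cand, loglik_only = TRUE)$loglik
      if (ll_c >= ev$loglik - 1e-10 || half >= 20L) break
      step <- step / 2
      half <- half + 1L
    }
    beta <- beta + step
    ll <- ev$loglik
    final <- ev
  }
  if (!converged) final <- eval_at(beta)

  ## Breslow baseline increments and score residuals for the sandwich
  dlam <- dcnt / final$S0
  mbar <- final$S1 / final$S0
  H <- cumsum(dlam)
  M <- col_cumsum(mbar * dlam)
  Hd <- c(0, H)
  Md <- rbind(0, M)
  dH <- Hd[a_idx + 1L] - Hd[b_idx + 1L]
  dM <- Md[a_idx + 1L, , drop = FALSE] - Md[b_idx + 1L, , drop = FALSE]
  resid <- -final$w * (Xc * dH - dM)
  ev_rows <- match(exit[death], ut)
  resid[death, ] <- resid[death, , drop = FALSE] +
    Xc[death, , drop = FALSE] - mbar[ev_rows, , drop = FALSE]

  schoenfeld <- Xc[death, , drop = FALSE] - mbar[ev_rows, , drop = FALSE]
  names(beta) <- colnames(X)
  list(beta = beta, info = final$info, loglik = final$loglik,
       converged = converged, iterations = iter, score = final$score,
       score_rows = resid, schoenfeld = schoenfeld,
       death_times = exit[death], n_events = length(death))
}

#' Cox proportional-hazards regression with delayed entry
#'
#' Fits a Cox model on the age timescale: individuals enter the risk set
#' at their age at diagnosis and leave at their age at death or last
#' follow-up, so the risk set at an event age `t` is
#' `{entry < t <= exit}`. The partial likelihood uses the Efron correction
#' for tied event ages and is maximized by Newton iterations until the
#' largest score component is below `tol_score`. Records with
#' `exit == entry` are shifted by one day (1/365.25 years) with a warning.
#' Standard errors are cluster-robust (by study) when `cluster` is given,
#' model-based otherwise.
#'
#' @param formula Right-hand-side formula of covariates, e.g.
#'   `~ grs + PC1 + ... + study`.
#' @param data Data frame.
#' @param entry,exit Entry and exit ages: column names or numeric vectors.
#' @param event Event indicator (0/1): column name or vector.
#' @param cluster Optional cluster labels (column name or vector).
#' @param tol_score,maxit Convergence controls.
#' @return An object of class `c("mr_cox", "mrfit")` with coefficients on
#'   the log-hazard scale, a Wald table with hazard ratios, `n`,
#'   `n_events` and `person_years`.
#' @export
fit_cox <- function(formula, data, entry, exit, event, cluster = NULL,
                    tol_score = 1e-8, maxit = 30L) {
  get_col <- function(v) {
    if (is.character(v) && length(v) == 1L) data[[v]] else v
  }
  en <- as.numeric(get_col(entry))
  ex <- as.numeric(get_col(exit))
  evt <- as.integer(get_col(event))
  stopifnot(length(en) == nrow(data), length(ex) == nrow(data),
            length(evt) == nrow(data))
  if (!all(evt %in% c(0L, 1L), na.rm = TRUE)) stop("event must be 0/1")

  aux <- data.frame(.entry = en, .exit = ex, .event = evt)
  des <- build_design(formula, cbind(data, aux), cluster,
                      need_response = FALSE)
  rows <- des$rows
  keep2 <- stats::complete.cases(aux[rows, ])
  X <- des$X[keep2, , drop = FALSE]
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  en <- en[rows][keep2]
  ex <- ex[rows][keep2]
  evt <- evt[rows][keep2]
  cl <- if (is.null(des$cluster)) NULL else des$cluster[keep2]
  if (any(ex < en)) stop("exit age before entry age for ",
                         sum(ex < en), " record(s)")
  same <- ex == en
  if (any(same)) {
    warning(sum(same), " record(s) with exit == entry shifted by 1/365.25 y")
    ex[same] <- ex[same] + 1 / 365.25
  }
  ## drop aliased columns once more after intercept removal
  qrX <- qr(X)
  dropped <- des$dropped
  if (qrX$rank < ncol(X)) {
    keep_col <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- c(dropped, colnames(X)[-keep_col])
    X <- X[, keep_col, drop = FALSE]
  }
  eng <- cox_engine(X, en, ex, evt, maxit = maxit, tol_score = tol_score)
  bread <- solve(eng$info)
  dimnames(bread) <- list(names(eng$beta), names(eng$beta))
  fit <- new_mrfit("mr_cox", eng$beta, bread, meat_rows = eng$score_rows,
                   scale = "log-hazard", n = nrow(X), cluster = cl,
                   dropped = dropped, converged = eng$converged,
                   iterations = eng$iterations, loglik = eng$loglik,
                   n_events = eng$n_events,
                   person_years = sum(ex - en),
                   schoenfeld = eng$schoenfeld,
                   death_times = eng$death_times,
                   info = eng$info, call = match.call())
  fit
}

#' Proportional-hazards diagnostic
#'
#' Score-type test of the proportional-hazards assumption based on
#' Schoenfeld residuals regressed against (a transform of) event age, in
#' the manner of Grambsch and Therneau: under proportional hazards the
#' residuals have no trend in time. Returns per-covariate and global p
#' values.
#'
#' @param fit An `mr_cox` fit.
#' @param transform Time transform applied to event ages before
#'   correlation: `"identity"`, `"rank"` or `"km"`-like log.
#' @return A data.frame with one row per covariate plus a `GLOBAL` row:
#'   `chisq`, `df`, `p`.
#' @export
ph_test <- function(fit, transform = c("identity", "rank", "log")) {
  stopifnot(inherits(fit, "mr_cox"))
  transform <- match.arg(transform)
  S <- fit$schoenfeld
  d <- ncol(S)
  ne <- nrow(S)
  if (ne < 2L) stop("need at least 2 events for the PH test")
  g <- switch(transform,
              identity = fit$death_times,
              rank = rank(fit$death_times),
              log = log(fit$death_times))
  gc <- g - mean(g)
  u <- drop(crossprod(S, gc))
  denom <- sum(gc^2) / ne
  chisq_each <- u^2 / (denom * diag(fit$info))
  p_each <- stats::pchisq(chisq_each, 1, lower.tail = FALSE)
  if (ne <= d) {
    warning("fewer events than covariates: global PH test skipped")
    glob <- c(NA_real_, NA_real_, NA_real_)
  } else {
    cg <- drop(u %*% solve(fit$info, u)) / denom
    glob <- c(cg, d, stats::pchisq(cg, d, lower.tail = FALSE))
  }
  out <- data.frame(
    term = c(names(fit$coefficients), "GLOBAL"),
    chisq = c(chisq_each, glob[1]),
    df = c(rep(1, d), glob[2]),
    p = c(p_each, glob[3]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
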