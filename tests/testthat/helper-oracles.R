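## Independent oracles used to validate the package's own estimators.
## These deliberately use brute force / enumeration, never the package's
## fitting code.

## Bernoulli log-likelihood maximized by iterative grid refinement
## (coordinate-free: full factorial grid, shrunk around the argmax).
oracle_logistic_grid <- function(X, y, lower = -6, upper = 6,
                                 rounds = 14, pts = 9) {
  d <- ncol(X)
  lo <- rep(lower, d)
  hi <- rep(upper, d)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  best <- rep(0, d)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1L, ll)
    best <- cand[which.max(vals), ]
    span <- (hi - lo) / (pts - 1)
    lo <- best - span
    hi <- best + span
  }
  unname(best)
}

## Exact Hardy-Weinberg test (conditional enumeration of heterozygote
## counts given the allele counts), two-sided by probability ordering.
oracle_hwe_exact <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]
  rare <- min(nA, 2 * n - nA)
  obs_het <- counts[2]
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    nhom_r <- (rare - h) / 2
    nhom_c <- n - h - nhom_r
    h * log(2) + lfactorial(n) - lfactorial(nhom_r) - lfactorial(h) -
      lfactorial(nhom_c) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(obs_het, hets)] * (1 + 1e-9)])
}

## Exhaustive Efron partial likelihood for a single covariate on a handful
## of subjects, maximized by golden-section search.
oracle_cox_loglik <- function(beta, x, entry, exit, event) {
  ut <- sort(unique(exit[event == 1]))
  ll <- 0
  for (t in ut) {
    D <- which(event == 1 & exit == t)
    R <- which(entry < t & exit >= t)
    dk <- length(D)
    wR <- sum(exp(beta * x[R]))
    wD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (j in seq_len(dk)) {
      ll <- ll - log(wR - (j - 1) / dk * wD)
    }
  }
  ll
}

oracle_cox_fit <- function(x, entry, exit, event) {
  stats::optimize(oracle_cox_loglik, c(-10, 10), x = x, entry = entry,
                  exit = exit, event = event,
                  maximum = TRUE, tol = 1e-10)$maximum
}

## Independent restatement of the staging rule for brute-force comparison.
oracle_stage <- function(t_tok, n_tok, m_tok) {
  toks <- c(t_tok, n_tok, m_tok)
  if (any(toks %in% c("T3", "T4", "N1", "M1"))) return("nonlocalised")
  t_ok <- t_tok %in% c("T1", "T2")
  n_ok <- n_tok %in% c("N0", "NX", "")
  m_ok <- m_tok %in% c("M0", "MX", "")
  if (t_ok && n_ok && m_ok) "localised" else NA_character_
}

## Small default simulation config for structural tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_studies = 6L, total_n = 2400L, case_fraction = 0.5,
                   seed = 99L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}
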