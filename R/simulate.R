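#' Simulate imputed allele dosages for one variant
#'
#' Draws hard genotypes `g ~ Binomial(2, freq)` and, when `r2 < 1`, blends
#' them with noise so the dosage behaves like a posterior-mean imputed
#' dosage: `d = 2*freq + r2*(g - 2*freq) + e` with
#' `e ~ N(0, r2*(1 - r2)*2*freq*(1 - freq))`, clipped to `[0, 2]`. Before
#' clipping the squared correlation between `d` and `g` is exactly `r2`;
#' clipping perturbs it only slightly. With `r2 = 1` the hard calls are
#' returned unchanged (integer-valued dosages).
#'
#' @param n Number of individuals.
#' @param freq Allele frequency of the counted allele, in (0, 1).
#' @param r2 Imputation quality in (0, 1].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return Numeric vector of dosages in `[0, 2]` with the hard genotypes in
#'   attribute `"hard"`.
#' @examples
#' d <- simulate_genotypes(1000, freq = 0.26, r2 = 0.8, seed = 1)
#' cor(d, attr(d, "hard"))^2
#' @export
simulate_genotypes <- function(n, freq, r2 = 1, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  if (freq <= 0 || freq >= 1) stop("freq must lie in (0, 1)")
  if (r2 <= 0 || r2 > 1) stop("r2 must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  g <- stats::rbinom(n, 2L, freq)
  if (r2 == 1) {
    d <- as.numeric(g)
  } else {
    vg <- 2 * freq * (1 - freq)
    d <- 2 * freq + r2 * (g - 2 * freq) +
      stats::rnorm(n, 0, sqrt(r2 * (1 - r2) * vg))
    d <- pmin(pmax(d, 0), 2)
  }
  attr(d, "hard") <- g
  d
}

## Root-find the logit intercept giving a target mean probability over the
## realized linear predictors eta.
tune_intercept <- function(eta, target, what = "case fraction") {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- f(-30)
  hi <- f(30)
  if (lo > 0 || hi < 0) {
    stop("target ", what, " ", format(target),
         " is unattainable given the configured effects")
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

study_seed <- function(master, i) {
  (abs(master) %% 1000003L) * 2048L + i
}

tnm_from_indicator <- function(nonloc) {
  ## Compose TNM token strings consistent with the staging rule:
  ## localised draws from {T1,T2}x{N0,NX}x{M0,MX}; nonlocalised is T3/T4,
  ## N1 or M1 with otherwise localised-compatible tokens.
  n <- length(nonloc)
  t_tok <- ifelse(stats::runif(n) < 0.5, "T1", "T2")
  n_tok <- ifelse(stats::runif(n) < 0.8, "N0", "NX")
  m_tok <- ifelse(stats::runif(n) < 0.8, "M0", "MX")
  kind <- stats::runif(n)
  adv_t <- nonloc & kind < 0.60
  adv_n <- nonloc & kind >= 0.60 & kind < 0.85
  adv_m <- nonloc & kind >= 0.85
  t_tok[adv_t] <- ifelse(stats::runif(sum(adv_t)) < 0.7, "T3", "T4")
  n_tok[adv_n] <- "N1"
  m_tok[adv_m] <- "M1"
  paste(t_tok, n_tok, m_tok)
}

#' Simulate a synthetic multi-study consortium cohort
#'
#' Generates a per-individual table with the causal and confounding
#' structure the downstream Mendelian randomization analysis assumes: two
#' imputed instrument dosages, a binary confounder (ever smoking) that
#' raises both coffee consumption and case odds, right-skewed coffee and
#' tea consumption driven by the genetic risk score, case status with a
#' per-study intercept tuned to the configured case fraction, stage and
#' grade indicators among cases re-expressed as TNM strings (odd-numbered
#' studies) or SEER labels (even-numbered studies) and Gleason scores, and
#' cause-specific Weibull death times from diagnosis on the age timescale
#' with administrative censoring. Principal components are pure noise
#' covariates.
#'
#' Each study uses its own RNG stream derived from the master seed, so
#' adding studies never changes earlier studies' data.
#'
#' Stored dosages count each variant's counted (ALT) allele as a VCF would;
#' for rs4410790 the coffee-increasing allele is the major (reference)
#' allele, so its stored dosage is `2 -` the increasing-allele dosage and
#' must be re-oriented with [orient_dosage()] before scoring.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with one row per individual: `sample_id`,
#'   `study`, `case`, `dos_rs4410790`, `dos_rs2472297` (counted-allele
#'   dosages), `coffee_cups`, `tea_cups`, `smoking`, `tnm`, `seer`,
#'   `gleason`, `age_diagnosis`, `vital_status`, `cause_death`, `age_exit`,
#'   `PC1`..`PC8`. Fields that only exist for cases are `NA` for controls.
#'   The configuration is attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  out <- vector("list", cfg$n_studies)
  for (i in seq_len(cfg$n_studies)) {
    set.seed(study_seed(cfg$seed, i))
    n <- cfg$study_sizes[i]
    lab <- sprintf("STUDY%02d", i)

    d_inc1 <- simulate_genotypes(n, cfg$freq_increasing[1], cfg$imputation_r2[1])
    d_inc2 <- simulate_genotypes(n, cfg$freq_increasing[2], cfg$imputation_r2[2])
    grs <- as.numeric(d_inc1) + as.numeric(d_inc2)
    u <- stats::rbinom(n, 1L, cfg$confounder_prev)

    ## beverages: only the leading coffee studies collected them
    if (i <= cfg$n_coffee_studies) {
      offset <- stats::rnorm(1, 0, cfg$study_coffee_sd)
      noise_c <- stats::rgamma(n, cfg$coffee_noise_shape,
                               scale = cfg$coffee_noise_scale)
      noise_t <- stats::rgamma(n, cfg$coffee_noise_shape,
                               scale = cfg$coffee_noise_scale)
      coffee <- pmax(0, cfg$coffee_intercept + offset +
                       cfg$coffee_share * cfg$gamma_coffee * grs +
                       cfg$coffee_share * cfg$confounder_coffee_effect * u +
                       noise_c)
      tea <- pmax(0, cfg$tea_intercept + offset +
                    (1 - cfg$coffee_share) * cfg$gamma_coffee * grs +
                    (1 - cfg$coffee_share) * cfg$confounder_coffee_effect * u +
                    noise_t)
    } else {
      coffee <- tea <- rep(NA_real_, n)
    }

    smoking <- ifelse(u == 1L, "ever", "never")
    smoking[stats::runif(n) < cfg$smoking_missing] <- NA_character_

    phi <- cfg$case_fraction[i]
    eta <- cfg$theta_reduced * grs + cfg$confounder_logor * u
    if (phi == 1) {
      case <- rep(1L, n)
    } else {
      alpha <- tune_intercept(eta, phi)
      case <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
    }
    idx <- which(case == 1L)
    ncase <- length(idx)

    tnm <- rep(NA_character_, n)
    seer <- rep(NA_character_, n)
    gleason <- rep(NA_integer_, n)
    age_dx <- rep(NA_real_, n)
    vital <- rep(NA_character_, n)
    cause <- rep(NA_character_, n)
    age_exit <- rep(NA_real_, n)

    if (ncase > 0L) {
      gc <- grs[idx]
      ## stage
      a_st <- tune_intercept(cfg$stage_logor * gc, cfg$stage_frac, "stage fraction")
      nonloc <- stats::rbinom(ncase, 1L, stats::plogis(a_st + cfg$stage_logor * gc)) == 1L
      st_missing <- stats::runif(ncase) < cfg$stage_missing
      if (i %% 2L == 1L) {
        tnm_i <- tnm_from_indicator(nonloc)
        tnm_i[st_missing] <- NA_character_
        tnm[idx] <- tnm_i
      } else {
        seer_i <- ifelse(nonloc,
                         ifelse(stats::runif(ncase) < 0.6, "regional", "distant"),
                         "local")
        seer_i[st_missing] <- NA_character_
        seer[idx] <- seer_i
      }
      ## grade
      a_gr <- tune_intercept(cfg$grade_logor * gc, cfg$grade_frac, "grade fraction")
      high <- stats::rbinom(ncase, 1L, stats::plogis(a_gr + cfg$grade_logor * gc)) == 1L
      gl <- integer(ncase)
      gl[high] <- sample(7:10, sum(high), replace = TRUE,
                         prob = c(0.55, 0.25, 0.15, 0.05))
      gl[!high] <- sample(2:6, sum(!high), replace = TRUE,
                          prob = c(0.03, 0.04, 0.13, 0.30, 0.50))
      gl[stats::runif(ncase) < cfg$grade_missing] <- NA_integer_
      gleason[idx] <- gl

      ## mortality: two latent cause-specific Weibull times, shared shape
      entry <- pmin(pmax(stats::rnorm(ncase, cfg$entry_age_mean,
                                      cfg$entry_age_sd), 40), 90)
      k <- cfg$baseline_hazard_shape
      lam <- cfg$baseline_hazard_scale
      fp <- cfg$frac_pca_deaths
      t_pca <- lam * (stats::rexp(ncase) /
                        (fp * exp(cfg$loghr_pca * gc)))^(1 / k)
      t_oth <- lam * (stats::rexp(ncase) /
                        ((1 - fp) * exp(cfg$loghr_allcause * gc)))^(1 / k)
      t_death <- pmin(t_pca, t_oth)
      dead <- t_death <= cfg$followup_years
      t_obs <- pmin(t_death, cfg$followup_years)
      cause_i <- ifelse(t_pca <= t_oth, "prostate_cancer", "other")
      cause_i[dead & stats::runif(ncase) < cfg$unknown_cause_rate] <- "unknown"
      vital_i <- ifelse(dead, "dead", "alive")
      vital_i[stats::runif(ncase) < cfg$unknown_vital_rate] <- "unknown"
      age_dx[idx] <- entry
      age_exit[idx] <- entry + pmax(t_obs, 1 / 365.25)
      vital[idx] <- vital_i
      cause[idx] <- ifelse(dead, cause_i, NA_character_)
    }

    pcs <- matrix(stats::rnorm(n * 8L), n, 8L,
                  dimnames = list(NULL, paste0("PC", 1:8)))
    df <- data.frame(
      sample_id = sprintf("S%02d_%05d", i, seq_len(n)),
      study = lab,
      case = case,
      ## stored dosages count the ALT allele: rs4410790's increasing allele
      ## is the REF (major) allele, so its stored dosage is reflected
      dos_rs4410790 = 2 - as.numeric(d_inc1),
      dos_rs2472297 = as.numeric(d_inc2),
      coffee_cups = coffee, tea_cups = tea, smoking = smoking,
      tnm = tnm, seer = seer, gleason = gleason,
      age_diagnosis = age_dx, vital_status = vital, cause_death = cause,
      age_exit = age_exit,
      stringsAsFactors = FALSE
    )
    out[[i]] <- cbind(df, pcs)
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  attr(cohort, "config") <- cfg
  cohort
}
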