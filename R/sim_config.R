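#' Configuration for the synthetic consortium generator
#'
#' Bundles every generative parameter of the synthetic multi-study
#' case-control consortium: allele frequencies of the two caffeine-intake
#' instruments, imputation quality, the first-stage effect of the genetic
#' risk score (GRS) on cups of coffee/tea, a smoking confounder that raises
#' both coffee consumption and case odds, reduced-form per-allele effects on
#' case status, stage and grade, cause-specific Weibull mortality from
#' diagnosis, and administrative censoring.
#'
#' Defaults reproduce the consortium's published marginal structure: 25
#' studies totalling 46,687 men, case fraction 0.4966, nonlocalised fraction
#' 4,850/19,758 among staged cases, high-grade fraction 9,293/18,915 among
#' graded cases, all-cause death fraction 4,081/15,555 by the end of
#' follow-up with 43% of deaths from prostate cancer. The coffee-increasing
#' allele frequencies (0.63 for rs4410790's major allele, 0.26 for
#' rs2472297's minor allele) are implementation defaults taken from European
#' reference panels, not values printed in the consortium analysis, and are
#' fully configurable.
#'
#' @param n_studies Number of studies in the consortium.
#' @param study_sizes Integer vector of per-study sample sizes (recycled /
#'   defaulted to an even split of `total_n`).
#' @param total_n Total consortium size used when `study_sizes` is `NULL`.
#' @param case_fraction Target case fraction per study; scalar or length
#'   `n_studies`. A value of exactly 1 makes a study case-only.
#' @param freq_increasing Named frequencies of the coffee-increasing allele
#'   for the two variants.
#' @param imputation_r2 Imputation quality (squared correlation between
#'   dosage and hard genotype) per variant, in (0, 1].
#' @param gamma_coffee True effect of one coffee-increasing allele on
#'   combined coffee + tea consumption, cups/day.
#' @param coffee_share Share of `gamma_coffee` (and of the confounder
#'   effect) acting on coffee rather than tea.
#' @param coffee_intercept,tea_intercept Baseline cups/day.
#' @param coffee_noise_shape,coffee_noise_scale Gamma parameters of the
#'   right-skewed residual added to each beverage.
#' @param study_coffee_sd SD of per-study offsets in baseline consumption.
#' @param n_coffee_studies Number of (leading) studies with coffee/tea data.
#' @param confounder_prev Prevalence of the binary confounder (ever
#'   smoking).
#' @param confounder_coffee_effect Cups/day added by the confounder.
#' @param confounder_logor Log-odds of case status added by the confounder.
#' @param theta_reduced Reduced-form per-allele log-odds on case status.
#' @param stage_logor Per-allele log-odds of nonlocalised (vs localised)
#'   disease among cases.
#' @param grade_logor Per-allele log-odds of high-grade (vs low-grade)
#'   disease among cases.
#' @param stage_frac,grade_frac Target marginal fractions of nonlocalised /
#'   high-grade disease among cases with non-missing stage / grade.
#' @param stage_missing,grade_missing Fraction of cases with missing stage /
#'   grade.
#' @param loghr_allcause Per-allele log hazard ratio on the non-prostate
#'   cause-specific mortality hazard.
#' @param loghr_pca Per-allele log hazard ratio on the prostate-cancer
#'   cause-specific mortality hazard.
#' @param frac_pca_deaths Baseline fraction of the total mortality hazard
#'   attributable to prostate cancer.
#' @param death_frac Target probability of death (any cause) by the end of
#'   administrative follow-up, used to calibrate the Weibull scale.
#' @param baseline_hazard_shape Weibull shape of time from diagnosis to
#'   death; > 1 gives an increasing hazard.
#' @param baseline_hazard_scale Weibull scale (years); if `NULL` it is
#'   solved from `death_frac`, `baseline_hazard_shape` and
#'   `followup_years`.
#' @param followup_years Administrative censoring horizon after diagnosis.
#' @param entry_age_mean,entry_age_sd Age at diagnosis distribution
#'   (years), truncated to 40-90.
#' @param unknown_vital_rate Fraction of cases whose vital status is
#'   recorded as unknown.
#' @param unknown_cause_rate Fraction of deaths with unknown cause.
#' @param smoking_missing Fraction of individuals with missing smoking
#'   status.
#' @param seed Master integer seed; each study draws from its own stream
#'   derived from it, so adding a study never changes earlier studies.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_genotypes()]
#' @export
sim_config <- function(n_studies = 25L,
                       study_sizes = NULL,
                       total_n = 46687L,
                       case_fraction = 0.4966,
                       freq_increasing = c(rs4410790 = 0.63, rs2472297 = 0.26),
                       imputation_r2 = c(rs4410790 = 0.95, rs2472297 = 0.95),
                       gamma_coffee = 0.10,
                       coffee_share = 0.5,
                       coffee_intercept = 1.2,
                       tea_intercept = 0.8,
                       coffee_noise_shape = 2,
                       coffee_noise_scale = 0.75,
                       study_coffee_sd = 0.2,
                       n_coffee_studies = 4L,
                       confounder_prev = 0.55,
                       confounder_coffee_effect = 0.5,
                       confounder_logor = 0.15,
                       theta_reduced = log(1.01),
                       stage_logor = log(1.03),
                       grade_logor = log(1.01),
                       stage_frac = 4850 / 19758,
                       grade_frac = 9293 / 18915,
                       stage_missing = 0.13,
                       grade_missing = 0.167,
                       loghr_allcause = 0,
                       loghr_pca = log(1.03),
                       frac_pca_deaths = 1754 / 4081,
                       death_frac = 4081 / 15555,
                       baseline_hazard_shape = 1.2,
                       baseline_hazard_scale = NULL,
                       followup_years = 8,
                       entry_age_mean = 65,
                       entry_age_sd = 8,
                       unknown_vital_rate = 0.02,
                       unknown_cause_rate = 0.05,
                       smoking_missing = 0.3,
                       seed = 1L) {
  n_studies <- as.integer(n_studies)
  if (n_studies < 1L) stop("n_studies must be >= 1")
  if (is.null(study_sizes)) {
    base <- total_n %/% n_studies
    study_sizes <- rep.int(base, n_studies)
    study_sizes[seq_len(total_n - base * n_studies)] <-
      study_sizes[seq_len(total_n - base * n_studies)] + 1L
  }
  study_sizes <- as.integer(study_sizes)
  if (length(study_sizes) != n_studies) {
    stop("study_sizes must have length n_studies")
  }
  if (any(study_sizes <= 0L)) stop("study_sizes must be positive")

  case_fraction <- rep_len(case_fraction, n_studies)
  if (any(case_fraction <= 0 | case_fraction > 1)) {
    stop("case_fraction must lie in (0, 1]")
  }
  check_prop <- function(x, nm, open_top = TRUE) {
    bad <- x <= 0 | (if (open_top) x >= 1 else x > 1)
    if (any(bad)) stop(nm, " must lie in (0, 1", if (open_top) ")" else "]")
  }
  check_prop(freq_increasing, "freq_increasing")
  check_prop(imputation_r2, "imputation_r2", open_top = FALSE)
  check_prop(confounder_prev, "confounder_prev")
  check_prop(stage_frac, "stage_frac")
  check_prop(grade_frac, "grade_frac")
  check_prop(death_frac, "death_frac")
  check_prop(frac_pca_deaths, "frac_pca_deaths")
  stopifnot(
    length(freq_increasing) == 2L, length(imputation_r2) == 2L,
    stage_missing >= 0, stage_missing < 1,
    grade_missing >= 0, grade_missing < 1,
    baseline_hazard_shape > 0, followup_years > 0,
    unknown_vital_rate >= 0, unknown_vital_rate < 1,
    unknown_cause_rate >= 0, unknown_cause_rate < 1
  )
  if (is.null(baseline_hazard_scale)) {
    baseline_hazard_scale <- weibull_scale_for(
      death_frac, baseline_hazard_shape, followup_years
    )
  }
  cfg <- list(
    n_studies = n_studies, study_sizes = study_sizes,
    case_fraction = case_fraction,
    freq_increasing = freq_increasing, imputation_r2 = imputation_r2,
    gamma_coffee = gamma_coffee, coffee_share = coffee_share,
    coffee_intercept = coffee_intercept, tea_intercept = tea_intercept,
    coffee_noise_shape = coffee_noise_shape,
    coffee_noise_scale = coffee_noise_scale,
    study_coffee_sd = study_coffee_sd,
    n_coffee_studies = as.integer(n_coffee_studies),
    confounder_prev = confounder_prev,
    confounder_coffee_effect = confounder_coffee_effect,
    confounder_logor = confounder_logor,
    theta_reduced = theta_reduced,
    stage_logor = stage_logor, grade_logor = grade_logor,
    stage_frac = stage_frac, grade_frac = grade_frac,
    stage_missing = stage_missing, grade_missing = grade_missing,
    loghr_allcause = loghr_allcause, loghr_pca = loghr_pca,
    frac_pca_deaths = frac_pca_deaths, death_frac = death_frac,
    baseline_hazard_shape = baseline_hazard_shape,
    baseline_hazard_scale = baseline_hazard_scale,
    followup_years = followup_years,
    entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
    unknown_vital_rate = unknown_vital_rate,
    unknown_cause_rate = unknown_cause_rate,
    smoking_missing = smoking_missing,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Weibull scale that yields a target event fraction by a horizon
#'
#' Solves `1 - exp(-(horizon/scale)^shape) = event_frac` for the scale.
#'
#' @param event_frac Target cumulative event probability in (0, 1).
#' @param shape Weibull shape parameter.
#' @param horizon Time horizon (years).
#' @return The Weibull scale in the same units as `horizon`.
#' @export
weibull_scale_for <- function(event_frac, shape, horizon) {
  stopifnot(event_frac > 0, event_frac < 1, shape > 0, horizon > 0)
  horizon / (-log(1 - event_frac))^(1 / shape)
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic consortium configuration\n")
  cat(sprintf("  studies: %d, total n: %d\n",
              x$n_studies, sum(x$study_sizes)))
  cat(sprintf("  case fraction: %s\n",
              paste(format(unique(x$case_fraction)), collapse = ", ")))
  cat(sprintf("  coffee-increasing allele freqs: %s\n",
              paste(names(x$freq_increasing),
                    format(x$freq_increasing), sep = "=", collapse = ", ")))
  cat(sprintf("  first stage gamma: %.3f cups/allele; theta (case): %.4f\n",
              x$gamma_coffee, x$theta_reduced))
  cat(sprintf("  stage/grade log OR: %.4f / %.4f; log HR (all-cause/PCa): %.4f / %.4f\n",
              x$stage_logor, x$grade_logor, x$loghr_allcause, x$loghr_pca))
  cat(sprintf("  Weibull(shape %.2f, scale %.2f y), follow-up %.1f y, seed %d\n",
              x$baseline_hazard_shape, x$baseline_hazard_scale,
              x$followup_years, x$seed))
  invisible(x)
}
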