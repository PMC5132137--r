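## End-to-end analysis pipeline: simulate (or read) -> variant QC ->
## phenotype coding -> association, survival and meta-analysis ->
## scaling/power report, with structured logging of every exclusion.

pc_terms <- paste0("PC", 1:8)

first_stage_formula <- function(exposure) {
  stats::as.formula(paste("cups ~", exposure, "+",
                          paste(pc_terms, collapse = " + ")))
}

#' Per-study first-stage regressions and random-effects pool
#'
#' For every study with beverage data, regresses cups/day (coffee, tea,
#' and coffee + tea combined) on the genetic risk score adjusting for the
#' eight principal components, with heteroscedasticity-robust (HC1)
#' standard errors, then pools the per-study slopes with
#' DerSimonian-Laird random effects.
#'
#' @param cohort Cohort data.frame with a `grs` column (see
#'   [add_instruments()]).
#' @param exposure Exposure column name (default `"grs"`).
#' @return List with `per_study` (data.frame of slopes), and `pooled`
#'   (list of `meta_result`s for coffee, tea, combined).
#' @export
first_stage_analysis <- function(cohort, exposure = "grs") {
  has_cups <- !is.na(cohort$coffee_cups) | !is.na(cohort$tea_cups)
  studies <- sort(unique(cohort$study[has_cups]))
  if (!length(studies)) stop("no studies with beverage data")
  rows <- list()
  for (s in studies) {
    d <- cohort[cohort$study == s & has_cups, , drop = FALSE]
    for (bev in c("coffee", "tea", "combined")) {
      d$cups <- switch(bev,
                       coffee = d$coffee_cups,
                       tea = d$tea_cups,
                       combined = d$coffee_cups + d$tea_cups)
      if (all(is.na(d$cups))) next
      f <- tryCatch(fit_linear_robust(first_stage_formula(exposure), d),
                    error = function(e) NULL)
      if (is.null(f)) next
      i <- match(exposure, f$table$term)
      rows[[length(rows) + 1L]] <- data.frame(
        study = s, beverage = bev, n = f$n,
        estimate = f$table$estimate[i], se = f$table$se[i],
        stringsAsFactors = FALSE)
    }
  }
  per_study <- do.call(rbind, rows)
  pooled <- lapply(c(coffee = "coffee", tea = "tea", combined = "combined"),
                   function(bev) {
                     sub <- per_study[per_study$beverage == bev, ]
                     if (nrow(sub) >= 2L) {
                       random_effects_dl(study_estimates(sub$estimate, sub$se,
                                                         sub$study))
                     } else {
                       NULL
                     }
                   })
  list(per_study = per_study, pooled = pooled)
}

#' Attach oriented dosages and the genetic risk score to a cohort
#'
#' Orients each stored counted-allele dosage onto its coffee-increasing
#' allele and adds per-variant columns (`g_<rsid>`) plus the additive
#' `grs` column.
#'
#' @param cohort Cohort data.frame with `dos_<rsid>` columns.
#' @param specs Variant specifications.
#' @return The cohort with `g_<rsid>` and `grs` columns appended.
#' @export
add_instruments <- function(cohort, specs = default_variant_specs()) {
  g <- lapply(names(specs), function(nm) {
    orient_dosage(cohort[[paste0("dos_", nm)]], specs[[nm]])
  })
  names(g) <- paste0("g_", names(specs))
  for (nm in names(g)) cohort[[nm]] <- g[[nm]]
  cohort$grs <- compute_grs(do.call(cbind, g))
  cohort
}

adj_formula <- function(outcome, exposure, with_study = TRUE) {
  stats::as.formula(paste(outcome, "~", exposure, "+",
                          paste(pc_terms, collapse = " + "),
                          if (with_study) "+ study" else ""))
}

## One reduced-form logistic row: pooled clustered fit plus per-study
## fixed-effect heterogeneity.
logistic_outcome_row <- function(data, outcome, exposure, label) {
  fit <- fit_logistic(adj_formula(outcome, exposure), data, cluster = "study")
  i <- match(exposure, fit$table$term)
  i2 <- per_study_i2(data, outcome, exposure, fit_logistic)
  data.frame(exposure = exposure, outcome = label, n = fit$n,
             estimate = fit$table$estimate[i], se = fit$table$se[i],
             or = fit$table$or[i], ci_low = fit$table$or_low[i],
             ci_high = fit$table$or_high[i], p = fit$table$p[i],
             i2 = i2, stringsAsFactors = FALSE)
}

per_study_i2 <- function(data, outcome, exposure, fitter, ...) {
  ests <- list()
  for (s in unique(data$study)) {
    d <- data[data$study == s, , drop = FALSE]
    f <- tryCatch(
      suppressWarnings(fitter(adj_formula(outcome, exposure,
                                          with_study = FALSE), d, ...)),
      error = function(e) NULL)
    if (is.null(f)) next
    i <- match(exposure, f$table$term)
    if (is.na(i) || !is.finite(f$table$se[i])) next
    ests[[length(ests) + 1L]] <- c(f$table$estimate[i], f$table$se[i])
  }
  if (length(ests) < 2L) return(NA_real_)
  m <- do.call(rbind, ests)
  heterogeneity(study_estimates(m[, 1], m[, 2]))$i2
}

#' Run the full Mendelian randomization analysis pipeline
#'
#' Orchestrates simulate (or load) -> variant QC -> instrument
#' construction -> phenotype coding -> first-stage, case-control, stage,
#' grade and mortality models -> meta-analytic heterogeneity ->
#' scaling/power report, logging every exclusion. Deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()], a list of `sim_config()` arguments, or
#'   the path to a YAML file with top-level keys `simulation:` (the
#'   `sim_config()` fields) and optional `analysis:`
#'   (`or_extreme`, `contrast`, `per_unit`, `alpha`, `power`) and
#'   `input:` (`genotype_file`, `phenotype_file` to read instead of
#'   simulating).
#' @param outdir Optional output directory; when given, tab-delimited
#'   result tables and a run log are written there.
#' @param override_qc Proceed even if a variant fails QC.
#' @return An object of class `mr_analysis_report`.
#' @export
run_analysis <- function(config, outdir = NULL, override_qc = FALSE) {
  analysis <- list(or_extreme = 0.96, contrast = 3.5, per_unit = 0.06,
                   alpha = 0.05, power = 0.80)
  input <- NULL
  if (is.character(config) && length(config) == 1L) {
    raw <- yaml::read_yaml(config)
    bad <- setdiff(names(raw), c("simulation", "analysis", "input"))
    if (length(bad)) {
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           " (expected simulation/analysis/input)")
    }
    sim_args <- raw$simulation
    if (!is.null(sim_args$freq_increasing)) {
      sim_args$freq_increasing <- unlist(sim_args$freq_increasing)
    }
    if (!is.null(sim_args$imputation_r2)) {
      sim_args$imputation_r2 <- unlist(sim_args$imputation_r2)
    }
    cfg <- tryCatch(do.call(sim_config, sim_args), error = function(e) {
      stop("config key 'simulation': ", conditionMessage(e))
    })
    analysis[names(raw$analysis)] <- raw$analysis
    input <- raw$input
  } else if (inherits(config, "sim_config")) {
    cfg <- config
  } else if (is.list(config)) {
    cfg <- do.call(sim_config, config)
  } else {
    stop("config must be a sim_config, an argument list, or a YAML path")
  }

  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    invisible(line)
  }

  if (!is.null(input)) {
    val <- validate_inputs(input$genotype_file, input$phenotype_file)
    cohort <- val$cohort
    for (iss in val$issues) note("input validation: %s", iss)
    note("loaded cohort: %d individuals from %s", nrow(cohort),
         input$phenotype_file)
  } else {
    cohort <- simulate_cohort(cfg)
    note("simulated cohort: %d individuals in %d studies (seed %d)",
         nrow(cohort), cfg$n_studies, cfg$seed)
  }

  specs <- default_variant_specs()
  qc <- withCallingHandlers(
    qc_variants(list(rs4410790 = cohort$dos_rs4410790,
                     rs2472297 = cohort$dos_rs2472297),
                cohort$case, specs,
                imputation_r2 = cfg$imputation_r2),
    warning = function(w) {
      note("QC: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (i in seq_len(nrow(qc))) {
    note("QC %s: call rate %.3f, HWE p %s, imputation R2 %.2f -> %s",
         qc$rsid[i], qc$call_rate[i],
         ifelse(is.na(qc$hwe_p[i]), "n/a", format(qc$hwe_p[i], digits = 3)),
         qc$imputation_r2[i], ifelse(qc$pass[i], "pass", qc$reasons[i]))
  }
  if (any(!qc$pass) && !override_qc) {
    stop("variant(s) failed QC: ",
         paste(qc$rsid[!qc$pass], collapse = ", "),
         "; rerun with override_qc = TRUE to force")
  }

  cohort <- add_instruments(cohort, specs)
  exposures <- c("g_rs4410790", "g_rs2472297", "grs")

  ## ---- first stage -------------------------------------------------
  fs <- first_stage_analysis(cohort)
  note("first stage: %d studies with beverage data",
       length(unique(fs$per_study$study)))

  ## ---- case-control ------------------------------------------------
  tab <- table(cohort$study, cohort$case)
  cc_ok <- rownames(tab)[tab[, "0"] > 0 & tab[, "1"] > 0]
  dropped_cc <- setdiff(rownames(tab), cc_ok)
  if (length(dropped_cc)) {
    note("%d studies excluded (no controls): %s", length(dropped_cc),
         paste(dropped_cc, collapse = ", "))
  }
  cc <- cohort[cohort$study %in% cc_ok, , drop = FALSE]
  table1 <- do.call(rbind, lapply(exposures, function(e) {
    logistic_outcome_row(cc, "case", e, "all_prostate_cancer")
  }))
  note("case-control model: %d cases, %d controls in %d studies",
       sum(cc$case == 1), sum(cc$case == 0), length(cc_ok))

  ## ---- stage and grade (case-only) ---------------------------------
  cases <- cohort[cohort$case == 1L, , drop = FALSE]
  cases$stage <- classify_stage(cases$tnm, cases$seer)
  cases$nonloc <- as.integer(cases$stage == "nonlocalised")
  st <- cases[!is.na(cases$nonloc), , drop = FALSE]
  st_keep <- names(which(tapply(st$nonloc, st$study, sum) > 0))
  dropped_st <- setdiff(unique(st$study), st_keep)
  if (length(dropped_st)) {
    note("%d studies excluded from the stage model (no nonlocalised cases): %s",
         length(dropped_st), paste(dropped_st, collapse = ", "))
  }
  st <- st[st$study %in% st_keep, , drop = FALSE]
  table1 <- rbind(table1, do.call(rbind, lapply(exposures, function(e) {
    logistic_outcome_row(st, "nonloc", e, "nonlocalised_vs_localised")
  })))
  note("stage model: %d localised, %d nonlocalised",
       sum(st$nonloc == 0), sum(st$nonloc == 1))

  cases$grade <- classify_grade(cases$gleason)
  gr <- cases[!is.na(cases$grade), , drop = FALSE]
  gr$high <- as.integer(gr$grade == "high")
  table1 <- rbind(table1, do.call(rbind, lapply(exposures, function(e) {
    logistic_outcome_row(gr, "high", e, "high_vs_low_grade")
  })))
  note("grade model: %d low grade, %d high grade",
       sum(gr$high == 0), sum(gr$high == 1))

  ## ---- mortality ---------------------------------------------------
  elig <- study_eligibility(cases$study, cases$vital_status,
                            cases$cause_death)
  mort <- resolve_mortality(cases$vital_status, cases$cause_death)
  excl_unknown <- sum(!mort$include)
  if (excl_unknown) {
    note("%d cases with unknown vital status excluded from mortality models",
         excl_unknown)
  }
  for (col in c("allcause", "pca")) {
    ineligible <- elig$study[!elig[[paste0("eligible_", col)]]]
    if (length(ineligible)) {
      note("%d studies ineligible for %s mortality: %s", length(ineligible),
           col, paste(ineligible, collapse = ", "))
    }
  }
  table2 <- NULL
  for (spec_m in list(list(col = "allcause", label = "all_cause"),
                      list(col = "pca", label = "prostate_cancer_specific"))) {
    ok_st <- elig$study[elig[[paste0("eligible_", spec_m$col)]]]
    d <- cases[cases$study %in% ok_st & mort$include &
                 !is.na(cases$age_diagnosis), , drop = FALSE]
    ev <- mort[[spec_m$col]][cases$study %in% ok_st & mort$include &
                               !is.na(cases$age_diagnosis)]
    if (!nrow(d) || sum(ev) == 0) {
      note("mortality model %s skipped: no eligible events", spec_m$label)
      next
    }
    for (e in exposures) {
      f <- fit_cox(stats::as.formula(
        paste("~", e, "+", paste(pc_terms, collapse = " + "), "+ study")),
        d, entry = "age_diagnosis", exit = "age_exit", event = ev,
        cluster = "study")
      i <- match(e, f$table$term)
      table2 <- rbind(table2, data.frame(
        exposure = e, outcome = spec_m$label, n = f$n,
        n_deaths = f$n_events,
        years_at_risk_1000s = f$person_years / 1000,
        estimate = f$table$estimate[i], se = f$table$se[i],
        hr = f$table$hr[i], ci_low = f$table$hr_low[i],
        ci_high = f$table$hr_high[i], p = f$table$p[i],
        stringsAsFactors = FALSE))
    }
    note("mortality model %s: %d men, %d deaths", spec_m$label,
         nrow(d), sum(ev))
  }

  ## ---- smoking subgroup --------------------------------------------
  smoking <- tryCatch(
    suppressWarnings(subgroup_interaction(adj_formula("case", "grs"), cc,
                                          stratum = "smoking",
                                          exposure = "grs",
                                          cluster = "study")),
    error = function(e) {
      note("smoking interaction failed: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(smoking)) {
    note("smoking interaction p = %s", format(smoking$interaction_p,
                                              digits = 3))
  }

  ## ---- scaling and power -------------------------------------------
  scaling <- list(
    or_extreme = analysis$or_extreme,
    contrast = analysis$contrast,
    per_unit = analysis$per_unit,
    per_unit_or = scale_categorical_or(analysis$or_extreme,
                                       analysis$contrast,
                                       analysis$per_unit),
    sensitivity = scaling_sensitivity(analysis$or_extreme,
                                      per_unit = analysis$per_unit),
    detectable = detectable_or(sum(cc$case == 1), sum(cc$case == 0),
                               var_g = grs_variance(cfg$freq_increasing),
                               gamma = cfg$gamma_coffee,
                               alpha = analysis$alpha,
                               power = analysis$power)
  )
  grs_row <- table1[table1$exposure == "grs" &
                      table1$outcome == "all_prostate_cancer", ]
  fsc <- fs$pooled$combined
  if (!is.null(fsc)) {
    scaling$wald <- wald_ratio(grs_row$estimate, grs_row$se,
                               fsc$estimate, fsc$se)
  }

  report <- structure(
    list(first_stage = fs, table1 = table1, table2 = table2, qc = qc,
         eligibility = elig, smoking = smoking, scaling = scaling,
         log = log, config = cfg, seed = cfg$seed),
    class = "mr_analysis_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$first_stage$per_study, "first_stage_per_study.tsv")
  pooled <- do.call(rbind, lapply(names(report$first_stage$pooled),
                                  function(b) {
    m <- report$first_stage$pooled[[b]]
    if (is.null(m)) return(NULL)
    data.frame(beverage = b, model = m$model, estimate = m$estimate,
               se = m$se, ci_low = m$ci_low, ci_high = m$ci_high,
               Q = m$Q, tau2 = m$tau2, i2 = m$i2, k = m$k)
  }))
  wt(pooled, "first_stage_pooled.tsv")
  wt(report$table1, "table1_risk_stage_grade.tsv")
  if (!is.null(report$table2)) wt(report$table2, "table2_mortality.tsv")
  wt(report$scaling$sensitivity, "scaling_sensitivity.tsv")
  det <- report$scaling$detectable
  wt(data.frame(per_unit_or = report$scaling$per_unit_or,
                detectable_or_per_allele = det$or_per_allele,
                detectable_or_per_cup = det$or_per_cup,
                se_beta = det$se_beta, n = det$n, phi = det$phi,
                var_g = det$var_g),
     "scaling_power.tsv")
  writeLines(report$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @method print mr_analysis_report
#' @export
print.mr_analysis_report <- function(x, ...) {
  cat("Mendelian randomization analysis report (seed", x$seed, ")\n\n")
  fsc <- x$first_stage$pooled$combined
  if (!is.null(fsc)) {
    cat(sprintf(
      "First stage (combined coffee+tea): %.3f cups/allele (95%% CI %.3f, %.3f), I2 = %.0f%%\n",
      fsc$estimate, fsc$ci_low, fsc$ci_high, fsc$i2))
  }
  cat("\nRisk, stage and grade (per coffee-increasing allele):\n")
  print(x$table1[, c("exposure", "outcome", "n", "or", "ci_low", "ci_high",
                     "p", "i2")], digits = 3, row.names = FALSE)
  if (!is.null(x$table2)) {
    cat("\nMortality (per coffee-increasing allele):\n")
    print(x$table2[, c("exposure", "outcome", "n", "n_deaths",
                       "years_at_risk_1000s", "hr", "ci_low", "ci_high",
                       "p")], digits = 3, row.names = FALSE)
  }
  det <- x$scaling$detectable
  cat(sprintf(
    "\nScaling: extreme-category OR %.2f equates to %.4f per %.2f cups;\n",
    x$scaling$or_extreme, x$scaling$per_unit_or, x$scaling$per_unit))
  cat(sprintf(
    "power: minimal detectable per-allele OR %.3f (per cup %.3f) at this sample size\n",
    det$or_per_allele, det$or_per_cup))
  cat("\nRun log:\n")
  cat(paste(" ", x$log), sep = "\n")
  invisible(x)
}
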