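#' Frequency-category map for beverage consumption
#'
#' Questionnaire frequency categories are recoded to cups/day at the
#' midpoint of each category; the open-ended top category is recoded to its
#' lower bound plus a configurable offset, and "never" to 0. The default
#' map (never = 0, "<1" = 0.5, "1" = 1, "2-3" = 2.5, ">=4" = 5) is a
#' documented stand-in for per-study questionnaires that are not publicly
#' available, and can be overridden per study.
#'
#' @param labels Character category labels, ordered.
#' @param lower,upper Numeric bounds in cups/day; `upper = Inf` marks the
#'   open-ended top category.
#' @param open_offset Cups/day added to the lower bound of the open-ended
#'   category.
#' @return A data.frame of class `category_map` with a `cups` column of
#'   midpoints.
#' @export
category_map <- function(labels = c("never", "<1", "1", "2-3", ">=4"),
                         lower = c(0, 0, 1, 2, 4),
                         upper = c(0, 1, 1, 3, Inf),
                         open_offset = 1) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper),
            !anyDuplicated(labels), all(upper >= lower), open_offset >= 0)
  if (is.unsorted(lower)) stop("categories must be ordered by lower bound")
  cups <- ifelse(is.infinite(upper), lower + open_offset, (lower + upper) / 2)
  m <- data.frame(label = labels, lower = lower, upper = upper, cups = cups,
                  stringsAsFactors = FALSE)
  class(m) <- c("category_map", "data.frame")
  m
}

#' Recode a frequency category to cups/day
#'
#' @param label Character vector of category labels.
#' @param map A [category_map()].
#' @return Numeric cups/day (`NA` with a warning for unknown labels).
#' @examples
#' recode_cups("2-3")        # 2.5
#' recode_cups("never")      # 0
#' @export
recode_cups <- function(label, map = category_map()) {
  stopifnot(inherits(map, "category_map"))
  i <- match(label, map$label)
  if (anyNA(i[!is.na(label)])) {
    bad <- unique(label[!is.na(label) & is.na(i)])
    warning("unknown consumption categories recoded to missing: ",
            paste(bad, collapse = ", "))
  }
  map$cups[i]
}

#' Classify tumour stage as localised vs nonlocalised
#'
#' TNM rule: nonlocalised if any of T3, T4, N1 or M1 is present; localised
#' if the T stage is T1/T2 and N is N0/NX (or absent) and M is M0/MX (or
#' absent); otherwise missing. Where TNM is unavailable, SEER summary
#' staging is used: "local" is localised, "regional" and "distant" are
#' nonlocalised. If both codings are present and disagree the record is
#' set missing with a warning.
#'
#' @param tnm Character vector of TNM token strings (e.g. `"T2 N0 M0"`;
#'   token order and separators are free; missing tokens allowed).
#' @param seer Character vector of SEER labels (`"local"`, `"regional"`,
#'   `"distant"`).
#' @return Factor with levels `localised`, `nonlocalised`; `NA` = missing.
#' @export
classify_stage <- function(tnm = NULL, seer = NULL) {
  n <- max(length(tnm), length(seer))
  if (is.null(tnm)) tnm <- rep(NA_character_, n)
  if (is.null(seer)) seer <- rep(NA_character_, n)
  stopifnot(length(tnm) == n, length(seer) == n)

  from_tnm <- vapply(tnm, classify_tnm_one, character(1), USE.NAMES = FALSE)
  seer_l <- tolower(trimws(seer))
  from_seer <- ifelse(is.na(seer_l), NA_character_,
                      ifelse(seer_l == "local", "localised",
                             ifelse(seer_l %in% c("regional", "distant"),
                                    "nonlocalised", NA_character_)))
  res <- from_tnm
  use_seer <- is.na(res) & !is.na(from_seer)
  res[use_seer] <- from_seer[use_seer]
  conflict <- !is.na(from_tnm) & !is.na(from_seer) & from_tnm != from_seer
  if (any(conflict)) {
    warning(sum(conflict), " record(s) with contradictory TNM and SEER ",
            "staging set to missing")
    res[conflict] <- NA_character_
  }
  factor(res, levels = c("localised", "nonlocalised"))
}

classify_tnm_one <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_character_)
  toks <- toupper(regmatches(x, gregexpr("[TNM][0-9X]+", toupper(x)))[[1]])
  t_tok <- grep("^T", toks, value = TRUE)
  n_tok <- grep("^N", toks, value = TRUE)
  m_tok <- grep("^M", toks, value = TRUE)
  # any nonlocalised token wins
  if (any(toks %in% c("T3", "T4", "N1", "M1"))) return("nonlocalised")
  t_ok <- length(t_tok) > 0 && all(t_tok %in% c("T1", "T2"))
  n_ok <- length(n_tok) == 0 || all(n_tok %in% c("N0", "NX"))
  m_ok <- length(m_tok) == 0 || all(m_tok %in% c("M0", "MX"))
  if (t_ok && n_ok && m_ok) "localised" else NA_character_
}

#' Classify tumour grade from the Gleason score
#'
#' Gleason score of 6 or less is low grade; 7 or more is high grade.
#' Scores outside 2-10 are set missing with a warning.
#'
#' @param gleason Integer vector of Gleason scores.
#' @return Factor with levels `low`, `high`; `NA` = missing.
#' @export
classify_grade <- function(gleason) {
  out_of_range <- !is.na(gleason) & (gleason < 2 | gleason > 10)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " Gleason score(s) outside 2-10 set to missing")
  }
  g <- ifelse(out_of_range, NA_real_, gleason)
  factor(ifelse(is.na(g), NA_character_, ifelse(g <= 6, "low", "high")),
         levels = c("low", "high"))
}

#' Resolve mortality event flags from vital status and cause of death
#'
#' Individuals with unknown vital status are excluded from mortality
#' analyses. Deaths count as all-cause events; they count as
#' prostate-cancer-specific events only when the recorded cause is
#' prostate cancer — a death with unknown cause is assumed not to be from
#' prostate cancer.
#'
#' @param vital_status Character: `"alive"`, `"dead"` or `"unknown"`.
#' @param cause_death Character: `"prostate_cancer"`, `"other"`,
#'   `"unknown"` or `NA` (for survivors).
#' @return A data.frame with columns `allcause` (0/1), `pca` (0/1) and
#'   `include` (logical).
#' @export
resolve_mortality <- function(vital_status, cause_death) {
  n <- length(vital_status)
  stopifnot(length(cause_death) == n)
  include <- !is.na(vital_status) & vital_status != "unknown"
  dead <- include & vital_status == "dead"
  allcause <- as.integer(dead)
  pca <- as.integer(dead & !is.na(cause_death) &
                      cause_death == "prostate_cancer")
  data.frame(allcause = allcause, pca = pca, include = include)
}

#' Per-study mortality-analysis eligibility
#'
#' A study enters the all-cause mortality analysis when mortality
#' follow-up among its cases is at least 90% complete (fraction of cases
#' with known vital status), and additionally enters the prostate-cancer
#' specific analysis when it recorded at least five prostate cancer
#' deaths. Both thresholds are inclusive.
#'
#' @param study Character study labels, one per case.
#' @param vital_status,cause_death As in [resolve_mortality()], one per
#'   case.
#' @param completeness_min,pca_deaths_min Eligibility thresholds.
#' @return Data.frame of class `mortality_eligibility`: `study`,
#'   `completeness`, `pca_deaths`, `eligible_allcause`, `eligible_pca`.
#' @export
study_eligibility <- function(study, vital_status, cause_death,
                              completeness_min = 0.90, pca_deaths_min = 5L) {
  stopifnot(length(vital_status) == length(study),
            length(cause_death) == length(study))
  known <- !is.na(vital_status) & vital_status != "unknown"
  pca_death <- known & vital_status == "dead" & !is.na(cause_death) &
    cause_death == "prostate_cancer"
  labs <- sort(unique(study))
  completeness <- vapply(labs, function(s) mean(known[study == s]), numeric(1))
  pca_deaths <- vapply(labs, function(s) sum(pca_death[study == s]), numeric(1))
  out <- data.frame(
    study = labs, completeness = completeness, pca_deaths = pca_deaths,
    eligible_allcause = completeness >= completeness_min,
    eligible_pca = completeness >= completeness_min &
      pca_deaths >= pca_deaths_min,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("mortality_eligibility", "data.frame")
  out
}
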