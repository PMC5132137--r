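#' Describe an instrument variant
#'
#' A `variant_spec` records, for one instrument SNP, which allele the
#' dosage file counts and which allele increases coffee consumption, so
#' that orientation is fixed by configuration and can never flip between
#' datasets.
#'
#' @param rsid Variant identifier.
#' @param counted_allele Base whose dosage the genotype file stores (the
#'   VCF ALT allele).
#' @param coffee_increasing_allele Base whose count the genetic risk score
#'   sums.
#' @param locus Locus label (e.g. `"AHR"` or `"CYP1A1/2"`).
#' @param chrom,pos,ref,alt Optional VCF coordinates and alleles used when
#'   writing genotype files.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(rsid, counted_allele, coffee_increasing_allele,
                         locus = NA_character_, chrom = NA_character_,
                         pos = NA_integer_, ref = NA_character_,
                         alt = counted_allele) {
  stopifnot(nchar(counted_allele) == 1L, nchar(coffee_increasing_allele) == 1L)
  alleles <- unique(c(ref, alt, counted_allele, coffee_increasing_allele))
  alleles <- alleles[!is.na(alleles)]
  if (!coffee_increasing_allele %in% alleles) {
    stop("coffee_increasing_allele must be one of the variant's alleles")
  }
  structure(
    list(rsid = rsid, counted_allele = counted_allele,
         coffee_increasing_allele = coffee_increasing_allele,
         locus = locus, chrom = chrom, pos = as.integer(pos),
         ref = ref, alt = alt),
    class = "variant_spec"
  )
}

#' @method print variant_spec
#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("%s (%s): counted allele %s, coffee-increasing allele %s%s\n",
              x$rsid, x$locus, x$counted_allele, x$coffee_increasing_allele,
              if (identical(x$counted_allele, x$coffee_increasing_allele))
                "" else " [dosage is reflected: 2 - d]"))
  invisible(x)
}

#' Default instrument specification for the two caffeine-intake SNPs
#'
#' The genetic risk score counts the coffee-increasing allele of each
#' variant: the major allele of rs4410790 (AHR) and the minor allele of
#' rs2472297 (CYP1A1/2). Files store the ALT-allele dosage, which for
#' rs4410790 is the non-increasing minor allele, so that variant's dosage
#' is reflected during orientation.
#'
#' @return Named list of two [variant_spec()] objects.
#' @export
default_variant_specs <- function() {
  list(
    rs4410790 = variant_spec("rs4410790", counted_allele = "T",
                             coffee_increasing_allele = "C", locus = "AHR",
                             chrom = "7", pos = 17284577L, ref = "C", alt = "T"),
    rs2472297 = variant_spec("rs2472297", counted_allele = "T",
                             coffee_increasing_allele = "T", locus = "CYP1A1/2",
                             chrom = "15", pos = 75027880L, ref = "C", alt = "T")
  )
}

#' Orient a dosage onto the coffee-increasing allele
#'
#' Returns the dosage unchanged when the counted allele is the
#' coffee-increasing allele and `2 - dosage` otherwise. Missing dosages
#' stay missing.
#'
#' @param dosage Numeric vector of dosages in `[0, 2]`.
#' @param spec A [variant_spec()].
#' @return Oriented dosages in `[0, 2]`.
#' @export
orient_dosage <- function(dosage, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) {
    stop("dosage outside [0, 2] for ", spec$rsid, " (e.g. ",
         format(dosage[!ok][1]), ")")
  }
  if (identical(spec$counted_allele, spec$coffee_increasing_allele)) {
    dosage
  } else {
    2 - dosage
  }
}

#' Genetic risk score from oriented dosages
#'
#' Sums the coffee-increasing allele dosages of the two instrument
#' variants under an additive model. If either dosage is missing the score
#' is missing; the score is never imputed.
#'
#' @param ... Two or more numeric vectors of oriented dosages (or a single
#'   matrix with one column per variant).
#' @return Numeric vector of scores in `[0, 2 * n_variants]`.
#' @export
compute_grs <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.matrix(args[[1L]])) {
    m <- args[[1L]]
  } else {
    m <- do.call(cbind, args)
  }
  if (ncol(m) < 2L) stop("compute_grs needs dosages for at least two variants")
  if (any(m < 0 | m > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  rowSums(m)  # NA in any variant propagates to the score
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of hard genotype
#' counts against the Hardy-Weinberg expectation computed from the sample
#' allele frequency. Intended for control samples; apply to hard-called
#' genotypes only.
#'
#' @param counts Integer vector `c(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return List with `statistic`, `p` and the expected counts.
#' @examples
#' hwe_test(c(25, 50, 25))$p  # exact HW proportions: p = 1
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || any(is.na(counts))) {
    stop("counts must be three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes to test")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    warning("monomorphic genotypes: HWE test degenerate, p = 1")
    return(list(statistic = 0, p = 1,
                expected = c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Variant quality control
#'
#' Applies the genotyping QC rules to each instrument variant: call rate at
#' least 95%, Hardy-Weinberg equilibrium in controls at P >= 1e-7, and
#' imputation R-squared at least 0.3. Thresholds are inclusive (a variant
#' exactly at a threshold passes). The HWE test needs hard genotype calls,
#' so it is computed from rounded dosages when the variant's imputation R²
#' is 1 and skipped with a warning otherwise.
#'
#' @param dosages Named list or data.frame of counted-allele dosage vectors,
#'   one per variant (names are rsids).
#' @param case Binary vector (1 = case, 0 = control) aligned with the
#'   dosage rows.
#' @param specs Named list of [variant_spec()] objects.
#' @param imputation_r2 Named numeric vector of imputation R² per variant.
#' @param call_rate_min,hwe_p_min,r2_min QC thresholds.
#' @return A data.frame of class `variant_qc_report` with one row per
#'   variant: `rsid`, `call_rate`, `hwe_p`, `imputation_r2`, `pass`,
#'   `reasons` (comma-separated failure reasons).
#' @export
qc_variants <- function(dosages, case, specs = default_variant_specs(),
                        imputation_r2, call_rate_min = 0.95,
                        hwe_p_min = 1e-7, r2_min = 0.3) {
  rsids <- names(dosages)
  stopifnot(length(rsids) > 0, all(rsids %in% names(specs)),
            all(rsids %in% names(imputation_r2)))
  n <- length(dosages[[1L]])
  if (length(case) != n) stop("case labels must align with dosage rows")
  has_controls <- any(case == 0L, na.rm = TRUE)
  if (!has_controls) {
    warning("no controls present: HWE not assessable; ",
            "pass decided on the remaining criteria")
  }
  rows <- lapply(rsids, function(rs) {
    d <- dosages[[rs]]
    cr <- mean(!is.na(d))
    r2 <- unname(imputation_r2[[rs]])
    hwe_p <- NA_real_
    if (has_controls) {
      if (r2 == 1) {
        g <- round(d[case == 0L & !is.na(d)])
        cnt <- c(sum(g == 2), sum(g == 1), sum(g == 0))
        hwe_p <- hwe_test(cnt)$p
      } else {
        warning("HWE test skipped for ", rs,
                ": dosages are imputed (r2 < 1), no hard calls available")
      }
    }
    reasons <- character(0)
    if (cr < call_rate_min) reasons <- c(reasons, "call_rate")
    if (!is.na(hwe_p) && hwe_p < hwe_p_min) reasons <- c(reasons, "hwe")
    if (r2 < r2_min) reasons <- c(reasons, "imputation_r2")
    data.frame(rsid = rs, call_rate = cr, hwe_p = hwe_p,
               imputation_r2 = r2, pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("variant_qc_report", "data.frame")
  rep
}

#' @method print variant_qc_report
#' @export
print.variant_qc_report <- function(x, ...) {
  cat("Variant QC report (pass requires call rate >= 0.95, HWE p >= 1e-7,",
      "imputation R2 >= 0.3)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
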