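## Cohort file I/O: genotypes as a VCF 4.2 with a per-sample DS (dosage)
## FORMAT field, phenotypes as tab-delimited text. Numeric fields are
## written with 17 significant digits so a write/read round trip
## reproduces the table exactly; missing values are written as "NA" in the
## phenotype file and "." in the VCF.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), ".", sprintf("%.17g", x))
  out
}

#' Write a cohort to genotype (VCF) and phenotype (TSV) files
#'
#' The VCF carries one record per instrument variant with a per-sample
#' `DS` FORMAT field holding the counted (ALT) allele dosage; the
#' phenotype file is tab-delimited with a header and `NA` for missing
#' values. [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort A cohort `data.frame` from [simulate_cohort()] (or with
#'   the same columns).
#' @param genotype_path,phenotype_path Output file paths.
#' @param specs Variant specifications providing VCF coordinates.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, genotype_path, phenotype_path,
                         specs = default_variant_specs()) {
  stopifnot(is.data.frame(cohort), "sample_id" %in% names(cohort))
  dos_cols <- paste0("dos_", names(specs))
  missing_cols <- setdiff(dos_cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks dosage columns: ", paste(missing_cols, collapse = ", "))
  }
  con <- file(genotype_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=coffeemr",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Imputed ALT allele dosage (0-2)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_id), collapse = "\t")
  ), con)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    line <- paste(c(sp$chrom, sp$pos, sp$rsid, sp$ref, sp$alt, ".", ".",
                    ".", "DS", fmt_num(cohort[[paste0("dos_", nm)]])),
                  collapse = "\t")
    writeLines(line, con)
  }
  pheno <- cohort[, setdiff(names(cohort), dos_cols), drop = FALSE]
  num <- vapply(pheno, is.numeric, logical(1))
  pheno[num] <- lapply(pheno[num], function(x) sprintf("%.17g", x))
  pheno[num] <- lapply(pheno[num], function(x) ifelse(x == "NA", NA, x))
  utils::write.table(pheno, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(genotype = genotype_path, phenotype = phenotype_path))
}

#' Read a cohort from genotype and phenotype files
#'
#' Reads the VCF `DS` dosage field (via the vcfR parser) and the
#' tab-delimited phenotype table, and joins them by sample id.
#'
#' @param genotype_path,phenotype_path Input file paths.
#' @return A cohort `data.frame` in the [simulate_cohort()] layout.
#' @export
read_cohort <- function(genotype_path, phenotype_path) {
  vcf <- vcfR::read.vcfR(genotype_path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  rsids <- vcfR::getID(vcf)
  pheno <- utils::read.delim(phenotype_path, sep = "\t",
                             stringsAsFactors = FALSE,
                             na.strings = "NA")
  idx <- match(pheno$sample_id, colnames(ds))
  if (anyNA(idx)) {
    stop("phenotype samples missing from the VCF: ",
         paste(utils::head(pheno$sample_id[is.na(idx)], 5), collapse = ", "))
  }
  for (i in seq_along(rsids)) {
    pheno[[paste0("dos_", rsids[i])]] <- unname(ds[i, idx])
  }
  ## restore the canonical column order where possible
  lead <- c("sample_id", "study", "case", paste0("dos_", rsids))
  rest <- setdiff(names(pheno), lead)
  pheno[, c(intersect(lead, names(pheno)), rest), drop = FALSE]
}

#' Validate genotype and phenotype inputs
#'
#' Structural validation run before any analysis: sample-id agreement
#' between the two files, dosage range, stage and grade vocabulary, and
#' age monotonicity. Hard failures (mismatched samples, out-of-range
#' dosages) raise errors; record-level problems are returned for logging.
#'
#' @param genotype_path,phenotype_path Input file paths.
#' @return List with `ok`, the parsed `cohort`, and a character vector of
#'   `issues` describing rejected records.
#' @export
validate_inputs <- function(genotype_path, phenotype_path) {
  if (!file.exists(genotype_path)) stop("genotype file not found: ",
                                        genotype_path)
  if (!file.exists(phenotype_path)) stop("phenotype file not found: ",
                                         phenotype_path)
  cohort <- read_cohort(genotype_path, phenotype_path)
  issues <- character(0)
  dos_cols <- grep("^dos_", names(cohort), value = TRUE)
  for (dc in dos_cols) {
    d <- cohort[[dc]]
    bad <- which(!is.na(d) & (d < 0 | d > 2))
    if (length(bad)) {
      stop("dosage outside [0, 2] for variant ", sub("^dos_", "", dc),
           ", sample ", cohort$sample_id[bad[1]],
           " (value ", format(d[bad[1]]), ")")
    }
  }
  if ("gleason" %in% names(cohort)) {
    g <- cohort$gleason
    bad <- !is.na(g) & (g < 2 | g > 10)
    if (any(bad)) {
      issues <- c(issues, sprintf("%d record(s) with Gleason outside 2-10",
                                  sum(bad)))
    }
  }
  if ("seer" %in% names(cohort)) {
    s <- tolower(cohort$seer)
    bad <- !is.na(s) & !s %in% c("local", "regional", "distant")
    if (any(bad)) {
      issues <- c(issues, sprintf("%d record(s) with unknown SEER label",
                                  sum(bad)))
    }
  }
  if (all(c("age_diagnosis", "age_exit") %in% names(cohort))) {
    bad <- !is.na(cohort$age_exit) & !is.na(cohort$age_diagnosis) &
      cohort$age_exit < cohort$age_diagnosis
    if (any(bad)) {
      issues <- c(issues,
                  sprintf("%d record(s) rejected: exit age before entry age",
                          sum(bad)))
      cohort$age_exit[bad] <- NA_real_
      cohort$age_diagnosis[bad] <- NA_real_
    }
  }
  list(ok = TRUE, cohort = cohort, issues = issues)
}
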