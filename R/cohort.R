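#' Definitions of the five genotyped polymorphisms
#'
#' Returns the panel of single-nucleotide polymorphisms used throughout the
#' package: CYP3A5*3 (rs776746), CYP3A4*1G (rs2242480), CYP3A4*1B
#' (rs2740574), ABCB1 G2677T (rs2032582) and ABCB1 C3435T (rs1045642).
#'
#' Each SNP carries a "coded" allele: the additive genotype code of a patient
#' is the number of copies (0, 1 or 2) of that allele. For CYP3A5 the coded
#' allele is the functional *1 allele, so that code 0 corresponds to the
#' *3/*3 non-expressor genotype, matching the genotype variable of the
#' dosing equation. For the remaining SNPs the named variant allele is
#' counted (*1G, the *1B promoter G, and the two ABCB1 T alleles).
#'
#' @return A tibble with columns `snp_id`, `gene_label`, `allele_a`,
#'   `allele_b`, `coded_allele`.
#' @export
#' @examples
#' snp_definitions()
snp_definitions <- function() {
  defs <- tibble::tibble(
    snp_id       = c("rs776746", "rs2242480", "rs2740574", "rs2032582", "rs1045642"),
    gene_label   = c("CYP3A5*3", "CYP3A4*1G", "CYP3A4*1B", "ABCB1 G2677T", "ABCB1 C3435T"),
    allele_a     = c("*1", "*1", "A", "G", "C"),
    allele_b     = c("*3", "*1G", "G", "T", "T"),
    coded_allele = c("*1", "*1G", "G", "T", "T")
  )
  validate_snp_defs(defs)
  defs
}

validate_snp_defs <- function(defs) {
  stopifnot(is.data.frame(defs))
  req <- c("snp_id", "gene_label", "allele_a", "allele_b", "coded_allele")
  missing <- setdiff(req, names(defs))
  if (length(missing) > 0) {
    stop("SNP definitions lack columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(defs$snp_id)) stop("duplicate snp_id in SNP definitions")
  if (any(defs$allele_a == defs$allele_b)) {
    stop("allele_a and allele_b must differ for every SNP")
  }
  ok <- defs$coded_allele == defs$allele_a | defs$coded_allele == defs$allele_b
  if (!all(ok)) {
    stop("coded_allele must be one of the two alleles: ",
         paste(defs$snp_id[!ok], collapse = ", "))
  }
  invisible(defs)
}

snp_def <- function(snp_defs, snp_id) {
  i <- match(snp_id, snp_defs$snp_id)
  if (is.na(i)) stop("unknown SNP: ", snp_id, call. = FALSE)
  as.list(snp_defs[i, ])
}

# Canonicalise one genotype string ("x/y", alleles in either order) against a
# SNP definition. Returns the canonical string (allele_a listed first) or NA;
# stops with row/column context on malformed input.
parse_genotype <- function(x, def, column = def$snp_id) {
  out <- rep(NA_character_, length(x))
  present <- !is.na(x) & trimws(x) != ""
  if (!any(present)) return(out)
  parts <- strsplit(trimws(x[present]), "/", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  alleles <- c(def$allele_a, def$allele_b)
  canon <- vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) != 2L || !all(p %in% alleles)) return(NA_character_)
    paste(p[order(match(p, alleles))], collapse = "/")
  }, character(1))
  bad <- bad | is.na(canon)
  if (any(bad)) {
    rows <- which(present)[bad]
    stop(sprintf(
      "malformed genotype in column '%s', row %s: '%s' (expected alleles %s/%s)",
      column, rows[1], x[rows[1]], def$allele_a, def$allele_b
    ), call. = FALSE)
  }
  out[present] <- canon
  out
}

genotype_from_code <- function(def, code) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 2L] <- paste(def$coded_allele, def$coded_allele, sep = "/")
  other <- setdiff(c(def$allele_a, def$allele_b), def$coded_allele)
  het <- paste(c(def$allele_a, def$allele_b), collapse = "/")
  out[!is.na(code) & code == 1L] <- het
  out[!is.na(code) & code == 0L] <- paste(other, other, sep = "/")
  out
}

outcome_columns <- function() {
  c("dgf", "early_dysfunction", "nodat", "rejection", "toxicity", "erythrocytosis")
}

observation_columns <- function() {
  as.vector(t(outer(c("weight_", "dose_", "c0_"), TIMEPOINTS, paste0)))
}

#' Construct a cohort object
#'
#' Bundles a patient table with the SNP panel definitions and validates the
#' combination: unique patient identifiers, plausible ages, known sex levels,
#' positive weights/doses, and genotype strings restricted to the defined
#' alleles (canonicalised so that "*3/*1" and "*1/*3" are the same call).
#'
#' @param patients Data frame with one row per patient. Required columns:
#'   `patient_id`, `age`, `sex`, one genotype column per SNP in `snp_defs`.
#'   Optional: per-timepoint `weight_*`, `dose_*`, `c0_*` columns
#'   (timepoints `day6`, `month6`, `year1`) and logical outcome flags
#'   `dgf`, `early_dysfunction`, `nodat`, `rejection`, `toxicity`,
#'   `erythrocytosis`.
#' @param snp_defs SNP panel, as returned by [snp_definitions()].
#' @return An object of class `tacro_cohort`: a list with elements
#'   `patients` (tibble) and `snp_defs`.
#' @export
new_cohort <- function(patients, snp_defs = snp_definitions()) {
  validate_snp_defs(snp_defs)
  patients <- tibble::as_tibble(patients)

  req <- c("patient_id", "age", "sex", snp_defs$snp_id)
  missing <- setdiff(req, names(patients))
  if (length(missing) > 0) {
    stop("cohort table lacks mandatory columns: ", paste(missing, collapse = ", "))
  }
  patients$patient_id <- as.character(patients$patient_id)
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_age <- !is.na(patients$age) & (patients$age <= 0 | patients$age >= 120)
  if (any(bad_age)) {
    stop("implausible age for patient ",
         paste(patients$patient_id[bad_age], collapse = ", "))
  }
  patients$sex <- parse_sex(patients$sex)

  for (id in snp_defs$snp_id) {
    patients[[id]] <- parse_genotype(as.character(patients[[id]]),
                                     snp_def(snp_defs, id), column = id)
  }
  for (col in observation_columns()) {
    if (!col %in% names(patients)) patients[[col]] <- NA_real_
    patients[[col]] <- as.numeric(patients[[col]])
    if (grepl("^(weight|dose)_", col)) {
      bad <- !is.na(patients[[col]]) & patients[[col]] <= 0
      if (any(bad)) {
        stop("nonpositive ", col, " for patient ",
             paste(patients$patient_id[bad], collapse = ", "))
      }
    }
  }
  for (col in outcome_columns()) {
    if (!col %in% names(patients)) patients[[col]] <- NA
    patients[[col]] <- parse_flag(patients[[col]], col)
  }

  structure(list(patients = patients, snp_defs = snp_defs),
            class = "tacro_cohort")
}

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "0")] <- "female"
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) stop("unrecognised sex value: ", x[which(bad)[1]], call. = FALSE)
  out
}

parse_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "no", "n")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unrecognised value in column '", col, "': ", x[which(bad)[1]],
         call. = FALSE)
  }
  out
}

#' Read a cohort table from a delimited file
#'
#' Reads a comma-delimited UTF-8 cohort table (one row per patient) and
#' validates it into a [new_cohort()] object. Genotypes are given as
#' slash-separated allele pairs in either order (`"*1/*3"` is the same call
#' as `"*3/*1"`); empty cells are recorded as missing, never dropped.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the standard column
#'   names (names) to the column names used in the file (values), for files
#'   whose headers differ from the packaged schema.
#' @param snp_defs SNP panel, see [snp_definitions()].
#' @return A `tacro_cohort`.
#' @seealso [write_cohort()]; a small synthetic example file (produced by
#'   [generate_cohort()]) ships as
#'   `system.file("extdata", "example_cohort.csv", package = "tacrodose")`.
#' @export
read_cohort <- function(path, schema = NULL, snp_defs = snp_definitions()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw)) {
        stop("schema maps '", std, "' to absent column '", schema[[std]], "'")
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  new_cohort(raw, snp_defs = snp_defs)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the patient table with canonical
#' genotype strings so that reading the file back reproduces the cohort.
#'
#' @param cohort A `tacro_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  write.csv(cohort$patients, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.tacro_cohort <- function(x, ...) {
  cat(sprintf("<tacro_cohort> %d patients, %d SNPs (%s)\n",
              nrow(x$patients), nrow(x$snp_defs),
              paste(x$snp_defs$snp_id, collapse = ", ")))
  for (tp in TIMEPOINTS) {
    n <- sum(!is.na(cohort_c0d(x, tp)))
    cat(sprintf("  %-7s C0/D available for %d patients\n", tp, n))
  }
  invisible(x)
}

#' Dose-adjusted trough concentration (C0/D)
#'
#' Divides the measured trough concentration by the weight-adjusted daily
#' dose: `C0 / (dose / weight)`, in (ng/ml)/(mg/kg/day).
#'
#' @param c0_ng_ml Trough concentration, ng/ml.
#' @param daily_dose_mg Total daily tacrolimus dose, mg/day.
#' @param weight_kg Body weight, kg.
#' @return Numeric vector of C0/D values; `NA` where any input is missing.
#' @export
#' @examples
#' compute_c0d(8, 4, 60)   # 120
compute_c0d <- function(c0_ng_ml, daily_dose_mg, weight_kg) {
  n <- max(length(c0_ng_ml), length(daily_dose_mg), length(weight_kg))
  c0_ng_ml <- rep_len(as.numeric(c0_ng_ml), n)
  daily_dose_mg <- rep_len(as.numeric(daily_dose_mg), n)
  weight_kg <- rep_len(as.numeric(weight_kg), n)
  if (any(!is.na(daily_dose_mg) & daily_dose_mg <= 0)) {
    stop("daily_dose_mg must be positive")
  }
  if (any(!is.na(weight_kg) & weight_kg <= 0)) {
    stop("weight_kg must be positive")
  }
  c0_ng_ml * weight_kg / daily_dose_mg
}

#' Per-patient C0/D at one timepoint
#'
#' @param cohort A `tacro_cohort`.
#' @param timepoint One of `"day6"`, `"month6"`, `"year1"`.
#' @return Numeric vector aligned with `cohort$patients`, `NA` where the
#'   observation is incomplete.
#' @export
cohort_c0d <- function(cohort, timepoint = "day6") {
  stopifnot(inherits(cohort, "tacro_cohort"))
  timepoint <- the_timepoint(timepoint)
  p <- cohort$patients
  compute_c0d(p[[paste0("c0_", timepoint)]],
              p[[paste0("dose_", timepoint)]],
              p[[paste0("weight_", timepoint)]])
}

#' Exclude patients unsuitable for C0/D association analysis
#'
#' Removes patients with delayed graft function or early graft dysfunction
#' within the first post-transplant week, whose treatment can distort
#' tacrolimus levels. The input cohort is not modified; counts removed per
#' criterion are reported via `message()` unless `quiet = TRUE`.
#'
#' @param cohort A `tacro_cohort`.
#' @param quiet Suppress the log message.
#' @return The filtered `tacro_cohort`. Idempotent.
#' @export
filter_for_association <- function(cohort, quiet = FALSE) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  p <- cohort$patients
  dgf <- !is.na(p$dgf) & p$dgf
  early <- !is.na(p$early_dysfunction) & p$early_dysfunction
  drop <- dgf | early
  if (!quiet) {
    message(sprintf(
      "filter_for_association: removed %d/%d patients (%d delayed graft function, %d early graft dysfunction)",
      sum(drop), nrow(p), sum(dgf), sum(early)))
  }
  out <- cohort
  out$patients <- p[!drop, , drop = FALSE]
  out
}

#' Additive genotype codes for one SNP
#'
#' Encodes each patient's genotype as the number of copies (0/1/2) of the
#' SNP's coded allele — for CYP3A5 (rs776746) the functional *1 allele, so
#' *3/*3 maps to 0, *1/*3 to 1 and *1/*1 to 2. Missing genotypes propagate
#' as `NA`; patients are never dropped.
#'
#' @param cohort A `tacro_cohort`.
#' @param snp_id One of the panel's SNP identifiers.
#' @return Integer vector aligned with `cohort$patients`.
#' @export
#' @examples
#' coh <- generate_cohort(default_study_config(n_patients = 20, seed = 1))
#' encode_genotypes(coh, "rs776746")
encode_genotypes <- function(cohort, snp_id) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  def <- snp_def(cohort$snp_defs, snp_id)
  geno <- cohort$patients[[snp_id]]
  codes <- rep(NA_integer_, length(geno))
  present <- !is.na(geno)
  if (any(present)) {
    parts <- strsplit(geno[present], "/", fixed = TRUE)
    codes[present] <- vapply(parts, function(p) sum(p == def$coded_allele), 1L)
  }
  codes
}

#' CYP3A5 expressor status
#'
#' Patients carrying at least one functional CYP3A5 *1 allele at rs776746
#' are expressors; *3/*3 homozygotes are non-expressors.
#'
#' @param cohort A `tacro_cohort`.
#' @return Factor with levels `"non-expressor"`, `"expressor"`; `NA` when
#'   the rs776746 genotype is missing.
#' @export
expressor_status <- function(cohort) {
  code <- encode_genotypes(cohort, "rs776746")
  factor(ifelse(is.na(code), NA_character_,
                ifelse(code >= 1L, "expressor", "non-expressor")),
         levels = c("non-expressor", "expressor"))
}
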