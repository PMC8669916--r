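# Default covariate set for the day-6 C0/D regression: age, male sex, and
# the additive codes of the five panel SNPs.
default_covariates <- function() {
  c("age", "male", "rs776746", "rs1045642", "rs2032582", "rs2242480",
    "rs2740574")
}

covariate_matrix <- function(cohort, covariates) {
  p <- cohort$patients
  cols <- lapply(covariates, function(v) {
    if (v == "age") {
      as.numeric(p$age)
    } else if (v == "male") {
      as.numeric(p$sex == "male")
    } else if (v %in% cohort$snp_defs$snp_id) {
      as.numeric(encode_genotypes(cohort, v))
    } else if (v %in% names(p)) {
      as.numeric(p[[v]])
    } else {
      stop("unknown covariate: ", v)
    }
  })
  names(cols) <- covariates
  tibble::as_tibble(cols)
}

#' Multivariable linear model for dose-adjusted trough concentration
#'
#' Fits ordinary least squares of C0/D at one timepoint on a constant plus
#' the requested covariates (default: age, male sex, and additive genotype
#' codes for CYP3A5*3, ABCB1 C3435T, ABCB1 G2677T, CYP3A4*1G, CYP3A4*1B).
#' Complete cases only; classical standard errors; 95% confidence intervals
#' from the Student-t distribution on `n - k` degrees of freedom.
#'
#' Covariates that are constant in the analysis sample are dropped with a
#' warning (they cannot be estimated alongside the intercept); a
#' rank-deficient design among the remaining columns is an error naming the
#' collinear terms.
#'
#' @param cohort A `tacro_cohort`, typically after
#'   [filter_for_association()].
#' @param timepoint `"day6"` (default), `"month6"` or `"year1"`.
#' @param covariates Character vector of covariate names.
#' @param conf_level Confidence level for the per-term intervals.
#' @return Object of class `c0d_fit`: `table` (tibble with `term`,
#'   `estimate`, `std_error`, `ci_low`, `ci_high`, `p_value`), `r_squared`,
#'   `n_used`, `timepoint`, `dropped` (constant covariates removed), and the
#'   underlying `lm` object as `$lm`.
#' @export
fit_c0d_model <- function(cohort, timepoint = "day6",
                          covariates = default_covariates(),
                          conf_level = 0.95) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  timepoint <- the_timepoint(timepoint)
  df <- covariate_matrix(cohort, covariates)
  df$c0d <- cohort_c0d(cohort, timepoint)
  df <- df[complete.cases(df), , drop = FALSE]

  dropped <- character(0)
  for (v in covariates) {
    if (length(unique(df[[v]])) < 2) {
      dropped <- c(dropped, v)
      df[[v]] <- NULL
    }
  }
  if (length(dropped) > 0) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  k <- ncol(df)  # remaining covariates + response; model has k terms w/ intercept
  if (nrow(df) < k + 1) {
    stop("too few complete cases (", nrow(df), ") for ", k - 1, " covariates")
  }

  fit <- lm(c0d ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  ci <- confint(fit, level = conf_level)
  coefs <- sm$coefficients
  table <- tibble::tibble(
    term = rownames(coefs),
    estimate = unname(coefs[, "Estimate"]),
    std_error = unname(coefs[, "Std. Error"]),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2]),
    p_value = unname(coefs[, "Pr(>|t|)"])
  )
  structure(list(table = table, r_squared = sm$r.squared,
                 n_used = nrow(df), timepoint = timepoint,
                 dropped = dropped, conf_level = conf_level, lm = fit),
            class = "c0d_fit")
}

#' @export
print.c0d_fit <- function(x, ...) {
  cat(sprintf("Linear model for %s C0/D (n = %d)\n", x$timepoint, x$n_used))
  print(x$table)
  cat(sprintf("  R-squared = %.3f\n", x$r_squared))
  if (length(x$dropped)) {
    cat("  dropped constant covariates:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict C0/D from a fitted model
#'
#' Evaluates the linear predictor of a [fit_c0d_model()] fit at new
#' covariate values — either a `tacro_cohort` (one prediction per patient,
#' `NA` where a covariate is missing) or a data frame of covariate columns.
#'
#' @param fit A `c0d_fit`.
#' @param newdata A `tacro_cohort` or a data frame with one column per
#'   model covariate.
#' @return Numeric vector of predicted C0/D values.
#' @export
predict_c0d <- function(fit, newdata) {
  stopifnot(inherits(fit, "c0d_fit"))
  vars <- setdiff(names(fit$lm$model), "c0d")
  if (inherits(newdata, "tacro_cohort")) {
    df <- covariate_matrix(newdata, vars)
  } else {
    df <- as.data.frame(newdata)
    missing <- setdiff(vars, names(df))
    if (length(missing) > 0) {
      stop("missing covariate(s): ", paste(missing, collapse = ", "))
    }
  }
  as.numeric(predict(fit$lm, newdata = df))
}

# Round half away from zero: 40.5 -> 41, -40.5 -> -41. (base::round rounds
# half to even, which would map 158.5 to 158.)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Genotype-guided starting-dose equation
#'
#' Builds the integer-rounded dosing rule
#' `required dose/kg = desired C0 / (intercept - coef x CYP3A5 code)` from a
#' fitted constant and CYP3A5 coefficient. With the published day-6 fit
#' (constant 158.74, CYP3A5 coefficient -40.48) this yields
#' `desired C0 / (159 - 40 x code)`, where the code counts CYP3A5 *1
#' alleles (0 for *3/*3, 1 for *1/*3, 2 for *1/*1).
#'
#' Rounding is half-away-from-zero to the nearest integer. The denominator
#' must be positive at every genotype code 0, 1 and 2.
#'
#' @param constant Fitted model constant, (ng/ml)/(mg/kg).
#' @param cyp3a5_beta Fitted CYP3A5 coefficient (per *1 allele; negative
#'   when expressors clear the drug faster).
#' @return Object of class `dosing_equation`: `intercept_const`,
#'   `genotype_coef` (both integers).
#' @export
#' @examples
#' dosing_equation(158.74, -40.48)  # 159 and 40
dosing_equation <- function(constant, cyp3a5_beta) {
  intercept_const <- unname(round_half_away(constant))
  genotype_coef <- unname(round_half_away(-cyp3a5_beta))
  denom <- intercept_const - genotype_coef * (0:2)
  if (any(denom <= 0)) {
    stop(sprintf(
      "dosing equation denominator not positive at genotype code %d (%g)",
      which(denom <= 0)[1] - 1L, denom[denom <= 0][1]))
  }
  structure(list(intercept_const = intercept_const,
                 genotype_coef = genotype_coef),
            class = "dosing_equation")
}

#' Derive the dosing equation from a fitted C0/D model
#'
#' Extracts the constant and the CYP3A5 term from a [fit_c0d_model()] fit
#' and rounds them into a [dosing_equation()].
#'
#' @param fit A `c0d_fit` containing an intercept and a CYP3A5 term.
#' @param cyp3a5_term Name of the CYP3A5 covariate in the fit.
#' @return A `dosing_equation`.
#' @export
derive_dosing_equation <- function(fit, cyp3a5_term = "rs776746") {
  stopifnot(inherits(fit, "c0d_fit"))
  tab <- fit$table
  if (!"(Intercept)" %in% tab$term) stop("fit has no constant term")
  if (!cyp3a5_term %in% tab$term) {
    stop("cannot derive dosing equation: no CYP3A5 term ('", cyp3a5_term,
         "') in the fit")
  }
  eq <- dosing_equation(tab$estimate[tab$term == "(Intercept)"],
                        tab$estimate[tab$term == cyp3a5_term])
  eq$source_fit <- fit
  eq
}

#' @export
print.dosing_equation <- function(x, ...) {
  cat("Genotype-guided tacrolimus starting dose\n")
  cat(sprintf(
    "  required dose (mg/kg/day) = desired day-6 C0 / (%d - %d x CYP3A5 *1-allele count)\n",
    x$intercept_const, x$genotype_coef))
  cat(sprintf("  denominators: code 0 -> %d, code 1 -> %d, code 2 -> %d\n",
              x$intercept_const, x$intercept_const - x$genotype_coef,
              x$intercept_const - 2 * x$genotype_coef))
  invisible(x)
}

#' Required weight-adjusted starting dose for a target trough level
#'
#' Inverts the dosing equation: the daily dose per kg needed for a desired
#' day-6 trough concentration, given the patient's CYP3A5 *1-allele count.
#' The dose is nondecreasing in the genotype code (expressors need more
#' drug) and linear in the target level. No clamping to protocol limits is
#' applied.
#'
#' @param eq A `dosing_equation`.
#' @param desired_c0 Target day-6 trough concentration, ng/ml (> 0).
#' @param genotype_code CYP3A5 *1-allele count: 0, 1 or 2 (vectorised).
#' @return Dose in mg/kg/day.
#' @export
#' @examples
#' eq <- dosing_equation(158.74, -40.48)
#' required_dose_per_kg(eq, desired_c0 = 7.95, genotype_code = 0)  # 0.05
required_dose_per_kg <- function(eq, desired_c0, genotype_code) {
  stopifnot(inherits(eq, "dosing_equation"))
  if (any(is.na(desired_c0)) || any(desired_c0 <= 0)) {
    stop("desired_c0 must be positive")
  }
  if (any(is.na(genotype_code)) || any(!genotype_code %in% 0:2)) {
    stop("genotype_code must be 0, 1 or 2")
  }
  desired_c0 / (eq$intercept_const - eq$genotype_coef * genotype_code)
}
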