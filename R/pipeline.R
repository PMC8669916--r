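#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: an input cohort CSV (or a
#' generator configuration when no file is given), the timepoints and
#' covariates to analyse, the output directory, and the analysis toggles
#' (which default to the choices that reproduce the published tables:
#' no continuity correction, equal-variance t-tests).
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param outdir Output directory (created if absent).
#' @param timepoints Timepoints to analyse.
#' @param covariates Covariates for the C0/D regression.
#' @param outcomes Named character vector: outcome column -> exposed group
#'   (`"non-expressor"` or `"expressor"`) for the 2x2 tables.
#' @param desired_c0 Optional target day-6 trough (ng/ml); when given, the
#'   dosing report includes per-genotype doses for this target.
#' @param seed Seed recorded in the log and passed to the generator.
#' @param yates Apply the Yates continuity correction to 2x2 chi-squares.
#' @param welch Use Welch t-tests for two-group C0/D comparisons.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = default_study_config(),
                            outdir = "tacrodose_report",
                            timepoints = "day6",
                            covariates = default_covariates(),
                            outcomes = c(nodat = "non-expressor",
                                         rejection = "expressor",
                                         toxicity = "non-expressor"),
                            desired_c0 = NULL, seed = NULL,
                            yates = FALSE, welch = FALSE) {
  timepoints <- vapply(timepoints, the_timepoint, character(1))
  structure(list(input = input, generator = generator, outdir = outdir,
                 timepoints = unname(timepoints), covariates = covariates,
                 outcomes = outcomes, desired_c0 = desired_c0, seed = seed,
                 yates = yates, welch = welch),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the fields of [pipeline_config()] as top-level YAML keys;
#' `generator` may itself be a mapping of [generator_config()] overrides
#' (e.g. `n_patients`, `seed`, `dgf_prob`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  gen <- if (is.null(gen_args)) default_study_config()
         else do.call(default_study_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  if (!is.null(args$outcomes)) args$outcomes <- unlist(args$outcomes)
  do.call(pipeline_config, c(args, list(generator = gen)))
}

write_report_table <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full genotype-to-dose pipeline
#'
#' Sequences the analysis end to end: read (or simulate) the cohort, apply
#' the association-analysis exclusions, summarise genotype/allele
#' frequencies with Hardy-Weinberg tests, compute all pairwise LD, test
#' genotype-C0/D associations per SNP and for expressor status, build the
#' outcome 2x2 tables, fit the day-6 C0/D regression, and derive the
#' genotype-guided dosing equation. Writes `snp_summary.tsv`, `ld.tsv`,
#' `association_c0d.tsv`, `outcomes_2x2.tsv`, `regression.tsv`,
#' `dosing_equation.txt` and `run.log` into `config$outdir`, each table
#' prefixed with a comment line recording the package version and the
#' configuration hash. If the dosing equation cannot be derived (e.g. a
#' monomorphic CYP3A5 locus), `dosing_equation.txt` records the reason
#' instead of aborting the run.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the report bundle: a list with the cohort, every
#'   intermediate result object, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(packageVersion("tacrodose"))
  cfg <- unclass(config)
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "outdir")])
  header <- sprintf("# tacrodose %s config_hash=%s", version, cfg_hash)
  log_lines <- c(header, sprintf("# seed=%s",
                                 if (is.null(config$seed)) "NA" else config$seed))
  log <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }

  cohort <- run_stage("input", {
    if (!is.null(config$input)) {
      log("input: read %s", config$input)
      read_cohort(config$input)
    } else {
      gen <- config$generator
      if (!is.null(config$seed)) gen$seed <- as.integer(config$seed)
      log("input: simulated cohort (n=%d, seed=%d)", gen$n_patients, gen$seed)
      generate_cohort(gen)
    }
  })
  log("cohort: %d patients", nrow(cohort$patients))

  filtered <- run_stage("filter", {
    msg <- character(0)
    fc <- withCallingHandlers(
      filter_for_association(cohort),
      message = function(m) {
        msg <<- c(msg, conditionMessage(m)); invokeRestart("muffleMessage")
      })
    log("%s", trimws(paste(msg, collapse = " ")))
    fc
  })
  log("association cohort: %d patients", nrow(filtered$patients))

  summary_tbl <- run_stage("snp_summary", snp_summary(filtered))
  ld_tbl <- run_stage("ld", ld_pairs(filtered))

  assoc_rows <- run_stage("association", {
    rows <- list()
    for (tp in config$timepoints) {
      for (by in c(filtered$snp_defs$snp_id, "expressor")) {
        gc <- tryCatch(group_c0d(filtered, by, tp, welch = config$welch),
                       error = function(e) NULL)
        if (is.null(gc)) {
          log("association: %s at %s skipped (insufficient groups)", by, tp)
          next
        }
        g <- gc$groups
        rows[[length(rows) + 1L]] <- tibble::tibble(
          timepoint = tp, grouping = gc$grouping, group = g$label,
          n = g$n, mean_c0d = g$mean, sd_c0d = g$sd, test = gc$test,
          statistic = gc$statistic, p = gc$p)
      }
    }
    do.call(rbind, rows)
  })

  outcome_rows <- run_stage("outcomes", {
    rows <- lapply(names(config$outcomes), function(oc) {
      tb <- two_by_two_outcome(filtered, oc,
                               exposed = config$outcomes[[oc]],
                               correct = config$yates)
      tibble::tibble(outcome = oc, exposed = config$outcomes[[oc]],
                     a = tb$a, b = tb$b, c = tb$c, d = tb$d,
                     odds_ratio = tb$odds_ratio, ci_low = tb$ci_low,
                     ci_high = tb$ci_high, chi2 = tb$chi2, p = tb$p,
                     haldane = tb$haldane)
    })
    do.call(rbind, rows)
  })

  fit <- run_stage("regression", {
    f <- withCallingHandlers(
      fit_c0d_model(filtered, timepoint = "day6",
                    covariates = config$covariates),
      warning = function(w) {
        log("regression: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log("regression: n=%d, R-squared=%.3f", f$n_used, f$r_squared)
    f
  })

  eq <- tryCatch(derive_dosing_equation(fit), error = function(e) e)

  paths <- list(
    snp_summary = file.path(config$outdir, "snp_summary.tsv"),
    ld = file.path(config$outdir, "ld.tsv"),
    association_c0d = file.path(config$outdir, "association_c0d.tsv"),
    outcomes_2x2 = file.path(config$outdir, "outcomes_2x2.tsv"),
    regression = file.path(config$outdir, "regression.tsv"),
    dosing_equation = file.path(config$outdir, "dosing_equation.txt"),
    run_log = file.path(config$outdir, "run.log")
  )
  write_report_table(summary_tbl, paths$snp_summary, header)
  write_report_table(ld_tbl, paths$ld, header)
  write_report_table(assoc_rows, paths$association_c0d, header)
  write_report_table(outcome_rows, paths$outcomes_2x2, header)
  reg_tbl <- fit$table
  reg_tbl$r_squared <- fit$r_squared
  reg_tbl$n_used <- fit$n_used
  write_report_table(reg_tbl, paths$regression, header)

  eq_lines <- c(header)
  if (inherits(eq, "error")) {
    log("dosing equation: not derived (%s)", conditionMessage(eq))
    eq_lines <- c(eq_lines, paste("dosing equation not derived:",
                                  conditionMessage(eq)))
    eq <- NULL
  } else {
    eq_lines <- c(eq_lines, sprintf(
      "required dose (mg/kg/day) = desired day-6 C0 / (%d - %d x CYP3A5 *1-allele count)",
      eq$intercept_const, eq$genotype_coef))
    if (!is.null(config$desired_c0)) {
      dose <- required_dose_per_kg(eq, config$desired_c0, 0:2)
      eq_lines <- c(eq_lines, sprintf(
        "target C0 %.2f ng/ml: code %d -> %.4f mg/kg/day",
        config$desired_c0, 0:2, dose))
    }
  }
  writeLines(eq_lines, paths$dosing_equation)
  writeLines(log_lines, paths$run_log)

  invisible(list(cohort = cohort, filtered = filtered,
                 snp_summary = summary_tbl, ld = ld_tbl,
                 association = assoc_rows, outcomes = outcome_rows,
                 fit = fit, equation = eq, paths = paths,
                 log = log_lines))
}
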