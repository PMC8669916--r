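#' Compare C0/D across genotype groups
#'
#' Summarises dose-adjusted trough concentration (mean, SD, n) per genotype
#' group at one timepoint and tests for a group difference: a two-sided
#' independent-samples t-test for two groups (equal variances by default,
#' Welch optionally) or a one-way ANOVA for three. Groups with fewer than
#' two observations are excluded from the test and flagged.
#'
#' @param cohort A `tacro_cohort`, already passed through
#'   [filter_for_association()] where appropriate.
#' @param by A panel SNP id (groups = genotypes, ordered by coded-allele
#'   count) or `"expressor"` (CYP3A5 non-expressor vs expressor).
#' @param timepoint `"day6"`, `"month6"` or `"year1"`.
#' @param welch Use the Welch (unequal-variance) t-test for two groups.
#' @return Object of class `group_comparison`: `groups` (tibble with
#'   `label`, `n`, `mean`, `sd`), `test` (`"t_test"` or `"anova"`),
#'   `statistic`, `df`, `p`, `excluded` (labels of too-small groups).
#' @export
group_c0d <- function(cohort, by, timepoint = "day6", welch = FALSE) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  timepoint <- the_timepoint(timepoint)
  c0d <- cohort_c0d(cohort, timepoint)

  if (identical(by, "expressor")) {
    grp <- expressor_status(cohort)
  } else {
    def <- snp_def(cohort$snp_defs, by)
    code <- encode_genotypes(cohort, by)
    labels <- genotype_from_code(def, 0:2)
    grp <- factor(labels[code + 1L], levels = labels)
  }
  keep <- !is.na(c0d) & !is.na(grp)
  c0d <- c0d[keep]
  grp <- droplevels(grp[keep])
  if (nlevels(grp) < 2) stop("need at least 2 nonempty groups")

  groups <- tibble::tibble(
    label = levels(grp),
    n = as.integer(table(grp)),
    mean = as.numeric(tapply(c0d, grp, mean)),
    sd = as.numeric(tapply(c0d, grp, sd))
  )
  small <- groups$label[groups$n < 2]
  use <- !(as.character(grp) %in% small)
  gg <- droplevels(grp[use])
  yy <- c0d[use]

  if (nlevels(gg) < 2) {
    test <- NA_character_; statistic <- NA_real_; df <- NA_real_; p <- NA_real_
  } else if (nlevels(gg) == 2) {
    tt <- t.test(yy ~ gg, var.equal = !welch)
    test <- "t_test"; statistic <- unname(tt$statistic)
    df <- unname(tt$parameter); p <- tt$p.value
  } else {
    av <- summary(aov(yy ~ gg))[[1]]
    test <- "anova"; statistic <- av[["F value"]][1]
    df <- c(av[["Df"]][1], av[["Df"]][2]); p <- av[["Pr(>F)"]][1]
  }

  structure(list(grouping = if (identical(by, "expressor")) "expressor" else by,
                 timepoint = timepoint, groups = groups, test = test,
                 statistic = statistic, df = df, p = p, excluded = small,
                 welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("C0/D by %s (%s)\n", x$grouping, x$timepoint))
  print(x$groups)
  if (length(x$excluded)) {
    cat("  excluded from test (n < 2):", paste(x$excluded, collapse = ", "), "\n")
  }
  if (!is.na(x$test)) {
    stat_lab <- if (x$test == "t_test") "t" else "F"
    cat(sprintf("  %s: %s = %.3f, p = %.4g\n", x$test, stat_lab,
                x$statistic, x$p))
  }
  invisible(x)
}

#' Odds ratio with Woolf confidence interval and Pearson chi-square
#'
#' Analyses a 2x2 exposure-by-outcome table. The odds ratio is
#' `(a d)/(b c)`; its 95% Woolf interval is
#' `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; the association
#' p-value comes from the Pearson chi-square on one degree of freedom,
#' without continuity correction unless `correct = TRUE`. When a cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied to
#' the odds ratio and interval, and the result is flagged.
#'
#' @param a,b,c,d Cell counts: `a` exposed with outcome, `b` exposed
#'   without, `c` unexposed with outcome, `d` unexposed without.
#' @param correct Apply the Yates continuity correction to the chi-square.
#' @param conf_level Confidence level of the Woolf interval.
#' @return Object of class `two_by_two`: the counts, `odds_ratio`,
#'   `ci_low`, `ci_high`, `chi2`, `p`, `haldane` flag.
#' @export
#' @examples
#' two_by_two(39, 30, 28, 48)  # OR 2.23, p 0.018
two_by_two <- function(a, b, c, d, correct = FALSE, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  odds_ratio <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se_log <- sqrt(sum(1 / cc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- unname(exp(log(odds_ratio) + c(-1, 1) * z * se_log))

  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(m, correct = correct))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(a = a, b = b, c = c, d = d,
                 odds_ratio = unname(odds_ratio),
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
                 chi2 = chi2, p = p, haldane = haldane, correct = correct),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 association\n")
  cat(sprintf("  counts: a=%d b=%d c=%d d=%d%s\n", x$a, x$b, x$c, x$d,
              if (x$haldane) " (Haldane-Anscombe +0.5 applied to OR)" else ""))
  cat(sprintf("  OR = %.3f (%.0f%% Woolf CI %.3f-%.3f)\n",
              x$odds_ratio, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  Pearson chi2 = %.3f, p = %.4g%s\n", x$chi2, x$p,
              if (x$correct) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Outcome-by-expressor-status 2x2 analysis
#'
#' Cross-tabulates a binary post-transplant outcome against CYP3A5
#' expressor status and delegates to [two_by_two()]. `exposed` selects which
#' status forms the exposure rows, i.e. the group whose odds the ratio
#' refers to (non-expressors for NODAT, expressors for rejection, matching
#' the usual at-risk presentation).
#'
#' @param cohort A `tacro_cohort`.
#' @param outcome One of `"nodat"`, `"rejection"`, `"toxicity"`,
#'   `"erythrocytosis"`, `"dgf"`, `"early_dysfunction"`.
#' @param exposed `"non-expressor"` or `"expressor"`.
#' @inheritParams two_by_two
#' @return A `two_by_two` object.
#' @export
two_by_two_outcome <- function(cohort, outcome,
                               exposed = c("non-expressor", "expressor"),
                               correct = FALSE) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  exposed <- match.arg(exposed)
  if (!outcome %in% outcome_columns()) stop("unknown outcome: ", outcome)
  status <- expressor_status(cohort)
  y <- cohort$patients[[outcome]]
  keep <- !is.na(status) & !is.na(y)
  status <- status[keep]
  y <- y[keep]
  exp_row <- status == exposed
  two_by_two(sum(exp_row & y), sum(exp_row & !y),
             sum(!exp_row & y), sum(!exp_row & !y), correct = correct)
}
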