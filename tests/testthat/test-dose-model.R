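test_that("noiseless linear data are recovered exactly", {
  geno <- rep(c("*3/*3", "*1/*3", "*1/*1"), each = 8)
  code <- rep(0:2, each = 8)
  c0d <- 100 - 40 * code
  coh <- make_c0d_cohort(c0d, geno)
  # summary.lm warns about the essentially perfect fit; that is the point
  fit <- suppressWarnings(fit_c0d_model(coh, covariates = "rs776746"))
  expect_equal(fit$table$estimate[fit$table$term == "(Intercept)"], 100,
               tolerance = 1e-10)
  expect_equal(fit$table$estimate[fit$table$term == "rs776746"], -40,
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to every covariate", {
  coh <- generate_cohort(default_study_config(n_patients = 300, seed = 19))
  coh <- suppressMessages(filter_for_association(coh))
  fit <- fit_c0d_model(coh)
  X <- stats::model.matrix(fit$lm)
  r <- stats::residuals(fit$lm)
  scale <- sum(abs(r)) * max(abs(X))
  expect_lt(max(abs(crossprod(X, r))), 1e-8 * scale)
})

test_that("type-I coverage: pure-noise response gives small R2 and ~95% CI coverage of 0", {
  set.seed(29)
  base <- generate_cohort(default_study_config(n_patients = 200, seed = 29,
                                               dgf_prob = 0,
                                               early_dysfunction_prob = 0))
  reps <- 250
  covered <- 0L
  slots <- 0L
  r2 <- numeric(reps)
  for (r in seq_len(reps)) {
    coh <- base
    coh$patients$c0_day6 <- rnorm(200) *
      coh$patients$dose_day6 / coh$patients$weight_day6
    fit <- fit_c0d_model(coh)
    tab <- fit$table[fit$table$term != "(Intercept)", ]
    covered <- covered + sum(tab$ci_low <= 0 & tab$ci_high >= 0)
    slots <- slots + nrow(tab)
    r2[r] <- fit$r_squared
  }
  expect_equal(covered / slots, 0.95, tolerance = 0.02)
  expect_lt(mean(r2), 0.1)
})

test_that("rank-deficient designs and undersized samples fail informatively", {
  coh <- generate_cohort(default_study_config(n_patients = 100, seed = 31))
  p <- coh$patients
  p$dup <- as.numeric(p$age)  # exact copy of age
  coh$patients <- p
  expect_error(fit_c0d_model(coh, covariates = c("age", "dup")),
               "collinear.*dup")

  small <- coh
  small$patients <- small$patients[1:5, ]
  expect_error(suppressWarnings(fit_c0d_model(small)),
               "too few complete cases")
})

test_that("constant covariates are dropped with a warning, not silently absorbed", {
  geno <- rep(c("*3/*3", "*1/*3"), each = 10)
  coh <- make_c0d_cohort(100 - 40 * rep(0:1, each = 10) + rnorm(20),
                         geno)  # age is constant in this fixture
  expect_warning(fit <- fit_c0d_model(coh, covariates = c("age", "rs776746")),
                 "constant covariate.*age")
  expect_false("age" %in% fit$table$term)
})

test_that("rounding the published fit yields the integer dosing equation", {
  eq <- dosing_equation(158.74, -40.48)
  expect_equal(eq$intercept_const, 159)
  expect_equal(eq$genotype_coef, 40)

  # integers pass through; rounding is half away from zero
  eq2 <- dosing_equation(100, -10)
  expect_equal(c(eq2$intercept_const, eq2$genotype_coef), c(100, 10))
  eq3 <- dosing_equation(158.5, -40.5)
  expect_equal(c(eq3$intercept_const, eq3$genotype_coef), c(159, 41))

  # denominator must stay positive at every genotype code
  expect_error(dosing_equation(79, -40), "not positive at genotype code 2")
})

test_that("derive_dosing_equation pulls the constant and CYP3A5 term from a fit", {
  set.seed(37)
  code <- rep(0:2, each = 30)
  geno <- rep(c("*3/*3", "*1/*3", "*1/*1"), each = 30)
  coh <- make_c0d_cohort(158.74 - 40.48 * code + rnorm(90, 0, 1e-6), geno)
  fit <- suppressWarnings(fit_c0d_model(coh, covariates = "rs776746"))
  eq <- derive_dosing_equation(fit)
  expect_equal(eq$intercept_const, 159)
  expect_equal(eq$genotype_coef, 40)

  coh2 <- make_c0d_cohort(158.74 - 40.48 * code + rnorm(90), geno,
                          age = 25 + seq_len(90) / 3)
  fit_no <- fit_c0d_model(coh2, covariates = "age")
  expect_error(derive_dosing_equation(fit_no), "no CYP3A5 term")
})

test_that("required dose is exact arithmetic, monotone in genotype, linear in target", {
  eq <- dosing_equation(158.74, -40.48)
  expect_equal(required_dose_per_kg(eq, 7.95, 0), 0.05)
  expect_equal(required_dose_per_kg(eq, 8, 2), 8 / 79)

  doses <- required_dose_per_kg(eq, 8.5, 0:2)
  expect_true(all(diff(doses) > 0))
  expect_equal(required_dose_per_kg(eq, 2 * 8.5, 0:2), 2 * doses)

  expect_error(required_dose_per_kg(eq, -1, 0), "positive")
  expect_error(required_dose_per_kg(eq, 8, 3), "genotype_code")
})

test_that("dosing a model-mean patient returns the desired trough up to rounding error", {
  eq <- dosing_equation(158.74, -40.48)
  target <- 8.5
  for (g in 0:2) {
    dose <- required_dose_per_kg(eq, target, g)
    implied_c0 <- dose * (158.74 - 40.48 * g)  # noise-free generative C0/D
    ratio <- (158.74 - 40.48 * g) / (159 - 40 * g)
    expect_equal(implied_c0, target * ratio, tolerance = 1e-12)
    expect_lt(abs(implied_c0 / target - 1), 0.02)
  }
})

test_that("predictions satisfy the OLS identities", {
  coh <- generate_cohort(default_study_config(n_patients = 200, seed = 41))
  coh <- suppressMessages(filter_for_association(coh))
  fit <- fit_c0d_model(coh)

  # prediction at the sample covariate means equals the sample mean response
  mm <- fit$lm$model
  at_means <- as.data.frame(as.list(colMeans(mm[setdiff(names(mm), "c0d")])))
  expect_equal(predict_c0d(fit, at_means), mean(mm$c0d), tolerance = 1e-8)

  # all-zero covariates return the constant; a unit CYP3A5 step moves the
  # prediction by the CYP3A5 coefficient
  zero <- at_means
  zero[] <- 0
  beta <- setNames(fit$table$estimate, fit$table$term)
  expect_equal(predict_c0d(fit, zero), unname(beta["(Intercept)"]),
               tolerance = 1e-8)
  one <- zero
  one$rs776746 <- 1
  expect_equal(predict_c0d(fit, one) - predict_c0d(fit, zero),
               unname(beta["rs776746"]), tolerance = 1e-8)

  expect_error(predict_c0d(fit, data.frame(age = 30)), "missing covariate")
})

test_that("refitting simulated cohorts recovers the generative coefficients without bias", {
  set.seed(43)
  reps <- 120
  est <- numeric(reps)
  cfg <- default_study_config(n_patients = 92, seed = 1,
                              c0d_model = "regression",
                              missing_probs = c(rs776746 = 0, rs2242480 = 0,
                                                rs2740574 = 0, rs2032582 = 0,
                                                rs1045642 = 0))
  seeds <- sample.int(.Machine$integer.max, reps)
  for (r in seq_len(reps)) {
    coh <- generate_cohort(cfg, seed = seeds[r])
    fit <- suppressWarnings(fit_c0d_model(coh))
    est[r] <- fit$table$estimate[fit$table$term == "rs776746"]
  }
  # Monte-Carlo standard error ~ se(beta)/sqrt(reps) ~ 14/sqrt(120) ~ 1.3
  expect_equal(mean(est), -40.48, tolerance = 3)
})
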