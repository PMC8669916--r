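test_that("published outcome 2x2 tables are reproduced exactly", {
  nodat <- two_by_two(39, 30, 28, 48)  # non-expressor rows, NODAT yes/no
  expect_equal(nodat$odds_ratio, 2.22, tolerance = 0.005)
  expect_equal(nodat$ci_low, 1.14, tolerance = 0.005)
  expect_equal(nodat$ci_high, 4.33, tolerance = 0.005)
  expect_lt(abs(nodat$p - 0.018), 5e-4)

  rejection <- two_by_two(24, 52, 11, 58)  # expressor rows
  expect_equal(rejection$odds_ratio, 2.43, tolerance = 0.005)
  expect_lt(abs(rejection$p - 0.028), 5e-4)

  toxicity <- two_by_two(22, 46, 18, 57)
  expect_equal(toxicity$odds_ratio, 1.51, tolerance = 0.005)
  expect_gt(toxicity$p, 0.05)
})

test_that("symmetric tables show no association", {
  x <- two_by_two(10, 10, 10, 10)
  expect_equal(x$odds_ratio, 1)
  expect_equal(x$p, 1)
  expect_lt(x$ci_low, 1)
  expect_gt(x$ci_high, 1)
})

test_that("swapping exposure rows inverts the OR but leaves chi-square unchanged", {
  set.seed(7)
  for (rep in 1:5) {
    cells <- rpois(4, 20) + 1
    x <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    y <- two_by_two(cells[3], cells[4], cells[1], cells[2])
    expect_equal(y$odds_ratio, 1 / x$odds_ratio, tolerance = 1e-12)
    expect_equal(y$chi2, x$chi2, tolerance = 1e-12)
    expect_equal(y$p, x$p, tolerance = 1e-12)
    # Woolf CI brackets the point estimate
    expect_lte(x$ci_low, x$odds_ratio)
    expect_gte(x$ci_high, x$odds_ratio)
  }
})

test_that("Woolf CI width shrinks as all cells scale up", {
  widths <- sapply(c(1, 2, 5, 10), function(k) {
    x <- two_by_two(8 * k, 12 * k, 6 * k, 14 * k)
    log(x$ci_high) - log(x$ci_low)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("zero cells trigger the Haldane-Anscombe correction with a flag", {
  x <- two_by_two(0, 20, 10, 10)
  expect_true(x$haldane)
  expect_equal(x$odds_ratio, (0.5 * 10.5) / (20.5 * 10.5))
  expect_true(is.finite(x$ci_low) && is.finite(x$ci_high))
})

test_that("Yates correction is available but off by default", {
  default <- two_by_two(39, 30, 28, 48)
  corrected <- two_by_two(39, 30, 28, 48, correct = TRUE)
  expect_lt(default$p, 0.02)   # 0.0176 uncorrected
  expect_gt(corrected$p, 0.02) # about 0.027 corrected
})

test_that("group_c0d summarises genotype groups and tests them", {
  set.seed(13)
  c0d <- c(rnorm(20, 150, 30), rnorm(20, 80, 30), rnorm(10, 65, 30))
  geno <- rep(c("*3/*3", "*1/*3", "*1/*1"), c(20, 20, 10))
  coh <- make_c0d_cohort(c0d, geno)
  gc <- group_c0d(coh, "rs776746")
  expect_equal(gc$groups$label, c("*3/*3", "*1/*3", "*1/*1"))
  expect_equal(gc$groups$n, c(20L, 20L, 10L))
  expect_equal(gc$groups$mean[1], mean(c0d[1:20]))
  expect_equal(gc$test, "anova")
  expect_lt(gc$p, 0.001)

  # expressor split on the same data uses a two-group t-test
  ge <- group_c0d(coh, "expressor")
  expect_equal(ge$test, "t_test")
  expect_equal(ge$groups$n, c(20L, 30L))
})

test_that("identical groups give t = 0, p = 1", {
  coh <- make_c0d_cohort(rep(c(100, 120, 140), 4),
                         rep(c("*3/*3", "*1/*3"), each = 6))
  gc <- group_c0d(coh, "expressor")
  expect_equal(unname(gc$statistic), 0, tolerance = 1e-12)
  expect_equal(gc$p, 1)
})

test_that("group t statistic matches the summary-statistic oracle", {
  # groups rebuilt to the published day-6 expressor summaries
  x1 <- vec_with_stats(50, 145.45, 54.99)
  x2 <- vec_with_stats(42, 74.82, 37.77)
  coh <- make_c0d_cohort(c(x1, x2), rep(c("*3/*3", "*1/*3"), c(50, 42)))
  gc <- group_c0d(coh, "expressor", welch = TRUE)
  oracle_t <- (145.45 - 74.82) / sqrt(54.99^2 / 50 + 37.77^2 / 42)
  expect_equal(abs(unname(gc$statistic)), oracle_t, tolerance = 1e-6)
  expect_equal(oracle_t, 7.3, tolerance = 0.01)
})

test_that("two-group ANOVA F equals the pooled t squared", {
  set.seed(17)
  for (rep in 1:5) {
    y <- rnorm(40, 100, 20)
    geno <- sample(rep(c("*3/*3", "*1/*3"), each = 20))
    coh <- make_c0d_cohort(y, geno)
    tt <- group_c0d(coh, "expressor")
    # force ANOVA machinery on the same two groups
    grp <- factor(geno)
    f_stat <- summary(aov(y ~ grp))[[1]][["F value"]][1]
    expect_equal(f_stat, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("groups with n < 2 are excluded from the test and flagged", {
  c0d <- c(rnorm(10, 150, 20), rnorm(10, 80, 20), 70)
  geno <- c(rep("*3/*3", 10), rep("*1/*3", 10), "*1/*1")
  gc <- group_c0d(make_c0d_cohort(c0d, geno), "rs776746")
  expect_equal(gc$excluded, "*1/*1")
  expect_equal(gc$test, "t_test")
})

test_that("two_by_two_outcome orients the table by the chosen exposed group", {
  coh <- generate_cohort(default_study_config(n_patients = 3000, seed = 23))
  a <- two_by_two_outcome(coh, "nodat", exposed = "non-expressor")
  b <- two_by_two_outcome(coh, "nodat", exposed = "expressor")
  expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-9)
  expect_equal(a$a + a$b + a$c + a$d, sum(!is.na(coh$patients$nodat)))
  expect_error(two_by_two_outcome(coh, "creatinine"), "unknown outcome")
})
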