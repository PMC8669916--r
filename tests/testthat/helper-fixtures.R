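# Shared fixtures and independent oracles for the test suite.

# A small hand-written patient table covering the full schema.
make_patient_df <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(34, 51, 28),
    sex = c("male", "female", "male"),
    weight_day6 = c(60, 55, 70),
    dose_day6 = c(4, 3.6, 5),
    c0_day6 = c(8, 7.2, 6.5),
    weight_month6 = c(62, NA, 71),
    dose_month6 = c(3.5, NA, 4.5),
    c0_month6 = c(7.5, NA, 6.9),
    weight_year1 = NA, dose_year1 = NA, c0_year1 = NA,
    rs776746 = c("*3/*3", "*1/*3", "*1/*1"),
    rs2242480 = c("*1/*1", "*1/*1G", "*1G/*1G"),
    rs2740574 = c("A/A", "A/G", "A/A"),
    rs2032582 = c("G/T", "T/T", "G/G"),
    rs1045642 = c("C/C", "C/T", "T/T"),
    dgf = c(FALSE, FALSE, TRUE),
    early_dysfunction = c(FALSE, FALSE, FALSE),
    nodat = c(TRUE, FALSE, FALSE),
    rejection = c(FALSE, FALSE, TRUE),
    toxicity = c(FALSE, TRUE, FALSE),
    erythrocytosis = c(FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Cohort whose day-6 C0/D equals `c0d` exactly (weight 60 kg, dose 3 mg/day
# => dose/kg = 0.05), with given CYP3A5 genotypes; other SNPs held benign.
make_c0d_cohort <- function(c0d, rs776746, sex = NULL, age = NULL) {
  n <- length(c0d)
  stopifnot(length(rs776746) == n)
  df <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age = if (is.null(age)) rep(40, n) else age,
    sex = if (is.null(sex)) rep("male", n) else sex,
    weight_day6 = 60, dose_day6 = 3, c0_day6 = c0d * 0.05,
    rs776746 = rs776746,
    rs2242480 = "*1/*1G", rs2740574 = "A/A",
    rs2032582 = "G/T", rs1045642 = "C/T",
    stringsAsFactors = FALSE
  )
  new_cohort(df)
}

# Vector of length n with exactly the requested mean and sd.
vec_with_stats <- function(n, mean, sd) {
  x <- as.numeric(scale(seq_len(n)))
  mean + sd * x
}

# --- Independent two-locus likelihood oracle (pure enumeration) ----------
# Genotype-pair probabilities for haplotype frequencies given by the one
# free parameter h11 = f(AB), with allele frequencies fixed at the sample
# values; built by brute-force enumeration of ordered haplotype pairs.
oracle_genotype_probs <- function(h11, pA, pB) {
  h <- c(h11, pA - h11, pB - h11, 1 - pA - pB + h11)
  Ac <- c(1, 1, 0, 0)
  Bc <- c(1, 0, 1, 0)
  probs <- matrix(0, 3, 3)
  for (i in 1:4) {
    for (j in 1:4) {
      r <- Ac[i] + Ac[j] + 1
      c <- Bc[i] + Bc[j] + 1
      probs[r, c] <- probs[r, c] + h[i] * h[j]
    }
  }
  probs
}

oracle_loglik <- function(h11, x, y) {
  P <- oracle_genotype_probs(h11, mean(x) / 2, mean(y) / 2)
  ll <- 0
  for (k in seq_along(x)) {
    p <- P[x[k] + 1, y[k] + 1]
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

# Maximum log-likelihood over a fine grid of the free haplotype frequency.
oracle_grid_max <- function(x, y, step = 1e-4) {
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  max(vapply(grid, oracle_loglik, numeric(1), x = x, y = y))
}

# One random point on the 4-simplex (flat Dirichlet).
rdirichlet1 <- function() {
  g <- rgamma(4, shape = 1)
  g / sum(g)
}

# TRUE when either locus of a simulated pair carries only one allele.
is_monomorphic_pair <- function(g) {
  px <- mean(g$x) / 2
  py <- mean(g$y) / 2
  px %in% c(0, 1) || py %in% c(0, 1)
}

# Simulate n unphased genotype pairs from haplotype frequencies
# h = c(AB, Ab, aB, ab) by random union of gametes.
sim_genotype_pairs <- function(n, h) {
  idx <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = h), nrow = 2)
  Ac <- c(1, 1, 0, 0)
  Bc <- c(1, 0, 1, 0)
  list(x = Ac[idx[1, ]] + Ac[idx[2, ]],
       y = Bc[idx[1, ]] + Bc[idx[2, ]])
}
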