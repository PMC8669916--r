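#' Allele frequencies from biallelic genotype counts
#'
#' @param n_aa Count of homozygotes for allele a.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of homozygotes for allele b.
#' @return A list with `n` (genotyped individuals), `count_a`, `count_b`
#'   (allele counts out of `2n`) and `freq_a`, `freq_b`.
#' @export
#' @examples
#' allele_frequencies(69, 61, 15)  # CYP3A5 *3: 199 alleles, freq 0.686
allele_frequencies <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotyped individuals")
  count_a <- 2 * n_aa + n_ab
  list(n = n, count_a = count_a, count_b = 2 * n - count_a,
       freq_a = count_a / (2 * n), freq_b = 1 - count_a / (2 * n))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with the counts expected under random
#' mating (`n p^2`, `2 n p q`, `n q^2`) using the Pearson chi-square
#' statistic on 1 degree of freedom, without continuity correction.
#'
#' @inheritParams allele_frequencies
#' @return Object of class `hwe_test`: `chi2`, `df`, `p`,
#'   `expected` (three expected counts), `freq_a`, `n`, and `monomorphic`
#'   (`TRUE` when one allele is absent, in which case `chi2 = 0`, `p = 1`).
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # exact Hardy-Weinberg proportions: chi2 = 0
hwe_test <- function(n_aa, n_ab, n_bb) {
  af <- allele_frequencies(n_aa, n_ab, n_bb)
  p <- af$freq_a
  q <- 1 - p
  expected <- af$n * c(p^2, 2 * p * q, q^2)
  observed <- c(n_aa, n_ab, n_bb)
  if (p == 0 || p == 1) {
    out <- list(chi2 = 0, df = 1L, p = 1, expected = expected,
                freq_a = p, n = af$n, monomorphic = TRUE)
  } else {
    chi2 <- sum((observed - expected)^2 / expected)
    out <- list(chi2 = chi2, df = 1L,
                p = pchisq(chi2, df = 1, lower.tail = FALSE),
                expected = expected, freq_a = p, n = af$n,
                monomorphic = FALSE)
  }
  structure(out, class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg chi-square test (df = 1)\n"))
  if (x$monomorphic) cat("  monomorphic locus\n")
  cat(sprintf("  n = %d, freq(a) = %.4f, chi2 = %.4f, p = %.4g\n",
              x$n, x$freq_a, x$chi2, x$p))
  invisible(x)
}

# Genotype-pair probabilities implied by four haplotype frequencies
# h = c(AB, Ab, aB, ab); rows index code at locus 1 (0,1,2), cols locus 2.
hap_genotype_probs <- function(h) {
  hAB <- h[1]; hAb <- h[2]; haB <- h[3]; hab <- h[4]
  matrix(c(
    hab^2,           2 * haB * hab,             haB^2,
    2 * hAb * hab,   2 * (hAB * hab + hAb * haB), 2 * hAB * haB,
    hAb^2,           2 * hAB * hAb,             hAB^2
  ), nrow = 3, byrow = TRUE)
}

hap_loglik <- function(h, N) {
  P <- hap_genotype_probs(h)
  use <- N > 0
  if (any(P[use] <= 0)) return(-Inf)
  sum(N[use] * log(P[use]))
}

#' Two-locus haplotype frequencies and linkage disequilibrium by EM
#'
#' Estimates the four haplotype frequencies of two biallelic loci from
#' unphased additive genotype codes, resolving the double-heterozygote phase
#' ambiguity with an expectation-maximisation algorithm, and derives the
#' standard disequilibrium summaries: `D = f(AB) - p_A p_B`, Lewontin's
#' `D' = |D| / D_max`, and the squared allelic correlation
#' `r2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' The EM is initialised at linkage equilibrium (products of the sample
#' allele frequencies) and iterated until the largest absolute change in any
#' haplotype frequency falls below `tol` or `max_iter` is reached. Because
#' the observed allele counts are fixed, the estimated haplotype margins
#' equal the sample allele frequencies at every iteration, and the
#' log-likelihood is non-decreasing.
#'
#' @param geno1,geno2 Integer vectors of codes (0/1/2), aligned by patient;
#'   pairs with any missing code are dropped.
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param max_iter Iteration cap; non-convergence raises a warning.
#' @return Object of class `ld_result`: `hap_freqs` (named AB, Ab, aB, ab),
#'   `D`, `D_prime`, `r2`, `em_iterations`, `loglik`, `n_pairs`,
#'   `converged`, `monomorphic`. When either locus is monomorphic the LD
#'   measures are `NA` and `monomorphic` is `TRUE`.
#' @export
#' @examples
#' g <- c(0, 1, 2, 1, 0, 2, 1, 0)
#' em_haplotypes(g, g)  # a locus with itself: D' = 1, r2 = 1
em_haplotypes <- function(geno1, geno2, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(geno1) == length(geno2))
  keep <- !is.na(geno1) & !is.na(geno2)
  x <- as.integer(geno1[keep])
  y <- as.integer(geno2[keep])
  if (length(x) < 2) stop("need at least 2 complete genotype pairs")
  if (any(!x %in% 0:2) || any(!y %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2")
  }
  n <- length(x)
  pA <- mean(x) / 2
  pB <- mean(y) / 2

  base <- list(n_pairs = n, em_iterations = 0L, loglik = NA_real_,
               converged = TRUE, monomorphic = FALSE)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    hf <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
            ab = (1 - pA) * (1 - pB))
    out <- c(base, list(hap_freqs = hf, D = NA_real_, D_prime = NA_real_,
                        r2 = NA_real_))
    out$monomorphic <- TRUE
    return(structure(out, class = "ld_result"))
  }

  N <- table(factor(x, levels = 0:2), factor(y, levels = 0:2))
  N <- matrix(as.numeric(N), nrow = 3)

  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  ll <- hap_loglik(h, N)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- h["AB"] * h["ab"] + h["Ab"] * h["aB"]
    w <- if (denom > 0) as.numeric(h["AB"] * h["ab"] / denom) else 0.5
    nAB <- 2 * N[3, 3] + N[3, 2] + N[2, 3] + w * N[2, 2]
    nAb <- 2 * N[3, 1] + N[3, 2] + N[2, 1] + (1 - w) * N[2, 2]
    naB <- 2 * N[1, 3] + N[1, 2] + N[2, 3] + (1 - w) * N[2, 2]
    nab <- 2 * N[1, 1] + N[1, 2] + N[2, 1] + w * N[2, 2]
    h_new <- c(AB = nAB, Ab = nAb, aB = naB, ab = nab) / (2 * n)
    ll_new <- hap_loglik(h_new, N)
    if (ll_new < ll - 1e-8) {
      stop("EM log-likelihood decreased; this indicates a bug")
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    ll <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not converge in ", iter, " iterations")
  }

  qA <- 1 - pA
  qB <- 1 - pB
  D <- as.numeric(h["AB"] - pA * pB)
  Dmax <- if (D >= 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  D_prime <- if (D == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * qA * pB * qB)

  structure(c(list(hap_freqs = h, D = D, D_prime = D_prime, r2 = r2),
              list(n_pairs = n, em_iterations = iter, loglik = ll,
                   converged = converged, monomorphic = FALSE)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("Two-locus LD (EM haplotype estimation)\n")
  if (x$monomorphic) {
    cat(sprintf("  monomorphic locus; LD undefined (n = %d)\n", x$n_pairs))
    return(invisible(x))
  }
  cat(sprintf("  n pairs = %d, EM iterations = %d, loglik = %.4f\n",
              x$n_pairs, x$em_iterations, x$loglik))
  cat(sprintf("  hap freqs: AB %.4f, Ab %.4f, aB %.4f, ab %.4f\n",
              x$hap_freqs["AB"], x$hap_freqs["Ab"],
              x$hap_freqs["aB"], x$hap_freqs["ab"]))
  cat(sprintf("  D = %.4f, D' = %.3f, r2 = %.3f\n", x$D, x$D_prime, x$r2))
  invisible(x)
}

#' Per-SNP genotype/allele summary with Hardy-Weinberg test
#'
#' One row per panel SNP: genotype counts in coded-allele orientation
#' (`n_hom_coded` carries two copies of the coded allele), allele counts and
#' frequencies, and the Hardy-Weinberg chi-square.
#'
#' @param cohort A `tacro_cohort`.
#' @return A tibble.
#' @export
snp_summary <- function(cohort) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  rows <- lapply(cohort$snp_defs$snp_id, function(id) {
    def <- snp_def(cohort$snp_defs, id)
    code <- encode_genotypes(cohort, id)
    code <- code[!is.na(code)]
    n2 <- sum(code == 2L); n1 <- sum(code == 1L); n0 <- sum(code == 0L)
    af <- allele_frequencies(n2, n1, n0)
    hw <- hwe_test(n2, n1, n0)
    other <- setdiff(c(def$allele_a, def$allele_b), def$coded_allele)
    tibble::tibble(
      snp_id = id, gene_label = def$gene_label, n = af$n,
      coded_allele = def$coded_allele, other_allele = other,
      n_hom_coded = n2, n_het = n1, n_hom_other = n0,
      count_coded = af$count_a, count_other = af$count_b,
      freq_coded = af$freq_a, freq_other = af$freq_b,
      hwe_chi2 = hw$chi2, hwe_p = hw$p, monomorphic = hw$monomorphic
    )
  })
  do.call(rbind, rows)
}

#' Pairwise linkage disequilibrium across the SNP panel
#'
#' Runs [em_haplotypes()] on every pair of panel SNPs (complete pairs only)
#' and tabulates D, D' and r-squared.
#'
#' @param cohort A `tacro_cohort`.
#' @param tol,max_iter Passed to [em_haplotypes()].
#' @return A tibble with one row per SNP pair: `snp1`, `snp2`, `n_pairs`,
#'   `D`, `D_prime`, `r2`, `monomorphic`.
#' @export
ld_pairs <- function(cohort, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(cohort, "tacro_cohort"))
  ids <- cohort$snp_defs$snp_id
  codes <- lapply(ids, encode_genotypes, cohort = cohort)
  names(codes) <- ids
  pairs <- combn(ids, 2)
  rows <- apply(pairs, 2, function(pr) {
    ld <- em_haplotypes(codes[[pr[1]]], codes[[pr[2]]],
                        tol = tol, max_iter = max_iter)
    tibble::tibble(snp1 = pr[1], snp2 = pr[2], n_pairs = ld$n_pairs,
                   D = ld$D, D_prime = ld$D_prime, r2 = ld$r2,
                   monomorphic = ld$monomorphic)
  })
  do.call(rbind, rows)
}
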