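# Population-genetic statistics: minor allele frequencies, the exact
# conditional Hardy-Weinberg test, EM haplotype-frequency estimation,
# pairwise linkage disequilibrium, and a synthetic cohort sampler.

#' Tabulate genotype counts per SNP
#'
#' Counts major-allele homozygotes, heterozygotes and minor-allele
#' homozygotes for each panel SNP, skipping missing genotypes.
#'
#' @param cohort An `mbl2_cohort`.
#' @param panel A `snp_panel`.
#' @return Data frame `rs_id`, `n_hom_major`, `n_het`, `n_hom_minor`, `N`.
#' @export
genotype_counts <- function(cohort, panel = mbl2_snp_panel()) {
  out <- data.frame(rs_id = panel$rs_id,
                    n_hom_major = 0L, n_het = 0L, n_hom_minor = 0L,
                    N = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    g <- cohort[[panel$rs_id[i]]]
    g <- g[!is.na(g)]
    maj <- panel$base_major[i]; mnr <- panel$base_minor[i]
    hom_major <- paste(sort(c(maj, maj)), collapse = "")
    hom_minor <- paste(sort(c(mnr, mnr)), collapse = "")
    het <- paste(sort(c(maj, mnr)), collapse = "")
    out$n_hom_major[i] <- sum(g == hom_major)
    out$n_het[i] <- sum(g == het)
    out$n_hom_minor[i] <- sum(g == hom_minor)
    out$N[i] <- length(g)
  }
  stopifnot(out$n_hom_major + out$n_het + out$n_hom_minor == out$N)
  out
}

#' Minor allele frequency
#'
#' `(2 n_hom_minor + n_het) / (2N)` on the 0-100 percent scale. "Minor" is
#' the assay's variant allele letter (H, X, Q, D, B, C), fixed by the panel
#' rather than re-derived per cohort, so reports stay comparable across
#' populations even if a variant allele exceeds 50% somewhere.
#'
#' @param counts Output of [genotype_counts()] (one or more rows).
#' @return Named numeric vector of MAFs in percent.
#' @export
maf <- function(counts) {
  if (any(counts$N == 0)) stop("no genotyped samples for some SNP")
  stats::setNames(100 * (2 * counts$n_hom_minor + counts$n_het) /
                    (2 * counts$N),
                  counts$rs_id)
}

# Exact conditional HWE test for a single SNP (Wigginton-style).
# n_het: observed heterozygotes; n_rare: count of the rarer allele; N:
# sample count. Sums probabilities of all heterozygote counts whose
# conditional probability (given N and n_rare) does not exceed that of the
# observed count.
hwe_exact_single <- function(n_het, n_rare, N) {
  n_alleles <- 2L * N
  if (n_rare > n_alleles - n_rare) n_rare <- n_alleles - n_rare
  if (n_rare == 0L) return(1.0)
  # heterozygote counts share the parity of the rare-allele count
  het_values <- seq(n_rare %% 2L, n_rare, by = 2L)
  probs <- numeric(length(het_values))
  # unnormalized probability at the smallest heterozygote count, then the
  # standard recurrence upward:
  # P(h+2)/P(h) = 4 * n_AA(h) * n_aa(h) / ((h+2)*(h+1))
  lp <- 0
  lps <- numeric(length(het_values))
  for (k in seq_along(het_values)) {
    lps[k] <- lp
    h <- het_values[k]
    if (k < length(het_values)) {
      n_aa <- (n_rare - h) / 2
      n_AA <- N - h - n_aa
      lp <- lp + log(4 * n_AA * n_aa) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(lps - max(lps))
  probs <- probs / sum(probs)
  obs <- match(n_het, het_values)
  if (is.na(obs)) {
    stop("heterozygote count ", n_het,
         " inconsistent with a rare-allele count of ", n_rare)
  }
  # include all configurations no more probable than the observed one,
  # with a small relative slack against floating-point ties
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-12)])
  min(1.0, p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' The exact conditional test of Hardy-Weinberg proportions: conditional on
#' the sample size and the observed allele counts, the p-value sums the
#' probabilities of all heterozygote counts at most as probable as the
#' observed one (the standard exact HWE test of Wigginton, Cutler and
#' Abecasis). Monomorphic SNPs have a single possible configuration and
#' return p = 1.
#'
#' @param counts Output of [genotype_counts()] (one or more rows).
#' @return Named numeric vector of p-values in (0, 1].
#' @export
hwe_exact_p <- function(counts) {
  p <- vapply(seq_len(nrow(counts)), function(i) {
    n_rare <- 2L * counts$n_hom_minor[i] + counts$n_het[i]
    hwe_exact_single(counts$n_het[i], n_rare, counts$N[i])
  }, numeric(1))
  stats::setNames(p, counts$rs_id)
}

# Enumerate the two-haplotype phase explanations of one unphased genotype.
# gv: named diplets over the subset SNPs. Returns a 2-column matrix of
# haplotype base strings, one row per unordered compatible pair.
phase_pairs <- function(gv) {
  alleles <- strsplit(gv, "")
  het <- vapply(alleles, function(a) a[1] != a[2], logical(1))
  m <- length(gv)
  if (!any(het)) {
    h <- paste(vapply(alleles, `[`, character(1), 1), collapse = "")
    return(matrix(c(h, h), nrow = 1))
  }
  het_idx <- which(het)
  # fix the first het site's phase to halve the enumeration (unordered pairs)
  n_free <- length(het_idx) - 1L
  combos <- as.matrix(expand.grid(rep(list(0:1), n_free)))
  if (n_free == 0) combos <- matrix(numeric(0), nrow = 1, ncol = 0)
  pairs <- matrix("", nrow = nrow(combos), ncol = 2)
  base1 <- vapply(alleles, `[`, character(1), 1)
  base2 <- vapply(alleles, `[`, character(1), 2)
  for (r in seq_len(nrow(combos))) {
    h1 <- base1; h2 <- base2
    flip <- het_idx[-1][combos[r, ] == 1]
    h1[flip] <- base2[flip]; h2[flip] <- base1[flip]
    pairs[r, ] <- c(paste(h1, collapse = ""), paste(h2, collapse = ""))
  }
  pairs
}

#' EM estimation of multilocus haplotype frequencies
#'
#' The standard expectation-maximization algorithm over unphased multilocus
#' genotypes. The E-step distributes each sample's probability mass over
#' its phase-consistent haplotype pairs assuming Hardy-Weinberg
#' proportions; the M-step re-estimates haplotype frequencies from the
#' expected counts. Iteration stops when the log-likelihood improves by
#' less than `tol` or after `max_iter` iterations. The default
#' initialization is the (deterministic) product of observed allele
#' frequencies; `random_start = TRUE` draws a random initial frequency
#' vector using `seed`.
#'
#' @param cohort An `mbl2_cohort`.
#' @param snp_subset SNP ids to phase (default: all panel SNPs). Samples
#'   missing any subset genotype are dropped.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE` with
#'   a warning and returns the best estimate.
#' @param random_start Use a random initial frequency vector.
#' @param seed Seed for the random start.
#' @return Object of class `hap_freq_fit`: `freq` (named vector over
#'   haplotype base strings, sums to 1), `loglik` (trace), `iterations`,
#'   `converged`, `n` (samples used).
#' @examples
#' coh <- reconstruct_table5_cohort()
#' fit <- em_haplotype_frequencies(coh)
#' round(100 * fit$freq[order(-fit$freq)][1:3], 1)
#' @export
em_haplotype_frequencies <- function(cohort,
                                     snp_subset = mbl2_snp_panel()$rs_id,
                                     tol = 1e-8, max_iter = 1000,
                                     random_start = FALSE, seed = NULL) {
  if (length(snp_subset) < 2) stop("need at least two SNPs")
  gmat <- as.data.frame(cohort)[, snp_subset, drop = FALSE]
  keep <- stats::complete.cases(gmat)
  gmat <- gmat[keep, , drop = FALSE]
  n <- nrow(gmat)
  if (n < 1) stop("no complete samples")

  # collapse to distinct genotype patterns with weights
  key <- do.call(paste, gmat)
  tab <- table(key)
  patterns <- names(tab)
  wt <- as.numeric(tab)
  pair_list <- lapply(patterns, function(k) {
    gv <- strsplit(k, " ", fixed = TRUE)[[1]]
    phase_pairs(gv)
  })

  haps <- sort(unique(unlist(pair_list)))
  H <- length(haps)
  pair_idx <- lapply(pair_list, function(p)
    cbind(match(p[, 1], haps), match(p[, 2], haps)))

  # initial frequencies
  if (random_start) {
    if (!is.null(seed)) set.seed(seed)
    f <- stats::runif(H)
  } else {
    # product of observed allele frequencies at each site
    site_freq <- lapply(seq_along(snp_subset), function(j) {
      a <- unlist(strsplit(gmat[[j]], ""))
      table(a) / length(a)
    })
    f <- vapply(haps, function(h) {
      b <- strsplit(h, "")[[1]]
      prod(vapply(seq_along(b), function(j) {
        fr <- site_freq[[j]][b[j]]
        if (is.na(fr)) 0 else as.numeric(fr)
      }, numeric(1)))
    }, numeric(1))
  }
  if (sum(f) == 0) f <- rep(1, H)
  f <- f / sum(f)

  pattern_lik <- function(f) {
    vapply(pair_idx, function(pi) {
      mult <- ifelse(pi[, 1] == pi[, 2], 1, 2)
      sum(mult * f[pi[, 1]] * f[pi[, 2]])
    }, numeric(1))
  }

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lik <- pattern_lik(f)
    loglik <- c(loglik, sum(wt * log(pmax(lik, 1e-300))))
    # E-step: expected haplotype counts
    cnt <- numeric(H)
    for (g in seq_along(pair_idx)) {
      pi <- pair_idx[[g]]
      mult <- ifelse(pi[, 1] == pi[, 2], 1, 2)
      pp <- mult * f[pi[, 1]] * f[pi[, 2]]
      if (sum(pp) == 0) pp <- rep(1, length(pp))
      pp <- pp / sum(pp)
      for (r in seq_len(nrow(pi))) {
        cnt[pi[r, 1]] <- cnt[pi[r, 1]] + wt[g] * pp[r]
        cnt[pi[r, 2]] <- cnt[pi[r, 2]] + wt[g] * pp[r]
      }
    }
    f_new <- cnt / (2 * n)
    f <- f_new / sum(f_new)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  names(f) <- haps
  structure(list(freq = f, loglik = loglik, iterations = length(loglik),
                 converged = converged, n = n, snps = snp_subset),
            class = "hap_freq_fit")
}

#' @export
print.hap_freq_fit <- function(x, ...) {
  cat("EM haplotype frequencies over", length(x$snps), "SNPs,",
      x$n, "samples\n")
  cat("log-likelihood", format(utils::tail(x$loglik, 1), digits = 8),
      "after", x$iterations, "iteration(s)",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  f <- sort(x$freq[x$freq > 1e-6], decreasing = TRUE)
  print(round(100 * f, 2))
  invisible(x)
}

#' @export
logLik.hap_freq_fit <- function(object, ...) {
  structure(utils::tail(object$loglik, 1), df = length(object$freq) - 1,
            class = "logLik")
}

#' Pairwise linkage disequilibrium
#'
#' Two-locus haplotype frequencies are estimated by
#' [em_haplotype_frequencies()]; from them `D = p_AB - p_A p_B` (computed
#' on the minor alleles), `D' = |D| / D_max` with the usual sign-dependent
#' `D_max`, and `r^2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param cohort An `mbl2_cohort`.
#' @param snp_i,snp_j rs ids of the two SNPs.
#' @param panel A `snp_panel`.
#' @return List of class `ld_estimate`: `D`, `D_prime`, `r2`, `hap_freq`
#'   (the four two-locus haplotype frequencies), `monomorphic` flag (when
#'   `TRUE` the LD measures are `NA`).
#' @export
ld_pair <- function(cohort, snp_i, snp_j, panel = mbl2_snp_panel()) {
  counts <- genotype_counts(cohort, panel)
  mafs <- maf(counts) / 100
  if (mafs[[snp_i]] %in% c(0, 1) || mafs[[snp_j]] %in% c(0, 1)) {
    return(structure(list(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                          hap_freq = NULL, monomorphic = TRUE,
                          snps = c(snp_i, snp_j)),
                     class = "ld_estimate"))
  }
  fit <- em_haplotype_frequencies(cohort, c(snp_i, snp_j))
  i <- match(snp_i, panel$rs_id); j <- match(snp_j, panel$rs_id)
  hAB <- paste0(panel$base_minor[i], panel$base_minor[j])
  pAB <- if (hAB %in% names(fit$freq)) fit$freq[[hAB]] else 0
  pA <- sum(fit$freq[substr(names(fit$freq), 1, 1) == panel$base_minor[i]])
  pB <- sum(fit$freq[substr(names(fit$freq), 2, 2) == panel$base_minor[j]])
  D <- pAB - pA * pB
  D_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  D_prime <- if (D_max == 0) NA_real_ else abs(D) / D_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, D_prime = D_prime, r2 = r2, hap_freq = fit$freq,
                 monomorphic = FALSE, snps = c(snp_i, snp_j)),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat("LD ", x$snps[1], " x ", x$snps[2], ": ", sep = "")
  if (x$monomorphic) {
    cat("undefined (monomorphic SNP)\n")
  } else {
    cat("D =", format(x$D, digits = 4),
        " D' =", format(x$D_prime, digits = 4),
        " r2 =", format(x$r2, digits = 4), "\n")
  }
  invisible(x)
}

#' Sample a synthetic cohort under Hardy-Weinberg equilibrium
#'
#' Draws two independent haplotypes per sample from the given frequency
#' table and emits the unphased genotypes, so the cohort is in
#' Hardy-Weinberg and linkage equilibrium-of-pairing by construction (the
#' haplotype frequencies themselves carry the LD).
#'
#' @param freqs Named numeric vector of haplotype frequencies; names are
#'   haplotype names from `hap_panel` or six-base strings. Must sum to 1
#'   (within 1e-6).
#' @param N Number of samples.
#' @param seed Integer seed (required: the sampler is the package's
#'   synthetic-data source and must be reproducible).
#' @param hap_panel A `haplotype_panel` used to translate haplotype names.
#' @param panel A `snp_panel`.
#' @return An `mbl2_cohort` with attribute `true_diplotypes` (character
#'   vector of the generating `"H1/H2"` pairs when names were given).
#' @examples
#' hp <- mbl2_haplotype_panel()
#' coh <- sample_synthetic_cohort(
#'   stats::setNames(hp$freq_czech_pct / sum(hp$freq_czech_pct), hp$name),
#'   N = 50, seed = 1)
#' @export
sample_synthetic_cohort <- function(freqs, N, seed,
                                    hap_panel = mbl2_haplotype_panel(),
                                    panel = mbl2_snp_panel()) {
  stopifnot(N > 0, all(freqs >= 0), length(freqs) >= 1)
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  named_haps <- all(names(freqs) %in% hap_panel$name)
  bases <- if (named_haps) {
    hap_panel$bases[match(names(freqs), hap_panel$name)]
  } else {
    if (!all(grepl("^[ACGT]+$", names(freqs)))) {
      stop("frequency names must be haplotype names or base strings")
    }
    names(freqs)
  }
  set.seed(seed)
  draw1 <- sample(seq_along(freqs), N, replace = TRUE, prob = freqs)
  draw2 <- sample(seq_along(freqs), N, replace = TRUE, prob = freqs)
  L <- nchar(bases[1])
  gmat <- matrix(NA_character_, nrow = N, ncol = L)
  for (s in seq_len(N)) {
    b1 <- strsplit(bases[draw1[s]], "")[[1]]
    b2 <- strsplit(bases[draw2[s]], "")[[1]]
    gmat[s, ] <- mapply(function(a, b)
      paste(sort(c(a, b)), collapse = ""), b1, b2)
  }
  cohort <- mbl2_cohort(sprintf("SIM%04d", seq_len(N)), gmat, panel)
  if (named_haps) {
    nm <- names(freqs)
    ord <- function(a, b) {
      i <- match(c(a, b), hap_panel$name)
      paste(hap_panel$name[sort(i)], collapse = "/")
    }
    attr(cohort, "true_diplotypes") <-
      mapply(ord, nm[draw1], nm[draw2], USE.NAMES = FALSE)
  }
  cohort
}
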