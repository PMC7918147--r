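# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (recurrences, EM) and use direct enumeration or
# closed-form combinatorics instead.

# Exact conditional HWE p-value by direct enumeration of genotype
# configurations: for fixed N and rare-allele count nA, the conditional
# probability of a configuration with n_het heterozygotes is
#   [ N! / (n_AA! n_het! n_aa!) * 2^n_het ] / C(2N, nA)
# computed here with exact log-factorials, independent of the package's
# recurrence-based implementation.
hwe_enumeration_oracle <- function(n_het, n_rare, N) {
  if (n_rare > N) n_rare <- 2L * N - n_rare
  if (n_rare == 0) return(1.0)
  hs <- seq(n_rare %% 2L, n_rare, by = 2L)
  lp <- vapply(hs, function(h) {
    n_aa <- (n_rare - h) / 2
    n_AA <- N - h - n_aa
    lfactorial(N) - lfactorial(n_AA) - lfactorial(h) - lfactorial(n_aa) +
      h * log(2) -
      (lfactorial(2 * N) - lfactorial(n_rare) - lfactorial(2 * N - n_rare))
  }, numeric(1))
  probs <- exp(lp)
  obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Count subsets of sizes 2..k of a k-element set by brute force over the
# full powerset (bitmask enumeration).
powerset_subset_count <- function(k) {
  n <- 0L
  for (mask in 0:(2^k - 1)) {
    if (sum(bitwAnd(mask, 2^(0:(k - 1))) > 0) >= 2) n <- n + 1L
  }
  n
}

# Maximum-likelihood two-locus haplotype frequencies by 1-D grid search.
# Given per-sample two-locus genotypes (vectors of diplets), the four
# haplotype frequencies have one free parameter once the allele
# frequencies are fixed at their sample values; the grid scans p_11 (the
# frequency of the minor-minor haplotype) and maximizes the multinomial
# likelihood of the nine genotype classes under random pairing.
ld_grid_oracle <- function(g1, g2, minor1, minor2, grid_n = 4001) {
  stopifnot(length(g1) == length(g2))
  count_minor <- function(g, minor)
    vapply(strsplit(g, ""), function(b) sum(b == minor), numeric(1))
  x <- count_minor(g1, minor1)   # 0/1/2 minor alleles at locus 1
  y <- count_minor(g2, minor2)
  p1 <- mean(x) / 2
  p2 <- mean(y) / 2
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  grid <- seq(lo, hi, length.out = grid_n)
  loglik <- vapply(grid, function(p11) {
    h <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)  # 11, 10, 01, 00
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 0)
    # genotype class probability: sum over compatible haplotype pairs
    gp <- function(xi, yi) {
      tot <- 0
      for (a in 0:1) for (b in 0:1) for (cc in 0:1) for (d in 0:1) {
        if (a + cc == xi && b + d == yi) {
          hap1 <- h[2 * (1 - a) + (1 - b) + 1]
          hap2 <- h[2 * (1 - cc) + (1 - d) + 1]
          tot <- tot + hap1 * hap2
        }
      }
      tot
    }
    sum(log(pmax(mapply(gp, x, y), 1e-300)))
  }, numeric(1))
  p11 <- grid[which.max(loglik)]
  list(p11 = p11, p1 = p1, p2 = p2, D = p11 - p1 * p2)
}

# A complete-genotype cohort where only two chosen SNPs vary; the other
# four sit at their major-allele homozygote. `g1`, `g2` are diplet vectors
# for the two varying SNPs.
two_snp_cohort <- function(g1, g2, snp_i, snp_j) {
  panel <- mbl2_snp_panel()
  n <- length(g1)
  gmat <- matrix(NA_character_, nrow = n, ncol = nrow(panel))
  for (k in seq_len(nrow(panel))) {
    gmat[, k] <- strrep(panel$base_major[k], 2)
  }
  gmat[, match(snp_i, panel$rs_id)] <- g1
  gmat[, match(snp_j, panel$rs_id)] <- g2
  mbl2_cohort(sprintf("T%03d", seq_len(n)), gmat, panel)
}

# All 36 unordered pairs of the eight panel haplotypes.
all_panel_pairs <- function(hap_panel = mbl2_haplotype_panel()) {
  n <- nrow(hap_panel)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    out[[length(out) + 1L]] <- c(hap_panel$name[i], hap_panel$name[j])
  }
  out
}
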