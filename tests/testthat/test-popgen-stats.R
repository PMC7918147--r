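test_that("genotype counts partition the cohort per SNP", {
  coh <- reconstruct_table5_cohort()
  cnt <- genotype_counts(coh)
  expect_true(all(cnt$n_hom_major + cnt$n_het + cnt$n_hom_minor == 328))
  # rs1800451: 12 heterozygous C carriers, no CC homozygote
  i <- match("rs1800451", cnt$rs_id)
  expect_equal(cnt$n_het[i], 12)
  expect_equal(cnt$n_hom_minor[i], 0)
})

test_that("minor allele frequencies follow the allele-count formula", {
  coh <- reconstruct_table5_cohort()
  m <- maf(genotype_counts(coh))
  expect_equal(m[["rs11003125"]], 100 * 251 / 656, tolerance = 1e-12)
  expect_equal(m[["rs1800451"]], 100 * 12 / 656, tolerance = 1e-12)
  # an all-major cohort has MAF 0
  panel <- mbl2_snp_panel()
  hom <- mbl2_cohort("h", t(strrep(panel$base_major, 2)))
  expect_true(all(maf(genotype_counts(hom)) == 0))
})

test_that("exact HWE test agrees with the enumeration oracle", {
  # every (N, rare-allele count, heterozygote count) configuration up to
  # N = 20
  for (N in c(2, 3, 5, 10, 20)) {
    for (n_rare in 0:N) {
      hs <- seq(n_rare %% 2, n_rare, by = 2)
      for (h in hs) {
        counts <- data.frame(rs_id = "x", n_hom_major = N - h - (n_rare - h) / 2,
                             n_het = h, n_hom_minor = (n_rare - h) / 2, N = N)
        expect_equal(unname(hwe_exact_p(counts)),
                     hwe_enumeration_oracle(h, n_rare, N),
                     tolerance = 1e-9,
                     label = sprintf("N=%d nA=%d het=%d", N, n_rare, h))
      }
    }
  }
})

test_that("HWE edge cases: monomorphic SNPs and the two-het toy case", {
  mono <- data.frame(rs_id = "x", n_hom_major = 50, n_het = 0,
                     n_hom_minor = 0, N = 50)
  expect_equal(unname(hwe_exact_p(mono)), 1)
  # N=2, both samples heterozygous: the two configurations with two minor
  # alleles have conditional probabilities 2/3 (two hets) and 1/3 (one
  # hom each); observing the more probable one sums to 1
  toy <- data.frame(rs_id = "x", n_hom_major = 0, n_het = 2,
                    n_hom_minor = 0, N = 2)
  expect_equal(unname(hwe_exact_p(toy)), 1)
  # the complementary observation keeps only the rarer configuration
  toy2 <- data.frame(rs_id = "x", n_hom_major = 1, n_het = 0,
                     n_hom_minor = 1, N = 2)
  expect_equal(unname(hwe_exact_p(toy2)), 1 / 3, tolerance = 1e-12)
})

test_that("EM equals direct counting when no sample has latent phase", {
  # at most one heterozygous site per sample: phase is observed
  g <- rbind(c("GG", "GG", "CC", "CC", "GG", "GG"),   # HYPA/HYPA
             c("CG", "GG", "CC", "CC", "GG", "GG"),   # HYPA/LYPA
             c("CC", "GG", "CC", "CC", "GG", "GG"),   # LYPA/LYPA
             c("CC", "GG", "CT", "CC", "GG", "GG"))   # LYPA/LYQA
  coh <- mbl2_cohort(paste0("s", 1:4), g)
  fit <- em_haplotype_frequencies(coh)
  direct <- c(GGCCGG = 3, CGCCGG = 4, CGTCGG = 1) / 8
  expect_equal(fit$freq[names(direct)], direct, tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and frequencies sum to one", {
  hp <- mbl2_haplotype_panel()
  freqs <- stats::setNames(hp$freq_czech_pct / sum(hp$freq_czech_pct),
                           hp$name)
  for (seed in 1:5) {
    coh <- sample_synthetic_cohort(freqs, N = 120, seed = seed)
    fit <- em_haplotype_frequencies(coh)
    expect_true(all(diff(fit$loglik) >= -1e-8), label = paste("seed", seed))
    expect_equal(sum(fit$freq), 1, tolerance = 1e-9)
    expect_true(all(fit$freq >= 0))
  }
  # random restarts land on the same optimum here
  coh <- sample_synthetic_cohort(freqs, N = 120, seed = 9)
  det <- em_haplotype_frequencies(coh)
  rnd <- em_haplotype_frequencies(coh, random_start = TRUE, seed = 1)
  common <- intersect(names(det$freq), names(rnd$freq))
  expect_equal(det$freq[common], rnd$freq[common], tolerance = 1e-4)
})

test_that("EM recovers known haplotype frequencies from simulation", {
  hp <- mbl2_haplotype_panel()
  freqs <- stats::setNames(hp$freq_czech_pct / sum(hp$freq_czech_pct),
                           hp$name)
  coh <- sample_synthetic_cohort(freqs, N = 500, seed = 11)
  fit <- em_haplotype_frequencies(coh)
  est <- fit$freq[hp$bases]
  est[is.na(est)] <- 0
  expect_lt(mean(abs(est - freqs)), 0.02)
})

test_that("LD pair statistics behave at the extremes", {
  # perfectly co-inherited SNPs: D' = 1, r2 = 1
  g1 <- c("CC", "CG", "GG", "CG")
  g2 <- c("GG", "GC", "CC", "GC")  # rs7096206 minor C tracks rs11003125 G
  coh <- two_snp_cohort(g1, g2, "rs11003125", "rs7096206")
  ld <- ld_pair(coh, "rs11003125", "rs7096206")
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  # independent SNPs at equilibrium frequencies: the 16-sample cross
  # product of two HWE-proportioned loci (1:2:1 each) factorizes exactly,
  # so D = 0
  l1 <- rep(c("CC", "CG", "GG"), times = c(1, 2, 1))
  l2 <- rep(c("GG", "GC", "CC"), times = c(1, 2, 1))
  grid <- expand.grid(a = l1, b = l2, stringsAsFactors = FALSE)
  coh <- two_snp_cohort(grid$a, grid$b, "rs11003125", "rs7096206")
  ld <- ld_pair(coh, "rs11003125", "rs7096206")
  expect_equal(ld$D, 0, tolerance = 1e-6)
  # monomorphic SNP: explicit flag
  mono <- two_snp_cohort(rep("CC", 4), c("GG", "GC", "GC", "CC"),
                         "rs11003125", "rs7096206")
  ld <- ld_pair(mono, "rs11003125", "rs7096206")
  expect_true(ld$monomorphic)
  expect_true(is.na(ld$r2))
})

test_that("two-locus EM matches the 1-D grid-search ML oracle", {
  # a mixture containing double heterozygotes, whose phase is latent
  g1 <- c("CG", "CG", "CG", "CC", "GG", "CG", "CC", "CG")
  g2 <- c("GC", "GC", "GG", "GC", "GG", "GC", "GG", "GG")
  coh <- two_snp_cohort(g1, g2, "rs11003125", "rs7096206")
  ld <- ld_pair(coh, "rs11003125", "rs7096206")
  oracle <- ld_grid_oracle(g1, g2, minor1 = "G", minor2 = "C")
  expect_equal(ld$D, oracle$D, tolerance = 2e-4)
})

test_that("the synthetic cohort sampler is seeded and degenerate-safe", {
  hp <- mbl2_haplotype_panel()
  freqs <- stats::setNames(hp$freq_czech_pct / sum(hp$freq_czech_pct),
                           hp$name)
  a <- sample_synthetic_cohort(freqs, N = 40, seed = 3)
  b <- sample_synthetic_cohort(freqs, N = 40, seed = 3)
  expect_identical(a, b)
  expect_false(identical(
    a, sample_synthetic_cohort(freqs, N = 40, seed = 4)))
  # degenerate table: everyone HYPA/HYPA
  mono <- sample_synthetic_cohort(c(HYPA = 1), N = 5, seed = 1)
  expect_true(all(mono$rs11003125 == "GG"))
  expect_true(all(attr(mono, "true_diplotypes") == "HYPA/HYPA"))
  expect_error(sample_synthetic_cohort(c(HYPA = 0.5), N = 5, seed = 1),
               "sum to 1")
  # large-N sanity: EM re-estimates within sampling error
  big <- sample_synthetic_cohort(freqs, N = 10000, seed = 21)
  fit <- em_haplotype_frequencies(big)
  est <- fit$freq[hp$bases]; est[is.na(est)] <- 0
  expect_true(all(abs(est - freqs) < 0.015))
})
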