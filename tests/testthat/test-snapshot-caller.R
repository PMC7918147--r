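test_that("expected layout has primer+1 sizes and strand-corrected bases", {
  lay <- expected_layout()
  p <- mbl2_snp_panel()
  expect_equal(lay$size, p$primer_length + 1L)
  # rs1800450: forward 22-mer, size 23, alleles observed as-is (A->G, B->A)
  i <- match("rs1800450", lay$rs_id)
  expect_equal(lay$size[i], 23L)
  expect_identical(lay$base_major_obs[i], "G")
  expect_identical(lay$base_minor_obs[i], "A")
  # rs1800451: reverse 27-mer, size 28, observed bases complemented
  # (A allele G -> C peak, C allele A -> T peak)
  j <- match("rs1800451", lay$rs_id)
  expect_equal(lay$size[j], 28L)
  expect_identical(lay$base_major_obs[j], "C")
  expect_identical(lay$base_minor_obs[j], "T")
  # unique sizes separated by at least 4 nt
  expect_gte(min(diff(sort(lay$size))), 4)
})

test_that("noise-free simulation emits one peak per present allele", {
  gv <- genotype_of_pair("HYPA", "LYQA")  # 2 het SNPs, 4 hom SNPs
  pt <- simulate_peak_table(gv)
  expect_equal(nrow(pt), 8)
  lay <- expected_layout()
  expect_true(all(pt$size %in% lay$size))
  hom <- genotype_of_pair("HYPA", "HYPA")
  expect_equal(nrow(simulate_peak_table(hom)), 6)
})

test_that("seeded simulation is deterministic", {
  gv <- genotype_of_pair("LYQA", "LYPB")
  noisy <- sbe_noise_model(height_cv = 0.25, size_jitter_sd = 0.3,
                           artifact_rate = 0.5)
  a <- simulate_peak_table(gv, noise = noisy, seed = 42)
  b <- simulate_peak_table(gv, noise = noisy, seed = 42)
  expect_identical(a, b)
  c <- simulate_peak_table(gv, noise = noisy, seed = 43)
  expect_false(identical(a, c))
})

test_that("noise-free simulate -> call round-trips every panel diplotype", {
  panel <- mbl2_snp_panel()
  for (pair in all_panel_pairs()) {
    gv <- genotype_of_pair(pair[1], pair[2])
    calls <- call_sample(simulate_peak_table(gv, panel), panel)
    expect_identical(calls$genotype, unname(gv),
                     label = paste(pair, collapse = "/"))
    expect_true(all(calls$flags == ""),
                label = paste(pair, collapse = "/"))
  }
})

test_that("heterozygote balance filters imbalanced minor peaks", {
  panel <- mbl2_snp_panel()
  lay <- expected_layout()
  i <- match("rs1800450", lay$rs_id)  # forward strand: obs bases G/A
  pk <- data.frame(sample_id = "s", size = rep(lay$size[i], 2),
                   base = c("G", "A"), height = c(1000, 150))
  calls <- call_sample(pk, panel)
  expect_identical(calls$genotype[i], "GG")  # 0.15 < 0.20
  expect_match(calls$flags[i], "imbalance_filtered")
  # at exactly the threshold the heterozygote stands
  pk$height <- c(1000, 200)
  calls <- call_sample(pk, panel)
  expect_identical(calls$genotype[i], "AG")
  expect_identical(calls$flags[i], "")
})

test_that("in-window peaks with unexpected bases are flagged and excluded", {
  panel <- mbl2_snp_panel()
  lay <- expected_layout()
  i <- match("rs7096206", lay$rs_id)  # forward: expected G/C
  pk <- data.frame(sample_id = "s",
                   size = rep(lay$size[i], 3),
                   base = c("G", "C", "T"),
                   height = c(900, 800, 700))
  calls <- call_sample(pk, panel)
  expect_identical(calls$genotype[i], "CG")
  expect_match(calls$flags[i], "unexpected_base")
})

test_that("reverse-strand calls are complemented back to the coding strand", {
  panel <- mbl2_snp_panel()
  lay <- expected_layout()
  i <- match("rs11003125", lay$rs_id)  # reverse: coding C/G -> obs G/C
  pk <- data.frame(sample_id = "s", size = rep(lay$size[i], 2),
                   base = c("G", "C"), height = c(1000, 950))
  calls <- call_sample(pk, panel)
  expect_identical(calls$genotype[i], "CG")
  # a lone observed G peak is the coding-strand C allele
  calls1 <- call_sample(pk[1, ], panel)
  expect_identical(calls1$genotype[i], "CC")
})

test_that("degenerate peak tables yield missing calls with low_signal", {
  panel <- mbl2_snp_panel()
  empty <- data.frame(sample_id = character(0), size = numeric(0),
                      base = character(0), height = numeric(0))
  calls <- call_sample(empty, panel)
  expect_true(all(is.na(calls$genotype)))
  expect_true(all(grepl("low_signal", calls$flags)))
  # peaks below the height floor behave like absence
  lay <- expected_layout()
  faint <- data.frame(sample_id = "s", size = lay$size,
                      base = lay$base_major_obs, height = 10)
  calls <- call_sample(faint, panel)
  expect_true(all(is.na(calls$genotype)))
})

test_that("artifact-free simulation maps every peak to a panel SNP", {
  gv <- genotype_of_pair("LXPA", "HYPD")
  pt <- simulate_peak_table(gv, noise = sbe_noise_model(size_jitter_sd = 0.2),
                            seed = 7)
  lay <- expected_layout()
  d <- vapply(pt$size, function(s) min(abs(s - lay$size)), numeric(1))
  expect_true(all(d <= 2))
})

test_that("dye-color peak tables are translated before calling", {
  panel <- mbl2_snp_panel()
  lay <- expected_layout()
  i <- match("rs1800450", lay$rs_id)
  pk <- data.frame(sample_id = "s", size = rep(lay$size[i], 2),
                   base = c("blue", "green"),  # G and A dyes
                   height = c(1000, 900))
  calls <- call_sample(pk, panel)
  expect_identical(calls$genotype[i], "AG")
})

test_that("peak tables round-trip through TSV", {
  gv <- genotype_of_pair("HYPA", "LYPB")
  pt <- simulate_peak_table(gv, noise = sbe_noise_model(height_cv = 0.1),
                            seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_tsv(pt, path)
  back <- read_peak_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(pt), tolerance = 1e-12)
})
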