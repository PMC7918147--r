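---
title: "MBL2 secretor haplotypes: the assay model, the calculator and the statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MBL2 secretor haplotypes: the assay model, the calculator and the statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbl2kit)
```

## The biological problem

Serum mannose-binding lectin (MBL) concentration is largely determined by
six variants of the *MBL2* gene: two promoter SNPs (rs11003125, alleles
H/L; rs7096206, alleles X/Y), one 5'UTR SNP (rs7095891, alleles P/Q) and
three exon-1 structural SNPs (rs5030737 allele D, rs1800450 allele B,
rs1800451 allele C, versus the normal allele A). Strong linkage
disequilibrium confines the observed allele combinations to a small set of
named *secretor haplotypes* (HYPA, LYQA, LXPA, LYPB, HYPD, LYPA, LYQC,
LYQB), each associated with a serum-level phenotype class — and the
clinically relevant quantity is the *diplotype*, the pair of haplotypes an
individual carries. `mbl2kit` models the six-SNP SNaPshot minisequencing
assay used to genotype these variants in one reaction and implements the
downstream analysis chain: genotype calling from electropherogram peaks,
combinatorial haplogenotype indexing, diplotype resolution with phenotype
prediction, and cohort-level population statistics.

## The single-base-extension model

In a SNaPshot reaction each SNP has one extension primer ending directly
5' of the variant base; a single fluorescent ddNTP is added, so the
product is `primer_length + 1` nucleotides long and its dye identifies the
incorporated base. Poly-T tails of different lengths separate the six
products by size; in canonical SNP order the primers are 42, 32, 47, 37,
22 and 27 nt, giving expected apparent sizes 43, 33, 48, 38, 23 and 28 nt
— unique and at least 4 nt apart, so a ±2 nt size window never overlaps
two SNPs. Four of the six primers interrogate the reverse strand; the
caller stores all genotypes in the coding-strand orientation of
NM_000242.2 and complements instrument bases at the boundary, which keeps
one unambiguous base convention everywhere else in the package.

```{r}
expected_layout()
```

The caller (`call_sample()`) assigns each peak to the nearest expected
size within `size_tolerance` (default ±2.0 nt; an exact tie between two
windows is flagged and dropped), discards peaks below `min_peak_height`
(default 50 fluorescence units), flags in-window peaks matching neither
expected allele (`unexpected_base`) and then applies the *heterozygote
balance* rule: two surviving alleles are called heterozygous only when the
minor/major height ratio reaches `het_balance`. The default of 0.20 is a
conventional review threshold for single-source SNaPshot data; the
original analysis software applies such a filter but its numeric value is
not documented, so the parameter is exposed and every flagged call carries
`imbalance_filtered` for audit. Peak tables may carry dye colors instead
of bases; the default map is the standard SNaPshot chemistry (green=A,
black=C, blue=G, red=T).

`simulate_peak_table()` is the package's synthetic-data source for the
assay. It emulates the structure of real electropherograms — one peak per
present allele at the expected size, optional Gaussian size jitter and
height noise, configurable heterozygote imbalance, and optional
non-specific artifact peaks at the D- and Q-allele positions (the artifact
pattern reported for partially degraded DNA). It does not model
dye-dependent mobility shifts, pull-up between dye channels, stutter, or
the size-standard calibration curve, so a perfect noise-free round trip
demonstrates the correctness of the calling logic, not the robustness of
the assay to real instrument physics. A per-SNP size-offset table can be
supplied implicitly by adjusting `size_tolerance` if calibrated offsets
are ever needed.

## The Haplogenotype Calculator

For association work on unphased data, the calculator gives every
combination of genotypes over every SNP subset a stable integer. For `k`
SNPs (2–10) it enumerates all `2^k - k - 1` subsets of size ≥ 2, builds
for each `m`-SNP subset the complete background set of `3^m` genotype
combinations, and assigns each sample the index of its exact match. The
original application promises only that each combination "has a unique
number"; this implementation defines the numbering as the lexicographic
rank with subset SNPs in input order (first SNP most significant) and each
SNP's genotypes ordered (Homozygote 1, Heterozygote, Homozygote 2), so
index 1 is always the all-Homozygote-1 combination and indices are
reproducible across runs and machines. Samples with missing genotypes at
a subset SNP, or with a genotype outside the declared alphabet, are
reported as unmatched rather than silently dropped. Output sheets are
grouped by subset size ("pairs", "triplets", ...) and written as one CSV
per size — diff-friendly, unlike a binary workbook.

## Diplotype resolution and its one ambiguity

`resolve_diplotype()` tests all 36 unordered pairs of the eight panel
haplotypes against a genotype; the panel is closed, so genotypes that
would require an unobserved haplotype (for instance an L-X-P-B
combination) are `unresolvable` rather than phased de novo. Of the 26
haplogenotype classes observed in the Czech cohort, 25 resolve uniquely.
One does not:

```{r}
resolve_diplotype(parse_genotype_string("CC GG CT CC GA GG"))
```

LYQA/LYPB and LYPA/LYQB imply the same unphased genotype — the two pairs
exchange the 5'UTR and exon-1 variants between chromosomes. The published
table prints LYQA/LYPB for this class, which is the overwhelmingly more
probable phasing given the haplotype frequencies (LYPA and LYQB are both
rare). The package therefore keeps resolution itself exhaustive and
unranked, and exposes frequency-based ranking as an explicit annotation:

```{r}
hp <- mbl2_haplotype_panel()
resolve_diplotype(parse_genotype_string("CC GG CT CC GA GG"),
                  rank_freq = stats::setNames(hp$freq_czech_pct, hp$name))$pair_prob
```

`resolve_cohort(..., ambiguous = "most_likely")` and
`count_haplotypes()` use this ranking (estimating the frequencies from
the cohort itself by EM when none are supplied), which is what reproduces
the published haplotype table; with `ambiguous = "unresolved"` the 20
affected samples are excluded and the counts shift visibly. Serum-level
categories for diplotypes (`diplotype_level()`) ship as an editable rule
table keyed by phenotype-class pairs: the High+Low = Medium and
Undetectable+Intermediate = Low entries follow the MBL literature, the
rest are marked `extrapolated` in the table and should be replaced where
finer clinical data exist; uncovered pairs return `"uncategorized"`
rather than a guess.

## Population statistics

*Minor allele frequency* is `(2·hom_minor + het) / 2N` with "minor" fixed
to the assay's variant letter (H, X, Q, D, B, C) rather than re-derived
per cohort, keeping reports comparable across populations.

*Hardy-Weinberg* uses the exact conditional test (Wigginton-Cutler-
Abecasis): conditional on N and the allele counts, sum the probabilities
of all heterozygote counts at most as probable as the observed one,
computed with the standard log-space recurrence. The exact test, not
chi-square, is what reproduces p = 1.00 for a SNP with 12 heterozygous
carriers and no minor homozygote in 328 samples; the test suite checks the
implementation against an independent enumeration oracle over every
configuration up to N = 20.

*Haplotype frequencies* come from the standard EM algorithm over unphased
multilocus genotypes: the E-step distributes each sample over its
phase-consistent haplotype pairs under Hardy-Weinberg proportions, the
M-step re-estimates frequencies. Initialization is the deterministic
product of observed allele frequencies; convergence is declared when the
log-likelihood improves by less than `tol = 1e-8`, capped at
`max_iter = 1000` (non-convergence warns and returns the best estimate;
random restarts are available behind a seed). The log-likelihood is
non-decreasing by construction and asserted in tests. *Pairwise LD*
(D, D', r²) is computed from two-locus EM frequencies with the usual
sign-dependent D_max normalization; monomorphic SNPs yield an explicit
undefined flag. No multiple-testing correction is applied anywhere, and
LD-block calling (Gabriel intervals) is out of scope — only pairwise
statistics are reported.

`sample_synthetic_cohort()` draws two independent haplotypes per sample
from a frequency table, so simulated cohorts are in Hardy-Weinberg
equilibrium by construction while inheriting the haplotypes' LD structure.
It emulates sampling variation only: no genotyping error, missingness or
population structure, so parameter-recovery results bound estimator
behaviour under the model, not under messy real data.

## The reconstructed Czech cohort and its error bound

The package ships the published distribution of the 26 haplogenotype
classes among 328 Czech individuals and rebuilds a per-sample cohort from
it (`reconstruct_table5_cohort()`): each class receives
`round(freq% × 328 / 100)` samples. Nearest-integer rounding happens to
conserve N = 328 exactly on this table (the constructor verifies it); a
largest-remainder variant is provided for arbitrary class tables. Class
frequencies are printed to one decimal, so each reconstructed count is
uncertain by up to ±0.5 samples (~0.15 percentage points); cohort-level
checks against published values therefore use a ±0.25 pp tolerance, the
provable bound for quantities touched by at most two classes. One
published quantity falls outside any such bound by nature: the exact HWE
p-value of rs5030737 depends sharply on the minor-homozygote count, which
the reconstruction fixes at 3 (from 0.9% × 328 = 2.95) while the true
count may have been 2 — the reconstructed p is 0.49 against a printed
0.80, and no faithful reconstruction can settle it. The test suite states
this rather than relaxing the check.

## Problem sizes and numerical choices

Validation runs use the sizes natural to this assay: the 328-sample
reconstruction for all cohort-level checks; 83 simulated samples for the
caller concordance analogue (mirroring the 83 Sanger-validated samples,
100% concordance); EM parameter recovery on 20 cohorts of N = 500, where
the mean absolute error of haplotype-frequency estimates stays below 2
percentage points. Degenerate inputs are defined, not errors: an empty
peak table yields all-missing calls flagged `low_signal`, an empty cohort
yields header-only calculator sheets, a monomorphic SNP yields a flagged
undefined LD estimate, and a single-haplotype frequency table yields a
uniform homozygous cohort.

## Limitations

The package analyses this specific six-SNP panel; it does not parse raw
.fsa traces, fit size-standard curves, call novel haplotypes, perform
association testing, or predict serum MBL concentration in mg/L. The
reconstructed cohort reproduces published class frequencies, not the
original per-sample data; statistics computed from it inherit the rounding
bound above.
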