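Package: mbl2kit
Title: MBL2 SNaPshot Genotyping, Haplogenotype Combinations and Secretor
    Haplotype Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the six-SNP mannose-binding lectin gene (MBL2)
    SNaPshot minisequencing assay and downstream analysis. Provides an
    in-silico model of the single-base-extension (SBE) panel with a
    seeded electropherogram peak simulator and a peak-to-genotype caller
    with quality flags; the Haplogenotype Calculator, which enumerates
    SNP subsets, builds uniquely numbered background sets of genotype
    combinations and assigns each sample its combination index;
    diplotype resolution of unphased genotypes against the panel of
    eight MBL secretor haplotypes (HYPA, LYQA, LXPA, LYPB, HYPD, LYPA,
    LYQC, LYQB) with phenotype prediction; and population-genetic
    statistics: minor allele frequencies, the exact conditional
    Hardy-Weinberg test, pairwise linkage disequilibrium (D', r2) and
    EM haplotype-frequency estimation, together with a synthetic cohort
    sampler and readers/writers for genotype TSV, peak tables and a
    small XML cohort dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
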