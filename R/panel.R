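# Core data model: the six-SNP MBL2 panel, allele nomenclature, genotype
# vectors and the secretor haplotype panel.
#
# All bases are stored in the coding-strand orientation of NM_000242.2 (the
# orientation of the HGVS c. labels). Reverse-strand complementation is
# confined to the SBE caller.

#' The six-SNP MBL2 SNaPshot panel
#'
#' Returns the definition of the six MBL2 SNPs genotyped by the SNaPshot
#' assay, in canonical order (rs11003125, rs7096206, rs7095891, rs5030737,
#' rs1800450, rs1800451). Each SNP carries its allele-letter nomenclature
#' (H/L, X/Y, P/Q and the exon-1 structural letters A/B, A/C, A/D), the
#' coding-strand base of each letter, the HGVS substitution, the strand and
#' length of its single-base-extension (SBE) primer and the primer
#' concentration in the SBE mix.
#'
#' The "minor" allele letter is fixed to the assay's variant letter
#' (H, X, Q, D, B, C) regardless of its frequency in a particular cohort,
#' so that allele-frequency reports stay comparable across populations.
#'
#' @return A data frame of class `snp_panel` with one row per SNP and
#'   columns `rs_id`, `location`, `hgvs`, `letter_major`, `letter_minor`,
#'   `base_major`, `base_minor`, `sbe_strand`, `primer_seq`,
#'   `primer_length`, `primer_conc_uM`.
#' @examples
#' mbl2_snp_panel()
#' @export
mbl2_snp_panel <- function() {
  panel <- data.frame(
    rs_id        = c("rs11003125", "rs7096206", "rs7095891",
                     "rs5030737", "rs1800450", "rs1800451"),
    location     = c("promoter", "promoter", "5'UTR of exon 1",
                     "exon 1", "exon 1", "exon 1"),
    hgvs         = c("c.-619C>G", "c.-290C>G", "c.-66C>T",
                     "c.154C>T", "c.161G>A", "c.170G>A"),
    letter_major = c("L", "Y", "P", "A", "A", "A"),
    letter_minor = c("H", "X", "Q", "D", "B", "C"),
    base_major   = c("C", "G", "C", "C", "G", "G"),
    base_minor   = c("G", "C", "T", "T", "A", "A"),
    sbe_strand   = c("reverse", "forward", "reverse",
                     "reverse", "forward", "reverse"),
    primer_seq   = c(
      "TTTTTTTTTTTTTTTTGGAGTTTGCTTCCCCTTGGTGTTTTA",
      "TTTTTTTTGGTCCCATTTGTTCTCACTGCCAC",
      "TTTTTTTTCAGGGAAGGTTAATCTCAGTTAATGAACACATATTTACC",
      "TTTTTTTTTTTTCCCTTTTCTYCCTTGGTGYCATCAC",
      "CCAGGCAAAGATGGGYGTGATG",
      "TTTTACGTACCTGGTTCCCCCTTTTCT"),
    primer_conc_uM = c(0.08, 0.06, 0.06, 0.08, 0.1, 0.18),
    stringsAsFactors = FALSE
  )
  panel$primer_length <- nchar(panel$primer_seq)
  stopifnot(
    !anyDuplicated(panel$rs_id),
    !anyDuplicated(panel$primer_length),
    panel$base_major != panel$base_minor
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("MBL2 SNaPshot SNP panel (", nrow(x), " SNPs)\n", sep = "")
  print.data.frame(x[, c("rs_id", "hgvs", "letter_major", "letter_minor",
                         "base_major", "base_minor", "sbe_strand",
                         "primer_length")], row.names = FALSE)
  invisible(x)
}

#' Watson-Crick complement of nucleotide bases
#'
#' @param base Character vector of single bases (`A`, `C`, `G`, `T`).
#' @return Character vector of complementary bases.
#' @examples
#' complement_base(c("A", "G"))
#' @export
complement_base <- function(base) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- map[base]
  if (anyNA(out)) {
    stop("non-nucleotide base(s): ",
         paste(unique(base[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

# Normalize one two-base diplet to alphabetical order ("GC" -> "CG").
normalize_diplet <- function(d) {
  b <- strsplit(d, "")
  vapply(b, function(x) paste(sort(x), collapse = ""), character(1))
}

#' Parse a space-separated genotype string
#'
#' Parses the printed haplogenotype notation: six whitespace-separated
#' two-base diplets in canonical SNP order, e.g. `"GC GG CT CC GG GG"`.
#' Diplets are order-insensitive (`GC` and `CG` denote the same unphased
#' genotype); bases are validated against each SNP's two alleles.
#'
#' @param text A single genotype string.
#' @param panel A `snp_panel` (default [mbl2_snp_panel()]).
#' @return A genotype vector: a named character vector with one element per
#'   SNP, each a two-base diplet in alphabetical order, `NA` for missing.
#' @examples
#' parse_genotype_string("GC GG CT CC GG GG")
#' @export
parse_genotype_string <- function(text, panel = mbl2_snp_panel()) {
  stopifnot(is.character(text), length(text) == 1)
  fields <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(fields) != nrow(panel)) {
    stop("expected ", nrow(panel), " genotype fields, got ", length(fields))
  }
  gv <- character(nrow(panel))
  names(gv) <- panel$rs_id
  for (i in seq_len(nrow(panel))) {
    f <- fields[i]
    if (f == "." || f == "..") {
      gv[i] <- NA_character_
      next
    }
    if (nchar(f) != 2L || !grepl("^[ACGT]{2}$", f)) {
      stop("malformed diplet '", f, "' at ", panel$rs_id[i])
    }
    bases <- strsplit(f, "")[[1]]
    allowed <- c(panel$base_major[i], panel$base_minor[i])
    bad <- setdiff(bases, allowed)
    if (length(bad)) {
      stop("base '", bad[1], "' not an allele of ", panel$rs_id[i],
           " (alleles: ", paste(allowed, collapse = "/"), ")")
    }
    gv[i] <- paste(sort(bases), collapse = "")
  }
  gv
}

#' Render a genotype vector as a space-separated string
#'
#' Inverse of [parse_genotype_string()] up to within-diplet base order
#' (diplets are rendered alphabetically; missing genotypes render as `"."`).
#'
#' @param gv A genotype vector (named character, one diplet per SNP).
#' @return A single string.
#' @export
format_genotype <- function(gv) {
  out <- ifelse(is.na(gv), ".", normalize_diplet(gv))
  paste(out, collapse = " ")
}

#' Build a secretor haplotype from its four-letter name
#'
#' A secretor haplotype name combines one letter per functional region:
#' H/L (rs11003125), X/Y (rs7096206), P/Q (rs7095891) and the exon-1
#' structural allele A, B, C or D. The exon-1 letter expands to the three
#' exon-1 SNPs (rs5030737, rs1800450, rs1800451): the named variant is set
#' at its own SNP and the other two stay at the normal (A) base.
#'
#' @param name Four-letter haplotype name, e.g. `"HYPA"`.
#' @param panel A `snp_panel`.
#' @return Named character vector of six coding-strand bases in canonical
#'   SNP order.
#' @examples
#' haplotype_from_name("HYPA")  # G G C C G G
#' @export
haplotype_from_name <- function(name, panel = mbl2_snp_panel()) {
  stopifnot(is.character(name), length(name) == 1)
  letters4 <- strsplit(name, "")[[1]]
  if (length(letters4) != 4L) stop("haplotype name must have 4 letters: ", name)
  if (!letters4[1] %in% c("H", "L") || !letters4[2] %in% c("X", "Y") ||
      !letters4[3] %in% c("P", "Q") || !letters4[4] %in% c("A", "B", "C", "D")) {
    stop("unknown haplotype name '", name, "'")
  }
  bases <- character(nrow(panel))
  names(bases) <- panel$rs_id
  letter_at <- function(i, letter) {
    if (letter == panel$letter_major[i]) panel$base_major[i]
    else if (letter == panel$letter_minor[i]) panel$base_minor[i]
    else stop("letter '", letter, "' is not an allele of ", panel$rs_id[i])
  }
  bases["rs11003125"] <- letter_at(1, letters4[1])
  bases["rs7096206"]  <- letter_at(2, letters4[2])
  bases["rs7095891"]  <- letter_at(3, letters4[3])
  # exon-1 structural letter: D -> rs5030737, B -> rs1800450, C -> rs1800451
  exon1 <- c(rs5030737 = "A", rs1800450 = "A", rs1800451 = "A")
  if (letters4[4] == "D") exon1["rs5030737"] <- "D"
  if (letters4[4] == "B") exon1["rs1800450"] <- "B"
  if (letters4[4] == "C") exon1["rs1800451"] <- "C"
  for (rs in names(exon1)) {
    i <- match(rs, panel$rs_id)
    bases[rs] <- letter_at(i, exon1[[rs]])
  }
  bases
}

#' The panel of eight MBL secretor haplotypes
#'
#' The eight haplotypes observed in the genotyped Czech cohort, with their
#' six-base coding-strand sequence (canonical SNP order), the MBL serum
#' phenotype class each is associated with, and the haplotype frequency
#' reported for the 328-sample Czech cohort (percent).
#'
#' @param panel A `snp_panel`.
#' @return A data frame of class `haplotype_panel` with columns `name`,
#'   `bases` (six-character string), `phenotype` and `freq_czech_pct`,
#'   ordered by decreasing Czech frequency.
#' @examples
#' mbl2_haplotype_panel()
#' @export
mbl2_haplotype_panel <- function(panel = mbl2_snp_panel()) {
  hp <- data.frame(
    name = c("HYPA", "LYQA", "LXPA", "LYPB", "HYPD", "LYPA", "LYQC", "LYQB"),
    phenotype = c("High", "High", "Low", "Undetectable", "Undetectable",
                  "Intermediate", "Undetectable", "Undetectable"),
    freq_czech_pct = c(29.8, 21.7, 21.4, 13.3, 8.5, 3.3, 1.8, 0.2),
    stringsAsFactors = FALSE
  )
  hp$bases <- vapply(hp$name, function(nm)
    paste(haplotype_from_name(nm, panel), collapse = ""), character(1))
  stopifnot(!anyDuplicated(hp$bases), !anyDuplicated(hp$name))
  hp <- hp[, c("name", "bases", "phenotype", "freq_czech_pct")]
  class(hp) <- c("haplotype_panel", "data.frame")
  hp
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("MBL secretor haplotype panel (", nrow(x), " haplotypes)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a cohort genotype table
#'
#' A cohort is a data frame with a `sample_id` column and one column per
#' panel SNP holding two-base diplets (alphabetical within the diplet) or
#' `NA` for missing genotypes.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param genotypes A character matrix or data frame, one row per sample and
#'   one column per SNP (canonical order), of diplets.
#' @param panel A `snp_panel`.
#' @return A data frame of class `mbl2_cohort`.
#' @export
mbl2_cohort <- function(sample_id, genotypes, panel = mbl2_snp_panel()) {
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  stopifnot(length(sample_id) == nrow(genotypes),
            ncol(genotypes) == nrow(panel))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  names(genotypes) <- panel$rs_id
  for (i in seq_len(nrow(panel))) {
    col <- genotypes[[i]]
    ok <- is.na(col)
    allowed <- c(panel$base_major[i], panel$base_minor[i])
    valid <- grepl("^[ACGT]{2}$", col[!ok])
    if (!all(valid)) stop("malformed diplet in column ", panel$rs_id[i])
    col[!ok] <- normalize_diplet(col[!ok])
    bases_ok <- vapply(strsplit(col[!ok], ""), function(b)
      all(b %in% allowed), logical(1))
    if (!all(bases_ok)) {
      stop("base outside the ", panel$rs_id[i], " alleles (",
           paste(allowed, collapse = "/"), ")")
    }
    genotypes[[i]] <- col
  }
  out <- cbind(data.frame(sample_id = as.character(sample_id),
                          stringsAsFactors = FALSE),
               genotypes)
  class(out) <- c("mbl2_cohort", "data.frame")
  out
}

#' @export
print.mbl2_cohort <- function(x, ...) {
  cat("MBL2 cohort: ", nrow(x), " samples, ",
      ncol(x) - 1L, " SNPs\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

# Extract one sample's genotype vector from a cohort.
cohort_genotype <- function(cohort, row, panel = mbl2_snp_panel()) {
  gv <- unlist(cohort[row, panel$rs_id, drop = TRUE])
  gv <- as.character(gv)
  names(gv) <- panel$rs_id
  gv
}
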