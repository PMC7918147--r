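# The Haplogenotype Calculator: enumerate SNP subsets, build uniquely
# numbered background sets of genotype combinations, and assign each
# sample's multi-SNP genotype its combination index per subset.

#' Enumerate SNP subsets of sizes 2..k
#'
#' All subsets of the given SNPs with between 2 and `length(snp_ids)`
#' members, ordered by subset size and then lexicographically by the SNPs'
#' input order. The count is `2^k - k - 1` for `k` SNPs. The calculator
#' supports 2 to 10 SNPs.
#'
#' @param snp_ids Character vector of SNP identifiers (input order is
#'   preserved inside subsets and drives the ordering).
#' @return List of character vectors, each one subset.
#' @examples
#' length(enumerate_subsets(paste0("SNP", 1:4)))  # 11
#' @export
enumerate_subsets <- function(snp_ids) {
  k <- length(snp_ids)
  if (k < 2 || k > 10) stop("the calculator supports 2 to 10 SNPs, got ", k)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  out <- list()
  for (m in 2:k) {
    idx <- utils::combn(k, m, simplify = FALSE)
    out <- c(out, lapply(idx, function(i) snp_ids[i]))
  }
  out
}

#' Genotype alphabet for the calculator
#'
#' For each SNP an ordered triple of genotype labels (Homozygote 1,
#' Heterozygote, Homozygote 2). The default derives the triple from the
#' panel: major-allele homozygote, heterozygote, minor-allele homozygote,
#' written as alphabetical diplets so they match cohort tables directly.
#'
#' @param panel A `snp_panel`.
#' @return Named list: per SNP a character vector of the three labels in
#'   the order (Hom1, Het, Hom2).
#' @export
genotype_alphabet <- function(panel = mbl2_snp_panel()) {
  al <- lapply(seq_len(nrow(panel)), function(i) {
    maj <- panel$base_major[i]; mnr <- panel$base_minor[i]
    c(paste(sort(c(maj, maj)), collapse = ""),
      paste(sort(c(maj, mnr)), collapse = ""),
      paste(sort(c(mnr, mnr)), collapse = ""))
  })
  names(al) <- panel$rs_id
  stopifnot(all(vapply(al, function(x) length(unique(x)) == 3, logical(1))))
  al
}

#' Build the background set of genotype combinations for one SNP subset
#'
#' Enumerates all `3^m` genotype combinations of an `m`-SNP subset and
#' numbers them 1..`3^m` by lexicographic rank: the first subset SNP is the
#' most significant digit and each SNP's genotypes are ordered
#' (Homozygote 1, Heterozygote, Homozygote 2).
#'
#' @param subset Character vector of SNP ids (one subset).
#' @param alphabet A genotype alphabet covering every subset SNP.
#' @return Data frame with columns `index` and one label column per subset
#'   SNP; `3^m` rows.
#' @export
build_background <- function(subset, alphabet = genotype_alphabet()) {
  missing <- setdiff(subset, names(alphabet))
  if (length(missing)) {
    stop("alphabet missing entries for: ", paste(missing, collapse = ", "))
  }
  levels <- lapply(subset, function(s) alphabet[[s]])
  names(levels) <- subset
  # expand.grid varies the first factor fastest; reverse so that the first
  # subset SNP is the most significant digit, then restore column order
  grid <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(subset)), drop = FALSE]
  names(grid) <- subset
  cbind(data.frame(index = seq_len(nrow(grid))), grid)
}

#' Assign cohort samples their background combination index
#'
#' Each sample's genotype restricted to the subset SNPs is matched exactly
#' against the background set; a match yields that combination's unique
#' index. Samples with a missing genotype at any subset SNP, or carrying a
#' genotype outside the alphabet, get `NA` (unmatched).
#'
#' @param cohort An `mbl2_cohort`.
#' @param background Output of [build_background()].
#' @return Data frame `sample_id`, `index` (integer, `NA` = unmatched).
#' @export
assign_samples <- function(cohort, background) {
  subset <- setdiff(names(background), "index")
  if (!all(subset %in% names(cohort))) {
    stop("cohort lacks subset SNP column(s): ",
         paste(setdiff(subset, names(cohort)), collapse = ", "))
  }
  key <- do.call(paste, c(background[subset], sep = "|"))
  sample_key <- do.call(paste, c(as.data.frame(cohort)[subset], sep = "|"))
  idx <- background$index[match(sample_key, key)]
  data.frame(sample_id = cohort$sample_id, index = idx,
             stringsAsFactors = FALSE)
}

# English sheet names for subset sizes 2..10.
subset_size_name <- function(m) {
  nm <- c("pairs", "triplets", "quadruplets", "quintuplets", "sextuplets",
          "septuplets", "octuplets", "nonuplets", "decuplets")
  nm[m - 1L]
}

#' Run the full Haplogenotype Calculator
#'
#' Enumerates every SNP subset of size 2 up to the panel size, builds each
#' subset's background set and assigns every cohort sample its combination
#' index. Results are grouped by subset size into sheets named "pairs",
#' "triplets", ..., each a data frame with `sample_id` and one index
#' column per subset (column named by joining the subset's SNP ids with
#' `+`).
#'
#' @param cohort An `mbl2_cohort`.
#' @param snp_ids SNPs to combine (default: all cohort SNP columns, input
#'   order).
#' @param alphabet A genotype alphabet.
#' @return Named list of data frames, one per subset size, of class
#'   `haplocalc_result`.
#' @examples
#' coh <- reconstruct_table5_cohort()
#' res <- run_calculator(coh)
#' names(res)
#' @export
run_calculator <- function(cohort, snp_ids = setdiff(names(cohort),
                                                     "sample_id"),
                           alphabet = genotype_alphabet()) {
  subsets <- enumerate_subsets(snp_ids)
  sizes <- vapply(subsets, length, integer(1))
  out <- list()
  for (m in sort(unique(sizes))) {
    sheet <- data.frame(sample_id = cohort$sample_id,
                        stringsAsFactors = FALSE)
    for (ss in subsets[sizes == m]) {
      bg <- build_background(ss, alphabet)
      asg <- assign_samples(cohort, bg)
      sheet[[paste(ss, collapse = "+")]] <- asg$index
    }
    out[[subset_size_name(m)]] <- sheet
  }
  class(out) <- c("haplocalc_result", class(out))
  out
}

#' @export
print.haplocalc_result <- function(x, ...) {
  cat("Haplogenotype Calculator output:",
      sum(vapply(x, function(s) ncol(s) - 1L, integer(1))),
      "SNP subsets over", length(x), "sheet(s)\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", ncol(x[[nm]]) - 1L, " subset(s), ",
        nrow(x[[nm]]), " samples\n", sep = "")
  }
  invisible(x)
}

#' Write calculator sheets as CSV files
#'
#' One CSV per subset size (`pairs.csv`, `triplets.csv`, ...) in `dir`.
#'
#' @param result A `haplocalc_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_calculator_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(result)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(result[[nm]], p, row.names = FALSE, na = "unmatched")
    paths <- c(paths, p)
  }
  invisible(paths)
}
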