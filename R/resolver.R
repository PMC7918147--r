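# Diplotype resolution: translate unphased six-SNP genotypes into pairs of
# known secretor haplotypes, and predict MBL phenotype / serum-level
# categories.

#' Genotype implied by a pair of haplotypes
#'
#' The unphased genotype vector of an individual carrying haplotypes `h1`
#' and `h2`: per SNP the unordered pair of the two haplotypes' bases.
#' Symmetric in its arguments.
#'
#' @param h1,h2 Haplotype names present in `hap_panel`.
#' @param hap_panel A `haplotype_panel`.
#' @return A genotype vector (named alphabetical diplets).
#' @examples
#' format_genotype(genotype_of_pair("HYPA", "LYQA"))  # "CG GG CT CC GG GG"
#' @export
genotype_of_pair <- function(h1, h2, hap_panel = mbl2_haplotype_panel()) {
  b1 <- hap_bases(h1, hap_panel)
  b2 <- hap_bases(h2, hap_panel)
  gv <- mapply(function(a, b) paste(sort(c(a, b)), collapse = ""), b1, b2)
  names(gv) <- names(b1)
  gv
}

# Look up a haplotype's bases as a named character vector.
hap_bases <- function(name, hap_panel) {
  i <- match(name, hap_panel$name)
  if (is.na(i)) stop("unknown haplotype '", name, "'")
  b <- strsplit(hap_panel$bases[i], "")[[1]]
  names(b) <- mbl2_snp_panel()$rs_id
  b
}

#' Resolve an unphased genotype to secretor haplotype pairs
#'
#' Exhaustively tests every unordered pair of panel haplotypes (including
#' homozygous pairs) for consistency with the genotype. Resolution is
#' restricted to the declared panel: genotypes explainable only by
#' haplotypes absent from the panel come back `unresolvable` rather than
#' phased de novo.
#'
#' On the eight-haplotype MBL2 panel 25 of the 26 observed haplogenotype
#' classes resolve uniquely; one genotype (`CC GG CT CC AG GG`) is
#' consistent with both LYQA/LYPB and LYPA/LYQB. All consistent pairs are
#' always returned; when `rank_freq` supplies haplotype frequencies the
#' pairs are additionally ordered by their diplotype probability under
#' random pairing (`2 f1 f2`, or `f1^2` for a homozygous pair) and the
#' probabilities are reported — an annotation, not a filter.
#'
#' @param genotype A complete genotype vector.
#' @param hap_panel A `haplotype_panel`.
#' @param rank_freq Optional named numeric vector of haplotype frequencies
#'   (names from `hap_panel`, any scale) used to rank ambiguous pairs.
#' @return List of class `diplotype_resolution`: `pairs` (character vector
#'   of `"H1/H2"` names, haplotypes ordered by panel row), `status`
#'   (`"unique"`, `"ambiguous"` or `"unresolvable"`), and with `rank_freq`
#'   a `pair_prob` vector (normalized over the consistent pairs).
#' @examples
#' resolve_diplotype(parse_genotype_string("GC GG CT CC GG GG"))
#' @export
resolve_diplotype <- function(genotype, hap_panel = mbl2_haplotype_panel(),
                              rank_freq = NULL) {
  if (anyNA(genotype)) {
    stop("genotype has missing SNPs; partial resolution is not supported")
  }
  n <- nrow(hap_panel)
  hits <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      gp <- genotype_of_pair(hap_panel$name[i], hap_panel$name[j], hap_panel)
      if (identical(unname(gp[names(genotype)]), unname(genotype))) {
        hits <- c(hits, paste(hap_panel$name[i], hap_panel$name[j],
                              sep = "/"))
      }
    }
  }
  status <- if (length(hits) == 0) "unresolvable"
            else if (length(hits) == 1) "unique" else "ambiguous"
  out <- list(pairs = hits, status = status, genotype = genotype)
  if (!is.null(rank_freq) && length(hits) > 0) {
    f <- rank_freq / sum(rank_freq)
    prob <- vapply(strsplit(hits, "/", fixed = TRUE), function(h) {
      p1 <- f[[h[1]]]; p2 <- f[[h[2]]]
      if (h[1] == h[2]) p1 * p2 else 2 * p1 * p2
    }, numeric(1))
    ord <- order(prob, decreasing = TRUE)
    out$pairs <- hits[ord]
    out$pair_prob <- prob[ord] / sum(prob)
  }
  structure(out, class = "diplotype_resolution")
}

#' @export
print.diplotype_resolution <- function(x, ...) {
  cat("Genotype ", format_genotype(x$genotype), ": ", x$status, sep = "")
  if (length(x$pairs)) cat(" -> ", paste(x$pairs, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' MBL phenotype class of a haplotype
#'
#' @param name Haplotype name.
#' @param hap_panel A `haplotype_panel`.
#' @return One of `"High"`, `"Intermediate"`, `"Low"`, `"Undetectable"`.
#' @export
phenotype_of <- function(name, hap_panel = mbl2_haplotype_panel()) {
  i <- match(name, hap_panel$name)
  if (anyNA(i)) stop("unknown haplotype: ",
                     paste(name[is.na(i)], collapse = ", "))
  hap_panel$phenotype[i]
}

#' Default diplotype-level rule table
#'
#' Maps unordered pairs of haplotype phenotype classes to an MBL
#' serum-level category. Two entries reflect statements from the MBL
#' literature: a High plus a Low haplotype gives medium levels (the
#' HYPA/LXPA case) and a defect (Undetectable) haplotype combined with an
#' Intermediate one gives low levels. The remaining entries are documented
#' extrapolations (column `source`) and are meant to be overridden by the
#' user where finer serum-level data exist. Two defect haplotypes are
#' categorized `Deficient`.
#'
#' @return Data frame `class1`, `class2`, `level`, `source`.
#' @export
default_level_rules <- function() {
  r <- rbind(
    c("High", "High", "High", "extrapolated"),
    c("High", "Intermediate", "High", "extrapolated"),
    c("High", "Low", "Medium", "literature"),
    c("High", "Undetectable", "Medium", "extrapolated"),
    c("Intermediate", "Intermediate", "Intermediate", "extrapolated"),
    c("Intermediate", "Low", "Low", "extrapolated"),
    c("Intermediate", "Undetectable", "Low", "literature"),
    c("Low", "Low", "Low", "extrapolated"),
    c("Low", "Undetectable", "Low", "extrapolated"),
    c("Undetectable", "Undetectable", "Deficient", "extrapolated")
  )
  stats::setNames(as.data.frame(r, stringsAsFactors = FALSE),
                  c("class1", "class2", "level", "source"))
}

#' MBL serum-level category of a diplotype
#'
#' Looks up the unordered pair of the two haplotypes' phenotype classes in
#' a rule table (default [default_level_rules()]). Pairs not covered by the
#' table return `"uncategorized"`.
#'
#' @param diplotype A `"H1/H2"` string or character vector of two names.
#' @param rules A rule table as returned by [default_level_rules()].
#' @param hap_panel A `haplotype_panel`.
#' @return A single level string.
#' @examples
#' diplotype_level("HYPA/LXPA")  # "Medium"
#' @export
diplotype_level <- function(diplotype, rules = default_level_rules(),
                            hap_panel = mbl2_haplotype_panel()) {
  names2 <- if (length(diplotype) == 1)
    strsplit(diplotype, "/", fixed = TRUE)[[1]] else diplotype
  if (length(names2) != 2) stop("a diplotype names exactly two haplotypes")
  cls <- sort(phenotype_of(names2, hap_panel))
  rkey <- paste(pmin(rules$class1, rules$class2),
                pmax(rules$class1, rules$class2))
  hit <- match(paste(cls[1], cls[2]), rkey)
  if (is.na(hit)) "uncategorized" else rules$level[hit]
}

#' Resolve a whole cohort and annotate phenotypes
#'
#' With `ambiguous = "unresolved"` (the default) samples whose genotype is
#' consistent with more than one panel pair keep `status = "ambiguous"`
#' and list every pair. With `ambiguous = "most_likely"` such samples are
#' assigned the pair with the highest diplotype probability under
#' `rank_freq`; when `rank_freq` is missing it is estimated from the
#' cohort itself by [em_haplotype_frequencies()].
#'
#' @param cohort An `mbl2_cohort` with complete genotypes.
#' @param hap_panel A `haplotype_panel`.
#' @param rules Diplotype-level rule table.
#' @param ambiguous How to report multi-pair genotypes (see Details).
#' @param rank_freq Optional haplotype frequencies for the ranking.
#' @return Data frame `sample_id`, `diplotype` (or `NA`), `status`,
#'   `level`.
#' @export
resolve_cohort <- function(cohort, hap_panel = mbl2_haplotype_panel(),
                           rules = default_level_rules(),
                           ambiguous = c("unresolved", "most_likely"),
                           rank_freq = NULL) {
  ambiguous <- match.arg(ambiguous)
  panel <- mbl2_snp_panel()
  if (ambiguous == "most_likely" && is.null(rank_freq)) {
    rank_freq <- cohort_panel_freq(cohort, hap_panel)
  }
  out <- data.frame(sample_id = cohort$sample_id,
                    diplotype = NA_character_,
                    status = NA_character_,
                    level = NA_character_,
                    stringsAsFactors = FALSE)
  # resolve each distinct genotype once
  key <- do.call(paste, as.data.frame(cohort)[panel$rs_id])
  for (k in unique(key)) {
    rows <- which(key == k)
    res <- resolve_diplotype(cohort_genotype(cohort, rows[1], panel),
                             hap_panel, rank_freq = rank_freq)
    out$status[rows] <- res$status
    if (res$status == "unique" ||
        (res$status == "ambiguous" && ambiguous == "most_likely")) {
      out$diplotype[rows] <- res$pairs[1]
      out$level[rows] <- diplotype_level(res$pairs[1], rules, hap_panel)
    } else if (res$status == "ambiguous") {
      out$diplotype[rows] <- paste(res$pairs, collapse = ";")
    }
  }
  out
}

# Panel-haplotype frequencies estimated from the cohort by EM, for ranking
# ambiguous diplotypes.
cohort_panel_freq <- function(cohort, hap_panel = mbl2_haplotype_panel()) {
  fit <- em_haplotype_frequencies(cohort)
  f <- fit$freq[hap_panel$bases]
  f[is.na(f)] <- 0
  if (sum(f) == 0) f[] <- 1
  stats::setNames(f / sum(f), hap_panel$name)
}

#' Haplotype frequencies by counting resolved diplotypes
#'
#' Resolves every sample and counts each panel haplotype among the `2N`
#' resolved haplotypes. By default ambiguous genotypes contribute their
#' most likely pair (frequency-ranked, see [resolve_cohort()]); with
#' `ambiguous = "unresolved"` they are dropped from numerator and
#' denominator.
#'
#' @param cohort An `mbl2_cohort`.
#' @param hap_panel A `haplotype_panel`.
#' @param ambiguous Passed to [resolve_cohort()].
#' @return Named numeric vector of frequencies in percent, in panel order.
#' @export
count_haplotypes <- function(cohort, hap_panel = mbl2_haplotype_panel(),
                             ambiguous = c("most_likely", "unresolved")) {
  ambiguous <- match.arg(ambiguous)
  res <- resolve_cohort(cohort, hap_panel, ambiguous = ambiguous)
  keep <- if (ambiguous == "most_likely") c("unique", "ambiguous")
          else "unique"
  res <- res[res$status %in% keep & !is.na(res$diplotype), , drop = FALSE]
  res <- res[!grepl(";", res$diplotype, fixed = TRUE), , drop = FALSE]
  haps <- unlist(strsplit(res$diplotype, "/", fixed = TRUE))
  counts <- table(factor(haps, levels = hap_panel$name))
  freq <- 100 * as.numeric(counts) / length(haps)
  stats::setNames(freq, hap_panel$name)
}
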