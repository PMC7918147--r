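# Cohort file formats and the reconstruction of the 328-sample Czech
# cohort from its published haplogenotype class distribution.

#' The 26 haplogenotype classes of the Czech cohort
#'
#' The published distribution of six-SNP MBL2 haplogenotypes among 328
#' healthy Czech individuals: each class's genotype string (canonical SNP
#' order), the secretor haplotype pair it translates to, and its relative
#' frequency in percent.
#'
#' @return Data frame `genotype`, `diplotype`, `freq_pct` (26 rows).
#' @export
table5_classes <- function() {
  txt <- c(
    "GC GG CT CC GG GG|HYPA/LYQA|16.2",
    "GC GC CC CC GG GG|HYPA/LXPA|11.9",
    "CC GC CT CC GG GG|LYQA/LXPA|10.1",
    "GG GG CC CC GG GG|HYPA/HYPA|7.9",
    "GC GG CC CC GA GG|HYPA/LYPB|7.3",
    "CC GG CT CC GA GG|LYQA/LYPB|6.1",
    "CC CC CC CC GG GG|LXPA/LXPA|5.5",
    "GG GG CC CT GG GG|HYPA/HYPD|5.2",
    "CC GC CC CC GA GG|LXPA/LYPB|4.0",
    "CC GG TT CC GG GG|LYQA/LYQA|3.7",
    "GC GG CC CT GA GG|LYPB/HYPD|3.0",
    "GC GC CC CT GG GG|LXPA/HYPD|3.0",
    "GC GG CT CT GG GG|LYQA/HYPD|2.4",
    "GC GG CC CC GG GG|HYPA/LYPA|2.4",
    "CC GG CC CC AA GG|LYPB/LYPB|2.1",
    "CC GC CT CC GG GA|LXPA/LYQC|1.8",
    "CC GG CC CC GA GG|LYPB/LYPA|1.2",
    "CC GG CT CC GG GG|LYQA/LYPA|1.2",
    "GC GG CC CT GG GG|HYPD/LYPA|0.9",
    "CC GC CC CC GG GG|LXPA/LYPA|0.9",
    "GG GG CC TT GG GG|HYPD/HYPD|0.9",
    "GC GG CT CC GG GA|HYPA/LYQC|0.6",
    "CC GG CT CC GA GA|LYPB/LYQC|0.6",
    "CC GG TT CC GG GA|LYQA/LYQC|0.3",
    "GC GG CT CT GG GA|HYPD/LYQC|0.3",
    "GC GG CT CC GA GG|HYPA/LYQB|0.3")
  parts <- strsplit(txt, "|", fixed = TRUE)
  data.frame(genotype = vapply(parts, `[`, character(1), 1),
             diplotype = vapply(parts, `[`, character(1), 2),
             freq_pct = as.numeric(vapply(parts, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Apportion class counts by largest remainder
#'
#' Distributes `N` among classes proportionally to `freq` and resolves the
#' fractional seats by largest remainder (ties broken by class order).
#'
#' @param freq Numeric vector of class weights (need not sum to anything
#'   particular).
#' @param N Total to apportion.
#' @return Integer vector summing to `N`.
#' @export
largest_remainder <- function(freq, N) {
  quota <- freq / sum(freq) * N
  base <- floor(quota)
  left <- N - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Reconstruct the 328-sample Czech cohort from its class distribution
#'
#' Rebuilds a per-sample genotype table from the published class
#' frequencies: each class receives `round(freq_pct * N / 100)` synthetic
#' samples carrying the class genotype. Nearest-integer rounding conserves
#' `N = 328` exactly on the published table (asserted; any other outcome
#' would indicate a corrupted class table). For arbitrary class tables use
#' `rounding = "largest_remainder"`, which conserves `N` by construction.
#' Because class frequencies are printed to one decimal place, per-class
#' counts (and every statistic computed from the reconstruction) carry a
#' rounding uncertainty of up to about 0.15 percentage points per class.
#'
#' @param classes A class table as from [table5_classes()].
#' @param N Cohort size.
#' @param rounding `"nearest"` or `"largest_remainder"`.
#' @return An `mbl2_cohort` of `N` samples with attribute `diplotype`
#'   (the generating class's haplotype pair, one per sample).
#' @examples
#' coh <- reconstruct_table5_cohort()
#' nrow(coh)  # 328
#' @export
reconstruct_table5_cohort <- function(classes = table5_classes(), N = 328,
                                      rounding = c("nearest",
                                                   "largest_remainder")) {
  rounding <- match.arg(rounding)
  counts <- switch(rounding,
    nearest = as.integer(round(classes$freq_pct * N / 100)),
    largest_remainder = largest_remainder(classes$freq_pct, N))
  if (sum(counts) != N) {
    stop("class counts sum to ", sum(counts), ", not ", N,
         "; the class table is corrupted or needs largest-remainder",
         " rounding")
  }
  panel <- mbl2_snp_panel()
  gvs <- lapply(classes$genotype, parse_genotype_string, panel = panel)
  rows <- rep(seq_len(nrow(classes)), counts)
  gmat <- do.call(rbind, gvs)[rows, , drop = FALSE]
  cohort <- mbl2_cohort(sprintf("CZ%03d", seq_len(N)), gmat, panel)
  attr(cohort, "diplotype") <- classes$diplotype[rows]
  cohort
}

#' Read / write cohort genotype tables as tab-separated text
#'
#' The TSV has a header row with `sample_id` plus one column per SNP rs id;
#' cells are two-base diplets (any within-diplet order) or `"."` for
#' missing. Unknown SNP columns are rejected unless `loose = TRUE`, in
#' which case they are dropped with a warning.
#'
#' @param path File path.
#' @param panel A `snp_panel`.
#' @param loose Tolerate (drop) unknown columns.
#' @return `read_genotype_tsv` returns an `mbl2_cohort`.
#' @export
read_genotype_tsv <- function(path, panel = mbl2_snp_panel(),
                              loose = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column")
  extra <- setdiff(names(df), c("sample_id", panel$rs_id))
  if (length(extra)) {
    if (!loose) stop("unknown SNP column(s): ", paste(extra, collapse = ", "))
    warning("dropping unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  absent <- setdiff(panel$rs_id, names(df))
  if (length(absent)) stop("missing SNP column(s): ",
                           paste(absent, collapse = ", "))
  g <- df[, panel$rs_id, drop = FALSE]
  for (j in seq_along(g)) g[[j]][g[[j]] %in% c(".", "")] <- NA_character_
  bad <- which(!vapply(seq_len(nrow(g)), function(r)
    all(is.na(unlist(g[r, ])) | grepl("^[ACGT]{2}$", unlist(g[r, ]))),
    logical(1)))
  if (length(bad)) {
    stop("malformed diplet at data line ", bad[1], " of ", path)
  }
  mbl2_cohort(df$sample_id, g, panel)
}

#' @rdname read_genotype_tsv
#' @param cohort An `mbl2_cohort`.
#' @export
write_genotype_tsv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df[is.na(df)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write cohorts in the XML dialect
#'
#' A minimal XML dialect for sample-genotype exchange, defined by this
#' package:
#' ```
#' <cohort>
#'   <sample id="S001">
#'     <genotype snp="rs11003125">CG</genotype>
#'     ...
#'   </sample>
#' </cohort>
#' ```
#' Every sample element must carry one `genotype` child per panel SNP
#' (`"."` for missing). The reader produces a cohort identical to what
#' [read_genotype_tsv()] yields on the same content.
#'
#' @param path File path.
#' @param panel A `snp_panel`.
#' @return `read_xml_cohort` returns an `mbl2_cohort`.
#' @export
read_xml_cohort <- function(path, panel = mbl2_snp_panel()) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "cohort") {
    stop("root element must be <cohort>, found <",
         xml2::xml_name(doc), ">")
  }
  samples <- xml2::xml_find_all(doc, "./sample")
  if (length(samples) == 0) {
    return(mbl2_cohort(character(0),
                       matrix(character(0), 0, nrow(panel)), panel))
  }
  ids <- xml2::xml_attr(samples, "id")
  if (anyNA(ids)) stop("<sample> element without an id attribute")
  gmat <- matrix(NA_character_, nrow = length(samples),
                 ncol = nrow(panel))
  for (s in seq_along(samples)) {
    gts <- xml2::xml_find_all(samples[[s]], "./genotype")
    snps <- xml2::xml_attr(gts, "snp")
    vals <- xml2::xml_text(gts)
    absent <- setdiff(panel$rs_id, snps)
    if (length(absent)) {
      stop("sample '", ids[s], "' lacks <genotype> for ",
           paste(absent, collapse = ", "))
    }
    v <- vals[match(panel$rs_id, snps)]
    v[v == "."] <- NA_character_
    gmat[s, ] <- v
  }
  mbl2_cohort(ids, gmat, panel)
}

#' @rdname read_xml_cohort
#' @param cohort An `mbl2_cohort`.
#' @export
write_xml_cohort <- function(cohort, path, panel = mbl2_snp_panel()) {
  doc <- xml2::xml_new_root("cohort")
  for (r in seq_len(nrow(cohort))) {
    s <- xml2::xml_add_child(doc, "sample", id = cohort$sample_id[r])
    for (rs in panel$rs_id) {
      v <- cohort[[rs]][r]
      xml2::xml_add_child(s, "genotype", if (is.na(v)) "." else v,
                          snp = rs)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
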