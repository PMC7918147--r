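# In-silico model of the SNaPshot single-base-extension assay: expected
# electropherogram layout, a seeded synthetic peak generator and a
# peak-to-genotype caller with QC flags.

#' Caller parameters
#'
#' Tuning knobs of the peak-to-genotype caller.
#'
#' @param size_tolerance Half-width (nt) of the window around each SNP's
#'   expected apparent size within which peaks are considered.
#' @param min_peak_height Absolute fluorescence floor; smaller peaks are
#'   ignored.
#' @param het_balance Minimum minor/major peak-height ratio within one SNP
#'   for a heterozygote call. Peak pairs below this ratio are treated as a
#'   homozygote for the major peak plus an artifact, mirroring the
#'   heterozygote-balance filter used during electropherogram review.
#' @param dye_to_base Named character vector mapping dye colors to bases,
#'   used when peak tables carry dye colors instead of called bases.
#'   Default is the standard SNaPshot chemistry (green=A, black=C, blue=G,
#'   red=T).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(size_tolerance = 2.0,
                          min_peak_height = 50,
                          het_balance = 0.20,
                          dye_to_base = c(green = "A", black = "C",
                                          blue = "G", red = "T")) {
  stopifnot(size_tolerance > 0, het_balance > 0, het_balance < 1,
            min_peak_height >= 0)
  structure(list(size_tolerance = size_tolerance,
                 min_peak_height = min_peak_height,
                 het_balance = het_balance,
                 dye_to_base = dye_to_base),
            class = "caller_params")
}

#' Expected electropherogram layout of the SBE panel
#'
#' Each SBE primer is extended by exactly one fluorescent ddNTP, so the
#' expected apparent fragment size is `primer_length + 1`. The observed
#' extension base equals the coding-strand allele base for forward primers
#' and its Watson-Crick complement for reverse primers.
#'
#' @param panel A `snp_panel`.
#' @return Data frame with one row per SNP: `rs_id`, `size`,
#'   `base_major_obs`, `base_minor_obs` (instrument-observed bases).
#' @examples
#' expected_layout()
#' @export
expected_layout <- function(panel = mbl2_snp_panel()) {
  rev_strand <- panel$sbe_strand == "reverse"
  obs_major <- ifelse(rev_strand, complement_base(panel$base_major),
                      panel$base_major)
  obs_minor <- ifelse(rev_strand, complement_base(panel$base_minor),
                      panel$base_minor)
  data.frame(rs_id = panel$rs_id,
             size = panel$primer_length + 1L,
             strand = panel$sbe_strand,
             base_major_obs = obs_major,
             base_minor_obs = obs_minor,
             stringsAsFactors = FALSE)
}

#' Noise model for synthetic peak tables
#'
#' @param height_cv Coefficient of variation of peak heights (0 = fixed
#'   heights).
#' @param size_jitter_sd Standard deviation (nt) of apparent-size jitter.
#' @param artifact_rate Per-sample probability of one non-specific artifact
#'   peak appearing at the position and color of the D or Q allele, the
#'   artifact pattern seen with partially degraded DNA.
#' @param mean_height Mean peak height (arbitrary fluorescence units).
#' @param het_ratio Height of the second (minor) allele peak of a
#'   heterozygote relative to the first; 1 = balanced.
#' @return A list of class `sbe_noise_model`.
#' @export
sbe_noise_model <- function(height_cv = 0, size_jitter_sd = 0,
                            artifact_rate = 0, mean_height = 2000,
                            het_ratio = 1) {
  stopifnot(height_cv >= 0, size_jitter_sd >= 0,
            artifact_rate >= 0, artifact_rate <= 1,
            mean_height > 0, het_ratio > 0, het_ratio <= 1)
  structure(list(height_cv = height_cv, size_jitter_sd = size_jitter_sd,
                 artifact_rate = artifact_rate, mean_height = mean_height,
                 het_ratio = het_ratio),
            class = "sbe_noise_model")
}

#' Simulate an SBE peak table for one sample
#'
#' Emits one peak per allele present in the genotype at the SNP's expected
#' apparent size (plus optional jitter), with the instrument-observed base
#' (complemented for reverse-strand primers). Heterozygous SNPs produce two
#' peaks whose relative height is controlled by the noise model; optionally
#' a non-specific artifact peak is added at the D- or Q-allele position.
#'
#' @param genotype A complete genotype vector (named diplets, no `NA`).
#' @param panel A `snp_panel`.
#' @param noise An `sbe_noise_model`.
#' @param seed Integer seed; required for reproducibility whenever the
#'   noise model is stochastic.
#' @param sample_id Sample identifier recorded in the table.
#' @return Data frame of class `peak_table`: `sample_id`, `size`, `base`,
#'   `height`.
#' @export
simulate_peak_table <- function(genotype, panel = mbl2_snp_panel(),
                                noise = sbe_noise_model(), seed = NULL,
                                sample_id = "sample1") {
  if (anyNA(genotype)) stop("genotype must be complete")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  layout <- expected_layout(panel)
  sizes <- numeric(0); bases <- character(0); heights <- numeric(0)
  rheight <- function(mu) {
    if (noise$height_cv == 0) mu
    else max(1, stats::rnorm(1, mu, noise$height_cv * mu))
  }
  rsize <- function(s) {
    if (noise$size_jitter_sd == 0) s
    else stats::rnorm(1, s, noise$size_jitter_sd)
  }
  for (i in seq_len(nrow(panel))) {
    gt <- strsplit(genotype[[panel$rs_id[i]]], "")[[1]]
    alleles <- unique(gt)
    obs <- c(layout$base_major_obs[i], layout$base_minor_obs[i])
    names(obs) <- c(panel$base_major[i], panel$base_minor[i])
    mult <- if (length(alleles) == 2) c(1, noise$het_ratio) else 1
    for (k in seq_along(alleles)) {
      sizes <- c(sizes, rsize(layout$size[i]))
      bases <- c(bases, obs[[alleles[k]]])
      heights <- c(heights, rheight(noise$mean_height * mult[k]))
    }
  }
  if (noise$artifact_rate > 0 && stats::runif(1) < noise$artifact_rate) {
    # non-specific peak at the position/color of the D or Q allele
    target <- sample(c("rs5030737", "rs7095891"), 1)
    j <- match(target, layout$rs_id)
    sizes <- c(sizes, rsize(layout$size[j]))
    bases <- c(bases, layout$base_minor_obs[j])
    heights <- c(heights, rheight(noise$mean_height * 0.3))
  }
  out <- data.frame(sample_id = sample_id, size = sizes, base = bases,
                    height = heights, stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Call genotypes from an SBE peak table
#'
#' Assigns each peak to the nearest panel SNP within `size_tolerance` (a
#' peak equidistant from two SNP windows is flagged and dropped), discards
#' peaks below `min_peak_height`, flags in-window peaks whose base matches
#' neither expected allele (`unexpected_base`) and excludes them from the
#' genotype. Among surviving allele peaks of one SNP, two alleles whose
#' minor/major height ratio reaches `het_balance` yield a heterozygote;
#' below the ratio the call is homozygous for the major allele with an
#' `imbalance_filtered` flag. Instrument bases of reverse-strand SNPs are
#' complemented back to the coding strand before reporting. SNPs with no
#' usable peak are missing with a `low_signal` flag.
#'
#' @param peaks A `peak_table` for one sample.
#' @param panel A `snp_panel`.
#' @param params A `caller_params`.
#' @return Data frame with one row per SNP in canonical order: `rs_id`,
#'   `genotype` (alphabetical diplet or `NA`), `flags` (comma-separated,
#'   `""` if clean).
#' @export
call_sample <- function(peaks, panel = mbl2_snp_panel(),
                        params = caller_params()) {
  layout <- expected_layout(panel)
  n <- nrow(panel)
  genotype <- rep(NA_character_, n)
  flags <- vector("list", n)
  for (i in seq_len(n)) flags[[i]] <- character(0)

  if (nrow(peaks) > 0 && !all(peaks$base %in% c("A", "C", "G", "T"))) {
    # dye-color peak tables
    peaks$base <- unname(params$dye_to_base[peaks$base])
    if (anyNA(peaks$base)) stop("unknown dye color in peak table")
  }

  kept <- peaks[peaks$height >= params$min_peak_height, , drop = FALSE]
  # peak -> SNP assignment by nearest expected size within tolerance
  assign_snp <- rep(NA_integer_, nrow(kept))
  if (nrow(kept) > 0) {
    for (p in seq_len(nrow(kept))) {
      d <- abs(kept$size[p] - layout$size)
      inwin <- which(d <= params$size_tolerance)
      if (length(inwin) == 0) next
      best <- inwin[d[inwin] == min(d[inwin])]
      if (length(best) > 1) {
        # exact tie between two SNP windows: conservative drop
        for (b in best) flags[[b]] <- union(flags[[b]], "ambiguous_size")
        next
      }
      assign_snp[p] <- best
    }
  }

  for (i in seq_len(n)) {
    mine <- kept[which(assign_snp == i), , drop = FALSE]
    if (nrow(mine) == 0) {
      flags[[i]] <- union(flags[[i]], "low_signal")
      next
    }
    expected <- c(layout$base_major_obs[i], layout$base_minor_obs[i])
    unexpected <- !(mine$base %in% expected)
    if (any(unexpected)) flags[[i]] <- union(flags[[i]], "unexpected_base")
    mine <- mine[!unexpected, , drop = FALSE]
    if (nrow(mine) == 0) {
      flags[[i]] <- union(flags[[i]], "low_signal")
      next
    }
    # sum heights per observed base (duplicate peaks of one allele merge)
    hts <- tapply(mine$height, mine$base, sum)
    hts <- sort(hts, decreasing = TRUE)
    obs_to_coding <- c(panel$base_major[i], panel$base_minor[i])
    names(obs_to_coding) <- expected
    if (length(hts) == 1) {
      b <- obs_to_coding[[names(hts)[1]]]
      genotype[i] <- paste(sort(c(b, b)), collapse = "")
    } else {
      ratio <- hts[2] / hts[1]
      major <- obs_to_coding[[names(hts)[1]]]
      if (ratio >= params$het_balance) {
        minor <- obs_to_coding[[names(hts)[2]]]
        genotype[i] <- paste(sort(c(major, minor)), collapse = "")
      } else {
        genotype[i] <- paste(sort(c(major, major)), collapse = "")
        flags[[i]] <- union(flags[[i]], "imbalance_filtered")
      }
    }
  }

  data.frame(rs_id = panel$rs_id,
             genotype = genotype,
             flags = vapply(flags, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Call genotypes for a multi-sample peak table
#'
#' @param peaks A `peak_table` possibly covering several `sample_id`s.
#' @param panel A `snp_panel`.
#' @param params A `caller_params`.
#' @return An `mbl2_cohort` of the called genotypes, with a `call_flags`
#'   attribute (data frame `sample_id`, `rs_id`, `flags` for flagged calls).
#' @export
call_cohort <- function(peaks, panel = mbl2_snp_panel(),
                        params = caller_params()) {
  ids <- unique(peaks$sample_id)
  gmat <- matrix(NA_character_, nrow = length(ids), ncol = nrow(panel))
  flagged <- list()
  for (s in seq_along(ids)) {
    calls <- call_sample(peaks[peaks$sample_id == ids[s], , drop = FALSE],
                         panel, params)
    gmat[s, ] <- calls$genotype
    f <- calls[calls$flags != "", c("rs_id", "flags")]
    if (nrow(f)) flagged[[length(flagged) + 1L]] <-
        cbind(sample_id = ids[s], f)
  }
  cohort <- mbl2_cohort(ids, gmat, panel)
  attr(cohort, "call_flags") <- if (length(flagged))
    do.call(rbind, flagged)
  else data.frame(sample_id = character(0), rs_id = character(0),
                  flags = character(0))
  cohort
}

#' Read / write peak tables as tab-separated text
#'
#' Columns: `sample_id`, `size`, `base`, `height` (header required).
#'
#' @param path File path.
#' @return `read_peak_tsv` returns a `peak_table` data frame.
#' @export
read_peak_tsv <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "size", "base", "height")
  if (!all(need %in% names(pt))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  pt <- pt[, need]
  pt$sample_id <- as.character(pt$sample_id)
  class(pt) <- c("peak_table", "data.frame")
  pt
}

#' @rdname read_peak_tsv
#' @param peaks A `peak_table`.
#' @export
write_peak_tsv <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
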