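#' Binned coverage profile of one embryo
#'
#' A `bin_profile` carries one sample through the coverage stages: raw per-bin
#' read counts (`raw`), GC-bias-corrected counts (`corrected`), and the
#' normalised copy-number ratio (`cn_ratio`, scaled so diploid = 2), together
#' with sample-level depth summaries. Create one with [count_reads()] or
#' [simulate_bin_counts()]; advance it with [gc_correct()] and
#' [normalize_cn()]. `tidy()` returns the per-bin table, `glance()` the
#' one-row sample summary.
#'
#' @name bin_profile
NULL

new_bin_profile <- function(genome, raw, sample_id, n_reads_total, n_dropped,
                            read_length, mito_read_count,
                            mito_fraction_covered) {
  bins <- genome$bins
  stopifnot(length(raw) == nrow(bins))
  bins$raw <- as.numeric(raw)
  bins$corrected <- NA_real_
  bins$cn_ratio <- NA_real_
  structure(
    list(sample_id = sample_id, bins = bins, genome = genome,
         n_reads_total = n_reads_total, n_dropped = n_dropped,
         read_length = read_length,
         genome_mean_depth = sum(raw) * read_length / genome_length(genome),
         mito_read_count = mito_read_count,
         mito_mean_depth = mito_read_count * read_length / genome$mito_length,
         mito_fraction_covered = mito_fraction_covered,
         sample_median = NA_real_, sample_mad = NA_real_,
         stage = "raw"),
    class = "bin_profile"
  )
}

#' @export
print.bin_profile <- function(x, ...) {
  cat("<bin_profile> sample ", x$sample_id, " [stage: ", x$stage, "]  ",
      nrow(x$bins), " bins, ", format(sum(x$bins$raw), big.mark = ","),
      " nuclear reads (", x$n_dropped, " dropped), mito depth ratio ",
      if (x$genome_mean_depth > 0)
        sprintf("%.1f", x$mito_mean_depth / x$genome_mean_depth) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' @rdname bin_profile
#' @param x A `bin_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bin_profile <- function(x, ...) {
  dplyr::select(x$bins, "chrom", "bin", "start", "end", "gc", "raw",
                "corrected", "cn_ratio")
}

#' @rdname bin_profile
#' @exportS3Method generics::glance
glance.bin_profile <- function(x, ...) {
  tibble(sample_id = x$sample_id, stage = x$stage,
         n_bins = nrow(x$bins), n_reads_total = x$n_reads_total,
         n_dropped = x$n_dropped,
         genome_mean_depth = x$genome_mean_depth,
         mito_mean_depth = x$mito_mean_depth,
         mito_fraction_covered = x$mito_fraction_covered,
         sample_median = x$sample_median, sample_mad = x$sample_mad)
}

# GC-decile trend evaluated at every bin. Each stratum's level is the median
# across chromosomes of the within-chromosome stratum medians, so a single
# aneuploid chromosome that happens to dominate a GC stratum cannot drag the
# stratum onto its shifted copy level.
stratified_gc_fit <- function(raw, gc, auto, chrom) {
  breaks <- unique(quantile(gc[auto], probs = seq(0, 1, 0.1)))
  stratum <- cut(gc, breaks = breaks, include.lowest = TRUE)
  per_chrom <- tapply(raw[auto], list(stratum[auto], chrom[auto]), median)
  med <- apply(per_chrom, 1, median, na.rm = TRUE)
  fhat <- as.numeric(med[stratum])
  fhat[is.na(fhat)] <- median(raw[auto])
  fhat
}

# Fraction of [0, total) covered by >= 1 interval [start, end).
interval_cover_fraction <- function(starts, ends, total) {
  if (length(starts) == 0L) return(0)
  o <- order(starts)
  s <- starts[o]; e <- pmin(ends[o], total)
  covered <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      covered <- covered + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  (covered + (cur_e - cur_s)) / total
}

#' Bin aligned read positions
#'
#' Assigns each read to the fixed-width genome bin containing its start
#' position (reads are far shorter than bins, so fractional overlap is not
#' modelled). Mitochondrial reads are tallied separately into the mean-depth
#' and coverage-fraction fields; reads on unknown chromosomes or out of
#' bounds are dropped with a tally, and an unknown-chromosome fraction above
#' `unknown_tol` raises an input-mismatch error.
#'
#' @param reads Data frame of read positions `chrom, start` (0-based;
#'   an `end` column is ignored for binning).
#' @param genome A `genome_model`.
#' @param read_length Read length in bp used for depth computations.
#' @param sample_id Sample identifier.
#' @param unknown_tol Maximum tolerated fraction of reads on chromosomes
#'   absent from the genome model (default 1%).
#' @return A `bin_profile` at the raw-count stage.
#' @export
#' @examples
#' g <- genome_model(data.frame(chrom = "chr1", length = 1e7))
#' reads <- data.frame(chrom = "chr1", start = c(0, 10, 1e6 + 1))
#' tidy(count_reads(reads, g))$raw
count_reads <- function(reads, genome, read_length = 50, sample_id = "sample",
                        unknown_tol = 0.01) {
  stopifnot(inherits(genome, "genome_model"))
  reads <- as_tibble(reads)
  n_input <- nrow(reads)

  known <- reads$chrom %in% genome$chromosomes$chrom
  is_mito <- reads$chrom == genome$mito_name
  n_unknown <- sum(!known & !is_mito)
  if (n_input > 0 && n_unknown / n_input > unknown_tol) {
    abort(sprintf("%.1f%% of reads on chromosomes absent from the genome model",
                  100 * n_unknown / n_input),
          class = "embryoscreen_input_mismatch")
  }

  mito <- reads[is_mito, ]
  mito_in <- mito$start >= 0 & mito$start < genome$mito_length
  nuclear <- reads[known, ]
  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  in_bounds <- nuclear$start >= 0 & nuclear$start < chrom_len[nuclear$chrom]
  nuclear <- nuclear[in_bounds, ]
  n_dropped <- n_unknown + sum(!in_bounds) + sum(!mito_in)

  bins <- genome$bins
  key <- paste(nuclear$chrom, floor(nuclear$start / genome$bin_size))
  counts_tab <- table(key)
  raw <- as.numeric(counts_tab[paste(bins$chrom, bins$bin)])
  raw[is.na(raw)] <- 0

  mito <- mito[mito_in, ]
  new_bin_profile(
    genome = genome, raw = raw, sample_id = sample_id,
    n_reads_total = n_input, n_dropped = n_dropped, read_length = read_length,
    mito_read_count = nrow(mito),
    mito_fraction_covered = interval_cover_fraction(
      mito$start, mito$start + read_length, genome$mito_length)
  )
}

#' Remove GC/WGA coverage bias
#'
#' Whole-genome amplification of a few biopsied cells induces a smooth,
#' GC-dependent coverage bias. This stage fits the count-versus-GC trend
#' \eqn{\hat f} on autosomal bins and rescales each bin by
#' `raw / f(gc) * mean(f)`, then restores the total count mass exactly.
#' The default trend estimator is a robust LOESS (degree 2,
#' `family = "symmetric"` so CNV bins do not drag the fit); genomes with
#' fewer than 200 autosomal bins fall back to a stratified GC-decile median,
#' which is more stable at that scale. Bins with GC outside the fitted
#' support use the nearest-edge fit.
#'
#' @param profile A raw-stage [bin_profile].
#' @param method `"auto"` (default), `"loess"` or `"stratified"`.
#' @param span LOESS span (default 0.3).
#' @return The profile with `corrected` populated.
#' @export
gc_correct <- function(profile, method = c("auto", "loess", "stratified"),
                       span = 0.3) {
  stopifnot(inherits(profile, "bin_profile"))
  method <- match.arg(method)
  bins <- profile$bins
  auto <- bins$is_autosome
  if (sum(auto & bins$raw > 0) < 50) {
    abort("need >= 50 autosomal bins with nonzero counts for GC correction",
          class = "embryoscreen_insufficient_data")
  }
  gc <- bins$gc
  if (diff(range(gc[auto])) <= 0.001) {
    warn("degenerate GC track; GC correction is the identity")
    profile$bins$corrected <- bins$raw
    profile$stage <- "corrected"
    return(profile)
  }
  if (method == "auto") {
    method <- if (sum(auto) < 200) "stratified" else "loess"
  }

  gc_clamped <- pmin(pmax(gc, min(gc[auto])), max(gc[auto]))
  if (method == "loess") {
    # two-pass fit: a coarse stratified-median pre-fit flags bins whose
    # count ratio looks copy-number-shifted (|log2| > log2(1.37), i.e.
    # between the steepest within-stratum bias variation and a single-copy
    # change), and the smooth trend is fitted on the remaining bins only, so
    # CNV segments cannot drag the trend at sparse GC extremes
    f0 <- stratified_gc_fit(bins$raw, gc_clamped, auto, bins$chrom)
    ratio <- bins$raw / pmax(f0, 1e-8)
    keep <- auto & abs(log2(pmax(ratio, 1e-8) / median(ratio[auto]))) < log2(1.37)
    fit <- loess(raw ~ gc, data = bins[keep, ], span = span, degree = 2,
                 family = "symmetric",
                 control = stats::loess.control(surface = "direct"))
    fhat <- predict(fit, newdata = data.frame(
      gc = pmin(pmax(gc, min(gc[keep])), max(gc[keep]))))
  } else {
    fhat <- stratified_gc_fit(bins$raw, gc_clamped, auto, bins$chrom)
  }
  fhat <- pmax(fhat, 0.01 * mean(fhat, na.rm = TRUE))
  corrected <- bins$raw / fhat * mean(fhat[auto])
  # rescaling convention: correction preserves total count mass exactly
  corrected <- corrected * sum(bins$raw) / sum(corrected)

  profile$bins$corrected <- corrected
  profile$stage <- "corrected"
  profile
}

#' Normalise corrected counts to copy-number ratios
#'
#' Scales GC-corrected counts so the autosomal median sits exactly at 2
#' (diploid): `cn_ratio = 2 * corrected / median(autosomal corrected)`. Sex
#' chromosomes are excluded from the median and from the robust noise scale
#' so a male X does not shift the baseline. The per-sample noise scale is the
#' median absolute deviation of autosomal `cn_ratio` scaled by 1.4826 (a
#' consistent estimate of sigma under normality), which later drives the
#' dynamic calling thresholds.
#'
#' @param profile A corrected-stage [bin_profile].
#' @return The profile with `cn_ratio`, `sample_median` and `sample_mad`
#'   populated.
#' @export
normalize_cn <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  if (all(is.na(profile$bins$corrected))) {
    abort("run gc_correct() before normalize_cn()",
          class = "embryoscreen_stage_error")
  }
  auto <- profile$bins$is_autosome
  med <- median(profile$bins$corrected[auto])
  if (!is.finite(med) || med <= 0) {
    abort("autosomal median corrected count is zero; no signal",
          class = "embryoscreen_no_signal")
  }
  profile$bins$cn_ratio <- 2 * profile$bins$corrected / med
  profile$sample_median <- median(profile$bins$cn_ratio[auto])
  profile$sample_mad <- mad(profile$bins$cn_ratio[auto])  # 1.4826-scaled
  profile$stage <- "cn"
  profile
}

#' Mitochondrial depth-ratio statistics
#'
#' The relative mtDNA copy number of a sample is the ratio of mean
#' mitochondrial depth to mean nuclear genome depth
#' (`ChrM_depth / Mean_depth`); the coverage fraction is the share of
#' mitochondrial positions seen by at least one read.
#'
#' @param profile A [bin_profile].
#' @return One-row tibble `ratio, fraction_covered`.
#' @export
mito_stats <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  if (profile$genome_mean_depth <= 0) {
    abort("nuclear mean depth is zero; mtDNA ratio undefined",
          class = "embryoscreen_no_signal")
  }
  tibble(ratio = profile$mito_mean_depth / profile$genome_mean_depth,
         fraction_covered = profile$mito_fraction_covered)
}
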