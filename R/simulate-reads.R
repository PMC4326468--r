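#' Specify a simulated embryo karyotype
#'
#' A karyotype is a set of non-overlapping integer copy-number events on top
#' of a diploid background (autosomes at 2 copies; sex chromosomes at the
#' dose implied by `sex`), plus a multiplier on mitochondrial depth standing
#' in for per-embryo mtDNA copy-number variation.
#'
#' @param events Data frame with columns `chrom, start, end, copy_number`
#'   (0-based half-open bp; integer copies in 0..4). An empty data frame (the
#'   default) is euploid. A whole-chromosome event spans `[0, length)`.
#' @param sex `"XX"` or `"XY"`.
#' @param mito_copy_factor Positive multiplier on expected mitochondrial
#'   depth relative to the euploid baseline.
#' @return A list of class `karyotype_spec`.
#' @export
karyotype_spec <- function(events = NULL, sex = c("XX", "XY"),
                           mito_copy_factor = 1) {
  sex <- match.arg(sex)
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- tibble(chrom = character(), start = numeric(),
                     end = numeric(), copy_number = integer())
  }
  events <- as_tibble(events)[c("chrom", "start", "end", "copy_number")]
  stopifnot(all(events$end > events$start),
            all(events$copy_number %in% 0:4),
            mito_copy_factor > 0)
  if (any(events$copy_number == 2 & !is_sex_chrom(events$chrom))) {
    abort("copy number 2 on an autosome is not an event",
          class = "embryoscreen_invalid_karyotype")
  }
  # non-overlap within chromosome
  ev <- events[order(events$chrom, events$start), ]
  by_chrom <- split(ev, ev$chrom)
  for (e in by_chrom) {
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort("overlapping events on one chromosome",
            class = "embryoscreen_invalid_karyotype")
    }
  }
  structure(list(events = events, sex = sex,
                 mito_copy_factor = mito_copy_factor),
            class = "karyotype_spec")
}

#' Read-simulation configuration
#'
#' Controls depth, WGA-style GC bias and overdispersion of the simulator.
#' The default depth is the shallow-screen standard of 8.2 million reads per
#' 3.08 Gb human genome, scaled to the simulated genome's size; the default
#' mitochondrial depth ratio of 100 and overdispersion give a mitochondrial
#' contig covered at essentially every position, as in the real assay.
#'
#' @param n_reads Total nuclear reads; `NULL` (default) scales 8.2e6 to the
#'   genome length at simulation time.
#' @param gc_bias_peak,gc_bias_strength Unimodal (quadratic) sampling-weight
#'   curve `w(gc) = max(0.05, 1 - strength * (gc - peak)^2)`; strength 0 is
#'   bias-free. WGA amplification favours mid-GC fragments, hence a peak near
#'   0.45.
#' @param overdispersion Negative-binomial overdispersion of per-bin counts
#'   (`variance = mu + overdispersion * mu^2`); 0 gives Poisson counts.
#' @param mito_mean_depth_ratio Expected mitochondrial/nuclear mean-depth
#'   ratio for a euploid baseline embryo.
#' @param read_length Read length in bp (single-end 50 bp by default).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = NULL, gc_bias_peak = 0.45,
                            gc_bias_strength = 8, overdispersion = 0.01,
                            mito_mean_depth_ratio = 100, read_length = 50,
                            seed = 1) {
  stopifnot(is.null(n_reads) || (is_count(n_reads) && n_reads > 0),
            gc_bias_strength >= 0, overdispersion >= 0,
            mito_mean_depth_ratio > 0, is_count(read_length))
  structure(list(n_reads = n_reads, gc_bias_peak = gc_bias_peak,
                 gc_bias_strength = gc_bias_strength,
                 overdispersion = overdispersion,
                 mito_mean_depth_ratio = mito_mean_depth_ratio,
                 read_length = read_length, seed = seed),
            class = "read_sim_config")
}

gc_weight <- function(gc, cfg) {
  pmax(0.05, 1 - cfg$gc_bias_strength * (gc - cfg$gc_bias_peak)^2)
}

default_n_reads <- function(genome, cfg) {
  cfg$n_reads %||% round(8.2e6 * genome_length(genome) / 3.08e9)
}

# Integer copy number of each nuclear bin under a karyotype: diploid/sex-dosed
# background overridden by any event covering the bin midpoint.
expected_bin_cn <- function(genome, karyotype) {
  bins <- genome$bins
  cn <- ifelse(bins$is_autosome, 2,
               ifelse(is_x_chrom(bins$chrom),
                      if (karyotype$sex == "XX") 2 else 1,
                      if (karyotype$sex == "XX") 0 else 1))
  ev <- karyotype$events
  if (nrow(ev) > 0) {
    chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    bad <- !(ev$chrom %in% names(chrom_len)) | ev$start < 0 |
      ev$end > chrom_len[ev$chrom]
    if (any(bad)) {
      abort("karyotype event outside chromosome bounds",
            class = "embryoscreen_invalid_karyotype")
    }
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(ev))) {
      hit <- bins$chrom == ev$chrom[i] & mid >= ev$start[i] & mid < ev$end[i]
      cn[hit] <- ev$copy_number[i]
    }
  }
  cn
}

# Per-bin expected counts: proportional to (copy number / 2) x GC weight,
# normalised to n_reads.
expected_bin_counts <- function(genome, karyotype, cfg, n_reads) {
  w <- (expected_bin_cn(genome, karyotype) / 2) * gc_weight(genome$bins$gc, cfg)
  n_reads * w / sum(w)
}

draw_bin_counts <- function(mu, overdispersion) {
  if (overdispersion <= 0) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
}

# Expected number of mitochondrial reads so that
# E[mito depth / nuclear depth] = mito_mean_depth_ratio * mito_copy_factor.
expected_mito_reads <- function(genome, karyotype, cfg, n_reads) {
  cfg$mito_mean_depth_ratio * karyotype$mito_copy_factor *
    n_reads * genome$mito_length / genome_length(genome)
}

#' Simulate aligned read positions for one embryo
#'
#' Draws per-bin read counts as negative-binomial (Poisson when
#' `overdispersion = 0`) around an expectation proportional to local copy
#' number times the GC bias curve, then scatters read start positions
#' uniformly within each bin; mitochondrial reads are drawn so the expected
#' mitochondrial/nuclear depth ratio equals
#' `mito_mean_depth_ratio * mito_copy_factor`. Deterministic given
#' `cfg$seed`.
#'
#' @param genome A `genome_model`.
#' @param karyotype A [karyotype_spec()].
#' @param cfg A [read_sim_config()].
#' @return Tibble of read positions `chrom, start, end` (0-based half-open).
#' @seealso [simulate_bin_counts()] for the fast path that skips individual
#'   read positions.
#' @export
simulate_reads <- function(genome, karyotype, cfg = read_sim_config()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(karyotype, "karyotype_spec"))
  n_reads <- default_n_reads(genome, cfg)
  mu <- expected_bin_counts(genome, karyotype, cfg, n_reads)
  counts <- with_component_seed(cfg$seed, "bin_counts", 0L,
                                draw_bin_counts(mu, cfg$overdispersion))
  bins <- genome$bins
  starts <- with_component_seed(cfg$seed, "read_positions", 0L, {
    off <- runif(sum(counts))
    rep(bins$start, counts) +
      floor(off * pmax(1, rep(bins$end - bins$start, counts) - cfg$read_length))
  })
  nuclear <- tibble(chrom = rep(bins$chrom, counts), start = starts,
                    end = starts + cfg$read_length)

  m <- with_component_seed(cfg$seed, "mito_count", 0L,
                           rpois(1, expected_mito_reads(genome, karyotype, cfg, n_reads)))
  mstart <- with_component_seed(cfg$seed, "mito_positions", 0L,
                                floor(runif(m, 0, genome$mito_length - cfg$read_length)))
  dplyr::bind_rows(nuclear,
                   tibble(chrom = rep(genome$mito_name, m), start = mstart,
                          end = mstart + cfg$read_length))
}

#' Simulate a binned coverage profile directly
#'
#' Fast path of the simulator: draws the same per-bin counts as
#' [simulate_reads()] (identical first and second moments) but skips
#' materialising individual read positions, returning a raw-stage
#' [bin_profile] ready for [gc_correct()].
#'
#' @inheritParams simulate_reads
#' @param sample_id Sample identifier recorded in the profile.
#' @return A `bin_profile` at the raw-count stage.
#' @export
simulate_bin_counts <- function(genome, karyotype, cfg = read_sim_config(),
                                sample_id = "sim") {
  n_reads <- default_n_reads(genome, cfg)
  mu <- expected_bin_counts(genome, karyotype, cfg, n_reads)
  counts <- with_component_seed(cfg$seed, "bin_counts", 0L,
                                draw_bin_counts(mu, cfg$overdispersion))
  m <- with_component_seed(cfg$seed, "mito_count", 0L,
                           rpois(1, expected_mito_reads(genome, karyotype, cfg, n_reads)))
  mstart <- with_component_seed(cfg$seed, "mito_positions", 0L,
                                floor(runif(m, 0, genome$mito_length - cfg$read_length)))
  new_bin_profile(
    genome = genome, raw = counts, sample_id = sample_id,
    n_reads_total = sum(counts) + m, n_dropped = 0L,
    read_length = cfg$read_length,
    mito_read_count = m,
    mito_fraction_covered = interval_cover_fraction(mstart,
                                                    mstart + cfg$read_length,
                                                    genome$mito_length)
  )
}

#' Write / read BED-like read positions
#'
#' Three-column tab-separated text (`chrom`, 0-based `start`, `end`), the
#' simulator's on-disk interchange format.
#'
#' @param reads Tibble `chrom, start, end`.
#' @param path File path.
#' @return `read_bed_reads` returns a tibble; `write_reads_bed` returns
#'   `path` invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  readr::write_tsv(reads[c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_bed_reads <- function(path) {
  reads <- suppressWarnings(
    readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                    col_types = "cdd", progress = FALSE))
  if (nrow(reads) == 0L || !all(c("chrom", "start", "end") %in% names(reads)) ||
      anyNA(reads[["start"]])) {
    abort("malformed read file: expected 3-column BED-like TSV",
          class = "embryoscreen_input_error")
  }
  reads
}
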