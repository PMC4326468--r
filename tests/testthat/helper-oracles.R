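# Shared fixtures and independent oracles, built in code at test time.

# Small two-autosome genome with a flat or supplied GC track.
tiny_genome <- function(lengths = c(chr1 = 5e7, chr2 = 4e7), bin_size = 1e6,
                        gc = NULL, bands = 4) {
  spec <- synthetic_genome_spec(
    autosome_lengths = unname(lengths),
    include_sex_chromosomes = FALSE,
    band_count_per_chromosome = bands
  )
  g <- make_synthetic_genome(spec, seed = 7, bin_size = bin_size)
  if (!is.null(gc)) g$bins$gc <- gc
  g
}

# Mid-sized genome with sex chromosomes for calling tests.
sexed_genome <- function(seed = 7) {
  make_synthetic_genome(
    synthetic_genome_spec(autosome_lengths = c(40, 35, 30, 25) * 1e6,
                          x_length = 15e6, y_length = 10e6),
    seed = seed
  )
}

# Wrap a raw count vector in a profile without simulation.
profile_from_counts <- function(genome, raw, mito_reads = 0) {
  embryoscreen:::new_bin_profile(
    genome = genome, raw = raw, sample_id = "fixture",
    n_reads_total = sum(raw) + mito_reads, n_dropped = 0L, read_length = 50,
    mito_read_count = mito_reads, mito_fraction_covered = NA_real_
  )
}

# Brute-force single-split oracle: naive loop over all admissible splits.
naive_best_split <- function(values, min_seg_bins) {
  n <- length(values)
  best_i <- NA_integer_; best_t <- 0
  for (i in min_seg_bins:(n - min_seg_bins)) {
    l <- values[1:i]; r <- values[(i + 1):n]
    s <- sqrt((sum((l - mean(l))^2) + sum((r - mean(r))^2)) / (n - 2))
    t <- if (s == 0) {
      if (abs(mean(l) - mean(r)) > 1e-12) Inf else 0
    } else {
      (mean(l) - mean(r)) / (s * sqrt(1 / i + 1 / (n - i)))
    }
    if (abs(t) > abs(best_t)) { best_t <- t; best_i <- i }
  }
  if (abs(best_t) == 0) list(index = min_seg_bins, statistic = 0)
  else list(index = best_i, statistic = best_t)
}

# Exhaustive least-squares changepoint oracle: minimal within-segment SSE
# over all breakpoint sets of size k with segments >= min_len bins.
exhaustive_ls_breaks <- function(values, k, min_len = 3) {
  n <- length(values)
  if (k == 0) return(integer())
  sse <- function(breaks) {
    bounds <- c(0, breaks, n)
    sum(vapply(seq_len(length(bounds) - 1), function(j) {
      seg <- values[(bounds[j] + 1):bounds[j + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  cand <- utils::combn(seq_len(n - 1), k, simplify = FALSE)
  cand <- Filter(function(b) all(diff(c(0, b, n)) >= min_len), cand)
  stopifnot(length(cand) > 0)
  scores <- vapply(cand, sse, numeric(1))
  cand[[which.min(scores)]]
}

# Complete-enumeration two-sided Mann-Whitney oracle (no ties): enumerates
# every assignment of the pooled values to group a, computes U for each, and
# doubles the smaller tail probability of the observed U.
enumerate_mw <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1, simplify = FALSE)
  u_all <- vapply(idx, function(i) u_of(pooled[i], pooled[-i]), numeric(1))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Textbook Pearson chi-squared on a 2x2 table.
textbook_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Reciprocal-overlap match between one true event and a call table.
recovered <- function(event, calls, min_overlap = 0.5) {
  calls <- calls[calls$chrom == event$chrom, ]
  for (k in seq_len(nrow(calls))) {
    ov <- max(0, min(calls$end_bp[k], event$end) -
                 max(calls$start_bp[k], event$start))
    if (ov >= min_overlap * (event$end - event$start) &&
        ov >= min_overlap * calls$length_bp[k]) {
      return(TRUE)
    }
  }
  FALSE
}

hg18_fixture_genome <- function() {
  cb <- read_cytoband(system.file("extdata",
                                  "cytoband_hg18_chr1_chr2_synthetic.txt",
                                  package = "embryoscreen"))
  genome_model(
    data.frame(chrom = c("chr1", "chr2"),
               length = c(247249719, 242951149)),
    bin_size = 1e6, cytobands = cb
  )
}
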