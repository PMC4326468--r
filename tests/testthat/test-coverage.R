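test_that("reads land in the bin containing their start position", {
  g <- genome_model(data.frame(chrom = "chr1", length = 1e7))
  reads <- data.frame(chrom = "chr1", start = c(0, 10, 1e6 + 1))
  p <- count_reads(reads, g)
  expect_equal(p$bins$raw, c(2, 1, rep(0, 8)))

  empty <- count_reads(reads[0, ], g)
  expect_true(all(empty$bins$raw == 0))
  expect_equal(empty$genome_mean_depth, 0)
})

test_that("read counting conserves every input read exactly", {
  g <- tiny_genome()
  set.seed(41)
  reads <- tibble::tibble(
    chrom = sample(c("chr1", "chr2", "chrM", "chrUn"), 5000, replace = TRUE,
                   prob = c(0.6, 0.37, 0.025, 0.005)),
    start = sample.int(4e7, 5000) - 1
  )
  reads$start[reads$chrom == "chrM"] <-
    sample.int(16000, sum(reads$chrom == "chrM"))
  reads$start[1] <- 9e7  # out of bounds on chr1
  p <- count_reads(reads, g)
  expect_equal(sum(p$bins$raw) + p$mito_read_count + p$n_dropped, nrow(reads))

  mostly_unknown <- dplyr::mutate(reads, chrom = "chrZ")
  expect_error(count_reads(mostly_unknown, g),
               class = "embryoscreen_input_mismatch")
})

test_that("uniform simulated reads give Poisson-consistent counts per bin", {
  g <- tiny_genome(lengths = c(chr1 = 5e7, chr2 = 5e7))
  cfg <- read_sim_config(n_reads = 1e5, gc_bias_strength = 0,
                         overdispersion = 0, seed = 8)
  reads <- simulate_reads(g, karyotype_spec(), cfg)
  p <- count_reads(reads, g)
  expect_true(all(abs(p$bins$raw - 1e3) < 5 * sqrt(1e3)))
  expect_equal(sum(p$bins$raw) + p$mito_read_count, nrow(reads))
})

test_that("GC correction recovers a known multiplicative bias curve", {
  g <- make_synthetic_genome(
    synthetic_genome_spec(autosome_lengths = rep(25e7, 4),
                          include_sex_chromosomes = FALSE), seed = 2)
  w <- pmax(0.05, 1 - 8 * (g$bins$gc - 0.45)^2)
  # noise-free: correction must be flat to within 1%
  p <- profile_from_counts(g, 2500 * w)
  pc <- gc_correct(p, method = "loess")
  corr <- pc$bins$corrected
  expect_lt((max(corr) - min(corr)) / mean(corr), 0.01)
  # mass preservation
  expect_equal(sum(corr), sum(p$bins$raw), tolerance = 1e-3)
  # with sampling noise the residual GC correlation must vanish
  noisy <- profile_from_counts(g, withr::with_seed(3, rpois(nrow(g$bins),
                                                            2500 * w)))
  expect_lt(abs(stats::cor(gc_correct(noisy, method = "loess")$bins$corrected,
                           g$bins$gc)), 0.05)
})

test_that("GC correction leaves flat counts essentially untouched", {
  g <- tiny_genome(lengths = c(chr1 = 6e7, chr2 = 6e7))
  p <- profile_from_counts(g, rep(3000, nrow(g$bins)))
  pc <- gc_correct(p)
  expect_true(all(pc$bins$corrected / p$bins$raw > 0.99 &
                    pc$bins$corrected / p$bins$raw < 1.01))
})

test_that("degenerate and insufficient inputs are handled explicitly", {
  g <- tiny_genome(gc = rep(0.45, 90))
  p <- profile_from_counts(g, rep(1000, 90))
  expect_warning(pc <- gc_correct(p), "degenerate")
  expect_equal(pc$bins$corrected, p$bins$raw)

  sparse <- profile_from_counts(tiny_genome(), c(rep(1000, 40), rep(0, 50)))
  expect_error(gc_correct(sparse), class = "embryoscreen_insufficient_data")
})

test_that("post-correction residuals are GC-independent on a simulated euploid", {
  g <- make_synthetic_genome(
    synthetic_genome_spec(autosome_lengths = rep(25e7, 4),
                          include_sex_chromosomes = FALSE), seed = 2)
  p <- simulate_bin_counts(g, karyotype_spec(), read_sim_config(seed = 6))
  pc <- gc_correct(p, method = "loess")
  expect_lt(abs(stats::cor(pc$bins$corrected, g$bins$gc)), 0.05)
})

test_that("copy-number normalisation is exact, robust and scale-invariant", {
  g <- tiny_genome()
  p <- profile_from_counts(g, rep(1234, 90))
  p$bins$corrected <- p$bins$raw
  pn <- normalize_cn(p)
  expect_true(all(pn$bins$cn_ratio == 2))
  expect_equal(pn$sample_mad, 0)
  expect_equal(pn$sample_median, 2)

  # noise-free trisomy of a chromosome smaller than half the genome
  raw <- ifelse(tiny_genome()$bins$chrom == "chr2", 1500, 1000)
  p2 <- profile_from_counts(g, raw)
  p2$bins$corrected <- p2$bins$raw
  pn2 <- normalize_cn(p2)
  expect_true(all(pn2$bins$cn_ratio[g$bins$chrom == "chr2"] == 3))
  expect_true(all(pn2$bins$cn_ratio[g$bins$chrom == "chr1"] == 2))

  p3 <- p2
  p3$bins$corrected <- p3$bins$corrected * 17.3
  expect_equal(normalize_cn(p3)$bins$cn_ratio, pn2$bins$cn_ratio,
               tolerance = 1e-12)

  # autosomal median of cn_ratio is 2 by construction on noisy data too
  noisy <- simulate_bin_counts(tiny_genome(), karyotype_spec(),
                               read_sim_config(seed = 13))
  pn4 <- normalize_cn(gc_correct(noisy))
  expect_equal(stats::median(pn4$bins$cn_ratio[pn4$bins$is_autosome]), 2,
               tolerance = 1e-9)
  expect_equal(mean(pn4$bins$cn_ratio[pn4$bins$is_autosome]), 2,
               tolerance = 0.05)

  zero <- profile_from_counts(g, rep(0, 90))
  zero$bins$corrected <- zero$bins$raw
  expect_error(normalize_cn(zero), class = "embryoscreen_no_signal")
})

test_that("mtDNA depth ratio follows its defining arithmetic", {
  g <- tiny_genome()
  base <- tibble::tibble(chrom = rep(g$bins$chrom, 100),
                         start = rep(g$bins$start, 100))
  mito <- tibble::tibble(chrom = "chrM", start = seq(0, 16000, by = 40))
  p1 <- count_reads(dplyr::bind_rows(base, mito), g)
  p2 <- count_reads(dplyr::bind_rows(base, mito, mito), g)
  s1 <- mito_stats(p1); s2 <- mito_stats(p2)
  expect_equal(s1$ratio,
               p1$mito_mean_depth / p1$genome_mean_depth, tolerance = 1e-12)
  expect_equal(s2$ratio, 2 * s1$ratio, tolerance = 1e-12)
  expect_gt(s1$fraction_covered, 0.9)

  none <- count_reads(base[0, ], g)
  expect_error(mito_stats(none), class = "embryoscreen_no_signal")
})

test_that("simulated euploid mitochondrial ratio matches the configured target", {
  g <- tiny_genome()
  p <- simulate_bin_counts(g, karyotype_spec(),
                           read_sim_config(mito_mean_depth_ratio = 100,
                                           seed = 21))
  expect_gt(mito_stats(p)$ratio, 90)
  expect_lt(mito_stats(p)$ratio, 110)
})
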