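test_that("synthetic genomes honour the construction contract and are deterministic", {
  spec <- synthetic_genome_spec(autosome_lengths = c(5e7, 5e7),
                                include_sex_chromosomes = FALSE)
  g1 <- make_synthetic_genome(spec, seed = 7)
  g2 <- make_synthetic_genome(spec, seed = 7)
  expect_equal(nrow(g1$bins), 100)
  expect_true(all(g1$bins$gc >= 0.25 & g1$bins$gc <= 0.65))
  expect_identical(g1, g2)
  expect_false(identical(g1$bins$gc,
                         make_synthetic_genome(spec, seed = 8)$bins$gc))

  expect_error(
    make_synthetic_genome(
      synthetic_genome_spec(autosome_lengths = c(5e7, 5e6),
                            include_sex_chromosomes = FALSE), seed = 1),
    class = "embryoscreen_invalid_spec")
})

test_that("generated cytobands tile every chromosome without gaps or overlaps", {
  g <- tiny_genome(bands = 4)
  for (ch in g$chromosomes$chrom) {
    cb <- g$cytobands[g$cytobands$chrom == ch, ]
    cb <- cb[order(cb$start), ]
    expect_equal(nrow(cb), 4)
    expect_equal(cb$start[1], 0)
    expect_equal(cb$end[4], g$chromosomes$length[g$chromosomes$chrom == ch])
    expect_equal(cb$start[-1], cb$end[-4])
    expect_equal(cb$band, c("p2", "p1", "q1", "q2"))
  }
})

test_that("genome models round-trip through JSON", {
  g <- tiny_genome()
  path <- withr::local_tempfile(fileext = ".json")
  write_genome_json(g, path)
  g2 <- read_genome_json(path)
  expect_equal(g2$bins$gc, g$bins$gc, tolerance = 1e-12)
  expect_equal(g2$chromosomes$length, g$chromosomes$length)
  expect_equal(as.data.frame(g2$cytobands), as.data.frame(g$cytobands))
})

test_that("unbiased dispersion-free simulation approaches uniform sampling", {
  g <- tiny_genome(lengths = c(chr1 = 5e7, chr2 = 5e7))
  cfg <- read_sim_config(n_reads = 1e6, gc_bias_strength = 0,
                         overdispersion = 0, seed = 3)
  p <- simulate_bin_counts(g, karyotype_spec(), cfg)
  expect_true(all(abs(p$bins$raw - 1e4) < 5 * sqrt(1e4)))
})

test_that("a trisomy raises mean bin counts by a factor near 1.5", {
  g <- tiny_genome(lengths = c(chr1 = 5e7, chr2 = 4e7, chr3 = 5e7))
  kt <- karyotype_spec(data.frame(chrom = "chr2", start = 0, end = 4e7,
                                  copy_number = 3))
  p <- simulate_bin_counts(g, kt, read_sim_config(seed = 11))
  in_ev <- p$bins$chrom == "chr2"
  ratio <- mean(p$bins$raw[in_ev]) / mean(p$bins$raw[!in_ev])
  expect_gt(ratio, 1.40)
  expect_lt(ratio, 1.60)
})

test_that("expected bin counts are linear in simulated copy number", {
  g <- tiny_genome(lengths = c(5e7, 5e7, 5e7, 5e7, 5e7))
  kt <- karyotype_spec(data.frame(
    chrom = c("chr2", "chr3", "chr4"), start = 0, end = 5e7,
    copy_number = c(0L, 1L, 3L)))
  cfg <- read_sim_config(gc_bias_strength = 0, overdispersion = 0,
                         n_reads = 1e6, seed = 5)
  mu <- embryoscreen:::expected_bin_counts(g, kt, cfg, 1e6)
  cn <- embryoscreen:::expected_bin_cn(g, kt)
  fit <- stats::lm(mu ~ cn)
  expect_equal(unname(stats::coef(fit)[["cn"]]) /
                 (mu[cn == 2][1] / 2), 1, tolerance = 1e-9)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-12)
})

test_that("GC bias is injected when on and absent when off", {
  g <- make_synthetic_genome(
    synthetic_genome_spec(autosome_lengths = rep(25e7, 4),
                          include_sex_chromosomes = FALSE),
    seed = 2)  # 1000 bins
  kt <- karyotype_spec()
  biased <- simulate_bin_counts(g, kt, read_sim_config(seed = 4))
  flat <- simulate_bin_counts(g, kt,
                              read_sim_config(gc_bias_strength = 0, seed = 4))
  # the bias curve is quadratic around its peak, so the association is
  # tested against the curve's own driver, not raw GC
  driver <- (g$bins$gc - 0.45)^2
  expect_lt(stats::cor.test(biased$bins$raw, driver)$p.value, 1e-6)
  expect_lt(abs(stats::cor(flat$bins$raw, g$bins$gc)), 0.05)
  expect_gt(stats::cor.test(flat$bins$raw, driver)$p.value, 0.01)
})

test_that("mitochondrial depth ratio is linear in the copy factor", {
  g <- tiny_genome()
  cfg <- read_sim_config(seed = 9)
  r1 <- mito_stats(simulate_bin_counts(g, karyotype_spec(mito_copy_factor = 1),
                                       cfg))$ratio
  r2 <- mito_stats(simulate_bin_counts(g, karyotype_spec(mito_copy_factor = 2),
                                       cfg))$ratio
  expect_equal(r2 / r1, 2, tolerance = 0.1)
  expect_equal(r1, 100, tolerance = 0.1)  # euploid baseline at the default
})

test_that("karyotype validation rejects malformed event sets", {
  expect_error(karyotype_spec(data.frame(chrom = "chr1", start = 0, end = 1e7,
                                         copy_number = 2)),
               class = "embryoscreen_invalid_karyotype")
  expect_error(
    karyotype_spec(data.frame(chrom = "chr1", start = c(0, 5e6),
                              end = c(1e7, 1.5e7), copy_number = c(1L, 3L))),
    class = "embryoscreen_invalid_karyotype")
  g <- tiny_genome()
  out_of_bounds <- karyotype_spec(data.frame(chrom = "chr2", start = 0,
                                             end = 9e7, copy_number = 3))
  expect_error(simulate_bin_counts(g, out_of_bounds, read_sim_config()),
               class = "embryoscreen_invalid_karyotype")
})

test_that("cohort simulation draws the requested class mix with valid truth", {
  g <- sexed_genome()
  all_euploid <- simulate_cohort(5, c(1, 0, 0, 0), genome = g, seed = 1)
  expect_equal(all_euploid$truth$class, rep("euploid", 5))
  expect_true(all(vapply(all_euploid$truth$events, nrow, integer(1)) == 0))

  coh <- simulate_cohort(400, c(0.5, 0.5, 0, 0), genome = g, seed = 2)
  frac <- mean(coh$truth$class == "euploid")
  expect_lt(abs(frac - 0.5), 2.576 * sqrt(0.25 / 400))

  both <- simulate_cohort(30, c(0, 0, 0, 1), genome = g, seed = 3)
  for (ev in both$truth$events) {
    lens <- setNames(g$chromosomes$length, g$chromosomes$chrom)
    whole <- ev$start == 0 & ev$end == lens[ev$chrom]
    expect_true(any(whole) && any(!whole))
  }

  empty <- simulate_cohort(0, genome = g, seed = 4)
  expect_equal(nrow(empty$truth), 0)

  again <- simulate_cohort(5, c(1, 0, 0, 0), genome = g, seed = 1)
  expect_identical(all_euploid$truth, again$truth)
  expect_identical(all_euploid$samples[[1]]$bins$raw,
                   again$samples[[1]]$bins$raw)
})
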