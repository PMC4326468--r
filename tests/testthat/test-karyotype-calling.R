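segments_for <- function(genome, chrom, bounds_bp, means) {
  bins <- genome$bins[genome$bins$chrom == chrom, ]
  edges <- c(0, bounds_bp, max(bins$end))
  purrr::map_dfr(seq_along(means), function(k) {
    sel <- bins$start >= edges[k] & bins$start < edges[k + 1]
    tibble::tibble(chrom = chrom,
                   start_bin = min(bins$bin[sel]), end_bin = max(bins$bin[sel]) + 1,
                   start_bp = min(bins$start[sel]), end_bp = max(bins$end[sel]),
                   mean_cn = means[k], n_bins = sum(sel))
  })
}

thr <- tibble::tibble(gain_cut = 2.4, loss_cut = 1.6)

test_that("segments become calls only beyond the dynamic thresholds", {
  g <- tiny_genome()
  whole <- segments_for(g, "chr1", numeric(), 3.02)
  calls <- call_cnvs(whole, thr, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$copy_number, 3)
  expect_equal(calls$scope, "whole-chromosome")
  expect_equal(calls$start_bp, 0)
  expect_equal(calls$end_bp, 5e7)

  below <- segments_for(g, "chr1", numeric(), 2.2)
  expect_equal(nrow(call_cnvs(below, thr, g)), 0)

  # a rounded diploid inside an extreme threshold is discarded
  wide <- tibble::tibble(gain_cut = 2.3, loss_cut = 1.7)
  borderline <- segments_for(g, "chr1", numeric(), 2.35)
  expect_equal(nrow(call_cnvs(borderline, wide, g)), 0)
})

test_that("adjacent same-direction candidate segments merge into one call", {
  g <- tiny_genome()
  seg <- segments_for(g, "chr1", c(2e7, 3e7), c(2.9, 3.15, 2.0))
  calls <- call_cnvs(seg, thr, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start_bp, 0)
  expect_equal(calls$end_bp, 3e7)
  expect_equal(calls$mean_cn, (2.9 * 20 + 3.15 * 10) / 30)

  opposite <- segments_for(g, "chr1", c(2e7, 3e7), c(2.9, 1.2, 2.0))
  expect_equal(nrow(call_cnvs(opposite, thr, g)), 2)
})

test_that("sex-aware dosage turns a Y gain into a x2 call in a male embryo", {
  g <- sexed_genome()
  seg <- dplyr::bind_rows(
    segments_for(g, "chrY", numeric(), 1.97),
    segments_for(g, "chrX", numeric(), 1.02)
  )
  calls <- call_cnvs(seg, thr, g, sex = "XY")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "chrY")
  expect_equal(calls$copy_number, 2)

  # undetermined sex: sex chromosomes are not called at all
  expect_equal(nrow(call_cnvs(seg, thr, g, sex = "undetermined")), 0)
})

test_that("sub-minimum-length calls are dropped", {
  g <- tiny_genome(bin_size = 5e5)
  seg <- segments_for(g, "chr1", c(2e7, 2.05e7), c(2.0, 3.1, 2.0))
  expect_equal(nrow(call_cnvs(seg, thr, g, min_cnv_length = 1e6)), 0)
  expect_equal(nrow(call_cnvs(seg, thr, g, min_cnv_length = 5e5)), 1)
})

test_that("sex inference uses X and Y dosage with midpoint cutpoints", {
  g <- sexed_genome()
  p <- profile_from_counts(g, rep(1000, nrow(g$bins)))
  set_sex_cn <- function(p, x, y) {
    p$bins$cn_ratio <- 2
    p$bins$cn_ratio[embryoscreen:::is_x_chrom(p$bins$chrom)] <- x
    p$bins$cn_ratio[embryoscreen:::is_y_chrom(p$bins$chrom)] <- y
    p
  }
  expect_equal(infer_sex(set_sex_cn(p, 1.98, 0.02)), "XX")
  expect_equal(infer_sex(set_sex_cn(p, 1.05, 0.97)), "XY")
  expect_equal(infer_sex(set_sex_cn(p, 1.5, 0.2)), "undetermined")
  expect_equal(infer_sex(set_sex_cn(p, 1.9, 0.5)), "undetermined")

  no_sex <- profile_from_counts(tiny_genome(), rep(1000, 90))
  expect_equal(infer_sex(no_sex), "undetermined")
})

test_that("the four-way classification follows call scopes, order-invariantly", {
  expect_equal(classify_calls(NULL), "euploid")
  expect_equal(classify_calls(tibble::tibble(scope = character())), "euploid")
  expect_equal(classify_calls(tibble::tibble(scope = "whole-chromosome")),
               "numerical")
  expect_equal(classify_calls(tibble::tibble(scope = "segmental")),
               "imbalanced")
  # event mix of a published male embryo: whole Y gain + segmental 8p loss
  # and 18q gain
  mixed <- tibble::tibble(
    scope = c("whole-chromosome", "segmental", "segmental"))
  expect_equal(classify_calls(mixed), "numerical+imbalanced")
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(classify_calls(mixed[perm, ]), "numerical+imbalanced")
  }
})

test_that("published call strings reproduce character-for-character", {
  g <- hg18_fixture_genome()
  call_chr2 <- tibble::tibble(chrom = "chr2", start_bp = 182458385,
                              end_bp = 242690112, copy_number = 1)
  expect_identical(format_call(call_chr2, g),
                   "seq 2q31.3 → qter(182458386–242690112)×1")
  call_chr1 <- tibble::tibble(chrom = "chr1", start_bp = 181509439,
                              end_bp = 246832193, copy_number = 3)
  expect_identical(format_call(call_chr1, g),
                   "seq 1q25.3 → qter(181509440–246832193)×3")
})

test_that("terminal-band and interior-band rendering rules hold", {
  g <- tiny_genome(bands = 4)
  whole <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 5e7,
                          copy_number = 3)
  expect_identical(format_call(whole, g),
                   "seq 1pter → qter(1–50000000)×3")
  inner <- tibble::tibble(chrom = "chr1", start_bp = 11e6, end_bp = 15e6,
                          copy_number = 1)
  s <- format_call(inner, g)
  parsed <- parse_call(s)
  expect_equal(parsed$band_start, parsed$band_end)
})

test_that("formatted calls round-trip through the parser exactly", {
  g <- hg18_fixture_genome()
  cases <- tibble::tibble(
    chrom = c("chr2", "chr1", "chr2"),
    start_bp = c(182458385, 0, 34106490),
    end_bp = c(242690112, 246832193, 91800000),
    copy_number = c(1, 3, 4)
  )
  for (i in seq_len(nrow(cases))) {
    s <- format_call(cases[i, ], g)
    p <- parse_call(s)
    expect_equal(paste0("chr", p$chrom), cases$chrom[i])
    expect_equal(p$start_bp, cases$start_bp[i])
    expect_equal(p$end_bp, cases$end_bp[i])
    expect_equal(p$copy_number, cases$copy_number[i])
  }
  expect_error(parse_call("arr 2q31 (1-2)x3"),
               class = "embryoscreen_parse_error")
})

test_that("calls outside cytoband coverage raise an annotation error", {
  g <- tiny_genome()
  g$cytobands <- g$cytobands[g$cytobands$chrom != "chr2", ]
  seg <- segments_for(g, "chr2", numeric(), 3.1)
  expect_error(call_cnvs(seg, thr, g),
               class = "embryoscreen_annotation_error")
})
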