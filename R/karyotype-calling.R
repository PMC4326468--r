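#' Convert filtered segments into CNV calls
#'
#' Segments whose mean copy-number ratio deviates from the chromosome's
#' expected dose by at least the dynamic threshold become calls. For
#' autosomes the expected dose is 2; for sex chromosomes it follows the
#' supplied `sex` (XX: X = 2, Y = 0; XY: X = Y = 1), so a Y-chromosome gain
#' in a male embryo is called at x2. Adjacent same-direction candidate
#' segments with no gap merge before rounding; the integer copy number is
#' `round(mean_cn)` clamped to 0..4, and a segment whose rounded copy number
#' equals the expected dose is discarded. Calls shorter than `min_cnv_length`
#' are dropped (shallow coverage cannot resolve sub-megabase events), and a
#' call covering at least `whole_chrom_fraction` of its chromosome is
#' flagged whole-chromosome. When `sex` is `"undetermined"`, sex chromosomes
#' are not called.
#'
#' @param segments Segment tibble from [segment_profile()].
#' @param thresholds One-row tibble `gain_cut, loss_cut` from
#'   [dynamic_thresholds()].
#' @param genome A `genome_model` (must carry cytobands for nomenclature).
#' @param sex `"XX"`, `"XY"` or `"undetermined"` (see [infer_sex()]).
#' @param min_cnv_length Minimum call length in bp (default 1e6).
#' @param whole_chrom_fraction Chromosome fraction above which a call is
#'   whole-chromosome (default 0.9).
#' @return Tibble of calls: `chrom, start_bp, end_bp, length_bp, mean_cn,
#'   copy_number, scope, band_start, band_end, label`.
#' @export
call_cnvs <- function(segments, thresholds, genome, sex = "undetermined",
                      min_cnv_length = 1e6, whole_chrom_fraction = 0.9) {
  stopifnot(inherits(genome, "genome_model"))
  gain_dev <- thresholds$gain_cut[1] - 2
  loss_dev <- 2 - thresholds$loss_cut[1]

  seg <- as_tibble(segments)
  seg$expected <- chrom_expected_cn(seg$chrom, sex)
  seg <- seg[!is.na(seg$expected), ]
  seg$direction <- dplyr::case_when(
    seg$mean_cn - seg$expected >= gain_dev ~ "gain",
    seg$mean_cn - seg$expected <= -loss_dev ~ "loss",
    TRUE ~ "none"
  )

  cand <- seg[seg$direction != "none", ]
  if (nrow(cand) == 0L) return(empty_calls())

  # merge adjacent same-direction candidates with no intervening bin
  cand <- cand[order(cand$chrom, cand$start_bin), ]
  new_run <- c(TRUE, !(cand$chrom[-1] == cand$chrom[-nrow(cand)] &
                         cand$direction[-1] == cand$direction[-nrow(cand)] &
                         cand$start_bin[-1] == cand$end_bin[-nrow(cand)]))
  cand$run <- cumsum(new_run)
  calls <- cand |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
      mean_cn = sum(.data$mean_cn * .data$n_bins) / sum(.data$n_bins),
      expected = .data$expected[1], .groups = "drop"
    ) |>
    dplyr::select(-"run")

  calls$length_bp <- calls$end_bp - calls$start_bp
  calls$copy_number <- pmin(pmax(round(calls$mean_cn), 0), 4)
  calls <- calls[calls$copy_number != calls$expected &
                   calls$length_bp >= min_cnv_length, ]
  if (nrow(calls) == 0L) return(empty_calls())

  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  calls$scope <- ifelse(
    calls$length_bp >= whole_chrom_fraction * unname(chrom_len[calls$chrom]),
    "whole-chromosome", "segmental")
  calls$band_start <- band_at(genome, calls$chrom, calls$start_bp)
  calls$band_end <- band_at(genome, calls$chrom, calls$end_bp - 1)
  calls <- dplyr::select(calls, "chrom", "start_bp", "end_bp", "length_bp",
                         "mean_cn", "copy_number", "scope", "band_start",
                         "band_end")
  calls$label <- vapply(seq_len(nrow(calls)),
                        function(i) format_call(calls[i, ], genome),
                        character(1))
  calls
}

empty_calls <- function() {
  tibble(chrom = character(), start_bp = numeric(), end_bp = numeric(),
         length_bp = numeric(), mean_cn = numeric(), copy_number = integer(),
         scope = character(), band_start = character(),
         band_end = character(), label = character())
}

# Expected integer dose per chromosome given sex; NA = do not call.
chrom_expected_cn <- function(chrom, sex) {
  dplyr::case_when(
    !is_sex_chrom(chrom) ~ 2,
    sex == "XX" & is_x_chrom(chrom) ~ 2,
    sex == "XX" & is_y_chrom(chrom) ~ 0,
    sex == "XY" ~ 1,
    TRUE ~ NA_real_
  )
}

band_at <- function(genome, chrom, pos) {
  cb <- genome$cytobands
  if (is.null(cb)) {
    abort("genome model has no cytobands; cannot annotate calls",
          class = "embryoscreen_annotation_error")
  }
  vapply(seq_along(chrom), function(i) {
    hit <- cb$chrom == chrom[i] & cb$start <= pos[i] & cb$end > pos[i]
    if (!any(hit)) {
      abort(sprintf("position %s:%d outside cytoband coverage",
                    chrom[i], as.integer(pos[i])),
            class = "embryoscreen_annotation_error")
    }
    cb$band[which(hit)[1]]
  }, character(1))
}

#' Infer embryo sex from sex-chromosome dosage
#'
#' Classifies by the median copy-number ratio of X and Y bins: XX when X is
#' near 2 and Y near 0, XY when both are near 1, with cutpoints at the
#' midpoints 1.5 (X) and 0.5 (Y); medians exactly on a cutpoint, or a genome
#' without sex chromosomes, give `"undetermined"`.
#'
#' @param profile A cn-stage [bin_profile].
#' @return `"XX"`, `"XY"` or `"undetermined"`.
#' @export
infer_sex <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  bins <- profile$bins
  x <- bins$cn_ratio[is_x_chrom(bins$chrom)]
  y <- bins$cn_ratio[is_y_chrom(bins$chrom)]
  if (length(x) == 0L || length(y) == 0L || anyNA(c(x, y))) {
    return("undetermined")
  }
  xm <- median(x); ym <- median(y)
  if (xm > 1.5 && ym < 0.5) return("XX")
  if (xm < 1.5 && ym > 0.5) return("XY")
  "undetermined"
}

#' Classify an embryo from its CNV calls
#'
#' Four-way scheme used in cohort reporting: no calls is euploid; only
#' whole-chromosome calls is a numerical aberration; only segmental calls is
#' an imbalanced (structural) aberration; both kinds together are
#' numerical+imbalanced. Invariant to the order of calls.
#'
#' @param calls Call tibble from [call_cnvs()] (needs a `scope` column).
#' @return One of `"euploid"`, `"numerical"`, `"imbalanced"`,
#'   `"numerical+imbalanced"`.
#' @export
classify_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) return("euploid")
  whole <- any(calls$scope == "whole-chromosome")
  segm <- any(calls$scope == "segmental")
  if (whole && segm) "numerical+imbalanced"
  else if (whole) "numerical"
  else "imbalanced"
}

#' Render a CNV call in "seq" nomenclature
#'
#' Formats one call as
#' `seq {chrom}{band_start} → {band_end}({start}–{end})×{copies}`,
#' e.g. `seq 2q31.3 → qter(182458386–242690112)×1`. Coordinates
#' print 1-based inclusive (internally 0-based half-open); the chromosome's
#' first band renders as `pter` when the call starts within the first bin,
#' and the terminal band renders as `qter`. The separator is an en dash.
#'
#' @param call One-row data frame with `chrom, start_bp, end_bp, copy_number,
#'   band_start, band_end`.
#' @param genome A `genome_model` with cytobands.
#' @return A string.
#' @export
format_call <- function(call, genome) {
  cb <- genome$cytobands[genome$cytobands$chrom == call$chrom, ]
  cb <- cb[order(cb$start), ]
  first_band <- cb$band[1]
  last_band <- cb$band[nrow(cb)]
  band_start <- call[["band_start"]] %||%
    band_at(genome, call$chrom, call$start_bp)
  band_end <- call[["band_end"]] %||%
    band_at(genome, call$chrom, call$end_bp - 1)
  if (band_start == first_band && call$start_bp < genome$bin_size) {
    band_start <- "pter"
  }
  if (band_end == last_band) band_end <- "qter"
  sprintf("seq %s%s → %s(%d–%d)×%d",
          strip_chr(call$chrom), band_start, band_end,
          as.integer(call$start_bp + 1), as.integer(call$end_bp),
          as.integer(call$copy_number))
}

#' Parse a "seq" call string
#'
#' Inverse of [format_call()] for the fields it can recover exactly:
#' chromosome (band prefix), 0-based half-open coordinates and copy number.
#'
#' @param label A string produced by [format_call()].
#' @return One-row tibble `chrom, band_start, band_end, start_bp, end_bp,
#'   copy_number` (chrom without `chr` prefix).
#' @export
parse_call <- function(label) {
  m <- stringr::str_match(
    label,
    "^seq ([0-9XY]+?)(pter|[pq][0-9.]+) → (qter|pter|[pq][0-9.]+)\\((\\d+)–(\\d+)\\)×(\\d)$")
  if (anyNA(m)) {
    abort("not a well-formed seq call string",
          class = "embryoscreen_parse_error")
  }
  tibble(chrom = m[, 2], band_start = m[, 3], band_end = m[, 4],
         start_bp = as.numeric(m[, 5]) - 1, end_bp = as.numeric(m[, 6]),
         copy_number = as.integer(m[, 7]))
}
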