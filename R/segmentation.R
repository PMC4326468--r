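#' Segmentation and dynamic-threshold parameters
#'
#' Free parameters of breakpoint detection and of the per-sample dynamic
#' calling thresholds.
#'
#' @param min_seg_bins Minimum bins per segment (default 3).
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_permutations Permutation draws for the split null (default 1000);
#'   0 switches to deterministic acceptance (any nonzero split statistic),
#'   appropriate only for noise-free input.
#' @param max_depth Recursion cap (default 20).
#' @param threshold_k Multiplier on the sample MAD in the dynamic threshold
#'   (default 3: a three-sigma rule on the mean of a minimal segment).
#' @param threshold_floor Minimal copy-number deviation ever called (default
#'   0.4), so sub-mosaic wobble on a quiet sample is not called.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(min_seg_bins = 3, alpha = 0.01, n_permutations = 1000,
                       max_depth = 20, threshold_k = 3, threshold_floor = 0.4) {
  stopifnot(is_count(min_seg_bins), min_seg_bins >= 2,
            alpha > 0, alpha < 1, is_count(n_permutations),
            is_count(max_depth), threshold_k >= 0, threshold_floor >= 0)
  structure(list(min_seg_bins = min_seg_bins, alpha = alpha,
                 n_permutations = n_permutations, max_depth = max_depth,
                 threshold_k = threshold_k, threshold_floor = threshold_floor),
            class = "seg_params")
}

#' Best single split of a copy-number series
#'
#' The binary-segmentation kernel: over candidate split points `i`
#' (`min_seg_bins <= i <= n - min_seg_bins`, counting left-side bins), finds
#' the `i` maximising the absolute two-sample t-like statistic
#' \deqn{T(i) = \frac{\bar x_{1..i} - \bar x_{i+1..n}}{s\sqrt{1/i + 1/(n-i)}}}
#' with `s` the pooled standard deviation. Ties break to the smallest `i`; a
#' constant series returns statistic 0 at `i = min_seg_bins`; a split with
#' zero pooled variance but unequal means returns `Inf` (signed).
#'
#' @param values Numeric per-bin copy-number series, length >= 2 *
#'   `min_seg_bins`.
#' @param min_seg_bins Minimum bins on each side of the split.
#' @return List with `index` (left-side bin count) and `statistic` (signed
#'   `T` at the chosen split).
#' @export
#' @examples
#' best_split(c(2, 2, 2, 2, 3, 3, 3, 3), min_seg_bins = 2)
best_split <- function(values, min_seg_bins = 3) {
  n <- length(values)
  stopifnot(n >= 2 * min_seg_bins)
  i <- seq.int(min_seg_bins, n - min_seg_bins)
  cs <- cumsum(values)
  cs2 <- cumsum(values^2)
  nl <- i
  nr <- n - i
  mean_l <- cs[i] / nl
  mean_r <- (cs[n] - cs[i]) / nr
  ss_l <- cs2[i] - nl * mean_l^2
  ss_r <- (cs2[n] - cs2[i]) - nr * mean_r^2
  s <- sqrt(pmax(0, ss_l + ss_r) / (n - 2))
  diff <- mean_l - mean_r
  t_stat <- diff / (s * sqrt(1 / nl + 1 / nr))
  t_stat[s == 0 & abs(diff) > 1e-12] <- sign(diff[s == 0 & abs(diff) > 1e-12]) * Inf
  t_stat[s == 0 & abs(diff) <= 1e-12] <- 0
  best <- which.max(abs(t_stat))  # first max: ties break to smallest i
  if (abs(t_stat[best]) == 0) return(list(index = min_seg_bins, statistic = 0))
  list(index = i[best], statistic = t_stat[best])
}

# Two-boundary scan statistic over a segment: the maximal |T| comparing the
# interior run values[(i+1)..j] against the rest of the segment, over all
# (i, j) with each resulting piece at least min_seg_bins long (i = 0 or
# j = n reduce to the single-split kernel of best_split()). A single split
# cannot expose a short event in the middle of a segment - its up-step and
# down-step cancel in any one mean contrast - so the recursion tests this
# statistic instead, as circular binary segmentation does.
cbs_scan <- function(values, min_seg_bins) {
  n <- length(values)
  s1 <- c(0, cumsum(values))
  s2 <- c(0, cumsum(values^2))
  i <- 0:(n - min_seg_bins)            # left boundary (0 = segment start)
  j <- min_seg_bins:n                  # right boundary (n = segment end)
  n_in <- outer(i, j, function(a, b) b - a)
  ok <- n_in >= min_seg_bins & (n - n_in) >= min_seg_bins &
    outer(i, j, function(a, b) (a == 0 | a >= min_seg_bins) &
                               (b == n | b <= n - min_seg_bins))
  if (!any(ok)) return(list(i = 0L, j = n, statistic = 0))
  n_in_s <- pmax(n_in, 1)                       # invalid pairs masked below
  n_out <- pmax(n - n_in, 1)
  sum_in <- outer(i, j, function(a, b) s1[b + 1] - s1[a + 1])
  ss_in <- outer(i, j, function(a, b) s2[b + 1] - s2[a + 1]) -
    sum_in^2 / n_in_s
  sum_out <- s1[n + 1] - sum_in
  ss_out <- (s2[n + 1] - outer(i, j, function(a, b) s2[b + 1] - s2[a + 1])) -
    sum_out^2 / n_out
  s <- sqrt(pmax(0, ss_in + ss_out) / (n - 2))
  diff <- sum_in / n_in_s - sum_out / n_out
  t_stat <- diff / (s * sqrt(1 / n_in_s + 1 / n_out))
  zero_s <- s == 0
  t_stat[zero_s & abs(diff) > 1e-12] <- Inf
  t_stat[zero_s & abs(diff) <= 1e-12] <- 0
  t_stat[!ok] <- 0
  t_stat <- abs(t_stat)
  best <- arrayInd(which.max(t_stat), dim(t_stat))
  list(i = i[best[1]], j = j[best[2]], statistic = max(t_stat))
}

# Permutation acceptance with early termination: the candidate is accepted
# when fewer than alpha * n_permutations shuffled segments reach the observed
# scan statistic (the counting form of exceeding the (1 - alpha) null
# quantile); counting stops as soon as acceptance is impossible.
split_accepted <- function(values, stat, params) {
  if (abs(stat) == 0) return(FALSE)
  if (params$n_permutations == 0) return(TRUE)
  limit <- params$alpha * params$n_permutations
  exceed <- 0
  for (b in seq_len(params$n_permutations)) {
    if (cbs_scan(sample(values), params$min_seg_bins)$statistic >= stat) {
      exceed <- exceed + 1
      if (exceed >= limit) return(FALSE)
    }
  }
  TRUE
}

#' Segment one chromosome by recursive binary segmentation
#'
#' Recursively splits the series at the strongest mean shift. The split
#' kernel is a two-boundary scan (the circular form of the [best_split()]
#' contrast): the maximal t-like statistic comparing an interior run against
#' the remainder of the segment, which a plain single split cannot expose
#' when a short event sits mid-segment. A candidate split is kept only if
#' its statistic beats the `(1 - alpha)` quantile of a within-segment
#' permutation null (shuffles of the segment's own values); recursion stops
#' on rejection, on segments too short to split, or at `max_depth`. The
#' returned segments tile the series exactly.
#'
#' @param values Numeric per-bin copy-number series.
#' @param params A [seg_params()].
#' @param seed Integer seed for the permutation null.
#' @return Tibble `start_bin, end_bin, mean_cn, n_bins` with 0-based
#'   half-open bin ranges.
#' @export
segment_chromosome <- function(values, params = seg_params(), seed = 1) {
  stopifnot(length(values) >= 1)
  withr::with_seed(derive_seed(seed, "segmentation", length(values)), {
    bounds <- segment_recurse(values, params, depth = 0L)
  })
  starts <- c(0L, bounds)
  ends <- c(bounds, length(values))
  tibble(
    start_bin = starts, end_bin = ends,
    mean_cn = vapply(seq_along(starts),
                     function(k) mean(values[(starts[k] + 1):ends[k]]),
                     numeric(1)),
    n_bins = ends - starts
  )
}

# Returns interior breakpoints (0-based bin offsets) of `values`.
segment_recurse <- function(values, params, depth) {
  n <- length(values)
  if (n < 2 * params$min_seg_bins || depth >= params$max_depth) return(integer())
  sp <- cbs_scan(values, params$min_seg_bins)
  if (!split_accepted(values, sp$statistic, params)) return(integer())
  cuts <- sort(unique(setdiff(c(sp$i, sp$j), c(0L, n))))
  pieces <- Map(function(a, b) values[(a + 1):b],
                c(0L, cuts), c(cuts, n))
  offsets <- c(0L, cuts)
  out <- integer()
  for (k in seq_along(pieces)) {
    out <- c(out, offsets[k] + segment_recurse(pieces[[k]], params, depth + 1L))
  }
  sort(unique(c(out, cuts)))
}

#' Segment a whole copy-number profile
#'
#' Runs [segment_chromosome()] independently on each chromosome of a
#' normalised [bin_profile] (breakpoints cannot span chromosomes) and maps
#' bin ranges back to base-pair coordinates.
#'
#' @param profile A cn-stage [bin_profile].
#' @param params A [seg_params()].
#' @param seed Integer seed for the permutation nulls.
#' @return Tibble `chrom, start_bin, end_bin, start_bp, end_bp, mean_cn,
#'   n_bins`; segments tile every chromosome.
#' @export
segment_profile <- function(profile, params = seg_params(), seed = 1) {
  stopifnot(inherits(profile, "bin_profile"))
  if (all(is.na(profile$bins$cn_ratio))) {
    abort("run normalize_cn() before segment_profile()",
          class = "embryoscreen_stage_error")
  }
  chroms <- profile$genome$chromosomes$chrom
  purrr::imap_dfr(setNames(chroms, chroms), function(ch, nm) {
    b <- profile$bins[profile$bins$chrom == ch, ]
    seg <- segment_chromosome(b$cn_ratio, params,
                              seed = derive_seed(seed, ch))
    seg <- dplyr::mutate(seg, chrom = ch,
                         start_bp = b$start[.data$start_bin + 1],
                         end_bp = b$end[.data$end_bin])
    dplyr::select(seg, "chrom", "start_bin", "end_bin", "start_bp", "end_bp",
                  "mean_cn", "n_bins")
  })
}

#' Per-sample dynamic calling thresholds
#'
#' The calling cutoffs adapt to each sample's WGA noise: a segment is a
#' candidate gain if its mean exceeds `gain_cut` and a candidate loss below
#' `loss_cut`, where
#' `gain/loss_cut = 2 +/- max(threshold_floor, threshold_k * MAD / sqrt(min_seg_bins))`.
#' The MAD term is a `threshold_k`-sigma bound on the mean of a
#' minimal-length segment; the floor stops a very quiet sample from calling
#' biologically meaningless deviations.
#'
#' @param profile A cn-stage [bin_profile] (needs `sample_mad`).
#' @param params A [seg_params()].
#' @return One-row tibble `gain_cut, loss_cut`.
#' @export
#' @examples
#' # MAD 0.3, k = 3, min_seg_bins = 3: deviation 3 * 0.3 / sqrt(3) = 0.5196
dynamic_thresholds <- function(profile, params = seg_params()) {
  stopifnot(inherits(profile, "bin_profile"))
  if (is.na(profile$sample_mad)) {
    abort("run normalize_cn() before dynamic_thresholds()",
          class = "embryoscreen_stage_error")
  }
  dev <- max(params$threshold_floor,
             params$threshold_k * profile$sample_mad / sqrt(params$min_seg_bins))
  tibble(gain_cut = 2 + dev, loss_cut = 2 - dev)
}
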