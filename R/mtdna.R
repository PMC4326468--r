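#' Mann-Whitney U test of two ratio samples
#'
#' Two-sided rank-sum comparison used for relative mtDNA copy-number groups.
#' With both groups of size at most 8 and no ties the exact null distribution
#' is used; otherwise the normal approximation with tie correction and
#' continuity correction. `U` is reported for the first group, so
#' `U_a + U_b = n1 * n2`.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return One-row tibble `statistic` (U for `a`), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))  # exact two-sided p = 0.1
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be nonempty", class = "embryoscreen_insufficient_data")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
         method = if (exact) "exact" else "normal approximation")
}

#' Compare mtDNA copy-number ratios between euploid and abnormal embryos
#'
#' Partitions a cohort of embryo results into euploid versus chromosomally
#' abnormal (numerical, imbalanced or numerical+imbalanced), compares their
#' `ChrM_depth/Mean_depth` ratios with [mann_whitney()], and records which
#' group has the greater median.
#'
#' @param results Data frame with columns `classification` and `mito_ratio`,
#'   e.g. row-bound [glance()] outputs of [call_karyotype()].
#' @return One-row tibble `n_euploid, n_abnormal, median_euploid,
#'   median_abnormal, statistic, p_value, direction`.
#' @export
compare_mtdna <- function(results) {
  results <- as_tibble(results)
  stopifnot(all(c("classification", "mito_ratio") %in% names(results)))
  eu <- results$mito_ratio[results$classification == "euploid"]
  ab <- results$mito_ratio[results$classification != "euploid"]
  if (length(eu) == 0L || length(ab) == 0L) {
    abort("need at least one euploid and one abnormal embryo",
          class = "embryoscreen_insufficient_data")
  }
  mw <- mann_whitney(eu, ab)
  med_eu <- median(eu); med_ab <- median(ab)
  tibble(n_euploid = length(eu), n_abnormal = length(ab),
         median_euploid = med_eu, median_abnormal = med_ab,
         statistic = mw$statistic, p_value = mw$p_value,
         direction = if (med_ab > med_eu) "abnormal greater"
                     else if (med_eu > med_ab) "euploid greater" else "tie")
}
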