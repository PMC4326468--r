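#' Pearson chi-squared test on a 2x2 table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' row/column margins and the chi-squared distribution on 1 degree of
#' freedom. No Yates continuity correction is applied — the convention used
#' throughout the clinical outcome comparisons in this package.
#'
#' @param a,b Successes and failures in group 1.
#' @param c,d Successes and failures in group 2.
#' @return One-row tibble `chi2, p_value`.
#' @export
#' @examples
#' pearson_chi2_2x2(49, 31, 115, 88)  # p = 0.480
pearson_chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero margin: chi-squared test undefined",
          class = "embryoscreen_undefined_test")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), p_value = ct$p.value)
}

#' Build clinical outcome comparison tables
#'
#' Computes the four standard embryo-transfer outcome measures for two
#' screening groups and compares each with [pearson_chi2_2x2()]. Denominator
#' conventions: clinical and ongoing pregnancy per transfer cycle;
#' miscarriage per clinical pregnancy; implantation per embryo transferred.
#' An outcome with zero events in both groups is flagged untestable
#' (`testable = FALSE`, `chi2`/`p_value` `NA`) rather than erroring.
#'
#' @param counts Data frame with exactly two rows (one per group) and columns
#'   `group, transfer_cycles, clinical_pregnancies, ongoing_pregnancies,
#'   miscarriages, embryos_transferred, implantations`.
#' @return Tibble with one row per outcome: numerators/denominators per
#'   group, rates in percent, pooled rate, `chi2`, `p_value`, `testable`.
#' @export
#' @examples
#' build_outcome_tables(pgs_reference_outcomes())
build_outcome_tables <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("group", "transfer_cycles", "clinical_pregnancies",
            "ongoing_pregnancies", "miscarriages", "embryos_transferred",
            "implantations")
  stopifnot(all(need %in% names(counts)), nrow(counts) == 2)
  defs <- tibble(
    outcome = c("clinical_pregnancy", "ongoing_pregnancy", "miscarriage",
                "implantation"),
    num = c("clinical_pregnancies", "ongoing_pregnancies", "miscarriages",
            "implantations"),
    den = c("transfer_cycles", "transfer_cycles", "clinical_pregnancies",
            "embryos_transferred")
  )
  purrr::pmap_dfr(defs, function(outcome, num, den) {
    k <- counts[[num]]
    n <- counts[[den]]
    if (any(k > n)) {
      abort(sprintf("%s: numerator exceeds denominator", outcome),
            class = "embryoscreen_inconsistent_counts")
    }
    testable <- sum(k) > 0 && sum(n - k) > 0
    test <- if (testable) pearson_chi2_2x2(k[1], n[1] - k[1], k[2], n[2] - k[2])
            else tibble(chi2 = NA_real_, p_value = NA_real_)
    tibble(outcome = outcome,
           group1 = counts$group[1], successes1 = k[1], total1 = n[1],
           group2 = counts$group[2], successes2 = k[2], total2 = n[2],
           rate1 = 100 * k[1] / n[1], rate2 = 100 * k[2] / n[2],
           pooled_rate = 100 * sum(k) / sum(n),
           chi2 = test$chi2, p_value = test$p_value, testable = testable)
  })
}

#' Cross-tabulate embryo classifications by clinical indication
#'
#' Aggregates per-embryo four-way classifications into a cohort table:
#' counts and percentages per classification within each stratum
#' (e.g. Robertsonian translocation, reciprocal translocation, inversion,
#' AMA/RM), plus an overall stratum. Percentages are taken against the
#' stratum's biopsied total.
#'
#' @param results Data frame with columns `classification` and `stratum`
#'   (any other columns are ignored). Every embryo must carry both labels.
#' @return Tibble `stratum, classification, n, n_total, pct` including an
#'   `"overall"` stratum.
#' @export
aggregate_cohort <- function(results) {
  results <- as_tibble(results)
  stopifnot(all(c("classification", "stratum") %in% names(results)))
  if (anyNA(results$classification) || anyNA(results$stratum)) {
    abort("every embryo needs a classification and a stratum label",
          class = "embryoscreen_labeling_error")
  }
  levels4 <- c("euploid", "numerical", "imbalanced", "numerical+imbalanced")
  stopifnot(all(results$classification %in% levels4))
  results$classification <- factor(results$classification, levels = levels4)

  per_stratum <- results |>
    dplyr::count(.data$stratum, .data$classification, .drop = FALSE,
                 name = "n") |>
    dplyr::mutate(stratum = as.character(.data$stratum))
  overall <- results |>
    dplyr::count(.data$classification, .drop = FALSE, name = "n") |>
    dplyr::mutate(stratum = "overall")
  out <- dplyr::bind_rows(per_stratum, overall) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(n_total = sum(.data$n),
                  pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(classification = as.character(.data$classification))
  out[c("stratum", "classification", "n", "n_total", "pct")]
}

#' Reference clinical outcome counts
#'
#' Outcome counts from a published clinical comparison of
#' sequencing-based versus SNP-array-based embryo screening with
#' cryopreserved blastocyst transfer: 80 vs 203 transfer cycles, 114 vs 292
#' embryos transferred. Bundled as the package's worked example and used by
#' the acceptance script; [build_outcome_tables()] on these counts
#' reproduces the published rates and chi-squared p-values.
#'
#' @return Tibble in the format required by [build_outcome_tables()].
#' @export
pgs_reference_outcomes <- function() {
  tibble(group = c("sequencing", "snp_array"),
         transfer_cycles = c(80, 203),
         clinical_pregnancies = c(49, 115),
         ongoing_pregnancies = c(42, 98),
         miscarriages = c(7, 17),
         embryos_transferred = c(114, 292),
         implantations = c(60, 139))
}

#' Reference cohort classification counts
#'
#' Per-indication four-way classification counts of 454 sequenced blastocysts
#' from the same published screening cohort (Robertsonian translocation,
#' reciprocal translocation, inversion, advanced maternal age / recurrent
#' miscarriage strata). [aggregate_cohort()]-compatible long format; the
#' overall euploid fraction of these counts is 43.6%.
#'
#' @return Tibble `stratum, classification, n`.
#' @export
pgs_reference_cohort <- function() {
  tidyr::expand_grid(
    stratum = c("robertsonian", "reciprocal", "inversion", "ama_rm"),
    classification = c("euploid", "numerical", "imbalanced",
                       "numerical+imbalanced")
  ) |>
    dplyr::mutate(n = c(31, 18, 6, 3,
                        84, 26, 105, 29,
                        18, 8, 6, 1,
                        65, 33, 10, 11))
}
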