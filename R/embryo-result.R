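#' Call a full embryo karyotype from a normalised profile
#'
#' Runs the calling stages on a cn-stage [bin_profile]: dynamic thresholds,
#' per-chromosome binary segmentation, CNV calling with band nomenclature,
#' sex inference, four-way classification and the mtDNA depth ratio.
#'
#' @param profile A cn-stage [bin_profile].
#' @param params A [seg_params()].
#' @param min_cnv_length Minimum call length in bp.
#' @param whole_chrom_fraction Whole-chromosome scope boundary.
#' @param seed Integer seed for the segmentation permutation null.
#' @return An object of class `embryo_result` with fields `sample_id`, `sex`,
#'   `calls`, `classification`, `karyotype_strings`, `mito_ratio`,
#'   `thresholds`, `segments` and the input `profile`. `tidy()` returns the
#'   call table, `glance()` a one-row summary.
#' @export
call_karyotype <- function(profile, params = seg_params(),
                           min_cnv_length = 1e6, whole_chrom_fraction = 0.9,
                           seed = 1) {
  stopifnot(inherits(profile, "bin_profile"))
  thresholds <- dynamic_thresholds(profile, params)
  segments <- segment_profile(profile, params, seed = seed)
  sex <- infer_sex(profile)
  calls <- call_cnvs(segments, thresholds, profile$genome, sex = sex,
                     min_cnv_length = min_cnv_length,
                     whole_chrom_fraction = whole_chrom_fraction)
  structure(
    list(sample_id = profile$sample_id, sex = sex, calls = calls,
         classification = classify_calls(calls),
         karyotype_strings = calls$label,
         mito_ratio = mito_stats(profile)$ratio,
         thresholds = thresholds, segments = segments, profile = profile),
    class = "embryo_result"
  )
}

#' @export
print.embryo_result <- function(x, ...) {
  cat("<embryo_result> sample ", x$sample_id, "\n",
      "  sex: ", x$sex, "   classification: ", x$classification, "\n",
      "  mtDNA depth ratio: ", sprintf("%.1f", x$mito_ratio), "\n", sep = "")
  if (nrow(x$calls) == 0L) {
    cat("  no CNV calls\n")
  } else {
    cat(paste0("  ", x$karyotype_strings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @rdname call_karyotype
#' @param x An `embryo_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.embryo_result <- function(x, ...) {
  dplyr::mutate(x$calls, sample_id = x$sample_id, .before = 1)
}

#' @rdname call_karyotype
#' @exportS3Method generics::glance
glance.embryo_result <- function(x, ...) {
  tibble(sample_id = x$sample_id, sex = x$sex,
         classification = x$classification, n_calls = nrow(x$calls),
         mito_ratio = x$mito_ratio,
         gain_cut = x$thresholds$gain_cut, loss_cut = x$thresholds$loss_cut)
}
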