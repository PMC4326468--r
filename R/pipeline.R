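#' Pipeline configuration
#'
#' Bundles every tunable of the per-embryo analysis so a run is fully
#' described by (inputs, config, seed). The configuration is serialised into
#' each run's parameter record.
#'
#' @param bin_size Bin width in bp.
#' @param read_length Read length in bp.
#' @param gc_method GC-trend estimator passed to [gc_correct()].
#' @param gc_span LOESS span.
#' @param params A [seg_params()].
#' @param min_cnv_length Minimum call length in bp.
#' @param whole_chrom_fraction Whole-chromosome scope boundary.
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_size = 1e6, read_length = 50,
                            gc_method = "auto", gc_span = 0.3,
                            params = seg_params(), min_cnv_length = 1e6,
                            whole_chrom_fraction = 0.9, seed = 1) {
  structure(list(bin_size = bin_size, read_length = read_length,
                 gc_method = gc_method, gc_span = gc_span, params = params,
                 min_cnv_length = min_cnv_length,
                 whole_chrom_fraction = whole_chrom_fraction, seed = seed),
            class = "pipeline_config")
}

#' Analyse one embryo end to end
#'
#' Runs count -> GC-correct -> normalise -> segment -> call -> classify on
#' one embryo and, if `out_dir` is given, writes a per-embryo text report
#' (karyotype strings, classification, mtDNA ratio), a per-bin profile TSV, a
#' calls TSV, a JSON parameter record sufficient to re-execute the run, and a
#' genome-wide copy-number plot. Identical inputs, config and seed produce
#' byte-identical reports.
#'
#' @param reads A read-position data frame (`chrom, start[, end]`), a path to
#'   a BED-like TSV, or an already raw-stage [bin_profile].
#' @param genome A `genome_model`.
#' @param config A [pipeline_config()].
#' @param sample_id Sample identifier.
#' @param out_dir Optional output directory (created if missing).
#' @return An `embryo_result` (invisibly when writing files).
#' @export
run_embryo <- function(reads, genome, config = pipeline_config(),
                       sample_id = "sample", out_dir = NULL) {
  result <- tryCatch({
    profile <- if (inherits(reads, "bin_profile")) {
      reads
    } else {
      if (is.character(reads)) reads <- read_bed_reads(reads)
      count_reads(reads, genome, read_length = config$read_length,
                  sample_id = sample_id)
    }
    profile <- gc_correct(profile, method = config$gc_method,
                          span = config$gc_span)
    profile <- normalize_cn(profile)
    call_karyotype(profile, params = config$params,
                   min_cnv_length = config$min_cnv_length,
                   whole_chrom_fraction = config$whole_chrom_fraction,
                   seed = config$seed)
  }, error = function(e) {
    abort(paste0("sample ", sample_id, ": ", conditionMessage(e)),
          class = "embryoscreen_pipeline_error", parent = e)
  })

  if (!is.null(out_dir)) {
    write_embryo_report(result, config, out_dir)
    return(invisible(result))
  }
  result
}

write_embryo_report <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- result$sample_id
  readr::write_tsv(tidy(result$profile),
                   file.path(out_dir, paste0(id, "_profile.tsv")),
                   progress = FALSE)
  readr::write_tsv(tidy(result),
                   file.path(out_dir, paste0(id, "_calls.tsv")),
                   progress = FALSE)
  lines <- c(
    paste0("sample\t", id),
    paste0("sex\t", result$sex),
    paste0("classification\t", result$classification),
    paste0("mito_ratio\t", sprintf("%.4f", result$mito_ratio)),
    paste0("gain_cut\t", sprintf("%.4f", result$thresholds$gain_cut)),
    paste0("loss_cut\t", sprintf("%.4f", result$thresholds$loss_cut)),
    if (length(result$karyotype_strings))
      paste0("call\t", result$karyotype_strings) else "call\tnone"
  )
  writeLines(lines, file.path(out_dir, paste0(id, "_report.txt")))
  cfg <- config
  cfg$params <- unclass(cfg$params)
  jsonlite::write_json(unclass(cfg),
                       file.path(out_dir, paste0(id, "_params.json")),
                       auto_unbox = TRUE, digits = NA)
  tryCatch(
    ggplot2::ggsave(file.path(out_dir, paste0(id, "_profile.png")),
                    autoplot(result), width = 10, height = 4, dpi = 150),
    error = function(e) warn(paste0("plot not written: ", conditionMessage(e)))
  )
  invisible(out_dir)
}

#' Analyse a cohort of embryos
#'
#' Runs [run_embryo()] over a manifest, aggregates the four-way
#' classification by stratum, compares mtDNA ratios between euploid and
#' abnormal embryos (when both are present), and, given clinical outcome
#' counts, builds the outcome comparison tables. Failing samples are listed
#' in a skip report and the run continues, unless `strict = TRUE`.
#'
#' @param manifest Data frame with columns `sample_id`, `stratum`, and either
#'   `reads` (list-column of read tibbles / raw-stage profiles) or `path`
#'   (BED-like files).
#' @param genome A `genome_model`.
#' @param config A [pipeline_config()].
#' @param clinical_counts Optional counts for [build_outcome_tables()].
#' @param out_dir Optional directory for cohort TSV outputs.
#' @param strict Abort on the first failing sample (default FALSE).
#' @return List with `results` (one glance row per embryo), `cohort_summary`,
#'   `mtdna_comparison` (or NULL), `outcome_tables` (or NULL), `skipped`.
#' @export
run_cohort <- function(manifest, genome, config = pipeline_config(),
                       clinical_counts = NULL, out_dir = NULL,
                       strict = FALSE) {
  manifest <- as_tibble(manifest)
  stopifnot(all(c("sample_id", "stratum") %in% names(manifest)))
  if (nrow(manifest) == 0L && strict) {
    abort("empty manifest", class = "embryoscreen_input_error")
  }

  results <- list()
  skipped <- character()
  for (i in seq_len(nrow(manifest))) {
    input <- if ("reads" %in% names(manifest)) manifest$reads[[i]]
             else manifest$path[i]
    res <- tryCatch(
      run_embryo(input, genome, config, sample_id = manifest$sample_id[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (strict) stop(res)
      skipped <- c(skipped, manifest$sample_id[i])
    } else {
      results[[manifest$sample_id[i]]] <- res
    }
  }

  res_tbl <- purrr::map_dfr(results, glance)
  if (nrow(res_tbl) > 0) {
    res_tbl <- dplyr::left_join(res_tbl,
                                manifest[c("sample_id", "stratum")],
                                by = "sample_id")
  }
  summary_tbl <- if (nrow(res_tbl) > 0) aggregate_cohort(res_tbl) else NULL
  mt <- if (nrow(res_tbl) > 0 &&
            any(res_tbl$classification == "euploid") &&
            any(res_tbl$classification != "euploid")) {
    compare_mtdna(res_tbl)
  }
  outcomes <- if (!is.null(clinical_counts)) build_outcome_tables(clinical_counts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(res_tbl, file.path(out_dir, "embryo_results.tsv"),
                     progress = FALSE)
    if (!is.null(summary_tbl)) {
      readr::write_tsv(summary_tbl, file.path(out_dir, "cohort_summary.tsv"),
                       progress = FALSE)
    }
    if (!is.null(mt)) {
      readr::write_tsv(mt, file.path(out_dir, "mtdna_comparison.tsv"),
                       progress = FALSE)
    }
    if (!is.null(outcomes)) {
      readr::write_tsv(outcomes, file.path(out_dir, "outcome_tables.tsv"),
                       progress = FALSE)
    }
    if (length(skipped)) {
      writeLines(skipped, file.path(out_dir, "skipped_samples.txt"))
    }
  }
  list(results = res_tbl, cohort_summary = summary_tbl,
       mtdna_comparison = mt, outcome_tables = outcomes, skipped = skipped)
}
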