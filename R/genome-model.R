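#' Build a genome model
#'
#' A genome model is the coordinate frame for the whole pipeline: an ordered
#' set of chromosomes, a fixed bin grid with a per-bin GC fraction, a cytoband
#' map for call nomenclature, and a mitochondrial contig handled separately
#' from the nuclear bins. Coordinates are 0-based half-open internally; bins
#' are `[k * bin_size, (k + 1) * bin_size)` with the last bin of each
#' chromosome truncated at the chromosome end.
#'
#' @param chromosomes Data frame with columns `chrom` and `length` (base
#'   pairs), in the order chromosomes should be reported. Sex chromosomes are
#'   recognised by name (`chrX`/`X`, `chrY`/`Y`).
#' @param bin_size Bin width in base pairs (default 1e6, matching the >1 Mb
#'   design resolution of shallow-coverage calling).
#' @param gc Optional numeric vector of per-bin GC fractions, one value per
#'   bin in genome order. Defaults to a flat 0.45 if omitted.
#' @param cytobands Optional data frame `chrom, start, end, band` tiling each
#'   chromosome (0-based half-open). Required for band nomenclature.
#' @param mito_name,mito_length Name and length of the mitochondrial contig.
#'
#' @return An object of class `genome_model`: a list with tibbles
#'   `chromosomes`, `bins` (`chrom, bin, start, end, gc, is_autosome`),
#'   `cytobands`, plus `bin_size`, `mito_name`, `mito_length`.
#' @export
#' @examples
#' g <- genome_model(data.frame(chrom = c("chr1", "chr2"),
#'                              length = c(5e6, 4e6)), bin_size = 1e6)
#' g$bins
genome_model <- function(chromosomes, bin_size = 1e6, gc = NULL,
                         cytobands = NULL, mito_name = "chrM",
                         mito_length = 16569) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            is_count(bin_size), bin_size > 0)
  if (anyDuplicated(chromosomes$chrom) > 0) {
    abort("duplicated chromosome names", class = "embryoscreen_invalid_spec")
  }
  chromosomes <- dplyr::mutate(
    chromosomes,
    length = as.numeric(.data$length),
    is_autosome = !is_sex_chrom(.data$chrom)
  )

  bins <- purrr::pmap_dfr(
    chromosomes[c("chrom", "length")],
    function(chrom, length) {
      starts <- seq(0, length - 1, by = bin_size)
      tibble(chrom = chrom, bin = seq_along(starts) - 1L, start = starts,
             end = pmin(starts + bin_size, length))
    }
  )
  bins$is_autosome <- !is_sex_chrom(bins$chrom)
  if (is.null(gc)) gc <- rep(0.45, nrow(bins))
  if (length(gc) != nrow(bins)) {
    abort("`gc` must have one value per bin", class = "embryoscreen_invalid_spec")
  }
  stopifnot(all(gc > 0 & gc < 1))
  bins$gc <- as.numeric(gc)

  if (!is.null(cytobands)) {
    cytobands <- as_tibble(cytobands)[c("chrom", "start", "end", "band")]
    validate_cytobands(cytobands, chromosomes)
  }

  structure(
    list(chromosomes = chromosomes, bins = bins, bin_size = bin_size,
         cytobands = cytobands, mito_name = mito_name,
         mito_length = as.numeric(mito_length)),
    class = "genome_model"
  )
}

# Cytobands must tile each declared chromosome exactly: start at 0, end at the
# chromosome length, no gaps or overlaps.
validate_cytobands <- function(cytobands, chromosomes) {
  for (i in seq_len(nrow(chromosomes))) {
    cb <- cytobands[cytobands$chrom == chromosomes$chrom[i], ]
    if (nrow(cb) == 0L) next
    cb <- cb[order(cb$start), ]
    ok <- cb$start[1] == 0 &&
      cb$end[nrow(cb)] == chromosomes$length[i] &&
      all(cb$end[-nrow(cb)] == cb$start[-1]) &&
      all(cb$end > cb$start)
    if (!ok) {
      abort(paste0("cytobands do not tile ", chromosomes$chrom[i]),
            class = "embryoscreen_invalid_spec")
    }
  }
  invisible(cytobands)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$bins), " bins of ", format(x$bin_size, big.mark = ","),
      " bp; mito contig ", x$mito_name, " (", x$mito_length, " bp)\n", sep = "")
  invisible(x)
}

genome_length <- function(genome) sum(genome$chromosomes$length)

n_bins <- function(genome) nrow(genome$bins)

#' Read a UCSC-format cytoband file
#'
#' Reads the tab-separated `cytoBand.txt` dialect (`chrom, start, end, band,
#' stain`); the Giemsa stain column is ignored.
#'
#' @param path Path to the file.
#' @return Tibble with columns `chrom, start, end, band`.
#' @export
read_cytoband <- function(path) {
  cb <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "band", "stain"),
                        col_types = "ciicc", progress = FALSE)
  cb[c("chrom", "start", "end", "band")]
}

#' Write / read a genome model as JSON
#'
#' Round-trips a `genome_model` through a JSON file so simulated genomes can be
#' shared between runs.
#'
#' @param genome A `genome_model`.
#' @param path File path.
#' @return `read_genome_json` returns a `genome_model`;
#'   `write_genome_json` returns `path` invisibly.
#' @export
write_genome_json <- function(genome, path) {
  obj <- list(
    chromosomes = genome$chromosomes[c("chrom", "length")],
    bin_size = genome$bin_size,
    gc = genome$bins$gc,
    cytobands = genome$cytobands,
    mito_name = genome$mito_name,
    mito_length = genome$mito_length
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genome_model(
    chromosomes = as_tibble(obj$chromosomes),
    bin_size = obj$bin_size,
    gc = obj$gc,
    cytobands = if (!is.null(obj$cytobands)) as_tibble(obj$cytobands),
    mito_name = obj$mito_name,
    mito_length = obj$mito_length
  )
}
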