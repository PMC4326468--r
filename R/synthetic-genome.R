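#' Specify a synthetic genome
#'
#' Describes a small human-like genome for simulation: a handful of autosomes,
#' optional sex chromosomes, a mitochondrial contig, a smooth per-bin GC
#' landscape and a generated cytoband map. The defaults give a ~300 Mb genome
#' whose per-bin read counts, at the depth of a typical shallow-sequencing
#' embryo screen (8.2 million reads per ~3.1 Gb genome equivalent), match the
#' signal-to-noise of the real assay.
#'
#' @param autosome_lengths Numeric vector of autosome lengths in bp.
#' @param include_sex_chromosomes Add chrX/chrY (default TRUE).
#' @param x_length,y_length Sex-chromosome lengths in bp.
#' @param mito_length Mitochondrial contig length (human-like 16,569 bp).
#' @param gc_amplitude,gc_noise_sd GC landscape: a low-frequency sinusoid of
#'   this amplitude around 0.45 plus Gaussian noise, clamped to [0.25, 0.65].
#' @param band_count_per_chromosome Cytobands generated per chromosome.
#' @param centromere_fraction Centromere position as a fraction of length.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(autosome_lengths = c(48, 45, 40, 35, 33, 30, 25, 20) * 1e6,
                                  include_sex_chromosomes = TRUE,
                                  x_length = 15e6, y_length = 10e6,
                                  mito_length = 16569,
                                  gc_amplitude = 0.12, gc_noise_sd = 0.02,
                                  band_count_per_chromosome = 8,
                                  centromere_fraction = 0.4) {
  stopifnot(length(autosome_lengths) >= 1, all(autosome_lengths > 0),
            is_count(band_count_per_chromosome),
            band_count_per_chromosome >= 2,
            centromere_fraction > 0, centromere_fraction < 1)
  structure(
    list(autosome_lengths = autosome_lengths,
         include_sex_chromosomes = include_sex_chromosomes,
         x_length = x_length, y_length = y_length,
         mito_length = mito_length,
         gc_amplitude = gc_amplitude, gc_noise_sd = gc_noise_sd,
         band_count_per_chromosome = band_count_per_chromosome,
         centromere_fraction = centromere_fraction),
    class = "synthetic_genome_spec"
  )
}

#' Generate a synthetic genome model
#'
#' Builds a deterministic `genome_model` from a [synthetic_genome_spec()]:
#' autosomes `chr1..chrN` (plus `chrX`/`chrY` if requested), a per-bin GC
#' track drawn as a low-frequency sinusoid with noise clamped to
#' \[0.25, 0.65\], and synthetic cytobands named `p2, p1, q1, q2, ...` per arm
#' around a centromere at a configurable fraction of the chromosome.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param seed Integer seed; the same `(spec, seed)` always yields an
#'   identical genome.
#' @param bin_size Bin width in bp.
#' @return A `genome_model`.
#' @export
#' @examples
#' g <- make_synthetic_genome(synthetic_genome_spec(), seed = 1)
#' g
make_synthetic_genome <- function(spec, seed, bin_size = 1e6) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  chroms <- tibble(
    chrom = paste0("chr", seq_along(spec$autosome_lengths)),
    length = as.numeric(spec$autosome_lengths)
  )
  if (isTRUE(spec$include_sex_chromosomes)) {
    chroms <- dplyr::bind_rows(
      chroms,
      tibble(chrom = c("chrX", "chrY"),
             length = c(spec$x_length, spec$y_length))
    )
  }
  if (any(chroms$length < 10 * bin_size)) {
    abort("every chromosome must span at least 10 bins",
          class = "embryoscreen_invalid_spec")
  }

  bins_per_chrom <- ceiling(chroms$length / bin_size)
  gc <- with_component_seed(seed, "gc_track", 0L, {
    unlist(purrr::map2(seq_len(nrow(chroms)), bins_per_chrom, function(i, nb) {
      phase <- runif(1, 0, 2 * pi)
      period <- runif(1, 15, 40)                      # bins per GC wave
      raw <- 0.45 +
        spec$gc_amplitude * sin(2 * pi * seq_len(nb) / period + phase) +
        rnorm(nb, sd = spec$gc_noise_sd)
      pmin(pmax(raw, 0.25), 0.65)
    }))
  })

  cytobands <- purrr::pmap_dfr(chroms, function(chrom, length, ...) {
    synthetic_bands(chrom, length, spec$band_count_per_chromosome,
                    spec$centromere_fraction)
  })

  genome_model(chroms, bin_size = bin_size, gc = gc, cytobands = cytobands,
               mito_length = spec$mito_length)
}

# Equal-width bands per arm, numbered outward from the centromere so the
# p-terminal band is p{np} and the q-terminal band is q{nq}, mirroring real
# ISCN ordering. Bands tile [0, length) exactly.
synthetic_bands <- function(chrom, length, n_bands, centromere_fraction) {
  np <- max(1L, floor(n_bands / 2))
  nq <- max(1L, n_bands - np)
  cen <- round(length * centromere_fraction)
  p_edges <- round(seq(0, cen, length.out = np + 1))
  q_edges <- round(seq(cen, length, length.out = nq + 1))
  tibble(
    chrom = chrom,
    start = c(p_edges[-(np + 1)], q_edges[-(nq + 1)]),
    end = c(p_edges[-1], q_edges[-1]),
    band = c(paste0("p", rev(seq_len(np))), paste0("q", seq_len(nq)))
  )
}

#' @importFrom stats rnorm
NULL
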