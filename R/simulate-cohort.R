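#' Simulate a labelled cohort of embryos
#'
#' Draws a four-way truth class for each embryo, builds a matching
#' [karyotype_spec()] (numerical: 1-2 whole-chromosome aneuploidies;
#' imbalanced: 1-2 segmental events; numerical+imbalanced: at least one of
#' each, on different chromosomes), and simulates its coverage profile.
#' Event copy numbers are drawn from \{1, 3\}; segmental event lengths are
#' uniform between `seg_length_range` bounds, capped at 60% of the carrying
#' autosome so a segmental event never masquerades as whole-chromosome.
#' Abnormal embryos receive a median mitochondrial copy-factor shift of
#' `mito_shift_abnormal` (with log-normal embryo-to-embryo scatter),
#' emulating the elevated relative mtDNA copy number reported for
#' chromosomally abnormal blastocysts.
#'
#' @param n_embryos Number of embryos (0 gives an empty cohort).
#' @param class_frequencies Probabilities of the four classes, in the order
#'   euploid, numerical, imbalanced, numerical+imbalanced; must sum to 1.
#' @param genome A `genome_model`.
#' @param cfg A [read_sim_config()]; its seed is ignored in favour of
#'   per-embryo seeds derived from `seed`.
#' @param seed Integer seed for the whole cohort.
#' @param method `"counts"` (fast path, default) to return raw-stage
#'   [bin_profile]s, or `"reads"` to return read-position tibbles.
#' @param seg_length_range Segmental event length bounds in bp.
#' @param mito_shift_abnormal Median mito copy-factor of abnormal embryos
#'   relative to euploid ones.
#' @return A list with `truth` (tibble `sample_id, class, sex,
#'   mito_copy_factor, events` (list-column)) and `samples` (named list of
#'   profiles or read tibbles).
#' @export
simulate_cohort <- function(n_embryos,
                            class_frequencies = c(0.436, 0.187, 0.280, 0.097),
                            genome, cfg = read_sim_config(), seed = 1,
                            method = c("counts", "reads"),
                            seg_length_range = c(3e6, 50e6),
                            mito_shift_abnormal = 1.3) {
  method <- match.arg(method)
  stopifnot(is_count(n_embryos),
            length(class_frequencies) == 4, all(class_frequencies >= 0),
            abs(sum(class_frequencies) - 1) < 1e-8)
  classes <- c("euploid", "numerical", "imbalanced", "numerical+imbalanced")
  if (n_embryos == 0L) {
    return(list(truth = tibble(sample_id = character(), class = character(),
                               sex = character(), mito_copy_factor = numeric(),
                               events = list()),
                samples = list()))
  }

  truth <- with_component_seed(seed, "cohort_truth", 0L, {
    drawn <- sample(classes, n_embryos, replace = TRUE,
                    prob = class_frequencies)
    purrr::map_dfr(seq_len(n_embryos), function(i) {
      sex <- sample(c("XX", "XY"), 1)
      shift <- if (drawn[i] == "euploid") 1 else mito_shift_abnormal
      tibble(sample_id = sprintf("E%03d", i), class = drawn[i], sex = sex,
             mito_copy_factor = shift * rlnorm(1, 0, 0.2),
             events = list(draw_events(drawn[i], genome, seg_length_range)))
    })
  })

  samples <- purrr::map(seq_len(n_embryos), function(i) {
    kt <- karyotype_spec(truth$events[[i]], sex = truth$sex[i],
                         mito_copy_factor = truth$mito_copy_factor[i])
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, "embryo", i)
    if (method == "counts") {
      simulate_bin_counts(genome, kt, cfg_i, sample_id = truth$sample_id[i])
    } else {
      simulate_reads(genome, kt, cfg_i)
    }
  })
  names(samples) <- truth$sample_id
  list(truth = truth, samples = samples)
}

# Draw the event set implied by a truth class. Events live on autosomes only;
# whole-chromosome and segmental events of one embryo use distinct autosomes.
draw_events <- function(class, genome, seg_length_range) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  copy_number = integer())
  if (class == "euploid") return(empty)
  autos <- genome$chromosomes[genome$chromosomes$is_autosome, ]
  n_whole <- switch(class, numerical = sample(1:2, 1),
                    imbalanced = 0L, `numerical+imbalanced` = 1L)
  n_seg <- switch(class, numerical = 0L,
                  imbalanced = sample(1:2, 1), `numerical+imbalanced` = 1L)
  picked <- sample(nrow(autos), n_whole + n_seg)
  ev <- empty
  for (k in seq_len(n_whole)) {
    ch <- autos[picked[k], ]
    ev <- dplyr::bind_rows(ev, tibble(chrom = ch$chrom, start = 0,
                                      end = ch$length,
                                      copy_number = sample(c(1L, 3L), 1)))
  }
  for (k in seq_len(n_seg)) {
    ch <- autos[picked[n_whole + k], ]
    len <- runif(1, seg_length_range[1],
                 max(seg_length_range[1], min(seg_length_range[2],
                                              0.6 * ch$length)))
    start <- runif(1, 0, ch$length - len)
    ev <- dplyr::bind_rows(ev, tibble(chrom = ch$chrom, start = floor(start),
                                      end = floor(start + len),
                                      copy_number = sample(c(1L, 3L), 1)))
  }
  ev
}
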