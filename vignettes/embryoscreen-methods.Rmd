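---
title: "Copy-number screening of embryo biopsies from shallow WGS: models and methods"
author: "embryoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number screening of embryo biopsies from shallow WGS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscreen)
```

## The measurement problem

Preimplantation genetic diagnosis and screening (PGD/PGS) tests a 3–8-cell
trophectoderm biopsy of a day-5 blastocyst for chromosomal abnormalities
before the embryo is transferred. The few biopsied cells are whole-genome
amplified (WGA) and sequenced shallowly — on the order of 8.2 million
single-end reads per embryo, about 0.07× nuclear depth, covering roughly 5%
of the genome but essentially all of the small, high-copy mitochondrial
genome. At that depth individual positions are uninformative; what carries
signal is the *density* of reads along the genome. A region present in three
copies instead of two attracts 1.5× the reads; a monosomy attracts half.

`embryoscreen` implements the complete analysis downstream of alignment:

1. **Binning** — read starts are counted in fixed 1 Mb windows.
2. **GC/WGA bias correction** — WGA preferentially amplifies mid-GC
   fragments; the count-versus-GC trend is estimated and divided out.
3. **Normalisation** — corrected counts are scaled so the autosomal median
   equals 2, giving a per-bin copy-number ratio.
4. **Segmentation** — recursive binary segmentation with a permutation
   stopping rule locates breakpoints.
5. **Calling and classification** — segments beyond per-sample dynamic
   thresholds become integer-copy CNV calls (≥1 Mb), rendered in band-level
   "seq" nomenclature; each embryo is classified euploid / numerical /
   imbalanced / numerical+imbalanced.
6. **Cohort statistics** — relative mtDNA copy number
   (`ChrM_depth/Mean_depth`) compared between euploid and abnormal embryos
   by a Mann–Whitney test, and 2×2 Pearson chi-squared comparisons of
   clinical outcome rates.

A seeded synthetic-data generator stands in for patient sequencing data, so
every stage is testable end to end.

## Binning and bias correction

Bins are half-open `[k·10^6, (k+1)·10^6)` in 0-based coordinates, the last
bin truncated at the chromosome end. At 8.2 M reads per 3.1 Gb genome a 1 Mb
bin holds ~2,700 reads, so the per-bin Poisson coefficient of variation is
about 2% and the effective noise floor is set by WGA overdispersion rather
than counting statistics. Reads are assigned by start position only —
single-end 50 bp reads are three orders of magnitude shorter than a bin, so
fractional overlap handling would change nothing.

The GC trend \(\hat f(\text{gc})\) is fitted on autosomal bins and each bin
is corrected as

\[
c_k = r_k \cdot \frac{\overline{\hat f}}{\hat f(\text{gc}_k)},
\]

then rescaled so total count mass is preserved. The default estimator is a
robust LOESS (span 0.3, degree 2, symmetric family). Two safeguards matter
in practice:

* **Copy-number masking.** A CNV segment sitting in a sparsely populated GC
  range can drag the trend toward its shifted level. A coarse pre-fit
  (GC-decile medians, each decile's level taken as the median of
  per-chromosome medians so no single aneuploid chromosome can dominate a
  decile) flags bins whose count ratio deviates by more than a factor 1.37 —
  clearly beyond bias wobble, clearly short of a one-copy change — and the
  LOESS is fitted on the remaining bins only.
* **Small genomes.** Below 200 autosomal bins LOESS is under-determined and
  the stratified-decile median is used directly.

Bins with GC outside the fitted support use the nearest-edge fit; a
degenerate GC track (all bins equal to within 0.001) makes the correction an
identity, with a warning.

Normalisation sets `cn_ratio = 2 · c_k / median(autosomal c)`. Sex
chromosomes are excluded from the median and from the noise scale so a male
X (one copy) cannot shift the diploid baseline. The per-sample noise scale
is the median absolute deviation of autosomal `cn_ratio` scaled by 1.4826,
the standard consistent estimate of σ under normality.

## Segmentation and the dynamic threshold

The single-split kernel `best_split()` maximises over split points the
t-like contrast

\[
T(i) = \frac{\bar x_{1..i} - \bar x_{i+1..n}}{s\sqrt{1/i + 1/(n-i)}},
\]

with `s` the pooled standard deviation and ties broken to the smallest
index. A single mean contrast, however, cannot expose a *short event in the
middle* of a segment: its up-step and down-step cancel in every one-sided
split. The recursion therefore maximises the two-boundary (circular) form
of the same contrast — an interior run `values[(i+1)..j]` against the
remainder — which reduces to `best_split()` when one boundary coincides
with a segment end. This is the same consideration that motivates circular
binary segmentation in the CNV literature, and on noise-free input both
forms recover identical breakpoints (the test suite checks equality with an
exhaustive least-squares oracle on all series up to 30 bins).

A candidate split is accepted when its statistic exceeds the `(1 − α)`
quantile of a within-segment permutation null (the segment's own values
shuffled; α = 0.01, 1,000 permutations by default). The acceptance is
implemented in counting form — fewer than `α·B` of `B` shuffles may reach
the observed statistic — which allows early termination as soon as
acceptance becomes impossible; this leaves clearly diploid chromosomes
cheap while spending full permutations only where there is signal. With
`n_permutations = 0` acceptance is deterministic (any nonzero statistic),
appropriate only for noise-free series. Segmentation is per chromosome;
breakpoints cannot span chromosomes.

Calling thresholds adapt to each sample's noise:

\[
\text{gain/loss cut} = 2 \pm \max\Big(0.4,\;
  \frac{3 \cdot \text{MAD}}{\sqrt{\text{min\_seg\_bins}}}\Big).
\]

The MAD term is a 3σ bound on the mean of a minimal (3-bin) segment; the
floor of 0.4 keeps a very quiet sample from calling sub-mosaic wobble that
shallow WGA coverage cannot substantiate. Both constants are parameters of
`seg_params()`.

## Calls, sex, classification, nomenclature

A segment is a candidate call when its mean deviates from the chromosome's
*expected dose* by at least the threshold: 2 for autosomes; for sex
chromosomes the dose implied by the inferred sex (XX: X = 2, Y = 0; XY:
X = Y = 1), so a Y gain in a male embryo is called at ×2. Adjacent
same-direction candidates merge; the integer copy number is the rounded
segment mean clamped to 0..4 (shallow coverage cannot resolve higher
states), and a call that rounds back to the expected dose is discarded.
Calls shorter than 1 Mb are dropped — the method's stated resolution limit.
A call covering ≥90% of its chromosome counts as whole-chromosome; the 90%
boundary is a package choice (the four-way classification needs *some*
boundary and none is standard) and is configurable.

Sex is inferred from median X and Y dosage with cutpoints at the midpoints
1.5 and 0.5; a median exactly on a cutpoint gives `undetermined`, in which
case sex chromosomes are conservatively not called.

Classification: no calls → euploid; only whole-chromosome calls →
numerical; only segmental → imbalanced; both → numerical+imbalanced.

Calls render as
`seq {chrom}{band} → {band}({start}–{end})×{copies}` with 1-based inclusive
coordinates (internal arithmetic is 0-based half-open), `pter`/`qter` for
terminal bands, and an en dash between coordinates. `parse_call()` inverts
the rendering exactly for chromosome, coordinates and copy number.

## mtDNA copy number and clinical statistics

Relative mtDNA copy number is the ratio of mean mitochondrial to mean
nuclear depth. Groups (euploid versus any abnormality) are compared with a
two-sided Mann–Whitney test: exact when both groups have ≤8 observations
and no ties, otherwise the normal approximation with tie and continuity
corrections. Two-sidedness is an assumption — the underlying clinical
report does not state sidedness — and is documented rather than
configurable.

Clinical outcome rates use the field's denominator conventions: clinical
and ongoing pregnancy per transfer cycle, miscarriage per clinical
pregnancy, implantation per embryo transferred. The 2×2 comparisons use the
plain Pearson chi-squared statistic on 1 degree of freedom with **no Yates
continuity correction**; with the correction applied, the bundled reference
counts do not reproduce their published p-values (0.480, 0.522, 0.934,
0.362), which pins down the convention.

## The synthetic-data generator

`simulate_reads()` / `simulate_bin_counts()` emulate the statistical
structure the pipeline assumes, not sequencing itself (no bases, qualities,
or alignment): per-bin expected counts proportional to
(local copy number / 2) × a GC weight, negative-binomially dispersed, plus
mitochondrial reads drawn so the expected depth ratio equals
`mito_mean_depth_ratio × mito_copy_factor`. Choices, made once:

* **Depth** defaults to 8.2 million reads per 3.08 Gb scaled to the
  simulated genome — the study-scale coverage regime (~2,700 reads/bin).
* **GC bias** is a quadratic weight peaking at GC 0.45 with strength 8
  (range ≈ 0.68–1 over the generated GC interval [0.25, 0.65]); the true
  WGA bias shape is not published, so the curve is a free, documented
  parameter, and the correction stage is tested for *recovering* whatever
  curve was injected, not for this particular shape.
* **Overdispersion** 0.01 (negative-binomial `size` 100) gives a per-bin
  coefficient of variation ≈10% at study depth, matching the
  noise magnitude reported for WGA-based single-embryo sequencing; it is a
  realism choice, not a fit.
* **Mitochondrial ratio** defaults to 100 with log-normal embryo-to-embryo
  scatter (σ_log = 0.2); abnormal embryos in `simulate_cohort()` get a
  1.3× median shift, emulating the direction (higher in abnormal) of the
  published comparison, whose effect size is not reported.
* **Cohort class frequencies** default to the published four-way mix
  (43.6 / 18.7 / 28.0 / 9.7%); segmental events are 3–50 Mb, capped at 60%
  of the carrying autosome so they cannot masquerade as whole-chromosome
  events; events are placed on autosomes.
* The default synthetic genome is ~300 Mb (8 autosomes, X, Y, chrM), kept
  deliberately small: at fixed reads-per-megabase every per-bin statistic
  is scale-free, so a 300 Mb genome exercises the method at study
  signal-to-noise while keeping a 50-embryo cohort analysis under a minute.
  Synthetic cytobands (`p2, p1, q1, q2, …` around a centromere at 40% of
  the chromosome) exercise nomenclature code without a reference genome.

A single cohort seed expands into per-component seeds through a fixed
counter scheme, so re-simulating one embryo reproduces exactly its full-run
data.

What passing synthetic tests does **not** show: robustness to mappability
holes, centromeric/telomeric artefact bins, reference-genome blacklists,
GC–mappability interactions, or mosaicism (a biopsy whose cells disagree);
none of these are modelled, and a segment sitting between the thresholds is
silently diploid.

## Numerical and degenerate-input conventions

* Count conservation is exact: binned + mitochondrial + dropped = input
  reads; >1% of reads on unknown chromosomes is an input-mismatch error.
* GC correction requires ≥50 nonzero autosomal bins; an all-zero autosomal
  median is a no-signal error.
* `best_split` returns statistic 0 at index `min_seg_bins` for a constant
  series and ±Inf for a zero-variance split with unequal means.
* Permutation nulls are seeded; identical inputs and seeds give
  byte-identical reports (`run_embryo()` writes a JSON parameter record
  sufficient to re-execute the run).
* Mann–Whitney with an empty group, chi-squared with a zero margin, and a
  one-sided cohort partition raise typed errors rather than NA results.

## Worked example

```{r example, eval = FALSE}
genome <- make_synthetic_genome(synthetic_genome_spec(), seed = 1)
kt <- karyotype_spec(
  data.frame(chrom = "chr2", start = 0, end = 45e6, copy_number = 3),
  sex = "XY")
profile <- simulate_bin_counts(genome, kt, read_sim_config(seed = 3),
                               sample_id = "demo")
result <- profile |> gc_correct() |> normalize_cn() |> call_karyotype(seed = 5)
result
#> <embryo_result> sample demo
#>   sex: XY   classification: numerical
#>   mtDNA depth ratio: 99.1
#>   seq 2pter → qter(1–45000000)×3
autoplot(result)
```

The problem sizes used throughout the test suite — a ~300 Mb genome,
50-embryo cohorts, 100-series noise studies, 1,000-permutation nulls — are
the package's chosen test scale; every statistic involved is
reads-per-bin-normalised, so conclusions transfer to full-genome runs at
the same depth per megabase.

## Known limitations

Mosaicism and polyploidy are undetectable by count-based shallow WGS and are
not modelled. Balanced rearrangements produce no dosage signal and are
invisible by construction. The dynamic-threshold constants (k = 3, floor
0.4) and the 90% whole-chromosome boundary are package conventions, logged
with every run, not published values. The bundled clinical tables are
aggregate counts; per-couple structure (twins, repeated cycles) is not
modelled and rates are computed exactly on the aggregated counts.
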