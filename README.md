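# embryoscreen

Copy-number screening of embryo biopsies from shallow whole-genome
sequencing, for preimplantation genetic diagnosis and screening (PGD/PGS)
analysts and method developers.

A day-5 blastocyst trophectoderm biopsy (3–8 cells) is whole-genome
amplified and sequenced to ~0.07× depth (≈8.2 million single-end reads).
At that depth the informative signal is read *density*: a trisomic region
draws 1.5× the reads of a disomic one. `embryoscreen` implements the full
analysis downstream of alignment:

- **Binning** of aligned read starts into 1 Mb windows
  (`count_reads()`), from BED-like positions or simulated data.
- **GC/WGA bias removal** (`gc_correct()`): a robust LOESS fit of the
  count-versus-GC trend with copy-number masking, divided out of each bin.
- **Normalisation** (`normalize_cn()`): per-bin copy-number ratio scaled so
  the autosomal median is exactly 2, with a MAD-based per-sample noise
  scale.
- **Breakpoint detection** (`segment_profile()`): recursive binary
  segmentation maximising a t-like mean contrast (two-boundary/circular
  form), with a within-segment permutation stopping rule
  (α = 0.01, seeded).
- **CNV calling** (`call_cnvs()`, `call_karyotype()`): per-sample dynamic
  thresholds `2 ± max(0.4, 3·MAD/√3)`, integer copies 0–4, ≥1 Mb, sex-aware
  dosage on X/Y, four-way embryo classification (euploid / numerical /
  imbalanced / numerical+imbalanced), and band-level nomenclature such as
  `seq 2q31.3 → qter(182458386–242690112)×1`.
- **mtDNA copy number** (`mito_stats()`, `compare_mtdna()`): the
  `ChrM_depth/Mean_depth` ratio and a two-sided Mann–Whitney comparison of
  euploid versus abnormal embryos (exact for small groups without ties).
- **Clinical outcome statistics** (`build_outcome_tables()`,
  `pearson_chi2_2x2()`, `aggregate_cohort()`): transfer-cycle outcome rates
  with Pearson chi-squared tests (no continuity correction) and cohort
  classification tables.
- **Synthetic data** (`make_synthetic_genome()`, `simulate_reads()`,
  `simulate_cohort()`): seeded, GC-biased, negative-binomially
  overdispersed read simulation over configurable genomes and karyotypes,
  so the whole pipeline runs and is tested without patient data.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(embryoscreen)

genome <- make_synthetic_genome(synthetic_genome_spec(), seed = 1)

# a male embryo with trisomy of the 45 Mb synthetic chr2
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

glance(result)
#> # A tibble: 1 × 7
#>   sample_id sex   classification n_calls mito_ratio gain_cut loss_cut
#>   <chr>     <chr> <chr>            <int>      <dbl>    <dbl>    <dbl>
#> 1 demo      XY    numerical            1       99.1     2.49     1.51
```

The embryo is sexed XY from X/Y dosage, the whole-chromosome gain is called
at ×3 (`pter → qter` spans the chromosome), the classification is
"numerical", and the mitochondrial/nuclear depth ratio sits at its
simulated baseline of ~100. `gain_cut`/`loss_cut` are this sample's dynamic
calling thresholds, derived from its own noise level. `autoplot(result)`
draws the genome-wide digital-karyotype view with segment means and
thresholds.

Clinical outcome comparison on the bundled reference counts:

```r
build_outcome_tables(pgs_reference_outcomes())[, c("outcome", "rate1", "rate2", "p_value")]
#> # A tibble: 4 × 4
#>   outcome            rate1 rate2 p_value
#>   <chr>              <dbl> <dbl>   <dbl>
#> 1 clinical_pregnancy  61.2  56.7   0.480
#> 2 ongoing_pregnancy   52.5  48.3   0.522
#> 3 miscarriage         14.3  14.8   0.934
#> 4 implantation        52.6  47.6   0.362
```

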