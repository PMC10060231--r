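# meionascent

Run-on-calibrated analysis of nascent transcription across meiotic
prophase I.

## The problem

Nascent-transcription sequencing (ChRO-seq/PRO-seq style) maps the RNA
polymerase active site at single-base resolution, but libraries are
relative: a genome-wide burst of transcription — such as the one
spermatocytes undergo in pachynema — cancels out of per-library
normalization. `meionascent` is for analysts of stage-resolved
nascent-transcription data who need:

- **absolute normalization** anchored to radioactive nuclear run-on
  measurements. Serial-dilution standards give a calibration line
  `CPM = m·x + b`; each sorted cell fraction with stage composition
  `(f_LZ, f_P, f_D)` satisfies

  ```
  observed CPM / expected CPM = f_LZ·a_LZ + f_P·a_P + f_D·a_D
  ```

  and the per-stage relative activities `a_s` are solved by least squares.
  Combined with library sizes they yield bedGraph scale factors
  `(1/library size)·(a_s/a_ref)` and DESeq2-style size factors;
- **per-gene windowed indices**: pausing index = density(TSS→+250 bp) /
  density(gene body), post-PAS retention index = density(body) /
  density(3′ end→+5 kb), with strand-aware windows, eligibility filters
  (length > 500 bp, 3′ end ≥ 5 kb from neighbouring TSSs), and scaled
  metagene profiles (median of 1000 gene subsamples);
- **fold-change trajectories** (log2 vs the LZ stage, per window) and
  seeded clustering into co-regulated pattern groups (pachytene-burst vs
  steady-state archetypes);
- **permutation interval statistics**: chromosome-preserving,
  non-overlapping shuffles, center-based overlap fractions, empirical
  p-values with add-one smoothing (floor `1/(n_iter+1)`), and a 5-kb
  expanded-window co-occurrence test for the segregation of transcribed
  regulatory elements from DSB hotspots.

A synthetic-data generator (`sim_config()` + `simulate_*()`) plants every
parameter the pipeline estimates, so everything is testable without
external data.

## Worked example

```r
library(meionascent)

cfg <- sim_config(seed = 2, n_chroms = 2, chrom_length = 4e5, n_genes = 16,
                  purity = default_purity(17))
ann    <- simulate_annotation(cfg)
tracks <- simulate_stage_tracks(cfg, ann)
ro     <- simulate_runon_table(cfg)

curve <- fit_standard_curve(ro$standards)
act   <- deconvolve_activities(ro$samples, curve)
act
#> stage_activities:
#>  LZ   P   D
#> 1.0 2.7 1.0
#>   residual norm: 6.474e-16
```

The solver recovers the planted pachytene burst (activity 2.7 relative to
LZ) from the 17 mixed-composition samples. Activities plus library sizes
give normalization factors:

```r
libs <- sapply(tracks, function(tp) library_size(tp$plus) + library_size(tp$minus))
nf <- normalization_factors(libs, act, "LZ")
nf
#>   stage library_size activity activity_ratio    factor size_factor
#> 1    LZ         3437      1.0            1.0 0.0002910        3437
#> 2     P         8235      2.7            2.7 0.0003279        3050
#> 3     D         2974      1.0            1.0 0.0003362        2974
```

Per-gene summaries show the planted pause release (pause/body rate ratios
5, 3, 2 across LZ, P, D):

```r
summaries <- lapply(tracks, summarize_genes, genes = ann$genes)
pit <- pausing_index_table(summaries, ann$genes)
round(tapply(pit$pausing_index, pit$stage, median), 2)
#>   LZ    P    D
#> 4.95 3.13 2.14
```

Transcribed elements sit in accessible chromatin (planted co-location),
while DSB-marker peaks segregate away from them (`segregation = 1`
default): both permutation tests hit the add-one floor at 1000
iterations:

```r
pk <- simulate_peaks(cfg, ann)
overlap_enrichment_test(pk$accessible, pk$tre, ann$chrom_sizes,
                        n_iter = 1000, seed = 3)
#> permutation_result (center_overlap_fraction):
#>   observed = 0.6562, null mean = 0.02678 (n_iter = 1000)
#>   empirical p (greater, add_one) = 0.000999001

cooccurrence_test(pk$accessible, pk$tre, pk$dsb, n_iter = 1000, seed = 3,
                  chrom_sizes = ann$chrom_sizes)
#> permutation_result (cooccurrence_proportion):
#>   observed = 0, null mean = 0.1644 (n_iter = 1000)
#>   empirical p (less, add_one) = 0.000999001
```

`run_pipeline(out_dir, seed = 1)` chains all stages, writes BED/bedGraph/
CSV/TSV/JSON outputs and a checksummed manifest, and is byte-for-byte
reproducible from one master seed. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

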