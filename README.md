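# eqtlsat

Saturation analysis of cis-eQTL detection: how the number, tissue
specificity, and genomic properties of cis expression quantitative
trait loci (cis eQTLs) change with cohort size, and how far the yield
of a larger cohort can be extrapolated.

## What it computes

A cis eQTL is the association between a transcript's expression and a
SNP within ±1 Mb of its transcription start site (TSS); the eQTL is
identified with the transcript and the selected lead SNP is its eSNP.
Given a multi-tissue genotype/expression cohort, the package:

* calls cis eQTLs per tissue with a Kruskal–Wallis rank scan, keeping
  only the smallest-p SNP per 2 Mb window (one lead per transcript),
  with a per-subset MAF > 5% filter and a reporting threshold set by
  permutation to hold the false discovery rate at 10%;
* repeats the scans over 20 nested subsamples with sizes equally spaced
  in `ln(n)` (default 50 → full cohort), in 5 independent replicate
  series;
* classifies each detected transcript into one of 7 tissue-overlap
  classes (`Only A/B/C`, `AB`, `BC`, `CA`, `ABC`) at every step and
  tracks creation / deletion / move-in / move-out flows between
  consecutive steps, plus consecutive and reference overlap fractions at
  both the eQTL and eSNP level;
* fits the scaling law `√q = α + β·ln n` per tissue (`q` = number of
  detected cis eQTLs, `n` = sample size) and extrapolates
  `q(n) = (α + β·ln n)²` to larger cohorts, with sliding-window slopes
  to diagnose which overlap classes saturate.

A synthetic three-tissue cohort generator with known cis architecture
(shared eQTLs stronger and closer to the TSS than tissue-specific ones)
makes the whole pipeline testable without access-controlled data; see
`vignettes/eqtl-saturation-methods.Rmd` for the model, parameter
defaults, and what the generator does and does not emulate.

## Worked example

```r
library(eqtlsat)

cohort <- simulate_cohort(sim_config(seed = 1))   # 400 ind, 2000 SNPs, 300 transcripts
run <- run_pipeline(cohort = cohort, replicates = 1, seed = 1)

subset(run$series$manifest, step %in% c(1, 20))
#>    replicate step   n tissue  q  s  p_threshold
#> 1          1    1  50      A  2  2 1.734885e-05
#> 2          1    1  50      B  8  8 1.042249e-04
#> 3          1    1  50      C  3  3 2.559178e-06
#> 58         1   20 400      A 68 67 3.220079e-04
#> 59         1   20 400      B 77 77 3.533115e-04
#> 60         1   20 400      C 73 72 3.258747e-04

run$fits
#>   tissue replicate      alpha     beta r_squared n_points
#> 1      A         1 -11.623190 3.394698 0.9812278       20
#> 2      B         1  -8.634712 2.969920 0.9581688       20
#> 3      C         1 -10.586375 3.282560 0.9636690       20
```

Detection grows from single digits at n = 50 to ~70 per tissue at
n = 400, and `√q` is linear in `ln n` with R² ≈ 0.96–0.98. Extrapolating
a fitted law, or a published coefficient pair, is one call:

```r
predict_count(c(-85.832, 29.131), 744)
#> [1] 11403
```

The analysis itself is organised as numbered drivers over the package
functions — `analysis/01_simulate_cohort.R` through
`analysis/05_report.R` — each printing what it found and writing its
tables under `results/` (cohort composition, per-step scan tables,
overlap dynamics, scaling fits, summary).

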