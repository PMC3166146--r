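---
title: "Methods: cis-eQTL saturation, tissue-overlap dynamics, and the scaling law"
author: "eqtlsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-eQTL saturation, tissue-overlap dynamics, and the scaling law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

A cis expression quantitative trait locus (cis eQTL) is an association
between a SNP and the expression level of a nearby transcript — here,
a SNP within 1 Mb of the transcription start site (TSS). How many cis
eQTLs a study detects, and how tissue-specific they appear, depends
strongly on cohort size. This package implements the machinery to
measure that dependence: repeated cis-eQTL calling over nested
subsamples of a multi-tissue cohort, classification of detections into
tissue-overlap classes, transition-rate bookkeeping between subsample
steps, and a scaling-law fit that extrapolates eQTL yields to larger
cohorts. Because real genotype/expression cohorts are access-controlled,
the package ships a synthetic cohort generator with a known cis
architecture so the entire pipeline is testable end to end.

## The detection model

For each transcript, tissue, and sample subset:

1. **MAF filter.** SNPs whose minor allele frequency, computed on the
   subset only, does not strictly exceed 5% are removed. The filter is
   recomputed per subset: a SNP testable at n = 400 may be untestable at
   n = 50.
2. **Kruskal–Wallis scan.** Each SNP with position in
   `[tss - 1e6, tss + 1e6]` is tested by the Kruskal–Wallis rank test of
   expression across the genotype groups {0, 1, 2}, with tie correction
   and `df = (#non-empty groups) - 1`. The test is non-parametric, so it
   is insensitive to the expression scale; any monotone transform of
   expression leaves it unchanged.
3. **Lead-SNP selection.** Only the smallest-p SNP in the 2 Mb window is
   retained, so each transcript contributes at most one cis eQTL. The
   eQTL is identified with the *transcript*; the selected SNP is the
   *eSNP*. Ties on p are broken by smaller `|distance to TSS|`, then by
   SNP id, making scans deterministic.
4. **Permutation FDR.** The expression matrix's sample labels are
   shuffled (the same shuffle for all transcripts of a tissue, preserving
   their correlation) and the full scan, lead-SNP selection included, is
   repeated; by default 10 times. For a candidate threshold `p*`,
   `FDR(p*) = (mean permutation count of lead p <= p*) / (observed count
   of lead p <= p*)`. The curve is made monotone by a running maximum
   from the smallest p upward, and the reporting threshold is the largest
   observed p with monotone FDR at most the 10% target; if none
   qualifies the scan reports nothing.

Degenerate inputs are signals, not errors: a constant expression vector
or a window whose SNPs all collapse to one genotype group yields "no
association" (H = 0, p = 1), while a transcript with no SNP in its
window yields no lead at all. Missing genotypes are excluded pairwise
per SNP (a slower per-SNP code path used only when missing values are
present; the vectorised path computes all permutation columns of a
window in a handful of matrix products).

Two readings of the cis definition are possible — a window anchored at
the TSS versus anchored anywhere on the gene body. We anchor at the TSS
(±1 Mb, inclusive), because the eSNP–transcript distance δ is defined
from the start site; the half-width is configurable (`window_bp`).
Whether the MAF rule is `>` or `>=`, and how many permutations to use,
are not pinned down by convention; we use strict `>` (reading "exceed"
literally) and 10 permutations (each permutation scans every transcript,
so even 10 permutations pool thousands of null leads; the threshold is
stable well below Monte-Carlo noise of the counts it gates).

## The subsampling design

Twenty subsample sizes equally spaced in `ln(n)` between 50 and the full
cohort size, `n_i = round(exp(seq(log(50), log(n_max), length = 20)))`,
with exact endpoints; collisions after rounding are an error rather than
silently merged steps. Subsets are nested, built as prefixes of one
seeded permutation — distributionally identical to repeatedly deleting a
random set of individuals from the full cohort, and reproducible from
one integer. The whole series is repeated over 5 independent nested
series (replicates) of the same cohort; every randomness source derives
a sub-seed deterministically from one master seed, so a run is
bit-reproducible.

## Overlap classes and their dynamics

With tissues A, B, C, every transcript detected at a step falls in
exactly one of seven classes: `ONLY_A`, `ONLY_B`, `ONLY_C`, `AB`, `BC`,
`CA`, `ABC`. Between consecutive steps we count, per class: *creation*
(detected in the class, previously undetected everywhere), *deletion*
(previously in the class, now undetected everywhere), *move-out* and
*move-in* (still detected but in a different class). Counts are also
normalised by the change in sample size. These four flows satisfy an
exact bookkeeping identity,

```
count_X(i) = count_X(i-1) + creation_X + move_in_X - deletion_X - move_out_X,
```

which the tests verify at every step of real pipeline output — it is the
invariant that guards the classification code.

Overlap fractions between detection sets use the earlier (smaller) step
as denominator for consecutive steps, and both directions against the
largest subsample as reference (`forward` = share of a step's
detections present in the reference; `backward` = share of the
reference already found at that step). The same operations are applied
at the eSNP level, where identity is the lead SNP id — deliberately
fragile, since correlated SNPs trade places as leads when samples are
added; comparing eQTL-level to eSNP-level overlap quantifies that
instability. Distance/strength contrasts between classes use the
two-sided Mann–Whitney test (exact for combined sizes up to 12, normal
approximation with tie correction beyond; rank-based, hence invariant
under the log transform often applied to distances).

## The scaling law

Per tissue, ordinary least squares of `sqrt(q_i)` on `ln(n_i)` over the
20 steps gives `sqrt(q) = alpha + beta ln n`, i.e.
`q(n) = (alpha + beta ln n)^2`, and the fit is extrapolated by
evaluating the squared linear predictor at a larger n (reported rounded
half-up; requesting an n below the root of the linear predictor is an
error, not a zero). The square-root transform is pinned down
empirically: evaluating `(alpha + beta ln n)^2` with published
per-tissue coefficient tables at each tissue's full sample size
reproduces the published extrapolated counts to within one count
(rounding of three-decimal coefficients), whereas linear, log-log, and
exponential alternatives are off by orders of magnitude — the unit tests
re-verify this derivation. R² is computed as `1 - RSS/TSS` with a
constant series defined to have R² = 0. Saturation of individual class
series is diagnosed by the OLS slope within sliding windows of 10 or 15
consecutive steps: a falling slope means the class is exhausting its
pool, a rising slope means detection is still accelerating. Fits are
reported per replicate (mean ± sd across the 5 series) as well as pooled.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
at desk scale:

* **Genotypes.** One synthetic chromosome (default 50 Mb, 2,000 SNPs);
  per-SNP population allele frequency uniform on `[0.05, 0.5]`; two
  haplotypes per individual from a first-order allele-copy process in
  which each haplotype copies the previous SNP's allele with probability
  `ld_rho` (default 0.5). This is not a coalescent: it produces the
  short-range correlation needed to exercise lead-SNP instability and
  the MAF filter, nothing more.
* **Architecture.** Each of 300 transcripts draws one of eight patterns
  (probabilities: none 0.30, onlyA 0.14, onlyB 0.13, onlyC 0.13,
  AB 0.07, BC 0.04, CA 0.04, ABC 0.15 — tissues A and B are the related
  pair, sharing more than either does with C). Effect magnitudes are
  log-normal, `|b| ~ LogNormal(ln 0.25, 0.6)`, multiplied by 1.5 for
  patterns covering two or more tissues; the heavy right tail is what
  makes detections accrue gradually over n in [50, 400] and produces the
  near-linear `sqrt(q)` vs `ln(n)` behaviour the fit measures. Shared
  causal SNPs sit near an Exponential(mean 100 kb) distance from the
  TSS; tissue-specific ones are uniform over the ±1 Mb window. One sign
  and magnitude is shared across the pattern's tissues.
* **Expression.** `y = b * g + e`, Gaussian noise with unit standard
  deviation, independent across tissues — so a median effect explains
  about 2% of expression variance, and power grows from weak at n = 50
  to moderate at n = 400.

What the generator does **not** emulate: realistic LD maps and
population structure, covariates (age, sex, batch), array-normalisation
artifacts, polygenic trans effects, or correlated noise between the
tissues of one individual. Passing tests therefore demonstrate that the
pipeline measures what it claims on data with known truth — not that any
particular biological cohort will show the same numbers.

## Problem sizes and numerical choices

The default study design — 400 individuals, 2,000 SNPs, 300 transcripts,
20 steps, 10 permutations, one to five replicates — was chosen so a full
single-replicate run takes well under a minute on one core while leaving
every windowed scan with ~80 candidate SNPs and the smallest subsample
with single-digit to low-double-digit detections per tissue. That bottom
end is a real scale limitation: class percentages at n = 50 rest on
very few detections and are noisy, which is why the package reports the
specificity trend both per tissue and pooled over tissues, and why the
replicate-averaged view is the one to read. On this design the
per-tissue fit quality is R² ≈ 0.94–0.99, and the directional findings
are reproduced: the all-tissue class keeps accelerating while specific
classes plateau; shared eQTLs are markedly closer to the TSS and more
strongly associated; essentially all creations enter through the
tissue-specific classes; and the overall tissue-specific share of
detections falls as the cohort grows.

```{r example}
library(eqtlsat)
cohort <- simulate_cohort(sim_config(seed = 1))
run <- run_pipeline(cohort = cohort, replicates = 1, seed = 1,
                    out_dir = "results/run")
run$fits
report_summary("results/run")
```

## Known limitations

* Single chromosome; multi-chromosome cohorts would only require a
  per-chromosome position offset, since the cis logic uses positions
  alone.
* The permutation FDR pools lead p-values across transcripts (one
  threshold per scan), rather than estimating a per-transcript null.
* No covariate adjustment and no trans-eQTL scan, by design.
* Extrapolations carry no confidence intervals; the law is an empirical
  fit over the observed range and extrapolation beyond it inherits all
  the usual risks.
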