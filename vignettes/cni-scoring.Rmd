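---
title: "Copy number instability scoring from shallow-coverage cfDNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number instability scoring from shallow-coverage cfDNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cniscore)
```

## The problem

Most solid tumors — and essentially all high-grade serous ovarian
cancers — are chromosomally unstable: their genomes carry segmental gains
and losses rather than a small set of recurrent point mutations. When
tumor cells die, fragments of their DNA circulate in plasma alongside the
much larger pool of cfDNA from normal hematopoietic turnover. At a tumor
fraction $f$, a genomic segment present at total copy number $c$ in the
tumor shifts the expected sequencing coverage of that segment by the
admixture factor

$$\frac{2(1-f) + c f}{2},$$

i.e. an expected log2 ratio of $\log_2\!\big(1 + f(c-2)/2\big)$. Even at
$f \approx 0.05$–$0.1$ these shifts are detectable in very cheap,
low-coverage whole-genome sequencing if coverage is aggregated over
megabase-scale windows and compared against a well-characterized panel of
normals. The CNI-Score condenses a whole genome of such comparisons into
one non-negative number proportional to the circulating tumor DNA burden,
usable for detection and for treatment monitoring without any a priori
knowledge of the tumor's genotype.

## The pipeline

1. **Short-fragment counting.** Fragments with insert size strictly
   below 170 bp are kept — tumor-derived cfDNA is shorter than the
   mononucleosomal background, so this filter enriches the signal — and
   counted into fixed 0.55 Mbp autosomal windows by fragment *midpoint*.
   Midpoint assignment counts each fragment exactly once; whether the
   original assay used midpoint, start, or overlap assignment is not
   published, so midpoint is this package's stated convention. Fragments
   falling outside every window are tallied as unassigned, preserving the
   invariant assigned + unassigned = input.
2. **Bias correction.** Per sample, counts are divided by a locally
   weighted (lowess) fit of count on GC fraction over usable windows,
   then by a lowess fit on mappability, and rescaled so the sample median
   is 1. The two sequential 1-D fits are a deliberate simplification of
   two-dimensional bin-correction schemes: they are transparent, fast,
   and sufficient because the Z-scoring step only requires that panel and
   test samples be corrected identically. The median rescale makes the
   output invariant to sequencing depth. Windows failing the fit (or
   below the mappability threshold) are masked as `NA`, never dropped, so
   window indices stay aligned across samples and with the panel.
3. **Log2 and condensation.** Corrected values are log2-transformed
   (zeros masked, not $-\infty$) and groups of 10 small windows are
   averaged into ~5.5 Mbp condensed windows — 701 in the default
   geometry. A condensed window is masked when more than half its members
   are masked. Averaging after the log transform keeps condensation
   linear: shifting all inputs by $\delta$ shifts all outputs by
   $\delta$.
4. **Z-scores and the score.** Each condensed window is standardized
   against the per-window mean and $(n-1)$ SD of the panel of normals
   (137 samples by default). Windows with $|z| > 2.84$ (strict) are
   significant; the CNI-Score is $\sum |z|$ over them. Both the 2.84
   threshold and the classification cut-off of 24 use strict
   inequalities; 2.84 is used literally (it is the conventional printed
   rounding of $2\sqrt{2} = 2.8284\ldots$, and the two differ by less
   than half a percent of the threshold).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `small_window_bp` | 550,000 | bp | small-window width |
| `condense_factor` | 10 | windows | small windows per final window |
| `max_length_exclusive` | 170 | bp | strict insert-size filter |
| `mapq_min` | 30 | — | alignment quality floor (BAM input) |
| `loess_span` | 0.3 | fraction | lowess smoother span |
| `min_mappability` | 0 | fraction | windows below are masked |
| `sd_floor` | 1e-6 | log2 units | lower bound on panel SD |
| `z_crit` | 2.84 | SD | significance threshold |
| `cutoff` | 24 | score | positive/negative call |

The smoother span and mappability threshold of the accredited clinical
assay are unpublished; both are plain configuration parameters here. The
SD floor only matters for degenerate (e.g. duplicated) panels, where it
prevents division by zero at the cost of inflated Z-scores in those
windows — a warning reports how many windows were floored.

## The synthetic-data generator

No sequencing data accompany the study design this package implements, so
the generator is a first-class module that produces data with the
statistical structure the pipeline assumes:

- **Geometry.** 7010 small windows on 22 pseudo-autosomes, laid out so
  every chromosome holds a whole number of condensed groups (19
  chromosomes of 32 groups, 3 of 31), giving exactly 701 condensed
  windows with no trimming. Real genome coordinates are deliberately not
  used: no tested property depends on them.
- **Counts.** Negative-binomial per window with
  $\mathrm{Var} = \mu + \mu^2 d$, $d = 0.002$, the standard
  overdispersed model for shallow-WGS bin counts; mean 1800 per small
  window (~18,000 per condensed bin). The expected count is
  $\mu_w = 1800 \cdot \mathrm{bias}(\mathrm{gc}_w) \cdot
  \mathrm{map}_w \cdot \big(2(1-f)+c_w f\big)/2$, where the GC bias is a
  smooth unimodal curve of amplitude 0.3 known to the simulator but
  never to the pipeline — bias removal is therefore a genuine test.
- **Fragment lengths.** A two-mode mixture
  $(1-f)\,N(167,10) + f\,N(145,12)$ truncated to [50, 400] bp: the
  mononucleosomal peak and the shorter ctDNA mode. The mode locations
  are field-standard values, configurable; the study this models only
  established that shorter fragments accompany higher scores.
- **Seeds.** One master seed; panel sample $i$ uses seed $+i$, cohort
  sample $j$ uses seed $+10000+j$ for counts and $+20000+j$ for fragment
  lengths, so any single sample regenerates independently.

What the generator does *not* emulate: batch effects and inter-run
technical variance, inter-individual germline copy-number variation,
subclonal heterogeneity beyond a single tumor fraction, sex chromosomes,
and real hg19 window geometry (the published 701 windows arise from a
proprietary reference grid and blacklist; here 701 is a property of the
synthetic layout and fully configurable). Passing tests therefore
demonstrate correctness of the computation and sensitivity under an
idealized noise model, not clinical performance on real plasma.

## Null calibration: a subtlety

For 701 independent standard-normal window Z-scores the expected score is
$701 \cdot 2\varphi(2.84) \approx 9.9$ with median $\approx 9.3$ — the
classical calibration for a tumor-free sample, which the acceptance
script reproduces. The full pipeline's null scores run slightly higher:
a Z-score computed against a mean and SD *estimated* from $n$ panel
samples is distributed $\sqrt{1+1/n}\; t_{n-1}$ under the null, not
$N(0,1)$, which at $n = 137$ inflates the two-sided tail beyond 2.84
from 0.45% to about 0.53% and the null median from ~9 to ~12. The
pipeline test suite therefore checks simulated null scores against the
exact analytic oracle for $\sqrt{1+1/137}\,t_{136}$ (a numeric tail
integral), not against the iid-normal value. In practice the effect is
immaterial for classification: the null distribution still sits far
below tumor-level scores, and cut-offs are in any case calibrated on
control cohorts.

## Numerical and design choices

- Strict inequalities at every threshold (170 bp, $|z| > 2.84$,
  score > cut-off, $\pm 0.3$ tissue log2 thresholds), with boundary
  behavior pinned by tests.
- ROC thresholds are midpoints between consecutive distinct pooled
  scores plus $\mp\infty$ sentinels; AUC is the trapezoidal area, which
  equals the Mann–Whitney probability with ties counted 0.5. The
  Youden-optimal threshold breaks ties toward the lowest threshold,
  favoring sensitivity.
- Rank-sum p-values are exact (enumeration) when both groups have at
  most 8 untied observations, otherwise normal approximation with
  continuity and tie correction.
- The sample-size calculation inverts the exact noncentral-t power
  function by upward search — with the default design (detect a mean
  difference of 2 at SD 4, one-sided $\alpha = 0.01$, power 0.95) the
  minimum is 66 — and is cross-checked against a 100,000-replicate
  Monte-Carlo oracle in the test suite.
- Percentages are rounded (half away from zero) only at presentation;
  all stored sensitivities/specificities are exact fractions.
- The 120–150 bp short-fragment area uses a closed interval at both
  ends, and no smoothing is applied to length histograms before
  integration.

## Problem sizes in the test suite

The suite simulates at the full study geometry where the property being
checked depends on it — a 137-sample panel over 7010 windows, 241
simulated controls against 23 tumor samples at tumor fractions 0.1–0.4
for the sensitivity-at-95%-specificity check, 10,000 null replicates for
the score calibration, and 100,000 Monte-Carlo replicates for the power
oracle — and uses smaller flat-annotation systems (60–600 windows, 20
normals) for unit-level oracles where closed forms are available.

## Known limitations

- Sensitivity claims from simulation are upper bounds: real plasma adds
  batch variance, germline CNVs, and mappability artifacts that widen
  the null distribution.
- The pipeline estimates no tumor fraction; the score is proportional to
  ctDNA burden only through the panel-referenced Z-scale.
- Segmentation (e.g. CBS) is intentionally absent: the score is defined
  on fixed windows, and adding segmentation would change its null
  calibration.
- Frequency tracks treat samples as exchangeable; no recurrence
  significance model (GISTIC-style) is provided.
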