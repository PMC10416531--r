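---
title: "Methods: methylation quantification, synthetic assay model and clock calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation quantification, synthetic assay model and clock calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclocks)
library(dplyr)
```

## The problem

Targeted bisulfite sequencing measures DNA methylation at a predefined
panel of CG/CA cytosines: after bisulfite conversion, unmethylated
cytosines read as T (or A on the opposite strand) while methylated
cytosines remain C (or G). The per-site methylation level is the *beta
value*,

$$\beta = \frac{n_\text{meth}}{n_\text{meth} + n_\text{unmeth}},$$

the fraction of methylated read calls among all reads covering the site.
A panel of 161 such sites covers the markers of four epigenetic
estimators of aging-related parameters — two chronological-age clocks (a
71-CpG Hannum-style clock and a compact 6-CpG forensic blood-age model
drawn from a 44-CpG panel), a 46-CpG pace-of-aging score, and a 10-CpG
mortality risk score — with 9 markers shared between the two age-clock
panels and 1 between the pace-of-aging and mortality panels
(71 + 44 + 46 + 10 − 9 − 1 = 161).

This package implements the full downstream workflow from per-site read
counts: strand-merged beta calling with read-depth thresholding,
bisulfite-conversion QC, linear-clock prediction with mean imputation,
cross-technology calibration of clock outputs, and the assay-performance
statistics (sensitivity, repeatability, accuracy against methylation
standards, cross-method agreement, age-prediction error). Raw sequencing
data for the original assays are not publicly deposited, so a synthetic
generator reproduces the statistical structure of the study designs and
supplies exact truth tables for every generated quantity.

## Beta calling

Counts arrive per (sample, marker, strand). CpG methylation is
symmetric, so Watson and Crick counts for a marker are **summed before**
the ratio is taken (`merge_strands()`); markers assayable on a single
strand pass through unchanged. Two deliberately different comparators
are used:

* a site is **called** when its merged total is **at least** `min_reads`
  (default 50), i.e. "fewer than 50 reads" means missing data;
* coverage summaries report the fraction of markers covered by **more
  than** each threshold (50/200/1000 by default), mirroring the
  "covered more than 200×" convention of coverage reporting.

Missing calls stay missing in the beta matrix (empty cells in the TSV):
quantification never imputes. Imputation happens only inside the clock
engine, where it is the documented convention of the published
calculators. Beta values are stored at full precision; two-decimal
rounding is applied only in reports.

Conversion QC has two routes, matching how the two assay families
measure it: unmethylated **lambda spike-in** amplicons, where any
methylated call is a conversion failure (amplicons are pooled by summing
counts — at equal depths this equals per-amplicon averaging, and the
choice is tested); and **non-CpG cytosines** within targets for capture
protocols. Rates are reported as percentages on 0–100.

Bismark-style cytosine coverage files are supported at the boundary:
counts are taken from columns 5–6 and the percentage column is always
recomputed, never trusted. One deliberate discrepancy is documented
here: the "expected" normalised-depth reference line is computed as
1/(number of targets); published figures use slightly different
constants (0.00065 and 0.00060) whose denominator is not stated, and we
do not attempt to reverse-engineer it.

## The synthetic assay model

No generative model for assay noise is published; the generator's model
is the package's own and is deliberately minimal. A read at a site with
true methylation $\beta$ is called methylated with probability

$$p = \beta\,(1 - f) + (1 - \beta)\,(1 - c),$$

with two independent error channels: $c$, the bisulfite conversion rate
(default 0.998, the scale measured on lambda DNA), and $f$, the rate at
which methylated cytosines are inappropriately converted (default
0.005). Two channels are kept distinct because conversion QC measures
only the failure-to-convert channel. Counts are binomial given depth;
per-target depth is log-normal (`coverage_mu = log(3000)`,
`coverage_sigma = 1`), giving the heavy right tail seen in amplicon
coverage distributions with median ≈ 3000 reads. For both-strand markers
reads are split binomially (default 0.5) and the strands sampled
independently. All randomness flows through R's default Mersenne-Twister
stream seeded from `sim_config(seed=)`; a fixed seed reproduces count
tables bit-identically, and every run manifest records the seed and a
configuration hash.

Three presets mirror the study designs: seven methylation standards (0,
0.10, 0.25, 0.50, 0.75, 0.90, 1) in duplicate (14 libraries); a
sensitivity ladder of two levels across four DNA inputs in duplicate (16
libraries), where depth scales proportionally with input mass so smaller
inputs are noisier; and five blood donors aged 7, 28, 46, 61, 78 in
duplicate (10 libraries; mean age 44.0, sample SD 26.1 with the n−1
convention).

**Blood cohorts invert the generating clock.** For a linear clock with
weights $w_i$ and intercept, per-marker true betas are constructed as
$\beta_i(a) = m_i + w_i k (a - a_0)$ with $k = 1/\sum_i w_i^2$ and
baselines $m_i$ shifted so the clock evaluates exactly to the reference
age $a_0$ at baseline. Then the clock applied to noise-free betas
returns each donor's age *exactly*, so age-recovery tests have known
ground truth. Betas are clamped to [0.01, 0.99] and construction fails
loudly if clamping perturbs the round-trip by more than 0.1 years — this
is why the fixture clocks use weight magnitudes large enough (ladders of
1.5–3 for the 71-marker clock, 28–38 for the 6-marker clock) that the
ages 7–78 stay inside the feasible beta range. Markers outside the
generating clock receive fixed per-marker baselines drawn once from
U(0.2, 0.8). Optional Gaussian beta-scale noise (`noise_sd`) is added
per sample and marker before read sampling.

An optional **platform bias** distorts sampling betas through an affine
transform with clamping; the default array-like bias in examples,
$\beta' = 0.1 + 0.8\beta$, compresses values toward mid-range — the
direction microarrays are reported to err in (over-methylation calls at
low and under-methylation at high levels) — with an average offset of
about 0.1 at the extremes. The truth table always retains both the true
and the biased beta.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: amplicon dropout genetics, PCR duplicates and
amplification bias, read-level base-call errors, alignment artefacts,
probe cross-hybridisation, and any marker-specific biological
covariance. Tests on synthetic data validate the *pipeline arithmetic
and its statistical behaviour under the stated model*, not assay
chemistry.

## Clock engine

All four estimators share one linear form,
$v = \text{intercept} + \sum_i w_i \beta_i$, differing in coefficients
and units (years; pace-of-aging units where 1.0 ≈ one physiological year
per calendar year; mortality-score units). Missing markers are filled by
**mean imputation** from a per-model means table before prediction —
observed values are never altered, imputation is idempotent, and the
count of imputed markers is carried through to the outputs. Markers
absent from a platform go through the same path with no special-casing.

The categorical mortality risk score is exposed through two routes,
since the published description does not fix one: (i) per-marker
thresholding — one risk point per marker whose beta lies strictly on its
risk side (ties are not risk); and (ii) a quadratic mapping from the
calibrated continuous score (`mrs_cat_hts`), rounded and clamped to
0–10. The shipped threshold rule (threshold = imputation mean, direction
= sign of the continuous weight) is a fixture default. Scores interpret
as relative all-cause mortality risk: 0 reference, 1 two-fold, 2–5
three-fold, above 5 seven-fold.

The real published coefficient sets are not redistributed here: they are
external plug-ins loaded from TSV (`load_clock_model()`). The shipped
fixture clocks are clearly labelled synthetic; they preserve the marker
counts and overlap structure (71/6-of-44/46/10) so every test runs
offline, and their imputation means are likewise synthetic.

## Calibration

Predictors trained on microarray data show a systematic affine bias when
applied to sequencing-derived betas (on the order of 10% between the two
families). Correction is a degree-1 or degree-2 polynomial acting on
**clock outputs, never on betas** (all published correction equations
act on prediction outputs). Fitting is plain OLS via `stats::lm` —
deliberately not errors-in-variables, although both axes carry error,
because that matches how the shipped default equations were derived.
Six published equations ship as constants in `builtin_transforms()`
(they were derived on an extended donor set that is not distributed, so
they cannot be re-derived here):

| name | equation |
|---|---|
| `hannum_hts` | 0.64 + 0.89 x |
| `hannum_epic` | −5.16 + 1.10 x |
| `visage_ampliseq` | −1.61 + 0.93 x |
| `poam_hts` | 0.23 + 0.72 x |
| `mrs_cont_hts` | −1.72 + 0.61 x |
| `mrs_cat_hts` | 25.76 + 13.29 x + 1.81 x² |

Worked examples used in tests: the pace-of-aging transform maps a raw
1.11 to 1.0292 (1.03 at two decimals); the continuous mortality-score
transform maps −1.12 to −2.4032 (−2.40).

## Evaluation statistics

All dispersion statistics use the n−1 denominator (validated against the
duplicated-cohort age SD: ages 7, 28, 46, 61, 78 in duplicate give
44.0 ± 26.1). Missing cells are handled **pairwise-complete** — a
(pair, marker) cell is dropped when either side is missing, never
imputed — because these metrics describe measured values only. Every
summary carries the number of cells used, so scaled-down syntheses
remain comparable.

* `replicate_mad()`: mean ± SD of |β₁ − β₂| pooled over pairs and markers.
* `accuracy_vs_expected()`: pooled mean ± SD of |observed − expected| on
  standards.
* `sensitivity_summary()`: grouped mean ± SD per (input, level).
* `level_variability()`: per-level SD, per-marker-then-averaged by
  default with `pooled = TRUE` exposed, since the published "mean
  standard deviations" do not state which was used.
* `method_correlation()`: Spearman as the product-moment correlation of
  mid-ranks (tie handling is not stated in the source; mid-ranks are the
  standard choice and are what `stats::cor(method = "spearman")`
  computes — tests verify against an explicit rank-then-correlate
  oracle), plus pairwise mean |Δβ|.
* `mae_age()`, `clock_cross_correlation()`: age-prediction error and
  between-clock correlations, with a small-sample caveat below N = 10.

A binomial-noise expectation anchors the accuracy statistic: at depth
$n$ the expected absolute deviation is
$\sqrt{2/\pi}\,\sqrt{\beta(1-\beta)/n}$, so simulated standards at depth
10⁴ must come in well under 0.02.

## Numerical choices and degenerate inputs

* Threshold boundary: total exactly equal to `min_reads` passes.
* Zero depth: beta missing; lambda conversion rate missing (never 0/0).
* Clamping: platform bias and blood-cohort construction clamp betas into
  [0, 1] / [0.01, 0.99]; the cohort constructor errors rather than
  silently degrading the round-trip.
* Constant predictor in calibration fitting is an error (slope
  unidentifiable); constant clock columns in correlation matrices give
  NA entries, not errors.
* MRS thresholding uses strict inequalities; a beta exactly at threshold
  is not a risk point.
* Tie-breaks in Spearman use mid-ranks.
* The FNV-1a configuration hash in manifests identifies runs; it is not
  cryptographic.

## Problem sizes

The shipped tests and the acceptance script run the three study-design
presets at their natural sizes (14 + 16 + 10 libraries over the
161-marker panel) and use a reduced 13-marker panel with a 6-marker
clock for Monte-Carlo properties (20-seed loops for noise monotonicity,
input-sensitivity and calibration-improvement checks; 24-donor cohorts
for calibration splits; depths 10³–10⁵ where a binomial standard error
is the yardstick). These sizes were chosen to make the statistical
assertions sharp (3×SE bounds) while keeping the whole suite fast enough
to run routinely.

## Known limitations

* The binomial two-channel error model understates real assay
  dispersion (no overdispersion term); accuracy statistics on synthetic
  data are therefore optimistic relative to published real-data values,
  and no test asserts those real-data values.
* OLS calibration ignores error in the predictor axis.
* The fixture panel's genomic coordinates are placeholders; anything
  needing real loci (liftover, primer context) is out of scope.
* Replicates are assumed exchangeable; flowcell/chip batch structure is
  not modelled.
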