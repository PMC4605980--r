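---
title: "Methods: fingerprinting Ficoll-contaminated plasma NMR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting Ficoll-contaminated plasma NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ficollnmr)
```

## The problem

Plasma separated on a Ficoll density gradient — routine for biobanked
blood collected for lymphocyte work — is contaminated by the polymer: a
broad, intense absorption between 3.30 and 4.64 ppm centred at
3.80 ppm, plus sharp lines at 1.81, 1.84, 2.26, 5.42 and 5.58 ppm.
Because Ficoll's internal dynamics defeat relaxation-based filtering,
even CPMG spin-echo spectra retain these signals, and the contaminated
central region (which also holds the residual water signal and many
metabolites, glucose among them) must simply be excluded from analysis.
This package implements the resulting pipeline: spectral processing
with contaminated-region exclusion, PLS-based classification under
Monte-Carlo cross-validation, multilevel PLS for paired
pre/post-anesthesia contrasts, and Wilcoxon / Benjamini–Hochberg /
fold-change univariate statistics — plus a synthetic-cohort generator
that stands in for the real contaminated spectra.

## Processing model

FIDs are apodized with `exp(-pi * lb * t)` (`lb` in Hz, default 1.0 —
the conventional plasma-profiling choice; an `lb`-Hz exponential adds
exactly `lb` Hz to a Lorentzian line's FWHM) and Fourier transformed;
the real part is returned on the ppm axis carried by the FID metadata.
`synthesize_fid()` is the exact inverse at `lb = 0`, which gives the
processing stage a machine-precision round-trip test. The total
spectral sum is conserved under apodization exactly (the first FID
point is unscaled), so integral conservation is asserted on the
periodic-domain integral (sum × grid step), not the open trapezoid,
whose edge terms differ once broadening redistributes the tails.

Calibration targets the glucose anomeric doublet at δ 5.24. The locator
is doublet-aware: within the search window (default ± 0.05 ppm) it takes
the intensity-weighted centroid of the two tallest strict local maxima
above a noise floor (median of the window plus five robust standard
deviations of the whole trace), falling back to the single tallest.
The whole axis is shifted rigidly; intensities are untouched; the
operation is idempotent. A flat or empty window raises a
`calibration_failure` condition rather than silently shifting.

Bucketing divides [low, high) — default 0.20–10.00 ppm — into
`round((high - low)/width)` left-closed right-open bins (default width
0.02 ppm, hence 490 bins) and integrates each by the trapezoidal rule
on the native grid, linearly interpolating intensity at bin edges. With
that convention the bins are exactly additive: they sum to the
trapezoidal integral over the full range to rounding error, and the
flat-spectrum bin value is exactly `c × width`.

Exclusion removes bins whose *centre* lies strictly inside any
`(low, high)` interval; the default (3.30, 6.00) ppm removes 135 of the
490 bins, leaving 355. Bin membership by centre with half-open edges is
an arbitrary but unambiguous convention; the brute-force edge
enumeration in the test suite pins it down. The lower bound is
configurable because the literature quotes both 3.30 and 3.33 ppm for
this window; the default follows the processing convention (3.30).

Total-area normalization divides each retained bucket vector by its
sum; it is scale-invariant and idempotent, and an all-zero or
negative-sum row raises `normalization_failure`. No probabilistic
quotient normalization or segment alignment is offered — the pipeline
deliberately mirrors total-area-only practice.

## Chemometrics

`plsca()` fits NIPALS PLS2 against the centred one-hot class response
(mean-centring only, no unit-variance scaling — bucket tables are
already on one scale after total-area normalization; scaling is a
config switch away in spirit but deliberately not default). A Fisher
linear discriminant is then fit on the latent scores, with directions
scaled so the pooled within-class covariance is the identity; nearest
class mean in that canonical space is the Mahalanobis rule.
`coef()` maps the canonical directions back to bins, giving the loading
ranking used for marker recovery. A small ridge (1e-8 of the mean
within-class variance) keeps the discriminant defined when scores are
nearly collinear.

The number of latent components is selected, by default, by stratified
5-fold cross-validation over 1–10 components *inside each training
set*, exploiting the nestedness of NIPALS components (one fit at the
maximum, truncated evaluations); ties go to the smaller count. A fixed
`ncomp` overrides selection — the package's own analyses use `ncomp = 3`
for speed and stability at the simulated problem sizes.

`monte_carlo_cv()` repeats stratified random splits (default 10% test,
500 iterations) and pools one confusion matrix; accuracy, sensitivity
and specificity follow the standard 2×2 definitions, in percent, with
the positive class explicit (lexicographically first by default) and
zero-denominator rates reported as `NA`, never as 0.

For paired designs, `multilevel_split()` decomposes each row into its
subject mean (between part) and the residual (within part). The
algebra is exact: the two rows of a pair are negatives of each other,
and between + within reconstructs the data to floating-point error.
`mpls()` is PLS-CA on the within part with timepoint labels. In
cross-validation the resampling unit is the subject, so a subject's
pre/post pair never straddles the train/test boundary — row-level
resampling would leak the pair structure and inflate accuracy.

### Chance-level estimation

The chance-level control pools 20 random label permutations × 25
Monte-Carlo splits rather than using one permutation for all 500
iterations. A single fixed permutation of 40 samples in 355 correlated
bins can align by chance with latent cohort structure (per-subject
Ficoll intensity, between-subject variability) and yield held-out
accuracy well away from 50% — that is a genuine property of the fixed
labelling, not a leak. Averaging across permutations estimates the
permutation-null mean, which is the quantity the 50 ± 5% band refers
to.

## Univariate statistics

Rank-sum p-values are exact (enumeration) when the combined sample size
is at most 12 with no ties, otherwise normal approximation with
midranks, tie correction and continuity correction — the
continuity-corrected p tracks exact enumeration to within about 0.01 at
n = m = 10, where the uncorrected statistic can miss by three times
that. Signed-rank p-values drop zero differences (classic convention;
the count is reported), enumerate all `2^n` sign patterns for up to 12
nonzero differences — midranks make tied magnitudes exact too — and
use the corrected normal approximation beyond. All-zero differences
return a degenerate marker with p = 1.

Benjamini–Hochberg adjustment is the standard step-up formula applied
to the whole metabolite family of one contrast; significance is called
on the adjusted p at α = 0.05. The fold change is reported as
`-log2(median_A / median_B)` with groups A and B named in the output
metadata and a plain-language `direction` column, because the two
possible reading conventions of a signed fold change are easily
confused; the value is exactly antisymmetric under group swap, and
non-positive medians yield an explicit undefined marker.

## The synthetic cohort generator

The generator is the package's stand-in for the study's contaminated
plasma spectra and defines the conditions under which the pipeline is
validated:

* **Metabolite library** — 20 named small-molecule signal groups
  (lactate, alanine, branched-chain amino acids, glucose, citrate,
  aromatic amino acids, formate, …) as Lorentzian lines at their
  familiar plasma shifts, with a small seed-determined position jitter
  (sd 0.002 ppm) emulating referencing variability. About two-thirds
  of the peaks lie outside the excluded window; glucose does not,
  which is faithful — its resolved signals sit in the contaminated
  region, and its 5.24-ppm doublet serves calibration only.
* **Concentrations** — per-metabolite truth = baseline × group effect ×
  log-normal subject factor (default sd 0.15, a typical between-subject
  coefficient of variation) × anesthesia decrease (default 0.85 on all
  metabolites in post samples: a general moderate slowdown) — all
  multiplicative, keeping concentrations positive.
* **Spectral components** — macromolecular baseline (broad Gaussians at
  lipoprotein positions), residual water at 4.70 ppm, Ficoll
  contamination with per-*subject* log-normal intensity (sd 0.3; the
  batch-to-batch variability is not quantified anywhere, so this is a
  one-time realism choice), and sharp drug peaks present only in post
  samples, two of the three outside the excluded window.
* **Acquisition** — NOESY keeps small molecules and macromolecules at
  weight 1/1; CPMG attenuates macromolecules to 0.2; diffusion editing
  attenuates small molecules to 0.1; contaminant and drug components
  always carry weight 1 (no sequence filters Ficoll). The weights are
  qualitative stand-ins — actual attenuation is instrument physics and
  out of scope.
* **Noise** — additive Gaussian on intensities (default sd 0.01 against
  peak heights of order 0.3–2), the standard abstraction at this level.
* **Grid** — 0.00–10.20 ppm; 16,384 points by default, 8,192 in most
  tests (resolution is not the binding constraint at 0.02-ppm buckets).

The same design plus seed reproduces a cohort bit for bit. What the
generator does *not* emulate: phase and baseline errors, shimming
artifacts, ¹³C satellites, peak-position dependence on pH/ionic
strength, and the hundreds of minor overlapping signals of real plasma.
The last point matters for interpreting tests: real retained spectral
area is spread over many more signals, so compositional effects of any
single metabolite are smaller in real data than here (see below).

## Known limitations

**Compositional closure.** Total-area normalization imposes a
constant-sum constraint: if three metabolites double in one group,
every other normalized intensity in that group falls by several
percent. On these synthetic cohorts (20 signal groups, so each
metabolite is a relatively large share of the retained area) that
closure shift is detectable at n = 20/group and produces correlated
false positives in the spectral-quantification route. This is a
property of the method, not a bug — it is present in any total-area-
normalized analysis — and it is why the screening validation operates
on concentration tables with known truth, while
quantification-vs-truth agreement is verified separately on resolved,
isolated signals.

**Peak overlap.** Resolved-signal integration cannot separate
genuinely overlapping signals; the classic case here is threonine's
1.32-ppm doublet under lactate's 1.33-ppm methyl signal, which makes
threonine co-vary with lactate in quantification output. Quantification
regions are user-configurable for precisely this reason.

**Exact-set recovery under FDR control.** Benjamini–Hochberg at
α = 0.05 controls the *expected* false-discovery proportion, not the
probability of zero false flags. With three strong discoveries among
20 metabolites, the expected number of false flags per screen is about
0.15 — comfortably below 1 — but the probability that a screen flags
*exactly* the true set is correspondingly about 0.87, so any
requirement that 90% of replicates achieve exact-set recovery sits
above what the procedure can deliver by construction. The test suite
asserts both views and documents the tension rather than relaxing the
threshold.

**Calibration.** The doublet-aware centroid assumes the reference
doublet is the dominant feature in its search window; heavy overlap
inside the window would bias the centroid. Calibration is optional and
windowed tightly by default.

## Problem sizes

The package's own validation uses cohorts of 20 subjects per group
(40–80 samples), 8,192-point spectra, 490/355-bin bucket tables,
100–500 Monte-Carlo iterations, 50 screening replicates and 200
null-FDR replicates — sizes chosen so the whole suite and the
acceptance script each run in well under a minute on a single core
while keeping every Monte-Carlo standard error far below the asserted
margins.
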