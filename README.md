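# ficollnmr

Statistical fingerprinting of ¹H-NMR plasma spectra contaminated by
Ficoll, the density-gradient medium used to separate lymphocytes from
blood. Plasma recovered from Ficoll gradients — the norm for biobanked
oncology samples collected before metabolomics was anticipated — carries
polymer signals that no pulse sequence filters out: a broad, intense
envelope centred at 3.80 ppm spanning 3.30–4.64 ppm, plus sharp
resonances at 1.81, 1.84, 2.26, 5.42 and 5.58 ppm. The package
implements the complete analysis pipeline for such spectra — processing,
contaminated-region exclusion, supervised classification and univariate
metabolite statistics — together with a synthetic cohort generator that
reproduces the statistical structure of a paired pre/post-anesthesia
oncology study (colorectal cancer with and without liver metastasis), so
every stage is testable without spectrometer access.

It is aimed at metabolomics practitioners and methodologists who work
with retrospective plasma collections, and at anyone needing a
self-contained, seed-reproducible testbed for bucket-table chemometrics.

## What it computes

**Processing.** FIDs are multiplied by a decaying exponential equivalent
to a 1.0 Hz line broadening and Fourier transformed; spectra are
calibrated on the glucose anomeric doublet (δ 5.24); the region
0.20–10.00 ppm is segmented into 0.02-ppm buckets (490 bins) by
trapezoidal integration; bins whose centres fall in the excluded window
(3.30, 6.00) ppm — residual water plus the Ficoll envelope — are dropped
(135 bins), and the 355 retained bins are total-area normalized:
x_ij ← x_ij / Σ_j x_ij.

**Classification (PLS-CA).** Partial least squares (NIPALS, mean-centred,
one-hot class response) reduces the bucket matrix to a few latent
scores; a Fisher canonical discriminant on the scores assigns new
samples to the nearest class mean in canonical (Mahalanobis) space.
Performance is estimated by Monte-Carlo cross-validation: repeated
stratified 90/10 train/test splits with a pooled confusion matrix and
accuracy/sensitivity/specificity in percent.

**Paired designs (multilevel PLS).** For pre/post-anesthesia pairs the
bucket matrix is split as x_it = b_i + w_it, with b_i the subject mean
and w_it = x_it − b_i the within-subject part (w_i,pre = −w_i,post
exactly). PLS-CA on the within part isolates the treatment effect;
cross-validation resamples *subjects*, so a pair never straddles the
train/test boundary.

**Univariate screening.** Per metabolite: Wilcoxon rank-sum (unpaired)
or signed-rank (paired) two-sided p, exact by enumeration for small
samples; Benjamini–Hochberg adjustment over the metabolite family
(significant at adjusted p < 0.05); and the signed fold change
−log₂(median_A / median_B) with a plain-language direction.

**Simulation.** Cohorts are generated from ~20 named plasma metabolite
signal groups (Lorentzian lines at their familiar shifts), a
macromolecular baseline, residual water, per-subject Ficoll
contamination, group-level multiplicative effects, a general
post-anesthesia concentration decrease, drug (cefuroxime-like) peaks
present only post anesthesia, log-normal between-subject variability and
additive Gaussian noise. NOESY / CPMG / diffusion-edited acquisition is
emulated by component weights; contaminant peaks are never attenuated.

## Worked example

```r
library(ficollnmr)

design <- cohort_design(n_subjects_per_group = c(20, 20),
                        effect_table = list(LC = c(lactate = 1.6,
                                                   alanine = 0.7)),
                        axis = default_ppm_axis(8192), seed = 1)
cohort  <- simulate_cohort(design)
pre     <- cohort$annotation$timepoint == "pre"
buckets <- build_bucket_matrix(cohort$spectra[pre], calibrate_ppm = 5.24)
buckets
#> <bucket_matrix> 40 samples x 355 bins (0.02 ppm, cpmg, normalized)

monte_carlo_cv(buckets, cohort$annotation$group[pre],
               n_iterations = 200, test_fraction = 0.1, ncomp = 3,
               seed = 2)
#> <cv_report> pls-ca, 200 Monte-Carlo splits (test fraction 0.10, seed 2)
#>      predicted
#> true  CRC  LC
#>   CRC 350  50
#>   LC   42 358
#> accuracy 88.50%  sensitivity 87.50%  specificity 89.50%  (positive class: CRC)
```

A held-out accuracy of 88.5% says the simulated 1.6×/0.7× two-metabolite
group signature is readily detectable through the contaminated-spectrum
route. The univariate screen recovers the same signature:

```r
met    <- quantify_metabolites(cohort$spectra[pre], cohort$regions)
screen <- univariate_screen(met, cohort$annotation[pre, ],
                            list(type = "group", levels = c("CRC", "LC")))
head(as.data.frame(screen)[order(screen$adjusted_p),
                           c("metabolite", "adjusted_p", "neg_log2_fc",
                             "direction")], 3)
#>    metabolite   adjusted_p neg_log2_fc     direction
#> 1     lactate 1.287768e-06   0.4100198  higher-in-LC
#> 17  threonine 1.287768e-06   0.3969282  higher-in-LC
#> 2     alanine 4.768769e-06  -0.5394830 higher-in-CRC
```

Lactate (raised in LC) and alanine (lowered) are flagged with the
expected signs; threonine rides along because its 1.32-ppm doublet
overlaps lactate's 1.33-ppm signal — a real limitation of
resolved-signal integration discussed in the methods vignette.

The full configured pipeline (simulate → process → classify → screen)
runs from one call or from the shell:

```r
report <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "out")
```

```sh
Rscript inst/scripts/pipeline.R --stage run --config cfg.yaml --out out
```

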