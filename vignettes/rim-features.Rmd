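---
title: "Rim-based PET features and univariate survival screening: methods"
author: "petrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rim-based PET features and univariate survival screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrim)
```

## The problem

In head-and-neck squamous cell cancer, FDG-PET is routinely acquired before
and 8-12 weeks after chemoradiotherapy, but quantitative use of those scans
is usually limited to a handful of core-focused measures: the maximum
standardized uptake value (SUVmax), its sphere-averaged variant SUVpeak,
metabolic tumor volume (MTV) and total lesion glycolysis (TLG). A residual
hot spot on the follow-up scan is a diagnostically ambiguous finding —
roughly half of such scans are false positives — so features that look at
something other than the lesion core are of real clinical interest.

petrim computes a 22-feature panel from an SUV volume plus a lesion
segmentation, with particular attention to the lesion *periphery*: the rim
average (RA), the mean uptake of a 2-voxel-wide shell immediately
surrounding the lesion, and the standardized added metabolic activity
(SAM), a background-corrected TLG surrogate that uses the same rim. It then
provides the standard univariate survival screen for such panels: per-SD
Cox hazard ratios, Harrell's c, Benjamini-Hochberg FDR across the panel,
and Kaplan-Meier tertile curves against disease-free survival (DFS).

## The feature panel

For a lesion mask $L$ on an SUV volume with voxel volume $V_{vox}$ (ml,
the product of the three spacings divided by 1000):

* **Max, Mean, Min, Median, quartiles** — order statistics of the SUV
  multiset inside $L$. Quartiles use linear interpolation between order
  statistics (`stats::quantile` type 7). The convention matters only in
  small samples, but it is fixed so that tests are exact.
* **Std, RMS** — Std is the *population* (divide-by-$n$) standard
  deviation, so the identity $RMS^2 = Mean^2 + Std^2$ holds exactly and is
  tested. With an $n-1$ denominator the identity would only hold
  asymptotically.
* **Upper adjacent** — the boxplot whisker end: the largest observation not
  exceeding $Q_3 + 1.5\,IQR$. Note that when no observation falls between
  $Q_3$ and the fence, the upper adjacent value is *below* the interpolated
  $Q_3$; the package treats that as correct behaviour of the definition
  rather than clamping.
* **MTV** $= |L| \cdot V_{vox}$; **TLG** $= \overline{SUV}_L \cdot MTV$.
* **Peak** — the best mean over 1 cm³ spheres centered on lesion voxel
  centers; sphere membership is evaluated for voxel centers in physical mm
  coordinates (radius $(3000/4\pi)^{1/3} \approx 6.2035$ mm), so
  anisotropic grids are handled correctly. Spheres may extend beyond the
  lesion; sphere voxels falling outside the image grid are excluded from
  the average (the alternative — dropping such centers — can leave small
  near-edge lesions without any valid center).
* **Grayscale quarters** — the range $[Min, Max]$ is split into four equal
  bins, half-open $[lo, hi)$ except the last, which is closed. *Q1-Q4
  Distribution* are the percentages of lesion voxels per bin (summing to
  100); *Glycolysis Q1-Q4* are $\sum SUV \cdot V_{vox}$ per bin (summing
  to TLG). A degenerate range ($Max = Min$) assigns every voxel to Q1, a
  deterministic convention exercised by the tests.
* **RA** — mean SUV over the rim (below).
* **SAM** $= \sum_{v \in L \cup R} SUV(v) V_{vox} - RA \cdot Vol(L \cup R)$,
  which reduces algebraically to $TLG - RA \cdot MTV$: total activity of
  lesion plus rim, minus what a flat background at the rim mean would
  contribute over the same region. The measurement region for SAM is taken
  as lesion ∪ rim with the rim mean as the background estimate; the rim is
  the only auxiliary region the pipeline constructs, and this is the main
  interpretation choice in the panel. On a flat field SAM is exactly 0,
  and for a uniform lesion at uptake $L$ over background $B$ it equals
  $(L-B) \cdot MTV$ — both are tested.

### The rim

The rim is built by dilating the lesion mask `widthVoxels` times (default
2) with the 6-connected face-adjacency structuring element and subtracting
the lesion; equivalently, it is the set of non-lesion voxels within
city-block distance 2 of the lesion, clipped at the image boundary. Width
is counted in voxels, not millimetres, so the physical rim thickness
follows the voxel spacing. Whether a rim of this kind should use face
(6-connected) or full (26-connected) adjacency is not determined by the
wording "2 voxel wide"; face adjacency is the default because it matches
the city-block reading, and `connectivity = 26` is exposed as a parameter
for sensitivity analyses. The implementation is verified against an
exhaustive city-block-distance enumeration on small grids.

## Liver normalization and change features

To account for inter-scan differences in metabolic baseline activity, all
SUV-carrying features are divided by the mean SUV of a liver measurement
region (`liverMean()` over a user-supplied mask, or a scalar). MTV and the
quarter percentages are volume- or ratio-valued and are left unchanged;
`liverNormalizedFlags()` is the authoritative table and is asserted
feature-by-feature in the tests. SAM is computed raw first and then
divided by the liver mean — the background subtraction happens on the SUV
scale, the normalization afterwards. Normalization is a separate pass so
raw tables remain available for sensitivity analyses.

Change features are $\Delta f = f(t_0) - f(t_1)$, baseline minus
post-treatment, computed on normalized vectors (raw differencing is
allowed behind `allowRaw = TRUE`). A positive $\Delta RA$ means loss of
peripheral activity under treatment. Subjects with a complete metabolic
response have no post-treatment lesion, hence no change vector; the change
cohort is structurally smaller than the baseline cohort.

## Survival screening

Each feature is screened individually against DFS:

* features are standardized by the sample SD ($n-1$ denominator, complete
  cases for that feature), so hazard ratios are per one SD increase;
* Cox proportional-hazards fits use the Efron tie approximation, the
  default of the `survival` package this field's analyses are run with;
* confidence intervals and p-values are Wald on the log-hazard scale,
  two-sided;
* Harrell's c is computed from each model's prognostic score, with pairs
  tied on score counting 1/2 and tied event times not comparable — the
  implementation is checked against an $O(n^2)$ pair-enumeration oracle
  and against `survival::concordance(reverse = TRUE)` on tie-free data;
* BH adjustment runs across exactly the screened panel (the 22 features of
  one table; baseline and change analyses are adjusted separately), and
  features are flagged at a 10% FDR by default. Note BH-adjusted values
  are *not* a fixed point of re-adjustment; the tests assert the true BH
  properties (adjusted ≥ raw, order preservation, the step-up closed form)
  instead.
* Kaplan-Meier curves stratify subjects into low / intermediate / high
  groups by tertiles (type-7 percentiles at 1/3 and 2/3); subjects exactly
  at a cut point join the lower group. Monotone likelihood (perfectly
  separating features) is reported via a warning and a `converged = FALSE`
  flag rather than silently clipped.

Reproducing a published per-subject analysis requires the corresponding
per-subject feature/outcome CSV; `reproduceTables()` takes such a file
plus a column map (`defaultColumnMap()`), recomputes both screening tables
and the cohort descriptives, and is exercised by the acceptance tests when
the file is installed under `inst/extdata/`.

## Synthetic data: what it emulates, and what it does not

`makePhantom()` builds hot spherical lesions on a cooler background with a
disjoint uniform liver sphere, on grids with clinical PET spacings
(defaults 3.5×3.5×3.4 mm; the supported range of interest is roughly
3.4×3.4×2.0 to 4.3×4.3×5.0 mm). Three radial profiles are available:
`uniform` (hard edges; closed-form feature values, used for exact tests),
`gaussian` (smooth fall-off emulating scanner blur, which is what makes RA
sensitive to edge gradients), and `gradient` (linear ramp). Optional
Gaussian voxel noise is clamped at zero. Phantoms do not model sinograms,
reconstruction, attenuation, scatter, or realistic lesion shapes — passing
tests demonstrate the *arithmetic* of the features, not robustness to
acquisition physics.

`makeCohort()` draws feature vectors from a multivariate normal with
exchangeable correlation and generates DFS from an exponential
proportional-hazards model, $\lambda_i = \lambda_0 \exp(\sum_k \beta_k
z_{ik})$ on the standardized true features, with independent exponential
censoring. With the default rates (baseline 0.012/month, censoring
0.016/month) the censored fraction is 0.016/0.028 ≈ 57%, typical of such
cohorts. Under $\beta = 0$ the observed time is the minimum of two
exponentials, which the tests verify by a Kolmogorov-Smirnov check.

`makePaperLikeCohort()` produces a 58-subject cohort in which 25 subjects
carry post-treatment and change features, with an exponential baseline of
0.011/month, a −0.35 log-hazard offset for complete responders (complete
response portends better outcome), a modest baseline tumor-burden effect
(0.4 per SD of MTV), a rim-average-change effect (0.7 per SD of ΔRA)
within the residual subset, and administrative censoring uniform over a
6-124-month follow-up window. These rates were fixed once, by Monte-Carlo,
so that expected event counts land near 25 of 58 overall and 13 of 25 in
the residual subset — the structure of the clinical cohorts this package
targets. The generator is for end-to-end exercises of the pipeline; its
draws are not a numeric reproduction of any real cohort.

## Numerical choices and degenerate inputs

* All computation is double precision; no resampling to isotropic grids is
  performed anywhere, and masks must match their volume's grid exactly
  (shape and spacing) — mismatches are errors, not silent resamples.
* Degenerate grayscale range → all voxels in Q1. Empty lesions, rims or
  liver masks are errors. Zero-variance features are a screening error
  ("zero variance"), not an NA row.
* Volumes round-trip bit-for-bit through the NRRD writer/reader (gzip or
  raw encodings, little-endian); NIfTI-1 I/O goes through RNifti.
* Tie-breaking: peak takes the maximum over all candidate centers; tertile
  ties go to the lower group; risk-score ties count 1/2 in the c index.

## Problem sizes used by the test suite

The property suites run on sizes chosen to finish in minutes on one core
while still being informative: 1000 random lesion samples for the
partition/moment identities and the brute-force statistic oracles; 200
random censored cohorts (n ≤ 20) for the exact concordance comparison;
200 replicates of n = 500 per hazard-ratio level for recovery bias;
2000 null cohorts of n = 60 for the type-I error of the Wald screen
(5% ± 2%); and 100 null cohorts of n = 58 for the BH zero-discovery rate
(≥ 85% expected). Phantom grids are 20³-48³ voxels.

## Known limitations

* Lesion and liver segmentation are inputs; the package contains no
  segmentation or automatic liver-region detection.
* No registration between timepoints: change features compare feature
  values, not voxels.
* No texture (GLCM/GLRLM) or shape features; the panel is deliberately
  the 22 descriptors above.
* The normalized-SAM variant (dividing by the rim measurement itself) is
  not implemented; SAM here is liver-normalized like the other
  SUV-carrying features.
* DICOM ingestion and decay correction are out of scope;
  `suvFromActivity()` covers only the body-weight SUV formula for raw
  arrays.

## A worked phantom example

```{r phantom}
ph <- makePhantom(phantomSpec(backgroundSUV = 1, lesionSUV = 8,
                              liverSUV = 2))
fv <- extractFeatures(ph$volume, ph$lesion)
nv <- normalizeFeatures(fv, liverMean(ph$volume, ph$liver))
round(featureValues(nv)[c("Mean", "MTV", "TLG", "RA", "SAM")], 4)
```

The uniform lesion at SUV 8 over background 1 with liver 2 gives
normalized Mean 8/2 = 4, RA 1/2 = 0.5, and SAM equal to
$(8-1) \cdot MTV / 2$.

```{r screen}
ct <- makePaperLikeCohort(seed = 1)
res <- screenFeatures(ct, "delta")
head(formatResultsTable(res), 3)
```
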