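---
title: "circtime: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circtime: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtime)
```

# What the package computes

`circtime` re-implements, as tested reusable code, three stages of a
cerebrovascular imaging study of multiple sclerosis:

1. **Cerebral circulation time (CCT)** from digital subtraction angiography
   (DSA) frame sequences: the time between peak contrast concentration in
   the carotid siphon and in the cortical parietal veins, read off
   time-intensity curves after mask-frame subtraction. A color-coded
   circulation-time image renders the per-pixel time-to-peak (TTP) on an
   early-to-late hue ramp, so a delayed venous phase is visible as veins
   shifted toward blue.
2. **Native-space white-matter lesion volumetry** on FLAIR MRI: rigid
   T1-to-FLAIR coregistration, EM tissue segmentation of the T1, affine
   normalization to a package template used only to pull atlas exclusion
   masks (cerebellum, brainstem, thalamus, caudate, putamen) into native
   space, then thresholding the retained white-matter FLAIR voxels at the
   95th intensity percentile. The FLAIR itself is never resampled.
3. **Cohort statistics**: inter-rater ICC(A,1) with confidence intervals,
   a rater-by-side ANOVA, normality (D'Agostino-Pearson) and
   variance-homogeneity (Brown-Forsythe) gates in front of the two-group
   comparison (pooled t / Welch t / Mann-Whitney), a gender-by-group ANOVA
   with a log-transform branch, subtype and subsample comparisons
   (Mann-Whitney, Kolmogorov-Smirnov), a correlation battery, and
   noncentral-t power.

Because the patient data behind the modeled study are not public, the
package ships seeded generators for all three kinds of input, with exact
ground truth, and every downstream claim is tested against that truth.

# The synthetic world

## DSA sequences

Each compartment (carotid siphon, capillary bed, cortical veins,
background) follows a gamma-variate bolus curve
$C(t) = A\,u^{\alpha} e^{\alpha(1-u)}$, $u = (t-t_0)/t_p$, the standard
indicator-dilution form; its maximum is exactly $A$ at $t_0 + t_p$, so peak
times are analytic. The modeled study reads whole frames, so the generator
samples at 2-4 frames/s and the default peak reader does **not**
interpolate: the quantization bound |recovered - true| <= half a frame
interval is then a theorem for noiseless unimodal curves, and the tests
assert it at 2, 3 and 4 fps. Sub-frame parabolic interpolation (vertex of
the quadratic through the maximum and its neighbors, clamped to the
neighbor interval) is available but off by default.

Presets encode the two study groups: venous peak minus arterial peak of
4.9 s ("ms") and 2.8 s ("control"), the published group means. Noise is
i.i.d. Gaussian on every pixel of every frame. The anatomical baseline is
deterministic and removed exactly by mask-frame subtraction, which is why
`compute_cct` is invariant to adding a constant to all frames; invariance
to uniform intensity scaling follows from peak *location* reading.

## MRI phantoms

Anatomy is analytic: a brain ellipsoid (semi-axes 65 x 80 x 60 mm at scale
1) with an ellipsoidal-radius coordinate $\rho$; cortical gray matter on
$\rho \in (0.646, 0.965]$, deep white matter at $\rho \le 0.646$, a CSF rim,
a skull shell, lateral ventricles, thalamus/caudate/putamen (gray), and
cerebellum/brainstem compartments. Because membership functions are
evaluated directly at voxel-center world coordinates, any grid samples the
same anatomy: the T1 grid (1.3 x 1.3 x 1.2 mm), the FLAIR grid
(1 x 0.9 x 5 mm - the modeled acquisition), and the 2 mm template.

Three deliberate design choices:

* **Mis-registration is simulated against the header.** The FLAIR's stored
  affine is *not* updated when `applied_rigid` displaces its anatomy, so
  coregistration has something real to recover, and the generator knows the
  exact answer.
* **Intra-parenchyma texture.** A fixed sum of three sinusoids
  (wavelengths 17/19/23 mm, amplitude 5) rides on the parenchyma in both
  modalities, in anatomy coordinates. A piecewise-constant ellipsoidal
  phantom leaves mutual information flat within about a degree of rotation
  - rotation estimation is then genuinely ill-posed, which is a defect of
  the phantom, not of real brains (which are textured). The amplitude was
  fixed once at the noise scale.
* **Lesion load sits at the thresholding operating point.** Lesions are
  grown voxel-wise around seeds in the deep cerebral white matter (nearest
  eligible voxels first, ties by distance; the through-plane distance is
  weighted so foci span few 5 mm slices) until the target volume is met;
  the realized truth volume matches the target within one voxel. At full
  scale the retained white matter is ~310 ml, so the default total load of
  15.3 ml - the published mean - is ~5% of the retained volume. This is not
  an accident and the next section explains why it matters.

What the phantoms do **not** emulate: partial-volume mixing (voxels are
crisply assigned), bias fields, realistic gyral anatomy, T1 lesion
hypointensity, motion/ghosting. A green pipeline test therefore
establishes correctness of the *computation*, not clinical performance on
real scanners.

## Cohorts

Latent CCT per subject is normal per group (4.87 +/- 1.27 s for 80
patients, 2.78 +/- 0.51 s for 44 controls; 45 relapsing-remitting, 35
progressive). Observed readings are latent + rater bias + side offset +
Gaussian reading noise, quantized to the 0.25 s frame interval - two raters
times two sides. The default side offset is 0 s, consistent with the
modeled study's non-significant side effect. The default rater noise is
*calibrated*: for the additive model the expected single-measure ICC is
$\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$, and quantization contributes
approximately $\Delta^2/12$ to $\sigma_e^2$; `calibrate_rater_noise()`
inverts this for the target ICC of 0.984, and 500-replicate recovery is an
acceptance criterion. Covariates (age, EDSS, disease duration, onset age)
are drawn within the published ranges with subtype shifts in the clinical
direction; they are generated independently of CCT, so the correlation
battery's null calibration is exact by construction.

# Numerical and statistical choices

**Percentile support.** "The 95th percentile of the FLAIR image" is
ambiguous. The default support is the *retained* voxel set (white matter
minus excluded structures): a whole-image percentile would depend on how
much background padding the field of view happens to contain. The
whole-in-brain alternative is exposed as `support = "brain"`. The
percentile uses the linear-interpolation definition (R type 7), and
flagging is strictly-greater - with 1000 distinct retained values exactly
50 voxels are flagged, which the tests assert exactly.

**The operating point of percentile thresholding.** With near-distinct
intensities the method flags exactly (100-p)% of the retained voxels
*whatever the images contain*. Its volume estimate is therefore accurate
precisely when the true lesion fraction is near that rank fraction, and
degrades linearly as the truth departs from it. The acceptance phantoms
use loads of 14.4-16.2 ml around the published 15.3 ml mean, i.e. the
regime the method (and the published choice of the 95th percentile at this
head geometry) presupposes. Dice stays high in this regime because the
planted lesions are the brightest retained voxels, so the flagged set is
the lesion set up to the rank-count mismatch.

**Registration.** Both registrations maximize a 32-bin joint-histogram
mutual information over deterministic voxel subsamples (<= 25k), so results
are exactly reproducible. Three details matter and were found the hard
way:

* MI is weighted by the overlap fraction (clamped above 95%): otherwise
  the optimizer inflates MI by pushing hard-to-match samples off the other
  image's grid.
* Samples keep every head class (two-stage Otsu: background excluded, CSF
  and skull kept) - the low-intensity shells carry most of the rotational
  information; parenchyma-only sampling leaves MI flat in rotation.
* Nelder-Mead alone stalls on ridge-shaped MI surfaces; a cyclic
  coordinate-wise parabolic refinement follows it at the finer pyramid
  levels. For the 12-parameter affine the simplex search proved prone to
  *distant* local optima, so the affine uses moment initialization
  (foreground-weighted centroid and per-axis second moments) plus the
  monotone coordinate refinement only - it can then only improve on, and
  stay near, the moment fit. Nonlinear template warping is deliberately
  out of scope: the affine is used only to pull coarse, dilated exclusion
  masks into native space, and lesion measurement itself happens in native
  space.

**Tissue segmentation.** A univariate 3-class Gaussian mixture fitted by
EM (quantile-seeded k-means init, tolerance 1e-6, <= 500 iterations),
components labeled CSF < GM < WM by ascending mean - the T1 convention. A
variance floor of 1e-6 times the data variance lets the noiseless phantom
(three point masses) be recovered exactly rather than erroring;
degeneracy errors fire on near-zero component weight or fewer than three
distinct intensities. Volumes integrate posteriors (soft counting), in
the subject's own space, in cm^3.

**Statistics.** All tests are implemented from their definitions and
checked against independent routes: a definitional sums-of-squares oracle
for ICC(A,1) (exact algebraic agreement), frozen reference values from an
independent implementation for the D'Agostino-Pearson K^2, base R's
`t.test`/`wilcox.test`/`ks.test`/`power.t.test` as dual routes where they
exist, full-enumeration and permutation oracles for the nonparametrics.
Fractional Satterthwaite df appear only in the Welch branch; with equal
SDs and sizes the df collapse to n1+n2-2 exactly. The ICC confidence
interval is the McGraw & Wong F-based approximation, the only named-method
gap in the source material. The Mann-Whitney exact path enumerates all
group assignments (correct under ties) for n1+n2 <= 16 and otherwise uses
the normal approximation with tie and continuity corrections. Type-II
sums of squares are used for unbalanced two-way ANOVA; with balanced data
they coincide with the classical decomposition. No multiple-testing
correction is applied anywhere - the analysis reports raw p-values, as the
modeled study did.

**Decision flow.** `run_full_analysis()` reruns the published order:
per-group/per-side ICC; a rater x side two-way ANOVA per group (the four
reading series stacked, rater and side as between factors - the published
denominator df of 1 is inconsistent with the sample sizes and is not
reproduced); if neither factor is significant the right-side first-rater
series becomes the canonical series (it is also the fallback, by the
study's own convention); normality and homoscedasticity gates select
pooled-t, Welch or Mann-Whitney; the gender x group ANOVA log-transforms
CCT when raw-scale homoscedasticity fails; every result records the branch
that produced it in `decision_path`.

**Known discrepancies, kept honest.** From the printed summaries the
Welch machinery gives t = 12.94 and df = 114.1 against the published 12.88
and 115.22 - the ~1% drift expected when the original computation used
unrounded summaries; the mean difference (2.09 s) and 95% CI ([1.77, 2.41])
reproduce exactly to the printed precision. The published achieved power
of 0.83 (d = 0.5, alpha = 0.05, n = 80/44) is not what the standard
noncentral-t computation yields (0.753); the standard formula is
implemented and the computed value reported, not tuned. Published
quantities that depend on the raw patient data (U = 658, K-S = 0.0622, the
ICC confidence intervals, Brown-Forsythe F = 2.0733, the per-table volume
means) cannot be re-derived at the desk and are covered instead by the
oracle and calibration properties in the test suite.

# Limitations

* The affine "spatial normalization" is a 12-dof stand-in for nonlinear
  template warping; it is adequate only because the excluded structures
  are represented by dilated geometric masks.
* Percentile lesion segmentation has no notion of lesion count or shape;
  no connected-component or minimum-size filtering is applied (the modeled
  pipeline states none), and the visual-inspection step is replaced by an
  overlay image artifact for human review.
* The phantom's intensity model is piecewise-constant plus texture and
  noise; segmentation accuracies near 1.0 on it say nothing about
  performance under partial volume or bias fields.
* File formats: NIfTI-1 I/O is a minimal built-in codec (sform, gzip);
  2-D artifacts use plain-text netpbm (PGM/PPM) because the target
  environment has no PNG/TIFF codec for R.
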