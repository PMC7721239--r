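---
title: "Methods: simultaneous brain and cervical cord morphometry and qMRI analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous brain and cervical cord morphometry and qMRI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuraxis)
```

## What the package does

`neuraxis` implements a voxel-based morphometry (VBM) and voxel-based
quantification (VBQ) analysis stack that treats the brain and the cervical
spinal cord as one object. The pieces are:

* prior-weighted Gaussian-mixture tissue segmentation producing seven
  tissue classes, a combined neural-tissue (NT) map, and total
  intracranial volume (TIV);
* native-space cord morphometry: sub-voxel contouring of the NT map,
  direct ellipse fitting per axial slice, and the derived cord
  cross-sectional area (SCA), anterior-posterior width (APW) and
  left-right width (LRW), plus masked means of quantitative MT / R1 / R2*
  maps;
* spatial operators: resampling through displacement fields, Jacobian
  modulation, isotropic Gaussian smoothing, tissue-weighted (VBQ)
  smoothing, and a 0-6 mm smoothing scale-space sweep;
* group statistics: voxel-wise GLM t-maps with nuisance covariates,
  random-field-theory (RFT) peak-level family-wise error (FWE) correction
  within regions of interest, ANCOVA on scalar cord metrics, and ICC(A,1)
  method agreement;
* a synthetic phantom generator that provides cohorts with analytically
  known ground truth, because suitable patient MRI data cannot be
  redistributed.

## Segmentation model

Intensities are modelled as a mixture of Gaussians, with the template
priors $\pi_k(v)$ acting as voxel-wise mixing weights:
$p(y_v) = \sum_k \pi_k(v) \sum_g w_{kg}\, \mathcal N(y_v;\mu_{kg},\sigma^2_{kg})$.
By default one Gaussian models each of GM, WM, CSF and fat, two model
non-neural tissue and three each model soft tissue and bone/air
(`gaussians_per_class = c(1,1,1,1,2,3,3)`). EM maximises the likelihood
over the voxels with nonzero prior support; class posteriors are the
summed responsibilities of each class's Gaussians, rescaled so the
posterior sum equals the prior sum at each voxel.

Numerical choices:

* **Initialisation** is deterministic: Gaussian means start at
  prior-weighted intensity quantiles, with quantile positions spread by
  each Gaussian's global rank so that classes remain distinguishable even
  under completely flat priors (otherwise EM starts at a symmetric fixed
  point and cannot separate classes). Within-class weights start uniform;
  variances at the prior-weighted class variance divided by the number of
  Gaussians, floored at $10^{-8}$ of the overall variance.
* **Convergence**: relative log-likelihood change below `tol = 1e-6`
  (at most `max_iter = 100` iterations). The log-likelihood trace is
  retained and asserted non-decreasing in the tests.
* **No bias-field model**: inputs are assumed inhomogeneity-corrected
  upstream, and the phantoms are bias-free; this is a documented
  restriction, not an approximation error.
* **Alignment**: priors must already live on the image grid. Deformable
  template registration is deliberately out of scope; the deformation
  type exists so externally supplied or analytic fields can be applied
  and modulated.
* Hard labels (reports only) break ties by the first class in order.

NT is `clip(GM + WM, 0, 1)`: GM/WM separation inside the cord is
unreliable at typical resolutions, so cord analyses use their sum. TIV is
the integral of GM + WM + CSF probability times the voxel volume.

## Cord morphometry

The cord boundary is taken as the sub-voxel 0.5 iso-contour of the NT
probability map in each axial slice, extracted by bilinear interpolation
(marching-squares style) rather than from voxelised mask edges — this
removes the staircase bias that would otherwise dominate at 1 mm voxels.
Thresholding at 0.5 is inclusive (a voxel exactly at 0.5 is cord), the
largest 6-connected component is kept, and when a slice contains several
closed contours the longest perimeter wins (ties: larger enclosed area).
A contour that touches the slice edge or does not close marks the slice
invalid rather than raising an error.

An ellipse is fitted to each slice contour by the numerically stable
direct least-squares conic method (ellipse-constrained). From semi-axes
$a \ge b$ and tilt $\theta$:

* $\mathrm{SCA} = \pi a b$ — the area of the fitted ellipse. The
  alternative (mask voxel count times voxel area) is reported alongside in
  the per-slice table as `mask_area` for comparison, but the ellipse area
  is the primary definition.
* Widths are the full extents of the fitted ellipse along the anatomical
  axes (left-right = world $x$, anterior-posterior = world $y$): the
  extent along a unit vector $u$ is
  $2\sqrt{(a\,e_1\!\cdot\!u)^2 + (b\,e_2\!\cdot\!u)^2}$. This definition
  is rotation-consistent: rotating the anatomy 90° in-plane exactly swaps
  APW and LRW. Principal-axis lengths are available behind
  `widths = "principal"` for users who prefer them.
* The fit residual is the RMS gradient-normalised (Sampson) distance in
  mm; slices with residual above 0.5 mm are flagged invalid and excluded
  from subject means, with the valid-slice count reported.

The cervical coverage (the paper's visually defined C1-C3 span) is an
explicit `z_range` parameter; phantoms carry a labelled range. Masked
qMRI means are unweighted means over the binary cord mask.

## Tissue-weighted smoothing and the scale-space sweep

Plain Gaussian smoothing of quantitative maps mixes cord values with CSF.
VBQ smoothing computes $G*(w q)\,/\,G*(w)$ with the tissue probability
$w$ as weight, which preserves quantitative units and returns a constant
map unchanged wherever it is defined. Voxels whose smoothed weight falls
at or below `support_threshold = 0.05` are flagged missing (`NA`), not
zero-filled — zeros would bias group means. The weight is normalised by
its maximum before thresholding, which makes the operator invariant to
rescaling the tissue map by a positive constant; without that
normalisation the support set would depend on an arbitrary scale. The
boundary policy is zero padding; the weighted quotient self-corrects near
boundaries, and plain smoothing is mass-preserving away from them.

`scale_space_sweep()` applies the smoothing plan (default FWHM 0-6 mm in
1 mm steps) to every subject and returns one subjects-stack per scale, so
group statistics can be compared across scales. FWHM converts to the
Gaussian standard deviation as $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
(6 mm FWHM = 2.548 mm $\sigma$). Note that cord-toolbox documentation
sometimes quotes $\sigma = 3$ mm as "5.88 mm FWHM"; that does not follow
from the standard conversion (which gives 7.06 mm), and this package
implements the standard conversion only.

## Group statistics

**GLM.** The two-group design uses intercept-free group indicators plus
mean-centred age (and TIV where available) and 0/1 indicators for gender
and scanner; the default contrast is control minus patient. Continuous
covariates are centred so that the group columns retain their
interpretation as adjusted group means; whether centring was used in the
original analyses is not documented anywhere we could check, and centring
does not change the group-difference inference. Score-association models
use an intercept plus the centred score and the same covariates. Rank
deficiency is an error naming the offending columns; constant covariates
are dropped with a warning; subjects with missing values are excluded and
listed. Per-voxel OLS gives $t = c^\top\hat\beta / \sqrt{\hat\sigma^2
c^\top(X^\top X)^{-1}c}$ with $df = n - \mathrm{rank}(X)$; zero-variance
voxels are masked out.

**Smoothness.** Residuals are standardised voxel-wise (unit sum of
squares across volumes), and for each axis the mean squared forward
difference estimates the lag-one autocorrelation $\rho = 1 - s^2/2$. A
Gaussian autocorrelation model then gives
$\mathrm{FWHM} = \Delta \cdot 2\sqrt{2\ln 2} / (2\sqrt{-\ln\rho})$,
clamped below at one voxel. This autocorrelation form was chosen over the
raw variance-of-derivative formula because it behaves correctly in the
white-noise limit (the raw formula converges to 1.18 voxels rather than
the voxel size).

**Peak-level FWE.** ROI resel counts $R_0..R_3$ use the Worsley lattice
counting of points, edges, faces and cubes with per-axis voxel-to-FWHM
ratios — exact for box-shaped ROIs, an approximation (documented) for
curved ones. Corrected peak p-values are the expected Euler
characteristic bound $p = \min(1, \sum_d R_d\,\rho_d(t))$ with the
standard t-field EC densities at the map's df. Local maxima use
18-connectivity with ties kept; z-equivalents are the probit of the
t upper-tail probability, clamped at 8. Each ROI is corrected within
itself; no across-ROI correction is applied. The expected-EC bound is
non-monotone at low thresholds, so threshold inversion brackets the root
from the decreasing tail.

The Monte-Carlo calibration (`rft_fwe_calibration()`) simulates null
two-group t-fields of known smoothness: white noise smoothed on a padded
grid and cropped to a stationary 32³ interior. Its defaults — 15
subjects per group (df 28) and an 8-voxel FWHM — put the simulation in
the regime where the expected-EC bound is sharp. The regime matters, and
we mapped it with this same machinery: a smoothed *Gaussian* field at
5-voxel FWHM is calibrated almost exactly (empirical FWE 0.054 over
2000 replicates against the Gaussian EC densities), but the *t*-field at
df 28 gives ≈0.028 at 5-voxel FWHM, ≈0.035 at 7, and ≈0.05 at 8; at
df 58 it reaches ≈0.04-0.05 from 5-6 voxels. Counting excursion
components directly shows why: the continuum expected EC overpredicts
the lattice count for low-df t-fields (e.g. 0.090 observed vs 0.136
predicted at t = 5), because the locally varying SD denominator makes
t-excursions spatially sharper than the component fields, and a 1-voxel
lattice under-resolves them. Peak-level RFT is therefore a valid but
conservative bound for rough or low-df fields — a documented property of
the method, not an implementation artefact — and the calibration default
sits where the bound is tight.

**ANCOVA on cord metrics** fits `value ~ group + age + gender + scanner`
(TIV deliberately excluded for native-space cord metrics, which are not
normalised to head size in this pipeline). The group effect is reported
as control minus patient, so cord atrophy in patients appears as a
positive effect. Covariate-adjusted group means come from predictions at
reference covariate values.

**ICC(A,1)** is the two-way, absolute-agreement, single-measurement
intraclass correlation
$\mathrm{ICC}(A,1) = (MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E +
\tfrac{k}{n}(MS_C - MS_E))$, computed from direct sums of squares, with
reliability categories poor (< 0.5), moderate [0.5, 0.75), good
[0.75, 0.9) and excellent (>= 0.9). Note a terminology clash in the
literature: ICC(A,1) is the *single-measurement* absolute-agreement form
even when described as a "multiple raters" analysis; the formula
implemented is the (A,1) form as named. Absolute agreement means constant
offsets between methods lower the ICC, which is the property wanted when
comparing two processing routes. Missing cells are an error — no
imputation.

## The phantom generator

`phantom_spec()` defines a cohort of synthetic subjects on a common grid:
a tapered elliptical cord (default semi-axes 5.74 × 3.94 mm, giving a
control mean SCA of ~71 mm², APW ~7.9 mm, LRW ~11.5 mm — healthy
cervical values), a CSF-filled canal, non-neural/bone/soft/fat neck
layers, and a brain made of concentric ellipsoidal shells (WM core, GM
shell, CSF rim, skull, scalp). Tissue truth is generated as soft
probabilities by 3×3×3 sub-voxel supersampling of the analytic geometry,
so partial-volume boundaries behave like real probability maps and the
0.5 iso-contour is meaningfully sub-voxel. Ground-truth cord metrics are
analytic ($\mathrm{SCA} = \pi ab$, $\mathrm{APW} = 2b$,
$\mathrm{LRW} = 2a$), never voxelised, which makes them a clean recovery
oracle.

Default group effects are a 7% cord area reduction and an 8% cord MT
reduction — the magnitudes reported for chronic spinal cord injury in
the cord-metrics literature — so that power checks run under realistic
effect sizes. Quantitative-map means inside the cord default to MT 2.93
p.u., R1 876.88 and R2* 0.02, matching the scales on which cord qMRI
group tables are commonly reported; note that those published scales for
R1 and R2* look physically swapped or rescaled relative to SI
expectations (R1 of order 1 s⁻¹, R2* of order 20 s⁻¹), so the package
stores units exactly as declared and never "corrects" them.

Between-subject anatomical variability is a log-normal factor on true
cord area with a 5% coefficient of variation. Raw between-subject SDs of
cord area in patient cohorts are nearer 10%, but a sizeable share of that
is explained by the age/gender/scanner/body-size covariates that all the
statistical models here adjust for; 5% represents the residual,
covariate-adjusted variability, chosen once as the study condition for
the power analyses. All randomness flows through explicit seeds
(per-subject seeds are `seed + index`), so cohorts and manifests
regenerate byte-identically.

What the phantoms do **not** emulate: bias fields, motion, ghosting,
Gibbs ringing, spatially correlated physiological noise (one pipeline
test adds correlated noise explicitly where the contrast between
focal effects and smoothing is the point), real cord curvature beyond a
gentle bow, and real anatomy generally. Passing recovery and calibration
tests on phantoms therefore demonstrates correctness of the machinery
under known truth, not performance on clinical data.

## Simulation designs used by the tests and acceptance script

* RFT calibration: 1000 null t-fields, 32³ interior, FWHM 8 voxels,
  15 subjects/group; empirical FWE compared with the nominal 0.05.
* ANCOVA type-I error: 1000 cohorts of 10 + 10 subjects on a compact
  24×24×10 cord-only grid; power: 200 cohorts of 20 + 20 with the 7%
  atrophy default. These cohort simulations add measurement noise
  directly to the ground-truth NT probability maps and then run the full
  morphometric measurement chain (thresholding, largest component,
  sub-voxel contouring, ellipse fitting, ANCOVA). Per-subject EM
  segmentation is bypassed in these loops — its accuracy is validated
  separately (Dice ≥ 0.95 against truth on full phantoms) — because the
  type-I/power properties under test belong to the measurement and
  inference chain, and this keeps thousand-cohort simulations inside a
  desktop budget.
* Morphometry recovery: noiseless 32×32×12 phantoms at 1 mm; ellipse
  noise robustness: 100 seeded replicates with 0.1 mm point noise.

These sizes are the package's chosen validation conditions and are
stated here so they can be reproduced exactly.

## Known limitations

* Deformable registration and template construction are out of scope; the
  deformation contract covers externally supplied or analytic fields
  only, and phantom group analyses share one grid (identity deformation).
* Resel counts use the lattice approximation; for very small or highly
  curved ROIs relative to the smoothness, exact surface integrals would
  differ.
* The segmentation has no bias-field component and assumes aligned
  priors.
* Native-space cord metrics depend on the NT threshold (0.5) and the
  configured `z_range`; both are explicit parameters rather than
  anatomically detected landmarks (no vertebral-level detection).
* Cluster-level and FDR inference, permutation tests and nonstationary
  smoothness are not implemented.
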