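---
title: "Voxel-based morphometry for the mouse brain: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based morphometry for the mouse brain: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`mousevbm` implements a complete voxel-based morphometry (VBM) pipeline for
mouse structural MRI, together with the statistical validation framework
needed to trust its inferences. The pipeline follows the classic stage
sequence: a prior-penalised affine registration into bregma-origin
stereotaxic (Paxinos-convention) space; joint bias-field correction and
mixture-of-Gaussians tissue segmentation guided by tissue probability maps
(TPMs); small-deformation non-linear normalisation of the grey-matter (GM)
posterior with Jacobian modulation; Gaussian smoothing in world units; and a
voxelwise general linear model (GLM) with false discovery rate (FDR) or
random-field-theory (RFT) family-wise error (FWE) control. A synthetic
phantom generator supplies cohorts with fully known ground truth for every
stage.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and what the validation experiments do and do not
demonstrate.

# Coordinate conventions

All images are `volume3d` objects: a 3-D array plus a 4x4 voxel-to-world
matrix mapping 0-based voxel indices to millimetres relative to bregma, with
+x left-to-right lateral, +y posterior-to-anterior and +z
inferior-to-superior — the reading convention of the Franklin–Paxinos atlas.
The matrix is stored in the NIfTI sform with code "aligned"; the qform
mirrors it. Whether a given dataset's headers flip left–right is a property
of the acquisition, not of this convention; the package neither assumes nor
enforces a particular handedness beyond requiring a positive-determinant
linear block for decomposable affines.

# Affine registration with a population prior

The 12-parameter affine is kept in a rigid-invariant decomposition
`T · R · Z · W`: translation, rotation, then a stretch factor
`diag(scales) %*% unit-upper-triangular(shears)` obtained from the Cholesky
factor of `M'M`. Because `M'M` is unchanged by any rigid motion composed on
the left, the six scale/shear numbers are properties of the anatomy–template
size relationship alone, and the determinant of the transform is exactly the
product of the scales. (The symmetric polar factor shares the invariance but
not the determinant identity, which is why the triangular form is the one
used here and in the major human-imaging packages.)

The shipped prior on `(sx, sy, sz, hxy, hxz, hyz)` has means
`(1.00, 1.00, 1.00, 0.00, 0.01, 0.02)` and standard deviations
`(0.01, 0.02, 0.02, 0.02, 0.04, 0.01)` — the population statistics of mouse
brains aligned to a Paxinos-registered template. Only marginal SDs are
available, so the covariance is diagonal. The penalty is half the
Mahalanobis distance of the transform's invariant block from the prior mean;
it is added to the image term so that a 1-SD deviation costs 0.5 on the
log-likelihood scale.

The image dissimilarity is negative normalised mutual information on a
64-bin joint histogram of the resampled overlap, scaled by the number of
overlapping voxels so the data term dominates the prior in the
well-determined directions while the prior regularises the poorly
determined ones. NMI was chosen because the in vivo contrast differs
substantially from typical template contrast; a least-squares cost would
need an explicit intensity mapping. Optimisation is derivative-free
(Nelder–Mead) in four stages — rigid at half resolution, full affine at
half resolution, then two full-resolution passes, the last with a shrunken
simplex — with parameter-scaled steps (0.1 mm translations, 0.03 rad
rotations, 0.02 scales/shears). Initialisation is centre-of-mass alignment
unless a starting transform is supplied.

# Unified bias correction and segmentation

Each voxel's bias-corrected intensity is modelled as a mixture of
`gaussians_per_class` Gaussians (default 2) for each of four classes — GM,
WM, CSF and "everything else" — with spatial class priors taken from the
TPMs. The model alternates:

* an E-step computing component responsibilities from Gaussian likelihoods
  times the spatial priors;
* an M-step updating component weights, means and variances;
* a guarded update of the multiplicative bias field.

The bias field is `exp` of a separable low-frequency cosine (DCT) expansion,
which enforces positivity. The number of retained orders per axis is the
largest whose spatial period is at least `cutoff_mm`; the default cutoff of
12 mm is the midpoint of the 10–15 mm range appropriate for mouse surface
and solenoid coils. On desk-scale test grids whose field of view is only a
few millimetres this legitimately reduces to a DC-only basis; bias-recovery
experiments therefore use coarser voxels with a paper-scale field of view.
The field applies over the head (where the template expects tissue); air
voxels neither steer nor receive the gain model.

The bias update solves an exact weighted least-squares projection of the
log-ratio between the data and a class-level prediction onto the basis. Two
details matter:

* The prediction mixes the *class-average* means by the class posteriors.
  Class membership is driven largely by the spatial priors and class means
  are global scalars, so the prediction cannot chase the smooth field
  itself; using component-posterior means instead provably shrinks the
  recovered field (the fitted slope against a known truth drops to ~0.5).
* The fit is restricted to voxels whose template prior is nearly certain
  and 3-MAD trimmed, suppressing partial-volume outliers.

Each candidate update passes through a backtracking line search and is
accepted only if it lowers the penalised negative log-likelihood, so the
objective trace is non-increasing by construction; convergence is declared
at a relative change below `tol` (default `1e-5`) or `max_iter` (default
30) iterations.

Two deliberate softenings keep the posterior responsive to real anatomy:

* `tpm_blend` (default 0.25) mixes a uniform prior into the TPMs inside the
  head. A pure template prior with a hard floor effectively vetoes tissue
  that the template does not expect — exactly the situation created by
  pathology, such as ex vacuo CSF inside an atrophied structure — and can
  silently re-label disease tissue as the template class.
* The background class, when it has two or more components, devotes one
  *anchored* component (fixed mean midway between air and head intensity,
  fixed 30% mixing share) to head/air partial-volume voxels. Without it,
  boundary voxels are swallowed by the broadest tissue component and the
  total intracranial volume (TIV) is biased upward by several percent.

TIV is the posterior-weighted tissue volume: the sum of the GM, WM and CSF
posteriors times the voxel volume. The thresholded-map alternative was
considered and rejected because it quantises partial-volume voxels.

# Non-linear normalisation, modulation and smoothing

The warp is a small-deformation displacement field expanded on a separable
orthonormal DCT basis (default 8 x 8 x 6 orders per axis, ~1,150 scalar
parameters — the classic size for basis-function normalisation). The
objective is the mean squared difference of locally mean/variance
normalised images plus a bending-energy penalty, with the analytic gradient
of the data term propagated through the trilinear resampling; optimisation
is L-BFGS with a coarse-to-fine presmoothing schedule (6 then 2 voxels
FWHM) to extend the capture range beyond the image structure scale.

The bending penalty is diagonal in the frequency domain:
coefficient `(mx, my, mz)` is charged `(wx^2 + wy^2 + wz^2)^2`, with `w`
the angular frequency in radians per millimetre. Because the penalty is
quartic in inverse length, the *same physical stiffness* requires a much
larger weight on a miniature test brain than on a full-size mouse brain —
the familiar millimetre-scale rescaling problem that motivates
mouse-specific regularisation in the first place. The default `reg_weight`
of 0.05 per mm^4 suits full-size mouse fields of view; the desk-scale
sensitivity harness uses 2. A stiff warp is also what protects pathology
from being absorbed by registration: an aggressive warp can annihilate a
group difference in the warped maps without the coarse-basis Jacobian
restoring it, which we verified directly on phantoms.

Modulation multiplies the warped GM map by the warp's Jacobian determinant
(computed analytically from the basis derivatives), conserving total tissue
quantity; folding (non-positive determinants) is reported, not forbidden.
Smoothing is a separable Gaussian specified by FWHM in micrometres of world
space (default 400 for in vivo mouse work, the matched-filter scale for
small structures); each source voxel's outgoing kernel mass is renormalised
at the boundary, so the total intensity is conserved exactly and the
operator stays linear.

# GLM, FDR and random-field FWE

The design has two group-indicator columns plus either one mean-centred TIV
column or per-group mean-centred TIV columns (the TIV-by-genotype
interaction used for the 6-vs-6 in vivo style analysis, giving 8 error
degrees of freedom for 12 scans). Fitting is ordinary least squares per
voxel inside a mask (default: cohort-mean smoothed modulated GM above
0.05); residuals are retained. The one-tailed t contrast tests the stated
direction (control GM exceeding disease GM); any 1-row contrast squares
exactly to the corresponding F map.

FDR control is Benjamini–Hochberg without the log-factor correction
(positive regression dependence is assumed, the standard choice for
voxelwise VBM). FWE control offers:

* the RFT height threshold: the smallest height at which the expected Euler
  characteristic of the excursion set equals alpha, using the standard
  Euler-characteristic densities of t and F fields and resel counts of the
  actual mask. Resels come from the discrete count of in-mask points,
  edges, faces and cubes; the component-field FWHM per axis is estimated
  from the mean squared spatial derivative of the unit-normalised
  residuals, `FWHM = sqrt(4 log 2 / mean((du)^2))`. For white noise this
  estimator's exact value is 1.18 voxels; for noise smoothed at a known
  kernel it recovers the kernel FWHM within a few percent.
* a permutation threshold: the `(1 - alpha)` quantile of a supplied
  max-statistic null distribution.

Cluster reporting labels suprathreshold voxels by 26-neighbour connectivity
(6 optionally) and reports extents and bregma-relative peak coordinates.
Cluster-level significance, where wanted, is by permutation of the maximum
extent; no analytic cluster p-values are computed.

# Validation framework

*Residual normality.* The QQ coefficient correlates sorted residuals with
standard-normal quantiles at the Blom plotting positions
`(j - 3/8)/(J + 1/4)`; the quantile is `sqrt(2) * erfinv(2p - 1)`, i.e.
`qnorm(p)`. (A typeset variant with a leading 2 instead of sqrt(2) differs
only by a constant factor and leaves the correlation untouched.) The null
reference distribution is built from repeated Gaussian draws, optionally
run until every histogram bin's relative population changes by less than
0.1% between batches.

*Permutation null calibration.* `permutation_null` repeats the two-group
analysis under random balanced relabelings (sampled with replacement; the
identity labelling is not excluded), with the TIV covariate fixed to its
subject, the F-contrast `[-1 1 0]`, and either an uncorrected or an
RFT-FWE height rule. Under relabelling the design's degrees of freedom and
the residual smoothness are invariant, so the FWE threshold is estimated
once and reused across permutations — this is what makes thousands of
relabelings cheap, since only the GLM projection changes. Outputs are
per-permutation suprathreshold voxel and cluster counts, per-permutation
maxima, and a voxelwise false-positive count map renderable as
maximum-intensity projections.

*Spatial homogeneity.* The count map is tested against a common
`Binomial(n_perms, alpha)` law by a chi-square goodness of fit on the
histogram of counts. Neighbouring voxels of a smooth statistic field are
correlated, which overdisperses the histogram regardless of calibration, so
the test is run on a voxel lattice spaced beyond the smoothness FWHM
(`spacing_vox`), where counts are approximately independent.

*F-distribution comparison.* Pooled null F statistics are compared with the
theoretical F law via tabulated CDFs and the Kolmogorov–Smirnov distance.

# The phantom generator

Phantoms are stylised, not anatomically faithful: an ellipsoidal brain with
a WM core, two CSF ventricle lobes, and labelled striatum-like and
cortex-like GM regions, rendered as soft (partial-volume) probability maps
about 1.5 voxels wide at boundaries. Subject variability is a random global
affine — scale/shear SDs set to the same population values as the shipped
registration prior — plus a smooth random DCT warp whose default amplitude
(0.03 mm RMS on a 4th-order basis) produces local volume fluctuations of a
few percent, matching regional morphometric variability of inbred strains.
Intensities are class means (T2-like: CSF brightest at 1.0, GM 0.60,
WM 0.45, background 0.08) under a multiplicative `exp`-DCT bias field
(log-SD 0.05) and additive Gaussian noise (SD 0.03, an SNR in the range of
in vivo mouse T2 imaging; Rician noise is approximately Gaussian at these
SNRs). Every subject records its true tissue maps, label map, TIV, regional
GM volumes and the applied transform, and a spec plus seed reproduces a
cohort bit for bit.

Regional atrophy for disease subjects is implemented as *calibrated
rarefaction*: the GM partial volume inside the labelled region is reduced
along a smooth profile (strongest in the core, fading at the boundary),
scaled by bisection so the regional GM volume drops by exactly the
requested fraction, with the removed partial volume becoming CSF. A pure
boundary erosion of the same calibrated volume was implemented first and
rejected: at test-scale grids the eroded rim is thinner than one voxel
(depth roughly fraction/3 times the region radius) and vanishes into
partial-volume noise after the 400 um kernel, whereas rarefaction carries
the identical volumetric effect at a resolvable scale.

What passing phantom tests shows: the pipeline's statistical calibration
(null false-positive rates, threshold behaviour, residual normality
machinery) and its sensitivity to a known, calibrated volumetric effect
under realistic noise, bias and inter-subject geometry jitter. What it does
not show: robustness to real tissue-contrast heterogeneity, susceptibility
or motion artefacts, skull/scalp signal, or anatomically realistic
deformation fields.

# Problem sizes used by the shipped experiments

The packaged experiments are run at desk scale, chosen so each exercises
the full method on one CPU core:

* Null FWE calibration (`null_calibration_study`): 40 exchangeable subjects
  on a 48^3 grid at 0.1 mm, GM maps with 0.02 additive noise smoothed at
  400 um, 512 balanced relabelings, F(1, 37) design with TIV. The
  binomial-structure and spatial-homogeneity checks instead use the full
  42 + 42 validation design: with smaller cohorts the conditional
  permutation rates vary between voxels enough to overdisperse the count
  histogram relative to one shared binomial law.
* Sensitivity (`atrophy_detection_study`): 6-vs-6 cohorts on a
  32 x 40 x 26 grid with 15% striatal rarefaction, residual (post-affine)
  jitter, segmentation capped at 20 iterations, a 5 x 5 x 4 basis warp with
  weight 2 per mm^4, FDR q < 0.05, overlap scored as Dice against the true
  atrophy mask.
* Full in-vivo-sized cohorts (128 x 96 x 100 um voxels) generate in well
  under a minute; the preprocessing stages scale linearly in voxel count.

# Known limitations

* The warp update is not interleaved inside the segmentation loop; the
  stage-wise decomposition (segment, then normalise the GM posterior) is
  modular and testable but gives up the small mutual benefit of joint
  estimation.
* The segmentation has no Markov-random-field spatial regularisation and no
  skull/scalp classes; TIV carries a residual partial-volume bias of a few
  percent at coarse grids.
* RFT thresholds assume stationary smoothness; phantom residual fields mix
  a smooth anatomical-jitter component with rougher sensor noise, and the
  global smoothness estimate is then conservative in the rough regions.
* The small-deformation basis warp cannot express large or fine-scale
  deformations; diffeomorphic registration is out of scope.
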