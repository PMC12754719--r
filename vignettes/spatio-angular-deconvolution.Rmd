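---
title: "Spatio-angular deconvolution for polarized fluorescence microscopy"
author: "poldecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-angular deconvolution for polarized fluorescence microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Polarized fluorescence microscopy (PFM) modulates the excitation polarization
of a 3D fluorescence microscope and records one image volume per modulation.
Because the excitation probability of a fluorescent dipole scales as
$3\cos^2\gamma$ with the angle $\gamma$ between its transition moment and the
excitation axis $\hat p$, the recorded intensities carry information about the
*orientation distribution function* (ODF) of the emitters in every resolved
voxel, entangled with the ordinary spatial blur of the instrument. The
quantity of interest is the joint spatio-angular distribution $f(\mathbf r,
\hat s)$ — a density over position and (axial) orientation — and the forward
model is a spatio-angular convolution

$$ i_{\hat p}(\mathbf r_d) = \int_{\mathbb R^3}\!\!\int_{S^2}
   h_{\hat p}(\mathbf r_d - \mathbf r_o, \hat s)\, f(\mathbf r_o, \hat s)\,
   d\hat s\, d\mathbf r_o, $$

where $h_{\hat p}$ is the *dipole point spread function*: the irradiance
produced by a single emitter of orientation $\hat s$ under excitation
polarization $\hat p$. `poldecon` implements this forward model and a family
of inverse solvers, with the *efficient generalized Richardson–Lucy* (eGRL)
algorithm as the primary method.

## Angular representation

Dipole emission is antipodally symmetric, so all angular functions live in
the even-degree real spherical harmonics. Excitation (a $\cos^2$ law) and
emission dipole radiation are each band-limited at degree 2, and their
product at degree 4, so the entire imaging physics fits in the 15 channels
$(l,m) \in \{(0,0), (2,-2..2), (4,-4..4)\}$. This channel ordering is frozen
throughout the package (`shChannels`). The basis convention is the standard
orthonormal real basis with $Y_{1,1}\propto +x$, $Y_{1,-1}\propto +y$,
$Y_{1,0}\propto +z$ and no Condon–Shortley phase; it reproduces the
quarter-turn rotation block used to map the orthogonal detection view (the
$-1/2$ diagonal and $\sqrt3/2$ coupling entries of the degree-2 block).

Pointwise products of angular functions become Gaunt contractions of their
spectra; pointwise quotients become small per-voxel linear solves with the
Gaunt matrix $M_{lm,l'm'} = \sum G^{mm'm''}_{ll'l''}\,d_{l''m''}$ built from
the denominator spectrum. Gaunt coefficients are computed exactly through
Wigner-3j symbols and the real-to-complex change of basis, and are verified
against sphere quadrature in the test suite.

## The dipole PSF

The detection model is a vectorial pupil calculation: per dipole component,
pupil fields with an aplanatic apodization $A(\tau) =
(1-(\tau/\nu_m)^2)^{-1/4}$ inside the cutoff $\nu_c/2 = \mathrm{NA}/\lambda$,
a defocus phase $\exp(i 2\pi r_\parallel \sqrt{\nu_m^2 - \tau^2})$ per plane,
and the six dipole pupil patterns; the detector irradiance cross-terms are
Gaunt-contracted onto the six even $l \le 2$ channels. The printed pupil
functions use a dimensionless radial coordinate; we take it as
$\tau/\nu_m = \sin\theta$, which makes all six patterns consistent and
reproduces the expected transverse-over-axial detection efficiency at high
NA. Kernels are normalized so that the isotropically averaged response
integrates to one.

A wide-field system multiplies (Gaunt product) detection with the excitation
spectrum $P_{lm}(\hat p) = 4\pi Y_{lm}(\hat p)(\delta_{l0} +
\tfrac25\delta_{l2})$; a light-sheet system (SPIM) additionally confines the
kernel with the Gaussian sheet envelope $\exp(-2 (\mathbf r\cdot\hat
z)^2/w_0^2)$ along the detection axis; the orthogonal view of a dual-view
system (diSPIM) uses detection kernels rotated by 90° about $y$ — a real
Wigner block on the angular channels and an exact grid permutation in space,
as the data are registered to the first view's frame — with the envelope
along $x$. The rotation convention is pinned by an equivariance identity
tested to machine precision: rotating the excitation axis along with the
view reproduces the spatially rotated view-1 kernel exactly.

Sheet-tilt geometry: the sheet propagation axis is the view's illumination
axis rotated by the tilt angle about its detection axis, and the transverse
polarization angle $\psi$ rotates $\hat p$ in the plane orthogonal to the
propagation, with $\psi = 0$ along the detection axis. The instrument's
exact tilt mechanics are not public, so this convention is configurable
(explicit `p_hat` axes may be passed to `getScheme`).

## eGRL

Maximum-likelihood expectation-maximization for the Poisson imaging model
gives a multiplicative update (the generalized Richardson–Lucy iteration).
Implemented directly on an orientation grid (`grlReconstruct`) it is an
$O(|\text{grid}|)$-fold expansion of the data and serves here as a
brute-force oracle at small sizes. eGRL (`egrlReconstruct`) performs the same
estimation entirely in the spatial-frequency and angular-spectrum domains:

1. **Precompute** (per view): the back-projected data
   $E_{lm} = \mathcal F^{-1}\sum_p \overline{\hat H_{p,lm}}\hat I_p$ and the
   combined forward-and-back kernel
   $H^{comb}_{lm,l'm'} = \sum_p \hat H_{p,lm}\overline{\hat H_{p,l'm'}}$,
   a Hermitian channel-by-channel matrix of OTFs.
2. **FP+BP**: apply $H^{comb}$ to the current estimate — a direct object-to-
   object-space transformation.
3. **DV**: per-voxel spherical-harmonic division of the back-projected data
   by that projection (a 15×15 solve per voxel, batched in compiled code).
4. **Update**: per-voxel spherical-harmonic product of the estimate with the
   error map, truncated back to degree 4 (higher bands are invisible to the
   system operator).

Dual-view data alternate a view-A and a view-B half-update within each
iteration. Initialization is the modulation-summed raw data with an
isotropic angular part. Ten iterations are the default.

Two design points deserve emphasis:

* **Sensitivity normalization.** The bare orientation-grid GRL update must
  divide by the object-space sensitivity $\sum_p \int h_p\,d\mathbf r$
  (a function of $\hat s$). In the restructured eGRL iteration the combined
  FP+BP denominator already carries this factor: a perfect-data estimate is
  an exact fixed point of the iteration as implemented (verified to $<10^{-6}$
  with periodic operators), and dividing the ratio by the sensitivity a
  second time destroys that fixed point. The extra division is therefore
  available as an ablation toggle (`sensitivity_normalization`) but defaults
  to off.
* **Division safety.** The per-voxel Gaunt matrix is singular in empty
  space. Voxels whose projected density falls below `density_floor` (default
  $10^{-6}$ of the maximum) are frozen for that iteration, and every solve
  carries a relative ridge (`ridge`, default $10^{-9}$ of the matrix trace).

### Relationship between eGRL and the grid oracle

The two solvers share fixed points but are *not* the same algorithm: the
grid iteration divides in image space before back-projecting, the
restructured iteration divides in object space after, and multiplicative
updates on the grid generate angular content beyond degree 4 that the
spectral solver deliberately truncates. On noise-free data the two agree to
a level that scales roughly linearly with the object's anisotropy (a few
percent relative $L_2$ at GFA $\approx$ 0.1–0.2 after 5–30 iterations at
$16^3$). This residual is a property of the angular-domain reduction, not of
either implementation; both satisfy the MLEM guarantees (nonnegativity,
monotone Poisson data-fit) independently, and the acceptance suite records
the measured gap at the reference conditions.

## Baselines

* `rlDeconvolve` — scalar Richardson–Lucy with the matched flipped back
  projector, optionally alternating dual views.
* `egrlpReconstruct` — the decoupling ablation: channel-wise scalar RL, then
  per-voxel angular MLEM with the spatially integrated kernels as the
  angular response. With spatially delta kernels it coincides with eGRL
  exactly (tested). Under real blur its angular estimates degrade where the
  point spread mixes distinct orientations: on a two-orientation phantom
  (adjacent rods with orthogonal dipole axes) it scores lower GFA than eGRL
  at structure voxels, while on single-orientation tubes its pixelwise
  overfitting can instead inflate anisotropy.
* `svdReconstruct` — the per-frequency Tikhonov pseudoinverse
  $\hat F(\nu) = \sum_k \frac{\mu_k}{\mu_k^2+\eta} u_k (v_k^H \hat i)$ with
  views concatenated along the modulation axis; `etaSearch` scans
  $\eta \in 10^{-8}..10^0$ in steps of $10^{0.1}$ against a known truth,
  scoring by PSIM (ties resolve to the smallest $\eta$). Note the angular
  system is structurally rank-deficient: each view's excitation spans only
  the six $l\le2$ channels, so the per-frequency rank is at most 12 of 15
  for dual-view data — the pseudoinverse recovers the row-space component.

## Phantoms

All ground truths are `SHField`s with per-voxel band-limited delta ODFs
(`deltaODFSpectrum`): $F_{lm} = Y_{lm}(\hat n)$ with the $l>0$ bands scaled
by a factor in $[0,1]$. The truncated delta goes negative beyond the scale
$2/7$ (for $l\le4$), so phantom anisotropies default to 75% of that bound.
Geometries: the Gaussian-smoothed spherical shell and GUV membrane (radial
axes), random solid spheres (radial axes), and helical tubes (tangential
axes, anisotropy ramped along the axis — default range 0.07–0.21, i.e. 25%
to 75% of the positivity bound). The double-helix pair realizes two
DNA-like phantoms whose strand centerlines are offset along the common axis
by 554 nm (pitch 7020 nm) and 478 nm (pitch 7280 nm), both with 600 nm coil
radius; "inner space" is measured center-to-center. Helix rasterization
super-samples the tube at 3× and box-averages down; per-voxel axes are the
principal eigenvector of the accumulated tangent second moments.

## Analysis maps and metrics

`densityMap` returns the isotropic channel $F_{00}$; `gfaMap` the
generalized fractional anisotropy $\sqrt{1 - F_{00}^2/\sum F_{lm}^2}$;
`peakOrientationMap` the grid argmax of the synthesized ODF and
`principalOrientationMap` the axis maximizing the axial projection
$\sum_{\hat s'}|\hat s\cdot\hat s'| f(\hat s')$ (the plain dot product
vanishes for antipodally symmetric ODFs, so the axial form is used). Near
isotropic voxels (GFA < 0.02) and near-empty voxels are masked — the argmax
of a flat function is grid noise. `opMap` evaluates the order parameter
$\langle P_2(\hat s\cdot\hat n)\rangle$ from the $l=2$ channels with the
prefactor calibrated so a parallel delta scores exactly 1 (the printed
closed form is inconsistent with that anchor under the orthonormal basis,
so the calibrated constant is used); `opVsDistance` bins OP against an exact
Euclidean distance transform from a structure mask.

Similarity metrics: global-statistics SSIM for density volumes (the
windowed form is available behind a flag), PSIM (mean axial dot product of
peak maps), ONCC (per-voxel Pearson correlation of synthesized ODFs), OSIM
(one minus the mean squared ODF difference). Orientation comparisons are
axial throughout. Because the two density estimators compared in the
acceptance experiment reconstruct the same photon pool on different absolute
scales, SSIM there is evaluated on unit-mean-normalized volumes.

## Pipeline

`chunkPlan` tiles a volume into non-overlapping cores with a halo of
`ceil(halo * core)` voxels per face (10% by default, matching the
100-voxel-core, 10-voxel-halo working point); `blendWeights` builds
separable linear cross-fades that form an exact partition of unity;
`chunkedReconstruct` reconstructs each padded chunk independently and blends.
`motionExperiment` simulates acquisition with a rigid per-modulation object
translation (frequency-domain sub-voxel shifts) and reports the PSIM cost of
the motion relative to the static acquisition.

The motion experiment's reference profile is a zero-mean linear drift along
$x$ (the stage-scan axis), with shifts assigned in interleaved acquisition
order — both views are imaged per polarization state before the state
changes, as on the real instrument. On the triple-helix phantom this
experiment is intrinsically hard: the tangent direction completes a full
turn every pitch (1000 nm), so a drift approaching 1 µm sweeps a complete
orientation period through each voxel's polarization ratios. The measured
PSIM loss there is tens of percentage points, far above the few-percent
robustness reported for biological samples whose orientation fields vary on
much larger spatial scales; the package reports the honestly computed value.

## Numerical choices

* FFT-based convolutions zero-pad by half the PSF support per axis and crop
  after inversion; the periodic (`pad = 0`) operator pair is exactly
  self-adjoint and is used by the operator-consistency tests.
* Spherical quadrature uses Gauss–Legendre × uniform-azimuth product grids,
  exact for the stated degree; argmax searches use an antipodally
  symmetrized icosphere (subdivision 3, 642 vertices — about 5° resolution).
* Per-voxel solves run in compiled code with float64 accumulation; an
  ill-conditioned voxel falls back to a strongly ridged solve.
* Reference problem sizes: the double-helix experiment runs at $64^3$ voxels
  with $25^3$-voxel kernels and 12 modulations; the motion experiment at
  $48^3$. Kernels, volumes and iteration counts are all parameters.

## Known limitations

* No camera read-noise or offset model (Poisson only), no spectral
  bleed-through, no spatially varying PSFs, no aberration model beyond the
  aplanatic defocus phase.
* The sheet is assumed not to broaden along its propagation direction.
* Angular content beyond degree 4 is invisible to the forward operator and
  is not estimated; GFA of reconstructions is bounded accordingly.
* Synthetic phantoms exercise the estimator under exactly matched forward
  models; they do not probe registration error, refractive-index mismatch,
  or dye-photophysics effects present in real data.
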