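# poldecon

Spatio-angular image reconstruction for polarized fluorescence microscopy
(PFM) in R.

PFM modulates the excitation polarization of a 3D fluorescence microscope and
records one image volume per modulation. Because a fluorophore's excitation
probability follows a cos² law in the angle between its dipole axis and the
polarization, the stack of volumes encodes, in every diffraction-limited
voxel, an *orientation distribution function* (ODF) of the emitters —
entangled with the instrument's spatial blur. `poldecon` is for microscopists
and image-analysis developers who want to simulate this imaging process and
invert it: it reconstructs the joint density + orientation distribution
f(**r**, ŝ) from polarization-modulated stacks.

The imaging model is the spatio-angular convolution

    i_p(r) = ∫∫ h_p(r − r′, ŝ) f(r′, ŝ) dŝ dr′

with h_p the vectorial *dipole PSF* of the instrument (wide-field, light
sheet, or dual-view light sheet / diSPIM). All angular functions are carried
as real spherical-harmonic spectra on the even degrees l ≤ 4 (15 channels —
the band limit imposed by the physics). The primary solver is the
**efficient generalized Richardson–Lucy (eGRL)** algorithm: Poisson MLEM
restructured to run entirely in the spatial-frequency and angular-spectrum
domains, with a precomputed combined forward-and-back kernel, a per-voxel
spherical-harmonic division, and a spherical-harmonic product update.
Baselines included: a brute-force orientation-grid GRL oracle, the
channel-decoupled eGRL-p ablation, scalar Richardson–Lucy, and a
per-frequency Tikhonov/SVD pseudoinverse with a regularizer search.
Analysis operators produce density, peak/principal orientation, generalized
fractional anisotropy (GFA) and order-parameter (OP) maps, OP-versus-distance
curves, and the SSIM/PSIM/ONCC/OSIM quality metrics. A chunk–reconstruct–
blend pipeline handles volumes larger than memory, and a motion experiment
quantifies robustness to sample drift during acquisition.

## Worked example

Simulate a dual-view acquisition of a spherical-shell phantom whose dipoles
stand normal to the surface, reconstruct it, and inspect the maps:

```r
library(poldecon)

optics <- list(A = OpticalConfig(na_det = 1.1,  shape = 25L, view_axis = "z"),
               B = OpticalConfig(na_det = 0.67, shape = 25L, view_axis = "x"))
scheme <- getScheme("custom", psi = seq(0, 150, 30), views = c("A", "B"))
bank   <- psfBank(optics, scheme)           # 12 modulations x 15 channels

gt    <- makePhantom(phantomSpec("shell", dims = 48L, radius_vox = 15))
stack <- forwardProject(gt, bank)           # 12 noise-free volumes
noisy <- addPoissonNoise(stack, target_snr_db = 20, seed = 1)

rec <- egrlReconstruct(noisy, bank, reconConfig(iterations = 10))

g  <- defaultSphereGrid()
pk <- peakOrientationMap(rec, g)
cat("PSIM vs truth:", psim(peakOrientationMap(gt, g), pk), "\n")
cat("mean GFA on the shell:",
    mean(gfaMap(rec)[densityMap(gt) > 0.5 * max(densityMap(gt))]), "\n")
```

Typical output:

```
PSIM vs truth: 0.9043438
mean GFA on the shell: 0.3105875
```

A PSIM of 0.90 means the reconstructed per-voxel peak orientations deviate
from the true surface normals by ~25° on average (mean axial dot product of
0.90); the mean GFA of 0.31 on the shell is the phantom's designed
anisotropy (GFA 0.63, from a delta-ODF scale at 75% of the band-limited
positivity bound) attenuated by ten iterations of deconvolution from 20 dB
data. A
command-line wrapper over the same functions is installed at
`inst/cli/poldecon` (`simulate`, `reconstruct`, `analyze`, `metrics`,
`fixtures`).

See `vignettes/spatio-angular-deconvolution.Rmd` for the model, conventions,
solver details and limitations.

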