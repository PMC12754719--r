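#' Angular band limit of a spherical-harmonic expansion
#'
#' Describes the set of real spherical-harmonic channels carried by an angular
#' spectrum: all degrees `l <= lmax`, restricted (by default) to even degrees,
#' which encodes the antipodal symmetry of fluorescent dipole emission. The
#' channel order is frozen as (0,0), (2,-2)...(2,2), (4,-4)...(4,4), ...
#'
#' @slot lmax integer degree cutoff (even when `evenOnly`).
#' @slot evenOnly logical; keep only even degrees.
#' @export
setClass("BandLimit", representation(lmax = "integer", evenOnly = "logical"))

setValidity("BandLimit", function(object) {
  if (length(object@lmax) != 1L || object@lmax < 0L)
    return("lmax must be a single nonnegative integer")
  if (object@evenOnly && object@lmax %% 2L != 0L)
    return("even-only band limits require an even lmax")
  TRUE
})

#' @param lmax degree cutoff.
#' @param evenOnly keep only even degrees (default TRUE).
#' @rdname BandLimit-class
#' @export
BandLimit <- function(lmax = 4L, evenOnly = TRUE) {
  new("BandLimit", lmax = as.integer(lmax), evenOnly = isTRUE(evenOnly))
}

#' Real spherical-harmonic coefficient vector of one angular function
#'
#' @slot coeffs numeric vector, one entry per channel in the frozen order.
#' @slot bandlimit a [BandLimit-class].
#' @export
setClass("AngularSpectrum",
         representation(coeffs = "numeric", bandlimit = "BandLimit"))

setValidity("AngularSpectrum", function(object) {
  n <- nChannels(object@bandlimit)
  if (length(object@coeffs) != n)
    return(sprintf("coeffs must have %d entries for this band limit", n))
  if (!all(is.finite(object@coeffs))) return("coeffs must be finite")
  TRUE
})

#' @param coeffs numeric channel vector.
#' @param bandlimit a [BandLimit-class] (defaults to one matching the length).
#' @rdname AngularSpectrum-class
#' @export
AngularSpectrum <- function(coeffs, bandlimit = NULL) {
  if (is.null(bandlimit)) bandlimit <- .bandlimitForLength(length(coeffs))
  new("AngularSpectrum", coeffs = as.numeric(coeffs), bandlimit = bandlimit)
}

#' Discrete orientation samples on the sphere with quadrature weights
#'
#' @slot directions n x 3 matrix of unit vectors.
#' @slot weights quadrature weights in steradians (sum to 4*pi for quadrature
#'   grids; argmax grids may carry uniform nominal weights).
#' @export
setClass("SphereGrid",
         representation(directions = "matrix", weights = "numeric"))

setValidity("SphereGrid", function(object) {
  if (ncol(object@directions) != 3) return("directions must be n x 3")
  if (nrow(object@directions) != length(object@weights))
    return("weights must match directions")
  nrm <- sqrt(rowSums(object@directions^2))
  if (any(abs(nrm - 1) > 1e-12)) return("directions must be unit vectors")
  TRUE
})

#' Table of real Gaunt coefficients
#'
#' Sparse table of triple-product integrals of real spherical harmonics,
#' G(l,m,l',m',l'',m'') = integral of Y_lm Y_l'm' Y_l''m'' over the sphere.
#'
#' @slot entries data.frame with columns l1,m1,l2,m2,l3,m3,g (nonzero entries).
#' @slot lmax largest degree tabulated.
#' @export
setClass("GauntTable",
         representation(entries = "data.frame", lmax = "integer"))

#' Optical configuration of one detection view
#'
#' @slot na_det detection numerical aperture.
#' @slot n0 immersion refractive index.
#' @slot wavelength emission wavelength (nm).
#' @slot voxel isotropic voxel pitch (nm).
#' @slot shape PSF support in voxels per axis (odd).
#' @slot w0 light-sheet 1/e^2 waist (nm).
#' @slot view_axis optical (detection) axis of this view, "z" or "x".
#' @export
setClass("OpticalConfig",
         representation(na_det = "numeric", n0 = "numeric",
                        wavelength = "numeric", voxel = "numeric",
                        shape = "integer", w0 = "numeric",
                        view_axis = "character"))

setValidity("OpticalConfig", function(object) {
  if (object@na_det >= object@n0) return("na_det must be below n0")
  if (object@voxel <= 0) return("voxel pitch must be positive")
  if (object@w0 <= 0) return("light-sheet waist must be positive")
  if (any(object@shape %% 2L == 0L)) return("PSF support must be odd per axis")
  if (!object@view_axis %in% c("z", "x")) return("view_axis must be 'z' or 'x'")
  TRUE
})

#' @param na_det detection NA.
#' @param n0 immersion index.
#' @param wavelength emission wavelength in nm.
#' @param voxel voxel pitch in nm.
#' @param shape PSF support (scalar or length-3, odd).
#' @param w0 light-sheet waist in nm.
#' @param view_axis "z" (view A) or "x" (view B).
#' @rdname OpticalConfig-class
#' @export
OpticalConfig <- function(na_det = 1.1, n0 = 1.33, wavelength = 525,
                          voxel = 130, shape = 65L, w0 = 1300,
                          view_axis = "z") {
  shape <- as.integer(rep(shape, length.out = 3))
  new("OpticalConfig", na_det = na_det, n0 = n0, wavelength = wavelength,
      voxel = voxel, shape = shape, w0 = w0, view_axis = view_axis)
}

#' Ordered set of polarization modulations
#'
#' Each modulation is one acquisition setting: a view ("A" or "B"), a
#' transverse polarization angle psi (degrees), a light-sheet tilt (degrees),
#' and the derived effective excitation axis p_hat in the global frame.
#'
#' @slot states data.frame with columns view, psi, tilt.
#' @slot p_hat n x 3 matrix of unit excitation axes.
#' @slot name preset identifier.
#' @export
setClass("PolarizationScheme",
         representation(states = "data.frame", p_hat = "matrix",
                        name = "character"))

setValidity("PolarizationScheme", function(object) {
  if (nrow(object@states) < 1) return("scheme must be nonempty")
  if (nrow(object@p_hat) != nrow(object@states)) return("p_hat/states mismatch")
  nrm <- sqrt(rowSums(object@p_hat^2))
  if (any(abs(nrm - 1) > 1e-9)) return("p_hat rows must be unit vectors")
  TRUE
})

#' Polarization-modulated intensity stack
#'
#' One nonnegative 3D volume per polarization modulation, in registered global
#' coordinates.
#'
#' @slot volumes list of 3D arrays, one per modulation.
#' @slot scheme the [PolarizationScheme-class] that produced them.
#' @slot voxel voxel pitch in nm.
#' @export
setClass("PolarizedStack",
         representation(volumes = "list", scheme = "PolarizationScheme",
                        voxel = "numeric"))

setValidity("PolarizedStack", function(object) {
  if (length(object@volumes) != nrow(object@scheme@states))
    return("number of volumes must match the scheme")
  d <- dim(object@volumes[[1]])
  for (v in object@volumes) {
    if (!identical(dim(v), d)) return("all volumes must share one shape")
    if (min(v) < 0) return("intensities must be nonnegative")
  }
  TRUE
})

#' Dipole point-spread-function bank
#'
#' Per-modulation, per-channel spatial kernels H_{p,lm}(r) of the spatio-angular
#' forward model, with the matched back-projector obtained by spatial flip, and
#' the object-space sensitivity spectrum sum_p sum_r H_{p,lm}(r).
#'
#' @slot kernels list over modulations; each element a 4D array (C, kx, ky, kz).
#' @slot scheme the generating [PolarizationScheme-class].
#' @slot configs named list of per-view [OpticalConfig-class] ("A", "B").
#' @slot bandlimit band limit of the kernels (even l <= 4).
#' @slot sensitivity an [AngularSpectrum-class].
#' @slot otf_cache environment caching padded-grid OTFs.
#' @export
setClass("DipolePSFBank",
         representation(kernels = "list", scheme = "PolarizationScheme",
                        configs = "list", bandlimit = "BandLimit",
                        sensitivity = "AngularSpectrum",
                        otf_cache = "environment"))

#' Voxel field of real spherical-harmonic angular spectra
#'
#' The central data object: a band-limited spatio-angular distribution
#' f(r, s) stored as its per-voxel angular spectrum F_lm(r). The coefficient
#' array has the channel as its first dimension so one voxel's spectrum is a
#' contiguous column.
#'
#' @slot coeffs 4D numeric array (C, nx, ny, nz).
#' @slot bandlimit a [BandLimit-class].
#' @slot voxel voxel pitch in nm.
#' @export
setClass("SHField",
         representation(coeffs = "array", bandlimit = "BandLimit",
                        voxel = "numeric"))

setValidity("SHField", function(object) {
  d <- dim(object@coeffs)
  if (length(d) != 4) return("coeffs must be a 4D (C, nx, ny, nz) array")
  if (d[1] != nChannels(object@bandlimit))
    return("channel dimension must match the band limit")
  if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
  TRUE
})

#' @param coeffs 4D (C, nx, ny, nz) array.
#' @param bandlimit a [BandLimit-class]; inferred from `dim(coeffs)[1]` if NULL.
#' @param voxel voxel pitch in nm.
#' @rdname SHField-class
#' @export
SHField <- function(coeffs, bandlimit = NULL, voxel = 130) {
  if (is.null(bandlimit)) bandlimit <- .bandlimitForLength(dim(coeffs)[1])
  new("SHField", coeffs = coeffs, bandlimit = bandlimit, voxel = voxel)
}

## infer an even-only band limit from a channel count (15 -> lmax 4, 6 -> 2, ...)
.bandlimitForLength <- function(n) {
  for (lmax in seq(0L, 16L, by = 2L)) {
    if (nChannels(BandLimit(lmax)) == n) return(BandLimit(lmax))
  }
  stop("cannot infer a band limit from ", n, " channels")
}
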