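#' Number of spherical-harmonic channels
#' @param x a [BandLimit-class], [AngularSpectrum-class] or [SHField-class].
#' @return integer channel count (15 for the default even-l, lmax=4 band).
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
setMethod("nChannels", "BandLimit", function(x) {
  ls <- if (x@evenOnly) seq(0L, x@lmax, by = 2L) else seq(0L, x@lmax)
  sum(2L * ls + 1L)
})

#' @rdname nChannels
setMethod("nChannels", "AngularSpectrum", function(x) length(x@coeffs))

#' @rdname nChannels
setMethod("nChannels", "SHField", function(x) dim(x@coeffs)[1])

#' Channel (l, m) index table
#' @param x a [BandLimit-class].
#' @return data.frame with columns `l` and `m` in the frozen channel order.
#' @export
setGeneric("shChannels", function(x) standardGeneric("shChannels"))

#' @rdname shChannels
setMethod("shChannels", "BandLimit", function(x) {
  ls <- if (x@evenOnly) seq(0L, x@lmax, by = 2L) else seq(0L, x@lmax)
  do.call(rbind, lapply(ls, function(l) data.frame(l = l, m = seq(-l, l))))
})

#' Coefficient access
#' @param x an [AngularSpectrum-class] or [SHField-class].
#' @return numeric vector (spectrum) or 4D array (field).
#' @export
setGeneric("coeffs", function(x) standardGeneric("coeffs"))
#' @rdname coeffs
setMethod("coeffs", "AngularSpectrum", function(x) x@coeffs)
#' @rdname coeffs
setMethod("coeffs", "SHField", function(x) x@coeffs)

#' Band limit access
#' @param x an object carrying a band limit.
#' @export
setGeneric("bandLimit", function(x) standardGeneric("bandLimit"))
#' @rdname bandLimit
setMethod("bandLimit", "AngularSpectrum", function(x) x@bandlimit)
#' @rdname bandLimit
setMethod("bandLimit", "SHField", function(x) x@bandlimit)
#' @rdname bandLimit
setMethod("bandLimit", "DipolePSFBank", function(x) x@bandlimit)

#' Spatial dimensions of a voxel object
#' @param x an [SHField-class] or [PolarizedStack-class].
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))
#' @rdname spatialDim
setMethod("spatialDim", "SHField", function(x) dim(x@coeffs)[-1])
#' @rdname spatialDim
setMethod("spatialDim", "PolarizedStack", function(x) dim(x@volumes[[1]]))

#' Stack volumes access
#' @param x a [PolarizedStack-class].
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))
#' @rdname volumes
setMethod("volumes", "PolarizedStack", function(x) x@volumes)

#' Scheme access
#' @param x a [PolarizedStack-class] or [DipolePSFBank-class].
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname scheme
setMethod("scheme", "PolarizedStack", function(x) x@scheme)
#' @rdname scheme
setMethod("scheme", "DipolePSFBank", function(x) x@scheme)

#' Forward kernels and matched back-projector kernels of a PSF bank
#' @param x a [DipolePSFBank-class].
#' @return list over modulations of 4D (C, kx, ky, kz) arrays.
#' @export
setGeneric("kernels", function(x) standardGeneric("kernels"))
#' @rdname kernels
setMethod("kernels", "DipolePSFBank", function(x) x@kernels)

#' @rdname kernels
#' @export
setGeneric("backKernels", function(x) standardGeneric("backKernels"))
#' @rdname kernels
setMethod("backKernels", "DipolePSFBank", function(x) {
  lapply(x@kernels, function(k) {
    out <- k
    for (c in seq_len(dim(k)[1])) out[c, , , ] <- .flipKernel(k[c, , , ])
    out
  })
})

#' Object-space sensitivity spectrum of a PSF bank
#' @param x a [DipolePSFBank-class].
#' @return an [AngularSpectrum-class]: sum over modulations and space of the
#'   kernels, the normalization term of the MLEM update.
#' @export
setGeneric("sensitivitySpectrum", function(x) standardGeneric("sensitivitySpectrum"))
#' @rdname sensitivitySpectrum
setMethod("sensitivitySpectrum", "DipolePSFBank", function(x) x@sensitivity)

setMethod("show", "BandLimit", function(object) {
  cat(sprintf("BandLimit: lmax=%d%s, %d channels\n", object@lmax,
              if (object@evenOnly) " (even degrees)" else "",
              nChannels(object)))
})

setMethod("show", "AngularSpectrum", function(object) {
  cat(sprintf("AngularSpectrum with %d channels (lmax=%d)\n",
              nChannels(object), object@bandlimit@lmax))
  ch <- shChannels(object@bandlimit)
  print(stats::setNames(round(object@coeffs, 5),
                        sprintf("(%d,%d)", ch$l, ch$m)))
})

setMethod("show", "SphereGrid", function(object) {
  cat(sprintf("SphereGrid: %d directions, total weight %.6f sr\n",
              nrow(object@directions), sum(object@weights)))
})

setMethod("show", "GauntTable", function(object) {
  cat(sprintf("GauntTable: lmax=%d, %d nonzero entries\n", object@lmax,
              nrow(object@entries)))
})

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf(
    "OpticalConfig: NA %.2f / n0 %.2f, lambda %g nm, voxel %g nm, support %s, w0 %g nm, axis %s\n",
    object@na_det, object@n0, object@wavelength, object@voxel,
    paste(object@shape, collapse = "x"), object@w0, object@view_axis))
})

setMethod("show", "PolarizationScheme", function(object) {
  tab <- table(object@states$view)
  cat(sprintf("PolarizationScheme '%s': %d modulations (%s)\n", object@name,
              nrow(object@states),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "PolarizedStack", function(object) {
  cat(sprintf("PolarizedStack: %d modulations of %s voxels, pitch %g nm\n",
              length(object@volumes),
              paste(spatialDim(object), collapse = "x"), object@voxel))
})

setMethod("show", "DipolePSFBank", function(object) {
  cat(sprintf("DipolePSFBank: %d modulations, %d channels, support %s\n",
              length(object@kernels), nChannels(object@bandlimit),
              paste(dim(object@kernels[[1]])[-1], collapse = "x")))
})

setMethod("show", "SHField", function(object) {
  cat(sprintf("SHField: %s voxels x %d channels (lmax=%d), pitch %g nm\n",
              paste(spatialDim(object), collapse = "x"), nChannels(object),
              object@bandlimit@lmax, object@voxel))
})
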