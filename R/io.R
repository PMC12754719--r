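## TIFF + structured-text-sidecar I/O for spectral fields and polarized
## stacks. Volumes are stored as multi-page 32-bit float TIFF with a YAML
## sidecar recording shapes, axis order, the frozen channel ordering and
## provenance.

.sidecarPath <- function(path) paste0(path, ".yaml")

## the tiff writer stores samples on [0, 1]; volumes are affinely mapped
## there and the (offset, scale) pair recorded in the sidecar
.tiffScale <- function(pages) {
  lo <- min(vapply(pages, min, 0))
  hi <- max(vapply(pages, max, 0))
  sc <- if (hi > lo) hi - lo else 1
  list(offset = lo, scale = sc,
       pages = lapply(pages, function(p) (p - lo) / sc))
}

#' Write / read an SHField as multi-page float TIFF
#'
#' Pages are ordered channel-major: all z-planes of channel 1, then channel 2,
#' and so on. The sidecar (`<path>.yaml`) records the shape, voxel pitch,
#' band limit, channel ordering table and any provenance passed in `meta`.
#'
#' @param field an [SHField-class].
#' @param path output TIFF path.
#' @param meta optional named list of provenance entries.
#' @return `path`, invisibly.
#' @export
writeSHField <- function(field, path, meta = list()) {
  d <- spatialDim(field)
  C <- nChannels(field)
  pages <- vector("list", C * d[3])
  i <- 0
  for (c in seq_len(C)) for (z in seq_len(d[3])) {
    i <- i + 1
    pages[[i]] <- field@coeffs[c, , , z]
  }
  ts <- .tiffScale(pages)
  tiff::writeTIFF(ts$pages, path, bits.per.sample = 32L, reduce = FALSE)
  ch <- shChannels(field@bandlimit)
  yaml::write_yaml(c(list(
    type = "SHField", dims = as.integer(d), channels = C,
    lmax = field@bandlimit@lmax, even_only = field@bandlimit@evenOnly,
    offset = ts$offset, scale = ts$scale,
    voxel_nm = field@voxel, page_order = "channel-major (z fastest)",
    channel_table = paste(sprintf("(%d,%d)", ch$l, ch$m), collapse = " ")),
    meta), .sidecarPath(path))
  invisible(path)
}

#' @rdname writeSHField
#' @export
readSHField <- function(path) {
  info <- yaml::read_yaml(.sidecarPath(path))
  if (!identical(info$type, "SHField")) stop("not an SHField file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- info$dims
  C <- info$channels
  co <- array(0, c(C, d))
  i <- 0
  for (c in seq_len(C)) for (z in seq_len(d[3])) {
    i <- i + 1
    co[c, , , z] <- pages[[i]] * info$scale + info$offset
  }
  SHField(co, BandLimit(info$lmax, info$even_only), info$voxel_nm)
}

#' Write / read a polarized stack as multi-page float TIFF
#'
#' Pages ordered modulation-major (z fastest); the sidecar stores the scheme
#' states (view, psi, tilt) so the stack round-trips with its scheme.
#'
#' @param stack a [PolarizedStack-class].
#' @param path output TIFF path.
#' @param meta optional named list of provenance entries.
#' @return `path`, invisibly.
#' @export
writePolarizedStack <- function(stack, path, meta = list()) {
  d <- spatialDim(stack)
  P <- length(stack@volumes)
  pages <- vector("list", P * d[3])
  i <- 0
  for (p in seq_len(P)) for (z in seq_len(d[3])) {
    i <- i + 1
    pages[[i]] <- stack@volumes[[p]][, , z]
  }
  ts <- .tiffScale(pages)
  tiff::writeTIFF(ts$pages, path, bits.per.sample = 32L, reduce = FALSE)
  st <- stack@scheme@states
  yaml::write_yaml(c(list(
    type = "PolarizedStack", dims = as.integer(d), modulations = P,
    offset = ts$offset, scale = ts$scale,
    voxel_nm = stack@voxel, scheme_name = stack@scheme@name,
    page_order = "modulation-major (z fastest)",
    view = st$view, psi = st$psi, tilt = st$tilt,
    p_hat = as.numeric(t(stack@scheme@p_hat))), meta),
    .sidecarPath(path))
  invisible(path)
}

#' @rdname writePolarizedStack
#' @export
readPolarizedStack <- function(path) {
  info <- yaml::read_yaml(.sidecarPath(path))
  if (!identical(info$type, "PolarizedStack")) stop("not a stack file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- info$dims
  P <- info$modulations
  vols <- vector("list", P)
  i <- 0
  for (p in seq_len(P)) {
    v <- array(0, d)
    for (z in seq_len(d[3])) {
      i <- i + 1
      v[, , z] <- pages[[i]] * info$scale + info$offset
    }
    v[v < 0 & v > -1e-6 * info$scale] <- 0   # quantization of exact zeros
    vols[[p]] <- v
  }
  st <- data.frame(view = info$view, psi = info$psi, tilt = info$tilt)
  p_hat <- matrix(info$p_hat, ncol = 3, byrow = TRUE)
  p_hat <- p_hat / sqrt(rowSums(p_hat^2))   # undo sidecar rounding
  scheme <- new("PolarizationScheme", states = st, p_hat = p_hat,
                name = info$scheme_name %||% "custom")
  PolarizedStack(vols, scheme, info$voxel_nm)
}
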