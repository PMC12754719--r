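#' @useDynLib poldecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats fft rnorm rpois runif sd var
NULL

.pd_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angle` radians
#' about the unit vector `axis`.
#'
#' @param axis numeric length-3 unit vector.
#' @param angle rotation angle in radians.
#' @return a 3x3 orthogonal matrix `R` with `det(R) = 1`.
#' @export
rotationMatrix <- function(axis, angle) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be nonzero")
  a <- axis / nrm
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## centered voxel coordinates (in voxel units) along one axis of length n
.centeredAxis <- function(n) seq_len(n) - (n + 1) / 2

## FFT frequencies (cycles per sample) for length n, matching fft() ordering
.fftFreq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

## zero-pad a 3D array to dimension `dims`, keeping the center voxel
## (index floor(n/2)+1 per axis) at the center of the padded grid -- the same
## origin convention .ifftshiftKernel assumes
.padArray <- function(x, dims) {
  dx <- dim(x)
  if (all(dx == dims)) return(x)
  stopifnot(all(dims >= dx))
  out <- array(0, dims)
  off <- floor(dims / 2) - floor(dx / 2)
  out[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]), off[3] + seq_len(dx[3])] <- x
  out
}

## crop a padded array back to dimension `dims` (inverse of .padArray)
.cropArray <- function(x, dims) {
  dx <- dim(x)
  if (all(dx == dims)) return(x)
  off <- floor(dx / 2) - floor(dims / 2)
  x[off[1] + seq_len(dims[1]), off[2] + seq_len(dims[2]), off[3] + seq_len(dims[3]),
    drop = FALSE]
}

## circularly shift a centered kernel so its center lands at index [1,1,1],
## the convolution-theorem origin
.ifftshiftKernel <- function(k) {
  d <- dim(k)
  ctr <- floor(d / 2) + 1
  idx <- lapply(seq_len(3), function(a) {
    i <- seq_len(d[a])
    c(i[ctr[a]:d[a]], i[seq_len(ctr[a] - 1)])
  })
  k[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

## centered OTF of a (small) centered kernel embedded in a `dims` grid
.kernelOTF <- function(kernel, dims) {
  fft(.ifftshiftKernel(.padArray(kernel, dims)))
}

.ifftReal <- function(X) Re(fft(X, inverse = TRUE)) / length(X)

## spatially flip a 3D kernel about its center voxel (odd extents assumed)
.flipKernel <- function(k) {
  k[rev(seq_len(dim(k)[1])), rev(seq_len(dim(k)[2])), rev(seq_len(dim(k)[3])),
    drop = FALSE]
}

## exact +90 degree rotation about y for centered cubic grids:
## out(r) = in(R^-1 r), R = R_y(90): x' = z, z' = -x  =>  R^-1 r = (-z, y, x).
## On a centered odd-length axis, coordinate negation is index reversal, so
## out[ix,iy,iz] = in[n+1-iz, iy, ix] -- an exact permutation.
.rotateGrid90Y <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3, d[1] == d[3])
  aperm(a[rev(seq_len(d[1])), , , drop = FALSE], c(3, 2, 1))
}

## relative L2 difference of two arrays
.relL2 <- function(a, b) {
  den <- sqrt(sum(b^2))
  if (den == 0) return(sqrt(sum(a^2)))
  sqrt(sum((a - b)^2)) / den
}
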