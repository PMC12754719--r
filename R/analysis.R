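## ODF-derived maps (density, peak/principal orientation, GFA, order
## parameter), the order-parameter-versus-distance utility, and the four
## reconstruction quality metrics.

## synthesize ODF samples for a block of voxels: returns (ngrid x nvox)
.synthBlock <- function(E, grid, bandlimit) {
  Y <- realSHBasis(grid@directions, bandlimit)
  Y %*% E
}

## representative-hemisphere convention for axial vectors: z >= 0, ties by
## y >= 0 then x >= 0
.hemisphere <- function(v) {
  flip <- v[, 3] < 0 |
    (v[, 3] == 0 & (v[, 2] < 0 | (v[, 2] == 0 & v[, 1] < 0)))
  v[flip, ] <- -v[flip, , drop = FALSE]
  v
}

#' Density map of a spatio-angular field
#'
#' The orientation-independent spatial statistic: the (0,0) channel of the
#' angular spectrum (`rho = F00`; the spherical integral of the voxel ODF is
#' `2 sqrt(pi) * rho`).
#'
#' @param field an [SHField-class].
#' @return 3D array.
#' @export
densityMap <- function(field) {
  array(field@coeffs[1, , , ], spatialDim(field))
}

#' Generalized fractional anisotropy map
#'
#' `GFA = sqrt(1 - F00^2 / sum_lm F_lm^2)` per voxel; 0 where all channels
#' vanish.
#'
#' @param field an [SHField-class].
#' @return 3D array with values in `[0, 1]`.
#' @export
gfaMap <- function(field) {
  E <- matrix(field@coeffs, nrow = nChannels(field))
  tot <- colSums(E^2)
  g <- sqrt(pmax(0, 1 - E[1, ]^2 / ifelse(tot > 0, tot, 1)))
  g[tot == 0] <- 0
  array(g, spatialDim(field))
}

## voxels worth orienting: above relative density and above GFA floor
.orientationMask <- function(field, density_thresh = 1e-3, gfa_thresh = 0.02) {
  dens <- densityMap(field)
  g <- gfaMap(field)
  dens > density_thresh * max(dens) & g > gfa_thresh
}

#' Peak orientation map
#'
#' Per voxel, the grid direction maximizing the synthesized ODF, reduced to
#' the representative hemisphere (z >= 0, ties toward +y then +x). Voxels
#' with near-zero density or near-flat ODFs (GFA below `gfa_thresh`) are
#' masked.
#'
#' @param field an [SHField-class].
#' @param grid antipodally symmetric [SphereGrid-class].
#' @param density_thresh relative density floor for the mask.
#' @param gfa_thresh flat-ODF floor for the mask.
#' @return list with `axes` (nvox x 3 matrix), `mask` (3D logical array).
#' @export
peakOrientationMap <- function(field, grid = defaultSphereGrid(),
                               density_thresh = 1e-3, gfa_thresh = 0.02) {
  dims <- spatialDim(field)
  E <- matrix(field@coeffs, nrow = nChannels(field))
  mask <- .orientationMask(field, density_thresh, gfa_thresh)
  axes <- matrix(0, prod(dims), 3)
  sel <- which(mask)
  Y <- realSHBasis(grid@directions, field@bandlimit)
  for (blk in split(sel, ceiling(seq_along(sel) / 20000))) {
    V <- Y %*% E[, blk, drop = FALSE]
    axes[blk, ] <- grid@directions[max.col(t(V), ties.method = "first"), ]
  }
  axes[sel, ] <- .hemisphere(axes[sel, , drop = FALSE])
  list(axes = axes, mask = mask)
}

#' Principal orientation map
#'
#' Per voxel, the axis maximizing the axial projection of the whole ODF,
#' `argmax_s sum_s' |s . s'| f(s')` over the grid (the absolute value makes
#' the projection well defined for antipodally symmetric ODFs).
#'
#' @inheritParams peakOrientationMap
#' @return list with `axes` and `mask` as in [peakOrientationMap()].
#' @export
principalOrientationMap <- function(field, grid = defaultSphereGrid(),
                                    density_thresh = 1e-3, gfa_thresh = 0.02) {
  dims <- spatialDim(field)
  E <- matrix(field@coeffs, nrow = nChannels(field))
  mask <- .orientationMask(field, density_thresh, gfa_thresh)
  axes <- matrix(0, prod(dims), 3)
  sel <- which(mask)
  Y <- realSHBasis(grid@directions, field@bandlimit)
  K <- abs(grid@directions %*% t(grid@directions))   # |s . s'|
  W <- K %*% (grid@weights * Y)                      # projection operator
  for (blk in split(sel, ceiling(seq_along(sel) / 20000))) {
    V <- W %*% E[, blk, drop = FALSE]
    axes[blk, ] <- grid@directions[max.col(t(V), ties.method = "first"), ]
  }
  axes[sel, ] <- .hemisphere(axes[sel, , drop = FALSE])
  list(axes = axes, mask = mask)
}

#' Order parameter map
#'
#' `OP(r, n) = <P2(s . n)>` of the voxel ODF relative to a reference axis:
#' computed from the degree-2 channels as
#' `(4 pi / 5) sum_m F_2m Y_2m(n) / (2 sqrt(pi) F00)`, calibrated so a delta
#' ODF parallel to `n` scores 1, isotropic 0, perpendicular -1/2.
#'
#' @param field an [SHField-class].
#' @param n_hat unit reference axis.
#' @param density_thresh voxels below this relative density return NA.
#' @return 3D array.
#' @export
opMap <- function(field, n_hat, density_thresh = 1e-3) {
  n_hat <- n_hat / sqrt(sum(n_hat^2))
  dims <- spatialDim(field)
  E <- matrix(field@coeffs, nrow = nChannels(field))
  Y2 <- as.numeric(realSHBasis(rbind(n_hat), BandLimit(2L)))[2:6]
  num <- (4 * pi / 5) * colSums(E[2:6, , drop = FALSE] * Y2)
  den <- 2 * sqrt(pi) * E[1, ]
  op <- ifelse(abs(den) > 0, num / den, NA_real_)
  op[E[1, ] <= density_thresh * max(E[1, ])] <- NA_real_
  array(op, dims)
}

#' Mean order parameter versus distance from a structure
#'
#' Exact Euclidean distance transform from the structure mask; OP values are
#' binned by rounded voxel distance and averaged per bin.
#'
#' @param op 3D array of order-parameter values (NAs ignored).
#' @param structure_mask 3D logical array (nonempty).
#' @return data.frame with `distance` (voxels), `mean_op`, `n`.
#' @export
opVsDistance <- function(op, structure_mask) {
  if (!any(structure_mask)) stop("empty structure mask")
  d <- dim(structure_mask)
  dist <- sqrt(cpp_edt_sq(as.logical(structure_mask), d[1], d[2], d[3]))
  bin <- round(dist)
  ok <- is.finite(op)
  agg <- tapply(op[ok], bin[ok], mean)
  cnt <- tapply(op[ok], bin[ok], length)
  data.frame(distance = as.numeric(names(agg)),
             mean_op = as.numeric(agg), n = as.numeric(cnt))
}

#' Global structural similarity of two density maps
#'
#' The single-statistics SSIM
#' `(2 mu_a mu_b + C1)(2 cov + C2) / ((mu_a^2 + mu_b^2 + C1)(var_a + var_b + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` over the whole volume. A
#' sliding-window variant (cubic box window, averaged over voxels) is
#' available via `windowed = TRUE` for cross-checking against common imaging
#' practice.
#'
#' @param a,b equally shaped numeric arrays.
#' @param data_range dynamic range L (default: max of both ranges).
#' @param windowed use the local sliding-window form.
#' @param window odd box width for the windowed form.
#' @return scalar similarity (1 for identical inputs).
#' @export
ssimMetric <- function(a, b, data_range = NULL, windowed = FALSE, window = 7L) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  L <- data_range %||% max(diff(range(a)), diff(range(b)))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  if (!windowed) {
    ma <- mean(a); mb <- mean(b)
    va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
    cab <- mean((a - ma) * (b - mb))
    return(((2 * ma * mb + C1) * (2 * cab + C2)) /
             ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  d <- dim(a)
  box <- array(0, d)
  ww <- rep(seq_len(window) - (window + 1) / 2, 1)
  k <- array(0, d)
  ctr <- floor(d / 2) + 1
  rng <- lapply(1:3, function(i) ctr[i] + ww)
  k[rng[[1]], rng[[2]], rng[[3]]] <- 1 / window^3
  Kh <- fft(.ifftshiftKernel(k))
  sm <- function(x) .ifftReal(Kh * fft(x))
  ma <- sm(a); mb <- sm(b)
  va <- pmax(sm(a^2) - ma^2, 0); vb <- pmax(sm(b^2) - mb^2, 0)
  cab <- sm(a * b) - ma * mb
  mean(((2 * ma * mb + C1) * (2 * cab + C2)) /
         ((ma^2 + mb^2 + C1) * (va + vb + C2)))
}

#' Peak-orientation similarity (PSIM)
#'
#' Spatial mean of the axial dot product `|a . b|` of two orientation maps
#' over their joint valid mask.
#'
#' @param a,b orientation maps from [peakOrientationMap()].
#' @return scalar in `[0, 1]`.
#' @export
psim <- function(a, b) {
  m <- a$mask & b$mask
  if (!any(m)) stop("empty joint mask")
  sel <- which(m)
  mean(abs(rowSums(a$axes[sel, , drop = FALSE] * b$axes[sel, , drop = FALSE])))
}

#' ODF normalized cross-correlation (ONCC)
#'
#' Per voxel, the Pearson correlation of the two synthesized ODFs over the
#' grid directions, averaged over voxels with nonzero variance in both.
#'
#' @param a,b [SHField-class] objects of equal shape and band limit.
#' @param grid a [SphereGrid-class].
#' @param mask optional logical volume restricting the average.
#' @return scalar in `[-1, 1]`.
#' @export
oncc <- function(a, b, grid = defaultSphereGrid(), mask = NULL) {
  Ea <- matrix(a@coeffs, nrow = nChannels(a))
  Eb <- matrix(b@coeffs, nrow = nChannels(b))
  sel <- if (is.null(mask)) seq_len(ncol(Ea)) else which(mask)
  Y <- realSHBasis(grid@directions, a@bandlimit)
  tot <- 0; n <- 0
  for (blk in split(sel, ceiling(seq_along(sel) / 20000))) {
    Va <- Y %*% Ea[, blk, drop = FALSE]
    Vb <- Y %*% Eb[, blk, drop = FALSE]
    Va <- sweep(Va, 2, colMeans(Va)); Vb <- sweep(Vb, 2, colMeans(Vb))
    sa <- sqrt(colSums(Va^2)); sb <- sqrt(colSums(Vb^2))
    ok <- sa > 0 & sb > 0
    r <- colSums(Va * Vb)[ok] / (sa[ok] * sb[ok])
    tot <- tot + sum(r); n <- n + sum(ok)
  }
  if (n == 0) stop("no voxels with angular variance")
  tot / n
}

#' ODF similarity (OSIM)
#'
#' `1 - mean_r mean_s (f_a(r,s) - f_b(r,s))^2` over the grid directions.
#'
#' @inheritParams oncc
#' @return scalar (1 for identical fields).
#' @export
osim <- function(a, b, grid = defaultSphereGrid(), mask = NULL) {
  Ea <- matrix(a@coeffs, nrow = nChannels(a))
  Eb <- matrix(b@coeffs, nrow = nChannels(b))
  sel <- if (is.null(mask)) seq_len(ncol(Ea)) else which(mask)
  Y <- realSHBasis(grid@directions, a@bandlimit)
  tot <- 0
  for (blk in split(sel, ceiling(seq_along(sel) / 20000))) {
    D <- Y %*% (Ea[, blk, drop = FALSE] - Eb[, blk, drop = FALSE])
    tot <- tot + sum(colMeans(D^2))
  }
  1 - tot / length(sel)
}
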