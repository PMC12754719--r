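## Synthetic spatio-angular ground-truth objects: geometric phantoms with
## controlled density, per-voxel dipole orientation, and anisotropy.

#' Band-limited delta ODF spectrum
#'
#' Spectrum of an orientation distribution concentrated along one axis
#' (antipodally symmetric): `F_lm = Y_lm(axis)` for even degrees, with the
#' anisotropic bands (l > 0) scaled by `gfa_scale`. `gfa_scale = 0` is
#' isotropic; the largest scale that keeps the truncated delta nonnegative on
#' the sphere is [gfaPositivityBound()] (2/7 for the default band).
#'
#' @param axis unit 3-vector (axial: -axis gives the same spectrum).
#' @param gfa_scale anisotropy scale in `[0, 1]`.
#' @param bandlimit a [BandLimit-class].
#' @return an [AngularSpectrum-class].
#' @export
deltaODFSpectrum <- function(axis, gfa_scale = 1, bandlimit = BandLimit(4L)) {
  axis <- axis / sqrt(sum(axis^2))
  Y <- as.numeric(realSHBasis(rbind(axis), bandlimit))
  ch <- shChannels(bandlimit)
  co <- Y * ifelse(ch$l == 0, 1, gfa_scale)
  AngularSpectrum(co, bandlimit)
}

#' Phantom specification
#'
#' @param kind one of "shell", "guv", "spheres", "helix", "triple_helix",
#'   "double_helix", "double_helix_pair".
#' @param dims volume shape in voxels.
#' @param voxel voxel pitch in nm.
#' @param gfa_scale anisotropy scale of the per-voxel delta ODFs (default 75%
#'   of the positivity bound); may ramp for helical phantoms (see `gfa_range`).
#' @param gfa_range low/high anisotropy for ramped phantoms.
#' @param seed RNG seed for randomized phantoms.
#' @param ... geometry overrides (see Details: `radius_vox`, `sigma`,
#'   `n_spheres`, `coil_radius`, `pitch`, `tube_radius`, `inner_space`,
#'   `axis`, `density`).
#' @return a list of class `PhantomSpec`.
#' @export
phantomSpec <- function(kind, dims = c(64L, 64L, 64L), voxel = 130,
                        gfa_scale = 0.75 * gfaPositivityBound(),
                        gfa_range = NULL, seed = 1L, ...) {
  structure(c(list(kind = kind, dims = as.integer(rep(dims, length.out = 3)),
                   voxel = voxel, gfa_scale = gfa_scale,
                   gfa_range = gfa_range, seed = as.integer(seed)),
              list(...)),
            class = "PhantomSpec")
}

## 3D Gaussian blur via FFT (periodic; adequate for interior structures)
.gaussianBlur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  k <- lapply(d, function(n) {
    a <- .centeredAxis(n)
    g <- exp(-a^2 / (2 * sigma^2))
    g / sum(g)
  })
  ker <- outer(outer(k[[1]], k[[2]]), k[[3]])
  dim(ker) <- d
  .ifftReal(fft(.ifftshiftKernel(ker)) * fft(x))
}

## voxel-center coordinates (nm) of a volume, centered at the grid middle
.voxelCoords <- function(dims, voxel) {
  list(x = .centeredAxis(dims[1]) * voxel,
       y = .centeredAxis(dims[2]) * voxel,
       z = .centeredAxis(dims[3]) * voxel)
}

## assemble an SHField from density + per-voxel axes + per-voxel gfa scale;
## the spectrum is scaled so the density channel F00 equals `density`
.assembleField <- function(density, axes, gfa, bandlimit, voxel) {
  dims <- dim(density)
  C <- nChannels(bandlimit)
  E <- matrix(0, C, prod(dims))
  sel <- which(density > 0)
  if (length(sel)) {
    Y <- realSHBasis(axes[sel, , drop = FALSE], bandlimit)
    ch <- shChannels(bandlimit)
    y00 <- Y[, 1]
    for (c in seq_len(C)) {
      sc <- if (ch$l[c] == 0) 1 else gfa[sel]
      E[c, sel] <- density[sel] * sc * Y[, c] / y00
    }
  }
  SHField(array(E, c(C, dims)), bandlimit, voxel)
}

## rasterize a set of 3D curves into density + axial tangent statistics.
## curves: list of data frames with columns x,y,z (nm), tx,ty,tz, gfa.
## Returns density (supersample-averaged tube indicator), per-voxel principal
## tangent and mean gfa.
.rasterizeCurves <- function(curves, dims, voxel, tube_radius, ss = 3L) {
  sdims <- dims * ss
  svox <- voxel / ss
  dens <- array(0, sdims)
  ## per-coarse-voxel tangent second moments and gfa accumulators
  N <- prod(dims)
  TT <- matrix(0, 6, N)   # xx, yy, zz, xy, xz, yz
  GG <- numeric(N); CNT <- numeric(N)
  r_cells <- ceiling(tube_radius / svox)
  off <- as.matrix(expand.grid(-r_cells:r_cells, -r_cells:r_cells,
                               -r_cells:r_cells))
  off <- off[sqrt(rowSums((off * svox)^2)) <= tube_radius, , drop = FALSE]
  ctr <- (sdims + 1) / 2
  for (cv in curves) {
    ix <- round(cv$x / svox + ctr[1])
    iy <- round(cv$y / svox + ctr[2])
    iz <- round(cv$z / svox + ctr[3])
    for (s in seq_along(ix)) {
      vx <- off[, 1] + ix[s]; vy <- off[, 2] + iy[s]; vz <- off[, 3] + iz[s]
      ok <- vx >= 1 & vx <= sdims[1] & vy >= 1 & vy <= sdims[2] &
        vz >= 1 & vz <= sdims[3]
      if (!any(ok)) next
      idx <- cbind(vx[ok], vy[ok], vz[ok])
      dens[idx] <- 1
      ## coarse voxel accumulation (one entry per curve sample)
      cx <- pmin(pmax(ceiling(vx[ok] / ss), 1), dims[1])
      cy <- pmin(pmax(ceiling(vy[ok] / ss), 1), dims[2])
      cz <- pmin(pmax(ceiling(vz[ok] / ss), 1), dims[3])
      ci <- unique(cx + (cy - 1) * dims[1] + (cz - 1) * dims[1] * dims[2])
      t <- c(cv$tx[s], cv$ty[s], cv$tz[s])
      TT[1, ci] <- TT[1, ci] + t[1] * t[1]
      TT[2, ci] <- TT[2, ci] + t[2] * t[2]
      TT[3, ci] <- TT[3, ci] + t[3] * t[3]
      TT[4, ci] <- TT[4, ci] + t[1] * t[2]
      TT[5, ci] <- TT[5, ci] + t[1] * t[3]
      TT[6, ci] <- TT[6, ci] + t[2] * t[3]
      GG[ci] <- GG[ci] + cv$gfa[s]
      CNT[ci] <- CNT[ci] + 1
    }
  }
  ## box-downsample the supersampled tube indicator
  dd <- array(dens, c(ss, dims[1], ss, dims[2], ss, dims[3]))
  density <- apply(dd, c(2, 4, 6), mean)
  axes <- matrix(0, N, 3); axes[, 3] <- 1
  gfa <- numeric(N)
  sel <- which(CNT > 0 & as.numeric(density) > 0)
  for (i in sel) {
    M <- matrix(c(TT[1, i], TT[4, i], TT[5, i],
                  TT[4, i], TT[2, i], TT[6, i],
                  TT[5, i], TT[6, i], TT[3, i]), 3, 3)
    axes[i, ] <- eigen(M, symmetric = TRUE)$vectors[, 1]
    gfa[i] <- GG[i] / CNT[i]
  }
  ## voxels touched by the tube but without samples: nearest filled neighbour
  list(density = density, axes = axes, gfa = gfa)
}

## helix curve sample table: coil of radius R and pitch along `axis`, phase
## offset ph0, spanning [-len/2, len/2] along the axis, gfa ramped over span
.helixCurve <- function(axis = c(0, 0, 1), coil_radius = 600, pitch = 1000,
                        len = 4000, center = c(0, 0, 0), phase = 0,
                        gfa_range = c(0.2, 0.2), step = 20) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  t <- seq(-len / 2, len / 2, by = step)
  th <- 2 * pi * t / pitch + phase
  pos <- outer(t, a) + coil_radius * (outer(cos(th), e1) + outer(sin(th), e2))
  pos <- sweep(pos, 2, center, `+`)
  ## unnormalized tangent: d/dt [t a + R cos th e1 + R sin th e2]
  om <- 2 * pi / pitch
  tan <- outer(rep(1, length(t)), a) +
    coil_radius * om * (outer(-sin(th), e1) + outer(cos(th), e2))
  tan <- tan / sqrt(rowSums(tan^2))
  frac <- (t - t[1]) / (t[length(t)] - t[1])
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             tx = tan[, 1], ty = tan[, 2], tz = tan[, 3],
             gfa = gfa_range[1] + frac * (gfa_range[2] - gfa_range[1]))
}

#' Generate a spatio-angular phantom
#'
#' Geometric ground-truth objects with per-voxel band-limited delta ODFs:
#' \describe{
#'   \item{shell}{1-voxel-thick spherical shell (default radius 30 voxels),
#'     Gaussian-smoothed (sigma 2 voxels), radial dipole axes, uniform GFA.}
#'   \item{guv}{thin spherical membrane parameterized by radius in nm,
#'     radial dipole axes.}
#'   \item{spheres}{random solid spheres (radius 2-6 voxels, central density
#'     500-900 decaying as a Gaussian toward the edge), radial axes.}
#'   \item{helix}{single helical tube (coil radius 600 nm, pitch 1000 nm),
#'     tangential dipole axes, anisotropy ramped along the axis.}
#'   \item{triple_helix}{three such helices oriented along y, x and z,
#'     placed equidistantly along x.}
#'   \item{double_helix}{two intertwined strands on a common axis (600 nm
#'     coil radius) whose centerlines are offset along the axis by
#'     `inner_space` nm; `pitch` defaults to 7020 nm.}
#'   \item{double_helix_pair}{the 554 nm / 7020 nm and 478 nm / 7280 nm
#'     double helices side by side.}
#' }
#'
#' @param spec a [phantomSpec()].
#' @return an [SHField-class] ground truth.
#' @export
makePhantom <- function(spec) {
  bl <- BandLimit(4L)
  dims <- spec$dims; voxel <- spec$voxel
  gfa0 <- spec$gfa_scale
  gfa_range <- spec$gfa_range %||% c(gfa0, gfa0)
  co <- .voxelCoords(dims, voxel)
  switch(spec$kind,
    shell = , guv = {
      radius <- if (spec$kind == "shell") (spec$radius_vox %||% 30) * voxel
                else spec$radius %||% 2500
      thick <- (spec$thickness_vox %||% 1) * voxel
      sigma <- spec$sigma %||% 2
      R <- sqrt(outer(outer(co$x^2, co$y^2, `+`), co$z^2, `+`))
      dens <- array(0, dims)
      dens[abs(R - radius) < thick / 2] <- spec$density %||% 1
      dens <- .gaussianBlur3(dens, sigma)
      dens[dens < 1e-6 * max(dens)] <- 0
      ax <- cbind(rep(co$x, times = dims[2] * dims[3]),
                  rep(rep(co$y, each = dims[1]), times = dims[3]),
                  rep(co$z, each = dims[1] * dims[2]))
      nr <- sqrt(rowSums(ax^2)); nr[nr == 0] <- 1
      ax <- ax / nr
      ax[nr <= 1, ] <- rep(c(0, 0, 1), each = sum(nr <= 1))
      .assembleField(dens, ax, rep(gfa0, prod(dims)), bl, voxel)
    },
    spheres = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(spec$seed)
      n <- spec$n_spheres %||% 6L
      dens <- array(0, dims)
      axes <- matrix(rep(c(0, 0, 1), each = prod(dims)), ncol = 3)
      for (s in seq_len(n)) {
        rad <- runif(1, 2, 6)
        amp <- runif(1, 500, 900)
        ctr <- c(runif(1, rad + 1, dims[1] - rad),
                 runif(1, rad + 1, dims[2] - rad),
                 runif(1, rad + 1, dims[3] - rad))
        ix <- seq_len(dims[1]) ; iy <- seq_len(dims[2]); iz <- seq_len(dims[3])
        D2 <- outer(outer((ix - ctr[1])^2, (iy - ctr[2])^2, `+`),
                    (iz - ctr[3])^2, `+`)
        inside <- which(D2 <= rad^2)
        val <- amp * exp(-D2[inside] / (2 * (rad / 2)^2))
        keep <- val > dens[inside]
        idx <- inside[keep]
        dens[idx] <- val[keep]
        gi <- arrayInd(idx, dims)
        v <- sweep(gi, 2, ctr, `-`)
        nr <- sqrt(rowSums(v^2)); nr[nr == 0] <- 1
        axes[idx, ] <- v / nr
      }
      .assembleField(dens, axes, rep(gfa0, prod(dims)), bl, voxel)
    },
    helix = , triple_helix = , double_helix = , double_helix_pair = {
      tube <- spec$tube_radius %||% voxel
      curves <- switch(spec$kind,
        helix = list(.helixCurve(
          axis = spec$axis %||% c(0, 0, 1),
          coil_radius = spec$coil_radius %||% 600,
          pitch = spec$pitch %||% 1000,
          len = spec$len %||% (0.8 * min(dims) * voxel),
          gfa_range = gfa_range)),
        triple_helix = {
          span <- (spec$box_vox %||% 20) * voxel
          offs <- (dims[1] * voxel / 4) * c(-1, 0, 1)
          axs <- list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
          lapply(1:3, function(i) .helixCurve(
            axis = axs[[i]], coil_radius = spec$coil_radius %||% 600,
            pitch = spec$pitch %||% 1000, len = span,
            center = c(offs[i], 0, 0), gfa_range = gfa_range))
        },
        double_helix = {
          pitch <- spec$pitch %||% 7020
          isp <- spec$inner_space %||% 554
          len <- spec$len %||% (0.9 * dims[3] * voxel)
          list(
            .helixCurve(c(0, 0, 1), spec$coil_radius %||% 600, pitch, len,
                        center = spec$center %||% c(0, 0, 0),
                        phase = 0, gfa_range = gfa_range),
            .helixCurve(c(0, 0, 1), spec$coil_radius %||% 600, pitch, len,
                        center = spec$center %||% c(0, 0, 0),
                        phase = -2 * pi * isp / pitch, gfa_range = gfa_range))
        },
        double_helix_pair = {
          len <- spec$len %||% (0.9 * dims[3] * voxel)
          sep <- (dims[1] * voxel) / 4
          prm <- list(list(isp = 554, pitch = 7020, cx = -sep),
                      list(isp = 478, pitch = 7280, cx = sep))
          unlist(lapply(prm, function(q) list(
            .helixCurve(c(0, 0, 1), 600, q$pitch, len, center = c(q$cx, 0, 0),
                        phase = 0, gfa_range = gfa_range),
            .helixCurve(c(0, 0, 1), 600, q$pitch, len, center = c(q$cx, 0, 0),
                        phase = -2 * pi * q$isp / q$pitch,
                        gfa_range = gfa_range))), recursive = FALSE)
        })
      ras <- .rasterizeCurves(curves, dims, voxel, tube)
      dens <- ras$density * (spec$density %||% 1)
      .assembleField(dens, ras$axes, ras$gfa, bl, voxel)
    },
    stop("unknown phantom kind: ", spec$kind))
}
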