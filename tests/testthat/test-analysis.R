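## a one-voxel field from a coefficient vector
one_voxel <- function(co) SHField(array(co, c(15, 1, 1, 1)), voxel = 130)

test_that("density, GFA and OP maps evaluate their closed forms", {
  dims <- c(4L, 4L, 4L)
  E <- array(0, c(15, dims)); E[1, , , ] <- 7
  f <- SHField(E, voxel = 130)
  expect_equal(densityMap(f), array(7, dims))
  expect_equal(densityMap(SHField(E * 0, voxel = 130)), array(0, dims))
  expect_equal(gfaMap(f), array(0, dims))
  ## equal power split between the isotropic and one l=2 channel
  co <- rep(0, 15); co[1] <- 1; co[4] <- 1
  expect_equal(gfaMap(one_voxel(co))[1], sqrt(0.5), tolerance = 1e-12)
  ## GFA of the full band-limited delta
  expect_equal(gfaMap(one_voxel(coeffs(deltaODFSpectrum(c(0, 1, 0), 1))))[1],
               sqrt(14 / 15), tolerance = 1e-10)
  ## OP calibration: parallel delta 1, isotropic 0, perpendicular -1/2
  dl <- one_voxel(coeffs(deltaODFSpectrum(c(0, 0, 1), 1)))
  expect_equal(opMap(dl, c(0, 0, 1))[1], 1, tolerance = 1e-10)
  expect_equal(opMap(dl, c(1, 0, 0))[1], -0.5, tolerance = 1e-10)
  iso <- one_voxel(c(5, rep(0, 14)))
  expect_equal(opMap(iso, c(0, 1, 0))[1], 0, tolerance = 1e-12)
  ## both maps invariant under positive per-voxel scaling
  sc <- one_voxel(3.7 * coeffs(deltaODFSpectrum(c(0, 0, 1), 0.2)))
  un <- one_voxel(coeffs(deltaODFSpectrum(c(0, 0, 1), 0.2)))
  expect_equal(gfaMap(sc)[1], gfaMap(un)[1], tolerance = 1e-12)
  expect_equal(opMap(sc, c(0, 0, 1))[1], opMap(un, c(0, 0, 1))[1],
               tolerance = 1e-12)
})

test_that("peak and principal orientation maps find and mask correctly", {
  g <- defaultSphereGrid()
  ax <- c(2, 1, 2) / 3
  dl <- one_voxel(coeffs(deltaODFSpectrum(ax, 0.25)))
  pk <- peakOrientationMap(dl, g)
  expect_true(pk$mask[1])
  expect_lt(axial_angle_deg(pk$axes[1, ], ax), 6)
  ## hemisphere convention
  expect_gte(pk$axes[1, 3], 0)
  ## isotropic voxels are masked as flat
  iso <- one_voxel(c(5, rep(0, 14)))
  expect_false(peakOrientationMap(iso, g)$mask[1])
  expect_false(principalOrientationMap(iso, g)$mask[1])
  ## single-peak symmetric ODF: principal equals peak
  pr <- principalOrientationMap(dl, g)
  expect_lt(axial_angle_deg(pr$axes[1, ], pk$axes[1, ]), 11)
  ## two equal peaks along x and y: principal axis lies in the xy bisector set
  two <- one_voxel(coeffs(deltaODFSpectrum(c(1, 0, 0), 0.25)) +
                     coeffs(deltaODFSpectrum(c(0, 1, 0), 0.25)))
  pr2 <- principalOrientationMap(two, g)
  expect_lt(abs(pr2$axes[1, 3]), 0.2)
  expect_lt(abs(abs(pr2$axes[1, 1]) - abs(pr2$axes[1, 2])), 0.2)
})

test_that("orientation maps are equivariant under a global rotation", {
  g <- defaultSphereGrid()
  D <- wignerRotationBand(BandLimit(4L), c(0, 1, 0), pi / 2)
  R <- rotationMatrix(c(0, 1, 0), pi / 2)
  withr::with_seed(8, {
    for (i in 1:4) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      co <- coeffs(deltaODFSpectrum(ax, 0.25))
      p1 <- peakOrientationMap(one_voxel(as.numeric(D %*% co)), g)$axes[1, ]
      p0 <- peakOrientationMap(one_voxel(co), g)$axes[1, ]
      expect_lt(axial_angle_deg(p1, as.numeric(R %*% p0)), 8)
    }
  })
})

test_that("order parameter versus distance recovers constructed profiles", {
  dims <- c(24L, 24L, 24L)
  mask <- array(FALSE, dims); mask[12, 12, 12] <- TRUE
  ## distance bin 0 is the structure itself
  op <- array(0.4, dims)
  tb <- opVsDistance(op, mask)
  expect_equal(tb$mean_op[tb$distance == 0], 0.4)
  expect_equal(tb$n[tb$distance == 0], 1)
  expect_true(all(abs(tb$mean_op - 0.4) < 1e-12))
  ## exponential decay in distance is recovered within binning error
  d <- sqrt(array(poldecon:::cpp_edt_sq(as.logical(mask), 24, 24, 24), dims))
  op2 <- exp(-d / 5)
  tb2 <- opVsDistance(op2, mask)
  expect_lt(max(abs(tb2$mean_op - exp(-tb2$distance / 5))), 0.06)
  expect_error(opVsDistance(op, array(FALSE, dims)), "empty")
})

test_that("the distance transform is exactly Euclidean", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  dt <- sqrt(array(poldecon:::cpp_edt_sq(as.logical(m), 9, 9, 9), c(9, 9, 9)))
  expect_equal(dt[1, 1, 1], sqrt(48), tolerance = 1e-12)
  expect_equal(dt[5, 5, 5], 0)
  expect_equal(dt[9, 5, 5], 4)
  ## two seeds: nearest wins
  m[1, 1, 1] <- TRUE
  dt2 <- sqrt(array(poldecon:::cpp_edt_sq(as.logical(m), 9, 9, 9), c(9, 9, 9)))
  expect_equal(dt2[2, 1, 1], 1)
})

test_that("SSIM follows the global-statistics closed form", {
  withr::with_seed(31, a <- array(runif(512), c(8, 8, 8)))
  expect_equal(ssimMetric(a, a), 1, tolerance = 1e-12)
  ## hand computation on a two-voxel toy with a constant offset
  x <- array(c(0, 1), c(2, 1, 1)); y <- x + 0.5
  L <- 1.5; C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- 0.5; my <- 1; vx <- 0.25; vy <- 0.25; cxy <- 0.25
  byhand <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssimMetric(x, y, data_range = 1.5), byhand, tolerance = 1e-12)
  ## inverting a structured map destroys similarity
  b <- max(a) - a
  expect_lt(ssimMetric(a, b), 0.5)
  expect_error(ssimMetric(a, array(0, c(4, 4, 4))), "shape")
  ## the windowed variant also scores identical inputs as 1
  expect_equal(ssimMetric(a, a, windowed = TRUE), 1, tolerance = 1e-10)
})

test_that("PSIM is the mean axial dot product over the joint mask", {
  dims <- c(3L, 3L, 3L)
  n <- prod(dims)
  mk <- function(axes) list(axes = axes, mask = array(TRUE, dims))
  az <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  expect_equal(psim(mk(az), mk(az)), 1)
  ax <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  expect_equal(psim(mk(az), mk(ax)), 0)
  rot <- matrix(rep(c(sin(pi / 3), 0, cos(pi / 3)), each = n), ncol = 3)
  expect_equal(psim(mk(az), mk(rot)), 0.5, tolerance = 1e-12)
  ## symmetry
  expect_equal(psim(mk(az), mk(rot)), psim(mk(rot), mk(az)))
  empty <- list(axes = az, mask = array(FALSE, dims))
  expect_error(psim(mk(az), empty), "mask")
})

test_that("ONCC and OSIM compare ODF shapes as documented", {
  f <- one_voxel(coeffs(deltaODFSpectrum(c(0, 0, 1), 0.25)))
  g <- icosphereGrid(2L)
  expect_equal(oncc(f, f, g), 1, tolerance = 1e-12)
  expect_equal(osim(f, f, g), 1, tolerance = 1e-12)
  ## scale invariance of the correlation
  f2 <- one_voxel(4 * coeffs(f)[, 1, 1, 1])
  expect_equal(oncc(f, f2, g), 1, tolerance = 1e-10)
  ## symmetry of the correlation
  h <- one_voxel(coeffs(deltaODFSpectrum(c(1, 0, 0), 0.2)))
  expect_equal(oncc(f, h, g), oncc(h, f, g), tolerance = 1e-12)
  ## anticorrelated two-sample toy: Pearson -1 on a custom 2-direction grid
  g2 <- new("SphereGrid", directions = rbind(c(0, 0, 1), c(1, 0, 0)),
            weights = c(2 * pi, 2 * pi))
  fa <- one_voxel(coeffs(deltaODFSpectrum(c(0, 0, 1), 0.25)))
  fb <- one_voxel(coeffs(deltaODFSpectrum(c(1, 0, 0), 0.25)))
  expect_equal(oncc(fa, fb, g2), -1, tolerance = 1e-10)
  ## OSIM closed form against the zero field
  z <- one_voxel(rep(0, 15))
  Y <- realSHBasis(g@directions, BandLimit(4L))
  expect_equal(osim(fa, z, g), 1 - mean((Y %*% coeffs(fa)[, 1, 1, 1])^2),
               tolerance = 1e-12)
  ## OSIM decreases as independent perturbation grows
  withr::with_seed(17, pert <- rnorm(15))
  vals <- vapply(c(0.05, 0.15, 0.4), function(s)
    osim(fa, one_voxel(coeffs(fa)[, 1, 1, 1] + s * pert), g), 0)
  expect_true(all(diff(vals) < 0))
})
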