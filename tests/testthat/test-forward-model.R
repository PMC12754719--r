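test_that("scheme presets deliver the documented modulation sets", {
  s18 <- getScheme("18V")
  expect_equal(nrow(s18@states), 18L)
  expect_equal(as.numeric(table(s18@states$view)), c(9L, 9L))
  expect_equal(nrow(getScheme("6V")@states), 6L)
  expect_equal(nrow(getScheme("8V")@states), 8L)
  expect_equal(nrow(getScheme("sim42")@states), 42L)
  sc <- getScheme("custom", psi = c(0, 60, 120), views = c("A", "B"))
  expect_equal(nrow(sc@states), 6L)
  expect_equal(sqrt(rowSums(sc@p_hat^2)), rep(1, 6), tolerance = 1e-12)
  expect_error(getScheme("27Q"), "unknown")
})

test_that("a uniform isotropic lake projects flat for transverse schemes", {
  ang <- c(0, 45, 90, 135) * pi / 180
  schT <- getScheme("custom", p_hat = cbind(cos(ang), sin(ang), 0), views = "A")
  bankT <- psfBank(list(A = test_optics()$A), schT)
  lr <- lakeResponse(bankT)
  expect_lt((max(lr) - min(lr)) / mean(lr), 1e-6)
  ## forward projection of the unit lake: all volumes identical and constant
  dims <- c(16L, 16L, 16L)
  E <- array(0, c(15, dims)); E[1, , , ] <- 2 * sqrt(pi)
  st <- forwardProject(SHField(E, voxel = 130), bankT, pad = 0)
  v <- volumes(st)
  ctr <- lapply(v, function(x) x[8, 8, 8])
  expect_lt(max(abs(unlist(ctr) - ctr[[1]])) / ctr[[1]], 1e-6)
  ## scaling the object scales the responses
  st2 <- forwardProject(SHField(3 * E, voxel = 130), bankT, pad = 0)
  expect_equal(volumes(st2)[[1]], 3 * v[[1]], tolerance = 1e-10)
})

test_that("forward projection is linear and conserves flux", {
  bank <- test_bank()
  f1 <- smooth_field(seed = 11)
  f2 <- smooth_field(seed = 12, axis = c(0, 1, 0), gfa = 0.1)
  sa <- forwardProject(f1, bank, pad = 0)
  sb <- forwardProject(f2, bank, pad = 0)
  comb <- SHField(2 * coeffs(f1) + 3 * coeffs(f2), voxel = 130)
  sc <- forwardProject(comb, bank, pad = 0)
  expect_lt(rel_l2(volumes(sc)[[2]],
                   2 * volumes(sa)[[2]] + 3 * volumes(sb)[[2]]), 1e-10)
  ## zero-frequency identity: total intensity = sum_c Fhat_c(0) Hhat_c(0)
  dims <- spatialDim(f1)
  otf <- poldecon:::.modOTF(bank, 1, dims)
  tot <- sum(vapply(1:15, function(c)
    Re(otf[[c]][1, 1, 1]) * sum(coeffs(f1)[c, , , ]), 0))
  expect_equal(sum(volumes(sa)[[1]]), tot, tolerance = 1e-8)
  ## nonnegative object projects nonnegative up to FFT ripple
  expect_gt(attr(sa, "min_preclamp"), -1e-6 * max(volumes(sa)[[1]]))
})

test_that("single-dipole contrast follows the photoselection ratio", {
  ## one bright voxel with a delta ODF along/perpendicular to p_hat,
  ## validated against a dense quadrature evaluation of the imaging integral
  cfg <- test_optics()$A
  sch <- getScheme("custom", p_hat = rbind(c(0, 1, 0)), views = "A")
  bank <- psfBank(list(A = cfg), sch)
  dims <- c(15L, 15L, 15L)
  mk <- function(axis) {
    E <- array(0, c(15, dims))
    E[, 8, 8, 8] <- coeffs(deltaODFSpectrum(axis, 1))
    SHField(E, voxel = 130)
  }
  ipar <- sum(volumes(forwardProject(mk(c(0, 1, 0)), bank, pad = 0))[[1]])
  iperp <- sum(volumes(forwardProject(mk(c(1, 0, 0)), bank, pad = 0))[[1]])
  ## quadrature oracle: i = sum_s w(s) f(s) sum_r h(r, s)
  g <- quadratureSphereGrid(16)
  Y <- realSHBasis(g@directions, BandLimit(4L))
  hsum <- as.numeric(Y %*% rowSums(matrix(kernels(bank)[[1]], nrow = 15)))
  oracle <- function(axis)
    sum(g@weights * as.numeric(Y %*% coeffs(deltaODFSpectrum(axis, 1))) * hsum)
  expect_equal(ipar, oracle(c(0, 1, 0)), tolerance = 1e-6)
  expect_equal(iperp, oracle(c(1, 0, 0)), tolerance = 1e-6)
  ## 3:0 photoselection, softened by detection coupling and band limiting
  expect_gt(ipar / iperp, 2)
})

test_that("Poisson noise injection hits the requested SNR", {
  bank <- test_bank()
  dims <- c(48L, 48L, 48L)    # >= 1e5 voxels for the empirical check
  E <- array(0, c(15, dims)); E[1, , , ] <- 40
  st <- forwardProject(SHField(E, voxel = 130), bank, pad = 0)
  for (target in c(5, 20)) {
    nz <- addPoissonNoise(st, target, seed = 7L)
    expect_lt(abs(snrDB(st, nz) - target), 0.3)
  }
  ## constant stack: alpha * S = 10^(T/10) expected counts
  flat <- PolarizedStack(lapply(volumes(st), function(v) v * 0 + 20),
                         scheme(st), 130)
  nz5 <- addPoissonNoise(flat, 5, seed = 1L)
  expect_equal(attr(nz5, "alpha") * 20, 10^0.5, tolerance = 1e-10)
  ## determinism and seed sensitivity
  a <- addPoissonNoise(st, 10, seed = 3L)
  b <- addPoissonNoise(st, 10, seed = 3L)
  cc <- addPoissonNoise(st, 10, seed = 4L)
  expect_identical(volumes(a), volumes(b))
  expect_false(identical(volumes(a), volumes(cc)))
  ## SNR of the clean stack is infinite; decreasing alpha lowers SNR
  expect_equal(snrDB(st, st), Inf)
  snrs <- vapply(c(0, 5, 10, 15), function(t)
    snrDB(st, addPoissonNoise(st, t, seed = 2L)), 0)
  expect_true(all(diff(snrs) > 0))
  empty <- PolarizedStack(lapply(volumes(st), function(v) v * 0), scheme(st), 130)
  expect_error(addPoissonNoise(empty, 5), "zero")
})

test_that("lake calibration cancels synthetic per-modulation gains", {
  bank <- test_bank()
  gt <- smooth_field(seed = 13)
  st <- forwardProject(gt, bank, pad = 0)
  P <- length(volumes(st))
  glake <- lakeResponse(bank)
  ## instrument matches model: calibration is the identity
  same <- calibrateStack(st, glake, glake, p0 = 1L)
  expect_equal(volumes(same), volumes(st), tolerance = 1e-12)
  ## synthetic instrument gains gamma_p; g_cal = gamma_p * g_lake recovers
  withr::with_seed(21, gam <- runif(P, 0.5, 2))
  gained <- PolarizedStack(lapply(seq_len(P), function(p)
    gam[p] * volumes(st)[[p]]), scheme(st), 130)
  fixed <- calibrateStack(gained, gam * glake, glake, p0 = 1L)
  ref <- gam[1] * volumes(st)[[1]]  # common reference-gain factor remains
  for (p in seq_len(P))
    expect_lt(rel_l2(volumes(fixed)[[p]], gam[1] * volumes(st)[[p]]), 1e-10)
  ## linearity
  dbl <- calibrateStack(PolarizedStack(lapply(volumes(st), `*`, 2),
                                       scheme(st), 130), glake, glake)
  expect_equal(volumes(dbl)[[3]], 2 * volumes(st)[[3]], tolerance = 1e-12)
  expect_error(calibrateStack(st, rep(0, P), glake), "positive")
})

test_that("polarized-bead mimicry scales views by the lake gains", {
  sch <- getScheme("custom", psi = c(0, 90), views = c("A", "B"))
  withr::with_seed(9, beads <- list(A = array(runif(64), c(4, 4, 4)),
                                    B = array(runif(64), c(4, 4, 4))))
  ## equal gains reproduce the view volumes untouched
  same <- mimicPolarizedBeads(beads, sch, rep(2, 4), p0 = 1L)
  expect_equal(volumes(same)[[1]], beads$A)
  expect_equal(volumes(same)[[3]], beads$B)
  ## linear in the per-modulation gain
  gl <- c(1, 2, 3, 4)
  mim <- mimicPolarizedBeads(beads, sch, gl, p0 = 1L)
  expect_equal(volumes(mim)[[2]], 2 * beads$A)
  expect_equal(volumes(mim)[[4]], 4 * beads$B)
})
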