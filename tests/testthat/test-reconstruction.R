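test_that("a perfect-data estimate is an eGRL fixed point", {
  bank <- test_bank()
  gt <- smooth_field(seed = 3, gfa = 0.2)
  stack <- forwardProject(gt, bank, pad = 0)
  cfg <- reconConfig(iterations = 1, pad = 0, ridge = 1e-13)
  r1 <- egrlReconstruct(stack, bank, cfg, init = gt)
  expect_lt(rel_l2(coeffs(r1), coeffs(gt)), 1e-6)
  ## with the extra sensitivity division the fixed point is destroyed --
  ## the documented reason the toggle defaults to off
  cfgS <- reconConfig(iterations = 1, pad = 0, sensitivity_normalization = TRUE)
  rS <- egrlReconstruct(stack, bank, cfgS, init = gt)
  expect_gt(rel_l2(coeffs(rS), coeffs(gt)), 1e-3)
})

test_that("eGRL converges on noise-free data and stays finite", {
  bank <- test_bank()
  gt <- smooth_field(seed = 3, gfa = 0.2)
  stack <- forwardProject(gt, bank, pad = 0)
  nll <- function(rec) {
    st <- forwardProject(rec, bank, pad = 0)
    s <- 0
    for (p in seq_along(volumes(st))) {
      lam <- pmax(volumes(st)[[p]], 1e-12)
      s <- s + sum(lam - volumes(stack)[[p]] * log(lam))
    }
    s
  }
  cfgs <- lapply(c(1, 3, 6), function(n) reconConfig(iterations = n, pad = 0))
  recs <- lapply(cfgs, function(cf) egrlReconstruct(stack, bank, cf))
  nlls <- vapply(recs, nll, 0)
  ## monotone data fit on noise-free data
  expect_true(all(diff(nlls) < 1e-8 * abs(nlls[1])))
  ## density channel nonnegative, all channels finite
  expect_true(all(is.finite(coeffs(recs[[3]]))))
  expect_gte(min(coeffs(recs[[3]])[1, , , ]), 0)
  expect_error(egrlReconstruct(PolarizedStack(list(), scheme(stack), 130),
                               bank))
})

test_that("modulation order does not change the eGRL estimate", {
  bank <- test_bank()
  gt <- smooth_field(seed = 4, gfa = 0.15)
  stack <- forwardProject(gt, bank, pad = 0)
  cfg <- reconConfig(iterations = 3, pad = 0)
  ra <- egrlReconstruct(stack, bank, cfg)
  ## permute modulations consistently in stack and bank
  P <- length(volumes(stack))
  withr::with_seed(10, perm <- sample(P))
  sch <- scheme(stack)
  sch2 <- new("PolarizationScheme", states = sch@states[perm, ],
              p_hat = sch@p_hat[perm, ], name = sch@name)
  st2 <- PolarizedStack(volumes(stack)[perm], sch2, 130)
  bk2 <- new("DipolePSFBank", kernels = kernels(bank)[perm], scheme = sch2,
             configs = bank@configs, bandlimit = bandLimit(bank),
             sensitivity = sensitivitySpectrum(bank),
             otf_cache = new.env(parent = emptyenv()))
  rb <- egrlReconstruct(st2, bk2, cfg)
  expect_lt(rel_l2(coeffs(rb), coeffs(ra)), 1e-10)
})

test_that("the GRL oracle keeps MLEM guarantees on the orientation grid", {
  bank <- test_bank()
  gt <- smooth_field(seed = 5, gfa = 0.15)
  stack <- forwardProject(gt, bank, pad = 0)
  grl <- grlReconstruct(stack, bank, icosphereGrid(1L),
                        reconConfig(iterations = 3, pad = 0))
  ## nonnegativity of multiplicative updates
  expect_gte(min(grl$e), 0)
  expect_true(all(is.finite(grl$e)))
  ## size guard
  big <- PolarizedStack(lapply(volumes(stack), function(v)
    array(1, c(40, 40, 40))), scheme(stack), 130)
  expect_error(grlReconstruct(big, bank), "guard")
})

test_that("scalar Richardson-Lucy honors its textbook properties", {
  ## delta PSF: any number of iterations returns the input
  withr::with_seed(12, v <- array(runif(16^3, 0.5, 2), c(16, 16, 16)))
  psf <- array(0, c(5, 5, 5)); psf[3, 3, 3] <- 1
  expect_equal(rlDeconvolve(v, psf, 5, pad = 0), v, tolerance = 1e-10)
  ## flux conservation with a normalized PSF and interior object
  g <- array(0, c(7, 7, 7))
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    g[i, j, k] <- exp(-((i - 4)^2 + (j - 4)^2 + (k - 4)^2) / 4)
  g <- g / sum(g)
  obj <- array(0, c(24, 24, 24)); obj[12, 12, 12] <- 100; obj[9, 14, 12] <- 60
  blur <- poldecon:::.ifftReal(poldecon:::.kernelOTF(g, c(24, 24, 24)) * fft(obj))
  dec5 <- rlDeconvolve(blur, g, 5, pad = 0)
  expect_equal(sum(dec5), sum(blur), tolerance = 1e-6)
  ## peak sharpens monotonically
  peaks <- vapply(c(1, 5, 10, 20), function(n)
    max(rlDeconvolve(blur, g, n, pad = 0)), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("eGRL-p equals eGRL for blur-free systems and is more isotropic under blur", {
  ## delta-kernel bank: spatial coupling vanishes, the two must agree
  cfg <- test_optics()$A
  schA <- getScheme("custom", psi = c(0, 45, 90, 135), views = "A")
  bankA <- psfBank(list(A = cfg), schA)
  for (p in seq_along(bankA@kernels)) {
    a <- rowSums(matrix(bankA@kernels[[p]], nrow = 15))
    kd <- array(0, c(15, 5, 5, 5)); kd[, 3, 3, 3] <- a
    bankA@kernels[[p]] <- kd
  }
  bankA@otf_cache <- new.env(parent = emptyenv())
  gt <- smooth_field(seed = 6, gfa = 0.15)
  st <- forwardProject(gt, bankA, pad = 0)
  cfgr <- reconConfig(iterations = 5, pad = 0)
  expect_lt(rel_l2(coeffs(egrlpReconstruct(st, bankA, cfgr)),
                   coeffs(egrlReconstruct(st, bankA, cfgr))), 1e-6)
  ## zero stack maps to the zero field
  z <- PolarizedStack(lapply(volumes(st), function(v) v * 0), schA, 130)
  expect_equal(max(abs(coeffs(egrlpReconstruct(z, bankA, cfgr)))), 0)
})

test_that("the Tikhonov/SVD solver matches its pseudoinverse limits", {
  bank <- test_bank()
  gt <- smooth_field(seed = 7, gfa = 0.15)
  stack <- forwardProject(gt, bank, pad = 0)
  dims <- spatialDim(gt)
  rec <- svdReconstruct(stack, bank, eta = 1e-10, pad = 0)
  ## per-frequency: data consistency and row-space recovery at eta -> 0
  otfs <- poldecon:::.bankOTF(bank, dims)
  P <- length(otfs)
  Ihat <- lapply(seq_len(P), function(p) fft(volumes(stack)[[p]]))
  for (fidx in list(c(1, 1, 1), c(2, 2, 1))) {
    H <- t(vapply(seq_len(P), function(p) vapply(1:15, function(c)
      otfs[[p]][[c]][fidx[1], fidx[2], fidx[3]], 0i), complex(15)))
    iv <- vapply(seq_len(P), function(p)
      Ihat[[p]][fidx[1], fidx[2], fidx[3]], 0i)
    fr <- vapply(1:15, function(c)
      fft(array(coeffs(rec)[c, , , ], dims))[fidx[1], fidx[2], fidx[3]], 0i)
    fg <- vapply(1:15, function(c)
      fft(array(coeffs(gt)[c, , , ], dims))[fidx[1], fidx[2], fidx[3]], 0i)
    s <- svd(H)
    rk <- sum(s$d > 1e-6 * max(s$d))
    Pr <- s$v[, 1:rk] %*% Conj(t(s$v[, 1:rk]))
    expect_lt(sqrt(sum(Mod(H %*% fr - iv)^2) / sum(Mod(iv)^2)), 1e-6)
    expect_lt(sqrt(sum(Mod(Pr %*% (fr - fg))^2) / sum(Mod(Pr %*% fg)^2)), 1e-6)
  }
  ## monotone shrinkage toward zero as eta grows
  nrms <- vapply(c(1e-4, 1e-1, 1e2, 1e5), function(eta)
    sqrt(sum(coeffs(svdReconstruct(stack, bank, eta = eta, pad = 0))^2)), 0)
  expect_true(all(diff(nrms) < 0))
  expect_lt(nrms[4] / sqrt(sum(coeffs(gt)^2)), 1e-3)
  expect_error(svdReconstruct(stack, bank, eta = -1))
})

test_that("the eta search scans its default grid and respects ties", {
  cfgA <- OpticalConfig(na_det = 1.1, shape = 9L, voxel = 130, w0 = 1300)
  sch <- getScheme("custom", psi = c(0, 60, 120), views = "A")
  suppressWarnings(bank <- psfBank(list(A = cfgA), sch))
  gt <- smooth_field(dims = c(10L, 10L, 10L), seed = 8, gfa = 0.2)
  stack <- forwardProject(gt, bank, pad = 0)
  res <- etaSearch(stack, bank, gt, grid = icosphereGrid(2L))
  expect_equal(length(res$etas), 81L)
  expect_equal(length(res$scores), 81L)
  ## returned eta attains the maximum score, smallest among ties
  expect_equal(res$scores[match(res$eta, res$etas)], max(res$scores))
  ties <- res$etas[res$scores >= max(res$scores) - 1e-12]
  expect_equal(res$eta, min(ties))
  expect_error(etaSearch(stack, bank, gt, etas = numeric(0)), "empty")
})
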