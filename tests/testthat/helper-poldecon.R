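## shared fixtures: small optical configs, banks and phantoms, built once per
## session and cached (detection kernels are the expensive part)

.test_env <- new.env(parent = emptyenv())

test_optics <- function(sup = 13L) {
  list(A = OpticalConfig(na_det = 1.1, shape = sup, voxel = 130, w0 = 1300,
                         view_axis = "z"),
       B = OpticalConfig(na_det = 0.67, shape = sup, voxel = 130, w0 = 1300,
                         view_axis = "x"))
}

## dual-view bank with `k` transverse angles per view, cached by key
test_bank <- function(k = 3L, sup = 13L, views = c("A", "B")) {
  key <- paste0("bank_", k, "_", sup, "_", paste(views, collapse = ""))
  if (is.null(.test_env[[key]])) {
    psi <- seq(0, 180 - 180 / k, by = 180 / k)
    sch <- getScheme("custom", psi = psi, views = views)
    .test_env[[key]] <- suppressWarnings(psfBank(test_optics(sup), sch))
  }
  .test_env[[key]]
}

## smooth strictly-positive band-limited object (periodic, so pad = 0
## operators are exact on it)
smooth_field <- function(dims = c(16L, 16L, 16L), seed = 3L, gfa = 0.2,
                         axis = c(1, 1, 1) / sqrt(3)) {
  withr::with_seed(seed, {
    E <- array(0, c(15, dims))
    bump <- poldecon:::.gaussianBlur3(array(rnorm(prod(dims)), dims), 2)
    E[1, , , ] <- 2 + bump - min(bump)
    sp <- deltaODFSpectrum(axis, gfa)
    for (c in 2:15)
      E[c, , , ] <- E[1, , , ] * coeffs(sp)[c] / coeffs(sp)[1]
    SHField(E, voxel = 130)
  })
}

rel_l2 <- function(a, b) poldecon:::.relL2(a, b)

## angular degrees between two axial unit vectors
axial_angle_deg <- function(a, b) {
  d <- pmin(1, abs(rowSums(rbind(a) * rbind(b))))
  acos(d) * 180 / pi
}
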