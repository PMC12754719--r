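## Vectorial dipole PSF models: polarized excitation spectra, diffraction
## detection kernels from a vectorial pupil calculation, and their combination
## for wide-field, light-sheet (SPIM) and dual-view (diSPIM) geometries.

#' Polarized excitation angular spectrum
#'
#' Spectrum of the excitation probability `3 cos^2(angle between s and p)` of
#' a dipole with axis `s` under linear excitation polarization `p_hat`:
#' nonzero only at degrees 0 and 2, `P_lm = 4 pi Y_lm(p_hat) (delta_l0 +
#' (2/5) delta_l2)`.
#'
#' @param p_hat unit excitation polarization axis (length-3).
#' @return an [AngularSpectrum-class] with band limit lmax = 2 (even).
#' @export
excitationSpectrum <- function(p_hat) {
  p_hat <- as.numeric(p_hat)
  if (abs(sqrt(sum(p_hat^2)) - 1) > 1e-6) stop("p_hat must be a unit vector")
  bl <- BandLimit(2L)
  Y <- as.numeric(realSHBasis(rbind(p_hat), bl))
  ch <- shChannels(bl)
  co <- 4 * pi * Y * ifelse(ch$l == 0, 1, 2 / 5)
  AngularSpectrum(co, bl)
}

## pupil grid quantities shared by the detection model
.pupilGrid <- function(config) {
  n1 <- config@shape[1]; n2 <- config@shape[2]
  nux <- .fftFreq(n1) / config@voxel
  nuy <- .fftFreq(n2) / config@voxel
  TX <- matrix(nux, n1, n2)
  TY <- matrix(nuy, n1, n2, byrow = TRUE)
  tau <- sqrt(TX^2 + TY^2)
  phi <- atan2(TY, TX)
  list(tau = tau, phi = phi)
}

#' Detection dipole PSF kernels
#'
#' Vectorial pupil calculation of the detection response of an oriented
#' dipole: pupil fields per dipole component (with aplanatic apodization and
#' a defocus phase per plane), irradiance cross-terms on the detector, and a
#' Gaunt contraction onto the even degree-0/2 angular channels. The kernels
#' are normalized so the isotropically averaged response integrates to 1.
#'
#' @param config an [OpticalConfig-class].
#' @return 4D array (6, kx, ky, kz): channels (0,0),(2,-2)...(2,2).
#' @export
detectionKernels <- function(config) {
  nc <- 2 * config@na_det / config@wavelength      # nu_c: pupil cutoff 2NA/lambda
  nm <- config@n0 / config@wavelength              # nu_m: medium cutoff n0/lambda
  if (min(config@shape) * config@voxel < 4 * config@wavelength / (2 * config@na_det))
    warning("PSF support is below 4 resolution units; kernels will be clipped")
  pg <- .pupilGrid(config)
  tau <- pg$tau; phi <- pg$phi
  inside <- tau / nc < 0.5                         # rectangle cutoff |tau| < NA/lambda
  sth <- pmin(tau / nm, 1)                         # sin(theta) in the medium
  cth <- sqrt(pmax(0, 1 - sth^2))
  A <- ifelse(inside, (pmax(1 - sth^2, 1e-12))^(-0.25), 0)
  g <- list(
    `00` = sin(phi)^2 + cos(phi)^2 * cth,
    `10` = 0.5 * sin(2 * phi) * (cth - 1),
    `01` = 0.5 * sin(2 * phi) * (cth - 1),
    `11` = cos(phi)^2 + sin(phi)^2 * cth,
    `02` = sth * cos(phi),
    `12` = sth * sin(phi))
  n1 <- config@shape[1]; n2 <- config@shape[2]; n3 <- config@shape[3]
  ## Gaunt weights G_{l,1,1}^{m, eps_j, eps_j'} with eps = (1, -1, 0) mapping
  ## dipole components (x, y, z) onto the degree-1 orders
  bl2 <- BandLimit(2L)
  ch <- shChannels(bl2)
  eps <- c(1L, -1L, 0L)
  W <- array(0, c(6, 3, 3))
  for (c in seq_len(nrow(ch))) for (j in 1:3) for (jp in 1:3)
    W[c, j, jp] <- realGaunt(ch$l[c], ch$m[c], 1, eps[j], 1, eps[jp])
  out <- array(0, c(6, n1, n2, n3))
  zs <- .centeredAxis(n3) * config@voxel
  ## centered output via fftshift of the plane-wise inverse transform
  shift1 <- function(m) {
    c1 <- floor(n1 / 2); c2 <- floor(n2 / 2)
    m[c(seq(c1 + 1, n1), seq_len(c1)), c(seq(c2 + 1, n2), seq_len(c2))]
  }
  for (iz in seq_len(n3)) {
    Phi <- exp(2i * pi * zs[iz] * sqrt(pmax(0, nm^2 - tau^2)))
    beta <- lapply(g, function(gc) shift1(fft(A * Phi * gc, inverse = TRUE)))
    B <- array(0i, c(3, 3, n1, n2))
    for (j in 1:3) for (jp in 1:3) {
      acc <- matrix(0i, n1, n2)
      for (i in 0:1) {
        bi <- beta[[paste0(i, j - 1)]]
        bip <- beta[[paste0(i, jp - 1)]]
        acc <- acc + bi * Conj(bip)
      }
      B[j, jp, , ] <- acc
    }
    for (c in 1:6) {
      acc <- matrix(0, n1, n2)
      for (j in 1:3) for (jp in 1:3)
        if (W[c, j, jp] != 0) acc <- acc + W[c, j, jp] * Re(B[j, jp, , ])
      out[c, , , iz] <- (4 * pi / 3) * acc
    }
  }
  ## unit isotropic integrated response: sum_r H00 / (2 sqrt(pi)) = 1
  s00 <- sum(out[1, , , ])
  out * (2 * sqrt(pi) / s00)
}

## Gaunt product of detection kernels (6ch, voxels) with an excitation
## spectrum (6ch) -> 15-channel system kernels
.combineDetExc <- function(det, exc) {
  tr <- .gauntTriplets(BandLimit(4L), BandLimit(2L), BandLimit(2L))
  d <- dim(det)
  D <- matrix(det, nrow = 6)
  S <- matrix(0, 15, ncol(D))
  for (t in seq_along(tr$i))
    S[tr$i[t], ] <- S[tr$i[t], ] + tr$g[t] * D[tr$j[t], ] * exc@coeffs[tr$k[t]]
  array(S, c(15, d[-1]))
}

## Gaussian light-sheet envelope along a global axis ("z" or "x")
.sheetEnvelope <- function(kern, axis, w0, voxel) {
  d <- dim(kern)
  if (axis == "z") {
    env <- exp(-2 * (.centeredAxis(d[4]) * voxel)^2 / w0^2)
    sweep(kern, 4, env, `*`)
  } else {
    env <- exp(-2 * (.centeredAxis(d[2]) * voxel)^2 / w0^2)
    sweep(kern, 2, env, `*`)
  }
}

#' System dipole PSF kernels for one polarization modulation
#'
#' Combines the detection kernels and the excitation spectrum by
#' spherical-harmonic multiplication. For `"spim"` the wide-field product is
#' confined by the Gaussian light-sheet envelope along the detection axis z;
#' `"dispim_view2"` models the orthogonal view of a dual-view system: the
#' detection kernels are rotated 90 degrees about y (real Wigner block on the
#' channels, exact grid permutation in space) and the envelope runs along x.
#'
#' @param config an [OpticalConfig-class].
#' @param p_hat unit excitation polarization axis (global frame).
#' @param modality one of "widefield", "spim", "dispim_view2".
#' @return 4D array (15, kx, ky, kz) of real kernels.
#' @export
systemPSF <- function(config, p_hat, modality = c("spim", "widefield", "dispim_view2")) {
  modality <- match.arg(modality)
  det <- .pd_cacheDetection(config)
  if (modality == "dispim_view2") {
    if (dim(det)[2] != dim(det)[4])
      stop("dispim_view2 requires a cubic PSF support")
    D2 <- wignerRotation(2, c(0, 1, 0), pi / 2)
    rot <- det
    rot[2:6, , , ] <- array(
      D2 %*% matrix(det[2:6, , , ], nrow = 5),
      c(5, dim(det)[-1]))
    for (c in 1:6) rot[c, , , ] <- .rotateGrid90Y(rot[c, , , ])
    det <- rot
  }
  sys <- .combineDetExc(det, excitationSpectrum(p_hat))
  switch(modality,
         widefield = sys,
         spim = .sheetEnvelope(sys, "z", config@w0, config@voxel),
         dispim_view2 = .sheetEnvelope(sys, "x", config@w0, config@voxel))
}

## cache detection kernels per configuration (they are expensive)
.pd_cacheDetection <- function(config) {
  key <- paste0("det_", paste(c(config@na_det, config@n0, config@wavelength,
                                config@voxel, config@shape, config@w0),
                              collapse = "_"))
  if (is.null(.pd_env[[key]])) .pd_env[[key]] <- detectionKernels(config)
  .pd_env[[key]]
}

#' Assemble a dipole PSF bank for a polarization scheme
#'
#' Builds the per-modulation, per-channel spatial kernels for every state of
#' the scheme (view A states use the SPIM model along z, view B states the
#' rotated orthogonal-view model along x; single-view schemes may request
#' `modality = "widefield"`), plus the object-space sensitivity spectrum
#' `sum_p sum_r H_p,lm(r)` used to normalize MLEM updates.
#'
#' @param configs named list of [OpticalConfig-class] per view (`A`, `B`);
#'   a single config is accepted for single-view schemes.
#' @param scheme a [PolarizationScheme-class].
#' @param modality forward geometry of view-A states ("spim" or "widefield").
#' @return a [DipolePSFBank-class].
#' @export
psfBank <- function(configs, scheme, modality = "spim") {
  if (is(configs, "OpticalConfig")) configs <- list(A = configs)
  if (!is.null(configs$B) && configs$A@voxel != configs$B@voxel)
    stop("views must share one voxel pitch")
  st <- scheme@states
  kerns <- vector("list", nrow(st))
  for (p in seq_len(nrow(st))) {
    if (st$view[p] == "A") {
      kerns[[p]] <- systemPSF(configs$A, scheme@p_hat[p, ], modality)
    } else {
      if (is.null(configs$B)) stop("scheme uses view B but no B config given")
      kerns[[p]] <- systemPSF(configs$B, scheme@p_hat[p, ], "dispim_view2")
    }
  }
  sens <- Reduce(`+`, lapply(kerns, function(k) rowSums(matrix(k, nrow = 15))))
  new("DipolePSFBank", kernels = kerns, scheme = scheme, configs = configs,
      bandlimit = BandLimit(4L), sensitivity = AngularSpectrum(sens),
      otf_cache = new.env(parent = emptyenv()))
}

## OTFs of one modulation at padded grid `dims` (list over channels); no cache
.modOTF <- function(bank, p, dims) {
  k <- bank@kernels[[p]]
  lapply(seq_len(dim(k)[1]), function(c) .kernelOTF(k[c, , , ], dims))
}

## per-modulation OTFs of a bank at padded grid `dims`, cached in the bank;
## only used at small problem sizes (GRL/SVD baselines)
.bankOTF <- function(bank, dims) {
  key <- paste(dims, collapse = "x")
  if (!is.null(bank@otf_cache[[key]])) return(bank@otf_cache[[key]])
  otfs <- lapply(seq_along(bank@kernels), function(p) .modOTF(bank, p, dims))
  bank@otf_cache[[key]] <- otfs
  otfs
}

## subset a bank to the modulations of one view
.bankSubset <- function(bank, idx) {
  sch <- bank@scheme
  sub <- new("PolarizationScheme", states = sch@states[idx, , drop = FALSE],
             p_hat = sch@p_hat[idx, , drop = FALSE], name = sch@name)
  sens <- Reduce(`+`, lapply(bank@kernels[idx],
                             function(k) rowSums(matrix(k, nrow = 15))))
  new("DipolePSFBank", kernels = bank@kernels[idx], scheme = sub,
      configs = bank@configs, bandlimit = bank@bandlimit,
      sensitivity = AngularSpectrum(sens),
      otf_cache = new.env(parent = emptyenv()))
}
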