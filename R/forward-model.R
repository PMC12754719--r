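## Polarization schemes, the spatio-angular forward projection, Poisson noise
## at a target SNR, lake calibration, and polarized-bead mimicry.

## effective excitation axis in the global (view-A registered) frame.
## Per view: detection axis d and nominal sheet propagation axis k0 are
## orthogonal; the sheet tilt rotates k0 about d; psi rotates p_hat in the
## plane orthogonal to the propagation, with e1 the in-plane direction closest
## to the detection axis.
.excitationAxis <- function(view, psi, tilt) {
  if (view == "A") { d <- c(0, 0, 1); k0 <- c(1, 0, 0) }
  else             { d <- c(1, 0, 0); k0 <- c(0, 0, 1) }
  k <- as.numeric(rotationMatrix(d, tilt * pi / 180) %*% k0)
  e1 <- d - sum(d * k) * k
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(k[2] * e1[3] - k[3] * e1[2],
          k[3] * e1[1] - k[1] * e1[3],
          k[1] * e1[2] - k[2] * e1[1])
  cos(psi * pi / 180) * e1 + sin(psi * pi / 180) * e2
}

#' Build a polarization scheme
#'
#' Presets: `"18V"` (9 transverse angles per view, no tilt), `"8V"` (4 per
#' view), `"6V"` (3 per view), `"sim42"` (7 transverse angles x 3 sheet tilts
#' of -15/0/+15 degrees per view). Explicit `psi`/`tilt`/`views` override the
#' preset angle lists; `name = "custom"` uses them directly.
#'
#' @param name preset identifier or "custom".
#' @param psi transverse polarization angles in degrees (per view).
#' @param tilt sheet tilt angles in degrees (combined with each psi).
#' @param views views to include ("A", "B" or both).
#' @param p_hat optional explicit n x 3 matrix of unit excitation axes (used
#'   for every view in `views`, bypassing the psi/tilt geometry).
#' @return a [PolarizationScheme-class].
#' @export
getScheme <- function(name = "18V", psi = NULL, tilt = NULL,
                      views = c("A", "B"), p_hat = NULL) {
  if (!is.null(p_hat)) {
    p_hat <- rbind(p_hat)
    p_hat <- p_hat / sqrt(rowSums(p_hat^2))
    st <- do.call(rbind, lapply(views, function(v)
      data.frame(view = v, psi = NA_real_, tilt = NA_real_,
                 row.names = NULL)[rep(1, nrow(p_hat)), ]))
    p <- do.call(rbind, rep(list(p_hat), length(views)))
    rownames(st) <- NULL
    return(new("PolarizationScheme", states = st, p_hat = p, name = name))
  }
  presets <- list(
    "18V"   = list(psi = seq(0, 160, by = 20), tilt = 0),
    "8V"    = list(psi = c(0, 45, 90, 135), tilt = 0),
    "6V"    = list(psi = c(0, 60, 120), tilt = 0),
    "sim42" = list(psi = seq(0, 180 - 180 / 7, by = 180 / 7),
                   tilt = c(-15, 0, 15)))
  if (name != "custom") {
    if (is.null(presets[[name]])) stop("unknown scheme preset: ", name)
    psi <- psi %||% presets[[name]]$psi
    tilt <- tilt %||% presets[[name]]$tilt
  } else if (is.null(psi)) stop("custom schemes need explicit psi angles")
  tilt <- tilt %||% 0
  st <- do.call(rbind, lapply(views, function(v)
    expand.grid(view = v, tilt = tilt, psi = psi,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  st <- st[, c("view", "psi", "tilt")]
  p <- t(mapply(.excitationAxis, st$view, st$psi, st$tilt))
  dimnames(p) <- NULL
  new("PolarizationScheme", states = st, p_hat = p, name = name)
}

#' Construct a polarized stack
#' @param volumes list of nonnegative 3D arrays, one per modulation.
#' @param scheme the generating [PolarizationScheme-class].
#' @param voxel voxel pitch in nm.
#' @return a [PolarizedStack-class].
#' @export
PolarizedStack <- function(volumes, scheme, voxel = 130) {
  new("PolarizedStack", volumes = volumes, scheme = scheme, voxel = voxel)
}

#' Spatio-angular forward projection
#'
#' Projects a band-limited spatio-angular object through a dipole PSF bank:
#' per modulation, `I_p(nu) = sum_lm H_p,lm(nu) F_lm(nu)` evaluated on a
#' zero-padded grid (padding half the PSF support per axis), inverse
#' transformed and cropped; small negative FFT ripple is clamped to zero.
#'
#' @param object an [SHField-class].
#' @param bank a [DipolePSFBank-class] sharing the band limit and pitch.
#' @param pad per-side padding in voxels (default half the kernel support).
#' @return a [PolarizedStack-class].
#' @export
forwardProject <- function(object, bank, pad = NULL) {
  dims <- spatialDim(object)
  ksz <- dim(bank@kernels[[1]])[-1]
  if (nChannels(object) != nChannels(bank@bandlimit))
    stop("object and bank band limits differ")
  pad <- pad %||% floor(max(ksz) / 2)
  pdims <- dims + 2L * pad
  C <- nChannels(bank@bandlimit)
  Fh <- lapply(seq_len(C), function(c)
    fft(.padArray(object@coeffs[c, , , ], pdims)))
  minPre <- Inf
  vols <- lapply(seq_along(bank@kernels), function(p) {
    Hp <- .modOTF(bank, p, pdims)
    acc <- Hp[[1]] * Fh[[1]]
    for (c in 2:C) acc <- acc + Hp[[c]] * Fh[[c]]
    v <- .cropArray(.ifftReal(acc), dims)
    minPre <<- min(minPre, min(v))
    v[v < 0] <- 0
    v
  })
  out <- PolarizedStack(vols, bank@scheme, object@voxel)
  attr(out, "min_preclamp") <- minPre
  out
}

#' Empirical SNR of a noisy stack (dB)
#'
#' `10 log10(mean(S^2) / mean((noisy - S)^2))` over all modulations; infinite
#' for an exact copy.
#'
#' @param signal,noisy [PolarizedStack-class] objects of equal shape.
#' @return SNR in dB.
#' @export
snrDB <- function(signal, noisy) {
  s2 <- mean(unlist(lapply(signal@volumes, function(v) mean(v^2))))
  n2 <- mean(mapply(function(a, b) mean((b - a)^2),
                    signal@volumes, noisy@volumes))
  if (n2 == 0) return(Inf)
  10 * log10(s2 / n2)
}

#' Corrupt a stack with Poisson noise at a target SNR
#'
#' Scales the clean intensities by the factor `alpha` that sets the expected
#' SNR (signal power over Poisson noise power) to the target -- for Poisson
#' counts the expectation has the closed form
#' `alpha = 10^(snr/10) mean(S) / mean(S^2)` -- draws one Poisson realization
#' per voxel, and rescales back to the input intensity scale. The applied
#' `alpha` is attached as attribute `"alpha"`.
#'
#' @param stack a clean [PolarizedStack-class] (nonnegative).
#' @param target_snr_db target SNR in dB.
#' @param seed integer seed for the Poisson draw.
#' @return a noisy [PolarizedStack-class] on the input scale.
#' @export
addPoissonNoise <- function(stack, target_snr_db, seed = 1L) {
  m1 <- mean(unlist(lapply(stack@volumes, mean)))
  m2 <- mean(unlist(lapply(stack@volumes, function(v) mean(v^2))))
  if (m2 == 0) stop("all-zero stack cannot be noise-scaled")
  alpha <- 10^(target_snr_db / 10) * m1 / m2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vols <- lapply(stack@volumes, function(v) {
    n <- array(rpois(length(v), lambda = alpha * v), dim(v))
    n / alpha
  })
  out <- PolarizedStack(vols, stack@scheme, stack@voxel)
  attr(out, "alpha") <- alpha
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-modulation lake response of a PSF bank
#'
#' Forward projection of the unit "lake" object (uniform density, isotropic
#' ODF, `f = 1`): each modulation responds with the constant
#' `2 sqrt(pi) * sum_r H_p,00(r)`; used as the model side of gain calibration.
#'
#' @param bank a [DipolePSFBank-class].
#' @return numeric vector, one mean intensity per modulation.
#' @export
lakeResponse <- function(bank) {
  vapply(bank@kernels, function(k) 2 * sqrt(pi) * sum(k[1, , , ]), numeric(1))
}

#' Gain-calibrate a raw polarized stack
#'
#' Rescales each modulation by the measured-versus-modeled gain ratio,
#' `g = raw * (g_cal(p0)/g_cal(p)) * (g_lake(p)/g_lake(p0))`, so residual
#' per-modulation instrument gains cancel against the modeled lake response.
#'
#' @param raw a [PolarizedStack-class].
#' @param g_cal measured uniform-sample means per modulation (positive).
#' @param g_lake modeled lake response per modulation (positive).
#' @param p0 index of the reference modulation.
#' @return calibrated [PolarizedStack-class]; negative results are clamped at
#'   zero (count reported via a message when any).
#' @export
calibrateStack <- function(raw, g_cal, g_lake, p0 = 1L) {
  P <- length(raw@volumes)
  if (length(g_cal) != P || length(g_lake) != P)
    stop("calibration scalars must cover all modulations")
  if (any(g_cal <= 0) || any(g_lake <= 0)) stop("calibration scalars must be positive")
  nneg <- 0L
  vols <- lapply(seq_len(P), function(p) {
    v <- raw@volumes[[p]] * (g_cal[p0] / g_cal[p]) * (g_lake[p] / g_lake[p0])
    nneg <<- nneg + sum(v < 0)
    v[v < 0] <- 0
    v
  })
  if (nneg > 0) message(nneg, " voxels clamped at zero during calibration")
  PolarizedStack(vols, raw@scheme, raw@voxel)
}

#' Mimic polarized acquisitions from unpolarized bead volumes
#'
#' For randomly oriented emitters the only effect of a polarization modulation
#' is the global lake gain, so `bead_p,v(r) = bead_v(r) g_lake(p,v) /
#' g_lake(p0,v0)`.
#'
#' @param bead_volumes named list of per-view 3D arrays (`A`, `B`).
#' @param scheme the target [PolarizationScheme-class].
#' @param g_lake lake response per modulation of the scheme.
#' @param p0 reference modulation index.
#' @param voxel voxel pitch in nm.
#' @return a [PolarizedStack-class].
#' @export
mimicPolarizedBeads <- function(bead_volumes, scheme, g_lake, p0 = 1L,
                                voxel = 130) {
  st <- scheme@states
  if (is.null(bead_volumes[[st$view[p0]]])) stop("missing reference view volume")
  vols <- lapply(seq_len(nrow(st)), function(p) {
    v <- bead_volumes[[st$view[p]]]
    if (is.null(v)) stop("missing bead volume for view ", st$view[p])
    v * g_lake[p] / g_lake[p0]
  })
  PolarizedStack(vols, scheme, voxel)
}
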