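## End-to-end orchestration: chunked crop-reconstruct-stitch with linear
## blending, and the motion-robustness experiment.

#' Deterministic chunking plan
#'
#' Tiles a volume into non-overlapping core boxes (the last chunk per axis
#' shrinks to fit) and surrounds each core with a halo of
#' `ceil(halo * core)` voxels per face, clamped at the volume edges.
#'
#' @param vol_shape volume shape (3 integers).
#' @param core core chunk size per axis (scalar or length-3).
#' @param halo halo fraction of the core per face (default 0.1).
#' @return list of class `ChunkPlan`: `shape`, `core`, `halo`, and `chunks`,
#'   each chunk holding `core_lo/core_hi/pad_lo/pad_hi` index vectors.
#' @export
chunkPlan <- function(vol_shape, core, halo = 0.1) {
  vol_shape <- as.integer(rep(vol_shape, length.out = 3))
  core <- as.integer(rep(core, length.out = 3))
  if (any(vol_shape < 1)) stop("zero-size axis")
  if (any(core > vol_shape)) stop("core size exceeds the volume")
  h <- as.integer(ceiling(halo * core))
  starts <- lapply(1:3, function(a) seq(1L, vol_shape[a], by = core[a]))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  chunks <- lapply(seq_len(nrow(grid)), function(i) {
    lo <- as.integer(grid[i, ])
    hi <- pmin(lo + core - 1L, vol_shape)
    list(core_lo = lo, core_hi = hi,
         pad_lo = pmax(lo - h, 1L), pad_hi = pmin(hi + h, vol_shape))
  })
  structure(list(shape = vol_shape, core = core, halo = halo, chunks = chunks),
            class = "ChunkPlan")
}

## per-axis blend weight vectors: linear cross-fades across padded-box
## overlaps, partition of unity along each axis
.axisWeights <- function(plan, axis) {
  segs <- unique(t(vapply(plan$chunks, function(ch)
    c(ch$core_lo[axis], ch$core_hi[axis], ch$pad_lo[axis], ch$pad_hi[axis]),
    integer(4))))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  n <- nrow(segs)
  lapply(seq_len(n), function(i) {
    pa <- segs[i, 3]; pb <- segs[i, 4]
    w <- rep(1, pb - pa + 1)
    if (i > 1) {
      ov <- segs[i - 1, 4] - pa + 1          # left overlap length
      if (ov > 0) w[seq_len(ov)] <- seq_len(ov) / (ov + 1)
    }
    if (i < n) {
      ov <- pb - segs[i + 1, 3] + 1          # right overlap length
      if (ov > 0) w[(length(w) - ov + 1):length(w)] <- rev(seq_len(ov) / (ov + 1))
    }
    list(lo = pa, w = w, key = c(segs[i, 1], segs[i, 2]))
  })
}

#' Linear blend weights of a chunk plan
#'
#' Separable linear cross-fade masks over each chunk's padded box; at every
#' voxel the weights of all covering chunks sum to one.
#'
#' @param plan a [chunkPlan()].
#' @return list of 3D weight arrays, one per chunk (padded-box extents).
#' @export
blendWeights <- function(plan) {
  aw <- lapply(1:3, function(a) .axisWeights(plan, a))
  lapply(plan$chunks, function(ch) {
    wv <- lapply(1:3, function(a) {
      cand <- aw[[a]]
      hit <- which(vapply(cand, function(s)
        all(s$key == c(ch$core_lo[a], ch$core_hi[a])), logical(1)))
      cand[[hit[1]]]$w
    })
    outer(outer(wv[[1]], wv[[2]]), wv[[3]])
  })
}

#' Chunked reconstruction with linear-blend stitching
#'
#' Splits the stack into padded chunks, reconstructs each independently with
#' [egrlReconstruct()], multiplies every chunk by its blend mask and sums the
#' results into the full-size field.
#'
#' @param stack a [PolarizedStack-class].
#' @param bank the matching [DipolePSFBank-class].
#' @param config a [reconConfig()].
#' @param core core chunk size (voxels).
#' @param halo halo fraction per face.
#' @return an [SHField-class] with the input spatial shape.
#' @export
chunkedReconstruct <- function(stack, bank, config = reconConfig(),
                               core = 100L, halo = 0.1) {
  dims <- spatialDim(stack)
  plan <- chunkPlan(dims, core, halo)
  wts <- blendWeights(plan)
  C <- nChannels(bank@bandlimit)
  out <- array(0, c(C, dims))
  for (i in seq_along(plan$chunks)) {
    ch <- plan$chunks[[i]]
    sl <- lapply(1:3, function(a) ch$pad_lo[a]:ch$pad_hi[a])
    sub <- lapply(stack@volumes, function(v) v[sl[[1]], sl[[2]], sl[[3]], drop = FALSE])
    substack <- PolarizedStack(sub, stack@scheme, stack@voxel)
    rec <- tryCatch(egrlReconstruct(substack, bank, config),
                    error = function(e) stop("chunk ", i, " failed: ",
                                             conditionMessage(e)))
    w <- wts[[i]]
    for (c in seq_len(C))
      out[c, sl[[1]], sl[[2]], sl[[3]]] <- out[c, sl[[1]], sl[[2]], sl[[3]]] +
        rec@coeffs[c, , , ] * w
  }
  SHField(out, bank@bandlimit, stack@voxel)
}

## forward projection with a rigid per-modulation object translation
## (frequency-domain sub-voxel shifts); shifts in nm, one row per modulation
.forwardProjectShifted <- function(object, bank, shifts, pad = NULL) {
  dims <- spatialDim(object)
  ksz <- dim(bank@kernels[[1]])[-1]
  pad <- pad %||% floor(max(ksz) / 2)
  pdims <- dims + 2L * pad
  C <- nChannels(object)
  Fh <- lapply(seq_len(C), function(c)
    fft(.padArray(object@coeffs[c, , , ], pdims)))
  fr <- lapply(pdims, .fftFreq)
  FX <- array(rep(fr[[1]], times = pdims[2] * pdims[3]), pdims)
  FY <- array(rep(rep(fr[[2]], each = pdims[1]), times = pdims[3]), pdims)
  FZ <- array(rep(fr[[3]], each = pdims[1] * pdims[2]), pdims)
  vols <- lapply(seq_along(bank@kernels), function(p) {
    otfp <- .modOTF(bank, p, pdims)
    sv <- shifts[p, ] / object@voxel          # shift in voxels
    ph <- exp(-2i * pi * (FX * sv[1] + FY * sv[2] + FZ * sv[3]))
    acc <- otfp[[1]] * (Fh[[1]] * ph)
    for (c in 2:C) acc <- acc + otfp[[c]] * (Fh[[c]] * ph)
    v <- .cropArray(.ifftReal(acc), dims)
    v[v < 0] <- 0
    v
  })
  PolarizedStack(vols, bank@scheme, object@voxel)
}

#' Motion-robustness experiment
#'
#' Simulates the same phantom twice -- static, and rigidly translated by a
#' per-modulation shift profile (frequency-domain sub-voxel shifts) --
#' reconstructs both with eGRL, and reports the peak-orientation similarity
#' of each against the ground truth.
#'
#' @param phantom ground-truth [SHField-class].
#' @param bank a [DipolePSFBank-class].
#' @param shifts P x 3 matrix of per-modulation object shifts in nm.
#' @param config a [reconConfig()].
#' @param grid orientation grid for peak maps.
#' @return list: `psim_static`, `psim_moving`, `degradation_percent`
#'   (`100 * (psim_static - psim_moving)`), and the applied `shifts`.
#' @export
motionExperiment <- function(phantom, bank, shifts, config = reconConfig(),
                             grid = defaultSphereGrid()) {
  P <- length(bank@kernels)
  shifts <- matrix(shifts, nrow = P, ncol = 3)
  margin <- min(spatialDim(phantom)) / 4 * phantom@voxel
  if (max(abs(shifts)) > margin)
    stop("shift exceeds the phantom margin (", round(margin), " nm)")
  gtPeak <- peakOrientationMap(phantom, grid)
  static <- forwardProject(phantom, bank)
  moving <- .forwardProjectShifted(phantom, bank, shifts)
  recS <- egrlReconstruct(static, bank, config)
  recM <- egrlReconstruct(moving, bank, config)
  ps <- psim(gtPeak, peakOrientationMap(recS, grid))
  pm <- psim(gtPeak, peakOrientationMap(recM, grid))
  list(psim_static = ps, psim_moving = pm,
       degradation_percent = 100 * (ps - pm), shifts = shifts)
}
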