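## Real spherical harmonics machinery: evaluation, synthesis/analysis on
## sphere grids, Gaunt coefficients (via Wigner 3j + real<->complex transform),
## per-spectrum products and divisions, and real Wigner rotation blocks.
##
## Convention (frozen): orthonormal real basis, int Y_lm Y_l'm' dS = delta,
## with Y_{1,1} ∝ +x, Y_{1,-1} ∝ +y, Y_{1,0} ∝ +z and no Condon-Shortley
## phase in the real basis. Channel order: (0,0), (2,-2)..(2,2), (4,-4)..(4,4).

## associated Legendre values P_l^m(x) for m = 0..l (MATLAB convention,
## Condon-Shortley phase included), rows m, columns x
.assocLegendre <- function(l, x) {
  if (l == 0) return(matrix(1, 1, length(x)))
  matrix(pracma::legendre(l, x), nrow = l + 1)
}

## n x (2l+1) matrix of real Y_{l,m}(dir), columns m = -l..l
.realSHl <- function(l, directions) {
  directions <- rbind(directions)
  ct <- pmin(pmax(directions[, 3], -1), 1)
  phi <- atan2(directions[, 2], directions[, 1])
  P <- .assocLegendre(l, ct)                       # (l+1) x n, rows m=0..l
  out <- matrix(0, nrow(directions), 2 * l + 1)
  for (m in 0:l) {
    N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0) {
      out[, l + 1] <- N * P[1, ]
    } else {
      base <- (-1)^m * sqrt(2) * N * P[m + 1, ]
      out[, l + 1 + m] <- base * cos(m * phi)
      out[, l + 1 - m] <- base * sin(m * phi)
    }
  }
  out
}

#' Evaluate one real spherical harmonic
#'
#' Orthonormal real basis function Y_lm evaluated at unit direction vectors.
#'
#' @param l degree (nonnegative integer).
#' @param m order, `|m| <= l`.
#' @param directions n x 3 matrix (or length-3 vector) of unit directions.
#' @return numeric vector of basis values, one per direction.
#' @examples
#' realSH(0, 0, c(0, 0, 1))       # 1/(2 sqrt(pi))
#' realSH(2, 0, c(0, 0, 1))       # sqrt(5/(4 pi))
#' @export
realSH <- function(l, m, directions) {
  if (abs(m) > l) stop("|m| must not exceed l")
  directions <- rbind(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  .realSHl(l, directions)[, l + 1 + m]
}

#' Real spherical-harmonic basis matrix
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param bandlimit a [BandLimit-class].
#' @return n x C matrix; column c holds Y_c evaluated at all directions, in
#'   the frozen channel order.
#' @export
realSHBasis <- function(directions, bandlimit = BandLimit(4L)) {
  directions <- rbind(directions)
  ls <- if (bandlimit@evenOnly) seq(0L, bandlimit@lmax, by = 2L)
        else seq(0L, bandlimit@lmax)
  do.call(cbind, lapply(ls, function(l) .realSHl(l, directions)))
}

## ---------------------------------------------------------------- grids ----

#' Gauss-Legendre x uniform-azimuth quadrature grid
#'
#' Product quadrature grid on the sphere, exact for spherical polynomials of
#' total degree up to `degree` (so analysis of a band-`lmax` function sampled
#' from band-`lmax` data needs `degree >= 2*lmax`).
#'
#' @param degree largest polynomial degree integrated exactly.
#' @return a [SphereGrid-class]; weights sum to 4*pi.
#' @export
quadratureSphereGrid <- function(degree = 8) {
  ntheta <- floor(degree / 2) + 1
  nphi <- degree + 2
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = ntheta)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  new("SphereGrid", directions = dirs, weights = w)
}

## subdivided icosahedron vertices (unit sphere)
.icosphereVertices <- function(subdiv = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env(parent = emptyenv())
    getMid <- function(i, j) {
      key <- paste(sort(c(i, j)), collapse = "-")
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  v
}

#' Antipodally symmetric icosphere grid
#'
#' Near-uniform direction samples used for ODF argmax searches and shape
#' metrics; the vertex set is closed under s -> -s. Weights are uniform
#' (4*pi / n), adequate for averaging but not exact quadrature.
#'
#' @param subdiv icosahedron subdivision level (3 gives 642 vertices).
#' @return a [SphereGrid-class].
#' @export
icosphereGrid <- function(subdiv = 3L) {
  v <- .icosphereVertices(subdiv)
  v <- rbind(v, -v)
  ## deduplicate (antipodal closure may duplicate nothing for icosphere, but
  ## numerically identical vertices are merged)
  key <- apply(round(v, 10), 1, paste, collapse = ",")
  v <- v[!duplicated(key), , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  new("SphereGrid", directions = v, weights = rep(4 * pi / nrow(v), nrow(v)))
}

#' Default sphere grid for ODF peak searches
#' @return cached antipodal icosphere, subdivision 3.
#' @export
defaultSphereGrid <- function() {
  if (is.null(.pd_env$defgrid)) .pd_env$defgrid <- icosphereGrid(3L)
  .pd_env$defgrid
}

## ---------------------------------------------------- synthesis/analysis ----

#' Synthesize an angular function from its spectrum
#'
#' @param spectrum an [AngularSpectrum-class] (or plain coefficient vector).
#' @param grid a [SphereGrid-class].
#' @return numeric vector f(s_j) = sum_c coeffs[c] Y_c(s_j).
#' @export
shSynthesize <- function(spectrum, grid) {
  cf <- if (is(spectrum, "AngularSpectrum")) spectrum@coeffs else as.numeric(spectrum)
  bl <- if (is(spectrum, "AngularSpectrum")) spectrum@bandlimit
        else .bandlimitForLength(length(cf))
  as.numeric(realSHBasis(grid@directions, bl) %*% cf)
}

#' Expand sampled angular function values into a spectrum
#'
#' Quadrature projection onto the basis; round-trips [shSynthesize()] for
#' band-limited inputs when the grid is exact to degree `2*lmax`.
#'
#' @param samples function values aligned with `grid@directions`.
#' @param grid a [SphereGrid-class] with quadrature weights.
#' @param bandlimit target [BandLimit-class].
#' @return an [AngularSpectrum-class].
#' @export
shAnalyze <- function(samples, grid, bandlimit = BandLimit(4L)) {
  if (length(samples) != nrow(grid@directions))
    stop("samples must align with the grid directions")
  Y <- realSHBasis(grid@directions, bandlimit)
  AngularSpectrum(as.numeric(crossprod(Y, grid@weights * samples)), bandlimit)
}

## ------------------------------------------------------------------ Gaunt ----

#' Wigner 3j symbol
#'
#' Racah's closed form, evaluated in log-factorial space; exact (to double
#' precision) for the small degrees used here.
#'
#' @param j1,j2,j3 degrees.
#' @param m1,m2,m3 orders.
#' @return the 3j symbol value.
#' @export
wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  lf <- function(n) lgamma(n + 1)
  t1 <- j2 - m1 - j3
  t2 <- j1 + m2 - j3
  tmin <- max(0, t1, t2)
  tmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (tmin > tmax) return(0)
  ts <- tmin:tmax
  ssum <- sum((-1)^ts * exp(-(lf(ts) + lf(ts - t1) + lf(ts - t2) +
                              lf(j1 + j2 - j3 - ts) + lf(j1 - m1 - ts) +
                              lf(j2 + m2 - ts))))
  pref <- exp(0.5 * (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
                     lf(j1 + j2 + j3 + 1) + lf(j1 + m1) + lf(j1 - m1) +
                     lf(j2 + m2) + lf(j2 - m2) + lf(j3 + m3) + lf(j3 - m3)))
  (-1)^(j1 - j2 - m3) * pref * ssum
}

## complex Gaunt integral of three (Condon-Shortley) complex harmonics
.complexGaunt <- function(l1, m1, l2, m2, l3, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  sqrt((2 * l1 + 1) * (2 * l2 + 1) * (2 * l3 + 1) / (4 * pi)) *
    wigner3j(l1, l2, l3, 0, 0, 0) * wigner3j(l1, l2, l3, m1, m2, m3)
}

## complex components of one real harmonic: list of (mu, complex coefficient)
## such that Y^real_{l,m} = sum coef * Y^complex_{l,mu}
.realToComplex <- function(m) {
  if (m == 0) return(list(mu = 0, co = 1 + 0i))
  M <- abs(m)
  if (m > 0) list(mu = c(M, -M), co = c((-1)^M, 1) / sqrt(2))
  else list(mu = c(M, -M), co = c(-1i * (-1)^M, 1i) / sqrt(2))
}

#' Real Gaunt coefficient
#'
#' Triple-product integral of three real spherical harmonics, computed through
#' the complex Gaunt coefficients (Wigner 3j) and the real-to-complex unitary
#' transform.
#'
#' @param l1,m1,l2,m2,l3,m3 channel indices.
#' @return the integral of `Y_l1m1 Y_l2m2 Y_l3m3` over the sphere.
#' @export
realGaunt <- function(l1, m1, l2, m2, l3, m3) {
  if ((l1 + l2 + l3) %% 2 != 0) return(0)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) return(0)
  u1 <- .realToComplex(m1); u2 <- .realToComplex(m2); u3 <- .realToComplex(m3)
  acc <- 0 + 0i
  for (a in seq_along(u1$mu)) for (b in seq_along(u2$mu)) for (d in seq_along(u3$mu)) {
    if (u1$mu[a] + u2$mu[b] + u3$mu[d] != 0) next
    acc <- acc + u1$co[a] * u2$co[b] * u3$co[d] *
      .complexGaunt(l1, u1$mu[a], l2, u2$mu[b], l3, u3$mu[d])
  }
  Re(acc)
}

#' Table of all real Gaunt coefficients up to a degree cutoff
#'
#' @param lmax largest degree (all parities included).
#' @return a [GauntTable-class] whose entries are the nonzero coefficients.
#' @export
gauntTable <- function(lmax = 4L) {
  key <- paste0("gaunt", lmax)
  if (!is.null(.pd_env[[key]])) return(.pd_env[[key]])
  ch <- do.call(rbind, lapply(0:lmax, function(l) data.frame(l = l, m = -l:l)))
  n <- nrow(ch)
  res <- vector("list", 2048); nres <- 0
  for (i in seq_len(n)) for (j in i:n) {
    l1 <- ch$l[i]; m1 <- ch$m[i]; l2 <- ch$l[j]; m2 <- ch$m[j]
    for (k in j:n) {
      l3 <- ch$l[k]; m3 <- ch$m[k]
      g <- realGaunt(l1, m1, l2, m2, l3, m3)
      if (abs(g) > 1e-14) {
        nres <- nres + 1
        if (nres > length(res)) res <- c(res, vector("list", length(res)))
        res[[nres]] <- c(l1, m1, l2, m2, l3, m3, g)
      }
    }
  }
  ent <- as.data.frame(do.call(rbind, res[seq_len(nres)]))
  names(ent) <- c("l1", "m1", "l2", "m2", "l3", "m3", "g")
  out <- new("GauntTable", entries = ent, lmax = as.integer(lmax))
  .pd_env[[key]] <- out
  out
}

#' Look up one real Gaunt coefficient in a table
#' @param table a [GauntTable-class].
#' @param l1,m1,l2,m2,l3,m3 indices (any permutation of the stored triples).
#' @export
gauntLookup <- function(table, l1, m1, l2, m2, l3, m3) {
  prs <- rbind(c(l1, m1), c(l2, m2), c(l3, m3))
  o <- order(prs[, 1] * 100 + prs[, 2])
  prs <- prs[o, , drop = FALSE]
  e <- table@entries
  hit <- e$l1 == prs[1, 1] & e$m1 == prs[1, 2] & e$l2 == prs[2, 1] &
    e$m2 == prs[2, 2] & e$l3 == prs[3, 1] & e$m3 == prs[3, 2]
  if (any(hit)) e$g[which(hit)[1]] else 0
}

## triplets of channel indices (1-based) and Gaunt values for
## out_c = sum G(out, a, b) a_c b_c products; cached
.gauntTriplets <- function(blOut, blA = BandLimit(4L), blB = blA) {
  key <- paste("trip", blOut@lmax, blOut@evenOnly, blA@lmax, blA@evenOnly,
               blB@lmax, blB@evenOnly, sep = "_")
  if (!is.null(.pd_env[[key]])) return(.pd_env[[key]])
  chO <- shChannels(blOut); chA <- shChannels(blA); chB <- shChannels(blB)
  res <- vector("list", 4096); nres <- 0
  for (i in seq_len(nrow(chO))) for (j in seq_len(nrow(chA))) {
    l1 <- chO$l[i]; m1 <- chO$m[i]; l2 <- chA$l[j]; m2 <- chA$m[j]
    for (k in seq_len(nrow(chB))) {
      l3 <- chB$l[k]; m3 <- chB$m[k]
      if ((l1 + l2 + l3) %% 2 != 0) next
      if (l3 < abs(l1 - l2) || l3 > l1 + l2) next
      ms <- c(abs(m2 + m3), abs(m2 - m3))
      if (!abs(m1) %in% ms) next
      g <- realGaunt(l1, m1, l2, m2, l3, m3)
      if (abs(g) > 1e-14) {
        nres <- nres + 1
        if (nres > length(res)) res <- c(res, vector("list", length(res)))
        res[[nres]] <- c(i, j, k, g)
      }
    }
  }
  tr <- do.call(rbind, res[seq_len(nres)])
  out <- list(i = as.integer(tr[, 1]), j = as.integer(tr[, 2]),
              k = as.integer(tr[, 3]), g = tr[, 4])
  .pd_env[[key]] <- out
  out
}

## ----------------------------------------------------- products/divisions ----

#' Pointwise product of two angular functions, in the spectral domain
#'
#' Gaunt contraction `(ab)_lm = sum G a_l'm' b_l''m''`, truncated to
#' `out_bandlimit`.
#'
#' @param a,b [AngularSpectrum-class] objects.
#' @param out_bandlimit band limit of the returned product.
#' @return an [AngularSpectrum-class].
#' @export
shMultiply <- function(a, b, out_bandlimit = bandLimit(a)) {
  tr <- .gauntTriplets(out_bandlimit, bandLimit(a), bandLimit(b))
  out <- numeric(nChannels(out_bandlimit))
  val <- tr$g * a@coeffs[tr$j] * b@coeffs[tr$k]
  for (t in seq_along(tr$i)) out[tr$i[t]] <- out[tr$i[t]] + val[t]
  AngularSpectrum(out, out_bandlimit)
}

## build the per-spectrum division matrix M_{c,c'} = sum_c'' G_{c,c',c''} den_{c''}
.shDivisionMatrix <- function(den, bandlimit) {
  tr <- .gauntTriplets(bandlimit, bandlimit, bandLimit(den))
  C <- nChannels(bandlimit)
  M <- matrix(0, C, C)
  for (t in seq_along(tr$i))
    M[tr$i[t], tr$j[t]] <- M[tr$i[t], tr$j[t]] + tr$g[t] * den@coeffs[tr$k[t]]
  M
}

#' Spherical-harmonic division of two angular spectra
#'
#' Solves the per-spectrum linear system `M x = numer` where
#' `M_lm,l'm' = sum G denom_l''m''`, i.e. the spectral counterpart of the
#' pointwise quotient, with a small ridge for stability.
#'
#' @param numer,denom [AngularSpectrum-class] objects (same convention).
#' @param ridge relative ridge added as `ridge * trace(M)/C * I` (default 1e-9).
#' @return an [AngularSpectrum-class] in the numerator's band limit.
#' @export
shDivide <- function(numer, denom, ridge = 1e-9) {
  bl <- bandLimit(numer)
  M <- .shDivisionMatrix(denom, bl)
  lam <- ridge * abs(sum(diag(M))) / nrow(M)
  x <- tryCatch(solve(M + diag(lam, nrow(M)), numer@coeffs),
                error = function(e) solve(M + diag(1e6 * lam + 1e-12, nrow(M)),
                                          numer@coeffs))
  AngularSpectrum(as.numeric(x), bl)
}

## ---------------------------------------------------------------- Wigner ----

#' Real Wigner rotation block for one degree
#'
#' Dense `(2l+1) x (2l+1)` orthogonal block `D` such that if a function `f`
#' has degree-l coefficients `c`, the rotated function `f(R^-1 s)` has
#' coefficients `D %*% c`. Built by exact quadrature of
#' `Y_lm(R s) Y_lm'(s)` on a Gauss-Legendre product grid.
#'
#' @param l degree.
#' @param axis rotation axis (unit 3-vector).
#' @param angle rotation angle in radians.
#' @return orthogonal matrix, rows/columns ordered m = -l..l.
#' @export
wignerRotation <- function(l, axis, angle) {
  if (l == 0) return(matrix(1, 1, 1))
  R <- rotationMatrix(axis, angle)
  grid <- quadratureSphereGrid(2 * l + 2)
  Y <- .realSHl(l, grid@directions)
  YR <- .realSHl(l, grid@directions %*% t(R))
  D <- crossprod(YR, grid@weights * Y)
  ## clean numerically-zero entries for readability
  D[abs(D) < 1e-13] <- 0
  D
}

#' Block-diagonal real Wigner rotation over a band limit
#' @param bandlimit a [BandLimit-class].
#' @param axis,angle rotation (axis unit vector, angle radians).
#' @return C x C orthogonal matrix acting on full channel vectors.
#' @export
wignerRotationBand <- function(bandlimit, axis, angle) {
  ls <- if (bandlimit@evenOnly) seq(0L, bandlimit@lmax, by = 2L)
        else seq(0L, bandlimit@lmax)
  blocks <- lapply(ls, function(l) wignerRotation(l, axis, angle))
  C <- nChannels(bandlimit)
  D <- matrix(0, C, C)
  at <- 1
  for (b in blocks) {
    n <- nrow(b)
    D[at:(at + n - 1), at:(at + n - 1)] <- b
    at <- at + n
  }
  D
}

## largest anisotropy scale keeping a band-limited delta ODF nonnegative
#' @rdname deltaODFSpectrum
#' @export
gfaPositivityBound <- function(bandlimit = BandLimit(4L)) {
  key <- paste0("posb", bandlimit@lmax, bandlimit@evenOnly)
  if (!is.null(.pd_env[[key]])) return(.pd_env[[key]])
  ct <- seq(-1, 1, length.out = 20001)
  ch <- shChannels(bandlimit)
  ## delta along z: f(cos t) = Y00^2 + s * sum_{l>0} Y_l0(z) Y_l0(dir)
  f0 <- realSH(0, 0, c(0, 0, 1))^2
  ls <- setdiff(unique(ch$l), 0L)
  dirs <- cbind(sqrt(pmax(0, 1 - ct^2)), 0, ct)
  gsum <- 0
  for (l in ls)
    gsum <- gsum + realSH(l, 0, c(0, 0, 1)) * realSH(l, 0, dirs)
  mn <- min(gsum)
  out <- if (mn >= 0) Inf else as.numeric(-f0 / mn)
  .pd_env[[key]] <- out
  out
}
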