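// Batched per-voxel / per-frequency linear algebra used by the reconstruction
// and analysis code. Conventions: spectral fields are (channels x voxels)
// matrices, column-major, so one column is one voxel's angular spectrum.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-voxel spherical-harmonic division: solve M(r) x(r) = num(r), where
// M_ij(r) = sum_k G_ijk den_k(r). Triplets (gi,gj,gk,gv) enumerate the full
// (i,j) tensor (both orders present). A relative ridge lambda*I with
// lambda = ridgeRel * |trace(M)| / C is added before solving; voxels flagged
// inactive are returned as zero columns.
// [[Rcpp::export]]
arma::mat cpp_sh_divide_field(const arma::mat& num, const arma::mat& den,
                              const arma::uvec& gi, const arma::uvec& gj,
                              const arma::uvec& gk, const arma::vec& gv,
                              const double ridgeRel,
                              const arma::uvec& active) {
  const arma::uword C = num.n_rows, N = num.n_cols, T = gv.n_elem;
  arma::mat out(C, N, arma::fill::zeros);
  arma::mat M(C, C);
  arma::vec x(C);
  for (arma::uword n = 0; n < N; ++n) {
    if (!active[n]) continue;
    M.zeros();
    for (arma::uword t = 0; t < T; ++t)
      M(gi[t], gj[t]) += gv[t] * den(gk[t], n);
    double lam = ridgeRel * std::abs(arma::trace(M)) / double(C);
    M.diag() += lam;
    bool ok = arma::solve(x, M, num.col(n), arma::solve_opts::fast);
    if (!ok) {
      // ill-conditioned voxel: fall back to a strongly ridged solve
      M.diag() += 1e6 * lam + 1e-12;
      ok = arma::solve(x, M, num.col(n));
    }
    if (ok) out.col(n) = x;
  }
  return out;
}

// Per-voxel spherical-harmonic (Gaunt) product truncated to the output band:
// X_i(r) = sum_{j,k} G_ijk A_j(r) B_k(r).
// [[Rcpp::export]]
arma::mat cpp_sh_multiply_field(const arma::mat& A, const arma::mat& B,
                                const arma::uvec& gi, const arma::uvec& gj,
                                const arma::uvec& gk, const arma::vec& gv,
                                const int Cout) {
  const arma::uword N = A.n_cols, T = gv.n_elem;
  arma::mat out(Cout, N, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    const double g = gv[t];
    const arma::uword i = gi[t], j = gj[t], k = gk[t];
    out.row(i) += g * (A.row(j) % B.row(k));
  }
  return out;
}

// Per-frequency Tikhonov-regularized SVD pseudoinverse. H is a (P x C x N)
// complex cube (one P-by-C system matrix per spatial frequency), I a (P x N)
// complex matrix of measured spectra. Returns the (C x N) object spectrum
// F(nu) = sum_k mu_k/(mu_k^2+eta) u_k (v_k^H i).
// [[Rcpp::export]]
arma::cx_mat cpp_svd_tikhonov(const arma::cx_cube& H, const arma::cx_mat& I,
                              const double eta) {
  const arma::uword C = H.n_cols, N = H.n_slices;
  arma::cx_mat out(C, N, arma::fill::zeros);
  arma::cx_mat U, V;
  arma::vec s;
  for (arma::uword n = 0; n < N; ++n) {
    if (!arma::svd_econ(U, s, V, H.slice(n)))
      stop("SVD failed at frequency index %d", (int)n);
    arma::cx_vec proj = U.t() * I.col(n);        // U^H i, length R
    arma::vec filt = s / (arma::square(s) + eta);
    out.col(n) = V * (filt % arma::real(proj) +
                      arma::cx_double(0, 1) * (filt % arma::imag(proj)));
  }
  return out;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// separable 1D lower-envelope passes along each axis of a 3D grid ----
static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(const LogicalVector& mask, const int nx, const int ny,
                         const int nz) {
  const double INF = 1e30;
  std::vector<double> g((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      size_t off = (size_t)iz * nx * ny + (size_t)iy * nx;
      for (int ix = 0; ix < nx; ++ix) f[ix] = g[off + ix];
      edt_1d(f, d, v, z, nx);
      for (int ix = 0; ix < nx; ++ix) g[off + ix] = d[ix];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      size_t off = (size_t)iz * nx * ny + ix;
      for (int iy = 0; iy < ny; ++iy) f[iy] = g[off + (size_t)iy * nx];
      edt_1d(f, d, v, z, ny);
      for (int iy = 0; iy < ny; ++iy) g[off + (size_t)iy * nx] = d[iy];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      size_t off = (size_t)iy * nx + ix;
      for (int iz = 0; iz < nz; ++iz) f[iz] = g[off + (size_t)iz * nx * ny];
      edt_1d(f, d, v, z, nz);
      for (int iz = 0; iz < nz; ++iz) g[off + (size_t)iz * nx * ny] = d[iz];
    }
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = g[i];
  return out;
}
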