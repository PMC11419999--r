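// k-space pseudospectral solver for the first-order linear acoustic system
// on a heterogeneous c(x), rho(x) map with split-field PML. Spatial
// derivatives are spectral on staggered grids with the exact k-space
// correction sinc(c_ref |k| dt / 2); time stepping is leapfrog.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec fft_freqs(int n, double d) {
  // angular wavenumbers matching the DFT ordering
  vec k(n);
  for (int i = 0; i < n; i++) {
    int f = (i <= (n - 1) / 2) ? i : i - n;
    k(i) = 2.0 * datum::pi * f / (n * d);
  }
  return k;
}

// [[Rcpp::export]]
Rcpp::List kspace_forward_cpp(const arma::mat& p0, const arma::mat& cmap,
                              const arma::mat& rho, double dx, double dt,
                              int nt, const arma::umat& sens_idx,
                              const arma::mat& sens_w, const arma::vec& sig_y,
                              const arma::vec& sig_x, double c_ref,
                              bool record_energy) {
  const int nr = p0.n_rows, nc = p0.n_cols;
  const int ns = sens_idx.n_cols;

  // wavenumber grids: rows vary along y (matrix rows), cols along x
  vec ky = fft_freqs(nr, dx), kx = fft_freqs(nc, dx);
  mat KX(nr, nc), KY(nr, nc);
  for (int j = 0; j < nc; j++) KX.col(j).fill(kx(j));
  for (int i = 0; i < nr; i++) KY.row(i).fill(ky(i));
  mat K = sqrt(square(KX) + square(KY));
  mat kappa(nr, nc);
  for (uword i = 0; i < K.n_elem; i++) {
    double z = c_ref * K(i) * dt / 2.0;
    kappa(i) = (z == 0.0) ? 1.0 : std::sin(z) / z;
  }
  cx_mat OPXf = cx_double(0, 1) * KX % kappa % exp(cx_double(0, 1) * KX * (dx / 2));
  cx_mat OPXb = cx_double(0, 1) * KX % kappa % exp(cx_double(0, -1) * KX * (dx / 2));
  cx_mat OPYf = cx_double(0, 1) * KY % kappa % exp(cx_double(0, 1) * KY * (dx / 2));
  cx_mat OPYb = cx_double(0, 1) * KY % kappa % exp(cx_double(0, -1) * KY * (dx / 2));

  // PML attenuation factors (applied twice per update)
  mat ax(nr, nc), ay(nr, nc);
  for (int j = 0; j < nc; j++) ax.col(j).fill(std::exp(-sig_x(j) * dt / 2));
  for (int i = 0; i < nr; i++) ay.row(i).fill(std::exp(-sig_y(i) * dt / 2));

  mat c2 = square(cmap);
  // staggered densities (ux at i, j+1/2; uy at i+1/2, j in row direction)
  mat rho_sgx = rho, rho_sgy = rho;
  rho_sgx.cols(0, nc - 2) = (rho.cols(0, nc - 2) + rho.cols(1, nc - 1)) / 2;
  rho_sgy.rows(0, nr - 2) = (rho.rows(0, nr - 2) + rho.rows(1, nr - 1)) / 2;

  mat p = p0;
  mat rhox = p0 / (2 * c2), rhoy = rhox;
  mat ux(nr, nc, fill::zeros), uy(nr, nc, fill::zeros);
  mat traces(ns, nt, fill::zeros);
  vec energy;
  if (record_energy) energy.zeros(nt);

  auto sample = [&](int t) {
    for (int s = 0; s < ns; s++) {
      double acc = 0;
      for (int q = 0; q < 4; q++) acc += sens_w(q, s) * p(sens_idx(q, s) - 1);
      traces(s, t) = acc;
    }
  };
  // leapfrog-conserved energy: the potential term pairs the pressures at
  // consecutive steps around the velocity at t + dt/2 (exactly conserved by
  // the staggered scheme in a lossless medium)
  mat p_prev = p;
  auto tot_energy = [&]() {
    double e = 0;
    for (uword i = 0; i < p.n_elem; i++)
      e += rho_sgx(i) * ux(i) * ux(i) / 2 + rho_sgy(i) * uy(i) * uy(i) / 2 +
           p(i) * p_prev(i) / (2 * rho(i) * c2(i));
    return e * dx * dx;
  };

  sample(0);
  if (record_energy) energy(0) = tot_energy();

  for (int t = 1; t < nt; t++) {
    double dte = (t == 1) ? dt / 2 : dt;  // stagger velocities by half a step
    cx_mat P = fft2(cx_mat(p, zeros(nr, nc)));
    mat dpdx = real(ifft2(cx_mat(OPXf % P)));
    mat dpdy = real(ifft2(cx_mat(OPYf % P)));
    ux = ax % (ax % ux - dte * dpdx / rho_sgx);
    uy = ay % (ay % uy - dte * dpdy / rho_sgy);
    mat duxdx = real(ifft2(cx_mat(OPXb % fft2(cx_mat(ux, zeros(nr, nc))))));
    mat duydy = real(ifft2(cx_mat(OPYb % fft2(cx_mat(uy, zeros(nr, nc))))));
    rhox = ax % (ax % rhox - dt * rho % duxdx);
    rhoy = ay % (ay % rhoy - dt * rho % duydy);
    if (record_energy) p_prev = p;
    p = c2 % (rhox + rhoy);
    sample(t);
    if (record_energy) energy(t) = tot_energy();
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("traces") = traces);
  if (record_energy) out["energy"] = energy;
  return out;
}
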