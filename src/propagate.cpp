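// Krylov propagation of spin-network pure states.
//
// The generator is A = -i H - (1/2) diag(d): H is the real symmetric
// Hamiltonian in a fixed basis (full 2^M space or one magnetization
// sector), d >= 0 collects the anti-Hermitian decay sum_m gamma_m J_m^+ J_m,
// which is diagonal here because J_m^+ J_m is a site projector (loss) or
// the identity (dephasing). With d = 0 the generator is skew-Hermitian and
// a symmetric Lanczos recurrence applies; otherwise restarted Arnoldi.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// H x for complex x, reading H once (both real columns in one product)
static cx_vec hmatvec(const sp_mat& H, const cx_vec& x) {
  mat X(x.n_elem, 2);
  X.col(0) = real(x);
  X.col(1) = imag(x);
  mat Y = H * X;
  return cx_vec(Y.col(0), Y.col(1));
}

// exp(-i tau H) v, symmetric Lanczos with adaptive substeps
static cx_vec lanczos_expmv(const sp_mat& H, cx_vec v, double tau, int m,
                            double tol) {
  const uword n = v.n_elem;
  int mm = std::min<int>(m, (int)n);
  double t_done = 0.0, dt = tau;
  while (t_done < tau * (1.0 - 1e-14)) {
    double beta = norm(v);
    if (beta == 0.0) return v;
    cx_mat V(n, mm + 1);
    vec alpha(mm, fill::zeros), betav(mm, fill::zeros);
    V.col(0) = v / beta;
    int meff = mm;
    bool breakdown = false;
    for (int j = 0; j < mm; j++) {
      cx_vec w = hmatvec(H, V.col(j));
      if (j > 0) w -= betav[j - 1] * V.col(j - 1);
      double a = std::real(cdot(V.col(j), w));
      alpha[j] = a;
      w -= a * V.col(j);
      double hn = norm(w);
      betav[j] = hn;
      if (hn < 1e-12 * std::max(1.0, beta)) {
        meff = j + 1;
        breakdown = true;
        break;
      }
      V.col(j + 1) = w / hn;
    }
    mat T(meff, meff, fill::zeros);
    for (int j = 0; j < meff; j++) {
      T(j, j) = alpha[j];
      if (j + 1 < meff) { T(j + 1, j) = betav[j]; T(j, j + 1) = betav[j]; }
    }
    vec theta;
    mat W;
    eig_sym(theta, W, T);
    vec w0 = W.row(0).t();
    dt = std::min(dt, tau - t_done);
    for (;;) {
      vec fr = W * (cos(dt * theta) % w0);
      vec fi = W * (-sin(dt * theta) % w0);
      cx_vec f(fr, fi);
      double err = breakdown ? 0.0
        : beta * betav[meff - 1] * std::abs(f[meff - 1]) * dt;
      if (err <= std::max(tol * std::max(1.0, beta), 1e-15) || dt < 1e-12) {
        v = beta * (V.cols(0, meff - 1) * f);
        t_done += dt;
        if (err < 0.05 * tol * std::max(1.0, beta)) dt *= 2.0;
        break;
      }
      dt *= 0.5;
    }
  }
  return v;
}

// A x = -i H x - (1/2) d .* x
static cx_vec apply_gen(const sp_mat& H, const vec& d, const cx_vec& x) {
  cx_vec hx = hmatvec(H, x);
  cx_vec y = cx_double(0, -1) * hx;
  y -= cx_vec(0.5 * (d % real(x)), 0.5 * (d % imag(x)));
  return y;
}

// exp(tau A) v, restarted Arnoldi with adaptive substeps (dissipative)
static cx_vec arnoldi_expmv(const sp_mat& H, const vec& d, cx_vec v,
                            double tau, int m, double tol) {
  const uword n = v.n_elem;
  int mm = std::min<int>(m, (int)n);
  double t_done = 0.0, dt = tau;
  while (t_done < tau * (1.0 - 1e-14)) {
    double beta = norm(v);
    if (beta == 0.0) return v;
    cx_mat V(n, mm + 1);
    cx_mat Hm(mm + 1, mm, fill::zeros);
    V.col(0) = v / beta;
    int meff = mm;
    bool breakdown = false;
    for (int j = 0; j < mm; j++) {
      cx_vec w = apply_gen(H, d, V.col(j));
      for (int i = 0; i <= j; i++) {
        cx_double h = cdot(V.col(i), w);
        Hm(i, j) = h;
        w -= h * V.col(i);
      }
      for (int i = 0; i <= j; i++) { // one re-orthogonalization pass
        cx_double h = cdot(V.col(i), w);
        Hm(i, j) += h;
        w -= h * V.col(i);
      }
      double hn = norm(w);
      Hm(j + 1, j) = hn;
      if (hn < 1e-12 * std::max(1.0, beta)) {
        meff = j + 1;
        breakdown = true;
        break;
      }
      V.col(j + 1) = w / hn;
    }
    dt = std::min(dt, tau - t_done);
    for (;;) {
      cx_mat F = expmat(dt * cx_mat(Hm.submat(0, 0, meff - 1, meff - 1)));
      double err = breakdown ? 0.0
        : beta * std::abs(Hm(meff, meff - 1)) * std::abs(F(meff - 1, 0)) * dt;
      if (err <= std::max(tol * std::max(1.0, beta), 1e-15) || dt < 1e-12) {
        v = beta * (V.cols(0, meff - 1) * F.col(0));
        t_done += dt;
        if (err < 0.05 * tol * std::max(1.0, beta)) dt *= 2.0;
        break;
      }
      dt *= 0.5;
    }
  }
  return v;
}

static cx_vec expmv(const sp_mat& H, const vec& d, bool decay, cx_vec v,
                    double tau, int m, double tol) {
  if (tau <= 0.0) return v;
  return decay ? arnoldi_expmv(H, d, v, tau, m, tol)
               : lanczos_expmv(H, v, tau, m, tol);
}

// Per-site <sigma^z_i> of an (unnormalized) state; bits[b] is the up-spin
// bitmask of basis state b, site i <-> bit (i-1).
static vec site_mags(const cx_vec& psi, const Rcpp::IntegerVector& bits,
                     int n_sites) {
  vec p = square(abs(psi));
  double tot = accu(p);
  vec up(n_sites, fill::zeros);
  for (uword b = 0; b < p.n_elem; ++b) {
    double pb = p[b];
    if (pb == 0.0) continue;
    int bb = bits[b];
    for (int i = 0; i < n_sites; ++i)
      if (bb & (1 << i)) up[i] += pb;
  }
  return (2.0 * up - tot) / tot;
}

// [[Rcpp::export]]
arma::cx_vec cpp_krylov_propagate(const arma::sp_mat& H, const arma::vec& d,
                                  const arma::cx_vec& psi, double tau, int m,
                                  double tol) {
  bool decay = any(d > 0.0);
  return expmv(H, d, decay, psi, tau, m, tol);
}

// Propagate through successive intervals taus, recording magnetization and
// state norm after each. taus may contain zeros (record "now").
// [[Rcpp::export]]
Rcpp::List cpp_propagate_record(const arma::sp_mat& H, const arma::vec& d,
                                const arma::cx_vec& psi0,
                                const arma::vec& taus,
                                const Rcpp::IntegerVector& bits, int n_sites,
                                int m, double tol) {
  bool decay = any(d > 0.0);
  cx_vec psi = psi0;
  mat mags(n_sites, taus.n_elem);
  vec norms(taus.n_elem);
  for (uword k = 0; k < taus.n_elem; ++k) {
    if (taus[k] > 0.0) psi = expmv(H, d, decay, psi, taus[k], m, tol);
    norms[k] = norm(psi);
    mags.col(k) = site_mags(psi, bits, n_sites);
  }
  return Rcpp::List::create(Rcpp::Named("mag") = mags,
                            Rcpp::Named("psi") = psi,
                            Rcpp::Named("norm") = norms);
}

// [[Rcpp::export]]
arma::vec cpp_site_mags(const arma::cx_vec& psi,
                        const Rcpp::IntegerVector& bits, int n_sites) {
  return site_mags(psi, bits, n_sites);
}
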