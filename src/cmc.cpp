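// Fast fixed-step integrator for the coupled canonical-microcircuit (CMC)
// network.  State per node: 4 population voltages + 4 currents, populations
// ordered SP, SS, DP, II.  Dynamics per population:
//   xv' = xi
//   xi' = K*U - 2*K*xi - K^2*xv,   U = S*d + H + E
// where d is centred sigmoid firing, S the extrinsic drive (forward SP ->
// {SS,DP}, backward DP -> {SP,II}, lateral SP -> {SS,DP}), H = G * d the
// intrinsic drive, and E a Gaussian-bump exogenous input onto SS.
// Time is in ms throughout.  The inner loop is allocation-free.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const int SP = 0, SS = 1, DP = 2, II = 3;

struct Work {
  mat d, U, k1v, k1i, k2v, k2i, k3v, k3i, k4v, k4i, Xv2, Xi2;
  explicit Work(uword n)
    : d(4, n), U(4, n), k1v(4, n), k1i(4, n), k2v(4, n), k2i(4, n),
      k3v(4, n), k3i(4, n), k4v(4, n), k4i(4, n), Xv2(4, n), Xi2(4, n) {}
};

// derivative written into dXv, dXi; exo_now is the per-node SS drive
static void cmc_deriv(const mat& Xv, const mat& Xi,
                      const mat& K, const mat& K2, const cube& G,
                      const mat& Afwd, const mat& Abwd, const mat& Alat,
                      const double* exo_now, double r, double v0,
                      Work& w, mat& dXv, mat& dXi) {
  const uword n = Xv.n_cols;
  for (uword i = 0; i < n; ++i)
    for (uword p = 0; p < 4; ++p)
      w.d(p, i) = 1.0 / (1.0 + std::exp(-r * (Xv(p, i) - v0))) - 0.5;

  for (uword i = 0; i < n; ++i) {
    const mat& Gi = G.slice(i);
    double fwd = 0.0, bwd = 0.0, lat = 0.0;
    for (uword j = 0; j < n; ++j) {
      fwd += Afwd(i, j) * w.d(SP, j);
      bwd += Abwd(i, j) * w.d(DP, j);
      lat += Alat(i, j) * w.d(SP, j);
    }
    for (uword p = 0; p < 4; ++p) {
      double h = 0.0;
      for (uword q = 0; q < 4; ++q) h += Gi(p, q) * w.d(q, i);
      w.U(p, i) = h;
    }
    w.U(SS, i) += fwd + lat + exo_now[i];
    w.U(DP, i) += fwd + lat;
    w.U(SP, i) += bwd;
    w.U(II, i) += bwd;
  }
  dXv = Xi;
  for (uword i = 0; i < n; ++i)
    for (uword p = 0; p < 4; ++p)
      dXi(p, i) = K(p, i) * w.U(p, i) - 2.0 * K(p, i) * Xi(p, i)
        - K2(p, i) * Xv(p, i);
}

// [[Rcpp::export]]
Rcpp::List simulate_cmc_cpp(const arma::mat& K, const arma::cube& G,
                            const arma::mat& Afwd, const arma::mat& Abwd,
                            const arma::mat& Alat,
                            const arma::vec& exo_amp, const arma::vec& exo_onset,
                            const arma::vec& exo_width,
                            const arma::mat& J, const arma::vec& L,
                            double r, double v0,
                            double t0, double t1, double dt,
                            int record_every, bool return_states) {
  const uword n = K.n_cols;
  const int n_steps = (int) std::round((t1 - t0) / dt);
  const int n_out = n_steps / record_every + 1;

  mat K2 = K % K;
  mat Xv(4, n, fill::zeros), Xi(4, n, fill::zeros);
  Work w(n);
  mat Y(n, n_out);
  vec times(n_out);
  cube states;
  if (return_states) states.set_size(4, n, n_out);

  // exogenous SS drive precomputed on the half-step grid
  mat E(n, 2 * n_steps + 1, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    if (exo_amp(i) == 0.0 || exo_width(i) <= 0.0) continue;
    for (int s = 0; s <= 2 * n_steps; ++s) {
      double t = t0 + s * dt / 2.0;
      double z = (t - exo_onset(i)) / exo_width(i);
      E(i, s) = exo_amp(i) * std::exp(-0.5 * z * z);
    }
  }

  auto record = [&](int k, double t) {
    for (uword i = 0; i < n; ++i) {
      double acc = 0.0;
      for (uword p = 0; p < 4; ++p) acc += J(p, i) * Xv(p, i);
      Y(i, k) = L(i) * acc;
    }
    times(k) = t;
    if (return_states) states.slice(k) = Xv;
  };

  int k = 0;
  record(k++, t0);
  double diverged_at = NA_REAL;

  for (int s = 0; s < n_steps; ++s) {
    const double* e1 = E.colptr(2 * s);
    const double* e2 = E.colptr(2 * s + 1);
    const double* e3 = E.colptr(2 * s + 2);

    cmc_deriv(Xv, Xi, K, K2, G, Afwd, Abwd, Alat, e1, r, v0, w, w.k1v, w.k1i);
    w.Xv2 = Xv + 0.5 * dt * w.k1v; w.Xi2 = Xi + 0.5 * dt * w.k1i;
    cmc_deriv(w.Xv2, w.Xi2, K, K2, G, Afwd, Abwd, Alat, e2, r, v0, w, w.k2v, w.k2i);
    w.Xv2 = Xv + 0.5 * dt * w.k2v; w.Xi2 = Xi + 0.5 * dt * w.k2i;
    cmc_deriv(w.Xv2, w.Xi2, K, K2, G, Afwd, Abwd, Alat, e2, r, v0, w, w.k3v, w.k3i);
    w.Xv2 = Xv + dt * w.k3v; w.Xi2 = Xi + dt * w.k3i;
    cmc_deriv(w.Xv2, w.Xi2, K, K2, G, Afwd, Abwd, Alat, e3, r, v0, w, w.k4v, w.k4i);

    Xv += dt / 6.0 * (w.k1v + 2.0 * w.k2v + 2.0 * w.k3v + w.k4v);
    Xi += dt / 6.0 * (w.k1i + 2.0 * w.k2i + 2.0 * w.k3i + w.k4i);

    if (!Xv.is_finite() || !Xi.is_finite() || abs(Xv).max() > 1e6) {
      diverged_at = t0 + (s + 1) * dt;
      break;
    }
    if ((s + 1) % record_every == 0) record(k++, t0 + (s + 1) * dt);
  }

  if (!std::isnan(diverged_at)) {
    Y = Y.cols(0, k - 1);
    times = times.subvec(0, k - 1);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("y") = Y,
    Rcpp::Named("time") = times,
    Rcpp::Named("diverged_at") = diverged_at);
  if (return_states) out["states"] = states;
  return out;
}
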