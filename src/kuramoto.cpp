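#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Fixed-step classical RK4 for the Kuramoto model on a binary network:
//   dtheta_i/dt = omega_i + lambda * sum_j W_ij sin(theta_j - theta_i)
// The coupling sum is evaluated through the identity
//   sum_j in nb(i) sin(theta_j - theta_i) = cos(theta_i)*S_i - sin(theta_i)*C_i
// with S_i = sum_j sin(theta_j), C_i = sum_j cos(theta_j) over neighbours,
// so each derivative evaluation costs O(N) trig + O(E) adds.
// Phases are integrated unwrapped; sampling starts strictly after the
// transient, at t = t_transient + sample_dt, ..., t_total.

// [[Rcpp::export]]
NumericMatrix kuramoto_rk4_cpp(IntegerMatrix W, NumericVector omega,
                               NumericVector theta0, double lambda,
                               double t_total, double t_transient,
                               double dt, double sample_dt) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("adjacency matrix must be square");
  if (omega.size() != N || theta0.size() != N)
    stop("omega and theta0 must have length N");

  // compressed sparse rows of W (symmetric, but stored both ways)
  std::vector<int> ptr(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int j = 0; j < N; ++j) if (W(i, j) != 0) ++cnt;
    ptr[i + 1] = ptr[i] + cnt;
  }
  std::vector<int> idx(ptr[N]);
  for (int i = 0, p = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) if (W(i, j) != 0) idx[p++] = j;

  const long n_steps = std::lround(t_total / dt);
  const long n_trans = std::lround(t_transient / dt);
  const long per = std::lround(sample_dt / dt);
  const int n_samp = static_cast<int>((n_steps - n_trans) / per);
  if (n_samp < 1) stop("no samples after the transient");

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> s(N), c(N), k1(N), k2(N), k3(N), k4(N), tmp(N);

  NumericMatrix out(N, n_samp);

  auto deriv = [&](const std::vector<double>& x, std::vector<double>& d) {
    for (int i = 0; i < N; ++i) { s[i] = std::sin(x[i]); c[i] = std::cos(x[i]); }
    for (int i = 0; i < N; ++i) {
      double S = 0.0, C = 0.0;
      for (int p = ptr[i]; p < ptr[i + 1]; ++p) { S += s[idx[p]]; C += c[idx[p]]; }
      d[i] = omega[i] + lambda * (c[i] * S - s[i] * C);
    }
  };

  int col = 0;
  for (long step = 1; step <= n_steps; ++step) {
    deriv(th, k1);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < N; ++i)
      th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if (step > n_trans && (step - n_trans) % per == 0) {
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(th[i]))
          stop("non-finite phase for node %d at integration step %ld (t = %g)",
               i + 1, step, step * dt);
        out(i, col) = th[i];
      }
      ++col;
      if (col == n_samp) break;
    }
  }
  return out;
}
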