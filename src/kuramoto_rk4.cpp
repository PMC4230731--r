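#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phase derivative of the modular Kuramoto network in mean-field form.
// theta is stored column-major, oscillator k of node i at [k + N*i].
// The intra-node all-to-all sine coupling equals K_i * r_i * sin(psi_i - theta)
// exactly; the inter-node term uses the driving node's mean field
// kappa * A[i,j] * r_j * sin(psi_j - theta), with A[i,j] meaning j drives i.
static void deriv(const double *theta, const double *omega,
                  const double *A, const double *K, double kappa,
                  int n, int N, double *zr, double *zi, double *dtheta) {
  const double invN = 1.0 / N;
  for (int i = 0; i < n; ++i) {
    double sr = 0.0, si = 0.0;
    const double *th = theta + (size_t)N * i;
    for (int k = 0; k < N; ++k) {
      sr += std::cos(th[k]);
      si += std::sin(th[k]);
    }
    zr[i] = sr * invN;
    zi[i] = si * invN;
  }
  for (int i = 0; i < n; ++i) {
    // complex local field c_i = K_i z_i + kappa * sum_j A[i,j] z_j
    double cr = K[i] * zr[i], ci = K[i] * zi[i];
    for (int j = 0; j < n; ++j) {
      double a = A[i + (size_t)n * j];
      if (a != 0.0) {
        cr += kappa * a * zr[j];
        ci += kappa * a * zi[j];
      }
    }
    const double *th = theta + (size_t)N * i;
    const double *om = omega + (size_t)N * i;
    double *dt_ = dtheta + (size_t)N * i;
    for (int k = 0; k < N; ++k) {
      // Im(c_i * e^{-i theta}) = ci*cos(theta) - cr*sin(theta)
      dt_[k] = om[k] + ci * std::cos(th[k]) - cr * std::sin(th[k]);
    }
  }
}

// [[Rcpp::export(name = ".sim_kuramoto_rk4")]]
List sim_kuramoto_rk4(NumericMatrix adjacency, NumericVector K, double kappa,
                      NumericMatrix omega, NumericMatrix theta0,
                      double dt, int n_steps, int store_every) {
  const int n = adjacency.nrow();
  const int N = omega.nrow();
  const size_t M = (size_t)N * n;
  if (omega.ncol() != n || theta0.nrow() != N || theta0.ncol() != n)
    stop("inconsistent array shapes");

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> k1(M), k2(M), k3(M), k4(M), tmp(M);
  std::vector<double> zr(n), zi(n);

  const int n_store = n_steps / store_every + 1;
  NumericVector times(n_store);
  // stored phases, dims (time, node, oscillator)
  NumericVector phases((R_xlen_t)n_store * n * N);
  phases.attr("dim") = IntegerVector::create(n_store, n, N);

  const double twopi = 2.0 * M_PI;
  int si = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step % store_every == 0) {
      times[si] = step * dt;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < N; ++k) {
          double ph = theta[k + (size_t)N * i];
          ph -= std::floor(ph / twopi) * twopi;  // wrap to [0, 2*pi)
          phases[si + (R_xlen_t)n_store * (i + (R_xlen_t)n * k)] = ph;
        }
      ++si;
    }
    if (step == n_steps) break;

    deriv(theta.data(), REAL(omega), REAL(adjacency), REAL(K), kappa,
          n, N, zr.data(), zi.data(), k1.data());
    for (size_t m = 0; m < M; ++m) tmp[m] = theta[m] + 0.5 * dt * k1[m];
    deriv(tmp.data(), REAL(omega), REAL(adjacency), REAL(K), kappa,
          n, N, zr.data(), zi.data(), k2.data());
    for (size_t m = 0; m < M; ++m) tmp[m] = theta[m] + 0.5 * dt * k2[m];
    deriv(tmp.data(), REAL(omega), REAL(adjacency), REAL(K), kappa,
          n, N, zr.data(), zi.data(), k3.data());
    for (size_t m = 0; m < M; ++m) tmp[m] = theta[m] + dt * k3[m];
    deriv(tmp.data(), REAL(omega), REAL(adjacency), REAL(K), kappa,
          n, N, zr.data(), zi.data(), k4.data());
    bool ok = true;
    for (size_t m = 0; m < M; ++m) {
      theta[m] += dt / 6.0 * (k1[m] + 2.0 * k2[m] + 2.0 * k3[m] + k4[m]);
      if (!std::isfinite(theta[m])) ok = false;
    }
    if (!ok)
      stop("numerical failure: non-finite phase at integration step %d",
           step + 1);
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["phases"] = phases);
}
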