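#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Total-variation regularized differentiation of a sampled signal.
//
// The derivative u lives on the n-1 midpoints of the time grid. With the
// cumulative-sum (left endpoint) quadrature A u = dt * cumsum(u), which
// reconstructs f(t_{i+1}) - f(t_1) exactly for piecewise-constant u, we
// minimize
//
//   J(u) = (dt/2) * || A u - (f[2:n] - f[1]) ||^2 + alpha * sum_j phi(Du_j)
//
// with phi(s) = sqrt(s^2 + eps^2) the smoothed absolute value and D the
// forward difference on the midpoint grid. Lagged-diffusivity fixed point:
// repeatedly solve the linearized normal equations
//
//   (dt * A^T A + alpha * D^T W D) u = dt * A^T fhat,  W = diag(1/phi'(Du))
//
// by preconditioned conjugate gradients; A and A^T are applied in O(n) as
// running sums, so no matrix is ever formed.

static void apply_A(const std::vector<double>& u, std::vector<double>& out,
                    double dt) {
  double acc = 0.0;
  for (size_t i = 0; i < u.size(); ++i) {
    acc += u[i];
    out[i] = dt * acc;
  }
}

static void apply_At(const std::vector<double>& v, std::vector<double>& out,
                     double dt) {
  double acc = 0.0;
  const int m = (int)v.size();
  for (int i = m - 1; i >= 0; --i) {
    acc += v[i];
    out[i] = dt * acc;
  }
}

// H u = dt * A^T A u + alpha * D^T W D u
static void apply_H(const std::vector<double>& u, std::vector<double>& out,
                    const std::vector<double>& w, double dt, double alpha,
                    std::vector<double>& t1, std::vector<double>& t2) {
  const int m = (int)u.size();
  apply_A(u, t1, dt);
  apply_At(t1, t2, dt);
  for (int i = 0; i < m; ++i) out[i] = dt * t2[i];
  // D^T W D: tridiagonal stencil
  for (int j = 0; j < m - 1; ++j) {
    double d = w[j] * (u[j + 1] - u[j]);
    out[j] -= alpha * d;
    out[j + 1] += alpha * d;
  }
}

// [[Rcpp::export]]
List tvdiff_core(NumericVector f, double dt, double alpha, int max_iter,
                 double eps, int cg_max, double cg_tol, double outer_tol) {
  const int n = f.size();
  if (n < 3) stop("need at least 3 samples");
  const int m = n - 1;

  std::vector<double> fhat(m), u(m), b(m);
  for (int i = 0; i < m; ++i) fhat[i] = f[i + 1] - f[0];
  // init: naive finite differences (already on midpoints)
  for (int i = 0; i < m; ++i) u[i] = (f[i + 1] - f[i]) / dt;
  apply_At(fhat, b, dt);
  for (int i = 0; i < m; ++i) b[i] *= dt;

  std::vector<double> w(std::max(m - 1, 1)), r(m), z(m), p(m), Hp(m),
      t1(m), t2(m), diag(m), u_prev(m);

  bool converged = false;
  int outer_used = 0;
  for (int it = 0; it < max_iter; ++it) {
    outer_used = it + 1;
    for (int j = 0; j < m - 1; ++j) {
      double d = u[j + 1] - u[j];
      w[j] = 1.0 / std::sqrt(d * d + eps * eps);
    }
    // Jacobi preconditioner: diag(dt*A^T A) = dt^3 * (m - j), plus TV part
    for (int j = 0; j < m; ++j) {
      double dg = dt * dt * dt * (double)(m - j);
      if (j > 0) dg += alpha * w[j - 1];
      if (j < m - 1) dg += alpha * w[j];
      diag[j] = dg > 0 ? dg : 1.0;
    }
    u_prev = u;
    // PCG on H u = b, warm-started at current u
    apply_H(u, Hp, w, dt, alpha, t1, t2);
    double bnorm = 0.0;
    for (int j = 0; j < m; ++j) {
      r[j] = b[j] - Hp[j];
      bnorm += b[j] * b[j];
    }
    bnorm = std::sqrt(bnorm);
    if (bnorm == 0.0) bnorm = 1.0;
    double rz = 0.0;
    for (int j = 0; j < m; ++j) {
      z[j] = r[j] / diag[j];
      p[j] = z[j];
      rz += r[j] * z[j];
    }
    for (int cg = 0; cg < cg_max; ++cg) {
      double rnorm = 0.0;
      for (int j = 0; j < m; ++j) rnorm += r[j] * r[j];
      if (std::sqrt(rnorm) <= cg_tol * bnorm) break;
      apply_H(p, Hp, w, dt, alpha, t1, t2);
      double pHp = 0.0;
      for (int j = 0; j < m; ++j) pHp += p[j] * Hp[j];
      if (pHp <= 0) break;
      double a = rz / pHp;
      for (int j = 0; j < m; ++j) {
        u[j] += a * p[j];
        r[j] -= a * Hp[j];
      }
      double rz_new = 0.0;
      for (int j = 0; j < m; ++j) {
        z[j] = r[j] / diag[j];
        rz_new += r[j] * z[j];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int j = 0; j < m; ++j) p[j] = z[j] + beta * p[j];
    }
    double du = 0.0, nu = 0.0;
    for (int j = 0; j < m; ++j) {
      du += (u[j] - u_prev[j]) * (u[j] - u_prev[j]);
      nu += u[j] * u[j];
    }
    if (std::sqrt(du) <= outer_tol * (std::sqrt(nu) + 1e-300)) {
      converged = true;
      break;
    }
  }

  // map midpoint derivative back onto the sample grid
  NumericVector ddt(n);
  ddt[0] = u[0];
  ddt[n - 1] = u[m - 1];
  for (int i = 1; i < n - 1; ++i) ddt[i] = 0.5 * (u[i - 1] + u[i]);

  return List::create(_["ddt"] = ddt, _["converged"] = converged,
                      _["iterations"] = outer_used);
}
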