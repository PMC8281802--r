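// Inner loops of the harmonic-network relaxation. The R level owns the
// topology and all bookkeeping; this file only evaluates the spring
// energy/gradient and integrates the relaxation phases:
//   1. overdamped Langevin steps with Gaussian noise (R RNG, so a seed
//      set in R makes the trajectory reproducible),
//   2. limited-memory quasi-Newton descent (Armijo backtracking, only
//      energy decreases accepted) to pass through the soft collective
//      modes,
//   3. backtracking steepest descent, which is monotone in energy and
//      supplies the reported convergence criterion.
#include <Rcpp.h>
using namespace Rcpp;

static double energy_of(const NumericMatrix& X, const IntegerVector& si,
                        const IntegerVector& sj, const NumericVector& d0,
                        double k) {
  double e = 0.0;
  const int m = si.size();
  for (int s = 0; s < m; ++s) {
    const int i = si[s] - 1, j = sj[s] - 1;
    const double dx = X(i, 0) - X(j, 0);
    const double dy = X(i, 1) - X(j, 1);
    const double dz = X(i, 2) - X(j, 2);
    const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double ext = len - d0[s];
    e += 0.5 * k * ext * ext;
  }
  return e;
}

// dE/dr; coincident beads get a fixed fallback direction (never expected
// on sane inputs, keeps the gradient finite)
static void gradient_of(const NumericMatrix& X, const IntegerVector& si,
                        const IntegerVector& sj, const NumericVector& d0,
                        double k, NumericMatrix& G) {
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) { G(i, 0) = 0; G(i, 1) = 0; G(i, 2) = 0; }
  const int m = si.size();
  for (int s = 0; s < m; ++s) {
    const int i = si[s] - 1, j = sj[s] - 1;
    double dx = X(i, 0) - X(j, 0);
    double dy = X(i, 1) - X(j, 1);
    double dz = X(i, 2) - X(j, 2);
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-12) { dx = 1.0; dy = 0.0; dz = 0.0; len = 1.0; }
    const double f = k * (len - d0[s]) / len;
    G(i, 0) += f * dx; G(i, 1) += f * dy; G(i, 2) += f * dz;
    G(j, 0) -= f * dx; G(j, 1) -= f * dy; G(j, 2) -= f * dz;
  }
}

static double max_abs(const NumericMatrix& G) {
  double g = 0.0;
  for (int i = 0; i < G.nrow(); ++i)
    for (int d = 0; d < 3; ++d) g = std::max(g, std::fabs(G(i, d)));
  return g;
}

// [[Rcpp::export(name = ".enm_energy_cpp")]]
double enm_energy_cpp(NumericMatrix X, IntegerVector si, IntegerVector sj,
                      NumericVector d0, double k) {
  return energy_of(X, si, sj, d0, k);
}

// [[Rcpp::export(name = ".enm_gradient_cpp")]]
NumericMatrix enm_gradient_cpp(NumericMatrix X, IntegerVector si,
                               IntegerVector sj, NumericVector d0, double k) {
  NumericMatrix G(X.nrow(), 3);
  gradient_of(X, si, sj, d0, k, G);
  return G;
}

// [[Rcpp::export(name = ".enm_relax_cpp")]]
List enm_relax_cpp(NumericMatrix X0, IntegerVector si, IntegerVector sj,
                   NumericVector d0, double k, double temperature,
                   int md_steps, double step, double damping, double tol,
                   int quench_steps, int descent_steps) {
  NumericMatrix X = clone(X0);
  const int n = X.nrow();
  NumericMatrix G(n, 3);

  // phase 1: overdamped Langevin (noise from R's RNG)
  const double noise_sd = std::sqrt(2.0 * temperature * step);
  const double mob = step * damping;
  for (int t = 0; t < md_steps; ++t) {
    gradient_of(X, si, sj, d0, k, G);
    if (noise_sd > 0) {
      NumericVector eta = rnorm(3 * n, 0.0, noise_sd);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          X(i, d) += -mob * G(i, d) + eta[3 * i + d];
    } else {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) X(i, d) += -mob * G(i, d);
    }
  }

  // phase 2: curvature-accelerated monotone descent (limited-memory
  // quasi-Newton with Armijo backtracking); carries the stack through
  // its soft collective bending modes orders of magnitude faster than
  // first-order steps, accepting only energy decreases
  {
    const int mem = 8;
    const int dim = 3 * n;
    std::vector<std::vector<double> > Svec(mem, std::vector<double>(dim)),
        Yvec(mem, std::vector<double>(dim));
    std::vector<double> rho(mem, 0.0), alpha_buf(mem, 0.0);
    std::vector<double> g(dim), g_old(dim), x(dim), x_old(dim), p(dim);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = X(i, d);
    double e = energy_of(X, si, sj, d0, k);
    gradient_of(X, si, sj, d0, k, G);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) g[3 * i + d] = G(i, d);
    int stored = 0, head = 0;
    for (int t = 0; t < quench_steps; ++t) {
      double gmax = 0;
      for (int a = 0; a < dim; ++a) gmax = std::max(gmax, std::fabs(g[a]));
      if (gmax < tol) break;
      // two-loop recursion for the search direction
      for (int a = 0; a < dim; ++a) p[a] = -g[a];
      double gamma = 1.0;
      if (stored > 0) {
        for (int m = 0; m < stored; ++m) {
          int idx = (head - 1 - m + mem * 2) % mem;
          double a_i = 0;
          for (int a = 0; a < dim; ++a) a_i += Svec[idx][a] * p[a];
          a_i *= rho[idx];
          alpha_buf[idx] = a_i;
          for (int a = 0; a < dim; ++a) p[a] -= a_i * Yvec[idx][a];
        }
        int last = (head - 1 + mem) % mem;
        double sy = 0, yy = 0;
        for (int a = 0; a < dim; ++a) {
          sy += Svec[last][a] * Yvec[last][a];
          yy += Yvec[last][a] * Yvec[last][a];
        }
        if (yy > 0) gamma = sy / yy;
        for (int a = 0; a < dim; ++a) p[a] *= gamma;
        for (int m = stored - 1; m >= 0; --m) {
          int idx = (head - 1 - (stored - 1 - m) + mem * 2) % mem;
          double b = 0;
          for (int a = 0; a < dim; ++a) b += Yvec[idx][a] * p[a];
          b *= rho[idx];
          for (int a = 0; a < dim; ++a)
            p[a] += (alpha_buf[idx] - b) * Svec[idx][a];
        }
      } else {
        // first step: scale to a conservative displacement
        double pmax = 0;
        for (int a = 0; a < dim; ++a) pmax = std::max(pmax, std::fabs(p[a]));
        if (pmax > 0)
          for (int a = 0; a < dim; ++a) p[a] *= step / pmax;
      }
      double descent = 0;
      for (int a = 0; a < dim; ++a) descent += p[a] * g[a];
      if (descent >= 0) {      // not a descent direction: reset memory
        stored = 0; head = 0;
        for (int a = 0; a < dim; ++a) p[a] = -g[a] * step;
        descent = 0;
        for (int a = 0; a < dim; ++a) descent += p[a] * g[a];
      }
      // Armijo backtracking
      double stp = 1.0, e_new = e;
      bool accepted = false;
      for (int ls = 0; ls < 30; ++ls) {
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            X(i, d) = x[3 * i + d] + stp * p[3 * i + d];
        e_new = energy_of(X, si, sj, d0, k);
        if (R_finite(e_new) && e_new <= e + 1e-4 * stp * descent) {
          accepted = true; break;
        }
        stp *= 0.5;
      }
      if (!accepted) {
        if (stored == 0) break;  // plain gradient step failed too
        stored = 0; head = 0;    // retry with fresh memory
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) X(i, d) = x[3 * i + d];
        continue;
      }
      x_old = x; g_old = g;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) x[3 * i + d] = X(i, d);
      e = e_new;
      gradient_of(X, si, sj, d0, k, G);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) g[3 * i + d] = G(i, d);
      double sy = 0;
      for (int a = 0; a < dim; ++a) {
        Svec[head][a] = x[a] - x_old[a];
        Yvec[head][a] = g[a] - g_old[a];
        sy += Svec[head][a] * Yvec[head][a];
      }
      if (sy > 1e-12) {
        rho[head] = 1.0 / sy;
        head = (head + 1) % mem;
        if (stored < mem) ++stored;
      }
    }
  }

  // phase 3: backtracking steepest descent (monotone; reported energies)
  std::vector<double> energies;
  double e = energy_of(X, si, sj, d0, k);
  energies.push_back(e);
  double s = step;
  bool converged = false;
  double gnorm = NA_REAL;
  gradient_of(X, si, sj, d0, k, G);
  for (int t = 0; t < descent_steps; ++t) {
    gnorm = max_abs(G);
    if (gnorm < tol) { converged = true; break; }
    NumericMatrix trial(n, 3);
    double e_trial = 0;
    while (true) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) trial(i, d) = X(i, d) - s * G(i, d);
      e_trial = energy_of(trial, si, sj, d0, k);
      if (R_finite(e_trial) && e_trial <= e) break;
      s *= 0.5;
      if (s < 1e-14) break;
    }
    if (s < 1e-14) break;
    X = trial;
    e = e_trial;
    energies.push_back(e);
    s *= 1.2;
    gradient_of(X, si, sj, d0, k, G);
  }
  if (!converged) {
    gradient_of(X, si, sj, d0, k, G);
    gnorm = max_abs(G);
    converged = gnorm < tol;
  }
  return List::create(_["coords"] = X,
                      _["energies"] = NumericVector(energies.begin(), energies.end()),
                      _["converged"] = converged,
                      _["final_grad_norm"] = gnorm);
}
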