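#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic free-energy profile forms shared with R (see analytic_pmf()).
// form: 0 flat, 1 harmonic, 2 double_well, 3 multi_barrier (Gaussian bumps),
//       4 tabulated (linear interpolation of a precomputed gradient grid).
struct PmfSpec {
  int form;
  double p1, p2;                 // harmonic k / double-well height, width
  std::vector<double> heights, positions, widths;
  double tab_q0, tab_dq;
  std::vector<double> tab_grad;
};

static double pmf_grad_cpp(const PmfSpec &s, double q) {
  switch (s.form) {
  case 0: return 0.0;
  case 1: return s.p1 * q;
  case 2: { // h*((q/w)^2 - 1)^2
    double w2 = s.p2 * s.p2;
    return 4.0 * s.p1 * q * (q * q / w2 - 1.0) / w2;
  }
  case 3: {
    double g = 0.0;
    for (size_t j = 0; j < s.heights.size(); ++j) {
      double d = q - s.positions[j], sg = s.widths[j];
      g += -s.heights[j] * d / (sg * sg) * std::exp(-0.5 * d * d / (sg * sg));
    }
    return g;
  }
  case 4: {
    double t = (q - s.tab_q0) / s.tab_dq;
    int n = (int)s.tab_grad.size();
    if (t <= 0.0) return s.tab_grad.front();
    if (t >= n - 1) return s.tab_grad.back();
    int i = (int)std::floor(t);
    double f = t - i;
    return (1.0 - f) * s.tab_grad[i] + f * s.tab_grad[i + 1];
  }
  }
  return 0.0;
}

static PmfSpec make_spec(List pmf) {
  PmfSpec s;
  s.form = as<int>(pmf["form_id"]);
  s.p1 = as<double>(pmf["p1"]);
  s.p2 = as<double>(pmf["p2"]);
  s.heights = as<std::vector<double>>(pmf["heights"]);
  s.positions = as<std::vector<double>>(pmf["positions"]);
  s.widths = as<std::vector<double>>(pmf["widths"]);
  s.tab_q0 = as<double>(pmf["tab_q0"]);
  s.tab_dq = as<double>(pmf["tab_dq"]);
  s.tab_grad = as<std::vector<double>>(pmf["tab_grad"]);
  return s;
}

static double pmf_value_cpp(const PmfSpec &s, double q) {
  switch (s.form) {
  case 0: return 0.0;
  case 1: return 0.5 * s.p1 * q * q;
  case 2: {
    double t = q * q / (s.p2 * s.p2) - 1.0;
    return s.p1 * t * t;
  }
  case 3: {
    double v = 0.0;
    for (size_t j = 0; j < s.heights.size(); ++j) {
      double d = q - s.positions[j], sg = s.widths[j];
      v += s.heights[j] * std::exp(-0.5 * d * d / (sg * sg));
    }
    return v;
  }
  case 4: { // trapezoidal integral of the tabulated gradient from tab_q0
    double t = (q - s.tab_q0) / s.tab_dq;
    int n = (int)s.tab_grad.size();
    if (t < 0.0) t = 0.0;
    if (t > n - 1) t = n - 1;
    int i = (int)std::floor(t);
    double v = 0.0;
    for (int j = 0; j < i; ++j)
      v += 0.5 * (s.tab_grad[j] + s.tab_grad[j + 1]) * s.tab_dq;
    double f = t - i;
    if (i < n - 1) {
      double gq = (1.0 - f) * s.tab_grad[i] + f * s.tab_grad[i + 1];
      v += 0.5 * (s.tab_grad[i] + gq) * f * s.tab_dq;
    }
    return v;
  }
  }
  return 0.0;
}

// Metropolis-adjusted overdamped Langevin (MALA) under
// U = A*(q) + c/2 (q - anchor)^2, so the stationary law is exactly
// exp(-beta U) at any stable step size. `noise` is pre-scaled
// N(0, sqrt(2 kT dt / gamma)) and `unif` U(0,1), both drawn in R so that all
// randomness flows through R's RNG and seeds. kT = 0 degenerates to plain
// gradient descent (monotone relaxation to the biased minimum).
// [[Rcpp::export]]
NumericVector cpp_sample_window(List pmf, double anchor, double force_const,
                                double dt, double damping, double kT,
                                NumericVector noise, NumericVector unif,
                                int burn_in, int stride, int n_samples,
                                double q0) {
  PmfSpec s = make_spec(pmf);
  NumericVector out(n_samples);
  double q = q0;
  int n_steps = burn_in + stride * n_samples;
  if (noise.size() < n_steps) stop("noise vector shorter than trajectory");
  double h = dt / damping;
  double u_cur = pmf_value_cpp(s, q) +
    0.5 * force_const * (q - anchor) * (q - anchor);
  double g_cur = pmf_grad_cpp(s, q) + force_const * (q - anchor);
  int k = 0;
  for (int t = 0; t < n_steps; ++t) {
    double prop = q - h * g_cur + noise[t];
    if (!std::isfinite(prop) || std::fabs(prop) > 1e4)
      stop("trajectory diverged; reduce the time step dt = %f", dt);
    double u_prop = pmf_value_cpp(s, prop) +
      0.5 * force_const * (prop - anchor) * (prop - anchor);
    double g_prop = pmf_grad_cpp(s, prop) + force_const * (prop - anchor);
    bool accept;
    if (kT <= 0.0) {
      accept = u_prop <= u_cur;
    } else {
      double fwd = prop - q + h * g_cur;   // forward proposal residual
      double bwd = q - prop + h * g_prop;  // reverse proposal residual
      double log_alpha = -(u_prop - u_cur) / kT -
        (bwd * bwd - fwd * fwd) / (4.0 * kT * h);
      accept = (log_alpha >= 0.0) || (unif[t] < std::exp(log_alpha));
    }
    if (accept) {
      q = prop;
      u_cur = u_prop;
      g_cur = g_prop;
    }
    if (t >= burn_in && ((t - burn_in + 1) % stride == 0)) {
      out[k++] = q;
      if (k == n_samples) break;
    }
  }
  return out;
}

// Steered pull with a moving harmonic anchor; records q when the anchor
// first crosses each requested window anchor.
// [[Rcpp::export]]
List cpp_steered(List pmf, double q_from, double q_to, double velocity,
                 double force_const, double dt, double damping,
                 NumericVector noise, NumericVector anchors, double q0) {
  PmfSpec s = make_spec(pmf);
  int n_anchor = anchors.size();
  NumericVector snap_q(n_anchor, NA_REAL), snap_t(n_anchor, NA_REAL);
  double dir = (q_to >= q_from) ? 1.0 : -1.0;
  double q = q0;
  double span = std::fabs(q_to - q_from);
  int n_steps = (int)std::ceil(span / (velocity * dt)) + 1;
  if (noise.size() < n_steps) stop("noise vector shorter than pull");
  int next = 0;
  // anchors are visited in pull order; assume caller sorted them that way
  for (int t = 0; t < n_steps && next < n_anchor; ++t) {
    double a = q_from + dir * velocity * dt * t;
    double f = pmf_grad_cpp(s, q) + force_const * (q - a);
    q += -dt / damping * f + noise[t];
    if (!std::isfinite(q) || std::fabs(q) > 1e4)
      stop("pull diverged; reduce the time step dt = %f", dt);
    while (next < n_anchor && dir * (a - anchors[next]) >= 0.0) {
      snap_q[next] = q;
      snap_t[next] = dt * t;
      ++next;
    }
  }
  return List::create(_["q"] = snap_q, _["time"] = snap_t);
}

// Gaussian-kernel mean shift on a voxel grid. values: column-major array of
// dim[0] x dim[1] x dim[2]; voxel/origin in Angstrom. Negative densities are
// clamped to zero (carry no mass). Kernel truncated at 3 sigma.
// Returns converged points, kernel-smoothed density there, iteration counts,
// and a null-shift flag for starts with zero total weight.
// [[Rcpp::export]]
List cpp_mean_shift(NumericVector values, IntegerVector dim,
                    NumericVector voxel, NumericVector origin,
                    NumericMatrix starts, double bandwidth,
                    int max_iter, double tol) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = starts.nrow();
  NumericMatrix pts(n, 3);
  NumericVector dens(n);
  IntegerVector iters(n);
  LogicalVector null_shift(n);
  double sig2 = bandwidth * bandwidth;
  double cut = 3.0 * bandwidth;
  double cut2 = cut * cut;

  for (int p = 0; p < n; ++p) {
    double y[3] = {starts(p, 0), starts(p, 1), starts(p, 2)};
    int it = 0;
    bool null_flag = false;
    for (it = 0; it < max_iter; ++it) {
      int lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        lo[d] = (int)std::ceil((y[d] - cut - origin[d]) / voxel[d]);
        hi[d] = (int)std::floor((y[d] + cut - origin[d]) / voxel[d]);
        int nd = (d == 0 ? nx : (d == 1 ? ny : nz));
        if (lo[d] < 0) lo[d] = 0;
        if (hi[d] > nd - 1) hi[d] = nd - 1;
      }
      double wsum = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
      for (int k = lo[2]; k <= hi[2]; ++k) {
        double cz = origin[2] + k * voxel[2], dz = cz - y[2];
        for (int j = lo[1]; j <= hi[1]; ++j) {
          double cy = origin[1] + j * voxel[1], dy = cy - y[1];
          double dyz2 = dy * dy + dz * dz;
          if (dyz2 > cut2) continue;
          size_t base = (size_t)k * nx * ny + (size_t)j * nx;
          for (int i = lo[0]; i <= hi[0]; ++i) {
            double rho = values[base + i];
            if (rho <= 0.0) continue;
            double cx = origin[0] + i * voxel[0], dx = cx - y[0];
            double d2 = dx * dx + dyz2;
            if (d2 > cut2) continue;
            double w = rho * std::exp(-0.5 * d2 / sig2);
            wsum += w;
            mx += w * cx; my += w * cy; mz += w * cz;
          }
        }
      }
      if (wsum <= 0.0) { null_flag = true; break; }
      double ny_[3] = {mx / wsum, my / wsum, mz / wsum};
      double step2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = ny_[d] - y[d];
        step2 += dd * dd;
        y[d] = ny_[d];
      }
      if (max_iter == 1) break;
      if (std::sqrt(step2) < tol) { ++it; break; }
    }
    // kernel-smoothed density at the final point
    double dval = 0.0;
    {
      int lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        lo[d] = (int)std::ceil((y[d] - cut - origin[d]) / voxel[d]);
        hi[d] = (int)std::floor((y[d] + cut - origin[d]) / voxel[d]);
        int nd = (d == 0 ? nx : (d == 1 ? ny : nz));
        if (lo[d] < 0) lo[d] = 0;
        if (hi[d] > nd - 1) hi[d] = nd - 1;
      }
      for (int k = lo[2]; k <= hi[2]; ++k) {
        double dz = origin[2] + k * voxel[2] - y[2];
        for (int j = lo[1]; j <= hi[1]; ++j) {
          double dy = origin[1] + j * voxel[1] - y[1];
          double dyz2 = dy * dy + dz * dz;
          if (dyz2 > cut2) continue;
          size_t base = (size_t)k * nx * ny + (size_t)j * nx;
          for (int i = lo[0]; i <= hi[0]; ++i) {
            double rho = values[base + i];
            if (rho <= 0.0) continue;
            double dx = origin[0] + i * voxel[0] - y[0];
            double d2 = dx * dx + dyz2;
            if (d2 <= cut2) dval += rho * std::exp(-0.5 * d2 / sig2);
          }
        }
      }
    }
    pts(p, 0) = y[0]; pts(p, 1) = y[1]; pts(p, 2) = y[2];
    dens[p] = dval;
    iters[p] = it;
    null_shift[p] = null_flag;
  }
  return List::create(_["points"] = pts, _["density"] = dens,
                      _["iterations"] = iters, _["null_shift"] = null_shift);
}
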