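// Compiled twin of the R reference engine (R/engine.R). The arithmetic
// mirrors the R code operation for operation (including long-double sum
// accumulation, matching base R's sum()/cumsum()), so the two engines
// agree elementwise to ~1e-15 and tests can assert <= 1e-12.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Engine {
  int nx, ny, n;
  double ex, ey, cw, chh;
  std::vector<double> xs, ys;
  const double *S;
  // parameters (natural scale)
  double omega_A, omega_F, omega_FoR, omega_CB;
  double sigma_A, sigma_F, sigma_post, sigma_CB_x, sigma_CB_y;
  double gam, C_F, zeta, psi, chi, eta, nu, tau_pre, tau_post;
  bool center_bias, omp_literal;
  // state and scratch
  std::vector<double> A, F, Ftarget, At, pi, gx, gy, fg, dx2, dy2;

  Engine(const NumericMatrix &Smat, const List &par) {
    NumericVector xs_ = par["xs"], ys_ = par["ys"];
    nx = xs_.size();
    ny = ys_.size();
    n = nx * ny;
    if (Smat.nrow() != nx || Smat.ncol() != ny)
      stop("saliency map shape does not match the grid");
    xs.assign(xs_.begin(), xs_.end());
    ys.assign(ys_.begin(), ys_.end());
    ex = as<double>(par["extent_x"]);
    ey = as<double>(par["extent_y"]);
    cw = ex / nx;
    chh = ey / ny;
    S = Smat.begin();
    omega_A = as<double>(par["omega_A"]);
    omega_F = as<double>(par["omega_F"]);
    omega_FoR = as<double>(par["omega_FoR"]);
    omega_CB = as<double>(par["omega_CB"]);
    sigma_A = as<double>(par["sigma_A"]);
    sigma_F = as<double>(par["sigma_F"]);
    sigma_post = as<double>(par["sigma_post"]);
    sigma_CB_x = as<double>(par["sigma_CB_x"]);
    sigma_CB_y = as<double>(par["sigma_CB_y"]);
    gam = as<double>(par["gamma"]);
    C_F = as<double>(par["C_F"]);
    zeta = as<double>(par["zeta"]);
    psi = as<double>(par["psi"]);
    chi = as<double>(par["chi"]);
    eta = as<double>(par["eta"]);
    nu = as<double>(par["nu"]);
    tau_pre = as<double>(par["tau_pre"]);
    tau_post = as<double>(par["tau_post"]);
    center_bias = as<bool>(par["center_bias"]);
    omp_literal = as<bool>(par["omp_literal"]);
    A.resize(n);
    F.resize(n);
    Ftarget.resize(n);
    At.resize(n);
    pi.resize(n);
    gx.resize(nx);
    gy.resize(ny);
    fg.resize(n);
    dx2.resize(nx);
    dy2.resize(ny);
  }

  static double lsum(const std::vector<double> &v) {
    long double s = 0.0L;
    for (double x : v) s += x;
    return (double)s;
  }

  void cell_of(double x, double y, int &i, int &j) const {
    i = (int)std::floor(x / cw);
    if (i < 0) i = 0;
    if (i >= nx) i = nx - 1;
    j = (int)std::floor(y / chh);
    if (j < 0) j = 0;
    if (j >= ny) j = ny - 1;
  }

  // out = 1/(2 pi sx sy) * exp(...) at all cell centers (separable)
  void gauss(double cx, double cy, double sx, double sy,
             std::vector<double> &out) {
    const double k = 1.0 / (2.0 * M_PI * sx * sy);
    for (int i = 0; i < nx; i++)
      gx[i] = std::exp(-(xs[i] - cx) * (xs[i] - cx) / (2.0 * sx * sx));
    for (int j = 0; j < ny; j++)
      gy[j] = std::exp(-(ys[j] - cy) * (ys[j] - cy) / (2.0 * sy * sy));
    for (int j = 0; j < ny; j++) {
      double *col = out.data() + (size_t)j * nx;
      for (int i = 0; i < nx; i++) col[i] = k * (gx[i] * gy[j]);
    }
  }

  // attention input: normalized S * G(center, sigma)
  void attention_target(double cx, double cy, double sigma,
                        std::vector<double> &out) {
    gauss(cx, cy, sigma, sigma, out);
    for (int c = 0; c < n; c++) out[c] = S[c] * out[c];
    double s = lsum(out);
    if (!(s > 0.0))
      stop("saliency is degenerate under the attention aperture (zero sum)");
    for (int c = 0; c < n; c++) out[c] /= s;
  }

  // A = target + decay * (A - target), with the slower rate om_in inside
  // the square facilitation window around (px, py)
  void evolve_attention(const std::vector<double> &target, double dt,
                        double om_out, double om_in, bool has_win,
                        double px, double py) {
    const double e_out = std::exp(-om_out * dt);
    if (!has_win || om_in == om_out) {
      for (int c = 0; c < n; c++)
        A[c] = target[c] + e_out * (A[c] - target[c]);
      return;
    }
    const double e_in = std::exp(-om_in * dt);
    for (int j = 0; j < ny; j++) {
      const bool wy = std::fabs(ys[j] - py) < nu;
      for (int i = 0; i < nx; i++) {
        const int c = i + nx * j;
        const double e =
            (wy && std::fabs(xs[i] - px) < nu) ? e_in : e_out;
        A[c] = target[c] + e * (A[c] - target[c]);
      }
    }
  }

  void evolve_inhibition(double dt) {
    const double e = std::exp(-omega_F * dt);
    for (int c = 0; c < n; c++)
      F[c] = Ftarget[c] + e * (F[c] - Ftarget[c]);
  }

  void init_state() {
    if (center_bias) {
      gauss(ex / 2.0, ey / 2.0, sigma_CB_x, sigma_CB_y, A);
      double s = lsum(A);
      for (int c = 0; c < n; c++) A[c] /= s;
      std::fill(F.begin(), F.end(), 0.0);
    } else {
      std::fill(A.begin(), A.end(), 1.0 / n);
      std::fill(F.begin(), F.end(), 1.0 / n);
    }
  }

  // priority -> rectified -> probability map; use_omp adds the
  // oculomotor potential centered at (fx, fy)
  void build_pi(bool use_omp, double fx, double fy) {
    std::vector<double> &u = pi; // build in place
    for (int c = 0; c < n; c++) {
      double a = A[c] > 0.0 ? A[c] : 0.0;
      u[c] = std::pow(a, gam);
    }
    double sa = lsum(u);
    if (!(sa > 0.0)) stop("activation map is identically zero");
    for (int c = 0; c < n; c++) {
      double f = F[c] > 0.0 ? F[c] : 0.0;
      fg[c] = std::pow(f, gam);
    }
    double sf = lsum(fg);
    if (sf > 0.0) {
      for (int c = 0; c < n; c++) u[c] = u[c] / sa - C_F * (fg[c] / sf);
    } else {
      // all-zero inhibition happens only at t = 0 under center bias
      for (int c = 0; c < n; c++) u[c] = u[c] / sa;
    }
    if (use_omp && psi > 0.0) {
      // the potential is separable: ((x-xf)^2 (y-yf)^2)^chi =
      // ((x-xf)^2)^chi * ((y-yf)^2)^chi, with 0^chi := 0 on the cross
      std::vector<double> &omp = fg; // reuse scratch
      for (int i = 0; i < nx; i++) {
        const double b = (xs[i] - fx) * (xs[i] - fx);
        dx2[i] = b == 0.0 ? 0.0 : std::pow(b, chi);
      }
      for (int j = 0; j < ny; j++) {
        const double b = (ys[j] - fy) * (ys[j] - fy);
        dy2[j] = b == 0.0 ? 0.0 : std::pow(b, chi);
      }
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++)
          omp[i + nx * j] = dx2[i] * dy2[j];
      double so = lsum(omp);
      if (!(so > 0.0)) stop("oculomotor map has zero sum with `psi` > 0");
      if (omp_literal) {
        for (int c = 0; c < n; c++) u[c] = u[c] + psi * std::fabs(omp[c] / so);
      } else {
        for (int c = 0; c < n; c++) u[c] = u[c] - psi * (omp[c] / so);
      }
    }
    for (int c = 0; c < n; c++)
      if (u[c] < 0.0) u[c] = 0.0;
    double su = lsum(u);
    if (su > 0.0) {
      const double floor_p = zeta / n;
      for (int c = 0; c < n; c++)
        u[c] = (1.0 - zeta) * (u[c] / su) + floor_p;
    } else {
      if (zeta <= 0.0)
        stop("all-zero priority map with `zeta` = 0: selection undefined");
      for (int c = 0; c < n; c++) u[c] = 1.0 / n;
    }
  }

  // phases of fixation i at (x, y) with duration dur, previous fixation
  // (px, py) if has_prev; evolves A and F to the selection instant and
  // fills `pi`; returns the pre-phase duration still to run
  double advance(double x, double y, double dur, bool has_prev, double px,
                 double py, bool first, double &om_A_eff, double &om_FoR_eff) {
    const double pre = std::min(tau_pre, dur);
    double post = 0.0;
    double rx = 0.0, ry = 0.0;
    if (has_prev && (px != x || py != y)) {
      post = std::min(tau_post, dur - pre);
      if (post > 0.0) {
        const double dxv = x - px, dyv = y - py;
        const double len = std::sqrt(dxv * dxv + dyv * dyv);
        rx = x + dxv / len * eta;
        ry = y + dyv / len * eta;
      }
    }
    const double main_d = dur - pre - post;
    om_A_eff = (first && center_bias) ? omega_CB : omega_A;
    om_FoR_eff = has_prev ? std::min(omega_FoR, om_A_eff) : om_A_eff;
    if (post > 0.0) {
      attention_target(rx, ry, sigma_post, At);
      evolve_attention(At, post, om_A_eff, om_FoR_eff, has_prev, px, py);
    }
    if (main_d > 0.0) {
      attention_target(x, y, sigma_A, At);
      evolve_attention(At, main_d, om_A_eff, om_FoR_eff, has_prev, px, py);
    }
    gauss(x, y, sigma_F, sigma_F, Ftarget);
    double s = lsum(Ftarget);
    for (int c = 0; c < n; c++) Ftarget[c] /= s;
    evolve_inhibition(post + main_d);
    build_pi(true, x, y);
    return pre;
  }

  void finish(double pre, double nx_deg, double ny_deg, bool has_prev,
              double px, double py, double om_A_eff, double om_FoR_eff) {
    if (pre > 0.0) {
      attention_target(nx_deg, ny_deg, sigma_A, At);
      evolve_attention(At, pre, om_A_eff, om_FoR_eff, has_prev, px, py);
      evolve_inhibition(pre);
    }
  }

  // multinomial draw from `pi` by cumulative-sum inversion (one
  // unif_rand() call, matching runif(1) + cumsum in the R engine)
  int sample_cell() {
    const double u = unif_rand();
    long double acc = 0.0L;
    for (int c = 0; c < n; c++) {
      acc += pi[c];
      if (u < (double)acc) return c;
    }
    return n - 1;
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_replay(NumericMatrix path, NumericMatrix S, List par) {
  Engine e(S, par);
  const int m = path.nrow();
  if (m < 1) stop("empty scan path");
  NumericVector ll(m);
  e.init_state();
  int ci, cj;
  e.build_pi(false, 0.0, 0.0);
  e.cell_of(path(0, 0), path(0, 1), ci, cj);
  ll[0] = std::log2(e.pi[ci + e.nx * cj]);
  for (int i = 0; i + 1 < m; i++) {
    const bool has_prev = i > 0;
    const double px = has_prev ? path(i - 1, 0) : 0.0;
    const double py = has_prev ? path(i - 1, 1) : 0.0;
    double omA, omR;
    const double pre = e.advance(path(i, 0), path(i, 1), path(i, 2),
                                 has_prev, px, py, i == 0, omA, omR);
    e.cell_of(path(i + 1, 0), path(i + 1, 1), ci, cj);
    ll[i + 1] = std::log2(e.pi[ci + e.nx * cj]);
    e.finish(pre, path(i + 1, 0), path(i + 1, 1), has_prev, px, py, omA, omR);
  }
  return ll;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector durations, NumericMatrix S,
                           List par) {
  Engine e(S, par);
  const int m = durations.size();
  if (m < 1) stop("need at least one fixation duration");
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; i++) out(i, 2) = durations[i];
  e.init_state();
  if (e.center_bias) {
    e.build_pi(false, 0.0, 0.0);
    const int c = e.sample_cell();
    out(0, 0) = e.xs[c % e.nx];
    out(0, 1) = e.ys[c / e.nx];
  } else {
    out(0, 0) = e.ex / 2.0;
    out(0, 1) = e.ey / 2.0;
  }
  for (int i = 0; i + 1 < m; i++) {
    const bool has_prev = i > 0;
    const double px = has_prev ? out(i - 1, 0) : 0.0;
    const double py = has_prev ? out(i - 1, 1) : 0.0;
    double omA, omR;
    const double pre = e.advance(out(i, 0), out(i, 1), durations[i],
                                 has_prev, px, py, i == 0, omA, omR);
    const int c = e.sample_cell();
    out(i + 1, 0) = e.xs[c % e.nx];
    out(i + 1, 1) = e.ys[c / e.nx];
    e.finish(pre, out(i + 1, 0), out(i + 1, 1), has_prev, px, py, omA, omR);
  }
  colnames(out) = CharacterVector::create("x", "y", "dur");
  return out;
}
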