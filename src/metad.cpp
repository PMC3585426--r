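// Langevin (BAOAB) propagation and well-tempered metadynamics on toy
// potentials, with the bias held on a regular grid: every deposited hill is
// accumulated exactly (analytic value and derivative at every node, no
// cutoff) and per-step forces use multilinear interpolation. The same
// node-accumulation routine serves the in-run bias and the replay from a
// hills record, so the two are bit-identical by construction.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

static inline double pow_int(double x, int e) {
  double r = 1.0;
  for (int i = 0; i < e; ++i) r *= x;
  return r;
}

struct Grid {
  int d;
  std::vector<std::vector<double>> ax; // node positions per axis (uniform)
  std::vector<double> h;               // spacing
  std::vector<int> n;
  std::vector<double> V;               // values, first axis fastest
  std::vector<std::vector<double>> dV; // analytic derivative per axis
  long ntot;

  void init(const List& axes, bool with_deriv) {
    d = axes.size();
    ax.resize(d); h.resize(d); n.resize(d);
    ntot = 1;
    for (int k = 0; k < d; ++k) {
      NumericVector a = axes[k];
      ax[k] = std::vector<double>(a.begin(), a.end());
      n[k] = a.size();
      if (n[k] < 2) stop("bias grid axis needs at least 2 points");
      h[k] = (ax[k][n[k] - 1] - ax[k][0]) / (n[k] - 1);
      ntot *= n[k];
    }
    V.assign(ntot, 0.0);
    if (with_deriv) {
      dV.resize(d);
      for (int k = 0; k < d; ++k) dV[k].assign(ntot, 0.0);
    }
  }

  // add one Gaussian hill exactly at every node
  void add_hill(const double* c, const double* s, double height) {
    std::vector<int> idx(d, 0);
    for (long m = 0; m < ntot; ++m) {
      double e = 0.0;
      for (int k = 0; k < d; ++k) {
        double dx = ax[k][idx[k]] - c[k];
        e += dx * dx / (2.0 * s[k] * s[k]);
      }
      double g = height * std::exp(-e);
      V[m] += g;
      if (!dV.empty())
        for (int k = 0; k < d; ++k) {
          double dx = ax[k][idx[k]] - c[k];
          dV[k][m] += g * (-dx / (s[k] * s[k]));
        }
      for (int k = 0; k < d; ++k) {
        if (++idx[k] < n[k]) break;
        idx[k] = 0;
      }
    }
  }

  // multilinear interpolation of V (and optionally force = -dV)
  double interp(const double* x, double* force) const {
    std::vector<int> i0(d);
    std::vector<double> f(d);
    for (int k = 0; k < d; ++k) {
      double u = (x[k] - ax[k][0]) / h[k];
      if (u < 0.0 || u > n[k] - 1)
        stop("CV excursion beyond the bias grid; widen the grid or add walls");
      int i = (int)std::floor(u);
      if (i > n[k] - 2) i = n[k] - 2;
      i0[k] = i;
      f[k] = u - i;
    }
    double val = 0.0;
    if (force) for (int k = 0; k < d; ++k) force[k] = 0.0;
    int corners = 1 << d;
    for (int cmask = 0; cmask < corners; ++cmask) {
      double w = 1.0;
      long m = 0, stride = 1;
      for (int k = 0; k < d; ++k) {
        int bit = (cmask >> k) & 1;
        w *= bit ? f[k] : (1.0 - f[k]);
        m += (long)(i0[k] + bit) * stride;
        stride *= n[k];
      }
      val += w * V[m];
      if (force)
        for (int k = 0; k < d; ++k) force[k] -= w * dV[k][m];
    }
    return val;
  }
};

static void potential_force(int kind, const NumericVector& pars,
                            const std::vector<double>& x,
                            double& U, std::vector<double>& F) {
  int d = x.size();
  U = 0.0;
  if (kind == 1) { // separable double well: sum a*(x^2-1)^2
    double a = pars[0];
    for (int k = 0; k < d; ++k) {
      double q = x[k] * x[k] - 1.0;
      U += a * q * q;
      F[k] = -4.0 * a * x[k] * q;
    }
  } else if (kind == 2) { // harmonic: sum 0.5*kf*x^2
    double kf = pars[0];
    for (int k = 0; k < d; ++k) {
      U += 0.5 * kf * x[k] * x[k];
      F[k] = -kf * x[k];
    }
  } else stop("unknown toy potential kind");
}

// walls matrix columns: cv (1-based), at, side (+1 upper / -1 lower),
// kappa, rescale, exponent
static void wall_force(const NumericMatrix& walls, const std::vector<double>& x,
                       double& U, std::vector<double>& F) {
  for (int w = 0; w < walls.nrow(); ++w) {
    int j = (int)walls(w, 0) - 1;
    double at = walls(w, 1), side = walls(w, 2);
    double kappa = walls(w, 3), r = walls(w, 4);
    int e = (int)walls(w, 5);
    double s = x[j];
    bool active = side > 0 ? (s > at) : (s < at);
    if (!active) continue;
    double u = (s - at) / r;
    U += kappa * pow_int(u, e);
    F[j] -= kappa * e * pow_int(u, e - 1) / r;
  }
}

// [[Rcpp::export]]
List metad_run_cpp(int pot_kind, NumericVector pot_pars, NumericVector x0,
                   double mass, double dt, double friction,
                   double temperature, int n_steps, int pace, double h0,
                   NumericVector sigma, double biasf, NumericMatrix walls,
                   List axes, int record_stride, double xbound,
                   NumericMatrix init_centers, NumericMatrix init_sigmas,
                   NumericVector init_heights) {
  int d = x0.size();
  if (d < 1 || d > 4) stop("1 to 4 CVs supported");
  Grid grid;
  grid.init(axes, true);
  // pre-accumulated static bias (e.g. a frozen bias state)
  for (int hl = 0; hl < init_centers.nrow(); ++hl) {
    std::vector<double> c(d), s(d);
    for (int k = 0; k < d; ++k) { c[k] = init_centers(hl, k); s[k] = init_sigmas(hl, k); }
    grid.add_hill(c.data(), s.data(), init_heights[hl]);
  }
  double kT = KB * temperature;
  double dT = (biasf - 1.0) * temperature; // CV temperature
  std::vector<double> x(x0.begin(), x0.end()), v(d), Fpot(d), Fw(d), Fb(d);
  // Maxwell-Boltzmann initial velocities
  for (int k = 0; k < d; ++k) v[k] = std::sqrt(kT / mass) * norm_rand();
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  double U, Uw;
  potential_force(pot_kind, pot_pars, x, U, Fpot);
  Uw = 0.0;
  std::fill(Fw.begin(), Fw.end(), 0.0);
  wall_force(walls, x, Uw, Fw);
  grid.interp(x.data(), Fb.data());

  int n_rec = n_steps / record_stride + 1;
  NumericMatrix colvar(n_rec, d + 2); // time, x..., hill bias at x
  int n_hills_max = pace > 0 ? n_steps / pace + 1 : 0;
  NumericMatrix hills(n_hills_max, 1 + 2 * d + 1); // time, center, sigma, height
  int irec = 0, ihill = 0;
  colvar(0, 0) = 0.0;
  for (int k = 0; k < d; ++k) colvar(0, k + 1) = x[k];
  colvar(0, d + 1) = grid.interp(x.data(), nullptr);

  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * (Fpot[k] + Fw[k] + Fb[k]) / mass;
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    for (int k = 0; k < d; ++k) v[k] = c1 * v[k] + c2 * norm_rand();
    for (int k = 0; k < d; ++k) x[k] += 0.5 * dt * v[k];
    for (int k = 0; k < d; ++k)
      if (std::abs(x[k]) > xbound) stop("divergent trajectory (|x| beyond bound)");
    potential_force(pot_kind, pot_pars, x, U, Fpot);
    Uw = 0.0; std::fill(Fw.begin(), Fw.end(), 0.0);
    wall_force(walls, x, Uw, Fw);
    double Vb = grid.interp(x.data(), Fb.data());
    for (int k = 0; k < d; ++k) v[k] += 0.5 * dt * (Fpot[k] + Fw[k] + Fb[k]) / mass;

    if (pace > 0 && step % pace == 0) {
      // well-tempered height rescale from the instantaneous bias
      double height = h0 * std::exp(-Vb / (KB * dT));
      hills(ihill, 0) = step * dt;
      for (int k = 0; k < d; ++k) {
        hills(ihill, 1 + k) = x[k];
        hills(ihill, 1 + d + k) = sigma[k];
      }
      hills(ihill, 1 + 2 * d) = height;
      ++ihill;
      grid.add_hill(x.data(), &sigma[0], height);
      Vb = grid.interp(x.data(), Fb.data());
    }
    if (step % record_stride == 0) {
      colvar(irec + 1, 0) = step * dt;
      for (int k = 0; k < d; ++k) colvar(irec + 1, k + 1) = x[k];
      colvar(irec + 1, d + 1) = Vb;
      ++irec;
    }
  }
  NumericVector Vgrid(grid.V.begin(), grid.V.end());
  return List::create(_["colvar"] = colvar,
                      _["hills"] = hills(Range(0, std::max(ihill - 1, 0)), _),
                      _["n_hills"] = ihill,
                      _["grid_values"] = Vgrid);
}

// Replay: accumulate hills (in deposition order) on a grid. Shares the
// node-accumulation routine with the runner, so replaying the emitted hills
// reproduces the in-run bias grid bit-for-bit.
// [[Rcpp::export]]
NumericVector accumulate_hills_grid_cpp(NumericMatrix centers,
                                        NumericMatrix sigmas,
                                        NumericVector heights, List axes) {
  int d = axes.size();
  if (centers.ncol() != d || sigmas.ncol() != d)
    stop("hill dimensionality does not match the grid");
  Grid grid;
  grid.init(axes, false);
  std::vector<double> c(d), s(d);
  for (int hl = 0; hl < centers.nrow(); ++hl) {
    for (int k = 0; k < d; ++k) { c[k] = centers(hl, k); s[k] = sigmas(hl, k); }
    grid.add_hill(c.data(), s.data(), heights[hl]);
  }
  return NumericVector(grid.V.begin(), grid.V.end());
}

// Exact (non-grid) bias value V(s_t, t) for a series of frames: for each
// frame, the sum over hills deposited at or before the frame time.
// [[Rcpp::export]]
NumericVector eval_bias_series_cpp(NumericVector hill_times,
                                   NumericMatrix centers,
                                   NumericMatrix sigmas,
                                   NumericVector heights,
                                   NumericVector frame_times,
                                   NumericMatrix S) {
  int d = centers.ncol(), H = centers.nrow(), F = S.nrow();
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    double t = frame_times[f], V = 0.0;
    for (int hl = 0; hl < H; ++hl) {
      if (hill_times[hl] > t) break; // hills are time-ordered
      double e = 0.0;
      for (int k = 0; k < d; ++k) {
        double dx = S(f, k) - centers(hl, k);
        e += dx * dx / (2.0 * sigmas(hl, k) * sigmas(hl, k));
      }
      V += heights[hl] * std::exp(-e);
    }
    out[f] = V;
  }
  return out;
}

// Time-dependent bias offset c(t), updated once per hill on the grid:
// c_k = (1/beta) * log( sum exp(beta*g1*V) / sum exp(beta*g2*V) )
// with g1 = gamma/(gamma-1), g2 = 1/(gamma-1).
// [[Rcpp::export]]
NumericVector bias_offset_cpp(NumericMatrix centers, NumericMatrix sigmas,
                              NumericVector heights, List axes,
                              double beta, double biasf) {
  int d = axes.size(), H = centers.nrow();
  Grid grid;
  grid.init(axes, false);
  double g1 = biasf / (biasf - 1.0), g2 = 1.0 / (biasf - 1.0);
  NumericVector out(H);
  std::vector<double> c(d), s(d);
  for (int hl = 0; hl < H; ++hl) {
    for (int k = 0; k < d; ++k) { c[k] = centers(hl, k); s[k] = sigmas(hl, k); }
    grid.add_hill(c.data(), s.data(), heights[hl]);
    double m = *std::max_element(grid.V.begin(), grid.V.end());
    double s1 = 0.0, s2 = 0.0;
    for (long i = 0; i < grid.ntot; ++i) {
      s1 += std::exp(beta * g1 * (grid.V[i] - m));
      s2 += std::exp(beta * g2 * (grid.V[i] - m));
    }
    out[hl] = (std::log(s1) - std::log(s2)) / beta + (g1 - g2) * m;
  }
  return out;
}
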