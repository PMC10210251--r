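// Langevin / TAMD integration engine and grid utilities.
//
// Units throughout: kcal/mol (energy), Angstrom (length), ps (time),
// amu (mass), Kelvin (temperature).  1 kcal/mol = 418.4 amu A^2/ps^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double KB = 0.0019872041;   // kcal/(mol K)
static const double FCONV = 418.4;       // (kcal/mol) -> amu A^2/ps^2

// ---------------------------------------------------------------------------
// Model potentials.  kind: 1 harmonic, 2 double well, 3 Mueller-Brown,
// 4 toy selectivity filter (ions in a cylinder + 1D gate particle).
// Parameters arrive as a flat numeric vector assembled on the R side; the
// layouts here must stay in lockstep with the R constructors.
// ---------------------------------------------------------------------------

// Mueller-Brown standard constants
static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

struct ToyFilterParams {
  int n_ions;
  double radius, k_rad;
  std::vector<double> centers, depths;
  double sigma;            // well width
  double rep_height, rep_sigma;
  double zlo, zhi, k_zdom; // container walls along z
  double gate_c1, gate_c2, gate_h, gate_kxy;
  double couple, couple_sigma;
};

static ToyFilterParams parse_toy(const NumericVector& p) {
  ToyFilterParams tp;
  int i = 0;
  tp.n_ions = (int)p[i++];
  tp.radius = p[i++]; tp.k_rad = p[i++];
  int nw = (int)p[i++];
  tp.centers.resize(nw); tp.depths.resize(nw);
  for (int w = 0; w < nw; ++w) tp.centers[w] = p[i++];
  for (int w = 0; w < nw; ++w) tp.depths[w] = p[i++];
  tp.sigma = p[i++];
  tp.rep_height = p[i++]; tp.rep_sigma = p[i++];
  tp.zlo = p[i++]; tp.zhi = p[i++]; tp.k_zdom = p[i++];
  tp.gate_c1 = p[i++]; tp.gate_c2 = p[i++]; tp.gate_h = p[i++];
  tp.gate_kxy = p[i++];
  tp.couple = p[i++]; tp.couple_sigma = p[i++];
  return tp;
}

// energy + accumulate gradient (grad must be zero-initialised by caller)
static double potential_eg(int kind, const NumericVector& params,
                           const double* x, int n, double* grad) {
  double e = 0.0;
  if (kind == 1) {            // harmonic, params = per-coordinate k
    for (int i = 0; i < n; ++i) {
      double k = params[i];
      e += 0.5 * k * x[i] * x[i];
      grad[i] += k * x[i];
    }
  } else if (kind == 2) {     // double well in x, harmonic in y
    double h = params[0], a = params[1], ky = params[2];
    double u = x[0] / a, q = u * u - 1.0;
    e += h * q * q + 0.5 * ky * x[1] * x[1];
    grad[0] += 4.0 * h * q * u / a;
    grad[1] += ky * x[1];
  } else if (kind == 3) {     // Mueller-Brown
    for (int k = 0; k < 4; ++k) {
      double dx = x[0] - MB_x0[k], dy = x[1] - MB_y0[k];
      double ex = MB_A[k] * std::exp(MB_a[k]*dx*dx + MB_b[k]*dx*dy + MB_c[k]*dy*dy);
      e += ex;
      grad[0] += ex * (2.0*MB_a[k]*dx + MB_b[k]*dy);
      grad[1] += ex * (MB_b[k]*dx + 2.0*MB_c[k]*dy);
    }
  } else if (kind == 4) {     // toy filter: n = 3*(n_ions+1), gate last
    ToyFilterParams tp = parse_toy(params);
    int ni = tp.n_ions;
    int gi = 3 * ni;          // gate offset
    for (int p = 0; p < ni; ++p) {
      double xi = x[3*p], yi = x[3*p+1], zi = x[3*p+2];
      double r = std::sqrt(xi*xi + yi*yi);
      if (r > tp.radius) {
        double d = r - tp.radius;
        e += 0.5 * tp.k_rad * d * d;
        double f = tp.k_rad * d / r;
        grad[3*p]   += f * xi;
        grad[3*p+1] += f * yi;
      }
      for (size_t w = 0; w < tp.centers.size(); ++w) {
        double dz = zi - tp.centers[w];
        double g = std::exp(-dz*dz / (2.0*tp.sigma*tp.sigma));
        e += -tp.depths[w] * g;
        grad[3*p+2] += tp.depths[w] * g * dz / (tp.sigma*tp.sigma);
      }
      if (zi < tp.zlo) { e += 0.5*tp.k_zdom*(zi-tp.zlo)*(zi-tp.zlo); grad[3*p+2] += tp.k_zdom*(zi-tp.zlo); }
      if (zi > tp.zhi) { e += 0.5*tp.k_zdom*(zi-tp.zhi)*(zi-tp.zhi); grad[3*p+2] += tp.k_zdom*(zi-tp.zhi); }
      // gate coupling (repulsive Gaussian on axial separation)
      double dzg = zi - x[gi+2];
      double s2 = tp.couple_sigma * tp.couple_sigma;
      double gc = tp.couple * std::exp(-dzg*dzg / (2.0*s2));
      e += gc;
      grad[3*p+2] += -gc * dzg / s2;
      grad[gi+2]  +=  gc * dzg / s2;
    }
    // axial pair repulsion
    for (int p = 0; p < ni; ++p)
      for (int q = p+1; q < ni; ++q) {
        double dz = x[3*p+2] - x[3*q+2];
        double s2 = tp.rep_sigma * tp.rep_sigma;
        double g = tp.rep_height * std::exp(-dz*dz / (2.0*s2));
        e += g;
        grad[3*p+2] += -g * dz / s2;
        grad[3*q+2] +=  g * dz / s2;
      }
    // gate particle: transverse harmonic + axial double well
    double gx = x[gi], gy = x[gi+1], gz = x[gi+2];
    e += 0.5 * tp.gate_kxy * (gx*gx + gy*gy);
    grad[gi]   += tp.gate_kxy * gx;
    grad[gi+1] += tp.gate_kxy * gy;
    double mid = 0.5*(tp.gate_c1 + tp.gate_c2), half = 0.5*(tp.gate_c2 - tp.gate_c1);
    double u = (gz - mid)/half, q = u*u - 1.0;
    e += tp.gate_h * q * q;
    grad[gi+2] += 4.0 * tp.gate_h * q * u / half;
  } else {
    stop("unknown potential kind %d", kind);
  }
  return e;
}

// ---------------------------------------------------------------------------
// Restraints.  Parsed from an R list of lists, field `type` in
// {"exclusion","wall","positional"}; index fields are 0-based flat
// coordinate indices (or, for exclusion, the flat x-offset of each 3D
// particle).
// ---------------------------------------------------------------------------

struct Excl { std::vector<int> off; double xmin,xmax,ymin,ymax,zmin,zmax,k,w; };
struct Wall { std::vector<int> idx; double bound, kappa; int side; }; // side +1: penalize > bound
struct Posr { std::vector<int> idx; std::vector<double> ref; double kappa; };

struct RestraintSet {
  std::vector<Excl> ex;
  std::vector<Wall> wl;
  std::vector<Posr> pr;
};

static RestraintSet parse_restraints(List restraints) {
  RestraintSet rs;
  for (int i = 0; i < restraints.size(); ++i) {
    List r = restraints[i];
    std::string type = as<std::string>(r["type"]);
    if (type == "exclusion") {
      Excl e;
      IntegerVector off = r["offsets"];
      e.off.assign(off.begin(), off.end());
      NumericVector b = r["box"]; // xmin xmax ymin ymax zmin zmax
      e.xmin=b[0]; e.xmax=b[1]; e.ymin=b[2]; e.ymax=b[3]; e.zmin=b[4]; e.zmax=b[5];
      e.k = as<double>(r["k"]); e.w = as<double>(r["ramp_width"]);
      rs.ex.push_back(e);
    } else if (type == "wall") {
      Wall w;
      IntegerVector idx = r["idx"];
      w.idx.assign(idx.begin(), idx.end());
      w.bound = as<double>(r["bound"]);
      w.kappa = as<double>(r["kappa"]);
      w.side = as<int>(r["side"]);
      rs.wl.push_back(w);
    } else if (type == "positional") {
      Posr p;
      IntegerVector idx = r["idx"];
      p.idx.assign(idx.begin(), idx.end());
      NumericVector ref = r["ref"];
      p.ref.assign(ref.begin(), ref.end());
      p.kappa = as<double>(r["kappa"]);
      rs.pr.push_back(p);
    } else {
      stop("unknown restraint type '%s'", type.c_str());
    }
  }
  return rs;
}

// C1 smoothstep plateau: 0 outside [lo,hi], 1 on [lo+w, hi-w]
static inline double plateau(double u, double lo, double hi, double w, double* ds) {
  *ds = 0.0;
  if (u <= lo || u >= hi) return 0.0;
  if (u < lo + w) {
    double t = (u - lo) / w;
    *ds = (6.0*t - 6.0*t*t) / w;
    return t*t*(3.0 - 2.0*t);
  }
  if (u > hi - w) {
    double t = (hi - u) / w;
    *ds = -(6.0*t - 6.0*t*t) / w;
    return t*t*(3.0 - 2.0*t);
  }
  return 1.0;
}

static double restraint_eg(const RestraintSet& rs, const double* x, int n, double* grad) {
  double e = 0.0;
  for (const Excl& r : rs.ex) {
    for (int off : r.off) {
      double dsx, dsy, dsz;
      double sx = plateau(x[off],   r.xmin, r.xmax, r.w, &dsx);
      double sy = plateau(x[off+1], r.ymin, r.ymax, r.w, &dsy);
      double sz = plateau(x[off+2], r.zmin, r.zmax, r.w, &dsz);
      e += r.k * sx * sy * sz;
      grad[off]   += r.k * dsx * sy * sz;
      grad[off+1] += r.k * sx * dsy * sz;
      grad[off+2] += r.k * sx * sy * dsz;
    }
  }
  for (const Wall& w : rs.wl) {
    for (int i : w.idx) {
      double d = (x[i] - w.bound) * w.side;
      if (d > 0) {
        e += 0.5 * w.kappa * d * d;
        grad[i] += w.kappa * d * w.side;
      }
    }
  }
  for (const Posr& p : rs.pr) {
    for (size_t j = 0; j < p.idx.size(); ++j) {
      double d = x[p.idx[j]] - p.ref[j];
      e += 0.5 * p.kappa * d * d;
      grad[p.idx[j]] += p.kappa * d;
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_potential_eval(int kind, NumericVector params, NumericVector x) {
  int n = x.size();
  NumericVector grad(n);
  double e = potential_eg(kind, params, x.begin(), n, grad.begin());
  return List::create(_["energy"] = e, _["gradient"] = grad);
}

// [[Rcpp::export]]
NumericVector cpp_potential_energy_batch(int kind, NumericVector params,
                                         NumericMatrix X) {
  int m = X.nrow(), n = X.ncol();
  NumericVector out(m);
  std::vector<double> xi(n), g(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) xi[j] = X(i, j);
    std::fill(g.begin(), g.end(), 0.0);
    out[i] = potential_eg(kind, params, xi.data(), n, g.data());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_restraint_eval(List restraints, NumericVector x) {
  RestraintSet rs = parse_restraints(restraints);
  int n = x.size();
  NumericVector grad(n);
  double e = restraint_eg(rs, x.begin(), n, grad.begin());
  return List::create(_["energy"] = e, _["gradient"] = grad);
}

// ---------------------------------------------------------------------------
// Integrator: BAOAB Langevin on x, optional TAMD auxiliaries z with
// overdamped Euler-Maruyama and harmonic tethers kappa to theta = J x.
// Uses R's RNG; seed determinism comes from set.seed() on the R side.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_langevin(int kind, NumericVector params, List restraints,
                  NumericVector x0, NumericVector v0, NumericVector masses,
                  double dt, double gamma, double temperature,
                  int n_steps, int save_every,
                  Nullable<NumericMatrix> Jcv, double kappa,
                  NumericVector z0, double gamma_bar, double T_bar,
                  double max_spring_ext = 250.0) {
  int n = x0.size();
  RestraintSet rs = parse_restraints(restraints);
  bool tamd = Jcv.isNotNull();
  NumericMatrix J;
  int M = 0;
  if (tamd) { J = NumericMatrix(Jcv); M = J.nrow(); }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> z(M), theta(M), grad(n), fx(n);
  if (tamd) for (int j = 0; j < M; ++j) z[j] = z0[j];

  // per-coordinate OU coefficients
  double a_ou = std::exp(-gamma * dt);
  std::vector<double> b_ou(n), invm(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = FCONV / masses[i];
    b_ou[i] = std::sqrt(KB * temperature * invm[i] * (1.0 - a_ou * a_ou));
  }
  double z_drift = dt * kappa / gamma_bar;
  double z_noise = std::sqrt(2.0 * dt * KB * T_bar / gamma_bar);

  int n_save = n_steps / save_every;
  NumericVector times(n_save);
  NumericMatrix X(n_save, n);
  NumericMatrix Z(tamd ? n_save : 0, M), TH(tamd ? n_save : 0, M);

  RNGScope scope;

  auto eval_theta = [&]() {
    for (int j = 0; j < M; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += J(j, i) * x[i];
      theta[j] = s;
    }
  };

  auto forces = [&]() -> double {
    std::fill(grad.begin(), grad.end(), 0.0);
    double e = potential_eg(kind, params, x.data(), n, grad.data());
    e += restraint_eg(rs, x.data(), n, grad.data());
    if (tamd) {
      eval_theta();
      for (int j = 0; j < M; ++j) {
        double d = theta[j] - z[j];
        e += 0.5 * kappa * d * d;
        for (int i = 0; i < n; ++i) grad[i] += kappa * d * J(j, i);
      }
    }
    for (int i = 0; i < n; ++i) fx[i] = -grad[i];
    return e;
  };

  double e = forces();
  if (!std::isfinite(e)) stop("non-finite initial energy");
  int isave = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B A O A B
    for (int i = 0; i < n; ++i) v[i] += 0.5 * dt * fx[i] * invm[i];
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    if (gamma > 0.0 && temperature > 0.0) {
      for (int i = 0; i < n; ++i) v[i] = a_ou * v[i] + b_ou[i] * norm_rand();
    } else if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) v[i] = a_ou * v[i];
    }
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    // auxiliary overdamped step uses theta at the pre-force positions of
    // this step's end; evaluate after x update, before force refresh
    if (tamd) {
      eval_theta();
      for (int j = 0; j < M; ++j) {
        z[j] += z_drift * (theta[j] - z[j]) + z_noise * norm_rand();
        if (std::fabs(theta[j] - z[j]) > max_spring_ext)
          stop("TAMD spring extension diverged (|theta-z| > %g A) at step %d",
               max_spring_ext, step);
      }
    }
    e = forces();
    for (int i = 0; i < n; ++i) v[i] += 0.5 * dt * fx[i] * invm[i];
    if (e > 1e8 || !std::isfinite(e))
      stop("energy overflow (%g kcal/mol) at step %d", e, step);

    if (step % save_every == 0) {
      times[isave] = step * dt;
      for (int i = 0; i < n; ++i) X(isave, i) = x[i];
      if (tamd) {
        for (int j = 0; j < M; ++j) { Z(isave, j) = z[j]; TH(isave, j) = theta[j]; }
      }
      ++isave;
    }
  }

  List out = List::create(
    _["times"] = times, _["x_frames"] = X,
    _["x_final"] = NumericVector(x.begin(), x.end()),
    _["v_final"] = NumericVector(v.begin(), v.end()),
    _["final_energy"] = e);
  if (tamd) { out["z_frames"] = Z; out["theta_frames"] = TH; }
  return out;
}

// ---------------------------------------------------------------------------
// Minimax (highest point minimised) path value between two nodes of a
// gridded surface: sort nodes by value, activate in order with union-find
// over 4-neighbourhoods; the node whose activation first connects the two
// endpoints is the saddle of the minimax path.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export]]
List cpp_minimax_saddle(NumericMatrix V, int i1, int j1, int i2, int j2) {
  // indices are 1-based from R
  int nr = V.nrow(), nc = V.ncol();
  int s = (i1-1) + (j1-1)*nr, t = (i2-1) + (j2-1)*nr;
  int N = nr * nc;
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return V[a] < V[b]; });
  std::vector<int> par(N, -1);
  for (int k = 0; k < N; ++k) {
    int id = ord[k];
    if (!std::isfinite(V[id])) break;
    par[id] = id;
    int r = id % nr, c = id / nr;
    const int dr[4] = {1,-1,0,0}, dc[4] = {0,0,1,-1};
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int nb = rr + cc * nr;
      if (par[nb] >= 0) {
        int ra = uf_find(par, id), rb = uf_find(par, nb);
        if (ra != rb) par[ra] = rb;
      }
    }
    if (par[s] >= 0 && par[t] >= 0 && uf_find(par, s) == uf_find(par, t)) {
      return List::create(_["value"] = V[id],
                          _["i"] = id % nr + 1, _["j"] = id / nr + 1);
    }
  }
  stop("endpoints are not connected on the finite part of the surface");
}
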