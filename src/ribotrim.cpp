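#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Boltzmann constant in kcal mol^-1 K^-1
static const double KB_KCAL = 0.0019872041;

// ---------------------------------------------------------------------------
// Model surfaces.  kind codes: 1 harmonic, 2 double well (1D), 3 staged
// three-coordinate mechanism surface.  Parameters are packed flat so the
// sampler can evaluate them without calling back into R.
// ---------------------------------------------------------------------------

// quintic smootherstep on [0,1]: zero first and second derivative at both ends
static inline double smstep(double t) { return t * t * t * (10.0 + t * (-15.0 + 6.0 * t)); }
static inline double smstep_d(double t) { double u = t * (1.0 - t); return 30.0 * u * u; }

// mechanism surface parameters: D (deprotonation cost), B (main barrier),
// alpha (asynchronicity), a (half CV displacement), K (channel coupling),
// M (synchrony stiffness), Ep (product free energy), cw (wall stiffness)
struct MechPar {
  double D, B, alpha, a, K, M, Ep, cw;
};

static inline void mech_P(const MechPar& p, double x1, double* E, double* dE) {
  if (x1 < -p.a) {
    *E = p.cw * (x1 + p.a) * (x1 + p.a);
    *dE = 2.0 * p.cw * (x1 + p.a);
  } else if (x1 <= p.a) {
    double t = (x1 + p.a) / (2.0 * p.a);
    *E = p.D * smstep(t);
    *dE = p.D * smstep_d(t) / (2.0 * p.a);
  } else {
    *E = p.D + p.cw * (x1 - p.a) * (x1 - p.a);
    *dE = 2.0 * p.cw * (x1 - p.a);
  }
}

static inline void mech_h(const MechPar& p, double x1, double* h, double* dh) {
  if (x1 < -p.a) { *h = 1.0; *dh = 0.0; }
  else if (x1 <= p.a) {
    double t = (x1 + p.a) / (2.0 * p.a);
    *h = 1.0 - smstep(t);
    *dh = -smstep_d(t) / (2.0 * p.a);
  } else { *h = 0.0; *dh = 0.0; }
}

static inline void mech_Q(const MechPar& p, double u, double* Q, double* dQ) {
  if (u < -p.a) {
    *Q = p.cw * (u + p.a) * (u + p.a);
    *dQ = 2.0 * p.cw * (u + p.a);
  } else if (u <= 0.0) {
    double t = (u + p.a) / p.a;
    *Q = (p.B - p.D) * smstep(t);
    *dQ = (p.B - p.D) * smstep_d(t) / p.a;
  } else if (u <= p.a) {
    double t = u / p.a;
    *Q = (p.B - p.D) + (p.Ep - p.B) * smstep(t);
    *dQ = (p.Ep - p.B) * smstep_d(t) / p.a;
  } else {
    *Q = (p.Ep - p.D) + p.cw * (u - p.a) * (u - p.a);
    *dQ = 2.0 * p.cw * (u - p.a);
  }
}

// asynchrony shape: C1, peaks at u = 0, vanishes with zero slope at |u| >= a
static inline void mech_phi(const MechPar& p, double u, double* f, double* df) {
  double t = u / p.a;
  if (t <= -1.0 || t >= 1.0) { *f = 0.0; *df = 0.0; return; }
  double w = 1.0 - t * t;
  *f = w * w;
  *df = -4.0 * t * w / p.a;
}

static double surf_eval(int kind, const double* par, int d, const double* x,
                        double* grad) {
  if (kind == 1) { // harmonic: par = k[0..d-1], c[0..d-1]
    double E = 0.0;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - par[d + i];
      E += 0.5 * par[i] * dx * dx;
      if (grad) grad[i] = par[i] * dx;
    }
    return E;
  }
  if (kind == 2) { // symmetric double well: par = (barrier, separation)
    double b = par[0], sep = par[1];
    double q = (2.0 * x[0] / sep) * (2.0 * x[0] / sep);
    double E = b * (q - 1.0) * (q - 1.0);
    if (grad) grad[0] = b * 2.0 * (q - 1.0) * (8.0 * x[0] / (sep * sep));
    return E;
  }
  if (kind == 3) { // mechanism surface
    MechPar p;
    p.D = par[0]; p.B = par[1]; p.alpha = par[2]; p.a = par[3];
    p.K = par[4]; p.M = par[5]; p.Ep = par[6]; p.cw = par[7];
    double x1 = x[0], u = 0.5 * (x[1] + x[2]), v = 0.5 * (x[1] - x[2]);
    double P, dP, h, dh, Q, dQ, f, df;
    mech_P(p, x1, &P, &dP);
    mech_h(p, x1, &h, &dh);
    mech_Q(p, u, &Q, &dQ);
    mech_phi(p, u, &f, &df);
    double ua = u + p.a;
    double dv = v - p.alpha * f;
    double E = P + Q + p.K * h * ua * ua + p.M * dv * dv;
    if (grad) {
      double gx1 = dP + p.K * dh * ua * ua;
      double gu = dQ + 2.0 * p.K * h * ua - 2.0 * p.M * dv * p.alpha * df;
      double gv = 2.0 * p.M * dv;
      grad[0] = gx1;
      grad[1] = 0.5 * (gu + gv);
      grad[2] = 0.5 * (gu - gv);
    }
    return E;
  }
  stop("unknown surface kind code");
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector surf_energy_cpp(int kind, NumericVector par, NumericMatrix s) {
  int n = s.nrow(), d = s.ncol();
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = s(i, j);
    out[i] = surf_eval(kind, par.begin(), d, x.data(), nullptr);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix surf_gradient_cpp(int kind, NumericVector par, NumericMatrix s) {
  int n = s.nrow(), d = s.ncol();
  NumericMatrix out(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = s(i, j);
    surf_eval(kind, par.begin(), d, x.data(), g.data());
    for (int j = 0; j < d; ++j) out(i, j) = g[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian hill bias.  Hills are (centers n x d, sigmas n x d, heights n).
// Contributions below exp(-30) are dropped; this truncation is deterministic.
// ---------------------------------------------------------------------------

// `nh` hills stored column-major with leading dimension `ld`
static double bias_at(const double* centers, const double* sigmas,
                      const double* heights, int nh, int ld, int d,
                      const double* s, double* grad) {
  double V = 0.0;
  if (grad) for (int j = 0; j < d; ++j) grad[j] = 0.0;
  for (int i = 0; i < nh; ++i) {
    double z = 0.0;
    for (int j = 0; j < d; ++j) {
      double ds = (s[j] - centers[i + (size_t)ld * j]) / sigmas[i + (size_t)ld * j];
      z += 0.5 * ds * ds;
      if (z > 30.0) break;
    }
    if (z > 30.0) continue;
    double g = heights[i] * std::exp(-z);
    V += g;
    if (grad) {
      for (int j = 0; j < d; ++j) {
        double sig = sigmas[i + (size_t)ld * j];
        grad[j] += -g * (s[j] - centers[i + (size_t)ld * j]) / (sig * sig);
      }
    }
  }
  return V;
}

// [[Rcpp::export]]
NumericVector bias_energy_cpp(NumericMatrix centers, NumericMatrix sigmas,
                              NumericVector heights, NumericMatrix s) {
  int nh = centers.nrow(), d = s.ncol(), n = s.nrow();
  if (nh > 0 && centers.ncol() != d) stop("hill dimensionality does not match points");
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = s(i, j);
    out[i] = bias_at(REAL(centers), REAL(sigmas), REAL(heights), nh, nh, d, x.data(), nullptr);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix bias_gradient_cpp(NumericMatrix centers, NumericMatrix sigmas,
                                NumericVector heights, NumericMatrix s) {
  int nh = centers.nrow(), d = s.ncol(), n = s.nrow();
  if (nh > 0 && centers.ncol() != d) stop("hill dimensionality does not match points");
  NumericMatrix out(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = s(i, j);
    bias_at(REAL(centers), REAL(sigmas), REAL(heights), nh, nh, d, x.data(), g.data());
    for (int j = 0; j < d; ++j) out(i, j) = g[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multi-walker metadynamics: BAOAB Langevin dynamics in CV space on
// energy = surface + accumulated bias, reflecting walls at the domain box,
// synchronous hill deposition every `pace` steps.  Uses R's RNG so runs are
// reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List meta_run_cpp(int kind, NumericVector par,
                  NumericVector lower, NumericVector upper,
                  NumericMatrix init, double dt, double temp, double friction,
                  NumericVector mass, double hill_h, NumericVector hill_w,
                  int pace, int nsteps, int record_stride, double biasf,
                  NumericMatrix hills0_centers, NumericMatrix hills0_sigmas,
                  NumericVector hills0_heights, double t0) {
  int nw = init.nrow(), d = init.ncol();
  int n0 = hills0_centers.nrow();
  int ndep = (pace > 0 && hill_h > 0.0) ? (nsteps / pace) : 0;
  int cap = n0 + ndep * nw;

  // column-major hill storage shared by all walkers
  std::vector<double> hc((size_t)cap * d), hs((size_t)cap * d), hh(cap);
  std::vector<double> htime(cap);
  std::vector<int> hwalker(cap);
  for (int i = 0; i < n0; ++i) {
    for (int j = 0; j < d; ++j) {
      hc[i + (size_t)cap * j] = hills0_centers(i, j);
      hs[i + (size_t)cap * j] = hills0_sigmas(i, j);
    }
    hh[i] = hills0_heights[i];
    htime[i] = NA_REAL;
    hwalker[i] = NA_INTEGER;
  }
  int nh = n0;

  std::vector<double> x((size_t)nw * d), v((size_t)nw * d), f((size_t)nw * d);
  std::vector<double> c1(d), c2(d);
  double kT = KB_KCAL * temp;
  for (int j = 0; j < d; ++j) {
    c1[j] = std::exp(-friction * dt);
    c2[j] = (temp > 0.0) ? std::sqrt(kT / mass[j] * (1.0 - c1[j] * c1[j])) : 0.0;
  }

  RNGScope scope;
  for (int w = 0; w < nw; ++w) {
    for (int j = 0; j < d; ++j) {
      x[w + (size_t)nw * j] = init(w, j);
      v[w + (size_t)nw * j] = (temp > 0.0) ? std::sqrt(kT / mass[j]) * norm_rand() : 0.0;
    }
  }

  std::vector<double> sj(d), g(d), gb(d);
  auto forces = [&](int w) {
    for (int j = 0; j < d; ++j) sj[j] = x[w + (size_t)nw * j];
    double E = surf_eval(kind, par.begin(), d, sj.data(), g.data());
    if (!std::isfinite(E)) return false;
    if (nh > 0) {
      bias_at(hc.data(), hs.data(), hh.data(), nh, cap, d, sj.data(), gb.data());
      for (int j = 0; j < d; ++j) g[j] += gb[j]; // total gradient: surface + bias
    }
    for (int j = 0; j < d; ++j) f[w + (size_t)nw * j] = -g[j];
    return true;
  };
  for (int w = 0; w < nw; ++w)
    if (!forces(w)) stop("non-finite energy at initial position of walker %d", w + 1);

  int nrec = (record_stride > 0) ? nsteps / record_stride : 0;
  NumericVector traj((size_t)nw * nrec * d); // walker-major cube, filled below
  traj.attr("dim") = IntegerVector::create(nw, nrec, d);

  for (int step = 1; step <= nsteps; ++step) {
    for (int w = 0; w < nw; ++w) {
      for (int j = 0; j < d; ++j) {
        size_t k = w + (size_t)nw * j;
        v[k] += 0.5 * dt * f[k] / mass[j];
        x[k] += 0.5 * dt * v[k];
        // reflecting walls
        while (x[k] < lower[j] || x[k] > upper[j]) {
          if (x[k] < lower[j]) { x[k] = 2.0 * lower[j] - x[k]; v[k] = -v[k]; }
          else { x[k] = 2.0 * upper[j] - x[k]; v[k] = -v[k]; }
        }
        v[k] = c1[j] * v[k] + c2[j] * norm_rand();
        x[k] += 0.5 * dt * v[k];
        while (x[k] < lower[j] || x[k] > upper[j]) {
          if (x[k] < lower[j]) { x[k] = 2.0 * lower[j] - x[k]; v[k] = -v[k]; }
          else { x[k] = 2.0 * upper[j] - x[k]; v[k] = -v[k]; }
        }
      }
      if (!forces(w)) stop("non-finite energy at step %d (walker %d)", step, w + 1);
      for (int j = 0; j < d; ++j) {
        size_t k = w + (size_t)nw * j;
        v[k] += 0.5 * dt * f[k] / mass[j];
      }
    }
    if (ndep > 0 && step % pace == 0) {
      for (int w = 0; w < nw; ++w) {
        double h = hill_h;
        if (biasf > 1.0) { // well-tempered rescaling
          for (int j = 0; j < d; ++j) sj[j] = x[w + (size_t)nw * j];
          double Vb = bias_at(hc.data(), hs.data(), hh.data(), nh, cap, d, sj.data(), nullptr);
          h = hill_h * std::exp(-Vb / (KB_KCAL * temp * (biasf - 1.0)));
        }
        for (int j = 0; j < d; ++j) {
          hc[nh + (size_t)cap * j] = x[w + (size_t)nw * j];
          hs[nh + (size_t)cap * j] = hill_w[j];
        }
        hh[nh] = h;
        htime[nh] = t0 + step * dt;
        hwalker[nh] = w + 1;
        ++nh;
      }
    }
    if (record_stride > 0 && step % record_stride == 0) {
      int r = step / record_stride - 1;
      for (int w = 0; w < nw; ++w)
        for (int j = 0; j < d; ++j)
          traj[w + (size_t)nw * (r + (size_t)nrec * j)] = x[w + (size_t)nw * j];
    }
  }

  int nnew = nh - n0;
  NumericMatrix out_c(nnew, d), out_s(nnew, d);
  NumericVector out_h(nnew), out_t(nnew);
  IntegerVector out_w(nnew);
  for (int i = 0; i < nnew; ++i) {
    for (int j = 0; j < d; ++j) {
      out_c(i, j) = hc[n0 + i + (size_t)cap * j];
      out_s(i, j) = hs[n0 + i + (size_t)cap * j];
    }
    out_h[i] = hh[n0 + i];
    out_t[i] = htime[n0 + i];
    out_w[i] = hwalker[n0 + i];
  }
  NumericMatrix fin(nw, d);
  for (int w = 0; w < nw; ++w)
    for (int j = 0; j < d; ++j) fin(w, j) = x[w + (size_t)nw * j];
  return List::create(_["centers"] = out_c, _["sigmas"] = out_s,
                      _["heights"] = out_h, _["times"] = out_t,
                      _["walkers"] = out_w, _["trajectory"] = traj,
                      _["final"] = fin);
}

// ---------------------------------------------------------------------------
// Bottleneck (minimax) shortest path on a regular grid with king-move
// adjacency (all 3^d - 1 unit-offset neighbours).  Ties in the bottleneck
// value are broken by hop count, then by predecessor index.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bottleneck_path_cpp(NumericVector values, IntegerVector dims,
                         int start, int end) {
  int d = dims.size();
  long n = 1;
  for (int j = 0; j < d; ++j) n *= dims[j];
  if (start < 0 || start >= n || end < 0 || end >= n) stop("node off grid");
  std::vector<long> stride(d);
  stride[0] = 1;
  for (int j = 1; j < d; ++j) stride[j] = stride[j - 1] * dims[j - 1];

  // enumerate neighbour offsets
  std::vector<std::vector<int>> offs;
  std::vector<int> cur(d, -1);
  while (true) {
    bool allz = true;
    for (int j = 0; j < d; ++j) if (cur[j] != 0) { allz = false; break; }
    if (!allz) offs.push_back(cur);
    int j = 0;
    for (; j < d; ++j) {
      if (cur[j] < 1) { cur[j]++; break; }
      cur[j] = -1;
    }
    if (j == d) break;
  }

  const double INF = R_PosInf;
  std::vector<double> best(n, INF);
  std::vector<long> hops(n, LONG_MAX), pred(n, -1);
  std::vector<int> idx(d);
  typedef std::tuple<double, long, long> Node; // (bottleneck, hops, node)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  if (!R_finite(values[start])) stop("start node is masked (non-finite)");
  best[start] = values[start];
  hops[start] = 0;
  pq.push(Node(best[start], 0, start));
  while (!pq.empty()) {
    Node t = pq.top(); pq.pop();
    double b = std::get<0>(t);
    long h = std::get<1>(t), u = std::get<2>(t);
    if (b > best[u] || (b == best[u] && h > hops[u])) continue;
    if (u == end) break;
    long rem = u;
    for (int j = d - 1; j >= 0; --j) { idx[j] = rem / stride[j]; rem %= stride[j]; }
    for (size_t o = 0; o < offs.size(); ++o) {
      long vtx = 0;
      bool ok = true;
      for (int j = 0; j < d; ++j) {
        int nj = idx[j] + offs[o][j];
        if (nj < 0 || nj >= dims[j]) { ok = false; break; }
        vtx += nj * stride[j];
      }
      if (!ok) continue;
      if (!R_finite(values[vtx])) continue;
      double nb = std::max(b, values[vtx]);
      long nhp = h + 1;
      if (nb < best[vtx] || (nb == best[vtx] && nhp < hops[vtx]) ||
          (nb == best[vtx] && nhp == hops[vtx] && pred[vtx] > u)) {
        best[vtx] = nb;
        hops[vtx] = nhp;
        pred[vtx] = u;
        pq.push(Node(nb, nhp, vtx));
      }
    }
  }
  if (!R_finite(best[end]))
    stop("product node unreachable: grid is disconnected by masked (non-finite) regions");
  std::vector<long> path;
  for (long u = end; u != -1; u = pred[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  IntegerVector out(path.size());
  for (size_t i = 0; i < path.size(); ++i) out[i] = path[i] + 1; // 1-based
  return List::create(_["nodes"] = out, _["bottleneck"] = best[end]);
}

// steepest-descent walk on the grid to the local minimum serving a node
// [[Rcpp::export]]
int grid_descend_cpp(NumericVector values, IntegerVector dims, int start) {
  int d = dims.size();
  long n = 1;
  for (int j = 0; j < d; ++j) n *= dims[j];
  std::vector<long> stride(d);
  stride[0] = 1;
  for (int j = 1; j < d; ++j) stride[j] = stride[j - 1] * dims[j - 1];
  std::vector<int> idx(d);
  long u = start;
  for (long iter = 0; iter < n; ++iter) {
    long rem = u;
    for (int j = d - 1; j >= 0; --j) { idx[j] = rem / stride[j]; rem %= stride[j]; }
    long bestv = u;
    double bval = values[u];
    // scan all king-move neighbours
    std::vector<int> cur(d, -1);
    while (true) {
      bool allz = true;
      for (int j = 0; j < d; ++j) if (cur[j] != 0) { allz = false; break; }
      if (!allz) {
        long vtx = 0; bool ok = true;
        for (int j = 0; j < d; ++j) {
          int nj = idx[j] + cur[j];
          if (nj < 0 || nj >= dims[j]) { ok = false; break; }
          vtx += nj * stride[j];
        }
        if (ok && R_finite(values[vtx]) && values[vtx] < bval) { bval = values[vtx]; bestv = vtx; }
      }
      int j = 0;
      for (; j < d; ++j) {
        if (cur[j] < 1) { cur[j]++; break; }
        cur[j] = -1;
      }
      if (j == d) break;
    }
    if (bestv == u) return (int)(u + 1); // 1-based
    u = bestv;
  }
  return (int)(u + 1);
}
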