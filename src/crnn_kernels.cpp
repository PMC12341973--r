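// Fixed-step RK4 kernels with hand-derived reverse-mode gradients
// (discretize-then-differentiate) for the CRNN right-hand side
//   f(y) = V * exp(b + W * log(max(y, floor)))
// and for the unconstrained dense tanh MLP used as a baseline.
// All matrices are small (tens of species/reactions), so plain loops
// beat BLAS dispatch here.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double YMAX = 1e6; // divergence guard on states

// ---------------------------------------------------------------- CRNN

struct CrnnPar {
  int m, s;                 // hidden reactions, species
  const double *W;          // m x s, column-major (reaction orders)
  const double *b;          // m (log rate constants)
  const double *V;          // s x m, column-major: net stoichiometry
                            // (untied) or product coefficients (tied)
  double floor_;
  bool tied;                // net stoichiometry = V - t(W)
};

// effective net stoichiometric coefficient of species i in reaction j
static inline double crnn_stoich(const CrnnPar &p, int i, int j) {
  double v = p.V[i + j * p.s];
  if (p.tied) v -= p.W[j + i * p.m];
  return v;
}

// log-clamped concentrations and candidate rates at state y
static inline void crnn_lr(const CrnnPar &p, const double *y, double *l,
                           double *r) {
  for (int i = 0; i < p.s; ++i)
    l[i] = std::log(std::max(y[i], p.floor_));
  for (int j = 0; j < p.m; ++j) {
    double z = p.b[j];
    for (int i = 0; i < p.s; ++i) z += p.W[j + i * p.m] * l[i];
    r[j] = std::exp(z);
  }
}

static inline void crnn_f(const CrnnPar &p, const double *y, double *dy,
                          double *rbuf) {
  static thread_local std::vector<double> l;
  l.resize(p.s);
  crnn_lr(p, y, l.data(), rbuf);
  for (int i = 0; i < p.s; ++i) {
    double acc = 0.0;
    for (int j = 0; j < p.m; ++j) acc += crnn_stoich(p, i, j) * rbuf[j];
    dy[i] = acc;
  }
}

// VJP of f with precomputed l and r at the same state
static inline void crnn_vjp_lr(const CrnnPar &p, const double *y,
                               const double *l, const double *r,
                               const double *a, double *gW, double *gb,
                               double *gV, double *ay, double *u) {
  for (int j = 0; j < p.m; ++j) {
    double q = 0.0;
    for (int i = 0; i < p.s; ++i) q += crnn_stoich(p, i, j) * a[i];
    u[j] = q * r[j];
    gb[j] += u[j];
    for (int i = 0; i < p.s; ++i) {
      gV[i + j * p.s] += a[i] * r[j];
      gW[j + i * p.m] += u[j] * l[i];
      if (p.tied) gW[j + i * p.m] -= a[i] * r[j];
    }
  }
  for (int i = 0; i < p.s; ++i) {
    double acc = 0.0;
    if (y[i] > p.floor_) {
      for (int j = 0; j < p.m; ++j) acc += p.W[j + i * p.m] * u[j];
      acc /= y[i];
    }
    ay[i] = acc;
  }
}

// One RK4 step forward from y (length s) with step h; writes y_out.
// Returns false on divergence.
template <typename F>
static inline bool rk4_step(F f, int s, const double *y, double h,
                            double *y_out, double *k1, double *k2,
                            double *k3, double *k4, double *tmp) {
  f(y, k1);
  for (int i = 0; i < s; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  f(tmp, k2);
  for (int i = 0; i < s; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  f(tmp, k3);
  for (int i = 0; i < s; ++i) tmp[i] = y[i] + h * k3[i];
  f(tmp, k4);
  for (int i = 0; i < s; ++i) {
    y_out[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(y_out[i]) || std::fabs(y_out[i]) > YMAX) return false;
  }
  return true;
}

// forward integration into out (T x s, column-major); returns index of
// the last valid time point (T-1 on success) or the failure interval
static int crnn_forward(const CrnnPar &p, const double *y0,
                        const double *times, int T, int substeps,
                        double *out /* T*s col-major */) {
  const int s = p.s;
  static thread_local std::vector<double> r, y, ynext, k1, k2, k3, k4, tmp;
  r.resize(p.m); y.resize(s); ynext.resize(s);
  k1.resize(s); k2.resize(s); k3.resize(s); k4.resize(s); tmp.resize(s);
  auto f = [&](const double *yy, double *dy) { crnn_f(p, yy, dy, r.data()); };
  for (int i = 0; i < s; ++i) { y[i] = y0[i]; out[0 + (long)i * T] = y0[i]; }
  for (int t = 1; t < T; ++t) {
    double h = (times[t] - times[t - 1]) / substeps;
    for (int ss = 0; ss < substeps; ++ss) {
      if (!rk4_step(f, s, y.data(), h, ynext.data(), k1.data(), k2.data(),
                    k3.data(), k4.data(), tmp.data()))
        return t - 1;
      y = ynext;
    }
    for (int i = 0; i < s; ++i) out[t + (long)i * T] = y[i];
  }
  return T - 1;
}

// loss + gradient core; writes into caller buffers (gW, gb, gV are
// ACCUMULATED into). Returns true on success, false on divergence (the
// caller then uses the capped loss and skips the gradients).
static bool crnn_loss_grad_core(const CrnnPar &p, const double *y0,
                                const double *times, const double *obs,
                                int T, int loss_kind, int substeps,
                                double mape_floor, double &loss,
                                double *gW, double *gb, double *gV) {
  const int s = p.s, m = p.m, nsub = substeps, nsteps = (T - 1) * nsub;
  static thread_local std::vector<double> store, dLdy, r, k1, k2, k3, k4,
      tmp, a, ak1, ak2, ak3, ak4, ay, y2, y3, y4, l0, l2v, l3v, l4v, r0,
      r2v, r3v, r4v, u;
  store.resize((long)(nsteps + 1) * s);
  dLdy.assign((long)T * s, 0.0);
  r.resize(m); u.resize(m);
  k1.resize(s); k2.resize(s); k3.resize(s); k4.resize(s); tmp.resize(s);
  a.resize(s); ak1.resize(s); ak2.resize(s); ak3.resize(s); ak4.resize(s);
  ay.resize(s); y2.resize(s); y3.resize(s); y4.resize(s);
  l0.resize(s); l2v.resize(s); l3v.resize(s); l4v.resize(s);
  r0.resize(m); r2v.resize(m); r3v.resize(m); r4v.resize(m);

  auto f = [&](const double *yy, double *dy) { crnn_f(p, yy, dy, r.data()); };
  for (int i = 0; i < s; ++i) store[i] = y0[i];
  int idx = 0;
  for (int t = 1; t < T; ++t) {
    double h = (times[t] - times[t - 1]) / nsub;
    for (int ss = 0; ss < nsub; ++ss, ++idx)
      if (!rk4_step(f, s, &store[(long)idx * s], h,
                    &store[(long)(idx + 1) * s], k1.data(), k2.data(),
                    k3.data(), k4.data(), tmp.data()))
        return false;
  }

  loss = 0.0;
  long cnt = 0;
  for (int t = 0; t < T; ++t) {
    const double *yt = &store[(long)t * nsub * s];
    for (int i = 0; i < s; ++i) {
      double o = obs[t + (long)i * T], d = yt[i] - o;
      if (loss_kind == 0) {
        loss += std::fabs(d);
        dLdy[t + (long)i * T] = (d > 0) - (d < 0);
        ++cnt;
      } else if (o > mape_floor) {
        loss += 100.0 * std::fabs(d) / o;
        dLdy[t + (long)i * T] = 100.0 * ((d > 0) - (d < 0)) / o;
        ++cnt;
      }
    }
  }
  if (cnt == 0 || !std::isfinite(loss)) return false;
  loss /= cnt;
  for (long i = 0; i < (long)T * s; ++i) dLdy[i] /= cnt;

  for (int i = 0; i < s; ++i) a[i] = dLdy[(T - 1) + (long)i * T];
  idx = nsteps - 1;
  for (int t = T - 1; t >= 1; --t) {
    double h = (times[t] - times[t - 1]) / nsub;
    for (int ss = 0; ss < nsub; --idx, ++ss) {
      const double *yin = &store[(long)idx * s];
      // recompute the stage states together with their rates
      crnn_lr(p, yin, l0.data(), r0.data());
      for (int i = 0; i < s; ++i) {
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += crnn_stoich(p, i, j) * r0[j];
        k1[i] = acc;
        y2[i] = yin[i] + 0.5 * h * acc;
      }
      crnn_lr(p, y2.data(), l2v.data(), r2v.data());
      for (int i = 0; i < s; ++i) {
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += crnn_stoich(p, i, j) * r2v[j];
        k2[i] = acc;
        y3[i] = yin[i] + 0.5 * h * acc;
      }
      crnn_lr(p, y3.data(), l3v.data(), r3v.data());
      for (int i = 0; i < s; ++i) {
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += crnn_stoich(p, i, j) * r3v[j];
        k3[i] = acc;
        y4[i] = yin[i] + h * acc;
      }
      crnn_lr(p, y4.data(), l4v.data(), r4v.data());
      for (int i = 0; i < s; ++i) {
        ak1[i] = h / 6.0 * a[i];
        ak2[i] = h / 3.0 * a[i];
        ak3[i] = h / 3.0 * a[i];
        ak4[i] = h / 6.0 * a[i];
      }
      crnn_vjp_lr(p, y4.data(), l4v.data(), r4v.data(), ak4.data(), gW, gb,
                  gV, ay.data(), u.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak3[i] += h * ay[i]; }
      crnn_vjp_lr(p, y3.data(), l3v.data(), r3v.data(), ak3.data(), gW, gb,
                  gV, ay.data(), u.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak2[i] += 0.5 * h * ay[i]; }
      crnn_vjp_lr(p, y2.data(), l2v.data(), r2v.data(), ak2.data(), gW, gb,
                  gV, ay.data(), u.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak1[i] += 0.5 * h * ay[i]; }
      crnn_vjp_lr(p, yin, l0.data(), r0.data(), ak1.data(), gW, gb, gV,
                  ay.data(), u.data());
      for (int i = 0; i < s; ++i) a[i] += ay[i];
    }
    if (t >= 2)
      for (int i = 0; i < s; ++i) a[i] += dLdy[(t - 1) + (long)i * T];
  }
  return true;
}

// [[Rcpp::export(name = ".crnn_integrate_cpp")]]
List crnn_integrate_cpp(NumericMatrix W, NumericVector b, NumericMatrix V,
                        NumericVector y0, NumericVector times,
                        int substeps = 1, double floor_ = 1e-8,
                        bool tied = false) {
  const int m = W.nrow(), s = W.ncol(), T = times.size();
  if (V.nrow() != s || V.ncol() != m || b.size() != m || y0.size() != s)
    stop("parameter dimension mismatch");
  CrnnPar p{m, s, REAL(W), REAL(b), REAL(V), floor_, tied};
  NumericMatrix out(T, s);
  int last = crnn_forward(p, REAL(y0), REAL(times), T, substeps, REAL(out));
  return List::create(_["trajectory"] = out,
                      _["diverged"] = last < T - 1,
                      _["last_time"] = times[last]);
}

// loss_kind: 0 = MAE, 1 = MAPE (percent, entries with obs > mape_floor)
// [[Rcpp::export(name = ".crnn_loss_grad_cpp")]]
List crnn_loss_grad_cpp(NumericMatrix W, NumericVector b, NumericMatrix V,
                        NumericVector y0, NumericVector times,
                        NumericMatrix obs, int loss_kind = 0,
                        int substeps = 1, double floor_ = 1e-8,
                        double mape_floor = 1e-6, double cap = 1e6,
                        bool tied = false) {
  const int m = W.nrow(), s = W.ncol(), T = times.size();
  if (obs.nrow() != T || obs.ncol() != s)
    stop("observation matrix must be times x species");
  CrnnPar p{m, s, REAL(W), REAL(b), REAL(V), floor_, tied};
  NumericMatrix gW(m, s), gV(s, m);
  NumericVector gb(m);
  double loss = cap;
  bool ok = crnn_loss_grad_core(p, REAL(y0), REAL(times), REAL(obs), T,
                                loss_kind, substeps, mape_floor, loss,
                                REAL(gW), REAL(gb), REAL(gV));
  if (!ok) {
    std::fill(gW.begin(), gW.end(), 0.0);
    std::fill(gb.begin(), gb.end(), 0.0);
    std::fill(gV.begin(), gV.end(), 0.0);
    loss = cap;
  }
  return List::create(_["loss"] = loss, _["gW"] = gW, _["gb"] = gb,
                      _["gV"] = gV, _["diverged"] = !ok);
}

// ----------------------------------------------------------------- MLP
// f(y) = W3 * tanh(W2 * tanh(W1 y + b1) + b2) + b3

struct MlpPar {
  int s, h1, h2;
  const double *W1, *b1, *W2, *b2, *W3, *b3; // column-major
};

static inline void mlp_f(const MlpPar &p, const double *y, double *dy,
                         double *a1, double *a2) {
  for (int j = 0; j < p.h1; ++j) {
    double z = p.b1[j];
    for (int i = 0; i < p.s; ++i) z += p.W1[j + i * p.h1] * y[i];
    a1[j] = std::tanh(z);
  }
  for (int j = 0; j < p.h2; ++j) {
    double z = p.b2[j];
    for (int i = 0; i < p.h1; ++i) z += p.W2[j + i * p.h2] * a1[i];
    a2[j] = std::tanh(z);
  }
  for (int i = 0; i < p.s; ++i) {
    double z = p.b3[i];
    for (int j = 0; j < p.h2; ++j) z += p.W3[i + j * p.s] * a2[j];
    dy[i] = z;
  }
}

static inline void mlp_vjp(const MlpPar &p, const double *y, const double *a,
                           double *gW1, double *gb1, double *gW2, double *gb2,
                           double *gW3, double *gb3, double *ay,
                           double *a1, double *a2, double *d2, double *d1) {
  mlp_f(p, y, d1 /*scratch for dy, unused*/, a1, a2);
  // back through output layer
  for (int j = 0; j < p.h2; ++j) {
    double acc = 0.0;
    for (int i = 0; i < p.s; ++i) {
      acc += p.W3[i + j * p.s] * a[i];
      gW3[i + j * p.s] += a[i] * a2[j];
    }
    d2[j] = acc * (1.0 - a2[j] * a2[j]);
  }
  for (int i = 0; i < p.s; ++i) gb3[i] += a[i];
  // back through second hidden layer
  for (int j = 0; j < p.h1; ++j) {
    double acc = 0.0;
    for (int i = 0; i < p.h2; ++i) {
      acc += p.W2[i + j * p.h2] * d2[i];
      gW2[i + j * p.h2] += d2[i] * a1[j];
    }
    d1[j] = acc * (1.0 - a1[j] * a1[j]);
  }
  for (int i = 0; i < p.h2; ++i) gb2[i] += d2[i];
  // back through first hidden layer
  for (int i = 0; i < p.s; ++i) {
    double acc = 0.0;
    for (int j = 0; j < p.h1; ++j) {
      acc += p.W1[j + i * p.h1] * d1[j];
      gW1[j + i * p.h1] += d1[j] * y[i];
    }
    ay[i] = acc;
  }
  for (int j = 0; j < p.h1; ++j) gb1[j] += d1[j];
}

// [[Rcpp::export(name = ".mlp_integrate_cpp")]]
List mlp_integrate_cpp(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
                       NumericVector b2, NumericMatrix W3, NumericVector b3,
                       NumericVector y0, NumericVector times,
                       int substeps = 1) {
  const int s = W1.ncol(), h1 = W1.nrow(), h2 = W2.nrow(), T = times.size();
  MlpPar p{s, h1, h2, REAL(W1), REAL(b1), REAL(W2), REAL(b2),
           REAL(W3), REAL(b3)};
  std::vector<double> a1(h1), a2(h2);
  auto f = [&](const double *y, double *dy) {
    mlp_f(p, y, dy, a1.data(), a2.data());
  };
  NumericMatrix out(T, s);
  std::vector<double> y(s), ynext(s), k1(s), k2(s), k3(s), k4(s), tmp(s);
  for (int i = 0; i < s; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }
  bool ok = true;
  for (int t = 1; t < T && ok; ++t) {
    double h = (times[t] - times[t - 1]) / substeps;
    for (int ss = 0; ss < substeps && ok; ++ss) {
      ok = rk4_step(f, s, y.data(), h, ynext.data(), k1.data(), k2.data(),
                    k3.data(), k4.data(), tmp.data());
      y = ynext;
    }
    for (int i = 0; i < s; ++i) out(t, i) = y[i];
    if (!ok)
      return List::create(_["trajectory"] = out, _["diverged"] = true,
                          _["last_time"] = times[t - 1]);
  }
  return List::create(_["trajectory"] = out, _["diverged"] = false,
                      _["last_time"] = times[T - 1]);
}

// [[Rcpp::export(name = ".mlp_loss_grad_cpp")]]
List mlp_loss_grad_cpp(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
                       NumericVector b2, NumericMatrix W3, NumericVector b3,
                       NumericVector y0, NumericVector times,
                       NumericMatrix obs, int substeps = 1,
                       double cap = 1e6) {
  const int s = W1.ncol(), h1 = W1.nrow(), h2 = W2.nrow(), T = times.size();
  if (obs.nrow() != T || obs.ncol() != s)
    stop("observation matrix must be times x species");
  MlpPar p{s, h1, h2, REAL(W1), REAL(b1), REAL(W2), REAL(b2),
           REAL(W3), REAL(b3)};
  std::vector<double> a1(h1), a2(h2);
  auto f = [&](const double *y, double *dy) {
    mlp_f(p, y, dy, a1.data(), a2.data());
  };
  NumericMatrix gW1(h1, s), gW2(h2, h1), gW3(s, h2);
  NumericVector gb1(h1), gb2(h2), gb3(s);
  const int nsub = substeps, nsteps = (T - 1) * nsub;
  std::vector<double> store((long)(nsteps + 1) * s);
  std::vector<double> k1(s), k2(s), k3(s), k4(s), tmp(s);
  for (int i = 0; i < s; ++i) store[i] = y0[i];
  bool ok = true;
  int idx = 0;
  for (int t = 1; t < T && ok; ++t) {
    double h = (times[t] - times[t - 1]) / nsub;
    for (int ss = 0; ss < nsub && ok; ++ss, ++idx)
      ok = rk4_step(f, s, &store[(long)idx * s], h, &store[(long)(idx + 1) * s],
                    k1.data(), k2.data(), k3.data(), k4.data(), tmp.data());
  }
  if (!ok)
    return List::create(_["loss"] = cap, _["gW1"] = gW1, _["gb1"] = gb1,
                        _["gW2"] = gW2, _["gb2"] = gb2, _["gW3"] = gW3,
                        _["gb3"] = gb3, _["diverged"] = true);
  double loss = 0.0;
  NumericMatrix dLdy(T, s);
  long cnt = (long)T * s;
  for (int t = 0; t < T; ++t) {
    const double *yt = &store[(long)t * nsub * s];
    for (int i = 0; i < s; ++i) {
      double d = yt[i] - obs(t, i);
      loss += std::fabs(d);
      dLdy(t, i) = (double)((d > 0) - (d < 0)) / cnt;
    }
  }
  loss /= cnt;
  std::vector<double> a(s, 0.0), ak1(s), ak2(s), ak3(s), ak4(s), ay(s);
  std::vector<double> y2(s), y3(s), y4(s), d2(h2), d1(std::max(h1, s));
  for (int i = 0; i < s; ++i) a[i] = dLdy(T - 1, i);
  idx = nsteps - 1;
  for (int t = T - 1; t >= 1; --t) {
    double h = (times[t] - times[t - 1]) / nsub;
    for (int ss = 0; ss < nsub; --idx, ++ss) {
      const double *yin = &store[(long)idx * s];
      mlp_f(p, yin, k1.data(), a1.data(), a2.data());
      for (int i = 0; i < s; ++i) y2[i] = yin[i] + 0.5 * h * k1[i];
      mlp_f(p, y2.data(), k2.data(), a1.data(), a2.data());
      for (int i = 0; i < s; ++i) y3[i] = yin[i] + 0.5 * h * k2[i];
      mlp_f(p, y3.data(), k3.data(), a1.data(), a2.data());
      for (int i = 0; i < s; ++i) y4[i] = yin[i] + h * k3[i];
      for (int i = 0; i < s; ++i) {
        ak1[i] = h / 6.0 * a[i];
        ak2[i] = h / 3.0 * a[i];
        ak3[i] = h / 3.0 * a[i];
        ak4[i] = h / 6.0 * a[i];
      }
      mlp_vjp(p, y4.data(), ak4.data(), REAL(gW1), REAL(gb1), REAL(gW2),
              REAL(gb2), REAL(gW3), REAL(gb3), ay.data(), a1.data(),
              a2.data(), d2.data(), d1.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak3[i] += h * ay[i]; }
      mlp_vjp(p, y3.data(), ak3.data(), REAL(gW1), REAL(gb1), REAL(gW2),
              REAL(gb2), REAL(gW3), REAL(gb3), ay.data(), a1.data(),
              a2.data(), d2.data(), d1.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak2[i] += 0.5 * h * ay[i]; }
      mlp_vjp(p, y2.data(), ak2.data(), REAL(gW1), REAL(gb1), REAL(gW2),
              REAL(gb2), REAL(gW3), REAL(gb3), ay.data(), a1.data(),
              a2.data(), d2.data(), d1.data());
      for (int i = 0; i < s; ++i) { a[i] += ay[i]; ak1[i] += 0.5 * h * ay[i]; }
      mlp_vjp(p, yin, ak1.data(), REAL(gW1), REAL(gb1), REAL(gW2),
              REAL(gb2), REAL(gW3), REAL(gb3), ay.data(), a1.data(),
              a2.data(), d2.data(), d1.data());
      for (int i = 0; i < s; ++i) a[i] += ay[i];
    }
    if (t >= 2)
      for (int i = 0; i < s; ++i) a[i] += dLdy(t - 1, i);
  }
  return List::create(_["loss"] = loss, _["gW1"] = gW1, _["gb1"] = gb1,
                      _["gW2"] = gW2, _["gb2"] = gb2, _["gW3"] = gW3,
                      _["gb3"] = gb3, _["diverged"] = false);
}

// ------------------------------------------------------------ trainer
// Runs a chunk of training epochs entirely in C++. Mini-batch indices
// and unit-variance noise are pre-drawn in R (reproducibility lives
// with R's RNG); this routine is deterministic given its inputs.
// Returns the updated state, per-epoch train/validation losses and the
// per-epoch parameter vectors.

// [[Rcpp::export(name = ".crnn_epochs_cpp")]]
List crnn_epochs_cpp(List datasets, IntegerMatrix batch_idx,
                     NumericMatrix noise, NumericVector theta0,
                     NumericVector v0, int epoch0, int m, int s,
                     List ctrl, IntegerVector val_idx) {
  const int n_epochs = batch_idx.nrow(), bsz = batch_idx.ncol();
  const int nW = m * s, nb = m, P = theta0.size();
  const int loss_kind = as<std::string>(ctrl["loss"]) == "mae" ? 0 : 1;
  const double lambda = ctrl["lambda"], beta = ctrl["beta"],
               l2 = ctrl["l2"], l1 = ctrl["l1"], alpha = ctrl["alpha"],
               step_b = ctrl["step_b"], step_gamma = ctrl["step_gamma"],
               floor_ = ctrl["floor"], mape_floor = ctrl["mape_floor"],
               cap = ctrl["cap"], grad_clip = ctrl["grad_clip"],
               gscale = ctrl["gscale"], n_noise = ctrl["n_noise"];
  const int substeps = ctrl["substeps"];
  const int val_every = ctrl["val_every"];
  const bool ema_printed = as<std::string>(ctrl["ema"]) == "printed";
  const bool precond_sqrt =
      as<std::string>(ctrl["preconditioner"]) == "sqrt";
  const bool noise_printed =
      as<std::string>(ctrl["noise_scale"]) == "printed";
  const bool psgld = as<std::string>(ctrl["optimizer"]) == "psgld";
  const bool tied = ctrl["tied"];

  // cache raw views of every dataset once
  const int nd = datasets.size();
  std::vector<const double *> d_y0(nd), d_times(nd), d_obs(nd);
  std::vector<int> d_T(nd);
  for (int k = 0; k < nd; ++k) {
    List d = datasets[k];
    NumericVector y0 = d["y0"], times = d["times"];
    NumericMatrix obs = d["concentrations"];
    d_y0[k] = REAL(y0); d_times[k] = REAL(times); d_obs[k] = REAL(obs);
    d_T[k] = times.size();
    if (obs.nrow() != d_T[k] || obs.ncol() != s)
      stop("dataset %d has inconsistent dimensions", k + 1);
  }

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> v(v0.begin(), v0.end());
  NumericVector train_loss(n_epochs), val_loss(n_epochs);
  NumericMatrix thetas(n_epochs, P);
  std::vector<double> grad(P), gtmp(P);
  std::vector<double> pred;
  double precond_max = 0.0;
  int consec_fail = 0, max_consec_fail = 0;

  for (int e = 0; e < n_epochs; ++e) {
    CrnnPar p{m, s, theta.data(), theta.data() + nW, theta.data() + nW + nb,
              floor_, tied};
    std::fill(grad.begin(), grad.end(), 0.0);
    double total = 0.0;
    int ndiv = 0;
    for (int k = 0; k < bsz; ++k) {
      int di = batch_idx(e, k) - 1;
      double loss = cap;
      std::fill(gtmp.begin(), gtmp.end(), 0.0);
      bool ok = crnn_loss_grad_core(p, d_y0[di], d_times[di], d_obs[di],
                                    d_T[di], loss_kind, substeps,
                                    mape_floor, loss, gtmp.data(),
                                    gtmp.data() + nW,
                                    gtmp.data() + nW + nb);
      if (!ok) {
        total += cap;
        ++ndiv;
      } else {
        total += loss;
        for (int i = 0; i < P; ++i) grad[i] += gtmp[i];
      }
    }
    total /= bsz;
    int n_ok = bsz - ndiv;
    if (n_ok > 0)
      for (int i = 0; i < P; ++i) grad[i] /= n_ok;
    // regularization
    if (loss_kind == 0) {
      double ss = 0.0, sa = 0.0;
      for (int i = 0; i < P; ++i) ss += theta[i] * theta[i];
      for (int i = nW + nb; i < P; ++i) sa += std::fabs(theta[i]);
      total += l2 * ss + l1 * sa;
      for (int i = 0; i < P; ++i) grad[i] += 2.0 * l2 * theta[i];
      for (int i = nW + nb; i < P; ++i)
        grad[i] += l1 * ((theta[i] > 0) - (theta[i] < 0));
    } else {
      double sa = 0.0, ss = 0.0;
      for (int i = nW + nb; i < P; ++i) sa += std::fabs(theta[i]);
      for (int i = 0; i < nW + nb; ++i) ss += theta[i] * theta[i];
      total += l1 * sa + l2 * ss;
      for (int i = nW + nb; i < P; ++i)
        grad[i] += l1 * ((theta[i] > 0) - (theta[i] < 0));
      for (int i = 0; i < nW + nb; ++i) grad[i] += 2.0 * l2 * theta[i];
    }
    for (int i = 0; i < P; ++i) {
      grad[i] *= gscale;
      if (grad[i] > grad_clip) grad[i] = grad_clip;
      if (grad[i] < -grad_clip) grad[i] = -grad_clip;
    }
    bool update_v = ndiv < bsz;
    consec_fail = (ndiv == bsz) ? consec_fail + 1 : 0;
    if (consec_fail > max_consec_fail) max_consec_fail = consec_fail;

    const double eps =
        alpha * std::pow(step_b + (double)(epoch0 + e), -step_gamma);
    for (int i = 0; i < P; ++i) {
      if (update_v)
        v[i] = ema_printed
                   ? (1.0 - beta) * v[i] + beta * grad[i] * grad[i]
                   : beta * v[i] + (1.0 - beta) * grad[i] * grad[i];
      double G = 1.0;
      if (psgld)
        G = 1.0 / (lambda + (precond_sqrt ? std::sqrt(v[i]) : v[i]));
      if (G > precond_max) precond_max = G;
      double sd = noise_printed ? std::sqrt(eps * G) / n_noise
                                : std::sqrt(2.0 * eps * G);
      theta[i] += -eps * grad[i] * G + noise(e, i) * sd;
    }
    for (int i = 0; i < nW; ++i)
      if (theta[i] < 0) theta[i] = 0;   // nonnegative reaction orders
    if (tied)                            // product coefficients too
      for (int i = nW + nb; i < P; ++i)
        if (theta[i] < 0) theta[i] = 0;

    train_loss[e] = total;
    for (int i = 0; i < P; ++i) thetas(e, i) = theta[i];

    // validation loss (forward solves only, every val_every epochs)
    if (val_idx.size() > 0 &&
        ((epoch0 + e) % val_every == 0 || e == n_epochs - 1 ||
         epoch0 + e == 1)) {
      CrnnPar pv{m, s, theta.data(), theta.data() + nW,
                 theta.data() + nW + nb, floor_, tied};
      double vtot = 0.0;
      for (int k = 0; k < val_idx.size(); ++k) {
        int di = val_idx[k] - 1;
        const int T = d_T[di];
        pred.resize((long)T * s);
        int last = crnn_forward(pv, d_y0[di], d_times[di], T, substeps,
                                pred.data());
        if (last < T - 1) {
          vtot += cap;
          continue;
        }
        double lsum = 0.0;
        long cnt = 0;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < s; ++i) {
            double o = d_obs[di][t + (long)i * T];
            if (loss_kind == 0) {
              lsum += std::fabs(pred[t + (long)i * T] - o);
              ++cnt;
            } else if (o > mape_floor) {
              lsum += 100.0 * std::fabs(pred[t + (long)i * T] - o) / o;
              ++cnt;
            }
          }
        vtot += cnt ? lsum / cnt : cap;
      }
      val_loss[e] = vtot / val_idx.size();
    } else if (val_idx.size() > 0) {
      val_loss[e] = e > 0 ? val_loss[e - 1] : NA_REAL;
    } else {
      val_loss[e] = total;
    }
  }
  return List::create(_["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss, _["thetas"] = thetas,
                      _["precond_max"] = precond_max,
                      _["max_consec_fail"] = max_consec_fail);
}
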