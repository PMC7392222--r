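// Core numerical engine: deterministic RK4 integration of the switch ODEs for
// attractor-basin fate classification, Newton refinement of attractor
// locations (exact 2-D reduction in the group activities u = sum x_i^n,
// v = sum y_i^n) used for per-cell mutation updates, and the exact Gillespie
// (SSA) population simulator with binomial partitioning at division.
//
// Conventions shared with the R layer:
//  - state layout (length 2m): x1..xm, y1..ym
//  - alpha layout (length 4m): aA_x[1..m], aI_x[1..m], aA_y[1..m], aI_y[1..m]
//  - attractor record (length 21): for each of A, B, C in that order, seven
//    slots (x1, x2, x3, y1, y2, y3, exists) with unused element slots zero.
//  - fate codes: 0 = A (x-dominant), 1 = B (y-dominant), 2 = C (stem),
//    3 = unclassifiable (no attractor available).
// All randomness uses R's RNG so seeding is controlled from R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double ipow(double x, int k) {
  double r = 1.0;
  while (k) { if (k & 1) r *= x; x *= x; k >>= 1; }
  return r;
}

struct Shared {
  int m, n;
  double beta, gamma, bn;
  Shared(int m_, int n_, double beta_, double gamma_)
    : m(m_), n(n_), beta(beta_), gamma(gamma_), bn(ipow(beta_, n_)) {}
};

// Full 2m-dimensional right-hand side. Production of element i is
// aA_i * u/(bn + u) + aI_i * bn/(bn + v') with u, v the group activities
// (sums of n-th powers) of its own and the opposing group.
static void rhs_full(const double* s, const double* al, const Shared& sh, double* out) {
  const int m = sh.m;
  double u = 0.0, v = 0.0;
  for (int i = 0; i < m; ++i) { u += ipow(s[i], sh.n); v += ipow(s[m + i], sh.n); }
  const double Hx = u / (sh.bn + u), Rx = sh.bn / (sh.bn + u);
  const double Hy = v / (sh.bn + v), Ry = sh.bn / (sh.bn + v);
  for (int i = 0; i < m; ++i)
    out[i] = al[i] * Hx + al[m + i] * Ry - sh.gamma * s[i];
  for (int i = 0; i < m; ++i)
    out[m + i] = al[2 * m + i] * Hy + al[3 * m + i] * Rx - sh.gamma * s[m + i];
}

// One classic RK4 step, in place.
static void rk4_step(double* s, const double* al, const Shared& sh, double dt,
                     double* k1, double* k2, double* k3, double* k4, double* tmp) {
  const int d = 2 * sh.m;
  rhs_full(s, al, sh, k1);
  for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
  rhs_full(tmp, al, sh, k2);
  for (int j = 0; j < d; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
  rhs_full(tmp, al, sh, k3);
  for (int j = 0; j < d; ++j) tmp[j] = s[j] + dt * k3[j];
  rhs_full(tmp, al, sh, k4);
  for (int j = 0; j < d; ++j)
    s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

// Capture test: master pair within `radius` of the attractor's master pair,
// with a loose full-state proximity guard so a transient master-pair
// coincidence in an extended switch cannot trigger a false capture.
static int capture(const double* s, const Shared& sh, const double* attr, double radius) {
  const int m = sh.m;
  const double r2 = radius * radius;
  const double rfull2 = 9.0 * radius * radius * m;
  for (int k = 0; k < 3; ++k) {
    const double* a = attr + 7 * k;
    if (a[6] < 0.5) continue;
    const double dxm = s[0] - a[0], dym = s[m] - a[3];
    if (dxm * dxm + dym * dym >= r2) continue;
    double full = 0.0;
    for (int j = 0; j < m; ++j) {
      const double ex = s[j] - a[j], ey = s[m + j] - a[3 + j];
      full += ex * ex + ey * ey;
    }
    if (full < rfull2) return k;
  }
  return -1;
}

// Integrate from `s` (modified in place) until captured by an attractor or
// the horizon is reached; at the horizon fall back to the nearest attractor
// in master-pair coordinates and set `warned`.
static int classify_one(double* s, const double* al, const Shared& sh, const double* attr,
                        double radius, double horizon, double dt, bool& warned) {
  const int d = 2 * sh.m;
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  int hit = capture(s, sh, attr, radius);
  double t = 0.0;
  while (hit < 0 && t < horizon) {
    rk4_step(s, al, sh, dt, k1, k2, k3, k4, tmp);
    for (int j = 0; j < d; ++j) if (s[j] < 0.0) s[j] = 0.0;
    t += dt;
    hit = capture(s, sh, attr, radius);
  }
  if (hit >= 0) return hit;
  warned = true;
  int best = 3;
  double bd = R_PosInf;
  for (int k = 0; k < 3; ++k) {
    const double* a = attr + 7 * k;
    if (a[6] < 0.5) continue;
    const double dxm = s[0] - a[0], dym = s[sh.m] - a[3];
    const double dd = dxm * dxm + dym * dym;
    if (dd < bd) { bd = dd; best = k; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Fixed-point refinement in the group activities (u, v).
// At a fixed point x_i = (aA_i H(u) + aI_i R(v)) / gamma with H(u) =
// u/(bn+u), R(v) = bn/(bn+v), so u = sum x_i^n closes a 2-D system. The
// Jacobian of the full dynamics is -gamma I plus a rank-2 update whose
// nonzero spectrum is that of a 2x2 matrix M, giving eigenvalues
// {-gamma + eig(M)} plus -gamma with multiplicity 2m - 2.
// ---------------------------------------------------------------------------
struct RootUV {
  double u, v, maxre;
  double x[3], y[3];
  bool ok;
};

static RootUV newton_uv(const double* al, const Shared& sh, double u, double v) {
  RootUV out; out.ok = false; out.maxre = NA_REAL;
  const int m = sh.m, n = sh.n;
  const double g = sh.gamma, bn = sh.bn;
  double x[3] = {0, 0, 0}, yy[3] = {0, 0, 0};
  for (int it = 0; it < 120; ++it) {
    const double du = bn + u, dv = bn + v;
    const double H = u / du, Rv = bn / dv, Hy = v / dv, Ru = bn / du;
    double F1 = -u, F2 = -v;
    double Sx1 = 0, Sx2 = 0, Sy1 = 0, Sy2 = 0;
    for (int i = 0; i < m; ++i) {
      x[i] = (al[i] * H + al[m + i] * Rv) / g;
      yy[i] = (al[2 * m + i] * Hy + al[3 * m + i] * Ru) / g;
      if (x[i] < 0) x[i] = 0;
      if (yy[i] < 0) yy[i] = 0;
      F1 += ipow(x[i], n);
      F2 += ipow(yy[i], n);
      const double xp = n * ipow(x[i], n - 1), yp = n * ipow(yy[i], n - 1);
      Sx1 += xp * al[i]; Sx2 += xp * al[m + i];
      Sy1 += yp * al[2 * m + i]; Sy2 += yp * al[3 * m + i];
    }
    const double Hp = bn / (du * du);   // dH/du
    const double Rvp = -bn / (dv * dv); // dR/dv
    const double Hyp = bn / (dv * dv);
    const double Rup = -bn / (du * du);
    const double J11 = Sx1 * Hp / g - 1.0, J12 = Sx2 * Rvp / g;
    const double J21 = Sy2 * Rup / g, J22 = Sy1 * Hyp / g - 1.0;
    const double det = J11 * J22 - J12 * J21;
    if (det == 0.0 || !std::isfinite(det)) return out;
    const double su = (F1 * J22 - J12 * F2) / det;
    const double sv = (J11 * F2 - F1 * J21) / det;
    u -= su; v -= sv;
    if (u < 0.0) u = 0.0;
    if (v < 0.0) v = 0.0;
    if (std::fabs(F1) < 1e-8 * (1.0 + u) && std::fabs(F2) < 1e-8 * (1.0 + v) &&
        std::fabs(su) < 1e-7 * (1.0 + u) && std::fabs(sv) < 1e-7 * (1.0 + v)) {
      // dynamics stability via the 2x2 reduced matrix M
      const double M11 = Hp * Sx1, M12 = Rvp * Sx2;
      const double M21 = Rup * Sy2, M22 = Hyp * Sy1;
      const double tr = M11 + M22, dt2 = M11 * M22 - M12 * M21;
      const double disc = tr * tr - 4.0 * dt2;
      const double mu = (disc >= 0.0) ? 0.5 * (tr + std::sqrt(disc)) : 0.5 * tr;
      out.u = u; out.v = v; out.maxre = -g + mu;
      for (int i = 0; i < m; ++i) { out.x[i] = x[i]; out.y[i] = yy[i]; }
      out.ok = true;
      return out;
    }
  }
  return out;
}

// Continue the three fate-map attractors of each cell after a parameter
// mutation. Fate lives in the 2-D master-pair system (the tri-stable circuit
// of x1 and y1 alone, with the cell's master-element alphas and the shared
// beta/gamma/n), so the attractors tracked here are that system's. Newton
// starts from the cell's previous attractor locations; fallback rows A, B, C
// (3 x 2) hold the founding preset's master-pair attractors.
// [[Rcpp::export]]
NumericMatrix cpp_attractors_update(NumericMatrix alphas, double beta, int n, double gamma,
                                    int m, NumericMatrix attr_prev, NumericMatrix fallback) {
  const Shared sh(1, n, beta, gamma);
  const int nc = alphas.nrow();
  NumericMatrix out(nc, 21);
  for (int c = 0; c < nc; ++c) {
    const double arow[4] = { alphas(c, 0), alphas(c, m),
                             alphas(c, 2 * m), alphas(c, 3 * m) };
    RootUV roots[3];
    bool ok[3];
    for (int k = 0; k < 3; ++k) {
      double u0, v0;
      if (attr_prev(c, 7 * k + 6) > 0.5) {
        u0 = ipow(attr_prev(c, 7 * k), n);
        v0 = ipow(attr_prev(c, 7 * k + 3), n);
      } else {
        u0 = ipow(fallback(k, 0), n);
        v0 = ipow(fallback(k, 1), n);
      }
      roots[k] = newton_uv(arow, sh, u0, v0);
      ok[k] = roots[k].ok && roots[k].maxre < -1e-9;
    }
    // an attractor that merged with another is lost
    auto close = [&](int a, int b) {
      return std::fabs(roots[a].x[0] - roots[b].x[0]) < 1e-3 &&
             std::fabs(roots[a].y[0] - roots[b].y[0]) < 1e-3;
    };
    if (ok[1] && ok[0] && close(1, 0)) ok[1] = false;
    if (ok[2] && ((ok[0] && close(2, 0)) || (ok[1] && close(2, 1)))) ok[2] = false;
    for (int k = 0; k < 3; ++k) {
      if (!ok[k]) { out(c, 7 * k + 6) = 0.0; continue; }
      out(c, 7 * k) = roots[k].x[0];
      out(c, 7 * k + 3) = roots[k].y[0];
      out(c, 7 * k + 6) = 1.0;
    }
  }
  return out;
}

// Batch fate classification of states sharing one parameter set.
// [[Rcpp::export]]
IntegerVector cpp_classify_batch(NumericMatrix states, NumericVector alphas, double beta,
                                 int n, double gamma, int m, NumericVector attr,
                                 double radius, double horizon, double dt) {
  const Shared sh(m, n, beta, gamma);
  const int nc = states.nrow(), d = 2 * m;
  IntegerVector out(nc);
  std::vector<double> al(alphas.begin(), alphas.end());
  std::vector<double> at(attr.begin(), attr.end());
  int warns = 0;
  std::vector<double> s(d);
  for (int c = 0; c < nc; ++c) {
    for (int j = 0; j < d; ++j) s[j] = states(c, j);
    bool w = false;
    out[c] = classify_one(s.data(), al.data(), sh, at.data(), radius, horizon, dt, w);
    if (w) ++warns;
  }
  out.attr("warnings") = warns;
  return out;
}

// Deterministic trajectory endpoint (fixed-step RK4); cross-checked against
// deSolve in the test suite.
// [[Rcpp::export]]
NumericVector cpp_ode_endpoint(NumericVector state, NumericVector alphas, double beta,
                               int n, double gamma, int m, double t_total, double dt) {
  const Shared sh(m, n, beta, gamma);
  const int d = 2 * m;
  std::vector<double> s(state.begin(), state.end());
  std::vector<double> al(alphas.begin(), alphas.end());
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  double t = 0.0;
  while (t < t_total - 1e-12) {
    double h = std::min(dt, t_total - t);
    rk4_step(s.data(), al.data(), sh, h, k1, k2, k3, k4, tmp);
    for (int j = 0; j < d; ++j) if (s[j] < 0.0) s[j] = 0.0;
    t += h;
  }
  return NumericVector(s.begin(), s.end());
}

// ---------------------------------------------------------------------------
// Exact SSA for one population of stem cells.
// Global channel order: all per-cell update channels in cell insertion order
// (within a cell: x-productions, x-degradations, y-productions,
// y-degradations), then one division channel per cell, in the same cell
// order. Each event redraws (u1, u2): u1 selects the channel, u2 the waiting
// time.
// ---------------------------------------------------------------------------
struct PopState {
  int d, a4;
  std::vector<double> st, al, at, cnt, ch, U;
  std::vector<int> lin;
  int n() const { return (int)U.size(); }
};

static void compute_chans(PopState& P, const Shared& sh, int c) {
  const int m = sh.m;
  const double* s = &P.st[c * P.d];
  const double* a = &P.al[c * P.a4];
  double* cc = &P.ch[c * P.a4];
  double u = 0.0, v = 0.0;
  for (int i = 0; i < m; ++i) { u += ipow(s[i], sh.n); v += ipow(s[m + i], sh.n); }
  const double Hx = u / (sh.bn + u), Rx = sh.bn / (sh.bn + u);
  const double Hy = v / (sh.bn + v), Ry = sh.bn / (sh.bn + v);
  double tot = 0.0;
  for (int i = 0; i < m; ++i) { cc[i] = a[i] * Hx + a[m + i] * Ry; tot += cc[i]; }
  for (int i = 0; i < m; ++i) { cc[m + i] = sh.gamma * s[i]; tot += cc[m + i]; }
  for (int i = 0; i < m; ++i) { cc[2 * m + i] = a[2 * m + i] * Hy + a[3 * m + i] * Rx; tot += cc[2 * m + i]; }
  for (int i = 0; i < m; ++i) { cc[3 * m + i] = sh.gamma * s[m + i]; tot += cc[3 * m + i]; }
  P.U[c] = tot;
}

static void erase_cell(PopState& P, int c) {
  P.st.erase(P.st.begin() + (size_t)c * P.d, P.st.begin() + (size_t)(c + 1) * P.d);
  P.al.erase(P.al.begin() + (size_t)c * P.a4, P.al.begin() + (size_t)(c + 1) * P.a4);
  P.at.erase(P.at.begin() + (size_t)c * 21, P.at.begin() + (size_t)(c + 1) * 21);
  P.cnt.erase(P.cnt.begin() + (size_t)c * 6, P.cnt.begin() + (size_t)(c + 1) * 6);
  P.ch.erase(P.ch.begin() + (size_t)c * P.a4, P.ch.begin() + (size_t)(c + 1) * P.a4);
  P.U.erase(P.U.begin() + c);
  P.lin.erase(P.lin.begin() + c);
}

// [[Rcpp::export]]
List cpp_pop_run(IntegerMatrix states, NumericMatrix alphas, NumericMatrix attr,
                 NumericMatrix counters, IntegerVector lineage, int next_id,
                 double beta, int n, double gamma, int m,
                 double t0, double t_end, double div_rate,
                 int stop_rule, int k_div, int cap,
                 double radius, double horizon, double dt_ode,
                 bool record_counts, bool classify_full) {
  const Shared sh(m, n, beta, gamma);
  PopState P;
  P.d = 2 * m; P.a4 = 4 * m;
  const int n0 = states.nrow();
  P.st.resize((size_t)n0 * P.d);
  P.al.resize((size_t)n0 * P.a4);
  P.at.resize((size_t)n0 * 21);
  P.cnt.resize((size_t)n0 * 6);
  P.ch.resize((size_t)n0 * P.a4);
  P.U.resize(n0);
  P.lin.resize(n0);
  for (int c = 0; c < n0; ++c) {
    for (int j = 0; j < P.d; ++j) P.st[c * P.d + j] = states(c, j);
    for (int j = 0; j < P.a4; ++j) P.al[c * P.a4 + j] = alphas(c, j);
    for (int j = 0; j < 21; ++j) P.at[c * 21 + j] = attr(c, j);
    for (int j = 0; j < 6; ++j) P.cnt[c * 6 + j] = counters(c, j);
    P.lin[c] = lineage[c];
    compute_chans(P, sh, c);
  }

  std::vector<double> log_t;
  std::vector<int> log_mother, log_f1, log_f2;
  std::vector<double> log_c1, log_c2;

  double t = t0;
  double S_upd = 0.0;
  for (int c = 0; c < P.n(); ++c) S_upd += P.U[c];
  long n_prod = 0, n_deg = 0, n_div = 0, events = 0;
  long stem_total = 0, daughters_total = 0;
  int warns = 0;
  bool extinct = false, capped = false, rule_met = false, timed_out = false;
  bool need_check = (stop_rule == 1);

  for (;;) {
    const int nc = P.n();
    if (nc == 0) { extinct = true; break; }
    if (nc >= cap) { capped = true; break; }
    if (need_check) {
      need_check = false;
      double mn = R_PosInf;
      for (int c = 0; c < nc; ++c) mn = std::min(mn, P.cnt[c * 6 + 3]);
      if (mn >= (double)k_div) { rule_met = true; break; }
    }
    if ((events & 8191) == 0) { // refresh running sum against FP drift
      S_upd = 0.0;
      for (int c = 0; c < nc; ++c) S_upd += P.U[c];
    }
    const double S = S_upd + nc * div_rate;
    if (S <= 0.0) { t = t_end; break; }
    const double u1 = unif_rand();
    const double u2 = unif_rand();
    const double dtv = -std::log(u2) / S;
    if (t + dtv > t_end) { t = t_end; timed_out = true; break; }
    t += dtv;
    ++events;
    const double target = u1 * S;
    if (target <= S_upd && S_upd > 0.0) {
      // update reaction: locate cell then channel by prefix sums
      double cum = 0.0;
      int c = -1;
      for (int i = 0; i < nc; ++i) {
        if (P.U[i] > 0.0 && cum + P.U[i] >= target) { c = i; break; }
        cum += P.U[i];
      }
      if (c < 0) { // numerical edge: take last cell with positive total
        for (int i = nc - 1; i >= 0; --i) if (P.U[i] > 0.0) { c = i; break; }
        if (c < 0) continue;
        cum = S_upd - P.U[c];
      }
      const double rem = target - cum;
      double cc = 0.0;
      int j = -1;
      for (int j2 = 0; j2 < P.a4; ++j2) {
        const double w = P.ch[c * P.a4 + j2];
        if (w > 0.0) { cc += w; if (cc >= rem) { j = j2; break; } }
      }
      if (j < 0) {
        for (int j2 = P.a4 - 1; j2 >= 0; --j2)
          if (P.ch[c * P.a4 + j2] > 0.0) { j = j2; break; }
        if (j < 0) continue;
      }
      double* s = &P.st[c * P.d];
      if (j < m)            { s[j] += 1.0; ++n_prod; }
      else if (j < 2 * m)   { s[j - m] -= 1.0; ++n_deg; }
      else if (j < 3 * m)   { s[m + (j - 2 * m)] += 1.0; ++n_prod; }
      else                  { s[m + (j - 3 * m)] -= 1.0; ++n_deg; }
      S_upd -= P.U[c];
      compute_chans(P, sh, c);
      S_upd += P.U[c];
    } else {
      // division channel block
      int c = (div_rate > 0.0) ? (int)((target - S_upd) / div_rate) : 0;
      if (c >= nc) c = nc - 1;
      if (c < 0) c = 0;
      ++n_div;
      // binomial partition of every determinant
      std::vector<double> d1(P.d), d2(P.d);
      const double* s = &P.st[c * P.d];
      for (int j = 0; j < P.d; ++j) {
        d1[j] = R::rbinom(s[j], 0.5);
        d2[j] = s[j] - d1[j];
      }
      // fate of each daughter: domain of its master pair (x1, y1) in the
      // mother's own (possibly mutated) 2-D master-pair fate map; with
      // classify_full, basin of the full 2m-dimensional daughter state
      // (requires matching full-system attractor records)
      bool w1 = false, w2 = false;
      int f1, f2;
      if (classify_full) {
        std::vector<double> tr1(d1), tr2(d2);
        f1 = classify_one(tr1.data(), &P.al[c * P.a4], sh, &P.at[c * 21],
                          radius, horizon, dt_ode, w1);
        f2 = classify_one(tr2.data(), &P.al[c * P.a4], sh, &P.at[c * 21],
                          radius, horizon, dt_ode, w2);
      } else {
        const Shared sh1(1, sh.n, sh.beta, sh.gamma);
        const double alm[4] = { P.al[c * P.a4], P.al[c * P.a4 + m],
                                P.al[c * P.a4 + 2 * m], P.al[c * P.a4 + 3 * m] };
        double mp1[2] = { d1[0], d1[m] }, mp2[2] = { d2[0], d2[m] };
        f1 = classify_one(mp1, alm, sh1, &P.at[c * 21],
                          radius, horizon, dt_ode, w1);
        f2 = classify_one(mp2, alm, sh1, &P.at[c * 21],
                          radius, horizon, dt_ode, w2);
      }
      if (w1) ++warns;
      if (w2) ++warns;
      const int stem = (f1 == 2) + (f2 == 2);
      stem_total += stem;
      daughters_total += 2;
      // lineage-continuation bookkeeping: update the mother's counters, then
      // both stem daughters inherit the updated record
      double* q = &P.cnt[c * 6];
      q[0] += 1.0; q[1] += stem; q[2] += 2.0;
      q[3] += 1.0; q[4] += stem; q[5] += 2.0;
      log_t.push_back(t);
      log_mother.push_back(P.lin[c]);
      log_f1.push_back(f1);
      log_f2.push_back(f2);
      if (record_counts) {
        for (int j = 0; j < P.d; ++j) log_c1.push_back(d1[j]);
        for (int j = 0; j < P.d; ++j) log_c2.push_back(d2[j]);
      }
      // stash inherited rows before the mother is removed
      std::vector<double> mal(P.al.begin() + (size_t)c * P.a4, P.al.begin() + (size_t)(c + 1) * P.a4);
      std::vector<double> mat(P.at.begin() + (size_t)c * 21, P.at.begin() + (size_t)(c + 1) * 21);
      std::vector<double> mcnt(P.cnt.begin() + (size_t)c * 6, P.cnt.begin() + (size_t)(c + 1) * 6);
      S_upd -= P.U[c];
      erase_cell(P, c);
      const int fates[2] = { f1, f2 };
      const std::vector<double>* dss[2] = { &d1, &d2 };
      for (int k = 0; k < 2; ++k) {
        if (fates[k] != 2) continue; // differentiated daughters die at birth
        for (int j = 0; j < P.d; ++j) P.st.push_back((*dss[k])[j]);
        P.al.insert(P.al.end(), mal.begin(), mal.end());
        P.at.insert(P.at.end(), mat.begin(), mat.end());
        P.cnt.insert(P.cnt.end(), mcnt.begin(), mcnt.end());
        P.ch.resize(P.ch.size() + P.a4);
        P.U.push_back(0.0);
        P.lin.push_back(next_id++);
        compute_chans(P, sh, P.n() - 1);
        S_upd += P.U[P.n() - 1];
      }
      if (stop_rule == 1) need_check = true;
    }
  }

  const int nf = P.n();
  IntegerMatrix st_out(nf, P.d);
  NumericMatrix al_out(nf, P.a4), at_out(nf, 21), cnt_out(nf, 6);
  IntegerVector lin_out(nf);
  for (int c = 0; c < nf; ++c) {
    for (int j = 0; j < P.d; ++j) st_out(c, j) = (int)std::lround(P.st[c * P.d + j]);
    for (int j = 0; j < P.a4; ++j) al_out(c, j) = P.al[c * P.a4 + j];
    for (int j = 0; j < 21; ++j) at_out(c, j) = P.at[c * 21 + j];
    for (int j = 0; j < 6; ++j) cnt_out(c, j) = P.cnt[c * 6 + j];
    lin_out[c] = P.lin[c];
  }
  const int nd = (int)log_t.size();
  List log;
  if (record_counts) {
    NumericMatrix c1(nd, P.d), c2(nd, P.d);
    for (int r = 0; r < nd; ++r)
      for (int j = 0; j < P.d; ++j) {
        c1(r, j) = log_c1[(size_t)r * P.d + j];
        c2(r, j) = log_c2[(size_t)r * P.d + j];
      }
    log = List::create(_["time"] = wrap(log_t), _["mother"] = wrap(log_mother),
                       _["fate1"] = wrap(log_f1), _["fate2"] = wrap(log_f2),
                       _["counts1"] = c1, _["counts2"] = c2);
  } else {
    log = List::create(_["time"] = wrap(log_t), _["mother"] = wrap(log_mother),
                       _["fate1"] = wrap(log_f1), _["fate2"] = wrap(log_f2));
  }
  return List::create(
    _["states"] = st_out, _["alphas"] = al_out, _["attr"] = at_out,
    _["counters"] = cnt_out, _["lineage"] = lin_out, _["next_id"] = next_id,
    _["time"] = t, _["log"] = log,
    _["events"] = NumericVector::create(_["production"] = (double)n_prod,
                                        _["degradation"] = (double)n_deg,
                                        _["division"] = (double)n_div),
    _["stem_daughters"] = (double)stem_total,
    _["total_daughters"] = (double)daughters_total,
    _["warnings"] = warns,
    _["extinct"] = extinct, _["capped"] = capped,
    _["rule_met"] = rule_met, _["timed_out"] = timed_out);
}
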