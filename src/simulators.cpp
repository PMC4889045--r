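// Compiled cores for the three simulators (Extrande thinning, slow input
// approximation, modified-next integral method) on mass-action networks whose
// rate constants may be multiplied by an exogenous input value read from a
// pre-simulated grid. Networks with arbitrary R propensity functions use the
// pure-R mirrors in R/simulate-r.R instead.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() on the R side
// gives bit-reproducible trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <numeric>
using namespace Rcpp;

namespace {

// Gridded exogenous input on [0, T_grid]; left-constant (step) or linear
// interpolation. Queries are monotone in time within one simulation, but the
// look-ahead bound scans forward, so lookups binary-search from a cursor.
struct InputGrid {
  const double* t;
  const double* v;
  int n;
  bool linear;
  mutable int cur;

  InputGrid(const NumericVector& tt, const NumericVector& vv, bool lin)
      : t(tt.begin()), v(vv.begin()), n(tt.size()), linear(lin), cur(0) {}

  int index_at(double tt) const {
    if (tt <= t[0]) return 0;
    if (cur < n - 1 && t[cur] <= tt && tt < t[cur + 1]) return cur;
    // advance cursor if close, otherwise binary search
    int i = cur;
    if (t[i] <= tt) {
      int steps = 0;
      while (i < n - 1 && t[i + 1] <= tt && steps++ < 8) ++i;
      if (i < n - 1 && t[i + 1] <= tt) {
        int lo = i, hi = n - 1;
        while (lo < hi) {
          int mid = (lo + hi + 1) / 2;
          if (t[mid] <= tt) lo = mid; else hi = mid - 1;
        }
        i = lo;
      }
    } else {
      int lo = 0, hi = i;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (t[mid] <= tt) lo = mid; else hi = mid - 1;
      }
      i = lo;
    }
    cur = i;
    return i;
  }

  double value_at(double tt) const {
    if (tt >= t[n - 1]) return v[n - 1];
    int i = index_at(tt);
    if (!linear) return v[i];
    double w = (tt - t[i]) / (t[i + 1] - t[i]);
    return v[i] + w * (v[i + 1] - v[i]);
  }

  // supremum of the interpolated trajectory on [t0, t1)
  double window_max(double t0, double t1) const {
    double m = value_at(t0);
    int i0 = index_at(t0);
    for (int i = i0 + 1; i < n && t[i] < t1; ++i)
      if (v[i] > m) m = v[i];
    // the right endpoint belongs to the closure when interpolating linearly,
    // or when a left-constant window is clipped at the grid horizon
    if (linear || t1 >= t[n - 1]) {
      double end = value_at(t1 < t[n - 1] ? t1 : t[n - 1]);
      if (end > m) m = end;
    }
    return m;
  }

  double global_max() const {
    double m = v[0];
    for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
    return m;
  }
};

struct MassActionNet {
  int n_sp, M;
  std::vector<int> stoich;   // n_sp x M, column-major
  std::vector<int> orders;   // n_sp x M, reactant copies consumed per firing
  std::vector<double> rates;
  std::vector<int> in_scaled;

  MassActionNet(const IntegerMatrix& S, const IntegerMatrix& O,
                const NumericVector& c, const LogicalVector& f)
      : n_sp(S.nrow()), M(S.ncol()),
        stoich(S.begin(), S.end()), orders(O.begin(), O.end()),
        rates(c.begin(), c.end()), in_scaled(f.begin(), f.end()) {}

  // propensity of channel j; input clipped at 0 so propensities stay >= 0
  double prop(int j, const std::vector<int>& x, double I) const {
    double a = rates[j];
    if (in_scaled[j]) a *= (I > 0.0 ? I : 0.0);
    if (a == 0.0) return 0.0;
    const int* o = &orders[(size_t)j * n_sp];
    for (int s = 0; s < n_sp; ++s) {
      for (int k = 0; k < o[s]; ++k) a *= (x[s] - k);
      if (a <= 0.0) return a > 0.0 ? a : 0.0;
    }
    return a;
  }

  double total(const std::vector<int>& x, double I, std::vector<double>& a) const {
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = prop(j, x, I); a0 += a[j]; }
    return a0;
  }

  void apply(int j, std::vector<int>& x) const {
    const int* s = &stoich[(size_t)j * n_sp];
    for (int k = 0; k < n_sp; ++k) x[k] += s[k];
  }
};

struct Recorder {
  bool record;
  bool record_pseudo;
  std::vector<double> times;
  std::vector<int> labels;      // 1..M channel, 0 thin, -1 reject-horizon
  std::vector<int> states;      // row per recorded event, n_sp wide
  int n_sp;

  const double* out_t;
  int n_out, out_k;
  std::vector<double> out_states;

  Recorder(bool rec, bool pseudo, int nsp, const NumericVector& ot)
      : record(rec), record_pseudo(pseudo), n_sp(nsp),
        out_t(ot.begin()), n_out(ot.size()), out_k(0) {
    out_states.resize((size_t)n_out * nsp);
  }

  void event(double t, int label, const std::vector<int>& x) {
    if (!record) return;
    if (label <= 0 && !record_pseudo) return;
    times.push_back(t);
    labels.push_back(label);
    states.insert(states.end(), x.begin(), x.end());
  }

  // record state (right-continuous) at output times strictly before t_new
  void flush_until(double t_new, const std::vector<int>& x) {
    while (out_k < n_out && out_t[out_k] < t_new) {
      for (int s = 0; s < n_sp; ++s)
        out_states[(size_t)out_k * n_sp + s] = x[s];
      ++out_k;
    }
  }

  void flush_final(const std::vector<int>& x) {
    while (out_k < n_out) {
      for (int s = 0; s < n_sp; ++s)
        out_states[(size_t)out_k * n_sp + s] = x[s];
      ++out_k;
    }
  }

  List result(const std::vector<int>& x_final) const {
    int ne = times.size();
    IntegerMatrix st(ne, n_sp);
    for (int i = 0; i < ne; ++i)
      for (int s = 0; s < n_sp; ++s) st(i, s) = states[(size_t)i * n_sp + s];
    NumericMatrix os(n_out, n_sp);
    for (int i = 0; i < n_out; ++i)
      for (int s = 0; s < n_sp; ++s) os(i, s) = out_states[(size_t)i * n_sp + s];
    return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                        _["labels"] = IntegerVector(labels.begin(), labels.end()),
                        _["states"] = st,
                        _["out_states"] = os,
                        _["x_final"] = IntegerVector(x_final.begin(), x_final.end()));
  }
};

} // namespace

// [[Rcpp::export(name = ".extrande_cpp")]]
List extrande_cpp(IntegerMatrix stoich, IntegerMatrix orders, NumericVector rates,
                  LogicalVector input_scaled, IntegerVector x0,
                  NumericVector grid_t, NumericVector grid_v, bool linear,
                  double T, double L, int l_policy, int bound_strategy,
                  double safety, NumericVector out_times,
                  bool record_events, bool record_pseudo) {
  RNGScope scope;
  MassActionNet net(stoich, orders, rates, input_scaled);
  InputGrid grid(grid_t, grid_v, linear);
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> a(net.M);
  Recorder rec(record_events, record_pseudo, net.n_sp, out_times);

  double t = 0.0;
  double L_cur = (l_policy == 0 || l_policy == 2) ? L : T;
  double Ig = (bound_strategy == 1) ? grid.global_max() : 0.0;
  long n_acc = 0, n_thin = 0, n_rej = 0, n_prop = 0, n_exp = 0;
  int accept_streak = 0;
  const double L_floor = L / 1024.0;

  while (t < T) {
    double Leff;
    if (l_policy == 1) Leff = T - t;
    else Leff = std::min(L_cur, T - t);   // terminal clipping: L <= T - t

    double Istar = (bound_strategy == 1) ? Ig : grid.window_max(t, t + Leff);
    double B = safety * net.total(x, Istar, a);
    n_prop += net.M;

    if (B <= 0.0) {
      // nothing can fire anywhere in the window: putative time is infinite
      n_rej++; n_exp++;
      rec.flush_until(t + Leff, x);
      t += Leff;
      rec.event(t, -1, x);
      continue;
    }

    double tau = exp_rand() / B;
    n_exp++;

    if (tau > Leff) {                      // 'Reject': advance by L
      n_rej++;
      rec.flush_until(t + Leff, x);
      t += Leff;
      rec.event(t, -1, x);
      if (l_policy == 2) {
        L_cur = std::max(L_cur / 2.0, L_floor);
        accept_streak = 0;
      }
      continue;
    }

    rec.flush_until(t + tau, x);
    t += tau;
    double I = grid.value_at(t);
    double a0 = net.total(x, I, a);
    n_prop += net.M;
    if (a0 > B * (1.0 + 1e-12) + 1e-12)
      stop("Extrande bound violated at t=%g: a0=%g > B=%g", t, a0, B);

    double u = unif_rand();
    if (a0 >= B * u) {                     // 'Accept': same u selects the channel
      double target = B * u, csum = 0.0;
      int j = net.M - 1;
      for (int k = 0; k < net.M; ++k) {
        csum += a[k];
        if (csum >= target) { j = k; break; }
      }
      net.apply(j, x);
      for (int s = 0; s < net.n_sp; ++s)
        if (x[s] < 0) stop("negative copy number after channel %d", j + 1);
      n_acc++;
      rec.event(t, j + 1, x);
    } else {                               // 'Thin': extra channel fires
      n_thin++;
      rec.event(t, 0, x);
    }
    if (l_policy == 2 && ++accept_streak >= 10) {
      L_cur = std::min(L_cur * 2.0, T);
      accept_streak = 0;
    }
  }
  rec.flush_final(x);

  List out = rec.result(x);
  out["stats"] = NumericVector::create(
      _["n_accepted"] = (double)n_acc, _["n_thinned"] = (double)n_thin,
      _["n_rejected"] = (double)n_rej,
      _["n_propensity_evaluations"] = (double)n_prop,
      _["n_exponentials_drawn"] = (double)n_exp);
  return out;
}

// [[Rcpp::export(name = ".sia_cpp")]]
List sia_cpp(IntegerMatrix stoich, IntegerMatrix orders, NumericVector rates,
             LogicalVector input_scaled, IntegerVector x0,
             NumericVector grid_t, NumericVector grid_v, bool linear,
             double T, NumericVector out_times, bool record_events) {
  RNGScope scope;
  MassActionNet net(stoich, orders, rates, input_scaled);
  InputGrid grid(grid_t, grid_v, linear);
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> a(net.M);
  Recorder rec(record_events, false, net.n_sp, out_times);

  double t = 0.0;
  double I_stale = grid.value_at(0.0);     // input only updates at firings
  long n_acc = 0, n_prop = 0;
  bool trapped = false;

  while (t < T) {
    double a0 = net.total(x, I_stale, a);
    n_prop += net.M;
    if (a0 <= 0.0) { trapped = true; break; }
    double tau = exp_rand() / a0;
    if (t + tau > T) { t = T; break; }
    rec.flush_until(t + tau, x);
    t += tau;
    double r = unif_rand() * a0;           // stale propensities pick the channel
    double csum = 0.0;
    int j = net.M - 1;
    for (int k = 0; k < net.M; ++k) {
      csum += a[k];
      if (csum >= r) { j = k; break; }
    }
    net.apply(j, x);
    n_acc++;
    rec.event(t, j + 1, x);
    I_stale = grid.value_at(t);
  }
  rec.flush_final(x);

  List out = rec.result(x);
  out["stats"] = NumericVector::create(
      _["n_accepted"] = (double)n_acc,
      _["n_propensity_evaluations"] = (double)n_prop);
  out["trapped"] = trapped;
  return out;
}

// [[Rcpp::export(name = ".mn_integral_cpp")]]
List mn_integral_cpp(IntegerMatrix stoich, IntegerMatrix orders, NumericVector rates,
                     LogicalVector input_scaled, IntegerVector x0,
                     NumericVector grid_t, NumericVector grid_v, bool linear,
                     double T, double dt_int, bool direct,
                     NumericVector out_times, bool record_events) {
  RNGScope scope;
  MassActionNet net(stoich, orders, rates, input_scaled);
  InputGrid grid(grid_t, grid_v, linear);
  std::vector<int> x(x0.begin(), x0.end());
  Recorder rec(record_events, false, net.n_sp, out_times);
  const int M = net.M;

  // modified-next: one unit-exponential target per channel;
  // direct: a single target on the total propensity a0
  int nacc_ch = direct ? 1 : M;
  std::vector<double> P(nacc_ch), Tj(nacc_ch, 0.0);
  for (int j = 0; j < nacc_ch; ++j) P[j] = exp_rand();

  std::vector<double> a_prev(M), a_next(M), ach(M);
  double t = 0.0;
  long n_fired = 0, n_prop = 0;
  net.total(x, grid.value_at(0.0), a_prev);
  n_prop += M;

  auto accum = [&](int j) {
    return direct ? std::accumulate(a_prev.begin(), a_prev.end(), 0.0) : a_prev[j];
  };

  while (t < T) {
    double h = std::min(dt_int, T - t);
    double t1 = t + h;
    net.total(x, grid.value_at(t1), a_next);
    n_prop += M;

    // earliest within-step crossing among channels, propensity linear in step
    int j_fire = -1;
    double d_fire = h;
    for (int j = 0; j < nacc_ch; ++j) {
      double p0, p1;
      if (direct) {
        p0 = std::accumulate(a_prev.begin(), a_prev.end(), 0.0);
        p1 = std::accumulate(a_next.begin(), a_next.end(), 0.0);
      } else { p0 = a_prev[j]; p1 = a_next[j]; }
      double R = P[j] - Tj[j];
      double inc = 0.5 * (p0 + p1) * h;
      if (inc < R) continue;
      double d;
      double slope = (p1 - p0) / h;
      if (std::fabs(slope) < 1e-14 * (std::fabs(p0) + 1.0)) {
        d = (p0 > 0.0) ? R / p0 : h;
      } else {
        double disc = p0 * p0 + 2.0 * slope * R;
        if (disc < 0.0) disc = 0.0;
        d = (-p0 + std::sqrt(disc)) / slope;
      }
      if (d < 0.0) d = 0.0;
      if (d > h) d = h;
      if (d < d_fire || (d == d_fire && j_fire < 0)) { d_fire = d; j_fire = j; }
    }

    if (j_fire < 0) {                       // no firing: accumulate full step
      for (int j = 0; j < nacc_ch; ++j) {
        double p0, p1;
        if (direct) {
          p0 = std::accumulate(a_prev.begin(), a_prev.end(), 0.0);
          p1 = std::accumulate(a_next.begin(), a_next.end(), 0.0);
        } else { p0 = a_prev[j]; p1 = a_next[j]; }
        Tj[j] += 0.5 * (p0 + p1) * h;
      }
      rec.flush_until(t1, x);
      t = t1;
      a_prev.swap(a_next);
      continue;
    }

    // fire at t + d_fire; accumulate partial-step integrals for all channels
    double tf = t + d_fire;
    for (int j = 0; j < nacc_ch; ++j) {
      double p0, p1;
      if (direct) {
        p0 = std::accumulate(a_prev.begin(), a_prev.end(), 0.0);
        p1 = std::accumulate(a_next.begin(), a_next.end(), 0.0);
      } else { p0 = a_prev[j]; p1 = a_next[j]; }
      double slope = (p1 - p0) / h;
      Tj[j] += p0 * d_fire + 0.5 * slope * d_fire * d_fire;
    }

    int ch;
    if (direct) {
      // channel chosen proportional to propensities at the firing time
      double a0f = net.total(x, grid.value_at(tf), ach);
      n_prop += M;
      double r = unif_rand() * a0f, csum = 0.0;
      ch = M - 1;
      for (int k = 0; k < M; ++k) { csum += ach[k]; if (csum >= r) { ch = k; break; } }
      Tj[0] = P[0];
      P[0] += exp_rand();
    } else {
      ch = j_fire;
      Tj[ch] = P[ch];
      P[ch] += exp_rand();
    }

    rec.flush_until(tf, x);
    net.apply(ch, x);
    n_fired++;
    t = tf;
    rec.event(t, ch + 1, x);
    net.total(x, grid.value_at(t), a_prev);  // state changed: refresh propensities
    n_prop += M;
  }
  rec.flush_final(x);

  List out = rec.result(x);
  out["stats"] = NumericVector::create(
      _["n_accepted"] = (double)n_fired,
      _["n_propensity_evaluations"] = (double)n_prop);
  return out;
}
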