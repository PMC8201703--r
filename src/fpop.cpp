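// Functional dynamic programming for exact penalized changepoint detection
// on run-length encoded count profiles, in the style of functional-pruning
// optimal partitioning solvers for graph-constrained models.
//
// The optimal cost of the data up to run t, as a function of the current
// segment parameter theta, is piecewise in one of three two-function bases:
//   gaussian: a*theta^2 + b*theta + c  (loss is the squared residual)
//   poisson:  a*theta   + b*log(theta) + c
//   nbinom:   a*log(theta) + b*log(theta + phi) + c
// Every piece is unimodal on the parameter domain, which is all the
// envelope (min-less-equal / min-greater-equal) and pointwise-min
// operators below rely on.
//
// Models:
//   unconstrained: one state, transition cost = global min + lambda.
//   updown: two states (Down = background, Up = peak). Down->Up requires
//     theta_up >= theta_down (min-less-equal envelope), Up->Down the
//     mirror. The chain starts and ends in Down, so every peak is closed.
//
// Ties are resolved in favour of the no-change branch, so among equal-cost
// optima the solver returns one with the fewest changepoints.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum Family { GAUSSIAN = 0, POISSON = 1, NBINOM = 2 };

struct Piece {
  double lo, hi;       // theta interval
  double a, b, c;      // basis coefficients
  int tag_time;        // runs consumed before the current segment started
  int tag_state;       // state before that change (-1 at profile start)
};

typedef std::vector<Piece> Fun;

struct Ctx {
  int family;
  double phi;
  double dom_lo, dom_hi;

  double eval(const Piece &p, double t) const {
    switch (family) {
    case GAUSSIAN: return p.a * t * t + p.b * t + p.c;
    case POISSON:  return p.a * t + p.b * std::log(t) + p.c;
    default:       return p.a * std::log(t) + p.b * std::log(t + phi) + p.c;
    }
  }

  double deriv(const Piece &p, double t) const {
    switch (family) {
    case GAUSSIAN: return 2.0 * p.a * t + p.b;
    case POISSON:  return p.a + p.b / t;
    default:       return p.a / t + p.b / (t + phi);
    }
  }

  // stationary point of a*f + b*g on (0, inf); NaN when none / degenerate
  double stationary(double a, double b) const {
    switch (family) {
    case GAUSSIAN:
      if (a != 0.0) return -b / (2.0 * a);
      return NAN;
    case POISSON:
      if (a != 0.0 && -b / a > 0.0) return -b / a;
      return NAN;
    default:
      if (a + b != 0.0) {
        double t = -a * phi / (a + b);
        if (t > 0.0) return t;
      }
      return NAN;
    }
  }

  // argmin of piece p over [p.lo, p.hi] (p unimodal there)
  double argmin(const Piece &p) const {
    double ts = stationary(p.a, p.b);
    if (std::isnan(ts)) {
      // monotone or constant: pick the downhill end
      double dmid = deriv(p, 0.5 * (p.lo + p.hi));
      return (dmid > 0.0) ? p.lo : p.hi;
    }
    if (ts < p.lo) {
      // if increasing at lo take lo, else decreasing everywhere -> hi
      return (deriv(p, p.lo) >= 0.0) ? p.lo : p.hi;
    }
    if (ts > p.hi) return (deriv(p, p.hi) <= 0.0) ? p.hi : p.lo;
    // stationary inside: could be a max for sign-flipped coefficients
    double vts = eval(p, ts), vlo = eval(p, p.lo), vhi = eval(p, p.hi);
    if (vts <= vlo && vts <= vhi) return ts;
    return (vlo <= vhi) ? p.lo : p.hi;
  }

  // roots of a*f + b*g + c on (x0, x1), strictly inside; at most 2
  void roots(double a, double b, double c, double x0, double x1,
             std::vector<double> &out) const {
    double ts = stationary(a, b);
    std::vector<double> knots;
    knots.push_back(x0);
    if (!std::isnan(ts) && ts > x0 && ts < x1) knots.push_back(ts);
    knots.push_back(x1);
    Piece p; p.a = a; p.b = b; p.c = c; p.lo = x0; p.hi = x1;
    for (size_t i = 0; i + 1 < knots.size(); ++i) {
      double l = knots[i], u = knots[i + 1];
      double fl = eval(p, l), fu = eval(p, u);
      if (fl == 0.0 && l > x0) { out.push_back(l); continue; }
      if ((fl > 0.0) == (fu > 0.0)) continue;
      // bisection on a monotone stretch
      for (int it = 0; it < 200; ++it) {
        double m = 0.5 * (l + u);
        double fm = eval(p, m);
        if (fm == 0.0) { l = u = m; break; }
        if ((fm > 0.0) == (fl > 0.0)) { l = m; fl = fm; } else { u = m; fu = fm; }
        if (u - l <= 1e-13 * (1.0 + std::fabs(m))) break;
      }
      double r = 0.5 * (l + u);
      if (r > x0 && r < x1) out.push_back(r);
    }
  }
};

static void add_loss(const Ctx &cx, Fun &f, double w, double y) {
  double da = 0, db = 0, dc = 0;
  switch (cx.family) {
  case GAUSSIAN: da = w; db = -2.0 * w * y; dc = w * y * y; break;
  case POISSON:  da = w; db = -w * y; break;
  default:       da = -w * y; db = w * (y + cx.phi); break;
  }
  for (size_t i = 0; i < f.size(); ++i) {
    f[i].a += da; f[i].b += db; f[i].c += dc;
  }
}

static void add_const(Fun &f, double v) {
  for (size_t i = 0; i < f.size(); ++i) f[i].c += v;
}

static void set_tags(Fun &f, int time, int state) {
  for (size_t i = 0; i < f.size(); ++i) {
    f[i].tag_time = time; f[i].tag_state = state;
  }
}

// global minimum; fills argmin and the piece index
static double fun_min(const Ctx &cx, const Fun &f, double *arg, int *idx) {
  double best = INF, bt = cx.dom_lo; int bi = -1;
  for (size_t i = 0; i < f.size(); ++i) {
    double t = cx.argmin(f[i]);
    double v = cx.eval(f[i], t);
    if (v < best) { best = v; bt = t; bi = (int)i; }
  }
  if (arg) *arg = bt;
  if (idx) *idx = bi;
  return best;
}

// minimum restricted to [rlo, rhi]
static double fun_min_restricted(const Ctx &cx, const Fun &f, double rlo,
                                 double rhi, double *arg, int *idx) {
  double best = INF, bt = rlo; int bi = -1;
  for (size_t i = 0; i < f.size(); ++i) {
    double l = std::max(f[i].lo, rlo), u = std::min(f[i].hi, rhi);
    if (l > u) continue;
    Piece q = f[i]; q.lo = l; q.hi = u;
    double t = cx.argmin(q);
    double v = cx.eval(q, t);
    if (v < best) { best = v; bt = t; bi = (int)i; }
  }
  if (arg) *arg = bt;
  if (idx) *idx = bi;
  return best;
}

static void push_piece(Fun &out, const Piece &p) {
  if (p.hi - p.lo <= 1e-12 * (1.0 + std::fabs(p.lo))) return;
  if (!out.empty()) {
    Piece &q = out.back();
    bool same = std::fabs(q.a - p.a) <= 1e-10 * (1.0 + std::fabs(p.a)) &&
                std::fabs(q.b - p.b) <= 1e-10 * (1.0 + std::fabs(p.b)) &&
                std::fabs(q.c - p.c) <= 1e-10 * (1.0 + std::fabs(p.c)) &&
                q.tag_time == p.tag_time && q.tag_state == p.tag_state;
    if (same) { q.hi = p.hi; return; }
    q.hi = p.lo;  // keep contiguity against rounding drift
  }
  out.push_back(p);
}

// G(t) = min_{t' <= t} F(t'), the envelope used by Down->Up transitions
static Fun env_leq(const Ctx &cx, const Fun &f) {
  Fun out;
  double best = INF;
  Piece cst; cst.a = cst.b = 0.0; cst.tag_time = 0; cst.tag_state = -1;
  for (size_t i = 0; i < f.size(); ++i) {
    Piece p = f[i];
    double ts = cx.argmin(p);
    // decreasing stretch [lo, ts], then prefix-min is constant p(ts)
    if (ts > p.lo) {
      double vlo = cx.eval(p, p.lo);
      if (best <= vlo) {
        // constant dominates until p dips below it
        std::vector<double> rs;
        cx.roots(p.a, p.b, p.c - best, p.lo, ts, rs);
        if (!rs.empty()) {
          cst.c = best; cst.lo = p.lo; cst.hi = rs[0];
          push_piece(out, cst);
          Piece q = p; q.lo = rs[0]; q.hi = ts;
          push_piece(out, q);
        } else if (cx.eval(p, ts) >= best) {
          // p never dips below best on this stretch
          cst.c = best; cst.lo = p.lo; cst.hi = ts;
          push_piece(out, cst);
        } else {
          // p(lo) == best and p decreasing: p below best throughout
          Piece q = p; q.hi = ts;
          push_piece(out, q);
        }
      } else {
        Piece q = p; q.hi = ts;
        push_piece(out, q);
      }
    }
    double vts = cx.eval(p, ts);
    if (vts < best) best = vts;
    if (p.hi > ts) {
      cst.c = best; cst.lo = ts; cst.hi = p.hi;
      push_piece(out, cst);
    }
  }
  if (out.empty()) {  // single degenerate piece; keep a constant
    cst.c = best; cst.lo = cx.dom_lo; cst.hi = cx.dom_hi;
    out.push_back(cst);
  }
  out.front().lo = cx.dom_lo;
  out.back().hi = cx.dom_hi;
  return out;
}

// G(t) = min_{t' >= t} F(t'), used by Up->Down transitions
static Fun env_geq(const Ctx &cx, const Fun &f) {
  std::vector<Piece> rev;
  double best = INF;
  Piece cst; cst.a = cst.b = 0.0; cst.tag_time = 0; cst.tag_state = -1;
  for (int i = (int)f.size() - 1; i >= 0; --i) {
    Piece p = f[i];
    double ts = cx.argmin(p);
    if (p.hi > ts) {
      double vhi = cx.eval(p, p.hi);
      if (best <= vhi) {
        std::vector<double> rs;
        cx.roots(p.a, p.b, p.c - best, ts, p.hi, rs);
        if (!rs.empty()) {
          cst.c = best; cst.lo = rs.back(); cst.hi = p.hi;
          rev.push_back(cst);
          Piece q = p; q.lo = ts; q.hi = rs.back();
          rev.push_back(q);
        } else if (cx.eval(p, ts) >= best) {
          cst.c = best; cst.lo = ts; cst.hi = p.hi;
          rev.push_back(cst);
        } else {
          Piece q = p; q.lo = ts;
          rev.push_back(q);
        }
      } else {
        Piece q = p; q.lo = ts;
        rev.push_back(q);
      }
    }
    double vts = cx.eval(p, ts);
    if (vts < best) best = vts;
    if (ts > p.lo) {
      cst.c = best; cst.lo = p.lo; cst.hi = ts;
      rev.push_back(cst);
    }
  }
  Fun out;
  for (int i = (int)rev.size() - 1; i >= 0; --i) push_piece(out, rev[i]);
  if (out.empty()) {
    cst.c = best; cst.lo = cx.dom_lo; cst.hi = cx.dom_hi;
    out.push_back(cst);
  }
  out.front().lo = cx.dom_lo;
  out.back().hi = cx.dom_hi;
  return out;
}

static const Piece *piece_at(const Fun &f, double t) {
  for (size_t i = 0; i < f.size(); ++i) {
    if (t <= f[i].hi || i + 1 == f.size()) return &f[i];
  }
  return &f.back();
}

// pointwise minimum; ties go to `stay` (the first argument)
static Fun pmin_fun(const Ctx &cx, const Fun &stay, const Fun &trans) {
  std::vector<double> xs;
  for (size_t i = 0; i < stay.size(); ++i) {
    xs.push_back(stay[i].lo); xs.push_back(stay[i].hi);
  }
  for (size_t i = 0; i < trans.size(); ++i) {
    xs.push_back(trans[i].lo); xs.push_back(trans[i].hi);
  }
  std::sort(xs.begin(), xs.end());
  std::vector<double> bx;
  for (size_t i = 0; i < xs.size(); ++i) {
    if (bx.empty() || xs[i] - bx.back() > 1e-12 * (1.0 + std::fabs(xs[i])))
      bx.push_back(xs[i]);
  }
  Fun out;
  for (size_t i = 0; i + 1 < bx.size(); ++i) {
    double x0 = bx[i], x1 = bx[i + 1];
    double mid = 0.5 * (x0 + x1);
    const Piece *ps = piece_at(stay, mid);
    const Piece *pt = piece_at(trans, mid);
    std::vector<double> cuts;
    cuts.push_back(x0);
    std::vector<double> rs;
    cx.roots(ps->a - pt->a, ps->b - pt->b, ps->c - pt->c, x0, x1, rs);
    for (size_t k = 0; k < rs.size(); ++k) cuts.push_back(rs[k]);
    cuts.push_back(x1);
    for (size_t k = 0; k + 1 < cuts.size(); ++k) {
      double m = 0.5 * (cuts[k] + cuts[k + 1]);
      Piece q = (cx.eval(*pt, m) < cx.eval(*ps, m)) ? *pt : *ps;
      q.lo = cuts[k]; q.hi = cuts[k + 1];
      push_piece(out, q);
    }
  }
  if (out.empty()) out = stay;
  out.front().lo = cx.dom_lo;
  out.back().hi = cx.dom_hi;
  return out;
}

// [[Rcpp::export]]
List fpop_solve(NumericVector values, NumericVector weights, int family,
                double phi, double penalty, bool updown, double dom_lo,
                double dom_hi) {
  int R = values.size();
  if (R < 1) stop("empty profile");
  if (penalty < 0) stop("penalty must be >= 0");
  Ctx cx; cx.family = family; cx.phi = phi;
  cx.dom_lo = dom_lo; cx.dom_hi = dom_hi;

  std::vector<Fun> down(R), up;
  if (updown) up.resize(R);

  Piece p0; p0.lo = dom_lo; p0.hi = dom_hi; p0.a = p0.b = p0.c = 0.0;
  p0.tag_time = 0; p0.tag_state = -1;
  down[0].push_back(p0);
  add_loss(cx, down[0], weights[0], values[0]);

  for (int t = 1; t < R; ++t) {
    if (updown) {
      // Down -> Up (up change; new theta must be >= previous)
      Fun upTrans = env_leq(cx, down[t - 1]);
      add_const(upTrans, penalty);
      set_tags(upTrans, t, 0);
      if (up[t - 1].empty()) up[t] = upTrans;
      else up[t] = pmin_fun(cx, up[t - 1], upTrans);
      // Up -> Down (down change)
      if (!up[t - 1].empty()) {
        Fun dnTrans = env_geq(cx, up[t - 1]);
        add_const(dnTrans, penalty);
        set_tags(dnTrans, t, 1);
        down[t] = pmin_fun(cx, down[t - 1], dnTrans);
      } else {
        down[t] = down[t - 1];
      }
      add_loss(cx, up[t], weights[t], values[t]);
    } else {
      double m = fun_min(cx, down[t - 1], NULL, NULL);
      Piece tr; tr.lo = dom_lo; tr.hi = dom_hi;
      tr.a = tr.b = 0.0; tr.c = m + penalty;
      tr.tag_time = t; tr.tag_state = 0;
      Fun trans; trans.push_back(tr);
      down[t] = pmin_fun(cx, down[t - 1], trans);
    }
    add_loss(cx, down[t], weights[t], values[t]);
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // backtrack from the final Down state
  std::vector<int> seg_start;   // run index where each segment starts
  std::vector<double> seg_theta;
  std::vector<int> seg_state;
  int state = 0, t_end = R;
  double rlo = dom_lo, rhi = dom_hi;
  double total = NA_REAL;
  bool first = true;
  while (true) {
    const Fun &f = (state == 0) ? down[t_end - 1] : up[t_end - 1];
    double arg; int idx;
    double v = fun_min_restricted(cx, f, rlo, rhi, &arg, &idx);
    if (idx < 0) stop("internal error: empty cost function in backtrack");
    if (first) { total = v; first = false; }
    const Piece &pc = f[idx];
    seg_start.push_back(pc.tag_time);
    seg_theta.push_back(arg);
    seg_state.push_back(state);
    if (pc.tag_time == 0) break;
    int bt = pc.tag_time, bstate = pc.tag_state;
    if (updown) {
      if (state == 1) { rlo = dom_lo; rhi = arg; }   // previous Down <= current Up
      else           { rlo = arg;    rhi = dom_hi; } // previous Up >= current Down
    } else {
      rlo = dom_lo; rhi = dom_hi;
    }
    state = bstate;
    t_end = bt;
  }
  std::reverse(seg_start.begin(), seg_start.end());
  std::reverse(seg_theta.begin(), seg_theta.end());
  std::reverse(seg_state.begin(), seg_state.end());

  return List::create(
    _["seg_start_run"] = wrap(seg_start),
    _["theta"] = wrap(seg_theta),
    _["state"] = wrap(seg_state),
    _["penalized_cost"] = total);
}
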