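// Event-driven discrete molecular dynamics core.
//
// Particles move ballistically between instantaneous events located at the
// discontinuities of piecewise-constant pair potentials, at the boundaries of
// bonded distance-range constraints (reflecting walls), and at the well edges
// of gated backbone hydrogen bonds.  Velocities change only at events, by
// closed-form momentum- and energy-conserving impulses, so total energy is
// conserved to floating-point accumulation between thermostat events.
//
// Bookkeeping follows standard event-driven practice: a binary heap with lazy
// invalidation through per-particle collision counters; per-particle local
// clocks (a particle's position is advanced only when it takes part in an
// event), which makes trajectories bitwise independent of the snapshot
// interval; and a periodic global re-prediction ("resync") event that also
// refreshes minimum-image assumptions in periodic boxes.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <random>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// event types
enum EvType { EV_PAIR = 0, EV_BOND = 1, EV_HB = 2, EV_GHOST = 3, EV_RESYNC = 4 };

struct Ev {
  double t;
  int idx;        // pair / bond / hb row index (-1 for ghost & resync)
  int a, b;       // particles involved (-1 when not applicable)
  int type;
  int aux;        // +(k+1): outward crossing of radius k; -(k+1): inward
  unsigned ca, cb;
};

struct EvCmp {
  // min-heap on (t, a, b, type): deterministic serialization of ties
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.t != y.t) return x.t > y.t;
    if (x.a != y.a) return x.a > y.a;
    if (x.b != y.b) return x.b > y.b;
    return x.type > y.type;
  }
};

struct Engine {
  int N;
  double boxL;            // 0 => open boundaries
  std::vector<double> px, py, pz, vx, vy, vz, pt, mass;
  double tnow;

  // potentials
  std::vector<std::vector<double>> radii;     // per potential, increasing
  std::vector<std::vector<double>> energ;     // per potential, length nradii+1
  // nonbonded pairs
  std::vector<int> pi_, pj_, ppot_;
  std::vector<int> pshell_;
  // bonds
  std::vector<int> bi_, bj_;
  std::vector<double> blo_, bhi_;
  // hydrogen bonds
  std::vector<int> hh_, ho_, hn_;
  std::vector<double> hrmin_, hrmax_, hdepth_, hgmin_, hgmax_;
  std::vector<int> hin_;        // 1 = H..O inside well range
  std::vector<int> hbonded_;    // 1 = carrying well energy
  std::vector<int> hb_busy_;    // per particle: engaged in a formed bond

  // adjacency: per particle, rows of each table it participates in
  std::vector<std::vector<int>> adj_pair, adj_bond, adj_hb;

  std::vector<unsigned> cnt;
  std::vector<Ev> heap;
  EvCmp cmp;

  double Epot;                  // tracked potential energy
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  std::uniform_real_distribution<double> unif;

  long n_exec[5] = {0, 0, 0, 0, 0};
  long n_stale = 0;
  size_t compact_cap;

  double mic(double d) const {
    if (boxL > 0) d -= boxL * std::round(d / boxL);
    return d;
  }

  // relative separation b-a and relative velocity at absolute time t
  void rel(int a, int b, double t, double r[3], double v[3]) const {
    r[0] = mic((px[b] + vx[b] * (t - pt[b])) - (px[a] + vx[a] * (t - pt[a])));
    r[1] = mic((py[b] + vy[b] * (t - pt[b])) - (py[a] + vy[a] * (t - pt[a])));
    r[2] = mic((pz[b] + vz[b] * (t - pt[b])) - (pz[a] + vz[a] * (t - pt[a])));
    v[0] = vx[b] - vx[a]; v[1] = vy[b] - vy[a]; v[2] = vz[b] - vz[a];
  }

  double dist(int a, int b, double t) const {
    double r[3], v[3];
    rel(a, b, t, r, v);
    return std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
  }

  void advance(int a, double t) {
    double dt = t - pt[a];
    px[a] += vx[a] * dt; py[a] += vy[a] * dt; pz[a] += vz[a] * dt;
    pt[a] = t;
  }

  void push_ev(const Ev& e) {
    heap.push_back(e);
    std::push_heap(heap.begin(), heap.end(), cmp);
    if (heap.size() > compact_cap) compact();
  }

  bool valid(const Ev& e) const {
    if (e.type == EV_GHOST || e.type == EV_RESYNC) return true;
    if (e.a >= 0 && cnt[e.a] != e.ca) return false;
    if (e.b >= 0 && cnt[e.b] != e.cb) return false;
    return true;
  }

  void compact() {
    std::vector<Ev> keep;
    keep.reserve(heap.size() / 4 + 64);
    for (const Ev& e : heap) if (valid(e)) keep.push_back(e);
    heap.swap(keep);
    std::make_heap(heap.begin(), heap.end(), cmp);
  }

  // earliest positive root of |r + v tau| = R, sign-aware.
  // outward: crossing from inside (r < R); inward: from outside (r > R).
  static double t_outward(double a, double b, double c) {
    // a tau^2 + 2 b tau + c = 0, c <= 0 expected (inside)
    if (a <= 0) return INF;
    double disc = b * b - a * c;
    if (disc < 0) return INF;
    double tau = (-b + std::sqrt(disc)) / a;
    return tau >= 0 ? tau : INF;
  }
  static double t_inward(double a, double b, double c) {
    if (a <= 0 || b >= 0) return INF;   // must be approaching
    double disc = b * b - a * c;
    if (disc < 0) return INF;
    double tau = (-b - std::sqrt(disc)) / a;
    return tau >= 0 ? tau : INF;
  }

  // predict and schedule next event for nonbonded pair row p
  void predict_pair(int p, double t) {
    int a = pi_[p], b = pj_[p];
    double r[3], v[3];
    rel(a, b, t, r, v);
    double vv = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
    if (vv == 0) return;
    double rv = r[0]*v[0] + r[1]*v[1] + r[2]*v[2];
    double rr = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    const std::vector<double>& R = radii[ppot_[p]];
    int s = pshell_[p];
    int n = (int)R.size();
    double best = INF; int aux = 0;
    if (s < n) {
      double tau = t_outward(vv, rv, rr - R[s] * R[s]);
      if (tau < best) { best = tau; aux = +(s + 1); }
    }
    if (s > 0) {
      double tau = t_inward(vv, rv, rr - R[s-1] * R[s-1]);
      if (tau < best) { best = tau; aux = -s; }
    }
    if (best < INF) {
      Ev e{t + best, p, a, b, EV_PAIR, aux, cnt[a], cnt[b]};
      push_ev(e);
    }
  }

  void predict_bond(int q, double t) {
    int a = bi_[q], b = bj_[q];
    double r[3], v[3];
    rel(a, b, t, r, v);
    double vv = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
    if (vv == 0) return;
    double rv = r[0]*v[0] + r[1]*v[1] + r[2]*v[2];
    double rr = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    double chi = rr - bhi_[q] * bhi_[q];
    double best = INF; int aux = 0;
    if (chi >= 0) {
      // already at/past the outer wall (floating point): bounce now if receding
      if (rv > 0) { best = 0; aux = +1; }
      else { double tau = t_outward(vv, rv, chi); if (tau < best) { best = tau; aux = +1; } }
    } else {
      double tau = t_outward(vv, rv, chi);
      if (tau < best) { best = tau; aux = +1; }
    }
    if (blo_[q] > 0) {
      double clo = rr - blo_[q] * blo_[q];
      if (clo <= 0) {
        if (rv < 0) { best = 0; aux = -1; }
      } else {
        double tau = t_inward(vv, rv, clo);
        if (tau < best) { best = tau; aux = -1; }
      }
    }
    if (best < INF) {
      Ev e{t + best, q, a, b, EV_BOND, aux, cnt[a], cnt[b]};
      push_ev(e);
    }
  }

  void predict_hb(int h, double t) {
    int a = hh_[h], b = ho_[h];
    double r[3], v[3];
    rel(a, b, t, r, v);
    double vv = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
    if (vv == 0) return;
    double rv = r[0]*v[0] + r[1]*v[1] + r[2]*v[2];
    double rr = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    double best = INF; int aux = 0;
    if (hin_[h]) {
      double tau = t_outward(vv, rv, rr - hrmax_[h] * hrmax_[h]);
      if (tau < best) { best = tau; aux = +2; }
      double ti = t_inward(vv, rv, rr - hrmin_[h] * hrmin_[h]);
      if (ti < best) { best = ti; aux = -1; }
    } else {
      double tau = t_inward(vv, rv, rr - hrmax_[h] * hrmax_[h]);
      if (tau < best) { best = tau; aux = -2; }
    }
    if (best < INF) {
      Ev e{t + best, h, a, b, EV_HB, aux, cnt[a], cnt[b]};
      push_ev(e);
    }
  }

  void repredict_particle(int a, double t) {
    for (int p : adj_pair[a]) predict_pair(p, t);
    for (int q : adj_bond[a]) predict_bond(q, t);
    for (int h : adj_hb[a]) predict_hb(h, t);
  }

  // impulse along the unit separation vector; dU = energy of target shell
  // minus current shell (+INF => hard wall).  Returns true if the step was
  // crossed (refraction), false on reflection.
  bool impulse(int a, int b, const double r[3], double dU) {
    double rr = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
    double n0 = r[0] / rr, n1 = r[1] / rr, n2 = r[2] / rr;
    double mu = mass[a] * mass[b] / (mass[a] + mass[b]);
    double vr = (vx[b]-vx[a])*n0 + (vy[b]-vy[a])*n1 + (vz[b]-vz[a])*n2;
    bool cross;
    double vrp;
    if (!std::isfinite(dU)) {
      cross = false; vrp = -vr;
    } else if (dU <= 0 || 0.5 * mu * vr * vr > dU) {
      cross = true;
      double s = vr >= 0 ? 1.0 : -1.0;
      vrp = s * std::sqrt(vr * vr - 2.0 * dU / mu);
    } else {
      cross = false; vrp = -vr;
    }
    double dvr = vrp - vr;
    double fa = mu * dvr / mass[a], fb = mu * dvr / mass[b];
    vx[a] -= fa * n0; vy[a] -= fa * n1; vz[a] -= fa * n2;
    vx[b] += fb * n0; vy[b] += fb * n1; vz[b] += fb * n2;
    return cross;
  }

  double kinetic() const {
    double k = 0;
    for (int i = 0; i < N; ++i)
      k += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    return k;
  }

  // recompute potential energy from scratch at common time t
  double recompute_epot(double t) const {
    double e = 0;
    for (size_t p = 0; p < pi_.size(); ++p) {
      double d = dist(pi_[p], pj_[p], t);
      const std::vector<double>& R = radii[ppot_[p]];
      const std::vector<double>& E = energ[ppot_[p]];
      int s = (int)(std::upper_bound(R.begin(), R.end(), d) - R.begin());
      e += E[s];
    }
    for (size_t q = 0; q < bi_.size(); ++q) {
      double d = dist(bi_[q], bj_[q], t);
      if (d < blo_[q] - 1e-7 || d > bhi_[q] + 1e-7) e += INF;
    }
    for (size_t h = 0; h < hh_.size(); ++h)
      if (hbonded_[h]) e -= hdepth_[h];
    return e;
  }
};

}  // namespace

// Shared construction of an Engine from R-side arguments (1-based indices).
static void engine_init(Engine& eng,
                        NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                        double boxL, List pot_radii, List pot_energies,
                        IntegerVector pair_i, IntegerVector pair_j, IntegerVector pair_pot,
                        IntegerVector bond_i, IntegerVector bond_j,
                        NumericVector bond_lo, NumericVector bond_hi,
                        IntegerVector hb_h, IntegerVector hb_o, IntegerVector hb_n,
                        NumericVector hb_rmin, NumericVector hb_rmax,
                        NumericVector hb_depth, NumericVector hb_gmin,
                        NumericVector hb_gmax) {
  int N = x0.nrow();
  eng.N = N; eng.boxL = boxL; eng.tnow = 0;
  eng.px.resize(N); eng.py.resize(N); eng.pz.resize(N);
  eng.vx.resize(N); eng.vy.resize(N); eng.vz.resize(N);
  eng.pt.assign(N, 0.0); eng.mass.resize(N);
  for (int i = 0; i < N; ++i) {
    eng.px[i] = x0(i,0); eng.py[i] = x0(i,1); eng.pz[i] = x0(i,2);
    eng.vx[i] = v0(i,0); eng.vy[i] = v0(i,1); eng.vz[i] = v0(i,2);
    eng.mass[i] = mass[i];
    if (eng.mass[i] <= 0) stop("non-positive mass for particle %d", i + 1);
  }
  int npot = pot_radii.size();
  eng.radii.resize(npot); eng.energ.resize(npot);
  for (int k = 0; k < npot; ++k) {
    NumericVector R = pot_radii[k], E = pot_energies[k];
    if (E.size() != R.size() + 1)
      stop("potential %d: need length(energies) == length(radii) + 1", k + 1);
    for (int u = 1; u < R.size(); ++u)
      if (R[u] <= R[u-1]) stop("potential %d: radii not increasing", k + 1);
    eng.radii[k].assign(R.begin(), R.end());
    eng.energ[k].assign(E.begin(), E.end());
  }
  int np = pair_i.size();
  eng.pi_.resize(np); eng.pj_.resize(np); eng.ppot_.resize(np);
  eng.pshell_.assign(np, 0);
  for (int p = 0; p < np; ++p) {
    eng.pi_[p] = pair_i[p] - 1; eng.pj_[p] = pair_j[p] - 1;
    eng.ppot_[p] = pair_pot[p] - 1;
    if (eng.pi_[p] < 0 || eng.pj_[p] < 0 || eng.pi_[p] >= N || eng.pj_[p] >= N ||
        eng.pi_[p] == eng.pj_[p])
      stop("bad pair row %d", p + 1);
    if (eng.ppot_[p] < 0 || eng.ppot_[p] >= npot) stop("bad potential id in pair row %d", p + 1);
  }
  int nb = bond_i.size();
  eng.bi_.resize(nb); eng.bj_.resize(nb);
  eng.blo_.assign(bond_lo.begin(), bond_lo.end());
  eng.bhi_.assign(bond_hi.begin(), bond_hi.end());
  for (int q = 0; q < nb; ++q) {
    eng.bi_[q] = bond_i[q] - 1; eng.bj_[q] = bond_j[q] - 1;
    if (eng.blo_[q] < 0 || eng.blo_[q] >= eng.bhi_[q]) stop("bad bond range row %d", q + 1);
  }
  int nh = hb_h.size();
  eng.hh_.resize(nh); eng.ho_.resize(nh); eng.hn_.resize(nh);
  eng.hrmin_.assign(hb_rmin.begin(), hb_rmin.end());
  eng.hrmax_.assign(hb_rmax.begin(), hb_rmax.end());
  eng.hdepth_.assign(hb_depth.begin(), hb_depth.end());
  eng.hgmin_.assign(hb_gmin.begin(), hb_gmin.end());
  eng.hgmax_.assign(hb_gmax.begin(), hb_gmax.end());
  eng.hin_.assign(nh, 0); eng.hbonded_.assign(nh, 0);
  for (int h = 0; h < nh; ++h) {
    eng.hh_[h] = hb_h[h] - 1; eng.ho_[h] = hb_o[h] - 1; eng.hn_[h] = hb_n[h] - 1;
  }

  eng.adj_pair.assign(N, {}); eng.adj_bond.assign(N, {}); eng.adj_hb.assign(N, {});
  for (int p = 0; p < np; ++p) {
    eng.adj_pair[eng.pi_[p]].push_back(p);
    eng.adj_pair[eng.pj_[p]].push_back(p);
  }
  for (int q = 0; q < nb; ++q) {
    eng.adj_bond[eng.bi_[q]].push_back(q);
    eng.adj_bond[eng.bj_[q]].push_back(q);
  }
  for (int h = 0; h < nh; ++h) {
    eng.adj_hb[eng.hh_[h]].push_back(h);
    eng.adj_hb[eng.ho_[h]].push_back(h);
  }
  eng.cnt.assign(N, 0u);
  eng.compact_cap = std::max<size_t>((size_t)400000,
                                     8u * (size_t)(np + nb + nh) + 1024u);

  // initial shells, overlap check, tracked potential energy
  eng.Epot = 0;
  for (int p = 0; p < np; ++p) {
    double d = eng.dist(eng.pi_[p], eng.pj_[p], 0.0);
    const std::vector<double>& R = eng.radii[eng.ppot_[p]];
    const std::vector<double>& E = eng.energ[eng.ppot_[p]];
    int s = (int)(std::upper_bound(R.begin(), R.end(), d) - R.begin());
    if (!std::isfinite(E[s]))
      stop("particles %d and %d start inside a forbidden core (distance %.3f)",
           eng.pi_[p] + 1, eng.pj_[p] + 1, d);
    eng.pshell_[p] = s;
    eng.Epot += E[s];
  }
  for (int q = 0; q < nb; ++q) {
    double d = eng.dist(eng.bi_[q], eng.bj_[q], 0.0);
    if (d < eng.blo_[q] - 1e-7 || d > eng.bhi_[q] + 1e-7)
      stop("bond constraint %d violated at start: particles %d-%d at %.3f, range [%.3f, %.3f]",
           q + 1, eng.bi_[q] + 1, eng.bj_[q] + 1, d, eng.blo_[q], eng.bhi_[q]);
  }
  eng.hb_busy_.assign(N, 0);
  for (int h = 0; h < nh; ++h) {
    double d = eng.dist(eng.hh_[h], eng.ho_[h], 0.0);
    if (d < eng.hrmin_[h] - 1e-7)
      stop("hydrogen-bond pair %d starts below its core", h + 1);
    eng.hin_[h] = d < eng.hrmax_[h] ? 1 : 0;
    if (eng.hin_[h] && !eng.hb_busy_[eng.hh_[h]] && !eng.hb_busy_[eng.ho_[h]]) {
      double g = eng.dist(eng.hn_[h], eng.ho_[h], 0.0);
      if (g >= eng.hgmin_[h] && g <= eng.hgmax_[h]) {
        eng.hbonded_[h] = 1;
        eng.hb_busy_[eng.hh_[h]] = 1;
        eng.hb_busy_[eng.ho_[h]] = 1;
        eng.Epot -= eng.hdepth_[h];
      }
    }
  }
}

// [[Rcpp::export]]
List dmd_run_cpp(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                 double boxL, List pot_radii, List pot_energies,
                 IntegerVector pair_i, IntegerVector pair_j, IntegerVector pair_pot,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_lo, NumericVector bond_hi,
                 IntegerVector hb_h, IntegerVector hb_o, IntegerVector hb_n,
                 NumericVector hb_rmin, NumericVector hb_rmax,
                 NumericVector hb_depth, NumericVector hb_gmin, NumericVector hb_gmax,
                 double t_end, double snap_dt, double ghost_rate, double kT,
                 int seed, double resync_dt, double max_events,
                 bool log_events, int log_max) {
  Engine eng;
  engine_init(eng, x0, v0, mass, boxL, pot_radii, pot_energies,
              pair_i, pair_j, pair_pot, bond_i, bond_j, bond_lo, bond_hi,
              hb_h, hb_o, hb_n, hb_rmin, hb_rmax, hb_depth, hb_gmin, hb_gmax);
  int N = eng.N;
  eng.rng.seed((unsigned long long)seed * 0x9E3779B97F4A7C15ULL + 1ULL);

  // initial predictions
  for (size_t p = 0; p < eng.pi_.size(); ++p) eng.predict_pair((int)p, 0.0);
  for (size_t q = 0; q < eng.bi_.size(); ++q) eng.predict_bond((int)q, 0.0);
  for (size_t h = 0; h < eng.hh_.size(); ++h) eng.predict_hb((int)h, 0.0);
  double total_ghost_rate = ghost_rate * N;
  if (ghost_rate > 0) {
    std::exponential_distribution<double> ex(total_ghost_rate);
    Ev g{ex(eng.rng), -1, -1, -1, EV_GHOST, 0, 0u, 0u};
    eng.push_ev(g);
  }
  if (resync_dt > 0) {
    Ev rs{resync_dt, -1, -1, -1, EV_RESYNC, 0, 0u, 0u};
    eng.push_ev(rs);
  }

  // snapshots
  int nsnap = (int)std::floor(t_end / snap_dt + 1e-9) + 1;
  NumericVector frames((R_xlen_t)nsnap * N * 3);
  frames.attr("dim") = IntegerVector::create(N, 3, nsnap);
  NumericVector snap_times(nsnap), snap_E(nsnap), snap_K(nsnap);
  NumericMatrix snap_P(nsnap, 3);
  int isnap = 0;

  std::vector<double> log_t; std::vector<int> log_kind, log_i, log_j, log_sh;

  auto emit_until = [&](double tlimit) {
    while (isnap < nsnap) {
      double ts = (double)isnap * snap_dt;
      if (ts > tlimit + 1e-12) break;
      double K = eng.kinetic();
      double Px = 0, Py = 0, Pz = 0;
      for (int i = 0; i < N; ++i) {
        double dt = ts - eng.pt[i];
        frames[(R_xlen_t)isnap * N * 3 + 0 * N + i] = eng.px[i] + eng.vx[i] * dt;
        frames[(R_xlen_t)isnap * N * 3 + 1 * N + i] = eng.py[i] + eng.vy[i] * dt;
        frames[(R_xlen_t)isnap * N * 3 + 2 * N + i] = eng.pz[i] + eng.vz[i] * dt;
        Px += eng.mass[i] * eng.vx[i];
        Py += eng.mass[i] * eng.vy[i];
        Pz += eng.mass[i] * eng.vz[i];
      }
      snap_times[isnap] = ts;
      snap_K[isnap] = K;
      snap_E[isnap] = K + eng.Epot;
      snap_P(isnap, 0) = Px; snap_P(isnap, 1) = Py; snap_P(isnap, 2) = Pz;
      ++isnap;
    }
  };

  long nevents = 0;
  long interrupt_check = 0;
  while (true) {
    if (eng.heap.empty()) break;
    std::pop_heap(eng.heap.begin(), eng.heap.end(), eng.cmp);
    Ev e = eng.heap.back();
    eng.heap.pop_back();
    if (!eng.valid(e)) { ++eng.n_stale; continue; }
    if (e.t > t_end) break;
    if (e.t < eng.tnow - 1e-9)
      stop("event-time regression: %.12g < %.12g", e.t, eng.tnow);
    emit_until(e.t);
    eng.tnow = std::max(eng.tnow, e.t);

    if (++interrupt_check % 65536 == 0) Rcpp::checkUserInterrupt();

    switch (e.type) {
    case EV_PAIR: {
      int p = e.idx, a = e.a, b = e.b;
      eng.advance(a, e.t); eng.advance(b, e.t);
      double r[3], v[3];
      eng.rel(a, b, e.t, r, v);
      const std::vector<double>& E = eng.energ[eng.ppot_[p]];
      int s = eng.pshell_[p];
      int target = e.aux > 0 ? s + 1 : s - 1;
      double dU = E[target] - E[s];
      bool crossed = eng.impulse(a, b, r, dU);
      if (crossed) { eng.pshell_[p] = target; eng.Epot += dU; }
      eng.cnt[a]++; eng.cnt[b]++;
      eng.repredict_particle(a, e.t);
      eng.repredict_particle(b, e.t);
      ++eng.n_exec[EV_PAIR];
      if (log_events && (int)log_t.size() < log_max) {
        log_t.push_back(e.t); log_kind.push_back(EV_PAIR);
        log_i.push_back(a + 1); log_j.push_back(b + 1); log_sh.push_back(eng.pshell_[p]);
      }
      break;
    }
    case EV_BOND: {
      int a = e.a, b = e.b;
      eng.advance(a, e.t); eng.advance(b, e.t);
      double r[3], v[3];
      eng.rel(a, b, e.t, r, v);
      eng.impulse(a, b, r, INF);     // reflecting wall
      eng.cnt[a]++; eng.cnt[b]++;
      eng.repredict_particle(a, e.t);
      eng.repredict_particle(b, e.t);
      ++eng.n_exec[EV_BOND];
      if (log_events && (int)log_t.size() < log_max) {
        log_t.push_back(e.t); log_kind.push_back(EV_BOND);
        log_i.push_back(a + 1); log_j.push_back(b + 1); log_sh.push_back(e.aux);
      }
      break;
    }
    case EV_HB: {
      int h = e.idx, a = e.a, b = e.b;
      eng.advance(a, e.t); eng.advance(b, e.t);
      double r[3], v[3];
      eng.rel(a, b, e.t, r, v);
      if (e.aux == -1) {
        eng.impulse(a, b, r, INF);   // inner hard wall
      } else if (e.aux == -2) {
        // entering the well from outside: the bond forms only if the N-O
        // gate is open and both partners are free (saturating bonds: one
        // per donor and per acceptor)
        double g = eng.dist(eng.hn_[h], eng.ho_[h], e.t);
        bool open = (g >= eng.hgmin_[h] && g <= eng.hgmax_[h]) &&
                    !eng.hb_busy_[a] && !eng.hb_busy_[b];
        double dU = open ? -eng.hdepth_[h] : 0.0;
        bool crossed = eng.impulse(a, b, r, dU);
        if (crossed) {
          eng.hin_[h] = 1;
          eng.hbonded_[h] = open ? 1 : 0;
          if (open) { eng.hb_busy_[a] = 1; eng.hb_busy_[b] = 1; }
          eng.Epot += dU;
        }
      } else {
        // leaving the well
        double dU = eng.hbonded_[h] ? +eng.hdepth_[h] : 0.0;
        bool crossed = eng.impulse(a, b, r, dU);
        if (crossed) {
          if (eng.hbonded_[h]) {
            eng.Epot += dU;
            eng.hb_busy_[a] = 0; eng.hb_busy_[b] = 0;
          }
          eng.hin_[h] = 0;
          eng.hbonded_[h] = 0;
        }
      }
      eng.cnt[a]++; eng.cnt[b]++;
      eng.repredict_particle(a, e.t);
      eng.repredict_particle(b, e.t);
      ++eng.n_exec[EV_HB];
      if (log_events && (int)log_t.size() < log_max) {
        log_t.push_back(e.t); log_kind.push_back(EV_HB);
        log_i.push_back(a + 1); log_j.push_back(b + 1); log_sh.push_back(eng.hbonded_[h]);
      }
      break;
    }
    case EV_GHOST: {
      double u = eng.unif(eng.rng);
      int a = std::min(N - 1, (int)(u * N));
      eng.advance(a, e.t);
      double sd = std::sqrt(kT / eng.mass[a]);
      eng.vx[a] = sd * eng.gauss(eng.rng);
      eng.vy[a] = sd * eng.gauss(eng.rng);
      eng.vz[a] = sd * eng.gauss(eng.rng);
      eng.cnt[a]++;
      eng.repredict_particle(a, e.t);
      std::exponential_distribution<double> ex(total_ghost_rate);
      Ev g{e.t + ex(eng.rng), -1, -1, -1, EV_GHOST, 0, 0u, 0u};
      eng.push_ev(g);
      ++eng.n_exec[EV_GHOST];
      break;
    }
    case EV_RESYNC: {
      for (size_t p = 0; p < eng.pi_.size(); ++p) eng.predict_pair((int)p, e.t);
      Ev rs{e.t + resync_dt, -1, -1, -1, EV_RESYNC, 0, 0u, 0u};
      eng.push_ev(rs);
      ++eng.n_exec[EV_RESYNC];
      break;
    }
    }
    ++nevents;
    if (nevents >= (long)max_events) break;
  }
  emit_until(t_end);
  for (int i = 0; i < N; ++i) eng.advance(i, std::max(eng.tnow, isnap > 0 ? snap_times[isnap-1] : 0.0));

  NumericMatrix xf(N, 3), vf(N, 3);
  for (int i = 0; i < N; ++i) {
    xf(i,0) = eng.px[i]; xf(i,1) = eng.py[i]; xf(i,2) = eng.pz[i];
    vf(i,0) = eng.vx[i]; vf(i,1) = eng.vy[i]; vf(i,2) = eng.vz[i];
  }
  List lg = R_NilValue;
  if (log_events) {
    lg = List::create(_["time"] = wrap(log_t), _["kind"] = wrap(log_kind),
                      _["i"] = wrap(log_i), _["j"] = wrap(log_j),
                      _["shell"] = wrap(log_sh));
  }
  return List::create(
    _["frames"] = frames,
    _["times"] = snap_times[Range(0, std::max(isnap - 1, 0))],
    _["n_frames"] = isnap,
    _["x_final"] = xf, _["v_final"] = vf,
    _["t_final"] = eng.tnow,
    _["n_events"] = (double)nevents,
    _["n_stale"] = (double)eng.n_stale,
    _["event_counts"] = NumericVector::create(
        _["pair"] = (double)eng.n_exec[0], _["bond"] = (double)eng.n_exec[1],
        _["hbond"] = (double)eng.n_exec[2], _["ghost"] = (double)eng.n_exec[3],
        _["resync"] = (double)eng.n_exec[4]),
    _["energy"] = snap_E, _["kinetic"] = snap_K, _["momentum"] = snap_P,
    _["epot_final_tracked"] = eng.Epot,
    _["epot_final_recomputed"] = eng.recompute_epot(eng.tnow),
    _["event_log"] = lg);
}

// [[Rcpp::export]]
double dmd_energy_cpp(NumericMatrix x, NumericMatrix v, NumericVector mass,
                      double boxL, List pot_radii, List pot_energies,
                      IntegerVector pair_i, IntegerVector pair_j, IntegerVector pair_pot,
                      IntegerVector bond_i, IntegerVector bond_j,
                      NumericVector bond_lo, NumericVector bond_hi,
                      IntegerVector hb_h, IntegerVector hb_o, IntegerVector hb_n,
                      NumericVector hb_rmin, NumericVector hb_rmax,
                      NumericVector hb_depth, NumericVector hb_gmin,
                      NumericVector hb_gmax) {
  int N = x.nrow();
  double mic;
  double e = 0;
  auto dist = [&](int a, int b) {
    double d2 = 0;
    for (int k = 0; k < 3; ++k) {
      double d = x(b,k) - x(a,k);
      if (boxL > 0) d -= boxL * std::round(d / boxL);
      d2 += d * d;
    }
    return std::sqrt(d2);
  };
  (void)mic; (void)N;
  for (int i = 0; i < x.nrow(); ++i)
    e += 0.5 * mass[i] * (v(i,0)*v(i,0) + v(i,1)*v(i,1) + v(i,2)*v(i,2));
  for (int p = 0; p < pair_i.size(); ++p) {
    NumericVector R = pot_radii[pair_pot[p] - 1], E = pot_energies[pair_pot[p] - 1];
    double d = dist(pair_i[p] - 1, pair_j[p] - 1);
    int s = (int)(std::upper_bound(R.begin(), R.end(), d) - R.begin());
    e += E[s];
  }
  for (int q = 0; q < bond_i.size(); ++q) {
    double d = dist(bond_i[q] - 1, bond_j[q] - 1);
    if (d < bond_lo[q] - 1e-7 || d > bond_hi[q] + 1e-7) e += INF;
  }
  // saturating hydrogen bonds: greedy assignment in row order, one bond per
  // donor and per acceptor (matches the engine's initialization)
  std::vector<int> busy(N, 0);
  for (int h = 0; h < hb_h.size(); ++h) {
    int a = hb_h[h] - 1, b = hb_o[h] - 1;
    if (busy[a] || busy[b]) continue;
    double d = dist(a, b);
    if (d < hb_rmax[h]) {
      double g = dist(hb_n[h] - 1, b);
      if (g >= hb_gmin[h] && g <= hb_gmax[h]) {
        e -= hb_depth[h];
        busy[a] = 1; busy[b] = 1;
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List dmd_predict_pair_cpp(NumericVector xi, NumericVector xj,
                          NumericVector vi, NumericVector vj,
                          NumericVector radii, double boxL) {
  double r[3], v[3];
  for (int k = 0; k < 3; ++k) {
    r[k] = xj[k] - xi[k];
    if (boxL > 0) r[k] -= boxL * std::round(r[k] / boxL);
    v[k] = vj[k] - vi[k];
  }
  double rr = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
  double rv = r[0]*v[0] + r[1]*v[1] + r[2]*v[2];
  double vv = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
  double d = std::sqrt(rr);
  int n = radii.size();
  int s = (int)(std::upper_bound(radii.begin(), radii.end(), d) - radii.begin());
  double best = INF; int bidx = NA_INTEGER; bool outward = false;
  if (vv > 0) {
    if (s < n) {
      double tau = Engine::t_outward(vv, rv, rr - radii[s] * radii[s]);
      if (tau < best) { best = tau; bidx = s + 1; outward = true; }
    }
    if (s > 0) {
      double tau = Engine::t_inward(vv, rv, rr - radii[s-1] * radii[s-1]);
      if (tau < best) { best = tau; bidx = s; outward = false; }
    }
  }
  if (!std::isfinite(best))
    return List::create(_["time"] = R_PosInf, _["radius_index"] = NA_INTEGER,
                        _["outward"] = NA_LOGICAL, _["shell"] = s + 1);
  return List::create(_["time"] = best, _["radius_index"] = bidx,
                      _["outward"] = outward, _["shell"] = s + 1);
}

// [[Rcpp::export]]
List dmd_collide_cpp(NumericVector xi, NumericVector xj,
                     NumericVector vi, NumericVector vj,
                     double mi, double mj, double dU, double boxL) {
  double r[3];
  for (int k = 0; k < 3; ++k) {
    r[k] = xj[k] - xi[k];
    if (boxL > 0) r[k] -= boxL * std::round(r[k] / boxL);
  }
  double rr = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
  double n0 = r[0]/rr, n1 = r[1]/rr, n2 = r[2]/rr;
  double mu = mi * mj / (mi + mj);
  double vr = (vj[0]-vi[0])*n0 + (vj[1]-vi[1])*n1 + (vj[2]-vi[2])*n2;
  bool cross; double vrp;
  if (!std::isfinite(dU)) { cross = false; vrp = -vr; }
  else if (dU <= 0 || 0.5 * mu * vr * vr > dU) {
    cross = true;
    double s = vr >= 0 ? 1.0 : -1.0;
    vrp = s * std::sqrt(vr * vr - 2.0 * dU / mu);
  } else { cross = false; vrp = -vr; }
  double dvr = vrp - vr;
  NumericVector ui = clone(vi), uj = clone(vj);
  ui[0] -= mu * dvr / mi * n0; ui[1] -= mu * dvr / mi * n1; ui[2] -= mu * dvr / mi * n2;
  uj[0] += mu * dvr / mj * n0; uj[1] += mu * dvr / mj * n1; uj[2] += mu * dvr / mj * n2;
  return List::create(_["vi"] = ui, _["vj"] = uj, _["crossed"] = cross);
}
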