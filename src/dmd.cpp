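// Event-driven discrete molecular dynamics for bead models with stepwise
// pair potentials: exact ballistic propagation between potential
// discontinuities, hard-core bounces, square-well capture/escape,
// hard-walled bonds, state-tracked directional backbone hydrogen bonds,
// an Andersen-style ghost-collision thermostat and periodic boundaries
// (minimum image). Neighbour search uses per-bead Verlet lists with a
// displacement-guaranteed refresh (each bead rebuilds its list before
// moving half the skin), plus a full rebuild at every sample tick.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double kB = 0.0019872041; // kcal/mol/K
static const double TOL = 1e-9;        // boundary classification tolerance, nm

// ---------------------------------------------------------------- RNG -----
// splitmix64 + polar-free Box-Muller; self-contained so that runs are
// bit-reproducible across platforms and independent of R's RNG state.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  bool spare_ok = false;
  double spare = 0.0;
  double norm() {
    if (spare_ok) { spare_ok = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 1e-300);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    spare_ok = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// -------------------------------------------------------------- events ----
enum EvType { EV_PAIR = 0, EV_BOND = 1, EV_GHOST = 2, EV_SAMPLE = 3,
              EV_REFRESH = 4 };

struct Event {
  double t;
  int i, j;        // bead ids (j = -1 for single-bead / global events)
  long long ci, cj; // validity counters at scheduling time
  int type;
};

struct EvCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;          // min-heap on time
    if (a.type != b.type) return a.type > b.type;
    if (a.i != b.i) return a.i > b.i;          // deterministic tie-break
    return a.j > b.j;
  }
};

// boundary of a stepwise pair potential
struct Boundary {
  double r;
  int tag;   // 0 hard wall, 1 table step (aux = shell boundary index),
             // 2 hb capture/escape radius
  int aux;
};

struct Engine {
  int N;
  double L, halfL;
  std::vector<double> x, v;       // 3N, lazily propagated
  std::vector<double> tlast;      // per-bead time of last propagation
  std::vector<double> m;
  std::vector<char> mobile;
  std::vector<int> clazz, chain, resid, bbprev, bbnext;
  std::vector<int> mobileIdx;

  // bonds (hard-walled wells)
  struct Bond { int j; double rmin, rmax; };
  std::vector<std::vector<Bond>> bondOf;
  std::vector<std::array<int, 2>> bondList;
  std::vector<double> bondMin, bondMax;
  std::unordered_map<long long, int> bondIdx;

  // force-field tables: per class-pair list of breaks (first = hard core)
  // and shell energies between consecutive breaks (0 beyond the last)
  int ncl;
  std::vector<std::vector<double>> tbreaks, tener; // index a*ncl+b
  double maxRange;

  // hydrogen bonds
  double hb_rmin, hb_rmax, hb_eps, hb_cosmin;
  int hb_cap, hb_sep;
  std::unordered_set<long long> hb;
  std::vector<int> nhb;

  // thermostat / schedule
  double Tkelvin, ghostRate, sampleDt, tEnd, skin;
  long long maxEventsPerSample;

  double tnow = 0.0;
  std::vector<long long> cnt;   // pair-event validity counter per bead
  std::vector<long long> rcnt;  // refresh-event counter per bead
  std::vector<std::vector<int>> nbr;
  std::vector<double> listPos;  // 3N, position at last list build
  std::priority_queue<Event, std::vector<Event>, EvCmp> q;
  RNG rng;
  long long nPairEvents = 0, nGhost = 0, eventsSinceSample = 0;
  long long nInconsistent = 0;

  Engine(uint64_t seed) : rng(seed) {}

  inline long long key(int i, int j) const {
    int a = std::min(i, j), b = std::max(i, j);
    return (long long)a * (long long)N + b;
  }

  inline void mimg(double* d) const {
    for (int k = 0; k < 3; ++k) d[k] -= L * std::nearbyint(d[k] / L);
  }

  inline void posAt(int i, double t, double* out) const {
    double dt = t - tlast[i];
    for (int k = 0; k < 3; ++k) out[k] = x[3 * i + k] + v[3 * i + k] * dt;
  }

  inline void propagate(int i, double t) {
    double dt = t - tlast[i];
    if (dt != 0.0) {
      for (int k = 0; k < 3; ++k) x[3 * i + k] += v[3 * i + k] * dt;
      tlast[i] = t;
    }
  }

  // -1 excluded, 0 bonded, 1 non-bonded interacting
  inline int pairKind(int i, int j, const Bond** bnd) const {
    auto it = bondIdx.find(key(i, j));
    if (it != bondIdx.end()) {
      if (bnd) {
        int bi = it->second;
        static thread_local Bond tmp;
        tmp.j = j; tmp.rmin = bondMin[bi]; tmp.rmax = bondMax[bi];
        *bnd = &tmp;
      }
      return 0;
    }
    if (chain[i] == chain[j] && std::abs(resid[i] - resid[j]) <= 1) return -1;
    return 1;
  }

  inline bool hbEligibleClass(int i, int j) const {
    if (clazz[i] != 0 || clazz[j] != 0) return false;
    if (chain[i] == chain[j] && std::abs(resid[i] - resid[j]) < hb_sep)
      return false;
    return true;
  }

  inline bool isHB(int i, int j) const { return hb.count(key(i, j)) > 0; }

  // chain tangent at a backbone bead, at time t; false if undefined
  bool tangent(int i, double t, double* out) const {
    int p = bbprev[i], n = bbnext[i];
    double a[3], b[3];
    if (p < 0 && n < 0) return false;
    if (p < 0) p = i;
    if (n < 0) n = i;
    posAt(p, t, a);
    posAt(n, t, b);
    double d[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    mimg(d);
    double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (nn < 1e-12) return false;
    for (int k = 0; k < 3; ++k) out[k] = d[k] / nn;
    return true;
  }

  bool aligned(int i, int j, double t) const {
    double ti[3], tj[3];
    if (!tangent(i, t, ti) || !tangent(j, t, tj)) return false;
    double c = std::fabs(ti[0] * tj[0] + ti[1] * tj[1] + ti[2] * tj[2]);
    return c >= hb_cosmin;
  }

  // precomputed boundary lists: plain tables per class pair, the backbone
  // pair list with the hb capture radius, and the bonded-hb well
  std::vector<std::vector<Boundary>> pairBounds;
  std::vector<Boundary> hbCaptureBounds, hbBondedBounds;

  void precomputeBounds() {
    pairBounds.resize(ncl * ncl);
    for (int a = 0; a < ncl; ++a)
      for (int b = 0; b < ncl; ++b) {
        std::vector<Boundary>& out = pairBounds[a * ncl + b];
        const std::vector<double>& br = tbreaks[a * ncl + b];
        for (size_t k = 0; k < br.size(); ++k)
          out.push_back({br[k], k == 0 ? 0 : 1, (int)k});
      }
    hbCaptureBounds = pairBounds[0]; // class 0 = backbone
    hbCaptureBounds.push_back({hb_rmax, 2, -1});
    std::sort(hbCaptureBounds.begin(), hbCaptureBounds.end(),
              [](const Boundary& p, const Boundary& q) { return p.r < q.r; });
    hbBondedBounds = { {hb_rmin, 0, -1}, {hb_rmax, 2, -1} };
  }

  // boundary list currently governing a non-bonded pair
  const std::vector<Boundary>& boundaries(int i, int j) const {
    if (hbEligibleClass(i, j)) {
      if (isHB(i, j)) return hbBondedBounds;
      return hbCaptureBounds;
    }
    return pairBounds[clazz[i] * ncl + clazz[j]];
  }

  // shell energy of the plain table just below/above boundary index k
  inline double shellEnergy(int a, int b, int k) const {
    const std::vector<double>& en = tener[a * ncl + b];
    if (k < 0) return R_PosInf;
    if (k >= (int)en.size()) return 0.0;
    return en[k];
  }

  // earliest event for pair (i, j); returns false if none
  bool pairEventTime(int i, int j, double& tev) const {
    const Bond* bnd = nullptr;
    int kind = pairKind(i, j, &bnd);
    if (kind < 0) return false;
    double xi[3], xj[3];
    posAt(i, tnow, xi);
    posAt(j, tnow, xj);
    double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
    mimg(d);
    double w[3] = { v[3 * j] - v[3 * i], v[3 * j + 1] - v[3 * i + 1],
                    v[3 * j + 2] - v[3 * i + 2] };
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double bq = d[0] * w[0] + d[1] * w[1] + d[2] * w[2];
    double w2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    if (w2 <= 0.0) return false;
    double r = std::sqrt(r2);

    double Rlo = -1.0, Rhi = -1.0;
    if (kind == 0) {
      // bonded pair: confined between rmin and rmax
      Rlo = bnd->rmin; Rhi = bnd->rmax;
      // tolerate boundary-sitting states via the same side rule below
      bool belowLo = r < Rlo - TOL || (std::fabs(r - Rlo) <= TOL && bq < 0);
      if (belowLo) { Rhi = Rlo; Rlo = -1.0; } // outside inner wall: expelled
    } else {
      const std::vector<Boundary>& bl = boundaries(i, j);
      if (bl.empty()) return false;
      for (size_t k = 0; k < bl.size(); ++k) {
        double R = bl[k].r;
        bool below = r < R - TOL || (std::fabs(r - R) <= TOL && bq < 0);
        if (below) { Rhi = R; break; }
        Rlo = R;
      }
    }

    // approach to the boundary just below, if moving inward and reachable
    if (Rlo > 0 && bq < 0) {
      double disc = bq * bq - w2 * (r2 - Rlo * Rlo);
      if (disc > 0) {
        double s = (-bq - std::sqrt(disc)) / w2;
        if (s >= 0) { tev = tnow + s; return true; }
      }
    }
    if (Rhi > 0) {
      double disc = bq * bq - w2 * (r2 - Rhi * Rhi);
      if (disc < 0) disc = 0; // r <= Rhi guarantees disc >= bq^2
      double s = (-bq + std::sqrt(disc)) / w2;
      if (s >= 0) { tev = tnow + s; return true; }
    }
    return false;
  }

  int watch_i = -1, watch_j = -1;
  bool isWatched(int i, int j) const {
    return (i == watch_i && j == watch_j) || (i == watch_j && j == watch_i);
  }
  void watchDump(const char* what, int i, int j) const {
    double xi[3], xj[3];
    posAt(i, tnow, xi);
    posAt(j, tnow, xj);
    double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
    mimg(d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double w[3] = { v[3*j]-v[3*i], v[3*j+1]-v[3*i+1], v[3*j+2]-v[3*i+2] };
    double bq = d[0]*w[0] + d[1]*w[1] + d[2]*w[2];
    Rprintf("[watch %s] t=%.9f r=%.9f bq=%.6g cnt=(%lld,%lld)\n",
            what, tnow, r, bq, cnt[i], cnt[j]);
  }

  void pushPairEvent(int i, int j) {
    double tev;
    if (!pairEventTime(i, j, tev)) {
      if (isWatched(i, j)) watchDump("no-event", i, j);
      return;
    }
    if (isWatched(i, j))
      Rprintf("[watch push] t=%.9f tev=%.9f cnt=(%lld,%lld)\n",
              tnow, tev, cnt[std::min(i,j)], cnt[std::max(i,j)]);
    if (tev > tEnd + sampleDt) return;
    int a = std::min(i, j), b = std::max(i, j);
    int type = (bondIdx.count(key(i, j)) > 0) ? EV_BOND : EV_PAIR;
    q.push({tev, a, b, cnt[a], cnt[b], type});
  }

  void updateEventsFor(int i) {
    for (const Bond& bd : bondOf[i]) pushPairEvent(i, bd.j);
    for (int j : nbr[i]) pushPairEvent(i, j);
  }

  void buildList(int i) {
    nbr[i].clear();
    double range = maxRange + skin;
    double r2max = range * range;
    double xi[3];
    posAt(i, tnow, xi);
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      if (!mobile[i] && !mobile[j]) continue;
      const Bond* bnd;
      if (pairKind(i, j, &bnd) != 1) continue;
      double xj[3];
      posAt(j, tnow, xj);
      double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
      mimg(d);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < r2max)
        nbr[i].push_back(j);
    }
    for (int k = 0; k < 3; ++k) listPos[3 * i + k] = xi[k];
  }

  double speed(int i) const {
    return std::sqrt(v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                     v[3 * i + 2] * v[3 * i + 2]);
  }

  void scheduleRefresh(int i) {
    if (!mobile[i]) return;
    double xi[3];
    posAt(i, tnow, xi);
    double disp = 0;
    for (int k = 0; k < 3; ++k) {
      double dk = xi[k] - listPos[3 * i + k];
      disp += dk * dk;
    }
    disp = std::sqrt(disp);
    double budget = 0.5 * skin - disp;
    ++rcnt[i];
    if (budget <= 0) {
      refreshNow(i);
      return;
    }
    double sp = speed(i);
    double tref = (sp > 1e-12) ? tnow + budget / sp : tEnd + 2 * sampleDt;
    if (tref <= tEnd + sampleDt)
      q.push({tref, i, -1, rcnt[i], 0, EV_REFRESH});
  }

  void refreshNow(int i) {
    buildList(i);
    // symmetric append so the partner's updates also revisit this pair
    for (int j : nbr[i])
      if (mobile[j]) nbr[j].push_back(i);
    ++cnt[i];
    updateEventsFor(i);
    double sp = speed(i);
    ++rcnt[i];
    double tref = (sp > 1e-12) ? tnow + 0.5 * skin / sp : tEnd + 2 * sampleDt;
    if (tref <= tEnd + sampleDt)
      q.push({tref, i, -1, rcnt[i], 0, EV_REFRESH});
  }

  void fullRebuild() {
    q = std::priority_queue<Event, std::vector<Event>, EvCmp>();
    for (int i = 0; i < N; ++i) nbr[i].clear();
    for (int i : mobileIdx) buildList(i);
    // make lists symmetric for mobile-mobile pairs
    for (int i : mobileIdx)
      for (int j : nbr[i])
        if (mobile[j] && std::find(nbr[j].begin(), nbr[j].end(), i) ==
            nbr[j].end())
          nbr[j].push_back(i);
    for (int i = 0; i < N; ++i) { ++cnt[i]; }
    for (int i : mobileIdx) {
      for (const Bond& bd : bondOf[i])
        if (bd.j > i || !mobile[bd.j]) pushPairEvent(i, bd.j);
      for (int j : nbr[i])
        if (j > i || !mobile[j]) pushPairEvent(i, j);
      double sp = speed(i);
      ++rcnt[i];
      double tref = (sp > 1e-12) ? tnow + 0.5 * skin / sp
                                 : tEnd + 2 * sampleDt;
      if (tref <= tEnd + sampleDt)
        q.push({tref, i, -1, rcnt[i], 0, EV_REFRESH});
    }
    scheduleGhost();
  }

  void scheduleGhost() {
    if (ghostRate <= 0 || mobileIdx.empty()) return;
    double rate = ghostRate * mobileIdx.size();
    double u;
    do { u = rng.unif(); } while (u <= 1e-300);
    double tg = tnow - std::log(u) / rate;
    if (tg <= tEnd) q.push({tg, -1, -1, 0, 0, EV_GHOST});
  }

  void maxwellDraw(int i) {
    double sd = std::sqrt(kB * Tkelvin / m[i]);
    for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * rng.norm();
  }

  // apply the radial velocity change vr -> vrNew along unit vector nvec
  void applyImpulse(int i, int j, const double* nvec, double vr,
                    double vrNew, double mu) {
    double dp = mu * (vrNew - vr);
    if (mobile[j])
      for (int k = 0; k < 3; ++k) v[3 * j + k] += dp / m[j] * nvec[k];
    if (mobile[i])
      for (int k = 0; k < 3; ++k) v[3 * i + k] -= dp / m[i] * nvec[k];
  }

  // process a pair (or bond) event; returns a code describing what happened
  // 0 hard bounce, 1 well entry, 2 well exit, 3 reflected at well edge,
  // 4 hb capture, 5 hb escape, 6 hb pass-through, 7 bond boundary,
  // -1 inconsistent
  int processPair(int i, int j) {
    propagate(i, tnow);
    propagate(j, tnow);
    double d[3] = { x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                    x[3 * j + 2] - x[3 * i + 2] };
    mimg(d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double nvec[3] = { d[0] / r, d[1] / r, d[2] / r };
    double w[3] = { v[3 * j] - v[3 * i], v[3 * j + 1] - v[3 * i + 1],
                    v[3 * j + 2] - v[3 * i + 2] };
    double vr = w[0] * nvec[0] + w[1] * nvec[1] + w[2] * nvec[2];
    double mu;
    if (mobile[i] && mobile[j]) mu = m[i] * m[j] / (m[i] + m[j]);
    else if (mobile[i]) mu = m[i];
    else mu = m[j];

    const Bond* bnd = nullptr;
    int kind = pairKind(i, j, &bnd);
    int code = -1;

    if (kind == 0) {
      // hard bond wall: reflect whichever wall we are on
      double dmin = std::fabs(r - bnd->rmin), dmax = std::fabs(r - bnd->rmax);
      if (std::min(dmin, dmax) > 1e-5) { ++nInconsistent; }
      applyImpulse(i, j, nvec, vr, -vr, mu);
      code = 7;
    } else {
      const std::vector<Boundary>& bl = boundaries(i, j);
      // nearest boundary
      int kb = -1;
      double best = 1e30;
      for (size_t k = 0; k < bl.size(); ++k) {
        double dd = std::fabs(r - bl[k].r);
        if (dd < best) { best = dd; kb = (int)k; }
      }
      if (kb < 0 || best > 1e-5) {
        ++nInconsistent;
        if (mobile[i]) { ++cnt[i]; updateEventsFor(i); }
        if (mobile[j]) { ++cnt[j]; updateEventsFor(j); }
        return -1;
      }
      const Boundary& B = bl[kb];
      bool bondedHB = hbEligibleClass(i, j) && isHB(i, j);
      if (B.tag == 0) {                       // hard core / hb inner wall
        applyImpulse(i, j, nvec, vr, -vr, mu);
        code = 0;
      } else if (B.tag == 2 && bondedHB) {    // hb escape attempt
        if (vr > 0) {
          double need = 2.0 * hb_eps / mu;
          if (vr * vr > need) {
            applyImpulse(i, j, nvec, vr, std::sqrt(vr * vr - need), mu);
            hb.erase(key(i, j));
            --nhb[i]; --nhb[j];
            code = 5;
          } else {
            applyImpulse(i, j, nvec, vr, -vr, mu);
            code = 3;
          }
        } else code = 6; // approaching own escape radius: no-op
      } else if (B.tag == 2) {                // hb capture radius, unbonded
        if (vr < 0 && nhb[i] < hb_cap && nhb[j] < hb_cap &&
            aligned(i, j, tnow)) {
          double gain = 2.0 * hb_eps / mu;
          applyImpulse(i, j, nvec, vr, -std::sqrt(vr * vr + gain), mu);
          hb.insert(key(i, j));
          ++nhb[i]; ++nhb[j];
          code = 4;
        } else code = 6; // transparent crossing
      } else {                                // plain table step
        int a = clazz[i], b = clazz[j];
        // boundary index within the plain table
        int k = B.aux;
        double Ein = shellEnergy(a, b, k - 1);
        double Eout = shellEnergy(a, b, k);
        double dU = (vr < 0) ? (Ein - Eout) : (Eout - Ein);
        if (dU <= 0) { // downhill: transmit with speed-up
          double vrNew = (vr < 0 ? -1 : 1) * std::sqrt(vr * vr - 2 * dU / mu);
          applyImpulse(i, j, nvec, vr, vrNew, mu);
          code = (vr < 0) ? 1 : 2;
        } else {
          double need = 2.0 * dU / mu;
          if (vr * vr > need) {
            double vrNew = (vr < 0 ? -1 : 1) * std::sqrt(vr * vr - need);
            applyImpulse(i, j, nvec, vr, vrNew, mu);
            code = (vr < 0) ? 1 : 2;
          } else {
            applyImpulse(i, j, nvec, vr, -vr, mu);
            code = 3;
          }
        }
      }
    }
    // a static partner's state is unchanged by the collision: leave its
    // counter alone so pending events of other beads against it stay valid
    if (mobile[i]) { ++cnt[i]; scheduleRefresh(i); updateEventsFor(i); }
    if (mobile[j]) { ++cnt[j]; scheduleRefresh(j); updateEventsFor(j); }
    return code;
  }

  // potential energy over pairs involving at least one mobile bead
  // (the frozen template's internal energy is constant and excluded)
  double potentialEnergy() const {
    double U = 0.0;
    for (int idx = 0; idx < (int)mobileIdx.size(); ++idx) {
      int i = mobileIdx[idx];
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        if (mobile[j] && j < i) continue;
        const Bond* bnd;
        int kind = pairKind(i, j, &bnd);
        if (kind != 1) continue;
        double xi[3], xj[3];
        posAt(i, tnow, xi);
        posAt(j, tnow, xj);
        double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
        mimg(d);
        double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (hbEligibleClass(i, j) && isHB(i, j)) { U -= hb_eps; continue; }
        int a = clazz[i], b = clazz[j];
        const std::vector<double>& br = tbreaks[a * ncl + b];
        double w[3] = { v[3 * j] - v[3 * i], v[3 * j + 1] - v[3 * i + 1],
                        v[3 * j + 2] - v[3 * i + 2] };
        double bq = d[0] * w[0] + d[1] * w[1] + d[2] * w[2];
        int shell = 0;
        for (size_t k = 0; k < br.size(); ++k) {
          bool below = r < br[k] - TOL ||
                       (std::fabs(r - br[k]) <= TOL && bq < 0);
          if (below) break;
          shell = (int)k + 1;
        }
        U += shellEnergy(a, b, shell - 1);
      }
    }
    return U;
  }

  double kineticEnergy() const {
    double K = 0.0;
    for (int i : mobileIdx)
      K += 0.5 * m[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                         v[3 * i + 2] * v[3 * i + 2]);
    return K;
  }

  void checkInitial() const {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (!mobile[i] && !mobile[j]) continue;
        const Bond* bnd;
        int kind = pairKind(i, j, &bnd);
        if (kind < 0) continue;
        double d[3] = { x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                        x[3 * j + 2] - x[3 * i + 2] };
        mimg(d);
        double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (kind == 0) {
          if (r < bnd->rmin - 1e-7 || r > bnd->rmax + 1e-7)
            stop("bond %d-%d outside its well (r = %f nm)", i + 1, j + 1, r);
        } else {
          double core = tbreaks[clazz[i] * ncl + clazz[j]][0];
          if (r < core - 1e-7)
            stop("hard-core overlap between beads %d and %d (r = %f nm)",
                 i + 1, j + 1, r);
        }
      }
  }
};

// ------------------------------------------------------------ assembly ----
static Engine* makeEngine(List sys, List ffc, List opts) {
  NumericMatrix pos = sys["pos"];
  NumericMatrix vel = sys["vel"];
  NumericVector mass = sys["mass"];
  LogicalVector mob = sys["mobile"];
  IntegerVector clazz = sys["clazz"];
  IntegerVector chain = sys["chain"];
  IntegerVector resid = sys["resid"];
  IntegerVector bbprev = sys["bbprev"];
  IntegerVector bbnext = sys["bbnext"];
  IntegerMatrix bonds = sys["bonds"];
  NumericVector bmin = sys["bond_rmin"];
  NumericVector bmax = sys["bond_rmax"];
  IntegerMatrix hbp = sys["hb_pairs"];
  double box = as<double>(sys["box_length"]);
  double t0 = sys.containsElementNamed("time") ? as<double>(sys["time"]) : 0.0;

  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  Engine* E = new Engine(seed);
  int N = pos.nrow();
  E->N = N;
  E->L = box; E->halfL = box / 2;
  E->x.resize(3 * N); E->v.resize(3 * N);
  E->tlast.assign(N, t0);
  E->tnow = t0;
  E->m.resize(N); E->mobile.resize(N);
  E->clazz.resize(N); E->chain.resize(N); E->resid.resize(N);
  E->bbprev.resize(N); E->bbnext.resize(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) {
      E->x[3 * i + k] = pos(i, k);
      E->v[3 * i + k] = vel(i, k);
    }
    E->m[i] = mass[i];
    E->mobile[i] = (char)(mob[i] ? 1 : 0);
    E->clazz[i] = clazz[i];
    E->chain[i] = chain[i];
    E->resid[i] = resid[i];
    E->bbprev[i] = bbprev[i]; // already 0-based or -1 from R
    E->bbnext[i] = bbnext[i];
    if (E->mobile[i]) E->mobileIdx.push_back(i);
  }
  E->bondOf.assign(N, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1); // 0-based from R wrapper
    E->bondList.push_back({i, j});
    E->bondMin.push_back(bmin[b]);
    E->bondMax.push_back(bmax[b]);
    E->bondIdx[E->key(i, j)] = b;
    E->bondOf[i].push_back({j, bmin[b], bmax[b]});
    E->bondOf[j].push_back({i, bmin[b], bmax[b]});
  }

  int ncl = as<int>(ffc["n_class"]);
  E->ncl = ncl;
  List tb = ffc["breaks"];
  List te = ffc["energies"];
  E->tbreaks.resize(ncl * ncl);
  E->tener.resize(ncl * ncl);
  E->maxRange = 0;
  for (int a = 0; a < ncl; ++a)
    for (int b = 0; b < ncl; ++b) {
      int idx = a * ncl + b;
      E->tbreaks[idx] = as<std::vector<double>>(tb[idx]);
      E->tener[idx] = as<std::vector<double>>(te[idx]);
      if (!E->tbreaks[idx].empty())
        E->maxRange = std::max(E->maxRange, E->tbreaks[idx].back());
    }
  E->hb_rmin = as<double>(ffc["hb_rmin"]);
  E->hb_rmax = as<double>(ffc["hb_rmax"]);
  E->hb_eps = as<double>(ffc["hb_eps"]);
  E->hb_cosmin = std::cos(as<double>(ffc["hb_align_deg"]) * M_PI / 180.0);
  E->hb_cap = as<int>(ffc["hb_max_per_bead"]);
  E->hb_sep = as<int>(ffc["hb_min_seq_sep"]);
  E->maxRange = std::max(E->maxRange, E->hb_rmax);
  E->precomputeBounds();
  E->nhb.assign(N, 0);
  for (int r = 0; r < hbp.nrow(); ++r) {
    int i = hbp(r, 0), j = hbp(r, 1);
    E->hb.insert(E->key(i, j));
    ++E->nhb[i]; ++E->nhb[j];
  }

  E->Tkelvin = as<double>(opts["temperature"]);
  E->ghostRate = as<double>(opts["ghost_rate"]);
  E->sampleDt = as<double>(opts["sample_dt"]);
  E->tEnd = as<double>(opts["t_end"]);
  E->skin = opts.containsElementNamed("skin") ? as<double>(opts["skin"]) : 0.3;
  E->maxEventsPerSample =
    (long long)(opts.containsElementNamed("max_events_per_sample")
                ? as<double>(opts["max_events_per_sample"]) : 5e7);
  if (opts.containsElementNamed("watch")) {
    IntegerVector wp = opts["watch"];
    E->watch_i = wp[0]; E->watch_j = wp[1];
  }
  E->cnt.assign(N, 0);
  E->rcnt.assign(N, 0);
  E->nbr.assign(N, {});
  E->listPos.assign(3 * N, 0.0);
  return E;
}

static List snapshot(Engine* E) {
  int N = E->N;
  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; ++i) {
    double xi[3];
    E->posAt(i, E->tnow, xi);
    for (int k = 0; k < 3; ++k) {
      pos(i, k) = xi[k];
      vel(i, k) = E->v[3 * i + k];
    }
  }
  std::vector<int> hi, hj;
  for (long long kk : E->hb) {
    hi.push_back((int)(kk / N));
    hj.push_back((int)(kk % N));
  }
  IntegerMatrix hbp(hi.size(), 2);
  for (size_t r = 0; r < hi.size(); ++r) {
    hbp(r, 0) = hi[r];
    hbp(r, 1) = hj[r];
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["hb_pairs"] = hbp,
                      _["time"] = E->tnow);
}

// ------------------------------------------------------------- exports ----

// full production run: sample frames and energies every sample_dt
// [[Rcpp::export]]
List dmd_run_cpp(List sys, List ffc, List opts) {
  Engine* E = makeEngine(sys, ffc, opts);
  E->checkInitial();
  double t0 = E->tnow;
  int nSamples = (int)std::floor((E->tEnd - t0) / E->sampleDt + 1e-9);
  std::vector<NumericMatrix> frames;
  std::vector<double> times, energies, kinetic;
  bool record = !opts.containsElementNamed("record_frames") ||
                as<bool>(opts["record_frames"]);

  auto takeSample = [&](double t) {
    for (int i : E->mobileIdx) E->propagate(i, t);
    times.push_back(t);
    double K = E->kineticEnergy();
    kinetic.push_back(K);
    energies.push_back(K + E->potentialEnergy());
    if (record) {
      NumericMatrix fr(E->N, 3);
      for (int i = 0; i < E->N; ++i) {
        double xi[3];
        E->posAt(i, t, xi);
        for (int k = 0; k < 3; ++k) fr(i, k) = xi[k];
      }
      frames.push_back(fr);
    }
  };

  bool paranoid = opts.containsElementNamed("paranoid") &&
                  as<bool>(opts["paranoid"]);
  auto overlapCheck = [&](double t) {
    for (int i : E->mobileIdx)
      for (int j = 0; j < E->N; ++j) {
        if (j == i || (E->mobile[j] && j < i)) continue;
        const Engine::Bond* bnd;
        int kind = E->pairKind(i, j, &bnd);
        if (kind < 0) continue;
        double xi[3], xj[3];
        E->posAt(i, t, xi);
        E->posAt(j, t, xj);
        double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
        E->mimg(d);
        double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        if (kind == 0) {
          if (r < bnd->rmin - 1e-6 || r > bnd->rmax + 1e-6)
            stop("paranoid: bond %d-%d at r=%f t=%f", i, j, r, t);
        } else {
          double core = E->tbreaks[E->clazz[i] * E->ncl + E->clazz[j]][0];
          bool hbb = E->hbEligibleClass(i, j) && E->isHB(i, j);
          double lim = hbb ? E->hb_rmin : core;
          if (r < lim - 1e-6)
            stop("paranoid: overlap %d-%d (classes %d,%d, chains %d,%d) r=%f t=%f",
                 i, j, E->clazz[i], E->clazz[j], E->chain[i], E->chain[j],
                 r, t);
        }
      }
  };

  takeSample(t0);
  E->fullRebuild();
  int nextSample = 1;
  long long nEvents = 0;
  while (nextSample <= nSamples) {
    double tSample = t0 + nextSample * E->sampleDt;
    bool sampled = false;
    while (!E->q.empty()) {
      Event e = E->q.top();
      if (e.t > tSample) break;
      E->q.pop();
      if (e.type == EV_REFRESH) {
        if (e.ci != E->rcnt[e.i]) continue;
        E->tnow = e.t;
        E->refreshNow(e.i);
      } else if (e.type == EV_GHOST) {
        E->tnow = e.t;
        int pick = E->mobileIdx[(int)(E->rng.unif() * E->mobileIdx.size())];
        E->propagate(pick, e.t);
        E->maxwellDraw(pick);
        ++E->cnt[pick];
        E->scheduleRefresh(pick);
        E->updateEventsFor(pick);
        ++E->nGhost;
        E->scheduleGhost();
      } else { // pair or bond
        if (e.ci != E->cnt[e.i] || e.cj != E->cnt[e.j]) {
          if (E->isWatched(e.i, e.j))
            Rprintf("[watch stale] t=%.9f cnt=(%lld,%lld) vs (%lld,%lld)\n",
                    e.t, e.ci, e.cj, E->cnt[e.i], E->cnt[e.j]);
          continue;
        }
        E->tnow = e.t;
        if (E->isWatched(e.i, e.j)) E->watchDump("process", e.i, e.j);
        E->processPair(e.i, e.j);
        if (paranoid) {
          for (int bead : {e.i, e.j}) {
            if (!E->mobile[bead]) continue;
            double xi[3];
            E->posAt(bead, e.t, xi);
            for (int j2 = 0; j2 < E->N; ++j2) {
              if (j2 == bead) continue;
              const Engine::Bond* bnd2;
              if (E->pairKind(bead, j2, &bnd2) != 1) continue;
              double xj[3];
              E->posAt(j2, e.t, xj);
              double d2v[3] = { xj[0] - xi[0], xj[1] - xi[1],
                                xj[2] - xi[2] };
              E->mimg(d2v);
              double r2d = std::sqrt(d2v[0] * d2v[0] + d2v[1] * d2v[1] +
                                     d2v[2] * d2v[2]);
              double core2 =
                E->tbreaks[E->clazz[bead] * E->ncl + E->clazz[j2]][0];
              bool hbb2 = E->hbEligibleClass(bead, j2) && E->isHB(bead, j2);
              if (hbb2) core2 = E->hb_rmin;
              if (r2d < core2 - 1e-6) {
                bool inlist =
                  std::find(E->nbr[bead].begin(), E->nbr[bead].end(), j2)
                  != E->nbr[bead].end();
                Rprintf("OVERLAP after event (%d,%d) t=%f: pair (%d,%d) "
                        "r=%f core=%f hb=%d inlist=%d classes=%d,%d\n",
                        e.i, e.j, e.t, bead, j2, r2d, core2, (int)hbb2,
                        (int)inlist, E->clazz[bead], E->clazz[j2]);
                stop("paranoid overlap traced");
              }
            }
          }
        }
        ++E->nPairEvents;
        ++nEvents;
        if (++E->eventsSinceSample > E->maxEventsPerSample) {
          delete E;
          stop("inelastic collapse: event cascade exceeded the safety bound "
               "within one sample interval");
        }
      }
    }
    E->tnow = tSample;
    takeSample(tSample);
    if (paranoid) overlapCheck(tSample);
    E->eventsSinceSample = 0;
    E->fullRebuild();
    ++nextSample;
    sampled = true;
    (void)sampled;
    Rcpp::checkUserInterrupt();
  }

  List st = snapshot(E);
  List out = List::create(
    _["times"] = times, _["frames"] = wrap(frames),
    _["energies"] = energies, _["kinetic"] = kinetic,
    _["n_events"] = (double)E->nPairEvents,
    _["n_ghost"] = (double)E->nGhost,
    _["n_inconsistent"] = (double)E->nInconsistent,
    _["state"] = st);
  delete E;
  return out;
}

// peek at (n_process = 0) or process n events, returning an event log;
// internal neighbour-refresh events are handled silently
// [[Rcpp::export]]
List dmd_step_cpp(List sys, List ffc, List opts, int n_process) {
  Engine* E = makeEngine(sys, ffc, opts);
  E->checkInitial();
  E->fullRebuild();
  std::vector<double> evT;
  std::vector<int> evI, evJ, evCode;
  int done = 0;
  while ((int)evT.size() < std::max(n_process, 1)) {
    if (E->q.empty()) break;
    Event e = E->q.top();
    E->q.pop();
    if (e.type == EV_REFRESH) {
      if (e.ci != E->rcnt[e.i]) continue;
      E->tnow = e.t;
      E->refreshNow(e.i);
      continue;
    }
    if (e.type == EV_GHOST) {
      if (n_process == 0) {
        evT.push_back(e.t); evI.push_back(-1); evJ.push_back(-1);
        evCode.push_back(100);
        break;
      }
      E->tnow = e.t;
      int pick = E->mobileIdx[(int)(E->rng.unif() * E->mobileIdx.size())];
      E->propagate(pick, e.t);
      E->maxwellDraw(pick);
      ++E->cnt[pick];
      E->scheduleRefresh(pick);
      E->updateEventsFor(pick);
      E->scheduleGhost();
      evT.push_back(e.t); evI.push_back(pick); evJ.push_back(-1);
      evCode.push_back(100);
      ++done;
      continue;
    }
    // pair / bond
    if (e.ci != E->cnt[e.i] || e.cj != E->cnt[e.j]) continue;
    if (n_process == 0) {
      // classify without processing: inspect distance/direction
      evT.push_back(e.t); evI.push_back(e.i); evJ.push_back(e.j);
      evCode.push_back(e.type == EV_BOND ? 7 : 10);
      break;
    }
    E->tnow = e.t;
    int code = E->processPair(e.i, e.j);
    evT.push_back(e.t); evI.push_back(e.i); evJ.push_back(e.j);
    evCode.push_back(code);
    ++done;
  }
  List st = snapshot(E);
  double K = E->kineticEnergy(), U = E->potentialEnergy();
  List out = List::create(
    _["event_time"] = evT, _["event_i"] = evI, _["event_j"] = evJ,
    _["event_code"] = evCode, _["state"] = st,
    _["energy"] = K + U, _["kinetic"] = K, _["potential"] = U);
  delete E;
  return out;
}

// total, kinetic and step-potential energy of a state
// [[Rcpp::export]]
List dmd_energy_cpp(List sys, List ffc) {
  List opts = List::create(_["seed"] = 1.0, _["temperature"] = 300.0,
                           _["ghost_rate"] = 0.0, _["sample_dt"] = 1.0,
                           _["t_end"] = 0.0);
  Engine* E = makeEngine(sys, ffc, opts);
  double K = E->kineticEnergy(), U = E->potentialEnergy();
  List out = List::create(_["total"] = K + U, _["kinetic"] = K,
                          _["potential"] = U);
  delete E;
  return out;
}

// residue-level intermolecular contacts within a frame:
// unique (chain_i, resid_i, chain_j, resid_j) with any inter-bead distance
// below cutoff under minimum image; chains compared only when different
// [[Rcpp::export]]
IntegerMatrix residue_contacts_cpp(NumericMatrix pos, IntegerVector chain,
                                   IntegerVector resid, double cutoff,
                                   double box) {
  int N = pos.nrow();
  double c2 = cutoff * cutoff;
  std::set<std::array<int, 4>> found;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (chain[i] == chain[j]) continue;
      double d[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = pos(j, k) - pos(i, k);
        d[k] -= box * std::round(d[k] / box);
      }
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < c2) {
        int ci = chain[i], cj = chain[j], ri = resid[i], rj = resid[j];
        if (ci < cj) found.insert({ci, ri, cj, rj});
        else found.insert({cj, rj, ci, ri});
      }
    }
  IntegerMatrix out(found.size(), 4);
  int r = 0;
  for (const auto& f : found) {
    for (int k = 0; k < 4; ++k) out(r, k) = f[k];
    ++r;
  }
  return out;
}
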