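// Particle engine: Brownian diffusion of glutamate in the box-synapse ECS,
// specular reflection off membranes, crossing-based binding to tiled surface
// molecules, and competing-risks continuous-time Markov updates of receptor
// and transporter states (geometric next-event scheduling, exactly equivalent
// to an at-most-one-transition-per-step discretization).
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------- counter-based RNG (splitmix64 -> xoshiro256++) ----------
static inline uint64_t sm_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t seed_stream(uint64_t root, uint64_t a, uint64_t b) {
  uint64_t x = root;
  uint64_t h = sm_next(x);
  x = h ^ (a * 0xD2B74407B1CE6E93ULL);
  h = sm_next(x);
  x = h ^ (b * 0xCA5A826395121157ULL);
  return sm_next(x);
}

struct RNG {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) s[i] = sm_next(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; } // (0,1)
  inline double unif_open() { double u; do { u = unif(); } while (u <= 0.0); return u; }
  inline double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif_open(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
    spare = r * std::sin(th); have_spare = true;
    return r * std::cos(th);
  }
};

// [[Rcpp::export]]
int mix_seed(double root, double a, double b) {
  uint64_t v = seed_stream((uint64_t)root, (uint64_t)a, (uint64_t)b);
  return (int)(v & 0x7FFFFFFFULL);
}

// ---------- geometry ----------
struct Box { double lo[3], hi[3]; };

static Box as_box(NumericVector v) {
  Box b;
  b.lo[0] = v[0]; b.hi[0] = v[1];
  b.lo[1] = v[2]; b.hi[1] = v[3];
  b.lo[2] = v[4]; b.hi[2] = v[5];
  return b;
}

static inline bool inside(const Box &b, const double *p) {
  return p[0] > b.lo[0] && p[0] < b.hi[0] &&
         p[1] > b.lo[1] && p[1] < b.hi[1] &&
         p[2] > b.lo[2] && p[2] < b.hi[2];
}

struct Rect {
  int axis;        // constant axis (0,1,2)
  double pos;      // plane coordinate
  int ua, va;      // in-plane axes
  double u0, v0, du, dv;
  int nu, nv;
  int pop;         // population index, -1 = bare reflective (unused)
  int mol0;        // unused (tile_mol holds global ids)
  const int *tile_mol; // nu*nv tile -> molecule index within pop, or -1
  double p_scale;  // sqrt(pi dt / D) / A_tile (one-sided wall)
  double inward;   // sign of ECS-side normal
};

struct Pop {
  int n_states, initial, open; // 0-based, open = -1 if none
  std::vector<int> lig;
  // unimolecular transitions grouped by from-state
  std::vector<int> u_start;               // n_states+1 offsets
  std::vector<int> u_to;
  std::vector<double> u_rate;             // per microsecond
  std::vector<int> u_rel, u_rem;
  std::vector<double> ktot;               // per state
  // binding transitions grouped by from-state
  std::vector<int> b_start;
  std::vector<int> b_to;
  std::vector<double> b_kon;              // nm^3 / microsecond
  // molecules
  int n_mol = 0;
  std::vector<double> mx, my, mz;         // positions (already nudged into ECS)
  std::vector<int> state;
  std::vector<int> epoch;
};

struct Event { int pop, mol, epoch; };

struct World {
  Box peri, pre, post;
  std::vector<Rect> rects;
  std::vector<Pop> pops;
  double dt = 1.0;
  int bounce_limit = 64;
};

static const double EPS_NUDGE = 1e-6;

// first boundary hit of segment p -> p + d; returns t in [0,1] or >1
// axis/plane/inward describe the hit face
static bool first_hit(const World &w, const double *p, const double *d,
                      double &thit, int &axis, double &plane, double &inward) {
  thit = 2.0; axis = -1;
  // peri exit
  for (int a = 0; a < 3; a++) {
    if (d[a] > 0) {
      double t = (w.peri.hi[a] - p[a]) / d[a];
      if (t < thit) { thit = t; axis = a; plane = w.peri.hi[a]; inward = -1.0; }
    } else if (d[a] < 0) {
      double t = (w.peri.lo[a] - p[a]) / d[a];
      if (t < thit) { thit = t; axis = a; plane = w.peri.lo[a]; inward = 1.0; }
    }
  }
  // element entries
  const Box *els[2] = { &w.pre, &w.post };
  for (int e = 0; e < 2; e++) {
    const Box &b = *els[e];
    double tmin = 0.0, tmax = 1e300;
    int amin = -1; double pl = 0, inw = 0;
    bool ok = true;
    for (int a = 0; a < 3; a++) {
      if (d[a] == 0.0) {
        if (p[a] <= b.lo[a] || p[a] >= b.hi[a]) { ok = false; break; }
      } else {
        double t0 = (b.lo[a] - p[a]) / d[a];
        double t1 = (b.hi[a] - p[a]) / d[a];
        double face = b.lo[a], other = b.hi[a];
        if (t0 > t1) { std::swap(t0, t1); std::swap(face, other); }
        if (t0 > tmin) { tmin = t0; amin = a; pl = face; inw = (d[a] > 0 ? -1.0 : 1.0); }
        if (t1 < tmax) tmax = t1;
        if (tmin >= tmax) { ok = false; break; }
      }
    }
    if (ok && amin >= 0 && tmin > 0.0 && tmin < thit && tmin <= 1.0) {
      thit = tmin; axis = amin; plane = pl; inward = inw;
    }
  }
  return thit <= 1.0;
}

static inline const Rect *find_rect(const World &w, int axis, double plane,
                                    const double *h, int &iu, int &iv) {
  for (size_t r = 0; r < w.rects.size(); r++) {
    const Rect &rc = w.rects[r];
    if (rc.axis != axis || std::fabs(rc.pos - plane) > 1e-6) continue;
    double u = h[rc.ua], v = h[rc.va];
    if (u < rc.u0 || v < rc.v0) continue;
    double fu = (u - rc.u0) / rc.du, fv = (v - rc.v0) / rc.dv;
    if (fu >= rc.nu || fv >= rc.nv) continue;
    iu = (int)fu; if (iu >= rc.nu) iu = rc.nu - 1;
    iv = (int)fv; if (iv >= rc.nv) iv = rc.nv - 1;
    return &rc;
  }
  return nullptr;
}

// ---------- engine state ----------
struct Engine {
  World w;
  RNG rng;
  int n_steps;
  std::vector<std::vector<Event>> bucket;
  std::vector<double> fx, fy, fz; // free glutamate
  long bound_lig = 0, removed = 0, n_open = 0;
  long n_bind_events = 0, discarded = 0;
  int open_pop = -1;

  Engine(uint64_t seed) : rng(seed) {}

  void schedule(int pi, int mi, int base_step) {
    Pop &p = w.pops[pi];
    double kt = p.ktot[p.state[mi]];
    if (kt <= 0.0) return;
    double pstep = -std::expm1(-kt * w.dt);
    double u = rng.unif_open();
    double n = std::ceil(std::log(u) / std::log1p(-pstep));
    if (!(n >= 1.0)) n = 1.0;
    if (n > (double)(n_steps - base_step)) return;
    int at = base_step + (int)n;
    bucket[at].push_back(Event{pi, mi, p.epoch[mi]});
  }

  void apply_state_change(Pop &p, int pi, int mi, int to, int t) {
    int s = p.state[mi];
    if (p.open >= 0) {
      if (s == p.open) n_open--;
      if (to == p.open) n_open++;
    }
    p.state[mi] = to;
    p.epoch[mi]++;
    schedule(pi, mi, t);
  }

  void fire(int pi, int mi, int t) {
    Pop &p = w.pops[pi];
    int s = p.state[mi];
    int a = p.u_start[s], b = p.u_start[s + 1];
    if (a == b) return;
    double r = rng.unif() * p.ktot[s];
    int j = a;
    double acc = 0.0;
    for (; j < b - 1; j++) { acc += p.u_rate[j]; if (r < acc) break; }
    if (p.u_rel[j]) { // re-emit glutamate at the molecule position
      fx.push_back(p.mx[mi]); fy.push_back(p.my[mi]); fz.push_back(p.mz[mi]);
      bound_lig--;
    } else if (p.u_rem[j]) {
      removed++; bound_lig--;
    }
    apply_state_change(p, pi, mi, p.u_to[j], t);
  }

  // returns true if the particle was absorbed by binding
  bool move(double &x, double &y, double &z, int t) {
    double p[3] = { x, y, z };
    double d[3] = { 0, 0, 0 };
    double sigma = sigma_step;
    d[0] = sigma * rng.normal();
    d[1] = sigma * rng.normal();
    d[2] = sigma * rng.normal();
    double orig[3] = { x, y, z };
    for (int bounce = 0; bounce < w.bounce_limit; bounce++) {
      double thit, plane, inward; int axis;
      if (!first_hit(w, p, d, thit, axis, plane, inward)) {
        p[0] += d[0]; p[1] += d[1]; p[2] += d[2];
        if (inside(w.peri, p) && !inside(w.pre, p) && !inside(w.post, p)) {
          x = p[0]; y = p[1]; z = p[2];
        } else discarded++; // numerical corner case: keep previous position
        return false;
      }
      double h[3] = { p[0] + thit * d[0], p[1] + thit * d[1], p[2] + thit * d[2] };
      h[axis] = plane;
      int iu, iv;
      const Rect *rc = find_rect(w, axis, plane, h, iu, iv);
      if (rc) {
        int mi = rc->tile_mol[(size_t)iv * rc->nu + iu];
        if (mi >= 0) {
          Pop &pp = w.pops[rc->pop];
          int s = pp.state[mi];
          int ba = pp.b_start[s], bb = pp.b_start[s + 1];
          if (bb > ba) {
            double ktot_b = 0.0;
            for (int j = ba; j < bb; j++) ktot_b += pp.b_kon[j];
            double ptot = ktot_b * rc->p_scale;
            if (ptot > 1.0) ptot = 1.0;
            double u = rng.unif();
            if (u < ptot) {
              double r = u / rc->p_scale; // in kon units
              int j = ba; double acc = 0.0;
              for (; j < bb - 1; j++) { acc += pp.b_kon[j]; if (r < acc) break; }
              bound_lig++;
              n_bind_events++;
              apply_state_change(pp, rc->pop, mi, pp.b_to[j], t);
              return true;
            }
          }
        }
      }
      // specular reflection of the remaining displacement
      for (int a = 0; a < 3; a++) d[a] *= (1.0 - thit);
      d[axis] = -d[axis];
      p[0] = h[0]; p[1] = h[1]; p[2] = h[2];
      p[axis] = plane + EPS_NUDGE * inward;
    }
    // bounce limit exceeded: discard the step
    x = orig[0]; y = orig[1]; z = orig[2];
    discarded++;
    return false;
  }

  double sigma_step = 0.0;
};

static void build_pop(Pop &pp, List pop) {
  pp.n_states = as<int>(pop["n_states"]);
  pp.initial = as<int>(pop["initial"]);
  pp.open = as<int>(pop["open"]);
  pp.lig = as<std::vector<int>>(pop["lig"]);
  IntegerVector uf = pop["uni_from"], ut = pop["uni_to"],
                url = pop["uni_releases"], urm = pop["uni_removes"];
  NumericVector ur = pop["uni_rate"];
  pp.u_start.assign(pp.n_states + 1, 0);
  // counting sort by from-state (stable)
  for (int i = 0; i < uf.size(); i++) pp.u_start[uf[i] + 1]++;
  for (int s = 0; s < pp.n_states; s++) pp.u_start[s + 1] += pp.u_start[s];
  pp.u_to.resize(uf.size()); pp.u_rate.resize(uf.size());
  pp.u_rel.resize(uf.size()); pp.u_rem.resize(uf.size());
  std::vector<int> cur(pp.u_start.begin(), pp.u_start.end() - 1);
  for (int i = 0; i < uf.size(); i++) {
    int k = cur[uf[i]]++;
    pp.u_to[k] = ut[i]; pp.u_rate[k] = ur[i];
    pp.u_rel[k] = url[i]; pp.u_rem[k] = urm[i];
  }
  pp.ktot.assign(pp.n_states, 0.0);
  for (int s = 0; s < pp.n_states; s++)
    for (int j = pp.u_start[s]; j < pp.u_start[s + 1]; j++)
      pp.ktot[s] += pp.u_rate[j];
  IntegerVector bf = pop["bind_from"], bt = pop["bind_to"];
  NumericVector bk = pop["bind_kon"];
  pp.b_start.assign(pp.n_states + 1, 0);
  for (int i = 0; i < bf.size(); i++) pp.b_start[bf[i] + 1]++;
  for (int s = 0; s < pp.n_states; s++) pp.b_start[s + 1] += pp.b_start[s];
  pp.b_to.resize(bf.size()); pp.b_kon.resize(bf.size());
  std::vector<int> curb(pp.b_start.begin(), pp.b_start.end() - 1);
  for (int i = 0; i < bf.size(); i++) {
    int k = curb[bf[i]]++;
    pp.b_to[k] = bt[i]; pp.b_kon[k] = bk[i];
  }
  NumericMatrix mp = pop["mol_pos"];
  pp.n_mol = mp.nrow();
  pp.mx.resize(pp.n_mol); pp.my.resize(pp.n_mol); pp.mz.resize(pp.n_mol);
  for (int i = 0; i < pp.n_mol; i++) {
    pp.mx[i] = mp(i, 0); pp.my[i] = mp(i, 1); pp.mz[i] = mp(i, 2);
  }
  pp.state.assign(pp.n_mol, pp.initial);
  pp.epoch.assign(pp.n_mol, 0);
}

// [[Rcpp::export]]
List cpp_run_engine(List geom, List pops, List params) {
  World w;
  w.peri = as_box(geom["peri"]);
  w.pre = as_box(geom["pre"]);
  w.post = as_box(geom["post"]);
  w.dt = as<double>(params["dt"]);
  w.bounce_limit = as<int>(params["bounce_limit"]);

  int n_pop = pops.size();
  w.pops.resize(n_pop);
  std::vector<IntegerVector> tile_keep; // keep R vectors alive
  for (int pi = 0; pi < n_pop; pi++) {
    List pop = pops[pi];
    build_pop(w.pops[pi], pop);
    List rl = pop["rects"];
    for (int r = 0; r < rl.size(); r++) {
      List rr = rl[r];
      Rect rc;
      rc.axis = as<int>(rr["axis"]); rc.pos = as<double>(rr["pos"]);
      int axes[2];
      switch (rc.axis) {
        case 0: axes[0] = 1; axes[1] = 2; break;
        case 1: axes[0] = 0; axes[1] = 2; break;
        default: axes[0] = 0; axes[1] = 1; break;
      }
      rc.ua = axes[0]; rc.va = axes[1];
      rc.u0 = as<double>(rr["u0"]); rc.v0 = as<double>(rr["v0"]);
      rc.du = as<double>(rr["du"]); rc.dv = as<double>(rr["dv"]);
      rc.nu = as<int>(rr["nu"]); rc.nv = as<int>(rr["nv"]);
      rc.pop = pi;
      IntegerVector tm = rr["tile_mol"];
      tile_keep.push_back(tm);
      rc.tile_mol = INTEGER(tile_keep.back());
      rc.p_scale = as<double>(rr["p_scale"]);
      rc.inward = as<double>(rr["inward"]);
      w.rects.push_back(rc);
    }
  }

  int n_steps = as<int>(params["n_steps"]);
  int n_g = as<int>(params["n_g"]);
  NumericVector rel = params["release"];
  double sigma = as<double>(params["sigma"]);
  bool check_cons = as<bool>(params["check_conservation"]);
  IntegerVector record_steps = params["record_steps"]; // sorted, 1-based
  int record_pop = as<int>(params["record_pop"]);

  uint64_t seed = seed_stream((uint64_t)as<double>(params["root_seed"]),
                              (uint64_t)as<double>(params["config_id"]),
                              (uint64_t)as<double>(params["run_index"]));
  Engine eng(seed);
  eng.w = w;
  eng.n_steps = n_steps;
  eng.sigma_step = sigma;
  eng.bucket.resize(n_steps + 1);
  eng.fx.reserve(n_g); eng.fy.reserve(n_g); eng.fz.reserve(n_g);
  for (int i = 0; i < n_g; i++) {
    eng.fx.push_back(rel[0]); eng.fy.push_back(rel[1]); eng.fz.push_back(rel[2]);
  }
  // find the population whose open state is recorded
  for (int pi = 0; pi < n_pop; pi++)
    if (eng.w.pops[pi].open >= 0) { eng.open_pop = pi; break; }

  // account for molecules whose initial state is already open, and schedule
  // unimolecular exits from initial states that have outgoing rates
  for (int pi = 0; pi < n_pop; pi++) {
    Pop &pp = eng.w.pops[pi];
    for (int m = 0; m < pp.n_mol; m++) {
      if (pp.open >= 0 && pp.state[m] == pp.open) eng.n_open++;
      eng.schedule(pi, m, 0);
    }
  }

  IntegerVector open_counts(n_steps + 1);
  open_counts[0] = (int)eng.n_open;
  IntegerMatrix snapshots(record_steps.size(),
                          record_pop >= 0 ? eng.w.pops[record_pop].n_mol : 0);
  int rec_i = 0;
  bool cons_ok = true;
  int ended_at = n_steps;

  for (int t = 1; t <= n_steps; t++) {
    // 1. diffuse free glutamate, resolving reflections and binding
    for (size_t i = 0; i < eng.fx.size();) {
      if (eng.move(eng.fx[i], eng.fy[i], eng.fz[i], t)) {
        eng.fx[i] = eng.fx.back(); eng.fx.pop_back();
        eng.fy[i] = eng.fy.back(); eng.fy.pop_back();
        eng.fz[i] = eng.fz.back(); eng.fz.pop_back();
      } else i++;
    }
    // 2. unimolecular events scheduled for this step
    for (size_t e = 0; e < eng.bucket[t].size(); e++) {
      const Event &ev = eng.bucket[t][e];
      if (eng.w.pops[ev.pop].epoch[ev.mol] != ev.epoch) continue; // stale
      eng.fire(ev.pop, ev.mol, t);
    }
    eng.bucket[t].clear();
    // 3. record
    open_counts[t] = (int)eng.n_open;
    if (rec_i < record_steps.size() && record_steps[rec_i] == t) {
      if (record_pop >= 0) {
        Pop &pp = eng.w.pops[record_pop];
        for (int m = 0; m < pp.n_mol; m++)
          snapshots(rec_i, m) = (pp.state[m] == pp.open) ? 1 : 0;
      }
      rec_i++;
    }
    if (check_cons && (t % 1000 == 0 || t == n_steps)) {
      long bl = 0;
      for (int pi = 0; pi < n_pop; pi++) {
        Pop &pp = eng.w.pops[pi];
        for (int m = 0; m < pp.n_mol; m++) bl += pp.lig[pp.state[m]];
      }
      if (bl != eng.bound_lig ||
          (long)eng.fx.size() + bl + eng.removed != (long)n_g)
        cons_ok = false;
    }
    // early termination: all glutamate transported, nothing can open again
    if (eng.fx.size() == 0 && eng.bound_lig == 0 && eng.n_open == 0 &&
        rec_i >= record_steps.size()) {
      ended_at = t;
      break; // remaining open_counts entries stay 0
    }
  }

  long bl = 0;
  for (int pi = 0; pi < n_pop; pi++) {
    Pop &pp = eng.w.pops[pi];
    for (int m = 0; m < pp.n_mol; m++) bl += pp.lig[pp.state[m]];
  }
  if ((long)eng.fx.size() + bl + eng.removed != (long)n_g) cons_ok = false;

  return List::create(
    _["open_counts"] = open_counts,
    _["removed"] = (double)eng.removed,
    _["free_end"] = (double)eng.fx.size(),
    _["bound_end"] = (double)bl,
    _["discarded_steps"] = (double)eng.discarded,
    _["n_bind_events"] = (double)eng.n_bind_events,
    _["conservation_ok"] = cons_ok,
    _["ended_at"] = ended_at,
    _["snapshots"] = snapshots
  );
}

// reflection of a single segment, with crossing log (no binding) -- test hook
// [[Rcpp::export]]
List cpp_reflect_segment(List geom, NumericVector start, NumericVector disp,
                         int bounce_limit = 64) {
  World w;
  w.peri = as_box(geom["peri"]);
  w.pre = as_box(geom["pre"]);
  w.post = as_box(geom["post"]);
  double p[3] = { start[0], start[1], start[2] };
  double d[3] = { disp[0], disp[1], disp[2] };
  std::vector<double> log;
  bool discarded = true;
  for (int bounce = 0; bounce < bounce_limit; bounce++) {
    double thit, plane, inward; int axis;
    if (!first_hit(w, p, d, thit, axis, plane, inward)) {
      p[0] += d[0]; p[1] += d[1]; p[2] += d[2];
      discarded = false;
      break;
    }
    double h[3] = { p[0] + thit * d[0], p[1] + thit * d[1], p[2] + thit * d[2] };
    h[axis] = plane;
    log.push_back(axis); log.push_back(plane);
    log.push_back(h[0]); log.push_back(h[1]); log.push_back(h[2]);
    for (int a = 0; a < 3; a++) d[a] *= (1.0 - thit);
    d[axis] = -d[axis];
    p[0] = h[0]; p[1] = h[1]; p[2] = h[2];
    p[axis] = plane + EPS_NUDGE * inward;
  }
  int nh = log.size() / 5;
  NumericMatrix hits(nh, 5);
  for (int i = 0; i < nh; i++)
    for (int j = 0; j < 5; j++) hits(i, j) = log[5 * i + j];
  colnames(hits) = CharacterVector::create("axis", "plane", "x", "y", "z");
  return List::create(_["end"] = NumericVector::create(p[0], p[1], p[2]),
                      _["hits"] = hits,
                      _["discarded"] = discarded);
}

// non-reacting tracer in the synapse ECS: final positions after n_steps
// [[Rcpp::export]]
NumericMatrix cpp_tracer(List geom, int n, int n_steps, double sigma,
                         NumericVector start, double seed,
                         int bounce_limit = 64) {
  World w;
  w.peri = as_box(geom["peri"]);
  w.pre = as_box(geom["pre"]);
  w.post = as_box(geom["post"]);
  w.bounce_limit = bounce_limit;
  Engine eng(seed_stream((uint64_t)seed, 7, 7));
  eng.w = w;
  eng.sigma_step = sigma;
  eng.n_steps = n_steps;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double x = start[0], y = start[1], z = start[2];
    for (int t = 0; t < n_steps; t++) eng.move(x, y, z, t);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// free diffusion (no boundaries): squared displacement of n particles
// [[Rcpp::export]]
NumericVector cpp_free_sqdisp(int n, int n_steps, double sigma, double seed) {
  RNG rng(seed_stream((uint64_t)seed, 11, 13));
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double x = 0, y = 0, z = 0;
    for (int t = 0; t < n_steps; t++) {
      x += sigma * rng.normal();
      y += sigma * rng.normal();
      z += sigma * rng.normal();
    }
    out[i] = x * x + y * y + z * z;
  }
  return out;
}

// well-mixed calibration box: A particles diffusing in [0,L]^3, bottom face
// z=0 tiled nu x nv with B molecules; crossing captures A with prob p_bind
// and consumes the B tile (A + B -> C). Returns remaining-A count per step.
// [[Rcpp::export]]
IntegerVector cpp_calibration_box(double L, int n_a, int nu, int nv,
                                  double p_bind, double sigma, int n_steps,
                                  double seed) {
  RNG rng(seed_stream((uint64_t)seed, 3, 5));
  std::vector<double> x(n_a), y(n_a), z(n_a);
  for (int i = 0; i < n_a; i++) {
    x[i] = L * rng.unif(); y[i] = L * rng.unif(); z[i] = L * rng.unif();
  }
  std::vector<char> occ((size_t)nu * nv, 1);
  IntegerVector remaining(n_steps);
  int alive = n_a;
  std::vector<char> dead(n_a, 0);
  for (int t = 0; t < n_steps; t++) {
    for (int i = 0; i < n_a; i++) {
      if (dead[i]) continue;
      double nx = x[i] + sigma * rng.normal();
      double ny = y[i] + sigma * rng.normal();
      double nz = z[i] + sigma * rng.normal();
      if (nz < 0) { // crossed the reactive face
        double tt = z[i] / (z[i] - nz);
        double cx = x[i] + tt * (nx - x[i]);
        double cy = y[i] + tt * (ny - y[i]);
        // fold crossing point into the box
        cx = std::fabs(cx); if (cx > L) cx = 2 * L - cx;
        cy = std::fabs(cy); if (cy > L) cy = 2 * L - cy;
        int iu = (int)(cx / L * nu); if (iu >= nu) iu = nu - 1; if (iu < 0) iu = 0;
        int iv = (int)(cy / L * nv); if (iv >= nv) iv = nv - 1; if (iv < 0) iv = 0;
        size_t tile = (size_t)iv * nu + iu;
        if (occ[tile] && rng.unif() < p_bind) {
          occ[tile] = 0; dead[i] = 1; alive--;
          continue;
        }
        nz = -nz;
      }
      if (nz > L) nz = 2 * L - nz;
      nx = std::fabs(nx); if (nx > L) nx = 2 * L - nx;
      ny = std::fabs(ny); if (ny > L) ny = 2 * L - ny;
      if (nz < 0) nz = -nz; if (nz > L) nz = 2 * L - nz;
      x[i] = nx; y[i] = ny; z[i] = nz;
    }
    remaining[t] = alive;
  }
  return remaining;
}
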