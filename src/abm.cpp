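// On-lattice agent-based engine for CSC/CC tumor growth with phenotypic
// plasticity. Cells occupy single sites of a dynamically expanding 2D grid
// (10 um spacing); updates are hourly with a random permutation of the cells
// present at the start of each step.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// xoshiro256++ with splitmix64 seeding: one stream per (seed, stream) pair so
// replicate i of a cohort run is reproducible independently of the others.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  inline int below(int n) { return (int)(unif() * n); }
};

struct Par {
  double alpha, ps, pd, pdd, pp, pm;
};

static Par par_from_list(const List &p) {
  Par q;
  q.alpha = as<double>(p["alpha"]);
  q.ps    = as<double>(p["p_s"]);
  q.pd    = as<double>(p["p_d"]);
  q.pdd   = as<double>(p["p_dd"]);
  q.pp    = as<double>(p["p_p"]);
  q.pm    = as<double>(p["p_m"]);
  return q;
}

// ---------------------------------------------------------------------------
// Division kernel. One plasticity draw (u1) per division, then the division
// executes under the (possibly new) phenotype's rules; u2 is the symmetric-
// division draw used under STEM rules. Shared between the spatial engine and
// the vacancy-free theory harness, and exposed to R for unit tests.
// event bits: 1 = symmetric CSC division, 2 = differentiation,
//             4 = dedifferentiation.
struct DivRes {
  int par_stem, par_rho, dau_stem, dau_rho;
  bool parent_died;
  int event;
};

static inline DivRes divide_core(int stem, int rho, const Par &P,
                                 double u1, double u2) {
  DivRes r; r.parent_died = false; r.event = 0;
  r.dau_stem = -1; r.dau_rho = -1;
  if (stem) {
    if (u1 < P.pd) {               // differentiation: CSC -> CC, CC-rule division
      r.event |= 2;
      if (rho <= 0) {              // exhausted capacity at this mitotic attempt
        r.parent_died = true; r.par_stem = 0; r.par_rho = rho;
        return r;
      }
      r.par_stem = 0; r.par_rho = rho - 1;
      r.dau_stem = 0; r.dau_rho = rho - 1;
    } else if (u2 < P.ps) {        // symmetric: no telomere erosion
      r.event |= 1;
      r.par_stem = 1; r.par_rho = rho;
      r.dau_stem = 1; r.dau_rho = rho;
    } else {                       // asymmetric: CC daughter inherits rho uneroded
      r.par_stem = 1; r.par_rho = rho;
      r.dau_stem = 0; r.dau_rho = rho;
    }
  } else {
    if (u1 < P.pdd) {              // dedifferentiation: CC -> CSC with current rho
      r.event |= 4;
      if (u2 < P.ps) {
        r.event |= 1;
        r.par_stem = 1; r.par_rho = rho;
        r.dau_stem = 1; r.dau_rho = rho;
      } else {
        r.par_stem = 1; r.par_rho = rho;
        r.dau_stem = 0; r.dau_rho = rho;
      }
    } else {                       // plain CC division: both cells erode
      r.par_stem = 0; r.par_rho = rho - 1;
      r.dau_stem = 0; r.dau_rho = rho - 1;
    }
  }
  return r;
}

// [[Rcpp::export(name = ".cpp_divide_kernel")]]
List cpp_divide_kernel(int stem, int rho, List par, double u1, double u2) {
  Par P = par_from_list(par);
  DivRes r = divide_core(stem, rho, P, u1, u2);
  return List::create(_["parent_stem"] = r.par_stem,
                      _["parent_rho"] = r.par_rho,
                      _["daughter_stem"] = r.dau_stem,
                      _["daughter_rho"] = r.dau_rho,
                      _["parent_died"] = r.parent_died,
                      _["event"] = r.event);
}

// ---------------------------------------------------------------------------
// Engine

static const int NBX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int NBY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// Statuses returned by run()
enum Status { RUN_MAXHOURS = 0, RUN_EXTINCT = 1, RUN_TARGET = 2,
              RUN_EVENT = 3, RUN_INVADED = 4 };

class Engine {
public:
  int W, H;              // grid dims
  long ox, oy;           // world coord of grid (0,0)
  std::vector<int32_t> occ;       // cell index or -1
  std::vector<uint8_t> allow;     // admissibility mask (bounded mode)
  std::vector<uint8_t> term;      // terminal-zone mask (invasion mode)
  bool bounded = false, has_term = false;

  std::vector<int32_t> cx, cy, crho;
  std::vector<uint8_t> cstem, calive;
  int n_alive = 0, n_stem = 0;
  long time_h = 0;
  Xoshiro rng;
  Par P;

  // counters
  long long n_deaths_alpha = 0, n_deaths_exhaust = 0, n_migrations = 0,
            n_div_sym = 0, n_div_asym = 0, n_div_diff = 0, n_div_dediff = 0,
            n_div_total = 0;
  bool ev_sym = false, ev_dediff = false, ev_diff = false, invaded = false;

  static const int MARGIN = 10, PAD = 50;

  Engine(uint64_t seed, uint64_t stream, const Par &par)
    : rng(seed, stream), P(par) {}

  inline int idx(int gx, int gy) const { return gy * W + gx; }

  void init_unbounded(const IntegerVector &x, const IntegerVector &y) {
    long xmin = 0, xmax = 0, ymin = 0, ymax = 0;
    if (x.size() > 0) {
      xmin = xmax = x[0]; ymin = ymax = y[0];
      for (int i = 0; i < x.size(); ++i) {
        if (x[i] < xmin) xmin = x[i];
        if (x[i] > xmax) xmax = x[i];
        if (y[i] < ymin) ymin = y[i];
        if (y[i] > ymax) ymax = y[i];
      }
    }
    ox = xmin - PAD - MARGIN; oy = ymin - PAD - MARGIN;
    W = (int)(xmax - xmin) + 2 * (PAD + MARGIN) + 1;
    H = (int)(ymax - ymin) + 2 * (PAD + MARGIN) + 1;
    occ.assign((size_t)W * H, -1);
  }

  void init_bounded(const LogicalMatrix &allow_m,
                    Nullable<LogicalMatrix> term_m) {
    bounded = true;
    H = allow_m.nrow(); W = allow_m.ncol();
    ox = 1; oy = 1;  // world coords are 1-based matrix (col = x, row = y)
    occ.assign((size_t)W * H, -1);
    allow.assign((size_t)W * H, 0);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        allow[idx(c, r)] = allow_m(r, c) ? 1 : 0;
    if (term_m.isNotNull()) {
      has_term = true;
      LogicalMatrix tm(term_m);
      term.assign((size_t)W * H, 0);
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c)
          term[idx(c, r)] = tm(r, c) ? 1 : 0;
    }
  }

  void add_cells(const IntegerVector &x, const IntegerVector &y,
                 const IntegerVector &stem, const IntegerVector &rho) {
    for (int i = 0; i < x.size(); ++i) {
      int gx = (int)(x[i] - ox), gy = (int)(y[i] - oy);
      if (gx < 0 || gy < 0 || gx >= W || gy >= H)
        stop("initial cell outside lattice bounds");
      int k = idx(gx, gy);
      if (occ[k] != -1) stop("two initial cells on one lattice site");
      if (bounded && !allow[k]) stop("initial cell on non-admissible site");
      cx.push_back(gx); cy.push_back(gy);
      cstem.push_back(stem[i] ? 1 : 0);
      crho.push_back(rho[i]);
      calive.push_back(1);
      occ[k] = (int)cx.size() - 1;
      ++n_alive; if (stem[i]) ++n_stem;
    }
  }

  // expand all sides by PAD when any live cell sits within MARGIN of an edge
  void maybe_expand() {
    if (bounded) return;
    bool need = false;
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!calive[i]) continue;
      if (cx[i] < MARGIN || cy[i] < MARGIN ||
          cx[i] >= W - MARGIN || cy[i] >= H - MARGIN) { need = true; break; }
    }
    if (!need) return;
    int W2 = W + 2 * PAD, H2 = H + 2 * PAD;
    std::vector<int32_t> occ2((size_t)W2 * H2, -1);
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!calive[i]) continue;
      cx[i] += PAD; cy[i] += PAD;
      occ2[(size_t)cy[i] * W2 + cx[i]] = (int)i;
    }
    occ.swap(occ2); W = W2; H = H2; ox -= PAD; oy -= PAD;
  }

  void compact() {
    if (cx.size() - (size_t)n_alive < (size_t)n_alive + 64) return;
    std::vector<int32_t> nx, ny, nr; std::vector<uint8_t> ns;
    nx.reserve(n_alive); ny.reserve(n_alive);
    nr.reserve(n_alive); ns.reserve(n_alive);
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!calive[i]) continue;
      occ[idx(cx[i], cy[i])] = (int)nx.size();
      nx.push_back(cx[i]); ny.push_back(cy[i]);
      nr.push_back(crho[i]); ns.push_back(cstem[i]);
    }
    cx.swap(nx); cy.swap(ny); crho.swap(nr); cstem.swap(ns);
    calive.assign(cx.size(), 1);
  }

  inline void kill(int i) {
    occ[idx(cx[i], cy[i])] = -1;
    calive[i] = 0; --n_alive;
    if (cstem[i]) --n_stem;
  }

  // pick a uniformly random vacant (and admissible) Moore neighbor; -1 if none
  inline int pick_vacant(int i) {
    int cand[8], k = 0;
    int x0 = cx[i], y0 = cy[i];
    for (int d = 0; d < 8; ++d) {
      int x = x0 + NBX[d], y = y0 + NBY[d];
      if (x < 0 || y < 0 || x >= W || y >= H) continue;
      int j = idx(x, y);
      if (occ[j] != -1) continue;
      if (bounded && !allow[j]) continue;
      cand[k++] = j;
    }
    if (k == 0) return -1;
    return cand[k == 1 ? 0 : rng.below(k)];
  }

  inline void check_invasion(int site, int stem_flag) {
    if (has_term && stem_flag && term[site]) invaded = true;
  }

  void do_divide(int i, int site) {
    double u1 = rng.unif(), u2 = rng.unif();
    DivRes r = divide_core(cstem[i], crho[i], P, u1, u2);
    if (r.event & 1) { ev_sym = true; ++n_div_sym; }
    if (r.event & 2) { ev_diff = true; ++n_div_diff; }
    if (r.event & 4) { ev_dediff = true; ++n_div_dediff; }
    if ((r.event & 7) == 0) ++n_div_asym;  // plain division (CC or asym CSC)
    if (r.parent_died) { kill(i); ++n_deaths_exhaust; return; }
    ++n_div_total;                         // one daughter spawned per division
    if (cstem[i] != r.par_stem) {
      n_stem += r.par_stem ? 1 : -1;
      cstem[i] = (uint8_t)r.par_stem;
      check_invasion(idx(cx[i], cy[i]), r.par_stem);
    }
    crho[i] = r.par_rho;
    // daughter
    cx.push_back(site % W); cy.push_back(site / W);
    cstem.push_back((uint8_t)r.dau_stem);
    crho.push_back(r.dau_rho);
    calive.push_back(1);
    occ[site] = (int)cx.size() - 1;
    ++n_alive; if (r.dau_stem) ++n_stem;
    check_invasion(site, r.dau_stem);
  }

  // one hourly step over a random permutation of the cells present at start
  void step(std::vector<int> &order) {
    order.clear();
    for (size_t i = 0; i < cx.size(); ++i)
      if (calive[i]) order.push_back((int)i);
    // Fisher-Yates
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      int t = order[i]; order[i] = order[j]; order[j] = t;
    }
    // one uniform drives the sequential death -> proliferation -> migration
    // decision chain (equivalent to independent draws):
    //   CC:  u < alpha die; u < t2 proliferate; u < t3 migrate
    //   CSC: u < pp proliferate; u < t3s migrate
    const double t2c = P.alpha + (1 - P.alpha) * P.pp;
    const double t3c = t2c + (1 - t2c) * P.pm;
    const double t3s = P.pp + (1 - P.pp) * P.pm;
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      if (!calive[i]) continue;
      double u = rng.unif();
      bool is_stem = cstem[i] != 0;
      if (!is_stem && u < P.alpha) {                   // spontaneous CC death
        kill(i); ++n_deaths_alpha; continue;
      }
      if (u < (is_stem ? P.pp : t2c)) {                // proliferation attempt
        if (!is_stem && crho[i] == 0) {                // exhausted capacity
          kill(i); ++n_deaths_exhaust; continue;
        }
        int site = pick_vacant(i);
        if (site >= 0) do_divide(i, site);             // else quiescent
        if (invaded) return;
      } else if (u < (is_stem ? t3s : t3c)) {          // migration
        int site = pick_vacant(i);
        if (site >= 0) {
          occ[idx(cx[i], cy[i])] = -1;
          cx[i] = site % W; cy[i] = site / W;
          occ[site] = i; ++n_migrations;
          check_invasion(site, cstem[i]);
          if (invaded) return;
        }
      }
    }
    ++time_h;
    maybe_expand();
    compact();
  }

  // run until a stop condition; record (t, n, n_stem) every record_every hours
  int run(long max_hours, int record_every, long target_n,
          bool stop_sym, bool stop_dediff,
          std::vector<long> &rec_t, std::vector<long> &rec_n,
          std::vector<long> &rec_s) {
    std::vector<int> order;
    order.reserve(1024);
    long t0 = time_h;
    while (time_h - t0 < max_hours) {
      step(order);
      if (invaded) { ++time_h; return RUN_INVADED; }
      bool rec = (record_every > 0 && (time_h - t0) % record_every == 0);
      if (rec) {
        rec_t.push_back(time_h); rec_n.push_back(n_alive);
        rec_s.push_back(n_stem);
      }
      if (n_alive == 0) return RUN_EXTINCT;
      if (target_n > 0 && n_alive >= target_n) return RUN_TARGET;
      if ((stop_sym && ev_sym) || (stop_dediff && ev_dediff))
        return RUN_EVENT;
    }
    return RUN_MAXHOURS;
  }

  List cells_df() const {
    int n = n_alive, k = 0;
    IntegerVector x(n), y(n), rho(n);
    CharacterVector phen(n);
    for (size_t i = 0; i < cx.size(); ++i) {
      if (!calive[i]) continue;
      x[k] = (int)(cx[i] + ox); y[k] = (int)(cy[i] + oy);
      rho[k] = crho[i];
      phen[k] = cstem[i] ? "S" : "N";
      ++k;
    }
    return List::create(_["x"] = x, _["y"] = y,
                        _["phenotype"] = phen, _["rho"] = rho);
  }
};

// [[Rcpp::export(name = ".cpp_abm_run")]]
List cpp_abm_run(IntegerVector x, IntegerVector y, IntegerVector stem,
                 IntegerVector rho, List par, double start_hour,
                 double max_hours, int record_every, double target_n,
                 bool stop_on_symmetric, bool stop_on_dediff,
                 Nullable<LogicalMatrix> allow_mask,
                 Nullable<LogicalMatrix> terminal_mask,
                 double seed, double stream) {
  Par P = par_from_list(par);
  Engine E((uint64_t)seed, (uint64_t)stream, P);
  if (allow_mask.isNotNull()) {
    E.init_bounded(LogicalMatrix(allow_mask), terminal_mask);
  } else {
    E.init_unbounded(x, y);
  }
  E.add_cells(x, y, stem, rho);
  E.time_h = (long)start_hour;
  std::vector<long> rt, rn, rs;
  int status = E.run((long)max_hours, record_every, (long)target_n,
                     stop_on_symmetric, stop_on_dediff, rt, rn, rs);
  int m = (int)rt.size();
  IntegerVector st(m), sn(m), ss(m);
  for (int i = 0; i < m; ++i) { st[i] = (int)rt[i]; sn[i] = (int)rn[i]; ss[i] = (int)rs[i]; }
  const char *sname[] = {"max_hours", "extinct", "target", "event", "invaded"};
  return List::create(
    _["cells"] = E.cells_df(),
    _["time_h"] = (double)E.time_h,
    _["status"] = std::string(sname[status]),
    _["series_t"] = st, _["series_n"] = sn, _["series_s"] = ss,
    _["events"] = List::create(
      _["any_symmetric"] = E.ev_sym, _["any_dediff"] = E.ev_dediff,
      _["any_diff"] = E.ev_diff),
    _["counters"] = List::create(
      _["deaths_alpha"] = (double)E.n_deaths_alpha,
      _["deaths_exhaustion"] = (double)E.n_deaths_exhaust,
      _["migrations"] = (double)E.n_migrations,
      _["divisions_total"] = (double)E.n_div_total,
      _["divisions_symmetric"] = (double)E.n_div_sym,
      _["divisions_plain"] = (double)E.n_div_asym,
      _["divisions_differentiation"] = (double)E.n_div_diff,
      _["divisions_dedifferentiation"] = (double)E.n_div_dediff));
}

// ---------------------------------------------------------------------------
// Early-death Monte Carlo: fraction of replicates in which the founding CSC
// differentiates before any symmetric division and the whole population dies
// out without any dedifferentiation. Each replicate ends at extinction, first
// symmetric division, or first dedifferentiation; with the latter two as
// stops, extinction is equivalent to the event.
// [[Rcpp::export(name = ".cpp_early_death_mc")]]
List cpp_early_death_mc(List par, int rho0, int n_reps, double max_hours,
                        double seed) {
  Par P = par_from_list(par);
  int n_event = 0, n_sym = 0, n_dediff = 0, n_cap = 0;
  IntegerVector x(1), y(1), st(1), rh(1);
  x[0] = 0; y[0] = 0; st[0] = 1; rh[0] = rho0;
  for (int rep = 0; rep < n_reps; ++rep) {
    Engine E((uint64_t)seed, (uint64_t)rep + 1, P);
    E.init_unbounded(x, y);
    E.add_cells(x, y, st, rh);
    std::vector<long> rt, rn, rs;
    int status = E.run((long)max_hours, 0, 0, true, true, rt, rn, rs);
    if (status == RUN_EXTINCT) ++n_event;
    else if (status == RUN_EVENT) { if (E.ev_sym) ++n_sym; else ++n_dediff; }
    else ++n_cap;
    if ((rep & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_event"] = n_event, _["n_symmetric"] = n_sym,
                      _["n_dedifferentiation"] = n_dediff,
                      _["n_capped"] = n_cap, _["n_reps"] = n_reps);
}

// ---------------------------------------------------------------------------
// Vacancy-free division-outcome harness: per founding-CSC division, the change
// in the number of CSCs of the founder's capacity index, following an
// asymmetric division's CC daughter up to its death or first division. Uses
// the same divide kernel and hourly death-then-proliferation rule as the
// spatial engine, with unlimited vacancy.
// outcomes: 0 = -1 (differentiation), 1 = 0, 2 = +1, 3 = +2
// [[Rcpp::export(name = ".cpp_division_outcomes")]]
IntegerVector cpp_division_outcomes(List par, int n_divisions, double seed) {
  Par P = par_from_list(par);
  Xoshiro rng((uint64_t)seed, 7u);  // fixed stream
  IntegerVector counts(4);
  for (int i = 0; i < n_divisions; ++i) {
    double u1 = rng.unif(), u2 = rng.unif();
    DivRes r = divide_core(1, 1000000, P, u1, u2);  // capacity index immaterial
    if (r.event & 2) { ++counts[0]; continue; }      // CSC lost
    if (r.event & 1) { ++counts[2]; continue; }      // symmetric: +1
    // asymmetric: follow the CC daughter hour by hour
    int out = 1;                                     // default: no new CSC
    for (;;) {
      if (rng.unif() < P.alpha) break;               // died before dividing
      if (rng.unif() < P.pp) {                       // successful division
        double v1 = rng.unif(), v2 = rng.unif();
        DivRes d = divide_core(0, 1000000, P, v1, v2);
        if (d.event & 4) out = (d.event & 1) ? 3 : 2;
        break;
      }
    }
    ++counts[out];
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// ---------------------------------------------------------------------------
// Galton-Watson Monte Carlo for the four-outcome CSC process (offspring
// 0/1/2/3 with probabilities p1..p4). Population-level binomial thinning per
// generation using R's RNG (seed via set.seed() on the R side). A lineage
// that reaches max_gen generations or pop_cap individuals counts as surviving.
// [[Rcpp::export(name = ".cpp_branching_mc")]]
int cpp_branching_mc(double p1, double p2, double p3, double p4,
                     int n_reps, int max_gen, double pop_cap) {
  RNGScope scope;
  int n_extinct = 0;
  for (int rep = 0; rep < n_reps; ++rep) {
    double N = 1;
    int gen = 0;
    while (N > 0 && gen < max_gen && N < pop_cap) {
      double n0 = R::rbinom(N, p1);
      double rem = N - n0;
      double n1 = 0, n2 = 0, n3 = 0;
      if (rem > 0) {
        double q2 = (1 - p1) > 0 ? p2 / (1 - p1) : 0;
        n1 = R::rbinom(rem, q2);
        rem -= n1;
        if (rem > 0) {
          double q3 = (p3 + p4) > 0 ? p3 / (p3 + p4) : 0;
          n2 = R::rbinom(rem, q3);
          n3 = rem - n2;
        }
      }
      N = n1 + 2 * n2 + 3 * n3;
      ++gen;
    }
    if (N <= 0) ++n_extinct;
    if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return n_extinct;
}
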