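// Agent-based germinal center reaction engine.
//
// One compiled core advances all agents (B cells, Tfh, FDC network), the
// antigen ledgers and the antibody ODE system on a shared clock. The R side
// owns configuration, validation and analysis; everything here is driven by
// a flat parameter list and an integer seed, and is bitwise reproducible for
// a given (config, seed) pair.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// Counter-style RNG (splitmix64). One private stream per run so results do
// not depend on R's global RNG state.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
  int poisson(double mean) {
    // Knuth; means used here are << 1
    double L = std::exp(-mean), p = 1.0;
    int k = 0;
    do { k++; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// 26-neighborhood offsets; UP/DN index the 9 offsets with dz = +1 / -1.
struct Offsets {
  int ox[26], oy[26], oz[26];
  int up[9], dn[9];
  Offsets() {
    int k = 0, u = 0, d = 0;
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dz = -1; dz <= 1; dz++) {
          if (!dx && !dy && !dz) continue;
          ox[k] = dx; oy[k] = dy; oz[k] = dz;
          if (dz == 1) up[u++] = k;
          if (dz == -1) dn[d++] = k;
          k++;
        }
  }
};
static const Offsets OFF;

inline double hill_up(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  if (K <= 0.0) return 1.0;
  if (n == 2.0) {
    double x2 = x * x, K2 = K * K;
    return x2 / (x2 + K2);
  }
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (xn + Kn);
}
// 1 - t^2/(t^2 + K^2); K = Inf -> 1 (schedule disabled)
inline double hill_decay2(double t, double K) {
  if (!std::isfinite(K)) return 1.0;
  if (t <= 0.0) return 1.0;
  double t2 = t * t;
  return 1.0 - t2 / (t2 + K * K);
}

enum State { ST_DZ = 0, ST_UNSEL = 1, ST_FDCSEL = 2, ST_SEL = 3, ST_OUT = 4 };

struct Cell {
  int pos;
  int8_t bcr[4];
  uint8_t state;
  uint8_t alive;
  uint8_t window_started;
  uint8_t in_list; // registered in the active-contact list
  double p;          // captured antigen / pMHC density (portions)
  double tsig;       // integrated Tfh signal (hours)
  int divleft;
  int ncyc;          // completed DZ-LZ cycles
  int ndiv_next;     // divisions granted at last selection
  double t_event;    // next division / window end
  double t_lastup;   // last uptake attempt
  double t_contact;  // current contact end (<0: none)
  double t_rebind;   // earliest next Tfh binding (search time after a contact)
  int tfh;           // bound Tfh (-1: none)
  int uid;           // unique id (stable across compaction), used in event logs
  uint8_t dir;       // current walk direction (persistent random walk)
  uint8_t dirbias;   // bias under which dir was drawn (0 none, 1 up, 2 down)
  double aff[4];     // affinity vs each epitope (max 4)
};

struct FDC {
  int soma;
  std::vector<int> sites;          // soma + discretized dendrite sites
  std::vector<double> ag;          // antigen per site per epitope, [site*nep + e]
};

struct EvBuf {
  bool on; bool truncated;
  size_t cap;
  std::vector<double> t, v1, v2;
  std::vector<int> type, id, aux;
  void rec(double tt, int ty, int idd, int ax, double a, double b) {
    if (!on) return;
    if (t.size() >= cap) { truncated = true; return; }
    t.push_back(tt); type.push_back(ty); id.push_back(idd);
    aux.push_back(ax); v1.push_back(a); v2.push_back(b);
  }
};
// event types
enum { EV_INFLUX = 1, EV_DIVISION = 2, EV_UPTAKE = 3, EV_TRANSITION = 4,
       EV_CONTACT_START = 5, EV_CONTACT_END = 6, EV_SELECT = 7, EV_DEATH = 8,
       EV_EXIT = 9, EV_RECYCLE = 10 };

struct Sim {
  // --- geometry
  int L, c, R;
  double spacing;
  std::vector<uint8_t> inside; // 1 if lattice site within sphere
  // motile occupancy, one byte per site
  enum { OC_FREE = 0, OC_CELL = 1, OC_TFH = 2, OC_OUT = 3 };
  std::vector<uint8_t> occ;
  std::vector<int16_t> tfh_at; // Tfh index at site or -1
  std::vector<int32_t> fdc_head; // head of FDC site-ref list or -1
  struct FdcRef { int f, k, next; };
  std::vector<FdcRef> fdc_refs;
  int n_fdc_sites;

  // --- config
  double dt, duration_h, out_every_h;
  int nep;
  int epit[4][4];
  double epifrac[4];
  int shape_lo, shape_hi;
  double gamma2;
  int founder_dmin2, founder_dmax2;
  int n_fdc, n_tfh;
  double antigen_per_fdc, dendrite_um;
  double influx_rate, influx_window_h;
  int founder_div;
  double division_time_h, division_jitter_h;
  double p_move, chemo_bias, turn_prob;
  double mutation_prob, asym_prob;
  double collect_window_h, uptake_interval_h;
  double tfh_window_h, tfh_threshold, contact_h, rebind_delay_h;
  double n_min, n_max, hill_n, K_min, K_max;
  int rounding; // 0 stochastic, 1 nearest
  double J_min, J_max, K_p, T_max0;
  int mech;       // 0 control, 1..7
  int m6_mode;    // 0 antigen, 1 tsig, 2 time
  bool ndiv_on_p; // A1/A2
  bool J_of_p;    // A2/A4
  double portions, N_ab, k_c, fdc_growth, fdc_initial_um, fdc_switch_h;
  double uptake_ref; // pristine per-site antigen load (portions)
  double K_ext_h, k_int_h, k_ext0_h;
  double K_T, K_F, k_diff, K_K;
  int n_bins;
  double k_on, kd_lo, kd_hi, k1, k2_h, volume_l, plasma_halflife_h, R_test;
  int max_cells;

  // --- state
  RNG rng;
  std::vector<Cell> cells;
  std::vector<int> tfh_pos;
  std::vector<FDC> fdcs;
  int dendrite_k_last;
  double phi;                         // surface fraction (cycling, M4)
  std::vector<double> theta;          // masked occupancy [e*n_bins + i]
  std::vector<double> freefrac;       // per-epitope accessible fraction
  std::vector<double> A, kd, koff;    // antibody conc per [e,i]; KD/koff per bin
  std::vector<int> n_p, pending;      // plasma / pending output per [e,i]
  double consumed;
  int n_live, n_dead_slots, next_uid;

  // cumulative counters
  double c_founders, c_divisions, c_div_p, c_asym, c_daughters, c_mutated,
      c_attempts, c_success, c_selections, c_death_collect, c_death_tfh,
      c_recycles, c_out_asym, c_out_diff, c_exits, c_deferred_influx;

  // per-window accumulators
  double w_attempts, w_success, w_sel, w_sum_p, w_sum_tsig, w_rec, w_sum_ndiv,
      w_out_sel;

  EvBuf ev;

  // output rows
  std::vector<double> o_t, o_vol, o_dzz, o_lzz, o_sdz, o_suns, o_sfdc, o_ssel,
      o_sout, o_frlzsel, o_fdcsites, o_fdcperb, o_agtot, o_agfree, o_agmask,
      o_agint, o_cons, o_phi, o_att, o_succ, o_frsucc, o_selw, o_meanp,
      o_meants, o_recw, o_meandiv, o_frrec, o_outw, o_frout, o_abtot, o_nptot,
      o_pend, o_ip;

  Sim(List cfg, int seed) : rng((uint64_t)(uint32_t)seed) { load(cfg); }

  inline int idx(int x, int y, int z) const { return x + L * (y + L * z); }
  inline int zc(int site) const { return site / (L * L); }
  inline bool is_lz(int site) const { return zc(site) > c; }

  void load(List cfg) {
    double radius_um = as<double>(cfg["radius_um"]);
    spacing = as<double>(cfg["spacing_um"]);
    R = (int)std::floor(radius_um / spacing + 1e-9);
    L = 2 * R + 1;
    c = R;
    dt = as<double>(cfg["dt_h"]);
    duration_h = as<double>(cfg["duration_h"]);
    out_every_h = as<double>(cfg["out_every_h"]);

    IntegerMatrix em = as<IntegerMatrix>(cfg["epitopes"]);
    nep = em.nrow();
    if (nep > 4) stop("at most 4 epitopes supported");
    NumericVector ef = as<NumericVector>(cfg["epitope_fractions"]);
    for (int e = 0; e < nep; e++) {
      for (int d = 0; d < 4; d++) epit[e][d] = em(e, d);
      epifrac[e] = ef[e];
    }
    shape_lo = as<int>(cfg["shape_lo"]);
    shape_hi = as<int>(cfg["shape_hi"]);
    double g = as<double>(cfg["gamma"]);
    gamma2 = g * g;
    double dmin = as<double>(cfg["founder_dmin"]), dmax = as<double>(cfg["founder_dmax"]);
    founder_dmin2 = (int)std::round(dmin * dmin);
    founder_dmax2 = (int)std::round(dmax * dmax);

    n_fdc = as<int>(cfg["n_fdc"]);
    n_tfh = as<int>(cfg["n_tfh"]);
    antigen_per_fdc = as<double>(cfg["antigen_per_fdc"]);
    dendrite_um = as<double>(cfg["dendrite_um"]);
    influx_rate = as<double>(cfg["influx_rate"]);
    influx_window_h = as<double>(cfg["influx_window_h"]);
    founder_div = as<int>(cfg["founder_divisions"]);
    division_time_h = as<double>(cfg["division_time_h"]);
    division_jitter_h = as<double>(cfg["division_jitter_h"]);
    double speed = as<double>(cfg["bcell_speed_um_min"]); // um/min
    p_move = std::min(1.0, speed * 60.0 / spacing * dt);
    chemo_bias = as<double>(cfg["chemo_bias"]);
    turn_prob = as<double>(cfg["turn_prob"]);
    mutation_prob = as<double>(cfg["mutation_prob"]);
    asym_prob = as<double>(cfg["asym_prob"]);
    collect_window_h = as<double>(cfg["collect_window_h"]);
    uptake_interval_h = as<double>(cfg["uptake_interval_h"]);
    tfh_window_h = as<double>(cfg["tfh_window_h"]);
    tfh_threshold = as<double>(cfg["tfh_threshold_h"]);
    contact_h = as<double>(cfg["contact_duration_h"]);
    rebind_delay_h = as<double>(cfg["rebind_delay_h"]);

    n_min = as<double>(cfg["n_min"]);
    n_max = as<double>(cfg["n_max"]);
    hill_n = as<double>(cfg["hill_n"]);
    K_min = as<double>(cfg["K_min"]);
    K_max = as<double>(cfg["K_max"]);
    rounding = as<int>(cfg["rounding_mode"]);
    J_min = as<double>(cfg["J_min"]);
    J_max = as<double>(cfg["J_max"]);
    K_p = as<double>(cfg["K_p"]);
    T_max0 = as<double>(cfg["T_max0"]);

    mech = as<int>(cfg["mech_id"]);
    m6_mode = as<int>(cfg["m6_mode"]);
    ndiv_on_p = as<bool>(cfg["ndiv_on_p"]);
    J_of_p = as<bool>(cfg["J_of_p"]);
    portions = as<double>(cfg["portions_per_encounter"]);
    N_ab = as<double>(cfg["ab_feedback_N"]);
    k_c = as<double>(cfg["k_c"]);
    fdc_growth = as<double>(cfg["fdc_growth_rate"]);
    fdc_initial_um = as<double>(cfg["fdc_initial_um"]);
    fdc_switch_h = as<double>(cfg["fdc_switch_h"]);
    K_ext_h = as<double>(cfg["K_ext_h"]);
    k_int_h = as<double>(cfg["k_int_per_min"]) * 60.0;
    k_ext0_h = as<double>(cfg["k_ext0_per_min"]) * 60.0;
    K_T = as<double>(cfg["K_T"]);
    K_F = as<double>(cfg["K_F"]);
    k_diff = as<double>(cfg["k_diff"]);
    K_K = as<double>(cfg["K_K"]);

    n_bins = as<int>(cfg["n_bins"]);
    k_on = as<double>(cfg["k_on"]);
    kd_lo = as<double>(cfg["kd_lo_log10"]);
    kd_hi = as<double>(cfg["kd_hi_log10"]);
    k1 = as<double>(cfg["k1"]);
    k2_h = as<double>(cfg["k2_per_h"]);
    volume_l = as<double>(cfg["volume_l"]);
    plasma_halflife_h = as<double>(cfg["plasma_halflife_h"]);
    R_test = as<double>(cfg["R_test"]);
    max_cells = as<int>(cfg["max_cells"]);

    ev.on = as<bool>(cfg["record_events"]);
    ev.truncated = false;
    ev.cap = (size_t)as<double>(cfg["max_events"]);
  }

  // --- initialization -----------------------------------------------------
  void init() {
    int L3 = L * L * L;
    inside.assign(L3, 0);
    occ.assign(L3, OC_FREE);
    tfh_at.assign(L3, -1);
    fdc_head.assign(L3, -1);
    for (int z = 0; z < L; z++)
      for (int y = 0; y < L; y++)
        for (int x = 0; x < L; x++) {
          int dx = x - c, dy = y - c, dz = z - c;
          if (dx * dx + dy * dy + dz * dz <= R * R) inside[idx(x, y, z)] = 1;
          else occ[idx(x, y, z)] = OC_OUT;
        }

    // Tfh: random LZ sites
    tfh_pos.clear();
    for (int i = 0; i < n_tfh; i++) {
      int s = random_site(true, true);
      tfh_pos.push_back(s);
      occ[s] = OC_TFH;
      tfh_at[s] = (int16_t)i;
    }

    // FDCs: somata at random LZ sites (not on Tfh)
    fdcs.clear();
    double len0 = (mech == 3) ? fdc_initial_um : dendrite_um;
    for (int f = 0; f < n_fdc; f++) {
      FDC fd;
      fd.soma = random_site(true, false);
      fdcs.push_back(fd);
    }
    dendrite_k_last = -1;
    rebuild_fdc_sites(len0, true);

    int karm_full = std::max(0, (int)std::floor(dendrite_um / spacing + 1e-9));
    uptake_ref = antigen_per_fdc / (1.0 + 6.0 * karm_full);
    phi = (mech == 4) ? k_ext0_h / (k_ext0_h + k_int_h) : 1.0;
    theta.assign(nep * n_bins, 0.0);
    freefrac.assign(nep, phi);
    A.assign(nep * n_bins, 0.0);
    n_p.assign(nep * n_bins, 0);
    pending.assign(nep * n_bins, 0);
    kd.assign(n_bins, 0.0);
    koff.assign(n_bins, 0.0);
    for (int i = 0; i < n_bins; i++) {
      double lg = kd_lo + (kd_hi - kd_lo) * (double)i / (double)(n_bins - 1);
      kd[i] = std::pow(10.0, lg);
      koff[i] = k_on * kd[i];
    }
    consumed = 0.0;
    n_live = 0;
    n_dead_slots = 0;
    next_uid = 0;
    c_founders = c_divisions = c_div_p = c_asym = c_daughters = c_mutated =
        c_attempts = c_success = c_selections = c_death_collect = c_death_tfh =
            c_recycles = c_out_asym = c_out_diff = c_exits = c_deferred_influx = 0;
    reset_window();
  }

  void reset_window() {
    w_attempts = w_success = w_sel = w_sum_p = w_sum_tsig = w_rec = w_sum_ndiv =
        w_out_sel = 0;
  }

  int random_site(bool lz_only, bool require_free) {
    for (int tries = 0; tries < 100000; tries++) {
      int x = rng.below(L), y = rng.below(L), z = rng.below(L);
      int s = idx(x, y, z);
      if (!inside[s]) continue;
      if (lz_only && !is_lz(s)) continue;
      if (require_free && occ[s] != OC_FREE) continue;
      return s;
    }
    stop("could not place agent: lattice too crowded");
    return -1;
  }

  // dendrite site layout at length len (um): floor(len/spacing) sites per arm
  void rebuild_fdc_sites(double len_um, bool force) {
    int karm = std::max(0, (int)std::floor(len_um / spacing + 1e-9));
    if (!force && karm == dendrite_k_last) return;
    dendrite_k_last = karm;
    std::fill(fdc_head.begin(), fdc_head.end(), -1);
    fdc_refs.clear();
    const int armdx[6] = {1, -1, 0, 0, 0, 0};
    const int armdy[6] = {0, 0, 1, -1, 0, 0};
    const int armdz[6] = {0, 0, 0, 0, 1, -1};
    for (size_t f = 0; f < fdcs.size(); f++) {
      FDC &fd = fdcs[f];
      // previous total per epitope
      std::vector<double> tot(nep, 0.0);
      bool fresh = fd.sites.empty();
      if (fresh) {
        for (int e = 0; e < nep; e++) tot[e] = antigen_per_fdc * epifrac[e];
      } else {
        for (size_t k = 0; k < fd.sites.size(); k++)
          for (int e = 0; e < nep; e++) tot[e] += fd.ag[k * nep + e];
      }
      fd.sites.clear();
      fd.sites.push_back(fd.soma);
      int sx = fd.soma % L, sy = (fd.soma / L) % L, sz = fd.soma / (L * L);
      for (int a = 0; a < 6; a++)
        for (int k = 1; k <= karm; k++) {
          int x = sx + armdx[a] * k, y = sy + armdy[a] * k, z = sz + armdz[a] * k;
          if (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L) continue;
          int s = idx(x, y, z);
          if (!inside[s]) continue;
          fd.sites.push_back(s);
        }
      int ns = (int)fd.sites.size();
      fd.ag.assign((size_t)ns * nep, 0.0);
      for (int k = 0; k < ns; k++)
        for (int e = 0; e < nep; e++) fd.ag[(size_t)k * nep + e] = tot[e] / ns;
      for (int k = 0; k < ns; k++) {
        FdcRef r;
        r.f = (int)f; r.k = k; r.next = fdc_head[fd.sites[k]];
        fdc_head[fd.sites[k]] = (int)fdc_refs.size();
        fdc_refs.push_back(r);
      }
    }
    n_fdc_sites = 0;
    for (int s = 0; s < (int)fdc_head.size(); s++)
      if (fdc_head[s] != -1) n_fdc_sites++;
  }

  // --- shape space --------------------------------------------------------
  inline double affinity_to(const int8_t *bcr, int e) const {
    double d2 = 0;
    for (int d = 0; d < 4; d++) {
      double dd = (double)bcr[d] - (double)epit[e][d];
      d2 += dd * dd;
    }
    return std::exp(-d2 / gamma2);
  }
  void set_aff(Cell &cl) {
    for (int e = 0; e < nep; e++) cl.aff[e] = affinity_to(cl.bcr, e);
  }
  void mutate_bcr(int8_t *bcr) {
    int cand[8], nc = 0;
    for (int d = 0; d < 4; d++) {
      if (bcr[d] + 1 <= shape_hi) cand[nc++] = d * 2;
      if (bcr[d] - 1 >= shape_lo) cand[nc++] = d * 2 + 1;
    }
    int pick = cand[rng.below(nc)];
    bcr[pick / 2] += (pick % 2 == 0) ? 1 : -1;
  }
  void draw_founder_bcr(int8_t *bcr) {
    int span = shape_hi - shape_lo + 1;
    for (int tries = 0; tries < 1000000; tries++) {
      int v[4];
      for (int d = 0; d < 4; d++) v[d] = shape_lo + rng.below(span);
      int best = 1 << 30;
      for (int e = 0; e < nep; e++) {
        int d2 = 0;
        for (int d = 0; d < 4; d++) {
          int dd = v[d] - epit[e][d];
          d2 += dd * dd;
        }
        if (d2 < best) best = d2;
      }
      if (best >= founder_dmin2 && best <= founder_dmax2) {
        for (int d = 0; d < 4; d++) bcr[d] = (int8_t)v[d];
        return;
      }
    }
    stop("founder band empty: no shape points in the configured distance band");
  }

  // --- mechanism laws -----------------------------------------------------
  inline double Tmax_at(double t) const {
    return (mech == 5) ? T_max0 * hill_decay2(t, K_T) : T_max0;
  }
  inline double J_of(const Cell &cl) const {
    if (!J_of_p) return 1.0;
    return J_min + (J_max - J_min) * hill_up(cl.p, K_p, 2.0);
  }
  inline double K_of(const Cell &cl) const {
    if (mech != 7) return K_min;
    return K_min + (K_max - K_min) * hill_up((double)cl.ncyc, K_K, 2.0);
  }
  double ndiv_of(const Cell &cl) {
    double x = ndiv_on_p ? cl.p : cl.tsig;
    double nd = n_min + (n_max - n_min) * hill_up(x, K_of(cl), hill_n);
    double r;
    if (rounding == 0) {
      double fl = std::floor(nd);
      r = fl + ((rng.unif() < nd - fl) ? 1.0 : 0.0);
    } else {
      r = std::round(nd);
    }
    if (r < n_min) r = n_min;
    if (r > n_max) r = n_max;
    return r;
  }
  double F_of(const Cell &cl, double t) {
    if (mech != 6) return 0.0;
    if (m6_mode == 0) return hill_up(cl.p, K_F, 2.0);
    if (m6_mode == 1) return hill_up(cl.tsig, K_F, 2.0);
    return 1.0 - std::exp(-k_diff * t);
  }

  // --- agents -------------------------------------------------------------
  int new_cell() {
    Cell cl;
    std::memset(&cl, 0, sizeof(cl));
    cells.push_back(cl);
    return (int)cells.size() - 1;
  }

  void influx(double t) {
    if (t > influx_window_h) return;
    int n = rng.poisson(influx_rate * dt);
    for (int i = 0; i < n; i++) {
      if ((int)cells.size() - n_dead_slots >= max_cells) { c_deferred_influx++; continue; }
      int s;
      bool found = false;
      for (int tries = 0; tries < 2000; tries++) {
        int x = rng.below(L), y = rng.below(L), z = rng.below(L);
        s = idx(x, y, z);
        if (occ[s] == OC_FREE) { found = true; break; }
      }
      if (!found) { c_deferred_influx++; continue; }
      int ci = new_cell();
      Cell &cl = cells[ci];
      cl.pos = s;
      occ[s] = OC_CELL;
      cl.state = ST_DZ;
      cl.alive = 1;
      draw_founder_bcr(cl.bcr);
      set_aff(cl);
      cl.p = 0; cl.tsig = 0;
      cl.divleft = founder_div;
      cl.ncyc = 0;
      cl.t_event = t + division_time_h + (2 * rng.unif() - 1) * division_jitter_h;
      cl.t_lastup = -1e9;
      cl.t_contact = -1;
      cl.tfh = -1;
      cl.uid = next_uid++;
      n_live++;
      c_founders++;
      ev.rec(t, EV_INFLUX, cl.uid, founder_div, 0, 0);
    }
  }

  inline int pick_dir(int biasdz) {
    if (biasdz != 0 && rng.unif() < chemo_bias) {
      int j = rng.below(9);
      return biasdz > 0 ? OFF.up[j] : OFF.dn[j];
    }
    return rng.below(26);
  }

  // persistent biased walk: keep the previous direction, re-draw when the
  // persistence time elapses, the chemotactic context changes, or the way
  // is blocked
  inline int walk_dir(Cell &cl, int biasdz) {
    uint8_t bcode = biasdz == 0 ? 0 : (biasdz > 0 ? 1 : 2);
    if (cl.dirbias != bcode || rng.unif() < turn_prob) {
      cl.dir = (uint8_t)pick_dir(biasdz);
      cl.dirbias = bcode;
    }
    return cl.dir;
  }

  // returns true if the cell exited the lattice (OUT state only)
  bool move_cell(int ci) {
    Cell &cl = cells[ci];
    int bias = 0;
    bool lz = is_lz(cl.pos);
    switch (cl.state) {
      case ST_DZ: bias = lz ? -1 : 0; break;
      case ST_UNSEL: bias = lz ? 0 : 1; break;
      case ST_FDCSEL: bias = lz ? 0 : 1; break;
      case ST_SEL: bias = lz ? -1 : 0; break;
      case ST_OUT: bias = 1; break;
    }
    for (int attempt = 0; attempt < 2; attempt++) {
      int d = walk_dir(cl, bias);
      int x = cl.pos % L + OFF.ox[d], y = (cl.pos / L) % L + OFF.oy[d],
          z = cl.pos / (L * L) + OFF.oz[d];
      bool outside = (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L);
      int s = outside ? -1 : idx(x, y, z);
      uint8_t v = outside ? (uint8_t)OC_OUT : occ[s];
      if (v == OC_OUT) {
        if (cl.state == ST_OUT) return true;
        cl.dirbias = 255; // force a new direction next time
        continue;
      }
      if (v != OC_FREE) { cl.dirbias = 255; continue; }
      occ[cl.pos] = OC_FREE;
      occ[s] = OC_CELL;
      cl.pos = s;
      return false;
    }
    return false;
  }

  void kill(int ci, double t, bool at_tfh) {
    Cell &cl = cells[ci];
    end_contact(ci, t);
    occ[cl.pos] = OC_FREE;
    cl.alive = 0;
    n_live--;
    n_dead_slots++;
    if (at_tfh) c_death_tfh++; else c_death_collect++;
    ev.rec(t, EV_DEATH, cl.uid, at_tfh ? 1 : 0, cl.p, cl.tsig);
  }

  void end_contact(int ci, double t) {
    Cell &cl = cells[ci];
    if (cl.tfh >= 0) {
      ev.rec(t, EV_CONTACT_END, cl.uid, cl.tfh, cl.tsig, 0);
      cl.tfh = -1;
      cl.t_contact = -1;
      cl.t_rebind = t + rebind_delay_h;
    }
  }

  void exit_cell(int ci, double t) {
    Cell &cl = cells[ci];
    occ[cl.pos] = OC_FREE;
    cl.alive = 0;
    n_live--;
    n_dead_slots++;
    c_exits++;
    // bin the exiting cell by its affinity to its best epitope
    int be = 0;
    for (int e = 1; e < nep; e++)
      if (cl.aff[e] > cl.aff[be]) be = e;
    double aff = cl.aff[be];
    int bin = (int)std::round(aff * (n_bins - 1));
    if (bin < 0) bin = 0;
    if (bin > n_bins - 1) bin = n_bins - 1;
    pending[be * n_bins + bin]++;
    ev.rec(t, EV_EXIT, cl.uid, be * n_bins + bin, aff, 0);
  }

  void try_uptake(int ci, double t) {
    Cell &cl = cells[ci];
    if (t - cl.t_lastup < uptake_interval_h) return;
    int href = fdc_head[cl.pos];
    if (href == -1) return;
    // free (surface, unmasked) antigen at this site, per epitope
    double fr[4], ftot = 0;
    for (int e = 0; e < nep; e++) fr[e] = 0;
    for (int r = href; r != -1; r = fdc_refs[r].next) {
      FDC &fd = fdcs[fdc_refs[r].f];
      for (int e = 0; e < nep; e++)
        fr[e] += fd.ag[(size_t)fdc_refs[r].k * nep + e] * freefrac[e];
    }
    for (int e = 0; e < nep; e++) ftot += fr[e];
    if (ftot < 1.0) return; // needs at least one free portion on site
    cl.t_lastup = t;
    // epitope sampled by free-amount share
    int e = 0;
    if (nep > 1) {
      double u = rng.unif() * ftot, acc = 0;
      for (e = 0; e < nep; e++) { acc += fr[e]; if (u <= acc) break; }
      if (e >= nep) e = nep - 1;
    }
    c_attempts++;
    w_attempts++;
    // capture succeeds with probability affinity x availability, where
    // availability is the site's free surface antigen relative to the
    // pristine per-site load of a fully grown FDC
    double avail = std::min(1.0, ftot / uptake_ref);
    bool success = rng.unif() < cl.aff[e] * avail;
    if (success) {
      cl.p += 1.0;
      c_success++;
      w_success++;
      if (mech == 1 && portions > 0) {
        // consume: remove portions from this site's ledger, epitope e,
        // proportionally over co-occupying FDCs
        double avail = fr[e] / std::max(freefrac[e], 1e-12); // total epitope-e antigen at site
        double take = std::min(portions, avail);
        if (take > 0) {
          for (int r = href; r != -1; r = fdc_refs[r].next) {
            FDC &fd = fdcs[fdc_refs[r].f];
            double &a = fd.ag[(size_t)fdc_refs[r].k * nep + e];
            double share = take * (a / avail);
            a = std::max(0.0, a - share);
          }
          consumed += take;
        }
      }
    }
    ev.rec(t, EV_UPTAKE, cl.uid, success ? 1 : 0, cl.aff[e], cl.p);
  }

  void divide(int ci, double t) {
    Cell &mo = cells[ci];
    // daughter needs a free neighboring site; defer if none
    int free_dirs[26], nfree = 0;
    int x0 = mo.pos % L, y0 = (mo.pos / L) % L, z0 = mo.pos / (L * L);
    for (int d = 0; d < 26; d++) {
      int x = x0 + OFF.ox[d], y = y0 + OFF.oy[d], z = z0 + OFF.oz[d];
      if (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L) continue;
      int s = idx(x, y, z);
      if (occ[s] == OC_FREE) free_dirs[nfree++] = s;
    }
    if (nfree == 0 || (int)cells.size() - n_dead_slots >= max_cells) {
      mo.t_event = t + dt; // retry
      return;
    }
    int s = free_dirs[rng.below(nfree)];
    c_divisions++;
    bool has_p = mo.p > 0;
    if (has_p) c_div_p++;

    int di = new_cell();
    Cell &da = cells[di];
    Cell &mo2 = cells[ci]; // re-reference after potential realloc
    da = mo2;
    da.pos = s;
    occ[s] = OC_CELL;
    da.uid = next_uid++;
    da.tfh = -1;
    da.t_contact = -1;
    n_live++;

    bool mut_m = rng.unif() < mutation_prob;
    bool mut_d = rng.unif() < mutation_prob;
    if (mut_m) { mutate_bcr(mo2.bcr); set_aff(mo2); c_mutated++; }
    if (mut_d) { mutate_bcr(da.bcr); set_aff(da); c_mutated++; }
    c_daughters += 2;

    bool asym = has_p && (rng.unif() < asym_prob);
    if (asym) {
      c_asym++;
      // one daughter takes all captured antigen and leaves as an output cell
      da.p = mo2.p;
      mo2.p = 0;
      da.state = ST_OUT;
      c_out_asym++;
      ev.rec(t, EV_TRANSITION, da.uid, ST_OUT, da.p, 0);
    } else {
      da.p = mo2.p * 0.5;
      mo2.p *= 0.5;
    }
    ev.rec(t, EV_DIVISION, mo2.uid, da.uid, asym ? 1 : 0, (mut_m ? 1 : 0) + (mut_d ? 2 : 0));

    mo2.divleft--;
    da.divleft = mo2.divleft;
    for (int which = 0; which < 2; which++) {
      Cell &cl = which == 0 ? cells[ci] : cells[di];
      if (cl.state == ST_OUT) continue;
      if (cl.divleft <= 0) {
        cl.state = ST_UNSEL;
        cl.ncyc++;
        cl.tsig = 0;
        cl.window_started = 0;
        cl.t_event = 1e18;
        cl.t_lastup = -1e9;
        ev.rec(t, EV_TRANSITION, cl.uid, ST_UNSEL, cl.p, 0);
      } else {
        cl.t_event = t + division_time_h + (2 * rng.unif() - 1) * division_jitter_h;
      }
    }
  }

  void resolve_selection(int ci, double t) {
    Cell &cl = cells[ci];
    end_contact(ci, t);
    if (cl.tsig >= tfh_threshold) {
      c_selections++;
      w_sel++;
      w_sum_p += cl.p;
      w_sum_tsig += cl.tsig;
      ev.rec(t, EV_SELECT, cl.uid, 0, cl.p, cl.tsig);
      double F = F_of(cl, t);
      if (F > 0 && rng.unif() < F) {
        cl.state = ST_OUT;
        c_out_diff++;
        w_out_sel++;
        ev.rec(t, EV_TRANSITION, cl.uid, ST_OUT, cl.p, cl.tsig);
      } else {
        cl.state = ST_SEL;
        cl.ndiv_next = (int)ndiv_of(cl);
        c_recycles++;
        w_rec++;
        w_sum_ndiv += cl.ndiv_next;
        ev.rec(t, EV_RECYCLE, cl.uid, cl.ndiv_next, cl.p, cl.tsig);
      }
    } else {
      kill(ci, t, true);
    }
  }

  // one lattice timestep
  void step(double t) {
    influx(t);
    int ncur = (int)cells.size();
    for (int ci = 0; ci < ncur; ci++) {
      Cell &cl = cells[ci];
      if (!cl.alive) continue;
      switch (cl.state) {
        case ST_DZ: {
          if (rng.unif() < p_move) move_cell(ci);
          Cell &c2 = cells[ci];
          if (t >= c2.t_event && c2.divleft > 0) divide(ci, t);
          break;
        }
        case ST_UNSEL: {
          if (rng.unif() < p_move) move_cell(ci);
          Cell &c2 = cells[ci];
          if (!c2.window_started && is_lz(c2.pos)) {
            c2.window_started = 1;
            c2.t_event = t + collect_window_h;
          }
          if (c2.window_started) {
            if (t >= c2.t_event) {
              if (c2.p > 0) {
                c2.state = ST_FDCSEL;
                c2.t_event = t + tfh_window_h;
                c2.tsig = 0;
                ev.rec(t, EV_TRANSITION, c2.uid, ST_FDCSEL, c2.p, 0);
              } else {
                kill(ci, t, false);
              }
            } else {
              try_uptake(ci, t);
            }
          }
          break;
        }
        case ST_FDCSEL: {
          if (t >= cl.t_event) { resolve_selection(ci, t); break; }
          if (cl.tfh >= 0) {
            if (t >= cl.t_contact) end_contact(ci, t);
          }
          if (cl.tfh < 0) {
            if (rng.unif() < p_move) move_cell(ci);
            Cell &c2 = cells[ci];
            if (t < c2.t_rebind) break; // still searching after last contact
            // bind an adjacent Tfh, uniformly among those adjacent
            int x0 = c2.pos % L, y0 = (c2.pos / L) % L, z0 = c2.pos / (L * L);
            int chosen = -1, cnt = 0;
            for (int d = 0; d < 26; d++) {
              int x = x0 + OFF.ox[d], y = y0 + OFF.oy[d], z = z0 + OFF.oz[d];
              if (x < 0 || y < 0 || z < 0 || x >= L || y >= L || z >= L) continue;
              int tf = tfh_at[idx(x, y, z)];
              if (tf >= 0) {
                cnt++;
                if (rng.below(cnt) == 0) chosen = tf;
              }
            }
            if (chosen >= 0) {
              c2.tfh = chosen;
              c2.t_contact = t + contact_h;
              if (!c2.in_list) { c2.in_list = 1; contacts.push_back(ci); }
              ev.rec(t, EV_CONTACT_START, c2.uid, chosen, c2.p, 0);
            }
          }
          break;
        }
        case ST_SEL: {
          if (rng.unif() < p_move) move_cell(ci);
          Cell &c2 = cells[ci];
          if (!is_lz(c2.pos)) {
            c2.state = ST_DZ;
            c2.divleft = c2.ndiv_next;
            c2.t_event = t + division_time_h + (2 * rng.unif() - 1) * division_jitter_h;
            ev.rec(t, EV_TRANSITION, c2.uid, ST_DZ, c2.p, (double)c2.divleft);
          }
          break;
        }
        case ST_OUT: {
          if (rng.unif() < p_move) {
            if (move_cell(ci)) exit_cell(ci, t);
          }
          break;
        }
      }
    }
    // Tfh polarization: each Tfh polarizes toward its bound B cell with the
    // highest pMHC density; only the polarized cell integrates signal
    tfh_deliver(t);
    if (n_dead_slots > 512) compact();
  }

  std::vector<double> tf_best;
  std::vector<int> tf_bestc, tf_cnt, tf_target, contacts;
  void tfh_deliver(double t) {
    if (tf_best.empty()) {
      tf_best.assign(n_tfh, -1.0);
      tf_bestc.assign(n_tfh, -1);
      tf_cnt.assign(n_tfh, 0);
      tf_target.assign(n_tfh, -1);
    }
    // drop stale entries (kept incrementally; cells register on contact start)
    size_t w = 0;
    for (size_t k = 0; k < contacts.size(); k++) {
      int ci = contacts[k];
      Cell &cl = cells[ci];
      if (cl.alive && cl.state == ST_FDCSEL && cl.tfh >= 0) contacts[w++] = ci;
      else cl.in_list = 0;
    }
    contacts.resize(w);
    for (size_t k = 0; k < contacts.size(); k++) {
      int tf = cells[contacts[k]].tfh;
      tf_best[tf] = -1.0;
      tf_bestc[tf] = -1;
      tf_cnt[tf] = 0;
    }
    for (size_t k = 0; k < contacts.size(); k++) {
      int ci = contacts[k];
      Cell &cl = cells[ci];
      int tf = cl.tfh;
      if (cl.p > tf_best[tf]) {
        tf_best[tf] = cl.p;
        tf_bestc[tf] = ci;
        tf_cnt[tf] = 1;
      } else if (cl.p == tf_best[tf]) {
        // uniform tie-break among maximal-p cells (reservoir)
        tf_cnt[tf]++;
        if (rng.below(tf_cnt[tf]) == 0) tf_bestc[tf] = ci;
      }
    }
    // polarization is persistent: the Tfh keeps its current target as long
    // as that cell is still bound and still carries the maximal pMHC load;
    // otherwise it re-polarizes (uniformly among tied maximizers)
    double Tm = Tmax_at(t);
    for (size_t k = 0; k < contacts.size(); k++) {
      int tf = cells[contacts[k]].tfh;
      int tgt = tf_target[tf];
      bool keep = tgt >= 0 && tgt < (int)cells.size() && cells[tgt].alive &&
                  cells[tgt].state == ST_FDCSEL && cells[tgt].tfh == tf &&
                  cells[tgt].p >= tf_best[tf];
      if (!keep) tf_target[tf] = tf_bestc[tf];
    }
    for (size_t k = 0; k < contacts.size(); k++) {
      int ci = contacts[k];
      Cell &cl = cells[ci];
      if (tf_target[cl.tfh] == ci) cl.tsig += Tm * J_of(cl) * dt;
    }
  }

  void compact() {
    std::vector<Cell> nc;
    std::vector<int> remap(cells.size(), -1);
    nc.reserve(cells.size() - n_dead_slots);
    for (size_t i = 0; i < cells.size(); i++) {
      if (!cells[i].alive) continue;
      remap[i] = (int)nc.size();
      nc.push_back(cells[i]);
    }
    for (size_t tf = 0; tf < tf_target.size(); tf++)
      tf_target[tf] = (tf_target[tf] >= 0) ? remap[tf_target[tf]] : -1;
    cells.swap(nc);
    n_dead_slots = 0;
    // contact list holds raw indices; rebuild it after the remap
    contacts.clear();
    for (size_t i = 0; i < cells.size(); i++) {
      if (cells[i].alive && cells[i].state == ST_FDCSEL && cells[i].tfh >= 0) {
        cells[i].in_list = 1;
        contacts.push_back((int)i);
      } else {
        cells[i].in_list = 0;
      }
    }
  }

  // --- hourly module updates ---------------------------------------------
  void hourly_update(double t) {
    if (mech == 3) {
      // growth to day 7, then contraction back toward the initial stub
      // length; dendrites regress to their starting morphology, the soma
      // and 5-um processes persist
      double len = fdc_initial_um + fdc_growth * std::min(t, fdc_switch_h) -
                   k_c * std::max(t - fdc_switch_h, 0.0);
      if (len < fdc_initial_um) len = fdc_initial_um;
      rebuild_fdc_sites(len, false);
    }
    if (t > 0) {
      antibody_update(t - out_every_h, t);
      if (mech == 4) phi = cycle_phi(phi, t - out_every_h, t);
      if (mech == 2 && N_ab > 0) masking_update(out_every_h);
    }
    double thsum;
    for (int e = 0; e < nep; e++) {
      thsum = 0;
      for (int i = 0; i < n_bins; i++) thsum += theta[e * n_bins + i];
      freefrac[e] = phi * std::max(0.0, 1.0 - thsum);
    }
  }

  // exact exponential relaxation of the surface fraction, Eq-6 style, with
  // the externalization rate following its Hill decay schedule
  double cycle_phi(double phi0, double t0, double t1) {
    double p = phi0;
    double sub = 0.02;
    int n = (int)std::ceil((t1 - t0) / sub);
    double h = (t1 - t0) / n;
    for (int i = 0; i < n; i++) {
      double tm = t0 + (i + 0.5) * h;
      double ke = k_ext0_h * hill_decay2(tm, K_ext_h);
      double lam = ke + k_int_h;
      double pss = ke / lam;
      p = pss + (p - pss) * std::exp(-lam * h);
    }
    return p;
  }

  void antibody_update(double t0, double t1) {
    double dth = t1 - t0;
    double pconv = 1.0 - std::exp(-std::log(2.0) / plasma_halflife_h * dth);
    for (int e = 0; e < nep; e++)
      for (int i = 0; i < n_bins; i++) {
        int j = e * n_bins + i;
        int np0 = pending[j], conv = 0;
        for (int k = 0; k < np0; k++)
          if (rng.unif() < pconv) conv++;
        pending[j] -= conv;
        n_p[j] += conv;
        // dA/dt = k1/V * n_p - k2 A ; exact for constant n_p over the hour
        if (k2_h > 0) {
          double Ass = k1 / volume_l * n_p[j] / k2_h;
          A[j] = Ass + (A[j] - Ass) * std::exp(-k2_h * dth);
        } else {
          A[j] += k1 / volume_l * n_p[j] * dth;
        }
      }
  }

  // masked occupancy per bin: d theta_i/dt = kon N A_i (1 - sum theta) - koff_i theta_i
  void masking_update(double dth) {
    for (int e = 0; e < nep; e++) {
      double *th = &theta[e * n_bins];
      double maxrate = 0;
      for (int i = 0; i < n_bins; i++) {
        double r = k_on * N_ab * A[e * n_bins + i] + koff[i];
        if (r > maxrate) maxrate = r;
      }
      int nsub = std::max(1, (int)std::ceil(maxrate * dth / 0.05));
      double h = dth / nsub;
      for (int ssub = 0; ssub < nsub; ssub++) {
        double ths = 0;
        for (int i = 0; i < n_bins; i++) ths += th[i];
        double freep = std::max(0.0, 1.0 - ths);
        for (int i = 0; i < n_bins; i++) {
          double d = (k_on * N_ab * A[e * n_bins + i] * freep - koff[i] * th[i]) * h;
          th[i] += d;
          if (th[i] < 0) th[i] = 0;
        }
      }
    }
  }

  // --- readouts ------------------------------------------------------------
  void record(double t) {
    int vol = 0, dzz = 0, lzz = 0, st[5] = {0, 0, 0, 0, 0}, lzsel = 0;
    for (size_t i = 0; i < cells.size(); i++) {
      Cell &cl = cells[i];
      if (!cl.alive) continue;
      st[cl.state]++;
      if (cl.state == ST_OUT) continue; // leaving cells not part of GC volume
      vol++;
      if (is_lz(cl.pos)) {
        lzz++;
        if (cl.state == ST_SEL) lzsel++;
      } else {
        dzz++;
      }
    }
    double agtot = 0, agfree = 0, agmask = 0;
    std::vector<double> tote(nep, 0.0);
    for (size_t f = 0; f < fdcs.size(); f++)
      for (size_t k = 0; k < fdcs[f].sites.size(); k++)
        for (int e = 0; e < nep; e++) tote[e] += fdcs[f].ag[k * nep + e];
    for (int e = 0; e < nep; e++) {
      double ths = 0;
      for (int i = 0; i < n_bins; i++) ths += theta[e * n_bins + i];
      agtot += tote[e];
      agfree += tote[e] * phi * std::max(0.0, 1.0 - ths);
      agmask += tote[e] * phi * std::min(1.0, ths);
    }
    double agint = agtot * (1.0 - phi);
    double abtot = 0, ip = 0;
    int nptot = 0, pend = 0;
    for (int e = 0; e < nep; e++)
      for (int i = 0; i < n_bins; i++) {
        abtot += A[e * n_bins + i];
        ip += A[e * n_bins + i] / (kd[i] + R_test);
        nptot += n_p[e * n_bins + i];
        pend += pending[e * n_bins + i];
      }

    o_t.push_back(t);
    o_vol.push_back(vol);
    o_dzz.push_back(dzz);
    o_lzz.push_back(lzz);
    o_sdz.push_back(st[ST_DZ]);
    o_suns.push_back(st[ST_UNSEL]);
    o_sfdc.push_back(st[ST_FDCSEL]);
    o_ssel.push_back(st[ST_SEL]);
    o_sout.push_back(st[ST_OUT]);
    o_frlzsel.push_back(lzz > 0 ? (double)lzsel / lzz : NA_REAL);
    o_fdcsites.push_back(n_fdc_sites);
    o_fdcperb.push_back(vol > 0 ? (double)n_fdc_sites / vol : NA_REAL);
    o_agtot.push_back(agtot);
    o_agfree.push_back(agfree);
    o_agmask.push_back(agmask);
    o_agint.push_back(agint);
    o_cons.push_back(consumed);
    o_phi.push_back(phi);
    o_att.push_back(w_attempts);
    o_succ.push_back(w_success);
    o_frsucc.push_back(w_attempts > 0 ? w_success / w_attempts : NA_REAL);
    o_selw.push_back(w_sel);
    o_meanp.push_back(w_sel > 0 ? w_sum_p / w_sel : NA_REAL);
    o_meants.push_back(w_sel > 0 ? w_sum_tsig / w_sel : NA_REAL);
    o_recw.push_back(w_rec);
    o_meandiv.push_back(w_rec > 0 ? w_sum_ndiv / w_rec : NA_REAL);
    o_frrec.push_back(w_sel > 0 ? w_rec / w_sel : NA_REAL);
    o_outw.push_back(w_out_sel);
    o_frout.push_back(w_sel > 0 ? w_out_sel / w_sel : NA_REAL);
    o_abtot.push_back(abtot);
    o_nptot.push_back(nptot);
    o_pend.push_back(pend);
    o_ip.push_back(ip);
    reset_window();
  }

  List run() {
    init();
    long steps = (long)std::llround(duration_h / dt);
    long spo = (long)std::llround(out_every_h / dt);
    for (long s = 0; s <= steps; s++) {
      double t = s * dt;
      if (s % spo == 0) {
        hourly_update(t);
        record(t);
        if (s % (spo * 24) == 0) Rcpp::checkUserInterrupt();
      }
      if (s == steps) break;
      step(t);
    }

    DataFrame ts = DataFrame::create(
        Named("t") = o_t, Named("volume") = o_vol, Named("n_dz") = o_dzz,
        Named("n_lz") = o_lzz, Named("n_state_dz") = o_sdz,
        Named("n_state_unselected") = o_suns, Named("n_state_fdcselected") = o_sfdc,
        Named("n_state_selected") = o_ssel, Named("n_state_output") = o_sout,
        Named("frac_lz_selected") = o_frlzsel, Named("fdc_sites") = o_fdcsites,
        Named("fdc_sites_per_bcell") = o_fdcperb, Named("ag_total") = o_agtot,
        Named("ag_free") = o_agfree, Named("ag_masked") = o_agmask,
        Named("ag_interior") = o_agint, Named("ag_consumed") = o_cons,
        Named("surface_fraction") = o_phi, Named("uptake_attempts") = o_att,
        Named("uptake_successes") = o_succ);
    // DataFrame::create caps at 20 columns; append the rest
    List ts2 = as<List>(ts);
    ts2["frac_uptake_success"] = o_frsucc;
    ts2["selections"] = o_selw;
    ts2["mean_p_selected"] = o_meanp;
    ts2["mean_tsig_selected"] = o_meants;
    ts2["recycles"] = o_recw;
    ts2["mean_divisions"] = o_meandiv;
    ts2["frac_recycled"] = o_frrec;
    ts2["outputs_selected"] = o_outw;
    ts2["frac_output"] = o_frout;
    ts2["ab_total"] = o_abtot;
    ts2["n_plasma"] = o_nptot;
    ts2["n_pending"] = o_pend;
    ts2["immune_power"] = o_ip;
    ts2.attr("class") = "data.frame";
    ts2.attr("row.names") = seq_len((int)o_t.size());

    List counters = List::create(
        Named("founders") = c_founders, Named("divisions") = c_divisions,
        Named("divisions_with_antigen") = c_div_p,
        Named("asymmetric_divisions") = c_asym, Named("daughters") = c_daughters,
        Named("mutated_daughters") = c_mutated,
        Named("uptake_attempts") = c_attempts,
        Named("uptake_successes") = c_success, Named("selections") = c_selections,
        Named("deaths_collection") = c_death_collect,
        Named("deaths_tfh") = c_death_tfh, Named("recycles") = c_recycles,
        Named("outputs_asymmetric") = c_out_asym,
        Named("outputs_differentiation") = c_out_diff, Named("exits") = c_exits,
        Named("deferred_influx") = c_deferred_influx,
        Named("consumed") = consumed);

    NumericMatrix Am(nep, n_bins), thm(nep, n_bins);
    IntegerMatrix npm(nep, n_bins), pdm(nep, n_bins);
    for (int e = 0; e < nep; e++)
      for (int i = 0; i < n_bins; i++) {
        Am(e, i) = A[e * n_bins + i];
        thm(e, i) = theta[e * n_bins + i];
        npm(e, i) = n_p[e * n_bins + i];
        pdm(e, i) = pending[e * n_bins + i];
      }
    List antibody = List::create(
        Named("A") = Am, Named("n_plasma") = npm, Named("pending") = pdm,
        Named("masked_occupancy") = thm, Named("K_D") = NumericVector(kd.begin(), kd.end()),
        Named("k_off") = NumericVector(koff.begin(), koff.end()));

    List out = List::create(
        Named("timeseries") = ts2, Named("counters") = counters,
        Named("antibody") = antibody,
        Named("lattice") = List::create(
            Named("n_sites") = count_sites(), Named("L") = L,
            Named("n_fdc_sites") = n_fdc_sites,
            Named("n_fdc") = (int)fdcs.size(),
            Named("n_tfh") = (int)tfh_pos.size(),
            Named("n_fdc_somas_lz") = count_somas_lz(),
            Named("n_tfh_lz") = count_tfh_lz()),
        Named("events_truncated") = ev.truncated);
    if (ev.on) {
      out["events"] = DataFrame::create(
          Named("t") = ev.t, Named("type") = ev.type, Named("cell") = ev.id,
          Named("aux") = ev.aux, Named("v1") = ev.v1, Named("v2") = ev.v2);
    }
    return out;
  }

  int count_sites() const {
    int n = 0;
    for (size_t i = 0; i < inside.size(); i++) n += inside[i];
    return n;
  }

  int count_somas_lz() const {
    int n = 0;
    for (size_t f = 0; f < fdcs.size(); f++) n += is_lz(fdcs[f].soma) ? 1 : 0;
    return n;
  }

  int count_tfh_lz() const {
    int n = 0;
    for (size_t i = 0; i < tfh_pos.size(); i++) n += is_lz(tfh_pos[i]) ? 1 : 0;
    return n;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_gc(List cfg, int seed) {
  Sim sim(cfg, seed);
  return sim.run();
}

// [[Rcpp::export]]
List cpp_lattice_info(double radius_um, double spacing_um) {
  int R = (int)std::floor(radius_um / spacing_um + 1e-9);
  int L = 2 * R + 1, c = R;
  int n = 0, ndz = 0, nlz = 0;
  for (int z = 0; z < L; z++)
    for (int y = 0; y < L; y++)
      for (int x = 0; x < L; x++) {
        int dx = x - c, dy = y - c, dz = z - c;
        if (dx * dx + dy * dy + dz * dz <= R * R) {
          n++;
          if (z > c) nlz++; else ndz++;
        }
      }
  return List::create(Named("n_sites") = n, Named("n_dz") = ndz,
                      Named("n_lz") = nlz, Named("L") = L,
                      Named("sites_radius") = R);
}

// Draws from the engine's mutation kernel, for distribution checks.
// [[Rcpp::export]]
IntegerMatrix cpp_mutate_draws(IntegerVector point, int n, int lo, int hi, int seed) {
  if (point.size() != 4) stop("shape points have exactly 4 coordinates");
  RNG rng((uint64_t)(uint32_t)seed);
  IntegerMatrix out(n, 4);
  for (int r = 0; r < n; r++) {
    int cand[8], nc = 0;
    for (int d = 0; d < 4; d++) {
      if (point[d] + 1 <= hi) cand[nc++] = d * 2;
      if (point[d] - 1 >= lo) cand[nc++] = d * 2 + 1;
    }
    int pick = cand[rng.below(nc)];
    for (int d = 0; d < 4; d++) out(r, d) = point[d];
    out(r, pick / 2) += (pick % 2 == 0) ? 1 : -1;
  }
  return out;
}

// Surface-fraction relaxation used by the engine (immune-complex cycling),
// exported so the integrator can be compared with the closed-form solution.
// [[Rcpp::export]]
NumericVector cpp_cycle_surface(double phi0, double k_int_h, double k_ext0_h,
                                double K_ext_h, NumericVector times) {
  NumericVector out(times.size());
  double p = phi0, t0 = 0;
  for (int i = 0; i < times.size(); i++) {
    double t1 = times[i];
    double sub = 0.02;
    int n = std::max(1, (int)std::ceil((t1 - t0) / sub));
    double h = (t1 - t0) / n;
    for (int k = 0; k < n; k++) {
      double tm = t0 + (k + 0.5) * h;
      double ke = k_ext0_h * hill_decay2(tm, K_ext_h);
      double lam = ke + k_int_h;
      double pss = ke / lam;
      p = pss + (p - pss) * std::exp(-lam * h);
    }
    out[i] = p;
    t0 = t1;
  }
  return out;
}
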