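#include "rng.h"
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event codes shared with R (see lef_event_levels() in R/lef_engine.R)
enum EventKind {
  EV_BIND = 0, EV_UNBIND = 1, EV_STEP = 2, EV_STALL_BOUNDARY = 3,
  EV_STALL_COLLISION = 4, EV_PASS_BOUNDARY = 5, EV_CROSS_PHANTOM = 6,
  EV_BIND_REJECT = 7
};

struct EventLog {
  bool record;
  std::vector<double> time;
  std::vector<int> kind, lef, leg, pos;
  void add(double t, int k, int id, int lg, int p) {
    if (!record) return;
    time.push_back(t); kind.push_back(k); lef.push_back(id);
    leg.push_back(lg); pos.push_back(p);
  }
};

struct LefState {
  int n;                          // monomer lattice size
  std::vector<double> pass_left, pass_right;   // prob of entering site moving left/right
  std::vector<int> block_left, block_right;    // 1 if a boundary gates that direction
  std::vector<int> loading;       // loading-site anchors (0-based); empty => uniform
  bool symmetric, phantom;
  double k_bind, k_unbind, step_rate;  // per min (k_bind per unbound LEF)
  std::vector<int> left, right;
  std::vector<int> bound, lmob, rmob;
  std::vector<int> occ;           // legs per monomer
  double time;
  Xoshiro rng;

  LefState() : rng(0) {}

  int pool() const { return (int)bound.size(); }
  int n_bound() const {
    int k = 0;
    for (int b : bound) k += b;
    return k;
  }

  // try to bind LEF `id`; returns event code (EV_BIND or EV_BIND_REJECT)
  int bind_attempt(int id, EventLog& log) {
    int li = -1;
    if (loading.empty()) {
      // uniform over admissible adjacent pairs (i, i+1)
      if (!phantom) {
        bool found = false;
        for (int tries = 0; tries < 64; ++tries) {
          int i = rng.unif_int(n - 1);
          if (occ[i] == 0 && occ[i + 1] == 0) { li = i; found = true; break; }
        }
        if (!found) {
          // exact fallback: enumerate admissible pairs
          std::vector<int> adm;
          for (int i = 0; i < n - 1; ++i)
            if (occ[i] == 0 && occ[i + 1] == 0) adm.push_back(i);
          if (adm.empty()) { log.add(time, EV_BIND_REJECT, id, -1, -1); return EV_BIND_REJECT; }
          li = adm[rng.unif_int((int)adm.size())];
        }
      } else {
        li = rng.unif_int(n - 1);
      }
    } else {
      int s = loading[rng.unif_int((int)loading.size())];
      if (s + 1 >= n || (!phantom && (occ[s] != 0 || occ[s + 1] != 0))) {
        log.add(time, EV_BIND_REJECT, id, -1, s);
        return EV_BIND_REJECT;
      }
      li = s;
    }
    bound[id] = 1;
    left[id] = li;
    right[id] = li + 1;
    occ[li]++; occ[li + 1]++;
    if (symmetric) {
      lmob[id] = 1; rmob[id] = 1;
    } else {
      bool left_is_mobile = rng.unif() < 0.5;
      lmob[id] = left_is_mobile ? 1 : 0;
      rmob[id] = left_is_mobile ? 0 : 1;
    }
    log.add(time, EV_BIND, id, -1, li);
    return EV_BIND;
  }

  void unbind(int id, EventLog& log) {
    occ[left[id]]--; occ[right[id]]--;
    bound[id] = 0;
    log.add(time, EV_UNBIND, id, -1, left[id]);
  }

  // leg: 0 = left (moves toward smaller indices), 1 = right
  int step_attempt(int id, int leg, EventLog& log) {
    int cur = leg == 0 ? left[id] : right[id];
    int dir = leg == 0 ? -1 : +1;
    int tgt = cur + dir;
    if (tgt < 0 || tgt >= n) {
      log.add(time, EV_STALL_BOUNDARY, id, leg, cur);
      return EV_STALL_BOUNDARY;
    }
    double p = dir < 0 ? pass_left[tgt] : pass_right[tgt];
    bool gated = dir < 0 ? block_left[tgt] != 0 : block_right[tgt] != 0;
    if (gated) {
      bool pass = p >= 1.0 ? true : (p <= 0.0 ? false : rng.unif() < p);
      if (!pass) {
        log.add(time, EV_STALL_BOUNDARY, id, leg, cur);
        return EV_STALL_BOUNDARY;
      }
    }
    int code = EV_STEP;
    if (occ[tgt] > 0) {
      if (!phantom) {
        log.add(time, EV_STALL_COLLISION, id, leg, cur);
        return EV_STALL_COLLISION;
      }
      code = EV_CROSS_PHANTOM;
    } else if (gated) {
      code = EV_PASS_BOUNDARY;
    }
    occ[cur]--; occ[tgt]++;
    if (leg == 0) left[id] = tgt; else right[id] = tgt;
    log.add(time, code, id, leg, tgt);
    return code;
  }
};

static LefState parse_state(const List& st) {
  LefState s;
  s.n = as<int>(st["n_monomers"]);
  s.pass_left = as<std::vector<double>>(st["pass_left"]);
  s.pass_right = as<std::vector<double>>(st["pass_right"]);
  s.block_left = as<std::vector<int>>(st["block_left"]);
  s.block_right = as<std::vector<int>>(st["block_right"]);
  s.loading = as<std::vector<int>>(st["loading_sites"]);
  s.symmetric = as<bool>(st["symmetric"]);
  s.phantom = as<bool>(st["phantom"]);
  s.k_bind = as<double>(st["k_bind"]);
  s.k_unbind = as<double>(st["k_unbind"]);
  s.step_rate = as<double>(st["step_rate"]);
  s.left = as<std::vector<int>>(st["left"]);
  s.right = as<std::vector<int>>(st["right"]);
  s.bound = as<std::vector<int>>(st["bound"]);
  s.lmob = as<std::vector<int>>(st["left_mobile"]);
  s.rmob = as<std::vector<int>>(st["right_mobile"]);
  s.time = as<double>(st["time_min"]);
  s.rng = Xoshiro::load(as<RawVector>(st["rng_state"]));
  s.occ.assign(s.n, 0);
  for (int i = 0; i < s.pool(); ++i)
    if (s.bound[i]) { s.occ[s.left[i]]++; s.occ[s.right[i]]++; }
  return s;
}

static List state_to_list(const LefState& s, const List& tmpl) {
  List out = clone(tmpl);
  out["left"] = wrap(s.left);
  out["right"] = wrap(s.right);
  out["bound"] = wrap(s.bound);
  out["left_mobile"] = wrap(s.lmob);
  out["right_mobile"] = wrap(s.rmob);
  out["time_min"] = s.time;
  out["rng_state"] = s.rng.save();
  return out;
}

// state index for single-LEF occupancy tracking: 0 = unbound,
// 1 + 2*(l*n + r) + mobility_bit with bit 1 when only the right leg is mobile
static int state_index(const LefState& s) {
  for (int i = 0; i < s.pool(); ++i) {
    if (s.bound[i]) {
      int bit = (!s.symmetric && s.rmob[i] && !s.lmob[i]) ? 1 : 0;
      return 1 + 2 * (s.left[i] * s.n + s.right[i]) + bit;
    }
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_lef_advance(List state, double duration, bool record_events,
                     double sample_dt, bool record_samples,
                     int track_batches) {
  LefState s = parse_state(state);
  EventLog log; log.record = record_events;

  const double t0 = s.time, t_end = t0 + duration;
  double next_sample = sample_dt > 0 ? t0 + sample_dt : R_PosInf;

  std::vector<double> occupancy(s.n, 0.0);
  int n_samples = 0;
  // flat per-sample records of bound LEF legs
  std::vector<int> smp_idx, smp_lef, smp_l, smp_r;
  std::vector<double> smp_time;

  // accumulators (time integrals, monomer units for loop length)
  double loop_integral = 0.0, bound_integral = 0.0;
  long n_unbind_events = 0;
  std::vector<long> counts(8, 0);

  NumericMatrix state_time;
  int n_states = 0;
  double batch_len = 0.0;
  if (track_batches > 0) {
    n_states = 1 + 2 * s.n * s.n;
    state_time = NumericMatrix(n_states, track_batches);
    batch_len = duration / track_batches;
  }

  const double eps = 1e-9;
  double t = t0;
  while (t < t_end - eps) {
    int nb = s.n_bound();
    int nu = s.pool() - nb;
    int legs_per = s.symmetric ? 2 : 1;
    int n_legs = nb * legs_per;
    double r_bind = nu * s.k_bind;
    double r_unbind = nb * s.k_unbind;
    double r_step = n_legs * s.step_rate;
    double total = r_bind + r_unbind + r_step;

    double t_next = total > 0 ? t + s.rng.expo(total) : R_PosInf;
    double t_evt = std::min(t_next, t_end);

    // interval [t, t_evt) has constant state: samples + integrals
    while (next_sample <= t_evt + eps && next_sample <= t_end + eps) {
      n_samples++;
      for (int i = 0; i < s.pool(); ++i) {
        if (s.bound[i]) {
          occupancy[s.left[i]] += 1.0;
          occupancy[s.right[i]] += 1.0;
          if (record_samples) {
            smp_idx.push_back(n_samples);
            smp_time.push_back(next_sample);
            smp_lef.push_back(i);
            smp_l.push_back(s.left[i]);
            smp_r.push_back(s.right[i]);
          }
        }
      }
      next_sample += sample_dt;
    }

    double span = t_evt - t;
    bound_integral += span * nb;
    double loops = 0.0;
    for (int i = 0; i < s.pool(); ++i)
      if (s.bound[i]) loops += s.right[i] - s.left[i];
    loop_integral += span * loops;

    if (track_batches > 0 && span > 0) {
      int si = state_index(s);
      double a = t;
      while (a < t_evt - eps) {
        int b = (int)((a - t0) / batch_len);
        if (b >= track_batches) b = track_batches - 1;
        double b_end = std::min(t_evt, t0 + (b + 1) * batch_len);
        state_time(si, b) += b_end - a;
        a = b_end;
      }
    }

    if (t_next >= t_end) break;
    t = t_next;
    s.time = t;

    double u = s.rng.unif() * total;
    int code;
    if (u < r_bind) {
      int k = s.rng.unif_int(nu), id = -1;
      for (int i = 0; i < s.pool(); ++i)
        if (!s.bound[i] && k-- == 0) { id = i; break; }
      code = s.bind_attempt(id, log);
    } else if (u < r_bind + r_unbind) {
      int k = s.rng.unif_int(nb), id = -1;
      for (int i = 0; i < s.pool(); ++i)
        if (s.bound[i] && k-- == 0) { id = i; break; }
      s.unbind(id, log);
      code = EV_UNBIND;
      n_unbind_events++;
    } else {
      int k = s.rng.unif_int(n_legs), id = -1, leg = -1;
      for (int i = 0; i < s.pool() && id < 0; ++i) {
        if (!s.bound[i]) continue;
        if (s.symmetric) {
          if (k == 0) { id = i; leg = 0; }
          else if (k == 1) { id = i; leg = 1; }
          k -= 2;
        } else {
          if (k == 0) { id = i; leg = s.rmob[i] ? 1 : 0; }
          k -= 1;
        }
      }
      code = s.step_attempt(id, leg, log);
    }
    counts[code]++;
  }
  s.time = t_end;

  List ev = List::create(
    _["time_min"] = wrap(log.time), _["kind"] = wrap(log.kind),
    _["lef"] = wrap(log.lef), _["leg"] = wrap(log.leg), _["pos"] = wrap(log.pos));
  List samples = List::create(
    _["n_samples"] = n_samples, _["sample"] = wrap(smp_idx),
    _["time_min"] = wrap(smp_time), _["lef"] = wrap(smp_lef),
    _["left"] = wrap(smp_l), _["right"] = wrap(smp_r));
  List stats = List::create(
    _["loop_integral_monomer_min"] = loop_integral,
    _["bound_integral_lef_min"] = bound_integral,
    _["n_unbind"] = (double)n_unbind_events,
    _["event_counts"] = wrap(counts),
    _["duration_min"] = duration);

  List out = List::create(
    _["state"] = state_to_list(s, state),
    _["events"] = ev,
    _["occupancy"] = wrap(occupancy),
    _["samples"] = samples,
    _["stats"] = stats);
  if (track_batches > 0) out["state_time"] = state_time;
  return out;
}

// [[Rcpp::export]]
List cpp_lef_bind(List state, int lef_id) {
  LefState s = parse_state(state);
  if (s.bound[lef_id]) stop("LEF %d is already bound", lef_id);
  EventLog log; log.record = true;
  int code = s.bind_attempt(lef_id, log);
  return List::create(_["state"] = state_to_list(s, state), _["code"] = code);
}

// [[Rcpp::export]]
List cpp_lef_step(List state, int lef_id, int leg) {
  LefState s = parse_state(state);
  if (!s.bound[lef_id]) stop("LEF %d is not bound; cannot translocate", lef_id);
  bool mob = leg == 0 ? s.lmob[lef_id] : s.rmob[lef_id];
  if (!mob) stop("leg is anchored (asymmetric extrusion); cannot translocate");
  EventLog log; log.record = true;
  int code = s.step_attempt(lef_id, leg, log);
  return List::create(_["state"] = state_to_list(s, state), _["code"] = code);
}
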