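#include "rng.h"
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct EnergyPar {
  double bond_k, bond_rest, bend_k, loop_k, hardcore, bond_min, bond_max;
};

static EnergyPar parse_model(const List& m) {
  EnergyPar p;
  p.bond_k = as<double>(m["bond_k"]);
  p.bond_rest = as<double>(m["bond_rest_nm"]);
  p.bend_k = as<double>(m["bend_k"]);
  p.loop_k = as<double>(m["loop_k"]);
  p.hardcore = as<double>(m["hardcore_nm"]);
  p.bond_min = as<double>(m["bond_min_nm"]);
  p.bond_max = as<double>(m["bond_max_nm"]);
  return p;
}

static inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// uniform direction on the unit sphere (Marsaglia)
static inline void rand_dir(Xoshiro& rng, double* d) {
  double x1, x2, ss;
  do {
    x1 = 2.0 * rng.unif() - 1.0;
    x2 = 2.0 * rng.unif() - 1.0;
    ss = x1 * x1 + x2 * x2;
  } while (ss >= 1.0);
  double f = 2.0 * std::sqrt(1.0 - ss);
  d[0] = x1 * f;
  d[1] = x2 * f;
  d[2] = 1.0 - 2.0 * ss;
}

// Grow a self-avoiding random walk with fixed bond length; backtracks on
// dead ends. Coordinates in nm, bead 0 at the origin.
// [[Rcpp::export]]
NumericMatrix cpp_grow_chain(int n, double bond, double hardcore, int seed,
                             int max_backtrack) {
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(3 * n, 0.0);
  int backtracks = 0;
  int i = 1;
  while (i < n) {
    bool placed = false;
    for (int tr = 0; tr < 100 && !placed; ++tr) {
      double d[3];
      rand_dir(rng, d);
      double cx = x[3 * (i - 1)] + bond * d[0];
      double cy = x[3 * (i - 1) + 1] + bond * d[1];
      double cz = x[3 * (i - 1) + 2] + bond * d[2];
      bool ok = true;
      if (hardcore > 0) {
        for (int j = 0; j <= i - 2; ++j) {
          double dx = cx - x[3 * j], dy = cy - x[3 * j + 1], dz = cz - x[3 * j + 2];
          if (dx * dx + dy * dy + dz * dz < hardcore * hardcore) { ok = false; break; }
        }
      }
      if (ok) {
        x[3 * i] = cx; x[3 * i + 1] = cy; x[3 * i + 2] = cz;
        placed = true;
      }
    }
    if (placed) {
      ++i;
    } else {
      if (++backtracks > max_backtrack)
        stop("chain growth failed after %d backtracks; reduce density or hard-core diameter", backtracks);
      if (i > 1) --i;
    }
  }
  NumericMatrix out(n, 3);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = x[3 * k + c];
  return out;
}

// [[Rcpp::export]]
List cpp_polymer_energy(NumericMatrix pos, IntegerMatrix loops, List model) {
  EnergyPar p = parse_model(model);
  int n = pos.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xyz[3 * i + c] = pos(i, c);

  bool violated = false;
  double e_bond = 0.0, e_bend = 0.0, e_loop = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double d = dist3(&xyz[3 * i], &xyz[3 * (i + 1)]);
    if (d < p.bond_min || d > p.bond_max) violated = true;
    e_bond += p.bond_k * (d - p.bond_rest) * (d - p.bond_rest);
  }
  for (int j = 1; j + 1 < n; ++j) {
    double b1[3], b2[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = xyz[3 * j + c] - xyz[3 * (j - 1) + c];
      b2[c] = xyz[3 * (j + 1) + c] - xyz[3 * j + c];
    }
    double n1 = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2]);
    double n2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    double ct = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (n1 * n2);
    e_bend += p.bend_k * (1.0 - ct);
  }
  for (int l = 0; l < loops.nrow(); ++l) {
    double d = dist3(&xyz[3 * loops(l, 0)], &xyz[3 * loops(l, 1)]);
    e_loop += p.loop_k * (d - p.bond_rest) * (d - p.bond_rest);
  }
  if (p.hardcore > 0) {
    for (int i = 0; i < n && !violated; ++i)
      for (int j = i + 2; j < n; ++j) {
        double dx = xyz[3 * i] - xyz[3 * j], dy = xyz[3 * i + 1] - xyz[3 * j + 1],
               dz = xyz[3 * i + 2] - xyz[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < p.hardcore * p.hardcore) { violated = true; break; }
      }
  }
  double total = violated ? R_PosInf : e_bond + e_bend + e_loop;
  return List::create(_["total"] = total, _["bond"] = e_bond, _["bend"] = e_bend,
                      _["loop"] = e_loop, _["violated"] = violated);
}

// Metropolis single-bead displacement sweeps. Chain bonds are restricted to
// [bond_min, bond_max] (hard window) and beads to pairwise distance
// >= hardcore; both enter the acceptance rule as infinite-energy rejections,
// so detailed balance w.r.t. the total energy is preserved.
// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos, IntegerMatrix loops, List model,
                double temperature, double max_disp, int n_sweeps,
                RawVector rng_state) {
  EnergyPar p = parse_model(model);
  Xoshiro rng = Xoshiro::load(rng_state);
  int n = pos.nrow();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xyz[3 * i + c] = pos(i, c);

  // loop bonds incident to each bead
  std::vector<std::vector<int>> inc(n);
  for (int l = 0; l < loops.nrow(); ++l) {
    inc[loops(l, 0)].push_back(loops(l, 1));
    inc[loops(l, 1)].push_back(loops(l, 0));
  }

  const double hc2 = p.hardcore * p.hardcore;
  long accepted = 0;
  long attempted = (long)n_sweeps * n;

  auto bond_e = [&](const double* a, const double* b) {
    double d = dist3(a, b);
    if (d < p.bond_min || d > p.bond_max) return R_PosInf;
    return p.bond_k * (d - p.bond_rest) * (d - p.bond_rest);
  };
  auto loop_e = [&](const double* a, const double* b) {
    double d = dist3(a, b);
    return p.loop_k * (d - p.bond_rest) * (d - p.bond_rest);
  };
  auto angle_e = [&](const double* a, const double* b, const double* c) {
    double b1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double b2[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
    double n1 = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2]);
    double n2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    double ct = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (n1 * n2);
    return p.bend_k * (1.0 - ct);
  };

  // local energy of bead i at position q (other beads fixed)
  auto local_e = [&](int i, const double* q) {
    double e = 0.0;
    if (i > 0) e += bond_e(&xyz[3 * (i - 1)], q);
    if (i + 1 < n) e += bond_e(q, &xyz[3 * (i + 1)]);
    if (!R_FINITE(e)) return e;
    // bending terms whose center is i-1, i or i+1 involve bead i
    if (i >= 2) e += angle_e(&xyz[3 * (i - 2)], &xyz[3 * (i - 1)], q);
    if (i >= 1 && i + 1 < n) e += angle_e(&xyz[3 * (i - 1)], q, &xyz[3 * (i + 1)]);
    if (i + 2 < n) e += angle_e(q, &xyz[3 * (i + 1)], &xyz[3 * (i + 2)]);
    for (int j : inc[i]) e += loop_e(q, &xyz[3 * j]);
    return e;
  };

  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int tr = 0; tr < n; ++tr) {
      int i = rng.unif_int(n);
      double q[3] = {
        xyz[3 * i] + max_disp * (2.0 * rng.unif() - 1.0),
        xyz[3 * i + 1] + max_disp * (2.0 * rng.unif() - 1.0),
        xyz[3 * i + 2] + max_disp * (2.0 * rng.unif() - 1.0)};
      // excluded volume against all non-bonded beads
      if (p.hardcore > 0) {
        bool clash = false;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = q[0] - xyz[3 * j], dy = q[1] - xyz[3 * j + 1],
                 dz = q[2] - xyz[3 * j + 2];
          if (std::abs(i - j) == 1) continue;  // bond window handles neighbours
          if (dx * dx + dy * dy + dz * dz < hc2) { clash = true; break; }
        }
        if (clash) continue;
      }
      double e_old = local_e(i, &xyz[3 * i]);
      double e_new = local_e(i, q);
      if (!R_FINITE(e_new)) continue;
      double de = e_new - e_old;
      if (de <= 0 || rng.unif() < std::exp(-de / temperature)) {
        xyz[3 * i] = q[0]; xyz[3 * i + 1] = q[1]; xyz[3 * i + 2] = q[2];
        ++accepted;
      }
    }
  }

  NumericMatrix out(n, 3);
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 3; ++c) out(k, c) = xyz[3 * k + c];
  return List::create(_["positions"] = out,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted,
                      _["rng_state"] = rng.save());
}

// [[Rcpp::export]]
List cpp_check_conformation(NumericMatrix pos, IntegerMatrix loops,
                            double bond_min, double bond_max, double hardcore) {
  int n = pos.nrow();
  double min_bond = R_PosInf, max_bond = 0.0, min_pair = R_PosInf, max_loop = 0.0;
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xyz[3 * i + c] = pos(i, c);
  for (int i = 0; i + 1 < n; ++i) {
    double d = dist3(&xyz[3 * i], &xyz[3 * (i + 1)]);
    if (d < min_bond) min_bond = d;
    if (d > max_bond) max_bond = d;
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double d = dist3(&xyz[3 * i], &xyz[3 * j]);
      if (d < min_pair) min_pair = d;
    }
  for (int l = 0; l < loops.nrow(); ++l) {
    double d = dist3(&xyz[3 * loops(l, 0)], &xyz[3 * loops(l, 1)]);
    if (d > max_loop) max_loop = d;
  }
  bool bond_ok = n < 2 || (min_bond >= bond_min && max_bond <= bond_max);
  bool ev_ok = hardcore <= 0 || n < 3 || min_pair >= hardcore;
  bool loop_ok = loops.nrow() == 0 || max_loop <= bond_max;
  return List::create(_["bond_ok"] = bond_ok, _["excluded_volume_ok"] = ev_ok,
                      _["loop_ok"] = loop_ok, _["min_bond_nm"] = min_bond,
                      _["max_bond_nm"] = max_bond, _["min_nonadjacent_nm"] = min_pair,
                      _["max_loop_nm"] = max_loop);
}
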