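#include "rng.h"
#include <Rcpp.h>
#include <map>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Sum over snapshots of contacting monomer pairs (i < j, Euclidean distance
// <= cutoff) accumulated into symmetric bin-pair counts.
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(List pos_list, double cutoff,
                                 IntegerVector bin_idx, int n_bins) {
  NumericMatrix acc(n_bins, n_bins);
  const double c2 = cutoff * cutoff;
  for (int s = 0; s < pos_list.size(); ++s) {
    NumericMatrix pos = pos_list[s];
    int n = pos.nrow();
    std::vector<double> xyz(3 * n);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) xyz[3 * i + c] = pos(i, c);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = xyz[3 * i] - xyz[3 * j];
        double dy = xyz[3 * i + 1] - xyz[3 * j + 1];
        double dz = xyz[3 * i + 2] - xyz[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz <= c2) {
          int a = bin_idx[i], b = bin_idx[j];
          acc(a, b) += 1.0;
          if (a != b) acc(b, a) += 1.0;
        }
      }
    }
  }
  return acc;
}

// Number of distinct monomer pairs (i < j) mapping to each bin pair;
// used to normalize counts into per-pair contact probabilities.
// [[Rcpp::export]]
NumericMatrix cpp_pair_multiplicity(IntegerVector bin_idx, int n_bins) {
  int n = bin_idx.size();
  std::vector<double> per_bin(n_bins, 0.0);
  for (int i = 0; i < n; ++i) per_bin[bin_idx[i]] += 1.0;
  NumericMatrix mult(n_bins, n_bins);
  for (int a = 0; a < n_bins; ++a)
    for (int b = 0; b < n_bins; ++b)
      mult(a, b) = a == b ? per_bin[a] * (per_bin[a] - 1.0) / 2.0
                          : per_bin[a] * per_bin[b];
  return mult;
}

// Triplets (i < j < k) with all three pairwise distances <= cutoff, pooled
// into canonical bin triplets. Optional per-snapshot cap: when the number of
// triplets in a snapshot exceeds the cap, triplets are kept i.i.d. with
// probability cap/total and counted with weight total/kept (unbiased).
// [[Rcpp::export]]
DataFrame cpp_triplet_counts(List pos_list, double cutoff, IntegerVector bin_idx,
                             int max_per_snapshot, int seed) {
  const double c2 = cutoff * cutoff;
  Xoshiro rng((uint64_t)(seed < 0 ? 0 : seed));
  std::map<std::tuple<int, int, int>, double> counts;

  for (int s = 0; s < pos_list.size(); ++s) {
    NumericMatrix pos = pos_list[s];
    int n = pos.nrow();
    std::vector<double> xyz(3 * n);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) xyz[3 * i + c] = pos(i, c);
    // neighbor lists j > i
    std::vector<std::vector<int>> nb(n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = xyz[3 * i] - xyz[3 * j], dy = xyz[3 * i + 1] - xyz[3 * j + 1],
               dz = xyz[3 * i + 2] - xyz[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz <= c2) nb[i].push_back(j);
      }
    std::vector<std::tuple<int, int, int>> snap;
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& v = nb[i];
      for (size_t a = 0; a < v.size(); ++a)
        for (size_t b = a + 1; b < v.size(); ++b) {
          int j = v[a], k = v[b];
          double dx = xyz[3 * j] - xyz[3 * k], dy = xyz[3 * j + 1] - xyz[3 * k + 1],
                 dz = xyz[3 * j + 2] - xyz[3 * k + 2];
          if (dx * dx + dy * dy + dz * dz <= c2)
            snap.push_back(std::make_tuple(bin_idx[i], bin_idx[j], bin_idx[k]));
        }
    }
    if (max_per_snapshot > 0 && (int)snap.size() > max_per_snapshot) {
      double p = (double)max_per_snapshot / (double)snap.size();
      std::vector<std::tuple<int, int, int>> kept;
      for (auto& t : snap)
        if (rng.unif() < p) kept.push_back(t);
      double w = kept.empty() ? 0.0 : (double)snap.size() / (double)kept.size();
      for (auto& t : kept) counts[t] += w;
    } else {
      for (auto& t : snap) counts[t] += 1.0;
    }
  }

  int m = counts.size();
  IntegerVector bi(m), bj(m), bk(m);
  NumericVector cnt(m);
  int r = 0;
  for (auto& kv : counts) {
    bi[r] = std::get<0>(kv.first);
    bj[r] = std::get<1>(kv.first);
    bk[r] = std::get<2>(kv.first);
    cnt[r] = kv.second;
    ++r;
  }
  return DataFrame::create(_["bin_i"] = bi, _["bin_j"] = bj, _["bin_k"] = bk,
                           _["count"] = cnt);
}

// Fresh RNG state for a given integer seed.
// [[Rcpp::export]]
RawVector cpp_rng_state(int seed) {
  return Xoshiro((uint64_t)(uint32_t)seed).save();
}

// Stable cross-platform seed derivation for replicate / grid-cell streams.
// [[Rcpp::export]]
int cpp_derive_seed(int master, int a, int b) {
  uint64_t x = (uint64_t)(uint32_t)master;
  uint64_t h = Xoshiro::splitmix(x);
  x = h ^ ((uint64_t)(uint32_t)a * 0x9E3779B97F4A7C15ULL);
  h = Xoshiro::splitmix(x);
  x = h ^ ((uint64_t)(uint32_t)b * 0xBF58476D1CE4E5B9ULL);
  h = Xoshiro::splitmix(x);
  return (int)(h % 2147483647ULL) + 1;  // in [1, 2^31 - 1]
}
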