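#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multiscale bootstrap engine for correlation-distance UPGMA.
//
// Feature rows are the resampling units. For every (scale, replicate) a
// deterministic PRNG stream draws sample-size rows with replacement, the
// pairwise Pearson correlation distance between complexes is recomputed,
// a UPGMA tree is built (ties broken by the smallest pair of minimal
// original leaf indices), and every reference membership set found among
// the replicate's merges increments that edge's count for the scale.
//
// Membership sets are bitmasks over leaves (hence <= 64 complexes, far
// above anything this pipeline clusters). The PRNG is mt19937_64 seeded
// per (seed, scale, replicate) through a splitmix64 finalizer, so every
// replicate is independently reproducible and results do not depend on
// execution order.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// UPGMA over an n x n distance matrix (row-major vector, d[i*n+j]);
// appends the n-1 merge membership masks to `out`.
static void upgma_masks(std::vector<double> &d, int n,
                        std::vector<uint64_t> &out) {
  std::vector<uint64_t> mask(n);
  std::vector<int> rep(n), size(n), active;
  active.reserve(n);
  for (int i = 0; i < n; ++i) {
    mask[i] = 1ULL << i;
    rep[i] = i;
    size[i] = 1;
    active.push_back(i);
  }
  for (int step = 0; step < n - 1; ++step) {
    int na = (int)active.size();
    double best = R_PosInf;
    int bi = -1, bj = -1, bra = 0, brb = 0;
    for (int a = 0; a < na; ++a) {
      for (int b = a + 1; b < na; ++b) {
        int ia = active[a], ib = active[b];
        double dd = d[ia * n + ib];
        int ra = rep[ia] < rep[ib] ? rep[ia] : rep[ib];
        int rb = rep[ia] < rep[ib] ? rep[ib] : rep[ia];
        if (dd < best ||
            (dd == best && (ra < bra || (ra == bra && rb < brb)))) {
          best = dd; bi = a; bj = b; bra = ra; brb = rb;
        }
      }
    }
    int ia = active[bi], ib = active[bj];
    // size-weighted Lance-Williams update = unweighted mean over member pairs
    for (int c = 0; c < na; ++c) {
      int ic = active[c];
      if (ic == ia || ic == ib) continue;
      double nd = (size[ia] * d[ia * n + ic] + size[ib] * d[ib * n + ic]) /
                  (double)(size[ia] + size[ib]);
      d[ia * n + ic] = nd;
      d[ic * n + ia] = nd;
    }
    mask[ia] |= mask[ib];
    size[ia] += size[ib];
    rep[ia] = bra;
    active.erase(active.begin() + bj);
    out.push_back(mask[ia]);
  }
}

static void corr_distance(const std::vector<double> &s1,
                          const std::vector<double> &s2,
                          const std::vector<double> &cross,
                          int n, int m, std::vector<double> &d) {
  for (int i = 0; i < n; ++i) {
    d[i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double vi = m * s2[i] - s1[i] * s1[i];
      double vj = m * s2[j] - s1[j] * s1[j];
      double cv = m * cross[i * n + j] - s1[i] * s1[j];
      double dd;
      if (vi <= 0.0 || vj <= 0.0) dd = 1.0;  // degenerate: treat as uncorrelated
      else dd = 1.0 - cv / std::sqrt(vi * vj);
      d[i * n + j] = dd;
      d[j * n + i] = dd;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix boot_counts_cpp(NumericMatrix X, IntegerMatrix refSets,
                              IntegerVector sampleSizes, int nBoot,
                              double seed) {
  const int nf = X.nrow(), n = X.ncol();
  const int nEdges = refSets.nrow(), nScales = sampleSizes.size();
  if (n > 64) stop("bootstrap engine supports at most 64 complexes");

  std::vector<uint64_t> ref(nEdges);
  for (int e = 0; e < nEdges; ++e) {
    uint64_t msk = 0;
    for (int c = 0; c < n; ++c)
      if (refSets(e, c)) msk |= 1ULL << c;
    ref[e] = msk;
  }

  IntegerMatrix counts(nEdges, nScales);
  std::vector<double> s1(n), s2(n), cross(n * n), d(n * n);
  std::vector<uint64_t> merges;
  merges.reserve(n);
  const uint64_t sd = (uint64_t)(int64_t)seed;

  for (int s = 0; s < nScales; ++s) {
    const int m = sampleSizes[s];
    for (int rep = 0; rep < nBoot; ++rep) {
      uint64_t mix = splitmix64(sd ^ splitmix64(((uint64_t)(s + 1) << 32) ^
                                                (uint64_t)(rep + 1)));
      std::mt19937_64 rng(mix);
      std::fill(s1.begin(), s1.end(), 0.0);
      std::fill(s2.begin(), s2.end(), 0.0);
      std::fill(cross.begin(), cross.end(), 0.0);
      for (int t = 0; t < m; ++t) {
        int r = (int)(rng() % (uint64_t)nf);
        for (int i = 0; i < n; ++i) {
          double v = X(r, i);
          s1[i] += v;
          s2[i] += v * v;
          for (int j = i + 1; j < n; ++j)
            cross[i * n + j] += v * X(r, j);
        }
      }
      corr_distance(s1, s2, cross, n, m, d);
      merges.clear();
      upgma_masks(d, n, merges);
      for (size_t k = 0; k < merges.size(); ++k)
        for (int e = 0; e < nEdges; ++e)
          if (merges[k] == ref[e]) { counts(e, s)++; break; }
    }
  }
  return counts;
}

// Membership masks of the UPGMA tree on the full data (no resampling);
// used to cross-check the R implementation against the replicate engine.
// [[Rcpp::export]]
IntegerMatrix upgma_masks_cpp(NumericMatrix dist) {
  const int n = dist.nrow();
  if (n > 64) stop("at most 64 leaves supported");
  std::vector<double> d(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i * n + j] = dist(i, j);
  std::vector<uint64_t> merges;
  upgma_masks(d, n, merges);
  IntegerMatrix out((int)merges.size(), n);
  for (size_t k = 0; k < merges.size(); ++k)
    for (int c = 0; c < n; ++c)
      out((int)k, c) = (merges[k] >> c) & 1ULL ? 1 : 0;
  return out;
}
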