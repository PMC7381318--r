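// PAM k-medoids and stochastic local-search core selection.
//
// Both routines are deterministic given their seed: randomness comes from a
// self-contained splitmix64 generator, independent of R's RNG state and of
// the platform's standard-library distributions.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

const double EPS = 1e-12;
const double INF = std::numeric_limits<double>::infinity();

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n), rejection-free of modulo bias
  int bounded(int n) {
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do { x = next(); } while (x >= lim);
    return (int)(x % (uint64_t)n);
  }
};

// nearest and second-nearest medoid caches
void pam_caches(const NumericMatrix& D, const std::vector<int>& med,
                std::vector<double>& dn, std::vector<double>& ds,
                std::vector<int>& nearj) {
  int N = D.nrow(), k = med.size();
  for (int o = 0; o < N; ++o) {
    double b1 = INF, b2 = INF; int j1 = -1;
    for (int j = 0; j < k; ++j) {
      double d = D(o, med[j]);
      if (d < b1) { b2 = b1; b1 = d; j1 = j; }
      else if (d < b2) { b2 = d; }
    }
    dn[o] = b1; ds[o] = b2; nearj[o] = j1;
  }
}

} // namespace

// PAM: BUILD (greedy, tie-break lowest index) unless initial medoids are
// given, then best-improving SWAP until no exchange lowers the total cost.
// init: 0-based medoid indices, or empty to run BUILD.
// [[Rcpp::export]]
List cpp_pam(NumericMatrix D, int k, IntegerVector init) {
  int N = D.nrow();
  if (k < 1 || k > N) stop("k must be in [1, N]");
  std::vector<int> med;
  std::vector<bool> isMed(N, false);

  if (init.size() > 0) {
    if ((int)init.size() != k) stop("initial medoids must have length k");
    for (int i = 0; i < k; ++i) {
      int m = init[i];
      if (m < 0 || m >= N) stop("initial medoid index out of range");
      if (isMed[m]) stop("duplicate initial medoids");
      isMed[m] = true; med.push_back(m);
    }
  } else {
    // BUILD: start from the accession minimizing total distance to all
    double best = INF; int b = 0;
    for (int i = 0; i < N; ++i) {
      double s = 0;
      for (int j = 0; j < N; ++j) s += D(i, j);
      if (s < best - EPS) { best = s; b = i; }
    }
    med.push_back(b); isMed[b] = true;
    std::vector<double> dn(N);
    for (int o = 0; o < N; ++o) dn[o] = D(o, b);
    while ((int)med.size() < k) {
      double bestGain = -INF; int bi = -1;
      for (int c = 0; c < N; ++c) {
        if (isMed[c]) continue;
        double gain = 0;
        for (int o = 0; o < N; ++o) {
          double diff = dn[o] - D(o, c);
          if (diff > 0) gain += diff;
        }
        if (gain > bestGain + EPS) { bestGain = gain; bi = c; }
      }
      med.push_back(bi); isMed[bi] = true;
      for (int o = 0; o < N; ++o) dn[o] = std::min(dn[o], D(o, bi));
    }
  }

  // SWAP phase: best-improving exchange, deltas via nearest/second caches
  std::vector<double> dn(N), ds(N);
  std::vector<int> nearj(N);
  pam_caches(D, med, dn, ds, nearj);
  std::vector<double> dj(k);
  for (int iter = 0; iter < 10000; ++iter) {
    double bestDelta = -EPS; int bh = -1, bj = -1;
    for (int h = 0; h < N; ++h) {
      if (isMed[h]) continue;
      double shared = 0;
      std::fill(dj.begin(), dj.end(), 0.0);
      for (int o = 0; o < N; ++o) {
        double doh = D(o, h);
        double sharedCase = doh < dn[o] ? doh - dn[o] : 0.0;
        shared += sharedCase;
        double removalCase = std::min(doh, ds[o]) - dn[o];
        dj[nearj[o]] += removalCase - sharedCase;
      }
      for (int j = 0; j < k; ++j) {
        double delta = shared + dj[j];
        if (delta < bestDelta) { bestDelta = delta; bh = h; bj = j; }
      }
    }
    if (bh < 0) break;
    isMed[med[bj]] = false; isMed[bh] = true; med[bj] = bh;
    pam_caches(D, med, dn, ds, nearj);
  }

  double cost = 0;
  for (int o = 0; o < N; ++o) cost += dn[o];
  std::sort(med.begin(), med.end());
  pam_caches(D, med, dn, ds, nearj);
  IntegerVector medoids(k), assignment(N);
  for (int j = 0; j < k; ++j) medoids[j] = med[j] + 1;
  for (int o = 0; o < N; ++o) assignment[o] = med[nearj[o]] + 1;
  return List::create(_["medoids"] = medoids,
                      _["assignment"] = assignment,
                      _["cost"] = cost);
}

namespace {

// ---- local-search objective machinery -------------------------------
// objective codes: 1 ENE (max), 2 ANE (min), 3 Shannon (max),
// 4 expected heterozygosity (max), 5 allele coverage (max).
// Internally every objective is maximized as `score`.

struct SearchState {
  int objective, N, k, m;
  const NumericMatrix* D;
  const NumericMatrix* X;
  std::vector<double> Xt;      // row-contiguous copy: Xt[a*m + l]
  std::vector<int> sel;        // selected accession indices
  std::vector<char> inSel;     // size N
  std::vector<int> unsel;      // unselected accessions
  std::vector<int> unselPos;   // position of accession in unsel (-1 if sel)
  // ENE caches (size k): nearest other entry
  std::vector<double> e1, e2; std::vector<int> ei;
  // ANE caches (size N): nearest entry
  std::vector<double> a1, a2; std::vector<int> ai;
  // allele-count caches (size m)
  std::vector<double> cref, hl;
  std::vector<char> presRef, presAlt;
  double presTot = 0;
  double score = 0;

  double locus_term(double c) const {
    double tot = 2.0 * k;
    switch (objective) {
      case 3: { // Shannon: per-locus -f log f terms, f over the global pool
        double T = tot * m;
        double f1 = c / T, f2 = (tot - c) / T, t = 0;
        if (f1 > 0) t -= f1 * std::log(f1);
        if (f2 > 0) t -= f2 * std::log(f2);
        return t;
      }
      case 4: { // expected heterozygosity contribution
        double p = c / tot;
        return 2.0 * p * (1.0 - p);
      }
      default:
        return 0.0; // coverage terms are computed inline (need presence flags)
    }
  }

  void rebuild() {
    if (objective == 1) {
      e1.assign(k, INF); e2.assign(k, INF); ei.assign(k, -1);
      for (int a = 0; a < k; ++a) {
        for (int b = 0; b < k; ++b) {
          if (a == b) continue;
          double d = (*D)(sel[a], sel[b]);
          if (d < e1[a]) { e2[a] = e1[a]; e1[a] = d; ei[a] = b; }
          else if (d < e2[a]) e2[a] = d;
        }
      }
      double s = 0; for (int a = 0; a < k; ++a) s += e1[a];
      score = s;
    } else if (objective == 2) {
      a1.assign(N, INF); a2.assign(N, INF); ai.assign(N, -1);
      for (int o = 0; o < N; ++o) {
        for (int b = 0; b < k; ++b) {
          double d = (*D)(o, sel[b]);
          if (d < a1[o]) { a2[o] = a1[o]; a1[o] = d; ai[o] = b; }
          else if (d < a2[o]) a2[o] = d;
        }
      }
      double s = 0; for (int o = 0; o < N; ++o) s += a1[o];
      score = -s;
    } else {
      cref.assign(m, 0.0); hl.assign(m, 0.0);
      for (int a = 0; a < k; ++a) {
        const double* xa = &Xt[(size_t)sel[a] * m];
        for (int l = 0; l < m; ++l) cref[l] += 2.0 * xa[l];
      }
      double s = 0;
      if (objective == 5) {
        for (int l = 0; l < m; ++l) {
          double t = 0;
          if (cref[l] > 0.5 && presRef[l]) t += 1;
          if (2.0 * k - cref[l] > 0.5 && presAlt[l]) t += 1;
          hl[l] = t; s += t;
        }
      } else {
        for (int l = 0; l < m; ++l) { hl[l] = locus_term(cref[l]); s += hl[l]; }
      }
      score = s;
    }
  }

  // score of swapping selected position po for unselected accession u
  double try_swap(int po, int u) const {
    if (objective == 1) {
      double s = 0;
      for (int e = 0; e < k; ++e) {
        if (e == po) continue;
        double base = (ei[e] == po) ? e2[e] : e1[e];
        double d = (*D)(sel[e], u);
        s += std::min(base, d);
      }
      double bn = INF;
      for (int e = 0; e < k; ++e) {
        if (e == po) continue;
        bn = std::min(bn, (*D)(u, sel[e]));
      }
      return s + bn;
    } else if (objective == 2) {
      double s = 0;
      for (int o = 0; o < N; ++o) {
        double base = (ai[o] == po) ? a2[o] : a1[o];
        double d = (*D)(o, u);
        s += std::min(base, d);
      }
      return -s;
    } else {
      const double* xo = &Xt[(size_t)sel[po] * m];
      const double* xi = &Xt[(size_t)u * m];
      double s = score;
      for (int l = 0; l < m; ++l) {
        double co = 2.0 * xo[l], ci = 2.0 * xi[l];
        if (co == ci) continue;
        double c = cref[l] - co + ci;
        double t;
        if (objective == 5) {
          t = 0;
          if (c > 0.5 && presRef[l]) t += 1;
          if (2.0 * k - c > 0.5 && presAlt[l]) t += 1;
        } else t = locus_term(c);
        s += t - hl[l];
      }
      return s;
    }
  }

  void apply_swap(int po, int u) {
    int out = sel[po];
    if (objective >= 3) { // incremental count/contribution update
      const double* xo = &Xt[(size_t)out * m];
      const double* xi = &Xt[(size_t)u * m];
      for (int l = 0; l < m; ++l) {
        double co = 2.0 * xo[l], ci = 2.0 * xi[l];
        if (co == ci) continue;
        cref[l] += ci - co;
        double t;
        if (objective == 5) {
          t = 0;
          if (cref[l] > 0.5 && presRef[l]) t += 1;
          if (2.0 * k - cref[l] > 0.5 && presAlt[l]) t += 1;
        } else t = locus_term(cref[l]);
        score += t - hl[l];
        hl[l] = t;
      }
    }
    int up = unselPos[u];
    sel[po] = u; inSel[u] = 1; inSel[out] = 0;
    unsel[up] = out; unselPos[out] = up; unselPos[u] = -1;
    if (objective <= 2) rebuild();
  }

  // reported value on the statistic's natural scale
  double natural_value() const {
    switch (objective) {
      case 1: return score / k;
      case 2: return -score / N;
      case 3: return score;
      case 4: return score / m;
      default: return presTot > 0 ? score / presTot : 1.0;
    }
  }
};

} // namespace

// Stochastic random-descent subset selection. Per restart: seeded random
// initial k-subset, then repeated random (selected, unselected) swap
// proposals, accepting strictly improving ones, until the evaluation
// budget or the patience (evaluations since last improvement) is hit.
// Returns the best subset over all restarts.
// [[Rcpp::export]]
List cpp_local_search(int objective, NumericMatrix D, NumericMatrix X,
                      int k, int max_evals, int patience, int restarts,
                      double seed) {
  SearchState st;
  st.objective = objective;
  st.D = &D; st.X = &X;
  st.N = (objective <= 2) ? D.nrow() : X.nrow();
  st.m = (objective <= 2) ? 0 : X.ncol();
  st.k = k;
  int N = st.N;
  if (k < 1 || k > N) stop("k must be in [1, N]");
  if (objective == 1 && k < 2) stop("E-NE needs k >= 2");
  if (max_evals < 1 || patience < 1 || restarts < 1)
    stop("budget, patience and restarts must be positive");

  if (objective >= 3) {
    st.Xt.resize((size_t)N * st.m);
    for (int o = 0; o < N; ++o)
      for (int l = 0; l < st.m; ++l)
        st.Xt[(size_t)o * st.m + l] = X(o, l);
  }
  if (objective == 5) {
    st.presRef.assign(st.m, 0); st.presAlt.assign(st.m, 0);
    for (int l = 0; l < st.m; ++l) {
      for (int o = 0; o < N; ++o) {
        if (X(o, l) > 0) st.presRef[l] = 1;
        if (X(o, l) < 1) st.presAlt[l] = 1;
        if (st.presRef[l] && st.presAlt[l]) break;
      }
      st.presTot += st.presRef[l] + st.presAlt[l];
    }
  }

  SplitMix rng((uint64_t)(int64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> bestSel;
  double bestScore = -INF;
  long long evalsUsed = 0;

  std::vector<int> pool(N);
  for (int r = 0; r < restarts; ++r) {
    // random initial subset (partial Fisher-Yates)
    for (int i = 0; i < N; ++i) pool[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + rng.bounded(N - i);
      std::swap(pool[i], pool[j]);
    }
    st.sel.assign(pool.begin(), pool.begin() + k);
    st.inSel.assign(N, 0);
    st.unsel.clear(); st.unselPos.assign(N, -1);
    for (int i = 0; i < k; ++i) st.inSel[st.sel[i]] = 1;
    for (int i = 0; i < N; ++i)
      if (!st.inSel[i]) { st.unselPos[i] = st.unsel.size(); st.unsel.push_back(i); }
    st.rebuild();

    int sinceImprove = 0;
    for (int ev = 0; ev < max_evals && sinceImprove < patience; ++ev) {
      if (st.unsel.empty()) break;
      int po = rng.bounded(k);
      int u = st.unsel[rng.bounded((int)st.unsel.size())];
      double cand = st.try_swap(po, u);
      ++evalsUsed;
      if (cand > st.score + EPS) {
        st.apply_swap(po, u);
        if (st.objective >= 3) st.score = cand; // rebuilt already for 1-2
        sinceImprove = 0;
      } else ++sinceImprove;
    }
    if (st.score > bestScore) {
      bestScore = st.score;
      bestSel = st.sel;
    }
  }

  // recompute the reported value from scratch on the best subset
  std::sort(bestSel.begin(), bestSel.end());
  st.sel = bestSel;
  st.inSel.assign(N, 0);
  for (int i = 0; i < k; ++i) st.inSel[st.sel[i]] = 1;
  st.unsel.clear(); st.unselPos.assign(N, -1);
  for (int i = 0; i < N; ++i)
    if (!st.inSel[i]) { st.unselPos[i] = st.unsel.size(); st.unsel.push_back(i); }
  st.rebuild();

  IntegerVector entries(k);
  for (int i = 0; i < k; ++i) entries[i] = bestSel[i] + 1;
  return List::create(_["entries"] = entries,
                      _["value"] = st.natural_value(),
                      _["evaluations"] = (double)evalsUsed);
}
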