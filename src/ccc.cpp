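#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pair-agreement counts between two cluster label vectors (1-based, compacted),
// via the k_p x k_q contingency table in O(n + k_p * k_q). Counts are doubles:
// they grow as n^2 and products of counts as n^4, well inside double precision
// (exact up to 2^53) for any matrix this package targets.
static void pair_counts_core(const int *p, const int *q, const int n,
                             const int kp, const int kq, double out[4]) {
  std::vector<double> cont((size_t)kp * kq, 0.0);
  std::vector<double> a(kp, 0.0), b(kq, 0.0);
  for (int i = 0; i < n; ++i) {
    const int pi = p[i] - 1, qi = q[i] - 1;
    cont[(size_t)pi * kq + qi] += 1.0;
    a[pi] += 1.0;
    b[qi] += 1.0;
  }
  double S = 0.0, A = 0.0, B = 0.0;
  for (size_t c = 0; c < cont.size(); ++c) S += cont[c] * (cont[c] - 1.0) / 2.0;
  for (int i = 0; i < kp; ++i) A += a[i] * (a[i] - 1.0) / 2.0;
  for (int j = 0; j < kq; ++j) B += b[j] * (b[j] - 1.0) / 2.0;
  const double total = (double)n * (n - 1.0) / 2.0;
  out[0] = S;                  // n0: co-clustered in both
  out[1] = total - A - B + S;  // n1: separated in both
  out[2] = A - S;              // n2: co-clustered in p only
  out[3] = B - S;              // n3: co-clustered in q only
}

// ARI by the pair-count formula 2(n0*n1 - n2*n3) / ((n0+n2)(n2+n1) + (n0+n3)(n3+n1)).
// A zero denominator occurs only when both partitions are trivial in the same
// way (both one-cluster or both all-singletons, hence identical -> 1).
static double ari_core(const int *p, const int *q, const int n,
                       const int kp, const int kq) {
  double c[4];
  pair_counts_core(p, q, n, kp, kq, c);
  const double num = 2.0 * (c[0] * c[1] - c[2] * c[3]);
  const double den = (c[0] + c[2]) * (c[2] + c[1]) + (c[0] + c[3]) * (c[3] + c[1]);
  if (den == 0.0) return (c[2] == 0.0 && c[3] == 0.0) ? 1.0 : 0.0;
  return num / den;
}

static int max_label(const IntegerVector &x) {
  int k = 1;
  for (int i = 0; i < x.size(); ++i)
    if (x[i] > k) k = x[i];
  return k;
}

// [[Rcpp::export(name = ".cpp_pair_counts")]]
NumericVector cpp_pair_counts(IntegerVector p, IntegerVector q) {
  if (p.size() != q.size()) stop("label vectors have different lengths");
  double out[4];
  pair_counts_core(p.begin(), q.begin(), p.size(), max_label(p), max_label(q), out);
  return NumericVector::create(_["n0"] = out[0], _["n1"] = out[1],
                               _["n2"] = out[2], _["n3"] = out[3]);
}

// [[Rcpp::export(name = ".cpp_ari")]]
double cpp_ari(IntegerVector p, IntegerVector q) {
  if (p.size() != q.size()) stop("label vectors have different lengths");
  return ari_core(p.begin(), q.begin(), p.size(), max_label(p), max_label(q));
}

// [[Rcpp::export(name = ".cpp_ari_grid")]]
NumericMatrix cpp_ari_grid(List px, List py) {
  const int nx = px.size(), ny = py.size();
  NumericMatrix grid(nx, ny);
  std::vector<IntegerVector> pxs(nx), pys(ny);
  std::vector<int> kx(nx), ky(ny);
  for (int i = 0; i < nx; ++i) { pxs[i] = px[i]; kx[i] = max_label(pxs[i]); }
  for (int j = 0; j < ny; ++j) { pys[j] = py[j]; ky[j] = max_label(pys[j]); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      grid(i, j) = ari_core(pxs[i].begin(), pys[j].begin(), pxs[i].size(),
                            kx[i], ky[j]);
  return grid;
}

// Maximum ARI over the Cartesian product of two partition lists. Ties on the
// (unclamped) maximum are broken toward the smallest kx*ky, then smallest kx,
// so the reported maximizing pair is deterministic and minimally complex.
// Returns c(max_ari, i, j) with 1-based list indices.
// [[Rcpp::export(name = ".cpp_grid_max")]]
NumericVector cpp_grid_max(List px, List py) {
  const int nx = px.size(), ny = py.size();
  if (nx == 0 || ny == 0) stop("empty partition list");
  double best = R_NegInf;
  int bi = 0, bj = 0;
  long best_cpx = 0, best_kx = 0;
  std::vector<IntegerVector> pxs(nx), pys(ny);
  std::vector<int> kx(nx), ky(ny);
  for (int i = 0; i < nx; ++i) { pxs[i] = px[i]; kx[i] = max_label(pxs[i]); }
  for (int j = 0; j < ny; ++j) { pys[j] = py[j]; ky[j] = max_label(pys[j]); }
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      const double a = ari_core(pxs[i].begin(), pys[j].begin(), pxs[i].size(),
                                kx[i], ky[j]);
      const long cpx = (long)kx[i] * ky[j];
      const bool better =
          (a > best) ||
          (a == best && (cpx < best_cpx || (cpx == best_cpx && kx[i] < best_kx)));
      if (better) {
        best = a; bi = i; bj = j; best_cpx = cpx; best_kx = kx[i];
      }
    }
  }
  return NumericVector::create(best, bi + 1, bj + 1);
}

// Permutation null for CCC: for each permutation (Fisher-Yates from R's RNG,
// so set.seed() in R governs reproducibility) relabel the objects of every
// y-partition, recompute the clamped max ARI over the grid, and count the
// permuted values >= observed. Relabeling is valid because a quantile/category
// partition of a permuted vector is the same permutation of the original labels.
// [[Rcpp::export(name = ".cpp_perm_count")]]
int cpp_perm_count(List px, List py, int n_perm, double observed) {
  const int nx = px.size(), ny = py.size();
  if (nx == 0 || ny == 0) stop("empty partition list");
  std::vector<IntegerVector> pxs(nx), pys(ny);
  std::vector<int> kx(nx), ky(ny);
  for (int i = 0; i < nx; ++i) { pxs[i] = px[i]; kx[i] = max_label(pxs[i]); }
  for (int j = 0; j < ny; ++j) { pys[j] = py[j]; ky[j] = max_label(pys[j]); }
  const int n = pys[0].size();
  std::vector<int> perm(n), qperm(n);
  RNGScope scope;
  int count = 0;
  for (int t = 0; t < n_perm; ++t) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    double best = R_NegInf;
    for (int b = 0; b < ny; ++b) {
      const int *q = pys[b].begin();
      for (int i = 0; i < n; ++i) qperm[i] = q[perm[i]];
      for (int a = 0; a < nx; ++a) {
        const double v = ari_core(pxs[a].begin(), qperm.data(), n, kx[a], ky[b]);
        if (v > best) best = v;
      }
    }
    if (best < 0.0) best = 0.0;
    if (best >= observed) ++count;
  }
  return count;
}
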