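#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// uniform integer in [0, n)
static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? (n - 1) : k;
}

// Pedigree-expectation relationship matrix for any even ploidy m with
// double reduction w, on the normalized scale (non-inbred founder diagonal
// exactly 1). Gamete model: a gamete of v = m/2 alleles is built from
// floor(v/2) allele pairs (each pair: with prob. w one parental allele is
// duplicated, otherwise two distinct parental alleles are drawn without
// replacement) plus one uniform singleton when v is odd; pairs are
// independent. The recursion below is the exact expectation of that model:
//   A[i,j] = 0.5 (A[s,j] + A[d,j])                       (unknown parent -> 0)
//   gam_p  = [npair (w + (1-w) alpha_p) + (C(v,2)-npair) A[p,p]/m] / C(v,2)
//   alpha_i = [C(v,2)(gam_s + gam_d) + v^2 A[s,d]/m] / C(m,2)
//   A[i,i] = 1 + (m-1) alpha_i
// where alpha is the probability that two distinct alleles of an individual
// are IBD. At m = 2 this collapses to the classical tabular method.
// [[Rcpp::export]]
List amatrix_kernel_cpp(IntegerVector sire, IntegerVector dam, int ploidy, double w,
                        Nullable<NumericMatrix> prefill = R_NilValue,
                        Nullable<NumericVector> prealpha = R_NilValue) {
  const int N = sire.size();
  const int m = ploidy, v = m / 2, npair = v / 2;
  const double cv2 = v * (v - 1) / 2.0;
  const double cm2 = m * (m - 1) / 2.0;
  NumericMatrix A(N, N);
  NumericVector alpha(N);
  int start = 0;
  if (prefill.isNotNull()) {
    NumericMatrix A0(prefill.get());
    NumericVector a0(prealpha.get());
    start = A0.nrow();
    for (int i = 0; i < start; i++) {
      alpha[i] = a0[i];
      for (int j = 0; j < start; j++) A(i, j) = A0(i, j);
    }
  }
  for (int i = start; i < N; i++) {
    const int s = sire[i], d = dam[i];  // 1-based; 0 = unknown
    for (int j = 0; j < i; j++) {
      double val = 0.0;
      if (s) val += A(s - 1, j);
      if (d) val += A(d - 1, j);
      val *= 0.5;
      A(i, j) = val;
      A(j, i) = val;
    }
    double gs = 0.0, gd = 0.0;
    if (cv2 > 0.0) {
      if (s) gs = (npair * (w + (1.0 - w) * alpha[s - 1]) +
                   (cv2 - npair) * (A(s - 1, s - 1) / m)) / cv2;
      if (d) gd = (npair * (w + (1.0 - w) * alpha[d - 1]) +
                   (cv2 - npair) * (A(d - 1, d - 1) / m)) / cv2;
    }
    const double th = (s && d) ? A(s - 1, d - 1) / m : 0.0;
    alpha[i] = (cv2 * (gs + gd) + (double)v * (double)v * th) / cm2;
    A(i, i) = 1.0 + (m - 1) * alpha[i];
  }
  return List::create(_["A"] = A, _["alpha"] = alpha);
}

// draw one gamete of v allele labels from parent p (1-based; 0 = unknown ->
// v fresh mutually non-IBD labels)
static void make_gamete(int* out, int p, const std::vector<int>& lab,
                        int m, int v, int npair, double w, int& next_label) {
  if (p == 0) {
    for (int k = 0; k < v; k++) out[k] = next_label++;
    return;
  }
  const int* lp = &lab[(size_t)(p - 1) * m];
  int pos = 0;
  for (int q = 0; q < npair; q++) {
    if (unif_rand() < w) {
      int k = rint_n(m);
      out[pos++] = lp[k];
      out[pos++] = lp[k];
    } else {
      int k1 = rint_n(m);
      int k2 = rint_n(m - 1);
      if (k2 >= k1) k2++;
      out[pos++] = lp[k1];
      out[pos++] = lp[k2];
    }
  }
  if (pos < v) out[pos] = lp[rint_n(m)];
}

// Gene-dropping Monte-Carlo: uniquely labelled founder alleles are
// transmitted through the pedigree; realized relationship per locus is
// matches/m over the m x m ordered allele comparisons (with replacement),
// which scales founder self-relationship to exactly 1. Returns the mean
// over loci and the per-entry Monte-Carlo standard error.
// [[Rcpp::export]]
List gene_drop_cpp(IntegerVector sire, IntegerVector dam, int ploidy, double w,
                   int n_loci) {
  const int N = sire.size(), m = ploidy, v = m / 2, npair = v / 2;
  std::vector<int> lab((size_t)N * m);
  const size_t P = (size_t)N * (N + 1) / 2;
  std::vector<double> sum(P, 0.0), sumsq(P, 0.0);
  for (int loc = 0; loc < n_loci; loc++) {
    int next_label = 0;
    for (int i = 0; i < N; i++) {
      const int s = sire[i], d = dam[i];
      int* li = &lab[(size_t)i * m];
      if (s == 0 && d == 0) {
        for (int k = 0; k < m; k++) li[k] = next_label++;
      } else {
        make_gamete(li, s, lab, m, v, npair, w, next_label);
        make_gamete(li + v, d, lab, m, v, npair, w, next_label);
      }
    }
    size_t idx = 0;
    for (int i = 0; i < N; i++) {
      const int* li = &lab[(size_t)i * m];
      for (int j = 0; j <= i; j++) {
        const int* lj = &lab[(size_t)j * m];
        int matches = 0;
        for (int u = 0; u < m; u++)
          for (int t = 0; t < m; t++) matches += (li[u] == lj[t]);
        const double val = (double)matches / m;
        sum[idx] += val;
        sumsq[idx] += val * val;
        idx++;
      }
    }
  }
  NumericMatrix est(N, N), se(N, N);
  size_t idx = 0;
  for (int i = 0; i < N; i++) {
    for (int j = 0; j <= i; j++) {
      const double mu = sum[idx] / n_loci;
      double s2 = 0.0;
      if (n_loci > 1) {
        s2 = (sumsq[idx] - n_loci * mu * mu) / (n_loci - 1.0);
        if (s2 < 0.0) s2 = 0.0;
      }
      const double semu = std::sqrt(s2 / n_loci);
      est(i, j) = mu; est(j, i) = mu;
      se(i, j) = semu; se(j, i) = semu;
      idx++;
    }
  }
  return List::create(_["est"] = est, _["se"] = se);
}

// biallelic gamete: same transmission model, but alleles carry a 0/1 state;
// a fresh (founder / unknown-parent) allele is reference with prob. pk
static void gamete_state(int* out, int p, const std::vector<int>& al,
                         int m, int v, int npair, double w, double pk) {
  if (p == 0) {
    for (int k = 0; k < v; k++) out[k] = (unif_rand() < pk) ? 1 : 0;
    return;
  }
  const int* lp = &al[(size_t)(p - 1) * m];
  int pos = 0;
  for (int q = 0; q < npair; q++) {
    if (unif_rand() < w) {
      int k = rint_n(m);
      out[pos++] = lp[k];
      out[pos++] = lp[k];
    } else {
      int k1 = rint_n(m);
      int k2 = rint_n(m - 1);
      if (k2 >= k1) k2++;
      out[pos++] = lp[k1];
      out[pos++] = lp[k2];
    }
  }
  if (pos < v) out[pos] = lp[rint_n(m)];
}

// Drop biallelic markers (reference-allele frequency p[k] in founders)
// through the pedigree with the same transmission engine; returns allele
// dosages (count of reference alleles, 0..m) per individual x marker.
// [[Rcpp::export]]
IntegerMatrix sim_markers_cpp(IntegerVector sire, IntegerVector dam, int ploidy,
                              double w, NumericVector p) {
  const int N = sire.size(), m = ploidy, v = m / 2, npair = v / 2;
  const int K = p.size();
  IntegerMatrix D(N, K);
  std::vector<int> al((size_t)N * m);
  for (int k = 0; k < K; k++) {
    const double pk = p[k];
    for (int i = 0; i < N; i++) {
      const int s = sire[i], d = dam[i];
      int* li = &al[(size_t)i * m];
      if (s == 0 && d == 0) {
        for (int q = 0; q < m; q++) li[q] = (unif_rand() < pk) ? 1 : 0;
      } else {
        gamete_state(li, s, al, m, v, npair, w, pk);
        gamete_state(li + v, d, al, m, v, npair, w, pk);
      }
      int dos = 0;
      for (int q = 0; q < m; q++) dos += li[q];
      D(i, k) = dos;
    }
  }
  return D;
}
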