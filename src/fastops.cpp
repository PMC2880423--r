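#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Wilcoxon-Mann-Whitney AUC by exhaustive pair counting with 0.5 for ties.
static double auc_pairs(const std::vector<double>& sp,
                        const std::vector<double>& sn) {
  if (sp.empty() || sn.empty()) return NA_REAL;
  double acc = 0.0;
  for (double a : sp)
    for (double b : sn)
      acc += (a > b) ? 1.0 : (a == b ? 0.5 : 0.0);
  return acc / (double(sp.size()) * double(sn.size()));
}

// [[Rcpp::export]]
double cpp_auc(NumericVector scores, IntegerVector labels) {
  std::vector<double> sp, sn;
  for (int i = 0; i < scores.size(); ++i) {
    if (labels[i] == 1) sp.push_back(scores[i]); else sn.push_back(scores[i]);
  }
  return auc_pairs(sp, sn);
}

// Univariate ranking criterion over columns of X restricted to rows `rows`
// (1-based). type: 1 = |Welch t|, 4 = BSS/WSS, 5 = |mean difference|.
// Sample variances use the n-1 denominator throughout.
// [[Rcpp::export]]
NumericVector cpp_rank_criterion(NumericMatrix X, IntegerVector y,
                                 IntegerVector rows, int type) {
  const int p = X.ncol();
  const int m = rows.size();
  NumericVector out(p);
  int n1 = 0, n0 = 0;
  for (int r = 0; r < m; ++r) (y[rows[r] - 1] == 1 ? n1 : n0)++;
  for (int jc = 0; jc < p; ++jc) {
    double s1 = 0, s0 = 0, q1 = 0, q0 = 0;
    const double* col = &X(0, jc);
    for (int r = 0; r < m; ++r) {
      const int i = rows[r] - 1;
      const double v = col[i];
      if (y[i] == 1) { s1 += v; q1 += v * v; } else { s0 += v; q0 += v * v; }
    }
    const double m1 = s1 / n1, m0 = s0 / n0;
    double v1 = (q1 - n1 * m1 * m1) / (n1 - 1);
    double v0 = (q0 - n0 * m0 * m0) / (n0 - 1);
    if (v1 < 0) v1 = 0;
    if (v0 < 0) v0 = 0;
    const double d = m1 - m0;
    double crit;
    if (type == 1) {
      const double se2 = v1 / n1 + v0 / n0;
      crit = (se2 == 0.0) ? (d == 0.0 ? 0.0 : R_PosInf)
                          : std::abs(d) / std::sqrt(se2);
    } else if (type == 4) {
      const double gm = (s1 + s0) / (n1 + n0);
      const double bss = n1 * (m1 - gm) * (m1 - gm) + n0 * (m0 - gm) * (m0 - gm);
      const double wss = (n1 - 1) * v1 + (n0 - 1) * v0;
      crit = (wss == 0.0) ? (bss == 0.0 ? 0.0 : R_PosInf) : bss / wss;
    } else {
      crit = std::abs(d);
    }
    out[jc] = crit;
  }
  return out;
}

// DLDA evaluated over a whole feature-count grid in one pass.
// Fits diagonal LDA on `trainRows` using the already-ordered feature columns
// `ordFeat` (best first, 1-based), scores `testRows` cumulatively, and
// returns the test AUC for each feature count in `grid`. Matches the R
// reference fit: pooled per-feature variance with the n-2 denominator,
// floored at 1e-12.
// [[Rcpp::export]]
NumericVector cpp_dlda_grid_auc(NumericMatrix X, IntegerVector y,
                                IntegerVector trainRows, IntegerVector testRows,
                                IntegerVector ordFeat, IntegerVector grid) {
  const int ntr = trainRows.size(), nte = testRows.size();
  const int jmax = ordFeat.size(), G = grid.size();
  int n1 = 0, n0 = 0;
  for (int r = 0; r < ntr; ++r) (y[trainRows[r] - 1] == 1 ? n1 : n0)++;

  std::vector<double> scores(nte, 0.0);
  std::vector<double> sp, sn;
  NumericVector out(G);
  int g = 0;
  for (int f = 0; f < jmax && g < G; ++f) {
    const double* col = &X(0, ordFeat[f] - 1);
    double s1 = 0, s0 = 0, q1 = 0, q0 = 0;
    for (int r = 0; r < ntr; ++r) {
      const int i = trainRows[r] - 1;
      const double v = col[i];
      if (y[i] == 1) { s1 += v; q1 += v * v; } else { s0 += v; q0 += v * v; }
    }
    const double m1 = s1 / n1, m0 = s0 / n0;
    double v1 = (q1 - n1 * m1 * m1) / (n1 - 1);
    double v0 = (q0 - n0 * m0 * m0) / (n0 - 1);
    if (v1 < 0) v1 = 0;
    if (v0 < 0) v0 = 0;
    double vp = ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2);
    if (vp <= 0) vp = 1e-12;
    const double w = (m1 - m0) / vp;
    const double c = 0.5 * (m1 + m0);
    for (int t = 0; t < nte; ++t)
      scores[t] += w * (col[testRows[t] - 1] - c);
    if (f + 1 == grid[g]) {
      sp.clear(); sn.clear();
      for (int t = 0; t < nte; ++t) {
        if (y[testRows[t] - 1] == 1) sp.push_back(scores[t]);
        else sn.push_back(scores[t]);
      }
      out[g++] = auc_pairs(sp, sn);
    }
  }
  while (g < G) out[g++] = NA_REAL;
  return out;
}

// One full stratified-CV repeat for the univariate-ranking + DLDA pipeline.
// `rows` is the training view (1-based indices into X, duplicates allowed);
// foldid[i] in 1..k assigns rows[i] to a fold. For every fold, ranking
// statistics on the fold-training part are obtained from one shared pass
// (per-fold class sums subtracted from totals), features are ordered by the
// criterion (type 1/4/5 as in cpp_rank_criterion, ties by ascending column),
// DLDA is fit cumulatively and the left-out fold scored. Returns the k x G
// matrix of fold AUCs for the feature counts in `grid`.
// [[Rcpp::export]]
NumericMatrix cpp_cv_grid_auc(NumericMatrix X, IntegerVector y,
                              IntegerVector rows, IntegerVector foldid,
                              int k, IntegerVector grid, int type) {
  const int p = X.ncol();
  const int m = rows.size();
  const int G = grid.size();
  const int jmax = std::min<int>(grid[G - 1], p);

  // per-fold, per-class counts
  std::vector<int> n1f(k, 0), n0f(k, 0);
  for (int r = 0; r < m; ++r) {
    const int f = foldid[r] - 1;
    (y[rows[r] - 1] == 1 ? n1f[f] : n0f[f])++;
  }
  int n1tot = 0, n0tot = 0;
  for (int f = 0; f < k; ++f) { n1tot += n1f[f]; n0tot += n0f[f]; }

  // per-fold, per-class column sums and sums of squares (k x p, fold-major)
  std::vector<double> s1(size_t(k) * p, 0.0), q1(size_t(k) * p, 0.0),
                      s0(size_t(k) * p, 0.0), q0(size_t(k) * p, 0.0);
  for (int jc = 0; jc < p; ++jc) {
    const double* col = &X(0, jc);
    for (int r = 0; r < m; ++r) {
      const int i = rows[r] - 1;
      const double v = col[i];
      const size_t at = size_t(foldid[r] - 1) * p + jc;
      if (y[i] == 1) { s1[at] += v; q1[at] += v * v; }
      else           { s0[at] += v; q0[at] += v * v; }
    }
  }
  std::vector<double> S1(p, 0.0), Q1(p, 0.0), S0(p, 0.0), Q0(p, 0.0);
  for (int f = 0; f < k; ++f)
    for (int jc = 0; jc < p; ++jc) {
      S1[jc] += s1[size_t(f) * p + jc]; Q1[jc] += q1[size_t(f) * p + jc];
      S0[jc] += s0[size_t(f) * p + jc]; Q0[jc] += q0[size_t(f) * p + jc];
    }

  NumericMatrix out(k, G);
  std::vector<double> crit(p), w(jmax), cen(jmax);
  std::vector<int> ordidx(p), topf(jmax);
  std::vector<double> sp, sn;

  for (int f = 0; f < k; ++f) {
    const int n1 = n1tot - n1f[f], n0 = n0tot - n0f[f];
    const size_t off = size_t(f) * p;
    for (int jc = 0; jc < p; ++jc) {
      const double ts1 = S1[jc] - s1[off + jc], tq1 = Q1[jc] - q1[off + jc];
      const double ts0 = S0[jc] - s0[off + jc], tq0 = Q0[jc] - q0[off + jc];
      const double m1 = ts1 / n1, m0 = ts0 / n0;
      double v1 = (tq1 - n1 * m1 * m1) / (n1 - 1);
      double v0 = (tq0 - n0 * m0 * m0) / (n0 - 1);
      if (v1 < 0) v1 = 0;
      if (v0 < 0) v0 = 0;
      const double d = m1 - m0;
      double c;
      if (type == 1) {
        const double se2 = v1 / n1 + v0 / n0;
        c = (se2 == 0.0) ? (d == 0.0 ? 0.0 : R_PosInf)
                         : std::abs(d) / std::sqrt(se2);
      } else if (type == 4) {
        const double gm = (ts1 + ts0) / (n1 + n0);
        const double bss = n1 * (m1 - gm) * (m1 - gm) + n0 * (m0 - gm) * (m0 - gm);
        const double wss = (n1 - 1) * v1 + (n0 - 1) * v0;
        c = (wss == 0.0) ? (bss == 0.0 ? 0.0 : R_PosInf) : bss / wss;
      } else {
        c = std::abs(d);
      }
      crit[jc] = c;
    }
    for (int jc = 0; jc < p; ++jc) ordidx[jc] = jc;
    std::partial_sort(ordidx.begin(), ordidx.begin() + jmax, ordidx.end(),
                      [&](int a, int b) {
                        if (crit[a] != crit[b]) return crit[a] > crit[b];
                        return a < b;
                      });
    for (int t = 0; t < jmax; ++t) {
      const int jc = ordidx[t];
      const double m1 = (S1[jc] - s1[off + jc]) / n1;
      const double m0 = (S0[jc] - s0[off + jc]) / n0;
      double v1 = ((Q1[jc] - q1[off + jc]) - n1 * m1 * m1) / (n1 - 1);
      double v0 = ((Q0[jc] - q0[off + jc]) - n0 * m0 * m0) / (n0 - 1);
      if (v1 < 0) v1 = 0;
      if (v0 < 0) v0 = 0;
      double vp = ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2);
      if (vp <= 0) vp = 1e-12;
      topf[t] = jc;
      w[t] = (m1 - m0) / vp;
      cen[t] = 0.5 * (m1 + m0);
    }
    // cumulative scoring of the held-out fold
    std::vector<int> terow;
    for (int r = 0; r < m; ++r) if (foldid[r] - 1 == f) terow.push_back(rows[r] - 1);
    std::vector<double> scores(terow.size(), 0.0);
    int g = 0;
    for (int t = 0; t < jmax && g < G; ++t) {
      const double* col = &X(0, topf[t]);
      for (size_t u = 0; u < terow.size(); ++u)
        scores[u] += w[t] * (col[terow[u]] - cen[t]);
      if (t + 1 == grid[g]) {
        sp.clear(); sn.clear();
        for (size_t u = 0; u < terow.size(); ++u) {
          if (y[terow[u]] == 1) sp.push_back(scores[u]); else sn.push_back(scores[u]);
        }
        out(f, g++) = auc_pairs(sp, sn);
      }
    }
    while (g < G) out(f, g++) = NA_REAL;
  }
  return out;
}
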