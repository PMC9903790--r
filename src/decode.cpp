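// Inner loops of the Dirichlet-multinomial HMM: emission log-likelihoods,
// scaled forward-backward, Viterbi, and the fixed-point concentration
// update.  All sparse-aware: count data arrive as triplets (i, j, x).

#include <Rcpp.h>
using namespace Rcpp;

// bins x states DM log-likelihood matrix from sparse triplets.
// Zero entries contribute nothing beyond the n-dependent terms.
// [[Rcpp::export]]
NumericMatrix emission_loglik_cpp(NumericMatrix alpha, IntegerVector i,
                                  IntegerVector j, NumericVector x,
                                  NumericVector bin_totals, int B) {
  const int K = alpha.nrow();
  const int C = alpha.ncol();
  const int nnz = i.size();
  NumericMatrix E(B, K);
  std::vector<double> A(K, 0.0);
  for (int s = 0; s < K; ++s)
    for (int c = 0; c < C; ++c) A[s] += alpha(s, c);
  // state-independent multinomial coefficient
  std::vector<double> cons(B);
  for (int b = 0; b < B; ++b) cons[b] = R::lgammafn(bin_totals[b] + 1.0);
  for (int t = 0; t < nnz; ++t) cons[i[t]] -= R::lgammafn(x[t] + 1.0);
  // integer counts allow lgamma(z + k) - lgamma(z) = sum log(z + v):
  // build cumulative-log tables when the count ranges are small
  double maxx = 0.0, maxn = 0.0;
  bool int_x = true, int_n = true;
  for (int t = 0; t < nnz; ++t) {
    if (x[t] > maxx) maxx = x[t];
    if (x[t] != std::floor(x[t])) int_x = false;
  }
  for (int b = 0; b < B; ++b) {
    if (bin_totals[b] > maxn) maxn = bin_totals[b];
    if (bin_totals[b] != std::floor(bin_totals[b])) int_n = false;
  }
  const bool table_x = int_x && maxx <= 64;
  const bool table_n = int_n && maxn <= 4096;
  for (int s = 0; s < K; ++s) {
    const double lgA = R::lgammafn(A[s]);
    if (table_n) {
      std::vector<double> lgn((size_t)maxn + 1);
      lgn[0] = lgA;
      for (int v = 1; v <= (int)maxn; ++v)
        lgn[v] = lgn[v - 1] + std::log(A[s] + v - 1);
      for (int b = 0; b < B; ++b)
        E(b, s) = cons[b] + lgA - lgn[(int)bin_totals[b]];
    } else {
      for (int b = 0; b < B; ++b)
        E(b, s) = cons[b] + lgA - R::lgammafn(bin_totals[b] + A[s]);
    }
    if (table_x) {
      const int W = (int)maxx + 1;
      std::vector<double> lgx((size_t)C * W);
      for (int c = 0; c < C; ++c) {
        lgx[(size_t)c * W] = 0.0;
        for (int v = 1; v < W; ++v)
          lgx[(size_t)c * W + v] =
            lgx[(size_t)c * W + v - 1] + std::log(alpha(s, c) + v - 1);
      }
      for (int t = 0; t < nnz; ++t)
        E(i[t], s) += lgx[(size_t)j[t] * W + (int)x[t]];
    } else {
      for (int t = 0; t < nnz; ++t) {
        const double a = alpha(s, j[t]);
        E(i[t], s) += R::lgammafn(x[t] + a) - R::lgammafn(a);
      }
    }
  }
  return E;
}

// scaled forward-backward over one sequence; returns posteriors, expected
// transition counts, the first-bin posterior and the log-likelihood
// [[Rcpp::export]]
List fb_seq_cpp(NumericMatrix E, NumericMatrix A, NumericVector init) {
  const int T = E.nrow();
  const int K = E.ncol();
  NumericMatrix btld(T, K), ahat(T, K), bhat(T, K), gamma(T, K);
  NumericVector cvec(T);
  double shift = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = E(t, 0);
    for (int s = 1; s < K; ++s) if (E(t, s) > m) m = E(t, s);
    shift += m;
    for (int s = 0; s < K; ++s) btld(t, s) = std::exp(E(t, s) - m);
  }
  double c0 = 0.0;
  for (int s = 0; s < K; ++s) { ahat(0, s) = init[s] * btld(0, s); c0 += ahat(0, s); }
  if (!(c0 > 0.0) || !std::isfinite(c0))
    stop("non-finite forward probability at bin 1");
  for (int s = 0; s < K; ++s) ahat(0, s) /= c0;
  cvec[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int s = 0; s < K; ++s) {
      double acc = 0.0;
      for (int r = 0; r < K; ++r) acc += ahat(t - 1, r) * A(r, s);
      double v = acc * btld(t, s);
      ahat(t, s) = v;
      ct += v;
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      stop("non-finite forward probability at bin %d", t + 1);
    for (int s = 0; s < K; ++s) ahat(t, s) /= ct;
    cvec[t] = ct;
  }
  double loglik = shift;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]);
  for (int s = 0; s < K; ++s) bhat(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int s = 0; s < K; ++s) {
      double acc = 0.0;
      for (int r = 0; r < K; ++r)
        acc += A(s, r) * btld(t + 1, r) * bhat(t + 1, r);
      bhat(t, s) = acc / cvec[t + 1];
    }
  NumericMatrix tc(K, K);
  for (int t = 1; t < T; ++t) {
    double z = 0.0;
    for (int r = 0; r < K; ++r)
      for (int s = 0; s < K; ++s)
        z += ahat(t - 1, r) * A(r, s) * btld(t, s) * bhat(t, s);
    for (int r = 0; r < K; ++r)
      for (int s = 0; s < K; ++s)
        tc(r, s) += ahat(t - 1, r) * A(r, s) * btld(t, s) * bhat(t, s) / z;
  }
  for (int t = 0; t < T; ++t) {
    double z = 0.0;
    for (int s = 0; s < K; ++s) { gamma(t, s) = ahat(t, s) * bhat(t, s); z += gamma(t, s); }
    for (int s = 0; s < K; ++s) gamma(t, s) /= z;
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["trans_counts"] = tc);
}

// Viterbi over one sequence; ties break toward the lowest state index
// [[Rcpp::export]]
IntegerVector viterbi_seq_cpp(NumericMatrix E, NumericMatrix logA,
                              NumericVector loginit) {
  const int T = E.nrow();
  const int K = E.ncol();
  NumericVector delta(K), ndelta(K);
  IntegerMatrix psi(T, K);
  for (int s = 0; s < K; ++s) delta[s] = loginit[s] + E(0, s);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < K; ++s) {
      int best = 0;
      double bv = delta[0] + logA(0, s);
      for (int r = 1; r < K; ++r) {
        const double v = delta[r] + logA(r, s);
        if (v > bv) { bv = v; best = r; }
      }
      ndelta[s] = bv + E(t, s);
      psi(t, s) = best;
    }
    delta = clone(ndelta);
  }
  IntegerVector path(T);
  int best = 0;
  for (int s = 1; s < K; ++s) if (delta[s] > delta[best]) best = s;
  path[T - 1] = best + 1;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi(t + 1, path[t + 1] - 1) + 1;
  return path;
}

// fixed-point concentration update for one state (inner loop included)
// [[Rcpp::export]]
NumericVector alpha_fixed_point_cpp(NumericVector a0, NumericVector w,
                                    IntegerVector i, IntegerVector j,
                                    NumericVector x,
                                    NumericVector bin_totals,
                                    int inner, double floor_val) {
  const int C = a0.size();
  const int B = bin_totals.size();
  const int nnz = i.size();
  NumericVector a = clone(a0);
  // counts are small integers (capped per-cell matrices especially), so
  // digamma(x + a_c) takes few distinct values per column: build tables
  // when the ranges allow and fall back to direct evaluation otherwise
  double maxx = 0.0, maxn = 0.0;
  bool int_x = true, int_n = true;
  for (int t = 0; t < nnz; ++t) {
    if (x[t] > maxx) maxx = x[t];
    if (x[t] != std::floor(x[t])) int_x = false;
  }
  for (int b = 0; b < B; ++b) {
    if (bin_totals[b] > maxn) maxn = bin_totals[b];
    if (bin_totals[b] != std::floor(bin_totals[b])) int_n = false;
  }
  const bool table_x = int_x && maxx <= 64;
  const bool table_n = int_n && maxn <= 4096;
  std::vector<double> digx;      // [c * (maxx+1) + v] = digamma(a_c + v)
  std::vector<double> dign;      // [v] = digamma(v + A)
  for (int it = 0; it < inner; ++it) {
    double A = 0.0;
    for (int c = 0; c < C; ++c) A += a[c];
    double den = 0.0;
    const double dA = R::digamma(A);
    if (table_n) {
      dign.assign((size_t)maxn + 1, 0.0);
      dign[0] = dA;
      // digamma(z + 1) = digamma(z) + 1/z
      for (int v = 1; v <= (int)maxn; ++v)
        dign[v] = dign[v - 1] + 1.0 / (A + v - 1);
      for (int b = 0; b < B; ++b)
        if (w[b] > 0 && bin_totals[b] > 0)
          den += w[b] * (dign[(int)bin_totals[b]] - dA);
    } else {
      for (int b = 0; b < B; ++b)
        if (w[b] > 0 && bin_totals[b] > 0)
          den += w[b] * (R::digamma(bin_totals[b] + A) - dA);
    }
    if (!(den > 0.0)) break;
    std::vector<double> num(C, 0.0);
    if (table_x) {
      const int W = (int)maxx + 1;
      digx.assign((size_t)C * W, 0.0);
      for (int c = 0; c < C; ++c) {
        digx[(size_t)c * W] = R::digamma(a[c]);
        for (int v = 1; v < W; ++v)
          digx[(size_t)c * W + v] =
            digx[(size_t)c * W + v - 1] + 1.0 / (a[c] + v - 1);
      }
      for (int t = 0; t < nnz; ++t) {
        const double wt = w[i[t]];
        if (wt <= 0) continue;
        const size_t base = (size_t)j[t] * W;
        num[j[t]] += wt * (digx[base + (int)x[t]] - digx[base]);
      }
    } else {
      for (int t = 0; t < nnz; ++t) {
        const double wt = w[i[t]];
        if (wt <= 0) continue;
        const double ac = a[j[t]];
        num[j[t]] += wt * (R::digamma(x[t] + ac) - R::digamma(ac));
      }
    }
    for (int c = 0; c < C; ++c) {
      double v = a[c] * num[c] / den;
      a[c] = (v > floor_val) ? v : floor_val;
    }
  }
  return a;
}
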