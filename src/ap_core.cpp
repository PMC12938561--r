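#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Responsibility update. S carries the preferences on its diagonal, so one
// rule covers i == k:
//   r(i,k) = S(i,k) - max_{k' != k} (S(i,k') + ahat(i,k'))
static void resp_update(const NumericMatrix& S, const NumericMatrix& ahat,
                        NumericMatrix& r) {
  const int n = S.nrow();
  if (n == 1) { r(0, 0) = S(0, 0); return; }
  for (int i = 0; i < n; ++i) {
    double max1 = R_NegInf, max2 = R_NegInf;
    int arg1 = -1;
    for (int k = 0; k < n; ++k) {
      double v = S(i, k) + ahat(i, k);
      if (v > max1) { max2 = max1; max1 = v; arg1 = k; }
      else if (v > max2) { max2 = v; }
    }
    for (int k = 0; k < n; ++k)
      r(i, k) = S(i, k) - (k == arg1 ? max2 : max1);
  }
}

// Availability update from (smoothed) responsibilities:
//   a(i,k) = min(0, r(k,k) + sum_{k' not in {i,k}} max(0, r(k',k)))   (i != k)
//   a(k,k) = sum_{k' != k} max(0, r(k',k))
static void avail_update(const NumericMatrix& r, NumericMatrix& a) {
  const int n = r.nrow();
  if (n == 1) { a(0, 0) = 0.0; return; }
  for (int k = 0; k < n; ++k) {
    double sum_pos = 0.0;
    for (int i = 0; i < n; ++i)
      if (i != k && r(i, k) > 0.0) sum_pos += r(i, k);
    const double rkk = r(k, k);
    for (int i = 0; i < n; ++i) {
      if (i == k) { a(k, k) = sum_pos; continue; }
      double v = rkk + sum_pos - (r(i, k) > 0.0 ? r(i, k) : 0.0);
      a(i, k) = v < 0.0 ? v : 0.0;
    }
  }
}

// [[Rcpp::export(name = ".ap_resp_cpp")]]
NumericMatrix ap_resp_cpp(NumericMatrix S, NumericMatrix ahat) {
  NumericMatrix r(S.nrow(), S.ncol());
  resp_update(S, ahat, r);
  return r;
}

// [[Rcpp::export(name = ".ap_avail_cpp")]]
NumericMatrix ap_avail_cpp(NumericMatrix rhat) {
  NumericMatrix a(rhat.nrow(), rhat.ncol());
  avail_update(rhat, a);
  return a;
}

// Full message-passing loop. Smoothing is applied iteratively: the message
// retained at iteration m is the arithmetic mean of the fresh raw update
// and the messages retained at the previous three iterations — a moving
// average over the last four iterations, with the buffer primed by the
// zero initial messages. The availability update consumes the smoothed
// responsibilities. Convergence: the set of self-argmax points of rhat,
// which must be non-empty, unchanged for `convergence_window` consecutive
// iterations.
// [[Rcpp::export(name = ".ap_run_cpp")]]
List ap_run_cpp(NumericMatrix S, int max_iterations, int convergence_window) {
  const int n = S.nrow();
  const size_t nn = (size_t)n * (size_t)n;
  NumericMatrix rraw(n, n), araw(n, n), rhat(n, n), ahat(n, n);
  const int keep = 3;  // previous retained messages entering the average
  std::vector<std::vector<double>> hist_r(keep, std::vector<double>(nn, 0.0));
  std::vector<std::vector<double>> hist_a(keep, std::vector<double>(nn, 0.0));
  std::vector<double> rsum(nn, 0.0), asum(nn, 0.0);
  std::vector<int> ex_prev, ex_cur;
  int head = 0, unchanged = 0, iter = 0;
  bool converged = false, has_prev = false;

  for (iter = 1; iter <= max_iterations; ++iter) {
    resp_update(S, ahat, rraw);
    const double inv = 0.25;
    for (size_t j = 0; j < nn; ++j) rhat[j] = (rsum[j] + rraw[j]) * inv;
    avail_update(rhat, araw);
    for (size_t j = 0; j < nn; ++j) ahat[j] = (asum[j] + araw[j]) * inv;

    // push the retained (smoothed) messages into the ring buffer
    {
      const std::vector<double>& oldr = hist_r[head];
      const std::vector<double>& olda = hist_a[head];
      for (size_t j = 0; j < nn; ++j) { rsum[j] -= oldr[j]; asum[j] -= olda[j]; }
    }
    hist_r[head].assign(rhat.begin(), rhat.end());
    hist_a[head].assign(ahat.begin(), ahat.end());
    for (size_t j = 0; j < nn; ++j) { rsum[j] += rhat[j]; asum[j] += ahat[j]; }
    head = (head + 1) % keep;

    bool bad = false;
    for (size_t j = 0; j < nn && !bad; ++j)
      if (!std::isfinite(rhat[j]) || !std::isfinite(ahat[j])) bad = true;
    if (bad) stop("non-finite message at iteration %d", iter);

    ex_cur.clear();
    for (int i = 0; i < n; ++i) {
      double best = R_NegInf; int arg = 0;
      for (int k = 0; k < n; ++k)
        if (rhat(i, k) > best) { best = rhat(i, k); arg = k; }
      if (arg == i) ex_cur.push_back(i);
    }
    if (!ex_cur.empty() && has_prev && ex_cur == ex_prev) {
      if (++unchanged >= convergence_window) { converged = true; break; }
    } else {
      unchanged = 1;
      has_prev = !ex_cur.empty();
      if (has_prev) ex_prev = ex_cur;
    }
  }
  if (iter > max_iterations) iter = max_iterations;
  return List::create(_["rhat"] = rhat, _["ahat"] = ahat,
                      _["iterations"] = iter, _["converged"] = converged);
}

// Cross L1 nearest assignment: for each row of X, the row index of E with
// minimal L1 distance (ties to the lowest index), plus that distance.
// [[Rcpp::export(name = ".l1_nearest_cpp")]]
List l1_nearest_cpp(NumericMatrix X, NumericMatrix E) {
  const int n = X.nrow(), m = E.nrow(), d = X.ncol();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int arg = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += std::fabs(X(i, c) - E(j, c));
      if (s < best) { best = s; arg = j; }
    }
    idx[i] = arg + 1;
    dist[i] = best;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Mean pairwise L1 distance between rows (0 when fewer than 2 rows).
// [[Rcpp::export(name = ".l1_pairwise_mean_cpp")]]
double l1_pairwise_mean_cpp(NumericMatrix E) {
  const int m = E.nrow(), d = E.ncol();
  if (m < 2) return 0.0;
  double tot = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += std::fabs(E(i, c) - E(j, c));
      tot += s;
    }
  return tot / (0.5 * m * (m - 1));
}
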