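#include <Rcpp.h>
using namespace Rcpp;

// Draw a category index from the cumulative distribution `cum` (length m,
// cum[m-1] <= 1). Returns m if u falls in the residual off-target mass.
static inline int draw_cat(const std::vector<double>& cum) {
  const double u = unif_rand();
  const int m = static_cast<int>(cum.size());
  for (int j = 0; j < m; ++j) {
    if (u < cum[j]) return j;
  }
  return m;
}

// Coupon-collector simulation with unequal probabilities.
// prob: category probabilities (may sum to < 1; remainder is off-target),
// target: 0/1 flag per category. Streams Welford moments per discovery rank
// for both incremental draws (between successive discoveries) and cumulative
// draws (total up to each discovery). Uses R's RNG: set.seed => reproducible.
// [[Rcpp::export]]
List sim_collect_cpp(NumericVector prob, IntegerVector target, int n_iter) {
  const int m = prob.size();
  int K = 0;
  std::vector<double> cum(m);
  std::vector<int> rank_of(m, -1);
  double acc = 0.0;
  for (int j = 0; j < m; ++j) {
    acc += prob[j];
    cum[j] = acc;
    if (target[j]) rank_of[j] = K++;  // stable target indexing
  }
  if (K == 0) stop("no targets");
  if (K > 64) stop("too many targets");

  std::vector<double> inc_mean(K, 0.0), inc_m2(K, 0.0);
  std::vector<double> cum_mean(K, 0.0), cum_m2(K, 0.0);
  std::vector<char> seen(K);

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    std::fill(seen.begin(), seen.end(), 0);
    int found = 0;
    long draws = 0, last = 0;
    while (found < K) {
      ++draws;
      const int j = draw_cat(cum);
      if (j >= m) continue;
      const int r = rank_of[j];
      if (r < 0 || seen[r]) continue;
      seen[r] = 1;
      const double inc = static_cast<double>(draws - last);
      const double tot = static_cast<double>(draws);
      last = draws;
      // Welford update at this discovery rank (0-based `found`)
      double d = inc - inc_mean[found];
      inc_mean[found] += d / it;
      inc_m2[found] += d * (inc - inc_mean[found]);
      d = tot - cum_mean[found];
      cum_mean[found] += d / it;
      cum_m2[found] += d * (tot - cum_mean[found]);
      ++found;
    }
  }

  NumericVector im(K), is(K), cm(K), cs(K);
  for (int r = 0; r < K; ++r) {
    im[r] = inc_mean[r];
    cm[r] = cum_mean[r];
    is[r] = n_iter > 1 ? std::sqrt(inc_m2[r] / (n_iter - 1)) : NA_REAL;
    cs[r] = n_iter > 1 ? std::sqrt(cum_m2[r] / (n_iter - 1)) : NA_REAL;
  }
  return List::create(_["incremental_mean"] = im, _["incremental_sd"] = is,
                      _["cumulative_mean"] = cm, _["cumulative_sd"] = cs);
}

// Fixed-size screen: draw n_clones per iteration, count distinct targets.
// Optionally return the per-variant count matrix (n_iter x m).
// [[Rcpp::export]]
List sim_fixed_cpp(NumericVector prob, IntegerVector target, int n_clones,
                   int n_iter, bool keep_compositions) {
  const int m = prob.size();
  std::vector<double> cum(m);
  double acc = 0.0;
  for (int j = 0; j < m; ++j) { acc += prob[j]; cum[j] = acc; }

  IntegerVector distinct(n_iter);
  IntegerMatrix comp =
      keep_compositions ? IntegerMatrix(n_iter, m) : IntegerMatrix(0, 0);
  std::vector<int> counts(m);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int c = 0; c < n_clones; ++c) {
      const int j = draw_cat(cum);
      if (j < m) ++counts[j];
    }
    int d = 0;
    for (int j = 0; j < m; ++j) {
      if (target[j] && counts[j] > 0) ++d;
      if (keep_compositions) comp(it, j) = counts[j];
    }
    distinct[it] = d;
  }
  return List::create(_["distinct"] = distinct, _["compositions"] = comp);
}
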