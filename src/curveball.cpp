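#include <Rcpp.h>
using namespace Rcpp;

// Curveball trades on a binary incidence matrix (rows = cells, cols =
// species). Each trade picks two rows, keeps the species they share, and
// randomly re-deals the symmetric difference between them. Row sums and
// column sums are preserved exactly by construction. Uses R's RNG
// (unif_rand), so results are governed by set.seed() on the R side.

// [[Rcpp::export]]
IntegerMatrix curveball_trades(IntegerMatrix m, int n_trades) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out = clone(m);
  if (nr < 2 || n_trades <= 0) return out;

  std::vector< std::vector<int> > rows(nr);
  for (int r = 0; r < nr; ++r) {
    rows[r].reserve(nc);
    for (int c = 0; c < nc; ++c)
      if (out(r, c) != 0) rows[r].push_back(c);
  }

  std::vector<int> mark(nc, 0);
  std::vector<int> shared_i, pool;
  int stamp = 0;

  for (int t = 0; t < n_trades; ++t) {
    int i = (int)(unif_rand() * nr); if (i == nr) i = nr - 1;
    int j = (int)(unif_rand() * (nr - 1)); if (j == nr - 1) j = nr - 2;
    if (j >= i) ++j;  // j != i, uniform over the rest

    std::vector<int> &ri = rows[i], &rj = rows[j];
    if (ri.empty() || rj.empty()) continue;

    stamp += 2;  // mark == stamp: in row i; mark == stamp + 1: shared
    for (size_t k = 0; k < ri.size(); ++k) mark[ri[k]] = stamp;
    shared_i.clear(); pool.clear();
    for (size_t k = 0; k < rj.size(); ++k) {
      if (mark[rj[k]] == stamp) mark[rj[k]] = stamp + 1;  // shared
      else pool.push_back(rj[k]);                         // only in j
    }
    size_t n_i_only = 0;
    for (size_t k = 0; k < ri.size(); ++k) {
      if (mark[ri[k]] == stamp + 1) shared_i.push_back(ri[k]);
      else { pool.push_back(ri[k]); ++n_i_only; }
    }
    if (pool.size() < 2 || n_i_only == 0 || n_i_only == pool.size())
      continue;  // nothing exchangeable

    // Fisher-Yates shuffle of the exchangeable pool
    for (size_t k = pool.size() - 1; k > 0; --k) {
      size_t u = (size_t)(unif_rand() * (k + 1));
      if (u > k) u = k;
      std::swap(pool[k], pool[u]);
    }

    ri.assign(shared_i.begin(), shared_i.end());
    ri.insert(ri.end(), pool.begin(), pool.begin() + n_i_only);
    rj.assign(shared_i.begin(), shared_i.end());
    rj.insert(rj.end(), pool.begin() + n_i_only, pool.end());
  }

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) out(r, c) = 0;
    for (size_t k = 0; k < rows[r].size(); ++k) out(r, rows[r][k]) = 1;
  }
  out.attr("dimnames") = m.attr("dimnames");
  return out;
}
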