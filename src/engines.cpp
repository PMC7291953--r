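#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Weighted beta mean nearest taxon distance between two communities given a
// patristic matrix D. ia/ib are 0-based taxon indices of the taxa present in
// each community, wa/wb the matching relative abundances (each summing to 1).
// perm, when non-null, maps original taxon index -> shuffled index (one joint
// relabelling of D's rows and columns).
static double bmntd_pair(const NumericMatrix& D,
                         const std::vector<int>& ia,
                         const std::vector<double>& wa,
                         const std::vector<int>& ib,
                         const std::vector<double>& wb,
                         const int* perm) {
  double sa = 0.0, sb = 0.0;
  const int na = (int) ia.size(), nb = (int) ib.size();
  std::vector<double> colmin(nb, R_PosInf);
  for (int u = 0; u < na; ++u) {
    const int i = perm ? perm[ia[u]] : ia[u];
    double mn = R_PosInf;
    for (int v = 0; v < nb; ++v) {
      const int j = perm ? perm[ib[v]] : ib[v];
      const double d = D(i, j);
      if (d < mn) mn = d;
      if (d < colmin[v]) colmin[v] = d;
    }
    sa += wa[u] * mn;
  }
  for (int v = 0; v < nb; ++v) sb += wb[v] * colmin[v];
  return 0.5 * (sa + sb);
}

// Observed betaMNTD for each sample pair plus its null distribution under
// joint row/column permutations of the patristic matrix.
//   D:     taxa x taxa patristic distances
//   W:     samples x taxa relative abundances (rows sum to 1)
//   pairs: P x 2 sample indices (1-based)
//   perms: n_null x taxa permutations (1-based); each row is one shared
//          relabelling applied to every pair
// Returns list(observed = numeric(P), nulls = matrix(n_null x P)).
// [[Rcpp::export]]
List bmntd_engine(NumericMatrix D, NumericMatrix W, IntegerMatrix pairs,
                  IntegerMatrix perms) {
  const int S = W.nrow(), T = W.ncol(), P = pairs.nrow(),
            n_null = perms.nrow();
  if (D.nrow() != T || D.ncol() != T)
    stop("patristic matrix does not match taxon count");
  std::vector< std::vector<int> > idx(S);
  std::vector< std::vector<double> > wt(S);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t)
      if (W(s, t) > 0) { idx[s].push_back(t); wt[s].push_back(W(s, t)); }
  for (int s = 0; s < S; ++s)
    if (idx[s].empty()) stop("empty community (all-zero sample)");

  NumericVector obs(P);
  for (int p = 0; p < P; ++p) {
    const int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
    obs[p] = bmntd_pair(D, idx[a], wt[a], idx[b], wt[b], nullptr);
  }
  NumericMatrix nulls(n_null, P);
  std::vector<int> perm(T);
  for (int r = 0; r < n_null; ++r) {
    for (int t = 0; t < T; ++t) perm[t] = perms(r, t) - 1;
    for (int p = 0; p < P; ++p) {
      const int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
      nulls(r, p) = bmntd_pair(D, idx[a], wt[a], idx[b], wt[b], perm.data());
    }
  }
  return List::create(_["observed"] = obs, _["nulls"] = nulls);
}

// Draw one null community: `rich` distinct taxa chosen with probability
// proportional to occupancy `occ` (Efraimidis-Spirakis exponential keys,
// equivalent to sequential weighted sampling without replacement), then
// `total` reads distributed among the drawn taxa with probability
// proportional to pool relative abundance `relab`. Fills x (length T).
static void draw_null_community(std::vector<double>& x,
                                const NumericVector& occ,
                                const NumericVector& relab,
                                int rich, int total,
                                std::vector<double>& keys,
                                std::vector<int>& order_buf,
                                std::vector<int>& sel,
                                std::vector<double>& pr,
                                std::vector<int>& cnt) {
  const int T = occ.size();
  std::fill(x.begin(), x.end(), 0.0);
  for (int t = 0; t < T; ++t)
    keys[t] = occ[t] > 0 ? -std::log(unif_rand()) / occ[t] : R_PosInf;
  std::iota(order_buf.begin(), order_buf.end(), 0);
  std::partial_sort(order_buf.begin(), order_buf.begin() + rich,
                    order_buf.end(),
                    [&](int a, int b) { return keys[a] < keys[b]; });
  sel.assign(order_buf.begin(), order_buf.begin() + rich);
  double tot_p = 0.0;
  for (int k = 0; k < rich; ++k) tot_p += relab[sel[k]];
  pr.resize(rich);
  cnt.resize(rich);
  if (tot_p <= 0) {
    for (int k = 0; k < rich; ++k) pr[k] = 1.0 / rich;
  } else {
    for (int k = 0; k < rich; ++k) pr[k] = relab[sel[k]] / tot_p;
  }
  R::rmultinom(total, pr.data(), rich, cnt.data());
  for (int k = 0; k < rich; ++k) x[sel[k]] = (double) cnt[k];
}

// Null Bray-Curtis distribution for one sample pair under the Raup-Crick
// assembly null: both communities are reassembled from the metacommunity
// pool conditioning on their observed richness and read totals.
// [[Rcpp::export]]
NumericVector rc_null_bc(int n_null, NumericVector occ, NumericVector relab,
                         int rich_a, int tot_a, int rich_b, int tot_b) {
  const int T = occ.size();
  int pool = 0;
  for (int t = 0; t < T; ++t) if (occ[t] > 0) ++pool;
  if (rich_a > pool || rich_b > pool)
    stop("sample richness exceeds metacommunity pool size");
  NumericVector out(n_null);
  std::vector<double> xa(T), xb(T), keys(T), pr;
  std::vector<int> order_buf(T), sel, cnt;
  for (int r = 0; r < n_null; ++r) {
    draw_null_community(xa, occ, relab, rich_a, tot_a, keys, order_buf, sel,
                        pr, cnt);
    draw_null_community(xb, occ, relab, rich_b, tot_b, keys, order_buf, sel,
                        pr, cnt);
    double num = 0.0, den = 0.0;
    for (int t = 0; t < T; ++t) {
      num += std::fabs(xa[t] - xb[t]);
      den += xa[t] + xb[t];
    }
    out[r] = den > 0 ? num / den : 0.0;
  }
  return out;
}
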