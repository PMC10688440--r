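// Compiled core of the Potions Task simulation.
//
// All randomness is drawn from R's RNG (R::unif_rand) in a fixed, documented
// order so that a run is reproducible from set.seed() alone and so the pure-R
// reference engine in R/engine.R can consume the stream identically:
//
//   per epoch:
//     1. Fisher-Yates shuffle of the agent order (n-1 uniforms)
//     2. per focal agent (skipped without RNG use when isolated):
//        a. partner draw (1 uniform; weighted scan when edge weights exist)
//        b. split draw (1 uniform; < 0.5 means the focal contributes 1 item)
//        c. item draws, focal first then partner, one uniform per item,
//           weighted without replacement over the inventory in ascending
//           item-id order
//        d. on a valid combination with d > 0: one uniform per neighbour
//           lacking the item, focal's neighbours first then partner's, in
//           adjacency order
//     3. when r > 0: a second Fisher-Yates shuffle, then per agent one
//        uniform (rewire?); on success one uniform for the dropped edge and
//        one for the new partner (no further draws when the move is
//        infeasible)
//
// Adjacency lists stay sorted as built; rewiring erases in place and appends
// the new neighbour at the end, which the R reference mirrors.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int unif_pick(int k) {
  int j = (int)std::floor(R::unif_rand() * k);
  return j >= k ? k - 1 : j;
}

static inline int ws_pick(const std::vector<double>& w, int np) {
  double total = 0.0;
  for (int i = 0; i < np; ++i) total += w[i];
  double u = R::unif_rand() * total, acc = 0.0;
  for (int i = 0; i < np; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  return np - 1;
}

static inline void fy_shuffle(std::vector<int>& v) {
  for (int i = (int)v.size(); i > 1; --i) {
    int j = unif_pick(i);
    std::swap(v[i - 1], v[j]);
  }
}

static double gini_sorted(std::vector<double> x) {
  int n = (int)x.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  if (s <= 0.0) return 0.0;
  std::sort(x.begin(), x.end());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += (double)(i + 1) * x[i];
  double xbar = s / n;
  return (2.0 * acc) / ((double)n * n * xbar) - (double)(n + 1) / n;
}

// [[Rcpp::export]]
List run_engine_cpp(List adj0, Nullable<List> wadj0,
                    IntegerMatrix ing, IntegerVector prod,
                    NumericVector item_w, NumericVector item_ts,
                    IntegerVector basics,
                    double d, double r, int max_steps, int post_steps,
                    int a_term, int b_term, int cross_id) {
  const int n = adj0.size();
  const int m = item_w.size();
  const bool weighted = wadj0.isNotNull();

  std::vector<std::vector<int> > adj(n);
  std::vector<std::vector<double> > wadj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj0[i];
    adj[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < adj[i].size(); ++k) adj[i][k] -= 1;
  }
  if (weighted) {
    List wl(wadj0);
    for (int i = 0; i < n; ++i) {
      NumericVector v = wl[i];
      wadj[i].assign(v.begin(), v.end());
    }
  }

  // recipe lookup over sorted 0-based triads, 5 bits per id
  const int nr = ing.nrow();
  std::vector<int> lookup(32 * 32 * 32, -1);
  for (int k = 0; k < nr; ++k) {
    int t[3] = { ing(k, 0) - 1, ing(k, 1) - 1, ing(k, 2) - 1 };
    std::sort(t, t + 3);
    lookup[(t[0] << 10) | (t[1] << 5) | t[2]] = prod[k] - 1;
  }
  const int a3 = a_term - 1, b3 = b_term - 1, x4 = cross_id - 1;

  std::vector<std::vector<char> > inv(n, std::vector<char>(m, 0));
  std::vector<double> score(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < basics.size(); ++k) inv[i][basics[k] - 1] = 1;

  std::vector<char> discovered(m, 0);
  int first_a[2] = {-1, -1}, first_b[2] = {-1, -1}, first_x[2] = {-1, -1};

  std::vector<double> mean_series, gini_series, max_series;
  std::vector<int> order(n), order2(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  order2 = order;

  std::vector<int> pool(m);
  std::vector<double> pw(m);

  bool crossed = false;
  int cross_step = -1;
  int steps = 0;
  int post_left = -1;  // countdown once crossover happened

  while (true) {
    if (crossed && post_left == 0) break;
    if (!crossed && steps >= max_steps) break;
    ++steps;

    for (int i = 0; i < n; ++i) order[i] = i;
    fy_shuffle(order);
    for (int oi = 0; oi < n; ++oi) {
      int focal = order[oi];
      int deg = (int)adj[focal].size();
      if (deg == 0) continue;

      int partner;
      if (weighted) {
        partner = adj[focal][ws_pick(wadj[focal], deg)];
      } else {
        partner = adj[focal][unif_pick(deg)];
      }

      int kf = (R::unif_rand() < 0.5) ? 1 : 2;
      int names[3], nd = 0;
      const int who[2] = { focal, partner };
      const int kk[2] = { kf, 3 - kf };
      for (int s = 0; s < 2; ++s) {
        int ag = who[s];
        int np = 0;
        for (int it = 0; it < m; ++it)
          if (inv[ag][it]) { pool[np] = it; pw[np] = item_w[it]; ++np; }
        for (int t = 0; t < kk[s]; ++t) {
          int idx = ws_pick(pw, np);
          names[nd++] = pool[idx];
          for (int z = idx; z < np - 1; ++z) { pool[z] = pool[z + 1]; pw[z] = pw[z + 1]; }
          --np;
        }
      }

      int t0 = names[0], t1 = names[1], t2 = names[2];
      if (t0 > t1) std::swap(t0, t1);
      if (t1 > t2) std::swap(t1, t2);
      if (t0 > t1) std::swap(t0, t1);
      if (t0 == t1 || t1 == t2) continue;  // non-distinct draw: invalid

      int pr = lookup[(t0 << 10) | (t1 << 5) | t2];
      if (pr < 0) continue;

      if (!discovered[pr]) {
        discovered[pr] = 1;
        if (pr == a3) { first_a[0] = focal; first_a[1] = partner; }
        if (pr == b3) { first_b[0] = focal; first_b[1] = partner; }
        if (pr == x4) { first_x[0] = focal; first_x[1] = partner; crossed = true; }
      }
      for (int s = 0; s < 2; ++s) {
        int ag = who[s];
        if (!inv[ag][pr]) {
          inv[ag][pr] = 1;
          if (item_ts[pr] > score[ag]) score[ag] = item_ts[pr];
        }
      }
      if (d > 0) {
        for (int s = 0; s < 2; ++s) {
          int ag = who[s];
          for (size_t z = 0; z < adj[ag].size(); ++z) {
            int v = adj[ag][z];
            if (!inv[v][pr] && R::unif_rand() < d) {
              inv[v][pr] = 1;
              if (item_ts[pr] > score[v]) score[v] = item_ts[pr];
            }
          }
        }
      }
    }

    if (r > 0) {
      for (int i = 0; i < n; ++i) order2[i] = i;
      fy_shuffle(order2);
      for (int oi = 0; oi < n; ++oi) {
        int a = order2[oi];
        if (R::unif_rand() >= r) continue;
        int deg = (int)adj[a].size();
        if (deg == 0) continue;
        std::vector<char> isnb(n, 0);
        isnb[a] = 1;
        for (int z = 0; z < deg; ++z) isnb[adj[a][z]] = 1;
        std::vector<int> nonnb;
        for (int v = 0; v < n; ++v) if (!isnb[v]) nonnb.push_back(v);
        if (nonnb.empty()) continue;
        int ei = unif_pick(deg);
        int old = adj[a][ei];
        int nw = nonnb[unif_pick((int)nonnb.size())];
        double wgt = weighted ? wadj[a][ei] : 1.0;
        adj[a].erase(adj[a].begin() + ei);
        if (weighted) wadj[a].erase(wadj[a].begin() + ei);
        for (size_t z = 0; z < adj[old].size(); ++z) {
          if (adj[old][z] == a) {
            adj[old].erase(adj[old].begin() + z);
            if (weighted) wadj[old].erase(wadj[old].begin() + z);
            break;
          }
        }
        adj[a].push_back(nw);
        adj[nw].push_back(a);
        if (weighted) { wadj[a].push_back(wgt); wadj[nw].push_back(wgt); }
      }
    }

    double mx = 0.0, mn = 0.0;
    for (int i = 0; i < n; ++i) { mn += score[i]; if (score[i] > mx) mx = score[i]; }
    mean_series.push_back(mn / n);
    max_series.push_back(mx);
    gini_series.push_back(gini_sorted(score));

    if (crossed) {
      if (cross_step < 0) { cross_step = steps; post_left = post_steps; }
      else if (post_left > 0) --post_left;
      if (post_left == 0) break;
    }
  }

  LogicalMatrix inv_out(n, m);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k) inv_out(i, k) = inv[i][k] != 0;

  List adj_out(n), wadj_out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v((int)adj[i].size());
    for (size_t z = 0; z < adj[i].size(); ++z) v[z] = adj[i][z] + 1;
    adj_out[i] = v;
    if (weighted) wadj_out[i] = NumericVector(wadj[i].begin(), wadj[i].end());
  }

  auto pair_out = [](const int* p) {
    if (p[0] < 0) return IntegerVector(0);
    return IntegerVector::create(p[0] + 1, p[1] + 1);
  };

  return List::create(
    _["steps"] = steps,
    _["crossover_achieved"] = crossed,
    _["crossover_step"] = cross_step < 0 ? NA_INTEGER : cross_step,
    _["mean_series"] = NumericVector(mean_series.begin(), mean_series.end()),
    _["gini_series"] = NumericVector(gini_series.begin(), gini_series.end()),
    _["max_series"] = NumericVector(max_series.begin(), max_series.end()),
    _["scores"] = NumericVector(score.begin(), score.end()),
    _["inventory"] = inv_out,
    _["first_a"] = pair_out(first_a),
    _["first_b"] = pair_out(first_b),
    _["first_x"] = pair_out(first_x),
    _["adj_final"] = adj_out,
    _["wadj_final"] = weighted ? (RObject)wadj_out : (RObject)R_NilValue
  );
}
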