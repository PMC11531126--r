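#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Survival tree growing with log-rank split search.
//
// Node membership is a vector of data row indices (bootstrap multiplicity
// preserved). For each candidate feature the rows are sorted by value and
// moved one by one from the right to the left group; per-event-time at-risk
// and event counts for the left group are maintained incrementally, so each
// feature costs O(m * K) where m is node size and K the number of distinct
// event times in the node. The standardized absolute log-rank statistic
// |W| / sqrt(V) is maximized; ties are broken uniformly at random using R's
// RNG stream (so set.seed() on the R side makes forests reproducible).

namespace {

struct NodeWork {
  std::vector<int> rows;  // data row indices (with multiplicity)
  int depth;
  int node_id;
};

struct SplitResult {
  bool found;
  int feature;       // 0-based column
  double value;      // threshold: go left if x <= value
  double stat;
};

// Log-rank search over one feature within a node.
// dtimes: distinct event times in node (ascending); dtot/ytot: total event
// and at-risk counts per distinct time; ub[r]: number of dtimes <= Y_r for
// node-local row r; evt[r]: index into dtimes if row r is an event (-1
// otherwise); n_events: total events in node.
void search_feature(const NumericVector& xcol,
                    const std::vector<int>& rows,
                    const std::vector<int>& ub,
                    const std::vector<int>& evt,
                    const std::vector<double>& dtot,
                    const std::vector<double>& ytot,
                    int n_events,
                    double& best_stat, double& best_value, bool& any,
                    int& n_ties, int feature, int& best_feature) {
  const int m = rows.size();
  const int K = dtot.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return xcol[rows[a]] < xcol[rows[b]];
  });
  std::vector<double> yl(K, 0.0), dl(K, 0.0);
  int ev_left = 0;
  for (int s = 0; s < m - 1; ++s) {
    int r = ord[s];
    for (int k = 0; k < ub[r]; ++k) yl[k] += 1.0;
    if (evt[r] >= 0) { dl[evt[r]] += 1.0; ev_left += 1; }
    double v_here = xcol[rows[r]];
    double v_next = xcol[rows[ord[s + 1]]];
    if (v_next <= v_here) continue;           // not a boundary between values
    if (ev_left < 1 || (n_events - ev_left) < 1) continue;
    double W = 0.0, V = 0.0;
    for (int k = 0; k < K; ++k) {
      double Y = ytot[k];
      if (Y <= 0) continue;
      double frac = yl[k] / Y;
      W += dl[k] - frac * dtot[k];
      if (Y > 1.0) {
        V += dtot[k] * frac * (1.0 - frac) * (Y - dtot[k]) / (Y - 1.0);
      }
    }
    if (V <= 1e-12) continue;
    double stat = std::fabs(W) / std::sqrt(V);
    double thr = 0.5 * (v_here + v_next);
    double rel_tol = 1e-10 * std::max(1.0, best_stat);
    if (!any || stat > best_stat + rel_tol) {
      best_stat = stat; best_value = thr; best_feature = feature;
      any = true; n_ties = 1;
    } else if (std::fabs(stat - best_stat) <= rel_tol) {
      // equal-score candidates: reservoir-sample one uniformly
      n_ties += 1;
      if (unif_rand() < 1.0 / n_ties) {
        best_value = thr; best_feature = feature;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector times, IntegerVector events,
                   IntegerVector inbag, int mtry, int nodesize,
                   int min_unique_events) {
  const int p = X.ncol();
  std::vector<int> feature_out, left_out, right_out, depth_out;
  std::vector<double> value_out;
  std::vector<std::vector<int> > leaf_rows;

  std::vector<NodeWork> stack;
  NodeWork root;
  root.rows.assign(inbag.begin(), inbag.end());
  root.depth = 0;
  root.node_id = 0;
  feature_out.push_back(-1); value_out.push_back(NA_REAL);
  left_out.push_back(-1); right_out.push_back(-1); depth_out.push_back(0);
  leaf_rows.push_back(std::vector<int>());
  stack.push_back(root);

  std::vector<int> feat_pool(p);

  while (!stack.empty()) {
    NodeWork nd = stack.back();
    stack.pop_back();
    const std::vector<int>& rows = nd.rows;
    const int m = rows.size();

    // node-local event-time table
    std::vector<double> et;
    int n_events = 0;
    for (int r : rows) if (events[r] == 1) { et.push_back(times[r]); ++n_events; }
    std::sort(et.begin(), et.end());
    et.erase(std::unique(et.begin(), et.end()), et.end());
    const int K = et.size();

    bool make_leaf = (n_events < nodesize) || (K < min_unique_events);

    SplitResult best = {false, -1, 0.0, 0.0};
    if (!make_leaf) {
      std::vector<int> ub(m), evt(m, -1);
      std::vector<double> dtot(K, 0.0), ytot(K, 0.0);
      for (int i = 0; i < m; ++i) {
        int r = rows[i];
        int u = std::upper_bound(et.begin(), et.end(), times[r]) - et.begin();
        ub[i] = u;
        for (int k = 0; k < u; ++k) ytot[k] += 1.0;
        if (events[r] == 1) {
          int k = std::lower_bound(et.begin(), et.end(), times[r]) - et.begin();
          evt[i] = k;
          dtot[k] += 1.0;
        }
      }
      // sample mtry features without replacement via partial Fisher-Yates
      for (int j = 0; j < p; ++j) feat_pool[j] = j;
      int n_try = std::min(mtry, p);
      double best_stat = 0.0, best_value = 0.0;
      int best_feature = -1, n_ties = 0;
      bool any = false;
      for (int t = 0; t < n_try; ++t) {
        int pick = t + (int)(unif_rand() * (p - t));
        if (pick >= p) pick = p - 1;
        std::swap(feat_pool[t], feat_pool[pick]);
        int f = feat_pool[t];
        NumericVector xcol = X(_, f);
        search_feature(xcol, rows, ub, evt, dtot, ytot, n_events,
                       best_stat, best_value, any, n_ties, f, best_feature);
      }
      if (any) {
        best.found = true; best.feature = best_feature;
        best.value = best_value; best.stat = best_stat;
      } else {
        make_leaf = true;
      }
    }

    if (make_leaf) {
      leaf_rows[nd.node_id] = rows;
      continue;
    }

    NumericVector xcol = X(_, best.feature);
    NodeWork lft, rgt;
    for (int r : rows) {
      if (xcol[r] <= best.value) lft.rows.push_back(r);
      else rgt.rows.push_back(r);
    }
    int lid = feature_out.size();
    int rid = lid + 1;
    feature_out[nd.node_id] = best.feature;
    value_out[nd.node_id] = best.value;
    left_out[nd.node_id] = lid;
    right_out[nd.node_id] = rid;
    for (int c = 0; c < 2; ++c) {
      feature_out.push_back(-1); value_out.push_back(NA_REAL);
      left_out.push_back(-1); right_out.push_back(-1);
      depth_out.push_back(nd.depth + 1);
      leaf_rows.push_back(std::vector<int>());
    }
    lft.depth = rgt.depth = nd.depth + 1;
    lft.node_id = lid; rgt.node_id = rid;
    stack.push_back(rgt);
    stack.push_back(lft);
  }

  const int n_nodes = feature_out.size();
  List leaves(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    leaves[i] = wrap(leaf_rows[i]);  // 0-based data rows; empty if internal
  }
  return List::create(
      _["feature"] = wrap(feature_out), _["value"] = wrap(value_out),
      _["left"] = wrap(left_out), _["right"] = wrap(right_out),
      _["depth"] = wrap(depth_out), _["leaf_rows"] = leaves);
}

// [[Rcpp::export]]
IntegerVector predict_leaf_cpp(IntegerVector feature, NumericVector value,
                               IntegerVector left, IntegerVector right,
                               NumericMatrix Xnew) {
  const int n = Xnew.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (Xnew(i, feature[node]) <= value[node]) ? left[node]
                                                     : right[node];
    }
    out[i] = node;  // 0-based node id
  }
  return out;
}
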