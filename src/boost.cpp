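#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Gradient-boosted trees for binary outcomes (logistic loss, Newton leaves).
// Missing feature values are routed natively: each split learns a default
// direction by evaluating the gain with the missing block on either side.

struct TNode {
  int feature = -1;          // -1 => leaf
  double threshold = 0.0;
  bool miss_left = true;
  int left = -1, right = -1;
  double value = 0.0;
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  bool miss_left = true;
  double gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X,
                              const std::vector<double>& g,
                              const std::vector<double>& h,
                              const std::vector<int>& rows,
                              double lambda, int min_obs) {
  SplitResult best;
  const int p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  const double parent_score = G * G / (H + lambda);

  std::vector<std::pair<double, int>> vals;
  vals.reserve(rows.size());
  for (int f = 0; f < p; ++f) {
    vals.clear();
    double Gm = 0.0, Hm = 0.0;
    int nm = 0;
    for (int r : rows) {
      const double v = X(r, f);
      if (ISNAN(v)) { Gm += g[r]; Hm += h[r]; ++nm; }
      else vals.push_back(std::make_pair(v, r));
    }
    const int np = (int)vals.size();
    if (np < 2) continue;
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < np; ++i) {
      GL += g[vals[i].second]; HL += h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue;
      const double GR = G - Gm - GL, HR = H - Hm - HL;
      const int nl = i + 1, nr = np - nl;
      // missing rows to the left
      if (nl + nm >= min_obs && nr >= min_obs) {
        const double gain = (GL + Gm) * (GL + Gm) / (HL + Hm + lambda) +
          GR * GR / (HR + lambda) - parent_score;
        if (gain > best.gain) {
          best.gain = gain; best.feature = f; best.miss_left = true;
          best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
      // missing rows to the right
      if (nl >= min_obs && nr + nm >= min_obs) {
        const double gain = GL * GL / (HL + lambda) +
          (GR + Gm) * (GR + Gm) / (HR + Hm + lambda) - parent_score;
        if (gain > best.gain) {
          best.gain = gain; best.feature = f; best.miss_left = false;
          best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
  }
  return best;
}

static int build_node(const NumericMatrix& X, const std::vector<double>& g,
                      const std::vector<double>& h, std::vector<int>& rows,
                      int depth, int max_depth, double lambda, int min_obs,
                      double learn_rate, std::vector<TNode>& nodes,
                      std::vector<double>& importance) {
  const int id = (int)nodes.size();
  nodes.push_back(TNode());
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  SplitResult sp;
  if (depth < max_depth && (int)rows.size() >= 2 * min_obs)
    sp = best_split(X, g, h, rows, lambda, min_obs);
  if (sp.feature < 0 || sp.gain <= 1e-12) {
    nodes[id].value = learn_rate * G / (H + lambda);
    return id;
  }
  importance[sp.feature] += sp.gain;
  std::vector<int> lrows, rrows;
  for (int r : rows) {
    const double v = X(r, sp.feature);
    const bool go_left = ISNAN(v) ? sp.miss_left : (v < sp.threshold);
    (go_left ? lrows : rrows).push_back(r);
  }
  rows.clear(); rows.shrink_to_fit();
  nodes[id].feature = sp.feature;
  nodes[id].threshold = sp.threshold;
  nodes[id].miss_left = sp.miss_left;
  const int lid = build_node(X, g, h, lrows, depth + 1, max_depth, lambda,
                             min_obs, learn_rate, nodes, importance);
  const int rid = build_node(X, g, h, rrows, depth + 1, max_depth, lambda,
                             min_obs, learn_rate, nodes, importance);
  nodes[id].left = lid;
  nodes[id].right = rid;
  return id;
}

static NumericMatrix pack_tree(const std::vector<TNode>& nodes) {
  NumericMatrix m((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;    // -1 for leaf, 0-based otherwise
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].miss_left ? 1.0 : 0.0;
    m(i, 3) = nodes[i].left;
    m(i, 4) = nodes[i].right;
    m(i, 5) = nodes[i].value;
  }
  return m;
}

static double tree_predict(const NumericMatrix& m, const NumericMatrix& X,
                           int row) {
  int id = 0;
  while ((int)m(id, 0) >= 0) {
    const double v = X(row, (int)m(id, 0));
    const bool go_left = ISNAN(v) ? (m(id, 2) > 0.5) : (v < m(id, 1));
    id = (int)(go_left ? m(id, 3) : m(id, 4));
  }
  return m(id, 5);
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                 double learn_rate, double subsample, int min_obs,
                 double lambda, int seed) {
  const int n = X.nrow(), p = X.ncol();
  const double ybar = mean(y);
  const double f0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, f0), g(n), h(n);
  std::vector<double> importance(p, 0.0);
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = y[i] - pr;
      h[i] = std::max(pr * (1.0 - pr), 1e-10);
    }
    std::vector<int> rows;
    if (subsample < 1.0) {
      std::vector<int> perm = all;
      std::shuffle(perm.begin(), perm.end(), rng);
      const int m = std::max(2 * min_obs, (int)std::floor(subsample * n));
      rows.assign(perm.begin(), perm.begin() + std::min(m, n));
    } else rows = all;
    std::vector<TNode> nodes;
    build_node(X, g, h, rows, 0, max_depth, lambda, min_obs, learn_rate,
               nodes, importance);
    NumericMatrix tm = pack_tree(nodes);
    for (int i = 0; i < n; ++i) F[i] += tree_predict(tm, X, i);
    trees[t] = tm;
  }
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export]]
NumericVector cpp_gbt_margin(List trees, double f0, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector F(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) F[i] += tree_predict(tm, X, i);
  }
  return F;
}
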