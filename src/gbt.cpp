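// Gradient-boosted decision trees for binary classification with logistic
// loss and Newton leaf weights (second-order boosting). Level-wise exact
// greedy split search over presorted feature columns. Uses R's RNG for row
// subsampling so fits are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // split: x <= threshold -> left
  std::vector<int> left, right;  // child node ids, -1 for leaves
  std::vector<double> value;     // leaf weight (0 for internal)

  int addNode() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

double leafWeight(double G, double H, double lambda) {
  return -G / (H + lambda);
}

double scoreOf(double G, double H, double lambda) {
  return G * G / (H + lambda);
}

// Grow one depth-limited tree on gradients/hessians; rows with node[i] < 0
// are excluded (subsampling). Returns the tree; `node` is clobbered.
Tree growTree(const NumericMatrix& X,
              const std::vector<std::vector<int> >& sortedIdx,
              const std::vector<double>& grad,
              const std::vector<double>& hess,
              std::vector<int>& node,
              int maxDepth, double lambda, int minChild) {
  const int n = X.nrow(), p = X.ncol();
  Tree tree;
  tree.addNode(); // root = 0

  std::vector<int> frontier(1, 0); // node ids at current depth
  for (int depth = 0; depth < maxDepth && !frontier.empty(); ++depth) {
    int nNodes = (int)tree.feature.size();
    // aggregate G, H, counts per node
    std::vector<double> G(nNodes, 0.0), H(nNodes, 0.0);
    std::vector<int> cnt(nNodes, 0);
    for (int i = 0; i < n; ++i) {
      int nd = node[i];
      if (nd < 0) continue;
      G[nd] += grad[i];
      H[nd] += hess[i];
      cnt[nd] += 1;
    }
    std::vector<char> active(nNodes, 0);
    for (size_t a = 0; a < frontier.size(); ++a)
      if (cnt[frontier[a]] >= 2 * minChild) active[frontier[a]] = 1;

    std::vector<double> bestGain(nNodes, 1e-12), bestThr(nNodes, 0.0);
    std::vector<int> bestFeat(nNodes, -1);

    std::vector<double> gl(nNodes), hl(nNodes), lastVal(nNodes);
    std::vector<int> cl(nNodes);
    for (int j = 0; j < p; ++j) {
      std::fill(gl.begin(), gl.end(), 0.0);
      std::fill(hl.begin(), hl.end(), 0.0);
      std::fill(cl.begin(), cl.end(), 0);
      std::vector<char> seen(nNodes, 0);
      const std::vector<int>& ord = sortedIdx[j];
      for (size_t r = 0; r < ord.size(); ++r) {
        int i = ord[r];
        int nd = node[i];
        if (nd < 0 || !active[nd]) continue;
        double v = X(i, j);
        if (seen[nd] && v > lastVal[nd] && cl[nd] >= minChild &&
            cnt[nd] - cl[nd] >= minChild) {
          double gain = scoreOf(gl[nd], hl[nd], lambda) +
                        scoreOf(G[nd] - gl[nd], H[nd] - hl[nd], lambda) -
                        scoreOf(G[nd], H[nd], lambda);
          if (gain > bestGain[nd]) {
            bestGain[nd] = gain;
            bestFeat[nd] = j;
            bestThr[nd] = 0.5 * (lastVal[nd] + v);
          }
        }
        gl[nd] += grad[i];
        hl[nd] += hess[i];
        cl[nd] += 1;
        lastVal[nd] = v;
        seen[nd] = 1;
      }
    }

    // realize splits, reassign rows
    std::vector<int> newFrontier;
    std::vector<char> splitNode(nNodes, 0);
    for (size_t a = 0; a < frontier.size(); ++a) {
      int nd = frontier[a];
      if (bestFeat[nd] >= 0) {
        tree.feature[nd] = bestFeat[nd];
        tree.threshold[nd] = bestThr[nd];
        tree.left[nd] = tree.addNode();
        tree.right[nd] = tree.addNode();
        splitNode[nd] = 1;
        newFrontier.push_back(tree.left[nd]);
        newFrontier.push_back(tree.right[nd]);
      }
    }
    for (int i = 0; i < n; ++i) {
      int nd = node[i];
      if (nd < 0 || nd >= nNodes || !splitNode[nd]) continue;
      node[i] = (X(i, tree.feature[nd]) <= tree.threshold[nd])
                    ? tree.left[nd] : tree.right[nd];
    }
    frontier.swap(newFrontier);
  }

  // leaf values
  int nNodes = (int)tree.feature.size();
  std::vector<double> G(nNodes, 0.0), H(nNodes, 0.0);
  for (int i = 0; i < n; ++i) {
    int nd = node[i];
    if (nd < 0) continue;
    G[nd] += grad[i];
    H[nd] += hess[i];
  }
  for (int nd = 0; nd < nNodes; ++nd)
    if (tree.feature[nd] < 0) tree.value[nd] = leafWeight(G[nd], H[nd], lambda);
  return tree;
}

double treePredictRow(const Tree& tree, const NumericMatrix& X, int i) {
  int nd = 0;
  while (tree.feature[nd] >= 0)
    nd = (X(i, tree.feature[nd]) <= tree.threshold[nd]) ? tree.left[nd]
                                                        : tree.right[nd];
  return tree.value[nd];
}

List treeToList(const Tree& tree) {
  return List::create(_["feature"] = wrap(tree.feature),
                      _["threshold"] = wrap(tree.threshold),
                      _["left"] = wrap(tree.left),
                      _["right"] = wrap(tree.right),
                      _["value"] = wrap(tree.value));
}

Tree treeFromList(const List& lst) {
  Tree t;
  IntegerVector f = lst["feature"], l = lst["left"], r = lst["right"];
  NumericVector thr = lst["threshold"], val = lst["value"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(thr.begin(), thr.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.value.assign(val.begin(), val.end());
  return t;
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int nTrees, int maxDepth,
                 double learningRate, double subsample, double lambda,
                 int minChild) {
  const int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("X and y sizes differ");

  // presort feature columns once
  std::vector<std::vector<int> > sortedIdx(p);
  for (int j = 0; j < p; ++j) {
    std::vector<int>& ord = sortedIdx[j];
    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    const int jj = j;
    std::stable_sort(ord.begin(), ord.end(), [&X, jj](int a, int b) {
      return X(a, jj) < X(b, jj);
    });
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-10, std::max(1e-10, ybar));
  const double f0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> margin(n, f0), grad(n), hess(n);
  std::vector<int> node(n);
  List trees(nTrees);

  RNGScope rngScope; // row subsampling draws from R's RNG
  for (int t = 0; t < nTrees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    for (int i = 0; i < n; ++i)
      node[i] = (subsample >= 1.0 || R::unif_rand() < subsample) ? 0 : -1;
    Tree tree = growTree(X, sortedIdx, grad, hess, node, maxDepth, lambda,
                         minChild);
    for (int i = 0; i < n; ++i)
      margin[i] += learningRate * treePredictRow(tree, X, i);
    trees[t] = treeToList(tree);
  }

  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["learning_rate"] = learningRate,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  if (as<int>(model["n_features"]) != X.ncol())
    stop("feature count mismatch between model and new data");
  const double f0 = as<double>(model["f0"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  NumericVector out(n, f0);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tree = treeFromList(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += lr * treePredictRow(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
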