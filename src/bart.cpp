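// Probit Bayesian Additive Regression Trees.
//
// Sum-of-trees model for a binary outcome with Albert-Chib latent-variable
// augmentation: y_i = 1{z_i > 0}, z_i ~ N(sum_j g(x_i; T_j, M_j), 1).
// Trees are updated by Bayesian backfitting with Metropolis-Hastings
// structural moves (grow / prune / change) under the standard
// depth-regularizing prior p(split at depth d) = alpha (1 + d)^(-beta),
// leaf values mu ~ N(0, sigma_mu^2) with conjugate normal conditionals.
//
// Randomness comes from R's RNG (RNGScope), so results are reproducible
// with set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;      // split variable (0-based); -1 for a leaf
  double split; // rule: x[var] < split goes left
  int left, right, parent;
  double mu;    // leaf value (leaves only)
  int depth;
  bool active;
};

struct Tree {
  std::vector<Node> nodes;
  Tree() {
    Node root;
    root.var = -1; root.split = 0.0; root.left = -1; root.right = -1;
    root.parent = -1; root.mu = 0.0; root.depth = 0; root.active = true;
    nodes.push_back(root);
  }
  bool is_leaf(int k) const { return nodes[k].var < 0; }
  bool is_nog(int k) const { // internal node whose both children are leaves
    return !is_leaf(k) && is_leaf(nodes[k].left) && is_leaf(nodes[k].right);
  }
  std::vector<int> leaves() const {
    std::vector<int> out;
    for (int k = 0; k < (int)nodes.size(); ++k)
      if (nodes[k].active && is_leaf(k)) out.push_back(k);
    return out;
  }
  std::vector<int> nogs() const {
    std::vector<int> out;
    for (int k = 0; k < (int)nodes.size(); ++k)
      if (nodes[k].active && is_nog(k)) out.push_back(k);
    return out;
  }
  int traverse(const double *xrow, int n, int i) const {
    int k = 0;
    while (!is_leaf(k)) {
      const Node &nd = nodes[k];
      k = (xrow[nd.var * (long)n + i] < nd.split) ? nd.left : nd.right;
    }
    return k;
  }
};

// standard normal truncated to (a, Inf); Robert (1995) for far tails
double rtnorm_lower(double a) {
  if (a <= 0.0) {
    for (;;) {
      double x = norm_rand();
      if (x > a) return x;
    }
  }
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(unif_rand()) / lambda;
    double d = x - lambda;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

// z ~ N(mean, 1) truncated to (0, Inf) if positive, else (-Inf, 0]
double rtruncnorm01(double mean, bool positive) {
  if (positive) return mean + rtnorm_lower(-mean);
  return mean - rtnorm_lower(mean);
}

// log integrated likelihood of a leaf: residuals r ~ N(mu, 1),
// mu ~ N(0, s2mu); terms common to all structures dropped
double leaf_logml(double n, double s, double s2mu) {
  double denom = 1.0 + n * s2mu;
  return -0.5 * std::log(denom) + 0.5 * s2mu * s * s / denom;
}

double psplit(int depth, double alpha, double beta) {
  return alpha * std::pow(1.0 + depth, -beta);
}

} // namespace

// [[Rcpp::export]]
NumericVector sample_latent_cpp(IntegerVector y, NumericVector eta) {
  RNGScope scope;
  int n = y.size();
  NumericVector z(n);
  for (int i = 0; i < n; ++i) z[i] = rtruncnorm01(eta[i], y[i] == 1);
  return z;
}

// [[Rcpp::export]]
List bart_probit_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                     int m, int burn_in, int num_draws,
                     double alpha, double beta, double k_leaf,
                     double p_grow, double p_prune, double p_change,
                     bool keep_trees) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol(), ntest = Xtest.nrow();
  const double s2mu_sd = 3.0 / (k_leaf * std::sqrt((double)m));
  const double s2mu = s2mu_sd * s2mu_sd;

  // split-point candidates: distinct observed values per variable
  std::vector<std::vector<double>> cuts(p);
  for (int v = 0; v < p; ++v) {
    std::vector<double> vals(n);
    for (int i = 0; i < n; ++i) vals[i] = X(i, v);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    cuts[v] = vals;
  }

  std::vector<Tree> trees(m);
  std::vector<std::vector<int>> nodeof(m, std::vector<int>(n, 0));
  std::vector<double> allfit(n, 0.0), fitj(n), z(n);
  for (int i = 0; i < n; ++i) z[i] = rtruncnorm01(0.0, y[i] == 1);

  NumericMatrix test_draws(num_draws, ntest);
  NumericMatrix train_draws_sum(1, 1); // placeholder
  NumericVector train_mean(n, 0.0);
  NumericVector avg_leaves(num_draws);
  std::vector<double> tree_store; // rows: draw, tree, node, var, split, L, R, mu
  const double *xp = X.begin();

  int total_iter = burn_in + num_draws;
  for (int iter = 0; iter < total_iter; ++iter) {
    for (int j = 0; j < m; ++j) {
      Tree &tr = trees[j];
      std::vector<int> &asg = nodeof[j];
      // partial residual R = z - (allfit - fit_j)
      for (int i = 0; i < n; ++i) fitj[i] = tr.nodes[asg[i]].mu;
      // leaf sufficient stats
      int nn = tr.nodes.size();
      std::vector<double> cnt(nn, 0.0), sum(nn, 0.0);
      for (int i = 0; i < n; ++i) {
        double r = z[i] - allfit[i] + fitj[i];
        cnt[asg[i]] += 1.0;
        sum[asg[i]] += r;
      }
      // propose a structural move
      double u = unif_rand();
      std::vector<int> lv = tr.leaves();
      std::vector<int> ng = tr.nogs();
      if (u < p_grow) {
        // GROW
        int li = lv[(int)(unif_rand() * lv.size())];
        int v = (int)(unif_rand() * p);
        const std::vector<double> &cv = cuts[v];
        double c = cv[(int)(unif_rand() * cv.size())];
        double nl = 0, sl = 0, nr = 0, sr = 0;
        for (int i = 0; i < n; ++i) {
          if (asg[i] != li) continue;
          double r = z[i] - allfit[i] + fitj[i];
          if (X(i, v) < c) { nl += 1; sl += r; } else { nr += 1; sr += r; }
        }
        if (nl > 0 && nr > 0) {
          int d = tr.nodes[li].depth;
          double logml_new = leaf_logml(nl, sl, s2mu) +
                             leaf_logml(nr, sr, s2mu);
          double logml_old = leaf_logml(cnt[li], sum[li], s2mu);
          double ps_d = psplit(d, alpha, beta);
          double ps_d1 = psplit(d + 1, alpha, beta);
          double log_prior = std::log(ps_d) + 2.0 * std::log(1.0 - ps_d1) -
                             std::log(1.0 - ps_d);
          // nog count after growing at li: li becomes nog; its parent may
          // stop being nog
          int nog_after = (int)ng.size() + 1;
          int par = tr.nodes[li].parent;
          if (par >= 0 && tr.is_nog(par)) nog_after -= 1;
          // rule-choice factors (1/p, 1/ncut) appear identically in the
          // tree prior and the grow proposal and cancel
          double log_prop = std::log(p_prune) - std::log((double)nog_after)
              - std::log(p_grow) + std::log((double)lv.size());
          double logr = logml_new - logml_old + log_prior + log_prop;
          if (std::log(unif_rand()) < logr) {
            Node lch, rch;
            lch.var = -1; lch.split = 0; lch.left = -1; lch.right = -1;
            lch.parent = li; lch.mu = 0; lch.depth = d + 1; lch.active = true;
            rch = lch;
            int il = tr.nodes.size(); tr.nodes.push_back(lch);
            int ir = tr.nodes.size(); tr.nodes.push_back(rch);
            tr.nodes[li].var = v; tr.nodes[li].split = c;
            tr.nodes[li].left = il; tr.nodes[li].right = ir;
            for (int i = 0; i < n; ++i)
              if (asg[i] == li) asg[i] = (X(i, v) < c) ? il : ir;
          }
        }
      } else if (u < p_grow + p_prune) {
        // PRUNE
        if (!ng.empty()) {
          int gi = ng[(int)(unif_rand() * ng.size())];
          int il = trees[j].nodes[gi].left, ir = trees[j].nodes[gi].right;
          double nl = cnt[il], sl = sum[il], nr = cnt[ir], sr = sum[ir];
          int d = tr.nodes[gi].depth;
          double logml_new = leaf_logml(nl + nr, sl + sr, s2mu);
          double logml_old = leaf_logml(nl, sl, s2mu) +
                             leaf_logml(nr, sr, s2mu);
          double ps_d = psplit(d, alpha, beta);
          double ps_d1 = psplit(d + 1, alpha, beta);
          double log_prior = -(std::log(ps_d) +
                               2.0 * std::log(1.0 - ps_d1) -
                               std::log(1.0 - ps_d));
          int nleaf_after = (int)lv.size() - 1;
          double log_prop = std::log(p_grow)
              - std::log((double)nleaf_after)
              - std::log(p_prune) + std::log((double)ng.size());
          double logr = logml_new - logml_old + log_prior + log_prop;
          if (std::log(unif_rand()) < logr) {
            tr.nodes[il].active = false;
            tr.nodes[ir].active = false;
            tr.nodes[gi].var = -1;
            tr.nodes[gi].left = -1; tr.nodes[gi].right = -1;
            for (int i = 0; i < n; ++i)
              if (asg[i] == il || asg[i] == ir) asg[i] = gi;
          }
        }
      } else {
        // CHANGE rule of a no-grandchild internal node
        if (!ng.empty()) {
          int gi = ng[(int)(unif_rand() * ng.size())];
          int il = tr.nodes[gi].left, ir = tr.nodes[gi].right;
          int v = (int)(unif_rand() * p);
          const std::vector<double> &cv = cuts[v];
          double c = cv[(int)(unif_rand() * cv.size())];
          double nl = 0, sl = 0, nr = 0, sr = 0;
          for (int i = 0; i < n; ++i) {
            if (asg[i] != il && asg[i] != ir) continue;
            double r = z[i] - allfit[i] + fitj[i];
            if (X(i, v) < c) { nl += 1; sl += r; } else { nr += 1; sr += r; }
          }
          if (nl > 0 && nr > 0) {
            double logr = leaf_logml(nl, sl, s2mu) +
                          leaf_logml(nr, sr, s2mu) -
                          leaf_logml(cnt[il], sum[il], s2mu) -
                          leaf_logml(cnt[ir], sum[ir], s2mu);
            if (std::log(unif_rand()) < logr) {
              tr.nodes[gi].var = v; tr.nodes[gi].split = c;
              for (int i = 0; i < n; ++i)
                if (asg[i] == il || asg[i] == ir)
                  asg[i] = (X(i, v) < c) ? il : ir;
            }
          }
        }
      }
      // redraw leaf values from their normal conditionals
      int nn2 = tr.nodes.size();
      std::vector<double> cnt2(nn2, 0.0), sum2(nn2, 0.0);
      for (int i = 0; i < n; ++i) {
        double r = z[i] - allfit[i] + fitj[i];
        cnt2[asg[i]] += 1.0;
        sum2[asg[i]] += r;
      }
      for (int k = 0; k < nn2; ++k) {
        if (!tr.nodes[k].active || !tr.is_leaf(k)) continue;
        double post_var = s2mu / (1.0 + cnt2[k] * s2mu);
        double post_mean = post_var * sum2[k];
        tr.nodes[k].mu = post_mean + std::sqrt(post_var) * norm_rand();
      }
      // update fits
      for (int i = 0; i < n; ++i) {
        double newfit = tr.nodes[asg[i]].mu;
        allfit[i] += newfit - fitj[i];
      }
    }
    // redraw latents
    for (int i = 0; i < n; ++i) z[i] = rtruncnorm01(allfit[i], y[i] == 1);

    if (iter >= burn_in) {
      int s = iter - burn_in;
      // test predictions by traversal
      const double *xt = Xtest.begin();
      for (int i = 0; i < ntest; ++i) {
        double tot = 0.0;
        for (int j = 0; j < m; ++j) {
          int k = trees[j].traverse(xt, ntest, i);
          tot += trees[j].nodes[k].mu;
        }
        test_draws(s, i) = tot;
      }
      for (int i = 0; i < n; ++i) train_mean[i] += allfit[i];
      int nl_tot = 0;
      for (int j = 0; j < m; ++j) nl_tot += (int)trees[j].leaves().size();
      avg_leaves[s] = (double)nl_tot / m;
      if (keep_trees) {
        for (int j = 0; j < m; ++j) {
          const Tree &tr = trees[j];
          for (int k = 0; k < (int)tr.nodes.size(); ++k) {
            if (!tr.nodes[k].active) continue;
            const Node &nd = tr.nodes[k];
            double row[8] = {(double)(s + 1), (double)(j + 1), (double)k,
                             (double)(nd.var + 1), nd.split,
                             (double)nd.left, (double)nd.right, nd.mu};
            tree_store.insert(tree_store.end(), row, row + 8);
          }
        }
      }
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i) train_mean[i] /= num_draws;

  NumericMatrix trees_out;
  if (keep_trees) {
    int nr = tree_store.size() / 8;
    trees_out = NumericMatrix(nr, 8);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < 8; ++c) trees_out(r, c) = tree_store[r * 8 + c];
  }
  return List::create(_["test_draws"] = test_draws,
                      _["train_probit_mean"] = train_mean,
                      _["avg_leaves"] = avg_leaves,
                      _["trees"] = trees_out);
}

// predict probit-scale draws from serialized trees
// rows of `trees`: draw, tree, node_id, var (0 = leaf), split, left, right, mu
// [[Rcpp::export]]
NumericMatrix bart_predict_cpp(NumericMatrix trees, NumericMatrix Xnew,
                               int num_draws, int m) {
  const int nnew = Xnew.nrow(), nr = trees.nrow();
  NumericMatrix out(num_draws, nnew);
  // index rows by (draw, tree): node_id -> row
  int r = 0;
  while (r < nr) {
    int s = (int)trees(r, 0), j = (int)trees(r, 1);
    int r0 = r;
    while (r < nr && (int)trees(r, 0) == s && (int)trees(r, 1) == j) ++r;
    // map node id -> row index for this tree
    int max_id = 0;
    for (int q = r0; q < r; ++q)
      if ((int)trees(q, 2) > max_id) max_id = (int)trees(q, 2);
    std::vector<int> rowof(max_id + 1, -1);
    for (int q = r0; q < r; ++q) rowof[(int)trees(q, 2)] = q;
    for (int i = 0; i < nnew; ++i) {
      int k = 0; // root has node id 0
      for (;;) {
        int q = rowof[k];
        int var = (int)trees(q, 3);
        if (var == 0) { out(s - 1, i) += trees(q, 7); break; }
        k = (Xnew(i, var - 1) < trees(q, 4)) ? (int)trees(q, 5)
                                             : (int)trees(q, 6);
      }
    }
  }
  return out;
}
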