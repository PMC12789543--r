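// Sum-of-trees MCMC: Bayesian backfitting with grow/prune/change
// Metropolis-Hastings proposals, conjugate normal leaves integrated out,
// leaf means redrawn from their conditional, and the error variance from
// a scaled inverse-chi-square full conditional. The response is assumed
// already standardised by the R wrapper.
//
// Trees are stored as flat node arrays with a free list so grow/prune do
// not reallocate; serialisation compacts live nodes depth-first.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // var < 0 marks a leaf; children indices, -1 when leaf
  std::vector<int> var, left, right, parent;
  std::vector<double> cut, mu;
  std::vector<int> freelist;

  Tree() { reset(); }

  void reset() {
    var.assign(1, -1); left.assign(1, -1); right.assign(1, -1);
    parent.assign(1, -1); cut.assign(1, 0.0); mu.assign(1, 0.0);
    freelist.clear();
  }

  bool is_leaf(int i) const { return var[i] < 0; }

  int new_node(int par) {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else {
      id = (int)var.size();
      var.push_back(-1); left.push_back(-1); right.push_back(-1);
      parent.push_back(-1); cut.push_back(0.0); mu.push_back(0.0);
    }
    var[id] = -1; left[id] = -1; right[id] = -1; parent[id] = par;
    cut[id] = 0.0; mu[id] = 0.0;
    return id;
  }

  int depth(int i) const {
    int d = 0;
    while (parent[i] >= 0) { i = parent[i]; ++d; }
    return d;
  }

  int leaf_for(const double* xrow, int n /*stride*/) const {
    int node = 0;
    while (!is_leaf(node))
      node = (xrow[(size_t)var[node] * n] <= cut[node]) ? left[node] : right[node];
    return node;
  }

  void collect(int node, std::vector<int>& leaves, std::vector<int>& nogs) const {
    if (is_leaf(node)) { leaves.push_back(node); return; }
    if (is_leaf(left[node]) && is_leaf(right[node])) nogs.push_back(node);
    collect(left[node], leaves, nogs);
    collect(right[node], leaves, nogs);
  }
};

// walk x (row `xrow` of an n-row column-major matrix) down from `node`
int descend_node(const Tree& T, int node, const double* xrow, int n) {
  while (!T.is_leaf(node))
    node = (xrow[(size_t)T.var[node] * n] <= T.cut[node]) ? T.left[node] : T.right[node];
  return node;
}

struct Sampler {
  const NumericMatrix& X;   // n x p
  int n, p;
  std::vector<std::vector<double> > cuts;  // candidate cutpoints per feature
  double alpha, beta, sigma_mu2, nu, lambda;
  double pg, pp, pc;

  Sampler(const NumericMatrix& X_, double alpha_, double beta_, double sigma_mu_,
          double nu_, double lambda_, double pg_, double pp_, double pc_)
    : X(X_), n(X_.nrow()), p(X_.ncol()),
      alpha(alpha_), beta(beta_), sigma_mu2(sigma_mu_ * sigma_mu_),
      nu(nu_), lambda(lambda_), pg(pg_), pp(pp_), pc(pc_) {
    cuts.resize(p);
    for (int j = 0; j < p; ++j) {
      std::vector<double> v(X.begin() + (size_t)j * n, X.begin() + (size_t)(j + 1) * n);
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
      // midpoints between adjacent order statistics of the observed values
      for (size_t i = 0; i + 1 < v.size(); ++i)
        cuts[j].push_back(0.5 * (v[i] + v[i + 1]));
    }
  }

  double psplit(int d) const { return alpha * std::pow(1.0 + d, -beta); }

  // marginal log-likelihood contribution of one leaf (terms constant across
  // proposals with identical observation sets are dropped)
  double ll_leaf(double nl, double sl, double sig2) const {
    return 0.5 * std::log(sig2 / (sig2 + nl * sigma_mu2)) +
           sigma_mu2 * sl * sl / (2.0 * sig2 * (sig2 + nl * sigma_mu2));
  }

  void assign(const Tree& T, std::vector<int>& leafidx) const {
    for (int i = 0; i < n; ++i) leafidx[i] = T.leaf_for(&X[i], n);
  }

  void stats(const Tree& T, const std::vector<int>& leafidx,
             const std::vector<double>& R,
             std::vector<double>& nl, std::vector<double>& sl) const {
    nl.assign(T.var.size(), 0.0);
    sl.assign(T.var.size(), 0.0);
    for (int i = 0; i < n; ++i) { nl[leafidx[i]] += 1.0; sl[leafidx[i]] += R[i]; }
  }

  // one MH update of a single tree against residual R; leafidx updated in place
  void update_tree(Tree& T, std::vector<int>& leafidx,
                   const std::vector<double>& R, double sig2) {
    std::vector<int> leaves, nogs;
    leaves.reserve(16); nogs.reserve(8);
    T.collect(0, leaves, nogs);
    bool rootonly = (leaves.size() == 1);

    std::vector<double> nl, sl;
    stats(T, leafidx, R, nl, sl);

    double u = R::runif(0.0, 1.0);
    double move = rootonly ? 0.0 : u;  // a single-node tree can only grow

    if (move < pg || rootonly) {
      // ---- GROW ----
      int leaf = leaves[(int)std::floor(R::runif(0.0, 1.0) * leaves.size())];
      int j = (int)std::floor(R::runif(0.0, 1.0) * p);
      if (cuts[j].empty()) return;  // constant feature: never split
      double c = cuts[j][(int)std::floor(R::runif(0.0, 1.0) * cuts[j].size())];

      // children sufficient statistics
      double nlft = 0.0, slft = 0.0;
      for (int i = 0; i < n; ++i)
        if (leafidx[i] == leaf && X[i + (size_t)j * n] <= c) { nlft += 1.0; slft += R[i]; }
      double nrgt = nl[leaf] - nlft, srgt = sl[leaf] - slft;
      if (nlft < 1.0 || nrgt < 1.0) return;  // empty child: reject

      int d = T.depth(leaf);
      double pd = psplit(d), pd1 = psplit(d + 1);
      double logprior = std::log(pd) + 2.0 * std::log(1.0 - pd1) - std::log(1.0 - pd);
      double loglik = ll_leaf(nlft, slft, sig2) + ll_leaf(nrgt, srgt, sig2) -
                      ll_leaf(nl[leaf], sl[leaf], sig2);
      // nog count after grow: leaf's parent stops being nog iff its other child is a leaf
      int nog_after = (int)nogs.size() + 1;
      int par = T.parent[leaf];
      if (par >= 0) {
        int sib = (T.left[par] == leaf) ? T.right[par] : T.left[par];
        if (T.is_leaf(sib)) nog_after -= 1;
      }
      double pgrow = rootonly ? 1.0 : pg;
      double logprop = std::log(pp) - std::log(pgrow) +
                       std::log((double)leaves.size()) - std::log((double)nog_after);
      if (std::log(R::runif(0.0, 1.0)) < logprior + loglik + logprop) {
        int L = T.new_node(leaf), Rt = T.new_node(leaf);
        T.var[leaf] = j; T.cut[leaf] = c; T.left[leaf] = L; T.right[leaf] = Rt;
        for (int i = 0; i < n; ++i)
          if (leafidx[i] == leaf)
            leafidx[i] = (X[i + (size_t)j * n] <= c) ? L : Rt;
      }
    } else if (move < pg + pp) {
      // ---- PRUNE ----
      if (nogs.empty()) return;
      int node = nogs[(int)std::floor(R::runif(0.0, 1.0) * nogs.size())];
      int L = T.left[node], Rt = T.right[node];
      int d = T.depth(node);
      double pd = psplit(d), pd1 = psplit(d + 1);
      double logprior = -(std::log(pd) + 2.0 * std::log(1.0 - pd1) - std::log(1.0 - pd));
      double loglik = ll_leaf(nl[L] + nl[Rt], sl[L] + sl[Rt], sig2) -
                      ll_leaf(nl[L], sl[L], sig2) - ll_leaf(nl[Rt], sl[Rt], sig2);
      bool root_after = (leaves.size() == 2);  // pruning the only split
      double pgrow_after = root_after ? 1.0 : pg;
      double logprop = std::log(pgrow_after) - std::log(pp) +
                       std::log((double)nogs.size()) -
                       std::log((double)leaves.size() - 1.0);
      if (std::log(R::runif(0.0, 1.0)) < logprior + loglik + logprop) {
        T.var[node] = -1;
        T.freelist.push_back(L); T.freelist.push_back(Rt);
        T.left[node] = -1; T.right[node] = -1;
        for (int i = 0; i < n; ++i)
          if (leafidx[i] == L || leafidx[i] == Rt) leafidx[i] = node;
      }
    } else {
      // ---- CHANGE ---- redraw the rule of one internal node (shape unchanged)
      if (rootonly) return;
      std::vector<int> internals;
      for (size_t i = 0; i < T.var.size(); ++i)
        if (T.var[i] >= 0) {
          // skip freed nodes: a freed node has var = -1, so var >= 0 is live internal
          internals.push_back((int)i);
        }
      int node = internals[(int)std::floor(R::runif(0.0, 1.0) * internals.size())];
      int j = (int)std::floor(R::runif(0.0, 1.0) * p);
      if (cuts[j].empty()) return;
      double c = cuts[j][(int)std::floor(R::runif(0.0, 1.0) * cuts[j].size())];

      int oldvar = T.var[node]; double oldcut = T.cut[node];
      T.var[node] = j; T.cut[node] = c;
      std::vector<int> newidx(leafidx);
      // reassign observations that fall in this node's subtree
      std::vector<char> insub(T.var.size(), 0);
      mark_subtree(T, node, insub);
      for (int i = 0; i < n; ++i)
        if (insub[leafidx[i]]) newidx[i] = descend_node(T, node, &X[i], n);
      std::vector<double> nl2, sl2;
      stats(T, newidx, R, nl2, sl2);
      // all leaves of the subtree must stay populated
      bool ok = true;
      double lnew = 0.0, lold = 0.0;
      for (size_t i = 0; i < T.var.size(); ++i) {
        if (!insub[i] || !T.is_leaf((int)i)) continue;
        if (nl2[i] < 1.0) { ok = false; break; }
        lnew += ll_leaf(nl2[i], sl2[i], sig2);
        lold += ll_leaf(nl[i], sl[i], sig2);
      }
      if (ok && std::log(R::runif(0.0, 1.0)) < lnew - lold) {
        leafidx.swap(newidx);
      } else {
        T.var[node] = oldvar; T.cut[node] = oldcut;
      }
    }
  }

  static void mark_subtree(const Tree& T, int node, std::vector<char>& m) {
    m[node] = 1;
    if (!T.is_leaf(node)) {
      mark_subtree(T, T.left[node], m);
      mark_subtree(T, T.right[node], m);
    }
  }
};

// depth-first compaction of one tree into a 6-column matrix:
// var(1-based, 0 = leaf), cut, left, right (1-based row ids, 0 = none), mu, depth
void serialize_tree(const Tree& T, int node, std::vector<double>& rows,
                    int& counter, int depth) {
  int my = counter++;
  size_t base = (size_t)my * 6;
  if (rows.size() < base + 6) rows.resize(base + 6, 0.0);
  if (T.is_leaf(node)) {
    rows[base + 0] = 0; rows[base + 1] = 0;
    rows[base + 2] = 0; rows[base + 3] = 0;
    rows[base + 4] = T.mu[node]; rows[base + 5] = depth;
  } else {
    rows[base + 0] = T.var[node] + 1;
    rows[base + 1] = T.cut[node];
    rows[base + 4] = 0; rows[base + 5] = depth;
    int lid = counter;
    serialize_tree(T, T.left[node], rows, counter, depth + 1);
    int rid = counter;
    serialize_tree(T, T.right[node], rows, counter, depth + 1);
    rows[base + 2] = lid + 1;
    rows[base + 3] = rid + 1;
  }
}

} // namespace

// [[Rcpp::export]]
List bart_mcmc(NumericMatrix X, NumericVector y,
               int m, double alpha, double beta, double sigma_mu,
               double nu, double lambda, double sig2_init,
               int n_burn, int n_draws, int n_thin,
               double p_grow, double p_prune, double p_change) {
  int n = X.nrow();
  Sampler S(X, alpha, beta, sigma_mu, nu, lambda, p_grow, p_prune, p_change);

  std::vector<Tree> forest(m);
  std::vector<std::vector<int> > leafidx(m, std::vector<int>(n, 0));
  std::vector<std::vector<double> > treefit(m, std::vector<double>(n, 0.0));
  std::vector<double> fit(n, 0.0), R(n, 0.0);

  double sig2 = sig2_init;
  int total = n_burn + n_draws * n_thin;
  List forests(n_draws);
  NumericVector sigma_draws(n_draws);
  int kept = 0;

  for (int iter = 0; iter < total; ++iter) {
    for (int t = 0; t < m; ++t) {
      Tree& T = forest[t];
      // partial residual excluding tree t
      for (int i = 0; i < n; ++i) R[i] = y[i] - fit[i] + treefit[t][i];
      S.update_tree(T, leafidx[t], R, sig2);

      // redraw leaf means from their conditional normal
      std::vector<double> nl, sl;
      S.stats(T, leafidx[t], R, nl, sl);
      std::vector<double> newmu(T.var.size(), 0.0);
      for (size_t k = 0; k < T.var.size(); ++k) {
        if (!T.is_leaf((int)k)) continue;
        double vpost = 1.0 / (1.0 / S.sigma_mu2 + nl[k] / sig2);
        double mpost = vpost * sl[k] / sig2;
        newmu[k] = R::rnorm(mpost, std::sqrt(vpost));
      }
      for (size_t k = 0; k < T.var.size(); ++k)
        if (T.is_leaf((int)k)) T.mu[k] = newmu[k];
      for (int i = 0; i < n; ++i) {
        double g = T.mu[leafidx[t][i]];
        fit[i] += g - treefit[t][i];
        treefit[t][i] = g;
      }
    }
    // error variance: scaled inverse-chi-square full conditional
    double sse = 0.0;
    for (int i = 0; i < n; ++i) { double e = y[i] - fit[i]; sse += e * e; }
    sig2 = (nu * lambda + sse) / R::rchisq(nu + n);

    if (iter >= n_burn && ((iter - n_burn + 1) % n_thin) == 0 && kept < n_draws) {
      List draw(m);
      for (int t = 0; t < m; ++t) {
        std::vector<double> rows;
        int counter = 0;
        serialize_tree(forest[t], 0, rows, counter, 0);
        NumericMatrix M(counter, 6);
        for (int r = 0; r < counter; ++r)
          for (int c2 = 0; c2 < 6; ++c2) M(r, c2) = rows[(size_t)r * 6 + c2];
        draw[t] = M;
      }
      forests[kept] = draw;
      sigma_draws[kept] = std::sqrt(sig2);
      ++kept;
    }
  }

  return List::create(_["forests"] = forests, _["sigma"] = sigma_draws,
                      _["n_kept"] = kept);
}

// [[Rcpp::export]]
NumericMatrix bart_predict_cpp(List forests, NumericMatrix X) {
  int ndraws = forests.size();
  int n = X.nrow(), nX = X.nrow();
  NumericMatrix out(n, ndraws);
  for (int d = 0; d < ndraws; ++d) {
    List draw = forests[d];
    int m = draw.size();
    for (int t = 0; t < m; ++t) {
      NumericMatrix M = draw[t];
      for (int i = 0; i < n; ++i) {
        int node = 0;
        while (M(node, 0) > 0) {
          int j = (int)M(node, 0) - 1;
          node = (X[i + (size_t)j * nX] <= M(node, 1)) ? (int)M(node, 2) - 1
                                                       : (int)M(node, 3) - 1;
        }
        out(i, d) += M(node, 4);
      }
    }
  }
  return out;
}
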