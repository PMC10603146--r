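// Random survival forest: bootstrap aggregation of binary survival trees
// grown with log-rank splitting on mtry randomly chosen candidate
// variables and nsplit random cutpoints per candidate.  Terminal nodes
// carry Nelson-Aalen cumulative-hazard estimates; out-of-bag ensemble
// mortality feeds a Harrell-concordance prediction error.
//
// Randomness comes from R's RNG (unif_rand), so set.seed() in R makes a
// forest fully reproducible.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

int runif_int(int n) {  // uniform on {0, ..., n-1}
  int k = static_cast<int>(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct TreeBuilder {
  const arma::mat& X;
  const arma::vec& time;
  const arma::vec& status;
  int mtry, nodesize, nsplit;
  // node columns
  std::vector<int> var, left, right, depth, n_node;
  std::vector<double> cut, mortality;
  // number of global event times >= t, for leaf mortality
  const std::vector<double>& gev;  // sorted unique global event times

  TreeBuilder(const arma::mat& X_, const arma::vec& t_, const arma::vec& s_,
              int mtry_, int nodesize_, int nsplit_,
              const std::vector<double>& gev_)
      : X(X_), time(t_), status(s_), mtry(mtry_), nodesize(nodesize_),
        nsplit(nsplit_), gev(gev_) {}

  int n_unique_events(const std::vector<int>& idx) const {
    std::vector<double> ev;
    for (int i : idx) if (status(i) == 1.0) ev.push_back(time(i));
    std::sort(ev.begin(), ev.end());
    ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
    return static_cast<int>(ev.size());
  }

  // log-rank statistic (squared, variance-normalised) for the split
  // x_j <= c, over members sorted ascending by time
  double logrank(const std::vector<int>& sidx, int j, double c) const {
    const int m = static_cast<int>(sidx.size());
    double Y = m, YL = 0.0;
    for (int i : sidx) if (X(i, j) <= c) YL += 1.0;
    double num = 0.0, var = 0.0;
    int i = 0;
    while (i < m) {
      int k = i;
      double d = 0.0, dL = 0.0, blockL = 0.0;
      while (k < m && time(sidx[k]) == time(sidx[i])) {
        if (status(sidx[k]) == 1.0) {
          d += 1.0;
          if (X(sidx[k], j) <= c) dL += 1.0;
        }
        if (X(sidx[k], j) <= c) blockL += 1.0;
        ++k;
      }
      const double nb = k - i;
      if (d > 0.0 && Y > 1.0) {
        const double frac = YL / Y;
        num += dL - d * frac;
        var += d * frac * (1.0 - frac) * (Y - d) / (Y - 1.0);
      }
      Y -= nb;
      YL -= blockL;
      i = k;
    }
    if (var <= 0.0) return -1.0;
    return num * num / var;
  }

  double leaf_mortality(const std::vector<int>& sidx) const {
    // Nelson-Aalen on leaf members; mortality = sum over the global
    // event-time grid of the leaf's cumulative hazard.
    const int m = static_cast<int>(sidx.size());
    double Y = m, mort = 0.0;
    int i = 0;
    while (i < m) {
      int k = i;
      double d = 0.0;
      while (k < m && time(sidx[k]) == time(sidx[i])) {
        if (status(sidx[k]) == 1.0) d += 1.0;
        ++k;
      }
      if (d > 0.0 && Y > 0.0) {
        const double jump = d / Y;
        // number of global event times >= this time
        const double t = time(sidx[i]);
        const int ge = static_cast<int>(
            gev.end() - std::lower_bound(gev.begin(), gev.end(), t));
        mort += jump * ge;
      }
      Y -= (k - i);
      i = k;
    }
    return mort;
  }

  int build(std::vector<int> idx, int dep) {
    const int node = static_cast<int>(var.size());
    var.push_back(-1); cut.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    depth.push_back(dep); n_node.push_back(static_cast<int>(idx.size()));
    mortality.push_back(NA_REAL);

    bool terminal = static_cast<int>(idx.size()) < 2 ||
                    n_unique_events(idx) < nodesize;
    int best_j = -1;
    double best_c = 0.0, best_stat = -1.0;
    if (!terminal) {
      std::vector<int> sidx = idx;
      std::sort(sidx.begin(), sidx.end(), [&](int a, int b) {
        return time(a) < time(b);
      });
      const int p = static_cast<int>(X.n_cols);
      // sample mtry variables without replacement (partial Fisher-Yates)
      std::vector<int> pool(p);
      for (int j = 0; j < p; ++j) pool[j] = j;
      const int mt = std::min(mtry, p);
      for (int t = 0; t < mt; ++t) {
        const int pick = t + runif_int(p - t);
        std::swap(pool[t], pool[pick]);
        const int j = pool[t];
        double lo = X(idx[0], j), hi = lo;
        for (int i : idx) {
          const double v = X(i, j);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (lo == hi) continue;
        for (int s = 0; s < nsplit; ++s) {
          double c = X(idx[runif_int(static_cast<int>(idx.size()))], j);
          if (c >= hi) continue;  // right child would be empty
          const double stat = logrank(sidx, j, c);
          if (stat > best_stat) { best_stat = stat; best_j = j; best_c = c; }
        }
      }
      if (best_j < 0) terminal = true;
    }
    if (terminal) {
      std::vector<int> sidx = idx;
      std::sort(sidx.begin(), sidx.end(), [&](int a, int b) {
        return time(a) < time(b);
      });
      mortality[node] = leaf_mortality(sidx);
      return node;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_j) <= best_c) li.push_back(i); else ri.push_back(i);
    }
    var[node] = best_j;
    cut[node] = best_c;
    const int l = build(li, dep + 1);
    left[node] = l;
    const int r = build(ri, dep + 1);
    right[node] = r;
    return node;
  }
};

double predict_tree(const std::vector<int>& var, const std::vector<double>& cut,
                    const std::vector<int>& left, const std::vector<int>& right,
                    const std::vector<double>& mortality,
                    const arma::mat& X, int i) {
  int node = 0;
  while (var[node] >= 0)
    node = (X(i, var[node]) <= cut[node]) ? left[node] : right[node];
  return mortality[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_rsf_fit(const arma::mat& X, const arma::vec& time,
                 const arma::vec& status, const int ntree, const int mtry,
                 const int nodesize, const int nsplit) {
  const int n = static_cast<int>(X.n_rows);
  std::vector<double> gev;
  for (int i = 0; i < n; ++i) if (status(i) == 1.0) gev.push_back(time(i));
  std::sort(gev.begin(), gev.end());
  gev.erase(std::unique(gev.begin(), gev.end()), gev.end());
  if (gev.empty()) stop("cannot grow a survival forest on data with no events");

  arma::vec oob_sum(n, arma::fill::zeros);
  arma::ivec oob_count(n, arma::fill::zeros);
  List trees(ntree);

  for (int b = 0; b < ntree; ++b) {
    std::vector<int> bag;
    std::vector<bool> inbag(n, false);
    bag.reserve(n);
    for (int i = 0; i < n; ++i) {
      const int k = runif_int(n);
      bag.push_back(k);
      inbag[k] = true;
    }
    TreeBuilder tb(X, time, status, mtry, nodesize, nsplit, gev);
    tb.build(bag, 0);
    const int nn = static_cast<int>(tb.var.size());
    NumericMatrix tm(nn, 6);
    colnames(tm) = CharacterVector::create("var", "cut", "left", "right",
                                           "depth", "mortality");
    for (int k = 0; k < nn; ++k) {
      tm(k, 0) = tb.var[k] >= 0 ? tb.var[k] + 1 : NA_REAL;  // 1-based for R
      tm(k, 1) = tb.cut[k];
      tm(k, 2) = tb.left[k] >= 0 ? tb.left[k] + 1 : NA_REAL;
      tm(k, 3) = tb.right[k] >= 0 ? tb.right[k] + 1 : NA_REAL;
      tm(k, 4) = tb.depth[k];
      tm(k, 5) = tb.mortality[k];
    }
    trees[b] = tm;
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum(i) += predict_tree(tb.var, tb.cut, tb.left, tb.right,
                                   tb.mortality, X, i);
        oob_count(i) += 1;
      }
    }
  }
  return List::create(_["trees"] = trees, _["oob_sum"] = oob_sum,
                      _["oob_count"] = oob_count);
}

// Harrell concordance of a risk score against right-censored outcomes:
// pairs are usable when the smaller observed time is an event; the pair is
// concordant when the earlier failure has the higher score; score ties
// count one half.
// [[Rcpp::export]]
double cpp_concordance(const arma::vec& time, const arma::vec& status,
                       const arma::vec& score) {
  const int n = static_cast<int>(time.n_elem);
  double conc = 0.0, usable = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a = i, b = j;  // a: earlier observed time
      if (time(j) < time(i)) { a = j; b = i; }
      if (time(a) == time(b)) {
        if (status(a) == 1.0 && status(b) == 1.0) {
          usable += 1.0;
          conc += 0.5;  // tied failure times: order not informative
        }
        continue;
      }
      if (status(a) != 1.0) continue;
      usable += 1.0;
      if (score(a) > score(b)) conc += 1.0;
      else if (score(a) == score(b)) conc += 0.5;
    }
  }
  if (usable == 0.0) return NA_REAL;
  return conc / usable;
}
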