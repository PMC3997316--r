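// Compiled kernels: wave-fetch ray marching, exhaustive nearest-land search,
// and the stochastic gradient-boosted regression tree core.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wave fetch / openness
//
// For every water cell, rays are marched in `ndir` equally spaced directions;
// the fetch of a ray is the distance travelled before the first land sample,
// capped at max_fetch.  The region beyond the grid is treated as open water:
// a straight ray leaving the (convex) grid can never re-enter it, so the ray
// is then open to max_fetch.  Sample points sit half a step off cell
// boundaries so that 90-degree rotations of the mask map sample points onto
// sample points exactly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_fetch(LogicalMatrix land, double cell_size, int ndir,
                        double max_fetch) {
  const int nr = land.nrow(), nc = land.ncol();
  NumericMatrix out(nr, nc);
  const double step = 0.5;                       // in cell units
  const double maxf_cells = max_fetch / cell_size;
  const int max_steps = (int)std::ceil(maxf_cells / step) + 1;

  std::vector<double> dx(ndir), dy(ndir);
  for (int d = 0; d < ndir; ++d) {
    double th = 2.0 * M_PI * d / ndir;
    double cx = std::cos(th), cy = std::sin(th);
    if (std::fabs(cx) < 1e-12) cx = 0.0;
    if (std::fabs(cy) < 1e-12) cy = 0.0;
    dx[d] = cx; dy[d] = cy;
  }

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (land(i, j)) { out(i, j) = NA_REAL; continue; }
      double acc = 0.0;
      const double cx = j + 0.5, cy = i + 0.5;
      for (int d = 0; d < ndir; ++d) {
        double fetch = maxf_cells;
        for (int s = 1; s <= max_steps; ++s) {
          double t = (s - 0.5) * step;
          if (t >= maxf_cells) break;
          double x = cx + t * dx[d], y = cy + t * dy[d];
          int col = (int)std::floor(x), row = (int)std::floor(y);
          if (col < 0 || col >= nc || row < 0 || row >= nr) break; // open sea
          if (land(row, col)) { fetch = t; break; }
        }
        acc += std::min(fetch, maxf_cells);
      }
      out(i, j) = acc / ndir * cell_size;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive nearest-land search.  For every query cell the nearest land cell
// (Euclidean, cell centers) is found; distance ties (within 1e-9 cells) are
// broken by the smallest class code.  Returns the class and the distance in
// cell units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nearest_land(LogicalMatrix land, IntegerMatrix classes,
                      LogicalMatrix query) {
  const int nr = land.nrow(), nc = land.ncol();
  std::vector<int> lr, lc, lcl;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (land(i, j)) {
        lr.push_back(i); lc.push_back(j);
        lcl.push_back(classes(i, j) == NA_INTEGER ? INT_MAX : classes(i, j));
      }
  IntegerMatrix out_class(nr, nc);
  NumericMatrix out_dist(nr, nc);
  std::fill(out_class.begin(), out_class.end(), NA_INTEGER);
  std::fill(out_dist.begin(), out_dist.end(), NA_REAL);
  const size_t nl = lr.size();
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!query(i, j)) continue;
      double best = R_PosInf; int bestc = NA_INTEGER;
      for (size_t k = 0; k < nl; ++k) {
        double di = i - lr[k], dj = j - lc[k];
        double d2 = di * di + dj * dj;
        if (d2 < best - 1e-9) { best = d2; bestc = lcl[k]; }
        else if (std::fabs(d2 - best) <= 1e-9 && lcl[k] < bestc) bestc = lcl[k];
      }
      if (nl > 0) { out_dist(i, j) = std::sqrt(best); out_class(i, j) = bestc; }
    }
  }
  return List::create(_["class"] = out_class, _["dist"] = out_dist);
}

// ---------------------------------------------------------------------------
// Boosted regression trees, Bernoulli deviance.
//
// Trees are grown best-first on the gradient residuals (y - p) of a
// bag-fraction subsample drawn without replacement; split gain is the
// squared-error improvement on the residuals; terminal (and internal) node
// values are one-step Newton updates sum(r) / sum(p(1-p)).  Categorical
// predictors are split by exhaustive subset search for <= 8 classes, else by
// a mean-residual-ordered greedy scan.  Ties in gain are broken by lowest
// variable index, then lowest split point / subset mask.
// ---------------------------------------------------------------------------

struct Split {
  double gain = -1.0;
  int var = -1;
  double split = 0.0;
  unsigned mask = 0;
  bool is_cat = false;
};

struct BNode {
  std::vector<int> rows;
  double sum_r = 0.0, sum_h = 0.0;
  double value = 0.0;
  Split best;
  // realized split
  int var = -1;                // 0-based; -1 = leaf
  double split = 0.0;
  unsigned mask = 0;
  bool is_cat = false;
  int left = -1, right = -1;
};

static void node_stats(BNode &nd, const std::vector<double> &r,
                       const std::vector<double> &h) {
  nd.sum_r = 0.0; nd.sum_h = 0.0;
  for (int i : nd.rows) { nd.sum_r += r[i]; nd.sum_h += h[i]; }
  nd.value = nd.sum_h > 1e-10 ? nd.sum_r / nd.sum_h : 0.0;
}

static void find_best_split(BNode &nd, const NumericMatrix &X,
                            const IntegerVector &is_cat,
                            const IntegerVector &ncat,
                            const std::vector<double> &r, int minobs) {
  nd.best = Split();
  const int nvar = X.ncol();
  const int n = (int)nd.rows.size();
  if (n < 2 * minobs) return;
  double st = 0.0;
  for (int i : nd.rows) st += r[i];
  const double base = st * st / n;

  std::vector<std::pair<double, double>> vv;  // (x, r)
  for (int v = 0; v < nvar; ++v) {
    if (!is_cat[v]) {
      vv.clear();
      vv.reserve(n);
      bool varies = false;
      for (int i : nd.rows) vv.emplace_back(X(i, v), r[i]);
      std::sort(vv.begin(), vv.end(),
                [](const std::pair<double,double> &a,
                   const std::pair<double,double> &b) { return a.first < b.first; });
      for (int i = 1; i < n; ++i) if (vv[i].first > vv[0].first) { varies = true; break; }
      if (!varies) continue;
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += vv[i].second;
        if (vv[i + 1].first <= vv[i].first) continue;
        int nl = i + 1, nrr = n - nl;
        if (nl < minobs || nrr < minobs) continue;
        double sr = st - sl;
        double gain = sl * sl / nl + sr * sr / nrr - base;
        if (gain > nd.best.gain + 1e-12) {
          nd.best.gain = gain; nd.best.var = v;
          nd.best.split = 0.5 * (vv[i].first + vv[i + 1].first);
          nd.best.is_cat = false;
        }
      }
    } else {
      const int c = ncat[v];
      if (c < 2 || c > 32) continue;
      std::vector<double> cs(c, 0.0);
      std::vector<int> cn(c, 0);
      for (int i : nd.rows) {
        int code = (int)X(i, v);
        if (code >= 0 && code < c) { cs[code] += r[i]; cn[code]++; }
      }
      if (c <= 8) {
        const unsigned top = (1u << c) - 1u;
        for (unsigned m = 1; m < top; ++m) {
          double sl = 0.0; int nl = 0;
          for (int k = 0; k < c; ++k)
            if (m & (1u << k)) { sl += cs[k]; nl += cn[k]; }
          int nrr = n - nl;
          if (nl < minobs || nrr < minobs) continue;
          double sr = st - sl;
          double gain = sl * sl / nl + sr * sr / nrr - base;
          if (gain > nd.best.gain + 1e-12) {
            nd.best.gain = gain; nd.best.var = v;
            nd.best.mask = m; nd.best.is_cat = true;
          }
        }
      } else {
        std::vector<int> ord;
        for (int k = 0; k < c; ++k) if (cn[k] > 0) ord.push_back(k);
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
          double ma = cs[a] / cn[a], mb = cs[b] / cn[b];
          if (ma != mb) return ma < mb;
          return a < b;
        });
        double sl = 0.0; int nl = 0; unsigned m = 0;
        for (size_t q = 0; q + 1 < ord.size(); ++q) {
          sl += cs[ord[q]]; nl += cn[ord[q]]; m |= (1u << ord[q]);
          int nrr = n - nl;
          if (nl < minobs || nrr < minobs) continue;
          double sr = st - sl;
          double gain = sl * sl / nl + sr * sr / nrr - base;
          if (gain > nd.best.gain + 1e-12) {
            nd.best.gain = gain; nd.best.var = v;
            nd.best.mask = m; nd.best.is_cat = true;
          }
        }
      }
    }
  }
}

static double tree_value(const std::vector<BNode> &nodes, const NumericMatrix &X,
                         int row, const IntegerVector &ncat) {
  int id = 0;
  while (nodes[id].var >= 0) {
    const BNode &nd = nodes[id];
    double v = X(row, nd.var);
    if (ISNAN(v)) return nd.value;
    if (nd.is_cat) {
      int code = (int)v;
      if (code < 0 || code >= ncat[nd.var]) return nd.value;
      id = (nd.mask & (1u << code)) ? nd.left : nd.right;
    } else {
      id = (v < nd.split) ? nd.left : nd.right;
    }
  }
  return nodes[id].value;
}

// [[Rcpp::export]]
List cpp_brt_fit(NumericMatrix X, NumericVector y, IntegerVector is_cat,
                 IntegerVector ncat, double intercept, double lr, int tc,
                 double bf, int ntrees, int minobs, int seed,
                 Nullable<NumericMatrix> Xval_ = R_NilValue,
                 Nullable<NumericVector> yval_ = R_NilValue) {
  const int n = X.nrow(), nvar = X.ncol();
  std::vector<double> F(n, intercept);
  std::mt19937 rng((unsigned)seed);
  const int nbag = std::max(2 * minobs, (int)std::lround(bf * n));

  bool has_val = Xval_.isNotNull();
  NumericMatrix Xval;
  NumericVector yval;
  std::vector<double> Fval;
  if (has_val) {
    Xval = NumericMatrix(Xval_);
    yval = NumericVector(yval_);
    Fval.assign(Xval.nrow(), intercept);
  }

  List trees(ntrees);
  NumericMatrix gains(ntrees, nvar);
  NumericVector train_dev(ntrees), val_dev(has_val ? ntrees : 0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> r(n), h(n);

  for (int m = 0; m < ntrees; ++m) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - p;
      h[i] = std::max(p * (1.0 - p), 1e-12);
    }
    // bag: partial Fisher-Yates without replacement
    std::vector<int> bag;
    if (nbag >= n) {
      bag = idx;
    } else {
      for (int i = 0; i < nbag; ++i) {
        std::uniform_int_distribution<int> u(i, n - 1);
        std::swap(idx[i], idx[u(rng)]);
      }
      bag.assign(idx.begin(), idx.begin() + nbag);
      std::sort(bag.begin(), bag.end());
    }

    std::vector<BNode> nodes;
    nodes.reserve(2 * tc + 1);
    nodes.emplace_back();
    nodes[0].rows = bag;
    node_stats(nodes[0], r, h);
    find_best_split(nodes[0], X, is_cat, ncat, r, minobs);

    for (int s = 0; s < tc; ++s) {
      int pick = -1;
      double bg = 1e-12;
      for (size_t q = 0; q < nodes.size(); ++q)
        if (nodes[q].var < 0 && nodes[q].best.gain > bg) {
          bg = nodes[q].best.gain; pick = (int)q;
        }
      if (pick < 0) break;
      BNode &pn = nodes[pick];
      pn.var = pn.best.var; pn.split = pn.best.split;
      pn.mask = pn.best.mask; pn.is_cat = pn.best.is_cat;
      gains(m, pn.var) += pn.best.gain;
      BNode ln, rn;
      for (int i : pn.rows) {
        double v = X(i, pn.var);
        bool go_left;
        if (pn.is_cat) {
          int code = (int)v;
          go_left = (code >= 0 && code < ncat[pn.var]) &&
                    (pn.mask & (1u << code));
        } else {
          go_left = v < pn.split;
        }
        (go_left ? ln : rn).rows.push_back(i);
      }
      node_stats(ln, r, h);
      node_stats(rn, r, h);
      find_best_split(ln, X, is_cat, ncat, r, minobs);
      find_best_split(rn, X, is_cat, ncat, r, minobs);
      int li = (int)nodes.size();
      nodes[pick].left = li; nodes[pick].right = li + 1;
      nodes[pick].rows.clear(); nodes[pick].rows.shrink_to_fit();
      nodes.push_back(std::move(ln));
      nodes.push_back(std::move(rn));
    }

    // serialize and apply
    const int nn = (int)nodes.size();
    NumericMatrix tm(nn, 6);
    for (int q = 0; q < nn; ++q) {
      const BNode &nd = nodes[q];
      tm(q, 0) = nd.var + 1;      // 0 = leaf
      tm(q, 1) = nd.is_cat ? (double)nd.mask : nd.split;
      tm(q, 2) = nd.is_cat ? 1.0 : 0.0;
      tm(q, 3) = nd.left + 1;
      tm(q, 4) = nd.right + 1;
      tm(q, 5) = nd.value;
    }
    trees[m] = tm;

    for (int i = 0; i < n; ++i) F[i] += lr * tree_value(nodes, X, i, ncat);
    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      double sp = F[i] > 30 ? F[i] : std::log1p(std::exp(F[i]));
      dev += y[i] * F[i] - sp;
    }
    train_dev[m] = -2.0 * dev / n;

    if (has_val) {
      const int nv = Xval.nrow();
      double dv = 0.0;
      for (int i = 0; i < nv; ++i) {
        Fval[i] += lr * tree_value(nodes, Xval, i, ncat);
        double sp = Fval[i] > 30 ? Fval[i] : std::log1p(std::exp(Fval[i]));
        dv += yval[i] * Fval[i] - sp;
      }
      val_dev[m] = -2.0 * dv / nv;
    }
  }

  return List::create(_["trees"] = trees, _["gains"] = gains,
                      _["train_dev"] = train_dev, _["val_dev"] = val_dev);
}

// [[Rcpp::export]]
NumericVector cpp_brt_predict(List trees, NumericMatrix X, IntegerVector ncat,
                              double intercept, double lr, int ntrees) {
  const int n = X.nrow();
  NumericVector F(n, intercept);
  const int nt = std::min((int)trees.size(), ntrees);
  for (int m = 0; m < nt; ++m) {
    NumericMatrix tm = trees[m];
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while ((int)tm(id, 0) > 0) {
        int var = (int)tm(id, 0) - 1;
        double v = X(i, var);
        if (ISNAN(v)) break;
        if (tm(id, 2) > 0.5) {
          int code = (int)v;
          if (code < 0 || code >= ncat[var]) break;
          unsigned mask = (unsigned)tm(id, 1);
          id = (mask & (1u << code)) ? (int)tm(id, 3) - 1 : (int)tm(id, 4) - 1;
        } else {
          id = (v < tm(id, 1)) ? (int)tm(id, 3) - 1 : (int)tm(id, 4) - 1;
        }
      }
      F[i] += lr * tm(id, 5);
    }
  }
  return F;
}
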