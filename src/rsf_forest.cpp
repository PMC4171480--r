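// Random survival forest core: bagged survival trees with log-rank
// splitting over random split-point candidates ("log-rank random"),
// Nelson-Aalen terminal-node cumulative hazards on the shared grid of
// training event times. All randomness comes from R's RNG so a single
// set.seed() upstream makes the forest bit-reproducible.
//
// Performance notes: the bootstrap index list is sorted by time once
// per tree and node partitions preserve that order, so no per-node
// sorting is needed; node times/status/feature values are copied into
// contiguous buffers before the split sweeps.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> var;        // split feature (0-based), -1 = terminal
  std::vector<double> val;     // split value (x <= val goes left)
  std::vector<int> left, right, chfrow;
  std::vector<double> chf;     // row-major, n_terminal x m
  int m;
};

int rand_int(int n) {               // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct Grower {
  const NumericMatrix& X;
  const NumericVector& time;
  const IntegerVector& status;
  const NumericVector& grid;
  int mtry, nsplit, min_events;
  TreeBuf tb;
  std::vector<int> feat_pool;
  // scratch buffers sized to the bootstrap sample
  std::vector<double> tbuf, xbuf;
  std::vector<char> sbuf;

  Grower(const NumericMatrix& X_, const NumericVector& t_,
         const IntegerVector& s_, const NumericVector& g_,
         int mtry_, int nsplit_, int min_events_)
    : X(X_), time(t_), status(s_), grid(g_),
      mtry(mtry_), nsplit(nsplit_), min_events(min_events_) {
    tb.m = grid.size();
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int new_node() {
    tb.var.push_back(-1); tb.val.push_back(0.0);
    tb.left.push_back(-1); tb.right.push_back(-1); tb.chfrow.push_back(-1);
    return (int)tb.var.size() - 1;
  }

  // standardised |log-rank| statistic of the split xbuf[i] <= c over a
  // node whose tbuf/sbuf are ascending in time; returns -1 when the
  // variance is degenerate or a child has too few events
  double split_stat(int n, double c) {
    double num = 0.0, var = 0.0;
    int Y = n, Y1 = 0, d1tot = 0, d2tot = 0;
    for (int i = 0; i < n; ++i) if (xbuf[i] <= c) ++Y1;
    if (Y1 == 0 || Y1 == n) return -1.0;
    int i = 0;
    while (i < n) {
      const double t = tbuf[i];
      int d = 0, d1 = 0, g1 = 0, cnt = 0;
      int j = i;
      for (; j < n && tbuf[j] == t; ++j) {
        const bool left = xbuf[j] <= c;
        if (sbuf[j]) { ++d; if (left) ++d1; }
        if (left) ++g1;
        ++cnt;
      }
      if (d > 0) {
        num += d1 - (double)d * Y1 / Y;
        if (Y > 1)
          var += (double)d * ((double)Y1 / Y) * (1.0 - (double)Y1 / Y) *
                 (double)(Y - d) / (double)(Y - 1);
        d1tot += d1; d2tot += d - d1;
      }
      Y -= cnt; Y1 -= g1;
      i = j;
    }
    if (d1tot < min_events || d2tot < min_events) return -1.0;
    if (var <= 1e-12) return -1.0;
    return std::fabs(num) / std::sqrt(var);
  }

  // Nelson-Aalen cumulative hazard of the node, on the event-time grid
  void terminal_chf(const std::vector<int>& idx) {
    const int n = (int)idx.size(), m = tb.m;
    std::vector<double> ut, uh;
    int Y = n, i = 0;
    double H = 0.0;
    while (i < n) {
      const double t = time[idx[i]];
      int d = 0, cnt = 0, j = i;
      for (; j < n && time[idx[j]] == t; ++j) {
        if (status[idx[j]] == 1) ++d;
        ++cnt;
      }
      if (d > 0) { H += (double)d / Y; ut.push_back(t); uh.push_back(H); }
      Y -= cnt; i = j;
    }
    double cur = 0.0; size_t k = 0;
    const size_t base = tb.chf.size();
    tb.chf.resize(base + m);
    for (int g = 0; g < m; ++g) {
      while (k < ut.size() && ut[k] <= grid[g]) { cur = uh[k]; ++k; }
      tb.chf[base + g] = cur;
    }
  }

  // idx must be ascending in time; recursion preserves that order
  int build(std::vector<int>& idx) {
    const int node = new_node();
    const int n = (int)idx.size();
    int events = 0;
    for (int i = 0; i < n; ++i) if (status[idx[i]] == 1) ++events;

    int best_f = -1; double best_c = 0.0, best_stat = 0.0;
    if (events >= 2 * min_events && n >= 2) {
      if ((int)tbuf.size() < n) { tbuf.resize(n); xbuf.resize(n); sbuf.resize(n); }
      for (int i = 0; i < n; ++i) {
        tbuf[i] = time[idx[i]];
        sbuf[i] = (char)(status[idx[i]] == 1);
      }
      const int p = (int)feat_pool.size();
      const int k = std::min(mtry, p);
      for (int i = 0; i < k; ++i) {          // partial Fisher-Yates
        const int j = i + rand_int(p - i);
        std::swap(feat_pool[i], feat_pool[j]);
      }
      for (int fi = 0; fi < k; ++fi) {
        const int f = feat_pool[fi];
        const double* col = &X(0, f);
        for (int i = 0; i < n; ++i) xbuf[i] = col[idx[i]];
        for (int s = 0; s < nsplit; ++s) {
          const double c = xbuf[rand_int(n)];
          const double st = split_stat(n, c);
          if (st > best_stat) { best_stat = st; best_f = f; best_c = c; }
        }
      }
    }
    if (best_f < 0) {                       // terminal
      tb.chfrow[node] = (int)(tb.chf.size() / tb.m);
      terminal_chf(idx);
      return node;
    }
    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    const double* col = &X(0, best_f);
    for (int i = 0; i < n; ++i) {
      if (col[idx[i]] <= best_c) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    tb.var[node] = best_f; tb.val[node] = best_c;
    const int l = build(li);
    tb.left[node] = l;
    const int r = build(ri);
    tb.right[node] = r;
    return node;
  }
};

int descend(const IntegerMatrix& nodes, const NumericVector& val,
            const NumericMatrix& X, int i) {
  int node = 0;
  while (nodes(node, 0) >= 0)
    node = (X(i, nodes(node, 0)) <= val[node]) ? nodes(node, 1) : nodes(node, 2);
  return nodes(node, 3);      // chf row
}

} // namespace

// [[Rcpp::export]]
List cf_grow_forest(NumericMatrix X, NumericVector time, IntegerVector status,
                    int ntree, int mtry, int nsplit, int min_events) {
  const int n = X.nrow();
  // grid of unique event times
  std::vector<double> ev;
  for (int i = 0; i < n; ++i) if (status[i] == 1) ev.push_back(time[i]);
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());
  if (ev.empty()) stop("no events in training data");
  NumericVector grid(ev.begin(), ev.end());

  // subject order by time, for sorted bootstrap assembly
  std::vector<int> time_order(n);
  for (int i = 0; i < n; ++i) time_order[i] = i;
  std::sort(time_order.begin(), time_order.end(),
            [&](int a, int b) { return time[a] < time[b]; });

  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<int> draws(n), idx;
  for (int t = 0; t < ntree; ++t) {
    int tries = 0, e = 0;
    do {                               // redraw an all-censored bootstrap
      if (tries > 0) for (int i = 0; i < n; ++i) --inbag(draws[i], t);
      e = 0;
      for (int i = 0; i < n; ++i) {
        const int s = rand_int(n);
        draws[i] = s;
        ++inbag(s, t);
        if (status[s] == 1) ++e;
      }
      ++tries;
    } while (e == 0 && tries < 100);
    // assemble the bootstrap index list in ascending time order
    idx.clear();
    for (int oi = 0; oi < n; ++oi) {
      const int s = time_order[oi];
      for (int r = 0; r < inbag(s, t); ++r) idx.push_back(s);
    }
    Grower gr(X, time, status, grid, mtry, nsplit, min_events);
    gr.build(idx);
    const int nn = (int)gr.tb.var.size();
    IntegerMatrix nodes(nn, 4);
    NumericVector val(nn);
    for (int i = 0; i < nn; ++i) {
      nodes(i, 0) = gr.tb.var[i]; nodes(i, 1) = gr.tb.left[i];
      nodes(i, 2) = gr.tb.right[i]; nodes(i, 3) = gr.tb.chfrow[i];
      val[i] = gr.tb.val[i];
    }
    const int nt = (int)(gr.tb.chf.size() / gr.tb.m);
    NumericMatrix chf(nt, gr.tb.m);
    for (int r = 0; r < nt; ++r)
      for (int c = 0; c < gr.tb.m; ++c)
        chf(r, c) = gr.tb.chf[r * gr.tb.m + c];
    trees[t] = List::create(_["nodes"] = nodes, _["split_val"] = val,
                            _["chf"] = chf);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["grid"] = grid);
}

// Ensemble cumulative hazard: average tree CHF over the trees flagged
// in `use` (n x ntree, nonzero = include). Subjects with no usable
// tree get NaN rows.
// [[Rcpp::export]]
List cf_ensemble_chf(List trees, NumericMatrix X, IntegerMatrix use) {
  const int n = X.nrow(), ntree = trees.size();
  NumericMatrix first_chf = as<List>(trees[0])["chf"];
  const int m = first_chf.ncol();
  NumericMatrix out(n, m);
  IntegerVector cnt(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerMatrix nodes = tr["nodes"];
    NumericVector val = tr["split_val"];
    NumericMatrix chf = tr["chf"];
    for (int i = 0; i < n; ++i) {
      if (use(i, t) == 0) continue;
      const int row = descend(nodes, val, X, i);
      for (int c = 0; c < m; ++c) out(i, c) += chf(row, c);
      ++cnt[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    if (cnt[i] > 0) for (int c = 0; c < m; ++c) out(i, c) /= cnt[i];
    else for (int c = 0; c < m; ++c) out(i, c) = NA_REAL;
  }
  return List::create(_["chf"] = out, _["n_trees_used"] = cnt);
}
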