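// Honest subsampled forest engine shared by the regression (nuisance) and
// causal forests.  One tree grower, two splitting rules:
//   * regression: variance-reduction on the (node-centered) target;
//   * causal: gradient pseudo-outcomes of the residual-on-residual regression,
//     maximizing CATE differences across children weighted by child sizes.
//
// Determinism contract: all randomness is derived from (forest seed, tree
// index, node counter) and row *ids* (not row positions), and every node-level
// accumulation runs in a (covariate value, id)-sorted order, so refitting after
// any row permutation reproduces each person's prediction exactly.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream, independent of R's RNG.
// ---------------------------------------------------------------------------

static inline uint64_t sm64_next(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash2(uint64_t a, uint64_t b) {
  uint64_t s = a ^ (b * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() { return sm64_next(state); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------------------------
// Forest data structures
// ---------------------------------------------------------------------------

struct Node {
  int var;            // 0-based split covariate, -1 for leaf
  double thr;         // x <= thr goes left
  int left, right;    // node indices, -1 for leaf
  int depth;          // root = 1
  int mstart, mlen;   // slice into Tree::members (leaves only)
  double sum_wy;      // causal: sum of w~ * y~ over J2 members
  double sum_ww;      // causal: sum of w~^2 over J2 members
  double leaf_value;  // regression: J2 mean
  Node() : var(-1), thr(0), left(-1), right(-1), depth(1),
           mstart(0), mlen(0), sum_wy(0), sum_ww(0), leaf_value(0) {}
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> members;  // J2 row indices, concatenated by leaf
  std::vector<int> inbag;    // sorted subsample row indices
  std::vector<int> j1;       // sorted J1 row indices (structure half)
  std::vector<int> j2;       // sorted J2 row indices (estimation half)
};

struct Forest {
  int n, p;
  bool causal;
  int B, min_node, mtry;
  double sample_frac, honesty_frac;
  uint64_t seed;
  std::vector<double> X;    // column-major n*p
  std::vector<int> ids;     // stable positive ids
  std::vector<double> t1;   // y (regression) or y~ (causal)
  std::vector<double> t2;   // w~ (causal only)
  double global_tau;        // fallback when weighted treatment variance is 0
  double global_mean;
  std::vector<Tree> trees;
  inline double x(int row, int var) const { return X[(size_t)var * n + row]; }
};

// ---------------------------------------------------------------------------
// Split search on one covariate (shared by the grower and the exported
// stand-alone best_split used in oracle tests).
//
// idx1: J1 rows sorted by (value, id); idx2: J2 rows sorted likewise.
// rho:  per-row pseudo-outcome (indexed by row).
// Candidate thresholds are midpoints between consecutive distinct J1 values;
// both children must keep >= min_node rows in both halves.
// ---------------------------------------------------------------------------

struct SplitCandidate {
  int var;
  double thr;
  double delta;
  bool found;
  SplitCandidate() : var(-1), thr(0), delta(0), found(false) {}
};

static void scan_split_var(const Forest& F, int v,
                           const int* idx1, int n1,
                           const int* idx2, int n2,
                           const std::vector<double>& rho,
                           double rho_total, int min_node,
                           SplitCandidate& best) {
  const double* col = &F.X[(size_t)v * F.n];
  double sl = 0.0;
  int j2pos = 0;
  for (int i = 0; i + 1 < n1; ++i) {
    sl += rho[idx1[i]];
    double xa = col[idx1[i]], xb = col[idx1[i + 1]];
    if (!(xa < xb)) continue;           // no boundary between ties
    int nl1 = i + 1, nr1 = n1 - nl1;
    if (nl1 < min_node) continue;
    if (nr1 < min_node) break;          // only shrinks further
    double thr = xa + (xb - xa) / 2.0;
    if (!(thr > xa)) thr = xb;          // guard against underflow to xa
    while (j2pos < n2 && col[idx2[j2pos]] <= thr) ++j2pos;
    int nl2 = j2pos, nr2 = n2 - nl2;
    if (nl2 < min_node || nr2 < min_node) continue;
    double sr = rho_total - sl;
    double delta = sl * sl / nl1 + sr * sr / nr1;
    if (delta > best.delta || !best.found) {
      if (best.found && !(delta > best.delta)) continue;
      best.var = v; best.thr = thr; best.delta = delta; best.found = true;
    }
  }
}

// ---------------------------------------------------------------------------
// Tree growing
// ---------------------------------------------------------------------------

struct GrowCtx {
  Forest* F;
  Tree* T;
  uint64_t tree_seed;
  int node_counter;
  std::vector<double> rho;      // scratch, indexed by row
  std::vector<int> var_pool;    // scratch for mtry sampling
  // per-covariate row lists sorted by (value, id); node ranges are shared
  // across covariates and partitioned in place with one scratch buffer
  std::vector<std::vector<int>> s1, s2;
  std::vector<int> scratch;
  std::vector<char> side;       // per-row split side, cache-resident
};

// Stable in-place partition of segment [lo, hi) of arr by ctx.side, using
// ctx.scratch; returns the number of left rows.
static int partition_segment(GrowCtx& ctx, std::vector<int>& arr,
                             int lo, int hi) {
  std::vector<int>& right = ctx.scratch;
  const char* side = ctx.side.data();
  int nl = 0, nr = 0;
  for (int i = lo; i < hi; ++i) {
    int r = arr[i];
    if (side[r]) arr[lo + nl++] = r;
    else right[nr++] = r;
  }
  for (int k = 0; k < nr; ++k) arr[lo + nl + k] = right[k];
  return nl;
}

// Compute node pseudo-outcomes into ctx.rho for rows [lo, hi) of ctx.s1[0]
// (a fixed (value, id)-sorted order, so sums are permutation-invariant).
// Returns false if the node cannot be split on statistical grounds
// (causal: no residual treatment variation).
static bool node_pseudo(GrowCtx& ctx, int lo, int hi, double& rho_total) {
  Forest& F = *ctx.F;
  const int* rows = &ctx.s1[0][lo];
  const int n1 = hi - lo;
  if (F.causal) {
    double sww = 0.0, swy = 0.0;
    for (int i = 0; i < n1; ++i) {
      int r = rows[i];
      sww += F.t2[r] * F.t2[r]; swy += F.t2[r] * F.t1[r];
    }
    if (!(sww > 0.0)) return false;
    double tau = swy / sww;
    double A = sww / n1;
    double tot = 0.0;
    for (int i = 0; i < n1; ++i) {
      int r = rows[i];
      ctx.rho[r] = F.t2[r] * (F.t1[r] - F.t2[r] * tau) / A;
      tot += ctx.rho[r];
    }
    rho_total = tot;
  } else {
    double s = 0.0;
    for (int i = 0; i < n1; ++i) s += F.t1[rows[i]];
    double mean = s / n1;
    double tot = 0.0;
    for (int i = 0; i < n1; ++i) {
      int r = rows[i];
      ctx.rho[r] = F.t1[r] - mean; tot += ctx.rho[r];
    }
    rho_total = tot;
  }
  return true;
}

static void make_leaf(GrowCtx& ctx, int node_id, int lo2, int hi2) {
  Forest& F = *ctx.F;
  Tree& T = *ctx.T;
  Node& nd = T.nodes[node_id];
  nd.var = -1;
  nd.mstart = (int)T.members.size();
  nd.mlen = hi2 - lo2;
  for (int i = lo2; i < hi2; ++i) T.members.push_back(ctx.s2[0][i]);
  if (F.causal) {
    double sww = 0.0, swy = 0.0;
    for (int i = lo2; i < hi2; ++i) {
      int r = ctx.s2[0][i];
      sww += F.t2[r] * F.t2[r]; swy += F.t2[r] * F.t1[r];
    }
    nd.sum_ww = sww; nd.sum_wy = swy;
  } else {
    double s = 0.0;
    for (int i = lo2; i < hi2; ++i) s += F.t1[ctx.s2[0][i]];
    nd.leaf_value = (hi2 == lo2) ? F.global_mean : s / (double)(hi2 - lo2);
  }
}

// Node rows are [lo1, hi1) of every ctx.s1[v] and [lo2, hi2) of every
// ctx.s2[v]; each covariate's segment holds the same row set in its own
// (value, id) order.
static int grow_node(GrowCtx& ctx, int lo1, int hi1, int lo2, int hi2,
                     int depth) {
  Forest& F = *ctx.F;
  Tree& T = *ctx.T;
  int node_id = (int)T.nodes.size();
  T.nodes.push_back(Node());
  T.nodes[node_id].depth = depth;
  int my_counter = ctx.node_counter++;

  const int n1 = hi1 - lo1, n2 = hi2 - lo2;
  double rho_total = 0.0;
  bool splittable = n1 >= 2 * F.min_node && n2 >= 2 * F.min_node;
  if (splittable) splittable = node_pseudo(ctx, lo1, hi1, rho_total);

  SplitCandidate best;
  if (splittable) {
    // draw mtry candidate covariates, then scan them in ascending index order
    // so that exact-delta ties resolve to the lowest covariate index and,
    // within a covariate, the lowest threshold (first strict improvement wins)
    Rng rng(hash2(ctx.tree_seed, 0x6E0DE5ULL + (uint64_t)my_counter));
    std::vector<int>& pool = ctx.var_pool;
    pool.resize(F.p);
    for (int v = 0; v < F.p; ++v) pool[v] = v;
    int m = F.mtry < F.p ? F.mtry : F.p;
    for (int k = 0; k < m; ++k) {
      int j = k + rng.below(F.p - k);
      std::swap(pool[k], pool[j]);
    }
    std::sort(pool.begin(), pool.begin() + m);
    for (int k = 0; k < m; ++k)
      scan_split_var(F, pool[k], &ctx.s1[pool[k]][lo1], n1,
                     &ctx.s2[pool[k]][lo2], n2,
                     ctx.rho, rho_total, F.min_node, best);
    if (best.found && !(best.delta > 0.0)) best.found = false;
  }

  if (!best.found) {
    make_leaf(ctx, node_id, lo2, hi2);
    return node_id;
  }

  // mark split sides once (sequential reads of the split column over the
  // node's rows), then partition every covariate's segment in place
  const double* split_col = &F.X[(size_t)best.var * F.n];
  for (int i = lo1; i < hi1; ++i) {
    int r = ctx.s1[best.var][i];
    ctx.side[r] = split_col[r] <= best.thr;
  }
  for (int i = lo2; i < hi2; ++i) {
    int r = ctx.s2[best.var][i];
    ctx.side[r] = split_col[r] <= best.thr;
  }
  int nl1 = 0, nl2 = 0;
  for (int v = 0; v < F.p; ++v) {
    nl1 = partition_segment(ctx, ctx.s1[v], lo1, hi1);
    nl2 = partition_segment(ctx, ctx.s2[v], lo2, hi2);
  }

  int li = grow_node(ctx, lo1, lo1 + nl1, lo2, lo2 + nl2, depth + 1);
  int ri = grow_node(ctx, lo1 + nl1, hi1, lo2 + nl2, hi2, depth + 1);

  Node& nd = T.nodes[node_id];
  nd.var = best.var; nd.thr = best.thr; nd.left = li; nd.right = ri;
  return node_id;
}

static void grow_tree(Forest& F, int b,
                      const std::vector<std::vector<int>>& global_ord,
                      std::vector<char>& memb) {
  Tree& T = F.trees[b];
  uint64_t tree_seed = hash2(F.seed, (uint64_t)(b + 1));
  const int n = F.n;

  // subsample without replacement by ranking id hashes; first block is J1
  std::vector<std::pair<uint64_t,int>> keys(n);
  for (int i = 0; i < n; ++i)
    keys[i] = std::make_pair(hash2(tree_seed, (uint64_t)(uint32_t)F.ids[i]), i);
  std::sort(keys.begin(), keys.end(),
            [&F](const std::pair<uint64_t,int>& a, const std::pair<uint64_t,int>& b2) {
              if (a.first != b2.first) return a.first < b2.first;
              return F.ids[a.second] < F.ids[b2.second];
            });
  int s = (int)std::floor(F.sample_frac * n);
  if (s < 2) s = 2; if (s > n) s = n;
  int h = (int)std::floor(F.honesty_frac * s);
  if (h < 1) h = 1; if (h > s - 1) h = s - 1;

  std::fill(memb.begin(), memb.end(), 0);
  for (int k = 0; k < s; ++k) memb[keys[k].second] = (k < h) ? 1 : 2;

  T.inbag.clear(); T.j1.clear(); T.j2.clear();
  for (int i = 0; i < n; ++i) {
    if (memb[i]) T.inbag.push_back(i);
    if (memb[i] == 1) T.j1.push_back(i);
    else if (memb[i] == 2) T.j2.push_back(i);
  }

  GrowCtx ctx;
  ctx.F = &F; ctx.T = &T; ctx.tree_seed = tree_seed; ctx.node_counter = 0;
  ctx.rho.resize(n);
  ctx.scratch.resize(n);
  ctx.side.assign(n, 0);

  // per-covariate sorted row lists from the global pre-sort
  ctx.s1.assign(F.p, std::vector<int>());
  ctx.s2.assign(F.p, std::vector<int>());
  for (int v = 0; v < F.p; ++v) {
    ctx.s1[v].reserve(T.j1.size()); ctx.s2[v].reserve(T.j2.size());
    for (int r : global_ord[v]) {
      if (memb[r] == 1) ctx.s1[v].push_back(r);
      else if (memb[r] == 2) ctx.s2[v].push_back(r);
    }
  }

  grow_node(ctx, 0, (int)T.j1.size(), 0, (int)T.j2.size(), 1);
}

static int route(const Forest& F, const Tree& T, const double* xq) {
  int node = 0;
  while (T.nodes[node].var >= 0) {
    const Node& nd = T.nodes[node];
    node = (xq[nd.var] <= nd.thr) ? nd.left : nd.right;
  }
  return node;
}

static bool in_bag(const Tree& T, int row) {
  return std::binary_search(T.inbag.begin(), T.inbag.end(), row);
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

static Forest* get_forest(SEXP xp) {
  Rcpp::XPtr<Forest> ptr(xp);
  if (!ptr) stop("invalid forest pointer (forests cannot be re-loaded from disk; refit)");
  return ptr.get();
}

// [[Rcpp::export]]
SEXP cpp_fit_forest(NumericMatrix X, NumericVector target,
                    NumericVector w_tilde, bool causal,
                    IntegerVector ids, int num_trees, double sample_fraction,
                    double honesty_fraction, int min_node_size, int mtry,
                    double seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 rows");
  Rcpp::XPtr<Forest> ptr(new Forest(), true);
  Forest& F = *ptr;
  F.n = n; F.p = p; F.causal = causal;
  F.B = num_trees; F.min_node = min_node_size; F.mtry = mtry;
  F.sample_frac = sample_fraction; F.honesty_frac = honesty_fraction;
  F.seed = (uint64_t)seed;
  F.X.assign(X.begin(), X.end());
  F.ids.assign(ids.begin(), ids.end());
  F.t1.assign(target.begin(), target.end());
  if (causal) F.t2.assign(w_tilde.begin(), w_tilde.end());

  double s1v = 0.0, s2v = 0.0;
  for (int i = 0; i < n; ++i) s1v += F.t1[i];
  F.global_mean = s1v / n;
  if (causal) {
    double sww = 0.0, swy = 0.0;
    for (int i = 0; i < n; ++i) { sww += F.t2[i]*F.t2[i]; swy += F.t2[i]*F.t1[i]; }
    F.global_tau = (sww > 0.0) ? swy / sww : 0.0;
  } else F.global_tau = 0.0;
  (void)s2v;

  // global per-covariate pre-sort by (value, id)
  std::vector<std::vector<int>> ord(p);
  for (int v = 0; v < p; ++v) {
    ord[v].resize(n);
    for (int i = 0; i < n; ++i) ord[v][i] = i;
    const double* col = &F.X[(size_t)v * n];
    std::sort(ord[v].begin(), ord[v].end(), [col, &F](int a, int b) {
      if (col[a] != col[b]) return col[a] < col[b];
      return F.ids[a] < F.ids[b];
    });
  }

  F.trees.resize(num_trees);
  std::vector<char> memb(n);
  for (int b = 0; b < num_trees; ++b) {
    grow_tree(F, b, ord, memb);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return ptr;
}

// Regression predictions for new data (all trees).
// [[Rcpp::export]]
NumericVector cpp_rf_predict(SEXP xp, NumericMatrix Xq) {
  Forest& F = *get_forest(xp);
  if (F.causal) stop("regression prediction requested from a causal forest");
  int nq = Xq.nrow();
  if (Xq.ncol() != F.p) stop("newdata has wrong number of covariates");
  NumericVector out(nq);
  std::vector<double> xrow(F.p);
  for (int q = 0; q < nq; ++q) {
    for (int v = 0; v < F.p; ++v) xrow[v] = Xq(q, v);
    double s = 0.0; int cnt = 0;
    for (const Tree& T : F.trees) {
      int leaf = route(F, T, xrow.data());
      if (T.nodes[leaf].mlen == 0) continue;
      s += T.nodes[leaf].leaf_value; ++cnt;
    }
    out[q] = cnt ? s / cnt : F.global_mean;
  }
  return out;
}

// Out-of-bag regression predictions for the training rows.
// [[Rcpp::export]]
NumericVector cpp_rf_predict_oob(SEXP xp) {
  Forest& F = *get_forest(xp);
  if (F.causal) stop("regression prediction requested from a causal forest");
  NumericVector out(F.n);
  std::vector<double> xrow(F.p);
  for (int i = 0; i < F.n; ++i) {
    for (int v = 0; v < F.p; ++v) xrow[v] = F.x(i, v);
    double s = 0.0; int cnt = 0;
    for (const Tree& T : F.trees) {
      if (in_bag(T, i)) continue;
      int leaf = route(F, T, xrow.data());
      if (T.nodes[leaf].mlen == 0) continue;
      s += T.nodes[leaf].leaf_value; ++cnt;
    }
    if (cnt == 0) stop("no out-of-bag trees for row %d; increase num_trees", i + 1);
    out[i] = s / cnt;
  }
  return out;
}

// Causal forest CATE prediction.  query_rows[q] >= 0 marks a training row
// whose in-bag trees must be skipped (out-of-bag prediction); -1 uses all trees.
static List cf_predict_impl(Forest& F, NumericMatrix Xq, IntegerVector query_rows) {
  int nq = Xq.nrow();
  if (Xq.ncol() != F.p) stop("newdata has wrong number of covariates");
  NumericVector tau(nq);
  LogicalVector fallback(nq);
  std::vector<double> xrow(F.p);
  for (int q = 0; q < nq; ++q) {
    for (int v = 0; v < F.p; ++v) xrow[v] = Xq(q, v);
    int self = query_rows[q];
    double num = 0.0, den = 0.0; int used = 0;
    for (const Tree& T : F.trees) {
      if (self >= 0 && in_bag(T, self)) continue;
      int leaf = route(F, T, xrow.data());
      const Node& nd = T.nodes[leaf];
      if (nd.mlen == 0) continue;
      num += nd.sum_wy / nd.mlen;
      den += nd.sum_ww / nd.mlen;
      ++used;
    }
    if (used == 0) stop("no out-of-bag trees for row %d; increase num_trees", self + 1);
    if (den > 0.0) { tau[q] = num / den; fallback[q] = false; }
    else { tau[q] = F.global_tau; fallback[q] = true; }
  }
  return List::create(_["tau"] = tau, _["fallback"] = fallback);
}

// [[Rcpp::export]]
List cpp_cf_predict(SEXP xp, NumericMatrix Xq) {
  Forest& F = *get_forest(xp);
  if (!F.causal) stop("CATE prediction requested from a regression forest");
  IntegerVector qr(Xq.nrow(), -1);
  return cf_predict_impl(F, Xq, qr);
}

// [[Rcpp::export]]
List cpp_cf_predict_oob(SEXP xp) {
  Forest& F = *get_forest(xp);
  if (!F.causal) stop("CATE prediction requested from a regression forest");
  NumericMatrix Xq(F.n, F.p);
  for (int v = 0; v < F.p; ++v)
    for (int i = 0; i < F.n; ++i) Xq(i, v) = F.x(i, v);
  IntegerVector qr(F.n);
  for (int i = 0; i < F.n; ++i) qr[i] = i;
  return cf_predict_impl(F, Xq, qr);
}

// Adaptive forest weights alpha_i(x): share of estimation-leaf co-membership,
// averaged over counted trees.  exclude_rows[q] >= 0 applies the out-of-bag
// rule for training-row queries.
// [[Rcpp::export]]
NumericMatrix cpp_forest_weights(SEXP xp, NumericMatrix Xq, IntegerVector exclude_rows) {
  Forest& F = *get_forest(xp);
  int nq = Xq.nrow();
  if (Xq.ncol() != F.p) stop("newdata has wrong number of covariates");
  NumericMatrix W(nq, F.n);
  std::vector<double> xrow(F.p);
  for (int q = 0; q < nq; ++q) {
    for (int v = 0; v < F.p; ++v) xrow[v] = Xq(q, v);
    int self = exclude_rows[q];
    int used = 0;
    for (const Tree& T : F.trees) {
      if (self >= 0 && in_bag(T, self)) continue;
      ++used;
    }
    if (used == 0) stop("no out-of-bag trees for row %d", self + 1);
    for (const Tree& T : F.trees) {
      if (self >= 0 && in_bag(T, self)) continue;
      int leaf = route(F, T, xrow.data());
      const Node& nd = T.nodes[leaf];
      if (nd.mlen == 0) continue;
      double share = 1.0 / ((double)used * nd.mlen);
      for (int k = 0; k < nd.mlen; ++k)
        W(q, T.members[nd.mstart + k]) += share;
    }
  }
  return W;
}

// Depth-decayed split-frequency variable importance.
// [[Rcpp::export]]
NumericVector cpp_variable_importance(SEXP xp, double decay, int max_depth) {
  Forest& F = *get_forest(xp);
  std::vector<std::vector<double>> counts(max_depth + 1,
                                          std::vector<double>(F.p, 0.0));
  std::vector<double> totals(max_depth + 1, 0.0);
  for (const Tree& T : F.trees)
    for (const Node& nd : T.nodes)
      if (nd.var >= 0 && nd.depth <= max_depth) {
        counts[nd.depth][nd.var] += 1.0;
        totals[nd.depth] += 1.0;
      }
  NumericVector imp(F.p);
  for (int d = 1; d <= max_depth; ++d) {
    if (totals[d] <= 0) continue;
    double wd = std::pow((double)d, -decay);
    for (int v = 0; v < F.p; ++v) imp[v] += wd * counts[d][v] / totals[d];
  }
  double s = 0.0;
  for (int v = 0; v < F.p; ++v) s += imp[v];
  if (s > 0) for (int v = 0; v < F.p; ++v) imp[v] /= s;
  return imp;
}

// Serializable structure: per tree, the split table plus id-labeled halves and
// leaf membership (ids, not row positions).
// [[Rcpp::export]]
List cpp_forest_structure(SEXP xp) {
  Forest& F = *get_forest(xp);
  List trees(F.B);
  for (int b = 0; b < F.B; ++b) {
    const Tree& T = F.trees[b];
    int nn = (int)T.nodes.size();
    IntegerVector var(nn), left(nn), right(nn), depth(nn);
    NumericVector thr(nn);
    List members(nn);
    for (int k = 0; k < nn; ++k) {
      const Node& nd = T.nodes[k];
      var[k] = nd.var >= 0 ? nd.var + 1 : NA_INTEGER;
      thr[k] = nd.var >= 0 ? nd.thr : NA_REAL;
      left[k] = nd.left >= 0 ? nd.left + 1 : NA_INTEGER;
      right[k] = nd.right >= 0 ? nd.right + 1 : NA_INTEGER;
      depth[k] = nd.depth;
      if (nd.var < 0) {
        IntegerVector mem(nd.mlen);
        for (int j = 0; j < nd.mlen; ++j) mem[j] = F.ids[T.members[nd.mstart + j]];
        members[k] = mem;
      } else members[k] = R_NilValue;
    }
    IntegerVector j1((int)T.j1.size()), j2((int)T.j2.size());
    for (size_t k = 0; k < T.j1.size(); ++k) j1[k] = F.ids[T.j1[k]];
    for (size_t k = 0; k < T.j2.size(); ++k) j2[k] = F.ids[T.j2[k]];
    trees[b] = List::create(
      _["nodes"] = DataFrame::create(_["var"] = var, _["threshold"] = thr,
                                     _["left"] = left, _["right"] = right,
                                     _["depth"] = depth),
      _["leaf_members"] = members, _["j1"] = j1, _["j2"] = j2);
  }
  return trees;
}

// [[Rcpp::export]]
List cpp_forest_info(SEXP xp) {
  Forest& F = *get_forest(xp);
  return List::create(_["n"] = F.n, _["p"] = F.p, _["causal"] = F.causal,
                      _["num_trees"] = F.B, _["global_tau"] = F.global_tau,
                      _["global_mean"] = F.global_mean);
}

// ---------------------------------------------------------------------------
// Stand-alone node operations (transparent single-node versions of the
// machinery above, exported for inspection and oracle testing)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_node_pseudo_outcomes(NumericVector w_tilde, NumericVector y_tilde) {
  int n = w_tilde.size();
  double sww = 0.0, swy = 0.0;
  for (int i = 0; i < n; ++i) { sww += w_tilde[i]*w_tilde[i]; swy += w_tilde[i]*y_tilde[i]; }
  if (!(sww > 0.0)) stop("no residual treatment variation in node (sum of w_tilde^2 is zero)");
  double tau = swy / sww, A = sww / n;
  NumericVector rho(n);
  for (int i = 0; i < n; ++i) rho[i] = w_tilde[i] * (y_tilde[i] - w_tilde[i] * tau) / A;
  return List::create(_["tau"] = tau, _["A"] = A, _["rho"] = rho);
}

// [[Rcpp::export]]
SEXP cpp_best_split(NumericMatrix X1, NumericVector rho,
                    NumericMatrix X2, int min_node, IntegerVector candidates) {
  int n1 = X1.nrow(), n2 = X2.nrow(), p = X1.ncol();
  if (X2.ncol() != p) stop("X1 and X2 must have the same covariates");
  // pack into a throwaway Forest so scan_split_var can be reused verbatim:
  // rows 0..n1-1 are the splitting half, n1..n1+n2-1 the estimation half.
  Forest F;
  F.n = n1 + n2; F.p = p; F.causal = false;
  F.X.resize((size_t)F.n * p);
  F.ids.resize(F.n);
  for (int i = 0; i < F.n; ++i) F.ids[i] = i + 1;
  for (int v = 0; v < p; ++v) {
    for (int i = 0; i < n1; ++i) F.X[(size_t)v * F.n + i] = X1(i, v);
    for (int i = 0; i < n2; ++i) F.X[(size_t)v * F.n + n1 + i] = X2(i, v);
  }
  std::vector<double> rho_all(F.n, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n1; ++i) { rho_all[i] = rho[i]; tot += rho[i]; }

  SplitCandidate best;
  std::vector<int> cand(candidates.begin(), candidates.end());
  std::sort(cand.begin(), cand.end());
  for (int cv : cand) {
    int v = cv - 1;
    if (v < 0 || v >= p) stop("candidate covariate index out of range");
    std::vector<int> idx1(n1), idx2(n2);
    for (int i = 0; i < n1; ++i) idx1[i] = i;
    for (int i = 0; i < n2; ++i) idx2[i] = n1 + i;
    const double* col = &F.X[(size_t)v * F.n];
    auto cmp = [col, &F](int a, int b) {
      if (col[a] != col[b]) return col[a] < col[b];
      return F.ids[a] < F.ids[b];
    };
    std::sort(idx1.begin(), idx1.end(), cmp);
    std::sort(idx2.begin(), idx2.end(), cmp);
    scan_split_var(F, v, idx1.data(), n1, idx2.data(), n2,
                   rho_all, tot, min_node, best);
  }
  if (!best.found || !(best.delta > 0.0)) return R_NilValue;
  return List::create(_["var"] = best.var + 1, _["threshold"] = best.thr,
                      _["delta"] = best.delta);
}
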