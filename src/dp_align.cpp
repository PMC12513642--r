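#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Elastic pairwise alignment of SRVFs on a uniform grid by dynamic
// programming over slope-constrained monotone lattice paths.
//
// Lattice nodes are grid index pairs (i, j); admissible moves are the
// coprime steps (p, q) with 1 <= p, q <= 3, so local warp slopes lie in
// {p/q : 1 <= p, q <= 3}. The edge cost from (i, j) to (i+p, j+q) is the
// trapezoidal approximation of
//   int_{t_i}^{t_{i+p}} ( q1(t) - sqrt(gamma') q2(gamma(t)) )^2 dt
// with gamma linear on the edge (slope q/p in time because the grid is
// uniform) and q2 evaluated by linear interpolation.

static const int NSTEP = 7;
static const int STEP_P[NSTEP] = {1, 1, 2, 1, 3, 2, 3};
static const int STEP_Q[NSTEP] = {1, 2, 1, 3, 1, 3, 2};

// Precomputed sqrt(slope) * q2(j + slope * k) for every step s, offset
// k = 0..p and start column j; shared by the DP and the exhaustive oracle
// so both optimize the identical objective.
struct EdgeTable {
  int n;
  double dt;
  const double* q1;
  // tab[s][k*n + j]
  std::vector<std::vector<double>> tab;
};

static void build_table(EdgeTable& et, const double* q1, const double* q2,
                        int n, double dt) {
  et.n = n; et.dt = dt; et.q1 = q1;
  et.tab.assign(NSTEP, std::vector<double>());
  for (int s = 0; s < NSTEP; ++s) {
    int p = STEP_P[s], q = STEP_Q[s];
    double slope = (double)q / (double)p;
    double ssl = std::sqrt(slope);
    et.tab[s].assign((size_t)(p + 1) * n, 0.0);
    for (int k = 0; k <= p; ++k) {
      double off = slope * k;
      for (int j = 0; j < n; ++j) {
        double x = j + off;
        double v;
        if (x >= n - 1) v = q2[n - 1];
        else {
          int m = (int)x;
          double r = x - m;
          v = (1.0 - r) * q2[m] + r * q2[m + 1];
        }
        et.tab[s][(size_t)k * n + j] = ssl * v;
      }
    }
  }
}

// cost of the edge (i, j) -> (i + p, j + q) for step index s
static inline double edge_cost(const EdgeTable& et, int s, int i, int j) {
  int p = STEP_P[s];
  const double* tab = et.tab[s].data();
  const double* q1 = et.q1;
  int n = et.n;
  double acc = 0.0;
  for (int k = 0; k <= p; ++k) {
    double f = q1[i + k] - tab[(size_t)k * n + j];
    double w = (k == 0 || k == p) ? 0.5 : 1.0; // trapezoid weights
    acc += w * f * f;
  }
  return acc * et.dt;
}

// [[Rcpp::export]]
List dp_align_cpp(NumericVector q1, NumericVector q2, double dt) {
  int n = q1.size();
  if (q2.size() != n) stop("SRVF grids must have the same length");
  EdgeTable et;
  build_table(et, REAL(q1), REAL(q2), n, dt);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> H((size_t)n * n, INF);
  std::vector<int> pred((size_t)n * n, -1);
  H[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double h = H[(size_t)i * n + j];
      if (h == INF) continue;
      for (int s = 0; s < NSTEP; ++s) {
        int p = STEP_P[s], q = STEP_Q[s];
        int i2 = i + p, j2 = j + q;
        if (i2 >= n || j2 >= n) continue;
        double c = h + edge_cost(et, s, i, j);
        size_t idx = (size_t)i2 * n + j2;
        bool take = false;
        if (c < H[idx]) {
          take = true;
        } else if (c == H[idx] && pred[idx] >= 0) {
          // tie: prefer the step closest to the diagonal, then the shortest
          int s0 = pred[idx];
          int d0 = std::abs(STEP_P[s0] - STEP_Q[s0]);
          int d1 = std::abs(p - q);
          if (d1 < d0 || (d1 == d0 && p + q < STEP_P[s0] + STEP_Q[s0]))
            take = true;
        }
        if (take) { H[idx] = c; pred[idx] = s; }
      }
    }
  }
  // backtrack from (n-1, n-1)
  std::vector<int> pi, pj;
  int i = n - 1, j = n - 1;
  while (i > 0 || j > 0) {
    pi.push_back(i); pj.push_back(j);
    int s = pred[(size_t)i * n + j];
    if (s < 0) stop("no admissible lattice path reaches the end node");
    i -= STEP_P[s]; j -= STEP_Q[s];
  }
  pi.push_back(0); pj.push_back(0);
  int m = pi.size();
  IntegerVector path_i(m), path_j(m);
  for (int k = 0; k < m; ++k) {
    path_i[k] = pi[m - 1 - k] + 1;  // 1-based for R
    path_j[k] = pj[m - 1 - k] + 1;
  }
  return List::create(_["cost"] = H[(size_t)n * n - 1],
                      _["path_i"] = path_i, _["path_j"] = path_j);
}

// ---- continuous refinement of a DP warp ----
//
// The lattice quantizes gamma to grid nodes and its slopes to ratios p/q,
// which leaves a small residual misfit (SRVFs have sqrt-type cusps, so the
// objective is sensitive to sub-grid shifts). Starting from the DP path we
// run coordinate descent on the warp's node positions: each interior
// gamma(t_i) is optimized by golden-section search between its neighbours,
// with gamma linear on the two adjacent segments and the local objective
//   int_{t_{i-1}}^{t_{i+1}} ( q1(t) - sqrt(gamma') q2(gamma(t)) )^2 dt
// evaluated by composite trapezoid with `sub` subdivisions per segment.

static inline double interp_lin(const double* v, double x, int n) {
  if (x <= 0.0) return v[0];
  if (x >= n - 1) return v[n - 1];
  int m = (int)x;
  double r = x - m;
  return (1.0 - r) * v[m] + r * v[m + 1];
}

// misfit on segment [i0, i1] (index space) when gamma moves linearly from
// y0 to y1 there; `sub` sample subdivisions per unit index step
static double seg_cost(const double* q1, const double* q2, int n, double dt,
                       double i0, double i1, double y0, double y1, int sub) {
  if (y1 <= y0) return std::numeric_limits<double>::infinity();
  double len = i1 - i0;
  double slope = (y1 - y0) / len;
  double ssl = std::sqrt(slope);
  int npts = (int)(len * sub + 0.5);
  if (npts < 2) npts = 2;
  double acc = 0.0;
  for (int k = 0; k <= npts; ++k) {
    double a = (double)k / npts;
    double q1v = interp_lin(q1, i0 + a * len, n);
    double q2v = interp_lin(q2, y0 + a * (y1 - y0), n);
    double f = q1v - ssl * q2v;
    double w = (k == 0 || k == npts) ? 0.5 : 1.0;
    acc += w * f * f;
  }
  return acc * (len * dt) / npts;
}

// golden-section search for the best position of node i between its two
// neighbours (all in index space); returns the improved position
static double best_node(const double* q1, const double* q2, int n, double dt,
                        double iL, double iC, double iR,
                        double yL, double yC, double yR, int sub,
                        double blo, double bhi) {
  double lo = std::max(yL + 1e-8, blo), hi = std::min(yR - 1e-8, bhi);
  if (hi <= lo) return yC;
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = seg_cost(q1, q2, n, dt, iL, iC, yL, c, sub) +
              seg_cost(q1, q2, n, dt, iC, iR, c, yR, sub);
  double fd = seg_cost(q1, q2, n, dt, iL, iC, yL, d, sub) +
              seg_cost(q1, q2, n, dt, iC, iR, d, yR, sub);
  for (int it = 0; it < 20; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = seg_cost(q1, q2, n, dt, iL, iC, yL, c, sub) +
           seg_cost(q1, q2, n, dt, iC, iR, c, yR, sub);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = seg_cost(q1, q2, n, dt, iL, iC, yL, d, sub) +
           seg_cost(q1, q2, n, dt, iC, iR, d, yR, sub);
    }
  }
  double cand = (fc < fd) ? c : d;
  double fcand = (fc < fd) ? fc : fd;
  double fcur = seg_cost(q1, q2, n, dt, iL, iC, yL, yC, sub) +
                seg_cost(q1, q2, n, dt, iC, iR, yC, yR, sub);
  return (fcand < fcur) ? cand : yC;
}

// Coarse-to-fine coordinate descent: node positions are optimized on
// subsampled node sets (stride 16, 8, 4, 2, 1), each stage modelling the
// warp as piecewise linear between its nodes. Coarse stages move whole
// regions of the warp at once, so a few passes per stage converge where
// single-node descent would diffuse slowly. Every node stays within
// `max_move` grid steps of its DP position: the refinement removes the
// lattice's quantization, it is not a free optimizer (an unconstrained
// search would chase measurement noise and pinch the warp).
// [[Rcpp::export]]
NumericVector refine_warp_cpp(NumericVector q1, NumericVector q2,
                              NumericVector gamma_idx, double dt,
                              int passes = 2, int sub = 4,
                              double max_move = 5.0) {
  int n = q1.size();
  if (q2.size() != n || gamma_idx.size() != n)
    stop("inputs must share a grid");
  std::vector<double> y(REAL(gamma_idx), REAL(gamma_idx) + n);
  std::vector<double> y0(y);   // anchor: the DP warp
  const double* p1 = REAL(q1);
  const double* p2 = REAL(q2);
  static const int STRIDES[5] = {16, 8, 4, 2, 1};
  for (int si = 0; si < 5; ++si) {
    int S = STRIDES[si];
    if (S >= n / 3) continue;
    // node index set for this stage
    std::vector<int> idx;
    for (int i = 0; i < n; i += S) idx.push_back(i);
    if (idx.back() != n - 1) idx.push_back(n - 1);
    int m = idx.size();
    std::vector<double> yc(m);
    for (int k = 0; k < m; ++k) yc[k] = y[idx[k]];
    int np = (S == 1) ? passes * 3 : passes;
    for (int pass = 0; pass < np; ++pass) {
      for (int k = 1; k < m - 1; ++k) {
        yc[k] = best_node(p1, p2, n, dt,
                          idx[k - 1], idx[k], idx[k + 1],
                          yc[k - 1], yc[k], yc[k + 1], sub,
                          y0[idx[k]] - max_move, y0[idx[k]] + max_move);
      }
    }
    // rebuild the full-resolution warp piecewise linearly over the nodes
    for (int k = 0; k + 1 < m; ++k) {
      int i0 = idx[k], i1 = idx[k + 1];
      for (int i = i0; i <= i1; ++i) {
        double a = (i1 == i0) ? 0.0 : (double)(i - i0) / (i1 - i0);
        y[i] = yc[k] + a * (yc[k + 1] - yc[k]);
      }
    }
  }
  return NumericVector(y.begin(), y.end());
}

static void brute_rec(const EdgeTable& et, int i, int j, double acc,
                      double& best) {
  int n = et.n;
  if (i == n - 1 && j == n - 1) {
    if (acc < best) best = acc;
    return;
  }
  for (int s = 0; s < NSTEP; ++s) {
    int p = STEP_P[s], q = STEP_Q[s];
    int i2 = i + p, j2 = j + q;
    if (i2 >= n || j2 >= n) continue;
    brute_rec(et, i2, j2, acc + edge_cost(et, s, i, j), best);
  }
}

// Exhaustive minimum over every slope-constrained monotone lattice path.
// Independent of the DP recursion; intended for small grids only.
// [[Rcpp::export]]
double brute_align_cost_cpp(NumericVector q1, NumericVector q2, double dt) {
  int n = q1.size();
  if (q2.size() != n) stop("SRVF grids must have the same length");
  if (n > 24) stop("exhaustive search is limited to grids of at most 24 points");
  EdgeTable et;
  build_table(et, REAL(q1), REAL(q2), n, dt);
  double best = std::numeric_limits<double>::infinity();
  brute_rec(et, 0, 0, 0.0, best);
  return best;
}
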