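#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Digamma at positive integers via the harmonic-series identity
// psi(1) = -gamma, psi(n+1) = psi(n) + 1/n.  Tabulated once per call.
static std::vector<double> psi_table(int nmax) {
  std::vector<double> psi(nmax + 1, 0.0);
  psi[1] = -0.577215664901532860606512090082402431;
  for (int k = 1; k < nmax; ++k) psi[k + 1] = psi[k] + 1.0 / k;
  return psi;
}

// Static 2-D KD-tree with max-norm (Chebyshev) queries, built once per pair.
struct KDTree {
  struct Node {
    int lo, hi, left, right;
    double xmin, xmax, ymin, ymax;
  };
  const double *x, *y;
  std::vector<int> idx;
  std::vector<Node> nodes;
  static const int LEAF = 16;

  KDTree(const double *x_, const double *y_, int n) : x(x_), y(y_) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 4);
    build(0, n);
  }

  int build(int lo, int hi) {
    int id = nodes.size();
    nodes.push_back(Node());
    Node &nd = nodes[id];
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double xv = x[idx[i]], yv = y[idx[i]];
      if (xv < xmin) xmin = xv;
      if (xv > xmax) xmax = xv;
      if (yv < ymin) ymin = yv;
      if (yv > ymax) ymax = yv;
    }
    nd.xmin = xmin; nd.xmax = xmax; nd.ymin = ymin; nd.ymax = ymax;
    if (hi - lo > LEAF) {
      int mid = (lo + hi) / 2;
      if (xmax - xmin >= ymax - ymin)
        std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                         [&](int a, int b) { return x[a] < x[b]; });
      else
        std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                         [&](int a, int b) { return y[a] < y[b]; });
      int l = build(lo, mid);
      int r = build(mid, hi);
      nodes[id].left = l;
      nodes[id].right = r;
    }
    return id;
  }

  // max-norm distance from point (qx, qy) to a node's bounding box
  static double box_dist(const Node &nd, double qx, double qy) {
    double dx = 0.0, dy = 0.0;
    if (qx < nd.xmin) dx = nd.xmin - qx; else if (qx > nd.xmax) dx = qx - nd.xmax;
    if (qy < nd.ymin) dy = nd.ymin - qy; else if (qy > nd.ymax) dy = qy - nd.ymax;
    return dx > dy ? dx : dy;
  }

  // k nearest neighbours of point self (excluded); fills nb with indices
  void knn(int self, int k, std::vector<double> &kd, std::vector<int> &nb,
           int &filled, double &worstd, int node, double qx, double qy) const {
    const Node &nd = nodes[node];
    if (filled == k && box_dist(nd, qx, qy) > worstd) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (j == self) continue;
        double dx = std::fabs(x[j] - qx), dy = std::fabs(y[j] - qy);
        double d = dx > dy ? dx : dy;
        if (filled < k) {
          kd[filled] = d; nb[filled] = j; ++filled;
          if (filled == k) {
            worstd = kd[0];
            for (int t = 1; t < k; ++t) if (kd[t] > worstd) worstd = kd[t];
          }
        } else if (d < worstd) {
          int w = 0;
          for (int t = 1; t < k; ++t) if (kd[t] > kd[w]) w = t;
          kd[w] = d; nb[w] = j;
          worstd = kd[0];
          for (int t = 1; t < k; ++t) if (kd[t] > worstd) worstd = kd[t];
        }
      }
      return;
    }
    double dl = box_dist(nodes[nd.left], qx, qy);
    double dr = box_dist(nodes[nd.right], qx, qy);
    if (dl <= dr) {
      knn(self, k, kd, nb, filled, worstd, nd.left, qx, qy);
      knn(self, k, kd, nb, filled, worstd, nd.right, qx, qy);
    } else {
      knn(self, k, kd, nb, filled, worstd, nd.right, qx, qy);
      knn(self, k, kd, nb, filled, worstd, nd.left, qx, qy);
    }
  }
};

// KSG estimator, second algorithm: for each joint sample find its k nearest
// neighbours under the max norm, project that neighbourhood onto the
// marginals (eps_x(i)/2 = max |dx| over the k neighbours, likewise eps_y),
// count marginal neighbours boundary-inclusively (|x_i - x_j| <=
// eps_x(i)/2), and combine as
//   I = psi(k) - 1/k - mean(psi(n_x) + psi(n_y)) + psi(N).
// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N");

  KDTree tree(x.begin(), y.begin(), n);

  std::vector<double> xsort(x.begin(), x.end());
  std::vector<double> ysort(y.begin(), y.end());
  std::sort(xsort.begin(), xsort.end());
  std::sort(ysort.begin(), ysort.end());

  std::vector<double> psi = psi_table(n);
  std::vector<double> kd(k);
  std::vector<int> nb(k);
  double acc = 0.0;

  for (int i = 0; i < n; ++i) {
    int filled = 0;
    double worstd = R_PosInf;
    tree.knn(i, k, kd, nb, filled, worstd, 0, x[i], y[i]);

    double ex = 0.0, ey = 0.0;  // eps_x(i)/2, eps_y(i)/2
    for (int t = 0; t < k; ++t) {
      double dx = std::fabs(x[nb[t]] - x[i]);
      double dy = std::fabs(y[nb[t]] - y[i]);
      if (dx > ex) ex = dx;
      if (dy > ey) ey = dy;
    }

    // boundary-inclusive marginal counts, excluding the point itself;
    // binary search then linear extension so the defining neighbour is
    // never lost to floating-point rounding of x[i] +/- ex
    int lo = std::lower_bound(xsort.begin(), xsort.end(), x[i] - ex) - xsort.begin();
    int hi = std::upper_bound(xsort.begin(), xsort.end(), x[i] + ex) - xsort.begin();
    while (lo > 0 && x[i] - xsort[lo - 1] <= ex) --lo;
    while (hi < n && xsort[hi] - x[i] <= ex) ++hi;
    int nx = hi - lo - 1;

    lo = std::lower_bound(ysort.begin(), ysort.end(), y[i] - ey) - ysort.begin();
    hi = std::upper_bound(ysort.begin(), ysort.end(), y[i] + ey) - ysort.begin();
    while (lo > 0 && y[i] - ysort[lo - 1] <= ey) --lo;
    while (hi < n && ysort[hi] - y[i] <= ey) ++hi;
    int ny = hi - lo - 1;

    if (nx < 1) nx = 1;
    if (ny < 1) ny = 1;
    acc += psi[nx] + psi[ny];
  }

  return psi[k] - 1.0 / k + psi[n] - acc / n;
}
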