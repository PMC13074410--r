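#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <memory>
using namespace Rcpp;

// 2-D kd-tree over a point matrix (column 1 = row coord, column 2 = col coord).
// Built once per clustering run; fixed-radius queries prune half-spaces further
// than eps from the query point. Average query cost O(log n + k).
class KDTree2 {
public:
  KDTree2(const NumericMatrix& pts)
    : r_(REAL(pts)), c_(REAL(pts) + pts.nrow()), n_(pts.nrow()), idx_(n_) {
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    if (n_ > 0) build(0, n_, 0);
  }

  // All indices within Euclidean distance eps of (qr, qc). Traversal order
  // is fixed by the (deterministic) tree layout; DBSCAN's result does not
  // depend on the order neighbours are reported in, so no sort is needed.
  void radius(double qr, double qc, double eps, std::vector<int>& out) const {
    out.clear();
    if (n_ == 0) return;
    search(0, n_, 0, qr, qc, eps * eps, eps, out);
  }

private:
  const double* r_;
  const double* c_;
  int n_;
  std::vector<int> idx_;
  static const int LEAF = 16;

  void build(int lo, int hi, int axis) {
    if (hi - lo <= LEAF) return;
    int mid = (lo + hi) / 2;
    const double* d = axis == 0 ? r_ : c_;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [d](int a, int b) { return d[a] < d[b]; });
    build(lo, mid, 1 - axis);
    build(mid + 1, hi, 1 - axis);
  }

  void search(int lo, int hi, int axis, double qr, double qc,
              double eps2, double eps, std::vector<int>& out) const {
    if (hi - lo <= LEAF) {
      for (int k = lo; k < hi; ++k) {
        int i = idx_[k];
        double dr = r_[i] - qr, dc = c_[i] - qc;
        if (dr * dr + dc * dc <= eps2) out.push_back(i);
      }
      return;
    }
    int mid = (lo + hi) / 2;
    int i = idx_[mid];
    double dr = r_[i] - qr, dc = c_[i] - qc;
    if (dr * dr + dc * dc <= eps2) out.push_back(i);
    double split = axis == 0 ? r_[i] : c_[i];
    double q = axis == 0 ? qr : qc;
    if (q - eps <= split) search(lo, mid, 1 - axis, qr, qc, eps2, eps, out);
    if (q + eps >= split) search(mid + 1, hi, 1 - axis, qr, qc, eps2, eps, out);
  }
};

// Classic DBSCAN with deterministic, seed-free labelling: points are visited
// in row order, so cluster ids follow discovery order and a border point
// shared between two clusters attaches to the cluster discovered first
// (each cluster is expanded to completion before the outer loop moves on,
// which makes the labelling independent of the order neighbours are
// reported in). A point is core when its eps-neighbourhood (self included)
// holds at least min_samples points. Labels: -1 = noise, clusters numbered
// from 1. use_kdtree toggles the spatial index against a linear scan; both
// paths return identical labels.
// [[Rcpp::export]]
IntegerVector dbscan_labels_cpp(NumericMatrix pts, double eps,
                                int min_samples, bool use_kdtree) {
  const int n = pts.nrow();
  IntegerVector labels(n);
  if (n == 0) return labels;
  if (eps <= 0) stop("eps must be positive");
  if (min_samples < 1) stop("min_samples must be at least 1");

  const int UNSEEN = 0, NOISE = -1;
  std::vector<int> lab(n, UNSEEN);
  const double* r = REAL(pts);
  const double* c = r + n;
  const double eps2 = eps * eps;

  std::unique_ptr<KDTree2> tree;
  if (use_kdtree) tree.reset(new KDTree2(pts));

  std::vector<int> nbr, queue;
  nbr.reserve(1024);
  queue.reserve(1024);

  auto query = [&](int i) {
    if (tree) {
      tree->radius(r[i], c[i], eps, nbr);
    } else {
      nbr.clear();
      for (int j = 0; j < n; ++j) {
        double dr = r[j] - r[i], dc = c[j] - c[i];
        if (dr * dr + dc * dc <= eps2) nbr.push_back(j);
      }
    }
  };

  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != UNSEEN) continue;
    query(i);
    if ((int)nbr.size() < min_samples) {
      lab[i] = NOISE;
      continue;
    }
    ++cl;
    lab[i] = cl;
    // breadth-first expansion; every point enters the queue at most once
    queue.clear();
    for (int q : nbr) {
      if (lab[q] == UNSEEN) {
        lab[q] = cl;
        queue.push_back(q);
      } else if (lab[q] == NOISE) {
        lab[q] = cl;  // border point, non-core: no expansion
      }
    }
    for (size_t k = 0; k < queue.size(); ++k) {
      int q = queue[k];
      query(q);
      if ((int)nbr.size() < min_samples) continue;  // border point
      for (int v : nbr) {
        if (lab[v] == UNSEEN) {
          lab[v] = cl;
          queue.push_back(v);
        } else if (lab[v] == NOISE) {
          lab[v] = cl;
        }
      }
    }
  }

  for (int i = 0; i < n; ++i) labels[i] = lab[i];
  return labels;
}
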