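#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// Exact k-nearest-neighbour search via a median-split kd-tree.
// Ties in distance are broken toward the lower point index, which makes the
// neighbour lists fully deterministic (a contract the test oracles rely on).

namespace {

struct Cand {
  double d2;
  int i;
};

// "better": strictly closer, or equally close with a lower index.
inline bool better(const Cand& a, const Cand& b) {
  return a.d2 < b.d2 || (a.d2 == b.d2 && a.i < b.i);
}

struct WorstFirst {
  bool operator()(const Cand& a, const Cand& b) const { return better(a, b); }
};

class KdTree {
 public:
  KdTree(const NumericMatrix& pts) : pts_(pts), n_(pts.nrow()), idx_(n_) {
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    build(0, n_, 0);
  }

  void query(const double* q, int k, int self,
             std::priority_queue<Cand, std::vector<Cand>, WorstFirst>& heap) const {
    search(0, n_, 0, q, k, self, heap);
  }

 private:
  const NumericMatrix& pts_;
  int n_;
  std::vector<int> idx_;

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&](int a, int b) {
                       double va = pts_(a, d), vb = pts_(b, d);
                       return va < vb || (va == vb && a < b);
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  double dist2(int i, const double* q) const {
    double dx = pts_(i, 0) - q[0];
    double dy = pts_(i, 1) - q[1];
    double dz = pts_(i, 2) - q[2];
    return dx * dx + dy * dy + dz * dz;
  }

  void search(int lo, int hi, int depth, const double* q, int k, int self,
              std::priority_queue<Cand, std::vector<Cand>, WorstFirst>& heap) const {
    if (lo >= hi) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    int pi = idx_[mid];
    if (pi != self) {
      Cand c{dist2(pi, q), pi};
      if ((int)heap.size() < k) {
        heap.push(c);
      } else if (better(c, heap.top())) {
        heap.pop();
        heap.push(c);
      }
    }
    double diff = q[d] - pts_(pi, d);
    int nlo, nhi, flo, fhi;
    if (diff < 0) {
      nlo = lo; nhi = mid; flo = mid + 1; fhi = hi;
    } else {
      nlo = mid + 1; nhi = hi; flo = lo; fhi = mid;
    }
    search(nlo, nhi, depth + 1, q, k, self, heap);
    // <= so that an equidistant point with a lower index on the far side is
    // still visited (needed for the deterministic tie-break).
    if ((int)heap.size() < k || diff * diff <= heap.top().d2) {
      search(flo, fhi, depth + 1, q, k, self, heap);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List knn_cpp(NumericMatrix pts, NumericMatrix query, int k, bool self_exclude) {
  KdTree tree(pts);
  int m = query.nrow();
  IntegerMatrix nbr(m, k);
  NumericMatrix dist(m, k);
  std::priority_queue<Cand, std::vector<Cand>, WorstFirst> heap;
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int self = self_exclude ? i : -1;
    tree.query(q, k, self, heap);
    // Drain worst-first; fill from the back for ascending order.
    int j = (int)heap.size() - 1;
    for (; !heap.empty(); heap.pop(), --j) {
      nbr(i, j) = heap.top().i + 1;  // 1-based
      dist(i, j) = std::sqrt(heap.top().d2);
    }
  }
  return List::create(_["idx"] = nbr, _["dist"] = dist);
}

// [[Rcpp::export]]
double min_spacing_cpp(NumericMatrix pts) {
  KdTree tree(pts);
  int n = pts.nrow();
  double best = R_PosInf;
  std::priority_queue<Cand, std::vector<Cand>, WorstFirst> heap;
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    tree.query(q, 1, i, heap);
    if (heap.top().d2 < best * best) best = std::sqrt(heap.top().d2);
    heap.pop();
  }
  return best;
}
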