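#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t ekey(int a, int b, int nv) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (uint64_t)lo * (uint64_t)(nv + 1) + hi;
}

}  // namespace

// Watertight predicate: every undirected edge borders exactly two faces.
// Returns the counts needed for diagnostics.
// [[Rcpp::export]]
List edge_audit_cpp(IntegerMatrix F, int nv) {
  std::unordered_map<uint64_t, int> cnt;
  int nf = F.nrow();
  for (int i = 0; i < nf; ++i) {
    int a = F(i, 0), b = F(i, 1), c = F(i, 2);
    if (a == b || b == c || a == c) {
      return List::create(_["watertight"] = false, _["open_edges"] = -1,
                          _["over_edges"] = -1);
    }
    ++cnt[ekey(a, b, nv)];
    ++cnt[ekey(b, c, nv)];
    ++cnt[ekey(c, a, nv)];
  }
  int open = 0, over = 0;
  for (auto& kv : cnt) {
    if (kv.second == 1) ++open;
    else if (kv.second > 2) ++over;
  }
  return List::create(_["watertight"] = (open == 0 && over == 0 && nf > 0),
                      _["open_edges"] = open, _["over_edges"] = over);
}

// Breadth-first winding propagation across shared edges (right-hand rule):
// two faces sharing an edge are consistently wound iff they traverse the
// edge in opposite directions. Returns repaired faces plus a component id
// per face; the global sign of each component is left to the caller.
// [[Rcpp::export]]
List orient_faces_cpp(IntegerMatrix F, int nv) {
  int nf = F.nrow();
  // adjacency through edges: each undirected edge -> up to 2 faces
  std::unordered_map<uint64_t, std::pair<int, int>> e2f;
  e2f.reserve(nf * 2);
  for (int i = 0; i < nf; ++i) {
    for (int e = 0; e < 3; ++e) {
      uint64_t k = ekey(F(i, e), F(i, (e + 1) % 3), nv);
      auto it = e2f.find(k);
      if (it == e2f.end()) e2f[k] = {i, -1};
      else it->second.second = i;
    }
  }
  IntegerMatrix out(clone(F));
  std::vector<int> comp(nf, -1);
  std::vector<int> queue;
  queue.reserve(nf);
  int ncomp = 0;
  auto directed = [&](int f, int va, int vb) {
    // does face f (current winding in `out`) traverse edge va->vb in order?
    for (int e = 0; e < 3; ++e) {
      if (out(f, e) == va && out(f, (e + 1) % 3) == vb) return true;
    }
    return false;
  };
  for (int s = 0; s < nf; ++s) {
    if (comp[s] >= 0) continue;
    comp[s] = ncomp;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      int f = queue[head++];
      for (int e = 0; e < 3; ++e) {
        int va = out(f, e), vb = out(f, (e + 1) % 3);
        auto it = e2f.find(ekey(va, vb, nv));
        if (it == e2f.end()) continue;
        int other = (it->second.first == f) ? it->second.second
                                            : it->second.first;
        if (other < 0 || comp[other] >= 0) continue;
        // f traverses va->vb; `other` must traverse vb->va
        if (directed(other, va, vb)) {
          int tmp = out(other, 1);
          out(other, 1) = out(other, 2);
          out(other, 2) = tmp;
        }
        comp[other] = ncomp;
        queue.push_back(other);
      }
    }
    ++ncomp;
  }
  return List::create(_["faces"] = out, _["component"] = comp,
                      _["n_components"] = ncomp);
}

// Parity-count voxelization oracle: casts one +z ray per (x,y) voxel-centre
// column, collects triangle crossings, and counts voxel centres inside.
// Column coordinates are nudged by an irrational epsilon so rays never hit
// triangle edges of lattice-aligned meshes.
// [[Rcpp::export]]
double voxel_volume_cpp(NumericMatrix V, IntegerMatrix F, int n) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  int nv = V.nrow(), nf = F.nrow();
  for (int i = 0; i < nv; ++i) {
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(i, d));
      hi[d] = std::max(hi[d], V(i, d));
    }
  }
  double pad = 1e-9;
  for (int d = 0; d < 3; ++d) {
    double w = hi[d] - lo[d];
    lo[d] -= pad * (w + 1);
    hi[d] += pad * (w + 1);
  }
  double hx = (hi[0] - lo[0]) / n, hy = (hi[1] - lo[1]) / n,
         hz = (hi[2] - lo[2]) / n;
  const double eps_x = 0.5 + 1.1920928955078125e-5 * std::sqrt(2.0);
  const double eps_y = 0.5 + 1.1920928955078125e-5 * std::sqrt(3.0);

  // bin triangles by x-column ranges
  std::vector<std::vector<int>> cols((size_t)n * n);
  for (int f = 0; f < nf; ++f) {
    double tlo[2] = {R_PosInf, R_PosInf}, thi[2] = {R_NegInf, R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int vi = F(f, c) - 1;
      for (int d = 0; d < 2; ++d) {
        tlo[d] = std::min(tlo[d], V(vi, d));
        thi[d] = std::max(thi[d], V(vi, d));
      }
    }
    int x0 = std::max(0, (int)std::floor((tlo[0] - lo[0]) / hx - eps_x));
    int x1 = std::min(n - 1, (int)std::ceil((thi[0] - lo[0]) / hx - eps_x));
    int y0 = std::max(0, (int)std::floor((tlo[1] - lo[1]) / hy - eps_y));
    int y1 = std::min(n - 1, (int)std::ceil((thi[1] - lo[1]) / hy - eps_y));
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) cols[(size_t)y * n + x].push_back(f);
  }

  long long inside = 0;
  std::vector<double> zs;
  for (int y = 0; y < n; ++y) {
    double cy = lo[1] + (y + eps_y) * hy;
    for (int x = 0; x < n; ++x) {
      auto& tris = cols[(size_t)y * n + x];
      if (tris.empty()) continue;
      double cx = lo[0] + (x + eps_x) * hx;
      zs.clear();
      for (int f : tris) {
        int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
        double ax = V(i0, 0) - cx, ay = V(i0, 1) - cy;
        double bx = V(i1, 0) - cx, by = V(i1, 1) - cy;
        double ccx = V(i2, 0) - cx, ccy = V(i2, 1) - cy;
        // 2D barycentric point-in-triangle for the ray (cx, cy)
        double d1 = ax * by - ay * bx;
        double d2 = bx * ccy - by * ccx;
        double d3 = ccx * ay - ccy * ax;
        bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (has_neg && has_pos) continue;
        double area = d1 + d2 + d3;
        if (area == 0) continue;
        double z = (d2 * V(i0, 2) + d3 * V(i1, 2) + d1 * V(i2, 2)) / area;
        zs.push_back(z);
      }
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      // voxel centres between successive odd-even crossing pairs are inside
      for (size_t j = 0; j + 1 < zs.size(); j += 2) {
        int k0 = (int)std::ceil((zs[j] - lo[2]) / hz - 0.5);
        int k1 = (int)std::floor((zs[j + 1] - lo[2]) / hz - 0.5);
        if (k0 < 0) k0 = 0;
        if (k1 > n - 1) k1 = n - 1;
        if (k1 >= k0) inside += (k1 - k0 + 1);
      }
    }
    if (y % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return (double)inside * hx * hy * hz;
}
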