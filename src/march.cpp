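#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Marching tetrahedra over the g^3 lattice. Each cell is split into the six
// tetrahedra around the main diagonal (c0-c6); the decomposition uses the same
// global diagonal orientation on every shared face, so isosurface vertices on
// shared edges are welded by construction and the extracted surface is
// watertight whenever the level set stays inside the lattice. Triangles are
// wound so that their normals point away from the positive (interior) side.

namespace {

const int TETS[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                        {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
// local corner offsets (x,y,z)
const int CORNER[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                          {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct Key64Hash {
  size_t operator()(uint64_t k) const { return std::hash<uint64_t>()(k); }
};

}  // namespace

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, int g, NumericVector origin,
                    double h) {
  const R_xlen_t sy = g, sz = (R_xlen_t)g * g;
  std::unordered_map<uint64_t, int, Key64Hash> edge_vertex;
  std::vector<double> verts;  // x,y,z triples
  std::vector<int> faces;     // 1-based vertex ids

  // grid-vertex field value with an epsilon push off the level set so no
  // isosurface vertex coincides with a lattice node
  auto fval = [&](R_xlen_t i) -> double {
    double v = field[i];
    return v == 0.0 ? 1e-300 : v;
  };

  auto edge_point = [&](R_xlen_t ga, R_xlen_t gb, double fa, double fb) -> int {
    uint64_t a = (uint64_t)ga, b = (uint64_t)gb;
    if (a > b) std::swap(a, b);
    uint64_t key = a * (uint64_t)g * g * g + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = fa / (fa - fb);
    int ax = (int)(ga % g), ay = (int)((ga / g) % g), az = (int)(ga / sz);
    int bx = (int)(gb % g), by = (int)((gb / g) % g), bz = (int)(gb / sz);
    double px = origin[0] + h * (ax + t * (bx - ax));
    double py = origin[1] + h * (ay + t * (by - ay));
    double pz = origin[2] + h * (az + t * (bz - az));
    int id = (int)(verts.size() / 3) + 1;
    verts.push_back(px);
    verts.push_back(py);
    verts.push_back(pz);
    edge_vertex.emplace(key, id);
    return id;
  };

  // Emit a triangle (v1,v2,v3 are vertex ids); `inward` is a direction that
  // points from the triangle toward the positive (inside) region; the winding
  // is chosen so the face normal opposes it (outward convention).
  auto emit = [&](int v1, int v2, int v3, const double* inward) {
    const double* p1 = &verts[(v1 - 1) * 3];
    const double* p2 = &verts[(v2 - 1) * 3];
    const double* p3 = &verts[(v3 - 1) * 3];
    double u[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double w[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
    double nx = u[1] * w[2] - u[2] * w[1];
    double ny = u[2] * w[0] - u[0] * w[2];
    double nz = u[0] * w[1] - u[1] * w[0];
    double d = nx * inward[0] + ny * inward[1] + nz * inward[2];
    if (d > 0) std::swap(v2, v3);
    faces.push_back(v1);
    faces.push_back(v2);
    faces.push_back(v3);
  };

  R_xlen_t gid[8];
  double fv[8];
  for (int z = 0; z < g - 1; ++z) {
    for (int y = 0; y < g - 1; ++y) {
      for (int x = 0; x < g - 1; ++x) {
        R_xlen_t base = x + (R_xlen_t)y * sy + (R_xlen_t)z * sz;
        bool any_pos = false, any_neg = false;
        for (int c = 0; c < 8; ++c) {
          gid[c] = base + CORNER[c][0] + (R_xlen_t)CORNER[c][1] * sy +
                   (R_xlen_t)CORNER[c][2] * sz;
          fv[c] = fval(gid[c]);
          (fv[c] > 0 ? any_pos : any_neg) = true;
        }
        if (!any_pos || !any_neg) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int pos[4], neg[4], np = 0, nn = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[T[c]] > 0) pos[np++] = T[c];
            else neg[nn++] = T[c];
          }
          if (np == 0 || nn == 0) continue;
          // direction from negative centroid to positive centroid
          double inward[3] = {0, 0, 0};
          for (int c = 0; c < np; ++c)
            for (int d = 0; d < 3; ++d)
              inward[d] += (CORNER[pos[c]][d]) / (double)np;
          for (int c = 0; c < nn; ++c)
            for (int d = 0; d < 3; ++d)
              inward[d] -= (CORNER[neg[c]][d]) / (double)nn;
          if (np == 1 || nn == 1) {
            int apex = (np == 1) ? pos[0] : neg[0];
            int* other = (np == 1) ? neg : pos;
            int v1 = edge_point(gid[apex], gid[other[0]], fv[apex], fv[other[0]]);
            int v2 = edge_point(gid[apex], gid[other[1]], fv[apex], fv[other[1]]);
            int v3 = edge_point(gid[apex], gid[other[2]], fv[apex], fv[other[2]]);
            emit(v1, v2, v3, inward);
          } else {
            // 2-2 split: quad with corners on the four pos-neg edges
            int a0 = pos[0], a1 = pos[1], b0 = neg[0], b1 = neg[1];
            int q1 = edge_point(gid[a0], gid[b0], fv[a0], fv[b0]);
            int q2 = edge_point(gid[a0], gid[b1], fv[a0], fv[b1]);
            int q3 = edge_point(gid[a1], gid[b1], fv[a1], fv[b1]);
            int q4 = edge_point(gid[a1], gid[b0], fv[a1], fv[b0]);
            emit(q1, q2, q3, inward);
            emit(q1, q3, q4, inward);
          }
        }
      }
    }
    if (z % 16 == 0) Rcpp::checkUserInterrupt();
  }

  int nv = (int)(verts.size() / 3);
  int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[i * 3];
    V(i, 1) = verts[i * 3 + 1];
    V(i, 2) = verts[i * 3 + 2];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[i * 3];
    F(i, 1) = faces[i * 3 + 1];
    F(i, 2) = faces[i * 3 + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
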