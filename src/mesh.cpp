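#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra. Each grid cell is split into
// six tetrahedra around the (0,0,0)-(1,1,1) body diagonal; shared cell faces
// receive matching diagonals, so the resulting surface is watertight.
// Vertices lie on tetrahedron edges (linear interpolation) and are welded by
// the global index pair of the edge's end corners, making topology exact.

namespace {

struct Key {
  uint64_t k;
  bool operator==(const Key &o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key &a) const { return std::hash<uint64_t>()(a.k); }
};

// corner offsets, Bourke numbering
static const int CORNER[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
// six tetrahedra sharing diagonal 0-6
static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                               {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

struct Builder {
  const double *val;
  int nx, ny, nz;
  double iso;
  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> verts; // x,y,z triples, voxel units
  std::vector<int> faces;    // 1-based vertex ids, triples

  size_t lin(int x, int y, int z) const {
    return (size_t)z * nx * ny + (size_t)y * nx + x;
  }

  int edge_vertex(size_t ga, size_t gb, const double *pa, const double *pb,
                  double va, double vb) {
    size_t a = ga, b = gb;
    const double *qa = pa, *qb = pb;
    double wa = va, wb = vb;
    if (a > b) {
      std::swap(a, b);
      std::swap(qa, qb);
      std::swap(wa, wb);
    }
    Key key{(uint64_t)a << 32 | (uint64_t)b};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (wb == wa) ? 0.5 : (iso - wa) / (wb - wa);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    int id = (int)(verts.size() / 3) + 1;
    for (int i = 0; i < 3; ++i) verts.push_back(qa[i] + t * (qb[i] - qa[i]));
    vmap.emplace(key, id);
    return id;
  }

  void emit(int a, int b, int c, const double *inside_dir) {
    // orient so the normal points away from the high-valued (interior) side
    const double *A = &verts[(size_t)(a - 1) * 3];
    const double *B = &verts[(size_t)(b - 1) * 3];
    const double *C = &verts[(size_t)(c - 1) * 3];
    double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double v[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    double n[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                   u[0] * v[1] - u[1] * v[0]};
    double dot = n[0] * inside_dir[0] + n[1] * inside_dir[1] +
                 n[2] * inside_dir[2];
    if (dot > 0) std::swap(b, c); // normal must point away from interior
    faces.push_back(a);
    faces.push_back(b);
    faces.push_back(c);
  }

  void do_tet(const size_t g[4], const double p[4][3], const double v[4]) {
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; ++i) {
      in[i] = v[i] >= iso;
      if (in[i]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    // direction from outside centroid toward inside centroid
    double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k)
        (in[i] ? ci[k] : co[k]) += p[i][k];
    for (int k = 0; k < 3; ++k) {
      ci[k] /= nin;
      co[k] /= (4 - nin);
    }
    double dir[3] = {ci[0] - co[0], ci[1] - co[1], ci[2] - co[2]};
    int ins[4], outs[4], ni = 0, no = 0;
    for (int i = 0; i < 4; ++i) (in[i] ? ins[ni++] : outs[no++]) = i;
    if (nin == 1 || nin == 3) {
      int a = (nin == 1) ? ins[0] : outs[0];
      int others[3], m = 0;
      for (int i = 0; i < 4; ++i)
        if (i != a) others[m++] = i;
      int e0 = edge_vertex(g[a], g[others[0]], p[a], p[others[0]], v[a],
                           v[others[0]]);
      int e1 = edge_vertex(g[a], g[others[1]], p[a], p[others[1]], v[a],
                           v[others[1]]);
      int e2 = edge_vertex(g[a], g[others[2]], p[a], p[others[2]], v[a],
                           v[others[2]]);
      emit(e0, e1, e2, dir);
    } else { // 2 in, 2 out: quad on the four crossing edges
      int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
      int eac = edge_vertex(g[a], g[c], p[a], p[c], v[a], v[c]);
      int ead = edge_vertex(g[a], g[d], p[a], p[d], v[a], v[d]);
      int ebc = edge_vertex(g[b], g[c], p[b], p[c], v[b], v[c]);
      int ebd = edge_vertex(g[b], g[d], p[b], p[d], v[b], v[d]);
      emit(eac, ead, ebd, dir);
      emit(eac, ebd, ebc, dir);
    }
  }

  void run() {
    for (int z = 0; z < nz - 1; ++z)
      for (int y = 0; y < ny - 1; ++y)
        for (int x = 0; x < nx - 1; ++x) {
          size_t gl[8];
          double pv[8][3], vv[8];
          double lo = 1e30, hi = -1e30;
          for (int i = 0; i < 8; ++i) {
            int cx = x + CORNER[i][0], cy = y + CORNER[i][1],
                cz = z + CORNER[i][2];
            gl[i] = lin(cx, cy, cz);
            pv[i][0] = cx;
            pv[i][1] = cy;
            pv[i][2] = cz;
            vv[i] = val[gl[i]];
            lo = std::min(lo, vv[i]);
            hi = std::max(hi, vv[i]);
          }
          if (hi < iso || lo >= iso) continue;
          for (int t = 0; t < 6; ++t) {
            size_t g[4];
            double p[4][3], v[4];
            for (int i = 0; i < 4; ++i) {
              int c = TETS[t][i];
              g[i] = gl[c];
              for (int k = 0; k < 3; ++k) p[i][k] = pv[c][k];
              v[i] = vv[c];
            }
            do_tet(g, p, v);
          }
        }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, IntegerVector dims,
                             double iso) {
  Builder b;
  b.val = vol.begin();
  b.nx = dims[0];
  b.ny = dims[1];
  b.nz = dims[2];
  b.iso = iso;
  b.run();
  int nv = (int)(b.verts.size() / 3), nf = (int)(b.faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = b.verts[(size_t)i * 3 + k];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = b.faces[(size_t)i * 3 + k];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
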