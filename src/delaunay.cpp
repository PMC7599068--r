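// 3D Delaunay tessellation via the paraboloid lift: lower facets of the 4D
// convex hull of (x, y, z, x^2+y^2+z^2) are the Delaunay tetrahedra.
// The hull is built with a randomized-order incremental (beneath-beyond)
// algorithm; horizon ridges are found by the ridge-multiplicity trick, so no
// facet adjacency structure is needed. Input is jittered upstream (in R) to
// break exact degeneracies (cospherical / coplanar configurations); the
// jitter only decides combinatorics, all downstream measures are computed
// from the original coordinates.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

namespace {

const int D = 4; // ambient dimension of the lifted points

struct Facet {
  std::array<int, D> v;          // vertex indices
  std::array<double, D> normal;  // outward unit normal
  double offset;                 // normal . x = offset on the hyperplane
  bool alive;
};

double det3(const double m[3][3]) {
  return m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1])
       - m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0])
       + m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
}

// Hyperplane through D points: normal via generalized cross product
// (cofactor expansion) of the D-1 edge vectors; oriented away from `inside`.
bool facet_plane(const std::vector<std::array<double, D> >& pts,
                 Facet& f, const std::array<double, D>& inside) {
  double e[D - 1][D];
  for (int i = 0; i < D - 1; ++i)
    for (int j = 0; j < D; ++j)
      e[i][j] = pts[f.v[i + 1]][j] - pts[f.v[0]][j];
  double m[3][3];
  double norm2 = 0.0;
  for (int j = 0; j < D; ++j) {
    int cc = 0;
    for (int c = 0; c < D; ++c) {
      if (c == j) continue;
      for (int r = 0; r < D - 1; ++r) m[r][cc] = e[r][c];
      ++cc;
    }
    double cof = det3(m);
    f.normal[j] = ((j % 2) == 0) ? cof : -cof;
    norm2 += f.normal[j] * f.normal[j];
  }
  double nrm = std::sqrt(norm2);
  if (nrm <= 0.0 || !std::isfinite(nrm)) return false;
  for (int j = 0; j < D; ++j) f.normal[j] /= nrm;
  f.offset = 0.0;
  for (int j = 0; j < D; ++j) f.offset += f.normal[j] * pts[f.v[0]][j];
  double side = 0.0;
  for (int j = 0; j < D; ++j) side += f.normal[j] * inside[j];
  if (side > f.offset) { // flip so `inside` is on the negative side
    for (int j = 0; j < D; ++j) f.normal[j] = -f.normal[j];
    f.offset = -f.offset;
  }
  f.alive = true;
  return true;
}

double point_plane(const Facet& f, const std::array<double, D>& p) {
  double s = -f.offset;
  for (int j = 0; j < D; ++j) s += f.normal[j] * p[j];
  return s;
}

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix xyz) {
  const int n = xyz.nrow();
  if (xyz.ncol() != 3) stop("coordinate matrix must have 3 columns");
  if (n < 5) stop("at least 5 points are required for a 3D tessellation");

  // lift onto the paraboloid
  std::vector<std::array<double, D> > pts(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    for (int j = 0; j < 3; ++j) {
      pts[i][j] = xyz(i, j);
      q += xyz(i, j) * xyz(i, j);
      scale = std::max(scale, std::fabs(xyz(i, j)));
    }
    pts[i][3] = q;
    scale = std::max(scale, q);
  }
  const double eps = 1e-12 * std::max(1.0, scale);

  // initial simplex: greedily pick D+1 points spanning affine space,
  // maximizing the plane-distance at each step
  std::vector<int> simp;
  simp.push_back(0);
  {
    // farthest from point 0
    int best = -1; double bd = -1.0;
    for (int i = 1; i < n; ++i) {
      double d2 = 0.0;
      for (int j = 0; j < D; ++j) {
        double dd = pts[i][j] - pts[0][j];
        d2 += dd * dd;
      }
      if (d2 > bd) { bd = d2; best = i; }
    }
    if (bd <= eps * eps) stop("degenerate input: points coincide");
    simp.push_back(best);
  }
  // extend via Gram-Schmidt distance to current affine subspace
  std::vector<std::array<double, D> > basis;
  auto residual = [&](int i) {
    std::array<double, D> r;
    for (int j = 0; j < D; ++j) r[j] = pts[i][j] - pts[simp[0]][j];
    for (size_t b = 0; b < basis.size(); ++b) {
      double dot = 0.0;
      for (int j = 0; j < D; ++j) dot += r[j] * basis[b][j];
      for (int j = 0; j < D; ++j) r[j] -= dot * basis[b][j];
    }
    return r;
  };
  {
    std::array<double, D> e1;
    double nrm = 0.0;
    for (int j = 0; j < D; ++j) {
      e1[j] = pts[simp[1]][j] - pts[simp[0]][j];
      nrm += e1[j] * e1[j];
    }
    nrm = std::sqrt(nrm);
    for (int j = 0; j < D; ++j) e1[j] /= nrm;
    basis.push_back(e1);
  }
  while ((int)simp.size() < D + 1) {
    int best = -1; double bd = -1.0;
    std::array<double, D> bres{};
    for (int i = 0; i < n; ++i) {
      bool used = false;
      for (int s : simp) if (s == i) { used = true; break; }
      if (used) continue;
      std::array<double, D> r = residual(i);
      double d2 = 0.0;
      for (int j = 0; j < D; ++j) d2 += r[j] * r[j];
      if (d2 > bd) { bd = d2; best = i; bres = r; }
    }
    if (best < 0 || bd <= eps * eps)
      stop("degenerate input: points are affinely dependent after lifting "
           "(coplanar or cospherical configuration)");
    double nrm = std::sqrt(bd);
    for (int j = 0; j < D; ++j) bres[j] /= nrm;
    basis.push_back(bres);
    simp.push_back(best);
  }

  std::array<double, D> inside{};
  for (int s : simp)
    for (int j = 0; j < D; ++j) inside[j] += pts[s][j] / (D + 1);

  std::vector<Facet> facets;
  for (int omit = 0; omit < D + 1; ++omit) {
    Facet f;
    int k = 0;
    for (int i = 0; i < D + 1; ++i)
      if (i != omit) f.v[k++] = simp[i];
    if (!facet_plane(pts, f, inside)) stop("degenerate initial simplex");
    facets.push_back(f);
  }

  // incremental insertion
  std::vector<bool> done(n, false);
  for (int s : simp) done[s] = true;
  for (int p = 0; p < n; ++p) {
    if (done[p]) continue;
    // visible facets
    std::vector<int> vis;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!facets[f].alive) continue;
      if (point_plane(facets[f], pts[p]) > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue; // inside current hull
    // ridge multiplicity among visible facets: count 1 => horizon ridge
    std::map<std::array<int, D - 1>, int> ridges;
    for (int fi : vis) {
      const Facet& f = facets[fi];
      for (int omit = 0; omit < D; ++omit) {
        std::array<int, D - 1> r;
        int k = 0;
        for (int i = 0; i < D; ++i)
          if (i != omit) r[k++] = f.v[i];
        std::sort(r.begin(), r.end());
        ridges[r] += 1;
      }
    }
    for (int fi : vis) facets[fi].alive = false;
    for (std::map<std::array<int, D - 1>, int>::const_iterator it = ridges.begin();
         it != ridges.end(); ++it) {
      if (it->second != 1) continue;
      Facet f;
      for (int i = 0; i < D - 1; ++i) f.v[i] = it->first[i];
      f.v[D - 1] = p;
      if (!facet_plane(pts, f, inside))
        stop("degenerate facet encountered; increase jitter");
      facets.push_back(f);
    }
    // periodically compact the facet list
    if (facets.size() > 4096) {
      std::vector<Facet> keep;
      keep.reserve(facets.size());
      for (size_t f = 0; f < facets.size(); ++f)
        if (facets[f].alive) keep.push_back(facets[f]);
      facets.swap(keep);
    }
  }

  // lower facets (normal pointing down in the lifted coordinate) are the
  // Delaunay tetrahedra
  std::vector<std::array<int, D> > tets;
  for (size_t f = 0; f < facets.size(); ++f) {
    if (!facets[f].alive) continue;
    if (facets[f].normal[3] < -1e-9) tets.push_back(facets[f].v);
  }
  IntegerMatrix out((int)tets.size(), 4);
  for (size_t t = 0; t < tets.size(); ++t)
    for (int j = 0; j < 4; ++j)
      out((int)t, j) = tets[t][j] + 1; // 1-based for R
  return out;
}
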