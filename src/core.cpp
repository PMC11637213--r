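// Numerical core: nearest-neighbour search, normal estimation, NL-means,
// isosurface extraction (marching tetrahedra), Laplacian smoothing,
// 3-D labelling, MLS quadric patches + point-to-surface correspondence
// search, and the CPD E-step. All heavy per-point loops live here; the R
// layer owns the algorithms' control flow.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// kNN (brute force, deterministic tie-break: smaller index wins)
// ---------------------------------------------------------------------------

static inline double sqdist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// target: n x 3, query: m x 3, returns m x k matrix of 1-based indices
// ordered by ascending distance, ties broken by lower index.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(const arma::mat& target, const arma::mat& query, int k) {
  const int n = target.n_rows, m = query.n_rows;
  if (k < 1 || k > n) stop("k must be between 1 and the number of target points");
  arma::mat tt = target.t();  // 3 x n, column access
  arma::mat qq = query.t();
  IntegerMatrix out(m, k);
  std::vector<std::pair<double, int> > d(n);
  for (int j = 0; j < m; ++j) {
    const double* q = qq.colptr(j);
    for (int i = 0; i < n; ++i) d[i] = std::make_pair(sqdist3(tt.colptr(i), q), i);
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int i = 0; i < k; ++i) out(j, i) = d[i].second + 1;
  }
  return out;
}

// nearest neighbour only: returns list(index (1-based), dist)
// [[Rcpp::export]]
List cpp_nn1(const arma::mat& target, const arma::mat& query) {
  const int n = target.n_rows, m = query.n_rows;
  arma::mat tt = target.t(), qq = query.t();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int j = 0; j < m; ++j) {
    const double* q = qq.colptr(j);
    double best = R_PosInf; int bi = 0;
    for (int i = 0; i < n; ++i) {
      double d = sqdist3(tt.colptr(i), q);
      if (d < best) { best = d; bi = i; }
    }
    idx[j] = bi + 1;
    dist[j] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Normal estimation: smallest-eigenvalue eigenvector of the k-neighbourhood
// covariance (neighbourhood = the point plus its k nearest neighbours).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_estimate_normals(const arma::mat& pts, int k) {
  const int n = pts.n_rows;
  arma::mat tt = pts.t();
  arma::mat normals(n, 3);
  std::vector<int> degen;
  std::vector<std::pair<double, int> > d(n);
  arma::vec ctr = arma::vec(arma::mean(pts, 0).t());
  for (int j = 0; j < n; ++j) {
    const double* q = tt.colptr(j);
    for (int i = 0; i < n; ++i) d[i] = std::make_pair(sqdist3(tt.colptr(i), q), i);
    std::partial_sort(d.begin(), d.begin() + k + 1, d.end());
    arma::mat nb(k + 1, 3);
    for (int i = 0; i <= k; ++i) nb.row(i) = pts.row(d[i].second);
    arma::rowvec mu = arma::mean(nb, 0);
    nb.each_row() -= mu;
    arma::mat C = nb.t() * nb / (k + 1);
    double tr = arma::trace(C);
    if (tr < 1e-18) { degen.push_back(j + 1); normals.row(j).zeros(); continue; }
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, C);
    arma::vec nrm = evec.col(0);  // smallest eigenvalue
    // orient away from the cloud centroid
    arma::vec p(3); p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    if (arma::dot(nrm, p - ctr) < 0) nrm = -nrm;
    normals.row(j) = nrm.t();
  }
  return List::create(_["normals"] = normals, _["degenerate"] = wrap(degen));
}

// ---------------------------------------------------------------------------
// NL-means on one slice. block = patch radius, window = full odd width of
// the search window, decay = Gaussian bandwidth h on the intensity scale.
// ---------------------------------------------------------------------------

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
arma::mat cpp_nlmeans(const arma::mat& img, int block, int window, double decay) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int sr = (window - 1) / 2;     // search radius
  const int pr = block;                // patch radius
  const double h2 = decay * decay;
  const int np = (2 * pr + 1) * (2 * pr + 1);
  arma::mat out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double wsum = 0.0, vsum = 0.0;
      for (int dj = -sr; dj <= sr; ++dj) {
        for (int di = -sr; di <= sr; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          // mean squared patch difference with clamped borders
          double d2 = 0.0;
          for (int pj = -pr; pj <= pr; ++pj) {
            for (int pi = -pr; pi <= pr; ++pi) {
              double a = img(clampi(i + pi, 0, nr - 1), clampi(j + pj, 0, nc - 1));
              double b = img(clampi(ii + pi, 0, nr - 1), clampi(jj + pj, 0, nc - 1));
              double dd = a - b;
              d2 += dd * dd;
            }
          }
          d2 /= np;
          double w = std::exp(-d2 / h2);
          wsum += w;
          vsum += w * img(ii, jj);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over a 3-D scalar grid (column-major, dims nx,ny,nz).
// Each cube is split into 6 tetrahedra sharing the 0-6 diagonal. Vertices
// are interpolated on edges and deduplicated; coordinates are in voxel
// index units (scaled by spacing in R).
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> verts;  // x,y,z triples
  std::vector<int> faces;     // 1-based triples
};

// decode helper
static inline void decode(long g, int nx, int ny, int& i, int& j, int& k) {
  i = (int)(g % nx);
  j = (int)((g / nx) % ny);
  k = (int)(g / ((long)nx * ny));
}

static int mt_edge_vertex(MTState& st, int nx, int ny,
                          long ga, long gb, double va, double vb, double iso) {
  long lo = std::min(ga, gb), hi = std::max(ga, gb);
  if (lo == ga) { /* keep va,vb */ } else { std::swap(va, vb); }
  uint64_t key = ((uint64_t)lo << 32) | (uint64_t)hi;
  std::unordered_map<uint64_t, int>::iterator it = st.edge_map.find(key);
  if (it != st.edge_map.end()) return it->second;
  double t = (iso - va) / (vb - va);
  int i0, j0, k0, i1, j1, k1;
  decode(lo, nx, ny, i0, j0, k0);
  decode(hi, nx, ny, i1, j1, k1);
  st.verts.push_back(i0 + t * (i1 - i0));
  st.verts.push_back(j0 + t * (j1 - j0));
  st.verts.push_back(k0 + t * (k1 - k0));
  int id = (int)(st.verts.size() / 3);  // 1-based
  st.edge_map[key] = id;
  return id;
}

// [[Rcpp::export]]
List cpp_march_tets(const NumericVector& vol, const IntegerVector& dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);
  MTState st;
  // corner offsets of the unit cube
  const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  // 6 tetrahedra sharing diagonal 0-6
  const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
  };
  long cg[8]; double cv[8];
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          long g = (long)(i + co[c][0]) + (long)nx * (j + co[c][1]) +
                   (long)nx * ny * (k + co[c][2]);
          cg[c] = g;
          cv[c] = v[g];
        }
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c2 = tets[t][2], d = tets[t][3];
          int idxs[4] = {a, b, c2, d};
          bool in[4];
          int cnt = 0;
          for (int q = 0; q < 4; ++q) { in[q] = cv[idxs[q]] > iso; if (in[q]) ++cnt; }
          if (cnt == 0 || cnt == 4) continue;
          if (cnt == 1 || cnt == 3) {
            // single vertex on one side: one triangle
            bool want = (cnt == 1);
            int solo = -1;
            for (int q = 0; q < 4; ++q) if (in[q] == want) solo = q;
            int others[3]; int oi = 0;
            for (int q = 0; q < 4; ++q) if (q != solo) others[oi++] = q;
            int va_ = idxs[solo];
            int p0 = mt_edge_vertex(st, nx, ny, cg[va_], cg[idxs[others[0]]], cv[va_], cv[idxs[others[0]]], iso);
            int p1 = mt_edge_vertex(st, nx, ny, cg[va_], cg[idxs[others[1]]], cv[va_], cv[idxs[others[1]]], iso);
            int p2 = mt_edge_vertex(st, nx, ny, cg[va_], cg[idxs[others[2]]], cv[va_], cv[idxs[others[2]]], iso);
            if (p0 != p1 && p1 != p2 && p0 != p2) {
              st.faces.push_back(p0); st.faces.push_back(p1); st.faces.push_back(p2);
            }
          } else {
            // 2-2 split: quad -> two triangles
            int ins[2], outs[2]; int ii_ = 0, oo = 0;
            for (int q = 0; q < 4; ++q) { if (in[q]) ins[ii_++] = q; else outs[oo++] = q; }
            int A = idxs[ins[0]], B = idxs[ins[1]], C = idxs[outs[0]], D = idxs[outs[1]];
            int p0 = mt_edge_vertex(st, nx, ny, cg[A], cg[C], cv[A], cv[C], iso);
            int p1 = mt_edge_vertex(st, nx, ny, cg[A], cg[D], cv[A], cv[D], iso);
            int p2 = mt_edge_vertex(st, nx, ny, cg[B], cg[D], cv[B], cv[D], iso);
            int p3 = mt_edge_vertex(st, nx, ny, cg[B], cg[C], cv[B], cv[C], iso);
            if (p0 != p1 && p1 != p2 && p0 != p2) {
              st.faces.push_back(p0); st.faces.push_back(p1); st.faces.push_back(p2);
            }
            if (p0 != p2 && p2 != p3 && p0 != p3) {
              st.faces.push_back(p0); st.faces.push_back(p2); st.faces.push_back(p3);
            }
          }
        }
      }
    }
  }
  int nv = (int)(st.verts.size() / 3), nf = (int)(st.faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; ++q) {
    V(q, 0) = st.verts[3 * q];
    V(q, 1) = st.verts[3 * q + 1];
    V(q, 2) = st.verts[3 * q + 2];
  }
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nf; ++q) {
    F(q, 0) = st.faces[3 * q];
    F(q, 1) = st.faces[3 * q + 1];
    F(q, 2) = st.faces[3 * q + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Uniform Laplacian smoothing of a triangle mesh.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_laplacian_smooth(const arma::mat& verts, const IntegerMatrix& faces,
                               int iters, double lambda) {
  const int nv = verts.n_rows, nf = faces.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  arma::mat V = verts;
  for (int it = 0; it < iters; ++it) {
    arma::mat W = V;
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) continue;
      arma::rowvec m(3, arma::fill::zeros);
      for (size_t q = 0; q < adj[i].size(); ++q) m += V.row(adj[i][q]);
      m /= (double)adj[i].size();
      W.row(i) = V.row(i) + lambda * (m - V.row(i));
    }
    V = W;
  }
  return V;
}

// ---------------------------------------------------------------------------
// 3-D connected components (6-connectivity) and outside flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int* m = LOGICAL(mask);
  int cur = 0;
  std::vector<long> stack;
  const long off[6] = {1, -1, (long)nx, -(long)nx, (long)nx * ny, -(long)nx * ny};
  for (long s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long g = stack.back(); stack.pop_back();
      int i = (int)(g % nx), j = (int)((g / nx) % ny), k = (int)(g / ((long)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i, jj = j, kk = k;
        if (d == 0) ++ii; else if (d == 1) --ii;
        else if (d == 2) ++jj; else if (d == 3) --jj;
        else if (d == 4) ++kk; else --kk;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        long g2 = g + off[d];
        if (m[g2] && !lab[g2]) { lab[g2] = cur; stack.push_back(g2); }
      }
    }
  }
  return lab;
}

// reachable-from-border through !blocked (6-connectivity)
// [[Rcpp::export]]
LogicalVector cpp_outside_fill(const LogicalVector& blocked, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  LogicalVector reach(n, false);
  const int* b = LOGICAL(blocked);
  std::vector<long> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1) continue;
        long g = (long)i + (long)nx * j + (long)nx * ny * k;
        if (!b[g] && !reach[g]) { reach[g] = true; stack.push_back(g); }
      }
  const long off[6] = {1, -1, (long)nx, -(long)nx, (long)nx * ny, -(long)nx * ny};
  while (!stack.empty()) {
    long g = stack.back(); stack.pop_back();
    int i = (int)(g % nx), j = (int)((g / nx) % ny), k = (int)(g / ((long)nx * ny));
    for (int d = 0; d < 6; ++d) {
      int ii = i, jj = j, kk = k;
      if (d == 0) ++ii; else if (d == 1) --ii;
      else if (d == 2) ++jj; else if (d == 3) --jj;
      else if (d == 4) ++kk; else --kk;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      long g2 = g + off[d];
      if (!b[g2] && !reach[g2]) { reach[g2] = true; stack.push_back(g2); }
    }
  }
  return reach;
}

// ---------------------------------------------------------------------------
// MLS quadric patch: local tangent frame from neighbourhood PCA, weighted
// least-squares fit of z' = a0 + a1 x' + a2 y' + a3 x'^2 + a4 x'y' + a5 y'^2
// with Gaussian weights exp(-(d/h)^2), h = r_fit / 2.
// ---------------------------------------------------------------------------

struct PatchFit {
  bool ok;
  arma::vec coeffs;   // 6
  arma::vec origin;   // 3
  arma::mat axes;     // 3x3, rows = x', y', z' axes
  std::vector<int> nb; // 0-based neighbour indices
};

static PatchFit fit_patch_impl(const arma::mat& tt /*3 x n*/, int center0,
                               int kc, double r_fit) {
  PatchFit out; out.ok = false;
  const int n = tt.n_cols;
  int m = std::min(kc, n);
  std::vector<std::pair<double, int> > d(n);
  const double* q = tt.colptr(center0);
  for (int i = 0; i < n; ++i) d[i] = std::make_pair(sqdist3(tt.colptr(i), q), i);
  std::partial_sort(d.begin(), d.begin() + m, d.end());
  if (m < 6) return out;
  arma::mat nb(m, 3);
  arma::vec w(m);
  // a fitting radius below half the local point spacing (the distance to
  // the nearest neighbour) selects no usable neighbourhood: the patch
  // degrades to point-point matching
  double d1 = std::sqrt(d[1].first);
  if (r_fit < 0.5 * d1) return out;
  double dmed = std::sqrt(d[m / 2].first);
  // Gaussian bandwidth: r/2, floored at the neighbourhood's median
  // spacing so the weighted fit keeps enough effective support on sparse
  // clouds instead of collapsing onto the centre point
  double h = r_fit / 2.0;
  if (h < dmed) h = dmed;
  if (h <= 0) h = 1e-12;
  for (int i = 0; i < m; ++i) {
    nb.row(i) = arma::rowvec(tt.col(d[i].second).t());
    double dd = std::sqrt(d[i].first) / h;
    w[i] = std::exp(-dd * dd) + 1e-12;
    out.nb.push_back(d[i].second);
  }
  // frame from neighbourhood PCA
  arma::rowvec mu = arma::mean(nb, 0);
  arma::mat cc = nb;
  cc.each_row() -= mu;
  arma::mat C = cc.t() * cc / m;
  if (arma::trace(C) < 1e-18) return out;
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, C);  // ascending
  arma::vec az = evec.col(0), ax = evec.col(2), ay = evec.col(1);
  // deterministic signs: largest-|component| entry positive
  arma::vec* axs[3] = {&ax, &ay, &az};
  for (int a = 0; a < 3; ++a) {
    arma::uword im;
    arma::abs(*axs[a]).max(im);
    if ((*axs[a])[im] < 0) *axs[a] = -*axs[a];
  }
  // right-handed: fix via the y axis so the canonical z sign survives
  if (arma::dot(arma::cross(ax, ay), az) < 0) ay = -ay;
  arma::vec origin(3);
  origin[0] = q[0]; origin[1] = q[1]; origin[2] = q[2];
  // local coordinates
  arma::mat A(m, 6);
  arma::vec z(m);
  for (int i = 0; i < m; ++i) {
    arma::vec p = nb.row(i).t() - origin;
    double lx = arma::dot(p, ax), ly = arma::dot(p, ay), lz = arma::dot(p, az);
    A(i, 0) = 1.0; A(i, 1) = lx; A(i, 2) = ly;
    A(i, 3) = lx * lx; A(i, 4) = lx * ly; A(i, 5) = ly * ly;
    z[i] = lz;
  }
  arma::mat Aw = A;
  Aw.each_col() %= w;
  arma::mat AtWA = A.t() * Aw;
  arma::vec AtWz = A.t() * (w % z);
  // Tikhonov ridge: when the Gaussian weights support fewer than six
  // effective neighbours the quadric shrinks to the tangent plane at the
  // centre instead of blowing up
  double lam = 1e-7 * arma::trace(AtWA) + 1e-300;
  AtWA.diag() += lam;
  arma::vec coef;
  if (!arma::solve(coef, AtWA, AtWz, arma::solve_opts::likely_sympd))
    return out;
  out.ok = true;
  out.coeffs = coef;
  out.origin = origin;
  out.axes = arma::join_rows(ax, arma::join_rows(ay, az)).t();  // rows
  return out;
}

// [[Rcpp::export]]
List cpp_fit_patch(const arma::mat& pts, int center1, int kc, double r_fit) {
  arma::mat tt = pts.t();
  PatchFit f = fit_patch_impl(tt, center1 - 1, kc, r_fit);
  IntegerVector nb(f.nb.size());
  for (size_t i = 0; i < f.nb.size(); ++i) nb[i] = f.nb[i] + 1;
  if (!f.ok)
    return List::create(_["ok"] = false, _["neighbors"] = nb);
  return List::create(_["ok"] = true,
                      _["coeffs"] = f.coeffs,
                      _["origin"] = f.origin,
                      _["axes"] = f.axes,
                      _["neighbors"] = nb);
}

// grid samples of the quadric over the tangent-plane disk of radius r_s,
// spacing d_s; always includes the centre node (0,0).
// [[Rcpp::export]]
arma::mat cpp_patch_samples(const arma::vec& coeffs, const arma::vec& origin,
                            const arma::mat& axes, double r_s, double d_s) {
  int g = (d_s > 0) ? (int)std::floor(r_s / d_s + 1e-12) : 0;
  std::vector<double> buf;
  arma::vec ax = axes.row(0).t(), ay = axes.row(1).t(), az = axes.row(2).t();
  for (int gy = -g; gy <= g; ++gy) {
    for (int gx = -g; gx <= g; ++gx) {
      double x = gx * d_s, y = gy * d_s;
      if (x * x + y * y > r_s * r_s + 1e-12) continue;
      double z = coeffs[0] + coeffs[1] * x + coeffs[2] * y +
                 coeffs[3] * x * x + coeffs[4] * x * y + coeffs[5] * y * y;
      arma::vec p = origin + x * ax + y * ay + z * az;
      buf.push_back(p[0]); buf.push_back(p[1]); buf.push_back(p[2]);
    }
  }
  int ns = (int)(buf.size() / 3);
  arma::mat S(ns, 3);
  for (int i = 0; i < ns; ++i) {
    S(i, 0) = buf[3 * i]; S(i, 1) = buf[3 * i + 1]; S(i, 2) = buf[3 * i + 2];
  }
  return S;
}

// ---------------------------------------------------------------------------
// Batch point-to-surface correspondence search with per-centre patch caching.
// eligible[i] = the i-th target point sits in the k_y-neighbourhood of a
// mapping point; such centres get an MLS patch, the rest match point-point.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_match_correspondences(const arma::mat& target, const arma::mat& queries,
                               const LogicalVector& eligible, int kc,
                               double r_fit, double r_s, double d_s) {
  const int n = target.n_rows, m = queries.n_rows;
  arma::mat tt = target.t(), qq = queries.t();
  arma::mat matched(m, 3);
  IntegerVector flag(m), nn_index(m);
  std::vector<int> cached(n, 0);  // 0 unknown, 1 ok, -1 fallback
  std::vector<PatchFit> patches(n);
  int g = (d_s > 0) ? (int)std::floor(r_s / d_s + 1e-12) : 0;
  for (int j = 0; j < m; ++j) {
    const double* q = qq.colptr(j);
    double best = R_PosInf; int bi = 0;
    for (int i = 0; i < n; ++i) {
      double d = sqdist3(tt.colptr(i), q);
      if (d < best) { best = d; bi = i; }
    }
    nn_index[j] = bi + 1;
    double d_nn = std::sqrt(best);
    bool surf = false;
    if (eligible[bi]) {
      if (cached[bi] == 0) {
        patches[bi] = fit_patch_impl(tt, bi, kc, r_fit);
        cached[bi] = patches[bi].ok ? 1 : -1;
      }
      if (cached[bi] == 1 && g >= 1 && d_nn > 1e-9) {
        // an exact point match needs no patch; otherwise samples within
        // d_nn + d_s may improve the correspondence tangentially
        // a single-sample grid (g = 0) carries no surface information:
        // the matching then degenerates to point-point
        const PatchFit& pf = patches[bi];
        arma::vec ax = pf.axes.row(0).t(), ay = pf.axes.row(1).t(), az = pf.axes.row(2).t();
        arma::vec yv(3); yv[0] = q[0]; yv[1] = q[1]; yv[2] = q[2];
        double bestd = R_PosInf;
        arma::vec bestp(3);
        for (int gy = -g; gy <= g; ++gy) {
          for (int gx = -g; gx <= g; ++gx) {
            double x = gx * d_s, y = gy * d_s;
            if (x * x + y * y > r_s * r_s + 1e-12) continue;
            double z = pf.coeffs[0] + pf.coeffs[1] * x + pf.coeffs[2] * y +
                       pf.coeffs[3] * x * x + pf.coeffs[4] * x * y + pf.coeffs[5] * y * y;
            arma::vec p = pf.origin + x * ax + y * ay + z * az;
            double dd = arma::dot(p - yv, p - yv);
            if (dd < bestd) { bestd = dd; bestp = p; }
          }
        }
        if (std::isfinite(bestd) && std::sqrt(bestd) <= d_nn + d_s) {
          matched(j, 0) = bestp[0]; matched(j, 1) = bestp[1]; matched(j, 2) = bestp[2];
          surf = true;
        }
      }
    }
    if (!surf) {
      matched(j, 0) = tt(0, bi); matched(j, 1) = tt(1, bi); matched(j, 2) = tt(2, bi);
    }
    flag[j] = surf ? 1 : 0;
  }
  return List::create(_["matched"] = matched, _["flag"] = flag,
                      _["nn_index"] = nn_index);
}

// ---------------------------------------------------------------------------
// CPD E-step: posteriors of the Gaussian mixture with a uniform outlier
// component. X = target (N x 3), Y = transformed source (M x 3).
// Returns Pt1 (N), P1 (M), PX (M x 3) and the negative log-likelihood.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cpd_estep(const arma::mat& X, const arma::mat& Y, double sigma2, double w) {
  const int N = X.n_rows, M = Y.n_rows;
  arma::mat xt = X.t(), yt = Y.t();
  arma::vec Pt1(N, arma::fill::zeros), P1(M, arma::fill::zeros);
  arma::mat PX(M, 3, arma::fill::zeros);
  const double c = (w / (1.0 - w)) * (double)M / (double)N *
                   std::pow(2.0 * M_PI * sigma2, 1.5);
  double nll = 0.0;
  std::vector<double> pm(M);
  for (int nI = 0; nI < N; ++nI) {
    const double* x = xt.colptr(nI);
    double s = c;
    for (int mI = 0; mI < M; ++mI) {
      double d = sqdist3(yt.colptr(mI), x);
      pm[mI] = std::exp(-d / (2.0 * sigma2));
      s += pm[mI];
    }
    if (s <= 0) s = std::numeric_limits<double>::min();
    nll -= std::log(s) - 1.5 * std::log(2.0 * M_PI * sigma2) - std::log((double)M / (1.0 - w));
    double pt1 = (s - c) / s;
    Pt1[nI] = pt1;
    for (int mI = 0; mI < M; ++mI) {
      double p = pm[mI] / s;
      if (p > 0) {
        P1[mI] += p;
        PX(mI, 0) += p * x[0];
        PX(mI, 1) += p * x[1];
        PX(mI, 2) += p * x[2];
      }
    }
  }
  return List::create(_["Pt1"] = Pt1, _["P1"] = P1, _["PX"] = PX, _["nll"] = nll);
}
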