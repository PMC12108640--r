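// Compiled kernels: iso-surface extraction (marching tetrahedra),
// 3D connected components, per-vertex curvature via local quadric fit,
// exact kd-tree k-nearest-neighbour search, and a z-buffer rasterizer
// used by the synthetic-frame renderer.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- marching
// Cube corner offsets and a 6-tetrahedron decomposition sharing the 0-6
// diagonal; consistent across neighbouring cubes, so the surface is
// watertight by construction.
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
static const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

struct EdgeKey {
  uint64_t k;
  bool operator==(const EdgeKey& o) const { return k == o.k; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& e) const { return std::hash<uint64_t>()(e.k); }
};

// [[Rcpp::export]]
List cn_marching_tetrahedra(NumericVector vol, double iso,
                            NumericVector spacing, NumericVector origin) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double* v = vol.begin();
  auto lin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  std::unordered_map<EdgeKey, int, EdgeHash> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F0, F1, F2;

  double cx[8], cy[8], cz[8], cv[8];
  int64_t cl[8];

  auto edge_point = [&](int a, int b) -> int {
    int64_t la = cl[a], lb = cl[b];
    if (la > lb) std::swap(la, lb);
    EdgeKey key{(uint64_t)la * 2000000011ULL + (uint64_t)lb};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = cv[a], vb = cv[b];
    double t = (vb != va) ? (iso - va) / (vb - va) : 0.5;
    if (t < 1e-9) t = 1e-9;
    if (t > 1.0 - 1e-9) t = 1.0 - 1e-9;
    // interpolate in original (a,b) order regardless of key order
    VX.push_back(cx[a] + t * (cx[b] - cx[a]));
    VY.push_back(cy[a] + t * (cy[b] - cy[a]));
    VZ.push_back(cz[a] + t * (cz[b] - cz[a]));
    int id = (int)VX.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  auto emit = [&](int e0a, int e0b, int e1a, int e1b, int e2a, int e2b,
                  double gx_in, double gy_in, double gz_in) {
    int p0 = edge_point(e0a, e0b);
    int p1 = edge_point(e1a, e1b);
    int p2 = edge_point(e2a, e2b);
    if (p0 == p1 || p1 == p2 || p0 == p2) return;
    // orient so the normal points away from the inside centroid
    double ax = VX[p1] - VX[p0], ay = VY[p1] - VY[p0], az = VZ[p1] - VZ[p0];
    double bx = VX[p2] - VX[p0], by = VY[p2] - VY[p0], bz = VZ[p2] - VZ[p0];
    double nxn = ay * bz - az * by, nyn = az * bx - ax * bz, nzn = ax * by - ay * bx;
    double mx = (VX[p0] + VX[p1] + VX[p2]) / 3.0 - gx_in;
    double my = (VY[p0] + VY[p1] + VY[p2]) / 3.0 - gy_in;
    double mz = (VZ[p0] + VZ[p1] + VZ[p2]) / 3.0 - gz_in;
    if (nxn * mx + nyn * my + nzn * mz < 0) std::swap(p1, p2);
    F0.push_back(p0); F1.push_back(p1); F2.push_back(p2);
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
          cl[c] = lin(ii, jj, kk);
          cv[c] = v[cl[c]];
          cx[c] = ox + ii * sx; cy[c] = oy + jj * sy; cz[c] = oz + kk * sz;
          if (cv[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] >= iso) in[nin++] = T[c]; else out[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double gx = 0, gy = 0, gz = 0;
          for (int c = 0; c < nin; ++c) { gx += cx[in[c]]; gy += cy[in[c]]; gz += cz[in[c]]; }
          gx /= nin; gy /= nin; gz /= nin;
          if (nin == 1) {
            emit(in[0], out[0], in[0], out[1], in[0], out[2], gx, gy, gz);
          } else if (nin == 3) {
            emit(in[0], out[0], in[1], out[0], in[2], out[0], gx, gy, gz);
          } else { // 2 in, 2 out -> quad split into two triangles
            emit(in[0], out[0], in[0], out[1], in[1], out[0], gx, gy, gz);
            emit(in[1], out[0], in[0], out[1], in[1], out[1], gx, gy, gz);
          }
        }
      }

  int nV = (int)VX.size(), nF = (int)F0.size();
  NumericMatrix V(nV, 3);
  for (int i = 0; i < nV; ++i) { V(i,0) = VX[i]; V(i,1) = VY[i]; V(i,2) = VZ[i]; }
  IntegerMatrix Fm(nF, 3);
  for (int i = 0; i < nF; ++i) { Fm(i,0) = F0[i] + 1; Fm(i,1) = F1[i] + 1; Fm(i,2) = F2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ------------------------------------------------------- connected components
// 6-connected labelling; returns the component id (1-based) per voxel,
// 0 for background, ordered so component 1 is the largest.
// [[Rcpp::export]]
IntegerVector cn_label_components(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dim;
  const int* m = LOGICAL(mask);
  std::vector<int64_t> stack;
  std::vector<int64_t> sizes;
  int cur = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s] != 0) continue;
    ++cur;
    int64_t size = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int64_t p = stack.back(); stack.pop_back();
      ++size;
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / ((int64_t)nx * ny));
      const int di[6] = {-1,1,0,0,0,0}, dj[6] = {0,0,-1,1,0,0}, dk[6] = {0,0,0,0,-1,1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int64_t pp = (int64_t)ii + (int64_t)nx * ((int64_t)jj + (int64_t)ny * kk);
        if (m[pp] && lab[pp] == 0) { lab[pp] = cur; stack.push_back(pp); }
      }
    }
    sizes.push_back(size);
  }
  if (cur > 1) {
    // relabel so that 1 = largest
    std::vector<int> order(cur);
    for (int i = 0; i < cur; ++i) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> newlab(cur + 1, 0);
    for (int r = 0; r < cur; ++r) newlab[order[r] + 1] = r + 1;
    for (int64_t s = 0; s < n; ++s) if (lab[s]) lab[s] = newlab[lab[s]];
  }
  return lab;
}

// ----------------------------------------------------------------- curvature
// Per-vertex principal curvatures from a quadric height field fitted over a
// neighbourhood grown ring-by-ring until it reaches `radius` (mm) from the
// vertex (at least the one-ring, extended while fewer than `min_nb`
// neighbours), expressed in the vertex tangent frame; the shape operator is
// I^-1 II. Returns n x 7: k1, k2, K, dir(x,y,z) of k1's direction, n_used.
// [[Rcpp::export]]
arma::mat cn_vertex_curvature(const arma::mat& V, const arma::imat& F, int min_nb,
                              double radius) {
  const int n = V.n_rows, m = F.n_rows;
  std::vector<std::vector<int>> adj(n);
  arma::mat vnorm(n, 3, arma::fill::zeros);
  auto add_edge = [&](int a, int b) {
    for (int x : adj[a]) if (x == b) return;
    adj[a].push_back(b);
  };
  for (int f = 0; f < m; ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    add_edge(a,b); add_edge(b,a); add_edge(b,c); add_edge(c,b); add_edge(a,c); add_edge(c,a);
    arma::rowvec e1 = V.row(b) - V.row(a), e2 = V.row(c) - V.row(a);
    arma::rowvec fn = arma::cross(e1, e2); // area-weighted
    vnorm.row(a) += fn; vnorm.row(b) += fn; vnorm.row(c) += fn;
  }
  arma::mat out(n, 7, arma::fill::value(arma::datum::nan));
  for (int i = 0; i < n; ++i) {
    if (adj[i].empty()) continue;
    double nn = arma::norm(vnorm.row(i));
    if (nn < 1e-300) continue;
    arma::rowvec nv = vnorm.row(i) / nn;
    // gather neighbours by ring expansion within the metric radius
    std::vector<int> nb;
    std::vector<char> seen(n, 0);
    seen[i] = 1;
    std::vector<int> frontier = adj[i];
    for (int x : frontier) seen[x] = 1;
    nb = frontier;
    while (true) {
      bool expand = (int)nb.size() < min_nb;
      if (!expand && radius > 0) {
        for (int x : frontier) {
          if (arma::norm(V.row(x) - V.row(i)) < radius) { expand = true; break; }
        }
      }
      if (!expand || frontier.empty()) break;
      std::vector<int> next;
      for (int j : frontier)
        for (int k : adj[j])
          if (!seen[k]) {
            seen[k] = 1;
            if (radius <= 0 || arma::norm(V.row(k) - V.row(i)) <= radius ||
                (int)nb.size() + (int)next.size() < min_nb)
              next.push_back(k);
          }
      if (next.empty()) break;
      nb.insert(nb.end(), next.begin(), next.end());
      frontier = next;
    }
    int nn2 = (int)nb.size();
    if (nn2 < 5) continue;
    // tangent frame
    arma::rowvec a1 = std::abs(nv(0)) < 0.9 ? arma::rowvec{1,0,0} : arma::rowvec{0,1,0};
    arma::rowvec e1 = a1 - arma::dot(a1, nv) * nv;
    e1 /= arma::norm(e1);
    arma::rowvec e2 = arma::cross(nv, e1);
    arma::mat X(nn2, 5);
    arma::vec h(nn2);
    for (int q = 0; q < nn2; ++q) {
      arma::rowvec d = V.row(nb[q]) - V.row(i);
      double u = arma::dot(d, e1), w = arma::dot(d, e2);
      X(q,0) = 0.5 * u * u; X(q,1) = u * w; X(q,2) = 0.5 * w * w;
      X(q,3) = u; X(q,4) = w;
      h(q) = arma::dot(d, nv);
    }
    arma::mat XtX = X.t() * X;
    double ridge = 1e-9 * (arma::trace(XtX) + 1.0);
    arma::vec coef;
    bool ok = arma::solve(coef, XtX + ridge * arma::eye(5,5), X.t() * h,
                          arma::solve_opts::no_approx);
    if (!ok || !coef.is_finite()) continue;
    double A = coef(0), B = coef(1), C = coef(2), D = coef(3), E = coef(4);
    double denom = std::sqrt(1.0 + D * D + E * E);
    arma::mat22 I1 = {{1.0 + D * D, D * E}, {D * E, 1.0 + E * E}};
    arma::mat22 II = {{A / denom, B / denom}, {B / denom, C / denom}};
    arma::mat22 S = arma::solve(I1, II);
    // symmetrize (S is self-adjoint wrt I; numerically near-symmetric)
    double tr = S(0,0) + S(1,1), det = S(0,0) * S(1,1) - S(0,1) * S(1,0);
    double disc = tr * tr / 4.0 - det;
    if (disc < 0) disc = 0;
    double r = std::sqrt(disc);
    // height measured along the outward normal: convex => h < 0 => negate
    double k1 = -(tr / 2.0 - r), k2 = -(tr / 2.0 + r);
    if (k1 < k2) std::swap(k1, k2);
    // principal direction for k1 (eigenvector of S for eigenvalue -k1)
    double lam = -k1;
    arma::vec2 dir2;
    if (std::abs(S(0,1)) > 1e-14)
      dir2 = {S(0,1), lam - S(0,0)};
    else if (std::abs(S(1,0)) > 1e-14)
      dir2 = {lam - S(1,1), S(1,0)};
    else
      dir2 = (std::abs(S(0,0) - lam) < std::abs(S(1,1) - lam)) ? arma::vec2{1,0} : arma::vec2{0,1};
    double dn = arma::norm(dir2);
    if (dn < 1e-300) dir2 = {1, 0}; else dir2 /= dn;
    arma::rowvec d3 = dir2(0) * e1 + dir2(1) * e2;
    out(i,0) = k1; out(i,1) = k2; out(i,2) = k1 * k2;
    out(i,3) = d3(0); out(i,4) = d3(1); out(i,5) = d3(2);
    out(i,6) = nn2;
  }
  return out;
}

// --------------------------------------------------------------------- knn
// Exact kd-tree k-nearest-neighbour search (any dimension).
struct KDNode { int idx; int dim; int left; int right; };

static void kd_build(const arma::mat& P, std::vector<int>& ids, int lo, int hi,
                     int depth, std::vector<KDNode>& nodes, int& root) {
  if (lo >= hi) { root = -1; return; }
  int d = depth % P.n_cols;
  int mid = (lo + hi) / 2;
  std::nth_element(ids.begin() + lo, ids.begin() + mid, ids.begin() + hi,
                   [&](int a, int b) { return P(a, d) < P(b, d); });
  int me = (int)nodes.size();
  nodes.push_back({ids[mid], d, -1, -1});
  root = me;
  int l, r;
  kd_build(P, ids, lo, mid, depth + 1, nodes, l);
  kd_build(P, ids, mid + 1, hi, depth + 1, nodes, r);
  nodes[me].left = l; nodes[me].right = r;
}

static void kd_search(const arma::mat& P, const std::vector<KDNode>& nodes, int node,
                      const arma::rowvec& q, int k,
                      std::priority_queue<std::pair<double,int>>& heap) {
  if (node < 0) return;
  const KDNode& nd = nodes[node];
  double d2 = 0;
  for (arma::uword c = 0; c < P.n_cols; ++c) {
    double diff = P(nd.idx, c) - q(c);
    d2 += diff * diff;
  }
  if ((int)heap.size() < k) heap.push({d2, nd.idx});
  else if (d2 < heap.top().first) { heap.pop(); heap.push({d2, nd.idx}); }
  double split = q(nd.dim) - P(nd.idx, nd.dim);
  int near = split < 0 ? nd.left : nd.right;
  int far  = split < 0 ? nd.right : nd.left;
  kd_search(P, nodes, near, q, k, heap);
  if ((int)heap.size() < k || split * split < heap.top().first)
    kd_search(P, nodes, far, q, k, heap);
}

// [[Rcpp::export]]
List cn_knn(const arma::mat& data, const arma::mat& query, int k) {
  int n = data.n_rows, nq = query.n_rows;
  if (k > n) k = n;
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  std::vector<KDNode> nodes;
  nodes.reserve(n);
  int root;
  kd_build(data, ids, 0, n, 0, nodes, root);
  arma::imat idx(nq, k);
  arma::mat dist(nq, k);
  for (int q = 0; q < nq; ++q) {
    std::priority_queue<std::pair<double,int>> heap;
    kd_search(data, nodes, root, query.row(q), k, heap);
    int got = (int)heap.size();
    for (int r = got - 1; r >= 0; --r) {
      idx(q, r) = heap.top().second + 1;
      dist(q, r) = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ------------------------------------------------------------------ raster
// Pinhole z-buffer rasterizer with headlight Lambertian shading and
// per-face albedo. Camera: xc = R * xw + t; u = fx*xc/zc + cx,
// v = fy*yc/zc + cy (px, 0-based, origin top-left, x right / y down).
// Returns shaded image (h x w, [0,1]) and depth map (Inf where empty).
// [[Rcpp::export]]
List cn_raster_mesh(const arma::mat& V, const arma::imat& F,
                    double fx, double fy, double cx, double cy,
                    const arma::mat& R, const arma::vec& t,
                    int width, int height, const arma::vec& albedo) {
  arma::mat img(height, width, arma::fill::zeros);
  arma::mat depth(height, width);
  depth.fill(arma::datum::inf);
  arma::mat Vc = V * R.t();
  Vc.each_row() += t.t();
  for (arma::uword f = 0; f < F.n_rows; ++f) {
    arma::rowvec p0 = Vc.row(F(f,0) - 1), p1 = Vc.row(F(f,1) - 1), p2 = Vc.row(F(f,2) - 1);
    if (p0(2) <= 1e-6 || p1(2) <= 1e-6 || p2(2) <= 1e-6) continue;
    arma::rowvec n = arma::cross(p1 - p0, p2 - p0);
    double nn = arma::norm(n);
    if (nn < 1e-300) continue;
    n /= nn;
    double shade = -n(2); // headlight along +z
    if (shade <= 0) continue; // back face
    shade *= (albedo.n_elem == F.n_rows) ? albedo(f) : 1.0;
    double u0 = fx * p0(0) / p0(2) + cx, v0 = fy * p0(1) / p0(2) + cy;
    double u1 = fx * p1(0) / p1(2) + cx, v1 = fy * p1(1) / p1(2) + cy;
    double u2 = fx * p2(0) / p2(2) + cx, v2 = fy * p2(1) / p2(2) + cy;
    int umin = std::max(0, (int)std::floor(std::min({u0,u1,u2})));
    int umax = std::min(width - 1, (int)std::ceil(std::max({u0,u1,u2})));
    int vmin = std::max(0, (int)std::floor(std::min({v0,v1,v2})));
    int vmax = std::min(height - 1, (int)std::ceil(std::max({v0,v1,v2})));
    if (umin > umax || vmin > vmax) continue;
    double den = (v1 - v2) * (u0 - u2) + (u2 - u1) * (v0 - v2);
    if (std::abs(den) < 1e-12) continue;
    double iz0 = 1.0 / p0(2), iz1 = 1.0 / p1(2), iz2 = 1.0 / p2(2);
    for (int vv = vmin; vv <= vmax; ++vv)
      for (int uu = umin; uu <= umax; ++uu) {
        double w0 = ((v1 - v2) * (uu - u2) + (u2 - u1) * (vv - v2)) / den;
        double w1 = ((v2 - v0) * (uu - u2) + (u0 - u2) * (vv - v2)) / den;
        double w2 = 1.0 - w0 - w1;
        if (w0 < -1e-9 || w1 < -1e-9 || w2 < -1e-9) continue;
        double iz = w0 * iz0 + w1 * iz1 + w2 * iz2;
        double z = 1.0 / iz;
        if (z < depth(vv, uu)) { depth(vv, uu) = z; img(vv, uu) = shade; }
      }
  }
  return List::create(_["image"] = img, _["depth"] = depth);
}
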