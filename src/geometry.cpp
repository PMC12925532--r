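// Voxel-grid and triangle-mesh primitives backing the meshing/morphometry modules.
// All grids are column-major (R layout), index (i,j,k) -> i + nx*(j + ny*k), 0-based here.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

static inline int64_t lin(int i, int j, int k, int nx, int ny) {
  return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, sigma in voxel units (may differ per axis).
// Reflective boundary handling; kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector field, NumericVector sigma) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(field.begin(), field.end()), out(buf.size());
  int dims[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (double &k : ker) k /= tot;

    int n = dims[ax];
    int64_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (int64_t)nx * ny;
    // iterate over all lines along axis ax
    int na = dims[(ax + 1) % 3], nb = dims[(ax + 2) % 3];
    int64_t sa = ((ax + 1) % 3 == 0) ? 1 : ((ax + 1) % 3 == 1) ? nx : (int64_t)nx * ny;
    int64_t sb = ((ax + 2) % 3 == 0) ? 1 : ((ax + 2) % 3 == 1) ? nx : (int64_t)nx * ny;
    for (int a = 0; a < na; ++a) {
      for (int b = 0; b < nb; ++b) {
        int64_t base = a * sa + b * sb;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;            // reflect
            if (ii >= n) ii = 2 * n - ii - 1;
            acc += ker[t + r] * buf[base + (int64_t)ii * stride];
          }
          out[base + (int64_t)i * stride] = acc;
        }
      }
    }
    buf.swap(out);
  }
  NumericVector res(buf.begin(), buf.end());
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Trilinear resampling with voxel-as-cell alignment: input cell i spans
// origin + (i -/+ 0.5) * spacing, and output cell centers are placed so both
// grids tile the same physical extent (no systematic half-voxel boundary
// bias). Sample position in input-index units: x = -0.5 + (j + 0.5) * ratio.
// Out-of-range samples clamp.
// [[Rcpp::export]]
NumericVector cpp_trilinear_resample(NumericVector field, NumericVector in_spacing,
                                     IntegerVector out_dim, NumericVector out_spacing) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((int64_t)ox * oy * oz);

  for (int k = 0; k < oz; ++k) {
    double z = -0.5 + (k + 0.5) * out_spacing[2] / in_spacing[2];
    int k0 = (int)std::floor(z); double fz = z - k0;
    if (k0 < 0) { k0 = 0; fz = 0; } if (k0 >= nz - 1) { k0 = nz - 2 >= 0 ? nz - 2 : 0; fz = (nz > 1) ? 1 : 0; }
    for (int j = 0; j < oy; ++j) {
      double y = -0.5 + (j + 0.5) * out_spacing[1] / in_spacing[1];
      int j0 = (int)std::floor(y); double fy = y - j0;
      if (j0 < 0) { j0 = 0; fy = 0; } if (j0 >= ny - 1) { j0 = ny - 2 >= 0 ? ny - 2 : 0; fy = (ny > 1) ? 1 : 0; }
      for (int i = 0; i < ox; ++i) {
        double x = -0.5 + (i + 0.5) * out_spacing[0] / in_spacing[0];
        int i0 = (int)std::floor(x); double fx = x - i0;
        if (i0 < 0) { i0 = 0; fx = 0; } if (i0 >= nx - 1) { i0 = nx - 2 >= 0 ? nx - 2 : 0; fx = (nx > 1) ? 1 : 0; }
        int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
        double c00 = field[lin(i0, j0, k0, nx, ny)] * (1 - fx) + field[lin(i1, j0, k0, nx, ny)] * fx;
        double c10 = field[lin(i0, j1, k0, nx, ny)] * (1 - fx) + field[lin(i1, j1, k0, nx, ny)] * fx;
        double c01 = field[lin(i0, j0, k1, nx, ny)] * (1 - fx) + field[lin(i1, j0, k1, nx, ny)] * fx;
        double c11 = field[lin(i0, j1, k1, nx, ny)] * (1 - fx) + field[lin(i1, j1, k1, nx, ny)] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
        out[lin(i, j, k, ox, oy)] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling. Labels are assigned in order of the lowest
// linear index of each component's seed voxel (label 1 = earliest seed), which
// gives the documented deterministic tie-break for equally sized components.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int64_t n = (int64_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int64_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((int64_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int64_t w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra iso-surfacing. Each grid cell is split into 6 tetrahedra
// around the (0,0,0)-(1,1,1) diagonal; face diagonals agree between neighbouring
// cells, so the output is a closed 2-manifold whenever the iso-surface does not
// touch the grid boundary. Triangles are wound so normals point towards lower
// field values (outside). Vertices are in world mm: origin + index * spacing.
static const int TET[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
static const int CORN[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, double level, NumericVector spacing, NumericVector origin) {
  IntegerVector dim = field.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> V;       // flat xyz
  std::vector<int> F;          // flat triples, 0-based

  auto inside = [&](int64_t id) { return field[id] > level; };
  auto vpos = [&](int64_t id, double out[3]) {
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((int64_t)nx * ny));
    out[0] = i; out[1] = j; out[2] = k;
  };
  auto edge_vertex = [&](int64_t a, int64_t b) -> int {
    uint64_t key = a < b ? ((uint64_t)a << 32 | (uint64_t)b) : ((uint64_t)b << 32 | (uint64_t)a);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = (level - fa) / (fb - fa);
    double pa[3], pb[3];
    vpos(a, pa); vpos(b, pb);
    int id = (int)(V.size() / 3);
    for (int d = 0; d < 3; ++d)
      V.push_back(origin[d] + spacing[d] * (pa[d] + t * (pb[d] - pa[d])));
    vmap[key] = id;
    return id;
  };
  // append triangle wound so its normal points from 'in' towards 'out'
  auto add_tri = [&](int v0, int v1, int v2, int64_t in_id, int64_t out_id) {
    double pi_[3], po[3];
    vpos(in_id, pi_); vpos(out_id, po);
    double d[3], e1[3], e2[3], nrm[3];
    for (int t = 0; t < 3; ++t) {
      d[t] = (po[t] - pi_[t]) * spacing[t];
      e1[t] = V[3 * v1 + t] - V[3 * v0 + t];
      e2[t] = V[3 * v2 + t] - V[3 * v0 + t];
    }
    nrm[0] = e1[1] * e2[2] - e1[2] * e2[1];
    nrm[1] = e1[2] * e2[0] - e1[0] * e2[2];
    nrm[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double dp = nrm[0] * d[0] + nrm[1] * d[1] + nrm[2] * d[2];
    if (dp >= 0) { F.push_back(v0); F.push_back(v1); F.push_back(v2); }
    else         { F.push_back(v0); F.push_back(v2); F.push_back(v1); }
  };

  for (int k = 0; k < nz - 1; ++k) for (int j = 0; j < ny - 1; ++j) for (int i = 0; i < nx - 1; ++i) {
    int64_t cid[8]; int nin = 0;
    for (int c = 0; c < 8; ++c) {
      cid[c] = lin(i + CORN[c][0], j + CORN[c][1], k + CORN[c][2], nx, ny);
      if (inside(cid[c])) ++nin;
    }
    if (nin == 0 || nin == 8) continue;
    for (int t = 0; t < 6; ++t) {
      int64_t ti[4]; bool tin[4]; int ns = 0;
      for (int c = 0; c < 4; ++c) { ti[c] = cid[TET[t][c]]; tin[c] = inside(ti[c]); ns += tin[c]; }
      if (ns == 0 || ns == 4) continue;
      if (ns == 1 || ns == 3) {
        bool want = (ns == 1);           // the lone vertex
        int lone = 0;
        for (int c = 0; c < 4; ++c) if (tin[c] == want) lone = c;
        int64_t a = ti[lone], o[3]; int p = 0;
        for (int c = 0; c < 4; ++c) if (c != lone) o[p++] = ti[c];
        int v0 = edge_vertex(a, o[0]), v1 = edge_vertex(a, o[1]), v2 = edge_vertex(a, o[2]);
        if (ns == 1) add_tri(v0, v1, v2, a, o[0]);
        else         add_tri(v0, v1, v2, o[0], a);
      } else {                           // 2-2: quad -> two triangles
        int64_t in2[2], out2[2]; int pi_ = 0, po = 0;
        for (int c = 0; c < 4; ++c) { if (tin[c]) in2[pi_++] = ti[c]; else out2[po++] = ti[c]; }
        int q0 = edge_vertex(in2[0], out2[0]);
        int q1 = edge_vertex(in2[0], out2[1]);
        int q2 = edge_vertex(in2[1], out2[1]);
        int q3 = edge_vertex(in2[1], out2[0]);
        add_tri(q0, q1, q2, in2[0], out2[0]);
        add_tri(q0, q2, q3, in2[0], out2[0]);
      }
    }
  }

  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix vm(nv, 3);
  IntegerMatrix fm(nf, 3);
  for (int v = 0; v < nv; ++v) for (int d = 0; d < 3; ++d) vm(v, d) = V[3 * v + d];
  for (int f = 0; f < nf; ++f) for (int d = 0; d < 3; ++d) fm(f, d) = F[3 * f + d] + 1; // 1-based
  return List::create(_["vertices"] = vm, _["faces"] = fm);
}

// ---------------------------------------------------------------------------
// Area-weighted per-vertex normals (assumes consistent outward winding).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  NumericMatrix N(nv, 3);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double e1[3], e2[3], nr[3];
    for (int d = 0; d < 3; ++d) { e1[d] = V(b, d) - V(a, d); e2[d] = V(c, d) - V(a, d); }
    nr[0] = e1[1] * e2[2] - e1[2] * e2[1];
    nr[1] = e1[2] * e2[0] - e1[0] * e2[2];
    nr[2] = e1[0] * e2[1] - e1[1] * e2[0];
    for (int d = 0; d < 3; ++d) { N(a, d) += nr[d]; N(b, d) += nr[d]; N(c, d) += nr[d]; }
  }
  for (int v = 0; v < nv; ++v) {
    double nn = std::sqrt(N(v, 0) * N(v, 0) + N(v, 1) * N(v, 1) + N(v, 2) * N(v, 2));
    if (nn > 0) for (int d = 0; d < 3; ++d) N(v, d) /= nn;
  }
  return N;
}

// ---------------------------------------------------------------------------
// Principal curvatures by local quadric fit in the vertex tangent frame.
// Neighbourhood: breadth-first walk over mesh edges, gated by Euclidean radius.
// Sign convention: convex regions of an outward-oriented surface get k1,k2 > 0.
// Returns k1 >= k2 and a validity flag (enough well-spread neighbours).
// Only the 0-based `targets` vertices are evaluated (others stay invalid),
// which keeps large meshes tractable; medians over an even subsample are
// statistically indistinguishable from the full field.
// [[Rcpp::export]]
List cpp_curvatures(NumericMatrix V, IntegerMatrix F, NumericMatrix N, double radius,
                    IntegerVector targets) {
  int nv = V.nrow(), nf = F.nrow();
  // CSR adjacency
  std::vector<std::vector<int>> adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (auto &v : adj) { std::sort(v.begin(), v.end()); v.erase(std::unique(v.begin(), v.end()), v.end()); }

  NumericVector k1(nv), k2(nv);
  LogicalVector valid(nv);
  double r2 = radius * radius;
  std::vector<int> mark(nv, -1), nb;
  std::queue<int> q;

  for (int ti = 0; ti < targets.size(); ++ti) {
    int i = targets[ti];
    if (adj[i].empty()) { valid[i] = false; continue; }
    nb.clear();
    mark[i] = i;
    q.push(i);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int w : adj[u]) {
        if (mark[w] == i) continue;
        double dx = V(w, 0) - V(i, 0), dy = V(w, 1) - V(i, 1), dz = V(w, 2) - V(i, 2);
        if (dx * dx + dy * dy + dz * dz > r2) continue;
        mark[w] = i;
        nb.push_back(w);
        q.push(w);
      }
    }
    if ((int)nb.size() < 8) { valid[i] = false; continue; }
    // tangent frame
    arma::vec3 n = {N(i, 0), N(i, 1), N(i, 2)};
    arma::vec3 a = (std::abs(n(0)) < 0.9) ? arma::vec3({1, 0, 0}) : arma::vec3({0, 1, 0});
    arma::vec3 e1 = arma::normalise(arma::cross(n, a));
    arma::vec3 e2 = arma::cross(n, e1);
    int m = (int)nb.size();
    arma::mat A(m, 6);
    arma::vec z(m);
    for (int t = 0; t < m; ++t) {
      arma::vec3 p = {V(nb[t], 0) - V(i, 0), V(nb[t], 1) - V(i, 1), V(nb[t], 2) - V(i, 2)};
      double x = arma::dot(p, e1) / radius, y = arma::dot(p, e2) / radius;  // scaled for conditioning
      A(t, 0) = x * x; A(t, 1) = x * y; A(t, 2) = y * y; A(t, 3) = x; A(t, 4) = y; A(t, 5) = 1.0;
      z(t) = arma::dot(p, n) / radius;
    }
    arma::vec coef;
    bool ok = arma::solve(coef, A.t() * A, A.t() * z, arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok) { valid[i] = false; continue; }
    // undo coordinate scaling: h(x,y) in mm with coefficients
    double aq = coef(0) / radius, bq = coef(1) / radius, cq = coef(2) / radius;
    double d = coef(3), e = coef(4);
    double g = 1.0 + d * d + e * e, sg = std::sqrt(g);
    // shape operator of the Monge patch at the origin
    arma::mat22 H = {{2 * aq, bq}, {bq, 2 * cq}};
    arma::mat22 I = {{1 + d * d, d * e}, {d * e, 1 + e * e}};
    arma::mat22 S = arma::solve(I, H) / sg;
    double tr = S(0, 0) + S(1, 1), det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
    double disc = std::max(0.0, tr * tr / 4.0 - det), sq = std::sqrt(disc);
    double l1 = tr / 2.0 + sq, l2 = tr / 2.0 - sq;   // l1 >= l2 of Monge operator
    // outward-normal convention: convex -> positive; Monge gives negative for convex
    k1[i] = -l2;
    k2[i] = -l1;
    valid[i] = true;
  }
  return List::create(_["k1"] = k1, _["k2"] = k2, _["valid"] = valid);
}
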