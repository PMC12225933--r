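// Triangle-surface operations: implicit moving-least-squares signed distance
// from an oriented point cloud, marching-tetrahedra isosurface extraction,
// Taubin smoothing, vertex normals, cotangent mean curvature, point-to-surface
// distance, and normal-direction ray thickness.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---- IMLS signed distance on a regular grid ----
// f(x) = sum_i w_i (x - p_i) . n_i / sum_i w_i, Gaussian weights, compact support.
// [[Rcpp::export]]
List cpp_imls_grid(NumericMatrix points, NumericMatrix normals,
                   NumericVector origin, double spacing, IntegerVector dims,
                   double support) {
  int P = points.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  // bin points on cells of size `support`
  double cell = support;
  std::unordered_map<long long, std::vector<int> > bins;
  auto key = [&](int ix, int iy, int iz) {
    return ((long long)(ix + 1048576) << 42) ^ ((long long)(iy + 1048576) << 21) ^ (long long)(iz + 1048576);
  };
  for (int p = 0; p < P; ++p) {
    int ix = (int)std::floor(points(p, 0) / cell);
    int iy = (int)std::floor(points(p, 1) / cell);
    int iz = (int)std::floor(points(p, 2) / cell);
    bins[key(ix, iy, iz)].push_back(p);
  }
  NumericVector f(n, NA_REAL);
  double sig2 = (support / 2.5) * (support / 2.5);
  double sup2 = support * support;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing;
        double y = origin[1] + j * spacing;
        double z = origin[2] + k * spacing;
        int ix = (int)std::floor(x / cell), iy = (int)std::floor(y / cell), iz = (int)std::floor(z / cell);
        double num = 0.0, den = 0.0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              auto it = bins.find(key(ix + di, iy + dj, iz + dk));
              if (it == bins.end()) continue;
              for (int p : it->second) {
                double dx = x - points(p, 0), dy = y - points(p, 1), dz = z - points(p, 2);
                double d2 = dx*dx + dy*dy + dz*dz;
                if (d2 > sup2) continue;
                double w = std::exp(-0.5 * d2 / sig2);
                num += w * (dx * normals(p, 0) + dy * normals(p, 1) + dz * normals(p, 2));
                den += w;
              }
            }
        if (den > 1e-12)
          f[i + (long long)nx * (j + (long long)ny * k)] = num / den;
      }
  f.attr("dim") = dims;
  return List::create(_["f"] = f);
}

// ---- marching tetrahedra ----
// Kuhn 6-tet cell split; all tets share the main diagonal 0-7 so the
// decomposition is conforming. Corner c has offsets (c&1, (c>>1)&1, (c>>2)&1).
static const int KUHN[6][4] = {
  {0,5,1,7}, {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector f, IntegerVector dims,
                       NumericVector origin, double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto fid = [&](int i, int j, int k) {
    return (long long)i + (long long)nx * (j + (long long)ny * k);
  };
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<long long, int> edge_vertex;   // key on grid-node pair
  auto edge_key = [&](long long a, long long b) {
    if (a > b) std::swap(a, b);
    return a * (long long)(nx) * ny * nz + b;
  };
  auto get_vertex = [&](long long ga, long long gb, double va, double vb) {
    long long ek = edge_key(ga, gb);
    auto it = edge_vertex.find(ek);
    if (it != edge_vertex.end()) return it->second;
    double t = va / (va - vb);
    t = std::max(1e-6, std::min(1.0 - 1e-6, t));
    int ia = (int)(ga % nx), ja = (int)((ga / nx) % ny), ka = (int)(ga / ((long long)nx * ny));
    int ib = (int)(gb % nx), jb = (int)((gb / nx) % ny), kb = (int)(gb / ((long long)nx * ny));
    vx.push_back(origin[0] + spacing * (ia + t * (ib - ia)));
    vy.push_back(origin[1] + spacing * (ja + t * (jb - ja)));
    vz.push_back(origin[2] + spacing * (ka + t * (kb - ka)));
    int id = (int)vx.size() - 1;
    edge_vertex[ek] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const double* g) {
    // orient so the normal points toward increasing f (outward)
    double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
    double nxv = uy*wz - uz*wy, nyv = uz*wx - ux*wz, nzv = ux*wy - uy*wx;
    if (nxv*g[0] + nyv*g[1] + nzv*g[2] < 0) std::swap(b, c);
    fa.push_back(a); fb.push_back(b); fc.push_back(c);
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        long long gid[8];
        double fv[8];
        bool ok = true;
        for (int c = 0; c < 8; ++c) {
          gid[c] = fid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          fv[c] = f[gid[c]];
          if (ISNA(fv[c]) || !std::isfinite(fv[c])) { ok = false; break; }
        }
        if (!ok) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = KUHN[t];
          double tv[4] = { fv[T[0]], fv[T[1]], fv[T[2]], fv[T[3]] };
          int neg[4], pos[4], nn = 0, np = 0;
          for (int a = 0; a < 4; ++a) {
            if (tv[a] < 0) neg[nn++] = a; else pos[np++] = a;
          }
          if (nn == 0 || nn == 4) continue;
          // linear gradient of f within the tet for orientation
          double X[4][3];
          for (int a = 0; a < 4; ++a) {
            int c = T[a];
            X[a][0] = i + (c & 1); X[a][1] = j + ((c >> 1) & 1); X[a][2] = k + ((c >> 2) & 1);
          }
          double e1[3], e2[3], e3[3];
          for (int c = 0; c < 3; ++c) {
            e1[c] = X[1][c] - X[0][c];
            e2[c] = X[2][c] - X[0][c];
            e3[c] = X[3][c] - X[0][c];
          }
          // solve [e1;e2;e3]^T g = df (3x3 linear system by Cramer)
          double A[9] = { e1[0], e2[0], e3[0], e1[1], e2[1], e3[1], e1[2], e2[2], e3[2] };
          // A is column-major: col0=(e1x,e2x,e3x)? build row-major mentally; use Cramer on
          // M g = b where M rows are e1,e2,e3 and b = (f1-f0, f2-f0, f3-f0)
          double b0 = tv[1]-tv[0], b1 = tv[2]-tv[0], b2 = tv[3]-tv[0];
          double M[9] = { e1[0], e2[0], e3[0],   // column-major: col j is x-coords? no:
                          e1[1], e2[1], e3[1],
                          e1[2], e2[2], e3[2] };
          (void)A;
          // det of M interpreted with columns (e1,e2,e3) transposed is same det
          double det = e1[0]*(e2[1]*e3[2]-e2[2]*e3[1]) - e1[1]*(e2[0]*e3[2]-e2[2]*e3[0]) + e1[2]*(e2[0]*e3[1]-e2[1]*e3[0]);
          double g[3] = { 0, 0, 0 };
          if (std::fabs(det) > 1e-14) {
            auto det3 = [](double a1,double a2,double a3,double b1_,double b2_,double b3_,double c1,double c2,double c3){
              return a1*(b2_*c3-b3_*c2) - a2*(b1_*c3-b3_*c1) + a3*(b1_*c2-b2_*c1);
            };
            g[0] = det3(b0, e1[1], e1[2], b1, e2[1], e2[2], b2, e3[1], e3[2]) / det;
            g[1] = det3(e1[0], b0, e1[2], e2[0], b1, e2[2], e3[0], b2, e3[2]) / det;
            g[2] = det3(e1[0], e1[1], b0, e2[0], e2[1], b1, e3[0], e3[1], b2) / det;
          }
          (void)M;
          if (nn == 1) {
            int a = neg[0];
            int v0 = get_vertex(gid[T[a]], gid[T[pos[0]]], tv[a], tv[pos[0]]);
            int v1 = get_vertex(gid[T[a]], gid[T[pos[1]]], tv[a], tv[pos[1]]);
            int v2 = get_vertex(gid[T[a]], gid[T[pos[2]]], tv[a], tv[pos[2]]);
            emit(v0, v1, v2, g);
          } else if (nn == 3) {
            int a = pos[0];
            int v0 = get_vertex(gid[T[a]], gid[T[neg[0]]], tv[a], tv[neg[0]]);
            int v1 = get_vertex(gid[T[a]], gid[T[neg[1]]], tv[a], tv[neg[1]]);
            int v2 = get_vertex(gid[T[a]], gid[T[neg[2]]], tv[a], tv[neg[2]]);
            emit(v0, v1, v2, g);
          } else {
            // 2 neg / 2 pos -> quad split into two triangles
            int a0 = neg[0], a1 = neg[1], p0 = pos[0], p1 = pos[1];
            int v00 = get_vertex(gid[T[a0]], gid[T[p0]], tv[a0], tv[p0]);
            int v01 = get_vertex(gid[T[a0]], gid[T[p1]], tv[a0], tv[p1]);
            int v10 = get_vertex(gid[T[a1]], gid[T[p0]], tv[a1], tv[p0]);
            int v11 = get_vertex(gid[T[a1]], gid[T[p1]], tv[a1], tv[p1]);
            emit(v00, v01, v11, g);
            emit(v00, v11, v10, g);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int v = 0; v < nv; ++v) { verts(v,0)=vx[v]; verts(v,1)=vy[v]; verts(v,2)=vz[v]; }
  for (int t = 0; t < nf; ++t) { faces(t,0)=fa[t]; faces(t,1)=fb[t]; faces(t,2)=fc[t]; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---- Taubin smoothing (lambda | mu passes over the umbrella operator) ----
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix verts, IntegerMatrix faces,
                                int iterations, double lambda, double mu) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int> > nbr(nv);
  for (int t = 0; t < nf; ++t)
    for (int e = 0; e < 3; ++e) {
      int a = faces(t, e), b = faces(t, (e + 1) % 3);
      nbr[a].push_back(b);
      nbr[b].push_back(a);
    }
  for (int v = 0; v < nv; ++v) {
    std::sort(nbr[v].begin(), nbr[v].end());
    nbr[v].erase(std::unique(nbr[v].begin(), nbr[v].end()), nbr[v].end());
  }
  std::vector<double> x(nv), y(nv), z(nv);
  for (int v = 0; v < nv; ++v) { x[v]=verts(v,0); y[v]=verts(v,1); z[v]=verts(v,2); }
  std::vector<double> dx(nv), dy(nv), dz(nv);
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double fac = pass == 0 ? lambda : mu;
      for (int v = 0; v < nv; ++v) {
        if (nbr[v].empty()) { dx[v]=dy[v]=dz[v]=0; continue; }
        double sx=0, sy=0, sz=0;
        for (int u : nbr[v]) { sx+=x[u]; sy+=y[u]; sz+=z[u]; }
        double inv = 1.0 / nbr[v].size();
        dx[v] = sx*inv - x[v]; dy[v] = sy*inv - y[v]; dz[v] = sz*inv - z[v];
      }
      for (int v = 0; v < nv; ++v) { x[v]+=fac*dx[v]; y[v]+=fac*dy[v]; z[v]+=fac*dz[v]; }
    }
  }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v,0)=x[v]; out(v,1)=y[v]; out(v,2)=z[v]; }
  return out;
}

// ---- angle-weighted vertex normals (faces assumed outward-oriented) ----
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix verts, IntegerMatrix faces) {
  int nv = verts.nrow(), nf = faces.nrow();
  NumericMatrix nrm(nv, 3);
  for (int t = 0; t < nf; ++t) {
    int a = faces(t,0), b = faces(t,1), c = faces(t,2);
    double u[3], w[3];
    for (int i = 0; i < 3; ++i) { u[i] = verts(b,i)-verts(a,i); w[i] = verts(c,i)-verts(a,i); }
    double fn[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    for (int i = 0; i < 3; ++i) {
      nrm(a,i) += fn[i]; nrm(b,i) += fn[i]; nrm(c,i) += fn[i];
    }
  }
  for (int v = 0; v < nv; ++v) {
    double l = std::sqrt(nrm(v,0)*nrm(v,0) + nrm(v,1)*nrm(v,1) + nrm(v,2)*nrm(v,2));
    if (l > 1e-14) for (int i = 0; i < 3; ++i) nrm(v,i) /= l;
  }
  return nrm;
}

// ---- signed discrete mean curvature (cotangent formula) ----
// Sign convention: outward-oriented convex surface (sphere) positive,
// concave valleys (creases seen from outside) negative.
// [[Rcpp::export]]
NumericVector cpp_mean_curvature(NumericMatrix verts, IntegerMatrix faces) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<double> Kx(nv, 0), Ky(nv, 0), Kz(nv, 0), area(nv, 0);
  for (int t = 0; t < nf; ++t) {
    int id[3] = { faces(t,0), faces(t,1), faces(t,2) };
    double P[3][3];
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) P[a][c] = verts(id[a], c);
    // face area
    double u[3], w[3];
    for (int c = 0; c < 3; ++c) { u[c] = P[1][c]-P[0][c]; w[c] = P[2][c]-P[0][c]; }
    double fn[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    double A = 0.5 * std::sqrt(fn[0]*fn[0] + fn[1]*fn[1] + fn[2]*fn[2]);
    for (int a = 0; a < 3; ++a) area[id[a]] += A / 3.0;
    // cotangents at each corner weight the opposite edge
    for (int corner = 0; corner < 3; ++corner) {
      int i = (corner + 1) % 3, j = (corner + 2) % 3;
      double e1[3], e2[3];
      for (int c = 0; c < 3; ++c) {
        e1[c] = P[i][c] - P[corner][c];
        e2[c] = P[j][c] - P[corner][c];
      }
      double dot = e1[0]*e2[0] + e1[1]*e2[1] + e1[2]*e2[2];
      double cr[3] = { e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2], e1[0]*e2[1]-e1[1]*e2[0] };
      double crn = std::sqrt(cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2]);
      if (crn < 1e-14) continue;
      double cot = dot / crn;
      // edge (i, j): contribute cot * (x_i - x_j) to K_j and vice versa
      for (int c = 0; c < 3; ++c) {
        double d = P[i][c] - P[j][c];
        (void)d;
      }
      // K_i += cot * (x_i - x_j) accumulated at both ends
      int vi = id[i], vj = id[j];
      for (int c = 0; c < 3; ++c) {
        double diff = verts(vi, c) - verts(vj, c);
        if (c == 0) { Kx[vi] += cot * diff; Kx[vj] -= cot * diff; }
        else if (c == 1) { Ky[vi] += cot * diff; Ky[vj] -= cot * diff; }
        else { Kz[vi] += cot * diff; Kz[vj] -= cot * diff; }
      }
    }
  }
  NumericMatrix nrm = cpp_vertex_normals(verts, faces);
  NumericVector H(nv);
  for (int v = 0; v < nv; ++v) {
    if (area[v] < 1e-14) { H[v] = 0; continue; }
    double kx = Kx[v] / (2.0 * area[v]);
    double ky = Ky[v] / (2.0 * area[v]);
    double kz = Kz[v] / (2.0 * area[v]);
    // K = (1/2A) sum cot (x_i - x_j) points along the outward normal on a
    // convex surface; project so sphere -> +1/r, creases -> negative
    H[v] = 0.5 * (kx * nrm(v,0) + ky * nrm(v,1) + kz * nrm(v,2));
  }
  return H;
}

// ---- distances ----
static double point_tri_dist(const double* p, const double* a, const double* b,
                             const double* c) {
  // reuse logic: closest point via Ericson (duplicated small helper)
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) q[i]=a[i]; }
  else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) { bp[i]=p[i]-b[i]; cp[i]=p[i]-c[i]; }
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    double vc = d1*d4 - d3*d2, vb = d5*d2 - d1*d6, va = d3*d6 - d5*d4;
    if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) q[i]=b[i]; }
    else if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) q[i]=c[i]; }
    else if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      for (int i=0;i<3;++i) q[i] = a[i] + t*ab[i];
    } else if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      for (int i=0;i<3;++i) q[i] = a[i] + t*ac[i];
    } else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i=0;i<3;++i) q[i] = b[i] + t*(c[i]-b[i]);
    } else {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int i=0;i<3;++i) q[i] = a[i] + ab[i]*v + ac[i]*w;
    }
  }
  double dx=p[0]-q[0], dy=p[1]-q[1], dz=p[2]-q[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_surface(NumericMatrix points, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int P = points.nrow(), nf = faces.nrow();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double pt[3] = { points(p,0), points(p,1), points(p,2) };
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      double a[3] = { verts(faces(t,0),0), verts(faces(t,0),1), verts(faces(t,0),2) };
      double b[3] = { verts(faces(t,1),0), verts(faces(t,1),1), verts(faces(t,1),2) };
      double c[3] = { verts(faces(t,2),0), verts(faces(t,2),1), verts(faces(t,2),2) };
      double d = point_tri_dist(pt, a, b, c);
      if (d < best) best = d;
    }
    out[p] = best;
  }
  return out;
}

// Moller-Trumbore ray/triangle intersection; returns t or -1
static double ray_tri(const double* o, const double* d, const double* a,
                      const double* b, const double* c) {
  double e1[3], e2[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i]-a[i]; e2[i] = c[i]-a[i]; }
  double pv[3] = { d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2], d[0]*e2[1]-d[1]*e2[0] };
  double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
  if (std::fabs(det) < 1e-12) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = { o[0]-a[0], o[1]-a[1], o[2]-a[2] };
  double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return -1.0;
  double qv[3] = { tv[1]*e1[2]-tv[2]*e1[1], tv[2]*e1[0]-tv[0]*e1[2], tv[0]*e1[1]-tv[1]*e1[0] };
  double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return -1.0;
  double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
  return t > -1e-9 ? std::max(t, 0.0) : -1.0;
}

// Thickness by ray casting from each origin along `dirs` against a target
// surface; misses get -1 (caller applies the nearest-point fallback).
// [[Rcpp::export]]
NumericVector cpp_ray_thickness(NumericMatrix origins, NumericMatrix dirs,
                                NumericMatrix verts, IntegerMatrix faces) {
  int P = origins.nrow(), nf = faces.nrow();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double o[3] = { origins(p,0), origins(p,1), origins(p,2) };
    double d[3] = { dirs(p,0), dirs(p,1), dirs(p,2) };
    double best = -1.0;
    for (int t = 0; t < nf; ++t) {
      double a[3] = { verts(faces(t,0),0), verts(faces(t,0),1), verts(faces(t,0),2) };
      double b[3] = { verts(faces(t,1),0), verts(faces(t,1),1), verts(faces(t,1),2) };
      double c[3] = { verts(faces(t,2),0), verts(faces(t,2),1), verts(faces(t,2),2) };
      double tt = ray_tri(o, d, a, b, c);
      if (tt >= 0 && (best < 0 || tt < best)) best = tt;
    }
    out[p] = best;
  }
  return out;
}

// min distance from each query point to a reference point set (brute force)
// [[Rcpp::export]]
NumericVector cpp_min_dist_points(NumericMatrix query, NumericMatrix ref) {
  int Q = query.nrow(), P = ref.nrow();
  NumericVector out(Q);
  for (int q = 0; q < Q; ++q) {
    double x = query(q,0), y = query(q,1), z = query(q,2);
    double best = R_PosInf;
    for (int p = 0; p < P; ++p) {
      double dx = x - ref(p,0), dy = y - ref(p,1), dz = z - ref(p,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// total area of a triangle surface
// [[Rcpp::export]]
double cpp_surface_area(NumericMatrix verts, IntegerMatrix faces) {
  double A = 0.0;
  for (int t = 0; t < faces.nrow(); ++t) {
    double u[3], w[3];
    for (int c = 0; c < 3; ++c) {
      u[c] = verts(faces(t,1),c) - verts(faces(t,0),c);
      w[c] = verts(faces(t,2),c) - verts(faces(t,0),c);
    }
    double fn[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    A += 0.5 * std::sqrt(fn[0]*fn[0] + fn[1]*fn[1] + fn[2]*fn[2]);
  }
  return A;
}
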