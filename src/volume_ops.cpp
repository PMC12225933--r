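// 3D volumetric operations: separable Gaussian smoothing, central-difference
// gradients, Canny non-maximum suppression + hysteresis, 26-connected
// labeling, and principal-curvature (Hessian) blob detection.
// Volumes are R arrays in [x, y, z] order, x fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int refl(int i, int n) {
  // reflect-101 boundary
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void gauss1d(std::vector<double>& kern, double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  kern.resize(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;
}

static void smooth_axis(std::vector<double>& v, int nx, int ny, int nz,
                        const std::vector<double>& kern, int axis) {
  int r = ((int)kern.size() - 1) / 2;
  std::vector<double> out(v.size());
  int n[3] = { nx, ny, nz };
  long long stride[3] = { 1, nx, (long long)nx * ny };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx3[3] = { i, j, k };
        double s = 0.0;
        for (int o = -r; o <= r; ++o) {
          int q = refl(idx3[axis] + o, n[axis]);
          long long lin = (long long)i * (axis == 0 ? 0 : 1);
          // recompute linear index with axis coordinate replaced by q
          int ii = (axis == 0) ? q : i;
          int jj = (axis == 1) ? q : j;
          int kk = (axis == 2) ? q : k;
          (void)lin; (void)stride;
          s += kern[o + r] * v[ii + (long long)nx * (jj + (long long)ny * kk)];
        }
        out[i + (long long)nx * (j + (long long)ny * k)] = s;
      }
  v.swap(out);
}

static void smooth3(std::vector<double>& v, int nx, int ny, int nz, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> kern;
  gauss1d(kern, sigma);
  smooth_axis(v, nx, ny, nz, kern, 0);
  smooth_axis(v, nx, ny, nz, kern, 1);
  smooth_axis(v, nx, ny, nz, kern, 2);
}

#define IDX(i, j, k) ((i) + (long long)nx * ((j) + (long long)ny * (k)))

// [[Rcpp::export]]
List cpp_smooth_gradient(NumericVector stack, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  std::vector<double> v(stack.begin(), stack.end());
  smooth3(v, nx, ny, nz, sigma);
  NumericVector sm(n), gx(n), gy(n), gz(n), mag(n);
  for (long long i = 0; i < n; ++i) sm[i] = v[i];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double dx = 0.5 * (v[IDX(refl(i+1,nx), j, k)] - v[IDX(refl(i-1,nx), j, k)]);
        double dy = 0.5 * (v[IDX(i, refl(j+1,ny), k)] - v[IDX(i, refl(j-1,ny), k)]);
        double dz = 0.5 * (v[IDX(i, j, refl(k+1,nz))] - v[IDX(i, j, refl(k-1,nz))]);
        long long id = IDX(i, j, k);
        gx[id] = dx; gy[id] = dy; gz[id] = dz;
        mag[id] = std::sqrt(dx*dx + dy*dy + dz*dz);
      }
  sm.attr("dim") = dims; gx.attr("dim") = dims; gy.attr("dim") = dims;
  gz.attr("dim") = dims; mag.attr("dim") = dims;
  return List::create(_["smoothed"] = sm, _["gx"] = gx, _["gy"] = gy,
                      _["gz"] = gz, _["magnitude"] = mag);
}

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
  double fx = x - i, fy = y - j, fz = z - k;
  double s = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int ii = refl(i + di, nx), jj = refl(j + dj, ny), kk = refl(k + dk, nz);
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        s += w * v[ii + (long long)nx * (jj + (long long)ny * kk)];
      }
  return s;
}

// [[Rcpp::export]]
IntegerVector cpp_canny_nms_hysteresis(NumericVector mag, NumericVector gx,
                                       NumericVector gy, NumericVector gz,
                                       IntegerVector dims, double low, double high) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  const double* m = REAL(mag);
  std::vector<unsigned char> keep(n, 0);   // 1 weak, 2 strong
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i, j, k);
        double mm = m[id];
        if (mm < low) continue;
        double ux = gx[id] / mm, uy = gy[id] / mm, uz = gz[id] / mm;
        double m1 = trilinear(m, nx, ny, nz, i + ux, j + uy, k + uz);
        double m2 = trilinear(m, nx, ny, nz, i - ux, j - uy, k - uz);
        if (mm >= m1 && mm >= m2)
          keep[id] = (mm >= high) ? 2 : 1;
      }
  // hysteresis: BFS from strong through weak, 26-connectivity
  IntegerVector out(n, 0);
  std::vector<long long> stack_;
  for (long long id = 0; id < n; ++id)
    if (keep[id] == 2) { out[id] = 1; stack_.push_back(id); }
  while (!stack_.empty()) {
    long long id = stack_.back(); stack_.pop_back();
    int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((long long)nx * ny));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          long long nid = IDX(ii, jj, kk);
          if (keep[nid] >= 1 && !out[nid]) { out[nid] = 1; stack_.push_back(nid); }
        }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long long> stack_;
  int next = 0;
  for (long long seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack_.push_back(seed);
    while (!stack_.empty()) {
      long long id = stack_.back(); stack_.pop_back();
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((long long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            long long nid = IDX(ii, jj, kk);
            if (mask[nid] && !lab[nid]) { lab[nid] = next; stack_.push_back(nid); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// eigenvalues of a symmetric 3x3 matrix (ascending), trigonometric method
static void sym3_eigvals(double a11, double a22, double a33,
                         double a12, double a13, double a23, double* ev) {
  double p1 = a12*a12 + a13*a13 + a23*a23;
  if (p1 < 1e-30) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
    std::sort(ev, ev + 3);
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11*b11 + b22*b22 + b33*b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11/p, c22 = b22/p, c33 = b33/p, c12 = a12/p, c13 = a13/p, c23 = a23/p;
  double detB = c11*(c22*c33 - c23*c23) - c12*(c12*c33 - c23*c13) + c13*(c12*c23 - c22*c13);
  double r = detB / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  ev[2] = q + 2.0 * p * std::cos(phi);
  ev[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Blob detection: smooth at `scale`, Hessian eigenvalues per voxel, keep
// voxels where all three principal curvatures are negative and the
// smallest-magnitude one exceeds `threshold`; merge candidates into
// score-weighted component centroids.
// [[Rcpp::export]]
List cpp_blob_detect(NumericVector stack, IntegerVector dims, double scale,
                     double threshold) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  std::vector<double> v(stack.begin(), stack.end());
  smooth3(v, nx, ny, nz, scale);
  std::vector<double> score(n, 0.0);
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        long long id = IDX(i, j, k);
        double c = v[id];
        double hxx = v[IDX(i+1,j,k)] - 2*c + v[IDX(i-1,j,k)];
        double hyy = v[IDX(i,j+1,k)] - 2*c + v[IDX(i,j-1,k)];
        double hzz = v[IDX(i,j,k+1)] - 2*c + v[IDX(i,j,k-1)];
        double hxy = 0.25 * (v[IDX(i+1,j+1,k)] - v[IDX(i+1,j-1,k)] - v[IDX(i-1,j+1,k)] + v[IDX(i-1,j-1,k)]);
        double hxz = 0.25 * (v[IDX(i+1,j,k+1)] - v[IDX(i+1,j,k-1)] - v[IDX(i-1,j,k+1)] + v[IDX(i-1,j,k-1)]);
        double hyz = 0.25 * (v[IDX(i,j+1,k+1)] - v[IDX(i,j+1,k-1)] - v[IDX(i,j-1,k+1)] + v[IDX(i,j-1,k-1)]);
        double ev[3];
        sym3_eigvals(hxx, hyy, hzz, hxy, hxz, hyz, ev);
        if (ev[2] < 0 && -ev[2] > threshold) score[id] = -ev[2];
      }
  // 26-connected components of positive score; centroids are score-weighted
  // over the voxels above half the component's peak (robust to the tails of
  // neighboring blobs leaking into the component)
  std::vector<int> lab(n, 0);
  std::vector<long long> stack_;
  std::vector<std::vector<long long> > members;
  int next = 0;
  for (long long seed = 0; seed < n; ++seed) {
    if (score[seed] <= 0 || lab[seed]) continue;
    ++next;
    members.push_back(std::vector<long long>());
    lab[seed] = next;
    stack_.push_back(seed);
    while (!stack_.empty()) {
      long long id = stack_.back(); stack_.pop_back();
      members[next-1].push_back(id);
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((long long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            long long nid = IDX(ii, jj, kk);
            if (score[nid] > 0 && !lab[nid]) { lab[nid] = next; stack_.push_back(nid); }
          }
    }
  }
  NumericMatrix centroids(next, 3);
  NumericVector scores(next);
  for (int c = 0; c < next; ++c) {
    double smax = 0.0;
    for (long long id : members[c]) smax = std::max(smax, score[id]);
    double cx = 0, cy = 0, cz = 0, wsum = 0;
    for (long long id : members[c]) {
      double w = score[id];
      if (w < 0.5 * smax) continue;
      int i = (int)(id % nx), j = (int)((id / nx) % ny), k = (int)(id / ((long long)nx * ny));
      cx += w * i; cy += w * j; cz += w * k;
      wsum += w;
    }
    centroids(c, 0) = cx / wsum;
    centroids(c, 1) = cy / wsum;
    centroids(c, 2) = cz / wsum;
    scores[c] = smax;
  }
  return List::create(_["centroids"] = centroids, _["scores"] = scores);
}
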