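// Finite-strain neo-Hookean tetrahedral elements with multiplicative growth,
// penalty self-contact and damped semi-implicit quasi-static relaxation.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// ---- small 3x3 helpers (column-major double[9], A[i + 3*j]) ----
static inline void mat3_mul(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[i + 3*j] = A[i] * B[3*j] + A[i + 3] * B[1 + 3*j] + A[i + 6] * B[2 + 3*j];
}
static inline double mat3_det(const double* A) {
  return A[0]*(A[4]*A[8] - A[5]*A[7])
       - A[3]*(A[1]*A[8] - A[2]*A[7])
       + A[6]*(A[1]*A[5] - A[2]*A[4]);
}
static inline bool mat3_inv(const double* A, double* Ai) {
  double d = mat3_det(A);
  if (d == 0.0 || !std::isfinite(d)) return false;
  double id = 1.0 / d;
  Ai[0] =  (A[4]*A[8] - A[5]*A[7]) * id;
  Ai[1] = -(A[1]*A[8] - A[2]*A[7]) * id;
  Ai[2] =  (A[1]*A[5] - A[2]*A[4]) * id;
  Ai[3] = -(A[3]*A[8] - A[5]*A[6]) * id;
  Ai[4] =  (A[0]*A[8] - A[2]*A[6]) * id;
  Ai[5] = -(A[0]*A[5] - A[2]*A[3]) * id;
  Ai[6] =  (A[3]*A[7] - A[4]*A[6]) * id;
  Ai[7] = -(A[0]*A[7] - A[1]*A[6]) * id;
  Ai[8] =  (A[0]*A[4] - A[1]*A[3]) * id;
  return true;
}

// growth tensor G = (1+gt)(I - n n^T) + (1+gn) n n^T, column-major
static inline void growth_mat(const double* n, double gt, double gn, double* G) {
  double at = 1.0 + gt, an = 1.0 + gn;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      G[i + 3*j] = (i == j ? at : 0.0) + (an - at) * n[i] * n[j];
}

// Neo-Hookean response of one tet.
// X cols of Bm: inverse reference shape matrix; Vref: reference volume.
// Returns energy (W * Vref * detG); writes nodal forces into f (12 doubles,
// node-major: f[3*a + c]). Ginv, detG precomputed. Returns NaN if Je <= 0.
static inline double tet_response(const double* x0, const double* x1,
                                  const double* x2, const double* x3,
                                  const double* Bm, double Vref,
                                  const double* Ginv, double detG,
                                  double mu, double lam, double* f) {
  double Ds[9];
  for (int c = 0; c < 3; ++c) {
    Ds[c + 0] = x1[c] - x0[c];
    Ds[c + 3] = x2[c] - x0[c];
    Ds[c + 6] = x3[c] - x0[c];
  }
  double F[9], Fe[9];
  mat3_mul(Ds, Bm, F);
  mat3_mul(F, Ginv, Fe);
  double Je = mat3_det(Fe);
  if (!(Je > 0.0)) return NA_REAL;
  double FeInv[9];
  mat3_inv(Fe, FeInv);
  double lnJ = std::log(Je);
  double I1 = 0.0;
  for (int i = 0; i < 9; ++i) I1 += Fe[i] * Fe[i];
  double W = 0.5 * mu * (I1 - 3.0) - mu * lnJ + 0.5 * lam * lnJ * lnJ;
  // P = dW/dFe = mu (Fe - Fe^{-T}) + lam lnJ Fe^{-T}
  double P[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double feInvT = FeInv[j + 3*i];
      P[i + 3*j] = mu * (Fe[i + 3*j] - feInvT) + lam * lnJ * feInvT;
    }
  // dW/dF = P Ginv^T ; H = -Vref detG (dW/dF) Bm^T -> forces on nodes 1..3
  double dWdF[9], GinvT[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) GinvT[i + 3*j] = Ginv[j + 3*i];
  mat3_mul(P, GinvT, dWdF);
  double s = -Vref * detG;
  double H[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      H[i + 3*j] = s * (dWdF[i] * Bm[j] + dWdF[i + 3] * Bm[j + 3] + dWdF[i + 6] * Bm[j + 6]);
  // column a of H^T? careful: H = s * dWdF * Bm^T, column k = force on node k+1
  for (int k = 0; k < 3; ++k)
    for (int c = 0; c < 3; ++c) f[3*(k + 1) + c] = H[c + 3*k];
  for (int c = 0; c < 3; ++c) f[c] = -(f[3 + c] + f[6 + c] + f[9 + c]);
  return W * Vref * detG;
}

// [[Rcpp::export]]
List cpp_element_response(NumericMatrix Xref, NumericMatrix xcur,
                          NumericMatrix G, double mu, double lam) {
  double Dm[9];
  for (int c = 0; c < 3; ++c) {
    Dm[c + 0] = Xref(1, c) - Xref(0, c);
    Dm[c + 3] = Xref(2, c) - Xref(0, c);
    Dm[c + 6] = Xref(3, c) - Xref(0, c);
  }
  double Vref = mat3_det(Dm) / 6.0;
  if (Vref <= 0) stop("reference tetrahedron is degenerate or inverted");
  double Bm[9];
  mat3_inv(Dm, Bm);
  double Gm[9];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) Gm[i + 3*j] = G(i, j);
  double Ginv[9];
  if (!mat3_inv(Gm, Ginv)) stop("growth tensor is singular");
  double detG = mat3_det(Gm);
  double x[12];
  for (int a = 0; a < 4; ++a)
    for (int c = 0; c < 3; ++c) x[3*a + c] = xcur(a, c);
  double f[12];
  double en = tet_response(x, x + 3, x + 6, x + 9, Bm, Vref, Ginv, detG, mu, lam, f);
  if (!std::isfinite(en)) stop("element inversion: elastic Jacobian J_e <= 0");
  NumericMatrix fo(4, 3);
  for (int a = 0; a < 4; ++a)
    for (int c = 0; c < 3; ++c) fo(a, c) = f[3*a + c];
  return List::create(_["energy"] = en, _["forces"] = fo);
}

// ---- precomputation shared by assembly and relaxation ----
struct TetData {
  int n;                       // number of tets
  std::vector<int> t;          // 4n connectivity
  std::vector<double> Bm;      // 9n
  std::vector<double> Vref;    // n
};

static void precompute_tets(const NumericMatrix& nodes, const IntegerMatrix& tets,
                            TetData& td) {
  int M = tets.nrow();
  td.n = M;
  td.t.resize(4 * M);
  td.Bm.resize(9 * M);
  td.Vref.resize(M);
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 4; ++a) td.t[4*e + a] = tets(e, a);
    double Dm[9];
    int i0 = td.t[4*e], i1 = td.t[4*e+1], i2 = td.t[4*e+2], i3 = td.t[4*e+3];
    for (int c = 0; c < 3; ++c) {
      Dm[c + 0] = nodes(i1, c) - nodes(i0, c);
      Dm[c + 3] = nodes(i2, c) - nodes(i0, c);
      Dm[c + 6] = nodes(i3, c) - nodes(i0, c);
    }
    double V = mat3_det(Dm) / 6.0;
    if (!(V > 0))
      stop("tetrahedron %d has non-positive reference volume", e + 1);
    td.Vref[e] = V;
    mat3_inv(Dm, &td.Bm[9*e]);
  }
}

// Elastic forces + energy for an arbitrary nodal configuration.
// [[Rcpp::export]]
List cpp_elastic_forces(NumericMatrix nodes_ref, IntegerMatrix tets,
                        NumericMatrix positions,
                        NumericVector mu, NumericVector lam,
                        NumericMatrix normals, NumericVector gt, NumericVector gn) {
  int N = positions.nrow();
  TetData td;
  precompute_tets(nodes_ref, tets, td);
  std::vector<double> pos(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) pos[3*i + c] = positions(i, c);
  NumericMatrix force(N, 3);
  double energy = 0.0, minJe = R_PosInf;
  int bad = -1;
  for (int e = 0; e < td.n; ++e) {
    double nvec[3] = { normals(e, 0), normals(e, 1), normals(e, 2) };
    double G[9], Ginv[9];
    growth_mat(nvec, gt[e], gn[e], G);
    mat3_inv(G, Ginv);
    double detG = mat3_det(G);
    const int* tt = &td.t[4*e];
    double f[12];
    double en = tet_response(&pos[3*tt[0]], &pos[3*tt[1]], &pos[3*tt[2]], &pos[3*tt[3]],
                             &td.Bm[9*e], td.Vref[e], Ginv, detG, mu[e], lam[e], f);
    if (!std::isfinite(en)) { bad = e; break; }
    energy += en;
    // track min Je
    double Ds[9], F[9], Fe[9];
    const double* x0 = &pos[3*tt[0]];
    for (int c = 0; c < 3; ++c) {
      Ds[c + 0] = pos[3*tt[1] + c] - x0[c];
      Ds[c + 3] = pos[3*tt[2] + c] - x0[c];
      Ds[c + 6] = pos[3*tt[3] + c] - x0[c];
    }
    mat3_mul(Ds, &td.Bm[9*e], F);
    mat3_mul(F, Ginv, Fe);
    double Je = mat3_det(Fe);
    if (Je < minJe) minJe = Je;
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) force(tt[a], c) += f[3*a + c];
  }
  if (bad >= 0)
    stop("element inversion (J_e <= 0) in element %d", bad + 1);
  return List::create(_["forces"] = force, _["energy"] = energy, _["min_Je"] = minJe);
}

// ---- contact machinery ----
struct ContactSet {
  std::vector<int> tri;          // 3*S triangle vertex ids
  std::vector<int> snodes;       // surface node ids
  // adjacency: for surface node id -> set of vertex ids in its surface 1-ring
  std::unordered_map<int, std::unordered_set<int> > ring;
};

static void build_contact_set(const IntegerMatrix& tris, ContactSet& cs) {
  int S = tris.nrow();
  cs.tri.resize(3 * S);
  std::unordered_set<int> nodeset;
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < 3; ++k) {
      cs.tri[3*s + k] = tris(s, k);
      nodeset.insert(tris(s, k));
    }
  cs.snodes.assign(nodeset.begin(), nodeset.end());
  std::sort(cs.snodes.begin(), cs.snodes.end());
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < 3; ++k) {
      int v = cs.tri[3*s + k];
      for (int l = 0; l < 3; ++l) cs.ring[v].insert(cs.tri[3*s + l]);
    }
}

static inline double closest_point_tri(const double* p, const double* a,
                                       const double* b, const double* c,
                                       double* q, double* w) {
  // Ericson's closest point on triangle; also returns barycentric weights.
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) q[i]=a[i]; w[0]=1;w[1]=0;w[2]=0; }
  else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) { bp[i] = p[i]-b[i]; cp[i] = p[i]-c[i]; }
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    double vc = d1*d4 - d3*d2;
    double vb = d5*d2 - d1*d6;
    double va = d3*d6 - d5*d4;
    if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) q[i]=b[i]; w[0]=0;w[1]=1;w[2]=0; }
    else if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) q[i]=c[i]; w[0]=0;w[1]=0;w[2]=1; }
    else if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      for (int i=0;i<3;++i) q[i] = a[i] + t*ab[i];
      w[0]=1-t; w[1]=t; w[2]=0;
    } else if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      for (int i=0;i<3;++i) q[i] = a[i] + t*ac[i];
      w[0]=1-t; w[1]=0; w[2]=t;
    } else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i=0;i<3;++i) q[i] = b[i] + t*(c[i]-b[i]);
      w[0]=0; w[1]=1-t; w[2]=t;
    } else {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, wgt = vc * denom;
      for (int i=0;i<3;++i) q[i] = a[i] + ab[i]*v + ac[i]*wgt;
      w[0]=1-v-wgt; w[1]=v; w[2]=wgt;
    }
  }
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// candidate node-triangle pairs within radius+margin, via uniform hash grid
static void contact_candidates(const std::vector<double>& pos, const ContactSet& cs,
                               double radius, double margin,
                               std::vector<std::pair<int,int> >& pairs) {
  pairs.clear();
  int S = (int)cs.tri.size() / 3;
  if (S == 0) return;
  double cell = 2.0 * (radius + margin);
  std::unordered_map<long long, std::vector<int> > grid;
  auto key = [&](int ix, int iy, int iz) {
    return ((long long)(ix + 1048576) << 42) ^ ((long long)(iy + 1048576) << 21) ^ (long long)(iz + 1048576);
  };
  for (int s = 0; s < S; ++s) {
    double lo[3] = { R_PosInf, R_PosInf, R_PosInf }, hi[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int k = 0; k < 3; ++k) {
      const double* v = &pos[3 * cs.tri[3*s + k]];
      for (int c = 0; c < 3; ++c) { lo[c] = std::min(lo[c], v[c]); hi[c] = std::max(hi[c], v[c]); }
    }
    int i0 = (int)std::floor((lo[0] - radius - margin) / cell), i1 = (int)std::floor((hi[0] + radius + margin) / cell);
    int j0 = (int)std::floor((lo[1] - radius - margin) / cell), j1 = (int)std::floor((hi[1] + radius + margin) / cell);
    int k0 = (int)std::floor((lo[2] - radius - margin) / cell), k1 = (int)std::floor((hi[2] + radius + margin) / cell);
    for (int ix = i0; ix <= i1; ++ix)
      for (int iy = j0; iy <= j1; ++iy)
        for (int iz = k0; iz <= k1; ++iz)
          grid[key(ix, iy, iz)].push_back(s);
  }
  double r2 = (radius + margin) * (radius + margin);
  for (size_t m = 0; m < cs.snodes.size(); ++m) {
    int v = cs.snodes[m];
    const double* p = &pos[3*v];
    int ix = (int)std::floor(p[0] / cell), iy = (int)std::floor(p[1] / cell), iz = (int)std::floor(p[2] / cell);
    auto it = grid.find(key(ix, iy, iz));
    if (it == grid.end()) continue;
    const std::unordered_set<int>& ring = cs.ring.at(v);
    for (int s : it->second) {
      bool adjacent = false;
      for (int k = 0; k < 3; ++k)
        if (ring.count(cs.tri[3*s + k])) { adjacent = true; break; }
      if (adjacent) continue;
      double q[3], w[3];
      double d = closest_point_tri(p, &pos[3*cs.tri[3*s]], &pos[3*cs.tri[3*s+1]],
                                   &pos[3*cs.tri[3*s+2]], q, w);
      if (d * d <= r2) pairs.push_back(std::make_pair(v, s));
    }
  }
}

// apply penalty forces for candidate pairs; returns contact energy
static double apply_contact(const std::vector<double>& pos, const ContactSet& cs,
                            const std::vector<std::pair<int,int> >& pairs,
                            double k, double radius, std::vector<double>& force) {
  double energy = 0.0;
  for (size_t m = 0; m < pairs.size(); ++m) {
    int v = pairs[m].first, s = pairs[m].second;
    const double* p = &pos[3*v];
    double q[3], w[3];
    double d = closest_point_tri(p, &pos[3*cs.tri[3*s]], &pos[3*cs.tri[3*s+1]],
                                 &pos[3*cs.tri[3*s+2]], q, w);
    if (d >= radius || d < 1e-12) continue;
    double fmag = k * (radius - d);
    energy += 0.5 * k * (radius - d) * (radius - d);
    double dir[3] = { (p[0]-q[0])/d, (p[1]-q[1])/d, (p[2]-q[2])/d };
    for (int c = 0; c < 3; ++c) {
      force[3*v + c] += fmag * dir[c];
      for (int kk = 0; kk < 3; ++kk)
        force[3*cs.tri[3*s + kk] + c] -= fmag * dir[c] * w[kk];
    }
  }
  return energy;
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericMatrix positions, IntegerMatrix tris,
                        double k, double radius) {
  int N = positions.nrow();
  std::vector<double> pos(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) pos[3*i + c] = positions(i, c);
  ContactSet cs;
  build_contact_set(tris, cs);
  std::vector<std::pair<int,int> > pairs;
  contact_candidates(pos, cs, radius, 0.0, pairs);
  std::vector<double> force(3 * N, 0.0);
  double en = apply_contact(pos, cs, pairs, k, radius, force);
  NumericMatrix fo(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) fo(i, c) = force[3*i + c];
  return List::create(_["forces"] = fo, _["energy"] = en, _["n_pairs"] = (int)pairs.size());
}

// ---- quasi-static relaxation with linear growth ramp ----
// constraint codes: 0 fixed, 1 free, 2 lateral (project onto plane(s))
// [[Rcpp::export]]
List cpp_relax(NumericMatrix nodes_ref, IntegerMatrix tets,
               NumericVector mu, NumericVector lam,
               NumericMatrix normals, NumericVector gt_final, NumericVector gn_final,
               IntegerVector cons_code, NumericMatrix cons_n1, NumericMatrix cons_n2,
               IntegerMatrix surf_tris,
               double dt, double damping, double contact_k, double contact_radius,
               int contact_rebuild, double tol, int max_steps, int ramp_steps,
               int snapshot_every, int energy_trace_every) {
  int N = nodes_ref.nrow();
  TetData td;
  precompute_tets(nodes_ref, tets, td);
  int M = td.n;

  // lumped mass (unit pseudo-density)
  std::vector<double> mass(N, 0.0);
  for (int e = 0; e < M; ++e)
    for (int a = 0; a < 4; ++a) mass[td.t[4*e + a]] += 0.25 * td.Vref[e];
  for (int i = 0; i < N; ++i) if (mass[i] <= 0) mass[i] = 1.0;

  // auto time step: dt <= alpha * h_min * sqrt(rho / (lam + 2 mu))
  if (dt <= 0) {
    double dt_min = R_PosInf;
    for (int e = 0; e < M; ++e) {
      const int* tt = &td.t[4*e];
      double amax = 0.0;
      const int fc[4][3] = { {1,2,3}, {0,2,3}, {0,1,3}, {0,1,2} };
      for (int fidx = 0; fidx < 4; ++fidx) {
        double u[3], v[3];
        for (int c = 0; c < 3; ++c) {
          u[c] = nodes_ref(tt[fc[fidx][1]], c) - nodes_ref(tt[fc[fidx][0]], c);
          v[c] = nodes_ref(tt[fc[fidx][2]], c) - nodes_ref(tt[fc[fidx][0]], c);
        }
        double cx = u[1]*v[2]-u[2]*v[1], cy = u[2]*v[0]-u[0]*v[2], cz = u[0]*v[1]-u[1]*v[0];
        double area = 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
        if (area > amax) amax = area;
      }
      double h = 3.0 * td.Vref[e] / amax;   // min altitude
      double cw = std::sqrt(lam[e] + 2.0 * mu[e]);
      double dte = h / cw;
      if (dte < dt_min) dt_min = dte;
    }
    dt = 0.5 * dt_min;
  }
  // auto damping: near-critical for the slowest elastic mode of the domain
  if (damping <= 0) {
    double lo[3] = {R_PosInf,R_PosInf,R_PosInf}, hi[3] = {R_NegInf,R_NegInf,R_NegInf};
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(lo[c], nodes_ref(i, c));
        hi[c] = std::max(hi[c], nodes_ref(i, c));
      }
    double L = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) + (hi[2]-lo[2])*(hi[2]-lo[2]));
    double cw = 0.0;
    for (int e = 0; e < M; ++e) cw = std::max(cw, std::sqrt(lam[e] + 2.0 * mu[e]));
    damping = 2.0 * M_PI * cw / std::max(L, 1e-12);
  }
  // force scale for the relative residual test
  double fscale = 0.0, vmean = 0.0;
  for (int e = 0; e < M; ++e) { vmean += td.Vref[e]; }
  vmean /= std::max(M, 1);
  for (int e = 0; e < M; ++e)
    fscale = std::max(fscale, (mu[e] + lam[e]) * std::pow(vmean, 2.0/3.0));
  if (contact_k < 0) {
    double mumax = 0.0;
    for (int e = 0; e < M; ++e) mumax = std::max(mumax, mu[e]);
    contact_k = mumax;
  }

  ContactSet cs;
  bool use_contact = surf_tris.nrow() > 0 && contact_radius > 0;
  if (use_contact) build_contact_set(surf_tris, cs);
  std::vector<std::pair<int,int> > pairs;

  std::vector<double> pos(3 * N), vel(3 * N, 0.0), force(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) pos[3*i + c] = nodes_ref(i, c);

  std::vector<double> Ginv(9 * M), detG(M);
  std::vector<double> diag_energy, diag_contact, diag_maxv, diag_minje, diag_resid, diag_frac;
  std::vector<int> diag_steps, diag_conv;
  std::vector<double> energy_trace;
  List snapshots;
  std::string error_msg = "";

  for (int inc = 1; inc <= ramp_steps && error_msg.empty(); ++inc) {
    double r = (double)inc / ramp_steps;
    for (int e = 0; e < M; ++e) {
      double nvec[3] = { normals(e,0), normals(e,1), normals(e,2) };
      double G[9];
      growth_mat(nvec, r * gt_final[e], r * gn_final[e], G);
      mat3_inv(G, &Ginv[9*e]);
      detG[e] = mat3_det(G);
    }
    double resid = R_PosInf, energy = 0.0, contact_energy = 0.0, maxv = 0.0, minJe = R_PosInf;
    int step = 0;
    bool converged = false;
    for (step = 0; step < max_steps; ++step) {
      std::fill(force.begin(), force.end(), 0.0);
      energy = 0.0; minJe = R_PosInf;
      int bad = -1;
      for (int e = 0; e < M; ++e) {
        const int* tt = &td.t[4*e];
        double f[12];
        double en = tet_response(&pos[3*tt[0]], &pos[3*tt[1]], &pos[3*tt[2]], &pos[3*tt[3]],
                                 &td.Bm[9*e], td.Vref[e], &Ginv[9*e], detG[e], mu[e], lam[e], f);
        if (!std::isfinite(en)) { bad = e; break; }
        energy += en;
        for (int a = 0; a < 4; ++a)
          for (int c = 0; c < 3; ++c) force[3*tt[a] + c] += f[3*a + c];
      }
      if (bad >= 0) {
        error_msg = "element inversion (J_e <= 0) in element " + std::to_string(bad + 1) +
          " at increment " + std::to_string(inc) + " (dt = " + std::to_string(dt) + ")";
        break;
      }
      contact_energy = 0.0;
      if (use_contact) {
        if (step % contact_rebuild == 0)
          contact_candidates(pos, cs, contact_radius, 0.5 * contact_radius, pairs);
        contact_energy = apply_contact(pos, cs, pairs, contact_k, contact_radius, force);
      }
      // constraint projection on forces, residual
      resid = 0.0;
      for (int i = 0; i < N; ++i) {
        if (cons_code[i] == 0) { force[3*i] = force[3*i+1] = force[3*i+2] = 0.0; continue; }
        if (cons_code[i] == 2) {
          double d1 = force[3*i]*cons_n1(i,0) + force[3*i+1]*cons_n1(i,1) + force[3*i+2]*cons_n1(i,2);
          for (int c = 0; c < 3; ++c) force[3*i + c] -= d1 * cons_n1(i, c);
          double n2n = cons_n2(i,0)*cons_n2(i,0) + cons_n2(i,1)*cons_n2(i,1) + cons_n2(i,2)*cons_n2(i,2);
          if (n2n > 0.5) {
            double d2 = force[3*i]*cons_n2(i,0) + force[3*i+1]*cons_n2(i,1) + force[3*i+2]*cons_n2(i,2);
            for (int c = 0; c < 3; ++c) force[3*i + c] -= d2 * cons_n2(i, c);
          }
        }
        double fn = std::sqrt(force[3*i]*force[3*i] + force[3*i+1]*force[3*i+1] + force[3*i+2]*force[3*i+2]);
        if (fn > resid) resid = fn;
      }
      if (energy_trace_every > 0 && step % energy_trace_every == 0)
        energy_trace.push_back(energy + contact_energy);
      if (resid < tol * fscale) { converged = true; break; }
      // semi-implicit Euler with implicit viscous drag
      maxv = 0.0;
      for (int i = 0; i < N; ++i) {
        if (cons_code[i] == 0) { vel[3*i] = vel[3*i+1] = vel[3*i+2] = 0.0; continue; }
        double im = 1.0 / mass[i];
        for (int c = 0; c < 3; ++c) {
          double v = (vel[3*i + c] + dt * force[3*i + c] * im) / (1.0 + damping * dt);
          vel[3*i + c] = v;
        }
        if (cons_code[i] == 2) {
          double d1 = vel[3*i]*cons_n1(i,0) + vel[3*i+1]*cons_n1(i,1) + vel[3*i+2]*cons_n1(i,2);
          for (int c = 0; c < 3; ++c) vel[3*i + c] -= d1 * cons_n1(i, c);
          double n2n = cons_n2(i,0)*cons_n2(i,0) + cons_n2(i,1)*cons_n2(i,1) + cons_n2(i,2)*cons_n2(i,2);
          if (n2n > 0.5) {
            double d2 = vel[3*i]*cons_n2(i,0) + vel[3*i+1]*cons_n2(i,1) + vel[3*i+2]*cons_n2(i,2);
            for (int c = 0; c < 3; ++c) vel[3*i + c] -= d2 * cons_n2(i, c);
          }
        }
        double vn = 0.0;
        for (int c = 0; c < 3; ++c) {
          pos[3*i + c] += dt * vel[3*i + c];
          vn += vel[3*i + c] * vel[3*i + c];
        }
        vn = std::sqrt(vn);
        if (vn > maxv) maxv = vn;
      }
      if (!std::isfinite(maxv)) {
        error_msg = "divergent positions (NaN velocity) at increment " + std::to_string(inc) +
          " (dt = " + std::to_string(dt) + ")";
        break;
      }
    }
    // min Je at end of increment
    for (int e = 0; e < M && error_msg.empty(); ++e) {
      const int* tt = &td.t[4*e];
      double Ds[9], F[9], Fe[9];
      for (int c = 0; c < 3; ++c) {
        Ds[c + 0] = pos[3*tt[1] + c] - pos[3*tt[0] + c];
        Ds[c + 3] = pos[3*tt[2] + c] - pos[3*tt[0] + c];
        Ds[c + 6] = pos[3*tt[3] + c] - pos[3*tt[0] + c];
      }
      mat3_mul(Ds, &td.Bm[9*e], F);
      mat3_mul(F, &Ginv[9*e], Fe);
      double Je = mat3_det(Fe);
      if (Je < minJe) minJe = Je;
    }
    diag_frac.push_back(r);
    diag_energy.push_back(energy);
    diag_contact.push_back(contact_energy);
    diag_maxv.push_back(maxv);
    diag_minje.push_back(minJe);
    diag_resid.push_back(resid);
    diag_steps.push_back(step);
    diag_conv.push_back(converged ? 1 : 0);
    if (snapshot_every > 0 && (inc % snapshot_every == 0 || inc == ramp_steps)) {
      NumericMatrix snap(N, 3);
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) snap(i, c) = pos[3*i + c];
      snapshots.push_back(snap);
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix posOut(N, 3), velOut(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) { posOut(i, c) = pos[3*i + c]; velOut(i, c) = vel[3*i + c]; }
  DataFrame diag = DataFrame::create(
    _["increment"] = seq_len((int)diag_frac.size()),
    _["ramp_fraction"] = diag_frac,
    _["elastic_energy"] = diag_energy,
    _["contact_energy"] = diag_contact,
    _["max_velocity"] = diag_maxv,
    _["min_Je"] = diag_minje,
    _["residual"] = diag_resid,
    _["steps"] = diag_steps,
    _["converged"] = diag_conv);
  return List::create(
    _["positions"] = posOut, _["velocities"] = velOut,
    _["diagnostics"] = diag, _["snapshots"] = snapshots,
    _["dt"] = dt, _["damping"] = damping, _["force_scale"] = fscale,
    _["contact_k"] = contact_k,
    _["energy_trace"] = energy_trace,
    _["error"] = error_msg);
}
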