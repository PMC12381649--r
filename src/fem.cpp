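#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Explicit quasi-static (dynamic relaxation) FEM for differential tangential
// growth of a bilayer brain mesh. Linear tetrahedra, neo-Hookean energy
//   W = mu/2 (Je^{-2/3} tr(Fe^T Fe) - 3) + k/2 (Je - 1)^2
// with multiplicative growth F = Fe Fg:
//   cortex: Fg = theta I + (1 - theta) n0 (x) n0   (in-plane stretch theta)
//   white : Fg = theta^{1/3} I                     (volumetric factor theta)
// Nodal forces from the first Piola stress P = Jg * (dW/dFe) Fg^{-T}.
// A follower pressure acts on the pial boundary faces and a node-to-triangle
// penalty prevents fold self-intersection on the pial surface.

static inline double det3(const double M[9]) {
  return M[0]*(M[4]*M[8]-M[5]*M[7]) - M[1]*(M[3]*M[8]-M[5]*M[6])
       + M[2]*(M[3]*M[7]-M[4]*M[6]);
}

static inline void inv3(const double M[9], double out[9]) {
  double d = det3(M);
  double id = 1.0 / d;
  out[0] =  (M[4]*M[8]-M[5]*M[7])*id;
  out[1] = -(M[1]*M[8]-M[2]*M[7])*id;
  out[2] =  (M[1]*M[5]-M[2]*M[4])*id;
  out[3] = -(M[3]*M[8]-M[5]*M[6])*id;
  out[4] =  (M[0]*M[8]-M[2]*M[6])*id;
  out[5] = -(M[0]*M[5]-M[2]*M[3])*id;
  out[6] =  (M[3]*M[7]-M[4]*M[6])*id;
  out[7] = -(M[0]*M[7]-M[1]*M[6])*id;
  out[8] =  (M[0]*M[4]-M[1]*M[3])*id;
}

static inline void matmul(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[3*i+k]*B[3*k+j];
      C[3*i+j] = s;
    }
}

struct ContactPair { int v; int f; };

// closest point on triangle (a,b,c) to p -> cp, returns barycentric in w
static void closestPointTri(const double* p, const double* a, const double* b,
                            const double* c, double* cp, double* w) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for(int i=0;i<3;++i) cp[i]=a[i]; w[0]=1;w[1]=0;w[2]=0; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for(int i=0;i<3;++i) cp[i]=b[i]; w[0]=0;w[1]=1;w[2]=0; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1/(d1-d3);
    for(int i=0;i<3;++i) cp[i]=a[i]+t*ab[i];
    w[0]=1-t;w[1]=t;w[2]=0; return;
  }
  double cpv[3]; for (int i=0;i<3;++i) cpv[i]=p[i]-c[i];
  double d5 = ab[0]*cpv[0]+ab[1]*cpv[1]+ab[2]*cpv[2];
  double d6 = ac[0]*cpv[0]+ac[1]*cpv[1]+ac[2]*cpv[2];
  if (d6 >= 0 && d5 <= d6) { for(int i=0;i<3;++i) cp[i]=c[i]; w[0]=0;w[1]=0;w[2]=1; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2/(d2-d6);
    for(int i=0;i<3;++i) cp[i]=a[i]+t*ac[i];
    w[0]=1-t;w[1]=0;w[2]=t; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    double t = (d4-d3)/((d4-d3)+(d5-d6));
    for(int i=0;i<3;++i) cp[i]=b[i]+t*(c[i]-b[i]);
    w[0]=0;w[1]=1-t;w[2]=t; return;
  }
  double denom = 1.0/(va+vb+vc);
  double v = vb*denom, u = vc*denom;
  for(int i=0;i<3;++i) cp[i]=a[i]+ab[i]*u+ac[i]*v;
  w[0]=1-u-v; w[1]=u; w[2]=v;
}

// [[Rcpp::export]]
List cpp_simulate_growth(NumericMatrix nodes0, IntegerMatrix tets,
                         IntegerVector region, NumericMatrix n0mat,
                         IntegerMatrix pialFaces, IntegerVector pialVerts,
                         List exclRings, List par) {
  const int N = nodes0.nrow(), M = tets.nrow(), P = pialFaces.nrow();
  const double mu = as<double>(par["mu"]);
  const double kb = as<double>(par["kbulk"]);
  const double Gctx = as<double>(par["Gctx"]);
  const double Gsub = as<double>(par["Gsub"]);
  const double pressure = as<double>(par["pressure"]);
  const double t_end = as<double>(par["t_end"]);
  const int n_steps = as<int>(par["n_steps"]);
  const int n_snap = as<int>(par["n_snapshots"]);
  const double damp = as<double>(par["damp"]);
  const double cfl = as<double>(par["cfl"]);
  const int settle_steps = as<int>(par["settle_steps"]);
  const double settle_tol = as<double>(par["settle_tol"]);
  const bool contact_on = as<bool>(par["contact"]);
  const double gap = as<double>(par["contact_gap"]);
  const double kc = as<double>(par["contact_stiff"]);
  const int contact_every = as<int>(par["contact_every"]);
  const double vol_target = as<double>(par["vol_target"]); // NA -> disabled
  const double vol_tol = as<double>(par["vol_tol"]);

  const double dt = t_end / n_steps;

  // reference geometry
  std::vector<double> X(3*N), Vel(3*N, 0.0), Fc(3*N, 0.0), Mass(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < 3; ++j) X[3*i+j] = nodes0(i, j);

  std::vector<double> DmInv(9*M), V0(M);
  std::vector<int> T4(4*M);
  double hmin = 1e30, totV0w = 0.0;
  for (int e = 0; e < M; ++e) {
    for (int j = 0; j < 4; ++j) T4[4*e+j] = tets(e, j) - 1;
    double Dm[9];
    int a = T4[4*e], b = T4[4*e+1], c = T4[4*e+2], d = T4[4*e+3];
    for (int i = 0; i < 3; ++i) {
      Dm[3*i+0] = nodes0(b,i) - nodes0(a,i);
      Dm[3*i+1] = nodes0(c,i) - nodes0(a,i);
      Dm[3*i+2] = nodes0(d,i) - nodes0(a,i);
    }
    double vol = det3(Dm) / 6.0;
    if (vol <= 0) {
      return List::create(_["ok"] = false,
        _["message"] = "non-positive reference tet volume at element " +
                       std::to_string(e + 1));
    }
    V0[e] = vol;
    if (region[e] == 2) totV0w += vol;
    inv3(Dm, &DmInv[9*e]);
    // min altitude = 3 V / max face area
    double maxA = 0.0;
    const int fi[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
    for (int f = 0; f < 4; ++f) {
      int p0 = T4[4*e+fi[f][0]], p1 = T4[4*e+fi[f][1]], p2 = T4[4*e+fi[f][2]];
      double u[3], v[3];
      for (int i = 0; i < 3; ++i) {
        u[i] = nodes0(p1,i) - nodes0(p0,i);
        v[i] = nodes0(p2,i) - nodes0(p0,i);
      }
      double cx = u[1]*v[2]-u[2]*v[1], cy = u[2]*v[0]-u[0]*v[2], cz = u[0]*v[1]-u[1]*v[0];
      double A = 0.5*std::sqrt(cx*cx+cy*cy+cz*cz);
      if (A > maxA) maxA = A;
    }
    double h = 3.0*vol/maxA;
    if (h < hmin) hmin = h;
  }

  // mass scaling: fictitious density such that the explicit step is stable
  double cwave2_per_rho = kb + 4.0*mu/3.0; // c^2 * rho
  double rho = cwave2_per_rho * (dt*dt) / (cfl*cfl*hmin*hmin);
  for (int e = 0; e < M; ++e) {
    double m = rho * V0[e] / 4.0;
    for (int j = 0; j < 4; ++j) Mass[T4[4*e+j]] += m;
  }

  // contact bookkeeping
  std::vector<int> pv(pialVerts.size());
  for (int i = 0; i < (int)pv.size(); ++i) pv[i] = pialVerts[i] - 1;
  std::unordered_map<int,int> pvLocal;
  for (int i = 0; i < (int)pv.size(); ++i) pvLocal[pv[i]] = i;
  std::vector<std::vector<int>> excl(pv.size());
  if (contact_on) {
    for (int i = 0; i < (int)pv.size(); ++i) {
      IntegerVector e = exclRings[i];
      excl[i].assign(e.begin(), e.end());
      for (auto& x : excl[i]) x -= 1;
      std::sort(excl[i].begin(), excl[i].end());
    }
  }
  std::vector<ContactPair> cpairs;

  auto rebuildContacts = [&]() {
    cpairs.clear();
    double cell = std::max(3.0*gap, 1e-6);
    double margin = 2.0*gap;
    std::unordered_map<long long, std::vector<int>> grid;
    auto key = [&](double x, double y, double z) {
      long long ix = (long long)std::floor(x/cell);
      long long iy = (long long)std::floor(y/cell);
      long long iz = (long long)std::floor(z/cell);
      return ((ix*73856093LL) ^ (iy*19349663LL) ^ (iz*83492791LL));
    };
    for (int i = 0; i < (int)pv.size(); ++i) {
      int g = pv[i];
      grid[key(X[3*g], X[3*g+1], X[3*g+2])].push_back(i);
    }
    for (int f = 0; f < P; ++f) {
      int a = pialFaces(f,0)-1, b = pialFaces(f,1)-1, c = pialFaces(f,2)-1;
      double cx = (X[3*a]+X[3*b]+X[3*c])/3.0;
      double cy = (X[3*a+1]+X[3*b+1]+X[3*c+1])/3.0;
      double cz = (X[3*a+2]+X[3*b+2]+X[3*c+2])/3.0;
      // face circumradius-ish bound
      double r2max = 0;
      for (int vtx : {a,b,c}) {
        double dx=X[3*vtx]-cx, dy=X[3*vtx+1]-cy, dz=X[3*vtx+2]-cz;
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 > r2max) r2max = r2;
      }
      double rad = std::sqrt(r2max) + margin;
      int nc = (int)std::ceil(rad/cell);
      for (int ix = -nc; ix <= nc; ++ix)
        for (int iy = -nc; iy <= nc; ++iy)
          for (int iz = -nc; iz <= nc; ++iz) {
            auto it = grid.find(key(cx+ix*cell, cy+iy*cell, cz+iz*cell));
            if (it == grid.end()) continue;
            for (int li : it->second) {
              int g = pv[li];
              if (g == a || g == b || g == c) continue;
              const std::vector<int>& ex = excl[li];
              if (std::binary_search(ex.begin(), ex.end(), a) ||
                  std::binary_search(ex.begin(), ex.end(), b) ||
                  std::binary_search(ex.begin(), ex.end(), c)) continue;
              double dx=X[3*g]-cx, dy=X[3*g+1]-cy, dz=X[3*g+2]-cz;
              if (dx*dx+dy*dy+dz*dz < (rad)*(rad)) cpairs.push_back({g, f});
            }
          }
    }
  };

  double theta_ctx = 1.0, theta_sub = 1.0;
  double SE = 0.0, KE = 0.0;
  bool inverted = false;
  std::string msg = "ok";

  // one explicit step; grow==false freezes the growth multipliers
  auto step = [&](bool grow) {
    if (grow) { theta_ctx += Gctx*dt; theta_sub += Gsub*dt; }
    std::fill(Fc.begin(), Fc.end(), 0.0);
    SE = 0.0;
    double th_c = theta_ctx, th_w = theta_sub;
    double wpow = std::cbrt(th_w);
    for (int e = 0; e < M && !inverted; ++e) {
      int a = T4[4*e], b = T4[4*e+1], c = T4[4*e+2], d = T4[4*e+3];
      double Ds[9];
      for (int i = 0; i < 3; ++i) {
        Ds[3*i+0] = X[3*b+i]-X[3*a+i];
        Ds[3*i+1] = X[3*c+i]-X[3*a+i];
        Ds[3*i+2] = X[3*d+i]-X[3*a+i];
      }
      double F[9];
      matmul(Ds, &DmInv[9*e], F);
      double Fe[9], Jg;
      double FgInv[9]; // symmetric for both materials
      if (region[e] == 1) {
        const double nx = n0mat(e,0), ny = n0mat(e,1), nz = n0mat(e,2);
        double it = 1.0/th_c, co = 1.0 - it;
        FgInv[0] = it + co*nx*nx; FgInv[1] = co*nx*ny;      FgInv[2] = co*nx*nz;
        FgInv[3] = co*ny*nx;      FgInv[4] = it + co*ny*ny; FgInv[5] = co*ny*nz;
        FgInv[6] = co*nz*nx;      FgInv[7] = co*nz*ny;      FgInv[8] = it + co*nz*nz;
        Jg = th_c*th_c;
        matmul(F, FgInv, Fe);
      } else {
        double s = 1.0/wpow;
        for (int i = 0; i < 9; ++i) Fe[i] = F[i]*s;
        FgInv[0]=FgInv[4]=FgInv[8]=s; FgInv[1]=FgInv[2]=FgInv[3]=0;
        FgInv[5]=FgInv[6]=FgInv[7]=0;
        Jg = th_w;
      }
      double Je = det3(Fe);
      if (Je <= 0) { inverted = true; msg = "element inversion"; break; }
      double FeInv[9]; inv3(Fe, FeInv);
      double trC = 0; for (int i = 0; i < 9; ++i) trC += Fe[i]*Fe[i];
      double cb = std::cbrt(Je);
      double Jm23 = 1.0/(cb*cb);
      // P_e = mu Je^{-2/3} (Fe - trC/3 Fe^{-T}) + k (Je-1) Je Fe^{-T}
      double Pe[9];
      double coefT = -mu*Jm23*trC/3.0 + kb*(Je-1.0)*Je;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          Pe[3*i+j] = mu*Jm23*Fe[3*i+j] + coefT*FeInv[3*j+i];
      double Pt[9];
      matmul(Pe, FgInv, Pt); // Fg^{-T} = Fg^{-1} (symmetric)
      for (int i = 0; i < 9; ++i) Pt[i] *= Jg;
      // nodal forces: f_j = -V0 * (P DmInv^T) e_j, H_{ij} = sum_k P_{ik} DmInv_{jk}
      double H[9];
      const double* DI = &DmInv[9*e];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          H[3*i+j] = Pt[3*i+0]*DI[3*j+0] + Pt[3*i+1]*DI[3*j+1] + Pt[3*i+2]*DI[3*j+2];
      double v0 = V0[e];
      for (int i = 0; i < 3; ++i) {
        double f1 = -v0*H[3*i+0], f2 = -v0*H[3*i+1], f3 = -v0*H[3*i+2];
        Fc[3*b+i] += f1; Fc[3*c+i] += f2; Fc[3*d+i] += f3;
        Fc[3*a+i] -= (f1+f2+f3);
      }
      double W = 0.5*mu*(Jm23*trC - 3.0) + 0.5*kb*(Je-1.0)*(Je-1.0);
      SE += v0*Jg*W;
    }
    if (inverted) return;
    // follower pressure on pial faces (inward)
    if (pressure != 0.0) {
      for (int f = 0; f < P; ++f) {
        int a = pialFaces(f,0)-1, b = pialFaces(f,1)-1, c = pialFaces(f,2)-1;
        double u[3], v[3];
        for (int i = 0; i < 3; ++i) {
          u[i] = X[3*b+i]-X[3*a+i];
          v[i] = X[3*c+i]-X[3*a+i];
        }
        double nx = 0.5*(u[1]*v[2]-u[2]*v[1]);
        double ny = 0.5*(u[2]*v[0]-u[0]*v[2]);
        double nz = 0.5*(u[0]*v[1]-u[1]*v[0]);
        double s = -pressure/3.0;
        Fc[3*a+0]+=s*nx; Fc[3*a+1]+=s*ny; Fc[3*a+2]+=s*nz;
        Fc[3*b+0]+=s*nx; Fc[3*b+1]+=s*ny; Fc[3*b+2]+=s*nz;
        Fc[3*c+0]+=s*nx; Fc[3*c+1]+=s*ny; Fc[3*c+2]+=s*nz;
      }
    }
    // penalty self-contact
    if (contact_on) {
      for (const ContactPair& cp : cpairs) {
        int a = pialFaces(cp.f,0)-1, b = pialFaces(cp.f,1)-1, c = pialFaces(cp.f,2)-1;
        double pa[3] = {X[3*a],X[3*a+1],X[3*a+2]};
        double pb[3] = {X[3*b],X[3*b+1],X[3*b+2]};
        double pc[3] = {X[3*c],X[3*c+1],X[3*c+2]};
        double pp[3] = {X[3*cp.v],X[3*cp.v+1],X[3*cp.v+2]};
        double cpnt[3], w[3];
        closestPointTri(pp, pa, pb, pc, cpnt, w);
        double r[3] = {pp[0]-cpnt[0], pp[1]-cpnt[1], pp[2]-cpnt[2]};
        double d2 = r[0]*r[0]+r[1]*r[1]+r[2]*r[2];
        if (d2 >= gap*gap) continue;
        // outward face normal decides the push direction so that a vertex
        // that has just crossed the face is still pushed back outside
        double e1[3], e2[3];
        for (int i = 0; i < 3; ++i) { e1[i]=pb[i]-pa[i]; e2[i]=pc[i]-pa[i]; }
        double nf[3] = {e1[1]*e2[2]-e1[2]*e2[1],
                        e1[2]*e2[0]-e1[0]*e2[2],
                        e1[0]*e2[1]-e1[1]*e2[0]};
        double nl = std::sqrt(nf[0]*nf[0]+nf[1]*nf[1]+nf[2]*nf[2]);
        if (nl < 1e-20) continue;
        for (int i = 0; i < 3; ++i) nf[i] /= nl;
        double dist = std::sqrt(d2);
        double sgn = r[0]*nf[0]+r[1]*nf[1]+r[2]*nf[2];
        double nr[3];
        if (sgn >= 0 && dist > 1e-10) {
          nr[0]=r[0]/dist; nr[1]=r[1]/dist; nr[2]=r[2]/dist;
        } else {
          nr[0]=nf[0]; nr[1]=nf[1]; nr[2]=nf[2];
        }
        double pen = std::min(gap - (sgn >= 0 ? dist : -dist), 2.0*gap);
        double fmag = kc * pen;
        for (int i = 0; i < 3; ++i) {
          double fi_ = fmag*nr[i];
          Fc[3*cp.v+i] += fi_;
          Fc[3*a+i] -= w[0]*fi_;
          Fc[3*b+i] -= w[1]*fi_;
          Fc[3*c+i] -= w[2]*fi_;
        }
      }
    }
    // damped explicit update
    KE = 0.0;
    for (int i = 0; i < N; ++i) {
      double m = Mass[i];
      for (int j = 0; j < 3; ++j) {
        double v = damp*Vel[3*i+j] + dt*Fc[3*i+j]/m;
        Vel[3*i+j] = v;
        X[3*i+j] += dt*v;
      }
      KE += 0.5*m*(Vel[3*i]*Vel[3*i]+Vel[3*i+1]*Vel[3*i+1]+Vel[3*i+2]*Vel[3*i+2]);
    }
  };

  auto whiteVol = [&]() {
    double tv = 0;
    for (int e = 0; e < M; ++e) {
      if (region[e] != 2) continue;
      int a = T4[4*e], b = T4[4*e+1], c = T4[4*e+2], d = T4[4*e+3];
      double Ds[9];
      for (int i = 0; i < 3; ++i) {
        Ds[3*i+0] = X[3*b+i]-X[3*a+i];
        Ds[3*i+1] = X[3*c+i]-X[3*a+i];
        Ds[3*i+2] = X[3*d+i]-X[3*a+i];
      }
      tv += det3(Ds)/6.0;
    }
    return tv;
  };

  auto settle = [&]() {
    for (int s = 0; s < settle_steps && !inverted; ++s) {
      if (contact_on && s % contact_every == 0) rebuildContacts();
      step(false);
      if (s % 50 == 49 && KE < settle_tol * (SE + 1e-12)) break;
    }
  };

  List snaps(n_snap);
  int per = n_steps / n_snap;
  int snap_i = 0;
  int stepcount = 0;

  auto record = [&](int idx) {
    NumericMatrix nd(N, 3);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < 3; ++j) nd(i, j) = X[3*i+j];
    // per-element elastic jacobian + Cauchy stress Frobenius norm
    NumericVector jev(M), stf(M);
    double th_c = theta_ctx, wpow = std::cbrt(theta_sub);
    for (int e = 0; e < M; ++e) {
      int a = T4[4*e], b = T4[4*e+1], c = T4[4*e+2], d = T4[4*e+3];
      double Ds[9];
      for (int i = 0; i < 3; ++i) {
        Ds[3*i+0] = X[3*b+i]-X[3*a+i];
        Ds[3*i+1] = X[3*c+i]-X[3*a+i];
        Ds[3*i+2] = X[3*d+i]-X[3*a+i];
      }
      double F[9]; matmul(Ds, &DmInv[9*e], F);
      double Fe[9];
      if (region[e] == 1) {
        const double nx = n0mat(e,0), ny = n0mat(e,1), nz = n0mat(e,2);
        double it = 1.0/th_c, co = 1.0 - it;
        double FgInv[9] = {it+co*nx*nx, co*nx*ny, co*nx*nz,
                           co*ny*nx, it+co*ny*ny, co*ny*nz,
                           co*nz*nx, co*nz*ny, it+co*nz*nz};
        matmul(F, FgInv, Fe);
      } else {
        double s = 1.0/wpow;
        for (int i = 0; i < 9; ++i) Fe[i] = F[i]*s;
      }
      double Je = det3(Fe);
      jev[e] = Je;
      if (Je > 0) {
        double trB = 0; for (int i = 0; i < 9; ++i) trB += Fe[i]*Fe[i];
        double cb = std::cbrt(Je);
        double Jm23 = 1.0/(cb*cb);
        // T = mu/Je * Je^{-2/3} dev(B) + k (Je-1) I, B = Fe Fe^T
        double B[9];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            B[3*i+j] = Fe[3*i]*Fe[3*j] + Fe[3*i+1]*Fe[3*j+1] + Fe[3*i+2]*Fe[3*j+2];
        double s2 = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double dev = B[3*i+j] - (i==j ? trB/3.0 : 0.0);
            double Tij = mu/Je*Jm23*dev + ((i==j) ? kb*(Je-1.0) : 0.0);
            s2 += Tij*Tij;
          }
        stf[e] = std::sqrt(s2);
      } else stf[e] = NA_REAL;
    }
    snaps[idx] = List::create(
      _["nodes"] = nd, _["theta_ctx"] = theta_ctx, _["theta_sub"] = theta_sub,
      _["je"] = jev, _["stress_norm"] = stf,
      _["kinetic_energy"] = KE, _["strain_energy"] = SE,
      _["white_volume_ratio"] = (totV0w > 0 ? whiteVol()/totV0w : NA_REAL),
      _["time"] = stepcount * dt);
  };

  for (int s = 0; s < n_steps && !inverted; ++s) {
    if (contact_on && s % contact_every == 0) rebuildContacts();
    step(true);
    ++stepcount;
    if ((s+1) % per == 0 && snap_i < n_snap) {
      settle();
      if (inverted) break;
      record(snap_i++);
    }
  }

  // volume-ratio stop criterion: keep growing (same rates) until the deformed
  // white-matter volume reaches the target within tolerance
  if (!inverted && !ISNA(vol_target) && totV0w > 0) {
    for (int round = 0; round < 5 && !inverted; ++round) {
      double ratio = whiteVol()/totV0w;
      if (ratio >= vol_target*(1.0 - vol_tol)) break;
      double dtheta = vol_target - ratio;
      int extra = std::max(50, (int)std::ceil(dtheta/(Gsub*dt)));
      for (int s = 0; s < extra && !inverted; ++s) {
        if (contact_on && s % contact_every == 0) rebuildContacts();
        step(true);
        ++stepcount;
      }
      settle();
      if (!inverted && snap_i > 0) record(snap_i - 1);
    }
  }

  while (snap_i < n_snap && !inverted) { settle(); record(snap_i++); }

  return List::create(
    _["ok"] = !inverted, _["message"] = msg, _["snapshots"] = snaps,
    _["theta_ctx"] = theta_ctx, _["theta_sub"] = theta_sub,
    _["dt"] = dt, _["rho"] = rho, _["hmin"] = hmin,
    _["n_steps_total"] = stepcount);
}
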