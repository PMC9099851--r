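// Stabilized P1-P1 finite-element assembly for steady incompressible
// Navier-Stokes (kinematic pressure form): Galerkin terms plus PSPG/SUPG
// stabilization with element-constant convection velocity. Returns the
// linearized operator (Picard or Newton) as triplets together with the
// nonlinear residual at the supplied state.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ns_assemble(NumericMatrix nodes, IntegerMatrix tri,
                 NumericVector u, NumericVector v, NumericVector p,
                 double nu, bool newton, LogicalVector isdir,
                 bool want_jacobian) {
  const int n = nodes.nrow(), m = tri.nrow();
  std::vector<int> ti; std::vector<int> tj; std::vector<double> tx;
  if (want_jacobian) {
    ti.reserve((size_t)m * 81); tj.reserve((size_t)m * 81); tx.reserve((size_t)m * 81);
  }
  NumericVector F(3 * n);

  for (int k = 0; k < m; ++k) {
    int i0 = tri(k, 0) - 1, i1 = tri(k, 1) - 1, i2 = tri(k, 2) - 1;
    int id[3] = {i0, i1, i2};
    double xx[3], yy[3];
    for (int e = 0; e < 3; ++e) { xx[e] = nodes(id[e], 0); yy[e] = nodes(id[e], 1); }
    double det = (xx[1] - xx[0]) * (yy[2] - yy[0]) - (xx[2] - xx[0]) * (yy[1] - yy[0]);
    double A = 0.5 * det;
    if (A <= 0) stop("ns_assemble: inverted element");
    // P1 shape-gradient components
    double bx[3], by[3];
    bx[0] = (yy[1] - yy[2]) / det; by[0] = (xx[2] - xx[1]) / det;
    bx[1] = (yy[2] - yy[0]) / det; by[1] = (xx[0] - xx[2]) / det;
    bx[2] = (yy[0] - yy[1]) / det; by[2] = (xx[1] - xx[0]) / det;

    double ue[3], ve[3], pe[3];
    for (int e = 0; e < 3; ++e) {
      ue[e] = u[id[e]]; ve[e] = v[id[e]]; pe[e] = p[id[e]];
    }
    double am = (ue[0] + ue[1] + ue[2]) / 3.0;   // element-mean velocity
    double bm = (ve[0] + ve[1] + ve[2]) / 3.0;
    double pm = (pe[0] + pe[1] + pe[2]) / 3.0;
    double gux = 0, guy = 0, gvx = 0, gvy = 0, gpx = 0, gpy = 0;
    for (int e = 0; e < 3; ++e) {
      gux += ue[e] * bx[e]; guy += ue[e] * by[e];
      gvx += ve[e] * bx[e]; gvy += ve[e] * by[e];
      gpx += pe[e] * bx[e]; gpy += pe[e] * by[e];
    }
    double h = std::sqrt(4.0 * A / std::sqrt(3.0));
    double un = std::sqrt(am * am + bm * bm);
    double inv1 = 2.0 * un / h, inv2 = 12.0 * nu / (h * h);
    double tau = 1.0 / std::sqrt(inv1 * inv1 + inv2 * inv2);
    // momentum residual (element constant; viscous part vanishes for P1)
    double Rx = am * gux + bm * guy + gpx;
    double Ry = am * gvx + bm * gvy + gpy;

    for (int i = 0; i < 3; ++i) {
      int ru = id[i], rv = n + id[i], rp = 2 * n + id[i];
      double advW = am * bx[i] + bm * by[i];     // a . grad(phi_i)
      // residuals
      if (!isdir[ru]) {
        F[ru] += A * (nu * (bx[i] * gux + by[i] * guy)
                      + (am * gux + bm * guy) / 3.0
                      - bx[i] * pm
                      + tau * advW * Rx);
      }
      if (!isdir[rv]) {
        F[rv] += A * (nu * (bx[i] * gvx + by[i] * gvy)
                      + (am * gvx + bm * gvy) / 3.0
                      - by[i] * pm
                      + tau * advW * Ry);
      }
      if (!isdir[rp]) {
        F[rp] += A * ((gux + gvy) / 3.0
                      + tau * (bx[i] * Rx + by[i] * Ry));
      }
      if (!want_jacobian) continue;
      for (int j = 0; j < 3; ++j) {
        int cu = id[j], cv = n + id[j], cp = 2 * n + id[j];
        double advT = am * bx[j] + bm * by[j];   // a . grad(phi_j)
        double lap = bx[i] * bx[j] + by[i] * by[j];
        if (!isdir[ru]) {
          double Juu = A * (nu * lap + advT / 3.0 + tau * advW * advT);
          if (newton) Juu += A * (gux / 9.0 + tau * advW * gux / 3.0);
          double Juv = 0.0;
          if (newton) Juv = A * (guy / 9.0 + tau * advW * guy / 3.0);
          double Jup = A * (-bx[i] / 3.0 + tau * advW * bx[j]);
          ti.push_back(ru + 1); tj.push_back(cu + 1); tx.push_back(Juu);
          if (Juv != 0.0) { ti.push_back(ru + 1); tj.push_back(cv + 1); tx.push_back(Juv); }
          ti.push_back(ru + 1); tj.push_back(cp + 1); tx.push_back(Jup);
        }
        if (!isdir[rv]) {
          double Jvv = A * (nu * lap + advT / 3.0 + tau * advW * advT);
          if (newton) Jvv += A * (gvy / 9.0 + tau * advW * gvy / 3.0);
          double Jvu = 0.0;
          if (newton) Jvu = A * (gvx / 9.0 + tau * advW * gvx / 3.0);
          double Jvp = A * (-by[i] / 3.0 + tau * advW * by[j]);
          if (Jvu != 0.0) { ti.push_back(rv + 1); tj.push_back(cu + 1); tx.push_back(Jvu); }
          ti.push_back(rv + 1); tj.push_back(cv + 1); tx.push_back(Jvv);
          ti.push_back(rv + 1); tj.push_back(cp + 1); tx.push_back(Jvp);
        }
        if (!isdir[rp]) {
          double Jpu = A * (bx[j] / 3.0 + tau * bx[i] * advT);
          double Jpv = A * (by[j] / 3.0 + tau * by[i] * advT);
          double Jpp = A * tau * lap;
          ti.push_back(rp + 1); tj.push_back(cu + 1); tx.push_back(Jpu);
          ti.push_back(rp + 1); tj.push_back(cv + 1); tx.push_back(Jpv);
          ti.push_back(rp + 1); tj.push_back(cp + 1); tx.push_back(Jpp);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["F"] = F);
}

// Element-wise shear-rate magnitude sqrt(2 D:D) and element areas from a
// P1 velocity field.
// [[Rcpp::export]]
List shear_rate_elements(NumericMatrix nodes, IntegerMatrix tri,
                         NumericVector u, NumericVector v) {
  const int m = tri.nrow();
  NumericVector gam(m), area(m), cx(m), cy(m);
  for (int k = 0; k < m; ++k) {
    int id[3] = {tri(k, 0) - 1, tri(k, 1) - 1, tri(k, 2) - 1};
    double xx[3], yy[3];
    for (int e = 0; e < 3; ++e) { xx[e] = nodes(id[e], 0); yy[e] = nodes(id[e], 1); }
    double det = (xx[1] - xx[0]) * (yy[2] - yy[0]) - (xx[2] - xx[0]) * (yy[1] - yy[0]);
    double bx[3], by[3];
    bx[0] = (yy[1] - yy[2]) / det; by[0] = (xx[2] - xx[1]) / det;
    bx[1] = (yy[2] - yy[0]) / det; by[1] = (xx[0] - xx[2]) / det;
    bx[2] = (yy[0] - yy[1]) / det; by[2] = (xx[1] - xx[0]) / det;
    double gux = 0, guy = 0, gvx = 0, gvy = 0;
    for (int e = 0; e < 3; ++e) {
      gux += u[id[e]] * bx[e]; guy += u[id[e]] * by[e];
      gvx += v[id[e]] * bx[e]; gvy += v[id[e]] * by[e];
    }
    double sq = 2.0 * (gux * gux + gvy * gvy) + (guy + gvx) * (guy + gvx);
    gam[k] = std::sqrt(sq);
    area[k] = 0.5 * det;
    cx[k] = (xx[0] + xx[1] + xx[2]) / 3.0;
    cy[k] = (yy[0] + yy[1] + yy[2]) / 3.0;
  }
  return List::create(_["gamma"] = gam, _["area"] = area,
                      _["cx"] = cx, _["cy"] = cy);
}
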