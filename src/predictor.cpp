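#include <Rcpp.h>
using namespace Rcpp;

// Explicit predictor for one staggered velocity component on a masked
// voxel grid: central diffusion with linear-reflection no-slip ghosts and
// first-order upwind advection, evaluated only at the fluid faces.
//
// F        : face array of the component being advanced (column-major)
// fd       : its dims (3)
// compAxis : 1-based axis of the component (1 = u, 2 = v, 3 = w)
// O1, O2   : face arrays of the other two components (may be empty)
// o1d, o2d : their dims; o1ax/o2ax their 1-based component axes
// kp*, km* : per-axis known-neighbour masks at the F faces (0/1; length 0
//            marks an inactive axis, e.g. z on planar grids)
// fluidIdx : 1-based linear indices of the fluid faces to update
//
// Neighbour semantics match the R reference implementation: a neighbour
// face that is not known (wall beyond a half-cell, or outside the domain)
// contributes the ghost value -F (no-slip at the midway wall).

static inline double faceAvg(const NumericVector &O, const int *od,
                             int cAx, int oAx, int c0, int c1, int c2) {
  int co[3] = {c0, c1, c2};
  double s = 0.0;
  for (int da = 0; da < 2; ++da) {
    int a = co[cAx] - 1 + da;          // cell index along the target's axis
    if (a < 0 || a >= od[cAx]) continue; // outside: face value 0
    for (int db = 0; db < 2; ++db) {
      int b = co[oAx] + db;            // face index along the other's axis
      int ix[3] = {co[0], co[1], co[2]};
      ix[cAx] = a;
      ix[oAx] = b;
      s += O[ix[0] + od[0] * (ix[1] + od[1] * ix[2])];
    }
  }
  return s / 4.0;
}

// [[Rcpp::export(name = ".predictFaceCpp")]]
NumericVector predictFaceCpp(NumericVector F, IntegerVector fd, int compAxis,
                             NumericVector O1, IntegerVector o1d, int o1ax,
                             NumericVector O2, IntegerVector o2d, int o2ax,
                             NumericVector kpx, NumericVector kmx,
                             NumericVector kpy, NumericVector kmy,
                             NumericVector kpz, NumericVector kmz,
                             IntegerVector fluidIdx,
                             double h, double nu, double dt) {
  const int n1 = fd[0], n2 = fd[1], n3 = fd[2];
  const int cAx = compAxis - 1;
  const int od1[3] = {o1d.size() ? o1d[0] : 0, o1d.size() ? o1d[1] : 0,
                      o1d.size() ? o1d[2] : 0};
  const int od2[3] = {o2d.size() ? o2d[0] : 0, o2d.size() ? o2d[1] : 0,
                      o2d.size() ? o2d[2] : 0};
  const NumericVector *kp[3] = {&kpx, &kpy, &kpz};
  const NumericVector *km[3] = {&kmx, &kmy, &kmz};
  const int stride[3] = {1, n1, n1 * n2};
  const int nf[3] = {n1, n2, n3};
  NumericVector out = clone(F);
  const double ih = 1.0 / h, ih2 = nu / (h * h);

  for (int t = 0; t < fluidIdx.size(); ++t) {
    const int f = fluidIdx[t] - 1;
    const int i = f % n1;
    const int j = (f / n1) % n2;
    const int k = f / (n1 * n2);
    const int co[3] = {i, j, k};
    const double Fc = F[f];
    double acc = 0.0;
    for (int ax = 0; ax < 3; ++ax) {
      if (kp[ax]->size() == 0) continue;  // inactive axis
      const double kpv = (*kp[ax])[f];
      const double kmv = (*km[ax])[f];
      const double Fp = (co[ax] + 1 < nf[ax]) ? F[f + stride[ax]] : 0.0;
      const double Fm = (co[ax] > 0) ? F[f - stride[ax]] : 0.0;
      const double valP = Fp * kpv - Fc * (1.0 - kpv);
      const double valM = Fm * kmv - Fc * (1.0 - kmv);
      double a;
      if (ax == cAx) {
        a = Fc;
      } else if (ax == o1ax - 1) {
        a = faceAvg(O1, od1, cAx, ax, i, j, k);
      } else {
        a = faceAvg(O2, od2, cAx, ax, i, j, k);
      }
      acc += ih2 * (valP + valM - 2.0 * Fc);
      acc -= (a > 0 ? a * (Fc - valM) : a * (valP - Fc)) * ih;
    }
    out[f] = Fc + dt * acc;
  }
  return out;
}

// Divergence of the staggered field at the inside cells (zero elsewhere).
// [[Rcpp::export(name = ".divergenceCpp")]]
NumericVector divergenceCpp(NumericVector U, NumericVector V,
                            NumericVector W, IntegerVector d,
                            LogicalVector M, double h) {
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(nx * ny * nz);
  const bool has3 = W.size() > 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int c = i + nx * (j + ny * k);
        if (!M[c]) continue;
        double dv = U[(i + 1) + (nx + 1) * (j + ny * k)] -
                    U[i + (nx + 1) * (j + ny * k)] +
                    V[i + nx * ((j + 1) + (ny + 1) * k)] -
                    V[i + nx * (j + (ny + 1) * k)];
        if (has3)
          dv += W[i + nx * (j + ny * (k + 1))] - W[i + nx * (j + ny * k)];
        out[c] = dv / h;
      }
    }
  }
  return out;
}
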