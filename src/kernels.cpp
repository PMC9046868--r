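// Conservative finite-volume transport kernels.
//
// All operators are written in flux form on cell-centered uniform grids with
// zero-flux boundaries: the divergence returned for a slice sums to zero up
// to round-off.  Advection is first-order upwind (scheme = 0) or MUSCL with
// a minmod limiter (scheme = 1, falling back to first order where the
// second upstream cell is missing); diffusion is central with
// face-averaged diffusivities supplied by the caller.

#include <Rcpp.h>
using namespace Rcpp;

static inline double minmod2(double a, double b) {
  if (a > 0.0 && b > 0.0) return a < b ? a : b;
  if (a < 0.0 && b < 0.0) return a > b ? a : b;
  return 0.0;
}

// Total (advective + diffusive) flux across the face between cells L and R.
// cmm / cpp are the second-neighbour values used by the limiter; hasmm /
// haspp say whether they exist.
static inline double faceFlux(double cmm, bool hasmm,
                              double cL, double cR,
                              double cpp, bool haspp,
                              double u, double D, double h, int scheme) {
  double adv;
  if (u >= 0.0) {
    double val = cL;
    if (scheme == 1 && hasmm) val += 0.5 * minmod2(cL - cmm, cR - cL);
    adv = u * val;
  } else {
    double val = cR;
    if (scheme == 1 && haspp) val -= 0.5 * minmod2(cR - cL, cpp - cR);
    adv = u * val;
  }
  return adv - D * (cR - cL) / h;
}

// Divergence of advective+diffusive fluxes on a single 2D slice.
// m:      n1 x n2 cell averages
// uxFace: (n1+1) x n2 face-normal velocities on faces along dim 1
// uyFace: n1 x (n2+1) face-normal velocities on faces along dim 2
// dxFace / dyFace: matching face diffusivities
// Returns -div(F) with F = u*c - D*grad(c), zero-flux at the boundary.
// [[Rcpp::export]]
NumericMatrix fvDivergence2D(const NumericMatrix& m,
                             const NumericMatrix& uxFace,
                             const NumericMatrix& uyFace,
                             const NumericMatrix& dxFace,
                             const NumericMatrix& dyFace,
                             double h1, double h2, int scheme) {
  const int n1 = m.nrow(), n2 = m.ncol();
  NumericMatrix out(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      // dim-1 faces
      double Fw = 0.0, Fe = 0.0;
      if (i > 0)
        Fw = faceFlux(i >= 2 ? m(i - 2, j) : 0.0, i >= 2,
                      m(i - 1, j), m(i, j),
                      i + 1 < n1 ? m(i + 1, j) : 0.0, i + 1 < n1,
                      uxFace(i, j), dxFace(i, j), h1, scheme);
      if (i + 1 < n1)
        Fe = faceFlux(i >= 1 ? m(i - 1, j) : 0.0, i >= 1,
                      m(i, j), m(i + 1, j),
                      i + 2 < n1 ? m(i + 2, j) : 0.0, i + 2 < n1,
                      uxFace(i + 1, j), dxFace(i + 1, j), h1, scheme);
      acc -= (Fe - Fw) / h1;
      // dim-2 faces
      double Fs = 0.0, Fn = 0.0;
      if (j > 0)
        Fs = faceFlux(j >= 2 ? m(i, j - 2) : 0.0, j >= 2,
                      m(i, j - 1), m(i, j),
                      j + 1 < n2 ? m(i, j + 1) : 0.0, j + 1 < n2,
                      uyFace(i, j), dyFace(i, j), h2, scheme);
      if (j + 1 < n2)
        Fn = faceFlux(j >= 1 ? m(i, j - 1) : 0.0, j >= 1,
                      m(i, j), m(i, j + 1),
                      j + 2 < n2 ? m(i, j + 2) : 0.0, j + 2 < n2,
                      uyFace(i, j + 1), dyFace(i, j + 1), h2, scheme);
      acc -= (Fn - Fs) / h2;
      out(i, j) = acc;
    }
  }
  return out;
}

// Full right-hand side for the 4D cell density: spatial transport (shared
// face fields over all state slices), structural transport (shared face
// fields over all spatial cells; structural advection is horizontal only,
// so no y2 face velocities), and the separable reaction term
//   c * ( prolif(k,l)*growFac(i,j) - psiB(k,l)*killB(i,j) - psiH(k,l)*killH(i,j) ).
//
// c4 has dim (nx1, nx2, ny1, ny2), column-major.
// [[Rcpp::export]]
NumericVector cellRhs4D(const NumericVector& c4, const IntegerVector& dims,
                        const NumericMatrix& uxFace, const NumericMatrix& uyFace,
                        const NumericMatrix& dxfFace, const NumericMatrix& dyfFace,
                        const NumericMatrix& u1Face, const NumericMatrix& dhFace,
                        const NumericMatrix& dvFace,
                        const NumericMatrix& prolif, const NumericMatrix& psiB,
                        const NumericMatrix& psiH,
                        const NumericMatrix& growFac, const NumericMatrix& killBFac,
                        const NumericMatrix& killHFac,
                        double dx1, double dx2, double dy1, double dy2,
                        int scheme) {
  const int n1 = dims[0], n2 = dims[1], m1 = dims[2], m2 = dims[3];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2, s4 = (R_xlen_t)n1 * n2 * m1;
  NumericVector out(c4.size());
  const double* c = c4.begin();
  double* o = out.begin();

  for (int l = 0; l < m2; ++l) {
    for (int k = 0; k < m1; ++k) {
      const R_xlen_t base = s3 * k + s4 * l;
      const double pkl = prolif(k, l), bkl = psiB(k, l), hkl = psiH(k, l);
      for (int j = 0; j < n2; ++j) {
        for (int i = 0; i < n1; ++i) {
          const R_xlen_t id = base + i + s2 * j;
          const double cc = c[id];
          double acc = 0.0;

          // --- spatial dim 1 ---
          {
            double Fw = 0.0, Fe = 0.0;
            if (i > 0)
              Fw = faceFlux(i >= 2 ? c[id - 2] : 0.0, i >= 2,
                            c[id - 1], cc,
                            i + 1 < n1 ? c[id + 1] : 0.0, i + 1 < n1,
                            uxFace(i, j), dxfFace(i, j), dx1, scheme);
            if (i + 1 < n1)
              Fe = faceFlux(i >= 1 ? c[id - 1] : 0.0, i >= 1,
                            cc, c[id + 1],
                            i + 2 < n1 ? c[id + 2] : 0.0, i + 2 < n1,
                            uxFace(i + 1, j), dxfFace(i + 1, j), dx1, scheme);
            acc -= (Fe - Fw) / dx1;
          }
          // --- spatial dim 2 ---
          {
            double Fs = 0.0, Fn = 0.0;
            if (j > 0)
              Fs = faceFlux(j >= 2 ? c[id - 2 * s2] : 0.0, j >= 2,
                            c[id - s2], cc,
                            j + 1 < n2 ? c[id + s2] : 0.0, j + 1 < n2,
                            uyFace(i, j), dyfFace(i, j), dx2, scheme);
            if (j + 1 < n2)
              Fn = faceFlux(j >= 1 ? c[id - s2] : 0.0, j >= 1,
                            cc, c[id + s2],
                            j + 2 < n2 ? c[id + 2 * s2] : 0.0, j + 2 < n2,
                            uyFace(i, j + 1), dyfFace(i, j + 1), dx2, scheme);
            acc -= (Fn - Fs) / dx2;
          }
          // --- structural dim 1 (advection + diffusion) ---
          {
            double Fw = 0.0, Fe = 0.0;
            if (k > 0)
              Fw = faceFlux(k >= 2 ? c[id - 2 * s3] : 0.0, k >= 2,
                            c[id - s3], cc,
                            k + 1 < m1 ? c[id + s3] : 0.0, k + 1 < m1,
                            u1Face(k, l), dhFace(k, l), dy1, scheme);
            if (k + 1 < m1)
              Fe = faceFlux(k >= 1 ? c[id - s3] : 0.0, k >= 1,
                            cc, c[id + s3],
                            k + 2 < m1 ? c[id + 2 * s3] : 0.0, k + 2 < m1,
                            u1Face(k + 1, l), dhFace(k + 1, l), dy1, scheme);
            acc -= (Fe - Fw) / dy1;
          }
          // --- structural dim 2 (diffusion only) ---
          {
            double Fs = 0.0, Fn = 0.0;
            if (l > 0)
              Fs = -dvFace(k, l) * (cc - c[id - s4]) / dy2;
            if (l + 1 < m2)
              Fn = -dvFace(k, l + 1) * (c[id + s4] - cc) / dy2;
            acc -= (Fn - Fs) / dy2;
          }
          // --- reaction ---
          acc += cc * (pkl * growFac(i, j)
                       - bkl * killBFac(i, j) - hkl * killHFac(i, j));
          o[id] = acc;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Weighted 4D histogram: bin indices are 1-based per-axis cell indices.
// [[Rcpp::export]]
NumericVector weightedHist4D(const IntegerVector& b1, const IntegerVector& b2,
                             const IntegerVector& b3, const IntegerVector& b4,
                             const NumericVector& w, const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], m1 = dims[2], m2 = dims[3];
  NumericVector out((R_xlen_t)n1 * n2 * m1 * m2);
  double* o = out.begin();
  const R_xlen_t np = w.size();
  for (R_xlen_t p = 0; p < np; ++p) {
    const R_xlen_t id = (b1[p] - 1)
      + (R_xlen_t)n1 * (b2[p] - 1)
      + (R_xlen_t)n1 * n2 * (b3[p] - 1)
      + (R_xlen_t)n1 * n2 * m1 * (b4[p] - 1);
    o[id] += w[p];
  }
  out.attr("dim") = dims;
  return out;
}
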