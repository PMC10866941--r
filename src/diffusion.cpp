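#include <Rcpp.h>
using namespace Rcpp;

// Dimensionally split backward-Euler diffusion with a Dirichlet bath on the
// outermost ring, a zeroth-order uptake sink on live-cell sites and clipping
// of (roundoff-scale) negative values. Each substep solves
//   (I - r d2/dx2)(I - r d2/dy2) C = C_old,  r = D dt / h^2,
// by constant-coefficient Thomas sweeps; both 1D operators are M-matrices,
// so the discrete maximum principle holds for any time step. Matrices are
// column-major; the sweep along the strided (row) direction is vectorised
// across systems so every inner loop is contiguous.

// [[Rcpp::export]]
List diffuse_implicit(NumericMatrix conc, LogicalMatrix live, double r,
                      double uptake_per_step, double bath, int nsteps) {
  NumericMatrix C = clone(conc);
  const int nr = C.nrow(), nc = C.ncol();
  double *c = REAL(C);
  const int *lv = LOGICAL(live);
  const double b = 1.0 + 2.0 * r, a = -r;
  const int mi = nr - 2, mj = nc - 2; // interior extents
  std::vector<double> cpi(nr), cpj(nc), w((size_t)nr * nc), di(nr);
  double max_clip = 0.0;

  // constant-coefficient Thomas factorisations
  if (mi > 0) {
    cpi[1] = a / b;
    for (int i = 2; i <= mi; ++i) cpi[i] = a / (b - a * cpi[i - 1]);
  }
  if (mj > 0) {
    cpj[1] = a / b;
    for (int j = 2; j <= mj; ++j) cpj[j] = a / (b - a * cpj[j - 1]);
  }

  for (int s = 0; s < nsteps; ++s) {
    // Dirichlet ring
    for (int j = 0; j < nc; ++j) {
      c[(size_t)nr * j] = bath;
      c[(size_t)nr * j + nr - 1] = bath;
    }
    for (int i = 0; i < nr; ++i) {
      c[i] = bath;
      c[(size_t)nr * (nc - 1) + i] = bath;
    }
    if (r > 0.0 && mi > 0 && mj > 0) {
      // implicit along the column index j (systems = rows, swept in parallel)
      {
        double *w1 = &w[(size_t)nr];
        const double *c0 = c, *c1 = c + nr;
        double inv = 1.0 / b;
        for (int i = 1; i <= mi; ++i) w1[i] = (c1[i] + r * c0[i]) * inv;
        for (int j = 2; j <= mj; ++j) {
          const double denom = 1.0 / (b - a * cpj[j - 1]);
          double *wj = &w[(size_t)nr * j], *wp = &w[(size_t)nr * (j - 1)];
          const double *cj = c + (size_t)nr * j;
          const double *cb = c + (size_t)nr * (nc - 1);
          if (j == mj) {
            for (int i = 1; i <= mi; ++i)
              wj[i] = (cj[i] + r * cb[i] - a * wp[i]) * denom;
          } else {
            for (int i = 1; i <= mi; ++i)
              wj[i] = (cj[i] - a * wp[i]) * denom;
          }
        }
        double *cl = c + (size_t)nr * mj, *wl = &w[(size_t)nr * mj];
        for (int i = 1; i <= mi; ++i) cl[i] = wl[i];
        for (int j = mj - 1; j >= 1; --j) {
          double *cj = c + (size_t)nr * j, *cn = c + (size_t)nr * (j + 1);
          double *wj = &w[(size_t)nr * j];
          const double cpjj = cpj[j];
          for (int i = 1; i <= mi; ++i) cj[i] = wj[i] - cpjj * cn[i];
        }
      }
      // implicit along the row index i (contiguous within each column)
      for (int j = 1; j <= mj; ++j) {
        double *cj = c + (size_t)nr * j;
        di[1] = (cj[1] + r * cj[0]) / b;
        for (int i = 2; i <= mi; ++i) {
          double rhs = cj[i] + (i == mi ? r * cj[nr - 1] : 0.0);
          di[i] = (rhs - a * di[i - 1]) / (b - a * cpi[i - 1]);
        }
        cj[mi] = di[mi];
        for (int i = mi - 1; i >= 1; --i) cj[i] = di[i] - cpi[i] * cj[i + 1];
      }
    }
    if (uptake_per_step > 0.0) {
      for (int j = 1; j <= mj; ++j) {
        double *cj = c + (size_t)nr * j;
        const int *lj = lv + (size_t)nr * j;
        for (int i = 1; i <= mi; ++i) {
          if (lj[i]) {
            cj[i] -= uptake_per_step;
            if (cj[i] < 0.0) {
              if (-cj[i] > max_clip) max_clip = -cj[i];
              cj[i] = 0.0;
            }
          }
        }
      }
    }
  }
  for (int j = 0; j < nc; ++j) {
    c[(size_t)nr * j] = bath;
    c[(size_t)nr * j + nr - 1] = bath;
  }
  for (int i = 0; i < nr; ++i) {
    c[i] = bath;
    c[(size_t)nr * (nc - 1) + i] = bath;
  }
  return List::create(_["conc"] = C, _["max_clip"] = max_clip);
}
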