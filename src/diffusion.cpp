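#include <Rcpp.h>
using namespace Rcpp;

// Operator-split implicit finite-volume step on a regular voxel mesh:
// one backward-Euler tridiagonal (Thomas) sweep per axis, then exact
// exponential decay.  Zero-flux (reflecting) boundaries; an optional
// Dirichlet rim holds every boundary-adjacent voxel at a fixed value,
// which models a well-stirred medium surrounding the tissue.

static void thomas_line(double *c, int n, int stride, double alpha,
                        double *dp, double *cp) {
  // solve (I - alpha * L) x = c along one line, L = 1D Neumann Laplacian
  if (n == 1) return;
  // forward sweep
  double b0 = 1.0 + alpha;                 // boundary row (zero flux)
  cp[0] = -alpha / b0;
  dp[0] = c[0] / b0;
  for (int i = 1; i < n; ++i) {
    double bi = (i == n - 1) ? (1.0 + alpha) : (1.0 + 2.0 * alpha);
    double m = bi + alpha * cp[i - 1];
    cp[i] = -alpha / m;
    dp[i] = (c[i * stride] + alpha * dp[i - 1]) / m;
  }
  // back substitution
  c[(n - 1) * stride] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = dp[i] - cp[i] * c[(i + 1) * stride];
}

static void set_rim(double *c, int nx, int ny, int nz, double value) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool rim = (nx > 1 && (i == 0 || i == nx - 1)) ||
                   (ny > 1 && (j == 0 || j == ny - 1)) ||
                   (nz > 1 && (k == 0 || k == nz - 1));
        if (rim) c[(size_t)k * nx * ny + (size_t)j * nx + i] = value;
      }
}

// [[Rcpp::export]]
void cpp_diffuse(NumericVector dens, int nx, int ny, int nz, double dx,
                 double D, double lambda, double dt, int nsub,
                 double rim_value) {
  double *c = dens.begin();
  bool rim = R_FINITE(rim_value);
  double alpha = D * dt / (dx * dx);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> dp(nmax), cp(nmax);
  double decay = std::exp(-lambda * dt);
  for (int s = 0; s < nsub; ++s) {
    if (rim) set_rim(c, nx, ny, nz, rim_value);
    if (D > 0.0) {
      if (nx > 1) {
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            thomas_line(c + (size_t)k * nx * ny + (size_t)j * nx, nx, 1,
                        alpha, dp.data(), cp.data());
      }
      if (ny > 1) {
        for (int k = 0; k < nz; ++k)
          for (int i = 0; i < nx; ++i)
            thomas_line(c + (size_t)k * nx * ny + i, ny, nx,
                        alpha, dp.data(), cp.data());
      }
      if (nz > 1) {
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i)
            thomas_line(c + (size_t)j * nx + i, nz, nx * ny,
                        alpha, dp.data(), cp.data());
      }
    }
    if (lambda > 0.0)
      for (size_t q = 0; q < (size_t)nx * ny * nz; ++q) c[q] *= decay;
    if (rim) set_rim(c, nx, ny, nz, rim_value);
  }
}
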