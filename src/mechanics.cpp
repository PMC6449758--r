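#include <Rcpp.h>
#include "bc_rng.h"
using namespace Rcpp;

// Centre-based soft-sphere mechanics.  Repulsion c_rep*(1 - d/R)^2 inside
// the radii sum R; adhesion c_adh*(1 - d/(f*R))^2 inside the interaction
// range f*R.  Pair coefficients combine by geometric means (adhesion
// additionally scaled by the cells' dynamic adhesion coefficients).

struct PairParams {
  const double *adh_mat;   // S x S adhesion strengths (cell-cell)
  const double *rep_mat;   // S x S repulsion strengths
  const double *mat_adh;   // per-strain cell-matrix adhesion strength
  double sphere_rep;       // repulsion strength of passive spheres
  int S;
};

// force magnitude on agent a along the a<-b axis (positive = apart)
static inline double pair_force_mag(double d, double ra, double rb,
                                    int type_a, int type_b,
                                    int strain_a, int strain_b,
                                    double coef_a, double coef_b,
                                    double f, const PairParams &pp) {
  double R = ra + rb;
  double maxd = f * R;
  if (d >= maxd || R <= 0.0) return 0.0;
  double c_adh, c_rep;
  if (type_a == 0 && type_b == 0) {
    c_adh = pp.adh_mat[strain_a + pp.S * strain_b];
    c_rep = pp.rep_mat[strain_a + pp.S * strain_b];
  } else if (type_a != type_b) {
    int cs = (type_a == 0) ? strain_a : strain_b;
    c_adh = pp.mat_adh[cs];
    c_rep = std::sqrt(pp.rep_mat[cs + pp.S * cs] * pp.sphere_rep);
  } else { // sphere-sphere
    c_adh = 0.0;
    c_rep = pp.sphere_rep;
  }
  c_adh *= std::sqrt(coef_a * coef_b);
  double fm = 0.0;
  if (d < R) {
    double q = 1.0 - d / R;
    fm += c_rep * q * q;
  }
  double q2 = 1.0 - d / maxd;
  fm -= c_adh * q2 * q2;
  return fm;
}

struct Accum {
  double *fx, *fy, *fz;
};

static inline void add_pair(int i, int j, const double *x, const double *y,
                            const double *z, const double *r,
                            const int *type, const int *strain,
                            const double *coef, double f,
                            const PairParams &pp, Accum &acc, int dims) {
  double ddx = x[i] - x[j];
  double ddy = y[i] - y[j];
  double ddz = (dims == 3) ? z[i] - z[j] : 0.0;
  double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
  double ux, uy, uz;
  if (d <= 0.0) {
    // coincident centres: deterministic push along +x on i
    ux = 1.0; uy = 0.0; uz = 0.0; d = 0.0;
  } else {
    ux = ddx / d; uy = ddy / d; uz = ddz / d;
  }
  double fm = pair_force_mag(d, r[i], r[j], type[i], type[j],
                             strain[i], strain[j], coef[i], coef[j], f, pp);
  if (fm != 0.0) {
    acc.fx[i] += fm * ux; acc.fy[i] += fm * uy; acc.fz[i] += fm * uz;
    acc.fx[j] -= fm * ux; acc.fy[j] -= fm * uy; acc.fz[j] -= fm * uz;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericVector x, NumericVector y, NumericVector z,
                         NumericVector radius, IntegerVector type,
                         IntegerVector strain, NumericVector adhcoef,
                         NumericMatrix adh_mat, NumericMatrix rep_mat,
                         NumericVector mat_adh, double sphere_rep,
                         double f, int dims, bool use_hash) {
  int n = x.size();
  NumericMatrix F(n, 3);
  if (n == 0) return F;
  PairParams pp;
  pp.adh_mat = adh_mat.begin(); pp.rep_mat = rep_mat.begin();
  pp.mat_adh = mat_adh.begin(); pp.sphere_rep = sphere_rep;
  pp.S = adh_mat.nrow();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  Accum acc; acc.fx = fx.data(); acc.fy = fy.data(); acc.fz = fz.data();

  if (!use_hash) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        add_pair(i, j, x.begin(), y.begin(), z.begin(), radius.begin(),
                 type.begin(), strain.begin(), adhcoef.begin(), f, pp, acc, dims);
  } else {
    // uniform grid hash; bin edge = max interaction diameter
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
    double h = std::max(2.0 * f * rmax, 1e-6);
    double xmin = x[0], ymin = y[0], zmin = (dims == 3) ? z[0] : 0.0;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, x[i]); ymin = std::min(ymin, y[i]);
      if (dims == 3) zmin = std::min(zmin, z[i]);
    }
    std::vector<int> bx(n), by(n), bz(n);
    int nbx = 1, nby = 1, nbz = 1;
    for (int i = 0; i < n; ++i) {
      bx[i] = (int)((x[i] - xmin) / h);
      by[i] = (int)((y[i] - ymin) / h);
      bz[i] = (dims == 3) ? (int)((z[i] - zmin) / h) : 0;
      nbx = std::max(nbx, bx[i] + 1);
      nby = std::max(nby, by[i] + 1);
      nbz = std::max(nbz, bz[i] + 1);
    }
    std::vector<std::vector<int> > bins((size_t)nbx * nby * nbz);
    for (int i = 0; i < n; ++i)
      bins[(size_t)bz[i] * nbx * nby + (size_t)by[i] * nbx + bx[i]].push_back(i);
    std::vector<int> neigh;
    for (int i = 0; i < n; ++i) {
      neigh.clear();
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = bz[i] + dk;
        if (kk < 0 || kk >= nbz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = by[i] + dj;
          if (jj < 0 || jj >= nby) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = bx[i] + di;
            if (ii < 0 || ii >= nbx) continue;
            const std::vector<int> &b =
              bins[(size_t)kk * nbx * nby + (size_t)jj * nbx + ii];
            for (size_t q = 0; q < b.size(); ++q)
              if (b[q] > i) neigh.push_back(b[q]);
          }
        }
      }
      std::sort(neigh.begin(), neigh.end());
      for (size_t q = 0; q < neigh.size(); ++q)
        add_pair(i, neigh[q], x.begin(), y.begin(), z.begin(), radius.begin(),
                 type.begin(), strain.begin(), adhcoef.begin(), f, pp, acc, dims);
    }
  }
  for (int i = 0; i < n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return F;
}

// run-and-tumble polarity: tumble events are Poisson with rate 1/tau,
// after which a fresh uniform direction is drawn.
// [[Rcpp::export]]
void cpp_update_polarity(NumericVector px, NumericVector py, NumericVector pz,
                         IntegerMatrix rng, IntegerVector rows,
                         double tau, double dt, int dims) {
  double p_tumble = (tau > 0 && R_FINITE(tau)) ? -std::expm1(-dt / tau) : 0.0;
  int rs[4];
  for (int ii = 0; ii < rows.size(); ++ii) {
    int i = rows[ii] - 1;
    for (int m = 0; m < 4; ++m) rs[m] = rng(i, m);
    BCRng r = bc_load(rs);
    if (r.unif() < p_tumble) {
      if (dims == 2) {
        double th = 2.0 * M_PI * r.unif();
        px[i] = std::cos(th); py[i] = std::sin(th); pz[i] = 0.0;
      } else {
        double zc = 2.0 * r.unif() - 1.0;
        double th = 2.0 * M_PI * r.unif();
        double s = std::sqrt(std::max(0.0, 1.0 - zc * zc));
        px[i] = s * std::cos(th); py[i] = s * std::sin(th); pz[i] = zc;
      }
    }
    bc_store(r, rs);
    for (int m = 0; m < 4; ++m) rng(i, m) = rs[m];
  }
}
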