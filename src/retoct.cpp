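#include <Rcpp.h>
using namespace Rcpp;

// Anisotropic 3D total variation: sum of |forward differences| along the
// three axes (same functional the Chambolle solver minimises).
// [[Rcpp::export]]
double tv_norm_3d(NumericVector vol) {
  IntegerVector d = vol.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  auto at = [&](int i, int j, int k) { return vol[i + n1 * (j + (R_xlen_t)n2 * k)]; };
  double tv = 0.0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double v = at(i, j, k);
        if (i + 1 < n1) tv += std::fabs(at(i + 1, j, k) - v);
        if (j + 1 < n2) tv += std::fabs(at(i, j + 1, k) - v);
        if (k + 1 < n3) tv += std::fabs(at(i, j, k + 1) - v);
      }
  return tv;
}

// Chambolle-style dual projection for the ROF problem
//   min_u ||u - f||^2 + w * TV_aniso(u)
// (equivalent to the classical (1/2)||u-f||^2 + lambda TV with
// lambda = w/2). The dual field p has one component per axis; each
// component is clamped to [-1, 1] (anisotropic TV). Returns u.
// [[Rcpp::export]]
NumericVector tv_denoise_3d(NumericVector f, double weight, int max_iter,
                            double tol) {
  IntegerVector d = f.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  R_xlen_t n = f.size();
  double lambda = weight / 2.0;
  const double tau = 1.0 / 12.0;  // step bound for 3D

  std::vector<double> p1(n, 0.0), p2(n, 0.0), p3(n, 0.0), divp(n, 0.0),
      u(n, 0.0);
  auto idx = [&](int i, int j, int k) { return i + n1 * (j + (R_xlen_t)n2 * k); };

  double f_rng = 0.0;
  {
    double mn = f[0], mx = f[0];
    for (R_xlen_t t = 1; t < n; ++t) { mn = std::min(mn, f[t]); mx = std::max(mx, f[t]); }
    f_rng = mx - mn;
  }
  if (f_rng <= 0.0 || lambda <= 0.0) return clone(f);

  for (int it = 0; it < max_iter; ++it) {
    // u = f - lambda * div p ; track max change for the stopping rule
    double max_change = 0.0;
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          R_xlen_t t = idx(i, j, k);
          double dv = 0.0;
          dv += p1[t] - (i > 0 ? p1[idx(i - 1, j, k)] : 0.0);
          dv += p2[t] - (j > 0 ? p2[idx(i, j - 1, k)] : 0.0);
          dv += p3[t] - (k > 0 ? p3[idx(i, j, k - 1)] : 0.0);
          divp[t] = dv;
          double unew = f[t] - lambda * dv;
          max_change = std::max(max_change, std::fabs(unew - u[t]));
          u[t] = unew;
        }
    if (it > 0 && max_change < tol * f_rng) break;
    // gradient ascent on p with componentwise clamping
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          R_xlen_t t = idx(i, j, k);
          double g1 = (i + 1 < n1) ? (u[idx(i + 1, j, k)] - u[t]) : 0.0;
          double g2 = (j + 1 < n2) ? (u[idx(i, j + 1, k)] - u[t]) : 0.0;
          double g3 = (k + 1 < n3) ? (u[idx(i, j, k + 1)] - u[t]) : 0.0;
          double q1 = p1[t] - (tau / lambda) * g1;
          double q2 = p2[t] - (tau / lambda) * g2;
          double q3 = p3[t] - (tau / lambda) * g3;
          p1[t] = std::max(-1.0, std::min(1.0, q1));
          p2[t] = std::max(-1.0, std::min(1.0, q2));
          p3[t] = std::max(-1.0, std::min(1.0, q3));
        }
  }
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = u[t];
  out.attr("dim") = d;
  return out;
}

// Windowed k=1 nearest-neighbor distance from each point of the upper
// height map to the lower height map, in 3D micrometre space. Heights in
// um; grid spacings in um; search limited to |dy|,|dx| <= window_um.
// Invalid (NA) lower points are skipped; NA upper points give NA.
// [[Rcpp::export]]
NumericMatrix nn_surface_distance(NumericMatrix upper, NumericMatrix lower,
                                  double sy, double sx, double window_um) {
  int n1 = upper.nrow(), n2 = upper.ncol();
  int wy = (int)std::floor(window_um / sy);
  int wx = (int)std::floor(window_um / sx);
  NumericMatrix out(n1, n2);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double hu = upper(i, j);
      if (NumericMatrix::is_na(hu)) { out(i, j) = NA_REAL; continue; }
      double best = R_PosInf;
      int i0 = std::max(0, i - wy), i1 = std::min(n1 - 1, i + wy);
      int j0 = std::max(0, j - wx), j1 = std::min(n2 - 1, j + wx);
      for (int jj = j0; jj <= j1; ++jj) {
        double dx = (jj - j) * sx;
        double dx2 = dx * dx;
        if (dx2 >= best) continue;
        for (int ii = i0; ii <= i1; ++ii) {
          double hl = lower(ii, jj);
          if (NumericMatrix::is_na(hl)) continue;
          double dy = (ii - i) * sy;
          double dz = hl - hu;
          double d2 = dx2 + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
      }
      out(i, j) = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
    }
  return out;
}
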