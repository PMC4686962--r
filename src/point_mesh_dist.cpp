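#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

// Exact point-to-triangle distance (Eberly's region decomposition),
// with a centroid/circumradius lower bound to prune the triangle loop.

static double point_triangle_dist2(const double* p, const double* a,
                                   const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0]*ap[0] + ap[1]*ap[1] + ap[2]*ap[2];
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0]*bp[0] + bp[1]*bp[1] + bp[2]*bp[2];
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double dx[3];
    for (int k = 0; k < 3; ++k) dx[k] = ap[k] - v*ab[k];
    return dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0]*cp[0] + cp[1]*cp[1] + cp[2]*cp[2];
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double dx[3];
    for (int k = 0; k < 3; ++k) dx[k] = ap[k] - w*ac[k];
    return dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double dx[3];
    for (int k = 0; k < 3; ++k) dx[k] = bp[k] - w*(c[k] - b[k]);
    return dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double dx[3];
  for (int k = 0; k < 3; ++k) dx[k] = ap[k] - v*ab[k] - w*ac[k];
  return dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
}

// [[Rcpp::export(name = ".point_mesh_distances")]]
Rcpp::NumericVector point_mesh_distances(Rcpp::NumericMatrix points,
                                         Rcpp::NumericMatrix vertices,
                                         Rcpp::IntegerMatrix faces) {
  const int np = points.nrow();
  const int nf = faces.nrow();
  std::vector<double> cx(nf), cy(nf), cz(nf), crad(nf);
  std::vector<double> A(3*nf), B(3*nf), C(3*nf);
  for (int j = 0; j < nf; ++j) {
    int ia = faces(j, 0) - 1, ib = faces(j, 1) - 1, ic = faces(j, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      A[3*j+k] = vertices(ia, k);
      B[3*j+k] = vertices(ib, k);
      C[3*j+k] = vertices(ic, k);
    }
    cx[j] = (A[3*j] + B[3*j] + C[3*j]) / 3.0;
    cy[j] = (A[3*j+1] + B[3*j+1] + C[3*j+1]) / 3.0;
    cz[j] = (A[3*j+2] + B[3*j+2] + C[3*j+2]) / 3.0;
    double ra = 0, rb = 0, rc = 0;
    for (int k = 0; k < 3; ++k) {
      double cc = (k==0)?cx[j]:((k==1)?cy[j]:cz[j]);
      ra += (A[3*j+k]-cc)*(A[3*j+k]-cc);
      rb += (B[3*j+k]-cc)*(B[3*j+k]-cc);
      rc += (C[3*j+k]-cc)*(C[3*j+k]-cc);
    }
    crad[j] = std::sqrt(std::max(ra, std::max(rb, rc)));
  }
  Rcpp::NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double best = std::numeric_limits<double>::infinity();
    double bestd = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nf; ++j) {
      double dxc = p[0]-cx[j], dyc = p[1]-cy[j], dzc = p[2]-cz[j];
      double dc = std::sqrt(dxc*dxc + dyc*dyc + dzc*dzc) - crad[j];
      if (dc > bestd) continue;
      double d2 = point_triangle_dist2(p, &A[3*j], &B[3*j], &C[3*j]);
      if (d2 < best) {
        best = d2;
        bestd = std::sqrt(d2);
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
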