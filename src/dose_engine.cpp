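#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Piecewise-linear interpolation on sorted nodes, clamped at both ends.
// Node queries reproduce node values exactly (t == 0 on the left node).
static inline double lin_interp(const std::vector<double>& xs,
                                const std::vector<double>& ys, double x) {
  if (x <= xs.front()) return ys.front();
  if (x >= xs.back()) return ys.back();
  const std::size_t hi =
      std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
  const std::size_t lo = hi - 1;
  const double t = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + t * (ys[hi] - ys[lo]);
}

// Radiological (density-weighted) path length from source s to point p,
// in water-equivalent cm: Siddon/Amanatides-Woo exact voxel traversal of
// the segment, accumulating density * geometric segment length for the
// portion inside the grid. Material outside the grid contributes nothing.
static double radiological_path(const double* dens, const int* dims,
                                const double* org, const double* sp,
                                const double* s, const double* p) {
  double d[3] = {p[0] - s[0], p[1] - s[1], p[2] - s[2]};
  const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L == 0.0) return 0.0;

  double t0 = 0.0, t1 = 1.0;  // param range of the inside-grid portion
  for (int k = 0; k < 3; ++k) {
    const double lo = org[k], hi = org[k] + dims[k] * sp[k];
    if (d[k] == 0.0) {
      if (s[k] <= lo || s[k] >= hi) return 0.0;
    } else {
      double ta = (lo - s[k]) / d[k], tb = (hi - s[k]) / d[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;

  int idx[3], step[3];
  double tMax[3], tDelta[3];
  const double tstart = t0 + 1e-10;
  for (int k = 0; k < 3; ++k) {
    const double pos = s[k] + d[k] * tstart;
    int i = static_cast<int>(std::floor((pos - org[k]) / sp[k]));
    if (i < 0) i = 0;
    if (i >= dims[k]) i = dims[k] - 1;
    idx[k] = i;
    if (d[k] > 0.0) {
      step[k] = 1;
      tMax[k] = (org[k] + (i + 1) * sp[k] - s[k]) / d[k];
      tDelta[k] = sp[k] / d[k];
    } else if (d[k] < 0.0) {
      step[k] = -1;
      tMax[k] = (org[k] + i * sp[k] - s[k]) / d[k];
      tDelta[k] = -sp[k] / d[k];
    } else {
      step[k] = 0;
      tMax[k] = R_PosInf;
      tDelta[k] = R_PosInf;
    }
  }

  const long long nx = dims[0], ny = dims[1];
  double t = t0, rad = 0.0;
  while (t < t1 - 1e-12) {
    int kmin = 0;
    if (tMax[1] < tMax[kmin]) kmin = 1;
    if (tMax[2] < tMax[kmin]) kmin = 2;
    const double tn = tMax[kmin] < t1 ? tMax[kmin] : t1;
    if (tn > t)
      rad += (tn - t) * L * dens[idx[0] + nx * (idx[1] + ny * idx[2])];
    t = tn;
    if (tn >= t1) break;
    idx[kmin] += step[kmin];
    if (idx[kmin] < 0 || idx[kmin] >= dims[kmin]) break;
    tMax[kmin] += tDelta[kmin];
  }
  return rad;
}

// [[Rcpp::export]]
double cpp_radiological_depth(NumericVector density, IntegerVector dims,
                              NumericVector origin, NumericVector spacing,
                              NumericVector source, NumericVector point) {
  return radiological_path(density.begin(), dims.begin(), origin.begin(),
                           spacing.begin(), source.begin(), point.begin());
}

// Factorized divergent-beam dose accumulated over a list of beams:
// dose = MU * output_cal * PDD(d_rad)/PDD(d_ref) * OCR_x * OCR_y * (SAD/z)^2
// with off-axis offsets back-projected to the isocenter plane and z the
// source distance measured along the beam axis (factor 1 on that plane).
// beams: n x 5 matrix (iso_x, iso_y, iso_z, gantry_deg, mu).
// [[Rcpp::export]]
NumericVector cpp_plan_dose(NumericVector density, IntegerVector dims,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix beams, double sad,
                            double reference_depth, double output_cal,
                            NumericVector pdd_pos, NumericVector pdd_val,
                            NumericVector ocrx_pos, NumericVector ocrx_val,
                            NumericVector ocry_pos, NumericVector ocry_val) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long nvox = static_cast<long long>(nx) * ny * nz;
  NumericVector dose(nvox);

  const std::vector<double> px_(pdd_pos.begin(), pdd_pos.end());
  const std::vector<double> pv_(pdd_val.begin(), pdd_val.end());
  const std::vector<double> oxp(ocrx_pos.begin(), ocrx_pos.end());
  const std::vector<double> oxv(ocrx_val.begin(), ocrx_val.end());
  const std::vector<double> oyp(ocry_pos.begin(), ocry_pos.end());
  const std::vector<double> oyv(ocry_val.begin(), ocry_val.end());

  const double pdd_ref = lin_interp(px_, pv_, reference_depth);
  if (pdd_ref <= 0.0)
    stop("PDD is zero at the reference depth; cannot normalize");

  std::vector<double> cx(nx), cy(ny), cz(nz);
  for (int i = 0; i < nx; ++i) cx[i] = origin[0] + (i + 0.5) * spacing[0];
  for (int j = 0; j < ny; ++j) cy[j] = origin[1] + (j + 0.5) * spacing[1];
  for (int k = 0; k < nz; ++k) cz[k] = origin[2] + (k + 0.5) * spacing[2];

  const double* dens = density.begin();

  for (int b = 0; b < beams.nrow(); ++b) {
    const double ix = beams(b, 0), iy = beams(b, 1), iz = beams(b, 2);
    const double g = beams(b, 3) * M_PI / 180.0;
    const double mu = beams(b, 4);
    if (mu == 0.0) continue;
    const double ux = std::sin(g), uz = std::cos(g);  // isocenter -> source
    const double ex = std::cos(g), ez = -std::sin(g); // lateral unit vector
    const double src[3] = {ix + sad * ux, iy, iz + sad * uz};
    const double scale_mu = mu * output_cal;

    for (int k = 0; k < nz; ++k) {
      const double vz = cz[k] - iz;
      for (int j = 0; j < ny; ++j) {
        const double vy = cy[j] - iy;
        const long long row = static_cast<long long>(nx) * (j + static_cast<long long>(ny) * k);
        for (int i = 0; i < nx; ++i) {
          const double vx = cx[i] - ix;
          const double zax = sad - (vx * ux + vz * uz);
          if (zax < 1e-6) continue;  // at or behind the source
          const double proj = sad / zax;
          const double fy = lin_interp(oyp, oyv, vy * proj);
          if (fy == 0.0) continue;
          const double fx =
              lin_interp(oxp, oxv, (vx * ex + vz * ez) * proj);
          if (fx == 0.0) continue;
          const long long v = i + row;
          const double pt[3] = {cx[i], cy[j], cz[k]};
          const double rad = radiological_path(dens, dims.begin(),
                                               origin.begin(),
                                               spacing.begin(), src, pt);
          if (rad == 0.0 && dens[v] == 0.0) continue;  // no dose to air
          const double pf = lin_interp(px_, pv_, rad) / pdd_ref;
          dose[v] += scale_mu * pf * fx * fy * proj * proj;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return dose;
}
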