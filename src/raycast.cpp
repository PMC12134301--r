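// Cone-beam geometry primitives: point-source ray-cast line integrals
// (uniform-step trilinear sampling), rigid volume resampling, bilinear 2D
// shifts and 8-connected component labelling.
//
// Patient frame: x lateral, y superior-inferior, z anterior-posterior,
// isocentre at the origin. At gantry angle theta (degrees) the source sits at
// SAD*(cos t, 0, sin t); the detector plane lies SID from the source,
// perpendicular to the beam axis, with in-plane axes
//   e_u = (sin t, 0, -cos t)   (transverse) and  e_v = (0, 1, 0)  (SI),
// so a point offset (x,y,z) from the isocentre projects to
//   u = SID * (x sin t - z cos t) / (SAD - (x cos t + z sin t)),
//   v = SID * y / (SAD - (x cos t + z sin t)).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double trilinear(const arma::cube& V,
                               double fx, double fy, double fz) {
  // fx,fy,fz: continuous 0-based voxel coordinates
  const int nx = V.n_rows, ny = V.n_cols, nz = V.n_slices;
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
  const double c000 = V(x0, y0, z0),     c100 = V(x0 + 1, y0, z0);
  const double c010 = V(x0, y0 + 1, z0), c110 = V(x0 + 1, y0 + 1, z0);
  const double c001 = V(x0, y0, z0 + 1), c101 = V(x0 + 1, y0, z0 + 1);
  const double c011 = V(x0, y0 + 1, z0 + 1), c111 = V(x0 + 1, y0 + 1, z0 + 1);
  const double c00 = c000 * (1 - dx) + c100 * dx;
  const double c10 = c010 * (1 - dx) + c110 * dx;
  const double c01 = c001 * (1 - dx) + c101 * dx;
  const double c11 = c011 * (1 - dx) + c111 * dx;
  const double c0 = c00 * (1 - dy) + c10 * dy;
  const double c1 = c01 * (1 - dy) + c11 * dy;
  return c0 * (1 - dz) + c1 * dz;
}

// clip a parametric ray p = o + s*d to the axis-aligned box [lo, hi]
static inline bool clip_ray(const double o[3], const double d[3],
                            const double lo[3], const double hi[3],
                            double& s0, double& s1) {
  s0 = 0.0;
  s1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double t0 = (lo[a] - o[a]) / d[a], t1 = (hi[a] - o[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      s0 = std::max(s0, t0);
      s1 = std::min(s1, t1);
      if (s0 >= s1) return false;
    }
  }
  return s0 < s1;
}

// [[Rcpp::export(name = ".cpp_forward_project")]]
arma::mat cpp_forward_project(const arma::cube& vol,
                              const arma::vec& spacing,
                              const arma::vec& origin,
                              double sad, double sid,
                              int nu, int nv, double pitch,
                              double angle_deg, double step) {
  const double t = angle_deg * M_PI / 180.0;
  const double es[3] = {std::cos(t), 0.0, std::sin(t)};   // beam axis (to source)
  const double eu[3] = {std::sin(t), 0.0, -std::cos(t)};  // detector u
  const double src[3] = {sad * es[0], 0.0, sad * es[2]};
  // volume bounding box (voxel-centre extent)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a];
    hi[a] = origin[a] + (double)((a == 0 ? vol.n_rows : a == 1 ? vol.n_cols
                                                               : vol.n_slices) - 1) * spacing[a];
  }
  arma::mat img(nv, nu, arma::fill::zeros);  // rows = v (SI), cols = u
  const double cu = (nu + 1) / 2.0, cv = (nv + 1) / 2.0;
  for (int iu = 0; iu < nu; ++iu) {
    const double u = ((iu + 1) - cu) * pitch;
    for (int iv = 0; iv < nv; ++iv) {
      const double v = ((iv + 1) - cv) * pitch;
      // detector pixel centre position
      double det[3];
      for (int a = 0; a < 3; ++a)
        det[a] = src[a] - sid * es[a] + u * eu[a];
      det[1] += v;  // e_v = +y
      double dir[3];
      double norm = 0.0;
      for (int a = 0; a < 3; ++a) {
        dir[a] = det[a] - src[a];
        norm += dir[a] * dir[a];
      }
      norm = std::sqrt(norm);
      for (int a = 0; a < 3; ++a) dir[a] /= norm;
      double s0, s1;
      if (!clip_ray(src, dir, lo, hi, s0, s1)) continue;
      const double len = s1 - s0;
      const int n = std::max(1, (int)std::ceil(len / step));
      const double h = len / n;
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        const double s = s0 + (k + 0.5) * h;
        const double px = src[0] + s * dir[0];
        const double py = src[1] + s * dir[1];
        const double pz = src[2] + s * dir[2];
        acc += trilinear(vol, (px - origin[0]) / spacing[0],
                         (py - origin[1]) / spacing[1],
                         (pz - origin[2]) / spacing[2]);
      }
      img(iv, iu) = acc * h;
    }
  }
  return img;
}

// Resample a volume under a rigid map about the isocentre: output voxel at
// physical position p takes the input value at Rinv * (p - tr) (trilinear,
// zero fill). Rinv is the inverse rotation matrix; tr the translation (mm).
// [[Rcpp::export(name = ".cpp_rigid_resample")]]
arma::cube cpp_rigid_resample(const arma::cube& vol,
                              const arma::vec& spacing,
                              const arma::vec& origin,
                              const arma::mat& Rinv,
                              const arma::vec& tr) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  arma::cube out(nx, ny, nz, arma::fill::zeros);
  for (int k = 0; k < nz; ++k) {
    const double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      const double py = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        const double px = origin[0] + i * spacing[0];
        const double qx = px - tr[0], qy = py - tr[1], qz = pz - tr[2];
        const double sx = Rinv(0, 0) * qx + Rinv(0, 1) * qy + Rinv(0, 2) * qz;
        const double sy = Rinv(1, 0) * qx + Rinv(1, 1) * qy + Rinv(1, 2) * qz;
        const double sz = Rinv(2, 0) * qx + Rinv(2, 1) * qy + Rinv(2, 2) * qz;
        out(i, j, k) = trilinear(vol, (sx - origin[0]) / spacing[0],
                                 (sy - origin[1]) / spacing[1],
                                 (sz - origin[2]) / spacing[2]);
      }
    }
  }
  return out;
}

// Translate a 2D image by (du, dv) pixels (u = columns, v = rows), bilinear
// interpolation, zero fill outside.
// [[Rcpp::export(name = ".cpp_shift_image")]]
arma::mat cpp_shift_image(const arma::mat& img, double du, double dv) {
  const int nr = img.n_rows, nc = img.n_cols;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int c = 0; c < nc; ++c) {
    const double sc = c - du;
    if (sc < 0 || sc > nc - 1) continue;
    int c0 = (int)std::floor(sc);
    if (c0 == nc - 1) c0--;
    const double wc = sc - c0;
    for (int r = 0; r < nr; ++r) {
      const double sr = r - dv;
      if (sr < 0 || sr > nr - 1) continue;
      int r0 = (int)std::floor(sr);
      if (r0 == nr - 1) r0--;
      const double wr = sr - r0;
      out(r, c) = img(r0, c0) * (1 - wr) * (1 - wc) +
                  img(r0 + 1, c0) * wr * (1 - wc) +
                  img(r0, c0 + 1) * (1 - wr) * wc +
                  img(r0 + 1, c0 + 1) * wr * wc;
    }
  }
  return out;
}

// 8-connected component labelling by flood fill; labels assigned in
// row-major scan order (row-major = by row, then column, matching the
// documented smallest-row-major-index tie-break used downstream).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int cr = stack.back().first, cc = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              stack.push_back(std::make_pair(rr, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}
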