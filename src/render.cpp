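#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Tip-apex z at first steric contact between a sphere-capped-cone tip and a
// spherical bead, for lateral tip-axis/bead distance d. Sphere-sphere branch
// for d <= (R+r) cos(Theta), cone-flank branch beyond.
static inline double contact_z(double bz, double r, double d,
                               double R, double cosT, double sinT) {
  double Rr = R + r;
  if (d <= Rr * cosT) {
    return bz + std::sqrt(Rr * Rr - d * d) - R;
  }
  return bz + (Rr - d * cosT) / sinT - R;
}

// [[Rcpp::export(name = ".cpp_contact_height")]]
NumericVector cpp_contact_height(NumericVector bz, NumericVector r,
                                 NumericVector d, double R, double thetaDeg) {
  double cosT = std::cos(thetaDeg * DEG), sinT = std::sin(thetaDeg * DEG);
  int n = bz.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = contact_z(bz[i], r[i], d[i], R, cosT, sinT);
  return out;
}

// Render the scan lines listed in `rows` (1-based, bottom row = 1).
// coords are already posed (rotated/translated/stage-shifted), in nm.
// [[Rcpp::export(name = ".cpp_render_rows")]]
NumericMatrix cpp_render_rows(NumericMatrix coords, NumericVector radii,
                              double R, double thetaDeg,
                              int nx, double px, double ox, double oy,
                              IntegerVector rows) {
  double cosT = std::cos(thetaDeg * DEG), sinT = std::sin(thetaDeg * DEG);
  int nb = coords.nrow(), nr = rows.size();
  NumericMatrix out(nr, nx);
  for (int ri = 0; ri < nr; ++ri) {
    double cy = oy + (rows[ri] - 0.5) * px;
    for (int j = 0; j < nx; ++j) {
      double cx = ox + (j + 0.5) * px;
      double h = 0.0; // bare stage
      for (int b = 0; b < nb; ++b) {
        double dx = coords(b, 0) - cx, dy = coords(b, 1) - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        double z = contact_z(coords(b, 2), radii[b], d, R, cosT, sinT);
        if (z > h) h = z;
      }
      out(ri, j) = h;
    }
  }
  return out;
}

// Pose the model (rotate about the centroid by psi/phi/theta about the
// fixed z-, x-, y-axes, translate laterally, apply the stage convention)
// and render the requested scan lines in one call. Used by both the static
// and the per-line scan-lag renderers so that the two are bit-identical in
// the degenerate-noise case.
// [[Rcpp::export(name = ".cpp_render_posed")]]
NumericMatrix cpp_render_posed(NumericMatrix coords, NumericVector radii,
                               double px0, double py0, double phi,
                               double theta, double psi,
                               double R, double thetaDeg,
                               int nx, double px, double ox, double oy,
                               IntegerVector rows, bool surfaceStage) {
  int nb = coords.nrow();
  double cen[3] = {0, 0, 0};
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < 3; ++k) cen[k] += coords(b, k);
  for (int k = 0; k < 3; ++k) cen[k] /= nb;
  double Rm[9];
  {
    // inline rotation build (extrinsic z then x then y)
    double d = M_PI / 180.0;
    double cz = std::cos(psi * d), sz = std::sin(psi * d);
    double cx = std::cos(phi * d), sx = std::sin(phi * d);
    double cy = std::cos(theta * d), sy = std::sin(theta * d);
    double Rz[9] = {cz, -sz, 0, sz, cz, 0, 0, 0, 1};
    double Rx[9] = {1, 0, 0, 0, cx, -sx, 0, sx, cx};
    double Ry[9] = {cy, 0, sy, 0, 1, 0, -sy, 0, cy};
    double T1[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += Rx[3 * i + k] * Rz[3 * k + j];
        T1[3 * i + j] = s;
      }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += Ry[3 * i + k] * T1[3 * k + j];
        Rm[3 * i + j] = s;
      }
  }
  std::vector<double> bx(nb), by(nb), bz(nb);
  double zmin = INFINITY;
  for (int b = 0; b < nb; ++b) {
    double v[3] = {coords(b, 0) - cen[0], coords(b, 1) - cen[1],
                   coords(b, 2) - cen[2]};
    bx[b] = Rm[0] * v[0] + Rm[1] * v[1] + Rm[2] * v[2] + px0;
    by[b] = Rm[3] * v[0] + Rm[4] * v[1] + Rm[5] * v[2] + py0;
    bz[b] = Rm[6] * v[0] + Rm[7] * v[1] + Rm[8] * v[2];
    double z = surfaceStage ? bz[b] - radii[b] : bz[b];
    if (z < zmin) zmin = z;
  }
  double cosT = std::cos(thetaDeg * M_PI / 180.0);
  double sinT = std::sin(thetaDeg * M_PI / 180.0);
  int nr = rows.size();
  NumericMatrix out(nr, nx);
  for (int ri = 0; ri < nr; ++ri) {
    double cy = oy + (rows[ri] - 0.5) * px;
    for (int j = 0; j < nx; ++j) {
      double cx = ox + (j + 0.5) * px;
      double h = 0.0;
      for (int b = 0; b < nb; ++b) {
        double dx = bx[b] - cx, dy = by[b] - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        double z = contact_z(bz[b] - zmin, radii[b], d, R, cosT, sinT);
        if (z > h) h = z;
      }
      out(ri, j) = h;
    }
  }
  return out;
}

static inline void rot_zxy(double psi, double phi, double theta, double Rm[9]) {
  // extrinsic (fixed-axis) composition: Ry(theta) * Rx(phi) * Rz(psi)
  double cz = std::cos(psi * DEG), sz = std::sin(psi * DEG);
  double cx = std::cos(phi * DEG), sx = std::sin(phi * DEG);
  double cy = std::cos(theta * DEG), sy = std::sin(theta * DEG);
  // Rz
  double Rz[9] = {cz, -sz, 0, sz, cz, 0, 0, 0, 1};
  // Rx
  double Rx[9] = {1, 0, 0, 0, cx, -sx, 0, sx, cx};
  // Ry
  double Ry[9] = {cy, 0, sy, 0, 1, 0, -sy, 0, cy};
  double T1[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Rx[3 * i + k] * Rz[3 * k + j];
      T1[3 * i + j] = s;
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Ry[3 * i + k] * T1[3 * k + j];
      Rm[3 * i + j] = s;
    }
}

// Exhaustive rigid-body fit of candidate bead models to a reference image.
// Lexicographic search order (candidate, psi, phi, theta, R, Theta, shift_y,
// shift_x) with strict improvement, so ties break deterministically toward
// the earliest grid point. Returns the argmax plus a top-`keep` score table.
// [[Rcpp::export(name = ".cpp_rigid_fit")]]
List cpp_rigid_fit(List candCoords, List candRadii, NumericMatrix ref,
                   NumericVector psis, NumericVector phis, NumericVector thetas,
                   NumericVector Rvals, NumericVector Tvals,
                   int shiftPx, double px, double ox, double oy,
                   bool surfaceStage, int keep) {
  int ny = ref.nrow(), nx = ref.ncol(), np = nx * ny;
  // reference moments
  double mref = 0;
  for (int i = 0; i < ny; ++i) for (int j = 0; j < nx; ++j) mref += ref(i, j);
  mref /= np;
  double vref = 0;
  for (int i = 0; i < ny; ++i) for (int j = 0; j < nx; ++j) {
    double d = ref(i, j) - mref; vref += d * d;
  }
  if (vref <= 0) stop("reference image is constant");

  double bestCC = -2.0;
  int bState = -1, bPsi = -1, bPhi = -1, bTheta = -1, bR = -1, bT = -1,
      bSx = 0, bSy = 0;
  std::vector<double> topCC; std::vector<std::array<int, 8>> topIdx;

  arma::mat sim(ny, nx);
  for (int c = 0; c < candCoords.size(); ++c) {
    NumericMatrix xyz = candCoords[c];
    NumericVector rad = candRadii[c];
    int nb = xyz.nrow();
    double cen[3] = {0, 0, 0};
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < 3; ++k) cen[k] += xyz(b, k);
    for (int k = 0; k < 3; ++k) cen[k] /= nb;
    arma::mat rot(nb, 3);
    for (int ip = 0; ip < psis.size(); ++ip)
    for (int ih = 0; ih < phis.size(); ++ih)
    for (int it = 0; it < thetas.size(); ++it) {
      double Rm[9];
      rot_zxy(psis[ip], phis[ih], thetas[it], Rm);
      for (int b = 0; b < nb; ++b) {
        double v[3] = {xyz(b, 0) - cen[0], xyz(b, 1) - cen[1], xyz(b, 2) - cen[2]};
        for (int k = 0; k < 3; ++k)
          rot(b, k) = Rm[3 * k] * v[0] + Rm[3 * k + 1] * v[1] + Rm[3 * k + 2] * v[2];
      }
      // stage convention: shift so min(z - r) = 0 (surface) or min(z) = 0
      double zmin = INFINITY;
      for (int b = 0; b < nb; ++b) {
        double z = surfaceStage ? rot(b, 2) - rad[b] : rot(b, 2);
        if (z < zmin) zmin = z;
      }
      for (int iR = 0; iR < Rvals.size(); ++iR)
      for (int iT = 0; iT < Tvals.size(); ++iT) {
        double cosT = std::cos(Tvals[iT] * DEG), sinT = std::sin(Tvals[iT] * DEG);
        double Rtip = Rvals[iR];
        for (int i = 0; i < ny; ++i) {
          double cy = oy + (i + 0.5) * px;
          for (int j = 0; j < nx; ++j) {
            double cx = ox + (j + 0.5) * px;
            double h = 0.0;
            for (int b = 0; b < nb; ++b) {
              double dx = rot(b, 0) - cx, dy = rot(b, 1) - cy;
              double d = std::sqrt(dx * dx + dy * dy);
              double z = contact_z(rot(b, 2) - zmin, rad[b], d, Rtip, cosT, sinT);
              if (z > h) h = z;
            }
            sim(i, j) = h;
          }
        }
        // integer pixel shifts with zero fill: sim'(i,j) = sim(i-sy, j-sx)
        for (int sy = -shiftPx; sy <= shiftPx; ++sy)
        for (int sx = -shiftPx; sx <= shiftPx; ++sx) {
          double ss = 0, ss2 = 0, sprod = 0;
          for (int i = 0; i < ny; ++i) {
            int i0 = i - sy;
            if (i0 < 0 || i0 >= ny) continue;
            for (int j = 0; j < nx; ++j) {
              int j0 = j - sx;
              if (j0 < 0 || j0 >= nx) continue;
              double v = sim(i0, j0);
              ss += v; ss2 += v * v; sprod += v * ref(i, j);
            }
          }
          double msim = ss / np;
          double vsim = ss2 - np * msim * msim;
          if (vsim <= 1e-300) continue; // constant render: cc undefined
          double cc = (sprod - np * msim * mref) / std::sqrt(vsim * vref);
          if (cc > bestCC) {
            bestCC = cc; bState = c; bPsi = ip; bPhi = ih; bTheta = it;
            bR = iR; bT = iT; bSx = sx; bSy = sy;
          }
          if (keep > 0) {
            if ((int)topCC.size() < keep || cc > topCC.back()) {
              std::array<int, 8> idx = {c, ip, ih, it, iR, iT, sx, sy};
              size_t pos = 0;
              while (pos < topCC.size() && topCC[pos] >= cc) ++pos;
              topCC.insert(topCC.begin() + pos, cc);
              topIdx.insert(topIdx.begin() + pos, idx);
              if ((int)topCC.size() > keep) { topCC.pop_back(); topIdx.pop_back(); }
            }
          }
        }
      }
    }
  }
  if (bState < 0) stop("all candidate renders were constant");
  int ntop = topCC.size();
  IntegerMatrix topm(ntop, 8);
  NumericVector topc(ntop);
  for (int i = 0; i < ntop; ++i) {
    for (int k = 0; k < 8; ++k) topm(i, k) = topIdx[i][k];
    topc[i] = topCC[i];
  }
  return List::create(
    _["cc"] = bestCC, _["state"] = bState + 1,
    _["iPsi"] = bPsi + 1, _["iPhi"] = bPhi + 1, _["iTheta"] = bTheta + 1,
    _["iR"] = bR + 1, _["iT"] = bT + 1, _["sx"] = bSx, _["sy"] = bSy,
    _["topIdx"] = topm, _["topCC"] = topc);
}
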