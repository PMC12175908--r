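#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- small vector helpers ---------------------------------------------------

static inline double dist3(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline void unit_gauss(double *d) {
  // isotropic random unit vector from three normals (uses R's RNG)
  double n = 0.0;
  do {
    d[0] = norm_rand(); d[1] = norm_rand(); d[2] = norm_rand();
    n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  } while (n < 1e-12);
  d[0] /= n; d[1] /= n; d[2] /= n;
}

static inline void normalize3(double *d) {
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (n < 1e-12) { d[0] = 1.0; d[1] = 0.0; d[2] = 0.0; return; }
  d[0] /= n; d[1] /= n; d[2] /= n;
}

// two unit vectors perpendicular to u
static inline void perp_frame(const double *u, double *v, double *w) {
  double t[3] = {1.0, 0.0, 0.0};
  if (std::fabs(u[0]) > 0.9) { t[0] = 0.0; t[1] = 1.0; }
  // v = normalize(t x u)
  v[0] = t[1] * u[2] - t[2] * u[1];
  v[1] = t[2] * u[0] - t[0] * u[2];
  v[2] = t[0] * u[1] - t[1] * u[0];
  normalize3(v);
  // w = u x v
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

// ---- self-avoiding chain growth --------------------------------------------

// clash of candidate position p against beads [0, upto) of P (skip indices >= skipFrom)
// and against obstacle beads
static bool clash_free(const double *p, const NumericMatrix &P, int upto, int skipFrom,
                       double dmin, const NumericMatrix &obst, double dminObst) {
  double q[3];
  for (int j = 0; j < upto; ++j) {
    if (j >= skipFrom) continue;
    q[0] = P(j, 0); q[1] = P(j, 1); q[2] = P(j, 2);
    if (dist3(p, q) < dmin) return false;
  }
  for (int j = 0; j < obst.nrow(); ++j) {
    q[0] = obst(j, 0); q[1] = obst(j, 1); q[2] = obst(j, 2);
    if (dist3(p, q) < dminObst) return false;
  }
  return true;
}

// Ideal alpha-helix C-alpha trace: rise 1.5 A, radius 2.3 A, 100 deg/residue.
// Returns positions with bead 0 at p0, axis u.
static void helix_positions(const double *p0, const double *u, int len, double *out) {
  const double rise = 1.5, rad = 2.3, twist = 100.0 * M_PI / 180.0;
  double v[3], w[3];
  perp_frame(u, v, w);
  for (int k = 0; k < len; ++k) {
    double c = std::cos(twist * k) - 1.0, s = std::sin(twist * k);
    for (int d = 0; d < 3; ++d)
      out[3 * k + d] = p0[d] + u[d] * rise * k + rad * (v[d] * c + w[d] * s);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_grow_chain(int n, double bond, double dminChain, double dminObst,
                             IntegerMatrix helix, NumericMatrix anchorTarget,
                             double anchorTol, NumericMatrix obstacles,
                             double kappa, NumericVector attract,
                             int maxTries, int maxRestarts) {
  NumericMatrix P(n, 3);
  int H = helix.nrow();
  // helix id per bead (-1 = linker), 0-based residues
  std::vector<int> hid(n, -1);
  for (int h = 0; h < H; ++h)
    for (int r = helix(h, 0) - 1; r <= helix(h, 1) - 1; ++r)
      if (r >= 0 && r < n) hid[r] = h;

  int lastFail = -1;
  for (int rs = 0; rs <= maxRestarts; ++rs) {
    bool failed = false;
    double cen[3] = {0.0, 0.0, 0.0}; // running centroid of placed beads
    int i = 0;
    while (i < n && !failed) {
      int h = hid[i];
      bool helixStart = (h >= 0) && (i == helix(h, 0) - 1);
      if (helixStart) {
        int len = helix(h, 1) - helix(h, 0) + 1;
        bool anch = R_finite(anchorTarget(h, 0));
        double T[3] = {anchorTarget(h, 0), anchorTarget(h, 1), anchorTarget(h, 2)};
        bool ok = false;
        double nface[3] = {0.0, 0.0, 0.0};
        bool haveFace = anch && obstacles.nrow() > 0;
        if (haveFace) {
          double oc[3] = {0.0, 0.0, 0.0};
          for (int j = 0; j < obstacles.nrow(); ++j)
            for (int d = 0; d < 3; ++d) oc[d] += obstacles(j, d);
          for (int d = 0; d < 3; ++d) nface[d] = T[d] - oc[d] / obstacles.nrow();
          normalize3(nface);
        }
        for (int t = 0; t < 3 * maxTries && !ok; ++t) {
          double p0[3];
          if (i == 0) {
            if (anch) {
              double d0[3]; unit_gauss(d0);
              double rr = anchorTol * unif_rand();
              for (int d = 0; d < 3; ++d) p0[d] = T[d] + rr * d0[d];
            } else { p0[0] = p0[1] = p0[2] = 0.0; }
          } else {
            double dir[3]; unit_gauss(dir);
            if (anch) { // pull the connecting step toward the anchor site
              double a[3] = {T[0] - P(i - 1, 0), T[1] - P(i - 1, 1), T[2] - P(i - 1, 2)};
              normalize3(a);
              double damp = 1.0 / (1.0 + t / 25.0);
              for (int d = 0; d < 3; ++d) dir[d] += damp * 2.0 * a[d];
              normalize3(dir);
            }
            for (int d = 0; d < 3; ++d) p0[d] = P(i - 1, d) + bond * dir[d];
            if (anch && dist3(p0, T) > anchorTol) continue;
          }
          double u[3]; unit_gauss(u);
          if (haveFace) { // keep the helix axis tangential or outward
            double c = u[0] * nface[0] + u[1] * nface[1] + u[2] * nface[2];
            if (c < 0.0) for (int d = 0; d < 3; ++d) u[d] -= 2.0 * c * nface[d];
            normalize3(u);
          }
          std::vector<double> hp(3 * len);
          helix_positions(p0, u, len, hp.data());
          bool cf = true;
          for (int k = 0; k < len && cf; ++k) {
            int skip = (k == 0 && i > 0) ? (i - 1) : i; // allow bond to predecessor
            cf = clash_free(&hp[3 * k], P, i, skip, dminChain, obstacles, dminObst);
          }
          if (!cf) continue;
          for (int k = 0; k < len; ++k)
            for (int d = 0; d < 3; ++d) P(i + k, d) = hp[3 * k + d];
          ok = true;
        }
        if (!ok) { failed = true; break; }
        for (int k = 0; k < len; ++k)
          for (int d = 0; d < 3; ++d) cen[d] += (P(i + k, d) - cen[d]) / (i + k + 1.0);
        i += len;
        continue;
      }
      // linker bead
      // next anchored helix start after i (for bridging bias)
      int nextA = -1, stepsTo = 0;
      for (int h2 = 0; h2 < H; ++h2) {
        int s = helix(h2, 0) - 1;
        if (s >= i && R_finite(anchorTarget(h2, 0))) {
          if (nextA < 0 || s < stepsTo + i) { nextA = h2; stepsTo = s - i; }
        }
      }
      bool ok = false;
      for (int t = 0; t < maxTries && !ok; ++t) {
        double p[3];
        if (i == 0) {
          if (nextA >= 0) { // start within reach of the first anchor
            double T[3] = {anchorTarget(nextA, 0), anchorTarget(nextA, 1), anchorTarget(nextA, 2)};
            double d0[3]; unit_gauss(d0);
            double rhi = std::max(5.0, std::min(stepsTo * bond * 0.8, 25.0));
            double rr = 4.0 + (rhi - 4.0) * std::pow(unif_rand(), 1.0 / 3.0);
            for (int d = 0; d < 3; ++d) p[d] = T[d] + rr * d0[d];
          } else { p[0] = p[1] = p[2] = 0.0; }
        } else {
          double dir[3]; unit_gauss(dir);
          // fade the soft biases out over failed tries so a clash-free
          // direction can always be found; hard constraints stay as
          // rejections below
          double damp = 1.0 / (1.0 + t / 25.0);
          if (kappa > 0.0 && attract.size() == 3) {
            double a[3] = {attract[0] - P(i - 1, 0), attract[1] - P(i - 1, 1), attract[2] - P(i - 1, 2)};
            normalize3(a);
            for (int d = 0; d < 3; ++d) dir[d] += damp * kappa * a[d];
          } else if (kappa < 0.0 && i > 1) {
            double a[3] = {P(i - 1, 0) - cen[0], P(i - 1, 1) - cen[1], P(i - 1, 2) - cen[2]};
            normalize3(a);
            for (int d = 0; d < 3; ++d) dir[d] += damp * (-kappa) * a[d];
          }
          if (nextA >= 0 && stepsTo > 0) {
            double T[3] = {anchorTarget(nextA, 0), anchorTarget(nextA, 1), anchorTarget(nextA, 2)};
            double prev[3] = {P(i - 1, 0), P(i - 1, 1), P(i - 1, 2)};
            double dT = dist3(prev, T);
            double rho = dT / (stepsTo * bond);
            double g = 4.0 * std::pow(std::min(rho, 1.2), 6.0);
            // staged waypoints route the approach over the obstacle pole and
            // outside the target face, so the guidance never points across
            // the excluded bundle; the reachability rejection below stays
            // expressed against the anchor itself
            double W[3] = {T[0], T[1], T[2]};
            double guide = 0.0;
            if (obstacles.nrow() > 0) {
              if (stepsTo > 55) {
                guide = 0.0;
              } else if (stepsTo > 30) {
                W[0] = 0.0; W[1] = 0.0; W[2] = (prev[2] >= 0.0 ? 34.0 : -34.0);
                guide = 1.5;
              } else if (stepsTo > 8) {
                W[0] = 2.0 * T[0]; W[1] = 2.0 * T[1]; W[2] = 2.0 * T[2];
                guide = 1.5;
              } else {
                guide = 1.0;
              }
            }
            double aw[3] = {W[0] - prev[0], W[1] - prev[1], W[2] - prev[2]};
            normalize3(aw);
            for (int d = 0; d < 3; ++d) dir[d] += (g + guide) * damp * aw[d];
          }
          normalize3(dir);
          for (int d = 0; d < 3; ++d) p[d] = P(i - 1, d) + bond * dir[d];
          if (nextA >= 0) { // keep the anchor reachable
            double T[3] = {anchorTarget(nextA, 0), anchorTarget(nextA, 1), anchorTarget(nextA, 2)};
            double rem = (stepsTo - 1) * bond * 0.95 + anchorTol + 0.5 * bond;
            if (stepsTo > 0 && dist3(p, T) > rem) continue;
          }
        }
        int skip = (i > 0) ? (i - 1) : i;
        if (!clash_free(p, P, i, skip, dminChain, obstacles, dminObst)) continue;
        for (int d = 0; d < 3; ++d) P(i, d) = p[d];
        ok = true;
      }
      if (!ok) { failed = true; break; }
      for (int d = 0; d < 3; ++d) cen[d] += (P(i, d) - cen[d]) / (i + 1.0);
      ++i;
    }
    if (!failed) return P;
    lastFail = i;
  }
  stop("chain growth failed after %d restarts (excluded volume/anchoring infeasible near bead %d)",
       maxRestarts, lastFail + 1);
  return P; // not reached
}

// ---- batch Solomon-Bloembergen Gamma2 ---------------------------------------

// coords: nb x 3 x nf array (Angstrom). Electron candidates on a spherical-cap
// Fibonacci grid of half-angle coneHalf around the outward axis
// (attachment - centroid of centroidIdx), at tether length from the attachment
// bead; Boltzmann weights from a soft-sphere clash energy against all beads
// except excludeIdx.
// [[Rcpp::export]]
NumericMatrix cpp_gamma2_site(NumericVector coords, IntegerVector dims,
                              IntegerVector protonIdx, int attachIdx,
                              IntegerVector centroidIdx, IntegerVector excludeIdx,
                              int K, double tether, double coneHalf,
                              double clashSigma, double clashEps,
                              double prefactor, double tauc, double taut,
                              double omega) {
  int nb = dims[0], nf = dims[2];
  int np = protonIdx.size();
  NumericMatrix G(np, nf);
  const double *X = coords.begin();
  std::vector<char> excl(nb, 0);
  for (int j = 0; j < excludeIdx.size(); ++j) excl[excludeIdx[j]] = 1;
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  double cosA = std::cos(coneHalf);
  double d0 = tauc / (1.0 + omega * omega * tauc * tauc);
  double d1 = taut / (1.0 + omega * omega * taut * taut);

  std::vector<double> E(K), pK(K), ex(K), ey(K), ez(K);
  for (int f = 0; f < nf; ++f) {
    const double *xf = X + (size_t)f * nb * 3; // column-major: [nb x 3]
    double at[3] = {xf[attachIdx], xf[attachIdx + nb], xf[attachIdx + 2 * nb]};
    double cen[3] = {0, 0, 0};
    for (int j = 0; j < centroidIdx.size(); ++j) {
      int b = centroidIdx[j];
      cen[0] += xf[b]; cen[1] += xf[b + nb]; cen[2] += xf[b + 2 * nb];
    }
    for (int d = 0; d < 3; ++d) cen[d] /= centroidIdx.size();
    double u[3] = {at[0] - cen[0], at[1] - cen[1], at[2] - cen[2]};
    normalize3(u);
    double v[3], w[3];
    perp_frame(u, v, w);
    // candidate electron positions + clash energies
    double Emin = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double ct = 1.0 - (1.0 - cosA) * ((k + 0.5) / K);
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph = golden * k;
      double dir[3];
      for (int d = 0; d < 3; ++d)
        dir[d] = u[d] * ct + st * (v[d] * std::cos(ph) + w[d] * std::sin(ph));
      ex[k] = at[0] + tether * dir[0];
      ey[k] = at[1] + tether * dir[1];
      ez[k] = at[2] + tether * dir[2];
      double e = 0.0;
      for (int b = 0; b < nb; ++b) {
        if (excl[b]) continue;
        double dx = ex[k] - xf[b], dy = ey[k] - xf[b + nb], dz = ez[k] - xf[b + 2 * nb];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 1e-4) r2 = 1e-4;
        double s2 = clashSigma * clashSigma / r2;
        if (s2 > 0.04) { // skip negligible contributions (r > 5 sigma)
          double s6 = s2 * s2 * s2;
          e += clashEps * s6 * s6;
        }
      }
      E[k] = e;
      if (e < Emin) Emin = e;
    }
    double Z = 0.0;
    for (int k = 0; k < K; ++k) { pK[k] = std::exp(-(E[k] - Emin)); Z += pK[k]; }
    for (int k = 0; k < K; ++k) pK[k] /= Z;
    // per-proton moments and order parameters
    for (int ip = 0; ip < np; ++ip) {
      int b = protonIdx[ip];
      double hx = xf[b], hy = xf[b + nb], hz = xf[b + 2 * nb];
      double m3 = 0.0, m6 = 0.0;
      double M[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (int k = 0; k < K; ++k) {
        double dx = hx - ex[k], dy = hy - ey[k], dz = hz - ez[k];
        double rA = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (rA < 1e-3) rA = 1e-3;
        double rm = rA * 1e-10; // metres
        double r3 = 1.0 / (rm * rm * rm), r6 = r3 * r3;
        double q = pK[k] * r3;
        m3 += q; m6 += pK[k] * r6;
        double exu = dx / rA, eyu = dy / rA, ezu = dz / rA;
        M[0] += q * exu * exu; M[1] += q * exu * eyu; M[2] += q * exu * ezu;
        M[4] += q * eyu * eyu; M[5] += q * eyu * ezu; M[8] += q * ezu * ezu;
      }
      double s2ang = 0.0;
      double tr2 = M[0] * M[0] + M[4] * M[4] + M[8] * M[8] +
        2.0 * (M[1] * M[1] + M[2] * M[2] + M[5] * M[5]);
      s2ang = 1.5 * tr2 / (m3 * m3) - 0.5;
      if (s2ang < 0.0) s2ang = 0.0;
      if (s2ang > 1.0) s2ang = 1.0;
      double s2rad = m3 * m3 / m6;
      double S2 = s2ang * s2rad;
      double J0 = m6 * (S2 * tauc + (1.0 - S2) * taut);
      double Jw = m6 * (S2 * d0 + (1.0 - S2) * d1);
      G(ip, f) = prefactor * (4.0 * J0 + 3.0 * Jw);
    }
  }
  return G;
}

// ---- minimum inter-segment distances ----------------------------------------

// coords: nb x 3 x nf; segStart/segEnd: 0-based inclusive bead index per segment;
// pairs: P x 2 (0-based segment ids). Returns P x nf minimum distances.
// [[Rcpp::export]]
NumericMatrix cpp_segpair_mindist(NumericVector coords, IntegerVector dims,
                                  IntegerVector segStart, IntegerVector segEnd,
                                  IntegerMatrix pairs) {
  int nb = dims[0], nf = dims[2], P = pairs.nrow();
  NumericMatrix D(P, nf);
  const double *X = coords.begin();
  for (int f = 0; f < nf; ++f) {
    const double *xf = X + (size_t)f * nb * 3;
    for (int p = 0; p < P; ++p) {
      int a = pairs(p, 0), b = pairs(p, 1);
      double best = R_PosInf;
      for (int i = segStart[a]; i <= segEnd[a]; ++i) {
        double xi = xf[i], yi = xf[i + nb], zi = xf[i + 2 * nb];
        for (int j = segStart[b]; j <= segEnd[b]; ++j) {
          double dx = xi - xf[j], dy = yi - xf[j + nb], dz = zi - xf[j + 2 * nb];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < best) best = r2;
        }
      }
      D(p, f) = std::sqrt(best);
    }
  }
  return D;
}
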