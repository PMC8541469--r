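#include <Rcpp.h>
#include <vector>
#include "physics.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Monte Carlo coincidence simulator: back-to-back 511 keV photon pairs from
// cylindrical sources, Woodcock (delta) tracking through axis-aligned
// cylinder phantoms with Compton (Klein-Nishina) and photoelectric
// interactions, detection on the inner faces of a polygonal block ring,
// Gaussian energy blur, and coincidence acceptance.
// All randomness goes through R's RNG so set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

namespace {

struct Cyl {
  double cx, cy, cz, r2, hh;
  int mat;  // 0 air, 1 water
};

// later list entries override earlier ones (enables cold/air inserts)
inline int material_at(const std::vector<Cyl>& ph, double x, double y, double z) {
  for (int i = (int)ph.size() - 1; i >= 0; --i) {
    const Cyl& c = ph[i];
    double dx = x - c.cx, dy = y - c.cy;
    if (std::fabs(z - c.cz) <= c.hh && dx * dx + dy * dy <= c.r2) return c.mat;
  }
  return 0;
}

inline double runif_pos() {
  double u = unif_rand();
  return (u <= 0.0) ? 1e-300 : u;
}

// rejection sampling of cos(theta) against the Klein-Nishina differential
// cross-section; dsigma/dOmega is maximal at theta = 0 where the weight is 2
inline double kn_sample_cost(double E) {
  double a = E / pet::MEC2;
  for (;;) {
    double c = 2.0 * unif_rand() - 1.0;
    double r = 1.0 / (1.0 + a * (1.0 - c));
    double w = r * r * (r + 1.0 / r - 1.0 + c * c);
    if (2.0 * unif_rand() <= w) return c;
  }
}

inline void rotate_direction(double& dx, double& dy, double& dz,
                             double cost, double phi) {
  // orthonormal basis around (dx,dy,dz)
  double e1x, e1y, e1z;
  if (std::fabs(dz) < 0.999) {
    // e1 = d x zhat (normalized)
    double nrm = std::sqrt(dx * dx + dy * dy);
    e1x = dy / nrm; e1y = -dx / nrm; e1z = 0.0;
  } else {
    e1x = 1.0; e1y = 0.0; e1z = 0.0;
  }
  // e2 = d x e1
  double e2x = dy * e1z - dz * e1y;
  double e2y = dz * e1x - dx * e1z;
  double e2z = dx * e1y - dy * e1x;
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx = cost * dx + sint * (cp * e1x + sp * e2x);
  double ny = cost * dy + sint * (cp * e1y + sp * e2y);
  double nz = cost * dz + sint * (cp * e1z + sp * e2z);
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx / nrm; dy = ny / nrm; dz = nz / nrm;
}

struct PhotonState {
  bool alive;
  double x, y, z, dx, dy, dz, E;
  int nscat;
};

// Woodcock tracking with majorant mu_total_water(E); air is vacuum so every
// tentative collision inside water is real.  The returned position is the
// last in-world point, a valid ray origin for the (vacuum) flight to the ring.
PhotonState transport(double x, double y, double z,
                      double dx, double dy, double dz, double E,
                      const std::vector<Cyl>& ph,
                      double world_r2, double world_hz, double cutoff) {
  PhotonState s{true, x, y, z, dx, dy, dz, E, 0};
  if (ph.empty()) return s;
  for (;;) {
    double mu = pet::mu_total_water(s.E);
    double step = -std::log(runif_pos()) / mu;
    double nx = s.x + step * s.dx, ny = s.y + step * s.dy, nz = s.z + step * s.dz;
    if (nx * nx + ny * ny > world_r2 || std::fabs(nz) > world_hz) {
      return s;  // exits the phantom world
    }
    s.x = nx; s.y = ny; s.z = nz;
    if (material_at(ph, s.x, s.y, s.z) == 1) {
      double muc = pet::mu_compton_water(s.E);
      if (unif_rand() < muc / mu) {
        double c = kn_sample_cost(s.E);
        double ep = pet::compton_eprime(s.E, c);
        rotate_direction(s.dx, s.dy, s.dz, c, 2.0 * M_PI * unif_rand());
        s.E = ep;
        s.nscat += 1;
        if (s.E < cutoff) { s.alive = false; return s; }
      } else {
        s.alive = false;  // photoelectric absorption
        return s;
      }
    }
    // air: virtual collision, keep flying
  }
}

struct Hit {
  bool ok;
  int block;
  double u, v, doi, t;
};

// nearest block inner face crossed by the ray (x,y,z) + t*(dx,dy,dz)
Hit detect(double x, double y, double z, double dx, double dy, double dz,
           int n_blocks, const std::vector<double>& bc,
           const std::vector<double>& bs,
           double apothem, double half_w, double half_h, double depth) {
  Hit best{false, -1, 0, 0, 0, 1e300};
  for (int k = 0; k < n_blocks; ++k) {
    double nx = bc[k], ny = bs[k];
    double dn = dx * nx + dy * ny;
    if (dn <= 1e-12) continue;  // must approach the face from inside
    double t = (apothem - (x * nx + y * ny)) / dn;
    if (t <= 1e-9 || t >= best.t) continue;
    double hx = x + t * dx, hy = y + t * dy, hz = z + t * dz;
    double u = -hx * ny + hy * nx;  // tangential coordinate
    if (std::fabs(u) <= half_w && std::fabs(hz) <= half_h) {
      best.ok = true; best.block = k; best.u = u; best.v = hz; best.t = t;
      double chord = depth / dn;                   // chord through the crystal slab
      best.doi = std::min(depth, 0.5 * chord);     // midpoint-depth surrogate
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_compton_energy(NumericVector E, NumericVector theta) {
  R_xlen_t n = std::max(E.size(), theta.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double c = std::cos(theta[i % theta.size()]);
    out[i] = pet::compton_eprime(E[i % E.size()], c);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mu_water(NumericVector E) {
  NumericMatrix out(E.size(), 3);
  for (R_xlen_t i = 0; i < E.size(); ++i) {
    out(i, 0) = pet::mu_compton_water(E[i]);
    out(i, 1) = pet::mu_photo_water(E[i]);
    out(i, 2) = pet::mu_total_water(E[i]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_kn(double E, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::acos(kn_sample_cost(E));
  return out;
}

// Transport n independent photons from one origin/direction; for tests
// (Beer-Lambert survival, vacuum transport, multiplicity distributions).
// [[Rcpp::export]]
NumericMatrix cpp_transport_pencil(NumericVector origin, NumericVector dir,
                                   double E0, NumericMatrix phantom,
                                   double world_r, double world_hz,
                                   double cutoff, int n) {
  std::vector<Cyl> ph;
  for (int i = 0; i < phantom.nrow(); ++i) {
    ph.push_back({phantom(i, 0), phantom(i, 1), phantom(i, 2),
                  phantom(i, 3) * phantom(i, 3), phantom(i, 4),
                  (int)phantom(i, 5)});
  }
  NumericMatrix out(n, 9);  // alive,x,y,z,dx,dy,dz,E,nscat
  for (int i = 0; i < n; ++i) {
    PhotonState s = transport(origin[0], origin[1], origin[2],
                              dir[0], dir[1], dir[2], E0, ph,
                              world_r * world_r, world_hz, cutoff);
    out(i, 0) = s.alive; out(i, 1) = s.x; out(i, 2) = s.y; out(i, 3) = s.z;
    out(i, 4) = s.dx; out(i, 5) = s.dy; out(i, 6) = s.dz;
    out(i, 7) = s.E; out(i, 8) = s.nscat;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(double n_decays, NumericMatrix src, List src_excl,
                  NumericMatrix phantom, int n_blocks, double apothem,
                  double half_w, double half_h, double block_depth,
                  double fwhm_frac, double acc_lo, double acc_hi, int min_sep,
                  double cutoff, double world_r, double world_hz,
                  double time0) {
  std::vector<Cyl> ph;
  for (int i = 0; i < phantom.nrow(); ++i) {
    ph.push_back({phantom(i, 0), phantom(i, 1), phantom(i, 2),
                  phantom(i, 3) * phantom(i, 3), phantom(i, 4),
                  (int)phantom(i, 5)});
  }
  int ncomp = src.nrow();
  std::vector<double> cum(ncomp);
  double tot = 0.0;
  for (int i = 0; i < ncomp; ++i) { tot += src(i, 5); cum[i] = tot; }
  if (tot <= 0.0) {
    return List::create(_["events"] = NumericMatrix(0, 17),
                        _["counters"] = NumericVector::create(0, 0, 0, 0, 0, 0),
                        _["component_decays"] = NumericVector(ncomp));
  }
  std::vector<std::vector<Cyl>> excl(ncomp);
  for (int i = 0; i < ncomp; ++i) {
    NumericMatrix em = src_excl[i];
    for (int j = 0; j < em.nrow(); ++j) {
      excl[i].push_back({em(j, 0), em(j, 1), em(j, 2),
                         em(j, 3) * em(j, 3), em(j, 4), 0});
    }
  }

  std::vector<double> bc(n_blocks), bs(n_blocks);
  for (int k = 0; k < n_blocks; ++k) {
    double a = 2.0 * M_PI * k / n_blocks;
    bc[k] = std::cos(a); bs[k] = std::sin(a);
  }

  double world_r2 = world_r * world_r;
  double sig511 = fwhm_frac * pet::MEC2 / 2.3548200450309493;
  std::vector<double> rows;
  rows.reserve(1 << 16);
  NumericVector comp_decays(ncomp);
  double n_both_exit = 0, n_both_hit = 0, n_same_block = 0,
         n_pair_rej = 0, n_window_rej = 0, n_acc = 0;

  for (double idec = 0; idec < n_decays; ++idec) {
    // emission point
    double u = unif_rand() * tot;
    int ic = 0;
    while (u > cum[ic]) ++ic;
    comp_decays[ic] += 1;
    double px, py, pz;
    for (int tries = 0;; ++tries) {
      double rr = std::sqrt(unif_rand()) * src(ic, 3);
      double ang = 2.0 * M_PI * unif_rand();
      px = src(ic, 0) + rr * std::cos(ang);
      py = src(ic, 1) + rr * std::sin(ang);
      pz = src(ic, 2) + (2.0 * unif_rand() - 1.0) * src(ic, 4);
      bool inside_excl = false;
      for (const Cyl& c : excl[ic]) {
        double ddx = px - c.cx, ddy = py - c.cy;
        if (std::fabs(pz - c.cz) <= c.hh && ddx * ddx + ddy * ddy <= c.r2) {
          inside_excl = true; break;
        }
      }
      if (!inside_excl || tries > 1000) break;
    }
    // isotropic back-to-back pair
    double ct = 2.0 * unif_rand() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double aphi = 2.0 * M_PI * unif_rand();
    double dx = st * std::cos(aphi), dy = st * std::sin(aphi), dz = ct;

    PhotonState p1 = transport(px, py, pz, dx, dy, dz, pet::MEC2, ph,
                               world_r2, world_hz, cutoff);
    if (!p1.alive) continue;
    PhotonState p2 = transport(px, py, pz, -dx, -dy, -dz, pet::MEC2, ph,
                               world_r2, world_hz, cutoff);
    if (!p2.alive) continue;
    n_both_exit += 1;

    Hit h1 = detect(p1.x, p1.y, p1.z, p1.dx, p1.dy, p1.dz, n_blocks, bc, bs,
                    apothem, half_w, half_h, block_depth);
    if (!h1.ok) continue;
    Hit h2 = detect(p2.x, p2.y, p2.z, p2.dx, p2.dy, p2.dz, n_blocks, bc, bs,
                    apothem, half_w, half_h, block_depth);
    if (!h2.ok) continue;
    n_both_hit += 1;

    if (h1.block == h2.block) { n_same_block += 1; continue; }
    int d = std::abs(h1.block - h2.block);
    int circ = std::min(d, n_blocks - d);
    if (circ < min_sep) { n_pair_rej += 1; continue; }

    double e1 = p1.E + norm_rand() * sig511 * std::sqrt(p1.E / pet::MEC2);
    double e2 = p2.E + norm_rand() * sig511 * std::sqrt(p2.E / pet::MEC2);
    if (e1 < acc_lo || e1 > acc_hi || e2 < acc_lo || e2 > acc_hi) {
      n_window_rej += 1; continue;
    }
    n_acc += 1;
    double row[17] = {(double)h1.block, h1.u, h1.v, h1.doi, e1, p1.E,
                      (double)p1.nscat,
                      (double)h2.block, h2.u, h2.v, h2.doi, e2, p2.E,
                      (double)p2.nscat,
                      pz, (double)(ic + 1), time0 + idec};
    rows.insert(rows.end(), row, row + 17);
  }

  R_xlen_t nev = (R_xlen_t)(rows.size() / 17);
  NumericMatrix events(nev, 17);
  for (R_xlen_t i = 0; i < nev; ++i)
    for (int j = 0; j < 17; ++j) events(i, j) = rows[i * 17 + j];
  NumericVector counters = NumericVector::create(
      _["emitted"] = n_decays, _["both_exited"] = n_both_exit,
      _["both_hit"] = n_both_hit, _["same_block"] = n_same_block,
      _["pair_rejected"] = n_pair_rej, _["window_rejected"] = n_window_rej);
  return List::create(_["events"] = events, _["counters"] = counters,
                      _["component_decays"] = comp_decays);
}
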