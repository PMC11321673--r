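// Stokes-tracked polarized Monte Carlo photon transport through a
// smoke-over-surface slab. The R surface (run_simulation, scatter_photon,
// surface_interaction) wraps the entry points at the bottom of this file.
//
// Conventions:
//  * z axis points down into the slab; the source enters at z = 0 moving +z.
//  * Each photon carries an orthonormal frame (u, v): u is the propagation
//    direction, v the Stokes reference axis (Q = +1 means E parallel to v).
//    w = u x v completes the right-handed triad.
//  * Rotating the reference frame by phi about u maps v -> v cos(phi) +
//    w sin(phi) and the Stokes vector by the usual rotation Mueller matrix
//    Q' = Q cos(2phi) + U sin(2phi), U' = -Q sin(2phi) + U cos(2phi).
//  * The sphere Mueller matrix acts in the scattering-plane frame:
//    I' = S11 I + S12 Q ; Q' = S12 I + S11 Q ;
//    U' = S33 U + S34 V ; V' = -S34 U + S33 V.
//  * Stokes vectors are kept normalized to I = 1; energy lives in the
//    scalar weight. Joint (theta, phi) sampling from the polarization-
//    dependent density keeps the weight unbiased without an extra factor.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic, platform-independent RNG (xorshift128+ seeded by splitmix64)

struct Rng {
  uint64_t s0, s1;
  double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);  // in (0,1)
  }
};

static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// one independent substream per photon index: results do not depend on
// execution order
static Rng photon_rng(uint64_t seed, uint64_t index) {
  uint64_t st = seed ^ (0xA24BAED4963EE407ULL * (index + 1));
  Rng r;
  r.s0 = splitmix64(st);
  r.s1 = splitmix64(st);
  if (r.s0 == 0 && r.s1 == 0) r.s1 = 1;
  for (int i = 0; i < 4; ++i) r.unif();
  return r;
}

// ---------------------------------------------------------------------------
// small vector helpers

static inline void cross(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void normalize(double a[3]) {
  double n = std::sqrt(dot(a, a));
  a[0] /= n; a[1] /= n; a[2] /= n;
}

static inline void rotate_stokes(double S[4], double phi) {
  double c = std::cos(2.0 * phi), s = std::sin(2.0 * phi);
  double Q = S[1] * c + S[2] * s;
  double U = -S[1] * s + S[2] * c;
  S[1] = Q; S[2] = U;
}

// ---------------------------------------------------------------------------
// tabulated single-scattering matrix (uniform angle grid, radians)

struct PhaseTable {
  std::vector<double> theta, s11, s12, s33, s34, cdf;
  double dtheta;

  void interp(double th, double& a11, double& a12, double& a33,
              double& a34) const {
    double pos = th / dtheta;
    int i = (int)pos;
    int n = (int)theta.size();
    if (i >= n - 1) i = n - 2;
    if (i < 0) i = 0;
    double f = pos - i;
    a11 = s11[i] + f * (s11[i + 1] - s11[i]);
    a12 = s12[i] + f * (s12[i + 1] - s12[i]);
    a33 = s33[i] + f * (s33[i + 1] - s33[i]);
    a34 = s34[i] + f * (s34[i + 1] - s34[i]);
  }

  // inverse-CDF sample of the polar scattering angle
  double sample_theta(double u) const {
    int lo = 0, hi = (int)cdf.size() - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] <= u) lo = mid; else hi = mid;
    }
    double c0 = cdf[lo], c1 = cdf[hi];
    double f = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.0;
    return theta[lo] + f * (theta[hi] - theta[lo]);
  }
};

struct Photon {
  double pos[3];
  double u[3];  // direction
  double v[3];  // Stokes reference axis, perpendicular to u
  double S[4];  // normalized Stokes, S[0] == 1
  double w;     // weight
  int tag;      // 0 = smoke only, 1 = target interacted
};

// rotate the reference frame so that v aligns with `e1` (perpendicular to
// u); returns the Stokes vector expressed with reference e1
static void align_reference(Photon& p, const double e1[3]) {
  double w3[3];
  cross(p.u, p.v, w3);
  double alpha = std::atan2(dot(e1, w3), dot(e1, p.v));
  rotate_stokes(p.S, alpha);
  p.v[0] = e1[0]; p.v[1] = e1[1]; p.v[2] = e1[2];
}

// build the in-detector-plane reference axis: lab x projected
// perpendicular to u (fallback to lab y when u is along x)
static void detector_axis(const double u[3], double e1[3]) {
  double ax[3] = {1.0, 0.0, 0.0};
  double c = dot(ax, u);
  e1[0] = ax[0] - c * u[0];
  e1[1] = ax[1] - c * u[1];
  e1[2] = ax[2] - c * u[2];
  double n2 = dot(e1, e1);
  if (n2 < 1e-12) {
    double ay[3] = {0.0, 1.0, 0.0};
    c = dot(ay, u);
    e1[0] = ay[0] - c * u[0];
    e1[1] = ay[1] - c * u[1];
    e1[2] = ay[2] - c * u[2];
  }
  normalize(e1);
}

// single scattering event; rng supplies randomness; forced_theta/forced_phi
// (< 0 disables) pin the sampled angles for unit tests
static void scatter(Photon& p, const PhaseTable& tab, Rng& rng,
                    double forced_theta, double forced_phi,
                    double* out_theta = nullptr, double* out_phi = nullptr) {
  double th = (forced_theta >= 0) ? forced_theta
                                  : tab.sample_theta(rng.unif());
  double a11, a12, a33, a34;
  tab.interp(th, a11, a12, a33, a34);
  double r = (a11 > 0) ? a12 / a11 : 0.0;
  double q = p.S[1], uu = p.S[2];
  double phi;
  if (forced_phi >= 0) {
    phi = forced_phi;
  } else {
    double fmax = 1.0 + std::fabs(r) * std::sqrt(q * q + uu * uu) + 1e-12;
    for (;;) {
      phi = 2.0 * M_PI * rng.unif();
      double f = 1.0 + r * (q * std::cos(2.0 * phi) + uu * std::sin(2.0 * phi));
      if (rng.unif() * fmax <= f) break;
    }
  }
  if (out_theta) *out_theta = th;
  if (out_phi) *out_phi = phi;

  // rotate reference into the scattering plane
  double w3[3];
  cross(p.u, p.v, w3);
  double cp = std::cos(phi), sp = std::sin(phi);
  double v1[3] = {cp * p.v[0] + sp * w3[0],
                  cp * p.v[1] + sp * w3[1],
                  cp * p.v[2] + sp * w3[2]};
  rotate_stokes(p.S, phi);

  // deflect within the scattering plane
  double ct = std::cos(th), st = std::sin(th);
  double un[3] = {ct * p.u[0] + st * v1[0],
                  ct * p.u[1] + st * v1[1],
                  ct * p.u[2] + st * v1[2]};
  double vn[3] = {-st * p.u[0] + ct * v1[0],
                  -st * p.u[1] + ct * v1[1],
                  -st * p.u[2] + ct * v1[2]};

  // sphere Mueller matrix in the scattering-plane frame
  double I2 = a11 * p.S[0] + a12 * p.S[1];
  double Q2 = a12 * p.S[0] + a11 * p.S[1];
  double U2 = a33 * p.S[2] + a34 * p.S[3];
  double V2 = -a34 * p.S[2] + a33 * p.S[3];
  if (I2 <= 0) I2 = 1e-300;
  p.S[0] = 1.0; p.S[1] = Q2 / I2; p.S[2] = U2 / I2; p.S[3] = V2 / I2;

  normalize(un);
  // re-orthogonalize v against u to control drift
  double c = dot(vn, un);
  vn[0] -= c * un[0]; vn[1] -= c * un[1]; vn[2] -= c * un[2];
  normalize(vn);
  for (int i = 0; i < 3; ++i) { p.u[i] = un[i]; p.v[i] = vn[i]; }
}

// Fresnel interaction with the lower boundary (smooth dielectric surface
// backed by a Lambertian diffuse reflector). Returns false if the photon
// dies (weight fully transmitted/absorbed below).
static bool surface_interact(Photon& p, double n2, double diffuse_albedo,
                             Rng& rng, double& transmitted_bottom,
                             int* out_branch = nullptr) {
  p.tag = 1;
  double ci = p.u[2];                  // cos(theta_i), u points down
  if (ci < 0) ci = -ci;
  if (ci > 1) ci = 1;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double stt = si / n2;               // Snell, n1 = 1
  double ctt = std::sqrt(std::max(0.0, 1.0 - stt * stt));
  double rs = (ci - n2 * ctt) / (ci + n2 * ctt);
  double rp = (n2 * ci - ctt) / (n2 * ci + ctt);
  double Rs = rs * rs, Rp = rp * rp;

  // rotate the Stokes reference into the plane of incidence (v in-plane)
  if (si > 1e-9) {
    double zax[3] = {0.0, 0.0, 1.0};
    double e1[3];
    double c = dot(zax, p.u);
    e1[0] = zax[0] - c * p.u[0];
    e1[1] = zax[1] - c * p.u[1];
    e1[2] = zax[2] - c * p.u[2];
    normalize(e1);
    align_reference(p, e1);
  }
  // Q = +1 now means E in the plane of incidence (p-polarized)
  double Reff = 0.5 * (Rp * (1.0 + p.S[1]) + Rs * (1.0 - p.S[1]));
  if (Reff > 1) Reff = 1;

  if (rng.unif() < Reff) {
    // specular reflection, Fresnel Mueller matrix in the s-p frame
    double I2 = 0.5 * ((Rp + Rs) * p.S[0] + (Rp - Rs) * p.S[1]);
    double Q2 = 0.5 * ((Rp - Rs) * p.S[0] + (Rp + Rs) * p.S[1]);
    double U2 = rp * rs * p.S[2];
    double V2 = rp * rs * p.S[3];
    if (I2 <= 0) I2 = 1e-300;
    p.S[0] = 1.0; p.S[1] = Q2 / I2; p.S[2] = U2 / I2; p.S[3] = V2 / I2;
    double w3[3];
    cross(p.u, p.v, w3);          // s axis, unchanged by the mirror
    p.u[2] = -p.u[2];
    cross(w3, p.u, p.v);          // new in-plane axis, right-handed triad
    normalize(p.v);
    if (out_branch) *out_branch = 0;
    return true;
  }
  // transmitted into the surface: a fraction re-emerges as depolarized
  // Lambertian diffuse light, the rest is lost below
  transmitted_bottom += p.w * (1.0 - diffuse_albedo);
  p.w *= diffuse_albedo;
  if (out_branch) *out_branch = 1;
  if (p.w <= 0) return false;
  double uz = -std::sqrt(rng.unif());            // cosine-weighted, upward
  double psi = 2.0 * M_PI * rng.unif();
  double sr = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  p.u[0] = sr * std::cos(psi);
  p.u[1] = sr * std::sin(psi);
  p.u[2] = uz;
  double e1[3];
  detector_axis(p.u, e1);
  p.v[0] = e1[0]; p.v[1] = e1[1]; p.v[2] = e1[2];
  p.S[0] = 1.0; p.S[1] = 0.0; p.S[2] = 0.0; p.S[3] = 0.0;
  return true;
}

// electric-field-direction bin from a normalized Stokes vector; folding by
// Q only, so orientations psi and 180 - psi share a bin. Returns 0-based
// bin index in [0, nbins-1]; unpolarized linear part goes to the 45-deg bin.
static int efd_bin(double Q, double U, double bw_deg, int nbins) {
  double lin = std::sqrt(Q * Q + U * U);
  double theta_deg;
  if (lin < 1e-12) {
    theta_deg = 45.0;
  } else {
    double c = Q / lin;
    if (c > 1) c = 1;
    if (c < -1) c = -1;
    theta_deg = 0.5 * std::acos(c) * 180.0 / M_PI;
  }
  int b = (int)std::floor(theta_deg / bw_deg + 1e-9);
  if (b > nbins - 1) b = nbins - 1;
  if (b < 0) b = 0;
  return b;
}

// ---------------------------------------------------------------------------

static PhaseTable make_table(NumericVector theta, NumericVector s11,
                             NumericVector s12, NumericVector s33,
                             NumericVector s34, NumericVector cdf) {
  PhaseTable tab;
  tab.theta.assign(theta.begin(), theta.end());
  tab.s11.assign(s11.begin(), s11.end());
  tab.s12.assign(s12.begin(), s12.end());
  tab.s33.assign(s33.begin(), s33.end());
  tab.s34.assign(s34.begin(), s34.end());
  tab.cdf.assign(cdf.begin(), cdf.end());
  tab.dtheta = theta[1] - theta[0];
  return tab;
}

// [[Rcpp::export]]
List cpp_run_simulation(int n_photons, double seed,
                        NumericVector theta, NumericVector s11,
                        NumericVector s12, NumericVector s33,
                        NumericVector s34, NumericVector cdf,
                        double mu_s, double mu_a, double depth,
                        double surface_index, double diffuse_albedo,
                        NumericVector source_stokes,
                        double plane_half, int nx, double bin_width,
                        double roulette_threshold, double roulette_survival,
                        int max_steps) {
  PhaseTable tab = make_table(theta, s11, s12, s33, s34, cdf);
  const int nbins = (int)(90.0 / bin_width) + 1;
  const double mu_t = mu_s + mu_a;
  const double albedo_ss = (mu_t > 0) ? mu_s / mu_t : 1.0;
  const double cell = 2.0 * plane_half / nx;

  std::vector<double> stokes_acc((size_t)nx * nx * 4 * 2, 0.0);
  std::vector<double> efd_acc((size_t)nx * nx * nbins * 4 * 2, 0.0);
  double detected_top = 0, transmitted_bottom = 0, absorbed = 0,
         lost_side = 0;
  int n_capped = 0;

  double S0n = source_stokes[0];

  for (int ip = 0; ip < n_photons; ++ip) {
    if (ip % 4096 == 0) Rcpp::checkUserInterrupt();
    Rng rng = photon_rng((uint64_t)seed, (uint64_t)ip);
    Photon p;
    p.pos[0] = 0; p.pos[1] = 0; p.pos[2] = 0;
    p.u[0] = 0; p.u[1] = 0; p.u[2] = 1;
    p.v[0] = 1; p.v[1] = 0; p.v[2] = 0;
    for (int k = 0; k < 4; ++k) p.S[k] = source_stokes[k] / S0n;
    p.w = 1.0;
    p.tag = 0;
    bool alive = true;
    int steps = 0;

    while (alive) {
      if (++steps > max_steps) {
        absorbed += p.w;
        ++n_capped;
        break;
      }
      double s = (mu_t > 0) ? -std::log(rng.unif()) / mu_t : 1e30;
      double z_new = p.pos[2] + p.u[2] * s;

      if (p.u[2] < 0 && z_new <= 0) {
        // exits through the top: move to the z = 0 plane and detect
        double sb = -p.pos[2] / p.u[2];
        double x = p.pos[0] + p.u[0] * sb;
        double y = p.pos[1] + p.u[1] * sb;
        if (std::fabs(x) <= plane_half && std::fabs(y) <= plane_half) {
          double e1[3];
          detector_axis(p.u, e1);
          align_reference(p, e1);
          int ix = (int)((x + plane_half) / cell);
          int iy = (int)((y + plane_half) / cell);
          if (ix > nx - 1) ix = nx - 1;
          if (iy > nx - 1) iy = nx - 1;
          int b = efd_bin(p.S[1], p.S[2], bin_width, nbins);
          int t = p.tag;
          for (int k = 0; k < 4; ++k) {
            size_t idx = (size_t)ix + nx * ((size_t)iy + nx *
                          ((size_t)k + 4 * (size_t)t));
            stokes_acc[idx] += p.w * p.S[k];
            size_t jdx = (size_t)ix + nx * ((size_t)iy + nx *
                          ((size_t)b + nbins * ((size_t)k + 4 * (size_t)t)));
            efd_acc[jdx] += p.w * p.S[k];
          }
          detected_top += p.w;
        } else {
          lost_side += p.w;
        }
        break;
      }

      if (p.u[2] > 0 && z_new >= depth) {
        // hits the lower boundary: move there and interact
        double sb = (depth - p.pos[2]) / p.u[2];
        p.pos[0] += p.u[0] * sb;
        p.pos[1] += p.u[1] * sb;
        p.pos[2] = depth;
        alive = surface_interact(p, surface_index, diffuse_albedo, rng,
                                 transmitted_bottom);
      } else {
        // full step inside the medium, then scatter
        p.pos[0] += p.u[0] * s;
        p.pos[1] += p.u[1] * s;
        p.pos[2] = z_new;
        if (mu_t <= 0) continue;  // vacuum: keep streaming until a boundary
        absorbed += p.w * (1.0 - albedo_ss);
        p.w *= albedo_ss;
        scatter(p, tab, rng, -1.0, -1.0);
      }

      if (alive && p.w < roulette_threshold) {
        // Russian roulette; the net weight change is booked against the
        // absorbed ledger so the energy balance closes exactly per run
        if (rng.unif() < roulette_survival) {
          absorbed -= p.w * (1.0 / roulette_survival - 1.0);
          p.w /= roulette_survival;
        } else {
          absorbed += p.w;
          alive = false;
        }
      }
    }
  }

  NumericVector stokes(stokes_acc.begin(), stokes_acc.end());
  stokes.attr("dim") = IntegerVector::create(nx, nx, 4, 2);
  NumericVector efd(efd_acc.begin(), efd_acc.end());
  efd.attr("dim") = IntegerVector::create(nx, nx, nbins, 4, 2);
  return List::create(
      _["stokes"] = stokes,
      _["efd"] = efd,
      _["ledger"] = NumericVector::create(
          _["launched"] = (double)n_photons,
          _["detected_top"] = detected_top,
          _["transmitted_bottom"] = transmitted_bottom,
          _["absorbed"] = absorbed,
          _["lost_side"] = lost_side),
      _["n_capped"] = n_capped,
      _["n_bins_efd"] = nbins);
}

// repeated single-scatter events from a fixed initial state (for sampling
// and polarization unit tests)
// [[Rcpp::export]]
List cpp_scatter_samples(NumericVector u0, NumericVector v0,
                         NumericVector S0, NumericVector theta,
                         NumericVector s11, NumericVector s12,
                         NumericVector s33, NumericVector s34,
                         NumericVector cdf, int n, double seed,
                         double forced_theta, double forced_phi) {
  PhaseTable tab = make_table(theta, s11, s12, s33, s34, cdf);
  NumericVector th_out(n), phi_out(n), w_out(n);
  NumericMatrix U(n, 3), V(n, 3), S(n, 4);
  for (int i = 0; i < n; ++i) {
    Rng rng = photon_rng((uint64_t)seed, (uint64_t)i);
    Photon p;
    for (int k = 0; k < 3; ++k) { p.u[k] = u0[k]; p.v[k] = v0[k]; }
    double s0 = S0[0];
    for (int k = 0; k < 4; ++k) p.S[k] = S0[k] / s0;
    p.w = 1.0; p.tag = 0;
    double th, ph;
    scatter(p, tab, rng, forced_theta, forced_phi, &th, &ph);
    th_out[i] = th; phi_out[i] = ph; w_out[i] = p.w;
    for (int k = 0; k < 3; ++k) { U(i, k) = p.u[k]; V(i, k) = p.v[k]; }
    for (int k = 0; k < 4; ++k) S(i, k) = p.S[k];
  }
  return List::create(_["theta"] = th_out, _["phi"] = phi_out,
                      _["direction"] = U, _["reference"] = V,
                      _["stokes"] = S, _["weight"] = w_out);
}

// repeated lower-boundary interactions from a fixed initial state
// [[Rcpp::export]]
List cpp_surface_samples(NumericVector u0, NumericVector v0,
                         NumericVector S0, double surface_index,
                         double diffuse_albedo, int n, double seed) {
  NumericMatrix U(n, 3), S(n, 4);
  NumericVector w_out(n);
  IntegerVector branch(n), alive(n);
  double transmitted = 0;
  for (int i = 0; i < n; ++i) {
    Rng rng = photon_rng((uint64_t)seed, (uint64_t)i);
    Photon p;
    for (int k = 0; k < 3; ++k) { p.u[k] = u0[k]; p.v[k] = v0[k]; }
    double s0 = S0[0];
    for (int k = 0; k < 4; ++k) p.S[k] = S0[k] / s0;
    p.w = 1.0; p.tag = 0;
    int br = -1;
    bool ok = surface_interact(p, surface_index, diffuse_albedo, rng,
                               transmitted, &br);
    branch[i] = br;
    alive[i] = ok ? 1 : 0;
    w_out[i] = p.w;
    for (int k = 0; k < 3; ++k) U(i, k) = p.u[k];
    for (int k = 0; k < 4; ++k) S(i, k) = p.S[k];
  }
  return List::create(_["branch"] = branch, _["direction"] = U,
                      _["stokes"] = S, _["weight"] = w_out,
                      _["alive"] = alive,
                      _["transmitted_bottom"] = transmitted);
}
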