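// Voxel Monte Carlo photon transport engine.
//
// Track-length fluence estimator with continuous absorption: along a segment
// of length s in a voxel with absorption mua the packet weight decays as
// w * exp(-mua * s) and the voxel fluence tally receives the path integral
// w * (1 - exp(-mua * s)) / mua (limit w * s as mua -> 0).  Scattering events
// are sampled from the Henyey-Greenstein phase function; refractive-index
// mismatches at voxel faces are handled with unpolarized Fresnel
// reflect/refract; packets below the roulette threshold survive with
// probability p at weight / p.  Single-threaded and bit-reproducible for a
// given seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double C_MM_NS = 299.792458; // speed of light, mm/ns

// ---------------------------------------------------------------------------
// xoroshiro128+ with splitmix64 seeding: fast, tiny state, reproducible.
// ---------------------------------------------------------------------------
static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t; else s1 = t;
    }
    if (!(s0 | s1)) s0 = 0x9e3779b97f4a7c15ULL;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = rotl64(a, 24) ^ b ^ (b << 16);
    s1 = rotl64(b, 37);
    return r;
  }
  // uniform in [0, 1)
  inline double u01() { return (next() >> 11) * 1.1102230246251565e-16; }
  // uniform in (0, 1], safe for log()
  inline double u01pos() { return 1.0 - u01(); }
};

// ---------------------------------------------------------------------------
// Henyey-Greenstein deflection cosine; g is clamped to [-0.999, 0.999].
// ---------------------------------------------------------------------------
static inline double hg_cost(double g, double u) {
  if (g > 0.999) g = 0.999;
  if (g < -0.999) g = -0.999;
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// [[Rcpp::export]]
NumericVector cpp_sample_hg(int n, double g, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cost(g, rng.u01());
  return out;
}

// Unpolarized Fresnel reflectance; on transmission *ct receives cos(theta_t).
static inline double fresnel_R(double n1, double n2, double ci, double* ct) {
  if (n1 == n2) { *ct = ci; return 0.0; }
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) return 1.0; // total internal reflection
  double c2 = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * c2) / (n1 * ci + n2 * c2);
  double rp = (n1 * c2 - n2 * ci) / (n1 * c2 + n2 * ci);
  *ct = c2;
  return 0.5 * (rs * rs + rp * rp);
}

// rotate unit vector u by deflection cos(theta) and azimuth phi (MCML style)
static inline void spin(double ct, double cp, double sp, double* ux,
                        double* uy, double* uz) {
  double st = std::sqrt(1.0 - ct * ct);
  if (std::fabs(*uz) > 0.99999) {
    *ux = st * cp;
    *uy = st * sp;
    *uz = (*uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - (*uz) * (*uz));
    double nux = st * ((*ux) * (*uz) * cp - (*uy) * sp) / den + (*ux) * ct;
    double nuy = st * ((*uy) * (*uz) * cp + (*ux) * sp) / den + (*uy) * ct;
    double nuz = -st * cp * den + (*uz) * ct;
    *ux = nux; *uy = nuy; *uz = nuz;
  }
}

struct Source {
  int kind;               // 0 disk, 1 rect, 2 isotropic point
  bool cosine;            // cosine-lobe emission instead of collimated
  double cx, cy, cz;      // center, grid mm
  double dx, dy, dz;      // emission direction (unit)
  double e1x, e1y, e1z;   // in-plane axis 1
  double e2x, e2y, e2z;   // in-plane axis 2
  double radius, w, h;
};

static inline void launch(const Source& S, Rng& rng, double* px, double* py,
                          double* pz, double* ux, double* uy, double* uz) {
  if (S.kind == 2) { // isotropic point
    *px = S.cx; *py = S.cy; *pz = S.cz;
    double ct = 2.0 * rng.u01() - 1.0;
    double st = std::sqrt(1.0 - ct * ct);
    double phi = 6.283185307179586 * rng.u01();
    *ux = st * std::cos(phi); *uy = st * std::sin(phi); *uz = ct;
    return;
  }
  double a = 0.0, b = 0.0;
  if (S.kind == 0) { // disk, uniform by area
    double r = S.radius * std::sqrt(rng.u01());
    double phi = 6.283185307179586 * rng.u01();
    a = r * std::cos(phi);
    b = r * std::sin(phi);
  } else { // rect
    a = (rng.u01() - 0.5) * S.w;
    b = (rng.u01() - 0.5) * S.h;
  }
  *px = S.cx + a * S.e1x + b * S.e2x;
  *py = S.cy + a * S.e1y + b * S.e2y;
  *pz = S.cz + a * S.e1z + b * S.e2z;
  if (S.cosine) {
    // cosine-weighted lobe about the surface normal
    double ct = std::sqrt(rng.u01());
    double st = std::sqrt(1.0 - ct * ct);
    double phi = 6.283185307179586 * rng.u01();
    double ca = st * std::cos(phi), cb = st * std::sin(phi);
    *ux = ca * S.e1x + cb * S.e2x + ct * S.dx;
    *uy = ca * S.e1y + cb * S.e2y + ct * S.dy;
    *uz = ca * S.e1z + cb * S.e2z + ct * S.dz;
  } else {
    *ux = S.dx; *uy = S.dy; *uz = S.dz; // collimated
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_launch(List src, int n, double seed) {
  Source S;
  std::string kind = as<std::string>(src["kind"]);
  S.kind = (kind == "disk") ? 0 : (kind == "rect") ? 1 : 2;
  NumericVector c0 = src["center"], d0 = src["direction"];
  S.cx = c0[0]; S.cy = c0[1]; S.cz = c0[2];
  S.dx = d0[0]; S.dy = d0[1]; S.dz = d0[2];
  S.radius = S.w = S.h = 0.0;
  S.cosine = src.containsElementNamed("cosine") && as<bool>(src["cosine"]);
  S.e1x = S.e1y = S.e1z = S.e2x = S.e2y = S.e2z = 0.0;
  if (S.kind != 2) {
    NumericVector e1 = src["e1"], e2 = src["e2"];
    S.e1x = e1[0]; S.e1y = e1[1]; S.e1z = e1[2];
    S.e2x = e2[0]; S.e2y = e2[1]; S.e2z = e2[2];
    if (S.kind == 0) S.radius = as<double>(src["radius"]);
    else { S.w = as<double>(src["width"]); S.h = as<double>(src["height"]); }
  }
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double px, py, pz, ux, uy, uz;
    launch(S, rng, &px, &py, &pz, &ux, &uy, &uz);
    out(i, 0) = px; out(i, 1) = py; out(i, 2) = pz;
    out(i, 3) = ux; out(i, 4) = uy; out(i, 5) = uz;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericVector mua, NumericVector mus, NumericVector gv,
                NumericVector nv, IntegerVector dims, NumericVector voxmm,
                List src, double n_photons, double seed, double gate_ns,
                int n_gates, double wthresh, double psurv, double max_path,
                double ambient_n) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = voxmm[0], hy = voxmm[1], hz = voxmm[2];
  const double Lx = nx * hx, Ly = ny * hy, Lz = nz * hz;
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;

  Source S;
  std::string kind = as<std::string>(src["kind"]);
  S.kind = (kind == "disk") ? 0 : (kind == "rect") ? 1 : 2;
  NumericVector c0 = src["center"], d0 = src["direction"];
  S.cx = c0[0]; S.cy = c0[1]; S.cz = c0[2];
  S.dx = d0[0]; S.dy = d0[1]; S.dz = d0[2];
  S.radius = S.w = S.h = 0.0;
  S.cosine = src.containsElementNamed("cosine") && as<bool>(src["cosine"]);
  S.e1x = S.e1y = S.e1z = S.e2x = S.e2y = S.e2z = 0.0;
  if (S.kind != 2) {
    NumericVector e1 = src["e1"], e2 = src["e2"];
    S.e1x = e1[0]; S.e1y = e1[1]; S.e1z = e1[2];
    S.e2x = e2[0]; S.e2y = e2[1]; S.e2z = e2[2];
    if (S.kind == 0) S.radius = as<double>(src["radius"]);
    else { S.w = as<double>(src["width"]); S.h = as<double>(src["height"]); }
  }

  // interleave the four per-voxel properties so adjacent cache lines serve
  // a whole voxel lookup in the hot loop
  std::vector<double> prop(4 * static_cast<size_t>(nvox));
  for (R_xlen_t v = 0; v < nvox; ++v) {
    prop[4 * v] = mua[v];
    prop[4 * v + 1] = mus[v];
    prop[4 * v + 2] = gv[v];
    prop[4 * v + 3] = nv[v];
  }

  NumericVector fluence(nvox); // sum of w * tracklength, mm
  NumericMatrix gates;
  bool gated = n_gates > 0;
  if (gated) gates = NumericMatrix(nvox, n_gates + 1); // last col = late bucket

  double absorbed = 0.0, escaped = 0.0, capped = 0.0;
  double roul_killed = 0.0, roul_boosted = 0.0;
  const bool roulette = wthresh > 0.0;

  Rng rng(static_cast<uint64_t>(seed));
  const long nph = static_cast<long>(n_photons);

  for (long ip = 0; ip < nph; ++ip) {
    double px, py, pz, ux, uy, uz;
    launch(S, rng, &px, &py, &pz, &ux, &uy, &uz);
    double w = 1.0, t = 0.0, path = 0.0;

    // Bring packets launched outside the grid to the bounding box.
    if (px < 0 || px >= Lx || py < 0 || py >= Ly || pz < 0 || pz >= Lz) {
      double t0 = 0.0, t1 = 1e300;
      bool miss = false;
      const double p[3] = {px, py, pz}, u[3] = {ux, uy, uz};
      const double L[3] = {Lx, Ly, Lz};
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(u[a]) < 1e-12) {
          if (p[a] < 0 || p[a] >= L[a]) { miss = true; break; }
        } else {
          double ta = (0.0 - p[a]) / u[a], tb = (L[a] - p[a]) / u[a];
          if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
      }
      if (miss || t0 <= 0.0) { escaped += w; continue; }
      px += (t0 + 1e-7) * ux;
      py += (t0 + 1e-7) * uy;
      pz += (t0 + 1e-7) * uz;
      t += t0 * ambient_n / C_MM_NS;
      path += t0;
    }

    double tau = -std::log(rng.u01pos());

    for (;;) {
      int ix = static_cast<int>(std::floor(px / hx));
      int iy = static_cast<int>(std::floor(py / hy));
      int iz = static_cast<int>(std::floor(pz / hz));
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped += w;
        break;
      }
      R_xlen_t vox = ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
      // absorption is continuous along the path, so the sampled optical
      // depth is consumed against the scattering coefficient only
      const double* P = &prop[4 * static_cast<size_t>(vox)];
      const double ma = P[0], ms = P[1], nn = P[3];

      // distance to the voxel boundary along the direction of travel
      double db = 1e300;
      int axis = -1;
      if (ux > 0) { double tb = ((ix + 1) * hx - px) / ux; if (tb < db) { db = tb; axis = 0; } }
      else if (ux < 0) { double tb = (ix * hx - px) / ux; if (tb < db) { db = tb; axis = 0; } }
      if (uy > 0) { double tb = ((iy + 1) * hy - py) / uy; if (tb < db) { db = tb; axis = 1; } }
      else if (uy < 0) { double tb = (iy * hy - py) / uy; if (tb < db) { db = tb; axis = 1; } }
      if (uz > 0) { double tb = ((iz + 1) * hz - pz) / uz; if (tb < db) { db = tb; axis = 2; } }
      else if (uz < 0) { double tb = (iz * hz - pz) / uz; if (tb < db) { db = tb; axis = 2; } }
      if (db < 0) db = 0;

      const double need = (ms > 0.0) ? tau / ms : 1e300;
      const bool interact = need <= db;
      const double s = interact ? need : db;

      // deposit along the segment
      if (s > 0.0) {
        int gi = 0;
        if (gated) {
          gi = static_cast<int>(t / gate_ns);
          if (gi > n_gates) gi = n_gates;
          if (gi < 0) gi = 0;
        }
        if (ma > 0.0) {
          // cubic series for small optical depths (relative error < 5e-8 at
          // x = 0.01) keeps exp() out of the common case; deposits and the
          // weight update share e, so energy bookkeeping stays exact
          double x = ma * s, e;
          if (x < 0.01)
            e = 1.0 - x * (1.0 - 0.5 * x * (1.0 - 0.3333333333333333 * x));
          else
            e = std::exp(-x);
          double dep = w * (1.0 - e);
          absorbed += dep;
          double fl = dep / ma;
          fluence[vox] += fl;
          if (gated) gates(vox, gi) += fl;
          w *= e;
        } else {
          fluence[vox] += w * s;
          if (gated) gates(vox, gi) += w * s;
        }
        px += s * ux; py += s * uy; pz += s * uz;
        t += s * nn / C_MM_NS;
        path += s;
      }

      if (interact) {
        // scatter (Henyey-Greenstein); azimuth via rejection sampling of a
        // point in the unit disk and the double-angle identities, avoiding
        // the trigonometric calls in the hot loop
        double ct = hg_cost(P[2], rng.u01());
        double ax, ay, r2;
        do {
          ax = 2.0 * rng.u01() - 1.0;
          ay = 2.0 * rng.u01() - 1.0;
          r2 = ax * ax + ay * ay;
        } while (r2 >= 1.0 || r2 < 1e-12);
        double cp = (ax * ax - ay * ay) / r2;
        double sp = 2.0 * ax * ay / r2;
        spin(ct, cp, sp, &ux, &uy, &uz);
        tau = -std::log(rng.u01pos());
      } else {
        // face crossing
        tau -= db * ms;
        if (tau < 0) tau = 0;
        int jx = ix, jy = iy, jz = iz;
        double sgn = 0.0;
        if (axis == 0) { sgn = (ux > 0) ? 1.0 : -1.0; jx += (ux > 0) ? 1 : -1; px = ((ux > 0) ? (ix + 1) : ix) * hx; }
        else if (axis == 1) { sgn = (uy > 0) ? 1.0 : -1.0; jy += (uy > 0) ? 1 : -1; py = ((uy > 0) ? (iy + 1) : iy) * hy; }
        else { sgn = (uz > 0) ? 1.0 : -1.0; jz += (uz > 0) ? 1 : -1; pz = ((uz > 0) ? (iz + 1) : iz) * hz; }
        bool inside = jx >= 0 && jx < nx && jy >= 0 && jy < ny && jz >= 0 && jz < nz;
        double n2 = inside
          ? prop[4 * static_cast<size_t>(jx + static_cast<R_xlen_t>(nx) * (jy + static_cast<R_xlen_t>(ny) * jz)) + 3]
          : ambient_n;
        if (nn != n2) {
          double ci = (axis == 0) ? std::fabs(ux) : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
          if (ci > 1.0) ci = 1.0;
          double c2;
          double R = fresnel_R(nn, n2, ci, &c2);
          if (rng.u01() < R) {
            // reflect: flip the normal component, stay in the current voxel
            if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
          } else {
            // refract: scale tangential components, set normal component
            double r = nn / n2;
            if (axis == 0) { uy *= r; uz *= r; ux = sgn * c2; }
            else if (axis == 1) { ux *= r; uz *= r; uy = sgn * c2; }
            else { ux *= r; uy *= r; uz = sgn * c2; }
          }
        }
        // nudge off the face along the (possibly updated) direction
        px += 1e-7 * ux; py += 1e-7 * uy; pz += 1e-7 * uz;
      }

      if (path > max_path) { capped += w; break; }
      if (roulette && w < wthresh) {
        if (rng.u01() < psurv) {
          roul_boosted += w * (1.0 / psurv - 1.0);
          w /= psurv;
        } else {
          roul_killed += w;
          break;
        }
      }
    }
  }

  List out = List::create(
    _["fluence"] = fluence, _["absorbed"] = absorbed, _["escaped"] = escaped,
    _["capped"] = capped, _["roulette_killed"] = roul_killed,
    _["roulette_boosted"] = roul_boosted, _["launched"] = (double)nph);
  if (gated) out["gates"] = gates;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling for 3-D logical masks (6/18/26 connectivity).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(nvox, 0);

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  const int nof = static_cast<int>(offs.size() / 3);

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t v0 = 0; v0 < nvox; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++next_label;
    lab[v0] = next_label;
    stack.clear();
    stack.push_back(v0);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int iz = static_cast<int>(v / (static_cast<R_xlen_t>(nx) * ny));
      int rem = static_cast<int>(v - static_cast<R_xlen_t>(iz) * nx * ny);
      int iy = rem / nx, ix = rem % nx;
      for (int k = 0; k < nof; ++k) {
        int jx = ix + offs[3 * k], jy = iy + offs[3 * k + 1], jz = iz + offs[3 * k + 2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
        R_xlen_t u = jx + static_cast<R_xlen_t>(nx) * (jy + static_cast<R_xlen_t>(ny) * jz);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next_label;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}
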