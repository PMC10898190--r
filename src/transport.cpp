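#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xoshiro256+ with splitmix64 seeding: a fast, high-quality generator local
// to the transport kernel.  The stream is fully determined by the seed
// argument, so runs are reproducible independent of R's RNG state.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0 so -log() is safe
  inline double runif() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};
}  // namespace

// Fraction of the circle of radius r (centred on the source axis) that lies
// inside a detector-fiber disk of radius a whose centre is d from the axis.
// Exact under the azimuthal symmetry of launch about the source axis.
static inline double arc_fraction(double r, double d, double a) {
  if (d <= a && r <= a - d) return 1.0;
  if (r >= d + a) return 0.0;
  if (d > a && r <= d - a) return 0.0;
  if (r <= 0.0) return (d <= a) ? 1.0 : 0.0;
  double c = (r * r + d * d - a * a) / (2.0 * r * d);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c) / M_PI;
}

// Unpolarized Fresnel reflectance for incidence cosine cosi, from medium n1
// into n2.  Returns 1 under total internal reflection.
static inline double fresnel_R(double n1, double n2, double cosi) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Photon transport in a semi-infinite homogeneous medium probed at z = 0.
// Henyey-Greenstein scattering, implicit-capture absorption, Fresnel
// reflection/refraction at the tissue-probe interface, Russian roulette,
// and a path-length cap (needed for white runs at mua = 0, whose mean exit
// path diverges).  The RNG stream is fully determined by `seed`.
//
// The energy ledger partitions the launched weight exactly:
//   launched = specular + diffuse_reflected + absorbed + terminated
// where `terminated` collects path-cap kills plus the (zero-mean) net
// roulette balance: +w on a kill, -(w/p - w) on a survival.
//
// Detection accumulates, per detector separation, the arc-fraction weighted
// exit weight of photons leaving within the acceptance cone
// (cos(exit angle) >= cos_accept, measured in tissue).  Optionally records
// (path length, exit radius, weight) for accepted exits with radius
// <= record_rmax, enabling white-Monte-Carlo rescaling in R.
// [[Rcpp::export]]
List mc_transport_cpp(double mua, double mus, double g,
                      double n_tissue, double n_ext,
                      double src_radius, NumericVector det_sep,
                      double det_radius, double cos_accept,
                      int n_photons, double w_min, double p_roulette,
                      double max_path, bool record_paths,
                      double record_rmax, double seed) {
  if (mus <= 0.0) stop("mus must be positive");
  if (mua < 0.0) stop("mua must be nonnegative");
  if (g < 0.0 || g >= 1.0) stop("anisotropy g must lie in [0, 1)");
  int ndet = det_sep.size();
  Xoshiro rng((uint64_t)seed);
  double mut = mua + mus;
  double albedo = mus / mut;

  std::vector<double> det_w(ndet, 0.0), det_w2(ndet, 0.0);
  double specular = 0.0, diffuse = 0.0, absorbed = 0.0, terminated = 0.0;
  std::vector<double> rec_L, rec_r, rec_w;
  if (record_paths) {
    rec_L.reserve(n_photons);
    rec_r.reserve(n_photons);
    rec_w.reserve(n_photons);
  }
  // specular loss at launch (fiber face -> tissue), deterministic split
  double R_sp = fresnel_R(n_ext, n_tissue, 1.0);

  std::vector<double> contrib(ndet);

  for (int ip = 0; ip < n_photons; ip++) {
    // launch uniformly over the source fiber disk, collimated along +z
    double rr = src_radius * std::sqrt(rng.runif());
    double phi0 = 2.0 * M_PI * rng.runif();
    double x = rr * std::cos(phi0), y = rr * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - R_sp;
    specular += R_sp;
    double L = 0.0;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.runif()) / mut;
      // propagate, handling boundary crossings within the step
      while (s > 0.0) {
        if (uz < 0.0 && z + uz * s < 0.0) {
          double d1 = -z / uz;
          x += ux * d1; y += uy * d1; L += d1; z = 0.0;
          s -= d1;
          double cosi = -uz;
          double Rf = fresnel_R(n_tissue, n_ext, cosi);
          if (rng.runif() < Rf) {
            uz = -uz;  // internally reflected, continue remaining step
          } else {
            // escapes through the surface
            diffuse += w;
            double rex = std::sqrt(x * x + y * y);
            if (cosi >= cos_accept) {
              for (int k = 0; k < ndet; k++) {
                double f = arc_fraction(rex, det_sep[k], det_radius);
                if (f > 0.0) {
                  double c = w * f;
                  det_w[k] += c;
                  det_w2[k] += c * c;
                }
              }
              if (record_paths && rex <= record_rmax) {
                rec_L.push_back(L);
                rec_r.push_back(rex);
                rec_w.push_back(w);
              }
            }
            alive = false;
            s = 0.0;
          }
        } else {
          x += ux * s; y += uy * s; z += uz * s; L += s;
          s = 0.0;
        }
      }
      if (!alive) break;
      if (L > max_path) {  // path cap: count remaining weight as terminated
        terminated += w;
        break;
      }
      // absorption by implicit capture
      if (mua > 0.0) {
        absorbed += w * (1.0 - albedo);
        w *= albedo;
      }
      // Henyey-Greenstein scatter
      double ct;
      if (g > 1e-6) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      } else {
        ct = 2.0 * rng.runif() - 1.0;
      }
      if (ct > 1.0) ct = 1.0;
      if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double ph = 2.0 * M_PI * rng.runif();
      double cp = std::cos(ph), sp = std::sin(ph);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
      }
      // Russian roulette with exact ledger bookkeeping
      if (w < w_min) {
        if (rng.runif() < p_roulette) {
          double gained = w / p_roulette - w;
          terminated -= gained;
          w /= p_roulette;
        } else {
          terminated += w;
          break;
        }
      }
    }
  }

  List rec = R_NilValue;
  if (record_paths) {
    rec = List::create(_["L"] = NumericVector(rec_L.begin(), rec_L.end()),
                       _["r"] = NumericVector(rec_r.begin(), rec_r.end()),
                       _["w"] = NumericVector(rec_w.begin(), rec_w.end()));
  }
  return List::create(
      _["det_w"] = NumericVector(det_w.begin(), det_w.end()),
      _["det_w2"] = NumericVector(det_w2.begin(), det_w2.end()),
      _["specular"] = specular, _["diffuse"] = diffuse,
      _["absorbed"] = absorbed, _["terminated"] = terminated,
      _["n_photons"] = n_photons, _["records"] = rec);
}

// Arc-fraction helper exposed for the rescaling path in R.
// [[Rcpp::export]]
NumericVector arc_fraction_cpp(NumericVector r, double d, double a) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = arc_fraction(r[i], d, a);
  return out;
}
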