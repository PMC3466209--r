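// Single-scattering Monte Carlo electron transport through a layered film.
//
// Physics conventions (energies keV, lengths nm unless noted):
//   - mean ionization potential: Berger-Seltzer
//   - total elastic cross-section: screened Rutherford, Joy's relativistic
//     factor constant 1024
//   - stopping power: Joy-Luo modified Bethe (valid below 1 keV)
// The same formulas are exported to R (materials module) and pinned against
// these by a consistency test.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

const double AVOGADRO = 6.02214076e23;
const double BOUNDARY_EPS = 1e-6;  // nm advanced past a layer interface

double bs_ionization_J(int Z) {
  if (Z < 13) return 11.5e-3 * Z;
  return (9.76 * Z + 58.5 * std::pow(static_cast<double>(Z), -0.19)) * 1e-3;
}

double screening_alpha(int Z, double E) {
  return 3.4e-3 * std::pow(static_cast<double>(Z), 0.67) / E;
}

// total elastic cross-section, cm^2
double sigma_elastic(int Z, double E) {
  const double a = screening_alpha(Z, E);
  const double rel = (E + 511.0) / (E + 1024.0);
  return 5.21e-21 * (static_cast<double>(Z) * Z) / (E * E) *
         (4.0 * M_PI / (a * (1.0 + a))) * rel * rel;
}

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

// xoshiro256**; per-electron substream seeded via splitmix64 so trajectories
// are stable under changes of n_electrons
struct Xoshiro256 {
  uint64_t s[4];
  Xoshiro256(uint64_t seed, uint64_t stream) {
    SplitMix64 sm(seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1)));
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }  // [0,1)
  double unif_oc() { return 1.0 - unif(); }                              // (0,1]
  double normal() {
    const double u1 = unif_oc(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct MatParams {
  double rho;                  // g/cm^3
  std::vector<int> Z;
  std::vector<double> ni;      // atoms/cm^3 of element i
  std::vector<double> wZA;     // w_i * Z_i / A_i
  std::vector<double> kJ, J;   // Joy-Luo k_i and J_i (keV)
};

// inverse mean free path contributions per element; returns total 1/lambda (1/cm)
double inv_mfp_cm(const MatParams& m, double E, std::vector<double>& part) {
  double tot = 0.0;
  part.resize(m.Z.size());
  for (size_t i = 0; i < m.Z.size(); ++i) {
    part[i] = m.ni[i] * sigma_elastic(m.Z[i], E);
    tot += part[i];
  }
  return tot;
}

// Joy-Luo stopping power, keV/nm
double stopping_keV_nm(const MatParams& m, double E) {
  double s = 0.0;
  for (size_t i = 0; i < m.Z.size(); ++i) {
    double arg = 1.166 * (E + m.kJ[i] * m.J[i]) / m.J[i];
    double term = std::log(arg);
    if (term < 0.0) term = 0.0;  // guard far below validity floor
    s += m.wZA[i] * term;
  }
  return 7.85e4 * (m.rho / E) * s * 1e-7;
}

void rotate_dir(double& ux, double& uy, double& uz, double ct, double phi) {
  double st2 = 1.0 - ct * ct;
  const double st = st2 > 0.0 ? std::sqrt(st2) : 0.0;
  const double cf = std::cos(phi), sf = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.999999) {
    nx = st * cf;
    ny = st * sf;
    nz = uz > 0 ? ct : -ct;
  } else {
    const double dd = std::sqrt(1.0 - uz * uz);
    nx = ux * ct + st * (ux * uz * cf - uy * sf) / dd;
    ny = uy * ct + st * (uy * uz * cf + ux * sf) / dd;
    nz = uz * ct - dd * st * cf;
  }
  const double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm;
  uy = ny / nrm;
  uz = nz / nrm;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_sigma_elastic")]]
double cpp_sigma_elastic(int Z, double E) { return sigma_elastic(Z, E); }

// [[Rcpp::export(name = ".cpp_ionization_J")]]
double cpp_ionization_J(int Z) { return bs_ionization_J(Z); }

// [[Rcpp::export(name = ".cpp_stopping_power")]]
double cpp_stopping_power(double rho, IntegerVector Z, NumericVector A,
                          NumericVector w, double E) {
  MatParams m;
  m.rho = rho;
  for (int i = 0; i < Z.size(); ++i) {
    m.Z.push_back(Z[i]);
    m.ni.push_back(AVOGADRO * rho * w[i] / A[i]);
    m.wZA.push_back(w[i] * Z[i] / A[i]);
    m.J.push_back(bs_ionization_J(Z[i]));
    m.kJ.push_back(0.731 + 0.0688 * std::log10(static_cast<double>(Z[i])));
  }
  return stopping_keV_nm(m, E);
}

// [[Rcpp::export(name = ".cpp_elastic_mfp")]]
double cpp_elastic_mfp(double rho, IntegerVector Z, NumericVector A,
                       NumericVector w, double E) {
  MatParams m;
  m.rho = rho;
  for (int i = 0; i < Z.size(); ++i) {
    m.Z.push_back(Z[i]);
    m.ni.push_back(AVOGADRO * rho * w[i] / A[i]);
  }
  std::vector<double> part;
  return 1e7 / inv_mfp_cm(m, E, part);  // nm
}

// Transport of n_electrons through the stack described by `bounds` (nm depths
// of layer interfaces, bounds[0] = 0) and `layers` (list of material
// parameter lists). Fates: 0 transmitted, 1 backscattered, 2 absorbed.
// [[Rcpp::export(name = ".cpp_run_transport")]]
List cpp_run_transport(NumericVector bounds, List layers, double E0,
                       double spot_fwhm, int beam_profile, int n_electrons,
                       double cutoff, int max_steps, double seed) {
  const int nl = layers.size();
  std::vector<MatParams> mats(nl);
  for (int l = 0; l < nl; ++l) {
    List ml = layers[l];
    IntegerVector Z = ml["Z"];
    NumericVector A = ml["A"], w = ml["w"];
    double rho = ml["density"];
    MatParams& m = mats[l];
    m.rho = rho;
    for (int i = 0; i < Z.size(); ++i) {
      m.Z.push_back(Z[i]);
      m.ni.push_back(AVOGADRO * rho * w[i] / A[i]);
      m.wZA.push_back(w[i] * Z[i] / A[i]);
      m.J.push_back(bs_ionization_J(Z[i]));
      m.kJ.push_back(0.731 + 0.0688 * std::log10(static_cast<double>(Z[i])));
    }
  }
  const double z_bottom = bounds[nl];
  const uint64_t useed = static_cast<uint64_t>(seed);
  const double beam_sigma = spot_fwhm / 2.3548200450309493;

  IntegerVector fate(n_electrons), nsteps(n_electrons);
  NumericVector exit_x(n_electrons, NA_REAL), exit_y(n_electrons, NA_REAL);
  NumericVector deposited(n_electrons), exit_energy(n_electrons);

  std::vector<double> part;
  for (int e = 0; e < n_electrons; ++e) {
    Xoshiro256 rng(useed, static_cast<uint64_t>(e));
    double x, y;
    if (beam_profile == 0) {  // gaussian, FWHM = spot diameter
      x = beam_sigma * rng.normal();
      y = beam_sigma * rng.normal();
    } else {  // uniform disk of diameter spot_fwhm
      const double r = 0.5 * spot_fwhm * std::sqrt(rng.unif());
      const double th = 2.0 * M_PI * rng.unif();
      x = r * std::cos(th);
      y = r * std::sin(th);
    }
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0, E = E0, dep = 0.0;
    int layer = 0, status = -1, steps = 0;

    while (steps < max_steps) {
      ++steps;
      const MatParams& m = mats[layer];
      const double invl = inv_mfp_cm(m, E, part);
      const double lambda = 1e7 / invl;  // nm
      const double sp = stopping_keV_nm(m, E);
      const double s_free = -lambda * std::log(rng.unif_oc());

      double t_bound = std::numeric_limits<double>::infinity();
      if (uz > 1e-12) t_bound = (bounds[layer + 1] - z) / uz;
      else if (uz < -1e-12) t_bound = (bounds[layer] - z) / uz;

      if (s_free < t_bound) {
        // free flight + elastic scatter inside the current layer
        double de = sp * s_free;
        if (de > E) de = E;
        x += ux * s_free;
        y += uy * s_free;
        z += uz * s_free;
        E -= de;
        dep += de;
        if (E <= cutoff) {
          dep += E;
          E = 0.0;
          status = 2;
          break;
        }
        // pick the scattering element with probability ~ n_i * sigma_i
        int zi = m.Z[0];
        if (m.Z.size() > 1) {
          double pick = rng.unif() * invl, acc = 0.0;
          for (size_t i = 0; i < part.size(); ++i) {
            acc += part[i];
            if (pick <= acc) { zi = m.Z[i]; break; }
            zi = m.Z[i];
          }
        }
        const double a = screening_alpha(zi, E);
        const double u = rng.unif();
        double ct = 1.0 - 2.0 * a * u / (1.0 + a - u);
        if (ct < -1.0) ct = -1.0;
        if (ct > 1.0) ct = 1.0;
        rotate_dir(ux, uy, uz, ct, 2.0 * M_PI * rng.unif());
      } else {
        // truncate at the interface, nudge into the adjacent medium
        const double step = t_bound + BOUNDARY_EPS;
        double de = sp * step;
        if (de > E) de = E;
        x += ux * step;
        y += uy * step;
        z += uz * step;
        E -= de;
        dep += de;
        if (z <= 0.0) { status = 1; break; }        // backscattered
        if (z >= z_bottom) { status = 0; break; }   // transmitted
        if (E <= cutoff) {
          dep += E;
          E = 0.0;
          status = 2;
          break;
        }
        layer += (uz > 0.0) ? 1 : -1;
      }
    }
    if (status < 0) {  // step budget exhausted: book as absorbed
      dep += E;
      E = 0.0;
      status = 2;
    }
    fate[e] = status;
    nsteps[e] = steps;
    deposited[e] = dep;
    exit_energy[e] = E;
    if (status == 0) {
      exit_x[e] = x;
      exit_y[e] = y;
    }
  }

  return List::create(_["fate"] = fate, _["exit_x"] = exit_x,
                      _["exit_y"] = exit_y, _["deposited"] = deposited,
                      _["exit_energy"] = exit_energy, _["n_steps"] = nsteps);
}
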