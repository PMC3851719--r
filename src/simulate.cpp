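#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Toy landscape: sum of wells. Each row of `wells`:
//   shape (0 = gaussian, 1 = smoothed-rectangular), center, depth, width, softness
// gaussian:  U -= depth * exp(-(x-c)^2 / (2 w^2))          (width = w)
// rectangular: U -= depth/2 * (tanh((x-a)/s) - tanh((x-b)/s)), a = c - w, b = c + w
//   (width = half-width, softness = s; depth is approached for w >> s)

static inline double landscape_energy(const NumericMatrix &wells, double x) {
  double u = 0.0;
  for (int j = 0; j < wells.nrow(); ++j) {
    const double c = wells(j, 1), d = wells(j, 2), w = wells(j, 3);
    if (wells(j, 0) == 0.0) {
      const double z = (x - c) / w;
      u -= d * std::exp(-0.5 * z * z);
    } else {
      const double s = wells(j, 4);
      u -= 0.5 * d * (std::tanh((x - (c - w)) / s) - std::tanh((x - (c + w)) / s));
    }
  }
  return u;
}

static inline double landscape_force(const NumericMatrix &wells, double x) {
  // returns -dU/dx
  double f = 0.0;
  for (int j = 0; j < wells.nrow(); ++j) {
    const double c = wells(j, 1), d = wells(j, 2), w = wells(j, 3);
    if (wells(j, 0) == 0.0) {
      const double z = (x - c) / w;
      f -= d * (z / w) * std::exp(-0.5 * z * z);
    } else {
      const double s = wells(j, 4);
      const double ta = std::tanh((x - (c - w)) / s);
      const double tb = std::tanh((x - (c + w)) / s);
      f += 0.5 * d * ((1.0 - ta * ta) - (1.0 - tb * tb)) / s;
    }
  }
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_potential(NumericMatrix wells, NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = landscape_energy(wells, x[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic per-trajectory RNG: xoshiro256++ seeded via splitmix64 from
// the user seed, with Box-Muller normals.  A given (landscape, protocol,
// seed) therefore yields a bitwise-identical trajectory, independently of
// R's RNG state.
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    const double u = runif(), v = runif();
    const double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// Overdamped Euler-Maruyama under a moving harmonic restraint.
// x <- x + beta*D*(F_landscape + F_restraint)*dt + sqrt(2 D dt) * eta
// Work by the potential-difference convention, accumulated every step:
//   W += V(x_t, lambda_{t+1}) - V(x_t, lambda_t),  V(q, l) = k/2 (q - l)^2
// Reflecting walls at the domain bounds.  The landscape force is tabulated
// on a 32768-node grid with linear interpolation (max error ~1e-5 of the
// well depth for the default geometries).  Initial x from the lambda0-
// restrained Boltzmann density by rejection sampling (proposal: the
// restraint Gaussian; exact well energies).
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix wells, double lo, double hi,
                  double th21, double th10,
                  double k, double lambda0, double v, double dt,
                  int n_steps, int record_every, double kT, double D,
                  double seed) {
  const double beta = 1.0 / kT;
  const double sigma = std::sqrt(kT / k);
  const double noise = std::sqrt(2.0 * D * dt);
  Rng rng((uint64_t)seed);

  const int NG = 32768;
  const double h = (hi - lo) / NG;
  std::vector<double> ftab(NG + 1);
  for (int g = 0; g <= NG; ++g)
    ftab[g] = landscape_force(wells, lo + g * h);

  // rejection-sample the restrained equilibrium starting point
  double umin = R_PosInf;
  const double glo = std::max(lo, lambda0 - 6.0 * sigma);
  const double ghi = std::min(hi, lambda0 + 6.0 * sigma);
  for (int g = 0; g <= 512; ++g)
    umin = std::min(umin, landscape_energy(wells, glo + (ghi - glo) * g / 512.0));
  double x = NA_REAL;
  for (int attempt = 0; attempt < 100000; ++attempt) {
    const double xp = lambda0 + sigma * rng.rnorm();
    if (xp < lo || xp > hi) continue;
    if (rng.runif() < std::exp(-beta * (landscape_energy(wells, xp) - umin))) {
      x = xp;
      break;
    }
  }
  if (!R_finite(x))
    stop("failed to sample a restrained starting point (rejection sampling)");

  const int n_rec = n_steps / record_every + 1 + (n_steps % record_every ? 1 : 0);
  NumericVector time(n_rec), pos(n_rec), lam(n_rec), work(n_rec);
  IntegerVector nhb(n_rec);

  const double bDdt = beta * D * dt;
  double W = 0.0, lambda = lambda0;
  int r = 0;
  for (int t = 0; t <= n_steps; ++t) {
    if (t % record_every == 0 || t == n_steps) {
      time[r] = t * dt;
      pos[r] = x;
      lam[r] = lambda;
      work[r] = W;
      nhb[r] = x < th21 ? 2 : (x < th10 ? 1 : 0);
      ++r;
    }
    if (t == n_steps) break;
    const double lambda_new = lambda0 + v * (t + 1) * dt;
    W += 0.5 * k * ((x - lambda_new) * (x - lambda_new) -
                    (x - lambda) * (x - lambda));
    lambda = lambda_new;
    const double g = (x - lo) / h;
    int gi = (int)g;
    if (gi >= NG) gi = NG - 1;
    if (gi < 0) gi = 0;
    const double fl = ftab[gi] + (g - gi) * (ftab[gi + 1] - ftab[gi]);
    const double force = fl - k * (x - lambda);
    if (!R_finite(force))
      stop("non-finite force at step %d (integration diverged)", t);
    x += bDdt * force + noise * rng.rnorm();
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return List::create(_["time"] = time, _["position"] = pos,
                      _["lambda"] = lam, _["work"] = work, _["nhb"] = nhb);
}
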