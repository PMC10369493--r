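#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <functional>
using namespace Rcpp;

// Metropolis Monte Carlo of N single-site Lennard-Jones particles in a
// periodic cubic box, with connected-component cluster detection under the
// minimum-image convention. The chain uses its own 64-bit Mersenne Twister
// seeded from R so that trajectories are reproducible across platforms and
// independent of R's RNG state.

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in [0, 1) with 53-bit resolution, implementation-independent
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) {
    // rejection sampling keeps the draw exactly uniform
    uint64_t bound = UINT64_MAX - UINT64_MAX % (uint64_t)n;
    uint64_t v;
    do { v = gen(); } while (v >= bound);
    return (int)(v % (uint64_t)n);
  }
};

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against rounding to exactly L
  return x;
}

inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

struct System {
  int n;
  double L, eps, sig2, rcut2;
  std::vector<double> px, py, pz;

  double pair_u(double r2) const {
    if (r2 >= rcut2) return 0.0;
    double inv = sig2 / r2;
    double i6 = inv * inv * inv;
    return 4.0 * eps * (i6 * i6 - i6);
  }

  double dist2(int i, int j) const {
    double dx = min_image(px[i] - px[j], L);
    double dy = min_image(py[i] - py[j], L);
    double dz = min_image(pz[i] - pz[j], L);
    return dx * dx + dy * dy + dz * dz;
  }

  // interaction energy of particle i at position (x, y, z)
  double energy_at(int i, double x, double y, double z) const {
    double u = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = min_image(x - px[j], L);
      double dy = min_image(y - py[j], L);
      double dz = min_image(z - pz[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      u += pair_u(r2);
    }
    return u;
  }
};

// union-find over particles; edges join pairs closer than r_bond
void cluster_sizes(const System& sys, double rbond2, std::vector<int>& out) {
  int n = sys.n;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (sys.dist2(i, j) < rbond2) {
        int ra = find(i), rb = find(j);
        if (ra != rb) parent[ra] = rb;
      }
    }
  }
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) csize[find(i)]++;
  std::fill(out.begin(), out.end(), 0);
  for (int i = 0; i < n; ++i) {
    if (csize[i] > 0) out[csize[i] - 1]++;
  }
}

} // namespace

// [[Rcpp::export(name = ".mc_chain_cpp")]]
List mc_chain_cpp(int n, double L, double eps, double sigma, double temp,
                  double rcut, double rbond, double max_disp,
                  double n_sweeps_d, int thin, double equil_frac,
                  bool adapt, double seed_d, int traj_every,
                  double p_swap) {
  const double RGAS = 0.0083144626; // kJ/(mol K)
  const double beta = 1.0 / (RGAS * temp);
  long long n_sweeps = (long long)n_sweeps_d;
  Rng rng((uint64_t)seed_d);

  System sys;
  sys.n = n; sys.L = L; sys.eps = eps;
  sys.sig2 = sigma * sigma; sys.rcut2 = rcut * rcut;
  sys.px.resize(n); sys.py.resize(n); sys.pz.resize(n);
  for (int i = 0; i < n; ++i) {
    sys.px[i] = rng.unif() * L;
    sys.py[i] = rng.unif() * L;
    sys.pz[i] = rng.unif() * L;
  }

  long long equil = (long long)std::floor(equil_frac * n_sweeps);
  long long n_prod = n_sweeps - equil;
  long long n_frames = n_prod / thin;
  IntegerMatrix counts(n_frames, n);
  std::vector<int> comp(n);
  double rbond2 = rbond * rbond;

  long long n_traj = (traj_every > 0) ? n_prod / traj_every : 0;
  NumericMatrix traj(n_traj > 0 ? n_traj : 1, n_traj > 0 ? 3 * n : 1);

  double disp = max_disp;
  const double disp_min = 1e-3, disp_max = 0.5 * L;
  long long acc_prod = 0, att_prod = 0;
  long long acc_win = 0, att_win = 0;
  long long frame = 0, tframe = 0;

  for (long long sweep = 0; sweep < n_sweeps; ++sweep) {
    bool production = sweep >= equil;
    for (int mv = 0; mv < n; ++mv) {
      bool accept;
      bool was_disp = true;
      if (n > 1 && rng.unif() < p_swap) {
        was_disp = false;
        // aggregation-volume-bias swap: move particle i into, or out of,
        // the association shell (radius rbond) of particle j. The proposal
        // is deterministic given the ordered pair and the current state,
        // so the Metropolis-Hastings ratio is the Boltzmann factor times
        // the ratio of proposal volumes.
        int i = rng.unif_int(n);
        int j = rng.unif_int(n - 1);
        if (j >= i) j++;
        double v_in = 4.0 / 3.0 * M_PI * rbond * rbond * rbond;
        double v_out = L * L * L - v_in;
        bool in_now = sys.dist2(i, j) < rbond * rbond;
        double nx, ny, nz;
        if (in_now) {
          // propose uniform outside the shell of j
          do {
            nx = rng.unif() * L; ny = rng.unif() * L; nz = rng.unif() * L;
          } while (
            [&]{ double dx = min_image(nx - sys.px[j], L),
                        dy = min_image(ny - sys.py[j], L),
                        dz = min_image(nz - sys.pz[j], L);
                 return dx * dx + dy * dy + dz * dz < rbond * rbond; }());
        } else {
          // propose uniform inside the shell of j
          double dx, dy, dz;
          do {
            dx = (2.0 * rng.unif() - 1.0) * rbond;
            dy = (2.0 * rng.unif() - 1.0) * rbond;
            dz = (2.0 * rng.unif() - 1.0) * rbond;
          } while (dx * dx + dy * dy + dz * dz >= rbond * rbond);
          nx = wrap(sys.px[j] + dx, L);
          ny = wrap(sys.py[j] + dy, L);
          nz = wrap(sys.pz[j] + dz, L);
        }
        double du = sys.energy_at(i, nx, ny, nz) -
                    sys.energy_at(i, sys.px[i], sys.py[i], sys.pz[i]);
        double vol_ratio = in_now ? v_out / v_in : v_in / v_out;
        accept = rng.unif() < std::exp(-beta * du) * vol_ratio;
        if (accept) { sys.px[i] = nx; sys.py[i] = ny; sys.pz[i] = nz; }
      } else {
        int i = rng.unif_int(n);
        double nx = wrap(sys.px[i] + (2.0 * rng.unif() - 1.0) * disp, L);
        double ny = wrap(sys.py[i] + (2.0 * rng.unif() - 1.0) * disp, L);
        double nz = wrap(sys.pz[i] + (2.0 * rng.unif() - 1.0) * disp, L);
        double du = sys.energy_at(i, nx, ny, nz) -
                    sys.energy_at(i, sys.px[i], sys.py[i], sys.pz[i]);
        accept = du <= 0.0 || rng.unif() < std::exp(-beta * du);
        if (accept) { sys.px[i] = nx; sys.py[i] = ny; sys.pz[i] = nz; }
      }
      if (production) { att_prod++; if (accept) acc_prod++; }
      else if (was_disp) { att_win++; if (accept) acc_win++; }
    }
    if (!production && adapt && att_win >= 200LL * n) {
      // tune toward ~40% acceptance during equilibration only; the
      // production chain runs with a frozen step to preserve detailed balance
      double rate = (double)acc_win / (double)att_win;
      if (rate < 0.35) disp *= 0.85;
      else if (rate > 0.45) disp *= 1.15;
      if (disp < disp_min) disp = disp_min;
      if (disp > disp_max) disp = disp_max;
      acc_win = att_win = 0;
    }
    if (production) {
      long long k = sweep - equil + 1;
      if (k % thin == 0 && frame < n_frames) {
        cluster_sizes(sys, rbond2, comp);
        for (int m = 0; m < n; ++m) counts(frame, m) = comp[m];
        frame++;
      }
      if (traj_every > 0 && k % traj_every == 0 && tframe < n_traj) {
        for (int i = 0; i < n; ++i) {
          traj(tframe, 3 * i) = sys.px[i];
          traj(tframe, 3 * i + 1) = sys.py[i];
          traj(tframe, 3 * i + 2) = sys.pz[i];
        }
        tframe++;
      }
    }
  }

  List out = List::create(
    _["counts"] = counts,
    _["acceptance"] = att_prod > 0 ? (double)acc_prod / att_prod : NA_REAL,
    _["max_disp_final"] = disp,
    _["equil_sweeps"] = (double)equil);
  if (n_traj > 0) out["trajectory"] = traj;
  return out;
}
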