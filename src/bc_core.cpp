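#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
static void fib_sphere(int n, std::vector<double> &px,
                       std::vector<double> &py, std::vector<double> &pz) {
  px.resize(n); py.resize(n); pz.resize(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }
}

// Shrake-Rupley SASA. coords: m x 3, radii: m. Returns per-atom SASA (A^2).
// For each atom, the fraction of test points on its solvent-expanded sphere
// not inside any other expanded sphere, times the expanded sphere area.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int m = coords.nrow();
  NumericVector out(m);
  if (m == 0) return out;
  std::vector<double> px, py, pz;
  fib_sphere(n_points, px, py, pz);
  std::vector<double> re(m);
  for (int i = 0; i < m; ++i) re[i] = radii[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < m; ++i) {
    nb.clear();
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double lim = re[i] + re[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + re[i] * px[k], qy = yi + re[i] * py[k],
             qz = zi + re[i] * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
               dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < re[j] * re[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    out[i] = (4.0 * M_PI * re[i] * re[i]) * ((double)exposed / n_points);
  }
  return out;
}

// Metropolis Monte Carlo titration over a pH grid.
// gamma: +1/-1 per site; pka_int: intrinsic pKa; W: n x n coupling matrix
// (kJ/mol, energy of both sites ionised); pairs: 2-column matrix (0-based)
// of strongly coupled pairs given joint flip moves. Uses the R RNG, so
// results are reproducible under set.seed(). Returns n_ph x n matrix of
// mean ionisation <s_i> averaged over post-burn-in sweeps.
// [[Rcpp::export]]
NumericMatrix cpp_mc_titration(NumericVector gamma_, NumericVector pka_int,
                               NumericMatrix W, double rt_kln10, double rt,
                               NumericVector ph_grid, int n_sweeps,
                               int n_burnin, IntegerMatrix pairs) {
  int n = gamma_.size();
  int nph = ph_grid.size();
  int npair = pairs.nrow();
  NumericMatrix out(nph, n);
  RNGScope scope;

  std::vector<int> s(n);
  std::vector<double> acc(n);
  for (int p = 0; p < nph; ++p) {
    double ph = ph_grid[p];
    std::vector<double> h(n);
    for (int i = 0; i < n; ++i)
      h[i] = gamma_[i] * rt_kln10 * (ph - pka_int[i]);
    // start from the uncoupled ground state
    for (int i = 0; i < n; ++i) s[i] = h[i] < 0 ? 1 : 0;
    std::fill(acc.begin(), acc.end(), 0.0);
    int kept = 0;
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      for (int a = 0; a < n; ++a) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        double field = h[i];
        for (int j = 0; j < n; ++j)
          if (j != i && s[j]) field += W(i, j);
        double dE = (1 - 2 * s[i]) * field;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) s[i] = 1 - s[i];
      }
      for (int q = 0; q < npair; ++q) {
        int i = pairs(q, 0), j = pairs(q, 1);
        int si = 1 - s[i], sj = 1 - s[j];
        double fi = h[i], fj = h[j];
        for (int k = 0; k < n; ++k) {
          if (k != i && k != j && s[k]) {
            fi += W(i, k);
            fj += W(j, k);
          }
        }
        double dE = (si - s[i]) * fi + (sj - s[j]) * fj +
                    (si * sj - s[i] * s[j]) * W(i, j);
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / rt)) {
          s[i] = si;
          s[j] = sj;
        }
      }
      if (sweep >= n_burnin) {
        for (int i = 0; i < n; ++i) acc[i] += s[i];
        ++kept;
      }
    }
    for (int i = 0; i < n; ++i) out(p, i) = acc[i] / kept;
  }
  return out;
}
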