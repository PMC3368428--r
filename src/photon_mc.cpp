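#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Layered-slab photon Monte Carlo (hop/drop/spin with weight deposition).
// Photons launched normally at z = 0 into a stack of contiguous layers; steps
// sampled against the total attenuation mu_t of the current layer, a fraction
// mu_a/mu_t of the weight deposited at each interaction, direction resampled
// from the Henyey-Greenstein phase function.  Photons crossing z = 0 upward
// are remitted and contribute their per-layer traversed path lengths.
// Russian roulette keeps the weight ledger exact: kills credit the absorbed
// bucket, survivals debit it, so remitted + absorbed + transmitted always
// sums to the launched weight.

static inline void hg_scatter(double g, double &ux, double &uy, double &uz,
                              std::mt19937_64 &rng,
                              std::uniform_real_distribution<double> &unif) {
  double ct;
  if (std::fabs(g) < 1e-12) {
    ct = 2.0 * unif(rng) - 1.0;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif(rng));
    ct = (1.0 + g * g - f * f) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif(rng);
  double cp = std::cos(phi), sp = std::sin(phi);
  double nux, nuy, nuz;
  if (std::fabs(uz) > 0.99999) {
    nux = st * cp;
    nuy = st * sp;
    nuz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nuz = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
  ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
}

// [[Rcpp::export(name = ".photon_mc_cpp")]]
List photon_mc_cpp(NumericVector z_top, NumericVector z_bot,
                   NumericVector mua, NumericVector mus, NumericVector g,
                   int n_photons, int seed,
                   double w_cutoff = 1e-4, double p_survive = 0.1) {
  const int nl = z_top.size();
  if (n_photons < 1) stop("n_photons must be >= 1");
  const double z_max = z_bot[nl - 1];

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> path(nl);           // per-photon partial paths
  std::vector<double> sum_w_path(nl, 0.0);
  double w_remit = 0.0, w_absorb = 0.0, w_transmit = 0.0;
  double sum_w_tot = 0.0, sum_w_tot2 = 0.0; // remitted-weighted total path moments
  double sum_w_maxdepth_ok = 0.0;           // weight with total path >= 2*max depth
  long n_remit = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    int layer = 0;
    std::fill(path.begin(), path.end(), 0.0);
    double max_depth = 0.0;
    bool alive = true;

    while (alive) {
      double s_dimless = -std::log(unif(rng) + 1e-300); // in units of mfp
      while (s_dimless > 0.0 && alive) {
        double mut = mua[layer] + mus[layer];
        double s_phys = (mut > 0) ? s_dimless / mut : 1e30;
        // distance to layer boundary along uz
        double db = 1e30;
        int next_layer = layer;
        bool exits_top = false, exits_bottom = false;
        if (uz > 1e-12) {
          db = (z_bot[layer] - z) / uz;
          if (layer == nl - 1) exits_bottom = true; else next_layer = layer + 1;
        } else if (uz < -1e-12) {
          db = (z_top[layer] - z) / uz;
          if (layer == 0) exits_top = true; else next_layer = layer - 1;
        }
        if (db < 0) db = 0;
        if (s_phys < db) {
          // interaction inside the layer
          x += ux * s_phys; y += uy * s_phys; z += uz * s_phys;
          path[layer] += s_phys;
          if (z > max_depth) max_depth = z;
          s_dimless = 0.0;
          if (mut > 0) {
            double dw = w * mua[layer] / mut;
            w_absorb += dw;
            w -= dw;
          }
          hg_scatter(g[layer], ux, uy, uz, rng, unif);
        } else {
          // move to the boundary, carry the residual dimensionless step
          x += ux * db; y += uy * db; z += uz * db;
          path[layer] += db;
          if (z > max_depth) max_depth = z;
          s_dimless -= db * mut;
          if (s_dimless < 0) s_dimless = 0;
          if (exits_top) {
            // remitted (matched refractive index: no internal reflection)
            w_remit += w;
            double tot = 0.0;
            for (int l = 0; l < nl; ++l) { sum_w_path[l] += w * path[l]; tot += path[l]; }
            sum_w_tot += w * tot;
            sum_w_tot2 += w * tot * tot;
            if (tot >= 2.0 * max_depth - 1e-9) sum_w_maxdepth_ok += w;
            ++n_remit;
            alive = false;
          } else if (exits_bottom) {
            w_transmit += w;
            alive = false;
          } else {
            layer = next_layer;
            // nudge off the boundary to avoid sticking
            z = (uz > 0) ? z_top[layer] + 1e-12 : z_bot[layer] - 1e-12;
            if (z < 0) z = 0; if (z > z_max) z = z_max;
          }
        }
      }
      if (alive && w < w_cutoff) {
        if (unif(rng) < p_survive) {
          double boost = w / p_survive - w;
          w_absorb -= boost;   // exact ledger: survivor gains come from the absorbed bucket
          w = w / p_survive;
        } else {
          w_absorb += w;
          alive = false;
        }
      }
    }
  }

  NumericVector mean_path(nl);
  bool empty = (w_remit <= 0.0);
  for (int l = 0; l < nl; ++l)
    mean_path[l] = empty ? 0.0 : sum_w_path[l] / w_remit;
  double mean_tot = empty ? 0.0 : sum_w_tot / w_remit;
  double var_tot = empty ? 0.0 : std::max(0.0, sum_w_tot2 / w_remit - mean_tot * mean_tot);

  return List::create(
    _["mean_path_mm"] = mean_path,
    _["mean_total_path_mm"] = mean_tot,
    _["se_total_path_mm"] = empty ? 0.0 : std::sqrt(var_tot / std::max(1L, n_remit)),
    _["remitted_fraction"] = w_remit / n_photons,
    _["absorbed_fraction"] = w_absorb / n_photons,
    _["transmitted_fraction"] = w_transmit / n_photons,
    _["n_remitted"] = (double)n_remit,
    _["path_depth_ok_fraction"] = empty ? 1.0 : sum_w_maxdepth_ok / w_remit,
    _["empty"] = empty);
}
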