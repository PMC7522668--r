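#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Layered-slab white Monte Carlo (no absorption during transport).
// Pencil beam enters normally at the origin of the top surface (z = 0,
// z increasing into the tissue, lengths in cm). Steps are sampled from the
// per-layer scattering coefficient `mus`; layer crossings split steps
// exactly at the interfaces. The top surface applies unpolarized Fresnel
// reflection (total internal reflection included) for relative index
// n_rel = n_in / n_out; photons crossing the bottom cap or exceeding the
// total pathlength cap are dropped. Photons exiting the top surface with
// exit radius in [r_min, r_max] are recorded with per-layer pathlengths,
// per-layer momentum-transfer sums (1 - cos(theta) per scattering event),
// exit radius, exit time, and scattering count.
//
// Scattering is isotropic when hg_g == 0 (similarity relation: pass
// mus = musp), Henyey-Greenstein otherwise (pass mus = musp / (1 - g)).
//
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
NumericMatrix mc_layered_cpp(NumericVector mus, NumericVector z_bound,
                             double n_rel, double n_photons,
                             double r_min, double r_max,
                             double path_cap, double hg_g) {
  const int K = mus.size();
  if (z_bound.size() != K + 1)
    stop("z_bound must have one more entry than mus");
  for (int k = 0; k < K; ++k)
    if (mus[k] <= 0) stop("every layer needs a positive scattering coefficient");

  const double crit_cos = (n_rel > 1.0)
    ? std::sqrt(1.0 - 1.0 / (n_rel * n_rel)) : 0.0;
  const int ncol = 2 * K + 3;
  std::vector<double> recs;

  std::vector<double> L(K), Y(K);

  for (long ip = 0; ip < (long)n_photons; ++ip) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    double total = 0;
    int k = 0, nscat = 0;
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(Y.begin(), Y.end(), 0.0);
    bool alive = true, detected = false;

    while (alive) {
      double d = -std::log(unif_rand());  // optical depth to next scattering
      // propagate, splitting at interfaces
      while (d > 0 && alive) {
        double dist_b = R_PosInf;
        if (uz > 0)      dist_b = (z_bound[k + 1] - z) / uz;
        else if (uz < 0) dist_b = (z_bound[k] - z) / uz;  // uz<0 => positive
        double s_free = d / mus[k];
        if (s_free < dist_b) {
          x += ux * s_free; y += uy * s_free; z += uz * s_free;
          L[k] += s_free; total += s_free; d = 0;
        } else {
          x += ux * dist_b; y += uy * dist_b;
          L[k] += dist_b; total += dist_b; d -= mus[k] * dist_b;
          if (uz > 0) {           // downward crossing
            z = z_bound[k + 1];
            if (k == K - 1) { alive = false; break; }   // bottom cap
            ++k;
          } else {                // upward crossing
            z = z_bound[k];
            if (k == 0) {         // top surface: Fresnel
              double ci = -uz;    // cos of incidence from inside
              double refl;
              if (ci <= crit_cos) refl = 1.0;  // total internal reflection
              else {
                double st2 = n_rel * n_rel * (1.0 - ci * ci);
                double ct = std::sqrt(1.0 - st2);
                double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
                double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
                refl = 0.5 * (rs * rs + rp * rp);
              }
              if (unif_rand() < refl) {
                uz = -uz;         // specular reflection back inside
              } else {
                double r = std::sqrt(x * x + y * y);
                if (r >= r_min && r <= r_max) detected = true;
                alive = false;
              }
            } else --k;
          }
        }
        if (total > path_cap) alive = false;
      }
      if (!alive) break;
      // scattering event
      double cdef;
      if (hg_g == 0.0) {
        double nz = 2.0 * unif_rand() - 1.0;
        double phi = 2.0 * M_PI * unif_rand();
        double sz = std::sqrt(std::max(0.0, 1.0 - nz * nz));
        double nx = sz * std::cos(phi), ny = sz * std::sin(phi);
        cdef = ux * nx + uy * ny + uz * nz;
        ux = nx; uy = ny; uz = nz;
      } else {
        double g = hg_g;
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        ct = std::max(-1.0, std::min(1.0, ct));
        double st = std::sqrt(1.0 - ct * ct);
        double phi = 2.0 * M_PI * unif_rand();
        double cp = std::cos(phi), sp = std::sin(phi);
        double nx, ny, nz;
        if (std::fabs(uz) > 0.99999) {
          nx = st * cp; ny = st * sp; nz = (uz >= 0 ? ct : -ct);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          nz = -st * cp * den + uz * ct;
        }
        cdef = ct;
        ux = nx; uy = ny; uz = nz;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }
      Y[k] += 1.0 - cdef;
      ++nscat;
    }

    if (detected) {
      for (int l = 0; l < K; ++l) recs.push_back(L[l]);
      for (int l = 0; l < K; ++l) recs.push_back(Y[l]);
      double r = std::sqrt(x * x + y * y);
      recs.push_back(r);
      recs.push_back(total);   // converted to seconds on the R side
      recs.push_back((double)nscat);
    }
  }

  const int nrec = recs.size() / ncol;
  NumericMatrix out(nrec, ncol);
  for (int i = 0; i < nrec; ++i)
    for (int j = 0; j < ncol; ++j)
      out(i, j) = recs[(size_t)i * ncol + j];
  return out;
}
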