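#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// linear interpolation over an increasing grid, clamped at the ends
static inline double interp_clamped(double x, const double* xs, const double* ys, int n) {
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid;
  }
  double t = (x - xs[lo]) / (xs[lo + 1] - xs[lo]);
  return ys[lo] + t * (ys[lo + 1] - ys[lo]);
}

// Condensed-history kernel Monte Carlo: electrons start at the origin with
// isotropic... (direction irrelevant by symmetry: +z), lose energy along
// CSDA sub-steps of the Katz-Penfold range and scatter per the Highland
// multiple-scattering angle each step. Deposited energy is binned by
// crow-flies radius. Uses R's RNG (honors set.seed upstream).
// [[Rcpp::export]]
NumericVector cpp_kernel_mc(NumericVector energies, int n_steps,
                            NumericVector e_grid, NumericVector r_grid,
                            double bin_mm, double r_max,
                            double e_cut, double x0_mm) {
  const int n = energies.size(), ng = e_grid.size();
  const int nb = (int)std::ceil(r_max / bin_mm);
  NumericVector dep(nb + 1); // last slot: beyond r_max
  const double* eg = e_grid.begin();
  const double* rg = r_grid.begin();
  const double me = 0.510999;

  for (int i = 0; i < n; ++i) {
    double E = energies[i];
    if (E <= e_cut) continue;
    double R0 = interp_clamped(E, eg, rg, ng);
    double ds = R0 / n_steps;
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    double range_left = R0;
    while (E > e_cut) {
      range_left -= ds;
      double Enew = range_left > 0 ? interp_clamped(range_left, rg, eg, ng) : 0.0;
      double dE = E - Enew;
      double xm = x + ux * ds * 0.5, ym = y + uy * ds * 0.5, zm = z + uz * ds * 0.5;
      double rad = std::sqrt(xm * xm + ym * ym + zm * zm);
      int ib = (int)(rad / bin_mm);
      dep[ib < nb ? ib : nb] += dE;
      x += ux * ds; y += uy * ds; z += uz * ds;
      E = Enew;
      if (E <= e_cut) {
        // deposit the sub-cutoff remainder locally
        double r2 = std::sqrt(x * x + y * y + z * z);
        int ib2 = (int)(r2 / bin_mm);
        dep[ib2 < nb ? ib2 : nb] += E;
        break;
      }
      // Highland multiple-scattering deflection for this step
      double W = 1 + E / me;
      double p = std::sqrt(W * W - 1) * me;
      double beta = std::sqrt(1 - 1 / (W * W));
      double xs = ds / x0_mm;
      double th0 = 13.6 / (beta * p) * std::sqrt(xs) * (1 + 0.038 * std::log(xs));
      if (th0 < 0) th0 = 0;
      double thx = R::rnorm(0, 1) * th0, thy = R::rnorm(0, 1) * th0;
      double th = std::sqrt(thx * thx + thy * thy);
      double ph = R::runif(0, 2 * M_PI);
      double st = std::sin(th), ct = std::cos(th);
      double sp = std::sin(ph), cp = std::cos(ph);
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp; nuy = st * sp; nuz = (uz > 0 ? ct : -ct);
      } else {
        double sz = std::sqrt(1 - uz * uz);
        nux = ux * ct + st * (ux * uz * cp - uy * sp) / sz;
        nuy = uy * ct + st * (uy * uz * cp + ux * sp) / sz;
        nuz = uz * ct - st * cp * sz;
      }
      double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
      ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
    }
  }
  return dep;
}

// Volume-source convolution of a calibrated point kernel over the
// cylindrical seed. Each history samples a uniform emission point and an
// isotropic ray; the cumulative kernel K is marched along the ray with
// the in-glass segment converted to water-equivalent length (rho_eff x
// geometric). Deposits are scored on the polar (r, theta) grid in units
// of "fraction of one decay's emitted energy". Uses R's RNG.
// [[Rcpp::export]]
List cpp_seed_convolve(int n_hist, double radius_mm, double half_len_mm,
                       double rho_eff, NumericVector k_r, NumericVector k_cum,
                       int n_r, double dr, int n_th, double dth,
                       double step_mm) {
  const int ng = k_r.size();
  const double* kr = k_r.begin();
  const double* kc = k_cum.begin();
  const double support = k_r[ng - 1];
  NumericMatrix cell(n_r, n_th);
  NumericVector radial(n_r);
  double fself = 0, beyond = 0;
  const double a2 = radius_mm * radius_mm;

  for (int i = 0; i < n_hist; ++i) {
    // uniform point in the cylinder
    double rr = radius_mm * std::sqrt(R::runif(0, 1));
    double phe = R::runif(0, 2 * M_PI);
    double x0 = rr * std::cos(phe), y0 = rr * std::sin(phe);
    double z0 = R::runif(-half_len_mm, half_len_mm);
    // isotropic direction
    double cz = R::runif(-1, 1);
    double sz = std::sqrt(1 - cz * cz);
    double phd = R::runif(0, 2 * M_PI);
    double ux = sz * std::cos(phd), uy = sz * std::sin(phd), uz = cz;
    // geometric exit distance through the finite cylinder
    double A = ux * ux + uy * uy;
    double tlat = R_PosInf;
    if (A > 1e-14) {
      double B = x0 * ux + y0 * uy;
      double C = x0 * x0 + y0 * y0 - a2;
      double disc = B * B - A * C;
      if (disc < 0) disc = 0;
      tlat = (-B + std::sqrt(disc)) / A;
    }
    double tcap = R_PosInf;
    if (std::fabs(uz) > 1e-14)
      tcap = uz > 0 ? (half_len_mm - z0) / uz : (-half_len_mm - z0) / uz;
    double tg = tlat < tcap ? tlat : tcap;
    double u0 = rho_eff * tg;           // water-equivalent depth at exit
    double Kprev = interp_clamped(u0, kr, kc, ng);
    fself += Kprev;
    if (Kprev >= 1.0 - 1e-12) continue;
    // march the escaped fraction through water
    double tmax = tg + (support - u0) + step_mm;
    for (double t1 = tg + step_mm; ; t1 += step_mm) {
      double K1 = interp_clamped(u0 + (t1 - tg), kr, kc, ng);
      double dE = K1 - Kprev;
      Kprev = K1;
      if (dE > 0) {
        double tm = t1 - step_mm * 0.5;
        double X = x0 + tm * ux, Y = y0 + tm * uy, Z = z0 + tm * uz;
        double rad = std::sqrt(X * X + Y * Y + Z * Z);
        int ir = (int)(rad / dr);
        if (ir < n_r) {
          double cth = Z / rad;
          if (cth > 1) cth = 1; else if (cth < -1) cth = -1;
          int it = (int)(std::acos(cth) / dth);
          if (it >= n_th) it = n_th - 1;
          cell(ir, it) += dE;
          radial[ir] += dE;
        } else {
          beyond += dE;
        }
      }
      if (K1 >= 1.0 - 1e-12 || t1 > tmax) {
        if (K1 < 1.0 - 1e-12) beyond += 1.0 - K1; // numerical guard
        break;
      }
    }
  }
  return List::create(_["cell"] = cell, _["radial"] = radial,
                      _["fself"] = fself, _["beyond"] = beyond,
                      _["n"] = n_hist);
}
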