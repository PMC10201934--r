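// Hot loops of the simulation: stepwise electron propagation, Cerenkov
// photon generation along steps, and optical ray tracing in the crystal.
// All randomness goes through R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double M_E_MEV = 0.511;

// linear interpolation on an ascending grid, clamped at the ends
static double interp(double x, const double* xs, const double* ys, int n) {
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid;
  }
  double w = (x - xs[lo]) / (xs[lo + 1] - xs[lo]);
  return ys[lo] + w * (ys[lo + 1] - ys[lo]);
}

static void rotate_dir(double* v, double theta, double phi) {
  double a[3];
  if (std::fabs(v[2]) < 0.999) { a[0] = 0; a[1] = 0; a[2] = 1; }
  else { a[0] = 1; a[1] = 0; a[2] = 0; }
  double u1[3] = {
    a[1] * v[2] - a[2] * v[1],
    a[2] * v[0] - a[0] * v[2],
    a[0] * v[1] - a[1] * v[0]
  };
  double n1 = std::sqrt(u1[0] * u1[0] + u1[1] * u1[1] + u1[2] * u1[2]);
  for (int k = 0; k < 3; ++k) u1[k] /= n1;
  double u2[3] = {
    v[1] * u1[2] - v[2] * u1[1],
    v[2] * u1[0] - v[0] * u1[2],
    v[0] * u1[1] - v[1] * u1[0]
  };
  double st = std::sin(theta), ct = std::cos(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  double out[3];
  for (int k = 0; k < 3; ++k)
    out[k] = st * (cp * u1[k] + sp * u2[k]) + ct * v[k];
  double nn = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
  for (int k = 0; k < 3; ++k) v[k] = out[k] / nn;
}

// [[Rcpp::export]]
NumericMatrix cpp_propagate(double ke0, NumericVector pos0, NumericVector dir0,
                            double t0, double delta_beta,
                            NumericVector ke_grid, NumericVector dedx_tot,
                            NumericVector dedx_col, NumericVector range_grid,
                            double beta_thr, double x0_mm,
                            double cutoff, double ke_cut,
                            bool msc, int max_steps) {
  const double* kg = ke_grid.begin();
  const double* dc = dedx_col.begin();
  const double* rg = range_grid.begin();
  const int ng = ke_grid.size();
  const double c_mm_ns = 299.792458;

  std::vector<double> rows; // 13 columns per step
  rows.reserve(13 * 1024);

  double ke = ke0, t = t0;
  double pos[3] = { pos0[0], pos0[1], pos0[2] };
  double dir[3] = { dir0[0], dir0[1], dir0[2] };
  double dn = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  for (int k = 0; k < 3; ++k) dir[k] /= dn;

  int nsteps = 0;
  while (ke > cutoff * (1 + 1e-9) && nsteps < max_steps) {
    double gamma = 1 + ke / M_E_MEV;
    double beta = std::sqrt(1 - 1 / (gamma * gamma));
    double r_here = interp(ke, kg, rg, ng);
    double dx;
    if (ke > 2 * ke_cut) dx = r_here - interp(ke_cut, kg, rg, ng);
    else dx = r_here - interp(cutoff, kg, rg, ng);
    if (dx <= 1e-12) break;
    double st = dx;
    if (delta_beta > 0 && beta > beta_thr) {
      double bf = beta * (1 - delta_beta);
      double gf = 1 / std::sqrt(1 - bf * bf);
      double dl = M_E_MEV * (gamma - gf) / interp(ke, kg, dc, ng);
      if (dl < st) st = dl;
    }
    double r_new = r_here - st;
    double ke_new;
    if (r_new <= rg[0]) ke_new = kg[0];
    else ke_new = interp(r_new, rg, kg, ng); // range grid is ascending in ke
    double g_new = 1 + ke_new / M_E_MEV;
    double b_new = std::sqrt(1 - 1 / (g_new * g_new));
    double t_new = t + st / (beta * c_mm_ns);

    rows.push_back(ke);        // pre_ke
    rows.push_back(ke_new);    // post_ke
    rows.push_back(st);        // length
    rows.push_back(pos[0]); rows.push_back(pos[1]); rows.push_back(pos[2]);
    rows.push_back(dir[0]); rows.push_back(dir[1]); rows.push_back(dir[2]);
    rows.push_back(t);         // pre_time
    rows.push_back(t_new);     // post_time
    rows.push_back(beta);      // pre_beta
    rows.push_back(b_new);     // post_beta

    for (int k = 0; k < 3; ++k) pos[k] += st * dir[k];
    t = t_new;
    ++nsteps;
    ke = ke_new;
    if (ke <= cutoff * (1 + 1e-9)) break;
    if (msc) {
      double p = gamma * M_E_MEV * beta; // pc in MeV
      double theta0 = 13.6 / (beta * p) * std::sqrt(st / x0_mm);
      double theta = std::fabs(norm_rand()) * theta0;
      double phi = 2 * M_PI * unif_rand();
      rotate_dir(dir, theta, phi);
    }
  }

  NumericMatrix out(nsteps, 13);
  for (int i = 0; i < nsteps; ++i)
    for (int j = 0; j < 13; ++j) out(i, j) = rows[13 * i + j];
  return out;
}

static double yield_mm(double beta, const double* eg, const double* ng,
                       int n, double pref) {
  if (beta <= 0) return 0.0;
  double b2 = beta * beta;
  double acc = 0.0;
  double fprev = 1 - 1 / (b2 * ng[0] * ng[0]);
  if (fprev < 0) fprev = 0;
  for (int i = 1; i < n; ++i) {
    double f = 1 - 1 / (b2 * ng[i] * ng[i]);
    if (f < 0) f = 0;
    acc += (f + fprev) / 2 * (eg[i] - eg[i - 1]);
    fprev = f;
  }
  return pref * acc;
}

// steps matrix columns: pre_beta post_beta length pre_x pre_y pre_z
//                       dir_x dir_y dir_z pre_time post_time
// mode 0: pre/post-averaged expected count, yield-weighted placement
// mode 1: pre-step expected count, uniform placement, sub-threshold discard
// [[Rcpp::export]]
NumericMatrix cpp_emit_cherenkov(NumericMatrix steps, NumericVector egrid,
                                 NumericVector ngrid, double prefactor,
                                 int mode) {
  const double* eg = egrid.begin();
  const double* ng = ngrid.begin();
  const int ne = egrid.size();
  const double emin = eg[0], emax = eg[ne - 1];
  double nmax = 0.0;
  for (int i = 0; i < ne; ++i) if (ng[i] > nmax) nmax = ng[i];

  std::vector<double> rows; // 9 columns per photon
  for (int s = 0; s < steps.nrow(); ++s) {
    double b1 = steps(s, 0), b2 = steps(s, 1), L = steps(s, 2);
    double y1 = yield_mm(b1, eg, ng, ne, prefactor);
    double y2 = yield_mm(b2, eg, ng, ne, prefactor);
    double mu = (mode == 0) ? L * (y1 + y2) / 2 : L * y1;
    if (mu <= 0) continue;
    int nph = (int) R::rpois(mu);
    for (int i = 0; i < nph; ++i) {
      double u;
      if (mode == 0 && std::fabs(y2 - y1) > 1e-12 * (y1 + y2)) {
        // position density linear in the interpolated yield
        double ur = unif_rand();
        double disc = y1 * y1 + ur * (y2 * y2 - y1 * y1);
        u = (std::sqrt(disc) - y1) / (y2 - y1);
      } else {
        u = unif_rand();
      }
      double bloc = b1 + u * (b2 - b1);
      if (bloc * nmax <= 1.0) continue; // locally below threshold
      double gmax = 1 - 1 / (bloc * bloc * nmax * nmax);
      double e = 0, nloc = 0;
      bool ok = false;
      for (int k = 0; k < 10000; ++k) {
        e = emin + unif_rand() * (emax - emin);
        nloc = interp(e, eg, ng, ne);
        double dens = 1 - 1 / (bloc * bloc * nloc * nloc);
        if (dens > 0 && unif_rand() * gmax < dens) { ok = true; break; }
      }
      if (!ok) continue;
      double cth = 1 / (bloc * nloc);
      double theta = std::acos(cth);
      double phi = 2 * M_PI * unif_rand();
      double d[3] = { steps(s, 6), steps(s, 7), steps(s, 8) };
      rotate_dir(d, theta, phi);
      rows.push_back(steps(s, 3) + u * L * steps(s, 6)); // x
      rows.push_back(steps(s, 4) + u * L * steps(s, 7)); // y
      rows.push_back(steps(s, 5) + u * L * steps(s, 8)); // z
      rows.push_back(steps(s, 9) + u * (steps(s, 10) - steps(s, 9))); // time
      rows.push_back(e);
      rows.push_back(d[0]); rows.push_back(d[1]); rows.push_back(d[2]);
      rows.push_back(s + 1.0); // emitting step (1-based)
    }
  }
  int nph = rows.size() / 9;
  NumericMatrix out(nph, 9);
  for (int i = 0; i < nph; ++i)
    for (int j = 0; j < 9; ++j) out(i, j) = rows[9 * i + j];
  return out;
}

static double fresnel_unpol(double cosi, double n1, double n2) {
  double sini2 = 1 - cosi * cosi;
  double sint2 = (n1 / n2) * (n1 / n2) * sini2;
  if (sint2 > 1) return 1.0; // TIR
  double cost = std::sqrt(1 - sint2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return (rs * rs + rp * rp) / 2;
}

// photons matrix columns: x y z time energy dir_x dir_y dir_z
// output columns: status (0 detected, 1 absorbed, 2 wrap_lost, 3 trapped),
//                 path_length, n_reflections, detection_time
// [[Rcpp::export]]
NumericMatrix cpp_trace_photons(NumericMatrix photons, double hx, double hy,
                                double zlen, NumericVector egrid,
                                NumericVector ngrid, NumericVector nggrid,
                                NumericVector absgrid, double wrap_refl,
                                double n_grease, int max_refl,
                                double c_mm_ns) {
  const double* eg = egrid.begin();
  const int ne = egrid.size();
  const double eps = 1e-9;
  NumericMatrix out(photons.nrow(), 4);

  for (int p = 0; p < photons.nrow(); ++p) {
    double pos[3] = { photons(p, 0), photons(p, 1), photons(p, 2) };
    double dir[3] = { photons(p, 5), photons(p, 6), photons(p, 7) };
    double e = photons(p, 4);
    double n1 = interp(e, eg, ngrid.begin(), ne);
    double ngi = interp(e, eg, nggrid.begin(), ne);
    double lam = interp(e, eg, absgrid.begin(), ne);
    double lim_lo[3] = { -hx, -hy, 0 };
    double lim_hi[3] = { hx, hy, zlen };
    double path = 0;
    int nrefl = 0;
    int status = 3; // trapped unless resolved
    bool done = false;

    while (!done) {
      // distance to nearest face
      double tmin = 1e30;
      int axis = -1, side = 0;
      for (int k = 0; k < 3; ++k) {
        if (dir[k] > eps) {
          double tt = (lim_hi[k] - pos[k]) / dir[k];
          if (tt < tmin) { tmin = tt; axis = k; side = +1; }
        } else if (dir[k] < -eps) {
          double tt = (lim_lo[k] - pos[k]) / dir[k];
          if (tt < tmin) { tmin = tt; axis = k; side = -1; }
        }
      }
      if (axis < 0 || tmin > 1e29) { status = 3; break; }
      if (tmin < 0) tmin = 0;
      // bulk absorption over the segment
      double dabs = -lam * std::log(unif_rand());
      if (dabs < tmin) { path += dabs; status = 1; break; }
      path += tmin;
      for (int k = 0; k < 3; ++k) pos[k] += tmin * dir[k];
      pos[axis] = (side > 0) ? lim_hi[axis] : lim_lo[axis];

      double cosi = std::fabs(dir[axis]);
      bool detector_face = (axis == 2 && side < 0);
      double n2 = detector_face ? n_grease : 1.0;
      double refl = fresnel_unpol(cosi, n1, n2);
      if (unif_rand() < refl) { // specular reflection (includes TIR)
        dir[axis] = -dir[axis];
        ++nrefl;
      } else if (detector_face) {
        status = 0; // transmitted into grease: detected (ideal PDE)
        done = true;
      } else {
        // transmitted through a polished face into the air gap: diffuse
        // Teflon wrap behind it. The photon leaves the wrap Lambertian in
        // air and must refract back into the crystal; reflected attempts
        // return to the wrap (each wrap interaction costs wrap_refl).
        bool back_inside = false;
        for (int attempt = 0; attempt < 200; ++attempt) {
          if (unif_rand() >= wrap_refl) { status = 2; break; } // absorbed in wrap
          double ct_air = std::sqrt(unif_rand()); // cosine-weighted in air
          double cosi_air = ct_air;
          double r_in = fresnel_unpol(cosi_air, 1.0, n1); // air -> crystal
          if (unif_rand() < r_in) continue; // back to the wrap
          // Snell refraction into the crystal about the inward normal
          double sin_air = std::sqrt(1 - ct_air * ct_air);
          double sin_c = sin_air / n1;
          double cos_c = std::sqrt(1 - sin_c * sin_c);
          double phi = 2 * M_PI * unif_rand();
          double nrm[3] = { 0, 0, 0 };
          nrm[axis] = (side > 0) ? -1.0 : 1.0; // inward
          double d[3] = { nrm[0], nrm[1], nrm[2] };
          rotate_dir(d, std::acos(cos_c), phi);
          for (int k = 0; k < 3; ++k) dir[k] = d[k];
          if ((side > 0 && dir[axis] > -eps) || (side < 0 && dir[axis] < eps))
            dir[axis] = (side > 0) ? -std::fabs(dir[axis]) - eps
                                   : std::fabs(dir[axis]) + eps;
          back_inside = true;
          break;
        }
        if (!back_inside) {
          if (status != 2) status = 2;
          break;
        }
        ++nrefl;
      }
      if (!done && nrefl >= max_refl) { status = 3; break; }
    }

    out(p, 0) = status;
    out(p, 1) = path;
    out(p, 2) = nrefl;
    out(p, 3) = photons(p, 3) + path * ngi / c_mm_ns;
  }
  return out;
}
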