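#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image separation component in a cubic periodic box of edge L.
inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double wrap_coord(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;  // guard against floor rounding at the boundary
  return w;
}

// Smallest gap (center distance minus contact distance) over all pairs.
// Negative values signal an overlap.
// [[Rcpp::export]]
double cpp_min_gap(NumericMatrix pos, NumericVector radii, double L) {
  int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(i, 0) - pos(j, 0), L);
      double dy = min_image(pos(i, 1) - pos(j, 1), L);
      double dz = min_image(pos(i, 2) - pos(j, 2), L);
      double gap = std::sqrt(dx * dx + dy * dy + dz * dz) - (radii[i] + radii[j]);
      if (gap < best) best = gap;
    }
  }
  return best;
}

// One Heyes-Melrose style correction sweep: every overlapping pair is moved
// apart along the center line exactly to contact, split in proportion to the
// per-particle weights (mobility-proportional for unequal particles).
// Returns the number of overlaps corrected; accumulates corrections in disp.
static int hm_sweep(NumericMatrix& pos, const NumericVector& radii,
                    const NumericVector& w, double L, NumericMatrix& disp) {
  int n = pos.nrow(), n_over = 0;
  const double rel_tol = 1e-12;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(i, 0) - pos(j, 0), L);
      double dy = min_image(pos(i, 1) - pos(j, 1), L);
      double dz = min_image(pos(i, 2) - pos(j, 2), L);
      double s = radii[i] + radii[j];
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dist >= s * (1.0 - rel_tol)) continue;
      ++n_over;
      double ux, uy, uz;
      if (dist < 1e-12) { ux = 1.0; uy = 0.0; uz = 0.0; dist = 0.0; }
      else { ux = dx / dist; uy = dy / dist; uz = dz / dist; }
      double push = s - dist;
      double wi = w[i] / (w[i] + w[j]);
      double wj = 1.0 - wi;
      double mi = wi * push, mj = wj * push;
      pos(i, 0) += ux * mi; pos(i, 1) += uy * mi; pos(i, 2) += uz * mi;
      pos(j, 0) -= ux * mj; pos(j, 1) -= uy * mj; pos(j, 2) -= uz * mj;
      disp(i, 0) += ux * mi; disp(i, 1) += uy * mi; disp(i, 2) += uz * mi;
      disp(j, 0) -= ux * mj; disp(j, 1) -= uy * mj; disp(j, 2) -= uz * mj;
    }
  }
  return n_over;
}

// [[Rcpp::export]]
List cpp_resolve_overlaps(NumericMatrix positions, NumericVector radii,
                          NumericVector weights, double L, int max_sweeps) {
  NumericMatrix pos = clone(positions);
  int n = pos.nrow();
  NumericMatrix disp(n, 3);
  int sweeps = 0;
  bool converged = false;
  for (int s = 0; s < max_sweeps; ++s) {
    int n_over = hm_sweep(pos, radii, weights, L, disp);
    ++sweeps;
    if (n_over == 0) { converged = true; sweeps = s; break; }
  }
  // A final clean check when the cap was hit on a correcting sweep.
  if (!converged && cpp_min_gap(pos, radii, L) >= -1e-12) converged = true;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) = wrap_coord(pos(i, k), L);
  return List::create(_["positions"] = pos, _["displacements"] = disp,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}

// Forward-Euler Brownian propagation of hard spheres with post-step overlap
// correction. Uses R's RNG so results are reproducible under set.seed().
// Frames (unwrapped positions) are sampled every `sample_every` steps,
// always including step 0.
// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix positions, NumericVector radii, NumericVector d0,
                double L, double dt, int n_steps, int sample_every,
                int max_sweeps) {
  int n = positions.nrow();
  NumericMatrix pos = clone(positions);   // wrapped
  NumericMatrix unw = clone(positions);   // unwrapped tracker
  int n_frames = 1 + n_steps / sample_every;
  NumericVector frames(Dimension(n_frames, n, 3));
  IntegerVector frame_steps(n_frames);
  NumericVector sigma(n);
  for (int i = 0; i < n; ++i) sigma[i] = std::sqrt(2.0 * d0[i] * dt);

  int f = 0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) frames[f + n_frames * (i + n * k)] = unw(i, k);
  frame_steps[0] = 0;
  ++f;

  NumericMatrix disp(n, 3);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        double dxi = sigma[i] * norm_rand();
        pos(i, k) = wrap_coord(pos(i, k) + dxi, L);
        unw(i, k) += dxi;
      }
    }
    std::fill(disp.begin(), disp.end(), 0.0);
    bool ok = false;
    for (int s = 0; s < max_sweeps; ++s) {
      if (hm_sweep(pos, radii, d0, L, disp) == 0) { ok = true; break; }
    }
    if (!ok && cpp_min_gap(pos, radii, L) < -1e-12)
      stop("overlap resolution did not converge at step %d; reduce dt or phi_occ",
           step);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k) {
        pos(i, k) = wrap_coord(pos(i, k), L);
        unw(i, k) += disp(i, k);
      }
    }
    if (step % sample_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[f + n_frames * (i + n * k)] = unw(i, k);
      frame_steps[f] = step;
      ++f;
    }
  }
  frames.attr("dim") = Dimension(n_frames, n, 3);
  return List::create(_["unwrapped"] = frames, _["frame_steps"] = frame_steps,
                      _["final_wrapped"] = pos);
}

// Random sequential addition of spheres (caller sorts largest-first).
// Returns positions, or stops naming the failing particle index (1-based).
// [[Rcpp::export]]
List cpp_rsa(NumericVector radii, double L, int max_attempts) {
  int n = radii.size();
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int a = 0; a < max_attempts; ++a) {
      double x = unif_rand() * L, y = unif_rand() * L, z = unif_rand() * L;
      bool clash = false;
      for (int j = 0; j < i; ++j) {
        double dx = min_image(x - pos(j, 0), L);
        double dy = min_image(y - pos(j, 1), L);
        double dz = min_image(z - pos(j, 2), L);
        double s = radii[i] + radii[j];
        if (dx * dx + dy * dy + dz * dz < s * s) { clash = true; break; }
      }
      if (!clash) {
        pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
        placed = true;
        break;
      }
    }
    if (!placed)
      return List::create(_["ok"] = false, _["failed_at"] = i + 1,
                          _["positions"] = R_NilValue);
  }
  return List::create(_["ok"] = true, _["failed_at"] = 0, _["positions"] = pos);
}

// Stepwise box compression with overlap sweeps: used when direct random
// insertion is infeasible (dense packings). Shrinks the box by `factor`
// per stage until edge `L_target`, rescaling centers and relaxing overlaps.
// [[Rcpp::export]]
List cpp_compress(NumericMatrix positions, NumericVector radii,
                  NumericVector weights, double L_start, double L_target,
                  double factor, int max_sweeps) {
  NumericMatrix pos = clone(positions);
  int n = pos.nrow();
  NumericMatrix disp(n, 3);
  double L = L_start;
  while (L > L_target) {
    double Lnew = std::max(L * factor, L_target);
    double scale = Lnew / L;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) pos(i, k) *= scale;
    L = Lnew;
    bool ok = false;
    for (int s = 0; s < max_sweeps; ++s) {
      if (hm_sweep(pos, radii, weights, L, disp) == 0) { ok = true; break; }
    }
    if (!ok && cpp_min_gap(pos, radii, L) < -1e-12)
      return List::create(_["ok"] = false, _["L"] = L,
                          _["positions"] = R_NilValue);
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) = wrap_coord(pos(i, k), L);
  return List::create(_["ok"] = true, _["L"] = L, _["positions"] = pos);
}

// Widom-style insertion: fraction of uniformly random tracer placements that
// overlap any crowder (minimum image).
// [[Rcpp::export]]
double cpp_phi_ex(NumericMatrix pos, NumericVector radii, double L,
                  double r_tracer, int n_insertions) {
  int n = pos.nrow();
  long hits = 0;
  for (int t = 0; t < n_insertions; ++t) {
    double x = unif_rand() * L, y = unif_rand() * L, z = unif_rand() * L;
    for (int j = 0; j < n; ++j) {
      double dx = min_image(x - pos(j, 0), L);
      double dy = min_image(y - pos(j, 1), L);
      double dz = min_image(z - pos(j, 2), L);
      double s = radii[j] + r_tracer;
      if (dx * dx + dy * dy + dz * dz < s * s) { ++hits; break; }
    }
  }
  return (double)hits / (double)n_insertions;
}

// Time- and particle-averaged MSD over all frame pairs at each lag.
// unwrapped: array (n_frames x n_particles x 3) of unwrapped coordinates.
// Returns total MSD per lag, pair counts, and the per-particle MSD matrix
// (lags x particles) for block uncertainty estimates.
// [[Rcpp::export]]
List cpp_msd(NumericVector unwrapped, IntegerVector lags) {
  IntegerVector dims = unwrapped.attr("dim");
  int F = dims[0], N = dims[1];
  int nl = lags.size();
  NumericVector msd(nl);
  IntegerVector n_pairs(nl);
  NumericMatrix per_particle(nl, N);
  for (int li = 0; li < nl; ++li) {
    int lag = lags[li];
    int npair = F - lag;
    if (npair <= 0) stop("lag exceeds trajectory length");
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      for (int t = 0; t < npair; ++t) {
        double sq = 0.0;
        for (int k = 0; k < 3; ++k) {
          int base = F * (i + N * k);
          double d = unwrapped[(t + lag) + base] - unwrapped[t + base];
          sq += d * d;
        }
        acc += sq;
      }
      per_particle(li, i) = acc / npair;
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) tot += per_particle(li, i);
    msd[li] = tot / N;
    n_pairs[li] = npair * N;
  }
  return List::create(_["msd"] = msd, _["n_pairs"] = n_pairs,
                      _["per_particle"] = per_particle);
}
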