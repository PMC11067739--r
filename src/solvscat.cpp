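// Compiled kernels: minimum-image pair statistics, Debye sums, histogram
// intensity synthesis, fused-sphere grid volumes and the hard-sphere
// Metropolis sampler.  All randomness uses R's RNG (seeded from R).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

static inline double pair_dist(const NumericMatrix& xyz, int i, int j,
                               const double* cell) {
  double dx = xyz(i, 0) - xyz(j, 0);
  double dy = xyz(i, 1) - xyz(j, 1);
  double dz = xyz(i, 2) - xyz(j, 2);
  if (cell) {
    dx = min_image(dx, cell[0]);
    dy = min_image(dy, cell[1]);
    dz = min_image(dz, cell[2]);
  }
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Element-pair-resolved distance histogram between two atom selections.
// Each unordered pair is accumulated once (i<j when same_set, every (i,j)
// once otherwise; the sets must be disjoint in the cross case).  Per bin we
// keep the count, the sum of distances and the sum of squared distances so
// that intensities can be evaluated at the within-bin mean with a
// second-moment damping.  Coincident pairs (r < 1e-9) are tallied apart.
// [[Rcpp::export]]
List cpp_pair_stats(NumericMatrix xyz, IntegerVector elem,
                    IntegerVector selA, IntegerVector selB, bool same_set,
                    NumericVector cell, double bin_width, double r_max,
                    int n_elem) {
  const int nbins = (int)std::ceil(r_max / bin_width);
  const bool periodic = cell.size() == 3;
  const double* cl = periodic ? REAL(cell) : nullptr;
  NumericVector counts(nbins * n_elem * n_elem);
  NumericVector sumr(nbins * n_elem * n_elem);
  NumericVector sumr2(nbins * n_elem * n_elem);
  NumericMatrix overlap(n_elem, n_elem);
  const int nA = selA.size(), nB = selB.size();
  for (int a = 0; a < nA; ++a) {
    const int i = selA[a];
    const int ei = elem[i];
    const int bstart = same_set ? a + 1 : 0;
    for (int b = bstart; b < nB; ++b) {
      const int j = selB[b];
      const double d = pair_dist(xyz, i, j, cl);
      int e1 = ei, e2 = elem[j];
      if (e1 > e2) std::swap(e1, e2);
      if (d < 1e-9) {
        overlap(e1, e2) += 1.0;
        continue;
      }
      if (d >= r_max) continue;
      const int bin = (int)(d / bin_width);
      const int idx = bin + nbins * (e1 + n_elem * e2);
      counts[idx] += 1.0;
      sumr[idx] += d;
      sumr2[idx] += d * d;
    }
  }
  counts.attr("dim") = IntegerVector::create(nbins, n_elem, n_elem);
  sumr.attr("dim") = IntegerVector::create(nbins, n_elem, n_elem);
  sumr2.attr("dim") = IntegerVector::create(nbins, n_elem, n_elem);
  return List::create(_["counts"] = counts, _["sumr"] = sumr,
                      _["sumr2"] = sumr2, _["overlap"] = overlap,
                      _["nbins"] = nbins);
}

// Synthesize the unordered-pair interference sum
//   S(Q) = sum_bins n_b f_e(Q) f_e'(Q) sinc(Q r_b) exp(-Q^2 s2_b / 2)
// from the histogram moments; r_b is the within-bin mean distance and s2_b
// the within-bin variance (a Debye-Waller-like smearing correction for the
// finite bin width).  fmat is nq x n_elem.
// [[Rcpp::export]]
NumericVector cpp_hist_intensity(NumericVector counts, NumericVector sumr,
                                 NumericVector sumr2, NumericMatrix overlap,
                                 NumericMatrix fmat, NumericVector q) {
  IntegerVector dim = counts.attr("dim");
  const int nbins = dim[0], K = dim[1];
  const int nq = q.size();
  NumericVector out(nq);
  for (int e1 = 0; e1 < K; ++e1) {
    for (int e2 = e1; e2 < K; ++e2) {
      const double ov = overlap(e1, e2);
      bool any = ov > 0;
      const int base = nbins * (e1 + K * e2);
      if (!any) {
        for (int b = 0; b < nbins; ++b)
          if (counts[base + b] > 0) { any = true; break; }
      }
      if (!any) continue;
      for (int iq = 0; iq < nq; ++iq) {
        const double Q = q[iq];
        const double ff = fmat(iq, e1) * fmat(iq, e2);
        double acc = ov;  // sinc -> 1 for coincident pairs
        for (int b = 0; b < nbins; ++b) {
          const double n = counts[base + b];
          if (n <= 0) continue;
          const double rb = sumr[base + b] / n;
          double s2 = sumr2[base + b] / n - rb * rb;
          if (s2 < 0) s2 = 0;
          const double x = Q * rb;
          const double snc = (x < 1e-8) ? 1.0 : std::sin(x) / x;
          acc += n * snc * std::exp(-0.5 * Q * Q * s2);
        }
        out[iq] += ff * acc;
      }
    }
  }
  return out;
}

// Brute-force Debye double sum over a set pair.  same_set: accumulates
// 2*sum_{i<j} (plus the self term if include_self); cross: each ordered
// (i in A, j in B) pair once.  r_max < 0 disables the distance cutoff.
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix xyz, IntegerVector elem,
                              IntegerVector selA, IntegerVector selB,
                              bool same_set, NumericVector cell,
                              double r_max, NumericMatrix fmat,
                              NumericVector q, bool include_self) {
  const bool periodic = cell.size() == 3;
  const double* cl = periodic ? REAL(cell) : nullptr;
  const int nq = q.size();
  NumericVector out(nq);
  const int nA = selA.size(), nB = selB.size();
  const double wt = same_set ? 2.0 : 1.0;
  for (int a = 0; a < nA; ++a) {
    const int i = selA[a];
    const int ei = elem[i];
    const int bstart = same_set ? a + 1 : 0;
    for (int b = bstart; b < nB; ++b) {
      const int j = selB[b];
      const double d = pair_dist(xyz, i, j, cl);
      if (r_max > 0 && d >= r_max) continue;
      const int ej = elem[j];
      if (d < 1e-9) {
        for (int iq = 0; iq < nq; ++iq)
          out[iq] += wt * fmat(iq, ei) * fmat(iq, ej);
        continue;
      }
      for (int iq = 0; iq < nq; ++iq) {
        const double x = q[iq] * d;
        const double snc = (x < 1e-8) ? 1.0 : std::sin(x) / x;
        out[iq] += wt * fmat(iq, ei) * fmat(iq, ej) * snc;
      }
    }
  }
  if (same_set && include_self) {
    for (int a = 0; a < nA; ++a) {
      const int ei = elem[selA[a]];
      for (int iq = 0; iq < nq; ++iq) out[iq] += fmat(iq, ei) * fmat(iq, ei);
    }
  }
  return out;
}

// Metropolis sweeps for hard spheres in a cubic periodic box; coords are
// modified copies wrapped to [0, L).  Returns the final configuration and
// the move acceptance rate.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_mc_hs(NumericMatrix start, double L, double sigma, double max_disp,
               int n_sweeps) {
  RNGScope scope;
  NumericMatrix xyz = clone(start);
  const int n = xyz.nrow();
  const double sig2 = sigma * sigma;
  long accepted = 0, attempted = 0;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double nx = xyz(i, 0) + (unif_rand() * 2.0 - 1.0) * max_disp;
      double ny = xyz(i, 1) + (unif_rand() * 2.0 - 1.0) * max_disp;
      double nz = xyz(i, 2) + (unif_rand() * 2.0 - 1.0) * max_disp;
      nx -= L * std::floor(nx / L);
      ny -= L * std::floor(ny / L);
      nz -= L * std::floor(nz / L);
      ++attempted;
      bool ok = true;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = min_image(nx - xyz(j, 0), L);
        const double dy = min_image(ny - xyz(j, 1), L);
        const double dz = min_image(nz - xyz(j, 2), L);
        if (dx * dx + dy * dy + dz * dz < sig2) { ok = false; break; }
      }
      if (ok) {
        xyz(i, 0) = nx; xyz(i, 1) = ny; xyz(i, 2) = nz;
        ++accepted;
      }
    }
  }
  return List::create(_["coords"] = xyz,
                      _["acceptance"] = (double)accepted / (double)attempted);
}

// Fused-sphere volume by counting grid-cell centres inside the union.
// [[Rcpp::export]]
double cpp_grid_volume(NumericMatrix centers, NumericVector radii, double h) {
  const int n = centers.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], centers(i, k) - radii[i]);
      hi[k] = std::max(hi[k], centers(i, k) + radii[i]);
    }
  for (int k = 0; k < 3; ++k) { lo[k] -= h; hi[k] += h; }
  long count = 0;
  for (double z = lo[2]; z < hi[2]; z += h) {
    for (double y = lo[1]; y < hi[1]; y += h) {
      for (double x = lo[0]; x < hi[0]; x += h) {
        for (int i = 0; i < n; ++i) {
          const double dx = x - centers(i, 0);
          const double dy = y - centers(i, 1);
          const double dz = z - centers(i, 2);
          if (dx * dx + dy * dy + dz * dz <= radii[i] * radii[i]) {
            ++count;
            break;
          }
        }
      }
    }
  }
  return (double)count * h * h * h;
}
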