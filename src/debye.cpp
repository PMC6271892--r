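#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Debye sum over point scatterers:
//   I(q) = sum_i sum_j w_i w_j sin(q r_ij) / (q r_ij)
// Self terms contribute w_i^2 (sinc(0) = 1).  Pairs outer, q inner, so each
// pairwise distance is computed once.  Positions in Angstrom, q in 1/Angstrom.
// [[Rcpp::export]]
NumericVector debye_sum_cpp(NumericMatrix pos, NumericVector w, NumericVector q) {
  const int n = pos.nrow();
  const int nq = q.size();
  NumericVector out(nq);
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += w[i] * w[i];
  for (int k = 0; k < nq; ++k) out[k] = self;
  for (int i = 0; i < n; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2), wi = w[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - pos(j, 0);
      const double dy = yi - pos(j, 1);
      const double dz = zi - pos(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ww2 = 2.0 * wi * w[j];
      if (r == 0.0) {
        for (int k = 0; k < nq; ++k) out[k] += ww2;
      } else {
        for (int k = 0; k < nq; ++k) {
          const double x = q[k] * r;
          out[k] += ww2 * std::sin(x) / x;
        }
      }
    }
  }
  return out;
}

// Weighted histogram of all n(n-1)/2 pairwise distances.  Bin k covers
// [k*dr, (k+1)*dr); weight of a pair is w_i * w_j.  Returns the counts and
// the maximum pairwise distance.
// [[Rcpp::export]]
List pair_hist_cpp(NumericMatrix pos, NumericVector w, double dr, int nbins) {
  const int n = pos.nrow();
  NumericVector counts(nbins);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2), wi = w[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - pos(j, 0);
      const double dy = yi - pos(j, 1);
      const double dz = zi - pos(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r > dmax) dmax = r;
      int k = (int)(r / dr);
      if (k >= 0 && k < nbins) counts[k] += wi * w[j];
    }
  }
  return List::create(Named("counts") = counts, Named("dmax") = dmax);
}

// Minimum distance from each row of A to any row of B (no periodicity).
// Early exit once a distance below `cutoff` is found; used for clash checks.
// [[Rcpp::export]]
double min_cross_dist_cpp(NumericMatrix A, NumericMatrix B, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  double best = R_PosInf;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < na; ++i) {
    const double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - B(j, 0);
      const double dy = yi - B(j, 1);
      const double dz = zi - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best < c2) return std::sqrt(best);
      }
    }
  }
  return std::sqrt(best);
}

// Histogram of reference-target distances for g(r), with optional
// minimum-image convention in an orthorhombic box (box = c(lx, ly, lz)).
// [[Rcpp::export]]
NumericVector rdf_hist_cpp(NumericMatrix ref, NumericMatrix tgt,
                           double dr, int nbins, NumericVector box) {
  const int nr = ref.nrow(), nt = tgt.nrow();
  const bool periodic = box.size() == 3;
  NumericVector counts(nbins);
  for (int i = 0; i < nr; ++i) {
    const double xi = ref(i, 0), yi = ref(i, 1), zi = ref(i, 2);
    for (int j = 0; j < nt; ++j) {
      double dx = xi - tgt(j, 0);
      double dy = yi - tgt(j, 1);
      double dz = zi - tgt(j, 2);
      if (periodic) {
        dx -= box[0] * std::round(dx / box[0]);
        dy -= box[1] * std::round(dy / box[1]);
        dz -= box[2] * std::round(dz / box[2]);
      }
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int k = (int)(r / dr);
      if (k >= 0 && k < nbins) counts[k] += 1.0;
    }
  }
  return counts;
}
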