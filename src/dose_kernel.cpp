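#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate analytic pencil-beam spots into a dose array.
//
// `wp` holds the water-equivalent depth of every voxel, permuted so the
// beam-depth axis is first: layout [nd, n1, n2] column-major.  `u`, `v`
// are the voxel-center coordinates (mm, ascending) of the two lateral
// axes.  `spots` has one row per spot: u, v, range, sigma, weight.  The
// depth dose is the two-piece plateau/Gaussian pristine peak; the
// lateral kernel is a normalized 2D Gaussian truncated at
// `cutoff * sigma`.
// [[Rcpp::export]]
NumericVector cpp_accumulate_spots(const NumericVector& wp,
                                   const IntegerVector& dims,
                                   const NumericVector& u,
                                   const NumericVector& v,
                                   const NumericMatrix& spots,
                                   double plateau, double sigma_p,
                                   double sigma_d, double cutoff) {
  const int nd = dims[0], n1 = dims[1];
  NumericVector dose(wp.size());
  const double inv2sp2 = 1.0 / (2.0 * sigma_p * sigma_p);
  const double inv2sd2 = 1.0 / (2.0 * sigma_d * sigma_d);
  const double one_m_p = 1.0 - plateau;
  const double inv_sqrt2pi = 0.3989422804014327;

  for (int s = 0; s < spots.nrow(); ++s) {
    const double su = spots(s, 0), sv = spots(s, 1);
    const double R = spots(s, 2), sg = spots(s, 3), wgt = spots(s, 4);
    if (wgt == 0.0) continue;
    const double half = cutoff * sg;
    const double gnorm = inv_sqrt2pi / sg;
    const double inv2sg2 = 1.0 / (2.0 * sg * sg);

    int i1lo = std::lower_bound(u.begin(), u.end(), su - half) - u.begin();
    int i1hi = std::upper_bound(u.begin(), u.end(), su + half) - u.begin();
    int i2lo = std::lower_bound(v.begin(), v.end(), sv - half) - v.begin();
    int i2hi = std::upper_bound(v.begin(), v.end(), sv + half) - v.begin();
    if (i1lo >= i1hi || i2lo >= i2hi) continue;

    std::vector<double> g1(i1hi - i1lo), g2(i2hi - i2lo);
    for (int i = i1lo; i < i1hi; ++i) {
      const double d = u[i] - su;
      g1[i - i1lo] = gnorm * std::exp(-d * d * inv2sg2);
    }
    for (int j = i2lo; j < i2hi; ++j) {
      const double d = v[j] - sv;
      g2[j - i2lo] = gnorm * std::exp(-d * d * inv2sg2);
    }

    for (int j = i2lo; j < i2hi; ++j) {
      const double wg2 = wgt * g2[j - i2lo];
      for (int i = i1lo; i < i1hi; ++i) {
        const double lat = wg2 * g1[i - i1lo];
        const double* wcol = &wp[(size_t)nd * (i + (size_t)n1 * j)];
        double* dcol = &dose[(size_t)nd * (i + (size_t)n1 * j)];
        for (int k = 0; k < nd; ++k) {
          const double dw = wcol[k] - R;
          const double depth_dose = (dw <= 0.0)
            ? plateau + one_m_p * std::exp(-dw * dw * inv2sp2)
            : std::exp(-dw * dw * inv2sd2);
          dcol[k] += lat * depth_dose;
        }
      }
    }
  }
  dose.attr("dim") = dims;
  return dose;
}

// Influence matrix for spot-weight optimization: dose per unit weight of
// each spot at a set of sample points.  `w` is the WEPL at each point,
// `pu`/`pv` its lateral coordinates; spot columns as above.
// [[Rcpp::export]]
NumericMatrix cpp_spot_influence(const NumericVector& w,
                                 const NumericVector& pu,
                                 const NumericVector& pv,
                                 const NumericMatrix& spots,
                                 double plateau, double sigma_p,
                                 double sigma_d) {
  const int n = w.size(), m = spots.nrow();
  NumericMatrix A(n, m);
  const double inv2sp2 = 1.0 / (2.0 * sigma_p * sigma_p);
  const double inv2sd2 = 1.0 / (2.0 * sigma_d * sigma_d);
  const double one_m_p = 1.0 - plateau;
  const double inv_sqrt2pi = 0.3989422804014327;
  for (int s = 0; s < m; ++s) {
    const double su = spots(s, 0), sv = spots(s, 1);
    const double R = spots(s, 2), sg = spots(s, 3);
    const double gnorm2 = inv_sqrt2pi * inv_sqrt2pi / (sg * sg);
    const double inv2sg2 = 1.0 / (2.0 * sg * sg);
    for (int i = 0; i < n; ++i) {
      const double du = pu[i] - su, dv = pv[i] - sv;
      const double g = gnorm2 * std::exp(-(du * du + dv * dv) * inv2sg2);
      const double dw = w[i] - R;
      const double depth_dose = (dw <= 0.0)
        ? plateau + one_m_p * std::exp(-dw * dw * inv2sp2)
        : std::exp(-dw * dw * inv2sd2);
      A(i, s) = g * depth_dose;
    }
  }
  return A;
}
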