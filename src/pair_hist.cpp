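#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image pair-distance histogram for one frame.
//
// Distances are binned as floor(d / dr) for d < r_max (half-open bins
// [i*dr, (i+1)*dr)).  The minimum-image convention maps each displacement
// component into [-box/2, +box/2), resolving a component exactly on the
// boundary to the negative image via floor(x/box + 0.5).  The arithmetic
// (subtract, floor-shift, square, sqrt) mirrors the plain-R reference
// implementation operation for operation so the two routes agree bit-exactly.
//
// center_ids / target_ids carry global atom indices; a pair with equal ids
// (the same atom appearing in both selections) is skipped.
// box <= 0 disables periodicity.
// [[Rcpp::export]]
NumericVector pair_hist_frame(NumericMatrix centers, NumericMatrix targets,
                              IntegerVector center_ids, IntegerVector target_ids,
                              double box, double r_max, double dr) {
  const int nc = centers.nrow(), nt = targets.nrow();
  const int nbins = (int)std::ceil(r_max / dr);
  NumericVector counts(nbins);
  const bool periodic = box > 0.0;
  for (int i = 0; i < nc; ++i) {
    const double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    const int ci = center_ids[i];
    for (int j = 0; j < nt; ++j) {
      if (target_ids[j] == ci) continue;
      double dx = targets(j, 0) - cx;
      double dy = targets(j, 1) - cy;
      double dz = targets(j, 2) - cz;
      if (periodic) {
        dx -= box * std::floor(dx / box + 0.5);
        dy -= box * std::floor(dy / box + 0.5);
        dz -= box * std::floor(dz / box + 0.5);
      }
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < r_max) counts[(int)std::floor(d / dr)] += 1.0;
    }
  }
  return counts;
}
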