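#include <Rcpp.h>
using namespace Rcpp;

// One trial of the trial-swap chain: draw two distinct rows (sites) and two
// distinct columns (species) uniformly; if the 2x2 submatrix is a perfect
// checkerboard (10/01 or 01/10), swap its state. Uses R's RNG so chains are
// reproducible under set.seed().
//
// n_steps counts trials by default; with count_swaps = true it counts
// successful swaps instead (guarded against matrices admitting no swap).

// [[Rcpp::export]]
IntegerMatrix trial_swap_cpp(IntegerMatrix m0, double n_steps, bool count_swaps) {
  IntegerMatrix m = clone(m0);
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) stop("need at least a 2 x 2 matrix");
  double done = 0.0, trials = 0.0;
  const double guard = count_swaps ? 1e4 * n_steps + 1e7 : n_steps;
  while (done < n_steps) {
    int r1 = (int)(unif_rand() * nr); if (r1 == nr) --r1;
    int r2 = (int)(unif_rand() * (nr - 1)); if (r2 == nr - 1) --r2;
    if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc); if (c1 == nc) --c1;
    int c2 = (int)(unif_rand() * (nc - 1)); if (c2 == nc - 1) --c2;
    if (c2 >= c1) ++c2;
    const int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    const bool cb = (a == 1 && d == 1 && b == 0 && c == 0) ||
                    (a == 0 && d == 0 && b == 1 && c == 1);
    if (cb) {
      m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
      m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
    }
    ++trials;
    done += count_swaps ? (cb ? 1.0 : 0.0) : 1.0;
    if (trials >= guard) {
      if (count_swaps && done < n_steps)
        warning("swap budget not reached within trial guard; matrix may admit no swap");
      break;
    }
  }
  return m;
}
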