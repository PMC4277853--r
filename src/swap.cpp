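#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard swap chain on a binary matrix. Each attempt draws two
// distinct rows and two distinct columns with R's RNG; if the 2x2 submatrix
// is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) it is flipped. Row and
// column sums are invariant by construction. The matrix is modified through
// a copy; the number of accepted swaps is returned via attribute "accepted".
// [[Rcpp::export]]
IntegerMatrix swap_chain(IntegerMatrix m, int attempts) {
  IntegerMatrix x = clone(m);
  int nr = x.nrow(), nc = x.ncol();
  if (nr < 2 || nc < 2) stop("swap chain needs >= 2 rows and >= 2 columns");
  int accepted = 0;
  for (int t = 0; t < attempts; ++t) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) ++r2;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) ++c2;
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    if ((a == 1 && d == 1 && b == 0 && c == 0) ||
        (a == 0 && d == 0 && b == 1 && c == 1)) {
      x(r1, c1) = 1 - a;
      x(r1, c2) = 1 - b;
      x(r2, c1) = 1 - c;
      x(r2, c2) = 1 - d;
      ++accepted;
    }
  }
  x.attr("accepted") = accepted;
  return x;
}

// Exhaustive scan for the existence of any swappable checkerboard.
// [[Rcpp::export]]
bool has_checkerboard(IntegerMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  for (int r1 = 0; r1 < nr - 1; ++r1) {
    for (int r2 = r1 + 1; r2 < nr; ++r2) {
      bool has10 = false, has01 = false;
      for (int c = 0; c < nc; ++c) {
        int a = x(r1, c), b = x(r2, c);
        if (a == 1 && b == 0) has10 = true;
        else if (a == 0 && b == 1) has01 = true;
        if (has10 && has01) return true;
      }
    }
  }
  return false;
}
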