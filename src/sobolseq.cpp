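#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Sobol' low-discrepancy sequence via the Gray-code construction.
// Direction numbers are supplied from R (primitive polynomials and initial
// values from the published Joe & Kuo tables).  An optional per-dimension
// digital shift (XOR mask) randomizes the sequence while preserving its
// net structure.
// [[Rcpp::export(name = ".sobol_points_cpp")]]
NumericMatrix sobol_points_cpp(int n, List minit, IntegerVector poly,
                               IntegerVector shift) {
  const int nbits = 31;
  int d = poly.size();
  if (d > minit.size()) stop("not enough direction-number sets");
  NumericMatrix out(n, d);
  const double scale = 1.0 / (1u << nbits) / 2.0 * 2.0;  // 2^-31
  for (int j = 0; j < d; ++j) {
    unsigned int p = (unsigned int)poly[j];
    int s = 0;
    while ((1u << (s + 1)) <= p) ++s;  // degree of the polynomial
    IntegerVector mj = minit[j];
    std::vector<unsigned int> v(nbits + 1);
    if (s == 0) {  // first dimension: van der Corput
      for (int k = 1; k <= nbits; ++k) v[k] = 1u << (nbits - k);
    } else {
      for (int k = 1; k <= s && k <= nbits; ++k)
        v[k] = ((unsigned int)mj[k - 1]) << (nbits - k);
      // interior polynomial coefficients a_1..a_{s-1}
      unsigned int a = (p >> 1) ^ (1u << (s - 1));
      for (int k = s + 1; k <= nbits; ++k) {
        v[k] = v[k - s] ^ (v[k - s] >> s);
        for (int i = 1; i < s; ++i)
          if ((a >> (s - 1 - i)) & 1u) v[k] ^= v[k - i];
      }
    }
    unsigned int x = (unsigned int)shift[j];
    out(0, j) = x * scale;
    for (int i = 1; i < n; ++i) {
      // index of the lowest zero bit of i-1 (Gray-code update)
      unsigned int ii = (unsigned int)(i - 1);
      int c = 1;
      while (ii & 1u) { ii >>= 1; ++c; }
      x ^= v[c];
      out(i - 1 + 1, j) = x * scale;
    }
  }
  return out;
}
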