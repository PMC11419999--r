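// Non-local means: each output pixel is the weighted average of pixels in a
// square search window (clipped to the image), weights
// exp(-||v_p - v_q||^2 / h^2) on the squared Euclidean distance between the
// surrounding patches. Patches at borders use reflective padding.
#include <Rcpp.h>
using namespace Rcpp;

static inline int refl(int i, int n) {
  // reflect index into [0, n-1] (edge-mirrored)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix nlm_cpp(NumericMatrix img, double h, int patch_radius,
                      int search_radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch_radius, sr = search_radius;
  NumericMatrix out(nr, nc);
  const double h2 = h * h;

  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double acc = 0, wsum = 0;
      int qj0 = std::max(0, j - sr), qj1 = std::min(nc - 1, j + sr);
      int qi0 = std::max(0, i - sr), qi1 = std::min(nr - 1, i + sr);
      for (int qj = qj0; qj <= qj1; qj++) {
        for (int qi = qi0; qi <= qi1; qi++) {
          double d2 = 0;
          for (int pj = -pr; pj <= pr; pj++) {
            for (int pi = -pr; pi <= pr; pi++) {
              double a = img(refl(i + pi, nr), refl(j + pj, nc));
              double b = img(refl(qi + pi, nr), refl(qj + pj, nc));
              d2 += (a - b) * (a - b);
            }
          }
          double w = std::exp(-d2 / h2);
          acc += w * img(qi, qj);
          wsum += w;
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
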