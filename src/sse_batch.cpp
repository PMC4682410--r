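#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of squared residuals of a batch of peak-model parameter rows
// against observed (m, y) points. Parameter rows use the canonical
// order (H, alpha, sigma1[, sigma2[, beta1, beta2]]).
// model: 0 = mAPV, 1 = Gaussian, 2 = Lorentz, 3 = Bi-Gaussian.
// [[Rcpp::export]]
NumericVector sse_batch_cpp(NumericMatrix Theta, NumericVector m,
                            NumericVector y, int model) {
  const int n = Theta.nrow();
  const int np = m.size();
  const double ln2 = std::log(2.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double H = Theta(i, 0), alpha = Theta(i, 1);
    const double s1 = Theta(i, 2);
    const double s2 = (model == 0 || model == 3) ? Theta(i, 3) : s1;
    const double b1 = (model == 0) ? Theta(i, 4) : 0.0;
    const double b2 = (model == 0) ? Theta(i, 5) : 0.0;
    double acc = 0.0;
    for (int j = 0; j < np; ++j) {
      const double d = m[j] - alpha;
      const bool left = d < 0.0;
      const double sig = left ? s1 : s2;
      const double z2 = (d / sig) * (d / sig);
      double v;
      switch (model) {
      case 2:  // Lorentz
        v = 1.0 / (1.0 + z2);
        break;
      case 1:  // Gaussian
      case 3:  // Bi-Gaussian
        v = std::exp(-ln2 * z2);
        break;
      default: {  // mAPV
        const double b = left ? b1 : b2;
        v = b / (1.0 + z2) + (1.0 - b) * std::exp(-ln2 * z2);
      }
      }
      const double r = H * v - y[j];
      acc += r * r;
    }
    out[i] = acc;
  }
  return out;
}
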