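// Fast chunk generator for the Monte-Carlo engine. Draws in exactly the
// same order as the R reference generator (.simulate_matrices): genotype,
// treatment, age, eps0, eps1, each as one column-major block — so for the
// same RNG state the two paths produce bit-identical cohorts.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_chunk(int n, int B, double maf, double treatment_prob,
                        double age_lo, double age_hi, double intercept,
                        double beta_G0, double beta_y0, double beta_G,
                        double beta_GT, double beta_T, double beta_X,
                        double sd_eps0, double sd_eps1, double floor_at) {
  const R_xlen_t N = (R_xlen_t)n * B;
  NumericMatrix g(n, B), trt(n, B), age(n, B), y0(n, B), y1(n, B);
  double* pg = g.begin();
  double* pt = trt.begin();
  double* pa = age.begin();
  double* p0 = y0.begin();
  double* p1 = y1.begin();

  for (R_xlen_t i = 0; i < N; ++i) pg[i] = R::rbinom(2.0, maf);
  for (R_xlen_t i = 0; i < N; ++i) pt[i] = R::rbinom(1.0, treatment_prob);
  for (R_xlen_t i = 0; i < N; ++i) pa[i] = R::runif(age_lo, age_hi);
  for (R_xlen_t i = 0; i < N; ++i) p0[i] = R::rnorm(0.0, sd_eps0);  // eps0
  for (R_xlen_t i = 0; i < N; ++i) p1[i] = R::rnorm(0.0, sd_eps1);  // eps1

  for (R_xlen_t i = 0; i < N; ++i) {
    double ly0 = intercept + beta_G0 * pg[i] + p0[i];
    double cfb = beta_T * pt[i] + beta_X * pa[i] + beta_y0 * ly0 +
                 beta_G * pg[i] + beta_GT * pg[i] * pt[i] + p1[i];
    double v0 = std::exp(ly0);
    double v1 = std::exp(ly0 + cfb);
    p0[i] = v0 < floor_at ? floor_at : v0;
    p1[i] = v1 < floor_at ? floor_at : v1;
  }
  return List::create(_["y0"] = y0, _["y1"] = y1, _["treatment"] = trt,
                      _["age"] = age, _["genotype"] = g);
}
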