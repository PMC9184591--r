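// Vectorized per-replicate fitting used by the Monte-Carlo engine.
// One column of the input matrices = one simulated cohort; each model's
// "primary" p-value (p_2df for the 2df models, Cochran's Q p for Q, the
// genotype-slope p otherwise) is returned per replicate. The slow R path
// in fit_model() is the reference implementation this engine is tested
// against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Fit {
  arma::vec beta;
  arma::mat cov;  // unscaled (X'X)^-1
  double s2;
  bool ok;
};

Fit ols(const arma::mat& D, const arma::vec& y) {
  Fit f;
  arma::mat XtX = D.t() * D;
  f.ok = arma::inv_sympd(f.cov, XtX);
  if (!f.ok) return f;
  f.beta = f.cov * (D.t() * y);
  arma::vec r = y - D * f.beta;
  double n = (double)y.n_elem, p = (double)D.n_cols;
  f.s2 = arma::dot(r, r) / (n - p);
  return f;
}

// rank-based inverse normal transform, average ranks for ties; qtab holds
// the precomputed quantiles for untied ranks 1..n
void int_transform(const arma::vec& x, arma::vec& out, const arma::vec& qtab,
                   double c) {
  const arma::uword n = x.n_elem;
  arma::uvec ord = arma::stable_sort_index(x);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    if (j == i) {
      out(ord(i)) = qtab(i);
    } else {
      double avg = 0.5 * ((double)i + (double)j) + 1.0;  // 1-based avg rank
      double q = R::qnorm((avg - c) / ((double)n + 1.0 - 2.0 * c),
                          0.0, 1.0, 1, 0);
      for (arma::uword k = i; k <= j; ++k) out(ord(k)) = q;
    }
    i = j + 1;
  }
}

// two-sided t test on the slope of z ~ 1 + g
double slope_test_p(const arma::vec& z, const arma::vec& g) {
  double n = (double)z.n_elem;
  double gm = arma::mean(g), zm = arma::mean(z);
  double sgg = arma::dot(g, g) - n * gm * gm;
  if (sgg <= 0.0) return 1.0;  // monomorphic genotype: degenerate fit
  double szz = arma::dot(z, z) - n * zm * zm;
  double sgz = arma::dot(g, z) - n * gm * zm;
  double rss = szz - sgz * sgz / sgg;
  if (rss <= 0.0) return 0.0;
  double se = std::sqrt(rss / (n - 2.0) / sgg);
  double t = (sgz / sgg) / se;
  return 2.0 * R::pt(-std::fabs(t), n - 2.0, 1, 0);
}

double two_step_p(const arma::vec& ph, const arma::mat& D, const arma::vec& g,
                  const arma::vec& qtab, double c) {
  Fit f = ols(D, ph);
  if (!f.ok) return NA_REAL;
  arma::vec r = ph - D * f.beta;
  arma::vec z(r.n_elem);
  int_transform(r, z, qtab, c);
  return slope_test_p(z, g);
}

double one_step_p(const arma::vec& y, const arma::mat& D, arma::uword gi,
                  int gti, bool want2df) {
  Fit f = ols(D, y);
  if (!f.ok) return 1.0;  // degenerate design (e.g. monomorphic genotype)
  double n = (double)y.n_elem, p = (double)D.n_cols;
  if (!want2df) {
    double se2 = f.s2 * f.cov(gi, gi);
    if (!(se2 > 0.0)) return 1.0;
    double t = f.beta(gi) / std::sqrt(se2);
    return 2.0 * R::pt(-std::fabs(t), n - p, 1, 0);
  }
  arma::uvec idx(2);
  idx(0) = gi;
  idx(1) = (arma::uword)gti;
  arma::mat V = f.s2 * f.cov.submat(idx, idx);
  arma::mat Vi;
  if (!arma::inv_sympd(Vi, V)) return 1.0;
  arma::vec b = f.beta.elem(idx);
  double w = arma::as_scalar(b.t() * Vi * b);
  // finite-sample F reference for the joint Wald statistic (matches the
  // default of the R reference path)
  return R::pf(w / 2.0, 2.0, n - p, 0, 0);
}

double cochran_p(const arma::vec& ly0, const arma::vec& ly1,
                 const arma::mat& D, arma::uword gi) {
  Fit f0 = ols(D, ly0);
  Fit f1 = ols(D, ly1);
  if (!f0.ok || !f1.ok) return 1.0;
  double v0 = f0.s2 * f0.cov(gi, gi);
  double v1 = f1.s2 * f1.cov(gi, gi);
  if (!(v0 + v1 > 0.0)) return 1.0;
  double d = f1.beta(gi) - f0.beta(gi);
  return R::pchisq(d * d / (v0 + v1), 1.0, 0, 0);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_batch_primary_p(const arma::mat& y0, const arma::mat& y1,
                                  const arma::mat& trt, const arma::mat& age,
                                  const arma::mat& gt,
                                  IntegerVector model_codes, double blom) {
  const arma::uword n = y0.n_rows, B = y0.n_cols;
  const int m = model_codes.size();
  NumericMatrix out((int)B, m);

  arma::vec qtab(n);
  for (arma::uword i = 0; i < n; ++i)
    qtab(i) = R::qnorm(((double)(i + 1) - blom) /
                       ((double)n + 1.0 - 2.0 * blom), 0.0, 1.0, 1, 0);
  arma::vec ones(n, arma::fill::ones);

  for (arma::uword b = 0; b < B; ++b) {
    arma::vec v0 = y0.col(b), v1 = y1.col(b);
    arma::vec T = trt.col(b), X = age.col(b), G = gt.col(b);
    arma::vec l0 = arma::log(v0), l1 = arma::log(v1);
    arma::vec lfc = l1 - l0;
    arma::vec ratio = (v1 - v0) / v0;
    arma::vec GT = G % T;
    for (int k = 0; k < m; ++k) {
      double p = NA_REAL;
      switch (model_codes[k]) {
        case 1: {  // M1: two-step, log-fold CFB, adjust ln y0
          arma::mat D = arma::join_rows(ones, l0, T, X);
          p = two_step_p(lfc, D, G, qtab, blom);
          break;
        }
        case 2: {  // M2: two-step, CFB ratio, unadjusted
          arma::mat D = arma::join_rows(ones, T, X);
          p = two_step_p(ratio, D, G, qtab, blom);
          break;
        }
        case 3: {  // M3: two-step, log-fold CFB, unadjusted
          arma::mat D = arma::join_rows(ones, T, X);
          p = two_step_p(lfc, D, G, qtab, blom);
          break;
        }
        case 4: {  // M4: two-step, CFB ratio, adjust raw y0
          arma::mat D = arma::join_rows(ones, v0, T, X);
          p = two_step_p(ratio, D, G, qtab, blom);
          break;
        }
        case 5: {  // M5: one-step 2df, adjusted
          arma::mat D = arma::join_rows(arma::join_rows(ones, l0, T),
                                        arma::join_rows(G, GT, X));
          p = one_step_p(lfc, D, 3, 4, true);
          break;
        }
        case 6: {  // M6: one-step 2df, unadjusted
          arma::mat D = arma::join_rows(arma::join_rows(ones, T),
                                        arma::join_rows(G, GT, X));
          p = one_step_p(lfc, D, 2, 3, true);
          break;
        }
        case 7: {  // M7: baseline association
          arma::mat D = arma::join_rows(ones, G, X);
          p = one_step_p(l0, D, 1, -1, false);
          break;
        }
        case 8: {  // M8: one-step 1df, adjusted
          arma::mat D = arma::join_rows(arma::join_rows(ones, l0, T),
                                        arma::join_rows(G, X));
          p = one_step_p(lfc, D, 3, -1, false);
          break;
        }
        case 9: {  // M9: one-step 1df, unadjusted
          arma::mat D = arma::join_rows(ones, T, G, X);
          p = one_step_p(lfc, D, 2, -1, false);
          break;
        }
        case 10: {  // M5*: log post-treatment, adjusted
          arma::mat D = arma::join_rows(arma::join_rows(ones, l0, T),
                                        arma::join_rows(G, X));
          p = one_step_p(l1, D, 3, -1, false);
          break;
        }
        case 11: {  // M6*: log post-treatment, unadjusted
          arma::mat D = arma::join_rows(ones, T, G, X);
          p = one_step_p(l1, D, 2, -1, false);
          break;
        }
        case 12: {  // Cochran's Q
          arma::mat D = arma::join_rows(ones, T, G, X);
          p = cochran_p(l0, l1, D, 2);
          break;
        }
        default:
          Rcpp::stop("unknown model code");
      }
      out((int)b, k) = p;
    }
    if (b % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
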