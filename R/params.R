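#' Parameters of the change-from-baseline generative model
#'
#' Bundles every coefficient and cohort dimension of the two-equation
#' generative model used throughout the package:
#' \deqn{\ln y_0 = b_0 + \beta_{G_0} G + \epsilon_0}
#' \deqn{\ln y_1 - \ln y_0 = \beta_T T + \beta_X X + \beta_{y_0} \ln y_0 +
#'   \beta_G G + \beta_{GT} G T + \epsilon_1}
#' with treatment arm \eqn{T \sim Bernoulli(p)}, age \eqn{X \sim U(18, 65)}
#' (years), genotype \eqn{G \sim Binomial(2, MAF)} allele counts, and
#' independent normal errors. The defaults reproduce the reference setting
#' of a 1000-subject two-arm trial with MAF 0.2, log-scale baseline mean 4.6,
#' treatment effect -0.25 and age effect -0.01 on the log-fold change.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param beta_G0 Genetic effect on the log baseline.
#' @param beta_y0 Coefficient of the log baseline in the change-from-baseline
#'   equation (the baseline-mediation path; usually negative in practice).
#' @param beta_G Direct genetic main effect on the change from baseline.
#' @param beta_GT Genotype-by-treatment interaction effect.
#' @param intercept_baseline Log-scale baseline intercept.
#' @param beta_T Treatment main effect on the change from baseline.
#' @param beta_X Age effect on the change from baseline (per year).
#' @param treatment_prob Probability of assignment to the active arm.
#' @param age_range Length-2 vector of age bounds in years.
#' @param sd_eps0,sd_eps1 Standard deviations of the two error terms.
#' @param seed Optional integer seed used by [simulate_cohort()] when no
#'   explicit seed is given there.
#'
#' @return An object of class `cfb_sim_params` (a validated named list).
#' @seealso [simulate_cohort()], [unadjusted_marginal_effect()]
#' @examples
#' p <- sim_params(beta_G0 = 0.1, beta_y0 = -0.2)
#' unadjusted_marginal_effect(p)
#' @export
sim_params <- function(n_subjects = 1000, maf = 0.2,
                       beta_G0 = 0, beta_y0 = 0, beta_G = 0, beta_GT = 0,
                       intercept_baseline = 4.6, beta_T = -0.25,
                       beta_X = -0.01, treatment_prob = 0.5,
                       age_range = c(18, 65), sd_eps0 = 1, sd_eps1 = 1,
                       seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stopf("n_subjects must be an integer >= 2, got %s", n_subjects)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stopf("maf must lie in (0, 0.5], got %s", maf)
  if (!is.numeric(treatment_prob) || treatment_prob <= 0 || treatment_prob >= 1)
    stopf("treatment_prob must lie in (0, 1), got %s", treatment_prob)
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stopf("age_range must be an increasing pair of years")
  if (sd_eps0 <= 0 || sd_eps1 <= 0)
    stopf("sd_eps0 and sd_eps1 must be positive")
  for (nm in c("beta_G0", "beta_y0", "beta_G", "beta_GT",
               "intercept_baseline", "beta_T", "beta_X")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopf("%s must be a finite scalar", nm)
  }
  structure(
    list(n_subjects = n_subjects, maf = maf, beta_G0 = beta_G0,
         beta_y0 = beta_y0, beta_G = beta_G, beta_GT = beta_GT,
         intercept_baseline = intercept_baseline, beta_T = beta_T,
         beta_X = beta_X, treatment_prob = treatment_prob,
         age_range = as.numeric(age_range), sd_eps0 = sd_eps0,
         sd_eps1 = sd_eps1, seed = seed),
    class = "cfb_sim_params")
}

#' @export
print.cfb_sim_params <- function(x, ...) {
  cat("Change-from-baseline simulation parameters\n")
  cat(sprintf("  n = %d, MAF = %g, treatment_prob = %g\n",
              x$n_subjects, x$maf, x$treatment_prob))
  cat(sprintf("  baseline:  ln y0 = %g + %g G + N(0, %g^2)\n",
              x$intercept_baseline, x$beta_G0, x$sd_eps0))
  cat(sprintf(
    "  CFB:  %g T + %g X + %g ln y0 + %g G + %g GT + N(0, %g^2)\n",
    x$beta_T, x$beta_X, x$beta_y0, x$beta_G, x$beta_GT, x$sd_eps1))
  invisible(x)
}

#' Multiplicative measurement-error configuration
#'
#' Observed responses are modelled as \eqn{(1 + r_i) y_i} with relative error
#' \eqn{r_i \sim N(\mu_i, \sigma^2)} drawn independently per subject at
#' baseline (i = 0) and post-treatment (i = 1), then truncated below at
#' `floor` so the log transform stays defined. With the default
#' \eqn{\sigma = 1/4}, relative errors fall within \eqn{\mu_i \pm 0.49} with
#' about 95% probability.
#'
#' Named presets cover the three studied mean configurations plus the
#' error-free case:
#' * `"none"`: no error applied;
#' * `"white"`: \eqn{\mu_0 = \mu_1 = 0} (white noise);
#' * `"same"`: \eqn{\mu_0 = \mu_1 = 0.25} (bias in the same direction);
#' * `"opposite"`: \eqn{\mu_0 = -0.25, \mu_1 = 0.25} (bias in different
#'   directions).
#'
#' @param preset Optional preset name; overrides `mu0`/`mu1`.
#' @param mu0,mu1 Mean relative error at baseline / post-treatment.
#' @param sigma Relative-error standard deviation (>= 0).
#' @param floor Lower truncation bound on observed responses (> 0).
#' @param enabled If `FALSE` the configuration is a no-op.
#' @return An object of class `cfb_me_config`.
#' @seealso [apply_measurement_error()]
#' @export
me_config <- function(preset = NULL, mu0 = 0, mu1 = 0, sigma = 0.25,
                      floor = 1, enabled = TRUE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("none", "white", "same", "opposite"))
    mus <- switch(preset,
                  none = c(0, 0),
                  white = c(0, 0),
                  same = c(0.25, 0.25),
                  opposite = c(-0.25, 0.25))
    mu0 <- mus[1]
    mu1 <- mus[2]
    enabled <- preset != "none"
  }
  if (sigma < 0) stopf("sigma must be >= 0")
  if (floor <= 0) stopf("floor must be > 0")
  structure(list(mu0 = mu0, mu1 = mu1, sigma = sigma, floor = floor,
                 enabled = isTRUE(enabled), preset = preset),
            class = "cfb_me_config")
}

#' @export
print.cfb_me_config <- function(x, ...) {
  if (!x$enabled) {
    cat("Measurement error: none\n")
  } else {
    cat(sprintf(
      "Measurement error: r0 ~ N(%g, %g^2), r1 ~ N(%g, %g^2), floor %g\n",
      x$mu0, x$sigma, x$mu1, x$sigma, x$floor))
  }
  invisible(x)
}
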