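# Synthetic cohort and variant-panel generation.
#
# The responses entering any log transform are bounded below at 1 (both the
# noiseless simulated responses and, in apply_measurement_error(), the
# corrupted ones), so ln y is always defined.

.RESPONSE_FLOOR <- 1

#' Construct a cohort from subject-level vectors
#'
#' Wraps already-available data (e.g. loaded from disk) into the cohort
#' container used by the fitting functions. All vectors must have equal
#' length; responses must be positive and genotypes in {0, 1, 2}.
#'
#' @param y0,y1 Baseline and post-treatment response on the natural scale.
#' @param treatment 0/1 arm indicator.
#' @param age Age in years (used as the covariate X).
#' @param genotype Allele counts 0/1/2.
#' @param truth Optional `cfb_sim_params` that generated the data.
#' @return A `data.frame` of class `cfb_cohort` with columns `subject_id`,
#'   `y0`, `y1`, `treatment`, `age`, `genotype`.
#' @export
cohort <- function(y0, y1, treatment, age, genotype, truth = NULL) {
  n <- length(y0)
  if (!all(lengths(list(y1, treatment, age, genotype)) == n))
    stopf("all cohort vectors must have identical length")
  if (any(y0 <= 0) || any(y1 <= 0))
    stopf("responses must be positive so that log transforms are defined")
  if (!all(genotype %in% 0:2))
    stopf("genotype must contain allele counts 0, 1 or 2")
  if (!all(treatment %in% 0:1))
    stopf("treatment must be a 0/1 indicator")
  out <- data.frame(subject_id = seq_len(n), y0 = as.numeric(y0),
                    y1 = as.numeric(y1), treatment = as.numeric(treatment),
                    age = as.numeric(age), genotype = as.numeric(genotype))
  attr(out, "truth") <- truth
  class(out) <- c("cfb_cohort", "data.frame")
  out
}

# Matrix-valued generator shared by simulate_cohort(), simulate_panel() and
# the Monte-Carlo engine: B independent cohorts as n x B columns.
# Draw order (fixed for reproducibility): genotype, treatment, age, eps0, eps1.
.simulate_matrices <- function(params, B) {
  n <- params$n_subjects
  g <- matrix(as.double(rbinom(n * B, 2L, params$maf)), n, B)
  trt <- matrix(as.double(rbinom(n * B, 1L, params$treatment_prob)), n, B)
  age <- matrix(runif(n * B, params$age_range[1], params$age_range[2]), n, B)
  ly0 <- params$intercept_baseline + params$beta_G0 * g +
    matrix(rnorm(n * B, 0, params$sd_eps0), n, B)
  cfb <- params$beta_T * trt + params$beta_X * age + params$beta_y0 * ly0 +
    params$beta_G * g + params$beta_GT * g * trt +
    matrix(rnorm(n * B, 0, params$sd_eps1), n, B)
  list(y0 = pmax(exp(ly0), .RESPONSE_FLOOR),
       y1 = pmax(exp(ly0 + cfb), .RESPONSE_FLOOR),
       treatment = trt, age = age, genotype = g)
}

#' Simulate one cohort from the generative model
#'
#' Draws genotype, treatment arm, age and the two error terms, forms
#' \eqn{\ln y_0} and \eqn{\ln y_1} from the two model equations, and returns
#' the responses on the natural scale (floored at 1). Deterministic for a
#' fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed; falls back to `params$seed`.
#' @return A `cfb_cohort` with the generating parameters attached as
#'   attribute `"truth"`.
#' @examples
#' co <- simulate_cohort(sim_params(beta_G0 = 0.1, beta_y0 = -0.2), seed = 1)
#' head(co)
#' @export
simulate_cohort <- function(params, seed = NULL) {
  if (!inherits(params, "cfb_sim_params")) stopf("params must come from sim_params()")
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  m <- .simulate_matrices(params, 1L)
  cohort(m$y0[, 1], m$y1[, 1], m$treatment[, 1], m$age[, 1], m$genotype[, 1],
         truth = params)
}

.apply_me_matrices <- function(y0, y1, config) {
  if (!config$enabled) return(list(y0 = y0, y1 = y1))
  r0 <- matrix(rnorm(length(y0), config$mu0, config$sigma), nrow(y0), ncol(y0))
  r1 <- matrix(rnorm(length(y1), config$mu1, config$sigma), nrow(y1), ncol(y1))
  list(y0 = pmax((1 + r0) * y0, config$floor),
       y1 = pmax((1 + r1) * y1, config$floor))
}

#' Corrupt a cohort with multiplicative measurement error
#'
#' Replaces the responses by \eqn{(1 + r_i) y_i} with independent
#' \eqn{r_i \sim N(\mu_i, \sigma^2)} per subject, truncated below at the
#' configured floor. The input cohort is not modified.
#'
#' @param x A `cfb_cohort`.
#' @param config A [me_config()] object.
#' @param seed Optional integer seed.
#' @return A new `cfb_cohort` with corrupted `y0`, `y1`.
#' @export
apply_measurement_error <- function(x, config, seed = NULL) {
  if (!inherits(x, "cfb_cohort")) stopf("x must be a cfb_cohort")
  if (!inherits(config, "cfb_me_config")) stopf("config must come from me_config()")
  if (!config$enabled) return(x)
  if (!is.null(seed)) set.seed(seed)
  y <- .apply_me_matrices(cbind(x$y0), cbind(x$y1), config)
  out <- x
  out$y0 <- y$y0[, 1]
  out$y1 <- y$y1[, 1]
  out
}

#' Describe the variant mix of a synthetic panel
#'
#' Each row assigns a fraction of the panel a truth tuple
#' (maf, beta_G0, beta_y0, beta_G, beta_GT). Fractions must sum to 1.
#'
#' @param fraction Numeric vector of variant fractions (sums to 1).
#' @param beta_G0,beta_y0,beta_G,beta_GT Per-class effect sizes (recycled).
#' @param maf Per-class minor allele frequency (recycled).
#' @return A `data.frame` usable as the `composition` of [simulate_panel()].
#' @examples
#' # 30% baseline-mediator variants among fully null ones
#' panel_composition(fraction = c(0.7, 0.3),
#'                   beta_G0 = c(0, 0.1), beta_y0 = c(0, -0.2))
#' @export
panel_composition <- function(fraction, beta_G0 = 0, beta_y0 = 0,
                              beta_G = 0, beta_GT = 0, maf = 0.2) {
  if (abs(sum(fraction) - 1) > 1e-8)
    stopf("composition fractions must sum to 1 (got %g)", sum(fraction))
  if (any(fraction < 0)) stopf("composition fractions must be non-negative")
  data.frame(fraction = fraction, maf = maf, beta_G0 = beta_G0,
             beta_y0 = beta_y0, beta_G = beta_G, beta_GT = beta_GT)
}

#' Simulate a multi-variant panel
#'
#' Generates a subjects-by-variants genotype matrix plus phenotypes under one
#' of two composition rules:
#' * `"single_causal"` (default): each variant gets its own phenotype
#'   replicate generated from its own truth tuple with fresh noise, matching
#'   a one-variant-at-a-time simulation design. `y0`/`y1` are then
#'   subjects-by-variants matrices.
#' * `"additive"`: one shared phenotype sums the genetic effects of all
#'   causal variants; `y0`/`y1` are vectors.
#'
#' Treatment and age are always shared across variants.
#'
#' @param n_subjects Number of subjects.
#' @param n_variants Number of variants.
#' @param composition A [panel_composition()] data frame.
#' @param rule Phenotype composition rule.
#' @param params Base [sim_params()] supplying the non-genetic coefficients
#'   (intercept, beta_T, beta_X, error SDs, treatment probability, ages).
#' @param seed Optional integer seed.
#' @return A list of class `cfb_panel` with elements `genotypes`, `y0`, `y1`,
#'   `treatment`, `age`, `truth` (per-variant tuple table with a
#'   `null_for_cfb` flag), and `rule`.
#' @export
simulate_panel <- function(n_subjects, n_variants, composition,
                           rule = c("single_causal", "additive"),
                           params = sim_params(n_subjects = n_subjects),
                           seed = NULL) {
  rule <- match.arg(rule)
  if (!is.data.frame(composition) ||
      !all(c("fraction", "maf", "beta_G0", "beta_y0", "beta_G", "beta_GT")
           %in% names(composition)))
    stopf("composition must come from panel_composition()")
  if (abs(sum(composition$fraction) - 1) > 1e-8)
    stopf("composition fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_subjects)
  m <- as.integer(n_variants)
  counts <- diff(c(0L, round(cumsum(composition$fraction) * m)))
  cls <- rep(seq_len(nrow(composition)), counts)
  truth <- composition[cls, c("maf", "beta_G0", "beta_y0", "beta_G", "beta_GT")]
  rownames(truth) <- NULL
  truth <- cbind(variant_id = sprintf("v%05d", seq_len(m)), truth)
  truth$null_for_cfb <- truth$beta_G == 0 & truth$beta_GT == 0

  trt <- as.double(rbinom(n, 1L, params$treatment_prob))
  age <- runif(n, params$age_range[1], params$age_range[2])
  g <- matrix(as.double(rbinom(n * m, 2L, rep(truth$maf, each = n))), n, m)
  colnames(g) <- truth$variant_id
  rownames(g) <- seq_len(n)

  if (rule == "single_causal") {
    e0 <- matrix(rnorm(n * m, 0, params$sd_eps0), n, m)
    ly0 <- params$intercept_baseline + g * rep(truth$beta_G0, each = n) + e0
    cfb <- params$beta_T * trt + params$beta_X * age +
      ly0 * rep(truth$beta_y0, each = n) + g * rep(truth$beta_G, each = n) +
      (g * trt) * rep(truth$beta_GT, each = n) +
      matrix(rnorm(n * m, 0, params$sd_eps1), n, m)
    y0 <- pmax(exp(ly0), .RESPONSE_FLOOR)
    y1 <- pmax(exp(ly0 + cfb), .RESPONSE_FLOOR)
  } else {
    ly0 <- params$intercept_baseline +
      drop(g %*% truth$beta_G0) + rnorm(n, 0, params$sd_eps0)
    cfb <- params$beta_T * trt + params$beta_X * age + params$beta_y0 * ly0 +
      drop(g %*% truth$beta_G) + drop((g * trt) %*% truth$beta_GT) +
      rnorm(n, 0, params$sd_eps1)
    y0 <- pmax(exp(ly0), .RESPONSE_FLOOR)
    y1 <- pmax(exp(ly0 + cfb), .RESPONSE_FLOOR)
  }
  structure(list(genotypes = g, y0 = y0, y1 = y1, treatment = trt, age = age,
                 truth = truth, rule = rule, params = params),
            class = "cfb_panel")
}

#' @export
print.cfb_panel <- function(x, ...) {
  cat(sprintf("cfb_panel: %d subjects x %d variants (%s rule)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$rule))
  cat(sprintf("  variants null for CFB: %d\n", sum(x$truth$null_for_cfb)))
  invisible(x)
}

# Subject-level view of one panel variant as a plain list (fast path used by
# run_gwas(); fit functions only index by name).
.panel_cohort <- function(panel, v) {
  single <- is.matrix(panel$y0)
  list(y0 = if (single) panel$y0[, v] else panel$y0,
       y1 = if (single) panel$y1[, v] else panel$y1,
       treatment = panel$treatment, age = panel$age,
       genotype = panel$genotypes[, v])
}
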