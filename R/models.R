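# The twelve analysis models: two-step INT-residual regressions (M1-M4),
# one-step regressions with 1df or joint 2df Wald tests (M5-M9, M5s, M6s),
# and Cochran's Q heterogeneity test. All tests are two-sided.

.model_registry <- list(
  M1  = list(id = "M1", label = "log-fold-CFB, adjusted, 1df, 2-step",
             phenotype = "log_fold_cfb", baseline_adjusted = TRUE,
             baseline_scale = "log", approach = "two_step_int", test = "wald_1df"),
  M2  = list(id = "M2", label = "CFB ratio, unadjusted, 1df, 2-step",
             phenotype = "cfb_ratio", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "two_step_int", test = "wald_1df"),
  M3  = list(id = "M3", label = "log-fold-CFB, unadjusted, 1df, 2-step",
             phenotype = "log_fold_cfb", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "two_step_int", test = "wald_1df"),
  M4  = list(id = "M4", label = "CFB ratio, adjusted on raw baseline, 1df, 2-step",
             phenotype = "cfb_ratio", baseline_adjusted = TRUE,
             baseline_scale = "raw", approach = "two_step_int", test = "wald_1df"),
  M5  = list(id = "M5", label = "log-fold-CFB, adjusted, 2df, 1-step",
             phenotype = "log_fold_cfb", baseline_adjusted = TRUE,
             baseline_scale = "log", approach = "one_step", test = "joint_2df"),
  M6  = list(id = "M6", label = "log-fold-CFB, unadjusted, 2df, 1-step",
             phenotype = "log_fold_cfb", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "one_step", test = "joint_2df"),
  M7  = list(id = "M7", label = "log-baseline association",
             phenotype = "log_baseline", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "one_step", test = "baseline_only"),
  M8  = list(id = "M8", label = "log-fold-CFB, adjusted, 1df, 1-step",
             phenotype = "log_fold_cfb", baseline_adjusted = TRUE,
             baseline_scale = "log", approach = "one_step", test = "wald_1df"),
  M9  = list(id = "M9", label = "log-fold-CFB, unadjusted, 1df, 1-step",
             phenotype = "log_fold_cfb", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "one_step", test = "wald_1df"),
  M5s = list(id = "M5s", label = "log-post-treatment, adjusted, 1df, 1-step",
             phenotype = "log_post", baseline_adjusted = TRUE,
             baseline_scale = "log", approach = "one_step", test = "wald_1df"),
  M6s = list(id = "M6s", label = "log-post-treatment, unadjusted, 1df, 1-step",
             phenotype = "log_post", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "one_step", test = "wald_1df"),
  Q   = list(id = "Q", label = "Cochran's Q heterogeneity test",
             phenotype = "log_baseline_and_post", baseline_adjusted = FALSE,
             baseline_scale = NA, approach = "cochran_q", test = "cochran_q")
)

# integer codes shared with the C++ batch engine
.MODEL_CODES <- c(M1 = 1L, M2 = 2L, M3 = 3L, M4 = 4L, M5 = 5L, M6 = 6L,
                  M7 = 7L, M8 = 8L, M9 = 9L, M5s = 10L, M6s = 11L, Q = 12L)

#' Identifiers of the twelve analysis models
#' @return Character vector `c("M1", ..., "M9", "M5s", "M6s", "Q")`.
#' @export
model_ids <- function() names(.model_registry)

#' Configuration of one analysis model
#'
#' @param id One of [model_ids()]. `"M5s"`/`"M6s"` are the post-treatment
#'   sensitivity variants of M5/M6 (1df, 1-step on log post-treatment value).
#' @return A list with elements `id`, `label`, `phenotype`,
#'   `baseline_adjusted`, `baseline_scale`, `approach`, `test`.
#' @export
model_spec <- function(id) {
  if (length(id) != 1L || !id %in% names(.model_registry))
    stopf("unknown model id '%s'; see model_ids()", paste(id, collapse = ","))
  .model_registry[[id]]
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal scores \eqn{\Phi^{-1}((r - c) / (n + 1 - 2c))} where
#' r is the (average, for ties) rank and c the rank offset. The default
#' offset 3/8 is the Blom convention standard in GWAS residual transforms.
#' The transform is order-preserving.
#'
#' @param x Numeric vector (finite, non-empty).
#' @param offset Rank offset c in \[0, 0.5\].
#' @return Numeric vector of normal scores.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  if (length(x) == 0L) stopf("cannot inverse-normal transform an empty vector")
  if (any(!is.finite(x))) stopf("values must be finite")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n + 1 - 2 * offset))
}

# one AssocResult row as a plain list (data.frame conversion happens at the
# user-facing surface; run_gwas() consumes the list form directly)
.assoc_row <- function(model_id, beta_y0 = NA_real_, se_y0 = NA_real_,
                       beta_G = NA_real_, se_G = NA_real_, p_G = NA_real_,
                       beta_GT = NA_real_, se_GT = NA_real_, p_GT = NA_real_,
                       p_2df = NA_real_, q_stat = NA_real_, p_Q = NA_real_,
                       n_used = NA_integer_, df_resid = NA_integer_,
                       degenerate = FALSE) {
  list(model_id = model_id, beta_y0 = beta_y0, se_y0 = se_y0,
       beta_G = beta_G, se_G = se_G, p_G = p_G, beta_GT = beta_GT,
       se_GT = se_GT, p_GT = p_GT, p_2df = p_2df, q_stat = q_stat,
       p_Q = p_Q, n_used = as.integer(n_used),
       df_resid = as.integer(df_resid), degenerate = degenerate)
}

.as_assoc_df <- function(row) {
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  class(out) <- c("cfb_assoc", "data.frame")
  out
}

.phenotype <- function(x, spec) {
  switch(spec$phenotype,
         log_fold_cfb = log(x$y1) - log(x$y0),
         cfb_ratio = (x$y1 - x$y0) / x$y0,
         log_baseline = log(x$y0),
         log_post = log(x$y1),
         stopf("no single phenotype for model %s", spec$id))
}

# OLS via QR with coefficient covariance; errors on rank deficiency naming
# the offending column(s)
.ols <- function(D, y) {
  qrD <- qr(D)
  p <- ncol(D)
  if (qrD$rank < p) {
    bad <- colnames(D)[qrD$pivot[seq(qrD$rank + 1L, p)]]
    stopf("design matrix is rank deficient; offending column(s): %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, y)
  res <- qr.resid(qrD, y)
  n <- length(y)
  s2 <- sum(res^2) / (n - p)
  V <- matrix(NA_real_, p, p)
  V[qrD$pivot, qrD$pivot] <- chol2inv(qr.R(qrD))
  dimnames(V) <- list(colnames(D), colnames(D))
  list(beta = beta, se = sqrt(s2 * diag(V)), cov_unscaled = V, s2 = s2,
       resid = res, df_resid = n - p, qr = qrD)
}

.design <- function(x, cols, covariates) {
  n <- length(x$y0)
  parts <- list(`(Intercept)` = rep(1, n))
  for (cl in cols) {
    parts[[cl]] <- switch(cl,
                          log_baseline = log(x$y0),
                          raw_baseline = x$y0,
                          treatment = x$treatment,
                          genotype = x$genotype,
                          gxt = x$genotype * x$treatment,
                          stopf("unknown design column %s", cl))
  }
  for (cv in covariates) {
    if (is.null(x[[cv]])) stopf("covariate '%s' not found in cohort", cv)
    parts[[cv]] <- x[[cv]]
  }
  do.call(cbind, parts)
}

.baseline_col <- function(spec) {
  if (!isTRUE(spec$baseline_adjusted)) return(NULL)
  if (identical(spec$baseline_scale, "raw")) "raw_baseline" else "log_baseline"
}

.two_sided_t <- function(t, df) 2 * pt(-abs(t), df)

# core of the two-step fit; exported wrapper validates and converts
.fit_two_step_row <- function(x, spec, covariates, int = TRUE,
                              residualize_genotype = FALSE,
                              int_offset = 3 / 8) {
  ph <- .phenotype(x, spec)
  D1 <- .design(x, c(.baseline_col(spec), "treatment"), covariates)
  f1 <- .ols(D1, ph)
  by0 <- sy0 <- NA_real_
  if (isTRUE(spec$baseline_adjusted)) {
    bc <- .baseline_col(spec)
    by0 <- unname(f1$beta[bc])
    sy0 <- unname(f1$se[bc])
  }
  z <- if (int) inverse_normal_transform(f1$resid, int_offset) else f1$resid
  g <- x$genotype
  if (residualize_genotype) g <- qr.resid(f1$qr, g)
  n <- length(z)
  if (var(g) == 0) {
    return(.assoc_row(spec$id, beta_y0 = by0, se_y0 = sy0, p_G = 1,
                      n_used = n, df_resid = n - 2L, degenerate = TRUE))
  }
  f2 <- .ols(cbind(`(Intercept)` = rep(1, n), genotype = g), z)
  tg <- f2$beta["genotype"] / f2$se["genotype"]
  .assoc_row(spec$id, beta_y0 = by0, se_y0 = sy0,
             beta_G = unname(f2$beta["genotype"]),
             se_G = unname(f2$se["genotype"]),
             p_G = .two_sided_t(tg, f2$df_resid),
             n_used = n, df_resid = f2$df_resid)
}

.fit_one_step_row <- function(x, spec, covariates, joint_reference = "f") {
  ph <- .phenotype(x, spec)
  n <- length(ph)
  if (var(x$genotype) == 0) {
    return(.assoc_row(spec$id, p_G = 1,
                      p_2df = if (spec$test == "joint_2df") 1 else NA_real_,
                      n_used = n, df_resid = NA, degenerate = TRUE))
  }
  cols <- c(.baseline_col(spec),
            if (spec$test != "baseline_only") "treatment",
            "genotype",
            if (spec$test == "joint_2df") "gxt")
  D <- .design(x, cols, covariates)
  f <- .ols(D, ph)
  by0 <- sy0 <- NA_real_
  if (isTRUE(spec$baseline_adjusted)) {
    bc <- .baseline_col(spec)
    by0 <- unname(f$beta[bc])
    sy0 <- unname(f$se[bc])
  }
  tg <- f$beta["genotype"] / f$se["genotype"]
  row <- .assoc_row(spec$id, beta_y0 = by0, se_y0 = sy0,
                    beta_G = unname(f$beta["genotype"]),
                    se_G = unname(f$se["genotype"]),
                    p_G = .two_sided_t(tg, f$df_resid),
                    n_used = n, df_resid = f$df_resid)
  if (spec$test == "joint_2df") {
    idx <- c("genotype", "gxt")
    V <- f$s2 * f$cov_unscaled[idx, idx]
    b <- f$beta[idx]
    w <- drop(t(b) %*% solve(V, b))
    tgt <- f$beta["gxt"] / f$se["gxt"]
    row$beta_GT <- unname(f$beta["gxt"])
    row$se_GT <- unname(f$se["gxt"])
    row$p_GT <- .two_sided_t(tgt, f$df_resid)
    row$p_2df <- if (joint_reference == "f") {
      pf(w / 2, 2, f$df_resid, lower.tail = FALSE)
    } else {
      pchisq(w, df = 2, lower.tail = FALSE)
    }
  }
  row
}

# Cochran's Q from per-stratum genotype coefficients and their variances,
# in the inverse-variance weighted-sum form
.q_stat <- function(betas, vars) {
  w <- 1 / vars
  bbar <- sum(w * betas) / sum(w)
  sum(w * (betas - bbar)^2)
}

.cochran_q_row <- function(x, covariates) {
  n <- length(x$y0)
  if (var(x$genotype) == 0) {
    return(.assoc_row("Q", p_G = 1, p_Q = 1, n_used = n, degenerate = TRUE))
  }
  D <- .design(x, c("treatment", "genotype"), covariates)
  f0 <- .ols(D, log(x$y0))
  f1 <- .ols(D, log(x$y1))
  b <- c(f0$beta["genotype"], f1$beta["genotype"])
  v <- c(f0$se["genotype"], f1$se["genotype"])^2
  q <- .q_stat(b, v)
  .assoc_row("Q", q_stat = q, p_Q = pchisq(q, df = 1, lower.tail = FALSE),
             n_used = n, df_resid = f0$df_resid)
}

.fit_row <- function(x, model, covariates = "age", int_offset = 3 / 8) {
  spec <- model_spec(model)
  switch(spec$approach,
         two_step_int = .fit_two_step_row(x, spec, covariates,
                                          int_offset = int_offset),
         one_step = .fit_one_step_row(x, spec, covariates),
         cochran_q = .cochran_q_row(x, covariates))
}

#' Fit one analysis model to a cohort
#'
#' Dispatches to the two-step INT-residual procedure (M1-M4), the one-step
#' least-squares fit with 1df or joint 2df Wald test (M5-M9, M5s, M6s), or
#' Cochran's Q (`"Q"`). Single-coefficient p-values use the t distribution
#' with the residual degrees of freedom; the 2df joint test is a Wald
#' chi-square on the genotype and interaction coefficients with their
#' estimated covariance. A monomorphic genotype yields a degenerate-fit flag
#' with p = 1 rather than an error.
#'
#' @param x A `cfb_cohort` (or list with elements `y0`, `y1`, `treatment`,
#'   `age`, `genotype`).
#' @param model A model id from [model_ids()].
#' @param covariates Names of additional covariate columns (default `"age"`).
#' @param int_offset Rank offset of the inverse normal transform.
#' @return A one-row `data.frame` of class `cfb_assoc` with columns
#'   `model_id`, `beta_y0`, `se_y0`, `beta_G`, `se_G`, `p_G`, `beta_GT`,
#'   `se_GT`, `p_GT`, `p_2df`, `q_stat`, `p_Q`, `n_used`, `df_resid`,
#'   `degenerate` (`NA` where not applicable).
#' @examples
#' co <- simulate_cohort(sim_params(beta_G = 0.3), seed = 1)
#' fit_model(co, "M1")
#' @export
fit_model <- function(x, model, covariates = "age", int_offset = 3 / 8) {
  .as_assoc_df(.fit_row(x, model, covariates, int_offset))
}

#' Two-step INT-residual association fit
#'
#' Step 1 regresses the model's phenotype on intercept, treatment and
#' covariates (plus the baseline term for the adjusted models: log baseline
#' for M1, raw baseline for M4); step 2 regresses the inverse-normal
#' transformed residuals on intercept and genotype and reports the two-sided
#' t-test on the genotype slope.
#'
#' @inheritParams fit_model
#' @param int Apply the inverse normal transform to the step-1 residuals
#'   (default). `FALSE` gives the plain-residual variant.
#' @param residualize_genotype Also residualize the genotype on the step-1
#'   design before step 2. With `int = FALSE` this makes the step-2 slope
#'   equal the corresponding one-step coefficient (Frisch-Waugh-Lovell).
#' @return A one-row `cfb_assoc` data frame.
#' @export
fit_two_step <- function(x, model, covariates = "age", int = TRUE,
                         residualize_genotype = FALSE, int_offset = 3 / 8) {
  spec <- model_spec(model)
  if (spec$approach != "two_step_int")
    stopf("model %s is not a two-step model", model)
  .as_assoc_df(.fit_two_step_row(x, spec, covariates, int,
                                 residualize_genotype, int_offset))
}

#' One-step least-squares association fit
#'
#' Single regression of the model's phenotype on its full design. 1df models
#' report the two-sided t-test on the genotype coefficient; 2df models (M5,
#' M6) additionally report the interaction coefficient and the joint Wald
#' test on (beta_G, beta_GT) with their estimated covariance. By default
#' the joint statistic (halved) is referred to an F distribution with the
#' residual denominator degrees of freedom, the finite-sample counterpart
#' of the t reference used for single coefficients and exactly calibrated
#' under normal errors; the large-sample chi-square reference is available
#' as a variant.
#'
#' @inheritParams fit_model
#' @param joint_reference `"f"` (default) or `"chisq"` reference
#'   distribution for the 2df joint statistic.
#' @return A one-row `cfb_assoc` data frame.
#' @export
fit_one_step <- function(x, model, covariates = "age",
                         joint_reference = c("f", "chisq")) {
  spec <- model_spec(model)
  if (spec$approach != "one_step")
    stopf("model %s is not a one-step model", model)
  .as_assoc_df(.fit_one_step_row(x, spec, covariates,
                                 match.arg(joint_reference)))
}

#' Cochran's Q heterogeneity test between baseline and post-treatment
#'
#' Fits `ln y_i ~ intercept + treatment + genotype + covariates` separately
#' for the baseline (i = 0) and post-treatment (i = 1) responses and forms
#' the inverse-variance weighted heterogeneity statistic of the two genotype
#' coefficients, which reduces to
#' \eqn{Q = (\hat\beta_{G1} - \hat\beta_{G0})^2 / (s_0^2 + s_1^2)},
#' referred to a chi-square with 1 degree of freedom. Because the two
#' coefficients share the baseline error they are positively correlated,
#' which makes this reference distribution conservative.
#'
#' @inheritParams fit_model
#' @return A one-row `cfb_assoc` data frame with `q_stat` and `p_Q`.
#' @export
cochran_q <- function(x, covariates = "age") {
  .as_assoc_df(.cochran_q_row(x, covariates))
}

#' Marginal genotype effect tested by baseline-unadjusted models
#'
#' When the baseline mediates part of the genotype effect, unadjusted models
#' of the change from baseline test `beta_G + beta_G0 * beta_y0` rather than
#' the direct effect `beta_G`; the second term is the mediator effect.
#'
#' @param params A [sim_params()] object.
#' @return The scalar `beta_G + beta_G0 * beta_y0`.
#' @examples
#' unadjusted_marginal_effect(sim_params(beta_G0 = 0.1, beta_y0 = -0.2))
#' @export
unadjusted_marginal_effect <- function(params) {
  params$beta_G + params$beta_G0 * params$beta_y0
}

#' Primary p-value of an association result
#'
#' The p-value a genome scan ranks on: `p_2df` for the 2df models (M5, M6),
#' `p_Q` for Cochran's Q, `p_G` otherwise.
#'
#' @param x A `cfb_assoc` data frame (any number of rows).
#' @return Numeric vector of primary p-values.
#' @export
primary_pvalue <- function(x) {
  ifelse(x$model_id %in% c("M5", "M6"), x$p_2df,
         ifelse(x$model_id == "Q", x$p_Q, x$p_G))
}
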