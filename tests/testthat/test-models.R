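test_that("the registry holds the twelve model configurations", {
  expect_setequal(model_ids(), c(paste0("M", 1:9), "M5s", "M6s", "Q"))
  expect_error(model_spec("M10"), "unknown model")
  m1 <- model_spec("M1")
  expect_true(m1$baseline_adjusted)
  expect_equal(m1$approach, "two_step_int")
  expect_equal(model_spec("M4")$baseline_scale, "raw")  # raw-scale baseline
  expect_equal(model_spec("M5")$test, "joint_2df")
  expect_false(model_spec("M6")$baseline_adjusted)
  expect_equal(model_spec("M7")$test, "baseline_only")
  expect_equal(model_spec("M5s")$phenotype, "log_post")
})

test_that("inverse normal transform matches its quantile definition", {
  expect_equal(inverse_normal_transform(5), 0)              # single value
  expect_error(inverse_normal_transform(numeric(0)), "empty")
  x <- c(2.5, -1, 0.3)
  z <- inverse_normal_transform(x)
  expect_equal(order(z), order(x))                          # order-preserving
  # n = 3 distinct: middle exactly 0, outer at +/- qnorm((1 - 3/8)/3.25)
  q <- qnorm((1 - 3 / 8) / (3 + 1 - 2 * 3 / 8))
  expect_equal(sort(z), c(q, 0, -q))
  # ties get the average-rank quantile
  zt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(zt[1], zt[2])
  expect_equal(zt[1], qnorm((1.5 - 3 / 8) / (3 + 1 - 2 * 3 / 8)))
  # strictly increasing input -> strictly increasing output
  xi <- sort(rnorm(50))
  expect_true(all(diff(inverse_normal_transform(xi)) > 0))
})

test_that("one-step coefficients equal the brute-force normal equations", {
  co <- simulate_cohort(sim_params(n_subjects = 20), seed = 42)
  for (mm in c("M5", "M7", "M8", "M6s")) {
    spec <- model_spec(mm)
    ph <- switch(spec$phenotype,
                 log_fold_cfb = log(co$y1) - log(co$y0),
                 log_baseline = log(co$y0),
                 log_post = log(co$y1))
    X <- cbind(1,
               if (isTRUE(spec$baseline_adjusted)) log(co$y0),
               if (mm != "M7") co$treatment,
               co$genotype,
               if (spec$test == "joint_2df") co$genotype * co$treatment,
               co$age)
    b <- solve(t(X) %*% X, t(X) %*% ph)  # independent brute-force solve
    gi <- 2 + isTRUE(spec$baseline_adjusted) + (mm != "M7")
    fit <- fit_one_step(co, mm)
    expect_equal(fit$beta_G, b[gi], tolerance = 1e-10)
  }
})

test_that("1-step and double-residualized 2-step agree (Frisch-Waugh-Lovell)", {
  for (seed in c(1, 2, 3)) {
    co <- make_fixture_cohort(n = 300, seed = seed)
    two <- fit_two_step(co, "M1", int = FALSE, residualize_genotype = TRUE)
    one <- fit_one_step(co, "M8")
    expect_lt(abs(two$beta_G - one$beta_G) / abs(one$beta_G), 1e-10)
  }
})

test_that("adjusted and unadjusted 2-step agree when G and baseline are unlinked", {
  # no genotype-baseline association and no baseline-CFB dependence:
  # adjusting for the baseline changes essentially nothing
  for (seed in 1:20) {
    co <- simulate_cohort(sim_params(beta_G = 0.2), seed = 100 + seed)
    t1 <- qnorm(fit_model(co, "M1")$p_G / 2)
    t3 <- qnorm(fit_model(co, "M3")$p_G / 2)
    expect_lt(abs(t1 - t3), 0.25)
  }
})

test_that("the joint 2df test dominates 1df tests under a strong interaction", {
  # opposing main and interaction effects null out the marginal slope
  co <- simulate_cohort(sim_params(n_subjects = 5000, beta_G = 0.08,
                                   beta_GT = -0.285), seed = 77)
  p2 <- fit_model(co, "M6")$p_2df
  expect_lt(p2, fit_model(co, "M9")$p_G / 10)
  expect_lt(p2, fit_model(co, "M3")$p_G / 10)
})

test_that("genotype permutation gives calibrated step-2 p-values", {
  set.seed(31)
  co <- make_fixture_cohort(n = 300, seed = 31)
  ps <- replicate(400, {
    co$genotype <- sample(co$genotype)
    fit_model(co, "M3")$p_G
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Cochran's Q reduces to the two-beta closed form", {
  # hand evaluation: betas 0.1/0.3 with variances 0.01 -> Q = 0.04/0.02 = 2
  expect_equal(cfbgwas:::.q_stat(c(0.1, 0.3), c(0.01, 0.01)), 2)
  # weighted-sum form equals (b1 - b0)^2 / (s0^2 + s1^2) on random inputs
  set.seed(8)
  for (i in 1:20) {
    b <- rnorm(2)
    v <- rexp(2)
    expect_equal(cfbgwas:::.q_stat(b, v), (b[2] - b[1])^2 / sum(v),
                 tolerance = 1e-12)
  }
  # identical strata: Q = 0, p = 1
  co <- make_fixture_cohort(n = 100, seed = 5)
  co$y1 <- co$y0
  fit <- cochran_q(co)
  expect_equal(fit$q_stat, 0)
  expect_equal(fit$p_Q, 1)
})

test_that("the unadjusted marginal effect is beta_G + beta_G0 * beta_y0", {
  expect_equal(unadjusted_marginal_effect(
    sim_params(beta_G0 = 0.1, beta_y0 = -0.2)), -0.02)
  expect_equal(unadjusted_marginal_effect(
    sim_params(beta_y0 = -0.9, beta_G = 0.2)), 0.2)
  # Monte-Carlo consistency: the one-step unadjusted slope estimates it
  p <- sim_params(n_subjects = 1e5, beta_G0 = 0.1, beta_y0 = -0.2)
  fit <- fit_model(simulate_cohort(p, seed = 12), "M9")
  expect_lt(abs(fit$beta_G - (-0.02)), 3 * fit$se_G)
  # and the baseline model recovers beta_G0 itself
  fit7 <- fit_model(simulate_cohort(p, seed = 13), "M7")
  expect_lt(abs(fit7$beta_G - 0.1), 3 * fit7$se_G)
})

test_that("monomorphic genotypes flag a degenerate fit instead of erroring", {
  co <- make_fixture_cohort(n = 80, seed = 3)
  co$genotype <- rep(0, 80)
  for (mm in c("M1", "M5", "M7", "Q")) {
    fit <- fit_model(co, mm)
    expect_true(fit$degenerate)
    expect_equal(primary_pvalue(fit), 1)
  }
})

test_that("rank-deficient designs name the offending column", {
  co <- make_fixture_cohort(n = 80, seed = 4)
  co$treatment <- rep(1, 80)  # one arm only: G x T duplicates G
  expect_error(fit_one_step(co, "M5"), "gxt|treatment")
})

test_that("the batch engine matches the reference fits on every model", {
  p <- sim_params(n_subjects = 300, beta_G0 = 0.1, beta_y0 = -0.2,
                  beta_G = 0.1, beta_GT = 0.1)
  A <- replicate_pvalues(p, 20, model_ids(), seed = 55, engine = "cpp")
  B <- replicate_pvalues(p, 20, model_ids(), seed = 55, engine = "r")
  expect_lt(max(abs(A - B)), 1e-10)
  # and with measurement error in the pipeline
  A2 <- replicate_pvalues(p, 10, model_ids(), seed = 56, engine = "cpp",
                          error_config = me_config("opposite"))
  B2 <- replicate_pvalues(p, 10, model_ids(), seed = 56, engine = "r",
                          error_config = me_config("opposite"))
  expect_lt(max(abs(A2 - B2)), 1e-10)
})

test_that("primary p-value picks the model's reported test", {
  co <- make_fixture_cohort(n = 200, seed = 21)
  f5 <- fit_model(co, "M5")
  expect_equal(primary_pvalue(f5), f5$p_2df)
  f8 <- fit_model(co, "M8")
  expect_equal(primary_pvalue(f8), f8$p_G)
  fq <- fit_model(co, "Q")
  expect_equal(primary_pvalue(fq), fq$p_Q)
})
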