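test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(maf = 0), "maf")
  expect_error(sim_params(maf = 0.6), "maf")
  expect_error(sim_params(n_subjects = 1), "n_subjects")
  expect_error(sim_params(sd_eps0 = 0), "positive")
  expect_error(sim_params(treatment_prob = 1), "treatment_prob")
  expect_error(sim_params(age_range = c(65, 18)), "age_range")
  expect_error(me_config(sigma = -1), "sigma")
  expect_error(me_config(floor = 0), "floor")
})

test_that("defaults reproduce the reference simulation setting", {
  p <- sim_params()
  expect_equal(p$n_subjects, 1000L)
  expect_equal(p$maf, 0.2)
  expect_equal(p$intercept_baseline, 4.6)
  expect_equal(p$beta_T, -0.25)
  expect_equal(p$beta_X, -0.01)
  expect_equal(p$age_range, c(18, 65))
  # the three measurement-error presets
  w <- me_config("white"); s <- me_config("same"); o <- me_config("opposite")
  expect_equal(c(w$mu0, w$mu1), c(0, 0))
  expect_equal(c(s$mu0, s$mu1), c(0.25, 0.25))
  expect_equal(c(o$mu0, o$mu1), c(-0.25, 0.25))
  expect_equal(w$sigma, 0.25)
  expect_false(me_config("none")$enabled)
})

test_that("simulated cohorts are deterministic in the seed and well-formed", {
  p <- sim_params(n_subjects = 500, beta_G0 = 0.1, beta_y0 = -0.2)
  a <- simulate_cohort(p, seed = 7)
  b <- simulate_cohort(p, seed = 7)
  c3 <- simulate_cohort(p, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$y0, c3$y0))
  expect_true(all(a$y0 > 0) && all(a$y1 > 0))
  expect_true(all(a$genotype %in% 0:2))
  expect_equal(nrow(a), 500L)
})

test_that("marginal moments match the generative model at large n", {
  p <- sim_params(n_subjects = 1e5)
  co <- simulate_cohort(p, seed = 1)
  # intercept-only baseline: mean ln y0 within 3 sd/sqrt(n) of 4.6
  expect_lt(abs(mean(log(co$y0)) - 4.6), 3 / sqrt(1e5))
  # allele-count mean near 2*MAF, arm frequency near 1/2
  expect_lt(abs(mean(co$genotype) - 0.4), 3 * sqrt(0.32 / 1e5))
  expect_lt(abs(mean(co$treatment) - 0.5), 3 * sqrt(0.25 / 1e5))
  # residual variance of ln y0 given G near sd_eps0^2 = 1
  r <- resid(lm(log(y0) ~ genotype, data = co))
  expect_lt(abs(var(r) - 1), 0.02)
})

test_that("degenerate noise collapses the baseline onto its mean", {
  co <- simulate_cohort(sim_params(n_subjects = 50, sd_eps0 = 1e-12),
                        seed = 2)
  expect_equal(log(co$y0), rep(4.6, 50), tolerance = 1e-9)
})

test_that("baseline/CFB correlation matches its closed form", {
  # corr(ln y0, CFB) = beta_y0 sd0 / sqrt(beta_y0^2 sd0^2 + sd1^2)
  p <- sim_params(n_subjects = 1e5, beta_y0 = -0.2)
  co <- simulate_cohort(p, seed = 3)
  expected <- -0.2 / sqrt(0.2^2 + 1)
  got <- cor(log(co$y0), log(co$y1) - log(co$y0))
  expect_lt(abs(got - expected), 0.01)
})

test_that("regression on the generating design recovers all coefficients", {
  # intercept raised so the floor-at-1 truncation never binds: the check
  # targets the linear model itself, and at n = 1e5 even a fraction of a
  # percent of floored responses shifts slopes beyond their tiny 3 SE
  p <- sim_params(n_subjects = 1e5, beta_G0 = 0.1, beta_y0 = -0.2,
                  beta_G = 0.1, beta_GT = -0.1, intercept_baseline = 8)
  co <- simulate_cohort(p, seed = 4)
  co$cfb <- log(co$y1) - log(co$y0)
  co$ly0 <- log(co$y0)
  fit <- summary(lm(cfb ~ treatment + age + ly0 + genotype +
                      genotype:treatment, data = co))$coefficients
  truth <- c(treatment = p$beta_T, age = p$beta_X, ly0 = p$beta_y0,
             genotype = p$beta_G, `treatment:genotype` = p$beta_GT)
  for (nm in rownames(fit)[-1]) {
    expect_lt(abs(fit[nm, "Estimate"] - truth[[nm]]),
              3 * fit[nm, "Std. Error"])
  }
})

test_that("measurement error has the configured mean, spread and floor", {
  co <- simulate_cohort(sim_params(n_subjects = 2e4), seed = 5)
  # zero-mean zero-spread error is an exact no-op
  expect_identical(apply_measurement_error(co, me_config(sigma = 0)), co)
  expect_identical(apply_measurement_error(co, me_config("none")), co)
  # same-direction preset scales responses by about 1.25 on average
  obs <- apply_measurement_error(co, me_config("same"), seed = 6)
  expect_lt(abs(mean(obs$y0 / co$y0) - 1.25), 3 * 0.25 / sqrt(2e4))
  expect_identical(co$y0, simulate_cohort(sim_params(n_subjects = 2e4),
                                          seed = 5)$y0)  # input untouched
  # relative errors fall within mu +/- 0.49 with about 95% probability
  r <- obs$y0 / co$y0 - 1
  expect_lt(abs(mean(abs(r - 0.25) < 0.49) - 0.95), 0.01)
  # truncation rule applied by hand: (1 - 0.9) * 0.5 = 0.05 -> floor 1
  tiny <- cohort(y0 = c(0.5, 20), y1 = c(30, 40), treatment = c(0, 1),
                 age = c(30, 40), genotype = c(1, 2))
  fl <- apply_measurement_error(tiny, me_config(mu0 = -0.9, mu1 = 0,
                                                sigma = 0))
  expect_equal(fl$y0[1], 1)
  expect_equal(fl$y0[2], 2)
})

test_that("panel composition bookkeeping and reproducibility hold", {
  expect_error(panel_composition(c(0.5, 0.4)), "sum to 1")
  comp_null <- panel_composition(1)
  pan <- simulate_panel(200, 100, comp_null, seed = 10)
  expect_true(all(pan$truth$beta_G0 == 0 & pan$truth$beta_G == 0 &
                    pan$truth$beta_GT == 0))
  expect_true(all(pan$truth$null_for_cfb))

  comp <- panel_composition(c(0.9, 0.1), beta_G0 = c(0, 0.1))
  pan2 <- simulate_panel(500, 1000, comp, seed = 11)
  expect_equal(sum(pan2$truth$beta_G0 != 0), 100)
  expect_identical(pan2$genotypes,
                   simulate_panel(500, 1000, comp, seed = 11)$genotypes)
  # per-variant empirical allele frequency near its truth maf
  afreq <- colMeans(pan2$genotypes) / 2
  expect_lt(max(abs(afreq - pan2$truth$maf)),
            4 * sqrt(0.2 * 0.8 / (2 * 500)))
  # single-causal rule stores per-variant phenotypes
  expect_true(is.matrix(pan2$y0))
  add <- simulate_panel(500, 50, comp, rule = "additive", seed = 12)
  expect_false(is.matrix(add$y0))
  expect_length(add$y0, 500)
})
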