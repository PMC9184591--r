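test_that("genomic lambda matches its median-based definition", {
  expect_equal(genomic_lambda(c(0.2, 0.5, 0.9)), 1)  # median p exactly 0.5
  # median p = 0.1 -> upper-tail chi-square quantile over the null median
  p <- c(0.05, 0.1, 0.7)
  expect_equal(genomic_lambda(p), qchisq(0.9, 1) / qchisq(0.5, 1))
  expect_error(genomic_lambda(numeric(0)), "empty")
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
  # calibration: uniform p-values give lambda near 1
  set.seed(14)
  expect_lt(abs(genomic_lambda(runif(1e5)) - 1), 0.02)
})

test_that("QQ data uses beta order-statistic bands", {
  set.seed(15)
  p <- runif(2000)
  qq <- qq_data(p)
  m <- length(p)
  k <- c(1, 50, 2000)
  expect_equal(qq$band_lo[k], -log10(qbeta(0.975, k, m + 1 - k)))
  expect_equal(qq$band_hi[k], -log10(qbeta(0.025, k, m + 1 - k)))
  expect_equal(qq$expected, -log10((seq_len(m) - 0.5) / m))
  # uniform sample hugs the diagonal (Kolmogorov-style sup bound on the
  # probability scale) and the null quantiles sit inside their own bands
  expect_lt(max(abs(sort(p) - (seq_len(m) - 0.5) / m)), 2 / sqrt(m))
  expect_true(all(qq$expected >= qq$band_lo & qq$expected <= qq$band_hi))
  # degenerate input
  expect_equal(qq_data(rep(1, 5))$observed, rep(0, 5))
})

test_that("mediator subset selection is threshold-faithful", {
  df <- data.frame(variant_id = c("a", "b", "c"),
                   p_G = c(0.5, 1e-4, 2e-3))
  expect_equal(mediator_subset(df, 1e-3), "b")
  expect_equal(mediator_subset(df, 1), c("a", "b", "c"))
  expect_length(mediator_subset(df, 1e-6), 0)
  expect_error(mediator_subset(df, 0), "threshold")
})

test_that("baseline filtering captures strong baseline variants at the oracle rate", {
  comp <- panel_composition(c(0.9, 0.1), beta_G0 = c(0, 0.3))
  pan <- simulate_panel(1000, 1000, comp, seed = 16)
  gw <- run_gwas(pan, models = "M7")
  flagged <- pan$truth$variant_id[pan$truth$beta_G0 != 0]
  capture <- mean(flagged %in% gw$mediator_subset)
  want <- oracle_power_baseline(0.3, 1000, 0.2, 1e-3)
  expect_gt(capture, 0.9)
  expect_lt(abs(capture - want), 3 * sqrt(want * (1 - want) / 100) + 0.01)
  # null variants enter at roughly the threshold rate
  null_in <- mean(setdiff(pan$truth$variant_id, flagged) %in%
                    gw$mediator_subset)
  expect_lt(null_in, 0.01)
})

test_that("a single-variant scan reduces to the direct model fits", {
  pan <- simulate_panel(400, 1, panel_composition(1, beta_G0 = 0.1),
                        seed = 17)
  gw <- run_gwas(pan, models = c("M1", "M5", "Q"))
  x <- cohort(pan$y0[, 1], pan$y1[, 1], pan$treatment, pan$age,
              pan$genotypes[, 1])
  for (mm in c("M1", "M5", "Q")) {
    direct <- fit_model(x, mm)
    row <- gw$assoc[gw$assoc$model_id == mm, ]
    expect_equal(row$beta_G, direct$beta_G)
    expect_equal(row$primary_p, primary_pvalue(direct))
  }
})

test_that("scans are invariant to variant ordering", {
  pan <- simulate_panel(300, 20, panel_composition(c(0.5, 0.5),
                                                   beta_G0 = c(0, 0.2)),
                        seed = 18)
  perm <- sample(20)
  pan2 <- pan
  pan2$genotypes <- pan$genotypes[, perm]
  pan2$y0 <- pan$y0[, perm]
  pan2$y1 <- pan$y1[, perm]
  pan2$truth <- pan$truth[perm, ]
  a <- run_gwas(pan, models = "M8")$assoc
  b <- run_gwas(pan2, models = "M8")$assoc
  b <- b[match(a$variant_id, b$variant_id), ]
  expect_equal(a$p_G, b$p_G)
})

test_that("loaded tables must align on subject id", {
  pan <- simulate_panel(50, 3, panel_composition(1), rule = "additive",
                        seed = 19)
  ph <- data.frame(subject_id = seq_len(50), y0 = pan$y0, y1 = pan$y1,
                   treatment = pan$treatment, age = pan$age)
  gm <- pan$genotypes
  rownames(gm) <- seq_len(50)
  gw <- run_gwas(NULL, models = "M9", genotypes = gm, phenotype = ph)
  expect_equal(nrow(gw$assoc), 3)
  rownames(gm) <- rev(seq_len(50))
  expect_error(run_gwas(NULL, models = "M9", genotypes = gm,
                        phenotype = ph), "align")
})

test_that("an all-null panel shows no genomic inflation", {
  pan <- simulate_panel(500, 2000, panel_composition(1), seed = 20)
  gw <- run_gwas(pan, models = c("M1", "M9"))
  expect_lt(abs(gw$lambda[["M1"]] - 1), 0.1)
  expect_lt(abs(gw$lambda[["M9"]] - 1), 0.1)
  expect_false(any(gw$assoc$degenerate))
})
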