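# Independent analytic oracles used by the tests. These are deliberately
# closed-form (noncentral-normal approximations) and share no code with the
# package's fitting paths.

# Type-I-error/alpha ratio of a baseline-unadjusted 1df test under a
# mediator-effect null: the genotype slope of the unadjusted residual is
# beta_y0 * beta_G0, giving a noncentral-normal test statistic with shift
# delta = |beta_y0 * beta_G0| sqrt(n Var(G)) / sd(residual).
oracle_unadjusted_ratio <- function(params, alpha) {
  delta <- abs(params$beta_y0 * params$beta_G0) *
    sqrt(params$n_subjects * 2 * params$maf * (1 - params$maf)) /
    sqrt(params$beta_y0^2 * params$sd_eps0^2 + params$sd_eps1^2)
  z <- qnorm(1 - alpha / 2)
  (pnorm(delta - z) + pnorm(-delta - z)) / alpha
}

# Two-sided power of the baseline-association test (M7) at level alpha
oracle_power_baseline <- function(beta_G0, n, maf, alpha, sd_eps0 = 1) {
  delta <- abs(beta_G0) * sqrt(n * 2 * maf * (1 - maf)) / sd_eps0
  z <- qnorm(1 - alpha / 2)
  pnorm(delta - z) + pnorm(-delta - z)
}

# Small fixture cohort with every effect switched on
make_fixture_cohort <- function(n = 400, seed = 99) {
  simulate_cohort(sim_params(n_subjects = n, beta_G0 = 0.1, beta_y0 = -0.2,
                             beta_G = 0.15, beta_GT = -0.1),
                  seed = seed)
}

# Primary p-value matrix for B replicates of one cell under a given engine
# and stream seed (used for engine-equivalence and calibration tests)
replicate_pvalues <- function(params, B, models, seed, engine = "cpp",
                              error_config = me_config("none"),
                              chunk_size = 5000L) {
  streams <- cfbgwas:::.rng_streams(seed, ceiling(B / chunk_size))
  P <- NULL
  done <- 0L
  for (ch in seq_along(streams)) {
    b <- min(chunk_size, B - done)
    done <- done + b
    cfbgwas:::.set_stream(streams[[ch]])
    P <- rbind(P, cfbgwas:::.chunk_primary_p(params, b, models, error_config,
                                             engine))
  }
  colnames(P) <- models
  P
}
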