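# Monte-Carlo estimation of empirical type I error and power over
# parameter x alpha grids, with the margin-of-error inflation criterion.
#
# Randomness flows from one master seed through L'Ecuyer-CMRG streams, one
# per (grid cell, replicate chunk). The chunk size is part of the grid, so
# results do not depend on how chunks are scheduled.

.rng_streams <- function(seed, k) {
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = .GlobalEnv)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  if (is.null(old_seed)) {
    RNGkind("default")
  } else {
    assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }
  out
}

.set_stream <- function(s) assign(".Random.seed", s, envir = .GlobalEnv)

#' Monte-Carlo evaluation grid
#'
#' Bundles the simulation cells, nominal alpha levels, replicate count,
#' measurement-error configuration, model list and seed of one type-I-error
#' or power run.
#'
#' @param params_list One [sim_params()] object or a list of them (the
#'   beta-grid cells).
#' @param alpha_levels Nominal levels in (0, 1); stored in decreasing order.
#' @param n_reps Number of simulation replicates per cell (>= 1).
#' @param models Model ids to evaluate (see [model_ids()]).
#' @param error_config A [me_config()] applied to every replicate.
#' @param seed Master integer seed.
#' @param chunk_size Replicates simulated per RNG stream; a fixed part of
#'   the design so results are invariant to execution order.
#' @return An object of class `cfb_eval_grid`.
#' @seealso [estimate_rates()], [compare_power()]
#' @export
eval_grid <- function(params_list, alpha_levels = c(0.05, 1e-2, 1e-3, 1e-4),
                      n_reps, models, error_config = me_config("none"),
                      seed = 1L, chunk_size = 5000L) {
  if (inherits(params_list, "cfb_sim_params")) params_list <- list(params_list)
  if (!length(params_list) ||
      !all(vapply(params_list, inherits, TRUE, "cfb_sim_params")))
    stopf("params_list must be sim_params() objects")
  if (any(alpha_levels <= 0 | alpha_levels >= 1))
    stopf("alpha_levels must lie in (0, 1)")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stopf("n_reps must be >= 1")
  bad <- setdiff(models, model_ids())
  if (length(bad)) stopf("unknown model id(s): %s", paste(bad, collapse = ", "))
  if (!inherits(error_config, "cfb_me_config"))
    stopf("error_config must come from me_config()")
  structure(list(params_list = params_list,
                 alpha_levels = sort(alpha_levels, decreasing = TRUE),
                 n_reps = n_reps, models = models,
                 error_config = error_config, seed = as.integer(seed),
                 chunk_size = as.integer(chunk_size)),
            class = "cfb_eval_grid")
}

# B replicates of one cell -> B x length(models) matrix of primary p-values.
# The cpp engine uses a fused C++ generator that draws in the same order as
# .simulate_matrices() and is bit-identical to it for the same RNG state.
.chunk_primary_p <- function(params, B, models, error_config,
                             engine = "cpp", int_offset = 3 / 8) {
  sim <- if (engine == "cpp") {
    cpp_simulate_chunk(params$n_subjects, B, params$maf,
                       params$treatment_prob, params$age_range[1],
                       params$age_range[2], params$intercept_baseline,
                       params$beta_G0, params$beta_y0, params$beta_G,
                       params$beta_GT, params$beta_T, params$beta_X,
                       params$sd_eps0, params$sd_eps1, .RESPONSE_FLOOR)
  } else {
    .simulate_matrices(params, B)
  }
  y <- .apply_me_matrices(sim$y0, sim$y1, error_config)
  if (engine == "cpp") {
    cpp_batch_primary_p(y$y0, y$y1, sim$treatment, sim$age, sim$genotype,
                        .MODEL_CODES[models], int_offset)
  } else {
    P <- matrix(NA_real_, B, length(models))
    for (b in seq_len(B)) {
      x <- list(y0 = y$y0[, b], y1 = y$y1[, b], treatment = sim$treatment[, b],
                age = sim$age[, b], genotype = sim$genotype[, b])
      for (k in seq_along(models)) {
        row <- .fit_row(x, models[k], covariates = "age",
                        int_offset = int_offset)
        P[b, k] <- switch(models[k],
                          M5 = , M6 = row$p_2df,
                          Q = row$p_Q,
                          row$p_G)
      }
    }
    P
  }
}

.cell_label <- function(p) {
  data.frame(n_subjects = p$n_subjects, maf = p$maf, beta_G0 = p$beta_G0,
             beta_y0 = p$beta_y0, beta_G = p$beta_G, beta_GT = p$beta_GT)
}

#' Empirical type I error / power rates over a grid
#'
#' For every replicate of every cell: simulate a cohort, apply the
#' measurement-error configuration, fit the requested models and count
#' primary p-values below each nominal level. The Monte-Carlo standard
#' error `mc_se = sqrt(alpha (1 - alpha) / n_reps)` is computed from the
#' nominal level, and a cell is flagged `inflated` when its rate exceeds
#' `alpha + 3 mc_se` (the margin-of-error criterion). For cells simulated
#' under an alternative (`beta_G != 0` or `beta_GT != 0`) the same rate is
#' the empirical power.
#'
#' @param grid An [eval_grid()].
#' @param engine `"cpp"` for the vectorized batch path (default) or `"r"`
#'   for the slow per-replicate reference path used in oracle tests.
#' @param int_offset Rank offset of the inverse normal transform.
#' @return A data frame with one row per (cell, model, alpha): the cell's
#'   beta columns, `model`, `alpha`, `n_reps`, `rate`, `mc_se`, `ratio`
#'   (= rate/alpha) and `inflated`.
#' @export
estimate_rates <- function(grid, engine = c("cpp", "r"), int_offset = 3 / 8) {
  engine <- match.arg(engine)
  if (!inherits(grid, "cfb_eval_grid")) stopf("grid must come from eval_grid()")
  alphas <- grid$alpha_levels
  models <- grid$models
  n_chunks <- ceiling(grid$n_reps / grid$chunk_size)
  streams <- .rng_streams(grid$seed, length(grid$params_list) * n_chunks)
  out <- vector("list", length(grid$params_list))
  for (ci in seq_along(grid$params_list)) {
    cell <- grid$params_list[[ci]]
    counts <- matrix(0, length(models), length(alphas))
    done <- 0L
    for (ch in seq_len(n_chunks)) {
      B <- min(grid$chunk_size, grid$n_reps - done)
      done <- done + B
      .set_stream(streams[[(ci - 1L) * n_chunks + ch]])
      P <- .chunk_primary_p(cell, B, models, grid$error_config, engine,
                            int_offset)
      for (ai in seq_along(alphas))
        counts[, ai] <- counts[, ai] + colSums(P < alphas[ai], na.rm = TRUE)
    }
    rate <- as.vector(t(counts)) / grid$n_reps
    alpha <- rep(alphas, times = length(models))
    mc_se <- sqrt(alpha * (1 - alpha) / grid$n_reps)
    out[[ci]] <- cbind(.cell_label(cell)[rep(1, length(rate)), , drop = FALSE],
                       data.frame(model = rep(models, each = length(alphas)),
                                  alpha = alpha, n_reps = grid$n_reps,
                                  rate = rate, mc_se = mc_se,
                                  ratio = rate / alpha,
                                  inflated = rate > alpha + 3 * mc_se))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Margin-of-error inflation threshold on the rate/alpha scale
#'
#' The ratio `(alpha + 3 SE) / alpha = 1 + 3 sqrt(alpha (1 - alpha) /
#' n_reps) / alpha` above which an empirical rate is declared inflated.
#'
#' @param alpha Nominal level in (0, 1).
#' @param n_reps Number of simulation replicates.
#' @return The threshold ratio (>= 1).
#' @examples
#' inflation_threshold(1e-6, 2e7) # about 1.67
#' @export
inflation_threshold <- function(alpha, n_reps) {
  if (any(alpha <= 0 | alpha >= 1)) stopf("alpha must lie in (0, 1)")
  if (any(n_reps < 1)) stopf("n_reps must be >= 1")
  1 + 3 * sqrt(alpha * (1 - alpha) / n_reps) / alpha
}

#' Paired power comparison of two models
#'
#' Runs both models on the same simulated replicates of every grid cell and
#' reports each model's power at a single nominal level together with the
#' paired Monte-Carlo difference and its standard error (computed from the
#' discordant-rejection counts, which is much tighter than treating the two
#' powers as independent).
#'
#' @param grid An [eval_grid()] whose cells are alternatives
#'   (`beta_G != 0` or `beta_GT != 0`); degenerate null cells simply return
#'   the type I error.
#' @param model_a,model_b Model ids to compare (e.g. a baseline-adjusted
#'   model and its unadjusted counterpart).
#' @param alpha Single nominal level at which power is evaluated.
#' @param engine Batch engine, as in [estimate_rates()].
#' @return A data frame per cell with `power_a`, `power_b`, `diff`
#'   (= power_a - power_b), `se_diff`, `alpha` and `n_reps`.
#' @export
compare_power <- function(grid, model_a, model_b, alpha = 1e-6,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(grid, "cfb_eval_grid")) stopf("grid must come from eval_grid()")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopf("alpha must be a single level in (0, 1)")
  models <- c(model_a, model_b)
  bad <- setdiff(models, model_ids())
  if (length(bad)) stopf("unknown model id(s): %s", paste(bad, collapse = ", "))
  n_chunks <- ceiling(grid$n_reps / grid$chunk_size)
  streams <- .rng_streams(grid$seed, length(grid$params_list) * n_chunks)
  out <- vector("list", length(grid$params_list))
  for (ci in seq_along(grid$params_list)) {
    cell <- grid$params_list[[ci]]
    na <- nb <- nab <- 0
    done <- 0L
    for (ch in seq_len(n_chunks)) {
      B <- min(grid$chunk_size, grid$n_reps - done)
      done <- done + B
      .set_stream(streams[[(ci - 1L) * n_chunks + ch]])
      P <- .chunk_primary_p(cell, B, models, grid$error_config, engine)
      ra <- !is.na(P[, 1]) & P[, 1] < alpha
      rb <- !is.na(P[, 2]) & P[, 2] < alpha
      na <- na + sum(ra)
      nb <- nb + sum(rb)
      nab <- nab + sum(ra & rb)
    }
    N <- grid$n_reps
    pa <- na / N
    pb <- nb / N
    d <- pa - pb
    # paired variance from discordant counts: Var(I_a - I_b)/N
    vd <- (pa + pb - 2 * nab / N - d^2) / N
    out[[ci]] <- cbind(.cell_label(cell),
                       data.frame(model_a = model_a, model_b = model_b,
                                  power_a = pa, power_b = pb, diff = d,
                                  se_diff = sqrt(max(vd, 0)), alpha = alpha,
                                  n_reps = N))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an evaluation grid from a YAML configuration file
#'
#' The file holds `cells` (a list of [sim_params()] argument sets),
#' `alpha_levels`, `n_reps`, `models`, optional `error_config` (a preset
#' name or mu0/mu1/sigma fields), `seed` and `chunk_size`.
#'
#' @param path Path to a YAML file.
#' @return An [eval_grid()].
#' @export
eval_grid_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("cells", "alpha_levels", "n_reps", "models")) {
    if (is.null(cfg[[f]])) stopf("config field '%s' is missing", f)
  }
  cells <- lapply(cfg$cells, function(cl) do.call(sim_params, cl))
  ec <- cfg$error_config %||% "none"
  error_config <- if (is.character(ec)) me_config(preset = ec)
  else do.call(me_config, ec)
  eval_grid(cells, alpha_levels = as.numeric(cfg$alpha_levels),
            n_reps = cfg$n_reps, models = as.character(cfg$models),
            error_config = error_config, seed = cfg$seed %||% 1L,
            chunk_size = cfg$chunk_size %||% 5000L)
}
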