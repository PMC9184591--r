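# Per-variant genome scans and their diagnostics: genomic inflation factor,
# QQ data, and the baseline-associated ("mediator-enriched") variant subset.

#' Genomic inflation factor (lambda)
#'
#' Median-based estimator: the observed p-values are converted to 1-df
#' chi-square statistics and the median observed statistic is divided by the
#' null chi-square median (about 0.455). Calibrated tests give lambda close
#' to 1.
#'
#' @param p Non-empty vector of p-values in (0, 1].
#' @return The scalar lambda.
#' @examples
#' genomic_lambda(c(0.2, 0.5, 0.9)) # median p = 0.5 -> lambda = 1
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stopf("cannot compute lambda on an empty p-value vector")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Variants with evidence of baseline association
#'
#' Selects the variant ids whose baseline-association p-value (model M7)
#' falls below a threshold. Under a negative baseline-CFB dependence these
#' variants are the ones where a mediator effect, and hence inflation of
#' baseline-unadjusted tests, is expected.
#'
#' @param baseline Data frame with columns `variant_id` and `p_G` (e.g. the
#'   M7 rows of a [run_gwas()] association table).
#' @param threshold p-value cutoff in (0, 1); default 1e-3.
#' @return Character vector of variant ids.
#' @export
mediator_subset <- function(baseline, threshold = 1e-3) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  if (!all(c("variant_id", "p_G") %in% names(baseline)))
    stopf("baseline must have columns variant_id and p_G")
  baseline$variant_id[!is.na(baseline$p_G) & baseline$p_G < threshold]
}

#' Expected/observed QQ data with a null confidence band
#'
#' Sorted observed -log10 p-values against the expected -log10 quantiles of
#' uniform order statistics, plus a pointwise confidence band from the
#' Beta(k, m + 1 - k) distribution of the k-th order statistic.
#'
#' @param p Non-empty vector of p-values in (0, 1].
#' @param level Band coverage (default 0.95).
#' @return A data frame with columns `rank`, `expected`, `observed`,
#'   `band_lo`, `band_hi` (all on the -log10 scale).
#' @export
qq_data <- function(p, level = 0.95) {
  p <- p[!is.na(p)]
  if (!length(p)) stopf("cannot build QQ data from an empty p-value vector")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(p)
  k <- seq_len(m)
  a <- (1 - level) / 2
  data.frame(rank = k,
             expected = -log10((k - 0.5) / m),
             observed = -log10(sort(p)),
             band_lo = -log10(qbeta(1 - a, k, m + 1 - k)),
             band_hi = -log10(qbeta(a, k, m + 1 - k)))
}

#' Run the model suite across a variant panel
#'
#' Fits each requested model to every variant and assembles the association
#' table, per-model genomic inflation factors, the baseline-associated
#' variant subset (from the baseline model at `baseline_threshold`) and the
#' per-model inflation factors restricted to that subset. Monomorphic
#' variants are flagged degenerate with p = 1 rather than aborting the scan.
#' The computation is deterministic given the panel.
#'
#' @param panel A [simulate_panel()] object, or `NULL` when `genotypes` and
#'   `phenotype` tables are supplied instead.
#' @param models Model ids to fit.
#' @param genotypes Subjects-by-variants dosage matrix with subject ids as
#'   row names (used when `panel` is `NULL`).
#' @param phenotype Data frame with columns `subject_id`, `y0`, `y1`,
#'   `treatment`, `age` (plus any extra covariates), aligned to `genotypes`
#'   by `subject_id`.
#' @param covariates Covariate column names (default `"age"`).
#' @param baseline_model Model providing the baseline-association p-values
#'   (default `"M7"`); the subset is only formed when it is among `models`.
#' @param baseline_threshold Subset p-value cutoff (default 1e-3).
#' @return A list of class `cfb_gwas` with elements `assoc` (one row per
#'   variant per model), `lambda` (named per model), `mediator_subset`
#'   (variant ids), `lambda_subset` (named per model, `NA` for the baseline
#'   model and when the subset is empty), and `baseline_threshold`.
#' @export
run_gwas <- function(panel = NULL, models = c("M1", "M3", "M7"),
                     genotypes = NULL, phenotype = NULL, covariates = "age",
                     baseline_model = "M7", baseline_threshold = 1e-3) {
  bad <- setdiff(models, model_ids())
  if (length(bad)) stopf("unknown model id(s): %s", paste(bad, collapse = ", "))
  if (is.null(panel)) {
    if (is.null(genotypes) || is.null(phenotype))
      stopf("supply either a panel or both genotypes and phenotype")
    ids <- rownames(genotypes)
    if (is.null(ids) || is.null(phenotype$subject_id) ||
        !identical(as.character(ids), as.character(phenotype$subject_id)))
      stopf(paste("subject ids of the genotype matrix and phenotype table",
                  "do not align"))
    if (is.null(colnames(genotypes)))
      colnames(genotypes) <- sprintf("v%05d", seq_len(ncol(genotypes)))
    panel <- structure(list(genotypes = as.matrix(genotypes),
                            y0 = phenotype$y0, y1 = phenotype$y1,
                            treatment = phenotype$treatment,
                            age = phenotype$age, truth = NULL,
                            rule = "loaded"),
                       class = "cfb_panel")
    for (cv in setdiff(covariates, "age")) panel[[cv]] <- phenotype[[cv]]
  }
  m <- ncol(panel$genotypes)
  vids <- colnames(panel$genotypes)
  nm <- length(models)
  rows <- vector("list", m * nm)
  for (v in seq_len(m)) {
    x <- .panel_cohort(panel, v)
    for (cv in setdiff(covariates, "age")) x[[cv]] <- panel[[cv]]
    for (k in seq_len(nm)) {
      rows[[(v - 1L) * nm + k]] <- .fit_row(x, models[k], covariates)
    }
  }
  num_cols <- c("beta_y0", "se_y0", "beta_G", "se_G", "p_G", "beta_GT",
                "se_GT", "p_GT", "p_2df", "q_stat", "p_Q")
  assoc <- data.frame(variant_id = rep(vids, each = nm),
                      model_id = rep(models, times = m))
  for (cc in num_cols)
    assoc[[cc]] <- vapply(rows, function(r) as.numeric(r[[cc]]), 0)
  assoc$n_used <- vapply(rows, function(r) as.integer(r$n_used), 0L)
  assoc$degenerate <- vapply(rows, function(r) isTRUE(r$degenerate), TRUE)
  assoc$primary_p <- primary_pvalue(assoc)

  lambda <- vapply(models, function(mm)
    genomic_lambda(assoc$primary_p[assoc$model_id == mm]), 0)
  subset_ids <- character(0)
  lambda_subset <- setNames(rep(NA_real_, nm), models)
  if (baseline_model %in% models) {
    subset_ids <- mediator_subset(
      assoc[assoc$model_id == baseline_model, c("variant_id", "p_G")],
      baseline_threshold)
    if (length(subset_ids)) {
      on_sub <- assoc$variant_id %in% subset_ids
      for (mm in setdiff(models, baseline_model))
        lambda_subset[mm] <- genomic_lambda(
          assoc$primary_p[on_sub & assoc$model_id == mm])
    }
  }
  structure(list(assoc = assoc, lambda = lambda,
                 mediator_subset = subset_ids,
                 lambda_subset = lambda_subset,
                 baseline_threshold = baseline_threshold),
            class = "cfb_gwas")
}

#' @export
print.cfb_gwas <- function(x, ...) {
  nv <- length(unique(x$assoc$variant_id))
  cat(sprintf("cfb_gwas: %d variants, models %s\n", nv,
              paste(names(x$lambda), collapse = ", ")))
  cat("  lambda:", paste(sprintf("%s=%.3f", names(x$lambda), x$lambda),
                         collapse = " "), "\n")
  cat(sprintf("  baseline-associated subset (p < %g): %d variants\n",
              x$baseline_threshold, length(x$mediator_subset)))
  ls <- x$lambda_subset[!is.na(x$lambda_subset)]
  if (length(ls))
    cat("  subset lambda:", paste(sprintf("%s=%.3f", names(ls), ls),
                                  collapse = " "), "\n")
  invisible(x)
}
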