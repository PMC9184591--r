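# Base-graphics diagnostics: QQ plots with the order-statistic band and
# type-I-error ratio curves against the nominal level.

#' QQ plot of association p-values
#'
#' Draws observed versus expected -log10 p with the pointwise beta
#' order-statistic band as a grey polygon and the diagonal in red.
#'
#' @param p Vector of p-values in (0, 1], or a data frame from [qq_data()].
#' @param level Band coverage when `p` is a raw vector.
#' @param main Plot title.
#' @param file Optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @return The [qq_data()] frame, invisibly.
#' @export
plot_qq <- function(p, level = 0.95, main = "QQ plot", file = NULL) {
  qq <- if (is.data.frame(p)) p else qq_data(p, level)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 150)
    on.exit(grDevices::dev.off())
  }
  ok <- is.finite(qq$observed)
  plot(qq$expected, pmin(qq$observed, max(qq$observed[ok])), type = "n",
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), main = main)
  graphics::polygon(c(qq$expected, rev(qq$expected)),
                    c(qq$band_lo, rev(qq$band_hi)),
                    col = "grey85", border = NA)
  graphics::abline(0, 1, col = "red")
  graphics::points(qq$expected, qq$observed, pch = 20, cex = 0.5)
  invisible(qq)
}

#' Ratio of empirical rate to nominal level across the alpha grid
#'
#' One curve per model of `rate / alpha` against `-log10(alpha)`, with the
#' margin-of-error criterion `1 + 3 SE / alpha` as a dashed line. Solid
#' lines are conventionally the baseline-adjusted models and dotted lines
#' the unadjusted ones; here adjusted models are drawn solid and
#' unadjusted dotted automatically from the model registry.
#'
#' @param rates Output of [estimate_rates()] (a single cell's rows).
#' @param file Optional PNG path.
#' @return `rates`, invisibly.
#' @export
plot_rates <- function(rates, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1100, height = 800, res = 150)
    on.exit(grDevices::dev.off())
  }
  models <- unique(rates$model)
  x <- -log10(rates$alpha)
  plot(range(x), range(c(rates$ratio, 1.8), finite = TRUE), type = "n",
       xlab = expression(-log[10](alpha)), ylab = "empirical rate / alpha",
       main = "Type I error inflation")
  crit <- 1 + 3 * sqrt(rates$alpha * (1 - rates$alpha) / rates$n_reps) /
    rates$alpha
  graphics::lines(sort(unique(x)),
                  tapply(crit, x, max)[as.character(sort(unique(x)))],
                  lty = 2, col = "grey40")
  for (i in seq_along(models)) {
    sel <- rates$model == models[i]
    adj <- isTRUE(model_spec(models[i])$baseline_adjusted)
    graphics::lines(x[sel], rates$ratio[sel], col = i,
                    lty = if (adj) 1 else 3)
    graphics::points(x[sel], rates$ratio[sel], col = i, pch = 20)
  }
  graphics::legend("topleft", legend = models, col = seq_along(models),
                   lty = vapply(models, function(m)
                     if (isTRUE(model_spec(m)$baseline_adjusted)) 1 else 3,
                     0), bty = "n")
  invisible(rates)
}
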