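#' Plot a permutation null sample with its fitted GEV density
#'
#' @param object A `gps_null` from [permutation_null()].
#' @param fit Optional `gev_fit`; fitted on the fly when omitted.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot: histogram of null GPS statistics with the fitted GEV
#'   density overlaid.
#' @export
autoplot.gps_null <- function(object, fit = NULL, bins = 50, ...) {
  if (is.null(fit)) fit <- fit_gev(object)
  df <- tibble::tibble(D = object$d_values)
  est <- fit$estimate
  grid <- tibble::tibble(
    D = seq(min(df$D), max(df$D), length.out = 400)
  )
  grid$density <- dgev(grid$D, est[["a"]], est[["b"]], est[["c"]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$density),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "null GPS statistic D",
      y = "density",
      title = sprintf("Permutation null (n_perm = %d) with fitted GEV(%.3f, %.3f, %.3f)",
                      object$n_perm, est[["a"]], est[["b"]], est[["c"]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a simulation experiment
#'
#' @param object A `gps_experiment` tibble from [run_type1_experiment()] or
#'   [run_power_experiment()].
#' @param x Name of the scenario column for the x-axis (default `n_shared`
#'   if present and varying, else `rho`).
#' @param ... Unused.
#' @return A ggplot of rejection rate vs the chosen scenario variable with
#'   Wilson 95% error bars, one colour per method.
#' @export
autoplot.gps_experiment <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    x <- if ("n_shared" %in% names(object) &&
             length(unique(object$n_shared)) > 1) "n_shared" else "rho"
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$rejection_rate,
                               colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$wilson_lo, ymax = .data$wilson_hi),
      width = 0, position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dotted") +
    ggplot2::labs(y = "rejection rate at alpha = 0.05") +
    ggplot2::theme_minimal()
}

#' Scatter a harmonized pair on the -log10 scale
#'
#' @param object A `gps_pair`.
#' @param highlight_argmax Mark the variant attaining the GPS supremum.
#' @param ... Unused.
#' @return A ggplot of paired -log10 p-values.
#' @export
autoplot.gps_pair <- function(object, highlight_argmax = TRUE, ...) {
  df <- tibble::tibble(x = -log10(object$p_a), y = -log10(object$p_b))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "-log10 p (trait 1)", y = "-log10 p (trait 2)") +
    ggplot2::theme_minimal()
  if (highlight_argmax && nrow(object) >= 5) {
    res <- gps_statistic(object)
    p <- p + ggplot2::annotate(
      "point", x = -log10(object$p_a[res$argmax_index]),
      y = -log10(object$p_b[res$argmax_index]),
      colour = "red", shape = 1, size = 3)
  }
  p
}
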