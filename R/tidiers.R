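#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the parameter estimates of a binding-model fit
#'
#' @param x An `emsa_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   whether the estimate sits on a box bound.
#' @method tidy emsa_fit
#' @export
tidy.emsa_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("kd_nM", "C", "f"),
    estimate = c(p$kd_nM, p$C, p$f),
    at_bound = c("kd_nM", "C", "f") %in% x$at_bound
  )
}

#' One-row summary of a binding-model fit
#'
#' @param x An `emsa_fit`.
#' @param ... Unused.
#' @return A one-row tibble: condition, estimates, second-site Kd, SSR,
#'   residual count, convergence flag and multistart count.
#' @method glance emsa_fit
#' @export
glance.emsa_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    condition = x$condition, kd_nM = p$kd_nM, C = p$C, f = p$f,
    kd2_nM = p$kd2_nM, ssr = x$ssr, n_points = x$n_points,
    converged = x$converged, n_starts = x$n_starts
  )
}

#' Tidy bootstrap confidence intervals
#'
#' @param x An `emsa_boot`.
#' @param ... Unused.
#' @return A tibble with `term`, point `estimate`, and percentile
#'   `lower`/`upper` bounds at the stored level.
#' @method tidy emsa_boot
#' @export
tidy.emsa_boot <- function(x, ...) {
  p <- x$point
  dplyr::mutate(x$ci,
                estimate = c(p$kd_nM, p$C, p$f),
                .after = "term")
}

#' One-row summary of a bootstrap run
#'
#' @param x An `emsa_boot`.
#' @param ... Unused.
#' @return A one-row tibble: condition, resample counts, failure count,
#'   seed and confidence level.
#' @method glance emsa_boot
#' @export
glance.emsa_boot <- function(x, ...) {
  tibble::tibble(condition = x$condition, n_boot = x$n_boot,
                 n_failed = x$n_failed, seed = x$seed, level = x$level)
}

#' Occupancy plot for a fitted titration
#'
#' Plots the observed mean sites filled (`p1 + 2 p2`, averaged over
#' replicates, with SD error bars) against complex concentration on a log
#' axis, overlaid with the fitted mixture-model curve. The dashed line
#' marks the saturation asymptote `1 + f`.
#'
#' @param object An `emsa_fit`.
#' @param n_curve Number of points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emsa_fit
#' @export
autoplot.emsa_fit <- function(object, n_curve = 200, ...) {
  summ <- summarize_replicates(object$data) |>
    dplyr::mutate(
      filled = .data$mean1 + 2 * .data$mean2,
      filled_sd = sqrt(.data$sd1^2 + 4 * .data$sd2^2)
    )
  p <- object$params
  conc_range <- range(object$data$conc_nM[object$data$conc_nM > 0])
  curve <- tibble::tibble(
    conc_nM = 10^seq(log10(conc_range[1L] / 2), log10(conc_range[2L] * 2),
                     length.out = n_curve)
  )
  curve$filled <- mean_sites_filled(curve$conc_nM / p$kd_nM, p$C, p$f)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$conc_nM, y = .data$filled)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$filled - .data$filled_sd,
                   ymax = .data$filled + .data$filled_sd),
      width = 0.05, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1 + p$f, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      title = object$condition,
      subtitle = sprintf("Kd = %.3g nM, C = %.3g, f = %.3g",
                         p$kd_nM, p$C, p$f),
      x = "complex concentration (nM)", y = "mean sites filled"
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution plot
#'
#' Histograms of the resampled estimates for each parameter with the
#' percentile interval bounds and the point estimate marked.
#'
#' @param object An `emsa_boot`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @method autoplot emsa_boot
#' @export
autoplot.emsa_boot <- function(object, bins = 40, ...) {
  long <- tidyr::pivot_longer(object$estimates, dplyr::everything(),
                              names_to = "term", values_to = "estimate")
  marks <- tidy.emsa_boot(object) |>
    tidyr::pivot_longer(c("estimate", "lower", "upper"),
                        names_to = "what", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$what),
      colour = "grey30"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(estimate = "solid", lower = "dashed", upper = "dashed"),
      guide = "none"
    ) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(
      title = sprintf("%s: %d bootstrap resamples, %.0f%% percentile CI",
                      object$condition, object$n_boot - object$n_failed,
                      100 * object$level),
      x = "resampled estimate", y = "count"
    ) +
    ggplot2::theme_minimal()
}
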