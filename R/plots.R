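#' Plot probit points and the fitted line
#'
#' Diagnostic plot of one participant x condition fit: probit-transformed
#' response proportions against SOA with the fitted regression line and the
#' PSS marked at the zero crossing. Requires ggplot2.
#'
#' @param points A [probit_points()] table.
#' @param fit Optional [fit_probit_line()] result for the same points.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(points, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_psychometric() requires ggplot2")
  }
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$soa, y = .data$probit)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_trials), alpha = 0.8) +
    ggplot2::labs(
      x = "SOA (ms)", y = "probit of response proportion",
      size = "trials"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$identifiable)) {
    p <- p +
      ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope) +
      ggplot2::geom_vline(xintercept = fit$pss, linetype = "dashed")
  }
  p
}

#' Plot the normalised RT-by-SOA profile
#'
#' Mean normalised reaction time per SOA with the fitted Gaussian bump, the
#' diagnostic counterpart of the RT-peak analysis.
#'
#' @param rt_trials Output of [normalize_rt()] restricted to one participant
#'   (or any set of trials to pool).
#' @param fit Optional [fit_rt_peak()] result.
#' @return A ggplot object.
#' @export
plot_rt_profile <- function(rt_trials, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rt_profile() requires ggplot2")
  }
  prof <- dplyr::summarise(
    dplyr::group_by(rt_trials, soa = .data$soa_visual),
    mean_rt_z = mean(.data$rt_z), n = dplyr::n(), .groups = "drop"
  )
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$soa, y = .data$mean_rt_z)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::labs(x = "visual-first SOA (ms)", y = "normalised RT (z)",
                  size = "trials") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(min(prof$soa), max(prof$soa), length.out = 200)
    curve <- tibble::tibble(
      soa = grid,
      mean_rt_z = fit$baseline + fit$amplitude *
        exp(-(grid - fit$peak_soa)^2 / (2 * fit$width^2))
    )
    p <- p + ggplot2::geom_line(data = curve) +
      ggplot2::geom_vline(xintercept = fit$peak_soa, linetype = "dashed")
  }
  p
}
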