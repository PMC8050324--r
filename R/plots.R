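## Loop and distribution figures.

#' Plot one site-year's flux-temperature hysteresis loop
#'
#' Daily points coloured by branch with the fitted earlier (red), later
#' (blue) and full-season (black) anchored quadratic curves.
#'
#' @param result A \code{hysteresis_result}.
#' @return A ggplot object.
#' @export
plot_hysteresis_loop <- function(result) {
  days <- result$day_table
  tt <- seq(0, result$season$t_max, length.out = 200)
  curves <- dplyr::bind_rows(
    tibble::tibble(branch = "earlier", t = tt,
                   f = eval_curve(result$fit_earlier, tt)),
    tibble::tibble(branch = "later", t = tt,
                   f = eval_curve(result$fit_later, tt)),
    tibble::tibble(branch = "full", t = tt,
                   f = eval_curve(result$fit_full, tt)))
  cols <- c(earlier = "#c0392b", later = "#2e6da4", full = "black")
  ggplot2::ggplot(days, ggplot2::aes(x = .data$t, y = .data$f_ch4,
                                     colour = .data$branch)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$f, colour = .data$branch),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(
      x = sprintf("%s (degC)", result$driver),
      y = expression(F[CH4] ~ (mg ~ C ~ m^-2 ~ d^-1)),
      title = sprintf("%s %s: H_A = %+.3f, H_mu = %+.2f", result$site_id,
                      result$season_year, result$h_area, result$h_mu)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of a hysteresis statistic across site-years
#'
#' @param summary Tibble from [siteyear_summary()].
#' @param metric \code{"h_area"} or \code{"h_mu"}.
#' @return A ggplot object.
#' @export
plot_h_distribution <- function(summary, metric = c("h_area", "h_mu")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(summary, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 30, fill = "#2e6da4", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, colour = "#c0392b",
                        linetype = "dashed") +
    ggplot2::labs(x = metric,
                  y = "site-years",
                  title = sprintf("%.0f%% of site-years positive",
                                  100 * mean(summary[[metric]] > 0))) +
    ggplot2::theme_minimal()
}
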