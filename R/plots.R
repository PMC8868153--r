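#' Per-trait annual genetic gain across scenarios
#'
#' Bar chart of the per-trait annual genetic gain in additive-standard-
#' deviation units, facetted by scheme and phenotyping intensity and
#' coloured by breeding goal.
#'
#' @param results List of [run_scenario()] results.
#' @return A ggplot object.
#' @export
plot_genetic_gain <- function(results) {
  long <- dplyr::bind_rows(purrr::map(results, function(x) {
    s <- x$summary
    s <- s[grepl("^gain_sd_", s$metric), ]
    tibble::tibble(
      scheme = x$scheme, intensity = paste0(100 * x$intensity, "%"),
      goal = x$goal, trait = sub("^gain_sd_", "", s$metric),
      gain = s$mean, se = s$se
    )
  }))
  long$trait <- factor(long$trait, levels = unique(long$trait))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$gain,
                                     fill = .data$goal)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gain - .data$se, ymax = .data$gain + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3,
      linewidth = 0.3
    ) +
    ggplot2::facet_grid(intensity ~ scheme) +
    ggplot2::labs(x = NULL, y = "annual genetic gain (additive SD units)",
                  fill = "breeding goal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn run_replicate Trajectory plot: mean inbreeding per line over
#'   the simulated years.
#' @param object A `replicate_result`.
#' @param ... Unused.
#' @method autoplot replicate_result
#' @export
autoplot.replicate_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$year, y = .data$mean_f,
                               colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "mean inbreeding coefficient",
                  colour = "line") +
    ggplot2::theme_minimal()
}

#' @describeIn run_scenario Endpoint plot: total gain against inbreeding
#'   rate with replicate scatter.
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$per_replicate,
                  ggplot2::aes(x = .data$dF_pct, y = .data$gain_total)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "rate of inbreeding (% per generation)",
      y = "annual genetic gain (EUR per pig)",
      title = paste0(object$scheme, " / ", object$goal, " / ",
                     100 * object$intensity, "% phenotyped")
    ) +
    ggplot2::theme_minimal()
}
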