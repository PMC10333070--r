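#' Consensus CDF curves across k
#'
#' The empirical CDF of the upper-triangle consensus indices for each k; a
#' flat middle (mass concentrated near 0 and 1) indicates a stable
#' clustering, and the PAC criterion is the CDF mass between 0.1 and 0.9.
#'
#' @param sweep A [consensus_sweep()] result.
#' @return A ggplot object.
#' @export
plot_consensus_cdf <- function(sweep) {
  stopifnot(inherits(sweep, "wm_consensus_sweep"))
  df <- purrr::map_dfr(sweep, function(r) {
    dplyr::mutate(r$cdf, k = factor(r$k))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cdf,
                                   colour = .data$k)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = c(0.1, 0.9), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "consensus index", y = "CDF",
                  title = "Consensus CDF by number of clusters") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' @param time,event Survival data.
#' @param group Grouping vector (e.g. high/low score groups).
#' @return A ggplot object with one step curve per group.
#' @export
plot_km_curves <- function(time, event, group) {
  group <- factor(group)
  df <- purrr::map_dfr(levels(group), function(g) {
    km <- km_estimate(time[group == g], event[group == g])
    tibble::tibble(time = c(0, km$time), survival = c(1, km$survival),
                   group = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Score distribution plot for a scored cohort
#'
#' Histogram of the per-patient score; if a cutpoint has been applied it is
#' drawn as a vertical line with groups coloured.
#'
#' @param object A `wm_scored` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_scored <- function(object, ...) {
  df <- object$scores
  p <- if (!is.null(df$group)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$wm_score, fill = .data$group))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$wm_score))
  }
  p <- p + ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "WM_Score", y = "patients") +
    ggplot2::theme_minimal()
  if (!is.null(object$cutpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cutpoint,
                                 linetype = "dashed")
  }
  p
}
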