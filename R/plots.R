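#' Plot a Markov cohort trace
#'
#' State occupancy over time for the three health states.
#'
#' @param object A `markov_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.markov_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "t", "n_pfs", "n_pd", "n_death"),
    -"t",
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state,
    levels = c("n_pfs", "n_pd", "n_death"),
    labels = c("Progression-free", "Progressed", "Dead")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$occupancy, colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Time (months)", y = "Cohort fraction", colour = NULL,
      title = "Markov cohort trace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted survival curves against the Kaplan-Meier estimate
#'
#' @param object A `fit_selection` from [select_best()].
#' @param ipd Optional individual-patient data to overlay the KM step.
#' @param horizon Plot horizon in months.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fit_selection <- function(object, ipd = NULL, horizon = 60, ...) {
  grid <- seq(0, horizon, length.out = 200)
  curves <- purrr::map_dfr(object$fits, function(f) {
    if (!f$converged) {
      return(tibble())
    }
    tibble(family = f$family, t = grid, survival = surv_prob(f$dist, grid))
  })
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$t, .data$survival)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$family,
      linewidth = .data$family == object$best_family
    )) +
    ggplot2::scale_linewidth_manual(values = c(0.4, 1.1), guide = "none") +
    ggplot2::labs(
      x = "Time (months)", y = "Survival fraction", colour = "Family",
      title = sprintf("Parametric fits (best by AIC: %s)", object$best_family)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(ipd)) {
    km <- km_estimate(ipd)
    p <- p + ggplot2::geom_step(
      data = km, ggplot2::aes(.data$time, .data$survival),
      colour = "black", linetype = 2
    )
  }
  p
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param object A `tornado` tibble from [one_way()].
#' @param top Number of parameters to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tornado <- function(object, top = 10, ...) {
  dat <- utils::head(object, top)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$icer_at_low, xend = .data$icer_at_high,
        y = .data$parameter, yend = .data$parameter
      ),
      linewidth = 5, colour = "steelblue"
    ) +
    ggplot2::geom_vline(
      ggplot2::aes(xintercept = .data$icer_base),
      linetype = 2
    ) +
    ggplot2::labs(
      x = "ICER ($/QALY)", y = NULL,
      title = "One-way sensitivity (tornado)"
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param wtp_line Optional willingness-to-pay threshold to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ceac_curve <- function(object, wtp_line = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay ($/QALY)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(wtp_line)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_line, linetype = 2)
  }
  p
}

#' Cost-effectiveness plane of PSA samples
#'
#' @param object A `psa_samples` tibble from [psa()].
#' @param wtp Willingness-to-pay threshold drawn as a line through the
#'   origin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_samples <- function(object, wtp = 30828, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost ($)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}
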