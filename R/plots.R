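#' Plot a time-activity curve
#'
#' Quick QC plot of one or more TACs on a log-scaled time axis, the
#' natural scale for a protocol spanning minutes to days.
#'
#' @param tacs a data frame with `t_start`, `t_end`, `conc` and
#'   optionally `region` / `subject_id` columns.
#' @return A ggplot object.
#' @export
plot_tac <- function(tacs) {
  sched <- validate_schedule(tacs)
  aes_extra <- if ("region" %in% names(sched)) {
    ggplot2::aes(x = .data$t_mid, y = .data$conc, colour = .data$region)
  } else {
    ggplot2::aes(x = .data$t_mid, y = .data$conc)
  }
  p <- ggplot2::ggplot(sched, aes_extra) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time post-injection (min)",
                  y = "concentration (kBq/ml)")
  if ("subject_id" %in% names(sched)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$subject_id))
  }
  p
}

#' @export
autoplot.triexp_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$conc)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time post-injection (min)",
                  y = "whole-blood concentration (kBq/ml)",
                  title = "Triexponential input-function fit")
}

#' @export
autoplot.kinetic_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$conc)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time post-injection (min)",
                  y = "concentration (kBq/ml)",
                  title = paste(object$model, "compartmental fit"))
}

#' @export
autoplot.patlak_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$in_window)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "red") +
    ggplot2::labs(x = "normalized time (min)", y = "tissue-to-blood ratio",
                  title = "Patlak plot", colour = "in window")
}

#' @export
autoplot.identifiability_report <- function(object, ...) {
  ggplot2::ggplot(
    tidyr::drop_na(object$sensitivity, "sensitivity"),
    ggplot2::aes(x = .data$t_mid, y = .data$sensitivity,
                 colour = .data$parameter)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time post-injection (min)",
                  y = "normalized sensitivity",
                  title = "Normalized sensitivity curves")
}
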