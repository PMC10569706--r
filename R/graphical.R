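#' Tissue-to-blood ratio curve
#'
#' Element-wise ratio of the regional concentration to the whole-blood
#' concentration on the same frames, \eqn{TBR_i = C_{T,i} / C_{p,i}}.
#' Frames where the blood value falls below a positivity floor are
#' masked (`NA`) rather than divided through.
#'
#' @param tissue,blood frame-aligned data frames with `t_start`, `t_end`
#'   and `conc` columns.
#' @param floor blood positivity floor in kBq/ml.
#' @return The tissue tibble with a `tbr` column (and `conc_blood`).
#' @export
tbr <- function(tissue, blood, floor = 1e-9) {
  ts <- validate_schedule(tissue)
  bs <- validate_schedule(blood)
  if (nrow(ts) != nrow(bs) ||
      max(abs(ts$t_start - bs$t_start)) > 1e-9 ||
      max(abs(ts$t_end - bs$t_end)) > 1e-9) {
    stop("tissue and blood TACs must be frame-aligned", call. = FALSE)
  }
  dplyr::mutate(ts,
    conc_blood = bs$conc,
    tbr = ifelse(bs$conc > floor, .data$conc / bs$conc, NA_real_)
  )
}

#' Patlak graphical analysis
#'
#' Linearises an (effectively) irreversible uptake process by plotting
#' the tissue-to-blood ratio against normalized time
#' \eqn{x(t) = \int_0^t C_p d\tau / C_p(t)}: for an irreversible tracer
#' the late-time slope estimates the net influx rate Ki. Both the
#' abscissa and the blood denominator use the fitted multiexponential
#' input function evaluated at frame midpoints, not the raw blood
#' frames. The equilibrium (linearity) time cannot be determined from a
#' protocol with only two late points, so the fitting window is an
#' explicit argument, not an automatic choice.
#'
#' @param tissue a data frame with `t_start`, `t_end`, `conc`.
#' @param input a [blood_curve()].
#' @param window_start_min only frames with midpoint at or after this
#'   time (minutes) enter the ordinary least-squares line (default 30).
#' @return An object of class `patlak_fit`: `$slope` (the Ki estimate,
#'   ml/cm^3/min), `$intercept`, and `$points`, a tibble of per-frame
#'   `(t_mid, x, y, in_window)`. `tidy()`/`glance()`/`autoplot()`
#'   methods are available.
#' @export
patlak <- function(tissue, input, window_start_min = 30) {
  stopifnot(inherits(input, "blood_curve"))
  sched <- validate_schedule(tissue)
  cp <- eval_blood(input, sched$t_mid)
  if (any(cp <= 0)) stop("input curve must be positive on all frames", call. = FALSE)
  x <- integral_blood(input, sched$t_mid) / cp
  y <- sched$conc / cp
  in_window <- sched$t_mid >= window_start_min
  if (sum(in_window) < 2) {
    stop("Patlak window must contain at least 2 frames", call. = FALSE)
  }
  ols <- stats::lm(y ~ x, subset = in_window)
  structure(
    list(
      slope = unname(stats::coef(ols)[2]),
      intercept = unname(stats::coef(ols)[1]),
      window_start_min = window_start_min,
      points = tibble::tibble(t_mid = sched$t_mid, x = x, y = y,
                              in_window = in_window),
      ols = ols
    ),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("<patlak_fit> slope (Ki est.) ", format(x$slope),
      " ml/cm^3/min, intercept ", format(x$intercept),
      " (window from ", x$window_start_min, " min, ",
      sum(x$points$in_window), " frames)\n", sep = "")
  invisible(x)
}

#' @export
tidy.patlak_fit <- function(x, ...) {
  s <- summary(x$ols)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"])
  )
}

#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    window_start_min = x$window_start_min,
    n_window = sum(x$points$in_window),
    r.squared = summary(x$ols)$r.squared
  )
}

#' Percentage change between two late time points
#'
#' \eqn{100 (v_{late} - v_{early}) / v_{early}}, e.g. the change of SUV
#' or TBR at the 48-hour time point relative to the 6-hour time point.
#'
#' @param value_late,value_early values at the later and earlier time
#'   points; `value_early` must be non-zero.
#' @return Percentage change; vectorised.
#' @examples
#' percent_change(0.6, 0.8) # -25
#' @export
percent_change <- function(value_late, value_early) {
  if (any(value_early == 0)) {
    stop("percentage change undefined for a zero baseline", call. = FALSE)
  }
  100 * (value_late - value_early) / value_early
}
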