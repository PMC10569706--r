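#' Multiexponential whole-blood input function
#'
#' A whole-blood clearance curve of the form
#' \deqn{C_p(t) = \sum_j A_j e^{-\lambda_j t}}
#' with non-negative amplitudes (kBq/ml) and rate constants (1/min).
#' For an 89Zr-labelled minibody the clearance is well described by a
#' triexponential with half-lives on the scale of minutes (distribution),
#' tens of minutes (intermediate) and tens of hours (terminal
#' elimination). With non-negative amplitudes the curve is non-negative
#' and monotonically non-increasing for t >= 0 and equals
#' `sum(amplitude)` at t = 0.
#'
#' @param amplitude amplitudes A_j in kBq/ml, all >= 0.
#' @param rate decay rates lambda_j in 1/min, all >= 0, same length.
#' @return An object of class `blood_curve`.
#' @seealso [generate_blood()], [eval_blood()], [integral_blood()]
#' @export
blood_curve <- function(amplitude, rate) {
  if (length(amplitude) != length(rate) || length(amplitude) == 0) {
    stop("`amplitude` and `rate` must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!is.finite(amplitude)) || any(!is.finite(rate)) ||
      any(amplitude < 0) || any(rate < 0)) {
    stop("amplitudes and rates must be finite and >= 0", call. = FALSE)
  }
  ord <- order(rate, decreasing = TRUE) # fastest component first
  structure(
    list(amplitude = as.numeric(amplitude[ord]), rate = as.numeric(rate[ord])),
    class = "blood_curve"
  )
}

#' @export
print.blood_curve <- function(x, ...) {
  cat("<blood_curve> ", length(x$amplitude), " exponential component(s)\n", sep = "")
  hl <- ifelse(x$rate > 0, log(2) / x$rate, Inf)
  print(tibble::tibble(
    amplitude_kBq_ml = x$amplitude, rate_per_min = x$rate, half_life_min = hl
  ))
  invisible(x)
}

#' @export
tidy.blood_curve <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$amplitude),
    amplitude = x$amplitude,
    rate = x$rate,
    half_life_min = ifelse(x$rate > 0, log(2) / x$rate, Inf)
  )
}

#' Half-lives of a blood curve
#'
#' @param curve a [blood_curve()].
#' @return Half-lives `log(2)/lambda` in minutes, sorted ascending
#'   (initial, intermediate, terminal); `Inf` for zero rates.
#' @export
half_lives <- function(curve) {
  stopifnot(inherits(curve, "blood_curve"))
  sort(ifelse(curve$rate > 0, log(2) / curve$rate, Inf))
}

#' Evaluate a blood curve
#'
#' `eval_blood()` evaluates the input function at time points;
#' `eval_blood_frames()` returns frame averages computed from the
#' analytic antiderivative, the appropriate comparison for
#' frame-averaged PET data.
#'
#' @param curve a [blood_curve()].
#' @param t times in minutes post-injection, all >= 0.
#' @param schedule a framing schedule (see [study_schedule()]).
#' @return Concentrations in kBq/ml.
#' @export
eval_blood <- function(curve, t) {
  stopifnot(inherits(curve, "blood_curve"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (j in seq_along(curve$amplitude)) {
    out <- out + curve$amplitude[j] * exp(-curve$rate[j] * t)
  }
  out
}

#' @rdname eval_blood
#' @export
eval_blood_frames <- function(curve, schedule) {
  sched <- validate_schedule(schedule)
  (integral_blood(curve, sched$t_end) - integral_blood(curve, sched$t_start)) /
    sched$dur
}

#' Analytic time integral of a blood curve
#'
#' Computes \eqn{\int_0^t C_p(\tau) d\tau} in closed form:
#' \eqn{\sum_j (A_j/\lambda_j)(1 - e^{-\lambda_j t})}, with zero-rate
#' components contributing \eqn{A_j t}. This integral divided by
#' \eqn{C_p(t)} is the "normalized time" abscissa of the Patlak plot.
#'
#' @inheritParams eval_blood
#' @return Integrated concentration in kBq min/ml.
#' @export
integral_blood <- function(curve, t) {
  stopifnot(inherits(curve, "blood_curve"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (j in seq_along(curve$amplitude)) {
    lam <- curve$rate[j]
    out <- out + if (lam > 0) {
      curve$amplitude[j] / lam * (1 - exp(-lam * t))
    } else {
      curve$amplitude[j] * t
    }
  }
  out
}

#' Generate a triexponential blood curve from half-lives
#'
#' Constructs the input function from half-lives and amplitude
#' fractions. The defaults are the reference synthetic curve used
#' throughout the package: half-lives 5.1 min, 55.9 min and 22.1 h with
#' amplitude fractions (0.6, 0.3, 0.1).
#'
#' @param half_lives_min strictly increasing half-lives in minutes.
#' @param fractions positive amplitude fractions summing to 1.
#' @param scale total concentration at t = 0 in kBq/ml.
#' @return A [blood_curve()] with `A_j = scale * f_j`,
#'   `lambda_j = log(2) / half_life_j`.
#' @examples
#' bc <- generate_blood()
#' eval_blood(bc, 0) # = scale
#' @export
generate_blood <- function(half_lives_min = c(5.1, 55.9, 22.1 * 60),
                           fractions = c(0.6, 0.3, 0.1),
                           scale = 3.7) {
  if (length(half_lives_min) != length(fractions)) {
    stop("`half_lives_min` and `fractions` must have equal length", call. = FALSE)
  }
  if (is.unsorted(half_lives_min, strictly = TRUE)) {
    stop("`half_lives_min` must be strictly increasing", call. = FALSE)
  }
  if (any(half_lives_min <= 0)) stop("half-lives must be > 0", call. = FALSE)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be positive and sum to 1", call. = FALSE)
  }
  blood_curve(amplitude = scale * fractions, rate = log(2) / half_lives_min)
}
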