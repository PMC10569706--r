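#' Fit a triexponential model to a whole-blood time-activity curve
#'
#' Estimates amplitudes and rate constants of a sum of `n_exp`
#' exponentials by weighted nonlinear least squares
#' (Levenberg-Marquardt), with predictions frame-averaged over each
#' frame so that rapidly changing early kinetics are compared to the
#' data on the scale at which the data were acquired. Fitting is
#' multi-start: rate triplets are taken log-spaced over
#' [1/2000, 1] min^-1 and, for each rate start, amplitudes are
#' initialised from a non-negativity-clipped weighted linear solve at
#' those fixed rates. The best weighted residual sum of squares (WRSS)
#' across starts is returned.
#'
#' @param tac a data frame with columns `t_start`, `t_end` (minutes) and
#'   `conc` (kBq/ml); needs at least 7 frames including both early
#'   (< 90 min) and late (> 300 min) times for a well-posed
#'   triexponential.
#' @param weights per-frame weights; default [frame_weights()] on the
#'   TAC's schedule, the same scheme used for compartmental fitting.
#' @param n_exp number of exponential components (default 3).
#' @param n_starts number of multi-start rate configurations (default 8).
#' @return An object of class `triexp_fit`: the fitted [blood_curve()]
#'   (`$curve`), `$half_lives_min` sorted ascending, `$wrss`,
#'   `$converged`, `$degenerate` (a rate pinned at the zero bound while
#'   its amplitude is non-negligible, or the model collapsed to fewer
#'   components), per-parameter `$std_errors` when the information
#'   matrix is invertible, and the data with fitted values. `tidy()` and
#'   `glance()` methods are available.
#' @export
fit_triexponential <- function(tac, weights = NULL, n_exp = 3, n_starts = 8) {
  sched <- validate_schedule(tac)
  y <- tac$conc
  if (length(y) < 2 * n_exp + 1) {
    stop("need at least ", 2 * n_exp + 1, " frames to fit ", n_exp,
         " exponentials", call. = FALSE)
  }
  if (is.null(weights)) weights <- frame_weights(sched)
  if (length(weights) != length(y) || any(weights < 0)) {
    stop("`weights` must be non-negative, one per frame", call. = FALSE)
  }
  sw <- sqrt(weights)

  # frame-averaged design column for one exponential rate
  frame_col <- function(lam) {
    if (lam > 1e-12) {
      (exp(-lam * sched$t_start) - exp(-lam * sched$t_end)) / (lam * sched$dur)
    } else {
      rep(1, nrow(sched))
    }
  }
  predict_frames <- function(amp, lam) {
    out <- numeric(nrow(sched))
    for (j in seq_along(amp)) out <- out + amp[j] * frame_col(lam[j])
    out
  }
  resid_fn <- function(par) {
    amp <- par[seq_len(n_exp)]
    lam <- par[n_exp + seq_len(n_exp)]
    sw * (y - predict_frames(amp, lam))
  }

  # multi-start rate configurations: triplets log-spaced over [1/2000, 1]
  grid <- exp(seq(log(1 / 2000), log(1), length.out = n_starts + 2 * (n_exp - 1)))
  starts <- lapply(seq_len(n_starts), function(s) {
    rev(grid[s + 2 * (seq_len(n_exp) - 1)]) # descending: fastest first
  })

  best <- NULL
  for (lam0 in starts) {
    X <- vapply(lam0, frame_col, numeric(nrow(sched)))
    amp0 <- tryCatch(
      stats::lm.wfit(X, y, w = weights)$coefficients,
      error = function(e) rep(max(y) / n_exp, n_exp)
    )
    amp0[!is.finite(amp0) | amp0 <= 0] <- 1e-6 * max(y)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(amp0, lam0), lower = rep(0, 2 * n_exp),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-12, ptol = 1e-12
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    wrss <- sum(fit$fvec^2)
    if (is.null(best) || wrss < best$wrss) best <- list(fit = fit, wrss = wrss)
  }
  if (is.null(best)) {
    stop("triexponential fit failed to converge from any start", call. = FALSE)
  }

  par <- best$fit$par
  amp <- par[seq_len(n_exp)]
  lam <- par[n_exp + seq_len(n_exp)]
  ord <- order(lam, decreasing = TRUE)
  amp <- amp[ord]
  lam <- lam[ord]
  tot <- sum(amp)
  # degenerate: a rate at the zero bound with non-negligible amplitude,
  # or a component whose amplitude collapsed to the zero bound
  degenerate <- any(lam < 1e-10 & amp > 1e-8 * tot) || any(amp <= 1e-8 * tot)

  std_errors <- tryCatch({
    covm <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
    if (is.null(covm)) rep(NA_real_, 2 * n_exp) else sqrt(diag(covm))[c(ord, n_exp + ord)]
  }, error = function(e) rep(NA_real_, 2 * n_exp))

  curve <- blood_curve(amplitude = amp, rate = pmax(lam, 0))
  fitted_vals <- predict_frames(curve$amplitude, curve$rate)
  structure(
    list(
      curve = curve,
      half_lives_min = half_lives(curve),
      wrss = best$wrss,
      converged = best$fit$info %in% 1:4,
      degenerate = degenerate,
      std_errors = std_errors,
      n = length(y),
      data = dplyr::mutate(sched, conc = y, fitted = fitted_vals,
                           weight = weights)
    ),
    class = "triexp_fit"
  )
}

#' @export
print.triexp_fit <- function(x, ...) {
  cat("<triexp_fit> WRSS ", format(x$wrss), ", converged: ", x$converged,
      if (x$degenerate) ", DEGENERATE" else "", "\n", sep = "")
  hl <- x$half_lives_min
  cat("half-lives (min):", paste(format(hl, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.triexp_fit <- function(x, ...) {
  k <- length(x$curve$amplitude)
  tibble::tibble(
    term = c(paste0("A", seq_len(k)), paste0("lambda", seq_len(k))),
    estimate = c(x$curve$amplitude, x$curve$rate),
    std.error = x$std_errors
  )
}

#' @export
glance.triexp_fit <- function(x, ...) {
  tibble::tibble(
    wrss = x$wrss, n = x$n, converged = x$converged,
    degenerate = x$degenerate,
    half_life_initial_min = x$half_lives_min[1],
    half_life_intermediate_min = x$half_lives_min[2],
    half_life_terminal_min = x$half_lives_min[3]
  )
}

#' Write / read a fitted blood curve as JSON
#'
#' Serialises the input-function parameters (amplitudes in kBq/ml, rates
#' in 1/min) for interchange between pipeline stages.
#'
#' @param curve a [blood_curve()] or `triexp_fit` (its curve is used).
#' @param path file path.
#' @return `read_blood_json()` returns a [blood_curve()];
#'   `write_blood_json()` returns `curve` invisibly.
#' @export
write_blood_json <- function(curve, path) {
  if (inherits(curve, "triexp_fit")) curve <- curve$curve
  stopifnot(inherits(curve, "blood_curve"))
  jsonlite::write_json(
    list(amplitude_kBq_ml = curve$amplitude, rate_per_min = curve$rate),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(curve)
}

#' @rdname write_blood_json
#' @export
read_blood_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("amplitude_kBq_ml", "rate_per_min") %in% names(obj))) {
    stop("blood JSON must contain `amplitude_kBq_ml` and `rate_per_min`", call. = FALSE)
  }
  blood_curve(obj$amplitude_kBq_ml, obj$rate_per_min)
}
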