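#' Kinetic microparameters
#'
#' Bundles the compartmental microparameters: fractional blood volume
#' `vb` (unitless, in [0, 1]), delivery rate `K1` (ml/cm^3/min), and the
#' exchange rates `k2`, `k3`, `k4` (1/min). The one-tissue model (1T3P)
#' has `k3 = k4 = 0`; the irreversible two-tissue model (2T4P) has
#' `k4 = 0`; the reversible two-tissue model (2T5P) frees all five.
#'
#' @param vb fractional blood volume in [0, 1].
#' @param K1,k2,k3,k4 non-negative rate constants.
#' @return A named numeric vector `c(vb, K1, k2, k3, k4)`.
#' @export
kinetic_params <- function(vb = 0, K1 = 0, k2 = 0, k3 = 0, k4 = 0) {
  p <- c(vb = vb, K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (vb < 0 || vb > 1) stop("`vb` must be in [0, 1]", call. = FALSE)
  if (any(p[-1] < 0)) stop("rate constants must be >= 0", call. = FALSE)
  p
}

# parameter sets per model id
.pet_models <- list(
  "1T3P" = c("vb", "K1", "k2"),
  "2T4P" = c("vb", "K1", "k2", "k3"),
  "2T5P" = c("vb", "K1", "k2", "k3", "k4")
)

.check_model <- function(model) {
  if (!model %in% names(.pet_models)) {
    stop("unknown model id: ", model, " (use 1T3P, 2T4P or 2T5P)", call. = FALSE)
  }
  model
}

# coerce to the full 5-vector, forcing parameters absent from the model to 0
.full_params <- function(params, model = "2T5P") {
  p <- kinetic_params(
    vb = params[["vb"]] %||% 0, K1 = params[["K1"]] %||% 0,
    k2 = params[["k2"]] %||% 0, k3 = params[["k3"]] %||% 0,
    k4 = params[["k4"]] %||% 0
  )
  p[setdiff(names(p), c(.pet_models[[.check_model(model)]]))] <- 0
  p
}

# --- closed-form convolution of exponential modes with an exponential input ---
# conv(alpha, lam, t) = e^{-alpha t} (x) e^{-lam t}
#                     = (e^{-lam t} - e^{-alpha t}) / (alpha - lam)
# with the degenerate limit t e^{-alpha t} when alpha == lam. A relative
# threshold routes near-coincident pairs to the limit form to avoid
# catastrophic cancellation.
.conv_exp <- function(alpha, lam, t) {
  if (abs(alpha - lam) <= 1e-9 * max(alpha, lam, 1e-6)) {
    t * exp(-((alpha + lam) / 2) * t)
  } else {
    (exp(-lam * t) - exp(-alpha * t)) / (alpha - lam)
  }
}

# int_0^T of .conv_exp; building block for frame averages
.iconv_exp <- function(alpha, lam, t) {
  g <- function(mu, t) if (mu > 1e-12) (1 - exp(-mu * t)) / mu else t
  if (abs(alpha - lam) <= 1e-9 * max(alpha, lam, 1e-6)) {
    a <- (alpha + lam) / 2
    if (a > 1e-12) (1 - (1 + a * t) * exp(-a * t)) / a^2 else t^2 / 2
  } else {
    (g(lam, t) - g(alpha, t)) / (alpha - lam)
  }
}

# exponential response modes (decay alpha_m, coefficient b_m per unit K1)
# of the two-tissue impulse response; part selects total tissue, free (C1)
# or bound (C2) compartment. The 1T model is the k3 = k4 = 0 special case
# (its alpha1 coefficient vanishes identically).
.response_modes <- function(params, part = c("total", "C1", "C2")) {
  part <- match.arg(part)
  k2 <- params[["k2"]]; k3 <- params[["k3"]]; k4 <- params[["k4"]]
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4 # = (k2 - k4)^2 + k3^2 + 2 k3 (k2 + k4) >= 0
  sq <- sqrt(max(disc, 0))
  a1 <- (s - sq) / 2
  a2 <- (s + sq) / 2
  if (a2 - a1 <= 1e-9 * max(s, 1e-6)) {
    # repeated root (k3 = 0, k2 = k4): nudge apart; the O(eps*t) error is
    # far below the fitting tolerances
    a2 <- a1 + 1e-9 * max(s, 1e-6)
  }
  d <- a2 - a1
  b <- switch(part,
    total = c((k3 + k4 - a1) / d, (a2 - k3 - k4) / d),
    C1 = c((k4 - a1) / d, (a2 - k4) / d),
    C2 = c(k3 / d, -k3 / d)
  )
  list(alpha = c(a1, a2), b = params[["K1"]] * b)
}

# instantaneous tissue concentration (no blood-volume term) at times t
.tissue_conc <- function(params, input, t, part = "total") {
  modes <- .response_modes(params, part)
  out <- numeric(length(t))
  for (m in 1:2) {
    if (modes$b[m] == 0) next
    for (j in seq_along(input$amplitude)) {
      out <- out + modes$b[m] * input$amplitude[j] *
        .conv_exp(modes$alpha[m], input$rate[j], t)
    }
  }
  out
}

# frame-averaged whole-region model concentration:
# (1 - vb) * C_tissue + vb * C_wb, averaged analytically over each frame
.model_conc <- function(params, input, sched) {
  modes <- .response_modes(params, "total")
  tis <- numeric(nrow(sched))
  for (m in 1:2) {
    if (modes$b[m] == 0) next
    for (j in seq_along(input$amplitude)) {
      hi <- .iconv_exp(modes$alpha[m], input$rate[j], sched$t_end)
      lo <- .iconv_exp(modes$alpha[m], input$rate[j], sched$t_start)
      tis <- tis + modes$b[m] * input$amplitude[j] * (hi - lo) / sched$dur
    }
  }
  vb <- params[["vb"]]
  (1 - vb) * tis + vb * eval_blood_frames(input, sched)
}

#' Forward-model a tissue time-activity curve
#'
#' Predicts the frame-averaged regional concentration
#' \deqn{C_{model}(t) = (1 - v_b) C_{tissue}(t) + v_b C_{wb}(t)}
#' under one- or two-tissue compartmental kinetics driven by a
#' multiexponential whole-blood input. The tissue response is the
#' standard two-tissue impulse response with eigenvalues
#' \deqn{\alpha_{1,2} = [(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}]/2,}
#' convolved in closed form against the exponential input components and
#' averaged analytically over each frame.
#'
#' @param params a [kinetic_params()] vector (or named vector with those
#'   elements).
#' @param input a [blood_curve()].
#' @param schedule a framing schedule ([study_schedule()] or compatible).
#' @param model model id used to force absent microparameters to zero;
#'   default `"2T5P"` uses the parameters as given.
#' @return A tibble: the schedule columns plus `conc`, the predicted
#'   frame-averaged concentration in kBq/ml.
#' @export
model_tac <- function(params, input, schedule, model = "2T5P") {
  stopifnot(inherits(input, "blood_curve"))
  sched <- validate_schedule(schedule)
  p <- .full_params(params, model)
  dplyr::mutate(sched, conc = .model_conc(p, input, sched))
}

#' Free and bound compartment concentrations on a time grid
#'
#' Returns the instantaneous concentrations of the first (free,
#' `C1`) and second (bound, `C2`) tissue compartments. For a reversible
#' model (`k4 > 0`) and a decaying input, the bound-compartment curve
#' rises to a single interior maximum and declines thereafter, the
#' signature of slow binding followed by washout of labelled cells.
#'
#' @inheritParams model_tac
#' @param grid time grid in minutes.
#' @return A tibble with columns `t`, `C1`, `C2` and `tissue`
#'   (`= C1 + C2`; the tissue part of the model, without the
#'   blood-volume term).
#' @export
compartment_curves <- function(params, input, grid, model = "2T5P") {
  stopifnot(inherits(input, "blood_curve"))
  if (any(grid < 0)) stop("`grid` times must be >= 0", call. = FALSE)
  p <- .full_params(params, model)
  c1 <- .tissue_conc(p, input, grid, "C1")
  c2 <- .tissue_conc(p, input, grid, "C2")
  tibble::tibble(t = grid, C1 = c1, C2 = c2, tissue = c1 + c2)
}

#' Per-frame fitting weights from frame duration and decay
#'
#' Weights each frame by its duration and the physical decay factor,
#' \eqn{w_i = \Delta t_i e^{-\lambda_{phys} t_{mid,i}}}: longer frames
#' and earlier (less decayed) frames carry more counts and hence more
#' weight on the decay-corrected scale. Frames belonging to late
#' single-frame sessions (anything outside the dynamic session) are
#' additionally divided by `late_downweight`, reflecting the larger
#' uncertainty of isolated late points; the default factor is 10.
#' Weights are normalised to sum to the number of frames.
#'
#' @param schedule a framing schedule; the `session` column, when
#'   present, identifies late sessions (`!= "dynamic"`), otherwise
#'   frames starting at or after 300 min are treated as late.
#' @param isotope_half_life_h physical isotope half-life in hours
#'   (default 78.4, zirconium-89).
#' @param late_downweight division factor for late-session frames.
#' @return Numeric weights, one per frame, summing to `nrow(schedule)`.
#' @export
frame_weights <- function(schedule, isotope_half_life_h = 78.4,
                          late_downweight = 10) {
  sched <- validate_schedule(schedule)
  lam <- log(2) / (isotope_half_life_h * 60)
  w <- sched$dur * exp(-lam * sched$t_mid)
  late <- if ("session" %in% names(sched)) {
    sched$session != "dynamic"
  } else {
    sched$t_start >= 300
  }
  w[late] <- w[late] / late_downweight
  w * length(w) / sum(w)
}

#' Net influx rate macroparameter
#'
#' The net influx (trapping) rate of the irreversible pathway,
#' \deqn{K_i = K_1 k_3 / (k_2 + k_3),} defined as 0 when `k3 = 0`. When
#' `k2 = k3 = 0` with `K1 > 0` the macroparameter is degenerate and 0 is
#' returned with a warning.
#'
#' @param params a named vector with `K1`, `k2`, `k3` (e.g.
#'   [kinetic_params()]).
#' @return Ki in ml/cm^3/min.
#' @export
ki_macro <- function(params) {
  K1 <- params[["K1"]]; k2 <- params[["k2"]]; k3 <- params[["k3"]]
  if (k3 == 0) {
    if (k2 == 0 && K1 > 0) {
      warning("k2 = k3 = 0 with K1 > 0: Ki is degenerate, returning 0")
    }
    return(0)
  }
  K1 * k3 / (k2 + k3)
}

#' Default parameter bounds for compartmental fitting
#'
#' Physiologic box constraints used by [fit_model()]: `vb` in [0, 0.6],
#' `K1` in [0, 2] ml/cm^3/min, `k2`, `k3`, `k4` in [0, 1] 1/min.
#'
#' @return A list with named `lower` and `upper` vectors.
#' @export
default_bounds <- function() {
  list(
    lower = c(vb = 0, K1 = 0, k2 = 0, k3 = 0, k4 = 0),
    upper = c(vb = 0.6, K1 = 2, k2 = 1, k3 = 1, k4 = 1)
  )
}

# deterministic quasi-random multi-start points (log-scaled for rates,
# linear for vb), so repeated fits are bit-identical without a seed
.start_points <- function(free, bounds, n_starts, default_start) {
  phi <- c(vb = 0.4142136, K1 = 0.7320508, k2 = 0.2360680,
           k3 = 0.6457513, k4 = 0.3166248) # frac(sqrt(2,3,5,7,11))
  starts <- list(pmin(pmax(default_start[free], bounds$lower[free]),
                      bounds$upper[free]))
  for (s in seq_len(max(n_starts - 1, 0))) {
    p <- vapply(free, function(nm) {
      frac <- (s * phi[[nm]]) %% 1
      lo <- bounds$lower[[nm]]; hi <- bounds$upper[[nm]]
      if (nm == "vb") {
        lo + frac * (hi - lo)
      } else {
        llo <- log(max(lo, 1e-4 * hi)); lhi <- log(hi)
        exp(llo + frac * (lhi - llo))
      }
    }, numeric(1))
    names(p) <- free
    starts <- c(starts, list(p))
  }
  starts
}

#' Fit a compartmental model to a tissue time-activity curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of a 1T3P,
#' 2T4P or 2T5P model against frame-averaged data, minimising
#' \eqn{\sum_i w_i (C_{meas,i} - C_{model,i})^2} subject to box
#' constraints, with deterministic multi-start initialisation. All
#' frames of the supplied TAC are used; with the full three-session
#' protocol that is every point out to 49 h post-injection.
#'
#' @param tac a data frame with `t_start`, `t_end` (minutes) and `conc`
#'   (kBq/ml, decay-corrected).
#' @param input a [blood_curve()], typically from
#'   [fit_triexponential()].
#' @param model `"1T3P"`, `"2T4P"` or `"2T5P"`.
#' @param fixed named numeric vector of parameters to hold fixed (e.g.
#'   `c(vb = 0.4)` for spleen, where `K1` and `k2` trade off against
#'   `vb` almost perfectly); fixed parameters are excluded from the free
#'   count `k` used by [aicc()].
#' @param weights per-frame weights; default [frame_weights()].
#' @param bounds list with `lower`/`upper` named vectors; default
#'   [default_bounds()].
#' @param start optional named starting values for free parameters;
#'   replaces the default first start.
#' @param n_starts total number of multi-start fits (>= 1, default 5).
#' @return An object of class `kinetic_fit` with elements `model`,
#'   `params` (all five microparameters, fixed and forced values
#'   included), `free`, `fixed`, `wrss`, `n`, `k`, `aicc`, `ki`,
#'   `converged`, `at_bounds` and `data` (schedule + `conc`, `fitted`,
#'   `weight`). `tidy()`, `glance()` and `autoplot()` methods are
#'   available.
#' @export
fit_model <- function(tac, input, model = "2T5P", fixed = NULL,
                      weights = NULL, bounds = default_bounds(),
                      start = NULL, n_starts = 5) {
  .check_model(model)
  stopifnot(inherits(input, "blood_curve"))
  if (all(input$amplitude <= 0)) stop("input curve has no positive amplitude", call. = FALSE)
  sched <- validate_schedule(tac)
  y <- tac$conc
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("TAC values must be finite and >= 0", call. = FALSE)
  }
  if (is.null(weights)) weights <- frame_weights(sched)
  if (length(weights) != length(y)) stop("one weight per frame required", call. = FALSE)
  sw <- sqrt(weights)

  pnames <- .pet_models[[model]]
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% pnames)) {
      stop("`fixed` must be named with parameters of model ", model, call. = FALSE)
    }
    bad <- fixed < bounds$lower[names(fixed)] | fixed > bounds$upper[names(fixed)]
    if (any(bad)) stop("fixed values outside bounds: ",
                       paste(names(fixed)[bad], collapse = ", "), call. = FALSE)
  }
  free <- setdiff(pnames, names(fixed))
  if (length(free) == 0) stop("no free parameters to fit", call. = FALSE)

  base <- kinetic_params() # all zero
  base[names(fixed)] <- fixed

  default_start <- c(vb = 0.05, K1 = 0.01, k2 = 0.01, k3 = 0.001, k4 = 1e-4)
  starts <- .start_points(free, bounds, n_starts, default_start)
  if (!is.null(start)) {
    if (!all(free %in% names(start))) {
      stop("`start` must name every free parameter: ",
           paste(free, collapse = ", "), call. = FALSE)
    }
    starts[[1]] <- pmin(pmax(start[free], bounds$lower[free]), bounds$upper[free])
  } else if (model != "1T3P") {
    # nested warm start: begin the richer model at the reduced-model
    # optimum with the extra rate at zero, so its initial WRSS equals the
    # reduced optimum and the nesting inequality
    # WRSS(2T5P) <= WRSS(2T4P) <= WRSS(1T3P) holds by construction
    reduced <- switch(model, "2T4P" = "1T3P", "2T5P" = "2T4P")
    warm <- tryCatch(
      fit_model(tac, input, model = reduced,
                fixed = fixed[names(fixed) %in% .pet_models[[reduced]]],
                weights = weights, bounds = bounds, n_starts = n_starts),
      error = function(e) NULL
    )
    if (!is.null(warm)) {
      starts <- c(starts, list(pmin(pmax(warm$params[free],
                                         bounds$lower[free]),
                                    bounds$upper[free])))
    }
  }

  resid_fn <- function(parfree) {
    p <- base
    p[free] <- parfree
    sw * (y - .model_conc(p, input, sched))
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = bounds$lower[free], upper = bounds$upper[free],
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-10, ptol = 1e-10
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    wrss <- sum(fit$fvec^2)
    if (is.null(best) || wrss < best$wrss) best <- list(fit = fit, wrss = wrss)
  }
  if (is.null(best)) {
    stop("compartmental fit failed to converge from any start (model ",
         model, ")", call. = FALSE)
  }

  params <- base
  params[free] <- best$fit$par
  tol_b <- 1e-6 * pmax(1, abs(bounds$upper[free]))
  at_bounds <- free[
    abs(params[free] - bounds$lower[free]) < tol_b |
      abs(params[free] - bounds$upper[free]) < tol_b
  ]
  k <- length(free)
  n <- length(y)
  fitted_vals <- .model_conc(params, input, sched)
  structure(
    list(
      model = model,
      params = params,
      free = free,
      fixed = fixed,
      wrss = best$wrss,
      n = n,
      k = k,
      aicc = if (n > k + 1 && best$wrss > 0) aicc(best$wrss, n, k) else NA_real_,
      ki = if (model == "1T3P") 0 else ki_macro(params),
      converged = best$fit$info %in% 1:4,
      at_bounds = at_bounds,
      input = input,
      data = dplyr::mutate(sched, conc = y, fitted = fitted_vals,
                           weight = weights)
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> ", x$model, " | WRSS ", format(x$wrss),
      " | AICc ", format(x$aicc), " | Ki ", format(x$ki), "\n", sep = "")
  est <- format(x$params, digits = 4)
  fixed_mark <- ifelse(names(x$params) %in% names(x$fixed), " (fixed)",
                       ifelse(names(x$params) %in% x$free, "", " (forced 0)"))
  cat(paste0("  ", names(x$params), " = ", est, fixed_mark, collapse = "\n"), "\n")
  if (length(x$at_bounds)) cat("  at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    fixed = names(x$params) %in% names(x$fixed),
    free = names(x$params) %in% x$free,
    at_bound = names(x$params) %in% x$at_bounds
  )
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, wrss = x$wrss, aicc = x$aicc, ki = x$ki,
    n = x$n, k = x$k, converged = x$converged,
    n_at_bounds = length(x$at_bounds)
  )
}
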