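#' Normalized sensitivity curves
#'
#' The relative sensitivity of the model TAC to each microparameter,
#' \deqn{S_j(t_i) = \frac{\partial C_{model}(t_i)}{\partial \theta_j}
#'   \frac{\theta_j}{C_{model}(t_i)},}
#' computed by central finite differences with relative step 1e-3 on
#' frame-averaged model values. A parameter whose influence keeps
#' growing out to the last session can only be identified by including
#' that session in the fit. Fixed parameters are excluded; frames where
#' the model value is zero are masked with a warning.
#'
#' @inheritParams model_tac
#' @param free parameter names to differentiate; default all parameters
#'   of `model`.
#' @param rel_step relative finite-difference step.
#' @return A long tibble with columns `t_mid`, `parameter`,
#'   `sensitivity`.
#' @export
normalized_sensitivity <- function(params, input, schedule, model = "2T5P",
                                   free = NULL, rel_step = 1e-3) {
  sched <- validate_schedule(schedule)
  p <- .full_params(params, model)
  if (is.null(free)) free <- .pet_models[[.check_model(model)]]
  c0 <- .model_conc(p, input, sched)
  mask <- c0 == 0
  if (any(mask)) {
    warning(sum(mask), " frame(s) with zero model value masked")
  }
  purrr::map_dfr(free, function(nm) {
    th <- p[[nm]]
    if (th == 0) {
      s <- rep(0, nrow(sched)) # zero parameter: normalized sensitivity is 0
    } else {
      h <- rel_step * th
      pp <- p; pp[nm] <- th + h
      pm <- p; pm[nm] <- th - h
      dc <- (.model_conc(pp, input, sched) - .model_conc(pm, input, sched)) / (2 * h)
      s <- ifelse(mask, NA_real_, dc * th / c0)
    }
    tibble::tibble(t_mid = sched$t_mid, parameter = nm, sensitivity = s)
  })
}

# weighted finite-difference Jacobian of the frame-averaged model with
# respect to the free parameters
.model_jacobian <- function(params, free, input, sched, rel_step = 1e-3) {
  J <- matrix(0, nrow(sched), length(free), dimnames = list(NULL, free))
  for (nm in free) {
    th <- params[[nm]]
    h <- if (th != 0) rel_step * abs(th) else 1e-6
    pp <- params; pp[nm] <- th + h
    pm <- params; pm[nm] <- max(th - h, 0)
    J[, nm] <- (.model_conc(pp, input, sched) - .model_conc(pm, input, sched)) /
      (pp[[nm]] - pm[[nm]])
  }
  J
}

.corr_from_jacobian <- function(J, weights) {
  M <- crossprod(J * sqrt(weights))
  degenerate <- FALSE
  covm <- tryCatch({
    if (rcond(M) < 1e-12) stop("near-singular")
    solve(M)
  }, error = function(e) {
    degenerate <<- TRUE
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  d <- sqrt(pmax(diag(covm), 0))
  corr <- covm / outer(d, d)
  corr[!is.finite(corr)] <- NA_real_
  diag(corr) <- 1
  dimnames(corr) <- dimnames(covm) <- list(colnames(J), colnames(J))
  structure(corr, degenerate = degenerate)
}

#' Parameter correlation matrix of a compartmental fit
#'
#' Linearised parameter correlations at the fitted values, from the
#' covariance approximation \eqn{(J^T W J)^{-1}} with `J` the
#' finite-difference Jacobian of the model and `W` the fitting weights.
#' Strong off-diagonal entries (e.g. between `K1`, `k2` and `vb` in
#' high-blood-volume organs such as the spleen) signal practical
#' non-identifiability: fixing one member of the correlated set is then
#' the standard remedy.
#'
#' @param fit a [fit_model()] result.
#' @return A symmetric correlation matrix over the free parameters with
#'   unit diagonal; attribute `degenerate` is `TRUE` when the
#'   information matrix was rank-deficient and a pseudo-inverse was
#'   used.
#' @export
correlation_matrix <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  sched <- fit$data
  J <- .model_jacobian(fit$params, fit$free, fit$input, sched)
  .corr_from_jacobian(J, sched$weight)
}

#' Frame noise standard deviations under the count-statistics model
#'
#' The package's TAC noise model on the decay-corrected scale:
#' \deqn{\sigma_i = S_c \sqrt{C_{model}(t_i)
#'   e^{\lambda_{phys} t_{mid,i}} / \Delta t_i},}
#' i.e. variance proportional to the decay-uncorrected count rate and
#' inversely proportional to frame duration, scaled back to the
#' decay-corrected scale. `Sc` sets the overall noise magnitude.
#'
#' @param conc_model model (noise-free) concentrations per frame.
#' @param schedule the framing schedule.
#' @param Sc noise scale (>= 0).
#' @param isotope_half_life_h physical half-life in hours.
#' @return Per-frame standard deviations (0 where `conc_model <= 0`).
#' @export
noise_sigma <- function(conc_model, schedule, Sc,
                        isotope_half_life_h = 78.4) {
  sched <- validate_schedule(schedule)
  if (Sc < 0) stop("`Sc` must be >= 0", call. = FALSE)
  lam <- log(2) / (isotope_half_life_h * 60)
  ifelse(conc_model > 0,
         Sc * sqrt(conc_model * exp(lam * sched$t_mid) / sched$dur),
         0)
}

#' Estimate the noise scale from measured and modelled TACs
#'
#' Finds the `Sc` of the [noise_sigma()] variance model that makes the
#' mean standardized squared residual between a measured TAC and its
#' model fit equal 1, i.e.
#' \eqn{S_c^2 = \mathrm{mean}_i\left[r_i^2 \Delta t_i
#'   e^{-\lambda_{phys} t_{mid,i}} / C_{model,i}\right]}.
#'
#' @param measured,fitted_model frame-aligned data frames with
#'   `t_start`, `t_end`, `conc` (the model TAC typically from
#'   [model_tac()] at fitted parameters).
#' @param isotope_half_life_h physical half-life in hours.
#' @return The estimated noise scale `Sc`.
#' @export
estimate_noise_scale <- function(measured, fitted_model,
                                 isotope_half_life_h = 78.4) {
  ms <- validate_schedule(measured)
  fs <- validate_schedule(fitted_model)
  if (nrow(ms) != nrow(fs) || max(abs(ms$t_mid - fs$t_mid)) > 1e-9) {
    stop("measured and model TACs must share the schedule", call. = FALSE)
  }
  if (nrow(ms) < 10) stop("need at least 10 frames", call. = FALSE)
  lam <- log(2) / (isotope_half_life_h * 60)
  keep <- fs$conc > 0
  if (!any(keep)) stop("all frames masked: model TAC is non-positive", call. = FALSE)
  r <- ms$conc[keep] - fs$conc[keep]
  sqrt(mean(r^2 * ms$dur[keep] * exp(-lam * ms$t_mid[keep]) / fs$conc[keep]))
}

#' Monte-Carlo bias, SD and RMSE of microparameter estimates
#'
#' Practical identifiability by simulation: generates `n_reps` noisy
#' replicates of the model TAC under the [noise_sigma()] noise model
#' (Gaussian, truncated at zero), refits each replicate (starting from
#' the true parameters plus one quasi-random restart), and summarises
#' per-parameter bias, SD and RMSE in percent of the true value. The SD
#' uses the population (1/n) denominator so that
#' RMSE^2 = bias^2 + SD^2 holds exactly.
#'
#' @inheritParams model_tac
#' @param fixed named parameters held fixed in every refit.
#' @param Sc noise scale, e.g. from [estimate_noise_scale()].
#' @param n_reps number of Monte-Carlo replicates (>= 2, default 100).
#' @param seed RNG seed (required; the caller's RNG state is restored).
#' @param isotope_half_life_h physical half-life in hours.
#' @param bounds fitting bounds, as in [fit_model()].
#' @return An object of class `identifiability_report`: `$summary`
#'   (tibble with `parameter`, `true`, `bias_pct`, `sd_pct`,
#'   `rmse_pct`), `$estimates` (one row per successful replicate),
#'   `$sensitivity` curves at the true parameters, `$correlation`
#'   matrix at the true parameters, `$noise_scale`, `$n_reps`, `$seed`,
#'   `$n_failed`, `$clip_frac` (fraction of simulated values truncated
#'   at zero) and `$unreliable` (`TRUE` when more than 20% of replicate
#'   fits failed).
#' @export
simulate_bias_sd <- function(params, input, schedule, model = "2T5P",
                             fixed = NULL, Sc, n_reps = 100, seed,
                             isotope_half_life_h = 78.4,
                             bounds = default_bounds()) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (n_reps < 2) stop("`n_reps` must be >= 2", call. = FALSE)
  sched <- validate_schedule(schedule)
  p_true <- .full_params(params, model)
  free <- setdiff(.pet_models[[.check_model(model)]], names(fixed))
  truth <- model_tac(p_true, input, sched, model = model)
  sig <- noise_sigma(truth$conc, sched, Sc,
                     isotope_half_life_h = isotope_half_life_h)
  weights <- frame_weights(sched, isotope_half_life_h = isotope_half_life_h)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  est <- matrix(NA_real_, n_reps, length(free), dimnames = list(NULL, free))
  n_clip <- 0L
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    y <- truth$conc + stats::rnorm(length(sig), 0, sig)
    n_clip <- n_clip + sum(y < 0)
    y <- pmax(y, 0)
    noisy <- dplyr::mutate(sched, conc = y)
    rand_start <- stats::setNames(vapply(free, function(nm) {
      lo <- bounds$lower[[nm]]; hi <- bounds$upper[[nm]]
      if (nm == "vb") stats::runif(1, lo, hi)
      else exp(stats::runif(1, log(max(lo, 1e-4 * hi)), log(hi)))
    }, numeric(1)), free)
    fit <- tryCatch({
      f1 <- fit_model(noisy, input, model = model, fixed = fixed,
                      weights = weights, bounds = bounds,
                      start = p_true[free], n_starts = 1)
      f2 <- tryCatch(
        fit_model(noisy, input, model = model, fixed = fixed,
                  weights = weights, bounds = bounds,
                  start = rand_start, n_starts = 1),
        error = function(e) NULL
      )
      if (!is.null(f2) && f2$wrss < f1$wrss) f2 else f1
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
    } else {
      est[r, ] <- fit$params[free]
    }
  }

  ok <- stats::complete.cases(est)
  summary_tbl <- purrr::map_dfr(free, function(nm) {
    th <- p_true[[nm]]
    e <- est[ok, nm]
    if (th > 0 && length(e) > 0) {
      bias <- mean(e - th) / th * 100
      sdp <- sqrt(mean((e - mean(e))^2)) / th * 100
      rmse <- sqrt(mean((e - th)^2)) / th * 100
    } else {
      bias <- sdp <- rmse <- NA_real_
    }
    tibble::tibble(parameter = nm, true = th, bias_pct = bias,
                   sd_pct = sdp, rmse_pct = rmse)
  })

  J <- .model_jacobian(p_true, free, input, sched)
  structure(
    list(
      summary = summary_tbl,
      estimates = tibble::as_tibble(est[ok, , drop = FALSE]),
      sensitivity = suppressWarnings(
        normalized_sensitivity(p_true, input, sched, model = model, free = free)
      ),
      correlation = .corr_from_jacobian(J, weights),
      noise_scale = Sc,
      n_reps = n_reps,
      seed = seed,
      n_failed = n_failed,
      clip_frac = n_clip / (n_reps * nrow(sched)),
      unreliable = n_failed > 0.2 * n_reps
    ),
    class = "identifiability_report"
  )
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report> ", x$n_reps, " replicates at Sc = ",
      format(x$noise_scale), ", seed ", x$seed,
      if (x$unreliable) " [UNRELIABLE: >20% fit failures]" else "",
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.identifiability_report <- function(x, ...) x$summary

#' @export
glance.identifiability_report <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps, n_failed = x$n_failed, noise_scale = x$noise_scale,
    seed = x$seed, clip_frac = x$clip_frac, unreliable = x$unreliable
  )
}
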