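# shared fixtures: reference input function, schedule and parameter regimes

ref_blood <- function() generate_blood()
ref_schedule <- function() study_schedule()

bone_marrow_params <- function() {
  kinetic_params(vb = 0.15, K1 = 0.25, k2 = 0.2, k3 = 0.03, k4 = 8e-4)
}
spleen_params <- function() {
  kinetic_params(vb = 0.4, K1 = 0.6, k2 = 0.15, k3 = 0.015, k4 = 8e-4)
}

# random valid parameter/input draws for property tests
draw_params <- function() {
  kinetic_params(
    vb = runif(1, 0, 0.6), K1 = 10^runif(1, -2, 0),
    k2 = 10^runif(1, -2.5, -0.5), k3 = 10^runif(1, -3, -1),
    k4 = 10^runif(1, -4, -2.5)
  )
}

# independent oracle: frame-averaged model TAC by numerically solving the
# two-tissue ODE system with deSolve (state A accumulates the whole-region
# concentration so frame means come from exact cumulative differences)
ode_model_tac <- function(params, input, schedule) {
  sched <- validate_schedule(schedule)
  vb <- params[["vb"]]
  deriv <- function(t, y, parms) {
    cp <- eval_blood(input, t)
    dC1 <- params[["K1"]] * cp - (params[["k2"]] + params[["k3"]]) * y[1] +
      params[["k4"]] * y[2]
    dC2 <- params[["k3"]] * y[1] - params[["k4"]] * y[2]
    dA <- (1 - vb) * (y[1] + y[2]) + vb * cp
    list(c(dC1, dC2, dA))
  }
  times <- sort(unique(c(0, sched$t_start, sched$t_end)))
  sol <- deSolve::ode(c(C1 = 0, C2 = 0, A = 0), times, deriv, NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-12)
  A <- stats::setNames(sol[, "A"], as.character(sol[, "time"]))
  (A[as.character(sched$t_end)] - A[as.character(sched$t_start)]) / sched$dur
}
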