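test_that("closed-form model TAC matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  bc <- ref_blood()
  sched <- ref_schedule()
  withr::local_seed(7)
  for (i in 1:25) {
    p <- draw_params()
    closed <- model_tac(p, bc, sched)$conc
    ode <- ode_model_tac(p, bc, sched)
    expect_lt(max(abs(closed - ode) / pmax(abs(ode), 1e-12)), 1e-6)
  }
})

test_that("model TAC limits and nesting identities hold", {
  bc <- ref_blood()
  sched <- ref_schedule()
  # K1 = 0, vb = 0: identically zero
  expect_equal(model_tac(kinetic_params(), bc, sched)$conc,
               rep(0, nrow(sched)))
  # constant input, pure integrator (k2 = 0, vb = 0): C = K1 c t, and the
  # frame average of a linear ramp is its midpoint value
  const <- blood_curve(2, 0)
  ramp <- model_tac(kinetic_params(K1 = 0.1), const, sched)
  expect_equal(ramp$conc, 0.1 * 2 * sched$t_mid)
  # 2T5P with k4 = 0 is exactly 2T4P
  p4 <- kinetic_params(vb = 0.1, K1 = 0.3, k2 = 0.1, k3 = 0.02, k4 = 0)
  expect_equal(model_tac(p4, bc, sched, model = "2T5P")$conc,
               model_tac(p4, bc, sched, model = "2T4P")$conc)
  # model id forces absent parameters to zero
  p5 <- kinetic_params(vb = 0.1, K1 = 0.3, k2 = 0.1, k3 = 0.02, k4 = 0.01)
  expect_equal(model_tac(p5, bc, sched, model = "2T4P")$conc,
               model_tac(p4, bc, sched)$conc)
  expect_error(model_tac(c(vb = 0.1, K1 = -1, k2 = 0, k3 = 0, k4 = 0),
                         bc, sched), ">= 0")
})

test_that("model TAC is linear in the input", {
  bc <- ref_blood()
  sched <- ref_schedule()
  p <- bone_marrow_params()
  scaled <- blood_curve(3 * bc$amplitude, bc$rate)
  expect_equal(model_tac(p, scaled, sched)$conc,
               3 * model_tac(p, bc, sched)$conc)
})

test_that("compartment curves satisfy the ODE and partition the tissue signal", {
  bc <- ref_blood()
  p <- spleen_params()
  h <- 0.04
  grid <- seq(0, 2940, by = h)
  cc <- compartment_curves(p, bc, grid)
  expect_true(all(cc$C1 >= 0) && all(cc$C2 >= 0))
  # C1 + C2 equals the tissue part of the model at matching times
  expect_equal(cc$tissue, cc$C1 + cc$C2)
  # mass balance of the reversible two-tissue system: the only exchange
  # with blood runs through C1, so d/dt(C1 + C2) = K1 Cp - k2 C1
  interior <- 2:(length(grid) - 1)
  dtot <- (cc$tissue[interior + 1] - cc$tissue[interior - 1]) / (2 * h)
  rhs <- p[["K1"]] * eval_blood(bc, grid[interior]) -
    p[["k2"]] * cc$C1[interior]
  expect_lt(max(abs(dtot - rhs)) / max(abs(rhs)), 1e-4)
  # and the bound compartment alone obeys dC2/dt = k3 C1 - k4 C2
  dC2 <- (cc$C2[interior + 1] - cc$C2[interior - 1]) / (2 * h)
  rhs2 <- p[["k3"]] * cc$C1[interior] - p[["k4"]] * cc$C2[interior]
  expect_lt(max(abs(dC2 - rhs2)) / max(abs(rhs2)), 1e-4)
  # bound compartment: k3 = 0 kills it; k4 > 0 gives one interior peak
  cc0 <- compartment_curves(kinetic_params(vb = 0.1, K1 = 0.3, k2 = 0.1),
                            bc, grid)
  expect_equal(cc0$C2, rep(0, length(grid)))
  peak <- which.max(cc$C2)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  expect_true(all(diff(cc$C2[peak:length(grid)]) <= 0))
})

test_that("frame weights follow duration and decay with late down-weighting", {
  sched <- ref_schedule()
  w <- frame_weights(sched)
  expect_equal(sum(w), nrow(sched))
  # raw (un-normalised) law: two equal frames one half-life apart -> 2:1
  toy <- tibble::tibble(t_start = c(0, 78.4 * 60), t_end = c(0, 78.4 * 60) + 1)
  wt <- frame_weights(toy, late_downweight = 1)
  expect_equal(wt[1] / wt[2], 2)
  # dynamic frames ordered by duration x decay
  lam <- log(2) / (78.4 * 60)
  dyn <- sched$session == "dynamic"
  raw <- sched$dur * exp(-lam * sched$t_mid)
  expect_equal(order(w[dyn]), order(raw[dyn]))
  # late frames down-weighted by 10, 48-h below 6-h
  w1 <- frame_weights(sched, late_downweight = 1)
  ratio <- (w1 / sum(w1)) / (w / sum(w))
  expect_equal(unname(ratio[sched$session == "6h"] /
                        ratio[sched$session == "dynamic"][1]), 10)
  expect_lt(w[sched$session == "48h"], w[sched$session == "6h"])
})

test_that("Ki macroparameter follows the trapping algebra", {
  expect_equal(ki_macro(c(K1 = 0.2, k2 = 0.1, k3 = 0.1)), 0.1)
  expect_equal(ki_macro(c(K1 = 0.5, k2 = 0.3, k3 = 0)), 0)
  expect_equal(ki_macro(c(K1 = 0.4, k2 = 0, k3 = 0.05)), 0.4)
  expect_warning(out <- ki_macro(c(K1 = 0.4, k2 = 0, k3 = 0)), "degenerate")
  expect_equal(out, 0)
})

test_that("noiseless fits recover generating parameters to 0.1%", {
  bc <- ref_blood()
  sched <- ref_schedule()
  cases <- list(
    list(model = "2T5P", p = bone_marrow_params(), fixed = NULL),
    list(model = "2T4P",
         p = kinetic_params(vb = 0.15, K1 = 0.02, k2 = 0.08, k3 = 0.01),
         fixed = NULL),
    list(model = "1T3P",
         p = kinetic_params(vb = 0.05, K1 = 0.02, k2 = 0.005), fixed = NULL)
  )
  for (cs in cases) {
    tac <- model_tac(cs$p, bc, sched, model = cs$model)
    fit <- fit_model(tac, bc, model = cs$model, fixed = cs$fixed)
    expect_true(fit$converged)
    free_true <- cs$p[fit$free]
    expect_lt(max(abs(fit$params[fit$free] - free_true) /
                    pmax(free_true, 1e-12)), 1e-3)
    expect_equal(fit$ki, ki_macro(cs$p), tolerance = 1e-3)
  }
})

test_that("fixed parameters are honoured, not estimated", {
  bc <- ref_blood()
  sched <- ref_schedule()
  tac <- model_tac(spleen_params(), bc, sched)
  fit <- fit_model(tac, bc, model = "2T5P", fixed = c(vb = 0.4))
  expect_identical(fit$params[["vb"]], 0.4)
  expect_false("vb" %in% fit$free)
  expect_equal(fit$k, 4)
  expect_error(fit_model(tac, bc, model = "2T5P", fixed = c(vb = 0.9)),
               "bounds")
  expect_error(fit_model(tac, bc, model = "1T3P", fixed = c(k4 = 0.1)),
               "named")
})

test_that("nested models can never fit better than richer ones", {
  bc <- ref_blood()
  sched <- ref_schedule()
  withr::local_seed(23)
  # strong late washout: 2T-generated data poorly served by 1T
  p <- kinetic_params(vb = 0.2, K1 = 0.4, k2 = 0.3, k3 = 0.05, k4 = 2e-3)
  for (i in 1:5) {
    noisy <- generate_tissue(p, bc, sched, Sc = 0.05, seed = 100 + i)
    w1 <- fit_model(noisy, bc, model = "1T3P")$wrss
    w4 <- fit_model(noisy, bc, model = "2T4P")$wrss
    w5 <- fit_model(noisy, bc, model = "2T5P")$wrss
    expect_lte(w5, w4 + 1e-12)
    expect_lte(w4, w1 + 1e-12)
    expect_gt(w1, w4) # washout actually distinguishes the families
  }
})
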