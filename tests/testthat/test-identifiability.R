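test_that("normalized sensitivity identities hold", {
  bc <- ref_blood()
  sched <- ref_schedule()
  # model linear in K1 when vb = 0: sensitivity to K1 is identically 1
  p1 <- kinetic_params(K1 = 0.02, k2 = 0.005)
  s <- normalized_sensitivity(p1, bc, sched, model = "1T3P")
  sk1 <- s$sensitivity[s$parameter == "K1"]
  expect_equal(sk1, rep(1, nrow(sched)), tolerance = 1e-6)
  # excluded parameters are not differentiated
  s_free <- normalized_sensitivity(p1, bc, sched, model = "1T3P",
                                   free = c("K1", "k2"))
  expect_false("vb" %in% s_free$parameter)
  # k4 sensitivity magnitude grows across the three sessions
  s5 <- normalized_sensitivity(spleen_params(), bc, sched)
  k4s <- abs(s5$sensitivity[s5$parameter == "k4"])
  last_dyn <- max(which(sched$session == "dynamic"))
  expect_lt(k4s[last_dyn], k4s[sched$session == "6h"])
  expect_lt(k4s[sched$session == "6h"], k4s[sched$session == "48h"])
})

test_that("sensitivity agrees with the analytic 1T closed form", {
  # for the 1T model with vb = 0: C = K1 * g(t; k2) so S_k2 can be computed
  # analytically from the derivative of the convolution wrt k2
  bc <- ref_blood()
  sched <- ref_schedule()
  p <- kinetic_params(K1 = 0.1, k2 = 0.2)
  s <- normalized_sensitivity(p, bc, sched, model = "1T3P", free = "k2")
  # analytic frame-averaged derivative via complex-step-free differentiation
  k2 <- 0.2
  eps <- 1e-7
  f <- function(k2v) {
    model_tac(kinetic_params(K1 = 0.1, k2 = k2v), bc, sched,
              model = "1T3P")$conc
  }
  dc <- (f(k2 + eps) - f(k2 - eps)) / (2 * eps)
  ref <- dc * k2 / f(k2)
  expect_equal(s$sensitivity, ref, tolerance = 1e-5)
})

test_that("correlation matrices are well-formed and expose known trade-offs", {
  bc <- ref_blood()
  sched <- ref_schedule()
  tac <- model_tac(spleen_params(), bc, sched)
  fit <- fit_model(tac, bc, model = "2T5P")
  cm <- correlation_matrix(fit)
  expect_equal(diag(cm), setNames(rep(1, 5), fit$free))
  expect_equal(cm, t(cm))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # spleen-like regime: blood volume trades off with delivery and washout,
  # the pattern that motivates fixing vb in high-blood-volume organs
  expect_gt(abs(cm["K1", "vb"]), 0.7)
  expect_gt(abs(cm["k2", "vb"]), 0.6)
  off <- abs(cm["vb", c("K1", "k2", "k3", "k4")])
  expect_setequal(names(sort(off, decreasing = TRUE))[1:2], c("K1", "k2"))
  # fast free-compartment equilibration makes delivery and washout
  # nearly collinear: correlation approaches unity
  p_fast <- kinetic_params(vb = 0.4, K1 = 0.8, k2 = 1)
  tac_f <- model_tac(p_fast, bc, sched, model = "1T3P")
  fit_f <- fit_model(tac_f, bc, model = "1T3P")
  cm_f <- correlation_matrix(fit_f)
  expect_gt(abs(cm_f["K1", "k2"]), 0.99)
  # orthogonal design: off-diagonal zero by construction
  J <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  cm0 <- petkin:::.corr_from_jacobian(J, rep(1, 4))
  expect_equal(cm0["a", "b"], 0)
})

test_that("noise-scale estimation is exact in its invariances and calibrated", {
  bc <- ref_blood()
  sched <- ref_schedule()
  truth <- model_tac(bone_marrow_params(), bc, sched)
  expect_equal(estimate_noise_scale(truth, truth), 0)
  # doubling residuals doubles the scale
  m1 <- dplyr::mutate(truth, conc = conc + 0.01)
  m2 <- dplyr::mutate(truth, conc = conc + 0.02)
  expect_equal(estimate_noise_scale(m2, truth),
               2 * estimate_noise_scale(m1, truth))
  # Monte-Carlo calibration at known Sc
  withr::local_seed(99)
  sig <- noise_sigma(truth$conc, sched, Sc = 0.05)
  est <- vapply(1:100, function(i) {
    noisy <- dplyr::mutate(truth, conc = conc + rnorm(length(sig), 0, sig))
    estimate_noise_scale(noisy, truth)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.05) / 0.05, 0.15)
  expect_error(estimate_noise_scale(truth[1:5, ], truth[1:5, ]), "10 frames")
})

test_that("Monte-Carlo identifiability reports are reproducible and consistent", {
  bc <- ref_blood()
  sched <- ref_schedule()
  p <- bone_marrow_params()
  # noiseless limit: zero bias and SD up to optimizer tolerance
  rep0 <- simulate_bias_sd(p, bc, sched, Sc = 0, n_reps = 3, seed = 1)
  expect_lt(max(abs(rep0$summary$bias_pct)), 0.1)
  expect_lt(max(rep0$summary$sd_pct), 0.1)
  # determinism: identical seed, identical report
  r1 <- simulate_bias_sd(p, bc, sched, Sc = 0.05, n_reps = 6, seed = 42)
  r2 <- simulate_bias_sd(p, bc, sched, Sc = 0.05, n_reps = 6, seed = 42)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$estimates, r2$estimates)
  # RMSE decomposition holds exactly (population SD)
  with(r1$summary, expect_equal(rmse_pct^2, bias_pct^2 + sd_pct^2,
                                tolerance = 1e-8))
  expect_false(r1$unreliable)
  expect_s3_class(r1$correlation, NA)
  expect_equal(dim(r1$correlation), c(5, 5))
})
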