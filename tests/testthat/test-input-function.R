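test_that("blood curve evaluation and integration are analytic and consistent", {
  bc <- ref_blood()
  expect_equal(eval_blood(bc, 0), sum(bc$amplitude))
  expect_equal(integral_blood(bc, 0), 0)
  # constant curve: zero rates allowed
  const <- blood_curve(c(2, 1), c(0, 0))
  expect_equal(eval_blood(const, c(0, 50, 1000)), rep(3, 3))
  expect_equal(integral_blood(const, 10), 30)
  # limit t -> infinity for positive rates
  expect_equal(integral_blood(bc, 1e9), sum(bc$amplitude / bc$rate))
  # agreement with numerical quadrature at 90 min
  quad <- stats::integrate(function(s) eval_blood(bc, s), 0, 90,
                           rel.tol = 1e-12)$value
  expect_equal(integral_blood(bc, 90), quad, tolerance = 1e-8)
  # derivative of the integral is the curve (finite differences)
  h <- 1e-4
  for (t in c(0.5, 5, 60, 400, 2900)) {
    fd <- (integral_blood(bc, t + h) - integral_blood(bc, t - h)) / (2 * h)
    expect_equal(fd, eval_blood(bc, t), tolerance = 1e-6)
  }
  expect_error(eval_blood(bc, -1), ">= 0")
})

test_that("frame-averaged evaluation matches the closed-form integral", {
  # single exponential over [0, T]: A (1 - exp(-lambda T)) / (lambda T)
  bc <- blood_curve(2, 0.1)
  sched <- tibble::tibble(t_start = 0, t_end = 20)
  expect_equal(eval_blood_frames(bc, sched),
               2 * (1 - exp(-0.1 * 20)) / (0.1 * 20))
})

test_that("normalized time is monotone increasing", {
  withr::local_seed(11)
  for (i in 1:20) {
    hl <- sort(c(runif(1, 2, 10), runif(1, 25, 130), runif(1, 700, 3100)))
    f <- runif(3, 0.1, 1)
    bc <- generate_blood(hl, f / sum(f), scale = runif(1, 1, 10))
    t <- ref_schedule()$t_mid
    x <- integral_blood(bc, t) / eval_blood(bc, t)
    expect_true(all(diff(x) > 0))
  }
})

test_that("noiseless triexponential fits recover the generating half-lives", {
  sched <- ref_schedule()
  # grid spanning the reported clearance ranges: initial 2.6-8.1 min,
  # intermediate 29.3-120 min, terminal 13.4-50.4 h
  grid <- list(
    c(5.1, 55.9, 22.1 * 60),
    c(2.6, 29.3, 13.4 * 60),
    c(8.1, 120, 50.4 * 60),
    c(2.6, 120, 13.4 * 60),
    c(8.1, 29.3, 50.4 * 60)
  )
  for (hl in grid) {
    bc <- generate_blood(hl, c(0.6, 0.3, 0.1), scale = 3.7)
    btac <- dplyr::mutate(sched, conc = eval_blood_frames(bc, sched))
    fit <- fit_triexponential(btac)
    expect_true(fit$converged)
    expect_false(fit$degenerate)
    expect_lt(max(abs(fit$half_lives_min - hl) / hl), 0.01)
  }
})

test_that("triexponential fitting flags nested-model degeneracy", {
  sched <- ref_schedule()
  mono <- blood_curve(3.7, log(2) / 55.9)
  btac <- dplyr::mutate(sched, conc = eval_blood_frames(mono, sched))
  fit <- fit_triexponential(btac)
  expect_true(fit$degenerate)
  # the fitted curve still reproduces the data
  expect_lt(fit$wrss, 1e-10)
})

test_that("triexponential fit is equivariant under amplitude scaling", {
  sched <- ref_schedule()
  bc <- ref_blood()
  btac <- dplyr::mutate(sched, conc = eval_blood_frames(bc, sched))
  f1 <- fit_triexponential(btac)
  f2 <- fit_triexponential(dplyr::mutate(btac, conc = conc * 4))
  expect_equal(f2$curve$amplitude, 4 * f1$curve$amplitude, tolerance = 1e-6)
  expect_equal(f2$curve$rate, f1$curve$rate, tolerance = 1e-6)
})

test_that("blood curve JSON round-trips", {
  bc <- ref_blood()
  path <- withr::local_tempfile(fileext = ".json")
  write_blood_json(bc, path)
  back <- read_blood_json(path)
  expect_equal(back$amplitude, bc$amplitude)
  expect_equal(back$rate, bc$rate)
})

test_that("blood curve constructors validate their inputs", {
  expect_error(generate_blood(c(5, 4, 100)), "increasing")
  expect_error(generate_blood(fractions = c(0.5, 0.3, 0.1)), "sum to 1")
  expect_error(blood_curve(c(1, -1), c(0.1, 0.2)), ">= 0")
  # single-component and time-rescaling laws
  mono <- generate_blood(10, 1, scale = 5)
  expect_equal(eval_blood(mono, 10), 2.5)
  doubled <- generate_blood(c(10.2, 111.8, 2652), c(0.6, 0.3, 0.1))
  bc <- ref_blood()
  expect_equal(eval_blood(doubled, 2 * c(1, 7, 300)),
               eval_blood(bc, c(1, 7, 300)))
})
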