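test_that("closed-form and ODE solutions agree and conserve mass", {
  set.seed(11)
  grid <- c(0, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16, 24)
  for (k in 1:20) {
    p <- random_params()
    a <- pk_profile(p, dose_event(1), grid)
    o <- pk_profile_ode(p, dose_event(1), grid)
    scale <- max(abs(as.matrix(a[, 2:7])))
    expect_lt(max(abs(as.matrix(a[, 2:7]) - as.matrix(o[, 2:7]))),
              1e-8 * scale)
    mb <- a$x_gut + a$x_central + a$x_peripheral + a$x_urine + a$x_other
    expect_lt(max(abs(mb - p$f * 1)), 1e-9)
  }
})

test_that("one-compartment IV collapses to a mono-exponential", {
  p <- structural_params(ka = 1, k12 = 0, k21 = 0, kel = 0.2, kel_ur = 0,
                         vc = 0.5, f = 1)
  tt <- seq(0, 48, by = 2)
  prof <- pk_profile(p, dose_event(1, route = "intravenous"), tt)
  expect_equal(prof$conc, (1 / 0.5) * 1000 * exp(-0.2 * tt), tolerance = 1e-12)
  expect_equal(prof$x_urine, rep(0, length(tt)))
})

test_that("initial conditions and monotonicity hold after an oral dose", {
  p <- control_params()
  tt <- c(0, sort(runif(40, 0.01, 48)))
  prof <- pk_profile(p, dose_event(1), tt)
  expect_equal(prof$conc[1], 0)
  expect_equal(prof$x_urine[1], 0)
  expect_equal(prof$x_gut[1], p$f * 1)
  expect_true(all(diff(prof$x_urine) >= 0))
  expect_true(all(diff(prof$x_other) >= 0))
  expect_true(all(diff(prof$x_gut) <= 0))
  expect_true(all(prof$conc >= 0))
  # unimodal: once the concentration starts falling it keeps falling
  d <- diff(prof$conc)
  first_fall <- which(d < 0)[1]
  expect_true(all(d[first_fall:length(d)] <= 1e-12))
})

test_that("asymptotic urinary recovery matches f * kel_ur / (kel + kel_ur)", {
  p <- control_params()
  lim <- pk_profile(p, dose_event(1), 200)$x_urine[[1]]
  expect_equal(lim, p$f * p$kel_ur / (p$kel + p$kel_ur), tolerance = 1e-6)
  # peak plasma concentration is bounded by the full bioavailable dose in vc
  prof <- pk_profile(p, dose_event(1), seq(0, 24, by = 0.05))
  expect_lt(max(prof$conc), 1000 * p$f / p$vc)
})

test_that("very fast oral absorption approaches the f-scaled IV bolus", {
  p_fast <- structural_params(ka = 1e3, k12 = 0.803, k21 = 0.965,
                              kel = 0.839, kel_ur = 0.190, vc = 0.448,
                              f = 0.867)
  p_iv <- control_params()
  tt <- c(1, 2, 4, 8)
  oral <- pk_profile_ode(p_fast, dose_event(1), tt, rtol = 1e-11)
  iv <- pk_profile(p_iv, dose_event(p_iv$f, route = "intravenous"), tt)
  expect_equal(oral$conc, iv$conc, tolerance = 1e-2)
})

test_that("zero-concentration trajectory for a zero-time grid edge cases", {
  p <- control_params()
  # dose at a later time: earlier samples are zero
  prof <- pk_profile(p, dose_event(1, time = 2), c(0, 1, 2, 3))
  expect_equal(prof$conc[1:3], c(0, 0, 0))
  expect_gt(prof$conc[4], 0)
})

test_that("coincident exponents are handled by the matrix-exponential path", {
  # ka exactly equal to alpha of the disposition system
  p0 <- structural_params(ka = 1, k12 = 0, k21 = 0, kel = 1, kel_ur = 0,
                          vc = 1, f = 1)
  tt <- c(0.5, 1, 2, 4)
  a <- pk_profile(p0, dose_event(1), tt)
  o <- pk_profile_ode(p0, dose_event(1), tt)
  expect_equal(a$conc, o$conc, tolerance = 1e-7)
  # analytic limit for ka == kel in one compartment: D k t e^{-kt} / vc
  expect_equal(a$conc, 1000 * tt * exp(-tt), tolerance = 1e-7)
})

test_that("parameter domain is enforced", {
  expect_error(structural_params(-1, 1, 1, 1, 1, 1, 0.9), "ka")
  expect_error(structural_params(1, 1, 1, 0, 0, 1, 0.9), "elimination")
  expect_error(structural_params(1, 1, 1, 1, 1, -1, 0.9), "vc")
  expect_error(structural_params(1, 1, 1, 1, 1, 1, 1.2), "f")
  expect_error(pk_profile(control_params(), dose_event(1), c(2, 1)), "sorted")
  expect_error(dose_event(-1), "amount")
})

test_that("macro constants reproduce the published absorption half-lives", {
  p_ctl <- control_params()
  expect_equal(round(macro_constants(p_ctl)$t_half_abs, 2), 0.54)
  p_oy <- structural_params(ka = 0.523, k12 = 0.803, k21 = 0.965,
                            kel = 0.839, kel_ur = 0.190, vc = 0.448,
                            f = 0.788)
  mc <- macro_constants(p_oy)
  expect_equal(round(mc$t_half_abs, 2), 1.33)
  # alpha, beta are the eigenvalues of the 2x2 disposition matrix
  k10 <- 0.839 + 0.190
  A <- matrix(c(-(0.803 + k10), 0.965, 0.803, -0.965), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A)$values)
  expect_equal(sort(c(mc$alpha, mc$beta)), ev, tolerance = 1e-12)
  expect_equal(mc$alpha * mc$beta, 0.965 * k10, tolerance = 1e-12)
  expect_equal(mc$alpha + mc$beta, 0.803 + 0.965 + k10, tolerance = 1e-12)
  expect_false(mc$flip_flop)
  # slow absorption below beta flips the terminal phase
  p_ff <- structural_params(ka = 0.05, k12 = 0.803, k21 = 0.965,
                            kel = 0.839, kel_ur = 0.190, vc = 0.448, f = 0.8)
  mcf <- macro_constants(p_ff)
  expect_true(mcf$flip_flop)
  expect_equal(mcf$t_half_terminal, log(2) / 0.05)
})
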