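test_that("noise-free mono-exponential IV data are recovered exactly", {
  p <- structural_params(ka = 1, k12 = 0, k21 = 0, kel = 0.2, kel_ur = 0,
                         vc = 0.5, f = 1)
  tt <- seq(0.5, 48, by = 0.5)
  prof <- pk_profile(p, dose_event(1, route = "intravenous"), tt)
  dat <- tibble::tibble(id = "iv1", group = "control",
                        type = c("dose", rep("plasma", length(tt))),
                        time = c(0, tt), value = c(1, prof$conc), flag = "")
  r <- run_nca(dat, route = "intravenous")
  expect_true(is.na(r$failure))
  # lambda_z equals the generating rate to 6 significant figures
  expect_equal(r$lambda_z, 0.2, tolerance = 1e-6)
  expect_equal(r$t_half, log(2) / 0.2, tolerance = 0.02 * log(2) / 0.2)
  # CL = vc * kel = 0.1 L/hr/kg = 1.667 mL/min/kg
  expect_equal(r$cl_f, 0.1 * 1000 / 60, tolerance = 0.02 * 0.1 * 1000 / 60)
  expect_equal(r$vz_f, 0.5, tolerance = 0.01)
})

test_that("oral control profile at the 9-point schedule matches the analytic AUC", {
  p <- control_params()
  dat <- noise_free_dataset(p)
  r <- run_nca(dat, iv_auc_ref = baclofen_iv_auc_reference())
  auc_true <- 1000 * p$f / (p$vc * (p$kel + p$kel_ur))
  expect_lt(abs(r$auc_inf - auc_true) / auc_true, 0.05)
  expect_true(r$auc_inf >= r$auc_all)
  # terminal slope approximates beta of the disposition system
  beta <- macro_constants(p)$beta
  expect_equal(r$lambda_z, beta, tolerance = 0.02 * beta)
  expect_equal(r$fe_urine, 100 * pk_profile(p, dose_event(1), 24)$x_urine[[1]],
               tolerance = 1e-8)
  # trapezoid refinement converges to the analytic integral
  dense <- noise_free_dataset(p, times = seq(1 / 60, 72, by = 1 / 60))
  r_dense <- run_nca(dense)
  expect_lt(abs(r_dense$auc_inf - auc_true) / auc_true, 1e-3)
})

test_that("Cmax and Tmax are read directly from the observations", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12)
  y <- c(10, 50, 50, 40, 20, 5, 1)  # tied maximum: first occurrence wins
  dat <- tibble::tibble(id = "s", group = "g",
                        type = c("dose", rep("plasma", 7)),
                        time = c(0, tt), value = c(1, y), flag = "")
  r <- run_nca(dat)
  expect_equal(r$cmax, 50)
  expect_equal(r$tmax, 0.5)
  expect_true(r$tmax %in% tt)
})

test_that("degenerate profiles fail with a structured reason", {
  flat <- tibble::tibble(id = "s", group = "g",
                         type = c("dose", rep("plasma", 5)),
                         time = c(0, 1:5), value = c(1, rep(7, 5)), flag = "")
  r <- run_nca(flat)
  expect_match(r$failure, "lambda_z")
  expect_true(is.na(r$auc_inf))

  few <- tibble::tibble(id = "s", group = "g",
                        type = c("dose", rep("plasma", 3)),
                        time = c(0, 1:3), value = c(1, 3, 2, 1), flag = "")
  expect_match(run_nca(few)$failure, "fewer than 4")
})

test_that("group summaries are arithmetic mean and SD", {
  r <- tibble::tibble(
    id = c("a", "b", "c", "d"), group = c("g1", "g1", "g2", "g2"),
    failure = NA_character_,
    t_half = c(1, 3, 2, 2), tmax = c(1, 1, 1, 1), cmax = c(5, 7, 6, 6),
    auc_all = c(1, 3, 2, 2), auc_inf = c(1, 3, 2, 2), vz_f = c(1, 1, 1, 1),
    cl_f = c(1, 3, 2, 2), fe_urine = c(50, 60, 55, 55),
    f_pct = c(NA, NA, NA, NA)
  )
  s <- nca_summary(r)
  th <- s[s$parameter == "t_half" & s$group == "g1", ]
  expect_equal(th$mean, 2)
  expect_equal(th$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(th$n, 2L)
  # identical subjects give SD exactly 0
  expect_equal(s$sd[s$parameter == "tmax"], c(0, 0))
  # all-NA parameters are dropped rather than summarised
  expect_false("f_pct" %in% s$parameter)
})

test_that("bioavailability uses the dose-normalized IV reference", {
  p <- control_params()
  dat <- noise_free_dataset(p)
  ref <- baclofen_iv_auc_reference()
  r <- run_nca(dat, iv_auc_ref = ref)
  expect_equal(r$f_pct, 100 * r$auc_inf / ref)
  expect_true(is.na(run_nca(dat)$f_pct))
})
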