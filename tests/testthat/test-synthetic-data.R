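test_that("zero variability reproduces the population medians exactly", {
  pop <- quiet_population(bsv = 0, resid_prop = 0, resid_add = 0)
  set.seed(1)
  ind <- draw_individual(pop, "OY")
  expect_equal(ind$ka, pop$ka[["OY"]])
  expect_equal(ind$f, pop$f[["OY"]])
  expect_equal(ind$vc, pop$vc)

  # full round trip: observations equal model predictions exactly
  pop$urine_cv <- 0
  dat <- simulate_study(pop, study_design(), seed = 5)
  one <- dat[dat$id == "control_01" & dat$type == "plasma", ]
  pred <- pk_profile(
    structural_params(pop$ka[["control"]], pop$k12, pop$k21, pop$kel,
                      pop$kel_ur, pop$vc, pop$f[["control"]]),
    dose_event(1), one$time
  )$conc
  expect_equal(one$value, pred)
  ur <- dat[dat$id == "AB_02" & dat$type == "urine", ]
  uf <- pk_profile(
    structural_params(pop$ka[["AB"]], pop$k12, pop$k21, pop$kel,
                      pop$kel_ur, pop$vc, pop$f[["AB"]]),
    dose_event(1), 24
  )$x_urine[[1]]
  expect_equal(ur$value, uf)
})

test_that("the CV <-> omega mapping yields the requested sample CV", {
  pop <- population_model()
  set.seed(42)
  draws <- replicate(10000, draw_individual(pop, "control")$ka)
  cv_hat <- sd(draws) / mean(draws)
  expect_lt(abs(cv_hat - 0.558), 0.03)
  # log-normal medians are preserved
  expect_equal(exp(mean(log(draws))), 1.28, tolerance = 0.03)
})

test_that("simulated datasets are deterministic under a fixed seed", {
  pop <- population_model()
  des <- study_design()
  d1 <- simulate_study(pop, des, seed = 99)
  d2 <- simulate_study(pop, des, seed = 99)
  expect_identical(d1, d2)
  d3 <- simulate_study(pop, des, seed = 100)
  expect_false(identical(d1$value, d3$value))
})

test_that("the default design matches the emulated study layout", {
  dat <- simulate_study(population_model(), study_design(), seed = 3)
  counts <- dplyr::count(dat, group, type) |>
    tidyr::pivot_wider(names_from = type, values_from = n)
  expect_setequal(counts$group, c("control", "OY", "AB"))
  expect_equal(counts$plasma[counts$group == "control"], 6L * 9L)
  expect_equal(counts$plasma[counts$group == "OY"], 4L * 9L)
  expect_equal(counts$plasma[counts$group == "AB"], 5L * 9L)
  expect_equal(sum(counts$dose), 15L)
  expect_equal(sum(counts$urine), 15L)
  expect_true(all(dat$value[dat$type == "plasma"] >= 0))
  tp <- attr(dat, "true_params")
  expect_equal(nrow(tp), 15L)
  expect_true(all(tp$f <= 1))
})

test_that("slow-absorption arm depresses Cmax in the large-n limit", {
  des <- study_design(groups = tibble::tibble(
    label = c("control", "OY", "AB"), n = c(100L, 100L, 100L)))
  dat <- simulate_study(population_model(), des, seed = 7)
  cmax <- dat |>
    dplyr::filter(type == "plasma") |>
    dplyr::group_by(group, id) |>
    dplyr::summarise(cmax = max(value), .groups = "drop") |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(cmax))
  m <- setNames(cmax$m, cmax$group)
  expect_lt(m[["OY"]], m[["control"]])
  expect_lt(m[["OY"]], m[["AB"]])
})

test_that("negative observations are truncated and flagged", {
  pop <- population_model(add_sd = 400)  # huge additive noise
  dat <- simulate_study(pop, study_design(), seed = 21)
  pl <- dat[dat$type == "plasma", ]
  expect_true(any(pl$flag == "truncated"))
  expect_true(all(pl$value[pl$flag == "truncated"] == 0))
  expect_true(all(pl$value >= 0))
})

test_that("unknown design groups are rejected", {
  des <- study_design(groups = tibble::tibble(label = "placebo", n = 3L))
  expect_error(simulate_study(population_model(), des, seed = 1),
               "placebo")
  expect_error(draw_individual(population_model(), "nope"), "unknown group")
})

test_that("swap_elimination exchanges the elimination split", {
  pop <- population_model(swap_elimination = TRUE)
  expect_equal(pop$kel, 0.190)
  expect_equal(pop$kel_ur, 0.839)
  expect_equal(pop$bsv_cv[["kel"]], 0.066)
  # swapped model recovers most of the dose in urine, as observed
  p <- structural_params(pop$ka[["control"]], pop$k12, pop$k21, pop$kel,
                         pop$kel_ur, pop$vc, pop$f[["control"]])
  expect_gt(pk_profile(p, dose_event(1), 200)$x_urine[[1]], 0.6)
})
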