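# Shared fixtures built in code.

# Published control-arm population medians.
control_params <- function() {
  structural_params(ka = 1.28, k12 = 0.803, k21 = 0.965,
                    kel = 0.839, kel_ur = 0.190, vc = 0.448, f = 0.867)
}

paper_times <- function() c(5 / 60, 15 / 60, 30 / 60, 1, 2, 4, 8, 12, 24)

# Random valid parameter draw over a broad domain (for property tests).
random_params <- function() {
  structural_params(
    ka = stats::runif(1, 0.1, 5),
    k12 = stats::runif(1, 0.05, 3),
    k21 = stats::runif(1, 0.05, 3),
    kel = stats::runif(1, 0.05, 2),
    kel_ur = stats::runif(1, 0.01, 2),
    vc = stats::runif(1, 0.1, 3),
    f = stats::runif(1, 0.3, 1)
  )
}

# One-subject long-format dataset from a noise-free profile.
noise_free_dataset <- function(params = control_params(), times = paper_times(),
                               dose = 1, id = "s1", group = "control",
                               urine_time = 24) {
  prof <- pk_profile(params, dose_event(dose), times)
  rows <- tibble::tibble(
    id = id, group = group,
    type = c("dose", rep("plasma", length(times))),
    time = c(0, times), value = c(dose, prof$conc), flag = ""
  )
  if (!is.na(urine_time)) {
    uf <- pk_profile(params, dose_event(dose), urine_time)$x_urine[[1]] / dose
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      id = id, group = group, type = "urine", time = urine_time,
      value = uf, flag = ""
    ))
  }
  rows
}

# A small quiet population for quick fitting tests: no BSV unless asked.
quiet_population <- function(bsv = 0, resid_prop = 0.02, resid_add = 0.5) {
  population_model(
    bsv_cv = c(k12 = bsv, k21 = bsv, kel = bsv, kel_ur = bsv, vc = bsv),
    bsv_cv_ka = c(control = bsv, OY = bsv, AB = bsv),
    bsv_cv_f = c(control = bsv, OY = bsv, AB = bsv),
    prop_cv = resid_prop, add_sd = resid_add, urine_cv = max(bsv, 0.02)
  )
}
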