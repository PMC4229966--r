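#' Noncompartmental analysis of a PK dataset
#'
#' Computes, for every subject in a long-format dataset, the standard
#' noncompartmental parameter set: `cmax` and `tmax` read directly from
#' the observations (first occurrence on ties); the terminal slope
#' `lambda_z` by unweighted log-linear regression over an automatically
#' selected terminal window; `t_half = ln(2) / lambda_z`; `auc_all` by the
#' linear-up/log-down trapezoid to the last positive observation;
#' `auc_inf = auc_all + c_last / lambda_z`; apparent clearance
#' `cl_f = dose / auc_inf` (mL/min/kg) and terminal volume
#' `vz_f = dose / (lambda_z * auc_inf)` (L/kg); the fraction of dose
#' excreted in urine `fe_urine` (%); and, when an intravenous reference
#' AUC is supplied, the absolute bioavailability
#' `f_pct = 100 * (auc_inf / dose) / iv_auc_ref`.
#'
#' Terminal window selection: among observations strictly after `tmax`
#' with positive concentration, every contiguous window of at least
#' `min_points` points ending at the last observation is fit by
#' `lm(log(conc) ~ time)`; the window with the best adjusted R-squared and
#' a negative slope wins, ties (within 1e-9) broken toward more points.
#' Subjects whose terminal phase cannot be fit are returned with
#' `failure` set and numeric results `NA`.
#'
#' For oral dosing a zero-concentration anchor at the dose time is
#' prepended before computing AUC, so the rising segment from dose to
#' first sample is included (linearly). For intravenous dosing, C0 is
#' back-extrapolated log-linearly through the first two observations.
#'
#' @param data Long-format dataset (see [validate_pk_dataset()]).
#' @param iv_auc_ref Dose-normalized intravenous reference AUC
#'   (ng·hr/mL per mg/kg) for absolute bioavailability, or `NULL` to skip
#'   `f_pct`. See [baclofen_iv_auc_reference()] for the shipped value.
#' @param auc_method `"lin-up-log-down"` (default) or `"linear"`.
#' @param min_points Minimum number of points in the terminal window.
#' @param route `"oral"` (default) or `"intravenous"`; controls the
#'   time-zero anchor described above.
#'
#' @return A tibble with one row per subject: `id`, `group`, `n_obs`,
#'   `cmax`, `tmax`, `lambda_z`, `t_half`, `auc_all`, `auc_inf`, `vz_f`,
#'   `cl_f`, `fe_urine`, `f_pct`, and the lambda-z diagnostics
#'   `lz_n_points`, `lz_adj_r2`, `auc_extrap_pct`, plus `failure`
#'   (`NA` when the subject was analysed successfully).
#' @examples
#' dat <- simulate_study(population_model(), study_design(), seed = 1)
#' run_nca(dat, iv_auc_ref = baclofen_iv_auc_reference())
#' @export
run_nca <- function(data, iv_auc_ref = NULL,
                    auc_method = c("lin-up-log-down", "linear"),
                    min_points = 3, route = c("oral", "intravenous")) {
  auc_method <- match.arg(auc_method)
  route <- match.arg(route)
  subjects <- .split_subjects(data)
  purrr::map_dfr(subjects, function(s) {
    .nca_one(s, iv_auc_ref = iv_auc_ref, auc_method = auc_method,
             min_points = min_points, route = route)
  })
}

.nca_one <- function(s, iv_auc_ref, auc_method, min_points, route) {
  na_row <- tibble::tibble(
    id = s$id, group = s$group, n_obs = length(s$conc),
    cmax = NA_real_, tmax = NA_real_, lambda_z = NA_real_,
    t_half = NA_real_, auc_all = NA_real_, auc_inf = NA_real_,
    vz_f = NA_real_, cl_f = NA_real_, fe_urine = NA_real_,
    f_pct = NA_real_, lz_n_points = NA_integer_, lz_adj_r2 = NA_real_,
    auc_extrap_pct = NA_real_, failure = NA_character_
  )
  fail <- function(msg) { na_row$failure <- msg; na_row }

  t <- s$times
  y <- s$conc
  if (length(y) < 4) return(fail("fewer than 4 post-dose observations"))
  if (all(y == 0)) return(fail("all concentrations are zero"))

  cmax <- max(y)
  tmax <- t[which.max(y)]  # first occurrence on ties

  lz <- .select_lambda_z(t, y, tmax, min_points)
  if (is.null(lz)) return(fail("no valid terminal window for lambda_z"))

  # AUC over observed span (to the last positive concentration)
  last_pos <- max(which(y > 0))
  ta <- t[seq_len(last_pos)]
  ya <- y[seq_len(last_pos)]
  if (ta[1] > s$dose_time) {
    if (route == "oral") {
      # rising segment from the (zero-concentration) dose time
      ta <- c(s$dose_time, ta)
      ya <- c(0, ya)
    } else if (ya[1] > 0 && ya[2] > 0 && ya[2] < ya[1]) {
      # IV bolus: back-extrapolate C0 log-linearly through the first
      # two observations (standard NCA convention)
      sl <- (log(ya[2]) - log(ya[1])) / (ta[2] - ta[1])
      c0 <- exp(log(ya[1]) - sl * (ta[1] - s$dose_time))
      ta <- c(s$dose_time, ta)
      ya <- c(c0, ya)
    }
  }
  auc_all <- .auc_trapezoid(ta, ya, auc_method)
  c_last <- ya[length(ya)]
  auc_inf <- auc_all + c_last / lz$lambda_z
  extrap <- 100 * (auc_inf - auc_all) / auc_inf

  dose_ng <- s$dose_amount * 1e6  # mg/kg -> ng/kg
  cl_f <- dose_ng / auc_inf / 60  # (ng/kg)/(ng·hr/mL)/60 = mL/min/kg
  vz_f <- dose_ng / (lz$lambda_z * auc_inf) / 1000  # mL/kg -> L/kg

  fe <- if (is.na(s$urine_frac)) NA_real_ else 100 * s$urine_frac
  f_pct <- if (is.null(iv_auc_ref)) NA_real_ else {
    100 * (auc_inf / s$dose_amount) / iv_auc_ref
  }

  tibble::tibble(
    id = s$id, group = s$group, n_obs = length(y),
    cmax = cmax, tmax = tmax, lambda_z = lz$lambda_z,
    t_half = log(2) / lz$lambda_z, auc_all = auc_all, auc_inf = auc_inf,
    vz_f = vz_f, cl_f = cl_f, fe_urine = fe, f_pct = f_pct,
    lz_n_points = lz$n_points, lz_adj_r2 = lz$adj_r2,
    auc_extrap_pct = extrap, failure = NA_character_
  )
}

# Best-adjusted-R^2 terminal window among suffixes of the post-Tmax
# positive observations; ties go to the window with more points.
.select_lambda_z <- function(t, y, tmax, min_points) {
  keep <- t > tmax & y > 0
  tt <- t[keep]
  yy <- y[keep]
  n <- length(tt)
  if (n < min_points) return(NULL)
  best <- NULL
  for (start in seq_len(n - min_points + 1)) {
    ts <- tt[start:n]
    ys <- log(yy[start:n])
    k <- length(ts)
    fit <- stats::lm.fit(cbind(1, ts), ys)
    slope <- fit$coefficients[[2]]
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum(fit$residuals^2)
    tss <- sum((ys - mean(ys))^2)
    if (tss <= 0) next
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-9 ||
        (abs(adj - best$adj_r2) <= 1e-9 && k > best$n_points)) {
      best <- list(lambda_z = -slope, adj_r2 = adj, n_points = k)
    }
  }
  best
}

.auc_trapezoid <- function(t, y, method) {
  dt <- diff(t)
  y1 <- y[-length(y)]
  y2 <- y[-1]
  seg <- (y1 + y2) / 2 * dt
  if (method == "lin-up-log-down") {
    logdown <- y2 < y1 & y2 > 0 & y1 > 0
    seg[logdown] <- (y1[logdown] - y2[logdown]) /
      log(y1[logdown] / y2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Group-level summary of NCA results
#'
#' Arithmetic mean and SD of each noncompartmental parameter per group,
#' in the layout of a summary PK table (one row per parameter per group).
#' Subjects with a `failure` are dropped with a message.
#'
#' @param results Output of [run_nca()].
#'
#' @return A tibble with columns `group`, `parameter`, `n`, `mean`, `sd`.
#' @export
nca_summary <- function(results) {
  failed <- !is.na(results$failure)
  if (any(failed)) {
    message(sum(failed), " subject(s) dropped from summary (NCA failure)")
    results <- results[!failed, ]
  }
  counts <- dplyr::count(results, .data$group)
  if (any(counts$n < 2)) {
    stop("need >= 2 analysable subjects per group to summarise",
         call. = FALSE)
  }
  pars <- c("t_half", "tmax", "cmax", "auc_all", "auc_inf", "vz_f", "cl_f",
            "fe_urine", "f_pct")
  results |>
    dplyr::select("group", dplyr::all_of(pars)) |>
    tidyr::pivot_longer(-"group", names_to = "parameter") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = pars)) |>
    dplyr::arrange(.data$parameter, .data$group) |>
    dplyr::mutate(parameter = as.character(.data$parameter))
}
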