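# Unit conventions, fixed package-wide: time in hr, dose in mg/kg, volumes in
# L/kg, rate constants in 1/hr, plasma concentration in ng/mL. A dose of
# 1 mg/kg distributed into 1 L/kg is 1 mg/L = 1000 ng/mL; that single
# conversion lives in the constant below and nowhere else.
MGKG_PER_LKG_TO_NGML <- 1000

#' Structural pharmacokinetic parameters for one subject
#'
#' Bundles the micro rate constants of the two-compartment model with
#' first-order oral absorption and a urinary elimination pathway: drug moves
#' from the gut depot into the central compartment at rate `ka`, exchanges
#' with a peripheral compartment (`k12`, `k21`), and leaves the central
#' compartment into urine (`kel_ur`) and by all other routes (`kel`).
#'
#' @param ka First-order absorption rate constant (1/hr), > 0.
#' @param k12,k21 Intercompartmental rate constants central <-> peripheral
#'   (1/hr), >= 0. Setting both to zero collapses the model to one
#'   compartment.
#' @param kel Elimination rate constant for non-urinary routes (1/hr), >= 0.
#' @param kel_ur Elimination rate constant into urine (1/hr), >= 0. The sum
#'   `kel + kel_ur` must be positive.
#' @param vc Central volume of distribution per body mass (L/kg), > 0.
#' @param f Bioavailable fraction of an oral dose, in (0, 1].
#'
#' @return An object of class `structural_params` (a named list).
#' @examples
#' structural_params(ka = 1.28, k12 = 0.803, k21 = 0.965,
#'                   kel = 0.839, kel_ur = 0.190, vc = 0.448, f = 0.867)
#' @export
structural_params <- function(ka, k12, k21, kel, kel_ur, vc, f) {
  vals <- c(ka = ka, k12 = k12, k21 = k21, kel = kel, kel_ur = kel_ur,
            vc = vc, f = f)
  if (!all(is.finite(vals))) {
    stop("all structural parameters must be finite numbers", call. = FALSE)
  }
  if (ka <= 0) stop("`ka` must be > 0", call. = FALSE)
  if (k12 < 0 || k21 < 0) stop("`k12` and `k21` must be >= 0", call. = FALSE)
  if (kel < 0 || kel_ur < 0) {
    stop("`kel` and `kel_ur` must be >= 0", call. = FALSE)
  }
  if (kel + kel_ur <= 0) {
    stop("total elimination `kel + kel_ur` must be > 0", call. = FALSE)
  }
  if (vc <= 0) stop("`vc` must be > 0", call. = FALSE)
  if (f <= 0 || f > 1) stop("`f` must be in (0, 1]", call. = FALSE)
  structure(as.list(vals), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("<structural_params>\n")
  cat(sprintf("  ka = %.4g /hr, k12 = %.4g, k21 = %.4g, kel = %.4g, kel_ur = %.4g /hr\n",
              x$ka, x$k12, x$k21, x$kel, x$kel_ur))
  cat(sprintf("  vc = %.4g L/kg, f = %.4g\n", x$vc, x$f))
  invisible(x)
}

#' Single dose event
#'
#' @param amount Dose per body mass (mg/kg), > 0.
#' @param time Administration time (hr), >= 0.
#' @param route `"oral"` (into the gut depot, scaled by the bioavailable
#'   fraction) or `"intravenous"` (bolus into the central compartment).
#'
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(amount = 1, time = 0, route = c("oral", "intravenous")) {
  route <- match.arg(route)
  if (!is.finite(amount) || amount <= 0) {
    stop("dose `amount` must be > 0", call. = FALSE)
  }
  if (!is.finite(time) || time < 0) stop("dose `time` must be >= 0", call. = FALSE)
  structure(list(amount = amount, time = time, route = route),
            class = "dose_event")
}

# Hybrid disposition exponents alpha >= beta: roots of
# lambda^2 - (k12 + k21 + k10) lambda + k21 * k10, with k10 = kel + kel_ur.
.disposition_exponents <- function(k12, k21, k10) {
  s <- k12 + k21 + k10
  p <- k21 * k10
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

# (1 - exp(-lambda * t)) / lambda, with the lambda -> 0 limit t.
.exp_int <- function(lambda, t) {
  if (abs(lambda) < 1e-12) return(t)
  -expm1(-lambda * t) / lambda
}

# TRUE when exponents are too close for the partial-fraction closed form.
.is_degenerate <- function(lams) {
  lams <- lams[lams > 1e-12]
  if (length(lams) < 2) return(FALSE)
  d <- abs(diff(sort(lams)))
  any(d < 1e-7 * max(lams))
}

# System matrix over states (gut, central, peripheral, urine, other).
.pk_matrix <- function(p) {
  A <- matrix(0, 5, 5)
  A[1, 1] <- -p$ka
  A[2, 1] <- p$ka
  A[2, 2] <- -(p$k12 + p$kel + p$kel_ur)
  A[2, 3] <- p$k21
  A[3, 2] <- p$k12
  A[3, 3] <- -p$k21
  A[4, 2] <- p$kel_ur
  A[5, 2] <- p$kel
  A
}

# Matrix-exponential evaluation; exact for any eigenstructure, used when the
# partial-fraction form degenerates (coincident exponents).
.solve_expm <- function(p, x0, tau) {
  A <- .pk_matrix(p)
  out <- vapply(tau, function(t) {
    if (t == 0) return(x0)
    as.numeric(Matrix::expm(A * t) %*% x0)
  }, numeric(5))
  t(out)
}

.solve_analytic_oral <- function(p, amount, tau) {
  ka <- p$ka
  k10 <- p$kel + p$kel_ur
  ab <- .disposition_exponents(p$k12, p$k21, k10)
  al <- ab$alpha
  be <- ab$beta
  fd <- p$f * amount

  if (.is_degenerate(c(ka, al, be))) {
    return(.solve_expm(p, c(fd, 0, 0, 0, 0), tau))
  }

  cka <- (p$k21 - ka) / ((al - ka) * (be - ka))
  cal <- (p$k21 - al) / ((ka - al) * (be - al))
  cbe <- (p$k21 - be) / ((ka - be) * (al - be))

  e_ka <- exp(-ka * tau)
  e_al <- exp(-al * tau)
  e_be <- exp(-be * tau)

  x1 <- ka * fd * (cka * e_ka + cal * e_al + cbe * e_be)
  x2 <- ka * p$k12 * fd *
    (e_ka / ((al - ka) * (be - ka)) +
     e_al / ((ka - al) * (be - al)) +
     e_be / ((ka - be) * (al - be)))
  ika <- vapply(tau, .exp_int, numeric(1), lambda = ka)
  ial <- vapply(tau, .exp_int, numeric(1), lambda = al)
  ibe <- vapply(tau, .exp_int, numeric(1), lambda = be)
  cum <- ka * fd * (cka * ika + cal * ial + cbe * ibe)
  cbind(gut = fd * e_ka, central = x1, peripheral = x2,
        urine = p$kel_ur * cum, other = p$kel * cum)
}

.solve_analytic_iv <- function(p, amount, tau) {
  k10 <- p$kel + p$kel_ur
  ab <- .disposition_exponents(p$k12, p$k21, k10)
  al <- ab$alpha
  be <- ab$beta

  if (.is_degenerate(c(al, be))) {
    return(.solve_expm(p, c(0, amount, 0, 0, 0), tau))
  }

  ca <- (p$k21 - al) / (be - al)
  cb <- (p$k21 - be) / (al - be)
  e_al <- exp(-al * tau)
  e_be <- exp(-be * tau)

  x1 <- amount * (ca * e_al + cb * e_be)
  x2 <- p$k12 * amount * (e_al / (be - al) + e_be / (al - be))
  ial <- vapply(tau, .exp_int, numeric(1), lambda = al)
  ibe <- vapply(tau, .exp_int, numeric(1), lambda = be)
  cum <- amount * (ca * ial + cb * ibe)
  cbind(gut = 0, central = x1, peripheral = x2,
        urine = p$kel_ur * cum, other = p$kel * cum)
}

.check_times <- function(times) {
  if (length(times) < 1 || !all(is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  invisible(times)
}

.trajectory_tibble <- function(times, states, vc) {
  tibble::tibble(
    time = as.numeric(times),
    x_gut = as.numeric(states[, 1]),
    x_central = as.numeric(states[, 2]),
    x_peripheral = as.numeric(states[, 3]),
    x_urine = as.numeric(states[, 4]),
    x_other = as.numeric(states[, 5]),
    conc = as.numeric(states[, 2]) / vc * MGKG_PER_LKG_TO_NGML
  )
}

#' Closed-form solution of the structural model
#'
#' Solves the linear compartment system exactly. The oral solution is the
#' standard tri-exponential with exponents `ka` and the hybrid disposition
#' constants alpha and beta; the intravenous solution is bi-exponential.
#' Urinary and non-urinary cumulative amounts are the corresponding
#' analytically integrated fluxes out of the central compartment. When two
#' exponents (numerically) coincide the evaluation falls back to a matrix
#' exponential of the full five-state system, so repeated eigenvalues are
#' handled without special-cased formulas.
#'
#' Initial conditions: an oral dose places `f * amount` in the gut depot; an
#' intravenous dose places `amount` in the central compartment
#' (bioavailability does not apply). All other states start at zero.
#'
#' @param params A [structural_params()] object.
#' @param dose A [dose_event()].
#' @param times Sorted, nonnegative time grid (hr).
#'
#' @return A tibble with columns `time`, the five state amounts (mg/kg):
#'   `x_gut`, `x_central`, `x_peripheral`, `x_urine` (cumulative urinary
#'   excretion), `x_other` (cumulative non-urinary elimination), and `conc`,
#'   the plasma concentration in ng/mL (`x_central / vc`, converted).
#' @seealso [pk_profile_ode()] for the numerical integrator,
#'   [macro_constants()] for derived kinetic quantities.
#' @examples
#' p <- structural_params(1.28, 0.803, 0.965, 0.839, 0.190, 0.448, 0.867)
#' pk_profile(p, dose_event(1), times = c(0, 0.5, 1, 2, 4, 8, 12, 24))
#' @export
pk_profile <- function(params, dose = dose_event(), times) {
  stopifnot(inherits(params, "structural_params"), inherits(dose, "dose_event"))
  .check_times(times)
  tau <- pmax(times - dose$time, 0)
  states <- if (dose$route == "oral") {
    .solve_analytic_oral(params, dose$amount, tau)
  } else {
    .solve_analytic_iv(params, dose$amount, tau)
  }
  # numerical guard: clip parts-per-trillion negative round-off
  states[states < 0 & states > -1e-12 * dose$amount] <- 0
  .trajectory_tibble(times, states, params$vc)
}

#' Numerical (ODE) solution of the structural model
#'
#' Integrates the same five-state system with a stiff-capable solver
#' ([deSolve::lsoda()]). Exists as an independent check on [pk_profile()]
#' and as the extension point for nonlinear kinetics.
#'
#' @inheritParams pk_profile
#' @param rtol,atol Relative and absolute integration tolerances.
#'
#' @return Same tibble layout as [pk_profile()].
#' @export
pk_profile_ode <- function(params, dose = dose_event(), times,
                           rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "structural_params"), inherits(dose, "dose_event"))
  .check_times(times)
  A <- .pk_matrix(params)
  x0 <- if (dose$route == "oral") {
    c(params$f * dose$amount, 0, 0, 0, 0)
  } else {
    c(0, dose$amount, 0, 0, 0)
  }
  tau <- pmax(times - dose$time, 0)
  grid <- sort(unique(c(0, tau)))
  sol <- deSolve::lsoda(
    y = x0, times = grid,
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    rtol = rtol, atol = atol
  )
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  states <- sol[match(tau, grid), -1, drop = FALSE]
  .trajectory_tibble(times, states, params$vc)
}

#' Derived macro-kinetic quantities
#'
#' Computes, from the micro constants: the absorption half-life `ln(2)/ka`;
#' the hybrid disposition exponents alpha and beta (eigenvalues of the 2x2
#' disposition matrix with total central elimination `k10 = kel + kel_ur`);
#' the terminal half-life `ln(2)` over the smallest exponent governing the
#' terminal phase (the minimum of alpha, beta and `ka` — when `ka` is the
#' smallest the profile shows flip-flop kinetics, flagged in the output);
#' the model total clearance `vc * k10`; and the fraction of absorbed drug
#' ultimately recovered in urine, `kel_ur / (kel + kel_ur)`.
#'
#' @param params A [structural_params()] object.
#'
#' @return A one-row tibble with columns `t_half_abs` (hr), `alpha`, `beta`
#'   (1/hr), `t_half_terminal` (hr), `cl` (L/hr/kg), `cl_ml_min`
#'   (mL/min/kg), `fe_urine` (fraction of absorbed drug excreted in urine)
#'   and `flip_flop` (logical).
#' @examples
#' p <- structural_params(0.523, 0.803, 0.965, 0.839, 0.190, 0.448, 0.788)
#' macro_constants(p)$t_half_abs  # 1.33 hr: slow absorption arm
#' @export
macro_constants <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  k10 <- params$kel + params$kel_ur
  ab <- .disposition_exponents(params$k12, params$k21, k10)
  lam_min <- min(ab$alpha, ab$beta, params$ka)
  tibble::tibble(
    t_half_abs = log(2) / params$ka,
    alpha = ab$alpha,
    beta = ab$beta,
    t_half_terminal = log(2) / lam_min,
    cl = params$vc * k10,
    cl_ml_min = params$vc * k10 * 1000 / 60,
    fe_urine = params$kel_ur / k10,
    flip_flop = params$ka < ab$beta
  )
}
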