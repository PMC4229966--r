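# Internal parameter layout for the population estimator.
#
# Random-effect slots, in fixed column order:
#   1 k12, 2 k21, 3 kel, 4 kel_ur, 5 vc (shared across arms),
#   6 ka (subject's own arm), 7 f (subject's own arm).
# Population means are carried on the log scale for rates/volume and the
# logit scale for bioavailability, so every draw stays in the parameter
# domain. Between-subject variability is a diagonal covariance over the
# seven slots, arm-resolved for ka and f.
.SHARED_SLOTS <- c("k12", "k21", "kel", "kel_ur", "vc")

#' Configuration for the population fit
#'
#' @param n_samples Importance samples per subject per EM iteration
#'   (>= 100).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the maximum relative change of the
#'   natural-scale population parameters between iterations (must hold on
#'   two consecutive iterations).
#' @param seed Integer seed; all Monte Carlo draws of the fit derive from
#'   it, so refits are reproducible and independent of subject row order.
#' @param include_urine Include the cumulative urine observation in each
#'   subject's likelihood (with its own proportional error). `FALSE` fits
#'   plasma concentrations only.
#' @param estimate_bsv Character vector of slots whose between-subject
#'   variance is estimated (`"k12"`, `"k21"`, `"kel"`, `"kel_ur"`, `"vc"`,
#'   `"ka"`, `"f"`). Slots not listed keep a small fixed computational
#'   prior (`frozen_omega`) and are reported with BSV `NA`.
#' @param frozen_omega Standard deviation of the computational prior for
#'   slots without estimated BSV. Kept small so the marginal likelihood
#'   is indistinguishable from the plain likelihood in those directions
#'   (their means are driven by the direct-likelihood polish step).
#' @param omega2_floor Lower floor for estimated variances (guards against
#'   degenerate collapse; hitting it is reported in the fit messages).
#' @param proposal_inflation Multiplier on the proposal standard
#'   deviation; > 1 keeps importance-weight tails safe.
#' @param polish_every Every this many EM iterations (and on the final
#'   one) the population means are refreshed by direct maximization of
#'   the importance-sampled marginal likelihood over the current fixed
#'   samples; this restores fast convergence for parameters whose
#'   between-subject variance is small.
#' @param iv_auc_ref Dose-normalized intravenous reference AUC
#'   (ng·hr/mL per mg/kg) anchoring the model total clearance, or `NULL`
#'   to fit without the anchor. With oral data alone, bioavailability
#'   and the central volume are only defined relative to intravenous
#'   information (the model has an exact scaling ridge); the default is
#'   the shipped back-derived reference ([baclofen_iv_auc_reference()]).
#' @param iv_auc_cv Relative uncertainty (lognormal SD) given to the
#'   anchor.
#' @param compute_rse Compute relative standard errors by the
#'   importance-sampling Fisher (outer-product) approximation.
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_samples = 300L, max_iter = 100L, tol = 1e-3,
                       seed = 1L, include_urine = TRUE,
                       estimate_bsv = c("k12", "k21", "kel", "kel_ur",
                                        "vc", "ka", "f"),
                       frozen_omega = 0.01, omega2_floor = 1e-4,
                       proposal_inflation = 1.25, polish_every = 8L,
                       iv_auc_ref = baclofen_iv_auc_reference(),
                       iv_auc_cv = 0.05, compute_rse = TRUE) {
  if (n_samples < 100) stop("`n_samples` must be >= 100", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  bad <- setdiff(estimate_bsv, c(.SHARED_SLOTS, "ka", "f"))
  if (length(bad) > 0) {
    stop("unknown BSV slot(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), max_iter = as.integer(max_iter),
    tol = tol, seed = as.integer(seed), include_urine = include_urine,
    estimate_bsv = estimate_bsv, frozen_omega = frozen_omega,
    omega2_floor = omega2_floor, proposal_inflation = proposal_inflation,
    polish_every = max(1L, as.integer(polish_every)),
    iv_auc_ref = iv_auc_ref, iv_auc_cv = iv_auc_cv,
    compute_rse = compute_rse
  ), class = "fit_config")
}

# Plasma log-likelihood rows for an M x J prediction matrix under the
# combined additive + proportional Gaussian residual model.
.plasma_ll_rows <- function(pred, y_mat, add_sd, prop_cv) {
  v <- add_sd^2 + (prop_cv * pred)^2
  rowSums(-0.5 * log(2 * pi * v) - (y_mat - pred)^2 / (2 * v))
}

.urine_ll_rows <- function(pred_frac, u_obs, urine_cv) {
  sdv <- pmax(urine_cv * pred_frac, 1e-8)
  -0.5 * log(2 * pi * sdv^2) - (u_obs - pred_frac)^2 / (2 * sdv^2)
}

#' Individual-level log-likelihood
#'
#' Gaussian log-likelihood of one subject's observations given structural
#' parameters: plasma points have variance
#' `add_sd^2 + (prop_cv * pred)^2`; the cumulative urine fraction (when
#' present and `include_urine = TRUE`) has a proportional error with CV
#' `urine_cv`. Predictions come from the closed-form solver.
#'
#' @param params A [structural_params()] object.
#' @param subject A long-format dataset slice containing exactly one
#'   subject (see [validate_pk_dataset()]).
#' @param residual List with elements `add_sd`, `prop_cv` and optionally
#'   `urine_cv`. A residual model with both plasma components zero is
#'   rejected.
#' @param include_urine Include the urine record, if any.
#'
#' @return The scalar log-likelihood.
#' @export
individual_loglik <- function(params, subject,
                              residual = list(add_sd = 1, prop_cv = 0.15,
                                              urine_cv = 0.10),
                              include_urine = TRUE) {
  stopifnot(inherits(params, "structural_params"))
  if ((residual$add_sd %||% 0) <= 0 && (residual$prop_cv %||% 0) <= 0) {
    stop("residual model has zero total variance; set `add_sd` and/or ",
         "`prop_cv` > 0", call. = FALSE)
  }
  subs <- .split_subjects(subject)
  if (length(subs) != 1) {
    stop("`subject` must contain exactly one subject", call. = FALSE)
  }
  s <- subs[[1]]
  if (length(s$conc) < 1) stop("subject has no plasma observations",
                               call. = FALSE)
  dose <- dose_event(s$dose_amount, s$dose_time, "oral")
  pred <- pk_profile(params, dose, s$times)$conc
  ll <- sum(.plasma_ll_rows(matrix(pred, nrow = 1),
                            matrix(s$conc, nrow = 1),
                            residual$add_sd, residual$prop_cv))
  if (include_urine && !is.na(s$urine_frac)) {
    uf <- pk_profile(params, dose, s$urine_time)$x_urine[[1]] / s$dose_amount
    ll <- ll + .urine_ll_rows(uf, s$urine_frac,
                              residual$urine_cv %||% 0.10)
  }
  ll
}

# Assemble per-subject working records for the estimator.
.fit_subjects <- function(data, include_urine) {
  subs <- .split_subjects(data)
  lapply(subs, function(s) {
    if (length(s$conc) < 2) {
      stop("subject ", s$id, " has fewer than 2 plasma observations",
           call. = FALSE)
    }
    list(id = s$id, group = s$group, dose = s$dose_amount,
         times = s$times - s$dose_time, y = s$conc,
         urine = if (include_urine && !is.na(s$urine_frac)) s$urine_frac else NA_real_,
         urine_time = if (include_urine && !is.na(s$urine_frac)) s$urine_time - s$dose_time else NA_real_)
  })
}

# Named vector of the seven slot variances for one subject's arm.
.omega_for_arm <- function(omega2, arm) {
  c(omega2[.SHARED_SLOTS], omega2[[paste0("ka_", arm)]],
    omega2[[paste0("f_", arm)]])
}

# Intravenous-reference anchor on total clearance.
#
# With oral data alone the model carries an exact flat ridge:
# (f, vc, kel_ur, kel) -> (c f, c vc, kel_ur / c, k10 - kel_ur / c)
# leaves every plasma and urine prediction unchanged, so bioavailability
# and the central volume are only defined relative to intravenous
# information — which is also how bioavailability is defined in the first
# place. The anchor is a Gaussian likelihood term tying the model total
# clearance vc * (kel + kel_ur) (L/hr/kg) to the clearance implied by a
# dose-normalized IV reference AUC (ng*hr/mL per mg/kg):
# CL_ref = 1000 / AUC_iv_norm.
.iv_anchor_ll <- function(theta_log, iv_ref, iv_cv) {
  if (is.null(iv_ref)) return(0)
  cl_model <- exp(theta_log[["vc"]]) *
    (exp(theta_log[["kel"]]) + exp(theta_log[["kel_ur"]]))
  stats::dnorm(log(cl_model), log(1000 / iv_ref), iv_cv, log = TRUE)
}

#' Fit the population model by importance-sampling EM
#'
#' Implements a Monte Carlo parametric expectation-maximization (MC-PEM)
#' estimator for the nonlinear mixed-effects model: individual parameters
#' are the population medians perturbed by log-normal (logit-normal for
#' bioavailability) random effects; the absorption rate and
#' bioavailability are arm-specific while the disposition parameters are
#' shared.
#'
#' E-step: for each subject, random-effect vectors are drawn from an
#' adaptive multivariate-normal proposal (mean and covariance carried over
#' from the previous iteration's importance-weighted conditional moments)
#' and weighted by prior x likelihood over proposal. M-step: population
#' means are moved by the average conditional random-effect mean,
#' variances are refreshed from the weighted second moments (with a small
#' floor), and the residual-error parameters are updated by direct
#' maximization of the importance-weighted expected log-likelihood.
#' Relative standard errors use the outer-product (BHHH) Fisher
#' approximation over the final importance samples.
#'
#' @param data Long-format dataset (see [validate_pk_dataset()]); at
#'   least 3 subjects.
#' @param config A [fit_config()].
#' @param pop_init Optional [population_model()] providing initial means
#'   and BSV; by default neutral starting values are derived from the
#'   data (a rough volume from Cmax, 1/hr rates, 80 % bioavailability).
#'
#' @return An object of class `mcpem_fit`; see [tidy.mcpem_fit()],
#'   [glance.mcpem_fit()], [as_population_model()], [vpc()], [npde()],
#'   [profile_objective()].
#' @examples
#' \donttest{
#' dat <- simulate_study(population_model(), study_design(), seed = 7)
#' fit <- fit_mcpem(dat, fit_config(n_samples = 150, max_iter = 30,
#'                                  compute_rse = FALSE))
#' tidy(fit)
#' }
#' @export
fit_mcpem <- function(data, config = fit_config(), pop_init = NULL) {
  stopifnot(inherits(config, "fit_config"))
  subs <- .fit_subjects(data, config$include_urine)
  n <- length(subs)
  if (n < 3) stop("need at least 3 subjects to fit", call. = FALSE)
  arms <- sort(unique(vapply(subs, `[[`, "", "group")))
  arm_of <- vapply(subs, `[[`, "", "group")

  # --- initial values -------------------------------------------------
  if (!is.null(pop_init)) {
    stopifnot(inherits(pop_init, "population_model"))
    missing_arms <- setdiff(arms, pop_init$arms)
    if (length(missing_arms) > 0) {
      stop("dataset group(s) not declared in `pop_init`: ",
           paste(missing_arms, collapse = ", "), call. = FALSE)
    }
    theta_log <- log(c(k12 = pop_init$k12, k21 = pop_init$k21,
                       kel = pop_init$kel, kel_ur = pop_init$kel_ur,
                       vc = pop_init$vc))
    lka <- log(pop_init$ka[arms])
    lgf <- stats::qlogis(pmin(pop_init$f[arms], 0.99))
    resid <- c(add_sd = pop_init$add_sd, prop_cv = pop_init$prop_cv,
               urine_cv = pop_init$urine_cv)
  } else {
    cmax <- vapply(subs, function(s) max(s$y), numeric(1))
    dose <- vapply(subs, `[[`, numeric(1), "dose")
    vc0 <- stats::median(dose * MGKG_PER_LKG_TO_NGML / pmax(cmax, 1e-6))
    vc0 <- min(max(vc0, 0.05), 5)
    theta_log <- log(c(k12 = 0.5, k21 = 0.5, kel = 0.4, kel_ur = 0.4,
                       vc = vc0))
    lka <- stats::setNames(rep(log(1), length(arms)), arms)
    lgf <- stats::setNames(rep(stats::qlogis(0.8), length(arms)), arms)
    resid <- c(add_sd = 1, prop_cv = 0.2, urine_cv = 0.15)
  }
  names(lka) <- arms
  names(lgf) <- arms

  om_names <- c(.SHARED_SLOTS, paste0("ka_", arms), paste0("f_", arms))
  slot_of <- c(.SHARED_SLOTS, rep("ka", length(arms)), rep("f", length(arms)))
  omega2 <- stats::setNames(
    ifelse(slot_of %in% config$estimate_bsv,
           log(1 + 0.3^2), config$frozen_omega^2),
    om_names
  )
  estimated_om <- stats::setNames(slot_of %in% config$estimate_bsv, om_names)

  M <- config$n_samples
  y_mats <- lapply(subs, function(s) {
    matrix(s$y, nrow = M, ncol = length(s$y), byrow = TRUE)
  })

  # proposal state: per-subject mean and covariance of the random effects
  prop_m <- replicate(n, numeric(7), simplify = FALSE)
  prop_S <- lapply(seq_len(n), function(i) {
    diag(.omega_for_arm(omega2, arm_of[i]))
  })

  natural_vec <- function() {
    c(exp(theta_log), stats::setNames(exp(lka), paste0("ka_", arms)),
      stats::setNames(100 * stats::plogis(lgf), paste0("f_", arms)), resid)
  }

  trace <- numeric(0)
  converged <- FALSE
  hits_floor <- character(0)
  consec_ok <- 0L
  last_polish_nat <- NULL
  polish_stable <- FALSE
  b_all <- matrix(0, n, 7)
  Ee2_all <- matrix(0, n, 7)
  S_post <- replicate(n, diag(7), simplify = FALSE)
  marg <- numeric(n)
  e_store <- vector("list", n)   # final-iteration samples, for RSE/profiles
  iter_done <- 0L

  for (it in seq_len(config$max_iter)) {
    set.seed(config$seed * 1000L + it)
    prev <- natural_vec()
    pred_store <- vector("list", n)

    for (i in seq_len(n)) {
      s <- subs[[i]]
      om2_i <- .omega_for_arm(omega2, s$group)
      R <- tryCatch(
        chol(prop_S[[i]] * config$proposal_inflation^2),
        error = function(e) chol(diag(om2_i) * config$proposal_inflation^2)
      )
      Z <- matrix(stats::rnorm(M * 7), M, 7)
      eta <- sweep(Z %*% R, 2, prop_m[[i]], `+`)
      lq <- -sum(log(diag(R))) - 0.5 * rowSums(Z^2) - 3.5 * log(2 * pi)

      P <- .params_from_eta(theta_log, lka[[s$group]], lgf[[s$group]], eta)
      pr <- .pred_oral_matrix(P, s$times, s$dose,
                              urine_time = if (is.na(s$urine)) NULL else s$urine_time)
      ll <- .plasma_ll_rows(pr$conc, y_mats[[i]], resid[["add_sd"]],
                            resid[["prop_cv"]])
      if (!is.na(s$urine)) {
        ll <- ll + .urine_ll_rows(pr$urine_frac, s$urine, resid[["urine_cv"]])
      }
      lp <- -3.5 * log(2 * pi) - 0.5 * sum(log(om2_i)) -
        0.5 * rowSums(sweep(eta^2, 2, om2_i, `/`))
      lw <- lp + ll - lq
      lw[!is.finite(lw)] <- -Inf
      if (all(lw == -Inf)) {
        # no sample carries weight (far-off proposal); keep the prior
        b_all[i, ] <- 0
        Ee2_all[i, ] <- om2_i
        S_post[[i]] <- diag(om2_i)
        marg[i] <- -1e10
        pred_store[[i]] <- list(conc = pr$conc, urine = pr$urine_frac,
                                wn = rep(1 / M, M))
        e_store[[i]] <- list(eta = eta, lq = lq)
        prop_m[[i]] <- numeric(7)
        next
      }
      a <- max(lw)
      w <- exp(lw - a)
      sw <- sum(w)
      wn <- w / sw
      marg[i] <- a + log(sw) - log(M)

      b <- colSums(eta * wn)
      Ee2 <- colSums(eta^2 * wn)
      Spost <- crossprod(eta, eta * wn) - tcrossprod(b)
      ess <- 1 / sum(wn^2)
      if (!all(is.finite(Spost)) || ess < 5) {
        Spost <- diag(om2_i)
      }
      b_all[i, ] <- b
      Ee2_all[i, ] <- Ee2
      S_post[[i]] <- Spost + diag(1e-8, 7)
      pred_store[[i]] <- list(conc = pr$conc, urine = pr$urine_frac, wn = wn)
      e_store[[i]] <- list(eta = eta, lq = lq)
    }

    # ---- M-step: population means (EM moment update) -----------------
    d_vec <- matrix(0, n, 7)
    for (s_idx in seq_along(.SHARED_SLOTS)) {
      d <- mean(b_all[, s_idx])
      theta_log[[.SHARED_SLOTS[s_idx]]] <- theta_log[[.SHARED_SLOTS[s_idx]]] + d
      d_vec[, s_idx] <- d
    }
    for (a in arms) {
      in_arm <- arm_of == a
      d_ka <- mean(b_all[in_arm, 6])
      d_f <- mean(b_all[in_arm, 7])
      lka[[a]] <- lka[[a]] + d_ka
      lgf[[a]] <- lgf[[a]] + d_f
      d_vec[in_arm, 6] <- d_ka
      d_vec[in_arm, 7] <- d_f
    }

    # ---- M-step: between-subject variances ---------------------------
    for (s_idx in seq_along(.SHARED_SLOTS)) {
      nm <- .SHARED_SLOTS[s_idx]
      if (!estimated_om[[nm]]) next
      d <- d_vec[1, s_idx]
      v <- mean(Ee2_all[, s_idx] - 2 * d * b_all[, s_idx] + d^2)
      if (!is.finite(v)) v <- omega2[[nm]]
      if (v < config$omega2_floor) {
        v <- config$omega2_floor
        hits_floor <- union(hits_floor, nm)
      }
      omega2[[nm]] <- v
    }
    for (a in arms) {
      in_arm <- arm_of == a
      for (col in c(6L, 7L)) {
        nm <- paste0(if (col == 6L) "ka_" else "f_", a)
        if (!estimated_om[[nm]]) next
        d <- d_vec[which(in_arm)[1], col]
        v <- mean(Ee2_all[in_arm, col] - 2 * d * b_all[in_arm, col] + d^2)
        if (!is.finite(v)) v <- omega2[[nm]]
        if (v < config$omega2_floor) {
          v <- config$omega2_floor
          hits_floor <- union(hits_floor, nm)
        }
        omega2[[nm]] <- v
      }
    }

    # ---- M-step: residual error --------------------------------------
    has_urine <- any(!is.na(vapply(subs, `[[`, numeric(1), "urine")))
    negQ <- function(par) {
      add <- exp(par[1]); prop <- exp(par[2])
      ucv <- if (has_urine) exp(par[3]) else resid[["urine_cv"]]
      q <- 0
      for (i in seq_len(n)) {
        ps <- pred_store[[i]]
        llm <- .plasma_ll_rows(ps$conc, y_mats[[i]], add, prop)
        if (!is.na(subs[[i]]$urine)) {
          llm <- llm + .urine_ll_rows(ps$urine, subs[[i]]$urine, ucv)
        }
        q <- q + sum(ps$wn * llm)
      }
      -q
    }
    par0 <- log(c(resid[["add_sd"]], resid[["prop_cv"]],
                  if (has_urine) resid[["urine_cv"]] else NULL))
    opt <- stats::nlminb(par0, function(p) {
      negQ(if (has_urine) p else c(p, 0))
    }, lower = log(c(1e-3, 1e-4, if (has_urine) 1e-4 else NULL)),
       upper = log(c(1e3, 2, if (has_urine) 2 else NULL)))
    resid[["add_sd"]] <- exp(opt$par[1])
    resid[["prop_cv"]] <- exp(opt$par[2])
    if (has_urine) resid[["urine_cv"]] <- exp(opt$par[3])

    # ---- periodic Monte-Carlo ML polish of the means -----------------
    # The EM moment update contracts slowly for slots with small
    # between-subject variance (their conditional means are shrunk
    # almost entirely to the current value). Every few iterations the
    # population means are therefore refreshed by direct maximization of
    # the importance-sampled marginal likelihood over the fixed current
    # samples (common random numbers), which targets the objective
    # exactly and breaks the slow crawl along correlated ridges.
    if ((it %% config$polish_every == 0L && it >= 5L) ||
        it == config$max_iter) {
      pack <- function() unname(c(theta_log, lka, lgf))
      unpack <- function(par) {
        th <- theta_log; ka <- lka; gf <- lgf
        th[.SHARED_SLOTS] <- par[seq_along(.SHARED_SLOTS)]
        idx <- length(.SHARED_SLOTS)
        for (a2 in arms) { idx <- idx + 1L; ka[[a2]] <- par[idx] }
        for (a2 in arms) { idx <- idx + 1L; gf[[a2]] <- par[idx] }
        list(th = th, ka = ka, gf = gf)
      }
      # all subjects share the design grid in the intended use, so the
      # samples stack into one big matrix and each objective evaluation
      # is a single vectorised pass; otherwise fall back to a loop
      same_grid <- all(vapply(subs, function(s) {
        identical(s$times, subs[[1]]$times) &&
          is.na(s$urine) == is.na(subs[[1]]$urine)
      }, logical(1)))
      if (same_grid) {
        eta_all <- do.call(rbind, lapply(e_store, `[[`, "eta"))
        lpq_all <- unlist(lapply(seq_len(n), function(i) {
          om2_i <- .omega_for_arm(omega2, arm_of[i])
          -3.5 * log(2 * pi) - 0.5 * sum(log(om2_i)) -
            0.5 * rowSums(sweep(e_store[[i]]$eta^2, 2, om2_i, `/`)) -
            e_store[[i]]$lq
        }))
        y_all <- do.call(rbind, y_mats)
        dose1 <- subs[[1]]$dose
        times1 <- subs[[1]]$times
        has_ur <- !is.na(subs[[1]]$urine)
        ur_time1 <- subs[[1]]$urine_time
        ur_all <- rep(vapply(subs, `[[`, numeric(1), "urine"), each = M)
        arm_row <- rep(arm_of, each = M)
        neg_marg <- function(par) {
          pp <- unpack(par)
          P <- .params_from_eta(pp$th, pp$ka[arm_row], pp$gf[arm_row],
                                eta_all)
          pr <- .pred_oral_matrix(P, times1, dose1,
            urine_time = if (has_ur) ur_time1 else NULL)
          ll <- .plasma_ll_rows(pr$conc, y_all, resid[["add_sd"]],
                                resid[["prop_cv"]])
          if (has_ur) {
            ll <- ll + .urine_ll_rows(pr$urine_frac, ur_all,
                                      resid[["urine_cv"]])
          }
          lw <- lpq_all + ll
          lw[!is.finite(lw)] <- -1e10
          LW <- matrix(lw, M, n)
          aa <- apply(LW, 2, max)
          tot <- sum(aa + log(colSums(exp(LW - rep(aa, each = M)))) -
                       log(M)) +
            .iv_anchor_ll(pp$th, config$iv_auc_ref, config$iv_auc_cv)
          -tot
        }
      } else {
        neg_marg <- function(par) {
          pp <- unpack(par)
          tot <- 0
          for (i in seq_len(n)) {
            s <- subs[[i]]
            smp <- e_store[[i]]
            P <- .params_from_eta(pp$th, pp$ka[[s$group]], pp$gf[[s$group]],
                                  smp$eta)
            pr <- .pred_oral_matrix(P, s$times, s$dose,
              urine_time = if (is.na(s$urine)) NULL else s$urine_time)
            ll <- .plasma_ll_rows(pr$conc, y_mats[[i]], resid[["add_sd"]],
                                  resid[["prop_cv"]])
            if (!is.na(s$urine)) {
              ll <- ll + .urine_ll_rows(pr$urine_frac, s$urine,
                                        resid[["urine_cv"]])
            }
            om2_i <- .omega_for_arm(omega2, s$group)
            lp <- -3.5 * log(2 * pi) - 0.5 * sum(log(om2_i)) -
              0.5 * rowSums(sweep(smp$eta^2, 2, om2_i, `/`))
            lw <- lp + ll - smp$lq
            lw[!is.finite(lw)] <- -1e10
            aa <- max(lw)
            tot <- tot + aa + log(sum(exp(lw - aa))) - log(M)
          }
          tot <- tot + .iv_anchor_ll(pp$th, config$iv_auc_ref,
                                     config$iv_auc_cv)
          -tot
        }
      }
      po <- stats::nlminb(pack(), neg_marg,
                          control = list(iter.max = 10, eval.max = 50))
      pp <- unpack(po$par)
      theta_log <- pp$th; lka <- pp$ka; lgf <- pp$gf
      polish_nat <- c(exp(unlist(theta_log)), exp(unlist(lka)),
                      stats::plogis(unlist(lgf)))
      if (!is.null(last_polish_nat)) {
        pol_rel <- max(abs(polish_nat - last_polish_nat) /
                         (abs(last_polish_nat) + 1e-8))
        if (pol_rel < 10 * config$tol) polish_stable <- TRUE
      }
      last_polish_nat <- polish_nat
    }

    # ---- proposal update & convergence -------------------------------
    for (i in seq_len(n)) {
      prop_m[[i]] <- b_all[i, ] - d_vec[i, ]
      prop_S[[i]] <- S_post[[i]]
    }
    trace <- c(trace, -2 * (sum(marg) +
                            .iv_anchor_ll(theta_log, config$iv_auc_ref,
                                          config$iv_auc_cv)))
    iter_done <- it
    relmax <- max(abs(natural_vec() - prev) / (abs(prev) + 1e-8))
    consec_ok <- if (relmax < config$tol) consec_ok + 1L else 0L
    if ((consec_ok >= 2L || polish_stable) && it >= 5L) {
      converged <- TRUE
      break
    }
  }
  if (length(hits_floor) > 0) {
    message("BSV variance floored for: ", paste(hits_floor, collapse = ", "))
  }

  # ---- assemble results ---------------------------------------------
  f_hat <- stats::plogis(lgf)
  bsv_cv <- stats::setNames(numeric(length(om_names)), om_names)
  for (nm in om_names) {
    if (!estimated_om[[nm]]) { bsv_cv[[nm]] <- NA_real_; next }
    om <- sqrt(omega2[[nm]])
    bsv_cv[[nm]] <- if (startsWith(nm, "f_")) {
      # delta method on the logit scale: SD(F) ~ omega * F(1-F)
      100 * om * (1 - f_hat[[sub("^f_", "", nm)]])
    } else {
      100 * .omega_to_cv(om)
    }
  }

  ebe <- purrr::map_dfr(seq_len(n), function(i) {
    p <- .params_from_eta(theta_log, lka[[subs[[i]]$group]],
                          lgf[[subs[[i]]$group]],
                          matrix(prop_m[[i]], 1, 7))
    tibble::as_tibble(p) |>
      dplyr::mutate(id = subs[[i]]$id, group = subs[[i]]$group,
                    .before = 1)
  })

  fit <- structure(list(
    theta_log = theta_log, lka = lka, lgf = lgf, omega2 = omega2,
    resid = resid, arms = arms, bsv_cv_pct = bsv_cv,
    estimated_om = estimated_om,
    ebe = ebe, trace = trace, objective = trace[length(trace)],
    converged = converged, iterations = iter_done,
    n_subjects = n, n_obs = sum(vapply(subs, function(s) length(s$y), 1L)) +
      sum(!is.na(vapply(subs, `[[`, numeric(1), "urine"))),
    config = config,
    design = .design_from_subjects(subs),
    rse = NULL,
    .subjects = subs, .samples = e_store, .y_mats = y_mats
  ), class = "mcpem_fit")

  if (config$compute_rse) {
    fit$rse <- tryCatch(.mcpem_rse(fit), error = function(e) {
      warning("RSE computation failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  fit
}

# Reconstruct the sampling design implied by a dataset (nominal times =
# union of observed times), used by the VPC simulator.
.design_from_subjects <- function(subs) {
  groups <- table(vapply(subs, `[[`, "", "group"))
  times <- sort(unique(unlist(lapply(subs, `[[`, "times"))))
  ut <- vapply(subs, `[[`, numeric(1), "urine_time")
  dose <- subs[[1]]$dose
  study_design(
    groups = tibble::tibble(label = names(groups), n = as.integer(groups)),
    dose = dose_event(dose, 0, "oral"),
    plasma_times = times,
    urine_interval = if (all(is.na(ut))) NA_real_ else max(ut, na.rm = TRUE)
  )
}

# Per-subject marginal log-likelihood at an arbitrary parameter point,
# re-weighting the fixed final importance samples (common random numbers).
.marg_ll_subjects <- function(fit, theta_log, lka, lgf, omega2, resid,
                              structural_changed = TRUE, pred_cache = NULL) {
  subs <- fit$.subjects
  n <- length(subs)
  out <- numeric(n)
  preds <- pred_cache %||% vector("list", n)
  M <- nrow(fit$.samples[[1]]$eta)
  for (i in seq_len(n)) {
    s <- subs[[i]]
    smp <- fit$.samples[[i]]
    if (structural_changed || is.null(preds[[i]])) {
      P <- .params_from_eta(theta_log, lka[[s$group]], lgf[[s$group]], smp$eta)
      preds[[i]] <- .pred_oral_matrix(P, s$times, s$dose,
        urine_time = if (is.na(s$urine)) NULL else s$urine_time)
    }
    pr <- preds[[i]]
    ll <- .plasma_ll_rows(pr$conc, fit$.y_mats[[i]], resid[["add_sd"]],
                          resid[["prop_cv"]])
    if (!is.na(s$urine)) {
      ll <- ll + .urine_ll_rows(pr$urine_frac, s$urine, resid[["urine_cv"]])
    }
    om2_i <- .omega_for_arm(omega2, s$group)
    lp <- -3.5 * log(2 * pi) - 0.5 * sum(log(om2_i)) -
      0.5 * rowSums(sweep(smp$eta^2, 2, om2_i, `/`))
    lw <- lp + ll - smp$lq
    a <- max(lw)
    out[i] <- a + log(sum(exp(lw - a))) - log(M)
  }
  attr(out, "preds") <- preds
  out
}

# Natural-scale parameter vector used for RSE reporting, and the inverse
# mapping back to internal scales.
.rse_param_vector <- function(fit) {
  means <- c(exp(fit$theta_log),
             stats::setNames(exp(fit$lka), paste0("ka_", fit$arms)),
             stats::setNames(100 * stats::plogis(fit$lgf),
                             paste0("f_", fit$arms)))
  omn <- names(fit$omega2)[fit$estimated_om[names(fit$omega2)]]
  om <- stats::setNames(sqrt(fit$omega2[omn]), paste0("omega_", omn))
  rs <- fit$resid
  c(means, om, rs)
}

.rse_apply <- function(fit, phi) {
  theta_log <- log(phi[.SHARED_SLOTS])
  lka <- log(stats::setNames(phi[paste0("ka_", fit$arms)], fit$arms))
  lgf <- stats::qlogis(stats::setNames(
    phi[paste0("f_", fit$arms)] / 100, fit$arms))
  omega2 <- fit$omega2
  for (nm in names(omega2)) {
    key <- paste0("omega_", nm)
    if (key %in% names(phi)) omega2[[nm]] <- phi[[key]]^2
  }
  resid <- fit$resid
  for (nm in names(resid)) if (nm %in% names(phi)) resid[[nm]] <- phi[[nm]]
  list(theta_log = theta_log, lka = lka, lgf = lgf, omega2 = omega2,
       resid = resid)
}

# BHHH / outer-product Fisher approximation over the per-subject scores,
# scores by central differences on the fixed final samples.
.mcpem_rse <- function(fit) {
  phi0 <- .rse_param_vector(fit)
  if (fit$n_subjects < length(phi0)) {
    warning("fewer subjects (", fit$n_subjects, ") than parameters (",
            length(phi0), "); outer-product Fisher approximation is ",
            "rank-deficient, RSEs not computed (consider a bootstrap)",
            call. = FALSE)
    return(NULL)
  }
  p0 <- .rse_apply(fit, phi0)
  base <- .marg_ll_subjects(fit, p0$theta_log, p0$lka, p0$lgf, p0$omega2,
                            p0$resid, structural_changed = TRUE)
  pred_cache <- attr(base, "preds")
  n <- fit$n_subjects
  npar <- length(phi0)
  S <- matrix(0, n, npar, dimnames = list(NULL, names(phi0)))
  anchor_score <- numeric(npar)
  structural <- c(.SHARED_SLOTS, paste0("ka_", fit$arms),
                  paste0("f_", fit$arms))
  for (j in seq_len(npar)) {
    nm <- names(phi0)[j]
    h <- 1e-3 * max(abs(phi0[[j]]), 1e-3)
    sc <- nm %in% structural
    up <- phi0; up[[j]] <- up[[j]] + h
    dn <- phi0; dn[[j]] <- dn[[j]] - h
    pu <- .rse_apply(fit, up)
    pd <- .rse_apply(fit, dn)
    lu <- .marg_ll_subjects(fit, pu$theta_log, pu$lka, pu$lgf, pu$omega2,
                            pu$resid, structural_changed = sc,
                            pred_cache = if (sc) NULL else pred_cache)
    ld <- .marg_ll_subjects(fit, pd$theta_log, pd$lka, pd$lgf, pd$omega2,
                            pd$resid, structural_changed = sc,
                            pred_cache = if (sc) NULL else pred_cache)
    S[, j] <- (as.numeric(lu) - as.numeric(ld)) / (2 * h)
    anchor_score[j] <- (.iv_anchor_ll(pu$theta_log, fit$config$iv_auc_ref,
                                      fit$config$iv_auc_cv) -
                        .iv_anchor_ll(pd$theta_log, fit$config$iv_auc_ref,
                                      fit$config$iv_auc_cv)) / (2 * h)
  }
  info <- crossprod(rbind(S, anchor_score))
  cv <- tryCatch(solve(info + diag(1e-10, npar)), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  se <- sqrt(pmax(diag(cv), 0))
  tibble::tibble(parameter = names(phi0), value = unname(phi0),
                 se = se, rse_pct = 100 * se / pmax(abs(phi0), 1e-12))
}

#' One-dimensional objective profile around an estimate
#'
#' Recomputes the importance-sampled marginal log-likelihood over a grid
#' around a population parameter, holding everything else fixed, using
#' the fit's final importance samples (common random numbers, so the
#' profile is smooth). A near-flat profile (range of -2 log-likelihood
#' below 0.02) triggers an identifiability warning.
#'
#' @param fit An [fit_mcpem()] result.
#' @param parameter One of the natural-scale population parameters, e.g.
#'   `"ka_OY"`, `"vc"`, `"f_control"` (in %), `"prop_cv"`.
#' @param rel_range Half-width of the grid, relative to the estimate.
#' @param n_points Grid size.
#'
#' @return A tibble with columns `value` and `objective`
#'   (-2 log-likelihood), with the estimate's row flagged in `at_estimate`.
#' @export
profile_objective <- function(fit, parameter, rel_range = 0.3,
                              n_points = 11) {
  stopifnot(inherits(fit, "mcpem_fit"))
  phi0 <- .rse_param_vector(fit)
  if (!parameter %in% names(phi0)) {
    stop("unknown parameter `", parameter, "`; choose from: ",
         paste(names(phi0), collapse = ", "), call. = FALSE)
  }
  center <- phi0[[parameter]]
  grid <- seq(center * (1 - rel_range), center * (1 + rel_range),
              length.out = n_points)
  structural <- c(.SHARED_SLOTS, paste0("ka_", fit$arms),
                  paste0("f_", fit$arms))
  sc <- parameter %in% structural
  p0 <- .rse_apply(fit, phi0)
  base <- .marg_ll_subjects(fit, p0$theta_log, p0$lka, p0$lgf, p0$omega2,
                            p0$resid, structural_changed = TRUE)
  cache <- attr(base, "preds")
  obj <- vapply(grid, function(g) {
    phi <- phi0; phi[[parameter]] <- g
    pp <- .rse_apply(fit, phi)
    ll <- .marg_ll_subjects(fit, pp$theta_log, pp$lka, pp$lgf, pp$omega2,
                            pp$resid, structural_changed = sc,
                            pred_cache = if (sc) NULL else cache)
    -2 * (sum(ll) + .iv_anchor_ll(pp$theta_log, fit$config$iv_auc_ref,
                                  fit$config$iv_auc_cv))
  }, numeric(1))
  if (max(obj) - min(obj) < 0.02) {
    warning("objective profile for `", parameter,
            "` is nearly flat: parameter may not be identifiable",
            call. = FALSE)
  }
  tibble::tibble(value = grid, objective = obj,
                 at_estimate = abs(grid - center) ==
                   min(abs(grid - center)))
}

#' Monte Carlo estimate of the marginal log-likelihood of a fit
#'
#' Re-estimates the total marginal log-likelihood at the fitted
#' population parameters by plain Monte Carlo over the random-effect
#' distribution (fresh draws, independent of the fit's own importance
#' samples). Useful to check the stability of the likelihood estimate:
#' at convergence the value should be invariant, within Monte Carlo
#' error, to doubling `n_samples`.
#'
#' @param fit An [fit_mcpem()] result.
#' @param n_samples Monte Carlo samples per subject.
#' @param seed Integer seed.
#'
#' @return The total marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(fit, n_samples = 1000, seed = 1L) {
  stopifnot(inherits(fit, "mcpem_fit"))
  set.seed(seed)
  tot <- 0
  for (s in fit$.subjects) {
    om2 <- .omega_for_arm(fit$omega2, s$group)
    eta <- matrix(stats::rnorm(n_samples * 7), ncol = 7) *
      rep(sqrt(om2), each = n_samples)
    P <- .params_from_eta(fit$theta_log, fit$lka[[s$group]],
                          fit$lgf[[s$group]], eta)
    pr <- .pred_oral_matrix(P, s$times, s$dose,
      urine_time = if (is.na(s$urine)) NULL else s$urine_time)
    ll <- .plasma_ll_rows(pr$conc,
                          matrix(s$y, n_samples, length(s$y), byrow = TRUE),
                          fit$resid[["add_sd"]], fit$resid[["prop_cv"]])
    if (!is.na(s$urine)) {
      ll <- ll + .urine_ll_rows(pr$urine_frac, s$urine,
                                fit$resid[["urine_cv"]])
    }
    a <- max(ll)
    tot <- tot + a + log(mean(exp(ll - a)))
  }
  tot
}

#' Convert a fit to a population model
#'
#' Packs the estimated population means, BSV CVs and residual-error
#' magnitudes into a [population_model()], ready for simulation-based
#' diagnostics ([vpc()], [npde()]) or new virtual studies.
#'
#' @param fit An [fit_mcpem()] result.
#' @return A [population_model()].
#' @export
as_population_model <- function(fit) {
  stopifnot(inherits(fit, "mcpem_fit"))
  arms <- fit$arms
  cv_or <- function(nm, fallback = 0) {
    v <- fit$bsv_cv_pct[[nm]]
    if (is.na(v)) fallback else v / 100
  }
  population_model(
    ka = stats::setNames(exp(fit$lka[arms]), arms),
    f = stats::setNames(stats::plogis(fit$lgf[arms]), arms),
    k12 = exp(fit$theta_log[["k12"]]), k21 = exp(fit$theta_log[["k21"]]),
    kel = exp(fit$theta_log[["kel"]]),
    kel_ur = exp(fit$theta_log[["kel_ur"]]),
    vc = exp(fit$theta_log[["vc"]]),
    bsv_cv = c(k12 = cv_or("k12"), k21 = cv_or("k21"), kel = cv_or("kel"),
               kel_ur = cv_or("kel_ur"), vc = cv_or("vc")),
    bsv_cv_ka = stats::setNames(
      vapply(arms, function(a) cv_or(paste0("ka_", a)), numeric(1)), arms),
    bsv_cv_f = stats::setNames(
      vapply(arms, function(a) cv_or(paste0("f_", a)), numeric(1)), arms),
    prop_cv = fit$resid[["prop_cv"]], add_sd = fit$resid[["add_sd"]],
    urine_cv = fit$resid[["urine_cv"]]
  )
}

.rse_lookup <- function(fit, nm) {
  if (is.null(fit$rse)) return(NA_real_)
  i <- match(nm, fit$rse$parameter)
  if (is.na(i)) NA_real_ else fit$rse$rse_pct[[i]]
}

#' Tidy population estimates
#'
#' One row per population parameter with estimate, relative standard
#' error, and the between-subject variability CV with its RSE — the shape
#' of a standard population-PK estimates table.
#'
#' @param x An [fit_mcpem()] result.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `rse_pct`,
#'   `bsv_cv_pct`, `bsv_rse_pct`. Bioavailabilities are in %, rates in
#'   1/hr, `vc` in L/kg; the residual rows carry the error magnitudes.
#' @method tidy mcpem_fit
#' @export
tidy.mcpem_fit <- function(x, ...) {
  rows <- list()
  for (nm in .SHARED_SLOTS) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = nm, estimate = exp(x$theta_log[[nm]]),
      rse_pct = .rse_lookup(x, nm),
      bsv_cv_pct = x$bsv_cv_pct[[nm]],
      bsv_rse_pct = .rse_lookup(x, paste0("omega_", nm))
    )
  }
  for (a in x$arms) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = paste0("f_", a),
      estimate = 100 * stats::plogis(x$lgf[[a]]),
      rse_pct = .rse_lookup(x, paste0("f_", a)),
      bsv_cv_pct = x$bsv_cv_pct[[paste0("f_", a)]],
      bsv_rse_pct = .rse_lookup(x, paste0("omega_f_", a))
    )
  }
  for (a in x$arms) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = paste0("ka_", a), estimate = exp(x$lka[[a]]),
      rse_pct = .rse_lookup(x, paste0("ka_", a)),
      bsv_cv_pct = x$bsv_cv_pct[[paste0("ka_", a)]],
      bsv_rse_pct = .rse_lookup(x, paste0("omega_ka_", a))
    )
  }
  for (nm in names(x$resid)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = nm, estimate = x$resid[[nm]],
      rse_pct = .rse_lookup(x, nm), bsv_cv_pct = NA_real_,
      bsv_rse_pct = NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

#' Fit-level summary
#'
#' @param x An [fit_mcpem()] result.
#' @param ... Unused.
#' @return A one-row tibble: `objective` (-2 log-likelihood, importance
#'   sampled), `n_subjects`, `n_obs`, `iterations`, `converged`.
#' @method glance mcpem_fit
#' @export
glance.mcpem_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, n_subjects = x$n_subjects, n_obs = x$n_obs,
    iterations = x$iterations, converged = x$converged
  )
}

#' @export
print.mcpem_fit <- function(x, ...) {
  cat(sprintf("<mcpem_fit> %d subjects, %d observations; %d EM iterations (%s)\n",
              x$n_subjects, x$n_obs, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  -2 log-likelihood (IS): %.2f\n", x$objective))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Empirical Bayes individual estimates
#'
#' @param fit An [fit_mcpem()] result.
#' @return A tibble of conditional-mean individual parameters, one row
#'   per subject.
#' @export
individual_estimates <- function(fit) {
  stopifnot(inherits(fit, "mcpem_fit"))
  fit$ebe
}

#' Observation-level predictions and autoplot for a fit
#'
#' Population predictions use the estimated medians; individual
#' predictions use each subject's empirical Bayes parameters.
#'
#' @param object An [fit_mcpem()] result.
#' @param ... Unused.
#' @return `autoplot.mcpem_fit()`: a ggplot of observed vs individual
#'   predicted concentrations.
#' @method autoplot mcpem_fit
#' @export
autoplot.mcpem_fit <- function(object, ...) {
  preds <- purrr::map_dfr(object$.subjects, function(s) {
    e <- object$ebe[object$ebe$id == s$id, ]
    p <- structural_params(e$ka, e$k12, e$k21, e$kel, e$kel_ur, e$vc, e$f)
    ipred <- pk_profile(p, dose_event(s$dose, 0, "oral"), s$times)$conc
    tibble::tibble(id = s$id, group = s$group, time = s$times,
                   observed = s$y, ipred = ipred)
  })
  ggplot2::ggplot(preds, ggplot2::aes(x = .data$ipred, y = .data$observed,
                                      colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Individual predicted (ng/mL)",
                  y = "Observed (ng/mL)",
                  title = "Observed vs individual predictions") +
    ggplot2::theme_minimal()
}
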