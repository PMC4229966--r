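# Vectorised closed-form predictions for many parameter draws at once.
# P is an M x 7 matrix with columns ka, k12, k21, kel, kel_ur, vc, f.
# Used inside the importance-sampling EM and the diagnostic simulators,
# where hundreds of parameter vectors are evaluated per subject per
# iteration; everything here is elementwise vector arithmetic.
#
# Exactly coincident exponents have probability zero under continuous
# sampling; a relative nudge of 1e-9 keeps the partial fractions finite if
# a draw lands on a degeneracy. The scalar path in pk_profile() uses the
# matrix-exponential fallback instead and is the reference.
.pred_oral_matrix <- function(P, times, amount, urine_time = NULL) {
  ka <- P[, 1]; k12 <- P[, 2]; k21 <- P[, 3]
  kel <- P[, 4]; kel_ur <- P[, 5]; vc <- P[, 6]; f <- P[, 7]
  k10 <- kel + kel_ur
  s <- k12 + k21 + k10
  disc <- sqrt(pmax(s * s - 4 * k21 * k10, 0))
  al <- (s + disc) / 2
  be <- (s - disc) / 2

  eps <- 1e-9
  near <- abs(al - be) < eps * al
  if (any(near)) be[near] <- be[near] - eps * al[near] - 1e-12
  near <- abs(ka - al) < eps * al
  if (any(near)) ka[near] <- ka[near] * (1 + 2 * eps)
  near <- abs(ka - be) < eps * pmax(be, 1e-6)
  if (any(near)) ka[near] <- ka[near] * (1 + 2 * eps)

  cka <- (k21 - ka) / ((al - ka) * (be - ka))
  cal <- (k21 - al) / ((ka - al) * (be - al))
  cbe <- (k21 - be) / ((ka - be) * (al - be))
  amp <- ka * f * amount

  conc <- (amp / vc * MGKG_PER_LKG_TO_NGML) *
    (cka * exp(-outer(ka, times)) +
     cal * exp(-outer(al, times)) +
     cbe * exp(-outer(be, times)))
  conc[conc < 0] <- 0

  urine <- NULL
  if (!is.null(urine_time)) {
    int1 <- -expm1(-ka * urine_time) / ka
    int2 <- -expm1(-al * urine_time) / al
    int3 <- ifelse(be > 1e-12, -expm1(-be * urine_time) / be, urine_time)
    # cumulative urinary amount as a fraction of the administered dose
    urine <- kel_ur * ka * f * (cka * int1 + cal * int2 + cbe * int3)
    urine[urine < 0] <- 0
  }
  list(conc = conc, urine_frac = urine)
}

# Individual parameter matrix from a population draw: eta is M x 7 on the
# transformed scale (log for rates and volume, logit for f).
# theta_log carries the five shared disposition logs; the subject's own
# arm supplies log-ka and logit-f.
.params_from_eta <- function(theta_log, log_ka, logit_f, eta) {
  cbind(
    ka     = exp(log_ka + eta[, 6]),
    k12    = exp(theta_log[["k12"]] + eta[, 1]),
    k21    = exp(theta_log[["k21"]] + eta[, 2]),
    kel    = exp(theta_log[["kel"]] + eta[, 3]),
    kel_ur = exp(theta_log[["kel_ur"]] + eta[, 4]),
    vc     = exp(theta_log[["vc"]] + eta[, 5]),
    f      = stats::plogis(logit_f + eta[, 7])
  )
}
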