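# Simulate K replicate plasma observation vectors for one subject's
# design directly from a population model (BSV + residual error), as an
# K x J matrix. Vectorised; used by the VPC and NPDE machinery.
.simulate_subject_matrix <- function(pop, group, times, dose_amount, K) {
  om <- c(.cv_to_omega(pop$bsv_cv[["k12"]]), .cv_to_omega(pop$bsv_cv[["k21"]]),
          .cv_to_omega(pop$bsv_cv[["kel"]]), .cv_to_omega(pop$bsv_cv[["kel_ur"]]),
          .cv_to_omega(pop$bsv_cv[["vc"]]), .cv_to_omega(pop$bsv_cv_ka[[group]]),
          .cv_to_omega(pop$bsv_cv_f[[group]]))
  eta <- matrix(stats::rnorm(K * 7), K, 7) * rep(om, each = K)
  P <- cbind(
    ka = pop$ka[[group]] * exp(eta[, 6]),
    k12 = pop$k12 * exp(eta[, 1]),
    k21 = pop$k21 * exp(eta[, 2]),
    kel = pop$kel * exp(eta[, 3]),
    kel_ur = pop$kel_ur * exp(eta[, 4]),
    vc = pop$vc * exp(eta[, 5]),
    f = pmin(pop$f[[group]] * exp(eta[, 7]), 1)
  )
  conc <- .pred_oral_matrix(P, times, dose_amount)$conc
  obs <- conc * (1 + matrix(stats::rnorm(length(conc), 0, pop$prop_cv),
                            nrow = K)) +
    matrix(stats::rnorm(length(conc), 0, pop$add_sd), nrow = K)
  obs[obs < 0] <- 0
  obs
}

.pop_from_any <- function(fit) {
  if (inherits(fit, "mcpem_fit")) as_population_model(fit)
  else if (inherits(fit, "population_model")) fit
  else stop("`fit` must be an `mcpem_fit` or a `population_model`",
            call. = FALSE)
}

#' Visual predictive check
#'
#' Simulates `nsim` replicate studies from the (fitted) population model
#' at the observed design and summarises the simulated plasma
#' concentrations at each nominal sampling time by their 10th, 25th, 50th,
#' 75th and 90th percentiles, per group. Observed points are overlaid and
#' the fraction of observations falling inside the 10th-90th band is
#' reported (expected about 80 % when the model generated the data).
#' Binning is at the nominal design times; no smoothing.
#'
#' @param fit An [fit_mcpem()] result or a [population_model()].
#' @param data The observed long-format dataset.
#' @param nsim Number of replicate studies (>= 200).
#' @param seed Integer seed.
#'
#' @return An object of class `vpc_result`: list with `bands` (tibble
#'   `group`, `time`, `p10`..`p90`), `observed`, `coverage_10_90`,
#'   `nsim`. Has an [autoplot()] method.
#' @export
vpc <- function(fit, data, nsim = 500, seed = 1L) {
  if (nsim < 200) stop("`nsim` must be >= 200", call. = FALSE)
  pop <- .pop_from_any(fit)
  subs <- .split_subjects(data)
  groups <- unique(vapply(subs, `[[`, "", "group"))
  missing_arms <- setdiff(groups, pop$arms)
  if (length(missing_arms) > 0) {
    stop("data group(s) unknown to the model: ",
         paste(missing_arms, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)

  # per group: pool simulated concentrations per nominal time
  bands <- list()
  for (g in groups) {
    g_subs <- subs[vapply(subs, `[[`, "", "group") == g]
    times <- sort(unique(unlist(lapply(g_subs, `[[`, "times"))))
    n_g <- length(g_subs)
    sims <- .simulate_subject_matrix(pop, g, times,
                                     g_subs[[1]]$dose_amount, nsim * n_g)
    qs <- apply(sims, 2, stats::quantile,
                probs = c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    bands[[g]] <- tibble::tibble(
      group = g, time = times,
      p10 = qs[1, ], p25 = qs[2, ], p50 = qs[3, ], p75 = qs[4, ],
      p90 = qs[5, ]
    )
  }
  bands <- dplyr::bind_rows(bands)

  observed <- purrr::map_dfr(subs, function(s) {
    tibble::tibble(id = s$id, group = s$group, time = s$times,
                   conc = s$conc)
  })
  obs_b <- dplyr::left_join(observed, bands, by = c("group", "time"))
  coverage <- mean(obs_b$conc >= obs_b$p10 & obs_b$conc <= obs_b$p90)

  structure(list(bands = bands, observed = observed,
                 coverage_10_90 = coverage, nsim = nsim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %d simulated studies; 10-90%% band coverage: %.1f%%\n",
              x$nsim, 100 * x$coverage_10_90))
  invisible(x)
}

#' @rdname vpc
#' @param object A `vpc_result`.
#' @param ... Unused.
#' @method autoplot vpc_result
#' @export
autoplot.vpc_result <- function(object, ...) {
  ggplot2::ggplot(object$bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), colour = "steelblue") +
    ggplot2::geom_point(data = object$observed,
                        ggplot2::aes(y = .data$conc), size = 1,
                        alpha = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = "Time (hr)", y = "Concentration (ng/mL)",
                  title = "Visual predictive check",
                  subtitle = "Median and 10-25-75-90th simulated percentiles") +
    ggplot2::theme_minimal()
}

#' Normalized prediction distribution errors
#'
#' For each subject, `nsim` replicate observation vectors are simulated
#' from the (fitted) population model at the subject's design. The
#' simulated vectors are decorrelated with the Cholesky factor of their
#' empirical covariance (ridge-regularized with a warning if singular),
#' the observed vector is decorrelated identically, and each observation's
#' rank-based prediction discrepancy is mapped through the standard normal
#' quantile. Under the generating model the NPDEs are approximately iid
#' standard normal.
#'
#' @param fit An [fit_mcpem()] result or a [population_model()].
#' @param data The observed long-format dataset (plasma records are
#'   used).
#' @param nsim Replicates per subject (>= 1000 recommended).
#' @param seed Integer seed.
#'
#' @return An object of class `npde_result`: list with `npde` (tibble
#'   `id`, `group`, `time`, `observed`, `npde`) and `summary` (one-row
#'   tibble: `mean`, `variance`, `t_pvalue` for mean 0, `shapiro_pvalue`
#'   for normality, `n`). Has [tidy()] and [autoplot()] methods.
#' @export
npde <- function(fit, data, nsim = 1000, seed = 1L) {
  pop <- .pop_from_any(fit)
  subs <- .split_subjects(data)
  missing_arms <- setdiff(unique(vapply(subs, `[[`, "", "group")), pop$arms)
  if (length(missing_arms) > 0) {
    stop("data group(s) unknown to the model: ",
         paste(missing_arms, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  ridge_used <- FALSE

  rows <- purrr::map_dfr(subs, function(s) {
    sims <- .simulate_subject_matrix(pop, s$group, s$times, s$dose_amount,
                                     nsim)
    mu <- colMeans(sims)
    V <- stats::cov(sims)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      ridge_used <<- TRUE
      L <- chol(V + diag(1e-6 * mean(diag(V)), ncol(V)))
    }
    # decorrelate: solve t(L) x = (y - mu)
    y_star <- backsolve(L, s$conc - mu, transpose = TRUE)
    sim_star <- t(backsolve(L, t(sims) - mu, transpose = TRUE))
    pd <- vapply(seq_along(y_star), function(j) {
      mean(sim_star[, j] < y_star[j])
    }, numeric(1))
    pd <- pmin(pmax(pd, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
    tibble::tibble(id = s$id, group = s$group, time = s$times,
                   observed = s$conc, npde = stats::qnorm(pd))
  })
  if (ridge_used) {
    warning("singular simulated covariance; ridge-regularized decorrelation",
            call. = FALSE)
  }

  tt <- stats::t.test(rows$npde)
  sh <- stats::shapiro.test(rows$npde)
  structure(list(
    npde = rows,
    summary = tibble::tibble(
      mean = mean(rows$npde), variance = stats::var(rows$npde),
      t_pvalue = tt$p.value, shapiro_pvalue = sh$p.value, n = nrow(rows)
    ),
    nsim = nsim
  ), class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat("<npde_result>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname npde
#' @param x An `npde_result`.
#' @param ... Unused.
#' @method tidy npde_result
#' @export
tidy.npde_result <- function(x, ...) x$npde

#' @rdname npde
#' @param object An `npde_result`.
#' @method autoplot npde_result
#' @export
autoplot.npde_result <- function(object, ...) {
  ggplot2::ggplot(object$npde, ggplot2::aes(x = .data$time, y = .data$npde,
                                            colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = 3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Time (hr)", y = "NPDE",
                  title = "Normalized prediction distribution errors") +
    ggplot2::theme_minimal()
}

# ---------------------------------------------------------------------
# Group comparison statistics
# ---------------------------------------------------------------------

#' Two-sample t-tests from summary statistics
#'
#' The Welch (unequal variance) and pooled-variance unpaired t-tests
#' computed directly from group means, SDs and sizes, so printed summary
#' tables can be compared without the raw data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#'
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_summary(744.00, 252.96, 6, 441.50, 63.30, 4)  # p < 0.05
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * stats::pt(-abs(stat), df))
}

#' @rdname welch_t_summary
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    # zero within-group variance: equality decides the test outright
    p <- if (mean1 == mean2) 1 else 0
    return(tibble::tibble(statistic = if (mean1 == mean2) 0 else Inf,
                          df = df, p_value = p))
  }
  stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * stats::pt(-abs(stat), df))
}

#' One-way ANOVA and Scheffe post hoc from summary statistics
#'
#' @param means,sds,ns Named numeric vectors of per-group summaries (same
#'   names, length >= 2).
#' @return `anova_summary()`: one-row tibble with `f_statistic`, `df1`,
#'   `df2`, `p_value`. `scheffe_summary()`: one row per group pair with
#'   the Scheffe-adjusted p-value, computed from the contrast form: the
#'   pairwise statistic `(m_i - m_j)^2 / (MSE (1/n_i + 1/n_j))` is
#'   referred to `(k - 1) F(k - 1, N - k)`.
#' @export
anova_summary <- function(means, sds, ns) {
  k <- length(means)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  mse <- ssw / df2
  if (mse == 0) {
    p <- if (ssb == 0) 1 else 0
    return(tibble::tibble(f_statistic = if (ssb == 0) 0 else Inf,
                          df1 = df1, df2 = df2, p_value = p, mse = mse))
  }
  f <- msb / mse
  tibble::tibble(f_statistic = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 mse = mse)
}

#' @rdname anova_summary
#' @export
scheffe_summary <- function(means, sds, ns) {
  k <- length(means)
  N <- sum(ns)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  an <- anova_summary(means, sds, ns)
  pairs <- utils::combn(names(means), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    if (an$mse == 0) {
      p <- if (means[[i]] == means[[j]]) 1 else 0
      return(tibble::tibble(group1 = i, group2 = j, difference =
                              means[[i]] - means[[j]], statistic = NA_real_,
                            p_value = p))
    }
    f_ij <- (means[[i]] - means[[j]])^2 /
      (an$mse * (1 / ns[[i]] + 1 / ns[[j]]))
    tibble::tibble(
      group1 = i, group2 = j, difference = means[[i]] - means[[j]],
      statistic = f_ij,
      p_value = stats::pf(f_ij / (k - 1), k - 1, N - k, lower.tail = FALSE)
    )
  })
}

#' Compare NCA parameters across groups
#'
#' For every NCA parameter: pairwise Welch and pooled unpaired t-tests,
#' and (with 3+ groups) one-way ANOVA followed by Scheffe's post hoc
#' contrasts. Both t-test variants are reported side by side; significance
#' is flagged at alpha = 0.05.
#'
#' @param results Per-subject NCA table from [run_nca()] (failed subjects
#'   dropped), or any tibble with a `group` column and numeric parameter
#'   columns.
#' @param parameters Parameter columns to test; defaults to the standard
#'   NCA set present in `results`.
#' @param alpha Significance level for the flags.
#'
#' @return A list of class `group_comparison`: `pairwise` (tibble with
#'   columns `parameter`, `group1`, `group2`, `welch_p`, `pooled_p`,
#'   `scheffe_p`, `significant` — Welch at `alpha`) and `anova` (tibble
#'   `parameter`, `f_statistic`, `df1`, `df2`, `p_value`).
#' @export
compare_groups <- function(results, parameters = NULL, alpha = 0.05) {
  if (!"group" %in% names(results)) stop("`results` needs a `group` column",
                                         call. = FALSE)
  if ("failure" %in% names(results)) {
    results <- results[is.na(results$failure), ]
  }
  std <- c("t_half", "tmax", "cmax", "auc_all", "auc_inf", "vz_f", "cl_f",
           "fe_urine", "f_pct")
  if (is.null(parameters)) {
    parameters <- intersect(std, names(results))
    parameters <- parameters[vapply(parameters, function(p) {
      sum(!is.na(results[[p]])) > 0
    }, logical(1))]
  }
  groups <- sort(unique(results$group))
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  cnt <- table(results$group)
  if (any(cnt < 2)) stop("need >= 2 subjects per group", call. = FALSE)
  k <- length(groups)

  pairwise <- list()
  anova_rows <- list()
  for (p in parameters) {
    d <- results[!is.na(results[[p]]), c("group", p)]
    means <- tapply(d[[p]], d$group, mean)[groups]
    sds <- tapply(d[[p]], d$group, stats::sd)[groups]
    ns <- as.numeric(table(d$group)[groups])
    names(ns) <- groups

    sch <- if (k >= 3) scheffe_summary(means, sds, ns) else NULL
    an <- if (k >= 3) anova_summary(means, sds, ns) else NULL
    if (!is.null(an)) {
      anova_rows[[p]] <- dplyr::mutate(an[, c("f_statistic", "df1", "df2",
                                              "p_value")],
                                       parameter = p, .before = 1)
    }
    for (pr in utils::combn(groups, 2, simplify = FALSE)) {
      g1 <- pr[1]; g2 <- pr[2]
      w <- welch_t_summary(means[[g1]], sds[[g1]], ns[[g1]],
                           means[[g2]], sds[[g2]], ns[[g2]])
      po <- pooled_t_summary(means[[g1]], sds[[g1]], ns[[g1]],
                             means[[g2]], sds[[g2]], ns[[g2]])
      sp <- if (is.null(sch)) NA_real_ else {
        sch$p_value[sch$group1 == g1 & sch$group2 == g2]
      }
      pairwise[[length(pairwise) + 1L]] <- tibble::tibble(
        parameter = p, group1 = g1, group2 = g2,
        welch_p = w$p_value, pooled_p = po$p_value, scheffe_p = sp,
        significant = w$p_value < alpha
      )
    }
  }
  structure(list(pairwise = dplyr::bind_rows(pairwise),
                 anova = dplyr::bind_rows(anova_rows), alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> pairwise tests (Welch flag at alpha =",
      x$alpha, ")\n")
  print(x$pairwise, n = Inf)
  if (nrow(x$anova) > 0) {
    cat("one-way ANOVA:\n")
    print(x$anova, n = Inf)
  }
  invisible(x)
}
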