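test_that("VPC bands are nested, calibrated and MC-stable", {
  pop <- population_model()
  dat <- simulate_study(pop, study_design(), seed = 31)
  v <- vpc(pop, dat, nsim = 400, seed = 32)

  expect_true(all(v$bands$p10 <= v$bands$p25 &
                  v$bands$p25 <= v$bands$p50 &
                  v$bands$p50 <= v$bands$p75 &
                  v$bands$p75 <= v$bands$p90))
  # data generated from the same model: ~80% inside the 10-90 band
  n_obs <- nrow(v$observed)
  tol <- 3 * sqrt(0.8 * 0.2 / n_obs)
  expect_gt(v$coverage_10_90, 0.8 - tol)
  expect_lt(v$coverage_10_90, 0.8 + tol)

  # determinism and MC stability under nsim doubling
  v2 <- vpc(pop, dat, nsim = 400, seed = 32)
  expect_identical(v$bands, v2$bands)
  v3 <- vpc(pop, dat, nsim = 800, seed = 33)
  med_rel <- abs(v3$bands$p50 - v$bands$p50) /
    pmax(v$bands$p50, max(v$bands$p50) * 0.05)
  expect_lt(stats::median(med_rel), 0.15)
  expect_s3_class(autoplot(v), "ggplot")
})

test_that("NPDE is null-calibrated under the generating model", {
  pop <- population_model()
  dat <- simulate_study(pop, study_design(), seed = 41)
  np <- npde(pop, dat, nsim = 1000, seed = 42)

  expect_equal(nrow(np$npde), 135L)  # every plasma observation scored
  expect_lt(abs(np$summary$mean), 0.25)
  expect_gt(np$summary$variance, 0.7)
  expect_lt(np$summary$variance, 1.3)

  np2 <- npde(pop, dat, nsim = 1000, seed = 42)
  expect_identical(np$npde, np2$npde)
  expect_s3_class(autoplot(np), "ggplot")
})

test_that("NPDE detects a misspecified absorption rate", {
  pop <- population_model()
  dat <- simulate_study(pop, study_design(), seed = 51)
  null_np <- npde(pop, dat, nsim = 600, seed = 52)
  halved <- population_model(ka = c(control = 0.64, OY = 0.26, AB = 0.87))
  bad_np <- npde(halved, dat, nsim = 600, seed = 52)
  expect_gt(abs(bad_np$summary$mean), abs(null_np$summary$mean))
  expect_gt(abs(bad_np$summary$mean), 0.3)
})

test_that("Welch t-test from the published Cmax summaries flags significance", {
  w <- welch_t_summary(744.00, 252.96, 6, 441.50, 63.30, 4)
  expect_lt(w$p_value, 0.05)
  # oracle: t.test on raw vectors constructed to have those exact moments
  mk <- function(n, m, s) {
    x <- scale(stats::rnorm(n))[, 1]
    m + s * x
  }
  set.seed(1)
  x1 <- mk(6, 744.00, 252.96)
  x2 <- mk(4, 441.50, 63.30)
  tt <- stats::t.test(x1, x2)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-10)

  po <- pooled_t_summary(744.00, 252.96, 6, 441.50, 63.30, 4)
  tt2 <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(po$p_value, tt2$p.value, tolerance = 1e-10)
})

test_that("identical groups give p = 1 under the pooled test", {
  po <- pooled_t_summary(5, 0, 4, 5, 0, 4)
  expect_equal(po$p_value, 1)
  po2 <- pooled_t_summary(5, 2, 4, 5, 2, 4)
  expect_equal(po2$p_value, 1)
})

test_that("summary-statistic ANOVA equals raw-data ANOVA", {
  mk <- function(n, m, s) m + s * scale(stats::rnorm(n))[, 1]
  set.seed(9)
  g <- list(a = mk(6, 10, 2), b = mk(5, 12, 3), c = mk(7, 9, 1.5))
  raw <- data.frame(y = unlist(g),
                    grp = rep(names(g), lengths(g)))
  fit <- stats::aov(y ~ grp, data = raw)
  f_raw <- summary(fit)[[1]]$`F value`[1]
  an <- anova_summary(sapply(g, mean), sapply(g, sd), lengths(g))
  expect_equal(an$f_statistic, f_raw, tolerance = 1e-10)
  expect_equal(an$p_value, summary(fit)[[1]]$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Scheffe is never more liberal than the unadjusted contrast test", {
  # same ANOVA error term: unadjusted pairwise contrast F with (1, N-k)
  # df vs the Scheffe criterion (k-1) F(k-1, N-k)
  set.seed(77)
  for (rep in 1:20) {
    ns <- sample(3:8, 3, replace = TRUE)
    means <- rnorm(3, 10, 2)
    sds <- runif(3, 0.5, 3)
    names(means) <- names(sds) <- names(ns) <- c("a", "b", "c")
    an <- anova_summary(means, sds, ns)
    sch <- scheffe_summary(means, sds, ns)
    for (i in seq_len(nrow(sch))) {
      p_unadj <- stats::pf(sch$statistic[i], 1, sum(ns) - 3,
                           lower.tail = FALSE)
      expect_gte(sch$p_value[i], p_unadj - 1e-12)
    }
  }
})

test_that("compare_groups assembles pairwise and ANOVA tables from NCA output", {
  dat <- simulate_study(population_model(), study_design(
    groups = tibble::tibble(label = c("control", "OY", "AB"),
                            n = c(12L, 12L, 12L))), seed = 61)
  nca <- run_nca(dat, iv_auc_ref = baclofen_iv_auc_reference())
  cmp <- compare_groups(nca)
  expect_s3_class(cmp, "group_comparison")
  expect_setequal(unique(cmp$pairwise$parameter), unique(cmp$anova$parameter))
  expect_equal(nrow(cmp$pairwise),
               3 * length(unique(cmp$pairwise$parameter)))
  # the slow-absorption arm separates on Cmax at n = 12/group
  cm <- cmp$pairwise[cmp$pairwise$parameter == "cmax" &
                       cmp$pairwise$group1 == "OY" |
                     cmp$pairwise$parameter == "cmax" &
                       cmp$pairwise$group2 == "OY", ]
  expect_true(any(cm$welch_p < 0.05))
  expect_error(compare_groups(nca[nca$group == "OY", ]), ">= 2 groups")
})
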