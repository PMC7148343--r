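# Adjusted AUC, comparative-Ct fold change, and the repeated-measures model.

test_that("adjusted AUC is the time-average of the trapezoid curve", {
  expect_equal(adjusted_auc(c(7, 14, 21, 28), c(400, 500, 600, 700))$value,
               11550 / 21)                       # hand trapezoid: 550
  expect_equal(adjusted_auc(c(0, 3, 10), rep(42, 3))$value, 42)  # constant

  # invariant under affine reparametrization of the day axis
  days <- c(7, 14, 21, 28); vals <- c(3, 1, 4, 1.5)
  a0 <- adjusted_auc(days, vals)$value
  expect_equal(adjusted_auc(3 * days + 10, vals)$value, a0)

  # log transform applies to the adjusted AUC value, not pointwise
  expect_equal(adjusted_auc(days, vals, log_transform = TRUE)$value, log(a0))

  expect_error(adjusted_auc(c(28, 21, 14, 7), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(adjusted_auc(7, 400), "at least two")
})

test_that("comparative-Ct fold changes reproduce the worked marker examples", {
  muc5ac_copd <- fold_change_from_auc(-1.1, -1.5)
  expect_equal(round(muc5ac_copd$fold, 1), 1.3)
  expect_equal(muc5ac_copd$direction, "increase")  # lower dCt = more mRNA

  muc5ac_hc <- fold_change_from_auc(-1.3, -2.0)
  expect_equal(round(muc5ac_hc$fold, 1), 1.6)
  expect_equal(muc5ac_hc$direction, "increase")

  scgb1a1_copd <- fold_change_from_auc(-10.3, -8.9)
  expect_equal(round(scgb1a1_copd$fold, 1), 2.6)
  expect_equal(scgb1a1_copd$direction, "decrease")

  same <- fold_change_from_auc(-4.2, -4.2)
  expect_equal(same$fold, 1)
  expect_equal(same$direction, "no change")
})

test_that("the repeated-measures fit recovers exact means and rejects broken pairing", {
  mc <- list(HC.Air = rep(10, 4), HC.CS = rep(7, 4),
             COPD.Air = rep(9, 4), COPD.CS = rep(5, 4))
  d <- generate_longitudinal(longitudinal_spec(subject_sd = 0, residual_sd = 0,
                                               mean_curves = mc, seed = 2))
  f <- fit_repeated_measures(adjusted_auc_table(d))
  expect_equal(f$cell_means["HC", "Air"], 10)
  expect_equal(f$cell_means["HC", "CS"], 7)
  expect_equal(f$cell_means["COPD", "CS"], 5)
  r <- test_one_sided(f, "COPD", "lower")
  expect_equal(r$estimate, -4)
  r0 <- test_one_sided(f, "HC", "upper")
  expect_equal(r0$estimate, -3)
  # zero effect, zero noise: estimate 0
  d2 <- generate_longitudinal(longitudinal_spec(
    subject_sd = 0, residual_sd = 0,
    mean_curves = list(HC.Air = rep(1, 4), HC.CS = rep(1, 4)), seed = 1))
  f2 <- fit_repeated_measures(adjusted_auc_table(d2))
  expect_equal(test_one_sided(f2, "HC", "lower")$estimate, 0)

  broken <- adjusted_auc_table(d)
  broken <- broken[!(broken$subject == "HC_02" & broken$treatment == "CS"), ]
  expect_error(fit_repeated_measures(broken), "HC_02")
})

test_that("the within-group treatment contrast equals the paired t-test", {
  for (seed in c(3, 17, 88)) {
    d <- generate_longitudinal(longitudinal_spec(
      n_subjects_per_group = 5, groups = "HC", subject_sd = 3, residual_sd = 1,
      within_subject_correlation = 0.4,
      mean_curves = list(HC.Air = c(5, 6, 7, 8), HC.CS = c(4, 5, 6, 7)),
      seed = seed))
    at <- adjusted_auc_table(d)
    f <- fit_repeated_measures(at)
    r <- test_one_sided(f, "HC", "lower")
    wide <- reshape(at[, c("subject", "treatment", "auc")],
                    idvar = "subject", timevar = "treatment",
                    direction = "wide")
    tt <- t.test(wide$auc.CS, wide$auc.Air, paired = TRUE,
                 alternative = "less")
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p_one_sided, tt$p.value, tolerance = 1e-12)
    expect_equal(r$df, unname(tt$parameter))
  }
})

test_that("the closed-form fit agrees with REML (nlme) on two-group data", {
  skip_if_not_installed("nlme")
  d <- generate_longitudinal(longitudinal_spec(
    n_subjects_per_group = 6, subject_sd = 2, residual_sd = 1,
    within_subject_correlation = 0.5,
    mean_curves = list(HC.Air = rep(8, 4), HC.CS = rep(6, 4),
                       COPD.Air = rep(7, 4), COPD.CS = rep(4, 4)),
    seed = 31))
  at <- adjusted_auc_table(d)
  f <- fit_repeated_measures(at)
  lfit <- nlme::lme(auc ~ 0 + group:treatment, random = ~ 1 | subject,
                    data = at, method = "REML")
  fe <- nlme::fixef(lfit)
  expect_equal(unname(fe["groupHC:treatmentAir"]), f$cell_means["HC", "Air"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fe["groupCOPD:treatmentCS"]), f$cell_means["COPD", "CS"],
               tolerance = 1e-8, ignore_attr = TRUE)
  # contrast SE: lme residual variance equals sigma2 * (1 - rho)
  sig_e2 <- lfit$sigma^2
  expect_equal(sig_e2, f$sigma2 * (1 - f$rho), tolerance = 1e-6)
  se_lme <- sqrt(2 * sig_e2 / 6)
  expect_equal(f$contrasts$se[f$contrasts$group == "HC"], se_lme,
               tolerance = 1e-6)
})

test_that("one-sided testing follows the registry and is directionally sane", {
  reg <- default_direction_registry()
  expect_setequal(reg$endpoint[reg$direction == "upper"],
                  c("SCGB1A1_dCt", "FOXJ1_dCt"))
  expect_true(all(reg$log_transform[reg$endpoint %in% c("teer", "active_area")]))

  d <- generate_longitudinal(longitudinal_spec(
    n_subjects_per_group = 4, groups = "HC", subject_sd = 1, residual_sd = 0.5,
    mean_curves = list(HC.Air = rep(0, 4), HC.CS = rep(5, 4)), seed = 12))
  f <- fit_repeated_measures(adjusted_auc_table(d))
  # strong effect opposite to the tested direction: p near 1
  expect_gt(test_one_sided(f, "HC", endpoint = "MUC5AC_dCt")$p_one_sided, 0.99)
  expect_lt(test_one_sided(f, "HC", endpoint = "SCGB1A1_dCt")$p_one_sided, 0.01)
  expect_error(test_one_sided(f, "HC", endpoint = "unregistered_thing"),
               "registry")
  expect_error(test_one_sided(f, "COPD", "lower"), "group 'COPD'")
  # determinism: identical data, identical p
  f2 <- fit_repeated_measures(adjusted_auc_table(d))
  expect_identical(test_one_sided(f2, "HC", "lower")$p_one_sided,
                   test_one_sided(f, "HC", "lower")$p_one_sided)
})

test_that("rejection rate is calibrated under the null and power grows with effect", {
  null_rate <- function(alpha, n_rep, seed_off) {
    mean(vapply(seq_len(n_rep), function(s) {
      d <- generate_longitudinal(longitudinal_spec(
        n_subjects_per_group = 3, subject_sd = 1, residual_sd = 1,
        within_subject_correlation = 0.5, seed = s + seed_off))
      f <- fit_repeated_measures(adjusted_auc_table(d))
      test_one_sided(f, "HC", "lower")$p_one_sided < alpha
    }, logical(1)))
  }
  r05 <- null_rate(0.05, 800, 0)
  r01 <- null_rate(0.01, 800, 5000)
  expect_lt(abs(r05 - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
  expect_lt(abs(r01 - 0.01), 3 * sqrt(0.01 * 0.99 / 800) + 0.002)

  power_at <- function(effect) {
    mean(vapply(1:200, function(s) {
      mc <- list(HC.Air = rep(0, 4), HC.CS = rep(-effect, 4))
      d <- generate_longitudinal(longitudinal_spec(
        n_subjects_per_group = 4, groups = "HC", subject_sd = 1,
        residual_sd = 1, mean_curves = mc, seed = s + 900))
      f <- fit_repeated_measures(adjusted_auc_table(d))
      test_one_sided(f, "HC", "lower")$p_one_sided < 0.05
    }, logical(1)))
  }
  pw <- vapply(c(0.5, 1.5, 3), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[3], 0.9)
})
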