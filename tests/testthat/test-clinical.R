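# printed per-patient percent columns, frozen as 2 d.p. expectations
pct_bipo_printed <- c(23.53, -12.50, 71.43, 33.33, 50.00, -5.88, 27.78,
                      -12.50, 46.15, 42.11, 4.76, 88.00, 21.43, 30.77, 8.33)
pct_mono_printed <- c(84, 21.43, 70.83, 28.57, 61.11, 21.05, 20, 0, 31.82,
                      50, 36, 80, 23.53, 37.5, 14.29)

test_that("percent conventions reproduce the printed cohort values", {
  expect_equal(percent_improvement_twstrs(25, 3), 88.00)
  expect_equal(round_half_up(percent_improvement_twstrs(8, 9), 2), -12.50)
  expect_equal(percent_improvement_twstrs(17, 17), 0)
  expect_error(percent_improvement_twstrs(0, 3), "undefined")

  tab <- load_cohort_table()
  expect_equal(round_half_up(tab$pct_improvement_bipolar, 2),
               pct_bipo_printed)
  expect_equal(round_half_up(tab$pct_improvement_monopolar, 2),
               pct_mono_printed)
})

test_that("UPDRS percent change references the ON score", {
  expect_equal(percent_change_updrs(5, 10), 50)
  expect_equal(percent_change_updrs(10, 10), 0)
  expect_equal(percent_change_updrs(12, 8), -50)
  expect_error(percent_change_updrs(3, 0), "undefined")
  expect_equal(updrs_bradykinesia_score(cbind(c(1, 2), c(0, 1),
                                              c(2, 2), c(1, 0))),
               c(4, 5))
})

test_that("paired t-test reproduces the cohort result and hand-computed cases", {
  tab <- load_cohort_table()
  expect_warning(tt <- paired_t_test(tab$twstrs_off, tab$twstrs_bipolar_on),
                 "Shapiro")
  expect_equal(round_half_up(tt$statistic, 2), 3.12)
  expect_equal(tt$df, 14)
  expect_equal(round_half_up(tt$p, 3), 0.008)
  expect_equal(round_half_up(abs(tt$effect_size), 2), 0.81)

  # differences (1,2,3): t = 2/1 * sqrt(3), df = 2
  x <- c(1, 2, 3)
  t2 <- suppressWarnings(paired_t_test(x + x, x))
  expect_equal(t2$statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(t2$df, 2)

  # antisymmetry
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  f <- suppressWarnings(paired_t_test(a, b))
  g <- suppressWarnings(paired_t_test(b, a))
  expect_equal(f$statistic, -g$statistic)
  expect_equal(f$p, g$p)
  expect_equal(abs(f$effect_size), abs(g$effect_size))

  expect_error(suppressWarnings(paired_t_test(x, x)), "zero variance")
})

test_that("Shapiro-Wilk behaves on normal and skewed samples", {
  set.seed(2)
  p_norm <- replicate(100, shapiro_wilk(rnorm(15))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_skew <- replicate(100, shapiro_wilk(rexp(50))$p)
  expect_gte(mean(p_skew < 0.05), 0.80)
  expect_true(all(replicate(20, shapiro_wilk(rnorm(10))$statistic) <= 1))
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("responder classification matches the printed split and boundary rule", {
  tab <- load_cohort_table()
  res <- classify_responders(tab)
  expect_equal(res$n_responders, 10)
  expect_equal(res$n_non_responders, 5)
  expect_true(res$rules_agree)  # >=20% and >=3-point MCID partition identically

  # exactly 20% improvement counts as response
  boundary <- data.frame(twstrs_off = 10, twstrs_bipolar_on = 8,
                         pct_improvement_bipolar = 20)
  expect_true(classify_responders(boundary)$responder)

  zero <- data.frame(twstrs_off = c(10, 8), twstrs_bipolar_on = c(10, 8),
                     pct_improvement_bipolar = c(0, 0))
  expect_equal(classify_responders(zero)$n_responders, 0)
})

test_that("Fisher-z sensitivity analysis gives rho_min 0.616 and inverts", {
  expect_equal(round_half_up(minimal_detectable_rho(15, 0.80, 0.05), 3), 0.616)
  for (p in c(0.5, 0.8, 0.9, 0.99)) {
    rho <- minimal_detectable_rho(20, p, 0.05)
    expect_equal(fisher_z_power(20, rho, 0.05), p, tolerance = 1e-9)
  }
  # power increases to 1 with n at fixed rho
  expect_lt(fisher_z_power(10, 0.3), fisher_z_power(100, 0.3))
  expect_gt(fisher_z_power(10000, 0.3), 0.999)
  # the closed form gives ~0.94 for rho = 0.73 at n = 15 (one-sided)
  expect_equal(fisher_z_power(15, 0.73), 0.94, tolerance = 0.005)
  expect_error(fisher_z_power(3, 0.5), "n > 3")
})

test_that("covariate model: standardized beta equals r for one predictor", {
  set.seed(3)
  x <- rnorm(15); y <- 2 * x + rnorm(15)
  cm <- covariate_model(y, data.frame(x = x))
  expect_equal(cm$beta_std, cor(x, y), tolerance = 1e-12)

  expect_error(covariate_model(y, data.frame(a = x, b = 2 * x)), "collinear")
  expect_error(covariate_model(rnorm(4),
                               data.frame(a = rnorm(4), b = rnorm(4),
                                          c = rnorm(4))),
               "need n >")
})

test_that("covariate model detects the similarity effect at the stated SNR", {
  set.seed(4)
  hits <- replicate(50, {
    similarity <- rnorm(15)
    age <- rnorm(15); dur <- rnorm(15); sev <- rnorm(15)
    y <- similarity + 0.5 * rnorm(15)
    cm <- covariate_model(y, data.frame(similarity, age, dur, sev))
    cm$p[cm$predictor == "similarity"] < 0.05 &&
      all(cm$p[cm$predictor != "similarity"] > 0.05 |
            abs(cm$beta_std[cm$predictor != "similarity"]) < 0.5)
  })
  expect_gte(mean(hits), 0.80)

  # null: standardized betas centred at zero
  set.seed(5)
  betas <- replicate(100, {
    cm <- covariate_model(rnorm(15), data.frame(a = rnorm(15), b = rnorm(15)))
    cm$beta_std
  })
  expect_lt(abs(mean(betas)), 0.06)
})

test_that("one-way ANOVA has the right df structure and calibration", {
  tab <- load_cohort_table()
  a <- anova_by_type(tab$pct_improvement_bipolar, tab$dystonia_type)
  expect_equal(a$df, c(1, 13))
  expect_gt(a$p, 0)

  expect_error(anova_by_type(rnorm(6), rep("CD", 6)), "two groups")
  expect_error(anova_by_type(rep(1, 6), rep(c("CD", "SD"), 3)),
               "zero variance")

  set.seed(6)
  pvals <- replicate(200, {
    anova_by_type(rnorm(15), rep(c("CD", "SD"), c(11, 4)))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("cohort summary reproduces the printed means and SDs", {
  tab <- load_cohort_table()
  s <- cohort_summary(tab)
  g <- function(col, what) s[[what]][s$column == col]
  expect_equal(g("pct_improvement_bipolar", "mean_rounded"), 27.78)
  expect_equal(g("pct_improvement_bipolar", "sd_rounded"), 29.22)
  expect_equal(round_half_up(g("twstrs_pre", "mean"), 0), 18)
  expect_equal(round_half_up(g("twstrs_off", "mean"), 0), 15)
  expect_equal(round_half_up(g("twstrs_bipolar_on", "mean"), 0), 10)
  expect_equal(round_half_up(g("twstrs_monopolar_on", "mean"), 0), 10)
  expect_equal(round_half_up(g("twstrs_off", "sd"), 0), 5)
  expect_equal(round_half_up(g("twstrs_bipolar_on", "sd"), 0), 5)
  expect_error(cohort_summary(data.frame(x = character(0))), "no numeric")
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(27.775, 2), 27.78)
})
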