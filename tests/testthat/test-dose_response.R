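test_that("noise-free mediation gives the exact closed-form slope", {
  cfg <- trial_config(n_per_arm = 150, seed = 101,
                      mediation_slopes = list(kccq = 6, sixmwd = 13,
                                              log_crp = -0.33),
                      change_noise_sds = list(kccq = 0, sixmwd = 0,
                                              log_crp = 0),
                      weight_response_sd = 3,
                      missing_rate_week52 = 0, death_rate = 0)
  df <- generate_trial(cfg)
  f <- fit_dose_response(df, "kccq", "model1")
  expect_equal(f$slope_per_10pct, 6, tolerance = 1e-6)
  expect_lt(f$ci_high - f$ci_low, 1e-4)
  # treated-arm change is an exact linear function of the regressors
  sem <- df[df$arm == "semaglutide", ]
  fit <- lm(I(kccq_week52 - kccq_baseline) ~ I(percent_weight_change(
    weight_baseline_kg, weight_week52_kg)) + kccq_baseline, data = sem)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-10)
})

test_that("ratio-to-percent-decrease is the stated monotone map", {
  expect_equal(ratio_to_percent_decrease(1.0), 0)
  expect_equal(ratio_to_percent_decrease(0.72), 28)
  out <- ratio_to_percent_decrease(0.72, 0.63, 0.84)
  expect_equal(unname(out), c(28, 16, 37))
  expect_error(ratio_to_percent_decrease(-0.5), "positive")
  # identity on (0, 100) through the inverse map
  pct <- c(5, 28, 60, 99)
  expect_equal(ratio_to_percent_decrease(1 - pct / 100), pct)
})

test_that("CRP dose-response is reported as a positive ratio", {
  df <- generate_trial(trial_config(n_per_arm = 400, seed = 102,
                                    missing_rate_week52 = 0, death_rate = 0))
  for (mod in c("model1", "model2")) {
    f <- fit_dose_response(df, "crp", mod)
    expect_equal(f$scale, "ratio")
    expect_true(f$slope_per_10pct > 0 && f$ci_low > 0)
    expect_true(f$ci_low < f$slope_per_10pct & f$slope_per_10pct < f$ci_high)
  }
})

test_that("adding the Model 2 covariates moves the slope by less than 2 SE", {
  df <- generate_trial(trial_config(n_per_arm = 800, seed = 103,
                                    missing_rate_week52 = 0, death_rate = 0))
  f1 <- fit_dose_response(df, "kccq", "model1")
  f2 <- fit_dose_response(df, "kccq", "model2")
  se1 <- (f1$ci_high - f1$ci_low) / (2 * qt(0.975, f1$n_used - 4))
  expect_lt(abs(f1$slope_per_10pct - f2$slope_per_10pct), 2 * se1)
})

test_that("MI dose-response pools per-imputation slopes", {
  df <- generate_trial(trial_config(n_per_arm = 300, seed = 104,
                                    missing_rate_week52 = 0, death_rate = 0))
  complete <- fit_dose_response(df, "kccq", "model1")
  masked <- induce_missingness(df, "MCAR", 0.2, seed = 9)
  imp <- impute_endpoint(masked, c("kccq", "weight"), m = 10, seed = 10)
  pooled <- fit_dose_response(imp, "kccq", "model1")
  se <- (pooled$ci_high - pooled$ci_low) / (2 * 1.96)
  expect_lt(abs(pooled$slope_per_10pct - complete$slope_per_10pct), 3 * se)
  expect_error(fit_dose_response(impute_endpoint(masked, "kccq", m = 2),
                                 "kccq", "model1"), "cover")
})

test_that("ordinal category analysis mirrors the continuous trend", {
  df <- generate_trial(trial_config(n_per_arm = 1500, seed = 105,
                                    missing_rate_week52 = 0, death_rate = 0))
  ord <- fit_ordinal_categories(df, "kccq")
  expect_equal(ord$table$category,
               c("lt5", "5to10", "10to15", "15to20", "ge20"))
  expect_lt(ord$linearity_p, 0.01)
  # adjusted means increase with weight loss under positive mediation
  expect_gt(cor(ord$table$mean, seq_len(5), method = "spearman"), 0.8)
  expect_equal(sum(ord$table$n),
               sum(df$arm == "semaglutide" & !is.na(df$weight_week52_kg)))
})

test_that("empty weight-loss categories are dropped with a warning", {
  df <- make_trial(arm = rep(c("semaglutide", "placebo"), each = 30),
                   pct_weight = rep(c(-2, -7, -12, 0), length.out = 60),
                   kccq_chg = rnorm(60, 0, 5), kccq0 = runif(60, 30, 80))
  expect_warning(ord <- fit_ordinal_categories(df, "kccq"),
                 "empty weight-loss categories dropped")
  expect_true(all(ord$table$category %in% c("lt5", "5to10", "10to15")))
  expect_true(is.finite(ord$linearity_f))
})

test_that("observed category counts partition the semaglutide arm", {
  pcts <- c(-2, 3, -6, -9.5, -11, -14.5, -16, -19.5, -21, -27)
  df <- make_trial(arm = rep(c("semaglutide", "placebo"), each = 10),
                   pct_weight = rep(pcts, 2))
  wcc <- weight_category_counts(df)
  expect_equal(wcc$n, c(2, 2, 2, 2, 2))  # the gain and -2% both fall in lt5
  expect_equal(sum(wcc$n), 10)
  expect_lt(abs(sum(wcc$pct) - 100), 0.2)
  none <- df
  none$weight_week52_kg <- NA_real_
  expect_error(weight_category_counts(none), "no observed week-52 weights")
})

test_that("baseline associations recover the generator's per-BMI slopes", {
  df <- generate_trial(trial_config(n_per_arm = 1000, seed = 106))
  f <- fit_baseline_association(df, "kccq")
  se <- (f$ci_high - f$ci_low) / (2 * 1.96)
  expect_lt(abs(f$slope_per_10pct - (-0.8)), 3 * se)
  fc <- fit_baseline_association(df, "crp")
  expect_equal(fc$scale, "ratio")
  expect_gt(fc$slope_per_10pct, 1)  # positive log-CRP slope per unit BMI
})
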