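test_that("Rubin pooling reproduces closed forms", {
  # zero between-imputation variance
  pl <- rubin_pool(rep(2, 4), rep(1, 4))
  expect_equal(pl$theta_bar, 2)
  expect_equal(pl$B, 0)
  expect_equal(pl$T, 1)
  expect_equal(pl$df, 1e6)
  # with identical estimates the CI equals the single-imputation Wald CI
  expect_equal(pl$ci_low, 2 - qt(0.975, 1e6), tolerance = 1e-10)

  pl <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(pl$theta_bar, 2)
  expect_equal(pl$W, 1)
  expect_equal(pl$B, 1)
  expect_equal(pl$T, 1 + (4 / 3) * 1)
  expect_true(pl$ci_low < pl$theta_bar && pl$theta_bar < pl$ci_high)
  expect_true(pl$T == pl$W + (1 + 1 / 3) * pl$B)
})

test_that("pooling is invariant to permutation of the imputations", {
  set.seed(9)
  est <- rnorm(12); v <- runif(12, 0.5, 2)
  p1 <- rubin_pool(est, v)
  idx <- sample(12)
  p2 <- rubin_pool(est[idx], v[idx])
  expect_equal(p1$theta_bar, p2$theta_bar)
  expect_equal(p1$T, p2$T)
  expect_equal(p1$p, p2$p)
})

test_that("pooling rejects malformed inputs", {
  expect_error(rubin_pool(1:3, 1:2), "length")
  expect_error(rubin_pool(1, 1), "m >= 2")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "positive")
})

test_that("large-m total variance converges to v + tau^2", {
  set.seed(17)
  theta <- 1.5; tau2 <- 0.4; v <- 0.7
  pl <- rubin_pool(rnorm(4000, theta, sqrt(tau2)), rep(v, 4000))
  expect_equal(pl$T, v + tau2, tolerance = 0.08)
})

test_that("degenerate MI on complete data reproduces the complete-data fit", {
  df <- generate_trial(trial_config(n_per_arm = 120, seed = 41,
                                    missing_rate_week52 = 0, death_rate = 0))
  imp <- impute_endpoint(df, "kccq", m = 3, seed = 2)
  for (i in 1:3) expect_identical(imp$completed[[i]], df)
  eff <- subgroup_etds_mi(imp, "kccq")
  direct <- fit_ancova(df, "kccq")
  expect_equal(eff$table$etd, direct$etd$est, tolerance = 1e-10)
  expect_equal(eff$interaction$f_stat, direct$interaction$f,
               tolerance = 1e-8)
})

test_that("pooled ETD after MCAR masking is close to the complete-data ETD", {
  df <- generate_trial(trial_config(n_per_arm = 250, seed = 43,
                                    missing_rate_week52 = 0, death_rate = 0))
  complete <- fit_ancova(df, "kccq")
  masked <- induce_missingness(df, "MCAR", 0.2, seed = 7)
  imp <- impute_endpoint(masked, "kccq", m = 30, seed = 8)
  eff <- subgroup_etds_mi(imp, "kccq")
  for (j in 1:3) {
    expect_lt(abs(eff$table$etd[j] - complete$etd$est[j]),
              3 * eff$table$se[j])
  }
})

test_that("imputation draws are deterministic, proper and scale-respecting", {
  df <- generate_trial(trial_config(n_per_arm = 80, seed = 44,
                                    missing_rate_week52 = 0.25,
                                    death_rate = 0))
  i1 <- impute_endpoint(df, "crp", m = 5, seed = 10)
  i2 <- impute_endpoint(df, "crp", m = 5, seed = 10)
  expect_identical(i1$completed, i2$completed)
  # log-scale imputation forces positive CRP
  for (i in 1:5) {
    expect_false(anyNA(i1$completed[[i]]$crp_week52_mg_l))
    expect_true(all(i1$completed[[i]]$crp_week52_mg_l > 0))
  }
  # observed values identical across imputations
  obs <- !is.na(df$crp_week52_mg_l)
  for (i in 1:5) {
    expect_identical(i1$completed[[i]]$crp_week52_mg_l[obs],
                     df$crp_week52_mg_l[obs])
  }
  # distinct imputations differ on the missing entries
  expect_false(identical(i1$completed[[1]]$crp_week52_mg_l,
                         i1$completed[[2]]$crp_week52_mg_l))
})

test_that("imputation contracts are enforced", {
  df <- generate_trial(trial_config(n_per_arm = 60, seed = 45))
  expect_error(impute_endpoint(df, "death", m = 5), "never imputed")
  expect_error(impute_endpoint(df, "hf_events", m = 5), "never imputed")
  expect_error(impute_endpoint(df, "kccq", m = 1), "m must be >= 2")
  expect_error(impute_endpoint(df, "bogus", m = 5), "unknown endpoint")
  tiny <- make_trial(arm = rep(c("semaglutide", "placebo"), each = 5),
                     kccq_chg = rnorm(10))
  expect_error(impute_endpoint(tiny, "kccq", m = 5), "fewer than 10 observed")
})
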