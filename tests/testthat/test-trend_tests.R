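test_that("JT statistic counts concordant cross-pairs", {
  tt <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)), exact = "never")
  expect_equal(unname(tt$statistic), 12)  # all 12 cross-pairs concordant
  expect_gt(tt$z, 0)

  # all observations equal: U is half the cross-pairs, z = 0, p = 1
  tt <- jonckheere_terpstra(list(rep(4, 3), rep(4, 3), rep(4, 2)),
                            exact = "never")
  expect_equal(unname(tt$statistic), (3 * 3 + 3 * 2 + 3 * 2) / 2)
  expect_equal(tt$z, 0)
  expect_equal(tt$p_two_sided, 1)
  expect_true(tt$tie_correction_applied)

  expect_error(jonckheere_terpstra(list(1:3)), ">= 2 ordered groups")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0))), "at least one")
})

test_that("two-group JT equals the Mann-Whitney U statistic", {
  set.seed(83)
  for (r in 1:5) {
    x <- rnorm(6); y <- rnorm(8)
    tt <- jonckheere_terpstra(list(x, y), exact = "never")
    expect_equal(unname(tt$statistic), unname(wilcox.test(y, x)$statistic))
  }
})

test_that("JT normal approximation tracks the exact permutation p at n = 12", {
  set.seed(84)
  for (r in 1:12) {
    sizes <- list(c(4, 4, 4), c(3, 4, 5), c(2, 5, 5))[[1 + r %% 3]]
    x <- rnorm(12)
    g <- split(x, rep(seq_along(sizes), sizes))
    pn <- jonckheere_terpstra(g, exact = "never")$p_two_sided
    pe <- jonckheere_terpstra(g, exact = "always")$p_two_sided
    expect_lt(abs(pn - pe), 0.02)
  }
})

test_that("Cochran-Armitage is null on proportional tables and antisymmetric", {
  tt <- cochran_armitage(c(10, 20, 30), c(20, 40, 60))
  expect_equal(tt$z, 0)
  expect_equal(tt$p_two_sided, 1)

  tt1 <- cochran_armitage(c(2, 5, 9), c(12, 12, 12))
  tt2 <- cochran_armitage(c(9, 5, 2), c(12, 12, 12))
  expect_equal(tt1$z, -tt2$z)
  expect_equal(tt1$p_two_sided, tt2$p_two_sided)

  expect_warning(cochran_armitage(c(0, 0, 0), c(5, 5, 5)), "degenerate")
  expect_error(cochran_armitage(c(6, 1), c(5, 5)), "successes")
})

test_that("CA z^2 equals the score chi-square from prop.trend.test", {
  set.seed(85)
  for (r in 1:5) {
    n <- sample(10:40, 3, replace = TRUE)
    s <- pmin(n, rbinom(3, n, c(0.2, 0.4, 0.6)))
    if (sum(s) == 0 || sum(s) == sum(n)) next
    tt <- cochran_armitage(s, n)
    ref <- suppressWarnings(prop.trend.test(s, n))
    expect_equal(tt$z^2, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("CMH correlation statistic has its closed-form identities", {
  # independence table: outer product of margins
  tab <- outer(c(10, 20, 30), c(5, 10, 15)) / 10
  tt <- cmh_score_trend(tab)
  expect_lt(unname(tt$statistic), 1e-10)
  expect_equal(tt$p_two_sided, 1, tolerance = 1e-6)

  # 2x2: statistic equals (N-1)/N times the Pearson chi-square
  tab <- matrix(c(12, 5, 7, 16), 2)
  N <- sum(tab)
  tt <- cmh_score_trend(tab)
  ref <- chisq.test(tab, correct = FALSE)$statistic
  expect_equal(unname(tt$statistic), unname(ref) * (N - 1) / N,
               tolerance = 1e-10)

  expect_warning(cmh_score_trend(matrix(c(5, 5, 0, 0), 2)), "degenerate")
  # NYHA-like table with a monotone shift is detected
  shift <- rbind(c(120, 50, 5), c(95, 70, 10), c(60, 100, 20))
  expect_lt(cmh_score_trend(shift)$p_two_sided, 0.05)
})

test_that("the baseline table dispatches variables to the matching test", {
  df <- generate_trial(trial_config(n_per_arm = 1000, seed = 91))
  bt <- baseline_trend_table(df)
  expect_s3_class(bt, "baseline_table")
  expect_true(all(c("variable", "class_I", "class_II", "class_III",
                    "p_trend") %in% names(bt)))
  # configured monotone baseline structure is detected
  expect_lt(bt$p_trend[bt$variable == "kccq_baseline"], 1e-4)
  expect_lt(bt$p_trend[bt$variable == "sixmwd_baseline_m"], 1e-4)
  expect_lt(bt$p_trend[bt$variable == "crp_baseline_mg_l"], 1e-4)
  expect_true(all(bt$p_trend > 0 & bt$p_trend <= 1))

  one_class <- df[assign_bmi_class(df$bmi) == "I", , drop = FALSE]
  expect_error(baseline_trend_table(one_class), ">= 2 ordered groups")
  expect_error(baseline_trend_table(df, list(list(name = "age", type = "odd"))),
               "unknown variable type")
  expect_error(baseline_trend_table(df, list(list(name = "nope",
                                                  type = "continuous"))),
               "unknown variable")
})
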