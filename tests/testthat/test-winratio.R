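test_that("pairwise comparison walks the hierarchy in order", {
  h <- hierarchy_spec()
  # death dominates: treated dies day 100, control alive through follow-up
  t1 <- make_trial("semaglutide", death_day = 100, obs = 100, kccq_chg = NA,
                   sixmwd_chg = NA)
  c1 <- make_trial("placebo", obs = 364)
  expect_equal(compare_pair(t1, c1, h),
               list(result = "loss", decided_at_level = 1L))
  # identical records tie
  expect_equal(compare_pair(c1, c1, h)$result, "tie")
  # KCCQ +16 vs +12 decides at the >= 15 threshold (level 3)
  t2 <- make_trial("semaglutide", kccq_chg = 16)
  c2 <- make_trial("placebo", kccq_chg = 12)
  expect_equal(compare_pair(t2, c2, h),
               list(result = "win", decided_at_level = 3L))
  # all KCCQ levels tie, 6MWD decides (level 6)
  t3 <- make_trial("semaglutide", kccq_chg = 12, sixmwd_chg = 35)
  c3 <- make_trial("placebo", kccq_chg = 11, sixmwd_chg = 10)
  expect_equal(compare_pair(t3, c3, h),
               list(result = "win", decided_at_level = 6L))
  # a missing KCCQ change falls through to the 6MWD level
  t4 <- make_trial("semaglutide", kccq_chg = NA, sixmwd_chg = 35)
  expect_equal(compare_pair(t4, c3, h),
               list(result = "win", decided_at_level = 6L))
})

test_that("hierarchy validation rejects malformed specifications", {
  expect_error(hierarchy_spec(kccq_thresholds = c(5, 10, 15)),
               "strictly decreasing")
  expect_error(hierarchy_spec(kccq_thresholds = c(10, -5)),
               "strictly decreasing")
  expect_error(hierarchy_spec(kccq_thresholds = numeric(0),
                              sixmwd_threshold = NULL,
                              include_death = FALSE,
                              include_hf_events = FALSE),
               "non-empty")
})

test_that("a hand-enumerated 3x3 toy set gives WR = 3", {
  df <- make_trial(arm = rep(c("semaglutide", "placebo"), each = 3),
                   kccq_chg = c(16, 12, 6, -10, 4, 16))
  w <- win_ratio(df, ci_method = "none")
  expect_equal(w$wins, 6)
  expect_equal(w$losses, 2)
  expect_equal(w$ties, 1)
  expect_equal(w$wr, 3)
  expect_equal(unname(w$wins_by_level[c("kccq_ge15", "kccq_ge10", "kccq_ge5")]),
               c(2, 2, 2))
  expect_equal(unname(w$losses_by_level["kccq_ge15"]), 2)
})

test_that("swapping arm labels inverts the win ratio exactly", {
  df <- rand_small_trial(101)
  w1 <- win_ratio(df, ci_method = "none")
  sw <- df
  sw$arm <- factor(ifelse(df$arm == "placebo", "semaglutide", "placebo"),
                   levels = levels(df$arm))
  w2 <- win_ratio(sw, ci_method = "none")
  expect_equal(w1$wins, w2$losses)
  expect_equal(w1$losses, w2$wins)
  expect_equal(w2$wr, 1 / w1$wr)
})

test_that("engine tallies equal the brute-force oracle on random small trials", {
  for (s in 1:40) {
    df <- rand_small_trial(s)
    w <- win_ratio(df, ci_method = "none")
    o <- oracle_tally(df)
    expect_equal(unname(w$wins_by_level), o$wins, info = paste("seed", s))
    expect_equal(unname(w$losses_by_level), o$losses, info = paste("seed", s))
    expect_equal(w$ties, o$ties, info = paste("seed", s))
  }
})

test_that("removing the 6MWD level only converts decisions into ties", {
  for (s in c(7, 19, 23)) {
    df <- rand_small_trial(s)
    full <- win_ratio(df, ci_method = "none")
    no6 <- win_ratio(df, hierarchy_spec(sixmwd_threshold = NULL),
                     ci_method = "none")
    expect_equal(no6$wins, full$wins - unname(full$wins_by_level["sixmwd_ge30"]))
    expect_equal(no6$losses,
                 full$losses - unname(full$losses_by_level["sixmwd_ge30"]))
    expect_gte(no6$ties, full$ties)
  }
})

test_that("an earlier treated death can never increase wins", {
  df <- rand_small_trial(31)
  base <- win_ratio(df, ci_method = "none")
  idx <- which(df$arm == "semaglutide")[1]
  worse <- df
  worse$death_day[idx] <- 10
  worse$observation_days[idx] <- 10
  worse$kccq_week52[idx] <- NA
  worse$sixmwd_week52_m[idx] <- NA
  after <- win_ratio(worse, ci_method = "none")
  expect_lte(after$wins, base$wins)
})

test_that("a single continuous level reproduces the Mann-Whitney win ratio", {
  set.seed(77)
  n1 <- 15; n2 <- 13
  df <- make_trial(arm = c(rep("semaglutide", n1), rep("placebo", n2)),
                   kccq_chg = round(rnorm(n1 + n2, 0, 9), 3))
  h <- structure(list(list(type = "continuous_change", variable = "kccq")),
                 class = "hierarchy_spec")
  w <- win_ratio(df, h, ci_method = "none")
  x <- df$kccq_week52[df$arm == "semaglutide"] -
    df$kccq_baseline[df$arm == "semaglutide"]
  y <- df$kccq_week52[df$arm == "placebo"] -
    df$kccq_baseline[df$arm == "placebo"]
  U <- unname(wilcox.test(x, y)$statistic)  # independent rank-based count
  expect_equal(w$wr, U / (n1 * n2 - U))
})

test_that("null data give a log win ratio near 0 and concordant variances", {
  set.seed(55)
  n <- 80
  df <- make_trial(arm = rep(c("semaglutide", "placebo"), each = n),
                   kccq_chg = rnorm(2 * n, 0, 12),
                   sixmwd_chg = rnorm(2 * n, 0, 40))
  wa <- win_ratio(df, ci_method = "analytic")
  expect_lt(abs(wa$log_wr), 3 * sqrt(wa$log_wr_var))
  wb <- win_ratio(df, ci_method = "bootstrap", B = 400, seed = 3)
  ratio <- sqrt(wb$log_wr_var / wa$log_wr_var)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
  expect_true(wa$ci_low < 1 && wa$ci_high > 1)
})

test_that("bootstrap CIs are deterministic given the seed", {
  df <- rand_small_trial(91)
  w1 <- win_ratio(df, ci_method = "bootstrap", B = 200, seed = 12)
  w2 <- win_ratio(df, ci_method = "bootstrap", B = 200, seed = 12)
  expect_identical(w1$log_wr_var, w2$log_wr_var)
})

test_that("MI win ratio pools on the log scale and guards its inputs", {
  df <- generate_trial(trial_config(n_per_arm = 80, seed = 71,
                                    missing_rate_week52 = 0, death_rate = 0))
  imp <- impute_endpoint(df, c("kccq", "sixmwd"), m = 3, seed = 5)
  wmi <- win_ratio_mi(imp, stratum = "I", ci_method = "analytic")
  single <- win_ratio(df, stratum = "I", ci_method = "analytic")
  expect_equal(wmi$wr, single$wr, tolerance = 1e-10)  # no missing data
  expect_equal(wmi$log_wr_var, single$log_wr_var, tolerance = 1e-10)

  bad <- impute_endpoint(df, c("kccq", "crp"), m = 2, seed = 5)
  expect_error(win_ratio_mi(bad), "pertinent only to KCCQ and 6MWD")
})

test_that("Cochran's Q matches hand arithmetic and guards infinities", {
  mk <- function(lwr, v, s) {
    structure(list(wr = exp(lwr), log_wr = lwr, log_wr_var = v, stratum = s),
              class = "win_ratio")
  }
  same <- list(mk(0.3, 0.2, "I"), mk(0.3, 0.2, "II"), mk(0.3, 0.2, "III"))
  q0 <- cochran_q_winratio(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  two <- list(mk(0, 0.25, "I"), mk(0.5, 0.25, "II"))
  q <- cochran_q_winratio(two)
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1)
  expect_equal(q$p, pchisq(0.5, 1, lower.tail = FALSE))

  inf <- list(mk(0, 0.25, "I"), structure(list(wr = Inf, log_wr = 5,
                                               log_wr_var = 1, stratum = "II"),
                                          class = "win_ratio"))
  expect_error(cochran_q_winratio(inf), "infinite or degenerate")
  expect_error(cochran_q_winratio(same[1]), ">= 2 strata")
})

test_that("zero losses flag an infinite win ratio with a one-sided CI", {
  df <- make_trial(arm = rep(c("semaglutide", "placebo"), each = 3),
                   kccq_chg = c(20, 20, 20, 0, 0, 0))
  w <- win_ratio(df, ci_method = "bootstrap", B = 100, seed = 2)
  expect_true(w$infinite)
  expect_equal(w$wr, Inf)
  expect_equal(w$ci_high, Inf)
  expect_true(is.finite(w$ci_low))
})
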