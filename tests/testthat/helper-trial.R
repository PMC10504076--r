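# Hand-constructed trial datasets and an independent (straight-line, scalar)
# win-ratio oracle used to cross-check the vectorized engine.

make_trial <- function(arm, kccq_chg = 0, sixmwd_chg = 0, death_day = NA,
                       hf_event_days = "", obs = 420, bmi = 33, kccq0 = 60,
                       sixmwd0 = 300, pct_weight = 0, crp_chg = 0,
                       on_treatment = TRUE, id_prefix = "T") {
  n <- length(arm)
  r <- function(x) rep_len(x, n)
  kccq_chg <- r(kccq_chg); sixmwd_chg <- r(sixmwd_chg)
  death_day <- r(death_day); hf_event_days <- r(hf_event_days)
  obs <- r(obs); bmi <- r(bmi); kccq0 <- r(kccq0); sixmwd0 <- r(sixmwd0)
  pct_weight <- r(pct_weight); crp_chg <- r(crp_chg)
  on_treatment <- r(on_treatment)
  height <- 1.7
  w0 <- bmi * height^2
  df <- data.frame(
    participant_id = paste0(id_prefix, seq_len(n)),
    arm = factor(arm, levels = c("placebo", "semaglutide")),
    age = 70, sex = factor("female", levels = c("female", "male")),
    height_m = height, weight_baseline_kg = w0, bmi = bmi,
    kccq_baseline = kccq0, sixmwd_baseline_m = sixmwd0,
    crp_baseline_mg_l = 3, ntprobnp_baseline_pg_ml = 500,
    nyha = factor("II", levels = c("II", "III", "IV")),
    afib = FALSE, cad = FALSE,
    weight_week52_kg = w0 * (1 + pct_weight / 100),
    kccq_week52 = kccq0 + kccq_chg,
    sixmwd_week52_m = sixmwd0 + sixmwd_chg,
    crp_week52_mg_l = exp(log(3) + crp_chg),
    death_day = death_day, hf_event_days = hf_event_days,
    observation_days = obs, on_treatment_at_week52 = on_treatment,
    stringsAsFactors = FALSE)
  class(df) <- c("trial_data", class(df))
  df
}

# independent scalar comparator: plain if/else walk of the default hierarchy
oracle_compare <- function(ti, cj, kccq_th = c(15, 10, 5), sixmwd_th = 30) {
  tau <- min(ti$observation_days, cj$observation_days)
  d1 <- if (is.na(ti$death_day)) Inf else ti$death_day
  d2 <- if (is.na(cj$death_day)) Inf else cj$death_day
  lev <- 1
  if (d1 <= tau || d2 <= tau) {
    if (d1 <= tau && d2 > tau) return(list(res = -1, lev = lev))
    if (d2 <= tau && d1 > tau) return(list(res = 1, lev = lev))
    if (d1 != d2) return(list(res = if (d1 > d2) 1 else -1, lev = lev))
  }
  lev <- 2
  parse_ev <- function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else
      as.numeric(strsplit(s, ";")[[1]])
  }
  e1 <- parse_ev(ti$hf_event_days); e1 <- e1[e1 <= tau]
  e2 <- parse_ev(cj$hf_event_days); e2 <- e2[e2 <= tau]
  if (length(e1) != length(e2)) {
    return(list(res = if (length(e1) < length(e2)) 1 else -1, lev = lev))
  }
  if (length(e1) > 0 && e1[1] != e2[1]) {
    return(list(res = if (e1[1] > e2[1]) 1 else -1, lev = lev))
  }
  k1 <- ti$kccq_week52 - ti$kccq_baseline
  k2 <- cj$kccq_week52 - cj$kccq_baseline
  for (th in kccq_th) {
    lev <- lev + 1
    if (!is.na(k1) && !is.na(k2)) {
      a <- k1 >= th; b <- k2 >= th
      if (a && !b) return(list(res = 1, lev = lev))
      if (b && !a) return(list(res = -1, lev = lev))
    }
  }
  lev <- lev + 1
  s1 <- ti$sixmwd_week52_m - ti$sixmwd_baseline_m
  s2 <- cj$sixmwd_week52_m - cj$sixmwd_baseline_m
  if (!is.na(s1) && !is.na(s2)) {
    a <- s1 >= sixmwd_th; b <- s2 >= sixmwd_th
    if (a && !b) return(list(res = 1, lev = lev))
    if (b && !a) return(list(res = -1, lev = lev))
  }
  list(res = 0, lev = NA)
}

# double-loop per-level tallies from the oracle
oracle_tally <- function(df, n_levels = 6) {
  dt <- df[df$arm == "semaglutide", , drop = FALSE]
  dc <- df[df$arm == "placebo", , drop = FALSE]
  wins <- losses <- integer(n_levels)
  ties <- 0L
  for (i in seq_len(nrow(dt))) {
    for (j in seq_len(nrow(dc))) {
      o <- oracle_compare(dt[i, ], dc[j, ])
      if (o$res == 1) wins[o$lev] <- wins[o$lev] + 1L
      else if (o$res == -1) losses[o$lev] <- losses[o$lev] + 1L
      else ties <- ties + 1L
    }
  }
  list(wins = wins, losses = losses, ties = ties)
}

# random small trial with deaths, HF events and missing week-52 changes
rand_small_trial <- function(seed) {
  set.seed(seed)
  n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
  n <- n1 + n2
  obs <- sample(150:420, n, replace = TRUE)
  dead <- runif(n) < 0.15
  death_day <- ifelse(dead, pmax(1, floor(runif(n) * obs)), NA)
  obs <- ifelse(dead, death_day, obs)
  hf <- vapply(seq_len(n), function(i) {
    k <- rpois(1, 0.5)
    if (k == 0) return("")
    paste(sort(sample(seq_len(obs[i]), min(k, obs[i]))), collapse = ";")
  }, character(1))
  kchg <- ifelse(runif(n) < 0.15 | dead, NA, round(rnorm(n, 0, 12), 1))
  schg <- ifelse(runif(n) < 0.15 | dead, NA, round(rnorm(n, 0, 40), 1))
  make_trial(arm = c(rep("semaglutide", n1), rep("placebo", n2)),
             kccq_chg = kchg, sixmwd_chg = schg, death_day = death_day,
             hf_event_days = hf, obs = obs,
             bmi = round(runif(n, 30, 50), 1))
}
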