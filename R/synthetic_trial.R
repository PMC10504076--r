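#' Configuration for the synthetic trial generator
#'
#' Defines the generative model for a 1:1 randomized weight-loss trial in an
#' obesity phenotype of HFpEF: a three-class BMI mixture (truncated
#' log-normal within class), baseline symptom/function/biomarker outcomes
#' that worsen with BMI, an arm effect on percent body-weight change, and
#' endpoint changes driven partly directly by treatment and partly through
#' each participant's realized weight change (mediation), plus MAR
#' missingness at week 52 and rare death/HF events over follow-up.
#'
#' `treatment_effects` are the *total* target estimated treatment
#' differences (ETDs); the direct arm effect is derived internally as the
#' total minus the component mediated through the expected between-arm
#' difference in weight loss. Each treatment effect may be a scalar
#' (homogeneous) or a length-3 vector (per obesity class) to induce
#' heterogeneity.
#'
#' @param n_per_arm Participants per arm (default 265, i.e. a 530-participant
#'   trial).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @param bmi_class_probs Probabilities of obesity classes I/II/III; must sum
#'   to 1.
#' @param bmi_within_class Per-class truncated log-normal parameters
#'   (`meanlog`, `sdlog`, `lower`, `upper`).
#' @param baseline_levels Mean baseline KCCQ-CSS (points), 6MWD (m) and log
#'   CRP at the reference BMI of 37 kg/m^2.
#' @param baseline_slopes Per-unit-BMI change in mean baseline KCCQ-CSS
#'   (points, negative), 6MWD (m, negative) and log CRP (positive).
#' @param noise_sds Baseline-outcome noise SDs (kccq, sixmwd, log_crp).
#'   KCCQ-CSS and 6MWD noise is symmetric scaled-beta (bounded), keeping
#'   scores in range around an exactly linear conditional mean; log CRP
#'   noise is normal.
#' @param treatment_effects Target total ETDs: `kccq` (points), `weight_pct`
#'   (percent body-weight change, negative = loss), `sixmwd` (m), `log_crp`
#'   (log ratio). Scalars or length-3 per-class vectors.
#' @param mediation_slopes Effect of each 10% of realized individual weight
#'   loss on the endpoint change (points, m, log units); acts in both arms.
#' @param change_noise_sds Residual SDs of the week-52 endpoint changes.
#' @param weight_response_sd SD of individual percent weight change in the
#'   semaglutide arm.
#' @param placebo_weight_sd SD of percent weight change in the placebo arm
#'   (centred at 0).
#' @param missing_rate_week52 Marginal probability that the week-52 visit is
#'   missing (MAR: depends on arm and baseline KCCQ only).
#' @param death_rate,hf_event_rate Events per participant-year.
#' @param discontinuation_rate Probability of being off treatment at week 52,
#'   independent of arm and outcome by default.
#' @param followup_days Administrative censoring time (default 420 days;
#'   week 52 = day 364).
#' @return A `trial_config` object.
#' @export
trial_config <- function(n_per_arm = 265,
                         seed = 1,
                         bmi_class_probs = c(0.34, 0.32, 0.34),
                         bmi_within_class = list(
                           I   = list(meanlog = log(32.5), sdlog = 0.045,
                                      lower = 30, upper = 35),
                           II  = list(meanlog = log(37.2), sdlog = 0.035,
                                      lower = 35, upper = 40),
                           III = list(meanlog = log(43.5), sdlog = 0.090,
                                      lower = 40, upper = 65)),
                         baseline_levels = list(kccq = 57, sixmwd = 323,
                                                log_crp = 1.25),
                         baseline_slopes = list(kccq = -0.8, sixmwd = -6,
                                                log_crp = 0.06),
                         noise_sds = list(kccq = 11, sixmwd = 65,
                                          log_crp = 0.85),
                         treatment_effects = list(kccq = 7.8,
                                                  weight_pct = -10.7,
                                                  sixmwd = 20,
                                                  log_crp = -0.3),
                         mediation_slopes = list(kccq = 6.0, sixmwd = 13.0,
                                                 log_crp = -0.33),
                         change_noise_sds = list(kccq = 14, sixmwd = 65,
                                                 log_crp = 0.8),
                         weight_response_sd = 6.5,
                         placebo_weight_sd = 3.5,
                         missing_rate_week52 = 0.07,
                         death_rate = 0.012,
                         hf_event_rate = 0.05,
                         discontinuation_rate = 0.10,
                         followup_days = 420) {
  cfg <- list(n_per_arm = n_per_arm, seed = seed,
              bmi_class_probs = bmi_class_probs,
              bmi_within_class = bmi_within_class,
              baseline_levels = baseline_levels,
              baseline_slopes = baseline_slopes,
              noise_sds = noise_sds,
              treatment_effects = treatment_effects,
              mediation_slopes = mediation_slopes,
              change_noise_sds = change_noise_sds,
              weight_response_sd = weight_response_sd,
              placebo_weight_sd = placebo_weight_sd,
              missing_rate_week52 = missing_rate_week52,
              death_rate = death_rate,
              hf_event_rate = hf_event_rate,
              discontinuation_rate = discontinuation_rate,
              followup_days = followup_days)
  validate_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_config <- function(cfg) {
  p <- cfg$bmi_class_probs
  if (length(p) != 3 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    stop("bmi_class_probs must be three probabilities summing to 1",
         call. = FALSE)
  }
  if (cfg$n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  for (r in c("missing_rate_week52", "discontinuation_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) {
      stop(r, " must be in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$death_rate < 0 || cfg$hf_event_rate < 0) {
    stop("event rates must be nonnegative", call. = FALSE)
  }
  med <- unlist(cfg$mediation_slopes)
  if (cfg$weight_response_sd == 0 && cfg$placebo_weight_sd == 0 &&
      any(med != 0)) {
    stop(paste("degenerate config: nonzero mediation slopes require",
               "variance in percent weight change"), call. = FALSE)
  }
  sds <- c(unlist(cfg$noise_sds), unlist(cfg$change_noise_sds),
           cfg$weight_response_sd, cfg$placebo_weight_sd)
  if (any(sds < 0)) stop("noise SDs must be nonnegative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic HFpEF weight-loss trial configuration\n")
  cat(sprintf("  n per arm: %d (seed %d)\n", x$n_per_arm, as.integer(x$seed)))
  cat(sprintf("  BMI class probabilities: %s\n",
              paste(format(x$bmi_class_probs), collapse = " / ")))
  te <- x$treatment_effects
  cat(sprintf("  target ETDs: KCCQ %s pts, weight %s%%, 6MWD %s m, logCRP %s\n",
              paste(te$kccq, collapse = "/"),
              paste(te$weight_pct, collapse = "/"),
              paste(te$sixmwd, collapse = "/"),
              paste(te$log_crp, collapse = "/")))
  cat(sprintf("  missingness %.0f%%, discontinuation %.0f%%\n",
              100 * x$missing_rate_week52, 100 * x$discontinuation_rate))
  invisible(x)
}

# truncated normal / log-normal via inverse-CDF
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# calibrate the logistic intercept so the marginal masking probability
# equals `rate` given the linear predictor `lin`
calibrate_logit_intercept <- function(lin, rate) {
  f <- function(a) mean(stats::plogis(a + lin)) - rate
  stats::uniroot(f, c(-30, 30))$root
}

#' Generate a synthetic trial
#'
#' Deterministic given the configuration (including its seed). Participants
#' are randomized 1:1; baseline outcomes vary with BMI per the configured
#' slopes; week-52 outcomes are baseline + direct arm effect + mediation
#' through realized percent weight change + noise; the week-52 visit is set
#' missing with the configured MAR probability; deaths and HF events are
#' exponential/Poisson over follow-up, independent of arm by default.
#'
#' @param config A [trial_config()].
#' @return A `trial_data` data frame with the generator configuration stored
#'   in the `"generator_config"` attribute.
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  validate_config(config)
  cfg <- config
  set.seed(as.integer(cfg$seed))
  n <- 2L * cfg$n_per_arm
  arm <- factor(sample(rep(ARM_LEVELS, each = cfg$n_per_arm)),
                levels = ARM_LEVELS)
  treated <- arm == "semaglutide"
  cls_idx <- sample.int(3L, n, replace = TRUE, prob = cfg$bmi_class_probs)

  bmi <- numeric(n)
  for (k in 1:3) {
    idx <- which(cls_idx == k)
    par <- cfg$bmi_within_class[[k]]
    bmi[idx] <- rtrunc_lnorm(length(idx), par$meanlog, par$sdlog,
                             par$lower, par$upper)
  }
  # demographics: higher class -> younger, more often female, higher NYHA,
  # less coronary disease (Table-1-style trend directions)
  p_female <- c(0.51, 0.52, 0.66)[cls_idx]
  sex <- factor(ifelse(stats::runif(n) < p_female, "female", "male"),
                levels = c("female", "male"))
  height <- ifelse(sex == "female", stats::rnorm(n, 1.63, 0.06),
                   stats::rnorm(n, 1.77, 0.06))
  height <- pmin(pmax(height, 1.40), 2.05)
  weight0 <- bmi * height^2
  age <- rtrunc_norm(n, c(71, 69, 66)[cls_idx], 8, 40, 92)
  p_nyha3 <- c(0.24, 0.30, 0.46)[cls_idx]
  p_nyha4 <- c(0.000, 0.005, 0.005)[cls_idx]
  u <- stats::runif(n)
  nyha <- factor(ifelse(u < p_nyha4, "IV",
                        ifelse(u < p_nyha4 + p_nyha3, "III", "II")),
                 levels = c("II", "III", "IV"))
  afib <- stats::runif(n) < 0.52
  cad <- stats::runif(n) < c(0.44, 0.30, 0.28)[cls_idx]

  b <- bmi - 37
  lv <- cfg$baseline_levels; sl <- cfg$baseline_slopes; ns <- cfg$noise_sds
  # Bounded scores use symmetric scaled-beta noise around an exactly linear
  # mean, so the configured per-BMI slope is the realized conditional slope
  # (truncating a normal would attenuate it) and baseline KCCQ stays below
  # the 90-point eligibility cut.
  rbounded <- function(n, sd) (stats::rbeta(n, 2, 2) - 0.5) * sd * sqrt(20)
  kccq0 <- pmin(pmax(lv$kccq + sl$kccq * b + rbounded(n, ns$kccq), 0), 89.9)
  sixmwd0 <- pmax(lv$sixmwd + sl$sixmwd * b + rbounded(n, ns$sixmwd), 10)
  crp0 <- exp(stats::rnorm(n, lv$log_crp + sl$log_crp * b, ns$log_crp))
  ntprobnp0 <- exp(stats::rnorm(n, 6.15 - 0.03 * b, 1.0))

  # events: exponential death time, Poisson HF events, censored at follow-up
  death_t <- if (cfg$death_rate > 0) {
    stats::rexp(n, rate = cfg$death_rate / 365)
  } else rep(Inf, n)
  obs_days <- pmin(death_t, cfg$followup_days)
  obs_days <- pmax(ceiling(obs_days), 1)
  death_day <- ifelse(death_t <= cfg$followup_days, obs_days, NA_real_)
  hf_events <- character(n)
  n_ev <- stats::rpois(n, cfg$hf_event_rate / 365 * obs_days)
  for (i in which(n_ev > 0)) {
    ev <- sort(unique(pmax(1, ceiling(stats::runif(n_ev[i]) * obs_days[i]))))
    hf_events[i] <- paste(ev, collapse = ";")
  }

  # realized percent weight change and endpoint changes
  te <- lapply(cfg$treatment_effects, rep_len, 3)
  med <- cfg$mediation_slopes
  cns <- cfg$change_noise_sds
  pct <- ifelse(treated,
                stats::rnorm(n, te$weight_pct[cls_idx], cfg$weight_response_sd),
                stats::rnorm(n, 0, cfg$placebo_weight_sd))
  loss10 <- -pct / 10  # units of 10% reduction
  exp_loss_diff <- -te$weight_pct / 10  # expected arm difference in loss10
  direct <- function(total, slope) total - slope * exp_loss_diff
  d_kccq <- direct(te$kccq, med$kccq)[cls_idx]
  d_6mwd <- direct(te$sixmwd, med$sixmwd)[cls_idx]
  d_lcrp <- direct(te$log_crp, med$log_crp)[cls_idx]

  chg_kccq <- d_kccq * treated + med$kccq * loss10 -
    0.25 * (kccq0 - lv$kccq) + stats::rnorm(n, 0, cns$kccq)
  chg_6mwd <- d_6mwd * treated + med$sixmwd * loss10 -
    0.25 * (sixmwd0 - lv$sixmwd) + stats::rnorm(n, 0, cns$sixmwd)
  chg_lcrp <- d_lcrp * treated + med$log_crp * loss10 -
    0.25 * (log(crp0) - lv$log_crp) + stats::rnorm(n, 0, cns$log_crp)

  weight52 <- weight0 * (1 + pct / 100)
  kccq52 <- pmin(100, pmax(0, kccq0 + chg_kccq))
  sixmwd52 <- pmax(0, sixmwd0 + chg_6mwd)
  crp52 <- exp(log(crp0) + chg_lcrp)

  # week-52 visit missing: structurally if dead before week 52, else MAR
  dead_by_w52 <- !is.na(death_day) & death_day <= 364
  miss <- dead_by_w52
  if (cfg$missing_rate_week52 > 0) {
    lin <- -0.3 * treated - 0.02 * (kccq0 - mean(kccq0))
    a <- calibrate_logit_intercept(lin, cfg$missing_rate_week52)
    miss <- miss | stats::runif(n) < stats::plogis(a + lin)
  }
  weight52[miss] <- NA; kccq52[miss] <- NA
  sixmwd52[miss] <- NA; crp52[miss] <- NA

  on_trt <- stats::runif(n) >= cfg$discontinuation_rate & !dead_by_w52

  df <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    arm = arm, age = age, sex = sex, height_m = height,
    weight_baseline_kg = weight0, bmi = bmi,
    kccq_baseline = kccq0, sixmwd_baseline_m = sixmwd0,
    crp_baseline_mg_l = crp0, ntprobnp_baseline_pg_ml = ntprobnp0,
    nyha = nyha, afib = afib, cad = cad,
    weight_week52_kg = weight52, kccq_week52 = kccq52,
    sixmwd_week52_m = sixmwd52, crp_week52_mg_l = crp52,
    death_day = death_day, hf_event_days = hf_events,
    observation_days = obs_days, on_treatment_at_week52 = on_trt,
    stringsAsFactors = FALSE)
  attr(df, "generator_config") <- cfg
  as_trial_data(df)
}

#' Mask week-52 outcomes with a missingness mechanism
#'
#' Masks all week-52 fields (weight, KCCQ-CSS, 6MWD, CRP) of a copy of the
#' dataset. Under MCAR, masking is a coin flip at `rate`; under MAR, the
#' masking probability is a logistic function of arm and baseline KCCQ only,
#' with the intercept calibrated so the marginal rate equals `rate`.
#'
#' @param dataset A `trial_data` data frame.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate Masking probability in \[0, 1).
#' @param seed Integer seed.
#' @return A new `trial_data` data frame; the input is untouched.
#' @export
induce_missingness <- function(dataset, mechanism = c("MCAR", "MAR"),
                               rate, seed = 1) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  df <- dataset
  if (rate == 0) return(df)
  set.seed(as.integer(seed))
  n <- nrow(df)
  if (mechanism == "MCAR") {
    miss <- stats::runif(n) < rate
  } else {
    lin <- -0.3 * (df$arm == "semaglutide") -
      0.03 * (df$kccq_baseline - mean(df$kccq_baseline))
    a <- calibrate_logit_intercept(lin, rate)
    miss <- stats::runif(n) < stats::plogis(a + lin)
  }
  for (col in c("weight_week52_kg", "kccq_week52", "sixmwd_week52_m",
                "crp_week52_mg_l")) {
    df[[col]][miss] <- NA_real_
  }
  df
}
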