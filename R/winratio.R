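#' Hierarchy of the composite endpoint
#'
#' Ordered endpoint levels walked during each treated-vs-control pairwise
#' comparison: all-cause death (earlier death within the pair's shared
#' follow-up loses), HF events (fewer events wins; tie on count broken by
#' later first event), descending KCCQ-CSS improvement thresholds (achieving
#' at least the threshold when the opponent does not wins), and a 6MWD
#' improvement threshold of 30 m.
#'
#' @param kccq_thresholds Strictly decreasing positive KCCQ-CSS improvement
#'   thresholds in points (default `c(15, 10, 5)`).
#' @param sixmwd_threshold 6MWD improvement threshold in meters (default 30);
#'   `NULL` drops the level.
#' @param include_death,include_hf_events Include the death / HF-event
#'   levels (defaults `TRUE`). The death level, when present, is first.
#' @param hf_rule `"count_then_time"` (default) compares event counts and
#'   breaks count ties by later first event; `"time_only"` compares only the
#'   time to first event.
#'
#' @details Custom hierarchies can also be built directly as a list of level
#'   descriptors of class `hierarchy_spec`; besides the level types above, a
#'   `list(type = "continuous_change", variable = ...)` level compares the
#'   raw change scores (greater improvement wins, the Pocock convention for
#'   a single continuous outcome).
#' @return A `hierarchy_spec`: ordered list of level descriptors.
#' @export
hierarchy_spec <- function(kccq_thresholds = c(15, 10, 5),
                           sixmwd_threshold = 30,
                           include_death = TRUE,
                           include_hf_events = TRUE,
                           hf_rule = c("count_then_time", "time_only")) {
  hf_rule <- match.arg(hf_rule)
  if (length(kccq_thresholds)) {
    if (any(kccq_thresholds <= 0) ||
        any(diff(kccq_thresholds) >= 0)) {
      stop("kccq_thresholds must be strictly decreasing and positive",
           call. = FALSE)
    }
  }
  levels <- list()
  if (include_death) levels <- c(levels, list(list(type = "death")))
  if (include_hf_events) {
    levels <- c(levels, list(list(type = "hf_events", rule = hf_rule)))
  }
  for (t in kccq_thresholds) {
    levels <- c(levels, list(list(type = "threshold_change",
                                  variable = "kccq", threshold = t)))
  }
  if (!is.null(sixmwd_threshold)) {
    levels <- c(levels, list(list(type = "threshold_change",
                                  variable = "sixmwd",
                                  threshold = sixmwd_threshold)))
  }
  if (!length(levels)) stop("hierarchy must be non-empty", call. = FALSE)
  structure(levels, class = "hierarchy_spec")
}

level_label <- function(lv) {
  switch(lv$type,
    death = "death",
    hf_events = "hf_events",
    threshold_change = sprintf("%s_ge%g", lv$variable, lv$threshold),
    continuous_change = sprintf("%s_change", lv$variable))
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat("Composite endpoint hierarchy:\n")
  for (i in seq_along(x)) cat(sprintf("  L%d: %s\n", i, level_label(x[[i]])))
  invisible(x)
}

# Sign matrix (+1 treated wins, -1 loses, 0 undecided) for one level over all
# treated x control pairs; `tau` is the matrix of shared follow-up times.
level_sign_matrix <- function(lv, dt, dc, tau) {
  n1 <- nrow(dt); n2 <- nrow(dc)
  M <- matrix(0, n1, n2)
  if (lv$type == "death") {
    d1 <- ifelse(is.na(dt$death_day), Inf, dt$death_day)
    d2 <- ifelse(is.na(dc$death_day), Inf, dc$death_day)
    D1 <- matrix(d1, n1, n2)
    D2 <- matrix(d2, n1, n2, byrow = TRUE)
    in1 <- D1 <= tau; in2 <- D2 <= tau
    M[in1 & !in2] <- -1
    M[!in1 & in2] <- 1
    both <- in1 & in2
    M[both] <- sign(D1 - D2)[both]  # later death wins
  } else if (lv$type == "hf_events") {
    ev1 <- parse_event_days(dt$hf_event_days)
    ev2 <- parse_event_days(dc$hf_event_days)
    cnt1 <- matrix(0, n1, n2); f1 <- matrix(Inf, n1, n2)
    for (i in seq_len(n1)) {
      e <- ev1[[i]]
      if (length(e)) {
        cnt1[i, ] <- findInterval(tau[i, ], e)
        f1[i, ] <- ifelse(cnt1[i, ] > 0, e[1], Inf)
      }
    }
    cnt2 <- matrix(0, n1, n2); f2 <- matrix(Inf, n1, n2)
    for (j in seq_len(n2)) {
      e <- ev2[[j]]
      if (length(e)) {
        cnt2[, j] <- findInterval(tau[, j], e)
        f2[, j] <- ifelse(cnt2[, j] > 0, e[1], Inf)
      }
    }
    if (lv$rule == "time_only") {
      t1 <- ifelse(cnt1 > 0, f1, Inf); t2 <- ifelse(cnt2 > 0, f2, Inf)
      fin <- is.finite(t1) | is.finite(t2)
      M[fin] <- sign(pmin(t1, 1e12) - pmin(t2, 1e12))[fin]  # later first wins
    } else {
      M <- sign(cnt2 - cnt1)  # fewer events wins
      tie <- M == 0 & cnt1 > 0
      M[tie] <- sign(f1 - f2)[tie]  # later first event wins
    }
  } else if (lv$type == "continuous_change") {
    ch1 <- endpoint_change(dt, lv$variable)
    ch2 <- endpoint_change(dc, lv$variable)
    d <- matrix(ch1, n1, n2) - matrix(ch2, n1, n2, byrow = TRUE)
    d[is.na(d)] <- 0
    M <- sign(d)
  } else {
    ch1 <- endpoint_change(dt, lv$variable)
    ch2 <- endpoint_change(dc, lv$variable)
    a1 <- matrix(as.numeric(ch1 >= lv$threshold), n1, n2)
    a2 <- matrix(as.numeric(ch2 >= lv$threshold), n1, n2, byrow = TRUE)
    d <- a1 - a2
    d[is.na(d)] <- 0  # a missing change cannot decide this level
    M <- sign(d)
  }
  M
}

# Walk the hierarchy over all treated x control pairs. Returns the decision
# matrix (+1/-1/0) and the level index that decided each pair (NA = tie).
win_matrix <- function(dt, dc, hierarchy) {
  n1 <- nrow(dt); n2 <- nrow(dc)
  tau <- outer(dt$observation_days, dc$observation_days, pmin)
  res <- matrix(0, n1, n2)
  lev <- matrix(NA_integer_, n1, n2)
  for (L in seq_along(hierarchy)) {
    M <- level_sign_matrix(hierarchy[[L]], dt, dc, tau)
    upd <- res == 0 & M != 0
    res[upd] <- M[upd]
    lev[upd] <- L
  }
  list(res = res, lev = lev)
}

#' Compare one treated-control pair through the hierarchy
#'
#' Walks the hierarchy levels in order; the first level producing a strict
#' preference decides the pair. Fatal and HF-event levels are compared over
#' the pair's shared follow-up window; a missing KCCQ/6MWD change means that
#' level cannot decide and falls through.
#'
#' @param treated,control Single-row `trial_data` data frames (one
#'   participant each).
#' @param hierarchy A [hierarchy_spec()].
#' @return List with `result` (`"win"`, `"loss"` or `"tie"`, from the treated
#'   participant's perspective) and `decided_at_level` (level index, `NA` for
#'   a tie).
#' @export
compare_pair <- function(treated, control, hierarchy = hierarchy_spec()) {
  wm <- win_matrix(treated, control, hierarchy)
  r <- wm$res[1, 1]
  list(result = c("loss", "tie", "win")[r + 2],
       decided_at_level = wm$lev[1, 1])
}

#' Win ratio of the hierarchical composite endpoint
#'
#' Evaluates all treated x control pairs in the stratum through the
#' hierarchy and tallies wins, losses and ties per level. The win ratio is
#' wins over losses ("the proportion of winners randomized to semaglutide
#' divided by the winners randomized to placebo"); its CI is computed on the
#' log scale from a within-arm participant bootstrap (default, B resamples)
#' or from a large-sample U-statistic projection variance
#' (`ci_method = "analytic"`).
#'
#' @param dataset A `trial_data` data frame.
#' @param hierarchy A [hierarchy_spec()].
#' @param stratum `"overall"` or an obesity class `"I"`, `"II"`, `"III"`.
#' @param ci_method `"bootstrap"`, `"analytic"` or `"none"`.
#' @param B Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A `win_ratio` object: tallies (total and per level), `wr`,
#'   `log_wr_var`, CI and method. With zero losses the ratio is flagged
#'   infinite and only a lower confidence bound is reported.
#' @export
win_ratio <- function(dataset, hierarchy = hierarchy_spec(),
                      stratum = "overall",
                      ci_method = c("bootstrap", "analytic", "none"),
                      B = 2000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  df <- dataset
  if (stratum != "overall") {
    if (!stratum %in% BMI_CLASS_LEVELS) {
      stop("stratum must be 'overall' or one of I/II/III", call. = FALSE)
    }
    df <- df[assign_bmi_class(df$bmi) == stratum, , drop = FALSE]
  }
  dt <- df[df$arm == "semaglutide", , drop = FALSE]
  dc <- df[df$arm == "placebo", , drop = FALSE]
  if (nrow(dt) == 0 || nrow(dc) == 0) {
    stop("stratum '", stratum, "' has an empty arm", call. = FALSE)
  }
  wm <- win_matrix(dt, dc, hierarchy)
  res <- wm$res
  n1 <- nrow(dt); n2 <- nrow(dc)
  labels <- vapply(hierarchy, level_label, character(1))
  wins_by_level <- losses_by_level <- stats::setNames(integer(length(labels)),
                                                      labels)
  for (L in seq_along(hierarchy)) {
    wins_by_level[L] <- sum(res == 1 & wm$lev == L, na.rm = TRUE)
    losses_by_level[L] <- sum(res == -1 & wm$lev == L, na.rm = TRUE)
  }
  wins <- sum(res == 1); losses <- sum(res == -1)
  ties <- n1 * n2 - wins - losses
  infinite <- losses == 0
  wr <- if (infinite) Inf else wins / losses
  log_wr <- if (wins > 0 && losses > 0) log(wr) else
    log((wins + 0.5) / (losses + 0.5))

  log_wr_var <- NA_real_
  if (ci_method == "analytic") {
    log_wr_var <- wr_projection_var(res)
  } else if (ci_method == "bootstrap") {
    set.seed(as.integer(seed))
    lwr_b <- numeric(B)
    for (b in seq_len(B)) {
      sub <- res[sample.int(n1, replace = TRUE),
                 sample.int(n2, replace = TRUE), drop = FALSE]
      w <- sum(sub == 1); l <- sum(sub == -1)
      cc <- 0.5 * (w == 0 || l == 0)
      lwr_b[b] <- log((w + cc) / (l + cc))
    }
    log_wr_var <- stats::var(lwr_b)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- ci_high <- NA_real_
  if (!is.na(log_wr_var)) {
    ci_low <- exp(log_wr - z * sqrt(log_wr_var))
    ci_high <- if (infinite) Inf else exp(log_wr + z * sqrt(log_wr_var))
  }
  structure(list(stratum = stratum, n_treated = n1, n_control = n2,
                 wins = wins, losses = losses, ties = ties,
                 wins_by_level = wins_by_level,
                 losses_by_level = losses_by_level,
                 wr = wr, log_wr = log_wr, log_wr_var = log_wr_var,
                 ci_low = ci_low, ci_high = ci_high, infinite = infinite,
                 method = ci_method, B = B, conf_level = conf_level,
                 hierarchy = hierarchy),
            class = "win_ratio")
}

# Large-sample variance of log(win ratio) by U-statistic projection: the
# win/loss proportions are two-sample U-statistics; their asymptotic
# (co)variance is estimated from the per-participant win/loss profiles and
# mapped to the log ratio by the delta method.
wr_projection_var <- function(res) {
  n1 <- nrow(res); n2 <- ncol(res)
  Wm <- res == 1; Lm <- res == -1
  th_w <- mean(Wm); th_l <- mean(Lm)
  if (th_w == 0 || th_l == 0) return(NA_real_)
  a <- rowMeans(Wm); b <- colMeans(Wm)
  cc <- rowMeans(Lm); d <- colMeans(Lm)
  v_w <- stats::var(a) / n1 + stats::var(b) / n2
  v_l <- stats::var(cc) / n1 + stats::var(d) / n2
  cv <- stats::cov(a, cc) / n1 + stats::cov(b, d) / n2
  v_w / th_w^2 + v_l / th_l^2 - 2 * cv / (th_w * th_l)
}

#' @export
print.win_ratio <- function(x, digits = 3, ...) {
  cat(sprintf("Win ratio, stratum %s (%d treated x %d control pairs)\n",
              x$stratum, x$n_treated, x$n_control))
  cat(sprintf("  wins %d, losses %d, ties %d\n", x$wins, x$losses, x$ties))
  wrtxt <- if (is.finite(x$wr)) sprintf("%.*g", digits, x$wr) else "Inf"
  cat(sprintf("  WR = %s, %.0f%% CI [%.*g, %.*g]  (%s)\n", wrtxt,
              100 * x$conf_level, digits, x$ci_low, digits, x$ci_high,
              x$method))
  lv <- data.frame(level = names(x$wins_by_level), wins = x$wins_by_level,
                   losses = x$losses_by_level, row.names = NULL)
  print(lv)
  invisible(x)
}

#' Multiply-imputed win ratio
#'
#' Per-imputation log win ratios and their variances are pooled by Rubin's
#' rules on the log scale and exponentiated. Imputations may complete only
#' the KCCQ-CSS and 6MWD components; death and HF events are never imputed.
#' Reported tallies are the averages over imputations.
#'
#' @param imputation_set An [impute_endpoint()] result whose endpoints are a
#'   subset of `{"kccq", "sixmwd"}`.
#' @inheritParams win_ratio
#' @return A `win_ratio` object (class also `win_ratio_mi`) with pooled
#'   `wr`, `log_wr_var`, CI, and `m`.
#' @export
win_ratio_mi <- function(imputation_set, hierarchy = hierarchy_spec(),
                         stratum = "overall",
                         ci_method = c("bootstrap", "analytic"),
                         B = 2000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(imputation_set, "imputation_set"))
  extra <- setdiff(imputation_set$endpoint, c("kccq", "sixmwd"))
  if (length(extra)) {
    stop("win-ratio imputations must be pertinent only to KCCQ and 6MWD; ",
         "found: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  m <- imputation_set$m
  per <- lapply(seq_len(m), function(i) {
    win_ratio(imputation_set$completed[[i]], hierarchy, stratum,
              ci_method = ci_method, B = B, seed = seed + i,
              conf_level = conf_level)
  })
  lwr <- vapply(per, function(w) w$log_wr, numeric(1))
  v <- vapply(per, function(w) w$log_wr_var, numeric(1))
  pl <- rubin_pool(lwr, v, conf_level = conf_level)
  avg <- function(f) mean(vapply(per, f, numeric(1)))
  wins_by_level <- rowMeans(vapply(per, function(w) w$wins_by_level,
                                   numeric(length(per[[1]]$wins_by_level))))
  losses_by_level <- rowMeans(vapply(per, function(w) w$losses_by_level,
                                     numeric(length(per[[1]]$losses_by_level))))
  structure(list(stratum = stratum, n_treated = per[[1]]$n_treated,
                 n_control = per[[1]]$n_control,
                 wins = avg(function(w) w$wins),
                 losses = avg(function(w) w$losses),
                 ties = avg(function(w) w$ties),
                 wins_by_level = wins_by_level,
                 losses_by_level = losses_by_level,
                 wr = exp(pl$theta_bar), log_wr = pl$theta_bar,
                 log_wr_var = pl$T, ci_low = exp(pl$ci_low),
                 ci_high = exp(pl$ci_high), infinite = FALSE,
                 method = paste0(ci_method, " + Rubin"), B = B,
                 conf_level = conf_level, hierarchy = hierarchy, m = m,
                 pooled = pl),
            class = c("win_ratio_mi", "win_ratio"))
}

#' Cochran's Q test of equality of win ratios across strata
#'
#' Inverse-variance-weighted chi-square test on the log scale: with weights
#' `w_k = 1 / var(log WR_k)`, `Q` is the weighted sum of squared deviations
#' of the stratum log win ratios from their weighted mean, compared to a
#' chi-square with K - 1 degrees of freedom.
#'
#' @param results List of [win_ratio()] results (>= 2 strata, all finite with
#'   positive log-scale variance).
#' @return A `cochran_q` object with `Q`, `df`, `p` and the pooled log win
#'   ratio.
#' @export
cochran_q_winratio <- function(results) {
  if (length(results) < 2) stop("need >= 2 strata", call. = FALSE)
  wr <- vapply(results, function(r) r$wr, numeric(1))
  lwr <- vapply(results, function(r) r$log_wr, numeric(1))
  v <- vapply(results, function(r) r$log_wr_var, numeric(1))
  if (any(!is.finite(wr)) || any(wr <= 0)) {
    stop(paste("infinite or degenerate win ratio in a stratum; Cochran's Q",
               "requires finite ratios (consider a continuity-corrected",
               "reanalysis of the offending stratum)"), call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all strata need a positive log-scale variance", call. = FALSE)
  }
  w <- 1 / v
  pooled <- sum(w * lwr) / sum(w)
  Q <- sum(w * (lwr - pooled)^2)
  df <- length(results) - 1
  structure(list(Q = Q, df = df,
                 p = stats::pchisq(Q, df, lower.tail = FALSE),
                 pooled_log_wr = pooled,
                 strata = vapply(results, function(r) r$stratum,
                                 character(1))),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf("Cochran's Q for equality of win ratios: Q = %.4g on %d df, p = %.3g\n",
              x$Q, x$df, x$p))
  cat(sprintf("  pooled WR = %.3g over strata %s\n", exp(x$pooled_log_wr),
              paste(x$strata, collapse = ", ")))
  invisible(x)
}
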