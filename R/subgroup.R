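#' Fit the subgroup ANCOVA to a completed dataset
#'
#' Linear model of the week-52 change score on treatment, obesity class,
#' their interaction and the baseline value of the endpoint ("the relevant
#' continuous baseline variable"). CRP is analyzed as the change in log CRP;
#' body weight as percent change. With a single obesity class present the
#' model collapses to a two-group ANCOVA and no interaction is reported.
#'
#' @param dataset A `trial_data` data frame with no missing change scores for
#'   the endpoint (post-imputation completed dataset or a complete-case
#'   subset).
#' @param endpoint One of `"kccq"`, `"weight"`, `"sixmwd"`, `"crp"`.
#' @return An `ancova_fit`: the `lm` fit plus per-class estimated treatment
#'   differences (ETD, semaglutide minus placebo) with variances, and the
#'   interaction contrast (estimates, covariance, F-test).
#' @export
fit_ancova <- function(dataset, endpoint) {
  df <- dataset
  chg <- endpoint_change(df, endpoint)
  if (anyNA(chg)) {
    stop("endpoint '", endpoint,
         "' has missing change scores; impute or restrict to complete cases",
         call. = FALSE)
  }
  cls <- factor(as.character(assign_bmi_class(df$bmi)),
                levels = BMI_CLASS_LEVELS)
  cls <- droplevels(cls)
  cells <- table(df$arm, cls)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: arm %s x class %s", rownames(cells)[idx[1]],
                 colnames(cells)[idx[2]]), call. = FALSE)
  }
  mf <- data.frame(.chg = chg, arm = df$arm, bmi_class = cls,
                   .base = endpoint_baseline(df, endpoint))
  n_cls <- nlevels(cls)
  fml <- if (n_cls > 1) .chg ~ arm * bmi_class + .base else .chg ~ arm + .base
  fit <- stats::lm(fml, data = mf)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  cn <- names(beta)
  arm_term <- "armsemaglutide"
  classes <- levels(cls)
  etd <- data.frame(subgroup = classes, est = NA_real_, var = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(classes)) {
    cvec <- stats::setNames(numeric(length(beta)), cn)
    cvec[arm_term] <- 1
    inter <- paste0(arm_term, ":bmi_class", classes[j])
    if (inter %in% cn) cvec[inter] <- 1
    etd$est[j] <- sum(cvec * beta)
    etd$var[j] <- drop(t(cvec) %*% V %*% cvec)
  }
  interaction <- NULL
  if (n_cls > 1) {
    inames <- paste0(arm_term, ":bmi_class", classes[-1])
    q <- beta[inames]
    Vq <- V[inames, inames, drop = FALSE]
    k <- length(q)
    fstat <- drop(t(q) %*% solve(Vq) %*% q) / k
    df2 <- stats::df.residual(fit)
    interaction <- list(q = q, V = Vq, f = fstat, df1 = k, df2 = df2,
                        p = stats::pf(fstat, k, df2, lower.tail = FALSE))
  }
  structure(list(fit = fit, endpoint = endpoint, classes = classes,
                 etd = etd, interaction = interaction,
                 df_residual = stats::df.residual(fit), n = nrow(df)),
            class = "ancova_fit")
}

make_subgroup_effects <- function(tab, interaction, endpoint, estimand, m) {
  structure(list(table = tab, interaction = interaction, endpoint = endpoint,
                 estimand = estimand, m = m,
                 scale = if (endpoint_is_log(endpoint)) "ratio" else
                   "difference"),
            class = "subgroup_effects")
}

# exponentiate ETD/CI columns for log-scale endpoints (CRP ratios)
to_report_scale <- function(tab, endpoint) {
  if (endpoint_is_log(endpoint)) {
    tab$etd <- exp(tab$etd)
    tab$ci_low <- exp(tab$ci_low)
    tab$ci_high <- exp(tab$ci_high)
  }
  tab
}

#' Intention-to-treat subgroup ETDs under multiple imputation
#'
#' Per-imputation within-class ETDs and their variances are combined by
#' Rubin's rules; the treatment-by-class interaction is combined by pooling
#' the joint interaction-contrast vector across imputations (multivariate
#' Rubin combination, the D1 statistic) and reported as an F-test with
#' numerator degrees of freedom equal to the number of classes minus one.
#' For CRP, ETDs and CIs are exponentiated to ratios.
#'
#' @param imputation_set An [impute_endpoint()] result covering `endpoint`.
#' @param endpoint Endpoint name.
#' @return A `subgroup_effects` object: per-class ETD table (estimate, SE on
#'   the analysis scale, CI, p) and the interaction test.
#' @export
subgroup_etds_mi <- function(imputation_set, endpoint) {
  stopifnot(inherits(imputation_set, "imputation_set"))
  if (!endpoint %in% imputation_set$endpoint) {
    stop("imputation set does not cover endpoint '", endpoint, "'",
         call. = FALSE)
  }
  fits <- lapply(imputation_set$completed, fit_ancova, endpoint = endpoint)
  classes <- fits[[1]]$classes
  m <- length(fits)
  rows <- lapply(seq_along(classes), function(j) {
    est <- vapply(fits, function(f) f$etd$est[j], numeric(1))
    v <- vapply(fits, function(f) f$etd$var[j], numeric(1))
    pl <- rubin_pool(est, v)
    data.frame(subgroup = classes[j], etd = pl$theta_bar, se = sqrt(pl$T),
               ci_low = pl$ci_low, ci_high = pl$ci_high, p = pl$p,
               stringsAsFactors = FALSE)
  })
  tab <- to_report_scale(do.call(rbind, rows), endpoint)
  interaction <- NULL
  if (!is.null(fits[[1]]$interaction)) {
    Q <- do.call(rbind, lapply(fits, function(f) f$interaction$q))
    U <- lapply(fits, function(f) f$interaction$V)
    d1 <- rubin_pool_mv(Q, U)
    interaction <- list(f_stat = d1$f, df_num = d1$df1, df_den = d1$df2,
                        p = d1$p)
  }
  make_subgroup_effects(tab, interaction, endpoint,
                        "intention-to-treat (multiple imputation)", m)
}

#' On-treatment subgroup ETDs (complete case)
#'
#' Complete-case ANCOVA restricted to participants on randomized treatment
#' at week 52 with an observed week-52 endpoint; same contrast structure as
#' the intention-to-treat analysis, with t-based within-class tests and the
#' interaction F-test from the single fit.
#'
#' @param dataset A `trial_data` data frame with `on_treatment_at_week52`.
#' @param endpoint Endpoint name.
#' @return A `subgroup_effects` object.
#' @export
subgroup_etds_on_treatment <- function(dataset, endpoint) {
  df <- dataset
  keep <- df$on_treatment_at_week52 & !is.na(endpoint_change(df, endpoint))
  fit <- fit_ancova(df[keep, , drop = FALSE], endpoint)
  dfree <- fit$df_residual
  tab <- fit$etd
  tab$se <- sqrt(tab$var)
  half <- stats::qt(0.975, dfree) * tab$se
  tab <- data.frame(subgroup = tab$subgroup, etd = tab$est, se = tab$se,
                    ci_low = tab$est - half, ci_high = tab$est + half,
                    p = 2 * stats::pt(-abs(tab$est / tab$se), dfree),
                    stringsAsFactors = FALSE)
  tab <- to_report_scale(tab, endpoint)
  interaction <- NULL
  if (!is.null(fit$interaction)) {
    interaction <- list(f_stat = fit$interaction$f,
                        df_num = fit$interaction$df1,
                        df_den = fit$interaction$df2, p = fit$interaction$p)
  }
  make_subgroup_effects(tab, interaction, endpoint, "on-treatment", 1L)
}

#' @export
print.subgroup_effects <- function(x, digits = 3, ...) {
  cat(sprintf("Treatment effect by obesity class - %s endpoint (%s)\n",
              x$endpoint, x$estimand))
  lab <- if (x$scale == "ratio") "ratio" else "ETD"
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  class %-3s %s %8.*g  [%.*g, %.*g]  p = %.3g\n",
                tab$subgroup[i], lab, digits, tab$etd[i], digits,
                tab$ci_low[i], digits, tab$ci_high[i], tab$p[i]))
  }
  if (!is.null(x$interaction)) {
    cat(sprintf("  interaction F = %.3g on (%d, %.4g) df, p = %.3g\n",
                x$interaction$f_stat, x$interaction$df_num,
                x$interaction$df_den, x$interaction$p))
  }
  invisible(x)
}

#' Adverse-event rate per 100 patient-years
#'
#' @param n_events Number of events.
#' @param person_years Total exposure in patient-years (> 0).
#' @return Rate per 100 patient-years, `100 * n_events / person_years`.
#' @examples
#' adverse_event_rate(5, 250)  # 2 per 100 patient-years
#' @export
adverse_event_rate <- function(n_events, person_years) {
  if (any(person_years <= 0)) {
    stop("person_years must be strictly positive", call. = FALSE)
  }
  100 * n_events / person_years
}
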