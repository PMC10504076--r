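# Design frame for the dose-response regressions (semaglutide arm only).
# Model 1 adjusts for baseline weight and the baseline endpoint (log CRP for
# the CRP endpoint); Model 2 additionally for age, sex, atrial fibrillation,
# coronary artery disease, NYHA class, log CRP and log NTproBNP.
dr_frame <- function(df, endpoint, model) {
  if (any(df$crp_baseline_mg_l <= 0, na.rm = TRUE)) {
    stop("non-positive CRP value", call. = FALSE)
  }
  out <- data.frame(
    .chg = endpoint_change(df, endpoint),
    .pct = percent_weight_change(df$weight_baseline_kg, df$weight_week52_kg),
    .wt0 = df$weight_baseline_kg,
    .base = endpoint_baseline(df, endpoint))
  if (model == "model2") {
    out$.age <- df$age
    out$.sex <- df$sex
    out$.afib <- df$afib
    out$.cad <- df$cad
    out$.nyha <- factor(as.character(df$nyha), levels = c("II", "III", "IV"))
    out$.lcrp <- log(df$crp_baseline_mg_l)
    out$.lntp <- log(df$ntprobnp_baseline_pg_ml)
    if (endpoint == "crp") out$.lcrp <- NULL  # already the baseline endpoint
  }
  out
}

dr_formula <- function(frame) {
  covs <- setdiff(names(frame), c(".chg", ".pct"))
  drop <- vapply(frame[covs], function(x) is.factor(x) &&
                   nlevels(droplevels(x)) < 2, logical(1))
  covs <- covs[!drop]
  stats::as.formula(paste(".chg ~ .pct +", paste(covs, collapse = " + ")))
}

# single complete-data fit: slope of change on percent weight change,
# rescaled to per-10%-decrease (sign flip applied at reporting)
dr_fit_one <- function(df, endpoint, model) {
  frame <- dr_frame(df, endpoint, model)
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  if (nrow(frame) < 10) stop("too few complete records", call. = FALSE)
  fit <- stats::lm(dr_formula(frame), data = frame)
  b <- unname(stats::coef(fit)[".pct"])
  if (is.na(b)) stop("percent weight change is aliased in the design",
                     call. = FALSE)
  v <- stats::vcov(fit)[".pct", ".pct"]
  list(est = -10 * b, var = 100 * v, df = stats::df.residual(fit),
       n = nrow(frame), fit = fit)
}

new_regression_fit <- function(endpoint, model, slope, ci_low, ci_high, p,
                               n_used, per, scale, m = 1L) {
  structure(list(endpoint = endpoint, model = model,
                 slope_per_10pct = slope, ci_low = ci_low, ci_high = ci_high,
                 p = p, n_used = n_used, per = per, scale = scale, m = m),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, digits = 3, ...) {
  lab <- if (x$scale == "ratio") "ratio" else "slope"
  cat(sprintf("%s endpoint, %s: %s %.*g [%.*g, %.*g] per %s, p = %.3g (n = %d)\n",
              x$endpoint, x$model, lab, digits, x$slope_per_10pct, digits,
              x$ci_low, digits, x$ci_high, x$per, x$p, x$n_used))
  invisible(x)
}

#' Weight-loss dose-response regression within the semaglutide arm
#'
#' Linear regression of the week-52 endpoint change (log scale for CRP) on
#' percent weight change among semaglutide-treated participants, adjusted
#' for the Model 1 or Model 2 covariate set. The slope is reported per 10%
#' *decrease* in body weight (positive slope = improvement with more loss);
#' the CRP slope is exponentiated to a multiplicative ratio. With an
#' imputation set, per-imputation slopes are pooled by Rubin's rules.
#'
#' @param x A `trial_data` data frame (complete-case analysis) or an
#'   [impute_endpoint()] result covering the endpoint and `"weight"`.
#' @param endpoint `"kccq"`, `"sixmwd"` or `"crp"`.
#' @param model `"model1"` (baseline weight + baseline endpoint) or
#'   `"model2"` (additionally age, sex, atrial fibrillation, coronary artery
#'   disease, NYHA class, log CRP, log NTproBNP).
#' @return A `regression_fit` with `slope_per_10pct`, CI, p and `n_used`.
#' @export
fit_dose_response <- function(x, endpoint, model = c("model1", "model2")) {
  model <- match.arg(model)
  if (!endpoint %in% c("kccq", "sixmwd", "crp")) {
    stop("endpoint must be one of kccq, sixmwd, crp", call. = FALSE)
  }
  if (inherits(x, "imputation_set")) {
    need <- c(endpoint, "weight")
    if (!all(need %in% x$endpoint)) {
      stop("imputation set must cover the endpoint and weight", call. = FALSE)
    }
    fits <- lapply(x$completed, function(df) {
      dr_fit_one(df[df$arm == "semaglutide", , drop = FALSE], endpoint, model)
    })
    pl <- rubin_pool(vapply(fits, `[[`, numeric(1), "est"),
                     vapply(fits, `[[`, numeric(1), "var"))
    est <- pl$theta_bar; lo <- pl$ci_low; hi <- pl$ci_high; p <- pl$p
    n <- fits[[1]]$n; m <- length(fits)
  } else {
    sem <- x[x$arm == "semaglutide", , drop = FALSE]
    if (nrow(sem) == 0) stop("no semaglutide-arm records", call. = FALSE)
    f <- dr_fit_one(sem, endpoint, model)
    se <- sqrt(f$var)
    half <- stats::qt(0.975, f$df) * se
    est <- f$est; lo <- est - half; hi <- est + half
    p <- 2 * stats::pt(-abs(est / se), f$df)
    n <- f$n; m <- 1L
  }
  if (endpoint_is_log(endpoint)) {
    new_regression_fit(endpoint, model, exp(est), exp(lo), exp(hi), p, n,
                       "10% weight decrease", "ratio", m)
  } else {
    new_regression_fit(endpoint, model, est, lo, hi, p, n,
                       "10% weight decrease", "difference", m)
  }
}

#' Convert a multiplicative ratio to a percent decrease
#'
#' `100 * (1 - ratio)`; a confidence interval maps through the same
#' monotone decreasing transform with its bounds swapped, so a ratio of
#' 0.72 (0.63, 0.84) becomes a 28 (16, 37) percent decrease.
#'
#' @param ratio Positive ratio (e.g. a CRP ratio per 10% weight decrease).
#' @param ci_low,ci_high Optional confidence bounds of the ratio.
#' @return The percent decrease; with bounds, a named vector
#'   `c(estimate, ci_low, ci_high)`.
#' @examples
#' ratio_to_percent_decrease(0.72, 0.63, 0.84)
#' @export
ratio_to_percent_decrease <- function(ratio, ci_low = NULL, ci_high = NULL) {
  if (any(ratio <= 0)) stop("ratio must be strictly positive", call. = FALSE)
  est <- 100 * (1 - ratio)
  if (is.null(ci_low) && is.null(ci_high)) return(est)
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    stop("ratio CI bounds must be strictly positive", call. = FALSE)
  }
  c(estimate = est, ci_low = 100 * (1 - ci_high),
    ci_high = 100 * (1 - ci_low))
}

#' Ordinal weight-loss category analysis with linearity F-test
#'
#' Adjusted mean endpoint changes per weight-loss category (<5%, 5-<10%,
#' 10-<15%, 15-<20%, >=20%; Model 1 covariates, semaglutide arm), evaluated
#' at the covariate sample means, plus a single-degree-of-freedom linear
#' contrast over the category scores 1..5 reported as an F-test. Empty
#' categories are dropped with a warning and the contrast uses the remaining
#' scores. With an imputation set, category membership is recomputed per
#' imputation from the imputed weights and estimates are pooled by Rubin's
#' rules.
#'
#' @param x A `trial_data` data frame or an [impute_endpoint()] result
#'   covering the endpoint and `"weight"`.
#' @param endpoint `"kccq"`, `"sixmwd"` or `"crp"`.
#' @return An `ordinal_trend_fit`: per-category adjusted means with CIs and
#'   `linearity_f`, `linearity_p`.
#' @export
fit_ordinal_categories <- function(x, endpoint) {
  if (inherits(x, "imputation_set")) {
    need <- c(endpoint, "weight")
    if (!all(need %in% x$endpoint)) {
      stop("imputation set must cover the endpoint and weight", call. = FALSE)
    }
    per <- lapply(x$completed, function(df) {
      ordinal_fit_one(df[df$arm == "semaglutide", , drop = FALSE], endpoint)
    })
    cats <- per[[1]]$table$category
    rows <- lapply(seq_along(cats), function(j) {
      est <- vapply(per, function(f) f$table$mean[j], numeric(1))
      v <- vapply(per, function(f) f$table$var[j], numeric(1))
      pl <- rubin_pool(est, v)
      data.frame(category = cats[j], n = round(mean(vapply(
        per, function(f) f$table$n[j], numeric(1)))),
        mean = pl$theta_bar, ci_low = pl$ci_low, ci_high = pl$ci_high)
    })
    tab <- do.call(rbind, rows)
    cpl <- rubin_pool(vapply(per, `[[`, numeric(1), "contrast_est"),
                      vapply(per, `[[`, numeric(1), "contrast_var"))
    fstat <- (cpl$theta_bar / sqrt(cpl$T))^2
    p <- cpl$p
    df2 <- cpl$df
  } else {
    sem <- x[x$arm == "semaglutide", , drop = FALSE]
    f <- ordinal_fit_one(sem, endpoint)
    tab <- f$table
    half <- stats::qt(0.975, f$df_residual) * sqrt(tab$var)
    tab$ci_low <- tab$mean - half
    tab$ci_high <- tab$mean + half
    tab$var <- NULL
    fstat <- f$contrast_est^2 / f$contrast_var
    df2 <- f$df_residual
    p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  }
  structure(list(table = tab, linearity_f = fstat, linearity_df = c(1, df2),
                 linearity_p = p, endpoint = endpoint),
            class = "ordinal_trend_fit")
}

ordinal_fit_one <- function(sem, endpoint) {
  frame <- dr_frame(sem, endpoint, "model1")
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  if (nrow(frame) == 0) stop("no complete semaglutide-arm records",
                             call. = FALSE)
  cat5 <- weight_loss_category(frame$.pct)
  present <- levels(cat5)[levels(cat5) %in% unique(as.character(cat5))]
  if (length(present) < length(levels(cat5))) {
    warning("empty weight-loss categories dropped: ",
            paste(setdiff(levels(cat5), present), collapse = ", "))
  }
  if (length(present) < 2) stop("need >= 2 populated categories",
                                call. = FALSE)
  frame$.cat <- factor(as.character(cat5), levels = present)
  fit <- stats::lm(.chg ~ .cat + .wt0 + .base, data = frame)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit, complete = FALSE)
  grid <- data.frame(.cat = factor(present, levels = present),
                     .wt0 = mean(frame$.wt0), .base = mean(frame$.base))
  X <- stats::model.matrix(~ .cat + .wt0 + .base, grid)
  # drop aliased terms (e.g. a constant covariate in a designed fixture)
  keep <- names(beta)[!is.na(beta)]
  beta <- beta[keep]
  X <- X[, keep, drop = FALSE]
  mu <- drop(X %*% beta)
  Vmu <- X %*% V %*% t(X)
  scores <- match(present, levels(cat5))
  cvec <- scores - mean(scores)
  tab <- data.frame(category = present,
                    n = as.integer(table(frame$.cat)[present]),
                    mean = mu, var = diag(Vmu), stringsAsFactors = FALSE)
  list(table = tab, contrast_est = sum(cvec * mu),
       contrast_var = drop(t(cvec) %*% Vmu %*% cvec),
       df_residual = stats::df.residual(fit))
}

#' @export
print.ordinal_trend_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Adjusted %s change by weight-loss category (semaglutide arm)\n",
              x$endpoint))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-6s n = %3d  %8.*g [%.*g, %.*g]\n", tab$category[i],
                tab$n[i], digits, tab$mean[i], digits, tab$ci_low[i],
                digits, tab$ci_high[i]))
  }
  cat(sprintf("  linearity F = %.3g on (1, %.4g) df, p = %.3g\n",
              x$linearity_f, x$linearity_df[2], x$linearity_p))
  invisible(x)
}

#' Observed weight-loss category counts in the semaglutide arm
#'
#' Counts and one-decimal percentages of the five weight-loss categories
#' among semaglutide-treated participants with a recorded week-52 body
#' weight.
#'
#' @param dataset A `trial_data` data frame.
#' @return Data frame with `category`, `n`, `pct`.
#' @export
weight_category_counts <- function(dataset) {
  sem <- dataset[dataset$arm == "semaglutide" &
                   !is.na(dataset$weight_week52_kg), , drop = FALSE]
  if (nrow(sem) == 0) stop("no observed week-52 weights", call. = FALSE)
  pct <- percent_weight_change(sem$weight_baseline_kg, sem$weight_week52_kg)
  counts <- table(weight_loss_category(pct))
  data.frame(category = names(counts), n = as.integer(counts),
             pct = count_percent(as.integer(counts)),
             stringsAsFactors = FALSE)
}

#' Baseline association of an endpoint with continuous BMI
#'
#' Linear regression of the baseline endpoint (log scale for CRP) on
#' continuous BMI adjusted for age, sex, NYHA class, history of atrial
#' fibrillation and history of coronary artery disease; the per-unit-BMI
#' slope is reported (as a multiplicative ratio for CRP).
#'
#' @param dataset A `trial_data` data frame (both arms, baseline only).
#' @param baseline_endpoint `"kccq"`, `"sixmwd"` or `"crp"`.
#' @return A `regression_fit` with the per-unit-BMI slope.
#' @export
fit_baseline_association <- function(dataset, baseline_endpoint) {
  if (!baseline_endpoint %in% c("kccq", "sixmwd", "crp")) {
    stop("baseline_endpoint must be one of kccq, sixmwd, crp", call. = FALSE)
  }
  df <- dataset
  frame <- data.frame(.y = endpoint_baseline(df, baseline_endpoint),
                      .bmi = df$bmi, .age = df$age, .sex = df$sex,
                      .nyha = factor(as.character(df$nyha),
                                     levels = c("II", "III", "IV")),
                      .afib = df$afib, .cad = df$cad)
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  frame$.nyha <- droplevels(frame$.nyha)
  fml <- if (nlevels(frame$.nyha) > 1) {
    .y ~ .bmi + .age + .sex + .nyha + .afib + .cad
  } else .y ~ .bmi + .age + .sex + .afib + .cad
  fit <- stats::lm(fml, data = frame)
  b <- stats::coef(fit)[".bmi"]
  se <- sqrt(stats::vcov(fit)[".bmi", ".bmi"])
  dfree <- stats::df.residual(fit)
  half <- stats::qt(0.975, dfree) * se
  p <- 2 * stats::pt(-abs(b / se), dfree)
  if (endpoint_is_log(baseline_endpoint)) {
    new_regression_fit(baseline_endpoint, "baseline_assoc", exp(b),
                       exp(b - half), exp(b + half), p, nrow(frame),
                       "unit BMI", "ratio")
  } else {
    new_regression_fit(baseline_endpoint, "baseline_assoc", unname(b),
                       unname(b - half), unname(b + half), p, nrow(frame),
                       "unit BMI", "difference")
  }
}
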