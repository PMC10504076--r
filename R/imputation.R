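#' ANCOVA-based multiple imputation of week-52 endpoints
#'
#' For each imputation, a normal-errors linear model of the week-52 change
#' score on treatment, obesity class, their interaction and the baseline
#' value of the endpoint is fitted among observed records; the residual
#' variance and coefficients are drawn from their sampling posterior (proper
#' imputation) and missing values are drawn from the resulting predictive
#' distribution. CRP is imputed on the natural-log scale, so imputed CRP
#' values are strictly positive; body weight is imputed as the percent
#' change from baseline. Death days and HF events are never imputed.
#'
#' @param dataset A `trial_data` data frame.
#' @param endpoint Endpoint name(s): any of `"kccq"`, `"weight"`,
#'   `"sixmwd"`, `"crp"`. Several endpoints are imputed marginally, in order,
#'   from one seeded RNG stream.
#' @param covariates Optional extra covariate column names entering the
#'   imputation model linearly.
#' @param m Number of imputations (>= 2).
#' @param seed Integer seed; imputations are deterministic given it.
#' @return An `imputation_set`: list of `m` completed datasets plus metadata.
#'   Observed values are identical across completed datasets.
#' @export
impute_endpoint <- function(dataset, endpoint, covariates = NULL,
                            m = 100, seed = 1) {
  if (any(endpoint %in% c("death", "death_day", "hf_events",
                          "hf_event_days"))) {
    stop("death and HF events are never imputed", call. = FALSE)
  }
  if (!all(endpoint %in% ENDPOINTS)) {
    stop("unknown endpoint(s): ",
         paste(setdiff(endpoint, ENDPOINTS), collapse = ", "), call. = FALSE)
  }
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  df <- dataset
  df$bmi_class <- assign_bmi_class(df$bmi)
  set.seed(as.integer(seed))
  completed <- replicate(m, dataset, simplify = FALSE)

  for (ep in endpoint) {
    chg <- endpoint_change(df, ep)
    base <- endpoint_baseline(df, ep)
    obs <- !is.na(chg)
    per_arm <- table(df$arm[obs])
    if (any(per_arm < 10)) {
      stop(sprintf("fewer than 10 observed '%s' values in the %s arm",
                   ep, names(per_arm)[which.min(per_arm)]), call. = FALSE)
    }
    cells <- table(df$arm[obs], droplevels(df$bmi_class[obs]))
    if (any(cells == 0)) {
      idx <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("no observed '%s' values in stratum %s x class %s",
                   ep, rownames(cells)[idx[1]], colnames(cells)[idx[2]]),
           call. = FALSE)
    }
    n_cls <- nlevels(droplevels(df$bmi_class))
    fml <- if (n_cls > 1) ~ arm * bmi_class + .base else ~ arm + .base
    mf <- data.frame(arm = df$arm, bmi_class = droplevels(df$bmi_class),
                     .base = base)
    if (!is.null(covariates)) {
      for (cv in covariates) mf[[cv]] <- df[[cv]]
      fml <- stats::update(fml, paste("~ . +", paste(covariates, collapse = "+")))
    }
    X <- stats::model.matrix(fml, mf)
    Xo <- X[obs, , drop = FALSE]
    yo <- chg[obs]
    qr_o <- qr(Xo)
    if (qr_o$rank < ncol(Xo)) stop("imputation model is rank deficient",
                                   call. = FALSE)
    betahat <- qr.coef(qr_o, yo)
    res <- yo - Xo %*% betahat
    nu <- length(yo) - ncol(Xo)
    rss <- sum(res^2)
    XtXinv <- chol2inv(qr.R(qr_o))
    R <- chol(XtXinv)
    mis <- which(!obs)
    for (i in seq_len(m)) {
      if (length(mis)) {
        sigma2 <- rss / stats::rchisq(1, nu)
        beta <- betahat + sqrt(sigma2) * drop(t(R) %*% stats::rnorm(ncol(Xo)))
        ymis <- drop(X[mis, , drop = FALSE] %*% beta) +
          stats::rnorm(length(mis), 0, sqrt(sigma2))
        completed[[i]] <- fill_endpoint(completed[[i]], ep, mis, ymis)
      }
    }
  }
  structure(list(completed = completed, m = m, endpoint = endpoint,
                 model_descriptor = "change ~ arm * bmi_class + baseline",
                 covariates = covariates, seed = seed),
            class = "imputation_set")
}

# write an imputed change score back to the week-52 column, original scale
fill_endpoint <- function(df, endpoint, idx, chg) {
  switch(endpoint,
    kccq   = { df$kccq_week52[idx] <- df$kccq_baseline[idx] + chg; df },
    sixmwd = { df$sixmwd_week52_m[idx] <- df$sixmwd_baseline_m[idx] + chg; df },
    crp    = { df$crp_week52_mg_l[idx] <-
                 exp(log(df$crp_baseline_mg_l[idx]) + chg); df },
    weight = { df$weight_week52_kg[idx] <-
                 df$weight_baseline_kg[idx] * (1 + chg / 100); df }
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d, endpoint(s): %s (seed %d)\n",
              x$m, paste(x$endpoint, collapse = ", "), as.integer(x$seed)))
  cat("  model:", x$model_descriptor, "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates;
#' the total variance is the mean within-imputation variance plus
#' (1 + 1/m) times the between-imputation variance; degrees of freedom use
#' the classic (m - 1)(1 + W / ((1 + 1/m) B))^2 formula, replaced by a
#' large-sample value of 1e6 when the between-imputation variance is exactly
#' zero.
#'
#' @param estimates,variances Numeric vectors of per-imputation point
#'   estimates and squared standard errors (same length, variances > 0).
#' @param m Number of imputations; defaults to `length(estimates)`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `pooled_estimate` with fields `theta_bar`, `W`, `B`, `T`, `df`,
#'   `ci_low`, `ci_high`, `p`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))
#' @export
rubin_pool <- function(estimates, variances, m = length(estimates),
                       conf_level = 0.95) {
  if (length(estimates) != length(variances) || m != length(estimates)) {
    stop("estimates and variances must have length m", call. = FALSE)
  }
  if (m < 2) stop("pooling requires m >= 2 imputations", call. = FALSE)
  if (any(variances <= 0)) stop("variances must be positive", call. = FALSE)
  theta_bar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  df <- if (B == 0) 1e6 else (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
  a <- 1 - (1 - conf_level) / 2
  half <- stats::qt(a, df) * sqrt(Tv)
  p <- 2 * stats::pt(-abs(theta_bar / sqrt(Tv)), df)
  structure(list(theta_bar = theta_bar, W = W, B = B, T = Tv, df = df,
                 ci_low = theta_bar - half, ci_high = theta_bar + half,
                 p = p, m = m, conf_level = conf_level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled estimate (Rubin's rules, m = %d)\n", x$m))
  cat(sprintf("  estimate %.*g, %.0f%% CI [%.*g, %.*g], p = %.3g\n",
              digits, x$theta_bar, 100 * x$conf_level, digits, x$ci_low,
              digits, x$ci_high, x$p))
  cat(sprintf("  W = %.*g, B = %.*g, T = %.*g, df = %.4g\n",
              digits, x$W, digits, x$B, digits, x$T, x$df))
  invisible(x)
}

# Multivariate Rubin combination (D1 statistic) of a k-dimensional contrast:
# Q is an m x k matrix of per-imputation estimates, U a list of m k x k
# within-imputation covariance matrices. Used for the interaction F-test.
rubin_pool_mv <- function(Q, U) {
  m <- nrow(Q)
  k <- ncol(Q)
  qbar <- colMeans(Q)
  ubar <- Reduce(`+`, U) / m
  Bmat <- if (m > 1) stats::cov(Q) else matrix(0, k, k)
  ubar_inv <- solve(ubar)
  r <- (1 + 1 / m) * sum(diag(Bmat %*% ubar_inv)) / k
  wald <- drop(t(qbar) %*% ubar_inv %*% qbar)
  if (r < 1e-12) {
    return(list(f = wald / k, df1 = k, df2 = 1e6,
                p = stats::pf(wald / k, k, 1e6, lower.tail = FALSE)))
  }
  f <- wald / (k * (1 + r))
  v <- k * (m - 1)
  df2 <- if (v > 4) 4 + (v - 4) * (1 + (1 - 2 / v) / r)^2
         else v * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  list(f = f, df1 = k, df2 = df2,
       p = stats::pf(f, k, df2, lower.tail = FALSE))
}
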