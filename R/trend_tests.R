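new_trend_test <- function(method, statistic, stat_name, z, p, n_groups,
                           ties) {
  structure(list(statistic = stats::setNames(statistic, stat_name),
                 z = z, p.value = p, p_two_sided = p, method = method,
                 n_groups = n_groups, tie_correction_applied = ties,
                 data.name = "grouped data", alternative = "two.sided"),
            class = c("trend_test", "htest"))
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' The statistic is the tie-adjusted count of concordant cross-group pairs,
#' `U = sum over ordered group pairs (i < j) of #\{y > x\} + 0.5 #\{y = x\}`.
#' Its null mean and tie-corrected variance give a normal-approximation
#' two-sided p-value; for small samples an exact permutation p-value is
#' computed by enumerating all group assignments.
#'
#' @param values_by_group List of numeric vectors, one per ordered group
#'   (each non-empty after dropping `NA`s).
#' @param exact `"auto"` (exact when total n <= 12), `"always"` or
#'   `"never"`.
#' @return A `trend_test` with fields `statistic` (U), `z`, `p_two_sided`
#'   and `tie_correction_applied`.
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
jonckheere_terpstra <- function(values_by_group,
                                exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  g <- lapply(values_by_group, function(x) x[!is.na(x)])
  if (length(g) < 2) stop(">= 2 ordered groups required", call. = FALSE)
  if (any(lengths(g) == 0)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  K <- length(g)
  n <- lengths(g)
  N <- sum(n)
  U <- 0
  for (i in 1:(K - 1)) {
    for (j in (i + 1):K) {
      cmp <- outer(g[[j]], g[[i]], `-`)
      U <- U + sum(cmp > 0) + 0.5 * sum(cmp == 0)
    }
  }
  mu <- (N^2 - sum(n^2)) / 4
  pooled <- unlist(g)
  tvec <- as.numeric(table(pooled))
  ties <- any(tvec > 1)
  A <- N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
    sum(tvec * (tvec - 1) * (2 * tvec + 5))
  Bt <- sum(n * (n - 1) * (n - 2)) * sum(tvec * (tvec - 1) * (tvec - 2))
  Ct <- sum(n * (n - 1)) * sum(tvec * (tvec - 1))
  v <- A / 72
  if (N > 2) v <- v + Bt / (36 * N * (N - 1) * (N - 2))
  v <- v + Ct / (8 * N * (N - 1))
  # continuity-corrected standardization: U moves on a lattice, so half a
  # step is subtracted from |U - mean| before comparing to the normal
  z <- if (v > 0) sign(U - mu) * max(abs(U - mu) - 0.5, 0) / sqrt(v) else 0
  p <- if (v > 0) 2 * stats::pnorm(-abs(z)) else 1

  do_exact <- exact == "always" || (exact == "auto" && N <= 12)
  if (do_exact) {
    p <- jt_exact_p(pooled, n, U)
  }
  out <- new_trend_test(
    paste0("Jonckheere-Terpstra trend test",
           if (do_exact) " (exact permutation)" else
             " (tie-corrected normal approximation)"),
    U, "JT", z, p, K, ties)
  out$mean_null <- mu
  out$var_null <- v
  out
}

# exact permutation distribution of the JT statistic by enumerating all
# assignments of the pooled values to groups of the observed sizes
jt_exact_p <- function(pooled, sizes, u_obs) {
  N <- length(pooled)
  G <- outer(pooled, pooled, function(b, a) (b > a) + 0.5 * (b == a))
  us <- numeric(0)
  recurse <- function(remaining, k, groups) {
    if (k > length(sizes)) {
      u <- 0
      for (i in 1:(length(groups) - 1)) {
        for (j in (i + 1):length(groups)) {
          u <- u + sum(G[groups[[j]], groups[[i]], drop = FALSE])
        }
      }
      us[length(us) + 1L] <<- u
      return(invisible())
    }
    if (k == length(sizes)) {
      recurse(integer(0), k + 1L, c(groups, list(remaining)))
      return(invisible())
    }
    sel <- utils::combn(remaining, sizes[k], simplify = FALSE)
    for (s in sel) {
      recurse(setdiff(remaining, s), k + 1L, c(groups, list(s)))
    }
    invisible()
  }
  recurse(seq_len(N), 1L, list())
  mu <- mean(us)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Cochran-Armitage test for trend in proportions
#'
#' Score test of a linear trend in proportions across ordered groups:
#' `z = sum s_k (r_k - n_k p) / sqrt(p (1 - p) (sum n_k s_k^2 -
#' (sum n_k s_k)^2 / N))` with `p` the pooled proportion and default scores
#' 1..K.
#'
#' @param successes_by_group,totals_by_group Integer vectors of successes
#'   and totals per ordered group.
#' @param scores Numeric group scores (default `1:K`).
#' @return A `trend_test` with the signed `z` statistic.
#' @export
cochran_armitage <- function(successes_by_group, totals_by_group,
                             scores = seq_along(successes_by_group)) {
  r <- successes_by_group; n <- totals_by_group; s <- scores
  if (length(r) != length(n) || length(r) != length(s)) {
    stop("groups, totals and scores must have equal length", call. = FALSE)
  }
  if (any(n <= 0) || any(r < 0) || any(r > n)) {
    stop("need 0 <= successes <= totals with positive totals", call. = FALSE)
  }
  N <- sum(n)
  pbar <- sum(r) / N
  if (pbar <= 0 || pbar >= 1) {
    warning("pooled proportion is 0 or 1; trend test is degenerate")
    return(new_trend_test("Cochran-Armitage trend test", 0, "Z", 0, 1,
                          length(r), FALSE))
  }
  denom2 <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N)
  if (denom2 <= 0) stop("zero score variance across groups", call. = FALSE)
  z <- sum(s * (r - n * pbar)) / sqrt(denom2)
  new_trend_test("Cochran-Armitage trend test", z, "Z", z,
                 2 * stats::pnorm(-abs(z)), length(r), FALSE)
}

#' Score-based Cochran-Mantel-Haenszel trend statistic
#'
#' Single-degree-of-freedom nonzero-correlation CMH statistic for a K x C
#' table of ordered groups by categories: `(N - 1) r^2` where `r` is the
#' Pearson correlation of the (row score, column score) pairs over all N
#' observations; compared to a chi-square with 1 df.
#'
#' @param contingency K x C matrix of nonnegative counts (rows = ordered
#'   groups).
#' @param row_scores,col_scores Numeric scores (defaults 1..K and 1..C).
#' @return A `trend_test` with the chi-square statistic and signed `z`.
#' @export
cmh_score_trend <- function(contingency,
                            row_scores = seq_len(nrow(contingency)),
                            col_scores = seq_len(ncol(contingency))) {
  tab <- as.matrix(contingency)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  N <- sum(tab)
  if (N < 2) stop("need N >= 2 observations", call. = FALSE)
  w <- tab / N
  mr <- sum(row_scores * rowSums(w))
  mc <- sum(col_scores * colSums(w))
  vr <- sum((row_scores - mr)^2 * rowSums(w))
  vc <- sum((col_scores - mc)^2 * colSums(w))
  if (vr <= 0 || vc <= 0) {
    warning("zero variance in a score margin; statistic is degenerate")
    return(new_trend_test("CMH correlation trend test", 0, "X-squared", 0, 1,
                          nrow(tab), FALSE))
  }
  cv <- sum(outer(row_scores - mr, col_scores - mc) * w)
  rho <- cv / sqrt(vr * vc)
  stat <- (N - 1) * rho^2
  z <- sign(rho) * sqrt(stat)
  new_trend_test("CMH correlation trend test", stat, "X-squared", z,
                 stats::pchisq(stat, 1, lower.tail = FALSE), nrow(tab),
                 FALSE)
}

#' Default baseline-variable specification for the trend table
#' @return List of `list(name, type)` variable descriptors.
#' @export
baseline_variables <- function() {
  list(
    list(name = "age", type = "continuous"),
    list(name = "weight_baseline_kg", type = "continuous"),
    list(name = "kccq_baseline", type = "continuous"),
    list(name = "sixmwd_baseline_m", type = "continuous"),
    list(name = "crp_baseline_mg_l", type = "continuous"),
    list(name = "ntprobnp_baseline_pg_ml", type = "continuous"),
    list(name = "sex", type = "binary"),
    list(name = "afib", type = "binary"),
    list(name = "cad", type = "binary"),
    list(name = "nyha", type = "multinomial")
  )
}

#' Baseline trend table across obesity classes
#'
#' Dispatches each baseline variable to the trend test matching its type:
#' continuous variables to the Jonckheere-Terpstra test, binary variables to
#' the Cochran-Armitage test and multinomial variables to the score-based
#' CMH statistic, with classes I/II/III as the ordered groups. Summaries are
#' median (Q1, Q3) for continuous variables and n (%) otherwise.
#'
#' @param dataset A `trial_data` data frame.
#' @param variables List of `list(name, type)` descriptors
#'   (default [baseline_variables()]).
#' @return A `baseline_table` data frame: variable, type, one summary column
#'   per class, and the two-sided trend p-value.
#' @export
baseline_trend_table <- function(dataset, variables = baseline_variables()) {
  df <- dataset
  cls <- droplevels(assign_bmi_class(df$bmi))
  if (nlevels(cls) < 2) stop(">= 2 ordered groups required", call. = FALSE)
  classes <- levels(cls)
  rows <- lapply(variables, function(v) {
    x <- df[[v$name]]
    if (is.null(x)) stop("unknown variable '", v$name, "'", call. = FALSE)
    if (v$type == "continuous") {
      byg <- split(as.numeric(x), cls)
      tt <- jonckheere_terpstra(byg, exact = "never")
      summ <- vapply(byg, function(g) {
        q <- stats::quantile(g, c(0.5, 0.25, 0.75), na.rm = TRUE)
        sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
      }, character(1))
    } else if (v$type == "binary") {
      ind <- if (is.logical(x)) x else x == levels(factor(x))[1]
      succ <- tapply(ind, cls, sum)
      tot <- tapply(ind, cls, length)
      tt <- cochran_armitage(as.numeric(succ), as.numeric(tot))
      summ <- sprintf("%d (%.1f)", succ, 100 * succ / tot)
    } else if (v$type == "multinomial") {
      tab <- table(cls, x)
      tt <- cmh_score_trend(tab)
      summ <- apply(tab, 1, function(r) {
        paste(sprintf("%s %d (%.1f)", colnames(tab), r,
                      100 * r / sum(r)), collapse = "; ")
      })
    } else {
      stop("unknown variable type '", v$type, "' for '", v$name, "'",
           call. = FALSE)
    }
    out <- data.frame(variable = v$name, type = v$type,
                      stringsAsFactors = FALSE)
    for (k in seq_along(classes)) out[[paste0("class_", classes[k])]] <- summ[k]
    out$p_trend <- tt$p_two_sided
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_table", class(out))
  out
}
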