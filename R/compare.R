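# Slope-then-intercept comparison of endotherm vs ectotherm allometric
# lines, for OLS, SMA and PGLS.

# (generalized) least squares Wald test on one coefficient.
# X built from x and the group indicator; C = NULL means OLS.
gls_wald <- function(x, y, g, C = NULL, term = c("interaction", "group")) {
  term <- match.arg(term)
  n <- length(x)
  X <- if (term == "interaction") cbind(1, x, g, g * x) else cbind(1, x, g)
  k <- ncol(X)
  if (!is.null(C)) {
    L <- tryCatch(chol(C), error = function(e) {
      abort("C is singular or not positive definite",
            class = "nasallom_error_singular")
    })
    X <- backsolve(L, X, transpose = TRUE)
    y <- backsolve(L, y, transpose = TRUE)
  }
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- n - k
  sigma2 <- rss / df
  se <- sqrt(sigma2 * solve(XtX)[k, k])
  est <- beta[k]
  scale <- max(sum(y^2), 1e-300)
  if (se == 0 || rss <= 1e-24 * scale) {
    # noise-free data: a zero coefficient is exactly zero evidence
    stat <- if (abs(est) <= 1e-10 * sqrt(scale / n)) 0 else Inf
  } else {
    stat <- est / se
  }
  list(estimate = est, se = se, statistic = stat, df = df,
       p_value = 2 * pt(-abs(stat), df))
}

# Warton-style SMA machinery -------------------------------------------

# correlation between residual (y - b x) and fitted (y + b x) axes
sma_rf_cor <- function(x, y, b) {
  r <- y - b * x
  f <- y + b * x
  vr <- var(r); vf <- var(f)
  if (vr <= 1e-24 * max(var(y), 1e-300) || vf <= 0) return(0)
  stats::cov(r, f) / sqrt(vr * vf)
}

sma_lr_stat <- function(x, y, g, b) {
  s <- 0
  for (gv in unique(g)) {
    i <- g == gv
    r2 <- sma_rf_cor(x[i], y[i], b)^2
    s <- s - (sum(i) - 2) * log(max(1 - r2, 1e-300))
  }
  s
}

# common-slope estimate and likelihood-ratio statistic
sma_common_slope <- function(x, y, g) {
  bs <- vapply(unique(g), function(gv) {
    i <- g == gv
    sign2(stats::cor(x[i], y[i])) * sd(y[i]) / sd(x[i])
  }, numeric(1))
  if (max(bs) - min(bs) < 1e-12 * max(abs(bs))) {
    return(list(b = bs[1], statistic = sma_lr_stat(x, y, g, bs[1])))
  }
  lo <- min(bs); hi <- max(bs)
  span <- hi - lo
  op <- optimize(function(b) sma_lr_stat(x, y, g, b),
                 interval = c(lo - 0.5 * span, hi + 0.5 * span))
  list(b = op$minimum, statistic = op$objective)
}

sma_slope_test <- function(x, y, g) {
  k <- length(unique(g))
  cs <- sma_common_slope(x, y, g)
  stat <- max(cs$statistic, 0)
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# elevation (intercept) test at the common SMA slope. The common-slope
# variance comes from the curvature of the likelihood-ratio profile
# (observed information), which tracks the finite-sample behaviour better
# than the closed-form asymptotic formula; the statistic is referred to a
# t distribution with N - 4 df (two means, one slope, one scale).
sma_elevation_test <- function(x, y, g) {
  cs <- sma_common_slope(x, y, g)
  b <- cs$b
  lv <- unique(g)
  z <- y - b * x
  a <- vapply(lv, function(gv) mean(z[g == gv]), numeric(1))
  vres <- vapply(lv, function(gv) var(z[g == gv]), numeric(1))
  ns <- vapply(lv, function(gv) sum(g == gv), numeric(1))
  xm <- vapply(lv, function(gv) mean(x[g == gv]), numeric(1))
  h <- max(abs(b), 1e-8) * 1e-3
  curv <- (sma_lr_stat(x, y, g, b + h) + sma_lr_stat(x, y, g, b - h) -
             2 * cs$statistic) / h^2
  var_b <- if (is.finite(curv) && curv > 0) 2 / curv else 0
  se2 <- sum(vres / ns) + diff(xm)^2 * var_b
  dif <- diff(a)
  df <- sum(ns) - 4
  stat <- if (se2 <= 1e-24 * max(var(y), 1e-300)) {
    if (abs(dif) < 1e-12) 0 else Inf
  } else {
    dif / sqrt(se2)
  }
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

prepare_two_groups <- function(data, x, y, group_col) {
  g <- data[[group_col]]
  if (is.null(g)) {
    abort(paste0("`data` needs a '", group_col, "' column"),
          class = "nasallom_error_config")
  }
  lv <- sort(unique(g))
  if (length(lv) != 2) {
    abort("exactly two groups are required", class = "nasallom_error_config")
  }
  ns <- table(g)
  if (any(ns < 3)) {
    abort(paste("each group needs at least 3 records; got",
                paste(ns, collapse = " and ")),
          class = "nasallom_error_config")
  }
  # endotherm coded 1 when present, else the second level
  ref <- if ("endotherm" %in% lv) "endotherm" else lv[2]
  list(xv = data[[x]], yv = data[[y]], ind = as.numeric(g == ref), g = g)
}

#' Test for a slope difference between two allometric lines
#'
#' OLS and PGLS use a Wald t test on the group-by-size interaction in the
#' pooled model `y ~ x + group + group:x` (generalized least squares under
#' the Brownian tree covariance for PGLS), df `n - 4`. SMA uses the
#' likelihood-ratio common-slope test (correlation between residual and
#' fitted axes at the common slope), referred to chi-square with
#' `groups - 1` df.
#'
#' @param data data frame with the (log10) variables and a group column.
#' @param x,y column names.
#' @param method `"ols"`, `"sma"` or `"pgls"`.
#' @param tree `phylo` tree (or a precomputed covariance matrix) for PGLS.
#' @param group_col column holding the two group labels.
#' @param tip_col column matching records to tree tips (PGLS).
#' @return tibble with `method`, `test`, `statistic`, `df`, `p_value`.
#' @export
test_slope_difference <- function(data, x, y, method = c("ols", "sma", "pgls"),
                                  tree = NULL, group_col = "thermo_class",
                                  tip_col = "species") {
  method <- tolower(match.arg(method))
  pg <- prepare_two_groups(data, x, y, group_col)
  res <- switch(method,
    ols = gls_wald(pg$xv, pg$yv, pg$ind, NULL, "interaction"),
    pgls = gls_wald(pg$xv, pg$yv, pg$ind,
                    align_covariance(tree, data[[tip_col]]), "interaction"),
    sma = sma_slope_test(pg$xv, pg$yv, pg$g))
  tibble::tibble(method = toupper(method), test = "slope",
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value)
}

#' Test for an intercept difference at a common slope
#'
#' Analysis of covariance on the group term: classical ANCOVA F for OLS,
#' a Wald t on the group dummy in the common-slope generalized
#' least-squares model for PGLS (phylogenetic ANCOVA), and the elevation
#' test at the common SMA slope for SMA. Valid only once slope homogeneity
#' has been established; by default the slope test is re-run and a
#' contract violation raised if it rejects at `alpha`.
#'
#' @inheritParams test_slope_difference
#' @param alpha level used for the slope-homogeneity contract check.
#' @param check_slopes verify slope homogeneity first (set `FALSE` when the
#'   caller, e.g. [compare_groups()], has already done so).
#' @return tibble with `method`, `test`, `statistic`, `df`, `p_value`.
#' @export
test_intercept_difference <- function(data, x, y,
                                      method = c("ols", "sma", "pgls"),
                                      tree = NULL, alpha = 0.05,
                                      check_slopes = TRUE,
                                      group_col = "thermo_class",
                                      tip_col = "species") {
  method <- tolower(match.arg(method))
  if (check_slopes) {
    st <- test_slope_difference(data, x, y, method, tree, group_col, tip_col)
    if (is.finite(st$p_value) && st$p_value < alpha) {
      abort(paste0("slopes differ (p = ", signif(st$p_value, 3),
                   "); an intercept comparison at a common slope is invalid"),
            class = "nasallom_error_contract")
    }
  }
  pg <- prepare_two_groups(data, x, y, group_col)
  res <- switch(method,
    ols = {
      w <- gls_wald(pg$xv, pg$yv, pg$ind, NULL, "group")
      list(statistic = w$statistic^2, df = w$df,
           p_value = pf(w$statistic^2, 1, w$df, lower.tail = FALSE))
    },
    pgls = gls_wald(pg$xv, pg$yv, pg$ind,
                    align_covariance(tree, data[[tip_col]]), "group"),
    sma = sma_elevation_test(pg$xv, pg$yv, pg$g))
  tibble::tibble(method = toupper(method), test = "intercept",
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value)
}

#' Conditional slope-then-intercept comparison of two groups
#'
#' Runs the slope-difference test; only when it does *not* reject at
#' `alpha` is the intercept (ANCOVA) test run -- when slopes already
#' differ, the lines differ and an elevation comparison at a common slope
#' is not meaningful (reported as "not tested").
#'
#' @inheritParams test_slope_difference
#' @param size_var,response_var column names of the (log10) size proxy and
#'   response.
#' @param alpha significance level of the conditional scheme.
#' @return an `allom_comparison`: slope and (possibly) intercept test
#'   results plus per-group `allom_fit`s. Use [tidy()] for a one-row
#'   summary.
#' @export
compare_groups <- function(data, size_var, response_var,
                           method = c("ols", "sma", "pgls"), tree = NULL,
                           alpha = 0.05, group_col = "thermo_class",
                           tip_col = "species") {
  method <- tolower(match.arg(method))
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)", class = "nasallom_error_config")
  }
  pg <- prepare_two_groups(data, size_var, response_var, group_col)
  slope_test <- test_slope_difference(data, size_var, response_var, method,
                                      tree, group_col, tip_col)
  intercept_test <- NULL
  if (!is.na(slope_test$p_value) && slope_test$p_value >= alpha) {
    intercept_test <- test_intercept_difference(
      data, size_var, response_var, method, tree, alpha,
      check_slopes = FALSE, group_col = group_col, tip_col = tip_col)
  }
  fits <- lapply(split(seq_len(nrow(data)), data[[group_col]]), function(i) {
    fit_allometry(data[i, , drop = FALSE], size_var, response_var, method,
                  tree = tree, tip_col = tip_col)
  })
  structure(list(
    comparison = paste(response_var, "~", size_var),
    size_var = size_var, response_var = response_var,
    method = toupper(method), alpha = alpha,
    n = table(data[[group_col]]),
    slope_test = slope_test, intercept_test = intercept_test,
    fits = fits), class = "allom_comparison")
}

#' @export
print.allom_comparison <- function(x, ...) {
  cat(sprintf("<allom_comparison %s, %s>\n", x$comparison, x$method))
  cat(sprintf("  slope:     stat = %.3g, p = %.3g\n",
              x$slope_test$statistic, x$slope_test$p_value))
  if (is.null(x$intercept_test)) {
    cat(sprintf("  intercept: not tested (slope p < %.3g)\n", x$alpha))
  } else {
    cat(sprintf("  intercept: stat = %.3g, p = %.3g\n",
                x$intercept_test$statistic, x$intercept_test$p_value))
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x an `allom_comparison`.
#' @param ... unused.
#' @return one-row tibble: comparison id, method, group sizes, slope
#'   statistic and p, intercept statistic and p (`NA` when not tested),
#'   and `intercept_tested`.
#' @method tidy allom_comparison
#' @export
tidy.allom_comparison <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison,
    size_var = x$size_var, response_var = x$response_var,
    method = x$method,
    slope_stat = x$slope_test$statistic,
    slope_p = x$slope_test$p_value,
    intercept_stat = if (is.null(x$intercept_test)) NA_real_
                     else x$intercept_test$statistic,
    intercept_p = if (is.null(x$intercept_test)) NA_real_
                  else x$intercept_test$p_value,
    intercept_tested = !is.null(x$intercept_test),
    alpha = x$alpha)
}
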