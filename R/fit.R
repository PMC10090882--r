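#' Log-transform measurement variables
#'
#' Base-10 logarithms of the selected columns, in place (allometric axes
#' conventionally span orders of magnitude; the base only shifts
#' intercepts, slopes and tests are unaffected).
#'
#' @param records data frame of measurements.
#' @param variables character vector of column names to transform.
#' @return tibble with the selected columns replaced by their log10.
#' @examples
#' log_transform(data.frame(m = c(1, 1000)), "m")$m  # 0, 3
#' @export
log_transform <- function(records, variables) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(variables, names(records))
  if (length(missing)) {
    abort(paste("unknown variables:", paste(missing, collapse = ", ")),
          class = "nasallom_error_config")
  }
  for (v in variables) {
    bad <- which(!is.na(records[[v]]) & records[[v]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive value in '%s' at row %d%s", v, bad[1],
                    if ("species" %in% names(records))
                      paste0(" (", records$species[bad[1]], ")") else ""),
            class = "nasallom_error_domain")
    }
    records[[v]] <- log10(records[[v]])
  }
  records
}

new_allom_fit <- function(method, slope, intercept, n, r_squared, sigma2,
                          vcov, logLik = NA_real_, df_residual = NA_real_,
                          x_mean = NA_real_, y_mean = NA_real_) {
  structure(list(method = method, slope = slope, intercept = intercept,
                 n = n, r_squared = r_squared, sigma2 = sigma2, vcov = vcov,
                 logLik = logLik, df_residual = df_residual,
                 x_mean = x_mean, y_mean = y_mean),
            class = "allom_fit")
}

#' @export
print.allom_fit <- function(x, ...) {
  cat(sprintf("<allom_fit %s> y = %.4g + %.4g x  (n = %d, r^2 = %.3f)\n",
              x$method, x$intercept, x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x an `allom_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`.
#' @method tidy allom_fit
#' @export
tidy.allom_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = se)
}

#' @rdname tidy.allom_fit
#' @method glance allom_fit
#' @export
glance.allom_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, r.squared = x$r_squared,
                 sigma2 = x$sigma2, logLik = x$logLik)
}

#' @export
predict.allom_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' Ordinary least-squares allometric line
#'
#' @param x,y numeric vectors (log10 scale), length at least 3.
#' @return an `allom_fit` with slope, intercept, `r_squared`, residual
#'   variance (denominator n - 2) and the estimate covariance matrix.
#' @export
fit_ols <- function(x, y) {
  check_xy(x, y)
  if (var(x) < .Machine$double.eps * max(1, mean(x)^2)) {
    abort("x has zero variance; slope undefined",
          class = "nasallom_error_degenerate")
  }
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - 2)
  vc <- sigma2 * matrix(c(1 / n + mean(x)^2 / sxx, -mean(x) / sxx,
                          -mean(x) / sxx, 1 / sxx), 2, 2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  ll <- -0.5 * n * (log(2 * pi * max(rss / n, 1e-300)) + 1)
  new_allom_fit("OLS", slope, intercept, n, r2, sigma2, vc, ll, n - 2,
                mean(x), mean(y))
}

#' Standardized (reduced) major axis allometric line
#'
#' Symmetric line fitting: `slope = sign(r) * sd(y) / sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`. The slope magnitude is the OLS
#' magnitude divided by `|r|`, so it is never smaller.
#'
#' @inheritParams fit_ols
#' @return an `allom_fit`; `sigma2` is the variance of `y - slope * x`,
#'   the slope standard error the large-sample
#'   `|slope| * sqrt((1 - r^2) / n)`.
#' @export
fit_sma <- function(x, y) {
  check_xy(x, y)
  n <- length(x)
  if (var(x) <= 0 || var(y) <= 0) {
    abort("correlation undefined: zero variance on an axis",
          class = "nasallom_error_degenerate")
  }
  r <- stats::cor(x, y)
  slope <- sign2(r) * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se_slope2 <- slope^2 * (1 - r^2) / n
  sxx <- sum((x - mean(x))^2)
  vc <- matrix(c(var(res) / n + mean(x)^2 * se_slope2, -mean(x) * se_slope2,
                 -mean(x) * se_slope2, se_slope2), 2, 2)
  new_allom_fit("SMA", slope, intercept, n, r^2, var(res), vc,
                df_residual = n - 2, x_mean = mean(x), y_mean = mean(y))
}

#' Phylogenetic generalized least-squares allometric line
#'
#' Generalized least squares with residual covariance proportional to a
#' Brownian-motion tree covariance `C`:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y` with `X = [1, x]`. The residual scale
#' uses the unbiased denominator `n - 2`; the log-likelihood is the
#' Gaussian ML value. With `C` the identity this reduces exactly to
#' [fit_ols()], and rescaling `C` by a constant leaves the estimates
#' unchanged.
#'
#' @inheritParams fit_ols
#' @param C symmetric positive-definite covariance (tips x tips), aligned
#'   with `x`/`y`; typically [bm_covariance()] of a tree, subset and
#'   ordered to the data.
#' @return an `allom_fit` with GLS estimate covariance and log-likelihood.
#' @export
fit_pgls <- function(x, y, C) {
  check_xy(x, y)
  n <- length(x)
  C <- as.matrix(C)
  if (nrow(C) != n || ncol(C) != n) {
    abort("C must be n x n, aligned with the records",
          class = "nasallom_error_config")
  }
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C))) {
    abort("C must be symmetric", class = "nasallom_error_config")
  }
  L <- tryCatch(chol(C), error = function(e) {
    abort(paste("C is singular or not positive definite;",
                "jitter zero-length terminal branches before inverting"),
          class = "nasallom_error_singular")
  })
  Xs <- backsolve(L, cbind(1, x), transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  res <- ys - Xs %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - 2)
  vc <- sigma2 * solve(XtX)
  # GLS R^2 against the GLS-weighted mean
  one_s <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(one_s * ys) / sum(one_s^2)
  tss <- sum((ys - mu * one_s)^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  logdetC <- 2 * sum(log(diag(L)))
  s2ml <- max(rss / n, 1e-300)
  ll <- -0.5 * (n * log(2 * pi * s2ml) + logdetC + n)
  xw <- sum(one_s * Xs[, 2]) / sum(one_s^2)
  new_allom_fit("PGLS", beta[2], beta[1], n, r2, sigma2, vc, ll, n - 2,
                xw, mu)
}

#' Fit an allometric line from a data frame
#'
#' Data-frame-first wrapper around [fit_ols()], [fit_sma()] and
#' [fit_pgls()].
#'
#' @param data data frame holding the (already log10-transformed)
#'   variables.
#' @param x,y column names of the size proxy and the response.
#' @param method `"ols"`, `"sma"` or `"pgls"` (case-insensitive).
#' @param tree for PGLS: a `phylo` tree whose tips cover
#'   `data[[tip_col]]`.
#' @param tip_col column matching records to tree tips.
#' @return an `allom_fit`.
#' @export
fit_allometry <- function(data, x, y, method = c("ols", "sma", "pgls"),
                          tree = NULL, tip_col = "species") {
  method <- tolower(match.arg(method))
  xv <- data[[x]]; yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) {
    abort("`x`/`y` must name columns of `data`",
          class = "nasallom_error_config")
  }
  switch(method,
    ols = fit_ols(xv, yv),
    sma = fit_sma(xv, yv),
    pgls = {
      C <- align_covariance(tree, data[[tip_col]])
      fit_pgls(xv, yv, C)
    })
}

align_covariance <- function(tree, tips) {
  if (is.null(tree)) {
    abort("PGLS needs a tree", class = "nasallom_error_config")
  }
  C <- if (is.matrix(tree)) tree else bm_covariance(tree)
  missing <- setdiff(tips, rownames(C))
  if (length(missing)) {
    abort(paste("records missing from the tree:",
                paste(missing, collapse = ", ")),
          class = "nasallom_error_tree")
  }
  C[tips, tips]
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "nasallom_error_config")
  }
  if (length(x) < 3) {
    abort("need at least 3 observations", class = "nasallom_error_config")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("x and y must not contain NA", class = "nasallom_error_config")
  }
  invisible(TRUE)
}

sign2 <- function(r) if (r < 0) -1 else 1
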