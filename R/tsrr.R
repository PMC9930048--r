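# Short-term PM-mortality association: log-link quasi-Poisson
# regression of daily death counts on same-day PM with a natural cubic
# spline of time, relative risk per interquartile increase, and
# DerSimonian-Laird random-effects pooling across zones.

#' Natural cubic spline basis for time adjustment
#'
#' Builds a natural cubic spline basis of the observation index with
#' `df` columns, interior knots at equally spaced quantiles (via
#' [splines::ns()]), each column centered. `df = 1` yields a single
#' linear-trend column: a natural cubic spline with no interior knot is
#' a straight line.
#'
#' @param dates Strictly increasing vector of dates (or numeric times).
#' @param df Number of basis columns, `1 <= df < n`.
#' @return Numeric matrix with `df` centered columns.
#' @export
build_time_basis <- function(dates, df) {
  n <- length(dates)
  stopifnot(df >= 1)
  if (df >= n) stop("spline df (", df, ") must be smaller than the number of observations (", n, ")")
  t <- as.numeric(dates)
  if (any(diff(t) <= 0)) stop("dates must be strictly increasing")
  b <- splines::ns(t, df = df)
  b <- scale(b, center = TRUE, scale = FALSE)
  attr(b, "scaled:center") <- NULL
  unname(b[, , drop = FALSE])
}

#' Daily health series constructor
#'
#' @param zone Zone label.
#' @param dates Strictly increasing dates.
#' @param deaths Nonnegative integer daily death counts.
#' @param pm PM concentrations (ug/m3) aligned to `dates`.
#' @return Object of class `health_series`.
#' @export
health_series <- function(zone, dates, deaths, pm) {
  stopifnot(length(dates) == length(deaths), length(deaths) == length(pm))
  if (any(deaths < 0) || any(deaths != round(deaths), na.rm = TRUE)) {
    stop("death counts must be nonnegative integers")
  }
  structure(list(zone = zone, dates = dates,
                 deaths = as.integer(deaths), pm = as.numeric(pm)),
            class = "health_series")
}

#' Quasi-Poisson regression of daily deaths on PM
#'
#' Fits `log E[deaths] = a + beta * pm + s(time)` by iteratively
#' reweighted least squares for the log-link Poisson likelihood, where
#' `s(time)` is the centered natural-spline basis of
#' [build_time_basis()]. Overdispersion is absorbed by the Pearson
#' dispersion `phi = X2 / (n - p)`; the standard error of `beta` is the
#' Poisson SE inflated by `sqrt(phi)`. Convergence: relative deviance
#' change below 1e-8 within 100 iterations; non-convergence is flagged,
#' never silent.
#'
#' @param series [health_series()] with at least 50 complete days.
#' @param spline_df Degrees of freedom for the time spline (0 drops the
#'   time adjustment entirely).
#' @return Object of class `pm_tsfit`: `beta` (per ug/m3 log-rate
#'   slope), `se_beta`, `dispersion`, `spline_df`, `deviance`, `qaic`
#'   (filled by [select_spline_df()]), `iqr` (interquartile range of
#'   the PM series), `converged`, `n`, `coefficients`, `zone`.
#' @export
fit_quasipoisson <- function(series, spline_df = 4) {
  stopifnot(inherits(series, "health_series"))
  ok <- !is.na(series$deaths) & !is.na(series$pm)
  y <- series$deaths[ok]
  pm <- series$pm[ok]
  dates <- series$dates[ok]
  n <- length(y)
  if (n < 50L) stop("need at least 50 complete (death, pm) days; got ", n)
  if (stats::sd(pm) == 0) {
    stop("PM series is constant: the PM slope is not identifiable")
  }
  X <- cbind(`(Intercept)` = 1, pm = pm)
  if (spline_df >= 1) {
    B <- build_time_basis(dates, spline_df)
    colnames(B) <- paste0("time", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient (collinear time basis)")

  # IRLS for log-link Poisson
  eta <- log(pmax(y, 0.5))
  dev_old <- Inf
  converged <- FALSE
  beta_hat <- NULL
  for (it in seq_len(100L)) {
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_hat <- fit$coefficients
    eta <- drop(X %*% beta_hat)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-8) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- exp(drop(X %*% beta_hat))
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- pearson / (n - p)
  XtWX <- crossprod(X * sqrt(mu))
  vcov_pois <- solve(XtWX)
  se <- sqrt(diag(vcov_pois) * dispersion)
  structure(list(zone = series$zone,
                 beta = unname(beta_hat["pm"]),
                 se_beta = unname(se["pm"]),
                 coefficients = beta_hat,
                 se = se,
                 dispersion = dispersion,
                 spline_df = spline_df,
                 deviance = dev,
                 qaic = NA_real_,
                 iqr = unname(stats::IQR(pm)),
                 converged = converged,
                 n = n, p = p),
            class = "pm_tsfit")
}

#' @export
print.pm_tsfit <- function(x, ...) {
  cat(sprintf("Quasi-Poisson PM-mortality fit [%s]\n", x$zone))
  cat(sprintf("  beta = %.6f per ug/m3 (SE %.6f), dispersion %.3f, spline df %d, n %d%s\n",
              x$beta, x$se_beta, x$dispersion, x$spline_df, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  rr <- rr_per_increment(x, x$iqr)
  cat(sprintf("  RR per IQR (%.1f ug/m3): %.4f (%.4f-%.4f)\n",
              x$iqr, rr$rr, rr$ci_low, rr$ci_high))
  invisible(x)
}

#' @export
coef.pm_tsfit <- function(object, ...) object$coefficients

#' @export
summary.pm_tsfit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.pm_tsfit")
}

#' @export
print.summary.pm_tsfit <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Spline degrees of freedom by quasi-AIC
#'
#' Refits the model over a grid of spline degrees of freedom and keeps
#' the fit minimising `QAIC = deviance / phi + 2p`, with the dispersion
#' `phi` estimated once from the richest candidate model (so candidates
#' are compared on a common scale). Ties break to the smallest df.
#'
#' @param series [health_series()].
#' @param df_grid Nonempty vector of candidate spline df.
#' @return The selected [fit_quasipoisson()] fit with `qaic` filled in.
#' @export
select_spline_df <- function(series, df_grid = c(1, 2, 4, 6, 8)) {
  stopifnot(length(df_grid) >= 1L)
  df_grid <- sort(unique(as.integer(df_grid)))
  fits <- lapply(df_grid, function(d) fit_quasipoisson(series, spline_df = d))
  phi <- fits[[length(fits)]]$dispersion
  qaic <- vapply(fits, function(f) f$deviance / phi + 2 * f$p, numeric(1L))
  best <- which.min(qaic)  # which.min returns the first (smallest df) on ties
  fit <- fits[[best]]
  fit$qaic <- qaic[best]
  fit
}

#' Relative risk per concentration increment
#'
#' `RR = exp(beta * increment)` with Wald 95% CI
#' `exp((beta +/- 1.96 se) * increment)`; multiplicative in the
#' increment.
#'
#' @param fit Converged [fit_quasipoisson()] fit.
#' @param increment Concentration increment in ug/m3 (> 0); default the
#'   interquartile range of the fitted PM series.
#' @return List `rr`, `ci_low`, `ci_high`, `increment`.
#' @export
rr_per_increment <- function(fit, increment = fit$iqr) {
  stopifnot(inherits(fit, "pm_tsfit"))
  if (!fit$converged) stop("fit did not converge; refusing to report an RR")
  if (increment <= 0) stop("increment must be > 0")
  list(rr = exp(fit$beta * increment),
       ci_low = exp((fit$beta - 1.96 * fit$se_beta) * increment),
       ci_high = exp((fit$beta + 1.96 * fit$se_beta) * increment),
       increment = increment)
}

#' Random-effects pooling of zone relative risks
#'
#' DerSimonian-Laird pooling on the log-RR scale. With Q the
#' fixed-effect heterogeneity statistic and w the fixed-effect inverse
#' variances, `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`;
#' the pooled estimate reweights by `w* = 1/(se^2 + tau2)` and its CI
#' is `+/- 1.96 / sqrt(sum(w*))`. With `tau2 = 0` this is exactly
#' fixed-effect inverse-variance pooling; with one zone it returns the
#' input.
#'
#' @param log_rr Zone log relative risks (on a common increment).
#' @param se Their standard errors (> 0), same length.
#' @return Object of class `pooled_rr`: `rr`, `ci_low`, `ci_high`,
#'   `log_rr`, `se_log_rr`, `tau2`, `q`, `k`.
#' @export
pool_random_effects <- function(log_rr, se) {
  k <- length(log_rr)
  if (k == 0L) stop("nothing to pool")
  stopifnot(length(se) == k, all(se > 0))
  if (k == 1L) {
    tau2 <- 0; q <- 0
    mu <- log_rr; se_mu <- se
  } else {
    w <- 1 / se^2
    mu_fe <- sum(w * log_rr) / sum(w)
    q <- sum(w * (log_rr - mu_fe)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    mu <- sum(ws * log_rr) / sum(ws)
    se_mu <- sqrt(1 / sum(ws))
  }
  structure(list(rr = exp(mu),
                 ci_low = exp(mu - 1.96 * se_mu),
                 ci_high = exp(mu + 1.96 * se_mu),
                 log_rr = mu, se_log_rr = se_mu,
                 tau2 = tau2, q = q, k = k),
            class = "pooled_rr")
}

#' @export
print.pooled_rr <- function(x, ...) {
  cat(sprintf("Pooled RR (random effects, k=%d): %.4f (%.4f-%.4f), tau2 = %.3g\n",
              x$k, x$rr, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}
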