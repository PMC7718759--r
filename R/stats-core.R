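#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with the Welch--Satterthwaite degrees of freedom
#' and a two-sided p-value from the t distribution. This is the test used
#' throughout the pipeline to compare replicate fitness measurements.
#'
#' @param sample_a,sample_b Numeric vectors of at least 2 finite values each.
#' @return A list of class `welch_test` with components `t_statistic`,
#'   `df` (Welch--Satterthwaite), `p_value` (two-sided), and `mean_diff`
#'   (`mean(sample_a) - mean(sample_b)`).
#' @details If both samples have zero variance and equal means the test is
#'   degenerate; by convention `t = 0`, `p = 1` and `df = n1 + n2 - 2`.
#'   Zero variance in both samples with differing means violates the test's
#'   assumptions and is an error.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each sample needs at least 2 values", call. = FALSE)
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("welch_t_test: samples must be finite and free of NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  md <- m1 - m2
  if (v1 == 0 && v2 == 0) {
    if (md == 0) {
      res <- list(t_statistic = 0, df = n1 + n2 - 2, p_value = 1,
                  mean_diff = 0)
      class(res) <- "welch_test"
      return(res)
    }
    stop("welch_t_test: both samples have zero variance with differing means",
         call. = FALSE)
  }
  se2 <- v1 / n1 + v2 / n2
  tt <- md / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  res <- list(t_statistic = tt, df = df, p_value = p, mean_diff = md)
  class(res) <- "welch_test"
  res
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.3g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values to control the false discovery rate by the
#' step-up procedure: the i-th smallest p-value is multiplied by n/i and a
#' running minimum is taken from the largest rank down, capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\]. NA values are
#'   propagated and ignored in the ranking.
#' @return Adjusted p-values in the input order, each at least the raw value.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("bh_adjust: p-values must be in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n > 0L) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / seq(n, 1) * pv[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Z-score normalization
#'
#' Centers and scales a numeric vector to mean 0 and standard deviation 1.
#' Used for per-plate normalization of fitness ratios in the colony screen.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param ddof Delta degrees of freedom for the standard deviation:
#'   `ddof = 1` (default) uses the sample SD, `ddof = 0` the population SD.
#' @return Numeric vector of z-scores.
#' @details A vector with zero spread cannot be normalized; this raises a
#'   condition of class `chemscreen_degenerate` so callers can flag the plate
#'   rather than silently zero it.
#' @export
zscore <- function(values, ddof = 1) {
  x <- as.numeric(values)
  if (length(x) < 2L || any(!is.finite(x)))
    stop("zscore: need >= 2 finite values", call. = FALSE)
  if (!ddof %in% c(0, 1)) stop("zscore: ddof must be 0 or 1", call. = FALSE)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - ddof))
  # spread at floating-point rounding level counts as degenerate
  if (s == 0 || s < 1e-12 * mean(abs(x))) {
    cond <- structure(
      class = c("chemscreen_degenerate", "error", "condition"),
      list(message = "zscore: zero spread (degenerate plate)", call = NULL))
    stop(cond)
  }
  (x - m) / s
}

#' Trapezoidal area under a curve
#'
#' Integrates an OD600 (or any) series over time by the trapezoid rule.
#' This empirical AUC is the default fitness proxy for growth curves.
#'
#' @param times Numeric vector of time points (hours), strictly increasing.
#' @param od Numeric vector of the same length as `times`.
#' @return The integral in OD x hours.
#' @examples
#' trapezoid_auc(c(0, 12, 24), c(0.5, 0.5, 0.5))  # 12
#' @export
trapezoid_auc <- function(times, od) {
  t <- as.numeric(times); y <- as.numeric(od)
  if (length(t) != length(y) || length(t) < 2L)
    stop("trapezoid_auc: times and od must have equal length >= 2",
         call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("trapezoid_auc: inputs must be finite", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("trapezoid_auc: times must be strictly increasing", call. = FALSE)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Logistic growth curve
#'
#' Population size under logistic growth,
#' `N(t) = K / (1 + ((K - N0)/N0) * exp(-r t))`.
#'
#' @param t Time (hours).
#' @param K Carrying capacity (OD units).
#' @param r Intrinsic growth rate (per hour).
#' @param N0 Initial population (OD units).
#' @return N(t), same length as `t`.
#' @export
logistic_od <- function(t, K, r, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

#' Closed-form AUC of a logistic curve
#'
#' Exact integral of [logistic_od()] from 0 to `t_end`:
#' `(K/r) * log((N0*(exp(r*t_end) - 1) + K) / K)`.
#'
#' @inheritParams logistic_od
#' @param t_end Upper limit of integration (hours).
#' @return The exact area in OD x hours.
#' @export
logistic_auc_exact <- function(K, r, N0, t_end) {
  (K / r) * log((N0 * (exp(r * t_end) - 1) + K) / K)
}

#' Fit a logistic growth model to an OD600 time series
#'
#' Nonlinear least-squares fit of the logistic model
#' `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` by Levenberg-Marquardt.
#' Initialization is deterministic: `K` starts at the maximum OD, `N0` at the
#' first positive OD, and `r` at the slope of a log-linear regression over
#' the early phase (points up to half the maximum OD), so repeated fits of
#' the same data are bit-identical.
#'
#' @param curve_times Numeric vector of time points (hours), strictly
#'   increasing, at least 8 points.
#' @param od Non-negative OD values, same length as `curve_times`.
#' @param min_signal Minimum OD range (`max - min`) regarded as growth;
#'   below it the fit is flagged non-converged and only the empirical AUC
#'   is reported. Default 0.05 OD.
#' @return An object of class `logistic_fit`: a list with
#'   `carrying_capacity_K`, `growth_rate_r`, `initial_N0`, `rss`,
#'   `converged`, `auc_empirical` (trapezoid on the raw data),
#'   `auc_fitted` (closed-form integral of the fitted model, NA when not
#'   converged), and the data (`times`, `od`).
#' @seealso [predict.logistic_fit()], [residuals.logistic_fit()],
#'   [simulate.logistic_fit()]
#' @examples
#' tt <- seq(0, 24, by = 0.25)
#' fit <- fit_logistic(tt, logistic_od(tt, K = 1.2, r = 0.4, N0 = 0.05))
#' coef(fit)
#' @export
fit_logistic <- function(curve_times, od, min_signal = 0.05) {
  t <- as.numeric(curve_times); y <- as.numeric(od)
  if (length(t) != length(y) || length(t) < 8L)
    stop("fit_logistic: need >= 8 time points with matching od", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("fit_logistic: times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0))
    stop("fit_logistic: od must be finite and non-negative", call. = FALSE)

  out <- list(carrying_capacity_K = NA_real_, growth_rate_r = NA_real_,
              initial_N0 = NA_real_, rss = NA_real_, converged = FALSE,
              auc_empirical = trapezoid_auc(t, y), auc_fitted = NA_real_,
              times = t, od = y)
  class(out) <- "logistic_fit"

  if (max(y) - min(y) < min_signal) return(out)

  K0 <- max(y)
  N0_0 <- y[y > 0][1]
  if (is.na(N0_0)) return(out)
  # early phase: points up to half-max OD, at least 3, positive OD only
  idx <- which(y > 0 & y <= K0 / 2)
  if (length(idx) < 3L) idx <- utils::head(which(y > 0), 3L)
  r0 <- tryCatch(unname(stats::coef(stats::lm(log(y[idx]) ~ t[idx]))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
      start = list(K = K0, r = r0, N0 = max(N0_0, 1e-6)),
      lower = c(K = 1e-8, r = 1e-8, N0 = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)

  cf <- stats::coef(fit)
  if (cf[["N0"]] > cf[["K"]]) return(out)
  out$carrying_capacity_K <- cf[["K"]]
  out$growth_rate_r <- cf[["r"]]
  out$initial_N0 <- cf[["N0"]]
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- TRUE
  out$auc_fitted <- logistic_auc_exact(cf[["K"]], cf[["r"]], cf[["N0"]],
                                       max(t) - min(t))
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Logistic growth fit: K = %.4g OD, r = %.4g /h, N0 = %.4g OD (rss = %.3g)\n",
      x$carrying_capacity_K, x$growth_rate_r, x$initial_N0, x$rss))
  } else {
    cat("Logistic growth fit: not converged (no growth signal or fit failure)\n")
  }
  cat(sprintf("Empirical AUC: %.4g OD*h\n", x$auc_empirical))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  if (object$converged)
    cat(sprintf("Fitted AUC: %.4g OD*h over %d points spanning %.3g h\n",
                object$auc_fitted, length(object$times),
                max(object$times) - min(object$times)))
  invisible(object)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$carrying_capacity_K, r = object$growth_rate_r,
    N0 = object$initial_N0)
}

#' Predicted OD from a logistic fit
#'
#' @param object A [fit_logistic()] result.
#' @param times Time points at which to evaluate the fitted model; defaults
#'   to the observed times.
#' @param ... Unused.
#' @export
predict.logistic_fit <- function(object, times = object$times, ...) {
  if (!object$converged)
    stop("predict.logistic_fit: fit did not converge", call. = FALSE)
  logistic_od(times, object$carrying_capacity_K, object$growth_rate_r,
              object$initial_N0)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$od - predict(object)
}

#' @export
fitted.logistic_fit <- function(object, ...) predict(object)

#' Plot a logistic fit
#'
#' Observed OD600 against time with the fitted logistic curve overlaid.
#'
#' @param x A [fit_logistic()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.logistic_fit <- function(x, ...) {
  graphics::plot(x$times, x$od, xlab = "Time (h)", ylab = "OD600",
                 pch = 16, cex = 0.5, ...)
  if (x$converged) {
    tt <- seq(min(x$times), max(x$times), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate noisy curves from a logistic fit
#'
#' Draws replicate OD600 series from the fitted model with additive Gaussian
#' noise estimated from the fit residuals (or supplied).
#'
#' @param object A converged [fit_logistic()] result.
#' @param nsim Number of replicate curves.
#' @param seed Optional integer seed.
#' @param sd Noise standard deviation; defaults to the residual SD.
#' @param ... Unused.
#' @return A matrix with one column per simulated curve.
#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL, sd = NULL,
                                  ...) {
  if (!object$converged)
    stop("simulate.logistic_fit: fit did not converge", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd)) sd <- stats::sd(residuals(object))
  mu <- predict(object)
  m <- matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd),
              ncol = nsim)
  m[m < 0] <- 0
  m
}
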