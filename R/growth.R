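# Richards growth-curve fitting (A, mu_max, lambda, nu) and depletion-rate
# estimation for nutrient uptake.

#' Construct a growth curve
#'
#' @param times Numeric vector of time points in hours, strictly
#'   increasing, length >= 5.
#' @param values Matching vector of non-negative measurements: OD595 for
#'   growth curves, or concentration (e.g. uM) for depletion curves.
#' @return Data frame of class `growth_curve` with columns `time_hr`,
#'   `value`.
#' @export
growth_curve <- function(times, values) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (length(times) < 5L) stop("a growth curve needs at least 5 points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(values < 0)) stop("'values' must be non-negative")
  structure(data.frame(time_hr = as.numeric(times),
                       value = as.numeric(values)),
            class = c("growth_curve", "data.frame"))
}

#' Richards growth model
#'
#' The four-parameter Richards curve in its growth-analysis
#' parameterisation, where `A` is the asymptote (OD595), `mu_max` the
#' maximum slope (OD595/hr), `lambda` the lag time (hr, the intercept of
#' the tangent at maximum slope with the baseline), and `nu` (> 0) the
#' shape parameter controlling asymmetry:
#' \deqn{y(t) = A \left[1 + \nu e^{1+\nu}
#'   e^{(\mu_{max}/A)(1+\nu)^{1+1/\nu}(\lambda - t)}\right]^{-1/\nu}.}
#' At `nu = 1` it reduces to the logistic growth form; `y` is
#' non-decreasing in `t` and tends to `A`.
#'
#' @param t Time(s) in hours.
#' @param A Asymptote (> 0).
#' @param mu_max Maximum slope (>= 0).
#' @param lambda Lag time (hr).
#' @param nu Shape parameter (> 0).
#' @return Model value(s) at `t`.
#' @examples
#' richards_value(10, A = 1.2, mu_max = 0.2, lambda = 5, nu = 1)
#' @export
richards_value <- function(t, A, mu_max, lambda, nu) {
  if (!all(is.finite(c(A, mu_max, lambda, nu))))
    stop("Richards parameters must be finite")
  if (A <= 0) stop("'A' must be > 0")
  if (mu_max < 0) stop("'mu_max' must be >= 0")
  if (nu <= 0) stop("'nu' must be > 0")
  A * (1 + nu * exp(1 + nu) *
         exp((mu_max / A) * (1 + nu)^(1 + 1 / nu) * (lambda - t)))^(-1 / nu)
}

richards_init <- function(times, values) {
  rng <- diff(range(values))
  slopes <- diff(values) / diff(times)
  lam0 <- times[which(values > min(values) + 0.05 * rng)[1]]
  if (is.na(lam0)) lam0 <- times[1]
  list(A = max(values),
       mu_max = max(max(slopes), 1e-6),
       lambda = lam0,
       nu = 1)
}

#' Fit the Richards model to a growth curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with deterministic
#' initialisation: `A` = maximum observed value, `mu_max` = maximum
#' finite-difference slope, `lambda` = first time the value exceeds 5% of
#' the observed range above the minimum, `nu` = 1. No random restarts, so
#' the fit is reproducible from the data alone.
#'
#' A curve with (numerically) no growth, or a fit that fails to converge,
#' is returned flagged (`converged = FALSE`) with the initialisation values
#' rather than raising an error.
#'
#' @param curve A [growth_curve()] (or anything with `time_hr`/`value`
#'   columns) with >= 8 points spanning lag and saturation.
#' @param offset If `TRUE`, an additive baseline parameter `y0` is
#'   estimated alongside the Richards terms, making `mu_max` invariant to a
#'   constant shift of the curve.
#' @return Object of class `growth_fit`: list with `A`, `mu_max`, `lambda`,
#'   `nu`, (`y0` when `offset`), `rss`, `converged`, `fitted`, `curve`.
#' @examples
#' tm <- seq(0, 30, length.out = 30)
#' cv <- growth_curve(tm, richards_value(tm, 1.2, 0.2, 5, 1))
#' fit_richards(cv)
#' @export
fit_richards <- function(curve, offset = FALSE) {
  stopifnot(all(c("time_hr", "value") %in% names(curve)))
  t <- curve$time_hr; y <- curve$value
  if (length(t) < 8L) stop("fitting needs at least 8 points")
  init <- richards_init(t, y)
  flat <- diff(range(y)) < 1e-8
  out <- c(init, list(y0 = if (offset) min(y) else NULL))
  fit <- NULL
  if (!flat) {
    form <- if (offset)
      y ~ y0 + richards_value(t, A, mu_max, lambda, nu)
    else
      y ~ richards_value(t, A, mu_max, lambda, nu)
    start <- if (offset) c(init, y0 = min(y)) else init
    lower <- if (offset) c(1e-8, 0, -Inf, 1e-6, -Inf)
             else c(1e-8, 0, -Inf, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    fitted <- rep(mean(y), length(t))
    res <- list(A = init$A, mu_max = if (flat) 0 else init$mu_max,
                lambda = init$lambda, nu = init$nu,
                y0 = if (offset) min(y) else NULL,
                rss = sum((y - fitted)^2), converged = FALSE,
                fitted = fitted, curve = curve)
  } else {
    cf <- as.list(stats::coef(fit))
    res <- list(A = cf$A, mu_max = cf$mu_max, lambda = cf$lambda,
                nu = cf$nu, y0 = cf$y0,
                rss = sum(stats::resid(fit)^2), converged = TRUE,
                fitted = as.numeric(stats::fitted(fit)), curve = curve)
  }
  structure(res, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(paste0("<growth_fit>%s A = %.4g, mu_max = %.4g/hr, ",
                     "lambda = %.4g hr, nu = %.4g, rss = %.3g\n"),
              if (x$converged) "" else " [NOT CONVERGED]",
              x$A, x$mu_max, x$lambda, x$nu, x$rss))
  invisible(x)
}

#' Maximum nutrient depletion rate from a concentration time series
#'
#' Reflects the falling concentration curve (`max(value) - value`) so that
#' uptake appears as growth, then fits both the Richards family and a
#' straight line and reports the maximum slope of whichever fits better
#' (lower residual sum of squares; ties go to the line). A flat series
#' yields rate 0; a series with an overall rising trend is flagged with a
#' warning and yields rate 0.
#'
#' @param curve A [growth_curve()] of extracellular concentration (e.g. uM)
#'   over hours, >= 5 points.
#' @return List of class `depletion_fit`: `rate` (concentration units per
#'   hour, >= 0), `model` (`"richards"`, `"linear"`, `"flat"`, or
#'   `"rising"`), and `fit` (the underlying fit object or `NULL`).
#' @examples
#' tm <- 0:10
#' estimate_depletion_rate(growth_curve(tm, 100 - 2 * tm))  # 2 per hour
#' @export
estimate_depletion_rate <- function(curve) {
  stopifnot(all(c("time_hr", "value") %in% names(curve)))
  t <- curve$time_hr; v <- curve$value
  if (diff(range(v)) < 1e-12)
    return(structure(list(rate = 0, model = "flat", fit = NULL),
                     class = "depletion_fit"))
  trend <- stats::coef(stats::lm(v ~ t))[["t"]]
  if (trend > 0) {
    warning("concentrations rise over time; depletion rate reported as 0")
    return(structure(list(rate = 0, model = "rising", fit = NULL),
                     class = "depletion_fit"))
  }
  y <- max(v) - v
  lin <- stats::lm(y ~ t)
  rss_lin <- sum(stats::resid(lin)^2)
  rich <- if (length(t) >= 8L)
    tryCatch(fit_richards(data.frame(time_hr = t, value = y)),
             error = function(e) NULL)
  else NULL
  if (!is.null(rich) && rich$converged && rich$rss < rss_lin) {
    structure(list(rate = rich$mu_max, model = "richards", fit = rich),
              class = "depletion_fit")
  } else {
    structure(list(rate = max(stats::coef(lin)[["t"]], 0), model = "linear",
                   fit = lin),
              class = "depletion_fit")
  }
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("<depletion_fit> rate = %.4g per hr (%s fit)\n",
              x$rate, x$model))
  invisible(x)
}
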