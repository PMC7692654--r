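# First-order isothermal degradation kinetics and the derived
# thermal-resistance parameters (k, D, t1/2, z, Ea).

#' Universal gas constant, J mol^-1 K^-1
#' @export
GAS_CONSTANT <- 8.314

celsius_to_kelvin <- function(t_c) t_c + 273.15

# OLS line with slope SE and r2 computed from residuals directly
# (summary.lm warns on exact fits, which are routine here).
ols_line <- function(x, y) {
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  n <- length(x)
  df <- n - 2L
  ssr <- sum(res^2)
  sxx <- sum((x - mean(x))^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = if (df > 0) sqrt(ssr / df / sxx) else NA_real_,
       r_squared = if (sst > .Machine$double.eps)
         max(0, min(1, 1 - ssr / sst)) else 0,
       df = df)
}

#' A concentration (or activity) vs time record at one temperature
#'
#' @param temperature Holding temperature, degrees C.
#' @param times Sampling times in minutes; strictly increasing, first
#'   element 0.
#' @param values Concentration or activity readings, same unit
#'   throughout; the value at t = 0 must be strictly positive.
#' @param replicate_id Optional replicate label.
#' @return An object of class `decay_series`.
#' @export
decay_series <- function(temperature, times, values, replicate_id = NULL) {
  if (!is.numeric(times) || !is.numeric(values) ||
      length(times) != length(values)) {
    stop("validation error: times and values must be numeric and equal length",
         call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop("validation error: non-finite time or value", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("insufficient data: need at least 3 time points", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("validation error: first sampling time must be 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("validation error: times must be strictly increasing", call. = FALSE)
  }
  if (values[1] <= 0) {
    stop("validation error: value at t = 0 must be strictly positive",
         call. = FALSE)
  }
  structure(list(temperature = temperature, times = times, values = values,
                 replicate_id = replicate_id), class = "decay_series")
}

#' Fit a first-order degradation rate constant
#'
#' Regresses `ln(C_t / C_0)` on time by ordinary least squares with a
#' free intercept and reports `k = -slope` with its standard error. A
#' free intercept keeps the fit robust to measurement error in the
#' initial reading; the intercept is reported so the forced-origin
#' variant is recoverable. Degradation is called significant when a
#' one-sided t-test rejects slope >= 0 at level `alpha`.
#'
#' @param series A [decay_series()].
#' @param alpha Significance level for the slope test (default 0.05).
#' @return An object of class `rate_fit` with fields `k`, `k_se`,
#'   `intercept`, `r_squared`, `n_points`, `significant_degradation`,
#'   `p_value`, `alpha`, `temperature`.
#' @examples
#' s <- decay_series(120, c(0, 2, 5, 7, 10, 20, 30, 40),
#'                   exp(-0.05 * c(0, 2, 5, 7, 10, 20, 30, 40)))
#' fit_first_order_rate(s)$k  # 0.05
#' @export
fit_first_order_rate <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "decay_series"))
  if (any(series$values <= 0)) {
    bad <- series$times[series$values <= 0]
    stop(sprintf(
      "transform error: non-positive value at t = %s min cannot be log-transformed",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  y <- log(series$values / series$values[1])
  t <- series$times
  fit <- ols_line(t, y)
  slope <- fit$slope
  intercept <- fit$intercept
  se <- fit$slope_se
  r2 <- fit$r_squared
  # one-sided test of slope < 0; an exact fit (zero residual) is decided
  # by the sign of the slope alone
  if (is.finite(se) && se > 0) {
    p_val <- stats::pt(slope / se, df = fit$df)
  } else {
    p_val <- if (slope < -.Machine$double.eps) 0 else 1
  }
  structure(list(
    k = max(0, -slope),
    k_se = se,
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    n_points = length(t),
    significant_degradation = is.finite(p_val) && p_val < alpha,
    p_value = p_val,
    alpha = alpha,
    temperature = series$temperature
  ), class = "rate_fit")
}

#' Decimal reduction time
#'
#' Time at constant temperature for a 10-fold reduction under
#' first-order decay: `D = ln(10) / k`.
#'
#' @param k First-order rate constant, min^-1 (vectorised, all > 0).
#' @return D in minutes.
#' @export
decimal_reduction_time <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("no degradation: D-value requires k > 0", call. = FALSE)
  }
  log(10) / k
}

#' Half-life under first-order decay
#'
#' `t1/2 = ln(2) / k`, the time for 50% loss.
#'
#' @param k First-order rate constant, min^-1 (vectorised, all > 0).
#' @return Half-life in minutes.
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("no degradation: half-life requires k > 0", call. = FALSE)
  }
  log(2) / k
}

#' z-value from decimal reduction times
#'
#' Fits `log10(D)` against temperature by ordinary least squares; the
#' z-value (temperature increase causing a 10-fold drop in D) is the
#' negative reciprocal slope. Its standard error follows from the slope
#' standard error by the delta method, `se(z) = se(slope) / slope^2`.
#'
#' @param temperatures Temperatures in degrees C (>= 3 values).
#' @param d_values Decimal reduction times, min, all > 0.
#' @return List with `z_value` (degrees C), `z_se`, `r_squared`,
#'   `slope`, `slope_se`, `n_temps`, and logical `non_physical` (TRUE
#'   when D does not decrease with temperature, in which case z is NA).
#' @export
fit_z_value <- function(temperatures, d_values) {
  if (length(temperatures) != length(d_values)) {
    stop("validation error: temperatures and d_values differ in length",
         call. = FALSE)
  }
  if (length(unique(temperatures)) < 3L) {
    stop("insufficient data: need at least 3 distinct temperatures",
         call. = FALSE)
  }
  if (any(d_values <= 0)) {
    stop("validation error: all D values must be > 0", call. = FALSE)
  }
  fit <- ols_line(temperatures, log10(d_values))
  slope <- fit$slope
  slope_se <- fit$slope_se
  r2 <- fit$r_squared
  if (slope >= 0) {
    warning("non-physical fit: D does not decrease with temperature")
    return(list(z_value = NA_real_, z_se = NA_real_, r_squared = r2,
                slope = slope, slope_se = slope_se,
                n_temps = length(temperatures), non_physical = TRUE))
  }
  list(z_value = -1 / slope,
       z_se = slope_se / slope^2,
       r_squared = r2,
       slope = slope, slope_se = slope_se,
       n_temps = length(temperatures), non_physical = FALSE)
}

#' Arrhenius fit of rate constants across temperature
#'
#' Fits `ln(k)` against reciprocal absolute temperature (`T_K = T_C +
#' 273.15`) by ordinary least squares. The activation energy is
#' `Ea = -slope * R` with R = 8.314 J mol^-1 K^-1, reported in kJ/mol;
#' the slope standard error propagates linearly to `ea_se`. Duplicate
#' temperatures are collapsed to their geometric-mean k (with a
#' message) before fitting.
#'
#' @param temperatures Temperatures in degrees C (>= 3 distinct values).
#' @param k Rate constants, min^-1, all > 0.
#' @return An object of class `arrhenius_fit` with fields `ea`, `ea_se`
#'   (kJ/mol), `ln_pre_exponential`, `slope`, `slope_se` (K),
#'   `r_squared`, `n_temps`.
#' @export
fit_arrhenius <- function(temperatures, k) {
  if (length(temperatures) != length(k)) {
    stop("validation error: temperatures and k differ in length",
         call. = FALSE)
  }
  if (any(k <= 0)) {
    stop("validation error: all rate constants must be > 0", call. = FALSE)
  }
  if (anyDuplicated(temperatures)) {
    message("duplicate temperatures collapsed by geometric-mean k")
    agg <- tapply(log(k), temperatures, mean)
    temperatures <- as.numeric(names(agg))
    k <- exp(unname(agg))
  }
  if (length(temperatures) < 3L) {
    stop("insufficient data: need at least 3 distinct temperatures",
         call. = FALSE)
  }
  fit <- ols_line(1 / celsius_to_kelvin(temperatures), log(k))
  structure(list(
    ea = -fit$slope * GAS_CONSTANT / 1000,
    ea_se = fit$slope_se * GAS_CONSTANT / 1000,
    ln_pre_exponential = fit$intercept,
    slope = fit$slope,
    slope_se = fit$slope_se,
    r_squared = fit$r_squared,
    n_temps = length(temperatures)
  ), class = "arrhenius_fit")
}

#' Model-implied percent retention
#'
#' `100 * exp(-k * t)`: the percentage of the initial content remaining
#' after `minutes` at the temperature whose rate constant is `k`.
#'
#' @param k First-order rate constant, min^-1 (>= 0).
#' @param minutes Holding time, min (>= 0).
#' @return Percent remaining (0-100].
#' @export
predicted_retention <- function(k, minutes) {
  if (any(k < 0)) stop("parameter error: k must be >= 0", call. = FALSE)
  if (any(minutes < 0)) {
    stop("parameter error: duration must be >= 0", call. = FALSE)
  }
  100 * exp(-k * minutes)
}

# Average replicicate readings at identical (temperature, time) points.
# Returns one decay_series per temperature.
pool_replicates <- function(series_list) {
  temps <- vapply(series_list, function(s) s$temperature, numeric(1))
  lapply(sort(unique(temps)), function(tt) {
    grp <- series_list[temps == tt]
    df <- do.call(rbind, lapply(grp, function(s)
      data.frame(time = s$times, value = s$values)))
    agg <- stats::aggregate(value ~ time, df, mean)
    agg <- agg[order(agg$time), ]
    decay_series(tt, agg$time, agg$value)
  })
}

#' Summarise degradation kinetics across temperatures
#'
#' Fits a first-order model at each temperature (replicates at the same
#' temperature and time are averaged first), derives D and t1/2 for
#' temperatures with statistically significant degradation, classifies
#' the remainder as thermostable, and fits the Arrhenius activation
#' energy and z-value across the significant temperatures. Ea and z are
#' flagged unavailable when fewer than 3 temperatures show significant
#' degradation.
#'
#' @param series_list A list of [decay_series()] (replicates allowed).
#' @param alpha Significance level for the per-temperature slope test.
#' @return An object of class `thermal_summary`: `rows` (data frame
#'   with `temperature_c`, `k_per_min`, `k_se`, `d_value_min`,
#'   `half_life_min`, `r_squared`, `significant`), `thermostable`
#'   (temperatures with no significant degradation), `arrhenius`
#'   (an `arrhenius_fit` or NULL), `z` (a z fit list or NULL), `alpha`.
#' @export
summarize_kinetics <- function(series_list, alpha = 0.05) {
  if (inherits(series_list, "decay_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, logical(1), "decay_series")))
  pooled <- pool_replicates(series_list)
  fits <- lapply(pooled, fit_first_order_rate, alpha = alpha)

  sig <- vapply(fits, function(f) f$significant_degradation, logical(1))
  temps <- vapply(fits, function(f) f$temperature, numeric(1))

  n_sig <- sum(sig)
  rows <- data.frame(
    temperature_c = temps[sig],
    k_per_min = vapply(fits[sig], function(f) f$k, numeric(1)),
    k_se = vapply(fits[sig], function(f) f$k_se, numeric(1)),
    d_value_min = rep(NA_real_, n_sig),
    half_life_min = rep(NA_real_, n_sig),
    r_squared = vapply(fits[sig], function(f) f$r_squared, numeric(1)),
    significant = rep(TRUE, n_sig)
  )
  if (nrow(rows)) {
    rows$d_value_min <- decimal_reduction_time(rows$k_per_min)
    rows$half_life_min <- half_life(rows$k_per_min)
    rows <- rows[order(rows$temperature_c), ]
    rownames(rows) <- NULL
  }

  arr <- NULL
  zfit <- NULL
  if (sum(sig) >= 3L) {
    arr <- fit_arrhenius(rows$temperature_c, rows$k_per_min)
    zfit <- fit_z_value(rows$temperature_c, rows$d_value_min)
  }
  structure(list(rows = rows,
                 thermostable = sort(temps[!sig]),
                 arrhenius = arr, z = zfit,
                 fits = fits, alpha = alpha),
            class = "thermal_summary")
}

#' Compare zero- and first-order model fits
#'
#' Optional model-selection helper: fits both a zero-order (`C` vs `t`)
#' and first-order (`ln C` vs `t`) line to a decay series and reports
#' the correlation coefficient (r-squared) of each. First-order is the
#' package default throughout; this diagnostic documents that choice on
#' a given dataset.
#'
#' @param series A [decay_series()].
#' @return List with `r_squared_zero_order`, `r_squared_first_order`,
#'   and `preferred` (`"zero"` or `"first"`, by larger r-squared; ties
#'   go to first-order).
#' @export
compare_reaction_orders <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$times
  r2 <- function(y) {
    f <- stats::lm(y ~ t)
    sst <- sum((y - mean(y))^2)
    if (sst <= .Machine$double.eps) return(0)
    max(0, min(1, 1 - sum(stats::residuals(f)^2) / sst))
  }
  r2_zero <- r2(series$values)
  r2_first <- if (all(series$values > 0)) r2(log(series$values)) else NA_real_
  list(r_squared_zero_order = r2_zero,
       r_squared_first_order = r2_first,
       preferred = if (!is.na(r2_first) && r2_first >= r2_zero)
         "first" else "zero")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "First-order fit at %g degC: k = %.4g +/- %.2g min^-1 (r2 = %.3f, n = %d)\n",
    x$temperature, x$k, x$k_se, x$r_squared, x$n_points))
  cat(sprintf("  degradation %ssignificant at alpha = %g (p = %.3g)\n",
              if (x$significant_degradation) "" else "NOT ", x$alpha,
              x$p_value))
  invisible(x)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures: Ea = %.2f +/- %.2f kJ/mol (r2 = %.3f)\n",
              x$n_temps, x$ea, x$ea_se, x$r_squared))
  invisible(x)
}

#' @export
print.thermal_summary <- function(x, ...) {
  cat("Thermal degradation summary\n")
  if (length(x$thermostable)) {
    cat("  thermostable (no significant degradation):",
        paste(x$thermostable, collapse = ", "), "degC\n")
  }
  if (nrow(x$rows)) {
    print(x$rows, digits = 4)
  } else {
    cat("  no temperatures with significant degradation\n")
  }
  if (!is.null(x$arrhenius)) {
    cat(sprintf("  Ea = %.2f +/- %.2f kJ/mol (r2 = %.3f)\n",
                x$arrhenius$ea, x$arrhenius$ea_se, x$arrhenius$r_squared))
  }
  if (!is.null(x$z) && !x$z$non_physical) {
    cat(sprintf("  z  = %.2f +/- %.2f degC (r2 = %.3f)\n",
                x$z$z_value, x$z$z_se, x$z$r_squared))
  }
  if (is.null(x$arrhenius)) {
    cat("  Ea/z unavailable (< 3 significant temperatures)\n")
  }
  invisible(x)
}
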