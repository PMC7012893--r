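#' Fit a log-linear dose-response calibration
#'
#' Ordinary least squares of mean signal on log10(concentration), the
#' standard model for an electrochemical titration whose linear range
#' spans several decades. Rows with `concentration_m == 0` are treated as
#' blank replicates (signal at zero analyte) and feed the blank mean/sd
#' used by the 3-delta detection limit; blanks may instead be supplied
#' via the `blanks` argument. The fit is performed on per-level mean
#' signals; the residual sd is pooled over all replicate residuals around
#' the fitted line (denominator `n - 2`).
#'
#' @param data Tibble with columns `concentration_m` (molar) and
#'   `signal_a` (amperes); an optional `replicate` column is carried
#'   along but not used by the fit.
#' @param blanks Optional numeric vector of blank signals; overrides any
#'   zero-concentration rows in `data`.
#'
#' @return A `calibration_fit` object with elements `slope`, `intercept`
#'   (signal vs log10 molar), `residual_sd`, `blank_mean`, `blank_sd`,
#'   `n_blanks`, `levels` (calibrated concentrations), and `data`.
#' @examples
#' cal <- make_calibration_dataset(seed = 1)
#' fit <- fit_log_linear(cal)
#' glance(fit)
#' @export
fit_log_linear <- function(data, blanks = NULL) {
  data <- as_tibble(data)
  if (!all(c("concentration_m", "signal_a") %in% names(data))) {
    stop_bad_arg("`data` must have columns concentration_m and signal_a.")
  }
  if (any(data$concentration_m < 0)) {
    stop_bad_arg("concentrations must be nonnegative (0 marks blanks).")
  }
  if (is.null(blanks)) {
    blanks <- data$signal_a[data$concentration_m == 0]
  }
  cal <- data[data$concentration_m > 0, , drop = FALSE]
  levels <- sort(unique(cal$concentration_m))
  if (length(levels) < 3L) {
    stop_bad_arg("need at least 3 distinct nonzero concentration levels.")
  }
  means <- cal |>
    dplyr::group_by(.data$concentration_m) |>
    dplyr::summarise(signal_a = mean(.data$signal_a), .groups = "drop") |>
    dplyr::mutate(log10_c = log10(.data$concentration_m))
  if (sd(means$log10_c) == 0) {
    stop_bad_arg("zero variance in log10(concentration).")
  }
  fit <- lm(signal_a ~ log10_c, data = means)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_tot <- sum((means$signal_a - mean(means$signal_a))^2)
  r_squared <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  resid_all <- cal$signal_a - (intercept + slope * log10(cal$concentration_m))
  residual_sd <- if (nrow(cal) > 2L) {
    sqrt(sum(resid_all^2) / (nrow(cal) - 2L))
  } else {
    0
  }
  structure(
    list(
      slope = slope,
      intercept = intercept,
      residual_sd = residual_sd,
      blank_mean = if (length(blanks)) mean(blanks) else NA_real_,
      blank_sd = if (length(blanks) > 1L) sd(blanks) else 0,
      n_blanks = length(blanks),
      levels = levels,
      r_squared = r_squared,
      data = cal
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> signal = %.4g * log10(c) + %.4g\n  %d levels (%.3g to %.3g M), residual sd %.3g, %d blanks\n",
    x$slope, x$intercept, length(x$levels),
    min(x$levels), max(x$levels), x$residual_sd, x$n_blanks
  ))
  invisible(x)
}

#' @describeIn fit_log_linear Coefficients as a two-row tibble.
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @describeIn fit_log_linear One-row fit summary including the 3-delta
#'   detection limit and the dynamic range in decades.
#' @export
glance.calibration_fit <- function(x, ...) {
  lod <- tryCatch(lod_3delta(x), error = function(e) NA_real_)
  tibble(
    slope = x$slope,
    intercept = x$intercept,
    residual_sd = x$residual_sd,
    r_squared = x$r_squared,
    blank_mean = x$blank_mean,
    blank_sd = x$blank_sd,
    lod_molar = as.numeric(lod),
    dynamic_range_decades = log10(max(x$levels) / min(x$levels))
  )
}

#' @describeIn fit_log_linear Predicted signal at new concentrations
#'   (molar).
#' @param object A `calibration_fit`.
#' @param concentration_m Concentrations at which to predict.
#' @export
predict.calibration_fit <- function(object, concentration_m, ...) {
  if (any(concentration_m <= 0)) stop_bad_arg("concentrations must be positive.")
  object$intercept + object$slope * log10(concentration_m)
}

#' Invert a calibration: concentration from signal
#'
#' @param fit A `calibration_fit`.
#' @param signal_a Signal(s) in amperes.
#' @return Concentration(s) in molar.
#' @export
invert_calibration <- function(fit, signal_a) {
  if (fit$slope == 0) stop_bad_arg("cannot invert a flat calibration.")
  10^((signal_a - fit$intercept) / fit$slope)
}

#' 3-delta detection limit
#'
#' The limit of detection under the 3-delta rule: the concentration whose
#' predicted signal equals the blank mean plus three blank standard
#' deviations (sample sd, n - 1), mapped through the inverse calibration:
#' `LOD = 10^((blank_mean + 3 * blank_sd - intercept) / slope)`. If the
#' LOD falls below the lowest calibrated level the value is extrapolated
#' and flagged with a warning and an `extrapolated` attribute.
#'
#' @param fit A `calibration_fit` with positive slope and blank
#'   statistics.
#' @return LOD in molar (attribute `extrapolated`).
#' @export
lod_3delta <- function(fit) {
  if (!inherits(fit, "calibration_fit")) stop_bad_arg("`fit` must be a calibration_fit.")
  if (is.na(fit$blank_mean)) stop_bad_arg("fit has no blank replicates.")
  if (fit$slope <= 0) stop_bad_arg("3-delta LOD requires a positive slope.")
  lod <- 10^((fit$blank_mean + 3 * fit$blank_sd - fit$intercept) / fit$slope)
  extrapolated <- lod < min(fit$levels)
  if (extrapolated) {
    warn(sprintf(
      "LOD %.3g M lies below the lowest calibrated level %.3g M (extrapolation).",
      lod, min(fit$levels)
    ))
  }
  structure(lod, extrapolated = extrapolated)
}

#' Signal gain relative to a reference
#'
#' Fold enhancement of a signal over a reference signal (e.g. an
#' interleaved-enzyme electrode versus the same enzymes free in
#' solution).
#'
#' @param signal Signal value(s).
#' @param reference Reference value (positive).
#' @return `signal / reference`.
#' @examples
#' signal_gain(25, 2) # 12.5-fold
#' @export
signal_gain <- function(signal, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop_bad_arg("`reference` must be positive.")
  }
  signal / reference
}

#' Inverse-distance model of cascade velocity
#'
#' Least-squares fit of reaction velocity against the reciprocal
#' inter-enzyme distance, `v = a / d + b` — the empirical behaviour of a
#' two-enzyme cascade whose intermediate must diffuse between active
#' sites. When per-distance assembly yields are supplied, velocities are
#' first corrected as `v / yield`.
#'
#' @param data Tibble with columns `distance_nm` (positive, strictly
#'   increasing recommended), `velocity` (nonnegative), and optionally
#'   `yield` in (0, 1].
#'
#' @return An `inverse_distance_fit` with elements `a`, `b`,
#'   `residual_ss`, and `data` (including `velocity_corrected`).
#' @examples
#' d <- tibble::tibble(distance_nm = c(10, 30, 50, 70), velocity = 6 / c(10, 30, 50, 70))
#' fit_inverse_distance(d)
#' @export
fit_inverse_distance <- function(data) {
  data <- as_tibble(data)
  if (!all(c("distance_nm", "velocity") %in% names(data))) {
    stop_bad_arg("`data` must have columns distance_nm and velocity.")
  }
  if (nrow(data) < 3L) stop_bad_arg("need at least 3 distances.")
  if (any(data$distance_nm <= 0)) stop_bad_arg("distances must be positive.")
  if (any(data$velocity < 0)) stop_bad_arg("velocities must be nonnegative.")
  data <- apply_yield(data)
  fit <- lm(velocity_corrected ~ I(1 / distance_nm), data = data)
  structure(
    list(
      a = unname(coef(fit)[2]),
      b = unname(coef(fit)[1]),
      residual_ss = sum(stats::residuals(fit)^2),
      data = data
    ),
    class = "inverse_distance_fit"
  )
}

apply_yield <- function(data) {
  if ("yield" %in% names(data) && !all(is.na(data$yield))) {
    if (any(data$yield <= 0 | data$yield > 1, na.rm = TRUE) || anyNA(data$yield)) {
      stop_bad_arg("`yield` values must lie in (0, 1].")
    }
    dplyr::mutate(data, velocity_corrected = .data$velocity / .data$yield)
  } else {
    dplyr::mutate(data, velocity_corrected = .data$velocity)
  }
}

#' @export
print.inverse_distance_fit <- function(x, ...) {
  cat(sprintf(
    "<inverse_distance_fit> v = %.4g / d + %.4g (residual SS %.3g)\n",
    x$a, x$b, x$residual_ss
  ))
  invisible(x)
}

#' @describeIn fit_inverse_distance Coefficients as a tibble.
#' @param x An `inverse_distance_fit`.
#' @param ... Unused.
#' @export
tidy.inverse_distance_fit <- function(x, ...) {
  tibble(term = c("a (nm * v)", "b"), estimate = c(x$a, x$b))
}

#' @describeIn fit_inverse_distance One-row summary.
#' @export
glance.inverse_distance_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, residual_ss = x$residual_ss, n = nrow(x$data))
}

#' Critical coupling length from distance-velocity data
#'
#' The critical coupling length (CCL) is the largest inter-enzyme
#' distance at which the cascade still transfers its intermediate
#' efficiently. It is estimated here by a half-max rule: the smallest
#' measured distance whose yield-corrected velocity is at least
#' `threshold_fraction` (default 0.5) of the maximum corrected velocity.
#' The threshold is a documented parameter of the estimate and is
#' recorded in the output.
#'
#' @inheritParams fit_inverse_distance
#' @param threshold_fraction Fraction of the maximum corrected velocity a
#'   distance must retain to count as coupled (default 0.5).
#'
#' @return One-row tibble: `ccl_nm`, `threshold_fraction`,
#'   `max_velocity_corrected`.
#' @examples
#' d <- tibble::tibble(
#'   distance_nm = c(10, 30, 50, 70),
#'   velocity = c(1.0, 0.4, 0.2, 0.1)
#' )
#' ccl_estimate(d)
#' @export
ccl_estimate <- function(data, threshold_fraction = 0.5) {
  data <- as_tibble(data)
  if (!all(c("distance_nm", "velocity") %in% names(data))) {
    stop_bad_arg("`data` must have columns distance_nm and velocity.")
  }
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop_bad_arg("`threshold_fraction` must lie in (0, 1].")
  }
  data <- apply_yield(data)
  vmax <- max(data$velocity_corrected)
  coupled <- data$distance_nm[data$velocity_corrected >= threshold_fraction * vmax]
  if (!length(coupled)) stop_bad_arg("no distance reaches the velocity threshold.")
  tibble(
    ccl_nm = min(coupled),
    threshold_fraction = threshold_fraction,
    max_velocity_corrected = vmax
  )
}

#' @describeIn fit_log_linear Calibration points and fitted line on a log
#'   concentration axis.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot(object$data, aes(x = log10(.data$concentration_m), y = .data$signal_a)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      color = "steelblue"
    ) +
    ggplot2::labs(
      x = expression(log[10] ~ "concentration (M)"),
      y = "signal (A)",
      title = "Log-linear dose-response calibration"
    ) +
    ggplot2::theme_minimal()
}
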