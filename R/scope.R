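#' Loess fit of per-embryo MO2 against wet weight
#'
#' Locally weighted polynomial regression (degree 2, tricube weights) of
#' per-embryo oxygen consumption on embryo wet weight at one temperature
#' class, as used to smooth TIMR-min / TIMR-max rates before computing the
#' thermal metabolic scope. Predictions are restricted to the observed
#' weight range (no extrapolation).
#'
#' @param rates metabolic-rate table from [process_run()] (`$rates`), or
#'   any data.frame with `weight_g`, `mo2_per_embryo` and either `temp_c`
#'   or `temperature_class`.
#' @param temperature temperature (degrees C) or class label ("LMR",
#'   "RMR", "HMR") selecting the subset; NULL uses all rows.
#' @param span loess span as a fraction of points. The default `NULL`
#'   picks `min(1, max(0.15, 35/n))`, i.e. a neighborhood of about 35
#'   points but never less than 15% of the data: with the few hundred
#'   embryos of a typical TIMR campaign this resolves features at the
#'   ~0.01 g scale of the activation step, which a fixed span of 0.5
#'   over-smooths (see the package vignette).
#' @param grid_n size of the internal prediction grid (default 200).
#' @return object of class `smooth_fit` with the loess fit, the weight
#'   grid and predicted MO2.
#' @export
fit_mo2_weight <- function(rates, temperature = NULL, span = NULL,
                           grid_n = 200) {
  d <- rates
  if (!is.null(temperature)) {
    sel <- if (is.numeric(temperature)) d$temp_c == temperature else
      d$temperature_class == temperature
    d <- d[sel & !is.na(sel), ]
  }
  if (nrow(d) < 10) {
    stopf("need >= 10 rates to fit a loess curve (got %d)", nrow(d))
  }
  span <- span %||% min(1, max(0.15, 35 / nrow(d)))
  fit <- stats::loess(mo2_per_embryo ~ weight_g, data = d, span = span,
                      degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  rng <- range(d$weight_g)
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  structure(list(fit = fit, temperature = temperature, span = span,
                 weight_range = rng, weight_grid = grid,
                 predicted_mo2 = as.numeric(stats::predict(fit, grid)),
                 n_points = nrow(d)),
            class = "smooth_fit")
}

#' Predict from a smooth MO2-weight fit (no extrapolation)
#'
#' @param object a `smooth_fit`.
#' @param weights weights (g) at which to predict; must lie within the
#'   observed range or an error is raised.
#' @param ... unused.
#' @return predicted per-embryo MO2, mg O2 h^-1 embryo^-1.
#' @export
predict.smooth_fit <- function(object, weights = object$weight_grid, ...) {
  rng <- object$weight_range
  if (any(weights < rng[1] | weights > rng[2])) {
    stopf("prediction outside the observed weight range [%.4g, %.4g]",
          rng[1], rng[2])
  }
  as.numeric(stats::predict(object$fit, weights))
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("<smooth_fit> loess span %.2g, degree 2, n = %d, weights %.4g-%.4g g\n",
              x$span, x$n_points, x$weight_range[1], x$weight_range[2]))
  invisible(x)
}

#' Thermal and factorial metabolic scope from two smooth fits
#'
#' On the intersection of the two fits' weight ranges, evaluates both
#' curves on a common grid and derives the thermal metabolic scope
#' `TMS = HMR - LMR` (difference between predicted TIMR-max and TIMR-min
#' oxygen consumption) and the factorial scope `FMS = HMR / LMR`
#' pointwise; the grand mean of the pointwise ratios is stored as
#' attribute `fms_mean`.
#'
#' @param low smooth fit at the low (TIMR-min) temperature.
#' @param high smooth fit at the high (TIMR-max) temperature.
#' @param grid_n common-grid density (default 200).
#' @return a `scope_curve` data.frame with columns `weight_g`, `lmr`,
#'   `hmr`, `tms`, `fms` (`fms` is NA where `lmr <= 0`).
#' @export
thermal_scope <- function(low, high, grid_n = 200) {
  stopifnot(inherits(low, "smooth_fit"), inherits(high, "smooth_fit"))
  lo <- max(low$weight_range[1], high$weight_range[1])
  hi <- min(low$weight_range[2], high$weight_range[2])
  if (lo >= hi) stopf("fits cover disjoint weight ranges")
  grid <- seq(lo, hi, length.out = grid_n)
  lmr <- predict(low, grid)
  hmr <- predict(high, grid)
  fms <- ifelse(lmr > 0, hmr / lmr, NA_real_)
  out <- data.frame(weight_g = grid, lmr = lmr, hmr = hmr,
                    tms = hmr - lmr, fms = fms)
  attr(out, "fms_mean") <- mean(fms, na.rm = TRUE)
  class(out) <- c("scope_curve", "data.frame")
  out
}

#' Locate features of a thermal-metabolic-scope curve
#'
#' Reports interior local maxima of TMS on the grid (optionally after a
#' running-mean smoothing), the global maximum, and the terminal trend
#' (sign of the OLS slope of TMS over the last decile of the grid). Peak
#' positions are grid points; no subgrid interpolation is attempted.
#'
#' @param curve a `scope_curve` from [thermal_scope()].
#' @param smooth_points odd window length for a running-mean smoothing of
#'   TMS before peak detection; 1 (default) disables smoothing.
#' @return data.frame with columns `feature` (`"local_max"`,
#'   `"global_max"`, `"terminal_trend"`), `weight_g`, `value`. For the
#'   terminal trend `value` is the slope sign (+1 / -1 / 0) and `weight_g`
#'   the start of the last decile.
#' @export
locate_scope_features <- function(curve, smooth_points = 1) {
  stopifnot(inherits(curve, "scope_curve"))
  w <- curve$weight_g
  s <- curve$tms
  n <- length(s)
  if (n < 5) stopf("grid too short to locate features (need >= 5 points)")
  if (smooth_points > 1) {
    k <- as.integer(smooth_points)
    if (k %% 2 == 0) k <- k + 1L
    s <- as.numeric(stats::filter(s, rep(1 / k, k), sides = 2))
    # filter leaves NA at the edges; fall back to raw values there
    s[is.na(s)] <- curve$tms[is.na(s)]
  }
  rows <- list()
  for (i in 2:(n - 1)) {
    if (s[i] > s[i - 1] && s[i] > s[i + 1]) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = "local_max", weight_g = w[i], value = s[i])
    }
  }
  gi <- which.max(s)
  rows[[length(rows) + 1L]] <- data.frame(
    feature = "global_max", weight_g = w[gi], value = s[gi])
  tail_i <- seq.int(n - max(ceiling(n / 10), 2) + 1, n)
  slope <- stats::coef(stats::lm(s[tail_i] ~ w[tail_i]))[2]
  rows[[length(rows) + 1L]] <- data.frame(
    feature = "terminal_trend", weight_g = w[tail_i[1]],
    value = sign(unname(slope)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
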