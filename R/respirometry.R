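#' Construct a closed-chamber oxygen trace
#'
#' @param times_s numeric vector of sampling times in seconds, strictly
#'   increasing, length >= 2.
#' @param o2 dissolved oxygen readings, mg O2 L^-1, same length, >= 0.
#' @param temperature measurement temperature, degrees C.
#' @param chamber_volume_l chamber water volume in litres (> 0). This is
#'   the vial volume; the embryo-displaced volume is subtracted downstream.
#' @param vial_id vial identifier.
#' @param is_blank TRUE for a control vial without an embryo.
#' @param embryo_id embryo identifier (NA for blanks).
#' @return an object of class `oxygen_trace`.
#' @export
oxygen_trace <- function(times_s, o2, temperature, chamber_volume_l,
                         vial_id = "vial", is_blank = FALSE,
                         embryo_id = NA_character_) {
  if (length(times_s) != length(o2) || length(o2) < 2) {
    stopf("times and o2 must have equal length >= 2")
  }
  if (any(diff(times_s) <= 0)) stopf("times must be strictly increasing")
  if (any(o2 < 0)) stopf("o2 must be >= 0")
  if (chamber_volume_l <= 0) stopf("chamber_volume_l must be > 0")
  structure(list(vial_id = vial_id, times_s = as.numeric(times_s),
                 o2 = as.numeric(o2), temperature = temperature,
                 chamber_volume_l = chamber_volume_l,
                 is_blank = isTRUE(is_blank), embryo_id = embryo_id),
            class = "oxygen_trace")
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf("<oxygen_trace %s%s> %d points, %.1f min, %.1f C, %.0f uL\n",
              x$vial_id, if (x$is_blank) " (blank)" else "",
              length(x$o2), diff(range(x$times_s)) / 60, x$temperature,
              x$chamber_volume_l * 1e6))
  invisible(x)
}

#' Linear-window selection settings
#'
#' The respiration slope is taken from a linear 5-10 minute segment of the
#' oxygen trace; this object sets the admissible window length and the
#' selection criterion.
#'
#' @param min_minutes minimum window length in minutes (default 5).
#' @param max_minutes maximum window length in minutes (default 10).
#' @param criterion `"max_r2"` (default) selects the window with maximum
#'   OLS R^2; `"min_residual_sd"` minimizes residual standard deviation.
#' @return object of class `window_config`.
#' @export
window_config <- function(min_minutes = 5, max_minutes = 10,
                          criterion = c("max_r2", "min_residual_sd")) {
  criterion <- match.arg(criterion)
  if (min_minutes <= 0 || min_minutes > max_minutes) {
    stopf("need 0 < min_minutes <= max_minutes")
  }
  structure(list(min_minutes = min_minutes, max_minutes = max_minutes,
                 criterion = criterion), class = "window_config")
}

# OLS slope/R2/residual SD for all admissible windows, via cumulative sums.
# Returns a matrix of candidate windows (start/end index, slope per
# second, r2, resid_sd). Internal.
window_scan <- function(times_s, o2, min_s, max_s) {
  x <- times_s - mean(times_s)   # centring limits cancellation error
  y <- o2
  n <- length(x)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y))
  cyy <- c(0, cumsum(y * y))
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    dt <- times_s - times_s[i]
    j <- which(dt >= min_s & dt <= max_s)
    if (length(j) == 0) next
    m <- j - i + 1                      # points per window
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    ssx <- sxx - sx^2 / m
    sst <- syy - sy^2 / m
    slope <- (sxy - sx * sy / m) / ssx
    sse <- pmax(sst - slope^2 * ssx, 0)
    r2 <- ifelse(sst > 0, pmax(pmin(1 - sse / sst, 1), 0), 0)
    slope[sst <= 0] <- 0
    resid_sd <- sqrt(sse / pmax(m - 2, 1))
    out[[i]] <- cbind(i0 = rep(i, length(j)), i1 = j, slope_s = slope,
                      r2 = r2, resid_sd = resid_sd)
  }
  do.call(rbind, out)
}

#' Find the best linear segment of an oxygen trace
#'
#' Enumerates every contiguous window aligned to sample points whose
#' duration lies within the configured bounds, fits OLS in each, and
#' returns the window maximizing the criterion. Ties are broken toward the
#' latest-starting (then longest) window, i.e. the steadiest state. A
#' trace shorter than the minimum window raises an error; a trace barely
#' longer than the minimum is used whole with a warning; when the trace is
#' shorter than the maximum window the admissible range is clamped to the
#' trace length.
#'
#' @param trace an [oxygen_trace()].
#' @param cfg a [window_config()].
#' @return list with `start_s`, `end_s`, `i0`, `i1` (sample indices),
#'   `slope_per_h` (mg O2 L^-1 h^-1, OLS), `r2`, `n`. A constant-O2 window
#'   reports slope 0 and, by documented convention, r2 = 0.
#' @export
#' @examples
#' tr <- oxygen_trace(seq(0, 1200, 15), 7.5 - 0.8 * seq(0, 1200, 15) / 3600,
#'                    24, 0.00175)
#' find_linear_window(tr)$slope_per_h
find_linear_window <- function(trace, cfg = window_config()) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (!inherits(cfg, "window_config")) stopf("cfg must be a window_config")
  t <- trace$times_s
  dur <- t[length(t)] - t[1]
  min_s <- cfg$min_minutes * 60
  max_s <- cfg$max_minutes * 60
  if (dur < min_s) {
    stopf("trace %s: duration %.1f min is shorter than the minimum window (%g min)",
          trace$vial_id, dur / 60, cfg$min_minutes)
  }
  step <- stats::median(diff(t))
  if (dur < min_s + 2 * step) {
    warnf("trace %s barely exceeds the minimum window; using the whole trace",
          trace$vial_id)
    min_s <- max_s <- dur
  } else if (dur < max_s) {
    max_s <- dur
  }
  cand <- window_scan(t, trace$o2, min_s, max_s)
  if (is.null(cand) || nrow(cand) == 0) {
    stopf("trace %s: no admissible window", trace$vial_id)
  }
  crit <- if (cfg$criterion == "max_r2") cand[, "r2"] else -cand[, "resid_sd"]
  best <- which(crit == max(crit))
  if (length(best) > 1) {                       # latest start, then longest
    best <- best[cand[best, "i0"] == max(cand[best, "i0"])]
    best <- best[which.max(cand[best, "i1"])]
  }
  w <- cand[best, ]
  list(start_s = t[w[["i0"]]], end_s = t[w[["i1"]]], i0 = w[["i0"]],
       i1 = w[["i1"]], slope_per_h = w[["slope_s"]] * 3600, r2 = w[["r2"]],
       n = w[["i1"]] - w[["i0"]] + 1)
}

#' Closed-chamber respiration rate (MO2)
#'
#' Computes `MO2 = (O2_A - O2_B) * (V / t) / M`: initial minus final
#' oxygen concentration, times chamber water volume over elapsed time,
#' divided by body mass. With concentrations in mg O2 L^-1, volume in
#' litres, time in hours and mass in grams wet weight the result is
#' mg O2 h^-1 g^-1. Negative results (net O2 production, usually a blank
#' or sensor artefact) are allowed but flagged with a warning.
#'
#' @param o2_a initial oxygen concentration, mg O2 L^-1.
#' @param o2_b final oxygen concentration, mg O2 L^-1.
#' @param volume_l chamber water volume minus embryo-displaced volume, L.
#' @param elapsed_h elapsed measurement time, hours.
#' @param mass_g embryo wet mass, g.
#' @return respiration rate, mg O2 h^-1 g^-1 wet weight (vectorized).
#' @export
#' @examples
#' compute_mo2(7.40, 6.90, volume_l = 0.00165, elapsed_h = 0.25,
#'             mass_g = 0.050) # 0.066
compute_mo2 <- function(o2_a, o2_b, volume_l, elapsed_h, mass_g) {
  if (any(volume_l <= 0)) stopf("volume_l must be > 0")
  if (any(elapsed_h <= 0)) stopf("elapsed_h must be > 0")
  if (any(mass_g <= 0)) stopf("mass_g must be > 0")
  mo2 <- (o2_a - o2_b) * (volume_l / elapsed_h) / mass_g
  if (any(mo2 < 0)) {
    warnf("negative MO2 (net O2 production): possible blank or sensor artefact")
  }
  mo2
}

#' Subtract the mean blank (control-vial) slope from an embryo slope
#'
#' @param embryo_slope embryo-vial O2 slope, mg O2 L^-1 h^-1.
#' @param blank_slopes numeric vector of blank-vial slopes from the same
#'   run/temperature.
#' @param on_missing `"warn"` (default) passes the slope through unchanged
#'   with a warning when no blanks are available; `"error"` stops.
#' @return list `slope` (corrected), `correction` (mean blank slope
#'   subtracted), `n_blanks`.
#' @export
#' @examples
#' blank_correct(-1.0, c(-0.1, -0.3))$slope # -0.8
blank_correct <- function(embryo_slope, blank_slopes,
                          on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  if (length(blank_slopes) == 0 || all(is.na(blank_slopes))) {
    if (on_missing == "error") stopf("no blank slopes available")
    warnf("no blank slopes available; slope left uncorrected")
    return(list(slope = embryo_slope, correction = 0, n_blanks = 0L))
  }
  corr <- mean(blank_slopes, na.rm = TRUE)
  list(slope = embryo_slope - corr, correction = corr,
       n_blanks = sum(!is.na(blank_slopes)))
}

#' Q10 temperature coefficient
#'
#' `Q10 = (rate2 / rate1) ^ (10 / (t2 - t1))`: the factor by which a rate
#' would change over a 10 degree C increase, assuming exponential
#' temperature dependence.
#'
#' @param rate1,rate2 positive metabolic rates at `t1` and `t2`.
#' @param t1,t2 temperatures in degrees C, `t1 != t2`.
#' @return the dimensionless Q10 coefficient (vectorized).
#' @export
#' @examples
#' q10(0.05, 11, 0.15, 30) # 3^(10/19)
q10 <- function(rate1, t1, rate2, t2) {
  if (any(rate1 <= 0) || any(rate2 <= 0)) stopf("rates must be > 0")
  if (any(t1 == t2)) stopf("t1 and t2 must differ")
  (rate2 / rate1)^(10 / (t2 - t1))
}

temperature_class <- function(temp_c) {
  cls <- c("LMR", "RMR", "HMR")
  ref <- c(11, 24, 30)
  out <- character(length(temp_c))
  for (i in seq_along(temp_c)) {
    d <- abs(temp_c[i] - ref)
    out[i] <- if (min(d) <= 0.5) cls[which.min(d)] else
      sprintf("T%g", temp_c[i])
  }
  out
}

#' Process a respirometry run into per-embryo metabolic rates
#'
#' For every embryo vial: selects the best linear window, corrects the
#' slope by the mean blank slope at the same temperature, and converts to
#' rates using the effective chamber volume (vial volume minus
#' embryo-displaced volume at `tissue_density`). The per-embryo rate is
#' `-corrected_slope * V` (mg O2 h^-1 embryo^-1); the weight-specific rate
#' divides by wet mass, which equals the MO2 equation evaluated at the
#' window's fitted endpoints. Vials whose `embryo_id` is missing from the
#' cohort are listed in a rejects table and the run continues.
#'
#' @param traces long-format trace table (columns `vial_id`, `time_s`,
#'   `o2_mg_per_l`, `temp_c`, `volume_ul`, `is_blank`, `embryo_id`), e.g.
#'   from [generate_traces()] or [read_traces_csv()].
#' @param cohort cohort table with `embryo_id`, `stage`, `phase`,
#'   `embryo_ww_mg`.
#' @param cfg a [window_config()].
#' @param blank_correction subtract mean blank slopes per temperature
#'   (default TRUE).
#' @param tissue_density embryo tissue density, g mL^-1, used to estimate
#'   displaced volume from wet mass (default 1.0).
#' @return list with `rates` (one row per matched embryo vial: ids, stage,
#'   phase, temperature and class, mass, window provenance, slopes,
#'   `mo2_per_embryo`, `mo2_specific`, `blank_corrected`) and `rejects`
#'   (`vial_id`, `reason`).
#' @export
process_run <- function(traces, cohort, cfg = window_config(),
                        blank_correction = TRUE, tissue_density = 1.0) {
  need <- c("vial_id", "time_s", "o2_mg_per_l", "temp_c", "volume_ul",
            "is_blank", "embryo_id")
  if (!all(need %in% names(traces))) {
    stopf("traces must have columns: %s", paste(need, collapse = ", "))
  }
  split_tr <- split(traces, traces$vial_id)
  meta <- do.call(rbind, lapply(split_tr, function(d) d[1, need[-(2:3)]]))

  # Blank slopes per temperature. Blanks estimate a small linear drift, so
  # the whole trace is used: restricting to a max-R2 sub-window of an
  # essentially flat noisy trace systematically selects spurious steep
  # segments and overstates the drift.
  blank_slopes <- list()
  for (v in meta$vial_id[meta$is_blank]) {
    d <- split_tr[[v]]
    x <- d$time_s - mean(d$time_s)
    slope <- sum(x * d$o2_mg_per_l) / sum(x * x) * 3600
    key <- as.character(d$temp_c[1])
    blank_slopes[[key]] <- c(blank_slopes[[key]], slope)
  }

  rates <- list(); rejects <- list()
  for (v in meta$vial_id[!meta$is_blank]) {
    d <- split_tr[[v]]
    eid <- d$embryo_id[1]
    row <- match(eid, cohort$embryo_id)
    if (is.na(eid) || is.na(row)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        vial_id = v, reason = "embryo_id not found in cohort")
      next
    }
    mass_g <- cohort$embryo_ww_mg[row] / 1000
    if (!is.finite(mass_g) || mass_g <= 0) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        vial_id = v, reason = "missing or non-positive embryo mass")
      next
    }
    tr <- oxygen_trace(d$time_s, d$o2_mg_per_l, d$temp_c[1],
                       d$volume_ul[1] / 1e6, v, embryo_id = eid)
    w <- find_linear_window(tr, cfg)
    key <- as.character(d$temp_c[1])
    if (blank_correction) {
      bc <- blank_correct(w$slope_per_h, blank_slopes[[key]] %||% numeric(0))
    } else {
      bc <- list(slope = w$slope_per_h, correction = 0, n_blanks = 0L)
    }
    v_eff <- tr$chamber_volume_l - mass_g / tissue_density / 1000
    if (v_eff <= 0) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        vial_id = v, reason = "embryo displaces entire chamber volume")
      next
    }
    per_embryo <- -bc$slope * v_eff
    rates[[length(rates) + 1L]] <- data.frame(
      embryo_id = eid, vial_id = v, stage = cohort$stage[row],
      phase = cohort$phase[row], temp_c = d$temp_c[1],
      temperature_class = temperature_class(d$temp_c[1]),
      mass_g = mass_g, weight_g = mass_g,
      window_start_s = w$start_s, window_end_s = w$end_s,
      window_r2 = w$r2, slope_raw = w$slope_per_h,
      blank_rate = bc$correction, blank_corrected = blank_correction,
      mo2_per_embryo = per_embryo, mo2_specific = per_embryo / mass_g,
      stringsAsFactors = FALSE)
  }
  rates <- if (length(rates)) do.call(rbind, rates) else
    data.frame(embryo_id = character(0))
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(vial_id = character(0), reason = character(0))
  rownames(rates) <- NULL
  list(rates = rates, rejects = rejects)
}
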