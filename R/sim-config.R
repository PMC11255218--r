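#' Default true MO2-weight profile for the trace generator
#'
#' Piecewise power + logistic profile of per-embryo oxygen consumption
#' (mg O2 h^-1 embryo^-1) against wet weight, mimicking the qualitative
#' shape reported for octopus embryos: at the cold TIMR-min temperature a
#' smooth power rise that keeps climbing through the growth phase; at warm
#' temperatures a power rise, a steep logistic step near the activation
#' weight (~0.09 g, the onset of heart and circulatory function), a
#' plateau, and a pronounced decline just before hatch. The implied
#' thermal scope (warm minus cold) therefore peaks just past the
#' activation step and falls toward hatch. This function is the
#' generator's ground truth for curve-recovery tests; it is not a fit to
#' any published dataset.
#'
#' @param weight_g embryo wet weight in grams (vectorized).
#' @param temperature measurement temperature in degrees C. Below 18 the
#'   cold (TIMR-min) branch is used; 18-27 the routine branch; above 27 the
#'   warm (TIMR-max) branch.
#' @return per-embryo oxygen consumption, mg O2 h^-1 embryo^-1.
#' @export
#' @examples
#' default_mo2_profile(c(0.01, 0.05, 0.10), 30)
default_mo2_profile <- function(weight_g, temperature) {
  w <- weight_g
  if (temperature < 18) {
    return(0.012 * (w / 0.12)^0.85)
  }
  fmax <- if (temperature >= 27) 0.025 else 0.020
  step <- stats::plogis((w - 0.091) / 0.004)
  decline <- stats::plogis((w - 0.112) / 0.005)
  fmax * (w / 0.12)^0.35 * (0.40 + 0.60 * step) * (1 - 0.45 * decline)
}

#' Default qPCR ground truth for the synthetic generator
#'
#' Eight genes: four antioxidant-system targets (CAT, MnSOD, CuSOD, HIF1A)
#' with designed phase fold-changes, and four candidate reference genes of
#' which TufM and Gpam are generated perfectly stable while EF1b and hnRNP
#' drift mildly across phases (so that a stability ranking should recover
#' TufM/Gpam as the two most stable, as in the real study design).
#' Efficiencies sit in the realistic 82-107% range.
#'
#' @param noise_sd_cq technical Cq noise SD in cycles (default 0.15).
#' @param n_per_phase biological samples per developmental phase (default 8).
#' @return a list with elements `efficiency`, `base_cq`, `phase_fold`
#'   (gene x phase matrix of fold-changes relative to blastulation),
#'   `reference_genes`, `noise_sd_cq`, `n_per_phase`, `dilution_levels`,
#'   `dilution_reps`, `dilution_factor`.
#' @export
default_qpcr_truth <- function(noise_sd_cq = 0.15, n_per_phase = 8L) {
  genes <- c("CAT", "MnSOD", "CuSOD", "HIF1A", "TufM", "Gpam", "EF1b", "hnRNP")
  efficiency <- c(CAT = 0.823, MnSOD = 1.066, CuSOD = 0.95, HIF1A = 0.905,
                  TufM = 0.885, Gpam = 0.908, EF1b = 0.991, hnRNP = 0.974)
  base_cq <- c(CAT = 24, MnSOD = 23, CuSOD = 22, HIF1A = 25,
               TufM = 20, Gpam = 21, EF1b = 19, hnRNP = 22)
  phase_fold <- rbind(
    CAT   = c(1, 1.4, 1.9, 2.4),   # rises through development
    MnSOD = c(1, 1.8, 2.6, 3.5),   # lowest at blastulation, highest at growth
    CuSOD = c(1, 1.6, 1.1, 0.7),   # peaks at organogenesis then declines
    HIF1A = c(1, 2.2, 2.1, 1.9),   # low only at blastulation
    TufM  = c(1, 1, 1, 1),
    Gpam  = c(1, 1, 1, 1),
    EF1b  = c(1, 1.2, 1.35, 1.5),
    hnRNP = c(1, 0.9, 0.75, 0.65)
  )
  colnames(phase_fold) <- phase_levels
  list(genes = genes, efficiency = efficiency, base_cq = base_cq,
       phase_fold = phase_fold, reference_genes = c("TufM", "Gpam"),
       noise_sd_cq = noise_sd_cq, n_per_phase = as.integer(n_per_phase),
       dilution_levels = 5L, dilution_reps = 3L, dilution_factor = 5)
}

#' Default biomarker ground truth for the synthetic generator
#'
#' Designed stage-mean profiles for six analytes over groups ovary (OV),
#' un-spawned eggs (USE) and embryo stages 6-19, mirroring the qualitative
#' pattern of octopus oogenesis and development: antioxidant enzymes (SOD,
#' CAT, GST) very high in ovary, low in eggs/early embryos, rising from the
#' activation phase; total glutathione (GSH) roughly flat in embryos but
#' elevated in un-spawned eggs; oxidative damage (LPO, PO) high in
#' ovary/eggs/early stages, declining to below 0.5 nmol mg^-1 by stage 19.
#' The designed OV/USE ratios for SOD and CAT are 350 and 150.
#'
#' @param cv coefficient of variation applied to every group mean (default
#'   0.15).
#' @param n_per_group samples per group (default 6).
#' @return named list per analyte: `profile` (named means for OV, USE,
#'   stages 6..19), `sd` (same names), `unit`.
#' @export
default_biomarker_truth <- function(cv = 0.15, n_per_group = 6L) {
  st <- as.character(6:19)
  mk <- function(ov, use, stages, unit) {
    profile <- c(OV = ov, USE = use, setNames(stages, st))
    list(profile = profile, sd = cv * profile, unit = unit,
         n_per_group = as.integer(n_per_group))
  }
  list(
    SOD = mk(350, 1, c(0.6, 0.6, 0.7, 0.7, 0.8, 0.9, 1.0, 1.2,
                       2.0, 3.0, 4.5, 6.0, 7.0, 8.0), "U mg-1 protein"),
    CAT = mk(150, 1, c(0.5, 0.5, 0.6, 0.6, 0.7, 0.8, 0.9, 1.1,
                       1.8, 2.6, 3.6, 4.6, 5.4, 6.0), "U mg-1 protein"),
    GST = mk(12, 2, c(1.0, 1.0, 1.0, 1.0, 1.1, 1.2, 1.3, 1.5,
                      2.5, 3.5, 4.5, 5.5, 6.0, 6.5), "U mg-1 protein"),
    GSH = mk(0.5, 0.9, rep(0.15, 14), "nmol mg-1 tissue"),
    LPO = mk(6, 5, c(4.0, 3.8, 3.5, 3.2, 3.0, 2.6, 2.2, 1.8,
                     1.4, 1.1, 0.8, 0.6, 0.45, 0.30), "nmol mg-1 tissue"),
    PO  = mk(8, 6, c(5.0, 4.6, 4.2, 3.8, 3.4, 3.0, 2.5, 2.0,
                     1.6, 1.2, 0.9, 0.7, 0.5, 0.40), "nmol mg-1 tissue")
  )
}

#' Build and validate a simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. A fixed `seed`
#' makes all generator output byte-identical across runs.
#'
#' @param seed integer RNG seed.
#' @param n_embryos_per_stage embryos generated per stage.
#' @param stages integer Naef stages, each within 6..19.
#' @param temperatures measurement temperatures (degrees C) cycled over
#'   embryos; default `c(11, 24, 30)` (TIMR-min, routine, TIMR-max).
#' @param chamber_volume_ul respirometry vial volume in microlitres
#'   (default 1750, a sensor-spot micro-plate vial).
#' @param interval_s sampling interval of the oxygen optode in seconds
#'   (default 15).
#' @param trace_minutes trace duration in minutes (default 20).
#' @param o2_start starting dissolved oxygen, mg O2 L^-1 (default 7.5).
#' @param noise_sd_o2 additive Gaussian sensor noise SD, mg O2 L^-1.
#' @param blank_drift background oxygen decline in blank vials,
#'   mg O2 L^-1 h^-1 (microbial/sensor drift; default 0.05).
#' @param n_blanks blank (control) vials per temperature (default 3).
#' @param transient list `amp` (mg O2 L^-1) and `tau_s` (s): optional
#'   exponentially decaying settling transient added to the trace start;
#'   `amp = 0` disables it.
#' @param growth_params list `a_mg`, `b` (embryo weight = a*exp(b*stage) mg),
#'   `sigma0`, `sigma_slope` (lognormal weight noise SD grows linearly with
#'   stage: sigma0 + sigma_slope*(stage - min)), `egg_a_mg`, `egg_b` (egg
#'   weight exponential).
#' @param mo2_profile function `(weight_g, temperature) -> mg O2 h^-1
#'   embryo^-1` giving true per-embryo oxygen consumption.
#' @param qpcr_truth see [default_qpcr_truth()].
#' @param biomarker_truth see [default_biomarker_truth()].
#' @return object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42, n_embryos_per_stage = 5)
simulation_config <- function(seed = 1L,
                              n_embryos_per_stage = 25L,
                              stages = 6:19,
                              temperatures = c(11, 24, 30),
                              chamber_volume_ul = 1750,
                              interval_s = 15,
                              trace_minutes = 20,
                              o2_start = 7.5,
                              noise_sd_o2 = 0.01,
                              blank_drift = 0.05,
                              n_blanks = 3L,
                              transient = list(amp = 0, tau_s = 90),
                              growth_params = list(a_mg = 1.5, b = 0.22,
                                                   sigma0 = 0.05,
                                                   sigma_slope = 0.005,
                                                   egg_a_mg = 55,
                                                   egg_b = 0.055),
                              mo2_profile = default_mo2_profile,
                              qpcr_truth = default_qpcr_truth(),
                              biomarker_truth = default_biomarker_truth()) {
  stages <- as.integer(stages)
  if (length(stages) == 0 || any(stages < 6L | stages > 19L)) {
    stopf("stages must be integers within 6..19")
  }
  if (chamber_volume_ul <= 0) stopf("chamber_volume_ul must be > 0")
  if (interval_s <= 0 || trace_minutes <= 0) {
    stopf("interval_s and trace_minutes must be > 0")
  }
  if (noise_sd_o2 < 0 || blank_drift < 0) {
    stopf("noise_sd_o2 and blank_drift must be >= 0")
  }
  gp <- growth_params
  if (gp$a_mg <= 0 || gp$sigma0 < 0 || gp$sigma_slope < 0) {
    stopf("growth_params: a_mg > 0 and sigma0, sigma_slope >= 0 required")
  }
  eff <- qpcr_truth$efficiency
  if (any(eff <= 0) || any(eff > 1.2)) {
    stopf("qpcr efficiencies must lie in (0, 1.2]")
  }
  for (an in names(biomarker_truth)) {
    bt <- biomarker_truth[[an]]
    if (any(bt$sd < 0) || any(bt$profile < 0)) {
      stopf("biomarker truth for %s must be non-negative", an)
    }
  }
  structure(list(seed = as.integer(seed),
                 n_embryos_per_stage = as.integer(n_embryos_per_stage),
                 stages = stages, temperatures = temperatures,
                 chamber_volume_ul = chamber_volume_ul,
                 interval_s = interval_s, trace_minutes = trace_minutes,
                 o2_start = o2_start, noise_sd_o2 = noise_sd_o2,
                 blank_drift = blank_drift, n_blanks = as.integer(n_blanks),
                 transient = transient, growth_params = gp,
                 mo2_profile = mo2_profile, qpcr_truth = qpcr_truth,
                 biomarker_truth = biomarker_truth),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  seed %d | %d embryos/stage, stages %d..%d | temps %s C\n",
              x$seed, x$n_embryos_per_stage, min(x$stages), max(x$stages),
              paste(x$temperatures, collapse = "/")))
  cat(sprintf("  vial %g uL, %g s sampling, %g min traces, O2 noise %g\n",
              x$chamber_volume_ul, x$interval_s, x$trace_minutes,
              x$noise_sd_o2))
  invisible(x)
}
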