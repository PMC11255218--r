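#' Generate a synthetic embryo cohort with known growth truth
#'
#' Embryo wet weight is drawn as `a * exp(b * stage) * exp(eps)` with
#' `eps ~ Normal(0, sigma(stage))` and `sigma` non-decreasing in stage
#' (lognormal noise whose spread grows with development, as observed in
#' real clutches). Egg wet weight follows its own, much flatter
#' exponential.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (data.frame `embryo_id`, `stage`, `phase`,
#'   `egg_ww_mg`, `embryo_ww_mg`) and `truth` (the generating parameters).
#' @export
#' @examples
#' gc <- generate_cohort(simulation_config(seed = 1, n_embryos_per_stage = 3))
#' head(gc$cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gp <- config$growth_params
  st <- rep(config$stages, each = config$n_embryos_per_stage)
  sigma <- gp$sigma0 + gp$sigma_slope * (st - min(config$stages))
  emb <- gp$a_mg * exp(gp$b * st) * exp(stats::rnorm(length(st), 0, sigma))
  egg <- gp$egg_a_mg * exp(gp$egg_b * st) *
    exp(stats::rnorm(length(st), 0, sigma))
  cohort <- data.frame(
    embryo_id = sprintf("E%04d", seq_along(st)),
    stage = st,
    phase = stage_phase(st),
    egg_ww_mg = egg,
    embryo_ww_mg = emb,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort,
       truth = list(a_mg = gp$a_mg, b = gp$b, sigma0 = gp$sigma0,
                    sigma_slope = gp$sigma_slope,
                    egg_a_mg = gp$egg_a_mg, egg_b = gp$egg_b))
}

#' Generate synthetic oxygen-depletion traces for a cohort
#'
#' Each embryo is assigned one measurement temperature (cycled over
#' `config$temperatures`) and a closed-chamber trace is built as
#' `O2(t) = O2_start - (trueMO2 * M + blank_rate * V) * t / V + transient +
#' noise`, truncated at 0 with a warning. `V` is the chamber volume minus
#' the embryo-displaced volume (tissue density 1 g mL^-1). Blank vials
#' (no embryo) carry drift and noise only.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param config a [simulation_config()].
#' @return list with `traces` (long data.frame in the trace CSV dialect:
#'   `vial_id`, `time_s`, `o2_mg_per_l`, `temp_c`, `volume_ul`, `is_blank`,
#'   `embryo_id`) and `truth` (per-vial true rates: `vial_id`, `embryo_id`,
#'   `temp_c`, `weight_g`, `true_mo2_embryo`, `true_mo2_specific`,
#'   `blank_rate`).
#' @export
generate_traces <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$trace_minutes <= 0) stopf("negative or zero trace duration")
  set.seed(config$seed + 1L)
  times <- seq(0, config$trace_minutes * 60, by = config$interval_s)
  t_h <- times / 3600
  n <- nrow(cohort)
  temp <- rep_len(config$temperatures, n)
  vol_chamber_l <- config$chamber_volume_ul / 1e6

  trace_list <- vector("list", n + config$n_blanks * length(config$temperatures))
  truth_list <- trace_list
  k <- 0L
  truncated <- FALSE
  for (i in seq_len(n)) {
    k <- k + 1L
    m_g <- cohort$embryo_ww_mg[i] / 1000
    v_l <- vol_chamber_l - m_g / 1000        # displaced volume at 1 g mL^-1
    per_embryo <- config$mo2_profile(m_g, temp[i])
    slope <- -(per_embryo + config$blank_drift * v_l) / v_l  # mg L^-1 h^-1
    o2 <- config$o2_start + slope * t_h
    if (config$transient$amp != 0) {
      o2 <- o2 + config$transient$amp * exp(-times / config$transient$tau_s)
    }
    o2 <- o2 + stats::rnorm(length(times), 0, config$noise_sd_o2)
    if (any(o2 < 0)) truncated <- TRUE
    o2 <- pmax(o2, 0)
    vial <- sprintf("V%04d", k)
    trace_list[[k]] <- data.frame(
      vial_id = vial, time_s = times, o2_mg_per_l = o2, temp_c = temp[i],
      volume_ul = config$chamber_volume_ul, is_blank = FALSE,
      embryo_id = cohort$embryo_id[i], stringsAsFactors = FALSE)
    truth_list[[k]] <- data.frame(
      vial_id = vial, embryo_id = cohort$embryo_id[i], temp_c = temp[i],
      weight_g = m_g, true_mo2_embryo = per_embryo,
      true_mo2_specific = per_embryo / m_g,
      blank_rate = config$blank_drift, stringsAsFactors = FALSE)
  }
  for (tc in unique(temp)) {
    for (b in seq_len(config$n_blanks)) {
      k <- k + 1L
      o2 <- config$o2_start - config$blank_drift * t_h +
        stats::rnorm(length(times), 0, config$noise_sd_o2)
      o2 <- pmax(o2, 0)
      vial <- sprintf("V%04d", k)
      trace_list[[k]] <- data.frame(
        vial_id = vial, time_s = times, o2_mg_per_l = o2, temp_c = tc,
        volume_ul = config$chamber_volume_ul, is_blank = TRUE,
        embryo_id = NA_character_, stringsAsFactors = FALSE)
      truth_list[[k]] <- data.frame(
        vial_id = vial, embryo_id = NA_character_, temp_c = tc,
        weight_g = NA_real_, true_mo2_embryo = NA_real_,
        true_mo2_specific = NA_real_, blank_rate = config$blank_drift,
        stringsAsFactors = FALSE)
    }
  }
  if (truncated) warnf("some O2 readings reached 0 and were truncated")
  list(traces = do.call(rbind, trace_list[seq_len(k)]),
       truth = do.call(rbind, truth_list[seq_len(k)]))
}

#' Generate synthetic qPCR data (dilution series + Cq matrix)
#'
#' Dilution-series Cq follows `Cq = c0 - log10(input) / log10(1 + E) +
#' noise`, so a 1:5 dilution step increases Cq by `log(5)/log(1+E)`
#' cycles. The sample Cq matrix encodes the configured per-phase
#' fold-changes on target genes relative to blastulation; designed-stable
#' reference genes have fold 1 everywhere.
#'
#' @param config a [simulation_config()]; `config$qpcr_truth` supplies
#'   efficiencies, fold-changes and noise.
#' @return list with `dilution` (data.frame `gene`, `log10_input`, `rep`,
#'   `cq`), `cq` (data.frame `sample_id`, `stage`, `phase`, `gene`, `rep`,
#'   `cq`, `is_reference`) and `truth` (efficiencies, fold matrix,
#'   reference genes).
#' @export
generate_qpcr <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  q <- config$qpcr_truth
  if (any(q$efficiency <= 0)) stopf("qpcr efficiency must be > 0")
  set.seed(config$seed + 2L)
  genes <- q$genes

  # dilution series: undiluted level has log10_input = 0
  lv <- -(seq_len(q$dilution_levels) - 1) * log10(q$dilution_factor)
  dil <- do.call(rbind, lapply(genes, function(g) {
    ex <- expand.grid(log10_input = lv, rep = seq_len(q$dilution_reps))
    cq <- q$base_cq[g] - ex$log10_input / log10(1 + q$efficiency[g]) +
      stats::rnorm(nrow(ex), 0, q$noise_sd_cq)
    data.frame(gene = g, log10_input = ex$log10_input, rep = ex$rep,
               cq = cq, stringsAsFactors = FALSE)
  }))

  # sample Cq matrix: n_per_phase samples per phase, technical triplicates
  phase_stage <- list(blastulation = 6:8, organogenesis = 9:13,
                      activation = 14:16, growth = 17:19)
  rows <- list()
  sid <- 0L
  for (p in phase_levels) {
    for (i in seq_len(q$n_per_phase)) {
      sid <- sid + 1L
      stg <- sample(phase_stage[[p]], 1)
      for (g in genes) {
        fold <- q$phase_fold[g, p]
        true_cq <- q$base_cq[g] - log(fold) / log(1 + q$efficiency[g])
        cq <- true_cq + stats::rnorm(3, 0, q$noise_sd_cq)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("S%03d", sid), stage = stg, phase = p,
          gene = g, rep = 1:3, cq = cq,
          is_reference = g %in% q$reference_genes, stringsAsFactors = FALSE)
      }
    }
  }
  list(dilution = dil, cq = do.call(rbind, rows),
       truth = list(efficiency = q$efficiency, phase_fold = q$phase_fold,
                    base_cq = q$base_cq,
                    reference_genes = q$reference_genes))
}

#' Generate a synthetic biomarker table
#'
#' Values are drawn `Normal(group mean, group SD)` truncated at 0 for each
#' analyte and group (OV, USE, embryo stages) of the configured profiles.
#'
#' @param config a [simulation_config()]; `config$biomarker_truth` supplies
#'   the designed profiles.
#' @return list with `table` (data.frame `sample_id`, `tissue`, `stage`,
#'   `analyte`, `value`, `unit`, `protein_mg`) and `truth` (the profiles).
#' @export
generate_biomarkers <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  rows <- list()
  sid <- 0L
  for (an in names(config$biomarker_truth)) {
    bt <- config$biomarker_truth[[an]]
    for (grp in names(bt$profile)) {
      tissue <- if (grp %in% c("OV", "USE")) grp else "embryo"
      stage <- if (tissue == "embryo") as.integer(grp) else NA_integer_
      n <- bt$n_per_group
      val <- pmax(stats::rnorm(n, bt$profile[grp], bt$sd[grp]), 0)
      prot <- pmax(stats::rnorm(n, 1.5, 0.2), 0.2)
      sid <- sid + n
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("B%04d", (sid - n + 1):sid), tissue = tissue,
        stage = stage, analyte = an, value = val, unit = bt$unit,
        protein_mg = prot, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), truth = config$biomarker_truth)
}

#' Run every generator and optionally write the pipeline input files
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `traces.csv`, `dilution.csv`, `cq.csv`, `biomarkers.csv` plus a
#'   `truth.json` snapshot of scalar ground truth.
#' @return list with components `cohort`, `traces`, `qpcr`, `biomarkers`
#'   (each as returned by its generator).
#' @export
simulate_all <- function(config, out_dir = NULL) {
  ch <- generate_cohort(config)
  tr <- generate_traces(ch$cohort, config)
  qp <- generate_qpcr(config)
  bm <- generate_biomarkers(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ch$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(tr$traces, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(qp$dilution, file.path(out_dir, "dilution.csv"),
                     row.names = FALSE)
    utils::write.csv(qp$cq, file.path(out_dir, "cq.csv"), row.names = FALSE)
    utils::write.csv(bm$table, file.path(out_dir, "biomarkers.csv"),
                     row.names = FALSE)
    truth <- list(growth = ch$truth,
                  qpcr = list(efficiency = as.list(qp$truth$efficiency),
                              reference_genes = qp$truth$reference_genes),
                  blank_drift = config$blank_drift)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = ch, traces = tr, qpcr = qp, biomarkers = bm)
}
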