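#' Normalize biomarker values to a per-milligram basis
#'
#' Divides each value by the stated denominator: the `protein_mg` column
#' for a per-mg-protein basis (enzyme activities) or an explicit tissue
#' denominator for a per-mg-tissue basis (metabolite/damage markers whose
#' inputs are often already per mg tissue, i.e. denominator 1). The unit
#' string is updated.
#'
#' @param table biomarker data.frame with columns `value`, `unit` and,
#'   for the protein basis, `protein_mg`.
#' @param basis `"per_mg_protein"` or `"per_mg_tissue"`.
#' @param tissue_mg denominator for the tissue basis (default 1,
#'   i.e. values already expressed per mg tissue).
#' @return the table with `value` normalized, `unit` annotated, and the
#'   denominator stored in a `norm_denominator` column (so the operation
#'   is invertible with [denormalize_biomarkers()]).
#' @export
normalize_biomarkers <- function(table,
                                 basis = c("per_mg_protein",
                                           "per_mg_tissue"),
                                 tissue_mg = 1) {
  basis <- match.arg(basis)
  if (basis == "per_mg_protein") {
    if (is.null(table$protein_mg) || any(is.na(table$protein_mg))) {
      stopf("per-mg-protein normalization requires a complete protein_mg column")
    }
    den <- table$protein_mg
    suffix <- " mg-1 protein"
  } else {
    den <- rep_len(tissue_mg, nrow(table))
    suffix <- " mg-1 tissue"
  }
  if (any(den <= 0)) stopf("normalization denominators must be > 0")
  table$value <- table$value / den
  table$unit <- paste0(table$unit, suffix)
  table$norm_denominator <- den
  table
}

#' Invert [normalize_biomarkers()]
#'
#' @param table a table previously normalized (has `norm_denominator`).
#' @return the table with original values restored.
#' @export
denormalize_biomarkers <- function(table) {
  if (is.null(table$norm_denominator)) {
    stopf("table carries no norm_denominator column; nothing to invert")
  }
  table$value <- table$value * table$norm_denominator
  table$unit <- sub(" mg-1 (protein|tissue)$", "", table$unit)
  table$norm_denominator <- NULL
  table
}

biomarker_group <- function(tissue, stage) {
  ifelse(tissue %in% c("OV", "USE"), tissue, as.character(stage))
}

#' Stage/tissue profile of one analyte
#'
#' Group means and standard deviations (n-1 denominator) for one analyte,
#' with groups ordered ovary (OV), un-spawned eggs (USE), then embryo
#' stages ascending. Groups with a single observation report `NA` for the
#' SD (the n-1 estimator is undefined), not 0.
#'
#' @param table biomarker data.frame (`tissue`, `stage`, `analyte`,
#'   `value`).
#' @param analyte analyte name, e.g. `"SOD"`.
#' @return a `stage_profile` data.frame with `group`, `tissue`, `stage`,
#'   `mean`, `sd`, `n`.
#' @export
stage_profile <- function(table, analyte) {
  d <- table[table$analyte == analyte, ]
  if (nrow(d) == 0) stopf("no measurements for analyte %s", analyte)
  d$group <- biomarker_group(d$tissue, d$stage)
  stats_by <- lapply(split(d$value, d$group), function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  })
  groups <- names(stats_by)
  stage_num <- suppressWarnings(as.integer(groups))
  ord <- order(match(groups, c("OV", "USE"), nomatch = 3L), stage_num)
  groups <- groups[ord]
  out <- data.frame(
    group = groups,
    tissue = ifelse(groups %in% c("OV", "USE"), groups, "embryo"),
    stage = suppressWarnings(as.integer(groups)),
    mean = vapply(stats_by[groups], `[[`, numeric(1), "mean"),
    sd = vapply(stats_by[groups], `[[`, numeric(1), "sd"),
    n = as.integer(vapply(stats_by[groups], `[[`, numeric(1), "n")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "analyte") <- analyte
  class(out) <- c("stage_profile", "data.frame")
  out
}

#' Fold-ratio between two groups with a bootstrap confidence interval
#'
#' Ratio of group means (e.g. ovary over un-spawned eggs) for one analyte,
#' with a seeded percentile bootstrap CI obtained by resampling within
#' each group.
#'
#' @param table biomarker data.frame (`tissue`, `stage`, `analyte`,
#'   `value`).
#' @param analyte analyte name.
#' @param group_a,group_b group labels: `"OV"`, `"USE"`, or a stage number
#'   (as integer or string).
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return list with `ratio`, `ci_lower`, `ci_upper`, `n_a`, `n_b`,
#'   `n_boot`, `conf`.
#' @export
fold_ratio <- function(table, analyte, group_a = "OV", group_b = "USE",
                       n_boot = 2000, conf = 0.95, seed = 1) {
  d <- table[table$analyte == analyte, ]
  d$group <- biomarker_group(d$tissue, d$stage)
  va <- d$value[d$group == as.character(group_a)]
  vb <- d$value[d$group == as.character(group_b)]
  if (length(va) == 0 || length(vb) == 0) {
    stopf("empty group for analyte %s", analyte)
  }
  if (mean(vb) <= 0 || mean(va) <= 0) {
    stopf("fold_ratio requires positive group means")
  }
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(va, replace = TRUE)) / mean(sample(vb, replace = TRUE))
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(ratio = mean(va) / mean(vb), ci_lower = qs[1], ci_upper = qs[2],
       n_a = length(va), n_b = length(vb), n_boot = n_boot, conf = conf)
}
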