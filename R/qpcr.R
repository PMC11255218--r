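#' Amplification efficiency from a serial-dilution standard curve
#'
#' For each gene, technical replicates are averaged per dilution level,
#' the mean Cq is regressed on log10 relative input, and the efficiency is
#' obtained from the slope as `E = -1 + 10^(-1/slope)`. A slope of
#' -3.3219 corresponds to perfect doubling (E = 100%). Efficiencies below
#' 80% or above 110% trigger a warning (poor assays), and a positive
#' slope flags the estimate invalid.
#'
#' @param dilution data.frame with columns `gene`, `log10_input`, `rep`,
#'   `cq` (>= 3 distinct input levels per gene, `cq > 0`).
#' @return an `efficiency_estimate` data.frame: `gene`, `slope` (cycles
#'   per log10 input), `e_fraction`, `e_percent`, `r2`, `n_points`,
#'   `valid`. Percentages are full precision; round to 0.1 for reports.
#' @export
#' @examples
#' d <- data.frame(gene = "X", log10_input = rep(-(0:3) * log10(5), 2),
#'                 rep = rep(1:2, each = 4),
#'                 cq = 20 + rep((0:3) * log10(5), 2) / log10(2))
#' efficiency_from_dilution(d)$e_percent # 100
efficiency_from_dilution <- function(dilution) {
  need <- c("gene", "log10_input", "cq")
  if (!all(need %in% names(dilution))) {
    stopf("dilution table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(dilution$cq <= 0)) stopf("cq values must be > 0")
  out <- lapply(split(dilution, dilution$gene), function(d) {
    mcq <- tapply(d$cq, d$log10_input, mean)
    lv <- as.numeric(names(mcq))
    if (length(lv) < 3) {
      stopf("gene %s: need >= 3 distinct dilution levels", d$gene[1])
    }
    fit <- stats::lm(as.numeric(mcq) ~ lv)
    slope <- unname(stats::coef(fit)[2])
    if (abs(slope) < .Machine$double.eps^0.5) {
      stopf("gene %s: zero standard-curve slope, efficiency undefined",
            d$gene[1])
    }
    e <- -1 + 10^(-1 / slope)
    valid <- slope < 0
    if (!valid) {
      warnf("gene %s: positive standard-curve slope; estimate flagged invalid",
            d$gene[1])
    } else if (e < 0.8 || e > 1.1) {
      warnf("gene %s: efficiency %.1f%% outside the usual 80-110%% range",
            d$gene[1], 100 * e)
    }
    data.frame(gene = d$gene[1], slope = slope, e_fraction = e,
               e_percent = 100 * e, r2 = summary(fit)$r.squared,
               n_points = length(lv), valid = valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("efficiency_estimate", "data.frame")
  out
}

#' Standard-curve slope implied by an amplification efficiency
#'
#' Inverse of the efficiency equation: `slope = -1 / log10(1 + E)`.
#' Useful for reconstructing slopes from reported percent efficiencies.
#'
#' @param e_fraction efficiency as a fraction (e.g. 0.823 for 82.3%).
#' @return slope in cycles per log10 input.
#' @export
slope_from_efficiency <- function(e_fraction) {
  if (any(e_fraction <= -1)) stopf("efficiency must exceed -1")
  -1 / log10(1 + e_fraction)
}

#' Efficiency-corrected relative quantity
#'
#' `RQ = (1 + E)^(Cq_cal - Cq)`: the quantity of a sample relative to a
#' calibrator, corrected for the gene's amplification efficiency.
#'
#' @param cq sample Cq (vectorized).
#' @param cq_cal calibrator Cq for the gene.
#' @param e_fraction amplification efficiency as a fraction (> -1).
#' @return relative quantity (> 0).
#' @export
#' @examples
#' relative_quantity(17, 20, 1) # 2^3 = 8
relative_quantity <- function(cq, cq_cal, e_fraction) {
  if (any(e_fraction <= -1)) stopf("efficiency must exceed -1")
  (1 + e_fraction)^(cq_cal - cq)
}

#' Normalization factor: geometric mean of reference-gene RQs
#'
#' @param ref_rqs positive reference-gene relative quantities for one
#'   sample (vector), or a matrix with samples in rows.
#' @return the normalization factor(s).
#' @export
#' @examples
#' normalization_factor(c(2, 8)) # 4
normalization_factor <- function(ref_rqs) {
  if (is.matrix(ref_rqs)) {
    return(apply(ref_rqs, 1, geometric_mean))
  }
  geometric_mean(ref_rqs)
}

average_tech_reps <- function(cq_df) {
  key <- interaction(cq_df$sample_id, cq_df$gene, drop = TRUE)
  agg <- lapply(split(cq_df, key), function(d) {
    d1 <- d[1, setdiff(names(d), c("rep", "cq"))]
    d1$cq <- mean(d$cq, na.rm = TRUE)
    d1
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Hellemans efficiency-corrected normalized relative expression
#'
#' Implements relative quantification with gene-specific efficiencies and
#' a multi-reference normalization factor: technical replicates are
#' averaged; each gene's relative quantity is computed against its
#' calibrator (default: the gene's mean Cq across all samples); the
#' normalization factor is the geometric mean of the sample's
#' reference-gene RQs; the normalized relative quantity `NRQ = RQ / NF`
#' is natural-log transformed for all downstream statistics (variances of
#' log-transformed values are not back-transformable, so summaries stay
#' on the ln scale).
#'
#' @param cq_df long Cq table: `sample_id`, `stage`, `phase`, `gene`,
#'   `rep`, `cq`, optionally `is_reference`.
#' @param efficiency named vector of per-gene efficiencies (fractions), or
#'   an `efficiency_estimate` table. Every gene must be covered.
#' @param reference_genes reference gene names; default: genes flagged by
#'   `is_reference`.
#' @param calibrator `"mean"` (per-gene mean Cq across samples, default)
#'   or the `sample_id` of a fixed calibrator sample.
#' @return a `relative_expression` data.frame: `sample_id`, `stage`,
#'   `phase`, `gene`, `cq`, `rq`, `nf`, `nrq`, `ln_nrq`, with reference
#'   genes excluded from the output rows (they define `nf`). Samples
#'   missing a Cq for a gene are dropped for that gene with a warning;
#'   samples missing any reference gene are dropped entirely.
#' @export
normalized_expression <- function(cq_df, efficiency,
                                  reference_genes = NULL,
                                  calibrator = "mean") {
  if (inherits(efficiency, "data.frame")) {
    efficiency <- stats::setNames(efficiency$e_fraction, efficiency$gene)
  }
  if (is.null(reference_genes)) {
    if (is.null(cq_df$is_reference)) {
      stopf("reference_genes not given and no is_reference column present")
    }
    reference_genes <- unique(cq_df$gene[cq_df$is_reference])
  }
  genes <- unique(cq_df$gene)
  missing_e <- setdiff(genes, names(efficiency))
  if (length(missing_e)) {
    stopf("no efficiency for gene(s): %s", paste(missing_e, collapse = ", "))
  }
  if (length(reference_genes) < 1) stopf("need >= 1 reference gene")

  d <- average_tech_reps(cq_df)
  drop <- is.na(d$cq)
  if (any(drop)) {
    warnf("dropping %d sample x gene cells with missing Cq", sum(drop))
    d <- d[!drop, ]
  }
  # per-gene RQ against the calibrator
  d$rq <- NA_real_
  for (g in unique(d$gene)) {
    idx <- d$gene == g
    cal <- if (identical(calibrator, "mean")) mean(d$cq[idx]) else {
      ci <- idx & d$sample_id == calibrator
      if (!any(ci)) stopf("calibrator sample %s missing for gene %s",
                          calibrator, g)
      d$cq[ci]
    }
    d$rq[idx] <- relative_quantity(d$cq[idx], cal, efficiency[[g]])
  }
  # per-sample NF from reference genes
  nf_by_sample <- vapply(split(d, d$sample_id), function(s) {
    rr <- s$rq[s$gene %in% reference_genes]
    if (length(rr) < length(reference_genes)) return(NA_real_)
    geometric_mean(rr)
  }, numeric(1))
  bad <- names(nf_by_sample)[is.na(nf_by_sample)]
  if (length(bad)) {
    warnf("dropping sample(s) missing reference genes: %s",
          paste(bad, collapse = ", "))
  }
  d$nf <- nf_by_sample[d$sample_id]
  d <- d[!is.na(d$nf) & !(d$gene %in% reference_genes), ]
  d$nrq <- d$rq / d$nf
  d$ln_nrq <- log(d$nrq)
  keep <- intersect(c("sample_id", "stage", "phase", "gene", "cq", "rq",
                      "nf", "nrq", "ln_nrq"), names(d))
  out <- d[, keep]
  rownames(out) <- NULL
  attr(out, "reference_genes") <- reference_genes
  attr(out, "efficiency") <- efficiency
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Reference-gene stability ranking
#'
#' Approximates a combined stability assessment with two published
#' components: a geNorm-style M value (for each candidate, the mean over
#' partner candidates of the SD across samples of the pairwise log2
#' expression ratio) and the comparative-delta-Ct SD (mean SD of pairwise
#' Cq differences). The overall ranking is the geometric mean of the two
#' component ranks; rank 1 is the most stable. When efficiencies are
#' supplied, log2 quantities are efficiency-scaled (`(cal - Cq) *
#' log2(1+E)`); otherwise perfect doubling is assumed.
#'
#' @param cq_df long Cq table (`sample_id`, `gene`, `rep`, `cq`).
#' @param candidates candidate gene names (>= 3); default all genes.
#' @param efficiency optional named efficiency vector or
#'   `efficiency_estimate` table.
#' @return a `stability_ranking` data.frame sorted most-stable first:
#'   `gene`, `genorm_m`, `deltact_sd`, `rank_genorm`, `rank_deltact`,
#'   `combined_rank` (geometric mean of component ranks), `rank`.
#' @export
reference_stability <- function(cq_df, candidates = NULL,
                                efficiency = NULL) {
  if (inherits(efficiency, "data.frame")) {
    efficiency <- stats::setNames(efficiency$e_fraction, efficiency$gene)
  }
  candidates <- candidates %||% unique(cq_df$gene)
  if (length(candidates) < 3) stopf("need >= 3 candidate genes")
  d <- average_tech_reps(cq_df[cq_df$gene %in% candidates, ])
  cqm <- tapply(d$cq, list(d$sample_id, d$gene), mean)
  cqm <- cqm[, candidates, drop = FALSE]
  if (any(is.na(cqm))) stopf("every candidate needs a Cq in every sample")
  if (nrow(cqm) < 8) stopf("need >= 8 samples for a stability ranking")

  # log2 relative quantity per gene (calibrator constants cancel in ratios)
  log2q <- cqm
  for (g in candidates) {
    e <- if (is.null(efficiency)) 1 else efficiency[[g]]
    log2q[, g] <- (mean(cqm[, g]) - cqm[, g]) * log2(1 + e)
  }
  ng <- length(candidates)
  genorm_m <- deltact_sd <- numeric(ng)
  for (j in seq_len(ng)) {
    sd_ratio <- sd_dct <- numeric(0)
    for (k in seq_len(ng)[-j]) {
      sd_ratio <- c(sd_ratio, stats::sd(log2q[, j] - log2q[, k]))
      sd_dct <- c(sd_dct, stats::sd(cqm[, j] - cqm[, k]))
    }
    genorm_m[j] <- mean(sd_ratio)
    deltact_sd[j] <- mean(sd_dct)
  }
  rank_g <- rank(genorm_m, ties.method = "average")
  rank_d <- rank(deltact_sd, ties.method = "average")
  combined <- sqrt(rank_g * rank_d)
  out <- data.frame(gene = candidates, genorm_m = genorm_m,
                    deltact_sd = deltact_sd, rank_genorm = rank_g,
                    rank_deltact = rank_d, combined_rank = combined,
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined_rank, out$genorm_m, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' Compare expression of one gene across developmental phases
#'
#' One-way ANOVA (default) of ln-transformed normalized relative
#' quantities across phases, with optional Tukey HSD pairwise contrasts;
#' Kruskal-Wallis is available as a distribution-free alternative. With
#' zero variance everywhere and equal group means the F statistic is
#' undefined and the result reports no evidence with a diagnostic note.
#'
#' @param expr a `relative_expression` table from
#'   [normalized_expression()].
#' @param gene target gene to test.
#' @param method `"anova"` (default) or `"kruskal"`.
#' @param pairwise also return Tukey HSD contrasts (ANOVA only).
#' @param group column used as grouping factor (default `"phase"`).
#' @return list with `method`, `statistic` (F or chi-squared), `df`,
#'   `p_value`, `groups` (per-group n and ln-scale means), `pairwise`
#'   (or NULL), `note` (or NULL).
#' @export
stage_comparison <- function(expr, gene, method = c("anova", "kruskal"),
                             pairwise = FALSE, group = "phase") {
  method <- match.arg(method)
  d <- expr[expr$gene == gene, ]
  if (nrow(d) == 0) stopf("gene %s not present in expression table", gene)
  g <- factor(d[[group]], levels = intersect(phase_levels,
                                             unique(d[[group]])))
  if (length(levels(g)) == 0) g <- factor(d[[group]])
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    stopf("need >= 2 groups with >= 2 samples each")
  }
  y <- d$ln_nrq
  grp_means <- tapply(y, g, mean)
  summary_tab <- data.frame(group = names(tab), n = as.integer(tab),
                            mean_ln_nrq = as.numeric(grp_means),
                            sd_ln_nrq = as.numeric(tapply(y, g, stats::sd)))
  within_var <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (within_var < .Machine$double.eps * sum(y^2 + 1)) {
    return(list(method = method, statistic = NA_real_, df = NA,
                p_value = NA_real_, groups = summary_tab, pairwise = NULL,
                note = "zero within-group variance: F undefined, no evidence assessed"))
  }
  if (method == "anova") {
    fit <- stats::aov(y ~ g)
    a <- stats::anova(fit)
    res <- list(method = "anova", statistic = a$`F value`[1],
                df = a$Df, p_value = a$`Pr(>F)`[1], groups = summary_tab,
                pairwise = NULL, note = NULL)
    if (pairwise) {
      res$pairwise <- as.data.frame(stats::TukeyHSD(fit)$g)
    }
    res
  } else {
    k <- stats::kruskal.test(y, g)
    list(method = "kruskal", statistic = unname(k$statistic),
         df = unname(k$parameter), p_value = k$p.value,
         groups = summary_tab, pairwise = NULL, note = NULL)
  }
}
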