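# Shared fixture builders and independent oracles.

# A synthetic oxygen trace with known slope (mg O2 L^-1 h^-1), optional
# exponential settling transient and Gaussian noise.
make_trace <- function(slope_per_h, minutes = 20, interval_s = 15,
                       o2_start = 7.5, noise_sd = 0, transient_amp = 0,
                       transient_tau = 90, temp = 24, vol_l = 0.00175,
                       vial_id = "T1") {
  t <- seq(0, minutes * 60, by = interval_s)
  o2 <- o2_start + slope_per_h * t / 3600 +
    transient_amp * exp(-t / transient_tau)
  if (noise_sd > 0) o2 <- o2 + rnorm(length(t), 0, noise_sd)
  oxygen_trace(t, pmax(o2, 0), temp, vol_l, vial_id)
}

# Exhaustive window-selection oracle, lm-based: enumerates every window
# aligned to sample points with duration within [min, max] minutes,
# fits lm() in each, applies the same criterion and tie-break (latest
# start, then longest). Independent of the package's cumulative-sum path.
brute_force_window <- function(trace, cfg = window_config(),
                               engine = c("lm", "cov")) {
  engine <- match.arg(engine)
  t <- trace$times_s
  y <- trace$o2
  n <- length(t)
  dur <- t[n] - t[1]
  min_s <- cfg$min_minutes * 60
  max_s <- cfg$max_minutes * 60
  if (dur < min_s + 2 * median(diff(t))) min_s <- max_s <- dur
  if (dur < max_s) max_s <- dur
  best <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      w <- t[j] - t[i]
      if (w < min_s || w > max_s) next
      xi <- t[i:j]; yi <- y[i:j]
      if (stats::var(yi) == 0) {
        slope <- 0; r2 <- 0
        resid_sd <- 0
      } else if (engine == "lm") {
        fit <- stats::lm(yi ~ xi)
        slope <- unname(coef(fit)[2])
        s <- summary(fit)
        r2 <- s$r.squared
        resid_sd <- s$sigma
      } else {
        slope <- stats::cov(xi, yi) / stats::var(xi)
        r2 <- stats::cor(xi, yi)^2
        res <- yi - mean(yi) - slope * (xi - mean(xi))
        resid_sd <- sqrt(sum(res^2) / (length(xi) - 2))
      }
      crit <- if (cfg$criterion == "max_r2") r2 else -resid_sd
      if (is.null(best) || crit > best$crit ||
          (crit == best$crit && (i > best$i0 ||
                                 (i == best$i0 && j > best$i1)))) {
        best <- list(i0 = i, i1 = j, crit = crit,
                     slope_per_h = slope * 3600, r2 = r2)
      }
    }
  }
  best
}

# A scope_curve built directly from vectors (for feature-location tests).
make_scope_curve <- function(weight_g, tms, lmr = rep(1, length(tms))) {
  out <- data.frame(weight_g = weight_g, lmr = lmr, hmr = lmr + tms,
                    tms = tms, fms = (lmr + tms) / lmr)
  class(out) <- c("scope_curve", "data.frame")
  out
}

# Dilution-series table with an exact standard-curve slope.
dilution_fixture <- function(slope, gene = "G1", c0 = 24, reps = 2,
                             levels = 5, factor = 5) {
  lv <- -(seq_len(levels) - 1) * log10(factor)
  ex <- expand.grid(log10_input = lv, rep = seq_len(reps))
  data.frame(gene = gene, log10_input = ex$log10_input, rep = ex$rep,
             cq = c0 + slope * ex$log10_input, stringsAsFactors = FALSE)
}

# Long-format Cq table builder: cq_matrix is samples x genes (rownames /
# colnames used as ids), one technical rep.
make_cq_df <- function(cq_matrix, phase = NULL, reference_genes = character(0)) {
  samples <- rownames(cq_matrix) %||% sprintf("S%02d", seq_len(nrow(cq_matrix)))
  genes <- colnames(cq_matrix)
  phase <- phase %||% rep("activation", length(samples))
  do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(sample_id = samples[i], stage = 15L, phase = phase[i],
               gene = genes, rep = 1L, cq = as.numeric(cq_matrix[i, ]),
               is_reference = genes %in% reference_genes,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
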