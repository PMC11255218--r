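test_that("efficiency from slope matches analytic values", {
  # slope -1/log10(2) is exact doubling
  e <- efficiency_from_dilution(dilution_fixture(-1 / log10(2)))
  expect_equal(e$e_percent, 100, tolerance = 1e-9)
  expect_equal(e$r2, 1, tolerance = 1e-12)
  expect_true(e$valid)
})

test_that("efficiency/slope round-trip is exact over random slopes", {
  set.seed(51)
  for (s in -runif(20, 2.8, 4.5)) {
    e <- suppressWarnings(
      efficiency_from_dilution(dilution_fixture(s))$e_fraction)
    expect_equal(slope_from_efficiency(e), s, tolerance = 1e-9)
  }
})

test_that("efficiency estimation flags and errors pathological curves", {
  expect_warning(e <- efficiency_from_dilution(dilution_fixture(3.3)),
                 "positive")
  expect_false(e$valid)
  expect_warning(efficiency_from_dilution(dilution_fixture(-4.5)),
                 "outside the usual")
  flat <- dilution_fixture(0)
  expect_error(suppressWarnings(efficiency_from_dilution(flat)),
               "zero standard-curve slope")
  few <- dilution_fixture(-3.3, levels = 2)
  expect_error(efficiency_from_dilution(few), "3 distinct dilution levels")
  neg <- dilution_fixture(-3.3)
  neg$cq[1] <- -1
  expect_error(efficiency_from_dilution(neg), "> 0")
})

test_that("relative quantity and normalization factor basics", {
  expect_equal(relative_quantity(20, 20, 0.9), 1)
  expect_equal(relative_quantity(17, 20, 1), 8)
  expect_equal(relative_quantity(19, 20, 0.823), 1.823)
  expect_error(relative_quantity(19, 20, -1), "efficiency")
  expect_equal(normalization_factor(c(2, 8)), 4)
  expect_equal(normalization_factor(5), 5)
  expect_equal(normalization_factor(c(1, 1, 1)), 1)
  expect_equal(normalization_factor(rbind(c(2, 8), c(1, 1))), c(4, 1))
  expect_error(normalization_factor(c(1, 0)), "positive")
})

test_that("normalized_expression: references define NF; shifts cancel", {
  set.seed(52)
  cqm <- cbind(T1 = rnorm(6, 24, 1), R1 = rep(20, 6), R2 = rep(22, 6))
  rownames(cqm) <- sprintf("S%02d", 1:6)
  d <- make_cq_df(cqm, reference_genes = c("R1", "R2"))
  ex <- normalized_expression(d, c(T1 = 1, R1 = 1, R2 = 1))
  # identical references across samples: NF constant, NRQ proportional to RQ
  expect_equal(ex$nf, rep(1, 6))
  expect_equal(ex$nrq, ex$rq)
  # adding a constant to every Cq of a gene leaves NRQ unchanged
  cqm2 <- cqm
  cqm2[, "T1"] <- cqm2[, "T1"] + 3
  ex2 <- normalized_expression(make_cq_df(cqm2, reference_genes = c("R1", "R2")),
                               c(T1 = 1, R1 = 1, R2 = 1))
  expect_equal(ex2$nrq, ex$nrq, tolerance = 1e-12)
})

test_that("E = 1 normalized expression reproduces delta-delta-Ct", {
  set.seed(53)
  for (i in 1:5) {
    cqm <- cbind(T1 = rnorm(8, 25, 1.2), T2 = rnorm(8, 27, 0.8),
                 R1 = rnorm(8, 20, 0.5), R2 = rnorm(8, 21, 0.5))
    rownames(cqm) <- sprintf("S%02d", 1:8)
    d <- make_cq_df(cqm, reference_genes = c("R1", "R2"))
    ex <- normalized_expression(d, c(T1 = 1, T2 = 1, R1 = 1, R2 = 1))
    for (g in c("T1", "T2")) {
      sub <- ex[ex$gene == g, ]
      # classic ddCt oracle: dCt = Cq_target - mean(Cq_refs); ratios between
      # samples must match 2^-(dCt_i - dCt_j)
      dct <- cqm[, g] - rowMeans(cqm[, c("R1", "R2")])
      expect_equal(sub$nrq / sub$nrq[1],
                   2^-(dct - dct[1]), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("missing Cq cells are dropped with a warning", {
  cqm <- cbind(T1 = c(24, 25, 24, 26, 25, 24), R1 = rep(20, 6),
               R2 = rep(21, 6))
  rownames(cqm) <- sprintf("S%02d", 1:6)
  d <- make_cq_df(cqm, reference_genes = c("R1", "R2"))
  d$cq[d$sample_id == "S01" & d$gene == "T1"] <- NA
  expect_warning(ex <- normalized_expression(d, c(T1 = 1, R1 = 1, R2 = 1)),
                 "missing Cq")
  expect_equal(nrow(ex), 5)
  # a sample missing a reference gene is dropped entirely
  d2 <- make_cq_df(cqm, reference_genes = c("R1", "R2"))
  d2$cq[d2$sample_id == "S02" & d2$gene == "R1"] <- NA
  expect_warning(ex2 <- normalized_expression(d2, c(T1 = 1, R1 = 1, R2 = 1)),
                 "reference genes")
  expect_false("S02" %in% ex2$sample_id)
})

test_that("technical replicates are averaged before quantification", {
  d1 <- data.frame(sample_id = "S1", stage = 10L, phase = "organogenesis",
                   gene = rep(c("T1", "R1", "R2"), each = 3), rep = 1:3,
                   cq = c(24, 25, 26, 20, 20, 20, 21, 21, 21),
                   is_reference = rep(c(FALSE, TRUE, TRUE), each = 3))
  d2 <- data.frame(sample_id = "S2", stage = 17L, phase = "growth",
                   gene = c("T1", "R1", "R2"), rep = 1L,
                   cq = c(24, 20, 21), is_reference = c(FALSE, TRUE, TRUE))
  ex <- normalized_expression(rbind(d1, d2), c(T1 = 1, R1 = 1, R2 = 1))
  # S1 mean T1 Cq is 25 vs S2's 24: one cycle at E=1 is a factor 2
  expect_equal(ex$nrq[ex$sample_id == "S2"] / ex$nrq[ex$sample_id == "S1"],
               2, tolerance = 1e-12)
})

test_that("reference stability: exact ratios, invariances, designed winners", {
  set.seed(54)
  # two genes with a constant Cq offset have pairwise ratio SD exactly 0
  base <- rnorm(10, 22, 1.5)
  cqm <- cbind(A = base, B = base + 2, C = rnorm(10, 25, 1))
  rownames(cqm) <- sprintf("S%02d", 1:10)
  st <- reference_stability(make_cq_df(cqm))
  expect_equal(st$genorm_m[st$gene == "A"],
               mean(c(0, sd((cqm[, "A"] - cqm[, "C"]) * -log2(2)))))
  # direct-oracle value for gene C
  m_c <- mean(c(sd(log2(2)^-1 * 0 + (cqm[, "C"] - cqm[, "A"]) * -1),
                sd((cqm[, "C"] - cqm[, "B"]) * -1)))
  expect_equal(st$genorm_m[st$gene == "C"], m_c)
  expect_true(all(st$gene[1:2] %in% c("A", "B")))

  # permutation of samples leaves the ranking unchanged
  perm <- sample(nrow(cqm))
  st_p <- reference_stability(make_cq_df(cqm[perm, ]))
  expect_equal(st_p[order(st_p$gene), ], st[order(st$gene), ],
               ignore_attr = TRUE)
  # relabeling genes permutes rows consistently
  cqm_r <- cqm[, c("C", "A", "B")]
  colnames(cqm_r) <- c("Z", "A", "B")
  st_r <- reference_stability(make_cq_df(cqm_r))
  expect_equal(st_r$genorm_m[st_r$gene == "Z"],
               st$genorm_m[st$gene == "C"])
  expect_error(reference_stability(make_cq_df(cqm[, 1:2])), "3 candidate")
  expect_error(reference_stability(make_cq_df(cqm[1:5, ])), "8 samples")
})

test_that("designed-stable reference genes rank top 2 in the generator world", {
  qp <- generate_qpcr(simulation_config(seed = 77))
  st <- reference_stability(qp$cq,
                            candidates = c("TufM", "Gpam", "EF1b", "hnRNP"))
  expect_setequal(st$gene[1:2], c("TufM", "Gpam"))
})

test_that("stage_comparison matches a hand-worked ANOVA on 8 numbers", {
  # two groups of 4 with symmetric noise: F computable by hand
  y <- c(5.1, 4.9, 5.2, 4.8, 6.1, 5.9, 6.2, 5.8)
  d <- data.frame(gene = "G", phase = rep(c("activation", "growth"), each = 4),
                  ln_nrq = y)
  res <- stage_comparison(d, "G")
  # hand-worked oracle: group means 5 and 6, SSB = 2*... computed directly
  m1 <- mean(y[1:4]); m2 <- mean(y[5:8]); gm <- mean(y)
  ssb <- 4 * ((m1 - gm)^2 + (m2 - gm)^2)
  ssw <- sum((y[1:4] - m1)^2) + sum((y[5:8] - m2)^2)
  f_oracle <- (ssb / 1) / (ssw / 6)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$df, c(1, 6))
  expect_lt(res$p_value, 0.05)
  # Tukey pairwise and Kruskal alternative run
  expect_s3_class(stage_comparison(d, "G", pairwise = TRUE)$pairwise,
                  "data.frame")
  expect_equal(stage_comparison(d, "G", method = "kruskal")$method, "kruskal")
})

test_that("degenerate zero-variance comparisons report no evidence", {
  d <- data.frame(gene = "G", phase = rep(c("activation", "growth"), each = 3),
                  ln_nrq = rep(2, 6))
  res <- stage_comparison(d, "G")
  expect_true(is.na(res$statistic))
  expect_true(is.na(res$p_value))
  expect_match(res$note, "zero within-group variance")
  expect_error(stage_comparison(d[1:3, ], "G"), ">= 2 groups")
})
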