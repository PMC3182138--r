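# TPTM normalization, the Audic-Claverie test, drought classification,
# two-fold patterns and expression PCA.

test_that("tptm arithmetic and error handling", {
  expect_equal(tptm(345, 5e6), 690)
  expect_equal(tptm(0, 1e6), 0)
  expect_equal(tptm(7, 7), 1e7)
  expect_error(tptm(1, 0), "positive")
})

test_that("log2 ratios reproduce a published row and handle zeros", {
  expect_equal(round(log2_ratio(1366, 489), 2), 1.48)
  expect_equal(log2_ratio(5, 5), 0)
  expect_true(is.na(log2_ratio(2, 0)))
  expect_true(is.na(log2_ratio(0, 2)))
})

test_that("conditional probability matches closed forms", {
  # x = y = 0 with equal totals reduces to 1/2
  expect_equal(ac_conditional_probability(0, 0, 1e6, 1e6), 0.5)
  # equal totals: p(y|x) is negative binomial with size x+1, prob 1/2
  expect_equal(ac_conditional_probability(10, 5, 1e6, 1e6),
               dnbinom(10, size = 6, prob = 0.5), tolerance = 1e-12)
  # unequal totals: NB with prob N1/(N1+N2)
  expect_equal(ac_conditional_probability(7, 3, 1e6, 2e6),
               dnbinom(7, size = 4, prob = 1 / 3), tolerance = 1e-12)
  expect_error(ac_conditional_probability(-1, 0, 1, 1), "input error")
})

test_that("conditional probabilities sum to one over y", {
  for (x in c(0, 3, 17)) {
    for (r in c(0.5, 1, 2)) {
      total <- sum(ac_conditional_probability(0:3000, x, 1e6, r * 1e6))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("two-tailed p-value: degenerate case, symmetry, oracle agreement", {
  expect_equal(ac_two_tailed_pvalue(0, 0, 1e6, 1e6), 1)
  set.seed(97)
  for (i in 1:200) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    N1 <- sample(1e5:2e6, 1)
    N2 <- round(N1 * runif(1, 0.25, 4))
    p1 <- ac_two_tailed_pvalue(x, y, N1, N2)
    expect_equal(p1, ac_two_tailed_pvalue(y, x, N2, N1), tolerance = 1e-9)
    expect_equal(p1, oracle_ac_pvalue(x, y, N1, N2), tolerance = 1e-10)
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
})

test_that("the negative-binomial form equals log-space summation", {
  # the accumulated probability switches to the closed negative-binomial
  # cumulative above x + y = 1e4; both representations agree below it
  for (case in list(c(400, 700), c(2500, 2100), c(4000, 5999))) {
    x <- case[1]; y <- case[2]
    q_sum <- droughtmiR:::ac_accumulated_q(x, y, 1e6, 1.3e6)
    q_nb <- pnbinom(y, size = x + 1, prob = 1e6 / (1e6 + 1.3e6))
    expect_equal(q_sum, q_nb, tolerance = 1e-9)
  }
  # p-values are continuous across the representation switch
  p_below <- ac_two_tailed_pvalue(4000, 5999, 1e6, 1.3e6)
  p_above <- ac_two_tailed_pvalue(4001, 6000, 1e6, 1.3e6)
  expect_lt(abs(log(p_below) - log(p_above)), 0.2)
})

test_that("equal counts with equal totals maximize p among fixed x + y", {
  for (s in c(10, 40)) {
    ps <- vapply(0:s, function(x)
      ac_two_tailed_pvalue(x, s - x, 1e6, 1e6), numeric(1))
    expect_equal(which.max(ps) - 1, s / 2)
  }
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni(0.001, m = 100), 0.1)
  expect_equal(bonferroni(0.5, m = 3), 1)
  set.seed(101)
  p <- runif(50)
  adj <- bonferroni(p, m = 80)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))   # monotone (ties at the cap)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("quantify_mature counts exact reads, plus 1-mismatch variants", {
  set.seed(103)
  mature <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  variant <- strsplit(mature, "", fixed = TRUE)[[1]]
  variant[10] <- setdiff(c("A", "C", "G", "T"), variant[10])[1]
  variant <- paste(variant, collapse = "")
  reads <- data.frame(sequence = c(mature, variant, strrep("A", 21)),
                      l1 = c(7L, 3L, 5L), l2 = c(0L, 1L, 0L),
                      stringsAsFactors = FALSE)
  prec <- list(m1 = list(
    sequence = paste0(strrep("C", 30), mature, strrep("G", 30)),
    mature_interval = c(30, 51)))
  exact <- quantify_mature(reads, c(m1 = mature))
  expect_equal(unname(exact["m1", ]), c(7, 0))
  mm <- quantify_mature(reads, c(m1 = mature),
                        mode = "one_mismatch_to_precursor",
                        precursors = prec)
  expect_equal(unname(mm["m1", ]), c(10, 1))
  none <- quantify_mature(reads, c(q = strrep("G", 21)))
  expect_equal(unname(none["q", ]), c(0, 0))
})

test_that("published TPTM tables reproduce printed log2 ratios at 2 dp", {
  tabs <- cowpea_expression_tables()
  t2 <- tabs$two_fold_tolerant
  r <- t2[t2$id == "miR1515", ]
  expect_equal(round(log2_ratio(r$it_drought, r$it_control), 2), 1.48)
  t3 <- tabs$two_fold_sensitive
  checks <- list(c("miR166a", 1.54), c("miR2111a", 2.53),
                 c("miR393", -2.12), c("miR482", -1.87))
  for (ck in checks) {
    r <- t3[t3$id == ck[1], ]
    expect_equal(round(log2_ratio(r$cb_drought, r$cb_control), 2),
                 as.numeric(ck[2]))
  }
})

test_that("the two-fold-only-in-one-genotype rule reproduces both tables", {
  tabs <- cowpea_expression_tables()
  p2 <- two_fold_pattern(tabs$two_fold_tolerant[, c("it_control", "it_drought")],
                         tabs$two_fold_tolerant[, c("cb_control", "cb_drought")])
  expect_equal(sum(p2 == "only_gA"), 12)
  p3 <- two_fold_pattern(tabs$two_fold_sensitive[, c("it_control", "it_drought")],
                         tabs$two_fold_sensitive[, c("cb_control", "cb_drought")])
  expect_equal(sum(p3 == "only_gB"), 10)
  # identical expression in both genotypes: neither
  flat <- data.frame(control = c(100, 50), drought = c(100, 50))
  expect_equal(two_fold_pattern(flat, flat), c("neither", "neither"))
})

test_that("drought classification applies all three criteria", {
  mk_tests <- function(tp, padj_gA, padj_gB) {
    data.frame(id = "m", x_gA = 1, y_gA = 1, x_gB = 1, y_gB = 1,
               tptm_gA_control = tp[1], tptm_gA_drought = tp[2],
               tptm_gB_control = tp[3], tptm_gB_drought = tp[4],
               log2_gA = log2_ratio(tp[2], tp[1]),
               log2_gB = log2_ratio(tp[4], tp[3]),
               p_gA = padj_gA, p_gB = padj_gB,
               padj_gA = padj_gA, padj_gB = padj_gB)
  }
  # published miR1515 pattern: strongly significant, up
  r <- classify_drought_associated(mk_tests(c(489, 1366, 1415, 2700),
                                            5e-63, 4e-60))
  expect_true(r$associated)
  expect_equal(r$direction, "up")
  # all four TPTM below 100: never associated
  r2 <- classify_drought_associated(mk_tests(c(9, 36, 8, 30), 1e-10, 1e-10))
  expect_false(r2$associated)
  # no significant comparison: not associated
  r3 <- classify_drought_associated(mk_tests(c(489, 1366, 1415, 2700),
                                             0.5, 0.02))
  expect_false(r3$associated)
  # discordant significant directions are flagged
  r4 <- classify_drought_associated(mk_tests(c(100, 500, 500, 100),
                                             1e-5, 1e-5))
  expect_true(r4$discordant)
})

test_that("classification is monotone in its thresholds", {
  pipe <- default_pipeline()
  t0 <- classify_drought_associated(pipe$tests)
  # raising the p threshold or lowering the TPTM floor keeps every call
  t_looser_p <- classify_drought_associated(pipe$tests, p_threshold = 0.05)
  t_lower_tptm <- classify_drought_associated(pipe$tests, min_tptm = 10)
  expect_true(all(which(t0$associated) %in% which(t_looser_p$associated)))
  expect_true(all(which(t0$associated) %in% which(t_lower_tptm$associated)))
})

test_that("simulated drought-regulated matures are recovered as associated", {
  pipe <- default_pipeline()
  tr <- default_truth()
  truth <- tr$mirna_table
  regulated <- truth$mature[truth$drought_log2fc != 0]
  tests <- pipe$tests
  tests$mature <- as_rna(tests$id)
  found <- tests$mature %in% regulated & tests$associated
  expect_gte(sum(found), length(regulated) - 1)
  # direction agrees with the design
  for (i in which(truth$drought_log2fc != 0)) {
    row <- tests[tests$mature == truth$mature[i], ]
    if (nrow(row) == 1 && row$associated) {
      expect_equal(row$direction,
                   if (truth$drought_log2fc[i] > 0) "up" else "down")
    }
  }
})

test_that("PCA separates a planted genotype effect and filters correctly", {
  # rank-1 structure: one genotype effect dominates
  set.seed(107)
  base <- exp(runif(40, log(60), log(800)))
  eff <- rep(c(4, 4, 0.25, 0.25), each = 1)
  tp <- outer(base, eff) + matrix(runif(160, 0, 0.5), 40)
  colnames(tp) <- c("gA_control", "gA_drought", "gB_control", "gB_drought")
  rownames(tp) <- paste0("m", 1:40)
  pc <- pca_expression(tp)
  expect_equal(sum(pc$variance_fraction), 1)
  expect_gt(pc$variance_fraction[1], 0.99)
  # combined TPTM 49 excluded, 50 included
  tp2 <- rbind(tp, m_edge49 = c(24, 25, 0, 0), m_edge50 = c(25, 25, 0, 0))
  pc2 <- pca_expression(tp2)
  expect_false("m_edge49" %in% pc2$kept)
  expect_true("m_edge50" %in% pc2$kept)
  expect_error(pca_expression(tp[1:2, ] * 0), "filter")
})

test_that("genotype-specific planted miRNAs dominate PC1 loadings", {
  pipe <- default_pipeline()
  tr <- default_truth()
  pc <- pca_expression(pipe$tptm)
  specific <- as_rna(tr$mirna_table$mature[tr$mirna_table$genotype_specific])
  top <- as_rna(pc$pc1_ranking$id[seq_len(length(specific) + 2)])
  expect_gte(sum(specific %in% top), length(specific) - 1)
})
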