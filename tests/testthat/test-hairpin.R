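# Anchor selection, window enumeration, star inference, the five criteria,
# best-hairpin choice and gene deduplication.

test_that("anchor selection sums counts across libraries at the threshold", {
  reads <- data.frame(sequence = c("A1", "A2", "A3"),
                      l1 = c(10L, 9L, 6L), l2 = c(0L, 0L, 5L),
                      l3 = 0L, l4 = 0L, stringsAsFactors = FALSE)
  reads$sequence <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20))
  a <- select_anchors(reads)
  # totals 10 (anchor), 9 (below), 11 summed across libraries (anchor)
  expect_setequal(a$sequence, reads$sequence[c(1, 3)])
  expect_equal(a$total[a$sequence == strrep("G", 20)], 11)
})

test_that("window enumeration follows the anchored 100-300/20 rule", {
  hit <- data.frame(read = strrep("A", 21), ref = "chr", start = 200L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- enumerate_windows(hit, ref_length = 1000)
  expect_equal(nrow(w), 22)
  expect_true(all(w$start <= 200 & w$end >= 221))
  unclipped <- w$end - w$start
  expect_true(all(sort(unique(unclipped[unclipped %in% seq(100, 300, 20)]))
                  %in% seq(100, 300, 20)))
  # left-anchored windows share their start 10 bp upstream of the read
  expect_true(any(w$start == 190))
  # right-anchored windows share their end 10 bp downstream of the read
  expect_true(any(w$end == 231))
})

test_that("windows near the reference edge are clipped or dropped", {
  hit <- data.frame(read = strrep("A", 21), ref = "chr", start = 50L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- enumerate_windows(hit, ref_length = 5000)
  expect_true(all(w$start >= 0))
  expect_true(all((w$end - w$start) >= 100))
  # a hit too close to the start for any right-anchored 100-nt window
  hit2 <- data.frame(read = strrep("A", 21), ref = "chr", start = 5L,
                     strand = "+", stringsAsFactors = FALSE)
  w2 <- enumerate_windows(hit2, ref_length = 5000)
  # right-anchored windows clip below the minimum length and drop entirely
  expect_true(all(w2$start == 0))
  expect_true(all(w2$end - w2$start >= 100))
})

test_that("star inference applies the 2-nt 3' overhang on a perfect stem", {
  set.seed(41)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  loop <- "CAACAACAAC"
  hp <- paste0(mature, loop, revcomp(mature), "AAAAAA")
  f <- fold_rna(hp)
  ml <- c(0, 22)
  star <- infer_star(f, ml)
  expect_false(is.null(star))
  # perfect duplex: star is the opposite arm shifted 2 nt toward the 3' end
  expect_equal(star[2] - star[1], 22)
  expect_equal(star[2], min(nchar(hp), 22 + nchar(loop) + 22 + 2))
})

test_that("a mature placed inside the terminal loop has no star", {
  set.seed(43)
  stem <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  loop <- strrep("CAA", 8)
  hp <- paste0(stem, loop, revcomp(stem))
  ml <- c(nchar(stem) + 1, nchar(stem) + nchar(loop) - 1)
  expect_null(infer_star(fold_rna(hp), ml))
})

test_that("criterion thresholds sit exactly at the stated boundaries", {
  # free energy: -35.0 passes, -34.9 fails
  c1 <- evaluate_criteria(make_test_candidate(energy = -35.0))$criteria
  expect_true(c1$delta_g_ok)
  c2 <- evaluate_criteria(make_test_candidate(energy = -34.9))$criteria
  expect_false(c2$delta_g_ok)
  # strand bias: 0.80 passes, 0.79 fails; precise 0.75 passes
  cand <- make_test_candidate()
  ml <- cand$mature_local
  mk_support <- function(sense_in, sense_out, anti) {
    data.frame(local_start = c(ml[1], 5, 5),
               local_end = c(ml[2], 15, 15),
               sense = c(TRUE, TRUE, FALSE),
               count = c(sense_in, sense_out, anti))
  }
  cand$support <- mk_support(60, 20, 20)   # bias 0.80, precise 0.75
  cc <- evaluate_criteria(cand)$criteria
  expect_equal(cc$strand_bias, 0.80)
  expect_true(cc$strand_ok)
  expect_equal(cc$precise_fraction, 0.75)
  expect_true(cc$precise_ok)
  cand$support <- mk_support(59, 20, 21)   # bias 0.79
  expect_false(evaluate_criteria(cand)$criteria$strand_ok)
})

test_that("duplex mismatches beyond 4 fail criterion 2", {
  cand <- make_test_candidate()
  ml <- cand$mature_local
  # fabricate a pairing table with 5 unpaired mature positions mid-duplex
  pm <- cand$fold$pairmate
  ppos <- (ml[1] + 1):ml[2]
  mid <- ppos[6:10]
  pm[pm[mid]] <- 0L
  pm[mid] <- 0L
  cand$fold$pairmate <- pm
  cr <- evaluate_criteria(cand)$criteria
  expect_equal(cr$duplex_mismatches, 5)
  expect_false(cr$duplex_ok)
})

test_that("planted hairpins with clean simulated reads pass all criteria", {
  pipe <- default_pipeline()
  tr <- default_truth()
  expect_true(all(planted_matures() %in% predicted_matures()))
  for (g in pipe$genes$genes[1:5]) {
    expect_true(g$criteria$pass)
  }
})

test_that("stored genes re-evaluate to pass (idempotent re-check)", {
  pipe <- default_pipeline()
  for (g in pipe$genes$genes) {
    re <- evaluate_criteria(g)
    expect_true(re$criteria$pass)
    expect_equal(re$criteria$delta_g, g$criteria$delta_g)
    expect_equal(re$criteria$strand_bias, g$criteria$strand_bias)
  }
})

test_that("tightening any criterion threshold never increases the gene count", {
  pipe <- default_pipeline()
  genes <- pipe$genes$genes
  n0 <- length(genes)
  tighter <- list(
    mirna_criteria(max_delta_g = -60),
    mirna_criteria(max_duplex_mismatches = 1),
    mirna_criteria(max_asym_bulges = 0),
    mirna_criteria(min_strand_bias = 0.95),
    mirna_criteria(min_precise_fraction = 0.95))
  for (crit in tighter) {
    n <- sum(vapply(genes, function(g)
      evaluate_criteria(g, crit)$criteria$pass, logical(1)))
    expect_lte(n, n0)
  }
  # loosening everything keeps every stored gene
  loose <- mirna_criteria(max_delta_g = -5, max_duplex_mismatches = 10,
                          max_asym_bulges = 5, max_bulge_size = 10,
                          min_strand_bias = 0, min_precise_fraction = 0)
  n_loose <- sum(vapply(genes, function(g)
    evaluate_criteria(g, loose)$criteria$pass, logical(1)))
  expect_equal(n_loose, n0)
})

test_that("choose_best_hairpin applies the lexicographic rule, order-free", {
  mk <- function(expr, dg, len, start) {
    structure(list(ref = "r", start = start, end = start + len, strand = "+",
                   mature_expression = expr, fold = list(energy = dg),
                   mature_genomic = c(start + 40, start + 61)),
              class = "hairpin_candidate")
  }
  a <- mk(100, -36, 120, 0); b <- mk(50, -50, 100, 0)
  expect_identical(choose_best_hairpin(list(a, b)), a)   # expression wins
  c1 <- mk(100, -40, 160, 0); c2 <- mk(100, -36, 120, 0)
  expect_identical(choose_best_hairpin(list(c1, c2)), c1) # then energy
  d1 <- mk(100, -40, 120, 5); d2 <- mk(100, -40, 160, 0)
  expect_identical(choose_best_hairpin(list(d1, d2)), d1) # then length
  # total order: permuting input never changes the selection
  set.seed(47)
  cands <- lapply(1:6, function(i)
    mk(sample(50:100, 1), -sample(36:60, 1), sample(c(100, 120, 140), 1),
       sample(0:5, 1)))
  picks <- vapply(1:10, function(i) {
    ch <- choose_best_hairpin(sample(cands))
    paste(ch$mature_expression, ch$fold$energy, ch$end - ch$start, ch$start)
  }, character(1))
  expect_equal(length(unique(picks)), 1)
  expect_error(choose_best_hairpin(list()), "no candidates")
})

test_that("deduplication merges contained precursors, keeps distinct loci", {
  mk_gene <- function(mature, prec, start, expr, set) {
    structure(list(ref = "r", start = start, end = start + nchar(prec),
                   strand = "+", sequence = prec, mature_seq = mature,
                   mature_expression = expr, fold = list(energy = -50),
                   mature_genomic = c(start + 10, start + 10 + nchar(mature)),
                   criteria = list(duplex_mismatches = 0L, asym_bulges = 0L,
                                   strand_bias = 1, precise_fraction = 1),
                   source_set = set), class = "hairpin_candidate")
  }
  set.seed(53)
  mat <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  long <- paste0(strrep("AC", 20), mat, strrep("GT", 30))
  short <- substr(long, 21, nchar(long) - 20)
  # a second homologous locus: same mature, different flanks
  long2 <- paste0(strrep("TG", 20), mat, strrep("CA", 30))
  gs1 <- list(genes = list(mk_gene(mat, long, 100, 40, "s1")),
              n_candidates_evaluated = 1L)
  gs2 <- list(genes = list(mk_gene(mat, short, 100, 40, "s2"),
                           mk_gene(mat, long2, 5000, 10, "s2")),
              n_candidates_evaluated = 2L)
  merged <- deduplicate_genes(list(gs1, gs2))
  # the contained precursor merges across sets; the homologous locus with
  # the same mature but distinct precursor stays a separate gene
  expect_equal(length(merged$genes), 2)
  expect_equal(length(unique(vapply(merged$genes, function(g) g$mature_seq,
                                    character(1)))), 1)
  # identical precursors found by two reference sets collapse to one gene
  both <- deduplicate_genes(list(
    list(genes = list(mk_gene(mat, long, 100, 40, "s1")),
         n_candidates_evaluated = 1L),
    list(genes = list(mk_gene(mat, long, 20, 35, "s2")),
         n_candidates_evaluated = 1L)))
  expect_equal(length(both$genes), 1)
})
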