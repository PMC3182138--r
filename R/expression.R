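# Digital expression: mature quantification, TPTM normalization, the
# Audic-Claverie exact test with Bonferroni adjustment, drought-association
# classification, two-fold genotype patterns, and PCA on log2 expression.

#' Quantify mature miRNAs per library
#'
#' In `exact` mode, a mature's count is the summed count of unique reads
#' identical to it. In `one_mismatch_to_precursor` mode, reads mapping with at
#' most one substitution to the precursor's mature interval (within 2 nt of
#' its boundaries) are also counted -- the re-mapping check used to rule out
#' SNP artifacts behind apparent genotype-specific expression.
#'
#' @param reads unique-read table from [collapse_unique()].
#' @param matures named character vector of mature sequences.
#' @param mode `"exact"` or `"one_mismatch_to_precursor"`.
#' @param precursors named list (parallel to `matures`) with elements
#'   `sequence` and `mature_interval` (0-based half-open); required for the
#'   one-mismatch mode.
#' @return integer matrix, matures x libraries.
#' @export
quantify_mature <- function(reads, matures,
                            mode = c("exact", "one_mismatch_to_precursor"),
                            precursors = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(matures) > 0)
  cc <- count_columns(reads)
  counts <- matrix(0L, nrow = length(matures), ncol = length(cc),
                   dimnames = list(names(matures), cc))
  mat_dna <- as_dna(matures)
  for (i in seq_along(matures)) {
    sel <- reads$sequence == mat_dna[i]
    if (mode == "one_mismatch_to_precursor") {
      if (is.null(precursors)) {
        stop("one-mismatch mode requires precursor sequences")
      }
      p <- precursors[[names(matures)[i]]]
      hits <- map_mismatch(reads$sequence,
                           setNames(p$sequence, "prec"), k = 1)
      iv <- p$mature_interval
      ok <- hits$start >= iv[1] - 2 &
        (hits$start + nchar(hits$read)) <= iv[2] + 2 & hits$strand == "+"
      sel <- sel | reads$sequence %in% hits$read[ok]
    }
    if (any(sel)) {
      counts[i, ] <- as.integer(colSums(reads[sel, cc, drop = FALSE]))
    }
  }
  counts
}

#' Normalize counts to transcripts per ten million (TPTM)
#'
#' @param count read count(s).
#' @param library_total total clean reads of the library (positive).
#' @return `count / library_total * 1e7`.
#' @export
tptm <- function(count, library_total) {
  if (any(library_total <= 0)) {
    stop("configuration error: library total must be positive")
  }
  count / library_total * 1e7
}

#' Per-cell TPTM of a count matrix
#'
#' @param counts matrix, matures x libraries.
#' @param library_totals named vector of per-library clean-read totals.
#' @return TPTM matrix of the same shape.
#' @export
tptm_matrix <- function(counts, library_totals) {
  stopifnot(ncol(counts) == length(library_totals))
  sweep(counts, 2, library_totals, function(c, n) tptm(c, n))
}

#' log2 ratio of normalized counts
#'
#' @param a,b TPTM values (numerator and denominator).
#' @return `log2(a / b)`; NA when either value is 0.
#' @export
log2_ratio <- function(a, b) {
  ifelse(a == 0 | b == 0, NA_real_, log2(a / b))
}

#' Audic-Claverie conditional probability p(y|x)
#'
#' The probability of observing `y` counts of a tag in a library of `N2`
#' total reads given `x` counts in a library of `N1` reads, under Poisson
#' sampling of a shared underlying rate:
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!}
#'   \left(1 + N_2/N_1\right)^{-(x+y+1)}}
#' evaluated in log space.
#'
#' @param y,x non-negative integer counts.
#' @param N1,N2 positive library totals.
#' @return probability mass (vectorized over `y` and `x`).
#' @export
ac_conditional_probability <- function(y, x, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(N1 <= 0) || any(N2 <= 0)) {
    stop("input error: counts must be non-negative, totals positive")
  }
  r <- N2 / N1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

# accumulated probability q = sum_{y' <= y} p(y'|x), stable log-space
# summation; for large x + y the equivalent negative-binomial cumulative
# form is used (p(.|x) is NB(x + 1, N1/(N1+N2)) by construction)
ac_accumulated_q <- function(x, y, N1, N2) {
  if (x + y > 1e4) {
    return(stats::pnbinom(y, size = x + 1, prob = N1 / (N1 + N2)))
  }
  yy <- 0:y
  r <- N2 / N1
  lp <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log1p(r)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

# upper tail 1 - q = sum_{y' > y} p(y'|x), summed directly so that small
# upper-tail p-values keep full relative precision (2 * (1 - q) would lose
# everything to cancellation when q is close to 1)
ac_upper_tail <- function(x, y, N1, N2) {
  if (x + y > 1e4) {
    return(stats::pnbinom(y, size = x + 1, prob = N1 / (N1 + N2),
                          lower.tail = FALSE))
  }
  r <- N2 / N1
  lterm <- function(yy) {
    yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log1p(r)
  }
  total <- 0
  yy <- y + 1
  repeat {
    block <- yy:(yy + 511)
    lp <- lterm(block)
    m <- max(lp)
    inc <- if (is.finite(m)) exp(m + log(sum(exp(lp - m)))) else 0
    total <- total + inc
    yy <- yy + 512
    # terms decay geometrically beyond the mean; stop once a block no
    # longer contributes at double precision
    if (inc <= total * 1e-18 || yy > y + 1 + 2e5) break
  }
  total
}

#' Audic-Claverie two-tailed p-value
#'
#' `q` is the accumulated probability of observing at most `y` counts; the
#' two-tailed p-value is `2q`, or `2(1 - q)` when `q` exceeds 0.5 (using the
#' x-y symmetry of the conditional distribution), capped into (0, 1]. The
#' `1 - q` branch sums the upper tail directly so small p-values retain full
#' relative precision.
#'
#' @inheritParams ac_conditional_probability
#' @return p-value(s) in (0, 1].
#' @export
ac_two_tailed_pvalue <- function(x, y, N1, N2) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  if (any(x < 0) || any(y < 0) || any(N1 <= 0) || any(N2 <= 0)) {
    stop("input error: counts must be non-negative, totals positive")
  }
  vapply(seq_len(n), function(i) {
    q <- ac_accumulated_q(x[i], y[i], N1[i], N2[i])
    p <- if (q > 0.5) 2 * ac_upper_tail(x[i], y[i], N1[i], N2[i]) else 2 * q
    min(max(p, .Machine$double.xmin), 1)
  }, numeric(1))
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param m number of tests (defaults to `length(p)`; must be at least that).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

#' Differential expression tests for both genotype comparisons
#'
#' Runs the Audic-Claverie test drought vs. control within each genotype and
#' Bonferroni-adjusts each comparison over the tested matures.
#'
#' @param counts integer matrix, matures x the four libraries (`gA_control`,
#'   `gA_drought`, `gB_control`, `gB_drought`).
#' @param library_totals named totals for the four libraries.
#' @return data frame per mature: raw counts, TPTM, per-genotype log2 ratios,
#'   raw and adjusted p-values.
#' @export
ac_test_table <- function(counts, library_totals) {
  tp <- tptm_matrix(counts, library_totals)
  ids <- rownames(counts)
  p_gA <- ac_two_tailed_pvalue(counts[, "gA_control"], counts[, "gA_drought"],
                               library_totals[["gA_control"]],
                               library_totals[["gA_drought"]])
  p_gB <- ac_two_tailed_pvalue(counts[, "gB_control"], counts[, "gB_drought"],
                               library_totals[["gB_control"]],
                               library_totals[["gB_drought"]])
  data.frame(
    id = ids,
    x_gA = counts[, "gA_control"], y_gA = counts[, "gA_drought"],
    x_gB = counts[, "gB_control"], y_gB = counts[, "gB_drought"],
    tptm_gA_control = tp[, "gA_control"], tptm_gA_drought = tp[, "gA_drought"],
    tptm_gB_control = tp[, "gB_control"], tptm_gB_drought = tp[, "gB_drought"],
    log2_gA = log2_ratio(tp[, "gA_drought"], tp[, "gA_control"]),
    log2_gB = log2_ratio(tp[, "gB_drought"], tp[, "gB_control"]),
    p_gA = p_gA, p_gB = p_gB,
    padj_gA = bonferroni(p_gA), padj_gB = bonferroni(p_gB),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify drought-associated miRNAs
#'
#' A mature is drought-associated when (1) the adjusted p-value is below
#' `p_threshold` in at least one genotype comparison, (2) TPTM reaches
#' `min_tptm` in at least one of the four libraries, and (3) the drought /
#' control log2 ratio exceeds `log2_threshold` in magnitude in at least one
#' genotype (NA ratios from zero counts do not qualify). The direction is the
#' sign of the qualifying genotype's ratio; records where both genotypes are
#' significant with opposite signs are flagged discordant.
#'
#' @param tests table from [ac_test_table()].
#' @param p_threshold adjusted p-value cut (default 0.01).
#' @param min_tptm normalized-count floor (default 100).
#' @param log2_threshold magnitude the log2 ratio must exceed (default 1).
#' @return `tests` with added columns `associated`, `direction`, `discordant`
#'   and `two_fold_pattern`.
#' @export
classify_drought_associated <- function(tests, p_threshold = 0.01,
                                        min_tptm = 100, log2_threshold = 1) {
  sig_A <- tests$padj_gA < p_threshold
  sig_B <- tests$padj_gB < p_threshold
  crit1 <- sig_A | sig_B
  tpcols <- c("tptm_gA_control", "tptm_gA_drought",
              "tptm_gB_control", "tptm_gB_drought")
  crit2 <- apply(tests[, tpcols], 1, max) >= min_tptm
  big_A <- !is.na(tests$log2_gA) & abs(tests$log2_gA) > log2_threshold
  big_B <- !is.na(tests$log2_gB) & abs(tests$log2_gB) > log2_threshold
  crit3 <- big_A | big_B
  tests$associated <- crit1 & crit2 & crit3
  dir_A <- ifelse(sig_A & !is.na(tests$log2_gA), sign(tests$log2_gA), NA)
  dir_B <- ifelse(sig_B & !is.na(tests$log2_gB), sign(tests$log2_gB), NA)
  tests$discordant <- !is.na(dir_A) & !is.na(dir_B) & dir_A != dir_B
  d <- ifelse(!is.na(dir_A), dir_A, dir_B)
  tests$direction <- ifelse(tests$associated & !tests$discordant,
                            ifelse(d > 0, "up", "down"), NA_character_)
  tests$two_fold_pattern <- two_fold_pattern(
    tests[, tpcols[1:2]], tests[, tpcols[3:4]])
  tests
}

#' Two-fold drought-change pattern per genotype
#'
#' A genotype shows a two-fold change when `|log2(drought/control TPTM)| >= 1`;
#' ratios undefined because of a zero count count as no change. Patterns are
#' `both`, `only_gA`, `only_gB` or `neither`.
#'
#' @param tptm_gA,tptm_gB two-column objects (control, drought TPTM) per
#'   genotype.
#' @return character vector of patterns.
#' @export
two_fold_pattern <- function(tptm_gA, tptm_gB) {
  lA <- log2_ratio(tptm_gA[[2]], tptm_gA[[1]])
  lB <- log2_ratio(tptm_gB[[2]], tptm_gB[[1]])
  twoA <- !is.na(lA) & abs(lA) >= 1
  twoB <- !is.na(lB) & abs(lB) >= 1
  ifelse(twoA & twoB, "both",
         ifelse(twoA, "only_gA", ifelse(twoB, "only_gB", "neither")))
}

#' Principal component analysis of log2 miRNA expression
#'
#' Matures with combined expression of at least `min_combined_tptm` across
#' the libraries are retained; the analysis runs on column-centered
#' `log2(TPTM + pseudocount)` with libraries as observations.
#'
#' @param tptm TPTM matrix, matures x libraries.
#' @param min_combined_tptm row-sum filter (default 50).
#' @param pseudocount added before the log2 transform (default 1).
#' @return object of class `pca_expression`: `scores` (libraries x PCs),
#'   `loadings` (matures x PCs), `variance_fraction`, and `pc1_ranking`
#'   (matures ranked by squared PC1 loading with cumulative fractions).
#' @export
pca_expression <- function(tptm, min_combined_tptm = 50, pseudocount = 1) {
  keep <- rowSums(tptm) >= min_combined_tptm
  if (sum(keep) < 2) stop("fewer than 2 miRNAs pass the expression filter")
  x <- log2(tptm[keep, , drop = FALSE] + pseudocount)
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  load1 <- pc$rotation[, 1]
  ord <- order(load1^2, decreasing = TRUE)
  ranking <- data.frame(
    id = rownames(pc$rotation)[ord],
    pc1_loading = load1[ord],
    squared_fraction = load1[ord]^2 / sum(load1^2),
    cumulative_fraction = cumsum(load1[ord]^2) / sum(load1^2),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, kept = rownames(tptm)[keep],
                 pc1_ranking = ranking),
            class = "pca_expression")
}

#' @export
print.pca_expression <- function(x, ...) {
  cat(sprintf("PCA on %d miRNAs x %d libraries\n", length(x$kept),
              nrow(x$scores)))
  vf <- round(100 * x$variance_fraction, 1)
  cat("variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}
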