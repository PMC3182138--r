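# Hairpin discovery: anchor selection, candidate window enumeration, star
# inference, the five annotation criteria, best-hairpin choice per region,
# and cross-reference-set deduplication.

#' Annotation criteria thresholds for hairpin evaluation
#'
#' The five criteria a candidate precursor must meet: (1) folding free energy
#' at or below `max_delta_g` kcal/mol; (2) at most `max_duplex_mismatches`
#' mismatches between the mature and star arms; (3) at most `max_asym_bulges`
#' asymmetric bulges of size at most `max_bulge_size` in the mature-star stem;
#' (4) at least `min_strand_bias` of locus-mapped reads on the hairpin's
#' transcribed strand; (5) at least `min_precise_fraction` of precursor-mapped
#' reads within the mature/star regions extended by `precise_slop` nt.
#'
#' @param max_delta_g free energy threshold, kcal/mol (default -35).
#' @param max_duplex_mismatches default 4.
#' @param max_asym_bulges default 1.
#' @param max_bulge_size default 2.
#' @param min_strand_bias default 0.80.
#' @param min_precise_fraction default 0.75.
#' @param precise_slop nt added to each side of mature/star (default 2).
#' @return a named list of thresholds (class `mirna_criteria`).
#' @export
mirna_criteria <- function(max_delta_g = -35, max_duplex_mismatches = 4,
                           max_asym_bulges = 1, max_bulge_size = 2,
                           min_strand_bias = 0.80, min_precise_fraction = 0.75,
                           precise_slop = 2) {
  structure(list(max_delta_g = max_delta_g,
                 max_duplex_mismatches = max_duplex_mismatches,
                 max_asym_bulges = max_asym_bulges,
                 max_bulge_size = max_bulge_size,
                 min_strand_bias = min_strand_bias,
                 min_precise_fraction = min_precise_fraction,
                 precise_slop = precise_slop),
            class = "mirna_criteria")
}

#' Select anchor reads for hairpin prediction
#'
#' Anchors are unique reads whose count summed across all libraries reaches
#' `min_copies` (default 10).
#'
#' @param reads unique-read table from [collapse_unique()].
#' @param min_copies redundancy threshold (default 10).
#' @return the subset of `reads` qualifying as anchors, with a `total` column.
#' @export
select_anchors <- function(reads, min_copies = 10) {
  cc <- count_columns(reads)
  total <- rowSums(as.matrix(reads[, cc, drop = FALSE]))
  out <- reads[total >= min_copies, , drop = FALSE]
  out$total <- total[total >= min_copies]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate precursor windows around a mapped anchor
#'
#' For window lengths 100, 120, ..., 300 nt, emits up to two windows per
#' length: one anchored with 10 bp of flank beyond the read's 5' end and one
#' with 10 bp beyond the read's 3' end, each containing the full read. Windows
#' extending past the reference are clipped to the reference bounds and
#' dropped when the clipped width falls below the minimum window length.
#'
#' @param hit one mapping-hit row (`ref`, `start`, `strand`, `read`).
#' @param ref_length length of the reference sequence.
#' @param lengths window lengths to sample (default `seq(100, 300, 20)`).
#' @param flank anchored flank beyond the read end (default 10).
#' @return data frame of windows: `ref`, `start`, `end` (0-based half-open,
#'   plus-strand coordinates), `strand`, `anchor` (`5p`/`3p`).
#' @export
enumerate_windows <- function(hit, ref_length,
                              lengths = seq(100, 300, by = 20), flank = 10) {
  rs <- hit$start             # 0-based read start
  re <- rs + nchar(hit$read)  # half-open read end
  # both anchorings are enumerated symmetrically in plus-strand coordinates;
  # for minus-strand hits the 5'/3' labels swap but the window set is the same
  left <- data.frame(start = rs - flank, end = rs - flank + lengths,
                     anchor = if (hit$strand == "+") "5p" else "3p")
  right <- data.frame(start = re + flank - lengths, end = re + flank,
                      anchor = if (hit$strand == "+") "3p" else "5p")
  w <- rbind(left, right)
  w$start <- pmax(w$start, 0L)
  w$end <- pmin(w$end, ref_length)
  keep <- (w$end - w$start) >= min(lengths) & w$start <= rs & w$end >= re
  w <- w[keep, , drop = FALSE]
  data.frame(ref = hit$ref, start = as.integer(w$start),
             end = as.integer(w$end), strand = hit$strand,
             anchor = w$anchor, stringsAsFactors = FALSE, row.names = NULL)
}

# window sequence in transcription orientation (revcomp for minus strand)
window_sequence <- function(reference, ref, start, end, strand) {
  s <- substr(reference[[ref]], start + 1, end)
  if (strand == "-") revcomp(s) else s
}

# convert a plus-strand subinterval to window-local, orientation-aware
# 0-based half-open coordinates
local_interval <- function(win_start, win_end, strand, start, end) {
  if (strand == "+") c(start - win_start, end - win_start)
  else c(win_end - end, win_end - start)
}

#' Infer the star interval from a fold and the mature position
#'
#' The star is the region paired opposite the mature, shifted to model the
#' canonical 2-nt 3' overhangs left by Dicer on both duplex strands. Fails
#' (`no_star`) when fewer than 60% of mature positions are paired or when the
#' pairing partners fall inside the mature itself (mature in the loop).
#'
#' @param fold a `fold_result`.
#' @param mature_interval 0-based half-open interval of the mature within the
#'   folded sequence.
#' @return 0-based half-open star interval, or NULL when no star can be
#'   assigned (the candidate fails).
#' @export
infer_star <- function(fold, mature_interval) {
  n <- nchar(fold$sequence)
  m1 <- mature_interval[1] + 1L   # 1-based inclusive
  m2 <- mature_interval[2]
  stopifnot(m1 >= 1, m2 <= n, m1 < m2)
  pos <- m1:m2
  mate <- fold$pairmate[pos]
  paired <- mate > 0
  if (mean(paired) < 0.60) {
    return(NULL)
  }
  inside <- mate[paired] >= m1 & mate[paired] <= m2
  if (any(inside)) {
    return(NULL)
  }
  ppos <- pos[paired]
  i_star <- ppos[1]            # first paired mature position
  j_star <- ppos[length(ppos)] # last paired mature position
  # partner index decreases as the mature index increases on either arm;
  # extrapolate partners for unpaired mature ends, then apply the 2-nt
  # 3' overhang shift on both strands
  lo <- fold$pairmate[j_star] - (m2 - j_star) + 2L
  hi <- fold$pairmate[i_star] + (i_star - m1) + 2L
  lo <- max(1L, lo)
  hi <- min(n, hi)
  if (hi <= lo) return(NULL)
  if (lo <= m2 && hi >= m1) return(NULL)
  c(lo - 1L, hi)
}

# stem geometry between mature and star: duplex mismatches and asymmetric
# bulges, measured from the pairing table within the mature span
duplex_geometry <- function(fold, mature_interval) {
  m1 <- mature_interval[1] + 1L
  m2 <- mature_interval[2]
  pos <- m1:m2
  mate <- fold$pairmate[pos]
  ppos <- pos[mate > 0]
  if (length(ppos) < 2) {
    return(list(mismatches = length(pos), bulges = integer(0)))
  }
  span <- ppos[1]:ppos[length(ppos)]
  mism <- sum(fold$pairmate[span] == 0)
  bulges <- integer(0)
  for (k in seq_len(length(ppos) - 1)) {
    gap_m <- ppos[k + 1] - ppos[k] - 1L
    gap_s <- abs(fold$pairmate[ppos[k]] - fold$pairmate[ppos[k + 1]]) - 1L
    if (gap_m != gap_s) bulges <- c(bulges, abs(gap_m - gap_s))
  }
  list(mismatches = mism, bulges = bulges)
}

#' Evaluate the five annotation criteria on a hairpin candidate
#'
#' @param candidate a `hairpin_candidate` (see [predict_mirna_genes()]); must
#'   carry `fold`, `mature_local`, `star_local` and the window-mapped read
#'   support (`support`: data frame with `local_start`, `local_end`, `sense`,
#'   `count`).
#' @param criteria thresholds from [mirna_criteria()].
#' @return the candidate with a `criteria` element: per-criterion measured
#'   values and pass flags, plus `pass` (overall).
#' @export
evaluate_criteria <- function(candidate, criteria = mirna_criteria()) {
  geom <- duplex_geometry(candidate$fold, candidate$mature_local)
  sup <- candidate$support
  total_reads <- sum(sup$count)
  sense_reads <- sum(sup$count[sup$sense])
  strand_bias <- if (total_reads > 0) sense_reads / total_reads else 0
  slop <- criteria$precise_slop
  regions <- rbind(candidate$mature_local + c(-slop, slop),
                   if (!is.null(candidate$star_local))
                     candidate$star_local + c(-slop, slop))
  sense <- sup[sup$sense, , drop = FALSE]
  in_region <- rep(FALSE, nrow(sense))
  for (r in seq_len(nrow(regions))) {
    in_region <- in_region |
      (sense$local_start >= regions[r, 1] & sense$local_end <= regions[r, 2])
  }
  precise <- if (sum(sense$count) > 0) {
    sum(sense$count[in_region]) / sum(sense$count)
  } else 0
  crit <- list(
    delta_g = candidate$fold$energy,
    delta_g_ok = candidate$fold$energy <= criteria$max_delta_g,
    duplex_mismatches = geom$mismatches,
    duplex_ok = geom$mismatches <= criteria$max_duplex_mismatches,
    asym_bulges = length(geom$bulges),
    max_bulge = if (length(geom$bulges)) max(geom$bulges) else 0L,
    bulges_ok = length(geom$bulges) <= criteria$max_asym_bulges &&
      (length(geom$bulges) == 0 || max(geom$bulges) <= criteria$max_bulge_size),
    strand_bias = strand_bias,
    strand_ok = strand_bias >= criteria$min_strand_bias,
    precise_fraction = precise,
    precise_ok = precise >= criteria$min_precise_fraction
  )
  crit$pass <- crit$delta_g_ok && crit$duplex_ok && crit$bulges_ok &&
    crit$strand_ok && crit$precise_ok
  candidate$criteria <- crit
  candidate
}

#' Choose the best hairpin among candidates from the same region
#'
#' Lexicographic selection: highest mature expression, then lowest free
#' energy, then shortest window, then leftmost start (final deterministic
#' tie-break).
#'
#' @param candidates list of evaluated `hairpin_candidate` objects.
#' @return the selected candidate.
#' @export
choose_best_hairpin <- function(candidates) {
  if (length(candidates) == 0) stop("no candidates to choose from")
  expr <- vapply(candidates, function(c) c$mature_expression, numeric(1))
  dg <- vapply(candidates, function(c) c$fold$energy, numeric(1))
  len <- vapply(candidates, function(c) c$end - c$start, numeric(1))
  st <- vapply(candidates, function(c) c$start, numeric(1))
  candidates[[order(-expr, dg, len, st)[1]]]
}

# per-window read support: each read counts once per window (multi-mapped
# reads are not double-counted); a read with any hit on the window's
# transcribed strand counts as sense, located at its first sense hit
window_support <- function(hits, win, totals) {
  if (nrow(hits) == 0) {
    return(data.frame(local_start = integer(0), local_end = integer(0),
                      sense = logical(0), count = numeric(0)))
  }
  s <- hits$strand == win$strand
  ord <- order(hits$read, !s, hits$start)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$read)
  h <- h[first, , drop = FALSE]
  hs <- h$start
  he <- h$start + nchar(h$read)
  if (win$strand == "+") {
    ls <- hs - win$start; le <- he - win$start
  } else {
    ls <- win$end - he; le <- win$end - hs
  }
  data.frame(local_start = ls, local_end = le,
             sense = s[ord][first],   # sense hits sort first per read
             count = unname(totals[h$read]),
             row.names = NULL)
}

# grouping of candidates from the same region: candidates whose mature loci
# overlap on the same reference strand are alternative hairpins for one gene
# (grouping by whole-window overlap would chain adjacent independent loci
# through long windows, collapsing genuinely distinct genes)
region_groups <- function(cands) {
  n <- length(cands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- vapply(cands, function(c) paste(c$ref, c$strand), character(1))
  starts <- vapply(cands, function(c) c$mature_genomic[1], numeric(1))
  ends <- vapply(cands, function(c) c$mature_genomic[2], numeric(1))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (key[i] == key[j] && starts[i] < ends[j] && starts[j] < ends[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Predict miRNA genes from unique reads and a reference set
#'
#' The full discovery stage: select anchor reads, map them perfectly to the
#' reference, enumerate 100-300 nt candidate windows around each hit, fold
#' each window with the configured backend, locate the star arm, evaluate the
#' five annotation criteria against the window's read support, and keep the
#' best-scoring hairpin per overlapping region.
#'
#' @param reads unique-read table (post filtering) from [collapse_unique()].
#' @param reference named character vector of reference sequences or FASTA
#'   path.
#' @param criteria thresholds from [mirna_criteria()].
#' @param min_copies anchor redundancy threshold (default 10).
#' @param backend folding backend passed to [fold_rna()].
#' @param source_set label recorded on each gene (reference set name).
#' @return object of class `mirna_gene_set`: list with `genes` (list of
#'   `hairpin_candidate` winners), `table` (per-gene summary data frame with
#'   all criterion values) and `n_candidates_evaluated`.
#' @export
predict_mirna_genes <- function(reads, reference, criteria = mirna_criteria(),
                                min_copies = 10, backend = "bundled",
                                source_set = "ref") {
  reference <- ref_as_vector(reference)
  ref_len <- nchar(reference)
  anchors <- select_anchors(reads, min_copies = min_copies)
  all_hits <- map_exact(reads, reference)
  cc <- count_columns(reads)
  totals <- rowSums(as.matrix(reads[, cc, drop = FALSE]))
  names(totals) <- reads$sequence
  anchor_hits <- map_exact(anchors, reference)

  fold_cache <- new.env(parent = emptyenv())
  passed <- list()
  n_eval <- 0L
  for (h in seq_len(nrow(anchor_hits))) {
    hit <- anchor_hits[h, ]
    wins <- enumerate_windows(hit, ref_len[[hit$ref]])
    wins <- wins[!duplicated(wins[, c("start", "end", "strand")]), ,
                 drop = FALSE]
    for (w in seq_len(nrow(wins))) {
      win <- wins[w, ]
      key <- paste(win$ref, win$start, win$end, win$strand, sep = ":")
      fold <- if (!is.null(fold_cache[[key]])) fold_cache[[key]] else {
        f <- fold_rna(window_sequence(reference, win$ref, win$start, win$end,
                                      win$strand), backend = backend)
        fold_cache[[key]] <- f
        f
      }
      mature_local <- local_interval(win$start, win$end, win$strand,
                                     hit$start, hit$start + nchar(hit$read))
      star <- infer_star(fold, mature_local)
      if (is.null(star)) next
      ov <- all_hits[all_hits$ref == win$ref &
                       all_hits$start < win$end &
                       (all_hits$start + nchar(all_hits$read)) > win$start, ,
                     drop = FALSE]
      support <- window_support(ov, win, totals)
      cand <- structure(list(
        ref = win$ref, start = win$start, end = win$end, strand = win$strand,
        sequence = fold$sequence, fold = fold,
        mature_local = mature_local, star_local = star,
        mature_genomic = c(hit$start, hit$start + nchar(hit$read)),
        mature_seq = hit$read,
        mature_expression = unname(totals[hit$read]),
        support = support, source_set = source_set),
        class = "hairpin_candidate")
      cand <- evaluate_criteria(cand, criteria)
      n_eval <- n_eval + 1L
      if (cand$criteria$pass) passed[[length(passed) + 1L]] <- cand
    }
  }
  genes <- list()
  if (length(passed) > 0) {
    grp <- region_groups(passed)
    for (g in unique(grp)) {
      genes[[length(genes) + 1L]] <- choose_best_hairpin(passed[grp == g])
    }
    ord <- order(vapply(genes, function(x) x$ref, character(1)),
                 vapply(genes, function(x) x$start, numeric(1)))
    genes <- genes[ord]
  }
  structure(list(genes = genes, table = gene_table(genes),
                 n_candidates_evaluated = n_eval, source_set = source_set),
            class = "mirna_gene_set")
}

gene_table <- function(genes) {
  if (length(genes) == 0) {
    return(data.frame(id = character(), ref = character(), start = integer(),
                      end = integer(), strand = character(),
                      mature = character(), expression = numeric(),
                      delta_g = numeric(), duplex_mismatches = integer(),
                      asym_bulges = integer(), strand_bias = numeric(),
                      precise_fraction = numeric(), source_set = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = sprintf("gene%03d", seq_along(genes)),
    ref = vapply(genes, function(g) g$ref, character(1)),
    start = vapply(genes, function(g) as.integer(g$start), integer(1)),
    end = vapply(genes, function(g) as.integer(g$end), integer(1)),
    strand = vapply(genes, function(g) g$strand, character(1)),
    mature = as_rna(vapply(genes, function(g) g$mature_seq, character(1))),
    expression = vapply(genes, function(g) g$mature_expression, numeric(1)),
    delta_g = vapply(genes, function(g) g$fold$energy, numeric(1)),
    duplex_mismatches = vapply(genes, function(g)
      as.integer(g$criteria$duplex_mismatches), integer(1)),
    asym_bulges = vapply(genes, function(g)
      as.integer(g$criteria$asym_bulges), integer(1)),
    strand_bias = vapply(genes, function(g) g$criteria$strand_bias,
                         numeric(1)),
    precise_fraction = vapply(genes, function(g) g$criteria$precise_fraction,
                              numeric(1)),
    source_set = vapply(genes, function(g) g$source_set, character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.mirna_gene_set <- function(x, ...) {
  cat(sprintf("miRNA gene set '%s': %d gene(s) from %d evaluated candidates\n",
              x$source_set, length(x$genes), x$n_candidates_evaluated))
  if (length(x$genes) > 0) print(x$table[, c("id", "ref", "start", "end",
                                             "strand", "mature", "expression",
                                             "delta_g")])
  invisible(x)
}

#' Merge predicted genes across reference sets, removing redundancy
#'
#' Genes with identical mature sequence whose precursors are identical,
#' mutually contained, or at least 90% identical over the shorter precursor
#' merge into one gene, keeping the candidate ranked best by
#' [choose_best_hairpin()]'s ordering. Distinct loci sharing a mature remain
#' distinct genes.
#'
#' @param gene_sets list of `mirna_gene_set` objects (one per reference set).
#' @param min_identity identity fraction over the shorter precursor (default
#'   0.9).
#' @return a single `mirna_gene_set` of merged genes.
#' @export
deduplicate_genes <- function(gene_sets, min_identity = 0.9) {
  genes <- unlist(lapply(gene_sets, function(s) s$genes), recursive = FALSE)
  n <- length(genes)
  if (n == 0) {
    return(structure(list(genes = list(), table = gene_table(list()),
                          n_candidates_evaluated = 0L,
                          source_set = "merged"), class = "mirna_gene_set"))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mature <- vapply(genes, function(g) g$mature_seq, character(1))
  prec <- vapply(genes, function(g) g$sequence, character(1))
  set <- vapply(genes, function(g) g$source_set, character(1))
  # redundancy removal acts across reference sets (whose coordinates are not
  # comparable); within one set, distinct loci are genuinely distinct genes
  # and were already collapsed per region during prediction
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (set[i] == set[j] || mature[i] != mature[j]) next
      if (precursors_redundant(prec[i], prec[j], min_identity)) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(unique(comp), function(g) {
    choose_best_hairpin(genes[comp == g])
  })
  ord <- order(vapply(merged, function(x) x$ref, character(1)),
               vapply(merged, function(x) x$start, numeric(1)))
  merged <- merged[ord]
  structure(list(genes = merged, table = gene_table(merged),
                 n_candidates_evaluated =
                   sum(vapply(gene_sets, function(s)
                     s$n_candidates_evaluated, integer(1))),
                 source_set = "merged"),
            class = "mirna_gene_set")
}

precursors_redundant <- function(a, b, min_identity = 0.9) {
  if (a == b) return(TRUE)
  if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) return(TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b)) >= min_identity
}
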