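# Family annotation: alignment-based mismatch distance, single-linkage
# clustering at <= 2 mismatches, and naming against a reference mature set.

#' Alignment-based mismatch distance between mature miRNAs
#'
#' The distance is the number of substitutions plus indel columns in the
#' optimal pairwise alignment (unit costs), i.e. the Levenshtein edit
#' distance. Counting indel columns as mismatches makes the 2-mismatch family
#' rule total over sequences of unequal length.
#'
#' @param a,b character vectors of mature sequences (RNA or DNA alphabet).
#' @return integer matrix of pairwise distances (`length(a)` x `length(b)`).
#' @export
mature_distance <- function(a, b = a) {
  unname(adist(as_dna(a), as_dna(b)))
}

#' Cluster mature miRNAs into families by single linkage
#'
#' Families are the connected components of the graph joining matures at
#' distance at most `threshold` (default 2 mismatches).
#'
#' @param matures character vector of mature sequences.
#' @param threshold maximum mismatch distance joining two matures.
#' @return integer vector of cluster ids (1-based, in order of first
#'   appearance), named by the input sequences.
#' @export
cluster_families <- function(matures, threshold = 2) {
  matures <- as_dna(matures)
  n <- length(matures)
  if (n == 0) return(setNames(integer(0), character(0)))
  d <- mature_distance(matures)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (d[i, j] <= threshold) parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  setNames(match(root, unique(root)), matures)
}

#' Assign family names to mature miRNA clusters
#'
#' A cluster takes the family name of the closest reference mature within 2
#' mismatches of any member (ties broken by smallest distance, then by the
#' lexicographically first family name); clusters with no reference match are
#' annotated as new families with sequential `vun_cand` labels in
#' first-discovery order.
#'
#' @param matures character vector of mature sequences.
#' @param reference_matures named character vector of reference mature
#'   sequences; family names are parsed from the names (see
#'   [parse_mirna_family()]) or taken verbatim when no miR pattern is found.
#' @param threshold maximum mismatch distance for a reference match.
#' @param new_prefix label prefix for new families.
#' @return data frame with columns `mature`, `cluster`, `family`.
#' @export
assign_family_names <- function(matures, reference_matures, threshold = 2,
                                new_prefix = "vun_cand") {
  cl <- cluster_families(matures, threshold = threshold)
  fam_of_ref <- parse_mirna_family(names(reference_matures))
  d <- if (length(reference_matures) > 0) {
    mature_distance(matures, reference_matures)
  } else {
    matrix(NA_integer_, length(matures), 0)
  }
  out <- data.frame(mature = as_rna(names(cl)), cluster = unname(cl),
                    family = NA_character_, stringsAsFactors = FALSE)
  new_counter <- 0L
  for (k in unique(cl)) {
    rows <- which(cl == k)
    dk <- d[rows, , drop = FALSE]
    best <- if (length(dk) > 0) min(dk) else Inf
    if (length(reference_matures) > 0 && best <= threshold) {
      cand <- fam_of_ref[unique(which(dk == best, arr.ind = TRUE)[, "col"])]
      out$family[rows] <- sort(cand)[1]
    } else {
      new_counter <- new_counter + 1L
      out$family[rows] <- sprintf("%s%03d", new_prefix, new_counter)
    }
  }
  out
}

#' Parse miRNA family names from FASTA headers
#'
#' Extracts the family identifier (e.g. `miR156` from `ath-miR156a`) from
#' miRBase-style sequence names; names without a recognizable pattern are
#' returned unchanged.
#'
#' @param x character vector of sequence names.
#' @return character vector of family names.
#' @export
parse_mirna_family <- function(x) {
  m <- regmatches(x, regexpr("miR[0-9]+", x))
  out <- x
  has <- grepl("miR[0-9]+", x)
  out[has] <- m
  out
}
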