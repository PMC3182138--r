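# Read preprocessing: adapter trimming, unique-read collapsing, contaminant
# filtering, and exact / bounded-mismatch mapping to reference sets.

#' Trim the 3' adapter from raw small RNA reads
#'
#' A read is kept only if it contains a clear adapter occurrence: the leftmost
#' exact match of the adapter's first `match_len` bases. The insert is the
#' prefix preceding that occurrence. Reads without an adapter occurrence, or
#' whose insert is shorter than `min_len`, are rejected with a reason code.
#' Input reads are uppercased and U-normalized to T.
#'
#' @param reads character vector of raw reads.
#' @param adapter adapter sequence (length >= 6).
#' @param min_len minimum insert length to keep (default 18).
#' @param match_len number of leading adapter bases that must match exactly
#'   (default 8, capped at the adapter length).
#' @return data frame with columns `read`, `insert` (NA when rejected) and
#'   `status` (`ok`, `no_adapter`, `too_short`, `empty`).
#' @export
trim_adapter <- function(reads, adapter, min_len = 18, match_len = 8) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nchar(adapter) >= 6)
  reads <- as_dna(reads)
  key <- substr(as_dna(adapter), 1, min(nchar(adapter), match_len))
  pos <- as.integer(regexpr(key, reads, fixed = TRUE))
  insert <- ifelse(pos > 0, substr(reads, 1, pos - 1), NA_character_)
  status <- rep("ok", length(reads))
  status[nchar(reads) == 0] <- "empty"
  status[status == "ok" & pos <= 0] <- "no_adapter"
  status[status == "ok" & nchar(insert) < min_len] <- "too_short"
  insert[status != "ok"] <- NA_character_
  data.frame(read = reads, insert = insert, status = status,
             stringsAsFactors = FALSE)
}

#' Collapse library inserts into unique reads with per-library counts
#'
#' @param inserts named list, one element per library; each element is either
#'   a character vector of inserts (one entry per read) or a data frame with
#'   columns `sequence` and `count` (pre-collapsed reads).
#' @return data frame with column `sequence` followed by one integer count
#'   column per library (named as in `inserts`). Per-library column sums equal
#'   the number of input inserts.
#' @export
collapse_unique <- function(inserts) {
  stopifnot(is.list(inserts), !is.null(names(inserts)))
  tabs <- lapply(inserts, function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("sequence", "count") %in% names(x)))
      tapply(as.integer(x$count), as_dna(x$sequence), sum)
    } else if (length(x) == 0) {
      integer(0)
    } else {
      table(as_dna(x))
    }
  })
  seqs <- sort(unique(unlist(lapply(tabs, names))))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(inserts)) {
    cnt <- integer(length(seqs))
    t <- tabs[[lib]]
    if (length(t) > 0) {
      idx <- match(names(t), seqs)
      cnt[idx] <- as.integer(t)
    }
    out[[lib]] <- cnt
  }
  out
}

# count columns of a unique-read table (everything except `sequence`)
count_columns <- function(reads) setdiff(names(reads), "sequence")

#' Remove reads matching annotated contaminant sets
#'
#' Removes any unique read that occurs exactly (on either strand) as a
#' substring of any sequence in any annotation set (rRNA, tRNA, snRNA, snoRNA,
#' repeats, ...).
#'
#' @param reads unique-read data frame from [collapse_unique()].
#' @param annotations named list of annotation sets; each set a named character
#'   vector of sequences (or a file path readable by [read_fasta()]).
#' @return list with `kept` (filtered unique-read table), `removed` (removed
#'   rows with a `set` column naming the first matching set) and
#'   `removed_counts` (total read counts removed per set).
#' @export
filter_annotated <- function(reads, annotations) {
  stopifnot(is.list(annotations), length(annotations) > 0)
  subjects <- lapply(annotations, function(a) {
    if (is.character(a) && length(a) == 1 && file.exists(a)) a <- read_fasta(a)
    paste(as_dna(a), collapse = "NNNN")
  })
  hit_set <- rep(NA_character_, nrow(reads))
  rc <- revcomp(reads$sequence)
  for (set in names(subjects)) {
    todo <- is.na(hit_set)
    if (!any(todo)) break
    fwd <- vapply(reads$sequence[todo], grepl, logical(1),
                  x = subjects[[set]], fixed = TRUE, USE.NAMES = FALSE)
    rev <- vapply(rc[todo], grepl, logical(1),
                  x = subjects[[set]], fixed = TRUE, USE.NAMES = FALSE)
    hit_set[which(todo)[fwd | rev]] <- set
  }
  removed <- reads[!is.na(hit_set), , drop = FALSE]
  removed$set <- hit_set[!is.na(hit_set)]
  counts <- vapply(names(annotations), function(s) {
    sum(as.matrix(removed[removed$set == s, count_columns(reads)]))
  }, numeric(1))
  list(kept = reads[is.na(hit_set), , drop = FALSE],
       removed = removed, removed_counts = counts)
}

#' Map unique reads to a reference with perfect matching
#'
#' Reports all exact occurrences of each read on the forward strand and of its
#' reverse complement on the minus strand. Coordinates are 0-based, half-open;
#' minus-strand hits report the plus-strand interval.
#'
#' @param reads character vector of read sequences, or a unique-read table.
#' @param reference named character vector of reference sequences, or a FASTA
#'   path.
#' @return data frame with columns `read`, `ref`, `start` (0-based), `strand`
#'   (`+`/`-`) and `mismatches` (all 0).
#' @export
map_exact <- function(reads, reference) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reference <- ref_as_vector(reference)
  reads <- as_dna(reads)
  lens <- sort(unique(nchar(reads)))
  hits <- list()
  for (rn in names(reference)) {
    subj <- reference[[rn]]
    for (L in lens) {
      n <- nchar(subj) - L + 1
      if (n < 1) next
      subs <- substring(subj, 1:n, L:(nchar(subj)))
      sel <- which(nchar(reads) == L)
      # forward strand
      idx <- which(subs %in% reads[sel])
      if (length(idx) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          read = subs[idx], ref = rn, start = idx - 1L, strand = "+",
          mismatches = 0L, stringsAsFactors = FALSE)
      }
      # minus strand: read equals revcomp of the reference window
      rcsubs <- revcomp(subs)
      idx <- which(rcsubs %in% reads[sel])
      if (length(idx) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          read = rcsubs[idx], ref = rn, start = idx - 1L, strand = "-",
          mismatches = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(read = character(), ref = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$ref, out$start, out$strand, out$read), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map unique reads allowing bounded substitutions
#'
#' Reports all occurrences with Hamming distance at most `k` on either strand
#' (no indels), via [Biostrings::matchPattern()].
#'
#' @inheritParams map_exact
#' @param k maximum number of substitutions (0, 1 or 2).
#' @return data frame as in [map_exact()], with `mismatches` the Hamming
#'   distance of each hit.
#' @export
map_mismatch <- function(reads, reference, k) {
  stopifnot(k %in% 0:2)
  if (is.data.frame(reads)) reads <- reads$sequence
  reference <- ref_as_vector(reference)
  reads <- as_dna(reads)
  hits <- list()
  for (rn in names(reference)) {
    subj <- Biostrings::DNAString(reference[[rn]])
    for (rd in unique(reads)) {
      for (strand in c("+", "-")) {
        pat <- Biostrings::DNAString(if (strand == "+") rd else revcomp(rd))
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = k,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        starts <- BiocGenerics::start(m)
        ok <- starts >= 1 & BiocGenerics::end(m) <= length(subj)
        starts <- starts[ok]
        if (length(starts) == 0) next
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          read = rd, ref = rn, start = starts - 1L, strand = strand,
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(read = character(), ref = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$ref, out$start, out$strand, out$read), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ref_as_vector <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && !grepl("^[ACGTUacgtu]+$", reference)) {
    reference <- read_fasta(reference)
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  as_dna(reference)
}
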