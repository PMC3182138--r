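# Target prediction: exhaustive site scanning and the position-dependent
# mispair penalty system for miRNA:target duplexes.

# per-column duplex states:
#   WC  Watson-Crick pair          GU  G:U wobble pair
#   MM  mismatch                   BM  bulged miRNA base (gap in target)
#   BT  bulged target base (no miRNA position)
DUPLEX_STATES <- c("WC", "GU", "MM", "BM", "BT")

#' Construct a miRNA:target duplex alignment
#'
#' Columns run along the miRNA 5' to 3'; each non-`BT` column consumes one
#' miRNA position (1..L from the 5' end), each non-`BM` column one target
#' base.
#'
#' @param states character vector of per-column states (`WC`, `GU`, `MM`,
#'   `BM`, `BT`).
#' @return object of class `duplex_alignment` with `states` and `mirna_pos`
#'   (NA for target bulges).
#' @export
duplex_alignment <- function(states) {
  if (!all(states %in% DUPLEX_STATES)) {
    stop("invalid duplex state(s): ",
         paste(setdiff(states, DUPLEX_STATES), collapse = ", "))
  }
  pos <- cumsum(states != "BT")
  pos[states == "BT"] <- NA_integer_
  structure(list(states = states, mirna_pos = as.integer(pos)),
            class = "duplex_alignment")
}

#' Score a miRNA:target duplex with the position-dependent penalty system
#'
#' Each mismatch, single-nucleotide bulge or gap scores 1 and each G:U pair
#' 0.5; scores are doubled in the core region (miRNA positions `core` from
#' the 5' end; default 2-13). A target-side bulge has no miRNA position and is
#' classified by the adjacent miRNA position on its 3' side. Multi-nucleotide
#' bulges score 1 per nucleotide.
#'
#' @param duplex a [duplex_alignment()].
#' @param core miRNA positions forming the core region (default `2:13`).
#' @return list with `penalty` (0.5 granularity) and `n_indels` (total bulged
#'   and gapped nucleotides).
#' @export
score_duplex <- function(duplex, core = 2:13) {
  stopifnot(inherits(duplex, "duplex_alignment"))
  st <- duplex$states
  pos <- duplex$mirna_pos
  # target bulges take the next miRNA position 3' of the bulge
  if (anyNA(pos)) {
    L <- max(pos, na.rm = TRUE)
    nxt <- rev(cummin(rev(ifelse(is.na(pos), L + 1L, pos))))
    pos[is.na(pos)] <- nxt[is.na(pos)]
  }
  base <- c(WC = 0, GU = 0.5, MM = 1, BM = 1, BT = 1)[st]
  mult <- ifelse(pos %in% core, 2, 1)
  list(penalty = sum(base * mult),
       n_indels = sum(st %in% c("BM", "BT")))
}

#' Accept or reject a scored target hit
#'
#' A hit is accepted when the penalty score is 4 or less and the total number
#' of bulges and gaps is less than 2.
#'
#' @param penalty penalty score from [score_duplex()].
#' @param n_indels total bulged/gapped nucleotides.
#' @param max_penalty,max_indels acceptance bounds (defaults 4 and 1).
#' @return logical.
#' @export
accept_target <- function(penalty, n_indels, max_penalty = 4,
                          max_indels = 1) {
  penalty <= max_penalty & n_indels <= max_indels
}

# classify one miRNA base (RNA, 5'->3') against one target base (DNA sense
# strand): the duplex pairs the miRNA with the reverse complement reading
pair_state <- function(mirna_base, target_base) {
  m <- chartr("T", "U", mirna_base)
  t <- chartr("T", "U", target_base)
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

# build the duplex for one candidate site configuration; site_seq is the
# target site on the sense strand, consumed 3'->5' against the miRNA 5'->3'
site_duplex <- function(mirna_chars, site_chars, gap = 0L, gap_at = 0L) {
  # gap = 0: ungapped; gap = +1: one extra target base (BT) after miRNA
  # position gap_at; gap = -1: miRNA base gap_at bulged (BM)
  L <- length(mirna_chars)
  tpos <- length(site_chars)  # consume target from its 3' end
  states <- character(0)
  i <- 1L
  while (i <= L) {
    if (gap == 1L && gap_at == i - 1L && length(states) > 0 &&
        !any(states == "BT")) {
      states <- c(states, "BT")
      tpos <- tpos - 1L
      next
    }
    if (gap == -1L && gap_at == i) {
      states <- c(states, "BM")
      i <- i + 1L
      next
    }
    states <- c(states, pair_state(mirna_chars[i], site_chars[tpos]))
    tpos <- tpos - 1L
    i <- i + 1L
  }
  duplex_alignment(states)
}

#' Scan a transcript for candidate miRNA binding sites
#'
#' Exhaustively aligns the mature against every transcript window, enumerating
#' the ungapped configuration and every single-nucleotide bulge placement
#' (bulged miRNA base or bulged target base). All configurations whose penalty
#' is at most `max_penalty` are emitted, a guaranteed superset of the
#' accepted hits (alignments with two or more bulged/gapped nucleotides
#' cannot be accepted and are not enumerated).
#'
#' @param mature mature miRNA sequence (RNA or DNA alphabet).
#' @param transcript target transcript sequence (sense strand).
#' @param max_penalty pre-filter bound (default 4, the acceptance bound).
#' @param core core region passed to [score_duplex()].
#' @return data frame with columns `start`, `end` (0-based half-open site
#'   interval on the transcript), `penalty`, `n_indels`, `accepted`, `duplex`
#'   (compact state string, miRNA 5'->3').
#' @export
scan_sites <- function(mature, transcript, max_penalty = 4, core = 2:13) {
  mirna <- strsplit(as_rna(mature), "", fixed = TRUE)[[1]]
  tx <- as_dna(transcript)
  L <- length(mirna)
  n <- nchar(tx)
  if (n < L) stop("transcript shorter than the mature sequence")
  hits <- list()
  add <- function(s, width, dup) {
    sc <- score_duplex(dup, core = core)
    if (sc$penalty <= max_penalty) {
      hits[[length(hits) + 1L]] <<- data.frame(
        start = s - 1L, end = s - 1L + width, penalty = sc$penalty,
        n_indels = sc$n_indels,
        accepted = accept_target(sc$penalty, sc$n_indels),
        duplex = paste(dup$states, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  for (s in seq_len(n - L + 1L)) {
    site <- strsplit(substr(tx, s, s + L - 1L), "", fixed = TRUE)[[1]]
    add(s, L, site_duplex(mirna, site))
  }
  # one bulged target base: site is L + 1 wide
  if (n >= L + 1L) {
    for (s in seq_len(n - L)) {
      site <- strsplit(substr(tx, s, s + L), "", fixed = TRUE)[[1]]
      for (at in seq_len(L - 1L)) {
        add(s, L + 1L, site_duplex(mirna, site, gap = 1L, gap_at = at))
      }
    }
  }
  # one bulged miRNA base: site is L - 1 wide
  for (s in seq_len(n - L + 2L)) {
    if (s + L - 2L > n) next
    site <- strsplit(substr(tx, s, s + L - 2L), "", fixed = TRUE)[[1]]
    for (at in 2:(L - 1L)) {
      add(s, L - 1L, site_duplex(mirna, site, gap = -1L, gap_at = at))
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(), penalty = numeric(),
                      n_indels = integer(), accepted = logical(),
                      duplex = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end, out$penalty), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict targets for a set of mature miRNAs
#'
#' @param matures named character vector of mature sequences.
#' @param transcripts named character vector of transcript sequences or FASTA
#'   path.
#' @param ... passed to [scan_sites()].
#' @return data frame with `mirna`, `transcript` and the [scan_sites()]
#'   columns; only accepted hits are flagged `accepted = TRUE`.
#' @export
predict_targets <- function(matures, transcripts, ...) {
  transcripts <- ref_as_vector(transcripts)
  out <- list()
  for (m in names(matures)) {
    for (tx in names(transcripts)) {
      h <- scan_sites(matures[[m]], transcripts[[tx]], ...)
      if (nrow(h) > 0) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(mirna = m, transcript = tx, stringsAsFactors = FALSE), h)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), penalty = numeric(),
                      n_indels = integer(), accepted = logical(),
                      duplex = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
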