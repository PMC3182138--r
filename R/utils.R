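# Sequence string helpers. All internal sequence handling is on the DNA
# alphabet (U normalized to T at ingest); mature miRNAs are reported as RNA.

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (ACGT, case preserved as upper).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(x))))
}

#' Convert between RNA and DNA alphabets
#'
#' @param x character vector of sequences.
#' @return `as_dna()` replaces U with T; `as_rna()` replaces T with U.
#'   Both uppercase their input.
#' @export
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

# random DNA sequences with a target GC content
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(names(p), l, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# evaluate `code` under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read and write count-collapsed FASTA
#'
#' Collapsed FASTA stores one record per distinct read with the read count
#' appended to the header as `>id-count`, the standard interchange format for
#' unique small RNA tags.
#'
#' @param path file path.
#' @param reads data frame with columns `sequence` and `count`.
#' @param prefix header prefix for written records.
#' @return `read_collapsed_fasta()` returns a data frame with columns
#'   `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- names(x)
  count <- suppressWarnings(as.integer(sub("^.*-([0-9]+)\\s*$", "\\1", nm)))
  count[is.na(count)] <- 1L
  data.frame(sequence = as_dna(as.character(x)), count = count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_collapsed_fasta
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "read") {
  stopifnot(is.data.frame(reads), all(c("sequence", "count") %in% names(reads)))
  lines <- character(2L * nrow(reads))
  if (nrow(reads) > 0) {
    lines[c(TRUE, FALSE)] <- sprintf(">%s%d-%d", prefix, seq_len(nrow(reads)),
                                     reads$count)
    lines[c(FALSE, TRUE)] <- reads$sequence
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as FASTQ with uniform quality
#'
#' Expands a collapsed read table into one FASTQ record per read copy, with a
#' constant quality string (the simulator does not model per-base qualities).
#'
#' @param reads data frame with columns `sequence` and `count`.
#' @param path output path.
#' @param quality_char quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- rep(reads$sequence, reads$count)
  lines <- character(4L * length(seqs))
  if (length(seqs) > 0) {
    idx <- seq_along(seqs)
    lines[seq(1, length(lines), by = 4)] <- sprintf("@read%d", idx)
    lines[seq(2, length(lines), by = 4)] <- seqs
    lines[seq(3, length(lines), by = 4)] <- "+"
    lines[seq(4, length(lines), by = 4)] <-
      vapply(nchar(seqs), function(n) strrep(quality_char, n), character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of uppercase DNA sequences (U converted to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as_dna(as.character(x)), sub("\\s.*$", "", names(x)))
}
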