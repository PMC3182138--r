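#' Predict the minimum-free-energy secondary structure of an RNA sequence
#'
#' The bundled backend is a nearest-neighbor dynamic program (simplified
#' Turner-style parameters: stacking energies for Watson-Crick and G:U pairs,
#' length-dependent hairpin, bulge and internal-loop penalties, affine
#' multiloops, no pseudoknots). It returns a single MFE structure in
#' dot-bracket notation with its free energy in kcal/mol. An external backend
#' (`"rnafold"`, ViennaRNA's RNAfold executable on the PATH) is pluggable
#' behind the same contract; absolute energies are backend-dependent, so
#' downstream thresholds are configurable.
#'
#' @param sequence a single RNA/DNA string (ACGTU; T is treated as U).
#' @param backend `"bundled"` (default) or `"rnafold"`.
#' @return an object of class `fold_result`: list with `sequence`,
#'   `structure` (dot-bracket), `energy` (kcal/mol) and `pairmate`
#'   (1-based pairing partner per position, 0 = unpaired).
#' @examples
#' f <- fold_rna(paste0(strrep("GC", 15), "AAAAAAAAAA", strrep("GC", 15)))
#' f$energy < 0
#' @export
fold_rna <- function(sequence,
                     backend = getOption("droughtmiR.fold_backend", "bundled")) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  if (grepl("[^ACGTU]", seq)) {
    stop("sequence contains non-ACGTU characters")
  }
  res <- switch(match.arg(backend, c("bundled", "rnafold")),
    bundled = .fold_mfe_cpp(seq),
    rnafold = fold_rnafold(seq)
  )
  structure(list(sequence = seq, structure = res$structure,
                 energy = res$energy, pairmate = res$pairmate),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, sprintf(" (%.2f kcal/mol)\n", x$energy),
      sep = "")
  invisible(x)
}

# pairing-partner vector (1-based, 0 = unpaired) from a dot-bracket string
pairmate_from_dotbracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  mate <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      mate[i] <- j
      mate[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  mate
}

#' Is the external RNAfold backend available?
#'
#' @return TRUE if an `RNAfold` executable is found on the PATH.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

# ViennaRNA RNAfold as an external folding backend
fold_rnafold <- function(seq) {
  if (!rnafold_available()) stop("RNAfold executable not found on PATH")
  out <- system2("RNAfold", args = c("--noPS"), input = chartr("T", "U", seq),
                 stdout = TRUE)
  line <- out[2]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3) stop("could not parse RNAfold output: ", line)
  db <- m[2]
  list(structure = db, energy = as.numeric(m[3]),
       pairmate = pairmate_from_dotbracket(db))
}
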