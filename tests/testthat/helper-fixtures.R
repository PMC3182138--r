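# Shared fixtures, built once per test run and memoised: the default
# synthetic study (ground truth, simulated libraries) and full pipeline runs
# are reused across test files to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_truth <- function(seed = 7) {
  memo(paste0("truth", seed), design_truth(synthetic_design(seed = seed)))
}

default_sim <- function(seed = 7) {
  memo(paste0("sim", seed), simulate_libraries(default_truth(seed)))
}

default_pipeline <- function(seed = 7) {
  memo(paste0("pipe", seed), {
    tr <- default_truth(seed)
    run_mirna_pipeline(default_sim(seed)$libraries,
                       references = list(genome = tr$reference),
                       annotations = tr$contaminants,
                       adapter = tr$design$adapter)
  })
}

planted_matures <- function(seed = 7) {
  vapply(default_truth(seed)$mirnas, function(m) m$mature, character(1))
}

predicted_matures <- function(seed = 7) {
  unique(vapply(default_pipeline(seed)$genes$genes,
                function(g) g$mature_seq, character(1)))
}

# a clean constructed hairpin candidate for criterion boundary tests:
# perfect 24-bp duplex, 8-nt loop, with read support supplied by the caller
make_test_candidate <- function(support = NULL, energy = NULL) {
  set.seed(99)
  mature <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  b <- build_precursor(mature, n_star_mismatches = 0, arm = "5p")
  ml <- c(b$mature_start, b$mature_start + nchar(mature))
  star <- infer_star(b$fold, ml)
  if (is.null(support)) {
    support <- data.frame(local_start = ml[1], local_end = ml[2],
                          sense = TRUE, count = 100)
  }
  fold <- b$fold
  if (!is.null(energy)) fold$energy <- energy
  structure(list(ref = "t", start = 0L, end = nchar(b$precursor),
                 strand = "+", sequence = b$precursor, fold = fold,
                 mature_local = ml, star_local = star,
                 mature_genomic = c(ml[1], ml[2]), mature_seq = mature,
                 mature_expression = sum(support$count[support$sense]),
                 support = support, source_set = "t"),
            class = "hairpin_candidate")
}

# independent brute-force Audic-Claverie accumulated probability: direct
# term-by-term recurrence from the printed formula (no lgamma, no dnbinom)
oracle_ac_q <- function(x, y, N1, N2) {
  r <- N2 / N1
  p <- (1 / (1 + r))^(x + 1)   # p(0 | x)
  q <- p
  if (y > 0) {
    for (yp in seq_len(y)) {
      p <- p * r / (1 + r) * (x + yp) / yp
      q <- q + p
    }
  }
  q
}

oracle_ac_pvalue <- function(x, y, N1, N2) {
  r <- N2 / N1
  t <- (1 / (1 + r))^(x + 1)
  q <- t
  yp <- 0
  while (yp < y) {
    yp <- yp + 1
    t <- t * r / (1 + r) * (x + yp) / yp
    q <- q + t
  }
  if (q <= 0.5) {
    p <- 2 * q
  } else {
    # small upper tail: keep summing the recurrence past the mode
    tail <- 0
    repeat {
      yp <- yp + 1
      t <- t * r / (1 + r) * (x + yp) / yp
      tail <- tail + t
      if (yp > (x + 1) * r && t <= tail * 1e-18) break
    }
    p <- 2 * tail
  }
  min(max(p, .Machine$double.xmin), 1)
}

# independent rule-by-rule duplex penalty: explicit per-column loop with
# literal core doubling, used as the scoring oracle
oracle_score <- function(states, core = 2:13) {
  pos <- 0L
  penalty <- 0
  n_indels <- 0L
  L <- sum(states != "BT")
  for (i in seq_along(states)) {
    st <- states[i]
    if (st != "BT") pos <- pos + 1L
    p <- switch(st, WC = 0, GU = 0.5, MM = 1, BM = 1, BT = 1)
    eff_pos <- if (st == "BT") min(pos + 1L, L + 1L) else pos
    if (eff_pos %in% core) p <- p * 2
    penalty <- penalty + p
    if (st %in% c("BM", "BT")) n_indels <- n_indels + 1L
  }
  list(penalty = penalty, n_indels = n_indels)
}

# independent Hamming-scan mapper using the shifted-comparison trick
oracle_hamming_hits <- function(read, ref_seq, k) {
  n <- nchar(ref_seq)
  rch <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else revcomp(read)
    pch <- strsplit(pat, "", fixed = TRUE)[[1]]
    L <- length(pch)
    if (L > n) next
    ns <- n - L + 1
    mism <- integer(ns)
    for (off in seq_len(L)) {
      mism <- mism + (rch[seq_len(ns) + off - 1L] != pch[off])
    }
    hit <- which(mism <= k)
    if (length(hit) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        read = read, start = hit - 1L, strand = strand,
        mismatches = mism[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(read = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  }
  do.call(rbind, out)
}
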