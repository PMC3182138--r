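# Synthetic reference and library simulator: plants miRNA hairpin loci with
# designed abundances in a synthetic reference, then draws four small RNA
# libraries (2 genotypes x 2 conditions) with adapter, contaminant,
# degradation and imprecise-processing structure, with full ground truth.

#' Design parameters for the synthetic study
#'
#' Defaults emulate a two-genotype (gA, gB) by two-condition (control,
#' drought) small RNA study at desk scale: 20 planted miRNA genes, four
#' libraries of 2e5 reads, a subset of genotype-specific miRNAs expressed in
#' only one genotype, and drought-regulated miRNAs with a designed |log2|
#' fold change of 2 in a designated genotype.
#'
#' @param n_mirnas number of planted miRNA genes.
#' @param n_genotype_specific planted miRNAs expressed in one genotype only.
#' @param n_drought_up,n_drought_down drought-regulated miRNAs (fold change
#'   applied in the designated genotype's drought library).
#' @param drought_log2fc magnitude of the designed drought log2 fold change.
#' @param library_depths total reads per library (gA_control, gA_drought,
#'   gB_control, gB_drought).
#' @param adapter 3' adapter ligated to every read.
#' @param contaminant_fraction fraction of reads drawn from rRNA/tRNA-like
#'   contaminant sequences.
#' @param degradation_fraction fraction of reads that are random degradation
#'   fragments of the reference (both strands, outside planted loci).
#' @param imprecise_fraction fraction of mature-derived reads with 1-2 nt
#'   shifted ends (imprecise processing).
#' @param background_pool number of distinct random background sequences that
#'   absorb the remaining depth (unmappable low-count tags).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return validated design (class `synthetic_design`).
#' @export
synthetic_design <- function(n_mirnas = 20, n_genotype_specific = 4,
                             n_drought_up = 4, n_drought_down = 3,
                             drought_log2fc = 2,
                             library_depths = rep(2e5, 4),
                             adapter = "TCGTATGCCGTCTTCTGCTTG",
                             contaminant_fraction = 0.10,
                             degradation_fraction = 0.05,
                             imprecise_fraction = 0.12,
                             background_pool = 20000,
                             seed = 7) {
  d <- list(n_mirnas = as.integer(n_mirnas),
            n_genotype_specific = as.integer(n_genotype_specific),
            n_drought_up = as.integer(n_drought_up),
            n_drought_down = as.integer(n_drought_down),
            drought_log2fc = drought_log2fc,
            library_depths = setNames(as.numeric(library_depths),
                                      library_ids()),
            adapter = as_dna(adapter),
            contaminant_fraction = contaminant_fraction,
            degradation_fraction = degradation_fraction,
            imprecise_fraction = imprecise_fraction,
            background_pool = as.integer(background_pool),
            seed = as.integer(seed))
  validate_design(d)
  structure(d, class = "synthetic_design")
}

library_ids <- function() c("gA_control", "gA_drought",
                            "gB_control", "gB_drought")

validate_design <- function(d) {
  if (d$n_mirnas < 1) stop("configuration error: n_mirnas must be positive")
  if (d$n_genotype_specific + d$n_drought_up + d$n_drought_down > d$n_mirnas) {
    stop("configuration error: special miRNA counts exceed n_mirnas")
  }
  fr <- c(d$contaminant_fraction, d$degradation_fraction,
          d$imprecise_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("configuration error: fractions must lie in [0, 1]")
  }
  if (any(d$library_depths <= 0)) {
    stop("configuration error: library depths must be positive")
  }
  if (nchar(d$adapter) < 6) {
    stop("configuration error: adapter must be at least 6 nt")
  }
  invisible(TRUE)
}

#' Construct a precursor around a mature sequence that passes all criteria
#'
#' Builds a stem-loop precursor: the opposite arm is the reverse complement of
#' the mature with up to `n_star_mismatches` planted mismatches, joined by an
#' unstructured 8-15 nt loop; a complementary stem extension below the duplex
#' deepens the hairpin, and random low-complementarity flanks (GC 0.45) pad
#' the precursor to 100-300 nt. The construction is re-checked by folding with
#' the bundled backend and re-evaluating the structural criteria; it retries
#' with fresh random parts (reducing planted mismatches) up to `max_tries`
#' times and errors if no construction satisfies the criteria.
#'
#' @param mature mature sequence, 20-24 nt (RNA or DNA alphabet).
#' @param n_star_mismatches mismatches planted between mature and star arms
#'   (at most 4).
#' @param arm which arm carries the mature (`"5p"` or `"3p"`).
#' @param criteria thresholds from [mirna_criteria()].
#' @param max_tries construction retries before failing.
#' @return list with `precursor` (DNA), `mature` (DNA), `star` (DNA, the
#'   designed opposite arm), `mature_start` (0-based within precursor), `arm`,
#'   `fold` (the construction-time `fold_result`).
#' @export
build_precursor <- function(mature, n_star_mismatches = 2,
                            arm = c("5p", "3p"),
                            criteria = mirna_criteria(), max_tries = 40) {
  arm <- match.arg(arm)
  mature <- as_dna(mature)
  L <- nchar(mature)
  stopifnot(L >= 20, L <= 24, n_star_mismatches <= 4)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (try in seq_len(max_tries)) {
    k <- max(0L, n_star_mismatches - (try - 1L) %/% 10L)
    star <- strsplit(revcomp(mature), "", fixed = TRUE)[[1]]
    if (k > 0) {
      at <- sample(3:(L - 3), k)
      for (p in at) {
        star[p] <- sample(setdiff(c("A", "C", "G", "T"), star[p]), 1)
      }
    }
    star <- paste(star, collapse = "")
    ext_len <- sample(10:22, 1)
    ext <- random_dna(1, ext_len, gc = 0.55)
    loop <- random_dna(1, sample(8:15, 1), gc = 0.30)
    f5 <- random_dna(1, sample(20:60, 1), gc = 0.45)
    f3 <- random_dna(1, sample(20:60, 1), gc = 0.45)
    if (arm == "5p") {
      prec <- paste0(f5, ext, mature, loop, star, revcomp(ext), f3)
      mstart <- nchar(f5) + ext_len
    } else {
      prec <- paste0(f5, ext, star, loop, mature, revcomp(ext), f3)
      mstart <- nchar(f5) + ext_len + nchar(star) + nchar(loop)
    }
    if (nchar(prec) > 300) next
    fold <- fold_rna(prec)
    m_int <- c(mstart, mstart + L)
    star_int <- infer_star(fold, m_int)
    if (is.null(star_int)) next
    geom <- duplex_geometry(fold, m_int)
    ok <- fold$energy <= criteria$max_delta_g &&
      geom$mismatches <= criteria$max_duplex_mismatches &&
      length(geom$bulges) <= criteria$max_asym_bulges &&
      (length(geom$bulges) == 0 ||
         max(geom$bulges) <= criteria$max_bulge_size)
    if (ok) {
      return(list(precursor = prec, mature = mature, star = star,
                  mature_start = as.integer(mstart), arm = arm, fold = fold,
                  star_interval = star_int))
    }
  }
  stop("construction error: could not build a criteria-passing precursor ",
       "for mature ", mature)
}

#' Generate the ground truth for a synthetic design
#'
#' Deterministically (given the design seed) plants `n_mirnas` precursors in a
#' synthetic reference contig, assigns base abundances and the designed
#' genotype-specific / drought-regulated expression structure, and builds the
#' contaminant annotation sets.
#'
#' @param design a [synthetic_design()].
#' @return object of class `ground_truth`: list with `design`, `mirnas` (list
#'   of planted miRNA records), `reference` (named character), `contaminants`
#'   (named list of annotation sets), `expected_counts` (matrix mature x
#'   library of designed expected read counts), `mirna_table` (summary data
#'   frame).
#' @export
design_truth <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  validate_design(design)
  with_seed(design$seed, {
    n <- design$n_mirnas
    mirnas <- vector("list", n)
    arms <- sample(c("5p", "3p"), n, replace = TRUE)
    for (i in seq_len(n)) {
      repeat {
        mat <- random_dna(1, sample(20:24, 1, prob = c(1, 3, 2, 1, 1)),
                          gc = 0.5)
        built <- tryCatch(
          build_precursor(mat, n_star_mismatches = sample(0:3, 1),
                          arm = arms[i]),
          error = function(e) NULL)
        if (!is.null(built)) break
      }
      mirnas[[i]] <- built
      mirnas[[i]]$id <- sprintf("planted%03d", i)
    }
    # expression structure
    base <- round(exp(runif(n, log(80), log(2000))))
    gs <- seq_len(design$n_genotype_specific)
    up <- seq_len(design$n_drought_up) + design$n_genotype_specific
    down <- seq_len(design$n_drought_down) + design$n_genotype_specific +
      design$n_drought_up
    on_genotype <- rep(NA_character_, n)
    on_genotype[gs] <- rep(c("gA", "gB"), length.out = length(gs))
    fc_genotype <- rep(NA_character_, n)
    fc_genotype[c(up, down)] <- rep(c("gA", "gB"),
                                    length.out = length(c(up, down)))
    log2fc <- rep(0, n)
    log2fc[up] <- design$drought_log2fc
    log2fc[down] <- -design$drought_log2fc
    expected <- matrix(rep(base, 4), nrow = n,
                       dimnames = list(NULL, library_ids()))
    for (i in seq_len(n)) {
      if (!is.na(fc_genotype[i])) {
        col <- paste0(fc_genotype[i], "_drought")
        expected[i, col] <- expected[i, col] * 2^log2fc[i]
      }
      if (!is.na(on_genotype[i])) {
        off <- setdiff(c("gA", "gB"), on_genotype[i])
        expected[i, paste0(off, c("_control", "_drought"))] <- 0
      }
    }
    rownames(expected) <- vapply(mirnas, function(m) m$id, character(1))
    depth_ok <- colSums(expected) <=
      design$library_depths * (1 - design$contaminant_fraction -
                                 design$degradation_fraction)
    if (!all(depth_ok)) {
      stop("configuration error: designed counts exceed library depth")
    }
    # reference: precursors separated by random spacers on one contig
    spacers <- random_dna(n + 1, sample(150:250, n + 1, replace = TRUE),
                          gc = 0.4)
    parts <- character(2 * n + 1)
    locus_start <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      parts[2 * i - 1] <- spacers[i]
      pos <- pos + nchar(spacers[i])
      parts[2 * i] <- mirnas[[i]]$precursor
      locus_start[i] <- pos
      pos <- pos + nchar(mirnas[[i]]$precursor)
    }
    parts[2 * n + 1] <- spacers[n + 1]
    reference <- c(synthctg1 = paste(parts, collapse = ""))
    for (i in seq_len(n)) {
      mirnas[[i]]$locus <- list(ref = "synthctg1", start = locus_start[i],
                                strand = "+")
      mirnas[[i]]$abundance <- expected[i, ]
      mirnas[[i]]$genotype_specific <- i %in% gs
      mirnas[[i]]$on_genotype <- on_genotype[i]
      mirnas[[i]]$drought_log2fc <- log2fc[i]
      mirnas[[i]]$fc_genotype <- fc_genotype[i]
    }
    contaminants <- list(
      rRNA = setNames(random_dna(3, c(1200, 800, 500), gc = 0.55),
                      paste0("rRNA_", 1:3)),
      tRNA = setNames(random_dna(4, c(76, 82, 88, 74), gc = 0.52),
                      paste0("tRNA_", 1:4)))
    tab <- data.frame(
      id = rownames(expected),
      mature = as_rna(vapply(mirnas, function(m) m$mature, character(1))),
      star = as_rna(vapply(mirnas, function(m) m$star, character(1))),
      arm = vapply(mirnas, function(m) m$arm, character(1)),
      locus_start = locus_start,
      precursor_length = vapply(mirnas, function(m)
        nchar(m$precursor), integer(1)),
      genotype_specific = vapply(mirnas, function(m)
        m$genotype_specific, logical(1)),
      on_genotype = on_genotype,
      drought_log2fc = log2fc,
      fc_genotype = fc_genotype,
      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(expected))
    structure(list(design = design, mirnas = mirnas, reference = reference,
                   contaminants = contaminants, expected_counts = expected,
                   mirna_table = tab),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic ground truth: %d planted miRNAs ",
                     "(%d genotype-specific, %d drought-up, %d drought-down) ",
                     "on a %d nt reference\n"),
              x$design$n_mirnas, x$design$n_genotype_specific,
              x$design$n_drought_up, x$design$n_drought_down,
              nchar(x$reference[[1]])))
  invisible(x)
}

# end-shift distribution for imprecise reads: +-1 nt favored over +-2
shift_variants <- function(truth, i) {
  m <- truth$mirnas[[i]]
  prec <- m$precursor
  s <- m$mature_start
  L <- nchar(m$mature)
  shifts <- expand.grid(d5 = -2:2, d3 = -2:2)
  shifts <- shifts[!(shifts$d5 == 0 & shifts$d3 == 0), ]
  w <- 0.45^abs(shifts$d5) * 0.45^abs(shifts$d3)
  seqs <- substr(rep(prec, nrow(shifts)), s + 1 + shifts$d5, s + L + shifts$d3)
  ok <- nchar(seqs) >= 18
  data.frame(sequence = seqs[ok], weight = w[ok] / sum(w[ok]),
             stringsAsFactors = FALSE)
}

#' Simulate the four small RNA libraries
#'
#' For each library, reads are drawn multinomially at the designed depth from:
#' precise mature reads (designed abundances), imprecise 1-2 nt end-shifted
#' variants, contaminant fragments, bidirectional degradation fragments of
#' non-planted reference regions, and unmappable random background that
#' absorbs the remaining depth. The adapter is appended to every read. Output
#' is written per library as count-collapsed FASTA (or FASTQ), together with
#' the reference, contaminant sets and ground-truth tables.
#'
#' @param truth from [design_truth()].
#' @param dir output directory (created if needed); NULL to skip writing.
#' @param format `"fasta"` (collapsed, default) or `"fastq"` (expanded,
#'   uniform quality).
#' @return list with `libraries` (named list of raw-read tables: `sequence`
#'   = insert + adapter, `count`), `true_counts` (matrix of realized
#'   mature-derived exact read counts per library), `files` (paths, when
#'   written).
#' @export
simulate_libraries <- function(truth, dir = NULL,
                               format = c("fasta", "fastq")) {
  stopifnot(inherits(truth, "ground_truth"))
  format <- match.arg(format)
  design <- truth$design
  n <- design$n_mirnas
  with_seed(design$seed + 1L, {
    # category pool shared across libraries
    variants <- lapply(seq_len(n), function(i) shift_variants(truth, i))
    cont_seqs <- unlist(truth$contaminants, use.names = FALSE)
    cont_pool <- unlist(lapply(cont_seqs, function(s) {
      len <- sample(18:26, 400, replace = TRUE)
      st <- floor(runif(400, 1, nchar(s) - len + 1))
      substring(s, st, st + len - 1)
    }))
    ref <- truth$reference[[1]]
    # degradation excluded from planted loci (+-20 nt)
    excl <- logical(nchar(ref))
    for (m in truth$mirnas) {
      lo <- max(1, m$locus$start - 19)
      hi <- min(nchar(ref), m$locus$start + nchar(m$precursor) + 20)
      excl[lo:hi] <- TRUE
    }
    # degradation is modeled as dense bidirectional fragment pile-ups over a
    # set of expressed non-miRNA source regions (runs of the reference away
    # from planted loci): each fragment is rare, but any window over a source
    # region carries many scattered fragments on both strands
    free_runs <- rle(excl)
    run_end <- cumsum(free_runs$lengths)
    run_start <- run_end - free_runs$lengths + 1
    open <- which(!free_runs$values & free_runs$lengths >= 80)
    open <- open[seq_len(min(12, length(open)))]
    deg_pool <- character(0)
    n_per_region <- ceiling(24000 / max(1, length(open)))
    for (r in open) {
      len <- sample(18:26, n_per_region, replace = TRUE)
      st <- floor(runif(n_per_region, run_start[r],
                        pmax(run_start[r] + 1, run_end[r] - len + 1)))
      frag <- substring(ref, st, pmin(st + len - 1, run_end[r]))
      frag <- frag[nchar(frag) >= 18]
      rc <- sample(c(TRUE, FALSE), length(frag), replace = TRUE)
      frag[rc] <- revcomp(frag[rc])
      deg_pool <- c(deg_pool, frag)
    }
    bg_pool <- random_dna(design$background_pool,
                          sample(18:26, design$background_pool,
                                 replace = TRUE), gc = 0.5)
    bg_w <- 1 / seq_len(design$background_pool)^0.6

    libraries <- list()
    true_counts <- matrix(0L, nrow = n, ncol = 4,
                          dimnames = list(rownames(truth$expected_counts),
                                          library_ids()))
    for (lib in library_ids()) {
      depth <- design$library_depths[[lib]]
      exp_mat <- truth$expected_counts[, lib]
      cats <- character(0); prob <- numeric(0); kind <- character(0)
      midx <- integer(0)
      for (i in seq_len(n)) {
        if (exp_mat[i] <= 0) next
        p_mat <- exp_mat[i] / depth
        cats <- c(cats, truth$mirnas[[i]]$mature)
        prob <- c(prob, p_mat * (1 - design$imprecise_fraction))
        kind <- c(kind, "mature"); midx <- c(midx, i)
        v <- variants[[i]]
        cats <- c(cats, v$sequence)
        prob <- c(prob, p_mat * design$imprecise_fraction * v$weight)
        kind <- c(kind, rep("imprecise", nrow(v)))
        midx <- c(midx, rep(i, nrow(v)))
      }
      cats <- c(cats, cont_pool)
      prob <- c(prob, rep(design$contaminant_fraction / length(cont_pool),
                          length(cont_pool)))
      kind <- c(kind, rep("contaminant", length(cont_pool)))
      midx <- c(midx, rep(NA_integer_, length(cont_pool)))
      cats <- c(cats, deg_pool)
      prob <- c(prob, rep(design$degradation_fraction / length(deg_pool),
                          length(deg_pool)))
      kind <- c(kind, rep("degradation", length(deg_pool)))
      midx <- c(midx, rep(NA_integer_, length(deg_pool)))
      p_bg <- max(0, 1 - sum(prob))
      cats <- c(cats, bg_pool)
      prob <- c(prob, p_bg * bg_w / sum(bg_w))
      kind <- c(kind, rep("background", length(bg_pool)))
      midx <- c(midx, rep(NA_integer_, length(bg_pool)))
      counts <- as.integer(rmultinom(1, size = depth, prob = prob))
      keep <- counts > 0
      tab <- data.frame(sequence = paste0(cats[keep], design$adapter),
                        count = counts[keep], stringsAsFactors = FALSE)
      # identical category sequences (e.g. a degradation fragment equal to a
      # background tag) collapse on output
      agg <- tapply(tab$count, tab$sequence, sum)
      libraries[[lib]] <- data.frame(sequence = names(agg),
                                     count = as.integer(agg),
                                     stringsAsFactors = FALSE,
                                     row.names = NULL)
      mk <- keep & kind == "mature"
      true_counts[midx[mk], lib] <- counts[mk]
    }
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list()
      for (lib in library_ids()) {
        f <- file.path(dir, paste0(lib, if (format == "fasta") ".fa"
                                   else ".fq"))
        if (format == "fasta") write_collapsed_fasta(libraries[[lib]], f)
        else write_fastq(libraries[[lib]], f)
        files[[lib]] <- f
      }
      files$reference <- file.path(dir, "reference.fa")
      write_fasta(truth$reference, files$reference)
      for (set in names(truth$contaminants)) {
        files[[set]] <- file.path(dir, paste0(set, ".fa"))
        write_fasta(truth$contaminants[[set]], files[[set]])
      }
      files$mirna_table <- file.path(dir, "planted_mirnas.tsv")
      write.table(truth$mirna_table, files$mirna_table, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files$true_counts <- file.path(dir, "true_counts.tsv")
      write.table(data.frame(id = rownames(true_counts), true_counts),
                  files$true_counts, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    list(libraries = libraries, true_counts = true_counts, files = files)
  })
}
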