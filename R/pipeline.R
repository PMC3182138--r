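# End-to-end pipeline: raw libraries -> clean unique reads -> predicted
# miRNA genes -> families -> expression matrix and differential tests.

#' Run the full small RNA miRNA discovery and expression pipeline
#'
#' Trims adapters and collapses each library to unique reads, removes
#' annotated contaminants, predicts miRNA genes against one or more reference
#' sets (merging redundant predictions), clusters matures into families, and
#' quantifies and tests mature expression across the four libraries.
#'
#' @param libraries named list of four raw-read tables (`sequence`, `count`;
#'   e.g. from [simulate_libraries()] or [read_collapsed_fasta()]) in the
#'   order gA_control, gA_drought, gB_control, gB_drought.
#' @param references named list of reference sets (each a named character
#'   vector or FASTA path).
#' @param annotations named list of contaminant sets for [filter_annotated()]
#'   (NULL to skip filtering).
#' @param adapter 3' adapter sequence.
#' @param reference_matures named character vector of known mature sequences
#'   for family naming (may be empty).
#' @param criteria thresholds from [mirna_criteria()].
#' @param min_copies anchor redundancy threshold.
#' @param backend folding backend.
#' @return object of class `mirna_pipeline`: list with `clean_reads`,
#'   `library_totals`, `filter_stats`, `genes` (merged `mirna_gene_set`),
#'   `families`, `counts`, `tptm`, `tests` (classified differential table).
#' @export
run_mirna_pipeline <- function(libraries, references, annotations = NULL,
                               adapter, reference_matures = character(0),
                               criteria = mirna_criteria(), min_copies = 10,
                               backend = "bundled") {
  stopifnot(is.list(libraries), length(libraries) == 4)
  inserts <- lapply(libraries, function(lib) {
    tr <- trim_adapter(lib$sequence, adapter)
    ok <- tr$status == "ok"
    data.frame(sequence = tr$insert[ok], count = lib$count[ok],
               stringsAsFactors = FALSE)
  })
  reads <- collapse_unique(inserts)
  filter_stats <- NULL
  if (!is.null(annotations)) {
    f <- filter_annotated(reads, annotations)
    reads <- f$kept
    filter_stats <- f$removed_counts
  }
  totals <- colSums(as.matrix(reads[, count_columns(reads), drop = FALSE]))
  gene_sets <- lapply(names(references), function(rn) {
    predict_mirna_genes(reads, references[[rn]], criteria = criteria,
                        min_copies = min_copies, backend = backend,
                        source_set = rn)
  })
  genes <- deduplicate_genes(gene_sets)
  matures <- unique(vapply(genes$genes, function(g) g$mature_seq,
                           character(1)))
  families <- if (length(matures) > 0) {
    assign_family_names(matures, reference_matures)
  } else {
    data.frame(mature = character(), cluster = integer(),
               family = character(), stringsAsFactors = FALSE)
  }
  counts <- if (length(matures) > 0) {
    quantify_mature(reads, setNames(matures, as_rna(matures)))
  } else {
    matrix(0L, 0, 4, dimnames = list(NULL, names(libraries)))
  }
  tp <- tptm_matrix(counts, totals)
  tests <- if (nrow(counts) > 0) {
    classify_drought_associated(ac_test_table(counts, totals))
  } else NULL
  structure(list(clean_reads = reads, library_totals = totals,
                 filter_stats = filter_stats, gene_sets = gene_sets,
                 genes = genes, families = families, counts = counts,
                 tptm = tp, tests = tests),
            class = "mirna_pipeline")
}

#' @export
print.mirna_pipeline <- function(x, ...) {
  cat("small RNA miRNA pipeline result\n")
  cat(sprintf("  unique clean reads : %d\n", nrow(x$clean_reads)))
  cat(sprintf("  library totals     : %s\n",
              paste(sprintf("%s=%d", names(x$library_totals),
                            as.integer(x$library_totals)), collapse = " ")))
  cat(sprintf("  predicted genes    : %d (%d unique matures, %d families)\n",
              length(x$genes$genes),
              length(unique(x$families$mature)),
              length(unique(x$families$family))))
  if (!is.null(x$tests)) {
    cat(sprintf("  drought-associated : %d (%d up, %d down)\n",
                sum(x$tests$associated),
                sum(x$tests$direction == "up", na.rm = TRUE),
                sum(x$tests$direction == "down", na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.mirna_pipeline <- function(object, ...) {
  print(object)
  if (length(object$genes$genes) > 0) {
    cat("\npredicted genes:\n")
    print(object$genes$table)
  }
  if (!is.null(object$tests)) {
    cat("\ndifferential expression (associated matures):\n")
    print(object$tests[object$tests$associated,
                       c("id", "tptm_gA_control", "tptm_gA_drought",
                         "tptm_gB_control", "tptm_gB_drought",
                         "log2_gA", "log2_gB", "padj_gA", "padj_gB",
                         "direction")])
  }
  invisible(object)
}
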