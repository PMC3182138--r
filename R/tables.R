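# Published TPTM expression tables from the cowpea drought small RNA study
# (two genotypes: IT93K503-1, drought-tolerant; CB46, drought-sensitive; each
# under well-watered control and drought stress). Bundled as plain TSV and
# used as inputs for fold-change and classification-pattern reproduction.

#' Published cowpea TPTM expression tables
#'
#' Returns the bundled normalized expression (TPTM) tables of a published
#' two-genotype cowpea drought study: matures reported with at least two-fold
#' drought change only in the tolerant genotype (IT93K503-1), only in the
#' sensitive genotype (CB46), and matures with genotype-specific expression.
#' Columns `it_*`/`cb_*` hold TPTM in the tolerant/sensitive genotype's
#' control and drought libraries; `log2_*` and `padj_*` are the published
#' log2 ratios and Bonferroni-adjusted p-values.
#'
#' @return named list of data frames: `two_fold_tolerant`,
#'   `two_fold_sensitive`, `genotype_specific`.
#' @export
cowpea_expression_tables <- function() {
  rd <- function(f) {
    read.delim(system.file("extdata", f, package = "droughtmiR",
                           mustWork = TRUE),
               stringsAsFactors = FALSE)
  }
  list(two_fold_tolerant = rd("cowpea_two_fold_tolerant.tsv"),
       two_fold_sensitive = rd("cowpea_two_fold_sensitive.tsv"),
       genotype_specific = rd("cowpea_genotype_specific.tsv"))
}
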