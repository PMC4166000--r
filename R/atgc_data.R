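## Published per-cluster genome dynamics rates bundled with the package.

#' Genome dynamics rates for 35 prokaryote genome clusters
#'
#' Per-site and per-gene rates of gene family gain, loss, expansion and
#' reduction for 35 alignable tight genome clusters (ATGCs; 34 bacterial,
#' 1 archaeal), as published. Rates are events per nucleotide substitution
#' per site (`*_site`) and per nucleotide substitution per gene
#' (`*_gene`). Used by the package's cross-cluster statistics (medians,
#' ratio summaries, PCA) and worked examples.
#'
#' @return a data frame with 35 rows and columns `atgc`, `genera`,
#'   `gain_site`, `gain_gene`, `loss_site`, `loss_gene`,
#'   `expansion_site`, `expansion_gene`, `reduction_site`,
#'   `reduction_gene`.
#' @export
atgc_gde_rates <- function() {
  path <- system.file("extdata", "atgc_gde_rates.tsv", package = "panflux",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
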