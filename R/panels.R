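#' Targeted-panel gene lists
#'
#' The assay exists in two versions: version 2 covers 11 genes frequently
#' mutated in colorectal cancer and related to EGFR-pathway signalling;
#' version 3 extends it to 16 genes (adds IRS1, MAP2K1, MET, PDGFRB, PTEN).
#' Version 2 is a strict subset of version 3.
#'
#' @param version `"v2"` or `"v3"`.
#' @return Character vector of gene symbols, in panel order.
#' @export
#' @examples
#' length(panel_genes("v2")) # 11
#' length(panel_genes("v3")) # 16
panel_genes <- function(version = c("v3", "v2")) {
  version <- match.arg(version)
  tab <- panel_table()
  if (version == "v2") tab$gene[tab$min_panel == "v2"] else tab$gene
}

panel_table <- function() {
  if (is.null(the$panel_table)) {
    the$panel_table <- readr::read_tsv(cf_extdata("panel_genes.tsv"),
                                       show_col_types = FALSE, progress = FALSE)
  }
  the$panel_table
}

#' hg19 coordinate intervals of the panel genes
#'
#' One interval per gene (gene span, hg19, chromosome labels without a
#' "chr" prefix). Used by the cohort simulator to place synthetic variants;
#' no reference sequence is required.
#'
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
gene_intervals <- function() {
  readr::read_tsv(cf_extdata("gene_intervals.tsv"),
                  col_types = readr::cols(gene = "c", chrom = "c",
                                          start = "i", end = "i"),
                  progress = FALSE)
}

#' Restrict calls to a sample's panel version
#'
#' Calls in genes outside the sample's panel are excluded from all
#' downstream counting; with `flag_only = TRUE` they are kept and marked in
#' an `in_panel` column instead.
#'
#' @param calls A variant-call tibble (see [variant_calls()]).
#' @param version Panel version of the sample, `"v2"` or `"v3"`.
#' @param flag_only Keep out-of-panel calls, flagged, instead of dropping.
#' @return The filtered (or flagged) call tibble.
#' @export
apply_panel <- function(calls, version, flag_only = FALSE) {
  genes <- panel_genes(version)
  if (flag_only) {
    calls$in_panel <- calls$gene %in% genes
    return(calls)
  }
  calls[calls$gene %in% genes, , drop = FALSE]
}
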