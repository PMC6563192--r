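# Bundled example tables: the curated differential-expression summary of
# LTR elements (DELs) and of their neighboring genes (DEGs) from a
# baculovirus-infection experiment in wild-silkmoth larval midgut
# (2 control vs 2 infected replicates). They are the canonical worked
# example for the fold-change arithmetic and the signed network.

#' Example DEL table (wild-silkmoth midgut, baculovirus infection)
#'
#' Twelve differentially expressed LTR elements with their group-mean
#' FPKMs (control = CK, infected = NPV), log2 fold change and FDR. The
#' smallest printed FPKM is 0.001, which is why 0.001 is the default
#' fold-change floor throughout the package.
#'
#' @return A tibble: `element_id`, `ck_mean_fpkm`, `npv_mean_fpkm`,
#'   `log2fc`, `fdr`.
#' @examples
#' dels <- midgut_del_table()
#' with(dels, fold_change_log2(ck_mean_fpkm, npv_mean_fpkm)) - dels$log2fc
#' @export
midgut_del_table <- function() {
  readr::read_tsv(
    system.file("extdata", "midgut_del_table.tsv", package = "ltrcisnet",
                mustWork = TRUE),
    show_col_types = FALSE)
}

#' Example DEG table: cis-neighbors of the example DELs
#'
#' Twenty-three differentially expressed genes located within the 100-kb
#' cis window of the [midgut_del_table()] elements, one row per
#' (element, gene) neighborhood pair, with the gene's log2 fold change.
#'
#' @return A tibble: `element_id`, `gene_id`, `gene_name`, `log2fc`.
#' @export
midgut_deg_table <- function() {
  readr::read_tsv(
    system.file("extdata", "midgut_deg_table.tsv", package = "ltrcisnet",
                mustWork = TRUE),
    show_col_types = FALSE, na = "NA")
}

#' Rebuild the example DEL-DEG network from the bundled tables
#'
#' Treats the rows of [midgut_deg_table()] as the cis pairs and signs each
#' edge by fold-change concordance with [build_cis_network()].
#'
#' @return An `ltr_cisnet` edge tibble (23 edges over 7 DELs and 23 DEGs;
#'   9 positive, 14 negative).
#' @export
midgut_network <- function() {
  dels <- midgut_del_table() |>
    transmute(feature_id = .data$element_id, log2fc = .data$log2fc)
  degs <- midgut_deg_table() |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    transmute(feature_id = .data$gene_id, log2fc = .data$log2fc)
  pairs <- midgut_deg_table() |> select("element_id", "gene_id")
  build_cis_network(dels, degs, pairs)
}
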