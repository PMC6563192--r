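#' Simulate a complete synthetic study
#'
#' Builds the canonical end-to-end fixture: a repeat-free genome with
#' planted LTR elements spanning the realistic parameter ranges (LTR
#' 150-600 bp, internal region 2-8 kb, pairwise identity 0.85-0.97, TSD
#' 4-6 bp, a mix of domain-bearing and domain-free elements), gene models
#' covering every positional class (inside an element, straddling a
#' boundary, at stated distances within and beyond the cis window, and on
#' an element-free scaffold), and a 2-control vs 2-infected
#' negative-binomial count matrix with planted log2 fold changes for a
#' subset of elements and genes.
#'
#' @param seed Integer seed; the whole study is deterministic given it.
#' @param n_scaffolds Scaffolds carrying elements (one more, element-free,
#'   is always added).
#' @param scaffold_len Length of each scaffold (bp).
#' @param library_size Per-sample library size for the count simulation.
#' @param dispersion NB dispersion of simulated counts.
#' @param planted_lfc Absolute log2 fold change planted into the affected
#'   features.
#' @return A list: `genome`, `gene_models`, `counts`, `design`,
#'   `truth_elements`, `truth_genes`, `truth_effects`.
#' @export
simulate_study <- function(seed = 1L, n_scaffolds = 3L,
                           scaffold_len = 60000L, library_size = 1e6,
                           dispersion = 0.1, planted_lfc = 3) {
  lens <- rep(scaffold_len, n_scaffolds + 1L)
  genome <- simulate_genome(lens, gc = 0.4, seed = seed)
  scafs <- genome$scaffold_id[seq_len(n_scaffolds)]

  ltr_lens <- c(150L, 300L, 600L)
  internal_lens <- c(2000L, 5000L, 8000L)
  idents <- c(0.97, 0.90, 0.85)
  tsds <- c(4L, 5L, 6L)
  domain_sets <- list(c("gag", "pol"), c("gag", "pro", "pol", "env"),
                      character())
  for (i in seq_len(n_scaffolds)) {
    j <- ((i - 1L) %% 3L) + 1L
    genome <- plant_ltr_element(
      genome, scafs[i], position = 20000L,
      ltr_len = ltr_lens[j], internal_len = internal_lens[j],
      identity = idents[j], tsd_len = tsds[j],
      domains = domain_sets[[j]], seed = seed + i)
  }
  truth <- ltr_truth(genome)

  placements <- bind_rows(
    # element 1 carries both an internal exon and a boundary-straddling
    # exon: the In+Part dual-class case
    tibble(type = "inside", element_id = truth$element_id[1]),
    tibble(type = "straddle", element_id = truth$element_id[1]),
    # a ladder of cis-distance genes right of every element, one beyond the
    # 100-kb window when the scaffold allows, plus upstream genes
    tidyr::crossing(element_id = truth$element_id,
                    distance = c(3000L, 8000L, 15000L, 24000L)) |>
      mutate(type = "distance", side = "right"),
    tibble(type = "distance", element_id = truth$element_id,
           distance = 12000L, side = "left"),
    tibble(type = "distance", element_id = truth$element_id,
           distance = 5000L, side = "left"),
    tibble(type = "unlinked",
           scaffold_id = genome$scaffold_id[n_scaffolds + 1L])
  )
  gene_models <- simulate_gene_models(genome, placements)
  genes <- gene_models |>
    filter(.data$kind == "gene") |>
    transmute(feature_id = .data$gene_id,
              length = .data$end - .data$start + 1L)
  elements <- truth |>
    transmute(feature_id = .data$element_id,
              length = .data$end - .data$start + 1L)
  features <- bind_rows(elements, genes)

  design <- make_design(c("Ap_CK1", "Ap_CK2"), c("Ap_NPV1", "Ap_NPV2"))
  # elements are expressed at a much lower FPKM scale than genes, as in
  # real midgut data; effects touch a small fraction of features so that
  # column-sum library sizes stay representative
  gene_ids <- genes$feature_id
  tg <- gene_truth(gene_models)
  near_el2 <- tg$gene_id[tg$type == "distance" &
                           tg$element_id == truth$element_id[min(2, nrow(truth))]]
  affected_genes <- utils::head(near_el2, 2)
  effects <- bind_rows(
    tibble(feature_id = elements$feature_id,
           planted_log2fc = rep(c(planted_lfc, -planted_lfc),
                                length.out = nrow(elements)),
           baseline_mean = 2, dispersion = dispersion),
    tibble(feature_id = gene_ids[!gene_ids %in% affected_genes],
           planted_log2fc = 0, baseline_mean = 50, dispersion = dispersion),
    tibble(feature_id = affected_genes,
           planted_log2fc = c(planted_lfc, -planted_lfc)[
             seq_along(affected_genes)],
           baseline_mean = 50, dispersion = dispersion)
  )
  counts <- simulate_counts(features, design, effects = effects,
                            library_sizes = library_size,
                            baseline_mean = 50, dispersion = dispersion,
                            seed = seed + 1000L)
  list(genome = genome, gene_models = gene_models, counts = counts,
       design = design, truth_elements = truth,
       truth_genes = gene_truth(gene_models), truth_effects = effects)
}

#' Write a simulated study to disk
#'
#' Emits the standard interchange files: `genome.fasta`, `genes.gff3`,
#' `counts.tsv`, `design.tsv` and the truth sidecars
#' (`truth_elements.tsv`, `truth_genes.tsv`, `truth_effects.tsv`).
#'
#' @param study A list from [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(study$genome, file.path(outdir, "genome.fasta"))
  write_gene_gff3(study$gene_models, file.path(outdir, "genes.gff3"))
  readr::write_tsv(study$counts, file.path(outdir, "counts.tsv"))
  readr::write_tsv(study$design, file.path(outdir, "design.tsv"))
  readr::write_tsv(study$truth_elements,
                   file.path(outdir, "truth_elements.tsv"))
  readr::write_tsv(study$truth_genes, file.path(outdir, "truth_genes.tsv"))
  readr::write_tsv(study$truth_effects,
                   file.path(outdir, "truth_effects.tsv"))
  invisible(outdir)
}
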