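#' Default pipeline configuration
#'
#' @param genome_fasta,genes_gff3,counts_tsv,design_tsv Input paths
#'   (`design_tsv` may be `NULL` when `design` is given directly).
#' @param outdir Output directory.
#' @param design Optional in-memory design tibble.
#' @param term_map_tsv Optional term-to-gene map (columns `term_id`,
#'   `gene_id`, optionally `term_name`) enabling the enrichment stage.
#' @param window Cis-window size (bp).
#' @param min_identity,min_sep,max_sep,min_ltr_len,max_ltr_len,require_tsd
#'   Detection parameters (see [find_ltr_pairs()]).
#' @param lfc,fdr,floor Differential-expression thresholds (see
#'   [call_de()]).
#' @param de_joint Compute the FDR correction jointly over elements and
#'   genes (`TRUE`) or separately per feature class (`FALSE`).
#' @param alpha Enrichment significance level.
#' @param seed Integer seed recorded in the run report (the analysis
#'   stages are deterministic; the seed matters when a simulation step
#'   produced the inputs).
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(genome_fasta, genes_gff3, counts_tsv,
                            design_tsv = NULL, outdir = "ltrcisnet_out",
                            design = NULL, term_map_tsv = NULL,
                            window = 100000L, min_identity = 0.80,
                            min_sep = 1000L, max_sep = 15000L,
                            min_ltr_len = 100L, max_ltr_len = 1000L,
                            require_tsd = TRUE, lfc = 1, fdr = 0.05,
                            floor = 0.001, de_joint = TRUE, alpha = 0.05,
                            seed = 1L) {
  as.list(environment())
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — detect elements, annotate
#' domains, classify positions, find cis-targets, call differential
#' expression of elements and genes, build the signed DEL-DEG network, and
#' (when a term map is supplied) test term enrichment of the cis-target
#' genes — writing each stage's TSV into `config$outdir` together with a
#' JSON run report echoing the parameters and the row count of every
#' output. Reruns on identical inputs produce byte-identical outputs.
#'
#' @param config A list from [pipeline_config()] (or a YAML file path
#'   with the same fields).
#' @return Invisibly, a list with every stage's table and the report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("reading a YAML config needs the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- do.call(pipeline_config, config[intersect(
    names(config), names(formals(pipeline_config)))])
  for (p in c("genome_fasta", "genes_gff3", "counts_tsv")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop_input("pipeline stage 'inputs': missing file for `%s`: %s",
                 p, cfg[[p]] %||% "<unset>")
    }
  }
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "ltrcis_error_stage")
    })
  }

  genome <- stage("read_genome", read_genome_fasta(cfg$genome_fasta))
  gene_models <- stage("read_genes", read_gene_gff3(cfg$genes_gff3))
  counts <- stage("read_counts", read_counts_tsv(cfg$counts_tsv))
  design <- if (!is.null(cfg$design)) {
    as_tibble(cfg$design)
  } else if (!is.null(cfg$design_tsv)) {
    readr::read_tsv(cfg$design_tsv, show_col_types = FALSE)
  } else {
    stop_input("pipeline stage 'inputs': no design given")
  }

  elements <- stage("detect", {
    find_ltr_pairs(genome, min_ltr_len = cfg$min_ltr_len,
                   max_ltr_len = cfg$max_ltr_len, min_sep = cfg$min_sep,
                   max_sep = cfg$max_sep, min_identity = cfg$min_identity,
                   require_tsd = cfg$require_tsd) |>
      (\(el) annotate_domains(genome, el))()
  })
  readr::write_tsv(select(elements, -"domain_hits"),
                   file.path(outdir, "elements.tsv"))
  write_elements_gff3(elements, file.path(outdir, "elements.gff3"))

  positions <- stage("context", classify_ltr_position(elements, gene_models))
  readr::write_tsv(positions, file.path(outdir, "positions.tsv"))
  stream_full <- elements |>
    filter(.data$category == "full_length") |>
    semi_join(filter(positions, .data$stream), by = "element_id")
  cis_pairs <- stage("context",
                     find_cis_targets(stream_full, gene_models,
                                      positions = positions,
                                      window = cfg$window))
  readr::write_tsv(cis_pairs, file.path(outdir, "cis_pairs.tsv"))

  element_ids <- elements$element_id
  gene_ids <- unique(gene_models$gene_id)
  de_all <- stage("de", {
    if (cfg$de_joint) {
      call_de(counts, design, lfc = cfg$lfc, fdr = cfg$fdr,
              floor = cfg$floor)
    } else {
      bind_rows(
        call_de(filter(counts, .data$feature_id %in% element_ids),
                design, lfc = cfg$lfc, fdr = cfg$fdr, floor = cfg$floor),
        call_de(filter(counts, .data$feature_id %in% gene_ids),
                design, lfc = cfg$lfc, fdr = cfg$fdr, floor = cfg$floor)
      )
    }
  })
  dels <- filter(de_all, .data$feature_id %in% element_ids)
  degs <- filter(de_all, .data$feature_id %in% gene_ids)
  readr::write_tsv(tidy(de_all), file.path(outdir, "de_results.tsv"))

  edges <- stage("network", build_cis_network(dels, degs, cis_pairs))
  readr::write_tsv(tidy(edges), file.path(outdir, "network_edges.tsv"))
  write_network_sif(edges, file.path(outdir, "network.sif"),
                    file.path(outdir, "network_nodes.tsv"))

  enrichment <- NULL
  if (!is.null(cfg$term_map_tsv)) {
    enrichment <- stage("enrich", {
      term_map <- readr::read_tsv(cfg$term_map_tsv, show_col_types = FALSE)
      targets <- intersect(unique(cis_pairs$gene_id), gene_ids)
      enrich_terms(targets, term_map, universe = gene_ids,
                   alpha = cfg$alpha)
    })
    readr::write_tsv(tidy(enrichment), file.path(outdir, "enrichment.tsv"))
  }

  report <- list(
    parameters = cfg[c("window", "min_identity", "min_sep", "max_sep",
                       "min_ltr_len", "max_ltr_len", "require_tsd", "lfc",
                       "fdr", "floor", "de_joint", "alpha", "seed")],
    inputs = cfg[c("genome_fasta", "genes_gff3", "counts_tsv")],
    row_counts = list(
      scaffolds = nrow(genome), genes = length(gene_ids),
      elements = nrow(elements),
      full_length = sum(elements$category == "full_length"),
      solo = sum(elements$category == "solo"),
      positions = nrow(positions), cis_pairs = nrow(cis_pairs),
      de_features = nrow(de_all),
      dels = sum(dels$status != "ns"), degs = sum(degs$status != "ns"),
      network_edges = nrow(edges),
      enrichment_terms = if (is.null(enrichment)) 0L else nrow(enrichment)
    )
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(elements = elements, positions = positions,
                 cis_pairs = cis_pairs, de = de_all, network = edges,
                 enrichment = enrichment, report = report))
}
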