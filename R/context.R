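# Positional relationship of elements to gene exons, and cis-target genes
# of independent ("Stream") elements.

# Pick the exon-like features used for classification: `exon` rows when the
# annotation provides them, otherwise the union of CDS and UTR rows
# (GFF3 dialects differ in which they annotate).
exonic_features <- function(gene_models) {
  gm <- as_tibble(gene_models)
  needed <- c("gene_id", "scaffold_id", "kind", "start", "end")
  if (!all(needed %in% names(gm))) {
    stop_input("`gene_models` needs columns %s", join_names(needed))
  }
  ex <- filter(gm, .data$kind == "exon")
  if (nrow(ex) == 0) {
    ex <- filter(gm, .data$kind %in%
                   c("CDS", "five_prime_UTR", "three_prime_UTR"))
  }
  ex
}

#' Classify elements by position relative to gene exons
#'
#' An element is:
#' * `In` if at least one gene exon lies entirely within the element
#'   interval;
#' * `Part` if at least one exon overlaps the element interval without
#'   being contained (In and Part can co-occur for one element);
#' * `Stream` (independent) if no exon overlaps the element at all.
#'
#' Introns never create overlap: only exon-kind features count. Elements on
#' scaffolds without any annotated gene are `Stream` with the
#' `no_gene_scaffold` flag set.
#'
#' @param elements Element tibble (needs `element_id`, `scaffold_id`,
#'   `start`, `end`).
#' @param gene_models Gene-feature tibble (see [simulate_gene_models()] or
#'   [read_gene_gff3()]).
#' @return A tibble with one row per element: `element_id`, logical
#'   `in_class`, `part_class`, `stream`, the joined `classes` label, and
#'   `no_gene_scaffold`.
#' @export
classify_ltr_position <- function(elements, gene_models) {
  elements <- as_tibble(elements)
  ex <- exonic_features(gene_models)
  gene_scaffolds <- unique(ex$scaffold_id)

  ov <- elements |>
    select("element_id", "scaffold_id", el_start = "start", el_end = "end") |>
    inner_join(select(ex, "scaffold_id", ex_start = "start", ex_end = "end"),
               by = "scaffold_id", relationship = "many-to-many") |>
    filter(.data$ex_start <= .data$el_end, .data$ex_end >= .data$el_start) |>
    mutate(contained = .data$ex_start >= .data$el_start &
             .data$ex_end <= .data$el_end) |>
    group_by(.data$element_id) |>
    summarise(in_class = any(.data$contained),
              part_class = any(!.data$contained), .groups = "drop")

  elements |>
    select("element_id", "scaffold_id") |>
    left_join(ov, by = "element_id") |>
    mutate(
      in_class = coalesce(.data$in_class, FALSE),
      part_class = coalesce(.data$part_class, FALSE),
      stream = !.data$in_class & !.data$part_class,
      classes = map2_chr(.data$in_class, .data$part_class, function(i, p) {
        cl <- c(if (i) "In", if (p) "Part")
        if (length(cl)) paste(cl, collapse = ",") else "Stream"
      }),
      no_gene_scaffold = !.data$scaffold_id %in% gene_scaffolds
    ) |>
    select(-"scaffold_id")
}

#' @importFrom purrr map2_chr
NULL

#' Find cis-target genes of independent elements
#'
#' A gene is a cis-target of a Stream element when at least one of its
#' annotated exons (UTR or CDS) lies within `window` bp of the element
#' boundary on either side (inclusive; 0 bp means the exon abuts the
#' element). The window is strand-agnostic: upstream/downstream refer to
#' genomic left/right of the element and are reported for information only.
#' Each (element, gene) pair is reported once with the minimum
#' exon-to-element distance.
#'
#' @param elements Element tibble restricted to Stream-classified elements;
#'   supplying a non-Stream element is an error.
#' @param gene_models Gene-feature tibble.
#' @param positions Classification tibble from [classify_ltr_position()];
#'   when `NULL` it is computed internally.
#' @param window Window size in bp (default 100 kb).
#' @return A tibble of cis pairs: `element_id`, `gene_id`, `distance` (bp
#'   gap, 0 when abutting), `side` (`upstream`/`downstream`).
#' @export
find_cis_targets <- function(elements, gene_models, positions = NULL,
                             window = 100000L) {
  elements <- as_tibble(elements)
  if (is.null(positions)) positions <- classify_ltr_position(elements,
                                                             gene_models)
  bad <- elements$element_id[!elements$element_id %in%
                               positions$element_id[positions$stream]]
  if (length(bad)) {
    stop_input("non-Stream element(s) supplied to find_cis_targets: %s",
               join_names(utils::head(bad, 5)))
  }
  ex <- exonic_features(gene_models)

  elements |>
    select("element_id", "scaffold_id", el_start = "start", el_end = "end") |>
    inner_join(select(ex, "gene_id", "scaffold_id",
                      ex_start = "start", ex_end = "end"),
               by = "scaffold_id", relationship = "many-to-many") |>
    mutate(
      gap_right = .data$ex_start - .data$el_end - 1L,
      gap_left = .data$el_start - .data$ex_end - 1L,
      distance = pmax(0L, pmax(.data$gap_left, .data$gap_right)),
      side = case_when(
        .data$gap_left >= 0L ~ "upstream",
        .data$gap_right >= 0L ~ "downstream",
        TRUE ~ "overlapping_window"
      )
    ) |>
    filter(.data$distance <= window) |>
    group_by(.data$element_id, .data$gene_id) |>
    arrange(.data$distance, .data$side, .by_group = TRUE) |>
    summarise(distance = first(.data$distance), side = first(.data$side),
              .groups = "drop") |>
    arrange(.data$element_id, .data$gene_id)
}
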