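#' Build the signed DEL-DEG cis-interaction network
#'
#' Joins differentially expressed LTR elements (DELs) to differentially
#' expressed genes (DEGs) through their cis-neighborhood pairs. One edge is
#' emitted per cis pair whose element is a DEL and whose gene is a DEG; the
#' edge sign is fold-change concordance (`positive` when the two log2 fold
#' changes have the same sign). With two replicates per group a per-pair
#' correlation coefficient is not estimable, so concordance is the signed
#' relation of record.
#'
#' @param dels Differential-expression table for elements (needs
#'   `feature_id`, `log2fc`; rows with a `status` column are filtered to
#'   `status != "ns"`).
#' @param degs Same, for genes.
#' @param cis_pairs Cis-pair tibble (`element_id`, `gene_id`, optionally
#'   `distance`), e.g. from [find_cis_targets()]. Pairs referencing ids
#'   absent from both tables are reported and skipped.
#' @return An `ltr_cisnet` tibble of edges ordered by (`del_id`,
#'   `deg_id`): `del_id`, `deg_id`, `del_log2fc`, `deg_log2fc`, `sign`
#'   (`positive`/`negative`), and `distance` when supplied.
#' @export
build_cis_network <- function(dels, degs, cis_pairs) {
  dels <- de_side(dels, "dels")
  degs <- de_side(degs, "degs")
  cis_pairs <- as_tibble(cis_pairs)
  if (!all(c("element_id", "gene_id") %in% names(cis_pairs))) {
    stop_input("`cis_pairs` needs columns `element_id` and `gene_id`")
  }

  # ids absent from the DE tables altogether (not merely non-significant)
  truly_unknown <- cis_pairs$element_id[!cis_pairs$element_id %in%
                                          dels$all_ids]
  truly_unknown <- c(truly_unknown,
                     cis_pairs$gene_id[!cis_pairs$gene_id %in% degs$all_ids])
  if (length(truly_unknown)) {
    inform(sprintf("skipping cis pair(s) with unknown feature id(s): %s",
                   join_names(unique(utils::head(truly_unknown, 5)))))
  }

  edges <- cis_pairs |>
    inner_join(select(dels$de, del_id = "feature_id",
                      del_log2fc = "log2fc"),
               by = c(element_id = "del_id")) |>
    inner_join(select(degs$de, deg_id = "feature_id",
                      deg_log2fc = "log2fc"),
               by = c(gene_id = "deg_id")) |>
    rename(del_id = "element_id", deg_id = "gene_id")
  if (nrow(edges) && any(edges$del_log2fc == 0 | edges$deg_log2fc == 0)) {
    stop_input("zero fold change on a network endpoint; inputs must pass DE thresholds")
  }
  edges <- edges |>
    mutate(sign = ifelse(.data$del_log2fc * .data$deg_log2fc > 0,
                         "positive", "negative")) |>
    distinct(.data$del_id, .data$deg_id, .keep_all = TRUE) |>
    arrange(.data$del_id, .data$deg_id) |>
    relocate("del_id", "deg_id", "del_log2fc", "deg_log2fc", "sign")
  class(edges) <- c("ltr_cisnet", class(edges))
  edges
}

# Normalise one DE-side input; returns the filtered table plus all known
# ids (for unknown-id diagnostics).
de_side <- function(x, arg) {
  x <- as_tibble(x)
  if ("element_id" %in% names(x) && !"feature_id" %in% names(x)) {
    x <- rename(x, feature_id = "element_id")
  }
  if ("gene_id" %in% names(x) && !"feature_id" %in% names(x)) {
    x <- rename(x, feature_id = "gene_id")
  }
  if (!all(c("feature_id", "log2fc") %in% names(x))) {
    stop_input("`%s` needs columns `feature_id` and `log2fc`", arg)
  }
  all_ids <- x$feature_id
  if ("status" %in% names(x)) x <- filter(x, .data$status != "ns")
  list(de = x, all_ids = all_ids)
}

#' Summarise a DEL-DEG network
#'
#' @param edges An edge tibble from [build_cis_network()].
#' @return A one-row tibble: `n_edges`, `n_dels`, `n_degs`, `n_positive`,
#'   `n_negative`.
#' @export
network_summary <- function(edges) {
  tibble(
    n_edges = nrow(edges),
    n_dels = dplyr::n_distinct(edges$del_id),
    n_degs = dplyr::n_distinct(edges$deg_id),
    n_positive = sum(edges$sign == "positive"),
    n_negative = sum(edges$sign == "negative")
  )
}

#' @export
glance.ltr_cisnet <- function(x, ...) network_summary(x)

#' @export
tidy.ltr_cisnet <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ltr_cisnet")
  as_tibble(out)
}

#' Bipartite plot of a DEL-DEG network
#'
#' DELs on the left, DEGs on the right, edges coloured by concordance
#' sign; node colour encodes the direction of regulation.
#'
#' @param object An `ltr_cisnet` edge tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltr_cisnet <- function(object, ...) {
  edges <- tidy(object)
  dels <- tibble(id = sort(unique(edges$del_id)), x = 0)
  dels$y <- seq(0, 1, length.out = max(2, nrow(dels)))[seq_len(nrow(dels))]
  degs <- tibble(id = sort(unique(edges$deg_id)), x = 1)
  degs$y <- seq(0, 1, length.out = max(2, nrow(degs)))[seq_len(nrow(degs))]
  nodes <- bind_rows(
    mutate(dels, role = "DEL",
           lfc = edges$del_log2fc[match(.data$id, edges$del_id)]),
    mutate(degs, role = "DEG",
           lfc = edges$deg_log2fc[match(.data$id, edges$deg_id)])
  ) |>
    mutate(direction = ifelse(.data$lfc > 0, "up", "down"))
  seg <- edges |>
    mutate(x = 0, xend = 1,
           y = dels$y[match(.data$del_id, dels$id)],
           yend = degs$y[match(.data$deg_id, degs$id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$direction,
                   shape = .data$role),
      size = 3, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(DEL = 22, DEG = 21)) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60")) +
    ggplot2::scale_colour_manual(values = c(positive = "#2980b9",
                                            negative = "#e67e22")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge sign", fill = "regulation", shape = NULL)
}

#' Write a network as a SIF-style edge list plus node attributes
#'
#' @param edges Edge tibble from [build_cis_network()].
#' @param sif_path Path for the edge list (`del_id  sign  deg_id`, TSV).
#' @param attr_path Optional path for the per-node log2fc attribute table.
#' @return `sif_path`, invisibly.
#' @export
write_network_sif <- function(edges, sif_path, attr_path = NULL) {
  readr::write_tsv(select(tidy(edges), "del_id", "sign", "deg_id"), sif_path)
  if (!is.null(attr_path)) {
    nodes <- bind_rows(
      edges |> distinct(.data$del_id, .data$del_log2fc) |>
        transmute(id = .data$del_id, role = "DEL", log2fc = .data$del_log2fc),
      edges |> distinct(.data$deg_id, .data$deg_log2fc) |>
        transmute(id = .data$deg_id, role = "DEG", log2fc = .data$deg_log2fc)
    )
    readr::write_tsv(nodes, attr_path)
  }
  invisible(sif_path)
}
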