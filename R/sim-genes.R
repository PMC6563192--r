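#' Simulate gene models at controlled positions relative to planted elements
#'
#' Realises a placement request table as multi-exon gene models, so that the
#' positional classifier and cis-target finder can be validated against a
#' known truth: a gene can be requested with an exon fully inside an element
#' (classifies the element "In"), straddling an element boundary ("Part"),
#' at a stated gap from an element boundary (a cis-target candidate of a
#' "Stream" element), or unlinked to any element.
#'
#' @param genome Genome tibble; planted-element truth is taken from
#'   [ltr_truth()].
#' @param placements A data frame with one row per gene and columns:
#'   * `type`: one of `"inside"`, `"straddle"`, `"distance"`, `"unlinked"`;
#'   * `element_id`: target element (all types except `"unlinked"`);
#'   * `distance`: gap in bp between the nearest exon and the element
#'     boundary (`"distance"` type only; 0 = abutting);
#'   * `side`: `"left"` or `"right"` of the element (default `"right"`);
#'   * `scaffold_id`: scaffold for `"unlinked"` genes;
#'   * `strand`: `"+"` or `"-"` (default `"+"`).
#' @param exons_per_gene Number of exons for `"distance"`/`"unlinked"` genes
#'   (`"inside"`/`"straddle"` genes are single-exon).
#' @param exon_len,intron_len,utr_len Exon/intron/UTR sizes in bp.
#' @param prefix Gene id prefix.
#' @return A tibble of gene features with columns `gene_id`, `scaffold_id`,
#'   `strand`, `kind` (`gene`, `exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`), `start`, `end` (1-based inclusive). The realised
#'   placements are kept in the `truth_genes` attribute (see
#'   [gene_truth()]).
#' @export
simulate_gene_models <- function(genome, placements,
                                 exons_per_gene = 3, exon_len = 200,
                                 intron_len = 500, utr_len = 50,
                                 prefix = "gene") {
  check_genome_tbl(genome)
  truth <- ltr_truth(genome)
  placements <- as_tibble(placements)
  if (!"type" %in% names(placements)) {
    stop_input("`placements` needs a `type` column")
  }
  for (col in c("element_id", "scaffold_id")) {
    if (!col %in% names(placements)) placements[[col]] <- NA_character_
  }
  if (!"distance" %in% names(placements)) placements$distance <- NA_integer_
  if (!"side" %in% names(placements)) placements$side <- "right"
  if (!"strand" %in% names(placements)) placements$strand <- "+"
  placements$side[is.na(placements$side)] <- "right"
  placements$strand[is.na(placements$strand)] <- "+"

  occupied <- list() # per-scaffold list of gene intervals already placed
  feats <- list()
  realized <- list()

  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    gene_id <- paste(prefix, i, sep = "_")
    el <- NULL
    if (p$type != "unlinked") {
      j <- match(p$element_id, truth$element_id)
      if (is.na(j)) stop_input("placement %d: unknown element '%s'",
                               i, p$element_id)
      el <- truth[j, ]
    }
    scaffold_id <- if (p$type == "unlinked") p$scaffold_id else el$scaffold_id
    scaf_len <- nchar(scaffold_seq(genome, scaffold_id))

    exons <- switch(
      p$type,
      inside = {
        room <- el$internal_len - exon_len
        if (room < 2) stop_input("placement %d: internal region too small", i)
        s <- el$ltr5_end + 1L + room %/% 2L
        tibble(start = s, end = s + exon_len - 1L)
      },
      straddle = {
        s <- el$start - exon_len %/% 2L
        if (s < 1) stop_input("placement %d: no room left of element", i)
        tibble(start = s, end = s + exon_len - 1L)
      },
      distance = {
        d <- as.integer(p$distance)
        if (is.na(d) || d < 0) stop_input("placement %d: bad `distance`", i)
        gene_span <- exons_per_gene * exon_len +
          (exons_per_gene - 1L) * intron_len
        if (p$side == "right") {
          s <- el$end + 1L + d
          if (s + gene_span - 1L > scaf_len) {
            stop_input("placement %d: no room right of element", i)
          }
          tibble(start = s + (seq_len(exons_per_gene) - 1L) *
                   (exon_len + intron_len)) |>
            mutate(end = .data$start + exon_len - 1L)
        } else {
          e <- el$start - 1L - d
          if (e - gene_span + 1L < 1) {
            stop_input("placement %d: no room left of element", i)
          }
          tibble(end = e - (seq_len(exons_per_gene) - 1L) *
                   (exon_len + intron_len)) |>
            mutate(start = .data$end - exon_len + 1L) |>
            arrange(.data$start)
        }
      },
      unlinked = {
        if (is.na(scaffold_id)) {
          stop_input("placement %d: `unlinked` needs a scaffold_id", i)
        }
        gene_span <- exons_per_gene * exon_len +
          (exons_per_gene - 1L) * intron_len
        s <- (scaf_len - gene_span) %/% 2L + 1L
        if (s < 1) stop_input("placement %d: scaffold too small", i)
        tibble(start = s + (seq_len(exons_per_gene) - 1L) *
                 (exon_len + intron_len)) |>
          mutate(end = .data$start + exon_len - 1L)
      },
      stop_input("placement %d: unknown type '%s'", i, p$type)
    )

    if (any(exons$start < 1) || any(exons$end > scaf_len)) {
      stop_input("placement %d: gene falls outside scaffold", i)
    }
    # keep placements honest: distance/unlinked exons must not touch any
    # element, otherwise the requested truth label would be wrong
    if (p$type %in% c("distance", "unlinked") && nrow(truth)) {
      tr <- truth[truth$scaffold_id == scaffold_id, ]
      if (nrow(tr)) {
        clash <- any(outer(exons$start, tr$end, `<=`) &
                       outer(exons$end, tr$start, `>=`))
        if (clash) stop_input("placement %d: exons would overlap an element", i)
      }
    }
    occ <- occupied[[scaffold_id]]
    if (!is.null(occ) &&
        any(occ$start <= max(exons$end) & occ$end >= min(exons$start))) {
      stop_input("placement %d: overlaps a previously placed gene", i)
    }
    occupied[[scaffold_id]] <- bind_rows(
      occ, tibble(start = min(exons$start), end = max(exons$end))
    )

    feats[[i]] <- gene_feature_rows(gene_id, scaffold_id, p$strand, exons,
                                    utr_len)
    realized_d <- if (p$type == "distance") {
      if (p$side == "right") min(exons$start) - el$end - 1L
      else el$start - max(exons$end) - 1L
    } else NA_integer_
    realized[[i]] <- tibble(
      gene_id = gene_id, type = p$type,
      element_id = if (is.null(el)) NA_character_ else el$element_id,
      scaffold_id = scaffold_id,
      requested_distance = as.integer(p$distance),
      realized_distance = realized_d
    )
  }

  out <- bind_rows(feats)
  attr(out, "truth_genes") <- bind_rows(realized)
  out
}

#' Realised gene-placement truth
#'
#' @param gene_models A gene-feature tibble from [simulate_gene_models()].
#' @return A tibble of realised placements (one row per gene).
#' @export
gene_truth <- function(gene_models) {
  attr(gene_models, "truth_genes") %||%
    tibble(gene_id = character(), type = character(),
           element_id = character(), scaffold_id = character(),
           requested_distance = integer(), realized_distance = integer())
}

# Expand a gene's exon intervals into gene/exon/CDS/UTR feature rows.
# UTRs are carved out of the terminal exons when they are wide enough.
gene_feature_rows <- function(gene_id, scaffold_id, strand, exons, utr_len) {
  exons <- arrange(exons, .data$start)
  ne <- nrow(exons)
  rows <- list(tibble(kind = "gene", start = min(exons$start),
                      end = max(exons$end)))
  rows <- c(rows, list(tibble(kind = "exon", start = exons$start,
                              end = exons$end)))
  use_utr <- utr_len > 0 &&
    all((exons$end - exons$start + 1L)[c(1, ne)] > 2L * utr_len + 3L)
  left_utr <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  right_utr <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  for (j in seq_len(ne)) {
    s <- exons$start[j]; e <- exons$end[j]
    cs <- s; ce <- e
    if (use_utr && j == 1L) {
      rows <- c(rows, list(tibble(kind = left_utr, start = s,
                                  end = s + utr_len - 1L)))
      cs <- s + utr_len
    }
    if (use_utr && j == ne) {
      rows <- c(rows, list(tibble(kind = right_utr, start = e - utr_len + 1L,
                                  end = e)))
      ce <- e - utr_len
    }
    rows <- c(rows, list(tibble(kind = "CDS", start = cs, end = ce)))
  }
  bind_rows(rows) |>
    mutate(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
           .before = 1)
}
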