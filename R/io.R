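# Readers and writers for the interchange formats: FASTA (Biostrings),
# GFF3 (rtracklayer), TSV (readr). All tibble coordinates are 1-based
# inclusive, matching GFF3, so round trips are the identity.

#' Read a genome FASTA file
#'
#' @param path FASTA path (wrapped or unwrapped).
#' @return Genome tibble (`scaffold_id`, `sequence`, `length`), sequences
#'   upper-cased. Scaffold ids are the first whitespace-delimited word of
#'   each header; duplicates are a format error.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_format("malformed FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop_format("duplicate ids in FASTA '%s'", path)
  genome <- tibble(scaffold_id = ids,
                   sequence = unname(toupper(as.character(ss))),
                   length = Biostrings::width(ss))
  attr(genome, "truth") <- empty_truth_tbl()
  genome
}

#' Write a genome tibble as FASTA
#'
#' @param genome Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  check_genome_tbl(genome)
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$scaffold_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts 1-based inclusive GFF3 with `gene` features and exon-level
#' children (`exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`); children
#' are attached to their gene through the `Parent` chain (an intermediate
#' mRNA level is resolved transitively). An exon-level feature without a
#' resolvable gene parent is a format error naming the offending row.
#'
#' @param path GFF3 path.
#' @return Gene-feature tibble (`gene_id`, `scaffold_id`, `strand`, `kind`,
#'   `start`, `end`).
#' @export
read_gene_gff3 <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  keep_kinds <- c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
                  "three_prime_UTR")
  g <- g[g$type %in% keep_kinds, , drop = FALSE]
  ids <- as.character(g$ID)
  parents <- vapply(g$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  type <- as.character(g$type)
  gene_of <- function(row) {
    p <- parents[row]
    for (hop in 1:5) {
      if (is.na(p)) return(NA_character_)
      j <- match(p, ids)
      if (is.na(j)) return(NA_character_)
      if (type[j] == "gene") return(ids[j])
      p <- parents[j]
    }
    NA_character_
  }
  child <- which(!type %in% c("gene", "mRNA"))
  owner <- vapply(child, gene_of, character(1))
  if (any(is.na(owner))) {
    bad <- child[which(is.na(owner))[1]]
    stop_format("row %d of '%s' (%s at %s:%d-%d) has no resolvable gene parent",
                bad, path, type[bad], g$seqid[bad], g$start[bad], g$end[bad])
  }
  bind_rows(
    tibble(gene_id = ids[type == "gene"],
           scaffold_id = as.character(g$seqid[type == "gene"]),
           strand = as.character(g$strand[type == "gene"]),
           kind = "gene",
           start = as.integer(g$start[type == "gene"]),
           end = as.integer(g$end[type == "gene"])),
    tibble(gene_id = owner,
           scaffold_id = as.character(g$seqid[child]),
           strand = as.character(g$strand[child]),
           kind = type[child],
           start = as.integer(g$start[child]),
           end = as.integer(g$end[child]))
  ) |>
    arrange(.data$scaffold_id, .data$gene_id, .data$start)
}

#' Write gene models as GFF3
#'
#' @param gene_models Gene-feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(gene_models, path) {
  gm <- as_tibble(gene_models)
  gm$strand[is.na(gm$strand) | !gm$strand %in% c("+", "-")] <- "+"
  is_gene <- gm$kind == "gene"
  child_id <- paste0(gm$gene_id, ":", tolower(gm$kind), ":",
                     cumsum(!is_gene) * as.integer(!is_gene))
  gr <- GenomicRanges::GRanges(
    seqnames = gm$scaffold_id,
    ranges = IRanges::IRanges(gm$start, gm$end),
    strand = gm$strand
  )
  S4Vectors::mcols(gr)$type <- gm$kind
  S4Vectors::mcols(gr)$ID <- ifelse(is_gene, gm$gene_id, child_id)
  S4Vectors::mcols(gr)$Parent <- parent_list(
    ifelse(is_gene, NA_character_, gm$gene_id))
  S4Vectors::mcols(gr)$phase <- ifelse(gm$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write detected elements as GFF3
#'
#' Emits `LTR_retrotransposon` parents with `long_terminal_repeat`,
#' `target_site_duplication` and `protein_match` children.
#'
#' @param elements Element tibble (from [find_ltr_pairs()], optionally
#'   annotated by [annotate_domains()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path) {
  el <- as_tibble(elements)
  rows <- list()
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    rows[[length(rows) + 1]] <- tibble(
      scaffold_id = e$scaffold_id, type = "LTR_retrotransposon",
      start = e$start, end = e$end, ID = e$element_id,
      Parent = NA_character_)
    rows[[length(rows) + 1]] <- tibble(
      scaffold_id = e$scaffold_id, type = "long_terminal_repeat",
      start = c(e$ltr5_start, e$ltr3_start),
      end = c(e$ltr5_end, e$ltr3_end),
      ID = paste0(e$element_id, ":ltr", c(5, 3)), Parent = e$element_id)
    if (!is.null(e$tsd) && !is.na(e$tsd)) {
      t <- nchar(e$tsd)
      rows[[length(rows) + 1]] <- tibble(
        scaffold_id = e$scaffold_id, type = "target_site_duplication",
        start = c(e$start - t, e$end + 1L),
        end = c(e$start - 1L, e$end + t),
        ID = paste0(e$element_id, ":tsd", 1:2), Parent = e$element_id)
    }
    if ("domain_hits" %in% names(el)) {
      dh <- e$domain_hits[[1]]
      if (!is.null(dh) && nrow(dh)) {
        rows[[length(rows) + 1]] <- tibble(
          scaffold_id = e$scaffold_id, type = "protein_match",
          start = dh$start, end = dh$end,
          ID = paste0(e$element_id, ":", dh$domain, ":", seq_len(nrow(dh))),
          Parent = e$element_id)
      }
    }
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(df$scaffold_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- parent_list(df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

parent_list <- function(x) {
  IRanges::CharacterList(lapply(x, function(p) {
    if (is.na(p)) character() else p
  }))
}

#' Read a wide count table
#'
#' @param path TSV with columns `feature_id`, `length`, then one column per
#'   sample.
#' @return A count tibble.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("feature_id", "length") %in% names(counts))) {
    stop_format("'%s' must have columns feature_id, length, <samples>", path)
  }
  counts
}
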