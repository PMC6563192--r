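#' Simulate a background genome
#'
#' Draws scaffolds of i.i.d. nucleotides with a configurable GC fraction.
#' The background is deliberately repeat-free so that every paired repeat a
#' detector finds on a simulated genome was planted with
#' [plant_ltr_element()].
#'
#' @param scaffold_lengths Integer vector of scaffold lengths in bp, each
#'   at least 1000. Length zero gives an empty genome.
#' @param gc GC fraction in (0, 1).
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   genomes.
#' @param prefix Scaffold id prefix; ids are `<prefix>_1`, `<prefix>_2`, ...
#' @return A tibble with columns `scaffold_id`, `sequence`, `length` and an
#'   empty element-truth table in its `truth` attribute (see [ltr_truth()]).
#' @examples
#' g <- simulate_genome(20000, gc = 0.4, seed = 1)
#' nchar(g$sequence)
#' @export
simulate_genome <- function(scaffold_lengths, gc = 0.4, seed = NULL,
                            prefix = "scf") {
  scaffold_lengths <- as.integer(scaffold_lengths)
  if (any(is.na(scaffold_lengths)) || any(scaffold_lengths < 1000)) {
    stop_input("all scaffold lengths must be integers >= 1000")
  }
  if (!is.numeric(gc) || length(gc) != 1 || gc <= 0 || gc >= 1) {
    stop_input("`gc` must be a single number strictly between 0 and 1")
  }
  n <- length(scaffold_lengths)
  seqs <- with_seed_(seed, lapply(scaffold_lengths, random_dna, gc = gc))
  genome <- tibble(
    scaffold_id = if (n) paste(prefix, seq_len(n), sep = "_") else character(),
    sequence = if (n) vapply(seqs, identity, character(1)) else character(),
    length = scaffold_lengths
  )
  attr(genome, "truth") <- empty_truth_tbl()
  genome
}

empty_truth_tbl <- function() {
  tibble(
    element_id = character(), scaffold_id = character(),
    start = integer(), end = integer(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    ltr_len = integer(), internal_len = integer(),
    planted_identity = double(), n_substitutions = integer(),
    tsd_seq = character(), domains = character()
  )
}

#' Truth records of planted elements
#'
#' @param genome A genome tibble produced by [simulate_genome()] and
#'   modified by [plant_ltr_element()].
#' @return A tibble of planted-element truth records (1-based inclusive
#'   coordinates; the element interval excludes the flanking TSD copies).
#' @export
ltr_truth <- function(genome) {
  attr(genome, "truth") %||% empty_truth_tbl()
}

#' Default domain motif table
#'
#' Short fixed peptide motifs standing in for the gag/pro/pol/env protein
#' domains of an LTR retrotransposon. One deterministic motif per domain;
#' a profile-HMM search is deliberately out of scope, so domain annotation
#' reduces to exact peptide-string matching in all six reading frames.
#'
#' @return A tibble with columns `domain` and `motif` (peptide string).
#' @export
default_domain_motifs <- function() {
  tibble(
    domain = c("gag", "pro", "pol", "env"),
    motif = c(
      "MQRGNFRNQRK",    # nucleocapsid-like gag signature
      "LLDTGADDTVL",    # DTGA protease active-site block
      "YQYMDDLYVGS",    # YxDD reverse-transcriptase block
      "AVGIGALFLGFLG"   # hydrophobic envelope block
    )
  )
}

# deterministic reverse translation: one fixed codon per amino acid
CODON_OF_ <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

reverse_translate <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, names(CODON_OF_))
  if (length(bad)) stop_input("cannot reverse-translate residues: %s",
                              paste(bad, collapse = ","))
  paste(CODON_OF_[aa], collapse = "")
}

#' Plant an LTR retrotransposon into a simulated genome
#'
#' Overwrites a stretch of the scaffold in place with
#' `TSD | 5' LTR | internal region | 3' LTR | TSD`. The 3' LTR is a copy of
#' the 5' LTR carrying `round((1 - identity) * ltr_len)` substitutions at
#' positions drawn uniformly without replacement from the LTR interior
#' (the first and last 10 bp of each LTR are left untouched so repeat
#' boundaries stay exact). Each requested domain is realised as an in-frame
#' `ATG`-to-stop ORF carrying that domain's motif inside the internal region.
#' Scaffold length is unchanged; planting over a previously planted element
#' is an error.
#'
#' @param genome Genome tibble from [simulate_genome()].
#' @param scaffold_id Scaffold to modify.
#' @param position 1-based start of the left TSD copy.
#' @param ltr_len LTR length in bp (default range of real elements is
#'   100-1000 bp).
#' @param internal_len Internal-region length in bp.
#' @param identity Requested pairwise LTR identity in (0, 1].
#' @param tsd_len Target-site-duplication length (4-6 bp).
#' @param domains Character vector, subset of
#'   `default_domain_motifs()$domain`. Empty means the element carries no
#'   protein domain (a "solo" element under downstream classification).
#' @param seed Optional integer seed.
#' @param motif_table Domain motif table (see [default_domain_motifs()]).
#' @return The modified genome tibble; the new truth record is appended to
#'   the `truth` attribute (see [ltr_truth()]).
#' @export
plant_ltr_element <- function(genome, scaffold_id, position,
                              ltr_len = 300, internal_len = 5000,
                              identity = 0.9, tsd_len = 4,
                              domains = character(), seed = NULL,
                              motif_table = default_domain_motifs()) {
  check_genome_tbl(genome)
  si <- match(scaffold_id, genome$scaffold_id)
  if (is.na(si)) stop_input("scaffold '%s' not in genome", scaffold_id)
  if (ltr_len < 100 || ltr_len > 1000) {
    stop_input("`ltr_len` must lie in [100, 1000]")
  }
  if (tsd_len < 4 || tsd_len > 6) stop_input("`tsd_len` must lie in [4, 6]")
  if (identity <= 0 || identity > 1) stop_input("`identity` must be in (0, 1]")
  if (internal_len < 1) stop_input("`internal_len` must be positive")
  domains <- as.character(domains)
  if (length(domains) && !all(domains %in% motif_table$domain)) {
    stop_input("unknown domain(s): %s",
               join_names(setdiff(domains, motif_table$domain)))
  }

  scaf_len <- nchar(genome$sequence[[si]])
  span <- 2L * tsd_len + 2L * ltr_len + internal_len
  lo <- as.integer(position)
  hi <- lo + span - 1L
  if (lo < 1 || hi > scaf_len) {
    stop_input("element span [%d, %d] overruns scaffold '%s' (length %d)",
               lo, hi, scaffold_id, scaf_len)
  }
  truth <- ltr_truth(genome)
  prev <- truth[truth$scaffold_id == scaffold_id, , drop = FALSE]
  if (nrow(prev) &&
      any(pmax(prev$start - prev_tsd_len(prev), lo) <=
          pmin(prev$end + prev_tsd_len(prev), hi))) {
    stop_input("element at [%d, %d] overlaps a previously planted element",
               lo, hi)
  }

  n_sub <- as.integer(round((1 - identity) * ltr_len))
  interior <- if (ltr_len > 20) seq(11L, ltr_len - 10L) else integer()
  if (n_sub > length(interior)) {
    stop_input("requested identity needs %d substitutions but only %d interior positions",
               n_sub, length(interior))
  }

  pieces <- with_seed_(seed, {
    tsd <- random_dna(tsd_len, gc = 0.5)
    ltr5 <- random_dna(ltr_len, gc = 0.5)
    internal <- random_dna(internal_len, gc = 0.5)
    internal <- plant_domain_orfs(internal, domains, motif_table)
    ltr3 <- ltr5
    if (n_sub > 0) {
      pos <- sort(sample(interior, n_sub))
      ch <- strsplit(ltr3, "")[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(DNA_BASES_, ch[p]), 1)
      }
      ltr3 <- paste(ch, collapse = "")
    }
    list(tsd = tsd, ltr5 = ltr5, internal = internal, ltr3 = ltr3)
  })

  block <- paste0(pieces$tsd, pieces$ltr5, pieces$internal, pieces$ltr3,
                  pieces$tsd)
  stopifnot(nchar(block) == span)
  seq <- genome$sequence[[si]]
  substr(seq, lo, hi) <- block
  # Canonicalise the insertion-site flanks: the genomic base immediately
  # outside either TSD copy must differ from the adjacent LTR-end base,
  # otherwise the emitted locus admits a second, equally valid
  # (element, TSD) interpretation shifted by one and the recorded truth
  # would not be the unique maximal-TSD annotation.
  rotate_base <- function(b) {
    DNA_BASES_[match(b, DNA_BASES_) %% 4L + 1L]
  }
  ltr3_last <- substr(pieces$ltr3, ltr_len, ltr_len)
  ltr5_first <- substr(pieces$ltr5, 1L, 1L)
  if (lo > 1 && substr(seq, lo - 1L, lo - 1L) == ltr3_last) {
    substr(seq, lo - 1L, lo - 1L) <- rotate_base(ltr3_last)
  }
  if (hi < scaf_len && substr(seq, hi + 1L, hi + 1L) == ltr5_first) {
    substr(seq, hi + 1L, hi + 1L) <- rotate_base(ltr5_first)
  }
  genome$sequence[[si]] <- seq

  el_start <- lo + tsd_len
  el_end <- el_start + 2L * ltr_len + internal_len - 1L
  rec <- tibble(
    element_id = paste(scaffold_id, el_start, el_end, sep = "_"),
    scaffold_id = scaffold_id,
    start = el_start, end = el_end,
    ltr5_start = el_start, ltr5_end = el_start + ltr_len - 1L,
    ltr3_start = el_end - ltr_len + 1L, ltr3_end = el_end,
    ltr_len = as.integer(ltr_len), internal_len = as.integer(internal_len),
    planted_identity = 1 - n_sub / ltr_len,
    n_substitutions = n_sub,
    tsd_seq = pieces$tsd,
    domains = join_names(domains)
  )
  attr(genome, "truth") <- bind_rows(truth, rec)
  genome
}

prev_tsd_len <- function(truth_rows) nchar(truth_rows$tsd_seq)

# Embed one ATG + motif codons + TAA ORF per requested domain, evenly spaced
# through the internal region. Overwrites in place; errors when there is no
# room.
plant_domain_orfs <- function(internal, domains, motif_table) {
  nd <- length(domains)
  if (nd == 0) return(internal)
  orfs <- vapply(domains, function(d) {
    motif <- motif_table$motif[match(d, motif_table$domain)]
    paste0("ATG", reverse_translate(motif), "TAA")
  }, character(1))
  len <- nchar(internal)
  slot <- len %/% nd
  if (slot < max(nchar(orfs)) + 10L) {
    stop_input("internal region (%d bp) too short for %d domain ORF(s)",
               len, nd)
  }
  for (i in seq_len(nd)) {
    o <- orfs[[i]]
    pos <- (i - 1L) * slot + 5L
    substr(internal, pos, pos + nchar(o) - 1L) <- o
  }
  internal
}
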