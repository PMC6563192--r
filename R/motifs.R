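# Envelope-gene motif scanning: ORF finding, the fusion-peptide consensus,
# and the upstream furin cleavage site.

FUSION_PATTERN <- "G.{5}G.{3}K.{3}G.{2}D.{2}D"
FUSION_LEN <- 21L

#' Find open reading frames in a DNA sequence
#'
#' Reports maximal start-to-stop ORFs (first ATG after the previous stop to
#' the next in-frame stop codon) in all six frames of both strands, with
#' peptides translated under the standard code (stop excluded).
#'
#' @param dna A DNA string (IUPAC; `N` permitted, other characters are a
#'   format error).
#' @param min_len_aa Minimum peptide length in amino acids (>= 1).
#' @return A tibble: `frame` (+1..+3 / -1..-3), `start`, `end` (1-based
#'   inclusive nucleotide interval on the forward strand, including the
#'   stop codon), `strand`, `peptide`.
#' @examples
#' find_orfs("ATGAAATAA", min_len_aa = 1)
#' @export
find_orfs <- function(dna, min_len_aa = 50L) {
  if (!is.character(dna) || length(dna) != 1 || is.na(dna)) {
    stop_input("`dna` must be a single string")
  }
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) {
    stop_format("characters outside IUPAC DNA (ACGTN) in input")
  }
  if (min_len_aa < 1) stop_input("`min_len_aa` must be >= 1")
  n <- nchar(dna)
  out <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (f in 0:2) {
      sub <- substr(s, f + 1L, f + ((n - f) %/% 3L) * 3L)
      if (nchar(sub) < 6) next
      pep <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      m <- gregexpr("M[^*]*\\*", pep)[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      for (h in seq_along(m)) {
        aa_len <- lens[h] - 1L # peptide without the stop
        if (aa_len < min_len_aa) next
        nt_start_s <- f + (as.integer(m[h]) - 1L) * 3L + 1L
        nt_end_s <- nt_start_s + lens[h] * 3L - 1L
        if (strand == "+") {
          g_start <- nt_start_s; g_end <- nt_end_s
        } else {
          g_end <- n - nt_start_s + 1L
          g_start <- n - nt_end_s + 1L
        }
        out[[length(out) + 1L]] <- tibble(
          frame = (if (strand == "+") 1L else -1L) * (f + 1L),
          start = g_start, end = g_end, strand = strand,
          peptide = substr(pep, as.integer(m[h]),
                           as.integer(m[h]) + aa_len - 1L)
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  strand = character(), peptide = character()))
  }
  bind_rows(out) |> arrange(.data$start, .data$frame)
}

#' Scan a peptide for the fusion-peptide consensus
#'
#' Matches the degenerate block `G-x(5)-G-x(3)-K-x(3)-G-x(2)-D-x(2)-D`
#' (21 residues; fixed positions G, G, K, G, D, D; `x` is any residue).
#' All offsets are reported, including overlapping ones. The ambiguity code
#' `X` never matches a fixed position.
#'
#' @param peptide A peptide string over the 20 amino acids (plus `X`).
#' @param protein_id Optional id carried into the result.
#' @return A tibble of hits: `protein_id`, `motif` (`"fusion_peptide"`),
#'   `start` (0-based offset), `matched_seq`.
#' @examples
#' scan_fusion_motif("GAAAAAGAAAKAAAGAADAAD")
#' @export
scan_fusion_motif <- function(peptide, protein_id = NA_character_) {
  empty <- tibble(protein_id = character(), motif = character(),
                  start = integer(), matched_seq = character())
  if (!is.character(peptide) || length(peptide) != 1 || is.na(peptide)) {
    stop_input("`peptide` must be a single string")
  }
  if (nchar(peptide) < FUSION_LEN) return(empty)
  peptide <- toupper(peptide)
  # lookahead for overlapping matches
  m <- gregexpr(paste0("(?=", FUSION_PATTERN, ")"), peptide, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  tibble(
    protein_id = protein_id,
    motif = "fusion_peptide",
    start = starts - 1L,
    matched_seq = substring(peptide, starts, starts + FUSION_LEN - 1L)
  )
}

#' Assess the furin cleavage site upstream of a fusion-peptide hit
#'
#' Scans the `search_window_aa` residues immediately upstream of the fusion
#' hit for an `R-x-x-R` furin cleavage site. The call is:
#' * `complete` - some 4-residue frame ending in the window has arginine at
#'   both anchor positions;
#' * `incomplete` - no complete site, but some frame has exactly one of the
#'   two anchor arginines;
#' * `absent` - otherwise.
#' The frame nearest the fusion peptide wins within each category, and a
#' complete site is preferred over a nearer incomplete one. A window
#' extending before the start of the peptide is truncated.
#'
#' @param peptide The peptide scanned.
#' @param fusion_start 0-based offset of the fusion hit (e.g. the `start`
#'   of a [scan_fusion_motif()] row).
#' @param search_window_aa Window length upstream of the fusion hit
#'   (>= 4).
#' @param protein_id Optional id carried into the result.
#' @return A one-row tibble: `protein_id`, `motif` (`"furin"`), `start`
#'   (0-based offset of the site, `NA` when absent), `matched_seq`,
#'   `furin_status`.
#' @examples
#' scan_furin_site("AARAKRGAAAAAGAAAKAAAGAADAAD", fusion_start = 6)
#' @export
scan_furin_site <- function(peptide, fusion_start, search_window_aa = 30L,
                            protein_id = NA_character_) {
  if (search_window_aa < 4) stop_input("`search_window_aa` must be >= 4")
  peptide <- toupper(peptide)
  win_end <- as.integer(fusion_start) # 0-based: first residue of fusion
  win_start <- max(0L, win_end - as.integer(search_window_aa))
  absent <- tibble(protein_id = protein_id, motif = "furin",
                   start = NA_integer_, matched_seq = NA_character_,
                   furin_status = "absent")
  if (win_end - win_start < 4L) return(absent)
  # candidate 4-mers, nearest to the fusion peptide first
  best_incomplete <- NULL
  for (s in seq(win_end - 4L, win_start)) { # 0-based frame start
    frame <- substr(peptide, s + 1L, s + 4L)
    if (nchar(frame) < 4L) next
    r1 <- substr(frame, 1, 1) == "R"
    r4 <- substr(frame, 4, 4) == "R"
    if (r1 && r4) {
      return(tibble(protein_id = protein_id, motif = "furin",
                    start = s, matched_seq = frame,
                    furin_status = "complete"))
    }
    if (xor(r1, r4) && is.null(best_incomplete)) {
      best_incomplete <- tibble(protein_id = protein_id, motif = "furin",
                                start = s, matched_seq = frame,
                                furin_status = "incomplete")
    }
  }
  best_incomplete %||% absent
}

#' Scan envelope-like proteins for fusion competence
#'
#' Convenience wrapper chaining [scan_fusion_motif()] and
#' [scan_furin_site()] over a set of peptides: an element is
#' "fusion-competent" when it carries a fusion-peptide hit with a complete
#' furin cleavage site directly upstream.
#'
#' @param peptides Named character vector of peptides (names become
#'   `protein_id`).
#' @param search_window_aa Upstream window for the furin scan.
#' @return A tibble with one row per peptide: `protein_id`, `n_fusion_hits`,
#'   `fusion_start`, `furin_status`, `fusion_competent`, plus a `hits`
#'   list-column holding the individual motif-hit rows.
#' @export
scan_env_proteins <- function(peptides, search_window_aa = 30L) {
  if (is.null(names(peptides)) || any(!nzchar(names(peptides)))) {
    names(peptides) <- paste0("protein_", seq_along(peptides))
  }
  map_dfr(names(peptides), function(id) {
    pep <- peptides[[id]]
    fh <- scan_fusion_motif(pep, protein_id = id)
    if (nrow(fh) == 0) {
      return(tibble(protein_id = id, n_fusion_hits = 0L,
                    fusion_start = NA_integer_,
                    furin_status = NA_character_,
                    fusion_competent = FALSE, hits = list(fh)))
    }
    fs <- fh$start[1]
    fur <- scan_furin_site(pep, fs, search_window_aa = search_window_aa,
                           protein_id = id)
    tibble(protein_id = id, n_fusion_hits = nrow(fh), fusion_start = fs,
           furin_status = fur$furin_status,
           fusion_competent = fur$furin_status == "complete",
           hits = list(bind_rows(fh, fur)))
  })
}
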