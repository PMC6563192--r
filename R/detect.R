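#' Pairwise LTR identity by global alignment
#'
#' Global (Needleman-Wunsch) alignment with affine gaps: match +1,
#' mismatch -1, gap of length g costs 2 + g. Identity is
#' matches / alignment columns; among maximum-score alignments the one with
#' the most matches (then fewest columns) defines the reported value, so the
#' function is deterministic and symmetric in its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' ltr_identity("ACGTACGT", "ACGTACGT")
#' @export
ltr_identity <- function(a, b) {
  ltr_align(a, b)$identity
}

#' @rdname ltr_identity
#' @return `ltr_align()` returns the full alignment statistics: a list with
#'   `score`, `matches`, `columns` and `identity`.
#' @export
ltr_align <- function(a, b) {
  if (!is.character(a) || !is.character(b) ||
      length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    stop_input("`a` and `b` must be single non-empty DNA strings")
  }
  .nw_align_stats(toupper(a), toupper(b))
}

#' Detect target-site duplications flanking candidate elements
#'
#' Returns, for each element, the longest exact sequence duplication with
#' length inside `tsd_len_range` whose two copies immediately flank the
#' element interval (`[start - t, start - 1]` versus `[end + 1, end + t]`).
#'
#' @param genome Genome tibble (`scaffold_id`, `sequence`).
#' @param elements Tibble with columns `scaffold_id`, `start`, `end`
#'   (1-based inclusive element intervals).
#' @param tsd_len_range Length-2 integer vector, smallest and largest TSD
#'   length considered (default 4-6 bp).
#' @return `elements` with a `tsd` character column (`NA` when no flanking
#'   duplication exists or the element sits at a scaffold edge without
#'   enough flank; the latter case is reported with a message).
#' @export
detect_tsd <- function(genome, elements, tsd_len_range = c(4L, 6L)) {
  check_genome_tbl(genome)
  elements <- as_tibble(elements)
  tmin <- as.integer(tsd_len_range[1]); tmax <- as.integer(tsd_len_range[2])
  if (tmin < 1 || tmax < tmin) stop_input("bad `tsd_len_range`")
  elements$tsd <- pmap(
    list(elements$scaffold_id, elements$start, elements$end),
    function(sc, s, e) {
      seq <- scaffold_seq(genome, sc)
      tsd_at(seq, s, e, tmin, tmax, note = TRUE)
    }
  ) |> map_chr(~ .x %||% NA_character_)
  elements
}

# Scalar TSD lookup; returns NULL when absent.
tsd_at <- function(seq, s, e, tmin, tmax, note = FALSE) {
  n <- nchar(seq)
  if (s - tmax < 1 || e + tmax > n) {
    if (s - tmin < 1 || e + tmin > n) {
      if (note) inform(sprintf(
        "element at [%d, %d] lacks flank room for a TSD; reporting absent",
        s, e))
      return(NULL)
    }
    tmax <- min(tmax, s - 1L, n - e)
  }
  for (t in seq(tmax, tmin)) {
    left <- substr(seq, s - t, s - 1L)
    right <- substr(seq, e + 1L, e + t)
    if (left == right) return(left)
  }
  NULL
}

#' Find paired-LTR retrotransposon candidates in a genome
#'
#' Structural detection by paired direct-repeat search: exact k-mer matches
#' between forward-strand positions are grouped by diagonal (candidate LTR
#' pairs have equal spacing throughout in the substitution-divergence
#' model), chained, extended to maximal similar blocks by ungapped X-drop
#' extension, and the element boundaries are refined against the
#' target-site-duplication criterion. A candidate is reported when
#'
#' * both LTR copies have length in `[min_ltr_len, max_ltr_len]`,
#' * the inner separation (bp between the 3' end of the 5' LTR and the
#'   start of the 3' LTR) lies in `[min_sep, max_sep]`,
#' * the global-alignment identity of the two copies (see [ltr_identity()])
#'   is at least `min_identity`, and
#' * (when `require_tsd`) an exact duplication of 4-6 bp immediately flanks
#'   the element.
#'
#' Overlapping candidates are resolved deterministically: highest identity
#' wins, ties go to the longer element, then the leftmost start. Only
#' direct (same-strand) repeats are considered and nested elements are not
#' resolved.
#'
#' @param genome Genome tibble (`scaffold_id`, `sequence`); sequences are
#'   upper-cased internally.
#' @param min_ltr_len,max_ltr_len Accepted LTR lengths (bp).
#' @param min_sep,max_sep Accepted inner separation between the two LTR
#'   copies (bp).
#' @param min_identity Minimum pairwise LTR identity (fraction).
#' @param tsd_len_range TSD length range (bp).
#' @param require_tsd Drop candidates without a flanking TSD (the screening
#'   criterion used for the real library).
#' @param seed_kmer Seed k-mer length.
#' @param max_seed_gap Maximum gap (bp) between chained seed matches on one
#'   diagonal.
#' @param xdrop X-drop threshold for ungapped extension.
#' @param boundary_jitter Half-width (bp) of the boundary search window used
#'   during TSD refinement.
#' @param max_kmer_occ Seed k-mers occurring more often than this per
#'   scaffold are skipped as low-complexity.
#' @return A tibble of elements, sorted by scaffold then start, with columns
#'   `element_id` (`<scaffold>_<start>_<end>`), `scaffold_id`, `start`,
#'   `end`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `ltr_identity`, `separation`, `tsd`. Domain annotation and the
#'   full-length/solo category are added by [annotate_domains()].
#' @export
find_ltr_pairs <- function(genome,
                           min_ltr_len = 100L, max_ltr_len = 1000L,
                           min_sep = 1000L, max_sep = 15000L,
                           min_identity = 0.80,
                           tsd_len_range = c(4L, 6L), require_tsd = TRUE,
                           seed_kmer = 12L, max_seed_gap = 300L,
                           xdrop = 12, boundary_jitter = 15L,
                           max_kmer_occ = 200L) {
  check_genome_tbl(genome)
  if (min_sep >= max_sep) stop_input("`min_sep` must be below `max_sep`")
  if (min_identity <= 0 || min_identity > 1) {
    stop_input("`min_identity` must be in (0, 1]")
  }
  if (nrow(genome) == 0) return(empty_element_tbl())
  bad <- grepl("[^ACGTNacgtn]", genome$sequence)
  if (any(bad)) {
    stop_format("non-IUPAC characters in scaffold(s): %s",
                join_names(genome$scaffold_id[bad]))
  }

  res <- map_dfr(seq_len(nrow(genome)), function(i) {
    scan_scaffold(genome$scaffold_id[i], toupper(genome$sequence[i]),
                  min_ltr_len, max_ltr_len, min_sep, max_sep, min_identity,
                  tsd_len_range, require_tsd, seed_kmer, max_seed_gap,
                  xdrop, boundary_jitter, max_kmer_occ)
  })
  if (nrow(res) == 0) return(empty_element_tbl())
  arrange(res, .data$scaffold_id, .data$start)
}

empty_element_tbl <- function() {
  tibble(element_id = character(), scaffold_id = character(),
         start = integer(), end = integer(),
         ltr5_start = integer(), ltr5_end = integer(),
         ltr3_start = integer(), ltr3_end = integer(),
         ltr_identity = double(), separation = integer(),
         tsd = character())
}

scan_scaffold <- function(scaffold_id, seq, min_ltr_len, max_ltr_len,
                          min_sep, max_sep, min_identity, tsd_len_range,
                          require_tsd, k, max_seed_gap, xdrop,
                          boundary_jitter, max_kmer_occ) {
  n <- nchar(seq)
  d_min <- min_sep + min_ltr_len
  d_max <- max_sep + max_ltr_len
  if (n < 2L * min_ltr_len + min_sep) return(empty_element_tbl())

  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  grp <- split(starts[keep], kmers[keep])
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= max_kmer_occ]
  if (!length(grp)) return(empty_element_tbl())

  seed_pairs <- map_dfr(grp, function(p) {
    m <- length(p)
    ii <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    jj <- unlist(lapply(2L:m, function(x) x:m), use.names = FALSE)
    tibble(i = p[ii], j = p[jj])
  })
  seed_pairs <- seed_pairs |>
    mutate(d = .data$j - .data$i) |>
    filter(.data$d >= d_min, .data$d <= d_max)
  if (nrow(seed_pairs) == 0) return(empty_element_tbl())

  clusters <- seed_pairs |>
    arrange(.data$d, .data$i) |>
    group_by(.data$d) |>
    mutate(run = cumsum(c(1L, as.integer(diff(.data$i) > max_seed_gap)))) |>
    group_by(.data$d, .data$run) |>
    summarise(i1 = min(.data$i), i2 = max(.data$i), nseed = n(),
              .groups = "drop")

  cand <- pmap_dfr(clusters[c("d", "i1", "i2")], function(d, i1, i2) {
    candidate_from_cluster(seq, n, d, i1, i2 + k - 1L,
                           min_ltr_len, max_ltr_len, min_sep, max_sep,
                           min_identity, tsd_len_range, require_tsd,
                           xdrop, boundary_jitter)
  })
  if (nrow(cand) == 0) return(empty_element_tbl())

  cand <- resolve_overlaps(distinct(cand))
  cand |>
    mutate(scaffold_id = scaffold_id,
           element_id = paste(scaffold_id, .data$start, .data$end, sep = "_"),
           .before = 1) |>
    relocate("element_id", "scaffold_id")
}

# Turn one chained seed block (copy1 spans [i1, i2], copy2 the same + d)
# into a refined candidate element row, or an empty tibble when any
# criterion fails.
candidate_from_cluster <- function(seq, n, d, i1, i2,
                                   min_ltr_len, max_ltr_len, min_sep,
                                   max_sep, min_identity, tsd_len_range,
                                   require_tsd, xdrop, boundary_jitter) {
  none <- empty_element_tbl()[0, c("start", "end", "ltr5_start", "ltr5_end",
                                   "ltr3_start", "ltr3_end", "ltr_identity",
                                   "separation", "tsd")]
  b1 <- i1 - .xdrop_extend(seq, i1, i1 + d, -1L, xdrop)
  b2 <- i2 + .xdrop_extend(seq, i2, i2 + d, +1L, xdrop)
  L <- b2 - b1 + 1L
  if (L < min_ltr_len - boundary_jitter || L > max_ltr_len + boundary_jitter) {
    return(none)
  }
  # A candidate is fully parameterised by (l, r, d): under the
  # substitution-divergence model both repeat copies lie on one diagonal,
  # so LTR5 = [l, r - d] and LTR3 = [l + d, r].
  l0 <- b1
  r0 <- b2 + d
  tmin <- as.integer(tsd_len_range[1]); tmax <- as.integer(tsd_len_range[2])
  ref <- refine_boundaries(seq, n, l0, r0, d, tmin, tmax, boundary_jitter)
  if (is.null(ref)) {
    if (require_tsd) return(none)
    if (l0 < 1 || r0 > n || r0 - l0 + 1L <= d) return(none)
    identity <- .nw_align_stats(substr(seq, l0, r0 - d),
                                substr(seq, l0 + d, r0))$identity
    ref <- list(l = l0, r = r0, tsd = NA_character_, identity = identity)
  }
  l <- ref$l; r <- ref$r
  ltr5_end <- r - d
  ltr3_start <- l + d
  L <- r - l + 1L - d
  if (L < min_ltr_len || L > max_ltr_len) return(none)
  sep <- d - L
  if (sep < min_sep || sep > max_sep) return(none)
  if (ref$identity < min_identity) return(none)
  tibble(start = l, end = r,
         ltr5_start = l, ltr5_end = ltr5_end,
         ltr3_start = ltr3_start, ltr3_end = r,
         ltr_identity = ref$identity, separation = sep,
         tsd = ref$tsd %||% NA_character_)
}

# Search a small jitter window around the extension boundaries for the
# element interval admitting a flanking TSD. Every TSD-bearing boundary
# pair (l, r) is scored by the global-alignment score of the implied LTR
# copies plus a bonus of 2 per duplicated TSD base; the best cell wins.
# The bonus makes the true insertion boundary dominate one-off shifts
# that trade a TSD base for a coincidentally matching flank pair, while a
# far-shifted boundary with a spurious duplication loses on alignment
# score. Ties go to the longer TSD, then the smallest boundary shift,
# then the leftmost start. NULL when no cell in the window admits a TSD.
refine_boundaries <- function(seq, n, l0, r0, d, tmin, tmax, jitter,
                              tsd_bonus = 1.5) {
  shifts <- seq(-jitter, jitter)
  grid <- expand.grid(dl = shifts, dr = shifts, KEEP.OUT.ATTRS = FALSE)
  grid$l <- l0 + grid$dl
  grid$r <- r0 + grid$dr
  grid <- grid[grid$l - tmin >= 1 & grid$r + tmin <= n &
                 grid$r - grid$l + 1L > d, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid$cost <- abs(grid$dl) + abs(grid$dr)
  grid <- grid[order(grid$cost, grid$l, grid$r), , drop = FALSE]
  best <- NULL
  for (idx in seq_len(nrow(grid))) {
    t <- tsd_at(seq, grid$l[idx], grid$r[idx], tmin, tmax)
    if (is.null(t)) next
    st <- .nw_align_stats(substr(seq, grid$l[idx], grid$r[idx] - d),
                          substr(seq, grid$l[idx] + d, grid$r[idx]))
    sc <- st$score + tsd_bonus * nchar(t)
    # grid is visited in order of increasing boundary shift, so on a score
    # tie the first (least-shifted) cell stands unless a same-shift cell
    # offers a longer TSD
    better <- is.null(best) ||
      sc > best$cell_score + 1e-9 ||
      (abs(sc - best$cell_score) <= 1e-9 &&
         grid$cost[idx] == best$cost && nchar(t) > nchar(best$tsd))
    if (better) {
      best <- list(l = grid$l[idx], r = grid$r[idx], tsd = t,
                   identity = st$identity, cell_score = sc,
                   cost = grid$cost[idx])
    }
  }
  best
}

# Deterministic resolution of overlapping candidates on one scaffold.
resolve_overlaps <- function(cand) {
  cand <- cand |>
    arrange(desc(.data$ltr_identity), desc(.data$end - .data$start),
            .data$start)
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(kept_start <= e & kept_end >= s)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Annotate internal protein domains and assign full-length/solo category
#'
#' Translates the internal region of each element (between the two LTR
#' copies) in all six reading frames and scans for the motif peptides of
#' `motif_table` as exact substrings. Elements with at least one domain hit
#' are categorised `full_length`; elements lacking all protein domains are
#' `solo`. A stop codon inside a motif's frame breaks the match (the
#' translated peptide then contains `*`).
#'
#' @param genome Genome tibble.
#' @param elements Element tibble from [find_ltr_pairs()].
#' @param motif_table Tibble with columns `domain` and `motif`.
#' @param min_len_aa Unused placeholder for API symmetry with [find_orfs()].
#' @return `elements` with `domains` (comma-joined names or `NA`),
#'   `category` (`"full_length"` or `"solo"`), and a `domain_hits`
#'   list-column of per-hit tibbles (`domain`, `frame`, `start`, `end` in
#'   genome nucleotide coordinates).
#' @export
annotate_domains <- function(genome, elements,
                             motif_table = default_domain_motifs(),
                             min_len_aa = NULL) {
  check_genome_tbl(genome)
  if (is.null(motif_table) || !all(c("domain", "motif") %in%
                                   names(motif_table))) {
    stop_config("`motif_table` must have columns `domain` and `motif`")
  }
  elements <- as_tibble(elements)
  hits <- pmap(
    list(elements$scaffold_id, elements$ltr5_end, elements$ltr3_start),
    function(sc, inner_lo, inner_hi) {
      seq <- scaffold_seq(genome, sc)
      internal <- substr(seq, inner_lo + 1L, inner_hi - 1L)
      scan_domain_motifs(internal, inner_lo + 1L, motif_table)
    }
  )
  elements$domain_hits <- hits
  elements$domains <- map_chr(hits, ~ join_names(sort(unique(.x$domain))))
  elements$category <- ifelse(map_int(hits, nrow) > 0, "full_length", "solo")
  elements
}

# Scan all six frames of `internal` (genome offset of its first base =
# `offset`) for exact motif peptides.
scan_domain_motifs <- function(internal, offset, motif_table) {
  out <- tibble(domain = character(), frame = integer(),
                start = integer(), end = integer())
  len <- nchar(internal)
  if (len < 3) return(out)
  fwd <- internal
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(internal)))
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (f in 0:2) {
      sub <- substr(s, f + 1L, f + ((len - f) %/% 3L) * 3L)
      if (nchar(sub) < 3) next
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
      for (m in seq_len(nrow(motif_table))) {
        locs <- gregexpr(motif_table$motif[m], pep, fixed = TRUE)[[1]]
        if (locs[1] == -1) next
        for (aa0 in as.integer(locs)) {
          nt_in_frame <- f + (aa0 - 1L) * 3L + 1L # within s
          nt_len <- nchar(motif_table$motif[m]) * 3L
          if (strand == 1L) {
            g_start <- offset + nt_in_frame - 1L
            g_end <- g_start + nt_len - 1L
          } else {
            g_end <- offset + (len - nt_in_frame + 1L) - 1L
            g_start <- g_end - nt_len + 1L
          }
          out <- bind_rows(out, tibble(
            domain = motif_table$domain[m],
            frame = strand * (f + 1L),
            start = g_start, end = g_end
          ))
        }
      }
    }
  }
  out
}
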