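# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive re-derivation (enumeration, brute force, explicit
# loops) of a quantity the package computes by a different route.

# ---- exhaustive global-alignment oracle (tiny strings) ---------------------
# Enumerates every global alignment recursively under the same cost model
# (match +1, mismatch -1, gap of length g costs 2 + g) and returns the best
# by (score, matches, fewest columns).
align_enum_oracle <- function(a, b, match = 1, mismatch = -1,
                              open = 2, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- NULL
  consider <- function(score, matches, cols) {
    if (is.null(best) ||
        score > best[1] + 1e-9 ||
        (abs(score - best[1]) < 1e-9 &&
         (matches > best[2] ||
          (matches == best[2] && cols < best[3])))) {
      best <<- c(score, matches, cols)
    }
  }
  rec <- function(i, j, score, matches, cols, prev) {
    if (i > length(A) && j > length(B)) {
      consider(score, matches, cols)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      m <- A[i] == B[j]
      rec(i + 1, j + 1, score + if (m) match else mismatch,
          matches + m, cols + 1, "M")
    }
    if (i <= length(A)) {
      rec(i + 1, j, score - extend - if (prev == "X") 0 else open,
          matches, cols + 1, "X")
    }
    if (j <= length(B)) {
      rec(i, j + 1, score - extend - if (prev == "Y") 0 else open,
          matches, cols + 1, "Y")
    }
  }
  rec(1, 1, 0, 0, 0, "")
  list(score = best[1], matches = best[2], columns = best[3],
       identity = best[2] / best[3])
}

# ---- brute-force paired-repeat search --------------------------------------
# All-substring-pair scan: every (start, diagonal, LTR length) window with
# ungapped identity >= min_identity, inner separation in range, and an
# exact flanking TSD; overlaps resolved with the same deterministic rule
# as the detector. Suitable for scaffolds up to ~20 kb with narrowed
# parameter ranges.
brute_find_ltr_pairs <- function(seq, min_ltr, max_ltr, min_sep, max_sep,
                                 min_identity, tsd_range = c(4L, 6L)) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  rows <- list()
  for (d in seq(min_sep + min_ltr, min(max_sep + max_ltr, n - 1))) {
    eq <- x[seq_len(n - d)] == x[seq(1 + d, n)]
    cs <- c(0, cumsum(eq))
    L_lo <- max(min_ltr, d - max_sep)
    L_hi <- min(max_ltr, d - min_sep)
    if (L_lo > L_hi) next
    for (L in L_lo:L_hi) {
      smax <- n - d - L + 1
      if (smax < 1) next
      s <- seq_len(smax)
      matches <- cs[s + L] - cs[s]
      hits <- s[matches / L >= min_identity]
      for (l in hits) {
        r <- l + d + L - 1
        tsd <- oracle_tsd(x, l, r, tsd_range)
        if (is.null(tsd)) next
        rows[[length(rows) + 1]] <- data.frame(
          start = l, end = r, L = L,
          identity = (cs[l + L] - cs[l]) / L)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer()))
  }
  cand <- unique(do.call(rbind, rows)[c("start", "end", "identity")])
  cand <- cand[order(-cand$identity, -(cand$end - cand$start), cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(ks <= cand$end[i] & ke >= cand$start[i])) {
      keep[i] <- TRUE
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  out <- cand[keep, c("start", "end")]
  out[order(out$start), , drop = FALSE]
}

oracle_tsd <- function(x, l, r, tsd_range) {
  n <- length(x)
  for (t in seq(tsd_range[2], tsd_range[1])) {
    if (l - t < 1 || r + t > n) next
    if (identical(x[(l - t):(l - 1)], x[(r + 1):(r + t)])) {
      return(paste(x[(l - t):(l - 1)], collapse = ""))
    }
  }
  NULL
}

# ---- positional classification / cis targets by explicit loops -------------
brute_classify <- function(elements, exons) {
  out <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    ex <- exons[exons$scaffold_id == e$scaffold_id, , drop = FALSE]
    inc <- FALSE; part <- FALSE
    if (nrow(ex)) {
      for (j in seq_len(nrow(ex))) {
        if (ex$start[j] <= e$end && ex$end[j] >= e$start) {
          if (ex$start[j] >= e$start && ex$end[j] <= e$end) inc <- TRUE
          else part <- TRUE
        }
      }
    }
    out[[i]] <- data.frame(element_id = e$element_id, in_class = inc,
                           part_class = part, stream = !inc && !part)
  }
  do.call(rbind, out)
}

brute_cis_targets <- function(elements, exons, window) {
  out <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    ex <- exons[exons$scaffold_id == e$scaffold_id, , drop = FALSE]
    for (g in unique(ex$gene_id)) {
      gx <- ex[ex$gene_id == g, , drop = FALSE]
      dmin <- Inf
      for (j in seq_len(nrow(gx))) {
        if (gx$start[j] <= e$end && gx$end[j] >= e$start) {
          d <- 0
        } else if (gx$start[j] > e$end) {
          d <- gx$start[j] - e$end - 1
        } else {
          d <- e$start - gx$end[j] - 1
        }
        dmin <- min(dmin, d)
      }
      if (dmin <= window) {
        out[[length(out) + 1]] <- data.frame(
          element_id = e$element_id, gene_id = g, distance = dmin)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(element_id = character(), gene_id = character(),
                      distance = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$element_id, res$gene_id), , drop = FALSE]
}

# ---- six-frame ORF enumeration by explicit codon walk ----------------------
orf_oracle <- function(dna, min_len_aa) {
  code <- Biostrings::GENETIC_CODE
  walk <- function(s, strand, n) {
    out <- list()
    for (f in 0:2) {
      ncod <- (nchar(s) - f) %/% 3
      start_cod <- NA
      for (ci in seq_len(ncod)) {
        codon <- substr(s, f + (ci - 1) * 3 + 1, f + ci * 3)
        aa <- code[[codon]]
        if (is.null(aa)) aa <- "X"
        if (aa == "M" && is.na(start_cod)) start_cod <- ci
        if (aa == "*") {
          if (!is.na(start_cod)) {
            nt_s <- f + (start_cod - 1) * 3 + 1
            nt_e <- f + ci * 3
            len_aa <- ci - start_cod
            if (len_aa >= min_len_aa) {
              gs <- if (strand == "+") nt_s else n - nt_e + 1
              ge <- if (strand == "+") nt_e else n - nt_s + 1
              out[[length(out) + 1]] <- data.frame(
                start = gs, end = ge, strand = strand, aa_len = len_aa)
            }
          }
          start_cod <- NA
        }
      }
    }
    out
  }
  n <- nchar(dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  res <- c(walk(toupper(dna), "+", n), walk(toupper(rc), "-", n))
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_len = integer()))
  }
  res <- do.call(rbind, res)
  res[order(res$start, res$strand, res$end), , drop = FALSE]
}

# ---- fusion-consensus matcher by explicit position checks ------------------
fusion_oracle <- function(pep) {
  p <- strsplit(toupper(pep), "")[[1]]
  n <- length(p)
  hits <- integer(0)
  if (n >= 21) {
    for (s in 1:(n - 20)) {
      if (p[s] == "G" && p[s + 6] == "G" && p[s + 10] == "K" &&
          p[s + 14] == "G" && p[s + 17] == "D" && p[s + 20] == "D") {
        hits <- c(hits, s - 1L) # 0-based
      }
    }
  }
  hits
}

# ---- hypergeometric upper tail by draw enumeration -------------------------
hyper_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# ---- replicate-consistency by all-pairs comparison -------------------------
consistency_oracle <- function(ck, npv) {
  all_up <- all(outer(npv, ck, ">"))
  all_down <- all(outer(npv, ck, "<"))
  all_eq <- length(unique(c(ck, npv))) == 1
  all_up || all_down || all_eq
}
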