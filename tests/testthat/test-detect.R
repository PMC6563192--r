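test_that("a planted element is recovered with exact boundaries", {
  g <- simulate_genome(30000, gc = 0.4, seed = 7)
  g <- plant_ltr_element(g, "scf_1", 5000, ltr_len = 300,
                         internal_len = 5000, identity = 0.85,
                         tsd_len = 4, domains = "pol", seed = 3)
  tr <- ltr_truth(g)
  el <- find_ltr_pairs(g)
  expect_equal(nrow(el), 1)
  expect_equal(el$start, tr$start)
  expect_equal(el$end, tr$end)
  expect_equal(el$ltr5_start, tr$ltr5_start)
  expect_equal(el$ltr3_end, tr$ltr3_end)
  expect_equal(el$tsd, tr$tsd_seq)
  expect_equal(el$ltr_identity, tr$planted_identity, tolerance = 1e-9)
  expect_equal(el$element_id, paste0("scf_1_", el$start, "_", el$end))
})

test_that("unplanted random sequence yields no detections", {
  g <- simulate_genome(50000, gc = 0.4, seed = 123)
  expect_equal(nrow(find_ltr_pairs(g)), 0)
  expect_equal(nrow(find_ltr_pairs(g[0, ])), 0)
})

test_that("identity below the threshold is not reported", {
  g <- simulate_genome(30000, gc = 0.4, seed = 31)
  g <- plant_ltr_element(g, "scf_1", 5000, ltr_len = 300,
                         internal_len = 5000, identity = 0.75,
                         tsd_len = 4, seed = 32)
  expect_equal(nrow(find_ltr_pairs(g, min_identity = 0.80)), 0)
  # but a permissive threshold finds it
  low <- find_ltr_pairs(g, min_identity = 0.70)
  expect_equal(nrow(low), 1)
  expect_equal(low$start, ltr_truth(g)$start)
})

test_that("reported identities and separations always satisfy the criteria", {
  for (seed in 101:106) {
    g <- small_planted_genome(seed)
    el <- detect_small(g)
    expect_true(all(el$ltr_identity >= small_detect_params$min_identity))
    expect_true(all(el$separation >= small_detect_params$min_sep))
    expect_true(all(el$separation <= small_detect_params$max_sep))
    L5 <- el$ltr5_end - el$ltr5_start + 1
    L3 <- el$ltr3_end - el$ltr3_start + 1
    expect_true(all(L5 >= small_detect_params$min_ltr_len &
                      L5 <= small_detect_params$max_ltr_len))
    expect_true(all(L3 >= small_detect_params$min_ltr_len &
                      L3 <= small_detect_params$max_ltr_len))
  }
})

test_that("detector equals the brute-force all-pair search on small scaffolds", {
  for (seed in c(201, 202, 203)) {
    g <- small_planted_genome(seed)
    el <- detect_small(g)
    orc <- oracle_small(g)
    expect_equal(nrow(el), nrow(orc))
    expect_equal(el$start, orc$start)
    expect_equal(el$end, orc$end)
    # and both equal the planted truth
    tr <- dplyr::arrange(ltr_truth(g), start)
    expect_equal(el$start, tr$start)
    expect_equal(el$end, tr$end)
  }
})

test_that("TSD detection prefers the longest duplication and handles edges", {
  g <- simulate_genome(10000, seed = 55)
  seq <- g$sequence[1]
  # construct element flanks by hand: 6-mer duplication present
  substr(seq, 994, 999) <- "ACGTAC"
  substr(seq, 2001, 2006) <- "ACGTAC"
  g$sequence[1] <- seq
  el <- tibble::tibble(scaffold_id = "scf_1", start = 1000L, end = 2000L)
  out <- detect_tsd(g, el)
  expect_equal(out$tsd, "ACGTAC")

  # 4-mer only
  seq2 <- g$sequence[1]
  substr(seq2, 994, 999) <- "TTTTTT"
  substr(seq2, 996, 999) <- "GCAT"
  substr(seq2, 2001, 2006) <- "GCATTT"
  g$sequence[1] <- seq2
  out2 <- detect_tsd(g, el)
  expect_equal(out2$tsd, "GCAT")

  # element at scaffold edge: absent, with a note
  edge <- tibble::tibble(scaffold_id = "scf_1", start = 2L, end = 2000L)
  expect_message(out3 <- detect_tsd(g, edge), "flank")
  expect_true(is.na(out3$tsd))
})

test_that("require_tsd drops candidates without a flanking duplication", {
  g <- simulate_genome(20000, seed = 77)
  g <- plant_ltr_element(g, "scf_1", 3000, ltr_len = 200,
                         internal_len = 2000, identity = 0.95,
                         tsd_len = 4, seed = 78)
  tr <- ltr_truth(g)
  # destroy the left TSD copy
  seq <- g$sequence[1]
  tsd <- substr(seq, tr$start - 4, tr$start - 1)
  repl <- chartr("ACGT", "GTAC", tsd)
  substr(seq, tr$start - 4, tr$start - 1) <- repl
  g$sequence[1] <- seq
  # boundary_jitter 0 pins the TSD check to the extension boundaries
  expect_equal(nrow(find_ltr_pairs(g, require_tsd = TRUE,
                                   boundary_jitter = 0L)), 0)
  found <- find_ltr_pairs(g, require_tsd = FALSE, boundary_jitter = 0L)
  expect_equal(nrow(found), 1)
  # without a TSD the exact insertion point is ambiguous; boundaries come
  # from ungapped extension alone and may wobble by a few bases
  expect_lt(abs(found$start - tr$start), 12)
  expect_lt(abs(found$end - tr$end), 12)
})

test_that("domain annotation separates full-length from solo", {
  g <- simulate_genome(c(30000, 30000), seed = 88)
  g <- plant_ltr_element(g, "scf_1", 4000, ltr_len = 250,
                         internal_len = 4000, identity = 0.9,
                         domains = c("gag", "pol"), seed = 89)
  g <- plant_ltr_element(g, "scf_2", 4000, ltr_len = 250,
                         internal_len = 4000, identity = 0.9,
                         domains = character(), seed = 90)
  el <- annotate_domains(g, find_ltr_pairs(g))
  el <- dplyr::arrange(el, scaffold_id)
  expect_equal(el$category, c("full_length", "solo"))
  expect_equal(el$domains[1], "gag,pol")
  expect_true(is.na(el$domains[2]))
  hits <- el$domain_hits[[1]]
  expect_setequal(hits$domain, c("gag", "pol"))
  expect_true(all(hits$start > el$ltr5_end[1] & hits$end < el$ltr3_start[1]))
})

test_that("a stop codon interrupting the motif frame kills the hit", {
  g <- simulate_genome(30000, seed = 91)
  g <- plant_ltr_element(g, "scf_1", 4000, ltr_len = 250,
                         internal_len = 4000, identity = 0.9,
                         domains = "pol", seed = 92)
  el <- find_ltr_pairs(g)
  with_hit <- annotate_domains(g, el)
  expect_equal(with_hit$category, "full_length")
  hit <- with_hit$domain_hits[[1]]
  # overwrite a mid-motif codon with TAA in the motif's own frame
  seq <- g$sequence[1]
  mid_codon_start <- hit$start[1] + 15
  substr(seq, mid_codon_start, mid_codon_start + 2) <- "TAA"
  g$sequence[1] <- seq
  after <- annotate_domains(g, find_ltr_pairs(g))
  expect_equal(after$category, "solo")
})

test_that("malformed genomes are rejected", {
  bad <- tibble::tibble(scaffold_id = "s1", sequence = "ACGTXXACGT")
  expect_error(find_ltr_pairs(bad), class = "ltrcis_error_format")
  dup <- tibble::tibble(scaffold_id = c("s", "s"),
                        sequence = c("ACGT", "ACGT"))
  expect_error(find_ltr_pairs(dup), class = "ltrcis_error_format")
  expect_error(annotate_domains(simulate_genome(1000, seed = 1),
                                tibble::tibble(), motif_table = NULL),
               class = "ltrcis_error_config")
})
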