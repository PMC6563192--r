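test_that("genome simulation is deterministic, GC-faithful, and validates input", {
  g1 <- simulate_genome(c(30000, 30000), gc = 0.4, seed = 7)
  g2 <- simulate_genome(c(30000, 30000), gc = 0.4, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$scaffold_id, c("scf_1", "scf_2"))

  obs_gc <- mean(strsplit(paste(g1$sequence, collapse = ""), "")[[1]] %in%
                   c("G", "C"))
  expect_lt(abs(obs_gc - 0.4), 0.02)

  empty <- simulate_genome(integer(0))
  expect_equal(nrow(empty), 0)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(empty, f)
  expect_equal(nrow(read_genome_fasta(f)), 0)

  expect_error(simulate_genome(c(500)), class = "ltrcis_error_input")
  expect_error(simulate_genome(10000, gc = 1.2), class = "ltrcis_error_input")
})

test_that("planted elements carry the requested structure", {
  g <- simulate_genome(20000, seed = 3)
  g <- plant_ltr_element(g, "scf_1", 2000, ltr_len = 300,
                         internal_len = 5000, identity = 0.85,
                         tsd_len = 4, domains = "pol", seed = 5)
  tr <- ltr_truth(g)
  expect_equal(tr$end - tr$start + 1L, 5600L)
  expect_equal(tr$n_substitutions, 45L)

  seq <- g$sequence[1]
  ltr5 <- substr(seq, tr$ltr5_start, tr$ltr5_end)
  ltr3 <- substr(seq, tr$ltr3_start, tr$ltr3_end)
  mism <- sum(strsplit(ltr5, "")[[1]] != strsplit(ltr3, "")[[1]])
  expect_equal(mism, 45L)
  # TSD flanks the element identically on both sides
  expect_equal(substr(seq, tr$start - 4, tr$start - 1), tr$tsd_seq)
  expect_equal(substr(seq, tr$end + 1, tr$end + 4), tr$tsd_seq)
})

test_that("identity 1 plants byte-identical LTR copies", {
  g <- simulate_genome(10000, seed = 2)
  g <- plant_ltr_element(g, "scf_1", 1000, ltr_len = 200,
                         internal_len = 2000, identity = 1, seed = 4)
  tr <- ltr_truth(g)
  seq <- g$sequence[1]
  expect_identical(substr(seq, tr$ltr5_start, tr$ltr5_end),
                   substr(seq, tr$ltr3_start, tr$ltr3_end))
})

test_that("planting rejects overruns, overlaps and bad parameters", {
  g <- simulate_genome(10000, seed = 1)
  expect_error(plant_ltr_element(g, "scf_1", 9000, ltr_len = 200,
                                 internal_len = 2000),
               class = "ltrcis_error_input")
  g <- plant_ltr_element(g, "scf_1", 1000, ltr_len = 150,
                         internal_len = 1500, seed = 2)
  expect_error(plant_ltr_element(g, "scf_1", 2000, ltr_len = 150,
                                 internal_len = 1500),
               class = "ltrcis_error_input")
  expect_error(plant_ltr_element(g, "scf_1", 6000, ltr_len = 50,
                                 internal_len = 1000),
               class = "ltrcis_error_input")
  expect_error(plant_ltr_element(g, "scf_1", 6000, tsd_len = 9),
               class = "ltrcis_error_input")
  expect_error(plant_ltr_element(g, "nope", 6000),
               class = "ltrcis_error_input")
})

test_that("gene placements are realised as requested", {
  g <- simulate_genome(c(60000, 60000), seed = 10)
  g <- plant_ltr_element(g, "scf_1", 20000, ltr_len = 200,
                         internal_len = 3000, identity = 0.9, seed = 11)
  el_id <- ltr_truth(g)$element_id
  gm <- simulate_gene_models(g, tibble::tibble(
    type = c("inside", "straddle", "distance", "unlinked"),
    element_id = c(el_id, el_id, el_id, NA),
    distance = c(NA, NA, 15000L, NA),
    side = c(NA, NA, "right", NA),
    scaffold_id = c(NA, NA, NA, "scf_2")
  ))
  tg <- gene_truth(gm)
  expect_equal(nrow(tg), 4)
  expect_equal(tg$realized_distance[tg$type == "distance"], 15000L)

  ex <- dplyr::filter(gm, kind == "exon")
  expect_true(all(!duplicated(unique(gm$gene_id))))
  # exons sorted and non-overlapping within each gene
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, ]
    expect_true(all(diff(e$start) > 0) || nrow(e) == 1)
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }

  # the requested placements drive the classifier as intended
  els <- ltr_truth(g)
  pos <- classify_ltr_position(els, gm)
  expect_true(pos$in_class)
  expect_true(pos$part_class)

  # distance placement lands in the cis output at the requested gap: use a
  # clean Stream element
  g2 <- simulate_genome(250000, seed = 12)
  g2 <- plant_ltr_element(g2, "scf_1", 20000, ltr_len = 200,
                          internal_len = 3000, identity = 0.9, seed = 13)
  gm2 <- simulate_gene_models(g2, tibble::tibble(
    type = "distance", element_id = ltr_truth(g2)$element_id,
    distance = 99000L, side = "right"))
  cis <- find_cis_targets(ltr_truth(g2), gm2)
  expect_equal(nrow(cis), 1)
  expect_equal(cis$distance, 99000L)

  # unsatisfiable placement errors
  expect_error(
    simulate_gene_models(g2, tibble::tibble(
      type = "distance", element_id = ltr_truth(g2)$element_id,
      distance = 400000L, side = "right")),
    class = "ltrcis_error_input")
})

test_that("count simulation recovers planted effects and validates input", {
  features <- tibble::tibble(feature_id = paste0("f", 1:300),
                             length = 1000L)
  design <- make_design(c("CK1", "CK2"), c("NPV1", "NPV2"))
  effects <- tibble::tibble(feature_id = "f1", planted_log2fc = 3,
                            baseline_mean = 500, dispersion = 0.05)
  cts <- simulate_counts(features, design, effects = effects,
                         library_sizes = 1e6, seed = 21)
  cts2 <- simulate_counts(features, design, effects = effects,
                          library_sizes = 1e6, seed = 21)
  expect_identical(cts, cts2)
  f1 <- as.numeric(cts[1, design$sample])
  emp_lfc <- log2(mean(f1[3:4]) / mean(f1[1:2]))
  expect_lt(abs(emp_lfc - 3), 0.5)

  expect_error(simulate_counts(features, design, library_sizes = 0),
               class = "ltrcis_error_input")
  expect_error(simulate_counts(features, design,
                               effects = tibble::tibble(
                                 feature_id = "nope", planted_log2fc = 1)),
               class = "ltrcis_error_input")
  expect_error(simulate_counts(features, design, dispersion = -1),
               class = "ltrcis_error_input")
})

test_that("truth sidecar coordinates always match the emitted sequence", {
  for (seed in 1:5) {
    g <- small_planted_genome(seed)
    tr <- ltr_truth(g)
    for (i in seq_len(nrow(tr))) {
      ltr5 <- substr(g$sequence[1], tr$ltr5_start[i], tr$ltr5_end[i])
      ltr3 <- substr(g$sequence[1], tr$ltr3_start[i], tr$ltr3_end[i])
      ham <- mean(strsplit(ltr5, "")[[1]] == strsplit(ltr3, "")[[1]])
      expect_equal(ham, tr$planted_identity[i], tolerance = 1e-12)
    }
  }
})
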