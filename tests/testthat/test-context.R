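mk_el <- function(id, scaffold, start, end) {
  tibble::tibble(element_id = id, scaffold_id = scaffold,
                 start = as.integer(start), end = as.integer(end))
}
mk_ex <- function(gene, scaffold, start, end) {
  tibble::tibble(gene_id = gene, scaffold_id = scaffold, strand = "+",
                 kind = "exon", start = as.integer(start),
                 end = as.integer(end))
}

test_that("In / Part / Stream follow the exon-containment definitions", {
  el <- mk_el("e1", "s1", 1000, 5999)
  # exon fully inside -> In
  pos <- classify_ltr_position(el, mk_ex("g1", "s1", 2000, 2499))
  expect_true(pos$in_class); expect_false(pos$part_class)
  expect_equal(pos$classes, "In")
  # exon crossing the boundary -> Part
  pos <- classify_ltr_position(el, mk_ex("g1", "s1", 5500, 6499))
  expect_equal(pos$classes, "Part")
  # both kinds of exon -> the In,Part dual class
  gm <- dplyr::bind_rows(mk_ex("g1", "s1", 5500, 6499),
                         mk_ex("g2", "s1", 2000, 2499))
  pos <- classify_ltr_position(el, gm)
  expect_true(pos$in_class && pos$part_class)
  expect_false(pos$stream)
  expect_equal(pos$classes, "In,Part")
  # intron-only overlap is Stream: exons flank the element without touching
  gm <- dplyr::bind_rows(mk_ex("g1", "s1", 100, 400),
                         mk_ex("g1", "s1", 8000, 8400))
  pos <- classify_ltr_position(el, gm)
  expect_true(pos$stream)
  expect_equal(pos$classes, "Stream")
})

test_that("elements on gene-free scaffolds are Stream with the flag set", {
  el <- mk_el(c("e1", "e2"), c("s1", "s2"), c(1000, 1000), c(3000, 3000))
  pos <- classify_ltr_position(el, mk_ex("g1", "s1", 100, 200))
  pos <- dplyr::arrange(pos, element_id)
  expect_equal(pos$no_gene_scaffold, c(FALSE, TRUE))
  expect_true(pos$stream[2])
  # every element gets at least one class and the partition reconciles
  expect_true(all(pos$in_class | pos$part_class | pos$stream))
})

test_that("cis-target window is inclusive at the boundary", {
  el <- mk_el("e1", "s1", 200000, 210000)
  inw <- find_cis_targets(el, mk_ex("g1", "s1", 309001, 309400))
  expect_equal(nrow(inw), 1)
  expect_equal(inw$distance, 99000L)
  expect_equal(inw$side, "downstream")
  at <- find_cis_targets(el, mk_ex("g1", "s1", 310001, 310400))
  expect_equal(at$distance, 100000L)
  out <- find_cis_targets(el, mk_ex("g1", "s1", 310002, 310400))
  expect_equal(nrow(out), 0)
  # abutting exon has distance 0
  ab <- find_cis_targets(el, mk_ex("g1", "s1", 210001, 210400))
  expect_equal(ab$distance, 0L)
  # upstream side, and minimum distance per (element, gene) pair
  gm <- dplyr::bind_rows(mk_ex("g1", "s1", 150000, 150400),
                         mk_ex("g1", "s1", 120000, 120400))
  up <- find_cis_targets(el, gm)
  expect_equal(nrow(up), 1)
  expect_equal(up$distance, 200000L - 150400L - 1L)
  expect_equal(up$side, "upstream")
})

test_that("supplying a non-Stream element is an error", {
  el <- mk_el("e1", "s1", 1000, 5999)
  gm <- mk_ex("g1", "s1", 2000, 2499)
  expect_error(find_cis_targets(el, gm), class = "ltrcis_error_input")
})

test_that("strand never changes membership and the window is monotone", {
  ann <- random_annotation(301)
  pos <- classify_ltr_position(ann$elements, ann$gene_models)
  stream <- dplyr::semi_join(ann$elements,
                             dplyr::filter(pos, stream), by = "element_id")
  flip <- ann$gene_models
  flip$strand <- ifelse(flip$strand == "+", "-", "+")
  a <- find_cis_targets(stream, ann$gene_models, window = 50000)
  b <- find_cis_targets(stream, flip, window = 50000)
  expect_equal(a, b)
  wider <- find_cis_targets(stream, ann$gene_models, window = 80000)
  expect_true(all(paste(a$element_id, a$gene_id) %in%
                    paste(wider$element_id, wider$gene_id)))
})

test_that("classifier and cis finder match the brute-force oracles", {
  for (seed in c(311, 312, 313)) {
    ann <- random_annotation(seed, n_elements = 6, n_genes = 60)
    pos <- classify_ltr_position(ann$elements, ann$gene_models) |>
      dplyr::arrange(element_id)
    orc <- brute_classify(ann$elements, ann$gene_models)
    orc <- orc[order(orc$element_id), ]
    expect_equal(pos$in_class, orc$in_class)
    expect_equal(pos$part_class, orc$part_class)
    expect_equal(pos$stream, orc$stream)

    stream <- dplyr::semi_join(ann$elements, dplyr::filter(pos, stream),
                               by = "element_id")
    cis <- find_cis_targets(stream, ann$gene_models, positions = pos,
                            window = 60000)
    corc <- brute_cis_targets(stream, ann$gene_models, 60000)
    expect_equal(nrow(cis), nrow(corc))
    expect_equal(cis$element_id, corc$element_id)
    expect_equal(cis$gene_id, corc$gene_id)
    expect_equal(cis$distance, as.integer(corc$distance))
  }
})

test_that("CDS/UTR rows stand in when no exon rows exist", {
  el <- mk_el("e1", "s1", 1000, 5999)
  gm <- tibble::tibble(gene_id = "g1", scaffold_id = "s1", strand = "+",
                       kind = c("five_prime_UTR", "CDS"),
                       start = c(2000L, 2100L), end = c(2099L, 2499L))
  pos <- classify_ltr_position(el, gm)
  expect_true(pos$in_class)
})
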