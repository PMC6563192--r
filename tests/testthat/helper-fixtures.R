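# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no fixture data lives on disk.

# A small genome with planted elements whose parameters sit inside narrow
# detector ranges, so the brute-force oracle stays tractable.
small_planted_genome <- function(seed, n_elements = 2, scaffold_len = 6000) {
  g <- simulate_genome(scaffold_len, gc = 0.45, seed = seed)
  positions <- c(800, 3400, 5200)[seq_len(n_elements)]
  idents <- c(0.9, 0.95, 0.88)
  for (i in seq_len(n_elements)) {
    g <- plant_ltr_element(g, g$scaffold_id[1], positions[i],
                           ltr_len = 120, internal_len = 1000,
                           identity = idents[i], tsd_len = 4,
                           domains = if (i == 1) "pol" else character(),
                           seed = seed + i)
  }
  g
}

small_detect_params <- list(min_ltr_len = 100L, max_ltr_len = 150L,
                            min_sep = 800L, max_sep = 1500L,
                            min_identity = 0.80)

detect_small <- function(genome) {
  find_ltr_pairs(genome,
                 min_ltr_len = small_detect_params$min_ltr_len,
                 max_ltr_len = small_detect_params$max_ltr_len,
                 min_sep = small_detect_params$min_sep,
                 max_sep = small_detect_params$max_sep,
                 min_identity = small_detect_params$min_identity)
}

oracle_small <- function(genome) {
  brute_find_ltr_pairs(genome$sequence[1],
                       min_ltr = small_detect_params$min_ltr_len,
                       max_ltr = small_detect_params$max_ltr_len,
                       min_sep = small_detect_params$min_sep,
                       max_sep = small_detect_params$max_sep,
                       min_identity = small_detect_params$min_identity)
}

# Random annotation (elements + genes) for classifier/cis-finder oracle
# equivalence. Gene exons are free to overlap elements.
random_annotation <- function(seed, n_elements = 5, n_genes = 50,
                              scaffold_len = 200000) {
  set.seed(seed)
  scaffolds <- c("sA", "sB")
  el <- tibble::tibble(
    element_id = paste0("el", seq_len(n_elements)),
    scaffold_id = sample(scaffolds, n_elements, replace = TRUE),
    start = sample.int(scaffold_len - 10000, n_elements)
  )
  el$end <- el$start + sample(2000:9000, n_elements, replace = TRUE)
  genes <- lapply(seq_len(n_genes), function(i) {
    sc <- sample(scaffolds, 1)
    ne <- sample(1:4, 1)
    lens <- sample(100:800, ne, replace = TRUE)
    gaps <- sample(50:2000, ne, replace = TRUE)
    anchor <- sample.int(scaffold_len - sum(lens + gaps) - 10, 1)
    starts <- anchor + cumsum(gaps) + cumsum(c(0L, lens[-ne]))
    tibble::tibble(gene_id = paste0("g", i), scaffold_id = sc,
                   strand = sample(c("+", "-"), 1), kind = "exon",
                   start = starts, end = starts + lens - 1L)
  })
  list(elements = el, gene_models = dplyr::bind_rows(genes))
}

random_peptide <- function(n, freq_boost = TRUE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # boost the consensus residues so random peptides actually produce hits
  w <- rep(1, 20)
  if (freq_boost) w[aa %in% c("G", "K", "D")] <- 4
  paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
}
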