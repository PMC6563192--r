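toy_counts <- function() {
  tibble::tibble(
    feature_id = c("a", "b", "c"),
    length = c(1000L, 2000L, 500L),
    CK1 = c(10L, 40L, 0L), CK2 = c(12L, 36L, 0L),
    NPV1 = c(100L, 35L, 0L), NPV2 = c(90L, 50L, 0L))
}
toy_design <- make_design(c("CK1", "CK2"), c("NPV1", "NPV2"))

test_that("FPKM follows the defining formula and its invariances", {
  counts <- tibble::tibble(feature_id = "f", length = 1000L,
                           CK1 = 10L, CK2 = 10L, NPV1 = 10L, NPV2 = 10L)
  fl <- compute_fpkm(counts, toy_design, library_sizes = c(
    CK1 = 1e6, CK2 = 1e6, NPV1 = 1e6, NPV2 = 1e6))
  expect_equal(fl$fpkm, rep(10, 4))

  # doubling every count in one sample leaves that sample's FPKM unchanged
  # when the library size is recomputed from column sums
  c1 <- toy_counts()
  f1 <- compute_fpkm(c1, toy_design)
  c2 <- dplyr::mutate(c1, NPV1 = NPV1 * 2L)
  f2 <- compute_fpkm(c2, toy_design)
  expect_equal(dplyr::filter(f1, sample == "NPV1")$fpkm,
               dplyr::filter(f2, sample == "NPV1")$fpkm)

  expect_equal(dplyr::filter(f1, feature_id == "c")$fpkm, rep(0, 4))
  bad <- dplyr::mutate(c1, CK1 = -1L)
  expect_error(compute_fpkm(bad, toy_design), class = "ltrcis_error_input")
})

test_that("fold changes reproduce the published table arithmetic", {
  expect_equal(fold_change_log2(0.355, 6.095), 4.101735, tolerance = 1e-3)
  expect_equal(fold_change_log2(0.71, 0.001), -9.47168, tolerance = 1e-3)
  expect_equal(fold_change_log2(110.745, 934.43), 3.076845, tolerance = 1e-3)
  expect_equal(fold_change_log2(12.995, 4.155), -1.64504, tolerance = 1e-3)
  expect_equal(fold_change_log2(5, 5), 0)
  # the floor keeps silent features finite
  expect_equal(fold_change_log2(0, 0.001), 0)
  # antisymmetry under group swap
  set.seed(17)
  ck <- runif(50, 0, 20); npv <- runif(50, 0, 20)
  expect_equal(fold_change_log2(ck, npv), -fold_change_log2(npv, ck))
})

test_that("consistency filter matches examples and the order-statistics oracle", {
  mk <- function(ck, npv) {
    tibble::tibble(feature_id = "f",
                   group = rep(c("CK", "NPV"), each = 2),
                   fpkm = c(ck, npv))
  }
  expect_true(consistency_filter(mk(c(1, 2), c(5, 7)))$consistent)
  expect_false(consistency_filter(mk(c(1, 6), c(3, 9)))$consistent)
  expect_true(consistency_filter(mk(c(2, 2), c(2, 2)))$consistent)

  set.seed(23)
  for (i in 1:100) {
    ck <- sample(0:5, 2, TRUE); npv <- sample(0:5, 2, TRUE)
    expect_equal(consistency_filter(mk(ck, npv))$consistent,
                 consistency_oracle(ck, npv),
                 info = paste(c(ck, npv), collapse = ","))
  }
  expect_error(consistency_filter(mk(c(1, 2), c(3, 4))[-1, ]),
               class = "ltrcis_error_input")
})

test_that("identical counts across samples produce zero calls", {
  counts <- tibble::tibble(feature_id = paste0("f", 1:20), length = 1000L,
                           CK1 = 7L, CK2 = 7L, NPV1 = 7L, NPV2 = 7L)
  res <- call_de(counts, toy_design)
  expect_true(all(res$status == "ns"))
  expect_true(all(res$log2fc == 0))
})

test_that("BH-adjusted values are monotone in raw p-value rank", {
  st <- simulate_study(seed = 9)
  res <- call_de(st$counts, st$design)
  tab <- dplyr::arrange(dplyr::filter(tidy(res), !is.na(pvalue)), pvalue)
  expect_true(all(diff(tab$fdr) >= -1e-12))
  expect_true(all(tab$fdr >= tab$pvalue - 1e-12))
})

test_that("planted effects are called at the published thresholds", {
  design <- make_design(c("CK1", "CK2"), c("NPV1", "NPV2"))
  features <- tibble::tibble(feature_id = paste0("f", 1:250),
                             length = 1000L)
  effects <- tibble::tibble(feature_id = paste0("f", 1:50),
                            planted_log2fc = rep(c(2, -2), 25),
                            baseline_mean = 100, dispersion = 0.1)
  counts <- simulate_counts(features, design, effects = effects,
                            baseline_mean = 100, dispersion = 0.1,
                            library_sizes = 1e6, seed = 71)
  res <- call_de(counts, design)
  called <- dplyr::filter(tidy(res), feature_id %in% effects$feature_id)
  recall <- mean(called$status != "ns")
  expect_gte(recall, 0.90)
  # directions agree with the planted sign
  dir_ok <- dplyr::inner_join(called, effects, by = "feature_id") |>
    dplyr::filter(status != "ns") |>
    dplyr::mutate(ok = (status == "up") == (planted_log2fc > 0))
  expect_true(all(dir_ok$ok))
})

test_that("the exact NB test agrees with an established DE package", {
  skip_if_not_installed("edgeR")
  design <- make_design(c("CK1", "CK2"), c("NPV1", "NPV2"))
  features <- tibble::tibble(feature_id = paste0("f", 1:200),
                             length = 1000L)
  effects <- tibble::tibble(feature_id = paste0("f", 1:20),
                            planted_log2fc = rep(c(3, -3), 10),
                            baseline_mean = 200, dispersion = 0.1)
  counts <- simulate_counts(features, design, effects = effects,
                            baseline_mean = 200, dispersion = 0.1,
                            library_sizes = 1e6, seed = 81)
  phi <- 0.1
  mine <- call_de(counts, design, dispersion = phi)
  cmat <- as.matrix(counts[design$sample])
  rownames(cmat) <- counts$feature_id
  y <- edgeR::DGEList(cmat, group = design$group)
  y$samples$norm.factors <- 1
  et <- edgeR::exactTest(y, dispersion = phi)
  ref_p <- et$table$PValue[match(tidy(mine)$feature_id, rownames(et$table))]
  expect_gt(stats::cor(log10(tidy(mine)$pvalue + 1e-300),
                       log10(ref_p + 1e-300)), 0.98)
  same_call <- (tidy(mine)$pvalue < 0.05) == (ref_p < 0.05)
  expect_gte(mean(same_call), 0.95)
})

test_that("zero-count features are excluded from testing and FDR", {
  counts <- toy_counts()
  res <- call_de(counts, toy_design)
  expect_true(is.na(dplyr::filter(tidy(res), feature_id == "c")$pvalue))
  expect_equal(dplyr::filter(tidy(res), feature_id == "c")$status, "ns")
})
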