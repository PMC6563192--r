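#' Build a two-group design table
#'
#' @param control,infected Sample names of the control (CK) and infected
#'   (NPV) replicates.
#' @return A tibble with columns `sample` and `group` (`"CK"` or `"NPV"`).
#' @examples
#' make_design(c("Ap_CK1", "Ap_CK2"), c("Ap_NPV1", "Ap_NPV2"))
#' @export
make_design <- function(control, infected) {
  if (length(control) < 1 || length(infected) < 1) {
    stop_input("both groups need at least one sample")
  }
  tibble(sample = c(control, infected),
         group = rep(c("CK", "NPV"), c(length(control), length(infected))))
}

check_design <- function(design, samples = NULL) {
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design))) {
    stop_input("`design` must have columns `sample` and `group`")
  }
  if (!all(design$group %in% c("CK", "NPV"))) {
    stop_input("`design$group` values must be 'CK' or 'NPV'")
  }
  if (!all(c("CK", "NPV") %in% design$group)) {
    stop_input("`design` must contain both a CK and an NPV group")
  }
  if (!is.null(samples) && !all(design$sample %in% samples)) {
    stop_input("design samples missing from counts: %s",
               join_names(setdiff(design$sample, samples)))
  }
  invisible(design)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Counts for feature *i* in sample *j* are drawn from a negative binomial
#' with mean
#' `baseline_mean_i * (length_i / 1e3) * (library_size_j / 1e6) * 2^lfc_ij`
#' (where `lfc_ij` is the planted log2 fold change for NPV samples and 0 for
#' CK samples) and dispersion `dispersion_i`. `baseline_mean` is therefore
#' the expected CK-group FPKM of the feature.
#'
#' @param features Tibble with columns `feature_id` and `length` (bp).
#' @param design Design tibble from [make_design()] (two groups; the study
#'   design this emulates has two replicates per group).
#' @param effects Optional tibble of planted effects with columns
#'   `feature_id`, `planted_log2fc`, and optionally `baseline_mean` and
#'   `dispersion` overriding the defaults per feature.
#' @param library_sizes Numeric vector of per-sample library sizes (mapped
#'   reads), recycled or named by sample; must be positive.
#' @param baseline_mean,dispersion Defaults for features without an
#'   `effects` row.
#' @param seed Optional integer seed; identical seeds give identical counts.
#' @return A wide count tibble: `feature_id`, `length`, one column per
#'   sample.
#' @export
simulate_counts <- function(features, design, effects = NULL,
                            library_sizes = 1e6, baseline_mean = 50,
                            dispersion = 0.1, seed = NULL) {
  features <- as_tibble(features)
  if (!all(c("feature_id", "length") %in% names(features))) {
    stop_input("`features` needs columns `feature_id` and `length`")
  }
  check_design(design)
  ns <- nrow(design)
  if (is.null(names(library_sizes))) {
    library_sizes <- rep_len(library_sizes, ns)
    names(library_sizes) <- design$sample
  }
  if (!all(design$sample %in% names(library_sizes))) {
    stop_input("`library_sizes` must cover every design sample")
  }
  library_sizes <- library_sizes[design$sample]
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop_input("library sizes must be positive")
  }

  nf <- nrow(features)
  base <- rep_len(baseline_mean, nf)
  disp <- rep_len(dispersion, nf)
  lfc <- rep(0, nf)
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    miss <- setdiff(effects$feature_id, features$feature_id)
    if (length(miss)) {
      stop_input("effects refer to unknown feature id(s): %s",
                 join_names(utils::head(miss, 5)))
    }
    idx <- match(effects$feature_id, features$feature_id)
    lfc[idx] <- effects$planted_log2fc
    if ("baseline_mean" %in% names(effects)) {
      ok <- !is.na(effects$baseline_mean)
      base[idx[ok]] <- effects$baseline_mean[ok]
    }
    if ("dispersion" %in% names(effects)) {
      ok <- !is.na(effects$dispersion)
      disp[idx[ok]] <- effects$dispersion[ok]
    }
  }
  if (any(base <= 0)) stop_input("baseline means must be positive")
  if (any(disp <= 0)) stop_input("dispersions must be positive")

  counts <- with_seed_(seed, {
    vapply(seq_len(ns), function(j) {
      fc <- if (design$group[j] == "NPV") 2^lfc else rep(1, nf)
      mu <- base * (features$length / 1e3) * (library_sizes[j] / 1e6) * fc
      rnbinom(nf, mu = mu, size = 1 / disp)
    }, numeric(nf))
  })
  counts <- matrix(counts, nrow = nf, ncol = ns,
                   dimnames = list(NULL, design$sample))
  bind_cols(features[c("feature_id", "length")], as_tibble(counts))
}
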