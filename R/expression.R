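#' Compute FPKM from a count table
#'
#' `fpkm = count * 1e9 / (feature_length * library_size)`; library sizes
#' default to the column sums of the counts, so doubling every count in a
#' sample leaves that sample's FPKM unchanged.
#'
#' @param counts Wide count tibble: `feature_id`, `length`, one column per
#'   sample (non-negative integers).
#' @param design Design tibble (see [make_design()]).
#' @param library_sizes Optional named per-sample library sizes; defaults
#'   to column sums.
#' @return A long tibble: `feature_id`, `length`, `sample`, `group`,
#'   `count`, `fpkm`.
#' @export
compute_fpkm <- function(counts, design, library_sizes = NULL) {
  counts <- as_tibble(counts)
  if (!all(c("feature_id", "length") %in% names(counts))) {
    stop_input("`counts` needs columns `feature_id` and `length`")
  }
  check_design(design, samples = names(counts))
  if (any(counts$length <= 0)) stop_input("feature lengths must be positive")
  cmat <- as.matrix(counts[design$sample])
  if (any(is.na(cmat)) || any(cmat < 0)) {
    stop_input("counts must be non-negative and complete")
  }
  if (is.null(library_sizes)) {
    library_sizes <- colSums(cmat)
  } else {
    if (is.null(names(library_sizes))) {
      stop_input("`library_sizes` must be named by sample")
    }
    library_sizes <- library_sizes[design$sample]
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop_input("library sizes must be positive")
  }
  counts |>
    select("feature_id", "length") |>
    bind_cols(as_tibble(cmat)) |>
    tidyr::pivot_longer(all_of(design$sample), names_to = "sample",
                        values_to = "count") |>
    left_join(design, by = "sample") |>
    mutate(fpkm = .data$count * 1e9 /
             (.data$length * unname(library_sizes[.data$sample])))
}

#' Log2 fold change from floored group-mean FPKMs
#'
#' `log2fc = log2(max(npv_mean, floor) / max(ck_mean, floor))`. The floor
#' (default 0.001, the smallest FPKM printed in the kind of expression
#' table this reproduces) keeps silent features finite.
#'
#' @param ck_mean,npv_mean Arithmetic means of per-replicate FPKM in the
#'   control (CK) and infected (NPV) groups; vectorised.
#' @param floor FPKM floor.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' fold_change_log2(0.355, 6.095) # about 4.10
#' @export
fold_change_log2 <- function(ck_mean, npv_mean, floor = 0.001) {
  if (any(ck_mean < 0, na.rm = TRUE) || any(npv_mean < 0, na.rm = TRUE)) {
    stop_input("mean FPKMs must be non-negative")
  }
  log2(pmax(npv_mean, floor) / pmax(ck_mean, floor))
}

#' Group mean FPKMs and fold change per feature
#'
#' @param fpkm_long Long FPKM tibble from [compute_fpkm()].
#' @param floor FPKM floor used in the fold change.
#' @return A tibble: `feature_id`, `ck_mean_fpkm`, `npv_mean_fpkm`,
#'   `log2fc`.
#' @export
group_fold_changes <- function(fpkm_long, floor = 0.001) {
  need <- c("feature_id", "group", "fpkm")
  if (!all(need %in% names(fpkm_long))) {
    stop_input("`fpkm_long` needs columns %s", join_names(need))
  }
  if (!all(c("CK", "NPV") %in% fpkm_long$group)) {
    stop_input("both CK and NPV groups are required")
  }
  fpkm_long |>
    group_by(.data$feature_id, .data$group) |>
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_fpkm") |>
    transmute(.data$feature_id,
              ck_mean_fpkm = .data$CK, npv_mean_fpkm = .data$NPV,
              log2fc = fold_change_log2(.data$CK, .data$NPV, floor = floor))
}

#' Replicate-consistency filter
#'
#' A feature is consistent when the infected replicates all lie on the same
#' side of all control replicates (`min(NPV) > max(CK)` or
#' `max(NPV) < min(CK)`), or when all values are equal. Features whose
#' replicates interleave between the groups are flagged inconsistent and
#' excluded from differential calls.
#'
#' @param fpkm_long Long FPKM tibble from [compute_fpkm()].
#' @return A tibble `feature_id`, `consistent` (logical).
#' @export
consistency_filter <- function(fpkm_long) {
  need <- c("feature_id", "group", "fpkm")
  if (!all(need %in% names(fpkm_long))) {
    stop_input("`fpkm_long` needs columns %s", join_names(need))
  }
  counts_per <- fpkm_long |>
    count(.data$feature_id, .data$group) |>
    tidyr::complete(.data$feature_id, group = c("CK", "NPV"),
                    fill = list(n = 0L))
  reps <- range(counts_per$n)
  if (any(is.na(counts_per$group)) || reps[1] < reps[2] || reps[1] == 0) {
    stop_input("every feature needs the full replicate set in both groups")
  }
  fpkm_long |>
    group_by(.data$feature_id) |>
    summarise(
      consistent = {
        ck <- .data$fpkm[.data$group == "CK"]
        npv <- .data$fpkm[.data$group == "NPV"]
        (min(npv) > max(ck)) || (max(npv) < min(ck)) ||
          (max(c(ck, npv)) == min(c(ck, npv)))
      },
      .groups = "drop"
    )
}

# ---- negative-binomial exact test ------------------------------------------

# Method-of-moments common dispersion across features, estimated within
# groups on library-size-adjusted counts and floored at 1e-4 (a 2-vs-2
# design cannot support per-feature dispersion).
estimate_common_dispersion <- function(pseudo, groups) {
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    if (ncol(y) < 2) next
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den <= 0) return(1e-4)
  max(1e-4, num / den)
}

# Exact two-group NB test on library-size-adjusted counts, conditioning on
# the feature's total count: groups sums S_g ~ NB(n_g * mu, phi / n_g);
# the p-value is the probability mass of all splits of the total at most as
# likely as the observed one.
nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  size1 <- n1 / phi
  size2 <- n2 / phi
  a <- 0:t
  la <- dnbinom(a, size = size1, mu = n1 * mu, log = TRUE)
  lb <- dnbinom(t - a, size = size2, mu = n2 * mu, log = TRUE)
  lp <- la + lb
  M <- max(lp)
  p_all <- exp(lp - M)
  p_obs <- p_all[s1 + 1]
  sum(p_all[p_all <= p_obs * (1 + 1e-10)]) / sum(p_all)
}

#' Call differentially expressed features
#'
#' The full differential-expression stage: FPKM, group means, fold change
#' with floor, replicate-consistency filter, per-feature p-value from a
#' two-group negative-binomial exact test on library-size-adjusted counts
#' with a common method-of-moments dispersion, Benjamini-Hochberg FDR over
#' all tested features, and the final call:
#' `up`/`down` requires `|log2fc| > lfc`, `fdr < fdr_threshold` and a
#' consistent replicate pattern; everything else is `ns`. Features with
#' zero counts in every sample are excluded before testing and before the
#' FDR correction.
#'
#' @param counts Wide count tibble (`feature_id`, `length`, sample
#'   columns).
#' @param design Design tibble (see [make_design()]).
#' @param lfc Absolute log2-fold-change threshold (calls require strictly
#'   greater).
#' @param fdr FDR threshold (calls require strictly smaller).
#' @param floor FPKM floor for the fold change.
#' @param library_sizes Optional named library sizes (default: column
#'   sums).
#' @param dispersion Optional fixed common dispersion; default: estimated
#'   by method of moments, floored at 1e-4.
#' @return An `ltr_de` tibble: `feature_id`, `ck_mean_fpkm`,
#'   `npv_mean_fpkm`, `log2fc`, `pvalue`, `fdr`, `status`
#'   (`up`/`down`/`ns`), `consistent`. The estimated dispersion and the
#'   thresholds are stored as attributes.
#' @export
call_de <- function(counts, design, lfc = 1, fdr = 0.05, floor = 0.001,
                    library_sizes = NULL, dispersion = NULL) {
  counts <- as_tibble(counts)
  check_design(design, samples = names(counts))
  fl <- compute_fpkm(counts, design, library_sizes = library_sizes)
  fc <- group_fold_changes(fl, floor = floor)
  cons <- consistency_filter(fl)

  cmat <- as.matrix(counts[design$sample])
  rownames(cmat) <- counts$feature_id
  expressed <- rowSums(cmat) > 0
  tested <- cmat[expressed, , drop = FALSE]
  if (nrow(tested) < 2) {
    inform("fewer than 2 expressed features; FDR equals the raw p-value")
  }

  if (is.null(library_sizes)) {
    libs <- colSums(cmat)
  } else {
    libs <- library_sizes[design$sample]
  }
  common_lib <- exp(mean(log(libs)))
  pseudo <- round(sweep(tested, 2, common_lib / libs, "*"))
  groups <- design$group
  phi <- dispersion %||% estimate_common_dispersion(pseudo, groups)

  n1 <- sum(groups == "CK")
  n2 <- sum(groups == "NPV")
  s1 <- rowSums(pseudo[, groups == "CK", drop = FALSE])
  s2 <- rowSums(pseudo[, groups == "NPV", drop = FALSE])
  pv <- vapply(seq_len(nrow(tested)), function(i) {
    nb_exact_pvalue(s1[i], s2[i], n1, n2, phi)
  }, numeric(1))
  ptab <- tibble(feature_id = rownames(tested), pvalue = pv,
                 fdr = p.adjust(pv, method = "BH"))

  out <- fc |>
    left_join(cons, by = "feature_id") |>
    left_join(ptab, by = "feature_id") |>
    mutate(status = case_when(
      is.na(.data$fdr) ~ "ns",
      !.data$consistent ~ "ns",
      .data$fdr >= .env$fdr ~ "ns",
      .data$log2fc > .env$lfc ~ "up",
      .data$log2fc < -.env$lfc ~ "down",
      TRUE ~ "ns"
    )) |>
    relocate("feature_id", "ck_mean_fpkm", "npv_mean_fpkm", "log2fc",
             "pvalue", "fdr", "status", "consistent")
  attr(out, "dispersion") <- phi
  attr(out, "thresholds") <- c(lfc = lfc, fdr = fdr, floor = floor)
  class(out) <- c("ltr_de", class(out))
  out
}

#' @export
tidy.ltr_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ltr_de")
  attr(out, "dispersion") <- NULL
  attr(out, "thresholds") <- NULL
  as_tibble(out)
}

#' @export
glance.ltr_de <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_consistent = sum(x$consistent, na.rm = TRUE),
    dispersion = attr(x, "dispersion") %||% NA_real_
  )
}

#' Volcano plot of a differential-expression result
#'
#' @param object An `ltr_de` table from [call_de()].
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 FDR, calls
#'   coloured by direction.
#' @export
autoplot.ltr_de <- function(object, ...) {
  th <- attr(object, "thresholds") %||% c(lfc = 1, fdr = 0.05)
  df <- filter(tidy(object), !is.na(.data$fdr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-th[["lfc"]], th[["lfc"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(th[["fdr"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (NPV / CK)", y = "-log10 FDR",
                  colour = "call") +
    ggplot2::theme_minimal()
}
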