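#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' random draw of `n` genes from a universe of `N` (of which `K` carry the
#' term) contains at least `k` carriers.
#'
#' @param k Observed carriers among the targets.
#' @param K Carriers in the universe.
#' @param n Target-set size.
#' @param N Universe size.
#' @return Probability in `(0, 1]`; vectorised over its arguments.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  ok <- k >= 0 & n >= 0 & k <= n & n <= N & k <= K & K <= N
  if (any(!ok | is.na(ok))) {
    stop_input("inconsistent counts: need 0 <= k <= n <= N and k <= K <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Term over-representation among target genes
#'
#' One hypergeometric upper-tail test per term with at least one target
#' member, against a user-supplied universe. Following the significance
#' criterion this reproduces, the raw p-value is compared with `alpha` by
#' default; Benjamini-Hochberg adjustment is available but off by default.
#'
#' @param target_genes Character vector of target gene ids (must all be in
#'   `universe`).
#' @param term_map Tibble with columns `term_id`, `gene_id` and optionally
#'   `term_name`.
#' @param universe Character vector of universe gene ids (e.g. all
#'   annotated genes).
#' @param alpha Significance level.
#' @param adjust Apply BH adjustment before the significance call.
#' @return An `ltr_enrichment` tibble sorted by p-value: `term_id`,
#'   (`term_name`,) `k`, `K`, `n`, `N`, `pvalue`, (`fdr`,) `significant`.
#' @export
enrich_terms <- function(target_genes, term_map, universe, alpha = 0.05,
                         adjust = FALSE) {
  target_genes <- unique(as.character(target_genes))
  universe <- unique(as.character(universe))
  missing <- setdiff(target_genes, universe)
  if (length(missing)) {
    stop_input("target gene(s) absent from universe: %s",
               join_names(utils::head(missing, 10)))
  }
  term_map <- as_tibble(term_map)
  if (!all(c("term_id", "gene_id") %in% names(term_map))) {
    stop_input("`term_map` needs columns `term_id` and `gene_id`")
  }
  term_map <- filter(term_map, .data$gene_id %in% universe)
  n <- length(target_genes)
  N <- length(universe)

  res <- term_map |>
    group_by(.data$term_id) |>
    summarise(
      term_name = if ("term_name" %in% names(term_map))
        first(.data$term_name) else NA_character_,
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, target_genes)),
      .groups = "drop"
    ) |>
    filter(.data$k >= 1) |>
    mutate(n = n, N = N,
           pvalue = hypergeom_upper_tail(.data$k, .data$K, n, N)) |>
    arrange(.data$pvalue, .data$term_id)
  if (adjust) {
    res <- mutate(res, fdr = p.adjust(.data$pvalue, method = "BH"),
                  significant = .data$fdr < alpha)
  } else {
    res <- mutate(res, significant = .data$pvalue < alpha)
  }
  class(res) <- c("ltr_enrichment", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' @export
tidy.ltr_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ltr_enrichment")
  as_tibble(out)
}

#' @export
glance.ltr_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha") %||% NA_real_)
}

#' Dot plot of term enrichment
#'
#' @param object An `ltr_enrichment` result.
#' @param top Number of top terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltr_enrichment <- function(object, top = 20, ...) {
  df <- utils::head(tidy(object), top) |>
    mutate(label = coalesce(.data$term_name, .data$term_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$pvalue),
    y = stats::reorder(.data$label, -.data$pvalue),
    size = .data$k, colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "target hits",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
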