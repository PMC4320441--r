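# Pathway over-representation of the overlap-filtered gene list.

#' One-sided Fisher's exact (hypergeometric upper-tail) p-value
#'
#' The probability of drawing at least `k` pathway genes when `n` query
#' genes are sampled without replacement from a universe of `N` genes of
#' which `K` belong to the pathway: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Computed through the hypergeometric tail
#' in `stats::phyper`, which works in log space internally, so small tails
#' are stable.
#'
#' @param k Query genes inside the pathway.
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail p-value (vectorised over its arguments).
#' @export
#' @examples
#' fisher_p(5, 5, 5, 10)  # 1/choose(10, 5)
fisher_p <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 1 & k <= pmin(K, n) & K <= N & n <= N &
    k >= pmax(0, K + n - N)
  if (any(!ok)) {
    stop("count constraints violated: need k <= min(K, n), K <= N, n <= N, ",
         "k >= max(0, K + n - N)", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway enrichment of a query gene list
#'
#' Scores every pathway by the one-sided Fisher's exact test of its overlap
#' with the query, after intersecting pathway membership with the universe.
#' Gene symbols are matched case-insensitively. Query genes outside the
#' universe are dropped with a warning. Results are sorted by ascending
#' p-value, ties broken by descending overlap `k` and then by pathway id;
#' the "most affected" pathway is the first row.
#'
#' No multiple-testing correction is applied by default (the significance
#' rule is the plain `p <= p_threshold`); Benjamini-Hochberg adjustment is
#' available with `p_adjust = "BH"`, in which case significance is judged on
#' the adjusted value.
#'
#' @param pathways Long pathway tibble from [read_gmt()].
#' @param query_genes Character vector of query gene symbols.
#' @param universe Character vector of background gene symbols (typically
#'   all genes with GO annotations).
#' @param p_threshold Significance threshold; default 0.01.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `splice_enrichment` with columns `pathway_id`,
#'   `name`, `k`, `K`, `n`, `N`, `p_value`, (`p_adjusted`,) `significant`,
#'   `query_members`.
#' @export
enrich_pathways <- function(pathways, query_genes, universe,
                            p_threshold = 0.01, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  query <- unique(norm_symbol(query_genes))
  query <- query[nzchar(query)]
  uni <- unique(norm_symbol(universe))
  uni <- uni[nzchar(uni)]
  if (length(uni) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query gene list", call. = FALSE)
  outside <- setdiff(query, uni)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "", call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("no query genes remain within the universe", call. = FALSE)

  ids <- unique(pathways$pathway_id)
  res <- purrr::map_dfr(ids, function(id) {
    p <- pathways[pathways$pathway_id == id, , drop = FALSE]
    members <- intersect(unique(p$gene_key), uni)
    hits <- intersect(members, query)
    tibble::tibble(
      pathway_id = id, name = p$name[1],
      k = length(hits), K = length(members),
      n = length(query), N = length(uni),
      p_value = fisher_p(length(hits), length(members), length(query), length(uni)),
      query_members = paste(sort(hits), collapse = ",")
    )
  })
  if (p_adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted <= p_threshold
  } else {
    res$significant <- res$p_value <= p_threshold
  }
  res <- dplyr::arrange(res, .data$p_value, dplyr::desc(.data$k), .data$pathway_id)
  res <- res[, c(setdiff(names(res), "query_members"), "query_members")]
  structure(res, class = c("splice_enrichment", class(tibble::tibble()))) |>
    add_enrich_attrs(p_threshold, p_adjust)
}

add_enrich_attrs <- function(x, p_threshold, p_adjust) {
  attr(x, "p_threshold") <- p_threshold
  attr(x, "p_adjust") <- p_adjust
  x
}

#' @export
tidy.splice_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @export
glance.splice_enrichment <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    n_significant = sum(x$significant),
    p_threshold = attr(x, "p_threshold"),
    p_adjust = attr(x, "p_adjust"),
    top_pathway = if (nrow(x)) x$pathway_id[1] else NA_character_,
    top_p_value = if (nrow(x)) x$p_value[1] else NA_real_
  )
}

#' Enrichment dot plot
#'
#' `-log10(p)` for the top pathways, most significant first.
#'
#' @param object A `splice_enrichment` tibble.
#' @param top Number of pathways to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_enrichment <- function(object, top = 15, ...) {
  df <- head(tibble::as_tibble(unclass(object)), top)
  df$pathway_id <- factor(df$pathway_id, levels = rev(df$pathway_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$pathway_id,
                                   colour = .data$significant,
                                   size = .data$k)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "p_threshold")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  colour = "significant", size = "overlap k") +
    ggplot2::theme_minimal()
}
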