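test_that("fisher_p reproduces exact enumeration values", {
  expect_equal(fisher_p(0, 5, 5, 10), 1)
  expect_equal(fisher_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(fisher_p(5, 5, 5, 10), oracle_hyper_p(5, 5, 5, 10))
  expect_equal(fisher_p(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_p(2, 2, 2, 4), oracle_hyper_p(2, 2, 2, 4))
})

test_that("fisher_p rejects impossible count configurations", {
  expect_error(fisher_p(6, 5, 5, 10), "constraints")
  expect_error(fisher_p(2, 5, 5, 4), "constraints")
  expect_error(fisher_p(0, 3, 4, 5), "constraints")  # k < K + n - N
})

test_that("p_value decreases as the overlap grows", {
  p <- fisher_p(0:10, 15, 10, 100)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a planted pathway ranks first and clears the threshold", {
  withr::local_seed(3)
  universe <- sprintf("G%03d", 1:500)
  query <- sprintf("G%03d", 1:10)
  planted <- c(query[1:8], sprintf("G%03d", 101:107))   # 8 of 15 from the query
  pw <- dplyr::bind_rows(
    tibble::tibble(pathway_id = "PLANTED", name = "planted", gene_symbol = planted),
    purrr::map_dfr(1:5, function(i) {
      tibble::tibble(pathway_id = sprintf("BG%02d", i), name = "bg",
                     gene_symbol = sample(universe, 15))
    })
  )
  pw$gene_key <- toupper(pw$gene_symbol)
  res <- enrich_pathways(pw, query, universe)
  expect_s3_class(res, "splice_enrichment")
  expect_equal(nrow(res), 6L)
  expect_equal(res$pathway_id[1], "PLANTED")
  expect_lte(res$p_value[1], 0.01)
  expect_true(res$significant[1])
  expect_equal(res$k[1], 8L)
  expect_equal(res$p_value[1], oracle_hyper_p(8, 15, 10, 500), tolerance = 1e-12)
})

test_that("everything-is-everything carries no enrichment signal", {
  pw <- tibble::tibble(pathway_id = "P1", name = "all", gene_symbol = c("A", "B"),
                       gene_key = c("A", "B"))
  res <- enrich_pathways(pw, c("A", "B"), c("A", "B"))
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("ties are broken by larger overlap, then pathway id", {
  universe <- sprintf("G%02d", 1:20)
  # two pathways with k = K (all members in the query) but different sizes
  pw <- dplyr::bind_rows(
    tibble::tibble(pathway_id = "B", name = "b", gene_symbol = universe[1:4]),
    tibble::tibble(pathway_id = "A", name = "a", gene_symbol = universe[1:4]))
  pw$gene_key <- pw$gene_symbol
  res <- enrich_pathways(pw, universe[1:6], universe)
  expect_equal(res$p_value[1], res$p_value[2])
  expect_equal(res$pathway_id, c("A", "B"))  # same k: id breaks the tie
})

test_that("symbols match case-insensitively and strays are dropped", {
  pw <- tibble::tibble(pathway_id = "P1", name = "p", gene_symbol = c("Egfr", "mTor"),
                       gene_key = c("EGFR", "MTOR"))
  expect_warning(
    res <- enrich_pathways(pw, c("EGFR", "NotAGene"), c("egfr", "mtor", "akt1")),
    "outside the universe")
  expect_equal(res$k, 1L)
  expect_equal(res$K, 2L)
  expect_equal(res$n, 1L)
  expect_error(suppressWarnings(enrich_pathways(pw, "NotAGene", c("egfr"))),
               "remain")
  expect_error(enrich_pathways(pw, character(0), c("egfr")), "empty query")
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  universe <- sprintf("G%03d", 1:100)
  pw <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(pathway_id = sprintf("P%d", i), name = "p",
                   gene_symbol = universe[seq(i, i + 9)])
  })
  pw$gene_key <- pw$gene_symbol
  res <- enrich_pathways(pw, universe[1:10], universe, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(res))
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  expect_equal(res$significant, res$p_adjusted <= 0.01)
})

test_that("tidy and glance summarise enrichment results", {
  pw <- tibble::tibble(pathway_id = "P1", name = "p", gene_symbol = c("A", "B"),
                       gene_key = c("A", "B"))
  res <- enrich_pathways(pw, "A", c("A", "B", "C"))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_pathways, 1L)
  expect_equal(g$top_pathway, "P1")
})
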