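mk_dom <- function(res_start, res_end, description = "some domain") {
  tibble::tibble(protein_key = "t1", accession = sprintf("D%02d", seq_along(res_start)),
                 name = "dom", description = description,
                 res_start = as.integer(res_start), res_end = as.integer(res_end))
}

# a diff row for an inclusion protein of length L with altered block [bs, be)
# and the given exclusion-side altered length
mk_diff <- function(L, bs, be, altered_excl = 0L) {
  Lx <- L - (be - bs) + altered_excl
  tibble::tibble(
    len_incl = as.integer(L), len_excl = as.integer(Lx),
    prefix_len = as.integer(bs), suffix_len = as.integer(L - be),
    altered_incl = as.integer(be - bs), altered_excl = as.integer(altered_excl),
    n_altered = max(be - bs, altered_excl),
    frac_altered = max(be - bs, altered_excl) / max(L, Lx),
    protein_changed = (be - bs) > 0 || altered_excl > 0)
}

test_that("domains away from the altered block stay intact (C-terminal event)", {
  ci <- classify_impact(mk_dom(9, 49), mk_diff(80, 59, 70))
  expect_equal(ci$statuses$status, "intact")
  expect_false(ci$domain_changed)
  expect_equal(ci$affected_region, "c_term")
})

test_that("a truncation ending inside a domain marks it truncated", {
  # exclusion protein ends at residue 30; domain [9, 49)
  ci <- classify_impact(mk_dom(9, 49), mk_diff(80, 30, 80))
  expect_equal(ci$statuses$status, "truncated")
  expect_true(ci$domain_changed)
  expect_equal(ci$affected_region, "domain")
})

test_that("lost, internally altered and frameshift cases classify correctly", {
  # domain wholly inside the removed block
  expect_equal(classify_impact(mk_dom(20, 30), mk_diff(80, 15, 40))$statuses$status,
               "lost")
  # block clips one end of the domain
  expect_equal(classify_impact(mk_dom(10, 30), mk_diff(80, 25, 40))$statuses$status,
               "internally_altered")
  # frameshift-divergent tail entering a domain is internal alteration,
  # not truncation
  expect_equal(classify_impact(mk_dom(9, 49), mk_diff(80, 30, 80, altered_excl = 12L)
                               )$statuses$status,
               "internally_altered")
})

test_that("positional classes cover zero-domain and flanking alterations", {
  no_dom <- mk_dom(integer(0), integer(0))
  expect_equal(classify_impact(no_dom, mk_diff(80, 0, 10))$affected_region, "n_term")
  expect_equal(classify_impact(no_dom, mk_diff(80, 70, 80))$affected_region, "c_term")
  expect_equal(classify_impact(no_dom, mk_diff(80, 30, 40))$affected_region, "linker")
  expect_equal(classify_impact(no_dom, mk_diff(80, 30, 30))$affected_region, "none")
  # alteration before the first domain
  expect_equal(classify_impact(mk_dom(40, 60), mk_diff(80, 5, 20))$affected_region,
               "n_term")
  # between two domains
  expect_equal(classify_impact(mk_dom(c(5, 60), c(15, 70)),
                               mk_diff(80, 30, 40))$affected_region, "linker")
  # unchanged protein
  expect_equal(classify_impact(mk_dom(5, 15), mk_diff(80, 0, 0))$affected_region,
               "none")
})

test_that("out-of-bounds domains are rejected", {
  expect_error(classify_impact(mk_dom(70, 95), mk_diff(80, 0, 10)), "bounds")
})

test_that("interval statuses equal the per-residue oracle on random pairs", {
  withr::local_seed(13)
  for (rep in 1:200) {
    L <- sample(30:120, 1)
    aa <- sample(AA20, L, replace = TRUE)
    incl <- paste(aa, collapse = "")
    kind <- sample(c("identical", "delete", "replace", "truncate", "extend",
                     "empty"), 1)
    excl <- switch(kind,
      identical = incl,
      delete = {
        k <- sample(1:(L - 2), 1); s0 <- sample(0:(L - k - 1), 1)
        paste(aa[-seq.int(s0 + 1, s0 + k)], collapse = "")
      },
      replace = {
        k <- sample(1:(L - 2), 1); s0 <- sample(0:(L - k - 1), 1)
        k2 <- sample(1:15, 1)
        paste(c(aa[seq_len(s0)], sample(AA20, k2, replace = TRUE),
                aa[seq.int(s0 + k + 1, L)]), collapse = "")
      },
      truncate = paste(aa[seq_len(sample(1:(L - 1), 1))], collapse = ""),
      extend = paste(c(aa, sample(AA20, sample(1:10, 1), replace = TRUE)),
                     collapse = ""),
      empty = "")
    d <- diff_proteins(incl, excl)
    n_dom <- sample(1:3, 1)
    ds <- sort(sample(0:(L - 5), n_dom))
    de <- pmin(L, ds + sample(3:20, n_dom, replace = TRUE))
    keep <- de > ds
    doms <- mk_dom(ds[keep], de[keep])
    got <- classify_impact(doms, d)$statuses$status
    want <- vapply(seq_len(nrow(doms)), function(i) {
      oracle_domain_status(incl, excl, doms$res_start[i], doms$res_end[i])
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("enlarging the altered block never rescues a changed domain", {
  withr::local_seed(14)
  for (rep in 1:50) {
    L <- 100L
    bs <- sample(10:60, 1); be <- bs + sample(5:30, 1)
    d1 <- mk_diff(L, bs, be)
    d2 <- mk_diff(L, bs - sample(0:5, 1), min(L, be + sample(0:5, 1)))
    ds <- sample(0:90, 1); de <- min(L, ds + sample(4:20, 1))
    dom <- mk_dom(ds, de)
    s1 <- classify_impact(dom, d1)$statuses$status
    s2 <- classify_impact(dom, d2)$statuses$status
    if (s1 != "intact") expect_true(s2 != "intact")
  }
})
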