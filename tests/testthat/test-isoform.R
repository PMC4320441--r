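test_that("exon skipping removes exactly the skipped exon", {
  tg <- toy_gene()
  ev <- make_event("chrT", 50, 80, "+", "skipped_exon", host = "txA.1")
  pair <- build_pair(tg$tx, ev)
  ex_excl <- pair$exclusion[pair$exclusion$type == "exon", ]
  expect_equal(ex_excl$start, c(0L, 100L))
  expect_equal(ex_excl$end, c(30L, 160L))
  ex_incl <- pair$inclusion[pair$inclusion$type == "exon", ]
  expect_equal(nrow(ex_incl), 3L)
  expect_equal(classify_region(pair), "coding")
})

test_that("alternative splice sites trim sub-exon regions, not whole exons", {
  tg <- toy_gene()
  # remove the last 3 codons of exon 2 (donor-side region)
  ev <- make_event("chrT", 71, 80, "+", "alt_5ss", host = "txA.1")
  pair <- build_pair(tg$tx, ev)
  ex <- pair$exclusion[pair$exclusion$type == "exon", ]
  expect_equal(ex$start, c(0L, 50L, 100L))
  expect_equal(ex$end, c(30L, 71L, 160L))
})

test_that("intron retention merges flanking exons and validates the region", {
  tg <- toy_gene()
  ev <- make_event("chrT", 30, 50, "+", "intron_retention", host = "txA.1")
  pair <- build_pair(tg$tx, ev)
  ex <- pair$inclusion[pair$inclusion$type == "exon", ]
  expect_equal(ex$start, c(0L, 100L))
  expect_equal(ex$end, c(80L, 160L))
  expect_equal(nrow(pair$exclusion[pair$exclusion$type == "exon", ]), 3L)

  bad <- make_event("chrT", 32, 48, "+", "intron_retention", host = "txA.1")
  expect_error(build_pair(tg$tx, bad), "exactly span")
})

test_that("region/strand preconditions are enforced", {
  tg <- toy_gene()
  intronic <- make_event("chrT", 31, 49, "+", "skipped_exon", host = "txA.1")
  expect_error(build_pair(tg$tx, intronic), "does not overlap")
  wrong_strand <- make_event("chrT", 50, 80, "-", "skipped_exon", host = "txA.1")
  expect_error(build_pair(tg$tx, wrong_strand), "strand")
})

test_that("alt_promoter and alt_polyA drop flanking exonic sequence", {
  tg <- toy_gene()
  # promoter event on exon 1: exclusion keeps only downstream exons
  ev <- make_event("chrT", 0, 30, "+", "alt_promoter", host = "txA.1")
  pair <- build_pair(tg$tx, ev)
  ex <- pair$exclusion[pair$exclusion$type == "exon", ]
  expect_equal(ex$start, c(50L, 100L))
  # polyA region inside exon 3: everything from the region on is dropped
  ev2 <- make_event("chrT", 112, 124, "+", "alt_polyA", host = "txA.1")
  pair2 <- build_pair(tg$tx, ev2)
  ex2 <- pair2$exclusion[pair2$exclusion$type == "exon", ]
  expect_equal(ex2$end, c(30L, 80L, 112L))
  # on the mirrored gene the same events give mirrored exclusions
  mg <- mirror_gene(tg$tx, tg$genome)
  mev2 <- mirror_event(ev2, tg$genome)
  pair3 <- build_pair(mg$tx, mev2)
  glen <- nchar(tg$genome[["chrT"]])
  ex3 <- pair3$exclusion[pair3$exclusion$type == "exon", ]
  expect_equal(sort(glen - ex3$start), sort(ex2$end))
})

test_that("complex events require and use an explicit partner transcript", {
  tg <- toy_gene()
  tx2 <- make_tx_tbl("txA.2", "chrT", "+",
                     data.frame(start = c(0, 100), end = c(30, 160)),
                     data.frame(start = c(12, 100), end = c(30, 124)))
  txs <- dplyr::bind_rows(tg$tx, tx2)
  ev <- make_event("chrT", 50, 80, "+", "complex", host = "txA.1")
  expect_error(build_pair(txs, ev), "partner_transcript_id")
  ev$partner_transcript_id <- "txA.2"
  pair <- build_pair(txs, ev)
  expect_equal(pair$exclusion$transcript_id[1], "txA.2")
})

test_that("region classification distinguishes coding, UTR and mixed", {
  tg <- toy_gene()
  coding <- build_pair(tg$tx, make_event("chrT", 50, 80, "+", "skipped_exon",
                                         host = "txA.1"))
  expect_equal(classify_region(coding), "coding")
  utr <- build_pair(tg$tx, make_event("chrT", 130, 160, "+", "alt_polyA",
                                      host = "txA.1"))
  expect_equal(classify_region(utr), "utr_only")
  mixed <- build_pair(tg$tx, make_event("chrT", 118, 140, "+", "alt_polyA",
                                        host = "txA.1"))
  expect_equal(classify_region(mixed), "mixed")
  # no CDS -> not_determined
  nc <- make_tx_tbl("txNC", "chrT", "+", data.frame(start = 0, end = 30))
  ev <- make_event("chrT", 0, 10, "+", "skipped_exon", host = "txNC")
  expect_equal(classify_region(build_pair(nc, ev)), "not_determined")
})

test_that("host fallback picks the longest CDS, ties broken lexicographically", {
  short <- make_tx_tbl("txB", "chrT", "+", data.frame(start = 0, end = 30),
                       data.frame(start = 12, end = 24))
  tg <- toy_gene()
  txs <- dplyr::bind_rows(tg$tx, short)
  ev <- make_event("chrT", 50, 80, "+", "skipped_exon", host = "")
  expect_equal(pick_host_transcript(txs, ev), "txA.1")
  # equal CDS lengths: lexicographically smallest id wins
  twin <- tg$tx
  twin$transcript_id <- "txA.0"
  expect_equal(pick_host_transcript(dplyr::bind_rows(tg$tx, twin), ev), "txA.0")
})

test_that("inclusion and exclusion exon unions differ exactly by the region", {
  fx <- shared_fixture()
  tx <- read_transcripts(fx$paths$transcripts)
  ev <- read_events(fx$paths$events)
  internal <- ev[ev$event_class %in% c("skipped_exon", "alt_5ss", "alt_3ss"), ]
  for (i in seq_len(nrow(internal))) {
    e <- internal[i, ]
    pair <- build_pair(tx, e)
    ex_in <- pair$inclusion[pair$inclusion$type == "exon", ]
    ex_ex <- pair$exclusion[pair$exclusion$type == "exon", ]
    gained <- spliceimpact:::iv_subtract(
      spliceimpact:::iv(ex_in$start, ex_in$end),
      spliceimpact:::iv(ex_ex$start, ex_ex$end))
    expect_equal(gained$start, e$start)
    expect_equal(gained$end, e$end)
  }
})

test_that("building on the mirrored gene yields the same protein", {
  tg <- toy_gene()
  ev <- make_event("chrT", 50, 80, "+", "skipped_exon", host = "txA.1")
  pair <- build_pair(tg$tx, ev)
  p1 <- translate_transcript(pair$exclusion, tg$genome)
  mg <- mirror_gene(tg$tx, tg$genome)
  mev <- mirror_event(ev, tg$genome)
  mpair <- build_pair(mg$tx, mev)
  p2 <- translate_transcript(mpair$exclusion, mg$genome)
  expect_identical(p1$sequence, p2$sequence)
  expect_gt(nchar(p1$sequence), 0)
})
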