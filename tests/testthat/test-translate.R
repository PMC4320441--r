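test_that("a simple CDS translates to the expected peptide", {
  tx <- make_tx_tbl("t1", "c1", "+", data.frame(start = 0, end = 9),
                    data.frame(start = 0, end = 9))
  p <- translate_transcript(tx, c(c1 = "ATGGAATAA"))
  expect_equal(p$sequence, "ME")
  expect_equal(p$coding_status, "coding")
  expect_true(p$stop_found)
})

test_that("minus-strand transcripts translate their reverse complement", {
  g <- c(c1 = oracle_revcomp("ATGGAATAA"))
  tx <- make_tx_tbl("t1", "c1", "-", data.frame(start = 0, end = 9),
                    data.frame(start = 0, end = 9))
  expect_equal(translate_transcript(tx, g)$sequence, "ME")
})

test_that("a one-nucleotide deletion frameshifts into a divergent tail", {
  # full gene: ATG AAA CCC GGG TTT TAG -> MKPGF
  g <- c(c1 = "ATGAAACCCGGGTTTTAGCCCTAACC")
  full <- make_tx_tbl("t1", "c1", "+", data.frame(start = 0, end = 26),
                      data.frame(start = 0, end = 18))
  expect_equal(translate_transcript(full, g)$sequence, "MKPGF")
  # removing genomic base 4 shifts the frame; the tail reads into the old UTR
  shifted <- make_tx_tbl("t2", "c1", "+",
                         data.frame(start = c(0, 5), end = c(4, 26)),
                         data.frame(start = c(0, 5), end = c(4, 18)))
  p <- translate_transcript(shifted, g)
  expect_equal(p$sequence, "MNPGFSPN")
  expect_false(p$stop_found)
  d <- diff_proteins("MKPGF", p$sequence)
  expect_equal(d$prefix_len, 1L)
  expect_equal(d$suffix_len, 0L)
  expect_equal(d$n_altered, 7L)
})

test_that("unknown nucleotides translate to X with a warning", {
  tx <- make_tx_tbl("t1", "c1", "+", data.frame(start = 0, end = 9),
                    data.frame(start = 0, end = 9))
  expect_warning(p <- translate_transcript(tx, c(c1 = "ATGGANTAA")), "X")
  expect_equal(p$sequence, "MX")
})

test_that("a removed start codon triggers a rescan for a viable AUG", {
  # mRNA: 6 junk nt, then ATG opening a 33-codon ORF
  orf <- paste(rep("GAA", 32), collapse = "")
  g <- c(c1 = paste0("CCTCCT", "ATG", orf, "TAACCC"))
  # CDS anchor points outside the exon (as after removing the start exon)
  tx <- tibble::tibble(
    transcript_id = "t1", gene_id = "g", gene_symbol = "G", chrom = "c1",
    strand = "+", type = c("exon", "CDS"),
    start = c(0L, 300L), end = c(nchar(g[["c1"]]), 303L), has_cds = TRUE)
  p <- suppressWarnings(translate_transcript(tx, g))
  expect_true(p$start_rescanned)
  expect_equal(p$sequence, paste0("M", strrep("E", 32)))

  # ORF below 30 codons and no other AUG -> non-coding
  g2 <- c(c1 = paste0("CCTCCT", "ATG", paste(rep("GAA", 10), collapse = ""),
                      "TAACCCTTTCCCTTTCCC"))
  tx2 <- tx
  tx2$end[1] <- nchar(g2[["c1"]])
  p2 <- translate_transcript(tx2, g2)
  expect_equal(p2$coding_status, "non_coding")
  expect_equal(p2$sequence, "")
})

test_that("stops far upstream of the last junction raise the NMD flag", {
  ex1 <- paste0("ATGTAA", rand_dna(60))
  g <- c(c1 = paste0(ex1, rand_dna(34), "CCTTCCTTCCTTCCTTCCTTCCTTCCTTCC"))
  tx <- make_tx_tbl("t1", "c1", "+",
                    data.frame(start = c(0, 100), end = c(66, 130)),
                    data.frame(start = 0, end = 6))
  p <- translate_transcript(tx, g)
  expect_equal(p$sequence, "M")
  expect_equal(p$coding_status, "premature_stop_flagged")
  # a stop within 50 nt of the junction (or in the last exon) is not flagged
  g2 <- c(c1 = paste0("ATG", strrep("GAA", 20), "TT",
                      substr(g[["c1"]], 66, nchar(g[["c1"]]))))
  tx2 <- make_tx_tbl("t1", "c1", "+",
                     data.frame(start = c(0, 100), end = c(65, 130)),
                     data.frame(start = 0, end = 63))
  p2 <- translate_transcript(tx2, g2)
  expect_true(p2$coding_status %in% c("coding", "non_coding"))
})

test_that("translation matches the brute-force oracle on random transcripts", {
  withr::local_seed(31)
  for (rep in 1:30) {
    n_ex <- sample(1:4, 1)
    ex_len <- sample(30:90, n_ex, replace = TRUE)
    mrna <- rand_dna(sum(ex_len))
    p0 <- sample(0:(sum(ex_len) - 25), 1)
    substr(mrna, p0 + 1, p0 + 3) <- "ATG"
    # scatter the mRNA over exons with random introns
    starts <- integer(n_ex); ends <- integer(n_ex)
    gseq <- rand_dna(20); off <- 0L
    for (i in seq_len(n_ex)) {
      starts[i] <- nchar(gseq)
      piece <- substr(mrna, off + 1, off + ex_len[i])
      gseq <- paste0(gseq, piece, rand_dna(25))
      ends[i] <- starts[i] + ex_len[i]
      off <- off + ex_len[i]
    }
    # CDS rows: the part of each exon at/after the start position
    cum <- cumsum(ex_len) - ex_len
    cds <- NULL
    for (i in seq_len(n_ex)) {
      a <- max(p0, cum[i]); b <- cum[i] + ex_len[i]
      if (a < b) cds <- rbind(cds, data.frame(start = starts[i] + (a - cum[i]),
                                              end = ends[i]))
    }
    tx <- make_tx_tbl("t1", "c1", "+", data.frame(start = starts, end = ends), cds)
    g <- c(c1 = gseq)
    got <- suppressWarnings(translate_transcript(tx, g)$sequence)
    want <- oracle_translate(oracle_mrna(gseq, starts, ends, "+"), p0)
    expect_identical(got, want)
    # and the mirrored minus-strand version
    mg <- mirror_gene(tx, g)
    got2 <- suppressWarnings(translate_transcript(mg$tx, mg$genome)$sequence)
    expect_identical(got2, want)
  }
})
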