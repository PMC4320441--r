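# In-code fixture builders shared across test files.

make_tx_tbl <- function(transcript_id, chrom, strand, exons, cds = NULL,
                        gene_id = "g1", gene_symbol = "GeneA") {
  rows <- data.frame(type = "exon", start = exons$start, end = exons$end)
  if (!is.null(cds) && nrow(cds) > 0) {
    rows <- rbind(rows, data.frame(type = "CDS", start = cds$start, end = cds$end))
  }
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, gene_symbol = gene_symbol,
    chrom = chrom, strand = strand, type = rows$type,
    start = as.integer(rows$start), end = as.integer(rows$end),
    has_cds = !is.null(cds) && nrow(cds) > 0
  )
}

make_event <- function(chrom, start, end, strand, event_class,
                       host = "", partner = "", gene_symbol = "GeneA",
                       probeset_id = "ps1") {
  tibble::tibble(
    probeset_id = probeset_id, gene_symbol = gene_symbol, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    event_class = event_class, host_transcript_id = host,
    partner_transcript_id = partner, SI = 1.5, FC = 2.0
  )
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A toy plus-strand three-exon gene used throughout the isoform tests:
#   exon1 [0,30): 12 nt UTR + ATG + 5 codons
#   exon2 [50,80): 10 codons
#   exon3 [100,160): 8 codons + TAA + UTR
toy_gene <- function() {
  u1 <- "CCTCCTCCTCCT"
  cod <- c("ATG", "AAA", "CCC", "GGG", "TTT", "CAA",
           "GAA", "CAT", "TGT", "TGG", "TAT", "CCA", "AGA", "GCT", "GTT", "GGA",
           "ATT", "ACA", "GAC", "TCC", "CTC", "AGC", "AAG", "CGT")
  ex1 <- paste0(u1, paste(cod[1:6], collapse = ""))
  ex2 <- paste(cod[7:16], collapse = "")
  ex3 <- paste0(paste(cod[17:24], collapse = ""), "TAA",
                "CCTTCCTTCCTTCCTTCCTTCCTTCCTTCCTTC")
  i1 <- "GGCCAAGGCCAAGGCCAAGG"; i2 <- "TTCCAATTCCAATTCCAATT"
  seq <- paste0(ex1, i1, ex2, i2, ex3)
  exons <- data.frame(start = c(0, 50, 100), end = c(30, 80, 160))
  cds <- data.frame(start = c(12, 50, 100), end = c(30, 80, 124))
  list(
    tx = make_tx_tbl("txA.1", "chrT", "+", exons, cds),
    genome = c(chrT = seq),
    protein = paste(unname(ORACLE_CODON[cod]), collapse = ""),
    codons = cod
  )
}

# mirror of an arbitrary single-chromosome gene: reverse-complement the
# chromosome and flip all coordinates, giving the equivalent minus-strand gene
mirror_gene <- function(tx, genome) {
  chrom <- tx$chrom[1]
  glen <- nchar(genome[[chrom]])
  tx2 <- tx
  tx2$start <- glen - tx$end
  tx2$end <- glen - tx$start
  tx2$strand <- ifelse(tx$strand == "+", "-", "+")
  tx2 <- tx2[order(tx2$type, tx2$start), , drop = FALSE]
  g2 <- genome
  g2[[chrom]] <- oracle_revcomp(genome[[chrom]])
  list(tx = tx2, genome = g2)
}

mirror_event <- function(ev, genome) {
  glen <- nchar(genome[[ev$chrom]])
  ev2 <- ev
  ev2$start <- glen - ev$end
  ev2$end <- glen - ev$start
  ev2$strand <- ifelse(ev$strand == "+", "-", "+")
  ev2
}

# one small generated fixture shared by io/pipeline tests (built once per run)
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "spliceimpact-shared-fx")
      spec <- fixture_spec(n_genes = 30, seed = 11,
                           planted_pathway_size = 8, planted_pathway_hits = 4)
      cache <<- generate_fixture(spec, dir)
    }
    cache
  }
})
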