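# Translation of (possibly synthesised) transcripts into protein sequences.

# standard genetic code, fetched from Biostrings once and cached
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

genome_seq <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) {
      stop("chromosome ", chrom, " not present in genome", call. = FALSE)
    }
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) {
      stop("chromosome ", chrom, " not present in genome", call. = FALSE)
    }
    return(genome[[chrom]])
  }
  stop("genome must be a named DNAStringSet or named character vector", call. = FALSE)
}

# Spliced mRNA in transcript orientation (reverse complement on minus strand).
spliced_mrna <- function(tx, genome) {
  ex <- tx_exons(tx)
  chrom_seq <- genome_seq(genome, tx$chrom[1])
  if (max(ex$end) > nchar(chrom_seq)) {
    stop("transcript ", tx$transcript_id[1], " extends past the end of ",
         tx$chrom[1], call. = FALSE)
  }
  pieces <- substring(chrom_seq, ex$start + 1L, ex$end)
  mrna <- paste(pieces, collapse = "")
  if (tx$strand[1] == "-") mrna <- revcomp_str(mrna)
  toupper(mrna)
}

# 0-based position in the spliced mRNA of a genomic base, or NA if not exonic.
mrna_pos_of_genomic <- function(tx, gpos) {
  ex <- tx_exons(tx)
  widths <- ex$end - ex$start
  hit <- which(gpos >= ex$start & gpos < ex$end)
  if (length(hit) == 0) return(NA_integer_)
  if (tx$strand[1] == "+") {
    before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
    as.integer(before + (gpos - ex$start[hit]))
  } else {
    after <- if (hit < nrow(ex)) sum(widths[seq(hit + 1, nrow(ex))]) else 0L
    as.integer(after + (ex$end[hit] - 1L - gpos))
  }
}

translate_orf <- function(nt) {
  n <- 3L * (nchar(nt) %/% 3L)
  if (n == 0) return(list(aa = "", has_stop = FALSE, n_codons = 0L))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  unknown <- is.na(aa)
  if (any(unknown)) {
    warning("unknown nucleotide symbol(s); codon(s) translated to X",
            call. = FALSE)
    aa[unknown] <- "X"
  }
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) {
    k <- stop_at[1] - 1L
    list(aa = paste(aa[seq_len(k)], collapse = ""), has_stop = TRUE,
         n_codons = k)
  } else {
    list(aa = paste(aa, collapse = ""), has_stop = FALSE,
         n_codons = length(aa))
  }
}

# First AUG (0-based mRNA offset) whose open reading frame runs for at least
# `min_codons` codons before hitting a stop (or the end of the mRNA).
rescan_start <- function(mrna, min_codons = 30L) {
  hits <- gregexpr("ATG", mrna, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  for (h in hits) {
    orf <- translate_orf(substring(mrna, h))
    if (orf$n_codons >= min_codons) return(as.integer(h - 1L))
  }
  NA_integer_
}

#' Translate a transcript into a protein record
#'
#' Splices the exons in transcript orientation, anchors translation at the
#' annotated CDS start, and reads through the mRNA with the standard genetic
#' code until the first stop codon (or the end of the molecule), so that
#' frameshifted isoforms naturally read into what was annotated as UTR. If
#' the annotated start codon was removed or broken by the event, the spliced
#' mRNA is rescanned for the first AUG opening a reading frame of at least
#' `rescan_min_codons` codons; if none exists the record is non-coding.
#'
#' A stop codon ending more than `nmd_distance` nucleotides upstream of the
#' last exon-exon junction sets the informational
#' `coding_status = "premature_stop_flagged"` (the usual rule of thumb for
#' nonsense-mediated decay); the flag feeds no downstream filter.
#'
#' @param tx Transcript tibble (one transcript).
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param rescan_min_codons Minimum ORF length, in codons, accepted when
#'   rescanning for a start codon. Default 30.
#' @param nmd_distance Premature-stop distance rule, in nucleotides.
#'   Default 50.
#' @return A list of class `protein_record` with elements `sequence`
#'   (amino-acid string without stop symbol), `coding_status` (one of
#'   `coding`, `non_coding`, `premature_stop_flagged`), `cds_used`,
#'   `start_rescanned`, `stop_found`.
#' @export
translate_transcript <- function(tx, genome, rescan_min_codons = 30L,
                                 nmd_distance = 50L) {
  cds <- tx_cds(tx)
  non_coding <- structure(
    list(sequence = "", coding_status = "non_coding", cds_used = cds,
         start_rescanned = FALSE, stop_found = FALSE),
    class = "protein_record")
  if (nrow(cds) == 0) return(non_coding)
  mrna <- spliced_mrna(tx, genome)
  anchor <- if (tx$strand[1] == "+") min(cds$start) else max(cds$end) - 1L
  pos <- mrna_pos_of_genomic(tx, anchor)
  rescanned <- FALSE
  if (is.na(pos) || substr(mrna, pos + 1L, pos + 3L) != "ATG") {
    pos <- rescan_start(mrna, rescan_min_codons)
    rescanned <- TRUE
    if (is.na(pos)) return(non_coding)
  }
  orf <- translate_orf(substring(mrna, pos + 1L))
  if (nchar(orf$aa) == 0) return(non_coding)
  status <- "coding"
  ex <- tx_exons(tx)
  if (orf$has_stop && nrow(ex) > 1) {
    widths <- ex$end - ex$start
    last_junction <- sum(widths) - widths[if (tx$strand[1] == "+") length(widths) else 1L]
    stop_end <- pos + 3L * (nchar(orf$aa) + 1L)  # 0-based exclusive end of stop codon
    if (last_junction - stop_end > nmd_distance) status <- "premature_stop_flagged"
  }
  structure(
    list(sequence = orf$aa, coding_status = status, cds_used = cds,
         start_rescanned = rescanned, stop_found = orf$has_stop),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$coding_status, ", ", nchar(x$sequence),
      " aa\n", sep = "")
  if (nchar(x$sequence) > 0) {
    cat("  ", substr(x$sequence, 1, 60),
        if (nchar(x$sequence) > 60) "..." else "", "\n", sep = "")
  }
  invisible(x)
}
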