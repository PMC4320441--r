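# Construction of the inclusion/exclusion transcript pair for each event,
# and classification of the event region as coding / UTR-only / mixed.

tx_rows <- function(transcripts, id) {
  transcripts[transcripts$transcript_id == id, , drop = FALSE]
}

tx_exons <- function(tx) {
  ex <- tx[tx$type == "exon", , drop = FALSE]
  iv_sort(iv(ex$start, ex$end))
}

tx_cds <- function(tx) {
  cd <- tx[tx$type == "CDS", , drop = FALSE]
  iv_sort(iv(cd$start, cd$end))
}

tx_cds_len <- function(tx) iv_width(tx_cds(tx))

# Build a transcript tibble from interval sets plus metadata carried over.
make_tx <- function(template, transcript_id, exons, cds) {
  meta <- template[1, c("gene_id", "gene_symbol", "chrom", "strand"), drop = FALSE]
  ex <- tibble::tibble(
    transcript_id = transcript_id, gene_id = meta$gene_id,
    gene_symbol = meta$gene_symbol, chrom = meta$chrom, strand = meta$strand,
    type = "exon", start = exons$start, end = exons$end
  )
  cd <- tibble::tibble(
    transcript_id = transcript_id, gene_id = meta$gene_id,
    gene_symbol = meta$gene_symbol, chrom = meta$chrom, strand = meta$strand,
    type = "CDS",
    start = if (nrow(cds)) cds$start else integer(0),
    end = if (nrow(cds)) cds$end else integer(0)
  )
  out <- dplyr::bind_rows(ex, cd)
  out$has_cds <- nrow(cds) > 0
  out
}

#' Choose a host transcript for an event
#'
#' When the event does not name a `host_transcript_id`, the fallback host is
#' the transcript of the event's gene with the longest total CDS, ties broken
#' by lexicographically smallest transcript id: a deterministic stand-in for
#' a manual "most representative transcript" choice.
#'
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param event A one-row event tibble (or list) from [read_events()].
#' @return The chosen transcript id (character scalar).
#' @export
pick_host_transcript <- function(transcripts, event) {
  host_id <- event$host_transcript_id
  if (!is.null(host_id) && !is.na(host_id) && nzchar(host_id)) {
    if (!host_id %in% transcripts$transcript_id) {
      stop("host transcript ", host_id, " not found in transcript models",
           call. = FALSE)
    }
    return(host_id)
  }
  cand <- transcripts[norm_symbol(transcripts$gene_symbol) ==
                        norm_symbol(event$gene_symbol), , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no transcript found for gene ", event$gene_symbol, call. = FALSE)
  }
  per_tx <- dplyr::summarise(
    dplyr::group_by(cand, .data$transcript_id),
    cds_len = sum((.data$end - .data$start)[.data$type == "CDS"]),
    .groups = "drop"
  )
  per_tx <- dplyr::arrange(per_tx, dplyr::desc(.data$cds_len), .data$transcript_id)
  per_tx$transcript_id[1]
}

#' Build the inclusion/exclusion transcript pair for one event
#'
#' The inclusion transcript contains the alternative region; the exclusion
#' transcript lacks it. For `skipped_exon`, `alt_5ss` and `alt_3ss` the
#' exclusion is the host minus the region (sub-exon regions are trimmed, not
#' whole exons deleted). For `intron_retention` the inclusion is the host
#' with the intron merged into its flanking exons and the exclusion is the
#' host itself. `alt_promoter` drops the region and all exonic sequence 5'
#' of it (transcript orientation); `alt_polyA` drops the region and all
#' exonic sequence 3' of it. `complex` events are paired from two explicitly
#' supplied transcript ids, with no synthesis.
#'
#' Synthesised transcripts carry CDS intervals intersected with their new
#' exon union; translation decides downstream what that does to the protein.
#'
#' @param transcripts Transcript tibble from [read_transcripts()].
#' @param event One-row event tibble.
#' @param host_id Optional host transcript id; defaults to
#'   [pick_host_transcript()].
#' @return An object of class `transcript_pair`: a list with elements
#'   `event`, `inclusion` and `exclusion` (transcript tibbles).
#' @export
build_pair <- function(transcripts, event, host_id = NULL) {
  if (is.null(host_id)) host_id <- pick_host_transcript(transcripts, event)
  host <- tx_rows(transcripts, host_id)
  if (nrow(host) == 0) stop("host transcript ", host_id, " not found", call. = FALSE)
  if (host$strand[1] != event$strand) {
    stop("event strand (", event$strand, ") does not match host transcript strand (",
         host$strand[1], ")", call. = FALSE)
  }
  if (host$chrom[1] != event$chrom) {
    stop("event chromosome does not match host transcript", call. = FALSE)
  }
  exons <- tx_exons(host)
  cds <- tx_cds(host)
  cls <- event$event_class
  rs <- event$start; re <- event$end
  strand <- host$strand[1]

  if (cls == "complex") {
    pid <- event$partner_transcript_id
    if (is.null(pid) || is.na(pid) || !nzchar(pid)) {
      stop("complex events require an explicit partner_transcript_id", call. = FALSE)
    }
    partner <- tx_rows(transcripts, pid)
    if (nrow(partner) == 0) stop("partner transcript ", pid, " not found", call. = FALSE)
    pair <- list(event = event, inclusion = host, exclusion = partner)
    class(pair) <- "transcript_pair"
    return(pair)
  }

  if (cls == "intron_retention") {
    gaps <- if (nrow(exons) > 1) {
      iv(exons$end[-nrow(exons)], exons$start[-1])
    } else iv_empty()
    hit <- which(gaps$start == rs & gaps$end == re)
    if (length(hit) != 1) {
      stop("intron_retention region must exactly span the intron between two ",
           "consecutive exons of the host", call. = FALSE)
    }
    merged <- iv_merge(rbind(exons, iv(rs, re)))
    inclusion <- make_tx(host, paste0(host_id, ":retained"), merged, cds)
    pair <- list(event = event, inclusion = inclusion, exclusion = host)
    class(pair) <- "transcript_pair"
    return(pair)
  }

  if (!iv_overlaps(exons, rs, re)) {
    stop("event region does not overlap the exons of host transcript ",
         host_id, call. = FALSE)
  }
  cut <- switch(cls,
    skipped_exon = , alt_5ss = , alt_3ss = iv(rs, re),
    alt_promoter = if (strand == "+") iv(min(exons$start), re) else iv(rs, max(exons$end)),
    alt_polyA    = if (strand == "+") iv(rs, max(exons$end)) else iv(min(exons$start), re),
    stop("unknown event_class: ", cls, call. = FALSE)
  )
  ex_excl <- iv_subtract(exons, cut)
  if (nrow(ex_excl) == 0) {
    stop("exclusion isoform would retain no exonic sequence", call. = FALSE)
  }
  cds_excl <- iv_intersect(cds, ex_excl)
  exclusion <- make_tx(host, paste0(host_id, ":excl"), ex_excl, cds_excl)
  pair <- list(event = event, inclusion = host, exclusion = exclusion)
  class(pair) <- "transcript_pair"
  pair
}

#' Classify an event region against the coding sequence
#'
#' `coding` if the region lies entirely within the genomic span of the
#' inclusion transcript's CDS, `utr_only` if entirely outside it, `mixed` if
#' it straddles a CDS boundary, and `not_determined` when the inclusion
#' transcript has no CDS. The CDS genomic span is used as the projection so
#' that a retained intron inside the coding region classifies as coding.
#'
#' @param pair A `transcript_pair` from [build_pair()].
#' @return One of `"coding"`, `"utr_only"`, `"mixed"`, `"not_determined"`.
#' @export
classify_region <- function(pair) {
  cds <- tx_cds(pair$inclusion)
  if (nrow(cds) == 0) return("not_determined")
  span_s <- min(cds$start); span_e <- max(cds$end)
  rs <- pair$event$start; re <- pair$event$end
  if (rs >= span_s && re <= span_e) return("coding")
  if (re <= span_s || rs >= span_e) return("utr_only")
  "mixed"
}

#' @export
print.transcript_pair <- function(x, ...) {
  cat("<transcript_pair> ", x$event$event_class, " event ",
      x$event$probeset_id, " (", x$event$gene_symbol, ")\n", sep = "")
  cat("  inclusion: ", x$inclusion$transcript_id[1], " (",
      sum(x$inclusion$type == "exon"), " exons)\n", sep = "")
  cat("  exclusion: ", x$exclusion$transcript_id[1], " (",
      sum(x$exclusion$type == "exon"), " exons)\n", sep = "")
  invisible(x)
}
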