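# Readers and writers for every external format the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates, both genomic
# and protein-residue. GTF/GFF3 and the domains TSV keep their native 1-based
# inclusive coordinates in files; the events TSV is an artifact-defined format
# and uses BED-like 0-based half-open genomic coordinates.

# quick structural scan so malformed lines are reported with their number;
# full parsing is delegated to rtracklayer
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nfield < 9]
  if (length(bad) > 0) {
    stop("malformed GTF/GFF record at line ", bad[1], " of ", path,
         " (expected >= 9 tab-separated fields)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read transcript models from GTF/GFF3
#'
#' Parses `exon` and `CDS` features and returns one row per interval with all
#' coordinates converted from the file's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. Transcripts without CDS
#' features are retained and flagged non-coding via `has_cds`.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `gene_symbol`,
#'   `chrom`, `strand`, `type` (`"exon"` or `"CDS"`), `start`, `end`
#'   (0-based half-open) and `has_cds`.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_gtf_lines(path)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!"type" %in% names(df)) stop("no feature types found in ", path, call. = FALSE)
  df <- df[as.character(df$type) %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0) stop("no exon/CDS features found in ", path, call. = FALSE)
  symbol <- if ("gene_name" %in% names(df)) df$gene_name else df$gene_id
  symbol <- ifelse(is.na(symbol) | !nzchar(symbol), df$gene_id, symbol)
  tx <- tibble::tibble(
    transcript_id = as.character(df$transcript_id),
    gene_id       = as.character(df$gene_id),
    gene_symbol   = as.character(symbol),
    chrom         = as.character(df$seqnames),
    strand        = as.character(df$strand),
    type          = as.character(df$type),
    start         = as.integer(df$start - 1L),
    end           = as.integer(df$end)
  )
  if (any(!tx$strand %in% c("+", "-"))) {
    stop("transcripts must be stranded (+/-); found: ",
         paste(unique(setdiff(tx$strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  }
  tx <- dplyr::arrange(tx, .data$transcript_id, .data$type, .data$start)
  validate_transcripts(tx)
  cds_tx <- unique(tx$transcript_id[tx$type == "CDS"])
  tx$has_cds <- tx$transcript_id %in% cds_tx
  tx
}

validate_transcripts <- function(tx) {
  idx <- split(seq_len(nrow(tx)), tx$transcript_id)
  for (id in names(idx)) {
    sub <- tx[idx[[id]], , drop = FALSE]
    if (length(unique(sub$chrom)) != 1 || length(unique(sub$strand)) != 1) {
      stop("transcript ", id, " mixes chromosomes or strands", call. = FALSE)
    }
    is_ex <- sub$type == "exon"
    if (!any(is_ex)) stop("transcript ", id, " has no exons", call. = FALSE)
    es <- sub$start[is_ex]; ee <- sub$end[is_ex]
    if (any(es >= ee)) {
      stop("transcript ", id, " has an empty or inverted exon", call. = FALSE)
    }
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)])) {
      stop("transcript ", id, " has overlapping exons", call. = FALSE)
    }
    cs <- sub$start[!is_ex]; ce <- sub$end[!is_ex]
    for (i in seq_along(cs)) {
      # a GTF CDS feature lies within a single exon
      if (!any(es <= cs[i] & ee >= ce[i])) {
        stop("CDS interval outside exons in transcript ", id, call. = FALSE)
      }
    }
  }
  invisible(tx)
}

#' Read a genome FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gn <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the first token
  names(gn) <- sub("\\s.*$", "", names(gn))
  gn
}

#' Read a DAS event table
#'
#' The events TSV is the package's own format: a header row with columns
#' `probeset_id, gene_symbol, chrom, start, end, strand, event_class,
#' host_transcript_id, SI, FC` (an optional `partner_transcript_id` column is
#' used by `complex` events). Genomic coordinates in the file are 0-based
#' half-open. The splicing index `SI` and fold change `FC` are carried as
#' metadata only and never recomputed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per event.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("probeset_id", "gene_symbol", "chrom", "start", "end", "strand",
           "event_class", "host_transcript_id", "SI", "FC")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("events table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(df$event_class), event_classes())
  if (length(bad_class) > 0) {
    stop("unknown event_class value(s): ", paste(bad_class, collapse = ", "),
         "; allowed: ", paste(event_classes(), collapse = ", "), call. = FALSE)
  }
  num <- function(x, nm) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & !is.na(x) & nzchar(x))) {
      stop("non-numeric ", nm, " value in events table", call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    probeset_id = df$probeset_id,
    gene_symbol = df$gene_symbol,
    chrom = df$chrom,
    start = as.integer(num(df$start, "start")),
    end = as.integer(num(df$end, "end")),
    strand = df$strand,
    event_class = df$event_class,
    host_transcript_id = ifelse(is.na(df$host_transcript_id), "", df$host_transcript_id),
    partner_transcript_id = if ("partner_transcript_id" %in% names(df)) {
      ifelse(is.na(df$partner_transcript_id), "", df$partner_transcript_id)
    } else "",
    SI = num(df$SI, "SI"),
    FC = num(df$FC, "FC")
  )
  if (any(out$start < 0 | out$start >= out$end)) {
    stop("event region must satisfy 0 <= start < end", call. = FALSE)
  }
  if (any(!out$strand %in% c("+", "-"))) {
    stop("event strand must be '+' or '-'", call. = FALSE)
  }
  out
}

#' Read a protein-domain hit table
#'
#' Expects a TSV with header `protein_key, accession, name, description,
#' res_start, res_end` where residue coordinates are 1-based inclusive on the
#' inclusion (reference) protein, as conserved-domain search exports print
#' them. They are converted to 0-based half-open internally. `protein_key`
#' may be a transcript id or a gene symbol.
#'
#' @param path Path to the TSV file.
#' @return A tibble with 0-based half-open `res_start`/`res_end`.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("protein_key", "accession", "name", "description", "res_start", "res_end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("domain table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rs <- suppressWarnings(as.integer(df$res_start))
  re <- suppressWarnings(as.integer(df$res_end))
  if (any(is.na(rs) | is.na(re))) stop("non-integer residue coordinates", call. = FALSE)
  if (any(rs < 1 | re < rs)) {
    stop("domain residue coordinates must satisfy 1 <= res_start <= res_end",
         call. = FALSE)
  }
  tibble::tibble(
    protein_key = df$protein_key,
    accession = df$accession,
    name = df$name,
    description = df$description,
    res_start = rs - 1L,
    res_end = re
  )
}

#' Read gene-to-GO annotations
#'
#' Accepts either a two-column TSV with header `gene_symbol, go_term`
#' (optionally a third `go_id` column) or a GAF 2.x file. GAF records carry
#' GO identifiers, not term names, so when a GAF is supplied the identifier
#' is used as the term text; supply the TSV form when term-name text overlap
#' is the goal.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene_symbol`, `go_term`, `go_id` and the
#'   normalised matching key `gene_key`.
#' @export
read_go <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  is_gaf <- any(startsWith(first, "!")) ||
    any(vapply(strsplit(first, "\t", fixed = TRUE), length, integer(1)) >= 15)
  if (is_gaf) {
    df <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (ncol(df) < 5) stop("GAF file has fewer than 5 columns", call. = FALSE)
    out <- tibble::tibble(gene_symbol = df[[3]], go_term = df[[5]], go_id = df[[5]])
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!all(c("gene_symbol", "go_term") %in% names(df))) {
      stop("GO TSV must have columns gene_symbol and go_term", call. = FALSE)
    }
    out <- tibble::tibble(
      gene_symbol = df$gene_symbol,
      go_term = df$go_term,
      go_id = if ("go_id" %in% names(df)) df$go_id else NA_character_
    )
  }
  if (any(!nzchar(out$gene_symbol)) || any(is.na(out$gene_symbol))) {
    stop("empty gene symbol in GO annotations", call. = FALSE)
  }
  if (any(!nzchar(out$go_term)) || any(is.na(out$go_term))) {
    stop("empty GO term in annotations", call. = FALSE)
  }
  out$gene_key <- norm_symbol(out$gene_symbol)
  out
}

#' Read pathway gene sets from GMT
#'
#' One pathway per line: set name, description, then member gene symbols,
#' tab-separated. Gene symbols are normalised (trimmed, upper-cased) into
#' `gene_key` once at load.
#'
#' @param path Path to the GMT file.
#' @return A long tibble with columns `pathway_id`, `name`, `gene_symbol`,
#'   `gene_key` (one row per pathway member).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has no member genes", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate pathway id(s) in GMT: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::map_dfr(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    tibble::tibble(pathway_id = f[1], name = f[2], gene_symbol = genes)
  })
  out$gene_key <- norm_symbol(out$gene_symbol)
  out
}

# Writers ---------------------------------------------------------------------

#' Write transcript models to GTF
#'
#' Converts internal 0-based half-open coordinates back to the GTF's 1-based
#' inclusive convention.
#'
#' @param tx Transcript tibble as produced by [read_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(tx, path) {
  tx <- dplyr::arrange(tx, .data$transcript_id,
                       factor(.data$type, levels = c("exon", "CDS")), .data$start)
  lines <- sprintf(
    '%s\tspliceimpact\t%s\t%d\t%d\t.\t%s\t%s\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    tx$chrom, tx$type, tx$start + 1L, tx$end, tx$strand,
    ifelse(tx$type == "CDS", "0", "."),
    tx$gene_id, tx$transcript_id, tx$gene_symbol
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a DAS event table
#' @param events Events tibble as produced by [read_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Write a protein-domain hit table (1-based inclusive residue coordinates)
#' @param domains Domains tibble as produced by [read_domains()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains_tsv <- function(domains, path) {
  out <- domains
  out$res_start <- out$res_start + 1L
  readr::write_tsv(out[, c("protein_key", "accession", "name", "description",
                           "res_start", "res_end")], path, progress = FALSE)
  invisible(path)
}

#' Write gene-to-GO annotations as TSV
#' @param go GO tibble as produced by [read_go()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_tsv <- function(go, path) {
  cols <- intersect(c("gene_symbol", "go_term", "go_id"), names(go))
  readr::write_tsv(go[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write pathway gene sets as GMT
#' @param pathways Long pathway tibble as produced by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  sp <- split(pathways, factor(pathways$pathway_id, levels = unique(pathways$pathway_id)))
  lines <- vapply(sp, function(p) {
    paste(c(p$pathway_id[1], p$name[1], p$gene_symbol), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
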