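# Deterministic generator of complete toy datasets (genome, transcripts,
# events, domains, GO, pathways) with a machine-readable planted truth table.
#
# Genes are synthesised codon-aware: coding sequences are built from random
# non-stop codons, every exon's coding part is a whole number of codons, and
# the planted event is applied at a known codon offset, so the designed
# inclusion and exclusion protein strings (and hence the truth labels) are
# known at generation time without running the genomic pipeline.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
# no stops (in-frame stops would shorten designed proteins) and no ATG
# (spurious start codons would derail the start-rescan of promoter events)
SAFE_CODONS <- setdiff(ALL_CODONS, c(STOP_CODONS, "ATG"))

# word pools for domain descriptions and GO term names; PASS words may be
# shared between the two, DESC words appear only in descriptions and GO
# words only in term names, so token overlap is fully controlled
PASS_WORDS <- c("kinase", "phosphatase", "transport", "calcium", "channel",
                "receptor", "helicase", "transferase", "ligase", "protease",
                "gtpase", "atpase")
DESC_WORDS <- c("finger", "motif", "fold", "barrel", "coil", "repeat",
                "cassette", "loop", "sheet", "bundle")
GO_WORDS <- c("process", "regulation", "signaling", "metabolic",
              "biosynthetic", "nuclear", "membrane", "cytoplasmic",
              "activity", "response")

pick1 <- function(v) v[sample.int(length(v), 1L)]

aa_of <- function(codons) paste(unname(codon_table()[codons]), collapse = "")

# draw codons, redrawing any whose junction with the previous codon (or the
# supplied tail) would create an "ATG" substring
draw_codons <- function(n, tail = "") {
  out <- sample(SAFE_CODONS, n, replace = TRUE)
  tl <- substr(tail, max(1L, nchar(tail) - 1L), nchar(tail))
  for (i in seq_len(n)) {
    prev <- if (i == 1L) tl else substr(out[i - 1L], 2L, 3L)
    while (grepl("ATG", paste0(prev, out[i]), fixed = TRUE)) {
      out[i] <- pick1(SAFE_CODONS)
    }
  }
  out
}

# random nucleotides with every "ATG" occurrence (including across the tail
# boundary) destroyed by a G -> C substitution, which cannot create new ones
draw_nt <- function(n, tail = "") {
  tl <- substr(tail, max(1L, nchar(tail) - 1L), nchar(tail))
  s <- paste0(tl, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
  repeat {
    i <- regexpr("ATG", s, fixed = TRUE)[1]
    if (i < 0) break
    substr(s, i + 2L, i + 2L) <- "C"
  }
  substring(s, nchar(tl) + 1L)
}

# redraw codon idx until its amino acid differs from every aa in `avoid_aa`
# and no ATG is created across either junction with its neighbours (the
# window deliberately excludes the neighbours' own interiors, since a
# planted start codon next door must not poison the draw)
resample_codon <- function(cod, idx, avoid_aa) {
  left <- if (idx > 1) substr(cod[idx - 1], 2L, 3L) else ""
  right <- if (idx < length(cod)) substr(cod[idx + 1], 1L, 2L) else ""
  repeat {
    cd <- pick1(SAFE_CODONS)
    if (!substr(aa_of(cd), 1, 1) %in% avoid_aa &&
        !grepl("ATG", paste0(left, cd, right), fixed = TRUE)) {
      cod[idx] <- cd
      return(cod)
    }
  }
}

#' Specify a synthetic fixture
#'
#' The defaults are the study conditions the rest of the package is tested
#' under: 200 genes of 3-10 exons, one planted splicing event per gene drawn
#' from the full event-class vocabulary, half the protein-changing events
#' hitting an annotated domain, half the domain-changing genes sharing a
#' description/GO token, and one planted over-represented pathway drawing 10
#' of its 15 members from the genes that pass the overlap filter.
#'
#' @param n_genes Number of genes (one planted event each).
#' @param exons_per_gene Length-2 integer range of exon counts.
#' @param event_class_mix Named probability vector over [event_classes()].
#' @param frac_domain_affecting Probability that a protein-changing event is
#'   planted on an annotated domain.
#' @param frac_overlap_pass Probability that a domain-changing gene's GO
#'   terms share a token with the changed-domain description.
#' @param planted_pathway_size,planted_pathway_hits Size of the planted
#'   pathway and how many of its members are drawn from the genes passing
#'   the overlap filter.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   fixture files.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200L,
                         exons_per_gene = c(3L, 10L),
                         event_class_mix = c(skipped_exon = 0.25, alt_5ss = 0.15,
                                             alt_3ss = 0.15, intron_retention = 0.15,
                                             alt_promoter = 0.10, alt_polyA = 0.10,
                                             complex = 0.10),
                         frac_domain_affecting = 0.5,
                         frac_overlap_pass = 0.5,
                         planted_pathway_size = 15L,
                         planted_pathway_hits = 10L,
                         seed = 1L) {
  stopifnot(n_genes >= 1, length(exons_per_gene) == 2,
            exons_per_gene[1] >= 3, exons_per_gene[2] >= exons_per_gene[1],
            all(event_class_mix >= 0), sum(event_class_mix) > 0,
            frac_domain_affecting >= 0, frac_domain_affecting <= 1,
            frac_overlap_pass >= 0, frac_overlap_pass <= 1,
            planted_pathway_size >= 1,
            planted_pathway_hits >= 0,
            planted_pathway_hits <= planted_pathway_size)
  bad <- setdiff(names(event_class_mix), event_classes())
  if (length(bad) > 0) stop("unknown event class in mix: ", paste(bad, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    event_class_mix = event_class_mix / sum(event_class_mix),
    frac_domain_affecting = frac_domain_affecting,
    frac_overlap_pass = frac_overlap_pass,
    planted_pathway_size = as.integer(planted_pathway_size),
    planted_pathway_hits = as.integer(planted_pathway_hits),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

# assign event classes so every class with positive probability appears
# (proportional allocation, remainder by largest fraction), then shuffle
assign_classes <- function(mix, n) {
  mix <- mix[mix > 0]
  raw <- mix * n
  base <- floor(raw)
  if (n >= length(mix)) base <- pmax(base, 1)
  while (sum(base) > n) base[which.max(base)] <- base[which.max(base)] - 1
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    base[extra[seq_len(rem)]] <- base[extra[seq_len(rem)]] + 1
  }
  sample(rep(names(base), times = base))
}

# Build one synthetic gene with its planted event. Returns all the pieces
# the fixture writer needs plus the designed protein strings.
gen_gene <- function(gi, cls, spec) {
  lo <- spec$exons_per_gene[1]; hi <- spec$exons_per_gene[2]
  strand <- if (gi %% 2 == 0) "-" else "+"
  gene_id <- sprintf("g%03d", gi)
  symbol <- sprintf("Sg%03d", gi)
  tx1 <- sprintf("tx%03d_1", gi)
  chrom <- sprintf("chr%03d", gi)

  variant <- NULL
  if (cls == "alt_promoter") {
    n_ex <- pick1(seq.int(max(4L, lo), hi))
    cc <- c(0L, sample(12:18, n_ex - 1, replace = TRUE))
    variant <- pick1(c("utr", "utr", "coding", "coding", "coding"))
    if (variant == "coding") {
      # planted restart must open an ORF of >= 30 codons
      while (sum(cc) - (cc[2] + 2L) < 32L) cc[n_ex] <- cc[n_ex] + 4L
    }
    u1 <- pick1(15:40); u2 <- pick1(10:40)
  } else if (cls == "alt_polyA") {
    variant <- pick1(c("utr", "utr", "coding", "coding", "mixed", "mixed"))
    n_ex <- pick1(seq.int(lo, hi))
    cc <- sample(8:16, n_ex, replace = TRUE)
    if (variant == "utr") cc[n_ex] <- 0L
    u1 <- pick1(10:40); u2 <- pick1(15:40)
  } else {
    n_ex <- pick1(seq.int(lo, hi))
    cc <- sample(8:16, n_ex, replace = TRUE)
    u1 <- pick1(10:40); u2 <- pick1(15:40)
  }
  L <- sum(cc)
  cod <- draw_codons(L)
  cod[1] <- "ATG"

  j <- NA_integer_; k <- NA_integer_
  block <- NULL          # altered residue block on the inclusion protein
  excl_protein <- NULL
  incl_cod <- cod        # codons of the inclusion protein
  retained_icod <- NULL
  planted_m <- NA_integer_
  region_class <- "coding"

  if (cls %in% c("skipped_exon", "complex", "alt_5ss", "alt_3ss")) {
    j <- pick1(seq.int(2L, n_ex - 1L))
    s0 <- sum(cc[seq_len(j - 1L)])            # codons before exon j
    if (cls %in% c("skipped_exon", "complex")) {
      k <- cc[j]
    } else if (cls == "alt_5ss") {
      k <- pick1(seq.int(3L, min(6L, cc[j] - 2L)))
      s0 <- s0 + cc[j] - k                    # trim the transcript-3' edge
    } else {
      k <- pick1(seq.int(3L, min(6L, cc[j] - 2L)))  # trim the transcript-5' edge
    }
    # distinct flank amino acids pin the diff block to the designed codons
    aa1 <- function(i) substr(aa_of(cod[i]), 1, 1)
    if (aa1(s0 + 1L) == aa1(s0 + k + 1L)) {
      cod <- resample_codon(cod, s0 + 1L, c(aa1(s0 + k + 1L), aa1(s0)))
    }
    if (aa1(s0 + k) == aa1(s0)) {
      cod <- resample_codon(cod, s0 + k, c(aa1(s0), aa1(s0 + k + 1L)))
    }
    incl_cod <- cod
    excl_protein <- aa_of(cod[-seq.int(s0 + 1L, s0 + k)])
    block <- c(s0, s0 + k)
  } else if (cls == "intron_retention") {
    j <- pick1(seq_len(n_ex - 1L))            # retained intron follows exon j
    Bi <- sum(cc[seq_len(j)])
    k <- pick1(6:12)
    icod <- draw_codons(k)
    aa1 <- function(v, i) substr(aa_of(v[i]), 1, 1)
    if (aa1(icod, 1L) == aa1(cod, Bi + 1L)) {
      icod <- resample_codon(icod, 1L, aa1(cod, Bi + 1L))
    }
    if (aa1(icod, k) == aa1(cod, Bi)) {
      icod <- resample_codon(icod, k, aa1(cod, Bi))
    }
    retained_icod <- icod
    incl_cod <- c(cod[seq_len(Bi)], icod, cod[seq.int(Bi + 1L, L)])
    excl_protein <- aa_of(cod)
    block <- c(Bi, Bi + k)
  } else if (cls == "alt_promoter") {
    if (variant == "utr") {
      excl_protein <- aa_of(cod)
      region_class <- "utr_only"
    } else {
      q <- 3L
      planted_m <- cc[2] + q - 1L             # 0-based codon index of the restart Met
      cod[planted_m + 1L] <- "ATG"
      aa1 <- function(i) substr(aa_of(cod[i]), 1, 1)
      if (aa1(2L) == aa1(planted_m + 2L)) {
        cod <- resample_codon(cod, 2L, aa1(planted_m + 2L))
      }
      incl_cod <- cod
      excl_protein <- aa_of(cod[seq.int(planted_m + 1L, L)])
      block <- c(1L, planted_m + 1L)
    }
  } else if (cls == "alt_polyA") {
    if (variant == "utr") {
      excl_protein <- aa_of(cod)
      region_class <- "utr_only"
    } else {
      t_rel <- pick1(seq.int(2L, cc[n_ex] - 2L))
      t <- sum(cc[seq_len(n_ex - 1L)]) + t_rel
      excl_protein <- aa_of(cod[seq_len(t)])
      block <- c(t, L)
      region_class <- if (variant == "mixed") "mixed" else "coding"
    }
  }
  incl_protein <- aa_of(incl_cod)
  Li <- nchar(incl_protein)

  # --- exon layout: per exon, 5' UTR nt, codon count, 3' tail nt -------------
  utr5 <- character(n_ex); utr3 <- character(n_ex)
  last_cod_exon <- max(which(cc > 0))
  for (i in seq_len(n_ex)) { utr5[i] <- ""; utr3[i] <- "" }
  utr5[1] <- draw_nt(u1)   # for alt_promoter exon 1 is pure UTR (cc[1] == 0)
  if (cls == "alt_polyA" && variant == "utr") {
    u2a <- pick1(8:20)
    utr3[last_cod_exon] <- paste0("TAA", draw_nt(u2a, tail = "AA"))
    utr3[n_ex] <- draw_nt(u2)
  } else {
    utr3[last_cod_exon] <- paste0("TAA", draw_nt(u2, tail = "AA"))
  }

  exon_nt <- character(n_ex)
  off <- 0L
  cds_local <- vector("list", n_ex)   # transcript-local [start, end) of coding part
  for (i in seq_len(n_ex)) {
    body <- if (cc[i] > 0) paste(cod[seq.int(off + 1L, off + cc[i])], collapse = "") else ""
    exon_nt[i] <- paste0(utr5[i], body, utr3[i])
    cds_local[i] <- list(
      if (cc[i] > 0) c(nchar(utr5[i]), nchar(utr5[i]) + 3L * cc[i]) else NULL)
    off <- off + cc[i]
  }
  introns <- character(n_ex - 1L)
  for (i in seq_len(n_ex - 1L)) {
    introns[i] <- if (cls == "intron_retention" && i == j) {
      paste(retained_icod, collapse = "")
    } else {
      draw_nt(pick1(30:80))
    }
  }

  # --- genome assembly and transcript-local -> genomic mapping ---------------
  pad <- 50L
  le <- nchar(exon_nt); li <- nchar(introns)
  gstart_ex <- integer(n_ex); gstart_in <- integer(max(0L, n_ex - 1L))
  if (strand == "+") {
    pos <- pad
    for (i in seq_len(n_ex)) {
      gstart_ex[i] <- pos; pos <- pos + le[i]
      if (i < n_ex) { gstart_in[i] <- pos; pos <- pos + li[i] }
    }
    gseq <- paste0(draw_nt(pad), paste0(rbind(c(exon_nt[-n_ex]), c(introns)), collapse = ""),
                   exon_nt[n_ex], draw_nt(pad))
  } else {
    pos <- pad
    for (i in rev(seq_len(n_ex))) {
      gstart_ex[i] <- pos; pos <- pos + le[i]
      if (i > 1) { gstart_in[i - 1L] <- pos; pos <- pos + li[i - 1L] }
    }
    mid <- character(0)
    for (i in rev(seq_len(n_ex))) {
      mid <- c(mid, revcomp_str(exon_nt[i]))
      if (i > 1) mid <- c(mid, revcomp_str(introns[i - 1L]))
    }
    gseq <- paste0(draw_nt(pad), paste(mid, collapse = ""), draw_nt(pad))
  }
  glen <- nchar(gseq)
  # map a transcript-orientation sub-interval [a, b) of a piece to genomic
  map_piece <- function(gstart, plen, a, b) {
    if (strand == "+") c(gstart + a, gstart + b) else c(gstart + plen - b, gstart + plen - a)
  }
  exon_iv <- t(vapply(seq_len(n_ex), function(i) map_piece(gstart_ex[i], le[i], 0L, le[i]),
                      numeric(2)))
  cds_iv <- do.call(rbind, lapply(seq_len(n_ex), function(i) {
    cl <- cds_local[[i]]
    if (is.null(cl)) return(NULL)
    m <- map_piece(gstart_ex[i], le[i], cl[1], cl[2])
    data.frame(start = m[1], end = m[2])
  }))

  # --- event region ----------------------------------------------------------
  region <- switch(cls,
    skipped_exon = , complex = map_piece(gstart_ex[j], le[j], 0L, le[j]),
    alt_5ss = map_piece(gstart_ex[j], le[j], le[j] - 3L * k, le[j]),
    alt_3ss = map_piece(gstart_ex[j], le[j], 0L, 3L * k),
    intron_retention = map_piece(gstart_in[j], li[j], 0L, li[j]),
    alt_promoter = if (variant == "utr") {
      map_piece(gstart_ex[1], le[1], 0L, le[1])
    } else {
      map_piece(gstart_ex[2], le[2], 0L, le[2])
    },
    alt_polyA = if (variant == "utr") {
      map_piece(gstart_ex[n_ex], le[n_ex], 0L, le[n_ex])
    } else {
      cl <- cds_local[[n_ex]]
      t_rel <- (block[1] - sum(cc[seq_len(n_ex - 1L)]))
      a <- cl[1] + 3L * t_rel
      b <- if (variant == "mixed") cl[2] + 3L + 10L else cl[2]
      map_piece(gstart_ex[n_ex], le[n_ex], a, b)
    }
  )

  # --- transcript table rows -------------------------------------------------
  tx_tbl <- tibble::tibble(
    transcript_id = tx1, gene_id = gene_id, gene_symbol = symbol,
    chrom = chrom, strand = strand,
    type = c(rep("exon", n_ex), rep("CDS", nrow(cds_iv))),
    start = as.integer(c(exon_iv[, 1], cds_iv$start)),
    end = as.integer(c(exon_iv[, 2], cds_iv$end))
  )
  partner <- ""
  if (cls == "complex") {
    partner <- sprintf("tx%03d_2", gi)
    keep <- setdiff(seq_len(n_ex), j)
    cds2 <- do.call(rbind, lapply(keep, function(i) {
      cl <- cds_local[[i]]
      if (is.null(cl)) return(NULL)
      m <- map_piece(gstart_ex[i], le[i], cl[1], cl[2])
      data.frame(start = m[1], end = m[2])
    }))
    tx_tbl <- dplyr::bind_rows(tx_tbl, tibble::tibble(
      transcript_id = partner, gene_id = gene_id, gene_symbol = symbol,
      chrom = chrom, strand = strand,
      type = c(rep("exon", length(keep)), rep("CDS", nrow(cds2))),
      start = as.integer(c(exon_iv[keep, 1], cds2$start)),
      end = as.integer(c(exon_iv[keep, 2], cds2$end))
    ))
  }

  list(gi = gi, cls = cls, variant = variant, gene_id = gene_id, symbol = symbol,
       tx1 = tx1, partner = partner, chrom = chrom, strand = strand,
       gseq = gseq, tx_tbl = tx_tbl,
       region = as.integer(region), region_class = region_class,
       incl_protein = incl_protein, excl_protein = excl_protein,
       block = block, Li = Li, planted_m = planted_m)
}

# place domain intervals on the inclusion protein; `affect` asks for a
# changed domain overlapping the altered block
place_domains <- function(Li, block, affect) {
  margin <- 3L
  doms <- list()
  add <- function(ds, de, changed) {
    doms[[length(doms) + 1L]] <<- c(ds, de, changed)
  }
  gap_domain <- function(gs, ge) {
    gw <- ge - gs
    if (gw < 4L) return(NULL)
    len <- pick1(seq.int(4L, min(10L, gw)))
    ds <- gs + pick1(seq.int(0L, gw - len))
    c(ds, ds + len)
  }
  has_block <- !is.null(block) && block[2] > block[1]
  if (affect && has_block) {
    bs <- block[1]; be <- block[2]; bw <- be - bs
    truncation_shaped <- be >= Li && bs > 0
    if (truncation_shaped) {
      want <- if (Li - bs >= 4L && runif(1) < 0.5) "lost" else "truncated"
      if (want == "lost") {
        ds <- bs + pick1(seq.int(0L, max(0L, Li - bs - 4L)))
        de <- min(Li, ds + pick1(4:10))
        add(ds, de, TRUE)
      } else {
        d1 <- pick1(seq_len(min(8L, bs)))
        d2 <- pick1(seq_len(min(8L, Li - bs)))
        add(bs - d1, bs + d2, TRUE)
      }
    } else {
      want <- if (bw >= 4L && runif(1) < 0.5) "lost" else "straddle"
      if (want == "lost") {
        ds <- bs + pick1(seq.int(0L, bw - 4L))
        de <- ds + pick1(seq.int(4L, min(10L, be - ds)))
        add(ds, de, TRUE)
      } else {
        d1 <- pick1(seq_len(min(6L, bs)))
        d2 <- pick1(seq_len(min(6L, bw)))
        add(bs - d1, bs + d2, TRUE)
      }
    }
    # optionally a second, untouched domain in a free gap
    if (runif(1) < 0.5) {
      used <- doms[[1]]
      gaps <- list(c(0L, min(used[1], bs) - margin),
                   c(max(used[2], be) + margin, Li))
      gaps <- Filter(function(g) g[2] - g[1] >= 4L, gaps)
      if (length(gaps) > 0) {
        g <- gaps[[pick1(seq_along(gaps))]]
        d <- gap_domain(g[1], g[2])
        if (!is.null(d)) add(d[1], d[2], FALSE)
      }
    }
  } else {
    if (runif(1) < 0.25) return(NULL)       # zero-domain protein
    gaps <- if (has_block) {
      list(c(0L, block[1] - margin), c(min(block[2], Li) + margin, Li))
    } else {
      list(c(0L, Li))
    }
    gaps <- Filter(function(g) g[2] - g[1] >= 4L, gaps)
    n_dom <- pick1(1:2)
    for (d in seq_len(min(n_dom, length(gaps)))) {
      g <- gaps[[d]]
      dd <- gap_domain(g[1], g[2])
      if (!is.null(dd)) add(dd[1], dd[2], FALSE)
    }
  }
  if (length(doms) == 0) return(NULL)
  m <- do.call(rbind, doms)
  data.frame(res_start = as.integer(m[, 1]), res_end = as.integer(m[, 2]),
             changed_intent = as.logical(m[, 3]))
}

#' Generate a synthetic fixture data set
#'
#' Writes a complete toy data set (genome FASTA, transcripts GTF, events
#' TSV, domains TSV, GO TSV, pathways GMT) plus a `truth.tsv` holding the
#' planted per-event labels (`region_class`, `protein_changed`,
#' `domain_changed`, `affected_region`, `passes_overlap_filter`) and the
#' planted pathway id. The same spec and seed produce byte-identical files;
#' genes alternate strands so both orientations are exercised.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the file `paths`, the `truth` tibble and
#'   `planted_pathway_id`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(spec$seed)

  classes <- assign_classes(spec$event_class_mix, spec$n_genes)
  genes <- vector("list", spec$n_genes)
  for (gi in seq_len(spec$n_genes)) {
    for (try in 1:100) {
      g <- gen_gene(gi, classes[gi], spec)
      if (g$cls == "alt_promoter" && identical(g$variant, "coding")) {
        # the restart AUG must be the first in the exclusion mRNA
        keep_ex <- g$tx_tbl[g$tx_tbl$type == "exon" &
                              g$tx_tbl$transcript_id == g$tx1, , drop = FALSE]
        cut <- if (g$strand == "+") c(min(keep_ex$start), g$region[2]) else
          c(g$region[1], max(keep_ex$end))
        ex2 <- iv_subtract(iv(keep_ex$start, keep_ex$end), iv(cut[1], cut[2]))
        mrna <- {
          pieces <- substring(g$gseq, ex2$start + 1L, ex2$end)
          m <- paste(pieces, collapse = "")
          if (g$strand == "-") revcomp_str(m) else m
        }
        first_atg <- regexpr("ATG", mrna, fixed = TRUE)[1]
        if (first_atg != 3L * 2L + 1L) next   # planted at codon 3 of the first kept exon
      }
      genes[[gi]] <- g
      break
    }
    if (is.null(genes[[gi]])) {
      stop("failed to synthesise gene ", gi, " after 100 attempts", call. = FALSE)
    }
  }

  # domains, GO, truth -------------------------------------------------------
  dom_rows <- list(); go_rows <- list(); truth_rows <- list()
  acc_counter <- 0L
  for (g in genes) {
    d0 <- diff_proteins(g$incl_protein, g$excl_protein)
    affect <- d0$protein_changed && runif(1) < spec$frac_domain_affecting
    doms <- place_domains(g$Li, g$block, affect)
    has_go <- runif(1) > 0.03
    go_terms <- replicate(pick1(1:3), paste(sample(GO_WORDS, 2), collapse = " "))

    descs <- character(0)
    if (!is.null(doms)) {
      pass_draw <- has_go && runif(1) < spec$frac_overlap_pass
      descs <- character(nrow(doms))
      for (i in seq_len(nrow(doms))) {
        if (doms$changed_intent[i] && affect && pass_draw) {
          w <- pick1(PASS_WORDS)
          descs[i] <- paste(w, pick1(DESC_WORDS), "domain")
          go_terms <- c(go_terms, paste(w, "activity"))
        } else if (!doms$changed_intent[i] && affect && !pass_draw && runif(1) < 0.5) {
          # decoy: an intact domain sharing a token with GO must not count
          w <- pick1(PASS_WORDS)
          descs[i] <- paste(w, pick1(DESC_WORDS), "domain")
          go_terms <- c(go_terms, paste(w, "response"))
        } else {
          descs[i] <- paste(paste(sample(DESC_WORDS, 2), collapse = " "), "domain")
        }
      }
    }

    dom_tbl <- if (is.null(doms)) {
      tibble::tibble(protein_key = character(0), accession = character(0),
                     name = character(0), description = character(0),
                     res_start = integer(0), res_end = integer(0))
    } else {
      key <- if (runif(1) < 0.7) g$tx1 else g$symbol
      accs <- sprintf("SD%05d", acc_counter + seq_len(nrow(doms)))
      acc_counter <- acc_counter + nrow(doms)
      tibble::tibble(protein_key = key, accession = accs,
                     name = paste0("dom_", accs),
                     description = descs,
                     res_start = doms$res_start, res_end = doms$res_end)
    }
    ci <- classify_impact(dom_tbl, d0)
    changed_desc <- ci$statuses$description[ci$statuses$status != "intact"]
    passes <- FALSE
    if (ci$domain_changed && has_go) {
      passes <- suppressWarnings(overlap_filter(changed_desc, go_terms)$passes)
    }
    dom_rows[[length(dom_rows) + 1L]] <- dom_tbl
    if (has_go) {
      go_rows[[length(go_rows) + 1L]] <- tibble::tibble(
        gene_symbol = g$symbol, go_term = unique(go_terms))
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      probeset_id = sprintf("ps%04d", g$gi),
      gene_symbol = g$symbol,
      event_class = g$cls,
      region_class = g$region_class,
      protein_changed = d0$protein_changed,
      domain_changed = ci$domain_changed,
      affected_region = ci$affected_region,
      passes_overlap_filter = passes
    )
  }
  truth <- dplyr::bind_rows(truth_rows)
  domains <- dplyr::bind_rows(dom_rows)
  go <- dplyr::bind_rows(go_rows)

  # pathways ------------------------------------------------------------------
  query_genes <- unique(truth$gene_symbol[truth$passes_overlap_filter])
  if (spec$planted_pathway_hits > length(query_genes)) {
    stop("infeasible fixture spec: planted_pathway_hits (",
         spec$planted_pathway_hits, ") exceeds the ", length(query_genes),
         " genes passing the overlap filter", call. = FALSE)
  }
  go_genes <- unique(go$gene_symbol)
  hits <- sample(query_genes, spec$planted_pathway_hits)
  filler_pool <- setdiff(go_genes, query_genes)
  n_fill <- min(spec$planted_pathway_size - spec$planted_pathway_hits,
                length(filler_pool))
  planted_members <- c(hits, sample(filler_pool, n_fill))
  all_symbols <- vapply(genes, `[[`, character(1), "symbol")
  pw_rows <- list(tibble::tibble(pathway_id = "PATH_PLANTED",
                                 name = "planted signaling pathway",
                                 gene_symbol = toupper(planted_members)))
  for (b in 1:10) {
    pw_rows[[b + 1L]] <- tibble::tibble(
      pathway_id = sprintf("PATH_%02d", b),
      name = sprintf("background pathway %d", b),
      gene_symbol = toupper(sample(all_symbols, min(15L, length(all_symbols)))))
  }
  pathways <- dplyr::bind_rows(pw_rows)
  pathways$gene_key <- norm_symbol(pathways$gene_symbol)

  # events ---------------------------------------------------------------------
  events <- dplyr::bind_rows(lapply(genes, function(g) {
    host <- if (g$cls != "complex" && runif(1) < 0.2) "" else g$tx1
    tibble::tibble(
      probeset_id = sprintf("ps%04d", g$gi), gene_symbol = g$symbol,
      chrom = g$chrom, start = g$region[1], end = g$region[2],
      strand = g$strand, event_class = g$cls,
      host_transcript_id = host, partner_transcript_id = g$partner,
      SI = round(runif(1, -4, 4), 2), FC = round(2^runif(1, -3, 3), 2))
  }))

  transcripts <- dplyr::bind_rows(lapply(genes, `[[`, "tx_tbl"))
  genome <- Biostrings::DNAStringSet(
    structure(vapply(genes, `[[`, character(1), "gseq"),
              names = vapply(genes, `[[`, character(1), "chrom")))

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    transcripts = file.path(out_dir, "transcripts.gtf"),
    events = file.path(out_dir, "events.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    go = file.path(out_dir, "go.tsv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_genome_fasta(genome, paths$genome)
  write_transcripts_gtf(transcripts, paths$transcripts)
  write_events_tsv(events, paths$events)
  write_domains_tsv(domains, paths$domains)
  write_go_tsv(go, paths$go)
  write_gmt(pathways, paths$pathways)
  truth_out <- truth
  truth_out$planted_pathway <- "PATH_PLANTED"
  readr::write_tsv(truth_out, paths$truth, progress = FALSE)

  invisible(list(paths = paths, truth = truth_out,
                 planted_pathway_id = "PATH_PLANTED", spec = spec))
}
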