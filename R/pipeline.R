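# End-to-end funnel: build pairs -> translate/diff -> domain impact ->
# overlap filter -> pathway enrichment, with per-event failure isolation.

maybe_read <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

domains_for <- function(domains, host_id, gene_symbol) {
  hit <- domains$protein_key == host_id |
    norm_symbol(domains$protein_key) == norm_symbol(gene_symbol)
  domains[hit, , drop = FALSE]
}

#' Run the splicing-impact funnel
#'
#' Executes the full annotation funnel over a DAS event table: for every
#' event the inclusion/exclusion isoform pair is built, both isoforms are
#' translated, the residue-level difference is computed, annotated domains
#' are classified as intact / internally altered / truncated / lost, the
#' changed-domain descriptions are compared with the gene's GO term names
#' (non-stopword token overlap), and finally the genes passing that filter
#' are tested for pathway over-representation with a one-sided Fisher's
#' exact test.
#'
#' Per-event failures (missing host transcript, non-coding host, malformed
#' region, out-of-bounds domain) are recorded with a reason code in the
#' `status` column and excluded from downstream counts; they are never
#' fatal.
#'
#' Arguments may be the in-memory objects or file paths (read with the
#' matching `read_*()` function).
#'
#' @param events Event tibble or path ([read_events()]).
#' @param transcripts Transcript tibble or path ([read_transcripts()]).
#' @param genome Named `DNAStringSet`/character vector or FASTA path.
#' @param domains Domain tibble or path ([read_domains()]); may be `NULL`.
#' @param go GO tibble or path ([read_go()]); may be `NULL`.
#' @param pathways Pathway tibble or path ([read_gmt()]); may be `NULL`, in
#'   which case enrichment is skipped.
#' @param stopwords Stopword tokens for the overlap filter.
#' @param p_threshold Enrichment significance threshold (default 0.01).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param out_dir If non-`NULL`, `impact.tsv`, `enrichment.tsv` and
#'   `funnel.tsv` are written there.
#' @param verbose Log per-stage counts to standard error.
#' @return An object of class `splice_funnel`; see [glance.splice_funnel()],
#'   [tidy.splice_funnel()], [autoplot.splice_funnel()].
#' @export
run_pipeline <- function(events, transcripts, genome, domains = NULL, go = NULL,
                         pathways = NULL, stopwords = default_stopwords(),
                         p_threshold = 0.01, p_adjust = c("none", "BH"),
                         out_dir = NULL, verbose = FALSE) {
  p_adjust <- match.arg(p_adjust)
  events <- maybe_read(events, read_events)
  transcripts <- maybe_read(transcripts, read_transcripts)
  genome <- if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    read_genome(genome)
  } else genome
  domains <- if (is.null(domains)) {
    tibble::tibble(protein_key = character(0), accession = character(0),
                   name = character(0), description = character(0),
                   res_start = integer(0), res_end = integer(0))
  } else maybe_read(domains, read_domains)
  go <- if (is.null(go)) NULL else maybe_read(go, read_go)
  pathways <- if (is.null(pathways)) NULL else maybe_read(pathways, read_gmt)
  log_msg <- function(...) if (verbose) message("[spliceimpact] ", ...)

  log_msg(nrow(events), " events in")
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    base <- tibble::tibble(
      probeset_id = ev$probeset_id, gene_symbol = ev$gene_symbol,
      event_class = ev$event_class, host_transcript_id = NA_character_,
      region_class = "not_determined",
      coding_status_incl = NA_character_, coding_status_excl = NA_character_,
      len_incl = NA_integer_, len_excl = NA_integer_,
      prefix_len = NA_integer_, suffix_len = NA_integer_,
      n_altered = NA_integer_, frac_altered = NA_real_,
      protein_changed = NA, n_domains = NA_integer_, domain_changed = NA,
      domain_statuses = NA_character_, affected_region = NA_character_,
      overlap_tokens = NA_character_, passes_overlap_filter = NA,
      SI = ev$SI, FC = ev$FC, status = "ok")
    tryCatch({
      host_id <- tryCatch(pick_host_transcript(transcripts, ev),
                          error = function(e) {
                            stop(errorCondition(conditionMessage(e),
                                                class = "no_host_error"))
                          })
      base$host_transcript_id <- host_id
      pair <- build_pair(transcripts, ev, host_id = host_id)
      base$region_class <- classify_region(pair)
      p_incl <- translate_transcript(pair$inclusion, genome)
      if (p_incl$coding_status == "non_coding") {
        base$status <- "NON_CODING_HOST"
        return(base)
      }
      p_excl <- translate_transcript(pair$exclusion, genome)
      d <- diff_proteins(p_incl, p_excl)
      base$coding_status_incl <- p_incl$coding_status
      base$coding_status_excl <- p_excl$coding_status
      base$len_incl <- d$len_incl; base$len_excl <- d$len_excl
      base$prefix_len <- d$prefix_len; base$suffix_len <- d$suffix_len
      base$n_altered <- d$n_altered; base$frac_altered <- d$frac_altered
      base$protein_changed <- d$protein_changed
      dom <- domains_for(domains, host_id, ev$gene_symbol)
      ci <- classify_impact(dom, d)
      base$n_domains <- nrow(dom)
      base$domain_changed <- ci$domain_changed
      base$affected_region <- ci$affected_region
      base$domain_statuses <- paste(
        sprintf("%s:%s", ci$statuses$accession, ci$statuses$status),
        collapse = ";")
      base$passes_overlap_filter <- FALSE
      base$overlap_tokens <- ""
      if (ci$domain_changed && !is.null(go)) {
        terms <- go$go_term[go$gene_key == norm_symbol(ev$gene_symbol)]
        changed_desc <- ci$statuses$description[ci$statuses$status != "intact"]
        ov <- suppressWarnings(overlap_filter(changed_desc, terms, stopwords))
        base$overlap_tokens <- paste(ov$shared, collapse = ",")
        base$passes_overlap_filter <- ov$passes
      }
      base
    },
    no_host_error = function(e) { base$status <- "NO_HOST_TRANSCRIPT"; base },
    error = function(e) {
      base$status <- paste0("BUILD_FAILED: ", conditionMessage(e))
      base
    })
  })
  impact <- dplyr::bind_rows(rows)
  if (nrow(impact) == 0) {
    impact <- tibble::tibble(
      probeset_id = character(0), gene_symbol = character(0),
      event_class = character(0), host_transcript_id = character(0),
      region_class = character(0), coding_status_incl = character(0),
      coding_status_excl = character(0), len_incl = integer(0),
      len_excl = integer(0), prefix_len = integer(0), suffix_len = integer(0),
      n_altered = integer(0), frac_altered = numeric(0),
      protein_changed = logical(0), n_domains = integer(0),
      domain_changed = logical(0), domain_statuses = character(0),
      affected_region = character(0), overlap_tokens = character(0),
      passes_overlap_filter = logical(0), SI = numeric(0), FC = numeric(0),
      status = character(0))
  }

  ok <- impact[impact$status == "ok", , drop = FALSE]
  log_msg(nrow(ok), " events annotated, ", nrow(impact) - nrow(ok), " excluded")
  n_protein <- sum(ok$protein_changed, na.rm = TRUE)
  n_domain <- sum(ok$domain_changed, na.rm = TRUE)
  pass <- ok[!is.na(ok$passes_overlap_filter) & ok$passes_overlap_filter, , drop = FALSE]
  overlap_genes <- unique(norm_symbol(pass$gene_symbol))
  log_msg(n_protein, " protein-changing, ", n_domain, " domain-changing, ",
          length(overlap_genes), " genes pass the overlap filter")

  enrichment <- NULL
  if (!is.null(pathways) && !is.null(go) && length(overlap_genes) > 0) {
    universe <- unique(go$gene_key)
    enrichment <- enrich_pathways(pathways, overlap_genes, universe,
                                  p_threshold = p_threshold, p_adjust = p_adjust)
    log_msg("top pathway: ", enrichment$pathway_id[1],
            " (p = ", signif(enrichment$p_value[1], 3), ")")
  }

  breakdown <- table(factor(ok$region_class, levels = region_classes()))
  res <- structure(list(
    n_events = nrow(impact),
    n_annotated = nrow(ok),
    n_excluded = nrow(impact) - nrow(ok),
    n_protein_changed = n_protein,
    n_domain_changed = n_domain,
    n_overlap_genes = length(overlap_genes),
    n_overlap_probesets = nrow(pass),
    region_class_breakdown = tibble::tibble(
      region_class = names(breakdown), n = as.integer(breakdown)),
    impact = impact,
    enrichment = enrichment,
    p_threshold = p_threshold
  ), class = "splice_funnel")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(impact, file.path(out_dir, "impact.tsv"), progress = FALSE)
    readr::write_tsv(glance(res), file.path(out_dir, "funnel.tsv"), progress = FALSE)
    if (!is.null(enrichment)) {
      readr::write_tsv(tibble::as_tibble(unclass(enrichment)),
                       file.path(out_dir, "enrichment.tsv"), progress = FALSE)
    }
  }
  res
}

#' Replay a previously annotated DAS table
#'
#' Applies the recorded per-row annotations of an already analysed event
#' table (no recomputation of translations or domains) to reproduce its
#' funnel counts. The table must be a TSV with columns `probeset_id`,
#' `gene_symbol`, `protein_changed`, `domain_changed` and
#' `passes_overlap_filter`; truthy values are `TRUE/true/yes/y/1`.
#'
#' @param path Path to the annotated TSV.
#' @return A `splice_funnel` object (without enrichment).
#' @export
replay_das_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("probeset_id", "gene_symbol", "protein_changed", "domain_changed",
           "passes_overlap_filter")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("replay table is missing column(s): ", paste(miss, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  truthy <- function(x) tolower(trimws(x)) %in% c("true", "yes", "y", "1", "t")
  pc <- truthy(df$protein_changed)
  dc <- truthy(df$domain_changed)
  pf <- truthy(df$passes_overlap_filter)
  breakdown <- if ("region_class" %in% names(df)) {
    tb <- table(factor(df$region_class, levels = region_classes()))
    tibble::tibble(region_class = names(tb), n = as.integer(tb))
  } else {
    tibble::tibble(region_class = character(0), n = integer(0))
  }
  impact <- tibble::tibble(
    probeset_id = df$probeset_id, gene_symbol = df$gene_symbol,
    protein_changed = pc, domain_changed = dc, passes_overlap_filter = pf,
    status = "ok")
  structure(list(
    n_events = nrow(df),
    n_annotated = nrow(df),
    n_excluded = 0L,
    n_protein_changed = sum(pc),
    n_domain_changed = sum(dc),
    n_overlap_genes = length(unique(norm_symbol(df$gene_symbol[pf]))),
    n_overlap_probesets = sum(pf),
    region_class_breakdown = breakdown,
    impact = impact,
    enrichment = NULL,
    p_threshold = NA_real_
  ), class = "splice_funnel")
}

#' @export
print.splice_funnel <- function(x, ...) {
  cat("<splice_funnel>\n")
  cat("  events:                 ", x$n_events, "\n")
  cat("  annotated (excluded):   ", x$n_annotated, " (", x$n_excluded, ")\n", sep = "")
  cat("  protein-changing:       ", x$n_protein_changed, "\n")
  cat("  domain-changing:        ", x$n_domain_changed, "\n")
  cat("  overlap-filter genes:   ", x$n_overlap_genes,
      " (", x$n_overlap_probesets, " probesets)\n", sep = "")
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
    cat("  top pathway:            ", x$enrichment$pathway_id[1],
        " (p = ", signif(x$enrichment$p_value[1], 3), ")\n", sep = "")
  }
  invisible(x)
}

#' One-row funnel summary
#' @param x A `splice_funnel`.
#' @param ... Unused.
#' @return A one-row tibble of funnel counts (and the top pathway, when
#'   enrichment was run).
#' @export
glance.splice_funnel <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events,
    n_annotated = x$n_annotated,
    n_excluded = x$n_excluded,
    n_protein_changed = x$n_protein_changed,
    n_domain_changed = x$n_domain_changed,
    n_overlap_genes = x$n_overlap_genes,
    n_overlap_probesets = x$n_overlap_probesets,
    top_pathway = if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
      x$enrichment$pathway_id[1]
    } else NA_character_,
    top_pathway_p = if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
      x$enrichment$p_value[1]
    } else NA_real_
  )
}

#' Per-event impact table
#' @param x A `splice_funnel`.
#' @param ... Unused.
#' @return The per-event impact tibble (the pipeline's central output).
#' @export
tidy.splice_funnel <- function(x, ...) x$impact

#' Funnel and impact plots
#'
#' `type = "funnel"` draws the event funnel (all events, protein-changing,
#' domain-changing, overlap-passing probesets); `type = "impact"` draws the
#' altered-length versus altered-fraction scatter, coloured by domain
#' change, the classic view of how much of each protein an event rewrites.
#'
#' @param object A `splice_funnel`.
#' @param type `"funnel"` or `"impact"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_funnel <- function(object, type = c("funnel", "impact"), ...) {
  type <- match.arg(type)
  if (type == "funnel") {
    df <- tibble::tibble(
      stage = factor(c("DAS events", "protein changed", "domain changed",
                       "overlap filter"),
                     levels = c("DAS events", "protein changed",
                                "domain changed", "overlap filter")),
      n = c(object$n_annotated, object$n_protein_changed,
            object$n_domain_changed, object$n_overlap_probesets))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
        ggplot2::labs(x = NULL, y = "events") +
        ggplot2::theme_minimal()
    )
  }
  ok <- object$impact[object$impact$status == "ok" &
                        !is.na(object$impact$n_altered), , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$n_altered, y = .data$frac_altered,
                                   colour = .data$domain_changed,
                                   shape = .data$protein_changed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "altered residues", y = "fraction of full-length protein",
                  colour = "domain changed", shape = "protein changed") +
    ggplot2::theme_minimal()
}
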