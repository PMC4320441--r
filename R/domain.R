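# Domain-impact classification: interval arithmetic between the altered
# block of the inclusion protein and each annotated domain interval.

# The altered block on the inclusion protein: residues with no counterpart
# in the exclusion isoform.
altered_block <- function(diff) {
  c(start = diff$prefix_len, end = diff$len_incl - diff$suffix_len)
}

#' Classify the impact of an event on annotated protein domains
#'
#' Domains are annotated on the inclusion (reference) protein as 0-based
#' half-open residue intervals. Each domain is classified against the
#' altered block of the prefix/suffix decomposition:
#'
#' * `lost` - every domain residue is absent from the exclusion isoform;
#' * `truncated` - the exclusion protein is a pure C-terminal truncation
#'   (no common suffix, no divergent exclusion tail) that ends inside the
#'   domain;
#' * `internally_altered` - some but not all domain residues are absent or
#'   replaced (frameshift-divergent residues inside a domain count as
#'   altered: a divergent sequence cannot preserve the domain);
#' * `intact` - the domain is untouched.
#'
#' When no domain changes but the protein does, the affected region is
#' positional: `n_term` if all altered inclusion residues precede the first
#' domain start, `c_term` if all follow the last domain end (or a pure
#' extension/truncation point lies beyond it), otherwise `linker`. Proteins
#' with zero annotated domains use the same vocabulary by position: an
#' alteration touching the first residue is `n_term`, one touching the last
#' is `c_term`, anything else `linker`.
#'
#' @param domains Tibble of domain hits for this protein (internal 0-based
#'   coordinates, as from [read_domains()]); may have zero rows.
#' @param diff One-row tibble from [diff_proteins()].
#' @return A list with `statuses` (the `domains` tibble plus a `status`
#'   column), `domain_changed` (logical) and `affected_region` (one of
#'   `domain`, `n_term`, `c_term`, `linker`, `none`).
#' @export
classify_impact <- function(domains, diff) {
  L <- diff$len_incl
  if (nrow(domains) > 0 && any(domains$res_start < 0 | domains$res_end > L |
                               domains$res_start >= domains$res_end)) {
    stop("domain interval out of protein bounds (protein length ", L, ")",
         call. = FALSE)
  }
  blk <- altered_block(diff)
  bs <- blk[["start"]]; be <- blk[["end"]]
  pure_truncation <- diff$suffix_len == 0 && diff$altered_excl == 0 &&
    diff$altered_incl > 0

  status <- character(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    ds <- domains$res_start[i]; de <- domains$res_end[i]
    ov <- max(0L, min(de, be) - max(ds, bs))
    status[i] <- if (ov == de - ds) {
      "lost"
    } else if (ov == 0L) {
      "intact"
    } else if (pure_truncation && ds < bs) {
      "truncated"
    } else {
      "internally_altered"
    }
  }
  domain_changed <- any(status != "intact")

  affected <- if (domain_changed) {
    "domain"
  } else if (!diff$protein_changed) {
    "none"
  } else {
    block_empty <- be <= bs  # pure insertion/extension in the exclusion isoform
    if (nrow(domains) == 0) {
      if (block_empty) {
        if (bs == 0) "n_term" else if (bs >= L) "c_term" else "linker"
      } else if (bs == 0) {
        "n_term"
      } else if (be >= L) {
        "c_term"
      } else {
        "linker"
      }
    } else {
      first_dom <- min(domains$res_start)
      last_dom <- max(domains$res_end)
      if (block_empty) {
        if (bs <= first_dom) "n_term" else if (bs >= last_dom) "c_term" else "linker"
      } else if (be <= first_dom) {
        "n_term"
      } else if (bs >= last_dom) {
        "c_term"
      } else {
        "linker"
      }
    }
  }

  statuses <- domains
  statuses$status <- status
  list(statuses = statuses, domain_changed = domain_changed,
       affected_region = affected)
}
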