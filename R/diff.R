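# Block-level comparison of the inclusion and exclusion proteins.
# The difference model is a longest-common-prefix / longest-common-suffix
# decomposition: no alignment is attempted, so frameshift-divergent tails are
# captured as one altered block. Deterministic and symmetric by construction.

protein_seq <- function(x) {
  if (inherits(x, "protein_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1) return(x)
  stop("expected a protein_record or a single amino-acid string", call. = FALSE)
}

#' Compare two protein isoforms
#'
#' Decomposes the pair into the longest common prefix, the longest common
#' suffix of the remainders (capped so that prefix + suffix never exceeds the
#' shorter length), and the altered blocks in between. A non-coding isoform
#' is treated as length zero, so its whole counterpart is altered.
#'
#' `n_altered = max(altered_incl, altered_excl)` and
#' `frac_altered = n_altered / max(len_incl, len_excl)` (0 when both are
#' empty), matching a "length of altered protein sequence" and a "fraction of
#' the full-length protein" reading where the full-length form is the longer
#' one, which keeps the fraction in \[0, 1\].
#'
#' @param incl,excl `protein_record`s or plain amino-acid strings for the
#'   inclusion and exclusion isoforms.
#' @return A one-row tibble: `len_incl`, `len_excl`, `prefix_len`,
#'   `suffix_len`, `altered_incl`, `altered_excl`, `n_altered`,
#'   `frac_altered`, `protein_changed`.
#' @export
#' @examples
#' diff_proteins("MKLAVGDE", "MKLDE")
diff_proteins <- function(incl, excl) {
  a <- protein_seq(incl); b <- protein_seq(excl)
  ar <- charToRaw(a); br <- charToRaw(b)
  la <- length(ar); lb <- length(br)
  m <- min(la, lb)
  p <- 0L
  if (m > 0) {
    mism <- which(ar[seq_len(m)] != br[seq_len(m)])
    p <- if (length(mism) == 0) m else mism[1] - 1L
  }
  cap <- m - p
  s <- 0L
  if (cap > 0) {
    ta <- ar[seq.int(la, la - cap + 1L)]
    tb <- br[seq.int(lb, lb - cap + 1L)]
    mism <- which(ta != tb)
    s <- if (length(mism) == 0) cap else mism[1] - 1L
  }
  altered_incl <- la - p - s
  altered_excl <- lb - p - s
  n_altered <- max(altered_incl, altered_excl)
  denom <- max(la, lb)
  tibble::tibble(
    len_incl = as.integer(la), len_excl = as.integer(lb),
    prefix_len = as.integer(p), suffix_len = as.integer(s),
    altered_incl = as.integer(altered_incl),
    altered_excl = as.integer(altered_excl),
    n_altered = as.integer(n_altered),
    frac_altered = if (denom == 0) 0 else n_altered / denom,
    protein_changed = n_altered > 0
  )
}

#' Residue correspondence from the inclusion to the exclusion protein
#'
#' Prefix residues map by identity, suffix residues map with a constant
#' offset of `len_excl - len_incl`, and altered-block residues map to absent
#' (`NA`). This is the coordinate liftover that lets domain intervals
#' annotated on the inclusion protein be interrogated on the exclusion
#' isoform.
#'
#' @param diff A one-row tibble from [diff_proteins()].
#' @return An integer vector of length `len_incl`; element `i + 1` holds the
#'   0-based exclusion residue index of inclusion residue `i`, or `NA` if the
#'   residue is absent from the exclusion isoform.
#' @export
residue_map <- function(diff) {
  L <- diff$len_incl; Lx <- diff$len_excl
  p <- diff$prefix_len; s <- diff$suffix_len
  v <- rep(NA_integer_, L)
  if (p > 0) v[seq_len(p)] <- seq_len(p) - 1L
  if (s > 0) v[seq.int(L - s + 1L, L)] <- seq.int(L - s, L - 1L) + (Lx - L)
  v
}
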