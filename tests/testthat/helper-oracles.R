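# Independent oracles used to cross-check the implementation. These are
# deliberately written without reference to the package internals (and
# without Biostrings): plain loops, set membership and choose() sums.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# the standard genetic code, typed out
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# brute-force translation of an mRNA from a 0-based start offset: codon by
# codon until a stop or the end of the molecule
oracle_translate <- function(mrna, start0) {
  out <- character(0)
  i <- start0 + 1L
  while (i + 2L <= nchar(mrna)) {
    aa <- ORACLE_CODON[[substr(mrna, i, i + 2L)]]
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# brute-force spliced mRNA: substring each exon of the genomic sequence in
# genomic order, concatenate, reverse-complement for the minus strand
oracle_mrna <- function(chrom_seq, exon_starts, exon_ends, strand) {
  pieces <- character(length(exon_starts))
  for (i in seq_along(exon_starts)) {
    pieces[i] <- substr(chrom_seq, exon_starts[i] + 1L, exon_ends[i])
  }
  m <- paste(pieces, collapse = "")
  if (strand == "-") m <- oracle_revcomp(m)
  m
}

# per-residue materialisation of the inclusion -> exclusion correspondence:
# walk equal residues from the front, then from the back (never crossing),
# everything in between is absent
oracle_residue_sets <- function(incl, excl) {
  a <- strsplit(incl, "", fixed = TRUE)[[1]]
  b <- strsplit(excl, "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b); m <- min(la, lb)
  p <- 0L
  while (p < m && a[p + 1L] == b[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < m - p && a[la - s] == b[lb - s]) s <- s + 1L
  map <- rep(NA_integer_, la)
  for (i in seq_len(p)) map[i] <- i - 1L
  for (i in seq_len(s)) map[la - i + 1L] <- lb - i
  map
}

oracle_domain_status <- function(incl, excl, ds, de) {
  map <- oracle_residue_sets(incl, excl)
  la <- nchar(incl); lb <- nchar(excl)
  dom <- seq.int(ds + 1L, de)        # 1-based positions of domain residues
  absent <- is.na(map[dom])
  if (all(absent)) return("lost")
  if (!any(absent)) return("intact")
  mapped_all <- which(!is.na(map))
  # pure C-terminal truncation: the mapped residues are exactly a prefix of
  # the inclusion protein that accounts for the whole exclusion protein
  prefix_only <- length(mapped_all) > 0 &&
    identical(mapped_all, seq_len(max(mapped_all))) &&
    length(mapped_all) == lb
  if (prefix_only && max(mapped_all) < de) return("truncated")
  "internally_altered"
}

# upper-tail hypergeometric probability by explicit enumeration of the
# overlap count, through binomial coefficients
oracle_hyper_p <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  j <- seq.int(k, jmax)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
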