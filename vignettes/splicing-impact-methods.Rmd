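---
title: "Annotating the functional impact of alternative splicing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating the functional impact of alternative splicing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceimpact)
```

## The problem

Exon-level differential results are routinely reduced to their gene symbols
before downstream interpretation, discarding the one thing that makes them
interesting: whether swapping the exon in or out changes the protein, and
whether it changes the part of the protein that carries the gene's
annotated function. `spliceimpact` formalises that assessment as a funnel:

    DAS events → protein-changing events → domain-changing events
              → genes whose changed domain matches their GO annotation
              → most over-represented pathway

Each stage is a deterministic, testable operation over standard inputs
(GTF/GFF3, FASTA, TSV, GAF, GMT). This vignette records the model behind
each stage, the tunable parameters, and the design decisions that were
genuinely open, so a maintainer can see *why* the code does what it does.

## Coordinates

All internal coordinates — genomic and protein-residue — are 0-based
half-open, so widths are `end − start` and abutment is equality, with no ±1
arithmetic anywhere in the middle of the pipeline. Files keep their native
conventions and are converted only at the boundary: GTF/GFF3 and the
domains TSV are 1-based inclusive; the events TSV (a format this package
defines) is BED-like 0-based half-open. Round-trip identity of every
reader/writer pair is tested.

Gene symbols are matched case-insensitively after trimming, because
real inputs freely mix mouse-style (`Egfr`) and human-style (`EGFR`)
spellings across annotation sources.

## Building the isoform pair

The *inclusion* isoform carries the alternative region, the *exclusion*
isoform lacks it. The host transcript is named per event
(`host_transcript_id`); when absent, the fallback is the gene's transcript
with the longest total CDS, ties broken by lexicographically smallest id.
This replaces a manual "most representative transcript" choice with a
deterministic one — the single most consequential substitution in the
package, and the reason the host can always be overridden explicitly.

Per event class:

* `skipped_exon`, `alt_5ss`, `alt_3ss` — the region is subtracted from the
  exon chain. Splice-site variants are represented as sub-exon regions
  abutting an exon edge, so the builder trims exons rather than deleting
  them.
* `intron_retention` — the region must exactly span the intron between two
  consecutive exons; the inclusion isoform merges the three pieces into one
  exon. Requiring exact spanning (rather than any intronic interval) is
  deliberate: a partial retention would not produce a well-formed exon
  chain.
* `alt_promoter` / `alt_polyA` — the region plus all exonic sequence 5′ or
  3′ of it (in transcript orientation) is dropped, modelling transcripts
  that start or end elsewhere. These events can therefore remove long
  terminal protein segments.
* `complex` — no synthesis is attempted; the pair is two explicitly named
  transcripts. Multi-exon rearrangements have no single defensible
  reconstruction rule, so the package refuses to guess.

Events in UTRs are *not* discarded when the region classifies as
`utr_only`: alternative terminations through non-coding exons can still
change the protein (for instance by removing the start codon), so protein
change is always decided by translation, never by region class alone.

## Translation

The spliced mRNA is read from the annotated CDS start through to the first
stop codon — deliberately *past* the annotated CDS end, so a frameshift
created by a non-multiple-of-three deletion runs naturally into the old
3′ UTR and produces the divergent tail a real ribosome would. If the
anchored start codon was removed or broken by the event, the mRNA is
rescanned for the first AUG opening an ORF of at least 30 codons
(`rescan_min_codons`); if none exists, the isoform is non-coding. The
30-codon floor filters the spurious micro-ORFs any UTR contains; it is the
package's explicit substitute for an undefined manual judgement, and is a
parameter precisely because it is a judgement.

A stop codon ending more than 50 nt (`nmd_distance`) upstream of the last
exon–exon junction sets `coding_status = "premature_stop_flagged"`, the
standard nonsense-mediated-decay rule of thumb. The flag is informational
only; it feeds no filter, because transcript degradation is a statement
about abundance, not about what the encoded protein would be.

Only the standard genetic code is supported; selenocysteine recoding and
non-standard codes are out of scope. Unknown nucleotides translate to `X`
with a warning rather than an error, so one ambiguous base cannot abort a
whole run.

## Protein difference and domain liftover

The two proteins are compared as whole sequences by longest common prefix
and longest common suffix (capped so their sum never exceeds the shorter
protein). No alignment is computed: alignment would be slower,
parameter-laden, and — for the dominant event types (contiguous in-frame
indels, truncations, frameshift tails) — identical in outcome. The altered
fraction uses the *longer* protein as denominator, keeping it in [0, 1]
with the natural reading "fraction of the full-length protein" when the
full-length form is the longer one.

Domain intervals live on the inclusion protein. The prefix/suffix
decomposition induces a residue map (identity / constant offset / absent),
and each domain classifies as:

* `lost` — all residues absent;
* `truncated` — the exclusion protein is a pure C-terminal truncation
  (empty suffix, no divergent exclusion residues) ending inside the domain;
* `internally_altered` — some residues absent or replaced. A
  frameshift-divergent tail entering a domain is classified here rather
  than as truncation, on the principle that substituted residues cannot
  preserve a domain any better than missing ones;
* `intact` — otherwise.

When the protein changes but no domain does, the event is positioned
relative to the annotated domains: `n_term` if every altered residue
precedes the first domain, `c_term` if every one follows the last (or a
pure truncation/extension point lies beyond it), else `linker`. Proteins
with no annotated domains use the same vocabulary by position in the
protein (touching residue 0 → `n_term`, touching the end → `c_term`, else
`linker`; an alteration spanning the whole protein counts as `n_term`), so
the classification remains total.

Domains are only annotated on — and only assessed against — the inclusion
protein. Domains that would appear *de novo* in the exclusion isoform are
undetectable without re-scanning that isoform against domain models, which
the package deliberately does not do (see Limitations).

## The overlap filter

Tokenization is lowercase, split on any non-alphanumeric character, with
single-character tokens and stopwords removed. The shipped stopword list
(`inst/extdata/stopwords_english.txt`, ~70 entries) contains English
conjunctions, prepositions, and articles; articles are included because a
shared "the" is meaningless, and the file is overridable for a stricter
conjunctions-and-prepositions-only reading. There is deliberately no
stemming, lemmatization, or synonym expansion: exact token equality keeps
the filter auditable (a reviewer can point at the shared word), whereas
stemming would silently change which genes pass.

Only the descriptions of *changed* domains enter the comparison — an
intact domain sharing a word with the GO annotation says nothing about the
event. The fixture generator plants exactly this decoy (an intact domain
whose description matches a GO term) to keep the implementation honest. A
gene with no GO annotation fails the filter with a warning rather than an
error. GO term *names* are compared; when annotations arrive as GAF (which
carries identifiers, not names) the identifier is used as the term text,
so the TSV form is the intended input for this filter.

## Enrichment

`fisher_p(k, K, n, N)` is the one-sided upper-tail hypergeometric
probability `P(X ≥ k)`, computed through `stats::phyper` (log-space
internally). One-sided because the question is over-representation only.
No multiple-testing correction is applied by default — the significance
rule is the plain `p ≤ 0.01` — with Benjamini–Hochberg available behind
`p_adjust = "BH"` for users screening many pathways. The default universe
is the set of genes carrying GO annotations in the input, on the view that
a gene invisible to the filter should not inflate the background;
`enrich_pathways()` accepts any other universe. Ties are broken by larger
overlap `k`, then pathway id, making "the most affected pathway" (the
first row) deterministic.

## The synthetic fixture generator

`generate_fixture()` emulates exactly the statistical structure the funnel
assumes: genes of 3–10 exons on alternating strands, one planted event per
gene drawn from all seven event classes, domains placed at known residue
intervals so a controlled fraction of events hits one, GO terms that do or
do not share a token with the changed-domain description, and one pathway
planted to be over-represented among the passing genes. CDSs are built
from random stop-free, AUG-free codons with every exon's coding part a
whole number of codons, and events are applied at known codon offsets, so
both protein strings are known analytically at generation time; truth
labels are derived from those designed strings and domain intervals,
never through the genomic pipeline being tested. Flanking codons at event
boundaries are resampled to encode distinct amino acids so the altered
block cannot slide, and for promoter events the generator verifies that
the planted restart AUG is the first in the exclusion mRNA.

Defaults: 200 genes; event mix 25% skipped exon, 15% each alternative
5′/3′ splice site and intron retention, 10% each alternative promoter,
alternative polyadenylation and complex; 50% of protein-changing events
domain-affecting; 50% of domain-changing genes passing the overlap filter;
planted pathway of 15 genes drawing 10 from the passing set against ~10
background pathways of 15 random genes. These were chosen once as a
realistic regime in which every stage has work to do and every label value
occurs, and the planted pathway is recoverable but not trivially so.

What the generator does **not** emulate — and therefore what passing tests
do **not** show about real data: real exon structures and codon usage,
overlapping or nested events, expression noise in SI/FC (carried as inert
metadata), annotation errors, paralogy, or isoform-level abundance. The
fixtures validate the *logic* of the funnel, not its robustness to messy
annotation.

## Numerical and degenerate-input choices

* Hypergeometric tails agree with exhaustive `choose()`-based enumeration
  to below 1e-10 across the full `N ≤ 60` grid (tested).
* `frac_altered` is defined as 0 when both proteins are empty.
* Empty event tables produce a zero-count report, not an error; per-event
  failures carry reason codes (`NO_HOST_TRANSCRIPT`, `NON_CODING_HOST`,
  `BUILD_FAILED: …`) in the impact table and are excluded from counts.
* Identical inputs give byte-identical output tables; fixtures are
  byte-identical under the same seed (single RNG stream, no global state
  leakage thanks to `withr::local_seed`).

## Replay mode

`replay_das_table()` reproduces funnel counts from an *already annotated*
event table — it applies the table's recorded per-row labels without
recomputing translations or domains. This exists because stage
computations depend on the annotation snapshot they were run against
(transcript models, domain databases and GO all move), so re-running an
old study's funnel from raw inputs is not expected to reproduce its counts
exactly; replaying its recorded annotations is.

## Problem sizes used by the test suite

Unit tests run on hand-built toy genes and 20–30-gene fixtures; the
end-to-end recovery test uses the full 200-gene default; the translation
oracle covers 100 random CDSs over both strands, the domain oracle 1,000
random isoform pairs, and the Fisher oracle every configuration up to
`N = 60`. These sizes were chosen so each check has enough variety to
exercise every branch while the whole suite stays fast enough to run on
every change.

## Known limitations

* Domain gains confined to the exclusion isoform are invisible (no HMM or
  PSSM re-scanning of the minor isoform, no structural modelling).
* The prefix/suffix difference model reports a compound event (two
  separated altered blocks) as one spanning block.
* Token overlap is lexical: "ion" does not match "ions", and a shared but
  semantically weak word still passes the filter.
* The enrichment background is only as good as the GO input; no attempt is
  made to correct for annotation bias between pathways.
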