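# Word-overlap filter between changed-domain descriptions and GO term names.

#' Default stopword list
#'
#' English conjunctions, prepositions and articles, one token per line,
#' shipped as a versioned data file. Articles are included because "the"/"a"
#' overlaps carry no information; override with your own file for a
#' conjunctions-and-prepositions-only behaviour.
#'
#' @param path Optional path to an alternative stopword file.
#' @return Character vector of lowercase stopword tokens.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_english.txt",
                        package = "spliceimpact")
  }
  tolower(trimws(readLines(path, warn = FALSE)))
}

#' Tokenize free text into a comparable token set
#'
#' Lower-cases, splits on any non-alphanumeric character, drops stopwords
#' and single-character tokens, and de-duplicates. No stemming or
#' lemmatization is applied: "ions" and "ion" are different tokens, so the
#' comparison is plain word equality.
#'
#' @param text Character vector; elements are concatenated.
#' @param stopwords Stopword tokens; defaults to [default_stopwords()].
#' @return Character vector of unique tokens (possibly empty).
#' @export
#' @examples
#' tokenize_terms("binding of calcium and zinc")
tokenize_terms <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0) return(character(0))
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[^a-z0-9]+"))
  toks <- toks[nchar(toks) > 1]
  unique(setdiff(toks, stopwords))
}

#' Word-overlap filter between domain descriptions and GO terms
#'
#' A gene passes when the descriptions of its *changed* domains share at
#' least one non-stopword token with the names of the gene's GO terms.
#' Callers are expected to supply only descriptions of domains whose status
#' is not `intact`. A gene with no GO annotations never passes (with a
#' warning, not an error).
#'
#' @param domain_descriptions Character vector of changed-domain description
#'   texts.
#' @param go_terms Character vector of the gene's GO term names.
#' @param stopwords Stopword tokens; defaults to [default_stopwords()].
#' @return A list with `shared` (character vector of shared tokens) and
#'   `passes` (logical).
#' @export
#' @examples
#' overlap_filter("protein kinase domain", "protein kinase activity")
overlap_filter <- function(domain_descriptions, go_terms,
                           stopwords = default_stopwords()) {
  if (length(go_terms) == 0 || all(!nzchar(go_terms))) {
    warning("gene has no GO annotations; overlap filter cannot pass",
            call. = FALSE)
    return(list(shared = character(0), passes = FALSE))
  }
  d <- tokenize_terms(domain_descriptions, stopwords)
  g <- tokenize_terms(go_terms, stopwords)
  shared <- sort(intersect(d, g))
  list(shared = shared, passes = length(shared) > 0)
}
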