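# Interval arithmetic on 0-based half-open [start, end) integer intervals.
# All internal genomic and residue coordinates use this convention; file
# formats keep their native conventions and are converted at the boundary.
# Interval sets are data frames with integer columns `start` and `end`.

iv <- function(start, end) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

iv_empty <- function() iv(integer(0), integer(0))

iv_sort <- function(x) x[order(x$start, x$end), , drop = FALSE]

iv_width <- function(x) sum(x$end - x$start)

# Merge overlapping or bookended intervals into a disjoint sorted set.
iv_merge <- function(x) {
  if (nrow(x) == 0) return(iv_empty())
  x <- iv_sort(x)
  os <- x$start[1]; oe <- x$end[1]
  for (i in seq_len(nrow(x))[-1]) {
    j <- length(oe)
    if (x$start[i] <= oe[j]) {
      oe[j] <- max(oe[j], x$end[i])
    } else {
      os <- c(os, x$start[i]); oe <- c(oe, x$end[i])
    }
  }
  iv(os, oe)
}

# Set difference x \ cut, both interval sets.
iv_subtract <- function(x, cut) {
  cut <- iv_merge(cut)
  rs <- integer(0); re <- integer(0)
  for (i in seq_len(nrow(x))) {
    ss <- x$start[i]; se <- x$end[i]
    for (j in seq_len(nrow(cut))) {
      cs <- cut$start[j]; ce <- cut$end[j]
      ns <- integer(0); ne <- integer(0)
      for (k in seq_along(ss)) {
        a <- ss[k]; b <- se[k]
        if (ce <= a || cs >= b) { ns <- c(ns, a); ne <- c(ne, b); next }
        if (cs > a) { ns <- c(ns, a); ne <- c(ne, cs) }
        if (ce < b) { ns <- c(ns, ce); ne <- c(ne, b) }
      }
      ss <- ns; se <- ne
    }
    rs <- c(rs, ss); re <- c(re, se)
  }
  iv_sort(iv(rs, re))
}

iv_intersect <- function(x, y) {
  y <- iv_merge(y)
  rs <- integer(0); re <- integer(0)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) {
      a <- max(x$start[i], y$start[j])
      b <- min(x$end[i], y$end[j])
      if (a < b) { rs <- c(rs, a); re <- c(re, b) }
    }
  }
  iv_merge(iv(rs, re))
}

# Is [s, e) fully covered by the union of x?
iv_contains <- function(x, s, e) {
  iv_width(iv_intersect(x, iv(s, e))) == (e - s)
}

iv_overlaps <- function(x, s, e) {
  iv_width(iv_intersect(x, iv(s, e))) > 0
}

iv_equal <- function(x, y) {
  x <- iv_merge(x); y <- iv_merge(y)
  nrow(x) == nrow(y) && all(x$start == y$start) && all(x$end == y$end)
}
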