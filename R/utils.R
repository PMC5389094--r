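# Internal helpers shared across modules. All genomic intervals inside the
# package are 0-based half-open [start, end); conversion to and from the
# 1-based closed convention happens only at the GFF3 boundary (see io.R)
# and when building IRanges objects here.

# Convert a tibble with chrom/start/end (0-based half-open) to GRanges
# (1-based closed, as IRanges expects).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Overlap pairs (>= 1 bp) between two interval tibbles; returns a tibble of
# row indices into each input.
overlap_pairs <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  tibble(
    query_row = S4Vectors::queryHits(hits),
    subject_row = S4Vectors::subjectHits(hits)
  )
}

# Number of intervals in `subject` overlapping each interval of `query`.
count_overlapping <- function(query, subject) {
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject))
}

check_interval_frame <- function(df, what = "interval table") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing, collapse = ", ")))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("%s has start >= end at row(s) %s", what,
                  paste(head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Vectorised "does [s, e) overlap any of a set of merged, sorted intervals".
# cls_start/cls_end must be non-overlapping and sorted by start.
overlaps_any_sorted <- function(s, e, cls_start, cls_end) {
  k <- length(cls_start)
  i <- findInterval(s, cls_start)
  hit_left <- i >= 1L & cls_end[pmax(i, 1L)] > s
  j <- pmin(i + 1L, k)
  hit_right <- i < k & cls_start[j] < e
  hit_left | hit_right
}

# Merge possibly-overlapping intervals on one chromosome into sorted
# disjoint intervals (plain numeric version used by the shuffle test).
merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}
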