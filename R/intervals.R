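#' Pairwise overlap length between two sets of genomic ranges
#'
#' Element-wise (parallel) overlap in base pairs between `a[i]` and `b[i]`.
#' Ranges on different sequences overlap by 0 bp. Shorter arguments of
#' length 1 are recycled. Strand is ignored throughout: all overlap
#' arithmetic in this package is strand-agnostic.
#'
#' @param a,b GRanges of equal length (or either of length 1).
#' @return integer vector of overlap lengths in bp.
#' @examples
#' library(GenomicRanges)
#' a <- GRanges("chr1", IRanges(1, 100))    # [0,100) in 0-based terms
#' b <- GRanges("chr1", IRanges(51, 150))   # [50,150)
#' overlapLength(a, b)  # 50
#' @export
overlapLength <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) != n) {
    stopifnot(length(a) == 1L)
    a <- rep(a, n)
  }
  if (length(b) != n) {
    stopifnot(length(b) == 1L)
    b <- rep(b, n)
  }
  if (n == 0L) return(integer(0))
  ol <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  as.integer(ifelse(same, pmax(0L, ol), 0L))
}

#' Mutual overlap fraction
#'
#' Overlap length divided by the length of the *longer* of the two ranges.
#' This is the strictest of the common "reciprocal overlap" readings: a
#' mutual overlap of at least `f` implies the shared segment covers at
#' least a fraction `f` of both ranges. A TE instance is defined to match
#' a deletion when their mutual overlap is at least 0.9; deletion
#' redundancy uses a 0.5 threshold.
#'
#' @inheritParams overlapLength
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' library(GenomicRanges)
#' mutualOverlap(GRanges("chr1", IRanges(1, 100)),
#'               GRanges("chr1", IRanges(11, 110)))  # 0.9
#' @export
mutualOverlap <- function(a, b) {
  ol <- overlapLength(a, b)
  n <- length(ol)
  wa <- if (length(a) == n) width(a) else rep(width(a), n)
  wb <- if (length(b) == n) width(b) else rep(width(b), n)
  if (n == 0L) return(numeric(0))
  ol / pmax(wa, wb)
}

## Overlapping pairs between two range sets passing a mutual-overlap
## threshold; returns a data.frame of (query, subject) indices.
mutualOverlapPairs <- function(query, subject, minMutual) {
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(query = integer(0), subject = integer(0)))
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  mo <- mutualOverlap(query[qi], subject[si])
  keep <- mo >= minMutual
  data.frame(query = qi[keep], subject = si[keep])
}
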