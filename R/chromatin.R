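#' Tile chromosomes into fixed-width overlapping windows
#'
#' Windows of `width` bp stepping by `width - overlap` (defaults: 151 bp
#' windows, 76 bp shared between consecutive windows, i.e. step 75).
#' Tiling starts at the chromosome start; a final partial window is
#' dropped.
#'
#' @param chromLengths named vector of chromosome lengths.
#' @param width tile width in bp (default 151).
#' @param overlap bp shared by consecutive tiles (default 76; must be
#'   smaller than `width`).
#' @return GRanges of tiles.
#' @export
tileChromosomes <- function(chromLengths, width = 151, overlap = 76) {
  stopifnot(width > overlap, overlap >= 0)
  step <- width - overlap
  parts <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    if (len < width) return(GRanges())
    starts <- seq.int(1L, len - width + 1L, by = step)
    GRanges(ch, IRanges(starts, width = width))
  })
  out <- suppressWarnings(do.call(c, parts))
  if (is.null(out)) out <- GRanges()
  out
}

#' Merge passing score tiles and trim to fixed-width candidate regions
#'
#' Tiles scoring at least `scoreMin` are merged greedily left to right:
#' a tile joins the current region while it overlaps it and the merged
#' span stays within `maxSpan`; otherwise it opens a new region. Each
#' merged region takes the score of its best-scoring member and is then
#' trimmed symmetrically to `outWidth` bp (when the excess is odd, the
#' extra base is trimmed from the right).
#'
#' @param tiles GRanges from [tileChromosomes()] with a `score` metadata
#'   column (and optionally `cell_line`).
#' @param scoreMin minimum tile score (default 1).
#' @param maxSpan maximum merged span in bp (default 601, i.e. a run of 7
#'   default tiles).
#' @param outWidth width of the trimmed output regions (default 151).
#' @return GRanges of candidate regions with a `score` metadata column.
#' @export
mergeAndTrim <- function(tiles, scoreMin = 1, maxSpan = 601,
                         outWidth = 151) {
  stopifnot(is(tiles, "GRanges"), "score" %in% names(mcols(tiles)))
  pass <- tiles[mcols(tiles)$score >= scoreMin]
  if (length(pass) == 0L) {
    out <- GRanges()
    mcols(out)$score <- numeric(0)
    return(out)
  }
  pass <- pass[order(as.character(seqnames(pass)), start(pass))]
  ch <- as.character(seqnames(pass))
  s <- start(pass); e <- end(pass); sc <- mcols(pass)$score
  n <- length(pass)
  regChrom <- character(n); regStart <- regEnd <- integer(n)
  regScore <- numeric(n)
  nr <- 0L
  for (i in seq_len(n)) {
    if (nr > 0L && ch[i] == regChrom[nr] && s[i] <= regEnd[nr] + 0L &&
        max(e[i], regEnd[nr]) - regStart[nr] + 1L <= maxSpan) {
      regEnd[nr] <- max(regEnd[nr], e[i])
      regScore[nr] <- max(regScore[nr], sc[i])
    } else {
      nr <- nr + 1L
      regChrom[nr] <- ch[i]; regStart[nr] <- s[i]; regEnd[nr] <- e[i]
      regScore[nr] <- sc[i]
    }
  }
  w <- regEnd[1:nr] - regStart[1:nr] + 1L
  excess <- pmax(0L, w - as.integer(outWidth))
  left <- excess %/% 2L
  out <- GRanges(regChrom[1:nr],
                 IRanges(regStart[1:nr] + left,
                         width = pmin(w, as.integer(outWidth))))
  mcols(out)$score <- regScore[1:nr]
  out
}

#' Keep the top candidate regions to match a measured site count
#'
#' Final prediction step: rank candidate regions by score and keep the
#' best `nMeasured`, so the predicted hypersensitive-site count equals
#' the experimentally measured count for the same cell type. Ties at the
#' cut are broken by (score descending, chrom, start). If fewer
#' candidates exist than requested, all are returned with a warning.
#'
#' @param regions GRanges from [mergeAndTrim()] with a `score` column.
#' @param nMeasured number of measured hypersensitive sites.
#' @return GRanges of predicted hypersensitive sites.
#' @export
thresholdToCount <- function(regions, nMeasured) {
  if (nMeasured < 0) stop("nMeasured must be non-negative")
  ord <- order(-mcols(regions)$score, as.character(seqnames(regions)),
               start(regions))
  if (length(regions) < nMeasured) {
    warning("only ", length(regions), " candidate regions for ",
            nMeasured, " measured sites")
    return(regions[ord])
  }
  regions[ord[seq_len(nMeasured)]]
}

#' Hypersensitive fraction of a TE subfamily in one cell line
#'
#' Fraction of genomic instances (polymorphic or not) overlapping a
#' hypersensitive site by at least `minOverlap` bp.
#'
#' @param instances GRanges of all genomic instances of the subfamily.
#' @param dhs GRanges of (predicted or measured) hypersensitive sites.
#' @param minOverlap bp of overlap defining hypersensitivity of an
#'   instance (default 50).
#' @return fraction in \[0, 1\], or `NA` for an empty subfamily.
#' @export
hypersensitiveFraction <- function(instances, dhs, minOverlap = 50) {
  if (length(instances) == 0L) return(NA_real_)
  if (length(dhs) == 0L) return(0)
  hit <- countOverlaps(instances, dhs, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE) > 0L
  mean(hit)
}

#' Cell-type specificity summaries of hypersensitive fractions
#'
#' From a subfamily x cell-line matrix of hypersensitive fractions,
#' derives each subfamily's largest fraction (row maximum) and the
#' per-cell-line fold enrichment (fraction divided by the subfamily's
#' mean fraction across all cell lines; rows with mean 0 get `NA`).
#'
#' @param fractions numeric matrix, rows = subfamilies, columns = cell
#'   lines, values in \[0, 1\].
#' @return list with `fractions` (the input), `largestFraction` (named
#'   vector) and `foldEnrichment` (matrix).
#' @export
specificityMatrix <- function(fractions) {
  stopifnot(is.matrix(fractions))
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  rm <- rowMeans(fractions)
  fold <- sweep(fractions, 1, rm, "/")
  fold[rm == 0, ] <- NA_real_
  list(fractions = fractions,
       largestFraction = apply(fractions, 1, max),
       foldEnrichment = fold)
}

#' Select ancient reference subfamilies
#'
#' The reference set for hypersensitivity benchmarking: subfamilies old
#' and abundant enough that read mappability is not a systematic worry.
#'
#' @param tes TE annotation GRanges.
#' @param minDivergence minimum average divergence in percent
#'   (default 20).
#' @param minInstances minimum genomic instance count (default 1000).
#' @return character vector of subfamily names.
#' @export
ancientSubfamilies <- function(tes, minDivergence = 20,
                               minInstances = 1000) {
  sf <- mcols(tes)$subfamily
  avgDiv <- tapply(mcols(tes)$divergence, sf, mean)
  counts <- table(sf)
  names(which(avgDiv >= minDivergence &
              as.numeric(counts[names(avgDiv)]) >= minInstances))
}
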