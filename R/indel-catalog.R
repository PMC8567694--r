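#' Size-filter a deletion call set
#'
#' Deletions shorter than `minSize` are discarded: they are unlikely to
#' correspond to mobile-element insertions. The boundary is inclusive
#' (a deletion of exactly `minSize` bp is kept).
#'
#' @param indels GRanges of deletions (see [readDeletions()]).
#' @param minSize minimum deletion length in bp (default 50).
#' @return filtered GRanges.
#' @export
filterDeletions <- function(indels, minSize = 50) {
  stopifnot(is(indels, "GRanges"))
  indels[width(indels) >= minSize]
}

#' Build the deletion overlap graph
#'
#' Nodes are deletions; an edge connects two deletions whose mutual
#' overlap (overlap length / longer interval) is at least
#' `edgeThreshold`. Built with an interval index so runtime is near-linear
#' in the number of overlapping pairs.
#'
#' @param indels size-filtered GRanges of deletions with unique
#'   `indel_id` metadata.
#' @param edgeThreshold mutual-overlap fraction defining an edge
#'   (default 0.5).
#' @return an [IndelOverlapGraph-class] object.
#' @export
buildOverlapGraph <- function(indels, edgeThreshold = 0.5) {
  stopifnot(is(indels, "GRanges"), "indel_id" %in% names(mcols(indels)))
  ids <- mcols(indels)$indel_id
  if (anyDuplicated(ids)) stop("indel_id values must be unique")
  hits <- findOverlaps(indels, drop.self = TRUE, drop.redundant = TRUE,
                       ignore.strand = TRUE)
  edges <- matrix(integer(0), ncol = 2)
  if (length(hits)) {
    qi <- queryHits(hits)
    si <- subjectHits(hits)
    mo <- mutualOverlap(indels[qi], indels[si])
    keep <- mo >= edgeThreshold
    qi <- qi[keep]; si <- si[keep]
    edges <- cbind(pmin(qi, si), pmax(qi, si))
  }
  new("IndelOverlapGraph",
      nodes = ids,
      edges = edges,
      nodeKey = data.frame(chrom = as.character(seqnames(indels)),
                           start = start(indels), end = end(indels),
                           stringsAsFactors = FALSE),
      edgeThreshold = edgeThreshold)
}

#' Prune a deletion catalogue by iterative max-degree removal
#'
#' Repeatedly removes the node of currently highest degree from the
#' overlap graph, updating neighbour degrees after each removal, until no
#' edges remain. The surviving set is edge-free: no retained pair of
#' deletions reaches the edge threshold of mutual overlap. Ties in degree
#' are broken deterministically towards the node that is lexicographically
#' smallest by (chrom, start, end, indel_id), so the result does not
#' depend on input row order.
#'
#' @param graph an [IndelOverlapGraph-class] from [buildOverlapGraph()].
#' @return character vector of retained indel ids.
#' @export
pruneByDegree <- function(graph) {
  stopifnot(is(graph, "IndelOverlapGraph"))
  n <- length(graph@nodes)
  e <- graph@edges
  if (nrow(e) == 0L) return(graph@nodes)
  adj <- vector("list", n)
  byFrom <- split(e[, 2], factor(e[, 1], levels = seq_len(n)))
  byTo <- split(e[, 1], factor(e[, 2], levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- c(byFrom[[i]], byTo[[i]])
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  # deterministic tie-break rank
  k <- graph@nodeKey
  tieRank <- order(order(k$chrom, k$start, k$end, graph@nodes))
  while (TRUE) {
    liveDeg <- deg[alive]
    if (!length(liveDeg) || max(liveDeg) == 0L) break
    md <- max(liveDeg)
    cand <- which(alive & deg == md)
    v <- cand[which.min(tieRank[cand])]
    alive[v] <- FALSE
    nb <- adj[[v]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
    deg[v] <- 0L
  }
  graph@nodes[alive]
}

#' Build the non-redundant deletion catalogue
#'
#' Convenience wrapper chaining the size filter, the overlap graph and
#' the max-degree pruning. Discarded deletions are kept in the output
#' with `retained = FALSE`: the expanded pMEI scan still needs them
#' (see [expandedPmeiScan()]).
#'
#' @inheritParams filterDeletions
#' @inheritParams buildOverlapGraph
#' @return GRanges of all size-passing deletions with the `retained`
#'   metadata column set; `metadata()` carries the record-count funnel
#'   (`input`, `size_pass`, `retained`).
#' @export
buildIndelCatalog <- function(indels, minSize = 50, edgeThreshold = 0.5) {
  nInput <- length(indels)
  indels <- filterDeletions(indels, minSize = minSize)
  graph <- buildOverlapGraph(indels, edgeThreshold = edgeThreshold)
  keep <- pruneByDegree(graph)
  mcols(indels)$retained <- mcols(indels)$indel_id %in% keep
  metadata(indels)$funnel <- c(input = nInput,
                               size_pass = length(indels),
                               retained = sum(mcols(indels)$retained))
  indels
}

#' Write a deletion catalogue with retention status
#'
#' BED-like TSV: chrom, start (0-based), end, indel_id, status
#' (retained/discarded), source.
#'
#' @param catalog GRanges from [buildIndelCatalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  df <- data.frame(
    chrom = as.character(seqnames(catalog)),
    start = start(catalog) - 1L,
    end = end(catalog),
    indel_id = mcols(catalog)$indel_id,
    status = ifelse(mcols(catalog)$retained, "retained", "discarded"),
    source = mcols(catalog)$source
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
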