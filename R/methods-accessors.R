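#' @rdname RmsScreenResult-class
#' @export
setMethod("resultTable", "RmsScreenResult", function(x) x@table)

#' @rdname RmsScreenResult-class
#' @export
setMethod("rmsSubfamilies", "RmsScreenResult", function(x)
  x@table$subfamily[x@table$is_rms])

#' @rdname RmsScreenResult-class
#' @export
setMethod("pmeis", "RmsScreenResult", function(x) x@pmeis)

#' @describeIn RmsScreenResult-class record-count funnel of the screen.
#' @export
screenFunnel <- function(x) {
  stopifnot(is(x, "RmsScreenResult"))
  x@funnel
}

setMethod("show", "RmsScreenResult", function(object) {
  tab <- object@table
  cat("RmsScreenResult:", nrow(tab), "tested subfamilies,",
      sum(tab$is_rms), "called RMS at Q <=", object@qThreshold, "\n")
  cat("  true deletions:", object@nTrue,
      "| pseudo-indels:", format(object@nPseudo, big.mark = ","),
      "| pMEIs:", length(object@pmeis), "\n")
  if (nrow(tab)) {
    top <- utils::head(tab[, c("subfamily", "n_human_specific", "t_te",
                               "expected_matches", "fold_enrichment",
                               "q_value")], 5L)
    print(top, row.names = FALSE, digits = 3)
    if (nrow(tab) > 5L) cat("  ...", nrow(tab) - 5L, "more rows\n")
  }
})

#' @rdname SimulatedGenome-class
#' @export
setMethod("teAnnotation", "SimulatedGenome", function(x) x@tes)

#' @rdname SimulatedGenome-class
#' @export
setMethod("indelCalls", "SimulatedGenome", function(x) x@indels)

#' @rdname SimulatedGenome-class
#' @export
setMethod("crossGenomeMappings", "SimulatedGenome", function(x) x@mappings)

#' @rdname SimulatedGenome-class
#' @export
setMethod("simulationTruth", "SimulatedGenome", function(x) x@truth)

#' @describeIn SimulatedGenome-class chromosome lengths of the simulated
#'   genome.
#' @export
simChromLengths <- function(x) {
  stopifnot(is(x, "SimulatedGenome"))
  x@chromLengths
}

setMethod("show", "SimulatedGenome", function(object) {
  lab <- table(object@truth$indels$label)
  cat("SimulatedGenome:", length(object@chromLengths), "chromosome(s),",
      format(sum(object@chromLengths), big.mark = ","), "bp\n")
  cat("  TEs:", length(object@tes), "instances,",
      length(unique(object@tes$subfamily)), "subfamilies (",
      sum(object@truth$subfamilies$mobile), "mobile )\n")
  cat("  indels:", length(object@indels),
      sprintf("(pMEI %d, pMED %d, background %d)\n",
              sum(lab["pMEI"], na.rm = TRUE),
              sum(lab["pMED"], na.rm = TRUE),
              sum(lab["background"], na.rm = TRUE)))
})

#' @rdname EnrichmentResult-class
#' @export
setMethod("pValue", "EnrichmentResult", function(x) x@pValue)

#' @describeIn EnrichmentResult-class the underlying 2x2 table.
#' @export
enrichmentTable <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@table
}

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", object@description, "\n")
  cat("  universe", object@universeSize, "| overlap", object@overlap,
      "| one-sided Fisher p =", format(object@pValue, digits = 3), "\n")
  print(object@table)
})

#' @rdname IndelOverlapGraph-class
#' @export
setMethod("graphNodes", "IndelOverlapGraph", function(x) x@nodes)

#' @rdname IndelOverlapGraph-class
#' @export
setMethod("graphEdges", "IndelOverlapGraph", function(x) x@edges)

#' @rdname IndelOverlapGraph-class
#' @export
setMethod("nodeDegrees", "IndelOverlapGraph", function(x) {
  deg <- integer(length(x@nodes))
  if (nrow(x@edges)) {
    t1 <- tabulate(x@edges[, 1], nbins = length(x@nodes))
    t2 <- tabulate(x@edges[, 2], nbins = length(x@nodes))
    deg <- t1 + t2
  }
  names(deg) <- x@nodes
  deg
})

setMethod("show", "IndelOverlapGraph", function(object) {
  cat("IndelOverlapGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (mutual overlap >=",
      object@edgeThreshold, ")\n")
})
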