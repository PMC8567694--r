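#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps distanceToNearest mcols mcols<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

#' Overlap graph over a deletion catalogue
#'
#' Nodes are deletion records; an undirected edge connects two deletions
#' whose mutual overlap (overlap length divided by the longer interval)
#' reaches the edge threshold. The graph is the substrate for redundancy
#' pruning by iterative max-degree removal.
#'
#' @slot nodes character vector of indel identifiers.
#' @slot edges two-column integer matrix of node indices, each unordered
#'   pair stored once with `edges[, 1] < edges[, 2]`.
#' @slot nodeKey data.frame with columns `chrom`, `start`, `end` used for
#'   deterministic tie-breaking during pruning.
#' @slot edgeThreshold mutual-overlap fraction defining an edge.
#'
#' @seealso [buildOverlapGraph()], [pruneByDegree()]
#' @exportClass IndelOverlapGraph
setClass("IndelOverlapGraph",
  representation(
    nodes = "character",
    edges = "matrix",
    nodeKey = "data.frame",
    edgeThreshold = "numeric"
  )
)

setValidity("IndelOverlapGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1] == e[, 2]))
      msg <- c(msg, "self-edges are not allowed")
    if (any(e < 1L) || any(e > length(object@nodes)))
      msg <- c(msg, "edge endpoints must index into nodes")
    if (any(e[, 1] > e[, 2]))
      msg <- c(msg, "edges must be stored with smaller index first")
    if (anyDuplicated(paste(e[, 1], e[, 2])))
      msg <- c(msg, "duplicate edges")
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node ids must be unique")
  if (nrow(object@nodeKey) != length(object@nodes))
    msg <- c(msg, "nodeKey must have one row per node")
  if (length(msg)) msg else TRUE
})

#' Result of a recently-mobile-subfamily screen
#'
#' Container for the per-subfamily test table produced by [rmsScreen()] /
#' [rmsTest()]: true-indel and pseudo-indel match counts, fold enrichment
#' over the pseudo-indel null, one-sided Fisher p-values and
#' Benjamini-Hochberg Q-values, plus the pMEI call set and the record-count
#' funnel of the upstream filters.
#'
#' @slot table data.frame with one row per tested subfamily (those with at
#'   least one human-specific instance), sorted by Q-value: columns
#'   `subfamily`, `family`, `avg_divergence`, `n_human_specific`, `t_te`,
#'   `p_te`, `expected_matches`, `fold_enrichment`, `p_value`, `q_value`,
#'   `log10_q`, `is_rms`.
#' @slot nTrue number of retained (non-redundant) true deletions entering
#'   every contingency table.
#' @slot nPseudo number of pseudo-indels actually generated (after
#'   chromosome-boundary clipping), shared by every contingency table.
#' @slot qThreshold FDR threshold used for the RMS call.
#' @slot pmeis GRanges of pMEI TE instances (human-specific instances of
#'   called subfamilies matching a deletion, including matches to
#'   deletions discarded during redundancy pruning).
#' @slot funnel named integer vector of record counts after each pipeline
#'   stage.
#'
#' @seealso [rmsScreen()], [resultTable()], [rmsSubfamilies()], [pmeis()]
#' @exportClass RmsScreenResult
setClass("RmsScreenResult",
  representation(
    table = "data.frame",
    nTrue = "integer",
    nPseudo = "numeric",
    qThreshold = "numeric",
    pmeis = "GRanges",
    funnel = "integer"
  )
)

setValidity("RmsScreenResult", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("subfamily", "n_human_specific", "t_te", "p_te",
            "expected_matches", "fold_enrichment", "p_value", "q_value",
            "is_rms")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    msg <- c(msg, paste("table lacks columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(tab)) {
    if (any(tab$t_te < 0) || any(tab$t_te > object@nTrue))
      msg <- c(msg, "t_te out of [0, nTrue]")
    if (any(tab$p_te < 0) || any(tab$p_te > object@nPseudo))
      msg <- c(msg, "p_te out of [0, nPseudo]")
    if (any(tab$p_value < 0 | tab$p_value > 1))
      msg <- c(msg, "p_value out of [0, 1]")
    if (any(tab$q_value + 1e-12 < tab$p_value))
      msg <- c(msg, "q_value below p_value")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic genome with planted mobility truth
#'
#' Output of [simulateGenome()]: a TE annotation, per-instance
#' cross-genome mapped fractions, a deletion call set, and the truth labels
#' (pMEI / pMED / background per deletion; mobile flag per subfamily)
#' against which the screen can be scored.
#'
#' @slot tes GRanges TE annotation with mcols `subfamily`, `family`,
#'   `divergence`, `instance_id`.
#' @slot mappings data.frame (`instance_id`, `genome`, `mapped_fraction`).
#' @slot indels GRanges deletion calls with mcols `indel_id`, `svtype`,
#'   `source`.
#' @slot truth list with `indels` (data.frame `indel_id`, `label`,
#'   `te_instance_id`) and `subfamilies` (data.frame `subfamily`,
#'   `mobile`).
#' @slot chromLengths named numeric vector of chromosome lengths.
#' @slot config the [simulationConfig()] list that produced the object.
#'
#' @seealso [simulateGenome()], [recoveryHarness()]
#' @exportClass SimulatedGenome
setClass("SimulatedGenome",
  representation(
    tes = "GRanges",
    mappings = "data.frame",
    indels = "GRanges",
    truth = "list",
    chromLengths = "numeric",
    config = "list"
  )
)

setValidity("SimulatedGenome", function(object) {
  msg <- character()
  if (!all(c("instance_id", "genome", "mapped_fraction") %in%
           names(object@mappings)))
    msg <- c(msg, "mappings needs instance_id, genome, mapped_fraction")
  if (!all(c("indels", "subfamilies") %in% names(object@truth)))
    msg <- c(msg, "truth needs elements 'indels' and 'subfamilies'")
  else {
    ti <- object@truth$indels
    if (nrow(ti) != length(object@indels))
      msg <- c(msg, "truth$indels must label every indel")
    if (nrow(ti) && !all(ti$label %in% c("pMEI", "pMED", "background")))
      msg <- c(msg, "indel labels must partition into pMEI/pMED/background")
  }
  if (nrow(object@mappings) &&
      (any(object@mappings$mapped_fraction < 0) ||
       any(object@mappings$mapped_fraction > 1)))
    msg <- c(msg, "mapped_fraction out of [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fisher enrichment result
#'
#' A 2x2 contingency table over a finite universe together with the
#' one-sided (enrichment) Fisher exact p-value.
#'
#' @slot table 2x2 integer matrix; rows = in/out of the hit set, columns =
#'   in/out of the target set.
#' @slot universeSize number of universe members (sum of the table).
#' @slot overlap count in the top-left cell.
#' @slot pValue one-sided Fisher exact p-value (enrichment).
#' @slot description free-text label of the comparison.
#'
#' @seealso [subfamilySetEnrichment()], [geneProximityEnrichment()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(
    table = "matrix",
    universeSize = "integer",
    overlap = "integer",
    pValue = "numeric",
    description = "character"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (!all(dim(object@table) == c(2L, 2L)))
    msg <- c(msg, "table must be 2x2")
  else if (sum(object@table) != object@universeSize)
    msg <- c(msg, "table margins must sum to universeSize")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue out of [0, 1]")
  if (length(msg)) msg else TRUE
})
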