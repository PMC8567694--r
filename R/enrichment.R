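#' Default subfamily remap for consensus-only names
#'
#' Some published insertion catalogues use subfamily names with no
#' annotated instances in the reference assembly; aligning their
#' consensus sequences assigns them to annotated subfamilies. This table
#' carries the standard remapping used for the tumour-insertion
#' catalogue: AluYb11 to AluYb9, AluYe5 to AluYf4, and AluYi6, AluYk2 and
#' AluYk3 to AluY.
#'
#' @return data.frame with columns `from` and `to`.
#' @export
defaultSubfamilyRemap <- function() {
  data.frame(
    from = c("AluYb11", "AluYe5", "AluYi6", "AluYk2", "AluYk3"),
    to = c("AluYb9", "AluYf4", "AluY", "AluY", "AluY"),
    stringsAsFactors = FALSE
  )
}

#' Translate subfamily names through a remap table
#'
#' Names present in the remap's `from` column are replaced by the
#' corresponding `to` name; all other names pass through. Duplicates in
#' the input are preserved (the collapsed multiset is returned). When a
#' `universe` is supplied, every remap target must belong to it.
#'
#' @param names character vector of subfamily names.
#' @param remap data.frame with `from` and `to` columns (default:
#'   [defaultSubfamilyRemap()]).
#' @param universe optional character vector of valid annotation-set
#'   subfamily names.
#' @return character vector, same length as `names`.
#' @export
remapSubfamilies <- function(names, remap = defaultSubfamilyRemap(),
                             universe = NULL) {
  stopifnot(all(c("from", "to") %in% colnames(remap)))
  if (!is.null(universe)) {
    bad <- setdiff(remap$to, universe)
    if (length(bad))
      stop("remap target(s) absent from the subfamily universe: ",
           paste(bad, collapse = ", "))
  }
  hit <- match(names, remap$from)
  ifelse(is.na(hit), names, remap$to[hit])
}

.enrichmentFromTable <- function(tab, universeSize, description) {
  p <- fisherSubfamily(tab[1, 1], tab[2, 1],
                       tab[1, 1] + tab[1, 2], tab[2, 1] + tab[2, 2])
  new("EnrichmentResult",
      table = tab,
      universeSize = as.integer(universeSize),
      overlap = as.integer(tab[1, 1]),
      pValue = p,
      description = description)
}

#' Enrichment of a hit set for a target set of subfamilies
#'
#' One-sided Fisher's exact test of whether `hitSet` (e.g. the called
#' RMS list) over-represents `targetSet` (e.g. disease-associated or
#' tumour-mobilized subfamilies) within a finite subfamily universe. The
#' 2x2 table is `[[|hit n target|, |target \\ hit|], [|hit \\ target|,
#' |universe \\ (hit u target)|]]`.
#'
#' @param universe character vector (or its size is taken from
#'   `length(universe)`) of all tested subfamilies.
#' @param hitSet,targetSet character vectors, both subsets of `universe`.
#' @param description free-text label.
#' @return an [EnrichmentResult-class].
#' @examples
#' # disease-catalogue worked example: 464 tested subfamilies, 20 called,
#' # 10 disease-associated, 8 shared
#' res <- subfamilySetEnrichment(sprintf("sf%03d", 1:464),
#'                               sprintf("sf%03d", 1:20),
#'                               sprintf("sf%03d", c(1:8, 463, 464)))
#' signif(pValue(res), 2)  # 1.1e-10
#' @export
subfamilySetEnrichment <- function(universe, hitSet, targetSet,
                                   description = "subfamily set enrichment") {
  if (anyDuplicated(universe)) stop("universe members must be unique")
  if (!all(hitSet %in% universe))
    stop("hitSet is not a subset of the universe")
  if (!all(targetSet %in% universe))
    stop("targetSet is not a subset of the universe")
  hitSet <- unique(hitSet); targetSet <- unique(targetSet)
  a <- length(intersect(hitSet, targetSet))
  b <- length(setdiff(targetSet, hitSet))
  c <- length(setdiff(hitSet, targetSet))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "not target"),
                                c("in hits", "not in hits")))
  .enrichmentFromTable(tab, length(universe), description)
}

#' Enrichment of allele-specific expression near pMEIs
#'
#' Tests whether expressed genes lying close to a pMEI show an excess of
#' allele-specific expression (ASE). A gene is "flanking" when its
#' edge-to-edge distance to the nearest pMEI is strictly below
#' `maxDistance` (0 for overlap); the Fisher table contrasts ASE status
#' of flanking versus non-flanking expressed genes.
#'
#' @param pmeis GRanges of pMEI instances.
#' @param genes GRanges of gene bodies with a `gene_id` metadata column.
#' @param aseGenes character vector of ASE gene ids (subset of
#'   `expressedGenes`).
#' @param expressedGenes character vector of all expressed gene ids.
#' @param maxDistance strict distance cutoff in bp (default 50,000).
#' @return an [EnrichmentResult-class].
#' @export
geneProximityEnrichment <- function(pmeis, genes, aseGenes, expressedGenes,
                                    maxDistance = 50000) {
  stopifnot(is(genes, "GRanges"), "gene_id" %in% names(mcols(genes)))
  if (!all(aseGenes %in% expressedGenes))
    stop("aseGenes must be a subset of expressedGenes")
  expressed <- genes[mcols(genes)$gene_id %in% expressedGenes]
  flanking <- character(0)
  if (length(pmeis) && length(expressed)) {
    hits <- distanceToNearest(expressed, pmeis, ignore.strand = TRUE)
    near <- mcols(hits)$distance < maxDistance
    flanking <- unique(mcols(expressed)$gene_id[queryHits(hits)[near]])
  }
  expressedGenes <- unique(expressedGenes)
  aseGenes <- unique(aseGenes)
  a <- length(intersect(flanking, aseGenes))
  b <- length(setdiff(flanking, aseGenes))
  c <- length(setdiff(aseGenes, flanking))
  d <- length(setdiff(expressedGenes, union(flanking, aseGenes)))
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("flanking", "not flanking"),
                                c("ASE", "not ASE")))
  # enrichment of ASE among flanking genes: condition on the ASE margin
  p <- fisherSubfamily(a, c, a + b, c + d)
  new("EnrichmentResult",
      table = tab,
      universeSize = as.integer(length(expressedGenes)),
      overlap = as.integer(a),
      pValue = p,
      description = sprintf(
        "ASE enrichment among %d pMEI-flanking genes (< %d bp)",
        length(flanking), maxDistance))
}
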