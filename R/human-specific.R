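#' Flag human-specific TE instances from cross-genome mapped fractions
#'
#' A TE instance counts as human-specific when no more than `maxFraction`
#' of its span maps to *any* of the non-human genomes surveyed (the
#' boundary is inclusive: a mapped fraction of exactly `maxFraction`
#' still qualifies). The mapping table may be sparse; an instance/genome
#' pair absent from the table is an unmapped instance, i.e. fraction 0.
#'
#' @param tes GRanges TE annotation (see [readRepeatMasker()]) with an
#'   `instance_id` metadata column.
#' @param mappings data.frame with columns `instance_id`, `genome`,
#'   `mapped_fraction` (see [readMappings()]). Rows referencing unknown
#'   instance ids are an error.
#' @param maxFraction largest cross-genome mapped fraction compatible with
#'   human specificity (default 0.20).
#' @return `tes` with the `human_specific` metadata column filled in.
#' @export
classifyHumanSpecific <- function(tes, mappings, maxFraction = 0.20) {
  stopifnot(is(tes, "GRanges"), "instance_id" %in% names(mcols(tes)))
  ids <- mcols(tes)$instance_id
  unknown <- setdiff(unique(mappings$instance_id), ids)
  if (length(unknown))
    stop("mapping rows reference unknown instance_id(s): ",
         paste(utils::head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) sprintf(" (and %d more)",
                                            length(unknown) - 10L) else "")
  maxFrac <- rep(0, length(tes))
  if (nrow(mappings)) {
    agg <- tapply(mappings$mapped_fraction, mappings$instance_id, max)
    idx <- match(names(agg), ids)
    maxFrac[idx] <- as.numeric(agg)
  }
  mcols(tes)$human_specific <- maxFrac <= maxFraction
  tes
}

#' Drop TE instances completely contained within tandem repeats
#'
#' Candidate human-specific instances fully contained in a tandem-repeat
#' interval are removed as potential tandem duplications; instances
#' overlapping a tandem repeat only partially are kept.
#'
#' @param tes GRanges TE annotation.
#' @param track GRanges of tandem-repeat intervals (e.g. imported from
#'   BED with [rtracklayer::import()]).
#' @return filtered GRanges.
#' @export
filterTandemContained <- function(tes, track) {
  stopifnot(is(tes, "GRanges"), is(track, "GRanges"))
  if (length(track) == 0L || length(tes) == 0L) return(tes)
  contained <- countOverlaps(tes, track, type = "within",
                             ignore.strand = TRUE) > 0L
  tes[!contained]
}
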