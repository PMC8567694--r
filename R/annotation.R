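#' Classify the genomic context of pMEIs
#'
#' Assigns exactly one context label per pMEI with the precedence
#' exonic > promoter > intronic > intergenic:
#' * **exonic** — at least 5 bp overlap with an exon;
#' * **promoter** — at least 50 bp overlap with a strand-aware promoter
#'   window (2 kb upstream to 1 kb downstream of a TSS);
#' * **intronic** — any overlap with a gene body;
#' * **intergenic** — none of the above.
#'
#' @param pmeis GRanges of pMEI instances.
#' @param genes GRanges of gene bodies with `gene_id`; strand determines
#'   the TSS and promoter orientation.
#' @param exons GRanges of exons.
#' @param minExonOverlap bp of exon overlap required for "exonic"
#'   (default 5).
#' @param minPromoterOverlap bp of promoter-window overlap required for
#'   "promoter" (default 50).
#' @param promoterUp,promoterDown promoter window extent around the TSS
#'   in bp (defaults 2000 upstream, 1000 downstream).
#' @return factor of contexts with levels exonic, promoter, intronic,
#'   intergenic (a partition: every pMEI gets exactly one label).
#' @export
classifyContext <- function(pmeis, genes, exons,
                            minExonOverlap = 5, minPromoterOverlap = 50,
                            promoterUp = 2000, promoterDown = 1000) {
  stopifnot(is(pmeis, "GRanges"), is(genes, "GRanges"), is(exons, "GRanges"))
  lv <- c("exonic", "promoter", "intronic", "intergenic")
  n <- length(pmeis)
  ctx <- rep("intergenic", n)
  if (length(genes)) {
    inGene <- countOverlaps(pmeis, genes, ignore.strand = TRUE) > 0L
    ctx[inGene] <- "intronic"
    prom <- GenomicRanges::promoters(genes, upstream = promoterUp,
                                     downstream = promoterDown)
    prom <- GenomicRanges::trim(suppressWarnings(prom))
    inProm <- countOverlaps(pmeis, prom,
                            minoverlap = as.integer(minPromoterOverlap),
                            ignore.strand = TRUE) > 0L
    ctx[inProm] <- "promoter"
  }
  if (length(exons)) {
    inExon <- countOverlaps(pmeis, exons,
                            minoverlap = as.integer(minExonOverlap),
                            ignore.strand = TRUE) > 0L
    ctx[inExon] <- "exonic"
  }
  factor(ctx, levels = lv)
}

#' Nearest gene (by TSS) for each pMEI
#'
#' Ties on TSS distance are broken lexicographically by gene id.
#'
#' @inheritParams classifyContext
#' @return data.frame with `gene_id` and `distance` (bp, edge-to-TSS; NA
#'   when no gene exists on any chromosome).
#' @export
nearestGene <- function(pmeis, genes) {
  n <- length(pmeis)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n))
  if (n == 0L || length(genes) == 0L) return(out)
  tss <- GenomicRanges::resize(genes, width = 1L, fix = "start",
                               ignore.strand = FALSE)
  ord <- order(mcols(genes)$gene_id)
  tss <- tss[ord]  # lexicographic tie-break: nearest() keeps first hit
  hits <- distanceToNearest(pmeis, tss, ignore.strand = TRUE, select = "all")
  if (length(hits)) {
    df <- data.frame(q = queryHits(hits), s = subjectHits(hits),
                     d = mcols(hits)$distance)
    df <- df[order(df$q, df$d, df$s), ]
    df <- df[!duplicated(df$q), ]
    out$gene_id[df$q] <- mcols(tss)$gene_id[df$s]
    out$distance[df$q] <- df$d
  }
  out
}

#' Assign candidate cis-regulatory element labels to pMEIs
#'
#' Each cCRE interval is first extended (`slop`) by 50 bp on both sides
#' to compensate for the low read mappability of young TE sequence; a
#' label is assigned whenever the pMEI overlaps the extended interval by
#' at least 1 bp. A pMEI can carry several labels (or none).
#'
#' @param pmeis GRanges of pMEI instances.
#' @param ccres GRanges of cCREs with a `label` metadata column (e.g.
#'   promoter-like / proximal-enhancer-like / distal-enhancer-like).
#' @param slop bp added to each side of every cCRE (default 50).
#' @return CharacterList, one (possibly empty) set of labels per pMEI.
#' @export
assignCcre <- function(pmeis, ccres, slop = 50) {
  stopifnot(is(pmeis, "GRanges"))
  out <- rep(list(character(0)), length(pmeis))
  if (length(ccres)) {
    stopifnot("label" %in% names(mcols(ccres)))
    ext <- suppressWarnings(ccres + slop)
    ext <- GenomicRanges::trim(ext)
    hits <- findOverlaps(pmeis, ext, ignore.strand = TRUE)
    if (length(hits)) {
      lab <- split(as.character(mcols(ccres)$label[subjectHits(hits)]),
                   factor(queryHits(hits), levels = seq_along(pmeis)))
      out <- lapply(lab, function(x) sort(unique(x)))
    }
  }
  IRanges::CharacterList(out)
}

#' Full pMEI annotation table
#'
#' Combines [classifyContext()], [nearestGene()] and [assignCcre()] into
#' one table.
#'
#' @inheritParams classifyContext
#' @param ccres optional labelled cCRE GRanges.
#' @param slop cCRE extension in bp (default 50).
#' @return DataFrame with `instance_id`, `subfamily`, `context`,
#'   `nearest_gene`, `distance` and `ccre_labels`.
#' @export
annotatePmeis <- function(pmeis, genes, exons, ccres = NULL, slop = 50) {
  ctx <- classifyContext(pmeis, genes, exons)
  ng <- nearestGene(pmeis, genes)
  labels <- if (is.null(ccres)) IRanges::CharacterList(
    rep(list(character(0)), length(pmeis)))
    else assignCcre(pmeis, ccres, slop = slop)
  DataFrame(
    instance_id = if ("instance_id" %in% names(mcols(pmeis)))
      mcols(pmeis)$instance_id else as.character(seq_along(pmeis)),
    subfamily = if ("subfamily" %in% names(mcols(pmeis)))
      mcols(pmeis)$subfamily else NA_character_,
    context = ctx,
    nearest_gene = ng$gene_id,
    distance = ng$distance,
    ccre_labels = labels
  )
}
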