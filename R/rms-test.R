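#' Tile pseudo-indels into the flanks of true deletions
#'
#' Each true deletion of length L is complemented by `nTotal` simulated
#' deletions ("pseudo-indels") of the same length, split evenly between
#' the two flanks. Tiles are laid outward starting flush with the
#' deletion boundaries: the innermost right tile starts where the
#' deletion ends and the innermost left tile ends where it starts.
#' Consecutive same-side tiles overlap by `floor(L / 2)` bp (the tiling
#' step is `L - floor(L / 2)`), i.e. by 50% of their length up to
#' rounding for odd L. Tiles that would extend past a chromosome end are
#' dropped, so the realised total can fall short of
#' `length(indels) * nTotal`; contingency tables must use the realised
#' count, which the attached metadata records.
#'
#' @param indels GRanges of true deletions (the retained catalogue).
#' @param nTotal pseudo-indels per deletion (must be even; default 500,
#'   i.e. 250 per side).
#' @param chromLengths named vector of chromosome lengths covering every
#'   chromosome in `indels`.
#' @return GRanges of pseudo-indels with metadata columns `parent_id`,
#'   `side` ("left"/"right") and `rank` (1 = innermost);
#'   `metadata()$nominal` and `metadata()$generated` record the tile
#'   bookkeeping.
#' @examples
#' library(GenomicRanges)
#' del <- GRanges("chr1", IRanges(10001, 10100))  # [10000,10100) 0-based
#' mcols(del)$indel_id <- "d1"
#' ps <- generatePseudoIndels(del, nTotal = 500, c(chr1 = 1e7))
#' length(ps)  # 500
#' @export
generatePseudoIndels <- function(indels, nTotal = 500, chromLengths) {
  stopifnot(is(indels, "GRanges"), nTotal >= 2, nTotal %% 2 == 0)
  ids <- if ("indel_id" %in% names(mcols(indels))) mcols(indels)$indel_id
         else as.character(seq_along(indels))
  chrom <- as.character(seqnames(indels))
  missing <- setdiff(unique(chrom), names(chromLengths))
  if (length(missing))
    stop("chromLengths lacks: ", paste(missing, collapse = ", "))
  if (length(indels) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(parent_id = character(0), side = character(0),
                            rank = integer(0))
    metadata(out) <- list(nominal = 0, generated = 0)
    return(out)
  }
  nSide <- nTotal %/% 2L
  L <- width(indels)
  step <- L - L %/% 2L
  idx <- rep(seq_along(indels), each = nSide)
  k <- rep.int(seq_len(nSide), length(indels))
  Li <- L[idx]
  off <- (k - 1L) * step[idx]
  chromI <- chrom[idx]
  clen <- unname(chromLengths[chromI])

  rs <- end(indels)[idx] + off + 1
  re <- rs + Li - 1
  keepR <- re <= clen
  le <- start(indels)[idx] - 1 - off
  ls <- le - Li + 1
  keepL <- ls >= 1

  right <- GRanges(chromI[keepR], IRanges(rs[keepR], re[keepR]))
  mcols(right) <- DataFrame(parent_id = ids[idx][keepR], side = "right",
                            rank = k[keepR])
  left <- GRanges(chromI[keepL], IRanges(ls[keepL], le[keepL]))
  mcols(left) <- DataFrame(parent_id = ids[idx][keepL], side = "left",
                           rank = k[keepL])
  out <- c(left, right)
  metadata(out) <- list(nominal = length(indels) * nTotal,
                        generated = length(out))
  out
}

#' Does a TE instance match a deletion?
#'
#' Element-wise test of the pMEI boundary signature: a TE instance
#' matches a deletion when the two segments show at least `minMutual`
#' (default 90%) mutual overlap.
#'
#' @param te,indel GRanges (parallel, recycled like [overlapLength()]).
#' @param minMutual match threshold on the mutual-overlap fraction.
#' @return logical vector.
#' @export
matchTE <- function(te, indel, minMutual = 0.9) {
  mutualOverlap(te, indel) >= minMutual
}

#' Per-subfamily match counts against true and pseudo-indels
#'
#' Counts, for one subfamily, the number of true deletions (T_TE) and of
#' pseudo-indels (P_TE) matched by at least one human-specific instance
#' of the subfamily. Each deletion or pseudo-indel is counted at most
#' once, however many instances match it.
#'
#' @param subfamily subfamily name.
#' @param hsTes GRanges of human-specific TE instances (any subfamilies;
#'   filtered internally).
#' @param trueIndels GRanges of retained true deletions.
#' @param pseudoIndels GRanges from [generatePseudoIndels()].
#' @param minMutual match threshold (default 0.9).
#' @return named integer vector `c(t_te = , p_te = )`.
#' @export
countMatches <- function(subfamily, hsTes, trueIndels, pseudoIndels,
                         minMutual = 0.9) {
  sel <- hsTes[mcols(hsTes)$subfamily == subfamily]
  pt <- mutualOverlapPairs(sel, trueIndels, minMutual)
  pp <- mutualOverlapPairs(sel, pseudoIndels, minMutual)
  c(t_te = length(unique(pt$subject)), p_te = length(unique(pp$subject)))
}

## log(sum(exp(x))) without overflow
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Upper tail P(X >= x) of Hypergeometric(m white, n black, k drawn),
## summed term-by-term in log space.
.hyperUpperTail <- function(x, m, n, k) {
  lo <- max(0, k - n)
  hi <- min(m, k)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  xs <- x:hi
  lt <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  min(1, exp(.logSumExp(lt)))
}

#' One-sided Fisher exact test for subfamily enrichment
#'
#' Exact p-value for an excess of true-deletion matches relative to
#' pseudo-indel matches, i.e. the upper hypergeometric tail of the 2x2
#' table `[[tTE, nTrue - tTE], [pTE, nPseudo - pTE]]`. Terms are summed
#' in log space for numerical stability at the very small p-values the
#' screen produces.
#'
#' @param tTE,pTE matched true-deletion and pseudo-indel counts.
#' @param nTrue,nPseudo total true deletions and total pseudo-indels
#'   actually generated.
#' @return p-value in \[0, 1\]. Vectorised over its arguments.
#' @examples
#' fisherSubfamily(8, 12, 10, 454)   # 1.078e-10
#' @export
fisherSubfamily <- function(tTE, pTE, nTrue, nPseudo) {
  n <- max(length(tTE), length(pTE), length(nTrue), length(nPseudo))
  tTE <- rep_len(tTE, n); pTE <- rep_len(pTE, n)
  nTrue <- rep_len(nTrue, n); nPseudo <- rep_len(nPseudo, n)
  bad <- tTE < 0 | pTE < 0 | tTE > nTrue | pTE > nPseudo
  if (any(bad))
    stop("inconsistent contingency counts (need 0 <= tTE <= nTrue, ",
         "0 <= pTE <= nPseudo)")
  vapply(seq_len(n), function(i) {
    .hyperUpperTail(tTE[i], m = tTE[i] + pTE[i],
                    n = (nTrue[i] - tTE[i]) + (nPseudo[i] - pTE[i]),
                    k = nTrue[i])
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate Q-values over the tested subfamilies
#' (thin wrapper over [stats::p.adjust()]; `m` defaults to the number of
#' p-values supplied, i.e. the subfamilies with at least one
#' human-specific instance).
#'
#' @param p p-values in \[0, 1\].
#' @param m number of tests (defaults to `length(p)`).
#' @return Q-values, same length as `p`.
#' @export
bhAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH", n = m)
}

#' Designate recently mobile subfamilies
#'
#' Applies the FDR threshold (inclusive: Q exactly at the threshold is
#' called) and returns the table sorted by Q, then p, then subfamily.
#'
#' @param table per-subfamily result data.frame carrying at least
#'   `subfamily`, `p_value` and `q_value` columns (from [rmsTest()]).
#' @param qThreshold FDR threshold (default 0.001).
#' @return the table with the `is_rms` logical column set, sorted by
#'   ascending Q.
#' @export
callRms <- function(table, qThreshold = 0.001) {
  if (nrow(table) == 0L) {
    table$is_rms <- logical(0)
    return(table)
  }
  table$is_rms <- table$q_value <= qThreshold
  table <- table[order(table$q_value, table$p_value, table$subfamily), ]
  rownames(table) <- NULL
  table
}

#' Per-subfamily pseudo-indel enrichment test
#'
#' The screen's core statistic. For every subfamily with at least one
#' human-specific instance, counts true deletions and pseudo-indels
#' matched (>= `minMutual` mutual overlap) by a human-specific instance
#' of that subfamily, forms the shared-margin 2x2 table against the
#' totals, and computes the one-sided Fisher p with BH Q-values across
#' the tested subfamilies. Expected matches are scaled from the
#' pseudo-indel match rate (`p_te * nTrue / nPseudo`); fold enrichment is
#' `t_te / expected` (infinite when expected is 0 but matches exist).
#'
#' @param tes full TE annotation with `human_specific` set (see
#'   [classifyHumanSpecific()]).
#' @param trueIndels GRanges of retained true deletions.
#' @param pseudoIndels GRanges from [generatePseudoIndels()] (its
#'   metadata supplies the realised pseudo-indel total).
#' @param minMutual match threshold (default 0.9).
#' @return data.frame, one row per tested subfamily, with match counts,
#'   expected matches, fold enrichment, `p_value`, `q_value`, `log10_q`
#'   (finite even where `q_value` underflows to 0 is not attempted;
#'   `log10(q)`), and `is_rms` initialised to `NA`.
#' @export
rmsTest <- function(tes, trueIndels, pseudoIndels, minMutual = 0.9) {
  stopifnot(is(tes, "GRanges"), "human_specific" %in% names(mcols(tes)))
  hs <- tes[mcols(tes)$human_specific %in% TRUE]
  tested <- sort(unique(mcols(hs)$subfamily))
  nTrue <- length(trueIndels)
  nPseudo <- metadata(pseudoIndels)$generated
  if (is.null(nPseudo)) nPseudo <- length(pseudoIndels)

  tTE <- pTE <- integer(length(tested))
  names(tTE) <- names(pTE) <- tested
  if (length(hs)) {
    sf <- mcols(hs)$subfamily
    pt <- mutualOverlapPairs(hs, trueIndels, minMutual)
    if (nrow(pt)) {
      agg <- tapply(pt$subject, sf[pt$query],
                    function(v) length(unique(v)))
      tTE[names(agg)] <- as.integer(agg)
    }
    pp <- mutualOverlapPairs(hs, pseudoIndels, minMutual)
    if (nrow(pp)) {
      agg <- tapply(pp$subject, sf[pp$query],
                    function(v) length(unique(v)))
      pTE[names(agg)] <- as.integer(agg)
    }
  }
  p <- fisherSubfamily(tTE, pTE, nTrue, nPseudo)
  q <- bhAdjust(p)
  expected <- pTE * nTrue / nPseudo
  fold <- ifelse(expected > 0, tTE / expected,
                 ifelse(tTE > 0, Inf, NA_real_))
  nHs <- table(factor(mcols(hs)$subfamily, levels = tested))
  allSf <- mcols(tes)$subfamily
  avgDiv <- tapply(mcols(tes)$divergence, allSf, mean)
  fam <- tapply(as.character(mcols(tes)$family), allSf, `[`, 1L)
  data.frame(
    subfamily = tested,
    family = as.character(fam[tested]),
    avg_divergence = as.numeric(avgDiv[tested]),
    n_human_specific = as.integer(nHs),
    t_te = unname(tTE),
    p_te = unname(pTE),
    n_true = nTrue,
    n_pseudo = nPseudo,
    expected_matches = unname(expected),
    fold_enrichment = unname(fold),
    p_value = unname(p),
    q_value = unname(q),
    log10_q = suppressWarnings(log10(unname(q))),
    is_rms = NA,
    stringsAsFactors = FALSE
  )
}

#' Expanded pMEI scan over retained and discarded deletions
#'
#' Once subfamilies are called, the pMEI list is completed by scanning
#' human-specific instances of the called subfamilies against *all*
#' deletions, including those discarded during redundancy pruning (their
#' matches are genuine insertions whose deletion record merely duplicated
#' another). TE instances are deduplicated by `instance_id`.
#'
#' @param rmsSet character vector of called subfamily names.
#' @param tes TE annotation with `human_specific` set.
#' @param allIndels GRanges of all size-passing deletions (retained and
#'   discarded; see [buildIndelCatalog()]).
#' @param minMutual match threshold (default 0.9).
#' @return GRanges of pMEI TE instances (unique), with an
#'   `n_matched_indels` metadata column.
#' @export
expandedPmeiScan <- function(rmsSet, tes, allIndels, minMutual = 0.9) {
  sel <- tes[mcols(tes)$human_specific %in% TRUE &
             mcols(tes)$subfamily %in% rmsSet]
  pairs <- mutualOverlapPairs(sel, allIndels, minMutual)
  if (nrow(pairs) == 0L) return(sel[0])
  idx <- sort(unique(pairs$query))
  out <- sel[idx]
  nm <- tabulate(pairs$query, nbins = length(sel))[idx]
  mcols(out)$n_matched_indels <- nm
  out
}

#' Run the full recently-mobile-subfamily screen
#'
#' End-to-end pipeline: human-specificity classification from mapped
#' fractions, tandem-repeat containment filter, deletion size filter and
#' redundancy pruning, pseudo-indel tiling, per-subfamily Fisher tests
#' with BH FDR, RMS designation, and the expanded pMEI scan.
#'
#' @param tes TE annotation GRanges (see [readRepeatMasker()]).
#' @param mappings cross-genome mapped-fraction table (see
#'   [readMappings()]).
#' @param indels deletion GRanges (see [readDeletions()]).
#' @param chromLengths named vector of chromosome lengths.
#' @param tandemRepeats optional GRanges of tandem repeats; human-specific
#'   instances completely contained in one are discarded.
#' @param maxMappedFraction human-specificity threshold (default 0.20).
#' @param minSize minimum deletion length (default 50).
#' @param edgeThreshold redundancy-pruning mutual overlap (default 0.5).
#' @param nPseudo pseudo-indels per deletion (default 500).
#' @param minMutual TE-deletion match threshold (default 0.9).
#' @param qThreshold FDR threshold for the RMS call (default 0.001).
#' @return an [RmsScreenResult-class].
#' @export
rmsScreen <- function(tes, mappings, indels, chromLengths,
                      tandemRepeats = NULL,
                      maxMappedFraction = 0.20, minSize = 50,
                      edgeThreshold = 0.5, nPseudo = 500,
                      minMutual = 0.9, qThreshold = 0.001) {
  tes <- classifyHumanSpecific(tes, mappings,
                               maxFraction = maxMappedFraction)
  if (!is.null(tandemRepeats) && length(tandemRepeats)) {
    contained <- countOverlaps(tes, tandemRepeats, type = "within",
                               ignore.strand = TRUE) > 0L
    tes <- tes[!(mcols(tes)$human_specific & contained)]
  }
  catalog <- buildIndelCatalog(indels, minSize = minSize,
                               edgeThreshold = edgeThreshold)
  retained <- catalog[mcols(catalog)$retained]
  pseudo <- generatePseudoIndels(retained, nTotal = nPseudo,
                                 chromLengths = chromLengths)
  tab <- rmsTest(tes, retained, pseudo, minMutual = minMutual)
  tab <- callRms(tab, qThreshold = qThreshold)
  pm <- expandedPmeiScan(tab$subfamily[tab$is_rms], tes, catalog,
                         minMutual = minMutual)
  funnel <- c(
    te_input = length(tes),
    te_human_specific = sum(mcols(tes)$human_specific),
    indel_input = unname(metadata(catalog)$funnel["input"]),
    indel_size_pass = unname(metadata(catalog)$funnel["size_pass"]),
    indel_retained = length(retained),
    pseudo_generated = as.integer(metadata(pseudo)$generated),
    subfamilies_tested = nrow(tab),
    rms_called = sum(tab$is_rms),
    pmeis = length(pm)
  )
  new("RmsScreenResult",
      table = tab,
      nTrue = length(retained),
      nPseudo = as.numeric(metadata(pseudo)$generated),
      qThreshold = qThreshold,
      pmeis = pm,
      funnel = funnel)
}
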