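#' Configuration for the synthetic-genome simulator
#'
#' Defines a genome with TE instances of many subfamilies, a subset of
#' which are "mobile": their planted instances are human-specific (zero
#' cross-genome mapped fraction) and carry a boundary-matched deletion
#' (a planted pMEI). Ancestral instances map almost fully to the
#' non-human genomes; a fraction of them is deleted together with
#' flanking sequence (planted pMEDs, whose deletions deliberately fail
#' the 90% mutual-overlap match). Background deletions of at least 50 bp
#' are placed uniformly, independent of TEs. All randomness flows from
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param chromLengths named vector of chromosome lengths (default one
#'   10 Mb chromosome).
#' @param nSubfamilies number of TE subfamilies (default 40).
#' @param nMobile number of mobile subfamilies (default 3).
#' @param instancesPerSubfamily genomic instances per subfamily
#'   (default 60).
#' @param pmeisPerMobile planted pMEIs per mobile subfamily (default 15).
#' @param teLengthMean,teLengthSd,teLengthMin TE length distribution in
#'   bp (normal, truncated below at `teLengthMin`; defaults 300/80/80,
#'   an Alu-sized spectrum).
#' @param mobileDivergence,ancestralDivergence percent divergence
#'   assigned to mobile vs ancestral subfamilies (defaults 1.5 and 22).
#' @param hsFraction fraction of non-planted instances that are
#'   human-specific (default 0.3); every subfamily therefore enters the
#'   tested universe.
#' @param boundaryJitterMax maximum bp jitter applied to each planted
#'   deletion boundary (default 2). Jitter is further capped at
#'   `floor(L / 38)` per instance, which guarantees by arithmetic that
#'   every planted pMEI keeps at least 90% mutual overlap with its
#'   deletion.
#' @param pmedRate fraction of ancestral instances deleted with flanking
#'   sequence (default 0.05).
#' @param flankSpillRange bp range of flank spill per side for pMEDs
#'   (default 60-400); each side additionally spills at least
#'   `6% of L + 1` bp so the deletion's mutual overlap with its TE stays
#'   below 0.9.
#' @param nBackground number of background deletions (default 5000).
#' @param backgroundMeanLog,backgroundSdLog log-normal size parameters
#'   for background deletions (defaults log(150) and 0.7), truncated
#'   below at `minIndelSize`.
#' @param minIndelSize minimum deletion size in bp (default 50).
#' @param nPseudo pseudo-indels per deletion for the downstream screen
#'   (default 500).
#' @return validated config list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             chromLengths = c(chr1 = 1e7),
                             nSubfamilies = 40,
                             nMobile = 3,
                             instancesPerSubfamily = 60,
                             pmeisPerMobile = 15,
                             teLengthMean = 300,
                             teLengthSd = 80,
                             teLengthMin = 80,
                             mobileDivergence = 1.5,
                             ancestralDivergence = 22,
                             hsFraction = 0.3,
                             boundaryJitterMax = 2,
                             pmedRate = 0.05,
                             flankSpillRange = c(60, 400),
                             nBackground = 5000,
                             backgroundMeanLog = log(150),
                             backgroundSdLog = 0.7,
                             minIndelSize = 50,
                             nPseudo = 500) {
  cfg <- list(seed = seed, chromLengths = chromLengths,
              nSubfamilies = nSubfamilies, nMobile = nMobile,
              instancesPerSubfamily = instancesPerSubfamily,
              pmeisPerMobile = pmeisPerMobile,
              teLengthMean = teLengthMean, teLengthSd = teLengthSd,
              teLengthMin = teLengthMin,
              mobileDivergence = mobileDivergence,
              ancestralDivergence = ancestralDivergence,
              hsFraction = hsFraction,
              boundaryJitterMax = boundaryJitterMax,
              pmedRate = pmedRate, flankSpillRange = flankSpillRange,
              nBackground = nBackground,
              backgroundMeanLog = backgroundMeanLog,
              backgroundSdLog = backgroundSdLog,
              minIndelSize = minIndelSize, nPseudo = nPseudo)
  stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
            nMobile <= nSubfamilies,
            pmeisPerMobile <= instancesPerSubfamily,
            teLengthMin >= 2, hsFraction >= 0, hsFraction <= 1,
            pmedRate >= 0, pmedRate <= 1,
            length(flankSpillRange) == 2,
            flankSpillRange[1] <= flankSpillRange[2],
            minIndelSize >= 1, nPseudo %% 2 == 0,
            boundaryJitterMax >= 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

## Uniform non-overlapping placement with bounded rejection rounds.
.placeNonOverlapping <- function(lengths, chromLengths, maxRounds = 200) {
  n <- length(lengths)
  if (n == 0L) return(GRanges())
  chromNames <- names(chromLengths)
  resChrom <- character(n); resStart <- integer(n)
  accepted <- GRanges()
  probs <- chromLengths / sum(chromLengths)
  pending <- seq_len(n)
  for (round in seq_len(maxRounds)) {
    if (!length(pending)) break
    ch <- sample(chromNames, length(pending), replace = TRUE, prob = probs)
    maxStart <- unname(chromLengths[ch]) - lengths[pending] + 1
    if (any(maxStart < 1))
      stop("infeasible placement: TE instance longer than a chromosome")
    st <- floor(runif(length(pending), 1, maxStart + 1))
    cand <- GRanges(ch, IRanges(as.integer(st), width = lengths[pending]))
    okAcc <- countOverlaps(cand, accepted) == 0L
    keep <- logical(length(cand))
    ord <- order(as.character(seqnames(cand)), start(cand))
    lastCh <- ""; lastEnd <- -1L
    cch <- as.character(seqnames(cand))
    for (j in ord) {
      if (!okAcc[j]) next
      if (cch[j] != lastCh || start(cand)[j] > lastEnd) {
        keep[j] <- TRUE; lastCh <- cch[j]; lastEnd <- end(cand)[j]
      }
    }
    idx <- pending[keep]
    resChrom[idx] <- cch[keep]
    resStart[idx] <- start(cand)[keep]
    accepted <- c(accepted, cand[keep])
    pending <- pending[!keep]
  }
  if (length(pending))
    stop("infeasible placement: could not place ", length(pending),
         " TE instances without overlap after ", maxRounds, " rounds; ",
         "reduce instance counts or enlarge the genome")
  GRanges(resChrom, IRanges(resStart, width = lengths))
}

#' Simulate a genome with planted mobility truth
#'
#' See [simulationConfig()] for the generative model. The output carries
#' the TE annotation, the per-instance cross-genome mapped fractions,
#' the pooled deletion call set and the truth labels.
#'
#' @param config a [simulationConfig()] list.
#' @return a [SimulatedGenome-class].
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  genomes <- c("panTro5", "gorGor3", "ponAbe2", "nomLeu3", "rheMac8")
  nSub <- config$nSubfamilies
  subfam <- sprintf("subfam%02d", seq_len(nSub))
  mobile <- c(rep(TRUE, config$nMobile), rep(FALSE, nSub - config$nMobile))
  family <- ifelse(mobile, "simMobile", "simAncestral")

  nPer <- config$instancesPerSubfamily
  n <- nSub * nPer
  sfIdx <- rep(seq_len(nSub), each = nPer)
  lengths <- pmax(config$teLengthMin,
                  round(rnorm(n, config$teLengthMean, config$teLengthSd)))
  tes <- .placeNonOverlapping(lengths, config$chromLengths)
  strand(tes) <- sample(c("+", "-"), n, replace = TRUE)
  mcols(tes) <- DataFrame(
    subfamily = subfam[sfIdx],
    family = family[sfIdx],
    divergence = round(ifelse(mobile[sfIdx],
                              config$mobileDivergence,
                              config$ancestralDivergence) +
                       runif(n, -0.5, 0.5), 2),
    instance_id = sprintf("te_%06d", seq_len(n)),
    human_specific = NA
  )

  # planted pMEI instances: a random subset of each mobile subfamily
  planted <- logical(n)
  for (si in which(mobile)) {
    inst <- which(sfIdx == si)
    planted[sample(inst, config$pmeisPerMobile)] <- TRUE
  }
  hs <- planted | (runif(n) < config$hsFraction)

  # cross-genome mapped fractions (long format, all instances x genomes)
  mapFrac <- matrix(0, nrow = n, ncol = length(genomes))
  for (g in seq_along(genomes)) {
    mapFrac[, g] <- ifelse(planted, 0,
                    ifelse(hs, runif(n, 0, 0.1), runif(n, 0.85, 1)))
  }
  mappings <- data.frame(
    instance_id = rep(mcols(tes)$instance_id, length(genomes)),
    genome = rep(genomes, each = n),
    mapped_fraction = as.vector(mapFrac),
    stringsAsFactors = FALSE
  )

  chromLens <- config$chromLengths

  # planted pMEI deletions: TE boundaries jittered within the arithmetic
  # guarantee of >= 90% mutual overlap (|jitter| <= floor(L / 38))
  pmeiIdx <- which(planted)
  jmax <- pmin(config$boundaryJitterMax, width(tes)[pmeiIdx] %/% 38L)
  d1 <- vapply(jmax, function(j) sample(seq(-j, j), 1L), numeric(1))
  d2 <- vapply(jmax, function(j) sample(seq(-j, j), 1L), numeric(1))
  pmeiDel <- GRanges(seqnames(tes)[pmeiIdx],
                     IRanges(start(tes)[pmeiIdx] + as.integer(d1),
                             end(tes)[pmeiIdx] + as.integer(d2)))
  pmeiTe <- mcols(tes)$instance_id[pmeiIdx]

  # planted pMED deletions: ancestral TEs removed with flank spill on
  # both sides (each side > 6% of L, so mutual overlap < 0.9 by
  # arithmetic); instances too close to a chromosome end are skipped
  ancestral <- which(!hs)
  nPmed <- round(config$pmedRate * length(ancestral))
  pmedDel <- GRanges(); pmedTe <- character(0)
  if (nPmed > 0) {
    candIdx <- sample(ancestral, min(nPmed * 2L, length(ancestral)))
    L <- width(tes)[candIdx]
    minSpill <- ceiling(0.06 * L) + 1L
    spillL <- pmax(minSpill, round(runif(length(candIdx),
                                         config$flankSpillRange[1],
                                         config$flankSpillRange[2])))
    spillR <- pmax(minSpill, round(runif(length(candIdx),
                                         config$flankSpillRange[1],
                                         config$flankSpillRange[2])))
    s <- start(tes)[candIdx] - spillL
    e <- end(tes)[candIdx] + spillR
    clen <- unname(chromLens[as.character(seqnames(tes))[candIdx]])
    ok <- s >= 1 & e <= clen
    take <- which(ok)[seq_len(min(nPmed, sum(ok)))]
    pmedDel <- GRanges(as.character(seqnames(tes))[candIdx[take]],
                       IRanges(s[take], e[take]))
    pmedTe <- mcols(tes)$instance_id[candIdx[take]]
  }

  # background deletions: uniform, independent of TEs
  nBg <- config$nBackground
  bgDel <- GRanges()
  if (nBg > 0) {
    bgLen <- pmax(config$minIndelSize,
                  round(rlnorm(nBg, config$backgroundMeanLog,
                               config$backgroundSdLog)))
    bgCh <- sample(names(chromLens), nBg, replace = TRUE,
                   prob = chromLens / sum(chromLens))
    maxStart <- unname(chromLens[bgCh]) - bgLen + 1
    bgLen <- pmin(bgLen, unname(chromLens[bgCh]))  # degenerate tiny chrom
    maxStart <- pmax(1, maxStart)
    bgStart <- floor(runif(nBg, 1, maxStart + 1))
    bgDel <- GRanges(bgCh, IRanges(as.integer(bgStart), width = bgLen))
  }

  indels <- suppressWarnings(c(pmeiDel, pmedDel, bgDel))
  label <- c(rep("pMEI", length(pmeiDel)), rep("pMED", length(pmedDel)),
             rep("background", length(bgDel)))
  teOf <- c(pmeiTe, pmedTe, rep(NA_character_, length(bgDel)))
  ids <- sprintf("sim_del_%06d", seq_along(indels))
  mcols(indels) <- DataFrame(indel_id = ids,
                             svtype = rep("DEL", length(indels)),
                             source = rep("sim", length(indels)),
                             retained = rep(NA, length(indels)))
  truth <- list(
    indels = data.frame(indel_id = ids, label = label,
                        te_instance_id = teOf, stringsAsFactors = FALSE),
    subfamilies = data.frame(subfamily = subfam, mobile = mobile,
                             stringsAsFactors = FALSE)
  )
  new("SimulatedGenome", tes = tes, mappings = mappings, indels = indels,
      truth = truth, chromLengths = chromLens,
      config = unclass(config))
}

#' Write a simulated genome in the pipeline's file formats
#'
#' Emits the simplified RepeatMasker-style TSV annotation, the mapping
#' TSV, the deletion BED and the truth TSV, so tests can exercise the
#' real I/O path.
#'
#' @param sim a [SimulatedGenome-class].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedGenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tes <- sim@tes
  teDf <- data.frame(chrom = as.character(seqnames(tes)),
                     start = start(tes) - 1L, end = end(tes),
                     strand = as.character(strand(tes)),
                     subfamily = mcols(tes)$subfamily,
                     family = mcols(tes)$family,
                     divergence = mcols(tes)$divergence,
                     instance_id = mcols(tes)$instance_id)
  paths <- c(tes = file.path(dir, "tes.tsv"),
             mappings = file.path(dir, "mappings.tsv"),
             indels = file.path(dir, "indels.bed"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(teDf, paths["tes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim@mappings, paths["mappings"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeBed(sim@indels, paths["indels"])
  utils::write.table(sim@truth$indels, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Planted-truth recovery harness
#'
#' Simulates genomes over a list of seeds, runs the full screen on each,
#' and scores the called RMS set against the planted truth.
#'
#' @param config a [simulationConfig()]; its `seed` element is replaced
#'   by each element of `seeds` in turn.
#' @param seeds integer vector of seeds.
#' @param qThreshold FDR threshold passed to [rmsScreen()]
#'   (default 0.001).
#' @param ... further arguments passed to [rmsScreen()].
#' @return list with `summary` (one row per seed: planted and called
#'   counts, confusion counts, extreme Q/p values) and `tables` (the
#'   per-seed result tables).
#' @export
recoveryHarness <- function(config, seeds = 1:3, qThreshold = 0.001, ...) {
  rows <- vector("list", length(seeds))
  tables <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulateGenome(cfg)
    res <- rmsScreen(sim@tes, sim@mappings, sim@indels,
                     chromLengths = sim@chromLengths,
                     nPseudo = cfg$nPseudo, qThreshold = qThreshold, ...)
    tab <- resultTable(res)
    tables[[i]] <- tab
    mobileSet <- sim@truth$subfamilies$subfamily[sim@truth$subfamilies$mobile]
    planted <- table(factor(
      sim@truth$indels$label, levels = c("pMEI", "pMED", "background")))
    called <- rmsSubfamilies(res)
    nullQ <- tab$q_value[!(tab$subfamily %in% mobileSet)]
    mobQ <- tab$q_value[tab$subfamily %in% mobileSet]
    rows[[i]] <- data.frame(
      seed = seeds[i],
      n_mobile = length(mobileSet),
      n_planted_pmeis = as.integer(planted["pMEI"]),
      n_tested = nrow(tab),
      n_called = length(called),
      true_pos = length(intersect(called, mobileSet)),
      false_pos = length(setdiff(called, mobileSet)),
      false_neg = length(setdiff(mobileSet, called)),
      max_mobile_q = if (length(mobQ)) max(mobQ) else NA_real_,
      min_null_q = if (length(nullQ)) min(nullQ) else NA_real_
    )
  }
  list(summary = do.call(rbind, rows), tables = tables)
}
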