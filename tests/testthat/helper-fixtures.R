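suppressPackageStartupMessages({
  library(GenomicRanges)
})

## GRanges from 0-based half-open coordinates, the convention used by
## the interval examples throughout the tests.
gr0 <- function(chrom, start0, end0, ...) {
  gr <- GRanges(rep_len(chrom, length(start0)),
                IRanges(start0 + 1L, end0))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

## deletion GRanges with the metadata the catalogue code expects
delGr <- function(chrom, start0, end0, ids = NULL) {
  gr <- gr0(chrom, start0, end0)
  mcols(gr)$indel_id <- if (is.null(ids))
    sprintf("d%03d", seq_along(gr)) else ids
  mcols(gr)$svtype <- rep("DEL", length(gr))
  mcols(gr)$source <- rep("test", length(gr))
  mcols(gr)$retained <- rep(NA, length(gr))
  gr
}

## TE GRanges with annotation metadata
teGr <- function(chrom, start0, end0, subfamily, family = "Alu",
                 divergence = 1, humanSpecific = TRUE) {
  gr <- gr0(chrom, start0, end0)
  mcols(gr)$subfamily <- subfamily
  mcols(gr)$family <- rep_len(family, length(gr))
  mcols(gr)$divergence <- rep_len(divergence, length(gr))
  mcols(gr)$instance_id <- sprintf("te%03d", seq_along(gr))
  mcols(gr)$human_specific <- rep_len(humanSpecific, length(gr))
  gr
}

## native RepeatMasker .out fixture: 5 rows, 2 subfamilies
writeRmOutFixture <- function(path = tempfile(fileext = ".out")) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class",
    ""
  )
  rows <- c(
    "  463   1.3  0.6  1.7  chr1    101    400 (999600) +  AluYa5  SINE/Alu   1 300  (0) 1",
    "  455   2.0  0.1  0.9  chr1   1001   1290 (998710) C  AluYa5  SINE/Alu   1 290  (0) 2",
    "  300  15.2  1.6  2.7  chr1   5001   5950 (994050) +  L1PA7   LINE/L1    1 950  (0) 3",
    "  290  16.0  2.0  2.0  chr2    201   1100 (998900) C  L1PA7   LINE/L1    1 900  (0) 4",
    "  488   0.8  0.0  0.3  chr2   3001   3300 (996700) +  AluYa5  SINE/Alu   1 300  (0) 5"
  )
  writeLines(c(hdr, rows), path)
  path
}

## small VCF fixture: one sequence-resolved 300 bp deletion, one
## insertion (must be dropped), one SNV, one symbolic <DEL> with END
writeVcfFixture <- function(path = tempfile(fileext = ".vcf")) {
  ref300 <- paste(rep("A", 301), collapse = "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##contig=<ID=chr1,length=10000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("chr1\t1000\tdel1\t%s\tA\t.\tPASS\t.", ref300),
    "chr1\t5000\tins1\tA\tATTTTTTTTT\t.\tPASS\t.",
    "chr1\t6000\tsnv1\tA\tG\t.\tPASS\t.",
    "chr1\t8000\tdel2\tN\t<DEL>\t.\tPASS\tEND=8300;SVTYPE=DEL"
  ), path)
  path
}

## a deliberately redundant deletion catalogue for pruning tests
redundantCatalog <- function(seed, n = 120, chromLen = 2e5) {
  set.seed(seed)
  base <- floor(runif(n, 1, chromLen - 2000))
  len <- pmax(50, round(rlnorm(n, log(200), 0.6)))
  # half the records are near-duplicates of another record
  dup <- sample(n, n %/% 2, replace = TRUE)
  s <- c(base, base[dup] + sample(-20:20, length(dup), replace = TRUE))
  l <- c(len, pmax(50, len[dup] + sample(-10:10, length(dup),
                                         replace = TRUE)))
  delGr("chr1", s, s + l)
}

## fast small-scale simulation config for unit tests
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(
    seed = seed,
    chromLengths = c(chr1 = 2e6),
    nSubfamilies = 8, nMobile = 2, instancesPerSubfamily = 25,
    pmeisPerMobile = 8, nBackground = 400, nPseudo = 100, ...
  )
}
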