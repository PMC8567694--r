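test_that("RepeatMasker .out rows become 1-based closed ranges", {
  path <- writeRmOutFixture()
  te <- readRepeatMasker(path)
  expect_length(te, 5)
  expect_setequal(unique(te$subfamily), c("AluYa5", "L1PA7"))
  # .out begin=101 end=400 (1-based inclusive) is [100, 400) half-open
  expect_equal(start(te)[1], 101)
  expect_equal(end(te)[1], 400)
  expect_equal(width(te)[1], 300)
  expect_equal(te$divergence[1], 1.3)
  expect_equal(te$family[1:3], c("Alu", "Alu", "L1"))
  expect_equal(as.character(strand(te))[2], "-")  # C means reverse
  expect_false(anyDuplicated(te$instance_id) > 0)
})

test_that("empty and malformed RepeatMasker input is handled", {
  empty <- tempfile()
  writeLines(c("   SW  perc", "score div.", ""), empty)
  expect_length(readRepeatMasker(empty), 0)

  bad <- tempfile()
  writeLines(c("   SW  perc", "score div.", "",
               "  463  1.3  0.6  1.7  chr1  101"), bad)
  expect_error(readRepeatMasker(bad), "line")

  unknown <- tempfile()
  writeLines("not an annotation at all", unknown)
  expect_error(readRepeatMasker(unknown), "dialect")
})

test_that("simplified TSV annotation round-trips 0-based coordinates", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", start = 100, end = 400,
                   strand = "+", subfamily = "AluYa5", family = "Alu",
                   divergence = 1.1, instance_id = "te_x")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  te <- readRepeatMasker(path)
  expect_equal(start(te), 101)
  expect_equal(end(te), 400)
  expect_equal(te$instance_id, "te_x")
})

test_that("VCF deletions are extracted and insertions discarded", {
  path <- writeVcfFixture()
  del <- suppressWarnings(readDeletions(path))
  expect_length(del, 2)  # the insertion and the SNV are not emitted
  # REF 301 bp, ALT 1 bp at POS 1000 -> deleted span [1000, 1300) 0-based
  expect_equal(start(del)[1], 1001)
  expect_equal(end(del)[1], 1300)
  expect_equal(width(del)[1], 300)
  # symbolic <DEL> with END=8300 at POS 8000 -> [8000, 8300)
  expect_equal(start(del)[2], 8001)
  expect_equal(end(del)[2], 8300)
  expect_true(all(del$svtype == "DEL"))
  expect_false(anyDuplicated(del$indel_id) > 0)
})

test_that("BED deletions pass through and BED writing round-trips", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1400\tx", bed)
  del <- readDeletions(bed)
  expect_equal(start(del), 1001)
  expect_equal(end(del), 1400)

  out <- tempfile(fileext = ".bed")
  writeBed(del, out)
  again <- readDeletions(out)
  expect_equal(as.character(seqnames(again)), as.character(seqnames(del)))
  expect_equal(start(again), start(del))
  expect_equal(end(again), end(del))
})

test_that("overlapLength follows half-open arithmetic", {
  expect_equal(overlapLength(gr0("chr1", 0, 100), gr0("chr1", 50, 150)), 50)
  expect_equal(overlapLength(gr0("chr1", 0, 100), gr0("chr1", 100, 200)), 0)
  expect_equal(overlapLength(gr0("chr1", 0, 100), gr0("chr2", 0, 100)), 0)
})

test_that("mutualOverlap divides by the longer interval", {
  a <- gr0("chr1", 0, 100)
  expect_equal(mutualOverlap(a, a), 1.0)
  expect_equal(mutualOverlap(a, gr0("chr1", 10, 110)), 0.9)
  expect_equal(mutualOverlap(a, gr0("chr1", 0, 1000)), 0.1)
})

test_that("mutualOverlap is symmetric and bounds both fractions", {
  set.seed(42)
  for (i in 1:200) {
    s1 <- sample(0:5000, 1); l1 <- sample(1:1000, 1)
    s2 <- sample(0:5000, 1); l2 <- sample(1:1000, 1)
    a <- gr0("chr1", s1, s1 + l1)
    b <- gr0("chr1", s2, s2 + l2)
    m <- mutualOverlap(a, b)
    expect_identical(m, mutualOverlap(b, a))
    ol <- overlapLength(a, b)
    # mutual >= f guarantees the overlap covers >= f of BOTH intervals
    expect_gte(ol / width(a), m - 1e-12)
    expect_gte(ol / width(b), m - 1e-12)
  }
})
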