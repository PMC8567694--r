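test_that("tiling steps by width - overlap and drops partial tiles", {
  tiles <- tileChromosomes(c(chrA = 301))
  expect_length(tiles, 3)
  expect_equal(start(tiles) - 1L, c(0, 75, 150))  # 0-based starts
  expect_true(all(width(tiles) == 151))
  expect_equal(overlapLength(tiles[1], tiles[2]), 76)
  expect_length(tileChromosomes(c(tiny = 150)), 0)
})

test_that("merge caps the span at 601 bp and trims to a central 151 bp", {
  # 7 consecutive passing tiles span exactly 6 * 75 + 151 = 601 bp
  tiles <- tileChromosomes(c(chrA = 1000))[1:7]
  mcols(tiles)$score <- c(1, 2, 5, 3, 1, 1, 1)
  out <- mergeAndTrim(tiles)
  expect_length(out, 1)
  expect_equal(width(out), 151)
  expect_equal(mcols(out)$score, 5)
  # symmetric trim of the 601 bp span [1, 601] -> [226, 376]
  expect_equal(start(out), 226)
  expect_equal(end(out), 376)
})

test_that("an isolated passing tile is returned unchanged; low scores drop", {
  tiles <- tileChromosomes(c(chrA = 2000))
  mcols(tiles)$score <- 0
  mcols(tiles)$score[5] <- 1.7
  mcols(tiles)$score[10] <- 0.99
  out <- mergeAndTrim(tiles)
  expect_length(out, 1)
  expect_equal(start(out), start(tiles)[5])
  expect_equal(mcols(out)$score, 1.7)
})

test_that("runs longer than the span cap break into multiple regions", {
  # 8 passing tiles span 676 bp: must split, never exceed 601 bp merged
  tiles <- tileChromosomes(c(chrA = 1000))[1:8]
  mcols(tiles)$score <- 1
  out <- mergeAndTrim(tiles)
  expect_length(out, 2)
  expect_true(all(width(out) == 151))
  # odd excess trims the extra base from the right
  one <- tileChromosomes(c(chrA = 400))[1:2]  # span 226, excess 75 (odd)
  mcols(one)$score <- 1
  t1 <- mergeAndTrim(one)
  expect_equal(start(t1), 1 + 37)    # floor(75/2) off the left
  expect_equal(end(t1), 226 - 38)    # ceiling(75/2) off the right
})

test_that("prediction count matches the measured count with lexicographic ties", {
  reg <- gr0("chr1", seq(0, by = 500, length.out = 10),
             seq(151, by = 500, length.out = 10))
  mcols(reg)$score <- c(5, 4, 3, 3, 2, 2, 2, 1, 1, 0.5)
  top3 <- thresholdToCount(reg, 3)
  expect_length(top3, 3)
  expect_equal(sort(mcols(top3)$score, decreasing = TRUE), c(5, 4, 3))
  # tie at the cut: the lexicographically earlier region is kept
  expect_equal(start(top3)[3], start(reg)[3])
  expect_length(suppressWarnings(thresholdToCount(reg, 99)), 10)
  expect_warning(thresholdToCount(reg, 99), "candidate")
  expect_error(thresholdToCount(reg, -1), "non-negative")
})

test_that("hypersensitive fractions require 50 bp of DHS overlap", {
  inst <- gr0("chr1", c(0, 1000, 2000, 3000), c(300, 1300, 2300, 3300))
  dhs <- gr0("chr1", c(100, 1251, 2251), c(251, 1400, 2400))
  # instance 1: 151 bp overlap; instance 2: 49 bp (not counted);
  # instance 3: 49 bp... make instance 3 overlap by 50
  dhs2 <- gr0("chr1", c(100, 1251, 2250), c(251, 1400, 2400))
  expect_equal(hypersensitiveFraction(inst, dhs2), 0.5)
  expect_equal(hypersensitiveFraction(inst, GRanges()), 0)
  expect_true(is.na(hypersensitiveFraction(GRanges(), dhs)))
})

test_that("specificity folds are ratios to the row mean", {
  m <- rbind(sfA = c(0.1, 0.3), sfB = c(0.2, 0.2), sfC = c(0, 0))
  colnames(m) <- c("K562", "GM12878")
  sp <- specificityMatrix(m)
  expect_equal(unname(sp$largestFraction), c(0.3, 0.2, 0))
  expect_equal(unname(sp$foldEnrichment["sfA", ]), c(0.5, 1.5))
  expect_equal(unname(sp$foldEnrichment["sfB", ]), c(1, 1))
  expect_true(all(is.na(sp$foldEnrichment["sfC", ])))
  # complete fold rows average to exactly 1
  expect_equal(unname(rowMeans(sp$foldEnrichment[1:2, ])), c(1, 1))
})

test_that("ancient reference subfamilies need age and abundance", {
  tes <- c(
    teGr("chr1", seq(0, by = 400, length.out = 1200),
         seq(300, by = 400, length.out = 1200), "oldBig",
         divergence = 25),
    teGr("chr1", seq(5e5, by = 400, length.out = 1200),
         seq(5e5 + 300, by = 400, length.out = 1200), "youngBig",
         divergence = 2),
    teGr("chr1", seq(2e6, by = 400, length.out = 50),
         seq(2e6 + 300, by = 400, length.out = 50), "oldSmall",
         divergence = 30)
  )
  expect_equal(ancientSubfamilies(tes), "oldBig")
})
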