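test_that("pseudo-indels tile outward with 50% neighbour overlap", {
  del <- delGr("chr1", 100000, 100100)  # L = 100, far from both edges
  ps <- generatePseudoIndels(del, nTotal = 500, c(chr1 = 1e7))
  expect_length(ps, 500)
  expect_equal(sum(ps$side == "left"), 250)
  expect_equal(sum(ps$side == "right"), 250)
  expect_true(all(width(ps) == 100))
  right <- ps[ps$side == "right"]
  right <- right[order(right$rank)]
  # innermost right tile starts flush at the deletion end (0-based 100100)
  expect_equal(start(right)[1:3] - 1L, c(100100, 100150, 100200))
  ol <- overlapLength(right[-length(right)], right[-1])
  expect_true(all(ol == 50))
  left <- ps[ps$side == "left"]
  left <- left[order(left$rank)]
  expect_equal(end(left)[1], 100000)  # innermost left tile ends at start
})

test_that("odd lengths step by L - floor(L/2) so neighbours share floor(L/2)", {
  del <- delGr("chr1", 50000, 50101)  # L = 101
  ps <- generatePseudoIndels(del, nTotal = 10, c(chr1 = 1e6))
  right <- ps[ps$side == "right"]
  right <- right[order(right$rank)]
  expect_equal(diff(start(right)), rep(51, 4))
  expect_equal(overlapLength(right[1], right[2]), 50)
})

test_that("tiles past the chromosome boundary are dropped and counted", {
  del <- delGr("chr1", 120, 220)  # left flank has room for one tile only
  ps <- generatePseudoIndels(del, nTotal = 500, c(chr1 = 1e7))
  expect_equal(sum(ps$side == "left"), 1)
  expect_equal(sum(ps$side == "right"), 250)
  meta <- S4Vectors::metadata(ps)
  expect_equal(meta$nominal, 500)
  expect_equal(meta$generated, 251)
})

test_that("TE-indel matching sits exactly at the 90% boundary", {
  te <- gr0("chr1", 0, 300)
  expect_true(matchTE(te, gr0("chr1", 0, 300)))
  expect_false(matchTE(te, gr0("chr1", 0, 269)))  # 269/300 < 0.9
  expect_true(matchTE(te, gr0("chr1", 15, 300)))  # 285/300 = 0.95
})

test_that("match counts agree with brute-force pair enumeration", {
  tes <- teGr("chr1", c(0, 10, 5000), c(300, 310, 5200), "AluYa5")
  trueDel <- delGr("chr1", c(5, 9000), c(305, 9100))
  pseudo <- generatePseudoIndels(trueDel, nTotal = 20, c(chr1 = 1e6))
  got <- countMatches("AluYa5", tes, trueDel, pseudo)

  brute <- function(indels) {
    hit <- logical(length(indels))
    for (i in seq_along(tes)) for (j in seq_along(indels))
      if (mutualOverlap(tes[i], indels[j]) >= 0.9) hit[j] <- TRUE
    sum(hit)
  }
  # both TEs match the same deletion; it is counted once
  expect_equal(unname(got["t_te"]), brute(trueDel))
  expect_equal(unname(got["t_te"]), 1L)
  expect_equal(unname(got["p_te"]), brute(pseudo))
  # a subfamily with no human-specific instances counts nothing
  none <- countMatches("L1HS", tes, trueDel, pseudo)
  expect_equal(unname(none), c(0L, 0L))
})

test_that("fisherSubfamily equals direct hypergeometric tail enumeration", {
  # T=0: the one-sided tail covers the whole support
  expect_equal(fisherSubfamily(0, 50, 100, 5000), 1.0)
  # [[2,8],[0,5000]]: enumerate the tail by direct binomial coefficients
  oracle <- choose(2, 2) * choose(5008, 8) / choose(5010, 10)
  expect_equal(fisherSubfamily(2, 0, 10, 5000), oracle, tolerance = 1e-12)
  # random small tables against stats::dhyper summation
  set.seed(101)
  for (i in 1:50) {
    nT <- sample(5:200, 1); nP <- sample(5:2000, 1)
    tT <- sample(0:min(20, nT), 1); pP <- sample(0:min(50, nP), 1)
    xs <- tT:min(tT + pP, nT)
    expected <- sum(stats::dhyper(xs, tT + pP, nT + nP - tT - pP, nT))
    expect_equal(fisherSubfamily(tT, pP, nT, nP), min(1, expected),
                 tolerance = 1e-10)
  }
  expect_error(fisherSubfamily(5, 0, 3, 100), "inconsistent")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bhAdjust(0.42), 0.42)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(20)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) > -1e-15))  # monotone in p-rank
})

test_that("the RMS call is inclusive at the Q threshold", {
  tab <- data.frame(subfamily = c("a", "b", "c"),
                    p_value = c(1e-5, 2e-4, 0.5),
                    q_value = c(0.001, 0.0011, 0.5))
  out <- callRms(tab)
  expect_equal(out$subfamily[out$is_rms], "a")
  expect_equal(out$subfamily, c("a", "b", "c"))  # sorted by Q
  empty <- callRms(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("expanded scan recovers matches to discarded deletions only for RMSs", {
  tes <- teGr("chr1", c(1000, 5000, 9000), c(1300, 5300, 9300),
              c("mob1", "mob1", "oldA"))
  indels <- delGr("chr1", c(1000, 5002, 9000), c(1300, 5302, 9300))
  mcols(indels)$retained <- c(TRUE, FALSE, TRUE)
  got <- expandedPmeiScan("mob1", tes, indels)
  # the mob1 TE matching a discarded deletion is included; oldA excluded
  expect_setequal(got$instance_id, c("te001", "te002"))
  # a TE matching both retained and discarded records appears once
  both <- delGr("chr1", c(1000, 1001), c(1300, 1301),
                ids = c("r1", "r2"))
  mcols(both)$retained <- c(TRUE, FALSE)
  gotBoth <- expandedPmeiScan("mob1", tes, both)
  expect_equal(sum(gotBoth$instance_id == "te001"), 1)
})

test_that("true and pseudo match rates agree when TEs are independent of indels", {
  # TEs and deletions placed independently: the true-indel match rate
  # must look like one more draw from the pseudo-indel rate
  set.seed(202)
  totT <- 0; totTrue <- 0; totP <- 0; totPseudo <- 0
  for (rep in 1:8) {
    n <- 60
    tePos <- floor(runif(n, 1000, 9e4))
    tes <- teGr("chr1", tePos, tePos + 200, "simX")
    m <- 150
    delPos <- floor(runif(m, 1000, 9e4))
    delLen <- sample(190:210, m, replace = TRUE)
    dels <- delGr("chr1", delPos, delPos + delLen)
    ps <- generatePseudoIndels(dels, nTotal = 100, c(chr1 = 1e5))
    cm <- countMatches("simX", tes, dels, ps)
    totT <- totT + cm["t_te"]; totTrue <- totTrue + m
    totP <- totP + cm["p_te"]
    totPseudo <- totPseudo + S4Vectors::metadata(ps)$generated
  }
  rate <- totP / totPseudo
  bounds <- qbinom(c(0.0005, 0.9995), totTrue, rate)
  expect_gte(unname(totT), bounds[1])
  expect_lte(unname(totT), bounds[2])
})
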