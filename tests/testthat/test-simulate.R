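test_that("the simulator is deterministic under a fixed seed", {
  s1 <- simulateGenome(tinyConfig(seed = 4))
  s2 <- simulateGenome(tinyConfig(seed = 4))
  expect_identical(teAnnotation(s1), teAnnotation(s2))
  expect_identical(crossGenomeMappings(s1), crossGenomeMappings(s2))
  expect_identical(indelCalls(s1), indelCalls(s2))
  expect_identical(simulationTruth(s1), simulationTruth(s2))
  s3 <- simulateGenome(tinyConfig(seed = 5))
  expect_false(identical(start(indelCalls(s1)), start(indelCalls(s3))))
})

test_that("planted truth is consistent with the matching rule", {
  sim <- simulateGenome(tinyConfig(seed = 9))
  truth <- simulationTruth(sim)$indels
  tes <- teAnnotation(sim)
  indels <- indelCalls(sim)
  byTe <- setNames(seq_along(tes), tes$instance_id)
  byDel <- setNames(seq_along(indels), indels$indel_id)
  pmei <- truth[truth$label == "pMEI", ]
  expect_gt(nrow(pmei), 0)
  for (i in seq_len(nrow(pmei))) {
    mo <- mutualOverlap(tes[byTe[pmei$te_instance_id[i]]],
                        indels[byDel[pmei$indel_id[i]]])
    expect_gte(mo, 0.9)
  }
  pmed <- truth[truth$label == "pMED", ]
  for (i in seq_len(nrow(pmed))) {
    mo <- mutualOverlap(tes[byTe[pmed$te_instance_id[i]]],
                        indels[byDel[pmed$indel_id[i]]])
    expect_lt(mo, 0.9)
  }
  # planted pMEI instances are human-specific by construction
  maps <- crossGenomeMappings(sim)
  frac <- tapply(maps$mapped_fraction, maps$instance_id, max)
  expect_true(all(frac[pmei$te_instance_id] == 0))
  # pMED hosts are ancestral
  expect_true(all(frac[pmed$te_instance_id] > 0.2))
})

test_that("zero jitter plants deletions with exact TE boundaries", {
  sim <- simulateGenome(tinyConfig(seed = 2, boundaryJitterMax = 0))
  truth <- simulationTruth(sim)$indels
  tes <- teAnnotation(sim)
  indels <- indelCalls(sim)
  pmei <- truth[truth$label == "pMEI", ]
  mo <- mutualOverlap(
    tes[match(pmei$te_instance_id, tes$instance_id)],
    indels[match(pmei$indel_id, indels$indel_id)])
  expect_true(all(mo == 1))
})

test_that("an empty generative model yields an empty indel set", {
  cfg <- simulationConfig(seed = 1, chromLengths = c(chr1 = 5e5),
                          nSubfamilies = 5, nMobile = 0,
                          instancesPerSubfamily = 10,
                          pmeisPerMobile = 0, pmedRate = 0,
                          nBackground = 0)
  sim <- simulateGenome(cfg)
  expect_length(indelCalls(sim), 0)
  expect_equal(nrow(simulationTruth(sim)$indels), 0)
})

test_that("TE instances never overlap and background sizes respect the floor", {
  sim <- simulateGenome(tinyConfig(seed = 3))
  tes <- teAnnotation(sim)
  hits <- findOverlaps(tes, drop.self = TRUE, ignore.strand = TRUE)
  expect_length(hits, 0)
  truth <- simulationTruth(sim)$indels
  bg <- indelCalls(sim)[truth$label == "background"]
  expect_true(all(width(bg) >= 50))
})

test_that("simulation files round-trip through the package readers", {
  sim <- simulateGenome(tinyConfig(seed = 6))
  dir <- tempfile()
  paths <- writeSimulation(sim, dir)
  tes <- readRepeatMasker(paths["tes"])
  expect_identical(start(tes), start(teAnnotation(sim)))
  expect_identical(tes$subfamily, teAnnotation(sim)$subfamily)
  maps <- readMappings(paths["mappings"])
  expect_equal(nrow(maps), nrow(crossGenomeMappings(sim)))
  dels <- readDeletions(paths["indels"])
  expect_identical(start(dels), start(indelCalls(sim)))
  expect_identical(end(dels), end(indelCalls(sim)))
})

test_that("the recovery harness finds planted subfamilies and no others", {
  rec <- recoveryHarness(tinyConfig(), seeds = c(11, 12))
  expect_equal(rec$summary$true_pos, rec$summary$n_mobile)
  expect_equal(rec$summary$false_pos, c(0, 0))
  expect_true(all(rec$summary$max_mobile_q <= 0.001))
})
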