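test_that("simulated trees are ultrametric, depth 1, and seeded", {
  t2 <- simulateTree(2, seed = 1)
  expect_equal(ape::node.depth.edgelength(t2)[1:2], c(1, 1))
  tr <- simulateTree(40, seed = 9)
  depths <- ape::node.depth.edgelength(tr)[1:40]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(ape::write.tree(simulateTree(40, seed = 9)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulateTree(40, seed = 10)),
                         ape::write.tree(tr)))
  expect_error(simulateTree(1), ">= 2")
})

test_that("Brownian traits accumulate variance sigma^2 * depth", {
  tree <- simulateTree(8, seed = 4)   # every tip at depth 1
  sigma <- 0.7
  set.seed(11)
  sims <- phytools::fastBM(tree, a = 0, sig2 = sigma^2, nsim = 2000)
  v <- apply(sims, 1, var)
  # each tip's trait variance within 5% of sigma^2 (depth = 1)
  expect_true(all(abs(v - sigma^2) / sigma^2 < 0.15))
  expect_lt(abs(mean(v) - sigma^2) / sigma^2, 0.05)
  # degenerate rate: all traits at the root value
  z <- evolveTrait(tree, 0)
  expect_equal(unname(z), rep(0, 8))
  # determinism
  expect_identical(evolveTrait(tree, 1, seed = 2),
                   evolveTrait(tree, 1, seed = 2))
})

test_that("sister tips are more trait-correlated than distant tips", {
  tree <- simulateTree(32, seed = 6)
  d <- copheneticMatrix(tree)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  near <- pairs[which.min(d[upper.tri(d)]), ]
  far <- pairs[which.max(d[upper.tri(d)]), ]
  set.seed(12)
  sims <- phytools::fastBM(tree, a = 0, sig2 = 1, nsim = 500)
  corNear <- cor(sims[near[1], ], sims[near[2], ])
  corFar <- cor(sims[far[1], ], sims[far[2], ])
  expect_gt(corNear, corFar)
})

test_that("community tables have exact depth, metadata, and reproducibility", {
  for (scn in c("homogeneous_selection", "variable_selection", "drift",
                "homogenizing_dispersal", "dispersal_limitation",
                "neutral")) {
    cfg <- scenarioConfig(scn, nTaxa = 32, nSamplesPerGroup = 2,
                          nGroups = 2, depth = 137, seed = 5)
    cs <- simulateScenario(cfg)
    m <- communityCounts(cs)
    expect_true(all(colSums(m) == 137), info = scn)
    expect_equal(ncol(m), 4, info = scn)
    expect_setequal(sampleGroups(cs), c("Oi", "Oe"))
    cs2 <- simulateScenario(cfg)
    expect_identical(m, communityCounts(cs2))
  }
})

test_that("an infinitely wide filter approaches uniform expected abundance", {
  cfg <- scenarioConfig("homogeneous_selection", nTaxa = 24,
                        nSamplesPerGroup = 8, nGroups = 1, depth = 5000,
                        filterWidth = 1e6, lotterySigma = 0, seed = 3)
  cs <- simulateScenario(cfg)
  m <- communityCounts(cs)
  props <- rowMeans(m) / 5000
  # expected relative abundance 1/24 for every taxon
  expect_lt(max(abs(props - 1 / 24)), 0.01)
})

test_that("well-separated environments drive between-group turnover", {
  ok <- 0
  for (seed in 1:10) {
    cfg <- scenarioConfig("variable_selection", nTaxa = 64,
                          nSamplesPerGroup = 3, nGroups = 2, depth = 500,
                          envSpacing = 6 * 0.3, seed = seed)
    cs <- simulateScenario(cfg)
    m <- communityCounts(cs)
    g <- sampleGroups(cs)
    bc <- as.matrix(vegan::vegdist(t(m), method = "bray"))
    within <- c(bc[g == "Oi", g == "Oi"][upper.tri(diag(3))],
                bc[g == "Oe", g == "Oe"][upper.tri(diag(3))])
    between <- bc[g == "Oi", g == "Oe"]
    if (mean(between) > mean(within)) ok <- ok + 1
  }
  expect_gte(ok, 10 * 0.95 - 1)  # >= 95% of replicates, allowing one miss
})

test_that("scenario export writes the four artifact files faithfully", {
  dir <- withr::local_tempdir()
  cfg <- scenarioConfig("neutral", nTaxa = 12, nSamplesPerGroup = 2,
                        nGroups = 2, depth = 60, seed = 2)
  writeScenario(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "table.tsv", "metadata.tsv", "truth.json")))))
  tree <- readTree(file.path(dir, "tree.nwk"))
  tab <- readCommunityTable(file.path(dir, "table.tsv"))
  md <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  expect_setequal(tree$tip.label, rownames(tab))
  expect_setequal(rownames(md), colnames(tab))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$scenario, "neutral")
  expect_identical(truth$seed, 2L)
})
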