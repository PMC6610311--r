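test_that("MNTD matches hand-derived values on the 4-tip tree", {
  d <- copheneticMatrix(fourTipTree())
  expect_equal(mntd(c(A = 1, B = 1, C = 1, D = 0), d), 8 / 3)
  expect_equal(mntd(c(A = 1, B = 1, C = 0, D = 0), d), 2)
  expect_equal(mntd(c(A = 3, B = 1, C = 0, D = 0), d, weighted = TRUE), 2)
  expect_warning(res <- mntd(c(A = 1, B = 0, C = 0, D = 0), d),
                 "fewer than 2")
  expect_true(is.na(res))
})

test_that("betaMNTD matches hand-derived values and its contract", {
  d <- copheneticMatrix(fourTipTree())
  ab <- c(A = 1, B = 1, C = 0, D = 0)
  cd <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(betaMNTD(ab, cd, d, weighted = FALSE), 4)
  expect_equal(betaMNTD(c(A = 0.5, B = 0.5, C = 0, D = 0),
                        c(A = 0, B = 0, C = 1, D = 0), d, weighted = TRUE), 4)
  expect_equal(betaMNTD(ab, ab, d), 0)
  expect_error(betaMNTD(ab, c(A = 0, B = 0, C = 0, D = 0), d),
               "present taxon")
})

test_that("mntd and betaMNTD agree with brute-force oracles on small cases", {
  set.seed(71)
  for (case in 1:120) {
    tree <- randomTree(sample(3:8, 1))
    d <- copheneticMatrix(tree)
    n <- nrow(d)
    kx <- sample(2:min(6, n), 1)
    ky <- sample(1:min(6, n), 1)
    x <- numeric(n)
    y <- numeric(n)
    x[sample(n, kx)] <- sample(1:9, kx, replace = TRUE)
    y[sample(n, ky)] <- sample(1:9, ky, replace = TRUE)
    names(x) <- names(y) <- rownames(d)
    for (wt in c(TRUE, FALSE)) {
      expect_equal(mntd(x, d, weighted = wt), bruteMntd(x, d, wt),
                   tolerance = 1e-12)
      expect_equal(betaMNTD(x, y, d, weighted = wt),
                   bruteBetaMntd(x, y, d, wt), tolerance = 1e-12)
      expect_equal(betaMNTD(x, y, d, weighted = wt),
                   betaMNTD(y, x, d, weighted = wt), tolerance = 1e-12)
    }
  }
})

test_that("abundance-weighted betaMNTD matches picante::comdistnt", {
  skip_if_not_installed("picante")
  cs <- smallCommunitySet(seed = 31, nTaxa = 24, nSamples = 4, depth = 300)
  m <- communityCounts(cs)
  d <- copheneticMatrix(communityTree(cs), order = rownames(m))
  ref <- as.matrix(picante::comdistnt(t(m), d, abundance.weighted = TRUE))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(betaMNTD(m[, i], m[, j], d, weighted = TRUE),
                 ref[colnames(m)[i], colnames(m)[j]], tolerance = 1e-10)
})

test_that("label shuffling permutes jointly and preserves the distance multiset", {
  d <- copheneticMatrix(randomTree(10, seed = 3))
  s1 <- shuffleLabels(d, seed = 5)
  s2 <- shuffleLabels(d, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(as.vector(s1)), sort(as.vector(d)))
  expect_equal(diag(s1), setNames(rep(0, 10), rownames(d)))
  # 2-taxon matrix: identity or swap, off-diagonal preserved
  d2 <- d[1:2, 1:2]
  s3 <- shuffleLabels(d2, seed = 1)
  expect_equal(s3[1, 2], d2[1, 2])
})

test_that("SES.MNTD flags permutation-invariant nulls as undefined", {
  # star phylogeny: all pairwise distances equal, every shuffle is a no-op
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- matrix(c(1, 1, 1, 0, 2, 0, 1, 1), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  md <- data.frame(group = c("g", "g"), row.names = c("s1", "s2"))
  cs <- CommunitySet(star, m, md)
  expect_warning(res <- sesMNTD(cs, reps = 49, seed = 1), "null sd = 0")
  expect_true(all(res$undefined))
  expect_true(all(is.na(res$ses_mntd)))

  # community holding every taxon: label shuffle is a bijection on the
  # full set, observed equals every null exactly
  tree <- randomTree(8, seed = 2)
  full <- matrix(1, 8, 1, dimnames = list(tree$tip.label, "s1"))
  d <- copheneticMatrix(tree, order = rownames(full))
  expect_warning(resF <- sesMNTD(full, dist = d, reps = 49, seed = 1))
  expect_true(resF$undefined[1])
})

test_that("SES.MNTD is reproducible and tracks picante's observed MNTD", {
  cs <- smallCommunitySet(seed = 8, nTaxa = 20, nSamples = 4, depth = 200)
  a <- sesMNTD(cs, reps = 99, seed = 4)
  b <- sesMNTD(cs, reps = 99, seed = 4)
  expect_identical(a, b)
  skip_if_not_installed("picante")
  m <- communityCounts(cs)
  d <- copheneticMatrix(communityTree(cs), order = rownames(m))
  ref <- picante::mntd(t(m), d, abundance.weighted = FALSE)
  expect_equal(a$mntd_obs, ref, tolerance = 1e-10)
})

test_that("betaNTI is reproducible, symmetric in input order, gauge invariant", {
  cs <- smallCommunitySet(seed = 12, nTaxa = 16, nSamples = 3, depth = 150)
  m <- communityCounts(cs)
  d <- copheneticMatrix(communityTree(cs), order = rownames(m))
  r1 <- betaNTI(m, dist = d, reps = 99, seed = 7)
  r2 <- betaNTI(m, dist = d, reps = 99, seed = 7)
  expect_identical(r1, r2)

  # gauge invariance: jointly relabeling taxa in table and distance
  # matrix leaves observed betaMNTD unchanged exactly and betaNTI
  # unchanged up to null-resampling (Monte-Carlo) error
  perm <- sample(nrow(m))
  m2 <- m[perm, , drop = FALSE]
  d2 <- d[perm, perm]
  r3 <- betaNTI(m2, dist = d2, reps = 999, seed = 7)
  r1b <- betaNTI(m, dist = d, reps = 999, seed = 7)
  expect_equal(r1b$beta_mntd, r3$beta_mntd, tolerance = 1e-12)
  expect_lt(max(abs(r1b$beta_nti - r3$beta_nti)), 0.3)
})

test_that("betaNTI on a star tree and on identical samples is undefined", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- matrix(c(1, 1, 0, 0, 0, 1, 1, 0), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  d <- copheneticMatrix(star, order = rownames(m))
  expect_warning(res <- betaNTI(m, dist = d, reps = 49, seed = 1),
                 "null sd = 0")
  expect_true(all(res$undefined))

  # identical samples: every taxon is shared, so observed and every null
  # betaMNTD are exactly 0 (the taxa-labels shuffle preserves the
  # diagonal) and the pair is flagged undefined
  tree <- randomTree(10, seed = 9)
  mm <- matrix(c(rep(1, 5), rep(0, 5)), 10, 2,
               dimnames = list(tree$tip.label, c("s1", "s2")))
  dd <- copheneticMatrix(tree, order = rownames(mm))
  expect_warning(resI <- betaNTI(mm, dist = dd, reps = 49, seed = 1))
  expect_equal(resI$beta_mntd, 0)
  expect_true(resI$undefined[1])
})

test_that("neutral communities mostly fall inside the +/-2 betaNTI band", {
  cs <- simulateScenario(scenarioConfig("neutral", seed = 33))
  bn <- suppressWarnings(betaNTI(cs, reps = 199, seed = 34,
                                 pairs = "within"))
  ok <- bn$beta_nti[!bn$undefined]
  expect_gte(mean(abs(ok) < 2), 0.8)
})

test_that("betaNTI pair selection honours groups and explicit pairs", {
  cs <- smallCommunitySet(seed = 21, nTaxa = 16, nSamples = 3, nGroups = 2,
                          depth = 150)
  within <- betaNTI(cs, reps = 19, seed = 1, pairs = "within")
  expect_equal(nrow(within), 2 * choose(3, 2))
  all <- betaNTI(cs, reps = 19, seed = 1, pairs = "all")
  expect_equal(nrow(all), choose(6, 2))
  g <- sampleGroups(cs)
  expect_true(all(g[within$sample_a] == g[within$sample_b]))
  named <- betaNTI(communityCounts(cs),
                   dist = copheneticMatrix(communityTree(cs),
                                           order = taxonNames(cs)),
                   reps = 19, seed = 1,
                   pairs = cbind(sampleNames(cs)[1], sampleNames(cs)[4]))
  expect_equal(nrow(named), 1)
})
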