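test_that("threshold classification matches the published rules", {
  expect_identical(classifyPair(-3.5, 0.2), "homogeneous_selection")
  expect_identical(classifyPair(3.5, 0.2), "variable_selection")
  expect_identical(classifyPair(0.5, 0.97), "dispersal_limitation")
  expect_identical(classifyPair(0.5, -0.97), "homogenizing_dispersal")
  expect_identical(classifyPair(0.5, 0.2), "undominated")
  # boundaries: exactly +/-2 is not selection; exactly +/-0.95 is
  # undominated (strict inequalities as printed)
  expect_identical(classifyPair(2, 0.99), "dispersal_limitation")
  expect_identical(classifyPair(-2, 0.2), "undominated")
  expect_identical(classifyPair(0, 0.95), "undominated")
  expect_identical(classifyPair(0, -0.95), "undominated")
  # undefined inputs
  expect_identical(classifyPair(NA_real_, 0.2), "undefined")
  expect_identical(classifyPair(0.5, NA_real_), "undefined")
  # rc is irrelevant when selection is detected
  expect_identical(classifyPair(-2.5, NA_real_), "homogeneous_selection")
})

test_that("the five regions tile the plane with no overlap or gap", {
  bnti <- seq(-4, 4, by = 0.05)   # includes -2 and +2 exactly
  rc <- seq(-1, 1, by = 0.05)     # includes -0.95 and +0.95 exactly
  grid <- expand.grid(bnti = bnti, rc = rc)
  # independent region predicates, written from the rules directly
  inHS <- grid$bnti < -2
  inVS <- grid$bnti > 2
  inDL <- abs(grid$bnti) <= 2 & grid$rc > 0.95
  inHD <- abs(grid$bnti) <= 2 & grid$rc < -0.95
  inUD <- abs(grid$bnti) <= 2 & abs(grid$rc) <= 0.95
  membership <- inHS + inVS + inDL + inHD + inUD
  expect_true(all(membership == 1))
  lab <- classifyPair(grid$bnti, grid$rc)
  expect_identical(lab == "homogeneous_selection", inHS)
  expect_identical(lab == "variable_selection", inVS)
  expect_identical(lab == "dispersal_limitation", inDL)
  expect_identical(lab == "homogenizing_dispersal", inHD)
  expect_identical(lab == "undominated", inUD)
})

makeResults <- function(labels, group = "Oi") {
  k <- length(labels)
  data.frame(
    sample_a = paste0("s", seq_len(k)), sample_b = paste0("s", seq_len(k) + k),
    group_a = group, group_b = group,
    beta_mntd = 0.1, beta_nti = 0, bray_curtis = 0.5, rc_bray = 0,
    process_label = labels, stringsAsFactors = FALSE)
}

test_that("per-group fractions count labels over defined pairs", {
  res <- makeResults(c("homogeneous_selection", "homogeneous_selection",
                       "undominated"))
  ps <- partitionFractions(res)
  fr <- processFractions(ps)
  expect_equal(fr$fraction[fr$process == "homogeneous_selection"], 2 / 3)
  expect_equal(fr$fraction[fr$process == "undominated"], 1 / 3)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_equal(processCounts(ps)$n_pairs, 3)
})

test_that("undefined pairs are excluded from the denominator but reported", {
  res <- rbind(makeResults(c("undominated", "undefined", "undefined")))
  ps <- partitionFractions(res)
  cnt <- processCounts(ps)
  expect_equal(cnt$n_pairs, 1)
  expect_equal(cnt$n_undefined, 2)
  fr <- processFractions(ps)
  expect_equal(fr$fraction[fr$process == "undominated"], 1)

  allUndef <- makeResults(c("undefined", "undefined"))
  ps2 <- partitionFractions(allUndef)
  expect_equal(processCounts(ps2)$n_pairs, 0)
  expect_equal(processCounts(ps2)$n_undefined, 2)
  expect_true(all(is.na(processFractions(ps2)$fraction)))
})

test_that("between-group pairs are ignored and tiny groups warn", {
  res <- makeResults(c("undominated", "undominated"))
  res$group_b[2] <- "Oe"   # cross-group pair
  md <- data.frame(group = c("Oi", "Oi", "Oi", "Oe"),
                   row.names = paste0("s", 1:4))
  expect_warning(ps <- partitionFractions(res, metadata = md), "< 2 samples")
  expect_equal(processCounts(ps)$n_pairs, 1)
  expect_false("Oe" %in% processCounts(ps)$group)
})

test_that("summaries serialize to JSON and tidy TSV", {
  ps <- partitionFractions(makeResults(c("undominated",
                                         "dispersal_limitation")))
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  writeProcessSummary(ps, jsonPath = jp, tsvPath = tp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$Oi$undominated, 0.5)
  expect_equal(back$Oi$n_pairs, 2)
  tidy <- utils::read.delim(tp)
  expect_setequal(unique(tidy$process), assemblyProcesses())
})
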