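test_that("the rule set forces the worked classifications", {
  expect_equal(classifyGene(2.0, 0.5, "up", "unique")$label, "frontloaded")
  expect_equal(classifyGene(0.9, 1.5, "down", "unique")$label,
               "relatively_upregulated")
  expect_equal(classifyGene(0.8, 0.9, "up", "unique")$label,
               "stress_tolerance")
  expect_equal(classifyGene(0.5, 0.8, "down", "unique")$label,
               "stress_tolerance")
  # higher constitutively but not lower under stress: left unclassified
  expect_equal(classifyGene(2.0, 1.5, "up", "unique")$label, "unclassified")
  expect_equal(classifyGene(2.0, 0.5, "up", "dual_discordant")$label,
               "opposite")
  expect_equal(classifyGene(2.0, 0.5, "up", "dual_concordant")$label,
               "unclassified")
  expect_error(classifyGene(2.0, 0.5, "up", "not_a_responder"),
               "not a responder")
  expect_error(classifyGene(-1, 0.5, "up", "unique"), "positive")

  # dead band: near-unit ratios become ties -> unclassified
  expect_equal(classifyGene(1.04, 0.5, "up", "unique", epsilon = 0.1)$label,
               "unclassified")
  expect_equal(classifyGene(2.0, 0.5, "up", "unique", epsilon = 0.1)$label,
               "frontloaded")
})

test_that("raising rC above 1 can only promote towards frontloaded", {
  # monotonicity with d = up, rT < 1 fixed
  labels <- vapply(c(0.6, 0.9, 0.999, 1.001, 1.5, 4, 50), function(rc)
    classifyGene(rc, 0.5, "up", "unique")$label, character(1))
  ranks <- c(stress_tolerance = 1, unclassified = 1, frontloaded = 2)
  expect_true(all(diff(ranks[labels]) >= 0))
  expect_equal(labels[length(labels)], "frontloaded")
})

test_that("classifyPatterns partitions responders and counts them", {
  se <- simulateNueCounts(nGenes = 500, nReplicates = 3,
                          archetypeCounts = c(frontloaded = 25,
                                              stress_tolerance_up = 5,
                                              stress_tolerance_down = 5,
                                              relatively_upregulated = 25,
                                              opposite = 4), seed = 14)
  cat <- buildContrastCatalog(se)
  pt <- classifyPatterns(cat, "T13")
  expect_true(all(pt$label %in% c("frontloaded", "stress_tolerance",
                                  "relatively_upregulated", "opposite",
                                  "unclassified")))
  counts <- S4Vectors::metadata(pt)$labelCounts
  expect_equal(sum(unlist(counts)), nrow(pt))
  expect_setequal(rownames(pt), degIDs(cat, "R13"))
  # opposite only for dual responders with discordant directions
  expect_true(all(pt$status[pt$label == "opposite"] == "dual_discordant"))
})

test_that("classification is mirror-symmetric under genotype swap", {
  for (s in 1:3) {
    se <- simulateNueCounts(nGenes = 250, nReplicates = 3,
                            archetypeCounts = c(frontloaded = 15,
                                                relatively_upregulated = 15,
                                                stress_tolerance_up = 5),
                            seed = 100 + s)
    ptA <- classifyPatterns(buildContrastCatalog(se), "T13")
    ptB <- classifyPatterns(buildContrastCatalog(swapGenotypes(se)), "T29")
    expect_setequal(rownames(ptA), rownames(ptB))
    ord <- rownames(ptA)
    expect_equal(ptA[ord, "label"], ptB[ord, "label"])
    expect_equal(ptA[ord, "rC"], ptB[ord, "rC"], tolerance = 1e-9)
  }
})

test_that("the direction chi-square matches its closed forms and oracle", {
  r <- chiSquareDirection(50, 50)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  r2 <- chiSquareDirection(70, 30)
  expect_equal(r2$statistic, 16)
  expect_equal(r2$p.value, 6.334248e-05, tolerance = 1e-6)
  expect_equal(r2$p.value,
               stats::chisq.test(c(70, 30), p = c(0.5, 0.5))$p.value,
               tolerance = 1e-12)

  expect_equal(chiSquareDirection(0, 100)$statistic, 100)
  expect_error(chiSquareDirection(0, 0), "zero total")
  expect_error(chiSquareDirection(-1, 5), "non-negative")
})

test_that("permuting gene order leaves labels unchanged", {
  se <- simulateNueCounts(nGenes = 200, nReplicates = 3,
                          archetypeCounts = c(frontloaded = 20), seed = 15)
  cat1 <- buildContrastCatalog(se)
  perm <- sample(nrow(se))
  se2 <- NueExperiment(counts(se)[perm, ], genotype = genotype(se),
                       condition = condition(se))
  cat2 <- buildContrastCatalog(se2)
  pt1 <- classifyPatterns(cat1, "T13")
  pt2 <- classifyPatterns(cat2, "T13")
  expect_setequal(rownames(pt1), rownames(pt2))
  expect_equal(pt1[rownames(pt1), "label"], pt2[rownames(pt1), "label"])
})
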