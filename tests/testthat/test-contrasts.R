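# Build a ContrastCatalog directly from fabricated DE tables so the set
# algebra can be checked exactly.
fakeCatalog <- function(degs, universe = paste0("g", 1:10)) {
  results <- lapply(c(R29 = "R29", R13 = "R13", GC = "GC", GT = "GT"),
                    function(cn) {
    ids <- degs[[cn]]
    up <- if (is.null(names(ids))) ids else ids[names(ids) != "down"]
    res <- S4Vectors::DataFrame(
      meanA = rep(10, length(universe)), meanB = rep(10, length(universe)),
      log2FC = ifelse(universe %in% ids, 1, 0),
      signedFC = 1, p = 1, padj = ifelse(universe %in% ids, 0.01, 1),
      isDEG = universe %in% ids,
      direction = ifelse(universe %in% ids, "up", "none"),
      row.names = universe)
    S4Vectors::metadata(res) <- list(contrast = cn, alpha = 0.05)
    res
  })
  new("ContrastCatalog", results = results, alpha = 0.05,
      sizeFactors = c(a = 1))
}

test_that("unique responders are the focal-minus-other set difference", {
  cat <- fakeCatalog(list(R13 = c("g1", "g2", "g3"), R29 = "g3",
                          GC = character(), GT = character()))
  r <- uniqueResponders(cat, "T13")
  expect_setequal(r$unique, c("g1", "g2"))
  expect_setequal(r$commonResponse, "g3")
  expect_setequal(r$unionAll, c("g1", "g2", "g3"))

  # disjoint DEG sets: unique sets equal the full sets
  cat2 <- fakeCatalog(list(R13 = c("g1", "g2"), R29 = c("g5", "g6"),
                           GC = character(), GT = character()))
  expect_setequal(uniqueResponders(cat2, "T13")$unique, c("g1", "g2"))
  expect_setequal(uniqueResponders(cat2, "T29")$unique, c("g5", "g6"))
  expect_length(intersect(uniqueResponders(cat2, "T13")$unique,
                          uniqueResponders(cat2, "T29")$unique), 0)
})

test_that("venn counts satisfy the set identities", {
  cat <- fakeCatalog(list(R13 = c("g1", "g2"), R29 = c("g2", "g3"),
                          GC = c("g4"), GT = character()))
  v <- vennCounts(cat)
  with(v$pairs, expect_equal(union, nA + nB - overlap))
  row <- v$pairs[v$pairs$contrastA == "R29" & v$pairs$contrastB == "R13", ]
  expect_equal(row$overlap, 1)
  expect_equal(row$union, 3)
  # union over the four contrasts equals an independently computed union
  expect_equal(v$unionAll, length(Reduce(union, list(c("g1", "g2"),
                                                     c("g2", "g3"), "g4",
                                                     character()))))

  empty <- fakeCatalog(list(R13 = character(), R29 = character(),
                            GC = character(), GT = character()))
  ve <- vennCounts(empty)
  expect_true(all(ve$pairs$overlap == 0))
  expect_equal(ve$unionAll, 0)
})

test_that("the catalog runs all four contrasts with fixed orientation", {
  se <- simulateNueCounts(nGenes = 300, nReplicates = 3,
                          archetypeCounts = c(constitutive = 40),
                          dispersion = 0.02, seed = 13)
  cat <- buildContrastCatalog(se)
  # constitutive genes differ between genotypes only: DEGs confined to GC/GT
  expect_lte(length(degIDs(cat, "R13")), 2)
  expect_lte(length(degIDs(cat, "R29")), 2)
  expect_gt(length(degIDs(cat, "GC")), 30)
  expect_gt(length(degIDs(cat, "GT")), 30)
  # orientation: constitutive genes are planted higher in T29
  expect_gt(mean(deResult(cat, "GC")[degIDs(cat, "GC"), "direction"] == "up"),
            0.8)
  # deterministic given identical input
  cat2 <- buildContrastCatalog(se)
  expect_equal(deResult(cat, "GC")$padj, deResult(cat2, "GC")$padj)

  # a missing design cell is reported by name
  keep <- designCells(se) != "T13_T"
  se2 <- NueExperiment(counts(se)[, keep], genotype = genotype(se)[keep],
                       condition = condition(se)[keep])
  expect_error(buildContrastCatalog(se2), "T13_T")
})
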