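test_that("method-of-moments dispersion matches hand computation", {
  A <- matrix(c(10, 20), 1)
  B <- matrix(c(10, 20), 1)
  # qbar = 15, pooled within-group variance 50 -> alpha = 35/225
  expect_equal(momDispersion(A, B, method = "per-gene"), 35 / 225)

  # variance below the mean floors at zero
  A2 <- matrix(c(100, 101), 1)
  B2 <- matrix(c(100, 100), 1)
  expect_equal(momDispersion(A2, B2, method = "per-gene"), 0)

  # Poisson data: large-replicate estimate collapses towards zero
  set.seed(6)
  A3 <- matrix(rpois(5000, 100), 1)
  B3 <- matrix(rpois(5000, 100), 1)
  a <- momDispersion(A3, B3, method = "per-gene")
  expect_gte(a, 0)
  expect_lt(a, 0.01)

  # zero-mean gene is flagged undefined
  expect_true(is.na(momDispersion(matrix(0, 1, 2), matrix(0, 1, 2),
                                  method = "per-gene")))
  # no replication at all falls back to Poisson with a warning
  expect_warning(z <- momDispersion(matrix(5, 1, 1), matrix(7, 1, 1)),
                 "Poisson")
  expect_equal(z, 0)
})

test_that("blended dispersion shrinks halfway to the across-gene mean", {
  set.seed(7)
  A <- matrix(rnbinom(40 * 3, mu = 200, size = 20), 40, 3)
  B <- matrix(rnbinom(40 * 3, mu = 200, size = 20), 40, 3)
  pg <- momDispersion(A, B, method = "per-gene")
  bl <- momDispersion(A, B, method = "blend")
  expect_equal(bl, 0.5 * pg + 0.5 * mean(pg))
})

test_that("BH adjustment matches brute force and validates input", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-15)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("the exact test is symmetric, Poisson-binomial, and validated", {
  # modal symmetric observation -> p = 1
  p <- nbExactTest(50, 50, c(1, 1), c(1, 1), q0 = 50, alpha = 0.1)
  expect_equal(as.numeric(p), 1)

  # alpha = 0 with equal library sizes equals the exact binomial test
  for (tot in c(5, 17, 40)) {
    for (a in 0:tot) {
      mine <- nbExactTest(a, tot - a, c(1, 1, 1), c(1, 1), q0 = tot / 5,
                          alpha = 0)
      expect_equal(as.numeric(mine), binomTwoSidedEnum(a, tot, 3 / 5),
                   tolerance = 1e-12)
    }
  }

  expect_error(nbExactTest(-1, 5, 1, 1, 3, 0), "non-negative")
  expect_error(nbExactTest(1, 5, 1, 1, 3, -0.2), "non-negative")
  expect_equal(as.numeric(nbExactTest(0, 0, 1, 1, 0, 0.1)), 1)
})

test_that("the large-total normal approximation tracks the exact tail", {
  sf <- rep(1, 3)
  for (split in list(c(6000, 6100), c(5800, 6500))) {
    q0 <- sum(split) / 6
    exact <- nbExactTest(split[1], split[2], sf, sf, q0, 0.01, cap = 1e6)
    appr <- nbExactTest(split[1], split[2], sf, sf, q0, 0.01, cap = 100)
    expect_equal(attr(appr, "method"), "normal")
    expect_lt(abs(log(as.numeric(appr) + 1e-12) -
                    log(as.numeric(exact) + 1e-12)), 0.35)
  }
})

test_that("signed fold change keeps magnitude >= 1 and is antisymmetric", {
  expect_equal(signedFoldChange(5, 5), 1)
  expect_equal(signedFoldChange(2, 10, pseudocount = 0), 5)
  expect_equal(signedFoldChange(10, 2, pseudocount = 0), -5)
  set.seed(9)
  a <- runif(100, 0, 50); b <- runif(100, 0, 50)
  fab <- signedFoldChange(a, b); fba <- signedFoldChange(b, a)
  nontrivial <- abs(fab) > 1
  expect_equal(fab[nontrivial], -fba[nontrivial])
  expect_true(all(abs(fab) >= 1))
  expect_error(signedFoldChange(-1, 2), "non-negative")
})

test_that("runContrast filters, calls and errors as specified", {
  se <- makeToyExperiment(nGenes = 80, nReplicates = 3, seed = 10)
  k <- counts(se)
  k[1, ] <- c(1, 0, 0, 0, 1, 0, 0, 0, 2, 0, 0, 1)   # total 5 < 10: filtered
  k[2, designCells(se) == "T13_T"] <- k[2, designCells(se) == "T13_T"] * 12
  se2 <- NueExperiment(k, genotype = genotype(se), condition = condition(se))
  res <- runContrast(se2, "T13_C", "T13_T")
  expect_equal(res$p[1], 1)
  expect_equal(res$padj[1], 1)
  expect_equal(res$direction[1], "none")
  expect_true(res$isDEG[2])
  expect_equal(res$direction[2], "up")
  expect_true(all(res$padj >= res$p))
  expect_true(all(res$isDEG == (res$padj < 0.05)))

  expect_error(runContrast(se2, "T13_C", "T13_C"), "disjoint")
  expect_error(runContrast(se2, "T13_C", "nonexistent"), "matches no samples")
})

test_that("reversing a contrast flips directions and signs, not membership", {
  se <- simulateNueCounts(nGenes = 150, nReplicates = 3,
                          archetypeCounts = c(frontloaded = 20), seed = 11)
  fwd <- runContrast(se, "T13_C", "T13_T")
  rev <- runContrast(se, "T13_T", "T13_C")
  expect_equal(fwd$isDEG, rev$isDEG)
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  flip <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(flip[fwd$direction]), unname(rev$direction))
  nontrivial <- abs(fwd$signedFC) > 1
  expect_equal(fwd$signedFC[nontrivial], -rev$signedFC[nontrivial],
               tolerance = 1e-9)
})
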