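test_that("the TF-based cutoff follows the stated relaxation rule", {
  z <- stats::setNames(c(-3, -1.5, -0.2, -1.8, -2.5, 0.4),
                       paste0("s", 1:6))

  # all TF-outlier samples beyond the target's own cutoff: no relaxation
  r <- tfBasedCutoff(z, c("s1", "s5"), "under")
  expect_equal(r$cutoffZ, -2)
  expect_setequal(r$relaxed, c("s1", "s5"))

  # least-extreme TF-outlier sample at z = -1.5 sets the cutoff
  r <- tfBasedCutoff(z, c("s1", "s2"), "under")
  expect_equal(r$cutoffZ, -1.5)
  expect_setequal(r$relaxed, c("s1", "s2", "s4", "s5"))

  # TF-outlier samples all within |z| < 1 clamp at |z| = 1
  r <- tfBasedCutoff(z, c("s3", "s6"), "under")
  expect_equal(r$cutoffZ, -1)
  expect_setequal(r$relaxed, c("s1", "s2", "s4", "s5"))

  # over-direction mirror
  zo <- stats::setNames(c(3, 1.4, 0.2, 2.6), paste0("s", 1:4))
  r <- tfBasedCutoff(zo, c("s1", "s2"), "over")
  expect_equal(r$cutoffZ, 1.4)
  expect_setequal(r$relaxed, c("s1", "s2", "s4"))

  expect_error(tfBasedCutoff(z, character(), "under"), "empty")
  expect_error(tfBasedCutoff(z, "s1", "none"), "direction")
})

test_that("the modified contingency table counts cells as defined", {
  samples <- paste0("s", 1:20)
  tab <- buildContingency(c("s1", "s2", "s3"), c("s2", "s3", "s4"),
                          c("s2", "s3", "s4", "s5"), samples)
  expect_identical(tab, c(tp = 2L, fp = 1L, fn = 1L, tn = 16L))

  # relaxed set equal to the expression set floors fp at 0
  tab <- buildContingency(c("s1", "s2"), c("s2", "s3"), c("s2", "s3"),
                          samples)
  expect_identical(tab[["fp"]], 0L)

  # disjoint sets give tp = 0
  tab <- buildContingency(c("s1", "s2"), c("s3", "s4"),
                          c("s3", "s4"), samples)
  expect_identical(tab[["tp"]], 0L)

  expect_error(buildContingency("s99", "s1", "s1", samples), "cohort")
  expect_error(buildContingency("s1", c("s2", "s3"), "s2", samples),
               "subset")
})

test_that("fisherExact agrees with hypergeometric enumeration", {
  # worked example: [[3,1],[1,3]], one-sided greater = 17/70
  expect_equal(fisherExact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
                           "greater"), 17 / 70, tolerance = 1e-12)
  # zero margin carries no evidence
  expect_equal(fisherExact(matrix(c(0, 0, 4, 6), 2, byrow = TRUE)), 1)
  # oracle sweep over random tables and all alternatives
  set.seed(101)
  for (i in 1:120) {
    tab <- randomTable()
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisherExact(tab, alt), oracleFisher(tab, alt),
                   tolerance = 1e-10,
                   label = paste(alt, paste(tab, collapse = ",")))
    }
  }
})

test_that("p is invariant to simultaneously transposing the table", {
  set.seed(55)
  for (i in 1:40) {
    tab <- randomTable()
    swapped <- tab[2:1, 2:1]  # swap both rows and columns
    expect_equal(fisherExact(tab, "greater"),
                 fisherExact(swapped, "greater"), tolerance = 1e-12)
  }
})

test_that("joint evidence never weakens the one-sided association", {
  # adding one sample to both the TF and target outlier sets moves a
  # tn-count into tp; p (greater) must not increase
  samples <- paste0("s", 1:30)
  tf <- paste0("s", 1:4); ex <- paste0("s", 3:8)
  for (extra in paste0("s", 20:24)) {
    t1 <- buildContingency(tf, ex, ex, samples)
    t2 <- buildContingency(c(tf, extra), c(ex, extra), c(ex, extra),
                           samples)
    p1 <- fisherExact(matrix(t1, 2, byrow = TRUE), "greater")
    p2 <- fisherExact(matrix(t2, 2, byrow = TRUE), "greater")
    expect_lte(p2, p1 + 1e-12)
    tf <- c(tf, extra); ex <- c(ex, extra)
  }
})

test_that("pairwise inference wires direction, sign, q-values together", {
  # hand-built calls: one over-expressed TF whose outlier samples are
  # exactly the under-outliers of mir1; mir2 is uncorrelated
  ns <- 20
  z <- matrix(0, 3, ns,
              dimnames = list(c("TF1", "mir1", "mir2"),
                              paste0("s", 1:ns)))
  z["TF1", 1:4] <- 3
  z["mir1", 1:4] <- -3
  z["mir2", c(5, 9)] <- -2.6
  ab <- makeAb(z, c("over", "under", "under"))
  m <- z + 8  # any matrix with matching dimnames
  x <- TFTargetExperiment(m, c(rep("normal", 8), rep("primary", 6),
                               rep("metastatic", 6)),
                          c("TF", "target", "target"))
  tests <- inferPairwise(ab, x)
  expect_identical(nrow(tests), 2L)
  strong <- tests[tests$target == "mir1", ]
  expect_identical(strong$sign, "inhibition")
  expect_identical(strong$tp, 4L)
  expect_lt(strong$q, 0.01)
  # BH with two tests never lowers p
  expect_true(all(tests$q >= tests$p))
})

test_that("a single tested pair keeps q equal to p", {
  z <- matrix(0, 2, 12, dimnames = list(c("TF1", "mir1"),
                                        paste0("s", 1:12)))
  z["TF1", 1:3] <- 2.5
  z["mir1", 2:4] <- -2.5
  ab <- makeAb(z, c("over", "under"))
  x <- TFTargetExperiment(z + 5, c(rep("normal", 6), rep("metastatic", 6)),
                          c("TF", "target"))
  tests <- inferPairwise(ab, x)
  expect_identical(nrow(tests), 1L)
  expect_equal(tests$q, tests$p)
})

test_that("null cohorts stay near the nominal false discovery rate", {
  # zero effect size: the fraction of q < 0.01 pairs over several null
  # cohorts must not exceed twice the nominal FDR
  nSig <- 0L; nTest <- 0L
  for (s in 1:6) {
    sim <- simulateCohort(synthConfig(tfEffect = 0, targetEffect = 0,
                                      nDecoyTFs = 80, nDecoyTargets = 120,
                                      nSharedTargets = 0, seed = s))
    ab <- discretizeAberrations(sim$experiment)
    tests <- inferPairwise(ab, sim$experiment)
    nTest <- nTest + nrow(tests)
    nSig <- nSig + sum(tests$q < 0.01)
  }
  # cohorts without a single aberrant TF/target pair contribute no tests
  # and trivially respect the bound
  expect_lte(nSig / max(nTest, 1L), 0.02)
})
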