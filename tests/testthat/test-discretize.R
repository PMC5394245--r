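test_that("degenerate and well-separated vectors are fitted sensibly", {
  # constant vector: one component, everyone assigned to it, no outliers
  fit <- fitMixture(rep(5, 30))
  expect_identical(fit$G, 1L)
  expect_true(all(fit$classification == 1L))
  out <- callOutliers(fit, stats::setNames(rep(5, 30), paste0("s", 1:30)))
  expect_false(any(out$over) || any(out$under))

  # 80 draws at 0 and 20 at 5: normal component is the big cluster and
  # assignments recover the generative labels almost perfectly
  set.seed(7)
  v <- c(rnorm(80, 0, 1), rnorm(20, 5, 1))
  fit <- fitMixture(v)
  expect_gte(fit$G, 2L)
  counts <- tabulate(fit$classification, fit$G)
  expect_identical(fit$normal, which.max(counts))
  labels <- rep(1:2, c(80, 20))
  # map each generative label to its majority component
  agree <- max(
    mean((fit$classification == fit$normal) == (labels == 1)),
    mean((fit$classification == fit$normal) == (labels == 2)))
  expect_gte(agree, 0.95)
})

test_that("a single Gaussian is rarely split into two components", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (fitMixture(rnorm(100))$G == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("z-scores are arithmetic in the normal component and strict", {
  fit <- list(mu = c(10, 0), sigma = c(2, 1), normal = 1L)
  v <- stats::setNames(c(10, 14, 10 + 2 * 2, 10 - 3 * 2), paste0("s", 1:4))
  out <- callOutliers(fit, v, zThreshold = 2)
  expect_equal(unname(out$z), c(0, 2, 2, -3))
  expect_false(out$over[["s1"]])
  expect_false(out$over[["s3"]])   # |z| == threshold is not an outlier
  expect_true(out$under[["s4"]])
  expect_false(any(out$under[1:3]))
})

test_that("direction selection follows metastatic enrichment", {
  cls <- stats::setNames(c(rep("normal", 20), rep("primary", 20),
                           rep("metastatic", 10)), paste0("s", 1:50))
  met <- paste0("s", 41:50)

  # over-outliers all metastatic, nothing under
  sel <- selectDirection(met[1:4], character(), cls)
  expect_identical(sel$direction, "over")

  # no outliers at all
  expect_identical(selectDirection(character(), character(),
                                   cls)$direction, "none")

  # 5 over-outliers (4 metastatic) vs 3 under-outliers (0 metastatic):
  # p must match the hypergeometric enumeration exactly
  over <- c(met[1:4], "s1")
  under <- paste0("s", 2:4)
  sel <- selectDirection(over, under, cls)
  expect_identical(sel$direction, "over")
  pOracle <- sum(vapply(4:5, oracleTableProb, 0, K = 10, N = 50, k = 5))
  expect_equal(sel$p, pOracle, tolerance = 1e-12)

  # no metastatic samples anywhere is an error
  expect_error(selectDirection("s1", character(),
                               stats::setNames(rep("normal", 3),
                                               paste0("s", 1:3))),
               "metastatic")
})

test_that("lowering the z threshold never removes an outlier call", {
  set.seed(11)
  for (i in 1:20) {
    v <- stats::setNames(rnorm(60, sample(5:10, 1), runif(1, 0.5, 2)),
                         paste0("s", 1:60))
    fit <- fitMixture(v)
    hi <- callOutliers(fit, v, zThreshold = 2)
    lo <- callOutliers(fit, v, zThreshold = 1.2)
    expect_true(all(lo$over[hi$over]))
    expect_true(all(lo$under[hi$under]))
  }
})

test_that("aberration flags are invariant to affine rescaling of a gene", {
  set.seed(23)
  sim <- simulateCohort(synthConfig(nDecoyTFs = 10, nDecoyTargets = 10,
                                    nSharedTargets = 6, seed = 23))
  x <- sim$experiment
  ab1 <- discretizeAberrations(x)
  m <- exprMatrix(x)
  g <- sim$truth@sharedTargets[1]
  m[g, ] <- 37.5 * m[g, ] - 12
  x2 <- TFTargetExperiment(m, sampleClass(x), geneRole(x))
  ab2 <- discretizeAberrations(x2)
  expect_identical(aberrationFlags(ab2)[g, ], aberrationFlags(ab1)[g, ])
  expect_identical(aberrationDirection(ab2)[[g]],
                   aberrationDirection(ab1)[[g]])
})

test_that("well-separated planted aberrations are recovered discretely", {
  sim <- simulateCohort(synthConfig(nDecoyTFs = 30, nDecoyTargets = 30,
                                    nSharedTargets = 10, tfEffect = 6,
                                    targetEffect = -6, seed = 5))
  ab <- discretizeAberrations(sim$experiment)
  agreement <- mean(aberrationFlags(ab) == truthFlags(sim$truth))
  expect_gte(agreement, 0.99)
})

test_that("matrix discretization is deterministic", {
  sim <- simulateCohort(synthConfig(nDecoyTFs = 5, nDecoyTargets = 5,
                                    nSharedTargets = 4, seed = 3))
  a1 <- discretizeAberrations(sim$experiment)
  a2 <- discretizeAberrations(sim$experiment)
  expect_identical(aberrationFlags(a1), aberrationFlags(a2))
  expect_identical(zScores(a1), zScores(a2))
})
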