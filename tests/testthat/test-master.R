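test_that("the master-TF binomial test matches the exact sum", {
  expect_equal(binomialMasterTest(0, 20, 0.1), 1)
  expect_equal(binomialMasterTest(10, 20, 0.1),
               oracleBinomUpper(10, 20, 0.1), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:30, 1); x <- sample(0:n, 1); p <- runif(1, 0.02, 0.9)
    expect_equal(binomialMasterTest(x, n, p), oracleBinomUpper(x, n, p),
                 tolerance = 1e-10)
  }
  expect_error(binomialMasterTest(3, 10, 0), "degenerate")
  expect_error(binomialMasterTest(3, 10, 1), "degenerate")
  expect_error(binomialMasterTest(11, 10, 0.5), "universe")
})

test_that("target overlap follows the hypergeometric oracle", {
  a <- paste0("g", 1:10); b <- c(paste0("g", 1:6), paste0("h", 1:2))
  tab <- matrix(c(6, 4, 2, 188), 2, byrow = TRUE)
  expect_equal(targetOverlapTest(a, b, 200),
               oracleFisher(tab, "greater"), tolerance = 1e-10)
  # identical sets reach the minimal p attainable for those margins
  ident <- targetOverlapTest(a, a, 200)
  expect_equal(ident, oracleTableProb(10, 10, 200, 10), tolerance = 1e-12)
  # disjoint sets carry no enrichment evidence
  expect_gte(targetOverlapTest(a, paste0("h", 1:8), 200), 0.999)
  expect_error(targetOverlapTest(a, b, 0), "universe")
})

test_that("mutual exclusivity is a depletion test with Haldane odds", {
  # perfectly co-occurring sets cannot look exclusive
  s <- paste0("s", 1:6)
  expect_equal(mutualExclusivityTest(s, s, 20)$p, 1)

  # the worked disjoint case: p = C(12,8)/C(20,8) = 495/125970
  r <- mutualExclusivityTest(paste0("s", 1:8), paste0("s", 9:16), 20)
  expect_equal(r$p, 495 / 125970, tolerance = 1e-12)
  expect_lt(r$oddsRatio, 1)  # Haldane-corrected, depleted overlap

  # symmetry in the two arguments, checked against the oracle
  set.seed(77)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    a <- sample(paste0("s", 1:n), sample(2:7, 1))
    b <- sample(paste0("s", 1:n), sample(2:7, 1))
    r1 <- mutualExclusivityTest(a, b, n)
    r2 <- mutualExclusivityTest(b, a, n)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    both <- length(intersect(a, b))
    tab <- matrix(c(both, length(a) - both, length(b) - both,
                    n - length(a) - length(b) + both), 2, byrow = TRUE)
    expect_equal(r1$p, oracleFisher(tab, "less"), tolerance = 1e-10)
  }
  expect_error(mutualExclusivityTest("s1", "s2", 0), "cohort")
})

test_that("the bimodality index has its closed forms and invariances", {
  expect_equal(bimodalityIndex(0.3, 4, 4, 2), 0)
  expect_equal(bimodalityIndex(0.5, 0, 2, 1), 1)     # 2 * sqrt(0.25)
  expect_equal(bimodalityIndex(0.3, 0, 4, 1), 4 * sqrt(0.21),
               tolerance = 1e-12)
  expect_error(bimodalityIndex(0.5, 0, 1, 0), "sigma")
  expect_error(bimodalityIndex(1, 0, 1, 1), "proportion")
  # affine invariance of the expression axis
  set.seed(13)
  for (i in 1:40) {
    p <- runif(1, 0.05, 0.95); mu <- rnorm(2, 0, 5); s <- runif(1, .2, 3)
    a <- runif(1, 0.1, 50); b <- rnorm(1, 0, 20)
    expect_equal(bimodalityIndex(p, a * mu[1] + b, a * mu[2] + b, a * s),
                 bimodalityIndex(p, mu[1], mu[2], s), tolerance = 1e-12)
  }
})

test_that("screening applies the strict cohort and bimodality cutoffs", {
  set.seed(19)
  bimodal <- c(rnorm(70, 0, 1), rnorm(30, 4, 1))   # BI ~ 4*sqrt(.21)
  unimodal <- rnorm(100)
  m99 <- rbind(bi = bimodal[1:99], uni = unimodal[1:99])
  colnames(m99) <- paste0("s", 1:99)
  r <- screenDataset(m99)
  expect_false(r$datasetPass)                      # 99 samples fail

  m101 <- rbind(bi = c(bimodal, rnorm(1, 0)), uni = c(unimodal, rnorm(1)))
  colnames(m101) <- paste0("s", 1:101)
  r <- screenDataset(m101)
  expect_true(r$datasetPass)                       # strict > 100
  tab <- r$genes
  expect_true(tab$pass[tab$gene == "bi"])
  expect_false(tab$pass[tab$gene == "uni"])
  expect_gt(tab$bi[tab$gene == "bi"], 1.1)
})

test_that("the random-predictor baseline stays below 13 percent", {
  expect_equal(randomPredictorRate(226), 100 * 226 / 1800)
  expect_equal(randomPredictorRate(0), 0)
  expect_lt(max(randomPredictorRate(c(226, 94, 129))), 13)
})

test_that("the master report wires the three statistics together", {
  # network: Ta regulates g1..g6, Tb regulates g4..g6 of a 10-target
  # universe drawn from 4 candidate TFs
  cand <- data.frame(
    tf = c(rep("Ta", 6), rep("Tb", 3)),
    target = c(paste0("g", 1:6), paste0("g", 4:6)),
    p = 1e-8)
  net <- greedySelect(cand, S = 4, n = 10)
  z <- matrix(0, 2, 12, dimnames = list(c("Ta", "Tb"), paste0("s", 1:12)))
  z["Ta", 1:3] <- 3; z["Tb", 4:6] <- 3
  ab <- makeAb(z, c("over", "over"))
  rep <- masterTFReport(net, ab, candidates = cand)
  expect_setequal(rep@perTF$tf, c("Ta", "Tb"))
  rate <- nrow(cand) / (4 * 10)
  expect_equal(rep@backgroundRate, rate)
  expect_equal(rep@perTF$binomP[rep@perTF$tf == "Ta"],
               binomialMasterTest(6, 10, rate), tolerance = 1e-12)
  pair <- rep@perPair
  expect_identical(pair$overlap, 3L)
  expect_equal(pair$overlapP, targetOverlapTest(paste0("g", 1:6),
                                                paste0("g", 4:6), 10),
               tolerance = 1e-12)
  expect_equal(pair$exclusivityP,
               mutualExclusivityTest(paste0("s", 1:3), paste0("s", 4:6),
                                     12)$p, tolerance = 1e-12)
  expect_identical(pair$bothOver, 0L)
})
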