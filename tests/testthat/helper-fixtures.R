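# Fixtures are built in code at test time; nothing is stored on disk.

# tiny deterministic experiment: 2 TFs + 2 targets over 10 samples
smallExperiment <- function() {
  m <- rbind(
    TF1  = c(1, 1, 2, 1, 2, 1, 9, 9, 1, 2),
    TF2  = c(2, 1, 1, 2, 1, 2, 1, 1, 9, 9),
    mir1 = c(8, 9, 8, 9, 8, 9, 1, 1, 1, 1),
    mir2 = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:10)
  TFTargetExperiment(
    m,
    sampleClass = c(rep("normal", 3), rep("primary", 3),
                    rep("metastatic", 4)),
    geneRole = c("TF", "TF", "target", "target"))
}

# hand-built AberrationCalls for pairwise unit tests: flags/z/directions
# are specified directly, with a trivial normal-component fit per gene
makeAb <- function(z, direction, zThreshold = 2) {
  flags <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  for (i in seq_len(nrow(z))) {
    if (direction[i] == "over") flags[i, ] <- z[i, ] > zThreshold
    if (direction[i] == "under") flags[i, ] <- z[i, ] < -zThreshold
  }
  fits <- lapply(seq_len(nrow(z)), function(i)
    list(mu = 0, sigma = 1, pro = 1,
         classification = rep(1L, ncol(z)), normal = 1L, G = 1L))
  names(fits) <- rownames(z)
  new("AberrationCalls", flags = flags, z = z, direction = direction,
      enrichP = rep(NA_real_, nrow(z)), zThreshold = zThreshold,
      fits = fits)
}

# random candidate-edge table for MDL tests (additive objective: no
# tpSamples column)
randomCandidates <- function(nTF = 8, nTarget = 12, density = 0.4) {
  tfs <- sprintf("T%02d", seq_len(nTF))
  tgts <- sprintf("g%02d", seq_len(nTarget))
  grid <- expand.grid(tf = tfs, target = tgts,
                      stringsAsFactors = FALSE)
  grid <- grid[stats::runif(nrow(grid)) < density, , drop = FALSE]
  grid$p <- 10^stats::runif(nrow(grid), -8, -0.5)
  rownames(grid) <- NULL
  grid
}
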