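#' Configuration of the synthetic cohort generator
#'
#' Defines a cohort in which `k` planted driver TFs are overexpressed in
#' disjoint blocks of the metastatic samples and co-repress a shared
#' target module, against a background of decoy TFs and targets. Effect
#' sizes are expressed in units of the per-gene baseline standard
#' deviation, so recovery difficulty is scale-free.
#'
#' @param nNormal,nPrimary,nMetastatic sample counts per class
#'   (defaults 20/25/15).
#' @param k number of planted drivers (default 3).
#' @param partition optional list of `k` disjoint metastatic sample-index
#'   vectors; default splits the metastatic samples into `k` equal
#'   consecutive blocks.
#' @param nSharedTargets size of the co-repressed target module
#'   (default 40).
#' @param nDecoyTFs,nDecoyTargets decoy gene counts (defaults 150/200).
#' @param tfEffect driver overexpression shift in sigma units
#'   (default 3).
#' @param targetEffect shared-target shift in sigma units, negative for
#'   repression (default -3).
#' @param baselineMean,baselineSpread per-gene baseline means are drawn
#'   from Normal(baselineMean, baselineSpread) (defaults 8 and 2,
#'   log2-expression scale).
#' @param geneSigma per-gene baseline standard deviation (default 1; the
#'   sigma the effects are expressed in).
#' @param noiseSigma additional per-entry measurement noise (default
#'   0.25).
#' @param flipRate probability that any single planted effect entry is
#'   dropped (label noise; default 0).
#' @param seed RNG seed (integer).
#' @return named list of class `SynthConfig`.
#' @export
synthConfig <- function(nNormal = 20, nPrimary = 25, nMetastatic = 15,
                        k = 3, partition = NULL, nSharedTargets = 40,
                        nDecoyTFs = 150, nDecoyTargets = 200,
                        tfEffect = 3, targetEffect = -3,
                        baselineMean = 8, baselineSpread = 2,
                        geneSigma = 1, noiseSigma = 0.25, flipRate = 0,
                        seed = 1L) {
  stopifnot(k >= 1, nMetastatic >= k, nNormal >= 1,
            nPrimary >= 0, nSharedTargets >= 0, nDecoyTFs >= 0,
            nDecoyTargets >= 0, geneSigma > 0, noiseSigma >= 0,
            flipRate >= 0, flipRate <= 1)
  if (is.null(partition)) {
    partition <- split(seq_len(nMetastatic),
                       rep(seq_len(k), length.out = nMetastatic,
                           each = ceiling(nMetastatic / k))[
                             seq_len(nMetastatic)])
    partition <- unname(partition)
  }
  idx <- unlist(partition)
  if (anyDuplicated(idx)) stop("partition blocks must be disjoint")
  if (any(idx < 1 | idx > nMetastatic))
    stop("partition exceeds the metastatic samples")
  if (length(partition) != k)
    stop("partition must have one block per driver")
  cfg <- list(nNormal = nNormal, nPrimary = nPrimary,
              nMetastatic = nMetastatic, k = k, partition = partition,
              nSharedTargets = nSharedTargets, nDecoyTFs = nDecoyTFs,
              nDecoyTargets = nDecoyTargets, tfEffect = tfEffect,
              targetEffect = targetEffect, baselineMean = baselineMean,
              baselineSpread = baselineSpread, geneSigma = geneSigma,
              noiseSigma = noiseSigma, flipRate = flipRate,
              seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  cfg
}

#' Simulate a cohort with planted mutually exclusive drivers
#'
#' Each gene's baseline is Normal(mu_g, geneSigma) per sample; driver k
#' gains `tfEffect * geneSigma` in its active metastatic block; every
#' shared target gains `targetEffect * geneSigma` (negative = repression)
#' in the union of all active blocks; decoys are unshifted; independent
#' Normal(0, noiseSigma) measurement noise is added to every entry.
#' Deterministic for a given `seed` (the caller's RNG state is
#' preserved).
#'
#' @param config a [synthConfig()].
#' @return list with `experiment` (a [TFTargetExperiment-class]) and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateCohort(synthConfig(nDecoyTFs = 5, nDecoyTargets = 5,
#'                                   nSharedTargets = 4))
#' truthDrivers(sim$truth)
#' @export
simulateCohort <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)
  samples <- c(sprintf("N%03d", seq_len(config$nNormal)),
               sprintf("P%03d", seq_len0(config$nPrimary)),
               sprintf("M%03d", seq_len(config$nMetastatic)))
  classes <- c(rep("normal", config$nNormal),
               rep("primary", config$nPrimary),
               rep("metastatic", config$nMetastatic))
  metSamples <- samples[classes == "metastatic"]
  drivers <- sprintf("TF_DRV%02d", seq_len(config$k))
  decoyTF <- sprintf("TF_DEC%03d", seq_len0(config$nDecoyTFs))
  shared <- sprintf("MIR_SHR%03d", seq_len0(config$nSharedTargets))
  decoyT <- sprintf("MIR_DEC%03d", seq_len0(config$nDecoyTargets))
  genes <- c(drivers, decoyTF, shared, decoyT)
  roles <- stats::setNames(
    c(rep("TF", length(drivers) + length(decoyTF)),
      rep("target", length(shared) + length(decoyT))), genes)
  nG <- length(genes); nS <- length(samples)
  mu <- stats::rnorm(nG, config$baselineMean, config$baselineSpread)
  m <- matrix(stats::rnorm(nG * nS, mean = mu, sd = config$geneSigma),
              nG, nS, dimnames = list(genes, samples))
  active <- lapply(config$partition, function(ix) metSamples[ix])
  names(active) <- drivers
  planted <- matrix(FALSE, nG, nS, dimnames = list(genes, samples))
  for (d in drivers) planted[d, active[[d]]] <- TRUE
  union <- unique(unlist(active))
  for (g in shared) planted[g, union] <- TRUE
  if (config$flipRate > 0) {
    hit <- which(planted)
    keep <- stats::rbinom(length(hit), 1L, 1 - config$flipRate) == 1L
    planted[hit[!keep]] <- FALSE
  }
  effect <- matrix(0, nG, nS)
  for (d in drivers)
    effect[match(d, genes), planted[d, ]] <-
      config$tfEffect * config$geneSigma
  for (g in shared)
    effect[match(g, genes), planted[g, ]] <-
      config$targetEffect * config$geneSigma
  m <- m + effect +
    matrix(stats::rnorm(nG * nS, 0, config$noiseSigma), nG, nS)
  truth <- new("SyntheticTruth", drivers = drivers,
               activeSamples = active, sharedTargets = shared,
               flags = planted,
               params = list(config = config, mu = mu))
  list(experiment = TFTargetExperiment(m, classes, roles),
       truth = truth)
}

# seq_len that tolerates 0 without the 1:0 trap
seq_len0 <- function(n) seq_len(max(n, 0L))

#' Score recovery of the planted structure
#'
#' Compares a pruned network (or a full pipeline report) against the
#' planted truth: driver precision/recall over the selected TF set and
#' edge precision/recall over the planted driver -> shared-target edges.
#' An empty prediction scores precision 1 by convention (no false
#' claims) and recall 0.
#'
#' @param result a [RegulatoryNetwork-class] or [PipelineReport-class].
#' @param truth a [SyntheticTruth-class].
#' @return list with `driverPrecision`, `driverRecall`, `edgePrecision`,
#'   `edgeRecall`, `exactDrivers` (logical: selected set equals the
#'   planted set) and `maxExclusivityP` (largest pairwise exclusivity p
#'   among selected TFs when a report is supplied, else NA).
#' @export
scoreRecovery <- function(result, truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  maxEx <- NA_real_
  if (is(result, "PipelineReport")) {
    pp <- result@master@perPair
    if (nrow(pp)) maxEx <- max(pp$exclusivityP)
    net <- result@network
  } else net <- result
  stopifnot(is(net, "RegulatoryNetwork"))
  sel <- net@selected
  hit <- intersect(sel, truth@drivers)
  driverPrecision <- if (!length(sel)) 1 else length(hit) / length(sel)
  driverRecall <- length(hit) / length(truth@drivers)
  trueEdges <- as.vector(outer(truth@drivers, truth@sharedTargets,
                               paste, sep = "\r"))
  predEdges <- if (nrow(net@edges))
    paste(net@edges$tf, net@edges$target, sep = "\r") else character()
  hitE <- intersect(predEdges, trueEdges)
  list(driverPrecision = driverPrecision, driverRecall = driverRecall,
       edgePrecision = if (!length(predEdges)) 1
                       else length(hitE) / length(predEdges),
       edgeRecall = length(hitE) / length(trueEdges),
       exactDrivers = setequal(sel, truth@drivers),
       maxExclusivityP = maxEx)
}
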