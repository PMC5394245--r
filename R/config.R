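#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' The defaults reproduce the published cutoffs: outlier z-score 2,
#' regulation FDR 0.01, master-TF binomial P 0.05, target-overlap Fisher
#' P 0.01, bimodality index 1.1 and a minimum screening cohort of more
#' than 100 samples.
#'
#' @param zThreshold positive numeric; a sample is an outlier for a gene
#'   when its absolute z-score relative to the normal mixture component
#'   strictly exceeds this value (default 2).
#' @param fdrCutoff Benjamini-Hochberg q-value cutoff for significant
#'   TF-target regulations (default 0.01).
#' @param masterPCutoff binomial-test P cutoff for calling a selected TF a
#'   master TF (default 0.05).
#' @param overlapPCutoff Fisher P cutoff for significant target-set overlap
#'   between two TFs (default 0.01).
#' @param exclusivityPCutoff Fisher P cutoff for significant mutual
#'   exclusivity of over-expression calls (default 0.05).
#' @param directionPCutoff one-sided hypergeometric P cutoff for declaring
#'   an outlier direction enriched with metastatic samples (default 0.05).
#' @param bimodalityCutoff bimodality-index cutoff for cross-dataset
#'   screening (default 1.1, strict).
#' @param minSamplesScreen a dataset passes screening only when it has
#'   strictly more samples than this (default 100).
#' @param kMax maximum number of mixture components per gene (default 3).
#' @param minSamplesMixture below this many samples a gene is fitted with a
#'   single component (default 8).
#' @param sigmaFloorFrac per-gene standard-deviation floor, as a fraction
#'   of that gene's value range (default 1e-3).
#' @param relaxZMin the TF-based relaxed target cutoff is never more
#'   permissive than this absolute z-score (default 1).
#' @param likelihoodCap maximum edge likelihood in bits (default 300).
#' @param backgroundRate optional fixed binomial background rate for the
#'   master-TF test; `NULL` (default) uses the network edge density,
#'   significant edges / (S * n).
#' @param lowAbundanceFilter logical; void an over-expression call when the
#'   sample's value is an order of magnitude below the competing TF's value
#'   in that sample (default `FALSE`).
#' @param logBase base of the log scale the expression values are on
#'   (default 2); used only by the low-abundance filter.
#' @param rngSeed integer seed recorded with the run (the pipeline itself
#'   is deterministic; the seed is consumed by the simulator and the CLI).
#'
#' @return A named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(fdrCutoff = 0.05)
#' cfg$zThreshold
#' @export
pipelineConfig <- function(zThreshold = 2, fdrCutoff = 0.01,
                           masterPCutoff = 0.05, overlapPCutoff = 0.01,
                           exclusivityPCutoff = 0.05,
                           directionPCutoff = 0.05,
                           bimodalityCutoff = 1.1, minSamplesScreen = 100,
                           kMax = 3, minSamplesMixture = 8,
                           sigmaFloorFrac = 1e-3, relaxZMin = 1,
                           likelihoodCap = 300, backgroundRate = NULL,
                           lowAbundanceFilter = FALSE, logBase = 2,
                           rngSeed = 1L) {
  cfg <- list(
    zThreshold = zThreshold, fdrCutoff = fdrCutoff,
    masterPCutoff = masterPCutoff, overlapPCutoff = overlapPCutoff,
    exclusivityPCutoff = exclusivityPCutoff,
    directionPCutoff = directionPCutoff,
    bimodalityCutoff = bimodalityCutoff,
    minSamplesScreen = minSamplesScreen,
    kMax = kMax, minSamplesMixture = minSamplesMixture,
    sigmaFloorFrac = sigmaFloorFrac, relaxZMin = relaxZMin,
    likelihoodCap = likelihoodCap, backgroundRate = backgroundRate,
    lowAbundanceFilter = lowAbundanceFilter, logBase = logBase,
    rngSeed = as.integer(rngSeed))
  thr <- c("zThreshold", "fdrCutoff", "masterPCutoff", "overlapPCutoff",
           "exclusivityPCutoff", "directionPCutoff", "bimodalityCutoff",
           "minSamplesScreen", "kMax", "minSamplesMixture",
           "sigmaFloorFrac", "relaxZMin", "likelihoodCap", "logBase")
  for (nm in thr) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", nm, "' must be a single positive number")
  }
  if (!is.null(backgroundRate) &&
      (backgroundRate <= 0 || backgroundRate >= 1))
    stop("backgroundRate must lie strictly between 0 and 1")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
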