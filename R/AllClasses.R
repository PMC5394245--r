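#' TFTargetExperiment: expression matrix with sample classes and gene roles
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] that
#' enforces the input contract of the pipeline: one numeric assay of
#' log-scale expression (genes in rows, samples in columns), a
#' `sampleClass` column in `colData` with levels `normal`, `primary`,
#' `metastatic`, and a `geneRole` column in `rowData` partitioning genes
#' into candidate regulators (`TF`) and candidate targets (`target`).
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("TFTargetExperiment", contains = "SummarizedExperiment")

.validTFTargetExperiment <- function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return("at least one assay is required")
  m <- SummarizedExperiment::assay(object)
  if (!is.numeric(m)) msg <- c(msg, "assay values must be numeric")
  if (anyNA(m)) msg <- c(msg, "assay contains missing values")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and sample identifiers are required as dimnames")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicated gene identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicated sample identifiers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"sampleClass" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'sampleClass' column")
  else {
    cls <- as.character(cd$sampleClass)
    bad <- setdiff(unique(cls), c("normal", "primary", "metastatic"))
    if (length(bad))
      msg <- c(msg, paste0("unknown sample class: ",
                           paste(bad, collapse = ", ")))
    if (!any(cls == "metastatic"))
      msg <- c(msg, "at least one metastatic sample is required")
    if (!any(cls == "normal"))
      msg <- c(msg, "at least one normal sample is required")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"geneRole" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'geneRole' column")
  else {
    rl <- as.character(rd$geneRole)
    bad <- setdiff(unique(rl), c("TF", "target"))
    if (length(bad))
      msg <- c(msg, paste0("unknown gene role: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("TFTargetExperiment", .validTFTargetExperiment)

#' Construct a TFTargetExperiment
#'
#' @param expr numeric matrix, genes in rows and samples in columns, with
#'   unique dimnames; log-scale expression.
#' @param sampleClass character vector (or named vector over the samples)
#'   with values `normal`, `primary` or `metastatic`.
#' @param geneRole character vector (or named vector over the genes) with
#'   values `TF` or `target`.
#' @return A [TFTargetExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("TF1", "TF2", "mir1"), paste0("s", 1:4)))
#' x <- TFTargetExperiment(m,
#'        sampleClass = c("normal", "primary", "metastatic", "metastatic"),
#'        geneRole = c("TF", "TF", "target"))
#' tfNames(x)
#' @export
TFTargetExperiment <- function(expr, sampleClass, geneRole) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (!is.null(names(sampleClass)))
    sampleClass <- sampleClass[colnames(expr)]
  if (!is.null(names(geneRole)))
    geneRole <- geneRole[rownames(expr)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(
      sampleClass = as.character(sampleClass), row.names = colnames(expr)),
    rowData = S4Vectors::DataFrame(
      geneRole = as.character(geneRole), row.names = rownames(expr)))
  new("TFTargetExperiment", se)
}

#' AberrationCalls: binary discretization of an expression matrix
#'
#' Holds, for every gene, the fitted mixture summary, the per-sample
#' z-scores relative to the normal component, the selected aberration
#' direction (`over`, `under` or `none`, by metastatic enrichment) and the
#' resulting binary aberration flags. Genes with direction `none` keep
#' all-`FALSE` rows.
#'
#' @slot flags logical genes-by-samples matrix of aberration calls.
#' @slot z numeric genes-by-samples matrix of z-scores (sigma units).
#' @slot direction character per-gene direction: over/under/none.
#' @slot enrichP numeric per-gene metastatic-enrichment p of the chosen
#'   direction (NA when none).
#' @slot zThreshold numeric; the |z| cutoff the flags were called at.
#' @slot fits list of per-gene mixture fits (see [fitMixture()]).
#' @export
setClass("AberrationCalls",
         slots = c(flags = "matrix", z = "matrix", direction = "character",
                   enrichP = "numeric", zThreshold = "numeric",
                   fits = "list"))

setValidity("AberrationCalls", function(object) {
  msg <- character()
  if (!identical(dim(object@flags), dim(object@z)))
    msg <- c(msg, "flags and z must have identical dimensions")
  if (length(object@direction) != nrow(object@flags))
    msg <- c(msg, "one direction per gene is required")
  bad <- setdiff(unique(object@direction), c("over", "under", "none"))
  if (length(bad)) msg <- c(msg, "direction must be over/under/none")
  if (!is.logical(object@flags)) msg <- c(msg, "flags must be logical")
  if (length(object@zThreshold) != 1L || object@zThreshold <= 0)
    msg <- c(msg, "zThreshold must be a single positive number")
  if (is.logical(object@flags) &&
      identical(dim(object@flags), dim(object@z)) &&
      length(object@direction) == nrow(object@flags)) {
    for (i in seq_len(nrow(object@flags))) {
      f <- object@flags[i, ]
      if (object@direction[i] == "none" && any(f)) {
        msg <- c(msg, "genes with direction 'none' must be all-FALSE")
        break
      }
      zi <- object@z[i, ]
      ok <- if (object@direction[i] == "over") zi > object@zThreshold
            else zi < -object@zThreshold
      if (any(f & !ok)) {
        msg <- c(msg, "flag set where |z| does not exceed the threshold")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' RegulatoryNetwork: MDL-selected driver TFs and their retained edges
#'
#' @slot selected character vector of selected TF identifiers.
#' @slot edges data.frame of retained edges (`tf`, `target`, `p`, `q`,
#'   `sign`, `lik`, and a `tpSamples` list-column of explained samples).
#' @slot S integer; number of candidate TFs the selection drew from.
#' @slot n integer; size of the target universe.
#' @slot objective numeric; value of the MDL objective (bits).
#' @slot likelihoodCap numeric; cap applied to edge likelihoods.
#' @export
setClass("RegulatoryNetwork",
         slots = c(selected = "character", edges = "data.frame",
                   S = "integer", n = "integer", objective = "numeric",
                   likelihoodCap = "numeric"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (length(object@selected) > object@S)
    msg <- c(msg, "more selected TFs than candidates (m > S)")
  if (nrow(object@edges) &&
      !all(object@edges$tf %in% object@selected))
    msg <- c(msg, "every edge's TF must be selected")
  if (length(msg)) msg else TRUE
})

#' MasterTFReport: post-network statistics
#'
#' @slot perTF data.frame: per selected TF, its target count, binomial p
#'   against the background edge density, and master-TF status.
#' @slot perPair data.frame: per TF pair, shared-target overlap count and
#'   Fisher p, co-overexpression counts, mutual-exclusivity Fisher p and
#'   odds ratio.
#' @slot backgroundRate numeric; binomial background rate used.
#' @export
setClass("MasterTFReport",
         slots = c(perTF = "data.frame", perPair = "data.frame",
                   backgroundRate = "numeric"))

#' SyntheticTruth: planted structure of a simulated cohort
#'
#' @slot drivers character; planted driver TF identifiers.
#' @slot activeSamples named list; per-driver overexpressing sample sets
#'   (pairwise disjoint by construction).
#' @slot sharedTargets character; identifiers of the co-repressed target
#'   module.
#' @slot flags logical genes-by-samples matrix of planted effect entries
#'   (the generative aberration labels).
#' @slot params list; the `synthConfig` used plus per-gene baselines.
#' @export
setClass("SyntheticTruth",
         slots = c(drivers = "character", activeSamples = "list",
                   sharedTargets = "character", flags = "matrix",
                   params = "list"))

setValidity("SyntheticTruth", function(object) {
  s <- unlist(object@activeSamples, use.names = FALSE)
  if (anyDuplicated(s))
    "driver active sample sets must be pairwise disjoint" else TRUE
})

#' PipelineReport: full result of one pipeline run
#'
#' @slot aberrations an [AberrationCalls-class] object.
#' @slot tests data.frame of all pairwise regulation tests.
#' @slot network a [RegulatoryNetwork-class] object.
#' @slot master a [MasterTFReport-class] object.
#' @slot config the `PipelineConfig` used (as a list).
#' @export
setClass("PipelineReport",
         slots = c(aberrations = "AberrationCalls", tests = "data.frame",
                   network = "RegulatoryNetwork", master = "MasterTFReport",
                   config = "list"))
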