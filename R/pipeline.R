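#' Run the full driver-TF inference pipeline
#'
#' Discretizes the expression matrix into aberration calls, infers
#' pairwise TF -> target regulations with modified Fisher tests, prunes
#' the FDR-significant candidates to a minimal driver set under the MDL
#' objective, and computes master-TF / overlap / mutual-exclusivity
#' statistics. Every stage is also callable independently with identical
#' results; the run is deterministic.
#'
#' @param x a [TFTargetExperiment-class].
#' @param config a [pipelineConfig()].
#' @return a [PipelineReport-class].
#' @examples
#' sim <- simulateCohort(synthConfig(nDecoyTFs = 10, nDecoyTargets = 10,
#'                                   nSharedTargets = 6))
#' rep <- runPipeline(sim$experiment)
#' selectedTFs(rep)
#' @export
runPipeline <- function(x, config = pipelineConfig()) {
  stopifnot(is(x, "TFTargetExperiment"))
  ab <- discretizeAberrations(x, config)
  dirs <- aberrationDirection(ab)
  flags <- aberrationFlags(ab)
  aberrant <- names(dirs)[dirs != "none" & rowSums(flags) > 0L]
  nTF <- length(intersect(tfNames(x), aberrant))
  nTgt <- length(intersect(targetNames(x), aberrant))
  if (nTF < 2L || nTgt < 2L)
    stop("insufficient aberrant genes: ", nTF, " TF(s) and ", nTgt,
         " target(s) after discretization (need at least 2 of each)")
  tests <- inferPairwise(ab, x, config)
  candidates <- tests[tests$q < config$fdrCutoff, , drop = FALSE]
  net <- greedySelect(candidates, S = nTF, n = nTgt,
                      cap = config$likelihoodCap)
  master <- masterTFReport(net, ab, candidates, config,
                           exprMat = exprMatrix(x))
  new("PipelineReport", aberrations = ab, tests = tests, network = net,
      master = master, config = unclass(config))
}

#' Serialize a pipeline report as canonical JSON
#'
#' Stage outputs (directions, edge table, selected network, master-TF
#' statistics, configuration) in a fixed key order, so two identical runs
#' serialize byte-identically.
#'
#' @param report a [PipelineReport-class].
#' @param digits significant digits for numeric output (default 12).
#' @return single JSON string.
#' @export
reportJSON <- function(report, digits = 12) {
  stopifnot(is(report, "PipelineReport"))
  edges <- networkEdges(report)
  edges <- edges[, setdiff(colnames(edges), "tpSamples"), drop = FALSE]
  tests <- regulationTests(report)
  tests <- tests[, setdiff(colnames(tests), "tpSamples"), drop = FALSE]
  net <- report@network
  obj <- list(
    aberrations = list(
      direction = as.list(aberrationDirection(report@aberrations)),
      nAberrant = sum(aberrationFlags(report))),
    tests = tests,
    network = list(selected = net@selected, S = net@S, n = net@n,
                   objective = net@objective, edges = edges),
    master = list(perTF = report@master@perTF,
                  perPair = report@master@perPair,
                  backgroundRate = report@master@backgroundRate),
    config = report@config[order(names(report@config))])
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = digits,
                                na = "null", null = "null"))
}

#' Write all stage outputs of a pipeline report
#'
#' Plain-text outputs only: the aberration matrix TSV, the full edge
#' table TSV, the selected-edge TSV, the oncoprint text of TF
#' overexpression calls, and one JSON report.
#'
#' @param report a [PipelineReport-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAberrations(report@aberrations,
                   file.path(dir, "aberrations.tsv"))
  writeEdgeTable(regulationTests(report), file.path(dir, "tests.tsv"))
  writeEdgeTable(networkEdges(report),
                 file.path(dir, "network_edges.tsv"))
  writeLines(oncoprintText(report@aberrations,
                           selectedTFs(report)),
             file.path(dir, "oncoprint.txt"))
  writeLines(reportJSON(report), file.path(dir, "report.json"))
  invisible(dir)
}
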