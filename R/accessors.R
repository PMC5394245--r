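#' @name accessors
#' @title Accessors for mexTF classes
#' @description Small accessor generics so user code never touches slots.
#' @param x an object of the documented class.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))
#' @rdname accessors
#' @export
setMethod("sampleClass", "TFTargetExperiment", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$sampleClass),
                  colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("geneRole", function(x) standardGeneric("geneRole"))
#' @rdname accessors
#' @export
setMethod("geneRole", "TFTargetExperiment", function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$geneRole),
                  rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("tfNames", function(x) standardGeneric("tfNames"))
#' @rdname accessors
#' @export
setMethod("tfNames", "TFTargetExperiment", function(x) {
  names(which(geneRole(x) == "TF"))
})

#' @rdname accessors
#' @export
setGeneric("targetNames", function(x) standardGeneric("targetNames"))
#' @rdname accessors
#' @export
setMethod("targetNames", "TFTargetExperiment", function(x) {
  names(which(geneRole(x) == "target"))
})

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setMethod("exprMatrix", "TFTargetExperiment", function(x) {
  SummarizedExperiment::assay(x)
})

#' @rdname accessors
#' @export
setGeneric("aberrationFlags", function(x) standardGeneric("aberrationFlags"))
#' @rdname accessors
#' @export
setMethod("aberrationFlags", "AberrationCalls", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("aberrationFlags", "PipelineReport",
          function(x) x@aberrations@flags)

#' @rdname accessors
#' @export
setGeneric("aberrationDirection",
           function(x) standardGeneric("aberrationDirection"))
#' @rdname accessors
#' @export
setMethod("aberrationDirection", "AberrationCalls", function(x) {
  stats::setNames(x@direction, rownames(x@flags))
})

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setMethod("zScores", "AberrationCalls", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("selectedTFs", function(x) standardGeneric("selectedTFs"))
#' @rdname accessors
#' @export
setMethod("selectedTFs", "RegulatoryNetwork", function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("selectedTFs", "PipelineReport", function(x) x@network@selected)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkEdges", "PipelineReport", function(x) x@network@edges)

#' @rdname accessors
#' @export
setGeneric("regulationTests", function(x) standardGeneric("regulationTests"))
#' @rdname accessors
#' @export
setMethod("regulationTests", "PipelineReport", function(x) x@tests)

#' @rdname accessors
#' @export
setGeneric("masterReport", function(x) standardGeneric("masterReport"))
#' @rdname accessors
#' @export
setMethod("masterReport", "PipelineReport", function(x) x@master)

#' @rdname accessors
#' @export
setGeneric("truthDrivers", function(x) standardGeneric("truthDrivers"))
#' @rdname accessors
#' @export
setMethod("truthDrivers", "SyntheticTruth", function(x) x@drivers)

#' @rdname accessors
#' @export
setGeneric("truthFlags", function(x) standardGeneric("truthFlags"))
#' @rdname accessors
#' @export
setMethod("truthFlags", "SyntheticTruth", function(x) x@flags)

setMethod("show", "AberrationCalls", function(object) {
  cat("AberrationCalls:", nrow(object@flags), "genes x",
      ncol(object@flags), "samples\n")
  cat("  directions:",
      sum(object@direction == "over"), "over,",
      sum(object@direction == "under"), "under,",
      sum(object@direction == "none"), "none\n")
  cat("  aberrant calls:", sum(object@flags),
      sprintf("(|z| > %g)\n", object@zThreshold))
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", length(object@selected), "of", object@S,
      "candidate TFs;", nrow(object@edges), "edges over",
      object@n, "targets\n")
  cat(sprintf("  MDL objective: %.3f bits\n", object@objective))
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "MasterTFReport", function(object) {
  cat("MasterTFReport:", nrow(object@perTF), "TFs,",
      nrow(object@perPair), "pairs",
      sprintf("(background rate %.4g)\n", object@backgroundRate))
  if (nrow(object@perTF)) {
    print(object@perTF, row.names = FALSE)
  }
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@drivers), "planted drivers,",
      length(object@sharedTargets), "shared targets\n")
  for (d in object@drivers)
    cat("  ", d, ": ",
        paste(object@activeSamples[[d]], collapse = ", "), "\n", sep = "")
})

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport\n")
  show(object@aberrations)
  cat("  pairwise tests:", nrow(object@tests), "\n")
  show(object@network)
  show(object@master)
})
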