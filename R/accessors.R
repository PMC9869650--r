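#' @name accessors
#' @title Accessors for designbench S4 objects
#' @description Read-only accessors for the slots of
#'   \linkS4class{BackboneStructure}, \linkS4class{PredictionSet},
#'   \linkS4class{DatasetMap} and \linkS4class{ModelReport}.
#' @param x An object of the relevant class.
#' @return The slot value; see individual generics.
NULL

#' @rdname accessors
#' @export
setGeneric("chainKey", function(x) standardGeneric("chainKey"))
#' @rdname accessors
#' @export
setMethod("chainKey", "BackboneStructure", function(x) x@chainKey)

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setMethod("nResidues", "BackboneStructure", function(x) length(x@seqIds))

#' @rdname accessors
#' @export
setGeneric("residueSequence", function(x) standardGeneric("residueSequence"))
#' @rdname accessors
#' @export
setMethod("residueSequence", "BackboneStructure", function(x) x@aaTrue)

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))
#' @rdname accessors
#' @export
setMethod("seqIds", "BackboneStructure", function(x) x@seqIds)

#' @rdname accessors
#' @export
setGeneric("backboneCoords", function(x) standardGeneric("backboneCoords"))
#' @rdname accessors
#' @export
setMethod("backboneCoords", "BackboneStructure", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setMethod("isComplete", "BackboneStructure", function(x) x@complete)

#' @rdname accessors
#' @export
setGeneric("resolutionOf", function(x) standardGeneric("resolutionOf"))
#' @rdname accessors
#' @export
setMethod("resolutionOf", "BackboneStructure", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setMethod("modelName", "PredictionSet", function(x) x@modelName)
#' @rdname accessors
#' @export
setMethod("modelName", "ModelReport", function(x) x@modelName)

#' @rdname accessors
#' @export
setGeneric("predictionMatrix", function(x) standardGeneric("predictionMatrix"))
#' @rdname accessors
#' @export
setMethod("predictionMatrix", "PredictionSet", function(x) x@probs)

#' @rdname accessors
#' @export
setGeneric("predictionChains", function(x) standardGeneric("predictionChains"))
#' @rdname accessors
#' @export
setMethod("predictionChains", "PredictionSet", function(x) x@chainKeys)

#' @rdname accessors
#' @export
setGeneric("datasetEntries", function(x) standardGeneric("datasetEntries"))
#' @rdname accessors
#' @export
setMethod("datasetEntries", "DatasetMap", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "ModelReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))
#' @rdname accessors
#' @export
setMethod("perClass", "ModelReport", function(x) x@perClass)

#' @rdname accessors
#' @export
setGeneric("globalMetrics", function(x) standardGeneric("globalMetrics"))
#' @rdname accessors
#' @export
setMethod("globalMetrics", "ModelReport", function(x) x@global)

#' @rdname accessors
#' @param which One of \code{"chain"}, \code{"ss"}, \code{"fold_class"},
#'   \code{"architecture"}.
#' @export
setGeneric("strataMetrics", function(x, which = "fold_class")
  standardGeneric("strataMetrics"))
#' @rdname accessors
#' @export
setMethod("strataMetrics", "ModelReport", function(x, which = "fold_class") {
  switch(match.arg(which, c("chain", "ss", "fold_class", "architecture")),
    chain = x@byChain, ss = x@bySS,
    fold_class = x@byFoldClass, architecture = x@byArchitecture)
})

#' @rdname accessors
#' @export
setGeneric("resolutionCor", function(x) standardGeneric("resolutionCor"))
#' @rdname accessors
#' @export
setMethod("resolutionCor", "ModelReport", function(x) x@resolutionR)

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setMethod("exclusions", "ModelReport", function(x) x@exclusions)

#' @rdname accessors
#' @export
setGeneric("scoredKeys", function(x) standardGeneric("scoredKeys"))
#' @rdname accessors
#' @export
setMethod("scoredKeys", "ModelReport", function(x) x@scoredKeys)

setMethod("show", "BackboneStructure", function(object) {
  res <- if (length(object@resolution)) sprintf("%.2f A", object@resolution) else "NA"
  cat(sprintf("BackboneStructure %s: %d residues (%d complete), resolution %s\n",
              object@chainKey, nResidues(object), sum(object@complete), res))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet '%s': %d residues across %d chain(s)\n",
              object@modelName, nrow(object@probs),
              length(unique(object@chainKeys))))
})

setMethod("show", "DatasetMap", function(object) {
  e <- object@entries
  cat(sprintf("DatasetMap: %d chains | %s\n", nrow(e),
              paste(sprintf("%s: %d", .foldClasses,
                            as.integer(table(factor(e$foldClass, .foldClasses)))),
                    collapse = ", ")))
})

setMethod("show", "ModelReport", function(object) {
  g <- object@global
  cat(sprintf(
    "ModelReport '%s': %d scored residues\n  accuracy %.3f | macro-recall %.3f | similarity %.3f | top-3 %.3f\n",
    object@modelName, g$n_residues, g$accuracy, g$macro_recall,
    g$similarity, g$top3))
})
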