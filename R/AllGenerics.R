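#' Accessors for the hfactor classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setGeneric("aaSequence", function(x) standardGeneric("aaSequence"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("sourcePath", function(x) standardGeneric("sourcePath"))
#' @rdname accessors
#' @export
setGeneric("models", function(x) standardGeneric("models"))
#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setGeneric("targetRow", function(x) standardGeneric("targetRow"))
#' @rdname accessors
#' @export
setGeneric("templateRow", function(x) standardGeneric("templateRow"))
#' @rdname accessors
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname accessors
#' @export
setGeneric("ssStates", function(x) standardGeneric("ssStates"))
#' @rdname accessors
#' @export
setGeneric("ssConfidence", function(x) standardGeneric("ssConfidence"))
#' @rdname accessors
#' @export
setGeneric("subScores", function(x) standardGeneric("subScores"))
#' @rdname accessors
#' @export
setGeneric("hFactorPercent", function(x) standardGeneric("hFactorPercent"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname accessors
setMethod("nResidues", "CaModel", function(x) length(x@resno))
#' @rdname accessors
setMethod("caCoords", "CaModel", function(x) x@xyz)
#' @rdname accessors
setMethod("residueNumbers", "CaModel", function(x) x@resno)
#' @rdname accessors
setMethod("aaSequence", "CaModel", function(x) x@aa)
#' @rdname accessors
setMethod("modelId", "CaModel", function(x) x@modelId)
#' @rdname accessors
setMethod("sourcePath", "CaModel", function(x) x@sourcePath)

#' @rdname accessors
setMethod("models", "ModelEnsemble", function(x) x@models)
#' @rdname accessors
setMethod("nModels", "ModelEnsemble", function(x) length(x@models))
#' @rdname accessors
setMethod("nResidues", "ModelEnsemble", function(x) nResidues(x@models[[1L]]))

#' @rdname accessors
setMethod("targetRow", "PairAlignment", function(x) x@target)
#' @rdname accessors
setMethod("templateRow", "PairAlignment", function(x) x@template)
#' @rdname accessors
setMethod("alignmentLength", "PairAlignment", function(x) nchar(x@target))

#' @rdname accessors
setMethod("ssStates", "SsTrack", function(x) x@states)
#' @rdname accessors
setMethod("ssConfidence", "SsTrack", function(x) x@conf)

#' @rdname accessors
setMethod("subScores", "HFactorReport", function(x)
  c(score1 = x@score1, score2 = x@score2, score3 = x@score3, score4 = x@score4))
#' @rdname accessors
setMethod("hFactorPercent", "HFactorReport", function(x) x@hFactorPercent)
#' @rdname accessors
setMethod("diagnostics", "HFactorReport", function(x) x@diagnostics)

setMethod("show", "CaModel", function(object) {
  cat(sprintf("CaModel '%s': %d residues (%d-%d)\n",
              object@modelId, length(object@resno),
              object@resno[1L], object@resno[length(object@resno)]))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d models x %d residues\n",
              length(object@models), nResidues(object@models[[1L]])))
})

setMethod("show", "PairAlignment", function(object) {
  n <- nchar(object@target)
  cat(sprintf("PairAlignment: N = %d columns\n", n))
  w <- min(n, 60L)
  cat(" target   ", substr(object@target, 1L, w),
      if (n > w) "..." else "", "\n", sep = "")
  cat(" template ", substr(object@template, 1L, w),
      if (n > w) "..." else "", "\n", sep = "")
})

setMethod("show", "SsTrack", function(object) {
  cat(sprintf("SsTrack (%s): %d residues, %s\n", object@kind,
              length(object@states),
              paste0(table(factor(object@states, c("H", "E", "C"))),
                     c("H", "E", "C"), collapse = " ")))
})

setMethod("show", "DomainHit", function(object) {
  cat(sprintf("DomainHit %s: target %d-%d, E = %.2g, %d reference(s)\n",
              object@pfamId, object@targetStart, object@targetEnd,
              object@eValue, length(object@referencePaths)))
})

setMethod("show", "AverageModel", function(object) {
  cat(sprintf("AverageModel: %d residues, %d iteration(s), %s\n",
              length(object@resno), object@convergenceIterations,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "HFactorReport", function(object) {
  cat(formatReportText(object), sep = "\n")
})
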