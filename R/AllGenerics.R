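#' Accessors for package classes
#'
#' Small accessor layer so that slots are never touched directly:
#' \code{scaleTag} (the preprocessing stage of a \linkS4class{QuantMatrix}),
#' \code{proteinIds} / \code{sampleIds} (identifier vectors),
#' \code{quantValues} (the proteins x samples intensity matrix),
#' \code{sigWeights} / \code{sigIntercept} (signature coefficients),
#' \code{cooScores} / \code{cooLabels} / \code{cooBoundaries}
#' (classification results), and \code{trueScores} / \code{trueLabels} /
#' \code{trueSignature} (simulation ground truth).
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
#' @aliases scaleTag proteinIds sampleIds quantValues sigWeights
#'   sigIntercept cooScores cooLabels cooBoundaries trueScores trueLabels
#'   trueSignature
NULL

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("quantValues", function(x) standardGeneric("quantValues"))
#' @rdname accessors
#' @export
setGeneric("sigWeights", function(x) standardGeneric("sigWeights"))
#' @rdname accessors
#' @export
setGeneric("sigIntercept", function(x) standardGeneric("sigIntercept"))
#' @rdname accessors
#' @export
setGeneric("cooScores", function(x) standardGeneric("cooScores"))
#' @rdname accessors
#' @export
setGeneric("cooLabels", function(x) standardGeneric("cooLabels"))
#' @rdname accessors
#' @export
setGeneric("cooBoundaries", function(x) standardGeneric("cooBoundaries"))
#' @rdname accessors
#' @export
setGeneric("trueScores", function(x) standardGeneric("trueScores"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("trueSignature", function(x) standardGeneric("trueSignature"))

#' @rdname accessors
setMethod("scaleTag", "QuantMatrix", function(x) x@scaleTag)
#' @rdname accessors
setMethod("proteinIds", "QuantMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("sampleIds", "QuantMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("quantValues", "QuantMatrix",
          function(x) SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
setMethod("sigWeights", "CooSignature", function(x) x@weights)
#' @rdname accessors
setMethod("sigIntercept", "CooSignature", function(x) x@intercept)
#' @rdname accessors
setMethod("sigWeights", "ZeroSumFit", function(x) x@beta)
#' @rdname accessors
setMethod("sigIntercept", "ZeroSumFit", function(x) x@beta0)

#' @rdname accessors
setMethod("cooScores", "CooResult", function(x) setNames(x@scores, x@sampleIds))
#' @rdname accessors
setMethod("cooLabels", "CooResult", function(x) setNames(x@labels, x@sampleIds))
#' @rdname accessors
setMethod("cooBoundaries", "CooResult", function(x)
  setNames(x@boundaries, c("lower", "upper")))
#' @rdname accessors
setMethod("sampleIds", "CooResult", function(x) x@sampleIds)

#' @rdname accessors
setMethod("trueScores", "SyntheticCohort", function(x) x@trueScores)
#' @rdname accessors
setMethod("trueLabels", "SyntheticCohort", function(x) x@trueLabels)
#' @rdname accessors
setMethod("trueSignature", "SyntheticCohort", function(x) x@trueSignature)
#' @rdname accessors
setMethod("quantValues", "SyntheticCohort", function(x) quantValues(x@matrix))
#' @rdname accessors
setMethod("sampleIds", "SyntheticCohort", function(x) sampleIds(x@matrix))
#' @rdname accessors
setMethod("proteinIds", "SyntheticCohort", function(x) proteinIds(x@matrix))

setMethod("show", "QuantMatrix", function(object) {
  v <- quantValues(object)
  cat(sprintf("QuantMatrix: %d proteins x %d samples [%s scale]\n",
              nrow(v), ncol(v), scaleTag(object)))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
})

setMethod("show", "CooSignature", function(object) {
  cat(sprintf("CooSignature: %d proteins (%s)\n", length(object@weights),
              object@provenance))
  w <- sort(object@weights, decreasing = TRUE)
  for (i in seq_along(w))
    cat(sprintf("  %-12s %+12.9f\n", names(w)[i], w[i]))
  cat(sprintf("  %-12s %+12.9f\n", "(intercept)", object@intercept))
})

setMethod("show", "ZeroSumFit", function(object) {
  cat(sprintf(
    "ZeroSumFit: lambda = %.4g, alpha = %.2f, %d/%d non-zero, %s\n",
    object@lambda, object@alpha, sum(object@beta != 0), length(object@beta),
    if (object@converged) sprintf("converged in %d sweeps", object@nSweeps)
    else sprintf("NOT converged after %d sweeps", object@nSweeps)))
})

setMethod("show", "ZeroSumCV", function(object) {
  i <- which(object@lambdaGrid == object@lambda1se)[1L]
  cat(sprintf(
    paste0("ZeroSumCV: %d lambdas, %d folds\n",
           "  lambda.min = %.4g, lambda.1se = %.4g",
           " (cv mse %.4g +/- %.4g, %d proteins)\n"),
    length(object@lambdaGrid), max(object@foldid), object@lambdaMin,
    object@lambda1se, object@cvm[i], object@cvsd[i],
    sum(object@fit1se@beta != 0)))
})

setMethod("show", "CooResult", function(object) {
  tab <- table(object@labels)
  cat(sprintf(
    "CooResult: %d samples; boundaries (%.4g, %.4g); ABC %d / unclassified %d / GCB %d\n",
    length(object@scores), object@boundaries[1L], object@boundaries[2L],
    tab[["ABC"]], tab[["unclassified"]], tab[["GCB"]]))
})

setMethod("show", "RtMap", function(object) {
  cat(sprintf(
    "RtMap: reference = %.6g * observed %+.6g min (%d anchors, rmse %.4g min)\n",
    object@slope, object@intercept, object@nAnchors, object@residualRmse))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  show(object@matrix)
  tab <- table(object@trueLabels)
  cat(sprintf("  true labels: ABC %d / unclassified %d / GCB %d\n",
              tab[["ABC"]], tab[["unclassified"]], tab[["GCB"]]))
})
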