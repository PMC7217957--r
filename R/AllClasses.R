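#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor lm median predict quantile rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' QuantMatrix: a protein quantitation matrix
#'
#' Container for a proteins x samples intensity matrix, carried as a
#' \linkS4class{SummarizedExperiment} with a single \code{"intensity"} assay.
#' Rows are protein groups (UniProt accessions), columns are samples; this is
#' the usual Bioconductor orientation, while the on-disk wide TSV dialect
#' (one row per sample) is transposed on read/write. The \code{scaleTag}
#' records where the object sits in the preprocessing chain:
#' \describe{
#'   \item{\code{raw}}{summed fragment/peptide ion intensities; entries are
#'     positive or \code{NA} (missing).}
#'   \item{\code{normalized}}{divided by the per-sample total intensity;
#'     positive or \code{NA}.}
#'   \item{\code{log2}}{base-2 logarithm; all entries finite — imputation
#'     must precede the transform.}
#' }
#'
#' @slot scaleTag character scalar, one of \code{"raw"}, \code{"normalized"},
#'   \code{"log2"}.
#' @seealso [QuantMatrix()], [rollupProtein()], [imputeGlobalMin()],
#'   [totalSumNormalize()], [log2Transform()]
#' @export
setClass("QuantMatrix",
  contains = "SummarizedExperiment",
  slots = c(scaleTag = "character"),
  prototype = prototype(scaleTag = "raw")
)

setValidity("QuantMatrix", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("raw", "normalized", "log2"))
    msg <- c(msg, "scaleTag must be one of 'raw', 'normalized', 'log2'")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    v <- SummarizedExperiment::assay(object, "intensity")
    if (identical(object@scaleTag, "log2")) {
      if (any(!is.finite(v)))
        msg <- c(msg, "log2-scale matrix must be finite everywhere (impute first)")
    } else {
      obs <- v[!is.na(v)]
      if (any(!is.finite(obs)) || any(obs <= 0))
        msg <- c(msg, sprintf("%s-scale entries must be positive or NA",
                              object@scaleTag))
    }
  }
  if (length(msg)) msg else TRUE
})

#' CooSignature: a zero-sum protein signature
#'
#' A named coefficient vector over protein accessions whose entries sum to
#' zero, plus an unconstrained intercept. Applying the signature to log2
#' intensities yields a continuous GCB score that is invariant to per-sample
#' rescaling of the raw intensities (reference-point insensitivity).
#'
#' @slot weights named numeric, zero-sum regression weights keyed by UniProt
#'   accession.
#' @slot intercept numeric scalar, the unpenalized intercept.
#' @slot provenance character scalar describing where the weights came from.
#' @seealso [cooSignature()], [scoreSamples()]
#' @export
setClass("CooSignature",
  slots = c(weights = "numeric", intercept = "numeric",
            provenance = "character"))

setValidity("CooSignature", function(object) {
  msg <- character()
  w <- object@weights
  if (length(w) < 2L) msg <- c(msg, "need at least two weights")
  if (is.null(names(w)) || anyNA(names(w)) || any(names(w) == "") ||
      anyDuplicated(names(w)))
    msg <- c(msg, "weights must have unique non-empty names (accessions)")
  if (anyNA(w) || any(!is.finite(w))) msg <- c(msg, "weights must be finite")
  else if (abs(sum(w)) > 1e-8)
    msg <- c(msg, sprintf("weights must sum to zero (|sum| = %.3g)",
                          abs(sum(w))))
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' ZeroSumFit: a fitted zero-sum elastic net at one penalty value
#'
#' @slot beta named numeric coefficient vector, constrained to sum to zero.
#' @slot beta0 numeric intercept (unpenalized, outside the constraint).
#' @slot lambda numeric penalty at which the fit was obtained.
#' @slot alpha numeric elastic-net mixing parameter in [0, 1].
#' @slot objective numeric value of the penalized objective at convergence.
#' @slot nSweeps integer number of full coordinate-pair sweeps used.
#' @slot converged logical, whether the sweep-to-sweep objective decrease
#'   fell below the tolerance before \code{maxSweeps}.
#' @seealso [fitZeroSum()], [cvZeroSum()]
#' @export
setClass("ZeroSumFit",
  slots = c(beta = "numeric", beta0 = "numeric", lambda = "numeric",
            alpha = "numeric", objective = "numeric", nSweeps = "integer",
            converged = "logical"))

setValidity("ZeroSumFit", function(object) {
  msg <- character()
  if (abs(sum(object@beta)) > 1e-8)
    msg <- c(msg, "beta must sum to zero within 1e-8")
  if (!is.finite(object@objective)) msg <- c(msg, "objective must be finite")
  if (length(msg)) msg else TRUE
})

#' ZeroSumCV: cross-validated lambda path for the zero-sum elastic net
#'
#' @slot lambdaGrid decreasing numeric grid of penalties.
#' @slot cvm per-lambda mean held-out squared error (mean of fold means).
#' @slot cvsd per-lambda standard error (sd of fold means / sqrt(n folds)).
#' @slot lambdaMin lambda with minimal cvm.
#' @slot lambda1se largest lambda with cvm within one standard error of the
#'   minimum (the parsimony-favouring choice used for the final model).
#' @slot foldid integer fold assignment per sample.
#' @slot fitMin,fit1se \linkS4class{ZeroSumFit} refits on the full data at
#'   the two selected penalties.
#' @slot betaPath coefficient matrix (proteins x lambdas) of the full-data
#'   path, for inspection.
#' @seealso [cvZeroSum()]
#' @export
setClass("ZeroSumCV",
  slots = c(lambdaGrid = "numeric", cvm = "numeric", cvsd = "numeric",
            lambdaMin = "numeric", lambda1se = "numeric", foldid = "integer",
            fitMin = "ZeroSumFit", fit1se = "ZeroSumFit",
            betaPath = "matrix"))

setValidity("ZeroSumCV", function(object) {
  msg <- character()
  if (object@lambda1se < object@lambdaMin)
    msg <- c(msg, "lambda1se must be >= lambdaMin")
  if (length(object@cvm) != length(object@lambdaGrid))
    msg <- c(msg, "cvm length must match lambdaGrid")
  if (length(msg)) msg else TRUE
})

#' CooResult: per-sample GCB scores and three-class COO calls
#'
#' @slot sampleIds character sample identifiers.
#' @slot scores numeric continuous GCB scores.
#' @slot labels factor with levels ABC, unclassified, GCB.
#' @slot boundaries numeric length-2 vector \code{c(lower, upper)}; scores
#'   strictly below \code{lower} are ABC, strictly above \code{upper} are
#'   GCB, all others (including exact boundary hits) unclassified.
#' @seealso [assignLabels()], [trainBoundaries()]
#' @export
setClass("CooResult",
  slots = c(sampleIds = "character", scores = "numeric", labels = "factor",
            boundaries = "numeric"))

setValidity("CooResult", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (length(object@sampleIds) != n || length(object@labels) != n)
    msg <- c(msg, "sampleIds, scores and labels must have equal length")
  if (length(object@boundaries) != 2L ||
      object@boundaries[1L] > object@boundaries[2L])
    msg <- c(msg, "boundaries must be c(lower, upper) with lower <= upper")
  if (!identical(levels(object@labels), cooLevels()))
    msg <- c(msg, "labels must have levels ABC, unclassified, GCB")
  if (n > 0L) {
    expect <- assignLabels(object@scores, object@boundaries)
    if (!identical(as.character(expect), as.character(object@labels)))
      msg <- c(msg, "labels inconsistent with scores and boundaries")
  }
  if (length(msg)) msg else TRUE
})

#' RtMap: a linear retention-time recalibration
#'
#' Least-squares line mapping observed retention times onto reference
#' (library) retention times, fitted on spike-in anchor peptides.
#'
#' @slot slope,intercept coefficients of the map (minutes).
#' @slot nAnchors number of anchor peptides used.
#' @slot residualRmse root-mean-square residual of the fit, minutes.
#' @seealso [fitRtMap()], [applyRtMap()]
#' @export
setClass("RtMap",
  slots = c(slope = "numeric", intercept = "numeric", nAnchors = "integer",
            residualRmse = "numeric"))

setValidity("RtMap", function(object) {
  msg <- character()
  if (object@nAnchors < 2L) msg <- c(msg, "need at least two anchors")
  if (!is.finite(object@slope) || object@slope == 0)
    msg <- c(msg, "slope must be finite and non-zero")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a simulated cohort with known truth
#'
#' @slot matrix raw-scale \linkS4class{QuantMatrix} with MNAR missingness.
#' @slot trueScores numeric ground-truth GCB scores per sample.
#' @slot trueLabels factor ground-truth COO labels (from the generating
#'   thresholds).
#' @slot trueSignature \linkS4class{CooSignature} generating the scores.
#' @slot config list echo of the simulation parameters.
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticCohort",
  slots = c(matrix = "QuantMatrix", trueScores = "numeric",
            trueLabels = "factor", trueSignature = "CooSignature",
            config = "list"))
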