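cooLevels <- function() c("ABC", "unclassified", "GCB")

asCooFactor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), cooLevels())
  if (length(bad))
    stop("labels outside the ABC/unclassified/GCB alphabet: ",
         paste(bad, collapse = ", "))
  factor(labels, levels = cooLevels())
}

#' The packaged eight-protein cell-of-origin signature
#'
#' Returns the published zero-sum signature (eight UniProt protein groups
#' plus intercept, at full nine-decimal precision) trained on log2 SWATH-MS
#' protein intensities of a 42-case DLBCL development cohort against
#' Affymetrix-derived GCB scores. The weights sum to zero exactly at the
#' distributed precision, which is what makes the resulting GCB score
#' independent of per-sample scale and hence of the measurement platform.
#'
#' @return a \linkS4class{CooSignature}.
#' @examples
#' sig <- cooSignature()
#' sum(sigWeights(sig))  # 0
#' @export
cooSignature <- function() {
  path <- system.file("extdata", "coo_signature.tsv",
                      package = "zeroSumCOO", mustWork = TRUE)
  readSignature(path, provenance = "packaged 8-protein DLBCL COO signature")
}

#' The published ABC/unclassified/GCB decision boundaries
#'
#' The development-cohort decision boundaries (-3.50, 1.28); scores below
#' the lower boundary are ABC-like, above the upper boundary GCB-like,
#' in between (boundaries included) unclassified.
#'
#' @return numeric \code{c(lower = -3.50, upper = 1.28)}.
#' @export
defaultBoundaries <- function() c(lower = -3.50, upper = 1.28)

#' Score samples with a zero-sum signature
#'
#' \eqn{score_i = \beta_0 + \sum_j w_j \, x_{ij}} over the signature
#' proteins only; other columns of the matrix are ignored. Every signature
#' accession must be present — there is no silent zero-fill.
#'
#' @param signature a \linkS4class{CooSignature}.
#' @param matrix a log2-scale \linkS4class{QuantMatrix}, or a samples x
#'   proteins log2 matrix with accession column names.
#' @return named numeric vector of GCB scores.
#' @examples
#' sig <- cooSignature()
#' m <- matrix(20, length(sigWeights(sig)), 1,
#'             dimnames = list(names(sigWeights(sig)), "s1"))
#' scoreSamples(sig, QuantMatrix(2^m))            # error: raw scale
#' scoreSamples(sig, log2Transform(QuantMatrix(2^m)))  # the intercept
#' @export
scoreSamples <- function(signature, matrix) {
  stopifnot(is(signature, "CooSignature"))
  X <- asPredictorMatrix(matrix)
  w <- sigWeights(signature)
  miss <- setdiff(names(w), colnames(X))
  if (length(miss))
    stop("matrix lacks signature protein(s): ", paste(miss, collapse = ", "))
  drop(X[, names(w), drop = FALSE] %*% w) + sigIntercept(signature)
}

#' Assign three-class COO labels from GCB scores
#'
#' Strictly below the lower boundary: ABC; strictly above the upper
#' boundary: GCB; otherwise (boundary hits included): unclassified.
#'
#' @param scores numeric GCB scores.
#' @param boundaries numeric \code{c(lower, upper)}, \code{lower <= upper};
#'   default the published boundaries.
#' @return factor with levels ABC, unclassified, GCB.
#' @examples
#' assignLabels(c(-5, 0, 2))
#' @export
assignLabels <- function(scores, boundaries = defaultBoundaries()) {
  if (length(boundaries) != 2L || boundaries[1L] > boundaries[2L])
    stop("boundaries must be c(lower, upper) with lower <= upper")
  if (anyNA(scores) || any(is.nan(scores)))
    stop("non-finite score")
  out <- rep("unclassified", length(scores))
  out[scores < boundaries[1L]] <- "ABC"
  out[scores > boundaries[2L]] <- "GCB"
  factor(out, levels = cooLevels())
}

#' Classify samples: score, threshold, package the result
#'
#' @inheritParams scoreSamples
#' @inheritParams assignLabels
#' @return a \linkS4class{CooResult}.
#' @export
classifyCoo <- function(signature, matrix, boundaries = defaultBoundaries()) {
  scores <- scoreSamples(signature, matrix)
  new("CooResult", sampleIds = names(scores), scores = unname(scores),
      labels = assignLabels(scores, boundaries),
      boundaries = unname(boundaries))
}

boundaryCandidates <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

countMisclass <- function(scores, labels, lower, upper) {
  sum(as.character(assignLabels(scores, c(lower, upper))) !=
        as.character(labels))
}

#' Train decision boundaries by misclassification minimization
#'
#' Exhaustive search over all candidate cut pairs — midpoints between
#' adjacent distinct sorted scores plus infinite sentinels — for the
#' \code{(lower, upper)} pair minimizing the number of label
#' misclassifications. Among equally optimal pairs the one maximizing the
#' minimum distance from any score to its nearest finite boundary (the
#' margin) is chosen; remaining ties resolve to the smallest cuts, so the
#' result is deterministic.
#'
#' @param scores numeric GCB scores.
#' @param referenceLabels reference COO labels (ABC/unclassified/GCB).
#' @return numeric \code{c(lower, upper)} with attribute
#'   \code{"misclassifications"}.
#' @examples
#' trainBoundaries(c(-2, -1, 0, 1, 2),
#'                 c("ABC", "ABC", "unclassified", "GCB", "GCB"))
#' @export
trainBoundaries <- function(scores, referenceLabels) {
  labels <- asCooFactor(referenceLabels)
  if (length(scores) < 1L) stop("need at least one sample")
  if (length(scores) != length(labels))
    stop("scores and referenceLabels must have equal length")
  if (anyNA(scores)) stop("non-finite score")
  cuts <- boundaryCandidates(scores)
  m <- length(cuts)
  s <- sort(scores)
  # cumulative label counts below each cut / above each cut
  isA <- labels == "ABC"; isU <- labels == "unclassified"; isG <- labels == "GCB"
  nBelow <- function(which) vapply(cuts, function(cc) sum(scores < cc & which), 0)
  nAbove <- function(which) vapply(cuts, function(cc) sum(scores > cc & which), 0)
  # misclass(l, u) = #nonABC below l + #nonGCB above u + #nonUNC in [l, u]
  nonAbelow <- nBelow(!isA)
  nonGabove <- nAbove(!isG)
  nonUbelowOrAt <- vapply(cuts, function(cc) sum(scores <= cc & !isU), 0)
  nonUbelow <- nBelow(!isU)
  best <- NULL
  bestErr <- Inf
  for (i in seq_len(m)) {
    errU <- nonGabove + (nonUbelowOrAt - nonUbelow[i])  # vector over upper cuts
    err <- nonAbelow[i] + errU
    err[seq_len(i - 1L)] <- Inf  # enforce lower <= upper
    j <- which(err == min(err))
    if (min(err) < bestErr) {
      bestErr <- min(err)
      best <- cbind(i, j)
    } else if (min(err) == bestErr) {
      best <- rbind(best, cbind(i, j))
    }
  }
  margin <- function(l, u) {
    d <- pmin(abs(s - l), abs(s - u))
    d[is.nan(d)] <- Inf  # |Inf - Inf| never occurs; abs(x - Inf) = Inf
    min(d)
  }
  margins <- apply(best, 1L, function(ij) margin(cuts[ij[1L]], cuts[ij[2L]]))
  best <- best[margins == max(margins), , drop = FALSE]
  best <- best[order(best[, 1L], best[, 2L])[1L], ]
  out <- c(lower = cuts[best[1L]], upper = cuts[best[2L]])
  attr(out, "misclassifications") <- as.integer(bestErr)
  out
}

#' Tally minor and major discrepancies between two COO labelings
#'
#' Minor discrepancies are switches involving the unclassified middle class
#' (ABC or GCB called unclassified, and vice versa); major discrepancies
#' are direct ABC/GCB swaps.
#'
#' @param predictedLabels,referenceLabels COO labels of equal length.
#' @return list with \code{minor}, \code{major} and the 3x3
#'   \code{confusion} table (rows reference, columns predicted).
#' @examples
#' tallyDiscrepancies(c("ABC", "unclassified"), c("ABC", "GCB"))
#' @export
tallyDiscrepancies <- function(predictedLabels, referenceLabels) {
  pred <- asCooFactor(predictedLabels)
  ref <- asCooFactor(referenceLabels)
  if (length(pred) != length(ref)) stop("label vectors must have equal length")
  confusion <- table(reference = ref, predicted = pred)
  disagree <- pred != ref
  minor <- sum(disagree & (pred == "unclassified" | ref == "unclassified"))
  major <- sum(disagree) - minor
  list(minor = as.integer(minor), major = as.integer(major),
       confusion = confusion)
}

#' Estimate the cross-platform intercept adjustment
#'
#' The zero-sum construction cancels any protein-independent platform
#' offset, so transferring the signature to a new measurement platform only
#' requires re-estimating the intercept. The adjustment is
#' \eqn{\Delta = \mathrm{mean}(score_{ref} - score_{new})} over paired
#' samples; adding \eqn{\Delta} to the new platform's intercept makes its
#' mean score equal the reference mean exactly.
#'
#' @param scoresReference,scoresNew paired score vectors, same sample order.
#' @return numeric scalar \eqn{\Delta}.
#' @examples
#' transferOffset(c(1, 2, 3), c(0, 0, 3))  # 1
#' @export
transferOffset <- function(scoresReference, scoresNew) {
  if (length(scoresReference) != length(scoresNew))
    stop("score vectors must be paired (equal length)")
  if (length(scoresReference) < 1L) stop("need at least one pair")
  mean(scoresReference - scoresNew)
}

#' Pearson correlation between two score vectors
#'
#' @param a,b numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @return the sample Pearson correlation coefficient.
#' @export
pearsonR <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0)
    stop("Pearson correlation undefined for a constant vector")
  cor(a, b, method = "pearson")
}
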