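#' Fit a linear retention-time recalibration
#'
#' Ordinary least-squares line mapping observed retention times onto
#' reference (library) retention times, fitted on spike-in anchor peptides
#' that span the LC gradient. No robust loss is used: the anchors are
#' assumed to be clean synthetic standards.
#'
#' @param observedRt,referenceRt numeric anchor retention times (minutes),
#'   paired; at least two anchors, observed times not all equal.
#' @return an \linkS4class{RtMap}.
#' @examples
#' fitRtMap(c(10, 50, 90), c(22, 102, 182))  # slope 2, intercept 2
#' @export
fitRtMap <- function(observedRt, referenceRt) {
  if (length(observedRt) != length(referenceRt))
    stop("anchor vectors must be paired (equal length)")
  if (length(observedRt) < 2L) stop("need at least two anchors")
  if (anyNA(observedRt) || anyNA(referenceRt))
    stop("anchor retention times must be finite")
  if (var(observedRt) == 0)
    stop("observed anchor times have zero variance: no line can be fitted")
  fit <- lm(referenceRt ~ observedRt)
  co <- coef(fit)
  new("RtMap", slope = unname(co[2L]), intercept = unname(co[1L]),
      nAnchors = length(observedRt),
      residualRmse = sqrt(mean(residuals(fit)^2)))
}

#' Apply a retention-time map
#'
#' @param map an \linkS4class{RtMap}.
#' @param observedRt numeric retention times (minutes).
#' @return recalibrated retention times on the reference scale.
#' @export
applyRtMap <- function(map, observedRt) {
  stopifnot(is(map, "RtMap"))
  map@slope * observedRt + map@intercept
}

#' Retention-time window matching
#'
#' TRUE when the recalibrated retention time falls within
#' \code{windowMin} minutes of the library value; the boundary is
#' inclusive.
#'
#' @param mappedRt recalibrated retention time (minutes).
#' @param libraryRt library retention time (minutes).
#' @param windowMin half-width of the matching window, minutes (default 5).
#' @return logical.
#' @examples
#' matchWithinWindow(60, 64.9)  # TRUE
#' matchWithinWindow(60, 65.1)  # FALSE
#' @export
matchWithinWindow <- function(mappedRt, libraryRt, windowMin = 5) {
  if (windowMin <= 0) stop("windowMin must be positive")
  abs(mappedRt - libraryRt) <= windowMin
}

#' @importFrom stats coef residuals
NULL
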