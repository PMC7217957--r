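#' Default simulation configuration
#'
#' Study-condition defaults for [simulateCohort()]: 100 samples, 50 protein
#' groups, an 8-sparse zero-sum true signature (the packaged weights
#' rescaled to unit L2 norm, carried by the first eight synthetic
#' accessions), a bimodal true-score mixture mimicking the ABC/GCB poles
#' with a sparse unclassified middle, log2 measurement noise of 0.5, and
#' per-sample size factors of sd 1 (reference-point shifts that the
#' zero-sum score must cancel). Missingness is missing-not-at-random:
#' only entries in the low-intensity tail of their protein can drop out.
#'
#' @param nSamples,nProteins cohort dimensions.
#' @param trueSignature a \linkS4class{CooSignature} over a subset of the
#'   simulated accessions, or \code{NULL} for the default.
#' @param noiseSd log2-scale measurement noise sd.
#' @param bioSd sd of per-protein biological variation (log2 units),
#'   orthogonalized against the signature on its support so that noise-free
#'   scoring still returns the true score exactly.
#' @param sizeFactorSd sd of the per-sample additive log2 shift.
#' @param missingRate target overall missing fraction (must be below
#'   \code{mnarQuantile}).
#' @param mnarQuantile per-protein intensity quantile below which entries
#'   are eligible to go missing.
#' @param scoreMixture list describing the true-score distribution: two
#'   Gaussian poles (\code{meanAbc}, \code{meanGcb}, \code{sdPole},
#'   \code{pAbc}, \code{pGcb}) and a uniform middle over
#'   \code{c(middleLower, middleUpper)}.
#' @param thresholds generating label thresholds \code{c(lower, upper)}.
#' @param seed integer seed.
#' @return a list of simulation parameters.
#' @export
simConfig <- function(nSamples = 100L, nProteins = 50L, trueSignature = NULL,
                      noiseSd = 0.5, bioSd = 1.0, sizeFactorSd = 1.0,
                      missingRate = 0.05, mnarQuantile = 0.25,
                      scoreMixture = list(meanAbc = -6, meanGcb = 4,
                                          sdPole = 1.5, pAbc = 0.45,
                                          pGcb = 0.45, middleLower = -3.5,
                                          middleUpper = 1.28),
                      thresholds = defaultBoundaries(), seed = 1L) {
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  if (mnarQuantile <= 0 || mnarQuantile >= 1)
    stop("mnarQuantile must be in (0, 1)")
  if (missingRate > mnarQuantile)
    stop("missingRate must not exceed mnarQuantile (dropout probability > 1)")
  if (is.null(trueSignature)) {
    w <- sigWeights(cooSignature())
    w <- w / sqrt(sum(w^2))
    names(w) <- sprintf("SYNP%03d", seq_along(w))
    trueSignature <- new("CooSignature", weights = w,
                         intercept = sigIntercept(cooSignature()),
                         provenance = "synthetic unit-norm default")
  }
  stopifnot(is(trueSignature, "CooSignature"))
  if (length(sigWeights(trueSignature)) > nProteins)
    stop("nProteins smaller than the signature support: loadings infeasible")
  list(nSamples = as.integer(nSamples), nProteins = as.integer(nProteins),
       trueSignature = trueSignature, noiseSd = noiseSd, bioSd = bioSd,
       sizeFactorSd = sizeFactorSd, missingRate = missingRate,
       mnarQuantile = mnarQuantile, scoreMixture = scoreMixture,
       thresholds = unname(thresholds), seed = as.integer(seed))
}

drawTrueScores <- function(n, mix) {
  comp <- sample(c("abc", "gcb", "mid"), n, replace = TRUE,
                 prob = c(mix$pAbc, mix$pGcb, 1 - mix$pAbc - mix$pGcb))
  s <- numeric(n)
  s[comp == "abc"] <- rnorm(sum(comp == "abc"), mix$meanAbc, mix$sdPole)
  s[comp == "gcb"] <- rnorm(sum(comp == "gcb"), mix$meanGcb, mix$sdPole)
  s[comp == "mid"] <- runif(sum(comp == "mid"), mix$middleLower,
                            mix$middleUpper)
  s
}

#' Simulate a quantitation cohort with known ground truth
#'
#' Generates log2 intensities
#' \deqn{x_{ij} = b_j + f_i + \ell_j t_i + v_{ij} + \varepsilon_{ij},}
#' with protein baselines \eqn{b_j \sim N(18, 2^2)} (log2 ion-count units),
#' per-sample size factors \eqn{f_i \sim N(0, sizeFactorSd^2)}, loadings
#' \eqn{\ell = w / \|w\|_2^2} for the true zero-sum signature \eqn{w}
#' (so that scoring noise-free data with \eqn{w} returns the true score
#' exactly — size factors cancel because \eqn{\sum_j w_j = 0}, and the
#' baselines are re-centred so the intercept is honoured), per-protein
#' biological variation \eqn{v_{ij}} of sd \code{bioSd} whose component
#' along \eqn{w} is projected out on the signature support (keeping the
#' score identity exact while giving every protein an identifiable signal
#' of its own), and Gaussian measurement noise of sd \code{noiseSd}.
#' Intensities are exponentiated to the raw
#' scale; entries in the lower \code{mnarQuantile} tail of their protein
#' then drop out with probability \code{missingRate / mnarQuantile}, giving
#' an expected overall missing fraction of \code{missingRate} with the
#' low-intensity bias typical of data-independent acquisition.
#'
#' @param config list from [simConfig()].
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' coh <- simulateCohort(simConfig(nSamples = 20, nProteins = 12, seed = 7))
#' coh
#' @export
simulateCohort <- function(config = simConfig()) {
  set.seed(config$seed)
  n <- config$nSamples
  p <- config$nProteins
  w <- sigWeights(config$trueSignature)
  proteins <- union(names(w), sprintf("SYNP%03d", seq_len(p)))[seq_len(p)]
  samples <- sprintf("S%03d", seq_len(n))

  t <- drawTrueScores(n, config$scoreMixture)
  f <- rnorm(n, 0, config$sizeFactorSd)
  b <- rnorm(p, 18, 2)
  names(b) <- proteins
  loading <- setNames(numeric(p), proteins)
  loading[names(w)] <- w / sum(w^2)
  # centre baselines on the signature support so that w'b = -intercept:
  # then w'x = w'b + t * w'loading = -b0 + t and the score recovers t.
  adj <- (-sigIntercept(config$trueSignature) - sum(w * b[names(w)])) /
    sum(w^2)
  b[names(w)] <- b[names(w)] + adj * w

  v <- matrix(rnorm(p * n, 0, config$bioSd), p, n)
  if (config$bioSd > 0) {
    # remove the w-component of the biological variation on the signature
    # support, so the zero-sum score of noise-free data stays exactly t
    supp <- match(names(w), proteins)
    proj <- crossprod(v[supp, , drop = FALSE], w) / sum(w^2)  # n x 1
    v[supp, ] <- v[supp, , drop = FALSE] - tcrossprod(w, drop(proj))
  }
  log2x <- matrix(b, p, n) + matrix(f, p, n, byrow = TRUE) +
    outer(loading, t) + v + matrix(rnorm(p * n, 0, config$noiseSd), p, n)
  raw <- 2^log2x
  dimnames(raw) <- list(proteins, samples)

  if (config$missingRate > 0) {
    qcut <- apply(raw, 1L, quantile, probs = config$mnarQuantile)
    eligible <- raw <= qcut  # row-wise low-intensity tail
    drop <- eligible &
      matrix(runif(p * n) < config$missingRate / config$mnarQuantile, p, n)
    raw[drop] <- NA_real_
  }

  labels <- assignLabels(t, config$thresholds)
  new("SyntheticCohort", matrix = QuantMatrix(raw, "raw"),
      trueScores = setNames(t, samples), trueLabels = labels,
      trueSignature = config$trueSignature, config = config)
}

#' Shift a cohort to a new measurement platform
#'
#' Adds a protein-independent global log2 offset (optionally
#' protein-dependent offsets) plus fresh measurement noise to every entry,
#' emulating re-measurement of the same samples on another LC-MS platform.
#' True scores and labels are unchanged. A protein-independent offset is
#' cancelled exactly by any zero-sum signature, so [transferOffset()]
#' recovers 0 for it; protein-dependent offsets induce a genuine score
#' shift that the intercept transfer must absorb.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param offset global log2 offset (scalar), or a per-protein named
#'   vector for the protein-dependent mode.
#' @param extraNoiseSd sd of additional log2 noise on the new platform.
#' @param seed integer seed for the fresh noise.
#' @return a \linkS4class{SyntheticCohort} on the new platform.
#' @export
applyPlatformShift <- function(cohort, offset, extraNoiseSd = 0, seed = 1L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  set.seed(as.integer(seed))
  v <- quantValues(cohort@matrix)
  log2x <- log2(v)
  if (length(offset) == 1L && is.null(names(offset))) {
    log2x <- log2x + offset
  } else {
    miss <- setdiff(rownames(log2x), names(offset))
    if (length(miss))
      stop("per-protein offset lacks: ", paste(head(miss, 3L), collapse = ", "))
    log2x <- log2x + offset[rownames(log2x)]
  }
  log2x <- log2x + matrix(rnorm(length(log2x), 0, extraNoiseSd),
                          nrow(log2x), ncol(log2x))
  out <- cohort
  out@matrix <- quantReplace(cohort@matrix, 2^log2x)
  out@config$platformOffset <- offset
  out
}
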