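#' @useDynLib zeroSumCOO, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

asPredictorMatrix <- function(X) {
  if (is(X, "QuantMatrix")) {
    if (!identical(scaleTag(X), "log2"))
      stop("predictors must be on the log2 scale (run preprocessQuant())")
    X <- t(quantValues(X))  # samples x proteins for regression
  }
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("predictor matrix contains non-finite values")
  X
}

#' Fit the zero-sum elastic net at a single penalty
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big)
#'   \quad \text{s.t.} \sum_j \beta_j = 0,}
#' by exact pairwise coordinate descent: coordinate pairs \eqn{(j,k)} are
#' visited in deterministic cyclic order and moved along the constraint-
#' preserving direction \eqn{(\beta_j+\delta, \beta_k-\delta)}, with
#' \eqn{\delta} solving the one-dimensional piecewise-quadratic subproblem
#' exactly. The intercept is unpenalized, excluded from the constraint, and
#' refreshed every sweep as \eqn{\beta_0 = \mathrm{mean}(y - X\beta)}.
#' Features are deliberately not standardized: standardization would break
#' the additive-shift invariance that makes the signature platform
#' independent.
#'
#' @param X samples x proteins numeric matrix of log2 intensities, or a
#'   log2-scale \linkS4class{QuantMatrix} (transposed internally).
#' @param y numeric response (continuous GCB scores), one per sample.
#' @param lambda positive penalty.
#' @param alpha elastic-net mixing in [0, 1]; 1 (the default, and the value
#'   used for the packaged signature) is the pure lasso penalty.
#' @param tol absolute objective decrease per sweep below which the solver
#'   stops (default 1e-8).
#' @param maxSweeps sweep budget (default 10000).
#' @param betaInit optional zero-sum warm start.
#' @return a \linkS4class{ZeroSumFit}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("P", 1:4)))
#' y <- X[, 1] - X[, 2] + rnorm(10, sd = 0.1)
#' fitZeroSum(X, y, lambda = 0.05)
#' @export
fitZeroSum <- function(X, y, lambda, alpha = 1, tol = 1e-8,
                       maxSweeps = 10000L, betaInit = NULL) {
  X <- asPredictorMatrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (ncol(X) < 2L) stop("zero-sum constraint needs at least 2 features")
  if (any(!is.finite(y))) stop("y contains non-finite values")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(betaInit)) betaInit <- numeric(ncol(X))
  stopifnot(length(betaInit) == ncol(X), abs(sum(betaInit)) < 1e-8)

  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  res <- .zerosum_cd_path(Xc, yc, lambda, alpha, tol,
                          as.integer(maxSweeps), betaInit)
  beta <- setNames(res$beta[, 1L], colnames(X))
  new("ZeroSumFit", beta = beta,
      beta0 = mean(y) - sum(xbar * beta), lambda = lambda, alpha = alpha,
      objective = res$objective[1L], nSweeps = res$nSweeps[1L],
      converged = res$converged[1L])
}

#' Build a geometric lambda grid for the zero-sum path
#'
#' \eqn{\lambda_{max}} is the smallest penalty at which the zero-sum
#' solution is entirely zero,
#' \eqn{\max_{j<k} |(x_j - x_k)^\top (y - \bar y)| / (2 n \alpha)}
#' (equivalently \eqn{(\max_j c_j - \min_j c_j)/(2\alpha)} with
#' \eqn{c_j = x_j^\top(y-\bar y)/n}); the grid descends geometrically to
#' \code{ratio * lambdaMax}.
#'
#' @inheritParams fitZeroSum
#' @param nLambda number of grid points (default 100).
#' @param ratio ratio of smallest to largest lambda (default 1e-4).
#' @return decreasing numeric vector of penalties.
#' @export
lambdaGrid <- function(X, y, alpha = 1, nLambda = 100L, ratio = 1e-4) {
  if (alpha <= 0) stop("alpha must be positive for a finite lambdaMax")
  X <- asPredictorMatrix(X)
  yc <- as.numeric(y) - mean(y)
  cj <- as.numeric(crossprod(X, yc)) / nrow(X)
  lambdaMax <- (max(cj) - min(cj)) / (2 * alpha)
  if (!is.finite(lambdaMax) || lambdaMax <= 0) {
    warning("degenerate response (lambdaMax = 0); returning a default tiny grid")
    lambdaMax <- 1e-3
  }
  exp(seq(log(lambdaMax), log(ratio * lambdaMax), length.out = nLambda))
}

fitZeroSumPath <- function(Xc, yc, lambdas, alpha, tol, maxSweeps) {
  .zerosum_cd_path(Xc, yc, lambdas, alpha, tol, as.integer(maxSweeps),
                   numeric(ncol(Xc)))
}

#' Cross-validate the zero-sum elastic net along a lambda path
#'
#' Samples are shuffled by a seeded permutation into \code{nFolds}
#' near-equal folds. For every penalty on the grid and every fold, the model
#' is fitted on the fold's complement (warm-started from larger penalties)
#' and the held-out squared error recorded. The reported curve is the mean
#' of fold means with standard error \eqn{sd(\text{fold means})/\sqrt{k}};
#' \code{lambda1se} is the largest penalty whose curve value is within one
#' standard error of the minimum — the parsimony-favouring rule used for the
#' final eight-protein signature.
#'
#' @inheritParams fitZeroSum
#' @param nFolds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param lambdas optional decreasing penalty grid; by default
#'   [lambdaGrid()] with \code{nLambda} points.
#' @param nLambda,ratio passed to [lambdaGrid()] when \code{lambdas} is
#'   \code{NULL}.
#' @return a \linkS4class{ZeroSumCV}.
#' @export
cvZeroSum <- function(X, y, alpha = 1, nFolds = 10L, seed = 1L,
                      lambdas = NULL, nLambda = 100L, ratio = 1e-4,
                      tol = 1e-8, maxSweeps = 10000L) {
  X <- asPredictorMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (nFolds < 2L) stop("need at least 2 folds")
  if (n < nFolds) stop("more folds than samples")
  if (is.null(lambdas)) lambdas <- lambdaGrid(X, y, alpha, nLambda, ratio)
  if (is.unsorted(rev(lambdas), strictly = TRUE))
    stop("lambdas must be strictly decreasing")
  L <- length(lambdas)

  foldid <- local({
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sample(rep_len(seq_len(nFolds), n))
  })
  if (min(tabulate(foldid, nFolds)) < 2L)
    stop("a fold has fewer than 2 samples; use fewer folds")

  foldErr <- matrix(NA_real_, nFolds, L)
  for (f in seq_len(nFolds)) {
    tr <- foldid != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    xbar <- colMeans(Xtr)
    path <- fitZeroSumPath(sweep(Xtr, 2L, xbar), ytr - mean(ytr), lambdas,
                           alpha, tol, maxSweeps)
    b0 <- mean(ytr) - as.numeric(crossprod(xbar, path$beta))
    pred <- X[!tr, , drop = FALSE] %*% path$beta +
      matrix(b0, sum(!tr), L, byrow = TRUE)
    foldErr[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cvm <- colMeans(foldErr)
  cvsd <- apply(foldErr, 2L, sd) / sqrt(nFolds)
  iMin <- which.min(cvm)
  ok <- which(cvm <= cvm[iMin] + cvsd[iMin])
  i1se <- min(ok)  # grid is decreasing: smallest index = largest lambda

  xbar <- colMeans(X)
  path <- fitZeroSumPath(sweep(X, 2L, xbar), y - mean(y), lambdas, alpha,
                         tol, maxSweeps)
  rownames(path$beta) <- colnames(X)
  mkFit <- function(i) {
    beta <- setNames(path$beta[, i], colnames(X))
    new("ZeroSumFit", beta = beta, beta0 = mean(y) - sum(xbar * beta),
        lambda = lambdas[i], alpha = alpha, objective = path$objective[i],
        nSweeps = path$nSweeps[i], converged = path$converged[i])
  }
  new("ZeroSumCV", lambdaGrid = lambdas, cvm = cvm, cvsd = cvsd,
      lambdaMin = lambdas[iMin], lambda1se = lambdas[i1se],
      foldid = as.integer(foldid), fitMin = mkFit(iMin),
      fit1se = mkFit(i1se), betaPath = path$beta)
}

#' Predict GCB scores from a zero-sum fit
#'
#' \eqn{score_i = \beta_0 + x_i^\top \beta}. Columns of \code{newdata} are
#' matched to coefficients by protein accession; unmatched accessions are an
#' error, never silently zero-filled.
#'
#' @param object a \linkS4class{ZeroSumFit}.
#' @param newdata samples x proteins log2 matrix with accession column
#'   names, or a log2-scale \linkS4class{QuantMatrix}.
#' @param ... ignored.
#' @return named numeric vector of per-sample scores.
#' @export
setMethod("predict", "ZeroSumFit", function(object, newdata, ...) {
  X <- asPredictorMatrix(newdata)
  acc <- names(object@beta)
  if (!is.null(colnames(X)) && !is.null(acc)) {
    miss <- setdiff(acc, colnames(X))
    if (length(miss))
      stop("predictor matrix lacks signature protein(s): ",
           paste(miss, collapse = ", "))
    X <- X[, acc, drop = FALSE]
  } else if (ncol(X) != length(object@beta)) {
    stop("cannot align unnamed predictor columns of differing dimension")
  }
  drop(X %*% object@beta) + object@beta0
})

#' Write / read the plain-text signature serialization
#'
#' Key-value dialect, one `accession<TAB>weight` line per protein plus
#' `intercept`, `lambda` and `alpha` entries, with nine decimal places —
#' round-trip safe at the precision the packaged signature is distributed
#' with.
#'
#' @param x a \linkS4class{CooSignature} or \linkS4class{ZeroSumFit}.
#' @param path file path.
#' @return \code{writeSignature}: the path, invisibly;
#'   \code{readSignature}: a \linkS4class{CooSignature}.
#' @export
writeSignature <- function(x, path) {
  w <- sigWeights(x)
  lines <- c(sprintf("%s\t%.9f", names(w), w),
             sprintf("intercept\t%.9f", sigIntercept(x)))
  if (is(x, "ZeroSumFit"))
    lines <- c(lines, sprintf("lambda\t%.9f", x@lambda),
               sprintf("alpha\t%.9f", x@alpha))
  writeLines(lines, path)
  invisible(path)
}

#' @param provenance provenance string recorded in the read signature.
#' @rdname writeSignature
#' @export
readSignature <- function(path, provenance = path) {
  tab <- read.delim(path, header = FALSE,
                    col.names = c("key", "value"),
                    stringsAsFactors = FALSE)
  meta <- tab$key %in% c("intercept", "lambda", "alpha")
  w <- setNames(tab$value[!meta], tab$key[!meta])
  b0 <- tab$value[tab$key == "intercept"]
  if (length(b0) != 1L) stop("signature file needs exactly one intercept line")
  new("CooSignature", weights = w, intercept = b0, provenance = provenance)
}
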