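# Shared fixtures and independent oracles used across the suite.

# Penalized zero-sum objective, coded independently of the package solver.
zsObjective <- function(X, y, b0, beta, lambda, alpha) {
  sum((y - b0 - X %*% beta)^2) / (2 * nrow(X)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# Global optimum of the zero-sum elastic net by exhaustive enumeration of
# all 3^p sign patterns; each pattern's equality-constrained smooth problem
# is solved exactly through its KKT linear system and kept only when the
# solution signs agree with the pattern. Exact for the convex problem at
# small p; completely independent of the coordinate-descent path.
oracleZeroSum <- function(X, y, lambda, alpha) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(Xc) / n
  cy <- as.numeric(crossprod(Xc, yc)) / n
  best <- zsObjective(Xc, yc, 0, numeric(p), lambda, alpha)
  bbest <- numeric(p)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    A <- which(s != 0)
    k <- length(A)
    if (k < 2L) next
    Q <- G[A, A, drop = FALSE] + lambda * (1 - alpha) * diag(k)
    K <- rbind(cbind(Q, 1), c(rep(1, k), 0))
    rhs <- c(cy[A] - lambda * alpha * s[A], 0)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    bA <- sol[seq_len(k)]
    if (any(sign(bA) * s[A] < 0)) next
    beta <- numeric(p)
    beta[A] <- bA
    f <- zsObjective(Xc, yc, 0, beta, lambda, alpha)
    if (f < best) {
      best <- f
      bbest <- beta
    }
  }
  list(objective = best, beta = bbest)
}

# Random regression instance with a zero-sum ground truth.
makeInstance <- function(n, p, noiseSd = 0.5) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("P%02d", 1:p)))
  betaTrue <- rnorm(p)
  betaTrue <- betaTrue - mean(betaTrue)
  y <- drop(X %*% betaTrue) + rnorm(n, sd = noiseSd)
  list(X = X, y = y, betaTrue = betaTrue)
}

# Brute-force decision-boundary search: all candidate cut pairs scored by
# direct recount, no cumulative-count shortcuts.
bruteForceBoundaries <- function(scores, labels) {
  u <- sort(unique(scores))
  cuts <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  labels <- as.character(labels)
  classify <- function(s, lo, up) {
    out <- rep("unclassified", length(s))
    out[s < lo] <- "ABC"
    out[s > up] <- "GCB"
    out
  }
  best <- Inf
  for (lo in cuts) for (up in cuts) {
    if (lo > up) next
    err <- sum(classify(scores, lo, up) != labels)
    if (err < best) best <- err
  }
  best
}

# Small raw-scale matrix used by several I/O tests.
makeRawMatrix <- function(values = c(4, 2, NA, 8), nr = 2, nc = 2) {
  m <- matrix(values, nr, nc,
              dimnames = list(sprintf("P%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  QuantMatrix(m, "raw")
}
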