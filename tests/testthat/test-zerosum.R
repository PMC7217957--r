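test_that("full shrinkage at the top of the lambda grid gives the null model", {
  set.seed(21)
  inst <- makeInstance(n = 15, p = 5)
  grid <- lambdaGrid(inst$X, inst$y)
  fit <- fitZeroSum(inst$X, inst$y, grid[1L])
  expect_equal(unname(sigWeights(fit)), rep(0, 5))
  expect_equal(sigIntercept(fit), mean(inst$y))
  # and a bit above lambda_max it stays null
  fit10 <- fitZeroSum(inst$X, inst$y, 10 * grid[1L])
  expect_equal(unname(sigWeights(fit10)), rep(0, 5))
})

test_that("p = 2 reduces to a univariate lasso with the closed-form solution", {
  set.seed(42)
  n <- 20
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.7 * (x1 - x2) + rnorm(n, sd = 0.3)
  X <- cbind(P1 = x1, P2 = x2)
  soft <- function(x, t) sign(x) * max(abs(x) - t, 0)
  for (alpha in c(1, 0.5)) for (lambda in c(0.02, 0.05, 0.2)) {
    z <- x1 - x2
    zc <- z - mean(z); yc <- y - mean(y)
    b1 <- soft(sum(zc * yc) / n, 2 * lambda * alpha) /
      (sum(zc^2) / n + 2 * lambda * (1 - alpha))
    fit <- fitZeroSum(X, y, lambda, alpha)
    expect_equal(unname(sigWeights(fit)), c(b1, -b1), tolerance = 1e-8)
  }
})

test_that("solver objective matches the sign-enumeration oracle on 25 seeded instances", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(8:20, 1); p <- sample(4:8, 1)
    alpha <- sample(c(1, 0.5), 1)
    inst <- makeInstance(n, p)
    lambda <- runif(1, 0.02, 0.3)
    fit <- fitZeroSum(inst$X, inst$y, lambda, alpha)
    orc <- oracleZeroSum(inst$X, inst$y, lambda, alpha)
    expect_lt(abs(fit@objective - orc$objective) / abs(orc$objective), 1e-5)
    expect_lt(abs(sum(sigWeights(fit))), 1e-8)
  }
})

test_that("lambda grid is geometric and its head nulls the fit", {
  set.seed(5)
  inst <- makeInstance(12, 4)
  g <- lambdaGrid(inst$X, inst$y, nLambda = 3L, ratio = 0.01)
  expect_equal(g[2L] / g[1L], g[3L] / g[2L], tolerance = 1e-12)
  expect_equal(g[3L], 0.01 * g[1L], tolerance = 1e-12)
  expect_warning(lambdaGrid(inst$X, rep(2, 12)), "degenerate")
})

test_that("predictions are invariant to per-sample additive shifts", {
  set.seed(9)
  inst <- makeInstance(18, 6)
  fit <- fitZeroSum(inst$X, inst$y, 0.05)
  shifts <- rnorm(18, sd = 3)
  expect_lt(max(abs(predict(fit, inst$X + shifts) - predict(fit, inst$X))),
            1e-10)
  # beta = 0 predicts the intercept everywhere
  g <- lambdaGrid(inst$X, inst$y)
  null <- fitZeroSum(inst$X, inst$y, g[1L])
  expect_equal(unname(predict(null, inst$X)), rep(mean(inst$y), 18))
  # independent dot-product recomputation
  manual <- apply(inst$X[, names(sigWeights(fit))], 1L,
                  function(r) sum(r * sigWeights(fit))) + sigIntercept(fit)
  expect_equal(unname(predict(fit, inst$X)), unname(manual),
               tolerance = 1e-12)
})

test_that("prediction refuses unmatched accessions", {
  set.seed(10)
  inst <- makeInstance(10, 4)
  fit <- fitZeroSum(inst$X, inst$y, 0.1)
  X2 <- inst$X[, 1:3]
  expect_error(predict(fit, X2), "P04")
})

test_that("cross-validation is seed-deterministic and honours the 1se rule", {
  set.seed(31)
  inst <- makeInstance(40, 8)
  cv1 <- cvZeroSum(inst$X, inst$y, seed = 7, nFolds = 5L, nLambda = 40L)
  cv2 <- cvZeroSum(inst$X, inst$y, seed = 7, nFolds = 5L, nLambda = 40L)
  expect_identical(cv1@cvm, cv2@cvm)
  expect_identical(cv1@foldid, cv2@foldid)
  expect_identical(sigWeights(cv1@fit1se), sigWeights(cv2@fit1se))
  expect_gte(cv1@lambda1se, cv1@lambdaMin)
  iMin <- which(cv1@lambdaGrid == cv1@lambdaMin)
  i1se <- which(cv1@lambdaGrid == cv1@lambda1se)
  expect_equal(cv1@cvm[iMin], min(cv1@cvm))
  expect_lte(cv1@cvm[i1se], cv1@cvm[iMin] + cv1@cvsd[iMin])
  # 1se is the LARGEST such lambda
  if (i1se > 1L)
    expect_gt(cv1@cvm[i1se - 1L], cv1@cvm[iMin] + cv1@cvsd[iMin])
})

test_that("pure-noise responses mostly select the null model under the 1se rule", {
  nulls <- 0L
  supp1se <- suppMin <- integer(30)
  for (s in 1:30) {
    set.seed(s)
    X <- matrix(rnorm(60 * 20), 60, 20,
                dimnames = list(NULL, sprintf("P%02d", 1:20)))
    y <- rnorm(60)
    cv <- cvZeroSum(X, y, seed = s)
    supp1se[s] <- sum(sigWeights(cv@fit1se) != 0)
    suppMin[s] <- sum(sigWeights(cv@fitMin) != 0)
    if (supp1se[s] == 0L) nulls <- nulls + 1L
  }
  # the 1se rule is parsimony-favouring: usually the null model on pure
  # noise, and never denser than the cv-minimum model
  expect_gte(nulls, 20L)
  expect_true(all(supp1se <= suppMin))
})

test_that("warm-started path objectives are coherent along the grid", {
  set.seed(55)
  inst <- makeInstance(25, 6)
  g <- lambdaGrid(inst$X, inst$y, nLambda = 20L, ratio = 1e-3)
  fits <- lapply(g, function(l) fitZeroSum(inst$X, inst$y, l))
  objs <- vapply(fits, function(f) f@objective, 0)
  # the unpenalized part of the objective can only shrink as lambda drops;
  # evaluating the previous solution at the next lambda can never beat the
  # next solution
  for (i in seq_along(g)[-1L]) {
    Xc <- scale(inst$X, scale = FALSE)
    yc <- inst$y - mean(inst$y)
    prev <- zsObjective(Xc, yc, 0, sigWeights(fits[[i - 1L]]), g[i], 1)
    expect_lte(objs[i], prev + 1e-10)
  }
  expect_true(all(vapply(fits, function(f) abs(sum(sigWeights(f))), 0) < 1e-8))
})

test_that("signature serialization round-trips at nine decimals", {
  set.seed(77)
  inst <- makeInstance(15, 5)
  fit <- fitZeroSum(inst$X, inst$y, 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignature(fit, path)
  back <- readSignature(path)
  expect_equal(sigWeights(back)[names(sigWeights(fit))], sigWeights(fit),
               tolerance = 1e-9)
  expect_equal(sigIntercept(back), sigIntercept(fit), tolerance = 1e-9)
})

test_that("degenerate inputs are rejected with informative errors", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  y <- rnorm(10)
  expect_error(fitZeroSum(X[, 1, drop = FALSE], y, 0.1), "at least 2 features")
  expect_error(fitZeroSum(X[1, , drop = FALSE], y[1], 0.1), "at least 2 samples")
  expect_error(fitZeroSum(X, c(y[-1], NA), 0.1), "non-finite")
  expect_error(fitZeroSum(X, y, -1), "lambda")
  expect_error(lambdaGrid(X, y, alpha = 0), "alpha")
  expect_error(cvZeroSum(X, y, nFolds = 11L), "folds")
})
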