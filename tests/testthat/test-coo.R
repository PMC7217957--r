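test_that("the packaged signature is zero-sum and scoring equal intensities returns the intercept", {
  sig <- cooSignature()
  expect_equal(length(sigWeights(sig)), 8L)
  expect_lt(abs(sum(sigWeights(sig))), 1e-9)
  for (common in c(10, 17.3, 25)) {
    m <- matrix(common, 8, 1,
                dimnames = list(names(sigWeights(sig)), "s1"))
    s <- scoreSamples(sig, QuantMatrix(2^m, "raw") |> log2Transform())
    expect_equal(unname(s), -1.258554293, tolerance = 1e-9)
  }
})

test_that("scores are invariant to rescaling a sample's raw intensities", {
  sig <- cooSignature()
  set.seed(3)
  m <- matrix(rnorm(8 * 5, 20, 2), 8, 5,
              dimnames = list(names(sigWeights(sig)), sprintf("s%d", 1:5)))
  s1 <- scoreSamples(sig, QuantMatrix(2^m, "raw") |> log2Transform())
  s2 <- scoreSamples(sig, QuantMatrix(2 * 2^m, "raw") |> log2Transform())
  expect_lt(max(abs(s1 - s2)), 1e-10)
  # independent spreadsheet-style recomputation
  w <- sigWeights(sig)
  manual <- sigIntercept(sig) + colSums(m[names(w), ] * w)
  expect_equal(unname(s1), unname(manual), tolerance = 1e-12)
})

test_that("scoring refuses matrices lacking a signature protein", {
  sig <- cooSignature()
  m <- matrix(20, 7, 1, dimnames = list(names(sigWeights(sig))[-8], "s1"))
  expect_error(scoreSamples(sig, QuantMatrix(2^m, "raw") |> log2Transform()),
               "P18031")
})

test_that("label assignment follows the published strict inequalities", {
  s <- c(-5, -3.50, 0, 1.28, 2)
  l <- assignLabels(s)
  expect_equal(as.character(l),
               c("ABC", "unclassified", "unclassified", "unclassified", "GCB"))
  expect_error(assignLabels(c(1, NA)), "non-finite")
  expect_error(assignLabels(1, c(2, 1)), "lower <= upper")
})

test_that("boundary training recovers a perfect separation with maximal margin", {
  b <- trainBoundaries(c(-2, -1, 0, 1, 2),
                       c("ABC", "ABC", "unclassified", "GCB", "GCB"))
  expect_equal(attr(b, "misclassifications"), 0L)
  expect_gt(b["lower"], -1); expect_lt(b["lower"], 0)
  expect_gt(b["upper"], 0); expect_lt(b["upper"], 1)
  expect_equal(as.numeric(b), c(-0.5, 0.5))  # margin-maximizing midpoints

  # all one class: sentinel boundaries, zero errors
  bg <- trainBoundaries(c(0.3, 1.2, 5), rep("GCB", 3))
  expect_equal(attr(bg, "misclassifications"), 0L)
  expect_true(all(c(0.3, 1.2, 5) > bg["upper"]))

  # inverted pair cannot go below one error
  bi <- trainBoundaries(c(0, 1), c("GCB", "ABC"))
  expect_equal(attr(bi, "misclassifications"), 1L)
})

test_that("boundary training equals brute force on random instances up to n = 30", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(2:30, 1)
    scores <- round(rnorm(n, 0, 3), 2)
    labels <- sample(c("ABC", "unclassified", "GCB"), n, replace = TRUE)
    b <- trainBoundaries(scores, labels)
    expect_equal(attr(b, "misclassifications"),
                 bruteForceBoundaries(scores, labels),
                 info = sprintf("instance %d", rep))
    # trained labels really do achieve the reported error count
    got <- sum(as.character(assignLabels(scores, b)) != labels)
    expect_equal(got, attr(b, "misclassifications"))
  }
})

test_that("trained boundaries are never beaten by a manual cut pair", {
  set.seed(23)
  scores <- rnorm(25, 0, 3)
  labels <- as.character(assignLabels(scores + rnorm(25, 0, 1.5)))
  b <- trainBoundaries(scores, labels)
  for (i in 1:50) {
    lo <- runif(1, -6, 6); up <- runif(1, lo, 6)
    manual <- sum(as.character(assignLabels(scores, c(lo, up))) != labels)
    expect_gte(manual, attr(b, "misclassifications"))
  }
})

test_that("discrepancy tally separates minor and major switches", {
  expect_equal(tallyDiscrepancies(c("ABC", "GCB"), c("ABC", "GCB"))[c("minor", "major")],
               list(minor = 0L, major = 0L))
  t1 <- tallyDiscrepancies("unclassified", "ABC")
  expect_equal(t1$minor, 1L); expect_equal(t1$major, 0L)
  t2 <- tallyDiscrepancies(c("GCB", "ABC"), c("ABC", "GCB"))
  expect_equal(t2$minor, 0L); expect_equal(t2$major, 2L)
  expect_error(tallyDiscrepancies("ABC", "gcb-like"), "alphabet")
  # minor + major + agreements partition the cohort
  set.seed(4)
  pred <- sample(c("ABC", "unclassified", "GCB"), 50, replace = TRUE)
  ref <- sample(c("ABC", "unclassified", "GCB"), 50, replace = TRUE)
  tl <- tallyDiscrepancies(pred, ref)
  expect_equal(tl$minor + tl$major + sum(diag(tl$confusion)), 50L)
})

test_that("intercept transfer recovers mean score differences", {
  expect_equal(transferOffset(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(transferOffset(c(1, 2, 3), c(1, 2, 3) - 2.5), 2.5)
  expect_equal(transferOffset(c(1, 2, 3), c(0, 0, 3)), 1)
  expect_error(transferOffset(1:3, 1:2), "paired")
  # applying the delta equalizes platform means exactly
  set.seed(8)
  ref <- rnorm(20); new <- ref - 1.7 + rnorm(20, sd = 0.1)
  d <- transferOffset(ref, new)
  expect_equal(mean(new + d), mean(ref), tolerance = 1e-12)
  # and shifting does not change the cross-platform correlation
  expect_equal(pearsonR(ref, new + d), pearsonR(ref, new), tolerance = 1e-12)
})

test_that("Pearson correlation matches hand values and rejects degenerate input", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearsonR(a, 2 * a + 1), 1)
  expect_equal(pearsonR(a, -a), -1)
  expect_equal(pearsonR(a, c(2, 1, 4, 3)), 0.6)
  expect_error(pearsonR(a, rep(1, 4)), "constant")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("classifyCoo packages consistent results", {
  sig <- cooSignature()
  set.seed(13)
  m <- matrix(rnorm(8 * 6, 20, 3), 8, 6,
              dimnames = list(names(sigWeights(sig)), sprintf("s%d", 1:6)))
  res <- classifyCoo(sig, QuantMatrix(2^m, "raw") |> log2Transform())
  expect_s4_class(res, "CooResult")
  expect_identical(as.character(cooLabels(res)),
                   as.character(assignLabels(cooScores(res))))
})
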