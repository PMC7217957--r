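test_that("rollup sums the top proteotypic peptides per sample", {
  tab <- data.frame(sample_id = "s1", protein_id = "P1",
                    peptide_seq = paste0("PEPTIDE", LETTERS[1:8]),
                    intensity = 8:1, is_proteotypic = TRUE)
  expect_equal(unname(quantValues(rollupProtein(tab))[1, 1]), 33)

  one <- data.frame(sample_id = "s1", protein_id = "P1",
                    peptide_seq = "PEPTIDEA", intensity = 10,
                    is_proteotypic = TRUE)
  expect_equal(unname(quantValues(rollupProtein(one))[1, 1]), 10)

  short <- data.frame(sample_id = "s1", protein_id = "P1",
                      peptide_seq = "PEPTIDE", intensity = 10,
                      is_proteotypic = TRUE)
  expect_true(is.na(quantValues(rollupProtein(short))[1, 1]))

  nonproteo <- data.frame(sample_id = "s1", protein_id = "P1",
                          peptide_seq = c("PEPTIDEA", "PEPTIDEB"),
                          intensity = c(5, 100),
                          is_proteotypic = c(TRUE, FALSE))
  expect_equal(unname(quantValues(rollupProtein(nonproteo))[1, 1]), 5)

  dup <- rbind(one, one)
  expect_error(rollupProtein(dup), "duplicate.*s1, P1, PEPTIDEA")
})

test_that("rollup ranking is per sample with lexicographic tie-break", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 3),
    protein_id = "P1",
    peptide_seq = rep(c("AAAAAAAA", "CCCCCCCC", "BBBBBBBB"), 2),
    intensity = c(1, 2, 3, 3, 2, 1),
    is_proteotypic = TRUE)
  v <- quantValues(rollupProtein(tab, maxPeptides = 2L))
  expect_equal(unname(v["P1", "s1"]), 5)  # top two in s1: 3 + 2
  expect_equal(unname(v["P1", "s2"]), 5)  # top two in s2: 3 + 2
  # exact tie: lexicographically earlier sequence wins the last slot
  tie <- data.frame(sample_id = "s1", protein_id = "P1",
                    peptide_seq = c("BBBBBBBB", "AAAAAAAA"),
                    intensity = c(7, 7), is_proteotypic = TRUE)
  expect_equal(unname(quantValues(rollupProtein(tie, maxPeptides = 1L))[1, 1]), 7)
})

test_that("missing-value filter applies the fewer-than-four rule", {
  set.seed(1)
  v <- matrix(rexp(10 * 42) + 1, 10, 42,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("s%02d", 1:42)))
  for (i in 1:10) v[i, seq_len(i - 1L)] <- NA  # protein i has i-1 missing
  qm <- QuantMatrix(v, "raw")
  f <- filterMissing(qm, maxMissing = 3L)
  expect_equal(f$report$proteinsKept, sprintf("P%02d", 1:4))  # counts 0..3
  expect_equal(length(f$report$proteinsDropped), 6L)
  expect_equal(unname(f$report$missingCounts), 0:9)
  expect_setequal(c(f$report$proteinsKept, f$report$proteinsDropped),
                  rownames(v))
  # kept proteins keep their missing counts
  expect_equal(unname(rowSums(is.na(quantValues(f$matrix)))), 0:3)
  expect_warning(filterMissing(qm, maxMissing = 42L), "vacuous")
})

test_that("global-minimum imputation replaces NA and zero entries", {
  qm <- makeRawMatrix(c(4, 2, NA, 8))
  out <- quantValues(imputeGlobalMin(qm))
  expect_equal(unname(out), matrix(c(4, 2, 2, 8), 2, 2))

  clean <- makeRawMatrix(c(4, 2, 3, 8))
  expect_equal(quantValues(imputeGlobalMin(clean)), quantValues(clean))

  allna <- makeRawMatrix(rep(NA_real_, 4))
  expect_error(imputeGlobalMin(allna), "nothing to impute")
})

test_that("total-sum normalization yields unit totals and is idempotent", {
  qm <- makeRawMatrix(c(2, 3, 5, 10, 20, 70), nr = 3, nc = 2)
  nm <- totalSumNormalize(qm)
  expect_equal(unname(quantValues(nm)[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(quantValues(nm))), c(1, 1), tolerance = 1e-12)
  expect_equal(scaleTag(nm), "normalized")
  # re-normalizing unit-sum columns changes nothing
  nm2 <- totalSumNormalize(QuantMatrix(quantValues(nm), "raw"))
  expect_equal(quantValues(nm2), quantValues(nm), tolerance = 1e-15)
})

test_that("log2 transform requires imputation and computes exact logs", {
  qm <- makeRawMatrix(c(8, 1, 10, 2))
  lg <- log2Transform(qm)
  expect_equal(unname(quantValues(lg)[, 1]), c(3, 0))
  expect_equal(unname(quantValues(lg)[1, 2]), log(10) / log(2))
  expect_equal(scaleTag(lg), "log2")
  expect_error(log2Transform(makeRawMatrix(c(8, 1, NA, 2))),
               "imputeGlobalMin")
})

test_that("wide-matrix TSV round-trips values and missingness", {
  set.seed(7)
  v <- matrix(rexp(12) * 1e6, 3, 4,
              dimnames = list(c("P1", "P2", "P3"), sprintf("s%d", 1:4)))
  v[2, 3] <- NA
  qm <- QuantMatrix(v, "raw")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeQuantMatrix(qm, path)
  back <- readQuantMatrix(path)
  expect_equal(quantValues(back), quantValues(qm), tolerance = 1e-12)
  expect_identical(is.na(quantValues(back)), is.na(quantValues(qm)))
  # empty-field dialect also read as missing
  txt <- readLines(path)
  txt <- sub("\tNA", "\t", txt)
  writeLines(txt, path)
  expect_identical(is.na(quantValues(readQuantMatrix(path))),
                   is.na(quantValues(qm)))
})

test_that("the preprocessing chain is deterministic", {
  set.seed(11)
  v <- matrix(rexp(60) * 1e5, 6, 10,
              dimnames = list(sprintf("P%d", 1:6), sprintf("s%d", 1:10)))
  v[sample(60, 8)] <- NA
  qm <- QuantMatrix(v, "raw")
  a <- preprocessQuant(qm, maxMissing = 2L)
  b <- preprocessQuant(qm, maxMissing = 2L)
  expect_identical(quantValues(a$matrix), quantValues(b$matrix))
  expect_identical(a$report, b$report)
  expect_false(anyNA(quantValues(a$matrix)))
})

test_that("QuantMatrix validity enforces the scale contract", {
  expect_error(QuantMatrix(matrix(c(-1, 2, 3, 4), 2, 2,
                                  dimnames = list(c("a", "b"), c("x", "y")))),
               "positive or NA")
  m <- matrix(c(1, 2, NA, 4), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(QuantMatrix(m, "log2"), "finite")
  expect_s4_class(QuantMatrix(m, "raw"), "QuantMatrix")
})
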