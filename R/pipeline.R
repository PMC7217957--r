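#' Run the full simulate/preprocess/fit/classify pipeline
#'
#' Orchestrates the package end to end and writes every artifact to
#' \code{outputDir}: the simulated wide matrix and truth table, the
#' preprocessed log2 matrix, the cross-validated zero-sum fit (serialized
#' signature), per-sample scores and COO labels, trained decision
#' boundaries, and a JSON run manifest (inputs, parameters, seed, package
#' version) sufficient to reproduce the run bit-identically.
#'
#' @param outputDir directory for artifacts (created if absent).
#' @param config simulation configuration from [simConfig()]; its seed
#'   drives every random draw in the run.
#' @param maxMissing missing-value filter tolerance for preprocessing, or
#'   \code{NULL} (default) to impute without dropping proteins.
#' @param normalize apply total-sum normalization during preprocessing.
#' @param lambdaRule \code{"1se"} (default) or \code{"min"}.
#' @param nFolds cross-validation folds.
#' @return invisibly, a list with the cohort, the \linkS4class{ZeroSumCV}
#'   fit, the \linkS4class{CooResult}, the trained boundaries and the
#'   manifest path.
#' @export
runPipeline <- function(outputDir, config = simConfig(), maxMissing = NULL,
                        normalize = TRUE, lambdaRule = c("1se", "min"),
                        nFolds = 10L) {
  lambdaRule <- match.arg(lambdaRule)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outputDir, f)

  cohort <- simulateCohort(config)
  writeQuantMatrix(cohort@matrix, pth("matrix_raw.tsv"))
  truth <- data.frame(sample_id = sampleIds(cohort),
                      true_score = unname(trueScores(cohort)),
                      true_label = as.character(trueLabels(cohort)))
  write.table(truth, pth("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  prep <- preprocessQuant(cohort@matrix, maxMissing = maxMissing,
                          normalize = normalize)
  writeQuantMatrix(prep$matrix, pth("matrix_log2.tsv"))

  cv <- cvZeroSum(prep$matrix, trueScores(cohort), seed = config$seed,
                  nFolds = nFolds)
  fit <- if (lambdaRule == "1se") cv@fit1se else cv@fitMin
  writeSignature(fit, pth("signature.tsv"))

  scores <- predict(fit, prep$matrix)
  bounds <- trainBoundaries(scores, trueLabels(cohort))
  result <- new("CooResult", sampleIds = names(scores),
                scores = unname(scores),
                labels = assignLabels(scores, bounds),
                boundaries = unname(bounds))
  out <- data.frame(sample_id = sampleIds(result),
                    score = unname(cooScores(result)),
                    label = as.character(cooLabels(result)))
  write.table(out, pth("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    package = "zeroSumCOO",
    version = as.character(utils::packageVersion("zeroSumCOO")),
    seed = config$seed,
    parameters = list(nSamples = config$nSamples,
                      nProteins = config$nProteins,
                      noiseSd = config$noiseSd,
                      sizeFactorSd = config$sizeFactorSd,
                      missingRate = config$missingRate,
                      mnarQuantile = config$mnarQuantile,
                      maxMissing = maxMissing, normalize = normalize,
                      lambdaRule = lambdaRule, nFolds = nFolds),
    selectedLambda = fit@lambda,
    boundaries = unname(bounds),
    artifacts = c("matrix_raw.tsv", "truth.tsv", "matrix_log2.tsv",
                  "signature.tsv", "scores.tsv"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, cv = cv, result = result,
                 boundaries = bounds, manifest = pth("manifest.json")))
}
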