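#' Construct a QuantMatrix
#'
#' @param values numeric matrix of intensities, proteins as rows and samples
#'   as columns, with row and column names set to protein accessions and
#'   sample identifiers. Missing measurements are \code{NA}.
#' @param scaleTag one of \code{"raw"}, \code{"normalized"}, \code{"log2"}.
#' @return a \linkS4class{QuantMatrix}.
#' @examples
#' m <- matrix(c(4, 2, NA, 8), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' QuantMatrix(m)
#' @export
QuantMatrix <- function(values, scaleTag = c("raw", "normalized", "log2")) {
  scaleTag <- match.arg(scaleTag)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs protein accessions as rownames and sample ids as colnames")
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values))
  new("QuantMatrix", se, scaleTag = scaleTag)
}

quantReplace <- function(x, values, tag = scaleTag(x)) {
  SummarizedExperiment::assay(x, "intensity", withDimnames = FALSE) <- values
  x@scaleTag <- tag
  validObject(x)
  x
}

#' Read a long-format peptide quantitation table
#'
#' Expects a TSV with columns \code{sample_id}, \code{protein_id},
#' \code{peptide_seq}, \code{intensity} and \code{is_proteotypic}
#' (logical or 0/1). Upstream identification filters (peptide FDR,
#' identification confidence) are assumed applied by the search engine and
#' enter only through the \code{is_proteotypic} flag.
#'
#' @param path path to the TSV file.
#' @return a validated \code{data.frame}.
#' @seealso [rollupProtein()]
#' @export
readPeptideTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validatePeptideTable(tab)
}

validatePeptideTable <- function(tab) {
  need <- c("sample_id", "protein_id", "peptide_seq", "intensity",
            "is_proteotypic")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  tab$is_proteotypic <- as.logical(tab$is_proteotypic)
  if (anyNA(tab$is_proteotypic)) stop("is_proteotypic must be logical or 0/1")
  if (any(!is.finite(tab$intensity)) || any(tab$intensity < 0))
    stop("intensities must be finite and non-negative")
  key <- paste(tab$sample_id, tab$protein_id, tab$peptide_seq, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup)
    stop(sprintf(
      "duplicate (sample, protein, peptide) row: (%s, %s, %s)",
      tab$sample_id[dup], tab$protein_id[dup], tab$peptide_seq[dup]))
  tab
}

#' Roll peptide intensities up to protein-group intensities
#'
#' For every (sample, protein) pair, sums the intensities of the top
#' \code{maxPeptides} proteotypic peptides of length at least
#' \code{minLength}, ranked by intensity within that sample (ties broken
#' lexicographically by peptide sequence, for determinism). Pairs with no
#' qualifying peptide are missing (\code{NA}). Non-proteotypic peptides are
#' ignored throughout.
#'
#' @param table a peptide table as returned by [readPeptideTable()].
#' @param maxPeptides number of top peptides summed per protein (default 6).
#' @param minLength minimum peptide length in amino acids (default 8).
#' @return a raw-scale \linkS4class{QuantMatrix} over all samples and
#'   proteins present in \code{table}.
#' @examples
#' tab <- data.frame(sample_id = "s1", protein_id = "P1",
#'                   peptide_seq = paste0("PEPTIDE", LETTERS[1:8]),
#'                   intensity = 8:1, is_proteotypic = TRUE)
#' quantValues(rollupProtein(tab))  # 33: top six of 8,7,6,5,4,3,2,1
#' @export
rollupProtein <- function(table, maxPeptides = 6L, minLength = 8L) {
  table <- validatePeptideTable(table)
  if (nrow(table) == 0L) stop("peptide table is empty")
  if (maxPeptides < 1L) stop("maxPeptides must be >= 1")
  samples <- unique(table$sample_id)
  proteins <- unique(table$protein_id)
  keep <- table$is_proteotypic & nchar(table$peptide_seq) >= minLength
  tab <- table[keep, , drop = FALSE]
  values <- matrix(NA_real_, length(proteins), length(samples),
                   dimnames = list(proteins, samples))
  if (nrow(tab)) {
    # rank within (sample, protein) by intensity desc, then sequence asc
    ord <- order(tab$sample_id, tab$protein_id, -tab$intensity,
                 tab$peptide_seq)
    tab <- tab[ord, , drop = FALSE]
    grp <- paste(tab$sample_id, tab$protein_id, sep = "\r")
    rank <- stats::ave(tab$intensity, grp, FUN = seq_along)
    tab <- tab[rank <= maxPeptides, , drop = FALSE]
    agg <- rowsum(tab$intensity, paste(tab$protein_id, tab$sample_id,
                                       sep = "\r"))
    ids <- strsplit(rownames(agg), "\r", fixed = TRUE)
    pi <- vapply(ids, `[`, "", 1L)
    si <- vapply(ids, `[`, "", 2L)
    values[cbind(match(pi, proteins), match(si, samples))] <- agg[, 1L]
  }
  values[!is.na(values) & values == 0] <- NA_real_  # all-zero evidence = missing
  QuantMatrix(values, "raw")
}

#' Drop proteins with too many missing values
#'
#' Removes protein groups whose number of missing samples exceeds
#' \code{maxMissing} (the default 3 keeps proteins with "fewer than four"
#' missing values). Column and row order of survivors is preserved.
#'
#' @param matrix a raw- or normalized-scale \linkS4class{QuantMatrix}.
#' @param maxMissing largest tolerated per-protein missing count (default 3).
#' @return a list with elements \code{matrix} (the filtered
#'   \linkS4class{QuantMatrix}) and \code{report}, a list with
#'   \code{proteinsKept}, \code{proteinsDropped} and \code{missingCounts}.
#' @export
filterMissing <- function(matrix, maxMissing = 3L) {
  stopifnot(is(matrix, "QuantMatrix"))
  if (identical(scaleTag(matrix), "log2"))
    stop("filterMissing applies before log2 transformation")
  if (maxMissing < 0L) stop("maxMissing must be non-negative")
  v <- quantValues(matrix)
  if (maxMissing >= ncol(v))
    warning("maxMissing >= number of samples: filter is vacuous")
  nmiss <- rowSums(is.na(v))
  keep <- nmiss <= maxMissing
  report <- list(proteinsKept = rownames(v)[keep],
                 proteinsDropped = rownames(v)[!keep],
                 missingCounts = setNames(as.integer(nmiss), rownames(v)))
  list(matrix = matrix[keep, ], report = report)
}

#' Impute missing and zero intensities with the global matrix minimum
#'
#' Every missing and every zero entry is replaced by the smallest observed
#' positive intensity of the whole matrix; observed positive values are left
#' untouched. This is the imputation applied before log2 transformation.
#'
#' @param matrix a raw- or normalized-scale \linkS4class{QuantMatrix}.
#' @return a \linkS4class{QuantMatrix} with no missing entries, same scale.
#' @export
imputeGlobalMin <- function(matrix) {
  stopifnot(is(matrix, "QuantMatrix"))
  if (identical(scaleTag(matrix), "log2"))
    stop("imputeGlobalMin applies before log2 transformation")
  v <- quantValues(matrix)
  obs <- v[!is.na(v) & v > 0]
  if (!length(obs)) stop("all entries missing: nothing to impute from")
  v[is.na(v) | v == 0] <- min(obs)
  quantReplace(matrix, v)
}

#' Normalize each sample by its total observed intensity
#'
#' Divides every observed entry by the total observed intensity of its
#' sample, so observed entries of each sample sum to one. Because the
#' downstream zero-sum score is invariant to per-sample rescaling, this step
#' changes no predicted score; it is retained for comparability of
#' intensities across samples.
#'
#' @param matrix a raw-scale \linkS4class{QuantMatrix}.
#' @return a normalized-scale \linkS4class{QuantMatrix}.
#' @export
totalSumNormalize <- function(matrix) {
  stopifnot(is(matrix, "QuantMatrix"))
  if (!identical(scaleTag(matrix), "raw"))
    stop("totalSumNormalize expects a raw-scale matrix")
  v <- quantValues(matrix)
  tot <- colSums(v, na.rm = TRUE)
  if (any(tot <= 0 | !is.finite(tot))) {
    bad <- colnames(v)[tot <= 0 | !is.finite(tot)][1L]
    stop("sample with zero total intensity: ", bad)
  }
  quantReplace(matrix, sweep(v, 2L, tot, "/"), tag = "normalized")
}

#' Log2-transform a fully observed intensity matrix
#'
#' @param matrix a raw- or normalized-scale \linkS4class{QuantMatrix} with
#'   no missing and no non-positive entries (run [imputeGlobalMin()] first).
#' @return a log2-scale \linkS4class{QuantMatrix}.
#' @export
log2Transform <- function(matrix) {
  stopifnot(is(matrix, "QuantMatrix"))
  if (identical(scaleTag(matrix), "log2"))
    stop("matrix is already on the log2 scale")
  v <- quantValues(matrix)
  if (anyNA(v) || any(v <= 0))
    stop("missing or non-positive entries: run imputeGlobalMin() first")
  quantReplace(matrix, log2(v), tag = "log2")
}

#' Preprocess a raw quantitation matrix for scoring
#'
#' Convenience chain: optional missing-value filter, global-minimum
#' imputation, optional total-sum normalization, log2 transform.
#'
#' @param matrix a raw-scale \linkS4class{QuantMatrix}.
#' @param maxMissing per-protein missing tolerance for [filterMissing()], or
#'   \code{NULL} to skip the filter.
#' @param normalize logical, apply [totalSumNormalize()] (default TRUE; the
#'   zero-sum score is identical either way).
#' @return a list with \code{matrix} (log2-scale \linkS4class{QuantMatrix})
#'   and \code{report} (the filter report, or \code{NULL}).
#' @export
preprocessQuant <- function(matrix, maxMissing = 3L, normalize = TRUE) {
  report <- NULL
  if (!is.null(maxMissing)) {
    f <- filterMissing(matrix, maxMissing)
    matrix <- f$matrix
    report <- f$report
  }
  matrix <- imputeGlobalMin(matrix)
  if (normalize) matrix <- totalSumNormalize(matrix)
  list(matrix = log2Transform(matrix), report = report)
}

#' Read / write the wide quantitation matrix TSV
#'
#' The on-disk dialect has a header \code{sample_id} followed by protein
#' accessions and one row per sample; missing values may be written as
#' \code{NA} or left empty (both are accepted on read; \code{NA} is
#' written). In memory the matrix is transposed to the proteins x samples
#' orientation.
#'
#' @param path file path.
#' @param scaleTag scale of the stored values (default \code{"raw"}).
#' @return \code{readQuantMatrix}: a \linkS4class{QuantMatrix}.
#' @export
readQuantMatrix <- function(path, scaleTag = c("raw", "normalized", "log2")) {
  scaleTag <- match.arg(scaleTag)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (names(tab)[1L] != "sample_id")
    stop("wide matrix TSV must start with a 'sample_id' column")
  values <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(values) <- as.character(tab$sample_id)
  QuantMatrix(values, scaleTag)
}

#' @param matrix a \linkS4class{QuantMatrix} to write.
#' @rdname readQuantMatrix
#' @return \code{writeQuantMatrix}: the path, invisibly.
#' @export
writeQuantMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "QuantMatrix"))
  v <- t(quantValues(matrix))
  out <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
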