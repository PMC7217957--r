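# Monoisotopic residue masses (Da), standard IUPAC/unimod values, and the
# constants used throughout: water for the peptide termini, the proton for
# charging.
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

#' Supported peptide modifications
#'
#' The four modifications carried by the targeted cell-of-origin panel, with
#' their monoisotopic mass shifts and site rules: \code{pyroGlu} (cyclized
#' N-terminal glutamine, -17.026549 Da), \code{propionamide} (acrylamide
#' adduct on cysteine, +71.037114 Da, from gel-assisted digestion),
#' \code{oxidation} (methionine, +15.994915 Da) and \code{deamidation}
#' (asparagine, +0.984016 Da).
#'
#' @return data.frame with columns \code{name}, \code{massDelta},
#'   \code{site}, \code{nTermOnly} and the bracket \code{tag} used in
#'   modified-sequence notation.
#' @export
modificationSpecs <- function() {
  data.frame(
    name = c("pyroGlu", "propionamide", "oxidation", "deamidation"),
    massDelta = c(-17.026549, 71.037114, 15.994915, 0.984016),
    site = c("Q", "C", "M", "N"),
    nTermOnly = c(TRUE, FALSE, FALSE, FALSE),
    tag = c("PGQ", "PPa", "Oxi", "Dea"),
    stringsAsFactors = FALSE)
}

#' Parse bracketed modified-peptide notation
#'
#' Accepts the panel's dialect: \code{"[PGQ]-QIQVSWLR"} (N-terminal
#' pyro-glutamate), \code{"ALSIGFETC[PPa]R"} (bracket tag following the
#' modified residue). Tags are matched case-insensitively against
#' [modificationSpecs()].
#'
#' @param modifiedSequence character scalar.
#' @return list with \code{sequence} (plain uppercase sequence) and
#'   \code{modifications} (data.frame of \code{position}, \code{name},
#'   \code{massDelta}).
#' @export
parseModifiedPeptide <- function(modifiedSequence) {
  specs <- modificationSpecs()
  s <- modifiedSequence
  mods <- data.frame(position = integer(), name = character(),
                     massDelta = numeric(), stringsAsFactors = FALSE)
  if (grepl("^\\[PGQ\\]-", s, ignore.case = TRUE)) {
    s <- sub("^\\[[^]]+\\]-", "", s)
    mods <- rbind(mods, data.frame(position = 1L, name = "pyroGlu",
                                   massDelta = specs$massDelta[specs$name == "pyroGlu"]))
  }
  repeat {
    m <- regexpr("\\[[^]]+\\]", s)
    if (m < 0) break
    tag <- substr(s, m + 1L, m + attr(m, "match.length") - 2L)
    hit <- which(tolower(specs$tag) == tolower(tag))
    if (!length(hit)) stop("unknown modification tag: ", tag)
    pos <- as.integer(m) - 1L
    if (pos < 1L) stop("modification tag with no preceding residue: ", tag)
    mods <- rbind(mods, data.frame(position = pos, name = specs$name[hit],
                                   massDelta = specs$massDelta[hit]))
    s <- paste0(substr(s, 1L, m - 1L),
                substr(s, m + attr(m, "match.length"), nchar(s)))
  }
  s <- toupper(s)
  checkResidues(s)
  for (i in seq_len(nrow(mods))) {
    spec <- specs[specs$name == mods$name[i], ]
    res <- substr(s, mods$position[i], mods$position[i])
    if (res != spec$site)
      stop(sprintf("modification %s requires %s at position %d, found %s",
                   mods$name[i], spec$site, mods$position[i], res))
    if (spec$nTermOnly && mods$position[i] != 1L)
      stop(mods$name[i], " is N-terminal only")
  }
  list(sequence = s, modifications = mods)
}

checkResidues <- function(sequence) {
  res <- strsplit(sequence, "")[[1L]]
  if (!length(res)) stop("empty peptide sequence")
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad))
    stop("unknown amino-acid residue(s): ", paste(unique(bad), collapse = ", "))
  invisible(res)
}

modDeltaSum <- function(mods, positions = NULL) {
  if (is.null(mods) || nrow(mods) == 0L) return(0)
  if (is.null(positions)) sum(mods$massDelta)
  else sum(mods$massDelta[mods$position %in% positions])
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (18.010565 Da) plus
#' any modification deltas.
#'
#' @param peptide plain sequence, or bracketed modified sequence understood
#'   by [parseModifiedPeptide()].
#' @return mass in Da.
#' @examples
#' monoisotopicMass("G")          # 75.032029
#' monoisotopicMass("QIQVSWLR")   # 1028.5767
#' @export
monoisotopicMass <- function(peptide) {
  p <- parseModifiedPeptide(peptide)
  res <- checkResidues(p$sequence)
  sum(AA_MONO[res]) + MASS_WATER + modDeltaSum(p$modifications)
}

#' Precursor m/z of a (modified) peptide
#'
#' \eqn{(M + z \cdot 1.007276)/z}.
#'
#' @inheritParams monoisotopicMass
#' @param charge positive integer precursor charge.
#' @return m/z.
#' @examples
#' precursorMz("AAAITSDILEALGR", 2)  # 700.8908
#' @export
precursorMz <- function(peptide, charge) {
  if (length(charge) != 1L || charge < 1L || charge != round(charge))
    stop("charge must be a positive integer")
  (monoisotopicMass(peptide) + charge * MASS_PROTON) / charge
}

#' y- and b-fragment m/z of a (modified) peptide
#'
#' For fragment index \eqn{k} of an \eqn{n}-residue peptide
#' (\eqn{1 \le k \le n-1}): the y ion carries the \eqn{k} C-terminal
#' residues plus water, the b ion the \eqn{k} N-terminal residues;
#' modifications travel with their residue. Singly and multiply charged
#' fragments follow the usual \eqn{(m + z\,p)/z} rule.
#'
#' @inheritParams precursorMz
#' @param series \code{"y"} or \code{"b"}.
#' @param index fragment index, 1 to peptide length - 1.
#' @return m/z.
#' @examples
#' fragmentMz("QIQVSWLR", "y", 6)  # 788.4413
#' @export
fragmentMz <- function(peptide, series = c("y", "b"), index, charge = 1L) {
  series <- match.arg(series)
  if (length(charge) != 1L || charge < 1L || charge != round(charge))
    stop("charge must be a positive integer")
  p <- parseModifiedPeptide(peptide)
  res <- checkResidues(p$sequence)
  n <- length(res)
  if (index < 1L || index > n - 1L)
    stop(sprintf("fragment index %d out of range 1..%d", index, n - 1L))
  pos <- if (series == "y") seq.int(n - index + 1L, n) else seq_len(index)
  m <- sum(AA_MONO[res[pos]]) + modDeltaSum(p$modifications, pos) +
    if (series == "y") MASS_WATER else 0
  (m + charge * MASS_PROTON) / charge
}

#' Build the 17-peptide targeted transition panel
#'
#' Emits the packaged transition list covering the eight signature proteins
#' with 17 proteotypic peptides (including the pyro-glutamate, oxidized and
#' deamidated variant forms) and their three most intense fragment ions,
#' recomputing every precursor and fragment m/z from the residue masses and
#' checking agreement with the distributed (library-observed) values within
#' \code{tolerance}.
#'
#' @param tolerance largest tolerated |computed - distributed| m/z
#'   (default 0.001; the distributed values are library-observed and may
#'   differ from theory in the fourth decimal).
#' @return data.frame with one row per transition: \code{protein},
#'   \code{modified_sequence}, \code{rt_min}, \code{precursor_charge},
#'   \code{precursor_mz} (computed), \code{fragment_series},
#'   \code{fragment_index}, \code{fragment_charge}, \code{fragment_mz}
#'   (computed), plus the distributed \code{precursor_mz_library} and
#'   \code{fragment_mz_library}.
#' @examples
#' panel <- buildSignaturePanel()
#' length(unique(panel$modified_sequence))  # 17
#' @export
buildSignaturePanel <- function(tolerance = 0.001) {
  path <- system.file("extdata", "coo_transition_panel.tsv",
                      package = "zeroSumCOO", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$precursor_mz <- vapply(seq_len(nrow(tab)), function(i)
    precursorMz(tab$modified_sequence[i], tab$precursor_charge[i]), 0)
  tab$fragment_mz <- vapply(seq_len(nrow(tab)), function(i)
    fragmentMz(tab$modified_sequence[i], tab$fragment_series[i],
               tab$fragment_index[i], tab$fragment_charge[i]), 0)
  dPre <- abs(tab$precursor_mz - tab$precursor_mz_library)
  dFrag <- abs(tab$fragment_mz - tab$fragment_mz_library)
  if (any(dPre > tolerance) || any(dFrag > tolerance)) {
    bad <- tab$modified_sequence[dPre > tolerance | dFrag > tolerance]
    stop("computed m/z deviates from the distributed panel beyond ",
         tolerance, " for: ", paste(unique(bad), collapse = ", "))
  }
  tab
}

#' Export a transition list as CSV
#'
#' @param panel data.frame as returned by [buildSignaturePanel()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTransitionList <- function(panel, path) {
  cols <- c("protein", "modified_sequence", "precursor_mz",
            "precursor_charge", "fragment_series", "fragment_index",
            "fragment_charge", "fragment_mz", "rt_min")
  utils::write.csv(panel[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
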