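#' @import methods
NULL

.AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

#' CaModel: an ordered C-alpha trace
#'
#' One structural model reduced to its C-alpha atoms: residue numbers,
#' one-letter amino-acid codes and Cartesian coordinates in Angstrom.
#' Residue numbers index positions on the target sequence (1-based),
#' so a model may omit unmodeled positions but numbers must be strictly
#' increasing.
#'
#' @slot modelId short label for the model.
#' @slot resno integer vector of residue numbers, strictly increasing.
#' @slot aa character vector of one-letter amino-acid codes (20 standard
#'   letters plus "X").
#' @slot xyz numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).
#' @slot sourcePath provenance string (file of origin, or NA).
#'
#' @exportClass CaModel
setClass("CaModel",
  representation(modelId = "character", resno = "integer",
                 aa = "character", xyz = "matrix", sourcePath = "character"),
  prototype(modelId = NA_character_, sourcePath = NA_character_))

setValidity("CaModel", function(object) {
  n <- length(object@resno)
  if (n < 1L) return("model must contain at least one residue")
  if (length(object@aa) != n) return("aa and resno lengths differ")
  if (!is.numeric(object@xyz) || nrow(object@xyz) != n || ncol(object@xyz) != 3L)
    return("xyz must be an n x 3 numeric matrix")
  if (any(!is.finite(object@xyz))) return("coordinates must be finite")
  if (n > 1L && any(diff(object@resno) <= 0L))
    return("residue numbers must be strictly increasing")
  if (!all(object@aa %in% .AA_LETTERS))
    return(sprintf("unknown amino-acid code(s): %s",
                   paste(setdiff(object@aa, .AA_LETTERS), collapse = ", ")))
  TRUE
})

#' @rdname CaModel-class
#' @param modelId,resno,aa,xyz,sourcePath see the corresponding slots.
#' @return a validated \code{CaModel}.
#' @export
CaModel <- function(modelId, resno, aa, xyz, sourcePath = NA_character_) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  new("CaModel", modelId = as.character(modelId), resno = as.integer(resno),
      aa = toupper(as.character(aa)), xyz = xyz,
      sourcePath = as.character(sourcePath))
}

#' ModelEnsemble: a set of comparable models
#'
#' Holds n >= 2 \code{CaModel}s built for the same target: all members must
#' share residue count, residue numbering and amino-acid sequence. Ensemble
#' heterogeneity is undefined for a single model, hence the hard minimum
#' of two.
#'
#' @slot models list of \code{CaModel}.
#' @exportClass ModelEnsemble
setClass("ModelEnsemble", representation(models = "list"))

setValidity("ModelEnsemble", function(object) {
  ms <- object@models
  if (length(ms) < 2L)
    return("an ensemble needs at least 2 models; heterogeneity cannot be computed on a singular model")
  if (!all(vapply(ms, is, logical(1), "CaModel")))
    return("all members must be CaModel objects")
  ref <- ms[[1L]]
  for (i in seq_along(ms)[-1L]) {
    m <- ms[[i]]
    if (length(m@resno) != length(ref@resno))
      return(sprintf("residue count mismatch between '%s' (%d) and '%s' (%d)",
                     ref@sourcePath, length(ref@resno), m@sourcePath,
                     length(m@resno)))
    if (!identical(m@aa, ref@aa) || !identical(m@resno, ref@resno))
      return(sprintf("sequence/numbering mismatch between '%s' and '%s'",
                     ref@sourcePath, m@sourcePath))
  }
  TRUE
})

#' @rdname ModelEnsemble-class
#' @param models list of \code{CaModel}, all of identical length and sequence.
#' @return a validated \code{ModelEnsemble}.
#' @export
ModelEnsemble <- function(models) new("ModelEnsemble", models = models)

#' PairAlignment: a gapped target-template pairwise alignment
#'
#' Two rows of equal gapped length N; the gap character is "-". No column
#' may be gapped in both rows.
#'
#' @slot target gapped target sequence (single string, uppercase).
#' @slot template gapped template sequence (single string, uppercase).
#' @exportClass PairAlignment
setClass("PairAlignment",
  representation(target = "character", template = "character"))

setValidity("PairAlignment", function(object) {
  tg <- object@target; tp <- object@template
  if (length(tg) != 1L || length(tp) != 1L) return("rows must be single strings")
  if (nchar(tg) != nchar(tp))
    return(sprintf("row lengths differ: target %d vs template %d",
                   nchar(tg), nchar(tp)))
  if (nchar(tg) < 1L) return("alignment must have length >= 1")
  a <- strsplit(tg, "")[[1]]; b <- strsplit(tp, "")[[1]]
  if (any(a == "-" & b == "-")) return("alignment contains an all-gap column")
  TRUE
})

#' @rdname PairAlignment-class
#' @param target,template gapped rows of equal length; "." is normalised
#'   to "-" and letters are uppercased.
#' @return a validated \code{PairAlignment}.
#' @export
PairAlignment <- function(target, template) {
  norm <- function(s) gsub(".", "-", toupper(s), fixed = TRUE)
  new("PairAlignment", target = norm(target), template = norm(template))
}

#' SsTrack: a per-residue secondary-structure track
#'
#' Either a 3-state prediction with per-residue 0-9 confidences (PSIPRED
#' style) or a 3-state assignment (STRIDE style, confidences absent).
#' Tracks are ungapped and indexed on their own sequence (target for
#' predictions, template for assignments); projection onto alignment
#' columns happens in \code{\link{projectTracks}}.
#'
#' @slot states character vector over {H, E, C}.
#' @slot conf integer vector of confidences 0-9 (all NA on assignment tracks).
#' @slot kind "prediction" or "assignment".
#' @exportClass SsTrack
setClass("SsTrack",
  representation(states = "character", conf = "integer", kind = "character"))

setValidity("SsTrack", function(object) {
  if (!object@kind %in% c("prediction", "assignment"))
    return("kind must be 'prediction' or 'assignment'")
  if (length(object@states) != length(object@conf))
    return("states and conf lengths differ")
  if (!all(object@states %in% c("H", "E", "C")))
    return("states must be in {H, E, C}")
  if (object@kind == "prediction") {
    if (any(is.na(object@conf)) ||
        any(object@conf < 0L | object@conf > 9L))
      return("prediction confidences must be integers in [0, 9]")
  } else if (!all(is.na(object@conf))) {
    return("assignment tracks carry no confidences")
  }
  TRUE
})

#' @rdname SsTrack-class
#' @param states,conf,kind see the corresponding slots; \code{conf} may be
#'   omitted for assignment tracks.
#' @return a validated \code{SsTrack}.
#' @export
SsTrack <- function(states, conf = NULL, kind = c("prediction", "assignment")) {
  kind <- match.arg(kind)
  if (is.null(conf)) conf <- rep(NA_integer_, length(states))
  new("SsTrack", states = toupper(as.character(states)),
      conf = as.integer(conf), kind = kind)
}

#' DomainHit: one Pfam-style domain hit on the target
#'
#' @slot pfamId Pfam accession (or profile name).
#' @slot targetStart,targetEnd 1-based inclusive envelope coordinates on
#'   the target sequence.
#' @slot eValue per-domain independent E-value.
#' @slot referencePaths coordinate-file paths for known structures of this
#'   domain (possibly empty until references are attached).
#' @exportClass DomainHit
setClass("DomainHit",
  representation(pfamId = "character", targetStart = "integer",
                 targetEnd = "integer", eValue = "numeric",
                 referencePaths = "character"))

setValidity("DomainHit", function(object) {
  if (is.na(object@targetStart) || is.na(object@targetEnd))
    return("envelope coordinates must be present")
  if (object@targetStart < 1L) return("envelope start must be >= 1")
  if (object@targetStart > object@targetEnd)
    return(sprintf("envelope start %d > end %d",
                   object@targetStart, object@targetEnd))
  if (is.na(object@eValue) || object@eValue < 0) return("E-value must be >= 0")
  TRUE
})

#' @rdname DomainHit-class
#' @param pfamId,targetStart,targetEnd,eValue,referencePaths see slots.
#' @return a validated \code{DomainHit}.
#' @export
DomainHit <- function(pfamId, targetStart, targetEnd, eValue,
                      referencePaths = character(0)) {
  new("DomainHit", pfamId = as.character(pfamId),
      targetStart = as.integer(targetStart), targetEnd = as.integer(targetEnd),
      eValue = as.numeric(eValue), referencePaths = as.character(referencePaths))
}

#' Superposition: a rigid-body fit of one trace onto another
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 numeric vector (Angstrom); the fit maps a
#'   mobile point x to \code{rotation \%*\% x + translation}.
#' @slot rmsd root-mean-square deviation after the fit (Angstrom).
#' @slot degenerate TRUE when the mobile points are (near-)collinear, in
#'   which case the rotation about the common axis is arbitrary but the
#'   RMSD is still the minimum.
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", degenerate = "logical"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' AverageModel: the consensus structure of an ensemble
#'
#' A \code{CaModel} whose coordinates are per-residue means over the
#' ensemble members after iterative superposition onto the evolving
#' consensus.
#'
#' @slot convergenceIterations number of superpose-and-mean iterations run.
#' @slot converged TRUE iff the last iteration moved the consensus by less
#'   than the tolerance.
#' @exportClass AverageModel
setClass("AverageModel", contains = "CaModel",
  representation(convergenceIterations = "integer", converged = "logical"))

#' HFactorReport: the four sub-scores and the composite percentage
#'
#' @slot score1,score2,score3 sub-scores on the 0-10 scale (0 = good).
#' @slot score4 sub-score on the 0-10 scale, or NA when no usable domain
#'   reference was found (in which case the composite averages 3 scores).
#' @slot hFactorPercent composite quality percentage in [0, 100]:
#'   10 x mean of the present sub-scores.
#' @slot diagnostics named list of per-score diagnostics (mismatch counts,
#'   identity fraction, mean cRMS, per-domain cRMS lists, skip reasons).
#' @exportClass HFactorReport
setClass("HFactorReport",
  representation(score1 = "numeric", score2 = "numeric", score3 = "numeric",
                 score4 = "numeric", hFactorPercent = "numeric",
                 diagnostics = "list"))

setValidity("HFactorReport", function(object) {
  s <- c(object@score1, object@score2, object@score3, object@score4)
  present <- s[!is.na(s)]
  if (any(is.na(s[1:3]))) return("scores 1-3 must be present")
  if (any(present < 0 | present > 10)) return("scores must lie in [0, 10]")
  expect <- 10 * mean(present)
  if (abs(object@hFactorPercent - expect) > 1e-9)
    return("hFactorPercent must equal 10 x mean of the present scores")
  TRUE
})

#' @rdname HFactorReport-class
#' @param score1,score2,score3,score4 sub-scores; \code{score4} may be NA.
#' @param diagnostics named list of per-score diagnostics.
#' @return a validated \code{HFactorReport}.
#' @export
HFactorReport <- function(score1, score2, score3, score4 = NA_real_,
                          diagnostics = list()) {
  s <- c(score1, score2, score3, score4)
  new("HFactorReport", score1 = as.numeric(score1),
      score2 = as.numeric(score2), score3 = as.numeric(score3),
      score4 = as.numeric(score4),
      hFactorPercent = 10 * mean(s[!is.na(s)]),
      diagnostics = diagnostics)
}

#' ScoreConstants: the affine calibration constants of the four sub-scores
#'
#' Each raw quantity (mean penalty, mean cRMS) is mapped to the 0-10 scale
#' by \code{a * x + b} and clipped to \code{[clipLo, clipHi]}. The defaults
#' are the published calibration: a1 = 1.3, b1 = 0.9 for the
#' secondary-structure score; a = 1.3, b = 0.87 for the two cRMS-based
#' scores, placing mean cRMS values of 0.1 and 7 Angstrom at scores of
#' 1 and 10.
#'
#' @slot a1,b1 affine constants for the secondary-structure score.
#' @slot a3,b3 affine constants for the ensemble-heterogeneity score.
#' @slot a4,b4 affine constants for the domain-integrity score.
#' @slot clipLo,clipHi clip bounds applied after each affine map.
#' @exportClass ScoreConstants
setClass("ScoreConstants",
  representation(a1 = "numeric", b1 = "numeric", a3 = "numeric",
                 b3 = "numeric", a4 = "numeric", b4 = "numeric",
                 clipLo = "numeric", clipHi = "numeric"))

#' @rdname ScoreConstants-class
#' @param a1,b1,a3,b3,a4,b4,clipLo,clipHi overrides for the published
#'   defaults; any override triggers a warning, since the 0-10 scale of the
#'   sub-scores (and hence the percentage scale of the composite) depends
#'   on the published calibration.
#' @return a validated \code{ScoreConstants}.
#' @export
scoreConstants <- function(a1 = 1.3, b1 = 0.9, a3 = 1.3, b3 = 0.87,
                           a4 = 1.3, b4 = 0.87, clipLo = 0, clipHi = 10) {
  defaults <- c(a1 = 1.3, b1 = 0.9, a3 = 1.3, b3 = 0.87, a4 = 1.3, b4 = 0.87,
                clipLo = 0, clipHi = 10)
  given <- c(a1 = a1, b1 = b1, a3 = a3, b3 = b3, a4 = a4, b4 = b4,
             clipLo = clipLo, clipHi = clipHi)
  if (any(given != defaults))
    warning("overriding published score constants (",
            paste(names(given)[given != defaults], collapse = ", "),
            "); scores are no longer on the calibrated 0-10 scale",
            call. = FALSE)
  new("ScoreConstants", a1 = a1, b1 = b1, a3 = a3, b3 = b3, a4 = a4, b4 = b4,
      clipLo = clipLo, clipHi = clipHi)
}
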