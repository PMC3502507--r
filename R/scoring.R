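#' Project secondary-structure tracks onto alignment columns
#'
#' Walks the alignment once: the (ungapped, target-indexed) prediction
#' advances only on non-gap target columns and the (ungapped,
#' template-indexed) assignment only on non-gap template columns, so every
#' input symbol is consumed exactly once. Gap columns carry NA on the
#' gapped side.
#'
#' @param alignment a \code{\link{PairAlignment}}.
#' @param prediction an \code{\link{SsTrack}} of kind "prediction", one
#'   entry per ungapped target residue.
#' @param assignment an \code{\link{SsTrack}} of kind "assignment", one
#'   entry per ungapped template residue.
#' @return a data.frame with one row per alignment column and columns
#'   \code{column} (1-based index), \code{target}, \code{template}
#'   (characters), \code{pred}, \code{conf} (NA on target gaps) and
#'   \code{assign} (NA on template gaps).
#' @export
projectTracks <- function(alignment, prediction, assignment) {
  tg <- .chars(alignment@target)
  tp <- .chars(alignment@template)
  nTarget <- sum(tg != "-")
  nTemplate <- sum(tp != "-")
  if (length(prediction@states) != nTarget)
    .inputError("prediction length ", length(prediction@states),
                " does not match ungapped target length ", nTarget)
  if (length(assignment@states) != nTemplate)
    .inputError("assignment length ", length(assignment@states),
                " does not match ungapped template length ", nTemplate)
  p <- s <- rep(NA_character_, length(tg))
  cc <- rep(NA_integer_, length(tg))
  p[tg != "-"] <- prediction@states
  cc[tg != "-"] <- prediction@conf
  s[tp != "-"] <- assignment@states
  data.frame(column = seq_along(tg), target = tg, template = tp,
             pred = p, conf = cc, assign = s, stringsAsFactors = FALSE)
}

#' Secondary-structure agreement score (score 1)
#'
#' Per alignment column, the penalty f is 0 when the predicted state of
#' the target equals the assigned state of the template; c + 1 (where c is
#' the 0-9 prediction confidence) when they differ, so that confidently
#' wrong predictions are penalised up to 10; and 1 when either row of the
#' column is a gap. The score is \code{a1 * mean(f) + b1} clipped to
#' [0, 10]; with the published constants a perfect match scores 0.9 and an
#' all-gap-penalty alignment 2.2.
#'
#' @param columns projected columns from \code{\link{projectTracks}}.
#' @param constants a \code{\link{ScoreConstants}}.
#' @param mismatchPenalty "confidence" (the default reading: f = c + 1 on
#'   mismatches) or "scaled" (f = (c + 1) / 10, retained only for
#'   sensitivity checks; it compresses the score range).
#' @return the score, with diagnostic counts (\code{nMatch},
#'   \code{nMismatch}, \code{nGap}, \code{meanPenalty}) as attributes.
#' @export
ssAgreementScore <- function(columns, constants = scoreConstants(),
                             mismatchPenalty = c("confidence", "scaled")) {
  mismatchPenalty <- match.arg(mismatchPenalty)
  gap <- columns$target == "-" | columns$template == "-"
  both <- !gap & !is.na(columns$pred) & !is.na(columns$assign)
  match_ <- both & columns$pred == columns$assign
  mismatch <- both & !match_
  f <- numeric(nrow(columns))
  f[gap] <- 1
  pen <- columns$conf[mismatch] + 1
  if (mismatchPenalty == "scaled") pen <- pen / 10
  f[mismatch] <- pen
  score <- .clip(constants@a1 * mean(f) + constants@b1,
                 constants@clipLo, constants@clipHi)
  structure(score, nMatch = sum(match_), nMismatch = sum(mismatch),
            nGap = sum(gap), meanPenalty = mean(f))
}

#' Target-template identity score (score 2)
#'
#' Scores the sequence identity over the full alignment: a column counts
#' as an identity iff the target and template characters are equal and
#' neither is a gap; the score is \code{10 * (1 - identities / N)} with N
#' the full alignment length including gap columns. 0 means identical
#' sequences, 10 means no identical column.
#'
#' @param alignment a \code{\link{PairAlignment}}.
#' @return the score, with \code{identityFraction} and \code{nIdentical}
#'   as attributes.
#' @export
alignmentIdentityScore <- function(alignment) {
  a <- .chars(alignment@target)
  b <- .chars(alignment@template)
  g <- a == b & a != "-"
  frac <- sum(g) / length(a)
  structure(10 * (1 - frac), identityFraction = frac, nIdentical = sum(g))
}

#' Ensemble heterogeneity score (score 3)
#'
#' Builds the average model MA of the ensemble, computes the mean cRMS r
#' of the members to MA, and maps it to the 0-10 scale as
#' \code{a3 * r + b3} clipped to [0, 10]. The published constants place
#' mean cRMS values of 0.1 and 7 Angstrom at scores of 1 and 10; an
#' ensemble of identical models scores 0.87.
#'
#' @param ensemble a \code{\link{ModelEnsemble}} (n >= 2 members).
#' @param constants a \code{\link{ScoreConstants}}.
#' @param ma optionally a precomputed \code{\link{AverageModel}}.
#' @return the score, with \code{meanCrms}, \code{perModelCrms} and
#'   \code{converged} as attributes.
#' @export
ensembleHeterogeneityScore <- function(ensemble, constants = scoreConstants(),
                                       ma = averageModel(ensemble)) {
  r <- meanEnsembleCrms(ensemble, ma)
  score <- .clip(constants@a3 * as.numeric(r) + constants@b3,
                 constants@clipLo, constants@clipHi)
  structure(score, meanCrms = as.numeric(r),
            perModelCrms = attr(r, "perModel"), converged = ma@converged)
}

#' Extract the average-model fragment of a domain hit
#'
#' Slices the average model at the target positions covered by the hit
#' envelope (residue numbers are 1-based target positions). Envelope
#' positions absent from the model (unmodeled) are dropped and counted; an
#' envelope with no modeled position yields NULL (a skip signal, not an
#' error).
#'
#' @param ma an \code{\link{AverageModel}} (or any \code{\link{CaModel}}).
#' @param hit a \code{\link{DomainHit}}.
#' @param alignment optional \code{\link{PairAlignment}} used to check the
#'   envelope against the ungapped target length.
#' @return a \code{\link{CaModel}} with attribute \code{droppedCount}, or
#'   NULL when the envelope is entirely unmodeled.
#' @export
extractFragment <- function(ma, hit, alignment = NULL) {
  if (!is.null(alignment)) {
    nTarget <- nchar(ungappedRow(alignment, "target"))
    if (hit@targetEnd > nTarget)
      .inputError("domain envelope ", hit@targetStart, "-", hit@targetEnd,
                  " exceeds target length ", nTarget)
  }
  sel <- ma@resno >= hit@targetStart & ma@resno <= hit@targetEnd
  dropped <- (hit@targetEnd - hit@targetStart + 1L) - sum(sel)
  if (!any(sel)) return(NULL)
  frag <- new("CaModel",
              modelId = paste0(ma@modelId, ":", hit@pfamId),
              resno = ma@resno[sel], aa = ma@aa[sel],
              xyz = ma@xyz[sel, , drop = FALSE],
              sourcePath = ma@sourcePath)
  structure(frag, droppedCount = dropped)
}

#' Residue correspondence between a fragment and a reference structure
#'
#' The cRMS between a domain fragment and a reference structure of
#' generally different length needs a residue pairing first. A global
#' (Needleman-Wunsch) alignment of the two amino-acid sequences is
#' computed with BLOSUM62 substitution scores, gap opening 10 and gap
#' extension 0.5; the aligned non-gap pairs define the correspondence. At
#' least 3 pairs are required; otherwise NULL is returned as a skip signal
#' for this reference.
#'
#' @param fragment,reference \code{\link{CaModel}}s of length >= 3.
#' @param gapOpening,gapExtension global-alignment gap penalties.
#' @return a 2-column integer matrix of (fragment index, reference index)
#'   pairs, or NULL when fewer than 3 residues align.
#' @export
correspondFragment <- function(fragment, reference,
                               gapOpening = 10, gapExtension = 0.5) {
  if (nResidues(fragment) < 3L || nResidues(reference) < 3L)
    .scoringError("correspondence requires at least 3 residues on each side")
  blosum <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(fragment@aa, collapse = "")),
    Biostrings::AAString(paste(reference@aa, collapse = "")),
    type = "global", substitutionMatrix = blosum,
    gapOpening = gapOpening, gapExtension = gapExtension)
  fr <- .chars(as.character(Biostrings::alignedPattern(pa)[[1L]]))
  rf <- .chars(as.character(Biostrings::alignedSubject(pa)[[1L]]))
  iF <- cumsum(fr != "-")
  iR <- cumsum(rf != "-")
  keep <- fr != "-" & rf != "-"
  pairs <- cbind(fragment = iF[keep], reference = iR[keep])
  if (nrow(pairs) < 3L) return(NULL)
  pairs
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$mat <- e$BLOSUM62
  }
  .blosum62_cache$mat
}

#' Domain structural-integrity score (score 4)
#'
#' For each domain hit, the corresponding fragment of the average model is
#' compared (cRMS over matched C-alpha pairs) with every reference
#' structure known for that domain. The grand mean over all
#' (domain, reference) pairs is mapped to the 0-10 scale as
#' \code{a4 * mean + b4} clipped to [0, 10]. Fragments without a usable
#' reference (no references, unmodeled envelope, or fewer than 3 aligned
#' residues) are skipped with a recorded reason; when every fragment is
#' skipped the score is absent (NA) and the composite averages the other
#' three scores.
#'
#' @param ma the \code{\link{AverageModel}} of the ensemble.
#' @param hits list of \code{\link{DomainHit}} (already filtered and
#'   capped by \code{\link{readDomainHits}}).
#' @param references named list (by pfamId) of lists of reference
#'   \code{\link{CaModel}}s; defaults to loading from the hits'
#'   \code{referencePaths}.
#' @param constants a \code{\link{ScoreConstants}}.
#' @param alignment optional \code{\link{PairAlignment}} for envelope
#'   bounds checking.
#' @return the score (NA when no domain is usable), with attributes
#'   \code{grandMeanCrms}, \code{perDomain} (named list of per-reference
#'   cRMS vectors) and \code{skipped} (named character vector of reasons).
#' @export
domainIntegrityScore <- function(ma, hits, references = loadDomainReferences(hits),
                                 constants = scoreConstants(),
                                 alignment = NULL) {
  perDomain <- list()
  skipped <- character(0)
  for (h in hits) {
    id <- h@pfamId
    frag <- extractFragment(ma, h, alignment)
    if (is.null(frag)) {
      skipped[id] <- "envelope entirely unmodeled"
      next
    }
    if (nResidues(frag) < 3L) {
      skipped[id] <- "fewer than 3 modeled residues in envelope"
      next
    }
    refs <- references[[id]]
    if (is.null(refs) || length(refs) == 0L) {
      skipped[id] <- "no reference structure for this domain"
      next
    }
    vals <- numeric(0)
    for (ref in refs) {
      pairs <- correspondFragment(frag, ref)
      if (is.null(pairs)) next
      vals <- c(vals, crms(caCoords(frag)[pairs[, 1L], , drop = FALSE],
                           caCoords(ref)[pairs[, 2L], , drop = FALSE]))
    }
    if (length(vals) == 0L) {
      skipped[id] <- "no reference aligned over >= 3 residues"
      next
    }
    perDomain[[id]] <- vals
  }
  if (length(perDomain) == 0L)
    return(structure(NA_real_, grandMeanCrms = NA_real_,
                     perDomain = perDomain, skipped = skipped))
  # pooled grand mean over all (domain, reference) pairs; identical to the
  # 1/(m n) normalisation when every domain has the same reference count
  all <- unlist(perDomain, use.names = FALSE)
  gm <- mean(all)
  score <- .clip(constants@a4 * gm + constants@b4,
                 constants@clipLo, constants@clipHi)
  structure(score, grandMeanCrms = gm, perDomain = perDomain,
            skipped = skipped)
}

#' Combine sub-scores into the H-factor percentage
#'
#' The composite is 10 times the arithmetic mean of the present sub-scores
#' (the domain score may be absent), giving a percentage in [0, 100] with
#' 0 = good. For display the percentage is rounded half-up to an integer;
#' the raw value is kept in reports.
#'
#' @param score1,score2,score3 sub-scores in [0, 10].
#' @param score4 sub-score in [0, 10], or NA when absent.
#' @return the raw percentage, with the displayed integer as attribute
#'   \code{"display"}.
#' @export
hFactor <- function(score1, score2, score3, score4 = NA_real_) {
  s <- c(score1, score2, score3, score4)
  if (sum(!is.na(s)) < 3L)
    .scoringError("at least 3 sub-scores are required")
  if (any(is.na(s[1:3])))
    .scoringError("scores 1-3 must all be present")
  present <- s[!is.na(s)]
  if (any(present < 0 | present > 10))
    .scoringError("sub-scores must lie in [0, 10]")
  pct <- 10 * mean(present)
  structure(pct, display = .roundHalfUp(pct))
}

#' Score a model ensemble end to end
#'
#' Runs the full pipeline on validated domain objects: project the
#' secondary-structure tracks onto the alignment, compute the four
#' sub-scores, and combine them into the H-factor. Every intermediate
#' diagnostic (column counts, identity fraction, mean cRMS, per-domain
#' cRMS lists, skip reasons) is carried in the report.
#'
#' @param ensemble a \code{\link{ModelEnsemble}}.
#' @param alignment a \code{\link{PairAlignment}}.
#' @param prediction target \code{\link{SsTrack}} (kind "prediction").
#' @param assignment template \code{\link{SsTrack}} (kind "assignment").
#' @param hits optional list of \code{\link{DomainHit}}; when empty the
#'   domain score is absent.
#' @param references named list of reference models per pfamId; defaults
#'   to loading from the hits' \code{referencePaths}.
#' @param constants a \code{\link{ScoreConstants}}.
#' @return an \code{\link{HFactorReport}}.
#' @export
evaluateHFactor <- function(ensemble, alignment, prediction, assignment,
                            hits = list(),
                            references = loadDomainReferences(hits),
                            constants = scoreConstants()) {
  stopifnot(is(ensemble, "ModelEnsemble"), is(alignment, "PairAlignment"),
            is(prediction, "SsTrack"), is(assignment, "SsTrack"))
  validObject(ensemble)
  columns <- projectTracks(alignment, prediction, assignment)
  s1 <- ssAgreementScore(columns, constants)
  s2 <- alignmentIdentityScore(alignment)
  ma <- averageModel(ensemble)
  s3 <- ensembleHeterogeneityScore(ensemble, constants, ma = ma)
  s4 <- if (length(hits) > 0L)
    domainIntegrityScore(ma, hits, references, constants, alignment)
  else structure(NA_real_, grandMeanCrms = NA_real_, perDomain = list(),
                 skipped = character(0))
  diag <- list(
    ss = list(nMatch = attr(s1, "nMatch"), nMismatch = attr(s1, "nMismatch"),
              nGap = attr(s1, "nGap"), meanPenalty = attr(s1, "meanPenalty")),
    identity = list(fraction = attr(s2, "identityFraction"),
                    nIdentical = attr(s2, "nIdentical"),
                    alignmentLength = alignmentLength(alignment)),
    heterogeneity = list(meanCrms = attr(s3, "meanCrms"),
                         perModelCrms = as.numeric(attr(s3, "perModelCrms")),
                         nModels = nModels(ensemble),
                         converged = attr(s3, "converged"),
                         iterations = ma@convergenceIterations),
    domains = list(perDomainCrms = attr(s4, "perDomain"),
                   grandMeanCrms = attr(s4, "grandMeanCrms"),
                   skipped = as.list(attr(s4, "skipped"))))
  HFactorReport(score1 = as.numeric(s1), score2 = as.numeric(s2),
                score3 = as.numeric(s3), score4 = as.numeric(s4),
                diagnostics = diag)
}
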