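# Kabsch superposition on raw n x 3 coordinate matrices. Returns the
# proper rotation R (column-vector convention: y = R x + t) and the
# minimum RMSD. The reflection case is resolved by flipping the sign of
# the smallest singular direction, so det(R) = +1 always, including for
# mirror-image inputs.
.kabsch <- function(P, Q) {
  n <- nrow(P)
  muP <- colMeans(P); muQ <- colMeans(Q)
  Pc <- sweep(P, 2L, muP); Qc <- sweep(Q, 2L, muQ)
  C <- crossprod(Pc, Qc)                     # t(Pc) %*% Qc
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  # optimal rotation in row-vector convention: rotated rows = Pc %*% Rr
  Rr <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  resid <- Pc %*% Rr - Qc
  rmsd <- sqrt(sum(resid^2) / n)
  R <- t(Rr)
  degenerate <- sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)
  list(rotation = R, translation = as.numeric(muQ - R %*% muP),
       rmsd = rmsd, degenerate = degenerate,
       fitted = sweep(Pc %*% Rr, 2L, muQ, "+"))
}

.coordsOf <- function(x) if (is.matrix(x)) x else caCoords(x)

.checkPair <- function(a, b) {
  A <- .coordsOf(a); B <- .coordsOf(b)
  if (nrow(A) != nrow(B))
    .scoringError("length mismatch: ", nrow(A), " vs ", nrow(B), " residues")
  if (nrow(A) < 3L)
    .scoringError("superposition needs at least 3 residues")
  list(A = A, B = B)
}

#' Optimal rigid-body superposition of two C-alpha traces
#'
#' Least-squares proper rotation and translation (Kabsch algorithm)
#' minimising the RMSD of \code{mobile} onto \code{reference}, with the
#' reflection branch excluded. Collinear inputs are flagged degenerate
#' (the rotation about the common axis is arbitrary) but still yield the
#' minimum RMSD.
#'
#' @param mobile,reference \code{\link{CaModel}}s (or n x 3 coordinate
#'   matrices) of equal length >= 3.
#' @return a \code{\link{Superposition}}.
#' @export
superpose <- function(mobile, reference) {
  p <- .checkPair(mobile, reference)
  k <- .kabsch(p$A, p$B)
  if (k$degenerate)
    warning("degenerate (collinear) input: rotation is not unique",
            call. = FALSE)
  new("Superposition", rotation = k$rotation, translation = k$translation,
      rmsd = k$rmsd, degenerate = k$degenerate)
}

#' Coordinate RMSD after optimal superposition (cRMS)
#'
#' The RMSD between two equal-length C-alpha traces after least-squares
#' rigid-body superposition; computed over all residues of the trace with
#' no trimming. Symmetric in its arguments.
#'
#' @param a,b \code{\link{CaModel}}s (or n x 3 coordinate matrices) of
#'   equal length >= 3.
#' @return the cRMS in Angstrom.
#' @export
crms <- function(a, b) {
  p <- .checkPair(a, b)
  .kabsch(p$A, p$B)$rmsd
}

#' Iterative average model of an ensemble
#'
#' The consensus structure whose coordinates are per-residue means over
#' the superposed members. Because a plain coordinate mean depends on the
#' frame each model sits in, the average is defined iteratively: seed the
#' consensus with model 1, superpose every member onto it, re-average, and
#' repeat until the consensus moves by less than \code{tolerance} (plain
#' RMSD between successive consensus coordinate sets) or \code{maxIter}
#' iterations. Non-convergence is reported via the \code{converged} flag,
#' not an error.
#'
#' @param ensemble a \code{\link{ModelEnsemble}}.
#' @param tolerance convergence tolerance in Angstrom (default 1e-6).
#' @param maxIter iteration cap (default 50).
#' @return an \code{\link{AverageModel}}.
#' @export
averageModel <- function(ensemble, tolerance = 1e-6, maxIter = 50L) {
  stopifnot(is(ensemble, "ModelEnsemble"))
  validObject(ensemble)
  ms <- ensemble@models
  coords <- lapply(ms, caCoords)
  ma <- coords[[1L]]
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    fitted <- lapply(coords, function(P) .kabsch(P, ma)$fitted)
    newMa <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(sum((newMa - ma)^2) / nrow(ma))
    ma <- newMa
    if (shift < tolerance) { converged <- TRUE; break }
  }
  proto <- ms[[1L]]
  dimnames(ma) <- list(NULL, c("x", "y", "z"))
  new("AverageModel", modelId = "average", resno = proto@resno,
      aa = proto@aa, xyz = ma, sourcePath = NA_character_,
      convergenceIterations = iter, converged = converged)
}

#' Mean cRMS of ensemble members to the average model
#'
#' Arithmetic mean of \code{crms(M_i, MA)} over all members; the raw
#' heterogeneity measure behind the ensemble-heterogeneity score.
#'
#' @param ensemble a \code{\link{ModelEnsemble}}.
#' @param ma the \code{\link{AverageModel}} built from it (computed if
#'   missing).
#' @return the mean cRMS in Angstrom, with the per-member cRMS values as
#'   attribute \code{"perModel"}.
#' @export
meanEnsembleCrms <- function(ensemble, ma = averageModel(ensemble)) {
  per <- vapply(ensemble@models, crms, numeric(1), b = ma)
  structure(mean(per), perModel = per)
}
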