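# Deterministic synthetic inputs: every knob targets exactly one
# sub-score, and counts are exact by construction (round(fraction * n)
# positions are altered, rather than i.i.d. flips), so fixture sub-scores
# are exact rather than approximate.

#' Ideal alpha-helical C-alpha trace
#'
#' A deterministic helix with radius 2.3 Angstrom, rise 1.5 Angstrom per
#' residue and 100 degrees of twist per residue. Biological realism is not
#' the goal; the fixed geometry makes consecutive C-alpha distances exactly
#' equal, which tests exploit.
#'
#' @param nRes number of residues (>= 3).
#' @param aa single one-letter code recycled, or a vector of length
#'   \code{nRes}.
#' @return a \code{\link{CaModel}} with residue numbers 1..nRes.
#' @export
generateHelix <- function(nRes, aa = "A") {
  if (nRes < 3L) .inputError("a helix fixture needs at least 3 residues")
  i <- seq_len(nRes) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  aa <- rep_len(toupper(aa), nRes)
  CaModel(modelId = "helix", resno = seq_len(nRes), aa = aa, xyz = xyz,
          sourcePath = NA_character_)
}

#' Gaussian-perturbed model ensemble
#'
#' Each member is the base trace plus i.i.d. Gaussian noise of standard
#' deviation \code{sigma} on every coordinate. The same seed yields
#' byte-identical PDB files.
#'
#' @param base a \code{\link{CaModel}}.
#' @param nModels ensemble size (>= 2).
#' @param sigma per-coordinate noise standard deviation in Angstrom (>= 0).
#' @param seed mandatory RNG seed.
#' @param dir optional directory; when given, members are written as
#'   \code{model_01.pdb} etc. and their paths recorded as source paths.
#' @return a \code{\link{ModelEnsemble}}.
#' @export
perturbEnsemble <- function(base, nModels, sigma, seed, dir = NULL) {
  if (nModels < 2L) .inputError("an ensemble needs at least 2 models")
  if (sigma < 0) .inputError("sigma must be >= 0")
  if (missing(seed)) .inputError("seed is mandatory")
  n <- nResidues(base)
  ms <- withr::with_seed(seed, lapply(seq_len(nModels), function(k) {
    xyz <- caCoords(base) + matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
    CaModel(modelId = sprintf("model_%02d", k), resno = base@resno,
            aa = base@aa, xyz = xyz)
  }))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ms <- lapply(ms, function(m) {
      p <- file.path(dir, paste0(m@modelId, ".pdb"))
      writeCaModel(m, p)
      m@sourcePath <- p
      m
    })
  }
  ModelEnsemble(ms)
}

#' Alignment fixture with an exact identity count
#'
#' A gapless pairwise alignment whose target row is uniformly random over
#' the 20 standard letters and whose template row equals the target on a
#' seeded random subset of exactly \code{round(identityFraction * nRes)}
#' positions and differs everywhere else, so the identity score is exact
#' by construction.
#'
#' @param nRes alignment length.
#' @param identityFraction fraction of identical columns in [0, 1].
#' @param seed mandatory RNG seed.
#' @param path optional aligned-FASTA output path.
#' @return a \code{\link{PairAlignment}}.
#' @export
generateAlignmentFixture <- function(nRes, identityFraction, seed,
                                     path = NULL) {
  if (identityFraction < 0 || identityFraction > 1)
    .inputError("identityFraction must lie in [0, 1]")
  if (missing(seed)) .inputError("seed is mandatory")
  aa20 <- setdiff(.AA_LETTERS, "X")
  out <- withr::with_seed(seed, {
    tg <- sample(aa20, nRes, replace = TRUE)
    tp <- vapply(tg, function(x) sample(setdiff(aa20, x), 1L), character(1))
    k <- round(identityFraction * nRes)
    if (k > 0L) {
      same <- sample.int(nRes, k)
      tp[same] <- tg[same]
    }
    list(tg = tg, tp = tp)
  })
  aln <- PairAlignment(paste(out$tg, collapse = ""),
                       paste(out$tp, collapse = ""))
  if (!is.null(path))
    writeLines(c(">target", aln@target, ">template", aln@template), path)
  aln
}

#' Secondary-structure fixture with an exact mismatch count
#'
#' The assignment follows a deterministic 3-state block pattern (helix,
#' coil, strand blocks); the prediction equals the assignment except on a
#' seeded random subset of exactly \code{round(mismatchFraction * nRes)}
#' positions, where the state is cycled (H to E, E to C, C to H), with a
#' uniform confidence everywhere.
#'
#' @param nRes track length.
#' @param mismatchFraction fraction of disagreeing positions in [0, 1].
#' @param confidenceLevel uniform prediction confidence, integer 0-9.
#' @param seed mandatory RNG seed.
#' @param dir optional directory; when given, the prediction is written as
#'   \code{target.horiz} and the assignment as \code{template.ss} (plain
#'   dialect).
#' @return a list with elements \code{prediction} and \code{assignment}
#'   (both \code{\link{SsTrack}}).
#' @export
generateSsFixture <- function(nRes, mismatchFraction, confidenceLevel, seed,
                              dir = NULL) {
  if (mismatchFraction < 0 || mismatchFraction > 1)
    .inputError("mismatchFraction must lie in [0, 1]")
  if (!confidenceLevel %in% 0:9)
    .inputError("confidenceLevel must be an integer in 0..9")
  if (missing(seed)) .inputError("seed is mandatory")
  pattern <- rep(c(rep("H", 8L), rep("C", 4L), rep("E", 6L), rep("C", 3L)),
                 length.out = nRes)
  cycle <- c(H = "E", E = "C", C = "H")
  k <- round(mismatchFraction * nRes)
  pred <- pattern
  if (k > 0L) {
    flip <- withr::with_seed(seed, sample.int(nRes, k))
    pred[flip] <- cycle[pattern[flip]]
  }
  prediction <- SsTrack(pred, rep(confidenceLevel, nRes), kind = "prediction")
  assignment <- SsTrack(pattern, kind = "assignment")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    .writeHoriz(prediction, file.path(dir, "target.horiz"))
    writeLines(.wrap60(paste(pattern, collapse = "")),
               file.path(dir, "template.ss"))
  }
  list(prediction = prediction, assignment = assignment)
}

.wrap60 <- function(s) {
  starts <- seq(1L, nchar(s), by = 60L)
  vapply(starts, function(i) substr(s, i, min(i + 59L, nchar(s))),
         character(1))
}

.writeHoriz <- function(prediction, path) {
  confStr <- paste(prediction@conf, collapse = "")
  predStr <- paste(prediction@states, collapse = "")
  confW <- .wrap60(confStr)
  predW <- .wrap60(predStr)
  aaW <- .wrap60(strrep("A", nchar(predStr)))
  blocks <- unlist(lapply(seq_along(confW), function(i)
    c(paste0("Conf: ", confW[i]), paste0("Pred: ", predW[i]),
      paste0("  AA: ", aaW[i]), "")))
  writeLines(c("# PSIPRED HFORMAT (synthetic fixture)", "", blocks), path)
  invisible(path)
}

#' Specification of a synthetic input bundle
#'
#' Collects every generator knob in one validated list. Defaults describe
#' a mid-quality scenario: 100 residues, 20 models (a typical ensemble
#' size for homology-model assessment), 0.5 Angstrom coordinate noise, 50
#' percent target-template identity, 20 percent secondary-structure
#' mismatch at confidence 7, and one full-length domain whose reference is
#' the unperturbed base trace. The seed has no default: unseeded
#' randomness is not allowed anywhere.
#'
#' @param nRes,nModels,noiseSigma,identityFraction,ssMismatchFraction,confidenceLevel
#'   generator knobs (see the individual generators).
#' @param withDomains include a domain-hit table and reference structure.
#' @param seed mandatory RNG seed.
#' @return a validated list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(nRes = 100L, nModels = 20L, noiseSigma = 0.5,
                        identityFraction = 0.5, ssMismatchFraction = 0.2,
                        confidenceLevel = 7L, withDomains = TRUE, seed) {
  if (missing(seed)) .inputError("seed is mandatory in a FixtureSpec")
  spec <- list(nRes = as.integer(nRes), nModels = as.integer(nModels),
               noiseSigma = as.numeric(noiseSigma),
               identityFraction = as.numeric(identityFraction),
               ssMismatchFraction = as.numeric(ssMismatchFraction),
               confidenceLevel = as.integer(confidenceLevel),
               withDomains = isTRUE(withDomains), seed = as.integer(seed))
  if (spec$nRes < 3L || spec$nModels < 2L || spec$noiseSigma < 0 ||
      spec$identityFraction < 0 || spec$identityFraction > 1 ||
      spec$ssMismatchFraction < 0 || spec$ssMismatchFraction > 1 ||
      !spec$confidenceLevel %in% 0:9 || is.na(spec$seed))
    .inputError("invalid FixtureSpec")
  class(spec) <- "FixtureSpec"
  spec
}

#' Write a complete, immediately scoreable input bundle
#'
#' Emits models (PDB), an aligned-FASTA alignment, a horiz-dialect
#' prediction, a plain-dialect assignment, optionally a domtblout hit
#' table plus a reference PDB (the unperturbed base trace), and a
#' \code{manifest.yaml} recording the spec. Re-feeding the manifest's spec
#' reproduces the bundle byte for byte.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the bundle's file paths (fields
#'   \code{models}, \code{alignment}, \code{ssPred}, \code{ssTemplate},
#'   \code{domains}, \code{refDir}, \code{manifest}).
#' @export
writeFixtureBundle <- function(spec, outDir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .inputError("cannot create output directory '", outDir, "'")
  }
  aln <- generateAlignmentFixture(spec$nRes, spec$identityFraction,
                                  seed = spec$seed + 1L,
                                  path = file.path(outDir, "alignment.fasta"))
  base <- generateHelix(spec$nRes, aa = .chars(ungappedRow(aln, "target")))
  ens <- perturbEnsemble(base, spec$nModels, spec$noiseSigma,
                         seed = spec$seed + 2L,
                         dir = file.path(outDir, "models"))
  generateSsFixture(spec$nRes, spec$ssMismatchFraction, spec$confidenceLevel,
                    seed = spec$seed + 3L, dir = outDir)
  paths <- list(
    models = vapply(ens@models, sourcePath, character(1)),
    alignment = file.path(outDir, "alignment.fasta"),
    ssPred = file.path(outDir, "target.horiz"),
    ssTemplate = file.path(outDir, "template.ss"),
    domains = NULL, refDir = NULL,
    manifest = file.path(outDir, "manifest.yaml"))
  if (spec$withDomains) {
    refDir <- file.path(outDir, "refs")
    if (!dir.exists(refDir)) dir.create(refDir)
    writeCaModel(base, file.path(refDir, "PF00001_1.pdb"))
    domPath <- file.path(outDir, "domains.domtblout")
    .writeDomtblout(domPath, pfamId = "PF00001", targetName = "target",
                    nRes = spec$nRes, eValue = 1e-50)
    paths$domains <- domPath
    paths$refDir <- refDir
  }
  yaml::write_yaml(list(spec = unclass(spec)), paths$manifest)
  invisible(paths)
}

# one full-length synthetic hit in hmmsearch --domtblout layout
.writeDomtblout <- function(path, pfamId, targetName, nRes, eValue) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  row <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9.1e %6.1f %5.1f %3d %3d %9.1e %9.1e %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    targetName, "-", nRes, pfamId, pfamId, nRes, eValue, 200.0, 0.1,
    1L, 1L, eValue, eValue, 200.0, 0.1,
    1L, nRes, 1L, nRes, 1L, nRes, 0.99, "synthetic fixture domain")
  writeLines(c(header, row), path)
  invisible(path)
}
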