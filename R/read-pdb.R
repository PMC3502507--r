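#' Read a C-alpha trace from a PDB file
#'
#' Extracts one C-alpha atom per residue from the ATOM records of a PDB
#' file. Only the first MODEL of a multi-model file is used (each file is
#' expected to contribute exactly one model); HETATM records are ignored.
#' Alternate locations are resolved by highest occupancy, ties by
#' first-seen order.
#'
#' @param path path to a PDB-format text file.
#' @param chain optional chain identifier; by default the first chain
#'   encountered is used.
#' @param modelId label for the model; defaults to the file name without
#'   extension.
#' @return a \code{\link{CaModel}}.
#' @export
readCaModel <- function(path, chain = NULL, modelId = NULL) {
  .checkFile(path, "PDB")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) .inputError("cannot parse PDB file '", path, "': ",
                                    conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) .inputError("no CA atoms in '", path, "'")

  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- chains[1L]
  } else if (!chain %in% chains) {
    .inputError("chain '", chain, "' not found in '", path,
                "' (available: ", paste(chains, collapse = ", "), ")")
  }
  at <- at[at$chain %in% chain, , drop = FALSE]

  # altloc resolution: highest occupancy wins, ties by first appearance;
  # two CA records without altloc labels for one residue are an error
  occ <- ifelse(is.na(at$o), 1.0, at$o)
  keep <- integer(0)
  for (rn in unique(at$resno)) {
    idx <- which(at$resno == rn)
    if (length(idx) > 1L) {
      alt <- at$alt[idx]
      if (all(is.na(alt) | alt == ""))
        .inputError("duplicate CA record for residue ", rn, " in '", path, "'")
      idx <- idx[order(-occ[idx], seq_along(idx))][1L]
    }
    keep <- c(keep, idx)
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) < 3L)
    .inputError("fewer than 3 CA residues in '", path, "'")
  if (any(diff(at$resno) <= 0L))
    .inputError("residue numbers not strictly increasing in '", path, "'")

  aa <- bio3d::aa321(at$resid)
  aa[is.na(aa) | !aa %in% .AA_LETTERS] <- "X"
  if (is.null(modelId))
    modelId <- tools::file_path_sans_ext(basename(path))
  CaModel(modelId = modelId, resno = at$resno, aa = aa,
          xyz = cbind(at$x, at$y, at$z), sourcePath = path)
}

#' Read an ensemble of models from several PDB files
#'
#' Parses every file with \code{\link{readCaModel}} and checks mutual
#' consistency (identical residue count, numbering and sequence). At least
#' two files are required: the heterogeneity score is undefined for a
#' single model.
#'
#' @param paths character vector of at least two PDB file paths; order is
#'   preserved.
#' @param chain optional chain id passed to every read.
#' @return a \code{\link{ModelEnsemble}}.
#' @export
readEnsemble <- function(paths, chain = NULL) {
  if (length(paths) < 2L)
    .inputError("at least 2 model files are required (got ", length(paths),
                "): the H-factor cannot be computed on a singular model")
  ms <- lapply(paths, readCaModel, chain = chain)
  tryCatch(ModelEnsemble(ms), error = function(e)
    .inputError("inconsistent ensemble: ", conditionMessage(e)))
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Emits one ATOM record per residue in fixed PDB columns; output is
#' byte-deterministic for a given model, which the fixture generator
#' relies on.
#'
#' @param model a \code{\link{CaModel}}.
#' @param path output file path.
#' @param chain single-character chain id.
#' @return \code{path}, invisibly.
#' @export
writeCaModel <- function(model, path, chain = "A") {
  stopifnot(is(model, "CaModel"))
  aa3 <- bio3d::aa123(model@aa)
  aa3[model@aa == "X"] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nResidues(model)), aa3, chain, model@resno,
    model@xyz[, 1L], model@xyz[, 2L], model@xyz[, 3L], 1.00, 0.00)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
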