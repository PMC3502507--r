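#' Read and filter a HMMER domtblout domain-hit table
#'
#' Parses the whitespace-separated per-domain table written by
#' \code{hmmsearch --domtblout} (comment lines start with '#'). The profile
#' accession (or name, when no accession is present) identifies the Pfam
#' domain and the envelope coordinates locate it on the target sequence.
#' Hits are filtered at the per-domain independent E-value: hits with
#' E-value above 1.0e-10 are removed (the cutoff is inclusive, so a hit at
#' exactly 1.0e-10 is kept), survivors are sorted by ascending E-value and
#' at most the top 5 are retained.
#'
#' @param path domtblout file path.
#' @param eValueCutoff inclusive E-value cutoff (default 1.0e-10).
#' @param maxHits maximum number of hits retained (default 5).
#' @return a list of \code{\link{DomainHit}} (possibly empty).
#' @export
readDomainHits <- function(path, eValueCutoff = 1.0e-10, maxHits = 5L) {
  .checkFile(path, "domain-hit")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hits <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 21L)
      .inputError("malformed domtblout row (", length(f),
                  " fields, expected >= 21): '", ln, "'")
    pfam <- if (f[5L] != "-") f[5L] else f[4L]
    ev <- suppressWarnings(as.numeric(f[13L]))
    envFrom <- suppressWarnings(as.integer(f[20L]))
    envTo <- suppressWarnings(as.integer(f[21L]))
    if (is.na(ev) || is.na(envFrom) || is.na(envTo))
      .inputError("malformed domtblout numeric field in row: '", ln, "'")
    if (envFrom > envTo)
      .inputError("domain envelope start ", envFrom, " > end ", envTo,
                  " in row: '", ln, "'")
    DomainHit(pfamId = pfam, targetStart = envFrom, targetEnd = envTo,
              eValue = ev)
  })
  ev <- vapply(hits, function(h) h@eValue, numeric(1))
  hits <- hits[ev <= eValueCutoff]
  ev <- ev[ev <= eValueCutoff]
  hits <- hits[order(ev)]
  if (length(hits) > maxHits) hits <- hits[seq_len(maxHits)]
  hits
}

#' Attach reference-structure paths to domain hits
#'
#' For each hit, files named \code{<pfamId>*.pdb} (the accession's version
#' suffix, e.g. ".12", is ignored) found under \code{refDir} are recorded
#' as that domain's reference structures, in sorted order.
#'
#' @param hits list of \code{\link{DomainHit}}.
#' @param refDir directory holding reference PDB files.
#' @return the hits with \code{referencePaths} filled in.
#' @export
attachReferences <- function(hits, refDir) {
  if (!dir.exists(refDir))
    .inputError("reference directory not found: '", refDir, "'")
  lapply(hits, function(h) {
    acc <- sub("\\.\\d+$", "", h@pfamId)
    paths <- sort(list.files(refDir, full.names = TRUE,
                             pattern = paste0("^", acc, ".*\\.pdb$")))
    h@referencePaths <- paths
    h
  })
}

#' Load the reference models of a set of domain hits
#'
#' @param hits list of \code{\link{DomainHit}} with references attached.
#' @param chain optional chain id passed to \code{\link{readCaModel}}.
#' @return a named list (by pfamId) of lists of \code{\link{CaModel}}.
#' @export
loadDomainReferences <- function(hits, chain = NULL) {
  refs <- lapply(hits, function(h)
    lapply(h@referencePaths, readCaModel, chain = chain))
  names(refs) <- vapply(hits, function(h) h@pfamId, character(1))
  refs
}
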