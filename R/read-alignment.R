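#' Read a pairwise target-template alignment
#'
#' Reads an aligned FASTA or Clustal file holding exactly two sequences of
#' equal gapped length. By default the first sequence is the target and
#' the second the template; either can be selected by name instead. Rows
#' are uppercased and "." gaps normalised to "-".
#'
#' @param path alignment file path.
#' @param format "fasta" (aligned FASTA) or "clustal".
#' @param target,template optional sequence names selecting which row is
#'   which, overriding file order.
#' @return a \code{\link{PairAlignment}}.
#' @export
readAlignment <- function(path, format = c("fasta", "clustal"),
                          target = NULL, template = NULL) {
  format <- match.arg(format)
  .checkFile(path, "alignment")
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path), error = function(e)
      .inputError("cannot parse FASTA '", path, "': ", conditionMessage(e)))
    nm <- names(set)
    seqs <- as.character(set)
  } else {
    parsed <- .readClustal(path)
    nm <- parsed$names
    seqs <- parsed$seqs
  }
  if (length(seqs) != 2L)
    .inputError("pairwise alignment required: '", path, "' holds ",
                length(seqs), " sequences")
  names(seqs) <- nm
  if (nchar(seqs[1L]) != nchar(seqs[2L]))
    .inputError("aligned rows in '", path, "' have unequal lengths (",
                nchar(seqs[1L]), " vs ", nchar(seqs[2L]), ")")
  pick <- function(name, default) {
    if (is.null(name)) return(default)
    i <- match(name, nm)
    if (is.na(i)) .inputError("sequence '", name, "' not found in '", path, "'")
    i
  }
  it <- pick(target, 1L)
  ip <- pick(template, if (it == 1L) 2L else 1L)
  if (it == ip) .inputError("target and template select the same sequence")
  tryCatch(PairAlignment(seqs[[it]], seqs[[ip]]), error = function(e)
    .inputError("invalid alignment in '", path, "': ", conditionMessage(e)))
}

# Minimal Clustal block parser: skip the CLUSTAL header, accumulate
# "name  segment" lines per block (a trailing residue count is tolerated),
# ignore blank and conservation lines.
.readClustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    .inputError("'", path, "' does not start with a CLUSTAL header")
  acc <- list()
  order <- character(0)
  for (ln in lines[-1L]) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next  # blank / conservation
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 2L)
      .inputError("malformed Clustal line in '", path, "': '", ln, "'")
    seg <- f[2L]
    if (!grepl("^[A-Za-z.\\-]+$", seg))
      .inputError("malformed Clustal segment in '", path, "': '", ln, "'")
    if (!f[1L] %in% order) order <- c(order, f[1L])
    acc[[f[1L]]] <- paste0(acc[[f[1L]]], seg)
  }
  if (length(order) == 0L) .inputError("no sequences in Clustal '", path, "'")
  list(names = order, seqs = unlist(acc[order], use.names = FALSE))
}

#' Ungapped sequence of one alignment row
#'
#' @param alignment a \code{\link{PairAlignment}}.
#' @param row "target" or "template".
#' @return the row with gap characters removed.
#' @export
ungappedRow <- function(alignment, row = c("target", "template")) {
  row <- match.arg(row)
  s <- if (row == "target") alignment@target else alignment@template
  gsub("-", "", s, fixed = TRUE)
}
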