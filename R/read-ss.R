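# STRIDE 7-state -> 3-state collapse. The conventional reduction:
# helices (alpha, 3-10, pi) -> H; strands and bridges -> E; turns, coil
# and bends -> C. Kept in one table so it can be swapped.
.STRIDE_COLLAPSE <- c(H = "H", G = "H", I = "H",
                      E = "E", B = "E", b = "E",
                      T = "C", C = "C", S = "C")

#' Read a PSIPRED secondary-structure prediction
#'
#' Returns a target-indexed, ungapped prediction track with a 0-9
#' confidence per residue. The .ss2 dialect carries three per-state
#' probabilities; its confidence is derived as \code{floor(10 * max
#' probability)} capped at 9, which lands on the same 0-9 scale the .horiz
#' dialect reports verbatim on its Conf line.
#'
#' @param path prediction file path.
#' @param dialect "ss2" (VFORMAT) or "horiz" (HFORMAT).
#' @return an \code{\link{SsTrack}} of kind "prediction".
#' @export
readSsPrediction <- function(path, dialect = c("ss2", "horiz")) {
  dialect <- match.arg(dialect)
  .checkFile(path, "secondary-structure prediction")
  lines <- readLines(path)
  if (dialect == "ss2") {
    rows <- grep("^\\s*\\d", lines, value = TRUE)
    if (length(rows) == 0L)
      .inputError("no data rows in ss2 file '", path, "'")
    states <- character(length(rows))
    conf <- integer(length(rows))
    for (i in seq_along(rows)) {
      f <- strsplit(trimws(rows[i]), "\\s+")[[1L]]
      if (length(f) < 6L)
        .inputError("malformed ss2 row in '", path, "': '", rows[i], "'")
      st <- toupper(f[3L])
      if (!st %in% c("H", "E", "C"))
        .inputError("ss2 state '", st, "' not in {H,E,C} in '", path, "'")
      p <- suppressWarnings(as.numeric(f[4:6]))
      if (any(is.na(p)))
        .inputError("malformed ss2 probabilities in '", path, "': '",
                    rows[i], "'")
      states[i] <- st
      conf[i] <- min(floor(10 * max(p)), 9)
    }
    SsTrack(states, conf, kind = "prediction")
  } else {
    grab <- function(tag) {
      m <- grep(paste0("^\\s*", tag, ":"), lines, value = TRUE)
      paste(gsub("\\s", "", sub(paste0("^\\s*", tag, ":"), "", m)),
            collapse = "")
    }
    confStr <- grab("Conf")
    predStr <- grab("Pred")
    if (nchar(predStr) == 0L)
      .inputError("no Pred lines in horiz file '", path, "'")
    if (nchar(confStr) != nchar(predStr))
      .inputError("Conf/Pred length disagreement in '", path, "' (",
                  nchar(confStr), " vs ", nchar(predStr), ")")
    states <- toupper(.chars(predStr))
    if (!all(states %in% c("H", "E", "C")))
      .inputError("horiz state(s) not in {H,E,C} in '", path, "': ",
                  paste(unique(setdiff(states, c("H", "E", "C"))),
                        collapse = ", "))
    conf <- suppressWarnings(as.integer(.chars(confStr)))
    if (any(is.na(conf)))
      .inputError("non-digit character on Conf line of '", path, "'")
    SsTrack(states, conf, kind = "prediction")
  }
}

#' Read a secondary-structure assignment for the template
#'
#' Returns a template-indexed, ungapped assignment track. The STRIDE
#' dialect reads ASG records and collapses the 7-state alphabet to 3
#' states (H,G,I to H; E,B,b to E; T,C,S to C); a gap in residue coverage
#' is reported as a warning and filled with coil. The plain dialect is one
#' H/E/C character per residue, whitespace ignored.
#'
#' @param path assignment file path.
#' @param dialect "stride" or "plain".
#' @return an \code{\link{SsTrack}} of kind "assignment".
#' @export
readSsAssignment <- function(path, dialect = c("stride", "plain")) {
  dialect <- match.arg(dialect)
  .checkFile(path, "secondary-structure assignment")
  lines <- readLines(path)
  if (dialect == "plain") {
    s <- gsub("\\s", "", paste(lines[!grepl("^\\s*#", lines)], collapse = ""))
    if (nchar(s) == 0L) .inputError("empty plain SS file '", path, "'")
    states <- toupper(.chars(s))
    if (!all(states %in% c("H", "E", "C")))
      .inputError("plain SS state(s) not in {H,E,C} in '", path, "'")
    return(SsTrack(states, kind = "assignment"))
  }
  asg <- grep("^ASG", lines, value = TRUE)
  if (length(asg) == 0L)
    .inputError("no ASG records in stride file '", path, "'")
  resno <- integer(length(asg))
  states <- character(length(asg))
  for (i in seq_along(asg)) {
    f <- strsplit(trimws(asg[i]), "\\s+")[[1L]]
    if (length(f) < 6L)
      .inputError("malformed ASG record in '", path, "': '", asg[i], "'")
    code <- f[6L]
    if (!code %in% names(.STRIDE_COLLAPSE))
      .inputError("unknown stride SS code '", code, "' in record: '",
                  asg[i], "'")
    rn <- suppressWarnings(as.integer(f[4L]))
    if (is.na(rn))
      .inputError("malformed ASG residue number in '", path, "': '",
                  asg[i], "'")
    resno[i] <- rn
    states[i] <- .STRIDE_COLLAPSE[[code]]
  }
  # fill numbering gaps with coil (reported): stride occasionally skips
  # residues it cannot assign
  full <- seq(resno[1L], resno[length(resno)])
  if (length(full) != length(resno)) {
    missing <- setdiff(full, resno)
    warning("stride file '", path, "' misses residue(s) ",
            paste(missing, collapse = ", "), "; filled with 'C'",
            call. = FALSE)
    filled <- rep("C", length(full))
    filled[match(resno, full)] <- states
    states <- filled
  }
  SsTrack(states, kind = "assignment")
}
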