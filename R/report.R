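#' Format an HFactorReport as human-readable text
#'
#' Sub-scores are printed to one decimal and the composite to the nearest
#' integer percent (half-up); an absent domain score prints as "n/a".
#'
#' @param report an \code{\link{HFactorReport}}.
#' @return a character vector of lines.
#' @export
formatReportText <- function(report) {
  s4 <- if (is.na(report@score4)) "n/a" else sprintf("%.1f", report@score4)
  c("H-factor report (0 = good, 100 = bad)",
    sprintf("  score1 (secondary-structure agreement): %.1f", report@score1),
    sprintf("  score2 (target-template non-identity):  %.1f", report@score2),
    sprintf("  score3 (ensemble heterogeneity):        %.1f", report@score3),
    sprintf("  score4 (domain structural integrity):   %s", s4),
    sprintf("  H-factor: %d%%", .roundHalfUp(report@hFactorPercent)))
}

#' Write an HFactorReport to disk
#'
#' The JSON format round-trips losslessly through \code{\link{readReport}};
#' the text format prints sub-scores to one decimal and the H-factor to the
#' nearest integer percent.
#'
#' @param report an \code{\link{HFactorReport}}.
#' @param path output file path.
#' @param format "json" or "text".
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  validObject(report)
  if (format == "text") {
    writeLines(formatReportText(report), path)
  } else {
    x <- list(score1 = report@score1, score2 = report@score2,
              score3 = report@score3,
              score4 = if (is.na(report@score4)) NULL else report@score4,
              h_factor_percent = report@hFactorPercent,
              h_factor_display = .roundHalfUp(report@hFactorPercent),
              diagnostics = report@diagnostics)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read a JSON HFactorReport back
#'
#' @param path a file written by \code{\link{writeReport}} with
#'   \code{format = "json"}.
#' @return an \code{\link{HFactorReport}}.
#' @export
readReport <- function(path) {
  .checkFile(path, "report")
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  HFactorReport(score1 = x$score1, score2 = x$score2, score3 = x$score3,
                score4 = if (is.null(x$score4)) NA_real_ else x$score4,
                diagnostics = if (is.null(x$diagnostics)) list()
                              else x$diagnostics)
}
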