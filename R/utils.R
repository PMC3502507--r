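# internal helpers shared across modules

.inputError <- function(...) {
  stop(errorCondition(paste0(...), class = c("hfactor_input_error", "error")))
}

.scoringError <- function(...) {
  stop(errorCondition(paste0(...), class = c("hfactor_scoring_error", "error")))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-up rounding to integer (R's round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.checkFile <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    .inputError(what, " file not found: '", path, "'")
  invisible(path)
}
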