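#' Assemble a run configuration
#'
#' Validates the file paths and option values the scoring pipeline needs.
#' Accepts either a YAML file (mirroring these arguments) or explicit
#' arguments; explicit arguments override the file.
#'
#' @param configFile optional YAML configuration file.
#' @param models character vector of model PDB paths, or a single
#'   directory containing \code{*.pdb} files.
#' @param alignment alignment file path.
#' @param alignmentFormat "fasta" or "clustal".
#' @param ssPred secondary-structure prediction path.
#' @param ssPredDialect "horiz" or "ss2".
#' @param ssTemplate template secondary-structure assignment path.
#' @param ssTemplateDialect "plain" or "stride".
#' @param domains optional domtblout path.
#' @param refDir optional directory of reference PDB files, required when
#'   \code{domains} is given.
#' @param chain optional chain id for model files.
#' @param constants optional named list of score-constant overrides
#'   (logged with a warning by \code{\link{scoreConstants}}).
#' @param out optional report output path.
#' @param outFormat "json" or "text".
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(configFile = NULL, models = NULL, alignment = NULL,
                      alignmentFormat = "fasta", ssPred = NULL,
                      ssPredDialect = "horiz", ssTemplate = NULL,
                      ssTemplateDialect = "plain", domains = NULL,
                      refDir = NULL, chain = NULL, constants = NULL,
                      out = NULL, outFormat = "json") {
  cfg <- list()
  if (!is.null(configFile)) {
    .checkFile(configFile, "configuration")
    cfg <- yaml::read_yaml(configFile)
    # resolve relative paths against the config file's directory
    base <- dirname(normalizePath(configFile))
    rel <- function(p) {
      if (is.null(p)) return(NULL)
      ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    }
    for (f in c("models", "alignment", "ssPred", "ssTemplate", "domains",
                "refDir", "out"))
      cfg[[f]] <- rel(cfg[[f]])
  }
  pickArg <- function(name, val, default = NULL) {
    if (!is.null(val)) val else if (!is.null(cfg[[name]])) cfg[[name]]
    else default
  }
  cfg <- list(
    models = pickArg("models", models),
    alignment = pickArg("alignment", alignment),
    alignmentFormat = pickArg("alignmentFormat", NULL, alignmentFormat),
    ssPred = pickArg("ssPred", ssPred),
    ssPredDialect = pickArg("ssPredDialect", NULL, ssPredDialect),
    ssTemplate = pickArg("ssTemplate", ssTemplate),
    ssTemplateDialect = pickArg("ssTemplateDialect", NULL, ssTemplateDialect),
    domains = pickArg("domains", domains),
    refDir = pickArg("refDir", refDir),
    chain = pickArg("chain", chain),
    constants = pickArg("constants", constants),
    out = pickArg("out", out),
    outFormat = pickArg("outFormat", NULL, outFormat))
  if (is.null(cfg$models)) .inputError("no model files configured")
  if (length(cfg$models) == 1L && dir.exists(cfg$models))
    cfg$models <- sort(list.files(cfg$models, pattern = "\\.pdb$",
                                  full.names = TRUE))
  for (p in cfg$models) .checkFile(p, "model")
  if (is.null(cfg$alignment)) .inputError("no alignment file configured")
  .checkFile(cfg$alignment, "alignment")
  if (is.null(cfg$ssPred)) .inputError("no secondary-structure prediction configured")
  .checkFile(cfg$ssPred, "secondary-structure prediction")
  if (is.null(cfg$ssTemplate)) .inputError("no template secondary-structure file configured")
  .checkFile(cfg$ssTemplate, "secondary-structure assignment")
  if (!is.null(cfg$domains)) {
    .checkFile(cfg$domains, "domain-hit")
    if (is.null(cfg$refDir))
      .inputError("domains given but no reference directory (refDir)")
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the scoring pipeline from a configuration
#'
#' Reads every configured input through the package's parsers, runs
#' \code{\link{evaluateHFactor}}, optionally writes the report, and logs
#' every file, dialect and skip decision via \code{message()}.
#'
#' @param config a \code{\link{runConfig}} (or a YAML path, which is passed
#'   through \code{runConfig}).
#' @param quiet suppress log messages.
#' @return the \code{\link{HFactorReport}}, invisibly.
#' @export
runScorePipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- runConfig(configFile = config)
  stopifnot(inherits(config, "RunConfig"))
  log <- function(...) if (!quiet) message(...)

  log("reading ", length(config$models), " model file(s)")
  ensemble <- readEnsemble(config$models, chain = config$chain)
  log("reading alignment '", config$alignment, "' (",
      config$alignmentFormat, ")")
  alignment <- readAlignment(config$alignment,
                             format = config$alignmentFormat)
  log("reading prediction '", config$ssPred, "' (", config$ssPredDialect, ")")
  prediction <- readSsPrediction(config$ssPred,
                                 dialect = config$ssPredDialect)
  log("reading assignment '", config$ssTemplate, "' (",
      config$ssTemplateDialect, ")")
  assignment <- readSsAssignment(config$ssTemplate,
                                 dialect = config$ssTemplateDialect)
  hits <- list()
  references <- list()
  if (!is.null(config$domains)) {
    log("reading domain hits '", config$domains, "'")
    hits <- readDomainHits(config$domains)
    log(length(hits), " hit(s) retained after E-value filter and top-5 cap")
    hits <- attachReferences(hits, config$refDir)
    references <- loadDomainReferences(hits, chain = config$chain)
  }
  constants <- if (is.null(config$constants)) scoreConstants()
               else do.call(scoreConstants, config$constants)
  report <- evaluateHFactor(ensemble, alignment, prediction, assignment,
                            hits = hits, references = references,
                            constants = constants)
  skipped <- report@diagnostics$domains$skipped
  for (nm in names(skipped))
    log("domain ", nm, " skipped: ", skipped[[nm]])
  if (!is.null(config$out)) {
    writeReport(report, config$out, format = config$outFormat)
    log("report written to '", config$out, "' (", config$outFormat, ")")
  }
  log(paste(formatReportText(report), collapse = "\n"))
  invisible(report)
}
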