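test_that("the helix fixture has uniform geometry matching the closed form", {
  m <- generateHelix(10)
  d <- sqrt(rowSums(diff(caCoords(m))^2))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
  r <- 2.3; twist <- 100 * pi / 180
  closedForm <- sqrt((r * (1 - cos(twist)))^2 + (r * sin(twist))^2 + 1.5^2)
  expect_equal(d[1], closedForm, tolerance = 1e-12)

  expect_equal(nResidues(generateHelix(3)), 3L)
  expect_error(generateHelix(2), "at least 3",
               class = "hfactor_input_error")
})

test_that("perturbed ensembles are deterministic and exact at sigma 0", {
  base <- generateHelix(15)
  same <- perturbEnsemble(base, 4, sigma = 0, seed = 1)
  expect_equal(caCoords(models(same)[[1]]), caCoords(models(same)[[4]]))
  expect_equal(as.numeric(ensembleHeterogeneityScore(same)), 0.87)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  perturbEnsemble(base, 3, sigma = 0.7, seed = 99, dir = d1)
  perturbEnsemble(base, 3, sigma = 0.7, seed = 99, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(perturbEnsemble(base, 3, sigma = 0.5),
               "seed is mandatory", class = "hfactor_input_error")
})

test_that("alignment fixtures hit their identity score exactly", {
  expect_equal(as.numeric(alignmentIdentityScore(
    generateAlignmentFixture(50, 1.0, seed = 2))), 0)
  expect_equal(as.numeric(alignmentIdentityScore(
    generateAlignmentFixture(50, 0.0, seed = 2))), 10)
  expect_equal(as.numeric(alignmentIdentityScore(
    generateAlignmentFixture(100, 0.5, seed = 2))), 5.0)
})

test_that("SS fixtures hit their agreement score exactly", {
  score <- function(nRes, mmf, conf, seed = 5) {
    ss <- generateSsFixture(nRes, mmf, conf, seed = seed)
    aln <- PairAlignment(strrep("A", nRes), strrep("A", nRes))
    as.numeric(ssAgreementScore(projectTracks(aln, ss$prediction,
                                              ss$assignment)))
  }
  expect_equal(score(40, 0, 7), 0.9)
  expect_equal(score(40, 1.0, 9), 10)                 # clipped from 13.9
  expect_equal(score(40, 0.5, 4), 1.3 * 2.5 + 0.9)    # mean f = 0.5 * (4+1)
})

test_that("each fixture knob moves only its own sub-score", {
  nRes <- 40
  base <- generateHelix(nRes)
  runCase <- function(idf = 0.5, mmf = 0.2, sigma = 0.5) {
    aln <- generateAlignmentFixture(nRes, idf, seed = 61)
    ss <- generateSsFixture(nRes, mmf, 7, seed = 62)
    ens <- perturbEnsemble(base, 5, sigma, seed = 63)
    subScores(evaluateHFactor(ens, aln, ss$prediction, ss$assignment))
  }
  ref <- runCase()
  moreNoise <- runCase(sigma = 2.0)
  expect_gt(moreNoise[["score3"]], ref[["score3"]])
  expect_equal(moreNoise[1:2], ref[1:2])

  lessIdentity <- runCase(idf = 0.2)
  expect_gt(lessIdentity[["score2"]], ref[["score2"]])
  expect_equal(lessIdentity[["score1"]], ref[["score1"]])
  expect_equal(lessIdentity[["score3"]], ref[["score3"]])

  moreMismatch <- runCase(mmf = 0.6)
  expect_gt(moreMismatch[["score1"]], ref[["score1"]])
  expect_equal(moreMismatch[2:3], ref[2:3])
})

test_that("fixture bundles are complete, scoreable and byte-deterministic", {
  spec <- fixtureSpec(nRes = 40, nModels = 5, seed = 77)
  d1 <- withr::local_tempdir()
  paths <- writeFixtureBundle(spec, d1)
  expect_true(all(file.exists(unlist(paths))))

  cfg <- runConfig(models = file.path(d1, "models"),
                   alignment = paths$alignment, ssPred = paths$ssPred,
                   ssTemplate = paths$ssTemplate, domains = paths$domains,
                   refDir = paths$refDir)
  rep <- runScorePipeline(cfg, quiet = TRUE)
  expect_s4_class(rep, "HFactorReport")
  expect_false(is.na(subScores(rep)[["score4"]]))

  # re-feeding the manifest's spec reproduces the bundle byte for byte
  manifest <- yaml::read_yaml(paths$manifest)
  spec2 <- do.call(fixtureSpec, manifest$spec)
  d2 <- withr::local_tempdir()
  writeFixtureBundle(spec2, d2)
  rel <- function(d) {
    f <- sort(list.files(d, recursive = TRUE))
    f[tools::file_ext(f) != "yaml"]
  }
  expect_equal(rel(d1), rel(d2))
  expect_identical(unname(tools::md5sum(file.path(d1, rel(d1)))),
                   unname(tools::md5sum(file.path(d2, rel(d2)))))
})

test_that("self-referenced domain fixtures score near the 0.87 fixed point", {
  spec <- fixtureSpec(nRes = 40, nModels = 10, noiseSigma = 0.05,
                      ssMismatchFraction = 0, identityFraction = 0.8,
                      seed = 55)
  d <- withr::local_tempdir()
  paths <- writeFixtureBundle(spec, d)
  rep <- runScorePipeline(runConfig(
    models = file.path(d, "models"), alignment = paths$alignment,
    ssPred = paths$ssPred, ssTemplate = paths$ssTemplate,
    domains = paths$domains, refDir = paths$refDir), quiet = TRUE)
  s4 <- subScores(rep)[["score4"]]
  # reference = unperturbed base; MA deviates only by residual noise
  expect_gte(s4, 0.87)
  expect_lt(s4, 1.1)
})

test_that("run configuration fails cleanly on bad input", {
  expect_error(runConfig(models = NULL), "no model files",
               class = "hfactor_input_error")
  d <- withr::local_tempdir()
  paths <- writeFixtureBundle(fixtureSpec(nRes = 30, nModels = 3, seed = 9,
                                          withDomains = FALSE), d)
  expect_error(runConfig(models = paths$models, alignment = paths$alignment,
                         ssPred = "/missing/file.horiz",
                         ssTemplate = paths$ssTemplate),
               "/missing/file.horiz", class = "hfactor_input_error")
  # a single model is rejected before any scoring
  cfg <- runConfig(models = paths$models[1], alignment = paths$alignment,
                   ssPred = paths$ssPred, ssTemplate = paths$ssTemplate)
  expect_error(runScorePipeline(cfg, quiet = TRUE), "singular model",
               class = "hfactor_input_error")
})

test_that("a YAML config file drives the pipeline", {
  d <- withr::local_tempdir()
  paths <- writeFixtureBundle(fixtureSpec(nRes = 30, nModels = 3, seed = 19), d)
  cfgFile <- file.path(d, "config.yaml")
  yaml::write_yaml(list(models = "models", alignment = "alignment.fasta",
                        ssPred = "target.horiz", ssTemplate = "template.ss",
                        domains = "domains.domtblout", refDir = "refs",
                        out = "report.json"), cfgFile)
  rep <- runScorePipeline(runConfig(configFile = cfgFile), quiet = TRUE)
  expect_true(file.exists(file.path(d, "report.json")))
  back <- readReport(file.path(d, "report.json"))
  expect_equal(subScores(back), subScores(rep))
})
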