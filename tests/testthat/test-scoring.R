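constantsDefault <- scoreConstants()

test_that("track projection consumes each symbol exactly once", {
  aln <- PairAlignment("AC-D", "ACED")
  pred <- SsTrack(c("H", "H", "C"), c(9, 9, 9), kind = "prediction")
  assn <- SsTrack(c("H", "H", "H", "C"), kind = "assignment")
  cols <- projectTracks(aln, pred, assn)
  expect_equal(cols$pred, c("H", "H", NA, "C"))
  expect_equal(cols$assign, c("H", "H", "H", "C"))
  expect_equal(cols$conf, c(9L, 9L, NA, 9L))

  # gapless alignment: plain zip
  aln2 <- PairAlignment("ACD", "ACD")
  cols2 <- projectTracks(aln2, pred, SsTrack(c("C", "H", "E"),
                                             kind = "assignment"))
  expect_equal(cols2$pred, c("H", "H", "C"))
  expect_equal(cols2$assign, c("C", "H", "E"))

  expect_error(projectTracks(aln, SsTrack("H", 5, kind = "prediction"), assn),
               "does not match ungapped target length",
               class = "hfactor_input_error")
})

test_that("secondary-structure score hits its forced values", {
  n <- 40
  mkCols <- function(pred, assign, conf = 9L) {
    aln <- PairAlignment(strrep("A", n), strrep("A", n))
    projectTracks(aln, SsTrack(rep(pred, n), rep(conf, n), "prediction"),
                  SsTrack(rep(assign, n), kind = "assignment"))
  }
  # all matching: mean f = 0 -> b1 = 0.9
  expect_equal(as.numeric(ssAgreementScore(mkCols("H", "H"))), 0.9)
  # all mismatching at confidence 9: mean f = 10 -> 13.9 clipped to 10
  expect_equal(as.numeric(ssAgreementScore(mkCols("H", "E", 9L))), 10)
  # all mismatching at confidence 0: mean f = 1 -> 2.2
  expect_equal(as.numeric(ssAgreementScore(mkCols("H", "E", 0L))), 2.2)

  # all columns gapped on one row: mean f = 1 -> 1.3 + 0.9 = 2.2
  aln <- PairAlignment(paste0(strrep("A", 10), strrep("-", 10)),
                       paste0(strrep("-", 10), strrep("A", 10)))
  cols <- projectTracks(aln, SsTrack(rep("H", 10), rep(9, 10), "prediction"),
                        SsTrack(rep("H", 10), kind = "assignment"))
  s <- ssAgreementScore(cols)
  expect_equal(as.numeric(s), 2.2)
  expect_equal(attr(s, "nGap"), 20L)
})

test_that("mismatch penalty rises with prediction confidence", {
  n <- 50
  aln <- PairAlignment(strrep("A", n), strrep("A", n))
  scores <- vapply(0:9, function(conf) {
    cols <- projectTracks(aln,
                          SsTrack(rep("H", n), rep(conf, n), "prediction"),
                          SsTrack(rep("E", n), kind = "assignment"))
    as.numeric(ssAgreementScore(cols))
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_true(all(diff(scores[1:7]) > 0))  # strictly, until clipping kicks in

  # flipping matched columns to mismatches never lowers the score
  st <- rep("H", n)
  for (k in c(0, 10, 25, 50)) {
    pred <- st; if (k > 0) pred[seq_len(k)] <- "E"
    cols <- projectTracks(aln, SsTrack(pred, rep(5, n), "prediction"),
                          SsTrack(st, kind = "assignment"))
    val <- as.numeric(ssAgreementScore(cols))
    if (k == 0) expect_equal(val, 0.9) else expect_gt(val, prev)
    prev <- val
  }
})

test_that("the scaled mismatch-penalty variant compresses the range", {
  n <- 20
  aln <- PairAlignment(strrep("A", n), strrep("A", n))
  cols <- projectTracks(aln, SsTrack(rep("H", n), rep(9, n), "prediction"),
                        SsTrack(rep("E", n), kind = "assignment"))
  expect_equal(as.numeric(ssAgreementScore(cols, mismatchPenalty = "scaled")),
               1.3 * 1.0 + 0.9)  # (9+1)/10 = 1 per column
})

test_that("identity score counts equal non-gap columns over full N", {
  expect_equal(as.numeric(alignmentIdentityScore(PairAlignment("ACDEF",
                                                               "ACDEF"))), 0)
  expect_equal(as.numeric(alignmentIdentityScore(PairAlignment("ACDEF",
                                                               "CDEFG"))), 10)
  s <- alignmentIdentityScore(PairAlignment("ACDEF", "ACD--"))
  expect_equal(as.numeric(s), 4.0)  # 3 identities over N = 5
  expect_equal(attr(s, "identityFraction"), 0.6)

  # strictly decreasing in the number of identical columns at fixed N
  n <- 30
  vals <- vapply(0:n, function(k) {
    tg <- rep("A", n); tp <- rep("C", n)
    if (k > 0) tp[seq_len(k)] <- "A"
    as.numeric(alignmentIdentityScore(PairAlignment(paste(tg, collapse = ""),
                                                    paste(tp, collapse = ""))))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("heterogeneity score hits its forced and clipped values", {
  base <- generateHelix(20)
  same <- ModelEnsemble(list(base, base, base))
  expect_equal(as.numeric(ensembleHeterogeneityScore(same)), 0.87)

  # far-apart members: mean cRMS > 7.02 must clip at 10
  far1 <- CaModel("a", 1:20, rep("A", 20), caCoords(base) +
                    matrix(withr::with_seed(1, rnorm(60, sd = 12)), 20, 3))
  far2 <- CaModel("b", 1:20, rep("A", 20), caCoords(base) +
                    matrix(withr::with_seed(2, rnorm(60, sd = 12)), 20, 3))
  ens <- ModelEnsemble(list(far1, far2))
  r <- as.numeric(meanEnsembleCrms(ens))
  expect_gt(r, 7.1)
  expect_equal(as.numeric(ensembleHeterogeneityScore(ens)), 10)

  # mid-range: affine map applied un-clipped
  mid <- perturbEnsemble(base, 6, sigma = 1.0, seed = 4)
  rMid <- as.numeric(meanEnsembleCrms(mid))
  expect_equal(as.numeric(ensembleHeterogeneityScore(mid)),
               1.3 * rMid + 0.87, tolerance = 1e-9)
})

test_that("fragments are sliced at target positions, dropping unmodeled ones", {
  base <- generateHelix(10)
  ens <- ModelEnsemble(list(base, base))
  ma <- averageModel(ens)
  full <- extractFragment(ma, DomainHit("PF1", 1, 10, 1e-20))
  expect_equal(unname(caCoords(full)), unname(caCoords(ma)))
  expect_equal(attr(full, "droppedCount"), 0L)

  sl <- extractFragment(ma, DomainHit("PF1", 3, 5, 1e-20))
  expect_equal(residueNumbers(sl), 3:5)
  expect_equal(unname(caCoords(sl)), unname(caCoords(ma)[3:5, ]))

  # residue 4 unmodeled -> 2-residue fragment, droppedCount 1
  gapped <- new("CaModel", modelId = "g", resno = c(1:3, 5:10),
                aa = rep("A", 9), xyz = caCoords(base)[c(1:3, 5:10), ],
                sourcePath = NA_character_)
  frag <- extractFragment(gapped, DomainHit("PF1", 3, 5, 1e-20))
  expect_equal(nResidues(frag), 2L)
  expect_equal(attr(frag, "droppedCount"), 1L)

  # entirely unmodeled envelope -> skip signal
  expect_null(extractFragment(gapped, DomainHit("PF1", 4, 4, 1e-20)))

  aln <- PairAlignment(strrep("A", 10), strrep("A", 10))
  expect_error(extractFragment(ma, DomainHit("PF1", 5, 40, 1e-20), aln),
               "exceeds target length", class = "hfactor_input_error")
})

test_that("residue correspondence handles identity, offsets and skips", {
  frag <- CaModel("f", 1:10, strsplit("ACDEFGHIKL", "")[[1]],
                  caCoords(generateHelix(10)))
  idPairs <- correspondFragment(frag, frag)
  expect_equal(idPairs[, "fragment"], 1:10)
  expect_equal(idPairs[, "reference"], 1:10)

  ref <- CaModel("r", 1:12, strsplit("MWACDEFGHIKL", "")[[1]],
                 caCoords(generateHelix(12)))
  off <- correspondFragment(frag, ref)
  expect_equal(nrow(off), 10L)
  expect_equal(off[, "reference"], off[, "fragment"] + 2L)

  # with free gaps an unrelated short peptide aligns < 3 residues -> skip
  tiny <- CaModel("t", 1:3, c("W", "W", "W"), caCoords(generateHelix(3)))
  long <- CaModel("l", 1:50, rep(c("A", "D", "K", "S", "T"), 10),
                  caCoords(generateHelix(50)))
  expect_null(correspondFragment(tiny, long, gapOpening = 0,
                                 gapExtension = 0))
})

test_that("domain integrity score pools references and records skips", {
  base <- generateHelix(30, aa = rep(c("A", "C", "D", "E", "F", "G"), 5))
  ens <- perturbEnsemble(base, 5, sigma = 0.1, seed = 8)
  ma <- averageModel(ens)
  hit <- DomainHit("PF00010", 1, 30, 1e-25)

  # self-reference: the fragment itself -> grand mean 0 -> b4 = 0.87
  self <- as(ma, "CaModel")
  s <- domainIntegrityScore(ma, list(hit), references = list(PF00010 = list(self)))
  expect_equal(as.numeric(s), 0.87)
  expect_equal(attr(s, "grandMeanCrms"), 0, tolerance = 1e-9)

  # two perturbed references: expected value from the grid-search oracle
  ref1 <- CaModel("r1", 1:30, aaSequence(base), caCoords(base) +
                    matrix(withr::with_seed(11, rnorm(90, sd = 0.8)), 30, 3))
  ref2 <- CaModel("r2", 1:30, aaSequence(base), caCoords(base) +
                    matrix(withr::with_seed(12, rnorm(90, sd = 2.5)), 30, 3))
  r1 <- gridCrms(caCoords(ma), caCoords(ref1))
  r2 <- gridCrms(caCoords(ma), caCoords(ref2))
  s2 <- domainIntegrityScore(ma, list(hit),
                             references = list(PF00010 = list(ref1, ref2)))
  expect_equal(as.numeric(s2), min(1.3 * mean(c(r1, r2)) + 0.87, 10),
               tolerance = 1e-3)
  expect_equal(unname(lengths(attr(s2, "perDomain"))), 2L)

  # no usable reference -> absent score with a reason
  s3 <- domainIntegrityScore(ma, list(hit), references = list())
  expect_true(is.na(as.numeric(s3)))
  expect_match(attr(s3, "skipped")[["PF00010"]], "no reference")
})

test_that("the H-factor is 10 x the mean of present sub-scores", {
  h <- hFactor(2.0, 6.2, 1.5, 5.0)
  expect_equal(as.numeric(h), 36.75, tolerance = 1e-12)
  expect_equal(attr(h, "display"), 37)

  h3 <- hFactor(2.0, 6.2, 1.5)
  expect_equal(as.numeric(h3), 10 * mean(c(2.0, 6.2, 1.5)), tolerance = 1e-12)

  expect_equal(as.numeric(hFactor(0, 0, 0, 0)), 0)
  expect_equal(as.numeric(hFactor(10, 10, 10, 10)), 100)

  expect_error(hFactor(2, 6, NA_real_, 5), "must all be present",
               class = "hfactor_scoring_error")
  expect_error(hFactor(2, 6, 11, 5), "lie in",
               class = "hfactor_scoring_error")
})

test_that("all scores stay in bounds on randomized sweeps", {
  base <- generateHelix(25)
  withr::with_seed(17, {
    for (i in 1:8) {
      idf <- runif(1); mmf <- runif(1); conf <- sample(0:9, 1)
      sigma <- runif(1, 0, 6)
      aln <- generateAlignmentFixture(25, idf, seed = i)
      ss <- generateSsFixture(25, mmf, conf, seed = i + 100)
      ens <- perturbEnsemble(base, 4, sigma, seed = i + 200)
      rep <- evaluateHFactor(ens, aln, ss$prediction, ss$assignment)
      sc <- subScores(rep)
      expect_true(all(sc[1:3] >= 0 & sc[1:3] <= 10))
      expect_true(is.na(sc[["score4"]]))
      expect_gte(hFactorPercent(rep), 0)
      expect_lte(hFactorPercent(rep), 100)
    }
  })
})

test_that("end-to-end evaluation wires every sub-score and skip rule", {
  nRes <- 60
  aln <- generateAlignmentFixture(nRes, 0.8, seed = 301)
  base <- generateHelix(nRes, aa = strsplit(ungappedRow(aln, "target"),
                                            "")[[1]])
  ens <- perturbEnsemble(base, 10, sigma = 0.05, seed = 302)
  ss <- generateSsFixture(nRes, 0, 9, seed = 303)
  hit <- DomainHit("PF00001", 1, nRes, 1e-30)
  rep <- evaluateHFactor(ens, aln, ss$prediction, ss$assignment,
                         hits = list(hit),
                         references = list(PF00001 = list(base)))
  sc <- subScores(rep)
  expect_equal(sc[["score1"]], 0.9)            # perfect SS match
  expect_equal(sc[["score2"]], 2.0)            # 80% identity
  expect_true(all(sc < 3))                     # "good model" scenario
  expect_false(is.na(sc[["score4"]]))

  # same scenario minus domain hits: score4 absent, mean over 3 scores
  rep2 <- evaluateHFactor(ens, aln, ss$prediction, ss$assignment)
  expect_true(is.na(subScores(rep2)[["score4"]]))
  expect_equal(hFactorPercent(rep2),
               10 * mean(subScores(rep2)[1:3]), tolerance = 1e-12)

  # a singular model never reaches scoring
  expect_error(ModelEnsemble(list(base)), "singular")
})
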