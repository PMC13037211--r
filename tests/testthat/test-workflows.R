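# end-to-end command wrappers on a small synthetic instance
wfDir <- file.path(tempdir(), "hnp-wf")
wfCfg <- simulationConfig(nNodes = 250L, moduleSize = 30L, seed = 14)
wfObjs <- suppressMessages(simulateToDirectory(wfCfg, wfDir))

test_that("integration command is deterministic and handles qualitative columns", {
  tab <- data.frame(
    symbol = c("a", "b", "c"),
    ctd = c(0, 5, 10), # raw: min-max scaled
    dg = c(0.2, 0.4, 1.0), # already in [0, 1]: passed through
    llm = c(2L, 4L, 8L), # counts: divided by max
    ttd = c(1, NA, 1) # qualitative
  )
  f <- tempfile(fileext = ".tsv")
  writeSourceScores(tab, f)
  o1 <- tempfile(fileext = ".tsv")
  o2 <- tempfile(fileext = ".tsv")
  runIntegrate(f, "multiplicative", o1)
  runIntegrate(f, "multiplicative", o2)
  expect_identical(readLines(o1), readLines(o2))

  got <- readIntegratedScores(o1)
  sc <- stats::setNames(got$score, got$symbol)
  # hand computation: eps-zero for ctd min, counts /8, eps-missing for b's ttd
  expect_equal(sc[["c"]], 1 * 1 * 1 * 1)
  expect_equal(sc[["b"]], 0.5 * 0.4 * 0.5 * 1e-20)
  expect_equal(sc[["a"]], 1e-5 * 0.2 * 0.25 * 1)
  expect_identical(attr(got, "scheme"), "multiplicative")

  # a fully-listed qualitative source (all 1.0) leaves the product unchanged
  tab2 <- tab
  tab2$ttd <- 1
  f2 <- tempfile(fileext = ".tsv")
  writeSourceScores(tab2, f2)
  o3 <- tempfile(fileext = ".tsv")
  runIntegrate(f2, "multiplicative", o3)
  tab3 <- tab2[, -5]
  f3 <- tempfile(fileext = ".tsv")
  writeSourceScores(tab3, f3)
  o4 <- tempfile(fileext = ".tsv")
  runIntegrate(f3, "multiplicative", o4)
  expect_equal(readIntegratedScores(o3)$score, readIntegratedScores(o4)$score)

  # additive mode: zero imputation
  oa <- tempfile(fileext = ".tsv")
  runIntegrate(f, "additive", oa)
  sa <- readIntegratedScores(oa)
  expect_identical(attr(sa, "scheme"), "additive")
  expect_equal(
    stats::setNames(sa$score, sa$symbol)[["b"]],
    0.5 + 0.4 + 0.5 + 0
  )
})

test_that("herb weighting command writes raw and normalized columns", {
  out1 <- tempfile(fileext = ".tsv")
  out3 <- tempfile(fileext = ".tsv")
  set1 <- suppressWarnings(runWeighHerb(
    file.path(wfDir, "formula.tsv"), file.path(wfDir, "abundance.tsv"),
    file.path(wfDir, "catalog.tsv"),
    method = 3, out = out1
  ))
  tab <- utils::read.delim(out1)
  expect_named(tab, c("protein", "raw_weight", "norm_weight"))
  expect_true(all(tab$norm_weight > 0 & tab$norm_weight <= 1))
  expect_setequal(tab$protein, proteins(set1))

  # method 1 equals method 3 when the catalog is all-validated unit A and P
  fo <- formulaComposition(c("h1", "h2"), c(0.5, 0.5))
  ab <- compoundAbundanceTable(c("h1", "h2"), c("c1", "c2"), c(1, 1))
  ct <- interactionCatalog(c("c1", "c2"), c("p1", "p2"), c(1, 1), "validated")
  ff <- tempfile(); fa <- tempfile(); fc <- tempfile()
  writeFormula(fo, ff); writeAbundance(ab, fa); writeCatalog(ct, fc)
  oM1 <- tempfile(); oM3 <- tempfile()
  suppressWarnings(runWeighHerb(ff, fa, fc, method = 1, out = oM1))
  suppressWarnings(runWeighHerb(ff, fa, fc, method = 3, out = oM3))
  expect_identical(readLines(oM1), readLines(oM3))
})

test_that("evaluation command sweeps Top-N with paired metrics", {
  scoresFile <- tempfile(fileext = ".tsv")
  ss <- wfObjs$scores
  intTab <- integrateMultiplicative(ss)
  writeIntegratedScores(intTab, scoresFile)
  herbFile <- tempfile(fileext = ".tsv")
  raw <- computeRawWeights(wfObjs$formula, wfObjs$abundance, wfObjs$catalog, 3)
  writeWeightedSet(normalizeWeights(raw), herbFile)
  outTsv <- tempfile(fileext = ".tsv")
  outJson <- tempfile(fileext = ".json")
  res <- suppressMessages(runEvaluate(
    file.path(wfDir, "edges.tsv"), herbFile, scoresFile,
    topnGrid = c(20L, 40L), nPerm = 25L, seed = 7, minBinSize = 40L,
    outTsv = outTsv, outJson = outJson
  ))
  expect_equal(res$topN, c(20L, 40L))
  expect_true(all(c("z_weighted", "z_unweighted", "jaccard") %in% names(res)))
  js <- jsonlite::fromJSON(outJson)
  expect_equal(js$mean_z_weighted, mean(res$z_weighted))
  res2 <- suppressMessages(runEvaluate(
    file.path(wfDir, "edges.tsv"), herbFile, scoresFile,
    topnGrid = "20:40:20", nPerm = 25L, seed = 7, minBinSize = 40L,
    outTsv = tempfile(fileext = ".tsv")
  ))
  expect_identical(res, res2) # grid string parses to the same sweep
  expect_error(
    suppressMessages(runEvaluate(
      file.path(wfDir, "edges.tsv"), herbFile, scoresFile,
      topnGrid = 10000L, nPerm = 5L, outTsv = tempfile()
    )),
    "exceeds"
  )
})

test_that("perturbation command reports Rs = 1 for alpha 0", {
  pf <- tempfile(fileext = ".tsv")
  writeWeightedSet(wfObjs$module, pf)
  long <- tempfile(fileext = ".tsv")
  summ <- tempfile(fileext = ".tsv")
  pr <- runPerturb(pf, alphas = 0, nSim = 10, seed = 3, outLong = long, outSummary = summ)
  expect_true(all(pr@rs == 1.0))
  tl <- utils::read.delim(long)
  expect_equal(nrow(tl), 10L)
  expect_true(all(tl$rs == 1.0))
  ts <- utils::read.delim(summ)
  expect_equal(ts$mean_rs, 1.0)
})

test_that("simulation command is reproducible directory-for-directory", {
  d1 <- file.path(tempdir(), "hnp-sim-a")
  d2 <- file.path(tempdir(), "hnp-sim-b")
  suppressMessages(runSimulate(d1, nNodes = 120L, moduleSize = 12L, seed = 9))
  suppressMessages(runSimulate(d2, nNodes = 120L, moduleSize = 12L, seed = 9))
  for (f in c("edges.tsv", "formula.tsv", "abundance.tsv", "catalog.tsv", "source_scores.tsv")) {
    expect_identical(
      tools::md5sum(file.path(d1, f))[[1]],
      tools::md5sum(file.path(d2, f))[[1]]
    )
  }
})

test_that("combine command unions sets with the max-weight rule", {
  fa <- tempfile(); fb <- tempfile(); out <- tempfile()
  writeWeightedSet(WeightedProteinSet(c(A = 0.5, B = 0.3)), fa)
  writeWeightedSet(WeightedProteinSet(c(B = 0.9, C = 0.2)), fb)
  comb <- runCombine(fa, fb, out)
  expect_equal(
    proteinWeights(comb)[c("A", "B", "C")],
    c(A = 0.5, B = 0.9, C = 0.2)
  )
  expect_equal(proteinWeights(readWeightedSet(out)), proteinWeights(comb))
})

test_that("result records serialize to well-formed JSON", {
  m <- jaccardIndex(c("a", "b"), c("b", "c"))
  js <- jsonlite::fromJSON(resultToJson(m))
  expect_equal(js$value, 1 / 3)
  expect_identical(js$metric, "jaccard")
})
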