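test_that("interactome generation is deterministic with the expected edge count", {
  cfg <- simulationConfig(nNodes = 100L, attachment = 2L, moduleSize = 10L, seed = 3)
  net <- generateInteractome(cfg)
  expect_equal(networkSize(net), 100L)
  # closed form for the attachment scheme: m(m-1)/2 + m(n-m)
  expect_equal(networkEdgeCount(net), 1L + 2L * 98L)
  net2 <- generateInteractome(cfg)
  expect_identical(
    igraph::as_edgelist(net@graph),
    igraph::as_edgelist(net2@graph)
  )
  # attachment 1 yields a tree
  tree <- generateInteractome(simulationConfig(nNodes = 10L, attachment = 1L, moduleSize = 3L, seed = 1))
  expect_equal(networkEdgeCount(tree), 9L)
  expect_true(igraph::is_connected(tree@graph))
})

test_that("planted disease modules are connected, weighted and reproducible", {
  cfg <- simulationConfig(nNodes = 200L, moduleSize = 25L, seed = 6)
  net <- generateInteractome(cfg)
  mod <- plantDiseaseModule(net, cfg)
  expect_equal(length(mod), 25L)
  sub <- igraph::induced_subgraph(net@graph, proteins(mod))
  expect_true(igraph::is_connected(sub))
  w <- proteinWeights(mod)
  expect_true(all(w > 0 & w <= 1))
  expect_equal(max(w), 1.0)
  expect_identical(proteinWeights(plantDiseaseModule(net, cfg)), w)

  one <- simulationConfig(nNodes = 50L, moduleSize = 1L, seed = 2)
  n1 <- generateInteractome(one)
  m1 <- plantDiseaseModule(n1, one)
  expect_identical(unname(proteinWeights(m1)), 1.0)
})

test_that("formula inputs satisfy their declared distributional contracts", {
  cfg <- simulationConfig(nNodes = 300L, moduleSize = 40L, seed = 8)
  net <- generateInteractome(cfg)
  mod <- plantDiseaseModule(net, cfg)
  inp <- generateFormulaInputs(net, mod, cfg)
  expect_s3_class(inp$formula, "FormulaComposition")
  expect_lt(abs(sum(inp$formula$ratio) - 1), 1e-9)
  expect_equal(nrow(inp$abundance), cfg$nHerbs * cfg$compoundsPerHerb)
  expect_true(all(inp$catalog$probability > 0 & inp$catalog$probability <= 1))
  expect_true(all(inp$catalog$probability[inp$catalog$provenance == "validated"] == 1))
  # determinism
  inp2 <- generateFormulaInputs(net, mod, cfg)
  expect_identical(as.data.frame(inp$catalog), as.data.frame(inp2$catalog))

  # full enrichment: every catalog protein inside module or its neighborhood
  cfg1 <- simulationConfig(nNodes = 300L, moduleSize = 40L, enrichment = 1, seed = 8)
  inpE <- generateFormulaInputs(net, mod, cfg1)
  pool <- union(proteins(mod), neighborsOf(net, proteins(mod)))
  expect_true(all(inpE$catalog$protein %in% pool))
})

test_that("noise-free source scores rank targets exactly like the truth", {
  cfg <- simulationConfig(nNodes = 150L, moduleSize = 30L, seed = 10)
  net <- generateInteractome(cfg)
  mod <- plantDiseaseModule(net, cfg)
  ss <- generateSourceScores(mod, proteins(net),
    noiseSd = 0, missingRate = 0,
    nSources = 4, seed = 3
  )
  tw <- proteinWeights(mod)
  for (col in c("source1", "source2", "source3")) {
    v <- stats::setNames(ss[[col]], ss$symbol)[names(tw)]
    expect_false(anyNA(v))
    expect_equal(spearmanRho(v, tw), 1.0)
  }
  # qualitative column: 1.0 for truth members, NA elsewhere
  q <- stats::setNames(ss$source4, ss$symbol)
  expect_true(all(q[names(tw)] == 1.0))
  expect_true(all(is.na(q[setdiff(ss$symbol, names(tw))])))

  # full missingness empties a column
  ssM <- generateSourceScores(mod, proteins(net), missingRate = 1, seed = 3)
  expect_true(all(is.na(ssM$source1)))
})

test_that("multiplicative integration recovers the planted top targets", {
  hits <- sapply(1:20, function(r) {
    cfg <- simulationConfig(nNodes = 400L, moduleSize = 120L, seed = 700 + r)
    net <- generateInteractome(cfg)
    mod <- plantDiseaseModule(net, cfg)
    ss <- generateSourceScores(mod, proteins(net),
      noiseSd = 0.1, missingRate = 0,
      nSources = 5, seed = 700 + r
    )
    est <- integrateMultiplicative(ss)
    tw <- sort(proteinWeights(mod), decreasing = TRUE)
    trueTop <- names(tw)[1:50]
    length(intersect(est$symbol[1:50], trueTop)) / 50
  })
  expect_gte(mean(hits), 0.8)
})

test_that("generated artifacts round-trip through writers and readers", {
  dir <- file.path(tempdir(), "hnp-sim")
  cfg <- simulationConfig(nNodes = 120L, moduleSize = 15L, seed = 5)
  objs <- suppressMessages(simulateToDirectory(cfg, dir))
  expect_true(all(file.exists(file.path(dir, c(
    "edges.tsv", "formula.tsv", "abundance.tsv", "catalog.tsv",
    "source_scores.tsv", "disease_module.tsv", "manifest.json"
  )))))
  net2 <- suppressMessages(loadEdgeList(file.path(dir, "edges.tsv")))
  expect_setequal(proteins(net2), proteins(objs$network))
  expect_equal(networkEdgeCount(net2), networkEdgeCount(objs$network))
  expect_equal(readFormula(file.path(dir, "formula.tsv"))$ratio, objs$formula$ratio)
  expect_equal(
    readAbundance(file.path(dir, "abundance.tsv"))$abundance,
    objs$abundance$abundance
  )
  cat2 <- readCatalog(file.path(dir, "catalog.tsv"))
  expect_identical(cat2$protein, objs$catalog$protein)
  expect_equal(cat2$probability, objs$catalog$probability)
  mod2 <- readWeightedSet(file.path(dir, "disease_module.tsv"))
  expect_equal(proteinWeights(mod2), proteinWeights(objs$module))
  expect_identical(setLabel(mod2), setLabel(objs$module))
  ss2 <- readSourceScores(file.path(dir, "source_scores.tsv"))
  expect_equal(ss2$source1, objs$scores$source1)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulationConfig(nNodes = 5), ">= 10")
  expect_error(simulationConfig(moduleSize = 3000), "moduleSize")
  expect_error(simulationConfig(enrichment = 1.2), "enrichment")
  expect_error(simulationConfig(dosageConcentration = 0), "positive")
})
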