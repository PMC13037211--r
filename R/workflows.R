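#' @name workflows
#' @title End-to-end workflow commands
#' @description File-in/file-out wrappers over the package's core
#'   operations, mirroring how the framework is driven from a shell: load
#'   inputs, run one pipeline stage, write TSV/JSON results. A thin
#'   command-line script over these functions ships in
#'   \code{inst/scripts/hnp-cli.R}. All commands are deterministic given
#'   (inputs, configuration, seed).
NULL

# "100:1000:100" or "100,200,300" -> integer vector
.parseGrid <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  if (grepl(":", spec)) {
    p <- as.integer(strsplit(spec, ":", fixed = TRUE)[[1L]])
    if (length(p) != 3L || anyNA(p)) stopf("grid spec must be from:to:by, got '%s'", spec)
    return(seq.int(p[1L], p[2L], by = p[3L]))
  }
  g <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1L]])
  if (anyNA(g)) stopf("cannot parse grid spec '%s'", spec)
  g
}

# Column-wise normalization policy for raw source tables: integer-valued
# columns are treated as literature counts (divide by max); columns already
# inside [0, 1] pass through with exact zeros replaced by epsilonZero;
# anything else is min-max scaled. A column of only 0/1 values is treated
# as qualitative (listed = 1).
.normalizeSourceColumn <- function(x, cfg) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) return(x)
  if (all(obs %in% c(0, 1))) {
    x[!is.na(x) & x == 0] <- cfg$epsilonMissing
    return(x)
  }
  if (all(obs >= 0) && all(obs == round(obs))) {
    m <- max(obs)
    if (m == 0) stopf("count column with all zeros cannot be normalized")
    x <- x / m
    x[!is.na(x) & x == 0] <- cfg$epsilonZero
    return(x)
  }
  if (all(obs >= 0 & obs <= 1)) {
    x[!is.na(x) & x == 0] <- cfg$epsilonZero
    return(x)
  }
  idx <- !is.na(x)
  x[idx] <- minmaxNormalizeSource(stats::setNames(x[idx], seq_len(sum(idx))), cfg)
  x
}

#' @rdname workflows
#' @param input path to a raw multi-source score TSV (column \code{symbol}
#'   plus one column per source; empty = missing).
#' @param mode "multiplicative" or "additive".
#' @param out output path.
#' @param cfg a [weightingConfig()].
#' @return \code{runIntegrate}: the \code{IntegratedScoreTable}, invisibly.
#' @export
runIntegrate <- function(input, mode = c("multiplicative", "additive"), out,
                         cfg = weightingConfig()) {
  mode <- match.arg(mode)
  raw <- readSourceScores(input)
  srcCols <- setdiff(names(raw), "symbol")
  for (cc in srcCols) raw[[cc]] <- .normalizeSourceColumn(raw[[cc]], cfg)
  res <- if (mode == "multiplicative") integrateMultiplicative(raw, cfg) else integrateAdditive(raw)
  writeIntegratedScores(res, out)
  invisible(res)
}

#' @rdname workflows
#' @param formulaFile,abundanceFile,catalogFile input TSV paths.
#' @param method herb-weighting method (1, 2 or 3).
#' @param multiplicity see [computeRawWeights()].
#' @return \code{runWeighHerb}: the herb
#'   \linkS4class{WeightedProteinSet}, invisibly.
#' @export
runWeighHerb <- function(formulaFile, abundanceFile, catalogFile, method = 3,
                         out, multiplicity = "per-compound",
                         cfg = weightingConfig()) {
  raw <- computeRawWeights(
    readFormula(formulaFile), readAbundance(abundanceFile),
    readCatalog(catalogFile),
    method = method, multiplicity = multiplicity
  )
  set <- normalizeWeights(raw, cfg)
  tab <- data.frame(
    protein = names(raw), raw_weight = unname(raw),
    norm_weight = unname(proteinWeights(set)[names(raw)])
  )
  .writeTsv(tab[order(-tab$norm_weight, tab$protein), ], out)
  invisible(set)
}

#' @rdname workflows
#' @param networkFile edge-list TSV.
#' @param herbWeightsFile weighted-set TSV (from \code{runWeighHerb} output
#'   columns or [writeWeightedSet()]).
#' @param diseaseScoresFile integrated score TSV (from \code{runIntegrate}).
#' @param topnGrid Top-N thresholds: integer vector or "from:to:by" string.
#' @param nPerm permutations per evaluation.
#' @param seed master seed.
#' @param minBinSize degree-bin size for the null model.
#' @param outTsv,outJson output paths (TSV of per-N rows; JSON summary).
#' @return \code{runEvaluate}: data frame of per-N results, invisibly;
#'   the JSON carries mean Z-scores across the Top-N grid.
#' @export
runEvaluate <- function(networkFile, herbWeightsFile, diseaseScoresFile,
                        topnGrid = "100:1000:100", nPerm = 500L, seed = 1L,
                        minBinSize = 100L, outTsv, outJson = NULL,
                        cfg = weightingConfig()) {
  net <- loadEdgeList(networkFile)
  herb <- restrictToNetwork(net, readWeightedSet(herbWeightsFile))
  scores <- readIntegratedScores(diseaseScoresFile)
  scores <- scores[scores$symbol %in% proteins(net), ]
  class(scores) <- c("IntegratedScoreTable", "data.frame")
  grid <- .parseGrid(topnGrid)
  if (any(grid > nrow(scores))) {
    stopf("Top-N grid exceeds the %d disease targets available on the network", nrow(scores))
  }
  bins <- buildDegreeBins(net, minBinSize)
  rows <- lapply(grid, function(n) {
    D <- topN(scores, n, cfg)
    pr <- nullZscore(net, herb, D,
      metric = "both", nPerm = nPerm,
      seed = deriveSeed(seed, n), bins = bins
    )
    data.frame(
      topN = n,
      coverage_overlap = metricValue(coverageOverlap(herb, D)),
      coverage_directlink = metricValue(coverageDirectlink(net, herb, D)),
      jaccard = metricValue(jaccardIndex(herb, D)),
      proximity_weighted = pr$weighted@sObs,
      z_weighted = zScore(pr$weighted),
      proximity_unweighted = pr$unweighted@sObs,
      z_unweighted = zScore(pr$unweighted)
    )
  })
  res <- do.call(rbind, rows)
  .writeTsv(res, outTsv)
  if (!is.null(outJson)) {
    writeLines(jsonlite::toJSON(list(
      topn_grid = grid, n_perm = nPerm, seed = seed,
      mean_z_weighted = mean(res$z_weighted),
      mean_z_unweighted = mean(res$z_unweighted)
    ), auto_unbox = TRUE, digits = NA), outJson)
  }
  invisible(res)
}

#' @rdname workflows
#' @param weightsFile weighted-set TSV.
#' @param alphas numeric vector of perturbation levels.
#' @param nSim simulations per alpha.
#' @param outLong,outSummary output TSVs (long: alpha/sim/rs; summary:
#'   alpha/mean_rs/sd_rs).
#' @return \code{runPerturb}: the \linkS4class{PerturbationResult},
#'   invisibly.
#' @export
runPerturb <- function(weightsFile, alphas = seq(0, 1, by = 0.1), nSim = 100L,
                       seed = 1L, outLong, outSummary = NULL) {
  w <- readWeightedSet(weightsFile)
  pr <- perturbationCurve(w, alphaGrid = alphas, nSim = nSim, seed = seed)
  long <- data.frame(
    alpha = rep(pr@alphaGrid, each = pr@nSim),
    sim = rep(seq_len(pr@nSim), times = length(pr@alphaGrid)),
    rs = as.vector(pr@rs)
  )
  .writeTsv(long, outLong)
  if (!is.null(outSummary)) {
    .writeTsv(data.frame(
      alpha = pr@alphaGrid,
      mean_rs = colMeans(pr@rs),
      sd_rs = apply(pr@rs, 2L, stats::sd)
    ), outSummary)
  }
  invisible(pr)
}

#' @rdname workflows
#' @param permGrid ascending permutation counts (vector or spec string).
#' @param nRepeats independent Z estimates per grid point.
#' @return \code{runConvergence}: the convergence data frame, invisibly.
#' @export
runConvergence <- function(networkFile, herbWeightsFile, diseaseScoresFile,
                           topn = 100L, permGrid = c(50L, 100L, 250L, 500L),
                           nRepeats = 20L, seed = 1L, minBinSize = 100L,
                           outTsv, cfg = weightingConfig()) {
  net <- loadEdgeList(networkFile)
  herb <- restrictToNetwork(net, readWeightedSet(herbWeightsFile))
  scores <- readIntegratedScores(diseaseScoresFile)
  scores <- scores[scores$symbol %in% proteins(net), ]
  class(scores) <- c("IntegratedScoreTable", "data.frame")
  D <- topN(scores, topn, cfg)
  res <- convergenceCurve(net, herb, D,
    metric = "weighted",
    permGrid = .parseGrid(permGrid), nRepeats = nRepeats,
    seed = seed, bins = buildDegreeBins(net, minBinSize)
  )
  .writeTsv(res, outTsv)
  invisible(res)
}

#' @rdname workflows
#' @param dir output directory for \code{runSimulate}.
#' @param ... passed to [simulationConfig()].
#' @return \code{runSimulate}: the generated objects, invisibly.
#' @export
runSimulate <- function(dir, ...) {
  simulateToDirectory(simulationConfig(...), dir)
}

#' @rdname workflows
#' @param setFileA,setFileB weighted-set TSVs to combine.
#' @param label label for the combined set.
#' @return \code{runCombine}: the combined set, invisibly.
#' @export
runCombine <- function(setFileA, setFileB, out, label = "combined") {
  combined <- combineInterventions(readWeightedSet(setFileA), readWeightedSet(setFileB), label = label)
  writeWeightedSet(combined, out)
  invisible(combined)
}
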