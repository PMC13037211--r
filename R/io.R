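.writeTsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = col.names
  )
  invisible(path)
}

.readTsv <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write a network as a normalized two-column edge list
#'
#' Edges are written with endpoints in lexicographic order and rows sorted,
#' so writing and re-loading reproduces an identical network.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- igraph::as_edgelist(net@graph)
  a <- pmin(e[, 1L], e[, 2L])
  b <- pmax(e[, 1L], e[, 2L])
  ord <- order(a, b)
  .writeTsv(data.frame(a = a[ord], b = b[ord]), path, col.names = FALSE)
}

#' Read / write a formula composition table
#'
#' TSV with header columns \code{herb}, \code{ratio}.
#' @param path TSV path.
#' @return [readFormula()] returns a [formulaComposition()].
#' @export
readFormula <- function(path) {
  tab <- .readTsv(path, "formula")
  if (!all(c("herb", "ratio") %in% names(tab))) stopf("formula file needs columns herb, ratio")
  formulaComposition(tab$herb, tab$ratio)
}

#' @rdname readFormula
#' @param formula a [formulaComposition()].
#' @export
writeFormula <- function(formula, path) {
  .writeTsv(as.data.frame(formula)[c("herb", "ratio")], path)
}

#' Read / write a compound-abundance table
#'
#' TSV with header columns \code{herb}, \code{compound}, \code{abundance}.
#' @param path TSV path.
#' @return [readAbundance()] returns a [compoundAbundanceTable()].
#' @export
readAbundance <- function(path) {
  tab <- .readTsv(path, "abundance")
  need <- c("herb", "compound", "abundance")
  if (!all(need %in% names(tab))) stopf("abundance file needs columns %s", paste(need, collapse = ", "))
  compoundAbundanceTable(tab$herb, tab$compound, tab$abundance)
}

#' @rdname readAbundance
#' @param abundance a [compoundAbundanceTable()].
#' @export
writeAbundance <- function(abundance, path) {
  .writeTsv(as.data.frame(abundance)[c("herb", "compound", "abundance")], path)
}

#' Read / write a compound-protein interaction catalog
#'
#' TSV with header columns \code{compound}, \code{protein},
#' \code{probability}, \code{provenance}.
#' @param path TSV path.
#' @return [readCatalog()] returns an [interactionCatalog()].
#' @export
readCatalog <- function(path) {
  tab <- .readTsv(path, "catalog")
  need <- c("compound", "protein", "probability", "provenance")
  if (!all(need %in% names(tab))) stopf("catalog file needs columns %s", paste(need, collapse = ", "))
  interactionCatalog(tab$compound, tab$protein, tab$probability, tab$provenance)
}

#' @rdname readCatalog
#' @param catalog an [interactionCatalog()].
#' @export
writeCatalog <- function(catalog, path) {
  .writeTsv(as.data.frame(catalog)[c("compound", "protein", "probability", "provenance")], path)
}

#' Read / write a multi-source score table
#'
#' TSV with header: a \code{symbol} column plus one column per source;
#' empty fields are missing scores.
#' @param path TSV path.
#' @return [readSourceScores()] returns the score data frame.
#' @export
readSourceScores <- function(path) {
  tab <- .readTsv(path, "source score")
  if (!"symbol" %in% names(tab)) stopf("source score file needs a 'symbol' column")
  tab
}

#' @rdname readSourceScores
#' @param table score data frame (column \code{symbol} + source columns).
#' @export
writeSourceScores <- function(table, path) .writeTsv(table, path)

#' Read / write an integrated score table
#'
#' TSV with header columns \code{symbol}, \code{score}, \code{rank}; the
#' integration scheme is carried in a \code{# scheme:} comment line.
#' @param path TSV path.
#' @return [readIntegratedScores()] returns an \code{IntegratedScoreTable}.
#' @export
readIntegratedScores <- function(path) {
  if (!file.exists(path)) stopf("integrated score file not found: %s", path)
  first <- readLines(path, n = 1L)
  scheme <- if (grepl("^# scheme:", first)) sub("^# scheme:\\s*", "", first) else "unknown"
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("symbol", "score", "rank") %in% names(tab))) {
    stopf("integrated score file needs columns symbol, score, rank")
  }
  attr(tab, "scheme") <- scheme
  class(tab) <- c("IntegratedScoreTable", "data.frame")
  tab
}

#' @rdname readIntegratedScores
#' @param table an \code{IntegratedScoreTable}.
#' @export
writeIntegratedScores <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme: %s", attr(table, "scheme")), con)
  utils::write.table(as.data.frame(table)[c("symbol", "score", "rank")], con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read / write a weighted protein set
#'
#' TSV with header columns \code{protein}, \code{weight}; the label is
#' carried in a \code{# label:} comment line.
#' @param path TSV path.
#' @return [readWeightedSet()] returns a \linkS4class{WeightedProteinSet}.
#' @export
readWeightedSet <- function(path) {
  if (!file.exists(path)) stopf("weighted set file not found: %s", path)
  first <- readLines(path, n = 1L)
  label <- if (grepl("^# label:", first)) sub("^# label:\\s*", "", first) else "protein-set"
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  # also accepts the protein/raw_weight/norm_weight layout of runWeighHerb
  if (all(c("protein", "norm_weight") %in% names(tab)) && !"weight" %in% names(tab)) {
    tab$weight <- tab$norm_weight
  }
  if (!all(c("protein", "weight") %in% names(tab))) {
    stopf("weighted set file needs columns protein, weight")
  }
  WeightedProteinSet(stats::setNames(tab$weight, tab$protein), label = label)
}

#' @rdname readWeightedSet
#' @param set a \linkS4class{WeightedProteinSet}.
#' @export
writeWeightedSet <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", setLabel(set)), con)
  w <- proteinWeights(set)
  utils::write.table(data.frame(protein = names(w), weight = unname(w)), con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Serialize a metric or permutation result as a JSON record
#'
#' @param x a \linkS4class{MetricValue} or \linkS4class{ProximityResult}.
#' @param path optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
resultToJson <- function(x, path = NULL) {
  rec <- if (methods::is(x, "ProximityResult")) {
    list(
      metric = x@metric, S_obs = x@sObs, mu_rand = x@muRand,
      sigma_rand = x@sigmaRand, zscore = x@zscore, n_perm = x@nPerm,
      seed = x@seed, counts = x@counts
    )
  } else if (methods::is(x, "MetricValue")) {
    list(metric = x@metric, value = x@value, counts = x@counts)
  } else {
    stopf("cannot serialize objects of class %s", class(x)[1L])
  }
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits the standard TSVs (edge list, formula, abundance, catalog, source
#' scores, disease module) plus a JSON manifest recording the configuration
#' and seed, so a benchmark run is fully auditable from its input directory.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the generated objects.
#' @export
simulateToDirectory <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generateInteractome(cfg)
  module <- plantDiseaseModule(net, cfg)
  inputs <- generateFormulaInputs(net, module, cfg)
  scores <- generateSourceScores(module, proteins(net), seed = deriveSeed(cfg$seed, 53L))
  writeEdgeList(net, file.path(dir, "edges.tsv"))
  writeFormula(inputs$formula, file.path(dir, "formula.tsv"))
  writeAbundance(inputs$abundance, file.path(dir, "abundance.tsv"))
  writeCatalog(inputs$catalog, file.path(dir, "catalog.tsv"))
  writeSourceScores(scores, file.path(dir, "source_scores.tsv"))
  writeWeightedSet(module, file.path(dir, "disease_module.tsv"))
  manifest <- list(
    tool = "HerbNetProx",
    version = as.character(utils::packageVersion("HerbNetProx")),
    config = unclass(cfg),
    files = c(
      "edges.tsv", "formula.tsv", "abundance.tsv", "catalog.tsv",
      "source_scores.tsv", "disease_module.tsv"
    )
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(dir, "manifest.json")
  )
  invisible(list(
    network = net, module = module, formula = inputs$formula,
    abundance = inputs$abundance, catalog = inputs$catalog, scores = scores
  ))
}
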