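#' Configuration of the synthetic benchmark generator
#'
#' Declares every distribution the generator draws from, so tests and
#' benchmarks state exactly what structure they assume. Defaults emulate,
#' at desk scale, the statistical shape of the framework's real inputs: a
#' heavy-tailed interactome, a connected disease module with right-skewed
#' weights (a few high-priority targets, many peripheral ones), Dirichlet
#' dosage ratios, log-normal compound abundances and Beta-distributed
#' interaction confidences.
#'
#' @param nNodes interactome size (>= 10; default 2000).
#' @param attachment edges added per node by preferential attachment
#'   (default 3, giving mean degree near 6 as in curated interactomes).
#' @param moduleSize disease-module size (default 150, < nNodes).
#' @param moduleShape1,moduleShape2 Beta shape parameters of raw module
#'   weights before (0, 1] normalization (default Beta(2, 5), right-skewed).
#' @param nHerbs herbs per formula (default 5).
#' @param dosageConcentration symmetric Dirichlet concentration of dosage
#'   ratios (default 2: moderately even formulas).
#' @param compoundsPerHerb compounds per herb (default 15).
#' @param targetsPerCompound catalog proteins per compound (default 8).
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters
#'   (default meanlog 0, sdlog 1).
#' @param interactionShape1,interactionShape2 Beta parameters of predicted
#'   interaction confidences (default Beta(2, 2)).
#' @param validatedFraction fraction of catalog entries flagged validated
#'   with P = 1 (default 0.2).
#' @param enrichment fraction of compound-protein edges forced into the
#'   disease module or its first neighbors (default 0.8; 0 gives a random
#'   "negative control" formula).
#' @param seed master seed.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nNodes = 2000L, attachment = 3L, moduleSize = 150L,
                             moduleShape1 = 2, moduleShape2 = 5,
                             nHerbs = 5L, dosageConcentration = 2,
                             compoundsPerHerb = 15L, targetsPerCompound = 8L,
                             abundanceMeanlog = 0, abundanceSdlog = 1,
                             interactionShape1 = 2, interactionShape2 = 2,
                             validatedFraction = 0.2, enrichment = 0.8,
                             seed = 1L) {
  cfg <- list(
    nNodes = as.integer(nNodes), attachment = as.integer(attachment),
    moduleSize = as.integer(moduleSize),
    moduleShape1 = moduleShape1, moduleShape2 = moduleShape2,
    nHerbs = as.integer(nHerbs), dosageConcentration = dosageConcentration,
    compoundsPerHerb = as.integer(compoundsPerHerb),
    targetsPerCompound = as.integer(targetsPerCompound),
    abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
    interactionShape1 = interactionShape1, interactionShape2 = interactionShape2,
    validatedFraction = validatedFraction, enrichment = enrichment,
    seed = as.integer(seed)
  )
  if (cfg$nNodes < 10L) stopf("nNodes must be >= 10")
  if (cfg$attachment < 1L || cfg$attachment >= cfg$nNodes) stopf("attachment must be in [1, nNodes)")
  if (cfg$moduleSize < 1L || cfg$moduleSize >= cfg$nNodes) stopf("moduleSize must be in [1, nNodes)")
  if (cfg$nHerbs < 1L || cfg$compoundsPerHerb < 1L || cfg$targetsPerCompound < 1L) {
    stopf("nHerbs, compoundsPerHerb and targetsPerCompound must be positive")
  }
  if (cfg$enrichment < 0 || cfg$enrichment > 1) stopf("enrichment must lie in [0, 1]")
  if (cfg$validatedFraction < 0 || cfg$validatedFraction > 1) stopf("validatedFraction must lie in [0, 1]")
  if (cfg$dosageConcentration <= 0) stopf("dosageConcentration must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate a connected scale-free interactome
#'
#' Preferential-attachment (Barabasi-Albert) graph: each new vertex attaches
#' to \code{attachment} existing vertices chosen proportionally to degree,
#' producing a connected graph with a heavy-tailed degree distribution. The
#' edge count is exactly \code{m(m-1)/2 + m(n-m)} for \code{m = attachment}
#' (early vertices attach to all vertices already present).
#'
#' @param cfg a [simulationConfig()].
#' @return an \linkS4class{InteractionNetwork} with nodes \code{P1..Pn};
#'   deterministic per seed.
#' @export
generateInteractome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  g <- withSeed(
    deriveSeed(cfg$seed, 11L),
    igraph::sample_pa(cfg$nNodes, m = cfg$attachment, directed = FALSE)
  )
  igraph::V(g)$name <- paste0("P", seq_len(cfg$nNodes))
  InteractionNetwork(g, metadata = list(generator = "preferential-attachment", config = unclass(cfg)))
}

#' Plant a connected, weighted disease module
#'
#' Grows a connected node subset by breadth-first expansion from a random
#' seed node, then draws raw weights from the configured Beta distribution
#' and normalizes them into (0, 1] with the smoothing-floor scaling.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param cfg a [simulationConfig()].
#' @param seed optional override of \code{cfg$seed}.
#' @return a \linkS4class{WeightedProteinSet} labelled
#'   \code{"disease-associated"} whose induced subgraph is connected.
#' @export
plantDiseaseModule <- function(net, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$moduleSize > networkSize(net)) stopf("moduleSize exceeds network size")
  withSeed(deriveSeed(seed, 23L), {
    root <- sample(proteins(net), 1L)
    ord <- as.integer(igraph::bfs(net@graph, root = root, unreachable = FALSE, order = TRUE)$order)
    ord <- ord[!is.na(ord)]
    if (length(ord) < cfg$moduleSize) {
      stopf("network component of the seed node is smaller than moduleSize")
    }
    members <- igraph::V(net@graph)$name[ord[seq_len(cfg$moduleSize)]]
    raw <- stats::rbeta(cfg$moduleSize, cfg$moduleShape1, cfg$moduleShape2)
    w <- .eq4Normalize(raw, weightingConfig()$epsilonNorm)
    names(w) <- members
    WeightedProteinSet(w, label = "disease-associated",
      metadata = list(root = root))
  })
}

#' Generate formula, abundance and interaction-catalog inputs
#'
#' Dirichlet dosage ratios, per-herb compound lists with log-normal
#' abundances, and a compound-protein catalog with Beta-distributed
#' confidences (a configured fraction validated at P = 1). A fraction
#' \code{cfg$enrichment} of catalog edges is placed inside the disease
#' module or its first neighbors -- module members are chosen with
#' probability proportional to their module weight (pure neighbors get the
#' module's minimum weight), emulating compounds that engage the core of
#' the disease module; the remaining edges land uniformly anywhere.
#' \code{enrichment = 0} yields a random-formula negative control.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param module a \linkS4class{WeightedProteinSet} inside \code{net}.
#' @param cfg a [simulationConfig()].
#' @param seed optional override of \code{cfg$seed}.
#' @return list with elements \code{formula}
#'   ([formulaComposition()]), \code{abundance}
#'   ([compoundAbundanceTable()]) and \code{catalog}
#'   ([interactionCatalog()]).
#' @export
generateFormulaInputs <- function(net, module, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"), methods::is(module, "WeightedProteinSet"))
  if (length(module) == 0L) stopf("module must be nonempty")
  withSeed(deriveSeed(seed, 37L), {
    herbs <- paste0("herb", seq_len(cfg$nHerbs))
    gam <- stats::rgamma(cfg$nHerbs, shape = cfg$dosageConcentration)
    fo <- formulaComposition(herbs, gam / sum(gam), name = "synthetic-formula")

    herbCol <- rep(herbs, each = cfg$compoundsPerHerb)
    compCol <- paste0(herbCol, "_c", rep(seq_len(cfg$compoundsPerHerb), times = cfg$nHerbs))
    ab <- compoundAbundanceTable(
      herbCol, compCol,
      stats::rlnorm(length(compCol), cfg$abundanceMeanlog, cfg$abundanceSdlog)
    )

    moduleSyms <- proteins(module)
    moduleW <- proteinWeights(module)
    pool <- union(moduleSyms, neighborsOf(net, moduleSyms))
    poolW <- ifelse(pool %in% moduleSyms, moduleW[pool], mean(moduleW))
    allNodes <- proteins(net)

    rows <- lapply(unique(compCol), function(cc) {
      k <- cfg$targetsPerCompound
      nEnr <- stats::rbinom(1L, k, cfg$enrichment)
      enr <- if (nEnr > 0L) {
        sample(pool, min(nEnr, length(pool)), prob = poolW)
      } else {
        character(0)
      }
      rest <- sample(allNodes, k - length(enr))
      prots <- unique(c(enr, rest))
      data.frame(compound = cc, protein = prots, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    p <- stats::rbeta(nrow(tab), cfg$interactionShape1, cfg$interactionShape2)
    validated <- stats::runif(nrow(tab)) < cfg$validatedFraction
    p[validated] <- 1.0
    cat <- interactionCatalog(
      tab$compound, tab$protein, p,
      provenance = ifelse(validated, "validated", "predicted")
    )
    list(formula = fo, abundance = ab, catalog = cat)
  })
}

#' Generate multi-source disease-target score tables with known truth
#'
#' Each quantitative source is a rank-preserving noisy copy of the true
#' module weights: independent Gaussian noise with standard deviation
#' \code{noiseSd} is added on the logit scale and mapped back to (0, 1).
#' Each source independently drops targets at \code{missingRate}
#' (\code{NA} = unlisted). The last source is rendered qualitative
#' (1.0 for listed targets, \code{NA} otherwise) to exercise the
#' listed/unlisted scoring path. Proteins outside the truth set are
#' unlisted everywhere.
#'
#' @param truth a \linkS4class{WeightedProteinSet} of true target weights.
#' @param universe character vector of all symbols (contains the truth set).
#' @param noiseSd logit-scale noise standard deviation.
#' @param missingRate per-source probability that a true target is unlisted.
#' @param nSources number of source columns (>= 2; the last is qualitative).
#' @param seed integer seed.
#' @return data frame with column \code{symbol} and columns
#'   \code{source1..sourceK}; attribute \code{qualitative} names the
#'   qualitative column.
#' @export
generateSourceScores <- function(truth, universe, noiseSd = 0.1,
                                 missingRate = 0.1, nSources = 5L, seed = 1L) {
  stopifnot(methods::is(truth, "WeightedProteinSet"))
  nSources <- as.integer(nSources)
  if (nSources < 2L) stopf("need at least 2 sources")
  tw <- proteinWeights(truth)
  if (length(setdiff(names(tw), universe))) stopf("truth set must lie inside the universe")
  lw <- stats::qlogis(pmin(pmax(tw, 1e-6), 1 - 1e-6))
  out <- data.frame(symbol = universe, stringsAsFactors = FALSE)
  for (s in seq_len(nSources)) {
    col <- rep(NA_real_, length(universe))
    names(col) <- universe
    withSeed(deriveSeed(seed, 53L, s), {
      listed <- names(tw)[stats::runif(length(tw)) >= missingRate]
      if (length(listed)) {
        if (s == nSources) {
          col[listed] <- 1.0
        } else {
          col[listed] <- stats::plogis(lw[listed] + stats::rnorm(length(listed), sd = noiseSd))
        }
      }
    })
    out[[paste0("source", s)]] <- unname(col)
  }
  attr(out, "qualitative") <- paste0("source", nSources)
  out
}
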