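#' Undirected protein-protein interaction network
#'
#' Wraps a simple undirected \pkg{igraph} graph over protein symbols.
#' Validity enforces the interactome contract: undirected, no self-loops,
#' no duplicate edges, named vertices with unique symbols.
#'
#' @slot graph an undirected simple \pkg{igraph} graph with a \code{name}
#'   vertex attribute.
#' @slot metadata list of loading diagnostics (dropped self-loops, merged
#'   duplicates, unmapped identifiers).
#' @seealso [loadEdgeList()], [shortestPathLengths()], [neighborsOf()]
#' @export
setClass("InteractionNetwork",
  slots = c(graph = "ANY", metadata = "list"),
  prototype = list(metadata = list())
)

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (igraph::vcount(g) == 0L) return("network must contain at least one node")
  if (is.null(igraph::V(g)$name)) return("vertices must carry protein symbols")
  if (anyDuplicated(igraph::V(g)$name)) return("protein symbols must be unique")
  if (any(igraph::which_loop(g))) return("self-loops are not allowed")
  if (any(igraph::which_multiple(g))) return("duplicate edges are not allowed")
  TRUE
})

#' Construct an InteractionNetwork from an edge data frame or igraph graph
#'
#' Self-loops are removed and duplicate (parallel) edges merged, with counts
#' recorded in \code{metadata}; the file-based loader [loadEdgeList()]
#' builds on this.
#'
#' @param edges two-column data frame (or matrix) of symbol pairs, or an
#'   igraph graph with named vertices.
#' @param metadata optional list of loading diagnostics.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
#' @examples
#' net <- InteractionNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' networkSize(net)
InteractionNetwork <- function(edges, metadata = list()) {
  if (igraph::is_igraph(edges)) {
    g <- edges
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) != 2L) stopf("edge table must have exactly 2 columns, got %d", ncol(edges))
    if (nrow(edges) == 0L) stopf("edge table is empty")
    edges[[1L]] <- as.character(edges[[1L]])
    edges[[2L]] <- as.character(edges[[2L]])
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  nLoops <- sum(igraph::which_loop(g))
  nMulti <- sum(igraph::which_multiple(g))
  if (nLoops + nMulti > 0L) {
    g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
    hnpLog("removed %d self-loop(s) and merged %d duplicate edge(s)", nLoops, nMulti)
  }
  if (igraph::vcount(g) == 0L) stopf("network is empty after cleaning")
  metadata$selfLoopsRemoved <- nLoops
  metadata$duplicatesMerged <- nMulti
  methods::new("InteractionNetwork", graph = g, metadata = metadata)
}

#' @describeIn InteractionNetwork-class protein symbols (vertex names)
#' @param x,object an \linkS4class{InteractionNetwork}.
#' @export
setMethod("proteins", "InteractionNetwork", function(x) igraph::V(x@graph)$name)

#' Number of proteins in a network
#' @param net an \linkS4class{InteractionNetwork}.
#' @return integer node count.
#' @export
networkSize <- function(net) igraph::vcount(net@graph)

#' Number of undirected interactions in a network
#' @param net an \linkS4class{InteractionNetwork}.
#' @return integer edge count.
#' @export
networkEdgeCount <- function(net) igraph::gsize(net@graph)

#' Node degrees
#' @param net an \linkS4class{InteractionNetwork}.
#' @param symbols optional subset of symbols; default all nodes.
#' @return named integer vector of degrees.
#' @export
degreeOf <- function(net, symbols = NULL) {
  d <- igraph::degree(net@graph)
  if (!is.null(symbols)) {
    missing <- setdiff(symbols, names(d))
    if (length(missing)) stopf("unknown protein(s): %s", paste(utils::head(missing, 5), collapse = ", "))
    d <- d[symbols]
  }
  storage.mode(d) <- "integer"
  d
}

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf(
    "InteractionNetwork: %d proteins, %d undirected interactions\n",
    networkSize(object), networkEdgeCount(object)
  ))
})

#' Node set with strictly positive weights in (0, 1]
#'
#' Carries herb-related or disease-associated proteins together with their
#' normalized node weights, the currency of the weighted proximity metric.
#'
#' @slot weights named numeric vector; names are protein symbols, values lie
#'   in (0, 1].
#' @slot label character scalar describing the set's provenance
#'   (e.g. "herb-related", "disease-associated").
#' @slot metadata list of diagnostics (e.g. members dropped when restricting
#'   to a network).
#' @seealso [normalizeWeights()], [topN()], [restrictToNetwork()]
#' @export
setClass("WeightedProteinSet",
  slots = c(weights = "numeric", label = "character", metadata = "list"),
  prototype = list(label = "protein-set", metadata = list())
)

setValidity("WeightedProteinSet", function(object) {
  w <- object@weights
  if (length(w) == 0L) return("weighted set must be nonempty")
  if (is.null(names(w)) || any(!nzchar(names(w)))) return("weights must be named by protein symbol")
  if (anyDuplicated(names(w))) return("protein symbols must be unique")
  if (anyNA(w) || any(w <= 0) || any(w > 1)) return("weights must lie in (0, 1]")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Construct a WeightedProteinSet
#' @param weights named numeric vector of weights in (0, 1].
#' @param label provenance label.
#' @param metadata optional diagnostics list.
#' @return a \linkS4class{WeightedProteinSet}.
#' @export
#' @examples
#' WeightedProteinSet(c(SNCA = 1, TH = 0.4), label = "disease-associated")
WeightedProteinSet <- function(weights, label = "protein-set", metadata = list()) {
  methods::new("WeightedProteinSet",
    weights = weights, label = as.character(label),
    metadata = metadata
  )
}

#' @describeIn WeightedProteinSet-class member symbols
#' @param x a \linkS4class{WeightedProteinSet}.
#' @export
setMethod("proteins", "WeightedProteinSet", function(x) names(x@weights))

#' @describeIn WeightedProteinSet-class named weight vector
#' @export
setMethod("proteinWeights", "WeightedProteinSet", function(x) x@weights)

#' @describeIn WeightedProteinSet-class provenance label
#' @export
setMethod("setLabel", "WeightedProteinSet", function(x) x@label)

#' @describeIn WeightedProteinSet-class number of members
#' @export
setMethod("length", "WeightedProteinSet", function(x) length(x@weights))

setMethod("show", "WeightedProteinSet", function(object) {
  w <- object@weights
  cat(sprintf(
    "WeightedProteinSet (%s): %d proteins, weights in [%.3g, %.3g]\n",
    object@label, length(w), min(w), max(w)
  ))
})

#' Degree binning for degree-aware null sampling
#'
#' Partitions the nodes of a network into degree intervals; random reference
#' sets are drawn bin by bin so null node sets preserve the degree profile of
#' the observed set. Bins start log2-spaced and sparse bins are merged upward
#' until every bin holds at least \code{minBinSize} nodes.
#'
#' @slot bins list of character vectors, one per bin, jointly partitioning
#'   the network's nodes.
#' @slot binOf named integer vector mapping every symbol to its bin index.
#' @slot binRanges two-column integer matrix of the inclusive degree range
#'   covered by each bin.
#' @slot minBinSize integer; minimum nodes per bin after merging.
#' @seealso [buildDegreeBins()], [sampleDegreeMatched()]
#' @export
setClass("DegreeBinning",
  slots = c(
    bins = "list", binOf = "integer",
    binRanges = "matrix", minBinSize = "integer"
  )
)

setValidity("DegreeBinning", function(object) {
  sizes <- lengths(object@bins)
  if (any(sizes < object@minBinSize)) return("every bin must hold >= minBinSize nodes")
  all_members <- unlist(object@bins, use.names = FALSE)
  if (anyDuplicated(all_members)) return("bins must be disjoint")
  if (!setequal(all_members, names(object@binOf))) return("binOf must cover exactly the binned nodes")
  TRUE
})

setMethod("show", "DegreeBinning", function(object) {
  cat(sprintf(
    "DegreeBinning: %d bins over %d nodes (min bin size %d)\n",
    length(object@bins), length(object@binOf), object@minBinSize
  ))
})

#' Value of a single network metric evaluation
#'
#' @slot metric metric name ("coverage_overlap", "jaccard",
#'   "proximity_weighted", ...).
#' @slot value numeric metric value.
#' @slot counts named list of bookkeeping counts: set sizes, pairs evaluated,
#'   pairs or source nodes dropped as unreachable.
#' @export
setClass("MetricValue",
  slots = c(metric = "character", value = "numeric", counts = "list")
)

#' @describeIn MetricValue-class numeric value
#' @param x a \linkS4class{MetricValue}.
#' @export
setMethod("metricValue", "MetricValue", function(x) x@value)

#' @describeIn MetricValue-class bookkeeping counts
#' @export
setMethod("metricCounts", "MetricValue", function(x) x@counts)

setMethod("show", "MetricValue", function(object) {
  cat(sprintf("MetricValue [%s]: %.6g\n", object@metric, object@value))
})

#' Result of a degree-aware permutation test
#'
#' Holds the observed metric, the permutation null summary and the Z-score
#' \code{(sObs - muRand) / sigmaRand}; negative Z means the intervention set
#' sits closer to the disease module than degree-matched chance.
#'
#' @slot metric metric name.
#' @slot sObs observed metric value.
#' @slot muRand mean of the permutation null.
#' @slot sigmaRand sample (n-1) standard deviation of the null.
#' @slot zscore the Z-score.
#' @slot nPerm number of permutations.
#' @slot seed master seed used for the null draws.
#' @slot nullSample the retained null metric values.
#' @slot counts diagnostics from the observed evaluation.
#' @seealso [nullZscore()]
#' @export
setClass("ProximityResult",
  slots = c(
    metric = "character", sObs = "numeric", muRand = "numeric",
    sigmaRand = "numeric", zscore = "numeric", nPerm = "integer",
    seed = "integer", nullSample = "numeric", counts = "list"
  )
)

setValidity("ProximityResult", function(object) {
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  if (length(object@nullSample) && length(object@nullSample) != object@nPerm) {
    return("retained null sample must have nPerm values")
  }
  if (is.finite(object@sigmaRand) && object@sigmaRand > 0) {
    z <- (object@sObs - object@muRand) / object@sigmaRand
    if (abs(z - object@zscore) > 1e-8) return("zscore inconsistent with null summary")
  }
  TRUE
})

#' @describeIn ProximityResult-class observed metric value
#' @param x a \linkS4class{ProximityResult}.
#' @export
setMethod("metricValue", "ProximityResult", function(x) x@sObs)

#' @describeIn ProximityResult-class observed-evaluation counts
#' @export
setMethod("metricCounts", "ProximityResult", function(x) x@counts)

#' @describeIn ProximityResult-class permutation Z-score
#' @export
setMethod("zScore", "ProximityResult", function(x) x@zscore)

#' @describeIn ProximityResult-class null metric values
#' @export
setMethod("nullValues", "ProximityResult", function(x) x@nullSample)

setMethod("show", "ProximityResult", function(object) {
  cat(sprintf(
    "ProximityResult [%s]: S_obs = %.4f, null %.4f +/- %.4f (n_perm = %d), Z = %.3f\n",
    object@metric, object@sObs, object@muRand, object@sigmaRand,
    object@nPerm, object@zscore
  ))
})

#' Weight-perturbation sensitivity result
#'
#' Spearman rank stability of a node-weight vector under convex mixing with
#' uniform noise, over an alpha grid and repeated simulations.
#'
#' @slot alphaGrid ascending perturbation levels in [0, 1].
#' @slot rs matrix of Spearman correlations, simulations x alpha levels.
#' @slot nSim simulations per alpha.
#' @slot seed master seed.
#' @seealso [perturbationCurve()]
#' @export
setClass("PerturbationResult",
  slots = c(alphaGrid = "numeric", rs = "matrix", nSim = "integer", seed = "integer")
)

setValidity("PerturbationResult", function(object) {
  if (is.unsorted(object@alphaGrid, strictly = FALSE)) return("alphaGrid must be ascending")
  if (any(object@alphaGrid < 0 | object@alphaGrid > 1)) return("alpha values must lie in [0, 1]")
  if (ncol(object@rs) != length(object@alphaGrid)) return("rs must have one column per alpha")
  if (nrow(object@rs) != object@nSim) return("rs must have one row per simulation")
  if (any(abs(object@rs) > 1 + 1e-12)) return("Spearman values must lie in [-1, 1]")
  TRUE
})

#' Mean rank stability per perturbation level
#' @param x a \linkS4class{PerturbationResult}.
#' @return named numeric vector, mean Rs per alpha.
#' @export
meanRs <- function(x) {
  stopifnot(methods::is(x, "PerturbationResult"))
  stats::setNames(colMeans(x@rs), format(x@alphaGrid))
}

setMethod("show", "PerturbationResult", function(object) {
  m <- colMeans(object@rs)
  cat(sprintf(
    "PerturbationResult: %d alphas in [%.2f, %.2f], %d sims; mean Rs %.3f -> %.3f\n",
    length(object@alphaGrid), min(object@alphaGrid), max(object@alphaGrid),
    object@nSim, m[1L], m[length(m)]
  ))
})
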