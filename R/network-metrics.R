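.metric <- function(name, value, counts) {
  methods::new("MetricValue", metric = name, value = value, counts = counts)
}

#' Direct-overlap coverage of a disease set
#'
#' Fraction of disease-associated proteins that are themselves targeted by
#' the intervention: \code{|H intersect D| / |D|}.
#'
#' @param H intervention protein symbols (character vector or
#'   \linkS4class{WeightedProteinSet}).
#' @param D nonempty disease protein symbols (likewise).
#' @return a \linkS4class{MetricValue}.
#' @export
coverageOverlap <- function(H, D) {
  H <- .asSymbols(H)
  D <- .asSymbols(D)
  if (length(D) == 0L) stopf("disease set must be nonempty")
  inter <- length(intersect(H, D))
  .metric(
    "coverage_overlap", inter / length(D),
    list(nH = length(H), nD = length(D), nIntersect = inter)
  )
}

#' Direct-link coverage of a disease set
#'
#' Fraction of disease proteins lying in the intervention set or its
#' first-degree network neighborhood:
#' \code{|D intersect (H union N(H))| / |D|}.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @inheritParams coverageOverlap
#' @return a \linkS4class{MetricValue}.
#' @export
coverageDirectlink <- function(net, H, D) {
  H <- .asSymbols(H)
  D <- .asSymbols(D)
  if (length(D) == 0L) stopf("disease set must be nonempty")
  reach <- union(H, neighborsOf(net, H))
  hit <- length(intersect(D, reach))
  .metric(
    "coverage_directlink", hit / length(D),
    list(nH = length(H), nD = length(D), nReachable = hit)
  )
}

#' Jaccard similarity of two protein sets
#'
#' \code{|H intersect D| / |H union D|}.
#'
#' @inheritParams coverageOverlap
#' @return a \linkS4class{MetricValue}.
#' @export
jaccardIndex <- function(H, D) {
  H <- .asSymbols(H)
  D <- .asSymbols(D)
  u <- union(H, D)
  if (length(u) == 0L) stopf("both sets are empty")
  inter <- length(intersect(H, D))
  .metric(
    "jaccard", inter / length(u),
    list(nH = length(H), nD = length(D), nIntersect = inter, nUnion = length(u))
  )
}

# closest-distance proximity from a distance matrix (rows = H, cols = D);
# Inf marks unreachable. Rows with no finite entry are dropped from both
# numerator and divisor.
.closestProximity <- function(dmat) {
  mins <- apply(dmat, 1L, min)
  usable <- is.finite(mins)
  if (!any(usable)) stopf("no intervention node can reach the disease set")
  list(
    value = mean(mins[usable]),
    nDropped = sum(!usable)
  )
}

# weighted all-pairs proximity from a distance matrix; unreachable pairs are
# excluded from both the weighted-distance sum and the weight-mass sum.
.weightedProximity <- function(dmat, wH, wD) {
  wmat <- outer(wH, wD)
  fin <- is.finite(dmat)
  if (!any(fin)) stopf("no reachable (intervention, disease) pair")
  list(
    value = sum(dmat[fin] * wmat[fin]) / sum(wmat[fin]),
    nDropped = sum(!fin)
  )
}

#' Unweighted network proximity (closest-distance measure)
#'
#' The mean over intervention nodes \code{h} of the minimum shortest-path
#' length to any disease node: \code{(1/|H|) sum_h min_d dist(h, d)}.
#' Intervention nodes that cannot reach any disease node are dropped from
#' both the sum and the divisor (counted in the result). The all-pairs
#' variant (\code{allPairs = TRUE}) instead averages \code{dist(h, d)} over
#' every reachable pair, for sensitivity checks against the closest
#' measure.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param H,D nonempty symbol vectors or \linkS4class{WeightedProteinSet}s,
#'   all members in the network.
#' @param allPairs use the all-pairs mean instead of the closest measure.
#' @param dmat optional precomputed distance matrix (rows H, cols D) from
#'   [shortestPathLengths()].
#' @return a \linkS4class{MetricValue}.
#' @export
proximityUnweighted <- function(net, H, D, allPairs = FALSE, dmat = NULL) {
  H <- .asSymbols(H)
  D <- .asSymbols(D)
  if (is.null(dmat)) dmat <- shortestPathLengths(net, H, D)
  if (allPairs) {
    fin <- is.finite(dmat)
    if (!any(fin)) stopf("no reachable (intervention, disease) pair")
    return(.metric(
      "proximity_unweighted_allpairs", mean(dmat[fin]),
      list(
        nH = length(H), nD = length(D),
        nPairs = sum(fin), nPairsDropped = sum(!fin)
      )
    ))
  }
  r <- .closestProximity(dmat)
  .metric(
    "proximity_unweighted", r$value,
    list(
      nH = length(H), nD = length(D),
      nSourcesUsed = length(H) - r$nDropped, nSourcesDropped = r$nDropped
    )
  )
}

#' Weighted network proximity
#'
#' All-pairs shortest-path distance averaged with node-weight products:
#' \code{sum_{h,d} dist(h,d) w_h w_d / sum_{h,d} w_h w_d}. Pairs of higher
#' biological relevance (large \code{w_h w_d}) dominate the average.
#' Unreachable pairs are excluded from both sums (counted in the result);
#' the denominator cannot vanish because all weights are strictly positive.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param H,D \linkS4class{WeightedProteinSet}s with members in the network.
#' @param dmat optional precomputed distance matrix (rows H, cols D).
#' @return a \linkS4class{MetricValue}.
#' @export
proximityWeighted <- function(net, H, D, dmat = NULL) {
  stopifnot(methods::is(H, "WeightedProteinSet"), methods::is(D, "WeightedProteinSet"))
  wH <- proteinWeights(H)
  wD <- proteinWeights(D)
  if (is.null(dmat)) dmat <- shortestPathLengths(net, names(wH), names(wD))
  r <- .weightedProximity(dmat, wH, wD)
  .metric(
    "proximity_weighted", r$value,
    list(
      nH = length(wH), nD = length(wD),
      nPairs = length(wH) * length(wD) - r$nDropped, nPairsDropped = r$nDropped
    )
  )
}
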