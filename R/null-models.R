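#' Draw a degree-matched random protein set
#'
#' Replaces every member of \code{reference} with a node drawn uniformly,
#' without replacement, from that member's degree bin; the sampled node
#' inherits the weight of the node it replaces, so the weight multiset of
#' the null set equals that of the reference set.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param reference a \linkS4class{WeightedProteinSet} inside the network.
#' @param bins a \linkS4class{DegreeBinning} of \code{net}.
#' @param seed optional integer; when \code{NULL} the current RNG stream is
#'   used.
#' @return a \linkS4class{WeightedProteinSet} of the same size and weight
#'   multiset as \code{reference}.
#' @export
sampleDegreeMatched <- function(net, reference, bins, seed = NULL) {
  stopifnot(methods::is(reference, "WeightedProteinSet"), methods::is(bins, "DegreeBinning"))
  refSyms <- proteins(reference)
  out <- setdiff(refSyms, proteins(net))
  if (length(out)) stopf("reference node(s) not in network: %s", paste(utils::head(out, 5), collapse = ", "))
  draw <- function() .sampleFromBins(bins, refSyms)
  sampled <- if (is.null(seed)) draw() else withSeed(seed, draw())
  w <- proteinWeights(reference)
  names(w) <- sampled
  WeightedProteinSet(w, label = paste0("null:", setLabel(reference)))
}

# one degree-matched draw; returns sampled symbols aligned with refSyms
.sampleFromBins <- function(bins, refSyms) {
  b <- bins@binOf[refSyms]
  if (anyNA(b)) stopf("reference node(s) missing from the degree binning")
  out <- character(length(refSyms))
  for (bi in unique(b)) {
    idx <- which(b == bi)
    pool <- bins@bins[[bi]]
    if (length(pool) < length(idx)) {
      stopf(
        "degree bin %d holds %d nodes but must supply %d replacements; rebuild bins with a larger minBinSize",
        bi, length(pool), length(idx)
      )
    }
    out[idx] <- sample(pool, length(idx))
  }
  out
}

# shared evaluation context: distances from every network node to the fixed
# disease set are computed once (BFS from each disease node), so each
# permutation reduces to indexing rows of one matrix.
.nullEngine <- function(net, H, D, bins, allPairs = FALSE) {
  if (!methods::is(H, "WeightedProteinSet")) {
    H <- WeightedProteinSet(stats::setNames(rep(1, length(H)), .asSymbols(H)), label = "herb-related")
  }
  if (!methods::is(D, "WeightedProteinSet")) {
    D <- WeightedProteinSet(stats::setNames(rep(1, length(D)), .asSymbols(D)), label = "disease-associated")
  }
  nodes <- proteins(net)
  out <- setdiff(c(proteins(H), proteins(D)), nodes)
  if (length(out)) {
    stopf(
      "set member(s) not in network (restrictToNetwork first): %s",
      paste(utils::head(out, 5), collapse = ", ")
    )
  }
  dmatAll <- t(igraph::distances(net@graph, v = proteins(D), to = igraph::V(net@graph), algorithm = "unweighted"))
  rownames(dmatAll) <- nodes
  colnames(dmatAll) <- proteins(D)
  list(
    H = H, D = D, bins = bins, dmatAll = dmatAll, allPairs = allPairs,
    wH = proteinWeights(H), wD = proteinWeights(D)
  )
}

# both metric values for a given intervention-side symbol vector whose
# weights are `w` (aligned with syms)
.engineMetrics <- function(ctx, syms, w) {
  dmat <- ctx$dmatAll[syms, , drop = FALSE]
  if (ctx$allPairs) {
    fin <- is.finite(dmat)
    unw <- mean(dmat[fin])
  } else {
    unw <- .closestProximity(dmat)$value
  }
  c(
    weighted = .weightedProximity(dmat, w, ctx$wD)$value,
    unweighted = unw
  )
}

.engineNullDraws <- function(ctx, nPerm, seed) {
  refSyms <- proteins(ctx$H)
  vals <- matrix(NA_real_, nrow = nPerm, ncol = 2L,
                 dimnames = list(NULL, c("weighted", "unweighted")))
  for (p in seq_len(nPerm)) {
    syms <- withSeed(deriveSeed(seed, 104729L, p), .sampleFromBins(ctx$bins, refSyms))
    vals[p, ] <- .engineMetrics(ctx, syms, ctx$wH)
  }
  vals
}

.proximityResult <- function(metricName, sObs, nulls, nPerm, seed, counts) {
  mu <- mean(nulls)
  sg <- stats::sd(nulls)
  if (!is.finite(sg) || sg == 0) stopf("degenerate null distribution (sd = 0) for %s", metricName)
  methods::new("ProximityResult",
    metric = metricName, sObs = sObs, muRand = mu, sigmaRand = sg,
    zscore = (sObs - mu) / sg, nPerm = as.integer(nPerm),
    seed = as.integer(seed), nullSample = as.numeric(nulls), counts = counts
  )
}

#' Permutation Z-score of network proximity against a degree-aware null
#'
#' Computes the observed proximity between intervention set \code{H} and
#' disease set \code{D}, then \code{nPerm} null values in which the
#' intervention side is replaced by degree-matched random sets (weights
#' inherited; the disease side stays fixed). The Z-score is
#' \code{(S_obs - mu_rand) / sigma_rand} with the sample (n-1) standard
#' deviation; negative Z means closer to the disease module than
#' degree-matched chance. When both metrics are requested they are scored
#' on the same null sets, so their Z-scores are paired.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param H intervention set (\linkS4class{WeightedProteinSet}; a character
#'   vector is taken with uniform weight 1).
#' @param D disease set (likewise).
#' @param metric "weighted", "unweighted", or "both".
#' @param nPerm number of permutations (default 500).
#' @param seed master seed; every permutation derives its own substream.
#' @param bins optional \linkS4class{DegreeBinning}; defaults to
#'   \code{buildDegreeBins(net)}.
#' @param randomizeBoth also degree-match-resample the disease side in each
#'   permutation (off by default; fixing the disease module is the
#'   convention in proximity work).
#' @param allPairs score the unweighted metric with the all-pairs mean
#'   instead of the closest measure.
#' @return a \linkS4class{ProximityResult}, or a named list of two (for
#'   \code{metric = "both"}).
#' @export
nullZscore <- function(net, H, D, metric = c("both", "weighted", "unweighted"),
                       nPerm = 500L, seed = 1L, bins = NULL,
                       randomizeBoth = FALSE, allPairs = FALSE) {
  metric <- match.arg(metric)
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stopf("nPerm must be >= 1")
  if (is.null(bins)) bins <- buildDegreeBins(net)
  ctx <- .nullEngine(net, H, D, bins, allPairs = allPairs)
  obs <- .engineMetrics(ctx, proteins(ctx$H), ctx$wH)
  if (randomizeBoth) {
    nulls <- matrix(NA_real_, nrow = nPerm, ncol = 2L,
                    dimnames = list(NULL, c("weighted", "unweighted")))
    refH <- proteins(ctx$H)
    refD <- proteins(ctx$D)
    for (p in seq_len(nPerm)) {
      sampled <- withSeed(
        deriveSeed(seed, 104729L, p),
        list(h = .sampleFromBins(bins, refH), d = .sampleFromBins(bins, refD))
      )
      dsub <- igraph::distances(net@graph, v = sampled$h, to = sampled$d, algorithm = "unweighted")
      unw <- if (allPairs) mean(dsub[is.finite(dsub)]) else .closestProximity(dsub)$value
      nulls[p, ] <- c(
        weighted = .weightedProximity(dsub, ctx$wH, ctx$wD)$value,
        unweighted = unw
      )
    }
  } else {
    nulls <- .engineNullDraws(ctx, nPerm, seed)
  }
  countsW <- metricCounts(proximityWeighted(net, ctx$H, ctx$D,
    dmat = ctx$dmatAll[proteins(ctx$H), , drop = FALSE]
  ))
  countsU <- list(nH = length(ctx$wH), nD = length(ctx$wD))
  res <- list(
    weighted = function() .proximityResult("proximity_weighted", obs[["weighted"]], nulls[, "weighted"], nPerm, seed, countsW),
    unweighted = function() {
      .proximityResult(
        if (allPairs) "proximity_unweighted_allpairs" else "proximity_unweighted",
        obs[["unweighted"]], nulls[, "unweighted"], nPerm, seed, countsU
      )
    }
  )
  switch(metric,
    both = list(weighted = res$weighted(), unweighted = res$unweighted()),
    weighted = res$weighted(),
    unweighted = res$unweighted()
  )
}

#' Z-score stability as a function of permutation count
#'
#' For each permutation count in \code{permGrid}, computes
#' \code{nRepeats} independent Z-score estimates (each with its own null
#' draws) and reports their spread; the spread shrinks as the null sample
#' grows, showing how many permutations are needed for stable Z-scores.
#'
#' @inheritParams nullZscore
#' @param permGrid ascending integer vector of permutation counts.
#' @param nRepeats independent Z estimates per grid point.
#' @return data frame with columns \code{nPerm}, \code{meanZ}, \code{sdZ};
#'   attribute \code{zMatrix} holds the full \code{nRepeats x grid} matrix.
#' @export
convergenceCurve <- function(net, H, D, metric = c("weighted", "unweighted"),
                             permGrid = c(50L, 100L, 250L, 500L),
                             nRepeats = 20L, seed = 1L, bins = NULL,
                             allPairs = FALSE) {
  metric <- match.arg(metric)
  permGrid <- as.integer(permGrid)
  if (is.unsorted(permGrid, strictly = TRUE)) stopf("permGrid must be strictly ascending")
  if (any(permGrid < 1L) || nRepeats < 1L) stopf("permGrid and nRepeats must be positive")
  if (is.null(bins)) bins <- buildDegreeBins(net)
  ctx <- .nullEngine(net, H, D, bins, allPairs = allPairs)
  obs <- .engineMetrics(ctx, proteins(ctx$H), ctx$wH)[[metric]]
  z <- matrix(NA_real_, nrow = nRepeats, ncol = length(permGrid),
              dimnames = list(NULL, permGrid))
  for (j in seq_along(permGrid)) {
    for (r in seq_len(nRepeats)) {
      nulls <- .engineNullDraws(ctx, permGrid[j], deriveSeed(seed, permGrid[j], r))[, metric]
      sg <- stats::sd(nulls)
      if (!is.finite(sg) || sg == 0) stopf("degenerate null at nPerm = %d", permGrid[j])
      z[r, j] <- (obs - mean(nulls)) / sg
    }
  }
  out <- data.frame(nPerm = permGrid, meanZ = colMeans(z), sdZ = apply(z, 2L, stats::sd))
  attr(out, "zMatrix") <- z
  rownames(out) <- NULL
  out
}
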