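#' Epsilon configuration for evidence weighting
#'
#' Three small constants govern the weighting pipeline: \code{epsilonZero}
#' replaces exact zeros produced by min-max scaling (which would annihilate a
#' multiplicative product), \code{epsilonMissing} is imputed for targets a
#' source does not list, and \code{epsilonNorm} is the smoothing floor of the
#' (0, 1] weight normalization.
#'
#' @param epsilonZero replacement for post-scaling zeros (default 1e-5).
#' @param epsilonMissing score imputed for unlisted/missing targets
#'   (default 1e-20).
#' @param epsilonNorm smoothing floor of the weight normalization
#'   (default 1e-6).
#' @return a list of class \code{WeightingConfig}.
#' @export
weightingConfig <- function(epsilonZero = 1e-5, epsilonMissing = 1e-20,
                            epsilonNorm = 1e-6) {
  for (e in c(epsilonZero, epsilonMissing, epsilonNorm)) {
    if (!is.numeric(e) || length(e) != 1L || e <= 0 || e >= 1) {
      stopf("every epsilon must be a single number in (0, 1)")
    }
  }
  structure(
    list(
      epsilonZero = epsilonZero, epsilonMissing = epsilonMissing,
      epsilonNorm = epsilonNorm
    ),
    class = "WeightingConfig"
  )
}

#' Normalize literature-mining counts to [0, 1]
#'
#' Divides each target's literature frequency by the maximum frequency
#' observed, so the most-cited target scores exactly 1.
#'
#' @param counts named nonnegative numeric vector of per-target counts.
#' @return named numeric scores in [0, 1].
#' @export
#' @examples
#' normalizeLlmCounts(c(SNCA = 10, TH = 5, DDC = 2))
normalizeLlmCounts <- function(counts) {
  if (length(counts) == 0L) stopf("counts must be nonempty")
  if (is.null(names(counts)) || anyDuplicated(names(counts))) {
    stopf("counts must be uniquely named by target symbol")
  }
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be nonnegative")
  m <- max(counts)
  if (m == 0) stopf("all counts are zero; normalization undefined")
  counts / m
}

#' Min-max scale a quantitative source column into (0, 1]
#'
#' Maps scores to \code{(x - min)/(max - min)} and replaces the resulting
#' exact zeros (the minimum) with \code{cfg$epsilonZero} so they cannot
#' annihilate a multiplicative integration.
#'
#' @param scores named numeric vector of raw scores.
#' @param cfg a [weightingConfig()].
#' @return named numeric scores in (0, 1].
#' @export
#' @examples
#' minmaxNormalizeSource(c(a = 0, b = 5, c = 10))
minmaxNormalizeSource <- function(scores, cfg = weightingConfig()) {
  if (length(scores) < 2L) stopf("need at least 2 scores to min-max scale")
  if (anyNA(scores)) stopf("scores must be non-missing (impute upstream)")
  rng <- range(scores)
  if (rng[1L] == rng[2L]) {
    stopf("constant score column: min-max scaling undefined; drop the source or supply pre-normalized scores")
  }
  x <- (scores - rng[1L]) / (rng[2L] - rng[1L])
  x[x == 0] <- cfg$epsilonZero
  x
}

#' Score a qualitative (listed/unlisted) source
#'
#' Listed targets receive 1.0; every other member of the universe receives
#' \code{cfg$epsilonMissing}.
#'
#' @param listed character vector of listed symbols.
#' @param universe character vector of all symbols under consideration;
#'   must contain \code{listed}.
#' @param cfg a [weightingConfig()].
#' @return named numeric scores over \code{universe}.
#' @export
scoreQualitativeSource <- function(listed, universe, cfg = weightingConfig()) {
  if (length(setdiff(listed, universe))) stopf("listed symbols must be a subset of the universe")
  s <- rep(cfg$epsilonMissing, length(universe))
  names(s) <- universe
  s[universe %in% listed] <- 1.0
  s
}

.checkSourceTable <- function(table) {
  if (!is.data.frame(table) || !"symbol" %in% names(table)) {
    stopf("source table must be a data frame with a 'symbol' column")
  }
  if (ncol(table) < 2L) stopf("source table needs at least one source column")
  if (anyDuplicated(table$symbol)) stopf("symbols must be unique in a source table")
  srcCols <- setdiff(names(table), "symbol")
  vals <- as.matrix(table[srcCols])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stopf("source columns must be pre-normalized to (0, 1] (NA = missing)")
  }
  srcCols
}

.orderedScoreTable <- function(symbols, score, scheme) {
  ord <- order(-score, symbols)
  out <- data.frame(
    symbol = symbols[ord], score = score[ord],
    rank = seq_along(symbols), stringsAsFactors = FALSE
  )
  attr(out, "scheme") <- scheme
  class(out) <- c("IntegratedScoreTable", "data.frame")
  out
}

#' Multiplicative integration of normalized source scores
#'
#' The integrated target score is the product of the per-source normalized
#' scores, a consensus filter that rewards targets supported by every line
#' of evidence. Missing entries are imputed with \code{cfg$epsilonMissing},
#' so all integrated scores remain strictly positive.
#'
#' @param table data frame with a \code{symbol} column plus one normalized
#'   score column per source (values in (0, 1], \code{NA} = missing).
#' @param cfg a [weightingConfig()].
#' @return an \code{IntegratedScoreTable}: data frame of \code{symbol},
#'   \code{score}, \code{rank}, ordered by descending score with
#'   lexicographic tie-breaking; attribute \code{scheme} is
#'   \code{"multiplicative"}.
#' @export
integrateMultiplicative <- function(table, cfg = weightingConfig()) {
  srcCols <- .checkSourceTable(table)
  vals <- as.matrix(table[srcCols])
  vals[is.na(vals)] <- cfg$epsilonMissing
  if (any(vals <= 0)) stopf("normalized scores must be strictly positive; apply zero-epsilon replacement upstream")
  score <- apply(vals, 1L, prod)
  .orderedScoreTable(table$symbol, score, "multiplicative")
}

#' Additive integration of normalized source scores
#'
#' Alternative scheme: the integrated score is the sum of per-source
#' normalized scores, with missing scores imputed as zero.
#'
#' @inheritParams integrateMultiplicative
#' @return an \code{IntegratedScoreTable} with \code{scheme = "additive"}.
#' @export
integrateAdditive <- function(table) {
  srcCols <- .checkSourceTable(table)
  vals <- as.matrix(table[srcCols])
  vals[is.na(vals)] <- 0
  .orderedScoreTable(table$symbol, rowSums(vals), "additive")
}

# (0,1] rescaling with smoothing floor eps: min -> eps, max -> 1 exactly.
# Degenerate input (max == min) maps everything to 1.0; callers that want a
# warning for that case emit it themselves.
.eq4Normalize <- function(raw, eps) {
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    return(stats::setNames(rep(1.0, length(raw)), names(raw)))
  }
  (raw - rng[1L]) / (rng[2L] - rng[1L]) * (1 - eps) + eps
}

#' Select the Top-N integrated targets as a weighted disease set
#'
#' Takes the \code{n} highest-scoring targets (ties broken by ascending
#' symbol for reproducibility) and rescales their integrated scores into
#' (0, 1] with the smoothing-floor normalization, yielding the
#' disease-side node weights used by the weighted proximity metric.
#'
#' @param table an \code{IntegratedScoreTable}.
#' @param n number of targets, \code{1 <= n <= nrow(table)}.
#' @param cfg a [weightingConfig()] (its \code{epsilonNorm} is the floor).
#' @return a \linkS4class{WeightedProteinSet} labelled
#'   \code{"disease-associated"}.
#' @export
topN <- function(table, n, cfg = weightingConfig()) {
  if (!inherits(table, "IntegratedScoreTable")) stopf("table must be an IntegratedScoreTable")
  n <- as.integer(n)
  if (n < 1L || n > nrow(table)) stopf("n must be in [1, %d]", nrow(table))
  sel <- table[seq_len(n), ]
  w <- .eq4Normalize(sel$score, cfg$epsilonNorm)
  names(w) <- sel$symbol
  WeightedProteinSet(w,
    label = "disease-associated",
    metadata = list(scheme = attr(table, "scheme"), n = n)
  )
}

#' Compare two integration schemes across Top-N thresholds
#'
#' For each \code{n} in \code{nGrid}: the Jaccard similarity of the two
#' Top-n target sets and the Spearman rank correlation of the two rankings
#' over the union of the Top-n sets. A target present in only one table
#' receives rank \code{nrow(table) + 1} in the other; ties share midranks.
#'
#' @param a,b \code{IntegratedScoreTable}s over a shared target universe.
#' @param nGrid integer vector of Top-N thresholds.
#' @return data frame with columns \code{n}, \code{jaccard},
#'   \code{spearman}.
#' @export
compareRankings <- function(a, b, nGrid) {
  if (!inherits(a, "IntegratedScoreTable") || !inherits(b, "IntegratedScoreTable")) {
    stopf("a and b must be IntegratedScoreTables")
  }
  nGrid <- as.integer(nGrid)
  if (any(nGrid < 1L) || any(nGrid > min(nrow(a), nrow(b)))) {
    stopf("every n must be in [1, %d]", min(nrow(a), nrow(b)))
  }
  # midranks by descending score within each full table
  rankIn <- function(tab) stats::setNames(rank(-tab$score, ties.method = "average"), tab$symbol)
  ra <- rankIn(a)
  rb <- rankIn(b)
  res <- lapply(nGrid, function(n) {
    ta <- a$symbol[seq_len(n)]
    tb <- b$symbol[seq_len(n)]
    u <- union(ta, tb)
    xa <- ifelse(u %in% names(ra), ra[u], nrow(a) + 1)
    xb <- ifelse(u %in% names(rb), rb[u], nrow(b) + 1)
    data.frame(
      n = n,
      jaccard = length(intersect(ta, tb)) / length(u),
      spearman = spearmanRho(xa, xb)
    )
  })
  do.call(rbind, res)
}
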