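#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed vectors (the standard
#' tie-handling convention).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in [-1, 1].
#' @export
#' @examples
#' spearmanRho(1:4, c(1, 3, 2, 4)) # 0.8
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations for a rank correlation")
  if (anyNA(x) || anyNA(y)) stopf("inputs must be non-missing")
  if (min(x) == max(x) || min(y) == max(y)) stopf("constant input: rank correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Perturb node weights by convex mixing with uniform noise
#'
#' \code{w_i^(alpha) = (1 - alpha) * w_i + alpha * r_i} with
#' \code{r_i ~ Uniform(0, 1)} drawn independently per node. \code{alpha = 0}
#' returns the original weights exactly; \code{alpha = 1} is full
#' randomization. For weights in (0, 1] the perturbed values stay strictly
#' positive.
#'
#' @param w a \linkS4class{WeightedProteinSet} or named numeric weights.
#' @param alpha perturbation level in [0, 1].
#' @param seed optional integer; when \code{NULL} the current RNG stream is
#'   used.
#' @return named numeric vector of perturbed weights.
#' @export
perturbWeights <- function(w, alpha, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stopf("alpha must be a single number in [0, 1]")
  }
  if (methods::is(w, "WeightedProteinSet")) w <- proteinWeights(w)
  if (length(w) == 0L) stopf("weights must be nonempty")
  draw <- function() stats::runif(length(w))
  r <- if (is.null(seed)) draw() else withSeed(seed, draw())
  out <- (1 - alpha) * w + alpha * r
  names(out) <- names(w)
  out
}

#' Rank-stability curve under weight perturbation
#'
#' For each perturbation level alpha, runs \code{nSim} independent
#' perturbations of the weight vector and scores each by the Spearman
#' correlation between the original and perturbed rankings. Summarizes the
#' resilience of a weighting scheme to noise: the mean curve Rs(alpha)
#' starts at exactly 1 (alpha = 0) and declines toward 0 at full
#' randomization.
#'
#' Each (alpha, simulation) cell draws from its own substream of the master
#' seed, so extending the alpha grid leaves existing draws unchanged.
#'
#' @param w a \linkS4class{WeightedProteinSet} or named numeric weights with
#'   at least 3 members; must not be constant.
#' @param alphaGrid ascending perturbation levels in [0, 1].
#' @param nSim simulations per alpha (default 100).
#' @param seed master seed.
#' @return a \linkS4class{PerturbationResult}.
#' @export
perturbationCurve <- function(w, alphaGrid = seq(0, 1, by = 0.1),
                              nSim = 100L, seed = 1L) {
  if (methods::is(w, "WeightedProteinSet")) w <- proteinWeights(w)
  if (length(w) < 3L) stopf("need at least 3 weights for rank stability")
  if (min(w) == max(w)) stopf("constant weights: ranking undefined")
  if (is.unsorted(alphaGrid)) stopf("alphaGrid must be ascending")
  if (any(alphaGrid < 0 | alphaGrid > 1)) stopf("alpha values must lie in [0, 1]")
  nSim <- as.integer(nSim)
  if (nSim < 1L) stopf("nSim must be >= 1")
  rs <- matrix(NA_real_, nrow = nSim, ncol = length(alphaGrid))
  for (j in seq_along(alphaGrid)) {
    a <- alphaGrid[j]
    aTag <- as.integer(round(a * 1e6))
    for (s in seq_len(nSim)) {
      pw <- perturbWeights(w, a, seed = deriveSeed(seed, aTag, s))
      rs[s, j] <- spearmanRho(w, pw)
    }
  }
  methods::new("PerturbationResult",
    alphaGrid = as.numeric(alphaGrid), rs = rs,
    nSim = nSim, seed = as.integer(seed)
  )
}
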