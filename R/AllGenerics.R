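#' @import methods
NULL

#' Protein symbols of an object
#' @param x an object holding protein symbols.
#' @return character vector of symbols.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' Node weights of a weighted protein set
#' @param x a \linkS4class{WeightedProteinSet}.
#' @return named numeric vector of weights in (0, 1].
#' @export
setGeneric("proteinWeights", function(x) standardGeneric("proteinWeights"))

#' Set label ("herb-related", "disease-associated", ...)
#' @param x a \linkS4class{WeightedProteinSet}.
#' @return character scalar.
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' Numeric value of a network metric
#' @param x a \linkS4class{MetricValue} or \linkS4class{ProximityResult}.
#' @return numeric scalar.
#' @export
setGeneric("metricValue", function(x) standardGeneric("metricValue"))

#' Bookkeeping counts attached to a metric evaluation
#' @param x a \linkS4class{MetricValue} or \linkS4class{ProximityResult}.
#' @return named list of counts (set sizes, pairs evaluated/dropped).
#' @export
setGeneric("metricCounts", function(x) standardGeneric("metricCounts"))

#' Permutation Z-score of a proximity evaluation
#' @param x a \linkS4class{ProximityResult}.
#' @return numeric scalar.
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' Null distribution retained from a permutation test
#' @param x a \linkS4class{ProximityResult}.
#' @return numeric vector of null metric values.
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
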