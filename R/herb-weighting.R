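#' Formula composition table
#'
#' A multi-herb prescription with normalized dosage ratios.
#'
#' @param herb character vector of herb identifiers (unique).
#' @param ratio positive dosage ratios summing to 1 within 1e-9.
#' @param name optional formula name.
#' @return data frame of class \code{FormulaComposition} with columns
#'   \code{herb}, \code{ratio} and attribute \code{name}.
#' @export
#' @examples
#' formulaComposition(c("gastrodia", "uncaria"), c(0.6, 0.4))
formulaComposition <- function(herb, ratio, name = "") {
  herb <- as.character(herb)
  ratio <- as.numeric(ratio)
  if (length(herb) != length(ratio) || length(herb) == 0L) {
    stopf("herb and ratio must be nonempty and of equal length")
  }
  if (anyDuplicated(herb)) stopf("herbs must be unique within a formula")
  if (any(ratio <= 0)) stopf("dosage ratios must be positive")
  if (abs(sum(ratio) - 1) > 1e-9) {
    stopf("dosage ratios must sum to 1 (got %.12f)", sum(ratio))
  }
  out <- data.frame(herb = herb, ratio = ratio, stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("FormulaComposition", "data.frame")
  out
}

#' Compound relative-abundance table
#'
#' @param herb,compound character vectors; (herb, compound) pairs unique.
#' @param abundance positive relative abundances.
#' @return data frame of class \code{CompoundAbundanceTable}.
#' @export
compoundAbundanceTable <- function(herb, compound, abundance) {
  out <- data.frame(
    herb = as.character(herb), compound = as.character(compound),
    abundance = as.numeric(abundance), stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) stopf("abundance table is empty")
  if (any(out$abundance <= 0)) stopf("abundances must be positive")
  if (anyDuplicated(out[c("herb", "compound")])) stopf("(herb, compound) pairs must be unique")
  class(out) <- c("CompoundAbundanceTable", "data.frame")
  out
}

#' Compound-protein interaction catalog
#'
#' Interaction confidences in (0, 1]; experimentally validated entries carry
#' a definitive probability of exactly 1.0.
#'
#' @param compound,protein character vectors.
#' @param probability confidences in (0, 1].
#' @param provenance "validated" or "predicted" per entry (default
#'   "predicted"; entries with probability 1 may be flagged "validated").
#' @return data frame of class \code{InteractionCatalog}.
#' @export
interactionCatalog <- function(compound, protein, probability,
                               provenance = "predicted") {
  out <- data.frame(
    compound = as.character(compound), protein = as.character(protein),
    probability = as.numeric(probability),
    provenance = rep_len(as.character(provenance), length(compound)),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) stopf("interaction catalog is empty")
  if (any(out$probability <= 0 | out$probability > 1)) {
    stopf("interaction probabilities must lie in (0, 1]")
  }
  if (!all(out$provenance %in% c("validated", "predicted"))) {
    stopf("provenance must be 'validated' or 'predicted'")
  }
  bad <- out$provenance == "validated" & out$probability != 1
  if (any(bad)) stopf("validated interactions must carry probability 1.0")
  class(out) <- c("InteractionCatalog", "data.frame")
  out
}

#' Raw herb-related protein weights under three weighting methods
#'
#' The raw weight of protein \code{j} is the sum over herbs \code{h} and
#' their compounds \code{c} of \code{R_h * A_{c,h} * P(c, j)} across the
#' (compound, protein) pairs of the catalog, where \code{R_h} is the herb's
#' dosage ratio, \code{A_{c,h}} the compound's relative abundance and
#' \code{P(c, j)} the interaction confidence. The three methods form a
#' hierarchy:
#' \describe{
#'   \item{Method 1}{dosage ratios only: \code{A = 1}, \code{P = 1}.}
#'   \item{Method 2}{ratios and abundances: \code{P = 1}.}
#'   \item{Method 3}{ratios, abundances and interaction confidences.}
#' }
#' Under Method 1 an herb by default contributes \code{R_h} once per
#' interacting compound (the literal reduction of the sum); set
#' \code{multiplicity = "per-herb"} to count each herb at most once per
#' protein instead.
#'
#' @param formula a [formulaComposition()].
#' @param abundance a [compoundAbundanceTable()] linking herbs to compounds;
#'   required for every (herb, compound) pair used.
#' @param catalog an [interactionCatalog()].
#' @param method 1, 2 or 3.
#' @param multiplicity "per-compound" (default) or "per-herb"; Method 1 only.
#' @return named numeric vector of raw weights; proteins with no interacting
#'   compound are absent.
#' @export
computeRawWeights <- function(formula, abundance, catalog, method = 3,
                              multiplicity = c("per-compound", "per-herb")) {
  multiplicity <- match.arg(multiplicity)
  if (!inherits(formula, "FormulaComposition")) stopf("formula must be a FormulaComposition")
  if (!inherits(abundance, "CompoundAbundanceTable")) stopf("abundance must be a CompoundAbundanceTable")
  if (!inherits(catalog, "InteractionCatalog")) stopf("catalog must be an InteractionCatalog")
  if (!method %in% 1:3) stopf("method must be 1, 2 or 3")

  tab <- merge(abundance, formula, by = "herb")
  if (nrow(tab) == 0L) stopf("no abundance rows match the formula's herbs")
  tab <- merge(tab, as.data.frame(catalog), by = "compound")
  if (nrow(tab) == 0L) stopf("no catalog interaction matches the formula's compounds")

  A <- if (method == 1) 1 else tab$abundance
  P <- if (method == 3) tab$probability else 1
  contrib <- tab$ratio * A * P
  if (method == 1 && multiplicity == "per-herb") {
    keep <- !duplicated(tab[c("herb", "protein")])
    contrib <- contrib[keep]
    tab <- tab[keep, ]
  }
  w <- tapply(contrib, tab$protein, sum)
  stats::setNames(as.numeric(w), names(w))
}

#' Normalize raw weights into (0, 1] with a smoothing floor
#'
#' Rescales raw weights so the minimum maps exactly to
#' \code{cfg$epsilonNorm} and the maximum exactly to 1:
#' \code{(w - min)/(max - min) * (1 - eps) + eps}. The floor keeps every
#' protein strictly positive so no node is eliminated from weighted
#' metrics. If all raw weights are equal the profile carries no ranking
#' information and every weight is set to 1.0, with a warning.
#'
#' @param raw named numeric vector of raw weights.
#' @param cfg a [weightingConfig()].
#' @param label provenance label for the resulting set.
#' @return a \linkS4class{WeightedProteinSet}.
#' @export
#' @examples
#' normalizeWeights(c(a = 0, b = 0.5, c = 1))
normalizeWeights <- function(raw, cfg = weightingConfig(), label = "herb-related") {
  if (length(raw) == 0L) stopf("raw weights must be nonempty")
  if (is.null(names(raw)) || anyDuplicated(names(raw))) {
    stopf("raw weights must be uniquely named by protein symbol")
  }
  if (anyNA(raw)) stopf("raw weights must be non-missing")
  if (min(raw) == max(raw)) {
    warning("all raw weights equal; mapping every weight to 1.0", call. = FALSE)
  }
  WeightedProteinSet(.eq4Normalize(raw, cfg$epsilonNorm), label = label)
}

#' Combine two intervention protein sets
#'
#' Union of members; a protein present in both keeps the larger of its two
#' weights. Used to evaluate integrative regimens (e.g. a formula combined
#' with a single-compound drug) with the same machinery as a single
#' intervention.
#'
#' @param a,b \linkS4class{WeightedProteinSet}s.
#' @param label label of the combined set.
#' @return a \linkS4class{WeightedProteinSet}.
#' @export
combineInterventions <- function(a, b, label = "combined") {
  stopifnot(methods::is(a, "WeightedProteinSet"), methods::is(b, "WeightedProteinSet"))
  wa <- proteinWeights(a)
  wb <- proteinWeights(b)
  members <- union(names(wa), names(wb))
  w <- pmax(
    ifelse(members %in% names(wa), wa[members], 0),
    ifelse(members %in% names(wb), wb[members], 0)
  )
  names(w) <- members
  WeightedProteinSet(w, label = label)
}

#' Represent a single-compound drug as a one-compound formula
#'
#' Convenience wrapper for evaluating a conventional drug (one active
#' compound with known pharmacological targets) with the herb machinery:
#' dosage ratio 1, abundance 1, catalog-provided confidences (1.0 for known
#' targets by default).
#'
#' @param drug drug/compound identifier.
#' @param targets character vector of target protein symbols.
#' @param probability confidences in (0, 1]; default 1.0 for all targets.
#' @param cfg a [weightingConfig()].
#' @return a \linkS4class{WeightedProteinSet} labelled with the drug name.
#' @export
drugProteinSet <- function(drug, targets, probability = 1.0,
                           cfg = weightingConfig()) {
  fo <- formulaComposition(drug, 1, name = drug)
  ab <- compoundAbundanceTable(drug, drug, 1)
  cat <- interactionCatalog(
    rep(drug, length(targets)), targets,
    rep_len(probability, length(targets)),
    provenance = ifelse(rep_len(probability, length(targets)) == 1, "validated", "predicted")
  )
  raw <- computeRawWeights(fo, ab, cat, method = 3)
  suppressWarnings(normalizeWeights(raw, cfg, label = drug))
}
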