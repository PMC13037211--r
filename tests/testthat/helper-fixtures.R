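# Small graphs and tables used across the suite; all built in code.

# path graph A-B-C-...-
makePathNet <- function(symbols = c("A", "B", "C", "D")) {
  n <- length(symbols)
  InteractionNetwork(data.frame(a = symbols[-n], b = symbols[-1]))
}

makeCycleNet <- function(n = 6) {
  s <- sprintf("c%d", seq_len(n))
  InteractionNetwork(data.frame(a = s, b = c(s[-1], s[1])))
}

makeStarNet <- function(nLeaves = 5) {
  InteractionNetwork(data.frame(a = rep("hub", nLeaves), b = sprintf("l%d", seq_len(nLeaves))))
}

randomNet <- function(n, p = 0.15, seed = 1) {
  InteractionNetwork(randomEdgeTable(n, p, seed))
}

# Eq.-3 toy from the hand-worked example: two herbs 0.6/0.4, compound c1 in
# h1 (A = 1.0, P(c1, j) = 0.5), compound c2 in h2 (A = 0.5, P(c2, j) = 1.0)
toyFormulaInputs <- function() {
  list(
    formula = formulaComposition(c("h1", "h2"), c(0.6, 0.4)),
    abundance = compoundAbundanceTable(c("h1", "h2"), c("c1", "c2"), c(1.0, 0.5)),
    catalog = interactionCatalog(
      c("c1", "c2"), c("j", "j"), c(0.5, 1.0),
      provenance = c("predicted", "validated")
    )
  )
}

writeTempEdgeList <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
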