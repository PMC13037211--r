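# HerbNetProx

Node-weighted network proximity for evaluating multi-herb interventions
against disease modules on a protein–protein interaction (PPI) network.

Multi-herb prescriptions engage many protein targets at once, with very
unequal strength: herbs enter a formula at different dosage ratios, their
compounds at different abundances, and each compound engages each protein
with a different confidence. Likewise, disease genes differ widely in how
strongly the evidence implicates them. HerbNetProx is for computational
pharmacologists and systems biologists who want those quantities kept in
the analysis instead of flattened into binary target lists.

## The model

Weights live on network nodes, never on edges.

**Disease side.** Per-source target scores are normalized into (0, 1]
(min–max scaling with a 1e-5 replacement for exact zeros; literature
counts divided by the maximum count; qualitative sources scored 1.0 /
1e-20 for listed / unlisted) and integrated per target:

    s_i = prod_k s_{i,k}        (multiplicative consensus, default)
    s_i = sum_k  s_{i,k}        (additive alternative)

Top-N targets with rescaled scores form the weighted disease module
*D* with node weights *w_d*.

**Herb side.** A protein *j* receives the raw weight

    W_j = sum_h sum_c  R_h * A_{c,h} * P(c, j)

over herbs *h* (dosage ratio `R_h`, sum 1) and compounds *c* (relative
abundance `A_{c,h}`, interaction confidence `P(c,j)` in (0,1], 1.0 when
validated). Raw weights are rescaled into (0, 1] by
`(W - min)/(max - min) * (1 - 1e-6) + 1e-6`, giving the weighted
intervention set *H* with weights *w_h*.

**Metrics.** Coverage (`|H ∩ D|/|D|` and its first-neighbor extension),
Jaccard similarity, closest-distance proximity
`d(H,D) = 1/|H| * sum_h min_d dist(h,d)`, and the weighted proximity

    d_w(H,D) = sum_{h,d} dist(h,d) w_h w_d  /  sum_{h,d} w_h w_d

with unweighted BFS shortest-path distances.

**Statistics.** Each observed proximity is compared against a null of
(default) 500 degree-matched random intervention sets — nodes resampled
bin-by-bin from a log2 degree binning, weights inherited — and summarized
as `Z = (S_obs − μ_rand)/σ_rand`. Negative Z: closer to the disease
module than degree-matched chance. A weight-perturbation module
quantifies rank stability under convex mixing with uniform noise, and a
synthetic-data module generates full benchmark instances (scale-free
interactome, planted weighted module, formula/abundance/catalog tables,
multi-source score tables with known truth) so every stage is testable
offline.

## Worked example

```r
library(HerbNetProx)

cfg    <- simulationConfig(nNodes = 1000, moduleSize = 80, seed = 7)
net    <- generateInteractome(cfg)
module <- plantDiseaseModule(net, cfg)
inputs <- generateFormulaInputs(net, module, cfg)
herb   <- restrictToNetwork(net, normalizeWeights(
  computeRawWeights(inputs$formula, inputs$abundance, inputs$catalog, method = 3)
))

net
#> InteractionNetwork: 1000 proteins, 2994 undirected interactions
herb
#> WeightedProteinSet (herb-related): 423 proteins, weights in [1e-06, 1]

metricValue(coverageOverlap(herb, module))
#> [1] 0.575
metricValue(coverageDirectlink(net, herb, module))
#> [1] 1

bins <- buildDegreeBins(net, minBinSize = 50)
res  <- nullZscore(net, herb, module, metric = "both", nPerm = 500, seed = 3, bins = bins)
res$weighted
#> ProximityResult [proximity_weighted]: S_obs = 3.0141, null 3.2365 +/- 0.0368 (n_perm = 500), Z = -6.040
res$unweighted
#> ProximityResult [proximity_unweighted]: S_obs = 0.9953, null 1.2558 +/- 0.0200 (n_perm = 500), Z = -13.006
```

Reading the output: 57.5% of the module is hit directly and all of it
within one network step; the formula's weighted proximity (3.01) sits
about six null standard deviations below the degree-matched expectation
(3.24), so the intervention is far closer to the disease module than
chance — as it should be, since this synthetic formula was generated
with 80% of its compound–protein edges enriched toward the module.
Repeating with `enrichment = 0` gives Z near 0.

File-based workflows (`runIntegrate`, `runWeighHerb`, `runEvaluate`,
`runPerturb`, `runConvergence`, `runSimulate`, `runCombine`) wrap the
same operations for TSV inputs and outputs, and
`inst/scripts/hnp-cli.R` exposes them as shell subcommands.

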