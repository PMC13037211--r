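---
title: "Node-weighted network proximity for multi-herb interventions"
author: "HerbNetProx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-weighted network proximity for multi-herb interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HerbNetProx)
```

## The problem and the model

Multi-herb prescriptions act through many compounds on many protein
targets at once. Conventional network-pharmacology screens reduce this to
binary questions — does a target list overlap a disease gene list? — and
discard two kinds of quantitative information: how strongly a protein is
implicated in the disease, and how much of an intervention actually
reaches it. HerbNetProx keeps both, as *node weights* on a
protein–protein interaction (PPI) network, and asks how close a weighted
intervention set sits to a weighted disease module relative to
degree-matched chance.

The pipeline has four layers:

1. **Disease-side weights.** Per-source disease–target scores (curated
   databases, literature-mining counts) are normalized into $(0, 1]$ and
   integrated per target. The default is multiplicative,
   $s_i = \prod_k s_{i,k}$, a consensus filter: a target scores high only
   when every independent line of evidence supports it. An additive
   alternative $s_i = \sum_k s_{i,k}$ is provided for comparison, and
   `compareRankings()` quantifies how much the two schemes disagree
   (Jaccard of Top-$N$ sets, Spearman correlation of rankings).
2. **Herb-side weights.** A protein $j$ targeted by a formula receives
   the raw weight
   $W_j = \sum_{h} \sum_{c} R_h \, A_{c,h} \, P(c,j)$,
   where $R_h$ is the herb's dosage ratio ($\sum_h R_h = 1$), $A_{c,h}$
   the relative abundance of compound $c$ in herb $h$, and $P(c,j)$ the
   confidence that the compound engages the protein (1.0 for validated
   interactions). Three nested methods set $A = P = 1$ (method 1), keep
   $A$ only (method 2), or use all three factors (method 3).
3. **Network metrics.** Coverage (direct overlap and first-neighbor
   reach), Jaccard similarity, the closest-distance proximity
   $d(H,D) = \frac{1}{|H|}\sum_{h \in H} \min_{d \in D} \mathrm{dist}(h,d)$,
   and the weighted all-pairs proximity
   $d^{w}(H,D) = \frac{\sum_{h,d} \mathrm{dist}(h,d)\, w_h w_d}
   {\sum_{h,d} w_h w_d}$,
   with distances as unweighted BFS shortest paths.
4. **Null model.** Observed proximities are compared against
   permutation nulls in which the intervention set is replaced by random
   node sets drawn bin-by-bin from a degree binning of the network, so
   the null preserves the degree profile (hubs are replaced by hubs). The
   Z-score $(S_{obs} - \mu_{rand})/\sigma_{rand}$ is the effect size;
   negative Z means closer to the disease module than degree-matched
   chance.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| zero-epsilon | $10^{-5}$ | replaces exact zeros after min–max scaling, so a single zero cannot annihilate a multiplicative product |
| missing-epsilon | $10^{-20}$ | imputed for targets a source does not list; many orders below any observed score, so absence is a strong but finite penalty |
| normalization floor | $10^{-6}$ | smoothing floor of the $(0,1]$ weight rescaling $(w - \min)/(\max - \min)\cdot(1-\epsilon)+\epsilon$; keeps every node strictly positive so weighted denominators never vanish |
| permutations | 500 | null sample per Z-score; the convergence tool shows the Z spread shrinking severalfold between 50 and 500 draws, after which it stabilizes |
| degree-bin size | 100 nodes | minimum bin occupancy after merging log2-spaced degree intervals upward; 100 is appropriate for genome-scale interactomes and should be lowered for small graphs |
| perturbation simulations | 100 per $\alpha$ | Monte-Carlo sample for the rank-stability curve |

All three epsilons live in a single `weightingConfig()` object and are
plumbed through every operation.

## Numerical choices and degenerate inputs

* **Unreachable pairs.** The network is not forced to be connected; a
  pair with no path carries an explicit `Inf` marker and is excluded from
  proximity sums (closest measure: sources that reach nothing are dropped
  from numerator and divisor). The same policy applies to observed and
  null evaluations, so Z-scores compare like with like. No finite
  substitute distance is invented.
* **Ties.** Top-$N$ selection orders by descending score, then ascending
  symbol, so a rank cut is reproducible. Spearman correlations use
  midranks. When two schemes are compared over the union of their
  Top-$N$ sets, a target absent from one table receives that table's
  worst rank plus one.
* **Degenerate weight profiles.** If all raw herb weights are equal, the
  profile carries no ranking information; `normalizeWeights()` maps every
  weight to 1.0 with a warning rather than collapsing the set to the
  floor, which would distort weighted products asymmetrically.
* **Constant source columns** cannot be min–max scaled and are rejected
  with guidance rather than silently passed through.
* **Seeding.** One master seed spawns tagged substreams (per permutation,
  per $\alpha$, per simulation) via `deriveSeed()`, so results are
  independent of evaluation order and extending a grid never changes
  draws already made. Identical inputs and seed reproduce null vectors
  bitwise.
* **Null weights.** A sampled null node inherits the weight of the node
  it replaces; the weight multiset of every null set equals that of the
  observed set, keeping the weighted metric on the same scale under the
  null. The intervention side is randomized and the disease module held
  fixed (the convention in drug–disease proximity work); a flag permits
  randomizing both sides. When weighted and unweighted metrics are
  requested together they are scored on the same null sets, so their
  Z-scores are paired.

## Design decisions on genuinely open points

* The closest-distance proximity is implemented exactly as its formula
  reads (mean over the intervention side of the minimum over the disease
  side), although prose descriptions of such measures sometimes suggest
  an all-pairs average; an `allPairs` switch exposes the other variant
  for sensitivity checks.
* Method 1 follows the weight sum literally with $A = P = 1$, so an herb
  contributes $R_h$ once per interacting compound. Because "weights from
  dosage ratios alone" can also be read as once-per-herb, a
  `multiplicity = "per-herb"` switch implements that alternative without
  asserting either as canonical.
* Abundances are used as given, with no per-herb renormalization; users
  who want within-herb proportions can pre-normalize.
* A single-compound drug is a one-compound formula with $R = 1$,
  $A = 1$ and catalog confidences (1.0 for known pharmacological
  targets), so integrative regimens (formula + drug) are evaluated with
  the same machinery via `combineInterventions()` (union, max weight).
* Analyses are not restricted to the largest connected component;
  unreachable pairs are dropped instead.

## What the synthetic generator emulates — and what it does not

`simulationConfig()` declares every distribution the generator draws
from: a preferential-attachment interactome (heavy-tailed degrees,
connected), a disease module grown by breadth-first expansion with
Beta(2, 5) raw weights (right-skewed: few high-priority targets),
symmetric-Dirichlet dosage ratios, log-normal abundances, Beta(2, 2)
interaction confidences with a validated fraction pinned at 1.0, and a
configurable *enrichment*: the fraction of compound–protein edges placed
inside the module or its first neighborhood. Enriched edges select
module members proportionally to module weight, with pure neighbors at
the module's mean weight — so most enriched edges engage the module's
periphery and few its core, reproducing the regime reported for real
formula data (direct herb–disease overlap low, first-neighbor coverage
near 1). `enrichment = 0` is the negative control.

Source-score tables are rank-preserving noisy copies of the true module
weights (Gaussian noise on the logit scale, per-source missingness, one
qualitative listed/unlisted source), so integration can be tested against
a known truth.

Passing tests on these fixtures show that the machinery is correct and
that the framework separates planted signal from degree-matched noise.
They do not show that real interactomes satisfy the generator's
assumptions: real PPI networks carry study bias (well-studied proteins
have more edges), real evidence sources are not independent noisy copies
of one truth, and real compound–target catalogs mix heterogeneous
assay types. Results on real data inherit those biases.

Default problem sizes — a 2,000-node interactome with a 150-protein
module for end-to-end evaluations, 300–500 nodes for null-model
calibration studies, 100 random graphs of up to 40 nodes for oracle
comparisons — were chosen so that the full benchmark suite runs on a
single CPU in minutes while leaving every structural property (heavy
tail, module connectivity, degree binning) intact.

## Known limitations

* **Z-scores are not comparable across estimators at small scale.** A
  Z-score divides an observed shift by a null standard deviation, and
  different estimators have very different null spreads: on a small dense
  graph the closest-distance null varies little (the minimum over a
  sizeable disease set is almost always 1), and the weighted all-pairs
  null varies more than the uniform one (its effective sample size is
  reduced by weight concentration). On desk-scale instances the
  unweighted closest Z is therefore systematically larger in magnitude
  than the weighted Z even when the weights are informative; the
  magnitude ordering reported on genome-scale interactomes, where both
  null spreads are minuscule, does not transfer to small graphs. Compare
  Z-scores across interventions within one metric, not across metrics.
* The degree binning is a design choice (log2 intervals merged upward to
  a minimum occupancy); other binnings preserve degree differently.
* Edge weights (interaction confidences on the network itself) are out
  of scope: weights live on nodes only, and distances are unweighted
  BFS path lengths.
* The perturbation analysis assesses the stability of a weight *ranking*
  under noise; it does not re-evaluate downstream proximity under
  perturbed weights.

## A worked miniature

```{r example, eval = FALSE}
cfg <- simulationConfig(nNodes = 1000, moduleSize = 80, seed = 7)
net <- generateInteractome(cfg)
module <- plantDiseaseModule(net, cfg)
inputs <- generateFormulaInputs(net, module, cfg)
herb <- restrictToNetwork(net, normalizeWeights(
  computeRawWeights(inputs$formula, inputs$abundance, inputs$catalog, method = 3)
))
bins <- buildDegreeBins(net, minBinSize = 50)
nullZscore(net, herb, module, metric = "both", nPerm = 500, seed = 3, bins = bins)
```

The README shows this example with the numbers it prints.
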