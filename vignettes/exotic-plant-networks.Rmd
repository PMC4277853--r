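---
title: "Methods: how exoticnets quantifies exotic-plant integration into pollination networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how exoticnets quantifies exotic-plant integration into pollination networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoticnets)
```

# The scientific question

Exotic plants that establish in a new region usually depend on the resident
pollinator fauna. `exoticnets` implements a four-level screen of bipartite
plant–pollinator networks that asks where, in the structure of a mutualistic
community, exotic plants leave a signature:

1. **Community level** — richness (plant `P`, pollinator `A`, total
   `S = P + A`, ratio `R = A/P`) and plant phylogenetic diversity, compared
   between invaded and uninvaded networks with Kruskal–Wallis rank-sum
   tests.
2. **Network level** — the connectance family (`C = L/(PA)`, `C_P = L/P`,
   `C_A = L/A`), NODF nestedness `N`, and relative nestedness
   `N* = (N − N̄)/N̄` against a probabilistic null.
3. **Species level** — within-network ranks of plant degree, nestedness
   contribution, and phylogenetic uniqueness, comparing exotic to native
   plants.
4. **Interaction and pollinator level** — mutual dependences and
   mass-action preferences on quantitative networks, and a mixed-effects
   logistic contrast that asks *which pollinators* carry the links to
   exotic plants, relative to degree-preserving randomizations of the same
   networks.

Empirical inputs are labelled interaction matrices (plants × pollinators,
visit counts or presence) with a metadata sidecar declaring the exotic
plants; exotic status is always an input annotation, never inferred.
Because the original global data cannot be redistributed, the package
carries a first-class synthetic generator whose planted structure exercises
every stage.

# Models and estimators

## NODF nestedness

For every ordered pair of rows `(u, v)` with `degree(u) > degree(v) > 0`,
the paired term is `100 · |shared partners| / degree(v)`; pairs with equal
degree contribute 0. Summing over row pairs and column pairs and dividing
by `P(P−1)/2 + A(A−1)/2` gives `N ∈ [0, 100]`. Quantitative weights are
binarized at `weight > 0`: NODF is a binary-structure metric, and the
package applies the same rule to degrees everywhere (an open choice the
data description leaves unstated; binarization is the convention of the
NODF literature).

## The averaged-fill (cell-model) null

Each cell gets an independent interaction probability

p_ij = (k_i/A + k_j/P) / 2,

the average of the focal row's fill and the focal column's fill. The total
∑ p_ij equals the observed link count `L` exactly. Relative nestedness
`N*` is `(N − N̄)/N̄` with `N̄` the mean NODF over draws from this model
(empty rows/columns rejected and redrawn, because NODF is undefined for
them). Default ensemble: 1000 draws (no count is stated in the source
description; 1000 holds the Monte-Carlo SE of `N̄` well below 1% at desk
scale).

Two finite-size properties of this null are worth knowing, and both are
exercised by the test suite:

* the null's expected row degree is `(k_i + L/P)/2` — it *shrinks* degree
  heterogeneity toward the mean. Small networks (≈ 6×8) therefore show a
  small positive `N*` even for draws from the null itself; by ≈ 12×16 the
  effect is inside Monte-Carlo error.
* conversely, because the null conditions on realized marginals, large
  homogeneous (Erdős–Rényi-like) networks sit slightly *below* zero
  (measured ≈ −0.07 at 25×50). A green "flat world ≈ 0" test therefore
  asserts a |mean| < 0.1 band plus an order-of-magnitude planted contrast,
  not exact zero.

## Nestedness contributions

A species' contribution is the z-score `z_i = (N − μ_i)/σ_i`, where μ and σ
summarize NODF over an ensemble in which *only the focal species'* links
are redrawn: its `k` partners are resampled without replacement with
probability proportional to the averaged-fill `p` for its row (or column).
Positive `z` means the observed links hold nestedness above the species'
random rewiring. If the focal species is connected to every potential
partner the ensemble is degenerate (σ = 0) and the contribution is flagged
undefined rather than forced. Default 100 replicates per species;
`rank_normalize` then maps z-scores to within-network ranks in [0, 1]
(average ranks at ties, min → 0, max → 1, constants → 0.5).

## Degree-preserving swaps

The pollinator-level contrast randomizes binary structure with checkerboard
swaps (`[[1,0],[0,1]] ↔ [[0,1],[1,0]]`), which preserve every row and
column total exactly, hence also connectance and each network's overall
chance of touching an exotic plant. The literature source of the method
names no chain length, so the package uses the common heuristic of
`10 × L` attempted swaps as burn-in and between successive replicates of a
single thinned chain (configurable; independent chains are available by
seeding `swap_randomize` directly). Topologies with no checkerboard (fully
nested ones) are returned unchanged with a warning — the null is
degenerate there, and silently pretending otherwise would understate
uncertainty.

## Dependences and preferences

On quantitative networks, `d_plant(i,j) = w_ij / Σ_j' w_ij'` is the share
of plant *i*'s visits carried by pollinator *j*, and symmetrically for
pollinators; each species' dependences sum to 1. Qualitative networks are
refused, not coerced: treating presence records as counts would fabricate
proportions.

Preference `Γ_ij` measures multiplicative deviation from a random-encounter
(mass-action) expectation. The estimator fits
`log w_ij = m + a_i + b_j + log Γ_ij` by least squares over the *observed*
cells only, with sum-to-zero constraints on the species effects, and
exponentiates the residual. Consequences, all tested: `Γ ≡ 1` exactly on
rank-one weight matrices; the geometric mean of `Γ` over observed links is
exactly 1; and `Γ` is invariant to rescaling any row or column. Fitting
observed cells only (rather than iterative proportional fitting of the full
matrix) avoids assigning expectations to structural zeros — this is the
module's single largest interpretive choice, since the cited preference
concept does not pin down an estimator. Cells with leverage ≈ 1 (e.g. a
species' only observed link) have their residual forced to zero by the
algebra; they are flagged `gamma_unreliable` instead of being reported as
genuine neutrality.

## The attachment contrast (the pollinator-level model)

For each invaded network, the response for pollinator *j* is whether it has
at least one link to an exotic plant. The model is a mixed-effects logistic
regression

logit(p) = α + β·k + γ·c + δ·k·c (+ α* + β*·k + γ*·c + δ*·k·c if randomized) + n,

with `k` the pollinator's ranked degree, `c` its ranked nestedness
contribution, `n` a random intercept per network identity, and the starred
terms the empirical-vs-randomized contrasts, fitted jointly on the stacked
table of one empirical instance plus (by default) 100 swap replicates per
network. The "Random" rows of the report are reconstructed as the sums
(α+α*, …) with standard errors from the fixed-effect covariance — exactly
the layout in which such results are conventionally printed. The residual
term in the written form of the model is read as the implicit binomial
variability of the logistic likelihood, not an additive Gaussian error.
`relative_probability(fit, k, c)` returns the ratio of empirical to
randomized predicted probabilities (random effect at 0), the quantity that
identifies which pollinator classes interact with exotic plants more often
than chance expects.

Because swap replicates preserve degrees, `k` is constant across instances
of a network while `c` must be recomputed per replicate. The contribution
ensemble behind each replicate's `c` defaults to 25 draws (against 100 for
empirical instances): the nesting of randomizations is otherwise quadratic
in runtime, and the ranks — the only thing the model consumes — stabilize
well before the z-scores themselves.

## Phylogenetic metrics

Plant phylogenies are consumed as dated Newick trees; trees without branch
lengths are rejected (dating is required, never defaulted). Phylogenetic
diversity is the mean distance from each community plant to the set's most
recent common ancestor (on an ultrametric tree: that ancestor's age);
uniqueness of a plant is its mean patristic distance to the other plants of
the same network. Plants missing from the tree are excluded with a warning
rather than given fabricated distances.

# The synthetic world

`generate_network` draws power-law-like expected degrees
(`∝ rank^(−nestedness_strength)`, rescaled to the target link count and
clamped to feasibility), forms links through the averaged-fill rule on
those expected degrees, and repairs empty rows/columns by redrawing the
affected line from its own cell probabilities (whole-matrix rejection is
astronomically unlikely to succeed at realistic sparsity; the line-wise
rule is the practical reading of "reject and redraw"). Quantitative
weights are `1 +` an overdispersed (negative binomial, geometric at
`weight_dispersion = 1`) count whose mean is a rank-one product of
lognormal abundance factors, so the planted world is mass-action-neutral:
`Γ` signals must come from explicit manipulation, not the generator.

Default parameters are the stated world of the emulated study design:
59 networks split 25 invaded / 34 uninvaded, a 20/59 chance of being
quantitative, exotic fractions that put 1–2 exotic plants in a typical
invaded network, and planted attachment coefficients
`(α, β, γ, δ) = (−3.69, 1.86, −3.69, 5.60)`. Where the design states no
value, the defaults (15 × 30 guild sizes, connectance 0.15, mean 4 visits
per link, pure-birth trees scaled to depth 100) are one-time choices at
the scale typical of published pollination networks; small drawn networks
get their connectance floored at ~1.3 links per species, mirroring the
empirical size–connectance relationship, since the template value can be
infeasible below ~10 species.

`plant_exotic_attachment` flags a random plant subset as exotic and
rewires each exotic plant's links, holding its degree fixed, to
pollinators sampled without replacement with probability proportional to
`logistic(α + βk + γc + δkc)` computed *before* any rewiring. A rewiring
can strand a pollinator whose only link came from an exotic plant; after a
bounded number of redraws such pollinators are dropped with a warning (in
the counterfactual community they were simply never observed). When
`γ = δ = 0` the contribution ensemble is skipped entirely — `c` cannot
affect the rule — which makes large calibration simulations affordable.

What the generator does **not** emulate: taxonomic or geographic structure,
sampling-effort artifacts, forbidden links (phenology, morphology), or
abundance data independent of the interaction matrix. A green test
therefore establishes correctness of the estimators on a world that obeys
the stated models — not that empirical communities obey them.

# Numerical and design choices

* **Ranks**: average ranks at ties, then min–max to [0, 1]; a constant
  vector maps to 0.5 (a deliberate degenerate-case convention).
* **Seeds**: every sampler is a pure function of `(input, seed)`; ensembles
  and the pipeline derive per-replicate seeds from one master seed and
  record them in manifests.
* **Kruskal–Wallis** uses the tie-corrected chi-squared reference; at very
  small samples (n ≤ 8) this asymptotic p can differ from the exact
  permutation p by ~0.1, which the property tests bound explicitly.
* **Cell-model sampling** rejects draws with empty rows/columns; this
  conditioning shifts small-matrix expectations (for 2×2 at p = 0.5 the
  exact conditional mean fill is 20/7, not 2), and tests assert the
  conditional values.
* **Two-sided tests throughout; no multiple-testing correction** — the
  analysis reports raw p-values, as is conventional for this screen.
* **Binomial dependence regression**: dependences are genuine proportions
  rather than integer successes, so the binomial GLM's non-integer warning
  is suppressed deliberately; the z-statistics are the quantity of
  interest.

# Known limitations

* The preference estimator is a declared stand-in honouring the `Γ ≷ 1`
  semantics of the mass-action concept; the originally cited estimator is
  not reproduced here.
* Nestedness contributions for species connected to everything are
  undefined (σ = 0), and fully nested topologies admit no swap null; both
  cases are reported as such rather than imputed.
* The attachment model assumes the random intercept captures all
  between-network heterogeneity; no random slopes are offered.
* Empirical results of the motivating global analysis are not reproducible
  without the original interaction data and invasive-status snapshots;
  the package's acceptance checks therefore target internal identities,
  oracle agreement, calibration, and parameter recovery on planted worlds.
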