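# exoticnets

Tools for asking how exotic (non-native) plants integrate into bipartite
plant–pollinator networks. The package is aimed at community ecologists who
have labelled interaction matrices — visit counts or presence/absence, with
plants as rows and pollinators as columns — plus a list of which plants are
exotic, and who want a reproducible, seed-stable version of the standard
four-level screen:

* **community**: richness (`P`, `A`, `S = P + A`, `R = A/P`) and plant
  phylogenetic diversity, compared invaded vs. uninvaded with
  Kruskal–Wallis rank-sum tests;
* **network**: connectance `C = L/(PA)`, links per plant `C_P`, links per
  pollinator `C_A`, NODF nestedness `N ∈ [0, 100]`, and relative
  nestedness `N* = (N − N̄)/N̄` against the averaged-fill null
  `p_ij = (k_i/A + k_j/P)/2`;
* **species**: within-network ranks of degree, nestedness-contribution
  z-score, and phylogenetic uniqueness for exotic vs. native plants;
* **interaction / pollinator**: mutual dependences
  `d_ij = w_ij / Σ w_i·`, mass-action preferences `Γ_ij` (exponentiated
  residuals of a log-additive species-effects fit; `Γ > 1` = preferred),
  and a mixed-effects logistic model

  `logit p = α + β k + γ c + δ k·c + n`

  of the probability that a pollinator (ranked degree `k`, ranked
  nestedness contribution `c`, network random intercept `n`) links to an
  exotic plant, contrasted against 100 degree-preserving (checkerboard
  swap) randomizations of each network via starred difference
  coefficients `α*, β*, γ*, δ*`.

A synthetic-data module generates single networks, dated ultrametric plant
phylogenies, and full invaded/uninvaded study sets with planted degree
heterogeneity, mass-action-neutral visit counts, and a planted logistic
attachment rule, so the entire pipeline is testable offline. See the
methods vignette (`vignettes/exotic-plant-networks.Rmd`) for the models,
defaults, and their rationale.

## Worked example

A small built-in demonstration community (synthetic, five plants of which
two are flagged exotic, five pollinators, visit counts):

```r
library(exoticnets)
net <- read_network(
  system.file("extdata", "example_network.csv",  package = "exoticnets"),
  system.file("extdata", "example_network.meta", package = "exoticnets"))
print(net)
#> <bipartite_network> demo_meadow: 5 plants x 5 pollinators, L = 16, quantitative
#>   exotic plants (2): Trifolium_repens, Cirsium_arvense

rn <- relative_nestedness(net, n_reps = 1000, rng_seed = 1)
# NODF N = 58.33, null mean N̄ = 61.78, N* = -0.056
```

`N = 58.33` is the observed NODF; the averaged-fill ensemble centred at
`N̄ = 61.78` gives `N* = −0.056`: this little community is marginally
*less* nested than its degree-informed random expectation.

```r
it <- interaction_table(net)
head(it[order(-it$gamma), c("plant", "pollinator", "weight", "d_plant",
                            "d_pollinator", "gamma")], 3)
#>              plant           pollinator weight d_plant d_pollinator gamma
#> 1 Trifolium_repens       Apis_mellifera     12   0.480        0.545  1.98
#> 10   Daucus_carota Episyrphus_balteatus      5   0.556        0.455  1.65
#> 12 Cirsium_arvense         Pieris_rapae      2   0.200        0.667  1.43
```

The honeybee carries 48% of white clover's visits (`d_plant = 0.480`) and
that interaction is observed ~2× more often (`Γ = 1.98`) than a
random-encounter model of the same row/column totals would predict.

The pollinator-level contrast, on a table simulated from the attachment
rule itself (60 networks × 40 pollinators, planted
`(α, β, γ, δ) = (−3.69, 1.86, −3.69, 5.60)`, zero contrasts):

```r
tab <- simulate_attachment_table(n_networks = 60, n_pollinators = 40,
                                 rng_seed = 7)
fit <- fit_exotic_link_model(tab)
print(fit)
#>    parameter estimate std_error       z   p_value
#> 1      alpha  -4.2423    0.5264 -8.0589 7.699e-16
#> 2       beta   2.5707    0.6887  3.7326 1.895e-04
#> 3      gamma  -2.5873    1.0287 -2.5152 1.190e-02
#> 4      delta   4.0511    1.3078  3.0977 1.951e-03
#> 5 alpha_star   0.3431    0.7154  0.4796 6.315e-01
#> ...
relative_probability(fit, 0, 0)   # 0.71 at this seed
```

All four planted coefficients are recovered within two standard errors and
the starred contrasts are indistinguishable from zero, so the
empirical-to-randomized probability ratio hovers around 1 across the unit
square — exactly what a null world should show. On empirical data, a ratio
well above 1 at low `(k, c)` is the signature of specialist, weakly
nested pollinators attaching to exotic plants more often than chance
allows.

End-to-end runs (simulate → metrics → comparisons → attachment model) are
available both programmatically and from the command line:

```r
run_pipeline(pipeline_config(synthetic = list(n_invaded = 25,
                                              n_uninvaded = 34),
                             out_dir = "out", seed = 1))
```

```sh
Rscript -e 'exoticnets::run_cli()' simulate --seed 1 --out nets/
Rscript -e 'exoticnets::run_cli()' analyze  --in nets/ --out results/ \
        --seed 1 --n-swap-reps 100 --n-null-reps 1000
```

Outputs are plain TSV/JSON reports (`network_metrics.tsv`,
`species_metrics.tsv`, `interactions.tsv`, `comparisons.tsv`,
`attachment_model.json`, `prediction_grid.tsv`) plus a manifest recording
every seed and replicate count; rerunning a config is byte-reproducible.

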