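# hillmix

Dose-response and mixture additivity modelling for reporter-gene
bioassays.

Receptor-transactivation assays (e.g. the estrogen-receptor CALUX) read
the joint activity of everything in a sample that binds the receptor as
one luminescence signal, expressed in percent of the maximal response of
the reference agonist 17β-estradiol (E2). `hillmix` answers the question
such assays pose for chemical mixtures: *is the measured mixture
response what additivity predicts, or is there evidence of synergy or
antagonism — and which additivity model describes it best?*

## The models

A single ligand follows the Hill equation on the reference scale
(y₀, m):

    y(x) = y0 + (m − y0) · a (x/c)^n / (1 + (x/c)^n)

with efficacy *a* (1 = full agonist, <1 partial, >1 supra-agonist, 0
pure antagonist), potency *c* (EC50, molar) and Hill slope *n*. For
several ligands on one receptor, mass-action occupancy gives the
multi-ligand generalisation (**GRA**, generic response addition):

    y = y0 + (m − y0) · Σᵢ aᵢ (xᵢ/cᵢ)^nᵢ / (1 + Σᵢ (xᵢ/cᵢ)^nᵢ)

Classical **concentration addition (CA)** treats components as dilutions
of one another: the mixture concentration producing effect X is
`(Σᵢ fᵢ / EC_X,i)⁻¹` for molar fractions fᵢ. CA is exactly the
aᵢ = 1, nᵢ = 1 special case of GRA.

On top of the forward models the package provides Levenberg–Marquardt
curve fitting with heteroscedasticity-robust standard errors, ECx/IC50
inversions and competitive-antagonist shift calculations, Monte-Carlo
95% prediction envelopes, an additivity / synergy / antagonism verdict,
assay QC helpers (LoD/LoQ classification, EC50 QC-well recovery), and a
synthetic plate generator (8-point serial dilutions in triplicate, E2
reference curve, QC wells, 7% multiplicative noise) so the entire
pipeline runs without laboratory data.

## A worked example

A fixed-ratio blend of two supra-/full phytoestrogens and the partial
agonist kaempferol, simulated at 7% assay noise, then tested against
the GRA envelope and scored under both models:

```r
library(hillmix)
library(dplyr)

lib <- fixture_library()
mix <- mixture(lib[lib$id %in% c("daidzein", "kaempferol", "equol"),
                   c("id", "a", "c", "n")],
               fractions = c(0.5, 0.3, 0.2))

obs <- simulate_curve(mix, seed = 11)
obs_cr <- tibble(concentration = obs$concentration_M,
                 response = obs$response_pct)

des <- mixture_design(mix, grid = sort(unique(obs$concentration_M)))
gra <- predict_curve_gra(des)
ca  <- predict_curve_ca(des)
#> Warning: CA curve truncated: 3 grid point(s) capped at the 60% ceiling
#> set by component 'kaempferol'.

env <- mc_envelope(des, uncertainty_uniform(mix, 0.1), "GRA",
                   n_sims = 2000, seed = 11)
glance(additivity_test(obs_cr, env))
#> # A tibble: 1 × 5
#>   overall  n_inside n_above n_below model
#>   <chr>       <int>   <int>   <int> <chr>
#> 1 additive        8       0       0 GRA

compare_models(obs_cr, ca, gra)
#> # A tibble: 2 × 4
#>   model  rmse   rsq n_obs
#>   <chr> <dbl> <dbl> <int>
#> 1 CA    62.0  0.311     8
#> 2 GRA    3.02 0.998     8
```

Reading the output: the simulated mixture sits inside the GRA 95%
envelope at all eight concentrations, so its behaviour is consistent
with additivity under the multi-ligand occupancy model. CA, whose
prediction is capped at kaempferol's 60% ceiling while the data rise
past 100%, explains only 31% of the variance versus 99.8% for GRA —
the characteristic failure of concentration addition for
non-equipotent blends of partial and supra-agonists. The truncation
warning is CA's documented limitation, reported rather than hidden.

`autoplot(env, observed = obs_cr)` draws the envelope with the observed
points; `fit_hill()`, `tidy()` and `glance()` cover single-compound
work; `run_pipeline(run_config(mode = "synthetic", seed = 1))` runs the
whole study (reference fit → single fits → CA/GRA predictions →
envelopes → verdicts → model comparison) in one call.

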