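---
title: "Modelling mixture activity in reporter-gene bioassays with hillmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mixture activity in reporter-gene bioassays with hillmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillmix)
library(dplyr)
```

## The problem

Receptor-transactivation bioassays such as the estrogen-receptor CALUX
measure the joint activity of everything in a sample that can bind the
receptor: a luciferase reporter integrates the contributions of full
agonists, partial agonists, supra-agonists and silent (antagonist)
binders into a single luminescence reading, expressed as a percentage of
the maximal response of the reference agonist 17β-estradiol (E2).
Assessing whether a chemical mixture behaves *additively* — or shows
signs of synergy or antagonism — requires a forward model of what
additive behaviour looks like, an uncertainty band around that
prediction, and a decision rule for the comparison. `hillmix` implements
that workflow end to end.

## The response model

A single ligand follows the Hill equation on the reference scale
$(y_0, m)$:

$$y(x) = y_0 + (m - y_0)\,\frac{a\,(x/c)^n}{1 + (x/c)^n}$$

with efficacy $a$ (fraction of the reference span: 1 for a full agonist,
0.6 for a partial agonist such as kaempferol, up to ~2 for
supra-agonists such as daidzein and genistein, 0 for a pure antagonist),
potency $c$ (the EC50, molar) and Hill slope $n$. Nominal (dosed)
concentrations are treated as free ligand concentrations, the standard
assumption in transactivation assays; the mass-action dissociation
constant is $c^n$ and is never stored separately.

For several ligands competing for one receptor, mass-action receptor
occupancy yields the multi-ligand generalisation we call **generic
response addition (GRA)**:

$$y = y_0 + (m - y_0)\,
\frac{\sum_i a_i\,(x_i/c_i)^{n_i}}{1 + \sum_i (x_i/c_i)^{n_i}}$$

Each ligand keeps its own $(a_i, c_i, n_i)$, taken literally with
per-ligand exponents in both numerator and denominator. A pure
antagonist ($a = 0$) appears only in the denominator: it occupies
receptor without activating it, so adding one can only lower the
response. Two closed-form consequences are used as correctness oracles
throughout the test suite: under a competitive antagonist with unit
slopes the apparent agonist EC50 shifts to
$c_\mathrm{ag}(1 + x_\mathrm{ant}/c_\mathrm{ant})$ (the Schild/Gaddum
form), and the antagonist IC50 against an agonist dosed at $x_\mathrm{ag}$
is $c_\mathrm{ant}(1 + x_\mathrm{ag}/c_\mathrm{ag})$ — increasing in the
agonist dose, as reversible competitive antagonism requires.

**Concentration addition (CA)** is the classical alternative: every
component is a dilution of the others, and the mixture concentration
producing effect $X$ is
$EC_{X,\mathrm{mix}} = (\sum_i f_i / EC_{X,i})^{-1}$ with molar
fractions $f_i$. CA is exactly the $a_i = 1,\ n_i = 1$ special case of
GRA; the suite asserts pointwise agreement to 1e-6 relative under those
conditions. Fractions are molar fractions of the total molar
concentration because both models operate on molar ligand
concentrations.

Two model behaviours deserve explicit mention because they are easy to
mistake for bugs:

* **CA truncation.** A partial agonist bounds the effect levels CA can
  describe: above $100 \min_i a_i$ percent the defining equation has no
  solution. `predict_curve_ca()` caps the curve at that ceiling and
  attaches a truncation record. Capping (rather than dropping the
  points) keeps CA and GRA comparable on a common grid, and reproduces
  CA's characteristic failure on mixtures containing supra- or partial
  agonists.
* **GRA need not be monotone.** For mixed efficacies, a steep
  low-efficacy component can dominate receptor occupancy at high doses
  and pull the response down from a supra-agonist's peak. This is real
  model behaviour, not a numerical artefact; the monotonicity property
  test is therefore scoped to equal-efficacy blends, where monotonicity
  provably holds.

## Fitting

Curves are fitted by unweighted least squares with the
Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`). Numerical choices
that matter:

* **log-potency parameterisation.** The EC50 is optimised as
  $\log_{10} c$: on the natural scale the normal equations are
  numerically singular (picomolar potencies against order-one
  efficacies). Estimates and standard errors are reported back on the
  natural scale by the delta method, and EC50 confidence intervals are
  formed on the log scale where the sampling distribution is closest to
  normal.
* **Deterministic multi-start.** Starts are the heuristic initialiser
  ($a \leftarrow$ max mean response / span, $c \leftarrow$ concentration
  nearest half-max, $n \leftarrow 1$) plus five log-spaced potency
  shifts ($\pm 2$ decades); best sum of squares wins, ties broken by the
  shallower slope. No randomness is involved, so fits are reproducible
  by construction.
* **Bounds.** $a \in [0, 3]$, $n \in [0.1, 10]$, $c$ within the tested
  range widened 100-fold either side — generous margins around the
  parameter ranges the assay produces in practice ($a$ roughly 0.5–2,
  $n$ 0.5–5).
* **Robust standard errors.** Luminescence noise is multiplicative
  (7% of signal is realistic for triplicates), so the classical
  constant-variance covariance badly understates the uncertainty of
  plateau-driven parameters: in simulation its nominal 95% Wald
  intervals cover the true efficacy only ~80% of the time. Standard
  errors therefore use an HC3-type heteroscedasticity-robust sandwich
  around the model Jacobian with $t_{n-p}$ quantiles, which restores
  per-parameter coverage to 93–96% in the suite's 200-curve recovery
  experiment.
* **Degenerate inputs.** Constant-response series are flagged
  (`converged = FALSE` with a note) rather than silently "fitted";
  fewer than four distinct concentrations is an input error.

Goodness of fit is `rmse = sqrt(SSres/n)` (an average difference, not
the $n - p$ estimator, so comparisons across models with different
parameter counts are self-consistent) and `rsq = 1 - SSres/SStot` about
the observed mean. The reference (E2) curve is fitted as a
four-parameter logistic with efficacy fixed at 1; its asymptotes become
the plate's `(y0, m)` scale and its EC50 the QC dosing point. Activity
classification follows the assay's detection thresholds — below 10% of
the reference maximum not detectable, below 20% not quantifiable — with
thresholds exclusive from below, so exactly 10% is `below_LoQ` and
exactly 20% is `quantifiable`.

## Monte-Carlo envelopes and the additivity verdict

Additivity is judged against a *prediction envelope*, not a single
curve. `mc_envelope()` draws parameter sets from per-parameter
distributions — normal(mean = estimate, sd = robust SE) when parameters
come from fits, uniform ±10% half-width when they come from fixture
tables; both distribution families are supported because either may be
appropriate depending on what is known — predicts the full mixture curve
per draw, and takes pointwise 2.5/50/97.5% quantiles (type-7, linear
interpolation of order statistics). Draws violating parameter validity
($a \ge 0$, $c > 0$, $n > 0$) are resampled; if more than half the
initial draws are invalid the specification is refused as inconsistent.
The default draw count is 10,000 (tests use 1,000–2,000, which keeps the
quantile error well below the decision tolerance). Envelopes are
reproducible bit-for-bit from their seed.

The verdict rule, chosen here because no canonical rule exists for
envelope comparisons: observed mean responses are interpolated onto the
envelope grid (shape-preserving `monoH.FC` cubic in log-concentration,
which unlike Hyman filtering tolerates the locally non-monotone means
assay noise produces), each point is flagged `inside` / `above` /
`below`, and additivity is rejected only when **two or more consecutive
points fall outside on the same side within the dynamic range** (envelope
median between 10% and 90% of the reference span). Excursions above
suggest synergy, below antagonism; isolated single-point excursions are
reported but tolerated, mirroring how borderline edge observations are
read in practice. In simulation this rule judges model-consistent noisy
data additive in well over 90% of runs and detects a halved mixture EC50
(a genuine left shift) in the majority of runs.

A calibration property ties the envelope to its nominal level: for
truth drawn from the same parameter distributions, the 95% envelope
contains the true curve at ~95% of grid points (the suite's 200-seed
experiment observes ~95.3%).

## The synthetic data generator

No raw assay data are deposited for this kind of study, so the package
ships a generator that emulates the statistical structure the analysis
assumes — it is first-class, tested code, not a throwaway fixture:

* **Plate layout:** 8-point 1:10 serial dilution, triplicates, blank
  wells, an E2 standard series, QC wells at the E2 EC50 (always in
  triplicate).
* **Noise:** multiplicative Gaussian, sd = 7% of signal, truncated at
  zero response — CV-style noise typical of luminescence readouts. An
  additive switch (sd as a fraction of the reference span) is provided
  for sensitivity analyses.
* **Compound library:** 15 entries (E2 plus 14 assay-relevant
  compounds). Efficacies follow the published qualitative constraints —
  kaempferol 0.6, daidzein/genistein 1.8–2.0, weak food-contact-material
  chemicals near the bottom of the scale — while EC50s and slopes are
  synthetic placeholders drawn once from class-plausible ranges and
  frozen; their provenance is labelled in the table itself.
* **Study scenario:** twelve fixed-ratio mixtures of 2–5 compounds at
  plausible (synthetic) food-like ratios, equipotent phytoestrogen
  blends at EC10 and EC50, and an E2-plus-mixture co-exposure series
  with E2 held at its EC50.

What passing tests on these data do **not** show: the generator draws
independent wells with a single noise scale, no plate-edge effects, no
cytotoxicity at high doses, no luciferase time-course kinetics, and its
compound potencies are placeholders. Conclusions about *real* mixtures
require the observed-data path (`run_config(mode = "observed")`) with
real plates.

## Problem sizes and reproducibility

The simulation experiments in the test suite and the acceptance script
use sizes chosen to estimate each quantity stably while keeping a full
run comfortably interactive: 100 seeded repetitions for the
goodness-of-fit distribution under 7% noise, 200 curves for Wald
coverage, 200 seeds × 1,000 draws for envelope calibration. The
goodness-of-fit experiment scores the fitted curve against the measured
(triplicate-mean) curve — the comparison the assay itself makes, since a
"measured concentration-response curve" is the mean of its replicate
wells — and uses the 8-point grid spanning EC50 ± 2 decades so the
sigmoid's rise carries several informative points. (The plate
generator's 1:10 dilution default is unchanged; aligned on the EC50 it
leaves the Hill slope weakly identified, which is a property of that
layout worth knowing about when designing real plates.)

Every stochastic step takes an explicit seed and records it in its
output; `run_pipeline()` writes the seed and a configuration hash into
its run log, and rerunning a configuration reproduces every number
bit-for-bit.

## A worked example

```{r example}
lib <- fixture_library()
mix <- mixture(
  lib[lib$id %in% c("daidzein", "kaempferol", "equol"),
      c("id", "a", "c", "n")],
  fractions = c(0.5, 0.3, 0.2))

obs <- simulate_curve(mix, seed = 11)
obs_cr <- dplyr::tibble(concentration = obs$concentration_M,
                        response = obs$response_pct)

des <- mixture_design(mix, grid = sort(unique(obs$concentration_M)))
gra <- predict_curve_gra(des)
ca <- predict_curve_ca(des)   # truncation warning: kaempferol caps CA at 60%

env <- mc_envelope(des, uncertainty_uniform(mix, 0.1), "GRA",
                   n_sims = 2000, seed = 11)
glance(additivity_test(obs_cr, env))
compare_models(obs_cr, ca, gra)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(env, observed = obs_cr)
```

## Known limitations

* The additivity verdict is a screening rule, not a formal hypothesis
  test; its operating characteristics are simulation-calibrated under
  the generator's assumptions.
* CA envelopes inherit the ceiling cap, so for supra-agonist mixtures a
  CA "synergy" flag often means *the CA model is inadequate*, not that
  chemistry is synergistic — read it together with the model comparison.
* Joint GRA fits of per-component parameters from a single mixture
  curve are weakly identified; they are intended for refinement around
  known single-compound fits, or with `share_params = TRUE` for
  homogeneous blends.
* No toxicokinetics, cytotoxicity correction, or receptor dimerization
  kinetics: the package models the transactivation readout only.
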