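---
title: "Methods: a hierarchical Bayesian cascade from abiotic gradients to herbivory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical Bayesian cascade from abiotic gradients to herbivory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the joint model and its assumptions, what the synthetic-data generator does
and does not emulate, the numerical and design choices that were genuinely
open, and what the validation suite can and cannot establish about real
data.

## The scientific setting

Insect herbivory in montane rainforest varies along steep abiotic
gradients, but much of that variation is indirect: climate and rock type
set soil chemistry, soil and climate shape foliar nutritional quality, and
herbivores respond to all of it. The package expresses this as a
three-tier directed cascade — climate/geology → soil → foliage → herbivory
— in which every tier is regressed on everything upstream, and indirect
influence is quantified by multiplying coefficients along directed paths.
The tier ordering is an assumption, not a discovery: the graph encodes the
study design, and no causal identification is claimed beyond it.

## The joint model

*Soil tier.* Each depth-averaged element concentration (N, P, K, Na, C:N)
is a site-level Gaussian response to geology (reference-cell coding,
basalt as reference) and to standardized linear and quadratic climate
terms. With 25 sites there is no room for a site random effect here; the
residual absorbs site heterogeneity.

*Foliage tier.* Total foliar N (% dry matter) and N digestibility (a
fraction in [0, 1], computed from paired pre/post in vitro digestion
measurements) are tree-level Gaussian responses with species-specific
intercepts, genus-specific slopes over the five standardized soil
elements, climate and geology, and a Gaussian site random effect. The
species panel has one widespread pioneer and two late-successional
congeners, so intercepts come in threes and slopes in twos. We apply the
genus-slope structure in both tree-level tiers; with 22 trees in the
rarest species, species-specific slopes would not be estimable, and the
genus split is the comparison of ecological interest (pioneer vs
late-successional strategy). Dry-matter digestibility is carried through
the data model but not regressed by default — it enters no reported
effect, and modelling it would only dilute the multiple-comparison budget.

*Herbivory tier.* The response is the tree-level mean of 20 per-leaf
damage proportions, modelled with a mean–precision beta likelihood,
`Beta(mu * phi, (1 - mu) * phi)`, `Var = mu(1-mu)/(1+phi)`, and a
logit-linear mean with species intercepts, genus slopes (over foliar total
N, N digestibility, soil, climate, geology) and a site random effect.
Whether damage should be modelled per leaf or per tree was an open choice;
we default to the tree level because the tree is the ecological unit the
covariates live on, and the mean of a fixed panel of leaves is the natural
estimator of a tree's expected damage. A consequence worth knowing: the
fitted precision is a *tree-level* quantity. If leaves are
`Beta(mu phi0, (1-mu) phi0)` and 20 are averaged, the tree-level mean has
variance close to `mu(1-mu)/(20 (1+phi0))`, so the fitted `phi` lands near
`20 (1 + phi0) - 1`, not near `phi0`. Validation therefore scores recovery
of regression coefficients, for which the tree-level model is exactly
right, and treats variance-type parameters as nuisance.

*Scale convention.* All predictors are standardized — site-level
covariates (climate, soil) over sites, tree-level covariates (foliar
chemistry) over trees — and quadratic climate terms are squares of the
standardized linear terms, so one prior is comparably vague across all of
them. Responses stay in their native units. The generator computes its
linear predictors with the same standardization code the model-preparation
step uses, so ground-truth coefficients sit exactly on the fitted scale
and recovery checks need no approximate rescaling.

*Priors.* "Vague" is made concrete as Normal(0, 10) on all intercepts,
offsets and slopes (standardized-predictor scale), half-Normal(5) on
residual and site-effect sds, and Gamma(0.01, 0.01) on the beta precision.
All are proper (the suite verifies the coefficient margin integrates to 1)
and all are configurable through `model_spec()`.

## Posterior computation

The sampler is a Metropolis-within-Gibbs sweep compiled with Rcpp:

- Gaussian-tier coefficient vectors and site effects have Normal priors
  and Gaussian likelihoods, so they are drawn from their exact conditional
  multivariate/scalar normals (conjugate Gibbs steps). This choice is
  deliberate: the soil elements are themselves functions of climate and
  geology, so the foliage and herbivory design matrices are collinear by
  construction, and scalar random-walk updates cross such ridges slowly.
- Everything non-conjugate — residual and site sds (log scale), the beta
  precision (log scale), and every herbivory-tier coefficient and site
  effect — uses scalar Gaussian random-walk Metropolis with per-parameter
  step sizes adapted towards 0.44 acceptance in batches of 50 iterations.
- The herbivory coefficient vector additionally gets one joint proposal
  per iteration with covariance `2.38^2/d` times the chain's own burn-in
  sample covariance, targeting 0.23 acceptance, to handle the same
  collinearity on the non-conjugate tier.

All adaptation happens during burn-in only, so retained draws come from a
fixed kernel. All randomness flows through R's RNG: a chain is a pure
function of its seed, and chains are initialized from least-squares
starting points with chain-specific overdispersion. A non-finite
log-posterior at initialization is an error, not a silent retry. The same
scalar kernel is exposed in pure R as `adaptive_mh()` and backs
`run_mcmc()` on arbitrary log-targets; the test suite uses it to verify
the kernel against conjugate closed forms (Normal mean with known
variance; a binomial proportion under a beta prior) to within three Monte
Carlo standard errors.

The production schedule is 3 chains of 400,000 iterations, half burn-in,
thinning 1/100 — exactly 6,000 retained joint draws. Fits in the tests,
the analysis drivers and the acceptance script use a desk schedule of 3 ×
20,000 thinned by 10 (3,000 draws); with the conjugate blocks in place
this converges comfortably (all R-hat − 1 < 0.1) on the default landscape
while keeping a full simulate–fit round near 15 seconds.

## Diagnostics

*Convergence* uses the classic (non-split, non-rank-normalized)
Gelman–Rubin factor, matching the `R-hat − 1 < 0.1` working rule; a split
variant is available as an option.

*Model fit* uses a posterior-predictive check on residual sums of squares:
for each retained draw, the RSS of the observations around that draw's
fitted means is paired with the RSS of one replicated dataset simulated
from the likelihood at the same draw, and the Bayesian p-value is the
fraction of draws whose replicated RSS is at least the observed one (ties
count as exceedance, so degenerate identical pairs give 1 by convention).
Raw RSS is reported per tier. How to pool tiers was an open choice: raw
RSS would be dominated by whichever tier has the largest units (the
Gaussian tiers dwarf damage proportions of order 0.04), so the pooled
headline discrepancy standardizes every residual by its model scale — the
tier's residual sd, or `sqrt(mu(1-mu)/(1+phi))` for the beta tier — before
summing. The suite checks both directions of this diagnostic: calibrated
(pooled p in [0.25, 0.75]) on well-specified fits, and decisive (p
leaving [0.05, 0.95]) when the observed damage is shifted on the logit
scale against a fit to clean data.

## Effect summaries and paths

Effects are posterior means with 89% equal-tailed credible intervals.
Equal-tailed is the default over highest-density because it is
deterministic, has a trivial independent oracle (sorted-sample
quantiles), and differs negligibly for the near-symmetric marginals this
model produces; an HDI option exists. "Does not greatly overlap zero" is
operationalized as the interval excluding zero; the level is an argument,
not a constant. No multiplicity adjustment is applied beyond the interval
rule — the screened edges should be read as a description of the fitted
posterior, not as a family of tests.

Indirect effects multiply standardized linear coefficients along a path
draw by draw (never from summarized means, which would ignore posterior
dependence). Quadratic terms are excluded from path products: a
coefficient product is only interpretable as "effect of a one-sd shift
propagated down the chain" for linear edges. `build_path_graph()` retains
edges whose intervals exclude zero and enumerates all 1- and 2-edge paths
from the abiotic nodes to herbivory; genus is carried through foliage
nodes, so a path through late-successional foliage can only terminate in
late-successional herbivory. At the 89% level roughly 11% of truly null
edges will be retained by chance — the suite measures exactly this on a
zero-effect landscape.

## The synthetic landscape

The generator is first-class, tested code: it is the package's substitute
for field data and the ground truth for every validation claim.

What it emulates, and the defaults: 25 sites, each with mean annual
temperature spanning 14–26 °C (tied to a latent elevation axis) and
precipitation spanning 1200–4000 mm/yr (tied to a latent longitude axis,
high near the coast), the two axes independent with configurable jitter
and the realized values clamped to their ranges; three parent materials
(basalt, granite, rhyolite), every class guaranteed present; three species
in two genera with the unbalanced sample plan 115/22/42 trees and
late-successional species restricted to a random subset of sites (site
inclusion probabilities 1.00/0.48/0.60, approximating the reported
coverage of such panels); 20 leaves per tree. The tree total is 179 by
default; the per-species counts are plain configuration, so a 120-tree
variant is one argument away — the package does not adjudicate between
the two published totals.

Ground-truth coefficients follow the qualitative sign structure the
package is designed to recover — basalt-derived soils nutrient-rich;
precipitation raising soil N and P while depleting K and C:N; temperature
raising K and lowering Na and C:N; foliar chemistry responding to geology
and (late-successional genus only) to climate, soil P and Na; herbivory
rising with temperature in both genera, with foliar N in the pioneer, and
falling with soil C:N in the late-successional genus — with standardized
magnitudes around 0.3–0.8, chosen once so that effects are recoverable,
but not trivially so, at 25 sites and 179 trees. For foliar responses
generated in natural units the raw slopes are those magnitudes times the
response sd (e.g. 0.04 on a digestibility scale with residual sd 0.07).
Herbivory intercepts put species mean damage near 2–7%, matching the
reported range, and the leaf-level precision is 40. Leaf damage is
clamped into `(1e-6, 1 - 1e-6)`: observed damage in real surveys never
hits 0 or 1 exactly (minima around 0.002% are reported), a strictly
positive floor keeps the beta likelihood finite, and unlike a global
shrink transform the clamp leaves interior values bit-identical. The same
epsilon is applied when leaf damage is averaged to the tree level.

What it does not emulate: geographic realism beyond the two gradient
axes (no rasters, no spatial autocorrelation beyond the site effect), no
seasonal or repeat-sampling structure (each tree is sampled once), no
measurement error model for the assay chemistry or leaf-image processing,
and no species beyond the three-species panel. Passing validation on this
generator therefore shows the *inferential machinery* is correct under
the model's own assumptions — it does not show the model is adequate for
any particular field dataset; that is what the posterior-predictive check
is for.

## Numerical choices and degenerate inputs

- Standardization refuses zero-variance columns by name rather than
  producing NaNs; back-transformation is exact to floating point.
- A digestibility index below 0 (possible with measurement noise) is
  returned with a warning, never silently clipped — clipping would bias
  downstream regressions.
- Depth averaging uses only non-missing depths and records how many
  contributed; all-missing is an error.
- Tree-level damage warns below 10 leaves (the design targets 20).
- Generated digestibility indices are clipped to [0, 1]; default
  parameters make clipping rare (intercepts 0.45–0.62, residual sd 0.07),
  so the Gaussian tier is effectively uncensored.
- `retained draws = n_chains * floor(n_iterations * (1 - burn_in) /
  thinning)` exactly, for every schedule; the burn-in count is adjusted so
  the floor identity holds rather than truncating recorded draws.
- R-hat requires at least 2 chains and 10 retained draws per chain;
  degenerate requests are errors, not NaNs.

## Problem sizes

The suite and the acceptance script run everything at the study's own
scale: 25 sites, 179 trees, 3,580 leaves, 200 parameters, desk-schedule
fits of 3 × 20,000 iterations. Recovery and calibration claims rest on 20
independent simulate–fit replicates (interval coverage pooled over
replicates × coefficients, accepted in [0.75, 0.97] around the nominal
0.89), five of which also back the planted-pathway and diagnostic checks;
Monte-Carlo moment checks use 10^4–10^5 draws with three-standard-error
tolerances.

## Known limitations

- The tier graph is assumed, so "indirect effects" are model-implied
  decompositions, not causal estimates.
- Observed soil and foliage values enter downstream tiers as fixed
  covariates; their measurement noise is not propagated (no latent-variable
  errors-in-variables structure).
- The classic R-hat can miss pathologies that split/rank-normalized
  variants catch; the split option is provided but not the default, to
  keep the headline diagnostic aligned with the working rule it
  implements.
- The beta likelihood's precision is tied to the 20-leaf averaging
  protocol (see above); comparing fitted `phi` across studies with
  different leaf counts requires the `20 (1 + phi0) - 1` correction.
- With 25 sites, the foliage and herbivory tiers carry 11–13 site-level
  predictors per genus; the late-successional genus occupies roughly 15
  sites, so its site-level slopes leaning on the prior is expected, and
  interval widths there should be read accordingly.
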