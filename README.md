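# herbcascade

Hierarchical Bayesian modelling of how climate and geology cascade through
soil chemistry and foliar nutritional chemistry into insect herbivory
pressure, built for tropical montane tree communities sampled across crossed
temperature, precipitation and parent-material gradients. The package is
aimed at ecologists who want to fit (and stress-test) this kind of
multi-tier path model on site/tree/leaf tables — and at anyone who needs a
fully synthetic, ground-truth-known replica of such a study to validate the
whole inferential pipeline: sampler correctness, convergence diagnostics,
posterior-predictive calibration, and credible-interval coverage.

## The model

Three likelihood tiers share a fixed acyclic ordering. For site $s$, tree
$t$ of species $j(t)$ and genus $g(t)$:

**Soil tier** (site level, one model per element
$e \in \{N, P, K, Na, C\!:\!N\}$):

$$y_{e,s} \sim \mathcal N\!\big(\alpha_e + \gamma_{e,\mathrm{geo}(s)} +
\beta_{e,1} T_s + \beta_{e,2} T_s^2 + \beta_{e,3} P_s + \beta_{e,4} P_s^2,\;
\sigma_e\big)$$

where $T$ and $P$ are standardized mean annual temperature and
precipitation (quadratic terms are squares of the standardized linear
terms) and geology uses reference-cell coding with basalt as the reference.

**Foliage tier** (tree level, for total foliar N and N digestibility):
species-specific intercepts, genus-specific slopes over the five
standardized soil elements, climate, and geology, a Gaussian site random
effect $u_s \sim \mathcal N(0, \tau)$, and Gaussian residuals — the
"three intercepts, two slopes per predictor" structure for a
pioneer/late-successional species panel.

**Herbivory tier** (tree level): the mean leaf-area loss of a tree follows
a mean-precision beta likelihood

$$y_t \sim \mathrm{Beta}\big(\mu_t \phi, (1 - \mu_t)\phi\big), \qquad
\mathrm{logit}(\mu_t) = \alpha_{j(t)} + x_t^\top \beta_{g(t)} + u_{s(t)},$$

with genus slopes over foliar chemistry, soil, climate and geology.
Priors are vague on standardized predictors: $\mathcal N(0, 10)$ on
coefficients, half-$\mathcal N(5)$ on sds, $\Gamma(0.01, 0.01)$ on $\phi$.

Posterior sampling uses a compiled Metropolis-within-Gibbs sweep (conjugate
draws for Gaussian-tier coefficients and site effects, adaptive random-walk
Metropolis elsewhere, plus an adaptive-covariance block move for the
herbivory coefficients). Convergence is judged by the classic Gelman–Rubin
$\hat R - 1 < 0.1$ rule, model fit by a posterior-predictive check on
residual sums of squares with a Bayesian p-value. Effects are summarized by
posterior means with 89% equal-tailed credible intervals; an effect is
"retained" when its interval excludes zero, and indirect effects are
draw-wise products of coefficients along paths such as
precipitation → soil C:N → herbivory.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic landscape (25 sites, 179 trees, 20 leaves per tree):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare.R
Rscript analysis/03_fit.R
Rscript analysis/04_diagnostics.R
Rscript analysis/05_effects.R
```

Step 1 prints the simulated conditions:

```
sites: 25 (basalt=9, granite=8, rhyolite=8)
trees: 179, leaves: 3580
MAT span 14.1-26.0 C, MAP span 1520-4000 mm/yr
mean leaf damage 4.00% (leaf range 0.0001% to 33.98%)
```

so herbivory sits around 4% of leaf area, with rare heavily eaten leaves.
Step 4 reports convergence and calibration of the fit (3 chains × 20000
iterations, half burn-in, thinning 10):

```
R-hat: max 1.0751; 0 of 200 parameters above the 1.1 rule
Bayesian p-values:  soil 0.66  foliage 0.52  herbivory 0.60  pooled 0.69
```

— all chains converged, and replicated discrepancies straddle the observed
ones, as they should for a well-specified fit. Step 5 summarizes effects
and pathways, e.g.

```
MAP -> soil_CN -> herb:Flindersia  0.828 [0.499, 1.200]
ground-truth recovery: 80.7% of 114 coefficients inside their 89% intervals
```

the first line being the indirect precipitation effect on late-successional
herbivory through soil C:N (precipitation lowers C:N, low C:N raises
herbivory, so the product is positive and its 89% interval excludes zero);
the second line checks the fit against the generator's known coefficients.
Tables land in `results/` (`coefficient_summary.csv`, `retained_edges.csv`,
`path_effects.csv`, `rhat.csv`, `ppc_discrepancies.csv`).

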