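---
title: "Models and methods: reconstructing brain and body mass evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reconstructing brain and body mass evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paleobrain` implements a comparative analysis of continuous-trait evolution
on time-calibrated phylogenies that carry both extant and fossil tips. This
vignette is the package's own account of the models it fits, the choices we
made where the methodology was genuinely open, and what our validation does
and does not establish.

## The evolutionary model

All analyses rest on the constant-variance random walk (Brownian motion):
along a branch of length $t$ Myr a trait changes by a normal increment with
mean $\beta t$ and variance $\alpha t$. $\alpha$ (trait² Myr⁻¹) is the
instantaneous variance of evolution; $\beta$ (trait Myr⁻¹) is a directional
drift, zero in the non-directional model. Stacking the independent branch
increments, the tip vector is multivariate normal,

$$x \sim \mathcal{N}\!\left(x_0 + \beta\,p,\; \alpha\,C\right),$$

where $x_0$ is the root state, $p$ the vector of root-to-tip path lengths,
and $C$ the phylogenetic covariance matrix whose $(i,j)$ entry is the shared
path length from the root to the most recent common ancestor of tips $i$
and $j$. On an ultrametric tree every entry of $p$ equals the tree height,
so $\beta$ is confounded with $x_0$: **a directional model is identifiable
only when fossil tips break ultrametricity**. Functions that need this
($\texttt{fit\_ml(directional=)}$, `trend_test()`, directional MCMC) refuse
ultrametric input with an explicit error rather than returning an
unidentified fit. Ultrametricity is judged with a relative tolerance
(path-length range ≤ 1e−7 of the height), because pruning and rescaling
accumulate float error of order 1e−8 on a 77.5-Myr tree.

Branch-length transforms modulate the tempo and mode assumptions: κ raises
each branch length to the power κ before $C$ is assembled (κ → 0 is
punctuational change, κ = 1 gradualism), λ multiplies the off-diagonal of
$C$ (phylogenetic signal), and δ raises the assembled entries to the power
δ (early- vs late-concentrated change). We apply them in that order — κ at
branch level, then λ, then δ on the assembled matrix — the conventional
sequence; the methodology we follow does not specify one. All three default
to 1 (the identity), are tested against 1 by likelihood-ratio tests
(`lr_test()`, χ² with 1 df; approximate when the null sits on a boundary,
as for λ = 1), and ranges are κ, δ ∈ [0, 3], λ ∈ [0, 1] in the numerical
fits.

## Ancestral state reconstruction

Three estimators are provided, deliberately implemented through different
algebra so they can check one another:

* **Weighted squared-change parsimony** minimises
  $\sum_e (x_{\text{child}} - x_{\text{parent}})^2 / \ell_e$ over internal
  states, a positive-definite quadratic solved exactly via the weighted
  graph Laplacian. Zero-length branches (inserted by random polytomy
  resolution, or fossils last seen exactly at their attachment node) would
  have infinite weight, so the nodes they join are *contracted* into one
  state before solving. Polytomy resolution order therefore provably cannot
  move an estimate, which is why the seeded `resolve_polytomies()` choice is
  treated as inconsequential.
* **ML under Brownian motion** computes each internal node's conditional
  expectation given the tips, with the root (and drift) profiled by GLS and
  $\alpha$ by its closed form. Standard errors include the propagated
  uncertainty of the GLS coefficients, which is what makes deep nodes —
  especially the root — visibly less certain on ultrametric trees. Because
  the joint Gaussian mode equals the vector of conditional means, parsimony
  and ML point estimates coincide to numerical precision; the test suite
  asserts max |difference| < 1e−8 and Spearman r = 1.000, and uses
  `ape::ace` as an independent cross-check of the ML route.
* **Bayesian MCMC** samples model parameters and internal node states
  jointly by Metropolis–Hastings under uniform priors (default −100 to 100;
  $\alpha$ on (0, 100]). The joint density factorises over branches, so
  latent-node updates are cheap; nodes are updated in two alternating
  "colours" (by depth parity) so that simultaneous proposals never touch
  both ends of a branch. Parameter ("rate deviation") and node ("data
  deviation") proposal widths are tuned separately during burn-in only —
  multiplied by 1.1 or 0.9 per 1000-iteration window until acceptance sits
  in the 20–40 % band — and then frozen, preserving detailed balance in the
  retained portion of the chain. Chains start at the ML solution with
  widths of about 2.4 GLS standard errors, so tuning only fine-tunes.
  Posterior node summaries report the mean, the central 95 % interval, and
  a Shapiro–Wilk normality p-value that is reported but never used to alter
  an estimate.

Default chain settings are 2,000,000 post-burn-in iterations thinned every
100 after a burn-in of 500,000; `iterations` counts post-burn-in sweeps, so
retained draws = iterations / thin. The test suite uses chains of
50,000/10/10,000 and shorter, which keeps the full suite within a few
minutes at one node-sampling chain per second-scale tree.

One deliberate narrowing: λ and δ destroy the branch-factorised form of the
joint density (they act on the assembled covariance, not on branches), so
the latent-node sampler accepts only a *fixed* κ among the transforms.
Sampling λ or δ is still available in the marginal-likelihood sampler
(`sample_nodes = FALSE`), which is the mode used for scaling-parameter and
trend Bayes-factor tests anyway; ML/PGLS support all three as fixed or
estimated parameters everywhere.

## Trend tests and the harmonic mean

Models are compared with Bayes factors computed from log harmonic means of
the sampled likelihoods, $BF = 2(\log HM_A - \log HM_B)$, with > 2 read as
positive, > 5 strong and > 10 very strong evidence. The harmonic-mean
estimator is retained because it is the estimator of the methodology this
package implements, and it is computed stably in log space
(log-sum-exp of negated log-likelihoods). It is *not* best practice: its
variance is heavy-tailed and it is insensitive to the prior, which is why
`trend_test()` results on null data scatter around zero with occasional
excursions above 2. Our acceptance checks therefore test it as an error
*rate* across 20 seeded replicates (power under β = 0.1 Myr⁻¹, specificity
under β = 0) rather than as a single-run guarantee. Stepping-stone or
thermodynamic estimators would be the modern replacements; they are out of
scope here.

## Allometry, residuals, and units

Relative brain size is the residual from the PGLS regression of log brain
on log body mass, fitted over *all* taxa (extant and fossil alike). An
`allometry_line` carries its unit conventions explicitly and converts to a
canonical grams scale; the published primate line (intercept 2.18, slope
0.684) is only internally consistent with brain mass in milligrams and body
mass in grams, so it is entered as
`allometry_line(2.18, 0.684, brain_unit = "mg")`. Absolute residuals shift
by a constant under a change of mass unit, but residual *differences* — the
only quantity the branch and scenario statistics use — are unit-invariant
for a fixed slope, and the tests assert this to 1e−12.

Ancestral relative brain size can be computed two ways: reconstruct brain
and body separately and take residuals at the nodes (*residuals second*),
or compute tip residuals first and reconstruct them as the evolving trait
(*residuals first*). For linear engines the two coincide exactly on on-line
data and are strongly rank-correlated otherwise; only *residuals first*
yields a trait to which the directional trend test can be applied, because
*residuals second* has no tip-level trait to model.

## Branch changes, decreases, and dwarfism scenarios

Differences of log₁₀ values at consecutive nodes give proportional changes
(reported both as Δlog and as 10^Δlog − 1, the "% change" reading);
differences of back-transformed masses give absolute changes; dividing by
branch length gives rates, with zero-length branches excluded from rate
statistics and flagged. Upper quartiles use R's default interpolated-rank
convention (published thresholds such as 0.344 are dataset outputs, not
contract values). The decrease census reports, per trait, the number and
fraction of decreasing branches and the fraction of total evolutionary time
they occupy, and for each brain-decrease branch the scaling ratio
(Δlog brain)/(Δlog body). Both all-branch and positive-length-branch
denominators are emitted because the published "% of branches" denominator
convention is ambiguous.

A dwarfism scenario (ancestor masses → descendant masses) is summarised by
three unit-invariant statistics — the scaling ratio, Δlog brain, and
Δ relative = Δlog brain − slope·Δlog body — each flagged by closed-interval
membership against a `decrease_envelope`. The envelope is preferably
computed from the user's own census; the published primate-wide constants
(ratio 0.006–0.825, largest single decrease −0.273) ship as a clearly
labelled default. The published bound for relative-brain decreases was
never printed, so that flag is `NA` under the default envelope rather than
guessed. The per-cell identity
Δrel = Δlog brain − slope·(Δlog brain / ratio) lets published scenario
tables be reproduced from their printed columns alone; because printed
ratios are rounded to 3 decimals, reproduction is exact to one unit in the
last printed digit (two cells of the published tables differ by exactly
that much, and one row of the published table fails the identity outright —
we treat it as an erratum and exclude it).

## The synthetic-data generator

`sim_config()` defaults define the data-generating conditions used
throughout testing: a pure-birth (Yule) tree of 37 extant tips rescaled to
77.5 Myr — the deep-root calibration scale of the primate radiation — with
23 fossil tips grafted at uniformly chosen interior nodes and
last-occurrence times uniform on (0, node age); log₁₀ body mass evolving by
BM from a ~49 g root at rate α_body = 0.013 (marginal tip SD ≈ 1 log unit,
matching a 10 g–100 kg genus-level spread); a brain residual evolving at
α_resid = 0.001 (tip SD ≈ 0.28, giving R² near the published 0.86); brain
mass assembled as line(body) + residual at every node, with an optional
residual drift β_brain emulating a trend in encephalization but not body
size. Terminal branches are snapped so extant tip depths equal the height
exactly. Fossil grafting reuses `graft_fossil()` — one code path for real
and simulated data — and every generator takes an explicit integer seed.

What the generator does *not* emulate: extinction (no birth–death
realism), body-mass-correlated fossil sampling, measurement error, or any
departure from the BM-plus-line model. Passing tests therefore show that
the estimators recover the model they assume, under realistic sizes and
rates — not that real primate data satisfy those assumptions.

Two calibration notes, established by the test suite rather than asserted:
PGLS on the 60-taxon fixture recovers the generating slope within ±0.05,
and ML node estimates on 40-extant-tip datasets with the default fossil
complement are rank-correlated with the simulation truth at r_s ≈ 0.93–0.95
for typical seeds. That recovery has a tail — across 20 seeds roughly one
in six realizations dips below 0.9, bottoming near 0.65 on unlucky
pure-birth topologies whose deep nodes are weakly constrained — so
node-level recovery should be read as a typical-case property of tree shape,
not a per-dataset guarantee.

## Numerical choices and degenerate inputs

* Likelihoods use Cholesky factorisations; a singular covariance (e.g. two
  tips with identical covariance structure from duplicate zero-length
  placements) raises an error naming the duplicated rows.
* ML fits with free scaling parameters use L-BFGS-B with five seeded
  restarts and a convergence factor of 1e3·machine-eps on the likelihood;
  the profiled parameters (root, drift, α) are exact given the transforms.
* `lr_test()` clamps tiny negative LR values (≥ −1e−6) to zero and treats
  anything more negative as an optimisation failure.
* Spearman correlations use average ranks for ties and the asymptotic
  two-sided p-value.
* Zero body-mass change makes the scaling ratio undefined and is an
  explicit error, not an Inf.
* Monte-Carlo standard errors use batch means with ⌊√n⌋ batches.

## Known limitations

No Ornstein–Uhlenbeck or multi-rate models; no measurement-error variance;
no stepping-stone marginal likelihoods; no tree inference or dating (trees
are taken as known without error, as in the analysis design this package
follows); NEXUS input is not parsed (Newick only). The harmonic-mean
caveats above apply to every Bayes factor the package reports.
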