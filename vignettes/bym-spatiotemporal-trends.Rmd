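---
title: "Smoothing and classifying block-level survey trends with the BYM spatiotemporal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing and classifying block-level survey trends with the BYM spatiotemporal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Household surveys repeated over several rounds can, in principle, track
health-indicator levels for every sub-district administrative block of a
state. In practice the per-block samples are small (a few dozen
respondents per round), so raw block proportions are unstable: a block can
appear to swing wildly between rounds purely through sampling noise, and a
block with no respondents for an indicator has no estimate at all.
`bymtrends` implements the standard small-area answer: a hierarchical
Bayesian Besag–York–Mollié (BYM) spatiotemporal model that borrows strength
across neighbouring blocks and across rounds, plus a decision layer that
asks whether trends genuinely differ between blocks and classifies each
block's trend with a controlled error rate.

## The model

For block $i$ and survey round with time value $t$ (years since the first
round, coded $0, 1, 2, \dots$), the linear predictor is

$$\eta_{it} = \alpha + \beta t + u_i + v_i \;[+\; \delta_i t]$$

with, for a binary (yes/no) indicator observed as $y_{it}$ successes out of
$n_{it}$ respondents,

$$y_{it} \sim \mathrm{Binomial}(n_{it},\, \mathrm{logit}^{-1}(\eta_{it})),$$

and for a count indicator aggregated to $y_{it}$ items out of a maximum
possible $n_{it}$,

$$y_{it} \sim \mathrm{Poisson}(n_{it}\, e^{\eta_{it}}).$$

The components are:

* $\alpha$ — the state-average level at the first round, on the link scale.
* $\beta$ — the state-average linear trend per year; $e^\beta$ is the
  average odds ratio (binary) or rate ratio (count) per year.
* $u_i$ — spatially structured block effect with an intrinsic conditional
  autoregressive (ICAR) prior on the contiguity graph: each $u_i$ is
  conditionally normal around the mean of its neighbours with precision
  $\tau_u d_i$ ($d_i$ = number of neighbours). The ICAR precision matrix
  $Q$ has $Q_{ii} = d_i$, $Q_{ij} = -1$ for neighbours, zero row sums, and
  rank deficiency equal to the number of connected components of the graph.
* $v_i$ — unstructured iid $N(0, \tau_v^{-1})$ heterogeneity.
* $\delta_i$ — optional per-block deviation from the average trend
  ("space–time interaction"), iid $N(0, \tau_\delta^{-1})$. Its presence is
  what "trends differ between blocks" means; $e^{\beta+\delta_i}$ is block
  $i$'s trend ratio per year.

Only the sum $u_i + v_i$ enters the likelihood; the two are separated by
their priors alone (spatially smooth vs noise), which is intrinsic to the
BYM formulation, not a defect of this implementation.

Contiguity ("blocks that share a border") is rook-style by default: two
blocks are neighbours when their boundaries share a segment of positive
length after snapping coordinates on a $10^{-9}$ grid; corner-touching
alone does not qualify. A queen option (shared vertex suffices) is exposed
for sensitivity analysis. The polygon reader assumes a topologically noded
layer, i.e. neighbouring polygons share their boundary vertices — true of
the lattice maps the generator writes and of typical administrative
boundary exports; repairing unnoded topology is out of scope, and an edge
list can always be supplied directly.

### Identifiability and constraints

The ICAR prior is improper: it is invariant to adding a constant per
connected component. We resolve this the standard way, by constraining $u$
to sum to zero within each component; likewise $\delta$ sums to zero so
that $\beta$ keeps its meaning as the state-average trend. In the sampler
both constraints are imposed by recentring after each sweep; the shifts are
absorbed into $\alpha$ (single-component graphs) and $\beta$ respectively,
so the linear predictor — and hence the likelihood — is untouched by the
recentring.

### Priors and defaults

The precision priors are $\tau_u, \tau_v, \tau_\delta \sim
\mathrm{Gamma}(1, 5\times10^{-4})$ and $\alpha, \beta \sim N(0,
\text{precision } 10^{-3})$ — the weakly-informative gamma family that is
the long-standing default in hierarchical disease-mapping software. All are
exposed in `model_spec()`. One behaviour of this prior is worth knowing:
its median corresponds to a random-effect standard deviation of only about
0.03, so on *small* maps (a few dozen blocks) with modest heterogeneity the
posterior can legitimately concentrate on strong shrinkage — we verified on
a 16-block fixture, against an independent JAGS fit, that this is the
correct posterior under this prior, not a sampler artifact. With realistic
map sizes (hundreds of blocks) the likelihood dominates and the effect
disappears. Users who want to regularise away from the collapsed regime on
tiny maps can raise `b_tau`.

## Inference engine

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
written in C++ (`fit_bym()`):

* $\alpha, \beta$: scalar random-walk Metropolis;
* $u_i$: single-site random walk against the ICAR full conditional
  $N(\bar u_{\partial i}, (\tau_u d_i)^{-1})$ and the block's likelihood;
* $v_i$, $\delta_i$: single-site random walks against their normal priors;
* an exact "ridge" Gibbs step that resamples the split of each block's
  level between $u_i$ and $v_i$ holding their sum fixed: only the sum is
  likelihood-identified, and along that line the conditional of $v_i$ is
  Gaussian in closed form, so the otherwise very slow random-walk mixing
  of the $u/v$ decomposition is replaced by an always-accepted draw;
* joint scale moves that rescale each of $u$, $v$, $\delta$ by a common
  lognormal factor with the appropriate Jacobian ($c^{\mathrm{rank}}$),
  interleaved with the precision updates and repeated within each sweep,
  which decouples the vectors from their precisions;
* $\tau_u, \tau_v, \tau_\delta$: conjugate gamma Gibbs updates, with shape
  contributions $\mathrm{rank}(Q)/2$, $n/2$ and $(n-1)/2$ respectively.

Proposal scales adapt toward 0.44 acceptance during burn-in only, so the
retained chain is a valid time-homogeneous Markov chain. Chains start from
a data-driven point — pooled level plus empirical-link block residuals
split between $u$ and $v$, precisions matched to the residual scale — which
keeps them out of the collapsed high-precision regime that a near-zero
start can take thousands of iterations to escape. All randomness flows
through R's RNG, so a fit is byte-reproducible given its seed.

Defaults are 4 chains × 5,000 iterations, 2,000 burn-in, thinning 2
(6,000 retained draws) — adequate for maps up to a few hundred blocks;
500-block maps typically want 8,000 iterations. Convergence is assessed by
split-$\hat R$ and an autocorrelation-based effective sample size for
every parameter; any split-$\hat R > 1.05$ flags the fit as unconverged in
the result and in the pipeline summary — never silently.

Correctness of the sampler is established against independent oracles in
the test suite: a dense three-parameter grid integration of the two-block
model with fixed precisions (posterior means and sds of $\alpha$ and
$\beta$ agree within 0.02 on the logit scale), and a one-dimensional
quadrature for a single observed cell.

### Missing blocks

Cells with no respondents contribute nothing to the likelihood; their
fitted values are posterior draws of
$\mathrm{logit}^{-1}(\eta_{it})$ (or $e^{\eta_{it}}$), so a block missing
an entire indicator is imputed from its neighbourhood via $u_i$'s ICAR
conditional plus the state-level terms. Imputed intervals are wider than
observed ones and their medians track the neighbourhood, which the
acceptance suite checks explicitly.

## Model comparison and trend classification

Both models — with and without $\delta$ — are always fitted. They are
compared by the deviance information criterion,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, using
the deviance without its saturated constant (it cancels in the
comparison). The lower DIC wins; exact ties go to the simpler model. A win
for the interaction model is read as evidence that trends vary between
blocks. DIC's known appetite for extra parameters means the no-interaction
truth is recovered only in a majority — not the vast majority — of
replicates; the acceptance suite encodes exactly that expectation.

Block trends are summarised from 10,000 posterior resamples of
$\beta + \delta_i$, exponentiated; the point estimate is the posterior
median (quantile-consistent with the interval endpoints) and the 95%
credible interval is the 2.5th/97.5th resample quantiles. Two resampling
modes are provided:

* `joint` (default): $\beta$ and $\delta_i$ are taken from the same
  posterior draw, preserving their posterior correlation;
* `independent`: each is resampled from its own marginal and the two are
  added — the literal "sample each effect and add" procedure. When
  $\beta$ and $\delta_i$ are posterior-correlated the independent mode
  overstates the interval width; with a perfectly anti-correlated
  posterior the joint interval collapses to a point while the independent
  one does not. Both modes are first-class and tested; the independent
  mode is validated against closed-form lognormal quantiles.

Classification follows the 97.5%-probability rule: an interval entirely
below 1.0 means at least 97.5% posterior probability of a declining trend
(`decrease`); entirely above 1.0, `increase`; anything else — including
intervals touching 1.0 exactly — `indeterminate`. For truly flat blocks
this mislabels at the nominal two-sided 5% rate at most; measured rates on
synthetic nulls are below 10%.

## The synthetic-data generator

`generate_dataset()` draws data from exactly the model above: a centred
ICAR field $u$ (sampled in the eigenbasis of $Q$), iid $v$, centred
$\delta$ (or a user-supplied per-block `delta_values` vector for designed
truths such as a bimodal rising/declining map), uniform integer
denominators, and binomial or Poisson outcomes. Defaults mirror the scale
of the motivating surveys: four rounds, denominators uniform on [19, 123],
and a default 534-block map built as a 23 × 24 rook lattice with 18 cells
removed — the analysis touches the map only through adjacency, so a
lattice stand-in is adequate and no real boundary file is bundled. Two
missingness mechanisms are provided: scattered single-round gaps
(`missing_fraction`) and whole blocks with no respondents for the
indicator (`missing_block_fraction`), the pattern whose imputation
genuinely depends on the spatial prior. Named `scenario()` presets cover a
universal rise, a universal decline, opposite trends across blocks
($\beta = 0$, $\mathrm{sd}(\delta) = 0.4$, i.e. typical block ORs around
1.5 and 0.67), a no-interaction truth, and a map with missing blocks.

What the generator does *not* emulate: the survey's sampling design
(cluster sampling, stratification by child age group), respondent-level
covariates, non-sampling error, and real administrative geography. Passing
tests therefore demonstrate that the estimator recovers the model's own
data-generating process at survey scale — the standard simulation check —
not that any particular field survey satisfies the model's assumptions.
For the Poisson family the generator truncates counts at the maximum
possible count, a negligible deviation at realistic rates (the model's
rates per item are well below 1).

## Numerical choices and edge cases

* Rounds are coded $t = 0, 1, 2, \dots$ treating rounds as annual, so
  $e^{\beta}$ is "relative change per year"; a custom `time_values` map
  accepts unequally spaced rounds.
* A zero denominator is rejected as input: a cell with no respondents is an
  *absent row*, never a zero count.
* Count indicators aggregate per-respondent (count, maximum) records as a
  ratio of sums — equivalently a maximum-weighted mean of per-respondent
  ratios — which is invariant to record order and to splitting records,
  and yields the $(y, n)$ pair the Poisson exposure model needs.
* Isolated blocks (no neighbours) are their own ICAR component: their $u_i$
  is pinned at zero and their level is carried entirely by $v_i$.
* Disconnected graphs are allowed; $u$ is centred per component, and the
  rank used in $\tau_u$'s Gibbs update is $n - (\text{components})$.
* Relabeling blocks permutes the posterior, but a sequential single-site
  sampler consumes randomness in block order, so permuted runs reproduce
  summaries only up to Monte-Carlo error, not bit-for-bit.
* DIC requires at least 100 deviance draws; trend resampling at least
  1,000 resamples; smoothed levels at least 500 retained draws, with a
  warning when the effective sample size falls below 500.

## Problem sizes used in the checks

The test and acceptance suites run at deliberately desk-scale sizes chosen
once: the quadrature cross-check on 2 blocks × 2 rounds; recovery, DIC
selection and imputation on 6 × 6 to 8 × 8 lattices with 4 rounds and
denominators of 50; classification on a 10 × 10 lattice at denominator
100; ten replicates where a rate is measured. The full 534-block default
map is exercised by the generator tests and the analysis scripts.

## Known limitations

* The BYM variance partition between $u$ and $v$ is prior-driven; we report
  and test functions of their sum and of $\beta, \delta$, which are
  likelihood-identified.
* The interaction is unstructured in space (each $\delta_i$ exchangeable);
  a spatially smooth interaction field is a deliberate non-goal.
* Trends are linear on the link scale; four rounds give little power for
  anything richer.
* No survey weights or covariate adjustment: the model smooths the
  published block-round aggregates as given.
* No multiplicity adjustment across indicators or blocks — the
  classification rule is per-block by design.
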