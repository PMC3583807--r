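---
title: "Power and accuracy of state-dependent diversification inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and accuracy of state-dependent diversification inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bissepower)
```

## The model

The binary-state speciation and extinction (BiSSE) model describes a
clade in which every lineage carries a binary character and the three
macroevolutionary processes depend on its state: speciation at rate
$\lambda_0$ or $\lambda_1$, extinction at rate $\mu_0$ or $\mu_1$, and
character change at rates $q_{01}$ (state 0 to 1) and $q_{10}$. The
data are a rooted, ultrametric, strictly bifurcating tree of extant
species with a known state at every tip. The likelihood is computed by
pruning: along every branch, working from the tips toward the root, two
coupled quantities per state are integrated —

* $E_s(t)$, the probability that a lineage in state $s$ at time $t$
  before the present leaves no surviving descendants today, and
* $D_s(t)$, the density of the observed subtree given the lineage was
  in state $s$ —

with

$$E_s' = \mu_s - (\lambda_s + \mu_s + q_{s\cdot})E_s +
  q_{s\cdot}E_{\bar s} + \lambda_s E_s^2, \qquad
  D_s' = -(\lambda_s + \mu_s + q_{s\cdot})D_s + q_{s\cdot}D_{\bar s} +
  2\lambda_s E_s D_s.$$

At an internal node the daughter values are combined,
$D_s \leftarrow \lambda_s D_s^{(L)} D_s^{(R)}$, and at the root the two
state-specific values are averaged with root weights, by default the
stationary state frequencies implied by the rates (matching the
simulator's root-state rule, so simulation and inference are mutually
consistent). The likelihood is not conditioned on clade survival. To
keep 500-tip likelihoods finite in floating point, $(D_0, D_1)$ are
renormalized at every node and the log factors accumulated.

This package exists to measure, by simulation, two properties of that
machinery: the **power** of likelihood-ratio tests to detect a rate
asymmetry, and the **accuracy and precision** of the maximum-likelihood
rate estimates, as functions of tree size and of how strongly the
asymmetry biases the tip-state frequencies.

## Stationary frequency and bias-targeted asymmetries

For rates with $q_{01}+q_{10}>0$ the stationary frequency $\hat x$ of
state 0 solves

$$g\,\hat x(1-\hat x) - \hat x\,q_{01} + (1-\hat x)\,q_{10} = 0,
  \qquad g = \lambda_0 - \mu_0 - \lambda_1 + \mu_1,$$

a quadratic in $\hat x$ with exactly one root in $[0,1]$
(`stationary_freq()`). We solve it in closed form and fall back to
bisection if cancellation leaves the closed-form root outside a
$10^{-10}$ residual — an iteration-free rule that keeps results
independent of any solver configuration. The expected tip ratio of a
clade at stationarity is $(1-\hat x):\hat x$, which is how "3:1" or
"7:1 tip bias" scenarios are defined.

`solve_rate_ratio()` inverts this relationship: given a target
$\hat x$ it finds the ratio $r$ such that placing one process's two
rates geometrically around their base value ($b/\sqrt r$ and
$b\sqrt r$) attains the target. Geometric placement is used because it
keeps the base value as the geometric mean of the pair. The direction
convention is fixed: state 1 is favoured when the target $\hat x <
1/2$, i.e. $\lambda_1 > \lambda_0$, $\mu_0 > \mu_1$, or $q_{01} >
q_{10}$. With bases $\lambda = 0.1$, $\mu = 0.05$, $q = 0.005$, the
ratios for a 3:1 target are 1.1425 (speciation), 1.3046 (extinction)
and exactly 3 (character change, where
$\hat x = q_{10}/(q_{01}+q_{10})$ is closed-form); the 7:1 targets give
1.407, 1.960 and 7.

Note that the single-process asymmetry scenarios
(`asymmetry_scenarios()`) quote *nominal* tip ratios: for example
$\lambda_1/\lambda_0 = 1.25$ with $\mu = 0.03$, $q = 0.01$ has exact
$\hat x = 0.2597$, displayed as "3:1".

## The synthetic-data generator

`sim_bisse()` is an exact continuous-time event simulation: the total
event rate is summed over living lineages ($\lambda_s + \mu_s +
q_{s\cdot}$ each), the waiting time is exponential in that total, and
the event type and victim lineage are chosen in proportion to their
rate contributions. We deliberately use the exact per-lineage,
state-dependent weighting rather than any aggregate-rate approximation:
correctness over micro-optimization. The simulation starts from a
single stem lineage whose state is drawn from the stationary
distribution (configurable), stops the first instant the living-lineage
count reaches the target, and restarts from scratch if the whole clade
dies (counted, capped at 1000 attempts). `prune_extinct()` then removes
extinct lineages, splices out the degree-2 nodes this creates, and
discards the stem above the most recent common ancestor of the
survivors, so the returned object is the reconstructed, extant-only,
ultrametric tree with tip states — exactly what the likelihood
consumes.

What the generator emulates: the joint distribution of reconstructed
tree shape and tip states under state-dependent diversification with
contemporaneous, completely sampled tips. What it does not emulate:
incomplete or biased taxon sampling, phylogenetic estimation error,
fossil tips, or rate variation unrelated to the character. Tests that
pass on these simulations therefore certify the *method under its own
assumptions*; they say nothing about robustness to violations of those
assumptions.

Under the exact simulation the 1.25× speciation scenario yields a mean
tip fraction of state 0 around 0.30 across replicates of 500-tip trees
(per-replicate SD ≈ 0.16, so batch means of 500 replicates carry a
standard error near 0.007) — above the stationary 0.26 because tips
oversample lineages that speciated recently, hence state-1-favouring
history.

Reproducibility: a batch draws one sub-seed per replicate up front from
the base seed, so replicate $i$ can be regenerated in isolation and
identical seeds give byte-identical Newick output.

## Numerical integration

Branch ODEs are integrated with the Runge–Kutta–Fehlberg 4(5) embedded
pair. The initial step is tree height/100; adaptive steps are clamped
to 1/10–10× that initial step; the final step of each branch is
shortened to land exactly on the branch end; a step that still exceeds
tolerance at the minimum clamp raises an integration failure (during
fitting such points are treated as having vanishing likelihood, which
is also what they are scientifically — they arise only at rates far
above one event per unit of tree height). Error control is mixed
absolute/relative per component with defaults `rel_tol = 1e-7`,
`abs_tol = 1e-9`, chosen so the accumulated log-likelihood error stays
near $10^{-6}$ on 500-tip trees — two orders of magnitude inside the
package's own $10^{-5}$ agreement checks against an independent
fixed-step classical RK4 oracle — while keeping step counts about a
third lower than a $10^{-8}$ setting. Extinction probabilities are
clipped to $[0,1]$ after each accepted step; sister lineages must agree
on $E$ at their parent node to $10^{-6}$, a cheap internal-consistency
check on the integration.

## Maximum likelihood

`bisse_fit()` maximizes over the free equality classes of a
`constraint_pattern()` — the 3- to 6-parameter models obtained by
constraining rates to be equal between states, never across processes.
The search is cyclic coordinate descent with Brent line searches
(`stats::optimize`) on log-transformed rates, because rates span orders
of magnitude and must stay positive. Line searches use a local bracket
around the current coordinate (expanded whenever the minimizer lands on
a bracket edge, and adapted to the size of recent moves), and cycling
stops when a full cycle improves the log-likelihood by less than
`reltol` (default $10^{-6}$).

The multi-start schedule: two random log-uniform starting points
(sampled in $[10^{-4}, 10]$ per rate) plus, for models with more than
three parameters, a warm start at the optimum of the fully constrained
symmetric model; every start runs two screening cycles, and the
screened leader — and always the warm start, so a warm-started fit can
never end below the fit that seeded it — is polished to convergence;
ties break to the lowest start index, so fits are deterministic given
the seed. The warm-start chain
(3 → 5 → 6 parameters) mirrors the strategy of starting searches from
more-constrained fits; nested fits therefore never invert the
likelihood ordering. Starts stranded where the clamped integrator
cannot resolve the ODEs (rates far above one event per unit tree
height) are pulled geometrically toward a feasible anchor rate rather
than discarded. The published study did not state its restart counts or
convergence thresholds; these defaults are the package's own,
documented and overridable, and the heavier simulation experiments in
the test suite use a leaner documented configuration (one random start,
single polished leader, `reltol` $10^{-3}$) whose residual
under-optimization affects null and alternative replicates alike.

## Hypothesis testing and power

For a focal process the full and constrained models differ by one
equality constraint; the statistic is $2(\ln L_{\mathrm{full}} - \ln
L_{\mathrm{constrained}})$, clipped at zero when optimizer noise leaves
it a hair negative (larger negatives flag an optimizer failure and the
replicate is redrawn). The factor of 2 is a convention — power is
unaffected because critical values are empirical quantiles of the same
statistic — but it makes the $\chi^2_1$ cutoff (3.841 at 5%)
directly comparable, and that comparison is exposed deliberately: the
simulated null distributions show why relying on the $\chi^2$
approximation is doubtful here. `build_null_distribution()` simulates
trees under symmetric rates, computes the statistic per replicate and
takes the empirical 95th percentile (type-7 interpolation, the
`stats::quantile` default, documented so critical values reproduce to
the digit). `estimate_power()` reports the fraction of
alternative-scenario statistics exceeding that critical value with a
normal-approximation binomial CI. Null rates for the single-process
scenarios set every process symmetric at the alternative's state-0
value; the reduced-model (4-vs-3 parameter) comparisons use their
explicit base rates ($\lambda = 0.1$, $\mu = 0.05$, $q = 0.005$).

## Parameter recovery

`run_recovery()` refits the unconstrained six-parameter model on each
replicate and summarizes per-rate means, standard deviations across
replicates (reported as the spread statistic — the magnitudes in the
published summaries are only plausible as SDs, not standard errors of
the mean, and that interpretation is adopted here), quantiles and bias.
Failed fits are excluded and counted; boundary-pinned fits are included
in the spread but flagged, since excluding them would understate the
spread the estimate clouds visibly contain. The scientifically
interesting behaviour this reproduces: at 500 tips and low tip bias all
six rates are recovered essentially unbiased; under strong bias (e.g.
extinction 10× higher in the common state's counterpart) the spread of
the focal rate explodes and the transition-rate estimate $\hat q_{01}$
inflates several-fold above its generating value — one process's
asymmetry masquerading as another's, the confounding effect.

## Problem sizes and numerical choices in the test suite

The shipped experiments are desk-scale versions of the cluster-scale
design (500 replicates × 4 tree sizes × ~20 scenarios): tip-bias
calibration uses 500 replicates of 500-tip trees; recovery experiments
use 25 replicates of 500-tip trees; type-I calibration uses 200 null
replicates of 100-tip trees with an independently seeded 200-replicate
check; the reduced-model power comparison uses 100 null and 100
alternative replicates of 300-tip trees for the 7:1 speciation
scenario. These sizes are the package's chosen compromise between
Monte-Carlo resolution and a test suite a maintainer will actually run;
the binomial/standard-error tolerances asserted in the tests are
derived from the replicate counts actually used.

## Known limitations

* Only the two-state model: no multistate, time-dependent or
  cladogenetic-change extensions, and no unresolved-clade or
  sampling-fraction corrections — trees must be complete.
* Extinction-rate estimates from extant-only trees are intrinsically
  noisy; with 25-replicate experiments the extinction columns of the
  recovery summaries carry wide Monte-Carlo error, which the acceptance
  tolerances reflect.
* The coordinate-descent optimizer is local; the screening schedule and
  warm-start chain make multimodality failures rare at these problem
  sizes but cannot exclude them. Suspect replicates (negative
  statistics beyond numerical noise) are redrawn and counted.
* Power estimates inherit the optimizer configuration used for both
  null and alternative batches; absolute power levels shift slightly
  with optimizer effort even though the orderings studied here are
  stable.
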