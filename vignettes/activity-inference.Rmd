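---
title: "Inferring dynamic enzyme-activity profiles in the sphingolipid heat-stress response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dynamic enzyme-activity profiles in the sphingolipid heat-stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingodyn)
```

## The scientific problem

When baker's yeast is shifted from 30 to 39 degrees C, the concentrations
of its simple sphingolipids — the sphingoid bases DHS and PHS, their
1-phosphates, and the ceramides DHC and PHC — change within minutes and
return close to baseline by half an hour. Those metabolite changes are
driven by rapid changes in enzyme activities (Arrhenius/Q10 amplification,
deactivation, and the first consequences of stress-induced gene
expression) that cannot be measured directly. `sphingodyn` addresses the
inverse problem: given sparse fold-change time courses of the six
measured sphingolipids and a kinetic model of the pathway, infer
time-varying activity profiles for the pathway enzymes, quantify which of
those profiles the data actually pin down, and run the validation
computations that make the inference credible.

## The model formalism

The pathway is represented in the General Mass Action (GMA) variant of
Biochemical Systems Theory. Every elementary process \(j\) has rate

\[ v_j = \gamma_j \prod_i X_i^{f_{ij}}, \]

with a positive rate constant \(\gamma_j\) and one real-valued kinetic
order \(f_{ij}\) per influencing variable. Metabolites are *dependent*
variables with ODEs \(\dot X_d = \sum_j s_{dj} v_j\) (stoichiometry
\(s_{dj}\) positive for producing, negative for consuming terms);
enzyme activities and fixed pools are *independent* variables that are
held constant within a simulation interval and reset at interval
boundaries. Two model instances ship with the package:

* `sphingo_core_model()` — a ten-species reduced model of the central
  pathway (3-KDHS, the six measured species, and the complex-lipid chain
  IPC, MIPC, M(IP)2C) with 14 enzyme activities. Baselines are
  normalised to 1 and rate constants are balanced so that the baseline is
  an exact steady state; the DHS node has exactly three influx and three
  efflux terms, mirroring the published equation structure. Because all
  baselines are 1, absolute concentrations and fold changes coincide,
  which makes the inference surface parameter *recovery* rather than the
  yeast parameter values themselves.
* `load_full_model()` — a 25-dependent / 41-independent variable model
  read from SBML. The shipped file is a synthetic stand-in with the
  published dimensions and topology (the original supplementary archive
  is not redistributed); any power-law SBML model of the same shape can
  be substituted via `read_sbml_model()`.

Kinetic orders in both bundled models default to 1 for substrates and
catalysts. This is deliberately the simplest member of the GMA family:
the inference machinery never exploits it, and `gma_model()` accepts
arbitrary real orders.

## From duplicate samples to per-minute targets

The measurement design is duplicate fold-change observations of six
species at t = 0, 5, 10, 15, 20, 25, 30 min. `average_replicates()`
takes arithmetic means (replicate scatter is retained for noise
calibration), and `smooth_targets()` fits one cubic smoothing spline per
species, choosing the smoothing level by generalized cross-validation
(`stats::smooth.spline`, `cv = FALSE`), then evaluates it on the
31-point grid 0, 1, ..., 30 min. GCV on seven support points is a
pragmatic default, not a statistically comfortable one; `spar`, `df` and
an exact-interpolation mode are exposed for sensitivity analysis. Curves
are floor-clipped at `eps = 1e-6` because DHS-P sits at a very small
absolute concentration and its fold curve must never touch zero where a
power law needs it positive.

## The piecewise inverse problem

`infer_trajectory()` implements per-interval optimization. Walking the
31-point grid one minute at a time, it searches for the free enzymes'
fold vector that, held constant over \([t, t+1)\), carries the simulated
state closest to the smoothed targets at \(t+1\), minimising

\[ \sum_{\text{species } i} \left( \frac{\hat X_i(t{+}1) - X^{\text{target}}_i(t{+}1)}{X_i^{\text{baseline}}} \right)^2 . \]

Scaling by the baseline makes this a fold-change residual, which
reproduces the strong sensitivity of the fit to proportionally tiny
species. Choices that the method description leaves open, and how this
package resolves them:

* **State carry-forward.** The metabolite state at each interval start
  is the simulated state from the previous interval, not the data: the
  published reconstruction figures show one continuous simulation in
  which only the activities are reset. The data-reset variant is
  available as `inverse_config(reset_state = TRUE)`; in our recovery
  experiments the two behave almost identically.
* **Random initialization.** The fold vector entering the first
  interval's optimization is drawn log-uniformly on \([0.25, 4]\) —
  spanning the plausible Q10 range of "up to about four times baseline"
  — and every later interval warm-starts from its predecessor's optimum.
  The random draw is the only stochastic element and is what
  distinguishes ensemble members.
* **Optimizer.** Bound-constrained L-BFGS-B (bounds \([0, 10]\) on the
  folds) with numerically estimated gradients, at most 60 iterations per
  interval. Each objective evaluation integrates one interval with a
  compiled fixed-step RK4 integrator (10 steps/min); the user-facing
  simulator `simulate_model()` uses `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10` since the full pathway mixes fast (KDHS turnover) and
  slow processes. The two integrators agree to ~1e-6 on the bundled
  models; the published work names neither solver nor tolerances, so
  these are package choices.
* **Degenerate states.** States are clipped at a floor of 1e-12 before
  power-law evaluation, so fractional or unit kinetic orders remain
  defined when an activity is driven to the zero bound.
* **Failure handling.** A non-converged interval is recorded in the
  candidate's `converged` flags rather than aborting; an integration
  failure inside the objective returns a large penalty value.

`run_ensemble()` repeats this from `n_runs` seeds derived reproducibly
from one base seed; `select_top()` keeps the best candidates by SSE or
AICc with ties broken by run order. The study-scale computation is 4144
runs with the best 2004 retained (a 48% retention fraction) on the full
model; the package's desk scale is 100 runs with the top 48 on the core
model, and the unit tests use 4-48 runs so the default suite completes
in minutes. These sizes are configuration, not method.

### AICc convention

For candidate comparison the package computes
\(\mathrm{AICc} = n \ln(\mathrm{SSE}/n) + 2k + 2k(k+1)/(n-k-1)\) with
\(n\) the number of residuals (species x 30 post-baseline grid points)
and \(k\) the number of *free enzymes*. Counting every per-interval fold
value as a parameter would give \(k > n\) and an undefined AICc for
every realistic configuration, so the per-interval values are treated as
re-estimates of the same unknowns rather than independent parameters.
Since all candidates in an ensemble share \(k\), the AICc ranking
provably coincides with the SSE ranking — which is exactly the
consistency property the selection comparison (`criterion_agreement()`)
is meant to exhibit; the check is that the pipeline preserves it at
desk scale.

## Ensemble summaries and identifiability

`summarize_ensemble()` reduces a selected ensemble to, per enzyme and
grid point, the arithmetic mean fold and the pointwise 2.5%/97.5%
quantiles ("enclosing 95% of the results"). The published figures plot
per-time-point bands, so the envelope is pointwise, not simultaneous —
a trajectory-wise band would be wider. `classify_identifiability()`
calls an enzyme *tight* when its mean relative band width
\(\langle (u-l)/\max(m, 0.05) \rangle\) falls below 0.75; the source
analysis classifies qualitatively, so the numeric threshold (and the
0.05 floor protecting the ratio where activities collapse to zero) are
package defaults with overrides. `zone_report()` groups the classes by
the pathway-zone annotation shipped in `inst/extdata/sphingo_zones.csv`.

## Validation computations

* `refit_with_means()` — enter the ensemble-mean activities into the
  model and simulate once. Averages of good fits are not guaranteed to
  be good fits, so the refit reports its own SSE and is judged against
  the median member SSE (default factor 2).
* `complex_lipid_flatness()` — the complex sphingolipids were not
  fitted; their staying nearly constant (default tolerance 0.25 on
  |fold - 1|) is the out-of-sample check. The qualitative published
  judgment is "almost constant"; 0.25 is a package default.
* `negative_control()` — clamp a chosen enzyme set at fold 1 and re-run
  the ensemble at equal seeds; when the clamped set contains the drivers,
  the constrained best SSE must be strictly worse. An empty clamp
  reproduces the unconstrained ensemble bit for bit.
* `cumulative_production()` — integrate a species' producing and
  consuming fluxes along the simulation. With constant influx and
  baseline activities the production of 3-KDHS is exactly linear in
  time; under a heat-stress schedule it is initially steeper and then
  stalls. The identity baseline + production - consumption =
  concentration is a flux-bookkeeping invariant checked to integrator
  tolerance.
* `estimate_q10()` — the immediate activity rise reflects the Arrhenius
  effect; for the 9-degree shift, \(Q_{10} = \text{peak}^{10/9}\) with
  the peak taken over the first 3 minutes (the deactivation phase starts
  "after just a few minutes", so a short window isolates the rise).

## The synthetic-data generator and what recovery can show

`make_truth()` builds ground-truth schedules from five parametric
archetypes that emulate the reported trend shapes: `spike_decay` (rise
to ~4-fold within 1-2 min, decay to near zero by ~6 min),
`spike_decay_late_rise` (late rise at 25-28 min), `sustained_then_drop`
(~20 min of hyperactivity), `triphasic`, and `flat`.
`generate_observations()` simulates the clean trajectory, samples the
six measured species at the seven design times in duplicate, and applies
multiplicative log-normal noise with `sigma = 0.1` (about a 10% CV; the
study does not quantify replicate scatter, so this is a package default
that all stochastic checks are conditional on).
`recovery_experiment()` chains the whole pipeline and scores, per
enzyme, the correlation of the ensemble mean with the truth and the
fraction of grid points covered by the 95% envelope.

Two structural facts limit what any such experiment can show, and the
package treats them as findings rather than defects:

1. **Observability.** Each 1-minute interval provides six residuals for
   14 free activities on the core model; enzyme pairs and cycles that
   act on the same measured balances (kinase/phosphatase/lyase,
   ceramidase/synthase, the IPC synthase/IPCase loop) are structurally
   confounded, and enzymes touching only unmeasured species (MIPC and
   M(IP)2C synthases, and the entry enzyme through the unmeasured
   3-KDHS pool) cannot be pinned pointwise at all. The recovery report
   exhibits exactly this asymmetry: strong shape recovery for enzymes
   such as ceramide synthase and IPCase, wide or biased envelopes for
   the confounded sets — the desk-scale analogue of the published
   observation that only the influx/efflux controllers have tight
   ranges while peripheral enzymes are not identifiable.
2. **Sampling aliasing.** The design samples every 5 minutes, while the
   archetype transients play out in 1-2 minutes. The smoothing spline
   therefore reconstructs a curve that deviates from the true trajectory
   between support points even at zero noise, and candidates fit that
   reconstruction far more closely than the truth itself fits it.
   Minute-resolution activity values inside the first sampling interval
   are thus determined by the interpolant, not by the data — a caveat
   that applies to the published minute-scale trends as much as to the
   synthetic recovery here.

Consequently the package's tests assert full recovery only in designed
identifiable scenarios (a determined two-species chain; a cycle
modulation with the free set restricted to the moving enzymes) and
assert the asymmetry — loose classification for unobservable enzymes,
selective recovery elsewhere — for the paper-shaped default truth. What
passing tests do *not* show is that real minute-scale activity spikes
are quantitatively recoverable from 5-minute sampling; they are not.

The generator emulates the study's design (species set, sampling times,
duplicates, fold-change units, multiplicative noise). It does not
emulate measurement-specific artifacts (detection floors,
species-dependent noise, replicate correlation), and its truth schedules
are smooth parametric shapes rather than outputs of any biological
model of heat signalling.

## Problem sizes and runtimes

Simulations in the test-suite use the 10-species core model with
ensembles of 4-48 members; the acceptance computation uses the desk
scale of 100 members with top-48 selection (a few minutes on one CPU). The full 25-species model is exercised structurally (loading,
steady state, simulation) rather than through ensembles.

## Known limitations

* Identifiability depends on the free-enzyme set; the default (all
  enzymes of the model) maximises honesty about degeneracy but also
  maximises envelope width. Restricting `inverse_config(free = ...)` to
  a hypothesis set sharpens recovery at the price of assuming the rest.
* The ensemble mean of an underdetermined problem is biased toward the
  mean of the initialization distribution (~1.35 for the log-uniform
  default) along unconstrained directions; envelope width, not the mean,
  is the trustworthy signal there.
* No regularization links adjacent intervals, matching the source
  method; inferred profiles can therefore be rougher than biologically
  plausible.
* SBML import is restricted to kinetic laws that are (sums of) products
  of power laws, which is the GMA class; anything else raises an error
  naming the reaction.
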