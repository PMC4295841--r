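---
title: "Synapse-count equilibria on a plastic multi-synaptic connection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synapse-count equilibria on a plastic multi-synaptic connection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structplast)
```

## The model

Paired recordings in cortex show that the number of synapses `S` carried by a
connected neuron pair is bimodal: most pairs are unconnected (75–99% at
`S = 0`) and connected pairs carry 3–8 synapses, with 1–2 synapses being
rare. `structplast` implements a minimal model that explains this shape from
the interaction of two processes on one connection with `P` *potential*
synaptic sites:

* **structural plasticity** — at every (slow) time step each vacant site
  builds a synapse with probability `p_build`, and each realised synapse with
  weight `w` is removed with probability
  `p_del(w) = p_build^rho * exp(-a^2 w^q)`, a decreasing function of the
  weight (big spines live longer); `q = 4/3` by default, motivated by
  spine-volume dynamics, and configurable because the results are insensitive
  to it;
* **synaptic plasticity** — between structural events each weight relaxes to
  the stable fixed point `w*` of a rate-based learning rule, evaluated at the
  self-consistent postsynaptic rate `v_i* = F(S w* v_j + I)` with logistic
  `F` (rates are normalised to [0, 1] in the analytic model).

Because structural changes are much slower than weight dynamics (time-scale
separation), the synapse count is a Markov chain whose one-step kernel
depends only on `S`. The stationary distribution comes from the dominant
eigenvector of the exact transition matrix, or in closed form from the
*first-step approximation* (at most one change per step), which puts the
chain in detailed balance:

```
p[S] / p[S-1] = (P - S + 1) / S * p_build / p_del(w*[S])
```

```{r equilibrium}
io    <- logistic_io()
rule  <- rule_spec("bcm_scaling")                 # mu, theta, kappa, v_tss defaults
sp    <- structural_params()                      # P = 12, ln p_build = -16, rho = 0.125, a = 2
point <- system_point(v_j = 0.656, v_i_S0 = 0.2975, io = io)

prof <- activity_profile(sp$P, point, rule, io)
pdel <- pdel_profile(sp, prof)
d    <- first_step_distribution(sp, pdel)
round(unclass(d), 3)
classify_case(delta_ln_p(sp, pdel))
```

At this working point the distribution is "case 6" — maxima at `S = 0` and
at `S = 4` — the experimentally observed shape.

## Why ρ is an exponent

The deletion probability is `p_build^rho * exp(-a^2 w^q)`, i.e. `rho` scales
the *logarithm* of the maximal deletion probability relative to
`log(p_build)`. With the reference parameters (`ln p_build = -16`,
`rho = 0.125`) weak synapses are deleted with probability `e^-2` per step,
about `3e5` times faster than sites build — which is exactly what the huge
peak at `S = 0` requires. A multiplicative reading (`p_build * rho`) would
cap deletion at `p_build/8` and make a maximum at `S = 0` algebraically
impossible for any weight profile; we therefore treat the exponent reading
as the model definition.

## Distribution shapes and rule constraints

`delta_ln_p()` is a discrete derivative of `ln p[S]`; its sign changes
locate the extrema, and `classify_case()` maps the sign pattern onto six
qualitative shapes (two boundary-peaked monotone cases, single interior
maximum, double boundary maxima, and the two two-crossing cases). Rewriting
the zero-crossing condition over continuous postsynaptic activity separates
the model components: `p_cf(v)` (combinatorics + build rate, always
increasing, S-shaped through the IO curve) against `p_d(v) = -ln p_del(w*(v))`
(the plasticity rule). Two intersections — the bimodal case — require:

1. **necessary**: the fixed weight must grow with the postsynaptic rate
   (`necessary_condition()`, central differences on a 200-point grid,
   step 1e-4, strictly positive throughout the evaluable range);
2. **sufficient**: the mean curvature of `delta_ln_p` between its two
   crossings must be negative (`sufficient_condition()`), supplied either by
   a concave IO curve or by a sublinear v–w relation.

Across {Hebb, BCM (fixed/sliding threshold), Oja, Hebb+scaling,
BCM+scaling} × {feed-forward, linear feedback}, only Hebb-with-scaling under
feedback and BCM-with-scaling in both systems pass the necessary condition —
reproduced exactly by the acceptance suite. The calcium-threshold spiking
rule also passes, with a sublinearly growing v–w relation
(`ca_vw_surface()`).

Degenerate inputs: an exactly zero `delta_ln_p` entry is counted as a
crossing at that state with the maximum assigned to the larger-probability
neighbour (a measure-zero tie needing a deterministic rule); all-zero
profiles report a degenerate result; more than two crossings fall outside
the six-case taxonomy and return `NA` with the pattern attached.

## Numerical choices

* All distribution arithmetic is in log space with one exp-normalisation at
  the end; unnormalised terms span `~e^(16 P)` scales at the reference
  parameters.
* The stationary distribution solves the singular balance system directly
  (one row replaced by normalisation), with an eigen fallback; the residual
  `||Mp - p||_inf < 1e-10` is enforced, and the first-step distribution must
  satisfy detailed balance to 1e-12.
* `consistent_state()` scans `g(v) = F(S w*(v) v_j + I) - v` on a 400-point
  grid and bisects each bracket (tolerance 1e-13, residual checked against
  1e-10). Where the rule has no finite stable fixed point, the clamped
  weight dynamics (`w >= 0`) may rest at the boundary `w = 0`; that
  "collapsed" state solves the self-consistency exactly at `v = F(I)` and is
  detected explicitly. With multiple roots the branch continued from the
  zero-synapse state (forward iteration from `v = F(I)`) is primary and all
  roots are reported. Saturated branches (`v -> 1` within double precision)
  are recovered by forward iteration above the grid.
* The combinatorial factor is continued to real `S` only inside the
  `p_cf`/`p_d` analysis, never in probability computations.

## The stochastic simulator and time rescaling

`run_equilibrium_sim()`/`run_hysteresis()` simulate the full dynamics in the
printed step order (rates → RK4 weight update → deletion → creation at the
sites vacant at the step start, matching the transition matrix), with new
synapses initialised at `w0 = 0.05 kappa (1 - v_tss)^{-1/2}` (the literal
reading of the reference simulations; the typography admits a `sqrt(kappa)`
reading, available via `sim_config(w_init = )`).

At `ln p_build = -16` the reference protocols need `~1e9` steps. Because
`p_del` is proportional to `p_build^rho` only through the *ratio* entering
every equilibrium quantity, multiplying **both** probabilities by a common
`speedup` factor compresses the structural clock without changing the
stationary distribution or the fixed-point diagram. The one thing that must
be preserved separately is the race between a new synapse's weight growth
and its (still high) deletion probability: setting `substeps = speedup`
gives each structural step `speedup` units of weight-integration time, so
the deletion hazard accumulated during the convergence transient is
invariant. Desk-scale runs use `speedup = substeps` of 30–100; the RK4 block
exits early once the weights are at rest, so converged steps cost one
substep.

## Bistability and hysteresis

Treating `S` as continuous, the net flow
`h(S) = (P - S) p_build - S p_del(w*(S))` has alternating stable/unstable
roots. Sweeping the postsynaptic stimulation (parameterised as the rate at
zero synapses) yields a bistable band bounded by two saddle-node
bifurcations; stable roots below one synapse are flagged as the effective
`S = 0` attractor and root pairs closer than one synapse as unresolvable by
the discrete chain (for presynaptic sweeps the upper bifurcation only occurs
through this discrete merging). Inside the band the chain's two basins are
connected only through the low-probability states at 1–2 synapses, so a
stimulation sweep faster than that mixing time shows hysteresis: the
decreasing branch keeps its synapses (their large weights protect them)
while the increasing branch stays empty until the lower attractor vanishes.
An equilibrated system shows no hysteresis — the loop is a statement about
time scales, not about the stationary state. The loop area is consequently
non-monotone in the dwell time per level: very short dwells never populate
the upper attractor at all (area shrinks again), very long dwells let the
chain mix across the barrier (area vanishes), and the loop is widest in
between. Desk-scale runs sit on the short side of that curve.

## Monte-Carlo goodness of fit

Sparse experimental histograms (10–50 pairs) defeat standard tests, so
`mc_pvalue()` resamples `N_exp` draws from the model `N_MC` times and reports
the fraction of resampled squared errors at least as large as the
experimental one. Ties are counted conservatively ("larger or equal"; the
strict count is also returned — the two differ only through discrete
coincidences). `scan_confidence_region()` maps the p-value over a grid of
(presynaptic activity, postsynaptic stimulation at `S = 0`) and masks
`p > 0.05`; per-cell seeds derive deterministically from one master seed so
scans are reproducible cell by cell. Failed cells (rule domain errors) are
`NA`, excluded from summaries, and reported as a coverage fraction. Grid
defaults are desk-scale (tens per axis); the published scans used up to
446 × 357 cells and are available by passing bigger axes.

When the number of potential synapses is itself distributed,
`mixture_over_P()` sums per-`P` equilibria under a prior
(`default_p_prior()` ships a clearly labelled synthetic stand-in over
`P = 1..20` with most mass below 12). Because small-`P` components pile
probability at `S = 0`, the mixture at the `P = 12` working point loses the
interior peak; matching data under a `P`-prior requires somewhat higher
presynaptic activities, which is why mixture confidence regions sit slightly
above the fixed-`P` ones.

## The calcium rule and the spiking pathway

The calcium-threshold rule is integrated event-by-event: the calcium trace
decays exponentially between spikes, downward threshold crossings have
closed-form times, and within each constant-indicator interval the weight
relaxes exponentially — exact up to floating point (the bistable potential
term of the original rule is omitted, as in the rate-model analysis). An
independent fixed-step Euler integrator exists purely as an oracle; the
acceptance suite requires agreement within 1e-3 absolute weight at
`dt = 1 µs` over 10-s Poisson pairs. Ensemble fixed weights stop when the
block-to-block change of the ensemble mean stays below the target accuracy
(0.005) for three consecutive blocks — an operationalisation of
"fluctuating around a stationary value", which the source describes only
qualitatively. The AdEx f-I curve uses forward Euler with per-step white
current noise (`sigma = 0.05 I`); the printed noise specification does not
fix the noise correlation time, so per-step white noise is our choice, and
the neuron constants (not reprinted in the source) default to the standard
regular-spiking set of the two-variable adaptive exponential model, placing
the rheobase at ~600 pA. All conclusions drawn from this pathway are
property-level (ordering, monotonicity, sublinearity), never value-level.

## What the synthetic fixtures are (and are not)

`generate_fixture()` emulates the *shape* of published synapse-count
histograms: a point mass at zero (default 0.9, within the reported
0.75–0.99) plus a discretised Gaussian bump centred at 3–8 synapses
(default 5, spread 1.2 synapses), sampled at `N_exp = 30` pairs. These
defaults are the stated world of the generator and are not revisited. The
fixtures carry none of the measurement structure of real data (quantal
analysis errors, unresolved multi-synapse contacts, selection of responsive
pairs), so a green comparison against a fixture establishes that the
machinery behaves as specified — not that the model fits any particular
laboratory dataset.

## Known limitations

* One Markov step has no fixed physical duration; all probabilities are per
  step and real-time statements require an external calibration of
  `p_build`.
* The feedback system is the linear approximation `v_j = r0 + r1 v_i`;
  intermediate `(r0, r1)` fixed weights substitute `v_j(v_i)` into the
  feed-forward closed forms, an extension beyond the two systems analysed in
  the source.
* Network effects beyond one connection, activity-dependent `P`, and
  absorbing-state/first-passage analyses are out of scope.
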