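---
title: "Flux-target model predictive control of fed-batch CHO cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-target model predictive control of fed-batch CHO cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmpc)
```

## The control problem

Industrial production of therapeutic antibodies runs Chinese Hamster
Ovary (CHO) cells in fed-batch bioreactors: a batch is inoculated, fed
over two to three weeks, and harvested. The feeding recipe is usually
fixed *a priori*, and ignores how the culture actually evolves.
`fluxmpc` implements a hybrid kinetic-stoichiometric alternative: a
stoichiometric model of cell metabolism supplies *target exchange
fluxes* per culture phase, a Monod-kinetic digital twin simulates the
reactor, and a model predictive controller (MPC) repeatedly re-plans the
feeding so that the culture's realised specific fluxes track the
targets.

The framework has three layers.

**1. Stage-wise flux balance analysis (FBA).** For a metabolite ×
reaction stoichiometric matrix $S$, FBA solves

$$\max_v \; v_\mathrm{biomass} \quad \text{s.t.} \quad S v = 0,\;
v_\mathrm{irrev} \ge 0,\; LB \le v \le UB,$$

once per culture stage (early/mid/late exponential, early/late
stationary), with stage-specific bounds expressing what the cell can do
in that phase. The tracked outputs are the exchange fluxes of the
extracellular metabolites plus the biomass flux (positive = secretion,
negative = uptake). Two implementation points matter:

* The strict positivity of irreversible fluxes is implemented as
  $v \ge 0$; a strict inequality has no LP meaning and zero flux is the
  closure of the constraint.
* Alternate optima are resolved by returning the *minimum-norm* point
  of the optimal face, so target tables are unique and reproducible.
  Both phases are obtained from a single exact projection QP: for a
  bounded flux polytope and a large enough pull $\lambda$, the minimiser
  of $\tfrac12\lVert v\rVert^2 - \lambda\, c^\top v$ is the projection of
  $\lambda c$ onto the polytope, which lies on the LP-optimal face and
  is its minimum-norm point. The solver escalates $\lambda$ until the
  optimum stabilises; divergence of $\lVert v\rVert$ diagnoses an
  unbounded problem. Correctness is cross-checked in the test suite
  against an independent vertex-enumeration oracle on the (deliberately
  small) fixture network.

**2. The digital twin.** The reactor model tracks volume $V$, viable and
dead cell densities $X_v, X_d$, the extracellular concentrations $C_i$,
and antibody titre $P$:

$$\frac{dV}{dt} = F_{in} - F_{out}, \qquad
\frac{d(V X_v)}{dt} = (\mu - \mu_d)V X_v - F_{out} X_v,$$
$$\frac{d(V C_i)}{dt} = F_{in} C_{feed,i} - F_{out} C_i + q_i X_v V,
\qquad \frac{d(V P)}{dt} = q_P X_v V - F_{out} P.$$

The rate laws follow the canonical CHO Monod structure: multiplicative
Monod limitation of growth on glucose, glutamine and asparagine,
multiplicative lactate and ammonia inhibition
($\mu = \mu_{max} \prod_i \frac{C_i}{K_i + C_i} \prod_j
\frac{K_{I,j}}{K_{I,j} + C_j}$); a linear ammonia term in the death rate
($\mu_d = k_{d,0} + k_{d,amm}[\mathrm{NH_4}]$); growth-linked glucose
uptake with a maintenance term; the *lactate shift* from production
(yield on glucose uptake) to consumption (Monod in lactate) as glucose
falls through a threshold, blended by a smooth sigmoid of width 0.5
mmol/L so the optimizer sees a differentiable model; ammonia and alanine
secretion yield-linked to glutamine uptake; and Luedeking-Piret antibody
production $q_P = \alpha\mu + \beta\,f(\mathrm{glc})$ with the
non-growth term gated by glucose so an empty medium is inert. All rate
laws live behind `specific_rates()` / `rhs_core()` so alternative
kinetic forms can be swapped in; the compiled C right-hand side used by
the integrator mirrors the R reference implementation and the tests
assert their agreement. Integration is adaptive (lsoda, relative
tolerance 1e-8 for reported trajectories, 1e-6 inside the optimizer);
concentrations are clipped at zero in the rate laws and clip events are
logged on the trajectory object.

Internal units are hours, litres, mmol/L, $10^9$ cells/L and mg/L;
specific rates are mmol per $10^9$ cells per hour and the biomass flux
is $\mu$ in 1/h. Configuration files may annotate quantities with units
(`L/min`, `mmol/min`, ...), converted exactly once at the I/O boundary.

**3. The controller.** Over a receding horizon $T_{opt}$ (default 72 h)
the controller chooses piecewise-linear profiles of three manipulated
variables - glucose feed concentration (0-1000 mmol/L), inlet flow
(0.001-1 L/min) and outlet flow (0-0.05 L/min) - with knots at every
control-interval boundary, minimising

$$OF = \int_0^{T_{opt}} \sum_j w_j\,
\bigl(\bar z_j(t) - z^{target}_j(t)\bigr)^2\, dt,$$

by trapezoidal quadrature on the simulation grid. Case A tracks all
extracellular metabolite fluxes plus biomass; Case B tracks the glucose
flux only. Targets follow the stage schedule along the horizon (a
horizon straddling a stage boundary uses each stage's own targets).
Because fluxes differ by orders of magnitude, the default weights are
$w_j = 1/\max(|z^{target}_j|, 10^{-6})^2$, making residuals
dimensionless; they are user-overridable. The antibody (product) flux is
reported alongside the targets but not tracked: its natural units (mass,
not moles) differ and treating it as tracked is not clearly supported.

The nonlinear program is solved by single shooting: decision variables
are the knot values, each candidate is simulated through the twin, and a
derivative-free local solver (BOBYQA; Brent for one free variable)
refines the best of a deterministic multistart set (minimum feed,
mid-bounds, and the previous solution shifted by one interval). The
returned solution is the best of all starts and refinements, so its
objective never exceeds any warm start's. The evaluation budget scales
with the decision dimension ($10n + 50$ per start) so finely
parameterised horizons receive proportionate effort. Optional seeded
random multistarts are available; the default configuration is fully
deterministic.

Two regularisation choices deserve note:

* *Rate-of-change limits.* The +/-5 or +/-10 mmol/L limits on the
  glucose feed concentration are implemented as hard constraints, by
  construction of the decision encoding: raw knot values are clamped
  sequentially into the moving band allowed by the previous knot (and,
  for the first knot, by the previously *implemented* value - at batch
  start, the actuator state 0). Every feasible sequence is a fixed point
  of the clamp, so the transform is surjective onto the feasible set and
  the optimizer works in a plain box. A soft quadratic penalty mode is
  also available for comparison.
* *Input regularisation.* Outflow removes broth at its current
  composition, so it does not enter any concentration balance and the
  tracking objective leaves it undetermined (other inputs can likewise
  be locally indifferent when targets saturate). A tiny quadratic
  penalty (1e-3, dimensionless) on normalised actuation breaks such
  ties toward minimal feeding and outflow; it is subtracted before the
  objective is reported.

**Closed loop.** Following the receding-horizon protocol, at every
control interval the twin state is read, the horizon problem is solved
(truncated at batch end), only the first interval of the optimal policy
is implemented, and the loop repeats. Implemented segments are
concatenated into one policy; re-optimization steps at the seams are
preserved as jump discontinuities (the earlier end knot is shifted back
by 1e-9 h), so replaying the concatenated policy open-loop reproduces
the closed-loop trajectory to integrator tolerance - an invariant the
acceptance suite checks. Percent improvements are computed at batch end
against an open-loop baseline simulation of a fixed recipe.

## The fixture: what it emulates and what it does not

The package ships a self-contained, deliberately small fixture so every
claim can be exercised without external data. **All fixture values are
illustrative**: they are chosen for a well-conditioned toy problem with
the right qualitative physiology, not estimated from any dataset.

* `toy_network()` - 11 metabolites, 14 reactions: exchanges for
  glucose, glutamine, asparagine, lactate, ammonia and alanine, a lumped
  glycolysis step, reversible lactate dehydrogenase, glutaminolysis and
  asparaginase lumps releasing ammonia, alanine transaminase, a biomass
  drain and an antibody synthesis/secretion pair. It is small enough for
  the brute-force vertex-enumeration LP oracle used in the tests.
* `toy_stage_bounds()` - five bound sets in which glucose uptake is
  pinned at a stage-typical value, glutamine/asparagine ceilings shrink
  with culture age, lactate is restricted to secretion in the
  exponential stages and forced to mild uptake in the stationary ones,
  and a minimum antibody-synthesis commitment peaks in early stationary
  phase. The resulting targets show strictly decreasing biomass flux, a
  lactate secretion-to-uptake sign change between late exponential and
  early stationary phase, and a product-flux peak in early stationary
  phase.
* `nominal_parameters()` - a 25-parameter reduced-scale kinetic set
  with CHO-plausible magnitudes ($\mu_{max}$ 0.045/h, saturated glucose
  uptake ~0.17 mmol/$10^9$ cells/h, ammonia death coefficient 8e-4
  L/mmol/h). The full-scale model this structure stands in for has 35
  parameters; the reduction comes from tracking 6 rather than 22
  extracellular species. The tracked species set is data-driven (from
  the network's extracellular metabolites), so a larger network extends
  the twin without code changes.
* `nominal_state()` and `baseline_policy()` - a 1000 L production-scale
  seed (0.3e9 cells/L) and a deliberately conservative fixed recipe
  (400 mmol/L glucose feed at 0.5 L/h): it sustains the early culture
  but underfeeds once cell density grows, leaving headroom for the
  controller, as a recipe "decided in advance" typically does. A no-feed
  batch depletes glucose at ~158 h and shows the canonical rise and fall
  of viable cells and the lactate shift.
* `fixture_control_config()` - the closed-loop study conditions. The
  literature manipulated-variable bounds remain the package defaults,
  but at 1000 L an inlet bound of 1 L/min would admit a twenty-fold
  volume expansion per batch, which is a dilution reactor rather than a
  fed-batch; the fixture campaigns therefore cap inlet at 0.05 L/min
  (at most ~2x volume per batch) and outlet at sampling scale
  (0.002 L/min).

What passing the fixture tests shows: the FBA solver is exact on small
networks, the twin integrates its stated equations to tight tolerance,
the optimizer returns feasible, warm-start-dominating, deterministic
solutions, and the closed loop on this fixture strongly outperforms its
baseline (roughly doubling final antibody mass), with Case A ahead of
Case B and tighter rate limits feeding less glucose. What it does not
show: performance on real cultures, where measurement noise,
plant-model mismatch and parameter drift dominate; the twin here is both
plant and model, the idealised setting of a digital-twin study.

## Problem sizes and numerical choices

The test and acceptance workloads use the fixture scale throughout: a
14-reaction network (vertex enumeration enumerates all basic solutions),
360 h batches on an 11-state ODE, and campaigns of 5-45 optimization
cycles with 6-30 decision variables. The fixed-step RK4 oracle runs at
dt = 0.01 h from an independent re-derivation of the model equations.
Determinism is exact: repeated runs with the same seed produce
bit-identical target tables, policies and metrics.

Degenerate inputs are handled explicitly: fully-fixed flux boxes skip
the QP; redundant stoichiometry rows are dropped by QR rank detection
(with feasibility re-checked on the full residual); empty horizons and
non-spanning policies raise informative errors; negative concentrations
are clipped in the rate laws only.

## Known limitations

* The interval-monotonicity claim (shorter control intervals yield more
  antibody) does **not** hold on this fixture: under the canonical
  Monod/Luedeking-Piret structure, product mass is monotone in nutrients
  fed, so a coarse controller that overfeeds the batch tail ends
  slightly (~0.5-2%) ahead of a finer tracker. Every dilution-resistant
  toxicity channel we examined either rewards the feed that causes it or
  lies beyond the controller's horizon. Reproducing that ordering
  appears to require a plant in which late glucose is net-toxic, which
  this twin structure does not produce; the package reports the
  measured ordering as is.
* Case B at short intervals shows near-bang-bang glucose feeding; the
  rate-of-change limit is the intended mitigation and behaves as
  documented (less glucose fed, at some cost in antibody).
* The twin has no intracellular states, pH/temperature/DO effects, cell
  lysis, or measurement noise (a hook for additive state noise exists
  but is off by default). Dead cells are tracked but inert.
* FBA targets are an idealised ceiling; the twin cannot realise some of
  them (e.g. stationary-phase glucose targets assume lactate refuels
  growth, which the kinetic structure does not represent). The
  controller is designed for exactly this situation - tracking weighs
  deviations rather than requiring feasibility - and the tracking
  report quantifies the residual per flux and stage.
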