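---
title: "Methods: a kinetic model of the branched Entner-Doudoroff pathway"
author: "edflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a kinetic model of the branched Entner-Doudoroff pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system

Thermoacidophilic Archaea such as *Sulfolobus solfataricus* (optimal
growth around 80 °C, pH 2–4) catabolize D-glucose to pyruvate through a
modified, branched Entner–Doudoroff (ED) pathway rather than classical
glycolysis.  Glucose is oxidized to D-gluconate (glucose dehydrogenase)
and dehydrated to 2-keto-3-deoxygluconate (KDG), where the pathway
bifurcates:

* the **semi-phosphorylative branch (spED)** phosphorylates KDG to KDPG,
  which the bifunctional KD(P)G aldolase cleaves into glyceraldehyde
  3-phosphate (GAP) and pyruvate; GAP proceeds through
  GAPDH/PGK (or the irreversible, non-phosphorylating GAPN bypass) and
  the phosphoglycerate mutase to 2-phosphoglycerate (2-PG);
* the **non-phosphorylative branch (npED)** cleaves KDG directly into
  glyceraldehyde (GA) and pyruvate; GA is oxidized to glycerate
  (ferredoxin-dependent GAOR) and phosphorylated by glycerate kinase
  (GK) to 2-PG.

The branches reconverge at 2-PG, which enolase converts to
phosphoenolpyruvate (PEP) and pyruvate kinase to pyruvate; PEP synthase
provides the anabolic back-reaction.  Three intermediates — GAP, 1,3-BPG
and PEP — are thermolabile at these temperatures and decay with
measured, temperature-specific half-lives.  Carbon also leaves the
modelled subsystem through two first-order sinks: from GAP towards
gluconeogenesis/glycogen, and from pyruvate towards the TCA cycle.

Two regulatory motifs are represented: glycerate inhibits its own
kinase (a feedforward throttle between the branches), and PGK carries a
generic effector-inhibition factor (effector configurable, 3-PG product
inhibition by default).

## Model structure

Twelve state metabolites (Glc, D-Gat, KDG, KDPG, GAP, 1,3-BPG, 3-PG,
2-PG, PEP, Pyr, GA, Gly) evolve under 20 reactions; 5 of them
(npED aldolase, GAPDH, PGK, mutase, enolase) are reversible and carry
independent forward/reverse maximal velocities, giving 25 velocity
parameters in total (22 maximal velocities/sink constants + 3 decay
rates).  Rate laws are the minimal forms consistent with the stated
reversibilities:

* influx: zero order, $v = V_{up}$;
* irreversible steps: Michaelis–Menten, $v = V S/(K_m + S)$;
* reversible steps: two-term reversible Michaelis–Menten,
  $v = (V_f S/K_{mS} - V_r P/K_{mP}) / (1 + S/K_{mS} + P/K_{mP})$, with
  a bimolecular product term for the npED aldolase (GA and Pyr);
* glycerate kinase: substrate-inhibited Michaelis–Menten,
  $v = V S / (K_m + S (1 + S/K_i))$, maximal at
  $S^\ast = \sqrt{K_m K_i}$;
* sinks and thermal decay: first order, with decay constants
  $\ln 2 / t_{1/2}$ from the half-lives.

Cofactor pools (ATP/ADP, NADP⁺/NADPH, reduced ferredoxin) are clamped:
each cofactor-dependent velocity is multiplied by a saturation factor
$c/(K_c + c)$ with fixed pool concentration $c$.  Pools are
near-saturating, so relaxing the clamp by ±25 % moves steady states
only mildly (`vary_cofactors()`; the package tests assert < 10 %).
GAPN activation by glucose 1-phosphate is folded into its effective
$V_{max}/K_m$, not modelled as a state.

Units: concentrations mM, time min.  Enzyme activities are stored as
measured in cell-free extract (U/g CE, U = µmol/min) and scaled to
intracellular fluxes (mM/min) with a cytosolic protein density of
0.250 g/mL (`scale_activity_to_flux()`).

The right-hand side is implemented twice: a compiled C version used by
the `deSolve::lsoda` integrator (steady-state solves are
milliseconds-scale, which keeps 1000-draw Monte-Carlo ensembles cheap) and
a pure-R reference implementation; the two are cross-checked in the
test suite.

## Steady states

`steady_state()` integrates over exponentially spaced checkpoints
(10, 100, …, 10⁶ min) and accepts the first checkpoint at which every
$|dX/dt| \le 10^{-6}$ mM/min — an absolute-rate criterion, appropriate
here because the metabolite scales span less than three orders of
magnitude.  The system is non-oscillatory, so checkpointed integration
suffices and no root polishing is applied.  Transient negative
excursions of the stiff variables are clamped to zero inside the rate
evaluation.

The default initial state is 0.1 mM for every metabolite except Glc and
D-Gat, which start at the concentrations that balance their
Michaelis–Menten consumption against the influx.  **Basin of
attraction:** the substrate-inhibited glycerate kinase has a finite
maximal throughput, so initial states loading several mM of Gly or GA
can trigger a self-reinforcing glycerate runaway (less GK flux → KDG
accumulates → more npED flux → more Gly) from which no steady state is
reached.  Initial-condition-independence is therefore asserted over an
order of magnitude around the documented 0.1 mM operating point
(log-uniform over 0.01–1 mM), and `steady_state()` reports
`converged = FALSE` with diagnostics outside the basin.

`weighted_relative_change()` compares two steady states element-wise:
$rc_i = ((sim_i - ref_i)/sim_i) \cdot E_i/\sum E$ with weights taken
from the `sim` state.  An "aggregate ratio" between two states can be
read either as the mean of per-element ratios or as the ratio of sums;
both are reported (attributes `mean_ratio`, `sum_ratio`) and the mean
of per-element ratios is the default throughout.

## Temperature machinery

Enzyme-catalyzed rate constants follow the Arrhenius law with a
characteristic activation enthalpy of 60 kJ/mol, giving
`arrhenius_rate_ratio()` $= \exp(E_i/R\,(1/T_1 - 1/T_2)) \approx 1.814$
between 343.15 K and 353.15 K — i.e. velocities roughly double per
+10 °C, the empirical Van't Hoff rule.  `vant_hoff_transform()` maps a
parameter set across the 10 °C step by doubling (or halving) every
maximal velocity and sink constant; Km/Ki are treated as
temperature-independent, and decay rates are *not* rescaled because
half-lives are measured per temperature and supplied as data.  The
1,3-BPG decay rate at 80 °C is transferred from 70 °C with
`degradation_rate_80_from_70()`; the published transfer formula divides
by the mean 70/80 ratio of the reference quantities, which slows decay
at the higher temperature if the ratios are ratios of half-lives and
accelerates it if they are ratios of rates.  The function implements
the division literally and exposes `inverted = TRUE` for the rate-ratio
(physically expected) convention, which the packaged parameterization
uses.

## Parameter estimation

Eleven of the 25 velocity parameters could not be measured in cell-free
extract in the original study (influx, KDG kinase, glycerate kinase,
both enolase directions, GAOR, the unassayed reverse directions of
GAPDH/PGK/mutase) and the two sink constants must also be estimated.
`fit_free_parameters()` minimizes, over the free velocities at both
temperatures jointly,

$$SSR = \sum_{m}\left(\frac{SS^{80}_m - SS^{sim80}_m}{SS^{80}_m}\right)^2
 + \sum_{m \in \{Glc, DGat, KDG, Gly\}}
   \left(\frac{SS^{70}_m/SS^{80}_m - \rho_m}{\rho_m}\right)^2,$$

where $SS^{sim80}$ is the steady state under doubled 70 °C velocities
(Van't Hoff consistency) and $\rho$ are the measured metabolome ratios
(0.97, 1.27, 4.16, 1.91).  Constraints: free velocities in
(10, 1000) U/g CE, optionally measured velocities within ±SD
(independently per temperature), every steady concentration below
100 mM (enforced as a quadratic penalty so the search space stays
connected; the final fit must satisfy it strictly), and a large flat
sentinel replaces the residuals when a candidate does not converge.

The optimizer is global-then-local: a cheap SSR screen over candidate
starts (the current values, lognormal jitters around them, and
log-uniform draws over the whole box) followed by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) in log10 space from the best
few.  This matters: jitter-only restarts stall in local minima on this
objective.

**Identifiability.**  The observables (four temperature-ratios,
cross-temperature consistency, the measured velocities) do not identify
absolute steady-state concentrations.  The objective has sloppy
directions — e.g. sink constants and glycerate-kinase capacity can move
substantially while every observable is preserved, because consistent
changes at both temperatures cancel in the ratios.  In controlled
recovery experiments with a synthetic ground truth, the influx is
recovered essentially exactly and the steady state is recovered well in
median, but individual metabolites governed by sloppy directions can be
off by tens of percent even at zero observation noise.  The package's
tests assert exactly what the data support; no profile-likelihood
machinery is provided.

There is also a structural tension inside the objective itself: under
exact Van't Hoff pairing the steady state is invariant to a uniform
doubling of all velocities except through the temperature-specific
decay rates, so large upstream temperature-ratios (such as the KDG
target of 4.16) can only be approached by sacrificing cross-temperature
consistency.  The fit settles at a compromise whose residuals are
dominated by the KDG ratio target.

## Perturbation analyses

* `single_parameter_sensitivity()`:
  $S = ((SS' - SS)/SS)/\delta$, a one-sided finite difference at
  relative perturbation $\delta$ (default ±20 %).  $S = 1$ means direct
  proportionality.
* `sensitivity_matrix()`: for each (velocity, metabolite) pair the
  signed $S$ of larger magnitude between the +20 % and −20 %
  perturbations, with a sign marker (ties toward +), plus
  per-metabolite averages.  Rows default to all 22 maximal
  velocities/sinks, excluding decay rates.
* `monte_carlo_external()`: the influx drawn from
  $U((1-f)v, (1+f)v)$, default $f = 0.5$, $n = 1000$.
* `monte_carlo_internal()`: all velocities drawn simultaneously —
  measured ones within ±SD, fitted ones within ±20 % — and by default
  the sink and decay rates within ±20 % as well (flags `include_sinks`,
  `include_deg`), since the perturbation is meant to cover every
  reaction velocity.  "X % around the value" is read as symmetric
  multiplicative uniform bounds.
* RSD is $100\,\mathrm{sd}/\mathrm{mean}$ with the sample ($n-1$)
  standard deviation; structurally absent metabolites (zero mean and
  spread, e.g. KDPG under the spED knockout) report RSD 0.  Draws with
  non-converging steady states are dropped and counted; an ensemble
  aborts if more than 5 % fail.
* `knockout()`: `SP0` zeroes the KDG-kinase velocity, `NP0` both
  directional velocities of the npED aldolase; all other parameters are
  untouched.  Knockout analyses run on the 80 °C parameterization.
* `perturb_feedforward()`: two ensembles from the same seed (identical
  velocity draws) with and without the GK inhibition constant
  additionally drawn within ±20 %; reports both ensembles and the
  per-metabolite RSD shift.
* `vary_cofactors()`: re-solves with all clamped pools scaled by
  (1 ± 25 %).

All stochastic analyses take an integer seed and are bit-reproducible
given the seed (base R generator).  Ensemble sizes of 1000 are the
default study condition; the convergence check in the test suite
compares $n = 1000$ against $n = 4000$ and finds RSDs stable to better
than 2 percentage points.

## Synthetic data and the packaged parameterization

`generate_ground_truth()` rejection-samples full parameterizations
(measured-tier velocities 30–300 U/g CE, free tier 20–200, influx
12–25, Km/Ki log-uniform over their plausible ranges, minutes-scale
half-lives that shorten 2–3.5× per +10 °C, Van't Hoff pairing
$v_{80} = 2 v_{70}$ up to lognormal jitter σ = 0.1) until both
temperatures converge below 100 mM.  `generate_observations()` adds
multiplicative lognormal noise at the observation level (velocity
tables with SD columns and the 11-velocity mask; metabolite
temperature-ratios; knockout ratios).  Lognormal noise is chosen for
positivity; the uniform distributions above are the robustness-analysis
convention, not a measurement-error model.  What the generator does
*not* emulate: correlated assay errors, temperature-dependent Km,
enzyme expression changes, or any raw metabolomics/assay signal — so
passing recovery tests demonstrate correctness of the estimation
machinery on data with the assumed statistical structure, not
performance on real extracts.

The packaged parameter table
(`inst/extdata/params_ed_synthetic.tsv`, `load_fixture_model()`) is a
**synthetic stand-in** parameterization, labelled as such: its
measured tier (11 velocities with SDs, Km/Ki, half-lives, cofactor
pools) was chosen once as field-plausible, and its free tier was
produced by the package's own constrained fit against the published
metabolome-ratio targets, selecting the best-SSR fit (over five
optimizer seeds) whose branch knockouts at 80 °C are well-posed — the
knockout experiments are part of the study design, and the
substrate-inhibited glycerate kinase makes some otherwise-equivalent
fits lose the knockout steady state.  `tools/make_fixture.R` reproduces
the table deterministically.  Quantities that depend on the original
study's exact measured values (individual sensitivities, knockout
ratios, RSD magnitudes and their temperature contrast) are properties
of that dataset and are not expected to transfer to the stand-in; the
structural properties (conservation laws, branch roles, feedforward
insulation of pyruvate, cofactor-clamp robustness) are.

## Numerical choices, degenerate inputs, limitations

* Steady-state tolerance 10⁻⁶ mM/min (absolute); integrator
  `rtol = 10⁻⁸`, `atol = 10⁻¹⁰`; horizon 10⁶ min with a non-converged
  diagnostic rather than an error.
* Zeroed velocities (knockouts) are preserved exactly under
  Monte-Carlo perturbation.
* Sensitivity ties between the two one-sided differences break toward
  the +20 % marker.
* The model export (`write_sbml()`/`read_sbml()`) is an SBML-Level-3
  shaped XML document written with xml2: species, stoichiometry and
  reversibility are standard; the kinetic content travels in a package
  annotation namespace, from which import reconstructs the model
  bit-exactly (round-trip is tested to 10⁻⁹ mM at steady state).
* Out of scope: TCA cycle and respiration, dynamic cofactor balancing,
  oscillation/bifurcation analysis, metabolic control analysis,
  profile-likelihood identifiability.
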