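---
title: "Modelling reversible safety-cap protection in [FeFe]-hydrogenase film electrochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reversible safety-cap protection in [FeFe]-hydrogenase film electrochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capkin)
```

## The system and the model

Most [FeFe]-hydrogenases are destroyed by O2: the gas binds the open
coordination site of the distal iron (Fe_d) of the H-cluster and the
resulting reactive species degrade the cofactor.  A small family of
enzymes, exemplified by CbA5H of *Clostridium beijerinckii*, escapes
this fate by parking itself in an inactive state, Hinact, in which the
thiol of a conserved cysteine (C367) swings onto Fe_d and caps the
binding site.  Capping is triggered by oxidising conditions, is fully
reversed by reduction, and while the cap is on, neither substrate nor
O2 can reach the iron.

Protein film electrochemistry (PFE) resolves the kinetics of this
protection.  The enzyme is adsorbed on a rotating graphite electrode;
the catalytic current is proportional to the number of active enzymes
times their turnover frequency at the applied potential.  Stepping the
potential and watching the current relax therefore reads out the
inter-conversion of active and inactive states in real time.

`capkin` implements the minimal kinetic scheme that accounts for those
relaxations — the **AAI scheme**, a linear three-state chain

$$\mathrm{A_1}
  \;\underset{k_{-1}}{\overset{k_1}{\rightleftarrows}}\;
  \mathrm{A_2}
  \;\underset{k_\mathrm{react}}{\overset{k_\mathrm{inact}}{\rightleftarrows}}\;
  \mathrm{H_{inact}}$$

where A1 and A2 are catalytically active conformers (A2 is an
intermediate loop conformation, about half as active as A1) and Hinact
is the capped state.  A mono-exponential two-state scheme (cap on/cap
off) cannot reproduce the multiphasic current relaxations; the
package keeps it as the explicit null model.

State occupancies evolve by the master equation $\dot s = G\,s$ over
$s = (a_1, a_2, h_\mathrm{inact})$, with the column-conservative
generator built from the four rate constants.  Under a
piecewise-constant potential program the solution is exact:
`propagate()` eigendecomposes the 3x3 generator (falling back to a
scaling-and-squaring matrix exponential when the spectrum is
degenerate — relative eigenvalue gap below 1e-9) and the simulators
chain these exact solutions across steps.  The observable is

$$i(t) = \mathrm{amp}(E)\,\bigl(\alpha_1 a_1(t) + \alpha_2 a_2(t)\bigr),$$

so the current jumps instantaneously at each potential step (the
turnover frequency of the active enzyme changes at once) and then
relaxes slowly as the Hinact population adjusts — the characteristic
peak-then-relax sawtooth of stepping experiments.

## Parameters, defaults, and why

* **Rate constants** `k1, k_neg1, k_inact, k_react` (1/s), all
  non-negative.  The wild-type pH 7 reference set shipped in
  `cba5h_rate_table()` is `0.061, 0.016, 0.42, 0.17`; the table also
  carries the published maximal determination errors (8%, 28%, 7%, 6%)
  used as recovery tolerances.
* **`alpha2 = 0.5`** — the intermediate conformer is about half as
  active as A1.  Fixed by default, optionally a fit parameter
  (`fit_alpha2`).
* **Amplitudes** are one free scale per *distinct* potential, shared
  across repeated visits: the turnover frequency depends on the
  potential, not on the visit index.  Inside `fit_model()` they are
  profiled out linearly (for fixed rates they have a closed-form
  least-squares solution), which removes two parameters from the
  nonlinear search while still counting them in model comparison.
* **`k_react(E)`**: only reactivation responds to potential and pH
  (it is a reduction-coupled, proton-coupled step).  Fitting leaves
  `k_react` free at each distinct protocol potential (a lookup table —
  no functional form is imposed on data).  For continuous sweeps and
  for generating synthetic data the package offers the minimal
  Tafel-like law
  $k_\mathrm{react}(E) = k_0 e^{-\beta (E - E_\mathrm{ref})}$ with
  default slope $\beta = 15\,\mathrm{V^{-1}}$ — roughly one third of
  $F/RT$ at 5 °C, i.e. a partially transferred electron, a deliberately
  conservative choice for a coupled chemical–electrochemical step.
* **Film loss** (`film_loss_tau`) is off by default; when enabled it
  multiplies the current by a single exponential.
* **Reference electrodes**: all potentials are stored vs SHE;
  `she_from_calomel()` (+0.244 V) and `she_from_agagcl()` (+0.205 V)
  convert measured scales.

## Fitting and model comparison

`fit_model()` estimates rates on the log scale (positivity for free)
with Levenberg–Marquardt from multiple seeded starts.  Random starts
are log-uniform, with the conformational rates started in the slow
regime (1e-3 to 1 /s) and the cap-chemistry rates in 1e-2 to 10 /s:
the A1/A2 interconversion sits behind a large activation barrier and
runs on the seconds-to-minutes timescale, and starting it fast
collapses the three-state model onto a persistent two-state-like local
minimum.  One additional deterministic start embeds a two-state fit of
the same trace into the AAI parameter space (instant conformational
pre-equilibrium, amplitudes rescaled by $1/\alpha_2$); since
Levenberg–Marquardt never accepts an uphill step, this guarantees the
three-state fit is at least as good as the nested two-state fit on
every trace.

The first `mask_after_step = 2` s after every step boundary are
excluded from the residuals by default.  This is protection against
capacitive charging transients in real data (alternatively, subtract a
recorded enzyme-free blank with `subtract_background()` and disable
the mask).  For synthetic data generated without a capacitive
component the mask should be set to 0 — it would only discard kinetic
signal, and fast relaxations (e.g. `k_inact + k_react` of order 1/s)
live mostly inside the first two seconds.

`compare_models()` reports both the nested F statistic and the AIC
difference and declares the AAI model preferred only when both agree:
the experimental rejection of the two-state scheme is qualitative, so
the package surfaces both measures instead of a single verdict.
Covariances come from a finite-difference residual Jacobian at the
optimum; standard errors on rates by the delta method.

## What the synthetic-data generator emulates

`generate_chronoamperogram()` produces the noise-free current model
plus (optionally) signed capacitive spikes
$\pm\,\mathrm{peak}\cdot e^{-\Delta t/\tau}$ after each step and
additive Gaussian noise with standard deviation `relative_sd` times
the maximal absolute current.  Every generating parameter, including
the seed, is stored in a `truth` attribute; generation is
bit-reproducible for a fixed seed.

The five-phase O2-exposure protocol (`generate_o2_experiment()`)
extends the state space by an absorbing `Dead` species:
$\mathrm{d(dead)}/\mathrm{d}t = k_\mathrm{dmg}\,[\mathrm{O_2}](t)\,(a_1 + a_2)$,
with the O2 concentration stepping to 50 µM at phase P3 and washing
out exponentially (default tau 60 s; the experimental five-fold buffer
exchange has no published time constant) from P4.  Damage strikes only
the active states — the capped Hinact state is O2-protected, which is
the mechanism under study — and is never repaired.  The default damage
rate constant, 500 /M/s, destroys an unprotected film essentially
completely during a 420 s exposure at 50 µM, matching the observed
fate of cap-less variants; the wild-type fixture uses a negligible
reactivation rate at 0 V (4e-4 /s), consistent with the observed
instantaneous, quantitative locking into Hinact under oxidising
conditions.  The integration uses a stiff ODE solver (lsoda) at tight
tolerances; four-species conservation holds to 1e-9.

Cyclic voltammetry (`simulate_cv()`, `generate_cv()`) is deliberately
qualitative: the current is a sigmoidal catalytic waveshape
$i_\mathrm{lim}\tanh(\mathrm{steepness}\,(E - E_\mathrm{eq}))$ scaled
by the weighted activity, with the AAI state integrated along the
triangular ramp and `k_react` following the exponential law.  That
reproduces the diagnostic *shapes* — the forward-branch current
maximum well below the vertex, the hysteresis between branches, the
reactivation wave on the return sweep — but not measured magnitudes:
mass transport, interfacial electron transfer and film dispersion are
out of scope.  The sweep starts from the A1/A2 conformational
equilibrium with no Hinact, so a scheme without inactivation traces
exactly coincident branches.

What passing tests on these synthetic data do **not** show: real
traces carry film desorption, drift, correlated noise, and enzyme
heterogeneity that the generator does not emulate (film loss is
available but off by default).  Recovery results quantify the
information content of the protocol under the stated noise model, not
instrument behaviour.

## Numerical and design choices

* Exact propagation vs. integration: eigendecomposition is exact for
  the piecewise-constant protocols; the test suite cross-checks it
  against fixed-step RK4 integration to 1e-8 over a thousand random
  rate/time instances.
* Degenerate chains: detached edges make the stationary distribution
  non-unique; `steady_state()` returns absorbing limits where they are
  well defined and errors otherwise rather than guessing.
* Ties and degeneracies in geometry: `pick_distal_fe()` refuses a
  symmetric tie (use the explicit serial override); superposition
  refuses collinear fit sets.
* Unweighted least squares: no weighting scheme is published for
  these fits; residuals are homoscedastic under the additive noise
  model.
* The initial state of every step fit is pure A1: stepping
  experiments begin well below the equilibrium potential precisely to
  ensure a fully activated film.
* Forward/backward sweep splitting in `cv_onset()` uses the sign of
  dE/dt after a 5-point median filter, robust to sampling jitter.

### Study conditions for the recovery experiments

The parameter-recovery studies (and `scripts/acceptance.R`) generate
replicates under the stepping protocol between -0.31 and -0.21 V
(50 s holds, 3 cycles, 10 Hz, 1% relative noise).  The generating
`k_react` equals the reference value at the oxidative potential and
follows the exponential law (slope 15 /V) at the reducing potential.
This matters: reactivation's potential dependence is what makes the
alternating protocol informative.  If instead `k_react` is held equal
at both potentials, the generator never changes across steps, the
whole trace collapses onto a single multi-exponential relaxation, and
the fit acquires a near-flat valley in which wildly different rate
sets (tens-of-percent displacements) change the curve by less than
the noise.  The recovery tolerances used in the tests are the
published per-rate maximal errors.

Problem sizes were chosen to keep the full test suite and the
acceptance script comfortably re-runnable on a single CPU: 25
replicates per recovery study, 1000 random instances for the
propagation oracle, four reference parameter rows (the three
wild-type pH series and A561F) in the recovery acceptance test.  The
fast-reactivation loop variants (L364F, P386L, and the double
exchange; `k_react` 1.45–2.09 /s at -0.196 V) are **not** included:
at -0.21 V they barely inactivate (`k_react` far exceeds `k_inact`),
so the stepping window that suits the wild type carries almost no
information about their rates — consistent with the observation that
these variants inactivate only at significantly higher potentials,
where their stepping experiments would have to be run.

## Known limitations

* The exponential `k_react(E)` law is a modelling convenience; the
  true potential dependence is not published in closed form.  Fits to
  data never rely on it (per-potential table).
* `alpha2` is weakly identified jointly with amplitudes on single
  protocols; it is fixed at 0.5 by default.
* CV simulation is qualitative by design (see above).
* Hetero-group naming for the H-cluster varies across depositions;
  the residue-name allowlists are overridable and an explicit atom
  serial always wins.
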