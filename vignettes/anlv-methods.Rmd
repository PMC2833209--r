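---
title: "Attenuated nonlinear viscoelastic models of passive extraocular muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuated nonlinear viscoelastic models of passive extraocular muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anlv)
```

## The problem

Passive extraocular muscle (EOM) produces large viscoelastic forces well
inside the physiologic range of eye rotations: the antagonist muscle of a
saccade is stretched by several millimetres in tens of milliseconds, and the
force it exerts afterwards decays over many seconds. Classical
quasi-linear viscoelastic (QLV) models, and their adaptive extension
(AQLV), reproduce the response to small quick-step elongations well but
grossly overestimate the force during and after large smooth elongations,
and they cannot reproduce two robust features of passive EOM: after an
elongation the force quickly becomes a function of the final length alone
(relaxation traces from very different elongations converge within about
100 ms), and traces that end with the *higher* force can end up with the
*lower* force a second later (cross-over).

This package implements the model family in which those failures are
repaired by a thixotropy-inspired *attenuation*: the ANLV (attenuated
nonlinear viscoelastic) model. It provides the protocol generators, an
exact-exponential simulator, the diagnostic statistics in which the
phenomenology is visible, synthetic noisy recordings, and a genetic-
algorithm identification procedure for the attenuation parameters.

## Model family

All models share one structure. With elongation $L(t)$ (mm, measured from
the slack reference length) and elongation speed $v(t) = \dot L \ge 0$
(only lengthening is modelled), the total force (gf; 1 gf
$\approx 0.0098$ N, exported as `GF_TO_N`) is

$$F(t) \;=\; F_{LT}(L) \;+\; \sum_{i=1}^{7} F_i(t) \;+\; \eta(L)\,v,$$

* **Length–tension curve** $F_{LT}(L) = c_0 + c_1 L + c_2(e^{c_3 L}-1)$
  (4 DOF): the equilibrium force after a length has been held for a very
  long time. The linear-plus-exponential form is essentially linear up to
  about 3 mm with accelerating stiffness beyond, matching the reported
  shape of the static curve over the ~8 mm working range.
* **Purely viscoelastic force**: seven first-order relaxation processes,
  process $i$ obeying
  $\dot F_i = u_i(t) - F_i/\tau_i$. The time constants
  $\tau_i$ are *fixed design constants* of the family, not fitted: the
  default ladder `DEFAULT_TAU` is geometric,
  $\{0.01, 0.04, \ldots, 40.96\}$ s, seven octaves ending near 41 s
  because EOM exhibits relaxation with time constants of tens of seconds.
* **Viscous force** $\eta(L)v$ with $\eta(L) = w_0 + w_1 L + w_2 L^2$
  clipped at zero (3 DOF) — the simplest three-parameter family that can
  be monotone in $L$.

The two base models differ only in the process drive $u_i$:

* **QLV** (15 DOF): $u_i = \alpha\, g_i\, F_{LT}'(L)\, v$ — the
  viscoelastic response is proportional to the slope of the static curve
  (8 spectrum DOF: $g_1,\dots,g_7$ and $\alpha$).
* **AQLV** (35 DOF): $u_i = k_i(L)\, v$ with a separate stiffness profile
  per process, each represented by a 4-knot piecewise-linear function of
  $L$ with constant extrapolation (4 DOF per process). This decouples the
  post-elongation decay from a single elastic law while keeping the DOF
  count exact.

## The attenuation extension (ANLV)

Thixotropic materials (gels, paints, suspensions) lose viscosity under
imposed shear because their microstructure breaks down; the standard
description carries a structural parameter $\lambda$ (1 = fully built up,
0 = fully broken down). The ANLV model borrows the breakdown kinetics but
departs from the classical use in one essential way: $\lambda$ does not
scale a viscosity, it scales the *force output* of each viscoelastic
process — stiffness and viscosity together — so the process time constants
do not change and hold-phase decay remains exactly exponential (a changing
gain during the decay would make it non-exponential, which is never
observed).

The kinetics implemented are breakdown-only:

$$\dot\lambda \;=\; -\,\frac{k_d\, v^{\,n}}{1 + k_f F}\;\lambda .$$

* The rebuilding term of the classical equation is dropped: the available
  double-elongation data cannot constrain it. At rest ($v = 0$) $\lambda$
  is frozen; `reset_state()` (and protocol reset marks) restore
  $\lambda_0$ explicitly, emulating the reset applied before the second
  elongation of a 45 s sequence. The API deliberately leaves rebuilding as
  a documented hook rather than an implementation.
* $\lambda$ is initialized at $\lambda_0 \ge 1$ and **clipped at 1** where
  it acts: `effective_lambda` $= \min(\lambda, 1)$. The excess
  $\lambda_0 - 1$ is a breakdown *reserve*: small (~0.5 mm) quick steps —
  the regime in which the base models are identified and already accurate
  — consume the reserve without producing any attenuation.
* The $1/(1 + k_f F)$ factor makes breakdown weaker at high force,
  capturing the observation that the models' overestimation is smaller at
  large initial elongations. The exact algebraic form of this force
  modulation is a declared design contract of this package (the division
  by $1 + k_f F$ is the simplest one-parameter law with the right
  monotonicity); it is pluggable in the scalar reference stepper
  (`lambda_update(force_modulation = ...)`) so alternatives such as
  $e^{-k_f F}$ can be explored, while the compiled integrator implements
  the default law.
* Each process has its own gain
  $\beta_i = 1 - \gamma_i\,(1 - \min(\lambda, 1))$, $\gamma_i \in [0,1]$:
  $\gamma_i = 1$ attenuates the process all the way down to $\lambda$ (so
  $\lambda$ is the maximum attenuation across processes), $\gamma_i = 0$
  leaves it untouched. The assembled force is

$$F = F_{LT}(L) + \sum_i \beta_i F_i + \eta(L) v,$$

with **no attenuation** on the equilibrium curve or the viscous term.

On DOF accounting: the extension's conventional count is ten
($k_d, n, \lambda_0, k_f$ plus six for the bounded $\gamma_i$), and
`dof()` reports 10. The constraint that would reduce the seven $\gamma_i$
to six effective DOF is not recoverable from the published parameter
tables (no column is normalized), so the fitter treats all seven as free;
this discrepancy is deliberate and documented here.

## Numerical scheme

The simulator is a state-space integrator (seven first-order states plus
$\lambda$), O(N) in the number of samples, with no stored history:

* Process states use the exact solution of
  $\dot x_i = u(t) - x_i/\tau_i$ for a drive varying linearly between its
  sampled endpoint values:
  $x_i \leftarrow x_i e^{-\Delta t/\tau_i} + u_k\,(g_i - h_i) + u_{k+1} h_i$
  with $g_i = \tau_i(1-e^{-\Delta t/\tau_i})$ and
  $h_i = \tau_i - \tau_i g_i/\Delta t$. On constant-drive segments
  (ramps, holds) this reduces to the frozen-drive exponential update and
  incurs no time-stepping error at all (the ramp closed form is reproduced
  to ~1e-12 relative); on smooth drives it is second order, so halving dt
  changes the force by far less than the 0.1% convergence budget.
* $\lambda$ uses its own exact-in-$\lambda$ exponential update
  $\lambda \leftarrow \lambda e^{-a\Delta t}$ with
  $a = k_d v^n/(1+k_f F)$, guaranteeing positivity; $v$ and $F$ are frozen
  over the step, with $F$ taken from the previous assembled sample
  (explicit coupling — this avoids an implicit solve and costs an O(dt)
  error, negligible because dt is far below every $\tau_i$ and the
  force-modulation factor is slowly varying).
* Default sampling `dt = 1 ms`, configurable: it resolves the fastest
  standard protocol (a 50 ms full-range ramp) with 50 samples; halving dt
  changes the force of that fastest protocol by well under 0.1%
  (sup-norm), which the test suite checks.
* Initial conditions are zero process states (muscle equilibrated at the
  start length) and $\lambda = \lambda_0$, both overridable to chain
  simulations.
* The inner loop is compiled (Rcpp), which keeps the identification
  procedure's ~10^4 simulations per fit cheap.

Degenerate inputs: zero-amplitude protocols are pure holds; a simulation
refuses a protocol whose integrated speed disagrees with its length change
by more than 0.2% of the range, because such inconsistencies (typical when
speed and length are recorded on separate channels) are known to create
spurious cross-over in base-model simulations. `validate_consistency()`
reports the discrepancy and offers an exactly rescaled velocity.

## Protocols

Generators cover the standard battery: quick steps (half-sinusoid velocity
over a default 5 ms rise — fast relative to every $\tau_i$ but with
bounded velocity; the acquisition rate and rise time of the original
recordings are not published, so these are declared defaults), saccade-like
elongations ($v(t) = v_{pk}\sin(\pi t/T)$ with
$T = \pi A/(2 v_{pk})$, so the integral is exactly the amplitude),
constant-speed ramps (80 s at 0.1 mm/s to 50 ms at 160 mm/s over the 8 mm
range), and concatenations with inter-stimulus intervals
$\{0.01, 0.1, 1, 45\}$ s, with attenuation reset marks at the 45 s ISI.
Sampled velocities are rescaled so the trapezoidal integral matches the
commanded amplitude exactly and the length is defined as the cumulative
integral of the sampled velocity; generated protocols are therefore
self-consistent to machine precision (the nominal peak speed is met to
O(dt²)). Shortening is excluded by the type invariant $v \ge 0$ rather
than silently clipped. Preconditioning cycles are not modelled: they are
part of the measurement procedure, not of the analyzed records.

## Packaged fixtures and the synthetic base model

`load_fixture()` provides the published attenuation parameter sets for the
four fitted muscles (two monkeys' superior/lateral recti), for both the
QLV-based and the AQLV-based variant. The corresponding *base-model*
parameters were published in a companion paper and are not transcribed
here: fixtures attach a **synthetic** base model, labeled as such in its
provenance. Its design constraints, chosen once:

* length–tension: $c_0 = 1.5$, $c_1 = 1$, $c_2 = 0.25$, $c_3 = 0.5$ —
  essentially linear to ~3 mm, ~23 gf at 8 mm;
* spectrum: $\alpha = 0.5$,
  $g = (0.25, 0.25, 0.25, 0.30, 0.35, 0.50, 1.40)$ — weight concentrated
  on the slow processes, reflecting that the dynamic force after a quick
  step takes seconds to decay and that even a 0.1 mm/s stretch develops a
  considerable dynamic force;
* viscosity: $\eta(L) = 0.01 + 0.002 L$ gf·s/mm, a small artifact-scale
  term.

With this base and the packaged attenuation values the model reproduces
the qualitative phenomenology the attenuation was introduced for:
relaxation cross-over after ramp families, saccadic-family convergence
within ~100 ms, data/model viscoelastic ratios below one and decreasing
with amplitude. Quantitative agreement with any particular muscle is *not*
claimed — the base model is synthetic.

## Synthetic recordings

`generate_recording()` adds to the simulated force a heartbeat-like
sinusoid (default 2 Hz, 0.1 gf), a respiration-like sinusoid (default
0.3 Hz, 0.2 gf) and white noise (default 0.02 gf s.d.), with phases drawn
from a seeded generator — plausible magnitudes for an anesthetized-primate
preparation whose residual noise after artifact removal is very small; no
quantitative noise levels are published, so these are declared
assumptions. The noise is additive and state-independent, and the ground
truth travels with every dataset. What the generator does **not** emulate:
the artifact-removal step itself, preconditioning history effects,
amplifier drift, or inter-animal variability. Passing recovery tests on
these data therefore demonstrate the identifiability and correctness of
the machinery under the stated conditions, not performance on raw in vivo
records.

## System identification

The objective mirrors the published procedure. For each elongation:
the mean squared error over the elongation phase, plus seven MSEs over
relaxation windows $[t_{end}, t_{end} + 3\tau_i]$ (truncated at the record
end), summed over elongations. Using *mean* rather than summed squares
makes window duration irrelevant — a raw SSE would let the slowest
process's 123 s window dominate everything.

The fitter is an elitist real-coded GA: tournament selection, BLX-0.5
blend crossover (p = 0.9), per-gene Gaussian mutation (p = 0.25, s.d. 10%
of each parameter's range), two elites. The published procedure names a
genetic algorithm with a Sobol DOE seed population inside a commercial
optimizer; this implementation seeds with a scrambled low-discrepancy
Halton design (radical-inverse sequences with a seeded random shift) and
records all operator settings in the fit result, trading fidelity to an
unnamed tool for exact reproducibility. The default budget is the
published one (50 generations × 75 designs); default bounds
($k_d \in [0,2]$, $n \in [0.5,3]$, $\lambda_0 \in [1,4]$,
$k_f \in [0,0.1]$, $\gamma_i \in [0,1]$) bracket all published values.
Base-model parameters are held fixed during attenuation fitting (they are
classically identified on quick-step data first). An optional bounded
L-BFGS-B polish from the best GA designs refines the optimum; its
evaluations are counted separately.

The package's recovery benchmark (used by the tests and the acceptance
script) runs at a reduced budget of 15 generations × 30 designs with
polish, on a zero-noise battery of four full-range ramps (1–160 mm/s) and
three saccadic elongations sampled at 2 ms with 12 s holds. The 12 s holds
matter: with short records the relaxation windows of the slow processes
are truncated so heavily that the slow-process $\gamma$ ordering is not
identifiable. Under these conditions the benchmark recovers $k_d$ to a few
percent and the identity of the three most-attenuated processes.

## Known limitations

* Rebuilding is not modelled, so sequences of large elongations at short
  ISI are expected to be *under*-predicted by a fitted ANLV model — the
  known failure mode of the breakdown-only formulation.
* Shortening ($v < 0$) is outside the model's domain by construction.
* The algebraic forms of the force-modulation law and the per-process
  gains are reconstructions stated as this package's contracts.
* The data/model viscoelastic ratio is only computed at simulated or
  supplied amplitudes; no extrapolation toward the quick-step regime is
  performed.
* The synthetic base model stands in for unpublished per-muscle base
  parameters; analyses that need a specific muscle's absolute forces must
  supply their own base model (all constructors accept full parameter
  sets, and configs round-trip through YAML).
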