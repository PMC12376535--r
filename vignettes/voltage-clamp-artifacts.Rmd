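---
title: "Modelling whole-cell voltage-clamp artifacts and their consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-cell voltage-clamp artifacts and their consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampsim)
```

## The problem

In a whole-cell patch-clamp voltage-clamp experiment the amplifier does not
control the membrane voltage directly. It controls the pipette potential
through a series resistance `Rs`, against a membrane capacitance `Cm`, with
stray pipette capacitance `Cp`, a seal leak, residual liquid-junction/offset
error, and several compensation circuits that each have their own dynamics.
For slow, small currents these imperfections are negligible. For the cardiac
fast sodium current (NaV1.5) they are not: tens of nanoamps flowing through
a few megaohms of series resistance produce tens of millivolts of "loss of
clamp" on a sub-millisecond timescale, which feeds back onto the very
channel gating being measured.

`clampsim` implements an equivalent-circuit model of the complete recording
chain so that the experiment itself can be simulated, diagnosed and fitted:

* the cell: `dVm/dt = (Vp + Voff - Vm)/(Rs Cm) - (I_ion + I_leak)/Cm`,
  with `I_leak = g_leak (Vm - E_leak)` and a pluggable ionic current
  `I_ion = f(t, Vm)`;
* series-resistance compensation: the command is augmented by
  `Rs* (alpha_R Iout)`, feeding the measured current back to offset the
  steady `Rs` voltage drop;
* supercharging ("prediction"): an internal estimate voltage relaxes as
  `dVest/dt = (Vcmd - Vest)/((1 - alpha_P) Rs* Cm*)` and the command is
  boosted by `Rs* alpha_P Cm* dVest/dt`, transiently overshooting to charge
  the membrane faster;
* fast (`Cp*`) and slow (`Cm*`) capacitance compensation, subtracting the
  predicted capacitive currents from the measured current;
* first-order delays for the amplifier (`tau_clamp`), the compensation
  summing circuit (`tau_sum`) and the recording filter (`tau_z`);
* leak subtraction as a post-processing step:
  `I_post = I_out - g_leak* (Vcmd - E_leak*)`.

Starred quantities are machine estimates; the gap between the truth and its
estimate (and the user-chosen fractions `alpha_R`, `alpha_P`, both capped at
0.95 because the supercharging time constant vanishes at 1) is what
generates artifacts. All right-hand sides are evaluated by explicit acyclic
substitution of the derivative terms, never by numerical differentiation;
`evaluate_derivatives()` is the reference R implementation and an identical
C version is integrated by deSolve's stiff solver.

## Units and parameters

Internally everything is in mV, ms, pA, pF, nS and GOhm, a closed system
(GOhm x pF = ms, nS x mV = pA, pF x mV/ms = pA). Resistances are MOhm at
the user interface and converted at the boundary.

Defaults that matter:

* `tau_clamp = tau_sum = tau_z = 0.01 ms`. These delay/filter constants are
  the order of real hardware: series-resistance-compensation speed settings
  on research amplifiers are 2-100 microseconds, and recording filters for
  fast sodium work run near 10 kHz (time constant ~16 microseconds). A much
  smaller value would make the compensation loop effectively instantaneous
  and visibly understate the artifact interactions that the model exists to
  capture. All three are configurable per amplifier.
* Solver tolerances `rtol = 1e-8`, `atol = 1e-10`; halving them moves peak
  currents by well under 0.1% (tested).
* Output sampling 0.01 ms within short segments (sub-millisecond artifact
  resolution); holding segments longer than 100 ms are sampled at 1 ms,
  since the state sits at its fixed point there.
* Command steps are exact discontinuities: integration restarts at every
  segment boundary, and boundaries belong to the later segment.
* Initialization assumes the cell was held at the starting command long
  before recording: all circuit voltages at the offset-shifted holding
  level, gating at steady state, observed current at its steady value.
* `Rs = 0` is rejected in artifact mode (the membrane equation is singular
  there); the artifact-free reference is `run_ideal()`, which solves the
  gating relaxations exactly per segment because `Vm` is then piecewise
  constant.

## Ionic models

The headline analyses all concern fast sodium current, so the package
ships three Hodgkin-Huxley-type formulations (definition files under
`inst/extdata/`, loadable and replaceable via `load_ionic_model()`):

* `hh_sodium()`: a generic parametric `m^3 h` current with Boltzmann
  steady states and flexible time-constant curves. Defaults place the
  activation threshold near -40 mV and the ideal-clamp I-V peak between
  -20 and -10 mV.
* `gray_franz_ina()`: a minimal `m^3 h` formulation in the style of the
  parsimonious ventricular model (constant 0.12 ms activation time
  constant, skewed-bell inactivation time constant), 20 nS/pF baseline,
  giving a peak I-V density near -1000 pA/pF under an ideal clamp.
* `ohara_ina_file()` / `ohara_ina()`: the fast component of the
  human-ventricular O'Hara-style INa (`m^3 (0.99 hf + 0.01 hs) j`,
  non-phosphorylated pathway), 75 nS/pF baseline.

Per-capacitance parameterizations (nS/pF) bind to absolute conductance with
`bind_density(model, Cm)`; `set_scale()` applies a dimensionless multiplier,
and current is linear in `g_max * scale` (tested pointwise). Free-form
models given as expression files integrate through a slower R fallback path
that is cross-checked against the compiled path in the tests.

## Verifying the simulator

Because the model cell used for hardware validation is linear, the whole
artifact system is linear time-invariant within each protocol segment, and
`linear_oracle()` solves it exactly with matrix exponentials. The test
suite requires the stiff integrator to agree with this closed-form solution
to 1e-8 (relative, max-norm on the observed current) across compensation
levels 0-95%, including the ringing/overshoot regime at 95%. The
right-hand side itself is checked against an independent transcription of
the circuit equations at 100 random parameter/state draws to 1e-12.

## The simulation studies

```{r studies, eval = FALSE}
protocols <- iv_protocol(-100, -90, 50, 10, hold_dur_ms = 2000,
                         step_dur_ms = 20)
tv <- attr(protocols, "test_voltages")

plan <- sampling_plan(50, "lhs", Cm_range_pF = c(50, 150),
                      Rs_range_MOhm = c(0.5, 2), seed = 1)
pop <- iv_population(plan, gray_franz_ina(), alpha = 0.8,
                     protocols = protocols, test_voltages = tv)
bias_report(average_iv(pop$curves)$mean, pop$ideal, interpolate = TRUE)
```

`iv_population()` emulates a population of patched cells: conductance scale
log-uniform over [0.2, 5], `Cm` and `Rs` uniform over their intervals
(Latin hypercube, one draw per equal-probability bin, seeded), perfect
machine estimates, both compensations at 80%. Each cell's baseline
conductance is the model density times its sampled `Cm`, so every cell has
the same ideal-clamp current density. `bias_report()` then quantifies how
far the averaged I-V curve sits from the artifact-free curve: peak-voltage
shift, peak-current reduction, and the underestimation of the maximum
activation-limb slope (successive differences over voltages at or below the
peak; the field has no standard operational definition of the I-V
"gradient", so this one is ours and is stated with the result).

The `mutant_study()` recipe emulates characterizing a conductance-only
mutant (current reduced to one-third, kinetics identical): conditions drawn
from `Rs ~ LogNormal(2.5, 1.5) MOhm` (QC-filtered to `Rs < 4 MOhm` by
rejection-resampling), `Cm ~ LogNormal(40, 10) pF`, offset error
`Normal(0, 2.5) mV` — lognormals parameterized by natural-scale mean and
variance — with 5% multiplicative error on the machine estimates of `Rs`
and `Cm`, n = 15 per arm, conductance calibrated so the ideal-clamp peak
densities are 1500 and 500 pA/pF. Although the two arms have identical
kinetics (their ideal-clamp curves peak at the same voltage, which the code
verifies), the observed averaged curves separate by roughly 8-10 mV purely
because the smaller current suffers smaller artifacts. Wild-type and
mutant conditions are drawn independently by default (`paired = TRUE`
reuses the draws).

Two peak-handling choices deserve emphasis:

* **Blanking.** Trace-level summaries (`summarize_iv()`) exclude the first
  0.05 ms of the test step so the capacitive spike is not mistaken for the
  ionic peak. The population recipes extend this to 0.3 ms: at 80%
  compensation the residual capacitive transient decays with
  `(1 - alpha) Rs Cm` (~25 microseconds for the study conditions) but is
  initially enormous, and at 0.05 ms enough remains to contaminate
  subthreshold steps; 0.3 ms is at least ten charging time constants for
  every condition sampled while the sodium peak on the activation limb
  occurs later than that.
* **Peak localization.** Averaged curves live on the 10 mV protocol grid.
  Where a sub-grid peak voltage is needed (the cardiomyocyte shift, the
  mutant separation) the peak is refined by the vertex of the parabola
  through the peak sample and its two neighbors, a standard peak
  localization; grid-resolved peaks are the default.

## What the studies do and do not show

The population generator emulates the dominant experimental variabilities —
cell size, access resistance, channel expression, offset error, estimate
error — under idealized conditions: perfectly ohmic leak (and none at all
in the population studies), a single first-order recording filter rather
than a multi-pole Bessel filter, no amplifier saturation or oscillation
protection, no temperature effects, and literature-style (not
pipette-solution-specific) channel kinetics. Passing tests therefore show
that the circuit model and study machinery behave correctly and reproduce
the documented direction and approximate size of the averaging biases; they
do not certify any particular amplifier, and two findings are genuinely
sensitive to the INa formulation: the activation-limb gradient
underestimation of the averaged curve (our faithful recomputation yields
far less than half, because a few high-conductance virtual cells retain an
ideal-steepness cliff in the average) and, to a lesser degree, the
peak-current reduction under cardiomyocyte conditions (the log-uniform
conductance spread inflates the average and partly cancels the per-cell
attenuation, which at baseline conductance is itself ~30%).

## Fitting

`fit_artifact()` fits any subset of `{g_max, Rs, Cm, Voff, g_leak}` to
recorded (or synthetic) post-processed current families by summed squared
residuals over the test steps (minus blanking). Positive parameters are
optimized as `p = p0 exp(s)` around references — 600 nS for the
conductance, the machine estimates `Rs*`, `Cm*`, `g_leak*` for the rest —
and the offset error stays on its natural scale. Optimization is
multi-restart derivative-free minimization (Nelder-Mead; Brent in one
dimension) with standard-normal initial points in the transformed space, 40
restarts by default, fully seeded. The machine estimates themselves are
never fitted. On noiseless synthetic I-V families the truth is recovered
to well under 1% (0.5 mV for the offset); with 2% multiplicative trace
noise, to within 5%. The tests run 8 restarts on a 4-sweep family at
0.05 ms sampling to keep the suite fast; the default 40 restarts are
recommended for real recordings.

## Action potentials and cables

To propagate sodium-current mischaracterization into tissue-level
consequences, `minimal_ap_model()` couples a fast INa density model with a
linear repolarizing current — deliberately minimal: it produces an
INa-driven upstroke and exponential repolarization, which is all the
upstroke-velocity and conduction-velocity analyses need. `run_ap()`
pre-paces (10 s at 2 Hz, 60 pA/pF for 1 ms by default) and records one
beat; `max_upstroke_velocity()` uses second-order central differences.
`run_cable()` chains cells with nearest-neighbor gap-junction current
`g_gap (Vi - Vj)` (per-capacitance, 14 nS/pF default), no-flux ends, and
analyzes a central window to avoid boundary effects. A stimulation region
of 5 cells (0.5 mm) launches the wave; a single stimulated cell cannot
reach threshold at physiological coupling because the gap-junction sink
spreads the charge over the electrotonic length first. With the bundled
minimal model the 14 nS/pF cable conducts at ~71 cm/s (100 micrometer
cells), and both conduction velocity and maximal upstroke rate fall
monotonically as the INa conductance is reduced, with conduction block
below roughly 0.4x. Tests use 120-150 cell cables with a central analysis
window; the full-scale default is 1500 cells analyzed over the central
1000.

## Problem sizes used in the checks

The packaged checks use: the full 15-step I-V family (2000 ms hold) for
all population studies at n = 5/25/75 (small-cell recipe), n = 50
(cardiomyocyte recipe) and n = 15 per arm (mutant recipe); 100-draw random
batteries for the algebraic oracles; 4-sweep families at 0.05 ms sampling
with 8 restarts for the recovery studies; and 120-cell cables. These sizes
make the whole suite run in minutes on one core while leaving every
qualitative conclusion unchanged at larger sizes (the averaging-futility
check verifies this explicitly across n).

## Known limitations

* Multi-pole (Bessel) recording filters and nonlinear seal leak are not
  modelled; the filter is first-order by design.
* No safeguards against over-compensated oscillation: ringing at 95%
  compensation is a legitimate simulated outcome.
* The supercharging estimate requires `Rs* Cm* > 0` whenever it feeds the
  command or the capacitance compensation; configurations that would make
  its dynamics degenerate are rejected rather than approximated.
* Markov-chain channel models are out of scope; the ionic-model interface
  assumes relaxation-form gating.
* The electrical model cell is the minimal two-branch network consistent
  with the validation circuit's described behavior; exact hardware
  component values are configurable, not asserted.
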