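# clampsim

Simulation, diagnosis and correction of whole-cell patch-clamp
voltage-clamp artifacts, with a focus on the cardiac fast sodium current
(NaV1.5).

A voltage-clamp amplifier never controls the membrane voltage directly: it
drives a pipette through a series resistance `Rs` against the membrane
capacitance `Cm`, with stray pipette capacitance, seal leak, residual
offset error, and a set of compensation circuits (series-resistance
compensation `alpha_R`, supercharging/prediction `alpha_P`, fast and slow
capacitance compensation, post-hoc leak subtraction), each with its own
dynamics. For currents as large and fast as INa these imperfections
produce a substantial "loss of voltage clamp" that feeds back onto channel
gating and systematically distorts current-voltage (I-V) relationships.

`clampsim` implements the full equivalent-circuit model of this recording
chain as a stiff ODE system with pluggable Hodgkin-Huxley-type ionic
models:

```
I_ion    = f(t, Vm)                                    ionic current
I_leak   = g_leak (Vm - E_leak)                        seal leak
dVm/dt   = (Vp + Voff - Vm)/(Rs Cm) - (I_ion + I_leak)/Cm
dVp/dt   = (Vclamp - Vp)/tau_clamp                     amplifier delay
dVest/dt = (Vcmd - Vest)/((1 - alpha_P) Rs* Cm*)       supercharging
V'cmd    = Vcmd + Rs*(alpha_R Iout + alpha_P Cm* dVest/dt)
dVclamp/dt = (V'cmd - Vclamp)/tau_sum                  compensation delay
I_in     = I_ion + I_leak + Cp dVp/dt - Cp* dVclamp/dt
           + Cm dVm/dt - Cm* dVest/dt                  capacitance comp.
dIout/dt = (I_in - Iout)/tau_z                         recording filter
I_post   = Iout - g_leak* (Vcmd - E_leak*)             leak subtraction
```

(`X*` = machine estimate of `X`.) On top of the simulator the package
provides: piecewise-constant protocol builders; an exact matrix-exponential
oracle for linear cells (the electrical "model cell" used for hardware
validation); I-V summaries and bias metrics against the artifact-free
ideal clamp; population studies (Latin-hypercube and distributional
condition sampling with QC) quantifying why averaging I-V curves does not
remove artifacts and how a conductance-only mutant appears kinetically
shifted; multi-restart fitting of artifact parameters and channel
conductance to recorded traces; and action-potential/1-D cable simulations
propagating INa mischaracterization into upstroke velocity and conduction
velocity. See the vignette in `vignettes/voltage-clamp-artifacts.Rmd` for
the methods.

## Worked example

Simulate an I-V experiment on a NaV1.5-expressing cell (`Rs` 5.7 MOhm,
`Cm` 14.1 pF) at 80% series-resistance compensation and supercharging,
and compare with the artifact-free curve:

```r
library(clampsim)
cell <- cell_parameters(Rs_MOhm = 5.7, Cm_pF = 14.1, Cp_pF = 4)
amp  <- matched_amplifier(cell, alpha_R = 0.8, alpha_P = 0.8)
ina  <- bind_density(ohara_ina(), cell)    # 75 nS/pF O'Hara-style INa

protocols <- iv_protocol(-100, -90, 50, 10, hold_dur_ms = 2000,
                         step_dur_ms = 20)
tv <- attr(protocols, "test_voltages")
traces   <- lapply(protocols, run_artifact, cell = cell, amp = amp,
                   ionic = ina)
observed <- summarize_iv(traces, tv, density_Cm = cell, blank_ms = 0.3)
ideal    <- ideal_iv_curve(ohara_ina(), protocols, tv)
print(observed)
print(ideal)
```

```
I-V curve: 15 steps, peak -985.7 pA/pF at -30 mV
I-V curve: 15 steps, peak -1049 pA/pF at -20 mV
```

Even at 80% compensation the observed curve peaks 10 mV left of the true
curve with a ~6% smaller peak density — and the simulation shows why: at
the -30 mV step the membrane actually reached -8.8 mV
(`max(traces[[which(tv == -30)]]$V_m_mV)`), a 21 mV loss of clamp.
`plot(traces[[8]])` displays the commanded and actual membrane voltage
with the post-processed current; `bias_report()`, `iv_population()`,
`mutant_study()` and `fit_artifact()` build the population and fitting
analyses on top (see the vignette).

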