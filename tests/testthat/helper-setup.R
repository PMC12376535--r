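# shared builders for small, fast test setups

small_cell <- function(...) {
  cell_parameters(Rs_MOhm = 5, Cm_pF = 15, Cp_pF = 4, ...)
}

fast_step <- function(hold = -80, test = 50, dur = 10, dt = 0.02) {
  step_protocol(hold, test, dur, dur, dur, sample_interval_ms = dt)
}

# tight-tolerance options for oracle comparisons
oracle_opts <- function() solver_opts(rtol = 1e-11, atol = 1e-12)

# an independent transcription of the circuit equations, written directly
# from their displayed form (deliberately separate from the package's RHS)
direct_rhs <- function(state, V_cmd, cell, amp, ionic) {
  Vm <- state[1]; Vp <- state[2]; Vest <- state[3]; Vclamp <- state[4]
  Iout <- state[5]
  ion <- state[-(1:5)]
  dVest <- (V_cmd - Vest) / ((1 - amp$alpha_P) * amp$Rs_est * amp$Cm_est)
  Vcmdp <- V_cmd + amp$Rs_est * (amp$alpha_R * Iout +
                                 amp$alpha_P * amp$Cm_est * dVest)
  dVclamp <- (Vcmdp - Vclamp) / amp$tau_sum
  dVp <- (Vclamp - Vp) / amp$tau_clamp
  Iion <- ionic_current(ionic, Vm, ion)
  Ileak <- cell$g_leak * (Vm - cell$E_leak)
  dVm <- (Vp + cell$V_off_err - Vm) / (cell$Rs * cell$Cm) -
    (Iion + Ileak) / cell$Cm
  Iin <- Iion + Ileak + cell$Cp * dVp - amp$Cp_est * dVclamp +
    cell$Cm * dVm - amp$Cm_est * dVest
  dIout <- (Iin - Iout) / amp$tau_z
  c(dVm, dVp, dVest, dVclamp, dIout,
    if (length(ion)) ionic_derivatives(ionic, Vm, ion))
}
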