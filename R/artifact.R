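# The equivalent-circuit ODE system of the voltage-clamp artifact model.
# State variables: Vm (membrane), Vp (pipette), Vest (supercharging
# estimate), Vclamp (delayed clamp voltage), Iout (filtered observed
# current), plus the ionic model's gating states. The right-hand side is
# acyclic once the derivative terms appearing inside other equations are
# substituted in the order used below; no numerical differentiation is
# involved.

#' Ohmic leak current
#'
#' `I_leak = g_leak * (Vm - E_leak)`.
#'
#' @param Vm membrane voltage (mV).
#' @param g_leak_nS leak conductance (nS).
#' @param E_leak_mV leak reversal potential (mV).
#' @return Current in pA.
#' @examples
#' leak_current(-80, g_leak_nS = 1)  # -80 pA
#' @export
leak_current <- function(Vm, g_leak_nS, E_leak_mV = 0) {
  g_leak_nS * (Vm - E_leak_mV)
}

#' Supercharging estimate-voltage rate
#'
#' `dVest/dt = (V_cmd - Vest) / ((1 - alpha_P) * Rs_est * Cm_est)`: the
#' amplifier's estimate of the membrane voltage relaxes toward the command
#' with a time constant shortened by the prediction fraction `alpha_P`, which
#' is what produces the transient command overshoot that charges the
#' membrane faster.
#'
#' @param V_cmd command voltage (mV).
#' @param Vest current estimate voltage (mV).
#' @param amp an [amplifier_settings()] object; requires
#'   `(1 - alpha_P) * Rs_est * Cm_est > 0`.
#' @return Rate in mV/ms.
#' @export
supercharging_rate <- function(V_cmd, Vest, amp) {
  den <- (1 - amp$alpha_P) * amp$Rs_est * amp$Cm_est
  if (den <= 0)
    stop("degenerate supercharging denominator: (1 - alpha_P) * Rs_est * ",
         "Cm_est must be > 0 (got ", den, " ms)")
  (V_cmd - Vest) / den
}

#' Series-resistance-compensated command voltage
#'
#' `V'_cmd = V_cmd + Rs_est * (alpha_R * Iout + alpha_P * Cm_est * dVest/dt)`:
#' the feedback term offsets the steady voltage drop over the series
#' resistance, the feed-forward term injects the predicted capacitive
#' charging current.
#'
#' @param V_cmd command voltage (mV).
#' @param Iout observed (filtered) current (pA).
#' @param dVest_dt supercharging estimate rate (mV/ms).
#' @param amp an [amplifier_settings()] object.
#' @return Compensated command in mV.
#' @export
compensated_command <- function(V_cmd, Iout, dVest_dt, amp) {
  V_cmd + amp$Rs_est * (amp$alpha_R * Iout + amp$alpha_P * amp$Cm_est * dVest_dt)
}

# internal: supercharging rate with the inactive-path escape used by the
# integrators (dVest = 0 is only permitted when the estimate feeds nothing,
# i.e. alpha_P = 0 and Cm_est = 0).
vest_rate <- function(V_cmd, Vest, amp) {
  den <- (1 - amp$alpha_P) * amp$Rs_est * amp$Cm_est
  if (den > 0) return((V_cmd - Vest) / den)
  if (amp$alpha_P == 0 && amp$Cm_est == 0) return(0 * V_cmd)
  stop("Rs_est * Cm_est must be > 0 when the supercharging estimate is on ",
       "the active path (alpha_P > 0 or Cm_est > 0)")
}

#' Evaluate the artifact-model right-hand side
#'
#' Computes the time derivatives of all amplifier/cell state variables and
#' the derived signals, substituting right-hand-side derivatives in acyclic
#' order: supercharging estimate rate; compensated command (using the stored
#' observed current); compensation delay; amplifier delay; ionic and leak
#' currents at the true membrane voltage; membrane equation (with the
#' residual offset error added to the pipette potential); pre-filter measured
#' current including pipette/membrane capacitive currents and their
#' compensation; recording filter; and finally the ionic model's own gating
#' derivatives.
#'
#' This is the reference (pure R) implementation; [run_artifact()] integrates
#' an equivalent compiled version.
#'
#' @param t time (ms); unused by the autonomous system but part of the
#'   signature.
#' @param state named numeric vector: `Vm`, `Vp`, `Vest`, `Vclamp`, `Iout`,
#'   followed by the ionic model's states.
#' @param V_cmd command voltage (mV).
#' @param cell a [cell_parameters()] object.
#' @param amp an [amplifier_settings()] object.
#' @param ionic an `ionic_model`.
#' @return List with `deriv` (named derivative vector, same layout as
#'   `state`) and `signals` (named vector: `I_ion`, `I_leak`, `V_cmd`,
#'   `V_cmd_prime`, `I_in`).
#' @export
evaluate_derivatives <- function(t, state, V_cmd, cell, amp, ionic) {
  if (!all(is.finite(state))) stop("non-finite state")
  Vm <- state[["Vm"]]; Vp <- state[["Vp"]]; Vest <- state[["Vest"]]
  Vclamp <- state[["Vclamp"]]; Iout <- state[["Iout"]]
  n_ion <- ionic$n_states
  ion_states <- if (n_ion > 0) unname(state[5 + seq_len(n_ion)]) else numeric(0)

  dVest <- vest_rate(V_cmd, Vest, amp)
  V_cmd_p <- V_cmd + amp$Rs_est * (amp$alpha_R * Iout +
                                   amp$alpha_P * amp$Cm_est * dVest)
  dVclamp <- (V_cmd_p - Vclamp) / amp$tau_sum
  dVp <- (Vclamp - Vp) / amp$tau_clamp
  I_ion <- as.numeric(ionic_current(ionic, Vm, ion_states))
  I_leak <- cell$g_leak * (Vm - cell$E_leak)
  dVm <- (Vp + cell$V_off_err - Vm) / (cell$Rs * cell$Cm) -
         (I_ion + I_leak) / cell$Cm
  I_in <- I_ion + I_leak + cell$Cp * dVp - amp$Cp_est * dVclamp +
          cell$Cm * dVm - amp$Cm_est * dVest
  dIout <- (I_in - Iout) / amp$tau_z

  d_ion <- if (n_ion > 0) ionic_derivatives(ionic, Vm, ion_states) else numeric(0)
  deriv <- c(Vm = dVm, Vp = dVp, Vest = dVest, Vclamp = dVclamp,
             Iout = dIout)
  if (n_ion > 0) deriv <- c(deriv, stats::setNames(d_ion, ionic$state_names))
  list(deriv = deriv,
       signals = c(I_ion = I_ion, I_leak = I_leak, V_cmd = V_cmd,
                   V_cmd_prime = V_cmd_p, I_in = I_in))
}

# vectorized derived-signal reconstruction on an output grid.
# states: matrix with columns Vm, Vp, Vest, Vclamp, Iout, <ion states>.
clamp_signals <- function(states, V_cmd, cell, amp, ionic) {
  Vm <- states[, 1]; Vp <- states[, 2]; Vest <- states[, 3]
  Vclamp <- states[, 4]; Iout <- states[, 5]
  dVest <- vest_rate(V_cmd, Vest, amp)
  V_cmd_p <- V_cmd + amp$Rs_est * (amp$alpha_R * Iout +
                                   amp$alpha_P * amp$Cm_est * dVest)
  dVclamp <- (V_cmd_p - Vclamp) / amp$tau_sum
  dVp <- (Vclamp - Vp) / amp$tau_clamp
  ion_states <- if (ionic$n_states > 0)
    states[, 5 + seq_len(ionic$n_states), drop = FALSE] else NULL
  I_ion <- as.numeric(ionic_current(ionic, Vm, ion_states))
  I_leak <- cell$g_leak * (Vm - cell$E_leak)
  dVm <- (Vp + cell$V_off_err - Vm) / (cell$Rs * cell$Cm) -
         (I_ion + I_leak) / cell$Cm
  I_in <- I_ion + I_leak + cell$Cp * dVp - amp$Cp_est * dVclamp +
          cell$Cm * dVm - amp$Cm_est * dVest
  list(I_ion = I_ion, I_leak = I_leak, I_in = I_in)
}

#' Post-hoc leak subtraction
#'
#' `I_post = I_out - g_leak_est * (V_cmd - E_leak_est)`, the post-processing
#' leak correction applied to the observed current using the estimated leak
#' parameters; it is not part of the circuit dynamics.
#'
#' @param Iout_trace observed current series (pA).
#' @param V_cmd_trace time-aligned command voltage series (mV).
#' @param amp an [amplifier_settings()] object supplying `g_leak_est` and
#'   `E_leak_est`.
#' @return Leak-corrected current series (pA).
#' @export
leak_subtract <- function(Iout_trace, V_cmd_trace, amp) {
  if (length(Iout_trace) != length(V_cmd_trace))
    stop("Iout_trace and V_cmd_trace must have equal length")
  Iout_trace - amp$g_leak_est * (V_cmd_trace - amp$E_leak_est)
}

# initial state at protocol start: the cell has been held at Vcmd(0) long
# before recording, so all voltages sit at the offset-shifted holding level,
# the observed current carries the steady leak, and gating is at steady
# state for that membrane voltage.
initial_clamp_state <- function(V_hold, cell, amp, ionic) {
  V0 <- V_hold + cell$V_off_err
  ion0 <- initial_states(ionic, V0)
  I0 <- as.numeric(ionic_current(ionic, V0, unname(ion0))) +
        cell$g_leak * (V0 - cell$E_leak)
  st <- c(Vm = V0, Vp = V0, Vest = V0, Vclamp = V0, Iout = I0)
  if (length(ion0)) st <- c(st, ion0)
  st
}
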