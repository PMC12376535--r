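#' @useDynLib clampsim, .registration = TRUE
NULL

# Ionic models supply the cell's current I_ion = f(t, Vm) and the dynamics of
# their gating states. All bundled models have gating of relaxation form
# dx/dt = (x_inf(Vm) - x)/tau_x(Vm), which permits exact per-segment solution
# under an ideal clamp and a compact compiled fast path (kinds 1-4 in
# src/clampsim.c). Models loaded from free-form expression files integrate
# through an R-level fallback instead.

sigm <- function(x) 1 / (1 + exp(-x))

# tau(V) = base + amp * exp(delta*x)/(1 + exp(x)), x = (V - vmid)/k.
# Overflow-safe; covers constant, sigmoid and skewed-bell curves.
tau_curve <- function(V, q) {
  x <- (V - q[3]) / q[4]
  val <- ifelse(x > 0,
                exp((q[5] - 1) * x) / (1 + exp(-x)),
                exp(q[5] * x) / (1 + exp(x)))
  q[1] + q[2] * val
}

new_ionic_model <- function(name, kind, state_names, g_max, scale, E_rev,
                            params, inf_tau, current_fn = NULL,
                            density_nS_per_pF = NA_real_) {
  structure(list(
    name = name, kind = kind,
    state_names = state_names, n_states = length(state_names),
    g_max = g_max, scale = scale, E_rev = E_rev,
    density_nS_per_pF = density_nS_per_pF,
    params = params, inf_tau = inf_tau, current_fn = current_fn
  ), class = "ionic_model")
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("Ionic model '%s' (%d state%s: %s)\n", x$name, x$n_states,
              if (x$n_states == 1) "" else "s",
              paste(x$state_names, collapse = ", ")))
  if (is.na(x$g_max))
    cat(sprintf("  density = %.3g nS/pF (unbound; supply Cm)\n",
                x$density_nS_per_pF))
  else
    cat(sprintf("  g_max = %.4g nS, scale = %.4g, E_rev = %.4g mV\n",
                x$g_max, x$scale, x$E_rev))
  invisible(x)
}

#' Ionic current of a model at a voltage and gating state
#'
#' Evaluates `I_ion` (pA) for any `ionic_model`, vectorized over time
#' points. Conductance-bearing models scale linearly in `g_max * scale`,
#' read from the model object at call time (so [set_scale()] and
#' [bind_density()] take effect).
#'
#' @param model an `ionic_model`.
#' @param Vm membrane voltage(s) (mV).
#' @param states numeric matrix (rows = time points, columns = the model's
#'   states), or a vector for a single time point; `NULL` for stateless
#'   models.
#' @return Current(s) in pA (negative = inward).
#' @export
ionic_current <- function(model, Vm, states = NULL) {
  if (!is.null(states) && is.null(dim(states)) && model$n_states > 0)
    states <- matrix(states, ncol = model$n_states)
  if (is.integer(model$kind) && !is.na(model$kind)) {
    return(switch(as.character(model$kind),
      "0" = 0 * Vm,
      "1" = effective_g(model) * (Vm - model$E_rev),
      "2" = effective_g(model) * states[, 1]^3 * states[, 2] *
            (Vm - model$E_rev),
      "3" = {
        h <- 0.99 * states[, 2] + 0.01 * states[, 3]
        effective_g(model) * states[, 1]^3 * h * states[, 4] *
          (Vm - model$E_rev)
      },
      "4" = Vm / model$params$R_m +
            (Vm - states[, 1]) / model$params$R_f))
  }
  model$current_fn(model, Vm, states)
}

# effective maximum conductance on the absolute scale (nS)
effective_g <- function(model) {
  if (is.na(model$g_max))
    stop("ionic model '", model$name, "' is parameterized per-capacitance; ",
         "bind it to a cell with bind_density() first")
  model$g_max * model$scale
}

#' Rescale an ionic model's conductance
#'
#' `set_scale()` sets the dimensionless conductance multiplier (current is
#' linear in `g_max * scale`); `bind_density()` converts a per-capacitance
#' parameterization (nS/pF) to an absolute `g_max` using a cell's membrane
#' capacitance.
#'
#' @param model an `ionic_model`.
#' @param scale dimensionless multiplier (> 0 for a conducting model).
#' @param Cm_pF membrane capacitance used for the density-to-absolute
#'   conversion, or a [cell_parameters()] object.
#' @return The modified `ionic_model`.
#' @export
set_scale <- function(model, scale) {
  stopifnot(inherits(model, "ionic_model"), is.numeric(scale), scale >= 0)
  model$scale <- scale
  model
}

#' @rdname set_scale
#' @export
bind_density <- function(model, Cm_pF) {
  stopifnot(inherits(model, "ionic_model"))
  if (inherits(Cm_pF, "cell_parameters")) Cm_pF <- Cm_pF$Cm
  if (is.na(model$density_nS_per_pF))
    stop("model '", model$name, "' has no per-capacitance density")
  model$g_max <- model$density_nS_per_pF * Cm_pF
  model
}

#' Initial gating states at a holding voltage
#'
#' Returns each gating variable at its voltage-dependent steady state, the
#' appropriate initialization for a cell held at `Vm` long before recording.
#'
#' @param model an `ionic_model`.
#' @param Vm membrane voltage (mV).
#' @return Named numeric vector of length `model$n_states`.
#' @export
initial_states <- function(model, Vm) {
  if (model$n_states == 0) return(numeric(0))
  it <- model$inf_tau(Vm)
  stats::setNames(as.numeric(it$inf), model$state_names)
}

#' Gating derivatives at a voltage
#'
#' All bundled models relax toward their steady-state curves:
#' `dx/dt = (x_inf(Vm) - x) / tau_x(Vm)` (per ms).
#'
#' @param model an `ionic_model`.
#' @param Vm membrane voltage (mV).
#' @param states numeric vector of current gating values.
#' @return Numeric vector of time derivatives (per ms).
#' @export
ionic_derivatives <- function(model, Vm, states) {
  if (model$n_states == 0) return(numeric(0))
  it <- model$inf_tau(Vm)
  (it$inf - states) / it$tau
}

# ---- built-in formulations ----------------------------------------------

#' Generic Hodgkin-Huxley fast sodium current
#'
#' A parametric m^3 h fast sodium current used as a stand-in for
#' literature INa formulations: Boltzmann steady-state activation
#' (`V_half_m`, `k_m > 0`) and inactivation (`V_half_h`, `k_h < 0`) with
#' time-constant curves `tau(V) = base + amp * exp(delta*x)/(1+exp(x))`,
#' `x = (V - vmid)/k`. The defaults give an activation threshold near -40 mV
#' and an ideal-clamp I-V peak between -20 and -10 mV, typical of
#' NaV1.5 at physiological temperature.
#'
#' @param g_max_nS maximum conductance (nS).
#' @param E_Na_mV sodium reversal potential (mV).
#' @param V_half_m_mV,k_m_mV activation midpoint and slope (k_m > 0).
#' @param V_half_h_mV,k_h_mV inactivation midpoint and slope (k_h < 0).
#' @param tau_m,tau_h time-constant curve parameters: length-5 numeric
#'   `(base_ms, amp_ms, vmid_mV, k_mV, delta)`; a scalar is taken as a
#'   constant time constant.
#' @param scale dimensionless conductance multiplier.
#' @return An `ionic_model` with states `m`, `h`.
#' @export
hh_sodium <- function(g_max_nS = 300, E_Na_mV = 65,
                      V_half_m_mV = -34, k_m_mV = 5.5,
                      V_half_h_mV = -68, k_h_mV = -6,
                      tau_m = c(0.03, 0.25, -45, 8, 0.5),
                      tau_h = c(0.15, 12, -68, 6, 0.55),
                      scale = 1) {
  stopifnot(k_m_mV > 0, k_h_mV < 0)
  if (length(tau_m) == 1) tau_m <- c(tau_m, 0, 0, 1, 0)
  if (length(tau_h) == 1) tau_h <- c(tau_h, 0, 0, 1, 0)
  stopifnot(length(tau_m) == 5, length(tau_h) == 5)
  params <- list(E_Na = E_Na_mV, V_half_m = V_half_m_mV, k_m = k_m_mV,
                 V_half_h = V_half_h_mV, k_h = k_h_mV,
                 tau_m = tau_m, tau_h = tau_h)
  inf_tau <- function(Vm) {
    list(inf = cbind(m = sigm((Vm - V_half_m_mV) / k_m_mV),
                     h = sigm((Vm - V_half_h_mV) / k_h_mV)),
         tau = cbind(m = tau_curve(Vm, tau_m),
                     h = tau_curve(Vm, tau_h)))
  }
  new_ionic_model("hh_sodium", kind = 2L, state_names = c("m", "h"),
                  g_max = g_max_nS, scale = scale, E_rev = E_Na_mV,
                  params = params, inf_tau = inf_tau)
}

#' Passive linear membrane
#'
#' A stateless ohmic membrane current `g * (Vm - E)`, used for oracle tests
#' and as the artifact model's simplest cell.
#'
#' @param g_nS conductance (nS, >= 0).
#' @param E_mV reversal potential (mV).
#' @return An `ionic_model` with no states.
#' @export
passive_membrane <- function(g_nS, E_mV = 0) {
  stopifnot(g_nS >= 0)
  new_ionic_model("passive", kind = 1L, state_names = character(0),
                  g_max = g_nS, scale = 1, E_rev = E_mV, params = list(),
                  inf_tau = function(Vm) list(inf = numeric(0),
                                              tau = numeric(0)))
}

#' O'Hara-style fast sodium current
#'
#' The fast component of the human-ventricular fast sodium current in the
#' style of the 2011 O'Hara-Rudy formulation: `g * m^3 * h * j * (V - E_Na)`
#' with `h = 0.99 h_fast + 0.01 h_slow` (non-phosphorylated pathway only).
#' The baseline conductance density is 75 nS/pF; bind to a cell with
#' [bind_density()] or pass `g_max_nS`.
#'
#' @param g_max_nS absolute maximum conductance (nS); `NA` keeps the model
#'   parameterized per-capacitance at `density_nS_per_pF`.
#' @param density_nS_per_pF conductance density (nS/pF).
#' @param E_Na_mV sodium reversal potential (mV).
#' @param scale dimensionless conductance multiplier.
#' @return An `ionic_model` with states `m`, `hf`, `hs`, `j`.
#' @export
ohara_ina <- function(g_max_nS = NA_real_, density_nS_per_pF = 75,
                      E_Na_mV = 70, scale = 1) {
  inf_tau <- function(Vm) {
    m_inf <- sigm((Vm + 39.57) / 9.871)
    tau_m <- 1 / (6.765 * exp((Vm + 11.64) / 34.77) +
                  8.552 * exp(-(Vm + 77.42) / 5.955))
    h_inf <- sigm(-(Vm + 82.90) / 6.086)
    tau_hf <- 1 / (1.432e-5 * exp(-(Vm + 1.196) / 6.285) +
                   6.149 * exp((Vm + 0.5096) / 20.27))
    tau_hs <- 1 / (0.009794 * exp(-(Vm + 17.95) / 28.05) +
                   0.3343 * exp((Vm + 5.730) / 56.66))
    tau_j <- 2.038 + 1 / (0.02136 * exp(-(Vm + 100.6) / 8.281) +
                          0.3052 * exp((Vm + 0.9941) / 38.45))
    list(inf = cbind(m = m_inf, hf = h_inf, hs = h_inf, j = h_inf),
         tau = cbind(m = tau_m, hf = tau_hf, hs = tau_hs, j = tau_j))
  }
  new_ionic_model("ohara_ina", kind = 3L,
                  state_names = c("m", "hf", "hs", "j"),
                  g_max = g_max_nS, scale = scale, E_rev = E_Na_mV,
                  params = list(), inf_tau = inf_tau,
                  density_nS_per_pF = density_nS_per_pF)
}

# internal: the electrical model cell's "ionic current" branch as an
# ionic_model (state V_Cf), so the artifact integrator can host it.
model_cell_ionic <- function(mc) {
  stopifnot(inherits(mc, "model_cell_params"))
  new_ionic_model("model_cell", kind = 4L, state_names = "V_Cf",
                  g_max = 1, scale = 1, E_rev = 0,
                  params = list(R_m = mc$R_m, R_f = mc$R_f, C_f = mc$C_f),
                  inf_tau = function(Vm) {
                    list(inf = cbind(V_Cf = Vm),
                         tau = cbind(V_Cf = rep(mc$R_f * mc$C_f,
                                                length(Vm))))
                  })
}

# parameter block for the compiled RHS (src/clampsim.c layout)
ion_cparams <- function(model) {
  g <- if (model$kind %in% c(2L, 3L)) effective_g(model) else NA
  switch(as.character(model$kind),
    "0" = numeric(0),
    "1" = c(effective_g(model), model$E_rev),
    "2" = with(model$params,
               c(g, E_Na, V_half_m, k_m, V_half_h, k_h, tau_m, tau_h)),
    "3" = c(g, model$E_rev),
    "4" = with(model$params, c(R_m, R_f, C_f)),
    stop("ionic model '", model$name, "' has no compiled fast path")
  )
}

has_compiled_path <- function(model) {
  is.integer(model$kind) && model$kind %in% 0:4
}

# ---- standalone operations ----------------------------------------------

#' Hodgkin-Huxley sodium current at given gating values
#'
#' Direct evaluation of `g_max * scale * m^3 * h * (Vm - E_Na)`.
#'
#' @param Vm membrane voltage (mV).
#' @param m,h activation and inactivation gate values in \[0, 1\].
#' @param g_max_nS maximum conductance (nS).
#' @param E_Na_mV reversal potential (mV).
#' @param scale dimensionless conductance multiplier.
#' @return Current in pA (negative = inward).
#' @examples
#' hh_sodium_current(-25, m = 0.5, h = 0.8, g_max_nS = 100, E_Na_mV = 65)
#' @export
hh_sodium_current <- function(Vm, m, h, g_max_nS, E_Na_mV, scale = 1) {
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  g_max_nS * scale * m^3 * h * (Vm - E_Na_mV)
}

#' Boltzmann gating steady states
#'
#' `x_inf(Vm) = 1 / (1 + exp(-(Vm - V_half)/k))`; increasing in `Vm` for the
#' activation gate (`k_m > 0`), decreasing for inactivation (`k_h < 0`).
#'
#' @param Vm membrane voltage (mV).
#' @param model an `ionic_model` built by [hh_sodium()] (or parameters given
#'   explicitly via `V_half_m_mV` etc.).
#' @param V_half_m_mV,k_m_mV,V_half_h_mV,k_h_mV Boltzmann parameters used
#'   when `model` is `NULL`.
#' @return List with elements `m_inf` and `h_inf`.
#' @export
gating_steady_state <- function(Vm, model = NULL,
                                V_half_m_mV = -34, k_m_mV = 5.5,
                                V_half_h_mV = -68, k_h_mV = -6) {
  if (!is.null(model)) {
    p <- model$params
    V_half_m_mV <- p$V_half_m; k_m_mV <- p$k_m
    V_half_h_mV <- p$V_half_h; k_h_mV <- p$k_h
  }
  list(m_inf = sigm((Vm - V_half_m_mV) / k_m_mV),
       h_inf = sigm((Vm - V_half_h_mV) / k_h_mV))
}

#' Passive membrane current
#'
#' @param Vm membrane voltage (mV).
#' @param g_nS conductance (nS, >= 0).
#' @param E_mV reversal potential (mV).
#' @return Current in pA.
#' @export
passive_membrane_current <- function(Vm, g_nS, E_mV = 0) {
  stopifnot(g_nS >= 0)
  g_nS * (Vm - E_mV)
}
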