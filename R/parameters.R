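#' Physical properties of the patched cell and pipette
#'
#' Bundles the true (as opposed to machine-estimated) physical parameters of a
#' whole-cell recording: series resistance, membrane and pipette capacitance,
#' ohmic seal/background leak, and the residual voltage-offset error remaining
#' after amplifier offset compensation.
#'
#' Resistances are user-facing in MOhm and stored internally in GOhm so that
#' the internal unit system (mV, ms, pA, pF, nS, GOhm) is closed:
#' GOhm * pF = ms and nS * mV = pA.
#'
#' @param Rs_MOhm series resistance between pipette electrode and cell
#'   interior (MOhm, > 0).
#' @param Cm_pF membrane capacitance (pF, > 0).
#' @param Cp_pF stray pipette capacitance (pF, >= 0).
#' @param g_leak_nS seal/background leak conductance (nS, >= 0).
#' @param E_leak_mV leak reversal potential (mV).
#' @param V_off_err_mV residual voltage-offset error after compensation (mV);
#'   a positive value depolarizes the effective pipette potential.
#' @return An object of class `cell_parameters`.
#' @examples
#' cell_parameters(Rs_MOhm = 5, Cm_pF = 15)
#' @export
cell_parameters <- function(Rs_MOhm, Cm_pF, Cp_pF = 4, g_leak_nS = 0,
                            E_leak_mV = 0, V_off_err_mV = 0) {
  stopifnot(is.numeric(Rs_MOhm), length(Rs_MOhm) == 1L, Rs_MOhm > 0,
            is.numeric(Cm_pF), Cm_pF > 0, Cp_pF >= 0, g_leak_nS >= 0)
  structure(list(
    Rs = Rs_MOhm * 1e-3,   # GOhm
    Cm = Cm_pF,
    Cp = Cp_pF,
    g_leak = g_leak_nS,
    E_leak = E_leak_mV,
    V_off_err = V_off_err_mV
  ), class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("Cell parameters (true values):\n")
  cat(sprintf("  Rs      = %.3f MOhm\n", x$Rs * 1e3))
  cat(sprintf("  Cm      = %.2f pF\n", x$Cm))
  cat(sprintf("  Cp      = %.2f pF\n", x$Cp))
  cat(sprintf("  g_leak  = %.3f nS (E_leak = %.1f mV)\n", x$g_leak, x$E_leak))
  cat(sprintf("  Voff+   = %.2f mV (residual offset error)\n", x$V_off_err))
  invisible(x)
}

#' Amplifier compensation settings and machine parameter estimates
#'
#' Houses the user-set compensation fractions, the amplifier's estimates of
#' the cell properties used by the compensation circuitry, and the circuit
#' delay/filter time constants.
#'
#' Both compensation fractions are capped at `alpha_max = 0.95`: the
#' supercharging estimate dynamics diverge as `alpha_P` approaches 1 (its
#' effective time constant is `(1 - alpha_P) * Rs_est * Cm_est`), and
#' compensation settings beyond 95% are not used experimentally.
#'
#' @param alpha_R series-resistance compensation fraction in \[0, 0.95\].
#' @param alpha_P supercharging (prediction) fraction in \[0, 0.95\].
#' @param Rs_est_MOhm machine estimate of the series resistance (MOhm).
#' @param Cm_est_pF machine estimate of the membrane capacitance (pF).
#' @param Cp_est_pF machine (fast-capacitance) estimate of the pipette
#'   capacitance (pF).
#' @param g_leak_est_nS post-processing estimate of the leak conductance (nS).
#' @param E_leak_est_mV post-processing estimate of the leak reversal (mV).
#' @param tau_clamp_ms amplifier delay time constant (ms, > 0). The 0.01 ms
#'   defaults for all three delay/filter constants are the order of real
#'   patch-clamp hardware (series-resistance compensation speed settings of
#'   2-100 us; recording filters around 10 kHz).
#' @param tau_sum_ms compensation-summation delay time constant (ms, > 0).
#' @param tau_z_ms recording filter time constant (ms, > 0).
#' @return An object of class `amplifier_settings`.
#' @examples
#' amplifier_settings(alpha_R = 0.8, alpha_P = 0.8,
#'                    Rs_est_MOhm = 5, Cm_est_pF = 15)
#' @export
amplifier_settings <- function(alpha_R = 0, alpha_P = 0,
                               Rs_est_MOhm = 0, Cm_est_pF = 0,
                               Cp_est_pF = 0, g_leak_est_nS = 0,
                               E_leak_est_mV = 0,
                               tau_clamp_ms = 0.01, tau_sum_ms = 0.01,
                               tau_z_ms = 0.01) {
  alpha_max <- 0.95
  if (alpha_R < 0 || alpha_R > alpha_max)
    stop("alpha_R must lie in [0, ", alpha_max, "]")
  if (alpha_P < 0 || alpha_P > alpha_max)
    stop("alpha_P must lie in [0, ", alpha_max, "] (the supercharging ",
         "denominator (1 - alpha_P) vanishes at 1)")
  stopifnot(Rs_est_MOhm >= 0, Cm_est_pF >= 0, Cp_est_pF >= 0,
            g_leak_est_nS >= 0,
            tau_clamp_ms > 0, tau_sum_ms > 0, tau_z_ms > 0)
  structure(list(
    alpha_R = alpha_R,
    alpha_P = alpha_P,
    Rs_est = Rs_est_MOhm * 1e-3,  # GOhm
    Cm_est = Cm_est_pF,
    Cp_est = Cp_est_pF,
    g_leak_est = g_leak_est_nS,
    E_leak_est = E_leak_est_mV,
    tau_clamp = tau_clamp_ms,
    tau_sum = tau_sum_ms,
    tau_z = tau_z_ms
  ), class = "amplifier_settings")
}

#' @export
print.amplifier_settings <- function(x, ...) {
  cat("Amplifier settings:\n")
  cat(sprintf("  alpha_R = %.0f%%, alpha_P = %.0f%%\n",
              100 * x$alpha_R, 100 * x$alpha_P))
  cat(sprintf("  Rs* = %.3f MOhm, Cm* = %.2f pF, Cp* = %.2f pF\n",
              x$Rs_est * 1e3, x$Cm_est, x$Cp_est))
  cat(sprintf("  g_leak* = %.3f nS (E_leak* = %.1f mV)\n",
              x$g_leak_est, x$E_leak_est))
  cat(sprintf("  tau_clamp = %g ms, tau_sum = %g ms, tau_z = %g ms\n",
              x$tau_clamp, x$tau_sum, x$tau_z))
  invisible(x)
}

#' Amplifier settings with perfect machine estimates for a cell
#'
#' Convenience constructor setting `Rs* = Rs`, `Cm* = Cm`, `Cp* = Cp` from a
#' [cell_parameters()] object (the "perfect estimates" condition used in the
#' population studies).
#'
#' @param cell a [cell_parameters()] object supplying the true values.
#' @param alpha_R,alpha_P compensation fractions.
#' @param g_leak_est_nS,E_leak_est_mV leak-subtraction estimates.
#' @param ... further arguments passed to [amplifier_settings()].
#' @return An `amplifier_settings` object.
#' @export
matched_amplifier <- function(cell, alpha_R = 0, alpha_P = 0,
                              g_leak_est_nS = cell$g_leak,
                              E_leak_est_mV = cell$E_leak, ...) {
  amplifier_settings(alpha_R = alpha_R, alpha_P = alpha_P,
                     Rs_est_MOhm = cell$Rs * 1e3, Cm_est_pF = cell$Cm,
                     Cp_est_pF = cell$Cp, g_leak_est_nS = g_leak_est_nS,
                     E_leak_est_mV = E_leak_est_mV, ...)
}

#' Electrical model-cell component values
#'
#' Parameters of the two-branch linear hardware circuit used for validating
#' the artifact model: a membrane RC branch (resistance `R_m`, with the cell
#' capacitance supplied separately as the simulated `Cm`) in parallel with a
#' series-RC "fast" branch (`R_f`, `C_f`) whose sub-millisecond time constant
#' mimics a fast ionic current.
#'
#' @param R_m_MOhm membrane-branch resistance (MOhm, > 0).
#' @param R_f_MOhm fast-branch resistance (MOhm, > 0).
#' @param C_f_pF fast-branch capacitance (pF, > 0).
#' @return An object of class `model_cell_params`.
#' @examples
#' model_cell_params()  # defaults: fast-branch time constant 0.5 ms
#' @export
model_cell_params <- function(R_m_MOhm = 500, R_f_MOhm = 25, C_f_pF = 20) {
  stopifnot(R_m_MOhm > 0, R_f_MOhm > 0, C_f_pF > 0)
  structure(list(
    R_m = R_m_MOhm * 1e-3,  # GOhm
    R_f = R_f_MOhm * 1e-3,  # GOhm
    C_f = C_f_pF
  ), class = "model_cell_params")
}

#' @export
print.model_cell_params <- function(x, ...) {
  cat("Electrical model cell:\n")
  cat(sprintf("  R_m = %.1f MOhm, R_f = %.1f MOhm, C_f = %.1f pF ",
              x$R_m * 1e3, x$R_f * 1e3, x$C_f))
  cat(sprintf("(fast tau = %.3f ms)\n", x$R_f * x$C_f))
  invisible(x)
}

# ---- flat key:value config serialization --------------------------------

cell_config_keys <- c("Rs_MOhm", "Cm_pF", "Cp_pF", "g_leak_nS", "E_leak_mV",
                      "V_off_err_mV")
amp_config_keys <- c("alpha_R", "alpha_P", "Rs_est_MOhm", "Cm_est_pF",
                     "Cp_est_pF", "g_leak_est_nS", "E_leak_est_mV",
                     "tau_clamp_ms", "tau_sum_ms", "tau_z_ms")
model_cell_config_keys <- c("R_m_MOhm", "C_m_cell_pF", "R_f_MOhm", "C_f_pF")

read_flat_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
}

write_flat_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Read and write parameter sets as flat key:value configs
#'
#' Parameter containers serialize to a flat key:value configuration in JSON or
#' YAML (chosen by file extension). The keys are, for cells: `Rs_MOhm, Cm_pF,
#' Cp_pF, g_leak_nS, E_leak_mV, V_off_err_mV`; for amplifier settings:
#' `alpha_R, alpha_P, Rs_est_MOhm, Cm_est_pF, Cp_est_pF, g_leak_est_nS,
#' E_leak_est_mV, tau_clamp_ms, tau_sum_ms, tau_z_ms`; for the model cell:
#' `R_m_MOhm, C_m_cell_pF, R_f_MOhm, C_f_pF` (where `C_m_cell_pF` maps onto
#' the simulated membrane capacitance). One file may carry any union of keys.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @param cell,amp,mc objects to serialize (any may be `NULL`).
#' @return `read_clamp_config()` returns a list with elements `cell`, `amp`
#'   and `mc` (each `NULL` when its keys are absent); `write_clamp_config()`
#'   returns `path` invisibly.
#' @export
read_clamp_config <- function(path) {
  cfg <- read_flat_config(path)
  out <- list(cell = NULL, amp = NULL, mc = NULL)
  if (all(c("Rs_MOhm", "Cm_pF") %in% names(cfg)))
    out$cell <- do.call(cell_parameters, cfg[intersect(cell_config_keys, names(cfg))])
  if (any(amp_config_keys %in% names(cfg)))
    out$amp <- do.call(amplifier_settings, cfg[intersect(amp_config_keys, names(cfg))])
  if (all(c("R_m_MOhm", "R_f_MOhm", "C_f_pF") %in% names(cfg)))
    out$mc <- model_cell_params(R_m_MOhm = cfg$R_m_MOhm,
                                R_f_MOhm = cfg$R_f_MOhm, C_f_pF = cfg$C_f_pF)
  out
}

#' @rdname read_clamp_config
#' @export
write_clamp_config <- function(path, cell = NULL, amp = NULL, mc = NULL) {
  cfg <- list()
  if (!is.null(cell))
    cfg <- c(cfg, list(Rs_MOhm = cell$Rs * 1e3, Cm_pF = cell$Cm,
                       Cp_pF = cell$Cp, g_leak_nS = cell$g_leak,
                       E_leak_mV = cell$E_leak,
                       V_off_err_mV = cell$V_off_err))
  if (!is.null(amp))
    cfg <- c(cfg, list(alpha_R = amp$alpha_R, alpha_P = amp$alpha_P,
                       Rs_est_MOhm = amp$Rs_est * 1e3,
                       Cm_est_pF = amp$Cm_est, Cp_est_pF = amp$Cp_est,
                       g_leak_est_nS = amp$g_leak_est,
                       E_leak_est_mV = amp$E_leak_est,
                       tau_clamp_ms = amp$tau_clamp,
                       tau_sum_ms = amp$tau_sum, tau_z_ms = amp$tau_z))
  if (!is.null(mc))
    cfg <- c(cfg, list(R_m_MOhm = mc$R_m * 1e3,
                       C_m_cell_pF = if (!is.null(cell)) cell$Cm else NA_real_,
                       R_f_MOhm = mc$R_f * 1e3, C_f_pF = mc$C_f))
  write_flat_config(cfg, path)
}
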