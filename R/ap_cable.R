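# Propagating sodium-current mischaracterization into cellular and tissue
# consequences: a minimal excitable action-potential model (pluggable fast
# INa density model + linear repolarizing current, all per-capacitance so
# units are pA/pF = mV/ms), maximum upstroke velocity, and a 1-D chain of
# gap-junction-coupled cells with no-flux ends.

#' Minimal excitable action-potential model
#'
#' `dV/dt = -(I_Na + g_K (V - E_K)) + I_stim` in density units (pA/pF),
#' with a swappable fast sodium current model. Deliberately minimal: it
#' produces an INa-driven upstroke and an exponential repolarization, which
#' is what the upstroke-velocity and conduction-velocity analyses need; it
#' is not a full ventricular model.
#'
#' @param ina a per-capacitance fast-sodium `ionic_model` (default the
#'   bundled Gray-Franz-style INa at 20 nS/pF).
#' @param ina_scale conductance multiplier applied to the INa (the handle
#'   for studying mischaracterized conductance).
#' @param g_K_nS_per_pF linear repolarizing conductance (nS/pF).
#' @param E_K_mV repolarizing reversal potential (mV).
#' @return An object of class `ap_model`.
#' @export
minimal_ap_model <- function(ina = gray_franz_ina(), ina_scale = 1,
                             g_K_nS_per_pF = 0.3, E_K_mV = -85) {
  if (is.na(ina$g_max)) ina <- bind_density(ina, 1)  # density units (per pF)
  ina <- set_scale(ina, ina_scale)
  model <- structure(list(ina = ina, g_K = g_K_nS_per_pF, E_K = E_K_mV,
                          state_names = c("V", ina$state_names),
                          n_states = 1L + ina$n_states),
                     class = "ap_model")
  model
}

#' @export
print.ap_model <- function(x, ...) {
  cat(sprintf("Minimal AP model: INa '%s' x %.3g, g_K = %g nS/pF, E_K = %g mV\n",
              x$ina$name, x$ina$scale, x$g_K, x$E_K))
  invisible(x)
}

# resting state: V where the total steady current vanishes, gating at
# steady state for that V
ap_rest <- function(model) {
  f <- function(V) {
    s <- matrix(unname(initial_states(model$ina, V)), nrow = 1)
    as.numeric(ionic_current(model$ina, V, s)) + model$g_K * (V - model$E_K)
  }
  V0 <- stats::uniroot(f, c(model$E_K - 5, -50))$root
  c(V0, unname(initial_states(model$ina, V0)))
}

# vectorized density-current RHS over n cells; y is a matrix [n x n_states]
ap_derivs <- function(model, y, Istim) {
  V <- y[, 1]
  ion <- if (model$ina$n_states > 0) y[, -1, drop = FALSE] else NULL
  I_ion <- as.numeric(ionic_current(model$ina, V, ion)) + model$g_K * (V - model$E_K)
  dV <- -I_ion + Istim
  d_ion <- if (!is.null(ion)) {
    it <- model$ina$inf_tau(V)
    (it$inf - ion) / it$tau
  } else NULL
  cbind(dV, d_ion)
}

#' Pacing configuration
#'
#' @param pre_pace_s pre-pacing duration (s).
#' @param frequency_Hz pacing frequency (Hz).
#' @param stim_amplitude_pA_per_pF stimulus current density (pA/pF).
#' @param stim_duration_ms stimulus duration (ms).
#' @return A list of class `pacing_config`.
#' @export
pacing_config <- function(pre_pace_s = 10, frequency_Hz = 2,
                          stim_amplitude_pA_per_pF = 60,
                          stim_duration_ms = 1) {
  stopifnot(pre_pace_s >= 0, frequency_Hz > 0,
            stim_amplitude_pA_per_pF > 0, stim_duration_ms > 0)
  structure(list(pre_pace_s = pre_pace_s, frequency_Hz = frequency_Hz,
                 stim_amplitude = stim_amplitude_pA_per_pF,
                 stim_duration = stim_duration_ms),
            class = "pacing_config")
}

#' Cable configuration
#'
#' A 1-D chain of identical cells coupled by nearest-neighbor gap-junction
#' currents `sum_j g_gap (V_i - V_j)` (per-capacitance conductance), no-flux
#' ends, stimulus applied to cell 1. Analysis is restricted to a central
#' window to avoid boundary effects.
#'
#' @param n_cells number of cells in the chain.
#' @param g_gap_nS_per_pF gap-junction conductance (nS/pF).
#' @param cell_length_um cell length along the cable (micrometers).
#' @param analysis_cells index range (length 2) analyzed; defaults to the
#'   central two-thirds (the central 1000 cells of a 1500-cell chain).
#' @param stim_amplitude_pA_per_pF,stim_duration_ms stimulus at the cable
#'   end.
#' @param stim_cells number of cells at the stimulated end receiving the
#'   stimulus. At physiological coupling a single stimulated cell cannot
#'   reach threshold (the gap-junction sink spreads the charge over the
#'   electrotonic length before activation), so a short stimulation region
#'   (default 5 cells = 0.5 mm) is used to launch the wave.
#' @return A list of class `cable_config`.
#' @export
cable_config <- function(n_cells = 1500, g_gap_nS_per_pF = 14,
                         cell_length_um = 100, analysis_cells = NULL,
                         stim_amplitude_pA_per_pF = 60,
                         stim_duration_ms = 1, stim_cells = 5) {
  stopifnot(n_cells >= 2, g_gap_nS_per_pF >= 0, cell_length_um > 0)
  if (is.null(analysis_cells)) {
    margin <- floor(n_cells / 6)
    analysis_cells <- c(1 + margin, n_cells - margin)
  }
  stopifnot(length(analysis_cells) == 2, analysis_cells[1] >= 1,
            analysis_cells[2] <= n_cells,
            analysis_cells[1] < analysis_cells[2])
  stopifnot(stim_cells >= 1, stim_cells < analysis_cells[1])
  structure(list(n_cells = as.integer(n_cells), g_gap = g_gap_nS_per_pF,
                 cell_length_um = cell_length_um,
                 analysis_cells = as.integer(analysis_cells),
                 stim_amplitude = stim_amplitude_pA_per_pF,
                 stim_duration = stim_duration_ms,
                 stim_cells = as.integer(stim_cells)),
            class = "cable_config")
}

integrate_ap_segment <- function(model, y0, times, stim_vec, bandwidth,
                                 rtol, atol) {
  n <- length(y0) / model$n_states
  rhs <- function(t, y, p) {
    ym <- matrix(y, nrow = n, byrow = TRUE)
    d <- ap_derivs(model, ym, p$stim + if (n > 1) p$gap(ym[, 1]) else 0)
    list(as.numeric(t(d)))
  }
  gap_fun <- NULL
  if (n > 1) {
    g <- stim_vec$g_gap
    gap_fun <- function(V) {
      left <- c(V[1], V[-n]); right <- c(V[-1], V[n])  # no-flux ends
      g * ((left - V) + (right - V))
    }
  }
  p <- list(stim = stim_vec$stim, gap = gap_fun)
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = p,
                        rtol = rtol, atol = atol,
                        jactype = if (n > 1) "bandint" else "fullint",
                        bandup = if (n > 1) bandwidth else NULL,
                        banddown = if (n > 1) bandwidth else NULL,
                        maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) stop("integrator failure in AP segment")
  sol
}

#' Simulate a paced action potential
#'
#' Pre-paces the model to its periodic state, then records one beat
#' stimulated with the same stimulus current. Deterministic.
#'
#' @param model an [minimal_ap_model()] (or compatible `ap_model`).
#' @param pacing a [pacing_config()].
#' @param record_dt_ms output sampling of the recorded beat (ms).
#' @param record_ms recorded duration from stimulus onset (ms); defaults to
#'   one pacing period.
#' @return Data frame with `t_ms` (0 at stimulus onset) and `V_mV`, class
#'   `ap_trace`.
#' @export
run_ap <- function(model, pacing = pacing_config(), record_dt_ms = 0.01,
                   record_ms = NULL) {
  period <- 1000 / pacing$frequency_Hz
  if (is.null(record_ms)) record_ms <- period
  n_pre <- floor(pacing$pre_pace_s * 1000 / period)
  y <- ap_rest(model)
  beat <- function(y, fine) {
    t_stim <- if (fine) seq(0, pacing$stim_duration, by = record_dt_ms)
              else c(0, pacing$stim_duration)
    s1 <- integrate_ap_segment(model, y, t_stim,
                               list(stim = pacing$stim_amplitude), 0,
                               1e-8, 1e-8)
    rest_end <- if (fine) record_ms else period
    t_rest <- if (fine)
      seq(pacing$stim_duration, rest_end, by = record_dt_ms)
    else c(pacing$stim_duration, period)
    s2 <- integrate_ap_segment(model, s1[nrow(s1), -1], t_rest,
                               list(stim = 0), 0, 1e-8, 1e-8)
    list(y = s2[nrow(s2), -1],
         t = c(s1[-nrow(s1), 1], s2[, 1]),
         V = c(s1[-nrow(s1), 2], s2[, 2]))
  }
  for (b in seq_len(n_pre)) y <- beat(y, fine = FALSE)$y
  rec <- beat(y, fine = TRUE)
  if (max(rec$V) < 0)
    warning("non-excitable: no upstroke crossed 0 mV in the recorded beat")
  structure(data.frame(t_ms = rec$t, V_mV = rec$V),
            class = c("ap_trace", "data.frame"))
}

#' Maximum upstroke velocity of a voltage trace
#'
#' Second-order accurate central differences on a uniform grid:
#' `max over interior i of (V[i+1] - V[i-1]) / (2 dt)`.
#'
#' @param trace an `ap_trace` or data frame with `t_ms` and `V_mV`, or a
#'   numeric voltage vector with `dt_ms` given.
#' @param dt_ms grid spacing when `trace` is a bare numeric vector.
#' @return Maximum dV/dt in mV/ms.
#' @export
max_upstroke_velocity <- function(trace, dt_ms = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    V <- trace
    stopifnot(!is.null(dt_ms))
  } else {
    V <- trace$V_mV
    dts <- diff(trace$t_ms)
    if (diff(range(dts)) > 1e-8 * mean(dts))
      stop("max_upstroke_velocity requires a uniform time grid")
    dt_ms <- mean(dts)
  }
  if (length(V) < 3) stop("need at least 3 points for central differences")
  n <- length(V)
  max((V[3:n] - V[1:(n - 2)]) / (2 * dt_ms))
}

#' Simulate a 1-D cable of coupled action-potential models
#'
#' Integrates `n_cells` copies of the AP model coupled by nearest-neighbor
#' gap-junction current with no-flux ends; the stimulus is applied to
#' cell 1. Only the analysis-window cells are returned.
#'
#' @param model an `ap_model`.
#' @param config a [cable_config()].
#' @param duration_ms simulated duration; defaults to a conservative bound
#'   on the propagation time across the chain.
#' @param record_dt_ms output sampling (ms).
#' @param rtol,atol integration tolerances.
#' @return List of class `cable_result`: `t_ms`, `V_mV` (matrix time x
#'   analysis cells), `cells` (their indices), `config`.
#' @export
run_cable <- function(model, config = cable_config(), duration_ms = NULL,
                      record_dt_ms = 0.02, rtol = 1e-6, atol = 1e-6) {
  n <- config$n_cells
  ns <- model$n_states
  if (is.null(duration_ms))
    duration_ms <- 10 + 0.5 * n
  # interleaved layout: (V_1, ion_1..), (V_2, ion_2..), ...
  y0 <- rep(ap_rest(model), n)
  stim_cells <- c(rep(config$stim_amplitude, config$stim_cells),
                  rep(0, n - config$stim_cells))
  seg1 <- integrate_ap_segment(model, y0,
                               seq(0, config$stim_duration,
                                   by = record_dt_ms),
                               list(stim = stim_cells, g_gap = config$g_gap),
                               ns, rtol, atol)
  seg2 <- integrate_ap_segment(model, seg1[nrow(seg1), -1],
                               seq(config$stim_duration, duration_ms,
                                   by = record_dt_ms),
                               list(stim = rep(0, n), g_gap = config$g_gap),
                               ns, rtol, atol)
  t_all <- c(seg1[-nrow(seg1), 1], seg2[, 1])
  Y <- rbind(seg1[-nrow(seg1), -1, drop = FALSE], seg2[, -1, drop = FALSE])
  v_cols <- 1 + ns * (seq(config$analysis_cells[1],
                          config$analysis_cells[2]) - 1)
  structure(list(t_ms = t_all, V_mV = Y[, v_cols, drop = FALSE],
                 cells = seq(config$analysis_cells[1],
                             config$analysis_cells[2]),
                 config = config),
            class = "cable_result")
}

#' Conduction velocity along the cable
#'
#' Activation is the first upward crossing of a threshold (default 0 mV,
#' linearly interpolated between samples); CV is the distance between the
#' first and last analysis cells divided by their activation-time
#' difference, using the configured cell length, reported in cm/s.
#'
#' @param result a `cable_result` from [run_cable()].
#' @param threshold_mV activation threshold (mV).
#' @return Conduction velocity in cm/s.
#' @export
conduction_velocity <- function(result, threshold_mV = 0) {
  act <- activation_times(result, threshold_mV)
  ok <- is.finite(act)
  if (sum(ok) < 2 || !is.finite(act[length(act)]))
    stop("no propagation: activation did not reach the analysis window end")
  i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
  dist_um <- (result$cells[i2] - result$cells[i1]) *
    result$config$cell_length_um
  dt_ms <- act[i2] - act[i1]
  if (dt_ms <= 0) stop("non-positive activation-time difference")
  (dist_um / dt_ms) * 0.1   # um/ms -> cm/s
}

# first threshold crossing per analysis cell (NA if never)
activation_times <- function(result, threshold_mV = 0) {
  apply(result$V_mV, 2, function(V) {
    i <- which(V[-1] >= threshold_mV & V[-length(V)] < threshold_mV)[1]
    if (is.na(i)) return(NA_real_)
    t0 <- result$t_ms[i]; t1 <- result$t_ms[i + 1]
    f <- (threshold_mV - V[i]) / (V[i + 1] - V[i])
    t0 + f * (t1 - t0)
  })
}

#' Write a cable run to CSV + JSON summary
#'
#' One CSV (cells x time matrix with headers) and a JSON summary with
#' `CV_cm_per_s`, `dVdt_max_mV_per_ms` (of the window's center cell) and
#' `threshold_mV`.
#'
#' @param result a `cable_result`.
#' @param path CSV path (summary goes to `<path>.json`).
#' @param threshold_mV activation threshold for the CV summary.
#' @return `path`, invisibly.
#' @export
write_cable_csv <- function(result, path, threshold_mV = 0) {
  m <- t(result$V_mV)
  dimnames(m) <- list(paste0("cell_", result$cells),
                      sprintf("t_%g", result$t_ms))
  utils::write.csv(m, path)
  center <- which.min(abs(result$cells - stats::median(result$cells)))
  cv <- tryCatch(conduction_velocity(result, threshold_mV),
                 error = function(e) NA_real_)
  dvdt <- max_upstroke_velocity(result$V_mV[, center],
                                dt_ms = diff(result$t_ms[1:2]))
  jsonlite::write_json(list(CV_cm_per_s = cv, dVdt_max_mV_per_ms = dvdt,
                            threshold_mV = threshold_mV),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
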