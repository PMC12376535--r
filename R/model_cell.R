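# The linear electrical "model cell": a membrane RC branch in parallel with
# a series-RC fast branch whose sub-millisecond time constant mimics a fast
# ionic current. Because the whole artifact system is then linear and
# time-invariant within each protocol segment, it admits an exact
# matrix-exponential solution that serves as an independent oracle for the
# numerical integrator.

#' Model-cell branch current and fast-branch dynamics
#'
#' `I_ion = Vm/R_m + (Vm - V_Cf)/R_f` and
#' `dV_Cf/dt = (Vm - V_Cf)/(R_f * C_f)` in internal units.
#'
#' @param Vm membrane voltage (mV).
#' @param V_Cf fast-branch capacitor voltage (mV).
#' @param params a [model_cell_params()] object.
#' @return List with `I_ion` (pA) and `dV_Cf_dt` (mV/ms).
#' @export
model_cell_current <- function(Vm, V_Cf, params) {
  stopifnot(inherits(params, "model_cell_params"))
  list(I_ion = Vm / params$R_m + (Vm - V_Cf) / params$R_f,
       dV_Cf_dt = (Vm - V_Cf) / (params$R_f * params$C_f))
}

# assemble the affine system dy/dt = A y + b for a linear ionic model at a
# fixed command voltage, by evaluating the (linear) RHS at basis vectors.
linear_system <- function(V_cmd, cell, amp, ionic) {
  nms <- c("Vm", "Vp", "Vest", "Vclamp", "Iout", ionic$state_names)
  n <- length(nms)
  f <- function(y) {
    unname(evaluate_derivatives(0, stats::setNames(y, nms), V_cmd,
                                cell, amp, ionic)$deriv)
  }
  b <- f(numeric(n))
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- f(e) - b
  }
  list(A = A, b = b, names = nms)
}

#' Exact linear-systems solution of the artifact model
#'
#' For a linear cell (the electrical model cell, or a passive membrane) the
#' artifact equations form a linear time-invariant system within each
#' protocol segment. This oracle solves each segment exactly via matrix
#' exponentials with state continuity at step boundaries, independently of
#' the numerical integrator, and returns the same trace columns as
#' [run_artifact()].
#'
#' @param protocol a `clamp_protocol`.
#' @param cell a [cell_parameters()] object.
#' @param amp an [amplifier_settings()] object.
#' @param mc a [model_cell_params()] object, or `NULL` to use a passive
#'   membrane given by the cell's leak alone.
#' @param opts a [solver_opts()] list (output-grid options only).
#' @return A `clamp_trace`.
#' @export
linear_oracle <- function(protocol, cell, amp, mc = NULL,
                          opts = solver_opts()) {
  validate_setup(cell, amp,
                 if (is.null(mc)) passive_membrane(0) else model_cell_ionic(mc))
  ionic <- if (is.null(mc)) passive_membrane(0) else model_cell_ionic(mc)
  grids <- segment_grids(protocol, opts)
  y <- unname(initial_clamp_state(protocol$voltage_mV[1], cell, amp, ionic))
  n <- length(y)
  rows_t <- numeric(0); rows_v <- numeric(0)
  states <- matrix(numeric(0), ncol = n)

  for (k in seq_along(grids)) {
    g <- grids[[k]]
    sys <- linear_system(g$v, cell, amp, ionic)
    qr_A <- qr(sys$A)
    if (qr_A$rank < n)
      stop("singular system matrix: steady-state offset not defined for ",
           "these parameters")
    y_ss <- -solve(qr_A, sys$b)
    times <- c(g$times, g$t_end)
    dts <- diff(times)
    # uniform grids propagate with a single cached exponential
    seg <- matrix(NA_real_, length(times), n)
    seg[1, ] <- y
    cache_dt <- NA_real_; E <- NULL
    for (i in seq_along(dts)) {
      if (!isTRUE(all.equal(dts[i], cache_dt))) {
        E <- as.matrix(Matrix::expm(sys$A * dts[i]))
        cache_dt <- dts[i]
      }
      seg[i + 1, ] <- y_ss + E %*% (seg[i, ] - y_ss)
    }
    keep <- seq_len(length(times) - 1L)
    if (k == length(grids)) keep <- seq_len(length(times))
    rows_t <- c(rows_t, times[keep])
    rows_v <- c(rows_v, rep(g$v, length(keep)))
    states <- rbind(states, seg[keep, , drop = FALSE])
    y <- seg[nrow(seg), ]
  }

  sig <- clamp_signals(states, rows_v, cell, amp, ionic)
  df <- data.frame(t_ms = rows_t, V_cmd_mV = rows_v,
                   V_m_mV = states[, 1], V_p_mV = states[, 2],
                   V_est_mV = states[, 3], V_clamp_mV = states[, 4],
                   I_ion_pA = sig$I_ion, I_leak_pA = sig$I_leak,
                   I_in_pA = sig$I_in, I_out_pA = states[, 5],
                   I_post_pA = leak_subtract(states[, 5], rows_v, amp))
  new_clamp_trace(df, list(mode = "linear_oracle", cell = cell, amp = amp,
                           ionic = ionic$name, g_max = ionic$g_max,
                           scale = ionic$scale, protocol = protocol,
                           opts = opts))
}

#' Simulate the electrical model cell under the artifact model
#'
#' Convenience wrapper running the numerical integrator with the model-cell
#' branch as the ionic current (the simulated analogue of the hardware
#' validation experiment).
#'
#' @inheritParams linear_oracle
#' @return A `clamp_trace`.
#' @export
run_model_cell <- function(protocol, cell, amp, mc, opts = solver_opts()) {
  run_artifact(protocol, cell, amp, model_cell_ionic(mc), opts)
}
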