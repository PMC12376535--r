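# Synthetic-fixture generator: voltage-clamp current traces produced by the
# artifact model with known ("truth") parameters, optionally with additive
# i.i.d. Gaussian measurement noise on the observed current. The generating
# truth is written to a sidecar so recovery workflows can score themselves.

default_fixture_setup <- function() {
  cell <- cell_parameters(Rs_MOhm = 5, Cm_pF = 15, Cp_pF = 4,
                          g_leak_nS = 1, E_leak_mV = 0, V_off_err_mV = 1)
  amp <- amplifier_settings(alpha_R = 0.8, alpha_P = 0.8,
                            Rs_est_MOhm = 5, Cm_est_pF = 15, Cp_est_pF = 4,
                            g_leak_est_nS = 1)
  ionic <- set_scale(bind_density(ohara_ina(), cell$Cm), 1)
  list(cell = cell, amp = amp, ionic = ionic)
}

#' Generate synthetic voltage-clamp fixtures
#'
#' Runs the artifact model with known parameters and writes CSV traces plus
#' a sidecar JSON holding the generating truth. `kind = "trace"` writes one
#' step-protocol trace, `"iv_family"` one trace per I-V test voltage plus
#' the summarized I-V curve, `"fit_recording"` an I-V family formatted as a
#' recorded data set for the fitting workflow. Gaussian noise of SD
#' `noise_sd_pA` is added to the observed (and post-processed) current.
#'
#' @param kind `"trace"`, `"iv_family"` or `"fit_recording"`.
#' @param dir output directory (created if needed).
#' @param cell,amp,ionic generating parameters; defaults are a small
#'   NaV1.5-type cell at 80% compensation.
#' @param protocols protocol or protocol family; defaults per kind.
#' @param noise_sd_pA additive Gaussian noise SD (pA).
#' @param seed integer seed (noise reproducibility).
#' @param opts a [solver_opts()] list.
#' @return Character vector of the files written (invisibly).
#' @export
generate_fixture <- function(kind = c("trace", "iv_family", "fit_recording"),
                             dir = ".", cell = NULL, amp = NULL,
                             ionic = NULL, protocols = NULL,
                             noise_sd_pA = 0, seed = 1,
                             opts = solver_opts()) {
  kind <- match.arg(kind)
  setup <- default_fixture_setup()
  if (is.null(cell)) cell <- setup$cell
  if (is.null(amp)) amp <- setup$amp
  if (is.null(ionic)) ionic <- setup$ionic
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  truth <- list(kind = kind, seed = seed, noise_sd_pA = noise_sd_pA,
                Rs_MOhm = cell$Rs * 1e3, Cm_pF = cell$Cm, Cp_pF = cell$Cp,
                g_leak_nS = cell$g_leak, E_leak_mV = cell$E_leak,
                V_off_err_mV = cell$V_off_err,
                alpha_R = amp$alpha_R, alpha_P = amp$alpha_P,
                Rs_est_MOhm = amp$Rs_est * 1e3, Cm_est_pF = amp$Cm_est,
                g_leak_est_nS = amp$g_leak_est,
                ionic = ionic$name, g_max_nS = ionic$g_max,
                scale = ionic$scale)

  add_noise <- function(tr) {
    if (noise_sd_pA > 0) {
      eps <- stats::rnorm(nrow(tr), 0, noise_sd_pA)
      tr$I_out_pA <- tr$I_out_pA + eps
      tr$I_post_pA <- tr$I_post_pA + eps
    }
    tr
  }

  files <- character(0)
  if (kind == "trace") {
    if (is.null(protocols)) protocols <- step_protocol(-80, 50, 20, 20, 20)
    tr <- add_noise(run_artifact(protocols, cell, amp, ionic, opts))
    f <- file.path(dir, "trace.csv")
    write_trace_csv(tr, f)
    files <- c(f, paste0(f, ".json"))
  } else {
    if (is.null(protocols))
      protocols <- iv_protocol(-100, -80, 60, 20, hold_dur_ms = 100,
                               step_dur_ms = 20)
    tests <- attr(protocols, "test_voltages")
    traces <- vector("list", length(protocols))
    for (i in seq_along(protocols)) {
      traces[[i]] <- add_noise(run_artifact(protocols[[i]], cell, amp,
                                            ionic, opts))
      f <- file.path(dir, sprintf("sweep_%03d.csv", i))
      utils::write.csv(data.frame(t_ms = traces[[i]]$t_ms,
                                  I_pA = traces[[i]]$I_post_pA),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
    truth$test_voltages_mV <- tests
    if (kind == "iv_family") {
      ivf <- file.path(dir, "iv_curve.csv")
      write_iv_csv(summarize_iv(traces, tests), ivf)
      files <- c(files, ivf, paste0(ivf, ".json"))
    }
  }
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  files <- c(files, tf)
  invisible(files)
}
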