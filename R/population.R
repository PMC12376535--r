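# Population simulation recipes: Latin-hypercube and distributional sampling
# of cell/rig conditions, I-V averaging with SEM, and bias metrics of the
# averaged curve against the artifact-free reference.

#' Sampling plan for population studies
#'
#' Two sampling methods are supported. `"lhs"` stratifies conductance scale
#' (log-uniform over `conductance_scale_range`), membrane capacitance and
#' series resistance (uniform over their intervals) with one draw per
#' equal-probability bin of each marginal. `"distributional"` draws
#' `Rs ~ LogNormal`, `Cm ~ LogNormal` and `Voff ~ Normal` parameterized by
#' their natural-scale mean and SD, applies multiplicative
#' `Normal(1, estimate_error_sd)` errors to the machine estimates `Rs*` and
#' `Cm*`, and enforces the quality-control filter `Rs < qc_Rs_max` by
#' rejection-resampling until `n` cells are accepted.
#'
#' @param n number of cells (after QC for distributional plans).
#' @param method `"lhs"` or `"distributional"`.
#' @param conductance_scale_range log-uniform scale bounds.
#' @param Cm_range_pF,Rs_range_MOhm uniform intervals for the LHS method.
#' @param Rs_lognormal_MOhm,Cm_lognormal_pF natural-scale `(mean, sd)` of the
#'   lognormal condition distributions.
#' @param Voff_normal_mV `(mean, sd)` of the offset-error distribution.
#' @param estimate_error_sd SD of the multiplicative machine-estimate error
#'   (0 = perfect estimates).
#' @param qc_Rs_max_MOhm QC ceiling on the series resistance (MOhm), or
#'   `Inf` for no filter.
#' @param seed integer seed recorded in outputs.
#' @return A list of class `sampling_plan`.
#' @export
sampling_plan <- function(n, method = c("lhs", "distributional"),
                          conductance_scale_range = c(0.2, 5),
                          Cm_range_pF = c(8, 22), Rs_range_MOhm = c(4, 15),
                          Rs_lognormal_MOhm = c(2.5, 1.5),
                          Cm_lognormal_pF = c(40, 10),
                          Voff_normal_mV = c(0, 2.5),
                          estimate_error_sd = 0.05,
                          qc_Rs_max_MOhm = 4, seed = 1) {
  method <- match.arg(method)
  stopifnot(n >= 1, diff(conductance_scale_range) > 0,
            all(conductance_scale_range > 0))
  structure(list(n = as.integer(n), method = method,
                 conductance_scale_range = conductance_scale_range,
                 Cm_range_pF = Cm_range_pF, Rs_range_MOhm = Rs_range_MOhm,
                 Rs_lognormal_MOhm = Rs_lognormal_MOhm,
                 Cm_lognormal_pF = Cm_lognormal_pF,
                 Voff_normal_mV = Voff_normal_mV,
                 estimate_error_sd = estimate_error_sd,
                 qc_Rs_max_MOhm = qc_Rs_max_MOhm,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Latin hypercube sample of (conductance scale, Cm, Rs)
#'
#' One stratified draw per equal-probability bin of each marginal:
#' conductance scale log-uniform over its range, `Cm` and `Rs` uniform over
#' theirs. Deterministic given the plan's seed.
#'
#' @param plan a [sampling_plan()] with `method = "lhs"`.
#' @return Data frame with columns `scale`, `Cm_pF`, `Rs_MOhm`.
#' @export
lhs_sample <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"), plan$method == "lhs")
  set.seed(plan$seed)
  u <- lhs::randomLHS(plan$n, 3)
  r <- plan$conductance_scale_range
  data.frame(
    scale = exp(log(r[1]) + u[, 1] * (log(r[2]) - log(r[1]))),
    Cm_pF = plan$Cm_range_pF[1] + u[, 2] * diff(plan$Cm_range_pF),
    Rs_MOhm = plan$Rs_range_MOhm[1] + u[, 3] * diff(plan$Rs_range_MOhm))
}

# natural-scale (mean m, sd s) -> log-scale (meanlog, sdlog)
lognormal_pars <- function(m, s) {
  v <- s^2
  c(meanlog = log(m^2 / sqrt(v + m^2)), sdlog = sqrt(log(1 + v / m^2)))
}

#' Distributional condition sample with QC and estimate errors
#'
#' Draws `(Rs, Cm, Voff)` from the plan's lognormal/normal distributions
#' (lognormals parameterized by natural-scale mean and variance), rejects
#' draws failing `Rs < qc_Rs_max` until `n` cells are accepted, then applies
#' multiplicative `Normal(1, estimate_error_sd)` errors to the machine
#' estimates.
#'
#' @param plan a [sampling_plan()] with `method = "distributional"`.
#' @return Data frame with columns `Rs_MOhm`, `Cm_pF`, `Voff_mV`,
#'   `Rs_est_MOhm`, `Cm_est_pF`.
#' @export
sample_conditions <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"),
            plan$method == "distributional")
  set.seed(plan$seed)
  rs_p <- lognormal_pars(plan$Rs_lognormal_MOhm[1], plan$Rs_lognormal_MOhm[2])
  cm_p <- lognormal_pars(plan$Cm_lognormal_pF[1], plan$Cm_lognormal_pF[2])
  acc <- data.frame(Rs_MOhm = numeric(0), Cm_pF = numeric(0),
                    Voff_mV = numeric(0))
  tries <- 0L
  while (nrow(acc) < plan$n) {
    m <- max(plan$n, 64L)
    Rs <- stats::rlnorm(m, rs_p[1], rs_p[2])
    keep <- Rs < plan$qc_Rs_max_MOhm
    tries <- tries + m
    if (tries > 1000 * plan$n && nrow(acc) == 0)
      stop("QC acceptance probability appears to be below 1e-3")
    if (any(keep)) {
      add <- data.frame(Rs_MOhm = Rs[keep],
                        Cm_pF = stats::rlnorm(sum(keep), cm_p[1], cm_p[2]),
                        Voff_mV = stats::rnorm(sum(keep),
                                               plan$Voff_normal_mV[1],
                                               plan$Voff_normal_mV[2]))
      acc <- rbind(acc, add)
    }
  }
  acc <- acc[seq_len(plan$n), ]
  acc$Rs_est_MOhm <- acc$Rs_MOhm *
    stats::rnorm(plan$n, 1, plan$estimate_error_sd)
  acc$Cm_est_pF <- acc$Cm_pF *
    stats::rnorm(plan$n, 1, plan$estimate_error_sd)
  rownames(acc) <- NULL
  acc
}

# run one virtual cell over an I-V family and summarize as current density
simulate_iv_cell <- function(protocols, test_voltages, cell, amp, ionic,
                             opts, blank_ms = 0.05) {
  traces <- lapply(protocols, run_artifact, cell = cell, amp = amp,
                   ionic = ionic, opts = opts)
  summarize_iv(traces, test_voltages, density_Cm = cell$Cm,
               blank_ms = blank_ms)
}

#' Simulate a population of I-V experiments under the artifact model
#'
#' Runs one virtual cell per sampled condition through the full I-V protocol
#' family with the artifact model at the given compensation level, plus the
#' ideal-clamp reference curve of the baseline model, all as current
#' densities (pA/pF, divided by each cell's true Cm).
#'
#' For LHS plans the machine estimates are perfect (`Rs* = Rs`,
#' `Cm* = Cm`); pipette capacitance is taken as perfectly compensated.
#' Each cell's baseline conductance is the model's density times its sampled
#' Cm (constant current density across the population), multiplied by its
#' sampled conductance scale.
#'
#' @param plan a [sampling_plan()].
#' @param ionic a per-capacitance `ionic_model` (e.g. [gray_franz_ina()] or
#'   [ohara_ina_file()]), unbound.
#' @param alpha compensation level applied to both `alpha_R` and `alpha_P`.
#' @param protocols,test_voltages the I-V family; defaults to 20 ms steps
#'   from a 2000 ms hold at -100 mV spanning -90..50 mV in 10 mV increments.
#' @param scale_override conductance scale applied to every cell (used by
#'   the mutant study); `NULL` uses the plan's sampled scales (LHS) or 1.
#' @param opts a [solver_opts()] list.
#' @param blank_ms start of the peak-search window after step onset (ms).
#'   The population default 0.3 ms is roughly ten charging time constants
#'   `(1 - alpha) Rs Cm` for the study conditions, so residual capacitive
#'   current has decayed while the sodium peak on the activation limb
#'   (>= 0.3 ms post-step) is untouched.
#' @return List of class `iv_population` with `curves` (per-cell
#'   `iv_curve`s), `ideal` (artifact-free density curve at scale 1),
#'   `conditions` (the sampled data frame) and `plan`.
#' @export
iv_population <- function(plan, ionic, alpha = 0.8,
                          protocols = NULL, test_voltages = NULL,
                          scale_override = NULL, opts = solver_opts(),
                          blank_ms = 0.3) {
  if (is.null(protocols)) {
    protocols <- iv_protocol(-100, -90, 50, 10, hold_dur_ms = 2000,
                             step_dur_ms = 20)
    test_voltages <- attr(protocols, "test_voltages")
  }
  stopifnot(!is.null(test_voltages))
  cond <- switch(plan$method, lhs = lhs_sample(plan),
                 distributional = sample_conditions(plan))
  n <- nrow(cond)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    Cm <- cond$Cm_pF[i]; Rs <- cond$Rs_MOhm[i]
    Voff <- if (!is.null(cond$Voff_mV)) cond$Voff_mV[i] else 0
    sc <- if (!is.null(scale_override)) scale_override
          else if (!is.null(cond$scale)) cond$scale[i] else 1
    mod <- set_scale(bind_density(ionic, Cm), sc)
    cell <- cell_parameters(Rs_MOhm = Rs, Cm_pF = Cm, Cp_pF = 4,
                            V_off_err_mV = Voff)
    Rs_est <- if (!is.null(cond$Rs_est_MOhm)) cond$Rs_est_MOhm[i] else Rs
    Cm_est <- if (!is.null(cond$Cm_est_pF)) cond$Cm_est_pF[i] else Cm
    amp <- amplifier_settings(alpha_R = alpha, alpha_P = alpha,
                              Rs_est_MOhm = Rs_est, Cm_est_pF = Cm_est,
                              Cp_est_pF = cell$Cp)
    curves[[i]] <- simulate_iv_cell(protocols, test_voltages, cell, amp,
                                    mod, opts, blank_ms = blank_ms)
  }
  ideal <- ideal_iv_curve(ionic, protocols, test_voltages, opts = opts,
                          blank_ms = blank_ms)
  structure(list(curves = curves, ideal = ideal, conditions = cond,
                 plan = plan, alpha = alpha),
            class = "iv_population")
}

#' Artifact-free I-V density curve of a per-capacitance model
#'
#' @param ionic a per-capacitance `ionic_model`.
#' @param protocols,test_voltages the I-V family (defaults as in
#'   [iv_population()]).
#' @param scale conductance scale.
#' @param opts a [solver_opts()] list.
#' @return An `iv_curve` in pA/pF.
#' @export
ideal_iv_curve <- function(ionic, protocols = NULL, test_voltages = NULL,
                           scale = 1, opts = solver_opts(),
                           blank_ms = 0.3) {
  if (is.null(protocols)) {
    protocols <- iv_protocol(-100, -90, 50, 10, hold_dur_ms = 2000,
                             step_dur_ms = 20)
    test_voltages <- attr(protocols, "test_voltages")
  }
  Cm_ref <- 100
  mod <- set_scale(bind_density(ionic, Cm_ref), scale)
  traces <- lapply(protocols, run_ideal, ionic = mod, opts = opts)
  summarize_iv(traces, test_voltages, density_Cm = Cm_ref,
               blank_ms = blank_ms)
}

#' Bias of an averaged I-V curve against the artifact-free curve
#'
#' Computes the three bias statistics of the averaging studies via
#' [iv_metrics()] on both curves: the peak-voltage shift (negative =
#' left-shifted relative to the artifact-free curve), the percentage
#' reduction of the peak current magnitude, and the percentage
#' underestimation of the activation-limb maximum gradient.
#'
#' @param avg averaged (observed) `iv_curve`.
#' @param ideal artifact-free `iv_curve` on the same voltage grid.
#' @param interpolate logical; parabolic peak refinement (resolves the peak
#'   voltage between grid points).
#' @return A list of class `bias_report`: `peak_shift_mV`,
#'   `peak_reduction_pct`, `gradient_underestimation_pct`, `n_used`.
#' @export
bias_report <- function(avg, ideal, interpolate = FALSE) {
  if (!isTRUE(all.equal(avg$V_mV, ideal$V_mV)))
    stop("averaged and ideal curves must share a voltage grid")
  ma <- iv_metrics(avg, interpolate = interpolate)
  mi <- iv_metrics(ideal, interpolate = interpolate)
  structure(list(
    peak_shift_mV = ma$peak_voltage - mi$peak_voltage,
    peak_reduction_pct = 100 * (abs(mi$peak_current) - abs(ma$peak_current)) /
      abs(mi$peak_current),
    gradient_underestimation_pct = 100 * (1 - ma$max_gradient / mi$max_gradient),
    n_used = attr(avg, "n")
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Averaged-I-V bias against the artifact-free curve:\n")
  cat(sprintf("  peak voltage shift      : %+.2f mV\n", x$peak_shift_mV))
  cat(sprintf("  peak current reduction  : %.1f %%\n", x$peak_reduction_pct))
  cat(sprintf("  gradient underestimation: %.1f %%\n",
              x$gradient_underestimation_pct))
  cat(sprintf("  n (after QC)            : %d\n", x$n_used))
  invisible(x)
}

#' Write a bias report to JSON
#'
#' @param report a [bias_report()].
#' @param path output file.
#' @param seed seed recorded alongside the metrics.
#' @return `path`, invisibly.
#' @export
write_bias_report <- function(report, path, seed = NA_integer_) {
  jsonlite::write_json(c(unclass(report), list(seed = seed)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Wild-type versus conductance-only mutant study
#'
#' Emulates characterizing a mutant (or drug) that reduces the current to a
#' fraction of control with identical kinetics. Conditions are drawn per the
#' distributional plan (independently per arm by default; `paired = TRUE`
#' reuses the wild-type draws), each cell's conductance is set from its
#' sampled Cm so every cell has the same ideal-clamp current density, and
#' both arms are simulated under the artifact model and averaged. The
#' conductances are calibrated so the ideal-clamp peak densities equal
#' `wt_peak_density_pA_per_pF` and its mutant fraction.
#'
#' @param plan a distributional [sampling_plan()] (per-arm n).
#' @param ionic a per-capacitance `ionic_model`.
#' @param mutant_fraction conductance fraction of the mutant (default 1/3).
#' @param wt_peak_density_pA_per_pF target ideal-clamp peak current density
#'   magnitude of the wild type.
#' @param alpha compensation level for both settings.
#' @param paired reuse the wild-type condition draws for the mutant arm.
#' @param protocols,test_voltages the I-V family (defaults as in
#'   [iv_population()]).
#' @param opts a [solver_opts()] list.
#' @return List of class `mutant_study` with the two `iv_population`s, the
#'   averaged curves, and `apparent_shift_mV` (mutant minus wild-type
#'   averaged peak voltage, parabolic-refined) against `true_shift_mV = 0`.
#' @export
mutant_study <- function(plan, ionic, mutant_fraction = 1 / 3,
                         wt_peak_density_pA_per_pF = 1500, alpha = 0.8,
                         paired = FALSE, protocols = NULL,
                         test_voltages = NULL, opts = solver_opts(),
                         blank_ms = 0.3) {
  stopifnot(plan$method == "distributional")
  if (is.null(protocols)) {
    protocols <- iv_protocol(-100, -90, 50, 10, hold_dur_ms = 2000,
                             step_dur_ms = 20)
    test_voltages <- attr(protocols, "test_voltages")
  }
  # calibrate the baseline density so the ideal-clamp peak density matches
  base_ideal <- ideal_iv_curve(ionic, protocols, test_voltages, opts = opts,
                               blank_ms = blank_ms)
  base_peak <- abs(min(base_ideal$I_peak))
  wt_scale <- wt_peak_density_pA_per_pF / base_peak
  mut_scale <- wt_scale * mutant_fraction

  plan_wt <- plan
  plan_mut <- plan
  if (!paired) plan_mut$seed <- plan$seed + 1L

  wt <- iv_population(plan_wt, ionic, alpha = alpha, protocols = protocols,
                      test_voltages = test_voltages,
                      scale_override = wt_scale, opts = opts,
                      blank_ms = blank_ms)
  mut <- iv_population(plan_mut, ionic, alpha = alpha, protocols = protocols,
                       test_voltages = test_voltages,
                       scale_override = mut_scale, opts = opts,
                       blank_ms = blank_ms)
  avg_wt <- average_iv(wt$curves)$mean
  avg_mut <- average_iv(mut$curves)$mean
  pv_wt <- iv_metrics(avg_wt, interpolate = TRUE)$peak_voltage
  pv_mut <- iv_metrics(avg_mut, interpolate = TRUE)$peak_voltage
  ideal_wt <- ideal_iv_curve(ionic, protocols, test_voltages,
                             scale = wt_scale, opts = opts,
                             blank_ms = blank_ms)
  ideal_mut <- ideal_iv_curve(ionic, protocols, test_voltages,
                              scale = mut_scale, opts = opts,
                              blank_ms = blank_ms)
  structure(list(wt = wt, mutant = mut, avg_wt = avg_wt, avg_mut = avg_mut,
                 ideal_wt = ideal_wt, ideal_mut = ideal_mut,
                 apparent_shift_mV = pv_mut - pv_wt,
                 true_shift_mV = iv_metrics(ideal_mut, TRUE)$peak_voltage -
                   iv_metrics(ideal_wt, TRUE)$peak_voltage),
            class = "mutant_study")
}

#' @export
print.mutant_study <- function(x, ...) {
  cat("Conductance-only mutant study (identical kinetics):\n")
  cat(sprintf("  apparent peak-voltage shift (observed) : %+.2f mV\n",
              x$apparent_shift_mV))
  cat(sprintf("  true peak-voltage shift (ideal clamp)  : %+.2f mV\n",
              x$true_shift_mV))
  invisible(x)
}
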