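# Fitting the artifact model plus an ionic conductance to recorded (or
# synthetic) current traces. Positive parameters (g_max, Rs, Cm, g_leak) are
# optimized on a log scale relative to reference values, p = p0 * exp(s);
# the offset error Voff can be negative and stays on its natural scale.
# The optimizer contract is multi-restart derivative-free minimization of
# the summed squared residuals; restarts draw standard-normal initial
# s-vectors around the references.

log_pars <- c("g_max", "Rs", "Cm", "g_leak")
all_fit_pars <- c("g_max", "Rs", "Cm", "Voff", "g_leak")

#' Log-reference parameter transform
#'
#' `transform: s = ln(p / p0)`, `untransform: p = p0 * exp(s)`.
#'
#' @param p natural parameter value (> 0).
#' @param p0 reference value (> 0).
#' @param s transformed value.
#' @return The transformed (or back-transformed) value.
#' @export
fit_transform <- function(p, p0) {
  if (any(p <= 0) || any(p0 <= 0))
    stop("log-transformed parameters require positive values")
  log(p / p0)
}

#' @rdname fit_transform
#' @export
fit_untransform <- function(s, p0) p0 * exp(s)

#' Fit specification
#'
#' @param free_parameters subset of `c("g_max", "Rs", "Cm", "Voff",
#'   "g_leak")` to optimize; the rest stay at the setup values. The machine
#'   estimates `Rs*`, `Cm*`, `g_leak*` are never fitted.
#' @param g_max_ref reference (nS) for the conductance log-transform.
#' @param n_restarts independent random restarts.
#' @param seed integer seed controlling the restart initialization.
#' @param blank_ms initial blanking excluded from the fit window within each
#'   test step.
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(free_parameters = all_fit_pars, g_max_ref = 600,
                     n_restarts = 40, seed = 1, blank_ms = 0.05) {
  stopifnot(all(free_parameters %in% all_fit_pars), n_restarts >= 1,
            g_max_ref > 0)
  structure(list(free_parameters = free_parameters, g_max_ref = g_max_ref,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), blank_ms = blank_ms),
            class = "fit_spec")
}

# assemble cell/amp/ionic for a candidate natural-parameter vector
apply_fit_params <- function(p, setup) {
  cell <- setup$cell
  if (!is.null(p[["Rs"]])) cell$Rs <- p[["Rs"]] * 1e-3
  if (!is.null(p[["Cm"]])) cell$Cm <- p[["Cm"]]
  if (!is.null(p[["Voff"]])) cell$V_off_err <- p[["Voff"]]
  if (!is.null(p[["g_leak"]])) cell$g_leak <- p[["g_leak"]]
  ionic <- setup$ionic
  if (!is.null(p[["g_max"]])) ionic$g_max <- p[["g_max"]]
  list(cell = cell, amp = setup$amp, ionic = ionic)
}

# fit-window index masks per sweep (test step minus blanking)
fit_windows <- function(setup, blank_ms) {
  lapply(setup$protocols, function(proto) {
    onset <- proto$duration_ms[1]
    step_end <- onset + proto$duration_ms[2]
    grid <- trace_grid_times(proto, setup$opts)
    which(grid >= onset + blank_ms & grid <= step_end)
  })
}

trace_grid_times <- function(protocol, opts) {
  g <- segment_grids(protocol, opts)
  c(unlist(lapply(g, `[[`, "times")), g[[length(g)]]$t_end)
}

#' Sum-of-squares objective for artifact-model fitting
#'
#' Simulates the artifact model with candidate parameters over the
#' recording's protocol family and returns the summed squared residuals of
#' the post-processed current over the fit windows (each test step minus an
#' initial blanking interval).
#'
#' @param p named natural-parameter vector (any subset of `g_max`, `Rs`,
#'   `Cm`, `Voff`, `g_leak`).
#' @param data list of recorded traces (data frames with `t_ms` and
#'   `I_post_pA`), one per protocol, on the simulation output grid.
#' @param setup list with `protocols`, `cell`, `amp`, `ionic`, `opts`
#'   describing the experiment (values in `cell`/`ionic` act as defaults for
#'   parameters not in `p`).
#' @param blank_ms initial blanking of each test step.
#' @return Scalar sum of squared residuals (pA^2).
#' @export
clamp_objective <- function(p, data, setup, blank_ms = 0.05) {
  cfg <- apply_fit_params(as.list(p), setup)
  windows <- fit_windows(setup, blank_ms)
  sse <- 0
  for (i in seq_along(setup$protocols)) {
    tr <- run_artifact(setup$protocols[[i]], cfg$cell, cfg$amp, cfg$ionic,
                       setup$opts)
    if (nrow(tr) != nrow(data[[i]]))
      stop("simulated and recorded traces do not share the sample grid")
    w <- windows[[i]]
    sse <- sse + sum((tr$I_post_pA[w] - data[[i]]$I_post_pA[w])^2)
  }
  sse
}

#' Fit the artifact model to recorded current traces
#'
#' Multi-restart derivative-free minimization of [clamp_objective()] in the
#' transformed parameter space: positive parameters on the log scale around
#' their references (`g_max` around `g_max_ref`, `Rs` around `Rs*`, `Cm`
#' around `Cm*`, `g_leak` around `g_leak*`), `Voff` on its natural scale.
#' Restart initial points are standard normal in the transformed space
#' (`Voff` in mV); the best restart is returned. Deterministic given the
#' spec's seed.
#'
#' @param spec a [fit_spec()].
#' @param data list of recorded traces (one per protocol; data frames with
#'   `I_post_pA` on the simulation grid).
#' @param setup list with `protocols`, `cell`, `amp`, `ionic`, `opts`; the
#'   amplifier's `Rs_est`, `Cm_est`, `g_leak_est` provide the references and
#'   stay fixed.
#' @param control passed to [stats::optim()] (Nelder-Mead); defaults give
#'   tight convergence.
#' @return An object of class `clamp_fit`: best parameters (natural scale),
#'   best objective (after a final polish from the best restart, so it is
#'   at most the best restart objective), and per-restart records.
#' @export
fit_artifact <- function(spec, data, setup, control = list()) {
  free <- spec$free_parameters
  refs <- c(g_max = spec$g_max_ref, Rs = setup$amp$Rs_est * 1e3,
            Cm = setup$amp$Cm_est, Voff = NA_real_,
            g_leak = setup$amp$g_leak_est)
  if ("g_leak" %in% free && refs[["g_leak"]] <= 0)
    stop("g_leak reference (g_leak*) must be > 0 to log-transform g_leak")
  is_log <- free %in% log_pars

  to_natural <- function(s) {
    p <- numeric(length(free)); names(p) <- free
    p[is_log] <- fit_untransform(s[is_log], refs[free[is_log]])
    p[!is_log] <- s[!is_log]
    p
  }
  obj_s <- function(s) {
    val <- try(clamp_objective(to_natural(s), data, setup,
                               blank_ms = spec$blank_ms), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e300 else val
  }

  ctl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12), control)
  run_opt <- function(s0) {
    if (length(s0) == 1)
      stats::optim(s0, obj_s, method = "Brent", lower = s0 - 10,
                   upper = s0 + 10,
                   control = ctl[setdiff(names(ctl), "reltol")])
    else
      stats::optim(s0, obj_s, method = "Nelder-Mead", control = ctl)
  }
  set.seed(spec$seed)
  restarts <- vector("list", spec$n_restarts)
  for (r in seq_len(spec$n_restarts)) {
    s0 <- stats::rnorm(length(free))
    names(s0) <- free
    ans <- run_opt(s0)
    restarts[[r]] <- list(initial = to_natural(s0),
                          final = to_natural(ans$par),
                          objective = ans$value,
                          converged = ans$convergence == 0)
  }
  objs <- vapply(restarts, `[[`, numeric(1), "objective")
  best <- which.min(objs)
  # polish the best restart from its own solution
  s_best <- numeric(length(free)); names(s_best) <- free
  pb <- restarts[[best]]$final
  s_best[is_log] <- fit_transform(pb[is_log], refs[free[is_log]])
  s_best[!is_log] <- pb[!is_log]
  ans <- run_opt(s_best)
  best_par <- to_natural(ans$par)
  structure(list(parameters = best_par, objective = ans$value,
                 restarts = restarts,
                 converged_count = sum(vapply(restarts, `[[`, logical(1),
                                              "converged")),
                 spec = spec, setup = setup, data = data),
            class = "clamp_fit")
}

#' @export
print.clamp_fit <- function(x, ...) {
  cat(sprintf("Artifact-model fit: %d restart(s), best SSE = %.6g pA^2\n",
              length(x$restarts), x$objective))
  print(round(x$parameters, 6))
  invisible(x)
}

#' @export
coef.clamp_fit <- function(object, ...) object$parameters

#' @export
summary.clamp_fit <- function(object, ...) {
  objs <- vapply(object$restarts, `[[`, numeric(1), "objective")
  cat(sprintf("Artifact-model fit (%d free parameter(s): %s)\n",
              length(object$parameters),
              paste(names(object$parameters), collapse = ", ")))
  cat(sprintf("Restarts: %d (converged: %d); objective range %.6g .. %.6g\n",
              length(objs), object$converged_count, min(objs), max(objs)))
  cat("Best parameters:\n")
  print(round(object$parameters, 6))
  invisible(object)
}

#' @export
residuals.clamp_fit <- function(object, ...) {
  cfg <- apply_fit_params(as.list(object$parameters), object$setup)
  unlist(lapply(seq_along(object$setup$protocols), function(i) {
    tr <- run_artifact(object$setup$protocols[[i]], cfg$cell, cfg$amp,
                       cfg$ionic, object$setup$opts)
    tr$I_post_pA - object$data[[i]]$I_post_pA
  }))
}

#' @export
simulate.clamp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- apply_fit_params(as.list(object$parameters), object$setup)
  lapply(object$setup$protocols, run_artifact, cell = cfg$cell,
         amp = cfg$amp, ionic = cfg$ionic, opts = object$setup$opts)
}

#' Write a fit result to JSON
#'
#' @param fit a `clamp_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    parameters = as.list(fit$parameters),
    objective = fit$objective,
    n_restarts = length(fit$restarts),
    converged_count = fit$converged_count,
    seed = fit$spec$seed,
    restart_objectives = vapply(fit$restarts, `[[`, numeric(1), "objective")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recorded trace family from CSV
#'
#' Reads per-sweep CSVs with `t_ms` and `I_pA` (or `I_post_pA`) columns plus
#' an optional shared sidecar JSON of per-cell metadata (`Rs_est_MOhm`,
#' `Cm_est_pF`, `alpha_R`, `alpha_P`, ...).
#'
#' @param paths CSV file paths, one per sweep.
#' @param metadata_path optional sidecar JSON path.
#' @return List with `data` (list of data frames with `I_post_pA`) and
#'   `metadata` (list, possibly empty).
#' @export
read_recordings <- function(paths, metadata_path = NULL) {
  data <- lapply(paths, function(p) {
    df <- utils::read.csv(p)
    if (is.null(df$I_post_pA)) {
      if (is.null(df$I_pA)) stop("recording needs an I_pA or I_post_pA column")
      df$I_post_pA <- df$I_pA
    }
    df
  })
  md <- if (!is.null(metadata_path))
    jsonlite::read_json(metadata_path, simplifyVector = TRUE) else list()
  list(data = data, metadata = md)
}
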