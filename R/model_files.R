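# Loader for human-readable ionic-model definition files: one "key: value"
# pair per line, '#' comments, expression values in R syntax for custom
# models. The bundled files under inst/extdata/ transcribe literature
# fast-sodium formulations into the package's declared rate families.

parse_definition_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed definition line(s): ", paste(lines[bad], collapse = "; "))
  stats::setNames(lapply(kv, function(m) m[[3]]),
                  vapply(kv, function(m) m[[2]], ""))
}

num_or <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) as.numeric(cfg[[key]])
  else if (!is.null(default)) default
  else NULL
}

#' Load an ionic model from a definition file
#'
#' Builds a conforming `ionic_model` from a human-readable structured text
#' file ("key: value" lines, `#` comments). Supported `type`s:
#' \describe{
#'   \item{`passive`}{keys `g_nS`, `E_mV`.}
#'   \item{`hh_sodium`}{the parametric m^3 h family of [hh_sodium()]; keys
#'     `E_rev_mV`, `m_V_half_mV`, `m_k_mV`, `h_V_half_mV`, `h_k_mV`, the
#'     `tau_m_*`/`tau_h_*` curve parameters, and either `g_max_nS` or
#'     `g_max_nS_per_pF`.}
#'   \item{`ohara_ina`}{the fixed rate equations of [ohara_ina()]; keys
#'     `E_rev_mV` and `g_max_nS` or `g_max_nS_per_pF`.}
#'   \item{`custom`}{free-form: `states` (space-separated names), one
#'     `<state>_inf` and `<state>_tau` R expression per state, and a
#'     `current` expression; expressions may use `v`, the state names, `g`
#'     (the effective conductance) and `E` (the reversal potential). Custom
#'     models integrate through the R fallback path.}
#' }
#'
#' Models declaring `g_max_nS_per_pF` are bound to absolute conductance via
#' `Cm_pF` (or later with [bind_density()]).
#'
#' @param path definition file path.
#' @param Cm_pF optional membrane capacitance (pF) for per-capacitance
#'   parameterizations.
#' @param scale dimensionless conductance multiplier.
#' @return An `ionic_model`.
#' @export
load_ionic_model <- function(path, Cm_pF = NULL, scale = 1) {
  cfg <- parse_definition_file(path)
  type <- cfg$type
  if (is.null(type)) stop("definition file lacks a 'type' key: ", path)
  model <- switch(type,
    passive = passive_membrane(g_nS = num_or(cfg, "g_nS"),
                               E_mV = num_or(cfg, "E_mV", 0)),
    hh_sodium = load_hh_sodium(cfg, scale),
    ohara_ina = ohara_ina(
      g_max_nS = num_or(cfg, "g_max_nS", NA_real_),
      density_nS_per_pF = num_or(cfg, "g_max_nS_per_pF", NA_real_),
      E_Na_mV = num_or(cfg, "E_rev_mV", 70), scale = scale),
    custom = load_custom_model(cfg, scale),
    stop("unknown ionic model type '", type, "' in ", path)
  )
  if (!is.null(cfg$name)) model$name <- cfg$name
  if (!is.null(Cm_pF) && is.na(model$g_max)) model <- bind_density(model, Cm_pF)
  model
}

load_hh_sodium <- function(cfg, scale) {
  need <- c("E_rev_mV", "m_V_half_mV", "m_k_mV", "h_V_half_mV", "h_k_mV")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("incomplete hh_sodium definition; missing: ",
         paste(missing, collapse = ", "))
  tau5 <- function(prefix, default_base) {
    c(num_or(cfg, paste0(prefix, "_base_ms"), default_base),
      num_or(cfg, paste0(prefix, "_amp_ms"), 0),
      num_or(cfg, paste0(prefix, "_vmid_mV"), 0),
      num_or(cfg, paste0(prefix, "_k_mV"), 1),
      num_or(cfg, paste0(prefix, "_delta"), 0))
  }
  model <- hh_sodium(
    g_max_nS = num_or(cfg, "g_max_nS", NA_real_),
    E_Na_mV = num_or(cfg, "E_rev_mV"),
    V_half_m_mV = num_or(cfg, "m_V_half_mV"),
    k_m_mV = num_or(cfg, "m_k_mV"),
    V_half_h_mV = num_or(cfg, "h_V_half_mV"),
    k_h_mV = num_or(cfg, "h_k_mV"),
    tau_m = tau5("tau_m", 0.1), tau_h = tau5("tau_h", 1),
    scale = scale)
  model$density_nS_per_pF <- num_or(cfg, "g_max_nS_per_pF", NA_real_)
  model
}

load_custom_model <- function(cfg, scale) {
  if (is.null(cfg$states)) stop("custom model definition lacks 'states'")
  states <- strsplit(trimws(cfg$states), "\\s+")[[1]]
  need <- c(paste0(states, "_inf"), paste0(states, "_tau"), "current")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("incomplete custom model definition; missing rate function(s): ",
         paste(missing, collapse = ", "))
  exprs <- lapply(cfg[need], function(s) parse(text = s)[[1]])
  g_max <- num_or(cfg, "g_max_nS", NA_real_)
  E_rev <- num_or(cfg, "E_rev_mV", 0)
  model <- new_ionic_model(
    name = "custom", kind = NA_integer_, state_names = states,
    g_max = g_max, scale = scale, E_rev = E_rev, params = list(cfg = cfg),
    inf_tau = NULL, current = NULL,
    density_nS_per_pF = num_or(cfg, "g_max_nS_per_pF", NA_real_))
  eval_env <- function(Vm, state_values = NULL, g = NA_real_) {
    e <- new.env(parent = baseenv())
    assign("v", Vm, envir = e)
    assign("exp", exp, envir = e)
    assign("g", g, envir = e)
    assign("E", E_rev, envir = e)
    if (!is.null(state_values))
      for (i in seq_along(states))
        assign(states[i], state_values[, i], envir = e)
    e
  }
  model$inf_tau <- function(Vm) {
    e <- eval_env(Vm)
    inf <- vapply(states, function(s)
      rep_len(eval(exprs[[paste0(s, "_inf")]], e), length(Vm)), numeric(length(Vm)))
    tau <- vapply(states, function(s)
      rep_len(eval(exprs[[paste0(s, "_tau")]], e), length(Vm)), numeric(length(Vm)))
    list(inf = matrix(inf, ncol = length(states),
                      dimnames = list(NULL, states)),
         tau = matrix(tau, ncol = length(states),
                      dimnames = list(NULL, states)))
  }
  model$current_fn <- function(self, Vm, states_mat) {
    states_mat <- matrix(states_mat, ncol = length(states))
    e <- eval_env(Vm, states_mat, g = effective_g(self))
    as.numeric(eval(exprs$current, e))
  }
  model
}

#' Bundled literature-style fast sodium current models
#'
#' Convenience loaders for the definition files shipped under
#' `inst/extdata/`: a minimal Gray-Franz-style m^3 h fast sodium current
#' (constant activation time constant, skewed-bell inactivation time
#' constant, baseline density 20 nS/pF) and the O'Hara-style fast INa
#' (baseline density 75 nS/pF). Both are per-capacitance parameterizations;
#' pass `Cm_pF` (or use [bind_density()]) to obtain absolute conductance.
#'
#' @param Cm_pF optional membrane capacitance (pF).
#' @param scale dimensionless conductance multiplier.
#' @return An `ionic_model`.
#' @export
gray_franz_ina <- function(Cm_pF = NULL, scale = 1) {
  load_ionic_model(system.file("extdata", "gray_franz_ina.txt",
                               package = "clampsim", mustWork = TRUE),
                   Cm_pF = Cm_pF, scale = scale)
}

#' @rdname gray_franz_ina
#' @export
ohara_ina_file <- function(Cm_pF = NULL, scale = 1) {
  load_ionic_model(system.file("extdata", "ohara_ina.txt",
                               package = "clampsim", mustWork = TRUE),
                   Cm_pF = Cm_pF, scale = scale)
}
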