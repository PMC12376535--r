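# Per-step peak-current summaries (I-V curves) and their derived metrics.
# Peaks use the inward-negative convention: the peak is the signed minimum
# of the post-processed current within the test-step window, excluding a
# short initial blanking interval so the capacitive spike is not mistaken
# for the ionic peak.

new_iv_curve <- function(df, normalized = FALSE, Cm_ref = NA_real_, n = 1L) {
  stopifnot(all(diff(df$V_mV) > 0))
  structure(df, normalized = normalized, Cm_ref = Cm_ref, n = n,
            class = c("iv_curve", "data.frame"))
}

#' Construct an I-V curve from peak summaries
#'
#' @param V_mV strictly increasing test voltages (mV).
#' @param I_peak peak currents (pA, or pA/pF when density-normalized).
#' @param t_peak_ms times to peak from step onset (ms).
#' @param normalized logical: currents divided by the peak magnitude.
#' @param Cm_ref reference capacitance (pF) when density-normalized.
#' @return An object of class `iv_curve`.
#' @export
iv_curve <- function(V_mV, I_peak, t_peak_ms = NA_real_, normalized = FALSE,
                     Cm_ref = NA_real_) {
  stopifnot(length(V_mV) == length(I_peak))
  new_iv_curve(data.frame(V_mV = V_mV, I_peak = I_peak,
                          t_peak_ms = rep_len(t_peak_ms, length(V_mV))),
               normalized, Cm_ref)
}

#' @export
print.iv_curve <- function(x, ...) {
  m <- iv_metrics(x)
  unit <- if (!is.na(attr(x, "Cm_ref"))) "pA/pF" else "pA"
  if (attr(x, "normalized")) unit <- "(normalized)"
  cat(sprintf("I-V curve: %d steps, peak %.4g %s at %g mV\n",
              nrow(x), m$peak_current, unit, m$peak_voltage))
  invisible(x)
}

#' @export
plot.iv_curve <- function(x, ...) {
  unit <- if (!is.na(attr(x, "Cm_ref"))) "I (pA/pF)" else "I (pA)"
  graphics::plot(x$V_mV, x$I_peak, type = "b", xlab = "V (mV)",
                 ylab = unit, ...)
  invisible(x)
}

#' Summarize traces into an I-V curve
#'
#' For each trace, the peak is the signed minimum of `I_post` within a window
#' inside the test step (most-negative value, the inward fast-sodium
#' convention), and `t_peak` is measured from step onset.
#'
#' @param traces list of `clamp_trace`s, one per test voltage, simulated
#'   with protocols whose second segment is the test step.
#' @param test_voltages test voltages (mV), strictly increasing.
#' @param window length-2 numeric: window relative to step onset (ms);
#'   defaults to the full test step minus the blanking interval.
#' @param density_Cm optional capacitance (pF): report current density
#'   (pA/pF) by dividing by the true Cm.
#' @param blank_ms initial blanking excluded from the default window so the
#'   capacitive spike is not picked as the peak.
#' @return An `iv_curve`.
#' @export
summarize_iv <- function(traces, test_voltages, window = NULL,
                         density_Cm = NULL, blank_ms = 0.05) {
  stopifnot(length(traces) == length(test_voltages))
  peaks <- numeric(length(traces)); tpk <- numeric(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    proto <- attr(tr, "metadata")$protocol
    onset <- proto$duration_ms[1]
    step_end <- onset + proto$duration_ms[2]
    w <- if (is.null(window)) c(blank_ms, proto$duration_ms[2])
         else window
    sel <- tr$t_ms >= onset + w[1] & tr$t_ms <= onset + w[2]
    if (!any(sel)) stop("empty peak-search window for step ", i)
    j <- which(sel)[which.min(tr$I_post_pA[sel])]
    peaks[i] <- tr$I_post_pA[j]
    tpk[i] <- tr$t_ms[j] - onset
  }
  Cm_ref <- NA_real_
  if (!is.null(density_Cm)) {
    if (inherits(density_Cm, "cell_parameters")) density_Cm <- density_Cm$Cm
    peaks <- peaks / density_Cm
    Cm_ref <- density_Cm
  }
  iv_curve(test_voltages, peaks, tpk, Cm_ref = Cm_ref)
}

#' Summary metrics of an I-V curve
#'
#' `peak_current` is the most-negative entry, `peak_voltage` its voltage and
#' `max_gradient` the maximum of `|dI/dV|` over successive points on the
#' activation limb (voltages at or below the peak voltage). With
#' `interpolate = TRUE` the peak location/value are refined by the vertex of
#' the parabola through the peak point and its neighbors, resolving the peak
#' between protocol grid voltages.
#'
#' @param curve an `iv_curve` with at least 3 points.
#' @param interpolate logical; parabolic refinement of the peak.
#' @return List with `peak_current`, `peak_voltage`, `max_gradient`
#'   (pA/mV, on the same current scale as the curve).
#' @export
iv_metrics <- function(curve, interpolate = FALSE) {
  if (nrow(curve) < 3) stop("iv_metrics needs at least 3 points")
  i <- which.min(curve$I_peak)
  pv <- curve$V_mV[i]; pc <- curve$I_peak[i]
  if (interpolate && i > 1 && i < nrow(curve)) {
    x <- curve$V_mV[(i - 1):(i + 1)]; y <- curve$I_peak[(i - 1):(i + 1)]
    co <- unname(solve(cbind(1, x, x^2), y))
    if (co[3] > 0) {           # convex near an inward (negative) peak
      pv <- -co[2] / (2 * co[3])
      pc <- co[1] + co[2] * pv + co[3] * pv^2
    }
  }
  limb <- which(curve$V_mV <= curve$V_mV[i])
  grad <- if (length(limb) >= 2)
    max(abs(diff(curve$I_peak[limb]) / diff(curve$V_mV[limb])))
  else abs(diff(curve$I_peak[1:2]) / diff(curve$V_mV[1:2]))
  list(peak_current = pc, peak_voltage = pv, max_gradient = grad)
}

#' Average I-V curves pointwise
#'
#' @param curves list of `iv_curve`s on identical voltage grids.
#' @return List with `mean` (an `iv_curve`, attribute `n` = number of
#'   curves) and `sem` (an `iv_curve` whose `I_peak` holds the pointwise
#'   standard error of the mean, SD/sqrt(n)).
#' @export
average_iv <- function(curves) {
  V <- curves[[1]]$V_mV
  for (cv in curves)
    if (!isTRUE(all.equal(cv$V_mV, V)))
      stop("I-V curves must share an identical voltage grid")
  mat <- vapply(curves, function(cv) cv$I_peak, numeric(length(V)))
  mat <- matrix(mat, nrow = length(V))
  n <- length(curves)
  mu <- rowMeans(mat)
  sem <- if (n > 1) apply(mat, 1, stats::sd) / sqrt(n) else rep(0, length(V))
  tp <- rowMeans(vapply(curves, function(cv) cv$t_peak_ms,
                        numeric(length(V))))
  list(mean = new_iv_curve(data.frame(V_mV = V, I_peak = mu,
                                      t_peak_ms = tp), n = n,
                           Cm_ref = attr(curves[[1]], "Cm_ref")),
       sem = new_iv_curve(data.frame(V_mV = V, I_peak = sem,
                                     t_peak_ms = NA_real_), n = n))
}

#' Normalize an I-V curve by its peak magnitude
#'
#' @param curve an `iv_curve` with a nonzero peak.
#' @return The curve divided by `|peak|` (peak entry becomes -1 for inward
#'   currents), flagged as normalized.
#' @export
normalize_iv <- function(curve) {
  pk <- max(abs(curve$I_peak))
  if (pk == 0) stop("cannot normalize an all-zero I-V curve")
  new_iv_curve(data.frame(V_mV = curve$V_mV, I_peak = curve$I_peak / pk,
                          t_peak_ms = curve$t_peak_ms),
               normalized = TRUE, n = attr(curve, "n"))
}

#' Write and read I-V curves as CSV
#'
#' Columns exactly `V_mV, I_peak, t_peak_ms`; the units/normalization flags
#' go to a `<path>.json` sidecar.
#'
#' @param curve an `iv_curve`.
#' @param path CSV file path.
#' @return `read_iv_csv()` returns an `iv_curve`; `write_iv_csv()` returns
#'   `path` invisibly.
#' @export
write_iv_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(list(V = "mV",
                            I = if (attr(curve, "normalized")) "normalized"
                                else if (!is.na(attr(curve, "Cm_ref"))) "pA/pF"
                                else "pA",
                            t_peak = "ms",
                            Cm_ref_pF = attr(curve, "Cm_ref"),
                            n = attr(curve, "n")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  md <- if (file.exists(side)) jsonlite::read_json(side,
                                                   simplifyVector = TRUE)
        else list()
  new_iv_curve(df,
               normalized = identical(md$I, "normalized"),
               Cm_ref = if (!is.null(md$Cm_ref_pF)) md$Cm_ref_pF else NA_real_,
               n = if (!is.null(md$n)) md$n else 1L)
}
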