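# Piecewise-constant command-voltage programs. Time starts at 0; segment
# boundaries belong to the later segment (half-open intervals), so sampling
# at a boundary returns the voltage of the segment that starts there.

#' Construct a piecewise-constant voltage protocol
#'
#' @param voltages_mV segment voltages (mV).
#' @param durations_ms segment durations (ms, all > 0).
#' @param sample_interval_ms output sampling interval (ms). The default
#'   0.01 ms resolves the sub-millisecond capacitive and supercharging
#'   transients of fast sodium current work.
#' @return An object of class `clamp_protocol`: a data frame with columns
#'   `voltage_mV` and `duration_ms`, with the sample interval and total
#'   duration as attributes.
#' @export
clamp_protocol <- function(voltages_mV, durations_ms,
                           sample_interval_ms = 0.01) {
  stopifnot(length(voltages_mV) == length(durations_ms),
            all(durations_ms > 0), sample_interval_ms > 0)
  structure(
    data.frame(voltage_mV = as.numeric(voltages_mV),
               duration_ms = as.numeric(durations_ms)),
    sample_interval = sample_interval_ms,
    class = c("clamp_protocol", "data.frame"))
}

#' @export
print.clamp_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol: %d segment(s), %.4g ms total, sampled at %g ms\n",
              nrow(x), protocol_duration(x), attr(x, "sample_interval")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname clamp_protocol
#' @param protocol a `clamp_protocol`.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_ms)

#' Evaluate the command voltage of a protocol
#'
#' @param protocol a `clamp_protocol`.
#' @param t_ms times (ms) in `[0, total duration]`; boundaries belong to the
#'   later segment, and the protocol end time returns the last voltage.
#' @return Command voltages (mV).
#' @export
v_cmd <- function(protocol, t_ms) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(t_ms, starts)   # boundary -> later segment
  idx[t_ms >= ends[length(ends)]] <- nrow(protocol)
  if (any(t_ms < 0 | t_ms > ends[length(ends)]))
    stop("t_ms outside [0, total duration]")
  protocol$voltage_mV[idx]
}

#' Three-segment voltage-step protocol
#'
#' hold / test / hold, the protocol used for single large activating steps
#' (e.g. -80 mV stepping to 50 mV for 20 ms and back).
#'
#' @param hold_mV,test_mV holding and test voltages (mV).
#' @param hold_pre_ms,step_dur_ms,hold_post_ms segment durations (ms).
#' @param sample_interval_ms output sampling interval (ms).
#' @return A `clamp_protocol`.
#' @examples
#' step_protocol(-80, 50, 20, 20, 20)
#' @export
step_protocol <- function(hold_mV, test_mV, hold_pre_ms = 20,
                          step_dur_ms = 20, hold_post_ms = 20,
                          sample_interval_ms = 0.01) {
  clamp_protocol(c(hold_mV, test_mV, hold_mV),
                 c(hold_pre_ms, step_dur_ms, hold_post_ms),
                 sample_interval_ms)
}

#' Family of I-V step protocols
#'
#' One protocol per test voltage: hold, then a step to an incrementally
#' increasing voltage, optionally followed by a return to holding. The
#' standard fast-sodium family holds at -100 mV for ~2000 ms before 20 ms
#' steps spanning -90 to 50 mV in 10 mV increments.
#'
#' @param hold_mV holding voltage (mV).
#' @param v_min_mV,v_max_mV,dv_mV test-voltage range and increment (mV,
#'   `dv_mV > 0`).
#' @param hold_dur_ms,step_dur_ms,post_dur_ms segment durations (ms);
#'   `post_dur_ms = 0` omits the return segment.
#' @param sample_interval_ms output sampling interval (ms).
#' @return A list of `clamp_protocol`s with attribute `test_voltages`.
#' @examples
#' length(iv_protocol(-100, -80, 60, 20, 1980, 20))  # 8 protocols
#' @export
iv_protocol <- function(hold_mV, v_min_mV, v_max_mV, dv_mV,
                        hold_dur_ms = 2000, step_dur_ms = 20,
                        post_dur_ms = 0, sample_interval_ms = 0.01) {
  stopifnot(dv_mV > 0, v_max_mV >= v_min_mV)
  tests <- v_min_mV + dv_mV * (0:floor((v_max_mV - v_min_mV) / dv_mV))
  protocols <- lapply(tests, function(v) {
    if (post_dur_ms > 0)
      clamp_protocol(c(hold_mV, v, hold_mV),
                     c(hold_dur_ms, step_dur_ms, post_dur_ms),
                     sample_interval_ms)
    else
      clamp_protocol(c(hold_mV, v), c(hold_dur_ms, step_dur_ms),
                     sample_interval_ms)
  })
  attr(protocols, "test_voltages") <- tests
  protocols
}

#' Read and write protocols as plain text
#'
#' One `"voltage_mV duration_ms"` pair per line; `#` starts a comment.
#'
#' @param protocol a `clamp_protocol`.
#' @param path file path.
#' @param sample_interval_ms sampling interval for the parsed protocol.
#' @return `read_protocol()` returns a `clamp_protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  writeLines(sprintf("%.17g %.17g", protocol$voltage_mV,
                     protocol$duration_ms), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path, sample_interval_ms = 0.01) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  if (any(vapply(parts, length, 1L) != 2L))
    stop("protocol lines must be 'voltage_mV duration_ms' pairs")
  m <- vapply(parts, as.numeric, numeric(2))
  clamp_protocol(m[1, ], m[2, ], sample_interval_ms)
}
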