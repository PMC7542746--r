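#' Current-clamp sweep
#'
#' The atomic electrophysiology record: one membrane-voltage trace on a
#' uniform time grid together with the rectangular command-current step that
#' evoked it. Internal units are fixed: time in seconds, voltage in mV,
#' current in pA.
#'
#' @param time Time stamps, s; strictly increasing, uniform to within 1 ppm.
#' @param voltage Membrane voltage, mV; finite, same length as `time`.
#' @param step List describing the command current: `baseline` (pA),
#'   `amplitude` (pA), `onset` (s), `offset` (s).
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class `sweep`.
#' @export
sweep <- function(time, voltage, step, sampling_rate) {
  if (length(time) != length(voltage) || length(time) < 2) {
    stop("time and voltage must be equal-length vectors (n >= 2)", call. = FALSE)
  }
  if (!all(is.finite(voltage))) stop("voltage must be finite", call. = FALSE)
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if ((max(dts) - min(dts)) > 1e-6 * mean(dts)) {
    stop("time grid must be uniform to within 1 ppm", call. = FALSE)
  }
  need <- c("baseline", "amplitude", "onset", "offset")
  if (!is.list(step) || !all(need %in% names(step))) {
    stop("step must be a list with baseline, amplitude, onset, offset", call. = FALSE)
  }
  if (step$onset >= step$offset) stop("step onset must precede offset", call. = FALSE)
  structure(list(time = time, voltage = voltage, step = step,
                 sampling_rate = sampling_rate),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("Current-clamp sweep: %d samples at %g Hz (%.3f s), step %+g pA [%g, %g] s\n",
              length(x$time), x$sampling_rate,
              x$time[length(x$time)] - x$time[1],
              x$step$amplitude, x$step$onset, x$step$offset))
  invisible(x)
}

# Fast construction path for sweeps whose grid is built uniform by the
# simulator; skips the per-sample validation of sweep().
new_sweep <- function(time, voltage, step, sampling_rate) {
  structure(list(time = time, voltage = voltage, step = step,
                 sampling_rate = sampling_rate),
            class = "sweep")
}

# Reconstruct the command-current vector (pA) on the sweep's time grid.
command_current <- function(sw) {
  on <- sw$time >= sw$step$onset & sw$time < sw$step$offset
  sw$step$baseline + ifelse(on, sw$step$amplitude, 0)
}

#' Step protocol: an ordered series of sweeps with incrementing amplitudes
#'
#' Groups the sweeps of one current-step series (e.g. the 500 ms F-I series
#' from +100 to +1200 pA in 100 pA increments, or the 50 ms fine-increment
#' single-AP series). Validates that sweep amplitudes form the declared
#' arithmetic progression and that all sweeps share one sampling rate.
#'
#' @param sweeps List of [sweep()] objects in ascending amplitude order.
#' @param kind Optional label (e.g. "fi", "fine_rheobase", "hyperpolarizing").
#' @return An object of class `step_protocol` with fields `sweeps`,
#'   `start_amplitude`, `increment`, `n_steps`, `step_duration` (ms), `kind`.
#' @export
step_protocol <- function(sweeps, kind = "fi") {
  if (!length(sweeps)) stop("a step protocol needs at least one sweep", call. = FALSE)
  if (!all(vapply(sweeps, inherits, logical(1), "sweep"))) {
    stop("sweeps must all be sweep objects", call. = FALSE)
  }
  amps <- vapply(sweeps, function(s) s$step$amplitude, numeric(1))
  rates <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1) {
    stop("all sweeps in a protocol must share one sampling rate", call. = FALSE)
  }
  inc <- if (length(amps) > 1) amps[2] - amps[1] else 0
  if (length(amps) > 1) {
    if (inc == 0) stop("amplitude increment must be non-zero", call. = FALSE)
    expected <- amps[1] + inc * (seq_along(amps) - 1)
    if (max(abs(amps - expected)) > 1e-9 * max(1, abs(inc))) {
      stop("sweep amplitudes must form an arithmetic progression", call. = FALSE)
    }
  }
  dur_ms <- (sweeps[[1]]$step$offset - sweeps[[1]]$step$onset) * 1000
  structure(list(sweeps = sweeps,
                 start_amplitude = amps[1],
                 increment = inc,
                 n_steps = length(amps),
                 step_duration = dur_ms,
                 kind = kind),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Step protocol [%s]: %d sweeps, %g pA start, %g pA increment, %g ms steps\n",
              x$kind, x$n_steps, x$start_amplitude, x$increment, x$step_duration))
  invisible(x)
}

protocol_amplitudes <- function(protocol) {
  vapply(protocol$sweeps, function(s) s$step$amplitude, numeric(1))
}
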