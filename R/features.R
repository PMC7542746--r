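#' Detect action potentials by fixed-level threshold crossing
#'
#' Spike times are the upward crossings of `detect_level`; crossings closer
#' than `min_interval` to the previously accepted spike are discarded
#' (lockout). A fixed -20 mV level with a 1 ms lockout is simple, auditable
#' and adequate for the large somatic spikes of Purkinje cells.
#'
#' @param sweep A [sweep()].
#' @param detect_level Crossing level, mV.
#' @param min_interval Lockout, ms.
#' @return Spike times, s (possibly empty).
#' @export
detect_spikes <- function(sweep, detect_level = -20, min_interval = 1) {
  stopifnot(inherits(sweep, "sweep"))
  v <- sweep$voltage
  up <- upward_crossings_cpp(v, detect_level)
  if (!length(up)) return(numeric(0))
  times <- sweep$time[up]
  lock <- min_interval / 1000
  keep <- times[1]
  if (length(times) > 1) {
    for (tt in times[-1]) {
      if (tt - keep[length(keep)] >= lock) keep <- c(keep, tt)
    }
  }
  keep
}

#' Mean firing rate over the step window
#'
#' Counts spikes with `step_onset <= t < step_offset` and divides by the
#' window length.
#'
#' @param spike_times Spike times, s.
#' @param step_onset,step_offset Window bounds, s.
#' @return Firing rate, Hz.
#' @export
mean_firing_rate <- function(spike_times, step_onset, step_offset) {
  if (step_offset <= step_onset) {
    stop("step window must have positive length", call. = FALSE)
  }
  sum(spike_times >= step_onset & spike_times < step_offset) /
    (step_offset - step_onset)
}

# Detected spike times per sweep, clipped to each sweep's step window
# (shared by the F-I curve and the firing-pattern classifier so the trace is
# scanned once).
protocol_window_spikes <- function(protocol, detect_level, min_interval) {
  lapply(protocol$sweeps, function(sw) {
    st <- detect_spikes(sw, detect_level, min_interval)
    st[st >= sw$step$onset & st < sw$step$offset]
  })
}

fi_curve_core <- function(protocol, win_spikes) {
  rates <- vapply(seq_along(protocol$sweeps), function(k) {
    sw <- protocol$sweeps[[k]]
    length(win_spikes[[k]]) / (sw$step$offset - sw$step$onset)
  }, numeric(1))
  structure(list(currents = protocol_amplitudes(protocol), rates = rates),
            class = "fi_curve")
}

classify_core <- function(protocol, win_spikes, min_spikes, cv_limit,
                          gap_factor, tail_fraction) {
  counts <- lengths(win_spikes)
  if (sum(counts > 0) < 3) {
    warning("fewer than 3 suprathreshold sweeps; labelling non_regular",
            call. = FALSE)
    return("non_regular")
  }
  k <- which(counts >= min_spikes)[1]
  if (is.na(k)) {
    warning(sprintf("no sweep reaches %d spikes; labelling non_regular", min_spikes),
            call. = FALSE)
    return("non_regular")
  }
  st <- win_spikes[[k]]
  sw <- protocol$sweeps[[k]]
  isi <- diff(st)
  cv <- stats::sd(isi) / mean(isi)
  med <- stats::median(isi)
  tail_start <- sw$step$offset - tail_fraction * (sw$step$offset - sw$step$onset)
  persists <- any(st >= tail_start)
  if (cv <= cv_limit && max(isi) <= gap_factor * med && persists) "regular"
  else "non_regular"
}

#' F-I curve from a step protocol
#'
#' One (current, mean firing rate) point per sweep, in protocol order; for
#' the standard depolarizing series (+100 to +1200 pA in 100 pA increments)
#' this yields exactly 12 points.
#'
#' @param protocol A [step_protocol()].
#' @param detect_level,min_interval Spike-detection parameters.
#' @return An object of class `fi_curve` with `currents` (pA) and `rates` (Hz).
#' @export
compute_fi_curve <- function(protocol, detect_level = -20, min_interval = 1) {
  stopifnot(inherits(protocol, "step_protocol"))
  fi_curve_core(protocol,
                protocol_window_spikes(protocol, detect_level, min_interval))
}

#' @export
print.fi_curve <- function(x, ...) {
  cat("F-I curve:\n")
  print(data.frame(current_pA = x$currents, rate_Hz = x$rates), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fi_curve <- function(x, ...) {
  plot(x$currents, x$rates, type = "b", pch = 16,
       xlab = "Injected current (pA)", ylab = "Mean firing rate (Hz)", ...)
  invisible(x)
}

#' Rheobase from an ascending step series
#'
#' The amplitude of the first sweep (ascending order) with at least one
#' detected spike inside the step window; `NA` when no sweep spikes
#' (absence is a value, not an error).
#'
#' @inheritParams compute_fi_curve
#' @return Rheobase, pA, or `NA_real_`.
#' @export
find_rheobase <- function(protocol, detect_level = -20, min_interval = 1) {
  d <- find_rheobase_detail(protocol, detect_level, min_interval)
  d$rheobase
}

# Rheobase plus the sweep and first spike that defined it (internal; the AP
# waveform analysis reuses them).
find_rheobase_detail <- function(protocol, detect_level = -20, min_interval = 1) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (protocol$n_steps > 1 && protocol$increment < 0) {
    stop("rheobase requires an ascending step series", call. = FALSE)
  }
  for (k in seq_along(protocol$sweeps)) {
    sw <- protocol$sweeps[[k]]
    st <- detect_spikes(sw, detect_level, min_interval)
    st <- st[st >= sw$step$onset & st < sw$step$offset]
    if (length(st)) {
      return(list(rheobase = sw$step$amplitude, sweep_index = k,
                  sweep = sw, first_spike = st[1]))
    }
  }
  list(rheobase = NA_real_, sweep_index = NA_integer_, sweep = NULL,
       first_spike = NA_real_)
}

#' Action-potential threshold by rate-of-rise criterion
#'
#' Searching backward from the spike peak, the threshold is the voltage at
#' the last sample where the centred-difference dV/dt rises through
#' `dvdt_criterion` (default 20 mV/ms, a standard operational definition of
#' spike initiation).
#'
#' @param sweep A [sweep()].
#' @param spike_time A spike time from [detect_spikes()] on this sweep, s.
#' @param dvdt_criterion Rate-of-rise criterion, mV/ms.
#' @param search_window Backward search span from the peak, ms.
#' @param smooth Optional moving-average half-width (samples) applied to the
#'   voltage before differentiation; 0 = raw trace.
#' @return An object of class `ap_features` with `threshold` (mV),
#'   `threshold_time`, `peak_time` (s), `peak_voltage` (mV); `amplitude` and
#'   `ahp_amplitude` are filled by [ap_amplitude()] / [ahp_amplitude()].
#' @export
ap_threshold <- function(sweep, spike_time, dvdt_criterion = 20,
                         search_window = 5, smooth = 0) {
  stopifnot(inherits(sweep, "sweep"))
  dt_s <- 1 / sweep$sampling_rate
  v <- sweep$voltage
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    v <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    v[is.na(v)] <- sweep$voltage[is.na(v)]
  }
  i_spk <- which.min(abs(sweep$time - spike_time))
  i_hi <- min(length(v), i_spk + as.integer(round(0.003 / dt_s)))
  i_peak <- (i_spk:i_hi)[which.max(v[i_spk:i_hi])]
  i_lo <- max(2L, i_peak - as.integer(round(search_window / 1000 / dt_s)))
  if (i_peak - i_lo < 2L) {
    stop("search window too small for threshold detection", call. = FALSE)
  }
  n <- length(v)
  idx <- i_lo:min(i_peak, n - 1L)
  dvdt <- (v[idx + 1L] - v[idx - 1L]) / (2 * dt_s * 1000)  # mV/ms
  above <- dvdt >= dvdt_criterion
  rising <- which(above[-1] & !above[-length(above)]) + 1L
  if (!length(rising)) {
    if (!any(above)) {
      stop(sprintf("dV/dt never reaches %g mV/ms within %g ms before the peak; no spike-like upstroke at t = %.4f s",
                   dvdt_criterion, search_window, spike_time), call. = FALSE)
    }
    # criterion already exceeded at the window start: take the first sample
    cross <- idx[which(above)[1]]
  } else {
    cross <- idx[rising[length(rising)]]
  }
  structure(list(threshold = sweep$voltage[cross],
                 threshold_time = sweep$time[cross],
                 peak_time = sweep$time[i_peak],
                 peak_voltage = sweep$voltage[i_peak],
                 amplitude = NA_real_,
                 ahp_amplitude = NA_real_),
            class = "ap_features")
}

#' Action-potential amplitude (peak minus threshold)
#'
#' The amplitude reference is the measured threshold, not the pre-step
#' baseline. Flat-topped (possibly clipped) spikes use the maximum sample
#' with a warning.
#'
#' @param sweep A [sweep()].
#' @param features An [ap_threshold()] result for a spike on this sweep.
#' @return Amplitude, mV.
#' @export
ap_amplitude <- function(sweep, features) {
  stopifnot(inherits(sweep, "sweep"), inherits(features, "ap_features"))
  if (is.na(features$threshold)) stop("threshold must be measured first", call. = FALSE)
  after <- sweep$time >= features$threshold_time &
    sweep$time <= features$peak_time + 0.001
  if (!any(after) || max(sweep$voltage[after]) <= features$threshold) {
    stop("no spike peak found after the threshold time", call. = FALSE)
  }
  vpk <- max(sweep$voltage[after])
  n_at_peak <- sum(sweep$voltage[after] >= vpk - 1e-9)
  if (n_at_peak > 2) {
    warning(sprintf("flat-topped spike (%d samples at the maximum); amplitude uses the maximum sample (possible clipping)",
                    n_at_peak), call. = FALSE)
  }
  vpk - features$threshold
}

#' Afterhyperpolarization amplitude
#'
#' Threshold voltage minus the post-spike voltage minimum within `window` ms
#' after the spike peak. The window is capped at the command-step offset
#' when the spike sits inside the step: the AHP is defined under sustained
#' drive, and letting the window run into the post-step repolarization
#' would conflate stimulus-off relaxation with the afterhyperpolarization
#' (biasing late-latency, near-rheobase spikes). A minimum above threshold
#' (no hyperpolarization) is floored at 0 with a warning; a window extending
#' past the record end is truncated with a warning.
#'
#' @param sweep A [sweep()].
#' @param features An [ap_threshold()] result.
#' @param window Post-peak search window, ms.
#' @return AHP amplitude, mV (>= 0).
#' @export
ahp_amplitude <- function(sweep, features, window = 10) {
  stopifnot(inherits(sweep, "sweep"), inherits(features, "ap_features"))
  if (is.na(features$threshold)) stop("threshold must be measured first", call. = FALSE)
  t_end <- features$peak_time + window / 1000
  if (features$peak_time < sweep$step$offset && t_end > sweep$step$offset) {
    t_end <- sweep$step$offset
  }
  rec_end <- sweep$time[length(sweep$time)]
  if (t_end > rec_end) {
    warning(sprintf("AHP window truncated at the record end (%.1f of %g ms available)",
                    (rec_end - features$peak_time) * 1000, window), call. = FALSE)
    t_end <- rec_end
  }
  inwin <- sweep$time > features$peak_time & sweep$time <= t_end
  if (!any(inwin)) stop("no samples after the spike peak", call. = FALSE)
  vmin <- min(sweep$voltage[inwin])
  ahp <- features$threshold - vmin
  if (ahp < 0) {
    warning("post-spike minimum above threshold; AHP amplitude floored at 0",
            call. = FALSE)
    ahp <- 0
  }
  ahp
}

#' Input resistance from a hyperpolarizing step
#'
#' Ohmic estimate: (steady-state voltage - baseline voltage) / step
#' amplitude. Steady state is averaged over the final `steady_fraction` of
#' the step, the baseline over `baseline_window` ms immediately before
#' onset.
#'
#' @param sweep A [sweep()] with a negative step amplitude and no spikes.
#' @param steady_fraction Final fraction of the step averaged as steady state.
#' @param baseline_window Pre-onset baseline window, ms.
#' @param detect_level Spike-detection level used for the no-spike check, mV.
#' @return Input resistance, MOhm.
#' @export
input_resistance <- function(sweep, steady_fraction = 0.2,
                             baseline_window = 50, detect_level = -20) {
  stopifnot(inherits(sweep, "sweep"))
  amp <- sweep$step$amplitude
  if (amp == 0) stop("step amplitude must be non-zero", call. = FALSE)
  if (amp > 0) stop("input resistance requires a hyperpolarizing (negative) step",
                    call. = FALSE)
  if (length(detect_spikes(sweep, detect_level))) {
    stop("spikes present in the sweep; input resistance estimate invalid",
         call. = FALSE)
  }
  on <- sweep$step$onset
  off <- sweep$step$offset
  base_idx <- sweep$time >= on - baseline_window / 1000 & sweep$time < on
  steady_idx <- sweep$time >= off - steady_fraction * (off - on) &
    sweep$time < off
  if (!any(base_idx) || !any(steady_idx)) {
    stop("baseline or steady-state window empty", call. = FALSE)
  }
  dv <- mean(sweep$voltage[steady_idx]) - mean(sweep$voltage[base_idx])
  r <- dv / amp * 1000  # mV/pA = GOhm; report MOhm
  if (r <= 0) stop("non-positive resistance estimate; check the sweep", call. = FALSE)
  r
}

#' Classify the firing pattern of a cell as regular or non-regular
#'
#' Applied at the first sweep with at least `min_spikes` spikes in the step
#' window: the cell is regular iff the ISI coefficient of variation is at
#' most `cv_limit`, no inter-spike gap exceeds `gap_factor` times the median
#' ISI, and firing persists into the final `tail_fraction` of the step (no
#' depolarization block). With fewer than 3 suprathreshold sweeps, or no
#' sweep reaching `min_spikes` spikes, the label is non-regular with a
#' warning.
#'
#' @param protocol The F-I [step_protocol()].
#' @param detect_level,min_interval Spike-detection parameters.
#' @param min_spikes Minimum spikes for the evaluation sweep.
#' @param cv_limit ISI coefficient-of-variation limit.
#' @param gap_factor Maximum gap as a multiple of the median ISI.
#' @param tail_fraction Final step fraction in which firing must persist.
#' @return "regular" or "non_regular".
#' @export
classify_firing_pattern <- function(protocol, detect_level = -20,
                                    min_interval = 1, min_spikes = 5,
                                    cv_limit = 0.5, gap_factor = 3,
                                    tail_fraction = 0.2) {
  stopifnot(inherits(protocol, "step_protocol"))
  classify_core(protocol,
                protocol_window_spikes(protocol, detect_level, min_interval),
                min_spikes, cv_limit, gap_factor, tail_fraction)
}

#' Extract every per-cell feature from a cell's sweep sets
#'
#' Composes the individual operations: F-I curve and firing-pattern label
#' from the depolarizing series, rheobase and single-AP waveform features
#' (threshold, amplitude, AHP) from the fine-increment series, input
#' resistance from the hyperpolarizing sweep. Missing protocols leave the
#' corresponding fields absent (`NULL`/`NA`); per-feature failures are
#' caught, logged with the cell id, and leave `NA`.
#'
#' @param cell A list with `cell_id`, `group` and `protocols` (named list
#'   with any of `fi` (step_protocol), `fine` (step_protocol), `hyper`
#'   (sweep)) -- the layout produced by [generate_cell_population()] and
#'   [read_sweeps()].
#' @param config A [feature_config()].
#' @return An object of class `protocol_result`.
#' @export
extract_cell_features <- function(cell, config = feature_config()) {
  pr <- cell$protocols
  if (is.null(pr) || !length(pr)) stop("cell has no protocols", call. = FALSE)
  logs <- character(0)
  note <- function(msg) logs <<- c(logs, sprintf("[%s] %s", cell$cell_id, msg))
  grab <- function(expr, what) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        note(sprintf("%s failed: %s", what, conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        note(sprintf("%s: %s", what, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  fi <- pattern <- NULL
  if (!is.null(pr$fi)) {
    ws <- grab(protocol_window_spikes(pr$fi, config$detect_level,
                                      config$min_interval), "spike detection")
    if (!is.null(ws)) {
      fi <- grab(fi_curve_core(pr$fi, ws), "F-I curve")
      pattern <- grab(classify_core(pr$fi, ws, config$min_spikes,
                                    config$cv_limit, config$gap_factor,
                                    config$tail_fraction),
                      "firing-pattern classification")
    }
  }
  rheo <- NA_real_
  ap <- NULL
  if (!is.null(pr$fine)) {
    det <- grab(find_rheobase_detail(pr$fine, config$detect_level,
                                     config$min_interval), "rheobase")
    if (!is.null(det) && !is.na(det$rheobase)) {
      rheo <- det$rheobase
      ap <- grab(ap_threshold(det$sweep, det$first_spike,
                              config$dvdt_criterion, config$search_window,
                              config$smooth), "AP threshold")
      if (!is.null(ap)) {
        amp <- grab(ap_amplitude(det$sweep, ap), "AP amplitude")
        if (!is.null(amp)) ap$amplitude <- amp
        ahp <- grab(ahp_amplitude(det$sweep, ap, config$ahp_window), "AHP amplitude")
        if (!is.null(ahp)) ap$ahp_amplitude <- ahp
      }
    } else if (!is.null(det)) {
      note("no spiking sweep in the fine protocol; rheobase absent")
    }
  }
  rin <- NA_real_
  if (!is.null(pr$hyper)) {
    r <- grab(input_resistance(pr$hyper, config$steady_fraction,
                               config$baseline_window, config$detect_level),
              "input resistance")
    if (!is.null(r)) rin <- r
  }
  structure(list(fi_curve = fi,
                 rheobase = rheo,
                 ap = ap,
                 input_resistance = rin,
                 pattern = if (is.null(pattern)) "non_regular" else pattern,
                 cell_id = cell$cell_id,
                 group_label = cell$group,
                 log = logs),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Cell %s (%s): pattern = %s\n", x$cell_id, x$group_label, x$pattern))
  cat(sprintf("  rheobase = %s pA, R_in = %s MOhm\n",
              format(x$rheobase, digits = 4), format(x$input_resistance, digits = 4)))
  if (!is.null(x$ap)) {
    cat(sprintf("  AP: threshold %.2f mV, amplitude %.2f mV, AHP %.2f mV\n",
                x$ap$threshold, x$ap$amplitude, x$ap$ahp_amplitude))
  }
  if (!is.null(x$fi_curve)) {
    cat(sprintf("  F-I: %d steps, max rate %.1f Hz\n",
                length(x$fi_curve$currents), max(x$fi_curve$rates)))
  }
  if (length(x$log)) cat("  notes:", length(x$log), "(see $log)\n")
  invisible(x)
}

#' Feature-extraction configuration
#'
#' Collects every tunable knob of the extraction stage with its documented
#' default. Unknown knobs are rejected.
#'
#' @param detect_level Spike-detection crossing level, mV.
#' @param min_interval Detection lockout, ms.
#' @param dvdt_criterion AP-threshold rate-of-rise criterion, mV/ms.
#' @param search_window Backward threshold search span, ms.
#' @param smooth Moving-average half-width for differentiation (samples).
#' @param ahp_window Post-peak AHP window, ms.
#' @param steady_fraction Steady-state fraction for input resistance.
#' @param baseline_window Pre-onset baseline, ms.
#' @param min_spikes,cv_limit,gap_factor,tail_fraction Regular-spiking rule.
#' @return A classed list of knobs.
#' @export
feature_config <- function(detect_level = -20, min_interval = 1,
                           dvdt_criterion = 20, search_window = 5, smooth = 0,
                           ahp_window = 10, steady_fraction = 0.2,
                           baseline_window = 50, min_spikes = 5,
                           cv_limit = 0.5, gap_factor = 3,
                           tail_fraction = 0.2) {
  structure(list(detect_level = detect_level, min_interval = min_interval,
                 dvdt_criterion = dvdt_criterion, search_window = search_window,
                 smooth = smooth, ahp_window = ahp_window,
                 steady_fraction = steady_fraction,
                 baseline_window = baseline_window, min_spikes = min_spikes,
                 cv_limit = cv_limit, gap_factor = gap_factor,
                 tail_fraction = tail_fraction),
            class = "feature_config")
}

#' Extract features for every cell of a dataset
#'
#' @param cells A `cell_population` from [generate_cell_population()], or a
#'   plain list of cell records (see [extract_cell_features()]).
#' @param config A [feature_config()].
#' @return List of `protocol_result`, ordered by `cell_id`.
#' @export
extract_features <- function(cells, config = feature_config()) {
  if (inherits(cells, "cell_population")) cells <- cells$cells
  if (!length(cells)) return(list())
  res <- lapply(cells, extract_cell_features, config = config)
  res[order(vapply(res, `[[`, character(1), "cell_id"))]
}

#' Per-cell feature table
#'
#' One row per cell with the column dictionary: `cell_id`, `group`,
#' `pattern` (regular/non_regular), `rheobase` (pA), `ap_threshold` (mV),
#' `ap_amplitude` (mV), `ahp_amplitude` (mV), `input_resistance` (MOhm).
#'
#' @param results List of `protocol_result` objects.
#' @return Data frame, one row per cell.
#' @export
feature_table <- function(results) {
  if (inherits(results, "protocol_result")) results <- list(results)
  getf <- function(r, what) {
    if (is.null(r$ap)) return(NA_real_)
    as.numeric(r$ap[[what]])
  }
  data.frame(
    cell_id = vapply(results, `[[`, character(1), "cell_id"),
    group = vapply(results, `[[`, character(1), "group_label"),
    pattern = vapply(results, `[[`, character(1), "pattern"),
    rheobase = vapply(results, function(r) as.numeric(r$rheobase), numeric(1)),
    ap_threshold = vapply(results, getf, numeric(1), what = "threshold"),
    ap_amplitude = vapply(results, getf, numeric(1), what = "amplitude"),
    ahp_amplitude = vapply(results, getf, numeric(1), what = "ahp_amplitude"),
    input_resistance = vapply(results, function(r) as.numeric(r$input_resistance),
                              numeric(1)),
    stringsAsFactors = FALSE)
}
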