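#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Constructs and validates the parameter set of the AdEx membrane model used
#' by the synthetic-data generator. Defaults describe a tonically firing
#' Purkinje-cell-like neuron: ~100 MOhm input resistance, 15 ms membrane time
#' constant, rheobase in the low hundreds of pA so the standard depolarizing
#' step series (+100 to +1200 pA) spans sub- to strongly supra-threshold
#' drive.
#'
#' @param membrane_capacitance Membrane capacitance, pF.
#' @param leak_conductance Leak conductance, nS (input resistance = 1000 /
#'   leak_conductance MOhm).
#' @param leak_reversal Leak reversal (resting) potential, mV.
#' @param spike_slope_factor Sharpness of the exponential spike-initiation
#'   term, mV. Must be > 0 for simulation.
#' @param soft_threshold Exponential-term threshold, mV; spikes self-ignite
#'   slightly above this voltage.
#' @param reset_potential Post-spike reset voltage, mV.
#' @param spike_cutoff Voltage at which a spike is registered and the membrane
#'   reset, mV.
#' @param refractory Absolute refractory period, ms.
#' @param adaptation_coupling Subthreshold adaptation conductance a, nS.
#' @param adaptation_increment Spike-triggered adaptation increment b, pA.
#' @param adaptation_tau Adaptation time constant, ms.
#' @param noise_sd Stationary SD of the stochastic membrane fluctuation, mV
#'   (0 for deterministic traces).
#' @param seed Optional integer seed; when set, every simulation from these
#'   parameters is reproducible in isolation.
#' @return An object of class `neuron_params` (a validated named list).
#' @examples
#' p <- neuron_params()
#' analytic_rheobase(neuron_params(adaptation_coupling = 0))
#' @export
neuron_params <- function(membrane_capacitance = 150,
                          leak_conductance = 10,
                          leak_reversal = -65,
                          spike_slope_factor = 2,
                          soft_threshold = -50,
                          reset_potential = -58,
                          spike_cutoff = 20,
                          refractory = 2,
                          adaptation_coupling = 2,
                          adaptation_increment = 60,
                          adaptation_tau = 120,
                          noise_sd = 0,
                          seed = NULL) {
  p <- list(membrane_capacitance = membrane_capacitance,
            leak_conductance = leak_conductance,
            leak_reversal = leak_reversal,
            spike_slope_factor = spike_slope_factor,
            soft_threshold = soft_threshold,
            reset_potential = reset_potential,
            spike_cutoff = spike_cutoff,
            refractory = refractory,
            adaptation_coupling = adaptation_coupling,
            adaptation_increment = adaptation_increment,
            adaptation_tau = adaptation_tau,
            noise_sd = noise_sd,
            seed = seed)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all neuron parameters must be finite numeric scalars", call. = FALSE)
  }
  if (p$membrane_capacitance <= 0) stop("membrane_capacitance must be > 0", call. = FALSE)
  if (p$leak_conductance <= 0) stop("leak_conductance must be > 0", call. = FALSE)
  if (p$spike_slope_factor <= 0) stop("spike_slope_factor must be > 0", call. = FALSE)
  if (p$adaptation_tau <= 0) stop("adaptation_tau must be > 0", call. = FALSE)
  if (p$reset_potential >= p$spike_cutoff) {
    stop("reset_potential must be below spike_cutoff", call. = FALSE)
  }
  if (p$refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(p$seed) && (!is.numeric(p$seed) || length(p$seed) != 1)) {
    stop("seed must be a single integer or NULL", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("AdEx neuron parameters\n")
  cat(sprintf("  C = %g pF, g_L = %g nS (R_in = %.1f MOhm), E_L = %g mV\n",
              x$membrane_capacitance, x$leak_conductance,
              1000 / x$leak_conductance, x$leak_reversal))
  cat(sprintf("  V_T = %g mV, Delta_T = %g mV, reset = %g mV, cutoff = %g mV, refractory = %g ms\n",
              x$soft_threshold, x$spike_slope_factor, x$reset_potential,
              x$spike_cutoff, x$refractory))
  cat(sprintf("  adaptation: a = %g nS, b = %g pA, tau_w = %g ms; noise_sd = %g mV\n",
              x$adaptation_coupling, x$adaptation_increment, x$adaptation_tau,
              x$noise_sd))
  invisible(x)
}

#' Optokinetic stimulation / eye-trace simulation parameters
#'
#' Parameters of the synthetic video-oculography record: a sinusoidal screen
#' (drum) stimulus and an eye trace that follows it with a gain below one,
#' plus slow drift, measurement noise and Poisson-timed quick phases
#' (saccade-like resetting ramps).
#'
#' The default stimulus is a 0.5 Hz oscillation with 5 degree peak amplitude
#' (10 degrees peak-to-peak); the amplitude convention is an explicit knob
#' because published protocol descriptions are often ambiguous between peak
#' and peak-to-peak.
#'
#' @param stimulus_frequency Screen oscillation frequency, Hz.
#' @param stimulus_amplitude Screen peak amplitude, degrees.
#' @param true_gain Eye/screen amplitude ratio to generate (dimensionless).
#' @param true_phase Eye phase relative to the screen, radians (positive =
#'   eye leads).
#' @param drift_slope Slow linear drift of eye position, degrees/s.
#' @param noise_sd Gaussian measurement noise SD, degrees.
#' @param saccade_rate Quick-phase rate, events/s (Poisson).
#' @param saccade_amplitude Typical quick-phase size, degrees.
#' @param duration Record duration, s.
#' @param sampling_rate Sampling rate, Hz; must exceed twice the stimulus
#'   frequency.
#' @param seed Optional integer seed.
#' @return An object of class `eye_sim_params`.
#' @export
eye_sim_params <- function(stimulus_frequency = 0.5,
                           stimulus_amplitude = 5,
                           true_gain = 0.7,
                           true_phase = 0,
                           drift_slope = 0.05,
                           noise_sd = 0.3,
                           saccade_rate = 0.1,
                           saccade_amplitude = 2,
                           duration = 50,
                           sampling_rate = 200,
                           seed = NULL) {
  p <- list(stimulus_frequency = stimulus_frequency,
            stimulus_amplitude = stimulus_amplitude,
            true_gain = true_gain,
            true_phase = true_phase,
            drift_slope = drift_slope,
            noise_sd = noise_sd,
            saccade_rate = saccade_rate,
            saccade_amplitude = saccade_amplitude,
            duration = duration,
            sampling_rate = sampling_rate,
            seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all eye-simulation parameters must be finite numeric scalars", call. = FALSE)
  }
  if (p$true_gain < 0) stop("true_gain must be >= 0", call. = FALSE)
  if (p$stimulus_frequency <= 0) stop("stimulus_frequency must be > 0", call. = FALSE)
  if (p$sampling_rate <= 2 * p$stimulus_frequency) {
    stop("sampling_rate must exceed twice the stimulus frequency (Nyquist)", call. = FALSE)
  }
  if (p$duration <= 2 / p$stimulus_frequency) {
    stop("duration must cover more than two stimulus cycles", call. = FALSE)
  }
  if (p$noise_sd < 0 || p$saccade_rate < 0) {
    stop("noise_sd and saccade_rate must be >= 0", call. = FALSE)
  }
  structure(p, class = "eye_sim_params")
}

# Run code under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. With seed = NULL the current stream is used as-is.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
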