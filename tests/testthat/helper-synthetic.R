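# Shared fixture builders; everything is generated in code at test time.

# Random non-adapting, noiseless AdEx parameter set in the physiological
# ranges used throughout the oracle tests (rheobase well-defined, 500 ms
# steps long enough to approach the sustained threshold).
rand_nonadapting <- function() {
  g <- runif(1, 10, 20)
  el <- runif(1, -75, -62)
  vt <- runif(1, -55, -45)
  dT <- runif(1, 1, 2.5)
  cm <- runif(1, 80, 160)
  if (vt - el - dT < 5) vt <- el + dT + 5 + runif(1, 0, 8)
  neuron_params(membrane_capacitance = cm, leak_conductance = g,
                leak_reversal = el, soft_threshold = vt,
                spike_slope_factor = dT, reset_potential = el + 5,
                adaptation_coupling = 0, adaptation_increment = 0)
}

# Artificial sweep with stylized triangular spikes at the given times (s):
# 0.5 ms rise from baseline to +10 mV, 0.5 ms fall to -60 mV, then baseline.
# Used to unit-test detection and classification with exactly known truth.
make_spike_sweep <- function(spike_times, duration = 0.7, fs = 20000,
                             amplitude = 300, onset = 0.1, offset = 0.6,
                             baseline = -65) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  v <- rep(baseline, n)
  rise <- round(0.0005 * fs)
  for (ts in spike_times) {
    i0 <- round(ts * fs) + 1
    up <- i0:(i0 + rise - 1)
    dn <- (i0 + rise):(i0 + 2 * rise - 1)
    v[up] <- baseline + (10 - baseline) * seq_along(up) / rise
    v[dn] <- 10 + (-60 - 10) * seq_along(dn) / rise
    v[i0 + 2 * rise] <- baseline
  }
  sweep(time = t, voltage = v,
        step = list(baseline = 0, amplitude = amplitude,
                    onset = onset, offset = offset),
        sampling_rate = fs)
}

# Gaussian random-intercept F-I long table with no group effect (null) or a
# rate deficit in the learned group (alternative).
make_fi_table <- function(n_per_group = 30, cell_sd = 15, res_sd = 8,
                          learned_deficit = 0) {
  steps <- seq(100, 1200, by = 100)
  cells <- sprintf("c%03d", seq_len(2 * n_per_group))
  grp <- rep(c("control", "learned"), each = n_per_group)
  d <- expand.grid(cell_id = cells, current_step = steps,
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$cell_id, cells)]
  b_cell <- rnorm(2 * n_per_group, 0, cell_sd)
  names(b_cell) <- cells
  d$firing_rate <- 20 + 0.08 * d$current_step + b_cell[d$cell_id] +
    rnorm(nrow(d), 0, res_sd) -
    ifelse(d$group == "learned", learned_deficit, 0)
  d
}

# Minimal hand-built protocol_result (for tests of the statistics layer that
# do not need simulated sweeps).
fake_result <- function(cell_id, group, rheobase, thr, amp, ahp, rin,
                        pattern = "regular", rates = NULL) {
  fi <- if (is.null(rates)) NULL else
    structure(list(currents = seq(100, by = 100, length.out = length(rates)),
                   rates = rates), class = "fi_curve")
  structure(list(fi_curve = fi, rheobase = rheobase,
                 ap = structure(list(threshold = thr, threshold_time = 0.1,
                                     peak_time = 0.101, peak_voltage = thr + amp,
                                     amplitude = amp, ahp_amplitude = ahp),
                                class = "ap_features"),
                 input_resistance = rin, pattern = pattern,
                 cell_id = cell_id, group_label = group, log = character(0)),
            class = "protocol_result")
}
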