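test_that("spike detection finds constructed crossings and nothing else", {
  flat <- make_spike_sweep(numeric(0))
  expect_identical(detect_spikes(flat), numeric(0))
  sw <- make_spike_sweep(c(0.2, 0.22))
  st <- detect_spikes(sw)
  expect_length(st, 2)
  expect_lt(max(abs(st - c(0.2, 0.22))), 1e-3)
  # crossings within the lockout are discarded
  sw2 <- make_spike_sweep(c(0.2, 0.2006, 0.25))
  expect_length(detect_spikes(sw2, min_interval = 1), 2)
})

test_that("mean firing rate is count over window length", {
  expect_equal(mean_firing_rate(seq(0.15, 0.55, length.out = 5), 0.1, 0.6), 10)
  expect_equal(mean_firing_rate(numeric(0), 0.1, 0.6), 0)
  expect_error(mean_firing_rate(0.2, 0.5, 0.5), "positive length")
})

test_that("F-I curve covers the protocol grid and is zero when subthreshold", {
  sweeps <- lapply(seq(100, 1200, by = 100), function(a)
    make_spike_sweep(numeric(0), amplitude = a))
  fi <- compute_fi_curve(step_protocol(sweeps))
  expect_equal(fi$currents, seq(100, 1200, by = 100))
  expect_equal(fi$rates, rep(0, 12))
})

test_that("F-I rates are non-decreasing for the noiseless non-adapting model", {
  set.seed(501)
  p <- rand_nonadapting()
  sweeps <- lapply(seq(100, 1200, by = 100), function(a)
    simulate_step_response(p, a, 500, 50, 25)$sweep)
  fi <- compute_fi_curve(step_protocol(sweeps))
  expect_true(all(diff(fi$rates) >= 0))
})

test_that("rheobase is the first spiking amplitude, or absent", {
  amps <- seq(210, 250, by = 10)
  sweeps <- lapply(amps, function(a)
    make_spike_sweep(if (a >= 230) c(0.3) else numeric(0), amplitude = a))
  expect_equal(find_rheobase(step_protocol(sweeps, "fine_rheobase")), 230)
  none <- lapply(amps, function(a) make_spike_sweep(numeric(0), amplitude = a))
  expect_true(is.na(find_rheobase(step_protocol(none, "fine_rheobase"))))
})

test_that("short-step fine-increment rheobase brackets the analytic value", {
  set.seed(502)
  for (i in 1:4) {
    p <- rand_nonadapting()
    r0 <- analytic_rheobase(p)
    amps <- seq(10 * floor((r0 - 50) / 10), 10 * ceiling((r0 + 150) / 10), by = 10)
    sweeps <- lapply(amps, function(a)
      simulate_step_response(p, a, 50, 25, 25)$sweep)
    rb <- find_rheobase(step_protocol(sweeps, "fine_rheobase"))
    expect_gte(rb, r0)
    expect_lte(rb - r0, 60)
  }
})

test_that("AP threshold reads the dV/dt criterion crossing off a constructed ramp", {
  fs <- 10000
  t <- (0:6999) / fs
  v <- rep(-60, 7000)
  # 5 mV/ms ramp from -60 to -45, then 100 mV/ms upstroke to +20, then decay
  i1 <- 3000; n_slow <- 30; n_fast <- 7
  v[i1:(i1 + n_slow)] <- -60 + (0:n_slow) * 0.5
  v[(i1 + n_slow + 1):(i1 + n_slow + n_fast)] <- -45 + (1:n_fast) * 10
  v[(i1 + n_slow + n_fast + 1):(i1 + n_slow + n_fast + 40)] <-
    seq(25, -58, length.out = 40)
  sw <- sweep(t, v, list(baseline = 0, amplitude = 100, onset = 0.1,
                         offset = 0.6), fs)
  st <- detect_spikes(sw)
  ap <- ap_threshold(sw, st[1], dvdt_criterion = 20)
  expect_equal(ap$threshold, -45, tolerance = 0.6)
  expect_lte(ap$threshold_time, ap$peak_time)
})

test_that("AP threshold rejects a bogus spike time on a subthreshold sweep", {
  sw <- make_spike_sweep(numeric(0))
  expect_error(ap_threshold(sw, 0.3), "dV/dt never reaches")
})

test_that("AdEx threshold sits in the band computed from the fine-dt reference", {
  set.seed(503)
  for (i in 1:6) {
    p <- rand_nonadapting()
    amp <- 1.5 * analytic_rheobase(p)
    r <- simulate_step_response(p, amp, 100, 20, 10)
    ap <- ap_threshold(r$sweep, detect_spikes(r$sweep)[1])
    # band frozen from dt = 0.001 ms reference integrations over these ranges
    expect_gt(ap$threshold, p$soft_threshold + 4)
    expect_lt(ap$threshold, p$soft_threshold + 16)
    rf <- simulate_step_response(p, amp, 100, 20, 10, dt = 0.005)
    apf <- ap_threshold(rf$sweep, detect_spikes(rf$sweep)[1])
    expect_lt(abs(ap$threshold - apf$threshold), 0.5)
  }
})

test_that("AP amplitude is peak minus threshold, with a clipping warning", {
  fake <- structure(list(threshold = -45, threshold_time = 0.30,
                         peak_time = 0.3005, peak_voltage = 35,
                         amplitude = NA_real_, ahp_amplitude = NA_real_),
                    class = "ap_features")
  fs <- 10000
  t <- (0:9999) / fs
  v <- rep(-65, 10000); v[3001:3005] <- c(-45, 0, 35, 0, -55)
  sw <- sweep(t, v, list(baseline = 0, amplitude = 100, onset = 0.1,
                         offset = 0.6), fs)
  expect_equal(ap_amplitude(sw, fake), 80)
  v2 <- v; v2[3002:3006] <- 35  # flat top
  sw2 <- sweep(t, v2, list(baseline = 0, amplitude = 100, onset = 0.1,
                           offset = 0.6), fs)
  fake2 <- fake; fake2$peak_time <- 0.3006
  expect_warning(a2 <- ap_amplitude(sw2, fake2), "flat-topped")
  expect_equal(a2, 80)
})

test_that("AdEx amplitude approximates cutoff minus measured threshold", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0,
                     spike_cutoff = 20)
  r <- simulate_step_response(p, 1.5 * analytic_rheobase(p), 100, 20, 10)
  ap <- ap_threshold(r$sweep, detect_spikes(r$sweep)[1])
  amp <- ap_amplitude(r$sweep, ap)
  expect_equal(amp, 20 - ap$threshold, tolerance = 2)
})

test_that("AHP amplitude is threshold minus post-peak minimum, floored at zero", {
  fs <- 10000
  t <- (0:9999) / fs
  v <- rep(-65, 10000)
  v[3001:3003] <- c(-45, 35, -58)   # spike then trough at -58
  v[3004:3050] <- seq(-58, -50, length.out = 47)
  v[3051:3200] <- -50
  sw <- sweep(t, v, list(baseline = 0, amplitude = 100, onset = 0.1,
                         offset = 0.6), fs)
  fake <- structure(list(threshold = -45, threshold_time = 0.3,
                         peak_time = t[3002], peak_voltage = 35,
                         amplitude = NA_real_, ahp_amplitude = NA_real_),
                    class = "ap_features")
  expect_equal(ahp_amplitude(sw, fake), 13)
  # monotone rising after the peak: no hyperpolarization
  v2 <- rep(-65, 10000); v2[3001:3002] <- c(-45, 35)
  v2[3003:10000] <- seq(-40, -20, length.out = 6998)
  sw2 <- sweep(t, v2, list(baseline = 0, amplitude = 100, onset = 0.1,
                           offset = 0.6), fs)
  expect_warning(a <- ahp_amplitude(sw2, fake), "floored")
  expect_equal(a, 0)
  # window truncation at the record end
  fake_end <- fake; fake_end$peak_time <- t[9995]
  expect_warning(ahp_amplitude(sw, fake_end), "truncated")
})

test_that("AdEx AHP equals measured threshold minus the reset potential", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0,
                     reset_potential = -58)
  r <- simulate_step_response(p, 1.3 * analytic_rheobase(p), 50, 25, 25)
  ap <- ap_threshold(r$sweep, detect_spikes(r$sweep)[1])
  expect_equal(ahp_amplitude(r$sweep, ap), ap$threshold - (-58), tolerance = 1)
})

test_that("input resistance recovers Ohm's law on the passive model", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0)
  r <- simulate_step_response(p, -100, 500, 100, 100)
  expect_equal(input_resistance(r$sweep), 100, tolerance = 0.01)
  r2 <- simulate_step_response(p, -50, 500, 100, 100)
  expect_equal(input_resistance(r2$sweep), 100, tolerance = 0.01)
})

test_that("input resistance rejects invalid sweeps", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0)
  dep <- simulate_step_response(p, 300, 500, 100, 100)$sweep
  expect_error(input_resistance(dep), "hyperpolarizing")
  spiky <- make_spike_sweep(c(0.3), amplitude = -100)
  expect_error(input_resistance(spiky), "spikes present")
  zero <- simulate_step_response(p, -100, 500, 100, 100)$sweep
  zero$step$amplitude <- 0
  expect_error(input_resistance(zero), "non-zero")
})

test_that("firing-pattern rule separates periodic, blocked and sparse trains", {
  periodic <- seq(0.11, 0.59, by = 0.02)  # 50 Hz through the step
  prot <- step_protocol(lapply(c(300, 400, 500), function(a)
    make_spike_sweep(periodic, amplitude = a)))
  expect_equal(classify_firing_pattern(prot), "regular")
  blocked <- periodic[periodic < 0.35]     # silent second half
  prot_b <- step_protocol(lapply(c(300, 400, 500), function(a)
    make_spike_sweep(blocked, amplitude = a)))
  expect_equal(classify_firing_pattern(prot_b), "non_regular")
  sparse <- step_protocol(lapply(c(300, 400, 500), function(a)
    make_spike_sweep(c(0.2, 0.4), amplitude = a)))
  expect_warning(lab <- classify_firing_pattern(sparse), "no sweep reaches")
  expect_equal(lab, "non_regular")
  sub <- step_protocol(lapply(c(300, 400, 500), function(a)
    make_spike_sweep(numeric(0), amplitude = a)))
  expect_warning(lab2 <- classify_firing_pattern(sub), "suprathreshold")
  expect_equal(lab2, "non_regular")
})

test_that("detection matches the simulator registry across a noisy population", {
  pop <- generate_cell_population(n_control = 8, n_learned = 8, seed = 61)
  for (cell in pop$cells) {
    for (k in seq_along(cell$protocols$fi$sweeps)) {
      sw <- cell$protocols$fi$sweeps[[k]]
      st <- detect_spikes(sw)
      expect_identical(length(st), length(cell$registry$fi[[k]]))
      expect_equal(mean_firing_rate(st, sw$step$onset, sw$step$offset),
                   mean_firing_rate(cell$registry$fi[[k]], sw$step$onset,
                                    sw$step$offset))
    }
  }
})

test_that("extraction composes the per-feature operations and orders by cell id", {
  pop <- generate_cell_population(n_control = 3, n_learned = 3, seed = 62,
                                  nonregular_fraction = 0)
  res <- extract_features(pop)
  expect_length(res, 6)
  ids <- vapply(res, `[[`, character(1), "cell_id")
  expect_identical(ids, sort(ids))
  cell <- pop$cells[[1]]
  r <- res[[match(cell$cell_id, ids)]]
  expect_equal(r$fi_curve$rates,
               compute_fi_curve(cell$protocols$fi)$rates)
  expect_equal(r$rheobase, find_rheobase(cell$protocols$fine))
  expect_equal(r$input_resistance, input_resistance(cell$protocols$hyper))
  # partial data: F-I only leaves the other fields absent
  partial <- list(cell_id = "x", group = "control",
                  protocols = list(fi = cell$protocols$fi))
  rp <- extract_cell_features(partial)
  expect_true(is.na(rp$rheobase))
  expect_null(rp$ap)
  expect_true(is.na(rp$input_resistance))
  expect_false(is.null(rp$fi_curve))
  expect_error(extract_cell_features(list(cell_id = "y", group = "g",
                                          protocols = list())),
               "no protocols")
})

test_that("raising the soft threshold never lowers rheobase nor raises F-I rates", {
  set.seed(504)
  p <- rand_nonadapting()
  pp <- unclass(p); pp$soft_threshold <- pp$soft_threshold + 3
  p_shift <- do.call(neuron_params, pp[setdiff(names(pp), "seed")])
  amps <- seq(100, 1200, by = 100)
  fi_a <- compute_fi_curve(step_protocol(lapply(amps, function(a)
    simulate_step_response(p, a, 500, 50, 25)$sweep)))
  fi_b <- compute_fi_curve(step_protocol(lapply(amps, function(a)
    simulate_step_response(p_shift, a, 500, 50, 25)$sweep)))
  expect_true(all(fi_b$rates <= fi_a$rates))
  expect_gte(simulated_rheobase(p_shift, 500), simulated_rheobase(p, 500))
})
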