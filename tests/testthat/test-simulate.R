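test_that("parameter constructors validate their invariants", {
  expect_s3_class(neuron_params(), "neuron_params")
  expect_error(neuron_params(leak_conductance = 0), "leak_conductance")
  expect_error(neuron_params(spike_slope_factor = -1), "spike_slope_factor")
  expect_error(neuron_params(adaptation_tau = 0), "adaptation_tau")
  expect_error(neuron_params(reset_potential = 30, spike_cutoff = 20), "reset")
  expect_error(neuron_params(membrane_capacitance = Inf), "finite")
  expect_error(eye_sim_params(sampling_rate = 0.9), "Nyquist")
  expect_error(eye_sim_params(duration = 3), "two stimulus cycles")
  expect_error(eye_sim_params(true_gain = -0.1), "true_gain")
})

test_that("zero step holds the membrane at rest with no spikes", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0)
  r <- simulate_step_response(p, 0, 500, 100, 50)
  expect_length(r$ground_truth$spike_times, 0)
  settled <- r$sweep$voltage[-(1:5000)]
  expect_lt(max(abs(settled - p$leak_reversal)), 0.01)
})

test_that("integration preconditions are enforced", {
  p <- neuron_params()
  expect_error(simulate_step_response(p, 100, dt = 0.1), "integration accuracy")
  expect_error(simulate_step_response(p, NaN), "finite")
  expect_error(simulate_step_response(p, 100, step_duration = -5), "durations")
})

test_that("a suprathreshold step spikes and the registry matches detection", {
  p <- neuron_params(adaptation_coupling = 0, adaptation_increment = 0)
  r <- simulate_step_response(p, 1.5 * analytic_rheobase(p), 500, 100, 50)
  expect_gte(length(r$ground_truth$spike_times), 1)
  expect_equal(length(detect_spikes(r$sweep)), length(r$ground_truth$spike_times))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- neuron_params(noise_sd = 1, seed = 123)
  r1 <- simulate_step_response(p, 300, 200, 50, 50)
  r2 <- simulate_step_response(p, 300, 200, 50, 50)
  expect_identical(r1$sweep$voltage, r2$sweep$voltage)
  expect_identical(r1$ground_truth$spike_times, r2$ground_truth$spike_times)
})

test_that("analytic rheobase evaluates the saddle-node formula", {
  p <- neuron_params(leak_conductance = 10, leak_reversal = -70,
                     soft_threshold = -50, spike_slope_factor = 2,
                     adaptation_coupling = 0)
  expect_equal(analytic_rheobase(p), 180)
  # integrate-and-fire limit of a vanishing slope factor
  p2 <- neuron_params(leak_conductance = 10, leak_reversal = -70,
                      soft_threshold = -50, spike_slope_factor = 1e-9,
                      adaptation_coupling = 0)
  expect_equal(analytic_rheobase(p2), 200, tolerance = 1e-6)
  expect_error(analytic_rheobase(neuron_params(adaptation_coupling = 2)),
               "non-adapting")
})

test_that("analytic rheobase agrees with the simulation-bisection oracle", {
  set.seed(401)
  for (i in 1:12) {
    p <- rand_nonadapting()
    d <- simulated_rheobase(p, step_duration = 2000) - analytic_rheobase(p)
    expect_gte(d, 0)
    expect_lte(d, 2)
  }
})

test_that("spike count is non-decreasing in step amplitude (noiseless, non-adapting)", {
  set.seed(402)
  for (i in 1:4) {
    p <- rand_nonadapting()
    counts <- vapply(seq(100, 1200, by = 100), function(a)
      length(simulate_step_response(p, a, 500, 50, 25)$ground_truth$spike_times),
      numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("halving dt preserves spike counts and shifts times < 0.5 ms", {
  set.seed(403)
  for (i in 1:3) {
    p <- rand_nonadapting()
    for (mult in c(1.5, 3)) {
      amp <- mult * analytic_rheobase(p)
      s1 <- simulate_step_response(p, amp, 500, 50, 25, dt = 0.01)$ground_truth$spike_times
      s2 <- simulate_step_response(p, amp, 500, 50, 25, dt = 0.005)$ground_truth$spike_times
      expect_equal(length(s1), length(s2))
      if (length(s1)) expect_lt(max(abs(s1 - s2)), 5e-4)
    }
  }
})

test_that("empty population is allowed and group counts validated", {
  pop <- generate_cell_population(n_control = 0, n_learned = 0, seed = 1)
  expect_equal(length(pop$cells), 0)
  expect_equal(nrow(pop$manifest), 0)
  expect_error(generate_cell_population(n_control = -1, n_learned = 2), ">= 0")
})

test_that("a soft-threshold shift raises the learned group's formula rheobase", {
  pop <- generate_cell_population(n_control = 6, n_learned = 6,
                                  learned_shift = c(soft_threshold = 4),
                                  nonregular_fraction = 0, seed = 21)
  m <- pop$manifest
  expect_gt(mean(m$rheobase_formula[m$group == "learned"]),
            mean(m$rheobase_formula[m$group == "control"]))
})

test_that("population generation is reproducible from its seed", {
  p1 <- generate_cell_population(n_control = 3, n_learned = 3, seed = 77)
  p2 <- generate_cell_population(n_control = 3, n_learned = 3, seed = 77)
  expect_identical(p1$manifest, p2$manifest)
  expect_identical(p1$cells[[2]]$protocols$fi$sweeps[[5]]$voltage,
                   p2$cells[[2]]$protocols$fi$sweeps[[5]]$voltage)
  expect_identical(p1$cells[[4]]$registry, p2$cells[[4]]$registry)
})

test_that("eye records round-trip the generating gain when clean", {
  p <- eye_sim_params(true_gain = 0.5, noise_sd = 0, saccade_rate = 0,
                      drift_slope = 0, seed = 1)
  rec <- generate_eye_record(p)
  eye_fit <- fit_sinusoid(rec$time, rec$eye_position, rec$stimulus_frequency)
  scr_fit <- fit_sinusoid(rec$time, rec$screen_position, rec$stimulus_frequency)
  expect_equal(eye_fit$amplitude / scr_fit$amplitude, 0.5, tolerance = 1e-12)
})

test_that("zero gain leaves only drift and noise in the eye trace", {
  p <- eye_sim_params(true_gain = 0, noise_sd = 0.2, saccade_rate = 0,
                      drift_slope = 0.05, seed = 4)
  rec <- generate_eye_record(p)
  f <- fit_sinusoid(rec$time, rec$eye_position, rec$stimulus_frequency)
  expect_lt(f$amplitude, 0.05)  # no stimulus-locked component beyond noise
})

test_that("quick-phase counts follow the Poisson law of the generator", {
  rate <- 0.2; dur <- 50; nseeds <- 200
  counts <- vapply(seq_len(nseeds), function(s) {
    r <- generate_eye_record(eye_sim_params(saccade_rate = rate, duration = dur,
                                            seed = s))
    nrow(r$ground_truth$quick_phases)
  }, numeric(1))
  lambda <- rate * dur
  # total count over all seeds within 4 sigma of the Poisson expectation
  expect_lt(abs(sum(counts) - nseeds * lambda), 4 * sqrt(nseeds * lambda))
  expect_gt(var(counts) / mean(counts), 0.6)  # dispersion of a Poisson count
  expect_lt(var(counts) / mean(counts), 1.6)
})

test_that("eye-record generation is deterministic under a fixed seed", {
  p <- eye_sim_params(seed = 11)
  r1 <- generate_eye_record(p)
  r2 <- generate_eye_record(p)
  expect_identical(r1$eye_position, r2$eye_position)
  expect_identical(r1$ground_truth$quick_phases, r2$ground_truth$quick_phases)
})
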