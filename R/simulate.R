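#' Simulate the membrane response to a rectangular current step
#'
#' Integrates the AdEx membrane equation with a fixed-step explicit (forward
#' Euler) scheme and returns both the recorded sweep and the simulator's own
#' spike registry (ground truth for validating spike detection downstream).
#' A spike is registered when the voltage reaches `spike_cutoff`; the voltage
#' is then reset and the adaptation current incremented.
#'
#' @param params A [neuron_params()] object.
#' @param step_amplitude Step amplitude, pA (may be negative).
#' @param step_duration Step duration, ms.
#' @param baseline_duration Pre-step baseline, ms.
#' @param tail_duration Post-step tail, ms.
#' @param dt Integration/sampling step, ms; must be <= 0.05 ms for acceptable
#'   integration accuracy (default 0.01 ms, i.e. 100 kHz).
#' @param baseline_current Holding current, pA.
#' @return A list with `sweep` (a [sweep()]) and `ground_truth` (list with
#'   `spike_times` in seconds and the generating parameters).
#' @export
simulate_step_response <- function(params, step_amplitude,
                                   step_duration = 500,
                                   baseline_duration = 100,
                                   tail_duration = 100,
                                   dt = 0.01,
                                   baseline_current = 0) {
  stopifnot(inherits(params, "neuron_params"))
  validate_neuron_params(params)
  if (!is.finite(step_amplitude)) stop("step_amplitude must be finite", call. = FALSE)
  if (dt > 0.05) {
    stop("dt must be <= 0.05 ms: coarser steps degrade integration accuracy ",
         "of the exponential spike-initiation term", call. = FALSE)
  }
  if (step_duration <= 0 || baseline_duration < 0 || tail_duration < 0) {
    stop("durations must be positive (baseline/tail may be zero)", call. = FALSE)
  }
  total_ms <- baseline_duration + step_duration + tail_duration
  n <- as.integer(round(total_ms / dt)) + 1L
  onset_idx <- as.integer(round(baseline_duration / dt))
  offset_idx <- as.integer(round((baseline_duration + step_duration) / dt))
  out <- with_local_seed(params$seed,
    adex_step_cpp(params$membrane_capacitance, params$leak_conductance,
                  params$leak_reversal, params$spike_slope_factor,
                  params$soft_threshold, params$reset_potential,
                  params$spike_cutoff, params$refractory,
                  params$adaptation_coupling, params$adaptation_increment,
                  params$adaptation_tau, params$noise_sd,
                  n, dt, baseline_current, step_amplitude,
                  onset_idx, offset_idx))
  time_s <- uniform_grid(n, dt)
  sw <- new_sweep(time = time_s, voltage = out$voltage,
                  step = list(baseline = baseline_current,
                              amplitude = step_amplitude,
                              onset = baseline_duration / 1000,
                              offset = (baseline_duration + step_duration) / 1000),
                  sampling_rate = 1000 / dt)
  list(sweep = sw,
       ground_truth = list(spike_times = out$spike_times_ms / 1000,
                           params = params,
                           step_amplitude = step_amplitude))
}

# Uniform time grids recur across the sweeps of a protocol; cache them by
# (n, dt) to avoid reallocating 10^4-10^5-sample vectors per sweep.
.grid_cache <- new.env(parent = emptyenv())
uniform_grid <- function(n, dt) {
  key <- sprintf("%d_%.17g", n, dt)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- (seq_len(n) - 1L) * dt / 1000
    .grid_cache[[key]] <- g
  }
  g
}

#' Closed-form rheobase of the non-adapting AdEx model
#'
#' The minimal sustained current for which the subthreshold fixed points of
#' the AdEx membrane equation vanish (saddle-node): `g_L * (V_T - E_L -
#' Delta_T)`. Valid only in the non-adapting limit (`adaptation_coupling =
#' 0`); with subthreshold adaptation the steady-state effective conductance
#' differs and the formula does not hold.
#'
#' @param params A [neuron_params()] with `adaptation_coupling = 0`.
#' @return Rheobase current, pA.
#' @export
analytic_rheobase <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  if (params$adaptation_coupling != 0) {
    stop("analytic_rheobase is only valid for adaptation_coupling = 0 ",
         "(non-adapting limit)", call. = FALSE)
  }
  params$leak_conductance *
    (params$soft_threshold - params$leak_reversal - params$spike_slope_factor)
}

#' Measure rheobase by bisection on simulated current steps
#'
#' Independent simulation-based measurement of the rheobase: finds the
#' smallest step amplitude (on a grid of `resolution` pA) that evokes at
#' least one spike within a noiseless step of the given duration, by doubling
#' to bracket and then bisecting. Assumes spiking is monotone in amplitude,
#' which holds for the noiseless non-adapting model.
#'
#' @param params A [neuron_params()]; its `noise_sd` is ignored (forced to 0).
#' @param step_duration Step duration, ms (long steps approach the sustained
#'   rheobase; short steps overshoot it).
#' @param resolution Amplitude grid, pA.
#' @param dt Integration step, ms.
#' @return Measured rheobase, pA, or `NA` if no amplitude up to 1e5 pA spikes.
#' @export
simulated_rheobase <- function(params, step_duration = 2000, resolution = 1,
                               dt = 0.01) {
  stopifnot(inherits(params, "neuron_params"))
  p <- params
  p$noise_sd <- 0
  spikes_at <- function(amp) {
    r <- simulate_step_response(p, amp, step_duration = step_duration,
                                baseline_duration = 20, tail_duration = 0,
                                dt = dt)
    length(r$ground_truth$spike_times) > 0
  }
  hi <- 100
  while (!spikes_at(hi)) {
    hi <- hi * 2
    if (hi > 1e5) return(NA_real_)
  }
  lo <- 0
  # invariant: lo never spikes, hi always spikes; bisect on the pA grid
  lo_k <- 0L
  hi_k <- as.integer(ceiling(hi / resolution))
  while (hi_k - lo_k > 1L) {
    mid <- lo_k + (hi_k - lo_k) %/% 2L
    if (spikes_at(mid * resolution)) hi_k <- mid else lo_k <- mid
  }
  hi_k * resolution
}

# Draw a jittered copy of base neuron parameters. `sd` is a named numeric
# vector: plain names are additive SDs (mV-scale parameters); names with a
# "_frac" suffix are fractional SDs applied multiplicatively.
jitter_params <- function(base, sd) {
  p <- unclass(base)
  for (nm in names(sd)) {
    if (grepl("_frac$", nm)) {
      field <- sub("_frac$", "", nm)
      fac <- max(0.2, 1 + stats::rnorm(1, 0, sd[[nm]]))
      p[[field]] <- p[[field]] * fac
    } else {
      p[[nm]] <- p[[nm]] + stats::rnorm(1, 0, sd[[nm]])
    }
  }
  do.call(neuron_params, p[setdiff(names(p), "seed")])
}

default_between_cell_sd <- function() {
  c(soft_threshold = 1, leak_reversal = 1.5, reset_potential = 1,
    leak_conductance_frac = 0.1, membrane_capacitance_frac = 0.1,
    adaptation_increment_frac = 0.2)
}

# Parameter overrides that turn a tonic cell into a bursting/stuttering one:
# reset above the soft threshold re-ignites spikes immediately, and a strong,
# slow adaptation current terminates each burst, producing long inter-burst
# silences (high ISI CV, large gaps).
nonregular_overrides <- function(base) {
  list(reset_potential = base$soft_threshold + 5,
       adaptation_increment = 300,
       adaptation_tau = 300,
       adaptation_coupling = 6)
}

#' Generate a ground-truthed population of simulated Purkinje-like cells
#'
#' Draws jittered AdEx parameter sets for a control and a learned group (the
#' learned group's mean parameters shifted by `learned_shift`), and simulates
#' for every cell the three standard protocols: the F-I series (+100 to
#' +1200 pA, 500 ms, 100 pA increments), a fine-increment single-AP series
#' (50 ms steps, 10 pA increments, spanning the cell's expected rheobase),
#' and one hyperpolarizing step for input resistance. A fixed fraction of
#' cells is generated with a bursting/stuttering phenotype (strong slow
#' adaptation plus supra-threshold reset) to exercise the regular-spiking
#' inclusion filter.
#'
#' Group sizes default to the 89 control / 67 learned cells of the study
#' design this generator emulates; tests and demos typically use smaller
#' cohorts.
#'
#' @param control_params Mean [neuron_params()] of the control group.
#' @param learned_shift Named numeric vector of additive offsets applied to
#'   the learned group's mean parameters (e.g. `c(soft_threshold = 4)` raises
#'   the spike-initiation threshold by 4 mV, raising rheobase and lowering
#'   F-I rates).
#' @param n_control,n_learned Cells per group (>= 0).
#' @param between_cell_sd Named jitter SDs; see [neuron_params()] fields.
#'   `_frac`-suffixed names are fractional (multiplicative) SDs.
#' @param nonregular_fraction Fraction of cells given the bursting phenotype.
#' @param hyper_amplitude Hyperpolarizing step amplitude, pA (negative).
#' @param dt Integration step, ms.
#' @param seed Integer seed; the whole population is reproducible from it.
#' @return An object of class `cell_population`: list of cells (each with
#'   `cell_id`, `group`, `phenotype`, `params`, `protocols`, spike
#'   `registry`) plus a `manifest` data frame of generating ground truth.
#' @export
generate_cell_population <- function(control_params = neuron_params(noise_sd = 0.8),
                                     learned_shift = c(soft_threshold = 4),
                                     n_control = 89, n_learned = 67,
                                     between_cell_sd = default_between_cell_sd(),
                                     nonregular_fraction = 0.2,
                                     hyper_amplitude = -200,
                                     dt = 0.01,
                                     seed = NULL) {
  stopifnot(inherits(control_params, "neuron_params"))
  if (n_control < 0 || n_learned < 0) stop("group sizes must be >= 0", call. = FALSE)
  fi_amps <- seq(100, 1200, by = 100)
  groups <- c(rep("control", n_control), rep("learned", n_learned))
  with_local_seed(seed, {
    cells <- vector("list", length(groups))
    for (k in seq_along(groups)) {
      grp <- groups[k]
      base <- unclass(control_params)
      if (grp == "learned") {
        for (nm in names(learned_shift)) base[[nm]] <- base[[nm]] + learned_shift[[nm]]
      }
      base <- do.call(neuron_params, base[setdiff(names(base), "seed")])
      p <- jitter_params(base, between_cell_sd)
      phenotype <- if (stats::runif(1) < nonregular_fraction) "non_regular" else "regular"
      if (phenotype == "non_regular") {
        ov <- nonregular_overrides(p)
        pp <- unclass(p)
        pp[names(ov)] <- ov
        p <- do.call(neuron_params, pp[setdiff(names(pp), "seed")])
      }
      # expected sustained rheobase of the cell ignoring adaptation; used
      # only to centre the fine-increment protocol, as an experimenter would
      r0 <- p$leak_conductance *
        (p$soft_threshold - p$leak_reversal - p$spike_slope_factor)
      fine_amps <- seq(max(10, 10 * floor((r0 - 50) / 10)),
                       10 * ceiling((r0 + 250) / 10), by = 10)

      sim_many <- function(amps, step_ms, base_ms, tail_ms) {
        res <- lapply(amps, function(a)
          simulate_step_response(p, a, step_duration = step_ms,
                                 baseline_duration = base_ms,
                                 tail_duration = tail_ms, dt = dt))
        list(protocol = step_protocol(lapply(res, `[[`, "sweep"),
                                      kind = if (step_ms >= 500) "fi" else "fine_rheobase"),
             registry = lapply(res, function(r) r$ground_truth$spike_times))
      }
      fi <- sim_many(fi_amps, 500, 100, 50)
      fine <- sim_many(fine_amps, 50, 25, 25)
      hyp <- simulate_step_response(p, hyper_amplitude, step_duration = 500,
                                    baseline_duration = 100,
                                    tail_duration = 100, dt = dt)
      cells[[k]] <- list(cell_id = sprintf("%s_%03d", grp, sum(groups[1:k] == grp)),
                         group = grp,
                         phenotype = phenotype,
                         params = p,
                         rheobase_formula = r0,
                         protocols = list(fi = fi$protocol,
                                          fine = fine$protocol,
                                          hyper = hyp$sweep),
                         registry = list(fi = fi$registry,
                                         fine = fine$registry,
                                         hyper = hyp$ground_truth$spike_times))
    }
    manifest <- data.frame(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      group = vapply(cells, `[[`, character(1), "group"),
      phenotype = vapply(cells, `[[`, character(1), "phenotype"),
      leak_conductance = vapply(cells, function(cl) cl$params$leak_conductance, numeric(1)),
      input_resistance_true = vapply(cells, function(cl)
        1000 / (cl$params$leak_conductance + cl$params$adaptation_coupling),
        numeric(1)),
      soft_threshold = vapply(cells, function(cl) cl$params$soft_threshold, numeric(1)),
      rheobase_formula = vapply(cells, `[[`, numeric(1), "rheobase_formula"),
      stringsAsFactors = FALSE)
    structure(list(cells = cells, manifest = manifest, seed = seed),
              class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("Synthetic cell population: %d cells (%s); %d non-regular phenotype\n",
              nrow(x$manifest),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
              sum(x$manifest$phenotype == "non_regular")))
  invisible(x)
}

#' Generate a synthetic video-oculography record
#'
#' Produces a screen (stimulus) trace `A sin(2 pi f t)` and an eye trace that
#' follows it with the requested gain and phase, plus slow drift, Gaussian
#' measurement noise, and Poisson-timed quick phases. Each quick phase is a
#' rapid resetting ramp (300 deg/s) that recentres the non-stimulus component
#' of eye position and lands `saccade_amplitude` degrees to a random side;
#' all quick phases are logged in the ground truth so desaccading can be
#' validated sample-by-sample.
#'
#' @param params An [eye_sim_params()] object.
#' @param animal_id,session_label Optional labels carried on the record.
#' @return An object of class `eye_record` with a `ground_truth` attribute
#'   (generating parameters and a data frame of quick phases).
#' @export
generate_eye_record <- function(params, animal_id = NA_character_,
                                session_label = NA_character_) {
  stopifnot(inherits(params, "eye_sim_params"))
  fs <- params$sampling_rate
  n <- as.integer(round(params$duration * fs))
  t <- (seq_len(n) - 1L) / fs
  screen <- params$stimulus_amplitude * sin(2 * pi * params$stimulus_frequency * t)
  with_local_seed(params$seed, {
    slow <- params$true_gain * params$stimulus_amplitude *
      sin(2 * pi * params$stimulus_frequency * t + params$true_phase)
    # quick-phase event times (Poisson process)
    ev <- numeric(0)
    if (params$saccade_rate > 0) {
      tt <- stats::rexp(1, params$saccade_rate)
      while (tt < params$duration) {
        ev <- c(ev, tt)
        tt <- tt + stats::rexp(1, params$saccade_rate)
      }
    }
    qp_v <- 300  # quick-phase velocity, deg/s
    dc <- numeric(n)            # drift + quick-phase component
    qp_log <- data.frame(onset = numeric(0), offset = numeric(0),
                         amplitude = numeric(0))
    level <- 0                   # dc level at segment start
    seg_start <- 0
    idx0 <- 1L
    for (tk in ev) {
      pre <- which(t >= seg_start & t < tk)
      if (length(pre)) dc[pre] <- level + params$drift_slope * (t[pre] - seg_start)
      pre_val <- level + params$drift_slope * (tk - seg_start)
      new_level <- sample(c(-1, 1), 1) * params$saccade_amplitude *
        stats::runif(1, 0.6, 1.2)
      jump <- new_level - pre_val
      dur <- abs(jump) / qp_v
      ramp <- which(t >= tk & t < tk + dur)
      if (length(ramp)) dc[ramp] <- pre_val + jump * (t[ramp] - tk) / dur
      qp_log <- rbind(qp_log, data.frame(onset = tk, offset = tk + dur,
                                         amplitude = jump))
      level <- new_level
      seg_start <- tk + dur
    }
    post <- which(t >= seg_start)
    if (length(post)) dc[post] <- level + params$drift_slope * (t[post] - seg_start)
    eye <- slow + dc + stats::rnorm(n, 0, params$noise_sd)
    rec <- eye_record(time = t, screen_position = screen, eye_position = eye,
                      sampling_rate = fs,
                      stimulus_frequency = params$stimulus_frequency,
                      animal_id = animal_id, session_label = session_label)
    rec$ground_truth <- list(params = params, quick_phases = qp_log)
    rec
  })
}

#' Generate a paired pre/post OKR cohort
#'
#' Simulates one pre-training and one post-training oculography session per
#' animal. Animal baseline gains are drawn around `gain_pre`; post-training
#' gains are raised by `gain_increase` (plus small session-to-session
#' variability), emulating the gain-up adaptation produced by sustained
#' optokinetic stimulation.
#'
#' @param n_animals Number of animals.
#' @param gain_pre Mean pre-training gain.
#' @param gain_increase Mean learning-induced gain increase.
#' @param between_animal_sd SD of animal baseline gains.
#' @param session_sd SD of session-level gain fluctuation.
#' @param base_params [eye_sim_params()] template (gain fields overridden).
#' @param seed Integer seed.
#' @return List of [generate_eye_record()] outputs, two per animal, with
#'   `animal_id` and `session_label` ("pre"/"post") set.
#' @export
generate_okr_cohort <- function(n_animals = 6, gain_pre = 0.5,
                                gain_increase = 0.2,
                                between_animal_sd = 0.05,
                                session_sd = 0.02,
                                base_params = eye_sim_params(),
                                seed = NULL) {
  with_local_seed(seed, {
    recs <- list()
    for (a in seq_len(n_animals)) {
      id <- sprintf("mouse_%02d", a)
      g0 <- max(0.05, stats::rnorm(1, gain_pre, between_animal_sd))
      for (ses in c("pre", "post")) {
        g <- g0 + if (ses == "post") gain_increase else 0
        g <- max(0.01, g + stats::rnorm(1, 0, session_sd))
        p <- unclass(base_params)
        p$true_gain <- g
        p$seed <- NULL
        recs[[length(recs) + 1L]] <-
          generate_eye_record(do.call(eye_sim_params, p),
                              animal_id = id, session_label = ses)
      }
    }
    recs
  })
}
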