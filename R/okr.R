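#' Video-oculography record
#'
#' Paired screen (stimulus) and eye position time series on a common uniform
#' time grid, with the stimulus frequency needed for sinusoid fitting.
#'
#' @param time Time stamps, s.
#' @param screen_position,eye_position Positions, degrees.
#' @param sampling_rate Sampling rate, Hz.
#' @param stimulus_frequency Stimulus oscillation frequency, Hz.
#' @param animal_id,session_label Optional labels ("pre"/"post").
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(time, screen_position, eye_position, sampling_rate,
                       stimulus_frequency, animal_id = NA_character_,
                       session_label = NA_character_) {
  n <- length(time)
  if (length(screen_position) != n || length(eye_position) != n) {
    stop("time, screen_position and eye_position must have equal length",
         call. = FALSE)
  }
  if (stimulus_frequency <= 0) stop("stimulus_frequency must be > 0", call. = FALSE)
  structure(list(time = time, screen_position = screen_position,
                 eye_position = eye_position, sampling_rate = sampling_rate,
                 stimulus_frequency = stimulus_frequency,
                 animal_id = animal_id, session_label = session_label,
                 mask = NULL),
            class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("Eye record%s%s: %.1f s at %g Hz, stimulus %g Hz%s\n",
              if (is.na(x$animal_id)) "" else paste0(" ", x$animal_id),
              if (is.na(x$session_label)) "" else paste0(" [", x$session_label, "]"),
              x$time[length(x$time)] - x$time[1], x$sampling_rate,
              x$stimulus_frequency,
              if (is.null(x$mask)) "" else sprintf(", %.1f%% masked",
                                                   100 * mean(x$mask))))
  invisible(x)
}

#' Mask quick phases (saccades) in an eye record
#'
#' Flags samples whose centred-difference eye velocity exceeds
#' `velocity_threshold`, dilates the flagged spans by `pad` on each side, and
#' stores the resulting logical mask on the record (TRUE = excluded from
#' fitting). The slow-phase peak velocity of the standard stimulus (~16
#' deg/s at 0.5 Hz, 5 deg, gain <= 1) sits well below the default threshold,
#' so pursuit is untouched while 300 deg/s quick phases are removed.
#'
#' Velocity is estimated by centred differences of a lightly smoothed
#' position (moving average over `smooth_ms`); without smoothing,
#' sample-to-sample measurement noise at video sampling rates masquerades as
#' high velocity and the mask saturates.
#'
#' @param record An [eye_record()].
#' @param velocity_threshold Velocity criterion, degrees/s.
#' @param pad Dilation on each side of a supra-threshold span, ms.
#' @param smooth_ms Moving-average window for the velocity estimate, ms
#'   (0 = raw differences).
#' @param max_masked_fraction Reject the record as unanalyzable when more
#'   than this fraction of samples is masked.
#' @return The record with its `mask` field set and a `fraction_masked`
#'   field added.
#' @export
desaccade <- function(record, velocity_threshold = 50, pad = 50,
                      smooth_ms = 25, max_masked_fraction = 0.6) {
  stopifnot(inherits(record, "eye_record"))
  x <- record$eye_position
  w <- as.integer(round(smooth_ms / 1000 * record$sampling_rate))
  if (w >= 2) {
    w <- w + (w %% 2 == 0)  # odd width, centred
    xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    xs[is.na(xs)] <- x[is.na(xs)]
    x <- xs
  }
  v <- centered_velocity(record$time, x)
  hit <- abs(v) > velocity_threshold
  pad_n <- as.integer(round(pad / 1000 * record$sampling_rate)) +
    (if (w >= 2) w %/% 2 else 0L)  # the smoother widens each event
  mask <- dilate_mask(hit, pad_n)
  frac <- mean(mask)
  if (frac > max_masked_fraction) {
    stop(sprintf("record unanalyzable: %.0f%% of samples masked as quick phases (limit %.0f%%); check velocity_threshold or the recording",
                 100 * frac, 100 * max_masked_fraction), call. = FALSE)
  }
  record$mask <- mask
  record$fraction_masked <- frac
  record
}

centered_velocity <- function(time, x) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  v[1] <- v[2]
  v[n] <- v[n - 1]
  v
}

dilate_mask <- function(hit, pad_n) {
  if (pad_n <= 0 || !any(hit)) return(hit)
  idx <- which(hit)
  out <- logical(length(hit))
  lo <- pmax(1L, idx - pad_n)
  hi <- pmin(length(hit), idx + pad_n)
  for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
  out
}

#' Least-squares sinusoid fit at a known frequency
#'
#' Fits `a sin(2 pi f t) + b cos(2 pi f t) + c` to the unmasked samples by
#' linear least squares (closed-form normal equations via QR). Amplitude is
#' `sqrt(a^2 + b^2)` and phase `atan2(b, a)`, so a pure sine at the stimulus
#' frequency has phase 0 and positive phase means the fitted signal leads it.
#'
#' Because each quick phase displaces the eye, the slow-phase trace is a
#' sinusoid riding on a piecewise-constant baseline that jumps at every
#' masked span. With `segment_offsets = TRUE` the fit therefore estimates
#' one constant offset per contiguous unmasked segment (sharing a single
#' sine/cosine pair); with a single segment this reduces exactly to the
#' three-parameter fit. The reported `offset` is the segment-length-weighted
#' mean baseline.
#'
#' @param time Time stamps, s.
#' @param position Position samples, degrees.
#' @param frequency Fit frequency, Hz.
#' @param mask Optional logical vector, TRUE = exclude sample.
#' @param segment_offsets Fit one baseline offset per unmasked segment.
#' @return An object of class `sinusoid_fit` with fields `amplitude`,
#'   `phase`, `offset`, `rms_residual`, `fraction_masked`, `coefficients`.
#' @export
fit_sinusoid <- function(time, position, frequency, mask = NULL,
                         segment_offsets = FALSE) {
  if (length(time) != length(position)) {
    stop("time and position must have equal length", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(FALSE, length(time))
  keep <- !mask & is.finite(position)
  tt <- time[keep]
  yy <- position[keep]
  span <- if (length(tt)) max(tt) - min(tt) else 0
  if (span * frequency < 2) {
    stop("need at least two stimulus cycles of unmasked data", call. = FALSE)
  }
  if (length(tt) / (span * frequency) < 4) {
    stop("fewer than 4 unmasked samples per stimulus cycle on average", call. = FALSE)
  }
  s <- sin(2 * pi * frequency * tt)
  cc <- cos(2 * pi * frequency * tt)
  if (segment_offsets) {
    seg <- cumsum(c(TRUE, diff(which(keep)) > 1))  # id of each unmasked run
    ind <- outer(seg, seq_len(max(seg)), `==`) + 0
    colnames(ind) <- paste0("offset", seq_len(max(seg)))
    X <- cbind(s = s, c = cc, ind)
  } else {
    seg <- rep(1L, length(tt))
    X <- cbind(s = s, c = cc, offset = 1)
  }
  fit <- stats::lm.fit(X, yy)
  a <- fit$coefficients[["s"]]
  b <- fit$coefficients[["c"]]
  offs <- fit$coefficients[-(1:2)]
  offset <- sum(offs * tabulate(seg), na.rm = TRUE) / length(seg)
  structure(list(amplitude = sqrt(a^2 + b^2),
                 phase = atan2(b, a),
                 offset = offset,
                 rms_residual = sqrt(mean(fit$residuals^2)),
                 fraction_masked = mean(mask),
                 frequency = frequency,
                 n_segments = max(seg),
                 coefficients = c(a = a, b = b)),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("Sinusoid fit @ %g Hz: amplitude %.4g deg, phase %.3f rad, offset %.3g deg (rms resid %.3g, %.1f%% masked)\n",
              x$frequency, x$amplitude, x$phase, x$offset, x$rms_residual,
              100 * x$fraction_masked))
  invisible(x)
}

#' OKR gain from eye and screen sinusoid fits
#'
#' Gain is the ratio of the fitted eye amplitude to the fitted screen
#' amplitude; phase lead is the wrapped eye-minus-screen phase difference
#' (positive = eye leads the screen).
#'
#' @param eye_fit,screen_fit [fit_sinusoid()] results for the eye and screen
#'   traces.
#' @param animal_id,session_label Optional labels carried into the result.
#' @return An object of class `gain_result` with `gain`, `phase_lead`, plus
#'   the two fits.
#' @export
compute_gain <- function(eye_fit, screen_fit, animal_id = NA_character_,
                         session_label = NA_character_) {
  stopifnot(inherits(eye_fit, "sinusoid_fit"), inherits(screen_fit, "sinusoid_fit"))
  if (screen_fit$amplitude <= 1e-9) {
    stop("screen amplitude is at or below the numerical floor; cannot form a gain",
         call. = FALSE)
  }
  dphi <- eye_fit$phase - screen_fit$phase
  dphi <- atan2(sin(dphi), cos(dphi))
  structure(list(gain = eye_fit$amplitude / screen_fit$amplitude,
                 phase_lead = dphi,
                 animal_id = animal_id, session_label = session_label,
                 eye_fit = eye_fit, screen_fit = screen_fit),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("OKR gain%s%s: %.4f (phase lead %.3f rad)\n",
              if (is.na(x$animal_id)) "" else paste0(" ", x$animal_id),
              if (is.na(x$session_label)) "" else paste0(" [", x$session_label, "]"),
              x$gain, x$phase_lead))
  invisible(x)
}

#' Full per-record OKR gain analysis
#'
#' Convenience wrapper: desaccades the eye trace, fits the stimulus-frequency
#' sinusoid to the (unmasked) eye and the (never masked) screen trace, and
#' forms the gain.
#'
#' @param record An [eye_record()].
#' @param velocity_threshold,pad Desaccading parameters; see [desaccade()].
#' @return A [compute_gain()] result.
#' @export
analyze_eye_record <- function(record, velocity_threshold = 50, pad = 50) {
  rec <- desaccade(record, velocity_threshold = velocity_threshold, pad = pad)
  eye_fit <- fit_sinusoid(rec$time, rec$eye_position, rec$stimulus_frequency,
                          mask = rec$mask, segment_offsets = TRUE)
  screen_fit <- fit_sinusoid(rec$time, rec$screen_position,
                             rec$stimulus_frequency)
  compute_gain(eye_fit, screen_fit, animal_id = rec$animal_id,
               session_label = rec$session_label)
}

#' Paired pre/post comparison of OKR gains
#'
#' Collects one pre and one post gain per animal and runs the paired t-test
#' on the per-animal differences (post minus pre).
#'
#' @param results List of [compute_gain()] results, or a data frame with
#'   columns `animal_id`, `session_label` ("pre"/"post") and `gain`.
#' @return A list with the paired [okr_stat] result (`test`) and the
#'   per-animal gain table (`pairs`).
#' @export
compare_learning <- function(results) {
  tab <- if (is.data.frame(results)) results else {
    data.frame(animal_id = vapply(results, `[[`, character(1), "animal_id"),
               session_label = vapply(results, `[[`, character(1), "session_label"),
               gain = vapply(results, `[[`, numeric(1), "gain"),
               stringsAsFactors = FALSE)
  }
  need <- c("animal_id", "session_label", "gain")
  if (!all(need %in% names(tab))) {
    stop("results must provide animal_id, session_label and gain", call. = FALSE)
  }
  ids <- unique(tab$animal_id)
  for (id in ids) {
    sub <- tab[tab$animal_id == id, ]
    if (sum(sub$session_label == "pre") != 1 || sum(sub$session_label == "post") != 1) {
      stop(sprintf("animal '%s' does not have exactly one pre and one post gain", id),
           call. = FALSE)
    }
  }
  pre <- vapply(ids, function(id)
    tab$gain[tab$animal_id == id & tab$session_label == "pre"], numeric(1))
  post <- vapply(ids, function(id)
    tab$gain[tab$animal_id == id & tab$session_label == "post"], numeric(1))
  pairs <- data.frame(animal_id = ids, pre = pre, post = post,
                      difference = post - pre, stringsAsFactors = FALSE)
  list(test = paired_t(pre, post), pairs = pairs)
}
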