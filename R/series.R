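# Logistic schedules and direct series simulators. These are the ground-truth
# kinematics of the synthetic movies and also serve as standalone trajectory
# generators for parameter-recovery studies.

#' Logistic rotation / constriction schedules
#'
#' `rotation_schedule()` evaluates R(t) = amplitude / (1 + exp(-(t - t0)/tau))
#' plus an optional zero-mean pulsatile modulation. `area_schedule()` evaluates
#' A(t) = A0 - A1 / (1 + exp(-(t - t0)/tau)) with the analogous modulation.
#'
#' The modulation is a rectified sinusoid of period `pulse_period` recentered
#' to zero mean, scaled by `pulse_amplitude` times the schedule amplitude.
#' It makes the instantaneous rate alternate sign once per period, producing
#' the pulse / anti-rotation (or constriction / expansion) intervals that the
#' rate segmentation is designed to detect.
#'
#' @param t Time points, minutes.
#' @param amplitude,t0,tau Logistic parameters (degrees or um^2, minutes).
#' @param pulse_amplitude Fraction of `amplitude` applied as modulation
#'   (0 disables pulses).
#' @param pulse_period Pulse period, minutes.
#' @return Numeric vector, degrees (rotation) or um^2 (area).
#' @export
rotation_schedule <- function(t, amplitude = 90, t0 = 250,
                              tau = 60 * 90 / (4 * 11),
                              pulse_amplitude = 0, pulse_period = 40) {
  amplitude / (1 + exp(-(t - t0) / tau)) +
    pulse_modulation(t, pulse_amplitude * amplitude, pulse_period)
}

#' @rdname rotation_schedule
#' @param baseline Pre-constriction area A0, um^2.
#' @export
area_schedule <- function(t, baseline = 20, amplitude = 12, t0 = 250,
                          tau = 72, pulse_amplitude = 0, pulse_period = 40) {
  baseline - amplitude / (1 + exp(-(t - t0) / tau)) +
    pulse_modulation(t, pulse_amplitude * amplitude, pulse_period)
}

# zero-mean rectified sinusoid: a * (|sin(pi t / P)| - 2/pi)
pulse_modulation <- function(t, a, period) {
  if (a == 0) return(rep(0, length(t)))
  a * (abs(sin(pi * t / period)) - 2 / pi)
}

new_rotation_series <- function(time_min, R_deg, frame = seq_along(time_min) - 1L,
                                frame_interval_min = NULL) {
  stopifnot(all(diff(time_min) > 0))
  df <- data.frame(frame = frame, time_min = time_min, R_deg = R_deg,
                   normalized = R_deg / 90)
  structure(df, class = c("rotation_series", "data.frame"),
            frame_interval_min = frame_interval_min %||% infer_interval(time_min))
}

new_area_series <- function(time_min, area_um2, frame = seq_along(time_min) - 1L,
                            frame_interval_min = NULL) {
  stopifnot(all(diff(time_min) > 0))
  a0 <- area_um2[which(!is.na(area_um2))[1]]
  df <- data.frame(frame = frame, time_min = time_min, area_um2 = area_um2,
                   constriction = 1 - area_um2 / a0)
  structure(df, class = c("area_series", "data.frame"),
            frame_interval_min = frame_interval_min %||% infer_interval(time_min))
}

infer_interval <- function(time_min) {
  if (length(time_min) < 2) return(NA_real_)
  median(diff(time_min))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate rotation / area trajectories from a logistic schedule
#'
#' Draws one noisy trajectory per call from the deterministic schedule plus
#' i.i.d. Gaussian measurement noise. Used for parameter-recovery studies of
#' [fit_logistic()] without rendering a full movie.
#'
#' @param n_frames Number of frames (10-min spacing by default).
#' @param frame_interval_min Sampling interval, minutes.
#' @param preset A [genotype_preset()]; its schedule parameters are used
#'   unless overridden.
#' @param noise_sd Gaussian noise SD (degrees or um^2); defaults to the
#'   preset's value.
#' @param pulses Include the preset's pulsatile modulation? Default `FALSE`
#'   (pure logistic plus noise).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `rotation_series` / `area_series` data frame with columns
#'   `frame`, `time_min`, and `R_deg` + `normalized` or `area_um2` +
#'   `constriction`.
#' @export
simulate_rotation_series <- function(n_frames = 51, frame_interval_min = 10,
                                     preset = genotype_preset("wild_type"),
                                     noise_sd = preset$noise_sd_deg,
                                     pulses = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_frames) - 1) * frame_interval_min
  r <- rotation_schedule(t, preset$rotation_amplitude_deg,
                         preset$rotation_t0_min, preset$rotation_tau_min,
                         if (pulses) preset$pulse_amplitude else 0,
                         preset$pulse_period_min)
  new_rotation_series(t, r + rnorm(n_frames, 0, noise_sd),
                      frame_interval_min = frame_interval_min)
}

#' @rdname simulate_rotation_series
#' @export
simulate_area_series <- function(n_frames = 51, frame_interval_min = 10,
                                 preset = genotype_preset("wild_type"),
                                 noise_sd = preset$noise_sd_um2,
                                 pulses = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_frames) - 1) * frame_interval_min
  a <- area_schedule(t, preset$area_baseline_um2, preset$area_amplitude_um2,
                     preset$area_t0_min, preset$area_tau_min,
                     if (pulses) preset$area_pulse_amplitude else 0,
                     preset$pulse_period_min)
  new_area_series(t, a + rnorm(n_frames, 0, noise_sd),
                  frame_interval_min = frame_interval_min)
}
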