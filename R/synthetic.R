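#' Synthetic low-severity rear-impact pulse
#'
#' Defines a smooth unimodal T1/sled boundary family emulating a low-speed
#' rear impact: the sled and T1 x-displacements follow a C2-smooth smoothstep
#' ramp reaching their peaks at `rise_time_ms` and holding, while the T1
#' z-displacement and y-rotation follow a C2-smooth unimodal bump over the
#' event (returning to zero).  All channels start at zero with zero initial
#' rate and acceleration.  Defaults approximate a ~2 g sled pulse with a
#' 0.12 m forward displacement, of the order of published low-severity
#' volunteer sled tests.
#'
#' @param peak_sled_displacement_m peak sled x-displacement, m.
#' @param rise_time_ms ramp duration to peak, ms (< duration).
#' @param t1_x_peak_m additional T1 x-displacement relative to the sled, m.
#' @param t1_z_peak_m peak T1 z-displacement (negative = downward), m.
#' @param t1_rotation_peak_rad peak T1 y-rotation (positive = extension), rad.
#' @param duration_ms event duration, ms.
#' @return an object of class `pulse_spec`.
#' @export
pulse_spec <- function(peak_sled_displacement_m = 0.12, rise_time_ms = 180,
                       t1_x_peak_m = 0.015, t1_z_peak_m = -0.008,
                       t1_rotation_peak_rad = 0.10, duration_ms = 300) {
  stop_if(rise_time_ms >= duration_ms, "rise_time must be below duration")
  stop_if(duration_ms <= 0, "duration must be positive")
  structure(list(peak_sled_displacement_m = peak_sled_displacement_m,
                 rise_time_ms = rise_time_ms, t1_x_peak_m = t1_x_peak_m,
                 t1_z_peak_m = t1_z_peak_m,
                 t1_rotation_peak_rad = t1_rotation_peak_rad,
                 duration_ms = duration_ms), class = "pulse_spec")
}

# C2 smoothstep ramp (0 -> 1 over [0, 1], zero first/second derivative at ends)
smoothstep5 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 - 15 * x + 6 * x^2)
}

# C2 unimodal bump on [0, 1] peaking at 1 in the middle, zero value/rate at ends
bump4 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  sin(pi * x)^4
}

#' Generate T1 boundary channels from a pulse specification
#'
#' @param spec a [pulse_spec()].
#' @param dt_ms sampling interval of the generated channels, ms.
#' @return a [kinematic_channels()] with `t1_x`, `t1_z`, `t1_ry`, `sled_x`
#'   (sled and T1 x-motion kept separable; the simulator adds them).
#' @export
generate_pulse <- function(spec, dt_ms = 1) {
  stopifnot(inherits(spec, "pulse_spec"))
  t <- seq(0, spec$duration_ms, by = dt_ms)
  ramp <- smoothstep5(t / spec$rise_time_ms)
  bump <- bump4(t / spec$duration_ms)
  kinematic_channels(t, list(
    t1_x = spec$t1_x_peak_m * ramp,
    t1_z = spec$t1_z_peak_m * bump,
    t1_ry = spec$t1_rotation_peak_rad * bump,
    sled_x = spec$peak_sled_displacement_m * ramp))
}

#' Volunteer-surrogate target specification
#'
#' Targets are produced by forward simulation with known "true" controller
#' parameters (defaults: the calibration initial values kp 0.601,
#' kd 412.62, tnd 15, tna_a 10, tna_d 40, tne 35), then perturbed with
#' seeded additive Gaussian noise (per-channel standard deviation expressed
#' as a fraction of the channel's range) and low-pass smoothed, emulating
#' averaged volunteer curves.  With `noise_sd = 0` the target is exactly a
#' forward-simulation output.
#'
#' @param true_params a [controller_params()] used to generate the target.
#' @param pulse a [pulse_spec()].
#' @param noise_sd additive noise sd as a fraction of each channel's range.
#' @param smoothing_hz low-pass cutoff applied after adding noise (0 = off).
#' @param seed integer seed for the noise.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(true_params = controller_params(), pulse = pulse_spec(),
                           noise_sd = 0, smoothing_hz = 40, seed = 1) {
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(true_params = true_params, pulse = pulse,
                 noise_sd = noise_sd, smoothing_hz = smoothing_hz,
                 seed = as.integer(seed)), class = "surrogate_spec")
}

#' Generate volunteer-surrogate target channels
#'
#' @param spec a [surrogate_spec()].
#' @param plant a [plant_config()].
#' @param muscles muscle set.
#' @param ... passed to [run_simulation()].
#' @return list with `channels` (the 10 target kinematic channels),
#'   `boundary` (the generated pulse), and `provenance` (true parameters,
#'   seed, noise settings) so recovery experiments are self-verifying.
#' @export
generate_surrogate_target <- function(spec, plant = plant_config(),
                                      muscles = default_muscles(plant), ...) {
  stopifnot(inherits(spec, "surrogate_spec"))
  boundary <- generate_pulse(spec$pulse)
  sim <- run_simulation(plant, spec$true_params, boundary, muscles = muscles, ...)
  keep <- c("head_x", "head_z", "head_ry", sprintf("c%d_ry", 1:7))
  ch <- sim$channels
  tm <- ch$time_ms
  vals <- lapply(keep, function(nm) ch[[nm]])
  names(vals) <- keep
  if (spec$noise_sd > 0) {
    dt_s <- (tm[2] - tm[1]) / 1000
    vals <- with_seed(spec$seed, {
      lapply(vals, function(v) {
        rng <- diff(range(v))
        if (rng == 0) rng <- max(abs(v), 1e-6)
        noisy <- v + rnorm(length(v), 0, spec$noise_sd * rng)
        if (spec$smoothing_hz > 0) {
          wn <- min(0.99, 2 * spec$smoothing_hz * dt_s)
          bf <- signal::butter(2, wn)
          as.numeric(signal::filtfilt(bf, noisy))
        } else noisy
      })
    })
  }
  list(channels = kinematic_channels(tm, vals),
       boundary = boundary,
       provenance = list(true_params = params_to_vec(spec$true_params),
                         cocontraction = spec$true_params$cocontraction,
                         noise_sd = spec$noise_sd,
                         smoothing_hz = spec$smoothing_hz,
                         seed = spec$seed))
}
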