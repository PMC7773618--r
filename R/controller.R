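#' Controller parameters for the angular-positioned feedback loop
#'
#' The reflex controller acts on the orientation of the vector from the T1
#' vertebral-body centre to the head centre of gravity.  The six calibrated
#' constants are the PD gains and the neural/muscle time constants; gains are
#' in percent contraction per radian (Kp) and per radian per millisecond (Kd),
#' time constants in milliseconds.
#'
#' Calibration bounds used throughout the package: kp in \[0.601, 40\],
#' kd in \[5, 412.62\], tnd in \[3.5, 20\], tna_a in \[5, 15\],
#' tna_d in \[20, 60\], tne in \[20, 50\].
#'
#' @param kp proportional gain, %contraction/rad.
#' @param kd derivative gain, %contraction/(rad/ms).
#' @param tnd neural transmission and processing delay, ms.
#' @param tna_a muscle activation time constant, ms.
#' @param tna_d muscle deactivation time constant, ms.
#' @param tne neural excitation time constant, ms.
#' @param cocontraction activation floor (baseline tone), in `[0, 1)`.
#' @param reference_angle target controller-vector angle, rad; `NA` means
#'   "capture at the end of gravity settling" (the usual case).
#' @param rate_before_delay if `TRUE` the error rate is formed before the
#'   neural delay and delayed as a separate signal; default differentiates
#'   the delayed error.
#' @param rate_lp_ms optional first-order low-pass time constant applied to
#'   the error rate (0 = off).
#' @return an object of class `controller_params`.
#' @export
controller_params <- function(kp = 0.601, kd = 412.62, tnd = 15,
                              tna_a = 10, tna_d = 40, tne = 35,
                              cocontraction = 0.05, reference_angle = NA_real_,
                              rate_before_delay = FALSE, rate_lp_ms = 0) {
  stop_if(any(c(tnd, tna_a, tna_d, tne) <= 0), "time constants must be positive")
  stop_if(kp < 0 || kd < 0, "gains must be non-negative")
  stop_if(cocontraction < 0 || cocontraction >= 1, "cocontraction must be in [0, 1)")
  structure(list(kp = kp, kd = kd, tnd = tnd, tna_a = tna_a, tna_d = tna_d,
                 tne = tne, cocontraction = cocontraction,
                 reference_angle = reference_angle,
                 rate_before_delay = isTRUE(rate_before_delay),
                 rate_lp_ms = rate_lp_ms),
            class = "controller_params")
}

#' Read or write controller parameters (YAML or JSON)
#'
#' The six calibrated constants keep their canonical key names
#' (`kp`, `kd`, `tnd`, `tna_a`, `tna_d`, `tne`).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_controller_params` returns a [controller_params()].
#' @export
read_controller_params <- function(path) {
  obj <- read_config_file(path)
  do.call(controller_params, obj[names(obj) %in% names(formals(controller_params))])
}

#' @param params a `controller_params` object.
#' @rdname read_controller_params
#' @export
write_controller_params <- function(params, path) {
  write_config_file(unclass(params), path)
}

#' Controller-vector angle
#'
#' Orientation of the vector from the T1 centre to the head centre of
#' gravity, measured from vertical (+z), positive rearward (extension, -x).
#' A head directly above T1 gives 0; a head displaced purely backward with
#' equal height offset gives +pi/4.
#'
#' @param head_cg 2-vector (x, z), m.
#' @param t1_center 2-vector (x, z), m.
#' @return angle in rad.
#' @export
controller_vector_angle <- function(head_cg, t1_center) {
  d <- head_cg - t1_center
  stop_if(sqrt(sum(d^2)) < 1e-12, "head C.G. and T1 centre coincide")
  atan2(-d[1], d[2])
}

#' Wrapped error angle
#'
#' @param current_angle,reference_angle angles in rad.
#' @return `current - reference` wrapped into `(-pi, pi]`.
#' @export
error_angle <- function(current_angle, reference_angle) {
  check_finite(c(current_angle, reference_angle), "angles")
  wrap_angle(current_angle - reference_angle)
}

#' Delay buffer for the neural transmission delay
#'
#' A delay buffer stores error-angle samples with their timestamps;
#' [delayed_sample()] returns the value `tnd` ms in the past by linear
#' interpolation, or the zero-error value before the buffer has warmed up.
#'
#' @param t_ms,value sample time (ms) and error value (rad).
#' @param buffer a `delay_buffer`.
#' @return `delay_buffer()` an empty buffer; `buffer_push()` the updated
#'   buffer.
#' @export
delay_buffer <- function() {
  structure(list(t_ms = numeric(0), value = numeric(0)), class = "delay_buffer")
}

#' @rdname delay_buffer
#' @export
buffer_push <- function(buffer, t_ms, value) {
  buffer$t_ms <- c(buffer$t_ms, t_ms)
  buffer$value <- c(buffer$value, value)
  buffer
}

#' @param t_now current time, ms.
#' @param tnd neural delay, ms (>= 0).
#' @rdname delay_buffer
#' @export
delayed_sample <- function(buffer, t_now, tnd) {
  stop_if(tnd < 0, "delay must be non-negative")
  tq <- t_now - tnd
  if (length(buffer$t_ms) == 0 || tq < buffer$t_ms[1]) return(0)
  if (tq >= buffer$t_ms[length(buffer$t_ms)]) return(buffer$value[length(buffer$value)])
  stats::approx(buffer$t_ms, buffer$value, xout = tq)$y
}

#' PD control law
#'
#' `u = (kp * e + kd * edot) / 100`: the gains are in percent contraction,
#' the output is an activation fraction.  The error rate is expressed in
#' rad/ms, matching the Kd unit.
#'
#' @param e_delayed delayed error angle, rad.
#' @param e_rate_delayed delayed error-angle rate, rad/ms.
#' @param params a [controller_params()].
#' @return dimensionless control signal u (signed).
#' @export
pd_control <- function(e_delayed, e_rate_delayed, params) {
  check_finite(c(e_delayed, e_rate_delayed), "controller inputs")
  (params$kp * e_delayed + params$kd * e_rate_delayed) / 100
}

#' Spatial-tuning projection of the control signal
#'
#' The sign of `u` selects the demand direction (positive = the head has
#' fallen rearward of the reference, so the restoring demand is forward /
#' flexion at direction 0; negative selects extension at direction pi).
#' Each muscle receives `|u| * max(0, cos(preferred - demand))`
#' (half-wave-rectified cosine tuning): aligned muscles receive `|u|`,
#' perpendicular and antagonist muscles receive 0, never a negative value.
#'
#' @param u signed control signal.
#' @param muscles list of [muscle_element()] with preferred directions.
#' @param forward_direction,backward_direction tuning-plane demand angles
#'   selected by the sign of `u`.
#' @return named numeric vector of per-muscle excitations.
#' @export
spatial_tuning <- function(u, muscles, forward_direction = 0,
                           backward_direction = pi) {
  dir <- if (u >= 0) forward_direction else backward_direction
  exc <- vapply(muscles, function(m) {
    abs(u) * max(0, cos(m$preferred_direction_rad - dir))
  }, numeric(1))
  names(exc) <- vapply(muscles, `[[`, character(1), "name")
  exc
}

#' One step of the neural excitation / muscle activation cascade
#'
#' Advances the two first-order equations
#' `dNe/dt = (u - Ne)/Tne` and `dNa/dt = (Ne - Na)/Tna` (Tna switching
#' between the activation and deactivation constants with the sign of
#' `Ne - Na`) by one step of length `dt_ms`, using the exact exponential
#' solution of the cascade with the excitation held constant over the step.
#'
#' @param u excitation input over the step (held constant).
#' @param state list/vector with elements `ne` and `na`.
#' @param dt_ms step length, ms (> 0).
#' @param params a [controller_params()].
#' @return list with updated `ne` and `na`.
#' @export
activation_dynamics_step <- function(u, state, dt_ms, params) {
  stop_if(dt_ms <= 0, "dt must be positive")
  stop_if(any(c(params$tne, params$tna_a, params$tna_d) <= 0),
          "time constants must be positive")
  if (dt_ms > params$tna_a / 5) {
    warning("dt is large relative to the activation time constant", call. = FALSE)
  }
  ne0 <- state$ne; na0 <- state$na
  ene <- exp(-dt_ms / params$tne)
  ta <- if (ne0 >= na0) params$tna_a else params$tna_d
  ea <- exp(-dt_ms / ta)
  ne1 <- u + (ne0 - u) * ene
  na1 <- if (abs(params$tne - ta) > 1e-9) {
    u + (na0 - u) * ea + (ne0 - u) * (params$tne / (params$tne - ta)) * (ene - ea)
  } else {
    u + (na0 - u) * ea + (ne0 - u) * (dt_ms / ta) * ea
  }
  list(ne = ne1, na = na1)
}

#' Min-max activation clamp
#'
#' Limits the filtered activation signal to the co-contraction floor below
#' and 1.0 above before it drives the muscle.
#'
#' @param na_raw raw activation value(s).
#' @param cocontraction activation floor.
#' @return clamped activation in `[cocontraction, 1]`.
#' @export
clamp_activation <- function(na_raw, cocontraction = 0.05) {
  pmin(pmax(na_raw, cocontraction), 1.0)
}
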