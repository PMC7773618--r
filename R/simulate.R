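#' Interpolated T1 base motion from boundary channels
#'
#' Builds continuously interpolated position/rotation functions of time from
#' the prescribed T1 channels (`t1_x`, `t1_z`, `t1_ry`), with the sled
#' x-displacement added to the T1 x-motion when a `sled_x` channel is
#' present.  Cubic spline interpolation; rates and accelerations are the
#' analytic derivatives of the interpolant.
#'
#' @param boundary a [kinematic_channels()] object containing `t1_x`, `t1_z`,
#'   `t1_ry` and optionally `sled_x`.
#' @return list of functions of time in ms: `pos(t)` (2-vector m), `ry(t)`
#'   (rad), `vel(t)` (m/s), `w(t)` (rad/s), `acc(t)` (m/s^2), plus the time
#'   span `range_ms`.
#' @export
prescribe_t1 <- function(boundary) {
  need <- c("t1_x", "t1_z", "t1_ry")
  missing <- setdiff(need, names(boundary))
  stop_if(length(missing) > 0,
          paste("missing boundary channels:", paste(missing, collapse = ", ")))
  t <- boundary$time_ms
  x <- boundary$t1_x
  if ("sled_x" %in% names(boundary)) x <- x + boundary$sled_x
  fx <- splinefun(t, x, method = "natural")
  fz <- splinefun(t, boundary$t1_z, method = "natural")
  fr <- splinefun(t, boundary$t1_ry, method = "natural")
  ms2s <- 1000  # derivative wrt ms -> per second
  list(
    pos = function(tt) c(fx(tt), fz(tt)),
    ry = function(tt) fr(tt),
    vel = function(tt) c(fx(tt, deriv = 1), fz(tt, deriv = 1)) * ms2s,
    w = function(tt) fr(tt, deriv = 1) * ms2s,
    acc = function(tt) c(fx(tt, deriv = 2), fz(tt, deriv = 2)) * ms2s^2,
    range_ms = range(t))
}

#' Run one closed-loop (or passive) simulation
#'
#' Couples the link-chain plant and the reflex controller in a fixed-step
#' loop: the plant first settles statically under gravity with muscles at the
#' co-contraction floor (the 100 ms settling window of the protocol), the
#' controller reference vector is captured from the settled posture, and the
#' event is then integrated over `[0, duration_ms]` with the prescribed T1
#' motion applied as a moving base.  RK4 integration at `dt_ms`, controller
#' updated every step, outputs sampled at `output_dt_ms`.
#'
#' @param plant a [plant_config()].
#' @param controller a [controller_params()] or `NULL` for the passive model
#'   (activations fixed at the co-contraction floor).
#' @param boundary T1 boundary channels, see [prescribe_t1()].
#' @param muscles list of [muscle_element()]; default [default_muscles()].
#' @param duration_ms event duration (output window), ms.
#' @param dt_ms integrator step, ms.
#' @param settle_ms nominal gravity-settling window, ms.
#' @param output_dt_ms output sampling interval, ms (must be a multiple of
#'   `dt_ms`).
#' @param frame `"t1"` (default) reports head displacements relative to the
#'   moving T1/sled base (the frame in which volunteer head excursions are
#'   usually plotted; the ground-fixed alternative is dominated by rigid
#'   transport with the sled); `"lab"` reports ground-fixed displacements.
#' @param cocontraction activation floor used when `controller` is `NULL`.
#' @param mech a [muscle_mechanics()] object.
#' @return an object of class `neck_sim`: list with `channels`
#'   (a [kinematic_channels()] with `head_x`, `head_z`, `head_ry`,
#'   `c1_ry`..`c7_ry`, `t1_x`, `t1_z`, `t1_ry` and `act_*` traces),
#'   `settle_state`, and `meta` (parameters, dt, clamp-contract flag).
#' @export
run_simulation <- function(plant, controller = NULL, boundary,
                           muscles = default_muscles(plant),
                           duration_ms = 300, dt_ms = plant$dt_ms,
                           settle_ms = 100, output_dt_ms = 1,
                           frame = c("t1", "lab"),
                           cocontraction = 0.05,
                           mech = muscle_mechanics()) {
  frame <- match.arg(frame)
  stop_if(!is.null(controller) && !inherits(controller, "controller_params"),
          "controller must be controller_params() or NULL")
  bc <- prescribe_t1(boundary)
  stop_if(bc$range_ms[1] > 0 || bc$range_ms[2] < duration_ms,
          "boundary channels must cover [0, duration_ms]")
  out_stride <- round(output_dt_ms / dt_ms)
  stop_if(abs(out_stride * dt_ms - output_dt_ms) > 1e-9,
          "output_dt_ms must be a multiple of dt_ms")
  n_steps <- round(duration_ms / dt_ms)
  stop_if(abs(n_steps * dt_ms - duration_ms) > 1e-9,
          "duration_ms must be a multiple of dt_ms")

  cocon <- if (is.null(controller)) cocontraction else controller$cocontraction
  settle <- settle_gravity(plant, settle_ms, muscles, cocon, mech = mech)
  ref <- controller_vector_angle(settle$head_cg, settle$t1)

  # base motion sampled on the half-step grid
  th <- seq(0, duration_ms, by = dt_ms / 2)
  bh <- rbind(vapply(th, function(tt) bc$pos(tt), numeric(2)),
              vapply(th, bc$ry, numeric(1)),
              vapply(th, function(tt) bc$vel(tt), numeric(2)),
              vapply(th, bc$w, numeric(1)),
              vapply(th, function(tt) bc$acc(tt), numeric(2)))

  ctrl <- if (is.null(controller)) {
    list(enabled = FALSE, cocontraction = cocon)
  } else {
    c(unclass(controller)[c("kp", "kd", "tnd", "tna_a", "tna_d", "tne",
                            "cocontraction", "rate_before_delay", "rate_lp_ms")],
      list(enabled = TRUE,
           reference_angle = if (is.finite(controller$reference_angle))
             controller$reference_angle else ref))
  }

  phi0 <- abs_angles(settle$joint_angles, bc$ry(0))
  res <- .sim_core_cpp(plant_core_list(plant), muscles_core_list(muscles),
                       mech_core_list(mech), ctrl, bh, dt_ms, n_steps,
                       out_stride, phi0, rep(0, length(phi0)))
  if (res$fail_step >= 0) {
    stop(sprintf("simulation unstable at step %d (t = %.1f ms)",
                 res$fail_step, res$fail_step * dt_ms), call. = FALSE)
  }

  tm <- drop(res$time_ms)
  head <- res$head
  cerv <- res$cervical
  act <- res$activation
  n <- length(plant$link_lengths_m)

  head_x <- head[, 1] - head[1, 1]
  head_z <- head[, 2] - head[1, 2]
  if (frame == "t1") {
    bx <- vapply(tm, function(tt) bc$pos(tt), numeric(2))
    head_x <- head_x - (bx[1, ] - bx[1, 1])
    head_z <- head_z - (bx[2, ] - bx[2, 1])
  }
  vals <- list(head_x = head_x, head_z = head_z,
               head_ry = head[, 3] - head[1, 3])
  # cervical columns are absolute link angles for links 1..n-1 = C7..C1
  for (j in seq_len(n - 1)) {
    vals[[sprintf("c%d_ry", n - j)]] <- cerv[, j] - cerv[1, j]
  }
  vals <- vals[c("head_x", "head_z", "head_ry", sprintf("c%d_ry", 1:7))]
  vals$t1_x <- vapply(tm, function(tt) bc$pos(tt)[1], numeric(1)) - bc$pos(0)[1]
  vals$t1_z <- vapply(tm, function(tt) bc$pos(tt)[2], numeric(1)) - bc$pos(0)[2]
  vals$t1_ry <- vapply(tm, bc$ry, numeric(1)) - bc$ry(0)
  mn <- vapply(muscles, `[[`, character(1), "name")
  for (j in seq_along(mn)) vals[[paste0("act_", mn[j])]] <- act[, j]

  clamp_ok <- all(act >= cocon - 1e-12 & act <= 1 + 1e-12)
  structure(list(
    channels = kinematic_channels(tm, vals),
    settle_state = settle,
    meta = list(controller = controller, dt_ms = dt_ms,
                settle_ms = settle_ms, frame = frame,
                reference_angle = ref, cocontraction = cocon,
                clamp_contract_ok = clamp_ok,
                version = as.character(utils::packageVersion("neckloop")))),
    class = "neck_sim")
}

#' @export
print.neck_sim <- function(x, ...) {
  cat("<neck_sim> ")
  print(x$channels)
  invisible(x)
}
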