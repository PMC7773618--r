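# shared fixtures: everything is generated in code, no stored data

default_plant <- function(...) plant_config(...)

# a chain config with an arbitrary number of links, bypassing the 8-joint
# pipeline validation (used for single-pendulum and reduced-chain oracles)
chain_config <- function(n, L = 0.1, m = 1, I_joint = NULL, k = 0, c = 0,
                         q0 = rep(0, n), g = 9.81, head_off = NULL) {
  L <- rep(L, length.out = n)
  m <- rep(m, length.out = n)
  if (is.null(head_off)) head_off <- c(0, L[n] / 2)
  if (is.null(I_joint)) I_joint <- m * (L / 2)^2 * 1.5
  cfg <- list(link_lengths_m = L, segment_masses_kg = m,
              segment_inertias_kgm2 = rep(I_joint, length.out = n),
              joint_stiffness_Nm_per_rad = rep(k, length.out = n) + 1e-12,
              joint_damping_Nms_per_rad = rep(c, length.out = n) + 1e-12,
              initial_alignment_rad = q0, gravity_mps2 = g,
              head_cg_offset_m = head_off, dt_ms = 0.5)
  structure(cfg, class = "plant_config")
}

zero_boundary <- function(duration_ms = 300, dt_ms = 1) {
  t <- seq(0, duration_ms, by = dt_ms)
  z <- rep(0, length(t))
  kinematic_channels(t, list(t1_x = z, t1_z = z, t1_ry = z))
}

# small but informative calibration scenario used by optimizer tests:
# an active truth well inside the bounds with fast activation dynamics
recovery_truth <- function() {
  c(kp = 35, kd = 200, tnd = 12, tna_a = 5, tna_d = 25, tne = 20)
}

sine_channel <- function(f_hz = 5, n = 50, t_end = 300, amp = 1, phase = 0) {
  t <- seq(0, t_end, length.out = n)
  structure(data.frame(time_ms = t, value = amp * sin(2 * pi * f_hz * t / 1000 + phase)),
            unit = "m", name = "x", class = c("kin_channel", "data.frame"))
}
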