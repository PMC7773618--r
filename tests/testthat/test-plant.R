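test_that("plant configuration enforces its invariants", {
  expect_s3_class(plant_config(), "plant_config")
  expect_error(plant_config(link_lengths_m = rep(0.02, 7)), "8 joints")
  expect_error(plant_config(segment_masses_kg = c(rep(0.2, 7), -1)), "positive")
  expect_error(plant_config(joint_stiffness_Nm_per_rad = rep(0, 8)), "positive")
})

test_that("plant config YAML round-trips", {
  f <- tempfile(fileext = ".yaml")
  cfg <- plant_config(gravity_mps2 = 3.7)
  write_plant_config(cfg, f)
  cfg2 <- read_plant_config(f)
  expect_equal(cfg2$gravity_mps2, 3.7)
  expect_equal(cfg2$link_lengths_m, cfg$link_lengths_m)
})

test_that("muscle force follows the Hill form and its edge cases", {
  el <- muscle_element("m", c(0L, 2L), rbind(c(0.02, 0.02), c(0, 0.01)),
                       pcsa_m2 = 1e-4, sigma_max_Pa = 5e5,
                       optimal_length_m = 0.05, slack_length_m = 0.05)
  # no activation, at slack: zero
  expect_equal(muscle_force(el, muscle_state(0.05, 0, 0)), 0)
  # full activation, isometric at optimum, no passive stretch: PCSA * sigma
  expect_equal(muscle_force(el, muscle_state(0.05, 0, 1)), 50)
  # independent straight-line evaluation of the chosen fl/fv/fpe forms
  mech <- muscle_mechanics()
  l <- 1.1 * el$optimal_length_m
  v <- -0.1
  na <- 0.5
  fl_ref <- exp(-(((l / 0.05) - 1) / mech$fl_width)^2)
  vmax <- mech$vmax_lopt_per_s * 0.05
  fv_ref <- (vmax + v) / (vmax - v / mech$fv_af)
  fpe_ref <- mech$fpe_scale * (exp(mech$fpe_shape * (l - 0.05) / 0.05) - 1)
  expect_equal(muscle_force(el, muscle_state(l, v, na)),
               1e-4 * 5e5 * (na * fv_ref * fl_ref + fpe_ref), tolerance = 1e-12)
  # tension-only: deep shortening cannot push
  expect_gte(muscle_force(el, muscle_state(0.02, -1, 1)), 0)
  expect_error(muscle_force(el, muscle_state(0.05, NaN, 0.5)), "finite")
})

test_that("muscle force is monotone non-decreasing in activation", {
  el <- muscle_element("m", c(0L, 2L), rbind(c(0.02, 0.02), c(0, 0.01)),
                       1e-4, 5e5, 0.05)
  for (l in c(0.04, 0.05, 0.062)) {
    for (v in c(-0.05, 0, 0.08)) {
      f <- vapply(seq(0, 1, 0.1), function(na)
        muscle_force(el, muscle_state(l, v, na)), numeric(1))
      expect_true(all(diff(f) >= -1e-12))
    }
  }
})

test_that("path length and velocity match geometry and a finite-difference oracle", {
  pl <- default_plant()
  # two points 0.05 m apart on adjacent segments at the straight posture
  el <- muscle_element("s", c(1L, 2L), rbind(c(0, 0), c(0, 0.033)),
                       1e-4, 5e5, 0.05)
  res <- path_length_and_velocity(el, pl, rep(0, 8))
  expect_equal(res$length_m, 0.05, tolerance = 1e-12)
  expect_equal(res$velocity_mps, 0)
  # via-point right angle: length is the sum of the two legs
  elv <- muscle_element("v", c(1L, 1L, 2L),
                        rbind(c(0, 0.03, 0.03), c(0, 0, 0.023)), 1e-4, 5e5, 0.07)
  expect_equal(path_length_and_velocity(elv, pl, rep(0, 8))$length_m, 0.07)
  # velocity against a central-difference oracle on a multi-joint muscle
  elm <- muscle_element("m", c(0L, 4L, 8L), rbind(c(-0.03, -0.03, -0.04),
                                                  c(0, 0.008, 0.03)),
                        1e-4, 5e5, 0.15)
  set.seed(2)
  q <- rnorm(8, 0, 0.1)
  qd <- rnorm(8, 0, 1)
  len_at <- function(qq) path_length_and_velocity(elm, pl, qq)$length_m
  h <- 1e-6
  v_fd <- (len_at(q + h * qd) - len_at(q - h * qd)) / (2 * h)
  expect_equal(path_length_and_velocity(elm, pl, q, qd)$velocity_mps, v_fd,
               tolerance = 1e-6)
  expect_error(path_length_and_velocity(
    muscle_element("z", c(1L, 2L), rbind(c(0, 0), c(0, -0.017)), 1e-4, 5e5, 0.01),
    pl, rep(0, 8)), "degenerate")
})

test_that("gravity settling: zero gravity exact, default sag small, stiffer is straighter", {
  pl0 <- plant_config(gravity_mps2 = 0)
  s0 <- settle_gravity(pl0)
  expect_identical(s0$joint_angles, pl0$initial_alignment_rad)
  pl <- default_plant()
  s1 <- settle_gravity(pl)
  expect_true(s1$converged)
  init_cg <- neckloop:::head_cg_position(pl, pl$initial_alignment_rad)
  expect_lt(sqrt(sum((s1$head_cg - init_cg)^2)), 0.02)
  pl2 <- plant_config(joint_stiffness_Nm_per_rad = rep(80, 8))
  s2 <- settle_gravity(pl2)
  expect_lt(max(abs(s2$joint_angles - pl2$initial_alignment_rad)),
            max(abs(s1$joint_angles - pl$initial_alignment_rad)))
})

test_that("unloaded stationary chain has zero accelerations", {
  cfg <- chain_config(4, k = 0, c = 0, g = 0)
  d <- plant_dynamics(cfg, list(joint_angles = c(0.3, -0.2, 0.5, 0.1),
                                joint_rates = rep(0, 4)))
  expect_lt(max(abs(d$link_accelerations)), 1e-6)
})

test_that("single-link reduction matches the closed-form pendulum on a moving base", {
  L <- 0.12; m <- 2.5; Ij <- 0.011; k <- 6; cd <- 0.4; g <- 9.81
  q0 <- 0.05
  cfg <- chain_config(1, L = L, m = m, I_joint = Ij, k = k, c = cd,
                      q0 = q0, g = g, head_off = c(0.01, 0.07))
  r <- c(0.01, 0.07)
  Icom <- Ij - m * sum(r^2)
  pend_qdd <- function(phi, phid, base) {
    # I_joint phidd = spring + damper + gravity moment + base-acceleration moment
    rotd <- c(-r[1] * sin(phi) - r[2] * cos(phi), r[1] * cos(phi) - r[2] * sin(phi))
    tau <- -k * (phi - base$ry - q0) - cd * (phid - base$w) +
      m * sum(rotd * c(0, -g)) - m * sum(rotd * base$acc)
    tau / (Icom + m * sum(r^2))
  }
  set.seed(7)
  for (i in 1:10) {
    phi <- rnorm(1, 0, 0.6); phid <- rnorm(1, 0, 3)
    base <- list(pos = c(0, 0), ry = rnorm(1, 0, 0.2), vel = rnorm(2),
                 w = rnorm(1), acc = rnorm(2, 0, 5))
    got <- plant_dynamics(cfg, list(joint_angles = phi - base$ry,
                                    joint_rates = phid - base$w),
                          base = base)$link_accelerations
    want <- pend_qdd(phi, phid, base)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("undamped unactuated gravity-free chain conserves energy over 400 ms", {
  cfg <- chain_config(8, L = 0.017, m = 0.2, I_joint = 5e-4, k = 20, c = 0,
                      g = 0, head_off = c(0, 0.05))
  cfg$segment_masses_kg[8] <- 3.6
  cfg$segment_inertias_kgm2[8] <- 0.029
  q <- cfg$initial_alignment_rad + c(0.2, -0.1, 0.15, 0, -0.2, 0.1, 0.05, -0.1)
  qd <- rep(0, 8)
  e0 <- neckloop:::chain_energy(cfg, q, qd)
  bh <- matrix(0, 8, 2 * 800 + 1)
  res <- neckloop:::.sim_core_cpp(neckloop:::plant_core_list(cfg), list(),
                                  unclass(muscle_mechanics()),
                                  list(enabled = FALSE, cocontraction = 0),
                                  bh, 0.5, 800, 800, cumsum(q), qd)
  expect_equal(res$fail_step, -1L)
  q1 <- diff(c(0, drop(res$phi_final)))
  qd1 <- diff(c(0, drop(res$phid_final)))
  e1 <- neckloop:::chain_energy(cfg, q1, qd1)
  expect_lt(abs(e1 - e0) / abs(e0), 0.001)
})
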