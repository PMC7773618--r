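test_that("controller-vector angle: vertical reference, 45-degree geometry, equivariance", {
  expect_equal(controller_vector_angle(c(0, 0.2), c(0, 0)), 0)
  # purely backward displacement (-x) with equal height offset: +pi/4
  expect_equal(controller_vector_angle(c(-0.1, 0.1), c(0, 0)), pi / 4)
  # rigid rotation of both points about T1 by phi changes the angle by phi
  rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                          sin(a) * p[1] + cos(a) * p[2])
  h <- c(0.03, 0.18); t1 <- c(0.01, 0.02)
  a0 <- controller_vector_angle(h, t1)
  for (phi in c(-0.7, 0.2, 1.1)) {
    # rotation about +y in the x-z plane tilts +z toward -x by +phi
    hr <- t1 + rot(h - t1, phi)
    expect_equal(controller_vector_angle(hr, t1), a0 + phi, tolerance = 1e-12)
  }
  expect_error(controller_vector_angle(c(1, 1), c(1, 1)), "coincide")
})

test_that("error angle wraps into (-pi, pi]", {
  expect_equal(error_angle(0.3, 0.3), 0)
  expect_equal(error_angle(0.4, 0.3), 0.1)
  expect_equal(error_angle(0.3 + 2 * pi, 0.3), 0)
  expect_equal(error_angle(0.3, 0.3 + 2 * pi), 0)
  expect_equal(error_angle(pi + 0.1, 0), -pi + 0.1, tolerance = 1e-12)
})

test_that("delayed sampling: constants, ramps exactly, sinusoids to O(dt^2)", {
  buf <- delay_buffer()
  for (t in seq(0, 50, 0.5)) buf <- buffer_push(buf, t, 0.7)
  expect_equal(delayed_sample(buf, 50, 3), 0.7)
  expect_equal(delayed_sample(buf, 50, 33.3), 0.7)
  # ramp: linear interpolation is exact
  buf <- delay_buffer()
  a <- 0.02
  for (t in seq(0, 60, 0.5)) buf <- buffer_push(buf, t, a * t)
  expect_equal(delayed_sample(buf, 60, 15), a * 45, tolerance = 1e-12)
  expect_equal(delayed_sample(buf, 47.25, 15.5), a * 31.75, tolerance = 1e-12)
  # sinusoid at dt = 0.5 ms, tnd = 15 ms: matches shifted analytic to O(dt^2)
  buf <- delay_buffer()
  w <- 2 * pi * 8 / 1000  # 8 Hz in rad/ms
  for (t in seq(0, 200, 0.5)) buf <- buffer_push(buf, t, sin(w * t))
  errs <- vapply(seq(100.13, 199, 7.31), function(t)
    abs(delayed_sample(buf, t, 15) - sin(w * (t - 15))), numeric(1))
  expect_lt(max(errs), (0.5 * w)^2)
  expect_error(delayed_sample(buf, 10, -1), "non-negative")
})

test_that("PD law converts percent-contraction gains to activation fraction", {
  p <- controller_params(kp = 4.89, kd = 0)
  expect_equal(pd_control(0.1, 0, p), 0.00489)
  p2 <- controller_params(kp = 0, kd = 5)
  expect_equal(pd_control(0, 0.01, p2), 0.0005)
  expect_equal(pd_control(0, 0, controller_params()), 0)
})

test_that("spatial tuning is half-wave-rectified cosine recruitment", {
  mk <- function(pref) muscle_element("m", c(0L, 2L), rbind(c(0.02, 0.02), c(0, 0.01)),
                                      1e-4, 5e5, 0.05, preferred_direction_rad = pref)
  muscles <- list(mk(0), mk(pi / 2), mk(pi), mk(pi / 3))
  e <- spatial_tuning(0.4, muscles)
  expect_equal(unname(e[1]), 0.4)            # aligned: |u| exactly
  expect_equal(unname(e[2]), 0, tolerance = 1e-15)  # perpendicular
  expect_equal(unname(e[3]), 0)              # antagonist: rectified to 0
  expect_equal(unname(e[4]), 0.4 * cos(pi / 3))
  expect_true(all(e >= 0))
  # negative u selects the backward direction: extensors recruited
  eb <- spatial_tuning(-0.4, muscles)
  expect_equal(unname(eb[3]), 0.4)
  expect_equal(unname(eb[1]), 0)
})

test_that("activation cascade: fixed point, first-order step response, fine-step oracle", {
  p <- controller_params(tne = 35, tna_a = 10, tna_d = 40)
  s <- list(ne = 0, na = 0)
  s1 <- activation_dynamics_step(0, s, 1, p)
  expect_equal(s1, list(ne = 0, na = 0))
  # step response of the neural excitation: Ne(35 ms) = 1 - exp(-1)
  s <- list(ne = 0, na = 0)
  for (i in 1:70) s <- activation_dynamics_step(1, s, 0.5, p)
  expect_equal(s$ne, 1 - exp(-1), tolerance = 1e-4)
  # cascade Na against a dt = 0.001 ms explicit reference integration
  ref <- list(ne = 0, na = 0)
  dtf <- 0.001
  for (i in seq_len(50 / dtf)) {
    dne <- (1 - ref$ne) / 35
    ta <- if (ref$ne >= ref$na) 10 else 40
    dna <- (ref$ne - ref$na) / ta
    ref <- list(ne = ref$ne + dtf * dne, na = ref$na + dtf * dna)
  }
  s <- list(ne = 0, na = 0)
  for (i in 1:100) s <- activation_dynamics_step(1, s, 0.5, p)
  expect_equal(s$na, ref$na, tolerance = 1e-4)
  expect_error(activation_dynamics_step(1, s, -1, p), "positive")
})

test_that("Ne is monotone for monotone input and Na lags Ne lags u", {
  p <- controller_params(tne = 30, tna_a = 8, tna_d = 30)
  u <- pmin(seq(0, 2, length.out = 200), 1)
  s <- list(ne = 0, na = 0)
  ne <- na <- numeric(200)
  for (i in seq_along(u)) {
    s <- activation_dynamics_step(u[i], s, 0.5, p)
    ne[i] <- s$ne; na[i] <- s$na
  }
  expect_true(all(diff(ne) >= -1e-12))
  expect_true(all(ne <= u + 1e-12))
  expect_true(all(na <= ne + 1e-12))
})

test_that("activation clamp has the documented floor and ceiling", {
  expect_equal(clamp_activation(0.01), 0.05)
  expect_equal(clamp_activation(0.5), 0.5)
  expect_equal(clamp_activation(1.7), 1.0)
  expect_equal(clamp_activation(c(-1, 0.3, 2), cocontraction = 0.1), c(0.1, 0.3, 1))
})

test_that("controller parameter files round-trip with canonical keys", {
  f <- tempfile(fileext = ".yaml")
  p <- controller_params(kp = 4.89, kd = 5, tnd = 15.07)
  write_controller_params(p, f)
  txt <- readLines(f)
  expect_true(any(grepl("^kp:", txt)) && any(grepl("^tna_a:", txt)))
  p2 <- read_controller_params(f)
  expect_equal(p2$kp, 4.89)
  expect_equal(p2$tnd, 15.07)
})
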