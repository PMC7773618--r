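test_that("objective presets match the published weighting schemes", {
  o1 <- objective_spec("opt1")
  expect_equal(o1$terms, c(head_x = 1, head_z = 1, head_ry = 1))
  o2 <- objective_spec("opt2")
  expect_equal(length(o2$terms), 7)
  expect_true(all(o2$terms == 1))
  o3 <- objective_spec("opt3")
  expect_equal(length(o3$terms), 10)
  o4 <- objective_spec("opt4")
  expect_equal(sum(o4$terms[sprintf("c%d_ry", 1:7)]), 1)
  expect_equal(unname(o4$terms["head_x"]), 1)
  expect_error(objective_spec(terms = c(a = -1)), "positive")
})

test_that("parameter bounds carry the published ranges and initial values", {
  b <- parameter_bounds()
  expect_equal(b["kp", ], data.frame(lower = 0.601, upper = 40, init = 0.601,
                                     row.names = "kp"))
  expect_equal(b["kd", "upper"], 412.62)
  expect_equal(b["tnd", "lower"], 3.5)
  expect_equal(unname(unlist(b["tne", ])), c(20, 50, 35))
})

test_that("objective is linear in weights and recomposes across presets", {
  pl <- default_plant()
  tg <- generate_surrogate_target(surrogate_spec(noise_sd = 0), pl)
  p <- controller_params(kp = 10, kd = 50)
  o1 <- evaluate_objective(p, objective_spec("opt1"), pl, tg$boundary, tg$channels)
  dbl <- objective_spec(terms = objective_spec("opt1")$terms * 2)
  o2 <- evaluate_objective(p, dbl, pl, tg$boundary, tg$channels)
  expect_equal(as.numeric(o2), 2 * as.numeric(o1), tolerance = 1e-12)
  # opt4 = opt1 + (1/7) * sum of cervical errors
  o4 <- evaluate_objective(p, objective_spec("opt4"), pl, tg$boundary, tg$channels)
  ocerv <- evaluate_objective(p, objective_spec("opt2"), pl, tg$boundary, tg$channels)
  expect_equal(as.numeric(o4), as.numeric(o1) + as.numeric(ocerv) / 7,
               tolerance = 1e-10)
  expect_error(evaluate_objective(p, objective_spec("opt2"), pl, tg$boundary,
                                  tg$channels[c("time_ms", "head_x")]),
               "missing channels")
})

# six-dimensional convex bowl centred inside the bounds; analytic stub, no
# simulation involved
bowl_objective <- function(center) {
  b <- parameter_bounds()
  rng <- b$upper - b$lower
  function(v) sum(((v[rownames(b)] - center) / rng)^2)
}

test_that("SRSM finds the minimum of a convex bowl within 1% of the range", {
  b <- parameter_bounds()
  center <- structure(b$lower + c(0.3, 0.6, 0.45, 0.5, 0.25, 0.7) * (b$upper - b$lower),
                      names = rownames(b))
  # smooth deterministic objective: the aggressive documented reduction
  # schedule (defaults are tuned for noisy simulation objectives)
  r <- optimize_srsm(bowl_objective(center), b, seed = 5,
                     zoom_lo = 0.3, zoom_start = 0.75, exploit_iters = 0)
  err <- abs(r$best_vec - center) / (b$upper - b$lower)
  expect_lt(max(err), 0.01)
  # trust-region containment: every sampled point within bounds
  expect_true(all(t(r$sampled_points) >= b$lower - 1e-12))
  expect_true(all(t(r$sampled_points) <= b$upper + 1e-12))
  expect_equal(r$best_objective, min(r$sampled_objectives))
})

test_that("GA finds the bowl minimum within 2% and behaves like a GA", {
  b <- parameter_bounds()
  center <- structure(b$lower + c(0.55, 0.2, 0.62, 0.4, 0.75, 0.35) * (b$upper - b$lower),
                      names = rownames(b))
  r <- optimize_ga(bowl_objective(center), b, seed = 8)
  err <- abs(r$best_vec - center) / (b$upper - b$lower)
  expect_lt(max(err), 0.02)
  # elitism: the elite objective is monotone non-increasing over generations
  elites <- vapply(r$history, `[[`, numeric(1), "elite")
  expect_true(all(diff(elites) <= 0))
  # determinism under the seed
  r2 <- optimize_ga(bowl_objective(center), b, seed = 8)
  expect_identical(r$sampled_objectives, r2$sampled_objectives)
  expect_identical(r$best_vec, r2$best_vec)
  expect_true(all(t(r$sampled_points) >= b$lower - 1e-12 &
                  t(r$sampled_points) <= b$upper + 1e-12))
})

test_that("chained validation frees only kp and kd and cannot regress", {
  b <- parameter_bounds()
  center <- structure(b$lower + 0.5 * (b$upper - b$lower), names = rownames(b))
  ga <- optimize_ga(bowl_objective(center), b, pop_size = 12, max_iter = 4, seed = 3)
  ch <- chained_validation(bowl_objective(center), b, ga, seed = 4)
  frozen <- setdiff(rownames(b), c("kp", "kd"))
  expect_identical(ch$best_vec[frozen], ga$best_vec[frozen])
  expect_lte(ch$best_objective, ga$best_objective + 1e-12)
  # freezing everything returns the start point with its objective
  all_fixed <- ga$best_vec
  r0 <- optimize_srsm(bowl_objective(center), b, fixed = all_fixed, seed = 1)
  expect_identical(r0$best_vec, all_fixed)
  expect_equal(r0$best_objective, bowl_objective(center)(all_fixed))
})

test_that("parameter correlations: collinearity, category boundaries, frozen entries", {
  b <- parameter_bounds()
  pn <- rownames(b)
  set.seed(12)
  # two perfectly collinear parameters
  n <- 40
  pts <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, pn))
  pts[, "kd"] <- 2 * pts[, "kp"] + 1
  pc <- parameter_correlations(pts)
  expect_equal(pc$matrix["kp", "kd"], 1, tolerance = 1e-12)
  expect_equal(pc$labels["kp", "kd"], "strong")
  expect_true(all(abs(pc$matrix[is.finite(pc$matrix)]) <= 1 + 1e-12))
  expect_equal(unname(diag(pc$matrix)), rep(1, 6))
  # frozen parameter: undefined entries
  pts2 <- pts; pts2[, "tne"] <- 35
  pc2 <- parameter_correlations(pts2)
  expect_true(all(is.na(pc2$matrix["tne", ])))
  # published category boundaries
  expect_equal(correlation_label(0.29), "weak")
  expect_equal(correlation_label(0.30), "medium")
  expect_equal(correlation_label(-0.42), "medium")
  expect_equal(correlation_label(0.49), "medium")
  expect_equal(correlation_label(0.50), "strong")
  expect_equal(correlation_label(-1), "strong")
})

test_that("independent uniform sampling yields weak correlations (3/sqrt(n))", {
  pn <- rownames(parameter_bounds())
  ok <- sapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 400
    pts <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, pn))
    pc <- parameter_correlations(pts)
    off <- pc$matrix[upper.tri(pc$matrix)]
    all(abs(off) < 3 / sqrt(n))
  })
  expect_gte(mean(ok), 0.8)
})
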