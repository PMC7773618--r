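#' Calibration objective specification
#'
#' Weighted channel-matching objective built from the curve-mapping metric.
#' Presets: `opt1` = head C.G. x/z/ry (weight 1 each); `opt2` = C1..C7
#' absolute y-rotations (weight 1 each); `opt3` = union of both, all weight
#' 1; `opt4` = head channels at weight 1 plus cervical channels at 1/7 each
#' (so the cervical weights sum to one).
#'
#' @param preset one of `"opt1"`, `"opt2"`, `"opt3"`, `"opt4"`, or `NULL`
#'   when `terms` is given.
#' @param terms named numeric vector of channel weights (> 0).
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(preset = c("opt1", "opt2", "opt3", "opt4"),
                           terms = NULL) {
  head_ch <- c(head_x = 1, head_z = 1, head_ry = 1)
  cerv1 <- structure(rep(1, 7), names = sprintf("c%d_ry", 1:7))
  if (is.null(terms)) {
    preset <- match.arg(preset)
    terms <- switch(preset,
                    opt1 = head_ch,
                    opt2 = cerv1,
                    opt3 = c(head_ch, cerv1),
                    opt4 = c(head_ch, cerv1 / 7))
  } else {
    preset <- "custom"
    stop_if(is.null(names(terms)) || any(!is.finite(terms)) || any(terms <= 0),
            "terms must be a named vector of positive weights")
  }
  structure(list(name = preset, terms = terms, metric = "curve_mapping"),
            class = "objective_spec")
}

#' Calibration parameter bounds
#'
#' Lower bound, upper bound and initial value for the six controller
#' parameters: kp (0.601, 40, init 0.601), kd (5, 412.62, init 412.62),
#' tnd (3.5, 20, init 15), tna_a (5, 15, init 10), tna_d (20, 60, init 40),
#' tne (20, 50, init 35).
#'
#' @return data.frame with rownames `kp, kd, tnd, tna_a, tna_d, tne` and
#'   columns `lower`, `upper`, `init`.
#' @export
parameter_bounds <- function() {
  data.frame(lower = c(0.601, 5, 3.5, 5, 20, 20),
             upper = c(40, 412.62, 20, 15, 60, 50),
             init = c(0.601, 412.62, 15, 10, 40, 35),
             row.names = c("kp", "kd", "tnd", "tna_a", "tna_d", "tne"))
}

param_names <- function() c("kp", "kd", "tnd", "tna_a", "tna_d", "tne")

params_to_vec <- function(p) {
  unlist(unclass(p)[param_names()])
}

vec_to_params <- function(v, template = controller_params()) {
  for (nm in param_names()) template[[nm]] <- unname(v[[nm]])
  template
}

#' Evaluate the calibration objective at one parameter set
#'
#' Runs one forward simulation with the given controller parameters and
#' returns the weighted sum of curve-mapping errors over the objective's
#' channels.  Deterministic given the parameters.  A simulation instability
#' yields the `penalty` value (flagged via the `"failed"` attribute) so
#' optimizers stay total.
#'
#' @param params a [controller_params()] or named vector of the six values.
#' @param spec an [objective_spec()].
#' @param plant a [plant_config()].
#' @param boundary T1 boundary channels.
#' @param targets target channels containing every channel named in `spec`.
#' @param muscles muscle set.
#' @param penalty objective value reported for failed simulations.
#' @param ... passed to [run_simulation()].
#' @return scalar objective with attributes `terms` (per-channel errors) and
#'   `failed`.
#' @export
evaluate_objective <- function(params, spec, plant, boundary, targets,
                               muscles = default_muscles(plant),
                               penalty = 1e6, ...) {
  if (!inherits(params, "controller_params")) {
    params <- vec_to_params(params)
  }
  missing <- setdiff(names(spec$terms), names(targets))
  stop_if(length(missing) > 0,
          paste("targets missing channels:", paste(missing, collapse = ", ")))
  sim <- tryCatch(
    run_simulation(plant, params, boundary, muscles = muscles, ...),
    error = function(e) e)
  if (inherits(sim, "error")) {
    return(structure(penalty, failed = TRUE, message = conditionMessage(sim)))
  }
  errs <- vapply(names(spec$terms), function(nm) {
    curve_mapping_error(channel(sim$channels, nm), channel(targets, nm))$value
  }, numeric(1))
  structure(sum(spec$terms * errs), terms = errs, failed = FALSE)
}

#' Build an objective closure over the six controller parameters
#'
#' Wraps [evaluate_objective()] into the function-of-a-named-6-vector form
#' the optimizers consume.
#'
#' @inheritParams evaluate_objective
#' @param template a [controller_params()] supplying the non-calibrated
#'   settings (co-contraction floor, rate options).
#' @param ... passed to [evaluate_objective()] / [run_simulation()].
#' @return function mapping a named vector `(kp, kd, tnd, tna_a, tna_d, tne)`
#'   to the scalar objective.
#' @export
make_objective <- function(spec, plant, boundary, targets,
                           muscles = default_muscles(plant),
                           template = controller_params(), ...) {
  function(v) {
    evaluate_objective(vec_to_params(v, template), spec, plant, boundary,
                       targets, muscles = muscles, ...)
  }
}

# greedy D-optimal row selection for a linear model over a candidate pool
# (determinant maximization of X'X with regularized updates)
select_d_optimal <- function(pool, n_select) {
  X <- cbind(1, pool)
  chosen <- integer(0)
  M <- diag(1e-8, ncol(X))
  for (i in seq_len(n_select)) {
    rest <- setdiff(seq_len(nrow(X)), chosen)
    Minv <- solve(M)
    gain <- vapply(rest, function(r) {
      x <- X[r, ]
      drop(1 + t(x) %*% Minv %*% x)
    }, numeric(1))
    pick <- rest[which.max(gain)]
    chosen <- c(chosen, pick)
    M <- M + tcrossprod(X[pick, ])
  }
  chosen
}

# hybrid global/local minimizer of a metamodel within a box: simulated
# annealing start, gradient (L-BFGS-B) polish
minimize_metamodel <- function(fn, lower, upper, start, sa_iter = 200) {
  d <- length(lower)
  x <- pmin(pmax(start, lower), upper)
  fx <- fn(x)
  best <- x; fbest <- fx
  temp <- 1
  for (i in seq_len(sa_iter)) {
    cand <- x + rnorm(d, 0, 0.25 * (upper - lower) * temp)
    cand <- pmin(pmax(cand, lower), upper)
    fc <- fn(cand)
    if (fc < fx || runif(1) < exp((fx - fc) / max(temp, 1e-12))) {
      x <- cand; fx <- fc
      if (fc < fbest) { best <- cand; fbest <- fc }
    }
    temp <- temp * 0.98
  }
  pol <- tryCatch(
    optim(best, fn, method = "L-BFGS-B", lower = lower, upper = upper),
    error = function(e) list(par = best, value = fbest))
  if (pol$value < fbest) pol$par else best
}

#' Sequential response surface (SRSM) parameter identification
#'
#' Metamodel-based optimization with domain reduction: per iteration a
#' candidate pool is drawn in the current trust region (Latin hypercube,
#' 10x the point count), a D-optimal subset of `points_per_iter` points
#' (including the region centre) is evaluated, a linear polynomial metamodel
#' is fitted by least squares and minimized in-region by a hybrid simulated
#' annealing + gradient search, and the region is then shrunk/panned around
#' the predicted optimum.  Stops at `max_iter` iterations or when both the
#' design change and the objective change fall below their tolerances
#' (fractions of the bounds range / current best objective).
#'
#' @param objective function mapping a named 6-vector
#'   (`kp, kd, tnd, tna_a, tna_d, tne`) to a scalar objective (may carry a
#'   `failed` attribute); build one with the internal simulation closure via
#'   [evaluate_objective()], or pass an analytic function for testing.
#' @param bounds a [parameter_bounds()] data.frame.
#' @param points_per_iter simulation points per iteration.
#' @param max_iter maximum number of global iterations.
#' @param tol_design,tol_objective convergence tolerances (1% defaults).
#' @param seed integer seed; the run is deterministic given it.
#' @param init named vector of starting values (defaults to the bounds'
#'   initial column).
#' @param fixed named vector of parameters frozen at given values.
#' @param shrink trust-region contraction factor on oscillation.
#' @param zoom_lo,zoom_start,zoom_hi zoom factors applied to the region
#'   size: at zero move the factor anneals from `zoom_start` (first
#'   iteration) to `zoom_lo` (last), approaching `zoom_hi` for a
#'   full-region move.
#' @param exploit_iters,exploit_frac number of terminal iterations that
#'   contract about the incumbent best point, and the region size (fraction
#'   of the bounds range) they start from.
#' @return an object of class `neck_opt`: `best_params`
#'   ([controller_params()]), `best_vec`, `best_objective`, `history`,
#'   `correlation_matrix`, `converged`, `at_bounds` flags, `seed`.
#' @export
optimize_srsm <- function(objective, bounds = parameter_bounds(),
                          points_per_iter = 11, max_iter = 10,
                          tol_design = 0.01, tol_objective = 0.01,
                          seed = 1, init = NULL, fixed = NULL, shrink = 0.7,
                          zoom_lo = 0.6, zoom_start = 0.8, zoom_hi = 1.0,
                          exploit_iters = 2, exploit_frac = 0.08,
                          center_on = c("predicted", "best")) {
  center_on <- match.arg(center_on)
  pn <- rownames(bounds)
  free <- setdiff(pn, names(fixed))
  full_range <- bounds$upper - bounds$lower
  names(full_range) <- pn
  x_full <- structure(bounds$init, names = pn)
  if (!is.null(init)) x_full[names(init)] <- init
  if (!is.null(fixed)) x_full[names(fixed)] <- fixed

  all_pts <- matrix(numeric(0), 0, length(pn), dimnames = list(NULL, pn))
  all_obj <- numeric(0)
  worst_ok <- -Inf
  eval_pt <- function(v) {
    o <- objective(v)
    if (isTRUE(attr(o, "failed"))) {
      o <- if (is.finite(worst_ok)) 10 * max(worst_ok, 1e-6) else 1e6
    } else {
      worst_ok <<- max(worst_ok, as.numeric(o))
    }
    as.numeric(o)
  }

  if (length(free) == 0) {
    ob <- eval_pt(x_full)
    pts <- matrix(x_full, 1, length(pn), dimnames = list(NULL, pn))
    return(finish_opt(x_full, ob, list(), pts, ob, bounds, TRUE, seed, "srsm"))
  }

  d <- length(free)
  center <- x_full[free]
  region <- structure(full_range[free], names = free)
  history <- list()
  prev_move <- rep(0, d)
  best_v <- x_full; best_o <- Inf; prev_best_o <- Inf
  converged <- FALSE

  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      if (it > max_iter - exploit_iters) {
        # terminal exploitation: contract about the incumbent best point
        center <- best_v[free]
        region <- pmin(region, exploit_frac * full_range[free])
      }
      if (it == 1) {
        # the first iteration screens the whole design space regardless of
        # where the initial point sits (it may be at a bounds corner)
        lo <- structure(bounds[free, "lower"], names = free)
        hi <- structure(bounds[free, "upper"], names = free)
      } else {
        lo <- pmax(center - region / 2, bounds[free, "lower"])
        hi <- pmin(center + region / 2, bounds[free, "upper"])
      }
      pool <- lhs::randomLHS(10 * points_per_iter, d)
      pool <- sweep(sweep(pool, 2, hi - lo, "*"), 2, lo, "+")
      idx <- select_d_optimal(scale01(pool, lo, hi), points_per_iter - 1)
      pts <- rbind(center, pool[idx, , drop = FALSE])
      objs <- numeric(nrow(pts))
      for (r in seq_len(nrow(pts))) {
        v <- x_full
        v[free] <- pts[r, ]
        objs[r] <- eval_pt(v)
        all_pts <- rbind(all_pts, v)
        all_obj <- c(all_obj, objs[r])
        if (objs[r] < best_o) { best_o <- objs[r]; best_v <- v }
      }
      # linear polynomial metamodel by least squares on the scaled region
      Xs <- scale01(pts, lo, hi)
      fit <- lm(objs ~ Xs)
      cf <- coef(fit)
      cf[is.na(cf)] <- 0
      mm <- function(x) drop(cf[1] + sum(cf[-1] * x))
      xs_opt <- minimize_metamodel(mm, rep(0, d), rep(1, d), rep(0.5, d))
      new_center <- lo + xs_opt * (hi - lo)
      if (center_on == "best") {
        # robust variant: follow the best evaluated point, using the
        # metamodel optimum only to break ties with the incumbent centre
        cand <- pts[which.min(objs), ]
        if (min(objs) <= best_o + 1e-15) new_center <- cand
      }
      move <- (new_center - center) / pmax(region, 1e-12)
      history[[it]] <- list(points = pts, objectives = objs,
                            region_lower = lo, region_upper = hi,
                            predicted_optimum = new_center)
      # domain reduction: shrink on oscillation, zoom with small moves,
      # pan (keep size) while the optimum keeps moving one way.  The zoom
      # floor anneals over the iterations: early iterations keep the region
      # wide while the response surface is still being localized, late
      # iterations contract hard for the final polish
      osc <- move * prev_move < 0
      zl <- zoom_start + (zoom_lo - zoom_start) * (it - 1) / max(1, max_iter - 1)
      region <- region * ifelse(osc, shrink, 1) *
        (zl + (zoom_hi - zl) * pmin(abs(move), 1))
      prev_move <- move
      design_change <- max(abs(new_center - center) / full_range[free])
      center <- pmin(pmax(new_center, bounds[free, "lower"]), bounds[free, "upper"])
      obj_change <- abs(best_o - prev_best_o) / max(abs(best_o), 1e-12)
      prev_best_o <- best_o
      if (it > 1 && design_change < tol_design && obj_change < tol_objective) {
        converged <- TRUE
        break
      }
    }
    # evaluate the final predicted optimum (next-iteration centre)
    v <- x_full
    v[free] <- center
    ob <- eval_pt(v)
    all_pts <- rbind(all_pts, v)
    all_obj <- c(all_obj, ob)
    if (ob < best_o) { best_o <- ob; best_v <- v }
  })
  finish_opt(best_v, best_o, history, all_pts, all_obj, bounds, converged,
             seed, "srsm")
}

scale01 <- function(x, lo, hi) {
  sweep(sweep(x, 2, lo, "-"), 2, pmax(hi - lo, 1e-12), "/")
}

finish_opt <- function(best_v, best_o, history, all_pts, all_obj, bounds,
                       converged, seed, method) {
  pn <- rownames(bounds)
  at_lower <- abs(best_v - bounds$lower) < 1e-9 * (bounds$upper - bounds$lower)
  at_upper <- abs(best_v - bounds$upper) < 1e-9 * (bounds$upper - bounds$lower)
  corr <- if (nrow(all_pts) >= 3) {
    parameter_correlations(all_pts)
  } else {
    na <- matrix(NA_real_, length(pn), length(pn), dimnames = list(pn, pn))
    list(matrix = na, labels = matrix(NA_character_, length(pn), length(pn),
                                      dimnames = list(pn, pn)))
  }
  structure(list(best_params = vec_to_params(best_v),
                 best_vec = best_v, best_objective = best_o,
                 history = history, sampled_points = all_pts,
                 sampled_objectives = all_obj,
                 correlation_matrix = corr$matrix,
                 correlation_labels = corr$labels,
                 converged = converged,
                 at_bounds = structure(at_lower | at_upper, names = pn),
                 seed = seed, method = method),
            class = "neck_opt")
}

#' @export
print.neck_opt <- function(x, ...) {
  cat(sprintf("<neck_opt:%s> best objective %.6g (%d evaluations)%s\n",
              x$method, x$best_objective, length(x$sampled_objectives),
              if (x$converged) ", converged" else ""))
  print(round(x$best_vec, 4))
  invisible(x)
}

#' Genetic-algorithm parameter identification
#'
#' Real-coded GA used as the cross-validation optimizer: tournament
#' selection, blend (BLX) crossover, bounded Gaussian mutation, one elite
#' kept per generation, plus verification re-evaluations of the elite after
#' the final generation.  Deterministic given `seed`.
#'
#' @inheritParams optimize_srsm
#' @param pop_size individuals per generation.
#' @param max_iter number of generations.
#' @param verification_iters verification evaluations of the elite.
#' @param p_cross,p_mut,blx_alpha,mut_sd_frac,anneal,tournament,local_frac
#'   GA operator settings (crossover/mutation probabilities, blend width,
#'   mutation scale and its annealing over generations, tournament size,
#'   and the fraction of each generation sampling the elite's
#'   neighbourhood).
#' @return an object of class `neck_opt`.
#' @export
optimize_ga <- function(objective, bounds = parameter_bounds(),
                        pop_size = 30, max_iter = 10, verification_iters = 1,
                        seed = 1, init = NULL, p_cross = 0.9, p_mut = 0.3,
                        blx_alpha = 0.3, mut_sd_frac = 0.1, anneal = 0.95,
                        tournament = 6, local_frac = 0.2) {
  pn <- rownames(bounds)
  d <- length(pn)
  lo <- structure(bounds$lower, names = pn)
  hi <- structure(bounds$upper, names = pn)
  all_pts <- matrix(numeric(0), 0, d, dimnames = list(NULL, pn))
  all_obj <- numeric(0)
  worst_ok <- -Inf
  eval_pt <- function(v) {
    o <- objective(v)
    if (isTRUE(attr(o, "failed"))) {
      o <- if (is.finite(worst_ok)) 10 * max(worst_ok, 1e-6) else 1e6
    } else worst_ok <<- max(worst_ok, as.numeric(o))
    as.numeric(o)
  }
  history <- list()
  best_v <- NULL; best_o <- Inf
  with_seed(seed, {
    pop <- sweep(sweep(lhs::randomLHS(pop_size, d), 2, hi - lo, "*"), 2, lo, "+")
    colnames(pop) <- pn
    pop[1, ] <- if (is.null(init)) bounds$init else init[pn]
    fit <- numeric(pop_size)
    for (i in seq_len(pop_size)) {
      v <- structure(pop[i, ], names = pn)
      fit[i] <- eval_pt(v)
      all_pts <- rbind(all_pts, v); all_obj <- c(all_obj, fit[i])
      if (fit[i] < best_o) { best_o <- fit[i]; best_v <- v }
    }
    history[[1]] <- list(points = pop, objectives = fit, elite = best_o)
    for (gen in seq_len(max_iter - 1)) {
      newpop <- matrix(0, pop_size, d, dimnames = list(NULL, pn))
      newpop[1, ] <- best_v  # elitism
      for (i in 2:pop_size) {
        pick <- function() {
          cand <- sample.int(pop_size, tournament)
          cand[which.min(fit[cand])]
        }
        a <- pop[pick(), ]; b <- pop[pick(), ]
        child <- if (runif(1) < p_cross) {
          clo <- pmin(a, b) - blx_alpha * abs(a - b)
          chi <- pmax(a, b) + blx_alpha * abs(a - b)
          runif(d, clo, chi)
        } else a
        mut <- runif(d) < p_mut
        # mutation scale anneals over the generations
        msd <- mut_sd_frac * (1 - anneal * gen / max(1, max_iter - 1))
        child[mut] <- child[mut] + rnorm(sum(mut), 0, msd * (hi - lo)[mut])
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      # memetic exploitation: a fraction of each generation samples the
      # elite's neighbourhood at the annealed mutation scale
      n_loc <- floor(local_frac * pop_size)
      if (n_loc > 0) {
        msd <- mut_sd_frac * (1 - anneal * gen / max(1, max_iter - 1))
        for (i in seq_len(n_loc)) {
          cand <- best_v + rnorm(d, 0, 0.5 * msd * (hi - lo))
          newpop[pop_size - i + 1, ] <- pmin(pmax(cand, lo), hi)
        }
      }
      pop <- newpop
      for (i in seq_len(pop_size)) {
        v <- structure(pop[i, ], names = pn)
        fit[i] <- eval_pt(v)
        all_pts <- rbind(all_pts, v); all_obj <- c(all_obj, fit[i])
        if (fit[i] < best_o) { best_o <- fit[i]; best_v <- v }
      }
      history[[gen + 1]] <- list(points = pop, objectives = fit, elite = best_o)
    }
    for (k in seq_len(verification_iters)) {
      ov <- eval_pt(best_v)
      all_pts <- rbind(all_pts, best_v); all_obj <- c(all_obj, ov)
      if (ov < best_o) best_o <- ov
    }
  })
  finish_opt(best_v, best_o, history, all_pts, all_obj, bounds, TRUE, seed, "ga")
}

#' Second validation optimization chained from a GA optimum
#'
#' Restarts the metamodel (SRSM) optimizer from a genetic-algorithm optimum
#' with only `kp` and `kd` free; the four time constants stay frozen at the
#' GA optimum values.
#'
#' @param objective objective closure as for [optimize_srsm()].
#' @param bounds a [parameter_bounds()].
#' @param ga_result a `neck_opt` from [optimize_ga()].
#' @param free parameters left free (default `kp`, `kd`).
#' @param ... passed to [optimize_srsm()].
#' @return an object of class `neck_opt`.
#' @export
chained_validation <- function(objective, bounds = parameter_bounds(),
                               ga_result, free = c("kp", "kd"), ...) {
  stopifnot(inherits(ga_result, "neck_opt"))
  pn <- rownames(bounds)
  fixed <- ga_result$best_vec[setdiff(pn, free)]
  optimize_srsm(objective, bounds, init = ga_result$best_vec,
                fixed = fixed, ...)
}

#' Linear correlation matrix of sampled parameters
#'
#' Pearson correlations over all parameter vectors evaluated during an
#' optimization, with each off-diagonal entry categorized by magnitude:
#' weak (|r| <= 0.29), medium (0.30-0.49), strong (0.50-1.00); the
#' categorization is applied to |r| rounded to two decimals.  Frozen
#' (zero-variance) parameters yield undefined (`NA`) entries.
#'
#' @param history matrix of sampled parameter vectors (rows = evaluations),
#'   or a `neck_opt` object.
#' @return list with `matrix` (6x6 correlations) and `labels`.
#' @export
parameter_correlations <- function(history) {
  pts <- if (inherits(history, "neck_opt")) history$sampled_points else as.matrix(history)
  stop_if(nrow(pts) < 3, "need at least 3 sampled points")
  sds <- apply(pts, 2, sd)
  cm <- suppressWarnings(cor(pts))
  cm[sds == 0, ] <- NA
  cm[, sds == 0] <- NA
  diag(cm) <- ifelse(sds == 0, NA, 1)
  labels <- matrix(correlation_label(cm), nrow(cm), ncol(cm),
                   dimnames = dimnames(cm))
  diag(labels) <- NA
  list(matrix = cm, labels = labels)
}

#' @param r correlation value(s).
#' @rdname parameter_correlations
#' @export
correlation_label <- function(r) {
  a <- round(abs(r), 2)
  out <- ifelse(is.na(a), NA_character_,
                ifelse(a <= 0.29, "weak",
                       ifelse(a <= 0.49, "medium", "strong")))
  out
}
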