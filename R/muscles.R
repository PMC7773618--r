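#' Hill-type line muscle elements
#'
#' A muscle element is a line-of-action actuator: an ordered list of
#' attachment points, each fixed to one segment of the chain (0 = T1,
#' 1..7 = C7..C1, 8 = head), with a physiological cross-sectional area,
#' maximum isometric stress, and a preferred recruitment direction in the
#' spatial-tuning plane (0 = forward/flexion demand, pi = rearward/extension).
#'
#' The element force is
#' `F = PCSA * sigma_max * (Na * fv(v) * fl(l) + fpe(l))`, clamped at zero
#' (muscles pull only), with `fl` a Gaussian active force-length curve,
#' `fv` a hyperbolic force-velocity curve saturating eccentrically, and
#' `fpe` an exponential passive curve; see [muscle_mechanics()].
#'
#' @param name identifier.
#' @param segments integer vector: segment index of each path point.
#' @param points 2 x n matrix of local (x, z) attachment coordinates, m.
#' @param pcsa_m2 physiological cross-sectional area, m^2.
#' @param sigma_max_Pa maximum isometric stress, Pa.
#' @param optimal_length_m length at the active force-length peak, m.
#' @param slack_length_m passive-force slack length, m (<= optimal).
#' @param preferred_direction_rad spatial-tuning preferred direction.
#' @return an object of class `muscle_element`.
#' @export
muscle_element <- function(name, segments, points, pcsa_m2, sigma_max_Pa,
                           optimal_length_m, slack_length_m = optimal_length_m,
                           preferred_direction_rad = pi) {
  segments <- as.integer(segments)
  points <- as.matrix(points)
  stop_if(length(segments) < 2, "muscle path needs at least 2 points")
  stop_if(nrow(points) != 2 || ncol(points) != length(segments),
          "points must be a 2 x n matrix matching segments")
  stop_if(length(unique(segments)) < 2, "muscle path must span at least one joint")
  stop_if(pcsa_m2 <= 0 || sigma_max_Pa <= 0, "pcsa and sigma_max must be positive")
  stop_if(!(slack_length_m > 0 && slack_length_m <= optimal_length_m),
          "need 0 < slack_length <= optimal_length")
  structure(list(name = name, segments = segments, points = points,
                 pcsa_m2 = pcsa_m2, sigma_max_Pa = sigma_max_Pa,
                 optimal_length_m = optimal_length_m,
                 slack_length_m = slack_length_m,
                 preferred_direction_rad = preferred_direction_rad),
            class = "muscle_element")
}

#' Muscle mechanics constants
#'
#' All constants of the force-length, force-velocity and passive curves in one
#' place.  Defaults: Gaussian force-length of width 0.56; hyperbolic
#' force-velocity with maximum shortening velocity of 5 optimal lengths per
#' second, curvature 0.25, eccentric saturation 1.5 approached with velocity
#' scale 0.15 vmax; exponential passive curve reaching ~0.6 of isometric
#' force at 50% stretch beyond slack.
#'
#' @param fl_width width of the Gaussian force-length curve (dimensionless).
#' @param vmax_lopt_per_s maximum shortening velocity, optimal lengths / s.
#' @param fv_af force-velocity curvature parameter.
#' @param fv_ecc_max eccentric force saturation factor.
#' @param fv_ecc_b eccentric velocity scale as a fraction of vmax.
#' @param fpe_scale,fpe_shape passive curve `fpe = scale * (exp(shape*eps)-1)`
#'   with `eps = (l - slack)/optimal`.
#' @return a named list of class `muscle_mechanics`.
#' @export
muscle_mechanics <- function(fl_width = 0.56, vmax_lopt_per_s = 5,
                             fv_af = 0.25, fv_ecc_max = 1.5, fv_ecc_b = 0.15,
                             fpe_scale = 0.05, fpe_shape = 5) {
  structure(list(fl_width = fl_width, vmax_lopt_per_s = vmax_lopt_per_s,
                 fv_af = fv_af, fv_ecc_max = fv_ecc_max, fv_ecc_b = fv_ecc_b,
                 fpe_scale = fpe_scale, fpe_shape = fpe_shape),
            class = "muscle_mechanics")
}

#' Force-curve components
#'
#' @param l current length, m; `v` rate of length change, m/s (positive =
#'   lengthening).
#' @param l_opt optimal length, m; `l_slack` passive slack length, m.
#' @param mech a [muscle_mechanics()] object.
#' @return dimensionless force factors.
#' @export
fl_curve <- function(l, l_opt, mech = muscle_mechanics()) {
  exp(-(((l / l_opt) - 1) / mech$fl_width)^2)
}

#' @rdname fl_curve
#' @param v rate of length change, m/s.
#' @export
fv_curve <- function(v, l_opt, mech = muscle_mechanics()) {
  vmax <- mech$vmax_lopt_per_s * l_opt
  ifelse(v <= -vmax, 0,
         ifelse(v <= 0, (vmax + v) / (vmax - v / mech$fv_af),
                mech$fv_ecc_max - (mech$fv_ecc_max - 1) * (mech$fv_ecc_b * vmax) /
                  (v + mech$fv_ecc_b * vmax)))
}

#' @rdname fl_curve
#' @export
fpe_curve <- function(l, l_slack, l_opt, mech = muscle_mechanics()) {
  eps <- (l - l_slack) / l_opt
  ifelse(eps <= 0, 0, mech$fpe_scale * (exp(mech$fpe_shape * eps) - 1))
}

#' Muscle state
#'
#' @param length_m current path length, m (> 0).
#' @param velocity_mps rate of length change, m/s.
#' @param activation activation level Na in `[0, 1]`.
#' @return a list of class `muscle_state`.
#' @export
muscle_state <- function(length_m, velocity_mps = 0, activation = 0) {
  stop_if(!all(is.finite(c(length_m, velocity_mps, activation))),
          "muscle state values must be finite")
  stop_if(length_m <= 0, "muscle length must be positive")
  stop_if(activation < 0 || activation > 1, "activation must be in [0, 1]")
  structure(list(length_m = length_m, velocity_mps = velocity_mps,
                 activation = activation), class = "muscle_state")
}

#' Tensile force of one muscle element
#'
#' @param element a [muscle_element()].
#' @param state a [muscle_state()].
#' @param mech a [muscle_mechanics()] object.
#' @return force in N, always >= 0 (tension only).
#' @export
muscle_force <- function(element, state, mech = muscle_mechanics()) {
  if (!inherits(state, "muscle_state")) state <- do.call(muscle_state, state)
  f <- element$pcsa_m2 * element$sigma_max_Pa *
    (state$activation * fv_curve(state$velocity_mps, element$optimal_length_m, mech) *
       fl_curve(state$length_m, element$optimal_length_m, mech) +
       fpe_curve(state$length_m, element$slack_length_m, element$optimal_length_m, mech))
  max(f, 0)
}

# --- geometry -------------------------------------------------------------

# absolute link angles from relative joint angles
abs_angles <- function(joint_angles, base_ry = 0) base_ry + cumsum(joint_angles)

link_dir <- function(phi) rbind(-sin(phi), cos(phi))
rot_local <- function(phi, w) {
  rbind(w[1] * cos(phi) - w[2] * sin(phi), w[1] * sin(phi) + w[2] * cos(phi))
}
rot_local_deriv <- function(phi, w) {
  rbind(-w[1] * sin(phi) - w[2] * cos(phi), w[1] * cos(phi) - w[2] * sin(phi))
}

# joint positions (2 x n matrix; column j = proximal joint of link j)
fk_joints <- function(cfg, phi, base_pos = c(0, 0)) {
  n <- length(phi)
  P <- matrix(0, 2, n)
  P[, 1] <- base_pos
  for (j in seq_len(n - 1)) P[, j + 1] <- P[, j] + cfg$link_lengths_m[j] * link_dir(phi[j])
  P
}

fk_point <- function(cfg, phi, base_pos, base_ry, seg, local) {
  if (seg == 0) return(base_pos + drop(rot_local(base_ry, local)))
  P <- fk_joints(cfg, phi, base_pos)
  P[, seg] + drop(rot_local(phi[seg], local))
}

head_cg_position <- function(cfg, joint_angles, base_pos = c(0, 0), base_ry = 0) {
  phi <- abs_angles(joint_angles, base_ry)
  n <- length(phi)
  P <- fk_joints(cfg, phi, base_pos)
  P[, n] + drop(rot_local(phi[n], cfg$head_cg_offset_m))
}

#' Muscle path length and lengthening velocity
#'
#' Straight-line path length over the polyline of attachment points after
#' forward kinematics, and its analytic time derivative given joint rates.
#'
#' @param element a [muscle_element()].
#' @param plant a [plant_config()].
#' @param joint_angles relative joint angles (rad), one per joint.
#' @param joint_rates relative joint rates (rad/s).
#' @param base list with `pos` (2-vector, m), `ry` (rad), `vel` (2-vector,
#'   m/s), `w` (rad/s) describing the prescribed T1 base.
#' @return list with `length_m` and `velocity_mps`.
#' @export
path_length_and_velocity <- function(element, plant, joint_angles,
                                     joint_rates = rep(0, length(joint_angles)),
                                     base = list(pos = c(0, 0), ry = 0,
                                                 vel = c(0, 0), w = 0)) {
  n <- length(plant$link_lengths_m)
  stop_if(length(joint_angles) != n || length(joint_rates) != n,
          "need one angle and one rate per joint")
  check_finite(c(joint_angles, joint_rates), "joint angles/rates")
  phi <- abs_angles(joint_angles, base$ry)
  phid <- base$w + cumsum(joint_rates)
  P <- fk_joints(plant, phi, base$pos)
  np <- length(element$segments)
  W <- matrix(0, 2, np)
  for (a in seq_len(np)) {
    s <- element$segments[a]
    W[, a] <- if (s == 0) base$pos + drop(rot_local(base$ry, element$points[, a]))
              else P[, s] + drop(rot_local(phi[s], element$points[, a]))
  }
  len <- 0
  grad <- numeric(n + 1)  # index 1 = base rotation, 2..n+1 = phi_1..phi_n
  dpoint <- function(a, k) {
    s <- element$segments[a]
    if (k == 0) {
      if (s == 0) drop(rot_local_deriv(base$ry, element$points[, a])) else c(0, 0)
    } else if (s == 0 || k > s) c(0, 0)
    else if (k < s) plant$link_lengths_m[k] * c(-cos(phi[k]), -sin(phi[k]))
    else drop(rot_local_deriv(phi[s], element$points[, a]))
  }
  for (a in seq_len(np - 1)) {
    d <- W[, a + 1] - W[, a]
    dl <- sqrt(sum(d^2))
    stop_if(dl < 1e-12, sprintf("degenerate zero-length path segment %d in '%s'",
                                a, element$name))
    e <- d / dl
    len <- len + dl
    for (k in 0:n) {
      grad[k + 1] <- grad[k + 1] + sum(e * (dpoint(a + 1, k) - dpoint(a, k)))
    }
  }
  vel <- grad[1] * base$w + sum(grad[-1] * phid)
  list(length_m = len, velocity_mps = vel, dlength_dangle = grad)
}

#' Default sagittal muscle set
#'
#' Eight line actuators: four extensor groups (posterior paths, preferred
#' direction pi) and four exactly mirrored flexor groups (anterior paths,
#' preferred direction 0), spanning 2-8 joints with via points.  The
#' mirrored geometry makes the co-contraction floor torques cancel in the
#' near-straight posture so baseline tone balances the head statically.
#' Optimal lengths are taken as the path length at the configured initial
#' alignment (slack = optimal, so passive force is zero at rest).
#'
#' @param plant a [plant_config()].
#' @param sigma_max_Pa maximum isometric stress applied to all groups.
#' @return list of [muscle_element()] objects.
#' @export
default_muscles <- function(plant, sigma_max_Pa = 1e6) {
  spec <- list(
    list(name = "multifidus", segs = c(0L, 3L), x = c(0.030, 0.030),
         z = c(0, 0.008), pcsa = 3.0e-4),
    list(name = "semispinalis_cervicis", segs = c(0L, 5L, 7L),
         x = c(0.035, 0.033, 0.030), z = c(0, 0.008, 0.010), pcsa = 3.5e-4),
    list(name = "splenius_capitis", segs = c(1L, 8L), x = c(0.035, 0.042),
         z = c(0.005, 0.020), pcsa = 2.5e-4),
    list(name = "semispinalis_capitis", segs = c(0L, 4L, 8L),
         x = c(0.040, 0.037, 0.048), z = c(0, 0.008, 0.030), pcsa = 3.0e-4))
  out <- list()
  for (sgn in c(-1, 1)) {   # -1 = posterior/extensor, +1 = anterior/flexor
    for (sp in spec) {
      nm <- paste0(if (sgn < 0) "ext_" else "flex_", sp$name)
      pts <- rbind(sgn * sp$x, sp$z)
      el <- muscle_element(nm, sp$segs, pts, sp$pcsa, sigma_max_Pa,
                           optimal_length_m = 1,  # placeholder, set below
                           slack_length_m = 1,
                           preferred_direction_rad = if (sgn < 0) pi else 0)
      l0 <- path_length_and_velocity(el, plant, plant$initial_alignment_rad)$length_m
      el$optimal_length_m <- l0
      el$slack_length_m <- l0
      out[[nm]] <- el
    }
  }
  out
}

# list handed to the C++ core
muscles_core_list <- function(muscles) {
  lapply(muscles, function(m) {
    list(seg = m$segments, pts = m$points,
         fmax = m$pcsa_m2 * m$sigma_max_Pa,
         lopt = m$optimal_length_m, lslack = m$slack_length_m,
         pref = m$preferred_direction_rad)
  })
}

mech_core_list <- function(mech) unclass(mech)
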