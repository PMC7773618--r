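#' Plant configuration for the sagittal head-neck chain
#'
#' The head-neck complex is modelled as a planar chain of eight rigid links
#' riding on a prescribed T1 base: seven cervical segments (C7 up to C1) and
#' the head.  Each joint carries a linear rotational spring (rest position at
#' the configured initial alignment) and a viscous damper.  All values are
#' surrogate constants chosen to give head excursions of volunteer order under
#' the default synthetic pulse; they are configuration, not anatomical truth.
#'
#' Coordinates: x forward (sled direction), z up; link angles are measured
#' from vertical and are positive in extension (head rotating rearward).
#'
#' @param link_lengths_m lengths of the 8 links (C7..C1 segments, head), m.
#' @param segment_masses_kg per-link mass, kg.
#' @param segment_inertias_kgm2 per-link rotational inertia about the
#'   proximal joint, kg m^2.
#' @param joint_stiffness_Nm_per_rad per-joint rotational stiffness.
#' @param joint_damping_Nms_per_rad per-joint rotational damping.
#' @param initial_alignment_rad per-joint initial relative angle; a mildly
#'   lordotic posture by default (negative = forward/flexed lower joints).
#' @param gravity_mps2 gravitational acceleration, m/s^2.
#' @param head_cg_offset_m head centre of gravity relative to the C1-head
#'   joint in the head frame (x forward, z up), m.
#' @param dt_ms default integrator step, ms.
#' @return an object of class `plant_config`.
#' @export
plant_config <- function(link_lengths_m = c(rep(0.017, 7), 0.09),
                         segment_masses_kg = c(rep(0.2, 7), 3.6),
                         segment_inertias_kgm2 = c(rep(5e-4, 7), 0.029),
                         joint_stiffness_Nm_per_rad = rep(40, 8),
                         joint_damping_Nms_per_rad = rep(0.35, 8),
                         initial_alignment_rad = c(-0.03, -0.022, -0.015,
                                                   -0.007, 0.007, 0.015,
                                                   0.022, 0.03),
                         gravity_mps2 = 9.81,
                         head_cg_offset_m = c(0, 0.055),
                         dt_ms = 0.5) {
  cfg <- list(link_lengths_m = as.numeric(link_lengths_m),
              segment_masses_kg = as.numeric(segment_masses_kg),
              segment_inertias_kgm2 = as.numeric(segment_inertias_kgm2),
              joint_stiffness_Nm_per_rad = as.numeric(joint_stiffness_Nm_per_rad),
              joint_damping_Nms_per_rad = as.numeric(joint_damping_Nms_per_rad),
              initial_alignment_rad = as.numeric(initial_alignment_rad),
              gravity_mps2 = as.numeric(gravity_mps2),
              head_cg_offset_m = as.numeric(head_cg_offset_m),
              dt_ms = as.numeric(dt_ms))
  validate_plant_config(structure(cfg, class = "plant_config"))
}

validate_plant_config <- function(cfg, n_joints = 8L) {
  n <- length(cfg$link_lengths_m)
  stop_if(n != n_joints && n_joints == 8L && !isTRUE(attr(cfg, "any_n")),
          sprintf("exactly 8 joints required (C7..C1 + head), got %d", n))
  for (f in c("segment_masses_kg", "segment_inertias_kgm2",
              "joint_stiffness_Nm_per_rad", "joint_damping_Nms_per_rad",
              "initial_alignment_rad")) {
    stop_if(length(cfg[[f]]) != n, sprintf("%s must have length %d", f, n))
  }
  for (f in c("link_lengths_m", "segment_masses_kg", "segment_inertias_kgm2",
              "joint_stiffness_Nm_per_rad", "joint_damping_Nms_per_rad")) {
    stop_if(any(!is.finite(cfg[[f]])) || any(cfg[[f]] <= 0),
            sprintf("%s must be strictly positive", f))
  }
  stop_if(length(cfg$head_cg_offset_m) != 2, "head_cg_offset_m must be a 2-vector")
  stop_if(!is.finite(cfg$gravity_mps2) || cfg$gravity_mps2 < 0,
          "gravity must be finite and non-negative")
  # inertia about the COM (parallel axis from the joint) must stay positive
  ic <- inertia_com(cfg)
  stop_if(any(ic <= 0), "segment inertia too small for its COM offset")
  cfg
}

# local COM offsets (2 x n): mid-link for vertebral segments, configured
# offset for the head (last link)
com_local <- function(cfg) {
  n <- length(cfg$link_lengths_m)
  r <- rbind(rep(0, n), cfg$link_lengths_m / 2)
  r[, n] <- cfg$head_cg_offset_m
  r
}

inertia_com <- function(cfg) {
  r <- com_local(cfg)
  cfg$segment_inertias_kgm2 - cfg$segment_masses_kg * colSums(r^2)
}

# list handed to the C++ core
plant_core_list <- function(cfg) {
  list(link_lengths = cfg$link_lengths_m,
       segment_masses = cfg$segment_masses_kg,
       segment_inertias_com = inertia_com(cfg),
       joint_stiffness = cfg$joint_stiffness_Nm_per_rad,
       joint_damping = cfg$joint_damping_Nms_per_rad,
       rest_angles = cfg$initial_alignment_rad,
       com_local = com_local(cfg),
       gravity = cfg$gravity_mps2)
}

#' Read or write a plant configuration (YAML or JSON)
#'
#' Field names carry explicit units (`_m`, `_kg`, `_Nm_per_rad`, ...).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_plant_config` returns a [plant_config()].
#' @export
read_plant_config <- function(path) {
  obj <- read_config_file(path)
  do.call(plant_config, obj[names(obj) %in% names(formals(plant_config))])
}

#' @param cfg a `plant_config` object.
#' @rdname read_plant_config
#' @export
write_plant_config <- function(cfg, path) {
  write_config_file(unclass(cfg), path)
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
}

write_config_file <- function(obj, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
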