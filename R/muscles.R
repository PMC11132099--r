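#' Model configuration defaults
#'
#' Tunable constants of the reduced glenohumeral model: muscle physiological
#' cross-sectional areas (cm^2, literature-ratio table), specific tension
#' (N/cm^2) setting the absolute strength scale, the deltoid wrap-sphere
#' margin over the humeral head (mm), the glenohumeral fraction of
#' humerothoracic elevation (2:1 scapulohumeral rhythm -> 2/3), hand load
#' (N), cartilage offset (mm), the generic-model reference glenoid height
#' (mm) and reference body mass (kg), the elevation grid, and solver
#' tolerances.
#'
#' @param ... named overrides of any default.
#' @return a named list of configuration values.
#' @export
model_config <- function(...) {
  cfg <- list(
    pcsa_cm2 = c(deltoid_anterior = 8.9, deltoid_lateral = 9.0,
                 deltoid_posterior = 7.1, supraspinatus = 6.7,
                 infraspinatus_superior = 5.3, infraspinatus_inferior = 5.3,
                 subscapularis_superior = 8.2, subscapularis_inferior = 8.2,
                 teres_minor = 3.0),
    specific_tension = 60,     # N/cm^2
    wrap_margin = 4,           # mm over the humeral head radius
    gh_fraction = 2 / 3,       # glenohumeral share of elevation (2:1 rhythm)
    hand_load = 10,            # N
    cartilage_offset = 2,      # mm
    reference_glenoid_height = 36,  # mm (generic model glenoid height)
    reference_mass = 75,       # kg at 1800 mm stature
    n_increments = 12,
    arc_max = 120,             # degrees
    gravity = 9.81,            # m/s^2
    solver_tol = 1e-8,
    use_cone = TRUE,
    cone_scale = 1.5)  # capsulolabral allowance beyond the bony rim polygon
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  cfg
}

#' A single line-of-action muscle element
#'
#' @param name muscle name.
#' @param origin 3-D origin on the scapula/acromion, mm.
#' @param insertion 3-D insertion in the humeral frame relative to the joint
#'   centre (neutral pose), mm.
#' @param strength maximum force, N (> 0).
#' @param wrap optional list(center, radius) wrap sphere.
#' @return an object of class `muscle_element`.
#' @export
muscle_element <- function(name, origin, insertion, strength, wrap = NULL) {
  if (strength <= 0) stop("muscle strength must be positive")
  if (vnorm(as.numeric(origin) - as.numeric(insertion)) < 1e-9)
    stop("muscle origin and insertion coincide")
  structure(list(name = name, origin = as.numeric(origin),
                 insertion = as.numeric(insertion), strength = strength,
                 wrap = wrap), class = "muscle_element")
}

# scapular frame (lateral, superior, anterior) derived from landmarks;
# anterior is resolved via the anterior glenoid landmark so left-mirrored
# shoulders keep anatomical sign semantics
scapular_frame <- function(landmarks) {
  lm <- unclass(landmarks)
  gc <- (lm["glenoid_superior", ] + lm["glenoid_inferior", ]) / 2
  e_lat <- unitize(gc - lm["angulus_superior", ])
  sup0 <- lm["glenoid_superior", ] - lm["glenoid_inferior", ]
  e_sup <- unitize(sup0 - sum(sup0 * e_lat) * e_lat)
  e_ant <- cross3(e_lat, e_sup)
  if (sum(e_ant * (lm["glenoid_anterior", ] - gc)) < 0) e_ant <- -e_ant
  list(origin = gc, lat = e_lat, sup = e_sup, ant = e_ant)
}

#' Build the nine-element muscle set for a fitted shoulder
#'
#' Three deltoid parts originating on the acromial arch (so they move with
#' the critical shoulder angle and acromial offset), the four rotator cuff
#' muscles split into the analysed bundles (supraspinatus, superior/inferior
#' infraspinatus, superior/inferior subscapularis) plus teres minor on the
#' scapular body. Strengths are proportional to the configured physiological
#' cross-sectional areas. Deltoid elements wrap a sphere centred at the
#' joint centre (the humeral head centre) with radius bone radius +
#' `wrap_margin`.
#'
#' @param joint a `joint_geometry` from [fit_joint_geometry()].
#' @param landmarks the subject's `landmark_set`.
#' @param config a [model_config()] list.
#' @return a list of nine `muscle_element`s.
#' @export
build_muscles <- function(joint, landmarks, config = model_config()) {
  fr <- scapular_frame(landmarks)
  lm <- unclass(landmarks)
  s <- vnorm(lm["glenoid_superior", ] - lm["glenoid_inferior", ]) / 36
  gc <- joint$glenoid_center
  at <- function(base, off) base + s * (off[1] * fr$lat + off[2] * fr$sup + off[3] * fr$ant)
  tip <- (lm["anterolateral_acromion", ] + lm["posterolateral_acromion", ]) / 2
  r <- joint$humeral_radius_bone
  ins <- function(off_r) r * (off_r[1] * fr$lat + off_r[2] * fr$sup + off_r[3] * fr$ant)
  strengths <- config$pcsa_cm2 * config$specific_tension
  wrap <- list(center = joint$joint_center, radius = r + config$wrap_margin)
  mk <- function(name, origin, insertion, wrapped = FALSE) {
    muscle_element(name, origin, insertion, strengths[[name]],
                   wrap = if (wrapped) wrap else NULL)
  }
  list(
    mk("deltoid_anterior", at(lm["anterolateral_acromion", ], c(0, 2, 8)),
       ins(c(0.8, -5.2, 0.1)), wrapped = TRUE),
    mk("deltoid_lateral", at(tip, c(2, 3, 0)),
       ins(c(0.8, -5.2, 0)), wrapped = TRUE),
    mk("deltoid_posterior", at(lm["posterolateral_acromion", ], c(-8, 2, -6)),
       ins(c(0.8, -5.2, -0.1)), wrapped = TRUE),
    mk("supraspinatus", at(gc, c(-55, 4, -2)), ins(c(0.45, 0.92, 0))),
    mk("infraspinatus_superior", at(gc, c(-50, -22, -5)), ins(c(0.72, 0.45, -0.55))),
    mk("infraspinatus_inferior", at(gc, c(-45, -42, -5)), ins(c(0.78, 0.12, -0.62))),
    mk("subscapularis_superior", at(gc, c(-45, -10, 5)), ins(c(0.55, 0.38, 0.68))),
    mk("subscapularis_inferior", at(gc, c(-40, -32, 6)), ins(c(0.62, 0.02, 0.72))),
    mk("teres_minor", at(gc, c(-20, -55, -4)), ins(c(0.66, -0.25, -0.68))))
}

#' Elevation pose on the simulation grid
#'
#' @param motion `"abduction"` (frontal plane) or `"flexion"` (sagittal
#'   plane).
#' @param elevation_angle humerothoracic elevation, degrees in [0, 120].
#' @param gh_fraction glenohumeral fraction of elevation (default 2/3, the
#'   2:1 scapulohumeral rhythm); the scapula rotates by the remainder.
#' @return an object of class `gh_pose` with the motion axis and the humeral
#'   and scapular rotation matrices.
#' @export
gh_pose <- function(motion = c("abduction", "flexion"), elevation_angle,
                    gh_fraction = 2 / 3) {
  motion <- match.arg(motion)
  if (elevation_angle < 0 || elevation_angle > 120)
    stop("elevation_angle must lie in [0, 120] degrees")
  axis <- if (motion == "abduction") c(0, 0, 1) else c(-1, 0, 0)
  structure(list(motion = motion, elevation_angle = elevation_angle,
                 scapular_upward_rotation = elevation_angle * (1 - gh_fraction),
                 axis = axis,
                 R_humerus = rotation_about(axis, elevation_angle),
                 R_scapula = rotation_about(axis, elevation_angle * (1 - gh_fraction))),
            class = "gh_pose")
}

# tangent departure direction for a sphere wrap: unit force direction applied
# to the humeral system by a muscle wrapping a sphere centred at `center`
wrap_path <- function(origin, insertion, center, radius) {
  o <- origin - center; i <- insertion - center
  d_line <- vnorm(cross3(i, o - i)) / vnorm(o - i)
  # does the segment (not its extension) come closer than the radius?
  t_star <- sum((o - i) * (-i)) / sum((o - i)^2)
  penetrates <- d_line < radius && t_star > 0 && t_star < 1 &&
    vnorm(o) > radius && vnorm(i) > radius
  if (!penetrates) {
    u <- unitize(origin - insertion)
    return(list(force_dir = u, moment = cross3(i, u), wrapped = FALSE))
  }
  m_hat <- unitize(cross3(i, o))
  e1 <- unitize(i)
  e2 <- cross3(m_hat, e1)
  o2d <- c(sum(o * e1), sum(o * e2))
  po <- vnorm(o2d)
  a_o <- atan2(o2d[2], o2d[1])
  t_ang <- a_o - acos(min(1, radius / po))   # tangent point toward the insertion side
  Tpt <- radius * (cos(t_ang) * e1 + sin(t_ang) * e2)
  u <- unitize(o - Tpt)
  list(force_dir = u, moment = radius * m_hat, wrapped = TRUE)
}

# per-pose unit wrench (force direction on the humerus and moment about the
# joint centre per newton of tension) for every muscle
muscle_system <- function(muscles, pose, joint, config = model_config()) {
  jc <- joint$joint_center
  Rh <- if (is.null(pose)) diag(3) else pose$R_humerus
  Rs <- if (is.null(pose)) diag(3) else pose$R_scapula
  n <- length(muscles)
  U <- matrix(0, 3, n); Mv <- matrix(0, 3, n)
  names_ <- character(n); strengths <- numeric(n); wrapped <- logical(n)
  for (k in seq_len(n)) {
    m <- muscles[[k]]
    origin_w <- jc + as.numeric(Rs %*% (m$origin - jc))
    insertion_w <- jc + as.numeric(Rh %*% m$insertion)
    if (!is.null(m$wrap)) {
      wp <- wrap_path(origin_w, insertion_w, jc, m$wrap$radius)
    } else {
      u <- unitize(origin_w - insertion_w)
      wp <- list(force_dir = u, moment = cross3(insertion_w - jc, u), wrapped = FALSE)
    }
    U[, k] <- wp$force_dir; Mv[, k] <- wp$moment
    names_[k] <- m$name; strengths[k] <- m$strength; wrapped[k] <- wp$wrapped
  }
  frame <- list(
    n = as.numeric(Rs %*% joint$glenoid_plane_normal),
    sup = as.numeric(Rs %*% (joint$e_superior %||% c(0, 1, 0))),
    ant = as.numeric(Rs %*% (joint$e_anterior %||% c(0, 0, 1))))
  rim <- NULL
  if (!is.null(joint$rim_points)) {
    rp <- as.matrix(joint$rim_points)
    rim <- sweep(sweep(rp, 2, jc, `-`) %*% t(Rs), 2, jc, `+`)
  }
  list(U = U, moments = Mv, names = names_, strengths = strengths,
       wrapped = wrapped, joint_center = jc, frame = frame, rim = rim,
       axis = if (is.null(pose)) c(0, 0, 1) else pose$axis)
}

#' Moment arm of a muscle about the motion axis
#'
#' Signed moment (mm per newton of tension) of the muscle's line of action
#' about the joint centre, projected on the instantaneous motion axis;
#' positive values are agonists of the motion, negative moment arms
#' facilitate the antagonistic motion. Deltoid elements take the tangent-arc
#' path around their wrap sphere; a line through the joint centre returns 0.
#'
#' @param muscle a `muscle_element`.
#' @param pose a [gh_pose()] (or `NULL` for the neutral pose).
#' @param joint a `joint_geometry`.
#' @param config a [model_config()] list.
#' @return moment arm in mm.
#' @export
moment_arm <- function(muscle, pose, joint, config = model_config()) {
  sys <- muscle_system(list(muscle), pose, joint, config)
  sum(sys$moments[, 1] * sys$axis)
}

# inward-oriented half-space normals of the stability cone built from the
# rim polygon edges and the joint-centre apex; rows are unit normals m_k with
# stability <=> m_k . G >= 0 for the glenoid-directed reaction G
cone_constraints <- function(rim, apex, scale = 1) {
  rim <- as.matrix(rim)
  ctr <- colMeans(rim)
  if (scale != 1) rim <- sweep(sweep(rim, 2, ctr, `-`) * scale, 2, ctr, `+`)
  nr <- nrow(rim)
  M <- matrix(0, nr, 3)
  for (k in seq_len(nr)) {
    k2 <- if (k == nr) 1L else k + 1L
    m <- cross3(rim[k, ] - apex, rim[k2, ] - apex)
    if (sum(m * (ctr - apex)) < 0) m <- -m
    M[k, ] <- m / vnorm(m)
  }
  M
}
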