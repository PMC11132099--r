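#' Quasi-static external moment the muscles must balance
#'
#' Gravitational moment of the straight arm (upper arm + forearm + hand,
#' standard anthropometric segment fractions of stature and body mass) plus
#' the hand-held load, about the glenohumeral joint centre, at a given
#' elevation pose. No inertial terms: the motion arcs are slow. The returned
#' `moment` is the moment the muscle set must generate (the negative of the
#' external moment); `external_force` is the total gravity + load force on
#' the arm, used downstream for the joint reaction.
#'
#' @param pose a [gh_pose()].
#' @param body output of [scale_patient()] (stature and mass).
#' @param hand_load load held in the hand, N (default 10).
#' @param config a [model_config()] list.
#' @return list with `moment` (3-vector, N mm) and `external_force`
#'   (3-vector, N).
#' @export
required_moment <- function(pose, body, hand_load = 10, config = model_config()) {
  h <- body$height_mm; mass <- body$body_mass_kg
  g <- config$gravity
  L_ua <- 0.186 * h; L_fa <- 0.146 * h; L_ha <- 0.108 * h
  segs <- list(
    list(m = 0.028 * mass, d = 0.436 * L_ua),
    list(m = 0.016 * mass, d = L_ua + 0.430 * L_fa),
    list(m = 0.006 * mass, d = L_ua + L_fa + 0.506 * L_ha))
  dirn <- as.numeric(pose$R_humerus %*% c(0, -1, 0))
  Fg <- c(0, -g, 0)
  M_ext <- c(0, 0, 0); F_ext <- c(0, 0, 0)
  for (s in segs) {
    M_ext <- M_ext + cross3(dirn * s$d, Fg * s$m)
    F_ext <- F_ext + Fg * s$m
  }
  d_load <- L_ua + L_fa + 0.506 * L_ha
  M_ext <- M_ext + cross3(dirn * d_load, c(0, -hand_load, 0))
  F_ext <- F_ext + c(0, -hand_load, 0)
  list(moment = -M_ext, external_force = F_ext)
}

# decompose the glenoid-directed reaction G into compression (into the
# glenoid, along -n), superior shear and anterior shear
decompose_reaction <- function(G, frame, body_weight_N = NA_real_) {
  comp <- -sum(G * frame$n)
  vs <- sum(G * frame$sup)
  hs <- sum(G * frame$ant)
  total <- vnorm(G)
  structure(list(total = total,
                 total_pctBW = if (is.na(body_weight_N)) NA_real_ else 100 * total / body_weight_N,
                 compression = comp, vertical_shear = vs, horizontal_shear = hs),
            class = "force_decomposition")
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat(sprintf("force_decomposition: total %.1f N (%.1f %%BW)\n", x$total,
              x$total_pctBW))
  cat(sprintf("  compression %.1f N, vertical shear %+.1f N, horizontal shear %+.1f N\n",
              x$compression, x$vertical_shear, x$horizontal_shear))
  invisible(x)
}

#' Cubic-cost muscle recruitment under the stability cone
#'
#' Minimises the third-order recruitment cost `sum((F_i / N_i)^3)` subject
#' to moment equilibrium about the joint centre, force bounds
#' `0 <= F_i <= N_i`, and (optionally) the concavity-compression stability
#' cone: the glenoid-directed joint reaction must pass from the joint-centre
#' apex through the glenoid rim polygon. The moment equality is eliminated
#' exactly by a nullspace parametrisation, so the equilibrium residual is at
#' machine precision; the remaining smooth convex program is solved by a
#' log-barrier interior method.
#'
#' @param muscles list of `muscle_element`s, or a precomputed system from
#'   the internal geometry step.
#' @param pose a [gh_pose()] or `NULL` (neutral).
#' @param required required muscle moment, 3-vector N mm (from
#'   [required_moment()]).
#' @param joint a `joint_geometry`.
#' @param config a [model_config()] list (`use_cone` toggles the cone).
#' @param external_force total non-muscular force on the arm, N (enters the
#'   joint reaction and hence the cone constraint).
#' @param body_weight_N optional body weight for %BW normalisation.
#' @param moment_basis optional 3 x k matrix of orthonormal axes on which the
#'   moment equality is enforced (default: all three axes). The arc
#'   simulation passes the two axes orthogonal to the humeral long axis:
#'   gravity and the hand load exert no moment about the arm's own axis, and
#'   axial rotation balance belongs to muscles outside the reduced set
#'   (pectoralis, latissimus, teres major), so it is not imposed on it.
#' @return list with `states` (data.frame: muscle, force_N, moment_arm_mm,
#'   torque_Nmm), `decomposition` (`force_decomposition`), `reaction`
#'   (3-vector, force on the glenoid, N) and `residual` (equilibrium
#'   residual, N mm).
#' @export
solve_recruitment <- function(muscles, pose, required, joint,
                              config = model_config(),
                              external_force = c(0, 0, 0),
                              body_weight_N = NA_real_,
                              moment_basis = NULL) {
  sys <- if (is.list(muscles) && !is.null(muscles$U)) muscles
         else muscle_system(muscles, pose, joint, config)
  A <- sys$moments                       # 3 x n, N mm per N
  U <- sys$U
  N <- sys$strengths
  n <- length(N)
  b <- as.numeric(required)
  if (!is.null(moment_basis)) {
    B <- as.matrix(moment_basis)
    A <- t(B) %*% A
    b <- as.numeric(t(B) %*% b)
  }

  # min-norm particular solution and nullspace of the moment equality
  sv <- svd(A, nu = nrow(A), nv = n)    # full SVD: nullspace needed
  tol_s <- max(sv$d) * 1e-10
  rank_ <- sum(sv$d > tol_s)
  if (rank_ == 0) {
    Fp <- rep(0, n)
    if (vnorm(b) > 1e-9) stop("required moment not achievable: all moment arms vanish")
  } else {
    Vr <- sv$v[, seq_len(rank_), drop = FALSE]
    Ur <- sv$u[, seq_len(rank_), drop = FALSE]
    Fp <- as.numeric(Vr %*% ((t(Ur) %*% b) / sv$d[seq_len(rank_)]))
    if (vnorm(A %*% Fp - b) > 1e-6 * max(vnorm(b), 1))
      stop("required moment not achievable: outside the span of the muscle moment arms")
  }
  Z <- if (rank_ < n) sv$v[, (rank_ + 1):n, drop = FALSE] else NULL

  # linear inequalities  ui %*% u >= ci  in nullspace coordinates
  cone_M <- NULL
  if (isTRUE(config$use_cone) && !is.null(sys$rim)) {
    cone_M <- cone_constraints(sys$rim, sys$joint_center,
                               scale = config$cone_scale %||% 1.5)
  }
  # rows in F-space: lower bounds, upper bounds, cone
  R_F <- rbind(diag(n), -diag(n), if (!is.null(cone_M)) cone_M %*% U)
  r_c <- c(rep(0, n), -N, if (!is.null(cone_M)) -as.numeric(cone_M %*% external_force))
  labels <- c(paste0("non-negativity of ", sys$names),
              paste0("strength bound of ", sys$names),
              if (!is.null(cone_M)) paste0("stability cone facet ", seq_len(nrow(cone_M))))
  scale_r <- pmax(sqrt(rowSums(R_F^2)), 1e-12)
  R_F <- R_F / scale_r; r_c <- r_c / scale_r

  slack <- function(F) as.numeric(R_F %*% F) - r_c
  check_feasible <- function(F, tol = 1e-7 * max(N)) {
    s <- slack(F)
    if (min(s) < -tol) {
      j <- which.min(s)
      stop(sprintf("infeasible recruitment: binding constraint '%s' (violation %.3g)",
                   labels[j], -s[j]))
    }
    s
  }

  if (is.null(Z)) {                     # fully determined by equilibrium
    check_feasible(Fp)
    return(recruitment_result(Fp, sys, A, b, external_force, body_weight_N))
  }

  ui <- R_F %*% Z
  ci <- r_c - as.numeric(R_F %*% Fp)
  eps_marg <- 1e-4 * max(N)

  # phase 1: strictly feasible interior point via squared hinge losses
  phase1 <- function(u) sum(pmax(0, ci + eps_marg - as.numeric(ui %*% u))^2)
  phase1_gr <- function(u) {
    h <- pmax(0, ci + eps_marg - as.numeric(ui %*% u))
    as.numeric(-2 * t(ui) %*% h)
  }
  u0 <- rep(0, ncol(Z))
  if (phase1(u0) > 0) {
    opt1 <- stats::optim(u0, phase1, phase1_gr, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))
    u0 <- opt1$par
  }
  s0 <- as.numeric(ui %*% u0) - ci
  if (min(s0) <= 0) {
    j <- which.min(s0)
    stop(sprintf("infeasible recruitment: binding constraint '%s' (violation %.3g)",
                 labels[j], -s0[j] * scale_r[j]))
  }

  obj <- function(u) { F <- Fp + as.numeric(Z %*% u); sum((pmax(F, 0) / N)^3) }
  grj <- function(u) {
    F <- Fp + as.numeric(Z %*% u)
    as.numeric(t(Z) %*% (3 * pmax(F, 0)^2 / N^3))
  }
  fit <- stats::constrOptim(u0, obj, grj, ui = ui, ci = ci, method = "BFGS",
                            outer.eps = config$solver_tol,
                            outer.iterations = 60,
                            control = list(maxit = 400, reltol = 1e-14))
  Fhat <- Fp + as.numeric(Z %*% fit$par)   # interior, so bounds hold strictly
  check_feasible(Fhat)
  recruitment_result(Fhat, sys, A, b, external_force, body_weight_N)
}

recruitment_result <- function(F, sys, A, b, external_force, body_weight_N) {
  G <- as.numeric(sys$U %*% F) + external_force
  ma <- as.numeric(t(sys$moments) %*% matrix(sys$axis))  # mm about motion axis
  states <- data.frame(muscle = sys$names, force_N = F, moment_arm_mm = ma,
                       torque_Nmm = ma * F)
  dec <- if (!is.null(sys$frame)) decompose_reaction(G, sys$frame, body_weight_N) else NULL
  list(states = states, decomposition = dec, reaction = G,
       residual = vnorm(as.numeric(A %*% F) - b))
}

#' Simulate an elevation arc for one subject
#'
#' Runs the full per-subject chain: mirror left-side anatomy to the
#' right-handed frame, fit the joint geometry, build the muscle set, and
#' solve recruitment at each elevation increment (default 12 increments over
#' 0-120 degrees) under the configured hand load, normalising forces by body
#' weight from the glenoid-height stature scaling.
#'
#' @param anatomy a `shoulder_anatomy` (from [generate_shoulder()]).
#' @param motion `"abduction"` or `"flexion"`.
#' @param config a [model_config()] list.
#' @param joint optional precomputed `joint_geometry` (skips the fit).
#' @return an object of class `arc_simulation`: list with `forces`
#'   (per-increment data.frame), `muscle_states` (long data.frame), `joint`,
#'   `body`, `motion` and `angles`.
#' @export
simulate_arc <- function(anatomy, motion = c("abduction", "flexion"),
                         config = model_config(), joint = NULL) {
  motion <- match.arg(motion)
  if (anatomy$params$side == "left") anatomy <- mirror_shoulder(anatomy)
  lm <- anatomy$landmarks
  if (is.null(joint))
    joint <- fit_joint_geometry(anatomy$scapula, anatomy$humerus, lm,
                                cartilage_offset = config$cartilage_offset)
  gh <- vnorm(unclass(lm)["glenoid_superior", ] - unclass(lm)["glenoid_inferior", ])
  body <- scale_patient(gh, config$reference_glenoid_height,
                        sex = anatomy$params$sex,
                        reference_mass = config$reference_mass)
  muscles <- build_muscles(joint, lm, config)
  angles <- seq(0, config$arc_max, length.out = config$n_increments)
  forces <- vector("list", length(angles))
  mstates <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    pose <- gh_pose(motion, angles[i], gh_fraction = config$gh_fraction)
    req <- required_moment(pose, body, hand_load = config$hand_load, config = config)
    # single-DOF inverse dynamics along the arc: enforce the moment about the
    # motion axis only. Axial humeral rotation and horizontal-plane balance
    # belong to muscles outside the reduced set (pectoralis major,
    # latissimus, teres major), and the external demand is purely about the
    # motion axis anyway.
    basis <- matrix(pose$axis, 3, 1)
    sol <- tryCatch(
      solve_recruitment(muscles, pose, req$moment, joint, config,
                        external_force = req$external_force,
                        body_weight_N = body$body_weight_N,
                        moment_basis = basis),
      error = function(e) stop(sprintf("increment %d (%.0f deg): %s", i,
                                       angles[i], conditionMessage(e)), call. = FALSE))
    d <- sol$decomposition
    forces[[i]] <- data.frame(
      increment = i, angle_deg = angles[i], total_N = d$total,
      total_pctBW = d$total_pctBW, compression_N = d$compression,
      vshear_N = d$vertical_shear, hshear_N = d$horizontal_shear,
      residual_Nmm = sol$residual, required_Nmm = vnorm(req$moment))
    mstates[[i]] <- cbind(increment = i, angle_deg = angles[i], sol$states)
  }
  structure(list(forces = do.call(rbind, forces),
                 muscle_states = do.call(rbind, mstates),
                 joint = joint, body = body, motion = motion, angles = angles,
                 params = anatomy$params),
            class = "arc_simulation")
}

#' @export
print.arc_simulation <- function(x, ...) {
  cat(sprintf("arc_simulation: %s, %d increments over 0-%.0f deg\n",
              x$motion, length(x$angles), max(x$angles)))
  cat(sprintf("  peak total force %.1f N (%.1f %%BW) at %.0f deg\n",
              max(x$forces$total_N), max(x$forces$total_pctBW),
              x$forces$angle_deg[which.max(x$forces$total_N)]))
  invisible(x)
}
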