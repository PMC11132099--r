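#' Parameters of one synthetic shoulder
#'
#' Generative parameters for a parametric scapula + proximal humerus. The
#' local coordinate frame is right-handed with +X lateral (toward the glenoid
#' face for a right shoulder), +Y superior and +Z anterior; units are mm and
#' degrees throughout.
#'
#' The glenoid inclination convention used by the generator and by
#' [measure_gi()]: GI is the angle between the supraspinatus-fossa axis
#' (glenoid centre toward the angulus superior, i.e. medial) and the
#' inferior-to-superior glenoid face line, projected on the scapular plane.
#' A perfectly "neutral" glenoid face perpendicular to the fossa axis gives
#' 90 deg; values below 90 deg tip the superior glenoid rim medially.
#'
#' @param csa_deg critical shoulder angle, degrees; must lie in [15, 45].
#' @param gi_deg glenoid inclination, degrees (convention above).
#' @param glenoid_height superior-inferior glenoid extent, mm.
#' @param glenoid_width anterior-posterior glenoid extent, mm; must not
#'   exceed `glenoid_height`.
#' @param humeral_head_radius bone-surface radius of the humeral head, mm
#'   (pre-cartilage).
#' @param acromion_lateral_offset extra length of the acromial arch along the
#'   CSA ray beyond the template length, mm (may be negative).
#' @param side `"left"` or `"right"`.
#' @param sex `0` for male, `1` for female (the stature-scaling convention).
#' @param seed integer seed for the subject-specific surface detail.
#' @return an object of class `anatomy_params`.
#' @export
anatomy_params <- function(csa_deg, gi_deg, glenoid_height = 36,
                           glenoid_width = 26, humeral_head_radius = 24,
                           acromion_lateral_offset = 0, side = "right",
                           sex = 0, seed = 1L) {
  if (!is.numeric(csa_deg) || csa_deg < 15 || csa_deg > 45)
    stop_param("csa_deg", "must lie in [15, 45] degrees")
  if (!is.numeric(gi_deg) || gi_deg < 55 || gi_deg > 115)
    stop_param("gi_deg", "must lie in [55, 115] degrees")
  for (f in c("glenoid_height", "glenoid_width", "humeral_head_radius")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) stop_param(f, "must be a positive length in mm")
  }
  if (glenoid_width > glenoid_height)
    stop_param("glenoid_width", "must not exceed glenoid_height")
  if (!side %in% c("left", "right")) stop_param("side", "must be 'left' or 'right'")
  if (!sex %in% c(0, 1)) stop_param("sex", "must be 0 (male) or 1 (female)")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop_param("seed", "must be a single integer")
  structure(list(csa_deg = csa_deg, gi_deg = gi_deg,
                 glenoid_height = glenoid_height, glenoid_width = glenoid_width,
                 humeral_head_radius = humeral_head_radius,
                 acromion_lateral_offset = acromion_lateral_offset,
                 side = side, sex = sex, seed = as.integer(seed)),
            class = "anatomy_params")
}

#' @export
print.anatomy_params <- function(x, ...) {
  cat(sprintf("anatomy_params: CSA %.1f deg, GI %.1f deg, glenoid %.1f x %.1f mm,\n",
              x$csa_deg, x$gi_deg, x$glenoid_height, x$glenoid_width))
  cat(sprintf("  humeral head r %.1f mm, %s side, sex %d, seed %d\n",
              x$humeral_head_radius, x$side, x$sex, x$seed))
  invisible(x)
}

#' Named anatomical landmark set
#'
#' Eleven scapular landmarks: lateral coracoid, antero/posterolateral
#' acromion, angulus inferior and superior, and the inferior, superior,
#' lateral, medial, anterior and posterior glenoid rim points.
#'
#' @param points named list (or 3-column matrix with rownames) of 3-D points, mm.
#' @return an object of class `landmark_set` (named 11 x 3 matrix).
#' @export
landmark_set <- function(points) {
  required <- c("lateral_coracoid", "anterolateral_acromion",
                "posterolateral_acromion", "angulus_inferior",
                "angulus_superior", "glenoid_inferior", "glenoid_superior",
                "glenoid_lateral", "glenoid_medial", "glenoid_anterior",
                "glenoid_posterior")
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  missing <- setdiff(required, rownames(points))
  if (length(missing))
    stop(sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")))
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  structure(points[required, , drop = FALSE], class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (mm):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Write / read landmarks as JSON
#'
#' JSON maps landmark name to `[x, y, z]` in mm (right-handed frame, +X
#' lateral toward the glenoid face for a right shoulder, +Y superior, +Z
#' anterior).
#'
#' @param landmarks a `landmark_set`.
#' @param path file path.
#' @return `path` (write) or a `landmark_set` (read).
#' @export
write_landmarks <- function(landmarks, path) {
  lst <- lapply(seq_len(nrow(landmarks)), function(i) as.numeric(landmarks[i, ]))
  names(lst) <- rownames(landmarks)
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(do.call(rbind, lst))
}

# quadratic Bezier sampled at k points
bezier3 <- function(p0, p1, p2, k) {
  t <- seq(0, 1, length.out = k)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  b
}

# smooth seeded bumps used for subject-specific surface detail (mm)
surface_detail <- function(xy, amplitude, n_modes = 4) {
  z <- numeric(nrow(xy))
  span <- max(apply(xy, 2, function(v) diff(range(v))), 1)
  for (m in seq_len(n_modes)) {
    k <- stats::runif(2, 0.5, 2.5) * 2 * pi / span
    ph <- stats::runif(2, 0, 2 * pi)
    a <- stats::rnorm(1, 0, amplitude)
    z <- z + a * sin(k[1] * xy[, 1] + ph[1]) * sin(k[2] * xy[, 2] + ph[2])
  }
  z
}

#' Generate a synthetic scapula, humerus, and landmark set
#'
#' Builds a simplified parametric shoulder: the glenoid is a shallow elliptic
#' dish whose rim lies exactly in the glenoid plane, the acromion is a lateral
#' arch whose tip position is solved from the prescribed critical shoulder
#' angle, and the coracoid and scapular blade are a fixed template scaled by
#' the glenoid height. The humeral head carries an exact spherical cap of the
#' prescribed bone radius, centred at the patient-adapted joint centre
#' (glenoid circle-fit centre plus the plane normal times bone radius + 2 mm
#' cartilage). The result is deterministic for a fixed parameter set.
#'
#' @param params an [anatomy_params()] object.
#' @param cartilage_offset cartilage allowance added when positioning the
#'   humeral head, mm.
#' @return a list of class `shoulder_anatomy` with elements `scapula`
#'   (`surface_mesh`), `humerus` (`surface_mesh`), `landmarks`
#'   (`landmark_set`) and `params`.
#' @export
generate_shoulder <- function(params, cartilage_offset = 2) {
  if (!inherits(params, "anatomy_params")) params <- do.call(anatomy_params, as.list(params))
  with_seed(params$seed, function() generate_shoulder_impl(params, cartilage_offset))
}

generate_shoulder_impl <- function(params, cartilage_offset) {
  h <- params$glenoid_height; w <- params$glenoid_width
  s <- h / 36
  gi <- deg2rad(params$gi_deg)
  d_sup <- c(-cos(gi), sin(gi), 0)          # inferior -> superior glenoid line
  n_lat <- c(sin(gi), cos(gi), 0)           # lateral glenoid plane normal
  e_ant <- c(0, 0, 1)
  c0 <- c(0, 0, 0)                          # true ellipse centre of the rim

  rim_phi <- seq(0, 350, by = 10)           # from superior, toward anterior
  rim <- t(vapply(rim_phi, function(p) {
    c0 + (h / 2) * cos(deg2rad(p)) * d_sup + (w / 2) * sin(deg2rad(p)) * e_ant
  }, numeric(3)))

  ## --- landmarks -----------------------------------------------------------
  gl_sup <- rim[1, ]; gl_ant <- rim[10, ]; gl_inf <- rim[19, ]; gl_post <- rim[28, ]
  gl_lat <- rim[which.max(rim[, 1]), ]
  gl_med <- rim[which.min(rim[, 1]), ]
  ang_sup <- c0 + s * c(-100, 0, 0)
  ang_inf <- c0 + s * c(-55, -120, 0)
  ray <- as.numeric(rotation_about(c(0, 0, 1), -params$csa_deg) %*% d_sup)
  arc_len <- 1.9 * h + params$acromion_lateral_offset
  tip <- gl_inf + arc_len * ray
  acr_al <- tip + c(0, 0, 6 * s)
  acr_pl <- tip + c(0, 0, -9 * s)
  coracoid <- c0 + s * c(8, 10, 20)
  lm <- landmark_set(rbind(
    lateral_coracoid = coracoid, anterolateral_acromion = acr_al,
    posterolateral_acromion = acr_pl, angulus_inferior = ang_inf,
    angulus_superior = ang_sup, glenoid_inferior = gl_inf,
    glenoid_superior = gl_sup, glenoid_lateral = gl_lat,
    glenoid_medial = gl_med, glenoid_anterior = gl_ant,
    glenoid_posterior = gl_post))

  ## --- scapula mesh --------------------------------------------------------
  depth <- 2.5 * s
  rho <- c(1, 0.8, 0.55, 0.3)
  dish <- do.call(rbind, lapply(rho, function(r) {
    sweep(rbind(t(vapply(rim_phi, function(p) {
      r * ((h / 2) * cos(deg2rad(p)) * d_sup + (w / 2) * sin(deg2rad(p)) * e_ant)
    }, numeric(3)))), 2, depth * (1 - r^2) * n_lat, `-`)
  }))
  dish <- rbind(dish, c0 - depth * n_lat)    # centre vertex
  nphi <- length(rim_phi)
  dish_faces <- list()
  for (ri in seq_len(length(rho) - 1)) {
    o1 <- (ri - 1) * nphi; o2 <- ri * nphi
    for (k in seq_len(nphi)) {
      k2 <- if (k == nphi) 1L else k + 1L
      dish_faces[[length(dish_faces) + 1L]] <-
        rbind(c(o1 + k, o1 + k2, o2 + k), c(o1 + k2, o2 + k2, o2 + k))
    }
  }
  ctr <- length(rho) * nphi + 1L
  o3 <- (length(rho) - 1) * nphi
  for (k in seq_len(nphi)) {
    k2 <- if (k == nphi) 1L else k + 1L
    dish_faces[[length(dish_faces) + 1L]] <- rbind(c(o3 + k, o3 + k2, ctr))
  }
  # neck: extrude the rim medially so dish vertices are isolated in space
  neck <- sweep(sweep(rim, 2, c0, `-`) * 0.9, 2, c0 - 7 * s * n_lat, `+`)
  nk0 <- nrow(dish)
  dish_all <- rbind(dish, neck)
  for (k in seq_len(nphi)) {
    k2 <- if (k == nphi) 1L else k + 1L
    dish_faces[[length(dish_faces) + 1L]] <-
      rbind(c(k, nk0 + k, k2), c(k2, nk0 + k, nk0 + k2))
  }
  scap_v <- dish_all
  scap_f <- do.call(rbind, dish_faces)

  # blade: bilinear patch in the scapular (z = 0) plane with seeded detail
  A <- c0[1:2] + s * c(-10, -14); B <- ang_inf[1:2]
  C <- ang_sup[1:2]; D <- c0[1:2] + s * c(-10, 10)
  nu <- 9; nv <- 7
  uu <- seq(0, 1, length.out = nu); vv <- seq(0, 1, length.out = nv)
  blade_xy <- do.call(rbind, lapply(uu, function(u) {
    t(vapply(vv, function(v) {
      (1 - u) * ((1 - v) * A + v * D) + u * ((1 - v) * B + v * C)
    }, numeric(2)))
  }))
  blade_z <- surface_detail(blade_xy, 0.25)
  blade <- cbind(blade_xy, blade_z)
  bf <- grid_faces(nu, nv) + nrow(scap_v)
  scap_v <- rbind(scap_v, blade)
  scap_f <- rbind(scap_f, bf)

  # acromial arch: quadratic ribbon from the spine root over to the tip
  root <- c0 + s * c(-70, 5, -8)
  mid <- c0 + s * c(-15, 18, -12)
  arc <- bezier3(root, mid, tip, 14)
  arc[, 2] <- arc[, 2] + surface_detail(arc[, c(1, 3)], 0.2)
  wa <- 5 * s
  ribbon <- rbind(sweep(arc, 2, c(0, 0, wa), `+`), sweep(arc, 2, c(0, 0, -wa), `+`))
  rbf <- cbind(seq_len(13), seq_len(13) + 1L, seq_len(13) + 14L)
  rbf <- rbind(rbf, cbind(seq_len(13) + 1L, seq_len(13) + 15L, seq_len(13) + 14L))
  scap_f <- rbind(scap_f, rbf + nrow(scap_v))
  scap_v <- rbind(scap_v, ribbon)

  # coracoid stub
  cb <- c0 + s * c(-5, 8, 6)
  cor <- bezier3(cb, (cb + coracoid) / 2 + c(0, 3 * s, 0), coracoid, 5)
  wc <- c(2.5 * s, -2.5 * s, 0)
  cor_v <- rbind(sweep(cor, 2, wc, `+`), sweep(cor, 2, wc, `-`))
  cf <- cbind(seq_len(4), seq_len(4) + 1L, seq_len(4) + 5L)
  cf <- rbind(cf, cbind(seq_len(4) + 1L, seq_len(4) + 6L, seq_len(4) + 5L))
  scap_f <- rbind(scap_f, cf + nrow(scap_v))
  scap_v <- rbind(scap_v, cor_v)

  scapula <- surface_mesh(scap_v, scap_f)

  ## --- humerus -------------------------------------------------------------
  # joint centre from the same geometric construction applied downstream
  rim9 <- glenoid_rim_points(scapula, lm, n = 9)
  pl <- fit_glenoid_plane(rim9, body_centroid = mesh_centroid(scapula))
  gc_fit <- fit_glenoid_center(rim9, pl)
  r_bone <- params$humeral_head_radius
  hc <- gc_fit + pl$normal * (r_bone + cartilage_offset)

  b1 <- d_sup; b2 <- as.numeric(cross3(-pl$normal, b1))
  psi <- seq(10, 110, by = 10); az <- seq(0, 345, by = 15)
  cap <- do.call(rbind, lapply(psi, function(p) {
    t(vapply(az, function(a) {
      hc + r_bone * (-pl$normal * cos(deg2rad(p)) +
                     (b1 * cos(deg2rad(a)) + b2 * sin(deg2rad(a))) * sin(deg2rad(p)))
    }, numeric(3)))
  }))
  pole <- hc - r_bone * pl$normal
  hv <- rbind(pole, cap)
  naz <- length(az)
  hf <- lapply(seq_len(naz), function(k) {
    k2 <- if (k == naz) 1L else k + 1L
    c(1L, 1L + k2, 1L + k)
  })
  hf <- do.call(rbind, hf)
  for (ri in seq_len(length(psi) - 1)) {
    o1 <- 1L + (ri - 1) * naz; o2 <- 1L + ri * naz
    for (k in seq_len(naz)) {
      k2 <- if (k == naz) 1L else k + 1L
      hf <- rbind(hf, c(o1 + k, o1 + k2, o2 + k), c(o1 + k2, o2 + k2, o2 + k))
    }
  }
  # shaft: cylinder hanging distally (-Y), detached from the exact cap
  sh_r <- 0.5 * r_bone
  sh_y <- c(-1.15 * r_bone, -2.2 * r_bone, -3.4 * r_bone, -4.5 * r_bone)
  shaft <- do.call(rbind, lapply(sh_y, function(y) {
    t(vapply(az, function(a) {
      hc + c(0, y, 0) + sh_r * c(cos(deg2rad(a)), 0, sin(deg2rad(a)))
    }, numeric(3)))
  }))
  o0 <- nrow(hv)
  for (ri in seq_len(length(sh_y) - 1)) {
    o1 <- o0 + (ri - 1) * naz; o2 <- o0 + ri * naz
    for (k in seq_len(naz)) {
      k2 <- if (k == naz) 1L else k + 1L
      hf <- rbind(hf, c(o1 + k, o1 + k2, o2 + k), c(o1 + k2, o2 + k2, o2 + k))
    }
  }
  hv <- rbind(hv, shaft)
  humerus <- surface_mesh(hv, hf)

  out <- list(scapula = scapula, humerus = humerus, landmarks = lm,
              params = params)
  if (params$side == "left") out <- mirror_shoulder(out)
  class(out) <- "shoulder_anatomy"
  out
}

#' Mirror a generated shoulder about the sagittal plane
#'
#' Flips the anterior (+Z) coordinate of meshes and landmarks, converting a
#' right-shoulder local frame into a left one and vice versa.
#'
#' @param anatomy a `shoulder_anatomy` list.
#' @return the mirrored `shoulder_anatomy`.
#' @export
mirror_shoulder <- function(anatomy) {
  anatomy$scapula <- mirror_mesh(anatomy$scapula)
  anatomy$humerus <- mirror_mesh(anatomy$humerus)
  lm <- mirror_points(unclass(anatomy$landmarks))
  anatomy$landmarks <- landmark_set(lm)
  anatomy
}

#' @export
print.shoulder_anatomy <- function(x, ...) {
  cat(sprintf("shoulder_anatomy (%s side): CSA %.1f deg, GI %.1f deg\n",
              x$params$side, x$params$csa_deg, x$params$gi_deg))
  cat(sprintf("  scapula %d vertices, humerus %d vertices\n",
              nrow(x$scapula$vertices), nrow(x$humerus$vertices)))
  invisible(x)
}

# group morphometric distributions and compositions used by sample_cohort()
cohort_reference <- function(group) {
  switch(group,
    RCT = list(csa = c(32.73, 4.89), gi = c(81.42, 5.89),
               n_male = 28, n_female = 27, n_left = 15, n_right = 40),
    OA  = list(csa = c(24.88, 6.15), gi = c(86.13, 7.16),
               n_male = 28, n_female = 20, n_left = 17, n_right = 31),
    stop("group must be 'RCT' or 'OA'"))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample a cohort of anatomy parameter sets
#'
#' Draws CSA and GI from normal distributions with the pathology-group means
#' and SDs (RCT: CSA 32.73 +/- 4.89 deg, GI 81.42 +/- 5.89 deg; OA: CSA
#' 24.88 +/- 6.15 deg, GI 86.13 +/- 7.16 deg), truncated by resampling to the
#' valid parameter range. Sex and side are assigned proportionally to the
#' group compositions (RCT 28 M / 27 F, 15 L / 40 R; OA 28 M / 20 F,
#' 17 L / 31 R).
#'
#' @param group `"RCT"` or `"OA"`.
#' @param n number of subjects (>= 2).
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return a list of [anatomy_params()] objects of length `n`.
#' @export
sample_cohort <- function(group, n, seed = 1L) {
  ref <- cohort_reference(match.arg(group, c("RCT", "OA")))
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  n <- as.integer(n)
  with_seed(seed, function() {
    csa <- rnorm_trunc(n, ref$csa[1], ref$csa[2], 15, 45)
    gi <- rnorm_trunc(n, ref$gi[1], ref$gi[2], 55, 115)
    gh <- rnorm_trunc(n, 36, 2.0, 31.5, 40.5)
    ratio <- rnorm_trunc(n, 0.72, 0.03, 0.55, 0.85)
    hr <- rnorm_trunc(n, 24, 1.5, 19, 29)
    acr <- rnorm_trunc(n, 0, 3, -6, 8)
    n_f <- round(n * ref$n_female / (ref$n_female + ref$n_male))
    n_l <- round(n * ref$n_left / (ref$n_left + ref$n_right))
    sex <- sample(c(rep(1, n_f), rep(0, n - n_f)))
    side <- sample(c(rep("left", n_l), rep("right", n - n_l)))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      anatomy_params(csa_deg = csa[i], gi_deg = gi[i], glenoid_height = gh[i],
                     glenoid_width = ratio[i] * gh[i], humeral_head_radius = hr[i],
                     acromion_lateral_offset = acr[i], side = side[i],
                     sex = sex[i], seed = seeds[i])
    })
  })
}

#' Cohort manifest as a data frame
#'
#' One row per subject with id, group and every generative parameter;
#' suitable for writing as the cohort CSV.
#'
#' @param cohort list of `anatomy_params` from [sample_cohort()].
#' @param group group label recorded per row.
#' @return a data.frame.
#' @export
cohort_manifest <- function(cohort, group) {
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    data.frame(id = sprintf("%s%03d", group, i), group = group,
               csa_deg = p$csa_deg, gi_deg = p$gi_deg,
               glenoid_height = p$glenoid_height, glenoid_width = p$glenoid_width,
               humeral_head_radius = p$humeral_head_radius,
               acromion_lateral_offset = p$acromion_lateral_offset,
               side = p$side, sex = p$sex, seed = p$seed)
  }))
}

#' Smooth random perturbation of a mesh
#'
#' Displaces vertices by a smooth random field (a sum of broad Gaussian
#' bumps), rescaled so the maximum vertex displacement equals `amplitude`.
#' Used to manufacture registration test pairs with a known error bound.
#'
#' @param mesh a `surface_mesh`.
#' @param amplitude maximum displacement, mm (>= 0); 0 returns the input.
#' @param seed integer seed for the field.
#' @return the perturbed `surface_mesh`.
#' @export
perturb_mesh <- function(mesh, amplitude, seed = 1L) {
  if (!is.numeric(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(mesh)
  v <- mesh$vertices
  with_seed(seed, function() {
    bb <- apply(v, 2, range)
    sigma <- 0.35 * vnorm(bb[2, ] - bb[1, ])
    disp <- matrix(0, nrow(v), 3)
    for (j in seq_len(6)) {
      ctr <- v[sample.int(nrow(v), 1), ]
      u <- unitize(stats::rnorm(3))
      a <- stats::rnorm(1)
      wgt <- exp(-rowSums(sweep(v, 2, ctr, `-`)^2) / (2 * sigma^2))
      disp <- disp + a * outer(wgt, u)
    }
    mx <- max(sqrt(rowSums(disp^2)))
    if (mx > 0) disp <- disp * (amplitude / mx)
    surface_mesh(v + disp, mesh$faces)
  })
}
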