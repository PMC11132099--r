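#' Least-squares sphere fit
#'
#' Algebraic least-squares sphere through a point cloud (linear in centre and
#' radius-squared), the classic normal-equation formulation. Exact for
#' noise-free spherical data; for noisy data it is the standard initialiser
#' whose bias is negligible at the sub-millimetre noise levels handled here.
#'
#' @param points numeric matrix (>= 4 non-coplanar rows) of 3-D points, mm.
#' @return list with `center` (3-vector, mm), `radius` (mm) and `rms`
#'   (root-mean-square radial residual, mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit needs >= 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4)
    stop("degenerate sphere fit: points are coplanar or otherwise rank-deficient")
  coef <- qr.coef(qr_A, b)
  center <- coef[1:3]
  r2 <- coef[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate sphere fit: non-positive squared radius")
  radius <- unname(sqrt(r2))
  res <- sqrt(rowSums(sweep(points, 2, center, `-`)^2)) - radius
  list(center = as.numeric(center), radius = radius,
       rms = sqrt(mean(res^2)))
}

#' Total-least-squares plane fit to glenoid rim points
#'
#' SVD plane through the rim points. The normal is oriented laterally (away
#' from the scapular body) when `body_centroid` is supplied; otherwise the
#' sign is fixed deterministically by the largest component.
#'
#' @param rim_points matrix of rim points (typically 9 x 3), mm.
#' @param body_centroid optional 3-D point medial of the glenoid (e.g. the
#'   scapular mesh centroid) used to orient the normal.
#' @return list with unit `normal`, `centroid`, and `rms` out-of-plane
#'   residual (mm).
#' @export
fit_glenoid_plane <- function(rim_points, body_centroid = NULL) {
  rim_points <- as.matrix(rim_points)
  if (nrow(rim_points) < 3) stop("plane fit needs >= 3 points")
  ctr <- colMeans(rim_points)
  X <- sweep(rim_points, 2, ctr, `-`)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate plane fit: points are collinear")
  normal <- sv$v[, 3]
  if (!is.null(body_centroid)) {
    if (sum(normal * (ctr - body_centroid)) < 0) normal <- -normal
  } else if (normal[which.max(abs(normal))] < 0) normal <- -normal
  list(normal = as.numeric(normal), centroid = as.numeric(ctr),
       rms = sqrt(mean((X %*% normal)^2)))
}

# algebraic (Kasa) circle fit in 2-D + a few Gauss-Newton geometric steps
fit_circle_2d <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("circle fit needs >= 3 points")
  A <- cbind(2 * xy, 1)
  qr_A <- qr(A)
  if (qr_A$rank < 3) stop("degenerate circle fit: points are collinear")
  coef <- unname(qr.coef(qr_A, rowSums(xy^2)))
  ctr <- coef[1:2]
  r <- sqrt(coef[3] + sum(ctr^2))
  for (it in 1:5) {  # geometric refinement
    d <- sweep(xy, 2, ctr, `-`)
    ri <- sqrt(rowSums(d^2))
    if (any(ri < 1e-12)) break
    J <- cbind(-d / ri, -1)
    res <- ri - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    ctr <- ctr + step[1:2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  list(center = as.numeric(ctr), radius = r)
}

#' Resample the glenoid rim at equal angular spacing
#'
#' Recovers the glenoid rim ring from a scapular mesh: vertices lying on the
#' plane through the four glenoid rim landmarks (superior, inferior,
#' anterior, posterior) within a radial annulus, ordered by in-plane angle
#' measured from the superior landmark rotating through the anterior one,
#' then linearly resampled at `n` equally spaced angles starting from the
#' superior landmark.
#'
#' @param mesh the scapular `surface_mesh`.
#' @param landmarks a `landmark_set`.
#' @param n number of rim points to return (9 for joint fitting, 8 for the
#'   passive-stability polygon).
#' @param plane_tol distance from the rim plane below which a vertex is a
#'   rim candidate, mm.
#' @return an `n x 3` matrix with attribute `angles` (degrees from superior,
#'   through anterior).
#' @export
glenoid_rim_points <- function(mesh, landmarks, n = 9, plane_tol = 0.2) {
  g4 <- unclass(landmarks)[c("glenoid_superior", "glenoid_anterior",
                             "glenoid_inferior", "glenoid_posterior"), ]
  pl <- fit_glenoid_plane(g4)
  ctr <- pl$centroid; nrm <- pl$normal
  e_s <- unitize(g4[1, ] - ctr - sum((g4[1, ] - ctr) * nrm) * nrm)
  ea0 <- g4[2, ] - ctr - sum((g4[2, ] - ctr) * nrm) * nrm
  e_a <- unitize(ea0 - sum(ea0 * e_s) * e_s)
  v <- mesh$vertices
  dplane <- abs(as.numeric(sweep(v, 2, ctr, `-`) %*% nrm))
  r4 <- sqrt(rowSums(sweep(g4, 2, ctr, `-`)^2))
  inplane <- sweep(v, 2, ctr, `-`)
  rad <- sqrt(rowSums(inplane^2))
  keep <- dplane < plane_tol & rad > 0.75 * min(r4) & rad < 1.25 * max(r4)
  if (sum(keep) < n) stop("could not identify enough rim vertices")
  vk <- v[keep, , drop = FALSE]
  ang <- atan2(as.numeric(sweep(vk, 2, ctr, `-`) %*% e_a),
               as.numeric(sweep(vk, 2, ctr, `-`) %*% e_s))
  ang <- (rad2deg(ang) + 360) %% 360
  ord <- order(ang)
  vk <- vk[ord, , drop = FALSE]; ang <- ang[ord]
  dup <- c(FALSE, diff(ang) < 1e-9)
  vk <- vk[!dup, , drop = FALSE]; ang <- ang[!dup]
  targets <- seq(0, 360, length.out = n + 1)[seq_len(n)]
  m <- length(ang)
  out <- t(vapply(targets, function(a) {
    j <- findInterval(a, ang)
    if (j == 0 || j == m) {  # wrap between last and first vertex
      a0 <- ang[m] - 360; a1 <- ang[1]
      p0 <- vk[m, ]; p1 <- vk[1, ]
      if (j == m && a >= ang[m]) { a0 <- ang[m]; a1 <- ang[1] + 360 }
    } else {
      a0 <- ang[j]; a1 <- ang[j + 1]
      p0 <- vk[j, ]; p1 <- vk[j + 1, ]
    }
    w <- if (a1 > a0) (a - a0) / (a1 - a0) else 0
    (1 - w) * p0 + w * p1
  }, numeric(3)))
  attr(out, "angles") <- targets
  out
}

#' Glenoid centre from a circle fit to the inferior rim
#'
#' The five of the nine rim points nearest the inferior direction (angular
#' distance to 180 deg from the superior landmark; ties broken by the smaller
#' angle) are projected onto the glenoid plane and a circle is fitted
#' (algebraic fit plus geometric refinement). The centre is returned in 3-D
#' on the plane.
#'
#' @param rim_points output of [glenoid_rim_points()] (9 x 3 with `angles`).
#' @param plane plane fit from [fit_glenoid_plane()].
#' @param n_inferior how many inferior points to use (default 5).
#' @return 3-D glenoid centre, mm, with attribute `radius` (fitted circle
#'   radius, mm).
#' @export
fit_glenoid_center <- function(rim_points, plane, n_inferior = 5) {
  rim_points <- as.matrix(rim_points)
  ang <- attr(rim_points, "angles")
  if (is.null(ang)) ang <- seq(0, 360, length.out = nrow(rim_points) + 1)[seq_len(nrow(rim_points))]
  if (nrow(rim_points) < 3) stop("glenoid centre fit needs >= 3 points")
  d180 <- abs(((ang - 180) + 180) %% 360 - 180)
  ord <- order(d180, ang)
  sel <- rim_points[ord[seq_len(min(n_inferior, nrow(rim_points)))], , drop = FALSE]
  nrm <- plane$normal; ctr <- plane$centroid
  e1 <- unitize(rim_points[1, ] - ctr - sum((rim_points[1, ] - ctr) * nrm) * nrm)
  e2 <- cross3(nrm, e1)
  xy <- cbind(as.numeric(sweep(sel, 2, ctr, `-`) %*% e1),
              as.numeric(sweep(sel, 2, ctr, `-`) %*% e2))
  cf <- fit_circle_2d(xy)
  out <- ctr + cf$center[1] * e1 + cf$center[2] * e2
  attr(out, "radius") <- cf$radius
  out
}

#' Sphere fit to the humeral head of a full proximal-humerus mesh
#'
#' Two-pass selection: vertices near the glenoid-facing pole initialise the
#' fit, then all vertices within 2 percent of the fitted radius are refitted,
#' excluding the shaft.
#'
#' @param humerus the humeral `surface_mesh`.
#' @param glenoid_point a point on or near the glenoid face used to find the
#'   articular pole (e.g. the rim centroid).
#' @return as [fit_sphere()].
#' @export
fit_humeral_head <- function(humerus, glenoid_point) {
  v <- humerus$vertices
  d <- sqrt(rowSums(sweep(v, 2, as.numeric(glenoid_point), `-`)^2))
  pole <- v[which.min(d), ]
  near <- sqrt(rowSums(sweep(v, 2, pole, `-`)^2)) < 20
  if (sum(near) < 10) stop("too few vertices near the articular pole")
  f1 <- fit_sphere(v[near, , drop = FALSE])
  on_sphere <- abs(sqrt(rowSums(sweep(v, 2, f1$center, `-`)^2)) - f1$radius) <
    0.02 * f1$radius
  fit_sphere(v[on_sphere, , drop = FALSE])
}

#' Patient-adapted glenohumeral joint centre
#'
#' Places the joint centre at the glenoid centre plus the lateral glenoid
#' plane normal times the effective humeral radius (bone radius plus a
#' uniform cartilage allowance, default 2 mm). This reorients the stability
#' cone to the patient glenoid.
#'
#' @param glenoid_center 3-D glenoid centre, mm.
#' @param normal unit lateral glenoid plane normal.
#' @param humeral_radius_bone sphere-fit bone radius, mm.
#' @param cartilage_offset cartilage allowance, mm (default 2).
#' @param rim_points 9 x 3 rim points carried into the stability cone.
#' @return an object of class `joint_geometry`.
#' @export
compute_joint_center <- function(glenoid_center, normal, humeral_radius_bone,
                                 cartilage_offset = 2, rim_points = NULL) {
  if (abs(vnorm(normal) - 1) > 1e-9)
    stop("internal error: glenoid plane normal must be unit length")
  if (humeral_radius_bone <= 0) stop("humeral radius must be positive")
  r_eff <- humeral_radius_bone + cartilage_offset
  jc <- as.numeric(glenoid_center) + as.numeric(normal) * r_eff
  structure(list(glenoid_center = as.numeric(glenoid_center),
                 glenoid_plane_normal = as.numeric(normal),
                 humeral_radius_bone = humeral_radius_bone,
                 humeral_radius_effective = r_eff,
                 cartilage_offset = cartilage_offset,
                 joint_center = jc,
                 rim_points = rim_points),
            class = "joint_geometry")
}

#' @export
print.joint_geometry <- function(x, ...) {
  cat("joint_geometry:\n")
  cat(sprintf("  glenoid centre  [%.2f, %.2f, %.2f] mm\n",
              x$glenoid_center[1], x$glenoid_center[2], x$glenoid_center[3]))
  cat(sprintf("  plane normal    [%.3f, %.3f, %.3f]\n",
              x$glenoid_plane_normal[1], x$glenoid_plane_normal[2], x$glenoid_plane_normal[3]))
  cat(sprintf("  humeral radius  %.2f mm bone, %.2f mm effective\n",
              x$humeral_radius_bone, x$humeral_radius_effective))
  cat(sprintf("  joint centre    [%.2f, %.2f, %.2f] mm\n",
              x$joint_center[1], x$joint_center[2], x$joint_center[3]))
  invisible(x)
}

#' Full geometric fit of a shoulder
#'
#' Runs the geometric chain on a scapula + humerus mesh pair with landmarks:
#' rim resampling (nine points at 40 deg spacing from the superior landmark),
#' glenoid plane fit (normal oriented laterally via the scapular mesh
#' centroid), circle fit of the inferior five rim points, humeral head sphere
#' fit, and the joint-centre construction.
#'
#' @param scapula scapular `surface_mesh`.
#' @param humerus humeral `surface_mesh`.
#' @param landmarks `landmark_set`.
#' @param cartilage_offset cartilage allowance, mm (default 2).
#' @return a `joint_geometry` with additional in-plane axes `e_superior` and
#'   `e_anterior` (anterior resolved via the anterior rim landmark, so the
#'   sign convention survives left-side mirroring) and the head-fit `rms`.
#' @export
fit_joint_geometry <- function(scapula, humerus, landmarks, cartilage_offset = 2) {
  rim9 <- glenoid_rim_points(scapula, landmarks, n = 9)
  pl <- fit_glenoid_plane(rim9, body_centroid = mesh_centroid(scapula))
  gc <- fit_glenoid_center(rim9, pl)
  head <- fit_humeral_head(humerus, pl$centroid)
  jg <- compute_joint_center(gc, pl$normal, head$radius,
                             cartilage_offset = cartilage_offset,
                             rim_points = rim9)
  lm <- unclass(landmarks)
  nrm <- jg$glenoid_plane_normal
  sup <- lm["glenoid_superior", ] - lm["glenoid_inferior", ]
  e_sup <- unitize(sup - sum(sup * nrm) * nrm)
  e_ant <- cross3(nrm, e_sup)
  if (sum(e_ant * (lm["glenoid_anterior", ] - jg$glenoid_center)) < 0)
    e_ant <- -e_ant
  jg$e_superior <- e_sup
  jg$e_anterior <- e_ant
  jg$head_fit_rms <- head$rms
  jg$head_center <- head$center
  jg
}

#' Serialise a joint geometry as JSON
#'
#' @param joint a `joint_geometry`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_joint_geometry <- function(joint, path) {
  jsonlite::write_json(lapply(unclass(joint), function(x) {
    if (is.matrix(x)) unname(apply(x, 1, as.numeric, simplify = FALSE)) else as.numeric(x)
  }), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# scapular-plane 2-D projection shared by the CSA and GI operators:
# plane through the glenoid centre (midpoint of the glenoid superior and
# inferior landmarks), the angulus inferior and the angulus superior (the
# medial end of the supraspinatus-fossa axis in this template)
scapular_projection <- function(landmarks) {
  lm <- unclass(landmarks)
  need <- c("glenoid_superior", "glenoid_inferior", "angulus_inferior",
            "angulus_superior")
  for (nm in need) if (any(!is.finite(lm[nm, ]))) stop(sprintf("missing landmark: %s", nm))
  gc <- (lm["glenoid_superior", ] + lm["glenoid_inferior", ]) / 2
  np <- unitize(cross3(lm["angulus_inferior", ] - gc, lm["angulus_superior", ] - gc))
  e1 <- unitize(gc - lm["angulus_superior", ] -
                sum((gc - lm["angulus_superior", ]) * np) * np)  # lateral
  e2 <- cross3(np, e1)
  if (sum(e2 * (lm["glenoid_superior", ] - lm["glenoid_inferior", ])) < 0) e2 <- -e2
  proj <- function(p) c(sum((p - gc) * e1), sum((p - gc) * e2))
  list(origin = gc, proj = proj)
}

#' Critical shoulder angle from landmarks
#'
#' Angle between the inferior-to-superior glenoid line and the line from the
#' inferior glenoid margin to the most lateral acromial landmark, measured as
#' a 2-D projection on the scapular plane (glenoid centre, angulus inferior,
#' angulus superior).
#'
#' @param landmarks a `landmark_set`.
#' @return CSA in degrees.
#' @export
measure_csa <- function(landmarks) {
  sp <- scapular_projection(landmarks)
  lm <- unclass(landmarks)
  gi2 <- sp$proj(lm["glenoid_inferior", ])
  gs2 <- sp$proj(lm["glenoid_superior", ])
  al2 <- sp$proj(lm["anterolateral_acromion", ])
  pl2 <- sp$proj(lm["posterolateral_acromion", ])
  acr <- if (pl2[1] > al2[1]) pl2 else al2  # most lateral; tie -> anterolateral
  angle_between(c(gs2 - gi2, 0), c(acr - gi2, 0))
}

#' Glenoid inclination from landmarks
#'
#' Angle between the supraspinatus-fossa axis (glenoid centre toward the
#' angulus superior, i.e. medial) and the inferior-to-superior glenoid line,
#' projected on the scapular plane. 90 deg means the glenoid face is
#' perpendicular to the fossa axis; smaller values tip the superior rim
#' medially. The clinical convention mapping is configurable downstream by
#' an affine relabelling, the generator and this operator share the same
#' definition.
#'
#' @param landmarks a `landmark_set`.
#' @return GI in degrees.
#' @export
measure_gi <- function(landmarks) {
  sp <- scapular_projection(landmarks)
  lm <- unclass(landmarks)
  gi2 <- sp$proj(lm["glenoid_inferior", ])
  gs2 <- sp$proj(lm["glenoid_superior", ])
  as2 <- sp$proj(lm["angulus_superior", ])
  angle_between(c(gs2 - gi2, 0), c(as2 - sp$proj(sp$origin), 0))
}

#' Effective glenoid height entering the stature scaling
#'
#' The generic reference model represents a male; for females 2.9 mm is
#' subtracted from the measured glenoid height before scaling.
#'
#' @param gh_patient measured glenoid height, mm.
#' @param sex 0 male, 1 female.
#' @return effective glenoid height, mm.
#' @export
effective_glenoid_height <- function(gh_patient, sex) {
  if (!all(sex %in% c(0, 1))) stop("sex must be 0 or 1")
  gh_patient - 2.9 * sex
}

#' Stature and body-mass scaling from glenoid height
#'
#' Patient height in mm follows
#' `h = 1800 + (gh_patient - gh_reference - 2.9 * sex) * 74`,
#' i.e. 7.4 cm of stature per millimetre of glenoid height, with a 2.9 mm
#' female glenoid-height offset. Body mass is scaled linearly with height
#' from a configurable reference mass at 1800 mm.
#'
#' @param gh_patient patient glenoid height, mm (> 0).
#' @param gh_reference glenoid height of the generic reference model, mm (> 0).
#' @param sex 0 male, 1 female.
#' @param reference_mass mass of the 1800 mm reference, kg.
#' @return list with `height_mm`, `body_mass_kg` and `body_weight_N`.
#' @export
scale_patient <- function(gh_patient, gh_reference, sex = 0, reference_mass = 75) {
  if (gh_patient <= 0 || gh_reference <= 0) stop("glenoid heights must be positive")
  h <- 1800 + (effective_glenoid_height(gh_patient, sex) - gh_reference) * 74
  mass <- reference_mass * h / 1800
  list(height_mm = h, body_mass_kg = mass, body_weight_N = mass * 9.81)
}
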