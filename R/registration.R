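sample_vertices <- function(mesh, n, seed = 1L) {
  v <- mesh$vertices
  if (nrow(v) <= n) return(v)
  with_seed(seed, function() v[sample.int(nrow(v), n), , drop = FALSE])
}

# principal-axes + centroid coarse alignment; sign ambiguity resolved by the
# lowest mean closest-point distance among proper rotations
principal_axes_init <- function(src, tgt) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  es <- eigen(stats::cov(src))$vectors
  et <- eigen(stats::cov(tgt))$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  best <- NULL; best_cost <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2))        # keeps det = +1
    R <- et %*% S %*% t(es)
    moved <- sweep(sweep(src, 2, cs, `-`) %*% t(R), 2, ct, `+`)
    nn <- cpp_nearest(moved, tgt)
    cost <- mean(sqrt(nn$dist2))
    if (cost < best_cost) { best_cost <- cost; best <- R }
  }
  Tm <- diag(4)
  Tm[1:3, 1:3] <- best
  Tm[1:3, 4] <- ct - as.numeric(best %*% cs)
  Tm
}

#' Affine iterative-closest-point alignment
#'
#' Aligns a source mesh to a target mesh with an affine transform: coarse
#' initialisation by centroid and principal axes, then ICP iterations in
#' which each step fits the least-squares affine map from the sampled source
#' points to their current closest target points. Iteration stops when the
#' relative improvement of the mean closest-point distance falls below
#' `tol` or after `max_iter` iterations.
#'
#' @param source,target `surface_mesh` objects.
#' @param n_samples surface points sampled per mesh (default 5000).
#' @param tol relative-improvement stopping threshold (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param seed sampling seed.
#' @return a 4x4 affine transform with attribute `residual` (final mean
#'   closest-point distance, mm).
#' @export
icp_affine <- function(source, target, n_samples = 5000, tol = 1e-6,
                       max_iter = 100, seed = 1L) {
  if (!nrow(source$vertices) || !nrow(target$vertices)) stop("empty mesh")
  src <- sample_vertices(source, n_samples, seed)
  tgt <- sample_vertices(target, n_samples, seed + 1L)
  Tm <- principal_axes_init(src, tgt)
  prev <- Inf
  H <- cbind(src, 1)
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(src, Tm)
    nn <- cpp_nearest(moved, tgt)
    cost <- mean(sqrt(nn$dist2))
    if (is.finite(prev) && prev - cost < tol * max(prev, 1e-12)) break
    prev <- cost
    corr <- tgt[nn$index, , drop = FALSE]
    M <- qr.solve(H, corr)               # 4 x 3, affine in homogeneous form
    Tm <- rbind(t(M), c(0, 0, 0, 1))
  }
  attr(Tm, "residual") <- prev
  Tm
}

# 3-D thin-plate spline map (biharmonic kernel U(r) = r plus affine part),
# fitted as a weighted ridge regression: large point weights act as hard
# constraints, the ridge on the kernel weights keeps the map smooth and the
# system well posed. Returns a function mapping points.
tps_fit <- function(ctrl, targets, weights, ridge = 1) {
  ctrl <- as.matrix(ctrl)
  m <- nrow(ctrl)
  K <- as.matrix(stats::dist(ctrl))
  P <- cbind(1, ctrl)
  B <- cbind(K, P)
  sw <- sqrt(weights)
  Baug <- rbind(B * sw, cbind(diag(sqrt(ridge), m), matrix(0, m, 4)))
  Yaug <- rbind(as.matrix(targets) * sw, matrix(0, m, 3))
  coef <- qr.coef(qr(Baug), Yaug)
  W <- coef[seq_len(m), , drop = FALSE]
  Aff <- coef[(m + 1):(m + 4), , drop = FALSE]
  function(x) {
    x <- as.matrix(x)
    d2 <- outer(rowSums(x^2), rep(1, m)) + outer(rep(1, nrow(x)), rowSums(ctrl^2)) -
      2 * x %*% t(ctrl)
    Dx <- sqrt(pmax(d2, 0))
    Dx %*% W + cbind(1, x) %*% Aff
  }
}

#' Landmark-constrained non-rigid warp
#'
#' Thin-plate-spline warp of an affinely pre-aligned source mesh toward a
#' target: control points are a subsample of the source surface paired with
#' their closest target points (soft, regularised), plus exactly four
#' glenoid landmarks treated as hard constraints (vanishing regularisation).
#' The warp is globally smooth; its maximum displacement-gradient norm over
#' the control sites is reported as an attribute.
#'
#' @param source pre-aligned source `surface_mesh`.
#' @param target target `surface_mesh`.
#' @param source_landmarks 4 x 3 matrix: glenoid landmark positions on the
#'   source (superior, anterior, inferior, posterior rim).
#' @param target_landmarks 4 x 3 matrix: their target positions.
#' @param n_controls surface control points (default 250).
#' @param lambda regularisation of the surface correspondences, mm (default 5).
#' @param seed sampling seed.
#' @return the warped `surface_mesh` with attributes `max_gradient` and
#'   `landmark_residual` (mm).
#' @export
nonrigid_warp <- function(source, target, source_landmarks, target_landmarks,
                          n_controls = 250, lambda = 5, seed = 1L) {
  source_landmarks <- as.matrix(source_landmarks)
  target_landmarks <- as.matrix(target_landmarks)
  if (nrow(source_landmarks) != 4 || nrow(target_landmarks) != 4)
    stop("exactly 4 constrained glenoid landmarks are required")
  ctrl_s <- sample_vertices(source, n_controls, seed)
  # keep the kernel system well conditioned: drop surface controls that sit
  # on top of a hard landmark constraint
  dlm <- cpp_nearest(ctrl_s, source_landmarks)
  ctrl_s <- ctrl_s[sqrt(dlm$dist2) > 2, , drop = FALSE]
  nn <- cpp_nearest(ctrl_s, target$vertices)
  ctrl_t <- target$vertices[nn$index, , drop = FALSE]
  ctrl <- rbind(ctrl_s, source_landmarks)
  tgts <- rbind(ctrl_t, target_landmarks)
  wts <- c(rep(1, nrow(ctrl_s)), rep(1e7, 4))
  f <- tps_fit(ctrl, tgts, wts, ridge = lambda)
  warped_v <- f(source$vertices)
  out <- surface_mesh(warped_v, source$faces)
  # displacement gradient estimated by central differences at control sites
  h <- 0.5
  gmax <- 0
  probe <- ctrl_s[seq_len(min(50, nrow(ctrl_s))), , drop = FALSE]
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- h
    gp <- (f(sweep(probe, 2, e, `+`)) - f(sweep(probe, 2, e, `-`))) / (2 * h)
    gp[, ax] <- gp[, ax] - 1
    gmax <- max(gmax, sqrt(rowSums(gp^2)))
  }
  attr(out, "max_gradient") <- gmax
  attr(out, "landmark_residual") <- max(sqrt(rowSums((f(source_landmarks) - target_landmarks)^2)))
  out
}

#' Registration accuracy metrics
#'
#' Symmetric Hausdorff distance, mean and median point-to-surface distance
#' (warped vertices to target surface, true point-to-triangle distances) and
#' per-landmark point-to-point errors.
#'
#' @param warped,target `surface_mesh` objects.
#' @param landmark_pairs optional list with `warped` and `target` matrices of
#'   corresponding landmarks (rownames preserved).
#' @return an object of class `registration_result`.
#' @export
registration_metrics <- function(warped, target, landmark_pairs = NULL) {
  if (!nrow(warped$vertices) || !nrow(target$vertices)) stop("empty mesh")
  d_wt <- cpp_point_surface_dist(warped$vertices, target$vertices, target$faces)
  d_tw <- cpp_point_surface_dist(target$vertices, warped$vertices, warped$faces)
  lm_err <- NULL
  if (!is.null(landmark_pairs)) {
    lw <- as.matrix(landmark_pairs$warped); lt <- as.matrix(landmark_pairs$target)
    lm_err <- sqrt(rowSums((lw - lt)^2))
    names(lm_err) <- rownames(lw)
  }
  structure(list(hausdorff = max(max(d_wt), max(d_tw)),
                 mean_p2s = mean(d_wt), median_p2s = stats::median(d_wt),
                 landmark_errors = lm_err),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: Hausdorff %.3f mm, mean p2s %.3f mm, median p2s %.3f mm\n",
              x$hausdorff, x$mean_p2s, x$median_p2s))
  if (!is.null(x$landmark_errors)) {
    cat("  landmark point-to-point errors (mm):\n")
    print(round(x$landmark_errors, 3))
  }
  invisible(x)
}

#' Full template-to-target registration
#'
#' Affine ICP followed by the landmark-constrained thin-plate-spline warp,
#' returning the warped mesh, the affine, and all accuracy metrics.
#'
#' @param source,target `surface_mesh` objects.
#' @param source_landmarks,target_landmarks `landmark_set`s of the two
#'   shoulders; the four glenoid rim landmarks (superior, anterior,
#'   inferior, posterior) are used as hard warp constraints and all eleven
#'   for the point-to-point verification.
#' @param n_samples ICP surface sample size.
#' @param seed sampling seed.
#' @return list with `warped_mesh`, `affine` and `metrics`
#'   (`registration_result`).
#' @export
register_scapula <- function(source, target, source_landmarks, target_landmarks,
                             n_samples = 5000, seed = 1L) {
  glenoid4 <- c("glenoid_superior", "glenoid_anterior", "glenoid_inferior",
                "glenoid_posterior")
  aff <- icp_affine(source, target, n_samples = n_samples, seed = seed)
  src_aff <- transform_mesh(source, aff)
  lm_s <- apply_transform(unclass(source_landmarks), aff)
  rownames(lm_s) <- rownames(unclass(source_landmarks))
  warped <- nonrigid_warp(src_aff, target,
                          lm_s[glenoid4, ], unclass(target_landmarks)[glenoid4, ],
                          seed = seed)
  # transport all 11 landmarks through the full map for verification
  all_warp <- nonrigid_warp_points(src_aff, target, lm_s[glenoid4, ],
                                   unclass(target_landmarks)[glenoid4, ],
                                   points = lm_s, seed = seed)
  metrics <- registration_metrics(warped, target,
                                  landmark_pairs = list(warped = all_warp,
                                                        target = unclass(target_landmarks)))
  list(warped_mesh = warped, affine = aff, metrics = metrics)
}

# apply the same TPS construction to arbitrary labelled points
nonrigid_warp_points <- function(source, target, source_landmarks,
                                 target_landmarks, points, n_controls = 250,
                                 lambda = 5, seed = 1L) {
  ctrl_s <- sample_vertices(source, n_controls, seed)
  dlm <- cpp_nearest(ctrl_s, as.matrix(source_landmarks))
  ctrl_s <- ctrl_s[sqrt(dlm$dist2) > 2, , drop = FALSE]
  nn <- cpp_nearest(ctrl_s, target$vertices)
  ctrl_t <- target$vertices[nn$index, , drop = FALSE]
  ctrl <- rbind(ctrl_s, as.matrix(source_landmarks))
  tgts <- rbind(ctrl_t, as.matrix(target_landmarks))
  wts <- c(rep(1, nrow(ctrl_s)), rep(1e7, 4))
  f <- tps_fit(ctrl, tgts, wts, ridge = lambda)
  out <- f(as.matrix(points))
  rownames(out) <- rownames(points)
  out
}
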