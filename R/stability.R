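#' Instability ratios of a joint reaction decomposition
#'
#' Vertical and horizontal instability ratios (shear over compression), the
#' radial magnitude `r_ins = sqrt(rho_vert^2 + rho_horz^2)` and the
#' quadrant-resolved direction `theta = atan2(rho_vert, rho_horz)` in the
#' glenoid plane (positive vertical = superior, positive horizontal =
#' anterior; superior is at 90 degrees).
#'
#' @param decomposition a `force_decomposition` (or list with `compression`,
#'   `vertical_shear`, `horizontal_shear`).
#' @return an object of class `instability_point`.
#' @export
instability_ratio <- function(decomposition) {
  comp <- decomposition$compression
  if (!is.finite(comp) || comp <= 0)
    stop("undefined instability ratio: compression must be positive")
  rv <- decomposition$vertical_shear / comp
  rh <- decomposition$horizontal_shear / comp
  structure(list(rho_vert = rv, rho_horz = rh,
                 r_ins = sqrt(rv^2 + rh^2),
                 theta = rad2deg(atan2(rv, rh))),
            class = "instability_point")
}

#' @export
print.instability_point <- function(x, ...) {
  cat(sprintf("instability_point: rho_vert %+.3f, rho_horz %+.3f, r_ins %.3f, theta %.1f deg\n",
              x$rho_vert, x$rho_horz, x$r_ins, x$theta))
  invisible(x)
}

#' Passive-stability polygon
#'
#' Passive stability ratios `p_n = g_n / r_humerus` at the eight rim
#' directions (45-degree increments around the glenoid cavity), where `g_n`
#' is the in-plane glenoid radius from the glenoid centre to the rim and
#' `r_humerus` the effective humeral radius. The polygon with vertex `n` at
#' distance `p_n` in its direction bounds the stable dynamic instability
#' ratios; its dimensionless area is computed by the shoelace formula.
#'
#' @param joint a `joint_geometry` (supplies the glenoid centre, plane frame
#'   and effective humeral radius).
#' @param rim_points_8 8 x 3 matrix of rim points at 45-degree spacing
#'   (e.g. from [glenoid_rim_points()] with `n = 8`).
#' @return an object of class `stability_polygon` with `p` (8 ratios), `g`
#'   (8 radii, mm), `theta` (8 directions, degrees, superior = 90),
#'   `r_humerus` (mm) and `area` (dimensionless).
#' @export
passive_polygon <- function(joint, rim_points_8) {
  rim <- as.matrix(rim_points_8)
  if (nrow(rim) != 8) stop("the passive polygon needs exactly 8 rim points")
  ctr <- joint$glenoid_center
  nrm <- joint$glenoid_plane_normal
  e_sup <- joint$e_superior %||% stop("joint geometry lacks in-plane axes")
  e_ant <- joint$e_anterior
  rel <- sweep(rim, 2, ctr, `-`)
  rel <- rel - outer(as.numeric(rel %*% nrm), nrm)   # project into the plane
  g <- sqrt(rowSums(rel^2))
  if (any(g <= 0)) stop("non-positive glenoid radius")
  r_h <- joint$humeral_radius_effective
  p <- g / r_h
  theta <- (rad2deg(atan2(as.numeric(rel %*% e_sup), as.numeric(rel %*% e_ant))) + 360) %% 360
  ord <- order(theta)
  structure(list(p = p[ord], g = g[ord], theta = theta[ord], r_humerus = r_h,
                 area = polygon_area(p[ord], theta[ord])),
            class = "stability_polygon")
}

# shoelace area of a radial polygon given vertex radii and angles (degrees)
polygon_area <- function(r, theta_deg) {
  th <- deg2rad(theta_deg)
  x <- r * cos(th); y <- r * sin(th)
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' @export
print.stability_polygon <- function(x, ...) {
  cat(sprintf("stability_polygon: area %.4f (dimensionless), r_humerus %.2f mm\n",
              x$area, x$r_humerus))
  cat("  p_n:", paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  invisible(x)
}

# polygon boundary radius in a given direction (degrees), by linear
# interpolation between the two adjacent vertices (ray-edge intersection)
polygon_boundary_radius <- function(polygon, theta_deg) {
  th <- polygon$theta
  r <- polygon$p
  n <- length(th)
  a <- (theta_deg + 360) %% 360
  j <- findInterval(a, th)
  i1 <- if (j == 0 || j == n) n else j
  i2 <- if (i1 == n) 1L else i1 + 1L
  t1 <- deg2rad(th[i1]); t2 <- deg2rad(th[i2])
  p1 <- c(r[i1] * cos(t1), r[i1] * sin(t1))
  p2 <- c(r[i2] * cos(t2), r[i2] * sin(t2))
  d <- c(cos(deg2rad(a)), sin(deg2rad(a)))
  e <- p2 - p1
  den <- d[1] * (-e[2]) - d[2] * (-e[1])
  if (abs(den) < 1e-14) return(vnorm(p1))
  s <- (p1[1] * (-e[2]) - p1[2] * (-e[1])) / den
  max(s, 0)
}

#' Exceedance of the passive-stability limit
#'
#' Compares each dynamic instability point to the passive polygon boundary
#' in its direction: `flag` is true when `r_ins` strictly exceeds the
#' boundary radius (points exactly on the polygon count as stable) and
#' `margin` is the boundary radius minus `r_ins`.
#'
#' @param series list of `instability_point`s (one per increment).
#' @param polygon a `stability_polygon`.
#' @return data.frame with increment, r_ins, theta, boundary, margin, exceed.
#' @export
exceedance <- function(series, polygon) {
  if (inherits(series, "instability_point")) series <- list(series)
  do.call(rbind, lapply(seq_along(series), function(i) {
    pt <- series[[i]]
    bound <- polygon_boundary_radius(polygon, pt$theta)
    data.frame(increment = i, r_ins = pt$r_ins, theta = pt$theta,
               boundary = bound, margin = bound - pt$r_ins,
               exceed = pt$r_ins > bound)
  }))
}

#' Instability-ratio series of a simulated arc
#'
#' Computes the dynamic instability point per increment of an
#' [simulate_arc()] result; increments with non-positive compression are
#' reported with `NA` ratios rather than dropped.
#'
#' @param sim an `arc_simulation`.
#' @return data.frame with increment, angle_deg, rho_vert, rho_horz, r_ins,
#'   theta, valid.
#' @export
instability_series <- function(sim) {
  f <- sim$forces
  do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    d <- list(compression = f$compression_N[i], vertical_shear = f$vshear_N[i],
              horizontal_shear = f$hshear_N[i])
    if (!is.finite(d$compression) || d$compression <= 0) {
      return(data.frame(increment = f$increment[i], angle_deg = f$angle_deg[i],
                        rho_vert = NA_real_, rho_horz = NA_real_,
                        r_ins = NA_real_, theta = NA_real_, valid = FALSE))
    }
    ip <- instability_ratio(d)
    data.frame(increment = f$increment[i], angle_deg = f$angle_deg[i],
               rho_vert = ip$rho_vert, rho_horz = ip$rho_horz,
               r_ins = ip$r_ins, theta = ip$theta, valid = TRUE)
  }))
}
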