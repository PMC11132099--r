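test_that("instability ratios follow the shear-over-compression arithmetic", {
  d <- list(compression = 10, vertical_shear = 0, horizontal_shear = 0)
  ip <- instability_ratio(d)
  expect_equal(c(ip$rho_vert, ip$rho_horz, ip$r_ins), c(0, 0, 0))

  d345 <- list(compression = 10, vertical_shear = 3, horizontal_shear = 4)
  ip345 <- instability_ratio(d345)
  expect_equal(ip345$rho_vert, 0.3)
  expect_equal(ip345$rho_horz, 0.4)
  expect_equal(ip345$r_ins, 0.5)
  expect_equal(ip345$r_ins, sqrt(ip345$rho_vert^2 + ip345$rho_horz^2),
               tolerance = 1e-12)

  deq <- list(compression = 8, vertical_shear = 2, horizontal_shear = 2)
  expect_equal(instability_ratio(deq)$theta, 45, tolerance = 1e-12)
  # quadrant resolution: posterior-inferior shear lands in (-180, -90)
  dpi <- list(compression = 10, vertical_shear = -3, horizontal_shear = -3)
  expect_equal(instability_ratio(dpi)$theta, -135, tolerance = 1e-12)
  expect_error(instability_ratio(list(compression = 0, vertical_shear = 1,
                                      horizontal_shear = 0)), "compression")
})

octagon_joint <- function(g = 26, r_bone = 24, offset = 2) {
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  rim <- cbind(0, g * sin(th), g * cos(th))
  jg <- compute_joint_center(c(0, 0, 0), c(1, 0, 0), r_bone,
                             cartilage_offset = offset)
  jg$e_superior <- c(0, 1, 0); jg$e_anterior <- c(0, 0, 1)
  list(joint = jg, rim = rim)
}

test_that("the unit-ratio polygon is a regular octagon of area 2*sqrt(2)", {
  ot <- octagon_joint(g = 26, r_bone = 24, offset = 2)  # g = r_effective
  poly <- passive_polygon(ot$joint, ot$rim)
  expect_equal(poly$p, rep(1, 8), tolerance = 1e-12)
  expect_equal(poly$area, 2 * sqrt(2), tolerance = 1e-12)
  # doubling the humeral radius halves every ratio and quarters the area
  ot2 <- octagon_joint(g = 26, r_bone = 50, offset = 2)
  poly2 <- passive_polygon(ot2$joint, ot2$rim)
  expect_equal(poly2$p, poly$p * 26 / 52, tolerance = 1e-12)
  expect_equal(poly2$area, poly$area / 4, tolerance = 1e-12)
})

test_that("irregular polygon area matches a triangulation oracle and label rotation", {
  g <- c(20, 24, 18, 26, 22, 19, 25, 21)
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  rim <- cbind(0, g * sin(th), g * cos(th))
  jg <- compute_joint_center(c(0, 0, 0), c(1, 0, 0), 24)
  jg$e_superior <- c(0, 1, 0); jg$e_anterior <- c(0, 0, 1)
  poly <- passive_polygon(jg, rim)
  # oracle: sum of triangle areas (centre fan) of the p-polygon
  p <- g / 26
  a_fan <- sum(vapply(1:8, function(k) {
    k2 <- if (k == 8) 1 else k + 1
    0.5 * p[k] * p[k2] * sin(pi / 4)
  }, 0))
  expect_equal(poly$area, a_fan, tolerance = 1e-12)
  # rotating the direction labels leaves the area unchanged
  rot <- c(4:8, 1:3)
  poly_rot <- passive_polygon(jg, rim[rot, ])
  expect_equal(poly_rot$area, poly$area, tolerance = 1e-12)
  expect_equal(poly$p, g / 26, tolerance = 1e-12)  # Eq exactness p = g / r
})

test_that("exceedance flags, margins and boundary interpolation are correct", {
  ot <- octagon_joint(g = 26, r_bone = 24, offset = 2)  # unit octagon
  poly <- passive_polygon(ot$joint, ot$rim)
  # the origin never exceeds; margin equals the boundary radius
  org <- exceedance(list(list(r_ins = 0, theta = 10)), poly)
  expect_false(org$exceed)
  expect_equal(org$margin, org$boundary, tolerance = 1e-12)
  # a point exactly on a vertex is stable by convention
  vert <- exceedance(list(list(r_ins = 1, theta = 90)), poly)
  expect_false(vert$exceed)
  expect_equal(vert$margin, 0, tolerance = 1e-12)
  # boundary mid-edge of the unit octagon: hand-computed edge intersection
  # between vertices at 0 and 45 degrees, the ray at 22.5 degrees crosses at
  # cos(pi/8) distance from the centre
  mid <- exceedance(list(list(r_ins = 1, theta = 22.5)), poly)
  expect_equal(mid$boundary, cos(pi / 8), tolerance = 1e-12)
  expect_true(mid$exceed)
  expect_equal(mid$margin, cos(pi / 8) - 1, tolerance = 1e-12)
  # monotone scaling of the shears can only switch flags on, never off
  comp <- 10
  flags <- vapply(c(0.5, 1, 1.5, 2, 3), function(s) {
    ip <- instability_ratio(list(compression = comp, vertical_shear = 6 * s,
                                 horizontal_shear = 3 * s))
    exceedance(list(ip), poly)$exceed
  }, NA)
  expect_true(all(diff(flags) >= 0))
})

test_that("instability series reports invalid increments instead of dropping them", {
  a <- demo_anatomy(seed = 3)
  sim <- simulate_arc(a, "abduction")
  ins <- instability_series(sim)
  expect_equal(nrow(ins), 12)
  expect_true(all(ins$valid))
  expect_equal(ins$r_ins, sqrt(ins$rho_vert^2 + ins$rho_horz^2), tolerance = 1e-12)
  # a forged non-positive compression increment is flagged, not dropped
  sim$forces$compression_N[3] <- -1
  ins2 <- instability_series(sim)
  expect_equal(nrow(ins2), 12)
  expect_false(ins2$valid[3])
  expect_true(is.na(ins2$r_ins[3]))
})
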