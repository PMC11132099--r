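test_that("sphere fit is exact on noise-free data and matches the nonlinear oracle", {
  pts <- sphere_points(100, center = c(0, 0, 0), radius = 25)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 25, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)

  noisy <- pts + withr::with_seed(2, matrix(rnorm(300, sd = 0.1), 100, 3))
  fitn <- fit_sphere(noisy)
  orc <- sphere_oracle(noisy)
  expect_lt(abs(fitn$radius - 25), 0.05)
  expect_lt(abs(fitn$radius - orc$radius), 2e-4)
  expect_lt(max(abs(fitn$center - orc$center)), 1e-3)

  coplanar <- cbind(matrix(rnorm(8), 4, 2), 0)
  expect_error(fit_sphere(coplanar), "degenerate|coplanar")
})

test_that("plane fit recovers exact and noisy planes, rejects collinear input", {
  th <- seq(0, 2 * pi, length.out = 10)[1:9]
  rim <- cbind(14 * cos(th), 14 * sin(th), 5)
  pl <- fit_glenoid_plane(rim, body_centroid = c(0, 0, -50))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_gt(pl$normal[3], 0)                  # oriented away from the body
  expect_equal(pl$centroid[3], 5, tolerance = 1e-12)

  noisy <- rim
  noisy[, 3] <- noisy[, 3] + withr::with_seed(3, runif(9, -0.2, 0.2))
  pln <- fit_glenoid_plane(noisy)
  ang <- acos(abs(sum(pln$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  # independent oracle: regression plane z = a x + b y + c
  cf <- coef(lm(noisy[, 3] ~ noisy[, 1] + noisy[, 2]))
  n_reg <- c(-cf[2], -cf[3], 1); n_reg <- n_reg / sqrt(sum(n_reg^2))
  expect_lt(acos(abs(sum(pln$normal * n_reg))) * 180 / pi, 0.05)

  line <- cbind(seq_len(9), 2 * seq_len(9), 3 * seq_len(9))
  expect_error(fit_glenoid_plane(line), "collinear")
})

test_that("glenoid centre circle fit is exact on circles and robust to noise", {
  th <- seq(0, 2 * pi, length.out = 10)[1:9]
  rim <- cbind(14 * sin(th), 14 * cos(th), 0)   # superior start, radius 14
  attr(rim, "angles") <- seq(0, 320, by = 40)
  pl <- list(normal = c(0, 0, 1), centroid = c(0, 0, 0))
  ctr <- fit_glenoid_center(rim, pl)
  expect_equal(as.numeric(ctr), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(attr(ctr, "radius"), 14, tolerance = 1e-9)

  noisy <- rim + withr::with_seed(4, cbind(matrix(rnorm(18, sd = 0.3), 9, 2), 0))
  attr(noisy, "angles") <- attr(rim, "angles")
  ctrn <- fit_glenoid_center(noisy, pl)
  expect_lt(sqrt(sum(ctrn^2)), 0.6)
  expect_error(fit_glenoid_center(rim[1:2, , drop = FALSE], pl), ">= 3")
})

test_that("joint centre follows the glenoid normal with the cartilage offset", {
  jg <- compute_joint_center(c(0, 0, 0), c(1, 0, 0), 25)
  expect_equal(jg$joint_center, c(27, 0, 0))
  jg0 <- compute_joint_center(c(1, 2, 3), c(0, 1, 0), 20, cartilage_offset = 0)
  expect_equal(sqrt(sum((jg0$joint_center - jg0$glenoid_center)^2)), 20)
  expect_error(compute_joint_center(c(0, 0, 0), c(2, 0, 0), 25), "unit length")

  a <- demo_anatomy(seed = 12)
  fit <- fit_joint_geometry(a$scapula, a$humerus, a$landmarks)
  gap <- sqrt(sum((fit$joint_center - fit$glenoid_center)^2)) - fit$humeral_radius_bone
  expect_equal(gap, 2, tolerance = 1e-6)
  # consequence of the construction: |joint - centre| = effective radius
  expect_equal(sqrt(sum((fit$joint_center - fit$glenoid_center)^2)),
               fit$humeral_radius_effective, tolerance = 1e-9)
})

test_that("CSA operator matches hand-constructed planar configurations", {
  mk <- function(acr) landmark_set(rbind(
    lateral_coracoid = c(5, 10, 15), anterolateral_acromion = acr,
    posterolateral_acromion = acr + c(-1, 0, -5),
    angulus_inferior = c(-40, -100, 0), angulus_superior = c(-90, 0, 0),
    glenoid_inferior = c(0, -18, 0), glenoid_superior = c(0, 18, 0),
    glenoid_lateral = c(0, 18, 0), glenoid_medial = c(0, -18, 0),
    glenoid_anterior = c(0, 0, 13), glenoid_posterior = c(0, 0, -13)))
  # collinear: acromion point straight along the glenoid line
  expect_equal(measure_csa(mk(c(0, 40, 0))), 0, tolerance = 1e-9)
  # 35-degree ray from the inferior margin (2-D arctangent construction)
  L <- 60
  acr35 <- c(L * sin(35 * pi / 180), -18 + L * cos(35 * pi / 180), 0)
  expect_equal(measure_csa(mk(acr35)), 35, tolerance = 1e-9)
  bad <- unclass(mk(c(0, 40, 0)))
  bad["angulus_superior", ] <- NA
  expect_error(measure_csa(structure(bad, class = "landmark_set")),
               "angulus_superior")
})

test_that("GI operator matches hand-constructed planar configurations", {
  mk <- function(sup) landmark_set(rbind(
    lateral_coracoid = c(5, 10, 15), anterolateral_acromion = c(30, 45, 0),
    posterolateral_acromion = c(29, 45, -5),
    angulus_inferior = c(-40, -100, 0), angulus_superior = c(-90, 0, 0),
    glenoid_inferior = -sup, glenoid_superior = sup,
    glenoid_lateral = sup, glenoid_medial = -sup,
    glenoid_anterior = c(0, 0, 13), glenoid_posterior = c(0, 0, -13)))
  # glenoid line perpendicular to the fossa axis
  expect_equal(measure_gi(mk(c(0, 18, 0))), 90, tolerance = 1e-9)
  # tipped 10 degrees medially: angle to the medial axis is 80 degrees
  sup80 <- 18 * c(-sin(10 * pi / 180), cos(10 * pi / 180), 0)
  expect_equal(measure_gi(mk(sup80)), 80, tolerance = 1e-9)
})

test_that("morphometrics are scale invariant, fits are scale equivariant", {
  a <- demo_anatomy(seed = 6)
  lm <- unclass(a$landmarks)
  big <- landmark_set(lm * 3)
  expect_equal(measure_csa(big), measure_csa(a$landmarks), tolerance = 1e-9)
  expect_equal(measure_gi(big), measure_gi(a$landmarks), tolerance = 1e-9)
  pts <- sphere_points(60, center = c(3, -2, 1), radius = 20)
  f1 <- fit_sphere(pts); f2 <- fit_sphere(pts * 2.5)
  expect_equal(f2$radius, 2.5 * f1$radius, tolerance = 1e-9)
  expect_equal(f2$center, 2.5 * f1$center, tolerance = 1e-9)
})

test_that("stature scaling follows the glenoid-height regression", {
  expect_equal(scale_patient(36, 36, sex = 0)$height_mm, 1800)
  expect_equal(scale_patient(37, 36, sex = 0)$height_mm, 1874)
  expect_equal(scale_patient(36, 36, sex = 1)$height_mm, 1800 - 2.9 * 74)
  # affine in glenoid height with slope exactly 74 mm/mm
  gh <- seq(30, 42, by = 0.5)
  h <- vapply(gh, function(g) scale_patient(g, 36)$height_mm, 0)
  expect_equal(unique(round(diff(h) / diff(gh), 9)), 74)
  # mass scales linearly with height from the reference mass
  s <- scale_patient(37, 36, reference_mass = 80)
  expect_equal(s$body_mass_kg, 80 * s$height_mm / 1800)
  expect_error(scale_patient(-1, 36), "positive")
  expect_equal(effective_glenoid_height(36, 1) - effective_glenoid_height(36, 0), -2.9)
})
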