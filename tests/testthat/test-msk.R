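test_that("moment arms match planar hand calculations and wrap geometry", {
  jg <- toy_joint()
  cfg <- model_config(use_cone = FALSE)
  # planar toy: origin (0,40,0), insertion (30,0,0), centre at origin, axis +z
  m <- muscle_element("toy", origin = c(0, 40, 0), insertion = c(30, 0, 0),
                      strength = 100)
  jg0 <- jg; jg0$joint_center <- c(0, 0, 0)
  pose <- gh_pose("abduction", 0)
  expect_equal(moment_arm(m, pose, jg0, cfg), 24, tolerance = 1e-9)

  # a line through the joint centre has zero lever
  m0 <- muscle_element("axial", origin = c(0, 40, 0), insertion = c(0, -40, 0),
                       strength = 100)
  expect_equal(moment_arm(m0, pose, jg0, cfg), 0, tolerance = 1e-12)

  # when the straight line penetrates the wrap sphere, the wrapped moment
  # arm is at least the straight-line one (and equals the wrap radius)
  mw <- muscle_element("wrapped", origin = c(5, 40, 0), insertion = c(10, -40, 0),
                       strength = 100, wrap = list(center = c(0, 0, 0), radius = 20))
  ms <- muscle_element("straight", origin = c(5, 40, 0), insertion = c(10, -40, 0),
                       strength = 100)
  aw <- moment_arm(mw, pose, jg0, cfg)
  as_ <- moment_arm(ms, pose, jg0, cfg)
  expect_gte(abs(aw), abs(as_))
  expect_equal(abs(aw), 20, tolerance = 1e-9)
})

test_that("muscle set construction follows the morphology", {
  a30 <- demo_anatomy(csa = 30, seed = 5)
  a38 <- demo_anatomy(csa = 38, seed = 5)
  j30 <- fit_joint_geometry(a30$scapula, a30$humerus, a30$landmarks)
  j38 <- fit_joint_geometry(a38$scapula, a38$humerus, a38$landmarks)
  m30 <- build_muscles(j30, a30$landmarks)
  m38 <- build_muscles(j38, a38$landmarks)
  expect_length(m30, 9)
  expect_true(all(vapply(m30, `[[`, 0, "strength") > 0))
  # strengths keep the configured PCSA proportions
  s <- vapply(m30, `[[`, 0, "strength")
  names(s) <- vapply(m30, `[[`, "", "name")
  cfg <- model_config()
  expect_equal(s / s[["supraspinatus"]],
               cfg$pcsa_cm2[names(s)] / cfg$pcsa_cm2[["supraspinatus"]],
               ignore_attr = TRUE)
  # a larger CSA puts the lateral deltoid origin farther lateral (along the
  # lateral axis) of the joint centre
  lat30 <- m30[[2]]$origin - j30$joint_center
  lat38 <- m38[[2]]$origin - j38$joint_center
  expect_gt(lat38[1], lat30[1])
  # the deltoid wrap sphere follows the joint centre (humeral head centre)
  expect_equal(m30[[2]]$wrap$center, j30$joint_center)
})

test_that("required moment vanishes with the hanging arm and is affine in load", {
  body <- scale_patient(36, 36)
  cfg <- model_config()
  m0 <- required_moment(gh_pose("abduction", 0), body, hand_load = 10, config = cfg)
  expect_lt(sqrt(sum(m0$moment^2)), 1e-9)
  m90 <- required_moment(gh_pose("abduction", 90), body, hand_load = 10, config = cfg)
  els <- vapply(seq(0, 120, by = 6), function(e) {
    sqrt(sum(required_moment(gh_pose("abduction", e), body, 10, cfg)$moment^2))
  }, 0)
  expect_equal(max(els), sqrt(sum(m90$moment^2)), tolerance = 1e-9)
  # doubling the load raises the moment affinely with the hand lever slope
  m1 <- required_moment(gh_pose("abduction", 60), body, 10, cfg)
  m2 <- required_moment(gh_pose("abduction", 60), body, 20, cfg)
  m3 <- required_moment(gh_pose("abduction", 60), body, 30, cfg)
  d12 <- m2$moment - m1$moment; d23 <- m3$moment - m2$moment
  expect_equal(d12, d23, tolerance = 1e-9)
  lever <- (0.186 + 0.146 + 0.506 * 0.108) * body$height_mm * sin(60 * pi / 180)
  expect_equal(sqrt(sum(d12^2)), 10 * lever, tolerance = 1e-6)
})

test_that("recruitment is exact for determined systems and symmetric cases", {
  jg <- toy_joint()
  cfg <- model_config(use_cone = FALSE)
  # single muscle, 1-DOF: F = M / r exactly
  mus <- toy_planar_muscles(arms = 20, strengths = 500)
  jg0 <- jg; jg0$joint_center <- c(0, 0, 0)
  sol <- solve_recruitment(mus, NULL, c(0, 0, 4000), jg0, cfg)
  expect_equal(sol$states$force_N, 200, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-9)
  # two identical parallel muscles share the load equally
  mus2 <- toy_planar_muscles(arms = c(20, 20), strengths = c(500, 500))
  sol2 <- solve_recruitment(mus2, NULL, c(0, 0, 4000), jg0, cfg)
  expect_equal(sol2$states$force_N[1], sol2$states$force_N[2], tolerance = 1e-4)
  expect_lt(sol2$residual, 1e-9)
  # infeasible demand names the binding constraint
  expect_error(solve_recruitment(mus, NULL, c(0, 0, 2e5), jg0, cfg),
               "strength bound")
  expect_error(solve_recruitment(mus, NULL, c(0, 4000, 0), jg0, cfg),
               "not achievable")
})

test_that("recruitment matches the brute-force grid oracle on a 3-muscle toy", {
  arms <- c(15, 25, 40)
  strengths <- c(300, 400, 250)
  mus <- toy_planar_muscles(arms, strengths)
  jg0 <- toy_joint(); jg0$joint_center <- c(0, 0, 0)
  cfg <- model_config(use_cone = FALSE)
  for (M in c(4000, 9000, 15000)) {
    sol <- solve_recruitment(mus, NULL, c(0, 0, M), jg0, cfg)
    ref <- grid_recruitment(arms, strengths, M, res = 0.1)
    expect_lt(max(abs(sol$states$force_N - ref) / strengths), 0.01)
    expect_lt(sol$residual, 1e-6 * M)
    # local optimality: random feasible nullspace perturbations cost more
    cost <- function(F) sum((F / strengths)^3)
    Zn <- c(1 / arms[1], -1 / arms[2], 0); Zn2 <- c(0, 1 / arms[2], -1 / arms[3])
    for (k in 1:20) {
      d <- rnorm(1, sd = 2) * Zn + rnorm(1, sd = 2) * Zn2
      Fp <- sol$states$force_N + d
      if (all(Fp >= 0 & Fp <= strengths))
        expect_gte(cost(Fp), cost(sol$states$force_N) - 1e-8)
    }
  }
})

test_that("simulated arcs satisfy equilibrium, decomposition and mirror invariance", {
  a <- demo_anatomy(seed = 17)
  sim <- simulate_arc(a, "abduction")
  expect_equal(nrow(sim$forces), 12)
  expect_true(all(sim$forces$residual_Nmm <=
                  1e-6 * pmax(sim$forces$required_Nmm, 1)))
  # norm conservation of the decomposition
  expect_equal(sim$forces$compression_N^2 + sim$forces$vshear_N^2 +
               sim$forces$hshear_N^2, sim$forces$total_N^2,
               tolerance = 1e-9)
  # left-side input is mirrored before analysis and gives identical forces
  al <- generate_shoulder(anatomy_params(csa_deg = 33, gi_deg = 84, seed = 17,
                                         side = "left"))
  sim_l <- simulate_arc(al, "abduction")
  expect_equal(sim_l$forces$total_N, sim$forces$total_N, tolerance = 1e-9)
})

test_that("with the cone disabled the unloaded hanging arm carries only its weight", {
  a <- demo_anatomy(seed = 19)
  cfg <- model_config(hand_load = 0, use_cone = FALSE)
  sim <- simulate_arc(a, "abduction", config = cfg)
  arm_weight <- (0.028 + 0.016 + 0.006) * sim$body$body_mass_kg * 9.81
  # the interior-point floor leaves fractions of a newton of muscle force
  expect_equal(sim$forces$total_N[1], arm_weight, tolerance = 0.01)
})

test_that("increasing hand load never decreases the peak total reaction", {
  a <- demo_anatomy(seed = 23)
  peaks <- vapply(c(0, 10, 20), function(L) {
    max(simulate_arc(a, "abduction", config = model_config(hand_load = L))$forces$total_N)
  }, 0)
  expect_true(all(diff(peaks) >= -1e-6))
})

test_that("medialising the joint centre lengthens the lateral deltoid lever and lowers peak force", {
  a <- demo_anatomy(csa = 32, seed = 7)
  run <- function(off) {
    cfg <- model_config(cartilage_offset = off)
    jg <- fit_joint_geometry(a$scapula, a$humerus, a$landmarks,
                             cartilage_offset = off)
    mus <- build_muscles(jg, a$landmarks, cfg)
    dl <- mus[[2]]
    ma <- vapply(seq(0, 120, length.out = 12), function(el) {
      moment_arm(dl, gh_pose("abduction", el), jg, cfg)
    }, 0)
    sim <- simulate_arc(a, "abduction", config = cfg, joint = jg)
    list(ma = ma, peak = max(sim$forces$total_N))
  }
  lateral <- run(2); medial <- run(-2)
  expect_true(all(medial$ma >= lateral$ma - 1e-9))
  expect_gt(mean(medial$ma - lateral$ma), 0.5)
  expect_lt(medial$peak, lateral$peak)
})
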