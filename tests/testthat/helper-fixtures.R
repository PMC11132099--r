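# shared fixtures: analytic point clouds, toy joints and toy muscle systems

sphere_points <- function(n, center = c(0, 0, 0), radius = 25, seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(n * 3), n, 3)
    u <- u / sqrt(rowSums(u^2))
    sweep(u * radius, 2, center, `+`)
  })
}

# independent nonlinear least-squares sphere oracle (geometric residuals)
sphere_oracle <- function(points) {
  obj <- function(th) {
    sum((sqrt(rowSums(sweep(points, 2, th[1:3], `-`)^2)) - th[4])^2)
  }
  start <- c(colMeans(points), mean(sqrt(rowSums(sweep(points, 2, colMeans(points), `-`)^2))))
  fit <- optim(start, obj, method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  list(center = fit$par[1:3], radius = fit$par[4])
}

# a small analytic "joint": circular rim of radius g in the y-z plane,
# apex along +x at distance r_eff from the centre
toy_joint <- function(g = 15, r_bone = 24, offset = 2, n_rim = 9) {
  th <- seq(0, 2 * pi, length.out = n_rim + 1)[seq_len(n_rim)]
  rim <- cbind(0, g * sin(th), g * cos(th))   # starts superior, through anterior
  jg <- compute_joint_center(c(0, 0, 0), c(1, 0, 0), r_bone,
                             cartilage_offset = offset, rim_points = rim)
  jg$e_superior <- c(0, 1, 0)
  jg$e_anterior <- c(0, 0, 1)
  jg
}

# planar toy muscles: insertion on the +x axis, origin straight above, so the
# moment arm about +z equals the insertion abscissa and the pull is +y
toy_planar_muscles <- function(arms, strengths) {
  lapply(seq_along(arms), function(i) {
    muscle_element(sprintf("toy%d", i),
                   origin = c(arms[i], 60, 0),
                   insertion = c(arms[i], 0, 0),
                   strength = strengths[i])
  })
}

# brute-force cubic-cost recruitment for <= 3 planar muscles at grid
# resolution `res`: F3 solved from the 1-DOF moment equation
grid_recruitment <- function(arms, strengths, M, res = 0.1) {
  f1 <- seq(0, strengths[1], by = res)
  f2 <- if (length(arms) >= 2) seq(0, strengths[2], by = res) else 0
  best <- NULL; best_cost <- Inf
  for (a in f1) {
    rem <- M - arms[1] * a
    if (length(arms) == 3) {
      f3 <- (rem - arms[2] * f2) / arms[3]
      ok <- f3 >= -1e-9 & f3 <= strengths[3] + 1e-9
      if (!any(ok)) next
      cost <- (a / strengths[1])^3 + (f2[ok] / strengths[2])^3 +
        (pmax(f3[ok], 0) / strengths[3])^3
      j <- which.min(cost)
      if (cost[j] < best_cost) {
        best_cost <- cost[j]
        best <- c(a, f2[ok][j], max(f3[ok][j], 0))
      }
    }
  }
  best
}

demo_anatomy <- function(csa = 33, gi = 84, seed = 2, side = "right", ...) {
  generate_shoulder(anatomy_params(csa_deg = csa, gi_deg = gi, seed = seed,
                                   side = side, ...))
}

# smooth null curves for SPM calibration: subjects x 12 angles
null_curves <- function(n_subj, n_angle = 12) {
  t(vapply(seq_len(n_subj), function(i) {
    a <- rnorm(3)
    x <- seq(0, 1, length.out = n_angle)
    a[1] + a[2] * sin(pi * x) + a[3] * cos(pi * x) + rnorm(n_angle, sd = 0.3)
  }, numeric(n_angle)))
}
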