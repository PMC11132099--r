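toy_curves <- function(values_by_subject, group, variable = "total_pctBW",
                       angles = seq(0, 120, length.out = 12), side = "right") {
  do.call(rbind, lapply(names(values_by_subject), function(s) {
    data.frame(subject = s, group = group, side = side, motion = "abduction",
               variable = variable, angle = angles,
               value = values_by_subject[[s]])
  }))
}

test_that("group summaries reproduce hand-computed means, SDs and peak differences", {
  base <- sin(seq(0, pi, length.out = 12)) * 50
  A <- toy_curves(list(a1 = base * 1.05, a2 = base * 1.15), "RCT")
  B <- toy_curves(list(b1 = base * 0.95, b2 = base * 1.05), "OA")
  gs <- group_summary(rbind(A, B))
  # identical groups: zero percent difference
  gsid <- group_summary(rbind(A, transform(A, group = "OA",
                                           subject = paste0(subject, "x"))))
  expect_equal(gsid$percent_difference, 0, tolerance = 1e-12)
  # A = 1.1 x B on the group means: +10 percent peak difference
  expect_equal(gs$percent_difference, 10, tolerance = 1e-9)
  # hand-computed mean and SD of a three-subject toy at one angle
  C <- toy_curves(list(c1 = base + 1, c2 = base + 3, c3 = base + 8), "RCT")
  gs3 <- group_summary(rbind(C, B))
  row <- gs3$table[gs3$table$group == "RCT" & gs3$table$angle == 0, ]
  expect_equal(row$mean, mean(c(1, 3, 8)))
  expect_equal(row$sd, sd(c(1, 3, 8)))
  expect_error(group_summary(toy_curves(list(x = base), "RCT")), ">= 2")
})

test_that("SPM detects injected effects, stays quiet under the null, and is symmetric", {
  withr::local_seed(11)
  n <- 15
  A <- null_curves(n); B <- null_curves(n)
  colnames(A) <- colnames(B) <- seq(0, 120, length.out = 12)
  null_res <- spm_ttest(A, B, seed = 101, n_perm = 500)
  expect_length(null_res$clusters, 0)
  # a 3-SD mean shift injected over angles 40-80 must be detected there
  shift <- B
  sd_col <- apply(B, 2, sd)
  idx <- which(as.numeric(colnames(B)) >= 40 & as.numeric(colnames(B)) <= 80)
  shift[, idx] <- shift[, idx] + 3 * sd_col[idx]
  eff <- spm_ttest(A, shift, seed = 101, n_perm = 500)
  expect_gt(length(eff$clusters), 0)
  covered <- unlist(lapply(eff$clusters, function(cl) {
    any(as.numeric(colnames(B)[idx]) >= cl[1] & as.numeric(colnames(B)[idx]) <= cl[2])
  }))
  expect_true(any(covered))
  # group-order symmetry up to the sign of t
  swapped <- spm_ttest(shift, A, seed = 101, n_perm = 500)
  expect_equal(swapped$t_curve, -eff$t_curve, tolerance = 1e-12)
  expect_error(spm_ttest(A[, 1:6], B), "grids differ")
})

test_that("the permutation threshold is stable across seeds", {
  withr::local_seed(12)
  A <- null_curves(20); B <- null_curves(20)
  ts <- vapply(1:6, function(s) spm_ttest(A, B, seed = s, n_perm = 10000)$t_star, 0)
  expect_lt(sd(ts) / mean(ts), 0.02)
})

test_that("mirroring flips only anterior-positive sign conventions before pooling", {
  base <- seq_len(12)
  right <- toy_curves(list(r = base), "RCT", variable = "hshear_N")
  left <- toy_curves(list(l = base), "RCT", variable = "hshear_N", side = "left")
  pooled <- mirror_and_pool(rbind(right, left))
  expect_equal(pooled$value[pooled$subject == "r"], base)
  expect_equal(pooled$value[pooled$subject == "l"], -base)
  vert <- toy_curves(list(l = base), "RCT", variable = "vshear_N", side = "left")
  expect_equal(mirror_and_pool(vert)$value, base)
  bad <- right; bad$side <- "upside-down"
  expect_error(mirror_and_pool(bad), "side")
  # a left-mirrored copy of the same subject pools with zero between-copy
  # variance once conventions are normalised
  a <- demo_anatomy(seed = 29)
  al <- generate_shoulder(anatomy_params(csa_deg = 33, gi_deg = 84, seed = 29,
                                         side = "left"))
  cr <- curves_from_sims(list(r = simulate_arc(a, "abduction")), "RCT")
  cl <- curves_from_sims(list(l = simulate_arc(al, "abduction")), "RCT")
  # the simulator already normalised conventions by mirroring the geometry
  pooled2 <- mirror_and_pool(rbind(cr, cl), flip_vars = character(0))
  sp <- split(pooled2$value, list(pooled2$variable, pooled2$angle))
  expect_true(all(vapply(sp, function(v) abs(diff(range(v))), 0) < 1e-9))
})
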