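#' Assemble long-format curve data from arc simulations
#'
#' One row per subject, variable and elevation angle, the standard exchange
#' format of the cohort-statistics layer.
#'
#' @param sims named list of `arc_simulation`s (names = subject ids).
#' @param group group label for all subjects in `sims`.
#' @return data.frame with subject, group, side, motion, variable, angle,
#'   value.
#' @export
curves_from_sims <- function(sims, group) {
  vars <- c(total_pctBW = "total_pctBW", compression_N = "compression_N",
            vshear_N = "vshear_N", hshear_N = "hshear_N")
  do.call(rbind, lapply(names(sims), function(id) {
    sim <- sims[[id]]
    f <- sim$forces
    do.call(rbind, lapply(names(vars), function(v) {
      data.frame(subject = id, group = group, side = sim$params$side,
                 motion = sim$motion, variable = v, angle = f$angle_deg,
                 value = f[[v]])
    }))
  }))
}

#' Mirror left-side curves and pool with right-side curves
#'
#' Anterior-positive quantities (horizontal shear and the horizontal
#' instability ratio) change sign convention under sagittal mirroring; for
#' subjects recorded as left-sided those variables are sign-flipped before
#' pooling so that positive always means anterior. Vertical, compressive and
#' total quantities are unchanged.
#'
#' Curves produced by [simulate_arc()] are already in the anatomical
#' convention (left-side geometry is mirrored before analysis), so pooling
#' them uses `flip_vars = character(0)`; the default flip set is for curves
#' recorded in a side-local frame.
#'
#' @param curves long-format data.frame from [curves_from_sims()].
#' @param flip_vars variables whose sign convention flips for left sides.
#' @return the pooled data.frame.
#' @export
mirror_and_pool <- function(curves, flip_vars = c("hshear_N", "rho_horz")) {
  if (!all(curves$side %in% c("left", "right")))
    stop("unknown side label; must be 'left' or 'right'")
  flip <- curves$side == "left" & curves$variable %in% flip_vars
  curves$value[flip] <- -curves$value[flip]
  curves$side <- "right"   # pooled, right-handed convention
  curves
}

#' Per-angle group summary and peak comparison
#'
#' Mean and SD per group at each angle of a variable, the peak of each
#' group-mean curve with its angle, and the percent difference of the group
#' peak means, `(peak_A - peak_B) / peak_B * 100` with groups in the order
#' given.
#'
#' @param curves long-format data.frame (one variable).
#' @param groups character(2): the comparison order (A, B).
#' @return list with `table` (angle, group, mean, sd, n), `peaks` and
#'   `percent_difference`.
#' @export
group_summary <- function(curves, groups = c("RCT", "OA")) {
  stopifnot(length(unique(curves$variable)) == 1)
  for (g in groups) {
    ns <- length(unique(curves$subject[curves$group == g]))
    if (ns < 2) stop(sprintf("group '%s' needs >= 2 subjects (has %d)", g, ns))
  }
  tab <- do.call(rbind, lapply(groups, function(g) {
    cg <- curves[curves$group == g, ]
    ag <- sort(unique(cg$angle))
    data.frame(angle = ag, group = g,
               mean = vapply(ag, function(a) mean(cg$value[cg$angle == a]), 0),
               sd = vapply(ag, function(a) stats::sd(cg$value[cg$angle == a]), 0),
               n = length(unique(cg$subject)))
  }))
  peaks <- do.call(rbind, lapply(groups, function(g) {
    tg <- tab[tab$group == g, ]
    i <- which.max(abs(tg$mean))
    # also the mean of per-subject maxima, reported alongside
    cg <- curves[curves$group == g, ]
    subj_max <- tapply(abs(cg$value), cg$subject, max)
    data.frame(group = g, peak_mean = tg$mean[i], peak_angle = tg$angle[i],
               mean_subject_peak = mean(subj_max))
  }))
  pd <- (peaks$peak_mean[1] - peaks$peak_mean[2]) / peaks$peak_mean[2] * 100
  list(table = tab, peaks = peaks, percent_difference = pd)
}

# wide matrix (subjects x angles) of one group's curves for one variable
curves_matrix <- function(curves, group) {
  cg <- curves[curves$group == group, ]
  ag <- sort(unique(cg$angle))
  subs <- unique(cg$subject)
  m <- t(vapply(subs, function(s) {
    cs <- cg[cg$subject == s, ]
    cs$value[match(ag, cs$angle)]
  }, numeric(length(ag))))
  rownames(m) <- subs; colnames(m) <- ag
  m
}

# pooled-variance two-sample t statistic per column
pointwise_t <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- (colSums(A * A) - na * ma^2) / (na - 1)
  vb <- (colSums(B * B) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' One-dimensional SPM two-sample t-test along the elevation arc
#'
#' Pointwise two-tailed two-sample t statistic over the angle grid, with the
#' family-wise critical threshold t* taken from the permutation distribution
#' of the curve-maximum statistic (max |t| over the grid under random
#' relabelling of group membership, observed labelling included). Angles
#' where |t| > t* form the significant clusters.
#'
#' @param curves_a,curves_b subject-by-angle matrices (identical angle
#'   grids), or a long-format data.frame plus `groups`.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_perm number of permutations (default 2000).
#' @param seed permutation seed.
#' @return an object of class `spm_result`: `t_curve`, `t_star`,
#'   `significant`, `clusters` (list of angle index ranges), `angles`,
#'   `alpha`.
#' @export
spm_ttest <- function(curves_a, curves_b, alpha = 0.05, n_perm = 2000,
                      seed = 1L) {
  A <- as.matrix(curves_a); B <- as.matrix(curves_b)
  if (ncol(A) != ncol(B)) stop("angle grids differ between groups")
  if (nrow(A) < 2 || nrow(B) < 2) stop("each group needs >= 2 subjects")
  t_obs <- pointwise_t(A, B)
  X <- rbind(A, B)
  na <- nrow(A); ntot <- nrow(X)
  max_t <- with_seed(seed, function() {
    vapply(seq_len(n_perm - 1), function(i) {
      idx <- sample.int(ntot, na)
      max(abs(pointwise_t(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])))
    }, 0)
  })
  max_t <- c(max(abs(t_obs)), max_t)      # include the observed labelling
  t_star <- stats::quantile(max_t, 1 - alpha, names = FALSE, type = 1)
  sig <- abs(t_obs) > t_star
  angles <- suppressWarnings(as.numeric(colnames(A)))
  if (any(is.na(angles))) angles <- seq_along(t_obs)
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  clusters <- Map(function(s, e) c(angles[s], angles[e]),
                  starts[runs$values], ends[runs$values])
  structure(list(t_curve = t_obs, t_star = t_star, significant = sig,
                 clusters = clusters, angles = angles, alpha = alpha,
                 n_perm = n_perm),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("spm_result: t* = %.3f (alpha %.2f, %d permutations)\n",
              x$t_star, x$alpha, x$n_perm))
  if (length(x$clusters)) {
    for (cl in x$clusters)
      cat(sprintf("  significant cluster: %.0f-%.0f deg\n", cl[1], cl[2]))
  } else cat("  no significant clusters\n")
  invisible(x)
}

#' Mean +/- SD band plot with significance bar
#'
#' Publication-style comparison of two group-mean curves with shaded SD
#' bands and a bar marking SPM-significant angles. Requires ggplot2.
#'
#' @param curves long-format data.frame (one variable).
#' @param spm an `spm_result` for the same comparison (optional).
#' @param groups character(2) group order.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_group_curves <- function(curves, spm = NULL, groups = c("RCT", "OA"),
                              ylab = unique(curves$variable)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gs <- group_summary(curves, groups)$table
  gs$lo <- gs$mean - gs$sd; gs$hi <- gs$mean + gs$sd
  p <- ggplot2::ggplot(gs, ggplot2::aes(x = .data$angle, y = .data$mean,
                                        colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Elevation angle (deg)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(spm) && any(spm$significant)) {
    ymin <- min(gs$lo)
    sig <- data.frame(angle = spm$angles[spm$significant], y = ymin)
    p <- p + ggplot2::geom_point(data = sig,
                                 ggplot2::aes(x = .data$angle, y = .data$y),
                                 inherit.aes = FALSE, shape = 15, colour = "grey40")
  }
  p
}
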