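#' Experiment configuration
#'
#' Validated configuration for a full cohort experiment: cohort sizes and
#' seeds, motions, hand load, cartilage offset, reference glenoid height and
#' mass, solver tolerance, SPM permutations and the output directory.
#'
#' @param n_rct,n_oa cohort sizes (default 55 RCT-like, 48 OA-like).
#' @param seed master seed; all per-subject and permutation seeds derive
#'   from it.
#' @param motions character vector of motions to simulate.
#' @param hand_load hand load, N.
#' @param cartilage_offset cartilage allowance, mm.
#' @param reference_glenoid_height generic-model glenoid height, mm.
#' @param reference_mass reference body mass, kg.
#' @param solver_tol recruitment solver tolerance.
#' @param n_perm SPM permutations.
#' @param out_dir output directory (created if missing).
#' @return a named list of class `experiment_config`.
#' @export
experiment_config <- function(n_rct = 55, n_oa = 48, seed = 1L,
                              motions = c("abduction", "flexion"),
                              hand_load = 10, cartilage_offset = 2,
                              reference_glenoid_height = 36,
                              reference_mass = 75, solver_tol = 1e-8,
                              n_perm = 2000, out_dir = tempfile("glenosim_")) {
  stopifnot(n_rct >= 2, n_oa >= 2, hand_load >= 0,
            reference_glenoid_height > 0, reference_mass > 0,
            all(motions %in% c("abduction", "flexion")))
  structure(list(n_rct = as.integer(n_rct), n_oa = as.integer(n_oa),
                 seed = as.integer(seed), motions = motions,
                 hand_load = hand_load, cartilage_offset = cartilage_offset,
                 reference_glenoid_height = reference_glenoid_height,
                 reference_mass = reference_mass, solver_tol = solver_tol,
                 n_perm = as.integer(n_perm), out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full cohort experiment
#'
#' Generates the two synthetic cohorts, fits each subject's joint geometry,
#' simulates the configured motion arcs, computes instability ratios and
#' passive-stability polygons, pools left-mirrored and right results, and
#' compares the groups with group summaries and SPM t-tests. Per-subject
#' failures (e.g. infeasible recruitment) are logged and the subject is
#' excluded with a report; the run is deterministic for a fixed seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-subject progress.
#' @return a result bundle (list) with `cohorts`, `curves`, `summaries`,
#'   `spm`, `polygons`, `failures` and `manifest`; files are written under
#'   `config$out_dir`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir)) stop("output directory is not writable")
  seeds <- derive_seeds(config$seed, 3)
  mc <- model_config(hand_load = config$hand_load,
                     cartilage_offset = config$cartilage_offset,
                     reference_glenoid_height = config$reference_glenoid_height,
                     reference_mass = config$reference_mass,
                     solver_tol = config$solver_tol)
  cohorts <- list(RCT = sample_cohort("RCT", config$n_rct, seed = seeds[1]),
                  OA = sample_cohort("OA", config$n_oa, seed = seeds[2]))
  manifest_df <- rbind(cohort_manifest(cohorts$RCT, "RCT"),
                       cohort_manifest(cohorts$OA, "OA"))
  utils::write.csv(manifest_df, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)

  failures <- list()
  all_curves <- list()
  polygons <- list()
  for (grp in names(cohorts)) {
    sims_by_motion <- stats::setNames(vector("list", length(config$motions)),
                                      config$motions)
    for (i in seq_along(cohorts[[grp]])) {
      id <- sprintf("%s%03d", grp, i)
      res <- tryCatch({
        anat <- generate_shoulder(cohorts[[grp]][[i]],
                                  cartilage_offset = config$cartilage_offset)
        if (anat$params$side == "left") anat <- mirror_shoulder(anat)
        joint <- fit_joint_geometry(anat$scapula, anat$humerus, anat$landmarks,
                                    cartilage_offset = config$cartilage_offset)
        rim8 <- glenoid_rim_points(anat$scapula, anat$landmarks, n = 8)
        polygons[[id]] <- passive_polygon(joint, rim8)
        for (mo in config$motions) {
          sims_by_motion[[mo]][[id]] <- simulate_arc(anat, mo, config = mc,
                                                     joint = joint)
        }
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(res)) {
        failures[[id]] <- res
        for (mo in config$motions) sims_by_motion[[mo]][[id]] <- NULL
      } else if (verbose) message(sprintf("subject %s done", id))
    }
    for (mo in config$motions) {
      cv <- curves_from_sims(sims_by_motion[[mo]], grp)
      # instability-ratio curves appended alongside the force components
      rc <- do.call(rbind, lapply(names(sims_by_motion[[mo]]), function(id) {
        ins <- instability_series(sims_by_motion[[mo]][[id]])
        sd_ <- sims_by_motion[[mo]][[id]]$params$side
        rbind(data.frame(subject = id, group = grp, side = sd_, motion = mo,
                         variable = "rho_vert", angle = ins$angle_deg,
                         value = ins$rho_vert),
              data.frame(subject = id, group = grp, side = sd_, motion = mo,
                         variable = "rho_horz", angle = ins$angle_deg,
                         value = ins$rho_horz))
      }))
      all_curves[[paste(grp, mo)]] <- rbind(cv, rc)
    }
  }
  curves <- do.call(rbind, all_curves)
  rownames(curves) <- NULL
  # simulate_arc mirrors left-side geometry before analysis, so the curves
  # are already anterior-positive: pool without re-flipping
  curves <- mirror_and_pool(curves, flip_vars = character(0))
  utils::write.csv(curves, file.path(config$out_dir, "curves.csv"),
                   row.names = FALSE)

  summaries <- list(); spm <- list()
  for (mo in config$motions) {
    for (v in unique(curves$variable)) {
      key <- paste(mo, v, sep = "_")
      cv <- curves[curves$motion == mo & curves$variable == v &
                   is.finite(curves$value), ]
      summaries[[key]] <- tryCatch(group_summary(cv), error = function(e) NULL)
      spm[[key]] <- tryCatch(
        spm_ttest(curves_matrix(cv, "RCT"), curves_matrix(cv, "OA"),
                  n_perm = config$n_perm, seed = seeds[3]),
        error = function(e) NULL)
    }
  }
  summary_tab <- do.call(rbind, lapply(names(summaries), function(k) {
    s <- summaries[[k]]
    if (is.null(s)) return(NULL)
    cbind(comparison = k, s$table)
  }))
  utils::write.csv(summary_tab, file.path(config$out_dir, "group_summary.csv"),
                   row.names = FALSE)

  poly_area <- vapply(polygons, function(p) p$area, 0)
  poly_group <- substr(names(polygons), 1, 2)
  polygon_comparison <- list(
    mean_area_RCT = mean(poly_area[poly_group == "RC"]),
    mean_area_OA = mean(poly_area[poly_group == "OA"]),
    percent_difference_OA_vs_RCT =
      (mean(poly_area[poly_group == "OA"]) / mean(poly_area[poly_group == "RC"]) - 1) * 100)
  jsonlite::write_json(polygon_comparison,
                       file.path(config$out_dir, "polygon_comparison.json"),
                       digits = NA, auto_unbox = TRUE)
  spm_out <- lapply(spm, function(s) if (is.null(s)) NULL else
    list(t_curve = s$t_curve, t_star = s$t_star, clusters = s$clusters,
         angles = s$angles, alpha = s$alpha))
  jsonlite::write_json(spm_out, file.path(config$out_dir, "spm.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, digits = NA, auto_unbox = TRUE)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, derived_seeds = seeds,
                   package_version = as.character(utils::packageVersion("glenosim")),
                   n_failures = length(failures),
                   failures = failures)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  list(cohorts = cohorts, curves = curves, summaries = summaries, spm = spm,
       polygons = polygons, polygon_comparison = polygon_comparison,
       failures = failures, manifest = manifest)
}
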