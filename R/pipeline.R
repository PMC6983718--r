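#' Default pipeline configuration
#'
#' Bundles per-stage parameter blocks for the three end-to-end analyses.
#' All defaults mirror the reference study conditions: 5-s cadence, sigma =
#' 3.0 kymograph smoothing, 14 um x 200 s composite extents, a 20-point
#' NEB-aligned window, AP-MS thresholds 3 / 20% / 50 / 1.5-fold and the
#' 1:100 abundance cut. `n_spindles` movies are simulated per condition
#' (each movie is one spindle and nucleus); the composite kymograph uses all
#' of them.
#'
#' @param conditions character subset of `c("control", "mora_inhibited")`.
#' @param n_spindles spindles (movies) per condition; the reference
#'   composite uses 6-10.
#' @param embryo overrides for [embryo_sim_config()] (list).
#' @param kymo a [kymograph_params()].
#' @param apms an [apms_sim_config()].
#' @param apms_filter an [apms_filter_params()].
#' @param curves list: `n_per_condition`, `polymerising` config overrides
#'   (list), `mt_count_means` (Poisson means for the planted MT-count
#'   comparison, A then B), `n_fields` per condition.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = c("control", "mora_inhibited"),
                            n_spindles = 6L,
                            embryo = list(),
                            kymo = kymograph_params(),
                            apms = apms_sim_config(),
                            apms_filter = apms_filter_params(),
                            curves = list(n_per_condition = 6L,
                                          mt_count_means = c(20, 2),
                                          n_fields = 10L)) {
  conditions <- match.arg(conditions, c("control", "mora_inhibited"),
                          several.ok = TRUE)
  structure(list(conditions = conditions, n_spindles = as.integer(n_spindles),
                 embryo = embryo, kymo = kymo, apms = apms,
                 apms_filter = apms_filter, curves = curves),
            class = "pipeline_config")
}

embryo_config_for <- function(config, condition) {
  do.call(embryo_sim_config,
          utils::modifyList(list(condition = condition), config$embryo))
}

#' Run the imaging pipeline end to end
#'
#' For each condition: simulate `n_spindles` embryo movies, track the poles,
#' build the per-spindle kymographs and the composite, extract the Otsu
#' growth-profile contour, compute the NEB-aligned nuclear/spindle dynamics
#' (using the ground-truth NEB frame) and collect spindle lengths at the
#' final frame. With two conditions a contrast report is added: front speed
#' and flatness per condition, mean post-NEB sd-ratio peaks, and the
#' one-tailed t-test on the spindle-length sets (alternative: inhibited
#' shorter).
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return list of class `imaging_bundle`: per-condition results
#'   (`tracks`, `distances_um`, `composite`, `contour`, `dynamics`) and
#'   optionally `contrast`.
#' @export
run_imaging_pipeline <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  per_cond <- list()
  for (cond in config$conditions) {
    ecfg <- embryo_config_for(config, cond)
    kyms <- vector("list", config$n_spindles)
    tracks <- vector("list", config$n_spindles)
    dyns <- vector("list", config$n_spindles)
    dist_final <- numeric(config$n_spindles)
    for (s in seq_len(config$n_spindles)) {
      sim <- simulate_embryo_movie(ecfg, derive_seed(seed, paste0(cond, "-spindle-", s)))
      tr <- track_poles(sim$movie)
      tracks[[s]] <- tr
      kyms[[s]] <- extract_spindle_profile(sim$movie, tr, config$kymo)
      dser <- pole_distance_series(tr)
      dist_final[s] <- dser$distance_um[nrow(dser)]
      ctr <- c((ecfg$image_size[2] - 1) / 2, (ecfg$image_size[1] - 1) / 2) *
        ecfg$pixel_size
      half_w <- 2
      dyns[[s]] <- nuclear_spindle_dynamics(
        sim$movie, nucleus_center = ctr,
        nucleus_radius = 0.9 * ecfg$nucleus_radius,
        spindle_xlim = range(c(tr$ax, tr$bx)),
        spindle_ylim = c(ctr[2] - half_w, ctr[2] + half_w),
        neb_frame = sim$truth$neb_frame)
    }
    comp <- composite_kymograph(kyms)
    per_cond[[cond]] <- list(
      tracks = tracks,
      distances_um = dist_final,
      composite = comp,
      contour = growth_profile_contour(comp, config$kymo),
      dynamics = dyns,
      dynamics_aggregate = aggregate_replicates(dyns))
  }
  bundle <- list(conditions = per_cond, seed = seed)
  if (all(c("control", "mora_inhibited") %in% names(per_cond))) {
    co <- per_cond$control; mi <- per_cond$mora_inhibited
    bundle$contrast <- list(
      front_speed = c(control = co$contour$front_speed,
                      mora_inhibited = mi$contour$front_speed),
      flatness = c(control = co$contour$flatness,
                   mora_inhibited = mi$contour$flatness),
      sd_ratio_peak = c(
        control = mean(vapply(co$dynamics, sd_ratio_peak, numeric(1))),
        mora_inhibited = mean(vapply(mi$dynamics, sd_ratio_peak, numeric(1)))),
      distance_comparison = compare_distance_sets(co$distances_um,
                                                  mi$distances_um))
  }
  structure(bundle, class = "imaging_bundle")
}

#' @export
print.imaging_bundle <- function(x, ...) {
  cat(sprintf("imaging_bundle: %s\n", paste(names(x$conditions), collapse = ", ")))
  for (nm in names(x$conditions)) {
    c_ <- x$conditions[[nm]]
    cat(sprintf("  %s: front speed %.3g um/s, flatness %.3f, median length %.3g um\n",
                nm, c_$contour$front_speed, c_$contour$flatness,
                stats::median(c_$distances_um)))
  }
  if (!is.null(x$contrast))
    cat(sprintf("  spindle-length t-test p = %.3g\n",
                x$contrast$distance_comparison$test$p_one_tailed))
  invisible(x)
}

#' Run the AP-MS tables pipeline end to end
#'
#' Simulates two bait runs plus the negative-control database, filters both
#' runs, restricts to the bait-relative core and reports the two-run
#' overlap.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return list of class `tables_bundle`: `filtered1`, `filtered2`, `core1`,
#'   `core2`, `overlap`, `labels`.
#' @export
run_tables_pipeline <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_apms_tables(config$apms, seed, config$apms_filter)
  if (!nrow(sim$run1)) stop("empty AP-MS record table")
  f1 <- filter_records(sim$run1, sim$control_db, config$apms_filter)
  f2 <- filter_records(sim$run2, sim$control_db, config$apms_filter)
  c1 <- abundance_restrict(f1)
  c2 <- abundance_restrict(f2)
  structure(list(filtered1 = f1, filtered2 = f2, core1 = c1, core2 = c2,
                 overlap = reproducibility_overlap(c1, c2),
                 labels = sim$labels, seed = seed),
            class = "tables_bundle")
}

#' Run the polymerisation-curves pipeline end to end
#'
#' Simulates a labelled ensemble of polymerising and flat control curves,
#' fits the four-parameter logistic to each, classifies them, and compares
#' planted MT counts per field between the two conditions.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return list of class `curves_bundle`: `fits`, `classes`, `truth_labels`,
#'   `accuracy`, `mt_comparison`.
#' @export
run_curves_pipeline <- function(config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  n <- config$curves$n_per_condition
  curves <- list(); labels <- character(0)
  for (i in seq_len(n)) {
    curves[[length(curves) + 1L]] <-
      simulate_polymerisation_curve(polymer_sim_config(polymerising = TRUE),
                                    derive_seed(seed, paste0("curve-poly-", i)))
    labels <- c(labels, "polymerising")
    curves[[length(curves) + 1L]] <-
      simulate_polymerisation_curve(polymer_sim_config(polymerising = FALSE),
                                    derive_seed(seed, paste0("curve-flat-", i)))
    labels <- c(labels, "non_polymerising")
  }
  fits <- lapply(curves, fit_sigmoid)
  classes <- vapply(fits, classify_polymerisation, character(1))
  counts <- with_seed(derive_seed(seed, "mt-counts"), {
    list(a = stats::rpois(config$curves$n_fields, config$curves$mt_count_means[1]),
         b = stats::rpois(config$curves$n_fields, config$curves$mt_count_means[2]))
  })
  structure(list(fits = fits, classes = classes, truth_labels = labels,
                 accuracy = mean(classes == labels),
                 mt_comparison = compare_mt_counts(counts$a, counts$b),
                 seed = seed),
            class = "curves_bundle")
}

#' Run all three pipelines and build a run manifest
#'
#' The manifest records the config hash, the seed, and an MD5 checksum of
#' each stage's result object; identical `(config, seed)` pairs reproduce
#' identical checksums for all deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, summary CSV/JSON outputs
#'   are written there.
#' @return list of class `pipeline_run`: `imaging`, `tables`, `curves`,
#'   `manifest`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), seed = 1,
                              out_dir = NULL) {
  warn <- character(0)
  wh <- function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") }
  imaging <- withCallingHandlers(run_imaging_pipeline(config, seed), warning = wh)
  tables <- withCallingHandlers(run_tables_pipeline(config, seed), warning = wh)
  curves <- withCallingHandlers(run_curves_pipeline(config, seed), warning = wh)
  manifest <- list(
    package_version = as.character(utils::packageVersion("spindledyn")),
    seed = seed,
    config_checksum = object_checksum(config),
    checksums = list(imaging = object_checksum(imaging),
                     tables = object_checksum(tables),
                     curves = object_checksum(curves)),
    warnings = warn,
    timestamp = format(Sys.time(), tz = "UTC"))
  run <- structure(list(imaging = imaging, tables = tables, curves = curves,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(run$imaging$conditions)) {
    c_ <- run$imaging$conditions[[nm]]
    utils::write.csv(contour_summary_df(c_$contour),
                     file.path(out_dir, paste0("contour_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(c_$dynamics_aggregate$series,
                     file.path(out_dir, paste0("dynamics_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(run$tables$core1$records,
                   file.path(out_dir, "apms_core_run1.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

contour_summary_df <- function(contour) {
  data.frame(time_s = contour$front_time_s,
             front_position_um = contour$front_position)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  print(x$imaging)
  cat(sprintf("  AP-MS: %d core interactors, Jaccard %.3f\n",
              sum(x$tables$core1$records$kept), x$tables$overlap$jaccard))
  cat(sprintf("  curves: classification accuracy %.0f%%, MT-count p = %.3g\n",
              100 * x$curves$accuracy,
              x$curves$mt_comparison$test$p_one_tailed))
  invisible(x)
}
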