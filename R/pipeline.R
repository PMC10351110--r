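#' Pipeline configuration
#'
#' Validates and normalizes a configuration for [run_pipeline()]. All
#' randomness downstream is controlled by `seed`. The default margins are
#' the reference scaling factors of the weighting step: urbanicity and
#' gender shares plus an asset-ownership distribution.
#'
#' @param seed master integer seed.
#' @param world arguments for [world_config()] (synthetic mode), or a
#'   directory path written by [write_world()].
#' @param margins named list: variable -> named target proportions.
#' @param index_specs named list of [index_spec()] (default
#'   [default_index_specs()]).
#' @param learners character vector of learner ids from
#'   [default_learner_pool()].
#' @param k_folds CV folds.
#' @param max_covs covariate-selection cap.
#' @param stage1_targets character vector of binary survey columns (coded
#'   yes/no) interpolated in stage 1.
#' @param tercile_index which index's terciles to interpolate (default
#'   "confidence"; NULL for none).
#' @param n_boot bootstrap replicates for validation CIs.
#' @param outdir output directory or NULL (no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            world = list(),
                            margins = list(
                              urbanicity = c(urban = 0.53, rural = 0.47),
                              gender = c(female = 0.49, male = 0.51),
                              asset_owner = c(yes = 0.45, no = 0.55)),
                            index_specs = default_index_specs(),
                            learners = c("enet", "gam", "knn", "ols"),
                            k_folds = 5, max_covs = 10,
                            stage1_targets = c("asset_owner", "radio_owner"),
                            tercile_index = "confidence",
                            n_boot = 200, outdir = NULL) {
  pool <- default_learner_pool()
  unknown <- setdiff(learners, names(pool))
  if (length(unknown))
    stop("config field 'learners' names unknown learner(s): ",
         paste(unknown, collapse = ", "))
  for (s in index_specs) stopifnot(inherits(s, "index_spec"))
  margin_specs <- lapply(names(margins), function(v)
    margin_spec(v, margins[[v]]))
  structure(list(seed = as.integer(seed), world = world,
                 margins = margin_specs, index_specs = index_specs,
                 learners = learners, k_folds = k_folds, max_covs = max_covs,
                 stage1_targets = stage1_targets,
                 tercile_index = tercile_index,
                 n_boot = n_boot, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "world", "learners", "k_folds", "max_covs",
              "stage1_targets", "tercile_index", "n_boot", "outdir"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$margins))
    args$margins <- lapply(raw$margins, unlist)
  do.call(pipeline_config, args)
}

#' Run the full pipeline: simulate, weight, index, access, interpolate,
#' validate, analyze
#'
#' Orchestrates every stage in dependency order on a synthetic world (or a
#' world directory produced by [write_world()]). A failing layer
#' validation yields a completed run carrying caution flags (`status` =
#' "caution"), never a crash. With `outdir` set, reports (CSV), model
#' cards (JSON), rasters (.asc) and a structured log are written.
#'
#' @param config [pipeline_config()].
#' @return list of class `pipeline_result` with elements `world`,
#'   `weights`, `mca` (models/scores/diagnostics/drivers), `interp`,
#'   `validation`, `analysis`, `status` ("pass"/"caution"), `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
  }

  # -- simulate -------------------------------------------------------------
  if (is.character(config$world)) {
    if (!dir.exists(config$world)) stop("missing input: ", config$world)
    world <- read_world(config$world)
    say("loaded world from %s (%d respondents)", config$world,
        nrow(world$survey))
  } else {
    wc <- do.call(world_config, c(config$world,
                                  if (is.null(config$world$seed))
                                    list(seed = config$seed)))
    world <- generate_world(wc)
    say("generated synthetic world: %d respondents, %d clusters",
        nrow(world$survey), wc$n_clusters)
  }
  survey <- world$survey

  # -- weight (IPF) ---------------------------------------------------------
  wr <- ipf_rake(survey, config$margins)
  if (!wr$converged)
    say("WARNING: IPF did not converge (max margin error %.2e)",
        wr$max_margin_error)
  w <- wr$weights
  say("IPF converged=%s in %d iteration(s), max margin error %.2e",
      wr$converged, wr$iterations, wr$max_margin_error)

  # -- access: recompute travel times and attach to the survey --------------
  fac_ml <- filter_facilities(world$facilities, c("medium", "large"))
  tt_walk <- travel_time(friction_surface(world$friction_walk, "walk"), fac_ml)
  tt_drive <- travel_time(friction_surface(world$friction_drive, "drive"), fac_ml)
  survey$walk_time <- extract_at_points(tt_walk$layer, survey$x, survey$y)
  survey$drive_time <- extract_at_points(tt_drive$layer, survey$x, survey$y)
  say("travel times attached (walk median %.0f min, drive median %.0f min)",
      stats::median(survey$walk_time), stats::median(survey$drive_time))

  # -- index (MCA) ----------------------------------------------------------
  models <- list(); scores <- list(); diagnostics <- list(); drivers <- list()
  for (nm in names(config$index_specs)) {
    sp <- config$index_specs[[nm]]
    models[[nm]] <- fit_mca(survey, sp, w)
    scores[[nm]] <- score_index(survey, models[[nm]], w)
    diagnostics[[nm]] <- mca_diagnostics(models[[nm]])
    drivers[[nm]] <- driver_correlations(survey, scores[[nm]], sp, w)
    say("index '%s': corrected dim-1 share %.3f%s", nm,
        diagnostics[[nm]]$inertia_share_corrected,
        if (diagnostics[[nm]]$flagged) " (FLAGGED)" else "")
  }
  if (all(c("accessibility", "time_financial") %in% names(scores))) {
    scores$convenience <- composite_convenience(scores$accessibility,
                                                scores$time_financial, w)
    say("composite convenience index built")
  }

  # -- interpolate ----------------------------------------------------------
  # derived accessibility products join the covariate stack (log travel
  # times, standardized), mirroring the use of friction-based layers as
  # interpolation inputs alongside the imagery covariates
  zlog <- function(tt) {
    v <- log1p(tt$layer$values)
    raster_grid(standardize_field(v), cell_size = tt$layer$cell_size,
                xll = tt$layer$xll, yll = tt$layer$yll, crs = tt$layer$crs)
  }
  base_stack <- raster_stack(c(world$covariates$layers,
                               list(travel_walk_log = zlog(tt_walk),
                                    travel_drive_log = zlog(tt_drive))))
  pool <- default_learner_pool()[config$learners]
  s1 <- lapply(config$stage1_targets, function(v)
    as.numeric(survey[[v]] == "yes"))
  names(s1) <- config$stage1_targets
  idx3 <- intersect(c("confidence", "complacency", "convenience"),
                    names(scores))
  s2 <- lapply(scores[idx3], function(sc) sc$score_0_100 / 100)
  names(s2) <- paste0("index_", idx3)
  if (!is.null(config$tercile_index) &&
      config$tercile_index %in% names(scores)) {
    tc <- scores[[config$tercile_index]]$tercile
    for (lv in c("low", "mid", "high"))
      s2[[paste0(config$tercile_index, "_", lv)]] <- as.numeric(tc == lv)
  }
  interp <- two_stage_interpolate(survey, w, s1, s2, base_stack,
                                  learner_pool = pool,
                                  k_folds = config$k_folds,
                                  seed = config$seed,
                                  max_covs = config$max_covs)
  for (nm in names(interp$stage2)) {
    r <- interp$stage2[[nm]]
    say("stage-2 '%s': %s, CV RMSE %.4f (null %.4f, %s)", nm,
        paste(r$model$learners, collapse = "+"), r$model$cv_rmse,
        r$null$null_rmse,
        if (isTRUE(r$null$passed)) "passed" else "NOT passed")
  }
  tershares <- NULL
  if (!is.null(config$tercile_index)) {
    tl <- paste0(config$tercile_index, c("_low", "_mid", "_high"))
    if (all(tl %in% names(interp$stage2)))
      tershares <- renormalize_terciles(interp$stage2[[tl[1]]]$layer,
                                        interp$stage2[[tl[2]]]$layer,
                                        interp$stage2[[tl[3]]]$layer)
  }

  # -- validate (state level = survey's level of representativeness) --------
  validation <- list()
  all_pass <- TRUE
  for (nm in idx3) {
    st <- survey_zone_mean_ci(survey, w, scores[[nm]]$score_0_100 / 100,
                              survey$state_id, n_boot = config$n_boot,
                              seed = config$seed + 77)
    rep_ <- validate_layer(interp$stage2[[paste0("index_", nm)]]$layer,
                           world$population, world$state_zones, st)
    validation[[nm]] <- rep_
    all_pass <- all_pass && rep_$passed
    say("validation '%s': %s%s", nm, if (rep_$passed) "pass" else "caution",
        if (length(rep_$failing_zones))
          paste0(" (states ", paste(rep_$failing_zones, collapse = ","), ")")
        else "")
  }

  # -- analyze --------------------------------------------------------------
  score_layers <- lapply(idx3, function(nm) {
    g <- interp$stage2[[paste0("index_", nm)]]$layer$layer
    raster_grid(g$values * 100, cell_size = g$cell_size, xll = g$xll,
                yll = g$yll, crs = g$crs)
  })
  names(score_layers) <- idx3
  stack100 <- raster_stack(score_layers)
  state_stats <- zonal_aggregate(stack100, world$state_zones, world$population)
  lga_stats <- zonal_aggregate(stack100, world$lga_zones, world$population)
  nat_pop <- sum(world$population$values, na.rm = TRUE)
  ranges <- lapply(idx3, function(nm) {
    list(state = range_summary(state_stats[[paste0(nm, "_mean")]]),
         lga = range_summary(lga_stats[[paste0(nm, "_mean")]]),
         hyperlocal = range_summary(as.vector(score_layers[[nm]]$values)))
  })
  names(ranges) <- idx3
  mcs_by_state <- NULL
  if (length(idx3) == 3) {
    lga_to_state <- zonal_aggregate(world$state_zones, world$lga_zones)
    mcs_by_state <- do.call(rbind, lapply(state_stats$zone, function(s) {
      lgas <- lga_to_state$zone[round(lga_to_state$layer_mean) == s]
      inl <- lga_stats$zone %in% lgas
      wid_lga <- vapply(idx3, function(nm)
        range_summary(lga_stats[[paste0(nm, "_mean")]][inl])$width, numeric(1))
      cells <- world$state_zones$values == s
      wid_hyp <- vapply(idx3, function(nm)
        range_summary(score_layers[[nm]]$values[cells])$width, numeric(1))
      data.frame(state = s,
                 mcs_lga = mean_cumulative_score(wid_lga)$mcs,
                 mcs_hyperlocal = mean_cumulative_score(wid_hyp)$mcs)
    }))
  }
  prev <- if (length(idx3) == 3)
    prevalent_determinant(score_layers$confidence, score_layers$complacency,
                          score_layers$convenience) else NULL
  pop_counts <- NULL
  if (!is.null(tershares))
    pop_counts <- population_count(tershares$low, world$population,
                                   world$lga_zones)
  say("analysis complete (national population %.0f)", nat_pop)

  status <- if (all_pass) "pass" else "caution"
  result <- structure(list(
    config = config, world = world, survey = survey, weights = wr,
    mca = list(models = models, scores = scores,
               diagnostics = diagnostics, drivers = drivers),
    access = list(walk = tt_walk, drive = tt_drive),
    interp = interp, terciles = tershares, validation = validation,
    analysis = list(state_stats = state_stats, lga_stats = lga_stats,
                    ranges = ranges, mcs_by_state = mcs_by_state,
                    prevalent = prev, population_counts = pop_counts,
                    national_population = nat_pop),
    status = status, log = log), class = "pipeline_result")

  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: status %s, %d log lines>\n",
              x$status, length(x$log)))
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  data.table::fwrite(result$analysis$state_stats,
                     file.path(outdir, "state_stats.csv"))
  data.table::fwrite(result$analysis$lga_stats,
                     file.path(outdir, "lga_stats.csv"))
  if (!is.null(result$analysis$mcs_by_state))
    data.table::fwrite(result$analysis$mcs_by_state,
                       file.path(outdir, "mcs_by_state.csv"))
  for (nm in names(result$mca$drivers))
    data.table::fwrite(result$mca$drivers[[nm]],
                       file.path(outdir, sprintf("drivers_%s.csv", nm)))
  for (nm in names(result$validation))
    data.table::fwrite(result$validation[[nm]]$table,
                       file.path(outdir, sprintf("validation_%s.csv", nm)))
  for (nm in names(result$interp$stage2)) {
    r <- result$interp$stage2[[nm]]
    card <- list(target = nm, learners = r$model$learners,
                 best_learner = r$model$best_learner,
                 covariates = r$model$covariates,
                 cv_rmse = r$model$cv_rmse, null_rmse = r$null$null_rmse,
                 null_passed = r$null$passed, seed = r$model$seed,
                 k_folds = r$model$k_folds, stage = r$model$stage)
    jsonlite::write_json(card,
                         file.path(outdir, sprintf("model_card_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_ascii_grid(r$layer$layer,
                     file.path(outdir, sprintf("layer_%s.asc", nm)))
  }
  if (!is.null(result$analysis$prevalent))
    write_ascii_grid(result$analysis$prevalent$layer,
                     file.path(outdir, "prevalent_determinant.asc"))
  prov <- list(seed = cfg$seed, status = result$status,
               timestamp_free = TRUE, learners = cfg$learners)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
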