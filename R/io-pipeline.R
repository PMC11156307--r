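#' Write/read a grid as plain text
#'
#' Serialises an [env_grid] to a self-describing CSV: a short `#`
#' metadata header (variable, period, scenario) followed by long-format
#' `lon,lat,value` rows, values printed with 17 significant digits so
#' the round trip is lossless at double precision. Masked cells are
#' stored as `NA`.
#'
#' @param grid an [env_grid].
#' @param path output file path.
#' @return `read_grid` returns the reconstructed [env_grid].
#' @export
write_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#fishcast-grid v1",
               paste0("#variable: ", grid$variable),
               paste0("#period: ", grid$period),
               paste0("#scenario: ", grid$scenario),
               "lon,lat,value"), con)
  LON <- rep(grid$lon, each = length(grid$lat))
  LAT <- rep(grid$lat, times = length(grid$lon))
  v <- as.vector(grid$values)
  writeLines(sprintf("%.17g,%.17g,%s", LON, LAT,
                     ifelse(is.na(v), "NA", sprintf("%.17g", v))), con)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  hdr <- readLines(path, n = 4)
  if (!identical(hdr[1], "#fishcast-grid v1")) stop("not a fishcast grid file: ", path)
  meta <- sub("^#[a-z]+: ", "", hdr[2:4])
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  vals <- matrix(NA_real_, length(lat), length(lon))
  vals[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$value
  env_grid(vals, lon, lat, variable = meta[1], period = meta[2],
           scenario = meta[3])
}

#' Pipeline configuration
#'
#' Collects the synthetic-study configuration and every module-level
#' switch into one validated object that fully determines a pipeline
#' run. All randomness flows from `synth$seed`.
#'
#' @param synth a [synth_config].
#' @param scenarios scenario labels to project (must be defined in
#'   `synth$scenarios`).
#' @param periods future period labels.
#' @param train_fraction training fraction of the survey split.
#' @param tune logical; run exhaustive hyperparameter tuning (default
#'   FALSE: fit with the documented default hyperparameters).
#' @param resample_method downscaling resampling kernel.
#' @param msy_convention exponent convention for [msy].
#' @param cold_pool_comparator `"lte"` or `"lt"`.
#' @param sensitivities sensitivity scenarios to evaluate.
#' @param effort_threshold fishing-ground effort threshold (hours).
#' @param n_rings,ring_width_km port-buffer ring layout.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            scenarios = names(synth$scenarios),
                            periods = FUTURE_PERIODS,
                            train_fraction = 0.8,
                            tune = FALSE,
                            resample_method = "bilinear",
                            msy_convention = "printed",
                            cold_pool_comparator = "lte",
                            sensitivities = "base",
                            effort_threshold = 1000,
                            n_rings = 8, ring_width_km = 100) {
  stopifnot(inherits(synth, "synth_config"))
  unknown <- setdiff(scenarios, names(synth$scenarios))
  if (length(unknown) > 0)
    stop("unknown scenario label(s): ", paste(unknown, collapse = ", "))
  if (!all(periods %in% FUTURE_PERIODS)) stop("unknown period label")
  if (!all(sensitivities %in% SENSITIVITY_SCENARIOS))
    stop("unknown sensitivity scenario")
  match.arg(resample_method, c("bilinear", "nearest"))
  match.arg(msy_convention, c("printed", "bmsy_consistent"))
  match.arg(cold_pool_comparator, c("lte", "lt"))
  structure(list(synth = synth, scenarios = scenarios, periods = periods,
                 train_fraction = train_fraction, tune = tune,
                 resample_method = resample_method,
                 msy_convention = msy_convention,
                 cold_pool_comparator = cold_pool_comparator,
                 sensitivities = sensitivities,
                 effort_threshold = effort_threshold,
                 n_rings = n_rings, ring_width_km = ring_width_km),
            class = "pipeline_config")
}

#' Round-trip a pipeline configuration through YAML
#'
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the reconstructed config,
#'   equal to the one written.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  synth <- do.call(synth_config, raw$synth[setdiff(names(raw$synth), NULL)])
  do.call(pipeline_config, c(list(synth = synth),
                             raw[setdiff(names(raw), "synth")]))
}

#' Per-cell maximum catch potential grid
#'
#' Sums, over species, each cell's biomass (density times cell area,
#' mt) multiplied by the species' exploitation rate at MSY — the
#' cumulative per-cell MCP field used for port-buffer profiles.
#'
#' @param species_surfaces named list (by species) of abundance
#'   [env_grid] for one period/scenario.
#' @param params reference-parameter table.
#' @return an [env_grid] of per-cell MCP (mt), variable `"MCP"`.
#' @export
mcp_cell_grid <- function(species_surfaces, params) {
  ref <- species_surfaces[[1]]
  area <- cell_areas(ref)
  total <- matrix(0, length(ref$lat), length(ref$lon))
  for (sp in names(species_surfaces)) {
    u <- params$u_msy[match(sp, params$species)]
    if (is.na(u)) stop("species missing from parameter table: ", sp)
    s <- species_surfaces[[sp]]
    v <- ifelse(is.na(s$values), 0, s$values)
    total <- total + v * area / 1000 * u
  }
  env_grid(total, ref$lon, ref$lat, variable = "MCP", period = ref$period,
           scenario = ref$scenario, mask = ref$mask)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full projection pipeline
#'
#' Chains all stages — simulate, downscale, fit, project, bioecon,
#' summarize — on synthetic inputs under one configuration and seed,
#' writing every output as plain text under `out_dir` and returning a
#' manifest of files with MD5 checksums and stage provenance. Rerunning
#' with an identical configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the `manifest` data.frame and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); stages <- character(0)
  emit <- function(path, stage) {
    files <<- c(files, path); stages <<- c(stages, stage)
  }
  say <- function(...) if (!quiet) message(...)

  say("stage simulate")
  synth <- config$synth
  env <- generate_environment(synth)
  niches <- make_species_niches(synth)
  surveys <- sample_surveys(env, niches, synth)
  params <- generate_reference_params(synth$n_species, seed = synth$seed)
  geo <- generate_geography(synth, env)
  emit(write_stage_csv(surveys, file.path(out_dir, "surveys.csv")), "simulate")
  emit(write_ref_params(params, file.path(out_dir, "params.csv")), "simulate")
  emit(write_stage_csv(geo$ports, file.path(out_dir, "ports.csv")), "simulate")
  emit(write_grid(geo$effort, file.path(out_dir, "effort.csv")), "simulate")
  for (v in names(env$fine_present))
    emit(write_grid(env$fine_present[[v]],
                    file.path(out_dir, sprintf("present_%s.csv", v))), "simulate")

  say("stage downscale")
  future_env <- downscale_all(env, scenarios = config$scenarios,
                              periods = config$periods,
                              method = config$resample_method)
  for (sc in config$scenarios) for (pd in config$periods)
    emit(write_grid(future_env[[sc]][[pd]]$SSBT,
                    file.path(out_dir, sprintf("SSBT_%s_%s.csv", sc, pd))),
         "downscale")

  say("stage fit")
  models <- list()
  for (i in seq_len(nrow(niches))) {
    sp <- niches$species[i]
    tab <- surveys[surveys$species == sp, , drop = FALSE]
    split <- split_train_test(tab, config$train_fraction, seed = synth$seed + i)
    rf_spec <- brt_spec <- NULL
    if (config$tune) {
      rf_spec <- tune_hyperparameters(split$train, "rf", seed = synth$seed + i)$spec
      brt_spec <- tune_hyperparameters(split$train, "brt", seed = synth$seed + i)$spec
    }
    models[[sp]] <- fit_ensemble(split$train, split$test, rf_spec, brt_spec,
                                 seed = synth$seed + i, species = sp)
  }
  model_summary <- do.call(rbind, lapply(models, function(m) {
    data.frame(species = m$species, w_rf = m$weights[["rf"]],
               w_brt = m$weights[["brt"]], rmse_rf = m$rmse[["rf"]],
               rmse_brt = m$rmse[["brt"]], var_explained = m$var_explained,
               stringsAsFactors = FALSE)
  }))
  emit(write_stage_csv(model_summary, file.path(out_dir, "models.csv")), "fit")

  say("stage project")
  surfaces <- list()
  for (sp in names(models)) {
    surfaces[[sp]] <- list(present = predict_surface(models[[sp]], env$fine_present))
    for (sc in config$scenarios) {
      surfaces[[sp]][[sc]] <- list()
      for (pd in config$periods)
        surfaces[[sp]][[sc]][[pd]] <- predict_surface(models[[sp]],
                                                      future_env[[sc]][[pd]])
    }
    emit(write_grid(surfaces[[sp]]$present,
                    file.path(out_dir, sprintf("surface_%s_present.csv", sp))),
         "project")
  }

  say("stage bioecon")
  region <- geo$eez$USA
  biomass <- list()
  for (sp in names(surfaces)) {
    biomass[[length(biomass) + 1]] <- data.frame(
      species = sp, period = PRESENT_PERIOD, scenario = "present",
      B = integrate_biomass(surfaces[[sp]]$present, region),
      stringsAsFactors = FALSE)
    for (sc in config$scenarios) for (pd in config$periods)
      biomass[[length(biomass) + 1]] <- data.frame(
        species = sp, period = pd, scenario = sc,
        B = integrate_biomass(surfaces[[sp]][[sc]][[pd]], region),
        stringsAsFactors = FALSE)
  }
  biomass <- do.call(rbind, biomass)
  records <- do.call(rbind, lapply(config$sensitivities, function(s)
    bioecon_records(biomass, params, sensitivity = s,
                    msy_convention = config$msy_convention)))
  aggregates <- fleet_aggregates(records)
  emit(write_stage_csv(records, file.path(out_dir, "bioecon_records.csv")), "bioecon")
  emit(write_stage_csv(aggregates, file.path(out_dir, "fleet_aggregates.csv")), "bioecon")

  say("stage summarize")
  tracks <- do.call(rbind, lapply(names(surfaces), function(sp)
    cog_track(surfaces[[sp]], species = sp)))
  emit(write_stage_csv(tracks, file.path(out_dir, "cog_tracks.csv")), "summarize")

  base_agg <- aggregates[aggregates$sensitivity == "base", ]
  pres <- base_agg[base_agg$period == PRESENT_PERIOD, ]
  fut <- base_agg[base_agg$period != PRESENT_PERIOD, ]
  pct <- do.call(rbind, lapply(seq_len(nrow(fut)), function(i)
    data.frame(scenario = fut$scenario[i], period = fut$period[i],
               MCP = percent_change(pres$MCP, fut$MCP[i]),
               MRP = percent_change(pres$MRP, fut$MRP[i]),
               MPP = percent_change(pres$MPP, fut$MPP[i]),
               stringsAsFactors = FALSE)))
  emit(write_stage_csv(pct, file.path(out_dir, "percent_changes.csv")), "summarize")

  profiles <- list()
  for (p in seq_len(nrow(geo$ports))) {
    port <- c(geo$ports$lon[p], geo$ports$lat[p])
    grids <- c(list(present = mcp_cell_grid(
      lapply(surfaces, `[[`, "present"), params)),
      stats::setNames(lapply(config$scenarios, function(sc)
        mcp_cell_grid(lapply(surfaces, function(s)
          s[[sc]][[config$periods[length(config$periods)]]]), params)),
        config$scenarios))
    for (lbl in names(grids)) {
      pr <- port_buffer_profile(grids[[lbl]], port,
                                ring_width_km = config$ring_width_km,
                                n_rings = config$n_rings,
                                jurisdiction = geo$eez$USA)
      pr$port <- geo$ports$port[p]; pr$layer <- lbl
      profiles[[length(profiles) + 1]] <- pr
    }
  }
  emit(write_stage_csv(do.call(rbind, profiles),
                       file.path(out_dir, "buffer_profiles.csv")), "summarize")

  grounds <- fishing_ground_compare(geo$effort, config$effort_threshold,
                                    surfaces, params, geo$eez,
                                    msy_convention = config$msy_convention)
  emit(write_stage_csv(grounds, file.path(out_dir, "fishing_grounds.csv")),
       "summarize")

  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  emit_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, emit_path, row.names = FALSE)
  say("pipeline complete: ", nrow(manifest), " outputs")
  invisible(list(manifest = manifest, env = env, niches = niches,
                 surveys = surveys, params = params, geo = geo,
                 models = models, surfaces = surfaces, records = records,
                 aggregates = aggregates, percent_changes = pct,
                 cog_tracks = tracks, fishing_grounds = grounds))
}
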