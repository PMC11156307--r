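#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic Bering/Chukchi-like study system:
#' the domain and its two grid resolutions, the survey design, the
#' scenario ladder, and the single seed that determines all generated
#' outputs. Defaults emulate the design the pipeline targets: a 0.25
#' degree observational grid, 1 degree scenario models with four ensemble
#' members, a 2000-2019 present window, and four scenarios whose
#' end-of-century warming amplitudes increase strictly with severity.
#'
#' @param lon_range,lat_range domain extent in degrees (cell edges).
#' @param fine_res,coarse_res grid resolutions in degrees; `fine_res`
#'   must divide `coarse_res` evenly.
#' @param n_species number of species to simulate.
#' @param n_surveys_per_year trawl stations per survey year.
#' @param years survey years of the present window.
#' @param scenarios named list, ordered mildest to most severe; each
#'   element has `warming` (deg C reached by 2081-2100), `ice_decline`
#'   and `npp_decline` (fractional losses reached by 2081-2100).
#' @param n_members pseudo-GCM ensemble members per scenario.
#' @param sigma lognormal dispersion of survey CPUE noise.
#' @param texture_sd amplitude of the smooth per-member spatial texture.
#' @param coast_frac fraction of the longitude span taken by the eastern
#'   land margin.
#' @param n_fishing_ground_cells cells engineered to exceed the
#'   1000-hour fishing-effort threshold.
#' @param seed integer; fully determines all generated outputs.
#' @return a `synth_config` list.
#' @export
synth_config <- function(lon_range = c(-180, -168), lat_range = c(55, 66),
                         fine_res = 0.25, coarse_res = 1.0,
                         n_species = 2, n_surveys_per_year = 60,
                         years = 2000:2019,
                         scenarios = list(
                           SSP126 = list(warming = 1.0, ice_decline = 0.20, npp_decline = 0.05),
                           SSP245 = list(warming = 2.0, ice_decline = 0.35, npp_decline = 0.10),
                           SSP370 = list(warming = 3.5, ice_decline = 0.55, npp_decline = 0.15),
                           SSP585 = list(warming = 5.0, ice_decline = 0.75, npp_decline = 0.20)
                         ),
                         n_members = 4, sigma = 0.3, texture_sd = 0.05,
                         coast_frac = 0.1, n_fishing_ground_cells = 40,
                         seed = 1L) {
  if (fine_res <= 0 || coarse_res <= 0) stop("resolutions must be positive")
  ratio <- coarse_res / fine_res
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("fine resolution must divide coarse resolution evenly")
  if (n_species < 1) stop("n_species must be >= 1")
  amp <- vapply(scenarios, `[[`, numeric(1), "warming")
  if (length(amp) > 1 && any(diff(amp) <= 0))
    stop("scenario warming amplitudes must increase strictly with severity")
  structure(list(
    lon_range = lon_range, lat_range = lat_range,
    fine_res = fine_res, coarse_res = coarse_res,
    n_species = n_species, n_surveys_per_year = n_surveys_per_year,
    years = years, scenarios = scenarios, n_members = n_members,
    sigma = sigma, texture_sd = texture_sd, coast_frac = coast_frac,
    n_fishing_ground_cells = n_fishing_ground_cells,
    seed = as.integer(seed)
  ), class = "synth_config")
}

axis_centers <- function(range, res) seq(range[1] + res / 2, range[2] - res / 2, by = res)

## fraction of the end-of-century trend realised by a period's midpoint
trend_fraction <- function(period) {
  y0 <- PERIOD_MIDYEARS[[PRESENT_PERIOD]]
  (PERIOD_MIDYEARS[[period]] - y0) / (PERIOD_MIDYEARS[["2081-2100"]] - y0)
}

## smooth zero-mean random field: white noise convolved with a Gaussian
## kernel along both axes, rescaled to the requested sd
smooth_field <- function(nlat, nlon, sd, scale_cells = 3) {
  w <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  half <- max(1L, ceiling(2 * scale_cells))
  k <- stats::dnorm(-half:half, sd = scale_cells)
  k <- k / sum(k)
  kmat <- function(n) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax(i + (-half:half), 1L), n) # reflecting-ish edges via clamping
      for (j in seq_along(idx)) m[i, idx[j]] <- m[i, idx[j]] + k[j]
    }
    m
  }
  f <- kmat(nlat) %*% w %*% t(kmat(nlon))
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f * (sd / s)
  f
}

## deterministic mean fields of the synthetic basin at given cell centers:
## colder and icier to the north, NPP peaking mid-basin, deepening offshore
basin_mean_fields <- function(lon, lat, config) {
  latf <- (lat - config$lat_range[1]) / diff(config$lat_range)
  lonf <- (config$lon_range[2] - lon) / diff(config$lon_range)
  LATF <- matrix(latf, length(lat), length(lon))
  LONF <- matrix(lonf, length(lat), length(lon), byrow = TRUE)
  list(
    SSBT = 6 - 8 * LATF,
    WSBT = 3 - 6 * LATF,
    WSST = 4 - 9 * LATF,
    WSIC = 100 * stats::plogis((LATF - 0.55) / 0.12),
    SNPP = 250 + 600 * exp(-(LATF - 0.5)^2 / (2 * 0.18^2)),
    depth = 20 + 3200 * LONF^2
  )
}

## eastern land margin; boundary longitude wiggles with latitude
land_mask <- function(lon, lat, config) {
  span <- diff(config$lon_range)
  latf <- (lat - config$lat_range[1]) / diff(config$lat_range)
  coast_lon <- config$lon_range[2] -
    span * config$coast_frac * (1 + 0.5 * sin(2 * pi * 1.3 * latf))
  outer(coast_lon, lon, function(cl, x) x > cl) # TRUE = land
}

#' Generate the synthetic environmental grids
#'
#' Builds the complete environmental input set: six fine-resolution
#' present-day layers (WSST, WSIC, WSBT, SSBT, SNPP, depth), a coarse
#' historical stack per pseudo-GCM member, and coarse future stacks per
#' scenario, period and member. Each member carries a fixed smooth
#' spatial texture (its "model identity"); future layers are that
#' member's historical layer plus a scenario- and period-scaled trend
#' (additive warming for temperatures, fractional decline for ice and
#' primary production). With all trend amplitudes at zero, future layers
#' therefore equal the historical layers exactly.
#'
#' @param config a [synth_config].
#' @return a list with elements `fine_present` (named list of
#'   [env_grid], one per variable), `coarse_hist` (per variable, a list
#'   of member grids), `coarse_future` (nested: scenario / period /
#'   variable / member), and `config`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  flon <- axis_centers(config$lon_range, config$fine_res)
  flat <- axis_centers(config$lat_range, config$fine_res)
  clon <- axis_centers(config$lon_range, config$coarse_res)
  clat <- axis_centers(config$lat_range, config$coarse_res)
  dyn_vars <- setdiff(ENV_VARIABLES, "depth")

  with_seed(config$seed, {
    fine_mean <- basin_mean_fields(flon, flat, config)
    land_f <- land_mask(flon, flat, config)
    noise_amp <- c(SSBT = 0.3, WSBT = 0.3, WSST = 0.4, WSIC = 3, SNPP = 20, depth = 40)
    fine_present <- list()
    for (v in ENV_VARIABLES) {
      vals <- fine_mean[[v]] +
        noise_amp[[v]] * smooth_field(length(flat), length(flon), 1, scale_cells = 4)
      b <- VAR_BOUNDS[[v]]
      vals <- pmin(pmax(vals, b[1]), b[2])
      vals[land_f] <- NA_real_
      fine_present[[v]] <- env_grid(vals, flon, flat, variable = v,
                                    period = PRESENT_PERIOD, scenario = "observed")
    }

    coarse_mean <- basin_mean_fields(clon, clat, config)
    land_c <- land_mask(clon, clat, config)
    ## fixed per-member, per-variable texture fields
    texture <- lapply(seq_len(config$n_members), function(m) {
      tx <- lapply(dyn_vars, function(v) {
        amp <- config$texture_sd * noise_amp[[v]] / 0.3 # scale texture to variable units
        amp * smooth_field(length(clat), length(clon), 1, scale_cells = 2)
      })
      names(tx) <- dyn_vars
      tx
    })

    coarse_hist <- lapply(dyn_vars, function(v) {
      lapply(seq_len(config$n_members), function(m) {
        vals <- coarse_mean[[v]] + texture[[m]][[v]]
        b <- VAR_BOUNDS[[v]]
        vals <- pmin(pmax(vals, b[1]), b[2])
        vals[land_c] <- NA_real_
        env_grid(vals, clon, clat, variable = v, period = HIST_PERIOD,
                 scenario = "historical")
      })
    })
    names(coarse_hist) <- dyn_vars

    coarse_future <- lapply(names(config$scenarios), function(sc) {
      pars <- config$scenarios[[sc]]
      per_period <- lapply(FUTURE_PERIODS, function(pd) {
        f <- trend_fraction(pd)
        per_var <- lapply(dyn_vars, function(v) {
          lapply(seq_len(config$n_members), function(m) {
            h <- coarse_hist[[v]][[m]]
            vals <- switch(v,
              SSBT = , WSBT = , WSST = h$values + pars$warming * f,
              WSIC = h$values * (1 - pars$ice_decline * f),
              SNPP = h$values * (1 - pars$npp_decline * f))
            env_grid(vals, clon, clat, variable = v, period = pd, scenario = sc,
                     mask = h$mask)
          })
        })
        names(per_var) <- dyn_vars
        per_var
      })
      names(per_period) <- FUTURE_PERIODS
      per_period
    })
    names(coarse_future) <- names(config$scenarios)

    list(fine_present = fine_present, coarse_hist = coarse_hist,
         coarse_future = coarse_future, config = config)
  })
}

#' Species niches with Gaussian environmental responses
#'
#' Each synthetic species responds to summer bottom temperature, depth
#' and summer net primary production through independent Gaussian
#' kernels; expected CPUE is the product of the three kernels times the
#' species' maximum density, so it equals the maximum density exactly at
#' the multivariate optimum. Temperature optima are spread from cold to
#' warm across species; a species is flagged `cold_optimum` when its
#' thermal optimum lies below the basin midpoint, which is the group
#' expected to track receding cold water poleward under warming.
#'
#' @param config a [synth_config].
#' @return data.frame with one row per species: optima, breadths,
#'   maximum density (kg/km2) and the cold-optimum flag.
#' @export
make_species_niches <- function(config) {
  n <- config$n_species
  with_seed(config$seed + 1000L, {
    opt_sbt <- seq(0.2, 3.8, length.out = max(n, 2))[seq_len(n)] +
      stats::runif(n, -0.2, 0.2)
    data.frame(
      species = sprintf("sp%02d", seq_len(n)),
      opt_sbt = opt_sbt,
      br_sbt = stats::runif(n, 1.2, 2.0),
      opt_depth = stats::runif(n, 60, 200),
      br_depth = stats::runif(n, 120, 220),
      opt_npp = stats::runif(n, 500, 800),
      br_npp = stats::runif(n, 250, 450),
      max_density = stats::runif(n, 80, 400),
      cold_optimum = opt_sbt < 2,
      stringsAsFactors = FALSE
    )
  })
}

#' Expected CPUE of a species at given covariate values
#'
#' @param niche one row of the [make_species_niches] table.
#' @param sbt,depth,npp covariate vectors.
#' @return expected CPUE in kg/km2.
#' @export
niche_expected_cpue <- function(niche, sbt, depth, npp) {
  g <- function(x, opt, br) exp(-0.5 * ((x - opt) / br)^2)
  niche$max_density * g(sbt, niche$opt_sbt, niche$br_sbt) *
    g(depth, niche$opt_depth, niche$br_depth) *
    g(npp, niche$opt_npp, niche$br_npp)
}

#' True (noise-free) abundance surface of a synthetic species
#'
#' @param niche one row of the niche table.
#' @param env_stack named list of fine [env_grid] layers (needs SSBT,
#'   depth, SNPP).
#' @return an [env_grid] of expected density, variable `"abundance"`.
#' @export
true_surface <- function(niche, env_stack) {
  sbt <- env_stack$SSBT; dep <- env_stack$depth; npp <- env_stack$SNPP
  vals <- niche_expected_cpue(niche, sbt$values, dep$values, npp$values)
  env_grid(vals, sbt$lon, sbt$lat, variable = "abundance",
           period = sbt$period, scenario = sbt$scenario, mask = sbt$mask)
}

## nearest-cell index lookup; errors when the point is outside the grid
cell_index <- function(grid, lon, lat) {
  rl <- grid$resolution
  if (any(lon < grid$lon[1] - rl[["lon"]] / 2 - 1e-9) ||
      any(lon > grid$lon[length(grid$lon)] + rl[["lon"]] / 2 + 1e-9) ||
      any(lat < grid$lat[1] - rl[["lat"]] / 2 - 1e-9) ||
      any(lat > grid$lat[length(grid$lat)] + rl[["lat"]] / 2 + 1e-9))
    stop("point outside grid extent")
  list(row = pmin(pmax(round((lat - grid$lat[1]) / rl[["lat"]]) + 1, 1), length(grid$lat)),
       col = pmin(pmax(round((lon - grid$lon[1]) / rl[["lon"]]) + 1, 1), length(grid$lon)))
}

#' Extract covariate values at points
#'
#' Nearest-cell lookup of every layer in a stack at given coordinates.
#'
#' @param env_stack named list of [env_grid] on one mesh.
#' @param lon,lat point coordinates (degrees).
#' @return data.frame with one column per layer.
#' @export
env_extract <- function(env_stack, lon, lat) {
  idx <- cell_index(env_stack[[1]], lon, lat)
  out <- lapply(env_stack, function(g) g$values[cbind(idx$row, idx$col)])
  as.data.frame(out, optional = TRUE)
}

#' Simulate bottom-trawl CPUE surveys
#'
#' Places survey stations uniformly at random over marine cells for each
#' year and records, for every species, a CPUE draw around its expected
#' niche response. Noise is multiplicative lognormal with dispersion
#' `sigma` and a mean-one correction (`meanlog = -sigma^2/2`), so the
#' expectation of observed CPUE equals the niche-expected CPUE, and at
#' `sigma = 0` the observation equals it exactly.
#'
#' @param env an environment list from [generate_environment] (or a bare
#'   fine stack in a list element `fine_present`).
#' @param niches the [make_species_niches] table.
#' @param config a [synth_config].
#' @param sigma lognormal dispersion; defaults to `config$sigma`.
#' @return data.frame of survey rows: year, lon, lat, species, cpue and
#'   the six environmental covariates.
#' @export
sample_surveys <- function(env, niches, config, sigma = config$sigma) {
  if (nrow(niches) == 0) stop("niche table is empty")
  stack <- env$fine_present
  g0 <- stack[[1]]
  marine <- which(g0$mask)
  schema <- data.frame(year = integer(), lon = numeric(), lat = numeric(),
                       species = character(), cpue = numeric(),
                       WSST = numeric(), WSIC = numeric(), WSBT = numeric(),
                       SSBT = numeric(), SNPP = numeric(), depth = numeric(),
                       stringsAsFactors = FALSE)
  if (config$n_surveys_per_year == 0) return(schema)
  with_seed(config$seed + 2000L, {
    rows <- lapply(config$years, function(yr) {
      cells <- sample(marine, config$n_surveys_per_year, replace = TRUE)
      rc <- arrayInd(cells, dim(g0$values))
      lon <- g0$lon[rc[, 2]]; lat <- g0$lat[rc[, 1]]
      cov <- env_extract(stack, lon, lat)
      per_sp <- lapply(seq_len(nrow(niches)), function(i) {
        mu <- niche_expected_cpue(niches[i, ], cov$SSBT, cov$depth, cov$SNPP)
        eps <- if (sigma > 0)
          exp(stats::rnorm(length(mu), mean = -sigma^2 / 2, sd = sigma)) else 1
        data.frame(year = yr, lon = lon, lat = lat,
                   species = niches$species[i], cpue = mu * eps, cov,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_sp)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate per-species bioeconomic reference parameters
#'
#' Draws the constant species-specific reference constants used by the
#' surplus-production bioeconomics: population growth rate `g`
#' (MSY/B_MSY), Pella-Tomlinson shape `phi` (0.188 for groundfish,
#' -0.093 for crab, fixing B_MSY/K at 0.40 and 0.35 respectively),
#' exploitation rate at MSY `u_msy`, ex-vessel price (USD/mt, constant
#' 2012 dollars), the open-access equilibrium ratios `f_bar` (F/F_MSY)
#' and `b_bar` (B/B_MSY), and the non-linear cost exponent `beta = 1.3`.
#'
#' @param n_species number of species.
#' @param groups character vector (`"groundfish"`/`"crab"`) per species;
#'   default makes the last species a crab when `n_species >= 2`.
#' @param seed integer seed for the draws.
#' @return data.frame, one row per species.
#' @export
generate_reference_params <- function(n_species, groups = NULL, seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (is.null(groups)) {
    groups <- rep("groundfish", n_species)
    if (n_species >= 2) groups[n_species] <- "crab"
  }
  stopifnot(length(groups) == n_species, all(groups %in% c("groundfish", "crab")))
  with_seed(seed + 3000L, {
    data.frame(
      species = sprintf("sp%02d", seq_len(n_species)),
      group = groups,
      g = stats::runif(n_species, 0.1, 0.6),
      phi = ifelse(groups == "crab", -0.093, 0.188),
      u_msy = stats::runif(n_species, 0.08, 0.35),
      price = stats::runif(n_species, 400, 2800),
      f_bar = stats::runif(n_species, 1.1, 2.2),
      b_bar = stats::runif(n_species, 0.25, 0.75),
      beta = 1.3,
      stringsAsFactors = FALSE
    )
  })
}

#' Read/write a reference-parameter table
#'
#' Plain-CSV round trip of the [generate_reference_params] table, so
#' reference values can also enter from a user-maintained file.
#'
#' @param params the parameter data.frame.
#' @param path CSV file path.
#' @return `read_ref_params` returns the parameter data.frame.
#' @export
write_ref_params <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ref_params
#' @export
read_ref_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate ports, a two-jurisdiction EEZ split, and a fishing-effort grid
#'
#' Places a southern "major" port and a northern "Arctic" port on marine
#' cells near the coast, splits the marine domain into two exclusive
#' economic zones at the mid-domain meridian (eastern = "USA", western =
#' "RUS"), and lays down an aggregated fishing-effort field (hours)
#' concentrated around the southern port. The effort field is rescaled
#' so that exactly `config$n_fishing_ground_cells` marine cells reach
#' the 1000-hour fishing-ground threshold.
#'
#' @param config a [synth_config].
#' @param env optional environment list (regenerated from `config` when
#'   missing) providing the fine grid and marine mask.
#' @return list with `ports` (data.frame: port, lon, lat), `eez` (named
#'   list of logical masks that partition the marine cells), `effort`
#'   (an [env_grid] of hours), and `boundary_lon`.
#' @export
generate_geography <- function(config, env = NULL) {
  if (is.null(env)) env <- generate_environment(config)
  g0 <- env$fine_present[[1]]
  marine <- g0$mask
  ## nearest marine cell to a target location
  nearest_marine <- function(lon0, lat0) {
    idx <- which(marine, arr.ind = TRUE)
    d <- geosphere::distHaversine(cbind(g0$lon[idx[, 2]], g0$lat[idx[, 1]]),
                                  c(lon0, lat0), r = EARTH_RADIUS_KM * 1000)
    i <- idx[which.min(d), ]
    c(lon = g0$lon[i[2]], lat = g0$lat[i[1]])
  }
  south <- nearest_marine(config$lon_range[2] - 0.15 * diff(config$lon_range),
                          config$lat_range[1] + 0.12 * diff(config$lat_range))
  north <- nearest_marine(config$lon_range[2] - 0.15 * diff(config$lon_range),
                          config$lat_range[1] + 0.85 * diff(config$lat_range))
  ports <- data.frame(port = c("south_major", "north_arctic"),
                      lon = c(south["lon"], north["lon"]),
                      lat = c(south["lat"], north["lat"]),
                      stringsAsFactors = FALSE)
  rownames(ports) <- NULL

  boundary_lon <- mean(config$lon_range)
  LON <- matrix(g0$lon, length(g0$lat), length(g0$lon), byrow = TRUE)
  eez <- list(USA = marine & LON >= boundary_lon,
              RUS = marine & LON < boundary_lon)

  ## effort: Gaussian plume around the southern port, lognormal-roughened,
  ## rescaled so exactly k marine cells sit at or above 1000 hrs
  k <- min(config$n_fishing_ground_cells, sum(marine))
  idx <- which(marine, arr.ind = TRUE)
  d <- geosphere::distHaversine(cbind(g0$lon[idx[, 2]], g0$lat[idx[, 1]]),
                                c(south["lon"], south["lat"]),
                                r = EARTH_RADIUS_KM * 1000) / 1000
  vals <- with_seed(config$seed + 4000L, {
    4000 * exp(-d^2 / (2 * 150^2)) * exp(stats::rnorm(length(d), 0, 0.3))
  })
  if (k >= 1) {
    v_sorted <- sort(vals, decreasing = TRUE)
    vals <- vals * (1000 / v_sorted[k])
  }
  eff <- matrix(NA_real_, length(g0$lat), length(g0$lon))
  eff[idx] <- vals
  effort <- env_grid(eff, g0$lon, g0$lat, variable = "effort",
                     period = PRESENT_PERIOD, scenario = "observed",
                     mask = marine)
  list(ports = ports, eez = eez, effort = effort, boundary_lon = boundary_lon)
}
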