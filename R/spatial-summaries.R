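#' Abundance-weighted center of gravity
#'
#' The biomass-weighted mean position of a surface: cell weights are
#' density times spherical cell area (true biomass weighting, not raw
#' density), applied to cell-center longitudes and latitudes. The
#' centroid of a basin wrapped around land can itself fall on land; no
#' correction is applied.
#'
#' @param surface an [env_grid] of density.
#' @return named numeric `c(lon, lat)` in degrees.
#' @export
center_of_gravity <- function(surface) {
  m <- surface$mask & !is.na(surface$values)
  w <- surface$values * cell_areas(surface)
  w[!m] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("all-zero abundance surface has no center of gravity")
  LON <- matrix(surface$lon, length(surface$lat), length(surface$lon), byrow = TRUE)
  LAT <- matrix(surface$lat, length(surface$lat), length(surface$lon))
  c(lon = sum(w * LON) / tot, lat = sum(w * LAT) / tot)
}

#' Great-circle distance between two points
#'
#' Haversine distance on a 6371-km sphere.
#'
#' @param p1,p2 numeric `c(lon, lat)` in degrees.
#' @return distance in km.
#' @export
gc_distance_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Decadal rate of center-of-gravity shift
#'
#' Great-circle distance between present and future COGs divided by
#' the elapsed decades between the period midpoint years (present
#' 2009.5; futures 2030.5, 2050.5, 2070.5, 2090.5).
#'
#' @param cog_present,cog_future `c(lon, lat)` positions.
#' @param present_mid,future_mid period midpoint years.
#' @return shift rate in km/decade (nonnegative).
#' @export
shift_rate <- function(cog_present, cog_future,
                       present_mid = PERIOD_MIDYEARS[[PRESENT_PERIOD]],
                       future_mid) {
  dec <- (future_mid - present_mid) / 10
  if (dec <= 0) stop("future midpoint must postdate the present midpoint")
  gc_distance_km(cog_present, cog_future) / dec
}

#' COG track and shift rates across scenarios and periods
#'
#' @param surfaces nested list `[[scenario]][[period]]` of abundance
#'   [env_grid] for one species, plus a `present` element.
#' @param species species label.
#' @return data.frame: species, scenario, period, COG lon/lat, and
#'   shift rate vs present (NA for the present row).
#' @export
cog_track <- function(surfaces, species = "species") {
  cog_p <- center_of_gravity(surfaces$present)
  rows <- list(data.frame(species = species, scenario = "present",
                          period = PRESENT_PERIOD,
                          lon = cog_p[["lon"]], lat = cog_p[["lat"]],
                          rate_km_per_decade = NA_real_,
                          stringsAsFactors = FALSE))
  for (sc in setdiff(names(surfaces), "present")) {
    for (pd in names(surfaces[[sc]])) {
      cg <- center_of_gravity(surfaces[[sc]][[pd]])
      rows[[length(rows) + 1]] <- data.frame(
        species = species, scenario = sc, period = pd,
        lon = cg[["lon"]], lat = cg[["lat"]],
        rate_km_per_decade = shift_rate(cog_p, cg,
                                        future_mid = PERIOD_MIDYEARS[[pd]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent change relative to present
#'
#' `100 * (future - present) / |present|`; the absolute-value
#' denominator keeps the sign convention meaningful when the present
#' value (e.g. a profit) is negative. A zero present value is flagged
#' undefined and returned as `NA` with a warning.
#'
#' @param present_value,future_value numeric vectors.
#' @return percent change.
#' @export
percent_change <- function(present_value, future_value) {
  out <- 100 * (future_value - present_value) / abs(present_value)
  if (any(present_value == 0)) {
    warning("percent change undefined for zero present value")
    out[present_value == 0] <- NA_real_
  }
  out
}

#' Ring-buffer profile of a gridded quantity around a port
#'
#' Assigns every marine cell center to a 100-km (by default) distance
#' ring around a port — ring k covers the half-open interval
#' ((k-1)w, kw], with the port's own cell in ring 1 — and averages the
#' per-cell values within each ring intersected with a jurisdiction
#' mask. Empty rings are reported as missing, not zero.
#'
#' @param grid an [env_grid] of the per-cell quantity (e.g. cumulative
#'   MCP per cell).
#' @param port `c(lon, lat)` of the port.
#' @param ring_width_km ring width in km (default 100).
#' @param n_rings number of rings.
#' @param jurisdiction optional logical matrix restricting the cells.
#' @return data.frame: ring index, inner/outer radii, cell count, mean
#'   value (NA for empty rings).
#' @export
port_buffer_profile <- function(grid, port, ring_width_km = 100, n_rings = 8,
                                jurisdiction = NULL) {
  if (ring_width_km <= 0) stop("ring width must be positive")
  cell_index(grid, port[1], port[2]) # errors if the port is outside the grid
  m <- grid$mask & !is.na(grid$values)
  if (!is.null(jurisdiction)) m <- m & jurisdiction
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no marine cell within the buffered region")
  d <- geosphere::distHaversine(cbind(grid$lon[idx[, 2]], grid$lat[idx[, 1]]),
                                c(port[1], port[2]),
                                r = EARTH_RADIUS_KM * 1000) / 1000
  ring <- pmax(ceiling(d / ring_width_km), 1L)
  vals <- grid$values[m]
  out <- data.frame(ring = seq_len(n_rings),
                    inner_km = (seq_len(n_rings) - 1) * ring_width_km,
                    outer_km = seq_len(n_rings) * ring_width_km,
                    n_cells = 0L, mean_value = NA_real_)
  for (k in seq_len(n_rings)) {
    sel <- ring == k
    out$n_cells[k] <- sum(sel)
    if (any(sel)) out$mean_value[k] <- mean(vals[sel])
  }
  if (all(out$n_cells == 0)) stop("no marine cell within the outermost ring")
  out
}

#' Bioeconomic comparison of high-effort fishing grounds
#'
#' Identifies present-day fishing grounds as cells with aggregated
#' effort at or above a threshold (default 1000 hours), intersects them
#' with each jurisdiction, and runs the full surplus-production chain
#' (biomass integral through MSY, MCP, revenue, cost, profit) with the
#' same species parameter set in every jurisdiction. A jurisdiction
#' whose fishing-ground mask is empty is reported as missing, not zero.
#'
#' @param effort an [env_grid] of aggregated fishing hours.
#' @param threshold effort threshold in hours (default 1000).
#' @param surfaces nested list of abundance surfaces:
#'   `[[species]]$present` and `[[species]][[scenario]][[period]]`.
#' @param params reference-parameter table.
#' @param jurisdictions named list of logical masks.
#' @param msy_convention exponent convention passed through to [msy].
#' @return data.frame of fleet aggregates (MCP, MRP, MPP) per
#'   jurisdiction, period and scenario.
#' @export
fishing_ground_compare <- function(effort, threshold = 1000, surfaces, params,
                                   jurisdictions, msy_convention = "printed") {
  ground <- effort$mask & !is.na(effort$values) & effort$values >= threshold
  out <- list()
  for (j in names(jurisdictions)) {
    region <- ground & jurisdictions[[j]]
    if (!any(region)) {
      out[[length(out) + 1]] <- data.frame(
        jurisdiction = j, period = NA_character_, scenario = NA_character_,
        sensitivity = NA_character_, MCP = NA_real_, MRP = NA_real_,
        MPP = NA_real_, stringsAsFactors = FALSE)
      next
    }
    biomass <- list()
    for (sp in names(surfaces)) {
      s <- surfaces[[sp]]
      biomass[[length(biomass) + 1]] <- data.frame(
        species = sp, period = PRESENT_PERIOD, scenario = "present",
        B = integrate_biomass(s$present, region), stringsAsFactors = FALSE)
      for (sc in setdiff(names(s), "present")) {
        for (pd in names(s[[sc]])) {
          biomass[[length(biomass) + 1]] <- data.frame(
            species = sp, period = pd, scenario = sc,
            B = integrate_biomass(s[[sc]][[pd]], region),
            stringsAsFactors = FALSE)
        }
      }
    }
    rec <- bioecon_records(do.call(rbind, biomass), params,
                           msy_convention = msy_convention)
    agg <- fleet_aggregates(rec)
    agg$jurisdiction <- j
    out[[length(out) + 1]] <- agg[, c("jurisdiction", "period", "scenario",
                                      "sensitivity", "MCP", "MRP", "MPP")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
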