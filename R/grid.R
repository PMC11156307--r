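#' @keywords internal
"_PACKAGE"

## Time windows used throughout: a 20-year present baseline and four
## 20-year future windows. Midpoint years anchor shift rates and the
## price/cost sensitivity ramp.
PRESENT_PERIOD <- "2000-2019"
FUTURE_PERIODS <- c("2021-2040", "2041-2060", "2061-2080", "2081-2100")
PERIOD_MIDYEARS <- c(
  "2000-2019" = 2009.5,
  "2021-2040" = 2030.5,
  "2041-2060" = 2050.5,
  "2061-2080" = 2070.5,
  "2081-2100" = 2090.5
)
HIST_PERIOD <- "2000-2014" # coarse-model historical reference window

EARTH_RADIUS_KM <- 6371

ENV_VARIABLES <- c("WSST", "WSIC", "WSBT", "SSBT", "SNPP", "depth")

## physical bounds enforced after delta addition (NA = unbounded)
VAR_BOUNDS <- list(
  WSST = c(-Inf, Inf),
  WSIC = c(0, 100),
  WSBT = c(-Inf, Inf),
  SSBT = c(-Inf, Inf),
  SNPP = c(0, Inf),
  depth = c(0, Inf)
)

#' Regular lon/lat environmental grid
#'
#' The basic spatial container of the package: a single 2-D layer on a
#' regular, cell-center registered lon/lat grid, tagged with the variable
#' it holds and the period/scenario it belongs to. Values are stored as a
#' matrix with rows indexing latitude (ascending) and columns indexing
#' longitude (ascending); `NA` cells are land or otherwise missing, and a
#' logical `mask` (TRUE = marine/valid) travels with the values.
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lon,lat strictly increasing cell-center coordinates in degrees.
#' @param variable layer name, e.g. `"SSBT"` (deg C), `"WSIC"` (percent),
#'   `"SNPP"` (mg C m-2 d-1), `"depth"` (m), or `"abundance"` (kg/km2).
#' @param period period label, e.g. `"2000-2019"`.
#' @param scenario scenario label, e.g. `"historical"` or `"SSP585"`.
#' @param mask logical matrix of the same shape, TRUE where the cell is
#'   marine/valid. Defaults to `!is.na(values)`.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(values, lon, lat, variable = "layer",
                     period = "present", scenario = "historical",
                     mask = NULL) {
  values <- as.matrix(values)
  if (length(lon) < 2 || length(lat) < 2)
    stop("grid needs at least 2 cells per axis")
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat must be strictly increasing")
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("values must be length(lat) x length(lon)")
  dlon <- diff(lon); dlat <- diff(lat)
  if (max(abs(dlon - dlon[1])) > 1e-8 || max(abs(dlat - dlat[1])) > 1e-8)
    stop("grid must be regular")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & !is.na(values)
  values[!mask] <- NA_real_
  structure(
    list(values = values, lon = as.numeric(lon), lat = as.numeric(lat),
         variable = variable, period = period, scenario = scenario,
         resolution = c(lon = dlon[1], lat = dlat[1]), mask = mask),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "<env_grid> %s [%s, %s]  %d x %d cells @ %.3g deg  range [%.4g, %.4g]\n",
    x$variable, x$period, x$scenario, length(x$lat), length(x$lon),
    x$resolution[["lon"]], rng[1], rng[2]))
  invisible(x)
}

#' @export
is.env_grid <- function(x) inherits(x, "env_grid")

grid_compatible <- function(a, b) {
  length(a$lon) == length(b$lon) && length(a$lat) == length(b$lat) &&
    max(abs(a$lon - b$lon)) < 1e-8 && max(abs(a$lat - b$lat)) < 1e-8
}

stopifnot_compatible <- function(a, b) {
  if (!grid_compatible(a, b)) stop("grids are not on the same lon/lat mesh")
  invisible(TRUE)
}

#' Per-cell areas of a regular lon/lat grid
#'
#' Spherical rectangle areas, `R^2 * dphi * dlambda * cos(phi_center)` with
#' Earth radius 6371 km, so all area-weighted quantities (biomass
#' integrals, cold-pool extent, centers of gravity) are reproducible
#' bit-for-bit.
#'
#' @param grid an [env_grid].
#' @return numeric matrix of cell areas in km2 (same shape as the values).
#' @export
cell_areas <- function(grid) {
  dphi <- grid$resolution[["lat"]] * pi / 180
  dlam <- grid$resolution[["lon"]] * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * dphi * dlam * cos(grid$lat * pi / 180)
  matrix(row_area, nrow = length(grid$lat), ncol = length(grid$lon))
}

## clamp a layer to its physical bounds (after delta addition)
clamp_variable <- function(grid) {
  b <- VAR_BOUNDS[[grid$variable]]
  if (is.null(b)) return(grid)
  grid$values <- pmin(pmax(grid$values, b[1]), b[2])
  grid
}

## replace values, keeping grid metadata
with_values <- function(grid, values, variable = grid$variable,
                        period = grid$period, scenario = grid$scenario) {
  env_grid(values, grid$lon, grid$lat, variable = variable,
           period = period, scenario = scenario, mask = grid$mask)
}

## evaluate seeded code without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
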