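# shared fixtures and independent oracles (kept free of package internals)

tiny_config <- function(seed = 7, n_surveys_per_year = 40, ...) {
  synth_config(lon_range = c(-178, -172), lat_range = c(56, 61),
               n_species = 2, n_surveys_per_year = n_surveys_per_year,
               seed = seed, ...)
}

two_scenarios <- list(
  SSP126 = list(warming = 1.0, ice_decline = 0.20, npp_decline = 0.05),
  SSP585 = list(warming = 5.0, ice_decline = 0.75, npp_decline = 0.20)
)

toy_grid <- function(values, lon = NULL, lat = NULL, variable = "SSBT", ...) {
  values <- as.matrix(values)
  if (is.null(lon)) lon <- seq_len(ncol(values))
  if (is.null(lat)) lat <- seq_len(nrow(values)) + 59
  env_grid(values, lon, lat, variable = variable, ...)
}

monthly_stack <- function(value_list, months, lon = c(0, 1), lat = c(60, 61),
                          variable = "WSST") {
  out <- lapply(seq_along(value_list), function(i) {
    g <- env_grid(as.matrix(value_list[[i]]), lon, lat, variable = variable)
    attr(g, "month") <- as.integer(months[i])
    g
  })
  out
}

# independent haversine (explicit formula, not the geosphere route)
haversine_km_oracle <- function(p1, p2, R = 6371) {
  to_rad <- pi / 180
  dlat <- (p2[2] - p1[2]) * to_rad
  dlon <- (p2[1] - p1[1]) * to_rad
  a <- sin(dlat / 2)^2 + cos(p1[2] * to_rad) * cos(p2[2] * to_rad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(pmin(a, 1)))
}

# independent bilinear interpolation with clamped (constant) extrapolation
bilinear_oracle <- function(x, y, Z, xq, yq) {
  xq <- pmin(pmax(xq, min(x)), max(x))
  yq <- pmin(pmax(yq, min(y)), max(y))
  out <- matrix(NA_real_, length(yq), length(xq))
  for (i in seq_along(yq)) for (j in seq_along(xq)) {
    jx <- max(which(x <= xq[j] + 1e-12)); jx <- min(jx, length(x) - 1)
    iy <- max(which(y <= yq[i] + 1e-12)); iy <- min(iy, length(y) - 1)
    u <- (xq[j] - x[jx]) / (x[jx + 1] - x[jx])
    v <- (yq[i] - y[iy]) / (y[iy + 1] - y[iy])
    out[i, j] <- Z[iy, jx] * (1 - u) * (1 - v) + Z[iy, jx + 1] * u * (1 - v) +
      Z[iy + 1, jx] * (1 - u) * v + Z[iy + 1, jx + 1] * u * v
  }
  out
}

# explicit spherical cell area (hand formula used by the area oracles)
cell_area_oracle <- function(lat_deg, res_lon, res_lat, R = 6371) {
  R^2 * (res_lat * pi / 180) * (res_lon * pi / 180) * cos(lat_deg * pi / 180)
}
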