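#' Seasonal mean of a monthly layer stack
#'
#' Per-cell arithmetic mean over the months of a season: winter is
#' January-April, summer June-August. Cells masked in some but not all
#' months are averaged over the available months and flagged in the
#' `"partial"` attribute; cells masked in every month stay masked.
#'
#' @param monthly list of [env_grid], each carrying a `month` attribute
#'   (integer 1-12).
#' @param season `"winter"` (months 1-4) or `"summer"` (months 6-8), or
#'   an integer vector of months.
#' @return an [env_grid] of seasonal means, with attribute `partial` (a
#'   logical matrix marking cells averaged over an incomplete season).
#' @export
seasonal_mean <- function(monthly, season = c("winter", "summer")) {
  months <- if (is.numeric(season)) as.integer(season)
            else switch(match.arg(season), winter = 1:4, summer = 6:8)
  have <- vapply(monthly, function(g) attr(g, "month"), integer(1))
  if (!all(months %in% have))
    stop("missing months for the season: ", paste(setdiff(months, have), collapse = ", "))
  sel <- monthly[match(months, have)]
  for (g in sel[-1]) stopifnot_compatible(sel[[1]], g)
  arrs <- lapply(sel, `[[`, "values")
  n_ok <- Reduce(`+`, lapply(arrs, function(a) !is.na(a)))
  total <- Reduce(`+`, lapply(arrs, function(a) ifelse(is.na(a), 0, a)))
  vals <- ifelse(n_ok > 0, total / n_ok, NA_real_)
  out <- env_grid(vals, sel[[1]]$lon, sel[[1]]$lat,
                  variable = sel[[1]]$variable, period = sel[[1]]$period,
                  scenario = sel[[1]]$scenario)
  attr(out, "partial") <- n_ok > 0 & n_ok < length(sel)
  out
}

#' Cell-wise mean across ensemble members
#'
#' @param members list of [env_grid] on one mesh.
#' @return an [env_grid] of the cross-member mean (NA where any member
#'   is masked, keeping the mask consistent across members).
#' @export
ensemble_mean <- function(members) {
  if (length(members) == 0) stop("no members")
  for (g in members[-1]) stopifnot_compatible(members[[1]], g)
  vals <- Reduce(`+`, lapply(members, `[[`, "values")) / length(members)
  with_values(members[[1]], vals)
}

#' Resample a layer to a different regular grid
#'
#' Interpolates cell-center values of `grid` at the cell centers of
#' `target`. Bilinear interpolation is the default (with constant
#' extrapolation beyond the outermost source cell centers); nearest
#' neighbour is available for categorical layers.
#'
#' @param grid source [env_grid].
#' @param target [env_grid] defining the output mesh (its values are
#'   ignored, its mask is applied).
#' @param method `"bilinear"` or `"nearest"`.
#' @return an [env_grid] on the target mesh.
#' @export
resample_grid <- function(grid, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  ## interpolation cannot carry NA holes; fill land cells with the source
  ## basin mean before interpolating, then re-apply the target mask
  src <- grid$values
  if (anyNA(src)) src[is.na(src)] <- mean(src, na.rm = TRUE)
  ## clamp target centers into the source center hull (constant edges)
  xq <- pmin(pmax(target$lon, grid$lon[1]), grid$lon[length(grid$lon)])
  yq <- pmin(pmax(target$lat, grid$lat[1]), grid$lat[length(grid$lat)])
  if (method == "bilinear") {
    pts <- expand.grid(x = xq, y = yq) # varies x fastest
    z <- pracma::interp2(grid$lon, grid$lat, src, pts$x, pts$y, method = "linear")
    vals <- matrix(z, nrow = length(yq), ncol = length(xq), byrow = TRUE)
  } else {
    ci <- vapply(xq, function(x) which.min(abs(grid$lon - x)), integer(1))
    ri <- vapply(yq, function(y) which.min(abs(grid$lat - y)), integer(1))
    vals <- src[ri, ci, drop = FALSE]
  }
  env_grid(vals, target$lon, target$lat, variable = grid$variable,
           period = grid$period, scenario = grid$scenario, mask = target$mask)
}

#' Delta-method spatial downscaling
#'
#' Anchors coarse scenario projections to a fine observational baseline:
#' the cross-member mean change (future minus historical) is computed on
#' the coarse grid, resampled to the fine grid, and added to the
#' fine-resolution present-day layer. After addition the result is
#' clamped to the variable's physical bounds (ice concentration to
#' [0, 100], primary production to nonnegative values), because an
#' additive anomaly can push bounded quantities out of range.
#'
#' @param coarse_hist,coarse_future lists of member [env_grid] on a
#'   common coarse mesh.
#' @param fine_present the fine-resolution present-day [env_grid] of the
#'   same variable.
#' @param method resampling kernel passed to [resample_grid].
#' @return fine-resolution future [env_grid] (period/scenario labels
#'   taken from the future members).
#' @export
delta_downscale <- function(coarse_hist, coarse_future, fine_present,
                            method = "bilinear") {
  hist_mean <- ensemble_mean(coarse_hist)
  fut_mean <- ensemble_mean(coarse_future)
  stopifnot_compatible(hist_mean, fut_mean)
  delta <- with_values(fut_mean, fut_mean$values - hist_mean$values)
  delta_fine <- resample_grid(delta, fine_present, method = method)
  out <- env_grid(fine_present$values + delta_fine$values,
                  fine_present$lon, fine_present$lat,
                  variable = fine_present$variable,
                  period = coarse_future[[1]]$period,
                  scenario = coarse_future[[1]]$scenario,
                  mask = fine_present$mask)
  clamp_variable(out)
}

#' Downscale every scenario/period of a synthetic environment
#'
#' Convenience driver: applies [delta_downscale] to each dynamic
#' variable for every scenario and period of a [generate_environment]
#' result, re-attaching the static depth layer to each future stack.
#'
#' @param env environment list from [generate_environment].
#' @param scenarios,periods subsets to process (defaults: all).
#' @param method resampling kernel.
#' @return nested list: `[[scenario]][[period]]` = named fine stack.
#' @export
downscale_all <- function(env, scenarios = names(env$coarse_future),
                          periods = FUTURE_PERIODS, method = "bilinear") {
  out <- lapply(scenarios, function(sc) {
    per <- lapply(periods, function(pd) {
      stack <- lapply(names(env$coarse_hist), function(v) {
        delta_downscale(env$coarse_hist[[v]],
                        env$coarse_future[[sc]][[pd]][[v]],
                        env$fine_present[[v]], method = method)
      })
      names(stack) <- names(env$coarse_hist)
      depth <- env$fine_present$depth
      depth$period <- pd; depth$scenario <- sc
      stack$depth <- depth
      stack
    })
    names(per) <- periods
    per
  })
  names(out) <- scenarios
  out
}

#' Cold-pool mask and areal extent
#'
#' The cold pool is the region of summer bottom water at or below a
#' temperature threshold (default 2 deg C). The comparator is
#' configurable between `<=` and `<`.
#'
#' @param ssbt summer bottom temperature [env_grid].
#' @param threshold temperature threshold in deg C.
#' @param comparator `"lte"` (default) or `"lt"`.
#' @return list with `mask` (logical matrix over marine cells) and
#'   `area_km2` (cos-latitude weighted cell-area sum).
#' @export
cold_pool_mask <- function(ssbt, threshold = 2, comparator = c("lte", "lt")) {
  comparator <- match.arg(comparator)
  cmp <- if (comparator == "lte") `<=` else `<`
  m <- ssbt$mask & !is.na(ssbt$values) & cmp(ssbt$values, threshold)
  list(mask = m, area_km2 = sum(cell_areas(ssbt)[m]))
}
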