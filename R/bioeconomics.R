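#' Integrate an abundance surface to total biomass
#'
#' Converts a predicted density surface (kg/km2) into a regional biomass
#' in metric tons: the sum over unmasked marine cells of density times
#' spherical cell area, divided by 1000.
#'
#' @param surface an [env_grid] of density in kg/km2.
#' @param region optional logical matrix selecting the cells to
#'   integrate (intersected with the surface's marine mask).
#' @return biomass in mt.
#' @export
integrate_biomass <- function(surface, region = NULL) {
  m <- surface$mask & !is.na(surface$values)
  if (!is.null(region)) m <- m & region
  if (!any(m)) stop("empty integration region")
  sum(surface$values[m] * cell_areas(surface)[m]) / 1000
}

check_phi <- function(phi) {
  if (any(phi == 0) || any(phi <= -1))
    stop("Pella-Tomlinson shape must satisfy phi > -1 and phi != 0")
  invisible(phi)
}

#' Pella-Tomlinson B_MSY/K ratio
#'
#' The ratio of biomass at maximum sustainable yield to carrying
#' capacity implied by a Pella-Tomlinson yield curve with shape `phi`:
#' `(phi + 1)^(-1/phi)`. `phi = 1` recovers the Graham-Schaefer logistic
#' value 0.5; the limit through `phi -> 0` is `1/e` (the Fox model).
#'
#' @param phi shape parameter, `phi > -1`, `phi != 0`.
#' @return dimensionless ratio in (0, 1).
#' @export
pella_tomlinson_bmsy_ratio <- function(phi) {
  check_phi(phi)
  (phi + 1)^(-1 / phi)
}

#' Maximum sustainable yield of a Pella-Tomlinson stock
#'
#' `MSY = g * B * (phi + 1)^(1/phi)` with `g` the population growth rate
#' (MSY/B_MSY) and `B` the model-derived biomass, taken to be at
#' carrying capacity for the present-day baseline. Two exponent
#' conventions are provided: `"printed"` (the default, exponent
#' `+1/phi`) and `"bmsy_consistent"` (exponent `-1/phi`, which makes
#' `MSY = g * B_MSY` exact when `B` is carrying capacity, since
#' `B_MSY = K * (phi+1)^(-1/phi)`). The convention used is recorded in
#' the `"convention"` attribute.
#'
#' @param B biomass in mt.
#' @param g population growth rate (yr^-1).
#' @param phi Pella-Tomlinson shape.
#' @param convention `"printed"` or `"bmsy_consistent"`.
#' @return MSY in mt.
#' @export
msy <- function(B, g, phi, convention = c("printed", "bmsy_consistent")) {
  convention <- match.arg(convention)
  check_phi(phi)
  if (any(B < 0)) stop("B must be nonnegative")
  s <- if (convention == "printed") 1 else -1
  out <- g * B * (phi + 1)^(s / phi)
  attr(out, "convention") <- convention
  out
}

#' Maximum catch potential
#'
#' `MCP = B * U_MSY`: the catch taken at the reference exploitation rate
#' at MSY, a proxy for sustainable yield.
#'
#' @param B biomass (mt).
#' @param u_msy exploitation rate at MSY in (0, 1].
#' @return MCP in mt.
#' @export
mcp <- function(B, u_msy) {
  if (any(B < 0)) stop("B must be nonnegative")
  if (any(u_msy <= 0) || any(u_msy > 1)) stop("u_msy must be in (0,1]")
  B * u_msy
}

#' Revenue and fleet revenue aggregate
#'
#' `R = p * MCP` per species; the maximum revenue potential `MRP` is the
#' exact sum of per-species revenues within a period/scenario.
#'
#' @param p ex-vessel price (USD/mt).
#' @param MCP maximum catch potential (mt).
#' @return revenue in USD.
#' @export
revenue <- function(p, MCP) {
  if (any(p < 0)) stop("price must be nonnegative")
  p * MCP
}

#' @rdname revenue
#' @param R vector of per-species revenues.
#' @export
mrp <- function(R) sum(R)

#' Cost parameter per unit of fishing mortality
#'
#' `c = p * f_bar * b_bar * MSY / (g * f_bar)^beta`, the unique grouping
#' under which revenue equals cost (zero profit) at the open-access
#' bioeconomic equilibrium, where catch is `f_bar * b_bar * MSY` and
#' fishing mortality is `g * f_bar` (with F_MSY identified with `g`).
#'
#' @param p ex-vessel price (USD/mt).
#' @param f_bar F/F_MSY at bioeconomic equilibrium.
#' @param b_bar B/B_MSY at bioeconomic equilibrium.
#' @param MSY maximum sustainable yield (mt).
#' @param g population growth rate.
#' @param beta non-linear cost exponent (> 1; reference value 1.3).
#' @return cost parameter in USD per unit mortality^beta.
#' @export
cost_param <- function(p, f_bar, b_bar, MSY, g, beta = 1.3) {
  if (any(g * f_bar <= 0)) stop("g * f_bar must be positive")
  p * f_bar * b_bar * MSY / (g * f_bar)^beta
}

#' Profit at MSY and fleet profit aggregate
#'
#' `pi_MSY = R - c * g^beta` per species (fishing at MSY exerts
#' mortality F_MSY = g at cost `c * g^beta`); the maximum profit
#' potential `MPP` is the exact per-species sum. Profit may be negative.
#'
#' @param R revenue (USD).
#' @param c_param cost parameter from [cost_param].
#' @param g population growth rate.
#' @param beta non-linear cost exponent.
#' @return profit in USD.
#' @export
profit_msy <- function(R, c_param, g, beta = 1.3) R - c_param * g^beta

#' @rdname profit_msy
#' @param pi_vec vector of per-species profits.
#' @export
mpp <- function(pi_vec) sum(pi_vec)

#' Price/cost sensitivity multiplier
#'
#' Linear ramp reaching a 20% increase at the end of the projection
#' period: `m(year) = 1 + rate * (year - y0) / (2100 - y0)` with
#' `y0 = 2019`. Period-level evaluation uses the period midpoint year.
#'
#' @param year evaluation year (in `[2019, 2100]`).
#' @param rate total increase reached at 2100 (default 0.2).
#' @param y0 anchor year (default 2019).
#' @return multiplier.
#' @export
sensitivity_multiplier <- function(year, rate = 0.2, y0 = 2019) {
  if (any(year < y0) || any(year > 2100)) stop("year must be within [y0, 2100]")
  1 + rate * (year - y0) / (2100 - y0)
}

SENSITIVITY_SCENARIOS <- c("base", "costs+20%", "prices+20%", "both+20%")

#' Per-species bioeconomic records for a set of biomass estimates
#'
#' Runs the full surplus-production chain for each row of a biomass
#' table: MSY, MCP, revenue, cost parameter and profit at MSY, under an
#' optional price/cost sensitivity scenario whose linear ramp is
#' evaluated at the period midpoint year (present-period rows keep
#' multiplier 1).
#'
#' @param biomass data.frame with columns `species`, `period`,
#'   `scenario`, `B` (mt).
#' @param params reference-parameter table (see
#'   [generate_reference_params]).
#' @param sensitivity one of `"base"`, `"costs+20%"`, `"prices+20%"`,
#'   `"both+20%"`.
#' @param msy_convention exponent convention passed to [msy].
#' @return data.frame of per-species records with columns B, MSY, MCP,
#'   R, c, profit plus the sensitivity label.
#' @export
bioecon_records <- function(biomass, params, sensitivity = "base",
                            msy_convention = "printed") {
  if (!sensitivity %in% SENSITIVITY_SCENARIOS)
    stop("unknown sensitivity scenario: ", sensitivity)
  i <- match(biomass$species, params$species)
  if (anyNA(i)) stop("species missing from parameter table")
  pr <- params[i, ]
  mid <- PERIOD_MIDYEARS[biomass$period]
  if (anyNA(mid)) stop("unknown period label")
  m <- rep(1, nrow(biomass))
  fut <- biomass$period != PRESENT_PERIOD
  m[fut] <- sensitivity_multiplier(pmin(mid[fut], 2100))
  p_mult <- if (sensitivity %in% c("prices+20%", "both+20%")) m else 1
  c_mult <- if (sensitivity %in% c("costs+20%", "both+20%")) m else 1
  MSY <- as.numeric(msy(biomass$B, pr$g, pr$phi, convention = msy_convention))
  MCP <- mcp(biomass$B, pr$u_msy)
  R <- revenue(pr$price * p_mult, MCP)
  cc <- cost_param(pr$price, pr$f_bar, pr$b_bar, MSY, pr$g, pr$beta) * c_mult
  pi_msy <- profit_msy(R, cc, pr$g, pr$beta)
  data.frame(species = biomass$species, period = biomass$period,
             scenario = biomass$scenario, sensitivity = sensitivity,
             B = biomass$B, MSY = MSY, MCP = MCP, R = R, c = cc,
             profit = pi_msy, stringsAsFactors = FALSE)
}

#' Fleet-level aggregates of per-species records
#'
#' Sums per-species MCP, revenue and profit over the fleet within each
#' period/scenario/sensitivity: MRP is the exact sum of revenues and
#' MPP the exact sum of profits.
#'
#' @param records output of [bioecon_records].
#' @return data.frame with one row per period/scenario/sensitivity and
#'   columns MCP, MRP, MPP.
#' @export
fleet_aggregates <- function(records) {
  key <- interaction(records$period, records$scenario, records$sensitivity,
                     drop = TRUE)
  agg <- lapply(split(records, key), function(d) {
    data.frame(period = d$period[1], scenario = d$scenario[1],
               sensitivity = d$sensitivity[1],
               MCP = sum(d$MCP), MRP = mrp(d$R), MPP = mpp(d$profit),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$scenario, out$period), , drop = FALSE]
}
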