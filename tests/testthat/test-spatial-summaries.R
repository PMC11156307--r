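test_that("center of gravity follows biomass weighting", {
  # point mass: the occupied cell's center
  v <- matrix(0, 3, 3); v[2, 3] <- 7
  g <- toy_grid(v, lon = c(10, 11, 12), lat = c(60, 61, 62), variable = "abundance")
  expect_equal(center_of_gravity(g), c(lon = 12, lat = 61))
  # two cells on one latitude: plain weighted mean of longitudes
  v2 <- matrix(0, 2, 3)
  v2[1, 1] <- 1; v2[1, 3] <- 3
  g2 <- toy_grid(v2, lon = c(0, 1, 2), lat = c(60, 61), variable = "abundance")
  expect_equal(center_of_gravity(g2), c(lon = 1.5, lat = 60))
  # uniform density: the area-weighted grid centroid (lat pulled toward
  # the equatorward rows, lon exactly central)
  g3 <- toy_grid(matrix(1, 3, 3), lon = c(0, 1, 2), lat = c(60, 61, 62),
                 variable = "abundance")
  a <- cell_area_oracle(c(60, 61, 62), 1, 1)
  expect_equal(center_of_gravity(g3),
               c(lon = 1, lat = sum(a * c(60, 61, 62)) / sum(a)))
  expect_error(center_of_gravity(toy_grid(matrix(0, 2, 2))), "all-zero")
})

test_that("COG is equivariant under a one-cell eastward translation", {
  cfg <- tiny_config()
  env <- generate_environment(cfg)
  tru <- true_surface(make_species_niches(cfg)[1, ], env$fine_present)
  v <- tru$values; v[is.na(v)] <- 0
  g <- env_grid(v, tru$lon, tru$lat, variable = "abundance")
  shifted <- v
  shifted[, 2:ncol(v)] <- v[, 1:(ncol(v) - 1)]
  shifted[, 1] <- 0
  gs <- env_grid(shifted, tru$lon, tru$lat, variable = "abundance")
  c0 <- center_of_gravity(g); c1 <- center_of_gravity(gs)
  # the mass in the last column is dropped; compare on the translatable part
  g_trim <- g; g_trim$values[, ncol(v)] <- 0
  c0t <- center_of_gravity(g_trim)
  expect_equal(c1[["lon"]], c0t[["lon"]] + tru$resolution[["lon"]], tolerance = 1e-9)
  expect_equal(c1[["lat"]], c0t[["lat"]], tolerance = 1e-9)
})

test_that("shift rates match an independent haversine oracle", {
  p <- c(-170, 60)
  expect_equal(shift_rate(p, p, future_mid = 2090.5), 0)
  # 1 deg of latitude over 2.1 decades
  q <- c(-170, 61)
  r <- shift_rate(p, q, present_mid = 2009.5, future_mid = 2030.5)
  expect_equal(r, haversine_km_oracle(p, q) / 2.1, tolerance = 1e-9)
  expect_equal(r, 52.9499650688375, tolerance = 1e-10) # frozen oracle value
  # doubling the elapsed decades halves the rate
  r2 <- shift_rate(p, q, present_mid = 2009.5, future_mid = 2051.5)
  expect_equal(r2, r / 2, tolerance = 1e-12)
  # diagonal displacement agrees with the hand formula
  q2 <- c(-168.3, 61.2)
  expect_equal(shift_rate(p, q2, future_mid = 2090.5),
               haversine_km_oracle(p, q2) / 8.1, tolerance = 1e-9)
  expect_error(shift_rate(p, q, present_mid = 2050, future_mid = 2030.5),
               "postdate")
})

test_that("percent change uses the absolute-present denominator", {
  expect_equal(percent_change(200, 200), 0)
  expect_equal(percent_change(200, 150), -25)
  # negative present profit: a rise toward zero is a positive change
  expect_equal(percent_change(-100, -50), 50)
  expect_equal(percent_change(-100, -150), -50)
  expect_warning(out <- percent_change(0, 10), "undefined")
  expect_true(is.na(out))
})

test_that("port ring means equal exhaustive cell-by-cell recomputation", {
  lon <- seq(-171, -167, 1); lat <- seq(58, 62, 1)
  port <- c(-169, 58)
  # constant field: every non-empty ring has the same mean
  gc_ <- env_grid(matrix(3.5, 5, 5), lon, lat, variable = "MCP")
  prof <- port_buffer_profile(gc_, port, 100, n_rings = 8)
  expect_true(all(prof$mean_value[prof$n_cells > 0] == 3.5))
  expect_true(all(is.na(prof$mean_value[prof$n_cells == 0])))
  # ring cell counts tile the buffered region
  expect_equal(sum(prof$n_cells), 25)
  # brute force on a varying 5x5 field
  set.seed(1)
  v <- matrix(runif(25, 0, 10), 5, 5)
  g <- env_grid(v, lon, lat, variable = "MCP")
  prof2 <- port_buffer_profile(g, port, 100, n_rings = 8)
  for (k in prof2$ring) {
    acc <- c()
    for (i in 1:5) for (j in 1:5) {
      d <- haversine_km_oracle(c(lon[j], lat[i]), port)
      if (max(ceiling(d / 100), 1) == k) acc <- c(acc, v[i, j])
    }
    if (length(acc) == 0) expect_true(is.na(prof2$mean_value[k]))
    else expect_equal(prof2$mean_value[k], mean(acc), tolerance = 1e-9)
  }
  # a single occupied cell ~150 km away contributes to ring 2 only
  v1 <- matrix(0, 5, 5)
  d_all <- outer(seq_along(lat), seq_along(lon), Vectorize(function(i, j)
    haversine_km_oracle(c(lon[j], lat[i]), port)))
  pick <- which(d_all > 100 & d_all <= 200, arr.ind = TRUE)[1, ]
  v1[pick[1], pick[2]] <- 9
  mask1 <- v1 > 0
  g1 <- env_grid(v1, lon, lat, variable = "MCP", mask = mask1)
  prof1 <- port_buffer_profile(g1, port, 100, n_rings = 4)
  expect_equal(prof1$mean_value[2], 9)
  expect_true(all(is.na(prof1$mean_value[-2])))
  expect_error(port_buffer_profile(g, c(-150, 20), 100, 4), "outside")
})

test_that("fishing-ground comparison equals a manual run of the bioeconomic chain", {
  lon <- c(0, 1, 2, 3); lat <- c(60, 61, 62)
  effort_vals <- matrix(c(1500, 800, 100, 2000, 1200, 50,
                          900, 1100, 10, 3000, 400, 0), 3, 4)
  eff <- env_grid(effort_vals, lon, lat, variable = "effort")
  jur <- list(A = matrix(rep(c(TRUE, FALSE), c(6, 6)), 3, 4),
              B = matrix(rep(c(FALSE, TRUE), c(6, 6)), 3, 4))
  dens <- matrix(seq(10, 120, 10), 3, 4)
  surf_p <- env_grid(dens, lon, lat, variable = "abundance",
                     period = "2000-2019", scenario = "present")
  surf_f <- env_grid(dens * 0.6, lon, lat, variable = "abundance",
                     period = "2081-2100", scenario = "SSP585")
  surfaces <- list(sp01 = list(present = surf_p,
                               SSP585 = list(`2081-2100` = surf_f)))
  params <- generate_reference_params(1, groups = "groundfish", seed = 3)
  params$species <- "sp01"
  got <- fishing_ground_compare(eff, 1000, surfaces, params, jur)
  # manual recomputation for jurisdiction A, present period
  ground <- effort_vals >= 1000
  cellA <- which(ground & jur$A)
  area <- cell_areas(surf_p)
  B <- sum(dens[cellA] * area[cellA]) / 1000
  MSY <- params$g * B * (params$phi + 1)^(1 / params$phi)
  MCP <- B * params$u_msy
  R <- params$price * MCP
  cc <- params$price * params$f_bar * params$b_bar * MSY /
    (params$g * params$f_bar)^params$beta
  prof <- R - cc * params$g^params$beta
  rowA <- got[got$jurisdiction == "A" & got$period == "2000-2019", ]
  expect_equal(rowA$MCP, MCP, tolerance = 1e-12)
  expect_equal(rowA$MRP, R, tolerance = 1e-12)
  expect_equal(rowA$MPP, prof, tolerance = 1e-12)
  # future row scales with the biomass ratio (single species, linear chain)
  rowAf <- got[got$jurisdiction == "A" & got$period == "2081-2100", ]
  expect_equal(rowAf$MCP / rowA$MCP, 0.6, tolerance = 1e-12)
  # a threshold above the maximum effort reports both jurisdictions missing
  none <- fishing_ground_compare(eff, 1e6, surfaces, params, jur)
  expect_true(all(is.na(none$MCP)))
  expect_equal(nrow(none), 2)
})

test_that("uniform effort and density split MCP by marine-area ratio", {
  lon <- c(0, 1, 2, 3); lat <- c(60, 61, 62)
  eff <- env_grid(matrix(2000, 3, 4), lon, lat, variable = "effort")
  surf <- env_grid(matrix(5, 3, 4), lon, lat, variable = "abundance",
                   period = "2000-2019", scenario = "present")
  jur <- list(A = matrix(rep(c(TRUE, FALSE), c(3, 9)), 3, 4),
              B = matrix(rep(c(FALSE, TRUE), c(3, 9)), 3, 4))
  params <- generate_reference_params(1, groups = "groundfish", seed = 1)
  got <- fishing_ground_compare(eff, 1000, list(sp01 = list(present = surf)),
                                params, jur)
  area <- cell_areas(surf)
  expect_equal(got$MCP[got$jurisdiction == "A"] / got$MCP[got$jurisdiction == "B"],
               sum(area[jur$A]) / sum(area[jur$B]), tolerance = 1e-12)
})

test_that("cog_track assembles per-scenario rates against the present", {
  cfg <- tiny_config(scenarios = two_scenarios)
  env <- generate_environment(cfg)
  niche <- make_species_niches(cfg)[1, ]
  fut <- downscale_all(env, periods = c("2041-2060", "2081-2100"))
  surfaces <- list(present = true_surface(niche, env$fine_present))
  for (sc in names(two_scenarios))
    surfaces[[sc]] <- lapply(fut[[sc]], function(st) true_surface(niche, st))
  tr <- cog_track(surfaces, species = "sp01")
  expect_equal(nrow(tr), 5)
  expect_true(is.na(tr$rate_km_per_decade[tr$scenario == "present"]))
  fut_rows <- tr[tr$scenario != "present", ]
  expect_true(all(fut_rows$rate_km_per_decade >= 0))
  # rates agree with a direct recomputation
  p <- c(tr$lon[1], tr$lat[1])
  i <- which(tr$scenario == "SSP585" & tr$period == "2081-2100")
  expect_equal(tr$rate_km_per_decade[i],
               haversine_km_oracle(p, c(tr$lon[i], tr$lat[i])) / 8.1,
               tolerance = 1e-9)
})
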