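test_that("config validation rejects impossible study designs", {
  expect_error(synth_config(fine_res = 0.3), "divide")
  expect_error(synth_config(fine_res = -0.25), "positive")
  expect_error(synth_config(scenarios = list(
    a = list(warming = 2, ice_decline = .1, npp_decline = .1),
    b = list(warming = 1, ice_decline = .2, npp_decline = .2))),
    "strictly")
})

test_that("environment generation is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  e1 <- generate_environment(cfg)
  e2 <- generate_environment(cfg)
  expect_identical(e1$fine_present$SSBT$values, e2$fine_present$SSBT$values)
  expect_identical(e1$coarse_future$SSP126[["2081-2100"]]$WSIC[[3]]$values,
                   e2$coarse_future$SSP126[["2081-2100"]]$WSIC[[3]]$values)
  e3 <- generate_environment(tiny_config(seed = 12))
  expect_false(identical(e1$fine_present$SSBT$values, e3$fine_present$SSBT$values))
})

test_that("zero trend amplitudes reproduce historical coarse layers exactly", {
  cfg <- tiny_config(scenarios = list(
    flat = list(warming = 0, ice_decline = 0, npp_decline = 0)))
  env <- generate_environment(cfg)
  for (v in names(env$coarse_hist)) for (m in seq_along(env$coarse_hist[[v]]))
    expect_identical(env$coarse_future$flat[["2081-2100"]][[v]][[m]]$values,
                     env$coarse_hist[[v]][[m]]$values)
})

test_that("end-of-century basin-mean warming equals the configured amplitude", {
  cfg <- tiny_config(scenarios = two_scenarios)
  env <- generate_environment(cfg)
  for (sc in names(two_scenarios)) {
    # brute-force mean over grid cells, across members
    deltas <- vapply(seq_len(cfg$n_members), function(m) {
      mean(env$coarse_future[[sc]][["2081-2100"]]$SSBT[[m]]$values -
             env$coarse_hist$SSBT[[m]]$values, na.rm = TRUE)
    }, numeric(1))
    expect_equal(mean(deltas), two_scenarios[[sc]]$warming, tolerance = 1e-10)
  }
})

test_that("basin means respect scenario severity ordering", {
  cfg <- tiny_config()
  env <- generate_environment(cfg)
  for (pd in c("2041-2060", "2081-2100")) {
    sbt <- vapply(names(cfg$scenarios), function(sc)
      mean(ensemble_mean(env$coarse_future[[sc]][[pd]]$SSBT)$values, na.rm = TRUE),
      numeric(1))
    sic <- vapply(names(cfg$scenarios), function(sc)
      mean(ensemble_mean(env$coarse_future[[sc]][[pd]]$WSIC)$values, na.rm = TRUE),
      numeric(1))
    expect_true(all(diff(sbt) > 0))
    expect_true(all(diff(sic) < 0))
  }
})

test_that("survey CPUE follows the Gaussian niche response exactly at zero noise", {
  niche <- data.frame(species = "sp01", opt_sbt = 2, br_sbt = 1.5,
                      opt_depth = 100, br_depth = 50, opt_npp = 600,
                      br_npp = 300, max_density = 250)
  # at the multivariate optimum the response product is 1
  expect_equal(niche_expected_cpue(niche, 2, 100, 600), 250)
  # one breadth away on a single axis: max density * exp(-1/2)
  expect_equal(niche_expected_cpue(niche, 2 + 1.5, 100, 600), 250 * exp(-0.5))
  expect_equal(niche_expected_cpue(niche, 2, 100 - 50, 600), 250 * exp(-0.5))
  # two axes displaced: product of the kernels
  expect_equal(niche_expected_cpue(niche, 3.5, 150, 600), 250 * exp(-1))
})

test_that("sampled surveys carry covariates and nonnegative CPUE; zero stations give empty schema", {
  cfg <- tiny_config()
  env <- generate_environment(cfg)
  niches <- make_species_niches(cfg)
  sv <- sample_surveys(env, niches, cfg)
  expect_equal(nrow(sv), length(cfg$years) * cfg$n_surveys_per_year * cfg$n_species)
  expect_true(all(sv$cpue >= 0))
  expect_true(all(c("WSST", "WSIC", "WSBT", "SSBT", "SNPP", "depth") %in% names(sv)))
  # covariates recorded in the table match a direct grid lookup
  look <- env_extract(env$fine_present, sv$lon[1:5], sv$lat[1:5])
  expect_equal(sv$SSBT[1:5], look$SSBT)
  # zero-noise draws equal the niche expectation
  sv0 <- sample_surveys(env, niches, cfg, sigma = 0)
  i <- sv0$species == niches$species[1]
  expect_equal(sv0$cpue[i],
               niche_expected_cpue(niches[1, ], sv0$SSBT[i], sv0$depth[i], sv0$SNPP[i]))
  empty <- sample_surveys(env, niches,
                          tiny_config(n_surveys_per_year = 0))
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), names(sv))
})

test_that("survey noise is mean-one multiplicative lognormal", {
  cfg <- tiny_config(n_surveys_per_year = 400, sigma = 0.4, seed = 3)
  env <- generate_environment(cfg)
  niche <- make_species_niches(cfg)[1, ]
  sv <- sample_surveys(env, niche, cfg)
  mu <- niche_expected_cpue(niche, sv$SSBT, sv$depth, sv$SNPP)
  ratio <- sv$cpue[mu > 1] / mu[mu > 1]
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(log(ratio)), 0.4, tolerance = 0.02)
})

test_that("points outside the grid are rejected", {
  cfg <- tiny_config()
  env <- generate_environment(cfg)
  expect_error(env_extract(env$fine_present, -160, 58), "outside")
})

test_that("reference parameters honour the group shapes and round-trip through CSV", {
  p <- generate_reference_params(8, groups = c(rep("groundfish", 7), "crab"),
                                 seed = 5)
  expect_equal(p$phi, c(rep(0.188, 7), -0.093))
  expect_true(all(p$beta == 1.3))
  expect_true(all(p$g > 0 & p$g <= 1))
  expect_true(all(p$u_msy > 0 & p$u_msy < 1))
  expect_true(all(p$price > 0 & p$f_bar > 0 & p$b_bar > 0))
  path <- tempfile(fileext = ".csv")
  write_ref_params(p, path)
  expect_equal(read_ref_params(path), p)
  expect_identical(generate_reference_params(8, seed = 5)$species, p$species)
})

test_that("geography has marine ports, an exact EEZ partition, and the designed fishing ground", {
  cfg <- tiny_config(n_fishing_ground_cells = 25)
  env <- generate_environment(cfg)
  geo <- generate_geography(cfg, env)
  marine <- env$fine_present$SSBT$mask
  # ports sit on marine cells
  for (i in 1:2) {
    idx <- fishcast:::cell_index(env$fine_present$SSBT,
                                 geo$ports$lon[i], geo$ports$lat[i])
    expect_true(marine[idx$row, idx$col])
  }
  expect_lt(geo$ports$lat[1], geo$ports$lat[2]) # south port is south
  # jurisdictions are disjoint and tile the marine domain
  expect_true(all(xor(geo$eez$USA[marine], geo$eez$RUS[marine])))
  expect_false(any(geo$eez$USA & geo$eez$RUS))
  # exactly the configured number of high-effort cells
  expect_equal(sum(geo$effort$values >= 1000, na.rm = TRUE), 25)
})
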