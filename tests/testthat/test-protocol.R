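test_that("experiment specs encode the factorial design", {
  s1 <- experimentSpec("S1")
  expect_equal(c(s1@co2_mode, s1@climate_mode, s1@luc_mode),
               rep("transient", 3))
  expect_equal(experimentSpec("S2")@co2_mode, "fixed_1900")
  expect_equal(experimentSpec("S3")@climate_mode,
               "fixed_1900_1919_climatology")
  expect_equal(experimentSpec("S4")@luc_mode, "fixed_1900")
  expect_error(experimentSpec("custom", co2_mode = "whatever"), "co2_mode")
})

test_that("equilibrium: null ecosystem, fixed point and analytic steady state", {
  g <- tinyGrid(1, 1, 4)
  years <- 1900:1909
  # constant, non-seasonal climate on a single cell
  sc <- stationaryScenario(seas_amp_base = 0, seas_amp_gradient = 0,
                           p_summer_conc = 0)
  f <- generateClimate(g, sc, 1L, years)
  props <- generateSoil(g, 1L)
  params <- defaultBiomeParams()
  clim <- monthlyClimatology(f)
  frac <- matrix(0, 1, 6, dimnames = list(NULL, coverTypes()))
  frac[, "grassland"] <- 1
  co2_ref <- 310

  # a biome that cannot assimilate settles at empty pools
  params0 <- params
  params0["grassland", "c_max"] <- 0
  eq0 <- runEquilibrium(clim, co2_ref, frac, props, params0, g, tol = 0.1)
  expect_true(all(eq0@converged))
  expect_lt(eq0@c_veg[1, "grassland"], 1)
  expect_lt(eq0@c_soil[1, "grassland"], 20)

  eq <- runEquilibrium(clim, co2_ref, frac, props, params, g, tol = 0.05)
  expect_true(all(eq@converged))

  # fixed point: one more year moves the annual NEP by less than tol
  more <- runSpinup(eq, f, co2_ref, props, params, years = 1,
                    block_years = 1)
  d_pool <- sum((more@c_veg - eq@c_veg) * eq@frac +
                (more@c_soil - eq@c_soil) * eq@frac)
  expect_lt(abs(d_pool), 0.05)

  # analytic steady state for the constant-forcing balance equations
  pg <- as.list(params["grassland", ])
  T <- clim$tair[1, 1]
  hi <- heatIndex(clim$tair)[1]
  pet <- vapply(1:12, function(m)
    potentialEvapotranspiration(T, m, cellCenters(g)$lat[1], hi),
    numeric(1))
  # bucket steady state month by month (period-1 fixed point)
  water <- props@water_capacity / 2
  for (r in 1:200) {
    for (m in 1:12) {
      out <- updateSoilWater(water, clim$precip[1, m], pet[m],
                             props@water_capacity)
      water <- out$water
    }
  }
  wv <- numeric(12)
  for (m in 1:12) {
    out <- updateSoilWater(water, clim$precip[1, m], pet[m],
                           props@water_capacity)
    water <- out$water
    wv[m] <- wfps(water, props@water_capacity)
  }
  f_w <- mean(fWater(wv))
  gpp <- pg$c_max * fTemp(T, pg$t_min, pg$t_opt, pg$t_max) *
    fCO2(co2_ref, pg$k_c) *
    (1 - pg$cloud_ext * clim$cloud[1, 1]) * f_w
  gv <- pg$q10_veg^((T - 10) / 10)
  gs <- pg$q10_soil^((T - 10) / 10)
  cv_star <- (1 - pg$r_g) * gpp / (pg$l_f + (1 - pg$r_g) * pg$r_m * gv)
  cs_star <- pg$l_f * cv_star / (pg$k_d * gs * f_w)
  expect_equal(unname(eq@c_veg[1, "grassland"]), cv_star, tolerance = 0.01)
  expect_equal(unname(eq@c_soil[1, "grassland"]), cs_star, tolerance = 0.01)
})

test_that("spin-up is a no-op at zero years, cyclic and deterministic", {
  inp <- stationaryInputs(tinyGrid(2, 2, 8), years = 1900:1919)
  st <- spunState(inp, spin_years = 30)
  expect_identical(runSpinup(st, inp$forcing, 310, inp$props, inp$params,
                             years = 0), st)
  a <- runSpinup(st, inp$forcing, 310, inp$props, inp$params, years = 20,
                 block_years = 20)
  b <- runSpinup(st, inp$forcing, 310, inp$props, inp$params, years = 20,
                 block_years = 20)
  expect_identical(a@c_veg, b@c_veg)
  expect_identical(a@c_soil, b@c_soil)
  expect_error(runSpinup(st, inp$forcing, 310, inp$props, inp$params,
                         years = 10, block_years = 50), "shorter")
})

test_that("stationary transient stays at equilibrium; archives deterministic", {
  inp <- stationaryInputs(tinyGrid(2, 3, 8), years = 1900:1929)
  st <- spunState(inp, spin_years = 50)
  a1 <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params, experimentSpec("S1"))
  a2 <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params, experimentSpec("S1"))
  expect_identical(SummarizedExperiment::assay(a1, "nep"),
                   SummarizedExperiment::assay(a2, "nep"))
  ns <- nationalSeries(aggregateRegion(a1))
  area <- sum(cellAreas(inp$grid))
  # |national NEP| stays below 2 * tol * area (tol 0.1 g C m-2 yr-1)
  expect_true(all(abs(ns$nep) * 1e12 < 2 * 0.1 * area))
})

test_that("CO2-only forcing separates cleanly in S1 - S2", {
  inp <- stationaryInputs(tinyGrid(2, 3, 8), years = 1900:2000)
  inp$co2 <- generateCO2Series(296, 369, "exponential")
  st <- spunState(inp, spin_years = 50)
  a1 <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params, experimentSpec("S1"))
  a2 <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params, experimentSpec("S2"))
  npp1 <- nationalSeries(aggregateRegion(a1))$npp
  npp2 <- nationalSeries(aggregateRegion(a2))$npp
  expect_lt(abs(npp1[1] - npp2[1]), 1e-6)   # identical in 1900
  expect_gt(mean(npp1[91:100] - npp2[91:100]), 0)  # fertilized 1990s
})

test_that("factorial runs share state and collapse under stationary forcing", {
  inp <- stationaryInputs(tinyGrid(2, 2, 8), years = 1900:1929)
  st <- spunState(inp, spin_years = 30)
  ar <- runFactorial(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params, experiments = c("S1", "S2", "S4"))
  # all drivers stationary: the runs are identical
  expect_equal(SummarizedExperiment::assay(ar$S1, "nep"),
               SummarizedExperiment::assay(ar$S2, "nep"))
  expect_equal(SummarizedExperiment::assay(ar$S1, "nep"),
               SummarizedExperiment::assay(ar$S4, "nep"))
  expect_equal(archiveManifest(ar$S2)$experiment, "S2")
})

test_that("attribution is null for identical archives", {
  inp <- stationaryInputs(tinyGrid(2, 2, 8), years = 1900:1929)
  st <- spunState(inp, spin_years = 30)
  ar <- runFactorial(st, inp$forcing, inp$co2, inp$land, inp$props,
                     inp$params)
  att <- attributionEffects(ar)
  eff <- factorEffects(att)
  expect_true(all(abs(eff$co2) < 1e-9))
  expect_true(all(abs(eff$climate) < 1e-9))
  expect_true(all(abs(eff$landuse) < 1e-9))
  # with null effects the residual is exactly S1's own decadal excursion
  d1 <- decadalMeans(nationalSeries(aggregateRegion(ar$S1))$nep,
                     archiveYears(ar$S1))
  expect_equal(eff$interaction_residual, unname(d1 - d1[1]),
               tolerance = 1e-9)
  expect_error(attributionEffects(list(S2 = ar$S2)), "S1")
})

test_that("S3 requires the 1900-1919 reference climate", {
  inp <- stationaryInputs(tinyGrid(2, 2, 8), years = 1950:1970)
  st <- spunState(inp, spin_years = 10)
  expect_error(runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                            inp$params, experimentSpec("S3")),
               "1900-1919")
})
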