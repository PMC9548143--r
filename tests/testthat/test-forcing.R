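test_that("generators are bit-identical under a fixed seed", {
  g <- tinyGrid()
  f1 <- generateClimate(g, climateScenario(), 42L, 1900:1930)
  f2 <- generateClimate(g, climateScenario(), 42L, 1900:1930)
  expect_identical(f1@tair, f2@tair)
  expect_identical(f1@precip, f2@precip)
  expect_identical(f1@cloud, f2@cloud)
  f3 <- generateClimate(g, climateScenario(), 43L, 1900:1930)
  expect_false(identical(f1@tair, f3@tair))

  l1 <- generateLandCover(g, landUseScenario(), 7L)
  l2 <- generateLandCover(g, landUseScenario(), 7L)
  expect_identical(l1@frac, l2@frac)
  s1 <- generateSoil(g, 7L)
  s2 <- generateSoil(g, 7L)
  expect_identical(s1@clay, s2@clay)
})

test_that("noise-free scenario reproduces the pure climatology", {
  g <- tinyGrid()
  sc <- stationaryScenario()
  f <- generateClimate(g, sc, 1L, 1900:1909)
  cc <- cellCenters(g)
  # independent reconstruction of the prescribed climatology
  tmean <- 38 - 0.75 * cc$lat
  amp <- 6 + 0.42 * (cc$lat - g@lat_min)
  for (m in c(1, 4, 7, 10)) {
    expected <- tmean + amp * cos(2 * pi * (m - 7) / 12)
    for (y in c(1, 10)) {
      expect_equal(f@tair[, (y - 1) * 12 + m], expected, tolerance = 1e-12)
    }
  }
  # identical every year (no trend, no noise)
  expect_identical(f@tair[, 1:12], f@tair[, 109:120])
  expect_identical(f@precip[, 1:12], f@precip[, 109:120])
})

test_that("generated warming matches the scenario trend targets", {
  g <- GridSpec()  # default China grid
  f <- generateClimate(g, climateScenario(), 42L)
  tnat <- nationalAnnualMean(f, "tair")
  # independent OLS on the national series over 1971-2000
  yrs <- 1971:2000
  y <- tnat[as.character(yrs)]
  slope <- sum((yrs - mean(yrs)) * (y - mean(y))) / sum((yrs - mean(yrs))^2)
  expect_lt(abs(slope * 10 - 0.30), 0.05)
  # decadal-mean rise 1900s -> 1990s near 1 degree (within 20%)
  dm <- decadalMeans(tnat, 1900:2000)
  expect_lt(abs(dm[["1990"]] - dm[["1900"]] - 1.0), 0.2)
  # precipitation has no prescribed trend
  pnat <- nationalAnnualMean(f, "precip")
  pt <- linearTrend(pnat, 1900:2000)
  expect_gt(pt$p_value, 0.01)
  # cloud declines slightly
  cnat <- nationalAnnualMean(f, "cloud")
  expect_lt(linearTrend(cnat, 1900:2000)$slope_per_decade, 0)
  expect_true(all(f@cloud >= 0 & f@cloud <= 1))
  expect_true(all(f@precip >= 0))
})

test_that("drought injection is local, multiplicative and reversible", {
  g <- tinyGrid()
  f <- generateClimate(g, stationaryScenario(), 5L, 1900:1940)
  # identity at factor 1
  f_id <- injectDrought(f, 1910, 1915, 1:3, 1.0)
  expect_identical(f_id@precip, f@precip)
  # locality: one cell-year exactly halved, everything else untouched
  f_half <- injectDrought(f, 1905, 1905, 4L, 0.5)
  cols <- 5 * 12 + 1:12
  expect_equal(f_half@precip[4, cols], f@precip[4, cols] / 2)
  expect_identical(f_half@precip[-4, ], f@precip[-4, ])
  expect_identical(f_half@precip[, -cols], f@precip[, -cols])
  # reversibility
  f_back <- f_half
  f_back@precip[4, cols] <- f_back@precip[4, cols] / 0.5
  expect_equal(f_back@precip, f@precip, tolerance = 1e-15)
  # guards
  expect_error(injectDrought(f, 1905, 1905, integer(0), 0.5), "empty")
  expect_error(injectDrought(f, 1890, 1905, 1:2, 0.5), "outside")

  # the default event produces a negative regional precipitation anomaly
  fd <- generateClimate(GridSpec(), climateScenario(), 42L)
  mask <- defaultDroughtMask(GridSpec())
  reg <- colMeans(fd@precip[mask, ])
  ann <- tapply(reg, rep(1:101, each = 12), sum)
  expect_lt(mean(ann[23:33]) - mean(ann), 0)
})

test_that("CO2 trajectories anchor endpoints and accelerate", {
  cs <- generateCO2Series(300, 300, "constant")
  expect_true(all(co2ppm(cs) == 300))
  cs <- generateCO2Series()
  ppm <- co2ppm(cs)
  expect_equal(unname(ppm["1900"]), 296)
  expect_equal(unname(ppm["2000"]), 369)
  d <- diff(ppm)
  expect_true(all(d >= 0))
  expect_gt(mean(d[91:100]), mean(d[1:10]))
  expect_error(generateCO2Series(-1, 300), "positive")
})

test_that("non-crop remainder allocation is proportional with bare fallback", {
  out <- allocateNoncrop(0.8, c(forest = 3, grassland = 1))
  expect_equal(unname(out), c(0.6, 0.2))
  expect_equal(sum(allocateNoncrop(0.37, c(a = 1, b = 5, c = 2))), 0.37)
  out0 <- allocateNoncrop(0, c(forest = 3, grassland = 1))
  expect_true(all(out0 == 0))
  outb <- allocateNoncrop(1, c(forest = 0, grassland = 0))
  expect_equal(unname(outb["bare"]), 1)
  expect_error(allocateNoncrop(-0.1, c(a = 1)), "remaining")
  expect_error(allocateNoncrop(0.5, c(a = -1)), "non-negative")
})

test_that("land cover closes to 1 and follows the cropland trajectory", {
  g <- GridSpec()
  land <- generateLandCover(g, landUseScenario(), 42L)
  tot <- apply(land@frac, c(1, 3), sum)
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(land@frac >= 0 & land@frac <= 1))
  # national area-weighted cropland: 1980 peak above both endpoints
  w <- cellAreas(g)
  natcrop <- function(year) {
    fr <- coverFractions(land, year)
    sum(fr[, "cropland"] * w) / sum(w)
  }
  expect_gt(natcrop(1980), natcrop(1900))
  expect_gt(natcrop(1980), natcrop(2000))
  # forest concentrates southeast of the grassland/bare northwest
  fr <- coverFractions(land, 1900)
  cc <- cellCenters(g)
  se <- cc$lat < 30 & cc$lon > 110
  nw <- cc$lat > 40 & cc$lon < 95
  expect_gt(mean(fr[se, "forest"]), mean(fr[nw, "forest"]))
  expect_gt(mean(fr[nw, "grassland"] + fr[nw, "bare"]),
            mean(fr[se, "grassland"] + fr[se, "bare"]))

  stat <- generateLandCover(g, staticLandUseScenario(), 42L)
  for (y in c(1950, 2000))
    expect_identical(coverFractions(stat, y), coverFractions(stat, 1900))
})

test_that("soil properties close and derive capacity from clay", {
  g <- GridSpec()
  props <- generateSoil(g, 42L)
  expect_true(all(abs(props@sand + props@silt + props@clay - 1) < 1e-9))
  expect_equal(waterCapacity(props), 150 * (1 - props@clay) + 50)
  expect_true(all(waterCapacity(props) > 0))
})
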