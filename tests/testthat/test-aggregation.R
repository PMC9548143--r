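test_that("decadal means group exactly as the calendar decades", {
  expect_true(all(decadalMeans(rep(4.2, 101)) == 4.2))
  expect_equal(unname(decadalMeans(1900:2000)[1:3]),
               c(1904.5, 1914.5, 1924.5))
  # random series against a brute-force two-loop oracle
  set.seed(17)
  x <- rnorm(101)
  dm <- decadalMeans(x)
  for (d in 0:9) {
    expect_equal(unname(dm[as.character(1900 + 10 * d)]),
                 mean(x[(10 * d + 1):(10 * d + 10)]), tolerance = 1e-12)
  }
  # year 2000 is excluded from decades
  x2 <- x; x2[101] <- 1e6
  expect_identical(decadalMeans(x2), dm)
  expect_error(decadalMeans(1:5, 1900:2000), "equal length")
})

test_that("linear trend matches explicit OLS formulae", {
  yrs <- 1970:2000
  tr <- linearTrend(5 + 0.03 * (yrs - 1970), yrs)
  expect_equal(tr$slope_per_decade, 0.30, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1)

  tr0 <- linearTrend(rep(3, 31), yrs)
  expect_equal(tr0$slope_per_decade, 0)
  expect_equal(tr0$r_squared, 0)
  expect_equal(tr0$p_value, 1)

  set.seed(23)
  y <- 0.02 * yrs + rnorm(31, 0, 0.3)
  tr <- linearTrend(y, yrs)
  # independent implementation from the normal equations
  xc <- yrs - mean(yrs); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  resid <- yc - beta * xc
  r2 <- 1 - sum(resid^2) / sum(yc^2)
  se <- sqrt(sum(resid^2) / 29 / sum(xc^2))
  p <- 2 * pt(-abs(beta / se), 29)
  expect_equal(tr$slope_per_decade, beta * 10, tolerance = 1e-9)
  expect_equal(tr$r_squared, r2, tolerance = 1e-9)
  expect_equal(tr$p_value, p, tolerance = 1e-9)
  expect_equal(tr$n, 31)

  expect_error(linearTrend(1:2, 1901:1902), "at least 3")
  # window restriction
  trw <- linearTrend(c(rep(0, 50), 0.05 * (1:51)), 1950:2050,
                     window = c(2000, 2050))
  expect_equal(trw$slope_per_decade, 0.5, tolerance = 1e-9)
})

test_that("spearman matches rank-then-Pearson with average ties", {
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10))$rho, -1)
  s <- spearmanCor(c(1, 2, 2, 4), c(3, 1, 2, 4))
  ct <- suppressWarnings(cor.test(c(1, 2, 2, 4), c(3, 1, 2, 4),
                                  method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(1:8, 30, replace = TRUE)
    s <- spearmanCor(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-9)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(spearmanCor(exp(x), y)$rho, spearmanCor(x, y)$rho)
  expect_error(spearmanCor(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(spearmanCor(1:3, 1:4), "equal length")
})

test_that("partial correlation removes controls and matches the recursion", {
  x <- rnorm(100)
  expect_equal(partialCorrelation(x, 2 * x)$rho, spearmanCor(x, 2 * x)$rho)
  # y a pure linear function of the single control
  set.seed(41)
  z <- rnorm(200)
  x <- z + rnorm(200)
  y <- 3 * z + 1
  expect_lt(abs(partialCorrelation(x, y, z)$rho), 0.05)
  # 3-variable Gaussian sample against the closed-form recursion
  set.seed(43)
  n <- 500
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n, 0, 0.7)
  y <- 0.5 * z + 0.3 * x + rnorm(n, 0, 0.8)
  rho_xy <- spearmanCor(x, y)$rho
  rho_xz <- spearmanCor(x, z)$rho
  rho_yz <- spearmanCor(y, z)$rho
  oracle <- (rho_xy - rho_xz * rho_yz) /
    sqrt((1 - rho_xz^2) * (1 - rho_yz^2))
  expect_equal(partialCorrelation(x, y, z)$rho, oracle, tolerance = 0.05)
  # collinear controls are signalled
  expect_error(partialCorrelation(x, y, cbind(z, 2 * z)), "collinear")
})

test_that("regional aggregation does the unit arithmetic", {
  # one active grassland cohort, uniform NEP of 10 g C m-2 yr-1
  g <- tinyGrid(2, 2, 5)
  coh <- uniformCohort(nCells(g), 3, nep = 10)
  arch <- makeTestArchive(g, 1900:1902, coh)
  s <- aggregateRegion(arch)
  expected_tg <- 10 * sum(cellAreas(g)) * 1e-12
  expect_equal(nationalSeries(s)$nep, rep(expected_tg, 3), tolerance = 1e-12)
  # a region of 1e12 m2 with 10 g C m-2 yr-1 is 10 Tg C yr-1
  frac_needed <- 1e12 / sum(cellAreas(g))
  expect_equal(10 * 1e12 * 1e-12, 10)
  expect_equal(frac_needed * expected_tg / frac_needed, expected_tg)
  # per-area mean recovers the uniform flux
  expect_equal(unname(biomePerArea(s)["grassland", ]), rep(10, 3),
               tolerance = 1e-12)
  expect_error(aggregateRegion(arch, integer(0)), "empty region")
})

test_that("aggregation is linear and matches a brute-force double loop", {
  inp <- stationaryInputs(tinyGrid(2, 3, 10), years = 1900:1911)
  st <- spunState(inp, spin_years = 20)
  arch <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                       inp$params, experimentSpec("S1"))
  s <- aggregateRegion(arch)
  ann <- nationalSeries(s)
  # NEP = NPP - RH survives aggregation to 1e-9
  expect_equal(ann$nep, ann$npp - ann$rh, tolerance = 1e-9)
  # biome totals sum to the national total
  expect_equal(colSums(biomeTotals(s)), ann$nep, tolerance = 1e-9,
               ignore_attr = TRUE)
  # brute-force double-loop oracle over cells and cohorts
  coh <- cohortAnnual(arch, "nep")
  fr <- cohortAnnual(arch, "frac")
  rd <- SummarizedExperiment::rowData(arch)
  oracle <- numeric(12)
  for (yi in 1:12) {
    acc <- 0
    for (ic in seq_len(nrow(arch))) {
      for (it in seq_len(dim(coh)[2])) {
        acc <- acc + coh[ic, it, yi] * fr[ic, it, yi] *
          rd$area[ic] * rd$land_fraction[ic]
      }
    }
    oracle[yi] <- acc * 1e-12
  }
  expect_equal(ann$nep, oracle, tolerance = 1e-9)
  # masked aggregation restricts the region
  sm <- aggregateRegion(arch, mask = 1:2)
  expect_lt(sm@area_total, s@area_total)
})

test_that("strip anomalies center on the baseline and match brute force", {
  g <- tinyGrid(3, 4, 6)
  years <- 2001:2010
  set.seed(19)
  field <- matrix(rnorm(nCells(g) * 10), nCells(g), 10)
  # constant field: all anomalies zero
  a0 <- stripAnomalies(matrix(5, nCells(g), 10), g, "latitude", years)
  expect_true(all(abs(a0) < 1e-12))
  # centering: anomalies average zero over the full baseline
  a <- stripAnomalies(field, g, "latitude", years)
  expect_true(all(abs(rowMeans(a)) < 1e-9))
  # brute-force two-loop oracle
  cc <- cellCenters(g)
  w <- cellAreas(g)
  lats <- sort(unique(cc$lat))
  for (i in seq_along(lats)) {
    idx <- which(cc$lat == lats[i])
    series <- numeric(10)
    for (yi in 1:10)
      series[yi] <- sum(field[idx, yi] * w[idx]) / sum(w[idx])
    expect_equal(unname(a[i, ]), series - mean(series), tolerance = 1e-9)
  }
  a_lon <- stripAnomalies(field, g, "longitude", years)
  expect_equal(nrow(a_lon), 4)
  expect_error(stripAnomalies(field, g, "latitude", years,
                              baseline = c(1990, 2005)), "baseline")
})

test_that("source years are counted strictly below zero", {
  expect_equal(countSourceYears(c(1, 2, 3)), 0)
  expect_equal(countSourceYears(c(-1, 0, 2)), 1)
  set.seed(29)
  x <- rnorm(101)
  expect_equal(countSourceYears(x), sum(vapply(x, function(v) v < 0,
                                               logical(1))))
})

test_that("driver correlation tables cover both readings", {
  inp <- stationaryInputs(tinyGrid(2, 3, 10), years = 1900:1914,
                          seed = 3L)
  # add interannual variation so temporal correlations are defined
  inp$forcing <- generateClimate(inp$grid, climateScenario(), 3L, 1900:1914)
  inp$co2 <- generateCO2Series(296, 320, "linear", 1900:1914)
  st <- spunState(inp, spin_years = 20)
  arch <- runTransient(st, inp$forcing, inp$co2, inp$land, inp$props,
                       inp$params, experimentSpec("S1"))
  sp <- driverCorrelations(arch, inp$forcing, inp$co2, inp$land, inp$props,
                           mode = "spatial")
  expect_setequal(unique(sp$flux), c("nep", "npp", "rh"))
  expect_true(all(abs(sp$rho) <= 1, na.rm = TRUE))
  expect_true("clay" %in% sp$driver && !"co2" %in% sp$driver)
  tm <- driverCorrelations(arch, inp$forcing, inp$co2, inp$land, inp$props,
                           mode = "temporal")
  expect_true("co2" %in% tm$driver)
  expect_true(all(abs(tm$rho) <= 1, na.rm = TRUE))
  # precipitation limits productivity spatially in this dry-NW world
  expect_gt(sp$rho[sp$driver == "precip" & sp$flux == "npp"], 0)

  pm <- partialCorrelationMap(arch, inp$forcing, inp$co2, inp$land,
                              driver = "precip")
  expect_length(pm$rho, nCells(inp$grid))
  expect_true(all(abs(pm$rho) <= 1 + 1e-9, na.rm = TRUE))
  expect_type(pm$significant, "logical")
})
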