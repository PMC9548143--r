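# Shared fixtures: everything is generated in code at test time.

tinyGrid <- function(n_lat = 3, n_lon = 4, resolution = 8) {
  GridSpec(lat_min = 20, lon_min = 80, resolution = resolution,
           n_lat = n_lat, n_lon = n_lon)
}

# fully stationary driver bundle on a small grid
stationaryInputs <- function(grid = tinyGrid(), years = 1900:2000,
                             seed = 11L, co2_ppm = 310) {
  list(
    grid = grid,
    forcing = generateClimate(grid, stationaryScenario(), seed, years),
    co2 = generateCO2Series(co2_ppm, co2_ppm, "constant", years),
    land = generateLandCover(grid, staticLandUseScenario(years = years),
                             seed),
    props = generateSoil(grid, seed),
    params = defaultBiomeParams()
  )
}

# equilibrium + spin-up for a driver bundle
spunState <- function(inp, tol = 0.1, spin_years = 150) {
  clim <- monthlyClimatology(inp$forcing)
  eq <- runEquilibrium(clim, mean(co2ppm(inp$co2)),
                       coverFractions(inp$land, min(inp$forcing@years)),
                       inp$props, inp$params, inp$grid, tol = tol)
  runSpinup(eq, inp$forcing, co2ppm(inp$co2)[1], inp$props, inp$params,
            years = spin_years,
            block_years = min(50L, length(inp$forcing@years)))
}

# minimal hand-built archive for unit-testing the aggregation arithmetic
makeTestArchive <- function(grid, years, cohort, land_fraction = NULL,
                            monthly = NULL) {
  ncell <- nCells(grid)
  ny <- length(years)
  nm <- 12L * ny
  types <- dimnames(cohort$gpp)[[2]]
  if (is.null(monthly)) {
    monthly <- lapply(stats::setNames(nm = c("gpp", "ra", "npp", "rh", "nep",
                                             "conversion_flux", "t_soil20",
                                             "wfps")),
                      function(v) matrix(0, ncell, nm))
  }
  if (is.null(land_fraction)) land_fraction <- rep(1, ncell)
  cc <- cellCenters(grid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = monthly,
    rowData = S4Vectors::DataFrame(lat = cc$lat, lon = cc$lon,
                                   area = cellAreas(grid),
                                   land_fraction = land_fraction,
                                   hu_side = huLineSide(cc$lat, cc$lon)),
    colData = S4Vectors::DataFrame(year = rep(years, each = 12),
                                   month = rep(1:12, ny),
                                   time = seq_len(nm)),
    metadata = list(years = years,
                    manifest = list(experiment = "test", years = range(years)),
                    cohort = cohort, types = types))
  new("FluxArchive", se)
}

# cohort arrays with a single uniform flux value and one active type
uniformCohort <- function(ncell, ny, nep = 10, type = "grassland") {
  types <- coverTypes()
  zero <- array(0, dim = c(ncell, length(types), ny),
                dimnames = list(NULL, types, NULL))
  frac <- zero
  frac[, type, ] <- 1
  out <- list()
  for (v in c("gpp", "ra", "npp", "rh", "nep", "c_veg", "c_soil"))
    out[[v]] <- zero
  out$nep[, type, ] <- nep
  out$npp[, type, ] <- nep
  out$frac <- frac
  out
}
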