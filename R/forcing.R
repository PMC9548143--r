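#' @include grid.R
NULL

# stationary AR(1) series: marginal sd `sd`, lag-1 autocorrelation `rho`
.ar1 <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  }
  x
}

# northwest-ness of every cell in [0, 1]: 0 at the SE corner, 1 at the NW
# corner of the grid box. Drives the SE-wet/NW-dry climatology, the cover
# zonation and the soil gradient.
.nwIndex <- function(grid) {
  cc <- cellCenters(grid)
  lat_span <- grid@n_lat * grid@resolution
  lon_span <- grid@n_lon * grid@resolution
  s <- 0.5 * ((cc$lat - grid@lat_min) / lat_span +
              (grid@lon_min + lon_span - cc$lon) / lon_span)
  pmin(1, pmax(0, s))
}

# quadrant block index 1..4 used for spatially coherent interannual noise
.cellBlocks <- function(grid) {
  cc <- cellCenters(grid)
  lat_mid <- grid@lat_min + grid@n_lat * grid@resolution / 2
  lon_mid <- grid@lon_min + grid@n_lon * grid@resolution / 2
  1L + (cc$lat > lat_mid) + 2L * (cc$lon > lon_mid)
}

#' Climate scenario parameters
#'
#' Bundles the climatological structure, trend targets and noise levels of
#' the synthetic climate generator. The defaults emulate the historical
#' drivers over China: a latitude-graded mean climate with a seasonal cycle
#' whose amplitude grows northward; about 1 degree C of warming between the
#' 1900s and 1990s decadal means, concentrated after 1970 (0.30 C per
#' decade over 1971-2000); trendless, high-variability precipitation decaying
#' from a wet southeast to an arid northwest with summer concentration;
#' slightly declining cloudiness; spatially coherent AR(1) interannual
#' anomalies shared within quadrant blocks (lag-1 rho 0.3) so that decadal
#' wet/dry spells emerge; and a 1922-1932 drought event over northern and
#' eastern cells (precipitation times 0.6).
#'
#' @param t_base,t_lat_gradient Mean annual temperature intercept (degrees C)
#'   and its decrease per degree latitude.
#' @param seas_amp_base,seas_amp_gradient Seasonal (July-January semi-)
#'   amplitude at the southern edge and its growth per degree latitude.
#' @param warming_pre1970,warming_post1970 Warming (degrees C) accumulated
#'   linearly over 1900-1970 and over 1970-2000.
#' @param t_block_sd,t_month_sd SD of block-level annual AR(1) and monthly
#'   white temperature anomalies (degrees C).
#' @param p_max_annual,p_decay Annual precipitation (mm) at the SE corner and
#'   its exponential decay rate toward the NW corner.
#' @param p_summer_conc Strength of the summer concentration of rainfall.
#' @param p_block_sd,p_month_sd Log-scale SDs of the multiplicative annual
#'   AR(1) and monthly precipitation anomalies (mean-one lognormal).
#' @param cloud_se,cloud_nw Mean cloudiness fraction at the SE and NW corners.
#' @param cloud_trend Cloudiness change per century (negative = clearing).
#' @param cloud_block_sd SD of block annual cloudiness anomalies.
#' @param ar1 Lag-1 autocorrelation of all annual anomaly series.
#' @param drought_enabled,drought_years,drought_factor The default drought
#'   event: multiply precipitation by \code{drought_factor} over
#'   \code{drought_years} in the northern/eastern mask.
#' @return A \code{ClimateScenario} object.
#' @seealso [generateClimate()], [injectDrought()]
#' @export
climateScenario <- function(t_base = 38, t_lat_gradient = 0.75,
                            seas_amp_base = 6, seas_amp_gradient = 0.42,
                            warming_pre1970 = 0.3, warming_post1970 = 0.9,
                            t_block_sd = 0.3, t_month_sd = 0.8,
                            p_max_annual = 1600, p_decay = 2.2,
                            p_summer_conc = 0.9,
                            p_block_sd = 0.2, p_month_sd = 0.3,
                            cloud_se = 0.65, cloud_nw = 0.45,
                            cloud_trend = -0.04, cloud_block_sd = 0.02,
                            ar1 = 0.3,
                            drought_enabled = TRUE,
                            drought_years = c(1922L, 1932L),
                            drought_factor = 0.6) {
  new("ClimateScenario", t_base = t_base, t_lat_gradient = t_lat_gradient,
      seas_amp_base = seas_amp_base, seas_amp_gradient = seas_amp_gradient,
      warming_pre1970 = warming_pre1970, warming_post1970 = warming_post1970,
      t_block_sd = t_block_sd, t_month_sd = t_month_sd,
      p_max_annual = p_max_annual, p_decay = p_decay,
      p_summer_conc = p_summer_conc,
      p_block_sd = p_block_sd, p_month_sd = p_month_sd,
      cloud_se = cloud_se, cloud_nw = cloud_nw, cloud_trend = cloud_trend,
      cloud_block_sd = cloud_block_sd, ar1 = ar1,
      drought_enabled = drought_enabled,
      drought_years = as.integer(drought_years),
      drought_factor = drought_factor)
}

#' Noise-free, trend-free climate scenario
#'
#' All noise SDs, trends and the drought event switched off: the generated
#' forcing is the pure latitude/season climatology, useful for stationary
#' control runs and degenerate-case tests.
#'
#' @param ... Overrides passed on to [climateScenario()].
#' @return A \code{ClimateScenario}.
#' @export
stationaryScenario <- function(...) {
  climateScenario(warming_pre1970 = 0, warming_post1970 = 0,
                  t_block_sd = 0, t_month_sd = 0,
                  p_block_sd = 0, p_month_sd = 0,
                  cloud_trend = 0, cloud_block_sd = 0,
                  drought_enabled = FALSE, ...)
}

#' Generate synthetic gridded monthly climate forcing
#'
#' Builds monthly air temperature, precipitation and cloudiness on the given
#' grid for the given years. Temperature is a latitude-graded climatology
#' plus seasonal sinusoid, a piecewise-linear century warming signal, and
#' AR(1)/white noise shared within quadrant blocks. Precipitation is a
#' SE-maximum exponentially NW-decaying climatology with summer
#' concentration, perturbed by mean-one lognormal block anomalies (no
#' prescribed trend). Cloudiness declines slightly over the century. The
#' scenario's default drought event is injected at the end. Identical
#' \code{(grid, scenario, seed)} give bit-identical output.
#'
#' @param grid A [GridSpec()].
#' @param scenario A [climateScenario()].
#' @param seed Integer seed governing all noise.
#' @param years Integer years covered (default 1900:2000).
#' @return A \code{ClimateForcing} with cell-by-month matrices.
#' @export
generateClimate <- function(grid, scenario = climateScenario(), seed = 42L,
                            years = 1900:2000) {
  stopifnot(is(grid, "GridSpec"), is(scenario, "ClimateScenario"))
  years <- as.integer(years)
  if (length(years) == 0) stop("empty year range")
  ny <- length(years)
  nm <- 12L * ny
  ncell <- nCells(grid)
  cc <- cellCenters(grid)
  s <- .nwIndex(grid)
  block <- .cellBlocks(grid)
  sc <- scenario

  seas <- cos(2 * pi * (1:12 - 7) / 12)  # +1 in July, -1 in January

  # --- temperature ---------------------------------------------------------
  tmean <- sc@t_base - sc@t_lat_gradient * cc$lat
  amp <- sc@seas_amp_base + sc@seas_amp_gradient * (cc$lat - grid@lat_min)
  clim12 <- outer(tmean, rep(1, 12)) + outer(amp, seas)
  warm <- ifelse(years <= 1970,
                 sc@warming_pre1970 * (years - 1900) / 70,
                 sc@warming_pre1970 + sc@warming_post1970 * (years - 1970) / 30)

  # --- precipitation climatology ------------------------------------------
  pw <- 1 + sc@p_summer_conc * seas
  pw <- pw / sum(pw)
  pann <- sc@p_max_annual * exp(-sc@p_decay * s)
  pclim12 <- outer(pann, pw)

  # --- cloudiness climatology ---------------------------------------------
  cclim <- sc@cloud_se + (sc@cloud_nw - sc@cloud_se) * s
  ctrend <- sc@cloud_trend * (years - 1900) / 100

  # --- seeded noise, drawn in a fixed order --------------------------------
  noise <- withr::with_seed(as.integer(seed), {
    t_a <- matrix(0, ny, 4); p_a <- matrix(0, ny, 4); c_a <- matrix(0, ny, 4)
    for (b in 1:4) t_a[, b] <- .ar1(ny, sc@t_block_sd, sc@ar1)
    t_m <- matrix(stats::rnorm(nm * 4, 0, sc@t_month_sd), nm, 4)
    for (b in 1:4) p_a[, b] <- .ar1(ny, sc@p_block_sd, sc@ar1)
    p_m <- matrix(stats::rnorm(nm * 4, 0, sc@p_month_sd), nm, 4)
    for (b in 1:4) c_a[, b] <- .ar1(ny, sc@cloud_block_sd, sc@ar1)
    list(t_a = t_a, t_m = t_m, p_a = p_a, p_m = p_m, c_a = c_a)
  })

  yrep <- rep(seq_len(ny), each = 12)
  tair <- matrix(0, ncell, nm)
  precip <- matrix(0, ncell, nm)
  cloud <- matrix(0, ncell, nm)
  for (yi in seq_len(ny)) {
    cols <- (yi - 1L) * 12L + 1:12
    tair[, cols] <- clim12 + warm[yi]
    precip[, cols] <- pclim12
    cloud[, cols] <- cclim + ctrend[yi]
  }
  t_anom <- t(noise$t_a[yrep, , drop = FALSE] + noise$t_m)      # 4 x nm
  tair <- tair + t_anom[block, , drop = FALSE]
  # mean-one lognormal factors (exact identity when the SDs are zero)
  p_fac <- t(exp(noise$p_a[yrep, , drop = FALSE] - sc@p_block_sd^2 / 2) *
             exp(noise$p_m - sc@p_month_sd^2 / 2))
  precip <- precip * p_fac[block, , drop = FALSE]
  c_anom <- t(noise$c_a[yrep, , drop = FALSE])
  cloud <- cloud + c_anom[block, , drop = FALSE]
  cloud <- pmin(pmax(cloud, 0), 1)

  forcing <- new("ClimateForcing", grid = grid, years = years,
                 tair = tair, precip = precip, cloud = cloud)
  if (sc@drought_enabled &&
      any(years >= sc@drought_years[1] & years <= sc@drought_years[2])) {
    forcing <- injectDrought(forcing,
                             max(sc@drought_years[1], min(years)),
                             min(sc@drought_years[2], max(years)),
                             defaultDroughtMask(grid), sc@drought_factor)
  }
  forcing
}

#' Default northern/eastern drought mask
#'
#' Cells north of 33 N or east of 108 E: the region over which the default
#' 1922-1932 drought event scales precipitation down.
#'
#' @param grid A [GridSpec()].
#' @return Integer vector of cell indices.
#' @export
defaultDroughtMask <- function(grid) {
  cc <- cellCenters(grid)
  which(cc$lat >= 33 | cc$lon >= 108)
}

#' Inject a multiplicative drought event
#'
#' Multiplies precipitation by \code{precip_factor} in the masked cells for
#' all months of the years \code{year_start:year_end}; every other value is
#' left untouched, so dividing by the factor restores the original field
#' exactly.
#'
#' @param forcing A \code{ClimateForcing}.
#' @param year_start,year_end Inclusive event years within the forcing range.
#' @param region_mask Integer cell indices affected.
#' @param precip_factor Multiplier in [0, 1].
#' @return The modified \code{ClimateForcing}.
#' @export
injectDrought <- function(forcing, year_start, year_end, region_mask,
                          precip_factor) {
  stopifnot(is(forcing, "ClimateForcing"))
  if (length(region_mask) == 0) stop("empty drought mask")
  if (precip_factor < 0 || precip_factor > 1)
    stop("precip_factor must lie in [0, 1]")
  yrs <- forcing@years
  if (year_start < min(yrs) || year_end > max(yrs) || year_start > year_end)
    stop("drought years outside forcing range")
  yi <- which(yrs >= year_start & yrs <= year_end)
  cols <- as.vector(outer(1:12, (yi - 1L) * 12L, `+`))
  forcing@precip[region_mask, cols] <-
    forcing@precip[region_mask, cols] * precip_factor
  forcing
}

#' Generate an annual atmospheric CO2 trajectory
#'
#' Monotone series from \code{start_ppm} (first year) to \code{end_ppm}
#' (last year). The default accelerating "exponential" shape mimics the
#' observed historical rise 296 -> 369 ppm over 1900-2000, with late-century
#' increments much larger than early ones.
#'
#' @param start_ppm,end_ppm Endpoint mixing ratios (ppm), both positive.
#' @param shape One of \code{"exponential"}, \code{"linear"},
#'   \code{"constant"}.
#' @param years Integer years (default 1900:2000).
#' @param k Curvature of the exponential shape.
#' @return A \code{CO2Series}.
#' @export
generateCO2Series <- function(start_ppm = 296, end_ppm = 369,
                              shape = c("exponential", "linear", "constant"),
                              years = 1900:2000, k = 2) {
  shape <- match.arg(shape)
  if (start_ppm <= 0 || end_ppm <= 0) stop("ppm must be positive")
  years <- as.integer(years)
  n <- length(years)
  f <- if (n == 1) 0 else (years - years[1]) / (years[n] - years[1])
  ppm <- switch(shape,
    constant = rep(start_ppm, n),
    linear = start_ppm + (end_ppm - start_ppm) * f,
    exponential = start_ppm + (end_ppm - start_ppm) *
      (exp(k * f) - 1) / (exp(k) - 1)
  )
  new("CO2Series", years = years, ppm = ppm)
}

#' @rdname CO2Series
#' @param x A \code{CO2Series}.
#' @export
setMethod("co2ppm", "CO2Series", function(x) {
  stats::setNames(x@ppm, x@years)
})

#' Proportional allocation of non-cropland area
#'
#' Distributes the non-crop remainder of a cell across cover types in
#' proportion to reference ratios (the remainder-allocation rule used to
#' reconcile a prescribed cropland fraction with a reference cover map).
#' When every ratio is zero the whole remainder goes to bare ground.
#'
#' @param remaining Non-crop area fraction in [0, 1].
#' @param reference_ratios Named non-negative numeric vector of reference
#'   shares (need not sum to 1); may include or omit \code{"bare"}.
#' @return Named fractions summing to \code{remaining}.
#' @examples
#' allocateNoncrop(0.8, c(forest = 3, grassland = 1))
#' @export
allocateNoncrop <- function(remaining, reference_ratios) {
  if (remaining < 0 || remaining > 1) stop("remaining must lie in [0, 1]")
  if (any(reference_ratios < 0)) stop("reference ratios must be non-negative")
  tot <- sum(reference_ratios)
  if (tot == 0) {
    out <- reference_ratios * 0
    out["bare"] <- remaining
    return(out)
  }
  reference_ratios / tot * remaining
}

#' Land-use scenario
#'
#' National cropland-fraction trajectory plus the rules mapping it to cells.
#' The default trajectory rises from 0.07 in 1900 to 0.13 in 1980 and then
#' declines slightly to 0.115 by 2000, echoing the historical cropland
#' expansion and the late-century contraction. Cropland is laid down
#' preferentially in the southeast (suitability \code{(1-s)^e} with \code{s}
#' the northwest-ness index), capped per cell; the non-crop remainder is
#' allocated across natural types by [allocateNoncrop()] using a fixed
#' per-cell reference map (forest in the SE grading to grassland and bare
#' ground in the NW).
#'
#' @param years Integer years.
#' @param crop_target National area-weighted cropland fraction per year;
#'   the default is the piecewise-linear 0.07 -> 0.13 -> 0.115 trajectory.
#' @param suitability_exponent Southeast-preference strength.
#' @param crop_max Per-cell cropland cap.
#' @param static If \code{TRUE} the 1900 map is used for every year.
#' @return A \code{LandUseScenario}.
#' @export
landUseScenario <- function(years = 1900:2000, crop_target = NULL,
                            suitability_exponent = 1.5, crop_max = 0.7,
                            static = FALSE) {
  years <- as.integer(years)
  if (is.null(crop_target)) {
    crop_target <- ifelse(years <= 1980,
                          0.07 + (0.13 - 0.07) * (years - 1900) / 80,
                          0.13 + (0.115 - 0.13) * (years - 1980) / 20)
  }
  new("LandUseScenario", crop_target = crop_target, years = years,
      suitability_exponent = suitability_exponent, crop_max = crop_max,
      static = static)
}

#' Static land-use scenario at a constant national cropland fraction
#'
#' @param level Constant national cropland fraction.
#' @param years Integer years.
#' @param ... Passed to [landUseScenario()].
#' @return A \code{LandUseScenario} with \code{static = TRUE}.
#' @export
staticLandUseScenario <- function(level = 0.07, years = 1900:2000, ...) {
  landUseScenario(years = years, crop_target = rep(level, length(years)),
                  static = TRUE, ...)
}

# fixed reference weights of the natural cover types per cell
.naturalWeights <- function(s) {
  cbind(
    forest = (1 - s)^2.5,
    shrubland = 0.3 * s * (1 - s) + 0.03,
    grassland = s * (1.3 - s),
    wetland = 0.06 * (1 - s) + 0.01,
    bare = 3 * pmax(0, s - 0.45)^2
  )
}

#' Generate per-cell, per-year land-cover fractions
#'
#' Builds the six-type cover map for every year from the scenario's national
#' cropland trajectory: cell cropland is the national target scaled by a
#' (seeded, weakly noisy) SE-preference suitability and capped, and the
#' remainder is split across the natural types in proportion to the cell's
#' fixed reference weights. Fractions close to 1 per cell-year by
#' construction.
#'
#' @param grid A [GridSpec()].
#' @param scenario A [landUseScenario()].
#' @param seed Integer seed for the suitability noise.
#' @return A \code{LandCoverGrid}.
#' @export
generateLandCover <- function(grid, scenario = landUseScenario(),
                              seed = 42L) {
  stopifnot(is(grid, "GridSpec"), is(scenario, "LandUseScenario"))
  years <- scenario@years
  ny <- length(years)
  ncell <- nCells(grid)
  types <- coverTypes()
  s <- .nwIndex(grid)
  areas <- cellAreas(grid)

  suit <- (1 - s)^scenario@suitability_exponent
  suit <- suit * withr::with_seed(as.integer(seed),
                                  exp(stats::rnorm(ncell, 0, 0.1)))
  suit_mean <- sum(suit * areas) / sum(areas)
  wnat <- .naturalWeights(s)

  frac <- array(0, dim = c(ncell, length(types), ny),
                dimnames = list(NULL, types, years))
  for (yi in seq_len(ny)) {
    target <- scenario@crop_target[if (scenario@static) 1L else yi]
    crop <- pmin(scenario@crop_max, target * suit / suit_mean)
    rest <- 1 - crop
    wsum <- rowSums(wnat)
    for (tname in colnames(wnat)) {
      frac[, tname, yi] <- wnat[, tname] / wsum * rest
    }
    frac[, "cropland", yi] <- crop
  }
  new("LandCoverGrid", grid = grid, years = years, types = types,
      frac = frac, land_fraction = rep(1, ncell))
}

#' @rdname LandCoverGrid
#' @param x A \code{LandCoverGrid}.
#' @param year Calendar year to extract.
#' @export
setMethod("coverFractions", "LandCoverGrid", function(x, year) {
  yi <- match(year, x@years)
  if (is.na(yi)) stop("year outside land-cover range")
  x@frac[, , yi, drop = TRUE]
})

#' Generate soil texture, elevation and bucket capacity
#'
#' Texture follows the NW-ness gradient (sandier toward the arid northwest,
#' clay-richer in the southeast) with small seeded noise; elevation rises
#' toward the western margin. The bucket water capacity is the texture
#' pedotransfer stand-in \code{150 * (1 - clay) + 50} mm: coarse soils
#' drain, clay caps storage.
#'
#' @param grid A [GridSpec()].
#' @param seed Integer seed.
#' @return A \code{SoilProperties}.
#' @export
generateSoil <- function(grid, seed = 42L) {
  ncell <- nCells(grid)
  s <- .nwIndex(grid)
  cc <- cellCenters(grid)
  noise <- withr::with_seed(as.integer(seed) + 1L,
                            matrix(stats::rnorm(ncell * 2, 0, 0.02), ncell, 2))
  clay <- pmin(0.6, pmax(0.05, 0.12 + 0.18 * (1 - s) + noise[, 1]))
  sand <- pmin(0.9 - clay, pmax(0.05, 0.25 + 0.35 * s + noise[, 2]))
  silt <- 1 - clay - sand
  lon_span <- grid@n_lon * grid@resolution
  elev <- 200 + 4500 * pmax(0, (grid@lon_min + lon_span - cc$lon) /
                                lon_span - 0.4)^1.5
  new("SoilProperties", grid = grid, sand = sand, silt = silt, clay = clay,
      elevation = elev, water_capacity = 150 * (1 - clay) + 50)
}

#' @rdname SoilProperties
#' @param x A \code{SoilProperties}.
#' @export
setMethod("waterCapacity", "SoilProperties", function(x) x@water_capacity)

#' @rdname ClimateForcing
#' @param x A \code{ClimateForcing}.
#' @export
setMethod("forcingYears", "ClimateForcing", function(x) x@years)

setMethod("show", "ClimateForcing", function(object) {
  cat(sprintf("ClimateForcing: %d cells x %d months (%d-%d)\n",
              nrow(object@tair), ncol(object@tair),
              min(object@years), max(object@years)))
})

#' National area-weighted annual mean of a forcing variable
#'
#' @param forcing A \code{ClimateForcing}.
#' @param var One of \code{"tair"}, \code{"precip"}, \code{"cloud"}.
#'   Precipitation is summed over months (mm yr-1), the others averaged.
#' @return Named numeric vector, one value per year.
#' @export
nationalAnnualMean <- function(forcing, var = c("tair", "precip", "cloud")) {
  var <- match.arg(var)
  m <- slot(forcing, var)
  w <- cellAreas(forcing@grid)
  w <- w / sum(w)
  natm <- colSums(m * w)  # monthly national means
  ny <- length(forcing@years)
  g <- rep(seq_len(ny), each = 12)
  out <- if (var == "precip") tapply(natm, g, sum) else tapply(natm, g, mean)
  stats::setNames(as.numeric(out), forcing@years)
}
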