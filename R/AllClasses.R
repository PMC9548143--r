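#' @import methods
#' @importFrom S4Vectors metadata SimpleList
#' @import SummarizedExperiment
NULL

#' Land-cover types tracked by the model
#'
#' The six cover classes carried per grid cell: five vegetated biomes and a
#' bare/sparsely-vegetated remainder that keeps cover fractions closed to 1.
#'
#' @return Character vector of the six cover-type names, in canonical order.
#' @examples
#' coverTypes()
#' @export
coverTypes <- function() {
  c("forest", "shrubland", "grassland", "wetland", "cropland", "bare")
}

# ---------------------------------------------------------------------------
# GridSpec
# ---------------------------------------------------------------------------

#' @rdname GridSpec
#' @export
setClass("GridSpec",
  representation(
    lat_min = "numeric", lon_min = "numeric",
    resolution = "numeric", n_lat = "integer", n_lon = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@resolution) != 1 || !is.finite(object@resolution) ||
      object@resolution <= 0) {
    msg <- c(msg, "resolution must be a single positive number")
  }
  if (object@n_lat < 1L || object@n_lon < 1L) {
    msg <- c(msg, "grid must contain at least one cell")
  }
  if (length(msg)) msg else TRUE
})

#' Regular latitude-longitude grid specification
#'
#' Defines a regular grid by its south-west corner, cell size and cell
#' counts. Cell centers sit at \code{bound + (i + 0.5) * resolution}. The
#' default is a China bounding box (18-54 N, 73-135 E) at 2 degrees, coarse
#' enough that a century simulation runs in seconds; pass
#' \code{resolution = 0.5} with \code{n_lat = 72, n_lon = 124} for the fine
#' grid.
#'
#' @param lat_min,lon_min South and west bounds in degrees.
#' @param resolution Cell size in degrees (same in both axes).
#' @param n_lat,n_lon Number of rows (latitude) and columns (longitude).
#' @return A \code{GridSpec} object.
#' @examples
#' g <- GridSpec()
#' nCells(g)
#' @export
GridSpec <- function(lat_min = 18, lon_min = 73, resolution = 2,
                     n_lat = NULL, n_lon = NULL) {
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be a single positive number")
  if (is.null(n_lat)) n_lat <- as.integer(round((54 - lat_min) / resolution))
  if (is.null(n_lon)) n_lon <- as.integer(round((135 - lon_min) / resolution))
  new("GridSpec", lat_min = lat_min, lon_min = lon_min,
      resolution = resolution,
      n_lat = as.integer(n_lat), n_lon = as.integer(n_lon))
}

# ---------------------------------------------------------------------------
# Forcing containers
# ---------------------------------------------------------------------------

#' @rdname ClimateForcing
#' @export
setClass("ClimateForcing",
  representation(
    grid = "GridSpec", years = "integer",
    tair = "matrix", precip = "matrix", cloud = "matrix"
  )
)

setValidity("ClimateForcing", function(object) {
  msg <- character()
  nm <- 12L * length(object@years)
  nc <- object@grid@n_lat * object@grid@n_lon
  for (s in c("tair", "precip", "cloud")) {
    m <- slot(object, s)
    if (!identical(dim(m), c(nc, nm)))
      msg <- c(msg, sprintf("%s must be a %d x %d matrix", s, nc, nm))
    if (anyNA(m)) msg <- c(msg, sprintf("%s contains missing values", s))
  }
  if (length(msg) == 0) {
    if (any(object@precip < 0)) msg <- c(msg, "precip must be non-negative")
    if (any(object@cloud < 0 | object@cloud > 1))
      msg <- c(msg, "cloud must lie in [0, 1]")
  }
  if (length(object@years) == 0) msg <- c(msg, "empty year range")
  if (length(msg)) msg else TRUE
})

#' @rdname CO2Series
#' @export
setClass("CO2Series",
  representation(years = "integer", ppm = "numeric")
)

setValidity("CO2Series", function(object) {
  msg <- character()
  if (length(object@years) != length(object@ppm))
    msg <- c(msg, "years and ppm must have equal length")
  if (any(object@ppm <= 0)) msg <- c(msg, "ppm must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname LandCoverGrid
#' @export
setClass("LandCoverGrid",
  representation(
    grid = "GridSpec", years = "integer", types = "character",
    frac = "array", land_fraction = "numeric"
  )
)

setValidity("LandCoverGrid", function(object) {
  msg <- character()
  nc <- object@grid@n_lat * object@grid@n_lon
  d <- dim(object@frac)
  if (length(d) != 3 || d[1] != nc || d[2] != length(object@types) ||
      d[3] != length(object@years)) {
    msg <- c(msg, "frac must be a cell x type x year array")
  } else {
    if (any(object@frac < -1e-12 | object@frac > 1 + 1e-12))
      msg <- c(msg, "cover fractions must lie in [0, 1]")
    tot <- apply(object@frac, c(1, 3), sum)
    if (any(abs(tot - 1) > 1e-9))
      msg <- c(msg, "cover fractions must sum to 1 per cell-year")
  }
  if (any(object@land_fraction < 0 | object@land_fraction > 1))
    msg <- c(msg, "land_fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SoilProperties
#' @export
setClass("SoilProperties",
  representation(
    grid = "GridSpec", sand = "numeric", silt = "numeric", clay = "numeric",
    elevation = "numeric", water_capacity = "numeric"
  )
)

setValidity("SoilProperties", function(object) {
  msg <- character()
  tot <- object@sand + object@silt + object@clay
  if (any(abs(tot - 1) > 1e-9))
    msg <- c(msg, "sand + silt + clay must equal 1")
  if (any(object@water_capacity <= 0))
    msg <- c(msg, "water_capacity must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Scenarios
# ---------------------------------------------------------------------------

#' @rdname climateScenario
#' @export
setClass("ClimateScenario",
  representation(
    t_base = "numeric", t_lat_gradient = "numeric",
    seas_amp_base = "numeric", seas_amp_gradient = "numeric",
    warming_pre1970 = "numeric", warming_post1970 = "numeric",
    t_block_sd = "numeric", t_month_sd = "numeric",
    p_max_annual = "numeric", p_decay = "numeric", p_summer_conc = "numeric",
    p_block_sd = "numeric", p_month_sd = "numeric",
    cloud_se = "numeric", cloud_nw = "numeric", cloud_trend = "numeric",
    cloud_block_sd = "numeric",
    ar1 = "numeric",
    drought_enabled = "logical", drought_years = "integer",
    drought_factor = "numeric"
  )
)

setValidity("ClimateScenario", function(object) {
  msg <- character()
  if (object@ar1 < 0 || object@ar1 >= 1)
    msg <- c(msg, "ar1 must lie in [0, 1)")
  if (object@drought_factor < 0 || object@drought_factor >= 1)
    msg <- c(msg, "drought_factor must lie in [0, 1)")
  sds <- c(object@t_block_sd, object@t_month_sd, object@p_block_sd,
           object@p_month_sd, object@cloud_block_sd)
  if (any(sds < 0)) msg <- c(msg, "noise SDs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname landUseScenario
#' @export
setClass("LandUseScenario",
  representation(
    crop_target = "numeric",   # national cropland fraction per year
    years = "integer",
    suitability_exponent = "numeric",
    crop_max = "numeric",
    static = "logical"
  )
)

setValidity("LandUseScenario", function(object) {
  msg <- character()
  if (length(object@crop_target) != length(object@years))
    msg <- c(msg, "crop_target must have one value per year")
  if (any(object@crop_target < 0 | object@crop_target > 1))
    msg <- c(msg, "cropland trajectory must lie in [0, 1]")
  if (object@crop_max <= 0 || object@crop_max > 1)
    msg <- c(msg, "crop_max must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Model state and experiment design
# ---------------------------------------------------------------------------

#' @rdname CellState
#' @export
setClass("CellState",
  representation(
    types = "character",
    c_veg = "matrix", c_soil = "matrix",   # cell x type, g C m-2 of cohort
    t_soil = "numeric", water = "numeric", # per cell
    frac = "matrix",                       # cell x type cover fractions
    converged = "logical", iterations = "integer"
  )
)

setValidity("CellState", function(object) {
  msg <- character()
  if (any(object@c_veg < 0) || any(object@c_soil < 0))
    msg <- c(msg, "carbon pools must be non-negative")
  if (!identical(dim(object@c_veg), dim(object@c_soil)))
    msg <- c(msg, "pool matrices must share dimensions")
  if (length(msg)) msg else TRUE
})

#' @rdname experimentSpec
#' @export
setClass("ExperimentSpec",
  representation(
    name = "character",
    co2_mode = "character", climate_mode = "character", luc_mode = "character"
  )
)

setValidity("ExperimentSpec", function(object) {
  msg <- character()
  if (!object@co2_mode %in% c("transient", "fixed_1900"))
    msg <- c(msg, "unknown co2_mode")
  if (!object@climate_mode %in% c("transient", "fixed_1900_1919_climatology"))
    msg <- c(msg, "unknown climate_mode")
  if (!object@luc_mode %in% c("transient", "fixed_1900"))
    msg <- c(msg, "unknown luc_mode")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Results
# ---------------------------------------------------------------------------

#' @rdname FluxArchive
#' @export
setClass("FluxArchive", contains = "SummarizedExperiment")

.archive_assays <- c("gpp", "ra", "npp", "rh", "nep", "conversion_flux",
                     "t_soil20", "wfps")

setValidity("FluxArchive", function(object) {
  msg <- character()
  missing <- setdiff(.archive_assays, SummarizedExperiment::assayNames(object))
  if (length(missing))
    msg <- c(msg, paste("missing assays:", paste(missing, collapse = ", ")))
  md <- S4Vectors::metadata(object)
  yrs <- md$years
  if (is.null(yrs) || ncol(object) != 12L * length(yrs))
    msg <- c(msg, "time axis must cover 12 months of every year")
  if (length(msg)) msg else TRUE
})

#' @rdname aggregateRegion
#' @export
setClass("RegionalSummary",
  representation(
    years = "integer",
    annual = "data.frame",        # year, nep, npp, rh, gpp (Tg C yr-1), soil_pool_pg
    biome_total_nep = "matrix",   # type x year, Tg C yr-1
    biome_per_area_nep = "matrix",# type x year, g C m-2 yr-1
    biome_area = "matrix",        # type x year, m2
    area_total = "numeric"
  )
)

#' @rdname attributionEffects
#' @export
setClass("AttributionResult",
  representation(
    decades = "character",
    effect_co2 = "numeric", effect_climate = "numeric",
    effect_luc = "numeric", interaction_residual = "numeric"
  )
)

setValidity("AttributionResult", function(object) {
  if (length(object@effect_co2) != length(object@decades) ||
      length(object@effect_climate) != length(object@decades) ||
      length(object@effect_luc) != length(object@decades))
    return("one effect value per decade is required")
  TRUE
})
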