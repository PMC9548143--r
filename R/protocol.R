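#' @include engine.R
NULL

#' Factorial experiment specifications
#'
#' The four-member factorial design: S1 runs every driver transient; S2
#' holds CO2 at its 1900 value; S3 replays the 1900-1919 mean monthly
#' climatology every year; S4 freezes land cover at its 1900 map. Subtracting
#' each single-driver-suppressed run from S1 isolates that driver's effect.
#'
#' @param name One of \code{"S1"}..\code{"S4"}, or \code{"custom"} with
#'   explicit modes.
#' @param co2_mode \code{"transient"} or \code{"fixed_1900"}.
#' @param climate_mode \code{"transient"} or
#'   \code{"fixed_1900_1919_climatology"}.
#' @param luc_mode \code{"transient"} or \code{"fixed_1900"}.
#' @return An \code{ExperimentSpec}.
#' @examples
#' experimentSpec("S2")
#' @export
experimentSpec <- function(name = c("S1", "S2", "S3", "S4", "custom"),
                           co2_mode = "transient",
                           climate_mode = "transient",
                           luc_mode = "transient") {
  name <- match.arg(name)
  modes <- switch(name,
    S1 = c("transient", "transient", "transient"),
    S2 = c("fixed_1900", "transient", "transient"),
    S3 = c("transient", "fixed_1900_1919_climatology", "transient"),
    S4 = c("transient", "transient", "fixed_1900"),
    custom = c(co2_mode, climate_mode, luc_mode)
  )
  new("ExperimentSpec", name = name, co2_mode = modes[1],
      climate_mode = modes[2], luc_mode = modes[3])
}

setMethod("show", "ExperimentSpec", function(object) {
  cat(sprintf("ExperimentSpec %s: co2=%s, climate=%s, landuse=%s\n",
              object@name, object@co2_mode, object@climate_mode,
              object@luc_mode))
})

# fresh pre-equilibrium state
.initState <- function(grid, frac, props, climatology) {
  ncell <- nCells(grid)
  ntype <- ncol(frac)
  list(c_veg = matrix(10, ncell, ntype),
       c_soil = matrix(100, ncell, ntype),
       t_soil = rowMeans(climatology$tair),
       water = props@water_capacity / 2,
       frac = frac)
}

#' Run cells to carbon equilibrium
#'
#' Iterates the mean annual climate cycle at a reference CO2 until the
#' annual cell-mean NEP stays below \code{tol} for five consecutive years
#' (per cell), or \code{max_iter} years are reached, in which case the cell
#' is flagged non-converged (never silently). During the early iterations
#' the slow soil pool is nudged analytically toward its litter/decomposition
#' balance to cut the spin cost; the final approach is always pure
#' relaxation, so a converged state is a genuine fixed point of the annual
#' cycle.
#'
#' @param climatology Mean annual cycle from [monthlyClimatology()].
#' @param co2_ref Reference CO2 (ppm); the protocol uses the 1900-2000 mean.
#' @param frac Cell-by-type cover fractions (the undisturbed/1900 map).
#' @param props A \code{SoilProperties}.
#' @param params Biome parameter table.
#' @param grid The \code{GridSpec} (for latitudes).
#' @param tol Convergence tolerance on |annual NEP|, g C m-2 yr-1.
#' @param max_iter Maximum years to iterate.
#' @param alpha Soil-temperature relaxation fraction.
#' @return A \code{CellState} with convergence flags.
#' @export
runEquilibrium <- function(climatology, co2_ref, frac, props, params, grid,
                           tol = 0.1, max_iter = 3000, alpha = 0.6) {
  stopifnot(tol > 0)
  validateBiomeParams(params)
  lat <- cellCenters(grid)$lat
  hi <- heatIndex(climatology$tair)
  state <- .initState(grid, frac, props, climatology)
  ncell <- nrow(frac)
  ok_years <- integer(ncell)
  converged_at <- rep(NA_integer_, ncell)
  iter <- 0L
  accel_until <- 1000L
  while (iter < max_iter) {
    iter <- iter + 1L
    sim <- .simulateMonths(state, climatology$tair, climatology$precip,
                           climatology$cloud, co2_ref, NULL, props, params,
                           lat, hi, alpha = alpha, record = TRUE)
    state <- sim$state
    nep_ann <- rowSums(sim$monthly$nep)
    ok_years <- ifelse(abs(nep_ann) < tol, ok_years + 1L, 0L)
    converged_at[is.na(converged_at) & ok_years >= 5L] <- iter
    if (all(ok_years >= 5L)) break
    if (iter <= accel_until && iter %% 25L == 0L) {
      l_f <- params[colnames(frac), "l_f"] # month-1, per type
      # soil pool: RH is linear in c_soil, so the litter/RH ratio is the
      # exact multiplicative step toward litter-decomposition balance
      litterA <- sweep(sim$state$c_veg, 2, 12 * l_f, `*`)
      rhA <- sim$cohort$rh[, , 1]
      fac_s <- ifelse(rhA > 1e-9, litterA / rhA,
                      ifelse(litterA > 1e-9, 3, 1))  # near-zero decomposition
      fac_s <- pmin(pmax(fac_s, 0.5), 3)
      # vegetation pool: damped step toward the NPP/litterfall balance
      nppA <- sim$cohort$npp[, , 1]
      fac_v <- ifelse(sim$state$c_veg > 1e-9 & nppA > 0,
                      nppA / litterA, 1)
      fac_v <- pmin(pmax(fac_v, 0.7), 1.5)
      live <- ok_years < 5L   # leave converged cells untouched
      moved <- live & (abs(fac_s - 1) > 0.02 | abs(fac_v - 1) > 0.02)
      state$c_soil[moved] <- state$c_soil[moved] * fac_s[moved]
      state$c_veg[moved] <- state$c_veg[moved] * fac_v[moved]
      touched <- rowSums(moved) > 0
      ok_years[touched] <- 0L
    }
  }
  tn <- list(NULL, colnames(frac))
  new("CellState", types = colnames(frac),
      c_veg = structure(state$c_veg, dimnames = tn),
      c_soil = structure(state$c_soil, dimnames = tn),
      t_soil = state$t_soil, water = state$water,
      frac = structure(state$frac, dimnames = tn),
      converged = !is.na(converged_at), iterations = iter)
}

setMethod("show", "CellState", function(object) {
  cat(sprintf(
    "CellState: %d cells x %d cohorts; mean Cv %.0f, Cs %.0f g C m-2; %d/%d converged (%d yr)\n",
    nrow(object@c_veg), ncol(object@c_veg),
    mean(object@c_veg), mean(object@c_soil),
    sum(object@converged), length(object@converged),
    object@iterations))
})

# CellState list view used by the integrator
.stateAsList <- function(state) {
  list(c_veg = state@c_veg, c_soil = state@c_soil, t_soil = state@t_soil,
       water = state@water, frac = state@frac)
}

#' Spin up the model over a recycled climate block
#'
#' Replays the first \code{block_years} years of the forcing cyclically for
#' \code{years} years (default 150 = three passes over 1900-1949), with CO2
#' and land cover held at their 1900 values, so that interannual variability
#' is imprinted on the initial state before the transient run.
#'
#' @param state A \code{CellState} from [runEquilibrium()].
#' @param forcing Transient \code{ClimateForcing} whose first
#'   \code{block_years} years form the spin block.
#' @param co2_1900 CO2 (ppm) held fixed during the spin-up.
#' @param props,params Soil properties and biome parameters.
#' @param years Spin-up length in years; 0 is a no-op.
#' @param block_years Length of the recycled climate block.
#' @param alpha Soil-temperature relaxation fraction.
#' @return The updated \code{CellState}.
#' @export
runSpinup <- function(state, forcing, co2_1900, props, params,
                      years = 150, block_years = 50, alpha = 0.6) {
  if (years == 0) return(state)
  if (length(forcing@years) < block_years)
    stop("forcing shorter than the spin-up block")
  grid <- forcing@grid
  lat <- cellCenters(grid)$lat
  clim <- monthlyClimatology(forcing,
                             forcing@years[seq_len(block_years)])
  hi <- heatIndex(clim$tair)
  cols <- (seq_len(years * 12L) - 1L) %% (block_years * 12L) + 1L
  sim <- .simulateMonths(.stateAsList(state),
                         forcing@tair[, cols, drop = FALSE],
                         forcing@precip[, cols, drop = FALSE],
                         forcing@cloud[, cols, drop = FALSE],
                         rep(co2_1900, years), NULL, props, params,
                         lat, hi, alpha = alpha, record = FALSE)
  tn <- list(NULL, state@types)
  new("CellState", types = state@types,
      c_veg = structure(sim$state$c_veg, dimnames = tn),
      c_soil = structure(sim$state$c_soil, dimnames = tn),
      t_soil = sim$state$t_soil, water = sim$state$water,
      frac = structure(sim$state$frac, dimnames = tn),
      converged = state@converged, iterations = state@iterations)
}

#' Run the transient 1900-2000 simulation for one experiment
#'
#' Integrates the spun-up state over the transient drivers, honoring the
#' experiment's modes: fixed CO2 uses the first-year value throughout; fixed
#' climate replays the 1900-1919 mean monthly cycle every year; fixed land
#' use keeps the state's cover fractions. Returns the complete monthly flux
#' archive.
#'
#' @param state Spun-up \code{CellState}.
#' @param forcing \code{ClimateForcing} covering the run years.
#' @param co2 \code{CO2Series} covering the run years.
#' @param land \code{LandCoverGrid} covering the run years.
#' @param props,params Soil properties and biome parameters.
#' @param spec An [experimentSpec()].
#' @param burn_fraction Share of cleared vegetation carbon burnt.
#' @param alpha Soil-temperature relaxation fraction.
#' @param manifest Optional named list merged into the archive manifest.
#' @return A \code{FluxArchive}.
#' @export
runTransient <- function(state, forcing, co2, land, props, params,
                         spec = experimentSpec("S1"), burn_fraction = 0.5,
                         alpha = 0.6, manifest = list()) {
  grid <- forcing@grid
  years <- forcing@years
  ny <- length(years)
  lat <- cellCenters(grid)$lat

  co2_by_year <- co2@ppm[match(years, co2@years)]
  if (anyNA(co2_by_year)) stop("CO2 series does not cover the run years")
  if (spec@co2_mode == "fixed_1900") co2_by_year <- rep(co2_by_year[1], ny)

  tair <- forcing@tair; precip <- forcing@precip; cloud <- forcing@cloud
  if (spec@climate_mode == "fixed_1900_1919_climatology") {
    ref_years <- 1900:1919
    if (!all(ref_years %in% years))
      stop("experiment requires climate data for 1900-1919")
    clim <- monthlyClimatology(forcing, ref_years)
    idx <- rep(1:12, ny)
    tair <- clim$tair[, idx, drop = FALSE]
    precip <- clim$precip[, idx, drop = FALSE]
    cloud <- clim$cloud[, idx, drop = FALSE]
  }

  frac_by_year <- NULL
  if (spec@luc_mode == "transient") {
    yi <- match(years, land@years)
    if (anyNA(yi)) stop("land cover does not cover the run years")
    frac_by_year <- land@frac[, , yi, drop = FALSE]
  }

  hi <- heatIndex(monthlyClimatology(forcing)$tair)
  sim <- .simulateMonths(.stateAsList(state), tair, precip, cloud,
                         co2_by_year, frac_by_year, props, params, lat, hi,
                         alpha = alpha, burn_fraction = burn_fraction,
                         record = TRUE)

  .makeArchive(sim, grid, years, land, spec,
               c(manifest, list(convergence_flagged =
                                  sum(!state@converged))))
}

# assemble the SummarizedExperiment-backed archive
.makeArchive <- function(sim, grid, years, land, spec, manifest) {
  cc <- cellCenters(grid)
  rd <- S4Vectors::DataFrame(lat = cc$lat, lon = cc$lon,
                             area = cellAreas(grid),
                             land_fraction = land@land_fraction,
                             hu_side = huLineSide(cc$lat, cc$lon))
  cd <- S4Vectors::DataFrame(year = rep(years, each = 12),
                             month = rep(1:12, length(years)),
                             time = seq_len(12 * length(years)))
  man <- c(list(experiment = spec@name, co2_mode = spec@co2_mode,
                climate_mode = spec@climate_mode, luc_mode = spec@luc_mode,
                grid = list(lat_min = grid@lat_min, lon_min = grid@lon_min,
                            resolution = grid@resolution,
                            n_lat = grid@n_lat, n_lon = grid@n_lon),
                years = range(years),
                units = list(flux = "g C m-2 month-1", t_soil20 = "degC",
                             wfps = "percent"),
                version = as.character(utils::packageVersion("ChinaCarbon"))),
           manifest)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = sim$monthly, rowData = rd, colData = cd,
    metadata = list(years = years, manifest = man, cohort = sim$cohort,
                    types = dimnames(sim$cohort$gpp)[[2]]))
  new("FluxArchive", se)
}

#' @rdname FluxArchive
#' @param x A \code{FluxArchive}.
#' @export
setMethod("archiveYears", "FluxArchive", function(x) {
  S4Vectors::metadata(x)$years
})

#' @rdname FluxArchive
#' @export
setMethod("archiveManifest", "FluxArchive", function(x) {
  S4Vectors::metadata(x)$manifest
})

#' Per-cohort annual fluxes and pools
#'
#' @rdname FluxArchive
#' @param var One of \code{"gpp"}, \code{"ra"}, \code{"npp"}, \code{"rh"},
#'   \code{"nep"}, \code{"c_veg"}, \code{"c_soil"}, \code{"frac"}.
#' @export
setMethod("cohortAnnual", "FluxArchive", function(x, var) {
  coh <- S4Vectors::metadata(x)$cohort
  if (!var %in% names(coh)) stop("unknown cohort variable: ", var)
  coh[[var]]
})

#' Annual cell-mean pool series (g C m-2)
#'
#' @rdname FluxArchive
#' @export
setMethod("poolSeries", "FluxArchive", function(x, var = c("c_veg", "c_soil")) {
  var <- match.arg(var)
  coh <- S4Vectors::metadata(x)$cohort
  pools <- coh[[var]]
  frac <- coh$frac
  apply(pools * frac, c(1, 3), sum)
})

setMethod("show", "FluxArchive", function(object) {
  man <- archiveManifest(object)
  cat(sprintf("FluxArchive %s: %d cells x %d months (%d-%d)\n",
              man$experiment, nrow(object), ncol(object),
              man$years[1], man$years[2]))
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
})

#' Run the four factorial experiments from one shared initial state
#'
#' @param state Spun-up \code{CellState} shared by all runs.
#' @param forcing,co2,land,props,params Transient drivers.
#' @param experiments Which members to run (default all of S1-S4).
#' @param ... Passed to [runTransient()].
#' @return Named list of \code{FluxArchive}s.
#' @export
runFactorial <- function(state, forcing, co2, land, props, params,
                         experiments = c("S1", "S2", "S3", "S4"), ...) {
  out <- lapply(experiments, function(nm) {
    runTransient(state, forcing, co2, land, props, params,
                 spec = experimentSpec(nm), ...)
  })
  stats::setNames(out, experiments)
}

#' Decadal factor effects on national NEP
#'
#' Differences of decadal national NEP means between the all-transient run
#' and each single-driver-suppressed run: \code{S1 - S2} is the CO2 effect,
#' \code{S1 - S3} the climate effect, \code{S1 - S4} the land-use effect
#' (all Tg C yr-1). The interaction residual per decade is the change of S1
#' from its first decade not accounted for by the three effects' changes.
#'
#' @param archives Named list with elements \code{S1}, \code{S2}, \code{S3},
#'   \code{S4} (any subset containing S1 plus the runs for the effects you
#'   want; missing runs yield NA effects).
#' @return An \code{AttributionResult}.
#' @export
attributionEffects <- function(archives) {
  if (!"S1" %in% names(archives)) stop("archives must contain S1")
  dec_nep <- function(a) {
    s <- nationalSeries(aggregateRegion(a))
    decadalMeans(s$nep, s$year)
  }
  d1 <- dec_nep(archives$S1)
  eff <- function(nm) {
    if (nm %in% names(archives)) d1 - dec_nep(archives[[nm]])
    else rep(NA_real_, length(d1))
  }
  e_co2 <- eff("S2"); e_cli <- eff("S3"); e_luc <- eff("S4")
  resid <- (d1 - d1[1]) -
    ((e_co2 - e_co2[1]) + (e_cli - e_cli[1]) + (e_luc - e_luc[1]))
  new("AttributionResult", decades = names(d1),
      effect_co2 = unname(e_co2), effect_climate = unname(e_cli),
      effect_luc = unname(e_luc),
      interaction_residual = unname(resid))
}

#' @rdname attributionEffects
#' @param x An \code{AttributionResult}.
#' @export
setMethod("factorEffects", "AttributionResult", function(x) {
  data.frame(decade = x@decades, co2 = x@effect_co2,
             climate = x@effect_climate, landuse = x@effect_luc,
             interaction_residual = x@interaction_residual)
})

setMethod("show", "AttributionResult", function(object) {
  cat("AttributionResult (Tg C yr-1 by decade):\n")
  print(factorEffects(object), row.names = FALSE, digits = 3)
})
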