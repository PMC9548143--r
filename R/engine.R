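#' @include carbon.R soil.R landuse.R forcing.R
NULL

# expand the per-type parameter table into ncell x ntype matrices so that
# every flux operation runs vectorized over all cohorts of all cells
.paramMatrices <- function(params, ncell, types) {
  lapply(as.list(params[types, , drop = FALSE]),
         function(v) matrix(v, ncell, length(types), byrow = TRUE))
}

#' Monthly climatology of a forcing
#'
#' Mean annual cycle (12 values per cell and variable) over the given years.
#'
#' @param forcing A \code{ClimateForcing}.
#' @param years Years to average over (default: all).
#' @return List of cell-by-12 matrices \code{tair}, \code{precip},
#'   \code{cloud}.
#' @export
monthlyClimatology <- function(forcing, years = NULL) {
  if (is.null(years)) years <- forcing@years
  yi <- match(years, forcing@years)
  if (anyNA(yi)) stop("climatology years outside forcing range")
  avg <- function(m) {
    out <- matrix(0, nrow(m), 12)
    for (mo in 1:12) {
      cols <- (yi - 1L) * 12L + mo
      out[, mo] <- rowMeans(m[, cols, drop = FALSE])
    }
    out
  }
  list(tair = avg(forcing@tair), precip = avg(forcing@precip),
       cloud = avg(forcing@cloud))
}

# core monthly integrator shared by equilibrium, spin-up and transient runs.
# tair/precip/cloud: ncell x nm; co2_by_year: length ny; frac_by_year: NULL
# (static cover) or ncell x ntype x ny. Returns final state and, when
# record = TRUE, monthly cell-mean flux matrices plus annual cohort arrays.
.simulateMonths <- function(state, tair, precip, cloud, co2_by_year,
                            frac_by_year, props, params, lat, heat_index,
                            alpha = 0.6, burn_fraction = 0.5,
                            record = FALSE) {
  ncell <- nrow(tair)
  nm <- ncol(tair)
  ny <- nm %/% 12L
  types <- rownames(params)
  ntype <- length(types)
  P <- .paramMatrices(params, ncell, types)
  capacity <- props@water_capacity

  c_veg <- state$c_veg; c_soil <- state$c_soil
  t_soil <- state$t_soil; water <- state$water
  frac <- state$frac

  if (record) {
    rec <- list()
    for (v in c("gpp", "ra", "npp", "rh", "nep", "conversion_flux",
                "t_soil20", "wfps"))
      rec[[v]] <- matrix(0, ncell, nm)
    coh <- list()
    for (v in c("gpp", "ra", "npp", "rh", "nep"))
      coh[[v]] <- array(0, dim = c(ncell, ntype, ny),
                        dimnames = list(NULL, types, NULL))
    c_vegA <- array(0, dim = c(ncell, ntype, ny),
                    dimnames = list(NULL, types, NULL))
    c_soilA <- c_vegA
    fracA <- c_vegA
  }
  released_year <- numeric(ncell)
  co2 <- co2_by_year[1]

  for (m in seq_len(nm)) {
    yi <- (m - 1L) %/% 12L + 1L
    month <- (m - 1L) %% 12L + 1L
    if (month == 1L) {
      co2 <- co2_by_year[yi]
      released_year <- numeric(ncell)
      if (!is.null(frac_by_year)) {
        target <- frac_by_year[, , yi, drop = FALSE]
        dim(target) <- c(ncell, ntype)
        changed <- which(rowSums(abs(target - frac)) > 1e-12)
        for (ic in changed) {
          tr <- applyTransition(
            list(c_veg = stats::setNames(c_veg[ic, ], types),
                 c_soil = stats::setNames(c_soil[ic, ], types)),
            stats::setNames(frac[ic, ], types),
            stats::setNames(target[ic, ], types),
            burn_fraction = burn_fraction)
          c_veg[ic, ] <- tr$cohorts$c_veg
          c_soil[ic, ] <- tr$cohorts$c_soil
          released_year[ic] <- tr$released
        }
        frac <- target
      }
    }

    t_soil <- updateSoilTemperature(t_soil, tair[, m], alpha)
    pet <- potentialEvapotranspiration(tair[, m], month, lat, heat_index)
    sw <- updateSoilWater(water, precip[, m], pet, capacity)
    water <- sw$water
    w <- wfps(water, capacity)

    res <- stepCohort(
      list(c_veg = c_veg, c_soil = c_soil),
      list(t_air = tair[, m], t_soil20 = t_soil, co2 = co2,
           cloud = cloud[, m], wfps = w),
      P)
    c_veg <- res$state$c_veg
    c_soil <- res$state$c_soil

    if (record) {
      fl <- res$fluxes
      rec$gpp[, m] <- rowSums(fl$gpp * frac)
      rec$ra[, m] <- rowSums(fl$ra * frac)
      rec$npp[, m] <- rowSums(fl$npp * frac)
      rec$rh[, m] <- rowSums(fl$rh * frac)
      rec$nep[, m] <- rowSums(fl$nep * frac)
      rec$conversion_flux[, m] <- released_year / 12
      rec$t_soil20[, m] <- t_soil
      rec$wfps[, m] <- w
      for (v in c("gpp", "ra", "npp", "rh", "nep"))
        coh[[v]][, , yi] <- coh[[v]][, , yi] + fl[[v]]
      if (month == 12L) {
        c_vegA[, , yi] <- c_veg
        c_soilA[, , yi] <- c_soil
        fracA[, , yi] <- frac
      }
    }
  }

  out <- list(state = list(c_veg = c_veg, c_soil = c_soil, t_soil = t_soil,
                           water = water, frac = frac))
  if (record) {
    out$monthly <- rec
    out$cohort <- c(coh, list(c_veg = c_vegA, c_soil = c_soilA,
                              frac = fracA))
  }
  out
}

# annual cell-mean NEP (g C m-2 yr-1) for one simulated year, used by the
# equilibrium convergence test
.annualNEP <- function(sim_year_coh, frac) {
  rowSums(sim_year_coh * frac)
}
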