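#' @include AllClasses.R
NULL

#' Default biome parameter table
#'
#' One row per cover type. Columns: \code{c_max} (maximum monthly GPP,
#' g C m-2 month-1), the photosynthesis temperature envelope
#' \code{t_min < t_opt < t_max} (degrees C), the CO2 half-saturation
#' \code{k_c} (ppm), maintenance-respiration coefficient \code{r_m}
#' (month-1 on the vegetation pool), growth-respiration share \code{r_g},
#' litterfall rate \code{l_f} (month-1), base decomposition rate \code{k_d}
#' (month-1), the Q10 values for plant and soil respiration, and the cloud
#' light-extinction strength \code{cloud_ext}. The values are this
#' package's calibration defaults for a transparent multiplicative-
#' limitation flux scheme; they can be overridden from a YAML table with
#' [readBiomeParams()].
#'
#' @return A data.frame keyed by cover type.
#' @export
defaultBiomeParams <- function() {
  p <- data.frame(
    row.names = coverTypes(),
    c_max = c(150, 60, 70, 90, 110, 5),
    t_min = c(-5, -6, -8, -5, 1, -10),
    t_opt = c(25, 22, 18, 22, 25, 15),
    t_max = c(40, 40, 38, 38, 40, 40),
    k_c   = rep(400, 6),
    r_m   = c(0.0035, 0.0040, 0.0045, 0.0035, 0.0090, 0.0050),
    r_g   = rep(0.25, 6),
    l_f   = c(0.005, 0.008, 0.020, 0.010, 0.030, 0.020),
    k_d   = c(0.0020, 0.0022, 0.0025, 0.0015, 0.0030, 0.0025),
    q10_veg  = rep(1.2, 6),
    q10_soil = rep(2.0, 6),
    cloud_ext = rep(0.8, 6)
  )
  p
}

#' Read a biome parameter table from YAML
#'
#' The file holds one mapping per cover type; missing fields fall back to
#' [defaultBiomeParams()]. A template is shipped at
#' \code{system.file("extdata", "biomes.yaml", package = "ChinaCarbon")}.
#'
#' @param path YAML file path.
#' @return A validated parameter data.frame.
#' @export
readBiomeParams <- function(path) {
  y <- yaml::read_yaml(path)
  p <- defaultBiomeParams()
  for (tname in names(y)) {
    if (!tname %in% rownames(p)) stop("unknown cover type: ", tname)
    for (f in names(y[[tname]])) {
      if (!f %in% colnames(p)) stop("unknown parameter: ", f)
      p[tname, f] <- y[[tname]][[f]]
    }
  }
  validateBiomeParams(p)
  p
}

#' @rdname defaultBiomeParams
#' @param params A biome parameter data.frame.
#' @export
validateBiomeParams <- function(params) {
  stopifnot(all(params$t_min < params$t_opt),
            all(params$t_opt < params$t_max),
            all(params$r_g >= 0 & params$r_g < 1),
            all(params$q10_veg >= 1), all(params$q10_soil >= 1),
            all(params[c("c_max", "r_m", "l_f", "k_d", "k_c")] >= 0))
  invisible(params)
}

#' Environmental limitation scalars
#'
#' The four dimensionless multipliers, each clamped to [0, 1], that scale
#' maximum GPP: a parabolic-ratio temperature response that is 1 at
#' \code{t_opt} and 0 outside \code{(t_min, t_max)}; Michaelis-Menten CO2
#' response normalized to 1 at 340 ppm; linear cloud light extinction
#' \code{1 - cloud_ext * cloud}; and a soil-moisture ramp rising 0 to 1 over
#' WFPS 0-60\% then easing back to 0.6 at saturation (anaerobic stress).
#' All arguments are vectorized; parameters may be scalars, vectors or
#' matrices conformable with the inputs.
#'
#' @param t_air Air temperature (degrees C).
#' @param co2 Atmospheric CO2 (ppm), positive.
#' @param cloud Cloudiness fraction.
#' @param wfps_pct Water-filled pore space (percent).
#' @param params List or data.frame row with \code{t_min, t_opt, t_max, k_c,
#'   cloud_ext}.
#' @return List of \code{f_temp, f_co2, f_light, f_water}.
#' @export
environmentalScalars <- function(t_air, co2, cloud, wfps_pct, params) {
  if (any(co2 <= 0)) stop("co2 must be positive")
  f_temp <- fTemp(t_air, params$t_min, params$t_opt, params$t_max)
  f_co2 <- fCO2(co2, params$k_c)
  f_light <- pmin(pmax(1 - params$cloud_ext * cloud, 0), 1)
  f_water <- fWater(wfps_pct)
  list(f_temp = f_temp, f_co2 = f_co2, f_light = f_light, f_water = f_water)
}

#' @rdname environmentalScalars
#' @param t_min,t_opt,t_max Temperature envelope (degrees C).
#' @export
fTemp <- function(t_air, t_min, t_opt, t_max) {
  num <- (t_air - t_min) * (t_max - t_air)
  den <- num - (t_air - t_opt)^2
  f <- ifelse(t_air <= t_min | t_air >= t_max | den == 0, 0, num / den)
  pmin(pmax(f, 0), 1)
}

#' @rdname environmentalScalars
#' @param k_c CO2 half-saturation (ppm).
#' @export
fCO2 <- function(co2, k_c) {
  f <- (co2 / (k_c + co2)) / (340 / (k_c + 340))
  pmin(pmax(f, 0), 1)
}

#' @rdname environmentalScalars
#' @export
fWater <- function(wfps_pct) {
  f <- ifelse(wfps_pct <= 60, wfps_pct / 60, 1 - 0.4 * (wfps_pct - 60) / 40)
  pmin(pmax(f, 0), 1)
}

#' Gross primary production
#'
#' \code{gpp = c_max * f_temp * f_co2 * f_light * f_water}: the
#' multiplicative-limitation surrogate for canopy carbon uptake. Zero
#' whenever any limitation scalar is zero.
#'
#' @param scalars Output of [environmentalScalars()].
#' @param params Parameters with \code{c_max}.
#' @return g C m-2 month-1.
#' @export
grossPrimaryProduction <- function(scalars, params) {
  params$c_max * scalars$f_temp * scalars$f_co2 * scalars$f_light *
    scalars$f_water
}

#' Plant autotrophic respiration
#'
#' Maintenance respiration on the vegetation pool with Q10 temperature
#' sensitivity, plus a growth share of the surplus assimilate:
#' \code{rm = r_m * c_veg * q10_veg^((t_air - 10)/10)};
#' \code{ra = rm + r_g * max(gpp - rm, 0)}.
#'
#' @param c_veg Vegetation carbon (g C m-2).
#' @param t_air Air temperature (degrees C).
#' @param gpp Gross primary production (g C m-2 month-1).
#' @param params Parameters with \code{r_m, r_g, q10_veg}.
#' @return g C m-2 month-1.
#' @export
autotrophicRespiration <- function(c_veg, t_air, gpp, params) {
  rm <- params$r_m * c_veg * params$q10_veg^((t_air - 10) / 10)
  rm + params$r_g * pmax(gpp - rm, 0)
}

#' Heterotrophic respiration
#'
#' First-order decomposition of soil organic carbon with Q10 sensitivity to
#' the 20 cm soil temperature and the same soil-moisture ramp that limits
#' photosynthesis (water co-limits plant growth and microbial activity):
#' \code{rh = k_d * c_soil * q10_soil^((t_soil - 10)/10) * f_water(wfps)},
#' capped at the available pool.
#'
#' @param c_soil Soil organic carbon (g C m-2).
#' @param t_soil20 Soil temperature at 20 cm (degrees C).
#' @param wfps_pct Water-filled pore space (percent).
#' @param params Parameters with \code{k_d, q10_soil}.
#' @return g C m-2 month-1.
#' @export
heterotrophicRespiration <- function(c_soil, t_soil20, wfps_pct, params) {
  rh <- params$k_d * c_soil * params$q10_soil^((t_soil20 - 10) / 10) *
    fWater(wfps_pct)
  pmin(rh, c_soil)
}

#' Advance one cohort by one month
#'
#' Computes the monthly fluxes and updates the cohort's carbon pools,
#' preserving the defining identities exactly: \code{npp = gpp - ra},
#' \code{nep = npp - rh}, and
#' \code{(c_veg' - c_veg) + (c_soil' - c_soil) = nep}. Respiration terms
#' are capped by pool availability (the cap is the flux adjustment that
#' keeps pools non-negative while the balance still closes).
#'
#' @param state List with \code{c_veg}, \code{c_soil} (vectorized).
#' @param env List with \code{t_air}, \code{t_soil20}, \code{co2},
#'   \code{cloud}, \code{wfps} for the month.
#' @param params Biome parameters (scalars or conformable arrays).
#' @return List with the updated \code{state} and the \code{fluxes}
#'   (\code{gpp, ra, npp, litter, rh, nep}).
#' @export
stepCohort <- function(state, env, params) {
  scal <- environmentalScalars(env$t_air, env$co2, env$cloud, env$wfps,
                               params)
  gpp <- grossPrimaryProduction(scal, params)
  litter <- params$l_f * state$c_veg
  ra_raw <- autotrophicRespiration(state$c_veg, env$t_air, gpp, params)
  ra <- pmin(ra_raw, gpp + state$c_veg - litter)  # cannot respire absent C
  npp <- gpp - ra
  rh <- heterotrophicRespiration(state$c_soil, env$t_soil20, env$wfps,
                                 params)
  nep <- npp - rh
  c_veg <- state$c_veg + npp - litter
  c_soil <- state$c_soil + litter - rh
  c_veg[c_veg < 0] <- 0   # floating-point guard; deficits are ~1e-16
  c_soil[c_soil < 0] <- 0
  list(state = list(c_veg = c_veg, c_soil = c_soil),
       fluxes = list(gpp = gpp, ra = ra, npp = npp, litter = litter,
                     rh = rh, nep = nep))
}
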