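#' @include AllClasses.R
NULL

# no-leap calendar
.month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
.mid_doy <- cumsum(.month_days) - .month_days / 2

#' Soil temperature update at 20 cm depth
#'
#' First-order relaxation of the 20 cm soil temperature toward monthly air
#' temperature: \code{t_prev + alpha * (t_air - t_prev)}. The recursion
#' attenuates and lags the annual cycle (gain
#' \code{alpha / sqrt(alpha^2 + 2 (1 - alpha)(1 - cos w))} at frequency
#' \code{w}) while tracking long-term warming, which is the behaviour the
#' model needs from the soil thermal state; a heat-diffusion solver is out
#' of scope.
#'
#' @param t_prev Previous soil temperature (degrees C), vectorized.
#' @param t_air Current monthly air temperature (degrees C).
#' @param alpha Relaxation fraction per month in (0, 1]; default 0.6.
#' @return Updated soil temperature.
#' @export
updateSoilTemperature <- function(t_prev, t_air, alpha = 0.6) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  t_prev + alpha * (t_air - t_prev)
}

#' Thornthwaite heat index from a monthly temperature cycle
#'
#' \code{I = sum((T/5)^1.514)} over months with positive mean temperature.
#'
#' @param monthly_t Numeric vector (length 12) or a cell-by-12 matrix of
#'   monthly mean air temperature.
#' @return Heat index (scalar or per-cell vector).
#' @export
heatIndex <- function(monthly_t) {
  if (is.matrix(monthly_t)) {
    rowSums((pmax(monthly_t, 0) / 5)^1.514)
  } else {
    sum((pmax(monthly_t, 0) / 5)^1.514)
  }
}

.thorn_a <- function(I) {
  6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
}

#' Unadjusted Thornthwaite evapotranspiration
#'
#' \code{e = 16 * (10 T / I)^a(I)} mm per 30-day month of 12-hour days;
#' zero at or below 0 degrees C.
#'
#' @param t_air Monthly mean air temperature (degrees C), vectorized.
#' @param heat_index Thornthwaite heat index of the location.
#' @return mm per standard month.
#' @export
thornthwaiteUnadjusted <- function(t_air, heat_index) {
  I <- pmax(heat_index, 1e-6)
  e <- 16 * (10 * pmax(t_air, 0) / I)^.thorn_a(I)
  ifelse(t_air <= 0, 0, e)
}

# day-length (hours) at mid-month from the standard declination formula
.dayLength <- function(latitude, month) {
  J <- .mid_doy[month]
  decl <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  x <- -tan(latitude * pi / 180) * tan(decl)
  ws <- acos(pmin(1, pmax(-1, x)))
  24 / pi * ws
}

#' Potential evapotranspiration (Thornthwaite)
#'
#' Monthly PET from temperature and latitude only, matching the parsimony of
#' the forcing: the unadjusted Thornthwaite value scaled by the day-length
#' and month-length correction \code{(L / 12) * (N / 30)}. Zero at or below
#' freezing and strictly increasing in temperature above it.
#'
#' @param t_air Monthly mean air temperature (degrees C), vectorized over
#'   cells.
#' @param month Month index 1-12 (scalar).
#' @param latitude Latitude in degrees (vectorized like \code{t_air}).
#' @param heat_index Thornthwaite heat index (per cell), typically from
#'   [heatIndex()] of the local mean annual cycle.
#' @return PET in mm per month.
#' @export
potentialEvapotranspiration <- function(t_air, month, latitude, heat_index) {
  if (month < 1 || month > 12) stop("month must be in 1..12")
  L <- .dayLength(latitude, month)
  thornthwaiteUnadjusted(t_air, heat_index) * (L / 12) *
    (.month_days[month] / 30)
}

#' Bucket soil-water update
#'
#' Single-store monthly water balance: actual evapotranspiration ramps
#' linearly with storage up to half capacity
#' (\code{aet = pet * min(1, water / (0.5 * capacity))}), the store is then
#' updated with precipitation minus AET, and any overflow above capacity
#' leaves as runoff. The balance closes exactly:
#' \code{water' - water = precip - aet - runoff}.
#'
#' @param water Current storage (mm), vectorized.
#' @param precip Precipitation (mm/month), non-negative.
#' @param pet Potential evapotranspiration (mm/month), non-negative.
#' @param capacity Bucket capacity (mm).
#' @return List with \code{water}, \code{aet}, \code{runoff}.
#' @export
updateSoilWater <- function(water, precip, pet, capacity) {
  if (any(precip < 0) || any(pet < 0)) stop("negative precip or pet")
  aet <- pmin(pet * pmin(1, water / (0.5 * capacity)), water + precip)
  w1 <- water + precip - aet
  runoff <- pmax(w1 - capacity, 0)
  w1 <- w1 - runoff
  list(water = w1, aet = aet, runoff = runoff)
}

#' Water-filled pore space
#'
#' Soil-moisture metric used throughout the diagnostics: storage as a
#' percentage of bucket capacity, in [0, 100].
#'
#' @param water Storage (mm).
#' @param capacity Bucket capacity (mm), positive.
#' @return Percent WFPS.
#' @export
wfps <- function(water, capacity) {
  if (any(capacity <= 0)) stop("zero or negative water capacity")
  100 * water / capacity
}
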