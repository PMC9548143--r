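#' @include AllClasses.R
NULL

#' Apply an annual land-cover transition to one cell
#'
#' Re-partitions the cell's cohort areas from \code{fracs_old} to
#' \code{fracs_new} with explicit carbon bookkeeping. Area lost by a type
#' donates its per-area carbon in proportion; area gained receives it.
#' Vegetation carbon entering cropland (clearing) is split: a
#' \code{burn_fraction} share is released to the atmosphere in the
#' transition year, the rest joins the cropland soil pool together with the
#' donated soil carbon. Transfers into natural types (abandonment /
#' afforestation) move both pools area-weighted with no release, so
#' recovery happens through subsequent growth. Total cell carbon plus the
#' released flux is conserved exactly.
#'
#' @param cohorts List with named per-type vectors \code{c_veg} and
#'   \code{c_soil} (g C per m2 of cohort area).
#' @param fracs_old,fracs_new Named cover fractions, each summing to 1.
#' @param burn_fraction Share of cleared vegetation carbon released
#'   immediately; default 0.5.
#' @return List with updated \code{cohorts}, \code{released} (g C m-2 of
#'   cell, total for the event) and \code{transferred_to_soil} (g C m-2).
#' @export
applyTransition <- function(cohorts, fracs_old, fracs_new,
                            burn_fraction = 0.5) {
  if (burn_fraction < 0 || burn_fraction > 1)
    stop("burn_fraction must lie in [0, 1]")
  if (abs(sum(fracs_old) - 1) > 1e-9 || abs(sum(fracs_new) - 1) > 1e-9)
    stop("cover fraction sets must sum to 1")
  types <- names(fracs_old)
  delta <- fracs_new[types] - fracs_old[types]
  if (all(abs(delta) < 1e-15)) {
    return(list(cohorts = cohorts, released = 0, transferred_to_soil = 0))
  }
  donated_area <- pmax(-delta, 0)
  gained_area <- pmax(delta, 0)
  D <- sum(donated_area)
  cv <- cohorts$c_veg[types]
  cs <- cohorts$c_soil[types]
  don_veg <- donated_area * cv   # absolute g C per m2 of cell
  don_soil <- donated_area * cs
  released <- 0
  to_soil <- 0
  in_veg <- stats::setNames(numeric(length(types)), types)
  in_soil <- stats::setNames(numeric(length(types)), types)
  for (r in types[gained_area > 0]) {
    share <- gained_area[r] / D
    veg_in <- share * sum(don_veg)
    soil_in <- share * sum(don_soil)
    if (r == "cropland") {
      released <- released + burn_fraction * veg_in
      in_soil[r] <- (1 - burn_fraction) * veg_in + soil_in
      to_soil <- to_soil + (1 - burn_fraction) * veg_in
    } else {
      in_veg[r] <- veg_in
      in_soil[r] <- soil_in
    }
  }
  a_new <- fracs_new[types]
  kept <- fracs_old[types] - donated_area   # area retained by each type
  cv_new <- ifelse(a_new > 0, (kept * cv + in_veg) / a_new, cv)
  cs_new <- ifelse(a_new > 0, (kept * cs + in_soil) / a_new, cs)
  list(
    cohorts = list(c_veg = stats::setNames(cv_new, types),
                   c_soil = stats::setNames(cs_new, types)),
    released = unname(released),
    transferred_to_soil = unname(to_soil)
  )
}

#' Net carbon exchange
#'
#' NEP minus the land-conversion release: the cell's full carbon exchange
#' with the atmosphere. Equals NEP whenever no conversion occurred.
#'
#' @param nep Net ecosystem production (g C m-2 month-1).
#' @param released Conversion flux released (g C m-2 month-1).
#' @return g C m-2 month-1.
#' @export
netCarbonExchange <- function(nep, released) {
  nep - released
}
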