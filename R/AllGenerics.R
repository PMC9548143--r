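#' @include AllClasses.R
NULL

#' @rdname GridSpec
#' @param object,x A \code{GridSpec}.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname GridSpec
#' @export
setGeneric("latCenters", function(x) standardGeneric("latCenters"))

#' @rdname GridSpec
#' @export
setGeneric("lonCenters", function(x) standardGeneric("lonCenters"))

#' @rdname GridSpec
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname GridSpec
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname ClimateForcing
#' @export
setGeneric("forcingYears", function(x) standardGeneric("forcingYears"))

#' @rdname CO2Series
#' @export
setGeneric("co2ppm", function(x) standardGeneric("co2ppm"))

#' @rdname LandCoverGrid
#' @export
setGeneric("coverFractions", function(x, year) standardGeneric("coverFractions"))

#' @rdname SoilProperties
#' @export
setGeneric("waterCapacity", function(x) standardGeneric("waterCapacity"))

#' @rdname FluxArchive
#' @export
setGeneric("archiveYears", function(x) standardGeneric("archiveYears"))

#' @rdname FluxArchive
#' @export
setGeneric("archiveManifest", function(x) standardGeneric("archiveManifest"))

#' @rdname FluxArchive
#' @export
setGeneric("cohortAnnual", function(x, var) standardGeneric("cohortAnnual"))

#' @rdname FluxArchive
#' @export
setGeneric("poolSeries", function(x, var) standardGeneric("poolSeries"))

#' @rdname aggregateRegion
#' @export
setGeneric("nationalSeries", function(x) standardGeneric("nationalSeries"))

#' @rdname aggregateRegion
#' @export
setGeneric("biomeTotals", function(x) standardGeneric("biomeTotals"))

#' @rdname aggregateRegion
#' @export
setGeneric("biomePerArea", function(x) standardGeneric("biomePerArea"))

#' @rdname attributionEffects
#' @export
setGeneric("factorEffects", function(x) standardGeneric("factorEffects"))
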