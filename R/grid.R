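#' @include AllGenerics.R
NULL

#' @rdname GridSpec
#' @export
setMethod("nCells", "GridSpec", function(x) x@n_lat * x@n_lon)

#' @rdname GridSpec
#' @export
setMethod("latCenters", "GridSpec", function(x) {
  x@lat_min + (seq_len(x@n_lat) - 0.5) * x@resolution
})

#' @rdname GridSpec
#' @export
setMethod("lonCenters", "GridSpec", function(x) {
  x@lon_min + (seq_len(x@n_lon) - 0.5) * x@resolution
})

#' Cell centers, latitude-major ordering
#'
#' Cells are ordered latitude-fastest: cell \code{k} has latitude index
#' \code{(k - 1) %% n_lat + 1} and longitude index \code{(k - 1) %/% n_lat + 1}.
#' This ordering is shared by every matrix/array in the package whose first
#' dimension is "cell".
#'
#' @rdname GridSpec
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  data.frame(
    cell = seq_len(nCells(x)),
    lat = rep(latCenters(x), times = x@n_lon),
    lon = rep(lonCenters(x), each = x@n_lat)
  )
})

#' Spherical area of a latitude-longitude cell
#'
#' Area of the spherical zone segment bounded by two parallels and two
#' meridians on a sphere of radius 6,371,000 m:
#' \code{R^2 * dlon_rad * (sin(lat_n) - sin(lat_s))}.
#'
#' @param lat_south,lat_north Latitude bounds in degrees, south < north.
#' @param lon_west,lon_east Longitude bounds in degrees, west < east.
#' @return Area in square meters.
#' @examples
#' cellArea(-0.5, 0.5, 0, 1)  # ~1.236e10 m2
#' @export
cellArea <- function(lat_south, lat_north, lon_west, lon_east) {
  if (any(lat_south >= lat_north) || any(lon_west >= lon_east))
    stop("inverted cell bounds")
  R <- 6371000
  d2r <- pi / 180
  R^2 * (lon_east - lon_west) * d2r *
    (sin(lat_north * d2r) - sin(lat_south * d2r))
}

#' @rdname GridSpec
#' @export
setMethod("cellAreas", "GridSpec", function(x) {
  cc <- cellCenters(x)
  h <- x@resolution / 2
  cellArea(cc$lat - h, cc$lat + h, cc$lon - h, cc$lon + h)
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells at %.2f deg, origin (%.2fN, %.2fE)\n",
              object@n_lat, object@n_lon, object@resolution,
              object@lat_min, object@lon_min))
})

#' Side of the Hu Huanyong line
#'
#' Classifies points relative to the Heihe-Tengchong (Hu Huanyong) line,
#' the demographic demarcation that the simulated 400 g C m-2 yr-1 NPP
#' contour approximately follows. The side is the sign of the cross product
#' of (P - Heihe) with (Tengchong - Heihe) in (lon, lat) space; points on
#' the line count as southeast.
#'
#' @param lat,lon Coordinates in degrees (vectorized).
#' @return Character vector, \code{"southeast"} or \code{"northwest"}.
#' @examples
#' huLineSide(31.2, 121.5)  # Shanghai: southeast
#' huLineSide(43.8, 87.6)   # Urumqi: northwest
#' @export
huLineSide <- function(lat, lon) {
  heihe <- c(lon = 127.5, lat = 50.25)
  tengchong <- c(lon = 98.5, lat = 25.0)
  v <- tengchong - heihe
  cross <- v["lon"] * (lat - heihe["lat"]) - v["lat"] * (lon - heihe["lon"])
  # v points SW from Heihe; points east/south of the directed line have
  # cross >= 0 (checked by hand for Shanghai/Urumqi); on-line -> southeast.
  unname(ifelse(cross >= 0, "southeast", "northwest"))
}
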