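#' @include protocol.R
NULL

#' Annual per-cell series from a monthly archive
#'
#' Sums flux assays (g C m-2 yr-1) or averages state assays (soil
#' temperature, WFPS) over the 12 months of each year.
#'
#' @param archive A \code{FluxArchive}.
#' @param var Assay name.
#' @return Cell-by-year matrix.
#' @export
cellAnnual <- function(archive, var) {
  m <- SummarizedExperiment::assay(archive, var)
  years <- archiveYears(archive)
  ny <- length(years)
  out <- matrix(0, nrow(m), ny, dimnames = list(NULL, years))
  state_var <- var %in% c("t_soil20", "wfps")
  for (yi in seq_len(ny)) {
    cols <- (yi - 1L) * 12L + 1:12
    out[, yi] <- if (state_var) rowMeans(m[, cols, drop = FALSE])
                 else rowSums(m[, cols, drop = FALSE])
  }
  out
}

#' Aggregate an archive to regional totals
#'
#' Converts per-area cohort fluxes to regional budgets: annual national (or
#' masked-region) NEP, NPP, RH and GPP in Tg C yr-1, the soil carbon pool in
#' Pg C, and per-biome NEP totals and per-area means. Cells are weighted by
#' spherical cell area times land fraction; cohorts by their cover fraction
#' of the year.
#'
#' @param archive A \code{FluxArchive}.
#' @param mask Optional integer cell indices restricting the region.
#' @return A \code{RegionalSummary}.
#' @export
aggregateRegion <- function(archive, mask = NULL) {
  rd <- SummarizedExperiment::rowData(archive)
  w <- rd$area * rd$land_fraction
  ncell <- length(w)
  if (is.null(mask)) mask <- seq_len(ncell)
  if (length(mask) == 0) stop("empty region mask")
  years <- archiveYears(archive)
  ny <- length(years)
  types <- S4Vectors::metadata(archive)$types
  frac <- cohortAnnual(archive, "frac")

  wm <- w[mask]
  nat <- list()
  biome_total <- NULL
  for (v in c("nep", "npp", "rh", "gpp")) {
    coh <- cohortAnnual(archive, v)
    tot <- numeric(ny)
    bt <- matrix(0, length(types), ny, dimnames = list(types, years))
    for (yi in seq_len(ny)) {
      contrib <- coh[mask, , yi, drop = FALSE] * frac[mask, , yi, drop = FALSE]
      bt[, yi] <- colSums(contrib * wm) * 1e-12
      tot[yi] <- sum(bt[, yi])
    }
    nat[[v]] <- tot
    if (v == "nep") biome_total <- bt
  }
  biome_area <- matrix(0, length(types), ny, dimnames = list(types, years))
  for (yi in seq_len(ny)) {
    biome_area[, yi] <- colSums(frac[mask, , yi, drop = FALSE] * wm)
  }
  biome_per_area <- ifelse(biome_area > 0,
                           biome_total * 1e12 / biome_area, 0)
  cs <- cohortAnnual(archive, "c_soil")
  soil_pg <- numeric(ny)
  for (yi in seq_len(ny)) {
    soil_pg[yi] <- sum(rowSums(cs[mask, , yi, drop = FALSE] *
                               frac[mask, , yi, drop = FALSE]) * wm) * 1e-15
  }
  ann <- data.frame(year = years, nep = nat$nep, npp = nat$npp,
                    rh = nat$rh, gpp = nat$gpp, soil_pool_pg = soil_pg)
  new("RegionalSummary", years = years, annual = ann,
      biome_total_nep = biome_total, biome_per_area_nep = biome_per_area,
      biome_area = biome_area, area_total = sum(wm))
}

#' @rdname aggregateRegion
#' @param x A \code{RegionalSummary}.
#' @export
setMethod("nationalSeries", "RegionalSummary", function(x) x@annual)

#' @rdname aggregateRegion
#' @export
setMethod("biomeTotals", "RegionalSummary", function(x) x@biome_total_nep)

#' @rdname aggregateRegion
#' @export
setMethod("biomePerArea", "RegionalSummary", function(x) x@biome_per_area_nep)

setMethod("show", "RegionalSummary", function(object) {
  cat(sprintf("RegionalSummary: %d years, area %.3g m2\n",
              length(object@years), object@area_total))
  cat(sprintf("  century mean NEP %.1f, NPP %.1f, RH %.1f Tg C yr-1\n",
              mean(object@annual$nep), mean(object@annual$npp),
              mean(object@annual$rh)))
})

#' Decadal means of an annual series
#'
#' Means over the complete calendar decades covered by the series (1900-1909
#' through 1990-1999 for a 1900-2000 run; the lone year 2000 belongs to no
#' complete decade and is excluded, though it still counts in century-wide
#' statistics).
#'
#' @param values Annual values.
#' @param years Matching years (default 1900:2000).
#' @return Named vector of decade means (names "1900", "1910", ...).
#' @export
decadalMeans <- function(values, years = 1900:2000) {
  if (length(values) != length(years))
    stop("values and years must have equal length")
  dec <- 10L * (years %/% 10L)
  counts <- table(dec)
  keep <- names(counts)[counts == 10L]
  out <- tapply(values[as.character(dec) %in% keep],
                dec[as.character(dec) %in% keep], mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Ordinary least-squares trend of an annual series
#'
#' Slope of value on year, reported per decade, with R-squared and the
#' two-sided p-value of the slope t statistic. A constant series returns a
#' zero slope with R-squared 0 and p 1.
#'
#' @param values Annual values.
#' @param years Matching years.
#' @param window Optional two-element year range restricting the fit.
#' @return List with \code{slope_per_decade}, \code{r_squared},
#'   \code{p_value}, \code{n}.
#' @export
linearTrend <- function(values, years, window = NULL) {
  if (!is.null(window)) {
    keep <- years >= window[1] & years <= window[2]
    values <- values[keep]; years <- years[keep]
  }
  n <- length(values)
  if (n < 3) stop("need at least 3 points for a trend")
  if (length(unique(years)) == 1) stop("degenerate (constant) year input")
  if (stats::var(values) == 0)
    return(list(slope_per_decade = 0, r_squared = 0, p_value = 1, n = n))
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  list(slope_per_decade = unname(stats::coef(fit)[2]) * 10,
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = n)
}

#' Latitude/longitude strip anomalies
#'
#' Area-weighted annual means over each strip of cells sharing a latitude
#' (or longitude) index, expressed as anomalies from the strip's own
#' baseline-period mean. This is the view in which coherent events such as
#' the 1922-1932 drought stand out.
#'
#' @param field Cell-by-year matrix of annual values.
#' @param grid The \code{GridSpec} the cells belong to.
#' @param axis \code{"latitude"} or \code{"longitude"}.
#' @param years Years of the field columns.
#' @param baseline Two-element year range for the reference mean (default:
#'   the full period).
#' @return Strip-by-year anomaly matrix (rows named by strip center degree).
#' @export
stripAnomalies <- function(field, grid, axis = c("latitude", "longitude"),
                           years, baseline = range(years)) {
  axis <- match.arg(axis)
  if (baseline[1] < min(years) || baseline[2] > max(years))
    stop("baseline outside the field years")
  cc <- cellCenters(grid)
  key <- if (axis == "latitude") cc$lat else cc$lon
  w <- cellAreas(grid)
  strips <- sort(unique(key))
  out <- matrix(0, length(strips), ncol(field),
                dimnames = list(strips, years))
  for (i in seq_along(strips)) {
    idx <- which(key == strips[i])
    if (length(idx) == 0) stop("empty strip")
    wi <- w[idx] / sum(w[idx])
    out[i, ] <- colSums(field[idx, , drop = FALSE] * wi)
  }
  base_cols <- which(years >= baseline[1] & years <= baseline[2])
  out - rowMeans(out[, base_cols, drop = FALSE])
}

#' Count carbon-source years
#'
#' Number of years with strictly negative NEP (zero is not a source).
#'
#' @param national_nep Annual national NEP (Tg C yr-1).
#' @return Integer count.
#' @export
countSourceYears <- function(national_nep) {
  sum(national_nep < 0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks),
#' with the two-sided p-value from the t approximation on n - 2 degrees of
#' freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearmanCor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero-variance input: rho undefined")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Partial rank correlation
#'
#' Correlation between \code{x} and \code{y} after removing the linear
#' dependence of both on the rank-transformed controls: all variables are
#' rank-transformed, \code{x} and \code{y} are residualized on the controls
#' by least squares, and the residuals are correlated. With no controls this
#' reduces to [spearmanCor()].
#'
#' @param x,y Numeric vectors.
#' @param controls Optional numeric vector, matrix or data.frame of control
#'   variables.
#' @return List with \code{rho}, \code{p_value}, \code{n},
#'   \code{n_controls}.
#' @export
partialCorrelation <- function(x, y, controls = NULL) {
  n <- length(x)
  if (is.null(controls) || NCOL(controls) == 0 ||
      (is.matrix(controls) && ncol(controls) == 0)) {
    s <- spearmanCor(x, y)
    return(list(rho = s$rho, p_value = s$p_value, n = n, n_controls = 0L))
  }
  Z <- as.matrix(as.data.frame(controls))
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > number of controls + 2")
  Zr <- apply(Z, 2, rank)
  X <- cbind(1, Zr)
  if (qr(X)$rank < ncol(X)) stop("collinear controls")
  rx <- stats::lm.fit(X, rank(x))$residuals
  ry <- stats::lm.fit(X, rank(y))$residuals
  # residuals that vanish up to rounding mean the controls explain the
  # variable exactly: the partial association is zero, not numerical noise
  if (stats::sd(rx) < 1e-8 * stats::sd(rank(x)) ||
      stats::sd(ry) < 1e-8 * stats::sd(rank(y))) {
    return(list(rho = 0, p_value = 1, n = n, n_controls = k))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = df)
  }
  list(rho = rho, p_value = p, n = n, n_controls = k)
}

#' Correlations between carbon fluxes and their drivers
#'
#' Two readings are provided because regional analyses mix them. In
#' \code{"spatial"} mode, century cell means of each flux are rank-correlated
#' across cells with cell-level drivers (mean temperature, precipitation,
#' cloudiness, clay fraction, elevation, mean cropland fraction); CO2 is
#' spatially uniform and excluded. In \code{"temporal"} mode, national
#' annual flux series are rank-correlated over years with national annual
#' drivers (temperature, precipitation, cloudiness, CO2, cropland fraction).
#'
#' @param archive A \code{FluxArchive}.
#' @param forcing The \code{ClimateForcing} that drove it.
#' @param co2 The \code{CO2Series}.
#' @param land The \code{LandCoverGrid}.
#' @param props The \code{SoilProperties}.
#' @param mode \code{"spatial"} or \code{"temporal"}.
#' @return Data frame with driver, flux, rho, p_value.
#' @export
driverCorrelations <- function(archive, forcing, co2, land, props,
                               mode = c("spatial", "temporal")) {
  mode <- match.arg(mode)
  years <- archiveYears(archive)
  fluxes <- c("nep", "npp", "rh")
  if (mode == "spatial") {
    fx <- lapply(fluxes, function(v) rowMeans(cellAnnual(archive, v)))
    names(fx) <- fluxes
    crop_mean <- rowMeans(land@frac[, "cropland", , drop = TRUE])
    drivers <- list(
      tair = rowMeans(forcing@tair),
      precip = rowMeans(forcing@precip) * 12,
      cloud = rowMeans(forcing@cloud),
      clay = props@clay,
      elevation = props@elevation,
      cropland = crop_mean)
  } else {
    summ <- nationalSeries(aggregateRegion(archive))
    fx <- list(nep = summ$nep, npp = summ$npp, rh = summ$rh)
    w <- cellAreas(forcing@grid); w <- w / sum(w)
    crop_nat <- colSums(land@frac[, "cropland", , drop = TRUE] * w)
    drivers <- list(
      tair = nationalAnnualMean(forcing, "tair"),
      precip = nationalAnnualMean(forcing, "precip"),
      cloud = nationalAnnualMean(forcing, "cloud"),
      co2 = co2@ppm[match(years, co2@years)],
      cropland = crop_nat[match(years, land@years)])
  }
  out <- expand.grid(driver = names(drivers), flux = fluxes,
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- tryCatch(spearmanCor(drivers[[out$driver[i]]], fx[[out$flux[i]]]),
                  error = function(e) NULL)  # constant driver -> undefined
    if (!is.null(s)) {
      out$rho[i] <- s$rho
      out$p_value[i] <- s$p_value
    }
  }
  out
}

#' Per-cell partial-correlation map of NEP against one driver
#'
#' For every cell, the partial rank correlation between the annual NEP
#' series and one driver's annual series, controlling for the remaining
#' drivers, with a two-sided 95\% significance flag.
#'
#' @param archive A \code{FluxArchive}.
#' @param forcing The \code{ClimateForcing}.
#' @param co2 The \code{CO2Series}.
#' @param land The \code{LandCoverGrid}.
#' @param driver One of \code{"tair"}, \code{"precip"}, \code{"cloud"},
#'   \code{"co2"}, \code{"cropland"}.
#' @return List with per-cell \code{rho} and logical \code{significant}.
#' @export
partialCorrelationMap <- function(archive, forcing, co2, land,
                                  driver = c("tair", "precip", "cloud",
                                             "co2", "cropland")) {
  driver <- match.arg(driver)
  years <- archiveYears(archive)
  ny <- length(years)
  ncell <- nrow(archive)
  nep <- cellAnnual(archive, "nep")
  ann <- function(m, f) {
    out <- matrix(0, nrow(m), ny)
    for (yi in seq_len(ny)) out[, yi] <- f(m[, (yi - 1) * 12 + 1:12])
    out
  }
  cellDrivers <- list(
    tair = ann(forcing@tair, rowMeans),
    precip = ann(forcing@precip, rowSums),
    cloud = ann(forcing@cloud, rowMeans),
    co2 = matrix(co2@ppm[match(years, co2@years)], ncell, ny, byrow = TRUE),
    cropland = land@frac[, "cropland", match(years, land@years)])
  rho <- rep(NA_real_, ncell)
  sig <- rep(FALSE, ncell)
  ctrl_names <- setdiff(names(cellDrivers), driver)
  for (ic in seq_len(ncell)) {
    Z <- vapply(ctrl_names, function(v) cellDrivers[[v]][ic, ], numeric(ny))
    Z <- Z[, apply(Z, 2, stats::sd) > 0, drop = FALSE]
    res <- tryCatch(
      partialCorrelation(cellDrivers[[driver]][ic, ], nep[ic, ],
                         if (ncol(Z)) Z else NULL),
      error = function(e) NULL)
    if (!is.null(res)) {
      rho[ic] <- res$rho
      sig[ic] <- res$p_value < 0.05
    }
  }
  list(rho = rho, significant = sig)
}
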