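#' @include aggregate.R
NULL

# full-precision matrix CSV: %.17g guarantees exact double round-trips
.writeMatrixCSV <- function(m, path, col_names) {
  header <- paste(col_names, collapse = ",")
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, body), path)
}

.readMatrixCSV <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

.timeLabels <- function(years) {
  paste0("y", rep(years, each = 12), "m", sprintf("%02d", rep(1:12, length(years))))
}

.gridToList <- function(grid) {
  list(lat_min = grid@lat_min, lon_min = grid@lon_min,
       resolution = grid@resolution, n_lat = grid@n_lat,
       n_lon = grid@n_lon)
}

.gridFromList <- function(g) {
  GridSpec(lat_min = g$lat_min, lon_min = g$lon_min,
           resolution = g$resolution, n_lat = g$n_lat, n_lon = g$n_lon)
}

#' Write climate forcing to a directory
#'
#' One directory per forcing: \code{meta.json} (grid, years, units) and one
#' full-precision CSV matrix per variable, columns labelled
#' \code{y<year>m<month>}.
#'
#' @param forcing A \code{ClimateForcing}.
#' @param path Directory to create.
#' @return \code{path}, invisibly.
#' @export
writeForcing <- function(forcing, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(grid = .gridToList(forcing@grid),
               years = forcing@years,
               units = list(tair = "degC", precip = "mm month-1",
                            cloud = "fraction"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  labs <- .timeLabels(forcing@years)
  for (v in c("tair", "precip", "cloud"))
    .writeMatrixCSV(slot(forcing, v), file.path(path, paste0(v, ".csv")), labs)
  invisible(path)
}

#' Read and validate climate forcing
#'
#' Loads a directory written by [writeForcing()] (or conforming to its
#' schema) and enforces the forcing invariants on load: no missing values,
#' non-negative precipitation, cloudiness within [0, 1] (violations are
#' reported with the offending cell and month), and a gap-free 12-month
#' calendar per year.
#'
#' @param path Directory path.
#' @return A validated \code{ClimateForcing}.
#' @export
readForcing <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  grid <- .gridFromList(meta$grid)
  years <- as.integer(meta$years)
  expected <- .timeLabels(years)
  vars <- list()
  for (v in c("tair", "precip", "cloud")) {
    f <- file.path(path, paste0(v, ".csv"))
    if (!file.exists(f)) stop("missing forcing variable file: ", v)
    m <- .readMatrixCSV(f)
    if (ncol(m) != length(expected) || !identical(colnames(m), expected))
      stop("calendar gap in ", v,
           ": time axis must hold 12 months of every year ",
           min(years), "-", max(years))
    if (nrow(m) != nCells(grid))
      stop(v, " has ", nrow(m), " cells; grid expects ", nCells(grid))
    if (anyNA(m)) stop("missing values in ", v)
    vars[[v]] <- unname(m)
  }
  bad <- which(vars$precip < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative precipitation at cell %d, month %s",
                 bad[1, 1], expected[bad[1, 2]]))
  bad <- which(vars$cloud < 0 | vars$cloud > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("cloudiness outside [0,1] at cell %d, month %s",
                 bad[1, 1], expected[bad[1, 2]]))
  new("ClimateForcing", grid = grid, years = years,
      tair = vars$tair, precip = vars$precip, cloud = vars$cloud)
}

#' Write a flux archive to a directory
#'
#' \code{meta.json} carries the run manifest, dimensions and units;
#' \code{cells.csv} and \code{time.csv} the axes; each assay and each
#' per-cohort annual variable its own full-precision CSV matrix.
#'
#' @param archive A complete \code{FluxArchive}.
#' @param path Directory to create.
#' @return \code{path}, invisibly.
#' @export
writeArchive <- function(archive, path) {
  missing <- setdiff(.archive_assays, SummarizedExperiment::assayNames(archive))
  if (length(missing))
    stop("partial archive, missing variable(s): ",
         paste(missing, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  years <- archiveYears(archive)
  types <- S4Vectors::metadata(archive)$types
  meta <- list(manifest = archiveManifest(archive), years = years,
               types = types)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(SummarizedExperiment::rowData(archive)),
                   file.path(path, "cells.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(SummarizedExperiment::colData(archive)),
                   file.path(path, "time.csv"), row.names = FALSE)
  labs <- .timeLabels(years)
  for (v in .archive_assays)
    .writeMatrixCSV(SummarizedExperiment::assay(archive, v),
                    file.path(path, paste0(v, ".csv")), labs)
  clabs <- paste0(rep(types, times = length(years)), ".",
                  rep(years, each = length(types)))
  for (v in names(S4Vectors::metadata(archive)$cohort)) {
    a <- S4Vectors::metadata(archive)$cohort[[v]]
    m <- matrix(a, nrow = dim(a)[1])
    .writeMatrixCSV(m, file.path(path, paste0("cohort_", v, ".csv")), clabs)
  }
  invisible(path)
}

#' Read a flux archive directory
#'
#' @param path Directory written by [writeArchive()].
#' @return A \code{FluxArchive}.
#' @export
readArchive <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  years <- as.integer(meta$years)
  types <- meta$types
  cells <- utils::read.csv(file.path(path, "cells.csv"))
  timeax <- utils::read.csv(file.path(path, "time.csv"))
  assays <- list()
  for (v in .archive_assays) {
    f <- file.path(path, paste0(v, ".csv"))
    if (!file.exists(f)) stop("archive is missing variable: ", v)
    assays[[v]] <- unname(.readMatrixCSV(f))
  }
  cohort <- list()
  for (v in c("gpp", "ra", "npp", "rh", "nep", "c_veg", "c_soil", "frac")) {
    f <- file.path(path, paste0("cohort_", v, ".csv"))
    if (!file.exists(f)) stop("archive is missing cohort variable: ", v)
    m <- unname(.readMatrixCSV(f))
    cohort[[v]] <- array(m, dim = c(nrow(m), length(types), length(years)),
                         dimnames = list(NULL, types, NULL))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(cells),
    colData = S4Vectors::DataFrame(timeax),
    metadata = list(years = years, manifest = meta$manifest,
                    cohort = cohort, types = types))
  new("FluxArchive", se)
}

# canonical config hash (stable across sessions; no timestamps involved)
.configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.defaultPipelineConfig <- function() {
  list(
    grid = list(lat_min = 18, lon_min = 73, resolution = 2,
                n_lat = 18, n_lon = 31),
    years = c(1900, 2000),
    seed = 42,
    climate_scenario = "default",
    landuse_scenario = "default",
    co2 = list(start_ppm = 296, end_ppm = 369, shape = "exponential"),
    experiments = c("S1", "S2", "S3", "S4"),
    spinup_years = 150,
    equilibrium = list(tol = 0.1, max_iter = 3000),
    burn_fraction = 0.5,
    out_dir = NULL,
    write_archives = FALSE
  )
}

#' Run the full pipeline from a configuration
#'
#' End to end: generate the seeded synthetic inputs, run the cells to
#' equilibrium at the century-mean CO2 and climatology, spin up over the
#' recycled early-century climate block, run the requested factorial
#' experiments, attribute NEP changes to CO2 / climate / land use (when all
#' four runs are present), and aggregate the national and biome summaries.
#' A single top-level seed governs every random draw. If \code{out_dir} is
#' set, summary CSVs and the run manifest are written there; outputs are
#' byte-identical across reruns of the same configuration.
#'
#' @param config Named list (missing entries take defaults) or the path of
#'   a YAML file holding one. See the package vignette for the schema.
#' @return List with \code{manifest}, \code{archives}, \code{attribution},
#'   \code{summary} (a \code{RegionalSummary} of S1).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  years <- seq(cfg$years[1], cfg$years[2])
  if ("S3" %in% cfg$experiments && !all(1900:1919 %in% years))
    stop("configuration error: experiment S3 needs climate data for ",
         "1900-1919, but the run years are ", cfg$years[1], "-",
         cfg$years[2])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  grid <- .gridFromList(cfg$grid)
  seed <- as.integer(cfg$seed)
  message("[gen-forcing] grid ", grid@n_lat, "x", grid@n_lon,
          ", seed ", seed)
  climate_sc <- stage("gen-forcing", switch(cfg$climate_scenario,
    default = climateScenario(),
    stationary = stationaryScenario(),
    stop("unknown climate scenario key: ", cfg$climate_scenario)))
  forcing <- stage("gen-forcing",
                   generateClimate(grid, climate_sc, seed, years))
  co2 <- stage("gen-forcing",
               generateCO2Series(cfg$co2$start_ppm, cfg$co2$end_ppm,
                                 cfg$co2$shape, years))
  lu_sc <- stage("gen-landcover", switch(cfg$landuse_scenario,
    default = landUseScenario(years),
    static = staticLandUseScenario(years = years),
    stop("unknown land-use scenario key: ", cfg$landuse_scenario)))
  land <- stage("gen-landcover", generateLandCover(grid, lu_sc, seed))
  props <- stage("gen-forcing", generateSoil(grid, seed))
  params <- defaultBiomeParams()

  message("[equilibrium] tol ", cfg$equilibrium$tol)
  clim <- monthlyClimatology(forcing)
  eq <- stage("equilibrium",
    runEquilibrium(clim, mean(co2@ppm), coverFractions(land, years[1]),
                   props, params, grid, tol = cfg$equilibrium$tol,
                   max_iter = cfg$equilibrium$max_iter))
  if (any(!eq@converged))
    message("[equilibrium] ", sum(!eq@converged), " cell(s) flagged ",
            "non-converged after ", eq@iterations, " years")

  message("[spin-up] ", cfg$spinup_years, " years")
  block <- min(50L, length(years))
  spun <- stage("spin-up",
    runSpinup(eq, forcing, co2@ppm[1], props, params,
              years = cfg$spinup_years, block_years = block))

  message("[factorial] ", paste(cfg$experiments, collapse = ", "))
  archives <- stage("factorial",
    runFactorial(spun, forcing, co2, land, props, params,
                 experiments = cfg$experiments,
                 burn_fraction = cfg$burn_fraction,
                 manifest = list(seed = seed)))

  attribution <- NULL
  if (all(c("S1", "S2", "S3", "S4") %in% names(archives)))
    attribution <- stage("attribution", attributionEffects(archives))

  summary <- stage("summarize", aggregateRegion(archives[[1]]))

  manifest <- list(
    config_hash = .configHash(cfg),
    seed = seed, grid = cfg$grid, years = cfg$years,
    climate_scenario = cfg$climate_scenario,
    landuse_scenario = cfg$landuse_scenario,
    experiments = cfg$experiments,
    equilibrium_iterations = eq@iterations,
    cells_not_converged = sum(!eq@converged),
    version = as.character(utils::packageVersion("ChinaCarbon")))

  if (!is.null(cfg$out_dir)) {
    stage("write-outputs", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      writeSummary(summary, attribution,
                   archives, file.path(cfg$out_dir))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(cfg$write_archives)) {
        for (nm in names(archives))
          writeArchive(archives[[nm]],
                       file.path(cfg$out_dir, paste0("archive_", nm)))
      }
    })
  }
  list(manifest = manifest, archives = archives, attribution = attribution,
       summary = summary)
}

#' Write summary CSV files
#'
#' \code{national_annual.csv} (year, NEP/NPP/RH/GPP in Tg C yr-1, soil pool
#' in Pg C), \code{biome_decadal_nep.csv} (biome x decade NEP totals) and,
#' when attribution is available, \code{decadal_effects.csv}.
#'
#' @param summary A \code{RegionalSummary}.
#' @param attribution An \code{AttributionResult} or NULL.
#' @param archives Named archive list (used for per-experiment annual NEP).
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSummary <- function(summary, attribution, archives, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- nationalSeries(summary)
  utils::write.csv(ann, file.path(dir, "national_annual.csv"),
                   row.names = FALSE)
  bt <- biomeTotals(summary)
  years <- summary@years
  dec <- t(apply(bt, 1, function(r) decadalMeans(r, years)))
  out <- data.frame(biome = rownames(bt), dec, check.names = FALSE)
  utils::write.csv(out, file.path(dir, "biome_decadal_nep.csv"),
                   row.names = FALSE)
  if (!is.null(attribution)) {
    utils::write.csv(factorEffects(attribution),
                     file.path(dir, "decadal_effects.csv"),
                     row.names = FALSE)
  }
  if (length(archives) > 1) {
    per <- data.frame(year = years)
    for (nm in names(archives))
      per[[nm]] <- nationalSeries(aggregateRegion(archives[[nm]]))$nep
    utils::write.csv(per, file.path(dir, "experiment_annual_nep.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
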