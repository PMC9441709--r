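# Text-format round-trips: CSV for tabular data, GeoJSON for vector layers,
# ESRI ASCII grid (.asc) for rasters, JSON for models and configuration.

#' Write / read minute-level sound logs
#'
#' Columns: `site_id`, `timestamp` (ISO-8601, local time = UTC; Ghana has
#' no daylight saving), `laeq_1min_dba`.
#' @param minutes Minute-level tibble.
#' @param path CSV path.
#' @return `read_minutes_csv` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_minutes_csv <- function(minutes, path) {
  out <- minutes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_minutes_csv
#' @export
read_minutes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    timestamp = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%SZ"),
    laeq_1min_dba = readr::col_double()
  ), progress = FALSE)
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) stores the standardization parameters and
#' the catalogue so the matrix round-trips with its provenance.
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_csv <- function(fm, path) {
  readr::write_csv(tibble::as_tibble(fm), path, progress = FALSE)
  side <- list(
    buffers = attr(fm, "buffers"),
    standardization = attr(fm, "standardization"),
    catalogue = attr(fm, "catalogue")
  )
  jsonlite::write_json(side, paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  fm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(fm, "buffers") <- side$buffers
  attr(fm, "standardization") <-
    if (!is.null(side$standardization)) tibble::as_tibble(side$standardization)
  attr(fm, "catalogue") <- tibble::as_tibble(side$catalogue)
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Serialize a fitted LUR model to JSON
#'
#' Stores everything prediction and reporting need: coefficients with CIs,
#' hour intercepts, variance components, R^2, the selection trace and the
#' standardization parameters. [read_lur_json()] reconstructs a model
#' usable by [predict_lur()] and [cross_validate()] (without the lme4 fit
#' object).
#' @param model A `lur_model`.
#' @param path JSON path.
#' @export
write_lur_json <- function(model, path) {
  payload <- list(
    period = model$period,
    variables = model$variables,
    coefficients = model$coefficients,
    hour_intercepts = as.list(model$hour_intercepts),
    site_variance = model$site_variance,
    hour_variance = model$hour_variance,
    residual_variance = model$residual_variance,
    r2_fixed = model$r2_fixed,
    r2_marginal = model$r2_marginal,
    n_sites = model$n_sites,
    n_obs = model$n_obs,
    standardization = model$standardization,
    trace = model$trace,
    vif = model$vif
  )
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lur_json
#' @export
read_lur_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(period = p$period,
         variables = as.character(p$variables %||% character()),
         coefficients = tibble::as_tibble(p$coefficients),
         hour_intercepts = unlist(p$hour_intercepts),
         site_variance = p$site_variance,
         hour_variance = p$hour_variance,
         residual_variance = p$residual_variance,
         r2_fixed = p$r2_fixed, r2_marginal = p$r2_marginal,
         n_sites = p$n_sites, n_obs = p$n_obs,
         standardization = tibble::as_tibble(p$standardization),
         trace = if (!is.null(p$trace)) tibble::as_tibble(p$trace),
         vif = if (!is.null(p$vif)) tibble::as_tibble(p$vif)),
    class = "lur_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by every GIS.
#' @param r An internal raster (or a matrix with `origin`/`res` given).
#' @param path Output `.asc` path.
#' @param nodata NODATA value (default -9999).
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", r$ncol),
    paste("nrows", r$nrow),
    paste("xllcorner", r$origin[1]),
    paste("yllcorner", r$origin[2]),
    paste("cellsize", r$res),
    paste("NODATA_value", nodata)
  ), con)
  # ASCII grids list rows north to south
  for (i in rev(seq_len(r$nrow))) {
    writeLines(paste(format(v[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          tolower(vapply(kv, `[`, "", 1)))
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == vals[["nodata_value"]]] <- NA
  nl_raster(m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
            res = vals[["cellsize"]])
}

geojson_geometry <- function(type, coords) {
  list(type = type, coordinates = coords)
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
            c(xmin, ymin)))
}

#' Write all city layers to a directory
#'
#' Vector layers become GeoJSON, rasters ASCII grids, enumeration-area
#' attributes a CSV alongside their polygons.
#' @param city A `city_layers` object.
#' @param dir Output directory (created if needed).
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roads <- purrr::pmap(city$roads, function(road_id, class, x0, y0, x1, y1) {
    geojson_feature(
      geojson_geometry("LineString", list(c(x0, y0), c(x1, y1))),
      list(road_id = road_id, class = class))
  })
  write_geojson(roads, file.path(dir, "roads.geojson"))
  pois <- purrr::pmap(city$pois, function(poi_id, category, x, y) {
    geojson_feature(geojson_geometry("Point", c(x, y)),
                    list(poi_id = poi_id, category = category))
  })
  write_geojson(pois, file.path(dir, "pois.geojson"))
  bld <- purrr::pmap(city$buildings, function(building_id, x, y) {
    geojson_feature(geojson_geometry("Point", c(x, y)),
                    list(building_id = building_id))
  })
  write_geojson(bld, file.path(dir, "buildings.geojson"))
  eas <- purrr::pmap(
    city$eas[, c("ea_id", "xmin", "ymin", "xmax", "ymax", "population")],
    function(ea_id, xmin, ymin, xmax, ymax, population) {
      geojson_feature(geojson_geometry("Polygon",
                                       rect_ring(xmin, ymin, xmax, ymax)),
                      list(ea_id = ea_id, population = population))
    })
  write_geojson(eas, file.path(dir, "eas.geojson"))
  readr::write_csv(tibble::as_tibble(city$eas), file.path(dir, "eas.csv"),
                   progress = FALSE)
  if (nrow(city$water) > 0) {
    wat <- purrr::pmap(city$water, function(water_id, xmin, xmax, ymin, ymax) {
      geojson_feature(geojson_geometry("Polygon",
                                       rect_ring(xmin, ymin, xmax, ymax)),
                      list(water_id = water_id))
    })
    write_geojson(wat, file.path(dir, "water.geojson"))
  }
  apt <- geojson_feature(
    geojson_geometry("Polygon", rect_ring(city$airport$xmin, city$airport$ymin,
                                          city$airport$xmax, city$airport$ymax)),
    list(name = "airport"))
  write_geojson(list(apt), file.path(dir, "airport.geojson"))
  write_asc(city$landcover, file.path(dir, "landcover.asc"))
  write_asc(city$ndvi, file.path(dir, "ndvi.asc"))
  write_asc(city$dem, file.path(dir, "dem.asc"))
  invisible(dir)
}

#' Write surface layers as ASCII grids
#'
#' One `.asc` per layer (the 4 aggregates), NODATA for masked cells, plus
#' the per-cell metrics CSV.
#' @param surface A `noise_surface`.
#' @param dir Output directory.
#' @export
write_surface <- function(surface, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- surface$grid
  dims <- attr(grid, "dims")
  cs <- attr(grid, "cell_size")
  for (layer in c("laeq_24hr", "l_den", "l_day", "l_night")) {
    m <- matrix(NA_real_, dims["nrow"], dims["ncol"])
    idx <- match(surface$metrics$cell_id, grid$cell_id)
    m[cbind(grid$row[idx], grid$col[idx])] <- round(surface$metrics[[layer]], 4)
    write_asc(nl_raster(m, origin = c(0, 0), res = cs),
              file.path(dir, paste0(layer, ".asc")))
  }
  readr::write_csv(surface$metrics, file.path(dir, "surface_metrics.csv"),
                   progress = FALSE)
  invisible(dir)
}
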