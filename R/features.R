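#' Catalogue of candidate spatial predictor variables
#'
#' Defines every candidate predictor the selection algorithm may consider,
#' the layer and zonal statistic it is computed from, the a-priori expected
#' direction of its association with noise (LUR convention: traffic and
#' activity variables positive, greenness and formal residential area
#' negative), and whether the column is standardized before model fitting.
#' Count and presence variables stay on their raw scale.
#'
#' @return Tibble with columns `name`, `layer`, `statistic`,
#'   `expected_sign` (`"+"`, `"-"`, `"either"`), `standardize`, `buffered`.
#' @export
feature_catalogue <- function() {
  poi <- poi_categories()
  poi_sign <- c(restaurant = "+", school = "+", hospital = "+",
                bus_station = "+", bar = "+", church = "+", mosque = "+",
                shopping_center = "+")
  dplyr::bind_rows(
    tibble::tibble(
      name = c("major_roads", "secondary_roads", "minor_roads", "all_roads"),
      layer = "roads", statistic = "length_sum", expected_sign = "+",
      standardize = TRUE, buffered = TRUE
    ),
    tibble::tibble(
      name = c("landcover_industrial", "landcover_informal",
               "landcover_formal", "landcover_other"),
      layer = "landcover", statistic = "area_sum",
      expected_sign = c("+", "+", "-", "either"),
      standardize = TRUE, buffered = TRUE
    ),
    tibble::tibble(name = "water_area", layer = "water",
                   statistic = "area_sum", expected_sign = "either",
                   standardize = TRUE, buffered = TRUE),
    tibble::tibble(name = "ndvi", layer = "ndvi", statistic = "raster_mean",
                   expected_sign = "-", standardize = TRUE, buffered = TRUE),
    tibble::tibble(name = "elevation", layer = "dem",
                   statistic = "raster_mean", expected_sign = "either",
                   standardize = TRUE, buffered = TRUE),
    tibble::tibble(name = "pop_density", layer = "eas",
                   statistic = "density_mean", expected_sign = "+",
                   standardize = TRUE, buffered = TRUE),
    tibble::tibble(name = "buildings", layer = "buildings",
                   statistic = "point_count", expected_sign = "+",
                   standardize = FALSE, buffered = TRUE),
    tibble::tibble(name = paste0(poi, "_count"), layer = "pois",
                   statistic = "point_count", expected_sign = poi_sign[poi],
                   standardize = FALSE, buffered = TRUE),
    tibble::tibble(name = paste0(poi, "_presence"), layer = "pois",
                   statistic = "point_presence", expected_sign = poi_sign[poi],
                   standardize = FALSE, buffered = TRUE),
    tibble::tibble(
      name = c("dist_major_road", "dist_secondary_road", "dist_airport"),
      layer = c("roads", "roads", "airport"), statistic = "distance",
      expected_sign = c("-", "-", "either"),
      standardize = TRUE, buffered = FALSE
    ),
    tibble::tibble(
      name = c("sqrt_dist_major_road", "sqrt_dist_secondary_road",
               "sqrt_dist_airport"),
      layer = c("roads", "roads", "airport"), statistic = "sqrt_distance",
      expected_sign = c("-", "-", "either"),
      standardize = TRUE, buffered = FALSE
    )
  )
}

#' Buffer radii used for zonal statistics
#' @param radii_m Strictly increasing positive radii in meters.
#' @return Validated numeric vector.
#' @export
buffer_spec <- function(radii_m = c(50, 100, 200, 500)) {
  if (any(radii_m <= 0) || any(diff(radii_m) <= 0)) {
    stop("buffer_spec: radii must be positive and strictly increasing",
         call. = FALSE)
  }
  radii_m
}

feature_name <- function(var, buffer) paste0(var, "_", buffer)

#' Extract buffer-based spatial predictors at locations
#'
#' For every location and buffer radius: clipped road length per class (m),
#' land-cover class area (m^2, cell-center inclusion at the raster's native
#' resolution), NDVI mean with negative (water) cells omitted, elevation
#' mean, area-weighted mean enumeration-area population density
#' (people/km^2), point counts and presence per POI category and for
#' building centroids; plus Euclidean and square-root distance to the
#' nearest major road, secondary road and the airport polygon. Buffers are
#' closed disks: features on the boundary count.
#'
#' @param locations Tibble with an id column (first column), `x`, `y`, and
#'   optionally `monitor_height_m` (default 4 m when absent).
#' @param city A `city_layers` object.
#' @param catalogue A [feature_catalogue()] (or subset of it).
#' @param buffers Radii from [buffer_spec()].
#' @return A `feature_matrix`: tibble with the id/coordinate columns plus
#'   one column per (variable, buffer) pair and per distance variable.
#'   Attributes: `catalogue`, `buffers`, `standardization` (NULL until
#'   [standardize_features()] is applied).
#' @export
extract_features <- function(locations, city, catalogue = feature_catalogue(),
                             buffers = buffer_spec()) {
  stopifnot(inherits(city, "city_layers"))
  known <- c("length_sum", "area_sum", "raster_mean", "point_count",
             "point_presence", "density_mean", "distance", "sqrt_distance")
  bad <- setdiff(catalogue$statistic, known)
  if (length(bad) > 0) {
    stop("extract_features: unknown statistic(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  px <- locations$x
  py <- locations$y
  ext <- city$extent
  if (any(px < ext$xmin | px > ext$xmax | py < ext$ymin | py > ext$ymax)) {
    stop("extract_features: locations outside the city extent", call. = FALSE)
  }
  n <- length(px)
  id_col <- names(locations)[1]
  out <- tibble::tibble(!!id_col := locations[[id_col]], x = px, y = py)
  out$monitor_height_m <- if ("monitor_height_m" %in% names(locations)) {
    locations$monitor_height_m
  } else rep(4, n)

  cls <- city$landcover_classes
  road_class_of <- c(major_roads = "major",
                     secondary_roads = "secondary_tertiary",
                     minor_roads = "minor")
  lc_var_class <- c(landcover_industrial = "industrial_commercial",
                    landcover_informal = "informal_residential",
                    landcover_formal = "formal_residential",
                    landcover_other = "other")

  ## road lengths: loop over segments, vectorised over locations
  len_vars <- intersect(catalogue$name[catalogue$statistic == "length_sum"],
                        names(road_class_of))
  if (length(len_vars) > 0 || "all_roads" %in% catalogue$name) {
    per_class <- list()
    for (rc in unique(city$roads$class)) {
      segs <- city$roads[city$roads$class == rc, ]
      acc <- matrix(0, n, length(buffers))
      for (i in seq_len(nrow(segs))) {
        for (b in seq_along(buffers)) {
          acc[, b] <- acc[, b] + seg_length_in_disk(
            segs$x0[i], segs$y0[i], segs$x1[i], segs$y1[i],
            px, py, buffers[b])
        }
      }
      per_class[[rc]] <- acc
    }
    for (v in len_vars) {
      m <- per_class[[road_class_of[v]]]
      if (is.null(m)) m <- matrix(0, n, length(buffers))
      for (b in seq_along(buffers)) out[[feature_name(v, buffers[b])]] <- m[, b]
    }
    if ("all_roads" %in% catalogue$name) {
      tot <- Reduce(`+`, per_class, matrix(0, n, length(buffers)))
      for (b in seq_along(buffers)) {
        out[[feature_name("all_roads", buffers[b])]] <- tot[, b]
      }
    }
  }

  ## raster-derived statistics share per-location disk masks
  need_lc <- any(names(lc_var_class) %in% catalogue$name)
  need_pop <- "pop_density" %in% catalogue$name
  need_ndvi <- "ndvi" %in% catalogue$name
  need_dem <- "elevation" %in% catalogue$name
  if (need_lc || need_pop || need_ndvi || need_dem) {
    dens_raster <- if (need_pop) ea_density_raster(city) else NULL
    lc_area <- city$landcover$res^2
    nb <- length(buffers)
    store <- function(vname) matrix(NA_real_, n, nb)
    lc_mats <- lapply(lc_var_class, function(z) matrix(0, n, nb))
    pop_mat <- store(); ndvi_mat <- store(); dem_mat <- store()
    for (i in seq_len(n)) {
      for (b in seq_len(nb)) {
        r <- buffers[b]
        if (need_lc || need_pop) {
          vals <- raster_values_in_disk(city$landcover, px[i], py[i], r)
          if (need_lc) {
            tab <- tabulate(vals, nbins = length(cls))
            for (k in seq_along(lc_var_class)) {
              lc_mats[[k]][i, b] <- tab[match(lc_var_class[k], cls)] * lc_area
            }
          }
          if (need_pop) {
            dv <- raster_values_in_disk(dens_raster, px[i], py[i], r)
            pop_mat[i, b] <- if (length(dv) > 0) mean(dv) else 0
          }
        }
        if (need_ndvi) {
          nv <- raster_values_in_disk(city$ndvi, px[i], py[i], r)
          nv <- nv[nv >= 0] # water/negative cells omitted
          ndvi_mat[i, b] <- if (length(nv) > 0) mean(nv) else 0
        }
        if (need_dem) {
          dvv <- raster_values_in_disk(city$dem, px[i], py[i], r)
          dem_mat[i, b] <- if (length(dvv) > 0) mean(dvv) else
            raster_value_at(city$dem, px[i], py[i])
        }
      }
    }
    for (k in seq_along(lc_var_class)) {
      v <- names(lc_var_class)[k]
      if (v %in% catalogue$name) {
        for (b in seq_len(nb)) out[[feature_name(v, buffers[b])]] <- lc_mats[[k]][, b]
      }
    }
    if (need_pop) for (b in seq_len(nb)) {
      out[[feature_name("pop_density", buffers[b])]] <- pop_mat[, b]
    }
    if (need_ndvi) for (b in seq_len(nb)) {
      out[[feature_name("ndvi", buffers[b])]] <- ndvi_mat[, b]
    }
    if (need_dem) for (b in seq_len(nb)) {
      out[[feature_name("elevation", buffers[b])]] <- dem_mat[, b]
    }
  }

  ## water area within buffers (rectangle/disk overlap by land-cover grid)
  if ("water_area" %in% catalogue$name) {
    wr <- city$water
    wmat <- matrix(0, n, length(buffers))
    if (nrow(wr) > 0) {
      wmask <- water_mask_raster(city)
      for (i in seq_len(n)) {
        for (b in seq_along(buffers)) {
          wv <- raster_values_in_disk(wmask, px[i], py[i], buffers[b])
          wmat[i, b] <- sum(wv) * city$landcover$res^2
        }
      }
    }
    for (b in seq_along(buffers)) {
      out[[feature_name("water_area", buffers[b])]] <- wmat[, b]
    }
  }

  ## point counts / presence
  pt_entries <- catalogue[catalogue$statistic %in%
                            c("point_count", "point_presence"), ]
  if (nrow(pt_entries) > 0) {
    for (row in seq_len(nrow(pt_entries))) {
      v <- pt_entries$name[row]
      if (pt_entries$layer[row] == "buildings") {
        qx <- city$buildings$x; qy <- city$buildings$y
      } else {
        # poi variable names are category + "_count" / category + "_presence"
        cat_name <- sub("_(count|presence)$", "", v)
        sel <- city$pois$category == cat_name
        qx <- city$pois$x[sel]; qy <- city$pois$y[sel]
      }
      cnt <- count_points_in_disks(px, py, qx, qy, buffers)
      for (b in seq_along(buffers)) {
        val <- cnt[, b]
        if (pt_entries$statistic[row] == "point_presence") val <- as.numeric(val > 0)
        out[[feature_name(v, buffers[b])]] <- val
      }
    }
  }

  ## distance variables (no buffer)
  dist_entries <- catalogue[catalogue$statistic %in% c("distance", "sqrt_distance"), ]
  if (nrow(dist_entries) > 0) {
    d_major <- min_dist_to_segments(px, py,
                                    city$roads[city$roads$class == "major", ])
    d_sec <- min_dist_to_segments(
      px, py, city$roads[city$roads$class == "secondary_tertiary", ])
    d_apt <- point_rect_dist(px, py, city$airport)
    base <- list(dist_major_road = d_major, dist_secondary_road = d_sec,
                 dist_airport = d_apt)
    for (v in dist_entries$name) {
      root <- sub("^sqrt_", "", v)
      if (!root %in% names(base)) {
        stop("extract_features: unknown distance variable ", v, call. = FALSE)
      }
      out[[v]] <- if (grepl("^sqrt_", v)) sqrt(base[[root]]) else base[[root]]
    }
  }

  structure(out, class = c("feature_matrix", class(out)),
            catalogue = catalogue, buffers = buffers,
            standardization = NULL)
}

# population density (people/km^2) of the containing EA, rasterised at the
# land-cover resolution; the buffer mean of this raster is the area-weighted
# mean of intersecting EA densities
ea_density_raster <- function(city) {
  lc <- city$landcover
  centers <- raster_cell_centers(lc)
  cx <- rep(centers$x, each = lc$nrow)
  cy <- rep(centers$y, times = lc$ncol)
  ids <- ea_lookup(city$eas, cx, cy)
  dens <- city$eas$population /
    ((city$eas$xmax - city$eas$xmin) * (city$eas$ymax - city$eas$ymin) / 1e6)
  vals <- dens[match(ids, city$eas$ea_id)]
  nl_raster(matrix(vals, lc$nrow, lc$ncol), origin = lc$origin, res = lc$res)
}

water_mask_raster <- function(city) {
  lc <- city$landcover
  centers <- raster_cell_centers(lc)
  cx <- rep(centers$x, each = lc$nrow)
  cy <- rep(centers$y, times = lc$ncol)
  m <- rep(FALSE, length(cx))
  for (w in seq_len(nrow(city$water))) {
    m <- m | point_in_rect(cx, cy, city$water[w, ])
  }
  nl_raster(matrix(as.numeric(m), lc$nrow, lc$ncol),
            origin = lc$origin, res = lc$res)
}

# counts of points (qx, qy) within each closed disk around (px, py), for
# each radius; chunked to bound memory
count_points_in_disks <- function(px, py, qx, qy, radii) {
  n <- length(px)
  out <- matrix(0, n, length(radii))
  if (length(qx) == 0) return(out)
  chunk <- max(1L, floor(2e6 / length(qx)))
  r2 <- radii^2
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    d2 <- outer(px[s:e], qx, "-")^2 + outer(py[s:e], qy, "-")^2
    for (b in seq_along(radii)) {
      out[s:e, b] <- rowSums(d2 <= r2[b])
    }
  }
  out
}

#' Standardize feature-matrix columns
#'
#' Z-scores the columns the catalogue flags for standardization, using the
#' sample (n-1) standard deviation computed on `fit_rows`. The fitted
#' means/SDs are stored and must be reused verbatim for prediction
#' locations ([apply_standardization()]). Zero-variance columns are
#' excluded with a warning (they cannot enter a regression).
#'
#' @param fm A `feature_matrix` from [extract_features()].
#' @param fit_rows Logical or integer row selector defining the fitting set
#'   (default: all rows).
#' @return The standardized `feature_matrix` with a `standardization`
#'   attribute (tibble `column`, `mean`, `sd`, `standardized`).
#' @export
standardize_features <- function(fm, fit_rows = NULL) {
  catalogue <- attr(fm, "catalogue")
  buffers <- attr(fm, "buffers")
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(fm))
  if (length(seq_len(nrow(fm))[fit_rows]) < 2) {
    stop("standardize_features: need at least 2 fitting rows", call. = FALSE)
  }
  cols <- feature_columns(fm)
  std_cols <- standardizable_columns(catalogue, buffers)
  params <- list()
  drop <- character()
  for (cn in cols) {
    do_std <- cn %in% std_cols
    mu <- mean(fm[[cn]][fit_rows])
    sdv <- stats::sd(fm[[cn]][fit_rows])
    if (do_std && (!is.finite(sdv) || sdv == 0)) {
      drop <- c(drop, cn)
      next
    }
    if (do_std) fm[[cn]] <- (fm[[cn]] - mu) / sdv
    params[[cn]] <- tibble::tibble(column = cn, mean = mu, sd = sdv,
                                   standardized = do_std)
  }
  if (length(drop) > 0) {
    warning("standardize_features: excluded zero-variance column(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
    fm <- fm[, setdiff(names(fm), drop)]
  }
  attr(fm, "standardization") <- dplyr::bind_rows(params)
  attr(fm, "catalogue") <- catalogue
  attr(fm, "buffers") <- buffers
  fm
}

#' Apply stored standardization parameters to new locations
#'
#' @param fm A raw (unstandardized) `feature_matrix` for new locations.
#' @param params The `standardization` attribute of a fitted matrix (or a
#'   fitted `feature_matrix` itself).
#' @return Standardized `feature_matrix` on the same scale as the fit.
#' @export
apply_standardization <- function(fm, params) {
  if (inherits(params, "feature_matrix")) {
    params <- attr(params, "standardization")
  }
  if (is.null(params)) {
    stop("apply_standardization: no standardization parameters", call. = FALSE)
  }
  miss <- setdiff(params$column, names(fm))
  if (length(miss) > 0) {
    stop("apply_standardization: feature matrix lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(params))) {
    if (params$standardized[i]) {
      cn <- params$column[i]
      fm[[cn]] <- (fm[[cn]] - params$mean[i]) / params$sd[i]
    }
  }
  attr(fm, "standardization") <- params
  fm
}

# row subset that keeps the feature_matrix attributes (plain tibble
# subsetting can drop them)
subset_feature_rows <- function(fm, keep) {
  out <- fm[keep, ]
  attr(out, "catalogue") <- attr(fm, "catalogue")
  attr(out, "buffers") <- attr(fm, "buffers")
  attr(out, "standardization") <- attr(fm, "standardization")
  class(out) <- class(fm)
  out
}

feature_columns <- function(fm) {
  setdiff(names(fm), c(names(fm)[1], "x", "y", "monitor_height_m"))
}

standardizable_columns <- function(catalogue, buffers) {
  std <- catalogue[catalogue$standardize, ]
  unlist(lapply(seq_len(nrow(std)), function(i) {
    if (std$buffered[i]) feature_name(std$name[i], buffers) else std$name[i]
  }))
}
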