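#' Configuration for the synthetic city generator
#'
#' Defines the extent, resolutions and feature densities of the miniature
#' synthetic city used to exercise the full noise-LUR pipeline against a
#' known ground truth. Defaults give a 4 x 4 km city with a 20 m land-cover
#' raster, a 30 m NDVI raster, a 90 m elevation raster and 40 census
#' enumeration areas -- a desk-scale stand-in for a metropolitan study area.
#'
#' @param width_m,height_m Extent of the study rectangle in meters.
#' @param landcover_res_m,ndvi_res_m,dem_res_m Raster resolutions (m).
#' @param n_eas Number of enumeration-area polygons (they partition the
#'   extent without overlap).
#' @param n_major,n_secondary,n_minor Road counts by class.
#' @param pois_per_category Points of interest per category.
#' @param n_buildings Number of building centroids.
#' @param water_fraction Fraction of the extent covered by water bodies;
#'   0 disables water.
#' @param ndvi_road_effect Strength of the (negative) coupling between NDVI
#'   and proximity to roads; 0 decouples them.
#' @return A named list of class `city_config`.
#' @export
city_config <- function(width_m = 4000, height_m = 4000,
                        landcover_res_m = 20, ndvi_res_m = 30,
                        dem_res_m = 90, n_eas = 40,
                        n_major = 3, n_secondary = 8, n_minor = 60,
                        pois_per_category = 12, n_buildings = 2500,
                        water_fraction = 0.03, ndvi_road_effect = 0.5) {
  cfg <- list(
    width_m = width_m, height_m = height_m,
    landcover_res_m = landcover_res_m, ndvi_res_m = ndvi_res_m,
    dem_res_m = dem_res_m, n_eas = n_eas,
    n_major = n_major, n_secondary = n_secondary, n_minor = n_minor,
    pois_per_category = pois_per_category, n_buildings = n_buildings,
    water_fraction = water_fraction, ndvi_road_effect = ndvi_road_effect
  )
  if (any(unlist(cfg[c("width_m", "height_m", "landcover_res_m",
                       "ndvi_res_m", "dem_res_m")]) <= 0)) {
    stop("city_config: extents and resolutions must be positive",
         call. = FALSE)
  }
  if (n_eas < 1) stop("city_config: n_eas must be >= 1", call. = FALSE)
  if (water_fraction < 0 || water_fraction >= 1) {
    stop("city_config: water_fraction must be in [0, 1)", call. = FALSE)
  }
  if (n_major < 1 || n_secondary < 1 || n_minor < 1) {
    stop("city_config: every road class needs at least one road",
         call. = FALSE)
  }
  structure(cfg, class = "city_config")
}

landcover_classes <- function() {
  c("industrial_commercial", "informal_residential",
    "formal_residential", "other")
}

poi_categories <- function() {
  c("restaurant", "school", "hospital", "bus_station",
    "bar", "church", "mosque", "shopping_center")
}

#' Generate a synthetic city
#'
#' Builds every geospatial layer the LUR pipeline consumes: a road network
#' in three classes, a categorical land-cover raster, an NDVI raster
#' negatively coupled to road proximity (vegetation thins near traffic), a
#' digital elevation model, points of interest, building centroids,
#' enumeration-area polygons carrying population and socioeconomic
#' attributes, water bodies and an airport polygon. All layers share one
#' planar CRS in meters and the output is deterministic for a fixed seed.
#'
#' @param config A [city_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs give
#'   byte-identical layers.
#' @return An object of class `city_layers`: a list with elements `extent`,
#'   `roads`, `landcover`, `ndvi`, `dem`, `pois`, `buildings`, `eas`,
#'   `water`, `airport`.
#' @examples
#' city <- generate_city(city_config(width_m = 1500, height_m = 1500,
#'                                   n_eas = 9, n_minor = 12,
#'                                   n_buildings = 200), seed = 1)
#' nrow(city$eas)
#' @export
generate_city <- function(config = city_config(), seed = 1L) {
  if (!inherits(config, "city_config")) config <- do.call(city_config, config)
  set.seed(seed)
  W <- config$width_m
  H <- config$height_m
  extent <- list(xmin = 0, xmax = W, ymin = 0, ymax = H)

  roads <- generate_roads(config, extent)
  major_sec <- roads[roads$class != "minor", ]

  ## land cover: nearest-seed regions whose class mixture depends on
  ## distance to the arterial network (industry hugs big roads, 'other'
  ## dominates the periphery)
  lc_res <- config$landcover_res_m
  lc_nrow <- max(1L, round(H / lc_res))
  lc_ncol <- max(1L, round(W / lc_res))
  lc_x <- (seq_len(lc_ncol) - 0.5) * lc_res
  lc_y <- (seq_len(lc_nrow) - 0.5) * lc_res
  grid_x <- rep(lc_x, each = lc_nrow)
  grid_y <- rep(lc_y, times = lc_ncol)

  n_seed <- max(12L, round(config$n_eas * 0.75))
  sx <- stats::runif(n_seed, 0, W)
  sy <- stats::runif(n_seed, 0, H)
  d_seed_major <- min_dist_to_segments(sx, sy, major_sec)
  cls <- landcover_classes()
  seed_class <- vapply(d_seed_major, function(d) {
    p <- if (d < 250) c(0.50, 0.30, 0.15, 0.05)
         else if (d < 700) c(0.15, 0.35, 0.40, 0.10)
         else c(0.03, 0.12, 0.30, 0.55)
    sample(cls, 1, prob = p)
  }, character(1))
  near_seed <- nearest_seed_index(grid_x, grid_y, sx, sy)
  lc_vals <- matrix(match(seed_class[near_seed], cls),
                    nrow = lc_nrow, ncol = lc_ncol)
  landcover <- nl_raster(lc_vals, origin = c(0, 0), res = lc_res)

  ## water: one lake placed in the cell farthest from arterials
  water <- tibble::tibble(water_id = character(), xmin = numeric(),
                          xmax = numeric(), ymin = numeric(), ymax = numeric())
  if (config$water_fraction > 0) {
    area <- config$water_fraction * W * H
    aspect <- stats::runif(1, 0.6, 1.6)
    ww <- sqrt(area * aspect)
    wh <- area / ww
    d_cell <- min_dist_to_segments(grid_x, grid_y, major_sec)
    ctr <- which.max(d_cell)
    cx <- min(max(grid_x[ctr], ww / 2), W - ww / 2)
    cy <- min(max(grid_y[ctr], wh / 2), H - wh / 2)
    water <- tibble::tibble(water_id = "W01",
                            xmin = cx - ww / 2, xmax = cx + ww / 2,
                            ymin = cy - wh / 2, ymax = cy + wh / 2)
    in_water <- matrix(grid_x >= water$xmin & grid_x <= water$xmax &
                         grid_y >= water$ymin & grid_y <= water$ymax,
                       nrow = lc_nrow, ncol = lc_ncol)
    landcover$values[in_water] <- match("other", cls)
  }
  # every class must exist on land (the lake may have erased one): carve a
  # small patch of the missing class out of the modal class, away from water
  land_cells <- which(!is_water_cell(landcover, water))
  for (k in seq_along(cls)) {
    if (!k %in% landcover$values[land_cells]) {
      modal <- as.integer(names(which.max(table(landcover$values[land_cells]))))
      pool <- land_cells[landcover$values[land_cells] == modal]
      landcover$values[pool[seq_len(min(25, length(pool)))]] <- k
    }
  }

  ## NDVI: greenness baseline minus a road-proximity deficit, plus noise
  nd_res <- config$ndvi_res_m
  nd_nrow <- max(1L, round(H / nd_res))
  nd_ncol <- max(1L, round(W / nd_res))
  nd_x <- rep((seq_len(nd_ncol) - 0.5) * nd_res, each = nd_nrow)
  nd_y <- rep((seq_len(nd_nrow) - 0.5) * nd_res, times = nd_ncol)
  d_road <- min_dist_to_segments(nd_x, nd_y, roads)
  nd_vals <- 0.55 - config$ndvi_road_effect * exp(-d_road / 200) +
    0.08 * sin(nd_x / 400) * cos(nd_y / 500) +
    stats::rnorm(nd_nrow * nd_ncol, 0, 0.04)
  nd_vals <- pmin(pmax(nd_vals, -1), 1)
  nd_vals <- matrix(nd_vals, nrow = nd_nrow, ncol = nd_ncol)
  if (nrow(water) > 0) {
    in_water <- matrix(nd_x >= water$xmin & nd_x <= water$xmax &
                         nd_y >= water$ymin & nd_y <= water$ymax,
                       nrow = nd_nrow, ncol = nd_ncol)
    nd_vals[in_water] <- -0.2
  }
  ndvi <- nl_raster(nd_vals, origin = c(0, 0), res = nd_res)

  ## elevation: gentle coastal-plain gradient with low hills
  dm_res <- config$dem_res_m
  dm_nrow <- max(1L, round(H / dm_res))
  dm_ncol <- max(1L, round(W / dm_res))
  dm_x <- rep((seq_len(dm_ncol) - 0.5) * dm_res, each = dm_nrow)
  dm_y <- rep((seq_len(dm_nrow) - 0.5) * dm_res, times = dm_ncol)
  dm_vals <- 30 + 40 * (dm_y / H) + 8 * sin(dm_x / 600) +
    stats::rnorm(dm_nrow * dm_ncol, 0, 1.5)
  dem <- nl_raster(matrix(dm_vals, dm_nrow, dm_ncol),
                   origin = c(0, 0), res = dm_res)

  ## enumeration areas: equal-height rows, equal-width columns per row
  eas <- generate_eas(config, extent, landcover, major_sec, water)

  ## POIs cluster along roads; buildings follow land-cover density
  pois <- generate_pois(config, roads, extent, water)
  buildings <- generate_buildings(config, landcover, extent, water, cls)

  ## airport polygon near the extent edge
  apt_w <- min(600, W / 4)
  apt_h <- min(400, H / 6)
  airport <- list(xmin = W - apt_w - 50, xmax = W - 50,
                  ymin = 50, ymax = 50 + apt_h)

  structure(
    list(extent = extent, roads = roads, landcover = landcover,
         ndvi = ndvi, dem = dem, pois = pois, buildings = buildings,
         eas = eas, water = water, airport = airport,
         landcover_classes = cls, crs = "local-planar-meters",
         config = config, seed = seed),
    class = "city_layers"
  )
}

is_water_cell <- function(landcover, water) {
  centers <- raster_cell_centers(landcover)
  cx <- rep(centers$x, each = landcover$nrow)
  cy <- rep(centers$y, times = landcover$ncol)
  m <- rep(FALSE, length(cx))
  for (w in seq_len(nrow(water))) {
    m <- m | point_in_rect(cx, cy, water[w, ])
  }
  m
}

nearest_seed_index <- function(px, py, sx, sy) {
  best <- rep(1L, length(px))
  bestd <- (px - sx[1])^2 + (py - sy[1])^2
  for (k in seq_along(sx)[-1]) {
    d <- (px - sx[k])^2 + (py - sy[k])^2
    upd <- d < bestd
    best[upd] <- k
    bestd[upd] <- d[upd]
  }
  best
}

generate_roads <- function(config, extent) {
  W <- extent$xmax
  H <- extent$ymax
  segs <- list()
  # major arterials: alternate horizontal/vertical full-extent lines
  for (i in seq_len(config$n_major)) {
    if (i %% 2 == 1) {
      yy <- stats::runif(1, 0.2, 0.8) * H
      segs[[length(segs) + 1]] <- c(0, yy, W, yy, 1)
    } else {
      xx <- stats::runif(1, 0.25, 0.75) * W
      segs[[length(segs) + 1]] <- c(xx, 0, xx, H, 1)
    }
  }
  # secondary/tertiary: random chords across the extent
  for (i in seq_len(config$n_secondary)) {
    p <- clip_line_to_extent(stats::runif(1, 0.1, 0.9) * W,
                             stats::runif(1, 0.1, 0.9) * H,
                             stats::runif(1, 0, pi),
                             extent)
    if (!is.null(p)) segs[[length(segs) + 1]] <- c(p, 2)
  }
  # minor: short local streets
  for (i in seq_len(config$n_minor)) {
    cx <- stats::runif(1, 0, W)
    cy <- stats::runif(1, 0, H)
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 150, 500)
    x0 <- max(0, min(W, cx - len / 2 * cos(th)))
    y0 <- max(0, min(H, cy - len / 2 * sin(th)))
    x1 <- max(0, min(W, cx + len / 2 * cos(th)))
    y1 <- max(0, min(H, cy + len / 2 * sin(th)))
    if ((x0 - x1)^2 + (y0 - y1)^2 > 1) {
      segs[[length(segs) + 1]] <- c(x0, y0, x1, y1, 3)
    }
  }
  m <- do.call(rbind, segs)
  tibble::tibble(
    road_id = sprintf("R%03d", seq_len(nrow(m))),
    class = c("major", "secondary_tertiary", "minor")[m[, 5]],
    x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4]
  )
}

generate_eas <- function(config, extent, landcover, major_sec, water) {
  n <- config$n_eas
  W <- extent$xmax
  H <- extent$ymax
  n_rows <- max(1L, floor(sqrt(n)))
  base <- n %/% n_rows
  extra <- n %% n_rows
  cols_per_row <- rep(base, n_rows)
  if (extra > 0) cols_per_row[seq_len(extra)] <- base + 1L
  row_h <- H / n_rows
  rows <- list()
  id <- 0L
  for (i in seq_len(n_rows)) {
    k <- cols_per_row[i]
    col_w <- W / k
    for (j in seq_len(k)) {
      id <- id + 1L
      rows[[id]] <- tibble::tibble(
        ea_id = sprintf("EA%03d", id),
        row = i, col = j,
        xmin = (j - 1) * col_w, xmax = j * col_w,
        ymin = (i - 1) * row_h, ymax = i * row_h
      )
    }
  }
  eas <- dplyr::bind_rows(rows)

  cls <- landcover_classes()
  dens_by_class <- c(industrial_commercial = 2500,
                     informal_residential = 15000,
                     formal_residential = 6000,
                     other = 400) # people / km^2
  cx <- (eas$xmin + eas$xmax) / 2
  cy <- (eas$ymin + eas$ymax) / 2
  dom <- character(nrow(eas))
  for (i in seq_len(nrow(eas))) {
    sub <- raster_values_in_disk(landcover, cx[i], cy[i],
                                 max(eas$xmax[i] - eas$xmin[i],
                                     eas$ymax[i] - eas$ymin[i]) / 2)
    dom[i] <- cls[as.integer(names(which.max(table(sub))))]
  }
  area_km2 <- (eas$xmax - eas$xmin) * (eas$ymax - eas$ymin) / 1e6
  pop <- round(dens_by_class[dom] * area_km2 *
                 exp(stats::rnorm(nrow(eas), 0, 0.3)))
  # water-dominated EAs can end up near-empty
  if (nrow(water) > 0) {
    overlap <- pmax(0, pmin(eas$xmax, water$xmax[1]) - pmax(eas$xmin, water$xmin[1])) *
      pmax(0, pmin(eas$ymax, water$ymax[1]) - pmax(eas$ymin, water$ymin[1]))
    frac <- overlap / ((eas$xmax - eas$xmin) * (eas$ymax - eas$ymin))
    pop <- round(pop * (1 - frac))
  }
  d_major <- min_dist_to_segments(cx, cy, major_sec)
  exposure_z <- exp(-d_major / 300)
  # log-consumption (log currency): wealthier away from arterials
  ses_consumption <- 7.5 - 1.0 * exposure_z + stats::rnorm(nrow(eas), 0, 0.25)
  ses_rel <- ses_consumption - mean(ses_consumption)
  ses_education <- stats::rpois(nrow(eas),
                                pmax(0.5, pop * 0.08 * exp(0.8 * ses_rel)))
  ses_unemployed <- stats::rpois(nrow(eas),
                                 pmax(0.5, pop * 0.06 * exp(-0.5 * ses_rel)))
  eas$population <- pmax(0, as.numeric(pop))
  eas$dominant_landcover <- dom
  eas$ses_consumption <- ses_consumption
  eas$ses_education <- as.numeric(ses_education)
  eas$ses_unemployed <- as.numeric(ses_unemployed)
  attr(eas, "n_rows") <- n_rows
  attr(eas, "cols_per_row") <- cols_per_row
  attr(eas, "extent") <- extent
  eas
}

# EA containing each point, using the row/column partition structure.
ea_lookup <- function(eas, px, py) {
  n_rows <- attr(eas, "n_rows")
  cols_per_row <- attr(eas, "cols_per_row")
  extent <- attr(eas, "extent")
  H <- extent$ymax
  W <- extent$xmax
  row <- pmin(pmax(ceiling(py / (H / n_rows)), 1L), n_rows)
  first_id <- cumsum(c(0L, cols_per_row))[row]
  k <- cols_per_row[row]
  col <- pmin(pmax(ceiling(px / (W / k)), 1L), k)
  idx <- first_id + col
  eas$ea_id[idx]
}

generate_pois <- function(config, roads, extent, water) {
  cats <- poi_categories()
  n_per <- config$pois_per_category
  seg_len <- sqrt((roads$x1 - roads$x0)^2 + (roads$y1 - roads$y0)^2)
  out <- list()
  id <- 0L
  for (cat in cats) {
    for (i in seq_len(n_per)) {
      for (try in 1:25) {
        s <- sample.int(nrow(roads), 1, prob = seg_len)
        t <- stats::runif(1)
        px <- roads$x0[s] + t * (roads$x1[s] - roads$x0[s]) +
          stats::rnorm(1, 0, 120)
        py <- roads$y0[s] + t * (roads$y1[s] - roads$y0[s]) +
          stats::rnorm(1, 0, 120)
        px <- min(max(px, 0), extent$xmax)
        py <- min(max(py, 0), extent$ymax)
        if (nrow(water) == 0 || !any(point_in_rect(px, py, water))) break
      }
      id <- id + 1L
      out[[id]] <- tibble::tibble(poi_id = sprintf("P%04d", id),
                                  category = cat, x = px, y = py)
    }
  }
  dplyr::bind_rows(out)
}

generate_buildings <- function(config, landcover, extent, water, cls) {
  n <- config$n_buildings
  wts <- c(industrial_commercial = 2, informal_residential = 8,
           formal_residential = 4, other = 0.3)
  cell_w <- wts[cls[as.vector(landcover$values)]]
  centers <- raster_cell_centers(landcover)
  idx <- sample.int(length(cell_w), n, replace = TRUE, prob = cell_w)
  i <- (idx - 1L) %% landcover$nrow + 1L
  j <- (idx - 1L) %/% landcover$nrow + 1L
  bx <- centers$x[j] + stats::runif(n, -0.5, 0.5) * landcover$res
  by <- centers$y[i] + stats::runif(n, -0.5, 0.5) * landcover$res
  keep <- rep(TRUE, n)
  if (nrow(water) > 0) keep <- !point_in_rect(bx, by, water)
  tibble::tibble(building_id = sprintf("B%05d", seq_len(sum(keep))),
                 x = bx[keep], y = by[keep])
}

#' @export
print.city_layers <- function(x, ...) {
  cat("<city_layers> ",
      sprintf("%.0f x %.0f m", x$extent$xmax, x$extent$ymax), "\n", sep = "")
  cat("  roads:      ", nrow(x$roads), " segments (",
      paste(names(table(x$roads$class)), table(x$roads$class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  landcover:  ", x$landcover$nrow, "x", x$landcover$ncol, " @ ",
      x$landcover$res, " m\n", sep = "")
  cat("  ndvi:       ", x$ndvi$nrow, "x", x$ndvi$ncol, " @ ",
      x$ndvi$res, " m\n", sep = "")
  cat("  pois:       ", nrow(x$pois), "\n", sep = "")
  cat("  buildings:  ", nrow(x$buildings), "\n", sep = "")
  cat("  eas:        ", nrow(x$eas), " (pop ",
      format(sum(x$eas$population), big.mark = ","), ")\n", sep = "")
  cat("  water:      ", nrow(x$water), " polygon(s)\n", sep = "")
  invisible(x)
}
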