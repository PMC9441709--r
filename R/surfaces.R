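#' Prediction grid with an out-of-sample mask
#'
#' Lays a square grid over the city extent and masks out cells where the
#' models would extrapolate beyond the measured environments: cells
#' touching water, and cells of 'other' land cover (grassland/forest/bare)
#' containing no road at all. The land-cover class of a cell is read at its
#' center from the native-resolution raster.
#'
#' @param city A `city_layers` object.
#' @param cell_size_m Grid resolution (default 50 m).
#' @return Tibble `cell_id`, `row`, `col`, `x`, `y` (cell centers),
#'   `landcover_class`, `has_road`, `in_water`, `in_sample`; attributes
#'   `cell_size`, `extent`, `dims`.
#' @export
make_grid <- function(city, cell_size_m = 50) {
  stopifnot(inherits(city, "city_layers"), cell_size_m > 0)
  W <- city$extent$xmax
  H <- city$extent$ymax
  ncol_g <- max(1L, round(W / cell_size_m))
  nrow_g <- max(1L, round(H / cell_size_m))
  col <- rep(seq_len(ncol_g), each = nrow_g)
  row <- rep(seq_len(nrow_g), times = ncol_g)
  x <- (col - 0.5) * cell_size_m
  y <- (row - 0.5) * cell_size_m
  xmin <- (col - 1) * cell_size_m
  xmax <- col * cell_size_m
  ymin <- (row - 1) * cell_size_m
  ymax <- row * cell_size_m

  in_water <- rep(FALSE, length(x))
  for (w in seq_len(nrow(city$water))) {
    wr <- city$water[w, ]
    in_water <- in_water |
      (xmin < wr$xmax & xmax > wr$xmin & ymin < wr$ymax & ymax > wr$ymin)
  }
  has_road <- rep(FALSE, length(x))
  for (i in seq_len(nrow(city$roads))) {
    has_road <- has_road | seg_intersects_rect(
      city$roads$x0[i], city$roads$y0[i], city$roads$x1[i], city$roads$y1[i],
      xmin, xmax, ymin, ymax)
  }
  lc <- city$landcover_classes[raster_value_at(city$landcover, x, y)]
  in_sample <- !in_water & !(lc == "other" & !has_road)

  out <- tibble::tibble(
    cell_id = sprintf("C%05d", seq_along(x)),
    row = row, col = col, x = x, y = y,
    landcover_class = lc, has_road = has_road, in_water = in_water,
    in_sample = in_sample
  )
  attr(out, "cell_size") <- cell_size_m
  attr(out, "extent") <- city$extent
  attr(out, "dims") <- c(nrow = nrow_g, ncol = ncol_g)
  out
}

#' Predict hourly and aggregate noise surfaces
#'
#' Extracts features at masked-in cell centers (monitor height fixed at
#' 4 m), standardizes them with the models' stored parameters, then
#' predicts 24 hourly LAeq_1hr layers: hours 06-21 from the day model and
#' 22-05 from the night model, each with its hour-specific intercept.
#' Aggregate layers (LAeq_24hr, L_den, L_day, L_night) are computed per
#' cell from the 24 hourly values via [period_metrics()], so the
#' aggregation identity holds exactly. Masked cells carry no values.
#'
#' @param day_model,night_model Fitted `lur_model`s (same standardization).
#' @param city A `city_layers` object.
#' @param grid Optional [make_grid()] result (default 50 m grid).
#' @param catalogue,buffers Feature extraction settings; defaults match
#'   [extract_features()].
#' @return Object of class `noise_surface`: `grid`, `hourly` (matrix,
#'   masked-in cells x 24), `metrics` (tibble with the four aggregate
#'   layers for masked-in cells).
#' @export
predict_surfaces <- function(day_model, night_model, city, grid = NULL,
                             catalogue = feature_catalogue(),
                             buffers = buffer_spec()) {
  if (is.null(grid)) grid <- make_grid(city)
  mp_day <- day_model$standardization
  mp_night <- night_model$standardization
  if (is.null(mp_day) || is.null(mp_night) ||
      !isTRUE(all.equal(as.data.frame(mp_day), as.data.frame(mp_night),
                        tolerance = 1e-12))) {
    stop("predict_surfaces: day and night models carry different ",
         "standardization parameters", call. = FALSE)
  }
  cells <- grid[grid$in_sample, ]
  if (nrow(cells) == 0) {
    warning("predict_surfaces: no predictable cells (all masked out)",
            call. = FALSE)
    return(structure(list(grid = grid,
                          hourly = matrix(numeric(0), 0, 24),
                          metrics = tibble::tibble()),
                     class = "noise_surface"))
  }
  loc <- tibble::tibble(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                        monitor_height_m = 4)
  fm <- extract_features(loc, city, catalogue, buffers)
  fm <- apply_standardization(fm, mp_day)

  hourly <- matrix(NA_real_, nrow(cells), 24,
                   dimnames = list(cells$cell_id, as.character(0:23)))
  fixed_day <- predict_lur(day_model, fm)
  fixed_night <- predict_lur(night_model, fm)
  for (h in 0:23) {
    m <- if (h %in% day_hours()) day_model else night_model
    fixed <- if (h %in% day_hours()) fixed_day else fixed_night
    off <- if (as.character(h) %in% names(m$hour_intercepts)) {
      m$hour_intercepts[[as.character(h)]]
    } else 0
    hourly[, h + 1] <- fixed + off
  }
  agg <- period_metrics_matrix(hourly)
  metrics <- tibble::tibble(cell_id = cells$cell_id, x = cells$x,
                            y = cells$y, laeq_24hr = agg$laeq_24hr,
                            l_den = agg$l_den, l_day = agg$l_day,
                            l_night = agg$l_night)
  structure(list(grid = grid, hourly = hourly, metrics = metrics),
            class = "noise_surface")
}

#' @export
print.noise_surface <- function(x, ...) {
  dims <- attr(x$grid, "dims")
  cat(sprintf("<noise_surface> %d x %d cells @ %g m, %d predictable\n",
              dims["nrow"], dims["ncol"], attr(x$grid, "cell_size"),
              nrow(x$metrics)))
  if (nrow(x$metrics) > 0) {
    cat(sprintf("  L_den median %.1f dBA (IQR %.1f-%.1f)\n",
                stats::median(x$metrics$l_den),
                stats::quantile(x$metrics$l_den, 0.25),
                stats::quantile(x$metrics$l_den, 0.75)))
  }
  invisible(x)
}

#' Summarize predicted noise near each road class
#'
#' Median and interquartile range of each aggregate metric over the
#' masked-in cells lying within `buffer_m` of each road class. Classes
#' with no in-buffer cells are omitted with a warning.
#'
#' @param surface A `noise_surface`.
#' @param city The `city_layers` the surface was predicted on.
#' @param buffer_m Distance band around road lines (default 100 m).
#' @return Tidy tibble `road_class`, `metric`, `n_cells`, `median`, `q25`,
#'   `q75`.
#' @export
summarize_by_roads <- function(surface, city, buffer_m = 100) {
  met <- surface$metrics
  if (nrow(met) == 0) {
    stop("summarize_by_roads: surface has no predictable cells", call. = FALSE)
  }
  out <- list()
  for (rc in unique(city$roads$class)) {
    segs <- city$roads[city$roads$class == rc, ]
    d <- min_dist_to_segments(met$x, met$y, segs)
    sel <- d <= buffer_m
    if (!any(sel)) {
      warning("summarize_by_roads: no cells within ", buffer_m, " m of ",
              rc, " roads; class omitted", call. = FALSE)
      next
    }
    for (metric in c("laeq_24hr", "l_den", "l_day", "l_night")) {
      v <- met[[metric]][sel]
      out[[length(out) + 1]] <- tibble::tibble(
        road_class = rc, metric = metric, n_cells = sum(sel),
        median = stats::median(v),
        q25 = as.numeric(stats::quantile(v, 0.25)),
        q75 = as.numeric(stats::quantile(v, 0.75)))
    }
  }
  dplyr::bind_rows(out)
}
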