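test_that("road length in buffers matches chord-length geometry", {
  city <- fx_tiny_city()
  # replace the road network with one straight horizontal road through a
  # known location
  loc_x <- 700; loc_y <- 700
  city$roads <- tibble::tibble(road_id = "R1", class = "major",
                               x0 = 0, y0 = loc_y, x1 = 1500, y1 = loc_y)
  cat <- feature_catalogue()
  cat <- cat[cat$name == "major_roads", ]
  loc <- tibble::tibble(id = "L1", x = loc_x, y = loc_y)
  fm <- extract_features(loc, city, cat, buffers = c(50, 100, 200))
  # road through the center: chord = diameter
  expect_equal(fm$major_roads_50, 100, tolerance = 1e-9)
  expect_equal(fm$major_roads_100, 200, tolerance = 1e-9)
  expect_equal(fm$major_roads_200, 400, tolerance = 1e-9)

  # offset the location 60 m off the road: chord = 2*sqrt(r^2 - 60^2)
  loc2 <- tibble::tibble(id = "L2", x = loc_x, y = loc_y + 60)
  fm2 <- extract_features(loc2, city, cat, buffers = c(50, 100, 200))
  expect_equal(fm2$major_roads_50, 0)
  expect_equal(fm2$major_roads_100, 2 * sqrt(100^2 - 60^2), tolerance = 1e-9)
})

test_that("a site with no roads nearby has zero road-length features", {
  city <- fx_tiny_city()
  city$roads <- tibble::tibble(road_id = "R1", class = "major",
                               x0 = 0, y0 = 10, x1 = 1500, y1 = 10)
  cat <- feature_catalogue()
  cat <- cat[cat$statistic == "length_sum", ]
  loc <- tibble::tibble(id = "L1", x = 750, y = 1400)
  fm <- extract_features(loc, city, cat)
  for (cn in noiselur:::feature_columns(fm)) expect_equal(fm[[cn]], 0)
})

test_that("points on the closed buffer boundary are counted", {
  city <- fx_tiny_city()
  city$pois <- tibble::tibble(poi_id = "P1", category = "restaurant",
                              x = 800, y = 700) # exactly 100 m east
  cat <- feature_catalogue()
  cat <- cat[cat$name %in% c("restaurant_count", "restaurant_presence"), ]
  loc <- tibble::tibble(id = "L1", x = 700, y = 700)
  fm <- extract_features(loc, city, cat, buffers = c(50, 100))
  expect_equal(fm$restaurant_count_50, 0)
  expect_equal(fm$restaurant_count_100, 1)
  expect_equal(fm$restaurant_presence_100, 1)
})

test_that("nested buffers are monotone for sum and count statistics", {
  fm <- fx_small_features()
  cat <- attr(fm, "catalogue")
  buffers <- attr(fm, "buffers")
  mono_vars <- cat$name[cat$statistic %in%
                          c("length_sum", "area_sum", "point_count") &
                          cat$buffered]
  # standardized columns do not preserve ordering; test on the raw matrix
  raw <- extract_features(fx_small_sites(), fx_small_city())
  for (v in mono_vars) {
    cols <- intersect(noiselur:::feature_name(v, buffers), names(raw))
    for (k in seq_len(length(cols) - 1)) {
      expect_true(all(raw[[cols[k]]] <= raw[[cols[k + 1]]] + 1e-9),
                  info = v)
    }
  }
})

test_that("sqrt-distance features are consistent with distances", {
  raw <- extract_features(fx_small_sites(), fx_small_city())
  expect_equal(raw$sqrt_dist_major_road^2, raw$dist_major_road,
               tolerance = 1e-9)
  expect_equal(raw$sqrt_dist_secondary_road^2, raw$dist_secondary_road,
               tolerance = 1e-9)
  expect_equal(raw$sqrt_dist_airport^2, raw$dist_airport, tolerance = 1e-9)
})

test_that("NDVI buffer means omit negative (water) cells", {
  city <- fx_tiny_city()
  # force a block of negative NDVI next to the probe
  city$ndvi$values[,] <- 0.5
  city$ndvi$values[1:10, 1:10] <- -0.3
  cat <- feature_catalogue()
  cat <- cat[cat$name == "ndvi", ]
  loc <- tibble::tibble(id = "L1", x = 150, y = 150)
  fm <- extract_features(loc, city, cat, buffers = c(500))
  expect_equal(fm$ndvi_500, 0.5, tolerance = 1e-12)
})

test_that("standardization matches the hand z-score and round-trips", {
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 13)
  fm <- extract_features(sites, city)
  std <- suppressWarnings(standardize_features(fm))
  params <- attr(std, "standardization")
  expect_true(all(c("column", "mean", "sd", "standardized") %in% names(params)))
  # standardized columns have mean 0, sample SD 1 over the fitting set
  for (cn in params$column[params$standardized][1:5]) {
    expect_equal(mean(std[[cn]]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[cn]]), 1, tolerance = 1e-12)
  }
  # count variables stay raw
  cnt <- grep("_count_", params$column, value = TRUE)
  expect_false(any(params$standardized[params$column %in% cnt]))
  # applying stored params to the raw matrix reproduces the z-scores
  back <- apply_standardization(fm, std)
  for (cn in intersect(params$column, names(back))) {
    expect_equal(back[[cn]], std[[cn]], tolerance = 1e-12)
  }
})

test_that("two-point column standardizes to +-1/sqrt(2) with sample SD", {
  x <- c(0, 10)
  z <- (x - mean(x)) / sd(x)
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # the same convention is used by standardize_features (ddof = 1)
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 13)
  fm <- extract_features(sites, city)
  std <- suppressWarnings(standardize_features(fm))
  p <- attr(std, "standardization")
  cn <- p$column[p$standardized][1]
  expect_equal(sd(fm[[cn]]), p$sd[p$column == cn], tolerance = 1e-12)
})

test_that("zero-variance columns are excluded with a warning", {
  city <- fx_tiny_city()
  city$water <- city$water[0, ] # no water anywhere -> water_area constant 0
  sites <- place_sites(city, 6, 2, seed = 13)
  fm <- extract_features(sites, city)
  expect_warning(std <- standardize_features(fm), "zero-variance")
  expect_false("water_area_50" %in% names(std))
})

test_that("locations outside the extent and bad radii error", {
  city <- fx_tiny_city()
  loc <- tibble::tibble(id = "L1", x = 1e6, y = 0)
  expect_error(extract_features(loc, city), "extent")
  expect_error(buffer_spec(c(100, 50)), "increasing")
  expect_error(buffer_spec(c(-5, 50)), "increasing|positive")
})
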