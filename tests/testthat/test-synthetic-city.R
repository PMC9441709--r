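test_that("generate_city is deterministic and honours the config", {
  cfg <- city_config(width_m = 1500, height_m = 1500, n_eas = 9,
                     n_minor = 12, n_buildings = 200)
  a <- generate_city(cfg, seed = 5)
  b <- generate_city(cfg, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a$eas), 9)
  expect_setequal(unique(a$roads$class),
                  c("major", "secondary_tertiary", "minor"))
  expect_true(all(a$ndvi$values >= -1 & a$ndvi$values <= 1))
  expect_true(all(a$eas$population >= 0))
  # every land-cover class present
  expect_setequal(sort(unique(as.vector(a$landcover$values))), 1:4)
})

test_that("EA polygons partition the extent without overlap", {
  city <- fx_tiny_city()
  eas <- city$eas
  areas <- (eas$xmax - eas$xmin) * (eas$ymax - eas$ymin)
  expect_equal(sum(areas), city$extent$xmax * city$extent$ymax)
  # lookup agrees with direct rectangle containment for random points
  set.seed(6)
  px <- runif(200, 0, city$extent$xmax)
  py <- runif(200, 0, city$extent$ymax)
  ids <- noiselur:::ea_lookup(eas, px, py)
  for (k in sample(200, 25)) {
    row <- eas[eas$ea_id == ids[k], ]
    expect_true(px[k] >= row$xmin && px[k] <= row$xmax &&
                  py[k] >= row$ymin && py[k] <= row$ymax)
  }
})

test_that("water_fraction = 0 removes all water", {
  cfg <- city_config(width_m = 1200, height_m = 1200, n_eas = 4,
                     n_minor = 8, n_buildings = 100, water_fraction = 0)
  city <- generate_city(cfg, seed = 7)
  expect_equal(nrow(city$water), 0)
  grid <- make_grid(city, 50)
  expect_false(any(grid$in_water))
})

test_that("config validation rejects impossible cities", {
  expect_error(city_config(width_m = -1), "positive")
  expect_error(city_config(landcover_res_m = 0), "positive")
  expect_error(city_config(water_fraction = 1.2), "water_fraction")
})

test_that("site placement is stratified, deterministic, and avoids water", {
  city <- fx_tiny_city()
  s <- place_sites(city, n_rotating = 136, n_fixed = 10, seed = 8)
  expect_equal(nrow(s), 146)
  expect_equal(sum(s$kind == "fixed"), 10)
  expect_identical(s, place_sites(city, 136, 10, seed = 8))
  # inside extent, not in water
  expect_true(all(s$x >= 0 & s$x <= city$extent$xmax))
  for (w in seq_len(nrow(city$water))) {
    expect_false(any(noiselur:::point_in_rect(s$x, s$y, city$water[w, ])))
  }
  # two seeds: different coordinates, same stratum tallies (allocation
  # depends only on the city)
  s2 <- place_sites(city, 136, 10, seed = 9)
  expect_false(all(s$x == s2$x))
  expect_equal(table(s$land_use_class), table(s2$land_use_class))
})

test_that("single-site and degenerate placements work", {
  city <- fx_tiny_city()
  s <- place_sites(city, n_rotating = 0, n_fixed = 1, seed = 1,
                   stratify = FALSE)
  expect_equal(nrow(s), 1)
  expect_error(place_sites(city, 1, 1, seed = 1), "stratified")
})

test_that("a noiseless truth yields exactly constant levels", {
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 3)
  tm <- truth_model(beta0 = 60, betas = setNames(numeric(0), character(0)),
                    hour_effects = rep(0, 24), sigma_site = 0,
                    sigma_resid = 0, event_rate = 0, event_gain = 0)
  m <- simulate_minute_levels(city, sites, tm, days_per_site = 1, seed = 1)
  expect_true(all(m$laeq_1min_dba == 60))
  expect_equal(nrow(m), 8 * 1440)
})

test_that("event minutes equal the closed-form energetic sum", {
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 3)
  tm <- truth_model(beta0 = 60, betas = setNames(numeric(0), character(0)),
                    hour_effects = rep(0, 24), sigma_site = 0,
                    sigma_resid = 0, event_rate = 3, event_gain = 10)
  m <- simulate_minute_levels(city, sites, tm, days_per_site = 1, seed = 2)
  lv <- unique(round(m$laeq_1min_dba, 9))
  # base 60 and event minutes at 10 log10(10^6 + 10^7) = 70.4139...
  expect_setequal(lv, round(c(60, 10 * log10(1e6 + 1e7)), 9))
  ev <- m$laeq_1min_dba > 65
  expect_equal(max(abs(m$laeq_1min_dba[ev] - 10 * log10(1e6 + 1e7))), 0,
               tolerance = 1e-9)
  # Poisson(3)/hour over 8 sites x 24 h: event count in a sane band
  expect_gt(mean(ev) * 60, 1.5)
  expect_lt(mean(ev) * 60, 4.5)
})

test_that("minute residual SD matches sigma_resid", {
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 3)
  tm <- truth_model(beta0 = 60, betas = setNames(numeric(0), character(0)),
                    hour_effects = rep(0, 24), sigma_site = 0,
                    sigma_resid = 3, event_rate = 0, event_gain = 0)
  m <- simulate_minute_levels(city, sites, tm, days_per_site = 2, seed = 4)
  expect_gt(nrow(m), 10000)
  sds <- tapply(m$laeq_1min_dba, m$site_id, sd)
  expect_true(all(abs(sds - 3) < 0.15))
})

test_that("unknown truth beta names are a configuration error", {
  city <- fx_tiny_city()
  sites <- place_sites(city, 6, 2, seed = 3)
  tm <- truth_model(betas = c(not_a_feature_42 = 1))
  expect_error(simulate_minute_levels(city, sites, tm, 1, seed = 1),
               "not_a_feature_42")
})

test_that("truth_model validates its parameters", {
  expect_error(truth_model(sigma_site = -1), "non-negative")
  expect_error(truth_model(hour_effects = rep(0, 23)), "24")
  expect_error(truth_model(betas = c(1, 2)), "named")
})
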