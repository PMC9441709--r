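test_that("a deterministic simulation is recovered exactly", {
  city <- fx_small_city()
  sites <- fx_small_sites()
  fm <- fx_small_features()
  tm <- truth_model(beta0 = 60,
                    betas = c(major_roads_100 = 2.5, ndvi_50 = -2.8),
                    hour_effects = rep(0, 24), sigma_site = 0,
                    sigma_resid = 0, event_rate = 0, event_gain = 0)
  minutes <- simulate_minute_levels(city, sites, tm, days_per_site = 1,
                                    seed = 31, features = fm)
  hourly <- hourly_levels(minutes)
  m <- fit_lur(hourly, fm, c("major_roads_100", "ndvi_50"), "day")
  co <- m$coefficients
  expect_equal(co$estimate[co$term == "major_roads_100"], 2.5,
               tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "ndvi_50"], -2.8, tolerance = 1e-6)
  expect_equal(m$r2_fixed, 1, tolerance = 1e-9)
})

test_that("an empty variable set yields an intercept + height model", {
  sim <- fx_small_sim()
  m <- fit_lur(sim$hourly, sim$features, character(), "day")
  expect_equal(sort(m$coefficients$term),
               sort(c("(Intercept)", "monitor_height_m")))
  expect_lt(m$r2_fixed, 0.2)
  # day model only covers day hours
  expect_setequal(as.integer(names(m$hour_intercepts)), 6:21)
  n <- fit_lur(sim$hourly, sim$features, character(), "night")
  expect_setequal(as.integer(names(n$hour_intercepts)), c(22, 23, 0:5))
})

test_that("singular designs fail loudly, naming the offending column", {
  sim <- fx_small_sim()
  fm <- sim$features
  fm$dup_col <- fm$major_roads_100
  attr(fm, "standardization") <- attr(sim$features, "standardization")
  expect_error(fit_lur(sim$hourly, fm, c("major_roads_100", "dup_col"), "day"),
               "dup_col")
})

test_that("refitting on shuffled rows gives identical coefficients", {
  sim <- fx_small_sim()
  m1 <- fit_lur(sim$hourly, sim$features, c("major_roads_100", "ndvi_50"),
                "day")
  set.seed(41)
  shuffled <- sim$hourly[sample(nrow(sim$hourly)), ]
  m2 <- fit_lur(shuffled, sim$features, c("major_roads_100", "ndvi_50"),
                "day")
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("best buffer screening finds the truth's radius and applies signs", {
  sim <- fx_small_sim()
  scr <- best_buffer_per_variable(sim$hourly, sim$features, "day")
  expect_true(all(c("variable", "feature", "buffer", "r", "direction_ok")
                  %in% names(scr)))
  # truth has major_roads at 100 m; the strongest road signal sits at or
  # adjacent to the generating buffer
  mr <- scr[scr$variable == "major_roads", ]
  expect_true(mr$buffer %in% c(50, 100, 200))
  expect_gt(mr$r, 0)
  nd <- scr[scr$variable == "ndvi", ]
  expect_lt(nd$r, 0) # greenness is quieter; sign matches expectation
  expect_true(nd$direction_ok)
})

test_that("sign-contradicting variables are excluded from candidates", {
  sim <- fx_small_sim()
  scr <- best_buffer_per_variable(sim$hourly, sim$features, "day")
  scr$direction_ok[scr$variable == "major_roads"] <- FALSE
  cands <- screen_candidates(scr)
  expect_false(any(grepl("^major_roads", cands)))
  # with the constraint off they return
  cands2 <- screen_candidates(scr, selection_config(sign_constraint = FALSE))
  expect_true(any(grepl("^major_roads", cands2)))
})

test_that("the stability rule retains modest-but-plausible coefficients", {
  # rule: drop iff CI crosses zero AND |t| < 1; the canonical cases
  expect_false(noiselur:::is_unstable(0.8, -0.4, 2.0, 0.8 / 0.6))
  expect_true(noiselur:::is_unstable(0.1, -2.0, 2.2, 0.1 / 1.07))
  expect_false(noiselur:::is_unstable(2.5, 1.2, 3.7, 2.5 / 0.64))
})

test_that("duplicated candidates cannot both enter the model", {
  sim <- fx_small_sim()
  fm <- sim$features
  fm$mr_copy <- fm$major_roads_100
  attr(fm, "standardization") <- attr(sim$features, "standardization")
  attr(fm, "catalogue") <- attr(sim$features, "catalogue")
  attr(fm, "buffers") <- attr(sim$features, "buffers")
  m <- forward_stepwise(sim$hourly, fm,
                        c("major_roads_100", "mr_copy", "ndvi_50"), "day")
  expect_false(all(c("major_roads_100", "mr_copy") %in% m$variables))
})

test_that("inert candidates produce an intercept-only model", {
  city <- fx_small_city()
  sites <- fx_small_sites()
  fm <- fx_small_features()
  # noiseless null truth: no candidate can clear the R2 gain threshold
  tm <- truth_model(beta0 = 60, betas = setNames(numeric(0), character(0)),
                    sigma_site = 0, sigma_resid = 0,
                    event_rate = 0, event_gain = 0)
  minutes <- simulate_minute_levels(city, sites, tm, days_per_site = 2,
                                    seed = 43, features = fm)
  hourly <- hourly_levels(minutes)
  m <- forward_stepwise(hourly, fm,
                        c("elevation_100", "school_count_200", "dist_airport"),
                        "day")
  expect_length(m$variables, 0)
  expect_warning(forward_stepwise(hourly, fm, character(), "day"),
                 "no candidates")
})

test_that("selection trace records every decision and is deterministic", {
  sim <- fx_small_sim()
  scr <- best_buffer_per_variable(sim$hourly, sim$features, "day")
  cands <- head(screen_candidates(scr), 6)
  m1 <- forward_stepwise(sim$hourly, sim$features, cands, "day")
  m2 <- forward_stepwise(sim$hourly, sim$features, cands, "day")
  expect_identical(m1$variables, m2$variables)
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate)
  expect_true(all(c("add", "stop") %in% c(m1$trace$action, "stop")))
  # accepted adds never decrease r2
  adds <- m1$trace[m1$trace$action == "add", ]
  if (nrow(adds) > 0) expect_true(all(adds$r2_after >= adds$r2_before))
})

test_that("VIFs are 1 for orthogonal predictors and explode near collinearity", {
  set.seed(44)
  n <- 200
  fm <- tibble::tibble(id = sprintf("S%03d", 1:n),
                       x = runif(n), y = runif(n), monitor_height_m = 4,
                       a = rnorm(n), b = rnorm(n))
  fm$c <- fm$a + rnorm(n, 0, 1e-4)
  v1 <- vif_lur(c("a", "b"), fm)
  expect_equal(v1$vif, c(1, 1), tolerance = 0.1)
  v2 <- vif_lur(c("a", "c"), fm)
  expect_true(all(v2$vif > 10))
  fm$d <- fm$a
  v3 <- vif_lur(c("a", "d"), fm)
  expect_true(all(is.infinite(v3$vif)))
})

test_that("IR models recover constructed signs and handle degenerate input", {
  set.seed(45)
  n <- 60
  sites <- tibble::tibble(site_id = sprintf("S%03d", 1:n),
                          land_use_class = rep(c("industrial_commercial",
                                                 "formal_residential"),
                                               length.out = n))
  fm <- tibble::tibble(site_id = sites$site_id,
                       x = runif(n), y = runif(n), monitor_height_m = 4,
                       major_roads_100 = rnorm(n),
                       elevation_100 = rnorm(n))
  attr(fm, "catalogue") <- tibble::tibble(
    name = c("major_roads", "elevation"), layer = c("roads", "dem"),
    statistic = c("length_sum", "raster_mean"),
    expected_sign = c("+", "either"), standardize = TRUE, buffered = TRUE)
  attr(fm, "buffers") <- c(100)
  class(fm) <- c("feature_matrix", class(fm))
  l_day <- 60 + 3 * fm$major_roads_100 + rnorm(n, 0, 1)
  ir_day <- 40 - 6 * fm$major_roads_100 + 0.5 * l_day + rnorm(n, 0, 2)
  sm <- tibble::tibble(site_id = sites$site_id, ir_day = ir_day,
                       ir_night = 30, # constant: nothing to model
                       l_day = l_day, l_night = l_day - 7)
  irm <- fit_ir_models(sm, fm, sites, interaction = FALSE)
  co <- irm$day$coefficients
  expect_true("major_roads_100" %in% co$term)
  expect_lt(co$estimate[co$term == "major_roads_100"], 0)
  # near-constant night IR: nothing clears the gain threshold
  expect_length(irm$night$variables, 0)
})

test_that("IR interaction is dropped with a warning for single-class data", {
  set.seed(46)
  n <- 40
  sites <- tibble::tibble(site_id = sprintf("S%03d", 1:n),
                          land_use_class = "formal_residential")
  fm <- tibble::tibble(site_id = sites$site_id,
                       x = runif(n), y = runif(n), monitor_height_m = 4,
                       major_roads_100 = rnorm(n))
  attr(fm, "catalogue") <- tibble::tibble(
    name = "major_roads", layer = "roads", statistic = "length_sum",
    expected_sign = "+", standardize = TRUE, buffered = TRUE)
  attr(fm, "buffers") <- c(100)
  class(fm) <- c("feature_matrix", class(fm))
  l_day <- 60 + rnorm(n)
  sm <- tibble::tibble(site_id = sites$site_id,
                       ir_day = 20 + 2 * l_day + rnorm(n),
                       ir_night = 20 + 2 * l_day + rnorm(n),
                       l_day = l_day, l_night = l_day - 7)
  expect_warning(fit_ir_models(sm, fm, sites, interaction = TRUE),
                 "single land-use class")
})

test_that("tidy and glance expose broom-style summaries", {
  sim <- fx_small_sim()
  m <- fit_lur(sim$hourly, sim$features, c("major_roads_100", "ndvi_50"),
               "day")
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
  gl <- glance(m)
  expect_equal(gl$n_predictors, 2)
  expect_true(gl$r2_fixed >= 0 && gl$r2_fixed <= 1)
})
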