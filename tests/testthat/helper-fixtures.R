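# Shared fixtures, built once per test run and cached (city generation and
# feature extraction dominate test runtime).

.fx <- new.env(parent = emptyenv())

fx_tiny_city <- function() {
  if (is.null(.fx$tiny_city)) {
    .fx$tiny_city <- generate_city(
      city_config(width_m = 1500, height_m = 1500, n_eas = 9, n_minor = 12,
                  n_buildings = 200),
      seed = 11)
  }
  .fx$tiny_city
}

fx_small_city <- function() {
  if (is.null(.fx$small_city)) {
    .fx$small_city <- generate_city(
      city_config(width_m = 2500, height_m = 2500, n_eas = 25, n_minor = 30,
                  n_buildings = 800),
      seed = 12)
  }
  .fx$small_city
}

fx_small_sites <- function() {
  if (is.null(.fx$small_sites)) {
    .fx$small_sites <- place_sites(fx_small_city(), n_rotating = 36,
                                   n_fixed = 4, seed = 12)
  }
  .fx$small_sites
}

fx_small_features <- function() {
  if (is.null(.fx$small_features)) {
    fm <- extract_features(fx_small_sites(), fx_small_city())
    .fx$small_features <- suppressWarnings(standardize_features(fm))
  }
  .fx$small_features
}

# deterministic small simulation shared by lur / evaluation tests
fx_small_sim <- function() {
  if (is.null(.fx$small_sim)) {
    minutes <- simulate_minute_levels(
      fx_small_city(), fx_small_sites(), truth_model(),
      days_per_site = 3, seed = 21, features = fx_small_features())
    .fx$small_sim <- list(minutes = minutes,
                          hourly = hourly_levels(minutes),
                          features = attr(minutes, "features"))
  }
  .fx$small_sim
}

# full campaign-scale fixture: default 4x4 km city, 140 sites
fx_campaign <- function() {
  if (is.null(.fx$campaign)) {
    city <- generate_city(city_config(), seed = 100)
    sites <- place_sites(city, n_rotating = 130, n_fixed = 10, seed = 100)
    fm <- suppressWarnings(standardize_features(extract_features(sites, city)))
    .fx$campaign <- list(city = city, sites = sites, features = fm)
  }
  .fx$campaign
}

# a minute-level tibble from raw vectors (hour-aligned, single day)
make_minutes <- function(levels, site_id = "S1",
                         start = "2020-01-06 00:00:00") {
  tibble::tibble(
    site_id = site_id,
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_along(levels) - 1L) * 60,
    laeq_1min_dba = levels
  )
}

# independent brute-force intermittency ratio: plain loop over minutes
ir_oracle <- function(levels, offset_c = 3) {
  e_total <- 0
  for (l in levels) e_total <- e_total + 10^(l / 10)
  k <- 10 * log10(e_total / length(levels)) + offset_c
  e_event <- 0
  for (l in levels) if (l >= k) e_event <- e_event + 10^(l / 10)
  min(max(100 * e_event / e_total, 0), 100)
}

# independent Moran's I with row-standardized inverse-distance weights
morans_oracle <- function(z, x, y) {
  n <- length(z)
  z <- z - mean(z)
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j) w[i, j] <- 1 / sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  }
  w <- w / rowSums(w)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}
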