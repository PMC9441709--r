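#' Ground-truth data-generating model for simulated sound levels
#'
#' The truth is a linear noise field on standardized spatial predictors plus
#' a fixed diurnal profile, site random intercepts, minute-level Gaussian
#' residuals, and intermittent sound events added energetically. Recovering
#' these parameters from simulated measurements is how every downstream
#' stage of the pipeline is validated.
#'
#' Default coefficients follow the magnitudes typical of urban noise LUR
#' models (a few dBA per standard deviation for road length, a negative
#' effect for greenness): major-road length +2.5, secondary/tertiary road
#' length +1.8, formal-residential area -0.8, NDVI -2.8, population density
#' +0.8 dBA per SD. The default diurnal profile has a higher day block than
#' night block (roughly a 7 dBA day-night gap), mirroring a city that quiets
#' at night but never fully sleeps.
#'
#' @param beta0 Intercept (dBA), the citywide base level.
#' @param betas Named numeric vector: dBA per standardized unit of each
#'   predictor (names must match feature-matrix columns, e.g.
#'   `major_roads_100`).
#' @param hour_effects Numeric length 24, dBA offsets for hours 0-23.
#' @param sigma_site SD of site random intercepts (dBA).
#' @param sigma_resid SD of minute-level residuals (dBA).
#' @param event_rate Expected intermittent events per hour (Poisson).
#' @param event_gain dBA added energetically on an event minute.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(beta0 = 60,
                        betas = c(major_roads_100 = 2.5,
                                  secondary_roads_200 = 1.8,
                                  landcover_formal_200 = -0.8,
                                  ndvi_50 = -2.8,
                                  pop_density_500 = 0.8),
                        hour_effects = default_hour_effects(),
                        sigma_site = 2, sigma_resid = 3,
                        event_rate = 2, event_gain = 12) {
  if (length(hour_effects) != 24) {
    stop("truth_model: hour_effects must have length 24", call. = FALSE)
  }
  if (sigma_site < 0 || sigma_resid < 0 || event_rate < 0 || event_gain < 0) {
    stop("truth_model: sigma_site, sigma_resid, event_rate and event_gain ",
         "must be non-negative", call. = FALSE)
  }
  if (length(betas) > 0 && is.null(names(betas))) {
    stop("truth_model: betas must be named by predictor", call. = FALSE)
  }
  structure(
    list(beta0 = beta0, betas = betas, hour_effects = as.numeric(hour_effects),
         sigma_site = sigma_site, sigma_resid = sigma_resid,
         event_rate = event_rate, event_gain = event_gain),
    class = "truth_model"
  )
}

#' Default diurnal profile (dBA offsets for hours 0-23)
#'
#' Morning and evening traffic peaks, a steady daytime plateau, and a quiet
#' small-hours trough; the day block (06-21) averages about 7 dBA above the
#' night block (22-05).
#' @return Numeric vector of length 24.
#' @export
default_hour_effects <- function() {
  c(-5, -5.5, -6, -6, -5.5, -4,            # 00-05
    0, 2, 3.5, 3.5, 3, 2.5, 2.5, 2.5,      # 06-13
    2.5, 2.5, 3, 3.5, 3.5, 3, 2, 1,        # 14-21
    -2, -3.5)                              # 22-23
}

#' Simulate minute-resolution A-weighted sound levels
#'
#' For each site and minute the base level is
#' `beta0 + sum(beta_k * x_k) + hour_effect + site_intercept + resid`,
#' with `x_k` the site's standardized spatial predictors. Intermittent
#' events arrive as a Poisson count per hour; on an event minute the event
#' energy is added energetically:
#' `L = 10 log10(10^(base/10) + 10^((base + gain)/10))`.
#'
#' @param city A `city_layers` object.
#' @param sites Site tibble from [place_sites()].
#' @param truth A [truth_model()].
#' @param days_per_site Integer vector recycled over sites; default 7 days
#'   for rotating sites and 30 for fixed sites (a desk-scale version of an
#'   unbalanced campaign).
#' @param seed Integer seed.
#' @param start_date First day of measurement (all sites start together;
#'   the city has no weather or season, so calendar alignment is
#'   inconsequential).
#' @param features Optional precomputed standardized feature matrix for the
#'   sites (saves re-extraction in simulation loops).
#' @return A tibble (`site_id`, `timestamp`, `laeq_1min_dba`) with
#'   attributes `features` (the standardized site feature matrix),
#'   `site_effects` (drawn random intercepts) and `truth`.
#' @examples
#' city <- generate_city(city_config(width_m = 1200, height_m = 1200,
#'                                   n_eas = 9, n_minor = 10,
#'                                   n_buildings = 150), seed = 2)
#' sites <- place_sites(city, n_rotating = 8, n_fixed = 2, seed = 2)
#' minutes <- simulate_minute_levels(city, sites,
#'                                   truth_model(event_rate = 1),
#'                                   days_per_site = 1, seed = 2)
#' head(minutes)
#' @export
simulate_minute_levels <- function(city, sites, truth = truth_model(),
                                   days_per_site = NULL, seed = 1L,
                                   start_date = "2020-01-06",
                                   features = NULL) {
  stopifnot(inherits(truth, "truth_model"))
  if (is.null(days_per_site)) {
    days_per_site <- ifelse(sites$kind == "fixed", 30L, 7L)
  }
  days_per_site <- rep(as.integer(days_per_site), length.out = nrow(sites))
  if (any(days_per_site < 1)) {
    stop("simulate_minute_levels: days_per_site must be >= 1", call. = FALSE)
  }
  if (is.null(features)) {
    features <- extract_features(sites, city)
    features <- standardize_features(features)
  }
  miss <- setdiff(names(truth$betas), names(features))
  if (length(miss) > 0) {
    stop("simulate_minute_levels: truth betas not in the feature catalogue: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n_sites <- nrow(sites)
  X <- as.matrix(features[, names(truth$betas), drop = FALSE])
  fixed_site <- truth$beta0 + as.numeric(X %*% truth$betas)
  site_int <- stats::rnorm(n_sites, 0, truth$sigma_site)

  origin <- as.POSIXct(paste0(start_date, " 00:00:00"), tz = "UTC")
  per_site <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    n_min <- days_per_site[s] * 1440L
    minute_of_day <- (seq_len(n_min) - 1L) %% 1440L
    hour <- minute_of_day %/% 60L
    base <- fixed_site[s] + site_int[s] + truth$hour_effects[hour + 1L] +
      stats::rnorm(n_min, 0, truth$sigma_resid)
    lvl <- base
    if (truth$event_rate > 0 && truth$event_gain > 0) {
      n_hr <- days_per_site[s] * 24L
      k <- stats::rpois(n_hr, truth$event_rate)
      k <- pmin(k, 60L)
      if (any(k > 0)) {
        hr_id <- rep(seq_len(n_hr), each = 60L)
        u <- stats::runif(n_min)
        pos <- integer(n_min)
        o <- order(hr_id, u)
        # after sorting by (hour, u) every hour is a consecutive block of 60
        pos[o] <- rep.int(seq_len(60L), n_hr)
        is_event <- pos <= k[hr_id]
        lvl[is_event] <- base[is_event] +
          10 * log10(1 + 10^(truth$event_gain / 10))
      }
    }
    per_site[[s]] <- tibble::tibble(
      site_id = sites$site_id[s],
      timestamp = origin + (seq_len(n_min) - 1L) * 60,
      laeq_1min_dba = lvl
    )
  }
  out <- dplyr::bind_rows(per_site)
  attr(out, "features") <- features
  attr(out, "site_effects") <- stats::setNames(site_int, sites$site_id)
  attr(out, "truth") <- truth
  out
}
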