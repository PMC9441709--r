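#' Validated run configuration for the full pipeline
#'
#' Merges user settings over the defaults and rejects unknown keys, so a
#' typo in a config file fails loudly instead of silently running the
#' defaults. The resolved configuration is serialized into every output
#' directory for provenance.
#'
#' @param x Named list of overrides (possibly nested), or a path to a YAML
#'   or JSON file.
#' @return List of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.json$", x)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  }
  defaults <- list(
    seed = 1L,
    city = unclass(city_config()),
    sites = list(n_rotating = 136L, n_fixed = 10L,
                 days_rotating = 7L, days_fixed = 30L),
    truth = list(beta0 = 60, sigma_site = 2, sigma_resid = 3,
                 event_rate = 2, event_gain = 12),
    buffers = c(50, 100, 200, 500),
    selection = list(r2_gain_threshold = 0.01, collinearity_r = 0.8,
                     sign_constraint = TRUE, stability_t = 1,
                     vif_report = TRUE),
    cv = list(scheme = "cv10_sites"),
    grid = list(cell_size_m = 50),
    exposure = list(bin_width = 5,
                    thresholds = list(l_den = 53, l_night = 45)),
    ir = list(offset_c = 3, interaction = TRUE)
  )
  merged <- merge_config(defaults, x, path = "")
  structure(merged, class = "run_config")
}

merge_config <- function(defaults, user, path) {
  if (length(user) == 0) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("run_config: unknown key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# one global seed fans out to per-stage child seeds so stages are
# independently re-runnable; offsets are arbitrary small constants
stage_seed <- function(seed, stage) {
  offs <- c(city = 11L, sites = 23L, simulate = 37L, cv = 53L,
            exposure = 71L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full noise-LUR pipeline on a synthetic city
#'
#' Chains every stage: city generation, site placement, minute-level
#' simulation, acoustic metrics, feature extraction, day/night model
#' selection, cross-validation, surface prediction, population exposure,
#' SES inequality, and intermittency-ratio models. Each stage writes its
#' artifacts (CSV/JSON/GeoJSON/ASCII grid) under `out_dir`, along with the
#' resolved configuration, the package version and a log including the
#' selection traces. Deterministic for a fixed config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (default all, in
#'   order): `simulate`, `metrics`, `features`, `fit`, `cv`, `predict`,
#'   `exposure`, `ir`. Later stages read earlier artifacts from `out_dir`
#'   when their in-memory inputs are absent.
#' @return Invisible list with every stage's objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir = "noiselur_run",
                         stages = c("simulate", "metrics", "features", "fit",
                                    "cv", "predict", "exposure", "ir")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(paste0(..., "\n"), file = logf, append = TRUE)
  }
  unlink(logf)
  jsonlite::write_json(
    list(config = unclass(config),
         package_version = as.character(utils::packageVersion("noiselur"))),
    file.path(out_dir, "resolved_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- list(config = config)
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("run_pipeline: stage '", stage, "' needs missing artifact ", path,
           "; run the earlier stages first", call. = FALSE)
    }
    path
  }

  if ("simulate" %in% stages) {
    log_line("stage simulate")
    city <- generate_city(do.call(city_config, config$city),
                          seed = stage_seed(config$seed, "city"))
    sites <- place_sites(city, config$sites$n_rotating, config$sites$n_fixed,
                         seed = stage_seed(config$seed, "sites"))
    truth <- truth_model(beta0 = config$truth$beta0,
                         sigma_site = config$truth$sigma_site,
                         sigma_resid = config$truth$sigma_resid,
                         event_rate = config$truth$event_rate,
                         event_gain = config$truth$event_gain)
    days <- ifelse(sites$kind == "fixed", config$sites$days_fixed,
                   config$sites$days_rotating)
    minutes <- simulate_minute_levels(city, sites, truth, days,
                                      seed = stage_seed(config$seed, "simulate"))
    write_city(city, file.path(out_dir, "city"))
    readr::write_csv(sites, file.path(out_dir, "sites.csv"), progress = FALSE)
    write_minutes_csv(minutes, file.path(out_dir, "minutes.csv"))
    res$city <- city; res$sites <- sites; res$truth <- truth
    res$minutes <- minutes
  }

  if ("metrics" %in% stages) {
    log_line("stage metrics")
    minutes <- res$minutes %||%
      read_minutes_csv(need(file.path(out_dir, "minutes.csv"), "metrics"))
    metrics <- site_noise_metrics(minutes, offset_c = config$ir$offset_c)
    readr::write_csv(metrics, file.path(out_dir, "site_metrics.csv"),
                     progress = FALSE)
    res$hourly <- hourly_levels(minutes)
    res$site_metrics <- metrics
  }

  if ("features" %in% stages) {
    log_line("stage features")
    city <- res$city %||% stop("run_pipeline: features stage requires the ",
                               "simulate stage in the same call", call. = FALSE)
    sites <- res$sites
    fm <- extract_features(sites, city, buffers = buffer_spec(config$buffers))
    fm <- standardize_features(fm)
    write_feature_csv(fm, file.path(out_dir, "features.csv"))
    res$features <- fm
  }

  sel_cfg <- selection_config(
    r2_gain_threshold = config$selection$r2_gain_threshold,
    collinearity_r = config$selection$collinearity_r,
    sign_constraint = config$selection$sign_constraint,
    stability_t = config$selection$stability_t,
    vif_report = config$selection$vif_report)

  if ("fit" %in% stages) {
    log_line("stage fit")
    hourly <- res$hourly
    fm <- res$features
    for (period in c("day", "night")) {
      screen <- best_buffer_per_variable(hourly, fm, period)
      cands <- screen_candidates(screen, sel_cfg)
      m <- forward_stepwise(hourly, fm, cands, period, sel_cfg)
      write_lur_json(m, file.path(out_dir, paste0("model_", period, ".json")))
      log_line("selection trace (", period, "):")
      log_line(paste(utils::capture.output(as.data.frame(m$trace)),
                     collapse = "\n"))
      res[[paste0("model_", period)]] <- m
    }
  }

  if ("cv" %in% stages) {
    log_line("stage cv")
    rows <- list()
    for (period in c("day", "night")) {
      m <- res[[paste0("model_", period)]]
      cv <- cross_validate(res$hourly, res$features, m$variables, period,
                           scheme = config$cv$scheme,
                           seed = stage_seed(config$seed, "cv"))
      rows[[period]] <- cv$pooled
      res[[paste0("cv_", period)]] <- cv
    }
    readr::write_csv(dplyr::bind_rows(rows), file.path(out_dir, "cv.csv"),
                     progress = FALSE)
  }

  if ("predict" %in% stages) {
    log_line("stage predict")
    grid <- make_grid(res$city, config$grid$cell_size_m)
    surface <- predict_surfaces(res$model_day, res$model_night, res$city,
                                grid, buffers = buffer_spec(config$buffers))
    write_surface(surface, file.path(out_dir, "surface"))
    road_sum <- summarize_by_roads(surface, res$city)
    readr::write_csv(road_sum, file.path(out_dir, "road_summary.csv"),
                     progress = FALSE)
    res$surface <- surface; res$road_summary <- road_sum
  }

  if ("exposure" %in% stages) {
    log_line("stage exposure")
    ea_lvl <- ea_average(res$surface, res$city$eas)
    readr::write_csv(ea_lvl, file.path(out_dir, "ea_levels.csv"),
                     progress = FALSE)
    expo <- exposure_distribution(
      ea_lvl, bin_width = config$exposure$bin_width,
      thresholds = unlist(config$exposure$thresholds))
    readr::write_csv(expo$bins, file.path(out_dir, "exposure_bins.csv"),
                     progress = FALSE)
    readr::write_csv(expo$exceedance,
                     file.path(out_dir, "exposure_exceedance.csv"),
                     progress = FALSE)
    ineq <- ses_inequality(ea_lvl, "ses_consumption")
    readr::write_csv(ineq$quintiles, file.path(out_dir, "ses_quintiles.csv"),
                     progress = FALSE)
    readr::write_csv(ineq$correlations,
                     file.path(out_dir, "ses_correlations.csv"),
                     progress = FALSE)
    res$ea_levels <- ea_lvl; res$exposure <- expo; res$inequality <- ineq
  }

  if ("ir" %in% stages) {
    log_line("stage ir")
    irm <- fit_ir_models(res$site_metrics, res$features, res$sites,
                         config = sel_cfg,
                         interaction = config$ir$interaction)
    for (period in c("day", "night")) {
      readr::write_csv(irm[[period]]$coefficients,
                       file.path(out_dir, paste0("ir_model_", period, ".csv")),
                       progress = FALSE)
      log_line("IR selection trace (", period, "):")
      log_line(paste(utils::capture.output(as.data.frame(irm[[period]]$trace)),
                     collapse = "\n"))
    }
    res$ir_models <- irm
  }

  log_line("done")
  invisible(res)
}
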