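#' Average predicted noise within enumeration areas
#'
#' Overlays the prediction surface on the enumeration-area polygons and
#' averages the masked-in cell values whose centers fall in each EA.
#' Averaging is arithmetic on the dBA scale by default (the convention for
#' area exposure summaries); an energetic variant is available.
#'
#' @param surface A `noise_surface`.
#' @param eas Enumeration-area tibble from a `city_layers` object.
#' @param energetic Average on the energy scale instead (default FALSE).
#' @return Tibble: one row per EA with `n_cells`, the four averaged
#'   metrics (NA and `missing = TRUE` for EAs with no covered cells),
#'   population and SES attributes.
#' @export
ea_average <- function(surface, eas, energetic = FALSE) {
  met <- surface$metrics
  if (nrow(met) == 0) {
    warning("ea_average: surface has no predictable cells", call. = FALSE)
    return(tibble::tibble())
  }
  ea_id <- ea_lookup(eas, met$x, met$y)
  avg <- function(v) if (energetic) energy_to_db(mean(db_to_energy(v))) else mean(v)
  per_ea <- tibble::tibble(ea_id = ea_id,
                           laeq_24hr = met$laeq_24hr, l_den = met$l_den,
                           l_day = met$l_day, l_night = met$l_night) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     laeq_24hr = avg(.data$laeq_24hr),
                     l_den = avg(.data$l_den),
                     l_day = avg(.data$l_day),
                     l_night = avg(.data$l_night),
                     .by = "ea_id")
  out <- eas |>
    dplyr::select("ea_id", "population", "dominant_landcover",
                  dplyr::starts_with("ses_")) |>
    dplyr::left_join(per_ea, by = "ea_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L),
                  missing = .data$n_cells == 0)
  if (all(out$missing)) {
    warning("ea_average: no EA overlaps a predictable cell", call. = FALSE)
  }
  out
}

#' Population distribution over noise-level bins
#'
#' Assigns each enumeration area's whole population to the 5 dBA bin of its
#' EA-mean level (bins are [5k, 5k+5)), and computes the cumulative share
#' of population by level and the share living above guideline thresholds
#' (defaults: WHO environmental noise guidelines for road traffic,
#' L_den 53 dBA and L_night 45 dBA).
#'
#' @param ea_levels Output of [ea_average()].
#' @param metrics Which EA-mean metrics to bin.
#' @param bin_width Bin width in dBA (default 5).
#' @param thresholds Named vector of guideline levels per metric.
#' @return Object of class `exposure_summary`: `bins`, `cumulative`,
#'   `exceedance`, `total_population`, `n_excluded` (EAs without levels).
#' @export
exposure_distribution <- function(ea_levels,
                                  metrics = c("l_den", "l_night"),
                                  bin_width = 5,
                                  thresholds = c(l_den = 53, l_night = 45)) {
  stopifnot(bin_width > 0)
  if (any(ea_levels$population < 0)) {
    stop("exposure_distribution: negative population", call. = FALSE)
  }
  dat <- ea_levels[!ea_levels$missing, ]
  n_excl <- sum(ea_levels$missing)
  if (n_excl > 0) {
    message("exposure_distribution: excluding ", n_excl,
            " EA(s) without predicted levels")
  }
  total_pop <- sum(dat$population)
  bins <- list()
  cum <- list()
  exc <- list()
  for (m in metrics) {
    lv <- dat[[m]]
    lo <- floor(lv / bin_width) * bin_width
    b <- tibble::tibble(metric = m, bin_lo = lo, bin_hi = lo + bin_width,
                        population = dat$population) |>
      dplyr::summarise(population = sum(.data$population),
                       .by = c("metric", "bin_lo", "bin_hi")) |>
      dplyr::arrange(.data$bin_lo) |>
      dplyr::mutate(pct = 100 * .data$population / total_pop)
    bins[[m]] <- b
    o <- order(lv)
    cum[[m]] <- tibble::tibble(metric = m, level = lv[o],
                               cum_population = cumsum(dat$population[o]),
                               cum_pct = 100 * cumsum(dat$population[o]) / total_pop)
    if (m %in% names(thresholds)) {
      above <- lv > thresholds[[m]]
      exc[[m]] <- tibble::tibble(
        metric = m, threshold_dba = thresholds[[m]],
        population_above = sum(dat$population[above]),
        pct_above = 100 * sum(dat$population[above]) / total_pop)
    }
  }
  structure(list(bins = dplyr::bind_rows(bins),
                 cumulative = dplyr::bind_rows(cum),
                 exceedance = dplyr::bind_rows(exc),
                 total_population = total_pop, n_excluded = n_excl,
                 bin_width = bin_width),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("<exposure_summary> population %s across %d bins\n",
              format(x$total_population, big.mark = ","),
              nrow(x$bins)))
  for (i in seq_len(nrow(x$exceedance))) {
    e <- x$exceedance[i, ]
    cat(sprintf("  %s > %g dBA: %.1f%% of population\n",
                e$metric, e$threshold_dba, e$pct_above))
  }
  invisible(x)
}

# Fisher-z confidence interval for a Pearson correlation
fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(tanh(z - q * se), tanh(z + q * se))
}

#' Socioeconomic inequality in noise exposure
#'
#' Splits enumeration areas into quintiles of a socioeconomic measure
#' (group sizes differ by at most one EA; ties broken by stable EA id
#' order), summarises the noise distribution per quintile, reports the
#' Pearson correlation of each metric with the SES measure (Fisher-z 95%
#' CI), and runs a Welch two-sample test between the bottom and top
#' quintiles.
#'
#' @param ea_levels Output of [ea_average()].
#' @param measure SES column: `"ses_consumption"` (median log equivalized
#'   household consumption), `"ses_education"` (residents with
#'   post-secondary education) or `"ses_unemployed"`.
#' @param metrics Noise metrics to analyse.
#' @return Object of class `ses_inequality`: `quintiles` (per-quintile
#'   median/IQR per metric), `correlations` (r with CI), `welch`
#'   (bottom-vs-top test per metric), plus the quintile assignment.
#' @export
ses_inequality <- function(ea_levels, measure = c("ses_consumption",
                                                  "ses_education",
                                                  "ses_unemployed"),
                           metrics = c("l_den", "l_night")) {
  measure <- match.arg(measure)
  dat <- ea_levels[!ea_levels$missing & !is.na(ea_levels[[measure]]), ]
  if (nrow(dat) < 10) {
    stop("ses_inequality: need at least 10 EAs with level and SES",
         call. = FALSE)
  }
  ses <- dat[[measure]]
  if (stats::sd(ses) == 0) {
    stop("ses_inequality: constant SES measure; quintiles undefined",
         call. = FALSE)
  }
  n <- nrow(dat)
  o <- order(ses, dat$ea_id)           # stable tie-break on EA id
  sizes <- rep(n %/% 5L, 5L)
  if (n %% 5L > 0) sizes[seq_len(n %% 5L)] <- sizes[seq_len(n %% 5L)] + 1L
  q <- integer(n)
  q[o] <- rep(1:5, times = sizes)
  dat$quintile <- q

  quint <- dat |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "level") |>
    dplyr::summarise(n = dplyr::n_distinct(.data$ea_id),
                     median = stats::median(.data$level),
                     q25 = as.numeric(stats::quantile(.data$level, 0.25)),
                     q75 = as.numeric(stats::quantile(.data$level, 0.75)),
                     .by = c("quintile", "metric")) |>
    dplyr::arrange(.data$metric, .data$quintile)

  cors <- purrr::map_dfr(metrics, function(m) {
    r <- stats::cor(dat[[m]], ses)
    ci <- fisher_ci(r, n)
    tibble::tibble(metric = m, measure = measure, r = r,
                   conf_low = ci[1], conf_high = ci[2], n = n)
  })
  welch <- purrr::map_dfr(metrics, function(m) {
    tt <- stats::t.test(dat[[m]][dat$quintile == 1],
                        dat[[m]][dat$quintile == 5])
    tibble::tibble(metric = m,
                   bottom_median = stats::median(dat[[m]][dat$quintile == 1]),
                   top_median = stats::median(dat[[m]][dat$quintile == 5]),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  structure(list(measure = measure, quintiles = quint, correlations = cors,
                 welch = welch,
                 assignment = dat[, c("ea_id", "quintile")]),
            class = "ses_inequality")
}

#' @export
print.ses_inequality <- function(x, ...) {
  cat(sprintf("<ses_inequality> measure: %s\n", x$measure))
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    cat(sprintf("  %s: r = %+.2f [%+.2f, %+.2f]\n", r$metric, r$r,
                r$conf_low, r$conf_high))
  }
  for (i in seq_len(nrow(x$welch))) {
    w <- x$welch[i, ]
    cat(sprintf("  %s bottom vs top quintile: %.1f vs %.1f dBA (p = %.3g)\n",
                w$metric, w$bottom_median, w$top_median, w$p_value))
  }
  invisible(x)
}
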