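# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted LUR model
#'
#' @param x A `lur_model`.
#' @param ... Unused.
#' @return Tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std.error`, `statistic`, `conf.low`, `conf.high`.
#' @method tidy lur_model
#' @export
tidy.lur_model <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(term = co$term, estimate = co$estimate,
                 std.error = co$std_error, statistic = co$statistic,
                 conf.low = co$conf_low, conf.high = co$conf_high)
}

#' One-row model summary of a LUR model
#'
#' @param x A `lur_model`.
#' @param ... Unused.
#' @return Tibble: period, number of predictors, both R^2 variants,
#'   variance components, sites and observations.
#' @method glance lur_model
#' @export
glance.lur_model <- function(x, ...) {
  tibble::tibble(period = x$period, n_predictors = length(x$variables),
                 r2_fixed = x$r2_fixed, r2_marginal = x$r2_marginal,
                 site_variance = x$site_variance,
                 hour_variance = x$hour_variance,
                 residual_variance = x$residual_variance,
                 n_sites = x$n_sites, n_obs = x$n_obs)
}

#' @rdname tidy.lur_model
#' @method tidy ir_model
#' @export
tidy.ir_model <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(term = co$term, estimate = co$estimate,
                 std.error = co$std_error, statistic = co$statistic,
                 conf.low = co$conf_low, conf.high = co$conf_high)
}

#' @rdname glance.lur_model
#' @method glance ir_model
#' @export
glance.ir_model <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n_predictors = length(x$variables),
                 r2 = x$r2_fixed, n_sites = x$n_sites)
}

#' @rdname glance.lur_model
#' @method glance lur_cv
#' @export
glance.lur_cv <- function(x, ...) {
  x$pooled
}
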