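# Site-level linear models for the intermittency ratio (IR). These reuse
# the two-step selection machinery on per-site data: no hour random effect
# (IR is one number per site and period), plain least squares, and the
# period noise level (L_day or L_night) offered as an additional candidate.
# The a-priori sign constraint is off here: unlike noise levels, steady
# heavy traffic LOWERS intermittency, so LUR sign conventions do not carry
# over.

fit_ir_lm <- function(dat, vars, outcome) {
  if (nrow(dat) < length(vars) + 3) {
    stop("fit_ir_models: fewer sites than predictors + 2", call. = FALSE)
  }
  form <- stats::as.formula(paste(
    outcome, "~", if (length(vars) == 0) "1" else
      paste(sprintf("`%s`", vars), collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  est <- stats::coef(fit)
  est <- est[!is.na(est)] # aliased (perfectly collinear) terms carry no info
  se <- sm$coefficients[names(est), "Std. Error"]
  z <- stats::qnorm(0.975)
  co <- tibble::tibble(
    term = gsub("`", "", names(est)),
    estimate = as.numeric(est),
    std_error = as.numeric(se),
    statistic = as.numeric(est / se),
    conf_low = as.numeric(est - z * se),
    conf_high = as.numeric(est + z * se)
  )
  yhat <- stats::fitted(fit)
  r2 <- if (stats::sd(yhat) > 0 && stats::sd(dat[[outcome]]) > 0) {
    stats::cor(yhat, dat[[outcome]])^2
  } else 0
  structure(list(outcome = outcome, variables = vars, coefficients = co,
                 r2_fixed = r2, n_sites = nrow(dat), fit = fit,
                 trace = NULL),
            class = "ir_model")
}

#' Model the intermittency ratio from spatial predictors and noise levels
#'
#' Fits linear models for the day and night intermittency ratio across
#' sites, following the same two-step selection as the noise-level models:
#' best buffer per variable by bivariate |r| with the IR, then forward
#' stepwise with stability pruning, challenge and collinearity filtering.
#' The period noise level (`l_day` / `l_night`) is offered as an extra
#' candidate. Afterwards, an optional interaction of the noise-level term
#' with the site's land-use class tests whether land use modifies that
#' association; with a single represented class the interaction is dropped
#' with a warning.
#'
#' @param site_metrics Per-site tibble with `site_id`, `ir_day`,
#'   `ir_night`, `l_day`, `l_night` (e.g. from [site_noise_metrics()]).
#' @param features Standardized `feature_matrix` for the sites.
#' @param sites Site tibble (provides `land_use_class`).
#' @param config A [selection_config()]; the sign constraint is ignored.
#' @param interaction Evaluate the land-use interaction term (default TRUE).
#' @return List of class `ir_models` with elements `day` and `night`, each
#'   an `ir_model` with coefficients, CIs, R^2 and a selection trace.
#' @export
fit_ir_models <- function(site_metrics, features, sites,
                          config = selection_config(), interaction = TRUE) {
  if (anyDuplicated(site_metrics$site_id)) {
    stop("fit_ir_models: expected one IR row per site", call. = FALSE)
  }
  id_col <- names(features)[1]
  dat0 <- site_metrics |>
    dplyr::inner_join(features, by = stats::setNames(id_col, "site_id")) |>
    dplyr::inner_join(sites[, c("site_id", "land_use_class")], by = "site_id")
  cfg <- config
  cfg$sign_constraint <- FALSE
  out <- list()
  for (period in c("day", "night")) {
    ir_col <- paste0("ir_", period)
    lvl_col <- paste0("l_", period)
    outcome_tbl <- tibble::tibble(site_id = dat0$site_id,
                                  laeq = dat0[[ir_col]])
    screen <- best_buffer_per_variable(NULL, features, period,
                                       outcome = outcome_tbl)
    cands <- screen_candidates(screen, cfg)
    # the period noise level enters the candidate list by its bivariate
    # strength
    r_lvl <- abs(suppressWarnings(stats::cor(dat0[[lvl_col]], dat0[[ir_col]])))
    if (is.na(r_lvl)) r_lvl <- 0
    pos <- sum(screen$abs_r[match(cands, screen$feature)] > r_lvl) + 1L
    cands <- append(cands, lvl_col, after = pos - 1L)
    out[[period]] <- ir_stepwise(dat0, cands, ir_col, cfg)
    if (interaction) {
      out[[period]] <- ir_add_interaction(out[[period]], dat0, lvl_col, cfg)
    }
  }
  structure(out, class = "ir_models")
}

ir_stepwise <- function(dat, candidates, outcome, config) {
  ffit <- function(vars) fit_ir_lm(dat, vars, outcome)
  gain_of <- function(vars, r2_base) {
    tryCatch(ffit(vars)$r2_fixed - r2_base, error = function(e) -Inf)
  }
  trace <- list()
  step <- 0L
  current <- character()
  r2_cur <- ffit(current)$r2_fixed
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    gains <- vapply(remaining, function(v) gain_of(c(current, v), r2_cur),
                    numeric(1))
    best <- which.max(gains)
    step <- step + 1L
    if (gains[best] >= config$r2_gain_threshold) {
      trace[[length(trace) + 1]] <- new_trace_row(
        step, "add", remaining[best], r2_cur, r2_cur + gains[best], TRUE)
      current <- c(current, remaining[best])
      r2_cur <- r2_cur + gains[best]
      remaining <- remaining[-best]
    } else {
      trace[[length(trace) + 1]] <- new_trace_row(
        step, "stop", remaining[best], r2_cur, r2_cur + gains[best], FALSE)
      break
    }
  }
  pr <- prune_unstable(ffit, current, config)
  current <- pr$variables
  trace <- c(trace, pr$trace)
  r2_cur <- ffit(current)$r2_fixed
  for (v in setdiff(candidates, current)) {
    step <- step + 1L
    gain <- gain_of(c(current, v), r2_cur)
    adopt <- gain >= config$r2_gain_threshold
    trace[[length(trace) + 1]] <- new_trace_row(
      step, "challenge", v, r2_cur, r2_cur + gain, adopt)
    if (adopt) {
      current <- c(current, v)
      r2_cur <- r2_cur + gain
    }
  }
  # collinearity among selected predictors
  repeat {
    if (length(current) < 2) break
    Xs <- as.matrix(dat[, current, drop = FALSE])
    C <- stats::cor(Xs)
    C[!upper.tri(C)] <- 0
    viol <- which(abs(C) > config$collinearity_r, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    i <- viol[1, 1]; j <- viol[1, 2]
    ry <- abs(stats::cor(Xs[, c(i, j)], dat[[outcome]]))
    drop_idx <- if (ry[1] >= ry[2]) j else i
    step <- step + 1L
    trace[[length(trace) + 1]] <- new_trace_row(
      step, "collinearity_drop", current[drop_idx], NA_real_, NA_real_, TRUE)
    current <- current[-drop_idx]
  }
  final <- fit_ir_lm(dat, current, outcome)
  final$trace <- dplyr::bind_rows(trace)
  final
}

ir_add_interaction <- function(model, dat, lvl_col, config) {
  if (!lvl_col %in% model$variables) return(model)
  classes <- unique(dat$land_use_class)
  if (length(classes) < 2) {
    warning("fit_ir_models: single land-use class among sites; ",
            "interaction term dropped", call. = FALSE)
    return(model)
  }
  vars <- model$variables
  form <- stats::as.formula(paste(
    model$outcome, "~",
    paste(c(sprintf("`%s`", setdiff(vars, lvl_col)),
            sprintf("`%s` * land_use_class", lvl_col)), collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  est <- stats::coef(fit)
  keep <- !is.na(est)
  if (any(!keep)) {
    warning("fit_ir_models: interaction produced inestimable contrasts; ",
            "interaction term dropped", call. = FALSE)
    return(model)
  }
  se <- sm$coefficients[, "Std. Error"]
  z <- stats::qnorm(0.975)
  model$interaction <- tibble::tibble(
    term = gsub("`", "", names(est)),
    estimate = as.numeric(est),
    std_error = as.numeric(se),
    conf_low = as.numeric(est - z * se),
    conf_high = as.numeric(est + z * se)
  )
  model$interaction_r2 <- sm$r.squared
  model$interaction_fit <- fit
  model
}

#' @export
print.ir_model <- function(x, ...) {
  cat(sprintf("Intermittency-ratio model (%s), %d sites, R2 = %.3f\n",
              x$outcome, x$n_sites, x$r2_fixed))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-28s %7.2f [%6.2f, %6.2f]\n", co$term[i],
                co$estimate[i], co$conf_low[i], co$conf_high[i]))
  }
  if (!is.null(x$interaction)) {
    cat(sprintf("  land-use interaction R2 = %.3f\n", x$interaction_r2))
  }
  invisible(x)
}

#' @export
print.ir_models <- function(x, ...) {
  print(x$day); print(x$night); invisible(x)
}
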