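#' Selection configuration for stepwise LUR model building
#'
#' @param r2_gain_threshold Minimum absolute gain in the fixed-effect R^2
#'   for a candidate to enter (default 0.01, i.e. "improved by at least
#'   1%").
#' @param collinearity_r Pairwise correlation above which two predictors
#'   are considered collinear; the one more correlated with the outcome is
#'   kept (default 0.8).
#' @param sign_constraint Drop candidates whose bivariate association
#'   contradicts the a-priori expected sign (default TRUE).
#' @param stability_t Absolute t below which a coefficient whose 95% CI
#'   crosses zero is deemed unstable and dropped (default 1: the CI
#'   half-width exceeds the coefficient magnitude).
#' @param vif_report Attach variance inflation factors to the final model.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(r2_gain_threshold = 0.01, collinearity_r = 0.8,
                             sign_constraint = TRUE, stability_t = 1,
                             vif_report = TRUE) {
  if (r2_gain_threshold <= 0 || r2_gain_threshold >= 1) {
    stop("selection_config: r2_gain_threshold must be in (0, 1)", call. = FALSE)
  }
  if (collinearity_r <= 0 || collinearity_r >= 1) {
    stop("selection_config: collinearity_r must be in (0, 1)", call. = FALSE)
  }
  structure(list(r2_gain_threshold = r2_gain_threshold,
                 collinearity_r = collinearity_r,
                 sign_constraint = sign_constraint,
                 stability_t = stability_t,
                 vif_report = vif_report),
            class = "selection_config")
}

period_hour_set <- function(period) {
  switch(period, day = day_hours(), night = night_hours(),
         stop("period must be 'day' or 'night'", call. = FALSE))
}

#' Fit a mixed-effects LAeq_1hr model
#'
#' Gaussian linear mixed model for hourly equivalent continuous levels:
#' `L_sh = b0 + sum_k b_k x_ks + gamma * height_s + a_h + b_s + e_sh`
#' with crossed random intercepts for hour of the day (`a_h`, diurnal
#' correlation) and site (`b_s`, unmeasured site effects). Monitor height
#' is always included as an adjustment covariate. Estimated with lme4
#' (REML by default). The reported `r2_fixed` is the squared Pearson
#' correlation between fixed-effect predictions and observations; a
#' marginal variance-partition R^2 is reported alongside.
#'
#' @param hourly Hourly levels (`site_id`, `date`, `hour`, `laeq_1hr_dba`)
#'   from [hourly_levels()].
#' @param features Standardized `feature_matrix` for the sites.
#' @param variables Character vector of feature columns for the fixed
#'   effects (may be empty: intercept + height model).
#' @param period `"day"` (hours 06-21) or `"night"` (22-05).
#' @param reml Use REML (default TRUE); selection uses ML for speed.
#' @return Object of class `lur_model`: coefficients with 95% Wald CIs,
#'   hour and site random-intercept estimates and variances, residual
#'   variance, the two R^2 variants, and the standardization parameters.
#' @export
fit_lur <- function(hourly, features, variables = character(),
                    period = c("day", "night"), reml = TRUE) {
  period <- match.arg(period)
  hrs <- period_hour_set(period)
  id_col <- names(features)[1]
  dat <- hourly |>
    dplyr::filter(.data$hour %in% hrs) |>
    dplyr::inner_join(features, by = stats::setNames(id_col, "site_id"))
  if (nrow(dat) == 0) stop("fit_lur: no observations in period", call. = FALSE)
  n_sites <- dplyr::n_distinct(dat$site_id)
  fixed_terms <- c(variables, "monitor_height_m")
  X <- as.matrix(cbind(1, dat[, fixed_terms, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fit_lur: singular fixed-effect design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat$hour_f <- factor(dat$hour, levels = sort(hrs))
  dat$site_f <- factor(dat$site_id)
  rhs <- paste(c(sprintf("`%s`", fixed_terms), "(1 | hour_f)", "(1 | site_f)"),
               collapse = " + ")
  form <- stats::as.formula(paste("laeq_1hr_dba ~", rhs))
  fit <- lme4::lmer(form, data = dat, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  terms_clean <- gsub("`", "", names(fe))
  coefs <- tibble::tibble(
    term = terms_clean,
    estimate = as.numeric(fe),
    std_error = as.numeric(se),
    statistic = as.numeric(fe / se),
    conf_low = as.numeric(fe - z * se),
    conf_high = as.numeric(fe + z * se)
  )
  yhat_fixed <- as.numeric(X %*% fe)
  y <- dat$laeq_1hr_dba
  r2_fixed <- if (stats::sd(yhat_fixed) > 0 && stats::sd(y) > 0) {
    stats::cor(yhat_fixed, y)^2
  } else 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_site <- vc$vcov[vc$grp == "site_f"]
  var_hour <- vc$vcov[vc$grp == "hour_f"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  r2_marginal <- stats::var(yhat_fixed) /
    (stats::var(yhat_fixed) + var_site + var_hour + var_resid)
  re <- lme4::ranef(fit)
  hour_int <- stats::setNames(re$hour_f[[1]],
                              as.character(rownames(re$hour_f)))
  site_int <- stats::setNames(re$site_f[[1]],
                              as.character(rownames(re$site_f)))
  structure(
    list(period = period, variables = variables, coefficients = coefs,
         hour_intercepts = hour_int, site_intercepts = site_int,
         site_variance = var_site, hour_variance = var_hour,
         residual_variance = var_resid,
         r2_fixed = r2_fixed, r2_marginal = r2_marginal,
         n_sites = n_sites, n_obs = nrow(dat),
         standardization = attr(features, "standardization"),
         trace = NULL, vif = NULL, fit = fit),
    class = "lur_model"
  )
}

#' Fixed-effect predictions from a LUR model
#'
#' Predicts LAeq_1hr at new locations from the fixed effects, optionally
#' adding the fitted hour random intercepts (one column per requested
#' hour). Features must carry the same standardization parameters the model
#' was fitted with; a mismatch is a hard error to prevent silent
#' mis-scaling.
#'
#' @param model A `lur_model` (or a deserialized one from
#'   [read_lur_json()]).
#' @param features `feature_matrix` for the prediction locations,
#'   standardized with the model's parameters.
#' @param hours NULL for the bare fixed-effect prediction, or an integer
#'   vector of hours to add hour intercepts for (hours unseen in training
#'   contribute 0).
#' @return Numeric vector (hours = NULL) or matrix (rows = locations,
#'   columns = hours).
#' @export
predict_lur <- function(model, features, hours = NULL) {
  check_standardization(model, features)
  coefs <- model$coefficients
  beta <- stats::setNames(coefs$estimate, coefs$term)
  pred <- rep(beta[["(Intercept)"]], nrow(features))
  for (term in setdiff(names(beta), "(Intercept)")) {
    if (!term %in% names(features)) {
      stop("predict_lur: feature matrix lacks model term ", term,
           call. = FALSE)
    }
    pred <- pred + beta[[term]] * features[[term]]
  }
  if (is.null(hours)) return(pred)
  hi <- model$hour_intercepts
  offs <- vapply(as.character(hours),
                 function(h) if (h %in% names(hi)) hi[[h]] else 0,
                 numeric(1))
  outer(pred, offs, "+")
}

check_standardization <- function(model, features) {
  fp <- attr(features, "standardization")
  mp <- model$standardization
  if (is.null(mp)) return(invisible(TRUE))
  if (is.null(fp)) {
    stop("predict_lur: features are not standardized; apply the model's ",
         "standardization parameters first", call. = FALSE)
  }
  shared <- intersect(mp$column, fp$column)
  a <- mp[match(shared, mp$column), c("mean", "sd")]
  b <- fp[match(shared, fp$column), c("mean", "sd")]
  if (!isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                        tolerance = 1e-12))) {
    stop("predict_lur: standardization parameters of the features do not ",
         "match the model's (refusing to predict on a different scale)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Site-level period LAeq
#'
#' The equivalent continuous level of each site over the day or night
#' hours, used as the outcome for bivariate screening (site-level screening
#' avoids pseudo-replication of hourly rows).
#'
#' @param hourly Output of [hourly_levels()].
#' @param period `"day"` or `"night"`.
#' @return Tibble `site_id`, `laeq` (dBA).
#' @export
site_period_laeq <- function(hourly, period = c("day", "night")) {
  period <- match.arg(period)
  hrs <- period_hour_set(period)
  hourly |>
    dplyr::filter(.data$hour %in% hrs) |>
    dplyr::summarise(laeq = energy_to_db(mean(db_to_energy(.data$laeq_1hr_dba))),
                     .by = "site_id")
}

#' Choose the best buffer per variable by bivariate correlation
#'
#' Step one of the two-step selection: for each buffered catalogue variable
#' the buffer radius whose feature correlates most strongly (|Pearson r|)
#' with the site-level period LAeq is retained; ties (|r| difference below
#' 1e-6) go to the smaller, more local buffer. A variable whose sign
#' contradicts the a-priori expectation is flagged (`direction_ok = FALSE`)
#' and excluded from the candidate list when the sign constraint is on.
#'
#' @param hourly Hourly levels.
#' @param features Standardized `feature_matrix`.
#' @param period `"day"` or `"night"`.
#' @param outcome Optional site-level outcome tibble (`site_id`, `laeq`);
#'   computed from `hourly` when NULL. Supplying e.g. intermittency ratios
#'   reuses the machinery for IR models.
#' @return Tibble `variable`, `feature`, `buffer`, `r`, `abs_r`,
#'   `direction_ok`, ordered by decreasing |r|.
#' @export
best_buffer_per_variable <- function(hourly, features,
                                     period = c("day", "night"),
                                     outcome = NULL) {
  period <- match.arg(period)
  if (is.null(outcome)) outcome <- site_period_laeq(hourly, period)
  catalogue <- attr(features, "catalogue")
  buffers <- attr(features, "buffers")
  id_col <- names(features)[1]
  y <- outcome$laeq[match(features[[id_col]], outcome$site_id)]
  keep <- !is.na(y)
  y_sd <- stats::sd(y[keep])
  empty_screen <- tibble::tibble(variable = character(),
                                 feature = character(), buffer = numeric(),
                                 r = numeric(), abs_r = numeric(),
                                 direction_ok = logical())
  if (!is.finite(y_sd) || y_sd == 0) return(empty_screen)
  rows <- list()
  for (i in seq_len(nrow(catalogue))) {
    v <- catalogue$name[i]
    cols <- if (catalogue$buffered[i]) feature_name(v, buffers) else v
    cols <- intersect(cols, names(features))
    if (length(cols) == 0) next
    rs <- vapply(cols, function(cn) {
      x <- features[[cn]][keep]
      if (stats::sd(x) == 0) return(NA_real_)
      stats::cor(x, y[keep])
    }, numeric(1))
    if (all(is.na(rs))) next
    ar <- abs(rs)
    best <- which(ar >= max(ar, na.rm = TRUE) - 1e-6)[1] # tie -> smaller buffer
    sign_ok <- catalogue$expected_sign[i] == "either" ||
      (catalogue$expected_sign[i] == "+" && rs[best] > 0) ||
      (catalogue$expected_sign[i] == "-" && rs[best] < 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, feature = cols[best],
      buffer = if (catalogue$buffered[i]) buffers[best] else NA_real_,
      r = rs[best], abs_r = ar[best], direction_ok = sign_ok
    )
  }
  if (length(rows) == 0) return(empty_screen)
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$abs_r))
}

#' Candidate feature list from a screening table
#'
#' @param screen Output of [best_buffer_per_variable()].
#' @param config A [selection_config()] (controls the sign constraint).
#' @return Character vector of feature columns, strongest |r| first.
#' @export
screen_candidates <- function(screen, config = selection_config()) {
  s <- screen[!is.na(screen$r), ]
  if (config$sign_constraint) s <- s[s$direction_ok, ]
  s$feature[order(-s$abs_r)]
}

new_trace_row <- function(step, action, variable, r2_before, r2_after,
                          accepted, note = "") {
  tibble::tibble(step = step, action = action, variable = variable,
                 r2_before = r2_before, r2_after = r2_after,
                 accepted = accepted, note = note)
}

#' Forward stepwise selection of a LUR model
#'
#' Step two of the selection: starting from the intercept + height model,
#' iteratively adds the candidate producing the largest gain in the
#' fixed-effect R^2, stopping when the best gain falls below the threshold;
#' then prunes unstable coefficients ([stability_prune()]); then challenges
#' the model by adding every excluded candidate back one at a time,
#' adopting any that clears the threshold; finally resolves collinear pairs
#' (|r| above the configured limit) by keeping the member more correlated
#' with the outcome. Every decision is recorded in the selection trace.
#' Deterministic given data and candidate order.
#'
#' @param hourly Hourly levels.
#' @param features Standardized `feature_matrix`.
#' @param candidates Feature columns ordered by bivariate |r| (strongest
#'   first), from [screen_candidates()].
#' @param period `"day"` or `"night"`.
#' @param config A [selection_config()].
#' @return A `lur_model` (refit with REML) with `trace` and, when
#'   requested, `vif` filled in.
#' @export
forward_stepwise <- function(hourly, features, candidates,
                             period = c("day", "night"),
                             config = selection_config()) {
  period <- match.arg(period)
  if (length(candidates) == 0) {
    warning("forward_stepwise: no candidates; returning intercept-only model",
            call. = FALSE)
    m <- fit_lur(hourly, features, character(), period)
    m$trace <- new_trace_row(0L, "stop", NA_character_, NA_real_,
                             m$r2_fixed, TRUE, "empty candidate list")
    return(m)
  }
  ffit <- function(vars) fit_lur(hourly, features, vars, period, reml = FALSE)
  # a candidate that makes the design singular simply cannot enter
  gain_of <- function(vars, r2_base) {
    tryCatch(ffit(vars)$r2_fixed - r2_base, error = function(e) -Inf)
  }
  trace <- list()
  step <- 0L
  current <- character()
  cur_fit <- ffit(current)
  r2_cur <- cur_fit$r2_fixed
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    gains <- vapply(remaining, function(v) gain_of(c(current, v), r2_cur),
                    numeric(1))
    best <- which.max(gains) # ties: earlier (stronger-screened) candidate
    step <- step + 1L
    if (gains[best] >= config$r2_gain_threshold) {
      trace[[length(trace) + 1]] <- new_trace_row(
        step, "add", remaining[best], r2_cur, r2_cur + gains[best], TRUE)
      current <- c(current, remaining[best])
      r2_cur <- r2_cur + gains[best]
      remaining <- remaining[-best]
    } else {
      trace[[length(trace) + 1]] <- new_trace_row(
        step, "stop", remaining[best], r2_cur, r2_cur + gains[best], FALSE,
        sprintf("best gain %.4f below threshold %.3f", gains[best],
                config$r2_gain_threshold))
      break
    }
  }

  ## stability prune
  pr <- prune_unstable(ffit, current, config)
  current <- pr$variables
  trace <- c(trace, pr$trace)
  cur_fit <- ffit(current)
  r2_cur <- cur_fit$r2_fixed

  ## challenge: excluded candidates re-offered one by one
  excluded <- setdiff(candidates, current)
  for (v in excluded) {
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
  if (length(setdiff(current, pr$variables)) > 0) {
    pr2 <- prune_unstable(ffit, current, config)
    current <- pr2$variables
    trace <- c(trace, pr2$trace)
  }

  ## collinearity filter on the selected set
  outcome <- site_period_laeq(hourly, period)
  id_col <- names(features)[1]
  y <- outcome$laeq[match(features[[id_col]], outcome$site_id)]
  repeat {
    if (length(current) < 2) break
    Xs <- as.matrix(features[, current, drop = FALSE])
    C <- stats::cor(Xs)
    C[!upper.tri(C)] <- 0
    viol <- which(abs(C) > config$collinearity_r, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    i <- viol[1, 1]; j <- viol[1, 2]
    ry <- abs(stats::cor(Xs[, c(i, j)], y, use = "complete.obs"))
    drop_idx <- if (ry[1] >= ry[2]) j else i
    step <- step + 1L
    trace[[length(trace) + 1]] <- new_trace_row(
      step, "collinearity_drop", current[drop_idx], NA_real_, NA_real_, TRUE,
      sprintf("|r|=%.3f with %s", abs(C[i, j]),
              current[if (drop_idx == i) j else i]))
    current <- current[-drop_idx]
  }

  final <- fit_lur(hourly, features, current, period, reml = TRUE)
  final$trace <- dplyr::bind_rows(trace)
  final$candidates <- candidates
  final$config <- config
  if (config$vif_report && length(current) >= 2) {
    final$vif <- vif_lur(final, features)
  }
  final
}

# unstable iff the 95% CI crosses zero AND |t| < stability_t (half-width
# exceeds the coefficient magnitude at the default threshold of 1)
is_unstable <- function(estimate, conf_low, conf_high, statistic,
                        stability_t = 1) {
  crosses <- conf_low < 0 & conf_high > 0
  crosses & abs(statistic) < stability_t
}

prune_unstable <- function(ffit, variables, config) {
  trace <- list()
  step <- 0L
  repeat {
    if (length(variables) == 0) break
    fit <- ffit(variables)
    co <- fit$coefficients
    co <- co[co$term %in% variables, ]
    unst <- is_unstable(co$estimate, co$conf_low, co$conf_high,
                        co$statistic, config$stability_t)
    if (!any(unst)) break
    worst <- co$term[unst][which.min(abs(co$statistic[unst]))]
    step <- step + 1L
    trace[[length(trace) + 1]] <- new_trace_row(
      step, "prune_drop", worst, fit$r2_fixed, NA_real_, TRUE,
      "CI crosses zero and |t| below stability threshold")
    variables <- setdiff(variables, worst)
  }
  list(variables = variables, trace = trace)
}

#' Drop unstable coefficients from a fitted LUR model
#'
#' A coefficient is unstable when its 95% confidence interval crosses zero
#' and the interval half-width exceeds the coefficient magnitude (|t| < 1):
#' large coefficient, larger uncertainty. Variables with CIs crossing zero
#' but |t| >= 1 are retained -- a modest, imprecise effect is kept, an
#' erratic one is not. The model is refit after each drop.
#'
#' @param model A fitted `lur_model`.
#' @param hourly,features The data the model was fitted on.
#' @param config A [selection_config()] (`stability_t` sets the threshold).
#' @return The pruned, refit `lur_model` (trace extended).
#' @export
stability_prune <- function(model, hourly, features,
                            config = selection_config()) {
  ffit <- function(vars) fit_lur(hourly, features, vars, model$period,
                                 reml = FALSE)
  pr <- prune_unstable(ffit, model$variables, config)
  out <- fit_lur(hourly, features, pr$variables, model$period, reml = TRUE)
  out$trace <- dplyr::bind_rows(c(list(model$trace), pr$trace))
  out
}

#' Variance inflation factors of a model's predictors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing predictor k on the other
#' selected predictors over the site-level feature rows. Perfect
#' collinearity reports `Inf`.
#'
#' @param model A `lur_model` (or character vector of feature columns).
#' @param features `feature_matrix` with those columns.
#' @return Tibble `variable`, `vif`.
#' @export
vif_lur <- function(model, features) {
  vars <- if (is.character(model)) model else model$variables
  if (length(vars) < 2) {
    return(tibble::tibble(variable = vars, vif = rep(1, length(vars))))
  }
  X <- as.matrix(features[, vars, drop = FALSE])
  vifs <- vapply(seq_along(vars), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(variable = vars, vif = vifs)
}

#' @export
print.lur_model <- function(x, ...) {
  cat(format_lur_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable LUR model report
#'
#' Formats the fitted model the way noise-LUR papers tabulate them: one row
#' per predictor with its buffer implied by the name, the coefficient and
#' 95% CI, followed by variance components and fit statistics.
#'
#' @param model A `lur_model`.
#' @return Character vector of report lines.
#' @export
format_lur_report <- function(model) {
  co <- model$coefficients
  fmt_row <- function(term, est, lo, hi) {
    sprintf("  %-28s %6.1f [%5.1f, %5.1f]", term, est, lo, hi)
  }
  lines <- c(
    sprintf("LAeq_1hr model, %s-time hours (dBA)", model$period),
    fmt_row("Intercept", co$estimate[co$term == "(Intercept)"],
            co$conf_low[co$term == "(Intercept)"],
            co$conf_high[co$term == "(Intercept)"])
  )
  for (i in seq_len(nrow(co))) {
    if (co$term[i] %in% c("(Intercept)")) next
    lines <- c(lines, fmt_row(co$term[i], co$estimate[i], co$conf_low[i],
                              co$conf_high[i]))
  }
  c(lines,
    sprintf("  sites: %d  obs: %d", model$n_sites, model$n_obs),
    sprintf("  var(site) = %.2f  var(hour) = %.2f  var(resid) = %.2f",
            model$site_variance, model$hour_variance,
            model$residual_variance),
    sprintf("  R2 (fixed-effect corr^2) = %.3f   R2 (marginal) = %.3f",
            model$r2_fixed, model$r2_marginal))
}
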