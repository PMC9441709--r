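#' Site-grouped cross-validation of a LUR model
#'
#' Folds partition SITES, never rows: held-out sites are fully unseen, so
#' predictions use the fixed effects plus the training-set hour intercepts
#' but no site intercept -- exactly the situation of predicting at an
#' unmonitored location. `cv10_sites` holds out ~10% of sites per fold;
#' `loocv` holds out one site at a time. The variable set is fixed and the
#' model refit per fold (selection is not re-run unless `reselect = TRUE`).
#'
#' @param hourly Hourly levels for all sites.
#' @param features Standardized `feature_matrix`.
#' @param variables Feature columns of the model being evaluated.
#' @param period `"day"` or `"night"`.
#' @param scheme `"cv10_sites"` or `"loocv"`.
#' @param seed Fold assignment seed (deterministic).
#' @param reselect Re-run screening + stepwise inside each training fold
#'   (slower; default FALSE).
#' @param catalogue,config Needed only when `reselect = TRUE`.
#' @return Object of class `lur_cv`: `pooled` (one-row tibble with
#'   `median_abs_error`, `mean_abs_error`, `mean_error`, `r`, `r2` over all
#'   held-out observations), `folds` (per-fold metrics) and `predictions`
#'   (site-hour rows with `observed`, `predicted`). Errors are
#'   predicted - observed.
#' @export
cross_validate <- function(hourly, features, variables,
                           period = c("day", "night"),
                           scheme = c("cv10_sites", "loocv"), seed = 1L,
                           reselect = FALSE, catalogue = NULL,
                           config = selection_config()) {
  period <- match.arg(period)
  scheme <- match.arg(scheme)
  id_col <- names(features)[1]
  sites <- unique(features[[id_col]])
  n_sites <- length(sites)
  k <- if (scheme == "loocv") n_sites else 10L
  if (n_sites < k) {
    stop("cross_validate: ", n_sites, " sites cannot form ", k, " folds",
         call. = FALSE)
  }
  set.seed(seed)
  fold_of <- stats::setNames(
    sample(rep(seq_len(k), length.out = n_sites)), sites)
  if (scheme == "loocv") fold_of <- stats::setNames(seq_len(n_sites), sites)

  hrs <- period_hour_set(period)
  hr_dat <- hourly[hourly$hour %in% hrs, ]
  preds <- list()
  fold_rows <- list()
  for (f in seq_len(k)) {
    test_sites <- names(fold_of)[fold_of == f]
    train_feat <- subset_feature_rows(features, !features[[id_col]] %in% test_sites)
    test_feat <- subset_feature_rows(features, features[[id_col]] %in% test_sites)
    train_hr <- hr_dat[!hr_dat$site_id %in% test_sites, ]
    test_hr <- hr_dat[hr_dat$site_id %in% test_sites, ]
    if (nrow(test_hr) == 0) next
    vars_f <- variables
    if (reselect) {
      screen <- best_buffer_per_variable(train_hr, train_feat, period)
      cands <- screen_candidates(screen, config)
      m <- forward_stepwise(train_hr, train_feat, cands, period, config)
      vars_f <- m$variables
    } else {
      m <- fit_lur(train_hr, train_feat, vars_f, period)
    }
    hi <- m$hour_intercepts
    fixed <- predict_lur(m, test_feat)
    offs <- vapply(as.character(test_hr$hour),
                   function(h) if (h %in% names(hi)) hi[[h]] else 0,
                   numeric(1))
    pred <- fixed[match(test_hr$site_id, test_feat[[id_col]])] + offs
    pr <- tibble::tibble(fold = f, site_id = test_hr$site_id,
                         date = test_hr$date, hour = test_hr$hour,
                         observed = test_hr$laeq_1hr_dba, predicted = pred)
    preds[[f]] <- pr
    err <- pr$predicted - pr$observed
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n_sites = length(test_sites), n_obs = nrow(pr),
      median_abs_error = stats::median(abs(err)),
      mean_abs_error = mean(abs(err)),
      mean_error = mean(err),
      r = suppressWarnings(stats::cor(pr$predicted, pr$observed)))
  }
  predictions <- dplyr::bind_rows(preds)
  err <- predictions$predicted - predictions$observed
  r <- stats::cor(predictions$predicted, predictions$observed)
  pooled <- tibble::tibble(
    scheme = scheme, period = period,
    n_obs = nrow(predictions),
    median_abs_error = stats::median(abs(err)),
    mean_abs_error = mean(abs(err)),
    mean_error = mean(err),
    r = r, r2 = r^2
  )
  structure(list(scheme = scheme, period = period, pooled = pooled,
                 folds = dplyr::bind_rows(fold_rows),
                 predictions = predictions,
                 fold_assignment = fold_of),
            class = "lur_cv")
}

#' @export
print.lur_cv <- function(x, ...) {
  cat(sprintf("Site-grouped cross-validation (%s, %s hours)\n",
              x$scheme, x$period))
  p <- x$pooled
  cat(sprintf("  MedAE %.2f  MAE %.2f  ME %+.2f dBA   r %.3f  r2 %.3f  (n=%d)\n",
              p$median_abs_error, p$mean_abs_error, p$mean_error,
              p$r, p$r2, p$n_obs))
  invisible(x)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with mean-centered
#' residuals `z` and row-standardized inverse-distance weights. Under
#' spatial randomness `E[I] = -1/(n-1)`. The p-value comes from a seeded
#' permutation test (residuals shuffled across locations).
#'
#' @param residuals Numeric site-level residuals.
#' @param x,y Site coordinates (meters).
#' @param nperm Number of permutations (default 999).
#' @param seed Permutation seed.
#' @param alternative `"greater"` (clustering, default), `"less"`, or
#'   `"two.sided"`.
#' @return One-row tibble: `i`, `expected_i`, `p_value`, `n`, `nperm`,
#'   `alternative`.
#' @export
morans_i <- function(residuals, x, y, nperm = 999, seed = 1L,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(residuals)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 8) stop("morans_i: need at least 8 sites", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0)) {
    stop("morans_i: coincident sites give undefined inverse-distance weights",
         call. = FALSE)
  }
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  s0 <- sum(w)
  stat <- function(z) {
    z <- z - mean(z)
    (n / s0) * as.numeric(z %*% w %*% z) / sum(z^2)
  }
  i_obs <- stat(residuals)
  set.seed(seed)
  i_perm <- vapply(seq_len(nperm), function(b) stat(sample(residuals)),
                   numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(i_perm >= i_obs)) / (nperm + 1),
    less = (1 + sum(i_perm <= i_obs)) / (nperm + 1),
    two.sided = {
      e <- -1 / (n - 1)
      (1 + sum(abs(i_perm - e) >= abs(i_obs - e))) / (nperm + 1)
    })
  tibble::tibble(i = i_obs, expected_i = -1 / (n - 1), p_value = p,
                 n = n, nperm = nperm, alternative = alternative)
}
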