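#' Place noise monitoring sites in a synthetic city
#'
#' Emulates a measurement campaign with rotating short-term sites and a few
#' fixed long-term sites. Rotating sites are selected by stratified random
#' sampling across land-cover classes (allocation proportional to class
#' area); fixed sites are spread round-robin across classes so they cover
#' diverse land uses. No site falls in water.
#'
#' @param city A [generate_city()] result.
#' @param n_rotating,n_fixed Numbers of rotating and fixed sites.
#' @param seed Integer seed (deterministic placement).
#' @param stratify Stratify rotating sites on land-cover class (default
#'   TRUE). When enabled, `n_rotating + n_fixed` must be at least twice the
#'   number of land-cover classes.
#' @return A tibble of sites: `site_id`, `x`, `y`, `kind`
#'   (`"rotating"`/`"fixed"`), `monitor_height_m` (~4 m, the deployment
#'   height), `land_use_class`.
#' @export
place_sites <- function(city, n_rotating = 136, n_fixed = 10, seed = 1L,
                        stratify = TRUE) {
  stopifnot(inherits(city, "city_layers"))
  n_total <- n_rotating + n_fixed
  if (n_total < 1) stop("place_sites: need at least one site", call. = FALSE)
  cls <- city$landcover_classes
  if (stratify && n_total < 2 * length(cls)) {
    stop("place_sites: stratified sampling needs n_rotating + n_fixed >= ",
         2 * length(cls), call. = FALSE)
  }
  set.seed(seed)
  lc <- city$landcover
  centers <- raster_cell_centers(lc)
  cx <- rep(centers$x, each = lc$nrow)
  cy <- rep(centers$y, times = lc$ncol)
  cell_class <- as.vector(lc$values)
  ok <- rep(TRUE, length(cx))
  if (nrow(city$water) > 0) {
    for (w in seq_len(nrow(city$water))) {
      ok <- ok & !point_in_rect(cx, cy, city$water[w, ])
    }
  }
  if (sum(ok) < n_total) {
    stop("place_sites: insufficient valid land area for ", n_total, " sites",
         call. = FALSE)
  }
  cx <- cx[ok]; cy <- cy[ok]; cell_class <- cell_class[ok]

  taken <- logical(length(cx))
  pick_in_class <- function(k, n) {
    pool <- which(cell_class == k & !taken)
    out <- integer(0)
    m <- min(n, length(pool))
    if (m > 0) {
      out <- if (length(pool) == 1) pool else sample(pool, m)
      taken[out] <<- TRUE
    }
    # deficit: redirect deterministically to the class with the most free
    # cells (keeps stratum tallies a function of the city, not the seed)
    while (length(out) < n) {
      free_tab <- tabulate(cell_class[!taken], nbins = length(cls))
      kk <- which.max(free_tab)
      pool2 <- which(cell_class == kk & !taken)
      pick <- if (length(pool2) == 1) pool2 else sample(pool2, 1)
      taken[pick] <<- TRUE
      out <- c(out, pick)
    }
    out
  }

  if (stratify && n_rotating > 0) {
    tab <- tabulate(cell_class, nbins = length(cls))
    # largest-remainder allocation proportional to class area, min 1 where
    # the class exists
    raw <- n_rotating * tab / sum(tab)
    alloc <- floor(raw)
    alloc[tab > 0 & alloc == 0 & n_rotating >= sum(tab > 0)] <- 1L
    while (sum(alloc) > n_rotating) {
      i <- which.max(alloc)
      alloc[i] <- alloc[i] - 1L
    }
    rem <- raw - floor(raw)
    while (sum(alloc) < n_rotating) {
      i <- which.max(rem)
      alloc[i] <- alloc[i] + 1L
      rem[i] <- -1
    }
    rot_idx <- unlist(lapply(seq_along(cls), function(k) pick_in_class(k, alloc[k])))
  } else if (n_rotating > 0) {
    rot_idx <- which(!taken)[sample.int(sum(!taken), n_rotating)]
    taken[rot_idx] <- TRUE
  } else {
    rot_idx <- integer(0)
  }
  fix_classes <- rep(seq_along(cls), length.out = n_fixed)
  fix_idx <- unlist(lapply(fix_classes, function(k) pick_in_class(k, 1)))
  idx <- c(rot_idx, fix_idx)

  jit <- lc$res * 0.4
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n_total)),
    x = cx[idx] + stats::runif(n_total, -jit, jit),
    y = cy[idx] + stats::runif(n_total, -jit, jit),
    kind = rep(c("rotating", "fixed"), c(length(rot_idx), length(fix_idx))),
    monitor_height_m = round(4 + stats::runif(n_total, -1, 1), 1),
    land_use_class = city$landcover_classes[cell_class[idx]]
  )
}
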