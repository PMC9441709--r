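# a hand-made ea_levels table (the ea_average output contract)
make_ea_levels <- function(l_den, l_night = l_den - 7, population = 100,
                           ses = NULL) {
  n <- length(l_den)
  tibble::tibble(
    ea_id = sprintf("EA%03d", seq_len(n)),
    population = rep_len(population, n),
    dominant_landcover = "formal_residential",
    ses_consumption = if (is.null(ses)) rnorm(n) else ses,
    ses_education = rpois(n, 50),
    ses_unemployed = rpois(n, 30),
    n_cells = 10L,
    laeq_24hr = l_den - 3, l_den = l_den, l_day = l_den - 2,
    l_night = l_night,
    missing = FALSE
  )
}

test_that("EA averages reproduce hand means over covered cells", {
  city <- fx_tiny_city()
  # constant surface: every EA mean equals the constant
  grid <- make_grid(city, 50)
  cells <- grid[grid$in_sample, ]
  surf <- structure(list(
    grid = grid,
    hourly = matrix(60, nrow(cells), 24),
    metrics = tibble::tibble(cell_id = cells$cell_id, x = cells$x,
                             y = cells$y, laeq_24hr = 60, l_den = 60,
                             l_day = 60, l_night = 60)),
    class = "noise_surface")
  ea <- ea_average(surf, city$eas)
  got <- ea[!ea$missing, ]
  expect_true(all(got$l_den == 60))

  # two-cell EA with 58 and 62 -> 60
  surf$metrics$l_den <- rep(c(58, 62), length.out = nrow(cells))
  ea2 <- ea_average(surf, city$eas)
  # brute-force oracle: mean by direct rectangle assignment
  for (k in seq_len(nrow(city$eas))) {
    row <- city$eas[k, ]
    sel <- surf$metrics$x >= row$xmin & surf$metrics$x <= row$xmax &
      surf$metrics$y >= row$ymin & surf$metrics$y <= row$ymax
    if (!any(sel)) next
    expect_equal(ea2$l_den[ea2$ea_id == row$ea_id],
                 mean(surf$metrics$l_den[sel]), tolerance = 1e-9)
  }
})

test_that("binned populations conserve the total and match hand binning", {
  ea <- make_ea_levels(c(61, 66), population = c(100, 300))
  expo <- exposure_distribution(ea)
  b <- expo$bins[expo$bins$metric == "l_den", ]
  expect_equal(b$population[b$bin_lo == 60], 100)
  expect_equal(b$population[b$bin_lo == 65], 300)
  expect_equal(sum(b$population), sum(ea$population))
  exc <- expo$exceedance[expo$exceedance$metric == "l_den", ]
  expect_equal(exc$pct_above, 100)

  # all below threshold -> 0 %
  ea2 <- make_ea_levels(c(45, 48), l_night = c(40, 41))
  expo2 <- exposure_distribution(ea2)
  expect_true(all(expo2$exceedance$pct_above == 0))
})

test_that("bin totals equal a brute-force loop oracle on random data", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    ea <- make_ea_levels(runif(n, 48, 78), population = rpois(n, 500))
    expo <- exposure_distribution(ea, metrics = "l_den")
    b <- expo$bins
    # oracle: loop every EA into its bin
    oracle <- new.env()
    for (i in seq_len(n)) {
      key <- as.character(floor(ea$l_den[i] / 5) * 5)
      oracle[[key]] <- (oracle[[key]] %||% 0) + ea$population[i]
    }
    for (j in seq_len(nrow(b))) {
      expect_equal(b$population[j], oracle[[as.character(b$bin_lo[j])]])
    }
    expect_equal(sum(b$population), sum(ea$population))
    # cumulative curve is monotone nondecreasing
    cum <- expo$cumulative
    expect_true(all(diff(cum$cum_pct) >= 0))
  }
})

test_that("quintile sizes differ by at most one EA", {
  set.seed(72)
  for (n in c(23, 40, 101)) {
    ea <- make_ea_levels(runif(n, 50, 75), ses = rnorm(n))
    res <- ses_inequality(ea)
    sizes <- table(res$assignment$quintile)
    expect_equal(length(sizes), 5)
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("Fisher-z confidence intervals match the closed form and cor.test", {
  set.seed(73)
  n <- 40
  ses <- rnorm(n)
  lden <- 65 - 2 * ses + rnorm(n, 0, 2)
  ea <- make_ea_levels(lden, ses = ses)
  res <- ses_inequality(ea, metrics = "l_den")
  r <- cor(lden, ses)
  expect_equal(res$correlations$r, r, tolerance = 1e-12)
  ci <- tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  expect_equal(c(res$correlations$conf_low, res$correlations$conf_high), ci,
               tolerance = 1e-9)
  ct <- cor.test(lden, ses)
  expect_equal(c(res$correlations$conf_low, res$correlations$conf_high),
               as.numeric(ct$conf.int), tolerance = 1e-9)
})

test_that("a constructed negative SES-noise dependence shows the gradient", {
  set.seed(74)
  n <- 60
  ses <- rnorm(n)
  lden <- 65 - 3 * ses + rnorm(n, 0, 1.5)
  ea <- make_ea_levels(lden, l_night = lden - 7, ses = ses)
  res <- ses_inequality(ea)
  expect_lt(res$correlations$r[res$correlations$metric == "l_den"], 0)
  q <- res$quintiles[res$quintiles$metric == "l_den", ]
  expect_gt(q$median[q$quintile == 1], q$median[q$quintile == 5])
  w <- res$welch[res$welch$metric == "l_den", ]
  expect_lt(w$p_value, 0.05)
  # Welch statistic matches stats::t.test directly
  asg <- res$assignment
  tt <- t.test(lden[asg$quintile == 1], lden[asg$quintile == 5])
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-12)
})

test_that("quintile assignment is invariant to monotone SES relabeling", {
  set.seed(75)
  n <- 47
  ses <- rnorm(n)
  ea <- make_ea_levels(runif(n, 50, 75), ses = ses)
  a1 <- ses_inequality(ea)$assignment
  ea$ses_consumption <- exp(2 * ses + 1) # strictly increasing transform
  a2 <- ses_inequality(ea)$assignment
  expect_identical(a1, a2)
})

test_that("degenerate SES input errors", {
  ea <- make_ea_levels(runif(20, 50, 70), ses = rep(1, 20))
  expect_error(ses_inequality(ea), "constant")
  ea2 <- make_ea_levels(runif(5, 50, 70))
  expect_error(ses_inequality(ea2), "at least 10")
})
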