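# Monthly first-of-month sampling dates spanning the given years (plus one
# extra January so every year has both boundaries).
monthly_dates <- function(years) {
  as.Date(paste(
    rep(c(years, max(years) + 1), each = 12)[seq_len(length(years) * 12 + 1)],
    rep(1:12, length.out = length(years) * 12 + 1), 1,
    sep = "-"
  ))
}

test_that("annual growth recovers exact linear and seasonal-plus-linear records", {
  yrs <- 2000:2010
  dates <- monthly_dates(yrs)
  t_dec <- carbonledger:::decimal_year(dates)
  # pure linear record, 2 ppm/yr
  lin <- tibble::tibble(date = dates, ppm = 350 + 2 * (t_dec - 2000))
  g <- annual_growth_ppm(lin)
  expect_equal(g$growth_ppm, rep(2, length(yrs)), tolerance = 1e-9)
  # adding a pure 12-month (plus semi-annual) cycle changes nothing
  seas <- dplyr::mutate(
    lin,
    ppm = ppm + 3 * sin(2 * pi * t_dec) + 0.5 * cos(4 * pi * t_dec)
  )
  gs <- annual_growth_ppm(seas)
  expect_equal(gs$growth_ppm, g$growth_ppm, tolerance = 1e-6)
})

test_that("stepwise growth rates are recovered from a piecewise-linear record", {
  yrs <- 2000:2002
  steps <- c(1.5, 2.5, 2.0)
  dates <- monthly_dates(yrs)
  t_dec <- carbonledger:::decimal_year(dates)
  boundary <- 370 + c(0, cumsum(steps))
  ppm <- approx(c(yrs, max(yrs) + 1), boundary, xout = t_dec)$y
  g <- annual_growth_ppm(tibble::tibble(date = dates, ppm = ppm))
  expect_equal(g$growth_ppm, steps, tolerance = 0.01)
})

test_that("growth computation rejects gappy records and is offset invariant", {
  yrs <- 2000:2005
  dates <- monthly_dates(yrs)
  t_dec <- carbonledger:::decimal_year(dates)
  ppm <- 350 + 2.2 * (t_dec - 2000) + sin(2 * pi * t_dec)
  full <- tibble::tibble(date = dates, ppm = ppm)
  gap <- full[-(30:36), ]
  expect_error(annual_growth_ppm(gap), "Gap")
  # constant offset leaves growth (hence factors) unchanged
  g0 <- annual_growth_ppm(full)
  g1 <- annual_growth_ppm(dplyr::mutate(full, ppm = ppm + 25))
  expect_equal(g1$growth_ppm, g0$growth_ppm, tolerance = 1e-9)
})

test_that("member factors divide net input by growth and flag unreliable years", {
  net <- tibble::tibble(
    member = "m1", year = 2000:2003,
    net_input_gtc = c(2.124, 4.248, 1.0, 0.002)
  )
  growth <- tibble::tibble(
    member = "m1", year = 2000:2003,
    growth_ppm = c(1, 2, 0.5, 0.01)
  )
  f <- member_conversion_factor(net, growth)
  expect_equal(f$factor[1:2], c(2.124, 2.124))
  expect_equal(f$factor[3], 2.0)
  expect_false(f$reliable[4]) # |growth| < 0.05 ppm/yr
  expect_true(all(f$reliable[1:3]))
})

test_that("ensemble statistics match direct recomputation and drop thin years", {
  f2 <- tibble::tibble(
    member = rep(c("a", "b"), each = 1), year = 2005,
    factor = c(2.0, 2.2), reliable = TRUE
  )
  s <- suppressWarnings(ensemble_factor_stats(f2, window = c(2005, 2005)))
  expect_equal(s$annual$mean, 2.1)
  expect_equal(s$annual$sd, sd(c(2.0, 2.2))) # 0.1414

  set.seed(8)
  many <- tidyr::expand_grid(
    member = paste0("m", 1:14), year = 2001:2023
  ) |>
    dplyr::mutate(factor = rnorm(dplyr::n(), 2.124, 0.05), reliable = TRUE)
  st <- ensemble_factor_stats(many)
  for (y in c(2001, 2010, 2023)) {
    v <- many$factor[many$year == y]
    expect_equal(st$annual$mean[st$annual$year == y], mean(v))
    expect_equal(st$annual$sd[st$annual$year == y], sd(v))
  }
  expect_equal(st$interannual_sd, sd(st$annual$mean))
  expect_equal(st$mean_ensemble_sd, mean(st$annual$sd))

  # identical members: zero spread
  same <- dplyr::mutate(many, factor = 2.124)
  expect_equal(unique(ensemble_factor_stats(same)$annual$sd), 0)

  # a year with a single member is dropped with a warning
  thin <- dplyr::bind_rows(
    many,
    tibble::tibble(member = "m1", year = 2024, factor = 2.1, reliable = TRUE)
  )
  expect_warning(st2 <- ensemble_factor_stats(thin), "2024")
  expect_false(2024 %in% st2$annual$year)
})

test_that("exactly consistent members give the reference factor and pure source-1 sigma", {
  # every member's net input is 2.124 x its own growth
  yrs <- 2001:2023
  growth <- tidyr::expand_grid(member = paste0("m", 1:5), year = yrs) |>
    dplyr::mutate(growth_ppm = 2 + 0.3 * sin(year))
  net <- dplyr::mutate(
    growth,
    net_input_gtc = 2.124 * growth_ppm
  ) |>
    dplyr::select(member, year, net_input_gtc)
  f <- member_conversion_factor(net, growth)
  expect_equal(unique(f$factor), 2.124)
  st <- ensemble_factor_stats(f)
  expect_equal(unique(st$annual$sd), 0)
  expect_equal(st$interannual_sd, 0)
  # sigma(G_ATM) then reduces to source (1) alone: sigma_ppm x factor
  g_atm <- flux_series("G_ATM", yrs, 2.124 * (2 + 0.3 * sin(yrs)))
  obs <- tibble::tibble(
    year = yrs, growth_ppm = 2 + 0.3 * sin(yrs), sigma_ppm = 0.1
  )
  su <- gatm_uncertainty(g_atm, obs, st)
  expect_equal(su$sigma, 0.1 / obs$growth_ppm * abs(g_atm$value))
  expect_equal(su$sigma, rep(0.1 * 2.124, length(yrs)), tolerance = 1e-12)
})

test_that("the three uncertainty sources combine as relative quadrature", {
  # three relative sources {1%, 2%, 2%} on G_ATM = 5.2 -> 5.2 x 3% = 0.156
  yrs <- 2001:2023
  st <- structure(
    list(
      annual = tibble::tibble(year = yrs, mean = 2.124, sd = 2.124 * 0.02, n = 5),
      interannual_sd = 2.124 * 0.02,
      mean_ensemble_sd = 2.124 * 0.02,
      window = c(2001, 2023),
      reference = 2.124
    ),
    class = "conversion_factor_series"
  )
  g_atm <- flux_series("G_ATM", yrs, 5.2)
  obs <- tibble::tibble(year = yrs, growth_ppm = 2, sigma_ppm = 0.02)
  su <- gatm_uncertainty(g_atm, obs, st)
  expect_equal(
    unique(round(su$sigma, 3)),
    round(5.2 * sqrt(0.01^2 + 0.02^2 + 0.02^2), 3) # 0.156
  )
  # all sources zero: sigma 0
  st0 <- st
  st0$interannual_sd <- 0
  st0$mean_ensemble_sd <- 0
  obs0 <- dplyr::mutate(obs, sigma_ppm = 0)
  expect_equal(unique(gatm_uncertainty(g_atm, obs0, st0)$sigma), 0)
  # missing source is a configuration error
  st_na <- st
  st_na$interannual_sd <- NA_real_
  expect_error(gatm_uncertainty(g_atm, obs, st_na), "three uncertainty sources")
})

test_that("imbalance significance flags respond to the band width", {
  yrs <- 2001:2010
  bim <- flux_series("B_IM", yrs, c(0.5, 0.5, rep(0.1, 8)))
  band1 <- bim_band(bim, sigma_gatm = rep(0.6, 10))
  expect_false(band1$significant[1]) # 0.5 < 0.6
  band2 <- bim_band(bim, sigma_gatm = rep(0.3, 10))
  expect_true(band2$significant[1]) # 0.5 > 0.3
  # halving the band: recount flags against a brute-force comparison
  set.seed(4)
  v <- rnorm(10, 0, 0.4)
  bimr <- flux_series("B_IM", yrs, v)
  sig <- runif(10, 0.1, 0.6)
  for (k in c(1, 2)) {
    got <- bim_band(bimr, sig, k = k)$significant
    expect_equal(got, abs(v) > k * sig)
  }
  halved <- bim_band(bimr, sig / 2)$significant
  expect_equal(halved, abs(v) > sig / 2)
  expect_gte(sum(halved), sum(bim_band(bimr, sig)$significant))
})

test_that("synthetic inversion ensembles recover the reference factor", {
  w <- simulate_world(world_config(seed = 6))
  growth <- annual_growth_ppm(w$inversions$molefractions)
  f <- member_conversion_factor(w$inversions$net_input, growth)
  st <- ensemble_factor_stats(f)
  gl <- glance(st)
  # members were built around 2.124 with 2% member noise: the window mean
  # must sit within a few ensemble standard errors of the reference
  expect_lt(
    abs(gl$mean_factor - 2.124),
    4 * gl$mean_ensemble_sd / sqrt(w$config$n_inversions) + 0.02
  )
})
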