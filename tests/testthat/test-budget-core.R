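test_that("budget imbalance reproduces printed decadal rows and the closure identity", {
  # consolidated row: 9.7 + 1.2 - 2.7 - 3.1 - 5.2 = -0.1
  revised <- constant_budget(
    c(E_FOS = 9.7, E_LUC = 1.2, S_LAND = 2.7, S_OCEAN = 3.1, G_ATM = 5.2),
    sigmas = c(
      E_FOS = 0.5, E_LUC = 0.7, S_LAND = 0.9, S_OCEAN = 0.5, G_ATM = 0.02
    )
  )
  bim <- budget_imbalance(revised)
  expect_equal(unique(bim$value), -0.1, tolerance = 1e-12)
  expect_equal(
    unique(bim$sigma),
    sqrt(0.5^2 + 0.7^2 + 0.9^2 + 0.5^2 + 0.02^2)
  )

  # baseline row from rounded inputs: 9.7 + 1.1 - 3.2 - 2.9 - 5.2 = -0.5
  baseline <- constant_budget(
    c(E_FOS = 9.7, E_LUC = 1.1, S_LAND = 3.2, S_OCEAN = 2.9, G_ATM = 5.2)
  )
  expect_equal(unique(budget_imbalance(baseline)$value), -0.5)

  # any budget closed through G_ATM has identically zero imbalance
  set.seed(42)
  yrs <- 1960:2023
  e_fos <- runif(length(yrs), 2, 10)
  e_luc <- runif(length(yrs), 0.5, 2)
  s_land <- runif(length(yrs), 0.5, 4)
  s_ocean <- runif(length(yrs), 0.5, 4)
  closed <- budget_table(
    flux_series("E_FOS", yrs, e_fos),
    flux_series("E_LUC", yrs, e_luc),
    flux_series("S_LAND", yrs, s_land),
    flux_series("S_OCEAN", yrs, s_ocean),
    flux_series("G_ATM", yrs, e_fos + e_luc - s_land - s_ocean)
  )
  expect_lt(max(abs(budget_imbalance(closed)$value)), 1e-12)
  # sigma absent when components carry no sigma
  expect_true(all(is.na(budget_imbalance(closed)$sigma)))
})

test_that("budget table construction rejects misaligned components", {
  yrs <- 2000:2009
  expect_error(
    budget_table(
      flux_series("E_FOS", yrs, 9),
      flux_series("E_LUC", 2001:2010, 1),
      flux_series("S_LAND", yrs, 3),
      flux_series("S_OCEAN", yrs, 3),
      flux_series("G_ATM", yrs, 4)
    ),
    "not aligned"
  )
  expect_error(flux_series("X", c(2000, 2002, 2003), 1:3), "contiguous")
  expect_error(flux_series("X", 2000:2002, 1:3, sigma = c(1, -1, 1)), "non-negative")
})

test_that("quadrature matches hand arithmetic and its order/monotonicity properties", {
  expect_equal(quadrature(c(0.9, 0.7)), sqrt(0.9^2 + 0.7^2)) # 1.140, prints 1.1
  expect_equal(round(quadrature(c(0.9, 0.7)), 1), 1.1)
  expect_equal(
    round(quadrature(c(0.02, 0.5, 0.7, 0.9, 0.5)), 1), 1.3
  )
  expect_equal(quadrature(0.37), 0.37)
  expect_error(quadrature(c(0.1, -0.2)), "non-negative")
  # properties over random cases
  set.seed(7)
  for (i in 1:50) {
    s <- runif(sample(2:6, 1), 0, 2)
    q <- quadrature(s)
    expect_gte(q, max(s))
    expect_gte(quadrature(s + 0.1), q) # monotone in each argument
    expect_equal(quadrature(sample(s)), q) # permutation invariant
  }
})

test_that("decadal mean averages values, carries mean sigma, and rejects bad windows", {
  s <- flux_series("S_LAND", 2014:2023, 1:10, sigma = seq(0.5, 1.4, by = 0.1))
  dm <- decadal_mean(s, 2014, 2023)
  expect_equal(dm$value, 5.5)
  expect_equal(dm$sigma, mean(seq(0.5, 1.4, by = 0.1))) # not sigma/sqrt(10)
  expect_equal(dm$n_years, 10L)
  const <- flux_series("X", 1990:2010, 3.14)
  expect_equal(decadal_mean(const, 1995, 2004)$value, 3.14)
  expect_true(is.na(decadal_mean(const, 1995, 2004)$sigma))
  expect_error(decadal_mean(s, 2010, 2019), "outside")
  expect_error(decadal_mean(s, 2020, 2015), "first_year")
})

test_that("decadal mean of AR(1) series is an unbiased estimator of the level", {
  # Monte Carlo: many independent AR(1) realisations around a known level
  mu <- 2.7
  phi <- 0.5
  sig <- 0.4
  reps <- 1000
  set.seed(11)
  means <- replicate(reps, {
    x <- numeric(10)
    x[1] <- rnorm(1, 0, sig / sqrt(1 - phi^2))
    for (t in 2:10) x[t] <- phi * x[t - 1] + rnorm(1, 0, sig)
    s <- flux_series("S_LAND", 2014:2023, mu + x)
    decadal_mean(s, 2014, 2023)$value
  })
  expect_lt(abs(mean(means) - mu), 4 * sd(means) / sqrt(reps))
})

test_that("linear trend recovers exact lines and is translation invariant", {
  yrs <- 1960:2023
  exact <- flux_series("B_IM", yrs, 0.3 - 0.014 * (yrs - 1960))
  # summary.lm warns about the perfect fit; only the estimates matter here
  tr <- suppressWarnings(linear_trend(exact))
  expect_equal(tr$slope, -0.14, tolerance = 1e-10) # per decade
  expect_lt(tr$p_value, 1e-12)
  # translation invariance
  shifted <- dplyr::mutate(exact, value = value + 5)
  expect_equal(
    suppressWarnings(linear_trend(shifted))$slope, tr$slope,
    tolerance = 1e-10
  )
  expect_error(linear_trend(flux_series("X", 2000:2001, 1:2)), "3 years")
  # tidy/glance structure
  td <- tidy(tr)
  expect_named(
    td, c("component", "term", "estimate", "std.error", "p.value")
  )
  expect_equal(glance(tr)$n_years, 64L)
})

test_that("trend estimator is centred on the truth under iid noise", {
  yrs <- 1960:2023
  true_slope <- -0.014 # GtC/yr per year => -0.14 per decade
  reps <- 600
  set.seed(21)
  slopes <- replicate(reps, {
    v <- 1 + true_slope * (yrs - 1960) + rnorm(length(yrs), 0, 0.8)
    linear_trend(flux_series("B_IM", yrs, v))$slope
  })
  mc_se <- sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - (-0.14)), 4 * mc_se)
})

test_that("ppm/GtC conversion applies the 2.124 factor and round-trips exactly", {
  expect_equal(ppm_gtc(1, "ppm_to_gtc"), 2.124)
  expect_equal(round(ppm_gtc(17.63, "gtc_to_ppm"), 2), 8.30)
  x <- c(0.1, 1, 5.2, 423)
  expect_equal(
    ppm_gtc(ppm_gtc(x, "ppm_to_gtc"), "gtc_to_ppm"), x,
    tolerance = 1e-15
  )
  expect_error(ppm_gtc(1, factor = 0), "positive")
  expect_error(ppm_gtc(1, factor = -2), "positive")
})

test_that("airborne fraction uses G_ATM over total emissions", {
  # revised decade: 5.2 / (9.7 + 1.2) = 0.477
  b <- constant_budget(
    c(E_FOS = 9.7, E_LUC = 1.2, S_LAND = 2.7, S_OCEAN = 3.1, G_ATM = 5.2)
  )
  expect_equal(round(unique(airborne_fraction(b)$value), 3), 0.477)
  # sinks zero and G_ATM = E: AF = 1
  yrs <- 2000:2009
  all_air <- budget_table(
    flux_series("E_FOS", yrs, 8),
    flux_series("E_LUC", yrs, 2),
    flux_series("S_LAND", yrs, 0),
    flux_series("S_OCEAN", yrs, 0),
    flux_series("G_ATM", yrs, 10)
  )
  expect_equal(unique(airborne_fraction(all_air)$value), 1)
  zero_g <- constant_budget(
    c(E_FOS = 8, E_LUC = 2, S_LAND = 5, S_OCEAN = 5, G_ATM = 0)
  )
  expect_equal(unique(airborne_fraction(zero_g)$value), 0)
  bad <- constant_budget(
    c(E_FOS = 0, E_LUC = 0, S_LAND = 0, S_OCEAN = 0, G_ATM = 0)
  )
  expect_error(airborne_fraction(bad), "positive")
  # cumulative mode equals ratio of running sums
  af_c <- airborne_fraction(all_air, mode = "cumulative")
  expect_equal(unique(af_c$value), 1)
})

test_that("flux CSV round-trips through the exchange schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- flux_series("S_OCEAN", 2000:2005, seq(2, 2.5, by = 0.1), sigma = 0.4)
  write_flux_csv(x, path)
  back <- read_flux_csv(path)
  expect_equal(back$value, x$value)
  expect_equal(back$sigma, x$sigma)
  expect_equal(back$component, x$component)
})
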