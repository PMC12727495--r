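#' Annual CO2 growth rate from monthly mole fractions
#'
#' Growth for calendar year y is the deseasonalised mole fraction at
#' 1 January (y+1) minus that at 1 January y, mirroring the
#' observation-network convention. The seasonal cycle is removed by
#' regressing the monthly series on a linear trend plus the first two annual
#' harmonics; the deseasonalised series (observations minus the fitted
#' harmonic terms) is then interpolated linearly to the year boundaries and
#' differenced. Input samples are expected at (or near) the first of each
#' month; gaps wider than `max_gap` months raise a coverage error.
#'
#' @param molefractions tibble with columns `date` (Date or ISO-8601
#'   string), `ppm`, and optionally `member` (growth is computed per
#'   member).
#' @param years integer years to report (default: all fully covered years).
#' @param max_gap largest tolerated gap between samples, in months.
#' @return Tibble with columns (`member`,) `year`, `growth_ppm`.
#' @export
annual_growth_ppm <- function(molefractions, years = NULL, max_gap = 2) {
  x <- as_tibble(molefractions)
  if (!all(c("date", "ppm") %in% names(x))) {
    abort("Need columns `date` and `ppm`.")
  }
  if (!"member" %in% names(x)) x$member <- "obs"
  x$date <- as.Date(x$date)
  one_member <- function(df) {
    df <- arrange(df, .data$date)
    t_dec <- decimal_year(df$date)
    if (any(diff(t_dec) > max_gap / 12 + 1e-9)) {
      abort("Gap in mole-fraction record exceeds `max_gap` months.")
    }
    h <- cbind(
      c1 = cos(2 * pi * t_dec), s1 = sin(2 * pi * t_dec),
      c2 = cos(4 * pi * t_dec), s2 = sin(4 * pi * t_dec)
    )
    fit <- lm(df$ppm ~ t_dec + h)
    seasonal <- h %*% coef(fit)[c("hc1", "hs1", "hc2", "hs2")]
    deseas <- df$ppm - as.numeric(seasonal)
    yr_range <- seq(ceiling(min(t_dec) - 1e-9), floor(max(t_dec) + 1e-9))
    if (length(yr_range) < 2) abort("Record covers no complete year.")
    boundary <- approx(t_dec, deseas, xout = yr_range)$y
    out <- tibble(
      year = as.integer(yr_range[-length(yr_range)]),
      growth_ppm = diff(boundary)
    )
    if (!is.null(years)) out <- filter(out, .data$year %in% years)
    out
  }
  x |>
    group_by(.data$member) |>
    dplyr::group_modify(~ one_member(.x)) |>
    ungroup()
}

#' Per-member ppm-to-GtC conversion factors
#'
#' For an atmospheric-inversion ensemble member, the net annual input of CO2
#' to the atmosphere (fossil emissions plus the inverse-derived net land and
#' ocean fluxes, GtC/yr) divided by that member's annual growth rate (ppm/yr)
#' gives the conversion factor in GtC/ppm. Years with |growth| below
#' `min_growth` yield unstable ratios: the factor is still returned but
#' flagged `reliable = FALSE` and excluded from ensemble statistics.
#'
#' @param net_input tibble (`member`, `year`, `net_input_gtc`).
#' @param growth tibble (`member`, `year`, `growth_ppm`), e.g. from
#'   [annual_growth_ppm()].
#' @param min_growth reliability threshold in ppm/yr (default 0.05).
#' @return Tibble (`member`, `year`, `factor`, `reliable`).
#' @export
member_conversion_factor <- function(net_input, growth, min_growth = 0.05) {
  joined <- inner_join(
    as_tibble(net_input), as_tibble(growth),
    by = c("member", "year")
  )
  if (!nrow(joined)) abort("No overlapping member-years between inputs.")
  joined |>
    mutate(
      factor = .data$net_input_gtc / .data$growth_ppm,
      reliable = abs(.data$growth_ppm) >= min_growth
    ) |>
    select("member", "year", "factor", "reliable")
}

#' Ensemble statistics of the conversion factor
#'
#' Per-year unweighted mean and sample (n-1) standard deviation of the
#' reliable member factors; years covered by fewer than two members are
#' dropped with a warning. The interannual variability is the standard
#' deviation of the annual-mean series over the analysis `window` (the
#' period covered by most inversions).
#'
#' @param factors tibble from [member_conversion_factor()].
#' @param window two-year vector, analysis window (default `c(2001, 2023)`).
#' @param reference constant reference factor, GtC/ppm.
#' @return A list of class `"conversion_factor_series"`: `annual` (tibble
#'   `year`, `mean`, `sd`, `n`), `interannual_sd`, `mean_ensemble_sd` (both
#'   over the window), `window`, `reference`.
#' @export
ensemble_factor_stats <- function(factors, window = c(2001, 2023),
                                  reference = 2.124) {
  factors <- filter(as_tibble(factors), .data$reliable)
  annual <- factors |>
    group_by(.data$year) |>
    summarise(
      mean = mean(.data$factor),
      sd = if (dplyr::n() >= 2) sd(.data$factor) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$year)
  dropped <- annual$year[annual$n < 2]
  if (length(dropped)) {
    warn(paste0(
      "Dropping year(s) with <2 members: ", paste(dropped, collapse = ", ")
    ))
    annual <- filter(annual, .data$n >= 2)
  }
  if (any(annual$mean <= 0)) {
    warn("Non-positive ensemble-mean conversion factor encountered.")
  }
  in_win <- annual$year >= window[1] & annual$year <= window[2]
  structure(
    list(
      annual = annual,
      interannual_sd = sd(annual$mean[in_win]),
      mean_ensemble_sd = mean(annual$sd[in_win]),
      window = window,
      reference = reference
    ),
    class = "conversion_factor_series"
  )
}

#' @export
print.conversion_factor_series <- function(x, ...) {
  in_win <- x$annual$year >= x$window[1] & x$annual$year <= x$window[2]
  cat(sprintf(
    "Conversion factor %d-%d: mean %.3f GtC/ppm (reference %.3f)\n  interannual sd %.3f, mean ensemble sd %.3f\n",
    x$window[1], x$window[2], mean(x$annual$mean[in_win]), x$reference,
    x$interannual_sd, x$mean_ensemble_sd
  ))
  invisible(x)
}

#' @rdname ensemble_factor_stats
#' @param x a `"conversion_factor_series"`.
#' @param ... unused.
#' @export
tidy.conversion_factor_series <- function(x, ...) x$annual

#' @rdname ensemble_factor_stats
#' @export
glance.conversion_factor_series <- function(x, ...) {
  in_win <- x$annual$year >= x$window[1] & x$annual$year <= x$window[2]
  tibble(
    window_start = x$window[1],
    window_end = x$window[2],
    mean_factor = mean(x$annual$mean[in_win]),
    interannual_sd = x$interannual_sd,
    mean_ensemble_sd = x$mean_ensemble_sd,
    reference = x$reference
  )
}

#' Propagate conversion-factor uncertainty to G_ATM
#'
#' Three independent error sources enter the mass growth rate: (1) the
#' annual uncertainty of the observation-based growth rate, (2) the
#' interannual variability of the conversion factor over the analysis
#' window, and (3) the mean ensemble spread of the inversions. Each is
#' expressed as a relative error -- (1) relative to the annual growth, (2)
#' and (3) relative to the mean factor -- combined in quadrature and
#' multiplied by G_ATM(t). All three sources must be supplied; there are no
#' silent defaults. G_ATM itself is never adjusted, only its sigma band.
#'
#' @param g_atm flux-series tibble for G_ATM (GtC/yr).
#' @param growth_obs tibble (`year`, `growth_ppm`, `sigma_ppm`), the
#'   observed growth and its annual 1-sigma.
#' @param cf a `"conversion_factor_series"` from [ensemble_factor_stats()].
#' @return Flux-series tibble for G_ATM with `sigma` filled per year.
#' @export
gatm_uncertainty <- function(g_atm, growth_obs, cf) {
  g_atm <- check_flux_series(g_atm)
  growth_obs <- as_tibble(growth_obs)
  if (!all(c("year", "growth_ppm", "sigma_ppm") %in% names(growth_obs))) {
    abort("`growth_obs` needs columns year, growth_ppm, sigma_ppm.")
  }
  if (!inherits(cf, "conversion_factor_series")) {
    abort("`cf` must come from ensemble_factor_stats().")
  }
  if (is.na(cf$interannual_sd) || is.na(cf$mean_ensemble_sd)) {
    abort("Conversion-factor series lacks window statistics; all three uncertainty sources are required.")
  }
  in_win <- cf$annual$year >= cf$window[1] & cf$annual$year <= cf$window[2]
  mean_factor <- mean(cf$annual$mean[in_win])
  joined <- inner_join(g_atm, growth_obs, by = "year")
  rel <- sqrt(
    (joined$sigma_ppm / joined$growth_ppm)^2 +
      (cf$interannual_sd / mean_factor)^2 +
      (cf$mean_ensemble_sd / mean_factor)^2
  )
  tibble(
    component = joined$component,
    year = joined$year,
    value = joined$value,
    sigma = abs(joined$value) * rel
  )
}

#' Flag years with a significant budget imbalance
#'
#' Annotates a budget-imbalance series with the G_ATM-derived sigma band:
#' a year is significant iff |B_IM| > k x sigma. Years inside the band do
#' not have a statistically significant imbalance.
#'
#' @param bim flux-series tibble for B_IM.
#' @param sigma_gatm per-year sigma band (numeric vector aligned with
#'   `bim`, or a tibble with `year` and `sigma`).
#' @param k band half-width in sigmas (default 1).
#' @return `bim` with columns `band_sigma` and `significant` added.
#' @export
bim_band <- function(bim, sigma_gatm, k = 1) {
  bim <- check_flux_series(bim)
  if (is.data.frame(sigma_gatm)) {
    joined <- inner_join(
      bim, sigma_gatm[, c("year", "sigma")] |> rename(band_sigma = "sigma"),
      by = "year"
    )
  } else {
    if (length(sigma_gatm) != nrow(bim)) {
      abort("`sigma_gatm` must align with the imbalance series.")
    }
    joined <- mutate(bim, band_sigma = as.numeric(sigma_gatm))
  }
  mutate(joined, significant = abs(.data$value) > k * .data$band_sigma)
}
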