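#' Assemble a budget table from the five component series
#'
#' Binds the five budget components -- fossil emissions (`E_FOS`), net
#' land-use-change emissions (`E_LUC`), land sink (`S_LAND`), ocean sink
#' (`S_OCEAN`) and atmospheric growth (`G_ATM`) -- into one long tibble after
#' checking that all five share an identical year axis. Sign convention:
#' sinks positive, sources positive, growth positive, so mass balance reads
#' E_FOS + E_LUC = S_LAND + S_OCEAN + G_ATM.
#'
#' @param e_fos,e_luc,s_land,s_ocean,g_atm flux-series tibbles (see
#'   [flux_series()]); component labels are overwritten with the canonical
#'   names.
#' @return A long tibble with the five components stacked, one row per
#'   component-year.
#' @export
budget_table <- function(e_fos, e_luc, s_land, s_ocean, g_atm) {
  comps <- list(
    E_FOS = e_fos, E_LUC = e_luc, S_LAND = s_land,
    S_OCEAN = s_ocean, G_ATM = g_atm
  )
  comps <- purrr::imap(comps, function(x, nm) {
    x <- check_flux_series(x)
    x$component <- nm
    x
  })
  ref <- comps[[1]]$year
  purrr::iwalk(comps, function(x, nm) {
    if (length(x$year) != length(ref) || !all(x$year == ref)) {
      abort(paste0("Component ", nm, " is not aligned with E_FOS."))
    }
  })
  bind_rows(comps)
}

budget_components <- c("E_FOS", "E_LUC", "S_LAND", "S_OCEAN", "G_ATM")

# Internal: long budget tibble -> wide (year x component) value / sigma pair.
budget_wide <- function(budget) {
  budget <- check_flux_series(budget)
  missing_comp <- setdiff(budget_components, unique(budget$component))
  if (length(missing_comp)) {
    abort(paste0(
      "Budget table lacks component(s): ",
      paste(missing_comp, collapse = ", ")
    ))
  }
  years <- sort(unique(budget$year))
  for (comp in budget_components) {
    yrs <- budget$year[budget$component == comp]
    if (length(yrs) != length(years) || !all(sort(yrs) == years)) {
      abort("All five components must share identical year axes.")
    }
  }
  value <- tidyr::pivot_wider(
    budget[, c("component", "year", "value")],
    names_from = "component", values_from = "value"
  )
  sigma <- tidyr::pivot_wider(
    budget[, c("component", "year", "sigma")],
    names_from = "component", values_from = "sigma"
  )
  list(value = arrange(value, .data$year), sigma = arrange(sigma, .data$year))
}

#' Budget imbalance B_IM
#'
#' The mass-conservation residual of the global carbon budget,
#' B_IM = E_FOS + E_LUC - S_LAND - S_OCEAN - G_ATM, computed per year.
#' Perfect closure gives zero; a positive imbalance means estimated sources
#' exceed estimated sinks plus atmospheric accumulation. The per-year sigma
#' is the quadrature of the five component sigmas when all are present, and
#' `NA` otherwise.
#'
#' @param budget a long budget tibble from [budget_table()] (or any tibble
#'   holding the five components on one year axis).
#' @return A flux-series tibble with `component = "B_IM"`.
#' @examples
#' yrs <- 2014:2023
#' b <- budget_table(
#'   flux_series("E_FOS", yrs, 9.7, 0.5),
#'   flux_series("E_LUC", yrs, 1.2, 0.7),
#'   flux_series("S_LAND", yrs, 2.7, 0.9),
#'   flux_series("S_OCEAN", yrs, 3.1, 0.5),
#'   flux_series("G_ATM", yrs, 5.2, 0.02)
#' )
#' budget_imbalance(b) # -0.1 GtC/yr each year
#' @export
budget_imbalance <- function(budget) {
  w <- budget_wide(budget)
  v <- w$value
  s <- w$sigma
  bim <- v$E_FOS + v$E_LUC - v$S_LAND - v$S_OCEAN - v$G_ATM
  sig <- sqrt(s$E_FOS^2 + s$E_LUC^2 + s$S_LAND^2 + s$S_OCEAN^2 + s$G_ATM^2)
  flux_series("B_IM", v$year, bim, sigma = NULL) |>
    mutate(sigma = as.numeric(sig))
}

#' Combine independent 1-sigma uncertainties in quadrature
#'
#' Square root of the sum of squares, the standard rule for combining
#' independent error sources in budget accounting.
#'
#' @param sigmas numeric vector of non-negative 1-sigma values.
#' @return A single non-negative number; `NA` if any input is `NA`.
#' @examples
#' quadrature(c(0.9, 0.7)) # 1.14, the net-land uncertainty
#' @export
quadrature <- function(sigmas) {
  if (any(sigmas < 0, na.rm = TRUE)) {
    abort("Uncertainties must be non-negative.")
  }
  sqrt(sum(sigmas^2))
}

#' Decadal (windowed) mean of an annual series
#'
#' Arithmetic mean of the annual values over `first_year:last_year`. The
#' reported sigma is the mean of the annual sigmas -- uncertainty on these
#' fluxes is dominated by systematic (fully correlated) error, so averaging
#' years does not shrink it by sqrt(n).
#'
#' @param series flux-series tibble.
#' @param first_year,last_year inclusive window bounds; must lie inside the
#'   series coverage.
#' @return One-row tibble: `component`, `first_year`, `last_year`, `value`,
#'   `sigma`, `n_years`.
#' @export
decadal_mean <- function(series, first_year, last_year) {
  series <- check_flux_series(series)
  if (first_year > last_year) abort("`first_year` must not exceed `last_year`.")
  if (first_year < min(series$year) || last_year > max(series$year)) {
    abort("Window lies outside the series coverage.")
  }
  win <- filter(series, .data$year >= first_year, .data$year <= last_year)
  tibble(
    component = win$component[1],
    first_year = as.integer(first_year),
    last_year = as.integer(last_year),
    value = mean(win$value),
    sigma = if (all(is.na(win$sigma))) NA_real_ else mean(win$sigma),
    n_years = nrow(win)
  )
}

#' Ordinary-least-squares trend of an annual series
#'
#' Fits value ~ year by OLS and reports the slope rescaled to GtC/yr per
#' decade, its standard error, and the two-sided t-test p-value. No
#' autocorrelation correction is applied; the iid-error t-test matches the
#' convention used in budget-imbalance trend reporting.
#'
#' @param series flux-series tibble with at least 3 years.
#' @return An object of class `"flux_trend"`; use [tidy()] / [glance()] for
#'   tibble output. Fields: `slope` (GtC/yr per decade), `slope_se`,
#'   `p_value`, `n_years`, `component`.
#' @export
linear_trend <- function(series) {
  series <- check_flux_series(series)
  if (nrow(series) < 3L) {
    abort("At least 3 years are required for a trend estimate.")
  }
  fit <- lm(value ~ year, data = series)
  sm <- summary(fit)$coefficients
  structure(
    list(
      component = series$component[1],
      slope = unname(sm["year", "Estimate"]) * 10,
      slope_se = unname(sm["year", "Std. Error"]) * 10,
      p_value = unname(sm["year", "Pr(>|t|)"]),
      n_years = nrow(series),
      fit = fit
    ),
    class = "flux_trend"
  )
}

#' @export
print.flux_trend <- function(x, ...) {
  cat(
    sprintf(
      "Trend of %s: %+.3f +/- %.3f GtC/yr per decade (P = %.3g, n = %d)\n",
      x$component, x$slope, x$slope_se, x$p_value, x$n_years
    )
  )
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x a `"flux_trend"` object from [linear_trend()].
#' @param ... unused.
#' @return `tidy()`: one row per quantity (slope per decade, se, p-value);
#'   `glance()`: a one-row model summary.
#' @importFrom generics tidy
#' @export
tidy.flux_trend <- function(x, ...) {
  tibble(
    component = x$component,
    term = "slope_per_decade",
    estimate = x$slope,
    std.error = x$slope_se,
    p.value = x$p_value
  )
}

#' @rdname tidy.flux_trend
#' @importFrom generics glance
#' @export
glance.flux_trend <- function(x, ...) {
  tibble(
    component = x$component,
    slope_per_decade = x$slope,
    slope_se = x$slope_se,
    p.value = x$p_value,
    n_years = x$n_years,
    significant_1pct = x$p_value < 0.01
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' Convert between ppm and GtC
#'
#' Atmospheric CO2 burden conversion with the standard factor 2.124 GtC per
#' ppm: multiplies for ppm to GtC, divides for GtC to ppm.
#'
#' @param value numeric amount(s) to convert.
#' @param direction `"ppm_to_gtc"` or `"gtc_to_ppm"`.
#' @param factor conversion factor in GtC/ppm, strictly positive.
#' @return Converted numeric value(s).
#' @examples
#' ppm_gtc(1, "ppm_to_gtc") # 2.124
#' ppm_gtc(17.63, "gtc_to_ppm") # 8.30
#' @export
ppm_gtc <- function(value, direction = c("ppm_to_gtc", "gtc_to_ppm"),
                    factor = 2.124) {
  direction <- match.arg(direction)
  if (!is.numeric(factor) || factor <= 0) {
    abort("`factor` must be a positive number.")
  }
  if (direction == "ppm_to_gtc") value * factor else value / factor
}

#' Airborne fraction
#'
#' Fraction of anthropogenic CO2 input that stays in the atmosphere. The
#' default definition is annual: AF_t = G_ATM_t / (E_FOS_t + E_LUC_t). A
#' `"cumulative"` mode (running sums in numerator and denominator) is
#' provided because the literature is not unanimous on the definition.
#'
#' @param budget long budget tibble with the five components.
#' @param mode `"annual"` (default) or `"cumulative"`.
#' @return Flux-series-shaped tibble with `component = "AF"`, dimensionless
#'   values.
#' @export
airborne_fraction <- function(budget, mode = c("annual", "cumulative")) {
  mode <- match.arg(mode)
  w <- budget_wide(budget)$value
  num <- w$G_ATM
  den <- w$E_FOS + w$E_LUC
  if (mode == "cumulative") {
    num <- cumsum(num)
    den <- cumsum(den)
  }
  if (any(den <= 0)) {
    abort("Airborne fraction undefined: total emissions must be positive.")
  }
  tibble(
    component = "AF", year = w$year, value = num / den, sigma = NA_real_
  )
}
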