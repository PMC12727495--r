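#' Climate-change effect on a carbon sink
#'
#' Vegetation and ocean models run paired historical simulations: one with
#' observed CO2 and climate, and one with the same CO2 increase but constant
#' (early-period) climate forcing. Their difference isolates the effect of
#' climate change on the sink. The effect is stored as positive weakening,
#' effect(t) = fixed_climate(t) - full(t): positive values mean climate
#' change reduced the sink. (Figures conventionally plot the effect as a
#' negative flux; negate for display.)
#'
#' @param full_run flux-series tibble, the CO2-plus-climate simulation.
#' @param fixed_climate_run flux-series tibble, the constant-climate
#'   simulation.
#' @return Flux-series tibble with component `"<component>_clim"`.
#' @export
climate_effect <- function(full_run, fixed_climate_run) {
  full_run <- check_flux_series(full_run)
  fixed_climate_run <- check_flux_series(fixed_climate_run)
  check_aligned(full_run, fixed_climate_run, c("full run", "fixed-climate run"))
  flux_series(
    paste0(full_run$component[1], "_clim"),
    full_run$year,
    fixed_climate_run$value - full_run$value
  )
}

#' Atmospheric-growth contribution of sink weakening
#'
#' The part of the climate-driven sink weakening that accumulates in the
#' atmosphere: G_ATM_clim(t) = AF(t) x (S_LAND_clim(t) + S_OCEAN_clim(t)),
#' where AF is the airborne fraction. The remainder is re-absorbed by the
#' (CO2-sensitive) sinks themselves.
#'
#' @param af airborne-fraction series (from [airborne_fraction()]) or a
#'   single constant in `[0, 1]`.
#' @param land_eff,ocean_eff climate-effect series from [climate_effect()],
#'   positive weakening.
#' @return Flux-series tibble with `component = "G_ATM_clim"` (GtC/yr).
#' @export
gatm_clim <- function(af, land_eff, ocean_eff) {
  land_eff <- check_flux_series(land_eff)
  ocean_eff <- check_flux_series(ocean_eff)
  check_aligned(land_eff, ocean_eff, c("land effect", "ocean effect"))
  if (is.numeric(af) && length(af) == 1L) {
    af_val <- rep(af, nrow(land_eff))
  } else {
    af <- check_flux_series(af)
    check_aligned(af, land_eff, c("airborne fraction", "land effect"))
    af_val <- af$value
  }
  if (any(af_val < 0 | af_val > 1)) {
    abort("Airborne fraction must lie in [0, 1].")
  }
  flux_series(
    "G_ATM_clim", land_eff$year, af_val * (land_eff$value + ocean_eff$value)
  )
}

#' Cumulative atmospheric concentration contribution
#'
#' Running sum of an atmospheric mass flux converted to ppm:
#' cumulative(t) = sum from base_year to t of G_ATM_clim / factor.
#'
#' @param gatm_clim_series flux-series tibble from [gatm_clim()].
#' @param factor conversion factor, GtC/ppm (default 2.124).
#' @param base_year start of the accumulation (default 1960).
#' @return Tibble (`year`, `value`) with cumulative ppm since `base_year`.
#' @export
cumulative_ppm <- function(gatm_clim_series, factor = 2.124,
                           base_year = 1960) {
  gatm_clim_series <- check_flux_series(gatm_clim_series)
  if (factor <= 0) abort("`factor` must be positive.")
  x <- filter(gatm_clim_series, .data$year >= base_year)
  tibble(
    year = x$year,
    value = cumsum(x$value / factor)
  )
}

#' Percentage sink reduction from climate change
#'
#' Relative weakening of a sink against its no-climate-change counterfactual
#' (the realised sink plus the weakening): 100 x effect / (sink + effect),
#' reported negative since it is a reduction.
#'
#' @param effect decadal-mean climate effect (positive weakening, GtC/yr).
#' @param sink decadal-mean realised sink (GtC/yr).
#' @return Percentage (negative).
#' @examples
#' percent_reduction(0.8, 2.7) # about -23%
#' @export
percent_reduction <- function(effect, sink) {
  counterfactual <- sink + effect
  if (any(counterfactual <= 0)) {
    abort("Counterfactual sink (sink + effect) must be positive.")
  }
  -100 * effect / counterfactual
}

#' Regional decomposition of the net land CO2 flux
#'
#' Decomposes the decadal net land flux per region into the response to
#' atmospheric CO2 increase (a sink), the climate-change impact (a source)
#' and land-use change (a source): net = co2 - climate - luc, with the net
#' uncertainty as the quadrature of the three component sigmas.
#'
#' @param regions tibble with one row per region: columns `region`, `co2`,
#'   `climate`, `luc` (decadal fluxes, GtC/yr, all entered as positive
#'   magnitudes under the stated sign convention) and optional sigma columns
#'   `co2_sigma`, `climate_sigma`, `luc_sigma`.
#' @return Tibble with `net` and `net_sigma` columns appended.
#' @export
regional_decomposition <- function(regions) {
  regions <- as_tibble(regions)
  need <- c("region", "co2", "climate", "luc")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in c("co2_sigma", "climate_sigma", "luc_sigma")) {
    if (!col %in% names(regions)) regions[[col]] <- NA_real_
  }
  regions |>
    mutate(
      net = .data$co2 - .data$climate - .data$luc,
      net_sigma = sqrt(
        .data$co2_sigma^2 + .data$climate_sigma^2 + .data$luc_sigma^2
      )
    )
}

#' Read a regional decomposition from CSV
#'
#' One row per (region, component) with columns `region`, `component`
#' (`co2`, `climate` or `luc`), `value_gtc_per_yr`, `sigma`; returns the
#' wide per-region layout accepted by [regional_decomposition()].
#'
#' @param path CSV file path.
#' @return Wide tibble, one row per region.
#' @export
read_regions_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("region", "component", "value_gtc_per_yr")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(raw$component %in% c("co2", "climate", "luc"))) {
    abort("`component` must be one of co2, climate, luc.")
  }
  if (!"sigma" %in% names(raw)) raw$sigma <- NA_real_
  values <- tidyr::pivot_wider(
    raw[, c("region", "component", "value_gtc_per_yr")],
    names_from = "component", values_from = "value_gtc_per_yr"
  )
  sigmas <- tidyr::pivot_wider(
    raw[, c("region", "component", "sigma")],
    names_from = "component", values_from = "sigma"
  ) |>
    rename(
      co2_sigma = "co2", climate_sigma = "climate", luc_sigma = "luc"
    )
  left_join(values, sigmas, by = "region")
}
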